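# Pairwise simple-matching engine.
#
# For two diploid locus pairs stored sorted ascending, the multiset
# intersection size is 2 iff the sorted pairs are identical, else 1 if any
# allele is shared, else 0 (exact for pairs of size two, which is what the
# greedy equal-size matching reduces to).
similarity_engine <- function(tbl, panel) {
  n <- nrow(tbl)
  matches <- matrix(0L, n, n)
  shared <- matrix(0L, n, n)
  for (loc in panel$locus) {
    p1 <- tbl[[paste0(loc, ".1")]]
    p2 <- tbl[[paste0(loc, ".2")]]
    present <- !is.na(p1)
    both <- outer(present, present, "&")
    e11 <- outer(p1, p1, "==")
    e22 <- outer(p2, p2, "==")
    e12 <- outer(p1, p2, "==")
    ident <- e11 & e22
    anyeq <- e11 | e22 | e12 | t(e12)
    m <- ifelse(ident, 2L, ifelse(anyeq, 1L, 0L))
    m[!both | is.na(m)] <- 0L
    matches <- matches + m
    shared <- shared + both
  }
  similarity <- ifelse(shared > 0, matches / (2 * shared), NA_real_)
  diag(similarity) <- ifelse(diag(shared) > 0, 1, NA_real_)
  dimnames(matches) <- dimnames(shared) <- dimnames(similarity) <-
    list(tbl$accession_id, tbl$accession_id)
  list(matches = matches, shared = shared, similarity = similarity)
}

#' Pairwise fingerprint similarity between accessions
#'
#' Computes the simple matching coefficient between every pair of accessions:
#' over the loci non-missing in both genotypes, alleles are matched as equal
#' binned sizes (multiset matching within each diploid pair) and similarity is
#' `matching_alleles / (2 * shared_loci)`. Pairs sharing fewer than
#' `min_shared` loci are flagged not comparable (`similarity = NA`).
#'
#' @param records Harmonized genotype tibble.
#' @param panel The [marker_panel()].
#' @param min_shared Minimum number of mutually typed loci for a comparison
#'   (default 8 of 16).
#' @return A tibble with one row per unordered pair: `id1`, `id2`,
#'   `shared_loci`, `matching_alleles`, `similarity`, `comparable`.
#' @export
ssr_similarity <- function(records, panel, min_shared = 8L) {
  eng <- similarity_engine(records, panel)
  n <- nrow(records)
  idx <- which(upper.tri(eng$shared), arr.ind = TRUE)
  out <- tibble::tibble(
    id1 = records$accession_id[idx[, 1]],
    id2 = records$accession_id[idx[, 2]],
    shared_loci = eng$shared[idx],
    matching_alleles = eng$matches[idx],
    similarity = eng$similarity[idx],
    comparable = eng$shared[idx] >= min_shared
  )
  out$similarity[!out$comparable] <- NA_real_
  out
}

#' Group accessions into molecular groups
#'
#' Builds a graph with an edge between every comparable pair whose similarity
#' exceeds `threshold` and takes connected components (single linkage) as
#' molecular groups: every accession reachable through a chain of
#' above-threshold matches lands in one group. Within each group the
#' representative genotype is the most frequent exact multilocus genotype,
#' ties broken by completeness (fewer missing loci) then by accession id.
#'
#' @param records Harmonized genotype tibble.
#' @param panel The [marker_panel()].
#' @param threshold Similarity above which two accessions are considered
#'   identical (default 0.90).
#' @param min_shared Passed to the similarity engine.
#' @return A tibble of class `molecular_groups`: `accession_id`, `group_id`
#'   (`"G001"` ... sorted by group size, descending), `is_representative`.
#'   Attributes: `representatives` (per-group representative genotype and its
#'   support count), `transitive` (ids of groups held together only by
#'   chained matches), `threshold`.
#' @export
build_groups <- function(records, panel, threshold = 0.90, min_shared = 8L) {
  eng <- similarity_engine(records, panel)
  n <- nrow(records)
  comparable <- eng$shared >= min_shared
  adj <- !is.na(eng$similarity) & eng$similarity > threshold & comparable
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership

  comp_rank <- rank(-tabulate(comp), ties.method = "first")
  group_id <- sprintf("G%03d", comp_rank[comp])

  cols <- locus_cols(panel)
  geno_key <- apply(as.matrix(records[, cols]), 1, function(r) {
    paste(ifelse(is.na(r), "?", r), collapse = "/")
  })
  n_missing <- rowSums(is.na(records[, cols]))

  membership <- tibble::tibble(
    accession_id = records$accession_id,
    group_id = group_id,
    is_representative = FALSE
  )
  rep_rows <- integer(0)
  support <- integer(0)
  transitive <- character(0)
  for (gid in unique(group_id)) {
    members <- which(group_id == gid)
    keys <- geno_key[members]
    freq <- table(keys)
    top <- max(freq)
    cand <- members[keys %in% names(freq)[freq == top]]
    cand <- cand[order(n_missing[cand], records$accession_id[cand])]
    rep_rows <- c(rep_rows, cand[1])
    support <- c(support, as.integer(top))
    if (length(members) > 1) {
      sub <- eng$similarity[members, members, drop = FALSE]
      low <- sub[upper.tri(sub)]
      if (any(is.na(low) | low <= threshold)) transitive <- c(transitive, gid)
    }
  }
  membership$is_representative[rep_rows] <- TRUE
  reps <- dplyr::bind_cols(
    tibble::tibble(group_id = group_id[rep_rows],
                   accession_id = records$accession_id[rep_rows],
                   support = support),
    records[rep_rows, cols]
  )
  reps <- dplyr::arrange(reps, .data$group_id)
  attr(membership, "representatives") <- reps
  attr(membership, "transitive") <- transitive
  attr(membership, "threshold") <- threshold
  class(membership) <- c("molecular_groups", class(membership))
  membership
}

#' Extract representative genotypes, one per molecular group
#'
#' Returns a genotype tibble with one row per molecular group (the unique
#' genotypes of a deduplicated collection), suitable as input for diversity
#' and phylogeny computations.
#'
#' @param groups A [build_groups()] result.
#' @param records The genotype tibble the groups were built from.
#' @return A genotype tibble with one row per group.
#' @export
representative_genotypes <- function(groups, records) {
  reps <- attr(groups, "representatives")
  out <- records[match(reps$accession_id, records$accession_id), , drop = FALSE]
  out$group_id <- reps$group_id
  tibble::as_tibble(out)
}

category_labels <- c(
  `1` = "true_to_type",
  `3` = "own_group_no_reference",
  `4` = "no_pomological_determination",
  `5` = "approved_with_reservation"
)

#' Assign trueness-to-type categories
#'
#' Combines molecular groups with pomological determinations into the
#' four-category trueness-to-type assessment used for sweet cherry curation
#' (category 2 is reserved for sour cherries and never emitted):
#'
#' * 1 `true_to_type`: pomologically determined, named consistently with the
#'   group consensus (the majority determined name among group members); an
#'   accession whose own determination conflicts with the consensus is
#'   reported under the consensus name with `relabel = TRUE`.
#' * 3 `own_group_no_reference`: forms its own molecular group but no
#'   pomological reference exists for its name.
#' * 4 `no_pomological_determination`: pomological determination impossible.
#' * 5 `approved_with_reservation`: determination approved with reservation.
#'
#' A group whose two most frequent determined names are equally supported has
#' no consensus: its determined members are reported `unresolved` and left
#' uncategorized.
#'
#' @param groups A [build_groups()] result.
#' @param records The genotype tibble with `pomological_status` and
#'   `determined_name`.
#' @param reference_names Character vector of cultivar names with pomological
#'   references.
#' @return A tibble: `accession_id`, `group_id`, `category` (integer, `NA`
#'   when unresolved), `category_label`, `resolved_name`, `relabel`,
#'   `unresolved`.
#' @export
assign_categories <- function(groups, records, reference_names = character(0)) {
  stopifnot(nrow(groups) == nrow(records))
  recs <- records[match(groups$accession_id, records$accession_id), ]
  out <- tibble::tibble(
    accession_id = groups$accession_id,
    group_id = groups$group_id,
    category = NA_integer_,
    resolved_name = NA_character_,
    relabel = FALSE,
    unresolved = FALSE
  )
  consensus <- vapply(unique(groups$group_id), function(gid) {
    m <- which(groups$group_id == gid)
    det <- recs$determined_name[m][recs$pomological_status[m] == "determined"]
    det <- det[!is.na(det)]
    if (length(det) == 0) return(NA_character_)
    freq <- sort(table(det), decreasing = TRUE)
    if (length(freq) > 1 && freq[1] == freq[2]) return("__TIE__")
    names(freq)[1]
  }, character(1))
  names(consensus) <- unique(groups$group_id)

  for (i in seq_len(nrow(out))) {
    st <- recs$pomological_status[i]
    cons <- consensus[[out$group_id[i]]]
    if (st == "determined") {
      if (identical(cons, "__TIE__")) {
        out$unresolved[i] <- TRUE
      } else {
        out$category[i] <- 1L
        out$resolved_name[i] <- cons
        out$relabel[i] <- !identical(recs$determined_name[i], cons)
      }
    } else if (st == "no_reference") {
      out$category[i] <- 3L
    } else if (st == "not_determined") {
      out$category[i] <- 4L
    } else if (st == "with_reservation") {
      out$category[i] <- 5L
      out$resolved_name[i] <- recs$determined_name[i]
    }
  }
  out$category_label <- unname(category_labels[as.character(out$category)])
  out
}
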