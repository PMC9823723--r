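#' Per-locus allele frequencies
#'
#' Counts gene copies per allele and locus: each individual typed at a locus
#' contributes two copies (homozygotes are stored as a duplicated size).
#' Loci typed in no individual are excluded with a warning.
#'
#' @param records Harmonized genotype tibble (typically the deduplicated
#'   representative genotypes, one per molecular group).
#' @param panel The [marker_panel()].
#' @return A tibble of class `allele_freqs`: `locus`, `allele`, `count`,
#'   `freq`, `n_typed` (individuals typed at the locus). Frequencies sum to 1
#'   within each locus.
#' @export
allele_frequencies <- function(records, panel) {
  out <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    loc <- panel$locus[i]
    a <- records[[paste0(loc, ".1")]]
    b <- records[[paste0(loc, ".2")]]
    typed <- !is.na(a)
    if (!any(typed)) {
      warning("locus ", loc, " typed in 0 individuals; excluded", call. = FALSE)
      next
    }
    copies <- c(a[typed], b[typed])
    cnt <- table(copies)
    out[[i]] <- tibble::tibble(
      locus = loc,
      allele = as.integer(names(cnt)),
      count = as.integer(cnt),
      freq = as.integer(cnt) / length(copies),
      n_typed = sum(typed)
    )
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("allele_freqs", class(res))
  res
}

# named list of per-locus frequency vectors (names = allele sizes)
freq_list <- function(freqs) {
  lapply(split(freqs, freqs$locus), function(d) {
    rlang::set_names(d$freq, d$allele)
  })
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, computed by the exact rarefaction formula
#' `Ar(g) = sum_i [1 - C(N - n_i, g) / C(N, g)]` with `n_i` the observed
#' copies of allele i and `N` the total copies at the locus. Standardizing
#' `g` corrects allele counts for unequal missing data across loci.
#'
#' @param freqs An [allele_frequencies()] result.
#' @param g Number of gene copies to rarefy to; must satisfy
#'   `2 <= g <= 2 * min(N)` over the included loci. Default: `2 * min(N)`.
#' @return A tibble `locus`, `Ar`, `g`.
#' @export
allelic_richness <- function(freqs, g = NULL) {
  n_by_locus <- vapply(split(freqs$count, freqs$locus), sum, numeric(1))
  if (is.null(g)) g <- 2L * as.integer(min(n_by_locus) / 2L)
  if (g < 2) stop("g must be at least 2 gene copies")
  if (g > min(n_by_locus)) {
    stop("g (", g, ") exceeds the smallest locus sample of ",
         min(n_by_locus), " gene copies")
  }
  ar <- vapply(split(freqs, freqs$locus), function(d) {
    N <- sum(d$count)
    sum(1 - exp(lchoose(N - d$count, g) - lchoose(N, g)))
  }, numeric(1))
  tibble::tibble(locus = names(ar), Ar = unname(ar), g = g)
}

#' Per-locus probability of identity
#'
#' The probability that two individuals drawn at random share a genotype at a
#' locus, under Hardy-Weinberg proportions:
#' `PI = 2 (sum p_i^2)^2 - sum p_i^4`, and its conservative full-sib variant
#' `PIsib = 0.25 + 0.5 sum p_i^2 + 0.5 (sum p_i^2)^2 - 0.25 sum p_i^4`.
#' Cumulative products over loci, taken in ascending order of the per-locus
#' value, give the multilocus identity probability of the best k-locus
#' combination.
#'
#' @param freqs An [allele_frequencies()] result.
#' @return A tibble sorted by ascending `PI`: `locus`, `PI`, `PIsib`,
#'   `cum_PI` (running product in this order), `rank_PIsib` and `cum_PIsib`
#'   (running product in ascending-`PIsib` order).
#' @export
pi_profile <- function(freqs) {
  fl <- freq_list(freqs)
  pi1 <- vapply(fl, function(p) 2 * sum(p^2)^2 - sum(p^4), numeric(1))
  pis <- vapply(fl, function(p) {
    0.25 + 0.5 * sum(p^2) + 0.5 * sum(p^2)^2 - 0.25 * sum(p^4)
  }, numeric(1))
  out <- tibble::tibble(locus = names(fl), PI = unname(pi1),
                        PIsib = unname(pis))
  out <- dplyr::arrange(out, .data$PI, .data$locus)
  out$cum_PI <- cumprod(out$PI)
  out$rank_PIsib <- rank(out$PIsib, ties.method = "first")
  out$cum_PIsib <- cumprod(sort(out$PIsib))[out$rank_PIsib]
  out
}

#' Per-locus diversity parameters
#'
#' The standard germplasm-characterization table: per locus the number of
#' typed individuals (`N`), distinct alleles (`Na`), effective alleles
#' (`Ne = 1 / sum p_i^2`), observed heterozygosity (`Ho` = heterozygotes/N),
#' expected heterozygosity (`He = 1 - sum p_i^2`), rarefied allelic richness
#' (`Ar`), and the identity probabilities `PI`/`PIsib`. Column means (via
#' [generics::glance()]) are unweighted arithmetic means across loci.
#'
#' @param records Harmonized genotype tibble (deduplicated).
#' @param panel The [marker_panel()].
#' @param g Gene copies for rarefaction (default `2 * min(N)`).
#' @return A tibble of class `locus_diversity` with one row per locus.
#' @export
locus_diversity <- function(records, panel, g = NULL) {
  freqs <- allele_frequencies(records, panel)
  fl <- freq_list(freqs)
  ar <- allelic_richness(freqs, g)
  pis <- pi_profile(freqs)
  loci <- panel$locus[panel$locus %in% names(fl)]
  rows <- lapply(loci, function(loc) {
    p <- fl[[loc]]
    a <- records[[paste0(loc, ".1")]]
    b <- records[[paste0(loc, ".2")]]
    typed <- !is.na(a)
    tibble::tibble(
      locus = loc,
      N = sum(typed),
      Na = length(p),
      Ne = 1 / sum(p^2),
      Ho = sum(a[typed] != b[typed]) / sum(typed),
      He = 1 - sum(p^2),
      Ar = ar$Ar[match(loc, ar$locus)],
      PI = pis$PI[match(loc, pis$locus)],
      PIsib = pis$PIsib[match(loc, pis$locus)]
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "g") <- ar$g[1]
  class(out) <- c("locus_diversity", class(out))
  out
}

#' Minimal discriminating marker set
#'
#' Finds how few loci suffice to tell all genotypes in a (deduplicated)
#' collection apart. In `empirical` mode loci are added in ascending-PI order
#' until every genotype pair differs at at least one included locus (a pair
#' counts as differing only at loci typed in both). In `sib` mode loci are
#' added in ascending-PIsib order until the cumulative PIsib drops below
#' `threshold` (default `1 / choose(n, 2)`, i.e. less than one chance-identical
#' pair expected among all pairs of relatives).
#'
#' @param records Deduplicated genotype tibble.
#' @param panel The [marker_panel()].
#' @param mode `"empirical"` or `"sib"`.
#' @param threshold Stopping threshold for `sib` mode.
#' @return A tibble of class `marker_set` with the selected loci in inclusion
#'   order: `locus`, `PI`, `PIsib`, `cum_PI`, `cum_PIsib`,
#'   `unresolved_pairs` (empirical mode: pairs still identical after adding
#'   the locus). Attributes `size` (loci needed) and `unresolved` (tibble of
#'   indistinguishable pairs when the full panel fails to separate them).
#' @export
minimal_marker_set <- function(records, panel,
                               mode = c("empirical", "sib"),
                               threshold = NULL) {
  mode <- match.arg(mode)
  freqs <- allele_frequencies(records, panel)
  prof <- pi_profile(freqs)
  n <- nrow(records)

  if (mode == "sib") {
    if (is.null(threshold)) threshold <- 1 / choose(n, 2)
    ord <- dplyr::arrange(prof, .data$PIsib, .data$locus)
    cum <- cumprod(ord$PIsib)
    k <- which(cum < threshold)[1]
    size <- if (is.na(k)) nrow(ord) else k
    out <- ord[seq_len(size), c("locus", "PI", "PIsib")]
    out$cum_PI <- cumprod(out$PI)
    out$cum_PIsib <- cum[seq_len(size)]
    out$unresolved_pairs <- NA_integer_
    attr(out, "size") <- size
    attr(out, "achieved") <- !is.na(k)
    attr(out, "mode") <- mode
    class(out) <- c("marker_set", class(out))
    return(out)
  }

  # empirical: resolve all pairs
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  unresolved <- rep(TRUE, nrow(pair_idx))
  picked <- integer(0)
  rows <- list()
  for (k in seq_len(nrow(prof))) {
    loc <- prof$locus[k]
    a <- records[[paste0(loc, ".1")]]
    b <- records[[paste0(loc, ".2")]]
    i <- pair_idx[, 1]; j <- pair_idx[, 2]
    differs <- !is.na(a[i]) & !is.na(a[j]) &
      (a[i] != a[j] | b[i] != b[j])
    unresolved <- unresolved & !differs
    picked <- c(picked, k)
    rows[[length(rows) + 1]] <- tibble::tibble(
      locus = loc, PI = prof$PI[k], PIsib = prof$PIsib[k],
      unresolved_pairs = sum(unresolved)
    )
    if (!any(unresolved)) break
  }
  out <- dplyr::bind_rows(rows)
  out$cum_PI <- cumprod(out$PI)
  out$cum_PIsib <- cumprod(out$PIsib)
  out <- out[, c("locus", "PI", "PIsib", "cum_PI", "cum_PIsib",
                 "unresolved_pairs")]
  attr(out, "size") <- nrow(out)
  attr(out, "achieved") <- !any(unresolved)
  if (any(unresolved)) {
    attr(out, "unresolved") <- tibble::tibble(
      id1 = records$accession_id[pair_idx[unresolved, 1]],
      id2 = records$accession_id[pair_idx[unresolved, 2]]
    )
  }
  attr(out, "mode") <- mode
  class(out) <- c("marker_set", class(out))
  out
}

#' Pairwise Fst between genotype clusters
#'
#' Wright's fixation index between every pair of supplied cluster labels,
#' using the heterozygosity-based estimator: per locus
#' `Fst = (Ht - Hs) / Ht` where `Hs` is the unweighted mean within-cluster
#' expected heterozygosity and `Ht` the expected heterozygosity of the
#' unweighted mean allele frequencies of the two clusters; the reported value
#' is the mean over loci with `Ht > 0`. Clusters with fewer than two
#' genotypes are excluded with a warning.
#'
#' @param records Harmonized genotype tibble.
#' @param labels Cluster label per record (vector aligned with `records`, or
#'   the name of a column of `records`).
#' @param panel The [marker_panel()].
#' @return A tibble `cluster1`, `cluster2`, `fst`.
#' @export
fst_pairwise <- function(records, labels, panel) {
  if (is.character(labels) && length(labels) == 1 && labels %in% names(records)) {
    labels <- records[[labels]]
  }
  stopifnot(length(labels) == nrow(records))
  tab <- table(labels)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    warning("cluster(s) with fewer than 2 genotypes excluded: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(names(tab), small)
  if (length(keep) < 2) stop("need at least two clusters of size >= 2")
  fl <- lapply(keep, function(cl) {
    freq_list(allele_frequencies(records[labels == cl, , drop = FALSE], panel))
  })
  names(fl) <- keep
  pairs <- utils::combn(keep, 2)
  out <- apply(pairs, 2, function(pr) {
    loci <- intersect(names(fl[[pr[1]]]), names(fl[[pr[2]]]))
    per_locus <- vapply(loci, function(loc) {
      p1 <- fl[[pr[1]]][[loc]]; p2 <- fl[[pr[2]]][[loc]]
      alleles <- union(names(p1), names(p2))
      q1 <- rlang::set_names(rep(0, length(alleles)), alleles)
      q2 <- q1
      q1[names(p1)] <- p1; q2[names(p2)] <- p2
      hs <- mean(c(1 - sum(q1^2), 1 - sum(q2^2)))
      pbar <- (q1 + q2) / 2
      ht <- 1 - sum(pbar^2)
      if (ht > 0) (ht - hs) / ht else NA_real_
    }, numeric(1))
    mean(per_locus, na.rm = TRUE)
  })
  tibble::tibble(cluster1 = pairs[1, ], cluster2 = pairs[2, ], fst = out)
}
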