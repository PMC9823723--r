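#' Dissimilarity matrix from SSR fingerprints
#'
#' `1 - similarity` under the simple matching coefficient of
#' [ssr_similarity()]. Every pair must be comparable (at least `min_shared`
#' mutually typed loci); incomparable pairs are an error listing the pairs.
#'
#' @param records Harmonized genotype tibble.
#' @param panel The [marker_panel()].
#' @param min_shared Minimum mutually typed loci per pair.
#' @return A symmetric numeric matrix with zero diagonal, dimnames =
#'   accession ids.
#' @export
dissimilarity_matrix <- function(records, panel, min_shared = 8L) {
  eng <- similarity_engine(records, panel)
  bad <- which(eng$shared < min_shared & upper.tri(eng$shared), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    pairs <- paste(records$accession_id[bad[, 1]],
                   records$accession_id[bad[, 2]], sep = " ~ ")
    stop("pair(s) share fewer than ", min_shared, " typed loci: ",
         paste(utils::head(pairs, 10), collapse = "; "),
         if (length(pairs) > 10) " ..." else "")
  }
  d <- 1 - eng$similarity
  diag(d) <- 0
  d
}

#' Unweighted neighbor joining
#'
#' Classic Saitou-Nei neighbor joining on a dissimilarity matrix: at each
#' step the pair minimizing the Q criterion is joined. Ties in Q are broken
#' toward the lexicographically lowest label pair (a cluster is labeled by
#' the smallest tip label it contains), so the result is deterministic.
#' Negative branch lengths are clamped to zero; the total clamped deficit is
#' recorded in attribute `negative_deficit`.
#'
#' @param d Symmetric dissimilarity matrix with dimnames (n >= 3).
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  node_id <- seq_len(n)              # active node ids (tips 1..n)
  node_name <- labels                # smallest tip label per active cluster
  next_internal <- n + 1L
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  deficit <- 0

  clamp <- function(x) {
    if (x < 0) { deficit <<- deficit + abs(x); 0 } else x
  }

  while (length(node_id) > 3) {
    r <- length(node_id)
    rs <- rowSums(d)
    q <- (r - 2) * d - outer(rs, rs, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      nm <- sort(c(node_name[ij[1]], node_name[ij[2]]))
      paste(nm, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]

    li <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    new_id <- next_internal
    next_internal <- next_internal + 1L
    edges <- rbind(edges, c(new_id, node_id[i]), c(new_id, node_id[j]))
    lens <- c(lens, clamp(li), clamp(lj))

    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    node_id <- c(node_id[keep], new_id)
    node_name <- c(node_name[keep], min(node_name[c(i, j)]))
  }

  root <- next_internal
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  edges <- rbind(edges, c(root, node_id[1]), c(root, node_id[2]),
                 c(root, node_id[3]))
  lens <- c(lens, clamp(l1), clamp(l2), clamp(l3))

  # renumber internal nodes to ape convention: root = n+1, then descendants
  internal <- c(root, setdiff(sort(unique(edges[edges > n])), root))
  remap <- rlang::set_names(seq(n + 1L, n + length(internal)), internal)
  edges_m <- matrix(edges, ncol = 2)
  edges_m[edges_m > n] <- remap[as.character(edges_m[edges_m > n])]
  storage.mode(edges_m) <- "integer"

  tree <- list(edge = edges_m, edge.length = lens, tip.label = labels,
               Nnode = length(internal))
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "negative_deficit") <- deficit
  tree
}

#' Neighbor-joining tree with locus-resampling bootstrap supports
#'
#' Builds the full-data NJ tree from the simple-matching dissimilarity
#' matrix, then resamples panel loci with replacement `B` times, rebuilds the
#' tree for each replicate, and attaches to each internal edge the percentage
#' of replicate trees containing the same bipartition (via
#' `ape::prop.clades`). A single integer seed drives all replicates
#' (replicate r uses the deterministic substream `seed + r`).
#'
#' @param records Harmonized genotype tibble (>= 4 accessions).
#' @param panel The [marker_panel()] (>= 2 loci).
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param min_shared Minimum mutually typed loci per pair.
#' @return An `ape::phylo` tree whose `node.label` holds integer support
#'   percentages (root label empty).
#' @export
bootstrap_support <- function(records, panel, B = 1000L, seed = 1L,
                              min_shared = 8L) {
  if (B < 1) stop("B must be at least 1")
  if (nrow(records) < 4) stop("need at least 4 genotypes")
  if (nrow(panel) < 2) stop("need at least 2 loci")
  tree <- neighbor_joining(dissimilarity_matrix(records, panel, min_shared))
  reps <- vector("list", B)
  for (r in seq_len(B)) {
    idx <- withr::with_seed(seed + r,
                            sample.int(nrow(panel), replace = TRUE))
    pnl <- panel[idx, , drop = FALSE]
    # resampled loci need unique column identities
    pnl$locus <- make.unique(pnl$locus, sep = "~rep")
    rec <- records["accession_id"]
    for (k in seq_along(idx)) {
      src <- panel$locus[idx[k]]
      rec[[paste0(pnl$locus[k], ".1")]] <- records[[paste0(src, ".1")]]
      rec[[paste0(pnl$locus[k], ".2")]] <- records[[paste0(src, ".2")]]
    }
    dm <- 1 - similarity_engine(rec, pnl)$similarity
    diag(dm) <- 0
    dm[is.na(dm)] <- 1
    reps[[r]] <- neighbor_joining(dm)
  }
  cnt <- ape::prop.clades(tree, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  supports <- round(100 * cnt / B)
  supports[1] <- NA  # root of the unrooted representation carries no support
  tree$node.label <- ifelse(is.na(supports), "", as.character(supports))
  tree
}
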