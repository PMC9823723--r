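#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Summarize molecular groups, one row per group
#'
#' @param x A [build_groups()] result.
#' @param ... Unused.
#' @return A tibble: `group_id`, `n_members`, `representative`, `support`,
#'   `transitive` (group held together only by chained matches).
#' @export
tidy.molecular_groups <- function(x, ...) {
  reps <- attr(x, "representatives")
  out <- dplyr::count(tibble::as_tibble(x), .data$group_id, name = "n_members")
  out$representative <- reps$accession_id[match(out$group_id, reps$group_id)]
  out$support <- reps$support[match(out$group_id, reps$group_id)]
  out$transitive <- out$group_id %in% attr(x, "transitive")
  dplyr::arrange(out, dplyr::desc(.data$n_members), .data$group_id)
}

#' One-row summary of a molecular grouping
#'
#' @param x A [build_groups()] result.
#' @param ... Unused.
#' @return A tibble: `n_accessions`, `n_groups`, `n_transitive`, `threshold`.
#' @export
glance.molecular_groups <- function(x, ...) {
  tibble::tibble(
    n_accessions = nrow(x),
    n_groups = length(unique(x$group_id)),
    n_transitive = length(attr(x, "transitive")),
    threshold = attr(x, "threshold")
  )
}

#' Unweighted column means of a per-locus diversity table
#'
#' @param x A [locus_diversity()] result.
#' @param ... Unused.
#' @return A one-row tibble of unweighted arithmetic means (`N`, `Na`, `Ne`,
#'   `Ho`, `He`, `Ar`, `PI`, `PIsib`) plus `g` and `n_loci`.
#' @export
glance.locus_diversity <- function(x, ...) {
  out <- dplyr::summarise(tibble::as_tibble(x), dplyr::across(
    c("N", "Na", "Ne", "Ho", "He", "Ar", "PI", "PIsib"), mean))
  out$g <- attr(x, "g")
  out$n_loci <- nrow(x)
  out
}

#' One-row summary of a minimal marker set
#'
#' @param x A [minimal_marker_set()] result.
#' @param ... Unused.
#' @return A tibble: `mode`, `size`, `achieved`, `n_unresolved_pairs`.
#' @export
glance.marker_set <- function(x, ...) {
  unres <- attr(x, "unresolved")
  tibble::tibble(
    mode = attr(x, "mode"),
    size = attr(x, "size"),
    achieved = attr(x, "achieved"),
    n_unresolved_pairs = if (is.null(unres)) 0L else nrow(unres)
  )
}

#' Verdict counts of a parentage verification
#'
#' @param x A [verify_pedigrees()] result.
#' @param ... Unused.
#' @return A tibble: `n_hypotheses`, `n_strict`, `n_relaxed`, `n_rejected`,
#'   `n_unevaluated`.
#' @export
glance.parentage_result <- function(x, ...) {
  tibble::tibble(
    n_hypotheses = nrow(x),
    n_strict = sum(x$verdict == "*", na.rm = TRUE),
    n_relaxed = sum(x$verdict == "+", na.rm = TRUE),
    n_rejected = sum(x$verdict == "-", na.rm = TRUE),
    n_unevaluated = sum(!x$evaluated)
  )
}
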