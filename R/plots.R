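#' Plot per-locus identity probabilities and their cumulative products
#'
#' Loci are ordered by ascending PI; points show per-locus PI and PIsib,
#' lines their running products — the multilocus probability that two
#' unrelated (or full-sib) individuals share the genotype of the best k
#' loci.
#'
#' @param pi A [pi_profile()] tibble.
#' @return A ggplot object.
#' @export
plot_pi_curve <- function(pi) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(pi, locus = factor(.data$locus, levels = pi$locus)),
    cols = c("PI", "PIsib", "cum_PI", "cum_PIsib"),
    names_to = "measure", values_to = "value")
  long$kind <- ifelse(grepl("^cum", long$measure), "cumulative", "per locus")
  long$family <- ifelse(grepl("sib", long$measure), "PIsib", "PI")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$locus, y = .data$value,
                                     colour = .data$family,
                                     linetype = .data$kind,
                                     group = interaction(.data$measure))) +
    ggplot2::geom_point(data = ~dplyr::filter(.x, .data$kind == "per locus")) +
    ggplot2::geom_line(data = ~dplyr::filter(.x, .data$kind == "cumulative")) +
    ggplot2::labs(x = NULL, y = "probability of identity",
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot-methods
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for curation results
#'
#' `autoplot.locus_diversity` shows observed vs expected heterozygosity per
#' locus; `autoplot.molecular_groups` the distribution of group sizes;
#' `autoplot.parentage_result` the LOD scores by analysis mode with the
#' calibrated strict/relaxed thresholds.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-methods
NULL

#' @rdname autoplot-methods
#' @export
autoplot.locus_diversity <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("Ho", "He"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$locus, y = .data$value,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "heterozygosity", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot-methods
#' @export
autoplot.molecular_groups <- function(object, ...) {
  sizes <- dplyr::count(tibble::as_tibble(object), .data$group_id)
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "accessions per molecular group", y = "groups") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @export
autoplot.parentage_result <- function(object, ...) {
  th <- attr(object, "thresholds")
  dat <- dplyr::filter(tibble::as_tibble(object), .data$evaluated)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$child, y = .data$LOD,
                                         colour = .data$verdict)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~mode, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "LOD", colour = "verdict") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
  if (!is.null(th)) {
    th_long <- tidyr::pivot_longer(th, cols = c("strict", "relaxed"),
                                   names_to = "level", values_to = "LOD")
    p <- p + ggplot2::geom_hline(data = th_long,
                                 ggplot2::aes(yintercept = .data$LOD,
                                              linetype = .data$level))
  }
  p
}
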