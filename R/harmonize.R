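#' Estimate per-batch fragment-size offsets from shared reference genotypes
#'
#' Capillary sequencers and sizing protocols differ between laboratories, so
#' the same allele can be reported with a constant per-locus size shift. A
#' small set of reference genotypes run in every batch lets those shifts be
#' estimated: for each (batch, locus) the offset is the rounded median, over
#' all reference alleles, of (reference-batch size - batch size). Adding the
#' offset to a batch's sizes moves them onto the reference batch's scale.
#'
#' @param records Genotype tibble with a `lab_batch` column; reference
#'   accessions appear once per batch under the same `assumed_name`.
#' @param reference_ids Character vector of `assumed_name` values identifying
#'   the reference genotypes.
#' @param panel The [marker_panel()].
#' @param reference_batch Batch whose sizing is taken as the target scale.
#' @return A tibble of class `ssr_offsets` with columns `lab_batch`, `locus`,
#'   `offset` (integer bp; 0 everywhere for the reference batch).
#' @export
estimate_offsets <- function(records, reference_ids, panel,
                             reference_batch = records$lab_batch[1]) {
  batches <- unique(records$lab_batch)
  if (!reference_batch %in% batches) {
    stop("reference_batch '", reference_batch, "' not present in records")
  }
  refs <- records[records$assumed_name %in% reference_ids, , drop = FALSE]
  in_ref_batch <- unique(refs$assumed_name[refs$lab_batch == reference_batch])
  absent <- setdiff(reference_ids, in_ref_batch)
  if (length(absent) > 0) {
    stop("reference genotype(s) absent from reference batch: ",
         paste(absent, collapse = ", "))
  }
  grid <- tidyr::expand_grid(lab_batch = batches, locus = panel$locus)
  grid$offset <- 0L
  for (b in setdiff(batches, reference_batch)) {
    for (loc in panel$locus) {
      cols <- paste0(loc, c(".1", ".2"))
      diffs <- integer(0)
      for (id in reference_ids) {
        r_ref <- refs[refs$assumed_name == id & refs$lab_batch == reference_batch, ]
        r_b   <- refs[refs$assumed_name == id & refs$lab_batch == b, ]
        if (nrow(r_ref) == 0 || nrow(r_b) == 0) next
        a_ref <- sort(c(r_ref[[cols[1]]][1], r_ref[[cols[2]]][1]))
        a_b   <- sort(c(r_b[[cols[1]]][1],  r_b[[cols[2]]][1]))
        if (anyNA(a_ref) || anyNA(a_b) || length(a_ref) != length(a_b)) next
        diffs <- c(diffs, a_ref - a_b)
      }
      if (length(diffs) == 0) {
        warning("no shared reference alleles for batch '", b, "' at locus ",
                loc, "; offset set to 0", call. = FALSE)
      } else {
        grid$offset[grid$lab_batch == b & grid$locus == loc] <-
          round_half_to_zero(stats::median(diffs))
      }
    }
  }
  class(grid) <- c("ssr_offsets", class(grid))
  grid
}

# round half toward zero (2.5 -> 2, -2.5 -> -2)
round_half_to_zero <- function(x) {
  as.integer(sign(x) * ceiling(abs(x) - 0.5))
}

#' Build a dataset-dependent allele binning map
#'
#' PCR fragment sizing carries roughly +-1 bp of technical uncertainty, so
#' two observed sizes 1 bp apart are treated as the same allele. For each
#' locus the distinct observed sizes are sorted and runs of consecutive sizes
#' with gaps <= 1 bp are greedily merged into one bin; the bin center is the
#' modal observed size of the run (ties broken toward the smaller size).
#' Chained merges (e.g. 150,151,152 collapsing into one bin) are permitted
#' but reported, as the pairwise tolerance under-determines them.
#'
#' @param records Genotype tibble (offsets already applied).
#' @param panel The [marker_panel()].
#' @return A tibble of class `ssr_bins` with columns `locus`, `size`
#'   (observed), `center` (bin center the size maps to). Attribute
#'   `chained` lists loci where a merged run spanned more than 2 bp.
#' @export
build_bins <- function(records, panel) {
  out <- vector("list", nrow(panel))
  chained <- character(0)
  for (i in seq_len(nrow(panel))) {
    loc <- panel$locus[i]
    vals <- c(records[[paste0(loc, ".1")]], records[[paste0(loc, ".2")]])
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) {
      out[[i]] <- tibble::tibble(locus = character(0), size = integer(0),
                                 center = integer(0))
      next
    }
    counts <- table(vals)
    sizes <- sort(unique(vals))
    run_id <- cumsum(c(1L, as.integer(diff(sizes) > 1L)))
    centers <- integer(length(sizes))
    for (r in unique(run_id)) {
      members <- sizes[run_id == r]
      if (max(members) - min(members) > 1L) chained <- c(chained, loc)
      cnt <- counts[as.character(members)]
      centers[run_id == r] <- members[which.max(cnt)]  # which.max: first = smaller size
    }
    out[[i]] <- tibble::tibble(locus = loc, size = sizes, center = centers)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "chained") <- unique(chained)
  class(res) <- c("ssr_bins", class(res))
  res
}

#' Apply offsets and binning to a genotype table
#'
#' Replaces every allele by its offset-corrected, binned center. Missing
#' alleles are preserved; the operation is idempotent on its own output. An
#' allele not covered by any bin is snapped to the nearest bin center if
#' within 1 bp, otherwise it is an error.
#'
#' @param records Genotype tibble.
#' @param panel The [marker_panel()].
#' @param offsets Optional [estimate_offsets()] result.
#' @param bins Optional [build_bins()] result (built on the offset-corrected
#'   records when both are supplied).
#' @return The harmonized genotype tibble (same rows, same missing mask).
#' @export
harmonize_genotypes <- function(records, panel, offsets = NULL, bins = NULL) {
  out <- records
  if (!is.null(offsets) && isTRUE(attr(records, "offsets_applied"))) {
    offsets <- NULL  # additive correction must not be applied twice
  }
  if (!is.null(offsets)) {
    for (b in unique(out$lab_batch)) {
      rows <- which(out$lab_batch == b)
      for (loc in panel$locus) {
        off <- offsets$offset[offsets$lab_batch == b & offsets$locus == loc]
        if (length(off) == 0 || off == 0L) next
        for (cc in paste0(loc, c(".1", ".2"))) {
          out[[cc]][rows] <- out[[cc]][rows] + off
        }
      }
    }
  }
  if (!is.null(bins)) {
    for (loc in panel$locus) {
      bl <- bins[bins$locus == loc, , drop = FALSE]
      if (nrow(bl) == 0) next
      for (cc in paste0(loc, c(".1", ".2"))) {
        v <- out[[cc]]
        idx <- match(v, bl$size)
        unmapped <- which(!is.na(v) & is.na(idx))
        if (length(unmapped) > 0) {
          for (u in unmapped) {
            d <- abs(bl$center - v[u])
            if (min(d) <= 1L) {
              idx[u] <- which.min(d)
            } else {
              stop("allele ", v[u], " at locus ", loc,
                   " not within 1 bp of any bin")
            }
          }
        }
        out[[cc]] <- ifelse(is.na(v), NA_integer_, bl$center[idx])
      }
    }
  }
  out <- canonicalize_genotypes(out, panel)
  attr(out, "offsets_applied") <- TRUE
  out
}
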