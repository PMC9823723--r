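#' Define an SSR marker panel
#'
#' A marker panel is the ordered set of microsatellite loci a collection is
#' genotyped on, with optional repeat-motif lengths and expected fragment-size
#' ranges. Genotype tables carry two columns per locus, `<locus>.1` and
#' `<locus>.2`, holding the diploid allele sizes in base pairs.
#'
#' @param loci Character vector of unique locus names.
#' @param motif Integer repeat-motif length in bp per locus (recycled).
#'   `NA` when unknown.
#' @param size_min,size_max Optional expected fragment-size range in bp per
#'   locus (recycled); alleles outside the range trigger a warning on read.
#'
#' @return A tibble of class `ssr_panel` with columns `locus`, `motif`,
#'   `size_min`, `size_max`.
#' @examples
#' marker_panel(c("BPPCT037", "PceGA34"), motif = 2)
#' @export
marker_panel <- function(loci, motif = NA_integer_,
                         size_min = NA_integer_, size_max = NA_integer_) {
  loci <- as.character(loci)
  if (length(loci) == 0L) stop("panel must contain at least one locus")
  if (anyDuplicated(loci)) stop("locus names must be unique")
  out <- tibble::tibble(
    locus    = loci,
    motif    = as.integer(rep_len(motif, length(loci))),
    size_min = as.integer(rep_len(size_min, length(loci))),
    size_max = as.integer(rep_len(size_max, length(loci)))
  )
  class(out) <- c("ssr_panel", class(out))
  out
}

#' The 16-locus ECPGR cherry marker panel
#'
#' The standard set of 16 SSR markers recommended by the ECPGR *Prunus*
#' working group for sweet cherry fingerprinting, two unlinked markers per
#' linkage group. All are treated as dinucleotide-motif markers for binning
#' purposes.
#'
#' @return An [marker_panel()] tibble with 16 rows.
#' @examples
#' cherry_panel()
#' @export
cherry_panel <- function() {
  marker_panel(
    c("BPPCT037", "CPPCT006", "CPPCT022", "EMPA002", "EMPA003", "EMPA017",
      "EMPA026", "EMPaS01", "EMPaS02", "EMPaS06", "EMPaS10", "EMPaS12",
      "EMPaS14", "PceGA34", "PS05C03", "UDP98-412"),
    motif = 2L, size_min = 60L, size_max = 350L
  )
}

# Column names of the two allele slots for each panel locus.
locus_cols <- function(panel) {
  as.vector(rbind(paste0(panel$locus, ".1"), paste0(panel$locus, ".2")))
}

# Check a genotype tibble against a panel; returns the tibble with allele
# columns coerced to integer and each pair sorted ascending (canonical form,
# NA last so missing loci stay NA/NA).
canonicalize_genotypes <- function(tbl, panel) {
  cols <- locus_cols(panel)
  missing_cols <- setdiff(cols, names(tbl))
  if (length(missing_cols) > 0) {
    stop("genotype table lacks allele columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (loc in panel$locus) {
    c1 <- paste0(loc, ".1"); c2 <- paste0(loc, ".2")
    a <- as.integer(tbl[[c1]]); b <- as.integer(tbl[[c2]])
    # a homozygote given once is expanded to a duplicated size
    a2 <- ifelse(is.na(a) & !is.na(b), b, a)
    b2 <- ifelse(is.na(b) & !is.na(a), a, b)
    tbl[[c1]] <- pmin(a2, b2)
    tbl[[c2]] <- pmax(a2, b2)
  }
  tbl
}
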