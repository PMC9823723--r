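# Shared fixtures: small panels and hand-built genotype tables.

tiny_panel <- function(n = 4L, prefix = "L") {
  marker_panel(sprintf("%s%d", prefix, seq_len(n)), motif = 2L)
}

# build a genotype tibble from a list of accessions, each a list with
# id and a length-2L vector of allele sizes (NA NA = missing locus)
make_geno <- function(panel, ..., status = "not_determined") {
  accs <- list(...)
  rows <- lapply(accs, function(a) {
    row <- tibble::tibble(
      accession_id = a$id,
      collection = a$collection %||% "siteA",
      assumed_name = a$assumed_name %||% NA_character_,
      pomological_status = a$status %||% status,
      determined_name = a$determined_name %||% NA_character_,
      lab_batch = a$lab_batch %||% "lab1"
    )
    for (i in seq_len(nrow(panel))) {
      pair <- sort(a$alleles[(2 * i - 1):(2 * i)], na.last = TRUE)
      row[[paste0(panel$locus[i], ".1")]] <- as.integer(pair[1])
      row[[paste0(panel$locus[i], ".2")]] <- as.integer(pair[2])
    }
    row
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# generator configuration whose corruption levels certify the grouping
# margins (<= 1 mistyped locus per clone, no sizing jitter)
dedup_config <- function(seed, n_trios = 0L, n_sib_families = 0L, ...) {
  generator_config(seed = seed, clone_error_rate = 0.05,
                   sizing_jitter_rate = 0, max_corrupt_loci_per_clone = 1L,
                   clones_per_cultivar = c(2L, 6L), n_trios = n_trios,
                   n_sib_families = n_sib_families, ...)
}

# clean single-copy collection: one pristine accession per cultivar
clean_config <- function(seed, n = 100L, ...) {
  generator_config(seed = seed, n_cultivars = n,
                   clones_per_cultivar = c(1L, 1L), clone_error_rate = 0,
                   sizing_jitter_rate = 0, missing_rate = 0, ...)
}

# check that molecular groups match the planted cultivar structure exactly
groups_match_truth <- function(groups, truth) {
  cultivar <- truth$accessions$cultivar[
    match(groups$accession_id, truth$accessions$accession_id)]
  by_group <- split(cultivar, groups$group_id)
  by_cultivar <- split(groups$group_id, cultivar)
  all(vapply(by_group, function(x) length(unique(x)) == 1L, logical(1))) &&
    all(vapply(by_cultivar, function(x) length(unique(x)) == 1L, logical(1)))
}
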