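#' Configuration for the synthetic genebank generator
#'
#' Describes a clonal fruit-collection dataset with known ground truth: a set
#' of founder cultivars drawn from per-locus Dirichlet allele frequencies on
#' a strict 2 bp allele ladder (so planted +-1 bp sizing jitter is
#' unambiguously a technical artifact), designed parent-offspring trios and
#' full-sib families, and per-cultivar clonal accessions corrupted by
#' per-reaction mistyping (~10%, the typical SSR PCR-artifact rate), sizing
#' jitter, missing loci and constant per-batch inter-lab size offsets.
#'
#' Defaults emulate the structure of a characterized sweet-cherry genebank:
#' 16 loci with 5-24 alleles each (mean about 15), expected heterozygosity
#' near 0.67, and 1-6 clonal trees per cultivar (mean near the 3.8 trees per
#' unique genotype seen in practice).
#'
#' @param n_cultivars Total distinct cultivars (founders + designed crosses).
#' @param clones_per_cultivar Integer range; each cultivar gets a uniform
#'   draw of clonal accessions.
#' @param n_loci Number of SSR loci.
#' @param alleles_per_locus Integer range of ladder sizes per locus.
#' @param motif Allele ladder step in bp.
#' @param dirichlet_concentration Symmetric Dirichlet concentration for
#'   allele frequencies (smaller = more uneven).
#' @param clone_error_rate Per-locus probability that a clone's reaction
#'   miscalls one allele.
#' @param sizing_jitter_rate Per-allele probability of a +-1 bp sizing shift.
#' @param missing_rate Per-locus probability that a clone's locus fails.
#' @param max_corrupt_loci_per_clone Optional hard cap on mistyped loci per
#'   clone; use it to certify that within-clone similarity stays above a
#'   grouping threshold (see [certify_margins()]). `NULL` = uncapped.
#' @param n_trios Cultivars generated as crosses of two named founders.
#' @param n_sib_families Full-sib families (each of `sib_family_size`
#'   cultivars sharing both parents).
#' @param sib_family_size Cultivars per sib family.
#' @param n_batches Genotyping batches; batches beyond the first get
#'   constant per-locus integer offsets drawn from `batch_offset_range`.
#' @param batch_offset_range Integer range of planted inter-lab offsets.
#' @param n_references Reference cultivars genotyped error-free in every
#'   batch (used to estimate offsets); 0 when `n_batches == 1`.
#' @param prob_no_reference Per-cultivar probability of having no pomological
#'   reference (its trees become category 3).
#' @param prob_not_determined,prob_with_reservation Per-tree probabilities of
#'   the corresponding pomological statuses (otherwise: determined).
#' @param seed Mandatory integer seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_cultivars = 50L,
                             clones_per_cultivar = c(1L, 6L),
                             n_loci = 16L,
                             alleles_per_locus = c(5L, 24L),
                             motif = 2L,
                             dirichlet_concentration = 0.2,
                             clone_error_rate = 0.10,
                             sizing_jitter_rate = 0.02,
                             missing_rate = 0.03,
                             max_corrupt_loci_per_clone = NULL,
                             n_trios = 5L,
                             n_sib_families = 2L,
                             sib_family_size = 3L,
                             n_batches = 1L,
                             batch_offset_range = c(-3L, 3L),
                             n_references = 8L,
                             prob_no_reference = 0.083,
                             prob_not_determined = 0.048,
                             prob_with_reservation = 0.017,
                             seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (n_loci < 2) stop("n_loci must be at least 2")
  rates <- c(clone_error_rate, sizing_jitter_rate, missing_rate,
             prob_no_reference, prob_not_determined, prob_with_reservation)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (max(alleles_per_locus) < 2 && (n_trios > 0 || n_sib_families > 0)) {
    stop("designed crosses need at least 2 alleles per locus")
  }
  n_designed <- n_trios + n_sib_families * sib_family_size
  if (n_cultivars - n_designed < 2) {
    stop("n_cultivars too small for the requested trios/sib families")
  }
  structure(as.list(environment()), class = "generator_config")
}

#' Generate a synthetic genebank collection with ground truth
#'
#' Draws founder cultivars from per-locus Dirichlet frequencies on a 2 bp
#' allele ladder, creates trio and full-sib cultivars as Mendelian crosses of
#' founders, emits clonal accessions per cultivar corrupted by mistyping,
#' sizing jitter, missingness and batch offsets, and records every planted
#' corruption so the emitted records can be reproduced from the pristine
#' genotypes (see [replay_corruptions()]).
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_collection`:
#' \describe{
#'   \item{records}{accession genotype tibble (pipeline input).}
#'   \item{panel}{the generated [marker_panel()].}
#'   \item{truth}{ground truth: `accessions` (accession to cultivar, parents,
#'     batch), `cultivars` (pristine cultivar genotypes), `corruptions`
#'     (per-accession planted events), `offsets` (per batch and locus),
#'     `frequencies` (true allele frequencies), `reference_names`
#'     (cultivars with pomological references), `pedigree` (designed
#'     trio/sib hypotheses).}
#' }
#' @export
generate_collection <- function(config) {
  cfg <- config
  withr::with_seed(cfg$seed, {
    loci <- sprintf("L%02d", seq_len(cfg$n_loci))
    base <- sample(seq(80L, 300L, by = 2L), cfg$n_loci, replace = TRUE)
    k <- sample(seq(cfg$alleles_per_locus[1], cfg$alleles_per_locus[2]),
                cfg$n_loci, replace = TRUE)
    panel <- marker_panel(loci, motif = cfg$motif,
                          size_min = 60L, size_max = 400L)
    ladders <- lapply(seq_len(cfg$n_loci), function(i) {
      base[i] + cfg$motif * (seq_len(k[i]) - 1L)
    })
    freqs <- lapply(seq_len(cfg$n_loci), function(i) {
      w <- stats::rgamma(k[i], shape = cfg$dirichlet_concentration)
      while (sum(w) == 0) w <- stats::rgamma(k[i], shape = cfg$dirichlet_concentration)
      rlang::set_names(w / sum(w), ladders[[i]])
    })
    names(freqs) <- loci

    draw_hwe <- function() {
      vapply(seq_len(cfg$n_loci), function(i) {
        sort(sample(ladders[[i]], 2, replace = TRUE, prob = freqs[[i]]))
      }, integer(2))
    }
    cross <- function(gm, gf) {
      vapply(seq_len(cfg$n_loci), function(i) {
        sort(c(gm[sample.int(2, 1), i], gf[sample.int(2, 1), i]))
      }, integer(2))
    }

    n_designed <- cfg$n_trios + cfg$n_sib_families * cfg$sib_family_size
    n_founders <- cfg$n_cultivars - n_designed
    cultivar_names <- sprintf("CV%03d", seq_len(cfg$n_cultivars))
    genotypes <- vector("list", cfg$n_cultivars)
    mother <- rep(NA_character_, cfg$n_cultivars)
    father <- rep(NA_character_, cfg$n_cultivars)
    for (j in seq_len(n_founders)) genotypes[[j]] <- draw_hwe()
    next_id <- n_founders + 1L
    pick_parents <- function() sort(sample.int(n_founders, 2))
    for (t in seq_len(cfg$n_trios)) {
      pr <- pick_parents()
      genotypes[[next_id]] <- cross(genotypes[[pr[1]]], genotypes[[pr[2]]])
      mother[next_id] <- cultivar_names[pr[1]]
      father[next_id] <- cultivar_names[pr[2]]
      next_id <- next_id + 1L
    }
    for (s in seq_len(cfg$n_sib_families)) {
      pr <- pick_parents()
      for (m in seq_len(cfg$sib_family_size)) {
        genotypes[[next_id]] <- cross(genotypes[[pr[1]]], genotypes[[pr[2]]])
        mother[next_id] <- cultivar_names[pr[1]]
        father[next_id] <- cultivar_names[pr[2]]
        next_id <- next_id + 1L
      }
    }

    batches <- sprintf("lab%d", seq_len(cfg$n_batches))
    offsets <- tidyr::expand_grid(lab_batch = batches, locus = loci)
    offsets$offset <- 0L
    if (cfg$n_batches > 1) {
      extra <- offsets$lab_batch != batches[1]
      offsets$offset[extra] <- sample(
        seq(cfg$batch_offset_range[1], cfg$batch_offset_range[2]),
        sum(extra), replace = TRUE)
    }
    off_lookup <- function(b, loc) {
      offsets$offset[offsets$lab_batch == b & offsets$locus == loc]
    }

    no_ref <- stats::runif(cfg$n_cultivars) < cfg$prob_no_reference
    reference_names <- cultivar_names[!no_ref]

    acc_rows <- list(); corr_rows <- list(); truth_rows <- list()
    acc_n <- 0L
    emit <- function(cultivar_idx, batch, corrupt, status_override = NULL) {
      acc_n <<- acc_n + 1L
      id <- sprintf("T%04d", acc_n)
      g <- genotypes[[cultivar_idx]]  # 2 x n_loci, columns sorted
      events <- list()
      if (corrupt) {
        n_mistyped <- 0L
        cap <- cfg$max_corrupt_loci_per_clone %||% Inf
        for (i in seq_len(cfg$n_loci)) {
          if (stats::runif(1) < cfg$clone_error_rate && k[i] > 1 &&
              n_mistyped < cap) {
            n_mistyped <- n_mistyped + 1L
            slot <- sample.int(2, 1)
            new <- sample(setdiff(ladders[[i]], g[slot, i]), 1)
            g[slot, i] <- new
            events[[length(events) + 1]] <-
              list(locus = loci[i], type = "mistype", slot = slot, value = new)
          }
          for (slot in 1:2) {
            if (stats::runif(1) < cfg$sizing_jitter_rate) {
              delta <- sample(c(-1L, 1L), 1)
              g[slot, i] <- g[slot, i] + delta
              events[[length(events) + 1]] <-
                list(locus = loci[i], type = "jitter", slot = slot,
                     value = delta)
            }
          }
          if (stats::runif(1) < cfg$missing_rate) {
            g[, i] <- NA_integer_
            events[[length(events) + 1]] <-
              list(locus = loci[i], type = "missing", slot = NA_integer_,
                   value = NA_integer_)
          }
        }
      }
      for (i in seq_len(cfg$n_loci)) {
        g[, i] <- g[, i] + off_lookup(batch, loci[i])
      }
      cv <- cultivar_names[cultivar_idx]
      if (is.null(status_override)) {
        status <- if (no_ref[cultivar_idx]) "no_reference" else {
          u <- stats::runif(1)
          if (u < cfg$prob_not_determined) "not_determined" else
            if (u < cfg$prob_not_determined + cfg$prob_with_reservation)
              "with_reservation" else "determined"
        }
      } else status <- status_override
      row <- tibble::tibble(
        accession_id = id,
        collection = sample(c("siteA", "siteB", "siteC"), 1),
        assumed_name = cv,
        pomological_status = status,
        determined_name = if (status %in% c("determined", "with_reservation"))
          cv else NA_character_,
        lab_batch = batch
      )
      for (i in seq_len(cfg$n_loci)) {
        pair <- sort(g[, i], na.last = TRUE)
        row[[paste0(loci[i], ".1")]] <- pair[1]
        row[[paste0(loci[i], ".2")]] <- pair[2]
      }
      acc_rows[[acc_n]] <<- row
      truth_rows[[acc_n]] <<- tibble::tibble(
        accession_id = id, cultivar = cv,
        mother = mother[cultivar_idx], father = father[cultivar_idx],
        lab_batch = batch, is_reference = !corrupt && !is.null(status_override)
      )
      if (length(events) > 0) {
        corr_rows[[length(corr_rows) + 1]] <<- dplyr::bind_rows(
          lapply(events, function(e) {
            tibble::tibble(accession_id = id, locus = e$locus, type = e$type,
                           slot = e$slot, value = e$value)
          }))
      }
      invisible(NULL)
    }

    for (j in seq_len(cfg$n_cultivars)) {
      n_clones <- sample(seq(cfg$clones_per_cultivar[1],
                             cfg$clones_per_cultivar[2]), 1)
      for (cl in seq_len(n_clones)) {
        emit(j, sample(batches, 1), corrupt = TRUE)
      }
    }
    if (cfg$n_batches > 1 && cfg$n_references > 0) {
      ref_idx <- seq_len(min(cfg$n_references, n_founders))
      for (j in ref_idx) {
        for (b in batches) {
          emit(j, b, corrupt = FALSE, status_override = "determined")
        }
      }
    }

    records <- dplyr::bind_rows(acc_rows)
    cultivars <- dplyr::bind_rows(lapply(seq_len(cfg$n_cultivars), function(j) {
      row <- tibble::tibble(cultivar = cultivar_names[j])
      for (i in seq_len(cfg$n_loci)) {
        row[[paste0(loci[i], ".1")]] <- genotypes[[j]][1, i]
        row[[paste0(loci[i], ".2")]] <- genotypes[[j]][2, i]
      }
      row
    }))
    freq_tbl <- dplyr::bind_rows(lapply(loci, function(loc) {
      tibble::tibble(locus = loc, allele = as.integer(names(freqs[[loc]])),
                     freq = unname(freqs[[loc]]))
    }))
    designed <- which(!is.na(mother))
    pedigree <- tibble::tibble(child = cultivar_names[designed],
                               mother = mother[designed],
                               father = father[designed])
    structure(list(
      records = records,
      panel = panel,
      truth = list(
        accessions = dplyr::bind_rows(truth_rows),
        cultivars = cultivars,
        corruptions = if (length(corr_rows) > 0) dplyr::bind_rows(corr_rows)
          else tibble::tibble(accession_id = character(0), locus = character(0),
                              type = character(0), slot = integer(0),
                              value = integer(0)),
        offsets = offsets,
        frequencies = freq_tbl,
        reference_names = reference_names,
        pedigree = pedigree,
        config = cfg
      )
    ), class = "synthetic_collection")
  })
}

#' Replay logged corruptions onto pristine cultivar genotypes
#'
#' Reconstructs the emitted accession records of a [generate_collection()]
#' result from its ground truth alone: start from each accession's pristine
#' cultivar genotype, apply the logged mistype/jitter/missing events in
#' order, then the batch offsets. Used to verify that corruption bookkeeping
#' is exact.
#'
#' @param collection A `synthetic_collection`.
#' @return A genotype tibble in the same row order as `collection$records`.
#' @export
replay_corruptions <- function(collection) {
  truth <- collection$truth
  panel <- collection$panel
  recs <- collection$records
  out <- recs
  for (r in seq_len(nrow(recs))) {
    id <- recs$accession_id[r]
    tr <- truth$accessions[truth$accessions$accession_id == id, ]
    g <- truth$cultivars[truth$cultivars$cultivar == tr$cultivar, ]
    pairs <- lapply(panel$locus, function(loc) {
      c(g[[paste0(loc, ".1")]], g[[paste0(loc, ".2")]])
    })
    names(pairs) <- panel$locus
    ev <- truth$corruptions[truth$corruptions$accession_id == id, ]
    for (e in seq_len(nrow(ev))) {
      loc <- ev$locus[e]
      p <- pairs[[loc]]
      if (ev$type[e] == "mistype") {
        p[ev$slot[e]] <- ev$value[e]
      } else if (ev$type[e] == "jitter") {
        p[ev$slot[e]] <- p[ev$slot[e]] + ev$value[e]
      } else if (ev$type[e] == "missing") {
        p[] <- NA_integer_
      }
      pairs[[loc]] <- p
    }
    for (loc in panel$locus) {
      off <- truth$offsets$offset[truth$offsets$lab_batch == tr$lab_batch &
                                    truth$offsets$locus == loc]
      p <- sort(pairs[[loc]] + off, na.last = TRUE)
      out[[paste0(loc, ".1")]][r] <- p[1]
      out[[paste0(loc, ".2")]][r] <- p[2]
    }
  }
  out
}

#' Certify grouping margins of a synthetic collection
#'
#' Molecular grouping recovers the planted clone structure exactly when (a)
#' within every cultivar the clones form a single connected component under
#' above-threshold similarity links (single linkage), and (b) no pair of
#' accessions from different cultivars exceeds the threshold. This helper
#' checks both margins on the harmonized records against the ground truth,
#' so tests can assert recovery exactly when the generator's corruption
#' levels guarantee it.
#'
#' @param collection A [generate_collection()] result.
#' @param threshold Grouping similarity threshold.
#' @param min_shared Minimum mutually typed loci per comparison.
#' @return A list: `within_ok`, `between_ok`, `certified` (both), plus
#'   `min_within_link` (smallest maximal link similarity a clone has inside
#'   its cultivar) and `max_between` similarity.
#' @export
certify_margins <- function(collection, threshold = 0.90, min_shared = 8L) {
  bins <- build_bins(collection$records, collection$panel)
  h <- harmonize_genotypes(collection$records, collection$panel, bins = bins)
  eng <- similarity_engine(h, collection$panel)
  sim <- eng$similarity
  sim[eng$shared < min_shared] <- NA_real_
  cultivar <- collection$truth$accessions$cultivar[
    match(h$accession_id, collection$truth$accessions$accession_id)]
  same <- outer(cultivar, cultivar, "==")
  diag(same) <- NA
  between <- sim[!is.na(same) & !same]
  max_between <- if (length(between) > 0) max(between, na.rm = TRUE) else -Inf
  within_ok <- TRUE
  min_link <- Inf
  for (cv in unique(cultivar)) {
    idx <- which(cultivar == cv)
    if (length(idx) < 2) next
    sub <- sim[idx, idx, drop = FALSE]
    diag(sub) <- NA_real_
    adj <- !is.na(sub) & sub > threshold
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (igraph::components(g)$no > 1) within_ok <- FALSE
    link <- suppressWarnings(
      min(apply(sub, 1, function(r) max(r, na.rm = TRUE))))
    min_link <- min(min_link, link)
  }
  between_ok <- max_between <= threshold
  list(within_ok = within_ok, between_ok = between_ok,
       certified = within_ok && between_ok,
       min_within_link = min_link, max_between = max_between)
}

#' Analytic expectation of the generator's diversity profile
#'
#' Under a symmetric Dirichlet(`a`) frequency model with `n` alleles the
#' expected homozygosity of the drawn frequency vector is
#' `E[sum p_i^2] = (a + 1) / (n a + 1)`, so the expected heterozygosity is
#' `1 - (a + 1) / (n a + 1)`. Averaging over the uniform allele-count range
#' gives the expected panel profile, used to tune configurations toward a
#' target He.
#'
#' @param config A [generator_config()].
#' @return A one-row tibble: `expected_Na`, `expected_He`.
#' @export
target_profile <- function(config) {
  ks <- seq(config$alleles_per_locus[1], config$alleles_per_locus[2])
  a <- config$dirichlet_concentration
  he <- vapply(ks, function(n) {
    if (n == 1) 0 else 1 - (a + 1) / (n * a + 1)
  }, numeric(1))
  tibble::tibble(expected_Na = mean(ks), expected_He = mean(he))
}
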