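#' Parentage analysis configuration
#'
#' Parameters of the likelihood-based parentage engine, defaulting to the
#' settings commonly used for SSR pedigree verification in fruit collections:
#' 100,000 simulated progeny, 95% of candidate parents sampled, 90% of loci
#' typed, 10% of loci mistyped, at least 13 typed loci per comparison, and
#' relaxed/strict confidence levels of 80% and 95%. Candidate counts per
#' analysis mode default to 31 (parent-pair), 18 (maternity) and 7
#' (paternity).
#'
#' @param n_simulated_progeny Number of simulated offspring for threshold
#'   calibration.
#' @param prop_parents_sampled Probability that the true parent is among the
#'   candidates.
#' @param prop_loci_typed Per-locus probability that a genotype is typed.
#' @param error_rate Per-locus probability that an observed genotype is a
#'   mistyping (replaced by a random Hardy-Weinberg genotype).
#' @param min_typed_loci Minimum usable loci for a hypothesis to be
#'   evaluated.
#' @param relaxed_confidence,strict_confidence Required proportion of correct
#'   assignments above the relaxed / strict threshold.
#' @param n_candidates Named integer vector of candidate counts for modes
#'   `trio`, `mother`, `father`.
#' @param statistic `"lod"` (score of the named hypothesis) or `"delta"`
#'   (best minus second-best among candidates).
#' @return A list of class `parentage_config`.
#' @export
parentage_config <- function(n_simulated_progeny = 100000L,
                             prop_parents_sampled = 0.95,
                             prop_loci_typed = 0.9,
                             error_rate = 0.1,
                             min_typed_loci = 13L,
                             relaxed_confidence = 0.80,
                             strict_confidence = 0.95,
                             n_candidates = c(trio = 31L, mother = 18L,
                                              father = 7L),
                             statistic = c("lod", "delta")) {
  statistic <- match.arg(statistic)
  probs <- c(prop_parents_sampled, prop_loci_typed, error_rate,
             relaxed_confidence, strict_confidence)
  if (any(probs <= 0 & c(TRUE, TRUE, FALSE, TRUE, TRUE)) || any(probs > 1)) {
    stop("probabilities must lie in (0, 1]")
  }
  structure(list(
    n_simulated_progeny = as.integer(n_simulated_progeny),
    prop_parents_sampled = prop_parents_sampled,
    prop_loci_typed = prop_loci_typed,
    error_rate = error_rate,
    min_typed_loci = as.integer(min_typed_loci),
    relaxed_confidence = relaxed_confidence,
    strict_confidence = strict_confidence,
    n_candidates = n_candidates,
    statistic = statistic
  ), class = "parentage_config")
}

# frequency lookup with a small floor for alleles unseen in the table
lookup_freq <- function(sizes, pv) {
  p <- unname(pv[as.character(sizes)])
  p[is.na(p) & !is.na(sizes)] <- min(pv, na.rm = TRUE) / 2
  p
}

# P(parent with genotype (m1,m2) transmits allele x); NA-safe
transmit <- function(m1, m2, x) {
  ((m1 == x) + (m2 == x)) / 2
}

# Per-locus likelihood ratio components, vectorized over individuals.
# ch1/ch2 etc. are aligned allele-size vectors (NA = missing locus); pv is
# the named per-locus frequency vector. Returns list(logratio, used,
# exclusion): logratio NA where the locus is skipped.
locus_lod_vec <- function(ch1, ch2, m1, m2, f1, f2, pv, e) {
  pa <- lookup_freq(ch1, pv)
  pb <- lookup_freq(ch2, pv)
  het <- !is.na(ch1) & ch1 != ch2
  T0 <- ifelse(het, 2 * pa * pb, pa * pb)

  have_m <- !is.na(m1)
  have_f <- !is.na(f1)
  T1m <- transmit(m1, m2, ch1) * pb + het * transmit(m1, m2, ch2) * pa
  T1f <- transmit(f1, f2, ch1) * pb + het * transmit(f1, f2, ch2) * pa
  T2 <- transmit(m1, m2, ch1) * transmit(f1, f2, ch2) +
    het * transmit(m1, m2, ch2) * transmit(f1, f2, ch1)

  # error model: each observed genotype independently replaced by a random
  # HWE genotype with probability e
  L_trio <- (1 - e) * ((1 - e)^2 * T2 + e * (1 - e) * (T1m + T1f) +
                         e^2 * T0) + e * T0
  L_pair_m <- (1 - e) * ((1 - e) * T1m + e * T0) + e * T0
  L_pair_f <- (1 - e) * ((1 - e) * T1f + e * T0) + e * T0

  L1 <- ifelse(have_m & have_f, L_trio,
               ifelse(have_m, L_pair_m,
                      ifelse(have_f, L_pair_f, NA_real_)))
  used <- !is.na(ch1) & (have_m | have_f)
  mendel <- ifelse(have_m & have_f, T2, ifelse(have_m, T1m, T1f))
  list(
    logratio = ifelse(used, log(L1) - log(T0), NA_real_),
    used = used,
    exclusion = used & !is.na(mendel) & mendel == 0
  )
}

#' Per-locus parentage likelihoods for one hypothesis
#'
#' Likelihood of the child's observed genotype given the named parents'
#' observed genotypes under Mendelian transmission, with every observed
#' genotype independently mistyped with probability `error_rate` (a
#' mistyping replaces the genotype by a random Hardy-Weinberg draw), against
#' the baseline likelihood of an unrelated Hardy-Weinberg child. An unnamed
#' (or locus-missing) parent is integrated over the collection's allele
#' frequencies. Loci missing in the child or in all named parents are
#' skipped.
#'
#' @param records Genotype tibble holding child and parents.
#' @param child,mother,father `accession_id` values (parents `NULL` when
#'   unknown; at least one required).
#' @param panel The [marker_panel()].
#' @param freqs [allele_frequencies()] of the collection.
#' @param error_rate Mistyping probability per observed genotype.
#' @return A tibble: `locus`, `log_ratio` (`NA` = skipped), `used`,
#'   `exclusion` (Mendelian impossibility given the named parents).
#' @export
genotype_likelihood <- function(records, child, mother = NULL, father = NULL,
                                panel, freqs, error_rate = 0.1) {
  if (is.null(mother) && is.null(father)) stop("name at least one parent")
  fl <- freq_list(freqs)
  get_row <- function(id) {
    if (is.null(id)) return(NULL)
    i <- match(id, records$accession_id)
    if (is.na(i)) stop("accession '", id, "' not found")
    records[i, , drop = FALSE]
  }
  rc <- get_row(child); rm_ <- get_row(mother); rf <- get_row(father)
  rows <- lapply(panel$locus, function(loc) {
    if (!loc %in% names(fl)) return(NULL)
    g <- function(r, s) if (is.null(r)) NA_integer_ else r[[paste0(loc, s)]]
    res <- locus_lod_vec(g(rc, ".1"), g(rc, ".2"),
                         g(rm_, ".1"), g(rm_, ".2"),
                         g(rf, ".1"), g(rf, ".2"),
                         fl[[loc]], error_rate)
    tibble::tibble(locus = loc, log_ratio = res$logratio,
                   used = res$used, exclusion = res$exclusion)
  })
  dplyr::bind_rows(rows)
}

#' LOD score of a pedigree hypothesis
#'
#' Sums the per-locus log likelihood ratios of [genotype_likelihood()] over
#' usable loci. The analysis mode follows which parents are genotyped: both
#' present gives a trio, one present a mother- or father-pair. Fewer than
#' `min_typed_loci` usable loci leaves the hypothesis unevaluated
#' (`LOD = NA`). A named parent whose fingerprint is identical to the child's
#' raises a consanguinity warning (self-as-parent is evaluable but suspect).
#'
#' @param records Genotype tibble.
#' @param child,mother,father `accession_id` values (`NA`/`NULL` parents are
#'   unknown).
#' @param panel The [marker_panel()].
#' @param freqs [allele_frequencies()] of the collection.
#' @param config A [parentage_config()].
#' @return One-row tibble: `child`, `mother`, `father`, `mode`, `LOD`,
#'   `loci_compared`, `mismatching_loci`, `evaluated`.
#' @export
lod_score <- function(records, child, mother = NULL, father = NULL,
                      panel, freqs, config = parentage_config()) {
  ids <- records$accession_id
  if (!is.null(mother) && is.na(mother)) mother <- NULL
  if (!is.null(father) && is.na(father)) father <- NULL
  has_m <- !is.null(mother) && mother %in% ids
  has_f <- !is.null(father) && father %in% ids
  child_in <- child %in% ids
  mode <- if (has_m && has_f) "trio" else if (has_m) "mother" else
    if (has_f) "father" else NA_character_
  if (!child_in || is.na(mode)) {
    return(tibble::tibble(child = child,
                          mother = mother %||% NA_character_,
                          father = father %||% NA_character_,
                          mode = mode, LOD = NA_real_, loci_compared = 0L,
                          mismatching_loci = 0L, evaluated = FALSE))
  }
  per <- genotype_likelihood(records, child,
                             if (has_m) mother else NULL,
                             if (has_f) father else NULL,
                             panel, freqs, config$error_rate)
  for (pid in c(if (has_m) mother, if (has_f) father)) {
    i <- match(pid, ids); j <- match(child, ids)
    cols <- locus_cols(panel)
    pv <- as.integer(unlist(records[i, cols]))
    cv <- as.integer(unlist(records[j, cols]))
    both <- !is.na(pv) & !is.na(cv)
    if (any(both) && all(pv[both] == cv[both])) {
      warning("parent '", pid, "' and child '", child,
              "' carry identical fingerprints (possible self/consanguinity)",
              call. = FALSE)
    }
  }
  used <- sum(per$used)
  evaluated <- used >= config$min_typed_loci
  tibble::tibble(
    child = child,
    mother = if (has_m) mother else NA_character_,
    father = if (has_f) father else NA_character_,
    mode = mode,
    LOD = if (evaluated) sum(per$log_ratio[per$used]) else NA_real_,
    loci_compared = used,
    mismatching_loci = sum(per$exclusion),
    evaluated = evaluated
  )
}

# --- simulation machinery -------------------------------------------------

# draw n HWE individuals at every locus: list(locus -> n x 2 matrix of sizes)
r_hwe_individuals <- function(fl, n) {
  lapply(fl, function(pv) {
    sizes <- as.integer(names(pv))
    matrix(sizes[sample.int(length(pv), 2 * n, replace = TRUE, prob = pv)],
           ncol = 2)
  })
}

# observation process: per locus drop to missing, or replace by HWE draw
observe <- function(geno, fl, prop_typed, error_rate) {
  out <- geno
  n <- nrow(geno[[1]])
  for (loc in names(geno)) {
    pv <- fl[[loc]]
    sizes <- as.integer(names(pv))
    err <- stats::runif(n) < error_rate
    if (any(err)) {
      k <- sum(err)
      out[[loc]][err, ] <- matrix(
        sizes[sample.int(length(pv), 2 * k, replace = TRUE, prob = pv)],
        ncol = 2)
    }
    miss <- stats::runif(n) >= prop_typed
    out[[loc]][miss, ] <- NA_integer_
  }
  out
}

# vectorized LOD of (child, named parents) over n simulated rows
lod_rows <- function(child, mother, father, fl, e, min_typed) {
  n <- nrow(child[[1]])
  total <- numeric(n)
  used <- integer(n)
  for (loc in names(fl)) {
    ch <- child[[loc]]
    mo <- if (is.null(mother)) matrix(NA_integer_, n, 2) else mother[[loc]]
    fa <- if (is.null(father)) matrix(NA_integer_, n, 2) else father[[loc]]
    res <- locus_lod_vec(pmin(ch[, 1], ch[, 2]), pmax(ch[, 1], ch[, 2]),
                         mo[, 1], mo[, 2], fa[, 1], fa[, 2],
                         fl[[loc]], e)
    ok <- res$used
    total[ok] <- total[ok] + res$logratio[ok]
    used <- used + ok
  }
  total[used < min_typed] <- NA_real_
  total
}

#' Simulate parentage assignments for threshold calibration
#'
#' Simulates offspring of random Hardy-Weinberg parents on the collection's
#' allele frequencies, applies the observation model (missingness and
#' mistyping), scores the true parent (included among the candidates with
#' probability `prop_parents_sampled`) against unrelated candidates, and
#' records for each progeny the best candidate's statistic and whether the
#' best candidate is the true parent.
#'
#' @param freqs [allele_frequencies()] of the collection.
#' @param config A [parentage_config()].
#' @param mode `"trio"` (candidate parent pairs), `"mother"` or `"father"`
#'   (single candidate parents).
#' @param seed Integer seed.
#' @return A tibble with `statistic` (LOD or delta of the best candidate)
#'   and `correct` (best candidate is the true parent / parent pair).
#' @export
simulate_parentage <- function(freqs, config, mode = c("trio", "mother", "father"),
                               seed = 1L) {
  mode <- match.arg(mode)
  fl <- freq_list(freqs)
  if (all(vapply(fl, length, integer(1)) < 2)) {
    stop("monomorphic panel: cannot calibrate parentage thresholds")
  }
  n <- config$n_simulated_progeny
  n_cand <- config$n_candidates[[mode]]
  withr::with_seed(seed, {
    mother <- r_hwe_individuals(fl, n)
    father <- r_hwe_individuals(fl, n)
    child <- lapply(names(fl), function(loc) {
      mi <- sample.int(2, n, replace = TRUE)
      fi <- sample.int(2, n, replace = TRUE)
      cbind(mother[[loc]][cbind(seq_len(n), mi)],
            father[[loc]][cbind(seq_len(n), fi)])
    })
    names(child) <- names(fl)

    child_o <- observe(child, fl, config$prop_loci_typed, config$error_rate)
    mother_o <- observe(mother, fl, config$prop_loci_typed, config$error_rate)
    father_o <- observe(father, fl, config$prop_loci_typed, config$error_rate)

    best <- rep(-Inf, n); second <- rep(-Inf, n); best_true <- rep(FALSE, n)
    consider <- function(lod, is_true) {
      lod[is.na(lod)] <- -Inf
      improves <- lod > best
      second <<- pmax(second, ifelse(improves, best, pmin(lod, best)))
      best_true <<- ifelse(improves, is_true, best_true)
      best <<- pmax(best, lod)
    }
    rand_parent <- function() {
      observe(r_hwe_individuals(fl, n), fl, config$prop_loci_typed,
              config$error_rate)
    }
    score <- function(cand_m, cand_f) {
      lod_rows(child_o, cand_m, cand_f, fl, config$error_rate,
               config$min_typed_loci)
    }

    if (mode == "trio") {
      # candidate mothers and fathers each sampled independently; the pair
      # pool mixes the true pair, half-true pairs (one true parent, one
      # unrelated) and fully unrelated pairs -- only the true pair counts as
      # a correct assignment
      m_sampled <- stats::runif(n) < config$prop_parents_sampled
      f_sampled <- stats::runif(n) < config$prop_parents_sampled
      both <- m_sampled & f_sampled
      consider(ifelse(both, score(mother_o, father_o), -Inf), TRUE)
      for (k in seq_len(n_cand - 1L)) {
        consider(ifelse(m_sampled, score(mother_o, rand_parent()), -Inf),
                 FALSE)
        consider(ifelse(f_sampled, score(rand_parent(), father_o), -Inf),
                 FALSE)
        consider(score(rand_parent(), rand_parent()), FALSE)
      }
    } else {
      sampled <- stats::runif(n) < config$prop_parents_sampled
      true_lod <- switch(mode,
        mother = score(mother_o, NULL),
        father = score(NULL, father_o))
      consider(ifelse(sampled, true_lod, -Inf), TRUE)
      n_unrelated <- ifelse(sampled, n_cand - 1L, n_cand)
      for (k in seq_len(max(n_unrelated))) {
        cm <- rand_parent()
        lod_k <- switch(mode,
          mother = score(cm, NULL),
          father = score(NULL, cm))
        lod_k[k > n_unrelated] <- -Inf
        consider(lod_k, FALSE)
      }
    }
    stat <- if (config$statistic == "delta") {
      ifelse(is.finite(second), best - second, best)
    } else best
    tibble::tibble(statistic = stat, correct = best_true & is.finite(best))
  })
}

# Threshold = smallest statistic value such that assignments above it are
# correct with at least the requested confidence. The confidence is treated
# as a guarantee, not an estimate: the Wilson lower bound (z = 3.89) on the
# cumulative precision replaces the raw proportion, absorbing both binomial
# noise and the optimism of scanning every candidate cut, which would
# otherwise leave fresh simulations below the stated confidence about half
# the time.
threshold_from_sim <- function(stat, correct, confidence) {
  ok <- is.finite(stat)
  stat <- stat[ok]; correct <- correct[ok]
  if (length(stat) == 0) return(Inf)
  ord <- order(stat, decreasing = TRUE)
  k_seq <- seq_along(ord)
  phat <- cumsum(correct[ord]) / k_seq
  z <- 3.89
  lower <- (phat + z^2 / (2 * k_seq) -
              z * sqrt(phat * (1 - phat) / k_seq + z^2 / (4 * k_seq^2))) /
    (1 + z^2 / k_seq)
  k <- which(lower >= confidence)
  if (length(k) == 0) return(Inf)
  stat[ord][max(k)]
}

#' Calibrate strict and relaxed LOD thresholds by simulation
#'
#' Runs [simulate_parentage()] for each requested mode and extracts the
#' statistic values above which the best-candidate assignment is correct in
#' at least `strict_confidence` / `relaxed_confidence` of simulations.
#'
#' @param freqs [allele_frequencies()] of the collection.
#' @param config A [parentage_config()].
#' @param seed Integer seed (each mode uses a deterministic substream).
#' @param modes Modes to calibrate.
#' @return A tibble of class `parentage_thresholds`: `mode`, `n_candidates`,
#'   `strict`, `relaxed`, `assignment_rate` (share of simulations whose best
#'   statistic clears the strict threshold).
#' @export
calibrate_thresholds <- function(freqs, config = parentage_config(), seed = 1L,
                                 modes = c("trio", "mother", "father")) {
  rows <- lapply(seq_along(modes), function(i) {
    sim <- simulate_parentage(freqs, config, modes[i], seed + 1000L * i)
    strict <- threshold_from_sim(sim$statistic, sim$correct,
                                 config$strict_confidence)
    relaxed <- threshold_from_sim(sim$statistic, sim$correct,
                                  config$relaxed_confidence)
    tibble::tibble(
      mode = modes[i],
      n_candidates = config$n_candidates[[modes[i]]],
      strict = strict,
      relaxed = min(relaxed, strict),
      assignment_rate = mean(is.finite(sim$statistic) & sim$statistic >= strict)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("parentage_thresholds", class(out))
  out
}

#' Verify pedigree hypotheses against calibrated thresholds
#'
#' Scores each pedigree hypothesis with [lod_score()] and labels it `"*"`
#' (clears the strict threshold), `"+"` (clears the relaxed threshold) or
#' `"-"` (below both), per analysis mode. Hypotheses whose child genotype is
#' absent or that have too few usable loci are emitted as unevaluated.
#'
#' @param hypotheses Tibble with `child`, `mother`, `father` (see
#'   [read_pedigree()]).
#' @param records Genotype tibble (one row per cultivar, `accession_id`
#'   matching the pedigree names).
#' @param panel The [marker_panel()].
#' @param config A [parentage_config()].
#' @param seed Integer seed for threshold calibration.
#' @param freqs Optional precomputed [allele_frequencies()].
#' @param thresholds Optional precomputed [calibrate_thresholds()].
#' @return A tibble of class `parentage_result`: `child`, `mother`, `father`,
#'   `mode`, `LOD`, `loci_compared`, `mismatching_loci`, `verdict`
#'   (`"*"`, `"+"`, `"-"`, or `NA` when unevaluated), `evaluated`.
#' @export
verify_pedigrees <- function(hypotheses, records, panel,
                             config = parentage_config(), seed = 1L,
                             freqs = NULL, thresholds = NULL) {
  if (is.null(freqs)) freqs <- allele_frequencies(records, panel)
  if (is.null(thresholds)) {
    modes_needed <- unique(stats::na.omit(vapply(seq_len(nrow(hypotheses)),
      function(i) {
        hm <- hypotheses$mother[i]; hf <- hypotheses$father[i]
        has_m <- !is.na(hm) && hm %in% records$accession_id
        has_f <- !is.na(hf) && hf %in% records$accession_id
        if (has_m && has_f) "trio" else if (has_m) "mother" else
          if (has_f) "father" else NA_character_
      }, character(1))))
    if (length(modes_needed) == 0) modes_needed <- "trio"
    thresholds <- calibrate_thresholds(freqs, config, seed, modes_needed)
  }
  rows <- lapply(seq_len(nrow(hypotheses)), function(i) {
    lod_score(records, hypotheses$child[i],
              hypotheses$mother[i], hypotheses$father[i],
              panel, freqs, config)
  })
  out <- dplyr::bind_rows(rows)
  out$verdict <- NA_character_
  for (i in seq_len(nrow(out))) {
    if (!isTRUE(out$evaluated[i])) next
    th <- thresholds[thresholds$mode == out$mode[i], ]
    if (nrow(th) == 0) next
    out$verdict[i] <- if (out$LOD[i] >= th$strict) "*" else
      if (out$LOD[i] >= th$relaxed) "+" else "-"
  }
  attr(out, "thresholds") <- thresholds
  class(out) <- c("parentage_result", class(out))
  out
}
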