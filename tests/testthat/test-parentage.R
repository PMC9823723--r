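make_trio_records <- function(panel, child, mother, father) {
  make_geno(panel,
    list(id = "child", alleles = child),
    list(id = "mother", alleles = mother),
    list(id = "father", alleles = father))
}

uniform_freqs <- function(panel, alleles = c(100L, 102L)) {
  dplyr::bind_rows(lapply(panel$locus, function(loc) {
    tibble::tibble(locus = loc, allele = alleles,
                   count = 10L, freq = 1 / length(alleles), n_typed = 10L)
  }))
}

test_that("Mendelian trios give the hand-computed likelihood ratio", {
  panel <- marker_panel("L1")
  recs <- make_trio_records(panel, c(100, 102), c(100, 100), c(102, 102))
  freqs <- uniform_freqs(panel)
  gl <- genotype_likelihood(recs, "child", "mother", "father", panel, freqs,
                            error_rate = 0)
  # transmission certain; baseline 2 * 0.5 * 0.5 -> log ratio = log 2
  expect_equal(gl$log_ratio, log(2))
  expect_false(gl$exclusion)
})

test_that("a Mendelian exclusion zeroes the likelihood only when error-free", {
  panel <- marker_panel("L1")
  recs <- make_trio_records(panel, c(104, 104), c(100, 102), c(100, 102))
  freqs <- uniform_freqs(panel, c(100L, 102L, 104L))
  g0 <- genotype_likelihood(recs, "child", "mother", NULL, panel, freqs,
                            error_rate = 0)
  expect_true(g0$exclusion)
  expect_equal(g0$log_ratio, -Inf)
  cfg0 <- parentage_config(error_rate = 0, min_typed_loci = 1L)
  expect_equal(lod_score(recs, "child", "mother", panel = panel,
                         freqs = freqs, config = cfg0)$LOD, -Inf)

  g1 <- genotype_likelihood(recs, "child", "mother", NULL, panel, freqs,
                            error_rate = 0.1)
  expect_true(is.finite(g1$log_ratio))
  expect_lt(g1$log_ratio, 0)
  expect_true(g1$exclusion)  # still flagged as a mismatching locus
})

test_that("LOD is additive over loci and ignores monomorphic loci", {
  panel <- tiny_panel(3)
  recs <- make_geno(panel,
    list(id = "child", alleles = c(100, 102, 200, 202, 300, 300)),
    list(id = "mother", alleles = c(100, 100, 200, 200, 300, 300)))
  freqs <- dplyr::bind_rows(
    tibble::tibble(locus = "L1", allele = c(100L, 102L), count = 10L,
                   freq = 0.5, n_typed = 10L),
    tibble::tibble(locus = "L2", allele = c(200L, 202L), count = 10L,
                   freq = 0.5, n_typed = 10L),
    tibble::tibble(locus = "L3", allele = 300L, count = 20L, freq = 1,
                   n_typed = 10L))
  cfg <- parentage_config(error_rate = 0.05, min_typed_loci = 1L)
  gl <- genotype_likelihood(recs, "child", "mother", NULL, panel, freqs,
                            error_rate = 0.05)
  total <- lod_score(recs, "child", "mother", panel = panel, freqs = freqs,
                     config = cfg)
  expect_equal(total$LOD, sum(gl$log_ratio))
  expect_equal(gl$log_ratio[gl$locus == "L3"], 0)  # monomorphic contributes 0
  expect_equal(total$loci_compared, 3L)
})

test_that("hypotheses degrade gracefully: self-parents, missing data, modes", {
  panel <- tiny_panel(16)
  g <- as.vector(rbind(seq(100, 160, 4), seq(100, 160, 4) + 2))
  recs <- make_geno(panel,
    list(id = "child", alleles = g),
    list(id = "twin", alleles = g),
    list(id = "other", alleles = g + 40),
    list(id = "ghost", alleles = rep(NA_integer_, 32)))
  freqs <- allele_frequencies(recs[1:3, ], panel)
  cfg <- parentage_config(min_typed_loci = 13L)
  expect_warning(
    r <- lod_score(recs, "child", "twin", panel = panel, freqs = freqs,
                   config = cfg),
    "identical fingerprints")
  expect_true(r$evaluated)
  expect_equal(r$mode, "mother")

  ped <- tibble::tibble(child = c("ghost", "child", "nosuch"),
                        mother = c("other", NA, "other"),
                        father = c(NA, "other", NA))
  th <- tibble::tibble(mode = c("trio", "mother", "father"),
                       n_candidates = 1L, strict = 5, relaxed = 0,
                       assignment_rate = NA_real_)
  out <- verify_pedigrees(ped, recs, panel, cfg, freqs = freqs,
                          thresholds = th)
  expect_false(out$evaluated[1])       # all-missing child: unevaluated
  expect_true(is.na(out$verdict[1]))
  expect_equal(out$mode[2], "father")  # only the father is genotyped
  expect_false(out$evaluated[3])       # child genotype absent
})

test_that("threshold calibration is deterministic and ordered", {
  col <- generate_collection(clean_config(20, n = 80))
  freqs <- allele_frequencies(col$records, col$panel)
  cfg <- parentage_config(n_simulated_progeny = 600L)
  t1 <- calibrate_thresholds(freqs, cfg, seed = 5)
  t2 <- calibrate_thresholds(freqs, cfg, seed = 5)
  expect_identical(t1, t2)
  expect_true(all(t1$strict >= t1$relaxed))
  expect_error(
    simulate_parentage(
      tibble::tibble(locus = "L1", allele = 100L, count = 2L, freq = 1,
                     n_typed = 1L),
      cfg, "mother", seed = 1),
    "monomorphic")
})

test_that("clean true trios pass strict and planted wrong fathers fail", {
  col <- generate_collection(generator_config(
    seed = 31, n_trios = 10, n_cultivars = 60, clones_per_cultivar = c(1, 1),
    clone_error_rate = 0, sizing_jitter_rate = 0, missing_rate = 0))
  recs <- col$records
  recs$accession_id <- recs$assumed_name
  ped <- col$truth$pedigree
  freqs <- allele_frequencies(recs, col$panel)
  cfg <- parentage_config(n_simulated_progeny = 3000L)
  th <- calibrate_thresholds(freqs, cfg, seed = 1, modes = "trio")
  good <- verify_pedigrees(ped, recs, col$panel, cfg, freqs = freqs,
                           thresholds = th)
  # every clean true trio is confirmed; most clear the strict level, but a
  # trio whose parents carry mostly common alleles can land at the relaxed
  # level (low LOD despite being true), as in real collections
  expect_true(all(good$verdict %in% c("*", "+")))
  expect_gte(mean(good$verdict == "*"), 0.8)

  founders <- setdiff(recs$accession_id,
                      c(ped$child, ped$father, ped$mother))
  wrong <- ped
  wrong$father <- withr::with_seed(9, sample(founders, nrow(ped)))
  bad <- verify_pedigrees(wrong, recs, col$panel, cfg, freqs = freqs,
                          thresholds = th)
  expect_gte(mean(bad$verdict == "-"), 0.9)
  expect_equal(glance(bad)$n_hypotheses, nrow(ped))
})
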