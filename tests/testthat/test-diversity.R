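test_that("allele frequencies count two gene copies per typed individual", {
  panel <- marker_panel("L1")
  recs <- make_geno(panel, list(id = "a", alleles = c(100, 100)),
                    list(id = "b", alleles = c(102, 102)))
  f <- allele_frequencies(recs, panel)
  expect_equal(f$freq, c(0.5, 0.5))
  expect_equal(unique(f$n_typed), 2L)

  het <- make_geno(panel, list(id = "a", alleles = c(100, 102)))
  fh <- allele_frequencies(het, panel)
  expect_equal(fh$freq, c(0.5, 0.5))
  d <- locus_diversity(het, panel, g = 2)
  expect_equal(d$Na, 2L)
  expect_equal(d$Ho, 1)

  empty <- make_geno(panel, list(id = "a", alleles = c(NA, NA)))
  expect_warning(allele_frequencies(empty, panel), "typed in 0")
})

test_that("per-locus frequencies sum to one and Ne matches 1/(1 - He)", {
  col <- generate_collection(clean_config(8))
  f <- allele_frequencies(col$records, col$panel)
  sums <- vapply(split(f$freq, f$locus), sum, numeric(1))
  expect_true(all(abs(sums - 1) < 1e-9))
  d <- locus_diversity(col$records, col$panel)
  expect_true(all(abs(d$Ne - 1 / (1 - d$He)) < 1e-9))
  expect_true(all(d$Ne >= 1 & d$Ne <= d$Na))
  expect_true(all(d$Ho >= 0 & d$Ho <= 1 & d$He >= 0 & d$He <= 1))
  expect_true(all(d$Ar <= d$Na + 1e-12))
  expect_true(all(d$PIsib >= d$PI))
})

test_that("monomorphic loci give Na=1, Ne=1, He=0, Ar=1, PI=1", {
  panel <- marker_panel(c("L1", "L2"))
  recs <- make_geno(panel, list(id = "a", alleles = c(100, 100, 200, 202)),
                    list(id = "b", alleles = c(100, 100, 200, 200)))
  d <- locus_diversity(recs, panel, g = 2)
  mono <- d[d$locus == "L1", ]
  expect_equal(mono$Na, 1L)
  expect_equal(mono$Ne, 1)
  expect_equal(mono$He, 0)
  expect_equal(mono$Ho, 0)
  expect_equal(mono$Ar, 1)
  expect_equal(mono$PI, 1)
  expect_equal(mono$PIsib, 1)
})

test_that("rarefied allelic richness matches the closed form and enumeration", {
  f22 <- tibble::tibble(locus = "L1", allele = c(100L, 102L),
                        count = c(2L, 2L), freq = 0.5, n_typed = 2L)
  expect_equal(allelic_richness(f22, g = 2)$Ar, 5 / 3)  # 2(1 - C(2,2)/C(4,2))

  # exact subsample enumeration oracle for small copy totals
  enum_ar <- function(counts, g) {
    copies <- rep(seq_along(counts), counts)
    draws <- utils::combn(length(copies), g)
    mean(apply(draws, 2, function(ix) length(unique(copies[ix]))))
  }
  set.seed(42)
  for (rep in 1:8) {
    k <- sample(2:4, 1)
    counts <- as.integer(table(factor(sample.int(k, sample(6:12, 1),
                                                 replace = TRUE),
                                      levels = seq_len(k))))
    counts <- counts[counts > 0]
    N <- sum(counts)
    ft <- tibble::tibble(locus = "L1",
                         allele = 100L + 2L * seq_along(counts),
                         count = counts, freq = counts / N,
                         n_typed = as.integer(N / 2))
    for (g in 2:min(N, 8)) {
      expect_equal(allelic_richness(ft, g = g)$Ar, enum_ar(counts, g),
                   tolerance = 1e-12)
    }
  }
  expect_error(allelic_richness(f22, g = 1), "at least 2")
})

test_that("allelic richness is non-decreasing in the rarefaction depth", {
  col <- generate_collection(clean_config(9, n = 40))
  f <- allele_frequencies(col$records, col$panel)
  ar <- t(vapply(2:20, function(g) allelic_richness(f, g = g)$Ar,
                 numeric(nrow(col$panel))))
  expect_true(all(diff(ar) > -1e-12))
})

test_that("identity probabilities match their genotype-space enumerations", {
  pi_formula <- function(p) 2 * sum(p^2)^2 - sum(p^4)
  pisib_formula <- function(p) {
    0.25 + 0.5 * sum(p^2) + 0.5 * sum(p^2)^2 - 0.25 * sum(p^4)
  }
  # enumeration oracles over the full genotype space
  enum_pi <- function(p) {
    k <- length(p); tot <- 0
    for (i in 1:k) for (j in i:k) {
      pg <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
      tot <- tot + pg^2
    }
    tot
  }
  enum_pisib <- function(p) {
    k <- length(p)
    trans <- function(g, a) ((g[1] == a) + (g[2] == a)) / 2
    genos <- expand.grid(i = 1:k, j = 1:k)
    genos <- genos[genos$i <= genos$j, ]
    tot <- 0
    for (m in seq_len(nrow(genos))) for (f in seq_len(nrow(genos))) {
      gm <- unlist(genos[m, ]); gf <- unlist(genos[f, ])
      pm <- if (gm[1] == gm[2]) p[gm[1]]^2 else 2 * p[gm[1]] * p[gm[2]]
      pf <- if (gf[1] == gf[2]) p[gf[1]]^2 else 2 * p[gf[1]] * p[gf[2]]
      same <- 0
      for (a in 1:k) for (b in a:k) {
        pc <- trans(gm, a) * trans(gf, b) +
          (if (a != b) trans(gm, b) * trans(gf, a) else 0)
        same <- same + pc^2
      }
      tot <- tot + pm * pf * same
    }
    as.numeric(tot)
  }
  expect_equal(pi_formula(c(0.5, 0.5)), 0.375)
  expect_equal(pisib_formula(c(0.5, 0.5)), 0.59375)
  expect_equal(pi_formula(1), 1)
  expect_equal(pisib_formula(1), 1)
  expect_equal(pi_formula(rep(0.25, 4)), 0.109375)
  expect_equal(enum_pi(rep(0.25, 4)), 0.109375)
  set.seed(7)
  for (rep in 1:5) {
    k <- sample(2:4, 1)
    p <- as.vector(stats::rgamma(k, 1)); p <- p / sum(p)
    expect_equal(pi_formula(p), enum_pi(p), tolerance = 1e-12)
    expect_equal(pisib_formula(p), enum_pisib(p), tolerance = 1e-12)
  }
})

test_that("pi_profile orders loci ascending and accumulates products", {
  col <- generate_collection(clean_config(10, n = 60))
  f <- allele_frequencies(col$records, col$panel)
  prof <- pi_profile(f)
  expect_true(!is.unsorted(prof$PI))
  expect_equal(prof$cum_PI, cumprod(prof$PI))
  expect_equal(sort(prof$cum_PIsib)[1], prod(sort(prof$PIsib)),
               tolerance = 1e-12)
  expect_true(all(prof$PIsib >= prof$PI))
})

test_that("minimal marker sets discriminate or report unresolved pairs", {
  panel <- tiny_panel(3)
  recs <- make_geno(panel,
    list(id = "a", alleles = c(100, 100, 200, 200, 300, 300)),
    list(id = "b", alleles = c(102, 102, 200, 200, 300, 300)),
    list(id = "c", alleles = c(104, 104, 200, 200, 300, 300)))
  ms <- minimal_marker_set(recs, panel)
  expect_equal(attr(ms, "size"), 1L)
  expect_equal(ms$locus[1], "L1")   # the only discriminating locus

  dup <- make_geno(panel,
    list(id = "a", alleles = c(100, 100, 200, 200, 300, 300)),
    list(id = "b", alleles = c(100, 100, 200, 200, 300, 300)))
  md <- minimal_marker_set(dup, panel)
  expect_false(attr(md, "achieved"))
  expect_equal(nrow(attr(md, "unresolved")), 1L)
  expect_equal(glance(md)$n_unresolved_pairs, 1L)
})

test_that("the empirical marker set is never larger than the sib-mode set", {
  for (s in 1:6) {
    col <- generate_collection(clean_config(s, n = 100))
    emp <- minimal_marker_set(col$records, col$panel, mode = "empirical")
    sib <- minimal_marker_set(col$records, col$panel, mode = "sib")
    expect_lte(attr(emp, "size"), attr(sib, "size"))
  }
})

test_that("Fst is 0 for identical clusters, 1 for fixed alternatives", {
  panel <- marker_panel(c("L1", "L2"))
  same <- make_geno(panel,
    list(id = "a", alleles = c(100, 102, 200, 202)),
    list(id = "b", alleles = c(100, 102, 200, 202)),
    list(id = "c", alleles = c(100, 102, 200, 202)),
    list(id = "d", alleles = c(100, 102, 200, 202)))
  f0 <- fst_pairwise(same, c("c1", "c1", "c2", "c2"), panel)
  expect_equal(f0$fst, 0)

  fixed <- make_geno(panel,
    list(id = "a", alleles = c(100, 100, 200, 200)),
    list(id = "b", alleles = c(100, 100, 200, 200)),
    list(id = "c", alleles = c(102, 102, 202, 202)),
    list(id = "d", alleles = c(102, 102, 202, 202)))
  f1 <- fst_pairwise(fixed, c("c1", "c1", "c2", "c2"), panel)
  expect_equal(f1$fst, 1)

  five <- dplyr::bind_rows(fixed,
    make_geno(panel, list(id = "e", alleles = c(100, 102, 200, 202))))
  expect_warning(
    fst_pairwise(five, c("c1", "c1", "c2", "c2", "tiny"), panel),
    "fewer than 2")
})

test_that("two-island Fst matches the oracle on the true frequencies", {
  set.seed(11)
  panel <- tiny_panel(16)
  k <- 8
  alleles <- 100L + 2L * (0:(k - 1))
  p1 <- replicate(16, { w <- stats::rgamma(k, 1); w / sum(w) })
  drift <- replicate(16, exp(stats::rnorm(k, sd = 0.6)))
  p2 <- p1 * drift
  p2 <- sweep(p2, 2, colSums(p2), "/")
  draw_island <- function(p, n, prefix) {
    rows <- lapply(seq_len(n), function(i) {
      al <- unlist(lapply(seq_len(16), function(l) {
        sort(sample(alleles, 2, replace = TRUE, prob = p[, l]))
      }))
      list(id = sprintf("%s%03d", prefix, i), alleles = al)
    })
    do.call(make_geno, c(list(panel), rows))
  }
  recs <- dplyr::bind_rows(draw_island(p1, 250, "A"), draw_island(p2, 250, "B"))
  labels <- rep(c("isl1", "isl2"), each = 250)
  fst <- fst_pairwise(recs, labels, panel)$fst
  oracle <- mean(vapply(seq_len(16), function(l) {
    hs <- mean(c(1 - sum(p1[, l]^2), 1 - sum(p2[, l]^2)))
    pb <- (p1[, l] + p2[, l]) / 2
    ht <- 1 - sum(pb^2)
    (ht - hs) / ht
  }, numeric(1)))
  expect_lt(abs(fst - oracle), 0.01)
})

test_that("diversity glance reports unweighted arithmetic means", {
  col <- generate_collection(clean_config(12, n = 50))
  d <- locus_diversity(col$records, col$panel)
  g <- glance(d)
  expect_equal(g$He, mean(d$He))
  expect_equal(g$Na, mean(d$Na))
  expect_equal(g$n_loci, nrow(col$panel))
})
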