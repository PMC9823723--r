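test_that("simple matching similarity counts shared alleles per locus pair", {
  panel <- tiny_panel(16)
  base <- as.vector(rbind(seq(100, 160, by = 4), seq(100, 160, by = 4) + 2))
  g1 <- base
  g2 <- base; g2[32] <- g2[32] + 2   # one allele differs at the last locus
  g3 <- base + 40                    # no allele shared anywhere
  recs <- make_geno(panel,
    list(id = "a", alleles = g1), list(id = "b", alleles = g1),
    list(id = "c", alleles = g2), list(id = "d", alleles = g3))
  sim <- ssr_similarity(recs, panel)
  get <- function(x, y) sim[sim$id1 == x & sim$id2 == y, ]
  expect_equal(get("a", "b")$similarity, 1)
  expect_equal(get("a", "c")$similarity, 31 / 32)
  expect_equal(get("a", "c")$matching_alleles, 31L)
  expect_equal(get("a", "d")$similarity, 0)
})

test_that("similarity is symmetric, unit on self, NA when too few shared loci", {
  col <- generate_collection(dedup_config(2, n_cultivars = 8L))
  eng <- ssrcurate:::similarity_engine(col$records, col$panel)
  expect_equal(eng$similarity, t(eng$similarity))
  complete <- rowSums(is.na(col$records[paste0(col$panel$locus, ".1")])) == 0
  expect_true(all(diag(eng$similarity)[complete] == 1))

  panel <- tiny_panel(16)
  sparse <- rep(NA_integer_, 32); sparse[1:8] <- c(100, 102, 104, 106, 108,
                                                   110, 112, 114)
  full <- seq(100, 162, by = 2)
  recs <- make_geno(panel, list(id = "a", alleles = sparse),
                    list(id = "b", alleles = full))
  sim <- ssr_similarity(recs, panel, min_shared = 8)
  expect_false(sim$comparable[1])  # 4 shared loci < 8
  expect_true(is.na(sim$similarity[1]))
})

test_that("exact copies group together and singletons stand alone", {
  panel <- tiny_panel(16)
  g <- seq(100, 162, by = 2)
  recs <- make_geno(panel,
    list(id = "a", alleles = g), list(id = "b", alleles = g),
    list(id = "c", alleles = g), list(id = "d", alleles = g + 40))
  grp <- build_groups(recs, panel)
  expect_equal(sort(table(grp$group_id), decreasing = TRUE),
               sort(table(c("G001", "G001", "G001", "G002")), decreasing = TRUE),
               ignore_attr = TRUE)
  expect_equal(sum(grp$is_representative), 2L)
  expect_equal(glance(grp)$n_groups, 2L)
})

test_that("single linkage chains above-threshold pairs into one logged group", {
  panel <- tiny_panel(10)
  base <- as.vector(rbind(seq(100, 136, by = 4), seq(100, 136, by = 4) + 2))
  gA <- base
  gB <- base; gB[2] <- gB[2] + 40            # A~B: 19/20 = 0.95
  gC <- gB;   gC[4] <- gC[4] + 40            # B~C: 0.95; A~C: 18/20 = 0.90
  recs <- make_geno(panel, list(id = "A", alleles = gA),
                    list(id = "B", alleles = gB), list(id = "C", alleles = gC))
  sim <- ssr_similarity(recs, panel)
  expect_equal(sort(sim$similarity), c(0.90, 0.95, 0.95))
  grp <- build_groups(recs, panel, threshold = 0.90)
  expect_equal(length(unique(grp$group_id)), 1L)      # 0.90 is not > 0.90,
  expect_equal(attr(grp, "transitive"), "G001")       # chained via B
})

test_that("groups partition the accessions and the representative is modal", {
  col <- generate_collection(dedup_config(4))
  bins <- build_bins(col$records, col$panel)
  h <- harmonize_genotypes(col$records, col$panel, bins = bins)
  grp <- build_groups(h, col$panel)
  expect_setequal(grp$accession_id, col$records$accession_id)
  expect_equal(anyDuplicated(grp$accession_id), 0L)
  reps <- attr(grp, "representatives")
  expect_setequal(reps$group_id, unique(grp$group_id))
  expect_true(all(reps$support >= 1))
  # representative genotype is carried by at least `support` members
  cols <- as.vector(rbind(paste0(col$panel$locus, ".1"),
                          paste0(col$panel$locus, ".2")))
  key <- apply(as.matrix(h[cols]), 1, paste, collapse = "/")
  for (i in seq_len(nrow(reps))) {
    members <- which(grp$group_id == reps$group_id[i])
    rep_key <- key[match(reps$accession_id[i], h$accession_id)]
    expect_gte(sum(key[members] == rep_key), reps$support[i])
  }
})

test_that("planted clone structure is recovered exactly under certified margins", {
  for (s in c(1, 2)) {
    col <- generate_collection(dedup_config(s))
    expect_true(certify_margins(col)$certified)
    bins <- build_bins(col$records, col$panel)
    h <- harmonize_genotypes(col$records, col$panel, bins = bins)
    grp <- build_groups(h, col$panel)
    expect_equal(length(unique(grp$group_id)), 50L)
    expect_true(groups_match_truth(grp, col$truth))
  }
})

test_that("trueness-to-type categories follow determination and consensus", {
  panel <- tiny_panel(16)
  g <- seq(100, 162, by = 2)
  recs <- make_geno(panel,
    list(id = "a1", alleles = g, status = "determined", determined_name = "Regina"),
    list(id = "a2", alleles = g, status = "determined", determined_name = "Regina"),
    list(id = "a3", alleles = g, status = "determined", determined_name = "Regina"),
    list(id = "a4", alleles = g, status = "determined", determined_name = "Regina"),
    list(id = "a5", alleles = g, status = "determined", determined_name = "Regina"))
  grp <- build_groups(recs, panel)
  cats <- assign_categories(grp, recs, reference_names = "Regina")
  expect_equal(cats$category, rep(1L, 5))
  expect_equal(cats$resolved_name, rep("Regina", 5))
  expect_false(any(cats$relabel))
})

test_that("a determination conflicting with its group consensus is relabeled", {
  panel <- tiny_panel(16)
  g <- seq(100, 162, by = 2)
  recs <- make_geno(panel,
    list(id = "b1", alleles = g, status = "determined",
         determined_name = "Büttners Rote Knorpelkirsche"),
    list(id = "b2", alleles = g, status = "determined",
         determined_name = "Büttners Rote Knorpelkirsche"),
    list(id = "q1", alleles = g, status = "determined",
         determined_name = "Querfurter Königskirsche"))
  grp <- build_groups(recs, panel)
  cats <- assign_categories(grp, recs)
  q <- cats[cats$accession_id == "q1", ]
  expect_equal(q$category, 1L)
  expect_equal(q$resolved_name, "Büttners Rote Knorpelkirsche")
  expect_true(q$relabel)

  # an exact tie between determined names leaves the group unresolved
  tie <- recs[c(1, 3), ]
  gt <- build_groups(tie, panel)
  ct <- assign_categories(gt, tie)
  expect_true(all(ct$unresolved))
  expect_true(all(is.na(ct$category)))
})

test_that("category counts match planted pomological statuses and sum to n", {
  col <- generate_collection(dedup_config(6, n_cultivars = 60L))
  bins <- build_bins(col$records, col$panel)
  h <- harmonize_genotypes(col$records, col$panel, bins = bins)
  grp <- build_groups(h, col$panel)
  cats <- assign_categories(grp, h, col$truth$reference_names)
  expect_equal(nrow(cats), nrow(col$records))
  planted <- table(col$records$pomological_status)
  got <- table(cats$category)
  expect_equal(unname(got[["1"]]), unname(planted[["determined"]]))
  expect_equal(unname(got[["3"]]), unname(planted[["no_reference"]]))
  if ("not_determined" %in% names(planted))
    expect_equal(unname(got[["4"]]), unname(planted[["not_determined"]]))
  if ("with_reservation" %in% names(planted))
    expect_equal(unname(got[["5"]]), unname(planted[["with_reservation"]]))
  expect_equal(sum(got) + sum(is.na(cats$category)), nrow(col$records))
})
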