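#' Run the full curation pipeline
#'
#' Orchestrates harmonize, deduplicate, categorize, diversity / identity
#' probability, phylogeny and parentage verification with one call, writing
#' every result as a plain-text CSV (and the tree as newick) plus a
#' machine-readable JSON manifest of all parameters and seeds, so a rerun
#' with the same inputs and seeds reproduces every output byte for byte. A
#' stage failure aborts with the stage name; outputs of completed stages are
#' retained.
#'
#' @param records Genotype tibble (see [read_genotype_table()]).
#' @param panel The [marker_panel()].
#' @param out_dir Output directory (created if needed).
#' @param reference_ids,reference_batch Reference genotypes (assumed names)
#'   and target batch for offset estimation; `NULL` skips offset correction.
#' @param reference_names Cultivar names with pomological references.
#' @param pedigree Optional pedigree hypothesis tibble ([read_pedigree()]).
#' @param threshold Similarity threshold for molecular grouping.
#' @param min_shared Minimum mutually typed loci per comparison.
#' @param bootstrap Bootstrap replicates for the tree stage (0 = plain NJ
#'   tree without supports; negative = skip the tree stage).
#' @param parentage A [parentage_config()].
#' @param seed Integer seed for all stochastic stages.
#' @return Invisibly, a list with the stage results: `records_harmonized`,
#'   `offsets`, `bins`, `groups`, `categories`, `category_summary`,
#'   `diversity`, `pi`, `marker_set`, `tree`, `parentage`, `manifest`.
#' @export
run_curation <- function(records, panel, out_dir,
                         reference_ids = NULL,
                         reference_batch = NULL,
                         reference_names = character(0),
                         pedigree = NULL,
                         threshold = 0.90,
                         min_shared = 8L,
                         bootstrap = 0L,
                         parentage = parentage_config(),
                         seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  res <- list()

  res$offsets <- stage("harmonize", {
    if (!is.null(reference_ids)) {
      estimate_offsets(records, reference_ids, panel,
                       reference_batch %||% records$lab_batch[1])
    } else NULL
  })
  res$bins <- stage("harmonize", {
    pre <- harmonize_genotypes(records, panel, offsets = res$offsets)
    build_bins(pre, panel)
  })
  res$records_harmonized <- stage("harmonize", {
    harmonize_genotypes(records, panel, offsets = res$offsets,
                        bins = res$bins)
  })

  res$groups <- stage("dedup", {
    g <- build_groups(res$records_harmonized, panel, threshold, min_shared)
    readr::write_csv(tibble::as_tibble(g), file.path(out_dir, "groups.csv"))
    g
  })

  res$categories <- stage("categorize", {
    cat_tbl <- assign_categories(res$groups, res$records_harmonized,
                                 reference_names)
    readr::write_csv(cat_tbl, file.path(out_dir, "categories.csv"))
    cat_tbl
  })
  res$category_summary <- stage("categorize", {
    s <- dplyr::count(res$categories,
                      .data$category, .data$category_label, name = "n_trees")
    s$pct_trees <- round(100 * s$n_trees / nrow(res$categories), 2)
    readr::write_csv(s, file.path(out_dir, "category_summary.csv"))
    s
  })

  reps <- stage("diversity", {
    representative_genotypes(res$groups, res$records_harmonized)
  })
  res$diversity <- stage("diversity", {
    d <- locus_diversity(reps, panel)
    tab <- dplyr::bind_rows(
      d, dplyr::bind_cols(tibble::tibble(locus = "Mean"),
                          glance(d)[, setdiff(names(glance(d)), c("g", "n_loci"))])
    )
    readr::write_csv(tab, file.path(out_dir, "diversity.csv"))
    d
  })
  res$pi <- stage("diversity", {
    p <- pi_profile(allele_frequencies(reps, panel))
    readr::write_csv(p, file.path(out_dir, "pi.csv"))
    p
  })
  res$marker_set <- stage("diversity", {
    m <- minimal_marker_set(reps, panel, mode = "empirical")
    readr::write_csv(tibble::as_tibble(m), file.path(out_dir, "marker_set.csv"))
    m
  })

  res$tree <- stage("phylogeny", {
    if (bootstrap < 0 || nrow(reps) < 4) NULL else {
      reps_t <- reps
      reps_t$accession_id <- reps_t$group_id
      tr <- if (bootstrap == 0) {
        neighbor_joining(dissimilarity_matrix(reps_t, panel, min_shared))
      } else {
        bootstrap_support(reps_t, panel, B = bootstrap, seed = seed,
                          min_shared = min_shared)
      }
      write_newick(tr, file.path(out_dir, "tree.nwk"))
      tr
    }
  })

  res$parentage <- stage("parentage", {
    if (is.null(pedigree)) NULL else {
      pr <- verify_pedigrees(pedigree, reps_named(reps, res$categories), panel,
                             config = parentage, seed = seed)
      readr::write_csv(tibble::as_tibble(pr),
                       file.path(out_dir, "parentage.csv"))
      pr
    }
  })

  res$manifest <- stage("manifest", {
    mf <- list(
      package = "ssrcurate",
      version = as.character(utils::packageVersion("ssrcurate")),
      seed = seed,
      parameters = list(
        threshold = threshold, min_shared = min_shared,
        bootstrap = bootstrap,
        parentage = unclass(parentage),
        reference_batch = reference_batch %||% NA,
        n_records = nrow(records), n_loci = nrow(panel)
      ),
      outputs = list.files(out_dir, pattern = "\\.(csv|nwk)$")
    )
    jsonlite::write_json(mf, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    mf
  })
  invisible(res)
}

# representatives keyed by resolved cultivar name where available, so
# pedigree hypotheses phrased in cultivar names can be matched
reps_named <- function(reps, categories) {
  out <- reps
  nm <- categories$resolved_name[match(reps$accession_id,
                                       categories$accession_id)]
  out$accession_id <- ifelse(!is.na(nm) & nm != "", nm, reps$accession_id)
  out[!duplicated(out$accession_id), , drop = FALSE]
}
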