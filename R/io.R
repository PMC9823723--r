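#' Read a two-column-per-locus SSR genotype table
#'
#' Reads a GenAlEx-style CSV with one row per tree and two columns per locus
#' (`<locus>.1`, `<locus>.2`, integer fragment sizes in bp). A two-line
#' GenAlEx numeric header before the column-name row is detected and skipped.
#' Missing alleles may be encoded as `0` or left empty; a homozygote given
#' once is expanded to a duplicated size, and every pair is stored sorted
#' ascending.
#'
#' Passport columns `accession_id` (required), `collection`, `assumed_name`,
#' `pomological_status`, `determined_name` and `lab_batch` are carried
#' through; absent ones are filled with defaults (`pomological_status`
#' defaults to `"not_determined"`).
#'
#' @param path Path to a CSV file (UTF-8; cultivar names may carry umlauts).
#' @param panel An [marker_panel()]; its loci must be present in the file.
#' @param locus_map Optional named character vector mapping panel locus names
#'   to the column-name prefixes used in the file (dialect tolerance), e.g.
#'   `c("UDP98-412" = "UDP98412")`.
#'
#' @return A tibble with one row per accession, passport columns first, then
#'   two integer allele columns per panel locus, in input order.
#' @export
read_genotype_table <- function(path, panel, locus_map = NULL) {
  lines <- readr::read_lines(path, n_max = 3L)
  skip <- 0L
  if (length(lines) >= 3L) {
    first <- strsplit(lines[1], ",")[[1]][1]
    if (!is.na(suppressWarnings(as.numeric(first))) &&
        grepl("accession_id", lines[3], fixed = TRUE)) {
      skip <- 2L
    }
  }
  raw <- readr::read_csv(path, skip = skip, col_types = readr::cols(.default = readr::col_character()),
                         locale = readr::locale(encoding = "UTF-8"),
                         progress = FALSE, show_col_types = FALSE)
  if (!"accession_id" %in% names(raw)) stop("column 'accession_id' is required")
  if (anyDuplicated(raw$accession_id)) {
    dup <- unique(raw$accession_id[duplicated(raw$accession_id)])
    stop("duplicate accession_id: ", paste(dup, collapse = ", "))
  }

  # map panel loci onto file column prefixes
  prefix <- rlang::set_names(panel$locus, panel$locus)
  if (!is.null(locus_map)) prefix[names(locus_map)] <- locus_map

  out <- tibble::tibble(
    accession_id       = raw$accession_id,
    collection         = raw[["collection"]] %||% NA_character_,
    assumed_name       = raw[["assumed_name"]] %||% NA_character_,
    pomological_status = raw[["pomological_status"]] %||% "not_determined",
    determined_name    = raw[["determined_name"]] %||% NA_character_,
    lab_batch          = raw[["lab_batch"]] %||% "batch1"
  )
  validate_pomological_status(out$pomological_status, out$determined_name)

  for (i in seq_len(nrow(panel))) {
    loc <- panel$locus[i]
    for (slot in 1:2) {
      col_in <- paste0(prefix[[loc]], ".", slot)
      col_out <- paste0(loc, ".", slot)
      if (!col_in %in% names(raw)) {
        stop("missing allele column '", col_in, "' for locus ", loc)
      }
      v <- raw[[col_in]]
      v[v %in% c("", "0", "NA")] <- NA_character_
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & (is.na(num) | num != round(num)))
      if (length(bad) > 0) {
        stop("non-integer allele at row ", bad[1], ", column ", col_in,
             " (value '", v[bad[1]], "')")
      }
      iv <- as.integer(num)
      rng <- c(panel$size_min[i], panel$size_max[i])
      if (!anyNA(rng)) {
        out_of_range <- which(!is.na(iv) & (iv < rng[1] | iv > rng[2]))
        if (length(out_of_range) > 0) {
          warning("locus ", loc, ": ", length(out_of_range),
                  " allele(s) outside declared range [", rng[1], ", ", rng[2],
                  "]; records kept", call. = FALSE)
        }
      }
      out[[col_out]] <- iv
    }
  }
  canonicalize_genotypes(out, panel)
}

validate_pomological_status <- function(status, determined_name) {
  ok <- c("determined", "no_reference", "not_determined", "with_reservation")
  bad <- setdiff(unique(status), ok)
  if (length(bad) > 0) {
    stop("unknown pomological_status: ", paste(bad, collapse = ", "),
         " (expected one of ", paste(ok, collapse = ", "), ")")
  }
  named <- status %in% c("determined", "with_reservation")
  noname <- named & (is.na(determined_name) | determined_name == "")
  if (any(noname)) {
    stop("pomological_status 'determined'/'with_reservation' requires a ",
         "non-empty determined_name (", sum(noname), " offending row(s))")
  }
  invisible(TRUE)
}

#' Write a genotype table as a GenAlEx-style CSV
#'
#' Emits the two-columns-per-locus integer layout preceded by the two-line
#' GenAlEx numeric header (number of samples, number of loci, number of
#' populations and their sizes; populations are the `collection` values).
#' Missing alleles are written as `0`. The file round-trips through
#' [read_genotype_table()].
#'
#' @param records Genotype tibble as returned by [read_genotype_table()] or
#'   [generate_collection()].
#' @param path Output CSV path.
#' @param panel The [marker_panel()] describing the allele columns.
#' @return `path`, invisibly.
#' @export
write_genalex <- function(records, path, panel) {
  if (nrow(records) == 0L) stop("no records to write")
  pops <- records$collection %||% rep("pop1", nrow(records))
  pops[is.na(pops)] <- "pop1"
  pop_sizes <- table(factor(pops, levels = unique(pops)))
  header1 <- paste(c(nrow(records), nrow(panel), length(pop_sizes),
                     as.integer(pop_sizes)), collapse = ",")
  header2 <- paste(c("ssrcurate export", "", names(pop_sizes)), collapse = ",")

  passport <- c("accession_id", "collection", "assumed_name",
                "pomological_status", "determined_name", "lab_batch")
  for (p in passport) if (!p %in% names(records)) records[[p]] <- NA_character_
  body <- records[, c(passport, locus_cols(panel))]
  for (cc in locus_cols(panel)) {
    v <- body[[cc]]
    v[is.na(v)] <- 0L
    body[[cc]] <- v
  }
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(header1, header2), con)
  readr::write_csv(body, con, na = "", append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read pedigree hypotheses from CSV
#'
#' Expects columns `child`, `mother`, `father` (cultivar names). An unknown
#' parent is encoded as empty, `NA` or `"UNKNOWN"`. Each hypothesis must name
#' at least one parent, and the child may not appear as its own parent.
#'
#' @param path CSV path.
#' @return A tibble with columns `child`, `mother`, `father` (`NA` = unknown).
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         locale = readr::locale(encoding = "UTF-8"),
                         progress = FALSE, show_col_types = FALSE)
  need <- c("child", "mother", "father")
  if (!all(need %in% names(ped))) {
    stop("pedigree CSV needs columns: ", paste(need, collapse = ", "))
  }
  ped <- tibble::as_tibble(ped[need])
  for (cc in need) {
    v <- ped[[cc]]
    v[v %in% c("", "UNKNOWN", "unknown", "open pollinated")] <- NA_character_
    ped[[cc]] <- v
  }
  if (anyNA(ped$child)) stop("every hypothesis needs a child name")
  no_parent <- is.na(ped$mother) & is.na(ped$father)
  if (any(no_parent)) {
    stop("hypothesis without any named parent: ",
         paste(ped$child[no_parent], collapse = ", "))
  }
  self <- !is.na(ped$mother) & ped$mother == ped$child |
    !is.na(ped$father) & ped$father == ped$child
  if (any(self)) {
    stop("child named as its own parent: ",
         paste(ped$child[self], collapse = ", "))
  }
  ped
}

#' Write a phylogenetic tree in newick format
#'
#' Writes an `ape::phylo` tree with branch lengths; internal node labels
#' (e.g. bootstrap supports) are emitted as newick internal labels. Leaf
#' labels containing spaces or newick metacharacters are single-quoted so the
#' file stays parseable by standard newick readers.
#'
#' @param tree An `ape::phylo` object with labeled tips.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  labs <- tree$tip.label
  if (is.null(labs) || any(is.na(labs) | labs == "")) {
    stop("every leaf must carry a non-empty label")
  }
  quote_label <- function(x) {
    needs <- grepl("[][ ,():;']", x)
    ifelse(needs, paste0("'", gsub("'", "''", x), "'"), x)
  }
  ntip <- length(labs)
  node_lab <- tree$node.label
  elen <- tree$edge.length
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  serialize <- function(node, edge_idx) {
    if (node <= ntip) {
      s <- quote_label(labs[node])
    } else {
      parts <- vapply(kids[[as.character(node)]], function(e) {
        serialize(tree$edge[e, 2], e)
      }, character(1))
      nl <- if (!is.null(node_lab)) node_lab[node - ntip] else ""
      if (is.na(nl)) nl <- ""
      s <- paste0("(", paste(parts, collapse = ","), ")", nl)
    }
    if (!is.na(edge_idx) && !is.null(elen) && !is.na(elen[edge_idx])) {
      s <- paste0(s, ":", format(elen[edge_idx], digits = 10))
    }
    s
  }
  root <- ntip + 1L
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0(serialize(root, NA_integer_), ";"), con)
  invisible(path)
}

#' Read a newick tree
#'
#' Thin wrapper around `ape::read.tree` that restores labels single-quoted by
#' [write_newick()].
#'
#' @param path Newick file path.
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  tree$tip.label <- gsub("''", "'", gsub("^'|'$", "", tree$tip.label))
  tree
}

`%||%` <- function(x, y) if (is.null(x)) y else x
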