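#' @importFrom rlang .data abort warn inform %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

#' Recognised annotation sources
#'
#' Chemical-gene association records carry a source attribution matching the
#' databases a CTD/STITCH-style export mixes: curated toxicogenomics (CTD),
#' chemical-protein interactions (STITCH), Connectivity Map up/down signatures
#' (CMAP_UP, CMAP_DOWN), DrugBank targets (DRUGBANK), or anything else (OTHER).
#'
#' @return Character vector of the recognised source codes.
#' @export
association_sources <- function() {
  c("CTD", "STITCH", "CMAP_UP", "CMAP_DOWN", "DRUGBANK", "OTHER")
}

assoc_columns <- c("chemical_id", "chemical_name", "gene_symbol",
                   "source", "evidence")

#' Validate a data frame of chemical-gene associations
#'
#' Coerces a data frame to a canonical association table: gene symbols are
#' uppercased, duplicate `(chemical_id, gene_symbol, source)` triples are
#' collapsed (the same gene/chemical pair from two sources is kept as two
#' records so provenance survives), and source/evidence codes are checked
#' against their enumerations.
#'
#' @param x A data frame with columns `chemical_id`, `chemical_name`,
#'   `gene_symbol`, `source` and `evidence` (or the names mapped by `dialect`).
#' @param dialect Optional named character vector mapping canonical column
#'   names to the names used in `x`, e.g.
#'   `c(chemical_id = "ChemicalID", gene_symbol = "GeneSymbol")`. Unmapped
#'   canonical names are looked up directly.
#' @param quiet Suppress the record-count message.
#' @return A tibble of class `assoc_table` with the five canonical columns.
#' @export
as_association_table <- function(x, dialect = NULL, quiet = FALSE) {
  x <- as_tibble(x)
  if (!is.null(dialect)) {
    bad <- setdiff(names(dialect), assoc_columns)
    if (length(bad) > 0) {
      abort(paste0("Unknown column(s) in dialect mapping: ",
                   paste(bad, collapse = ", ")))
    }
    for (canon in names(dialect)) {
      if (!dialect[[canon]] %in% names(x)) {
        abort(paste0("Association table is missing mapped column '",
                     dialect[[canon]], "' (for '", canon, "')"))
      }
      names(x)[names(x) == dialect[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(assoc_columns, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Association table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) {
    abort("Association table has no records")
  }
  x <- x |>
    select(all_of(assoc_columns)) |>
    mutate(across(all_of(assoc_columns), as.character),
           gene_symbol = toupper(.data$gene_symbol))
  if (any(is.na(x$gene_symbol) | x$gene_symbol == "")) {
    abort("gene_symbol must be non-empty for every record")
  }
  bad_src <- setdiff(unique(x$source), association_sources())
  if (length(bad_src) > 0) {
    abort(paste0("Unknown source code(s): ", paste(bad_src, collapse = ", "),
                 "; expected one of ",
                 paste(association_sources(), collapse = ", ")))
  }
  bad_ev <- setdiff(unique(x$evidence), c("curated", "inferred"))
  if (length(bad_ev) > 0) {
    abort(paste0("Unknown evidence code(s): ", paste(bad_ev, collapse = ", "),
                 "; expected 'curated' or 'inferred'"))
  }
  n_raw <- nrow(x)
  x <- distinct(x, .data$chemical_id, .data$gene_symbol, .data$source,
                .keep_all = TRUE)
  if (!quiet) {
    inform(sprintf(
      "Association table: %d records (%d duplicate triples collapsed), %d chemicals, %d genes",
      nrow(x), n_raw - nrow(x), n_distinct(x$chemical_id),
      n_distinct(x$gene_symbol)))
  }
  class(x) <- c("assoc_table", class(x))
  x
}

#' Read a chemical-gene association table from TSV
#'
#' Expects a UTF-8 TSV with a header row naming the five canonical columns
#' (`chemical_id`, `chemical_name`, `gene_symbol`, `source`, `evidence`),
#' or any column names via `dialect`.
#'
#' @inheritParams as_association_table
#' @param path Path to the TSV file.
#' @return A validated `assoc_table` tibble.
#' @export
read_associations <- function(path, dialect = NULL, quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (nrow(x) == 0) abort(paste0("Association file is empty: ", path))
  as_association_table(x, dialect = dialect, quiet = quiet)
}

#' Write an association table as canonical TSV
#'
#' Fixed column order: chemical_id, chemical_name, gene_symbol, source,
#' evidence.
#'
#' @param x An `assoc_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(x, path) {
  stopifnot(inherits(x, "assoc_table"))
  readr::write_tsv(x[, assoc_columns], path, progress = FALSE)
  invisible(path)
}

#' Background gene universe of an association table
#'
#' The set of all annotated gene symbols; its size is the `N` of the
#' enrichment statistic (the default background is every gene that carries
#' at least one annotation).
#'
#' @param x An `assoc_table`.
#' @return Sorted character vector of distinct gene symbols.
#' @export
gene_universe <- function(x) {
  stopifnot(inherits(x, "assoc_table"))
  sort(unique(x$gene_symbol))
}

#' Merge association tables
#'
#' Union of records with duplicate-triple collapse; the merged universe is the
#' union of the input universes. Commutative and associative up to record-set
#' equality.
#'
#' @param ... `assoc_table` objects, or a single list of them.
#' @return A merged `assoc_table`.
#' @export
merge_associations <- function(...) {
  tables <- list(...)
  if (length(tables) == 1 && is.list(tables[[1]]) &&
      !inherits(tables[[1]], "data.frame")) {
    tables <- tables[[1]]
  }
  if (length(tables) == 0) abort("Nothing to merge: no tables supplied")
  stopifnot(all(vapply(tables, inherits, logical(1), "assoc_table")))
  merged <- bind_rows(lapply(tables, function(t) {
    class(t) <- setdiff(class(t), "assoc_table")
    t
  }))
  as_association_table(merged, quiet = TRUE)
}

#' Per-chemical annotation sets
#'
#' Collapses association records into the annotation sets the enrichment
#' statistic tests. By default each `(chemical_id, source)` pair is one
#' testable unit, mirroring per-database drug terms, except that Connectivity
#' Map up and down signatures are pooled into a single `CMAP` set per chemical
#' (set `split_cmap_direction = TRUE` to keep them separate). With
#' `by_source = FALSE` all sources pool into one set per chemical -- the view
#' the network-building step uses.
#'
#' @param x An `assoc_table`.
#' @param by_source Test each chemical/source pair separately (default) or
#'   pool sources per chemical.
#' @param split_cmap_direction Keep CMAP_UP and CMAP_DOWN as distinct units
#'   (only meaningful when `by_source = TRUE`).
#' @return A tibble with columns `chemical_id`, `chemical_name`, `source`
#'   (comma-joined when pooled) and `genes` (list column of sorted symbol
#'   vectors).
#' @export
chemical_sets <- function(x, by_source = TRUE, split_cmap_direction = FALSE) {
  stopifnot(inherits(x, "assoc_table"))
  x <- as_tibble(x)
  unit <- if (by_source) {
    if (split_cmap_direction) x$source
    else ifelse(x$source %in% c("CMAP_UP", "CMAP_DOWN"), "CMAP", x$source)
  } else {
    "pooled"
  }
  x |>
    mutate(.unit = unit) |>
    group_by(.data$chemical_id, .data$.unit) |>
    summarise(
      chemical_name = first(.data$chemical_name),
      source = paste(sort(unique(.data$source)), collapse = ","),
      genes = list(sort(unique(.data$gene_symbol))),
      .groups = "drop") |>
    mutate(source = if (by_source) {
      ifelse(.data$.unit == "CMAP", "CMAP", .data$source)
    } else {
      .data$source
    }) |>
    select(-".unit") |>
    arrange(.data$chemical_id, .data$source)
}
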