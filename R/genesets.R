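#' Default gene exclusions for the AMD catalog
#'
#' Genes recurrently reported with macular dystrophies that are distinct from
#' age-related macular degeneration (Stargardt disease and allied monogenic
#' conditions) and therefore removed from every curated AMD list before
#' enrichment: ABCA4, ELOVL4, PROM1, BEST1.
#'
#' @return Character vector of gene symbols.
#' @export
amd_exclusions <- function() {
  c("ABCA4", "ELOVL4", "PROM1", "BEST1")
}

new_gene_catalog <- function(x) {
  x <- as_tibble(x)[, c("label", "gene")]
  class(x) <- c("gene_catalog", setdiff(class(x), "gene_catalog"))
  x
}

#' Build a gene-set catalog from labelled gene vectors
#'
#' A catalog is a long tibble (`label`, `gene`) holding one row per gene-set
#' membership, with set semantics per label (symbols uppercased, duplicates
#' collapsed).
#'
#' @param sets Named list of character vectors of gene symbols.
#' @return A `gene_catalog` tibble.
#' @export
gene_catalog <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("Every gene set needs a non-empty label")
  }
  if (anyDuplicated(names(sets))) {
    abort(paste0("Duplicate gene-set label(s): ",
                 paste(unique(names(sets)[duplicated(names(sets))]),
                       collapse = ", ")))
  }
  rows <- purrr::imap(sets, function(genes, label) {
    genes <- toupper(as.character(genes))
    genes <- genes[!is.na(genes) & genes != ""]
    if (length(genes) == 0) abort(paste0("Gene set '", label, "' is empty"))
    tibble(label = label, gene = sort(unique(genes)))
  })
  new_gene_catalog(bind_rows(rows))
}

#' Extract one set from a catalog
#'
#' @param catalog A `gene_catalog`.
#' @param label Set label.
#' @return Character vector of member gene symbols.
#' @export
gene_set <- function(catalog, label) {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (!label %in% catalog$label) {
    abort(paste0("Unknown gene-set label: ", label))
  }
  sort(catalog$gene[catalog$label == label])
}

#' Labels in a catalog
#' @param catalog A `gene_catalog`.
#' @return Character vector of set labels, in first-appearance order.
#' @export
catalog_labels <- function(catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  unique(catalog$label)
}

#' Read disease gene lists into a catalog
#'
#' Accepts plain-text lists (one symbol per line, `#` comments and blank lines
#' ignored; the set label defaults to the file name without extension) and/or
#' GMT files (tab-separated: label, description, then members). Within-list
#' duplicates are collapsed with a logged count.
#'
#' @param paths Character vector of file paths. Files ending in `.gmt` are
#'   parsed as GMT; anything else as a plain list.
#' @param labels Optional labels for the plain-list files (recycled against
#'   the non-GMT entries of `paths`).
#' @param quiet Suppress per-set messages.
#' @return A `gene_catalog`.
#' @export
read_gene_lists <- function(paths, labels = NULL, quiet = FALSE) {
  stopifnot(length(paths) >= 1)
  sets <- list()
  plain_idx <- 0
  for (path in paths) {
    if (!file.exists(path)) abort(paste0("No such file: ", path))
    if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
      for (row in strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)) {
        if (length(row) < 3) {
          abort(paste0("Malformed GMT row (need label, description, >=1 gene) in ",
                       path))
        }
        lab <- row[[1]]
        if (lab %in% names(sets)) abort(paste0("Duplicate gene-set label: ", lab))
        sets[[lab]] <- row[-(1:2)]
      }
    } else {
      lines <- readLines(path, warn = FALSE)
      lines <- trimws(sub("#.*$", "", lines))
      genes <- lines[lines != ""]
      if (length(genes) == 0) abort(paste0("Gene list file is empty: ", path))
      plain_idx <- plain_idx + 1
      lab <- if (!is.null(labels) && plain_idx <= length(labels)) {
        labels[[plain_idx]]
      } else {
        sub("\\.[^.]*$", "", basename(path))
      }
      if (lab %in% names(sets)) abort(paste0("Duplicate gene-set label: ", lab))
      n_dup <- length(genes) - length(unique(toupper(genes)))
      if (!quiet && n_dup > 0) {
        inform(sprintf("Gene list '%s': %d duplicate symbol(s) collapsed",
                       lab, n_dup))
      }
      sets[[lab]] <- genes
    }
  }
  gene_catalog(sets)
}

#' Write a catalog as GMT
#'
#' @param catalog A `gene_catalog`.
#' @param path Output path.
#' @param descriptions Optional named character vector of per-label
#'   descriptions (defaults to the label itself).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path, descriptions = NULL) {
  stopifnot(inherits(catalog, "gene_catalog"))
  lines <- vapply(catalog_labels(catalog), function(lab) {
    desc <- descriptions[lab] %||% lab
    paste(c(lab, unname(desc), gene_set(catalog, lab)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Remove excluded genes from every set in a catalog
#'
#' Applies the manual-curation step that drops genes attributed to distinct
#' macular dystrophies from every disease list. Excluding absent genes is a
#' no-op and the operation is idempotent.
#'
#' @param catalog A `gene_catalog`.
#' @param exclusions Character vector of gene symbols to remove
#'   (default [amd_exclusions()]; may be empty).
#' @param quiet Suppress the per-set removal counts.
#' @return The filtered `gene_catalog`.
#' @export
exclude_genes <- function(catalog, exclusions = amd_exclusions(),
                          quiet = FALSE) {
  stopifnot(inherits(catalog, "gene_catalog"))
  exclusions <- toupper(exclusions)
  out <- catalog[!(catalog$gene %in% exclusions), , drop = FALSE]
  if (!quiet) {
    removed <- catalog |>
      as_tibble() |>
      group_by(.data$label) |>
      summarise(n = sum(.data$gene %in% exclusions), .groups = "drop") |>
      filter(.data$n > 0)
    for (i in seq_len(nrow(removed))) {
      inform(sprintf("Excluded %d gene(s) from '%s'",
                     removed$n[i], removed$label[i]))
    }
  }
  if (any(!catalog_labels(catalog) %in% out$label)) {
    abort("Exclusion emptied at least one gene set")
  }
  new_gene_catalog(out)
}

#' Combine subtype gene sets by union
#'
#' Adds the plain set union of the named sets to the catalog under a new
#' label, mirroring the combined disease-stage lists (e.g. intermediate plus
#' dry, or intermediate plus dry plus geographic atrophy).
#'
#' @param catalog A `gene_catalog`.
#' @param combine_labels Labels of the sets to union.
#' @param new_label Label for the combined set.
#' @return The catalog with the combined set appended.
#' @export
combine_subtypes <- function(catalog, combine_labels, new_label) {
  stopifnot(inherits(catalog, "gene_catalog"))
  missing_lab <- setdiff(combine_labels, catalog_labels(catalog))
  if (length(missing_lab) > 0) {
    abort(paste0("Unknown gene-set label(s): ",
                 paste(missing_lab, collapse = ", ")))
  }
  if (new_label %in% catalog_labels(catalog)) {
    abort(paste0("Label already in catalog: ", new_label))
  }
  members <- sort(unique(unlist(lapply(combine_labels, gene_set,
                                       catalog = catalog))))
  new_gene_catalog(bind_rows(as_tibble(catalog),
                             tibble(label = new_label, gene = members)))
}
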