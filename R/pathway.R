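#' Validate a pathway annotation table
#'
#' Three columns: `pathway_id`, `pathway_name`, `gene_symbol`; gene symbols
#' uppercased, duplicate (pathway_id, gene_symbol) pairs collapsed. Accepts a
#' data frame, a 3-column TSV path, or a GMT path (set labels become both id
#' and name).
#'
#' @param x Data frame or file path.
#' @return A tibble of class `pathway_table`.
#' @export
as_pathway_annotations <- function(x) {
  if (is.character(x) && length(x) == 1) {
    if (grepl("\\.gmt$", x, ignore.case = TRUE)) {
      catalog <- read_gene_lists(x, quiet = TRUE)
      x <- as_tibble(catalog) |>
        transmute(pathway_id = .data$label, pathway_name = .data$label,
                  gene_symbol = .data$gene)
    } else {
      x <- readr::read_tsv(x, col_types = "ccc", progress = FALSE)
    }
  }
  x <- as_tibble(x)
  need <- c("pathway_id", "pathway_name", "gene_symbol")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Pathway table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) abort("Pathway table has no records")
  x <- x |>
    mutate(across(all_of(need), as.character),
           gene_symbol = toupper(.data$gene_symbol)) |>
    distinct(.data$pathway_id, .data$gene_symbol, .keep_all = TRUE) |>
    select(all_of(need))
  if (any(x$gene_symbol == "" | is.na(x$gene_symbol))) {
    abort("gene_symbol must be non-empty for every pathway record")
  }
  class(x) <- c("pathway_table", class(x))
  x
}

pathway_as_assoc <- function(annotations) {
  as_association_table(
    tibble(chemical_id = annotations$pathway_id,
           chemical_name = annotations$pathway_name,
           gene_symbol = annotations$gene_symbol,
           source = "OTHER", evidence = "curated"),
    quiet = TRUE)
}

#' Pathway over-representation analysis
#'
#' Identical statistic and BH machinery as [enrich()], applied with pathways
#' in place of chemicals (the pathway table is mapped onto the association
#' schema and run through the same code path). Selection supports both a
#' q-value cutoff and a top-K rule.
#'
#' @param annotations A `pathway_table` (or something
#'   [as_pathway_annotations()] accepts).
#' @param query Character vector of query gene symbols.
#' @param alpha FDR cutoff (default 0.05).
#' @param top_k Keep the K best pathways by q-value among all tested sets
#'   (default `NULL` = retain by the q cutoff instead; published
#'   gene-pathway networks typically use K = 6, making the printed
#'   significance threshold the observed K-th q-value rather than a
#'   constant).
#' @param ... Passed to [enrich()].
#' @return An `ora` object whose results carry `pathway_id`/`pathway_name`
#'   columns.
#' @export
pathway_enrich <- function(annotations, query, alpha = 0.05, top_k = NULL,
                           ...) {
  annotations <- as_pathway_annotations(annotations)
  args <- list(...)
  if (!is.null(top_k)) args$keep_all <- TRUE
  res <- do.call(enrich, c(list(pathway_as_assoc(annotations), query,
                                alpha = alpha), args))
  if (!is.null(top_k)) {
    res$results <- head(arrange(res$results, .data$rank), top_k) |>
      mutate(filtered_position = row_number())
  }
  res$results <- rename(res$results, pathway_id = "chemical_id",
                        pathway_name = "chemical_name")
  res
}

#' Build a gene-pathway bipartite network
#'
#' Edges connect each selected pathway to the query genes annotated to it;
#' centrality metrics come from the same machinery as the drug-gene networks
#' (nodes are typically coloured by closeness).
#'
#' @param annotations A `pathway_table`.
#' @param query Character vector of query gene symbols.
#' @param selected_pathways Character vector of pathway ids (e.g. the top-K
#'   from [pathway_enrich()]).
#' @param subtype Label carried by the network.
#' @return A `dg_network` whose "drug" side holds pathways.
#' @export
build_gene_pathway_network <- function(annotations, query, selected_pathways,
                                       subtype = "gene_pathway") {
  annotations <- as_pathway_annotations(annotations)
  if (length(selected_pathways) == 0) {
    abort("No pathways selected")
  }
  build_network(pathway_as_assoc(annotations), drugs = selected_pathways,
                genes = query, subtype = subtype)
}
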