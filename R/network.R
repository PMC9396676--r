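new_dg_network <- function(drugs, genes, edges, subtype = "") {
  structure(list(drugs = drugs, genes = genes, edges = edges,
                 subtype = subtype),
            class = "dg_network")
}

#' Build a bipartite drug-gene network
#'
#' Edges connect a selected chemical to each of its annotated genes that lies
#' in the given gene set (sources pooled per chemical). By default only nodes
#' incident to at least one edge are kept; listed drugs or genes with no
#' interactions can be retained with `keep_isolated = TRUE`.
#'
#' @param associations An `assoc_table`.
#' @param drugs Character vector of selected chemical ids.
#' @param genes Character vector of gene symbols (e.g. a subtype's curated
#'   set).
#' @param subtype Label carried by the network (default "").
#' @param sources Optional source filter, e.g. `"CTD"`; default uses every
#'   source in the table.
#' @param keep_isolated Keep listed drugs/genes without any edge.
#' @return A `dg_network`: tibbles `drugs` (`chemical_id`, `chemical_name`),
#'   `genes` (`gene_symbol`) and `edges` (`chemical_id`, `gene_symbol`,
#'   `source`), plus the subtype label.
#' @export
build_network <- function(associations, drugs, genes, subtype = "",
                          sources = NULL, keep_isolated = FALSE) {
  stopifnot(inherits(associations, "assoc_table"))
  if (length(drugs) == 0 || length(genes) == 0) {
    abort("Both drugs and genes must be non-empty")
  }
  genes <- unique(toupper(genes))
  drugs <- unique(as.character(drugs))
  x <- as_tibble(associations)
  if (!is.null(sources)) x <- filter(x, .data$source %in% sources)
  edges <- x |>
    filter(.data$chemical_id %in% drugs, .data$gene_symbol %in% genes) |>
    group_by(.data$chemical_id, .data$gene_symbol) |>
    summarise(source = paste(sort(unique(.data$source)), collapse = ","),
              .groups = "drop") |>
    arrange(.data$chemical_id, .data$gene_symbol)
  names_tbl <- x |>
    filter(.data$chemical_id %in% drugs) |>
    distinct(.data$chemical_id, .keep_all = TRUE) |>
    select("chemical_id", "chemical_name")
  if (nrow(edges) == 0) {
    warn("Drug-gene network has no edges")
  }
  if (keep_isolated) {
    drug_ids <- drugs
    gene_ids <- genes
  } else {
    drug_ids <- unique(edges$chemical_id)
    gene_ids <- unique(edges$gene_symbol)
  }
  drugs_tbl <- tibble(chemical_id = sort(drug_ids)) |>
    left_join(names_tbl, by = "chemical_id") |>
    mutate(chemical_name = coalesce(.data$chemical_name, .data$chemical_id))
  new_dg_network(drugs_tbl, tibble(gene_symbol = sort(gene_ids)), edges,
                 subtype)
}

#' @export
print.dg_network <- function(x, ...) {
  s <- network_stats(x)
  cat(sprintf(
    "Bipartite drug-gene network%s: %d drugs, %d genes, %d edges (density %.3g)\n",
    if (nzchar(x$subtype)) paste0(" [", x$subtype, "]") else "",
    s$n_drugs, s$n_genes, s$n_edges, s$density))
  invisible(x)
}

#' Network summary statistics
#'
#' One row per network: drug/gene/edge counts, bipartite density
#' `E / (D * G)` and mean drug degree `E / D` (also as a percentage of the
#' gene count).
#'
#' @param net A `dg_network`.
#' @return A one-row tibble.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "dg_network"))
  D <- nrow(net$drugs); G <- nrow(net$genes); E <- nrow(net$edges)
  tibble(
    subtype = net$subtype,
    n_drugs = D, n_genes = G, n_edges = E,
    density = if (D > 0 && G > 0) E / (D * G) else NA_real_,
    mean_drug_degree = if (D > 0) E / D else NA_real_,
    mean_drug_degree_pct = if (D > 0 && G > 0) 100 * E / D / G else NA_real_)
}

#' Bipartite network density
#'
#' Realized edges over the maximum possible drug-gene edges:
#' `E / (D * G)`.
#'
#' @param net A `dg_network`.
#' @return Density in `[0, 1]`.
#' @export
bipartite_density <- function(net) {
  stopifnot(inherits(net, "dg_network"))
  if (nrow(net$drugs) == 0 || nrow(net$genes) == 0) {
    abort("Density is undefined: one side of the network is empty")
  }
  nrow(net$edges) / (nrow(net$drugs) * nrow(net$genes))
}

#' Average drug degree
#'
#' Mean number of gene connections per drug, `E / D`.
#'
#' @param net A `dg_network`.
#' @return Genes per drug.
#' @export
average_drug_degree <- function(net) {
  stopifnot(inherits(net, "dg_network"))
  if (nrow(net$drugs) == 0) abort("No drugs in the network")
  nrow(net$edges) / nrow(net$drugs)
}

#' Drop genes with few drug connections
#'
#' Removes gene nodes whose degree is below `min_degree` together with their
#' incident edges (the published networks hide genes with fewer than three
#' drug interactions). Applied in a single pass; since removing a gene cannot
#' lower another gene's degree, one pass is idempotent. Drugs left isolated
#' are retained by default.
#'
#' @param net A `dg_network`.
#' @param min_degree Minimum drug connections a gene must have (default 3).
#' @param prune_isolated_drugs Also drop drugs left without edges.
#' @return The filtered `dg_network`.
#' @export
filter_low_degree_genes <- function(net, min_degree = 3,
                                    prune_isolated_drugs = FALSE) {
  stopifnot(inherits(net, "dg_network"), min_degree >= 0)
  deg <- table(factor(net$edges$gene_symbol, levels = net$genes$gene_symbol))
  keep <- names(deg)[deg >= min_degree]
  net$genes <- filter(net$genes, .data$gene_symbol %in% keep)
  net$edges <- filter(net$edges, .data$gene_symbol %in% keep)
  if (prune_isolated_drugs) {
    net$drugs <- filter(net$drugs,
                        .data$chemical_id %in% net$edges$chemical_id)
  }
  net
}

as_igraph <- function(net) {
  ids <- c(net$drugs$chemical_id, net$genes$gene_symbol)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  g <- igraph::set_vertex_attr(
    g, "type", value = c(rep("drug", nrow(net$drugs)),
                         rep("gene", nrow(net$genes))))
  if (nrow(net$edges) > 0) {
    g <- igraph::add_edges(
      g, rbind(match(net$edges$chemical_id, ids),
               match(net$edges$gene_symbol, ids)))
    g <- igraph::set_edge_attr(g, "source", value = net$edges$source)
  }
  g
}

#' Node and edge centrality of a drug-gene network
#'
#' Degree, per-component closeness and edge betweenness with unit edge
#' weights. Closeness of node v is `(|C| - 1) / sum of shortest-path
#' distances` within v's connected component C (0 for isolated nodes); edge
#' betweenness counts all-pairs shortest paths with fractional weighting of
#' ties.
#'
#' @param net A `dg_network`.
#' @return A list of class `centrality_report`: `nodes` tibble (`id`, `type`,
#'   `degree`, `closeness`) and `edges` tibble (`chemical_id`, `gene_symbol`,
#'   `betweenness`).
#' @export
centrality <- function(net) {
  stopifnot(inherits(net, "dg_network"))
  if (nrow(net$drugs) + nrow(net$genes) == 0) {
    abort("Network has no nodes")
  }
  g <- as_igraph(net)
  d <- igraph::distances(g)
  clos <- apply(d, 1, function(row) {
    reach <- row[is.finite(row)]
    reach <- reach[reach > 0]
    if (length(reach) == 0) 0 else length(reach) / sum(reach)
  })
  nodes <- tibble(
    id = igraph::V(g)$name,
    type = igraph::V(g)$type,
    degree = as.integer(igraph::degree(g)),
    closeness = as.numeric(clos))
  edges <- net$edges
  if (nrow(edges) > 0) {
    edges$betweenness <- as.numeric(igraph::edge_betweenness(g, directed = FALSE))
  } else {
    edges$betweenness <- numeric(0)
  }
  structure(list(nodes = nodes,
                 edges = edges[, c("chemical_id", "gene_symbol", "betweenness")]),
            class = "centrality_report")
}

#' Stratify a network by subtype gene sets and drug selections
#'
#' For each label, takes the induced subnetwork on that subtype's genes and
#' (optionally) its selected drugs; emits the per-stratum summary statistics
#' alongside.
#'
#' @param net A `dg_network`.
#' @param catalog A `gene_catalog` of subtype gene sets.
#' @param drugs_by_label Optional named list mapping labels to chemical-id
#'   vectors; labels not named keep all drugs of `net`.
#' @param labels Labels to stratify by (default: all catalog labels).
#' @return A list with `networks` (named list of `dg_network`) and `stats`
#'   (tibble of per-stratum [network_stats()] rows).
#' @export
stratify <- function(net, catalog, drugs_by_label = NULL, labels = NULL) {
  stopifnot(inherits(net, "dg_network"), inherits(catalog, "gene_catalog"))
  labels <- labels %||% catalog_labels(catalog)
  missing_lab <- setdiff(labels, catalog_labels(catalog))
  if (length(missing_lab) > 0) {
    abort(paste0("Unknown label(s): ", paste(missing_lab, collapse = ", ")))
  }
  nets <- lapply(labels, function(lab) {
    genes <- gene_set(catalog, lab)
    drugs <- drugs_by_label[[lab]] %||% net$drugs$chemical_id
    edges <- net$edges |>
      filter(.data$chemical_id %in% drugs, .data$gene_symbol %in% genes)
    new_dg_network(
      drugs = filter(net$drugs, .data$chemical_id %in% edges$chemical_id),
      genes = filter(net$genes, .data$gene_symbol %in% edges$gene_symbol),
      edges = edges, subtype = lab)
  })
  names(nets) <- labels
  list(networks = nets, stats = bind_rows(lapply(nets, network_stats)))
}

#' Write per-stratum network statistics as TSV
#'
#' Columns mirror the published network-property table: Condition, Drugs,
#' Genes, Interactions, Density.
#'
#' @param stats A tibble of [network_stats()] rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_stats <- function(stats, path) {
  out <- tibble(Condition = stats$subtype, Drugs = stats$n_drugs,
                Genes = stats$n_genes, Interactions = stats$n_edges,
                Density = stats$density)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Nodes carry bipartite side, display name, degree, closeness and the
#' subtype label; edges carry source attribution and betweenness, so viewers
#' can size and shade nodes without recomputing metrics.
#'
#' @param net A `dg_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "dg_network"))
  g <- as_igraph(net)
  cent <- centrality(net)
  g <- igraph::set_vertex_attr(g, "degree", value = cent$nodes$degree)
  g <- igraph::set_vertex_attr(g, "closeness", value = cent$nodes$closeness)
  g <- igraph::set_vertex_attr(g, "subtype", value = net$subtype)
  g <- igraph::set_vertex_attr(
    g, "display_name",
    value = c(net$drugs$chemical_name, net$genes$gene_symbol))
  if (nrow(net$edges) > 0) {
    g <- igraph::set_edge_attr(g, "betweenness", value = cent$edges$betweenness)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML export back into a network
#'
#' @param path Path written by [write_graphml()].
#' @return A `dg_network`.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  g <- igraph::read_graph(path, format = "graphml")
  type <- igraph::vertex_attr(g, "type")
  name <- igraph::vertex_attr(g, "name")
  display <- igraph::vertex_attr(g, "display_name") %||% name
  subtype <- igraph::vertex_attr(g, "subtype")
  ends <- igraph::as_edgelist(g)
  is_drug_end <- matrix(type[match(ends, name)], ncol = 2)
  chem <- ifelse(is_drug_end[, 1] == "drug", ends[, 1], ends[, 2])
  gene <- ifelse(is_drug_end[, 1] == "drug", ends[, 2], ends[, 1])
  edges <- tibble(chemical_id = chem, gene_symbol = gene,
                  source = igraph::edge_attr(g, "source") %||%
                    rep("OTHER", nrow(ends))) |>
    arrange(.data$chemical_id, .data$gene_symbol)
  new_dg_network(
    drugs = tibble(chemical_id = name[type == "drug"],
                   chemical_name = display[type == "drug"]) |>
      arrange(.data$chemical_id),
    genes = tibble(gene_symbol = sort(name[type == "gene"])),
    edges = edges,
    subtype = if (length(subtype)) subtype[[1]] else "")
}

#' Export a network in SIF format
#'
#' One line per edge: `<drug> targets <gene>` (whitespace-separated; spaces
#' in identifiers are replaced by underscores as SIF has no quoting).
#'
#' @param net A `dg_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "dg_network"))
  safe <- function(s) gsub("[[:space:]]+", "_", s)
  writeLines(paste(safe(net$edges$chemical_id), "targets",
                   safe(net$edges$gene_symbol)), path)
  invisible(path)
}

#' Export / import a TSV edge list
#'
#' Columns: `chemical_id`, `gene_symbol`, `source`.
#'
#' @param net A `dg_network`.
#' @param path File path.
#' @return `path` (writer, invisibly) or a `dg_network` (reader).
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "dg_network"))
  readr::write_tsv(net$edges[, c("chemical_id", "gene_symbol", "source")],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  edges <- readr::read_tsv(path, col_types = "ccc", progress = FALSE) |>
    arrange(.data$chemical_id, .data$gene_symbol)
  new_dg_network(
    drugs = tibble(chemical_id = sort(unique(edges$chemical_id))) |>
      mutate(chemical_name = .data$chemical_id),
    genes = tibble(gene_symbol = sort(unique(edges$gene_symbol))),
    edges = edges)
}

#' Tidy network nodes with centrality metrics
#'
#' @param x A `dg_network`.
#' @param ... Unused.
#' @return Node tibble with `id`, `type`, `degree`, `closeness`.
#' @exportS3Method generics::tidy
tidy.dg_network <- function(x, ...) {
  centrality(x)$nodes
}

#' One-row network summary
#'
#' @param x A `dg_network`.
#' @param ... Unused.
#' @return The [network_stats()] row.
#' @exportS3Method generics::glance
glance.dg_network <- function(x, ...) {
  network_stats(x)
}

#' Plot a drug-gene network
#'
#' Bipartite ggplot rendering with node size mapped to closeness centrality;
#' a convenience view, not a layout reproduction.
#'
#' @param object A `dg_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dg_network <- function(object, ...) {
  g <- as_igraph(object)
  xy <- igraph::layout_with_fr(g)
  cent <- centrality(object)
  nodes <- cent$nodes |>
    mutate(x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    left_join(select(nodes, id, xe = "x", ye = "y"),
              by = c(chemical_id = "id")) |>
    left_join(select(nodes, id, xg = "x", yg = "y"),
              by = c(gene_symbol = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xe, y = .data$ye, xend = .data$xg,
                   yend = .data$yg),
      colour = "grey80", linewidth = 0.3) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$type,
                   size = .data$closeness)) +
    ggplot2::scale_colour_manual(values = c(drug = "#d95f8a",
                                            gene = "#3bb3c3")) +
    ggplot2::labs(title = if (nzchar(object$subtype)) object$subtype else
      "Drug-gene network", colour = NULL, size = "Closeness") +
    ggplot2::theme_void()
}
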