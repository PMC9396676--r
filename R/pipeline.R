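#' Pipeline configuration
#'
#' Collects every setting of the end-to-end analysis in one declarative
#' object; `pipeline_config()` builds it from arguments,
#' [read_pipeline_config()] from a YAML file of the same field names.
#'
#' @param associations Path to the chemical-gene association TSV.
#' @param gene_lists Character vector of gene-list/GMT paths.
#' @param gene_list_labels Optional labels for plain-list files.
#' @param out_dir Output directory.
#' @param blocklist Path to a blocklist file, or `NULL` for the packaged
#'   default.
#' @param pathway_table Optional pathway annotation TSV/GMT path.
#' @param exclusions Gene symbols removed from every list (default
#'   [amd_exclusions()]).
#' @param combinations Named list; each element unions the named labels into
#'   a new set, e.g. `list(int_dry = c("intermediate", "dry"))`.
#' @param primary_label Label whose gene set drives the pathway stage
#'   (default: first loaded label).
#' @param alpha FDR threshold (default 0.05).
#' @param min_gene_degree Low-degree gene filter threshold (default 3).
#' @param consolidate_policy `"min_p"` or `"max_p"`.
#' @param universe_file Optional file with one background gene per line;
#'   default uses the association table's own universe.
#' @param top_k_pathways Pathways kept for the gene-pathway network
#'   (default 6).
#' @param seed Integer seed recorded in the manifest and set before the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(associations, gene_lists, out_dir,
                            gene_list_labels = NULL, blocklist = NULL,
                            pathway_table = NULL,
                            exclusions = amd_exclusions(),
                            combinations = list(), primary_label = NULL,
                            alpha = 0.05, min_gene_degree = 3,
                            consolidate_policy = "min_p",
                            universe_file = NULL, top_k_pathways = 6,
                            seed = 1) {
  if (!(alpha > 0 && alpha < 1)) abort("alpha must lie in (0, 1)")
  cfg <- list(associations = associations, gene_lists = gene_lists,
              gene_list_labels = gene_list_labels, out_dir = out_dir,
              blocklist = blocklist, pathway_table = pathway_table,
              exclusions = exclusions, combinations = combinations,
              primary_label = primary_label, alpha = alpha,
              min_gene_degree = min_gene_degree,
              consolidate_policy = consolidate_policy,
              universe_file = universe_file,
              top_k_pathways = top_k_pathways, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path Path to a YAML config file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Composes the stages end-to-end: load associations and gene lists, apply
#' the manual gene exclusions, build the combined subtype sets, run
#' per-subtype compound enrichment with blocklist filtering and cross-source
#' consolidation, reconstruct the filtered drug-gene network, stratify it by
#' subtype, optionally run the pathway stage, and export results plus a run
#' manifest. Rerunning with identical inputs and seed reproduces
#' byte-identical result tables.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return The run manifest (a list), invisibly written to
#'   `out_dir/manifest.yaml`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) inform(sprintf(...))
  counts <- list()

  assoc <- stage("load_associations",
                 read_associations(config$associations, quiet = TRUE))
  counts$association_records <- nrow(assoc)

  catalog <- stage("load_gene_lists",
                   read_gene_lists(config$gene_lists,
                                   labels = config$gene_list_labels,
                                   quiet = TRUE))
  counts$genes_loaded <- nrow(catalog)
  catalog <- stage("exclude_genes",
                   exclude_genes(catalog, config$exclusions, quiet = TRUE))
  counts$genes_after_exclusion <- nrow(catalog)
  say("Loaded %d association records; %d gene-set rows after exclusions",
      counts$association_records, counts$genes_after_exclusion)

  for (new_label in names(config$combinations)) {
    catalog <- stage("combine_subtypes",
                     combine_subtypes(catalog,
                                      config$combinations[[new_label]],
                                      new_label))
  }
  labels <- catalog_labels(catalog)
  primary <- config$primary_label %||% labels[[1]]
  universe <- if (!is.null(config$universe_file)) {
    toupper(trimws(readLines(config$universe_file, warn = FALSE)))
  } else {
    NULL
  }
  blocklist <- if (is.null(config$blocklist)) default_blocklist() else
    read_blocklist(config$blocklist)

  outputs <- character()
  selected <- list()
  enrich_counts <- list()
  for (lab in labels) {
    res <- stage(paste0("enrich[", lab, "]"),
                 enrich(assoc, catalog, label = lab, alpha = config$alpha,
                        universe = universe, quiet = TRUE))
    res <- apply_blocklist(res, blocklist, quiet = TRUE)
    res <- consolidate_duplicates(res, policy = config$consolidate_policy)
    path <- file.path(config$out_dir, paste0("enrichment_", lab, ".tsv"))
    write_enrichment(res, path)
    outputs <- c(outputs, path)
    selected[[lab]] <- res$results$chemical_id
    enrich_counts[[lab]] <- nrow(res$results)
    say("Subtype '%s': %d compound(s) retained", lab, nrow(res$results))
  }
  counts$selected_per_label <- enrich_counts

  all_genes <- unique(catalog$gene)
  all_drugs <- unique(unlist(selected))
  counts$network_drugs_selected <- length(all_drugs)
  net <- stage("build_network",
               build_network(assoc, all_drugs, all_genes, subtype = "all"))
  net <- stage("filter_network",
               filter_low_degree_genes(net, config$min_gene_degree))
  strat <- stage("stratify",
                 stratify(net, catalog, drugs_by_label = selected))
  stats <- bind_rows(network_stats(net), strat$stats)
  stats_path <- file.path(config$out_dir, "network_stats.tsv")
  write_network_stats(stats, stats_path)
  graphml_path <- file.path(config$out_dir, "network_all.graphml")
  sif_path <- file.path(config$out_dir, "network_all.sif")
  edges_path <- file.path(config$out_dir, "network_all_edges.tsv")
  write_graphml(net, graphml_path)
  write_sif(net, sif_path)
  write_edge_list(net, edges_path)
  outputs <- c(outputs, stats_path, graphml_path, sif_path, edges_path)
  counts$network_edges <- nrow(net$edges)
  say("Full network: %d drugs, %d genes, %d edges after degree-%d filter",
      nrow(net$drugs), nrow(net$genes), nrow(net$edges),
      config$min_gene_degree)

  if (!is.null(config$pathway_table)) {
    pres <- stage("pathway_enrich",
                  pathway_enrich(config$pathway_table,
                                 gene_set(catalog, primary),
                                 alpha = config$alpha,
                                 top_k = config$top_k_pathways,
                                 quiet = TRUE))
    ppath <- file.path(config$out_dir, "pathways.tsv")
    readr::write_tsv(pres$results, ppath, progress = FALSE)
    pnet <- stage("pathway_network",
                  build_gene_pathway_network(config$pathway_table,
                                             gene_set(catalog, primary),
                                             pres$results$pathway_id))
    pnet_path <- file.path(config$out_dir, "pathway_network.graphml")
    write_graphml(pnet, pnet_path)
    outputs <- c(outputs, ppath, pnet_path)
    counts$pathways_selected <- nrow(pres$results)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("oranet")),
    seed = config$seed,
    parameters = list(alpha = config$alpha,
                      min_gene_degree = config$min_gene_degree,
                      consolidate_policy = config$consolidate_policy,
                      top_k_pathways = config$top_k_pathways,
                      exclusions = config$exclusions,
                      primary_label = primary),
    inputs = list(associations = config$associations,
                  gene_lists = config$gene_lists,
                  pathway_table = config$pathway_table),
    counts = counts,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) list(path = f,
                                      md5 = unname(tools::md5sum(f)))))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Summarise a pipeline run from its manifest
#'
#' @param manifest A manifest list returned by [run_pipeline()], or the path
#'   to a `manifest.yaml`.
#' @return A tibble with one row per recorded output file (name, md5) plus
#'   the run's stage counts as a printed summary.
#' @export
pipeline_report <- function(manifest) {
  if (is.character(manifest)) manifest <- yaml::read_yaml(manifest)
  tibble(
    file = names(manifest$outputs),
    md5 = unname(vapply(manifest$outputs, function(o) o$md5, character(1))),
    seed = manifest$seed,
    alpha = manifest$parameters$alpha)
}
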