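#' Simulation configuration
#'
#' Describes a synthetic chemical-gene association database with optional
#' planted enriched compounds. Null compounds draw their annotation set
#' uniformly at random from the gene universe; planted compounds draw the
#' same way and then swap in query genes until their expected query overlap
#' equals `planting_strength` times the null expectation `n * M / N`
#' (capped at `min(M, n)`). Annotation-set sizes `M` follow a log-uniform
#' law between `annotation_size_range` bounds.
#'
#' @param universe_size Number of genes in the universe (default 2000).
#' @param n_compounds Number of compounds (default 200).
#' @param annotation_size_range Bounds of the log-uniform per-compound set
#'   size (default c(100, 1000)).
#' @param query_size Size of the query gene set (default 100).
#' @param n_planted Number of planted (truly enriched) compounds
#'   (default 20).
#' @param planting_strength Multiplier (>= 1) on the null expected overlap
#'   (default 3; 1 makes planted compounds exchangeable with null ones).
#' @param n_subtypes Number of subtype gene sets in the catalog (default 5);
#'   the first set, labelled `S1`, is the query.
#' @param subtype_overlap Fraction of each further subtype set shared with
#'   the query set (default 0.2).
#' @param seed Integer seed; replicate runs derive their streams as
#'   `seed + replicate`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(universe_size = 2000, n_compounds = 200,
                       annotation_size_range = c(100, 1000),
                       query_size = 100, n_planted = 20,
                       planting_strength = 3, n_subtypes = 5,
                       subtype_overlap = 0.2, seed = 1) {
  cfg <- list(universe_size = as.integer(universe_size),
              n_compounds = as.integer(n_compounds),
              annotation_size_range = as.integer(annotation_size_range),
              query_size = as.integer(query_size),
              n_planted = as.integer(n_planted),
              planting_strength = planting_strength,
              n_subtypes = as.integer(n_subtypes),
              subtype_overlap = subtype_overlap,
              seed = as.integer(seed))
  with(cfg, {
    if (n_planted > n_compounds) abort("n_planted must be <= n_compounds")
    if (query_size > universe_size) {
      abort("query_size must be <= universe_size")
    }
    if (planting_strength < 1) abort("planting_strength must be >= 1")
    if (length(annotation_size_range) != 2 ||
        annotation_size_range[1] < 1 ||
        annotation_size_range[1] > annotation_size_range[2] ||
        annotation_size_range[2] > universe_size) {
      abort("annotation_size_range must satisfy 1 <= lo <= hi <= universe_size")
    }
    if (subtype_overlap < 0 || subtype_overlap > 1) {
      abort("subtype_overlap must lie in [0, 1]")
    }
    # expected planted overlap s*n*M/N must fit min(M, n) for some feasible M;
    # the ratio is minimised at the lower size bound
    m_lo <- annotation_size_range[1]
    t_lo <- planting_strength * query_size * m_lo / universe_size
    if (t_lo > min(m_lo, query_size)) {
      abort("Infeasible config: expected planted overlap exceeds min(M, n) for every annotation size")
    }
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic dataset
#'
#' Deterministic for a given config (the seed is part of the config). Every
#' universe gene is guaranteed to appear in at least one annotation record
#' (uncovered genes are appended to randomly chosen compounds), so the
#' table's annotated-gene universe equals the configured universe and the
#' effective query size equals `query_size`. Gene symbols are generated as
#' `G000001`... and compound ids as `C0001`... to avoid collision with real
#' symbols.
#'
#' @param config A [sim_config()].
#' @return A list of class `ora_sim`: `associations` (an `assoc_table`),
#'   `catalog` (a `gene_catalog`, query set labelled `S1`), `truth` (tibble
#'   `chemical_id`, `planted`), and the `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  N <- config$universe_size
  n <- config$query_size
  genes <- sprintf("G%06d", seq_len(N))
  compounds <- sprintf("C%04d", seq_len(config$n_compounds))

  query <- sort(sample(genes, n))
  sets <- list(S1 = query)
  n_shared <- round(config$subtype_overlap * n)
  if (config$n_subtypes > 1) {
    for (i in 2:config$n_subtypes) {
      shared <- sample(query, n_shared)
      rest <- sample(setdiff(genes, query), n - n_shared)
      sets[[paste0("S", i)]] <- sort(c(shared, rest))
    }
  }
  catalog <- gene_catalog(sets)

  lo <- config$annotation_size_range[1]
  hi <- config$annotation_size_range[2]
  M <- round(exp(stats::runif(config$n_compounds, log(lo), log(hi))))
  M <- pmin(pmax(M, 1L), N)
  planted <- rep(FALSE, config$n_compounds)
  if (config$n_planted > 0) {
    planted[sample.int(config$n_compounds, config$n_planted)] <- TRUE
  }

  ann <- vector("list", config$n_compounds)
  for (i in seq_len(config$n_compounds)) {
    s <- sample(genes, M[i])
    if (planted[i] && config$planting_strength > 1) {
      t_extra <- (config$planting_strength - 1) * n * M[i] / N
      extra <- floor(t_extra) +
        stats::rbinom(1, 1, t_extra - floor(t_extra))
      cap <- min(M[i], n) - sum(s %in% query)  # room up to full overlap
      extra <- min(extra, cap, sum(!(s %in% query)))
      if (extra > 0) {
        out_genes <- sample(s[!(s %in% query)], extra)
        in_genes <- sample(setdiff(query, s), extra)
        s <- c(setdiff(s, out_genes), in_genes)
      }
    }
    ann[[i]] <- s
  }
  # coverage guarantee: every universe gene annotated at least once
  uncovered <- setdiff(genes, unique(unlist(ann)))
  if (length(uncovered) > 0) {
    host <- sample.int(config$n_compounds, length(uncovered), replace = TRUE)
    for (j in seq_along(uncovered)) {
      ann[[host[j]]] <- c(ann[[host[j]]], uncovered[j])
    }
  }

  src <- sample(c("CTD", "STITCH", "DRUGBANK", "CMAP_UP", "CMAP_DOWN"),
                config$n_compounds, replace = TRUE,
                prob = c(0.45, 0.30, 0.10, 0.075, 0.075))
  lens <- lengths(ann)
  tbl <- tibble(
    chemical_id = rep(compounds, lens),
    chemical_name = rep(paste0("cmpd-", tolower(compounds)), lens),
    gene_symbol = unlist(ann),
    source = rep(src, lens),
    evidence = sample(c("curated", "inferred"), sum(lens),
                      replace = TRUE, prob = c(0.6, 0.4)))
  structure(
    list(associations = as_association_table(tbl, quiet = TRUE),
         catalog = catalog,
         truth = tibble(chemical_id = compounds, planted = planted),
         config = config),
    class = "ora_sim")
}

#' Write a synthetic dataset to disk
#'
#' Emits the same formats the loaders read: `associations.tsv`,
#' `catalog.gmt`, and a `truth.tsv` sidecar with the planted flags.
#'
#' @param sim An `ora_sim`.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "ora_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_associations(sim$associations, file.path(dir, "associations.tsv"))
  write_gmt(sim$catalog, file.path(dir, "catalog.gmt"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}

#' Type-I-error calibration of the enrichment statistic under the null
#'
#' Generates replicate datasets with no planted compounds, runs the full
#' enrichment on each, and reports the fraction of compound tests with
#' `p <= t` for each threshold, together with the fraction of replicates
#' reporting any BH-significant compound. The hypergeometric test is
#' discrete, so both fractions are expected to sit at or below their nominal
#' levels.
#'
#' @param config A [sim_config()]; `n_planted` is forced to 0.
#' @param reps Number of Monte-Carlo replicates (>= 100 recommended).
#' @param thresholds P-value thresholds to tabulate (default 0.01/0.05/0.1).
#' @param alpha FDR level for the any-discovery fraction (default 0.05).
#' @return A list: `thresholds` tibble (`threshold`, `fraction`, `se`),
#'   `any_q_fraction`, `any_q_se`, `n_tests`, `reps`.
#' @export
null_pvalue_calibration <- function(config = sim_config(n_planted = 0),
                                    reps = 100,
                                    thresholds = c(0.01, 0.05, 0.1),
                                    alpha = 0.05) {
  stopifnot(inherits(config, "sim_config"), reps >= 1)
  config$n_planted <- 0L
  p_all <- vector("list", reps)
  any_q <- logical(reps)
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- simulate_dataset(cfg)
    res <- enrich(sim$associations, gene_set(sim$catalog, "S1"),
                  alpha = alpha, keep_all = TRUE, quiet = TRUE)
    p_all[[r]] <- res$results$p_value
    any_q[r] <- any(res$results$q_value < alpha)
  }
  p <- unlist(p_all)
  tab <- tibble(
    threshold = thresholds,
    fraction = vapply(thresholds, function(t) mean(p <= t), numeric(1)),
    se = vapply(thresholds, function(t) sqrt(t * (1 - t) / length(p)),
                numeric(1)))
  list(thresholds = tab,
       any_q_fraction = mean(any_q),
       any_q_se = sqrt(alpha * (1 - alpha) / reps),
       n_tests = length(p), reps = reps)
}

#' Planted-compound recovery and false discovery under planting
#'
#' Generates replicate datasets with planted compounds, runs enrichment, and
#' reports per-replicate recovery (fraction of planted compounds detected at
#' `q < alpha`) and the false discovery proportion among detections.
#'
#' @param config A [sim_config()] with `n_planted > 0`.
#' @param reps Number of replicates.
#' @param alpha FDR level (default 0.05).
#' @return A tibble with one row per replicate: `replicate`, `n_detected`,
#'   `recovery`, `fdp`.
#' @export
planted_recovery <- function(config = sim_config(), reps = 10,
                             alpha = 0.05) {
  stopifnot(inherits(config, "sim_config"), config$n_planted > 0)
  purrr::map_dfr(seq_len(reps), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- simulate_dataset(cfg)
    res <- enrich(sim$associations, gene_set(sim$catalog, "S1"),
                  alpha = alpha, quiet = TRUE)
    detected <- unique(res$results$chemical_id)
    planted_ids <- sim$truth$chemical_id[sim$truth$planted]
    tibble(replicate = r,
           n_detected = length(detected),
           recovery = mean(planted_ids %in% detected),
           fdp = if (length(detected) == 0) 0 else
             mean(!(detected %in% planted_ids)))
  })
}
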