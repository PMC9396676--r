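#' Hypergeometric upper-tail probability in log space
#'
#' The over-representation p-value: `P(X >= k)` for `X` counting annotated
#' genes in a draw of `n` genes from a universe of `N` genes of which `M`
#' are annotated,
#' \deqn{P = 1 - \sum_{i=0}^{k-1} \binom{M}{i}\binom{N-M}{n-i} / \binom{N}{n}.}
#' The upper tail is summed directly in log space (log-gamma terms combined
#' by log-sum-exp), so p-values far below double-precision underflow of the
#' naive complement (down to ~1e-300) come out as finite positive numbers;
#' the result is clamped to `[0, 1]`.
#'
#' @param k Number of query genes annotated to the compound (vectorised).
#' @param M Number of background genes annotated to the compound (vectorised).
#' @param n Query-list size.
#' @param N Background universe size.
#' @return Numeric vector of upper-tail probabilities.
#' @export
hyper_tail_p <- function(k, M, n, N) {
  stopifnot(length(n) == 1, length(N) == 1)
  if (N < 0 || n < 0 || n > N) abort("Require 0 <= n <= N")
  if (any(M < 0) || any(M > N)) abort("Require 0 <= M <= N")
  if (any(k < 0) || any(k > pmin(M, n))) {
    abort("Require 0 <= k <= min(M, n)")
  }
  mapply(function(ki, Mi) {
    if (ki == 0) return(1)
    i <- ki:min(Mi, n)
    log_terms <- lchoose(Mi, i) + lchoose(N - Mi, n - i) - lchoose(N, n)
    top <- max(log_terms)
    p <- exp(top + log(sum(exp(log_terms - top))))
    min(max(p, 0), 1)
  }, k, M)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH q-values with enforced monotonicity:
#' `q_(i) = min_{j >= i} p_(j) * m / j`, clamped at 1 and mapped back to the
#' input order, where `m` is the number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) abort("Empty p-value list")
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("All p-values must lie in [0, 1]")
  }
  m <- length(p)
  ord <- order(p)
  # multiply by the ratio m/j so that j = m leaves p exactly unchanged
  q_sorted <- pmin(1, rev(cummin(rev(p[ord] * (m / seq_len(m))))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Compound over-representation analysis
#'
#' Scores every testable annotation set (by default one per chemical/source
#' pair, with CMAP directions pooled; see [chemical_sets()]) against a query
#' gene set with the hypergeometric upper-tail statistic, adjusts across all
#' tested sets by Benjamini-Hochberg, and retains compounds with
#' `q < alpha` ranked by ascending p-value (ties broken by descending hit
#' count, then chemical id, then source).
#'
#' The background universe `N` defaults to every gene annotated in the
#' association table; the effective query size `n` is the query's overlap
#' with that universe (query genes outside it are dropped with a logged
#' count).
#'
#' @param associations An `assoc_table`.
#' @param query Character vector of query gene symbols, or a `gene_catalog`
#'   together with `label`.
#' @param alpha FDR threshold in (0, 1); compounds with `q < alpha` are
#'   retained (default 0.05).
#' @param label When `query` is a catalog, the set label to test; otherwise
#'   an optional display label for the query.
#' @param universe Optional user-supplied background gene universe; default
#'   is the table's own annotated-gene universe.
#' @param min_hits Minimum query overlap for a set to enter testing
#'   (default 1; set 0 to test every annotation set).
#' @param by_source,split_cmap_direction Passed to [chemical_sets()].
#' @param keep_all Keep non-significant rows (flagged by `significant`)
#'   instead of dropping them.
#' @param quiet Suppress progress messages.
#' @return An object of class `ora` wrapping a results tibble (see
#'   [tidy.ora()]) plus the test parameters.
#' @export
enrich <- function(associations, query, alpha = 0.05, label = NULL,
                   universe = NULL, min_hits = 1, by_source = TRUE,
                   split_cmap_direction = FALSE, keep_all = FALSE,
                   quiet = FALSE) {
  stopifnot(inherits(associations, "assoc_table"))
  if (!(alpha > 0 && alpha <= 1)) abort("alpha must lie in (0, 1]")
  if (inherits(query, "gene_catalog")) {
    if (is.null(label)) abort("Supply `label` when `query` is a catalog")
    query <- gene_set(query, label)
  }
  query <- unique(toupper(query))
  if (length(query) == 0) abort("Empty query gene set")
  if (is.null(universe)) {
    universe <- gene_universe(associations)
  } else {
    universe <- sort(unique(toupper(universe)))
  }
  N <- length(universe)
  query_eff <- intersect(query, universe)
  n_dropped <- length(query) - length(query_eff)
  if (length(query_eff) == 0) {
    abort("No testable genes: the query is disjoint from the background universe")
  }
  if (!quiet && n_dropped > 0) {
    inform(sprintf("Dropped %d query gene(s) absent from the universe (n = %d)",
                   n_dropped, length(query_eff)))
  }
  n <- length(query_eff)

  sets <- chemical_sets(associations, by_source = by_source,
                        split_cmap_direction = split_cmap_direction)
  in_query <- logical(N)
  names(in_query) <- universe
  in_query[query_eff] <- TRUE
  res <- sets |>
    mutate(
      hit_count_genome = lengths(.data$genes),
      hit_count_query = vapply(.data$genes,
                               function(g) sum(in_query[g]), integer(1))) |>
    filter(.data$hit_count_query >= min_hits)
  if (nrow(res) == 0) {
    abort("No annotation set overlaps the query at the configured min_hits")
  }
  res <- res |>
    mutate(p_value = hyper_tail_p(.data$hit_count_query,
                                  .data$hit_count_genome, n, N),
           q_value = bh_adjust(.data$p_value)) |>
    arrange(.data$p_value, desc(.data$hit_count_query),
            .data$chemical_id, .data$source) |>
    mutate(rank = row_number(),
           unfiltered_position = .data$rank,
           filtered_position = .data$rank,
           significant = .data$q_value < alpha) |>
    select("chemical_id", "chemical_name", "source", "p_value", "q_value",
           "hit_count_query", "hit_count_genome", "rank",
           "unfiltered_position", "filtered_position", "significant")
  n_tested <- nrow(res)
  if (!keep_all) res <- filter(res, .data$significant)
  if (!quiet) {
    inform(sprintf(
      "Tested %d annotation set(s): %d significant at q < %g (N = %d, n = %d)",
      n_tested, sum(res$significant), alpha, N, n))
  }
  structure(
    list(results = res, N = N, n = n, alpha = alpha,
         n_tested = n_tested, n_dropped_query = n_dropped,
         query = sort(query_eff), label = label %||% "query"),
    class = "ora")
}

#' @export
print.ora <- function(x, ...) {
  cat(sprintf(
    "Over-representation analysis of '%s'\n  universe N = %d, query n = %d, %d set(s) tested, %d retained at q < %g\n",
    x$label, x$N, x$n, x$n_tested, nrow(x$results), x$alpha))
  print(x$results, ...)
  invisible(x)
}

#' Read a compound blocklist
#'
#' One entry per line (`#` comments allowed); entries may be chemical ids or
#' display names and are matched case-insensitively.
#'
#' @param path Path to the blocklist file.
#' @return Character vector of entries.
#' @export
read_blocklist <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines[lines != ""]
}

#' Default compound blocklist
#'
#' Compounds deleterious to health or clinically unusable that the manual
#' curation step removes from enrichment hits (particulate matter, ozone,
#' asbestos, and close variants).
#'
#' @return Character vector of blocklist entries.
#' @export
default_blocklist <- function() {
  read_blocklist(system.file("extdata", "default_blocklist.txt",
                             package = "oranet"))
}

#' Remove blocklisted compounds from enrichment results
#'
#' Drops results whose chemical id or display name matches a blocklist entry
#' (case-insensitive). Surviving rows get consecutive `filtered_position`
#' 1..K while `unfiltered_position` keeps the pre-removal rank, mirroring the
#' filtered/unfiltered positions of published hit tables.
#'
#' @param x An `ora` object.
#' @param blocklist Character vector of chemical ids or names
#'   (default [default_blocklist()]).
#' @param quiet Suppress the removal count message.
#' @return The filtered `ora` object.
#' @export
apply_blocklist <- function(x, blocklist = default_blocklist(),
                            quiet = FALSE) {
  stopifnot(inherits(x, "ora"))
  bl <- tolower(blocklist)
  hit <- tolower(x$results$chemical_id) %in% bl |
    tolower(x$results$chemical_name) %in% bl
  removed <- x$results$chemical_name[hit]
  x$results <- x$results[!hit, , drop = FALSE] |>
    mutate(filtered_position = row_number())
  if (!quiet && length(removed) > 0) {
    inform(sprintf("Blocklist removed %d compound(s): %s", length(removed),
                   paste(removed, collapse = ", ")))
  }
  x$blocklist_removed <- removed
  x
}

#' Consolidate a compound reported by multiple sources
#'
#' When the same chemical id appears under several annotation sources, keeps
#' exactly one record per chemical. The default policy `"min_p"` retains the
#' most significant record; `"max_p"` retains the least significant one
#' (the literal reading of keeping the record with the higher p-value).
#' q-values from the original full test set are retained; set
#' `requalify = TRUE` to re-run BH across the consolidated records.
#'
#' @param x An `ora` object.
#' @param policy `"min_p"` (default) or `"max_p"`.
#' @param requalify Recompute q-values after consolidation (default FALSE).
#' @return The consolidated `ora` object; filtered positions are renumbered
#'   consecutively, unfiltered positions are preserved.
#' @export
consolidate_duplicates <- function(x, policy = c("min_p", "max_p"),
                                   requalify = FALSE) {
  stopifnot(inherits(x, "ora"))
  policy <- match.arg(policy)
  res <- x$results |>
    group_by(.data$chemical_id) |>
    arrange(if (policy == "min_p") .data$p_value else -.data$p_value,
            .data$source, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$unfiltered_position) |>
    mutate(filtered_position = row_number())
  if (requalify) res$q_value <- bh_adjust(res$p_value)
  x$results <- res
  x
}

#' Write enrichment results as a hit-table TSV
#'
#' Column schema mirrors published per-subtype hit tables:
#' `filtered_position`, `unfiltered_position`, `name`, `source`, `p_value`,
#' `q_value_fdr_bh`, `hit_count_in_query_list`, `hit_count_in_genome`.
#'
#' @param x An `ora` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(x, path) {
  stopifnot(inherits(x, "ora"))
  out <- x$results |>
    transmute(filtered_position = .data$filtered_position,
              unfiltered_position = .data$unfiltered_position,
              name = .data$chemical_name,
              source = .data$source,
              p_value = .data$p_value,
              q_value_fdr_bh = .data$q_value,
              hit_count_in_query_list = .data$hit_count_query,
              hit_count_in_genome = .data$hit_count_genome)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy enrichment results
#'
#' @param x An `ora` object.
#' @param ... Unused.
#' @return The per-compound results tibble.
#' @exportS3Method generics::tidy
tidy.ora <- function(x, ...) {
  x$results
}

#' One-row enrichment summary
#'
#' @param x An `ora` object.
#' @param ... Unused.
#' @return A one-row tibble: query label, universe size `N`, effective query
#'   size `n`, number of sets tested, number retained, alpha.
#' @exportS3Method generics::glance
glance.ora <- function(x, ...) {
  tibble(label = x$label, N = x$N, n = x$n, n_tested = x$n_tested,
         n_retained = nrow(x$results), alpha = x$alpha,
         min_p = if (nrow(x$results)) min(x$results$p_value) else NA_real_)
}

#' Plot top enrichment hits
#'
#' Bar chart of the top compounds by -log10 q-value.
#'
#' @param object An `ora` object.
#' @param top_n Number of compounds to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ora <- function(object, top_n = 20, ...) {
  df <- head(arrange(object$results, .data$p_value), top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(pmax(.data$q_value, 1e-300)),
    y = stats::reorder(.data$chemical_name, -.data$p_value),
    fill = .data$source)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10] ~ "q (BH)"), y = NULL,
                  fill = "Source",
                  title = paste0("Top compounds: ", object$label)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
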