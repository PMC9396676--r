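simple_assoc <- function() {
  make_assoc(list(
    list("c1", "alpha", "A", "CTD"), list("c1", "alpha", "B", "CTD"),
    list("c1", "alpha", "C", "CTD"),
    list("c2", "beta", "C", "CTD"), list("c2", "beta", "D", "CTD"),
    list("c3", "gamma", "E", "STITCH"), list("c3", "gamma", "F", "STITCH")))
}

test_that("enrich computes N, n, M, k from the table and query", {
  res <- enrich(simple_assoc(), c("A", "B", "C", "ZZZ"), keep_all = TRUE,
                quiet = TRUE)
  expect_equal(res$N, 6)          # universe A..F
  expect_equal(res$n, 3)          # ZZZ dropped
  expect_equal(res$n_dropped_query, 1)
  r <- tidy(res)
  c1 <- r[r$chemical_id == "c1", ]
  expect_equal(c1$hit_count_genome, 3)
  expect_equal(c1$hit_count_query, 3)
  expect_equal(c1$p_value, hyper_tail_p(3, 3, 3, 6))
  # c3 has zero overlap -> not tested under the default min_hits = 1
  expect_false("c3" %in% r$chemical_id)
  expect_equal(res$n_tested, 2)
})

test_that("saturated overlap is uninformative: universe == query gives p = 1", {
  tbl <- make_assoc(list(list("c1", "x", "A", "CTD"),
                         list("c1", "x", "B", "CTD")))
  res <- enrich(tbl, c("A", "B"), keep_all = TRUE, quiet = TRUE)
  expect_equal(tidy(res)$p_value, 1)
  expect_equal(nrow(enrich(tbl, c("A", "B"), quiet = TRUE)$results), 0)
})

test_that("reported q equals bh_adjust of reported p and ranks follow the tie-break", {
  sim <- simulate_dataset(sim_config(universe_size = 500, n_compounds = 200,
                                     annotation_size_range = c(25, 250),
                                     query_size = 50, n_planted = 20,
                                     planting_strength = 3, seed = 11))
  res <- enrich(sim$associations, gene_set(sim$catalog, "S1"),
                keep_all = TRUE, quiet = TRUE)
  r <- tidy(res)
  expect_equal(r$q_value, bh_adjust(r$p_value))
  expect_true(all(r$q_value >= r$p_value))
  ord <- order(r$p_value, -r$hit_count_query, r$chemical_id, r$source)
  expect_equal(r$rank[ord], seq_len(nrow(r)))
})

test_that("disjoint query raises a no-testable-genes error", {
  expect_error(enrich(simple_assoc(), c("X1", "X2"), quiet = TRUE),
               "No testable genes")
})

test_that("blocklist removal keeps unfiltered positions and renumbers filtered ones", {
  tbl <- make_assoc(list(
    list("oz", "Ozone", "A", "CTD"), list("oz", "Ozone", "B", "CTD"),
    list("oz", "Ozone", "C", "CTD"),
    list("c1", "alpha", "A", "CTD"), list("c1", "alpha", "B", "CTD"),
    list("c2", "beta", "A", "CTD"), list("c2", "beta", "D", "CTD"),
    list("c4", "delta", "D", "CTD"), list("c4", "delta", "E", "CTD")))
  res <- enrich(tbl, c("A", "B", "C"), alpha = 1, keep_all = TRUE,
                quiet = TRUE)
  filtered <- apply_blocklist(res, c("ozone"), quiet = TRUE)
  r <- tidy(filtered)
  expect_false("Ozone" %in% r$chemical_name)
  expect_equal(filtered$blocklist_removed, "Ozone")
  expect_equal(r$filtered_position, seq_len(nrow(r)))
  # unfiltered positions are a subset of the original ranking (naive re-sort)
  orig <- tidy(res)
  expect_equal(r$unfiltered_position,
               orig$rank[match(r$chemical_id, orig$chemical_id)])
  expect_true(all(diff(r$unfiltered_position) > 0))
  # empty blocklist is the identity
  same <- apply_blocklist(res, character(0), quiet = TRUE)
  expect_equal(tidy(same), tidy(res))
})

test_that("consolidation keeps one record per chemical under both policies", {
  tbl <- make_assoc(list(
    list("c1", "alpha", "A", "CTD"), list("c1", "alpha", "B", "CTD"),
    list("c1", "alpha", "A", "STITCH"),
    list("c2", "beta", "B", "CTD"),
    list("c3", "gamma", "C", "CTD"), list("c3", "gamma", "D", "CTD")))
  res <- enrich(tbl, c("A", "B"), alpha = 1, keep_all = TRUE, quiet = TRUE)
  expect_equal(sum(tidy(res)$chemical_id == "c1"), 2)  # CTD and STITCH units
  ids_before <- unique(tidy(res)$chemical_id)

  kept_min <- tidy(consolidate_duplicates(res))
  c1_min <- kept_min[kept_min$chemical_id == "c1", ]
  expect_equal(nrow(c1_min), 1)
  # CTD unit: k=2 of M=2 in N=4 -> p=1/6; STITCH unit: k=1 of M=1 -> p=1/2
  expect_equal(c1_min$source, "CTD")
  kept_max <- tidy(consolidate_duplicates(res, policy = "max_p"))
  c1_max <- kept_max[kept_max$chemical_id == "c1", ]
  expect_equal(nrow(c1_max), 1)
  expect_true(c1_max$p_value >= c1_min$p_value)
  # consolidation never changes the set of distinct chemicals
  expect_setequal(unique(kept_min$chemical_id), ids_before)
  expect_setequal(unique(kept_max$chemical_id), ids_before)
  # no duplicated chemicals -> identity
  res2 <- enrich(make_assoc(list(list("c9", "x", "A", "CTD"))), "A",
                 alpha = 1, keep_all = TRUE, quiet = TRUE)
  expect_equal(tidy(consolidate_duplicates(res2)), tidy(res2))
})

test_that("alpha = 1 retains every tested compound", {
  res <- enrich(simple_assoc(), c("A", "C"), alpha = 1, quiet = TRUE)
  expect_equal(nrow(tidy(res)), res$n_tested)
})

test_that("the hit-table TSV matches the published column schema", {
  res <- enrich(simple_assoc(), c("A", "B"), alpha = 1, keep_all = TRUE,
                quiet = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment(res, path)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_identical(header,
                   c("filtered_position", "unfiltered_position", "name",
                     "source", "p_value", "q_value_fdr_bh",
                     "hit_count_in_query_list", "hit_count_in_genome"))
})

test_that("glance and autoplot summarise an enrichment", {
  res <- enrich(simple_assoc(), c("A", "B"), alpha = 1, quiet = TRUE)
  g <- glance(res)
  expect_equal(g$N, 6)
  expect_equal(g$n_retained, nrow(tidy(res)))
  expect_s3_class(autoplot(res), "ggplot")
})
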