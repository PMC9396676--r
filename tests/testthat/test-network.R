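test_that("network building keeps only interacting nodes by default", {
  tbl <- make_assoc(list(
    list("d1", "drug1", "G1", "CTD"), list("d1", "drug1", "G2", "CTD"),
    list("d1", "drug1", "G3", "CTD"), list("d1", "drug1", "X9", "CTD"),
    list("d2", "drug2", "X8", "CTD")))
  net <- build_network(tbl, c("d1", "d2"), paste0("G", 1:5))
  expect_equal(nrow(net$drugs), 1)   # d2 has no overlap
  expect_equal(nrow(net$genes), 3)
  expect_equal(nrow(net$edges), 3)
  kept <- build_network(tbl, c("d1", "d2"), paste0("G", 1:5),
                        keep_isolated = TRUE)
  expect_equal(nrow(kept$drugs), 2)
  expect_equal(nrow(kept$genes), 5)
})

test_that("edge sets equal a naive double-loop intersection oracle", {
  sim <- simulate_dataset(sim_config(universe_size = 150, n_compounds = 40,
                                     annotation_size_range = c(5, 50),
                                     query_size = 30, n_planted = 5,
                                     seed = 5))
  drugs <- sim$truth$chemical_id[1:20]
  genes <- gene_set(sim$catalog, "S1")
  net <- suppressWarnings(build_network(sim$associations, drugs, genes))
  sets <- chemical_sets(sim$associations, by_source = FALSE)
  oracle <- list()
  for (d in drugs) {
    for (g in intersect(sets$genes[[match(d, sets$chemical_id)]], genes)) {
      oracle[[length(oracle) + 1]] <- c(d, g)
    }
  }
  oracle <- do.call(rbind, oracle)
  oracle <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
  expect_equal(net$edges$chemical_id, oracle[, 1])
  expect_equal(net$edges$gene_symbol, oracle[, 2])
})

test_that("density and drug degree follow their closed forms", {
  # complete bipartite 2x3
  tbl <- make_assoc(
    lapply(seq_len(6), function(i) {
      list(paste0("d", (i - 1) %/% 3 + 1), "x",
           paste0("G", (i - 1) %% 3 + 1), "CTD")
    }))
  net <- build_network(tbl, c("d1", "d2"), c("G1", "G2", "G3"))
  expect_equal(bipartite_density(net), 1)
  expect_equal(average_drug_degree(net), 3)
  s <- network_stats(net)
  expect_equal(s$density, s$n_edges / (s$n_drugs * s$n_genes))
  # single drug with 4 edges
  tbl2 <- make_assoc(lapply(1:4, function(i)
    list("d1", "x", paste0("G", i), "CTD")))
  expect_equal(average_drug_degree(build_network(tbl2, "d1",
                                                 paste0("G", 1:4))), 4)
})

test_that("low-degree gene filtering conserves edges and is idempotent", {
  set.seed(31)
  for (rep in 1:20) {
    net <- random_bipartite(sample(2:6, 1), sample(3:8, 1), 0.4,
                            seed = 1000 + rep)
    if (is.null(net)) next
    before <- network_stats(net)
    deg <- table(factor(net$edges$gene_symbol,
                        levels = net$genes$gene_symbol))
    removed_deg_sum <- sum(deg[deg < 3])
    out <- filter_low_degree_genes(net, 3)
    expect_equal(before$n_edges - nrow(out$edges), removed_deg_sum)
    expect_true(all(table(out$edges$gene_symbol) >= 3))
    again <- filter_low_degree_genes(out, 3)
    expect_equal(again$edges, out$edges)
    expect_equal(again$genes, out$genes)
    # drugs retained even if isolated, by default
    expect_equal(out$drugs, net$drugs)
    # min_degree 0 is the identity
    expect_equal(filter_low_degree_genes(net, 0)$edges, net$edges)
  }
})

test_that("closeness on a path and star matches hand-computed values", {
  # path d1 - g1 - d2
  tbl <- make_assoc(list(list("d1", "d1", "G1", "CTD"),
                         list("d2", "d2", "G1", "CTD")))
  net <- build_network(tbl, c("d1", "d2"), "G1")
  cent <- centrality(net)
  expect_equal(cent$nodes$closeness[cent$nodes$id == "G1"], 1.0)
  expect_equal(cent$nodes$closeness[cent$nodes$id == "d1"], 2 / 3)
  # star: center gene with 4 drugs; each edge lies on its endpoint pair
  # plus 3 leaf-pair paths
  tbl2 <- make_assoc(lapply(1:4, function(i)
    list(paste0("d", i), "x", "G1", "CTD")))
  star <- build_network(tbl2, paste0("d", 1:4), "G1")
  bet <- centrality(star)$edges$betweenness
  expect_equal(bet, rep(4, 4))
})

test_that("isolated nodes have closeness zero and degree zero", {
  tbl <- make_assoc(list(list("d1", "d1", "G1", "CTD"),
                         list("d2", "d2", "X1", "CTD")))
  net <- build_network(tbl, c("d1", "d2"), c("G1", "G2"),
                       keep_isolated = TRUE)
  cent <- centrality(net)
  g2 <- cent$nodes[cent$nodes$id == "G2", ]
  expect_equal(g2$degree, 0L)
  expect_equal(g2$closeness, 0)
})

test_that("degree, closeness and betweenness match brute-force enumeration", {
  set.seed(99)
  n_checked <- 0
  for (rep in 1:30) {
    net <- random_bipartite(sample(2:5, 1), sample(2:5, 1), 0.5,
                            seed = 2000 + rep)
    if (is.null(net)) next
    n_checked <- n_checked + 1
    cent <- centrality(net)
    nodes <- cent$nodes$id
    edges <- cbind(net$edges$chemical_id, net$edges$gene_symbol)
    oracle <- brute_force_graph_metrics(nodes, edges)
    expect_equal(cent$nodes$degree, as.integer(oracle$degree[nodes]),
                 ignore_attr = TRUE)
    expect_equal(cent$nodes$closeness, unname(oracle$closeness[nodes]),
                 tolerance = 1e-12)
    key <- paste(pmin(net$edges$chemical_id, net$edges$gene_symbol),
                 pmax(net$edges$chemical_id, net$edges$gene_symbol),
                 sep = "|")
    expect_equal(cent$edges$betweenness, unname(oracle$betweenness[key]),
                 tolerance = 1e-12)
  }
  expect_gte(n_checked, 20)
})

test_that("stratification yields induced subnetworks with monotone stats", {
  sim <- simulate_dataset(sim_config(universe_size = 200, n_compounds = 30,
                                     annotation_size_range = c(10, 60),
                                     query_size = 40, n_planted = 5,
                                     n_subtypes = 3, seed = 13))
  all_genes <- unique(sim$catalog$gene)
  net <- build_network(sim$associations, sim$truth$chemical_id, all_genes)
  catalog_all <- combine_subtypes(sim$catalog,
                                  catalog_labels(sim$catalog), "all")
  strat <- stratify(net, catalog_all)
  # the full-catalog stratum reproduces the input network
  expect_equal(strat$networks$all$edges, net$edges)
  for (lab in catalog_labels(sim$catalog)) {
    sub <- strat$networks[[lab]]
    expect_true(all(paste(sub$edges$chemical_id, sub$edges$gene_symbol) %in%
                      paste(net$edges$chemical_id, net$edges$gene_symbol)))
    expect_lte(nrow(sub$edges), nrow(net$edges))
    # naive filter-then-build oracle
    oracle <- suppressWarnings(
      build_network(sim$associations, net$drugs$chemical_id,
                    gene_set(catalog_all, lab), subtype = lab))
    oracle$edges <- oracle$edges[
      paste(oracle$edges$chemical_id, oracle$edges$gene_symbol) %in%
        paste(net$edges$chemical_id, net$edges$gene_symbol), ]
    expect_equal(sub$edges$chemical_id, oracle$edges$chemical_id)
    expect_equal(sub$edges$gene_symbol, oracle$edges$gene_symbol)
  }
  expect_error(stratify(net, sim$catalog, labels = "nope"), "nope")
})

test_that("graph exports round-trip through GraphML, SIF and edge lists", {
  tbl <- make_assoc(list(list("d1", "drug one", "G1", "CTD"),
                         list("d1", "drug one", "G2", "STITCH"),
                         list("d2", "drug two", "G2", "CTD")))
  net <- build_network(tbl, c("d1", "d2"), c("G1", "G2"), subtype = "demo")
  dir <- withr::local_tempdir()

  gml <- file.path(dir, "net.graphml")
  write_graphml(net, gml)
  back <- read_graphml(gml)
  expect_equal(back$edges, net$edges)
  expect_equal(back$drugs, net$drugs)
  expect_equal(back$subtype, "demo")
  expect_equal(network_stats(back)[-1], network_stats(net)[-1])

  sif <- file.path(dir, "net.sif")
  write_sif(net, sif)
  expect_equal(readLines(sif),
               c("d1 targets G1", "d1 targets G2", "d2 targets G2"))

  el <- file.path(dir, "net.tsv")
  write_edge_list(net, el)
  back2 <- read_edge_list(el)
  expect_equal(back2$edges, net$edges)
})

test_that("a synthetic network reloads from GraphML with identical stats", {
  sim <- simulate_dataset(sim_config(universe_size = 100, n_compounds = 15,
                                     annotation_size_range = c(5, 30),
                                     query_size = 25, n_planted = 3,
                                     seed = 17))
  net <- suppressWarnings(
    build_network(sim$associations, sim$truth$chemical_id,
                  gene_set(sim$catalog, "S1")))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  expect_equal(network_stats(read_graphml(gml))[-1], network_stats(net)[-1])
})

test_that("degenerate networks are handled as specified", {
  tbl <- make_assoc(list(list("d1", "x", "G1", "CTD")))
  expect_warning(net0 <- build_network(tbl, "d1", "G9"), "no edges")
  expect_error(bipartite_density(net0), "undefined")
  expect_error(build_network(tbl, character(0), "G1"), "non-empty")
  # tidy/glance accessors
  net <- build_network(tbl, "d1", "G1")
  expect_equal(glance(net)$n_edges, 1)
  expect_equal(nrow(tidy(net)), 2)
  expect_s3_class(autoplot(net), "ggplot")
})
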