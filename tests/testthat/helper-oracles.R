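# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# P(X >= k) by exhaustive enumeration of all C(N, n) draws (N small).
enum_hyper_tail <- function(k, M, n, N) {
  if (n == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= M)  # genes 1..M are the annotated ones
  mean(hits >= k)
}

# Naive O(m^2) BH: q_i = min over all j with p_j >= p_i of p_j * m / rank_j.
naive_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  r <- numeric(m)
  r[ord] <- seq_len(m)
  vapply(seq_len(m), function(i) {
    tail_idx <- which(r >= r[i])
    min(1, min(p[tail_idx] * m / r[tail_idx]))
  }, numeric(1))
}

# All-pairs shortest-path enumeration on a small undirected graph given as a
# 2-column character edge matrix. Returns per-node distances-based closeness,
# per-node degree and per-edge betweenness with fractional tie counting.
brute_force_graph_metrics <- function(nodes, edges) {
  n <- length(nodes)
  adj <- lapply(nodes, function(v) {
    c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])
  })
  names(adj) <- nodes
  # enumerate all shortest paths between a pair via BFS layers
  all_shortest_paths_pair <- function(a, b) {
    if (a == b) return(list())
    # BFS distances from a
    dist <- stats::setNames(rep(Inf, n), nodes)
    dist[a] <- 0
    frontier <- a
    while (length(frontier) > 0) {
      nxt <- character(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
    if (is.infinite(dist[b])) return(list())
    # backtrack all shortest paths from b to a
    paths <- list(b)
    repeat {
      done <- TRUE
      out <- list()
      for (p in paths) {
        v <- p[[1]]
        if (v == a) {
          out[[length(out) + 1]] <- p
          next
        }
        done <- FALSE
        preds <- adj[[v]][dist[adj[[v]]] == dist[v] - 1]
        for (u in preds) out[[length(out) + 1]] <- c(u, p)
      }
      paths <- out
      if (done) break
    }
    paths
  }
  dist_mat <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(dist_mat) <- 0
  edge_key <- function(u, v) paste(sort(c(u, v)), collapse = "|")
  bet <- stats::setNames(rep(0, nrow(edges)),
                         mapply(edge_key, edges[, 1], edges[, 2]))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      paths <- all_shortest_paths_pair(nodes[i], nodes[j])
      if (length(paths) == 0) next
      dist_mat[i, j] <- dist_mat[j, i] <- length(paths[[1]]) - 1
      for (p in paths) {
        for (s in seq_len(length(p) - 1)) {
          k <- edge_key(p[[s]], p[[s + 1]])
          bet[k] <- bet[k] + 1 / length(paths)
        }
      }
    }
  }
  closeness <- apply(dist_mat, 1, function(row) {
    reach <- row[is.finite(row) & row > 0]
    if (length(reach) == 0) 0 else length(reach) / sum(reach)
  })
  degree <- vapply(adj, length, numeric(1))
  list(degree = degree, closeness = closeness, betweenness = bet,
       distances = dist_mat)
}

# Small hand-rolled association tibble for fixture-free tests.
make_assoc <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chemical_id = r[[1]], chemical_name = r[[2]],
               gene_symbol = r[[3]], source = r[[4]],
               evidence = if (length(r) >= 5) r[[5]] else "curated")
  }))
  as_association_table(df, quiet = TRUE)
}

# Uniform random bipartite network as a dg_network, via the package builder.
random_bipartite <- function(n_drugs, n_genes, p_edge, seed) {
  set.seed(seed)
  drugs <- paste0("d", seq_len(n_drugs))
  genes <- paste0("GENE", seq_len(n_genes))
  pairs <- expand.grid(d = drugs, g = genes, stringsAsFactors = FALSE)
  pairs <- pairs[stats::runif(nrow(pairs)) < p_edge, , drop = FALSE]
  if (nrow(pairs) == 0) return(NULL)
  assoc <- as_association_table(
    data.frame(chemical_id = pairs$d, chemical_name = pairs$d,
               gene_symbol = pairs$g, source = "CTD",
               evidence = "curated"), quiet = TRUE)
  suppressWarnings(build_network(assoc, drugs, genes))
}
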