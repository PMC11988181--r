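# Independent oracles and small fixture builders used across tests.

# Random directed scored multigraph in the acceptance-property regime:
# every ordered pair carries an edge with probability edgeProb, scores
# uniform on (0.1, 1), effect DOWN with probability 0.5. A few duplicated
# rows are appended so parallel edges are exercised.
randomNetwork <- function(nNodes = 20, edgeProb = 0.15, seed = 1,
                          parallelFrac = 0.1) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(nNodes))
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- runif(nrow(pairs)) < edgeProb
  e <- pairs[keep, , drop = FALSE]
  if (!nrow(e)) e <- pairs[1, , drop = FALSE]
  dup <- e[runif(nrow(e)) < parallelFrac, , drop = FALSE]
  e <- rbind(e, dup)
  e$score <- runif(nrow(e), 0.1, 1)
  e$effect <- ifelse(runif(nrow(e)) < 0.5, "DOWN", "UP")
  CausalNetwork(e, nodes = nodes)
}

# Exhaustive-enumeration oracle via matrix powers: minimal-hop walks are
# exactly the shortest paths, so with W the signed score-sum adjacency and
# C the parallel-edge count adjacency, the aggregate for a pair at hop
# distance L is S0 * (W^L)[s, t] and the path count is (C^L)[s, t].
oracleAggregates <- function(net, S0 = 10000) {
  nodes <- nodeNames(net)
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  C <- W
  e <- edgeTable(net)
  for (i in seq_len(nrow(e))) {
    sg <- if (e$effect[i] == "DOWN") -1 else 1
    W[e$source[i], e$target[i]] <- W[e$source[i], e$target[i]] + sg * e$score[i]
    C[e$source[i], e$target[i]] <- C[e$source[i], e$target[i]] + 1
  }
  dist <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(dist) <- 0
  agg <- matrix(0, n, n, dimnames = list(nodes, nodes))
  diag(agg) <- S0
  np <- matrix(0, n, n, dimnames = list(nodes, nodes))
  diag(np) <- 1
  WL <- diag(n)
  CL <- diag(n)
  for (L in seq_len(n - 1)) {
    WL <- WL %*% W
    CL <- CL %*% C
    new <- is.infinite(dist) & CL > 0
    if (any(new)) {
      dist[new] <- L
      agg[new] <- S0 * WL[new]
      np[new] <- CL[new]
    }
    if (all(is.finite(dist))) break
  }
  list(dist = dist, agg = agg, n_paths = np)
}

# Recursive-DFS enumeration oracle for small graphs: minimal hop count from
# igraph, then every walk of exactly that many edges (each parallel edge a
# distinct choice) ending at the target.
enumShortestPaths <- function(net, s, t, S0 = 10000) {
  e <- edgeTable(net)
  g <- igraph::graph_from_data_frame(e[, c("source", "target")],
                                     directed = TRUE,
                                     vertices = nodeNames(net))
  d <- suppressWarnings(
    igraph::distances(g, v = s, to = t, mode = "out", weights = NA)[1, 1])
  if (!is.finite(d)) return(list())
  if (d == 0)
    return(list(list(nodes = s, rows = integer(0), value = S0)))
  found <- list()
  rec <- function(node, rows) {
    if (length(rows) == d) {
      if (node == t) found[[length(found) + 1L]] <<- rows
      return(invisible())
    }
    for (i in which(e$source == node)) rec(e$target[i], c(rows, i))
  }
  rec(s, integer(0))
  lapply(found, function(rows) list(
    nodes = c(s, e$target[rows]), rows = rows,
    value = S0 * prod(e$score[rows]) * (-1)^sum(e$effect[rows] == "DOWN")))
}

# Canonical signature of an enumerated path for set comparison.
pathSignature <- function(p) {
  paste(c(paste(p$nodes, collapse = ">"),
          paste(p$edges$effect, collapse = ","),
          paste(format(p$edges$score, digits = 12), collapse = ",")),
        collapse = "|")
}

# Hand-built weighted correlation network: nodes/edges/dist/weights set
# directly, bypassing the correlation step.
makeWeightedNet <- function(nodes, edges, weights) {
  edges$r <- if (is.null(edges$r)) rep(0.5, nrow(edges)) else edges$r
  edges$p <- 0
  edges$p_adj <- 0
  net <- new("CorrelationNetwork", nodes = nodes,
             edges = edges[, c("a", "b", "r", "p", "p_adj")])
  if (!is.null(edges$dist)) net@edges$dist <- edges$dist
  w <- weights
  names(w) <- nodes
  net@weights <- w
  net
}

# Write the standard small causal-network file used by parser tests.
writeNetFile <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("ENTITYA\tENTITYB\tEFFECT\tSCORE", lines), f)
  f
}
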