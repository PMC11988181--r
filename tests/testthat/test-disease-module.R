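test_that("correlation edges require both significance and causal adjacency", {
  set.seed(1)
  base <- rnorm(10)
  expr <- rbind(A = base, B = base * 2 + 1, C = rnorm(10), D = rnorm(10))
  colnames(expr) <- sprintf("s%02d", 1:10)
  degs <- data.frame(gene = c("A", "B", "C", "D"), log2fc = 1)
  adj <- CausalNetwork(data.frame(source = "A", target = "B",
                                  effect = "UP", score = 0.5),
                       nodes = c("A", "B", "C", "D"))
  net <- suppressMessages(buildCorrelationNetwork(expr, degs, adj))
  e <- edgeTable(net)
  expect_equal(nrow(e), 1L)
  expect_equal(sort(c(e$a, e$b)), c("A", "B"))
  expect_equal(e$r, 1)

  # same perfect correlation, but no causal adjacency -> no edge
  noAdj <- CausalNetwork(data.frame(source = "C", target = "D",
                                    effect = "UP", score = 0.5),
                         nodes = c("A", "B", "C", "D"))
  net2 <- suppressMessages(buildCorrelationNetwork(expr, degs, noAdj))
  expect_equal(numEdges(net2), 0L)

  expect_error(suppressMessages(
    buildCorrelationNetwork(expr[, 1:2], degs, adj)), "3 samples")
})

test_that("correlation network matches a brute-force cor.test/BH loop", {
  set.seed(42)
  genes <- sprintf("g%d", 1:5)
  expr <- matrix(rnorm(100), nrow = 5, dimnames = list(genes, sprintf("s%d", 1:20)))
  degs <- data.frame(gene = genes, log2fc = rnorm(5))
  # fully adjacent causal net so only the statistics decide
  pairsAll <- t(combn(genes, 2))
  causal <- CausalNetwork(data.frame(source = pairsAll[, 1],
                                     target = pairsAll[, 2],
                                     effect = "UP", score = 0.5))
  net <- suppressMessages(buildCorrelationNetwork(expr, degs, causal))
  # brute force: all-pairs cor.test, BH by hand, threshold
  ps <- apply(pairsAll, 1, function(pr)
    cor.test(expr[pr[1], ], expr[pr[2], ])$p.value)
  padj <- p.adjust(ps, "BH")
  keep <- which(padj < 0.05)
  expect_equal(nrow(edgeTable(net)), length(keep))
  if (length(keep)) {
    got <- with(edgeTable(net), sort(paste(pmin(a, b), pmax(a, b))))
    want <- sort(paste(pmin(pairsAll[keep, 1], pairsAll[keep, 2]),
                       pmax(pairsAll[keep, 1], pairsAll[keep, 2])))
    expect_equal(got, want)
    expect_equal(sort(edgeTable(net)$p_adj), sort(padj[keep]), tolerance = 1e-12)
  }
})

triangleNet <- function(log2fc) {
  # triangle A-B-C (degree 2 each) plus isolated D
  net <- new("CorrelationNetwork", nodes = c("A", "B", "C", "D"),
             edges = data.frame(a = c("A", "B", "C"), b = c("B", "C", "A"),
                                r = 0.5, p = 0, p_adj = 0))
  computeNodeWeights(net, data.frame(gene = c("A", "B", "C", "D"),
                                     log2fc = log2fc))
}

test_that("node weights are fold-change times degree, min-max normalised", {
  net <- triangleNet(c(-1, 0, 1, 5))
  w <- nodeWeights(net)
  # raw weights: {-2, 0, 2, 0}: D is isolated so its fold-change is ignored
  expect_equal(unname(w[c("A", "B", "C", "D")]), c(0, 0.5, 1, 0.5))
  expect_warning(triangleNet(c(0, 0, 0, 7)), "all raw node weights equal")

  # random-instance check against a two-line recomputation
  set.seed(9)
  for (i in 1:5) {
    fc <- rnorm(4)
    net <- triangleNet(fc)
    raw <- fc * c(2, 2, 2, 0)
    expect_equal(unname(nodeWeights(net)[c("A", "B", "C", "D")]),
                 (raw - min(raw)) / (max(raw) - min(raw)))
  }
})

test_that("edge distances shrink with correlation strength and are floored at 0", {
  net <- new("CorrelationNetwork", nodes = c("A", "B", "C", "D"),
             edges = data.frame(a = c("A", "B", "C"), b = c("B", "C", "D"),
                                r = c(1, 0.1, 0), p = 0, p_adj = 0))
  d <- edgeTable(computeEdgeDistances(net))$dist
  expect_equal(d[1], 0)          # -log10(1 + 1e-16) floored
  expect_equal(d[2], 1, tolerance = 1e-12)
  expect_equal(d[3], 16)
})

test_that("knode scores match a brute-force step-function evaluation", {
  # path graph A-B-C, weights {1, 0, 0}, unit edge distances
  net <- makeWeightedNet(c("A", "B", "C"),
                         data.frame(a = c("A", "B"), b = c("B", "C"),
                                    dist = c(1, 1)),
                         weights = c(1, 0, 0))
  kn <- knodeScores(net)
  sc <- setNames(kn$knode, kn$gene)
  # brute force: node weights fixed (A=1, B=0, C=0), distances vary with the
  # focal node; K(s) over s in {0, 1, 2}, step areas on [0,1) and [1,2)
  w <- c(1, 0, 0)
  brute <- function(d) {
    pbar <- mean(w)
    K <- function(s) 2 / (3 * pbar) * sum((w - pbar)[d <= s])
    K(0) * 1 + K(1) * 1
  }
  expect_equal(sc[["A"]], brute(c(0, 1, 2)))
  expect_equal(sc[["B"]], brute(c(1, 0, 1)))
  expect_equal(sc[["C"]], brute(c(2, 1, 0)))
  expect_gt(sc[["A"]], sc[["C"]])  # A is closest to the single heavy node
})

test_that("knode neighbourhood function is zero at the maximum distance", {
  for (seed in 1:5) {
    net0 <- randomNetwork(nNodes = 12, edgeProb = 0.25, seed = seed + 40)
    e <- edgeTable(net0)
    set.seed(seed)
    net <- makeWeightedNet(nodeNames(net0),
                           data.frame(a = e$source, b = e$target,
                                      dist = runif(nrow(e), 0.1, 2)),
                           weights = runif(length(nodeNames(net0))))
    g <- igraph::graph_from_data_frame(edgeTable(net)[, c("a", "b")],
                                       directed = FALSE,
                                       vertices = nodeNames(net))
    D <- igraph::distances(g, weights = edgeTable(net)$dist)
    sMax <- max(D[is.finite(D)])
    for (gene in sample(nodeNames(net), 4))
      expect_lt(abs(knodeCurve(net, gene, sMax)), 1e-9)
  }
})

test_that("uniform node weights give all-zero knode scores", {
  net <- makeWeightedNet(c("A", "B", "C"),
                         data.frame(a = c("A", "B"), b = c("B", "C"),
                                    dist = c(1, 2)),
                         weights = c(0.5, 0.5, 0.5))
  expect_equal(knodeScores(net)$knode, rep(0, 3))
  netZero <- makeWeightedNet(c("A", "B"),
                             data.frame(a = "A", b = "B", dist = 1),
                             weights = c(0, 0))
  expect_error(knodeScores(netZero), "zero")
})

test_that("raising a connected node's raw weight never lowers its own knode score", {
  for (seed in 1:5) {
    net0 <- randomNetwork(nNodes = 10, edgeProb = 0.3, seed = seed + 60)
    e <- edgeTable(net0)
    nodes <- nodeNames(net0)
    set.seed(seed)
    fc <- rnorm(length(nodes))
    degs <- data.frame(gene = nodes, log2fc = fc)
    corr <- new("CorrelationNetwork", nodes = nodes,
                edges = data.frame(a = e$source, b = e$target,
                                   r = runif(nrow(e), 0.2, 0.9),
                                   p = 0, p_adj = 0))
    corr <- computeEdgeDistances(corr)
    connected <- unique(c(e$source, e$target))
    target <- sample(connected, 1)
    scoreOf <- function(d) {
      w <- computeNodeWeights(corr, d)
      kn <- knodeScores(w)
      kn$knode[kn$gene == target]
    }
    before <- scoreOf(degs)
    degs2 <- degs
    degs2$log2fc[degs2$gene == target] <-
      degs2$log2fc[degs2$gene == target] + 2
    expect_gte(scoreOf(degs2), before - 1e-9)
  }
})

test_that("top-k selection is deterministic with the documented tie-breaks", {
  scores <- data.frame(gene = c("E", "B", "A", "D", "C"),
                       knode = c(3, 2, 2, 2, 1))
  degs <- data.frame(gene = c("A", "B", "C", "D", "E"),
                     log2fc = c(-2, 1, 0, 1, 0))
  got <- selectTopK(scores, degs, k = 3)
  # tie at knode 2 resolved by |log2fc| desc (A first), then gene symbol
  expect_equal(got, c("E", "A", "B"))
  expect_equal(selectTopK(scores, degs, k = 3), got)  # run-to-run identical
  expect_warning(all10 <- selectTopK(scores, degs, k = 25), "clipped")
  expect_length(all10, 5)
  expect_equal(defaultKRule(100), 25L)
  expect_equal(defaultKRule(500), 50L)
  expect_equal(defaultKRule(900), 100L)
})

test_that("permutation importance flags informative genes, not constants", {
  spec <- fixtureSpec(nGenes = 10, nPlanted = 2, effectSize = 3,
                      factorLoading = 0, loadingJitter = 0, effectJitter = 0,
                      nNormal = 50, nTumor = 50, nEdges = 40, seed = 5)
  ex <- generateExpression(spec)
  expr <- log2(ex$expr + 1)
  expr["G005", ] <- 7  # constant gene
  res <- refineByImportance(expr, rownames(expr), ex$labels,
                            degs = ex$degs, seed = 5)
  imp <- setNames(res$importance$importance, res$importance$gene)
  expect_lte(imp[["G005"]], 0)
  expect_true(all(imp[c("G001", "G002")] > 0))
  nulls <- setdiff(names(imp), c("G001", "G002"))
  expect_gte(sum(imp[nulls] <= 0.02), 7)
  expect_setequal(intersect(moduleGenes(res$module), c("G001", "G002")),
                  c("G001", "G002"))
})

test_that("column order of the expression matrix does not change the module", {
  spec <- fixtureSpec(nGenes = 10, nPlanted = 2, effectSize = 3,
                      factorLoading = 0, nNormal = 30, nTumor = 30,
                      nEdges = 40, seed = 11)
  ex <- generateExpression(spec)
  expr <- log2(ex$expr + 1)
  res1 <- refineByImportance(expr, rownames(expr), ex$labels,
                             degs = ex$degs, seed = 3)
  set.seed(99)
  perm <- sample(ncol(expr))
  res2 <- refineByImportance(expr[, perm], rownames(expr),
                             ex$labels[perm], degs = ex$degs, seed = 3)
  expect_equal(moduleGenes(res2$module), moduleGenes(res1$module))
  expect_equal(res2$importance, res1$importance)
})

test_that("importance refinement validates its inputs", {
  expr <- matrix(rnorm(40), nrow = 4,
                 dimnames = list(letters[1:4], sprintf("s%d", 1:10)))
  labels <- setNames(rep(c("a", "b"), 5), colnames(expr))
  expect_error(refineByImportance(expr, letters[1:4], labels, folds = 6),
               "at least 6 samples")
  labels3 <- setNames(rep(c("a", "b", "c"), length.out = 10), colnames(expr))
  expect_error(refineByImportance(expr, letters[1:4], labels3),
               "two classes")
})
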