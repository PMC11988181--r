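diamond <- CausalNetwork(data.frame(
  source = c("A", "A", "B", "C"), target = c("B", "C", "D", "D"),
  effect = "UP", score = 0.5))

test_that("single-path scores follow the signed product rule", {
  expect_equal(scorePath(data.frame(effect = "UP", score = 1.0)), 10000)
  expect_equal(scorePath(data.frame(effect = c("UP", "DOWN"),
                                    score = c(0.5, 0.7))), -3500)
  expect_equal(scorePath(data.frame(effect = c("DOWN", "DOWN"),
                                    score = c(0.9, 0.9))), 8100)
  # empty path: source equals target
  expect_equal(scorePath(data.frame(effect = character(),
                                    score = numeric())), 10000)
})

test_that("shortest paths are minimal hop-count and parallel edges are distinct", {
  ps <- allShortestPaths(diamond, "A", "D")
  expect_length(ps, 2L)
  expect_equal(sort(sapply(ps, function(p) paste(p$nodes, collapse = ""))),
               c("ABD", "ACD"))

  withDirect <- CausalNetwork(rbind(
    edgeTable(diamond),
    data.frame(source = "A", target = "D", effect = "DOWN", score = 0.4)))
  ps2 <- allShortestPaths(withDirect, "A", "D")
  expect_length(ps2, 1L)
  expect_equal(ps2[[1]]$signed_value, -4000)

  par <- CausalNetwork(data.frame(
    source = c("A", "A", "B"), target = c("B", "B", "C"),
    effect = c("UP", "DOWN", "UP"), score = c(0.5, 0.7, 0.8)))
  ps3 <- allShortestPaths(par, "A", "C")
  expect_length(ps3, 2L)  # the two parallel A->B edges give distinct paths
  expect_setequal(round(sapply(ps3, `[[`, "signed_value")), c(4000, -5600))

  expect_error(allShortestPaths(diamond, "A", "Z"), "Z")
})

test_that("aggregate scores match hand values, zero-contribution and self-pair rules", {
  agg <- defaultAggregateScore(diamond, "A", "D")
  expect_equal(agg$aggregate, 5000)
  expect_equal(agg$n_paths, 2)

  disc <- CausalNetwork(data.frame(source = "A", target = "B",
                                   effect = "UP", score = 0.5),
                        nodes = c("A", "B", "Z"))
  un <- defaultAggregateScore(disc, "A", "Z")
  expect_equal(un$aggregate, 0)
  expect_equal(un$n_paths, 0)

  self <- defaultAggregateScore(diamond, "A", "A")
  expect_equal(self$aggregate, 10000)
  expect_equal(self$n_paths, 1)
})

test_that("enumeration cap truncates loudly but leaves the aggregate exact", {
  expect_warning(ps <- allShortestPaths(diamond, "A", "D", maxPaths = 1),
                 "shortest paths")
  expect_length(ps, 1L)
  expect_true(attr(ps, "truncated"))
  agg <- defaultAggregateScore(diamond, "A", "D", maxPaths = 1)
  expect_true(agg$truncated)
  expect_equal(agg$aggregate, 5000)
})

test_that("DP aggregates equal the exhaustive enumeration oracle on random graphs", {
  for (seed in 1:15) {
    net <- randomNetwork(nNodes = 12 + seed, edgeProb = 0.15, seed = seed)
    or <- oracleAggregates(net)
    cache <- pairScoreCache(net)
    nodes <- nodeNames(net)
    for (s in nodes) {
      for (t in nodes) {
        got <- defaultAggregateScore(NULL, s, t, cache = cache)
        expect_equal(got$aggregate, or$agg[s, t], tolerance = 1e-10)
        expect_equal(got$n_paths, or$n_paths[s, t])
      }
    }
  }
})

test_that("enumerated path sets equal the recursive DFS oracle", {
  for (seed in 1:6) {
    net <- randomNetwork(nNodes = 9, edgeProb = 0.2, seed = seed + 100)
    nodes <- nodeNames(net)
    set.seed(seed)
    for (k in 1:5) {
      st <- sample(nodes, 2)
      got <- allShortestPaths(net, st[1], st[2])
      want <- enumShortestPaths(net, st[1], st[2])
      expect_length(got, length(want))
      if (length(want)) {
        sig <- function(nodes, vals) sort(paste(nodes, format(vals, digits = 12)))
        expect_equal(
          sig(sapply(got, function(p) paste(p$nodes, collapse = ">")),
              sapply(got, `[[`, "signed_value")),
          sig(sapply(want, function(p) paste(p$nodes, collapse = ">")),
              sapply(want, `[[`, "value")))
      }
    }
  }
})

test_that("final connection score obeys the sign algebra and additivity", {
  net <- randomNetwork(nNodes = 18, edgeProb = 0.18, seed = 77)
  nodes <- nodeNames(net)
  set.seed(7)
  targets <- data.frame(target = sample(nodes, 3),
                        moa = c("UP", "DOWN", "UP"))
  module <- DiseaseModule("d", data.frame(
    gene = sample(setdiff(nodes, targets$target), 4),
    log2fc = c(1.2, -0.5, 2, -3)))
  cache <- pairScoreCache(net)
  base <- finalConnectionScore(NULL, targets, module, cache = cache)

  flipT <- targets
  flipT$moa <- ifelse(targets$moa == "UP", "DOWN", "UP")
  expect_equal(finalConnectionScore(NULL, flipT, module, cache = cache)$final,
               -base$final)

  flipped <- moduleTable(module)
  flipped$log2fc <- -flipped$log2fc
  moduleF <- DiseaseModule("d", flipped)
  expect_equal(finalConnectionScore(NULL, flipT, moduleF, cache = cache)$final,
               base$final)

  # term-by-term: sum over single-target sub-drugs
  parts <- sum(vapply(seq_len(nrow(targets)), function(i)
    finalConnectionScore(NULL, targets[i, ], module, cache = cache)$final,
    numeric(1)))
  expect_equal(base$final, parts)

  # four-term hand sum on a 2x2 fixture
  t2 <- targets[1:2, ]
  m2 <- DiseaseModule("d", moduleTable(module)[1:2, ])
  hand <- 0
  for (i in 1:2) for (j in 1:2) {
    a <- defaultAggregateScore(NULL, t2$target[i],
                               moduleGenes(m2)[j], cache = cache)$aggregate
    hand <- hand + a * ifelse(t2$moa[i] == "DOWN", -1, 1) *
      ifelse(moduleTable(m2)$log2fc[j] < 0, -1, 1)
  }
  expect_equal(finalConnectionScore(NULL, t2, m2, cache = cache)$final, hand)
})

test_that("aggregates are bounded by start value times path count", {
  for (seed in 1:5) {
    net <- randomNetwork(nNodes = 15, edgeProb = 0.2, seed = seed + 200)
    cache <- pairScoreCache(net)
    nodes <- nodeNames(net)
    set.seed(seed)
    for (k in 1:10) {
      st <- sample(nodes, 2)
      a <- defaultAggregateScore(NULL, st[1], st[2], cache = cache)
      expect_lte(abs(a$aggregate), 10000 * max(a$n_paths, 0) + 1e-9)
    }
  }
})

test_that("unanchored drugs score zero and are flagged", {
  module <- DiseaseModule("d", data.frame(gene = "B", log2fc = 1))
  res <- finalConnectionScore(diamond,
                              data.frame(target = "ZZZ", moa = "UP"), module)
  expect_equal(res$final, 0)
  expect_equal(res$flag, "no anchored target")
})
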