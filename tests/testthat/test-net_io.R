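test_that("causal-network parser maps effects, drops bad rows, and keeps totals", {
  f <- writeNetFile(c("A\tB\tup-regulates\t0.9",
                      "B\tC\tdown-regulates activity\t0.4",
                      "C\tD\tform complex\t0.8"))
  net <- suppressMessages(parseCausalNetwork(f))
  expect_equal(numEdges(net), 2L)
  expect_equal(edgeTable(net)$effect, c("UP", "DOWN"))
  log <- parseLog(net)
  expect_equal(log$read, 3L)
  expect_equal(log$kept + log$dropped_bad_score +
               log$dropped_unmappable_effect + log$dropped_self_loop,
               log$read)

  f2 <- writeNetFile(c("A\tB\tup-regulates\t0.0",
                       "B\tC\tup-regulates\t0.5"))
  expect_warning(net2 <- suppressMessages(parseCausalNetwork(f2)),
                 "outside \\(0, 1\\]")
  expect_equal(numEdges(net2), 1L)

  f3 <- writeNetFile(c("A\tB\tup-regulates\t0.5",
                       "B\tB\tup-regulates\t0.5",
                       "B\tC\tup-regulates\t0.5",
                       "C\tD\tdown-regulates\t0.5",
                       "D\tA\tup-regulates\t0.5"))
  net3 <- suppressMessages(parseCausalNetwork(f3))
  expect_equal(numEdges(net3), 4L)
  expect_equal(parseLog(net3)$dropped_self_loop, 1L)

  f4 <- tempfile()
  writeLines(c("A\tB", "x\ty"), f4)
  expect_error(suppressMessages(parseCausalNetwork(f4)), "required column")
})

test_that("drug-target parser binarises MoA and excludes unmappable drugs", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("DRUG_ID\tDRUG_NAME\tTARGET\tMOA",
               "D1\tdrugA\tGRIA1\tInhibitor",
               "D1\tdrugA\tGRIA2\tModulator",
               "D2\tdrugB\tKRAS\tModulator"), f)
  ds <- suppressMessages(parseDrugTargets(f))
  expect_equal(drugIds(ds), "D1")
  expect_equal(drugTargets(ds, "D1"),
               data.frame(target = "GRIA1", moa = "DOWN"))
  expect_equal(parseLog(ds)$excluded_drugs, "D2")

  fEmpty <- tempfile(fileext = ".tsv")
  writeLines("DRUG_ID\tDRUG_NAME\tTARGET\tMOA", fEmpty)
  expect_length(drugIds(suppressMessages(parseDrugTargets(fEmpty))), 0)

  # same drug, same target, opposite modes of action: both entries retained
  fDup <- tempfile(fileext = ".tsv")
  writeLines(c("DRUG_ID\tDRUG_NAME\tTARGET\tMOA",
               "D1\tdrugA\tEGFR\tAgonist",
               "D1\tdrugA\tEGFR\tAntagonist"), fDup)
  dsDup <- suppressMessages(parseDrugTargets(fDup))
  t <- drugTargets(dsDup, "D1")
  expect_equal(nrow(t), 2L)
  expect_setequal(t$moa, c("UP", "DOWN"))
})

test_that("opposite-MoA duplicate entries score as two separate signed pairs", {
  # oracle: score each entry separately and sum
  net <- CausalNetwork(data.frame(source = "EGFR", target = "TP53",
                                  effect = "UP", score = 0.8))
  module <- DiseaseModule("d", data.frame(gene = "TP53", log2fc = 1))
  dup <- data.frame(target = c("EGFR", "EGFR"), moa = c("UP", "DOWN"))
  both <- finalConnectionScore(net, dup, module)
  single <- function(m) finalConnectionScore(
    net, data.frame(target = "EGFR", moa = m), module)$final
  expect_equal(both$final, single("UP") + single("DOWN"))
  expect_equal(both$final, 0)  # +8000 and -8000 cancel
})

test_that("BH adjustment matches hand-derived step-up values and is monotone", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.5), 0.5)
  expect_equal(bhAdjust(rep(0.05, 10)), rep(0.05, 10))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.5, -0.1)), "\\[0, 1\\]")
  set.seed(42)
  for (i in 1:5) {
    p <- runif(20)
    a <- bhAdjust(p)
    expect_true(all(a >= p - 1e-15))
    expect_true(all(a <= 1))
    expect_true(all(diff(a[order(p)]) >= -1e-15))
  }
})

test_that("edge tables round-trip through write and re-parse", {
  net <- randomNetwork(15, 0.2, seed = 3)
  f <- tempfile(fileext = ".tsv")
  writeCausalNetwork(net, f)
  net2 <- suppressMessages(parseCausalNetwork(f))
  key <- function(n) sort(with(edgeTable(n), paste(source, target, effect,
                                                   format(score, digits = 12))))
  expect_equal(key(net2), key(net))
})

test_that("subnetwork export writes SIF/GraphML/TSV with union semantics", {
  p1 <- list(nodes = c("A", "B", "C"),
             edges = data.frame(source = c("A", "B"), target = c("B", "C"),
                                effect = c("UP", "DOWN"), score = c(0.9, 0.5)))
  p2 <- list(nodes = c("A", "B", "D"),
             edges = data.frame(source = c("A", "B"), target = c("B", "D"),
                                effect = c("UP", "UP"), score = c(0.9, 0.7)))
  f <- tempfile(fileext = ".sif")
  exportSubnetwork(list(p1), f, format = "sif")
  expect_length(readLines(f), 2L)

  f2 <- tempfile(fileext = ".tsv")
  exportSubnetwork(list(p1, p2), f2, format = "tsv")
  tab <- read.delim(f2)
  expect_equal(nrow(tab), 3L)  # shared A->B written once
  expect_equal(tab$multiplicity[tab$source == "A"], 2L)

  f3 <- tempfile(fileext = ".graphml")
  exportSubnetwork(list(p1, p2), f3, format = "graphml",
                   nodeRoles = c(A = "drug_target", C = "disease_gene",
                                 D = "disease_gene"))
  g <- igraph::read_graph(f3, format = "graphml")
  expect_equal(igraph::gorder(g), 4)
  expect_equal(igraph::gsize(g), 3)
  expect_setequal(igraph::V(g)$role[igraph::V(g)$name == "B"], "intermediate")

  expect_error(exportSubnetwork(list(), f, format = "sif"), "no paths")
  expect_error(exportSubnetwork(list(p1), f, format = "dot"))
})
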