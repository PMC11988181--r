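## End-to-end orchestration: inputs -> disease modules -> connection scores
## -> size-matched nulls -> assessed associations -> exports + manifest.

#' Default pipeline configuration
#'
#' @param network,drugs paths to the causal-network and drug-target TSVs.
#' @param diseases list of per-disease input descriptors, each a list with
#'   \code{id}, \code{degs}, \code{expression}, \code{labels} (file paths).
#' @param outDir output directory.
#' @param alphaDeg,alphaCor,alphaSig thresholds for DEG selection,
#'   correlation edges and association significance (all 0.05 by default).
#' @param startValue arbitrary positive start value seeded at path sources
#'   (default 10000; all z-scores and p-values are invariant to it).
#' @param nDraws null draws per size combination (default 1000).
#' @param c stabilising constant for edge distances (default 1e-16).
#' @param maxPaths per-pair shortest-path count above which the pair is
#'   flagged (default 1e5).
#' @param k optional explicit module size overriding the sample-count rule.
#' @param seed master seed: module refinement and the null draws derive
#'   their seeds from it.
#' @param logExpression apply log2(x + 1) to the expression matrix before
#'   correlation/classification (default TRUE; appropriate for counts-like
#'   data).
#' @param explainTopPaths number of highest-|score| shortest paths exported
#'   for the top association (default 20; 0 disables).
#' @return A configuration list for [runPipeline()].
#' @export
pipelineConfig <- function(network, drugs, diseases, outDir,
                           alphaDeg = 0.05, alphaCor = 0.05, alphaSig = 0.05,
                           startValue = 10000, nDraws = 1000L, c = 1e-16,
                           maxPaths = 1e5, k = NULL, seed = 1L,
                           logExpression = TRUE, explainTopPaths = 20L) {
  stopifnot(alphaDeg > 0, alphaDeg < 1, alphaCor > 0, alphaCor < 1,
            alphaSig > 0, alphaSig < 1, startValue > 0)
  list(network = network, drugs = drugs, diseases = diseases,
       outDir = outDir, alphaDeg = alphaDeg, alphaCor = alphaCor,
       alphaSig = alphaSig, startValue = startValue,
       nDraws = as.integer(nDraws), c = c, maxPaths = maxPaths, k = k,
       seed = as.integer(seed), logExpression = isTRUE(logExpression),
       explainTopPaths = as.integer(explainTopPaths))
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipelineConfig()].
#' @return A configuration list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("network", "drugs", "diseases", "outDir")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("config lacks required field(s): ", paste(miss, collapse = ", "))
  do.call(pipelineConfig, y)
}

readExpressionMatrix <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  m
}

readLabels <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stats::setNames(d[[2]], d[[1]])
}

#' Run the full drug-repurposing pipeline
#'
#' Stages: parse the causal network and drug-target table; for each disease,
#' threshold its DEG table and build the refined disease module (correlation
#' network, knode ranking, top-k cut, importance refinement); score every
#' parsed drug against every module by summing sign-adjusted shortest-path
#' aggregates; build one size-matched 1000-draw null per (drug size, disease
#' size) combination over the shared pair-score cache; z-score and assign
#' lower-tail p-values; write all result tables, an explanation subnetwork
#' for the top association, and a run manifest.
#'
#' @param config list from [pipelineConfig()] or [readPipelineConfig()].
#' @return Invisibly, a list with \code{modules}, \code{scores},
#'   \code{associations}, \code{nulls} and the output \code{manifest} path.
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  net <- parseCausalNetwork(config$network)
  drugs <- parseDrugTargets(config$drugs)
  cache <- pairScoreCache(net, startValue = config$startValue,
                          maxPaths = config$maxPaths)
  modules <- list()
  moduleDir <- file.path(config$outDir, "modules")
  dir.create(moduleDir, showWarnings = FALSE)
  for (ds in config$diseases) {
    logMsg("pipeline", "building disease module: ", ds$id)
    degs <- readDegTable(ds$degs)
    expr <- readExpressionMatrix(ds$expression)
    labels <- readLabels(ds$labels)
    exprA <- if (config$logExpression) log2(expr + 1) else expr
    built <- buildDiseaseModule(exprA, labels, degs, net,
                                diseaseIdent = ds$id,
                                alphaDeg = config$alphaDeg,
                                alphaCor = config$alphaCor, c = config$c,
                                k = config$k, seed = config$seed)
    modules[[ds$id]] <- built$module
    utils::write.table(moduleTable(built$module),
                       file.path(moduleDir, paste0(ds$id, "_module.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  logMsg("pipeline", "scoring ", length(drugIds(drugs)), " drugs against ",
         length(modules), " disease module(s)")
  scores <- do.call(rbind, lapply(modules, function(m)
    scoreDrugSet(NULL, drugs, m, cache = cache)))
  rownames(scores) <- NULL
  unanchored <- scores$anchored_targets == 0
  if (any(unanchored))
    logMsg("pipeline", sum(unanchored),
           " drug-disease pair(s) had no anchored target; excluded from ",
           "significance assessment")
  assessed <- scores[!unanchored, , drop = FALSE]
  tab <- drugTable(drugs)
  targetPool <- sort(unique(tab$target[tab$target %in% nodeNames(net)]))
  poolRows <- do.call(rbind, lapply(modules, moduleTable))
  diseasePool <- poolRows[!duplicated(poolRows$gene),
                          c("gene", "log2fc"), drop = FALSE]
  nulls <- buildNullMemo(cache, assessed, targetPool, diseasePool,
                         moaProbs = moaFrequencies(drugs),
                         nDraws = config$nDraws, seed = config$seed)
  associations <- assessAssociations(assessed, nulls,
                                     alpha = config$alphaSig)
  utils::write.table(scores, file.path(config$outDir, "pair_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(associations,
                     file.path(config$outDir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  nullTab <- do.call(rbind, lapply(names(nulls), function(k) {
    n <- nulls[[k]]
    data.frame(combo = k, drug_size = n@drugSize,
               disease_size = n@diseaseSize, n_draws = n@nDraws,
               mean = n@mean, sd = n@sd, seed = n@seed)
  }))
  utils::write.table(nullTab,
                     file.path(config$outDir, "null_distributions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (config$explainTopPaths > 0 && nrow(associations)) {
    top <- associations[1, ]
    expDir <- file.path(config$outDir, "explanations")
    dir.create(expDir, showWarnings = FALSE)
    exportExplanation(net, drugs, modules[[top$disease_id]], top$drug_id,
                      file.path(expDir, paste0(top$drug_id, "_",
                                               top$disease_id, ".sif")),
                      topN = config$explainTopPaths,
                      startValue = config$startValue,
                      maxPaths = config$maxPaths)
  }
  manifest <- list(config = config[setdiff(names(config), "diseases")],
                   diseases = config$diseases,
                   n_drugs = length(drugIds(drugs)),
                   n_significant = sum(associations$significant),
                   versions = list(
                     package = as.character(utils::packageVersion("causalDR")),
                     r = paste(R.version$major, R.version$minor, sep = ".")))
  manifestPath <- file.path(config$outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  logMsg("pipeline", "done: ", sum(associations$significant),
         " significant association(s) of ", nrow(associations))
  invisible(list(modules = modules, scores = scores,
                 associations = associations, nulls = nulls,
                 manifest = manifestPath))
}

#' Export the explanation subnetwork for one drug-disease association
#'
#' Collects the shortest paths from every anchored target of the drug to
#' every module gene, keeps the \code{topN} by absolute signed connection
#' score, and writes their union through [exportSubnetwork()] with node
#' roles (drug target / disease gene / intermediate).
#'
#' @param net a [CausalNetwork-class].
#' @param drugs a [DrugSet-class].
#' @param module a [DiseaseModule-class].
#' @param drugId the drug to explain.
#' @param path output file; the extension picks the format (\code{.sif},
#'   \code{.graphml}, otherwise edge-table TSV).
#' @param topN number of paths kept (default 20).
#' @param startValue,maxPaths see [pairScoreCache()].
#' @return Invisibly, the list of exported paths.
#' @export
exportExplanation <- function(net, drugs, module, drugId, path, topN = 20L,
                              startValue = 10000, maxPaths = 1e5) {
  targets <- drugTargets(drugs, drugId)
  targets <- targets[targets$target %in% nodeNames(net), , drop = FALSE]
  if (!nrow(targets)) stop("drug ", drugId, " has no target in the network")
  genes <- intersect(moduleGenes(module), nodeNames(net))
  paths <- list()
  for (t in unique(targets$target)) {
    for (g in genes) {
      ps <- allShortestPaths(net, t, g, maxPaths = maxPaths,
                             startValue = startValue)
      paths <- c(paths, ps)
    }
  }
  if (!length(paths))
    stop("no path connects any target of ", drugId, " to the module")
  ord <- order(-abs(vapply(paths, function(p) p$signed_value, numeric(1))))
  keep <- paths[utils::head(ord, topN)]
  roles <- c(stats::setNames(rep("drug_target", nrow(targets)),
                             targets$target),
             stats::setNames(rep("disease_gene", length(genes)), genes))
  fmt <- if (grepl("\\.sif$", path)) "sif"
         else if (grepl("\\.graphml$", path)) "graphml" else "tsv"
  exportSubnetwork(keep, path, format = fmt, nodeRoles = roles)
  invisible(keep)
}
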