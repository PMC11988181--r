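## Synthetic fixtures with known ground truth: a causal network with a
## planted, correlated, up-regulated disease pathway; tumor/normal
## expression; a DEG table; and a drug-target table containing one "good"
## drug whose down-regulating targets sit directly upstream of the planted
## genes, guaranteeing a strongly negative final connection score.

#' Specification of a synthetic fixture
#'
#' A fixture is fully determined by its specification and seed. Defaults
#' describe a desk-scale study: 120 genes, a 480-edge scored causal network,
#' a 10-gene planted disease pathway shifted by 2 standard deviations
#' between 40 normal and 40 tumor samples, and 15 drugs of 2 targets each.
#'
#' @param nGenes number of genes (network nodes).
#' @param nEdges total number of causal edges generated (including the
#'   planted pathway's internal edges).
#' @param scoreRange range of the uniform edge-confidence distribution.
#' @param downProb probability that a random edge is down-regulating.
#' @param nPlanted size of the planted disease pathway (its genes are
#'   up-regulated in tumor samples and co-expressed through a shared latent
#'   factor, and are chained by causal edges so the correlation network can
#'   retain them).
#' @param effectSize tumor-vs-normal shift of planted genes, in standard
#'   deviations of their log-scale expression.
#' @param nNormal,nTumor samples per condition.
#' @param nDrugs number of drugs (one is the planted "good" drug; one extra
#'   decoy with only unmappable modes of action is always appended to
#'   exercise the parser).
#' @param targetsPerDrug targets per drug.
#' @param plantedEdgeScore confidence score of the engineered edges from the
#'   good drug's targets to the planted genes.
#' @param factorLoading mean loading of the shared latent factor on planted
#'   genes' log-expression (controls their pairwise correlation).
#' @param loadingJitter half-width of the per-gene uniform jitter around
#'   \code{factorLoading}; heterogeneous loadings keep the planted genes
#'   from being perfectly statistically redundant.
#' @param effectJitter per-gene effect sizes are
#'   \code{effectSize * U(1 - effectJitter, 1 + effectJitter)}; set 0 for
#'   identical shifts.
#' @param seed integer seed; sub-stages use seed, seed + 1, seed + 2.
#' @return A list of class \code{fixtureSpec}.
#' @export
fixtureSpec <- function(nGenes = 120L, nEdges = 480L,
                        scoreRange = c(0.1, 1), downProb = 0.3,
                        nPlanted = 10L, effectSize = 2,
                        nNormal = 40L, nTumor = 40L,
                        nDrugs = 15L, targetsPerDrug = 2L,
                        plantedEdgeScore = 0.9, factorLoading = 0.5,
                        loadingJitter = 0.15, effectJitter = 0.3,
                        seed = 1L) {
  spec <- list(nGenes = as.integer(nGenes), nEdges = as.integer(nEdges),
               scoreRange = scoreRange, downProb = downProb,
               nPlanted = as.integer(nPlanted), effectSize = effectSize,
               nNormal = as.integer(nNormal), nTumor = as.integer(nTumor),
               nDrugs = as.integer(nDrugs),
               targetsPerDrug = as.integer(targetsPerDrug),
               plantedEdgeScore = plantedEdgeScore,
               factorLoading = factorLoading,
               loadingJitter = loadingJitter, effectJitter = effectJitter,
               seed = as.integer(seed))
  stopifnot(spec$nPlanted < spec$nGenes,
            spec$nGenes > spec$nPlanted + spec$targetsPerDrug,
            spec$nEdges >= 2 * spec$nPlanted - 3)
  spec$genes <- sprintf("G%03d", seq_len(spec$nGenes))
  spec$planted <- spec$genes[seq_len(spec$nPlanted)]
  spec$goodTargets <- utils::tail(spec$genes, spec$targetsPerDrug)
  class(spec) <- "fixtureSpec"
  spec
}

#' Generate the synthetic causal network
#'
#' Produces a directed random multigraph with exactly \code{spec$nEdges}
#' edges and no self-loops: a chain (plus skip links) through the planted
#' pathway genes, then uniformly random ordered pairs. Scores are uniform on
#' \code{spec$scoreRange}; each random edge is down-regulating with
#' probability \code{spec$downProb} (planted-pathway edges are
#' up-regulating).
#'
#' @param spec a [fixtureSpec()].
#' @return A [CausalNetwork-class] whose node set is all \code{spec$genes}.
#' @export
generateCausalNetwork <- function(spec) {
  withSeed(spec$seed, {
    pl <- spec$planted
    nP <- length(pl)
    chain <- data.frame(source = pl[-nP], target = pl[-1])
    skip <- if (nP > 2)
      data.frame(source = pl[seq_len(nP - 2)], target = pl[-(1:2)])
    else NULL
    plantedEdges <- rbind(chain, skip)
    plantedEdges$effect <- "UP"
    plantedEdges$score <- stats::runif(nrow(plantedEdges), 0.6, 0.9)
    nRandom <- spec$nEdges - nrow(plantedEdges)
    src <- character(0); tgt <- character(0)
    while (length(src) < nRandom) {
      need <- nRandom - length(src)
      s <- sample(spec$genes, need, replace = TRUE)
      t <- sample(spec$genes, need, replace = TRUE)
      ok <- s != t
      src <- c(src, s[ok]); tgt <- c(tgt, t[ok])
    }
    rnd <- data.frame(source = src, target = tgt,
                      effect = ifelse(stats::runif(nRandom) < spec$downProb,
                                      "DOWN", "UP"),
                      score = stats::runif(nRandom, spec$scoreRange[1],
                                           spec$scoreRange[2]))
    CausalNetwork(rbind(plantedEdges, rnd), nodes = spec$genes)
  })
}

#' Generate synthetic expression, labels and a DEG table
#'
#' Log-normal counts-like data: each gene has a baseline log2 abundance;
#' planted genes share a per-sample latent factor (making them mutually
#' correlated, with heterogeneous per-gene loadings) and are shifted up by
#' around \code{spec$effectSize} standard deviations (heterogeneous per-gene
#' scales) in tumor samples, so that the planted module is informative but
#' not perfectly redundant. The DEG table is computed inside the fixture
#' by a Welch t-test on log2(count + 1) with Benjamini-Hochberg adjustment
#' (a deliberately simple stand-in differential-expression caller for
#' synthetic data), with log2 fold-change defined as the log2 ratio of mean
#' tumor over mean normal expression.
#'
#' @param spec a [fixtureSpec()].
#' @return list with \code{expr} (gene-by-sample count matrix),
#'   \code{labels} (named character, \code{"normal"}/\code{"tumor"}),
#'   \code{degs} (data.frame \code{gene}, \code{log2fc}, \code{p},
#'   \code{p_adj}) and \code{truth} (the planted genes).
#' @export
generateExpression <- function(spec) {
  withSeed(spec$seed + 1L, {
    nS <- spec$nNormal + spec$nTumor
    samples <- c(sprintf("N%03d", seq_len(spec$nNormal)),
                 sprintf("T%03d", seq_len(spec$nTumor)))
    labels <- stats::setNames(rep(c("normal", "tumor"),
                                  c(spec$nNormal, spec$nTumor)), samples)
    isTumor <- labels == "tumor"
    mu <- stats::runif(spec$nGenes, 4, 10)
    nP <- spec$nPlanted
    lf <- pmin(pmax(stats::runif(nP, spec$factorLoading - spec$loadingJitter,
                                 spec$factorLoading + spec$loadingJitter),
                    0), 0.95)
    es <- spec$effectSize * stats::runif(nP, 1 - spec$effectJitter,
                                         1 + spec$effectJitter)
    f <- stats::rnorm(nS)
    L <- matrix(stats::rnorm(spec$nGenes * nS), nrow = spec$nGenes)
    isPl <- which(spec$genes %in% spec$planted)
    for (i in seq_len(nP))
      L[isPl[i], ] <- lf[i] * f + sqrt(1 - lf[i]^2) * L[isPl[i], ]
    L[isPl, isTumor] <- L[isPl, isTumor] + es
    expr <- round(2^(mu + L))
    dimnames(expr) <- list(spec$genes, samples)
    lg <- log2(expr + 1)
    p <- apply(lg, 1, function(v)
      tryCatch(stats::t.test(v[isTumor], v[!isTumor])$p.value,
               error = function(e) 1))
    mT <- rowMeans(expr[, isTumor, drop = FALSE])
    mN <- rowMeans(expr[, !isTumor, drop = FALSE])
    degs <- data.frame(gene = spec$genes,
                       log2fc = log2((mT + 0.5) / (mN + 0.5)),
                       p = unname(p), p_adj = bhAdjust(unname(p)),
                       stringsAsFactors = FALSE)
    list(expr = expr, labels = labels, degs = degs, truth = spec$planted)
  })
}

#' Generate the synthetic drug-target table (and wire in the good drug)
#'
#' The first drug is the planted "good" drug: its targets (dedicated genes
#' outside the planted pathway) receive direct up-regulating,
#' high-confidence edges to every planted gene, and its mode of action is
#' suppressive, so its final connection score against an up-regulated
#' planted module is strongly negative. Decoy drugs draw random targets
#' (outside the planted pathway and the good targets) with random mappable
#' modes of action; one final decoy carries only the unmappable mode
#' "Modulator" and is expected to be excluded at parse time.
#'
#' @param spec a [fixtureSpec()].
#' @param net the [CausalNetwork-class] from [generateCausalNetwork()].
#' @return list with \code{drugs} (data.frame \code{drug_id},
#'   \code{drug_name}, \code{target}, \code{moa} with raw MoA strings),
#'   \code{network} (the input network augmented with the engineered
#'   drug-to-pathway edges) and \code{truth} (good drug id and targets).
#' @export
generateDrugs <- function(spec, net) {
  withSeed(spec$seed + 2L, {
    good <- data.frame(drug_id = "DRG001", drug_name = "planted-suppressor",
                       target = spec$goodTargets, moa = "Inhibitor",
                       stringsAsFactors = FALSE)
    wired <- expand.grid(source = spec$goodTargets, target = spec$planted,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    wired$effect <- "UP"
    wired$score <- spec$plantedEdgeScore
    pool <- setdiff(spec$genes, c(spec$planted, spec$goodTargets))
    decoys <- lapply(seq_len(spec$nDrugs - 1L), function(i) {
      data.frame(drug_id = sprintf("DRG%03d", i + 1L),
                 drug_name = sprintf("compound-%03d", i + 1L),
                 target = sample(pool, spec$targetsPerDrug),
                 moa = sample(c("Activator", "Inhibitor"),
                              spec$targetsPerDrug, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    unmappable <- data.frame(drug_id = "DRGBAD",
                             drug_name = "unmappable-moa-decoy",
                             target = sample(pool, spec$targetsPerDrug),
                             moa = "Modulator", stringsAsFactors = FALSE)
    drugs <- rbind(good, do.call(rbind, decoys), unmappable)
    network <- CausalNetwork(rbind(edgeTable(net), wired),
                             nodes = nodeNames(net))
    list(drugs = drugs, network = network,
         truth = list(good_drug = "DRG001", good_targets = spec$goodTargets))
  })
}

#' Write a complete synthetic fixture directory
#'
#' Generates the causal network, expression data, DEG table and drug-target
#' table and writes them in the package's parseable dialects:
#' \code{network.tsv}, \code{expression.tsv}, \code{labels.tsv},
#' \code{degs.tsv}, \code{drugs.tsv}, plus \code{truth.json} recording the
#' planted ground truth. Byte-identical across runs for a fixed spec.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with the file paths and the ground truth.
#' @export
writeFixture <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- generateCausalNetwork(spec)
  ex <- generateExpression(spec)
  dr <- generateDrugs(spec, net)
  paths <- list(
    network = file.path(dir, "network.tsv"),
    expression = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.tsv"),
    degs = file.path(dir, "degs.tsv"),
    drugs = file.path(dir, "drugs.tsv"),
    truth = file.path(dir, "truth.json"))
  writeCausalNetwork(dr$network, paths$network)
  exprOut <- data.frame(gene = rownames(ex$expr), ex$expr,
                        check.names = FALSE)
  utils::write.table(exprOut, paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = names(ex$labels),
                                condition = unname(ex$labels)),
                     paths$labels, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ex$degs, paths$degs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    stats::setNames(dr$drugs, c("DRUG_ID", "DRUG_NAME", "TARGET", "MOA")),
    paths$drugs, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(planted_genes = spec$planted,
                good_drug = dr$truth$good_drug,
                good_targets = dr$truth$good_targets,
                seed = spec$seed)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(paths = paths, truth = truth, spec = spec))
}
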