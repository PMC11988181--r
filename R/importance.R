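## Permutation-importance refinement of the knode-selected gene list.
##
## A K-nearest-neighbour classifier (k = 5, Euclidean distance on per-gene
## standardised expression) is evaluated by stratified 5-fold cross
## validation on the tumor/normal labels. The importance of a gene is the
## mean, over shuffling repeats, of (CV misclassification error with that
## gene's values shuffled) minus (baseline CV error). Genes with importance
## strictly greater than zero are retained as the disease module.
##
## All randomness (fold assignment, shuffles) is applied in a canonical
## sample order (sorted sample names), so permuting the columns of the
## expression matrix does not change the selected gene set.

# Stratified fold assignment in canonical sample order; returns integer
# folds aligned with the canonical order.
stratifiedFolds <- function(y, folds) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    m <- which(y == lv)
    fold[m] <- sample(rep_len(seq_len(folds), length(m)))
  }
  fold
}

knnCvError <- function(x, y, fold, folds, k) {
  wrong <- 0L
  for (f in seq_len(folds)) {
    te <- fold == f
    pred <- class::knn(train = x[!te, , drop = FALSE],
                       test = x[te, , drop = FALSE],
                       cl = y[!te], k = k)
    wrong <- wrong + sum(pred != y[te])
  }
  wrong / length(y)
}

#' Refine a gene list by K-NN permutation importance
#'
#' @param expr numeric gene-by-sample matrix with unique column names.
#' @param genes character vector of candidate genes (rows of \code{expr}).
#' @param labels condition per sample: factor or character with exactly two
#'   levels, named by sample or aligned with \code{colnames(expr)}.
#' @param degs optional data.frame with \code{gene}, \code{log2fc}; when
#'   given, the returned module members carry their fold-changes.
#' @param folds number of CV folds (default 5); each class must have at
#'   least \code{folds} samples.
#' @param repeats shuffling repeats per gene (default 10).
#' @param k neighbours for the K-NN classifier (default 5).
#' @param seed integer seed governing fold assignment and all shuffles.
#' @param diseaseIdent identifier stamped on the returned module.
#' @return list with \code{importance} (data.frame \code{gene},
#'   \code{importance}), \code{baseline_error}, \code{seed}, and
#'   \code{module} (a [DiseaseModule-class] of the genes with importance
#'   greater than zero). Zero surviving genes is an error with a diagnostic.
#' @export
refineByImportance <- function(expr, genes, labels, degs = NULL,
                               folds = 5L, repeats = 10L, k = 5L,
                               seed = 1L, diseaseIdent = "disease") {
  stopifnot(all(genes %in% rownames(expr)))
  samp <- colnames(expr)
  if (is.null(samp) || anyDuplicated(samp))
    stop("expression matrix must have unique column names")
  if (!is.null(names(labels))) labels <- labels[samp]
  y0 <- factor(as.character(labels))
  if (nlevels(y0) != 2) stop("labels must have exactly two classes")
  if (any(table(y0) < folds))
    stop("each class needs at least ", folds, " samples")
  co <- order(samp)  # canonical order: invariant to column permutation
  x <- t(expr[genes, co, drop = FALSE])
  y <- y0[co]
  x <- scale(x)
  x[!is.finite(x)] <- 0  # constant genes carry no information
  nS <- nrow(x)
  res <- withSeed(seed, {
    fold <- stratifiedFolds(y, folds)
    base <- knnCvError(x, y, fold, folds, k)
    imp <- matrix(NA_real_, nrow = length(genes), ncol = repeats)
    for (gi in seq_along(genes)) {
      for (rp in seq_len(repeats)) {
        xi <- x
        xi[, gi] <- x[sample.int(nS), gi]
        imp[gi, rp] <- knnCvError(xi, y, fold, folds, k) - base
      }
    }
    list(base = base, imp = rowMeans(imp))
  })
  importance <- data.frame(gene = genes, importance = res$imp,
                           stringsAsFactors = FALSE)
  keep <- importance$gene[importance$importance > 0]
  if (!length(keep))
    stop("no gene has importance > 0 (baseline CV error ",
         format(res$base, digits = 3),
         "); the candidate genes do not separate the classes")
  fc <- if (!is.null(degs)) degs$log2fc[match(keep, degs$gene)] else rep(NA_real_, length(keep))
  module <- DiseaseModule(diseaseIdent,
                          data.frame(gene = keep, log2fc = fc,
                                     stringsAsFactors = FALSE))
  list(importance = importance, baseline_error = res$base, seed = seed,
       module = module)
}

#' Build a disease module from expression data and a DEG table
#'
#' End-to-end module construction: correlation network over the DEGs
#' restricted to the causal network ([buildCorrelationNetwork()]), node
#' weights and edge distances, knode ranking ([knodeScores()]), top-k cut
#' ([selectTopK()]), and permutation-importance refinement
#' ([refineByImportance()]).
#'
#' @param expr numeric gene-by-sample matrix.
#' @param labels two-level condition per sample (named by sample or aligned
#'   with columns).
#' @param degs data.frame with \code{gene}, \code{log2fc}, \code{p_adj}
#'   (already thresholded, or pass \code{alphaDeg} to threshold here).
#' @param causal a [CausalNetwork-class].
#' @param diseaseIdent disease identifier for the module.
#' @param alphaDeg adjusted-p threshold applied to \code{degs} (default
#'   0.05; set \code{NULL} to use the table as given).
#' @param alphaCor threshold on adjusted correlation p-values (default 0.05).
#' @param c stabilising constant for edge distances.
#' @param kRule,k module-size rule / explicit override, see [selectTopK()].
#' @param folds,repeats,knnK,seed see [refineByImportance()].
#' @param verbose log stage counts to stderr.
#' @return list with \code{module} (a [DiseaseModule-class] whose members
#'   carry \code{log2fc}, \code{knode} and \code{importance}),
#'   \code{network} (the weighted [CorrelationNetwork-class]),
#'   \code{knode} (full ranking), \code{selected} (top-k genes) and
#'   \code{importance}.
#' @export
buildDiseaseModule <- function(expr, labels, degs, causal,
                               diseaseIdent = "disease",
                               alphaDeg = 0.05, alphaCor = 0.05, c = 1e-16,
                               kRule = defaultKRule, k = NULL,
                               folds = 5L, repeats = 10L, knnK = 5L,
                               seed = 1L, verbose = TRUE) {
  if (!is.null(alphaDeg) && !is.null(degs$p_adj))
    degs <- degs[degs$p_adj < alphaDeg, , drop = FALSE]
  if (!nrow(degs)) stop("no DEGs pass the adjusted-p threshold")
  net <- buildCorrelationNetwork(expr, degs, causal, alpha = alphaCor,
                                 verbose = verbose)
  if (numNodes(net) < 2) stop("fewer than 2 DEGs present in the network")
  net <- computeNodeWeights(net, degs)
  net <- computeEdgeDistances(net, c = c)
  kn <- knodeScores(net)
  sel <- selectTopK(kn, degs, nSamples = ncol(expr), kRule = kRule, k = k)
  if (verbose)
    logMsg("disease_module", sprintf("knode_ranked=%d selected=%d",
                                     nrow(kn), length(sel)))
  ref <- refineByImportance(expr, sel, labels, degs = degs, folds = folds,
                            repeats = repeats, k = knnK, seed = seed,
                            diseaseIdent = diseaseIdent)
  mem <- moduleTable(ref$module)
  mem$knode <- kn$knode[match(mem$gene, kn$gene)]
  mem$importance <- ref$importance$importance[match(mem$gene,
                                                    ref$importance$gene)]
  module <- new("DiseaseModule", diseaseId = diseaseIdent, members = mem)
  if (verbose)
    logMsg("disease_module", sprintf("importance>0: %d of %d genes kept",
                                     nrow(mem), length(sel)))
  list(module = module, network = net, knode = kn, selected = sel,
       importance = ref$importance)
}
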