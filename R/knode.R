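## knode ranking: nodes close to many heavy nodes score highest.
##
## For node i, K_i(s) = (2 / (n * pbar)) * sum_j (p_j - pbar) * I(dg(i,j) <= s),
## where p_j is the normalised node weight, pbar the mean weight, and dg the
## weighted shortest-path distance in the disease network using the
## correlation-derived edge distances. The knode score of i is the area under
## the step function K_i over [0, s_max]. The j-sum includes j = i (the
## indicator at distance 0 is always true). Because sum_j (p_j - pbar) = 0,
## K_i starts and ends at 0; we evaluate n and pbar within each connected
## component so that this endpoint identity holds on any input (it coincides
## with the whole-network evaluation whenever the network is connected,
## since unreachable pairs are never counted).

#' Compute knode scores for a weighted disease network
#'
#' @param net a [CorrelationNetwork-class] with node weights
#'   ([computeNodeWeights()]) and edge distances ([computeEdgeDistances()])
#'   already assigned.
#' @return data.frame with columns \code{gene}, \code{knode}, ordered by
#'   decreasing score.
#' @details Scores are areas under the distance-indexed weighted
#'   neighbourhood curve: a node surrounded (at small distances) by many
#'   genes of above-average weight accumulates positive area. Components in
#'   which every weight equals the component mean (in particular all-zero
#'   components) contribute all-zero scores; if the mean weight over the
#'   whole network is zero the call is an error, since the score prefactor
#'   is undefined.
#' @export
knodeScores <- function(net) {
  nodes <- nodeNames(net)
  w <- nodeWeights(net)
  if (!length(w)) stop("node weights not set; call computeNodeWeights() first")
  e <- edgeTable(net)
  if (is.null(e$dist))
    stop("edge distances not set; call computeEdgeDistances() first")
  w <- w[nodes]
  if (mean(w) == 0)
    stop("mean node weight is zero (all weights zero): knode undefined")
  g <- igraph::graph_from_data_frame(
    if (nrow(e)) e[, c("a", "b")] else data.frame(a = character(), b = character()),
    directed = FALSE, vertices = data.frame(name = nodes))
  D <- igraph::distances(g, weights = if (nrow(e)) e$dist else NULL)
  D <- D[nodes, nodes, drop = FALSE]
  finiteD <- D[is.finite(D)]
  sMax <- if (length(finiteD)) max(finiteD) else 0
  memb <- igraph::components(g)$membership[nodes]
  score <- numeric(length(nodes))
  names(score) <- nodes
  for (cm in unique(memb)) {
    m <- which(memb == cm)
    nC <- length(m)
    pbar <- mean(w[m])
    if (pbar == 0 || nC == 1) {
      score[m] <- 0
      next
    }
    pref <- 2 / (nC * pbar)
    for (i in m) {
      d <- D[i, m]
      ord <- order(d)
      dd <- d[ord]
      cw <- cumsum(w[m][ord] - pbar)
      # step integral over [0, s_max]; ties give zero-width intervals, and
      # the final plateau has height cw[nC] = 0 so its width is irrelevant
      widths <- c(diff(dd), sMax - dd[nC])
      score[i] <- pref * sum(cw * widths)
    }
  }
  out <- data.frame(gene = nodes, knode = unname(score),
                    stringsAsFactors = FALSE)
  out[order(-out$knode, out$gene), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Evaluate the knode neighbourhood function of one node at given distances
#'
#' Mainly a diagnostic/testing surface: returns K_i(s) at the supplied
#' distance thresholds, using the same component-local n and mean weight as
#' [knodeScores()].
#'
#' @param net a weighted [CorrelationNetwork-class] (weights and distances
#'   set).
#' @param gene the node.
#' @param s numeric vector of distance thresholds.
#' @return numeric vector of K values, same length as \code{s}.
#' @export
knodeCurve <- function(net, gene, s) {
  nodes <- nodeNames(net)
  stopifnot(gene %in% nodes)
  w <- nodeWeights(net)[nodes]
  e <- edgeTable(net)
  g <- igraph::graph_from_data_frame(
    if (nrow(e)) e[, c("a", "b")] else data.frame(a = character(), b = character()),
    directed = FALSE, vertices = data.frame(name = nodes))
  memb <- igraph::components(g)$membership[nodes]
  m <- which(memb == memb[[gene]])
  d <- igraph::distances(g, v = gene, weights = if (nrow(e)) e$dist else NULL)[1, nodes][m]
  nC <- length(m)
  pbar <- mean(w[m])
  if (pbar == 0) return(rep(0, length(s)))
  vapply(s, function(si) {
    2 / (nC * pbar) * sum((w[m] - pbar)[d <= si])
  }, numeric(1))
}

#' Default rule mapping sample count to module size k
#'
#' The top-k cut after knode ranking uses k in {25, 50, 100} depending on how
#' many samples support the disease: fewer than 300 samples gives 25, 300 to
#' 700 gives 50, and more than 700 gives 100. The mapping is overridable
#' wherever a \code{kRule} argument is accepted.
#'
#' @param nSamples total number of samples (both conditions).
#' @return k, one of 25, 50, 100.
#' @export
defaultKRule <- function(nSamples) {
  if (nSamples < 300) 25L else if (nSamples <= 700) 50L else 100L
}

#' Select the top-k genes by knode score
#'
#' Ties are broken by descending absolute log2 fold-change, then
#' lexicographically by gene symbol, so the selection is fully deterministic.
#' When fewer than k genes are available all are returned with a warning.
#'
#' @param scores data.frame from [knodeScores()] (columns \code{gene},
#'   \code{knode}).
#' @param degs data.frame with columns \code{gene}, \code{log2fc}.
#' @param nSamples sample count fed to the k rule.
#' @param kRule function mapping sample count to k; default [defaultKRule()].
#' @param k optional explicit k overriding the rule.
#' @return character vector of the selected gene symbols, in rank order.
#' @export
selectTopK <- function(scores, degs, nSamples = NULL,
                       kRule = defaultKRule, k = NULL) {
  if (is.null(k)) {
    if (is.null(nSamples)) stop("either k or nSamples must be given")
    k <- kRule(nSamples)
  }
  fc <- degs$log2fc[match(scores$gene, degs$gene)]
  fc[is.na(fc)] <- 0
  ord <- order(-scores$knode, -abs(fc), scores$gene)
  ranked <- scores$gene[ord]
  if (k > length(ranked)) {
    warning("only ", length(ranked), " genes available; k = ", k,
            " clipped to all")
    k <- length(ranked)
  }
  ranked[seq_len(k)]
}
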