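## Disease-specific co-expression network: Pearson correlations among DEGs,
## BH-filtered, intersected with the causal network's adjacency.

#' Build the disease-specific correlation network
#'
#' Computes Pearson correlations (with p-values from the t distribution) for
#' every pair of differentially expressed genes that are present both in the
#' expression matrix and in the causal network, adjusts the p-values with
#' Benjamini-Hochberg across all tested pairs of this disease, and keeps the
#' pairs that are significant at \code{alpha} AND adjacent (in either
#' direction, any effect) in the causal network.
#'
#' @param expr numeric gene-by-sample matrix (rownames are gene symbols).
#' @param degs data.frame of DEGs with columns \code{gene}, \code{log2fc}
#'   (restriction to genes present in \code{expr} and \code{causal} happens
#'   here and is logged).
#' @param causal a [CausalNetwork-class].
#' @param alpha significance threshold on the adjusted correlation p-values
#'   (default 0.05).
#' @param verbose log gene/edge counts to stderr.
#' @return A [CorrelationNetwork-class] whose nodes are the retained DEGs
#'   (zero-variance genes keep their node but contribute no edges, with a
#'   warning).
#' @export
buildCorrelationNetwork <- function(expr, degs, causal, alpha = 0.05,
                                    verbose = TRUE) {
  if (ncol(expr) < 3) stop("at least 3 samples are required")
  genes <- intersect(intersect(unique(degs$gene), rownames(expr)),
                     nodeNames(causal))
  if (verbose)
    logMsg("correlation_network",
           sprintf("degs=%d in_expr_and_network=%d dropped=%d",
                   length(unique(degs$gene)), length(genes),
                   length(unique(degs$gene)) - length(genes)))
  if (length(genes) < 2)
    return(new("CorrelationNetwork", nodes = genes))
  x <- t(expr[genes, , drop = FALSE])
  nS <- nrow(x)
  v <- apply(x, 2, stats::var)
  zeroVar <- !is.finite(v) | v == 0
  if (any(zeroVar))
    warning(sum(zeroVar), " zero-variance gene(s): their pairs are dropped")
  r <- suppressWarnings(stats::cor(x))
  ut <- upper.tri(r)
  ai <- row(r)[ut]
  bi <- col(r)[ut]
  rv <- r[ut]
  ok <- !zeroVar[ai] & !zeroVar[bi] & is.finite(rv)
  ai <- ai[ok]; bi <- bi[ok]; rv <- pmin(1, pmax(-1, rv[ok]))
  tstat <- rv * sqrt((nS - 2) / pmax(1 - rv^2, .Machine$double.eps))
  tstat[abs(rv) >= 1] <- sign(rv[abs(rv) >= 1]) * Inf
  p <- 2 * stats::pt(-abs(tstat), df = nS - 2)
  padj <- bhAdjust(p)
  # causal adjacency in either direction
  e <- edgeTable(causal)
  inSet <- e$source %in% genes & e$target %in% genes
  gi <- seq_along(genes); names(gi) <- genes
  ng <- length(genes)
  ekey <- unique(c(
    (pmin(gi[e$source[inSet]], gi[e$target[inSet]]) - 1) * ng +
      pmax(gi[e$source[inSet]], gi[e$target[inSet]])))
  pkey <- (pmin(ai, bi) - 1) * ng + pmax(ai, bi)
  keep <- padj < alpha & pkey %in% ekey
  edges <- data.frame(a = genes[ai[keep]], b = genes[bi[keep]],
                      r = rv[keep], p = p[keep], p_adj = padj[keep],
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  if (verbose)
    logMsg("correlation_network",
           sprintf("tested_pairs=%d significant_and_adjacent=%d",
                   length(p), nrow(edges)))
  new("CorrelationNetwork", nodes = genes, edges = edges)
}

#' Assign normalised node weights (fold-change times degree)
#'
#' The raw weight of a gene is its log2 fold-change multiplied by its degree
#' in the correlation network (an isolated gene therefore has raw weight 0
#' regardless of fold-change). Raw weights are then min-max normalised to
#' [0, 1]. When all raw weights are equal the normalisation denominator is
#' zero; all weights are set to 0 with a warning.
#'
#' @param net a [CorrelationNetwork-class].
#' @param degs data.frame with columns \code{gene}, \code{log2fc} covering
#'   every node of \code{net}.
#' @return \code{net} with the \code{weights} slot filled (named numeric in
#'   [0, 1]).
#' @export
computeNodeWeights <- function(net, degs) {
  nodes <- nodeNames(net)
  fc <- degs$log2fc[match(nodes, degs$gene)]
  if (any(is.na(fc)))
    stop("log2fc missing for node(s): ",
         paste(utils::head(nodes[is.na(fc)], 5), collapse = ", "))
  e <- edgeTable(net)
  deg <- table(factor(c(e$a, e$b), levels = nodes))
  raw <- fc * as.numeric(deg)
  rng <- range(raw)
  if (diff(rng) == 0) {
    warning("all raw node weights equal; normalised weights set to 0")
    w <- rep(0, length(nodes))
  } else {
    w <- (raw - rng[1]) / diff(rng)
  }
  names(w) <- nodes
  net@weights <- w
  validObject(net)
  net
}

#' Assign edge distances from correlation strength
#'
#' Each edge's distance is \code{-log10(|r| + c)} with a small stabilising
#' constant \code{c}, floored at 0 (at |r| = 1 the raw value is a tiny
#' negative number; distances must be nonnegative for shortest-path
#' computations). Strongly correlated genes are thus close.
#'
#' @param net a [CorrelationNetwork-class].
#' @param c stabilising constant (default 1e-16), bounding the distance of an
#'   |r| = 0 edge at 16.
#' @return \code{net} with a \code{dist} column added to its edge table.
#' @export
computeEdgeDistances <- function(net, c = 1e-16) {
  e <- edgeTable(net)
  e$dist <- pmax(0, -log10(abs(e$r) + c))
  net@edges <- e
  net
}
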