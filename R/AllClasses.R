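#' @import methods
NULL

#' CausalNetwork: a directed, signed, confidence-scored interaction network
#'
#' Container for a SIGNOR-style causal network: a directed multigraph whose
#' edges carry a binary effect (\code{"UP"} for up-regulation, \code{"DOWN"}
#' for down-regulation) and a confidence score in (0, 1]. Parallel edges
#' between the same ordered node pair (e.g. the same relation annotated with
#' different effects) are retained as distinct edges; self-loops are not
#' admitted because they can never lie on a shortest path between distinct
#' genes.
#'
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{effect} (\code{"UP"}/\code{"DOWN"}) and \code{score} in (0, 1].
#' @slot nodes character vector of node identifiers (gene symbols, treated as
#'   opaque case-sensitive strings); a superset of the edge endpoints.
#' @slot parseLog list of bookkeeping counts recorded at parse time.
#'
#' @seealso [parseCausalNetwork()], [defaultAggregateScore()]
#' @export
setClass("CausalNetwork",
  representation(edges = "data.frame", nodes = "character", parseLog = "list"),
  prototype(
    edges = data.frame(source = character(), target = character(),
                       effect = character(), score = numeric()),
    nodes = character(), parseLog = list())
)

setValidity("CausalNetwork", function(object) {
  e <- object@edges
  msg <- character()
  need <- c("source", "target", "effect", "score")
  if (!all(need %in% names(e)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (!all(e$effect %in% c("UP", "DOWN")))
      msg <- c(msg, "edge effects must be 'UP' or 'DOWN'")
    if (!is.numeric(e$score) || any(is.na(e$score)) ||
        any(e$score <= 0 | e$score > 1))
      msg <- c(msg, "edge scores must be numeric in (0, 1]")
    if (any(e$source == e$target))
      msg <- c(msg, "self-loops are not allowed")
    if (!all(c(e$source, e$target) %in% object@nodes))
      msg <- c(msg, "every edge endpoint must be a node")
  }
  if (anyDuplicated(object@nodes))
    msg <- c(msg, "node names must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a CausalNetwork from an edge table
#'
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{effect}, \code{score}.
#' @param nodes optional character vector of nodes; defaults to the union of
#'   edge endpoints. Isolated nodes may be supplied explicitly.
#' @param parseLog optional list of parse-time counts.
#' @return A [CausalNetwork-class] object.
#' @examples
#' net <- CausalNetwork(data.frame(
#'   source = c("A", "B"), target = c("B", "C"),
#'   effect = c("UP", "DOWN"), score = c(0.9, 0.5)))
#' numEdges(net)
#' @export
CausalNetwork <- function(edges, nodes = NULL, parseLog = list()) {
  edges <- as.data.frame(edges)
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$effect <- as.character(edges$effect)
  edges$score <- as.numeric(edges$score)
  rownames(edges) <- NULL
  if (is.null(nodes))
    nodes <- sort(unique(c(edges$source, edges$target)))
  new("CausalNetwork", edges = edges[, c("source", "target", "effect", "score")],
      nodes = as.character(nodes), parseLog = parseLog)
}

#' DrugSet: drugs with their targets and binary modes of action
#'
#' One row per (drug, target gene, mode of action) entry. The mode of action
#' is binarised to \code{"UP"} (the drug up-regulates its target) or
#' \code{"DOWN"} (it down-regulates it); entries whose textual mode of action
#' cannot be mapped onto this dichotomy are discarded at parse time, and drugs
#' left with no mapped target are excluded. A drug may list the same target
#' twice with opposite modes of action; both entries are kept and each
#' contributes its own sign-adjusted pair score downstream.
#'
#' @slot table data.frame with columns \code{drug_id}, \code{drug_name},
#'   \code{target}, \code{moa} (\code{"UP"}/\code{"DOWN"}).
#' @slot parseLog list of parse-time counts (dropped entries, excluded drugs).
#' @seealso [parseDrugTargets()]
#' @export
setClass("DrugSet",
  representation(table = "data.frame", parseLog = "list"),
  prototype(table = data.frame(drug_id = character(), drug_name = character(),
                               target = character(), moa = character()),
            parseLog = list())
)

setValidity("DrugSet", function(object) {
  t <- object@table
  need <- c("drug_id", "drug_name", "target", "moa")
  if (!all(need %in% names(t)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (nrow(t) && !all(t$moa %in% c("UP", "DOWN")))
    return("moa must be 'UP' or 'DOWN'")
  TRUE
})

#' @rdname DrugSet-class
#' @param table data.frame with columns \code{drug_id}, \code{drug_name},
#'   \code{target}, \code{moa}.
#' @param parseLog optional list of parse-time counts.
#' @export
DrugSet <- function(table, parseLog = list()) {
  table <- as.data.frame(table)
  rownames(table) <- NULL
  for (cl in c("drug_id", "drug_name", "target", "moa"))
    table[[cl]] <- as.character(table[[cl]])
  new("DrugSet", table = table[, c("drug_id", "drug_name", "target", "moa")],
      parseLog = parseLog)
}

#' CorrelationNetwork: a disease-specific co-expression network
#'
#' Undirected network over differentially expressed genes. Edges are gene
#' pairs whose Pearson correlation is significant after Benjamini-Hochberg
#' adjustment and whose node pair is also connected (in either direction) in
#' the causal network. Node weights (fold-change times degree, min-max
#' normalised) and edge distances (a decreasing function of |r|) are attached
#' by [computeNodeWeights()] and [computeEdgeDistances()].
#'
#' @slot nodes character vector of gene symbols.
#' @slot edges data.frame with columns \code{a}, \code{b}, \code{r},
#'   \code{p}, \code{p_adj} and, once computed, \code{dist}.
#' @slot weights named numeric vector of normalised node weights in [0, 1]
#'   (empty until [computeNodeWeights()] is called).
#' @export
setClass("CorrelationNetwork",
  representation(nodes = "character", edges = "data.frame",
                 weights = "numeric"),
  prototype(nodes = character(),
            edges = data.frame(a = character(), b = character(), r = numeric(),
                               p = numeric(), p_adj = numeric()),
            weights = numeric())
)

setValidity("CorrelationNetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("a", "b", "r", "p", "p_adj") %in% names(e)))
    return("edges must have columns a, b, r, p, p_adj")
  if (nrow(e)) {
    if (!all(c(e$a, e$b) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
    if (any(abs(e$r) > 1 + 1e-12))
      msg <- c(msg, "correlations must lie in [-1, 1]")
  }
  if (length(object@weights) && !all(names(object@weights) %in% object@nodes))
    msg <- c(msg, "weights must be named by nodes")
  if (length(msg)) msg else TRUE
})

#' DiseaseModule: the refined disease gene set
#'
#' The genes selected to represent a disease, each carrying its log2
#' fold-change (tumor over normal) and, when produced by the full selection
#' procedure, its knode score and permutation importance.
#'
#' @slot diseaseId single disease identifier.
#' @slot members data.frame with columns \code{gene}, \code{log2fc} and
#'   optionally \code{knode}, \code{importance}.
#' @export
setClass("DiseaseModule",
  representation(diseaseId = "character", members = "data.frame"),
  prototype(diseaseId = NA_character_,
            members = data.frame(gene = character(), log2fc = numeric()))
)

setValidity("DiseaseModule", function(object) {
  m <- object@members
  if (!all(c("gene", "log2fc") %in% names(m)))
    return("members must have columns gene, log2fc")
  if (anyDuplicated(m$gene))
    return("duplicate genes in module")
  if (length(object@diseaseId) != 1L)
    return("diseaseId must be a single string")
  TRUE
})

#' @rdname DiseaseModule-class
#' @param diseaseId single disease identifier.
#' @param members data.frame with columns \code{gene}, \code{log2fc}.
#' @export
DiseaseModule <- function(diseaseId, members) {
  members <- as.data.frame(members)
  rownames(members) <- NULL
  members$gene <- as.character(members$gene)
  members$log2fc <- as.numeric(members$log2fc)
  new("DiseaseModule", diseaseId = as.character(diseaseId), members = members)
}

#' NullDistribution: size-matched random-module null for connection scores
#'
#' Empirical distribution of final connection scores between randomly composed
#' pseudo-drug modules (targets drawn from the drug-target pool) and
#' pseudo-disease modules (genes drawn, with their fold-change signs, from the
#' disease-gene pool) of fixed sizes. Its mean and standard deviation are used
#' to z-score-normalise observed connection scores of the same size
#' combination.
#'
#' @slot drugSize number of targets in each pseudo-drug.
#' @slot diseaseSize number of genes in each pseudo-module.
#' @slot nDraws number of random module pairs drawn.
#' @slot mean,sd moments of the drawn final scores.
#' @slot seed integer seed that generated the draws.
#' @slot scores the drawn final connection scores (length \code{nDraws}).
#' @seealso [buildNull()], [assessAssociations()]
#' @export
setClass("NullDistribution",
  representation(drugSize = "integer", diseaseSize = "integer",
                 nDraws = "integer", mean = "numeric", sd = "numeric",
                 seed = "integer", scores = "numeric")
)

setValidity("NullDistribution", function(object) {
  if (length(object@scores) != object@nDraws)
    return("scores must hold exactly nDraws values")
  if (object@sd < 0) return("sd must be nonnegative")
  TRUE
})

## ---- accessors ----

#' Accessors for causalDR classes
#'
#' \code{nodeNames} returns the node identifiers of a network;
#' \code{edgeTable} its edge data.frame; \code{numNodes}/\code{numEdges} the
#' corresponding counts. \code{drugIds} lists the drug identifiers in a
#' [DrugSet-class]; \code{drugTargets} returns the (target, moa) entries of
#' one drug. \code{moduleGenes} and \code{moduleTable} access a
#' [DiseaseModule-class].
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))
#' @rdname accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))
#' @rdname accessors
#' @export
setGeneric("nodeWeights", function(x) standardGeneric("nodeWeights"))

#' @rdname accessors
#' @export
setMethod("nodeNames", "CausalNetwork", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("edgeTable", "CausalNetwork", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("numNodes", "CausalNetwork", function(x) length(x@nodes))
#' @rdname accessors
#' @export
setMethod("numEdges", "CausalNetwork", function(x) nrow(x@edges))

#' @rdname accessors
#' @export
setMethod("nodeNames", "CorrelationNetwork", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("edgeTable", "CorrelationNetwork", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("numNodes", "CorrelationNetwork", function(x) length(x@nodes))
#' @rdname accessors
#' @export
setMethod("numEdges", "CorrelationNetwork", function(x) nrow(x@edges))
#' @rdname accessors
#' @export
setMethod("nodeWeights", "CorrelationNetwork", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))
#' @rdname accessors
#' @export
setMethod("drugIds", "DrugSet", function(x) unique(x@table$drug_id))

#' @rdname accessors
#' @param id a single drug identifier.
#' @export
setGeneric("drugTargets", function(x, id) standardGeneric("drugTargets"))
#' @rdname accessors
#' @export
setMethod("drugTargets", "DrugSet", function(x, id) {
  t <- x@table[x@table$drug_id == id, c("target", "moa"), drop = FALSE]
  rownames(t) <- NULL
  t
})

#' @rdname accessors
#' @export
setGeneric("drugTable", function(x) standardGeneric("drugTable"))
#' @rdname accessors
#' @export
setMethod("drugTable", "DrugSet", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("moduleGenes", function(x) standardGeneric("moduleGenes"))
#' @rdname accessors
#' @export
setMethod("moduleGenes", "DiseaseModule", function(x) x@members$gene)

#' @rdname accessors
#' @export
setGeneric("moduleTable", function(x) standardGeneric("moduleTable"))
#' @rdname accessors
#' @export
setMethod("moduleTable", "DiseaseModule", function(x) x@members)

#' @rdname accessors
#' @export
setGeneric("diseaseId", function(x) standardGeneric("diseaseId"))
#' @rdname accessors
#' @export
setMethod("diseaseId", "DiseaseModule", function(x) x@diseaseId)

#' @rdname accessors
#' @export
setGeneric("parseLog", function(x) standardGeneric("parseLog"))
#' @rdname accessors
#' @export
setMethod("parseLog", "CausalNetwork", function(x) x@parseLog)
#' @rdname accessors
#' @export
setMethod("parseLog", "DrugSet", function(x) x@parseLog)

## ---- show methods ----

setMethod("show", "CausalNetwork", function(object) {
  cat("CausalNetwork:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
  if (nrow(object@edges)) {
    eff <- table(object@edges$effect)
    cat("  effects:", paste(names(eff), eff, sep = "=", collapse = ", "), "\n")
    cat("  score range: [", format(min(object@edges$score), digits = 3), ", ",
        format(max(object@edges$score), digits = 3), "]\n", sep = "")
  }
})

setMethod("show", "DrugSet", function(object) {
  cat("DrugSet:", length(unique(object@table$drug_id)), "drugs,",
      nrow(object@table), "target entries\n")
})

setMethod("show", "CorrelationNetwork", function(object) {
  cat("CorrelationNetwork:", length(object@nodes), "genes,",
      nrow(object@edges), "correlation edges\n")
  if (length(object@weights))
    cat("  node weights set (range [",
        format(min(object@weights), digits = 3), ", ",
        format(max(object@weights), digits = 3), "])\n", sep = "")
  if (!is.null(object@edges$dist))
    cat("  edge distances set\n")
})

setMethod("show", "DiseaseModule", function(object) {
  cat("DiseaseModule '", object@diseaseId, "': ",
      nrow(object@members), " genes\n", sep = "")
  up <- sum(object@members$log2fc >= 0)
  cat("  ", up, " up-regulated, ", nrow(object@members) - up,
      " down-regulated\n", sep = "")
})

setMethod("show", "NullDistribution", function(object) {
  cat("NullDistribution (drug size ", object@drugSize, " x disease size ",
      object@diseaseSize, "): ", object@nDraws, " draws, mean = ",
      format(object@mean, digits = 4), ", sd = ",
      format(object@sd, digits = 4), "\n", sep = "")
})
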