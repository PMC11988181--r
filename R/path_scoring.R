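## Signed shortest-path connection scoring over the causal network.
##
## A path's connection score is start_value * prod(edge confidence scores),
## with the sign flipping at every down-regulating edge. The default
## aggregate connection score between two genes is the sum of the scores of
## ALL minimal-hop-count directed paths between them (0 when unreachable).
## Because every minimal-hop walk is a simple path, the aggregate over all
## shortest paths factorises over the BFS shortest-path DAG, so it is
## computed exactly by dynamic programming, one BFS per source node, without
## enumerating paths.

# Compile a CausalNetwork into indexed adjacency structures.
# Parallel edges between the same ordered pair are collapsed for the DP into
# a signed score sum and a count, but original edge rows are kept per pair
# for explicit enumeration.
compileNetwork <- function(net) {
  nodes <- nodeNames(net)
  n <- length(nodes)
  idx <- seq_len(n)
  names(idx) <- nodes
  e <- edgeTable(net)
  if (nrow(e)) {
    si <- idx[e$source]
    ti <- idx[e$target]
    sgn <- ifelse(e$effect == "DOWN", -1, 1)
    key <- (si - 1) * n + ti
    agg <- rowsum(cbind(w = sgn * e$score, cnt = 1), group = key)
    ukey <- as.numeric(rownames(agg))
    u <- (ukey - 1) %/% n + 1
    v <- (ukey - 1) %% n + 1
    byU <- split(seq_along(u), u)
    edgeRowsByKey <- split(seq_len(nrow(e)), key)
  } else {
    u <- integer(0); v <- integer(0)
    agg <- cbind(w = numeric(0), cnt = numeric(0))
    byU <- list()
    edgeRowsByKey <- list()
  }
  outTo <- vector("list", n)
  outW <- vector("list", n)
  outN <- vector("list", n)
  for (nm in names(byU)) {
    i <- as.integer(nm)
    rows <- byU[[nm]]
    outTo[[i]] <- v[rows]
    outW[[i]] <- agg[rows, "w"]
    outN[[i]] <- agg[rows, "cnt"]
  }
  list(n = n, nodes = nodes, idx = idx, edges = e,
       outTo = outTo, outW = outW, outN = outN,
       edgeRowsByKey = edgeRowsByKey)
}

# One BFS + DP pass from a source node index. Returns hop distances, the
# signed path-product sums A (aggregate / start_value) and path counts P to
# every node. A[source] = 1, P[source] = 1 (the empty path).
signedReach <- function(comp, s) {
  n <- comp$n
  dist <- rep(NA_integer_, n)
  A <- numeric(n)
  P <- numeric(n)
  dist[s] <- 0L
  A[s] <- 1
  P[s] <- 1
  frontier <- s
  d <- 0L
  while (length(frontier)) {
    d1 <- d + 1L
    nxt <- integer(0)
    for (u in frontier) {
      vs <- comp$outTo[[u]]
      if (!length(vs)) next
      new <- is.na(dist[vs])
      if (any(new)) {
        dist[vs[new]] <- d1
        nxt <- c(nxt, vs[new])
      }
      ok <- dist[vs] == d1
      if (any(ok)) {
        tv <- vs[ok]
        A[tv] <- A[tv] + A[u] * comp$outW[[u]][ok]
        P[tv] <- P[tv] + P[u] * comp$outN[[u]][ok]
      }
    }
    frontier <- nxt
    d <- d1
  }
  list(dist = dist, A = A, P = P)
}

#' Pair-score cache over a causal network
#'
#' Builds a memoising cache of signed shortest-path aggregates: the first
#' query from a given source gene triggers one breadth-first pass computing
#' the aggregate connection score from that source to every node; later
#' queries (including every null draw) reuse it. Sharing one cache between
#' the observed associations and the permutation null is what makes the
#' 1000-draw null affordable.
#'
#' @param net a [CausalNetwork-class].
#' @param startValue the arbitrary positive start value seeded at the source
#'   node (default 10000). All downstream z-scores and p-values are invariant
#'   to it.
#' @param maxPaths pairs whose shortest-path count exceeds this are flagged
#'   as truncated in outputs (the aggregate itself is still exact).
#' @return An opaque cache object for [defaultAggregateScore()],
#'   [finalConnectionScore()] and [buildNull()].
#' @export
pairScoreCache <- function(net, startValue = 10000, maxPaths = 1e5) {
  env <- new.env(parent = emptyenv())
  env$comp <- compileNetwork(net)
  env$startValue <- startValue
  env$maxPaths <- maxPaths
  env$memo <- new.env(parent = emptyenv())
  class(env) <- "pairScoreCache"
  env
}

# Fetch (computing if needed) the reach record for one source gene symbol.
cacheReach <- function(cache, source) {
  key <- source
  r <- cache$memo[[key]]
  if (is.null(r)) {
    s <- cache$comp$idx[[source]]
    r <- signedReach(cache$comp, s)
    cache$memo[[key]] <- r
  }
  r
}

#' Score a single path
#'
#' The connection score of a directed path is the start value multiplied by
#' the confidence scores of its edges, with the sign flipped once per
#' down-regulating edge. The empty path (source equals target) scores
#' \code{+startValue}: a drug acting directly on a disease gene is the
#' strongest possible connection.
#'
#' @param path a list with an \code{edges} data.frame (columns \code{effect},
#'   \code{score}; zero rows for the empty path), or such a data.frame
#'   directly.
#' @param startValue start value (default 10000).
#' @return The signed connection score.
#' @examples
#' scorePath(data.frame(effect = c("UP", "DOWN"), score = c(0.5, 0.7)))
#' @export
scorePath <- function(path, startValue = 10000) {
  e <- if (is.data.frame(path)) path else path$edges
  if (is.null(e) || !nrow(e)) return(startValue)
  startValue * prod(e$score) * (-1)^sum(e$effect == "DOWN")
}

#' Enumerate all shortest paths between two genes
#'
#' Returns every directed path of minimal hop count from \code{source} to
#' \code{target}. Paths that traverse distinct parallel edges between the
#' same node pair count as distinct paths. When the number of shortest paths
#' exceeds \code{maxPaths} only the first \code{maxPaths} (in deterministic
#' enumeration order) are returned, with a loud warning and a
#' \code{truncated} attribute.
#'
#' @param net a [CausalNetwork-class].
#' @param source,target gene symbols present in the network.
#' @param maxPaths enumeration cap (default 1e5).
#' @param startValue start value passed to [scorePath()].
#' @return A list of paths, each a list with \code{nodes}, \code{edges} and
#'   \code{signed_value}; empty when the pair is unreachable. For
#'   \code{source == target} a single empty path scoring \code{+startValue}.
#'   Attribute \code{truncated} reports whether the cap was hit.
#' @export
allShortestPaths <- function(net, source, target, maxPaths = 1e5,
                             startValue = 10000) {
  comp <- compileNetwork(net)
  for (g in c(source, target))
    if (!g %in% comp$nodes) stop("gene not in network: ", g)
  s <- comp$idx[[source]]
  t <- comp$idx[[target]]
  r <- signedReach(comp, s)
  if (is.na(r$dist[t])) {
    out <- list()
    attr(out, "truncated") <- FALSE
    return(out)
  }
  if (s == t) {
    out <- list(list(nodes = source,
                     edges = comp$edges[0, , drop = FALSE],
                     signed_value = startValue))
    attr(out, "truncated") <- FALSE
    return(out)
  }
  truncated <- r$P[t] > maxPaths
  if (truncated)
    warning(sprintf(
      "pair %s -> %s has %.0f shortest paths; only the first %d enumerated",
      source, target, r$P[t], maxPaths))
  # in-adjacency restricted to the shortest-path DAG, walked backwards
  n <- comp$n
  nodePaths <- list()
  walk <- function(v, acc) {
    if (length(nodePaths) >= maxPaths) return()
    if (v == s) {
      nodePaths[[length(nodePaths) + 1L]] <<- c(s, rev(acc))
      return()
    }
    dPrev <- r$dist[v] - 1L
    for (u in which(r$dist == dPrev)) {
      if (v %in% comp$outTo[[u]])
        walk(u, c(acc, v))
    }
  }
  walk(t, integer(0))
  # expand parallel-edge choices per node path
  out <- list()
  for (np in nodePaths) {
    hops <- length(np) - 1L
    choiceRows <- vector("list", hops)
    for (h in seq_len(hops)) {
      key <- as.character((np[h] - 1) * n + np[h + 1L])
      choiceRows[[h]] <- comp$edgeRowsByKey[[key]]
    }
    grid <- expand.grid(rev(choiceRows), KEEP.OUT.ATTRS = FALSE)
    grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]
    for (gi in seq_len(nrow(grid))) {
      if (length(out) >= maxPaths) break
      rows <- as.integer(grid[gi, ])
      ed <- comp$edges[rows, , drop = FALSE]
      rownames(ed) <- NULL
      out[[length(out) + 1L]] <- list(
        nodes = comp$nodes[np],
        edges = ed,
        signed_value = scorePath(ed, startValue))
    }
    if (length(out) >= maxPaths) break
  }
  attr(out, "truncated") <- truncated
  out
}

#' Default aggregate connection score between two genes
#'
#' The sum of the signed connection scores of all shortest (minimal
#' hop-count) directed paths from \code{source} to \code{target}; 0 when the
#' pair is disconnected (the zero-contribution rule). Computed exactly by
#' dynamic programming over the shortest-path DAG.
#'
#' @param net a [CausalNetwork-class], or \code{NULL} when \code{cache} is
#'   given.
#' @param source,target gene symbols.
#' @param cache optional [pairScoreCache()]; recommended whenever more than
#'   one pair is scored.
#' @param startValue,maxPaths see [pairScoreCache()]; ignored when
#'   \code{cache} is supplied.
#' @return A list with \code{source}, \code{target}, \code{aggregate},
#'   \code{n_paths} and \code{truncated} (TRUE when \code{n_paths} exceeds
#'   the cap; the aggregate remains the exact full sum).
#' @examples
#' net <- CausalNetwork(data.frame(
#'   source = c("A", "A", "B", "C"), target = c("B", "C", "D", "D"),
#'   effect = "UP", score = 0.5))
#' defaultAggregateScore(net, "A", "D")$aggregate  # 2 paths x 2500
#' @export
defaultAggregateScore <- function(net, source, target, cache = NULL,
                                  startValue = 10000, maxPaths = 1e5) {
  if (is.null(cache)) cache <- pairScoreCache(net, startValue, maxPaths)
  for (g in c(source, target))
    if (!g %in% cache$comp$nodes) stop("gene not in network: ", g)
  r <- cacheReach(cache, source)
  t <- cache$comp$idx[[target]]
  if (is.na(r$dist[t]))
    return(list(source = source, target = target, aggregate = 0,
                n_paths = 0, truncated = FALSE))
  list(source = source, target = target,
       aggregate = cache$startValue * r$A[t],
       n_paths = r$P[t],
       truncated = r$P[t] > cache$maxPaths)
}

# Matrix of aggregates for sources x targets (gene symbols), via the cache.
pairAggregateMatrix <- function(cache, sources, targets) {
  ti <- cache$comp$idx[targets]
  M <- matrix(0, nrow = length(sources), ncol = length(targets),
              dimnames = list(sources, targets))
  Np <- M
  for (i in seq_along(sources)) {
    r <- cacheReach(cache, sources[i])
    a <- cache$startValue * r$A[ti]
    a[is.na(r$dist[ti])] <- 0
    M[i, ] <- a
    p <- r$P[ti]
    p[is.na(r$dist[ti])] <- 0
    Np[i, ] <- p
  }
  attr(M, "n_paths") <- Np
  M
}

#' Final connection score between a drug and a disease module
#'
#' Sums, over every (drug target, disease gene) pair, the default aggregate
#' connection score adjusted by two signs: the sign is reversed when the
#' drug's mode of action on that target is down-regulating, and reversed
#' again when the disease gene's log2 fold-change is negative. A strongly
#' negative final score therefore means the drug's propagated effect opposes
#' the disease's expression changes. Targets absent from the network
#' contribute zero; a drug with no target in the network scores 0 and is
#' flagged unanchored.
#'
#' @param net a [CausalNetwork-class] (may be \code{NULL} when \code{cache}
#'   is supplied).
#' @param drug either a data.frame with columns \code{target}, \code{moa}
#'   (as returned by [drugTargets()]) or a [DrugSet-class] together with
#'   \code{drugId}.
#' @param module a [DiseaseModule-class].
#' @param cache optional shared [pairScoreCache()].
#' @param drugId drug identifier used when \code{drug} is a [DrugSet-class];
#'   also recorded in the result.
#' @param startValue,maxPaths see [pairScoreCache()].
#' @return A list with \code{drug_id}, \code{disease_id}, \code{final},
#'   \code{drug_size} (number of target entries), \code{anchored_targets},
#'   \code{disease_size} and \code{truncated}.
#' @export
finalConnectionScore <- function(net, drug, module, cache = NULL,
                                 drugId = NULL, startValue = 10000,
                                 maxPaths = 1e5) {
  if (is(drug, "DrugSet")) {
    stopifnot(!is.null(drugId))
    targets <- drugTargets(drug, drugId)
  } else {
    targets <- as.data.frame(drug)
    if (is.null(drugId)) drugId <- NA_character_
  }
  stopifnot(all(c("target", "moa") %in% names(targets)))
  if (is.null(cache)) cache <- pairScoreCache(net, startValue, maxPaths)
  mem <- moduleTable(module)
  present <- targets$target %in% cache$comp$nodes
  out <- list(drug_id = drugId, disease_id = diseaseId(module),
              final = 0, drug_size = nrow(targets),
              anchored_targets = sum(present),
              disease_size = nrow(mem), truncated = FALSE)
  if (!any(present)) {
    out$flag <- "no anchored target"
    return(out)
  }
  tg <- targets[present, , drop = FALSE]
  genes <- mem$gene
  keepG <- genes %in% cache$comp$nodes
  if (!any(keepG)) return(out)
  M <- pairAggregateMatrix(cache, tg$target, genes[keepG])
  sigT <- moaSign(tg$moa)
  sigG <- fcSign(mem$log2fc[keepG])
  out$final <- as.numeric(sigT %*% M %*% sigG)
  out$truncated <- any(attr(M, "n_paths") > cache$maxPaths)
  out
}

#' Score every drug in a DrugSet against a disease module
#'
#' @param net a [CausalNetwork-class] (or \code{NULL} with \code{cache}).
#' @param drugs a [DrugSet-class].
#' @param module a [DiseaseModule-class].
#' @param cache optional shared [pairScoreCache()].
#' @param startValue,maxPaths see [pairScoreCache()].
#' @return data.frame with one row per drug: \code{drug_id},
#'   \code{drug_name}, \code{disease_id}, \code{final}, \code{drug_size},
#'   \code{anchored_targets}, \code{disease_size}, \code{truncated}.
#' @export
scoreDrugSet <- function(net, drugs, module, cache = NULL,
                         startValue = 10000, maxPaths = 1e5) {
  if (is.null(cache)) cache <- pairScoreCache(net, startValue, maxPaths)
  ids <- drugIds(drugs)
  tab <- drugTable(drugs)
  nameOf <- tab$drug_name[!duplicated(tab$drug_id)]
  names(nameOf) <- tab$drug_id[!duplicated(tab$drug_id)]
  rows <- lapply(ids, function(id) {
    s <- finalConnectionScore(NULL, drugs, module, cache = cache, drugId = id)
    data.frame(drug_id = id, drug_name = unname(nameOf[id]),
               disease_id = s$disease_id, final = s$final,
               drug_size = s$anchored_targets,
               anchored_targets = s$anchored_targets,
               disease_size = s$disease_size,
               truncated = s$truncated,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
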