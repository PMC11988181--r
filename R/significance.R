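## Size-matched permutation null and significance assessment.

#' Build a size-matched null distribution of final connection scores
#'
#' Draws \code{nDraws} random (pseudo-drug, pseudo-disease-module) pairs of
#' the requested sizes. Pseudo-drug targets are sampled without replacement
#' from the drug-target pool and each receives a mode of action drawn from
#' the empirical mode-of-action frequencies of the real drug-target entries;
#' pseudo-module genes are sampled without replacement from the disease-gene
#' pool and keep their pooled log2 fold-change signs. Each pair's final
#' connection score is computed through the shared pair-score cache; the
#' resulting mean and standard deviation z-score-normalise observed scores
#' of the same size combination.
#'
#' @param cache a [pairScoreCache()] over the causal network (shared with the
#'   observed scoring).
#' @param drugSize,diseaseSize module sizes to match.
#' @param targetPool character vector of candidate target genes (typically
#'   the union of mapped drug targets present in the network).
#' @param diseasePool data.frame with columns \code{gene}, \code{log2fc}
#'   (typically the union over all built disease modules).
#' @param moaProbs named numeric \code{c(UP = , DOWN = )} empirical
#'   mode-of-action frequencies.
#' @param nDraws number of random pairs (default 1000).
#' @param seed integer seed.
#' @return A [NullDistribution-class]. Zero spread across draws (a network
#'   in which no sampled pair is ever connected) is an error.
#' @export
buildNull <- function(cache, drugSize, diseaseSize, targetPool, diseasePool,
                      moaProbs = c(UP = 0.5, DOWN = 0.5), nDraws = 1000L,
                      seed = 1L) {
  drugSize <- as.integer(drugSize)
  diseaseSize <- as.integer(diseaseSize)
  if (length(targetPool) < drugSize)
    stop("target pool (", length(targetPool),
         ") smaller than drug size ", drugSize)
  if (nrow(diseasePool) < diseaseSize)
    stop("disease pool (", nrow(diseasePool),
         ") smaller than disease size ", diseaseSize)
  stopifnot(all(c("UP", "DOWN") %in% names(moaProbs)))
  M <- pairAggregateMatrix(cache, targetPool, diseasePool$gene)
  sigG <- fcSign(diseasePool$log2fc)
  pDown <- moaProbs[["DOWN"]] / (moaProbs[["UP"]] + moaProbs[["DOWN"]])
  scores <- withSeed(seed, {
    vapply(seq_len(nDraws), function(i) {
      ti <- sample.int(length(targetPool), drugSize)
      gi <- sample.int(nrow(diseasePool), diseaseSize)
      st <- ifelse(stats::runif(drugSize) < pDown, -1, 1)
      sum(st * (M[ti, gi, drop = FALSE] %*% sigG[gi]))
    }, numeric(1))
  })
  sdv <- stats::sd(scores)
  if (sdv == 0)
    stop("null distribution is degenerate (sd = 0): every random ",
         "drug-disease pair scored ", scores[1],
         "; the network carries no variable connectivity between the pools")
  new("NullDistribution", drugSize = drugSize, diseaseSize = diseaseSize,
      nDraws = as.integer(nDraws), mean = mean(scores), sd = sdv,
      seed = as.integer(seed), scores = scores)
}

#' Build (and memoise) nulls for every size combination present
#'
#' @param cache shared [pairScoreCache()].
#' @param sizes data.frame with columns \code{drug_size},
#'   \code{disease_size} (duplicates collapsed).
#' @param targetPool,diseasePool,moaProbs,nDraws see [buildNull()].
#' @param seed base seed; the null for the i-th distinct size combination
#'   uses \code{seed + i - 1}.
#' @return named list of [NullDistribution-class] objects keyed
#'   \code{"<drug_size>x<disease_size>"}.
#' @export
buildNullMemo <- function(cache, sizes, targetPool, diseasePool,
                          moaProbs = c(UP = 0.5, DOWN = 0.5),
                          nDraws = 1000L, seed = 1L) {
  sizes <- unique(sizes[, c("drug_size", "disease_size")])
  sizes <- sizes[order(sizes$drug_size, sizes$disease_size), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(sizes))) {
    key <- paste0(sizes$drug_size[i], "x", sizes$disease_size[i])
    out[[key]] <- buildNull(cache, sizes$drug_size[i], sizes$disease_size[i],
                            targetPool, diseasePool, moaProbs = moaProbs,
                            nDraws = nDraws, seed = seed + i - 1L)
  }
  out
}

#' Assess connection scores against their size-matched nulls
#'
#' z-score-normalises each observed final connection score with the null of
#' its (drug size, disease size) combination and assigns a one-sided
#' lower-tail normal p-value: only scores significantly LOWER than expected
#' (drug action opposing the disease signature) are of interest. A
#' Benjamini-Hochberg column is provided for convenience, but the
#' \code{significant} flag uses the raw p-value threshold.
#'
#' @param scores data.frame as from [scoreDrugSet()] (columns
#'   \code{drug_id}, \code{drug_name}, \code{disease_id}, \code{final},
#'   \code{drug_size}, \code{disease_size}).
#' @param nulls named list from [buildNullMemo()]; a missing size
#'   combination is an error naming it.
#' @param alpha significance threshold on the lower-tail p (default 0.05).
#' @return data.frame sorted ascending by final score (most negative, i.e.
#'   strongest counter-disease action, first) with added columns \code{z},
#'   \code{p}, \code{p_bh}, \code{significant}, \code{null_mean},
#'   \code{null_sd}, \code{null_seed}.
#' @export
assessAssociations <- function(scores, nulls, alpha = 0.05) {
  key <- paste0(scores$drug_size, "x", scores$disease_size)
  miss <- setdiff(unique(key), names(nulls))
  if (length(miss))
    stop("no null distribution for size combination(s): ",
         paste(miss, collapse = ", "))
  nm <- vapply(nulls[key], function(n) n@mean, numeric(1))
  ns <- vapply(nulls[key], function(n) n@sd, numeric(1))
  nseed <- vapply(nulls[key], function(n) as.numeric(n@seed), numeric(1))
  out <- scores
  out$z <- (out$final - nm) / ns
  out$p <- stats::pnorm(out$z)
  out$p_bh <- bhAdjust(out$p)
  out$significant <- out$p <= alpha
  out$null_mean <- nm
  out$null_sd <- ns
  out$null_seed <- nseed
  out <- out[order(out$final, out$drug_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Empirical mode-of-action frequencies of a DrugSet
#'
#' @param drugs a [DrugSet-class].
#' @return named numeric \code{c(UP = , DOWN = )} summing to 1.
#' @export
moaFrequencies <- function(drugs) {
  t <- drugTable(drugs)
  if (!nrow(t)) return(c(UP = 0.5, DOWN = 0.5))
  c(UP = mean(t$moa == "UP"), DOWN = mean(t$moa == "DOWN"))
}
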