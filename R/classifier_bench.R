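## Benchmark harness: compare two same-size gene sets as features of an
## RBF-kernel SVM on the tumor/normal classification task, reporting AUC,
## accuracy and Cohen's kappa from stratified cross-validation.

#' Cohen's kappa from a 2x2 confusion matrix
#'
#' Observed agreement Pr(a) = (tp + tn) / n; chance agreement
#' Pr(e) = (cm1 * rm1 / n + cm2 * rm2 / n) / n, where cm and rm are the
#' column and row marginals; kappa = (Pr(a) - Pr(e)) / (1 - Pr(e)). The
#' degenerate case Pr(e) = 1 (all counts in one cell) returns 0 with a
#' warning.
#'
#' @param tp,fp,fn,tn nonnegative integer counts; alternatively pass a 2x2
#'   matrix as \code{tp} (rows = prediction, columns = truth).
#' @return kappa in [-1, 1].
#' @examples
#' kappaStatistic(40, 10, 5, 45)  # 0.7
#' @export
kappaStatistic <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  if (is.matrix(tp)) {
    stopifnot(all(dim(tp) == 2))
    m <- tp
  } else {
    m <- matrix(c(tp, fn, fp, tn), nrow = 2)
  }
  if (any(m < 0)) stop("confusion-matrix counts must be nonnegative")
  n <- sum(m)
  if (n == 0) stop("empty confusion matrix")
  prA <- sum(diag(m)) / n
  cm <- colSums(m)
  rm_ <- rowSums(m)
  prE <- (cm[1] * rm_[1] / n + cm[2] * rm_[2] / n) / n
  if (prE >= 1) {
    warning("degenerate confusion matrix (chance agreement = 1); kappa = 0")
    return(0)
  }
  unname((prA - prE) / (1 - prE))
}

svmCvMetrics <- function(x, y, fold, folds) {
  dec <- numeric(length(y))
  pred <- factor(rep(levels(y)[1], length(y)), levels = levels(y))
  for (f in seq_len(folds)) {
    te <- fold == f
    xtr <- x[!te, , drop = FALSE]
    gam <- 1 / (ncol(x) * max(stats::var(as.vector(xtr)), .Machine$double.eps))
    fit <- e1071::svm(xtr, y[!te], kernel = "radial", cost = 1,
                      gamma = gam, scale = FALSE)
    pr <- stats::predict(fit, x[te, , drop = FALSE], decision.values = TRUE)
    dv <- drop(attr(pr, "decision.values"))
    # e1071 orients decision values as "<lvlA>/<lvlB>": positive favours lvlA
    lvlA <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1]][1]
    if (lvlA != levels(y)[1]) dv <- -dv
    dec[te] <- dv
    pred[te] <- pr
  }
  acc <- mean(pred == y)
  m <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    m[i, j] <- sum(pred == levels(y)[i] & y == levels(y)[j])
  kp <- suppressWarnings(kappaStatistic(m))
  roc <- pROC::roc(response = y, predictor = dec,
                   levels = c(levels(y)[2], levels(y)[1]),
                   direction = "<", quiet = TRUE)
  list(auc = as.numeric(pROC::auc(roc)), accuracy = acc, kappa = kp)
}

#' Benchmark two gene sets as classifier features
#'
#' Fits a radial-basis-function SVM (cost 1, gamma = 1 / (n_features *
#' variance of the training block), per-gene standardised expression) under
#' stratified cross-validation, using identical folds for both gene sets,
#' and reports AUC (from decision values pooled across held-out folds),
#' accuracy and Cohen's kappa for each set.
#'
#' @param expr numeric gene-by-sample matrix.
#' @param labels two-level condition per sample (named or column-aligned).
#' @param setA,setB character vectors of gene symbols; the intended use
#'   compares same-size sets (unequal sizes draw a warning). Any gene absent
#'   from \code{expr} is an error naming the missing genes.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return list with elements \code{setA} and \code{setB}, each a list
#'   \code{auc}/\code{accuracy}/\code{kappa}, plus \code{table}: a one-row
#'   data.frame shaped like a per-disease performance comparison
#'   (\code{kappa_a}, \code{kappa_b}, \code{accuracy_a}, \code{accuracy_b},
#'   \code{auc_a}, \code{auc_b}).
#' @export
benchmarkGeneSets <- function(expr, labels, setA, setB, folds = 5L,
                              seed = 1L) {
  missing <- setdiff(union(setA, setB), rownames(expr))
  if (length(missing))
    stop("gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  if (length(setA) != length(setB))
    warning("gene sets differ in size (", length(setA), " vs ",
            length(setB), "); the comparison is intended for equal sizes")
  samp <- colnames(expr)
  if (!is.null(names(labels))) labels <- labels[samp]
  y0 <- factor(as.character(labels))
  stopifnot(nlevels(y0) == 2)
  co <- order(samp)
  y <- y0[co]
  prep <- function(genes) {
    x <- t(expr[genes, co, drop = FALSE])
    x <- scale(x)
    x[!is.finite(x)] <- 0
    x
  }
  fold <- withSeed(seed, stratifiedFolds(y, folds))
  a <- svmCvMetrics(prep(setA), y, fold, folds)
  b <- svmCvMetrics(prep(setB), y, fold, folds)
  tab <- data.frame(kappa_a = a$kappa, kappa_b = b$kappa,
                    accuracy_a = a$accuracy, accuracy_b = b$accuracy,
                    auc_a = a$auc, auc_b = b$auc)
  list(setA = a, setB = b, table = tab)
}
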