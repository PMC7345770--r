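`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(..., call. = FALSE) {
  stop(paste0(...), call. = call.)
}

#' Area under the ROC curve from scores and class labels
#'
#' Computes the AUC as the Mann-Whitney concordance probability: the
#' proportion of (positive, negative) pairs in which the positive case
#' scores higher, with tied scores counting one half. Implemented through
#' midranks, which is algebraically identical to exhaustive pair counting.
#'
#' @param scores Numeric vector of classifier scores; higher means more
#'   positive-like.
#' @param labels Vector (factor, character or logical) of class labels.
#' @param positive Label value treated as the positive class (default
#'   `"NGHC"`).
#' @return A single number in \[0, 1\].
#' @examples
#' auc_mw(c(0.9, 0.8, 0.3, 0.1), c("NGHC", "NGHC", "NHC", "NHC"))
#' @export
auc_mw <- function(scores, labels, positive = "NGHC") {
  if (length(scores) != length(labels)) {
    stop_input("scores and labels must have the same length")
  }
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop_input("AUC undefined: need at least one case in each class")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Row-wise variance for a numeric matrix (denominator n - 1).
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

# Group-mean matrix: columns of `x` averaged within groups given by `f`
# (a factor over columns). Returns genes x levels(f). Implemented as a
# single matrix product so large simulations stay fast.
group_row_means <- function(x, f) {
  f <- as.factor(f)
  ind <- matrix(0, nrow = length(f), ncol = nlevels(f))
  ind[cbind(seq_along(f), as.integer(f))] <- 1
  cnt <- colSums(ind)
  out <- x %*% ind
  out <- sweep(out, 2, cnt, "/")
  colnames(out) <- levels(f)
  out
}
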