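#' Classification accuracy
#'
#' Proportion of samples predicted correctly: (TP + TN) / N.
#'
#' @param predictions 0/1 (or logical) predicted classes.
#' @param labels 0/1 (or logical) true classes, aligned.
#' @return a number in [0, 1].
#' @export
accuracy <- function(predictions, labels) {
  if (!length(predictions)) stop("empty input")
  if (length(predictions) != length(labels))
    stop("predictions and labels must be aligned")
  mean(as.numeric(predictions) == as.numeric(labels))
}

#' Rank-based AUC
#'
#' Area under the ROC curve via the rank formula
#' AUC = (sum of positive-case ranks - npos (npos + 1) / 2) /
#' (npos * nneg), with midranks for ties — identical to the Mann-Whitney
#' concordance probability (tied pairs count 1/2).
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels 0/1 class labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels) {
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1")
  npos <- sum(y == 1)
  nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks for ties
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# per-case and per-control placement values of one score vector
.delong_components <- function(scores, y) {
  x <- scores[y == 1]
  z <- scores[y == 0]
  psi <- outer(x, z, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
       m = length(x), n = length(z))
}

#' DeLong variance of a single AUC
#'
#' Structural-components estimate var(V10)/m + var(V01)/n, where V10 and
#' V01 are the per-case and per-control placement values.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return variance estimate of the empirical AUC.
#' @export
auc_variance_delong <- function(scores, labels) {
  y <- as.numeric(labels)
  cmp <- .delong_components(scores, y)
  stats::var(cmp$v10) / cmp$m + stats::var(cmp$v01) / cmp$n
}

#' Paired test for an AUC difference
#'
#' Compares the AUCs of two score vectors evaluated on the same samples.
#' The default is the paired DeLong test (normal approximation on the
#' structural components); a paired bootstrap over samples is available as
#' an alternative. Identical score vectors return p = 1.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels 0/1 labels shared by both.
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap replicates (bootstrap method only).
#' @param seed seed for the bootstrap resampling.
#' @return list: `auc_a`, `auc_b`, `p_value`, `method`.
#' @export
compare_auc <- function(scores_a, scores_b, labels,
                        method = c("delong", "bootstrap"),
                        n_boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  y <- as.numeric(labels)
  if (length(scores_a) != length(y) || length(scores_b) != length(y))
    stop("scores and labels must cover identical samples")
  a <- .delong_components(scores_a, y)
  b <- .delong_components(scores_b, y)
  if (isTRUE(all.equal(scores_a, scores_b, tolerance = 0)))
    return(list(auc_a = a$auc, auc_b = b$auc, p_value = 1, method = method))
  if (method == "delong") {
    s10 <- stats::cov(cbind(a$v10, b$v10))
    s01 <- stats::cov(cbind(a$v01, b$v01))
    v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / a$m +
      (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / a$n
    d <- a$auc - b$auc
    if (v <= 0) {
      if (abs(d) < 1e-12)
        return(list(auc_a = a$auc, auc_b = b$auc, p_value = 1,
                    method = method))
      stop("degenerate DeLong variance with nonzero AUC difference; ",
           "scores may be constant within class")
    }
    p <- 2 * stats::pnorm(-abs(d / sqrt(v)))
  } else {
    set.seed(seed)
    n <- length(y)
    d <- replicate(n_boot, {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[i])) < 2L) return(NA_real_)
      auc_rank(scores_a[i], y[i]) - auc_rank(scores_b[i], y[i])
    })
    d <- d[!is.na(d)]
    if (stats::sd(d) == 0)
      stop("degenerate bootstrap distribution of the AUC difference")
    p <- 2 * min(mean(d <= 0), mean(d >= 0))
    p <- min(1, max(p, 1 / length(d)))
  }
  list(auc_a = a$auc, auc_b = b$auc, p_value = p, method = method)
}

# sensitivity / specificity / PPV of thresholded probabilities
.threshold_metrics <- function(prob, y, threshold = 0.5) {
  pred <- as.numeric(prob >= threshold)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' ROC curve points
#'
#' Sensitivity / 1-specificity pairs at every distinct score threshold.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return data frame `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  y <- as.numeric(labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(th, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & y == 0) / max(1, sum(y == 0)),
      tpr = sum(pred & y == 1) / max(1, sum(y == 1)))
  }, numeric(2)))
  data.frame(threshold = th, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}
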