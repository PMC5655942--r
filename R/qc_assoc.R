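#' Class the yearly radiographic progression rate into outcome groups
#'
#' Computes the yearly joint-damage rate and dichotomizes it by tertiles.
#' With two X-rays per patient (`mode = "two_xray"`) the rate is
#' (follow-up SHS - baseline SHS) / interval in years. With a single X-ray
#' (`mode = "one_xray"`) the estimated rate is total SHS / disease years at
#' the time of the X-ray. Patients in the low tertile are labelled
#' `no_progression`, the high tertile `severe`, and the middle tertile is
#' excluded from analysis. Tertile cut points are the empirical 1/3 and 2/3
#' quantiles of the rate; membership is by quantile interval (rate below or
#' at the lower cut = low, at or above the upper cut = high).
#'
#' @param shs_baseline,shs_followup SHS at the two X-rays (two_xray mode).
#' @param interval_years years between the two X-rays (two_xray mode).
#' @param total_shs SHS at the single X-ray (one_xray mode).
#' @param disease_years disease duration at the X-ray (one_xray mode).
#' @param mode `"two_xray"` or `"one_xray"`.
#' @param sample_ids optional ids; defaults to names or indices.
#' @return data frame of class `rg_labels` with columns `sample`, `rate`,
#'   `tertile` (low/middle/high), `label` (no_progression/severe/excluded).
#'   Samples with nonpositive denominators are excluded and listed in
#'   `attr(, "errors")`.
#' @export
classify_progression <- function(shs_baseline = NULL, shs_followup = NULL,
                                 interval_years = NULL,
                                 total_shs = NULL, disease_years = NULL,
                                 mode = c("two_xray", "one_xray"),
                                 sample_ids = NULL) {
  mode <- match.arg(mode)
  if (mode == "two_xray") {
    stopifnot(!is.null(shs_baseline), !is.null(shs_followup),
              !is.null(interval_years))
    n <- length(shs_baseline)
    denom <- interval_years
    numer <- shs_followup - shs_baseline
    ids <- sample_ids %||% names(shs_baseline) %||% as.character(seq_len(n))
  } else {
    stopifnot(!is.null(total_shs), !is.null(disease_years))
    n <- length(total_shs)
    denom <- disease_years
    numer <- total_shs
    ids <- sample_ids %||% names(total_shs) %||% as.character(seq_len(n))
  }
  bad <- !is.finite(denom) | denom <= 0 | !is.finite(numer)
  rate <- ifelse(bad, NA_real_, numer / denom)

  ok <- which(!bad)
  tertile <- rep(NA_character_, n)
  if (length(ok) >= 3L) {
    q <- stats::quantile(rate[ok], c(1 / 3, 2 / 3), names = FALSE)
    if (q[1] == q[2])
      warning("degenerate rate distribution: tertile cut points coincide")
    tertile[ok] <- ifelse(rate[ok] <= q[1], "low",
                          ifelse(rate[ok] >= q[2], "high", "middle"))
  }
  # with fewer than 3 valid samples tertiles are undefined: rates are
  # still reported, labels stay excluded
  label <- ifelse(is.na(tertile), "excluded",
                  ifelse(tertile == "low", "no_progression",
                         ifelse(tertile == "high", "severe", "excluded")))
  out <- data.frame(sample = ids, rate = rate, tertile = tertile,
                    label = label, stringsAsFactors = FALSE)
  class(out) <- c("rg_labels", "data.frame")
  attr(out, "errors") <- data.frame(
    sample = ids[bad],
    reason = rep("nonpositive or missing denominator", sum(bad)),
    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on a biallelic genotype table: conditional on the
#' allele counts, the p-value sums the probabilities of all heterozygote
#' counts no more probable than the observed one (Wigginton-style
#' enumeration). Monomorphic variants return 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("HWE p undefined for an all-missing variant")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  rare <- min(nA, na)
  if (rare == 0L) return(1)
  # feasible heterozygote counts share the parity of the rare allele count
  het <- seq(rare %% 2L, rare, by = 2L)
  hom_rare <- (rare - het) / 2
  hom_common <- n - het - hom_rare
  logp <- het * log(2) - lfactorial(hom_rare) - lfactorial(het) -
    lfactorial(hom_common)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, het)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Variant quality control
#'
#' Keeps variants with minor allele frequency at or above `maf_min`,
#' per-variant call rate at or above `callrate_min`, and exact
#' Hardy-Weinberg p-value strictly above `hwe_min` (all three inclusive /
#' strict as stated). All-missing variants fail.
#'
#' @param g an `rg_genotypes` object.
#' @param maf_min,callrate_min,hwe_min thresholds (defaults 0.005, 0.95,
#'   5e-7).
#' @param hwe_method `"exact"` (default) or `"chisq"`.
#' @return list with `genotypes` (filtered) and `report`
#'   (per-input-variant data frame: maf, call_rate, hwe_p, pass).
#' @export
qc_filter <- function(g, maf_min = 0.005, callrate_min = 0.95,
                      hwe_min = 5e-7, hwe_method = c("exact", "chisq")) {
  stopifnot(inherits(g, "rg_genotypes"), ncol(g$dosage) > 0)
  hwe_method <- match.arg(hwe_method)
  dos <- g$dosage
  n <- nrow(dos)
  call_rate <- colMeans(!is.na(dos))
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  counts <- vapply(seq_len(ncol(dos)), function(j) {
    x <- dos[, j]
    c(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
      sum(x == 2, na.rm = TRUE))
  }, numeric(3))
  hwe_p <- vapply(seq_len(ncol(dos)), function(j) {
    if (sum(counts[, j]) == 0) return(NA_real_)
    if (hwe_method == "exact")
      hwe_exact_p(counts[1, j], counts[2, j], counts[3, j])
    else .hwe_chisq_p(counts[1, j], counts[2, j], counts[3, j])
  }, numeric(1))
  pass <- !is.na(maf) & maf >= maf_min & call_rate >= callrate_min &
    !is.na(hwe_p) & hwe_p > hwe_min
  report <- data.frame(variant = g$variant_ids, maf = maf,
                       call_rate = call_rate, hwe_p = hwe_p, pass = pass,
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  if (!any(pass)) warning("QC removed every variant: empty genotype matrix")
  keep <- which(pass)
  filtered <- structure(list(
    dosage = dos[, keep, drop = FALSE],
    sample_ids = g$sample_ids,
    variant_ids = g$variant_ids[keep],
    positions = g$positions[keep],
    ref = g$ref[keep], alt = g$alt[keep],
    chrom = g$chrom
  ), class = "rg_genotypes")
  list(genotypes = filtered, report = report)
}

.hwe_chisq_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  p <- (2 * n_AA + n_Aa) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (any(e == 0)) return(1)
  stats::pchisq(sum((c(n_AA, n_Aa, n_aa) - e)^2 / e), df = 1,
                lower.tail = FALSE)
}

#' Genotype principal components
#'
#' Mean-imputes missing dosages per variant, standardizes, and extracts the
#' top principal components of the sample covariance. Samples more than
#' 6 SD from the mean on any of the top ten PCs are flagged (reported, not
#' removed).
#'
#' @param g an `rg_genotypes` object (QC-passed).
#' @param n_pcs number of components (default 10); truncated with a warning
#'   if it exceeds the matrix rank.
#' @return object of class `rg_pcs`: `scores` (samples x PCs), `sdev`,
#'   `outliers` (flagged sample ids).
#' @export
compute_pcs <- function(g, n_pcs = 10L) {
  stopifnot(inherits(g, "rg_genotypes"))
  X <- .impute_standardize(g$dosage)$X
  rank_max <- min(nrow(X) - 1L, ncol(X))
  if (n_pcs > rank_max) {
    warning("n_pcs exceeds matrix rank; truncating to ", rank_max)
    n_pcs <- rank_max
  }
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE, rank. = n_pcs)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  rownames(scores) <- g$sample_ids
  top <- scores[, seq_len(min(10L, ncol(scores))), drop = FALSE]
  z <- sweep(sweep(top, 2, colMeans(top)), 2,
             pmax(apply(top, 2, stats::sd), 1e-12), "/")
  outliers <- g$sample_ids[apply(abs(z) > 6, 1, any)]
  structure(list(scores = scores, sdev = pc$sdev, outliers = outliers),
            class = "rg_pcs")
}

# mean-impute per variant, drop zero-variance columns, standardize
.impute_standardize <- function(dos, center = NULL, scale = NULL) {
  X <- dos
  if (is.null(center)) {
    mu <- colMeans(X, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
  } else mu <- center
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  if (is.null(scale)) {
    sdv <- apply(X, 2, stats::sd)
  } else sdv <- scale
  keep <- sdv > 0
  X <- sweep(X[, keep, drop = FALSE], 2, mu[keep])
  X <- sweep(X, 2, sdv[keep], "/")
  list(X = X, center = mu, scale = sdv, keep = keep)
}

#' Per-variant logistic association scan
#'
#' Fits, for each variant, an additive-coded logistic regression of severe
#' progression (severe = 1, no progression = 0) on the allele dosage,
#' adjusted for the supplied clinical covariates and principal components,
#' by iteratively reweighted least squares. The genotype term's Wald
#' p-value defines the significant set at `p < p_threshold` (strict).
#' Samples missing a dosage are dropped for that variant (complete-case);
#' samples missing any covariate are dropped globally with a logged count.
#' Variants with constant dosage or non-converged / separated fits are
#' flagged and never significant.
#'
#' @param g an `rg_genotypes` object.
#' @param labels an `rg_labels` object (or a named binary vector).
#' @param covariates data frame of per-sample covariates (may be `NULL`,
#'   e.g. for a replication cohort with no clinical data).
#' @param pcs an `rg_pcs` object or score matrix (may be `NULL`).
#' @param p_threshold significance threshold (default 0.05).
#' @return data frame of class `rg_assoc`: variant, beta, se, p, n,
#'   flagged; `attr(, "significant")` holds the significant variant ids.
#' @export
logistic_assoc <- function(g, labels, covariates = NULL, pcs = NULL,
                           p_threshold = 0.05) {
  stopifnot(inherits(g, "rg_genotypes"))
  y_all <- .binary_outcome(labels, g$sample_ids)
  use <- !is.na(y_all)

  Z <- NULL
  if (!is.null(covariates)) {
    Z <- as.matrix(covariates[g$sample_ids, , drop = FALSE])
  }
  if (!is.null(pcs)) {
    S <- if (inherits(pcs, "rg_pcs")) pcs$scores else as.matrix(pcs)
    Z <- cbind(Z, S[g$sample_ids, , drop = FALSE])
  }
  n_cov_dropped <- 0L
  if (!is.null(Z)) {
    cc <- stats::complete.cases(Z)
    n_cov_dropped <- sum(use & !cc)
    use <- use & cc
  }
  y <- y_all[use]
  if (length(unique(y)) < 2L)
    stop("association requires both outcome classes")
  X0 <- cbind(`(Intercept)` = rep(1, sum(use)),
              if (!is.null(Z)) Z[use, , drop = FALSE])
  dos <- g$dosage[use, , drop = FALSE]

  m <- ncol(dos)
  beta <- se <- pval <- rep(NA_real_, m)
  nn <- integer(m)
  flagged <- logical(m)
  for (j in seq_len(m)) {
    gj <- dos[, j]
    ok <- !is.na(gj)
    nn[j] <- sum(ok)
    if (nn[j] < ncol(X0) + 2L || stats::var(gj[ok]) == 0) {
      flagged[j] <- TRUE
      next
    }
    X <- cbind(X0[ok, , drop = FALSE], dosage = gj[ok])
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y[ok], family = stats::binomial(),
                                      control = stats::glm.control(maxit = 100))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || fit$boundary) {
      flagged[j] <- TRUE
      next
    }
    k <- ncol(X)
    # Wald from the unscaled covariance of the IRLS fit
    cov <- tryCatch(chol2inv(chol(crossprod(X * sqrt(fit$weights)))),
                    error = function(e) NULL)
    if (is.null(cov) || !is.finite(cov[k, k]) || cov[k, k] <= 0) {
      flagged[j] <- TRUE
      next
    }
    b <- fit$coefficients[k]
    s <- sqrt(cov[k, k])
    if (!is.finite(b) || s > 1e3) {  # quasi-separation guard
      flagged[j] <- TRUE
      next
    }
    beta[j] <- b
    se[j] <- s
    pval[j] <- 2 * stats::pnorm(-abs(b / s))
  }
  out <- data.frame(variant = g$variant_ids, beta = beta, se = se,
                    p = pval, n = nn, flagged = flagged,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("rg_assoc", "data.frame")
  attr(out, "significant") <-
    out$variant[!out$flagged & !is.na(out$p) & out$p < p_threshold]
  attr(out, "p_threshold") <- p_threshold
  attr(out, "covariates") <- colnames(Z)
  attr(out, "n_covariate_dropped") <- n_cov_dropped
  out
}

# labels -> named 0/1 vector over sample_ids (NA = excluded)
.binary_outcome <- function(labels, sample_ids) {
  if (inherits(labels, "rg_labels")) {
    y <- stats::setNames(rep(NA_real_, length(sample_ids)), sample_ids)
    idx <- match(labels$sample, sample_ids)
    ok <- !is.na(idx) & labels$label %in% c("no_progression", "severe")
    y[idx[ok]] <- as.numeric(labels$label[ok] == "severe")
    y
  } else {
    y <- stats::setNames(rep(NA_real_, length(sample_ids)), sample_ids)
    v <- labels[intersect(names(labels), sample_ids)]
    y[names(v)] <- as.numeric(v)
    y
  }
}
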