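#' Stratified cross-validation fold plan
#'
#' Partitions the analysis samples (those labelled `no_progression` or
#' `severe`) into `n_folds` groups, stratified by outcome so that each
#' fold's class counts differ by at most one sample from any other fold.
#' Deterministic under the seed.
#'
#' @param labels an `rg_labels` object, or a named 0/1 vector.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return data frame of class `rg_folds`: `sample`, `y`, `fold`.
#' @export
make_folds <- function(labels, n_folds = 10L, seed = 1L) {
  if (inherits(labels, "rg_labels")) {
    keep <- labels$label %in% c("no_progression", "severe")
    ids <- labels$sample[keep]
    y <- as.numeric(labels$label[keep] == "severe")
  } else {
    ids <- names(labels)
    y <- as.numeric(labels)
  }
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  if (min(table(y)) < n_folds)
    stop("fewer samples in a class than folds")
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in c(0, 1)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
  }
  out <- data.frame(sample = ids, y = y, fold = fold,
                    stringsAsFactors = FALSE)
  class(out) <- c("rg_folds", "data.frame")
  attr(out, "seed") <- seed
  attr(out, "n_folds") <- n_folds
  out
}

# subset an rg_genotypes object by sample ids
.subset_samples <- function(g, ids) {
  structure(list(dosage = g$dosage[ids, , drop = FALSE],
                 sample_ids = ids, variant_ids = g$variant_ids,
                 positions = g$positions, ref = g$ref, alt = g$alt,
                 chrom = g$chrom), class = "rg_genotypes")
}

# standardize a new matrix with stored training statistics
.apply_standardize <- function(X, std) {
  X <- X[, names(std$center), drop = FALSE]
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- std$center[idx[, 2]]
  X <- X[, std$keep, drop = FALSE]
  X <- sweep(X, 2, std$center[std$keep])
  sweep(X, 2, std$scale[std$keep], "/")
}

# RBF-SVM arm with Platt probabilities; training-fold statistics only
.svm_arm <- function(Xtr, ytr, Xte, cost = 1) {
  if (length(unique(ytr)) < 2L)
    return(list(prob = rep(mean(ytr), nrow(Xte)), fit = NULL, std = NULL))
  std <- .impute_standardize(Xtr)
  if (ncol(std$X) == 0L)
    return(list(prob = rep(0.5, nrow(Xte)), fit = NULL, std = NULL))
  fit <- e1071::svm(x = std$X, y = factor(ytr, levels = c(0, 1)),
                    kernel = "radial", cost = cost, probability = TRUE,
                    scale = FALSE)
  names(std$center) <- colnames(Xtr)
  prob <- if (nrow(Xte)) {
    Xte_s <- .apply_standardize(Xte, std)
    pr <- stats::predict(fit, Xte_s, probability = TRUE)
    unname(attr(pr, "probabilities")[, "1"])
  } else numeric(0)
  list(prob = prob, fit = fit, std = std)
}

#' Nested SNP-set-size selection by cross-validated accuracy
#'
#' For each fold, the entire post-GWAS pipeline is rerun on the training
#' samples only: variant QC, principal components, covariate-adjusted
#' logistic association, significance filtering, SNP-to-gene mapping, and
#' reprioritization under the chosen strategy. For each candidate SNP
#' count k, a radial-basis SVM is trained on the training folds' top-k
#' dosages and its accuracy measured on the held-out fold. The selected
#' k* maximizes the mean held-out accuracy (ties to the smallest k).
#'
#' @param cohort an `rg_cohort`.
#' @param bundle an `rg_bundle`.
#' @param scores an `rg_scores` object (network propagation is
#'   sample-independent, so it is computed once outside the folds).
#' @param fold_plan an `rg_folds` plan.
#' @param k_grid candidate SNP counts (default 10 to 150 by 5).
#' @param strategy `"network_score"` or `"gwas_p"`.
#' @param labels the `rg_labels` used to build the plan.
#' @param covariates clinical covariate data frame for association
#'   adjustment, or `NULL` for covariate-free association.
#' @param maf_min,callrate_min,hwe_min QC thresholds.
#' @param p_threshold association significance threshold.
#' @param r2_min LD proxy threshold.
#' @param n_pcs principal components to adjust for.
#' @param svm_cost SVM cost parameter.
#' @param seed seed controlling the per-fold SVM probability calibration.
#' @return list: `k_star`, `curve` (k, mean_accuracy), `fold_accuracy`
#'   (folds x k), `rankings` (per-fold full ranking), `probs` (per-k pooled
#'   held-out probabilities, named by sample), `n_significant` per fold.
#' @export
nested_select_k <- function(cohort, bundle, scores, fold_plan,
                            k_grid = seq(10L, 150L, by = 5L),
                            strategy = c("network_score", "gwas_p"),
                            labels, covariates = NULL,
                            maf_min = 0.005, callrate_min = 0.95,
                            hwe_min = 5e-7, p_threshold = 0.05,
                            r2_min = 0.8, n_pcs = 10L, svm_cost = 1,
                            seed = 1L) {
  strategy <- match.arg(strategy)
  n_folds <- attr(fold_plan, "n_folds")
  k_grid <- sort(unique(as.integer(k_grid)))
  acc <- matrix(NA_real_, n_folds, length(k_grid),
                dimnames = list(NULL, k_grid))
  rankings <- vector("list", n_folds)
  probs <- lapply(k_grid, function(k) numeric(0))
  names(probs) <- k_grid
  n_sig <- integer(n_folds)

  for (f in seq_len(n_folds)) {
    tr_ids <- fold_plan$sample[fold_plan$fold != f]
    te_ids <- fold_plan$sample[fold_plan$fold == f]
    y_tr <- fold_plan$y[fold_plan$fold != f]
    y_te <- fold_plan$y[fold_plan$fold == f]
    if (length(unique(y_tr)) < 2L)
      stop("training set of fold ", f, " lost an outcome class")

    gtr <- .subset_samples(cohort$genotypes, tr_ids)
    qc <- suppressWarnings(qc_filter(gtr, maf_min, callrate_min, hwe_min))
    pcs <- suppressWarnings(compute_pcs(qc$genotypes, n_pcs))
    assoc <- logistic_assoc(qc$genotypes, labels,
                            covariates = covariates, pcs = pcs,
                            p_threshold = p_threshold)
    cand <- attr(assoc, "significant")
    if (!length(cand)) {
      # degenerate training fold with no significant variant: fall back to
      # the smallest-p variants so a model can still be built
      ok <- !assoc$flagged & !is.na(assoc$p)
      cand <- assoc$variant[ok][order(assoc$p[ok])][seq_len(
        min(max(k_grid), sum(ok)))]
    }
    n_sig[f] <- length(cand)
    snpmap <- map_snp_to_genes(cand, cohort$genotypes$positions, bundle,
                               r2_min)
    tab <- score_snps(snpmap, scores, assoc)
    ranking <- rank_and_select(tab, nrow(tab), strategy)
    rankings[[f]] <- ranking

    set.seed(seed + 17L * f)
    for (ki in seq_along(k_grid)) {
      kk <- min(k_grid[ki], length(ranking))
      snps <- ranking[seq_len(kk)]
      arm <- .svm_arm(cohort$genotypes$dosage[tr_ids, snps, drop = FALSE],
                      y_tr,
                      cohort$genotypes$dosage[te_ids, snps, drop = FALSE],
                      cost = svm_cost)
      p <- stats::setNames(arm$prob, te_ids)
      acc[f, ki] <- accuracy(p >= 0.5, y_te)
      probs[[ki]] <- c(probs[[ki]], p)
    }
  }
  mean_acc <- colMeans(acc)
  k_star <- k_grid[which.max(mean_acc)]  # which.max takes the first = smallest k
  list(k_star = k_star,
       curve = data.frame(k = k_grid, mean_accuracy = unname(mean_acc)),
       fold_accuracy = acc, rankings = rankings, probs = probs,
       n_significant = n_sig, strategy = strategy)
}

#' Weighted probability ensemble
#'
#' Final probability of severe progression: w * p_snp + (1 - w) * p_clin.
#'
#' @param p_snp,p_clin probabilities from the SNP and clinical arms,
#'   covering identical samples (matched by name when named).
#' @param w SNP-arm weight in [0, 1].
#' @return numeric vector of combined probabilities.
#' @export
ensemble_predict <- function(p_snp, p_clin, w) {
  stopifnot(w >= 0, w <= 1)
  if (!is.null(names(p_snp)) && !is.null(names(p_clin))) {
    if (!setequal(names(p_snp), names(p_clin)))
      stop("the two arms cover different sample sets")
    p_clin <- p_clin[names(p_snp)]
  } else if (length(p_snp) != length(p_clin)) {
    stop("the two arms cover different sample sets")
  }
  w * p_snp + (1 - w) * p_clin
}

#' Ensemble weight selection
#'
#' Grid search for the SNP-arm weight maximizing the accuracy of the
#' combined held-out probabilities at decision threshold 0.5; ties go to
#' the smaller weight.
#'
#' @param p_snp,p_clin pooled held-out probabilities (matched by name).
#' @param labels 0/1 outcomes, named like the probabilities.
#' @param w_grid candidate weights (default 0 to 1 by 0.01).
#' @return list: `w_star`, `accuracy` (at `w_star`), `curve`
#'   (w, accuracy).
#' @export
fit_weight <- function(p_snp, p_clin, labels,
                       w_grid = seq(0, 1, by = 0.01)) {
  y <- if (!is.null(names(labels)) && !is.null(names(p_snp)))
    labels[names(p_snp)] else labels
  w_grid <- sort(w_grid)
  accs <- vapply(w_grid, function(w)
    accuracy(ensemble_predict(p_snp, p_clin, w) >= 0.5, y), numeric(1))
  i <- which.max(accs)  # first maximum = smallest w
  list(w_star = w_grid[i], accuracy = accs[i],
       curve = data.frame(w = w_grid, accuracy = accs))
}

#' Fit the cross-validated genetic + clinical ensemble
#'
#' The package's main fitting function. Classifies the yearly progression
#' rate into outcome tertiles, builds a stratified tenfold plan, runs the
#' nested SNP-selection cross-validation ([nested_select_k()]) under the
#' chosen prioritization strategy, trains the clinical SVM arm per fold,
#' optimizes the ensemble weight on the pooled held-out probabilities, and
#' computes accuracy, rank AUC, and threshold metrics — all from held-out
#' predictions only. A final model (association, ranking, and both SVM
#' arms refit on all analysis samples with the selected k* and weight) is
#' stored for [predict.ragnet_cv()] and cross-cohort transfer.
#'
#' @param cohort an `rg_cohort`.
#' @param bundle an `rg_bundle`.
#' @param network an `rg_network` (or a precomputed `rg_scores`).
#' @param strategy `"network_score"` (default) or `"gwas_p"`.
#' @param k_grid candidate SNP counts.
#' @param n_folds folds (default 10).
#' @param seed master seed for the fold plan and SVM calibration.
#' @param alpha propagation restart parameter.
#' @param w_grid ensemble weight grid.
#' @param use_clinical if `FALSE` (e.g. a replication cohort without
#'   clinical data), association is covariate-free and the ensemble
#'   reduces to the SNP arm (w = 1).
#' @param labels optional precomputed `rg_labels` (otherwise derived from
#'   the cohort's two X-rays).
#' @param maf_min,callrate_min,hwe_min,p_threshold,r2_min,n_pcs,svm_cost
#'   passed through to the pipeline stages.
#' @return an object of class `ragnet_cv`.
#' @export
ragnet_cv <- function(cohort, bundle, network,
                      strategy = c("network_score", "gwas_p"),
                      k_grid = seq(10L, 150L, by = 5L),
                      n_folds = 10L, seed = 1L, alpha = 0.5,
                      w_grid = seq(0, 1, by = 0.01),
                      use_clinical = TRUE, labels = NULL,
                      maf_min = 0.005, callrate_min = 0.95,
                      hwe_min = 5e-7, p_threshold = 0.05, r2_min = 0.8,
                      n_pcs = 10L, svm_cost = 1) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(cohort, "rg_cohort"), inherits(bundle, "rg_bundle"))
  if (is.null(labels))
    labels <- classify_progression(cohort$shs_baseline, cohort$shs_followup,
                                   cohort$xray_interval_years,
                                   mode = "two_xray")
  scores <- if (inherits(network, "rg_scores")) network
    else disease_correlation_scores(network, alpha = alpha)

  fold_plan <- make_folds(labels, n_folds, seed)
  covariates <- if (use_clinical) cohort$clinical else NULL

  sel <- nested_select_k(cohort, bundle, scores, fold_plan,
                         k_grid = k_grid, strategy = strategy,
                         labels = labels, covariates = covariates,
                         maf_min = maf_min, callrate_min = callrate_min,
                         hwe_min = hwe_min, p_threshold = p_threshold,
                         r2_min = r2_min, n_pcs = n_pcs,
                         svm_cost = svm_cost, seed = seed)

  ids <- fold_plan$sample
  y <- stats::setNames(fold_plan$y, ids)
  p_snp <- sel$probs[[as.character(sel$k_star)]][ids]

  p_clin <- NULL
  if (use_clinical) {
    p_clin <- stats::setNames(rep(NA_real_, length(ids)), ids)
    clin <- as.matrix(cohort$clinical[ids, , drop = FALSE])
    for (f in seq_len(attr(fold_plan, "n_folds"))) {
      tr <- fold_plan$fold != f
      set.seed(seed + 31L * f)
      arm <- .svm_arm(clin[tr, , drop = FALSE], fold_plan$y[tr],
                      clin[!tr, , drop = FALSE], cost = svm_cost)
      p_clin[ids[!tr]] <- arm$prob
    }
    wfit <- fit_weight(p_snp, p_clin, y, w_grid)
    w_star <- wfit$w_star
    p_final <- ensemble_predict(p_snp, p_clin, w_star)
  } else {
    wfit <- NULL
    w_star <- 1
    p_final <- p_snp
  }

  fold_of <- stats::setNames(fold_plan$fold, ids)
  fold_acc <- vapply(seq_len(attr(fold_plan, "n_folds")), function(f) {
    i <- names(fold_of)[fold_of == f]
    accuracy(p_final[i] >= 0.5, y[i])
  }, numeric(1))

  metrics <- list(
    mean_accuracy = mean(fold_acc),
    fold_accuracy = fold_acc,
    accuracy_snp = accuracy(p_snp >= 0.5, y),
    accuracy_clinical = if (use_clinical) accuracy(p_clin >= 0.5, y) else NA_real_,
    accuracy_ensemble = accuracy(p_final >= 0.5, y),
    auc_snp = auc_rank(p_snp, y),
    auc_clinical = if (use_clinical) auc_rank(p_clin, y) else NA_real_,
    auc_ensemble = auc_rank(p_final, y),
    threshold = .threshold_metrics(p_final, y))

  # final model on all analysis samples for predict()/transfer
  final <- .fit_final_model(cohort, bundle, scores, labels, ids, y,
                            covariates, sel$k_star, strategy, w_star,
                            maf_min, callrate_min, hwe_min, p_threshold,
                            r2_min, n_pcs, svm_cost, seed, use_clinical)

  structure(list(strategy = strategy, labels = labels,
                 fold_plan = fold_plan, selection = sel,
                 k_star = sel$k_star, w_star = w_star,
                 weight_curve = if (!is.null(wfit)) wfit$curve,
                 probabilities = list(snp = p_snp, clinical = p_clin,
                                      ensemble = p_final),
                 y = y, metrics = metrics, final = final,
                 use_clinical = use_clinical, alpha = scores$alpha,
                 seed = seed,
                 call = match.call()),
            class = "ragnet_cv")
}

.fit_final_model <- function(cohort, bundle, scores, labels, ids, y,
                             covariates, k_star, strategy, w_star,
                             maf_min, callrate_min, hwe_min, p_threshold,
                             r2_min, n_pcs, svm_cost, seed, use_clinical) {
  g <- .subset_samples(cohort$genotypes, ids)
  qc <- suppressWarnings(qc_filter(g, maf_min, callrate_min, hwe_min))
  pcs <- suppressWarnings(compute_pcs(qc$genotypes, n_pcs))
  assoc <- logistic_assoc(qc$genotypes, labels, covariates = covariates,
                          pcs = pcs, p_threshold = p_threshold)
  cand <- attr(assoc, "significant")
  if (!length(cand)) {
    ok <- !assoc$flagged & !is.na(assoc$p)
    cand <- assoc$variant[ok][order(assoc$p[ok])][seq_len(min(k_star, sum(ok)))]
  }
  snpmap <- map_snp_to_genes(cand, cohort$genotypes$positions, bundle, r2_min)
  tab <- score_snps(snpmap, scores, assoc)
  snps <- rank_and_select(tab, min(k_star, nrow(tab)), strategy)
  set.seed(seed + 9901L)
  snp_arm <- .svm_arm(cohort$genotypes$dosage[ids, snps, drop = FALSE], y,
                      cohort$genotypes$dosage[integer(0), snps, drop = FALSE],
                      cost = svm_cost)
  clin_arm <- NULL
  if (use_clinical) {
    set.seed(seed + 9902L)
    clin_arm <- .svm_arm(as.matrix(cohort$clinical[ids, , drop = FALSE]), y,
                         as.matrix(cohort$clinical[integer(0), , drop = FALSE]),
                         cost = svm_cost)
  }
  list(snps = snps, assoc = assoc, snp_table = tab,
       snp_arm = snp_arm, clin_arm = clin_arm, w = w_star)
}

#' Predict severe-progression probability for new samples
#'
#' Applies the final model (refit on all analysis samples at the selected
#' k* and ensemble weight) to a new cohort. Variants absent from the new
#' cohort are imputed at the training mean dosage; when the fit used
#' clinical data and the new cohort carries the six covariates, the
#' ensemble is applied, otherwise the SNP arm alone is used.
#'
#' @param object a `ragnet_cv` fit.
#' @param newdata an `rg_cohort` (or `rg_genotypes`).
#' @param ... unused.
#' @return named vector of probabilities of severe progression.
#' @export
predict.ragnet_cv <- function(object, newdata, ...) {
  g <- if (inherits(newdata, "rg_cohort")) newdata$genotypes else newdata
  snps <- object$final$snps
  X <- matrix(NA_real_, length(g$sample_ids), length(snps),
              dimnames = list(g$sample_ids, snps))
  found <- intersect(snps, g$variant_ids)
  X[, found] <- g$dosage[, found, drop = FALSE]
  arm <- object$final$snp_arm
  Xs <- .apply_standardize(X, arm$std)
  pr <- stats::predict(arm$fit, Xs, probability = TRUE)
  p_snp <- stats::setNames(attr(pr, "probabilities")[, "1"], g$sample_ids)
  clin_ok <- object$use_clinical && inherits(newdata, "rg_cohort") &&
    !is.null(newdata$clinical) && !is.null(object$final$clin_arm$fit)
  if (!clin_ok) return(p_snp)
  Xc <- .apply_standardize(as.matrix(newdata$clinical[g$sample_ids, ,
                                                      drop = FALSE]),
                           object$final$clin_arm$std)
  prc <- stats::predict(object$final$clin_arm$fit, Xc, probability = TRUE)
  p_clin <- stats::setNames(attr(prc, "probabilities")[, "1"], g$sample_ids)
  ensemble_predict(p_snp, p_clin, object$final$w)
}

#' Transfer a fitted model to an independent cohort
#'
#' Two replication modes. `"snp_set"` carries the selected SNP ids over
#' directly: it reports how many are present in the new cohort, then
#' cross-validates an SNP-arm SVM on the new cohort restricted to the
#' found SNPs. `"full_rerun"` (the primary replication mode) repeats the
#' whole pipeline — association, mapping, network scoring, nested
#' selection — inside the new cohort, SNP arm only (covariate-free
#' association), and reports its cross-validated metrics.
#'
#' @param fit a `ragnet_cv` object.
#' @param cohort_b the replication `rg_cohort`.
#' @param bundle,network annotation bundle and disease network (required
#'   for `full_rerun`; assumed cohort-independent resources).
#' @param mode `"snp_set"` or `"full_rerun"`.
#' @param n_folds,seed cross-validation controls for the new cohort.
#' @param labels_b optional precomputed labels for cohort B.
#' @param ... passed to [ragnet_cv()] in `full_rerun` mode.
#' @return object of class `rg_transfer`: found/missing SNP ids and the
#'   replication metrics (or a refusal when no SNP overlaps).
#' @export
cross_cohort_transfer <- function(fit, cohort_b, bundle = NULL,
                                  network = NULL,
                                  mode = c("snp_set", "full_rerun"),
                                  n_folds = 10L, seed = 1L,
                                  labels_b = NULL, ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "ragnet_cv"), inherits(cohort_b, "rg_cohort"))
  snps <- fit$final$snps
  found <- intersect(snps, cohort_b$genotypes$variant_ids)
  missing <- setdiff(snps, found)
  if (is.null(labels_b))
    labels_b <- classify_progression(cohort_b$shs_baseline,
                                     cohort_b$shs_followup,
                                     cohort_b$xray_interval_years,
                                     mode = "two_xray")
  if (mode == "snp_set") {
    if (!length(found))
      return(structure(list(mode = mode, found = found, missing = missing,
                            refused = TRUE,
                            reason = "no selected SNP present in cohort B"),
                       class = "rg_transfer"))
    plan <- make_folds(labels_b, n_folds, seed)
    ids <- plan$sample
    p <- stats::setNames(rep(NA_real_, length(ids)), ids)
    dos <- cohort_b$genotypes$dosage[ids, found, drop = FALSE]
    for (f in seq_len(n_folds)) {
      tr <- plan$fold != f
      set.seed(seed + 53L * f)
      arm <- .svm_arm(dos[tr, , drop = FALSE], plan$y[tr],
                      dos[!tr, , drop = FALSE])
      p[ids[!tr]] <- arm$prob
    }
    y <- stats::setNames(plan$y, ids)
    fold_acc <- vapply(seq_len(n_folds), function(f)
      accuracy(p[ids[plan$fold == f]] >= 0.5, y[ids[plan$fold == f]]),
      numeric(1))
    res <- list(mean_accuracy = mean(fold_acc), sd_accuracy = stats::sd(fold_acc),
                auc = auc_rank(p, y), probabilities = p)
  } else {
    if (is.null(bundle) || is.null(network))
      stop("full_rerun mode needs the annotation bundle and disease network")
    cvb <- ragnet_cv(cohort_b, bundle, network, strategy = fit$strategy,
                     n_folds = n_folds, seed = seed, use_clinical = FALSE,
                     labels = labels_b, ...)
    res <- list(mean_accuracy = cvb$metrics$mean_accuracy,
                auc = cvb$metrics$auc_ensemble, cv = cvb)
  }
  structure(c(list(mode = mode, found = found, missing = missing,
                   refused = FALSE), res),
            class = "rg_transfer")
}

#' @export
print.rg_transfer <- function(x, ...) {
  cat("Cross-cohort transfer (", x$mode, ")\n", sep = "")
  cat(sprintf("  SNPs found in cohort B: %d; missing: %d\n",
              length(x$found), length(x$missing)))
  if (isTRUE(x$refused)) {
    cat("  refused:", x$reason, "\n")
  } else {
    cat(sprintf("  mean CV accuracy %.4f, AUC %.4f\n",
                x$mean_accuracy, x$auc))
  }
  invisible(x)
}

#' @export
print.ragnet_cv <- function(x, ...) {
  cat("Cross-validated genetic + clinical progression model\n")
  cat(sprintf("  strategy: %s   folds: %d   selected k*: %d   weight w*: %.2f\n",
              x$strategy, attr(x$fold_plan, "n_folds"), x$k_star, x$w_star))
  cat(sprintf("  held-out mean accuracy: %.4f   AUC: %.4f\n",
              x$metrics$mean_accuracy, x$metrics$auc_ensemble))
  invisible(x)
}

#' @export
summary.ragnet_cv <- function(object, ...) {
  m <- object$metrics
  cat("Cross-validated progression model (", object$strategy, ")\n", sep = "")
  cat(sprintf("  analysis samples: %d (%d severe / %d no progression)\n",
              length(object$y), sum(object$y == 1), sum(object$y == 0)))
  cat(sprintf("  selected SNP count k*: %d   ensemble weight w*: %.2f\n",
              object$k_star, object$w_star))
  cat(sprintf("  held-out accuracy: SNP arm %.4f | clinical arm %s | ensemble %.4f\n",
              m$accuracy_snp,
              ifelse(is.na(m$accuracy_clinical), "-",
                     sprintf("%.4f", m$accuracy_clinical)),
              m$accuracy_ensemble))
  cat(sprintf("  held-out AUC:      SNP arm %.4f | clinical arm %s | ensemble %.4f\n",
              m$auc_snp,
              ifelse(is.na(m$auc_clinical), "-",
                     sprintf("%.4f", m$auc_clinical)),
              m$auc_ensemble))
  th <- m$threshold
  cat(sprintf("  at threshold 0.5: sensitivity %.4f, specificity %.4f, PPV %.4f\n",
              th["sensitivity"], th["specificity"], th["ppv"]))
  invisible(object)
}

#' @export
plot.ragnet_cv <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$selection$curve$k, x$selection$curve$mean_accuracy,
                 type = "b", pch = 16, xlab = "SNP count k",
                 ylab = "mean held-out accuracy",
                 main = "SNP-set size selection")
  graphics::abline(v = x$k_star, lty = 2)
  rp <- roc_points(x$probabilities$ensemble, x$y)
  graphics::plot(rp$fpr, rp$tpr, type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC (AUC %.3f)", x$metrics$auc_ensemble))
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
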