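test_that("fold plans are stratified, deterministic, and balanced", {
  y <- stats::setNames(rep(c(0, 1), each = 50), sprintf("s%03d", 1:100))
  p1 <- make_folds(y, 10, seed = 1)
  p2 <- make_folds(y, 10, seed = 1)
  expect_identical(p1, p2)
  tab <- table(p1$fold, p1$y)
  expect_true(all(tab == 5))
  expect_setequal(p1$sample, names(y))

  # unbalanced 61/39: per-fold class counts within one of each other
  yu <- stats::setNames(c(rep(0, 61), rep(1, 39)), sprintf("u%03d", 1:100))
  pu <- make_folds(yu, 10, seed = 2)
  tu <- table(pu$fold, pu$y)
  expect_lte(diff(range(tu[, "0"])), 1)
  expect_lte(diff(range(tu[, "1"])), 1)

  expect_error(make_folds(stats::setNames(c(rep(0, 5), rep(1, 50)),
                                          sprintf("x%02d", 1:55)), 10),
               "fewer")
})

test_that("accuracy and rank AUC match their counting oracles", {
  expect_equal(accuracy(c(1, 0, 1), c(1, 0, 1)), 1.0)
  pred <- c(rep(1, 3), rep(0, 2), rep(1, 2), rep(0, 3))
  lab <- c(rep(1, 3), rep(0, 2), rep(0, 2), rep(1, 3))
  expect_equal(accuracy(pred, lab), 0.5)  # TP=3, TN=2, N=10
  expect_error(accuracy(numeric(0), numeric(0)), "empty")

  expect_equal(auc_rank(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_rank(rep(1, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  set.seed(25)
  for (i in 1:20) {
    s <- sample(1:8, 25, replace = TRUE)  # many ties
    y <- rbinom(25, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc_rank(s, y), oracle_auc(s, y), tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  s <- rnorm(40); y <- rbinom(40, 1, 0.5)
  expect_equal(auc_rank(s, y), auc_rank(exp(3 * s) + 2, y))
})

test_that("DeLong machinery matches hand computation and pROC", {
  # 3 cases (scores 0.9, 0.8, 0.4) vs 3 controls (0.7, 0.3, 0.2):
  # placements computed by hand below
  s <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  y <- c(1, 1, 1, 0, 0, 0)
  v10 <- c(3, 3, 2) / 3          # per-case fraction of controls beaten
  v01 <- c(2, 3, 3) / 3          # per-control fraction of cases above
  expect_equal(auc_variance_delong(s, y),
               stats::var(v10) / 3 + stats::var(v01) / 3, tolerance = 1e-12)

  expect_equal(compare_auc(s, s, y)$p_value, 1)

  skip_if_not_installed("pROC")
  set.seed(6)
  y2 <- rbinom(60, 1, 0.5)
  a <- rnorm(60) + y2
  b <- rnorm(60) + 0.5 * y2
  ours <- compare_auc(a, b, y2)
  ref <- pROC::roc.test(pROC::roc(y2, a, quiet = TRUE),
                        pROC::roc(y2, b, quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-8)
})

test_that("ensemble weighting behaves at the endpoints and on the grid", {
  p_snp <- c(a = 0.9, b = 0.2)
  p_clin <- c(a = 0.4, b = 0.6)
  expect_equal(ensemble_predict(p_snp, p_clin, 0), unname(p_clin[c("a", "b")]),
               ignore_attr = TRUE)
  expect_equal(ensemble_predict(p_snp, p_clin, 1), p_snp)
  # a strongly genetic case downweighted below the decision threshold
  expect_equal(unname(ensemble_predict(c(x = 1.0), c(x = 0.0), 0.27)), 0.27)
  expect_error(ensemble_predict(c(a = 1), c(b = 0), 0.5), "different sample")

  set.seed(3)
  y <- rbinom(40, 1, 0.5)
  ps <- plogis(rnorm(40) + y)
  pc <- plogis(rnorm(40) + 0.5 * y)
  wf <- fit_weight(ps, pc, y, seq(0, 1, 0.01))
  # exhaustive oracle over the same grid
  best <- -1; wbest <- NA
  for (w in seq(0, 1, 0.01)) {
    acc <- mean((w * ps + (1 - w) * pc >= 0.5) == y)
    if (acc > best) { best <- acc; wbest <- w }
  }
  expect_equal(wf$w_star, wbest)
  expect_equal(wf$accuracy, best)
})

test_that("cross-cohort transfer reports overlap and an identity check", {
  st <- small_study()
  sc <- disease_correlation_scores(st$network)
  fit <- ragnet_cv(st$cohort, st$bundle, sc, k_grid = c(10, 15),
                   seed = 5, n_pcs = 4)
  tr <- cross_cohort_transfer(fit, st$cohort, mode = "snp_set", seed = 5)
  expect_setequal(tr$found, fit$final$snps)
  expect_length(tr$missing, 0)
  expect_true(tr$mean_accuracy > 0 && tr$mean_accuracy <= 1)

  # cohort B missing half the selected SNPs: exact set difference reported
  drop <- fit$final$snps[seq(1, length(fit$final$snps), by = 2)]
  g <- st$cohort$genotypes
  keep <- setdiff(g$variant_ids, drop)
  idx <- match(keep, g$variant_ids)
  cb <- st$cohort
  cb$genotypes <- structure(list(dosage = g$dosage[, idx], sample_ids = g$sample_ids,
                                 variant_ids = keep, positions = g$positions[idx],
                                 ref = g$ref[idx], alt = g$alt[idx], chrom = g$chrom),
                            class = "rg_genotypes")
  tr2 <- cross_cohort_transfer(fit, cb, mode = "snp_set", seed = 5)
  expect_setequal(tr2$missing, drop)

  # predictions from the final model cover new samples
  p <- predict(fit, cb)
  expect_length(p, length(g$sample_ids))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("the fitted CV object is deterministic and leakage-free in form", {
  st <- small_study(seed = 6)
  sc <- disease_correlation_scores(st$network)
  f1 <- ragnet_cv(st$cohort, st$bundle, sc, k_grid = c(10, 15),
                  seed = 9, n_pcs = 4)
  f2 <- ragnet_cv(st$cohort, st$bundle, sc, k_grid = c(10, 15),
                  seed = 9, n_pcs = 4)
  expect_identical(f1$probabilities, f2$probabilities)
  expect_identical(f1$k_star, f2$k_star)
  expect_identical(f1$w_star, f2$w_star)
  # metrics computed from held-out predictions only: every analysis sample
  # appears exactly once in the pooled probabilities
  expect_setequal(names(f1$probabilities$ensemble), f1$fold_plan$sample)
  # pooled ensemble accuracy is never below the better single arm
  expect_gte(f1$metrics$accuracy_ensemble,
             max(f1$metrics$accuracy_snp, f1$metrics$accuracy_clinical))
  expect_equal(f1$metrics$mean_accuracy, mean(f1$metrics$fold_accuracy))
})
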