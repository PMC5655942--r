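test_that("progression rates and tertile classes are computed as stated", {
  r <- classify_progression(shs_baseline = 10, shs_followup = 20,
                            interval_years = 2, sample_ids = "a")
  expect_equal(r$rate, 5.0)
  r1 <- classify_progression(total_shs = 30, disease_years = 10,
                             mode = "one_xray", sample_ids = "a")
  expect_equal(r1$rate, 3.0)

  # rates 1..9: lower three no_progression, upper three severe
  lab <- classify_progression(shs_baseline = rep(0, 9),
                              shs_followup = as.numeric(1:9),
                              interval_years = rep(1, 9))
  expect_equal(lab$label[1:3], rep("no_progression", 3))
  expect_equal(lab$label[4:6], rep("excluded", 3))
  expect_equal(lab$label[7:9], rep("severe", 3))

  # nonpositive denominator: excluded with an error record
  bad <- classify_progression(shs_baseline = c(0, 0, 0, 0),
                              shs_followup = c(1, 2, 3, 4),
                              interval_years = c(1, 1, 1, 0))
  expect_equal(bad$label[4], "excluded")
  expect_equal(attr(bad, "errors")$sample, "4")
})

test_that("exact HWE test matches degenerate cases and the enumeration oracle", {
  expect_equal(hwe_exact_p(0, 0, 50), 1)
  expect_equal(hwe_exact_p(25, 50, 25), 1, tolerance = 1e-12)
  expect_error(hwe_exact_p(0, 0, 0), "all-missing")

  set.seed(42)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    cnt <- as.vector(stats::rmultinom(1, n, c(0.3, 0.4, 0.3)))
    expect_equal(hwe_exact_p(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10)
  }
  # (40, 20, 40): strong heterozygote deficit, enumeration oracle
  expect_equal(hwe_exact_p(40, 20, 40), oracle_hwe(40, 20, 40),
               tolerance = 1e-12)
  expect_lt(hwe_exact_p(40, 20, 40), 1e-6)
})

test_that("QC thresholds are inclusive for MAF/call rate, strict for HWE", {
  # 100 samples; one variant with exactly one alternate allele (MAF 0.005)
  dos <- matrix(0L, 100, 3)
  dos[1, 1] <- 1L             # MAF exactly 0.005 -> kept
  dos[, 2] <- 0L              # monomorphic, MAF 0 -> removed
  dos[1:50, 3] <- 1L          # common variant -> kept
  g <- make_genotypes(dos)
  res <- suppressWarnings(qc_filter(g, maf_min = 0.005))
  expect_true(res$report$pass[1])
  expect_false(res$report$pass[2])
  expect_equal(res$report$maf[1], 0.005)

  # perfect equilibrium: p = 1, kept
  dperf <- matrix(c(rep(0L, 25), rep(1L, 50), rep(2L, 25)), ncol = 1)
  rperf <- qc_filter(make_genotypes(cbind(dperf, dperf)))
  expect_equal(rperf$report$hwe_p, c(1, 1), tolerance = 1e-12)

  # removing everything warns rather than failing silently
  expect_warning(qc_filter(make_genotypes(matrix(0L, 10, 2))),
                 "every variant")
})

test_that("QC is idempotent", {
  st <- small_study()
  once <- suppressWarnings(qc_filter(st$cohort$genotypes))
  twice <- suppressWarnings(qc_filter(once$genotypes))
  expect_identical(once$genotypes$variant_ids, twice$genotypes$variant_ids)
  expect_true(all(twice$report$pass))
})

test_that("principal components: duplicates, orthogonality, eigen oracle", {
  set.seed(1)
  dos <- matrix(rbinom(20 * 50, 2, 0.3), 20, 50)
  dos[2, ] <- dos[1, ]  # duplicated samples
  g <- make_genotypes(dos)
  pcs <- suppressWarnings(compute_pcs(g, 5))
  expect_equal(pcs$scores[1, ], pcs$scores[2, ], tolerance = 1e-10)
  xt <- crossprod(pcs$scores)
  expect_lt(max(abs(xt[upper.tri(xt)])), 1e-8)

  # variance along PC1 equals the top eigenvalue of the covariance
  X <- scale(apply(dos, 2, function(x) x))  # no missingness here
  X <- X[, apply(dos, 2, sd) > 0]
  ev <- eigen(stats::cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pcs$sdev[1]^2, ev[1], tolerance = 1e-8)

  expect_warning(compute_pcs(g, 50), "rank")
})

test_that("logistic association matches an independent Newton oracle", {
  # printed genotype-by-outcome table: controls (30, 15, 5), cases (20, 20, 10)
  gt <- c(rep(0L, 30), rep(1L, 15), rep(2L, 5),
          rep(0L, 20), rep(1L, 20), rep(2L, 10))
  y <- c(rep(0, 50), rep(1, 50))
  g <- make_genotypes(matrix(gt, ncol = 1))
  lab <- stats::setNames(y, g$sample_ids)
  a <- logistic_assoc(g, lab)
  # oracle: direct maximum-likelihood fit by BFGS on the log-likelihood
  nll <- function(b) {
    eta <- b[1] + b[2] * gt
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(c(0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(a$beta, opt$par[2], tolerance = 1e-6)
  expect_false(a$flagged)

  # constant genotype column cannot be fit
  gc <- make_genotypes(matrix(1L, 100, 1))
  ac <- logistic_assoc(gc, lab)
  expect_true(ac$flagged)
  expect_true(is.na(ac$p))
  expect_length(attr(ac, "significant"), 0)
})

test_that("association p-values are invariant to sample and variant order", {
  st <- small_study()
  lab <- classify_progression(st$cohort$shs_baseline, st$cohort$shs_followup,
                              st$cohort$xray_interval_years)
  g <- st$cohort$genotypes
  a1 <- logistic_assoc(g, lab)
  set.seed(8)
  sp <- sample(g$sample_ids)
  vp <- sample(seq_along(g$variant_ids))
  g2 <- structure(list(dosage = g$dosage[sp, vp],
                       sample_ids = sp, variant_ids = g$variant_ids[vp],
                       positions = g$positions[vp], ref = g$ref[vp],
                       alt = g$alt[vp], chrom = g$chrom),
                  class = "rg_genotypes")
  a2 <- logistic_assoc(g2, lab)
  expect_equal(a2$p[match(a1$variant, a2$variant)], a1$p, tolerance = 1e-9)
})

test_that("a pure-noise covariate barely moves the evidence", {
  st <- small_study()
  lab <- classify_progression(st$cohort$shs_baseline, st$cohort$shs_followup,
                              st$cohort$xray_interval_years)
  g <- st$cohort$genotypes
  a0 <- logistic_assoc(g, lab)
  set.seed(21)
  noise <- data.frame(z = rnorm(length(g$sample_ids)),
                      row.names = g$sample_ids)
  a1 <- logistic_assoc(g, lab, covariates = noise)
  ok <- !a0$flagged & !a1$flagged
  shift <- abs(-log10(a1$p[ok]) + log10(a0$p[ok]))
  expect_lt(median(shift, na.rm = TRUE), 0.2)
})
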