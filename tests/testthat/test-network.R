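test_that("prior assignment takes the max over disease routes", {
  gda <- data.frame(gene = c("g1", "g1", "g2"),
                    disease = c("d1", "d2", "target"),
                    score = c(0.8, 0.5, 0.7))
  ds <- data.frame(disease = c("d1", "d2", "target"),
                   score = c(0.5, 1.0, 1.0))
  y <- assign_prior(gda, ds, "target", genes = c("g1", "g2", "g3"))
  expect_equal(unname(y["g1"]), 0.5)   # max(0.8*0.5, 0.5*1.0)
  expect_equal(unname(y["g2"]), 0.7)   # direct target association
  expect_equal(unname(y["g3"]), 0)     # no GDA entry

  expect_error(assign_prior(data.frame(gene = "g", disease = "target",
                                       score = 1.2), ds, "target"), "0, 1")
  expect_error(assign_prior(gda, ds, "absent"), "absent")
})

test_that("prior assignment equals the exhaustive max oracle", {
  set.seed(77)
  genes <- sprintf("g%02d", 1:50)
  dis <- c("target", sprintf("d%d", 1:4))
  gda <- data.frame(gene = sample(genes, 120, replace = TRUE),
                    disease = sample(dis, 120, replace = TRUE),
                    score = round(runif(120), 3))
  ds <- data.frame(disease = dis, score = c(1, round(runif(4), 3)))
  y <- assign_prior(gda, ds, "target", genes = genes)
  for (g in genes) {
    rows <- gda[gda$gene == g, ]
    exp_y <- 0
    for (i in seq_len(nrow(rows)))
      exp_y <- max(exp_y, rows$score[i] * ds$score[ds$disease == rows$disease[i]])
    expect_equal(unname(y[g]), exp_y, tolerance = 1e-12)
  }
})

test_that("degree-symmetric normalization has the expected closed forms", {
  W2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(normalize_adjacency(W2), W2)

  # star K(1,3): center-leaf entries 1/sqrt(3)
  Ws <- matrix(0, 4, 4)
  Ws[1, 2:4] <- Ws[2:4, 1] <- 1
  Wn <- normalize_adjacency(Ws)
  expect_equal(Wn[1, 2], 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(Wn[2, 3], 0)

  set.seed(5)
  A <- matrix(rbinom(144, 1, 0.3), 12)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- 0
  ev <- eigen(normalize_adjacency(A), symmetric = TRUE,
              only.values = TRUE)$values
  expect_lte(max(ev), 1 + 1e-10)

  expect_error(normalize_adjacency(matrix(c(0, -1, -1, 0), 2)),
               "nonnegative")
})

test_that("propagation reaches the closed-form fixed point", {
  # null prior
  W2 <- matrix(c(0, 1, 1, 0), 2)
  f0 <- propagate(W2, c(0, 0), alpha = 0.5)
  expect_equal(unname(f0$F), c(0, 0))

  # two-node worked case: (1-a)(I - a W)^(-1) Y = (2/3, 1/3)
  f <- propagate(W2, c(1, 0), alpha = 0.5)
  expect_equal(unname(f$F), c(2 / 3, 1 / 3), tolerance = 1e-8)

  # random graph vs direct linear solve
  set.seed(9)
  A <- matrix(rbinom(900, 1, 0.15), 30)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- 0
  Wn <- normalize_adjacency(A)
  Y <- runif(30) * rbinom(30, 1, 0.4)
  ours <- propagate(Wn, Y, alpha = 0.5, tol = 1e-12)$F
  oracle <- 0.5 * solve(diag(30) - 0.5 * Wn, Y)
  expect_equal(unname(ours), unname(oracle), tolerance = 1e-8)
  expect_true(all(ours >= 0.5 * Y - 1e-12))  # F >= (1-alpha) Y
})

test_that("propagation invariants: monotonicity, alpha limit, permutation, zero components", {
  set.seed(13)
  A <- matrix(rbinom(400, 1, 0.2), 20)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- 0
  Wn <- normalize_adjacency(A)
  Y <- runif(20) * rbinom(20, 1, 0.5)
  f1 <- propagate(Wn, Y, alpha = 0.5, tol = 1e-12)$F
  Y2 <- Y; Y2[3] <- Y2[3] + 0.5
  f2 <- propagate(Wn, Y2, alpha = 0.5, tol = 1e-12)$F
  expect_true(all(f2 >= f1 - 1e-12))

  small <- propagate(Wn, Y, alpha = 1e-8, tol = 1e-14)$F
  expect_equal(unname(small), unname(Y), tolerance = 1e-6)

  perm <- sample(20)
  fp <- propagate(Wn[perm, perm], Y[perm], alpha = 0.5, tol = 1e-12)$F
  expect_equal(unname(fp), unname(f1[perm]), tolerance = 1e-9)

  # two disconnected components; prior only in the first
  B <- matrix(0, 4, 4)
  B[1, 2] <- B[2, 1] <- 1
  B[3, 4] <- B[4, 3] <- 1
  fz <- propagate(normalize_adjacency(B), c(1, 0, 0, 0), alpha = 0.5)$F
  expect_equal(unname(fz[3:4]), c(0, 0))
})

test_that("wrapper scores a simulated network end to end", {
  st <- small_study()
  sc <- disease_correlation_scores(st$network)
  expect_s3_class(sc, "rg_scores")
  expect_length(sc$F, length(st$network$genes))
  expect_true(all(sc$F >= 0))
  # genes with positive prior keep at least (1-alpha) of it
  y <- assign_prior(st$network$gda, st$network$ds, st$network$target,
                    genes = st$network$genes)
  expect_true(all(sc$F >= (1 - sc$alpha) * y - 1e-9))

  sens <- alpha_sensitivity(st$network, c(0.3, 0.7))
  expect_equal(dim(sens$scores), c(length(st$network$genes), 2L))
  expect_gt(sens$rank_correlation[1, 2], 0.5)
})
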