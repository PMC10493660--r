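make_cov_table <- function(n, seed = 1) {
  set.seed(seed)
  covariate_table(data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    age = runif(n, 20, 70),
    gender = rbinom(n, 1, 0.5),
    education = runif(n, 0, 18)))
}

test_that("residualization centers columns, is idempotent, and recovers zero-beta data", {
  cfg <- scn_sim_config(n_per_group = 300, n_rois = 15, n_factors = 3,
                        covariate_betas = c(age = 0, gender = 0, education = 0),
                        deficit_mm = 0, hub_loading_delta = 0, seed = 21)
  ds <- scn_simulate(cfg)
  rt <- residualize(ds$thickness, ds$covariates)

  expect_lt(max(abs(colMeans(rt$values))), 1e-10)
  # with no true covariate effect, residuals barely differ from centering
  cors <- vapply(seq_len(ncol(rt$values)), function(j)
    cor(rt$values[, j], ds$thickness$values[, j]), numeric(1))
  expect_true(all(cors > 0.99))

  # idempotence
  rt2 <- residualize(rt, ds$covariates)
  expect_lt(max(abs(rt2$values - rt$values)) / max(abs(rt$values)), 1e-10)
})

test_that("residualization is exact in degenerate designs and flags rank deficiency", {
  # covariates orthogonal to the column by construction: residual = centered column
  covs <- covariate_table(data.frame(
    subject_id = sprintf("s%03d", 1:6),
    age = c(-1, 1, -1, 1, -1, 1),
    gender = c(1, -1, -1, 1, 0, 0) * 1.0,
    education = c(0, 0, 1, -1, -1, 1)))
  y <- c(5, 5, 6, 6, 7, 7)  # centered y is orthogonal to every covariate
  tt <- thickness_table(cbind(A = y, B = y + 1), rep(c("g1", "g2"), 3),
                        subject_id = covs$subject_id)
  rt <- residualize(tt, covs)
  expect_equal(unname(rt$values[, "A"]), y - mean(y), tolerance = 1e-12)

  # saturated design: n = 4, intercept + 3 covariates => residuals all zero
  covs4 <- covariate_table(data.frame(
    subject_id = sprintf("s%03d", 1:4), age = c(1, 2, 3, 5),
    gender = c(0, 1, 0, 1) * 1.0, education = c(2, 7, 1, 9)))
  tt4 <- thickness_table(matrix(2 + runif(8), 4, 2), c("a", "a", "b", "b"),
                         subject_id = covs4$subject_id)
  rt4 <- residualize(tt4, covs4)
  expect_lt(max(abs(rt4$values)), 1e-10)

  # constant covariate names the culprit
  covs_bad <- covariate_table(data.frame(
    subject_id = sprintf("s%03d", 1:6), age = runif(6),
    gender = rep(1.0, 6), education = runif(6)))
  tt6 <- thickness_table(matrix(2 + runif(12), 6, 2), rep(c("a", "b"), 3),
                         subject_id = covs_bad$subject_id)
  expect_error(residualize(tt6, covs_bad), "gender")
})

test_that("results are invariant to affine recoding of a covariate", {
  cfg <- scn_sim_config(n_per_group = 15, n_rois = 8, n_factors = 2,
                        planted_hub_rois = integer(0), deficit_rois = integer(0),
                        seed = 31)
  ds <- scn_simulate(cfg)
  covs2 <- ds$covariates
  covs2$gender <- 2 * covs2$gender + 1  # 0/1 -> 1/3
  r1 <- residualize(ds$thickness, ds$covariates)
  r2 <- residualize(ds$thickness, covariate_table(covs2))
  expect_equal(r1$values, r2$values, tolerance = 1e-10)
})

test_that("per-ROI Welch test matches a textbook oracle and handles edge cases", {
  # hand-checkable example: {1,2,3} vs {4,5,6}
  tt <- tt_from_matrices(matrix(c(1, 2, 3) + 1, 3, 1),
                         matrix(c(4, 5, 6) + 1, 3, 1))
  res <- roi_group_test(tt)
  expect_equal(abs(res$t), 3.674, tolerance = 1e-3)
  expect_equal(res$df, 4, tolerance = 1e-9)
  expect_equal(res$p, 0.0213, tolerance = 1e-3)

  # oracle equivalence on random 5-subject inputs
  set.seed(42)
  for (i in 1:20) {
    m1 <- matrix(2 + runif(15), 5, 3)
    m2 <- matrix(2 + runif(15), 5, 3)
    res <- roi_group_test(tt_from_matrices(m1, m2))
    for (j in 1:3) {
      o <- oracle_welch(m1[, j], m2[, j])
      expect_equal(res$t[j], o$t, tolerance = 1e-12)
      expect_equal(res$p[j], o$p, tolerance = 1e-12)
    }
  }

  # identical samples: t = 0, p = 1; zero variance in both groups is flagged
  m <- matrix(2 + runif(6), 3, 2)
  res0 <- roi_group_test(tt_from_matrices(m, m))
  expect_true(all(res0$t == 0))
  expect_true(all(res0$p == 1))
  cm <- matrix(2, 3, 1)
  resz <- roi_group_test(tt_from_matrices(cm, cm))
  expect_true(resz$zero_variance)
  expect_equal(resz$p, 1)
})

test_that("planted deficits reach high significance at study-like sample size", {
  cfg <- scn_sim_config(n_per_group = 45, n_rois = 30, n_factors = 3,
                        deficit_rois = c(5L, 6L), deficit_mm = 4 * 0.15,
                        hub_loading_delta = 0, seed = 8)
  ds <- scn_simulate(cfg)
  res <- roi_group_test(residualize(ds$thickness, ds$covariates))
  expect_true(all(res$p[c(5, 6)] < 0.001))
})

test_that("partial correlation reduces to Pearson without covariates and is exact in corners", {
  set.seed(5)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  pc <- partial_correlation(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate), tolerance = 1e-10)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-10)

  # x = y with zero-effect covariates: r = 1
  covs <- matrix(rnorm(60), 30, 2)
  expect_equal(partial_correlation(x, x, covs)$r, 1, tolerance = 1e-12)

  # x orthogonalized against y within residual space: r = 0
  X <- cbind(1, covs)
  rx <- qr.resid(qr(X), x)
  ry <- qr.resid(qr(X), y)
  x_orth <- rx - sum(rx * ry) / sum(ry * ry) * ry
  expect_lt(abs(partial_correlation(x_orth, y, covs)$r), 1e-10)

  expect_error(partial_correlation(x[1:4], y[1:4], covs[1:4, ]), "n > k")
})
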