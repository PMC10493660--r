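test_that("AUC is the trapezoidal integral over the density grid", {
  g <- density_grid(360)  # 0.02 .. 0.47, 46 points
  expect_equal(metric_auc(rep(3, 46), g), 3 * 0.45, tolerance = 1e-12)
  expect_equal(metric_auc(seq(0, 1, length.out = 46), g), 0.225,
               tolerance = 1e-12)

  g2 <- density_grid(360, d_max = 0.03)
  expect_equal(metric_auc(c(0, 1), g2), 0.005, tolerance = 1e-12)

  expect_error(metric_auc(rep(1, 10), g), "one value per density")
  expect_error(metric_auc(c(rep(1, 45), NA), g), "finite")
})

test_that("FDR correction reproduces the Benjamini-Hochberg step-up rule", {
  expect_equal(fdr_correct(c(0.001, 0.2, 0.9)), c(TRUE, FALSE, FALSE))
  expect_equal(fdr_correct(rep(1, 5)), rep(FALSE, 5))
  m <- 7
  expect_equal(fdr_correct(rep(0.05 / m, m)), rep(TRUE, m))
  # monotone: lowering a p-value never removes discoveries
  p <- c(0.01, 0.02, 0.04, 0.2)
  d1 <- fdr_correct(p)
  p2 <- p; p2[4] <- 0.001
  expect_true(all(fdr_correct(p2)[d1]))
  expect_error(fdr_correct(numeric(0)), "empty")
  expect_error(fdr_correct(c(0.5, 0)), "p-values")
})

null_dataset <- function(seed, n = 12, rois = 24) {
  cfg <- scn_sim_config(n_per_group = n, n_rois = rois, n_factors = 3,
                        deficit_mm = 0, hub_loading_delta = 0, seed = seed)
  scn_simulate(cfg)
}

test_that("permutation inference is deterministic and invariant to row order", {
  ds <- null_dataset(3)
  rt <- residualize(ds$thickness, ds$covariates)
  g <- density_grid(24, d_max = 0.3)
  c1 <- scn_compare(rt, grid = g, metrics = c("eglob", "degree"),
                    n_perm = 60, seed = 10)
  c2 <- scn_compare(rt, grid = g, metrics = c("eglob", "degree"),
                    n_perm = 60, seed = 10)
  expect_equal(c1$results, c2$results)

  # shuffle subject rows: identical results
  idx <- sample(nrow(rt$values))
  rt_shuf <- thickness_table(rt$values[idx, ], rt$group[idx],
                             subject_id = rt$subject_id[idx],
                             residualized = TRUE)
  c3 <- scn_compare(rt_shuf, grid = g, metrics = c("eglob", "degree"),
                    n_perm = 60, seed = 10)
  expect_equal(c1$results, c3$results)
})

test_that("permutation p-values obey the add-one estimator bounds", {
  ds <- null_dataset(5)
  rt <- residualize(ds$thickness, ds$covariates)
  g <- density_grid(24, d_max = 0.3)
  cmp <- scn_compare(rt, grid = g,
                     metrics = c("eglob", "eloc", "cp", "lp", "degree"),
                     n_perm = 99, seed = 2)
  expect_true(all(cmp$results$p >= 1 / 100))
  expect_true(all(cmp$results$p <= 1))
  # CI rule consistency
  with(cmp$results, expect_equal(significant, diff < ci_low | diff > ci_high))
})

test_that("null permutation p-values are approximately uniform", {
  ps <- vapply(1:40, function(s) {
    ds <- null_dataset(400 + s, n = 10, rois = 20)
    rt <- residualize(ds$thickness, ds$covariates)
    g <- density_grid(20, d_max = 0.35)
    cmp <- scn_compare(rt, grid = g, metrics = c("eglob", "cp"),
                       n_perm = 99, seed = s)
    cmp$results$p
  }, numeric(2))
  ks <- suppressWarnings(ks.test(as.numeric(ps), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("sigma can be included in permutation inference with a reusable null", {
  ds <- null_dataset(6, n = 14, rois = 20)
  rt <- residualize(ds$thickness, ds$covariates)
  g <- density_grid(20, d_max = 0.3, step = 0.05)
  cmp <- scn_compare(rt, grid = g, metrics = "sigma", n_perm = 40, seed = 4,
                     sigma_n_random = 5, sigma_null = "reuse")
  res <- cmp$results
  expect_equal(res$metric, "sigma")
  expect_true(is.finite(res$diff))
  expect_true(res$p > 0 && res$p <= 1)
  # deterministic under the same seed
  cmp2 <- scn_compare(rt, grid = g, metrics = "sigma", n_perm = 40, seed = 4,
                      sigma_n_random = 5, sigma_null = "reuse")
  expect_equal(cmp$results, cmp2$results)
})

test_that("guards: too few permutations, unknown metrics, tiny groups", {
  ds <- null_dataset(7, n = 6, rois = 10)
  rt <- residualize(ds$thickness, ds$covariates)
  expect_error(scn_compare(rt, n_perm = 10), "40")
  expect_error(scn_compare(rt, metrics = "pagerank", n_perm = 50), "pagerank")
})
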