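pool <- default_pool()

test_that("run_test dispatches the configured datum", {
  gs <- draw_groups(pool, n = 5, m = 60, seed = 91)
  # identical groups: t and u tests return p = 1, no rejection
  for (nm in c("t_test", "u_test")) {
    res <- run_test(test_spec(nm, alpha = 0.01), gs$control, gs$control,
                    "length")
    expect_equal(res$p.value, 1)
    expect_false(res$reject)
  }
  res_ks <- run_test(test_spec("ks_test", alpha = 0.01), gs$control,
                     gs$control, "length")
  expect_equal(res_ks$p.value, 1)
  expect_error(test_spec("ks_test", datum = "per_sample_mean"),
               "inconsistent")
  expect_error(test_spec("t_test", alpha = 1.5), "alpha")
})

test_that("binary fraction test requires (or inherits) an area threshold", {
  gs <- draw_groups(pool, n = 4, m = 30, seed = 92)
  expect_error(run_test(test_spec("binary_fraction"), gs$control,
                        gs$treatment, "area"),
               "binary_area_threshold")
  cfg <- experiment_config(pool, n = 4, m = 30, variable = "area",
                           change = change_model("linear_growth",
                                                 variable = "area",
                                                 factor = 1.2),
                           test = test_spec("binary_fraction"))
  expect_equal(cfg$test$thresholds$binary_area_threshold,
               median(pool$area))
  expect_type(run_single_experiment(cfg, seed = 1)$reject, "logical")
})

test_that("single experiment runs are reproducible per seed", {
  cfg <- experiment_config(pool, n = 6, m = 60, variable = "head_width",
                           change = change_model("linear_growth",
                                                 variable = "head_width",
                                                 factor = 1.2),
                           test = test_spec("t_test", alpha = 0.01))
  r1 <- run_single_experiment(cfg, seed = 10)
  r2 <- run_single_experiment(cfg, seed = 10)
  expect_identical(r1, r2)
  expect_true(is.numeric(r1$p.value))
})

test_that("an extreme effect is detected essentially always", {
  cfg <- experiment_config(pool, n = 8, m = 60, variable = "length",
                           change = change_model("linear_growth",
                                                 variable = "length",
                                                 factor = 10),
                           test = test_spec("t_test", alpha = 0.01))
  est <- estimate_fnr(cfg, runs = 100, seed = 1)
  expect_equal(est$rate, 0)
})

test_that("a no-op change leaves the null rejection rate at alpha", {
  cfg <- experiment_config(pool, n = 8, m = 30, variable = "length",
                           change = change_model("linear_growth",
                                                 variable = "length",
                                                 factor = 1.0),
                           test = test_spec("t_test", alpha = 0.01))
  est <- estimate_fnr(cfg, runs = 600, seed = 2)
  expect_gt(est$rate, 0.95)   # ~ 1 - alpha
})

test_that("estimates are identical under the same master seed and close under different ones", {
  cfg <- experiment_config(pool, n = 5, m = 60, variable = "head_width",
                           change = change_model("linear_growth",
                                                 variable = "head_width",
                                                 factor = 1.2),
                           test = test_spec("t_test", alpha = 0.01))
  e1 <- estimate_fnr(cfg, runs = 400, seed = 3)
  e2 <- estimate_fnr(cfg, runs = 400, seed = 3)
  expect_identical(e1, e2)
  e3 <- estimate_fnr(cfg, runs = 400, seed = 4)
  se <- sqrt(e1$rate * (1 - e1$rate) / 400 + e3$rate * (1 - e3$rate) / 400)
  expect_lt(abs(e1$rate - e3$rate), 4 * se + 0.02)
})

test_that("false negative rate is non-increasing in n (CI-aware)", {
  rates <- sapply(c(4, 8, 16), function(n) {
    cfg <- experiment_config(pool, n = n, m = 60, variable = "head_width",
                             change = change_model("linear_growth",
                                                   variable = "head_width",
                                                   factor = 1.1),
                             test = test_spec("t_test", alpha = 0.01))
    estimate_fnr(cfg, runs = 400, seed = 5)$rate
  })
  for (i in 1:2) {
    se <- sqrt(sum(rates[i:(i + 1)] * (1 - rates[i:(i + 1)])) / 400)
    expect_gt(rates[i] - rates[i + 1], -2 * se)
  }
  expect_gt(rates[1], rates[3])
})

test_that("t-test and exact u-test keep their nominal / exact null size", {
  cfg <- experiment_config(pool, n = 8, m = 30, variable = "area",
                           test = test_spec("t_test", alpha = 0.05))
  est <- estimate_fpr(cfg, runs = 2000, seed = 6)
  expect_lt(est$ci95["low"], 0.05)
  expect_gt(est$ci95["high"], 0.05)

  cfg_u <- experiment_config(pool, n = 8, m = 30, variable = "area",
                             test = test_spec("u_test", alpha = 0.05))
  est_u <- estimate_fpr(cfg_u, runs = 2000, seed = 7)
  size <- exact_u_test_size(8, 8, 0.05)
  expect_lte(size, 0.05)
  expect_lt(est_u$ci95["low"], size + 1e-12)
  expect_gt(est_u$ci95["high"], size - 1e-12)
})

test_that("minimal-n search returns small n for strong effects and scans upward", {
  cfg <- experiment_config(pool, n = 2, m = 60, variable = "head_width",
                           change = change_model("linear_growth",
                                                 variable = "head_width",
                                                 factor = 3),
                           test = test_spec("t_test", alpha = 0.01))
  res <- find_min_samples(cfg, runs = 300, seed = 8)
  expect_lte(res$n, 3)
  expect_s3_class(res$fnr, "error_rate_estimate")
  expect_lte(res$fnr$rate, 0.05)
})

test_that("minimal n does not grow when m doubles (within MC noise)", {
  min_n <- sapply(c(30, 60), function(m) {
    cfg <- experiment_config(pool, n = 2, m = m, variable = "head_width",
                             change = change_model("linear_growth",
                                                   variable = "head_width",
                                                   factor = 1.5),
                             test = test_spec("t_test", alpha = 0.01))
    find_min_samples(cfg, runs = 400, seed = 9)$n
  })
  expect_lte(min_n[2], min_n[1] + 1)
})

test_that("power_table emits one row per grid cell with manifest", {
  tab <- suppressMessages(
    power_table(pool, magnitudes = 1.5, alphas = 0.01,
                variables = "head_width", m = 60, runs = 200L, seed = 10))
  expect_equal(nrow(tab), 1L)
  expect_true(!is.na(tab$min_n))
  expect_s3_class(attr(tab, "manifest"), "run_manifest")
})

test_that("sigma sweep is flat at zero and inflates the K-S rate at m = 60", {
  tab <- fpr_sigma_sweep(pool, sigmas = c(0, 0.15), n = 4, m = 60,
                         alpha = 0.01, runs = 800, seed = 11)
  flat <- tab$rate[tab$sigma == 0]
  infl <- tab$rate[tab$sigma == 0.15]
  expect_lt(flat, 0.04)
  expect_gt(infl, flat)
})

test_that("estimator guardrails reject inconsistent configurations", {
  cfg <- experiment_config(pool, n = 4, m = 30, variable = "length")
  expect_error(estimate_fnr(cfg, runs = 10, seed = 1), "non-`none`")
  cfg2 <- experiment_config(pool, n = 4, m = 30, variable = "length",
                            change = change_model("linear_growth",
                                                  variable = "length",
                                                  factor = 1.5))
  expect_error(estimate_fpr(cfg2, runs = 10, seed = 1),
               "systematic_perturbation")
})
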