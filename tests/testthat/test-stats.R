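test_that("t-test matches the closed-form worked example and base R", {
  res <- students_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4)
  expect_equal(res$p.value, 0.0213, tolerance = 1e-2)

  set.seed(71)
  for (i in 1:10) {
    x <- rnorm(sample(3:20, 1)); y <- rnorm(sample(3:20, 1), mean = 0.5)
    expect_equal(students_t_test(x, y)$p.value,
                 t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-12)
    expect_equal(students_t_test(x, y)$p.value,
                 students_t_test(y, x)$p.value)
  }
})

test_that("t-test degenerate conventions", {
  expect_equal(students_t_test(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_equal(students_t_test(c(2, 2, 2), c(2, 2))$p.value, 1)
  expect_equal(students_t_test(c(2, 2, 2), c(3, 3, 3))$p.value,
               .Machine$double.xmin)
  expect_error(students_t_test(1, c(1, 2)), ">= 2")
})

test_that("exact u-test equals full enumeration on all small tie-free inputs", {
  set.seed(72)
  for (i in 1:40) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    repeat {
      x <- round(rnorm(n1), 6); y <- round(rnorm(n2), 6)
      if (!anyDuplicated(c(x, y))) break
    }
    res <- exact_mann_whitney_test(x, y)
    expect_true(res$exact)
    expect_equal(res$p.value, brute_mann_whitney_p(x, y),
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("exact u-test agrees with wilcox.test on tie-free data", {
  set.seed(73)
  for (i in 1:20) {
    x <- rnorm(sample(2:10, 1)); y <- rnorm(sample(2:10, 1), 0.8)
    expect_equal(exact_mann_whitney_test(x, y)$p.value,
                 suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value),
                 tolerance = 1e-12)
  }
})

test_that("fully separated samples attain the minimal two-tailed p", {
  res7 <- exact_mann_whitney_test(1:7, 8:14)
  expect_equal(res7$p.value, 2 / 3432)
  res6 <- exact_mann_whitney_test(1:6, 7:12)
  expect_equal(res6$p.value, 2 / 924)
  expect_gt(res6$p.value, 0.001)   # no positive outcome possible at n = 6
  expect_lt(res7$p.value, 0.001)
  expect_equal(exact_mann_whitney_test(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
})

test_that("minimal attainable p matches enumeration and brackets alpha = 0.001", {
  expect_equal(min_attainable_p_u_test(6, 6), 2 / 924)
  expect_equal(min_attainable_p_u_test(7, 7), 2 / 3432)
  expect_equal(min_attainable_p_u_test(1, 1), 1)
  for (n in 2:8) {
    sep <- exact_mann_whitney_test(seq_len(n), n + seq_len(n))
    expect_equal(sep$p.value, min_attainable_p_u_test(n, n))
  }
  expect_true(all(sapply(2:6, function(n) min_attainable_p_u_test(n, n)) >
                    0.001))
  expect_true(all(sapply(7:12, function(n) min_attainable_p_u_test(n, n)) <=
                    0.001))
})

test_that("large-sample u-test falls back to a calibrated normal approximation", {
  set.seed(74)
  x <- rnorm(30); y <- rnorm(30)
  res <- exact_mann_whitney_test(x, y)
  expect_false(res$exact)
  expect_equal(res$p.value,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("K-S statistic and p-value behave on canonical cases", {
  same <- ks_two_sample(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  disjoint <- ks_two_sample(c(0, 0.1, 0.2), c(1, 1.1, 1.2))
  expect_equal(disjoint$statistic, 1)

  set.seed(75)
  a <- rnorm(300); b <- rnorm(300)
  expect_equal(ks_two_sample(a, b)$statistic,
               unname(suppressWarnings(ks.test(a, b)$statistic)))
  expect_equal(ks_two_sample(a, b)$p.value,
               ks.test(a, b, exact = FALSE)$p.value, tolerance = 1e-6)

  small_a <- rnorm(8); small_b <- rnorm(9)
  expect_equal(ks_two_sample(small_a, small_b)$p.value,
               ks.test(small_a, small_b, exact = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("K-S null rejection rate is calibrated at the asymptotic branch", {
  set.seed(76)
  rej <- 0
  runs <- 1500
  for (i in seq_len(runs)) {
    if (ks_two_sample(rnorm(300), rnorm(300))$p.value < 0.05) rej <- rej + 1
  }
  ci <- wilson_interval(rej, runs)
  expect_lt(ci["low"], 0.05)
  expect_gt(ci["high"], 0.03)
  expect_lt(rej / runs, 0.08)
})

test_that("p-values are symmetric in the group order", {
  set.seed(77)
  x <- rnorm(8); y <- rnorm(8, 0.6)
  expect_equal(exact_mann_whitney_test(x, y)$p.value,
               exact_mann_whitney_test(y, x)$p.value)
  expect_equal(ks_two_sample(x, y)$p.value, ks_two_sample(y, x)$p.value)
})

test_that("Wilson interval brackets the point estimate and stays in [0,1]", {
  ci <- wilson_interval(3, 1000)
  expect_true(ci["low"] < 3 / 1000 && 3 / 1000 < ci["high"])
  expect_gte(wilson_interval(0, 50)["low"], 0)
  expect_lte(wilson_interval(50, 50)["high"], 1)
})
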