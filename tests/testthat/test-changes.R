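group_of <- function(pop, n = 4, m = 30, seed = 51) {
  draw_groups(pop, n, m, seed = seed)$treatment
}

test_that("linear growth scales exactly one variable multiplicatively", {
  g <- group_of(default_pool())
  expect_identical(apply_linear_growth(g, "length", 1.0), g)

  g1 <- apply_linear_growth(g, "head_width", 1.5)
  expect_equal(g1$head_width, g$head_width * 1.5)
  expect_identical(g1$length, g$length)
  expect_identical(g1$area, g$area)

  # 0.50 um head grows to 0.75 um under 50% growth
  g2 <- spinesim:::new_spine_group(2, 2, length = rep(1, 4),
                                   head_width = rep(0.5, 4),
                                   neck_width = rep(0.3, 4),
                                   area = rep(0.4, 4))
  expect_equal(apply_linear_growth(g2, "head_width", 1.5)$head_width,
               rep(0.75, 4))

  twice <- apply_linear_growth(apply_linear_growth(g, "length", 1.1),
                               "length", 1.1)
  once <- apply_linear_growth(g, "length", 1.21)
  expect_equal(twice$length, once$length)
  expect_error(apply_linear_growth(g, "girth", 2), "variable")
})

test_that("head swelling is linear growth restricted to head width", {
  g <- group_of(default_pool())
  expect_identical(apply_head_swelling(g, 1.3),
                   apply_linear_growth(g, "head_width", 1.3))
})

test_that("small-spine growth uses pre-change membership", {
  g <- spinesim:::new_spine_group(1, 3, length = rep(1, 3),
                                  head_width = rep(0.5, 3),
                                  neck_width = rep(0.3, 3),
                                  area = c(0.5, 0.9, 0.79))
  out <- apply_small_spine_growth(g, area_threshold = 0.8, factor = 1.5)
  expect_equal(out$area, c(0.75, 0.9, 1.185))
})

test_that("filopodia elimination keeps m and empties the tail at p = 1", {
  pool <- default_pool()
  g <- group_of(pool, n = 3, m = 50)
  expect_identical(
    apply_filopodia_elimination(g, pool, p_elim = 0, seed = 1), g)

  gone <- apply_filopodia_elimination(g, pool, length_threshold = 2,
                                      p_elim = 1, seed = 1)
  expect_length(gone$length, 150L)
  expect_true(all(gone$length <= 2))

  e1 <- apply_filopodia_elimination(g, pool, seed = 9)
  e2 <- apply_filopodia_elimination(g, pool, seed = 9)
  expect_identical(e1, e2)
})

test_that("surviving long-spine fraction matches the renewal closed form", {
  pool <- default_pool()
  q <- mean(pool$length > 2)
  p <- 0.5
  expected <- q * (1 - p) / (1 - p * q)

  # brute-force oracle: simulate the accept/redraw chain directly
  set.seed(61)
  draws <- sample(pool$length, 2e5, replace = TRUE)
  keep <- draws <= 2 | runif(2e5) >= p
  oracle <- mean(draws[keep] > 2)
  expect_equal(oracle, expected, tolerance = 0.05)

  g <- draw_groups(pool, n = 20, m = 500, seed = 62)$treatment
  out <- apply_filopodia_elimination(g, pool, p_elim = p, seed = 63)
  expect_equal(mean(out$length > 2), expected, tolerance = 0.08)
})

test_that("below-threshold replacement mode never draws long spines", {
  pool <- default_pool()
  g <- group_of(pool, n = 3, m = 40)
  out <- apply_filopodia_elimination(g, pool, p_elim = 1, seed = 2,
                                     replacement_from = "below_threshold")
  expect_true(all(out$length <= 2))
})

test_that("systematic perturbation applies one shared factor per sample", {
  g <- group_of(default_pool(), n = 6, m = 25)
  expect_identical(apply_systematic_perturbation(g, "area", 0), g)

  out <- apply_systematic_perturbation(g, "area", 0.1, seed = 3)
  ratio <- out$area / g$area
  by_sample <- matrix(ratio, nrow = 25)
  expect_equal(apply(by_sample, 2, function(r) diff(range(r))),
               rep(0, 6), tolerance = 1e-12)
  expect_identical(out$length, g$length)
})

test_that("per-sample factors have the configured spread", {
  g <- spinesim:::new_spine_group(10000, 1, length = rep(1, 10000),
                                  head_width = rep(0.5, 10000),
                                  neck_width = rep(0.3, 10000),
                                  area = rep(0.4, 10000))
  out <- apply_systematic_perturbation(g, "length", 0.1, seed = 4)
  factors <- out$length
  expect_equal(mean(factors), 1, tolerance = 0.01)
  expect_equal(sd(factors), 0.1, tolerance = 0.05)
})

test_that("change models preserve spine count and positivity", {
  pool <- default_pool()
  g <- group_of(pool, n = 4, m = 35)
  for (ch in list(change_model("linear_growth", variable = "length",
                               factor = 1.2),
                  change_model("small_spine_growth"),
                  change_model("filopodia_elimination"),
                  change_model("systematic_perturbation",
                               variable = "area", sigma = 0.15))) {
    out <- apply_change(ch, g, pool, seed = 5)
    expect_length(out$length, 140L)
    for (v in c("length", "head_width", "neck_width", "area")) {
      expect_true(all(is.finite(out[[v]]) & out[[v]] > 0))
    }
  }
})
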