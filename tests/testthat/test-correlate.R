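test_that("pearson_test matches analytic cases and is affine-invariant", {
  x <- 1:10
  out <- pearson_test(x, 2 * x)
  expect_equal(out$r, 1)
  # affine transforms of either variable leave r unchanged (up to sign of scale)
  y <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  r0 <- pearson_test(x, y)$r
  expect_equal(pearson_test(5 * x - 2, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_test(x, 0.1 * y + 7)$r, r0, tolerance = 1e-12)
  # zero variance is reported as undefined, not an error
  und <- pearson_test(rep(1, 5), y[1:5])
  expect_true(is.na(und$r))
  expect_match(und$note, "zero variance")
  expect_error(pearson_test(1:2, 1:2), "3")
})

test_that("pearson estimate is unbiased against a Monte-Carlo oracle at rho = 0.9", {
  rho <- 0.9; n <- 15; B <- 1000
  withr::with_seed(31, {
    rs <- replicate(B, {
      x <- rnorm(n)
      y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
      pearson_test(x, y)$r
    })
  })
  # E[r] for bivariate normal: rho * (1 - (1-rho^2)/(2n)) + O(n^-2)
  expected <- rho * (1 - (1 - rho^2) / (2 * n))
  expect_lt(abs(mean(rs) - expected), 0.03)
})

test_that("null x-y pairs are usually non-significant", {
  withr::with_seed(32, {
    p_vals <- replicate(60, pearson_test(rnorm(15), rnorm(15))$p_value)
  })
  expect_gt(mean(p_vals > 0.05), 0.85)
})

test_that("the carbon-source sweep builds a complete replicate-level table", {
  summ <- build_condition_summary(seed = 2)
  expect_equal(nrow(summ), 15)
  expect_false(any(is.na(summ$mdk99)))
  expect_false(any(is.na(summ$persistence)))
  expect_true(all(summ$persistence > 0 & summ$persistence < 1))
  expect_true(all(summ$low_gtp_fraction >= 0 & summ$low_gtp_fraction <= 1))
  # growth rates ordered per scenario configuration (glucose fastest)
  means <- tapply(summ$growth_rate, summ$scenario, mean)
  expect_gt(means[["WT_glucose_VAN"]], means[["WT_glutamate_VAN"]])
  # between-replicate scatter stays near the configured noise level
  cv <- tapply(summ$growth_rate, summ$scenario, function(g) sd(g) / mean(g))
  expect_lt(max(cv), 0.15)
})

test_that("the uncoupling verdicts separate persistence from tolerance", {
  summ <- build_condition_summary(seed = 3)
  rep <- uncoupling_report(summ)
  v <- rep$verdicts
  expect_true(v[["growth_tolerance"]])
  expect_false(v[["growth_persistence"]])
  expect_true(v[["lowgtp_persistence"]])
  expect_false(v[["lowgtp_tolerance"]])
  # tolerance rises as growth slows: negative correlation in rate terms
  r_gt <- rep$correlations$r[rep$correlations$pair == "growth_tolerance"]
  expect_lt(r_gt, 0)
})

test_that("shuffling persistence destroys the low-GTP association in ~95% of permutations", {
  summ <- build_condition_summary(seed = 4)
  withr::with_seed(33, {
    flipped <- replicate(100, {
      s2 <- summ
      s2$persistence <- sample(s2$persistence)
      !uncoupling_report(s2)$verdicts[["lowgtp_persistence"]]
    })
  })
  expect_gte(mean(flipped), 0.9)
})

test_that("the verdict pattern is stable across master seeds", {
  patterns <- vapply(1:10, function(s) {
    v <- uncoupling_report(build_condition_summary(seed = 700 + s,
                                                   n_events = 5e4))$verdicts
    paste(as.integer(v), collapse = "")
  }, character(1))
  # coupled growth-tolerance, uncoupled growth-persistence,
  # coupled lowGTP-persistence, uncoupled lowGTP-tolerance
  expect_gte(mean(patterns == "1010"), 0.9)
})

test_that("a two-condition table errors instead of emitting a verdict", {
  summ <- build_condition_summary(scenarios = c("WT_glucose_VAN",
                                                "WT_glutamate_VAN"),
                                  seed = 5)
  expect_error(uncoupling_report(summ), "4 conditions")
})
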