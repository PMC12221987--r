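test_that("noiseless generator equals the closed form to machine precision", {
  kp <- list(f = 1e-3, k_s = 2.3, k_p = 0.04463, N0 = 1e8)
  tp <- c(0, 0.5, 1, 2, 3, 4, 5)
  kc <- generate_kill_curve(kill_params = kp, timepoints = tp, n_reps = 1,
                            noiseless = TRUE)
  expect_equal(kc$cfu,
               kp$N0 * biexp_survival(tp, kp$f, kp$k_s, kp$k_p),
               tolerance = 1e-12)
})

test_that("generator rejects invalid inputs", {
  expect_error(generate_kill_curve(kill_params = list(f = 1.2, k_s = 2, k_p = 0.01, N0 = 1e8)),
               "f")
  expect_error(generate_kill_curve("WT_exponential_VAN", timepoints = c(-1, 0, 2)),
               "non-negative")
  expect_error(generate_kill_curve("WT_exponential_VAN", timepoints = c(1, 2, 3)),
               "include 0")
})

test_that("biphasic fit recovers noiseless parameters essentially exactly", {
  kc <- noiseless_curve(f = 0.001, k_s = 4.6, k_p = 0.01)
  fit <- fit_biphasic(kc)
  expect_true(fit$converged)
  expect_false(fit$non_biphasic)
  expect_lt(abs(fit$f - 0.001) / 0.001, 1e-6)
  expect_lt(abs(fit$k_s - 4.6) / 4.6, 1e-6)
  expect_lt(abs(fit$k_p - 0.01) / 0.01, 1e-6)
})

test_that("fit is idempotent: refitting its own prediction reproduces the parameters", {
  kc <- noiseless_curve(f = 0.002, k_s = 3.1, k_p = 0.02)
  f1 <- fit_biphasic(kc)
  pred <- tibble::tibble(
    condition = "refit", replicate = 1, time = kc$time,
    cfu = f1$N0 * biexp_survival(kc$time, f1$f, f1$k_s, f1$k_p),
    below_detection = FALSE, detection_limit = 5)
  f2 <- fit_biphasic(pred)
  expect_equal(f2$f, f1$f, tolerance = 1e-6)
  expect_equal(f2$k_s, f1$k_s, tolerance = 1e-6)
  expect_equal(f2$k_p, f1$k_p, tolerance = 1e-6)
})

test_that("single-exponential curves are reported as non-biphasic with the kill rate recovered", {
  tp <- c(0, 0.5, 1, 1.5, 2, 3)
  kc <- tibble::tibble(condition = "single", replicate = 1, time = tp,
                       cfu = 1e8 * exp(-2.5 * tp),
                       below_detection = FALSE, detection_limit = 5)
  fit <- fit_biphasic(kc)
  expect_true(fit$non_biphasic)
  expect_equal(fit$f, 0)
  expect_equal(fit$k_s, 2.5, tolerance = 1e-4)
})

test_that("an all-below-detection curve yields an explicit unfit status", {
  kc <- tibble::tibble(condition = "dead", replicate = 1,
                       time = c(0, 1, 2, 3, 4),
                       cfu = rep(5, 5),
                       below_detection = rep(TRUE, 5), detection_limit = 5)
  fit <- fit_biphasic(kc)
  expect_false(fit$converged)
  expect_match(fit$status, "below_detection")
})

test_that("parameter recovery holds across the (f, k_s, k_p) grid at realistic noise", {
  grid <- expand.grid(f = c(1e-4, 1e-3, 0.05, 0.5),
                      k_s = c(1.5, 4, 9),
                      k_p = c(0, 0.03))
  rel_err <- mapply(function(f, k_s, k_p) {
    kc <- generate_kill_curve(
      kill_params = list(f = f, k_s = k_s, k_p = k_p, N0 = 1e8),
      n_reps = 3, seed = round(1e4 * f + 100 * k_s + 1000 * k_p))
    fs <- vapply(split(kc, kc$replicate),
                 function(d) fit_biphasic(d)$f, numeric(1))
    abs(persisterkit:::geomean(fs) - f) / f
  }, grid$f, grid$k_s, grid$k_p)
  expect_lt(median(rel_err), 0.25)
})

test_that("endpoint persister fraction matches the closed form and the plateau on clean data", {
  # pure exponential killing: 5-h survival is e^(-k_s * 5)
  tp <- c(0, 1, 2, 3, 4, 5)
  k_s <- 4.6
  kc <- tibble::tibble(condition = "c", replicate = 1, time = tp,
                       cfu = 1e8 * exp(-k_s * tp),
                       below_detection = FALSE, detection_limit = 5)
  expect_equal(persister_fraction(kc, "endpoint"), exp(-k_s * 5),
               tolerance = 1e-9)
  # plateau vs endpoint agree to 3 significant figures when persisters are not killed
  kc2 <- noiseless_curve(f = 1e-3, k_s = 4.6, k_p = 0)
  plateau <- persister_fraction(kc2, "plateau")
  endpoint <- persister_fraction(kc2, "endpoint")
  expect_equal(signif(plateau, 3), signif(endpoint, 3))
  # interpolation only when bracketed
  kc3 <- kc[kc$time != 5, ]
  expect_error(persister_fraction(kc3, "endpoint"), "bracket")
})

test_that("MDK99 reduces to ln(100)/k_s and is monotone in the kill rate", {
  f0 <- list(f = 0, k_s = log(100) / 2, k_p = 0)
  expect_equal(mdk99(f0), 2, tolerance = 1e-9)
  # persister subtraction makes MDK99 a pure susceptible-compartment property
  fit <- fit_biphasic(noiseless_curve(f = 0.01, k_s = 3, k_p = 0.04))
  expect_equal(fit$mdk99, log(100) / fit$k_s, tolerance = 1e-9)
  m <- vapply(c(2, 3, 5, 8),
              function(ks) mdk99(list(f = 0.001, k_s = ks, k_p = 0.02)),
              numeric(1))
  expect_true(all(diff(m) < 0))
})

test_that("MDK99 with persister subtraction is invariant to the persister fraction", {
  m <- vapply(c(1e-4, 1e-3, 1e-2, 0.3),
              function(f) mdk99(list(f = f, k_s = 3, k_p = 0.04)),
              numeric(1))
  expect_lt(diff(range(m)), 1e-9)
})

test_that("condition comparisons report fold changes with sensible edge behavior", {
  a <- c(1e-3, 1.2e-3, 0.9e-3)
  cmp <- compare_conditions(a, a, metric = "endpoint")
  expect_equal(cmp$fold_change, 1)
  expect_equal(cmp$p_value, 1, tolerance = 1e-12)
  tie <- compare_conditions(c(1, 1, 1), c(1, 1, 1), metric = "mdk99")
  expect_true(is.na(tie$p_value))
  expect_match(tie$note, "tie")
  expect_warning(compare_conditions(c(1, 2), c(1, 2, 3), metric = "mdk99"),
                 "replicates")
})

test_that("kill-curve CSV round-trips through the documented schema", {
  kc <- generate_kill_curve("WT_exponential_VAN", n_reps = 2, seed = 8)
  path <- tempfile(fileext = ".csv")
  pk_write_csv(kc, path, meta = list(seed = 8, scenario = "WT_exponential_VAN"))
  back <- read_kill_curves(path)
  expect_equal(back$cfu, kc$cfu)
  expect_equal(attr(back, "meta")$scenario, "WT_exponential_VAN")
  fit1 <- fit_biphasic(kc[kc$replicate == 1, ])
  fit2 <- fit_biphasic(back[back$replicate == 1, ])
  expect_equal(fit1$f, fit2$f, tolerance = 1e-10)
})
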