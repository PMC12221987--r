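make_events <- function(fl) {
  tibble::tibble(event = seq_along(fl), fluorescence = fl,
                 fsc = 1, is_control = FALSE)
}

test_that("autofluorescence subtraction recovers shifts and zeroes matched controls", {
  withr::with_seed(1, {
    ctrl <- make_events(rlnorm(20000, log(50), 0.3))
    samp <- make_events(rlnorm(20000, log(50), 0.3))
  })
  corr <- subtract_autofluorescence(samp, ctrl)
  # bulk mode collapses toward 0: the clamped-at-zero mean is far below the
  # raw mean and roughly half the events pin to exactly 0
  expect_lt(mean(corr$fluorescence), 0.2 * mean(samp$fluorescence))
  expect_gt(attr(corr, "n_clamped") / nrow(corr), 0.4)
  # a constant offset is removed exactly in the mean
  shifted <- make_events(samp$fluorescence + 100)
  corr2 <- subtract_autofluorescence(shifted, samp)
  expect_equal(mean(corr2$fluorescence), 100, tolerance = 0.05)
  # control brighter than sample warns prominently
  expect_warning(subtract_autofluorescence(samp, make_events(samp$fluorescence + 500)),
                 "control")
})

test_that("the fivefold gate has the documented edge and invariance properties", {
  # all events equal: nothing sits at 5x the mean
  g0 <- gate_low_gtp(make_events(rep(7, 1000)))
  expect_equal(g0$fraction, 0)
  # two-point mixture: weight w at 100x bulk gates out at ~w
  w <- 0.005
  withr::with_seed(2, {
    fl <- ifelse(runif(2e5) < w, 100, 1)
  })
  g <- gate_low_gtp(make_events(fl))
  expect_equal(g$fraction, w, tolerance = 3 * sqrt(w / 2e5) / w)
  # scale invariance: multiplying fluorescence by c > 0 changes nothing
  g2 <- gate_low_gtp(make_events(fl * 37.5))
  expect_equal(g2$fraction, g$fraction)
  # monotone: non-decreasing in bright weight, non-increasing in fold
  fr_w <- vapply(c(0.001, 0.005, 0.02), function(wi) {
    withr::with_seed(3, fli <- ifelse(runif(2e5) < wi, 100, 1))
    gate_low_gtp(make_events(fli))$fraction
  }, numeric(1))
  expect_true(all(diff(fr_w) >= 0))
  fr_fold <- vapply(c(2, 5, 20), function(fd) {
    gate_low_gtp(make_events(fl), fold = fd)$fraction
  }, numeric(1))
  expect_true(all(diff(fr_fold) <= 0))
  expect_error(gate_low_gtp(make_events(numeric(0))), "empty")
})

test_that("generated event tables reproduce the scenario mixture", {
  cy <- generate_cytometry("WT_exponential_VAN", n_events = 2e5, seed = 4)
  w <- get_scenario("WT_exponential_VAN")$cytometry$low_gtp_weight
  # binomial oracle on the latent labels
  expect_lt(abs(mean(cy$sample$latent_dormant) - w), 4 * sqrt(w / 2e5))
  corr <- subtract_autofluorescence(cy$sample, cy$control)
  g <- gate_low_gtp(corr)
  expect_gt(g$fraction, w / 4)
  expect_lt(g$fraction, w * 2)
  # alarmone-null: no bright subpopulation; gmk suppressor restores it
  cy0 <- generate_cytometry("ppGpp0_VAN", n_events = 1e5, seed = 5)
  g0 <- gate_low_gtp(subtract_autofluorescence(cy0$sample, cy0$control))
  expect_lt(g0$fraction, 2e-4)
  cyg <- generate_cytometry("ppGpp0_gmk_Q110R_VAN", n_events = 2e5, seed = 6)
  gg <- gate_low_gtp(subtract_autofluorescence(cyg$sample, cyg$control))
  expect_gt(gg$fraction, g0$fraction * 5)
  # weight-zero mixture gates at ~0 (trivial edge)
  cyz <- generate_cytometry("WT_exponential_VAN", n_events = 1e5, seed = 7,
                            weight = 0)
  gz <- gate_low_gtp(subtract_autofluorescence(cyz$sample, cyz$control))
  expect_lt(gz$fraction, 2e-4)
})

test_that("induced fraction is a floored difference under a shared gate", {
  cy <- generate_cytometry("WT_untreated_BAC", n_events = 1e5, seed = 8)
  g <- gate_low_gtp(subtract_autofluorescence(cy$sample, cy$control))
  same <- induced_fraction(g, g)
  expect_equal(same$value, 0)
  expect_false(same$negative_difference)
  cyb <- generate_cytometry("WT_bacitracin_pretreat_BAC", n_events = 1e5, seed = 9)
  gb <- gate_low_gtp(subtract_autofluorescence(cyb$sample, cyb$control))
  ind <- induced_fraction(g, gb)
  expect_gt(ind$value, 0.003)
  rev <- induced_fraction(gb, g)
  expect_equal(rev$value, 0)
  expect_true(rev$negative_difference)
  g2 <- gate_low_gtp(subtract_autofluorescence(cy$sample, cy$control), fold = 10)
  expect_error(induced_fraction(g2, gb), "mismatch")
})

test_that("sort-and-kill separates survival by latent dormancy, not by fluorescence per se", {
  kp <- list(k_s = 2.3, k_p = 0.04463)
  cy <- generate_cytometry("WT_exponential_VAN", n_events = 2e5, seed = 10)
  # permutation oracle: shuffled labels equalize the two fractions
  shuf <- cy$sample
  withr::with_seed(11, shuf$latent_dormant <- sample(shuf$latent_dormant))
  sk <- sort_and_kill(shuf, top_fraction = 0.01, kill_params = kp, seed = 12)
  w <- mean(shuf$latent_dormant)
  p_expect <- w * exp(-kp$k_p * 5) + (1 - w) * exp(-kp$k_s * 5)
  for (s in sk$survival) {
    expect_lt(abs(s - p_expect), 5 * sqrt(p_expect / min(sk$n_events)))
  }
  # all-dormant population survives at the persister rate in both gates
  all_d <- cy$sample
  all_d$latent_dormant <- TRUE
  sk2 <- sort_and_kill(all_d, top_fraction = 0.01, kill_params = kp, seed = 13)
  expect_equal(sk2$survival, rep(exp(-kp$k_p * 5), 2), tolerance = 0.05)
  # top_fraction -> 1 reproduces the bulk kill
  sk3 <- sort_and_kill(cy$sample, top_fraction = 1, kill_params = kp, seed = 14)
  bulk <- sk3[sk3$fraction == "bright", ]
  w0 <- mean(cy$sample$latent_dormant)
  expect_equal(bulk$survival,
               w0 * exp(-kp$k_p * 5) + (1 - w0) * exp(-kp$k_s * 5),
               tolerance = 0.3)
  expect_warning(sort_and_kill(cy$sample, top_fraction = 1e-4, kill_params = kp,
                               seed = 15),
                 "counting noise")
})
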