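test_that("growth-rate estimation is exact on canonical traces", {
  # constant length: mu = 0 everywhere
  flat <- tibble::tibble(cell = 1, time = seq(0, 150, 15), l = 2, F = 1,
                         division = FALSE)
  expect_equal(specific_growth_rate(flat)$mu, rep(0, 11))
  # exponential elongation: mu ~ r at interior frames
  tr <- exp_trace(r = 0.02, n = 25)
  mu <- specific_growth_rate(tr)$mu
  # centered difference of an exponential: r (1 + (r dt)^2/6 + ...), ~1.5% high
  interior <- mu[2:24]
  expect_equal(interior, rep(0.02, 23), tolerance = 0.02)
  # invariant to uniform length rescaling
  tr2 <- tr
  tr2$l <- tr2$l * 1000
  expect_equal(specific_growth_rate(tr2)$mu, mu)
  # non-positive lengths are named, not propagated
  bad <- tr
  bad$l[3] <- 0
  expect_error(specific_growth_rate(bad), "non-positive")
})

test_that("growth rates recovered from lineage traces match the simulator's latent rates", {
  p <- model_params()
  lin <- simulate_lineage(p, n_division_events = 800, seed = 17)
  tr <- specific_growth_rate(lin[, c("cell", "time", "l", "F", "division")])
  m <- merge(tr, lin[, c("cell", "time", "latent_mu")])
  m <- dplyr::arrange(m, cell, time)
  # the centered-difference estimate averages over two frame intervals, so it
  # is compared against the matching (1,2,1)/4-smoothed latent growth rate
  sm <- unlist(tapply(m$latent_mu, m$cell, function(v) {
    if (length(v) < 3) return(rep(NA_real_, length(v)))
    as.numeric(stats::filter(v, c(1, 2, 1) / 4, sides = 2))
  }))
  keep <- is.finite(m$mu) & is.finite(sm)
  rmse <- sqrt(mean((m$mu[keep] - sm[keep])^2))
  expect_lt(rmse, 0.1 * p$mu_max)
})

test_that("the entrance detector is specific: no events without the feedback switch", {
  p <- graded_params(model_params(sigma_eta = 0.01))
  lin <- simulate_lineage(p, n_division_events = 10000, seed = 18)
  expect_equal(nrow(attr(lin, "entrances")), 0)
  tr <- specific_growth_rate(lin[, c("cell", "time", "l", "F", "division")])
  ev <- detect_entrance(tr)
  expect_equal(nrow(ev), 0)
  # steadily growing single trace: no event either
  ev1 <- detect_entrance(specific_growth_rate(exp_trace(n = 30)))
  expect_equal(nrow(ev1), 0)
})

test_that("the detector recovers latent entrances within two frames and sees the reporter rise first", {
  frame_dt <- model_params()$frame_dt
  hits <- 0; callable_n <- 0; offsets <- c()
  for (run in wt_lineage_runs()) {
    truth <- attr(run$lin, "entrances")
    last_t <- max(run$lin$time)
    callable <- truth[truth$time < last_t - 4 * frame_dt, ]
    m <- merge(callable, run$ev, by = "cell")
    callable_n <- callable_n + nrow(callable)
    hits <- hits + nrow(m)
    offsets <- c(offsets, m$arrest_time - m$time)
  }
  expect_gt(callable_n, 5)
  expect_gte(hits / callable_n, 0.9)
  expect_true(all(abs(offsets) <= 2 * frame_dt))
  # reporter precedence in at least 90% of events (pooled)
  ev_all <- dplyr::bind_rows(lapply(wt_lineage_runs(), `[[`, "ev"))
  expect_gte(precedence_fraction(ev_all), 0.9)
  # fluorescence threshold consistency maps into the dormancy GTP band
  cons <- threshold_consistency(ev_all)
  expect_lt(cons$cv_F, 0.5)
  med_gtp <- median(cons$events$G_est_mM)
  expect_gt(med_gtp, 0.1)
  expect_lt(med_gtp, 0.2)
})

test_that("threshold consistency withholds summaries below three events and degenerates to CV 0", {
  ev <- tibble::tibble(cell = 1:2, arrest_time = c(10, 20),
                       F_arrest = c(5, 5), rise_onset_time = c(0, 10),
                       frames_sustained = c(3L, 3L),
                       precedence = c(TRUE, TRUE))
  out <- threshold_consistency(ev)
  expect_null(out$mean_F)
  expect_match(out$reason, "withheld")
  ev3 <- rbind(ev, ev[1, ])
  ev3$cell <- 1:3
  out3 <- threshold_consistency(ev3)
  expect_equal(out3$cv_F, 0)
})

test_that("precedence fraction behaves at the boundary and under randomization", {
  ev <- tibble::tibble(cell = 1:40, arrest_time = 100, F_arrest = 10,
                       rise_onset_time = 50, frames_sustained = 2L,
                       precedence = TRUE)
  expect_equal(precedence_fraction(ev), 1)
  withr::with_seed(19, ev$precedence <- sample(c(TRUE, FALSE), 40, TRUE))
  expect_lt(abs(precedence_fraction(ev) - 0.5), 0.25)
})

test_that("model comparison identifies linear and sigmoidal growth-fluorescence data", {
  # data generated from a line
  withr::with_seed(20, {
    n <- 3000
    Fv <- runif(n, 1, 100)
    mu <- 0.03 - 2e-4 * Fv + rnorm(n, 0, 0.001)
    lin_d <- tibble::tibble(cell = rep(1:60, length.out = n),
                            time = 1:n, F = Fv, mu = mu)
  })
  rl <- fit_growth_fluorescence(lin_d)
  expect_equal(rl$preferred, "linear")
  # data generated from a steep Hill response
  withr::with_seed(21, {
    mu_h <- 0.025 / (1 + (Fv / 40)^6) + rnorm(n, 0, 0.001)
    hill_d <- tibble::tibble(cell = rep(1:60, length.out = n),
                             time = 1:n, F = Fv, mu = mu_h)
  })
  rh <- fit_growth_fluorescence(hill_d)
  expect_equal(rh$preferred, "sigmoidal")
  expect_true(rh$decisive)
  expect_equal(rh$h, 6, tolerance = 0.15)
  expect_lt(rh$h_ci[1], rh$h)
  expect_gt(rh$h_ci[2], rh$h)
  # degenerate fluorescence range is withheld
  deg <- lin_d
  deg$F <- 5
  rd <- fit_growth_fluorescence(deg)
  expect_match(rd$preferred, "withheld")
})

test_that("wild-type traces show a decisive switch; graded-mutant traces do not", {
  run <- wt_lineage_runs()[[1]]
  # the ~100-trace summary design: all entrance traces plus growing traces
  grow_ids <- setdiff(unique(run$tr$cell), run$ev$cell)
  keep <- c(run$ev$cell, grow_ids[seq_len(min(90, length(grow_ids)))])
  r <- fit_growth_fluorescence(run$tr[run$tr$cell %in% keep, ])
  expect_equal(r$preferred, "sigmoidal")
  expect_true(r$decisive)
  pg <- scenario_model_params("ppGpp0_gmk_Q110R_VAN")
  ling <- simulate_lineage(pg, n_division_events = 6000, seed = 24)
  trg <- specific_growth_rate(ling[, c("cell", "time", "l", "F", "division")])
  rg <- fit_growth_fluorescence(trg)
  expect_false(rg$preferred == "sigmoidal" && rg$decisive)
})
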