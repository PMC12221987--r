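# Shared fixtures: all synthetic inputs are generated in code at test time.

# Deterministic (noise-free, feedback-off) parameter set for analytic checks.
quiet_params <- function(...) {
  model_params(sigma_eta = 0, V_B = 0, V_A = 0, a_R = 0, ...)
}

# One noiseless kill curve from explicit parameters.
noiseless_curve <- function(f = 1e-3, k_s = 4.6, k_p = 0.01, N0 = 1e8,
                            timepoints = c(0, 0.5, 1, 2, 3, 4, 5)) {
  generate_kill_curve(kill_params = list(f = f, k_s = k_s, k_p = k_p, N0 = N0),
                      timepoints = timepoints, n_reps = 1, noiseless = TRUE)
}

# Replicate fits for a scenario in one call.
fit_scenario_reps <- function(scenario, n_reps = 3, seed = 1,
                              k_p_fixed = NULL) {
  kc <- generate_kill_curve(scenario, n_reps = n_reps, seed = seed)
  lapply(split(kc, kc$replicate), fit_biphasic, k_p_fixed = k_p_fixed)
}

# Independent persister kill-rate estimate from a sorted-persister kill run,
# used to stabilize plateau fits (two-stage fitting).
measured_k_p <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cy <- generate_cytometry("WT_exponential_VAN", n_events = 4e5,
                               seed = 881)
      sk <- sort_and_kill(cy$sample, top_fraction = 0.001, duration_h = 5,
                          seed = 882)
      cache <<- -log(sk$survival[sk$fraction == "bright"]) / 5
    }
    cache
  }
})

# Three full-scale wild-type lineage benchmarks (30,000 division events each),
# computed once and shared across test blocks. Each element carries the raw
# record, the mu-annotated traces and the detected entrance events.
wt_lineage_runs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- lapply(c(401, 402, 403), function(s) {
        lin <- simulate_lineage(model_params(), n_division_events = 30000,
                                seed = s)
        tr <- specific_growth_rate(lin[, c("cell", "time", "l", "F",
                                           "division")])
        list(lin = lin, tr = tr, ev = detect_entrance(tr))
      })
    }
    cache
  }
})

# Synthetic exponential-growth trace with optional divisions.
exp_trace <- function(r = 0.02, l0 = 1.5, n = 20, dt = 15, cell = 1L) {
  time <- seq(0, by = dt, length.out = n)
  l <- l0 * exp(r * time)
  # fold lengths back into [l0, 2 l0) and set division flags
  lf <- l; div <- rep(FALSE, n)
  for (i in seq_len(n)) {
    while (lf[i] >= 2 * l0) {
      lf[i:n] <- lf[i:n] / 2
      div[i] <- TRUE
    }
  }
  tibble::tibble(cell = cell, time = time, l = lf, F = 1, division = div)
}
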