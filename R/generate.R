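#' Closed-form biexponential survival
#'
#' Two-compartment killing model: a fraction `f` of persisters killed at rate
#' `k_p` and the susceptible remainder killed at `k_s`, giving
#' `S(t) = (1 - f) exp(-k_s t) + f exp(-k_p t)`.
#'
#' @param t Time(s), hours.
#' @param f Persister fraction in \[0, 1).
#' @param k_s Susceptible kill rate, 1/h.
#' @param k_p Persister kill rate, 1/h (`k_p < k_s`).
#' @return Survival fraction(s).
#' @export
biexp_survival <- function(t, f, k_s, k_p) {
  stopifnot(f >= 0, f < 1, k_p <= k_s, all(t >= 0))
  (1 - f) * exp(-k_s * t) + f * exp(-k_p * t)
}

#' Generate synthetic time-kill curves for a scenario
#'
#' Draws replicate CFU/ml trajectories from the two-compartment killing model
#' of a scenario, emulating the counting pipeline of a persister assay:
#' replicate-level lognormal scatter on the inoculum, serial-dilution plating
#' in which the countable dilution (target window 30-300 colonies per plate,
#' `n_plates` technical plates) is Poisson-sampled, and a detection limit of
#' one colony on the undiluted plates. Counts that fall to zero at the lowest
#' dilution are flagged below detection and carry the limit, never zero.
#'
#' @param scenario Scenario name or `scenario_spec` (see [scenario_table()]);
#'   alternatively supply `kill_params` directly.
#' @param timepoints Sampling times, hours; must include 0, all non-negative.
#' @param n_reps Number of biological replicates (>= 1).
#' @param seed Integer seed.
#' @param kill_params Optional list `f, k_s, k_p, N0` overriding the scenario.
#' @param noiseless If `TRUE`, return the exact closed form (no sampling);
#'   used for analytic checks.
#' @param plate_volume_ml Plated volume per technical plate.
#' @param n_plates Technical plates per dilution.
#' @param n0_sdlog Lognormal s.d. of the replicate inoculum scatter.
#' @return A tibble with columns `condition`, `replicate`, `time` (h), `cfu`
#'   (CFU/ml), `below_detection`, `detection_limit`. Attributes: `kill_params`,
#'   `seed`.
#' @examples
#' kc <- generate_kill_curve("WT_exponential_VAN", seed = 1)
#' head(kc)
#' @export
generate_kill_curve <- function(scenario = NULL,
                                timepoints = c(0, 0.5, 1, 2, 3, 4, 5),
                                n_reps = 3, seed = NULL, kill_params = NULL,
                                noiseless = FALSE, plate_volume_ml = 0.1,
                                n_plates = 2, n0_sdlog = 0.05) {
  if (is.null(kill_params)) {
    if (is.character(scenario)) scenario <- get_scenario(scenario)
    kill_params <- scenario$kill_params
  }
  cond <- if (!is.null(scenario)) scenario$name else "custom"
  f <- kill_params$f; k_s <- kill_params$k_s
  k_p <- kill_params$k_p; N0 <- kill_params$N0
  if (any(timepoints < 0)) abort("timepoints must be non-negative")
  if (!0 %in% timepoints) abort("timepoints must include 0")
  if (f <= 0 || f >= 1) abort("persister fraction `f` must lie in (0, 1)")
  stopifnot(n_reps >= 1)

  vol <- plate_volume_ml * n_plates
  detection_limit <- 1 / vol
  with_seed(seed, {
    out <- purrr::map_dfr(seq_len(n_reps), function(r) {
      N0_rep <- if (noiseless) N0 else N0 * exp(rnorm(1, 0, n0_sdlog))
      truth <- N0_rep * biexp_survival(timepoints, f, k_s, k_p)
      if (noiseless) {
        tibble(condition = cond, replicate = r, time = timepoints,
               cfu = truth, below_detection = FALSE,
               detection_limit = detection_limit)
      } else {
        cfu <- vapply(truth, plate_count_emulation, numeric(1),
                      vol = vol)
        tibble(condition = cond, replicate = r, time = timepoints,
               cfu = ifelse(cfu > 0, cfu, detection_limit),
               below_detection = cfu <= 0,
               detection_limit = detection_limit)
      }
    })
    attr(out, "kill_params") <- kill_params
    attr(out, "seed") <- seed
    out
  })
}

# Emulate serial-dilution plating: pick the dilution whose expected count per
# plate falls at/below 300, Poisson-draw `vol/plate_volume` plates, return the
# back-calculated CFU/ml (0 when no colonies even undiluted).
plate_count_emulation <- function(cfu_true, vol) {
  expected <- cfu_true * vol
  dil <- max(0, ceiling(log10(max(expected, 1e-12) / 300)))
  lambda <- expected * 10^-dil
  count <- rpois(1, lambda)
  if (count == 0 && dil > 0) {       # re-plate less dilute, as at the bench
    dil <- 0
    count <- rpois(1, expected)
  }
  count * 10^dil / vol
}

#' Generate a synthetic flow-cytometry event table with matched control
#'
#' Draws per-event reporter fluorescence from the mixture the low-GTP
#' reporter produces in a population: a log-normal bulk component plus a rare
#' bright dormant component (mixture weight = the scenario's latent low-GTP
#' fraction, located well above the bulk), with additive log-normal
#' autofluorescence on every event. The matched control table (an isogenic
#' strain without the reporter) carries autofluorescence alone. A latent
#' per-event dormancy label is retained for the in-silico sort-and-kill
#' experiment ([sort_and_kill()]); gating operations never consult it.
#'
#' @param scenario Scenario name or `scenario_spec`.
#' @param n_events Number of events (>= 1000).
#' @param seed Integer seed.
#' @param weight Optional override of the dormant mixture weight.
#' @param autofluor_mean,autofluor_sdlog Autofluorescence component (AU).
#' @param bulk_sdlog,dormant_sdlog Log-scale spreads of the two reporter
#'   components.
#' @return List with elements `sample` and `control`, each a tibble with
#'   columns `event`, `fluorescence` (AU), `fsc` (scatter proxy), `is_control`,
#'   and (sample only) `latent_dormant`. Attributes on `sample`: `weight`,
#'   `seed`, `scenario`.
#' @examples
#' cy <- generate_cytometry("WT_exponential_VAN", n_events = 5000, seed = 1)
#' mean(cy$sample$latent_dormant)
#' @export
generate_cytometry <- function(scenario, n_events, seed = NULL, weight = NULL,
                               autofluor_mean = 50, autofluor_sdlog = 0.35,
                               bulk_sdlog = 0.4, dormant_sdlog = 0.9) {
  if (is.character(scenario)) scenario <- get_scenario(scenario)
  stopifnot(n_events >= 1000)
  cy <- scenario$cytometry
  w <- weight %||% cy$low_gtp_weight
  if (w < 0 || w > 1) abort("mixture weight must lie in [0, 1]")
  with_seed(seed, {
    dormant <- runif(n_events) < w
    n_d <- sum(dormant)
    reporter <- numeric(n_events)
    reporter[!dormant] <- rlnorm(n_events - n_d,
                                 log(cy$bulk_F_mean) - bulk_sdlog^2 / 2,
                                 bulk_sdlog)
    if (n_d > 0) {
      reporter[dormant] <- rlnorm(n_d, log(cy$dormant_F_mean), dormant_sdlog)
    }
    af_mu <- log(autofluor_mean) - autofluor_sdlog^2 / 2
    sample <- tibble(
      event = seq_len(n_events),
      fluorescence = reporter + rlnorm(n_events, af_mu, autofluor_sdlog),
      fsc = rlnorm(n_events, log(1.5), 0.25),
      is_control = FALSE,
      latent_dormant = dormant
    )
    control <- tibble(
      event = seq_len(n_events),
      fluorescence = rlnorm(n_events, af_mu, autofluor_sdlog),
      fsc = rlnorm(n_events, log(1.5), 0.25),
      is_control = TRUE
    )
    attr(sample, "weight") <- w
    attr(sample, "seed") <- seed
    attr(sample, "scenario") <- scenario$name
    list(sample = sample, control = control)
  })
}
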