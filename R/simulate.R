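#' Simulate single cells under the stochastic alarmone-GTP feedback model
#'
#' Integrates, for `n_cells` independent cells, the coupled dynamics of
#' alarmone `P` (uM), GTP `G` (mM), cell length `l` (um) and reporter
#' fluorescence `F` (AU):
#'
#' \deqn{dP/dt = [V_R (1 + a_R P/(K_B+P)) + V_B P^{n_B}/(K_B^{n_B}+P^{n_B})]
#'   e^{\eta - \sigma_\eta^2/2} + V_A \cdot 1[\mathrm{stress}] - d_P P}
#' \deqn{dG/dt = v_G/(1 + P/K_i) - s_{PG} \cdot \mathrm{syn}_P - \mu G}
#' \deqn{\mu = \mu_{max} \frac{G}{K_G+G} \max(0, 1 + \gamma_\mu \eta)}
#' \deqn{dF/dt = \alpha_F/(1 + (G/K_C)^{h_C}) - \mu F}
#'
#' where `eta` is a shared Ornstein-Uhlenbeck extrinsic noise factor
#' (stationary s.d. `sigma_eta`, autocorrelation time `tau_eta`) entering
#' alarmone synthesis as a mean-one lognormal multiplier and growth with
#' attenuation `gamma_mu`. Cells divide when length doubles (symmetric split
#' with `l_div_noise` CV); concentrations are conserved at division. A cell is
#' flagged dormant while its growth rate has stayed below `eps_mu` for at
#' least `tau_arrest` minutes. Integration is Euler-Maruyama at fixed `dt`
#' with exact OU updates; concentrations that would go negative are clamped at
#' zero and counted (see the `clamp_counts` attribute).
#'
#' @param params A [model_params()] object (or one returned by
#'   [scenario_model_params()]).
#' @param n_cells Number of independent cells (>= 1).
#' @param duration Simulated time, minutes.
#' @param dt Integration step, minutes. Aborts if too coarse for the fastest
#'   model timescale (stability requires `dt < min(1/d_P, tau_eta, 1/mu_max)/5`).
#' @param scenario Optional scenario (name or `scenario_spec`); when given,
#'   `params` is first passed through [scenario_model_params()].
#' @param record_dt Frame interval for the returned trajectories, minutes.
#' @param envelope_stress If `TRUE` the `V_A` synthesis term is active.
#' @param seed Integer seed; identical `(params, seed)` give identical output.
#' @return A tibble with columns `cell`, `time`, `P`, `G`, `l`, `F`, `eta`,
#'   `mu`, `dormant`, `divided`. Attributes: `params`, `clamp_counts` (named
#'   count of zero-clamps per state variable), `divisions` (total division
#'   events), `entrance_times` (per-cell first dormancy-entrance time, NA if
#'   none).
#' @examples
#' sim <- simulate_cells(model_params(sigma_eta = 0), n_cells = 2,
#'                       duration = 120, seed = 1)
#' head(sim)
#' @export
simulate_cells <- function(params = model_params(), n_cells, duration,
                           dt = 0.1, scenario = NULL,
                           record_dt = params$frame_dt,
                           envelope_stress = FALSE, seed = params$seed) {
  if (!is.null(scenario)) params <- scenario_model_params(scenario, params)
  stopifnot(n_cells >= 1, duration > 0, dt > 0)
  check_dt_stability(params, dt)
  with_seed(seed, {
    st <- init_state(params, n_cells)
    n_steps <- ceiling(duration / dt)
    rec_every <- max(1L, round(record_dt / dt))
    frames <- vector("list", floor(n_steps / rec_every) + 1L)
    frames[[1]] <- record_frame(st, 0)
    fi <- 1L
    divided_since <- logical(n_cells)
    for (k in seq_len(n_steps)) {
      st <- step_state(st, params, dt, envelope_stress)
      div <- step_divisions(st, params)
      st <- div$state
      divided_since <- divided_since | div$divided
      if (k %% rec_every == 0L) {
        fi <- fi + 1L
        fr <- record_frame(st, k * dt)
        fr$divided <- divided_since
        frames[[fi]] <- fr
        divided_since[] <- FALSE
      }
    }
    out <- dplyr::bind_rows(frames[seq_len(fi)])
    if (!"divided" %in% names(out)) out$divided <- FALSE
    out$divided[is.na(out$divided)] <- FALSE
    out <- dplyr::arrange(out, .data$cell, .data$time)
    attr(out, "params") <- params
    attr(out, "clamp_counts") <- st$clamps
    attr(out, "divisions") <- sum(st$divisions)
    attr(out, "entrance_times") <- st$entrance_time
    out
  })
}

check_dt_stability <- function(params, dt) {
  fastest <- min(1 / params$d_P, params$tau_eta, 1 / params$mu_max)
  if (dt > fastest / 5) {
    abort(sprintf(
      "dt = %g min is too coarse: fastest model timescale is %.2f min; use dt <= %.2f",
      dt, fastest, fastest / 5))
  }
  invisible(TRUE)
}

init_state <- function(params, n_cells) {
  P0 <- low_state_alarmone(params)
  G0 <- steady_gtp(params, P0)
  mu0 <- params$mu_max * G0 / (params$K_G + G0)
  F0 <- params$alpha_F / ((1 + (G0 / params$K_C)^params$h_C) * max(mu0, 1e-9))
  birth_l <- 1.5
  l0 <- birth_l * 2^runif(n_cells)
  list(
    P = rep(P0, n_cells), G = rep(G0, n_cells), l = l0,
    F = rep(F0, n_cells), eta = rnorm(n_cells, 0, params$sigma_eta),
    birth_l = rep(birth_l, n_cells),
    arrest_clock = rep(0, n_cells), dormant = rep(FALSE, n_cells),
    entrance_time = rep(NA_real_, n_cells), time = 0,
    divisions = rep(0L, n_cells), mu = rep(mu0, n_cells),
    clamps = c(P = 0L, G = 0L, F = 0L)
  )
}

# Steady-state GTP at fixed alarmone level P (supply = consumption + dilution).
steady_gtp <- function(params, P) {
  supply <- params$v_G / (1 + P / params$K_i) - params$s_PG * params$d_P * P
  if (supply <= 0) return(0)
  fn <- function(G) supply - params$mu_max * G / (params$K_G + G) * G
  uniroot(fn, c(0, 1e3))$root
}

step_state <- function(st, params, dt, envelope_stress) {
  a <- exp(-dt / params$tau_eta)
  st$eta <- st$eta * a +
    params$sigma_eta * sqrt(1 - a^2) * rnorm(length(st$eta))
  syn_factor <- exp(st$eta - params$sigma_eta^2 / 2)
  hill <- st$P^params$n_B / (params$K_B^params$n_B + st$P^params$n_B)
  syn_P <- (params$V_R * (1 + params$a_R * st$P / (params$K_B + st$P)) +
              params$V_B * hill) * syn_factor +
    params$V_A * as.numeric(envelope_stress)
  mu <- params$mu_max * st$G / (params$K_G + st$G) *
    pmax(0, 1 + params$gamma_mu * st$eta)
  dP <- syn_P - params$d_P * st$P
  dG <- params$v_G / (1 + st$P / params$K_i) - params$s_PG * syn_P - mu * st$G
  dF <- params$alpha_F / (1 + (st$G / params$K_C)^params$h_C) - mu * st$F

  P_new <- st$P + dP * dt
  G_new <- st$G + dG * dt
  F_new <- st$F + dF * dt
  l_new <- st$l * (1 + mu * dt)

  for (nm in c("P", "G", "F", "l")) {
    v <- switch(nm, P = P_new, G = G_new, F = F_new, l = l_new)
    if (any(!is.finite(v))) {
      abort(sprintf(
        "non-finite state in `%s` at t = %.2f min (first offending cell %d)",
        nm, st$time + dt, which(!is.finite(v))[1]))
    }
  }
  for (nm in c("P", "G", "F")) {
    v <- switch(nm, P = P_new, G = G_new, F = F_new)
    neg <- v < 0
    if (any(neg)) {
      st$clamps[nm] <- st$clamps[nm] + sum(neg)
      v[neg] <- 0
      if (nm == "P") P_new <- v else if (nm == "G") G_new <- v else F_new <- v
    }
  }

  st$P <- P_new; st$G <- G_new; st$F <- F_new; st$l <- l_new; st$mu <- mu
  st$time <- st$time + dt

  below <- mu < params$eps_mu
  st$arrest_clock <- ifelse(below, st$arrest_clock + dt, 0)
  newly_dormant <- !st$dormant & st$arrest_clock >= params$tau_arrest
  if (any(newly_dormant)) {
    onset <- st$time - st$arrest_clock[newly_dormant]
    idx <- which(newly_dormant)
    st$entrance_time[idx] <- ifelse(is.na(st$entrance_time[idx]), onset,
                                    st$entrance_time[idx])
  }
  st$dormant <- st$arrest_clock >= params$tau_arrest
  st
}

step_divisions <- function(st, params) {
  ready <- !st$dormant & st$l >= 2 * st$birth_l
  if (any(ready)) {
    frac <- pmin(0.7, pmax(0.3, rnorm(sum(ready), 0.5, 0.5 * params$l_div_noise)))
    st$l[ready] <- st$l[ready] * frac
    st$birth_l[ready] <- st$l[ready]
    st$divisions[ready] <- st$divisions[ready] + 1L
  }
  list(state = st, divided = ready)
}

record_frame <- function(st, time) {
  tibble(
    cell = seq_along(st$P), time = time,
    P = st$P, G = st$G, l = st$l, F = st$F,
    eta = st$eta, mu = st$mu, dormant = st$dormant
  )
}
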