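#' Simulate a growing lineage tree with time-lapse frame recording
#'
#' Grows a microcolony from a single seeded cell under the stochastic
#' alarmone-GTP model (see [simulate_cells()] for the dynamics) and records
#' frames at fixed spacing (default 15 min), emulating single-cell time-lapse
#' imaging. At division the mother keeps her identity as one daughter
#' (division flag set on that frame) and the sibling starts a new trace with
#' `parent` set, so each `cell` id is one continuous lineage path. Recorded
#' length and fluorescence carry multiplicative measurement noise
#' (`l_meas_cv`, `f_meas_cv`); the noise-free simulator state is retained in
#' `latent_*` columns which are flagged synthetic-only and must not be
#' consulted by analysis code (the entrance detector works from `l` and `F`
#' alone).
#'
#' To bound the live-cell count (emulating a finite field of view), whenever
#' the population exceeds `cap` live cells, non-dormant cells are uniformly
#' subsampled down to `cap`; dormant cells are always retained. Culled cells
#' simply stop being observed; their recorded frames and logged divisions
#' remain in the output.
#'
#' @param params A [model_params()] object.
#' @param n_division_events Target number of logged growth-and-division
#'   events (>= 1).
#' @param scenario Optional scenario applied via [scenario_model_params()].
#' @param dt Integration step, minutes.
#' @param cap Maximum number of concurrently simulated cells.
#' @param max_time Safety bound on simulated time, minutes.
#' @param seed Integer seed.
#' @return A tibble with columns `cell`, `parent`, `time`, `l`, `F`,
#'   `division` (flag: this frame follows a division of this cell),
#'   `latent_P`, `latent_G`, `latent_mu`, `latent_dormant`. Attributes:
#'   `divisions` (events logged), `entrances` (tibble of latent
#'   dormancy-entrance events: `cell`, `time`), `shortfall` (`TRUE` when the
#'   target count could not be reached because all lineages went dormant or
#'   `max_time` was hit), `params`.
#' @export
simulate_lineage <- function(params = model_params(), n_division_events,
                             scenario = NULL, dt = 0.1, cap = 500,
                             max_time = 20000, seed = params$seed) {
  if (!is.null(scenario)) params <- scenario_model_params(scenario, params)
  stopifnot(n_division_events >= 1)
  check_dt_stability(params, dt)
  frame_dt <- params$frame_dt
  with_seed(seed, {
    st <- init_state(params, 1L)
    id <- 1L
    parent <- NA_integer_
    next_id <- 2L
    total_div <- 0L
    time <- 0
    rec_every <- max(1L, round(frame_dt / dt))
    frames <- list()
    fi <- 0L
    div_since <- logical(1L)
    entr <- list()
    k <- 0L

    # run past the division target to the next frame boundary, so the state
    # that satisfied the target is always recorded
    while ((total_div < n_division_events || k %% rec_every != 0L) &&
           time < max_time) {
      k <- k + 1L
      prev_entr <- st$entrance_time
      st <- step_state(st, params, dt, FALSE)
      st$time <- k * dt            # avoid additive float drift in frame times
      time <- st$time
      new_e <- which(!is.na(st$entrance_time) & is.na(prev_entr))
      if (length(new_e)) {
        entr[[length(entr) + 1L]] <-
          tibble(cell = id[new_e], time = st$entrance_time[new_e])
      }

      ready <- which(!st$dormant & st$l >= 2 * st$birth_l)
      if (length(ready)) {
        frac <- pmin(0.7, pmax(0.3, rnorm(length(ready), 0.5,
                                          0.5 * params$l_div_noise)))
        l_div <- st$l[ready]
        # mother continues as daughter 1
        st$l[ready] <- l_div * frac
        st$birth_l[ready] <- st$l[ready]
        st$divisions[ready] <- st$divisions[ready] + 1L
        div_since[ready] <- TRUE
        # sibling daughters: copy state (concentrations conserved)
        nd <- length(ready)
        st$P <- c(st$P, st$P[ready]); st$G <- c(st$G, st$G[ready])
        st$F <- c(st$F, st$F[ready]); st$eta <- c(st$eta, st$eta[ready])
        st$mu <- c(st$mu, st$mu[ready])
        st$l <- c(st$l, l_div * (1 - frac))
        st$birth_l <- c(st$birth_l, l_div * (1 - frac))
        st$arrest_clock <- c(st$arrest_clock, st$arrest_clock[ready])
        st$dormant <- c(st$dormant, st$dormant[ready])
        st$entrance_time <- c(st$entrance_time, rep(NA_real_, nd))
        st$divisions <- c(st$divisions, rep(0L, nd))
        parent <- c(parent, id[ready])
        id <- c(id, seq.int(next_id, next_id + nd - 1L))
        div_since <- c(div_since, rep(TRUE, nd))
        next_id <- next_id + nd
        total_div <- total_div + nd
      }

      if (k %% rec_every == 0L) {
        fi <- fi + 1L
        n <- length(id)
        frames[[fi]] <- tibble(
          cell = id, parent = parent, time = time,
          l = st$l * exp(rnorm(n, 0, params$l_meas_cv)),
          F = st$F * exp(rnorm(n, 0, params$f_meas_cv)),
          division = div_since,
          latent_P = st$P, latent_G = st$G, latent_mu = st$mu,
          latent_dormant = st$dormant
        )
        div_since <- rep(FALSE, n)
      }

      live <- length(id)
      if (live > cap) {
        # protect committed cells: dormant, or mid-arrest (clock running)
        protected <- st$dormant | st$arrest_clock > 0
        keep_dormant <- which(protected)
        growing <- which(!protected)
        n_keep <- max(cap - length(keep_dormant), 2L)
        keep <- sort(c(keep_dormant,
                       sample(growing, min(n_keep, length(growing)))))
        st$P <- st$P[keep]; st$G <- st$G[keep]; st$F <- st$F[keep]
        st$eta <- st$eta[keep]; st$mu <- st$mu[keep]; st$l <- st$l[keep]
        st$birth_l <- st$birth_l[keep]
        st$arrest_clock <- st$arrest_clock[keep]
        st$dormant <- st$dormant[keep]
        st$entrance_time <- st$entrance_time[keep]
        st$divisions <- st$divisions[keep]
        id <- id[keep]; parent <- parent[keep]
        div_since <- div_since[keep]
      }
      if (all(st$dormant)) break
    }

    out <- dplyr::bind_rows(frames)
    out <- dplyr::arrange(out, .data$cell, .data$time)
    attr(out, "divisions") <- total_div
    attr(out, "entrances") <- if (length(entr)) {
      dplyr::distinct(dplyr::bind_rows(entr), .data$cell, .keep_all = TRUE)
    } else tibble(cell = integer(), time = double())
    attr(out, "shortfall") <- total_div < n_division_events
    attr(out, "params") <- params
    if (attr(out, "shortfall")) {
      warn(sprintf("lineage simulation stopped at %d of %d division events",
                   total_div, n_division_events))
    }
    out
  })
}
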