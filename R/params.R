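#' Parameters of the stochastic alarmone-GTP feedback model
#'
#' Constructs a validated parameter set for the single-cell model of
#' (p)ppGpp-GTP antagonism. The model couples four state variables per cell:
#' alarmone concentration `P` (uM), GTP concentration `G` (mM), cell length
#' `l` (um) and reporter fluorescence `F` (AU), plus one autocorrelated
#' extrinsic noise factor. Defaults are read from the packaged configuration
#' (`inst/extdata/model_params.yaml`), where the calibrated values live; any
#' field can be overridden by name.
#'
#' Key fields (units in the YAML config): `V_B`, `K_B`, `n_B` -- the
#' self-amplifying (SasB-type) synthesis term `V_B * P^n_B / (K_B^n_B + P^n_B)`
#' with allosteric Hill coefficient `n_B` (default 3); `V_R`, `a_R` -- basal
#' Rel-type synthesis `V_R * (1 + a_R * P/(K_B + P))` capturing activation of
#' Rel by the alarmone; `V_A` -- envelope-stress synthesis; `d_P` -- alarmone
#' turnover; `v_G`, `K_i`, `s_PG` -- GTP supply with alarmone inhibition and
#' synthesis-coupled consumption; `mu_max`, `K_G` -- GTP-limited growth;
#' `G_thr` -- the dormancy-associated GTP threshold (mM); `alpha_F`, `K_C`,
#' `h_C` -- the CodY-repressed low-GTP reporter; `sigma_eta`, `tau_eta`,
#' `gamma_mu` -- the Ornstein-Uhlenbeck extrinsic noise factor; `eps_mu`,
#' `tau_arrest` -- the growth-arrest (dormancy) call; `k_s`, `k_p` --
#' susceptible and persister kill rates under antibiotic (1/h).
#'
#' @param ... Named overrides of individual parameters.
#' @param seed Optional integer seed stored with the parameter set.
#' @return An object of class `model_params` (named list).
#' @examples
#' p <- model_params(n_B = 1, sigma_eta = 0.01)
#' p$n_B
#' @export
model_params <- function(..., seed = NULL) {
  defaults <- yaml::read_yaml(
    system.file("extdata", "model_params.yaml", package = "persisterkit")
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) {
      abort(paste0("unknown model parameter(s): ", paste(bad, collapse = ", ")))
    }
    defaults[names(overrides)] <- overrides
  }
  defaults$seed <- seed
  p <- structure(defaults, class = "model_params")
  validate_model_params(p)
  p
}

validate_model_params <- function(p) {
  pos <- c("V_B", "K_B", "V_R", "d_P", "v_G", "K_i", "mu_max", "K_G",
           "alpha_F", "K_C", "h_C", "tau_eta", "eps_mu", "tau_arrest",
           "k_s", "k_p", "g_cal", "frame_dt")
  # V_B and V_A may be set to zero to disable terms; the rest must be > 0
  strictly <- setdiff(pos, c("V_B"))
  for (nm in strictly) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      abort(paste0("model parameter `", nm, "` must be strictly positive"))
    }
  }
  if (p$V_B < 0 || p$V_A < 0 || p$s_PG < 0 || p$sigma_eta < 0 || p$a_R < 0) {
    abort("rate parameters must be non-negative")
  }
  if (p$n_B < 1) abort("`n_B` must be >= 1")
  if (p$k_p >= p$k_s) abort("`k_p` must be smaller than `k_s`")
  if (p$G_thr <= 0 || p$G_thr > 1) abort("`G_thr` must lie in (0, 1] mM")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> stochastic alarmone-GTP feedback model\n")
  nm <- setdiff(names(x), "seed")
  vals <- vapply(nm, function(n) format(x[[n]], digits = 4), character(1))
  cat(paste0("  ", format(nm, width = 10), " = ", vals), sep = "\n")
  if (!is.null(x$seed)) cat("  seed =", x$seed, "\n")
  invisible(x)
}

#' Feedback-free (graded) variant of a parameter set
#'
#' Removes the cooperative self-amplification that generates the bistable
#' switch: the Hill coefficient is set to 1 and the feedback synthase's
#' low-state contribution is folded into the basal synthesis rate while the
#' feedback amplitude itself is zeroed. Used to emulate graded-entry mutants
#' (no allosteric self-amplification) as a null model: alarmone and GTP then
#' fluctuate around a single fixed point and no switch-like dormancy entry
#' occurs.
#'
#' @param p A [model_params()] object.
#' @param reporter_graded If `TRUE` (default), also relax the reporter's
#'   cooperativity (`h_C = 1`) so fluorescence tracks GTP gradually, matching
#'   the linear growth-fluorescence relationship of graded-entry mutants.
#' @return A `model_params` object.
#' @export
graded_params <- function(p, reporter_graded = TRUE) {
  stopifnot(inherits(p, "model_params"))
  # low-state operating point of the deterministic system, feedback ignored
  P_lo <- low_state_alarmone(p)
  fold <- p$V_B * P_lo^p$n_B / (p$K_B^p$n_B + P_lo^p$n_B)
  p$V_R <- p$V_R + fold
  p$V_B <- 0
  p$n_B <- 1
  if (reporter_graded) p$h_C <- 1
  p
}

# Deterministic low-state alarmone fixed point with the feedback term off:
# V_R (1 + a_R P/(K_B+P)) = d_P P, solved by uniroot on a bracket.
low_state_alarmone <- function(p) {
  fn <- function(P) p$V_R * (1 + p$a_R * P / (p$K_B + P)) - p$d_P * P
  upper <- (p$V_R * (1 + p$a_R)) / p$d_P + 1
  uniroot(fn, c(1e-9, upper * 1.001))$root
}

#' Alarmone synthesis rate of the self-amplifying (SasB-type) synthase
#'
#' Evaluates the allosteric activation term
#' `V_B * P^n_B / (K_B^n_B + P^n_B)` of the model at alarmone concentration
#' `P`. This is the dose-response curve whose cooperativity (Hill coefficient
#' around 3) makes spontaneous dormancy entry switch-like.
#'
#' @param P Alarmone concentration(s), uM.
#' @param params A [model_params()] object.
#' @return Synthesis rate(s), uM/min.
#' @export
sasb_activation_rate <- function(P, params = model_params()) {
  stopifnot(all(P >= 0))
  params$V_B * P^params$n_B / (params$K_B^params$n_B + P^params$n_B)
}

#' Fit a Hill activation function to a dose-response curve
#'
#' Least-squares fit of `v = Vmax * x^n / (K^n + x^n)` used to recover the
#' allosteric cooperativity of the feedback synthase from its synthesis-rate
#' response (see [sasb_activation_rate()]).
#'
#' @param x Dose (concentration) grid, strictly positive.
#' @param v Response values.
#' @return List with `Vmax`, `K`, `n`, and the `nls` fit object.
#' @export
fit_hill <- function(x, v) {
  stopifnot(length(x) == length(v), all(x > 0))
  start <- list(Vmax = max(v) * 1.05, K = exp(mean(log(x))), n = 1.5)
  fit <- minpack.lm::nlsLM(
    v ~ Vmax * x^n / (K^n + x^n),
    start = start,
    lower = c(Vmax = 1e-12, K = 1e-12, n = 0.1),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- coef(fit)
  list(Vmax = unname(cf["Vmax"]), K = unname(cf["K"]), n = unname(cf["n"]),
       fit = fit)
}
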