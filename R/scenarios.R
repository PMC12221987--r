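#' Built-in scenario table
#'
#' Returns the packaged table of emulated experimental conditions (genotype x
#' environment), each resolving to a complete parameter set for the three
#' synthetic-data generators: phenomenological kill curves
#' ([generate_kill_curve()]), cytometry event tables ([generate_cytometry()])
#' and the mechanistic single-cell model ([simulate_cells()],
#' [simulate_lineage()]). Every non-default number in the table carries a
#' citation anchor recorded in the `citation` field. The table lives in
#' `inst/extdata/scenarios.yaml` and is append-only.
#'
#' @return A tibble with one row per scenario: `name`, `description`,
#'   `mic_multiple`, kill-curve parameters (`f`, `k_s`, `k_p`, `N0`),
#'   cytometry parameters (`low_gtp_weight`, `bulk_F_mean`, `dormant_F_mean`,
#'   `growth_rate`), `serial_passage`, `inducer`, `pre_exposure` and
#'   `citation`. The full nested records are attached as the `specs` attribute
#'   and retrievable per scenario with [get_scenario()].
#' @examples
#' scenario_table()[, c("name", "f", "k_s")]
#' @export
scenario_table <- function() {
  raw <- yaml::read_yaml(
    system.file("extdata", "scenarios.yaml", package = "persisterkit")
  )
  specs <- raw$scenarios
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  tab <- purrr::map_dfr(specs, function(s) {
    tibble(
      name = s$name,
      description = s$description,
      mic_multiple = s$mic_multiple,
      f = s$kill_params$f,
      k_s = s$kill_params$k_s,
      k_p = s$kill_params$k_p,
      N0 = s$kill_params$N0,
      low_gtp_weight = s$cytometry$low_gtp_weight,
      bulk_F_mean = s$cytometry$bulk_F_mean,
      dormant_F_mean = s$cytometry$dormant_F_mean,
      growth_rate = s$cytometry$growth_rate,
      serial_passage = s$environment$serial_passage,
      inducer = s$environment$inducer,
      pre_exposure = s$environment$pre_exposure,
      citation = s$citation
    )
  })
  validate_scenarios(tab)
  attr(tab, "specs") <- specs
  attr(tab, "schema_version") <- raw$schema_version
  tab
}

validate_scenarios <- function(tab) {
  stopifnot(
    all(tab$f > 0), all(tab$f < 1),
    all(tab$k_p < tab$k_s),
    all(tab$N0 > 0),
    all(tab$low_gtp_weight >= 0), all(tab$low_gtp_weight <= 1),
    !anyDuplicated(tab$name),
    all(nzchar(tab$citation))
  )
  invisible(tab)
}

#' Look up one scenario by name
#'
#' @param name Scenario name as listed by [scenario_table()].
#' @return A `scenario_spec` list with elements `name`, `description`,
#'   `genotype`, `environment`, `mic_multiple`, `kill_params`, `cytometry`,
#'   `mechanistic` and `citation`.
#' @examples
#' get_scenario("WT_exponential_VAN")$kill_params$f
#' @export
get_scenario <- function(name) {
  specs <- attr(scenario_table(), "specs")
  if (!name %in% names(specs)) {
    abort(paste0("unknown scenario `", name, "`; available: ",
                 paste(names(specs), collapse = ", ")))
  }
  structure(specs[[name]], class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", x$name, "-", x$description, "\n")
  kp <- x$kill_params
  cat(sprintf("  kill: f=%.3g  k_s=%.3g/h  k_p=%.3g/h  N0=%.3g CFU/ml\n",
              kp$f, kp$k_s, kp$k_p, kp$N0))
  cat(sprintf("  cytometry: low-GTP weight=%.3g  growth=%.3g/h\n",
              x$cytometry$low_gtp_weight, x$cytometry$growth_rate))
  cat("  citation:", x$citation, "\n")
  invisible(x)
}

#' Resolve a scenario's mechanistic model parameters
#'
#' Applies a scenario's mechanistic modifiers (basal-synthesis multiplier for
#' starvation induction, feedback removal for graded mutants, GTP-supply
#' reduction for guanine-nucleotide-synthesis knockdown, envelope-stress
#' synthesis for antibiotic exposure, alarmone-null) to the default
#' [model_params()].
#'
#' @param scenario A `scenario_spec` from [get_scenario()] or a scenario name.
#' @param params Base parameter set to modify.
#' @return A `model_params` object.
#' @export
scenario_model_params <- function(scenario, params = model_params()) {
  if (is.character(scenario)) scenario <- get_scenario(scenario)
  m <- scenario$mechanistic %||% list()
  if (isTRUE(m$ppgpp_null)) {
    params$V_R <- 1e-9; params$V_B <- 0; params$V_A <- 0
  }
  if (!is.null(m$v_r_factor)) params$V_R <- params$V_R * m$v_r_factor
  if (!is.null(m$v_b_factor)) params$V_B <- params$V_B * m$v_b_factor
  if (!is.null(m$v_g_factor)) params$v_G <- params$v_G * m$v_g_factor
  if (!is.null(m$n_b_override)) params$n_B <- m$n_b_override
  if (!is.null(m$v_a)) params$V_A <- m$v_a
  if (!is.null(m$sigma_eta)) params$sigma_eta <- m$sigma_eta
  if (identical(m$feedback, "graded")) params <- graded_params(params)
  validate_model_params(params)
  params
}
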