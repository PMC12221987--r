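#' Run configuration for end-to-end reproduction recipes
#'
#' A fully serializable bundle of the knobs a pipeline run depends on. Every
#' recipe writes the resolved configuration (plus its hash) alongside its
#' outputs so any artifact can be traced to the exact settings and master
#' seed that produced it. Per-stage seeds derive from the master seed via
#' [split_seed()].
#'
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed).
#' @param n_reps Replicates per condition.
#' @param gating_fold Gate multiple for [gate_low_gtp()].
#' @param endpoint_h Persistence endpoint, hours.
#' @param dt Integrator step, minutes.
#' @param n_events Cytometry events per sample.
#' @param scenarios Scenario set for sweep-style recipes.
#' @param lineage_divisions Division events for the lineage recipe.
#' @return Object of class `run_config` (named list).
#' @export
run_config <- function(seed = 1, out_dir = tempfile("persisterkit_run_"),
                       n_reps = 3, gating_fold = 5, endpoint_h = 5, dt = 0.1,
                       n_events = 2e5, scenarios = carbon_source_scenarios(),
                       lineage_divisions = 30000) {
  structure(list(seed = seed, out_dir = out_dir, n_reps = n_reps,
                 gating_fold = gating_fold, endpoint_h = endpoint_h, dt = dt,
                 n_events = n_events, scenarios = scenarios,
                 lineage_divisions = lineage_divisions),
            class = "run_config")
}

config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Execute an end-to-end reproduction recipe
#'
#' Each recipe chains the synthetic-data generators and the matching analysis
#' modules for one figure-level result family and writes its tables and fit
#' reports (CSV/JSON with provenance headers) into `config$out_dir`:
#'
#' * `killcurves`: kill-curve generation and biphasic fits for the wild-type,
#'   alarmone-null, starvation-triggered and serial-passage scenarios, with
#'   condition comparisons (persister fraction, MDK99).
#' * `sweep`: the carbon-source condition sweep and its uncoupling report.
#' * `sortkill`: cytometry generation, gating and the in-silico sort-and-kill
#'   experiment.
#' * `induction`: antibiotic-induced persistence (induced low-GTP fraction
#'   and the pretreated-versus-untreated persister comparison).
#' * `all`: every recipe above.
#'
#' Any stage failure aborts with a stage-named diagnostic; outputs written
#' before the failure are preserved.
#'
#' @param name Recipe name.
#' @param config A [run_config()].
#' @return Invisible named list of written file paths.
#' @export
run_recipe <- function(name = c("killcurves", "sweep", "sortkill",
                                "induction", "all"),
                       config = run_config()) {
  recipes <- c("killcurves", "sweep", "sortkill", "induction", "all")
  if (!is.character(name) || !name[1] %in% recipes) {
    abort(paste0("unknown recipe `", name[1], "`; available: ",
                 paste(recipes, collapse = ", ")))
  }
  name <- name[1]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(seed = config$seed, config_hash = config_hash(config))
  jsonlite::write_json(
    c(unclass(config), list(config_hash = config_hash(config))),
    file.path(config$out_dir, "run_config.json"), auto_unbox = TRUE)
  written <- list(config = file.path(config$out_dir, "run_config.json"))
  if (name %in% c("killcurves", "all")) {
    written <- c(written, run_stage("killcurves", recipe_killcurves, config, prov))
  }
  if (name %in% c("sweep", "all")) {
    written <- c(written, run_stage("sweep", recipe_sweep, config, prov))
  }
  if (name %in% c("sortkill", "all")) {
    written <- c(written, run_stage("sortkill", recipe_sortkill, config, prov))
  }
  if (name %in% c("induction", "all")) {
    written <- c(written, run_stage("induction", recipe_induction, config, prov))
  }
  invisible(written)
}

run_stage <- function(stage, fn, config, prov) {
  tryCatch(fn(config, prov), error = function(e) {
    abort(sprintf("recipe stage `%s` failed: %s", stage, conditionMessage(e)))
  })
}

recipe_killcurves <- function(config, prov) {
  scens <- c("WT_exponential_VAN", "ppGpp0_VAN", "WT_RHX_VAN",
             "WT_serial_passage_2")
  seeds <- split_seed(config$seed, length(scens), stream = 1L)
  all_curves <- list(); fits <- list()
  for (i in seq_along(scens)) {
    kc <- generate_kill_curve(scens[i], n_reps = config$n_reps,
                              seed = seeds[i])
    all_curves[[i]] <- kc
    fits[[scens[i]]] <- lapply(split(kc, kc$replicate), fit_biphasic)
  }
  curves <- dplyr::bind_rows(all_curves)
  p1 <- file.path(config$out_dir, "killcurves.csv")
  pk_write_csv(curves, p1, meta = prov)
  report <- lapply(fits, function(fl) {
    lapply(fl, function(ft) ft[c("f", "k_s", "k_p", "N0", "mdk99", "rss",
                                 "converged", "non_biphasic")])
  })
  report$comparisons <- list(
    ppGpp0_vs_WT_f = compare_conditions(fits$ppGpp0_VAN,
                                        fits$WT_exponential_VAN, "f"),
    RHX_vs_WT_f = compare_conditions(fits$WT_RHX_VAN,
                                     fits$WT_exponential_VAN, "f"),
    ppGpp0_vs_WT_mdk99 = compare_conditions(fits$ppGpp0_VAN,
                                            fits$WT_exponential_VAN, "mdk99")
  )
  p2 <- file.path(config$out_dir, "killcurve_fits.json")
  jsonlite::write_json(c(prov, report), p2, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  list(killcurves = p1, fits = p2)
}

recipe_sweep <- function(config, prov) {
  summ <- build_condition_summary(config$scenarios, n_reps = config$n_reps,
                                  seed = config$seed,
                                  n_events = config$n_events,
                                  endpoint_h = config$endpoint_h,
                                  gating_fold = config$gating_fold)
  rep <- uncoupling_report(summ)
  p1 <- file.path(config$out_dir, "condition_summary.csv")
  pk_write_csv(summ, p1, meta = prov)
  p2 <- file.path(config$out_dir, "uncoupling_report.json")
  jsonlite::write_json(
    c(prov, list(correlations = rep$correlations,
                 verdicts = as.list(rep$verdicts), alpha = rep$alpha)),
    p2, auto_unbox = TRUE, digits = NA, force = TRUE)
  list(condition_summary = p1, uncoupling = p2)
}

recipe_sortkill <- function(config, prov) {
  seeds <- split_seed(config$seed, 2, stream = 3L)
  cyt <- generate_cytometry("WT_exponential_VAN", n_events = config$n_events,
                            seed = seeds[1])
  corr <- subtract_autofluorescence(cyt$sample, cyt$control)
  gate <- gate_low_gtp(corr, fold = config$gating_fold)
  sk <- sort_and_kill(cyt$sample, top_fraction = 0.001,
                      duration_h = config$endpoint_h, seed = seeds[2])
  p1 <- file.path(config$out_dir, "sort_and_kill.csv")
  pk_write_csv(sk, p1, meta = prov)
  p2 <- file.path(config$out_dir, "gate.json")
  jsonlite::write_json(
    c(prov, gate[c("threshold", "fraction", "n_gated", "n_events", "fold")]),
    p2, auto_unbox = TRUE, digits = NA)
  list(sort_and_kill = p1, gate = p2)
}

recipe_induction <- function(config, prov) {
  seeds <- split_seed(config$seed, 4, stream = 4L)
  pre <- generate_cytometry("WT_untreated_BAC", n_events = config$n_events,
                            seed = seeds[1])
  post <- generate_cytometry("WT_bacitracin_pretreat_BAC",
                             n_events = config$n_events, seed = seeds[2])
  g_pre <- gate_low_gtp(subtract_autofluorescence(pre$sample, pre$control),
                        fold = config$gating_fold)
  g_post <- gate_low_gtp(subtract_autofluorescence(post$sample, post$control),
                         fold = config$gating_fold)
  ind <- induced_fraction(g_pre, g_post)
  kc_un <- generate_kill_curve("WT_untreated_BAC", n_reps = config$n_reps,
                               seed = seeds[3])
  kc_pre <- generate_kill_curve("WT_bacitracin_pretreat_BAC",
                                n_reps = config$n_reps, seed = seeds[4])
  fit_un <- lapply(split(kc_un, kc_un$replicate), fit_biphasic)
  fit_pre <- lapply(split(kc_pre, kc_pre$replicate), fit_biphasic)
  cmp <- compare_conditions(fit_pre, fit_un, "f")
  p1 <- file.path(config$out_dir, "induction.json")
  jsonlite::write_json(
    c(prov, list(induced_low_gtp_fraction = ind$value,
                 before = ind$before, after = ind$after,
                 persister_fold_increase = cmp$fold_change,
                 p_value = cmp$p_value)),
    p1, auto_unbox = TRUE, digits = NA)
  list(induction = p1)
}
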