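#' Build a replicate-level condition summary across scenarios
#'
#' Runs the full generator-plus-analysis chain for each scenario and
#' replicate: a kill curve is generated and fitted (persister fraction,
#' MDK99, 5-h endpoint survival) and a cytometry sample with matched control
#' is generated, corrected and gated; the scenario growth rate is recorded
#' with replicate-level noise. One row per replicate, matching how
#' condition-sweep correlations are computed (replicates are the unit, not
#' condition means). Fit failures propagate as missing cells with a message,
#' never as silent drops.
#'
#' @param scenarios Character vector of scenario names; default the
#'   five-carbon-source sweep.
#' @param n_reps Replicates per scenario.
#' @param seed Master seed; per-stage child seeds derive via [split_seed()].
#' @param n_events Cytometry events per replicate.
#' @param endpoint_h Endpoint for the persistence estimate, hours.
#' @param gating_fold Gate multiple for [gate_low_gtp()].
#' @param growth_cv Replicate-level CV of the recorded growth rate.
#' @return Tibble: `scenario`, `replicate`, `growth_rate` (1/h), `mdk99`
#'   (h), `persistence` (endpoint surviving fraction), `low_gtp_fraction`,
#'   `mean_F` (AU).
#' @export
build_condition_summary <- function(scenarios = carbon_source_scenarios(),
                                    n_reps = 3, seed = 1, n_events = 2e5,
                                    endpoint_h = 5, gating_fold = 5,
                                    growth_cv = 0.04) {
  grid <- expand.grid(scenario = scenarios, replicate = seq_len(n_reps),
                      stringsAsFactors = FALSE)
  seeds <- split_seed(seed, nrow(grid) * 3, stream = 11L)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    sc_name <- grid$scenario[i]
    rep_i <- grid$replicate[i]
    sc <- get_scenario(sc_name)
    s_kill <- seeds[3 * i - 2]; s_cyt <- seeds[3 * i - 1]; s_gr <- seeds[3 * i]
    row <- tibble(scenario = sc_name, replicate = rep_i,
                  growth_rate = NA_real_, mdk99 = NA_real_,
                  persistence = NA_real_, low_gtp_fraction = NA_real_,
                  mean_F = NA_real_)
    kc <- generate_kill_curve(sc, n_reps = 1, seed = s_kill)
    fit <- tryCatch(fit_biphasic(kc), error = function(e) {
      inform(sprintf("fit failed for %s rep %d: %s", sc_name, rep_i,
                     conditionMessage(e)))
      NULL
    })
    if (!is.null(fit) && fit$converged) {
      row$mdk99 <- fit$mdk99
      row$persistence <- persister_fraction(kc, method = "endpoint",
                                            endpoint_h = endpoint_h)
    }
    cyt <- generate_cytometry(sc, n_events = n_events, seed = s_cyt)
    corr <- subtract_autofluorescence(cyt$sample, cyt$control)
    g <- gate_low_gtp(corr, fold = gating_fold)
    row$low_gtp_fraction <- g$fraction
    row$mean_F <- g$mean_F
    row$growth_rate <- with_seed(s_gr, {
      sc$cytometry$growth_rate * exp(rnorm(1, 0, growth_cv))
    })
    row
  })
}

#' Names of the carbon-source sweep scenarios
#' @return Character vector of the five sweep scenarios.
#' @export
carbon_source_scenarios <- function() {
  c("WT_glucose_VAN", "WT_pyruvate_VAN", "WT_glycerol_VAN",
    "WT_succinate_VAN", "WT_glutamate_VAN")
}

#' Pearson correlation with two-tailed test
#'
#' Standard Pearson correlation with a t-distributed two-tailed p-value,
#' with optional log10 transforms for quantities that span decades
#' (fractions). Zero variance in either variable yields an undefined
#' correlation reported as such, not an error.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @param log_x,log_y Apply log10 before correlating.
#' @return List: `r`, `p_value`, `n`, `note`.
#' @export
pearson_test <- function(x, y, log_x = FALSE, log_y = FALSE) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("need at least 3 paired values")
  if (log_x) x <- log10(x)
  if (log_y) y <- log10(y)
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = length(x),
                note = "undefined: zero variance"))
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       note = NULL)
}

#' Correlation matrix and uncoupling verdicts for a condition sweep
#'
#' Computes the six pairwise correlations of the condition sweep (growth
#' rate, tolerance as MDK99, persistence as endpoint survival, low-GTP gated
#' fraction, mean reporter fluorescence) at replicate level, flags each at
#' `alpha`, and emits the headline verdict tuple that separates persistence
#' from tolerance: tolerance tracks the population growth rate while
#' persistence tracks the low-GTP outlier fraction and not the growth rate.
#' Persistence and gated fractions are correlated on the log10 scale (they
#' span decades); growth rate and MDK99 on the linear scale.
#'
#' @param summary Condition-summary table from [build_condition_summary()],
#'   at least 4 conditions with at least 3 replicates each.
#' @param alpha Significance level.
#' @return Object of class `uncoupling_report`: `correlations` (tibble:
#'   pair, r, p_value, n, significant), `verdicts` (named logical:
#'   `growth_tolerance`, `growth_persistence`, `lowgtp_persistence`,
#'   `lowgtp_tolerance`), `alpha`.
#' @export
uncoupling_report <- function(summary, alpha = 0.05) {
  n_cond <- length(unique(summary$scenario))
  n_rep <- min(table(summary$scenario))
  if (n_cond < 4) abort("need at least 4 conditions for the sweep verdicts")
  if (n_rep < 3) abort("need at least 3 replicates per condition")
  pairs <- list(
    growth_tolerance   = list("growth_rate", "mdk99", FALSE, FALSE),
    growth_persistence = list("growth_rate", "persistence", FALSE, TRUE),
    growth_lowgtp      = list("growth_rate", "low_gtp_fraction", FALSE, TRUE),
    growth_meanF       = list("growth_rate", "mean_F", FALSE, FALSE),
    lowgtp_persistence = list("low_gtp_fraction", "persistence", TRUE, TRUE),
    lowgtp_tolerance   = list("low_gtp_fraction", "mdk99", TRUE, FALSE)
  )
  cors <- purrr::map_dfr(names(pairs), function(nm) {
    sp <- pairs[[nm]]
    pt <- pearson_test(summary[[sp[[1]]]], summary[[sp[[2]]]],
                       log_x = sp[[3]], log_y = sp[[4]])
    tibble(pair = nm, x = sp[[1]], y = sp[[2]], r = pt$r,
           p_value = pt$p_value, n = pt$n,
           significant = is.finite(pt$p_value) && pt$p_value < alpha)
  })
  sig <- setNames(cors$significant, cors$pair)
  verdicts <- c(
    growth_tolerance   = unname(sig["growth_tolerance"]),
    growth_persistence = unname(sig["growth_persistence"]),
    lowgtp_persistence = unname(sig["lowgtp_persistence"]),
    lowgtp_tolerance   = unname(sig["lowgtp_tolerance"])
  )
  structure(list(correlations = cors, verdicts = verdicts, alpha = alpha),
            class = "uncoupling_report")
}

#' @export
print.uncoupling_report <- function(x, ...) {
  cat("<uncoupling_report> alpha =", x$alpha, "\n")
  df <- as.data.frame(x$correlations[, c("pair", "r", "p_value", "significant")])
  df$r <- round(df$r, 3)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  v <- x$verdicts
  cat(sprintf("  growth-tolerance %s | growth-persistence %s | lowGTP-persistence %s | lowGTP-tolerance %s\n",
              ifelse(v[1], "coupled", "uncoupled"),
              ifelse(v[2], "coupled", "uncoupled"),
              ifelse(v[3], "coupled", "uncoupled"),
              ifelse(v[4], "coupled", "uncoupled")))
  invisible(x)
}
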