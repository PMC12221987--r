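#' Fit the two-compartment (biphasic) killing model to one kill curve
#'
#' Least-squares fit of `log10 S(t) = log10[(1-f) e^(-k_s t) + f e^(-k_p t)]`
#' to a single replicate's CFU trajectory. Fitting is done in log10-survival
#' space (kill curves span many decades, so equal weight per timepoint is the
#' sensible loss), with below-detection points entering as one-sided censored
#' residuals (penalized only when the model predicts counts above the limit)
#' rather than being dropped. The optimizer uses 8 deterministic starts
#' spanning `f` from 1e-4 to 1e-1 (ties broken by RSS, then by smaller `f`)
#' on the unconstrained parameterization `(logit f, log k_s, log k_p/k_s
#' ratio, log N0)`, which enforces `0 < f < 1` and `0 <= k_p < k_s`. A
#' single-exponential model is always fitted alongside; when it achieves the
#' lower AIC the result is reported as non-biphasic with `f` at the zero
#' boundary.
#'
#' @param curve Data frame for one condition and replicate with columns
#'   `time` (hours, including 0), `cfu` (CFU/ml), and optionally
#'   `below_detection` and `detection_limit`. At least 4 quantified
#'   timepoints, one beyond 1 h.
#' @param n_starts Number of deterministic persister-fraction starts.
#' @param k_p_fixed Optional known persister kill rate (1/h). Over a 5-h
#'   series the plateau decay `k_p` is weakly identified and trades off
#'   against `f`, inflating the plateau-fraction variance several-fold; when
#'   an independent estimate exists (e.g. from the kill curve of sorted
#'   persisters), fixing it makes `f` a direct, stable plateau readout. The
#'   default fits `k_p` freely.
#' @return An object of class `biphasic_fit`: list with `f`, `k_s`, `k_p`,
#'   `N0`, `rss` (log10 space), `converged`, `non_biphasic`, `mdk99` (hours,
#'   via [mdk99()]), `se` (approximate parameter standard errors on the
#'   transformed scale, NA when the curvature is singular), `n_points`,
#'   `n_censored`, `aic_biphasic`, `aic_single`, `status`.
#' @examples
#' kc <- generate_kill_curve(kill_params = list(f = 1e-3, k_s = 4.6,
#'   k_p = 0.01, N0 = 1e8), noiseless = TRUE)
#' fit <- fit_biphasic(kc[kc$replicate == 1, ])
#' fit$f
#' @export
fit_biphasic <- function(curve, n_starts = 8, k_p_fixed = NULL) {
  curve <- as_tibble(curve)
  stopifnot(all(c("time", "cfu") %in% names(curve)))
  if (!"below_detection" %in% names(curve)) curve$below_detection <- FALSE
  if (!"detection_limit" %in% names(curve)) curve$detection_limit <- 0
  curve <- dplyr::arrange(curve, .data$time)
  if (!0 %in% curve$time) abort("kill curve must contain a t = 0 point")
  quant <- !curve$below_detection
  if (all(curve$below_detection)) {
    return(new_biphasic_fit(status = "unfit_all_below_detection"))
  }
  if (sum(quant) < 4) abort("need >= 4 quantified timepoints")
  if (max(curve$time[quant]) <= 1) abort("need a quantified point past 1 h")

  s0 <- curve$cfu[curve$time == 0][1]
  surv <- curve$cfu / s0
  if (any(diff(log10(pmax(curve$cfu[quant], 1e-300))) > 1)) {
    warn("gross non-monotone survival (>10x increase between timepoints); fitting anyway")
  }
  if (any(surv[quant] > 1.05)) {
    warn("survival above 1 at some timepoints; tolerated with warning")
  }

  t <- curve$time
  y <- log10(curve$cfu)
  lim <- log10(pmax(curve$detection_limit, 1e-300))
  cens <- curve$below_detection

  unpack <- function(theta) {
    f <- stats::plogis(theta[1])
    k_s <- exp(theta[2])
    k_p <- if (is.null(k_p_fixed)) k_s * stats::plogis(theta[3])
           else min(k_p_fixed, 0.999 * k_s)
    N0 <- exp(theta[length(theta)])
    list(f = f, k_s = k_s, k_p = k_p, N0 = N0)
  }
  obj <- function(theta) {
    p <- unpack(theta)
    pred <- log10(p$N0 * biexp_survival(t, p$f, p$k_s, p$k_p))
    r <- ifelse(cens, pmax(0, pred - lim), y - pred)
    sum(r^2)
  }
  n_free <- if (is.null(k_p_fixed)) 4L else 3L

  # slope-based initial k_s from the first decades of killing
  early <- quant & t <= max(2, sort(t[t > 0])[2])
  ks0 <- tryCatch({
    sl <- -coef(lm(y[early] ~ t[early]))[2] * log(10)
    max(min(sl, 20), 0.2)
  }, error = function(e) 2)
  f_starts <- 10^seq(-4, -1, length.out = n_starts)

  best <- NULL
  for (f0 in f_starts) {
    theta0 <- if (is.null(k_p_fixed)) {
      c(stats::qlogis(f0), log(ks0), stats::qlogis(0.01), log(s0))
    } else {
      c(stats::qlogis(f0), log(ks0), log(s0))
    }
    fit <- tryCatch(
      optim(theta0, obj, method = "BFGS",
            control = list(maxit = 300, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 &&
         stats::plogis(fit$par[1]) < stats::plogis(best$par[1]))) {
      best <- fit
    }
  }
  if (is.null(best)) return(new_biphasic_fit(status = "optim_failed"))

  # Levenberg-Marquardt polish from the best start: BFGS plateaus near the
  # optimum on these ill-scaled problems, LM converges to machine precision
  res_fn <- function(theta) {
    p <- unpack(theta)
    pred <- log10(p$N0 * biexp_survival(t, p$f, p$k_s, p$k_p))
    ifelse(cens, pmax(0, pred - lim), y - pred)
  }
  pol <- tryCatch(
    minpack.lm::nls.lm(best$par, fn = res_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (!is.null(pol) && sum(pol$fvec^2) <= best$value + 1e-15) {
    best$par <- pol$par
    best$value <- sum(pol$fvec^2)
    best$convergence <- if (pol$info %in% 1:4) 0L else best$convergence
  }

  # single-exponential reference model (f at the 0 boundary)
  obj1 <- function(th) {
    pred <- log10(exp(th[2])) - exp(th[1]) * t / log(10)
    r <- ifelse(cens, pmax(0, pred - lim), y - pred)
    sum(r^2)
  }
  fit1 <- optim(c(log(ks0), log(s0)), obj1, method = "BFGS",
                control = list(maxit = 300, reltol = 1e-10))
  n_pts <- length(t)
  aic_bi <- n_pts * log(max(best$value, 1e-300) / n_pts) + 2 * n_free
  aic_1 <- n_pts * log(max(fit1$value, 1e-300) / n_pts) + 2 * 2
  non_biphasic <- aic_1 <= aic_bi

  if (non_biphasic) {
    k_s <- exp(fit1$par[1])
    out <- new_biphasic_fit(
      f = 0, k_s = k_s, k_p = 0, N0 = exp(fit1$par[2]),
      rss = fit1$value, converged = fit1$convergence == 0,
      non_biphasic = TRUE, n_points = n_pts, n_censored = sum(cens),
      aic_biphasic = aic_bi, aic_single = aic_1, status = "ok")
  } else {
    h <- tryCatch(optim(best$par, obj, method = "BFGS", hessian = TRUE,
                        control = list(maxit = 1)),
                  error = function(e) NULL)
    se <- rep(NA_real_, n_free)
    if (!is.null(h)) {
      sigma2 <- best$value / max(n_pts - n_free, 1)
      cv <- tryCatch(solve(h$hessian / 2) * sigma2, error = function(e) NULL)
      if (!is.null(cv) && all(diag(cv) >= 0)) se <- sqrt(diag(cv))
    }
    pb <- unpack(best$par)
    out <- new_biphasic_fit(
      f = pb$f, k_s = pb$k_s, k_p = pb$k_p, N0 = pb$N0,
      rss = best$value, converged = best$convergence == 0,
      non_biphasic = FALSE, se = se, n_points = n_pts,
      n_censored = sum(cens), aic_biphasic = aic_bi, aic_single = aic_1,
      status = "ok")
  }
  if (out$converged && !out$non_biphasic) out$mdk99 <- mdk99(out)
  if (out$converged && out$non_biphasic) out$mdk99 <- log(100) / out$k_s
  out
}

new_biphasic_fit <- function(f = NA_real_, k_s = NA_real_, k_p = NA_real_,
                             N0 = NA_real_, rss = NA_real_, converged = FALSE,
                             non_biphasic = FALSE, se = rep(NA_real_, 4),
                             n_points = 0L, n_censored = 0L,
                             aic_biphasic = NA_real_, aic_single = NA_real_,
                             status = "unfit") {
  structure(
    list(f = f, k_s = k_s, k_p = k_p, N0 = N0, rss = rss,
         converged = converged, non_biphasic = non_biphasic,
         mdk99 = NA_real_, se = se, n_points = n_points,
         n_censored = n_censored, aic_biphasic = aic_biphasic,
         aic_single = aic_single, status = status),
    class = "biphasic_fit")
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat("<biphasic_fit>", x$status,
      if (x$non_biphasic) "(non-biphasic: single-exponential preferred)", "\n")
  cat(sprintf("  f = %.4g  k_s = %.4g/h  k_p = %.4g/h  N0 = %.4g\n",
              x$f, x$k_s, x$k_p, x$N0))
  cat(sprintf("  MDK99 = %.4g h  RSS(log10) = %.4g  censored = %d/%d\n",
              x$mdk99, x$rss, x$n_censored, x$n_points))
  invisible(x)
}

#' Persister fraction of a kill curve
#'
#' Two first-class estimators of the persister level: the fitted plateau
#' fraction `f` of the two-compartment model (`method = "plateau"`) and the
#' surviving fraction at a fixed endpoint, by default 5 h
#' (`method = "endpoint"`). The two are reported side by side in pipeline
#' summaries since published persister levels are variously one or the other.
#'
#' @param curve One replicate's kill curve (see [fit_biphasic()]).
#' @param method `"plateau"` or `"endpoint"`.
#' @param endpoint_h Endpoint time, hours.
#' @param fit Optional pre-computed [fit_biphasic()] result (plateau method).
#' @return Persister fraction (numeric scalar).
#' @export
persister_fraction <- function(curve, method = c("plateau", "endpoint"),
                               endpoint_h = 5, fit = NULL) {
  method <- match.arg(method)
  if (method == "plateau") {
    fit <- fit %||% fit_biphasic(curve)
    return(fit$f)
  }
  curve <- dplyr::arrange(as_tibble(curve), .data$time)
  s0 <- curve$cfu[curve$time == 0][1]
  if (endpoint_h %in% curve$time) {
    return(curve$cfu[curve$time == endpoint_h][1] / s0)
  }
  lo <- max(curve$time[curve$time < endpoint_h])
  hi_ok <- any(curve$time > endpoint_h)
  if (!hi_ok) {
    abort(sprintf("endpoint %g h not present and not bracketed by data",
                  endpoint_h))
  }
  hi <- min(curve$time[curve$time > endpoint_h])
  y_lo <- log10(curve$cfu[curve$time == lo][1])
  y_hi <- log10(curve$cfu[curve$time == hi][1])
  y <- y_lo + (y_hi - y_lo) * (endpoint_h - lo) / (hi - lo)
  10^y / s0
}

#' MDK99 with persister subtraction
#'
#' Minimum duration of killing for 99% of the persister-subtracted
#' population. The fitted persister compartment is removed from the survival
#' curve, `S_adj(t) = (S(t) - f e^(-k_p t)) / (1 - f)`, and the MDK99 is the
#' time at which `S_adj` reaches 0.01 -- the logarithmic killing phase of the
#' susceptible compartment. With `k_p = 0` this is the closed form
#' `ln(100)/k_s`; otherwise it is found numerically on `S_adj`.
#'
#' @param fit A converged [fit_biphasic()] result, or a list with `f`, `k_s`,
#'   `k_p`.
#' @return MDK99 in hours. Carries attribute `caveat = TRUE` when the
#'   persister fraction is so large that the adjusted scale is unreliable.
#' @export
mdk99 <- function(fit) {
  if (inherits(fit, "biphasic_fit") && !fit$converged) {
    abort("mdk99 requires a converged fit")
  }
  f <- fit$f; k_s <- fit$k_s; k_p <- fit$k_p
  if (f < 1e-12 || f > 1 - 1e-12 || k_p == 0) {
    out <- log(100) / k_s
  } else {
    s_adj <- function(t) {
      (biexp_survival(t, f, k_s, k_p) - f * exp(-k_p * t)) / (1 - f) - 0.01
    }
    # S_adj is exp(-k_s t), so the root is bracketed by 2 ln(100)/k_s
    upper <- 2 * log(100) / k_s
    out <- tryCatch(uniroot(s_adj, c(1e-12, upper), tol = 1e-12)$root,
                    error = function(e) log(100) / k_s)
  }
  if (f > 0.9) attr(out, "caveat") <- TRUE
  out
}

#' Compare a persistence or tolerance metric between two conditions
#'
#' Unpaired two-tailed t-test between replicate-level fits of two conditions.
#' Fractions (`f`, `endpoint`) are compared on the log10 scale with a
#' geometric-mean fold change (they span decades); MDK99 is compared
#' arithmetically.
#'
#' @param fitsA,fitsB Lists of [fit_biphasic()] results, or numeric vectors of
#'   the metric itself.
#' @param metric `"f"`, `"mdk99"` or `"endpoint"` (for `"endpoint"` pass
#'   numeric vectors).
#' @return List: `fold_change` (A relative to B), `p_value`, `metric`,
#'   `mean_A`, `mean_B`, `n_A`, `n_B`, `note`.
#' @export
compare_conditions <- function(fitsA, fitsB, metric = c("f", "mdk99", "endpoint")) {
  metric <- match.arg(metric)
  extract <- function(fits) {
    if (is.numeric(fits)) return(fits)
    vapply(fits, function(ft) {
      switch(metric, f = ft$f, mdk99 = ft$mdk99, endpoint = ft$f)
    }, numeric(1))
  }
  a <- extract(fitsA); b <- extract(fitsB)
  if (length(a) < 3 || length(b) < 3) {
    warn("fewer than 3 replicates in a group; comparison is underpowered")
  }
  log_scale <- metric %in% c("f", "endpoint")
  xa <- if (log_scale) log10(a) else a
  xb <- if (log_scale) log10(b) else b
  if (var(xa) == 0 && var(xb) == 0) {
    return(list(fold_change = if (log_scale) geomean(a) / geomean(b)
                else mean(a) / mean(b),
                p_value = NA_real_, metric = metric,
                mean_A = mean(a), mean_B = mean(b),
                n_A = length(a), n_B = length(b),
                note = "exact tie: zero variance in both groups, no p-value"))
  }
  tt <- t.test(xa, xb, var.equal = FALSE)
  list(
    fold_change = if (log_scale) geomean(a) / geomean(b) else mean(a) / mean(b),
    p_value = tt$p.value, metric = metric,
    mean_A = if (log_scale) geomean(a) else mean(a),
    mean_B = if (log_scale) geomean(b) else mean(b),
    n_A = length(a), n_B = length(b), note = NULL
  )
}
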