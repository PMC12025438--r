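#' Transition parameters for one treatment-state pair
#'
#' Within a health state, the monthly probability of progression after `t`
#' months in the state is `alpha * (1 + beta)^(t - 1)`; the monthly
#' probability of death before progression is `gamma`; the monthly
#' probability of death after progression is `delta`.
#'
#' @param alpha monthly baseline progression probability in `[0, 1]`.
#' @param beta per-month multiplicative trend, `> -1` (0 = constant hazard).
#' @param gamma monthly pre-progression death probability in `[0, 1]`.
#' @param delta monthly post-progression death probability in `[0, 1]`.
#' @param horizon months over which the joint constraint
#'   `alpha * (1 + beta)^(t - 1) + gamma <= 1` is checked; `NULL` skips it
#'   (the projection then clamps, with a flag).
#' @return object of class `transition_params`.
#' @export
transition_params <- function(alpha, beta, gamma, delta, horizon = NULL) {
  stopifnot(length(alpha) == 1, length(beta) == 1,
            length(gamma) == 1, length(delta) == 1)
  if (alpha < 0 || alpha > 1 || gamma < 0 || gamma > 1 ||
      delta < 0 || delta > 1) {
    stop("alpha, gamma, delta must lie in [0, 1]", call. = FALSE)
  }
  if (beta <= -1) stop("beta must exceed -1", call. = FALSE)
  if (!is.null(horizon)) {
    tmax <- if (beta > 0) horizon else 1
    if (alpha * (1 + beta)^(tmax - 1) + gamma > 1 + 1e-12) {
      stop("alpha*(1+beta)^(t-1) + gamma exceeds 1 within the horizon",
           call. = FALSE)
    }
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta),
            class = "transition_params")
}

#' @export
print.transition_params <- function(x, ...) {
  cat(sprintf(
    "transition_params: alpha=%.4g beta=%.4g gamma=%.4g delta=%.4g\n",
    x$alpha, x$beta, x$gamma, x$delta))
  invisible(x)
}

#' Monthly progression probability
#'
#' `alpha * (1 + beta)^(t - 1)`, clamped (with a warning) so that the result
#' plus `gamma` does not exceed 1.
#'
#' @param params a [transition_params()].
#' @param t month index within the state, integer `>= 1`; vectorized.
#' @return numeric vector of probabilities.
#' @export
progression_probability <- function(params, t) {
  if (any(t < 1) || any(t != round(t))) {
    stop("t must be an integer month index >= 1", call. = FALSE)
  }
  p <- params$alpha * (1 + params$beta)^(t - 1)
  cap <- 1 - params$gamma
  if (any(p > cap + 1e-15)) {
    warning("progression probability clamped at 1 - gamma", call. = FALSE)
    p <- pmin(p, cap)
  }
  p
}

#' Deterministic cohort projection of PFS and OS
#'
#' Projects the population-level survival curves implied by one set of
#' transition parameters: with `u(0) = 1` progression-free and `v(0) = 0`
#' progressed,
#' `u(t) = u(t-1) * (1 - P(t) - gamma)` and
#' `v(t) = v(t-1) * (1 - delta) + u(t-1) * P(t)`, where
#' `P(t) = alpha * (1 + beta)^(t-1)` (clamped at `1 - gamma`).
#' `PFS(t) = u(t)` and `OS(t) = u(t) + v(t)`.
#'
#' @param params a [transition_params()].
#' @param horizon projection length in months, `>= 1`.
#' @param label prefix for the output curve labels.
#' @return list with `pfs` and `os` ([km_curve()]s over months `0:horizon`),
#'   and `clamped` (was the progression probability ever clamped?).
#' @export
project_cohort <- function(params, horizon, label = "model") {
  stopifnot(horizon >= 1)
  p <- params$alpha * (1 + params$beta)^(seq_len(horizon) - 1)
  clamped <- any(p > 1 - params$gamma + 1e-15)
  p <- pmin(p, 1 - params$gamma)
  u <- v <- numeric(horizon)
  u_prev <- 1; v_prev <- 0
  for (t in seq_len(horizon)) {
    u[t] <- max(0, u_prev * (1 - p[t] - params$gamma))
    v[t] <- v_prev * (1 - params$delta) + u_prev * p[t]
    u_prev <- u[t]; v_prev <- v[t]
  }
  list(
    pfs = km_curve(0:horizon, c(1, u), label = paste0(label, " PFS")),
    os = km_curve(0:horizon, c(1, u + v), label = paste0(label, " OS")),
    clamped = clamped
  )
}

#' Mean-squared error between model and empirical PFS/OS curves
#'
#' Squared differences are pooled over both endpoints and every integer
#' month from 1 to the empirical follow-up (last observation carried
#' forward), then averaged with the given endpoint weights (equal by
#' default).
#'
#' @param model list with `pfs` and `os` [km_curve()]s.
#' @param empirical list with `pfs` and `os` [km_curve()]s.
#' @param weights length-2 numeric weights for (PFS, OS).
#' @param months fitting grid; defaults to
#'   `1:floor(min(last follow-up of the empirical curves))`.
#' @return the weighted mean-squared error (probability squared).
#' @export
curve_mse <- function(model, empirical, weights = c(1, 1), months = NULL) {
  if (is.null(months)) {
    months <- seq_len(floor(min(max(empirical$pfs$time),
                                max(empirical$os$time))))
  }
  months <- months[months <= min(max(model$pfs$time), max(model$os$time))]
  if (!length(months)) stop("empty overlap of time grids", call. = FALSE)
  dp <- km_eval(model$pfs, months) - km_eval(empirical$pfs, months)
  do <- km_eval(model$os, months) - km_eval(empirical$os, months)
  (weights[1] * sum(dp^2) + weights[2] * sum(do^2)) /
    (sum(weights) * length(months))
}

#' Parameter grid for the transition fit
#'
#' @param alpha,beta,gamma,delta numeric `c(min, max, step)` per parameter.
#'   Defaults: alpha in `[0, 0.25]`, beta in `[-0.10, 0.10]`, gamma in
#'   `[0, 0.10]`, delta in `[0, 0.25]`, all with step 0.005.
#' @param refine number of coarse-to-fine refinement passes; each pass
#'   re-centres a grid of one-tenth the step on the incumbent, spanning one
#'   old step either side (clipped to the original bounds).
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(alpha = c(0, 0.25, 0.005),
                      beta = c(-0.10, 0.10, 0.005),
                      gamma = c(0, 0.10, 0.005),
                      delta = c(0, 0.25, 0.005),
                      refine = 1L) {
  for (p in list(alpha, beta, gamma, delta)) {
    if (length(p) != 3 || p[3] <= 0 || p[1] > p[2]) {
      stop("each grid is c(min, max, step) with step > 0 and min <= max",
           call. = FALSE)
    }
  }
  if (alpha[1] < 0 || gamma[1] < 0 || delta[1] < 0 || beta[1] <= -1 ||
      alpha[2] > 1 || gamma[2] > 1 || delta[2] > 1) {
    stop("grid bounds must respect the parameter domain", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                 refine = as.integer(refine)),
            class = "grid_spec")
}

grid_values <- function(g) {
  vals <- seq(g[1], g[2] + g[3] * 1e-9, by = g[3])
  round(vals, 12)
}

#' Grid-search calibration of transition parameters to PFS/OS curves
#'
#' Evaluates the pooled PFS/OS mean-squared error of [project_cohort()] at
#' every feasible grid point and returns the minimizer, with optional
#' coarse-to-fine refinement re-centred on the incumbent.  Ties in MSE are
#' broken deterministically by smallest `|beta|`, then smallest `alpha`,
#' `gamma`, `delta` (preferring the most constant hazard).  Points needing
#' clamping of the progression probability within the fitting horizon are
#' evaluated with clamping; a clamped winner is flagged.  When the fitted
#' `alpha` is 0 no patient progresses, so `delta` is unidentified and fixed
#' at its grid minimum by the tie-break; the result flags this.
#'
#' @param empirical list with `pfs` and `os` [km_curve()]s (the fitting grid
#'   is every integer month from 1 to their common follow-up).
#' @param spec a [grid_spec()].
#' @param weights length-2 endpoint weights for (PFS, OS).
#' @return object of class `seqcea_fit`: `params`
#'   ([transition_params()]), `mse`, `fitted` (model `pfs`/`os` curves),
#'   `clamped`, `delta_identified`, `n_evaluated`, and `benchmark` (`NULL`;
#'   see [parametric_benchmark_fit()]).
#' @export
grid_search_fit <- function(empirical, spec = grid_spec(),
                            weights = c(1, 1)) {
  horizon <- floor(min(max(empirical$pfs$time), max(empirical$os$time)))
  if (horizon < 1) stop("empirical follow-up shorter than one month",
                        call. = FALSE)
  pfs_emp <- km_eval(empirical$pfs, seq_len(horizon))
  os_emp <- km_eval(empirical$os, seq_len(horizon))

  run <- function(av, bv, gv, dv) {
    fit_grid_cpp(av, bv, gv, dv, pfs_emp, os_emp,
                 weights[1] / sum(weights), weights[2] / sum(weights))
  }
  av <- grid_values(spec$alpha); bv <- grid_values(spec$beta)
  gv <- grid_values(spec$gamma); dv <- grid_values(spec$delta)
  res <- run(av, bv, gv, dv)
  if (!is.finite(res$mse)) stop("no feasible grid point", call. = FALSE)
  n_eval <- res$n_evaluated

  for (r in seq_len(spec$refine)) {
    refine1 <- function(val, g) {
      step <- g[3] / 10
      lo <- max(g[1], val - g[3]); hi <- min(g[2], val + g[3])
      round(seq(lo, hi + step * 1e-9, by = step), 12)
    }
    res2 <- run(refine1(res$alpha, spec$alpha), refine1(res$beta, spec$beta),
                refine1(res$gamma, spec$gamma), refine1(res$delta, spec$delta))
    n_eval <- n_eval + res2$n_evaluated
    if (res2$mse <= res$mse) res <- res2
    spec$alpha[3] <- spec$alpha[3] / 10; spec$beta[3] <- spec$beta[3] / 10
    spec$gamma[3] <- spec$gamma[3] / 10; spec$delta[3] <- spec$delta[3] / 10
  }

  params <- transition_params(res$alpha, res$beta, res$gamma, res$delta)
  structure(list(
    params = params,
    mse = res$mse,
    fitted = project_cohort(params, horizon, label = "fitted"),
    clamped = res$clamped,
    delta_identified = res$alpha > 0,
    n_evaluated = n_eval,
    benchmark = NULL
  ), class = "seqcea_fit")
}

#' @export
print.seqcea_fit <- function(x, ...) {
  cat("Transition-parameter fit\n")
  print(x$params)
  cat(sprintf("  MSE %.3e over %d grid evaluations\n", x$mse, x$n_evaluated))
  if (x$clamped) cat("  note: progression probability clamped in the tail\n")
  if (!x$delta_identified) cat("  note: delta unidentified (no progression)\n")
  if (!is.null(x$benchmark)) {
    for (nm in names(x$benchmark)) {
      cat(sprintf("  benchmark %s MSE %.3e\n", nm, x$benchmark[[nm]]$mse))
    }
  }
  invisible(x)
}

#' Parametric benchmark fit of reconstructed IPD
#'
#' Maximum-likelihood fit of a two-parameter Weibull or lognormal survival
#' model (via [flexsurv::flexsurvreg()]) to individual patient data, with
#' the fitted survival evaluated on the monthly grid and its mean-squared
#' error against an empirical curve returned.  Used to benchmark the
#' grid-search calibration against standard parametric fits.
#'
#' @param ipd data frame with `time` and `event` columns; needs at least one
#'   event.
#' @param empirical a [km_curve()] to score the fit against.
#' @param family `"weibull"` or `"lognormal"`.
#' @return list with `family`, `pars` (named parameter estimates), `curve`
#'   (fitted [km_curve()] on the monthly grid) and `mse`.
#' @export
parametric_benchmark_fit <- function(ipd, empirical,
                                     family = c("weibull", "lognormal")) {
  family <- match.arg(family)
  if (!nrow(ipd) || sum(ipd$event) < 1) {
    stop("IPD must contain at least one event", call. = FALSE)
  }
  dat <- ipd
  dat$time <- pmax(dat$time, 1e-6)  # parametric likelihoods need t > 0
  fit <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = dat,
                               dist = family)
  pars <- fit$res[, "est"]
  months <- seq_len(floor(max(empirical$time)))
  surv <- if (family == "weibull") {
    stats::pweibull(months, shape = pars["shape"], scale = pars["scale"],
                    lower.tail = FALSE)
  } else {
    stats::plnorm(months, meanlog = pars["meanlog"], sdlog = pars["sdlog"],
                  lower.tail = FALSE)
  }
  curve <- km_curve(c(0, months), c(1, surv),
                    label = paste0(family, " fit"))
  mse <- mean((surv - km_eval(empirical, months))^2)
  list(family = family, pars = pars, curve = curve, mse = mse)
}
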