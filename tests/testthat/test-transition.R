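test_that("progression probability follows alpha*(1+beta)^(t-1)", {
  expect_equal(progression_probability(transition_params(0.07, 0.02, 0, 0), 1),
               0.07)
  expect_equal(progression_probability(transition_params(0.05, 0, 0, 0),
                                       c(1, 7, 100)), rep(0.05, 3))
  expect_equal(progression_probability(transition_params(0.05, 0.10, 0, 0), 3),
               0.05 * 1.1^2)
  expect_error(progression_probability(transition_params(0.05, 0, 0, 0), 0),
               "t must be")
  expect_warning(
    p <- progression_probability(transition_params(0.5, 0.5, 0.3, 0), 10),
    "clamped")
  expect_equal(p, 0.7)
})

test_that("cohort projection matches closed forms and conserves mass", {
  # no transitions: both curves flat at 1
  pr <- project_cohort(transition_params(0, 0, 0, 0), 24)
  expect_true(all(pr$pfs$surv == 1) && all(pr$os$surv == 1))

  # beta = 0 closed form: PFS(t) = (1 - alpha - gamma)^t
  pr <- project_cohort(transition_params(0.1, 0, 0.05, 0), 36)
  expect_equal(km_eval(pr$pfs, 2), 0.85^2)
  expect_equal(pr$pfs$surv, 0.85^(0:36), tolerance = 1e-12)

  # delta = 1: progressed patients die after their entry month, so the
  # OS-PFS gap is exactly the newly progressed, u(t-1) * p(t)
  pr <- project_cohort(transition_params(0.1, 0, 0.05, 1), 36)
  u <- pr$pfs$surv
  gap <- pr$os$surv[-1] - u[-1]
  expect_equal(gap, u[-length(u)] * 0.1, tolerance = 1e-12)

  # mass conservation and monotonicity for random parameter draws
  set.seed(31)
  for (i in 1:20) {
    tp <- transition_params(runif(1, 0, 0.2), runif(1, -0.05, 0.02),
                            runif(1, 0, 0.1), runif(1, 0, 0.2))
    pr <- project_cohort(tp, 60)
    u <- pr$pfs$surv[-1]
    os <- pr$os$surv[-1]
    v <- os - u
    # independent death ledger: d(t) = d(t-1) + u(t-1)*gamma + v(t-1)*delta
    #                                  + clamped progression deaths (none here)
    d <- numeric(60)
    p <- pmin(tp$alpha * (1 + tp$beta)^(0:59), 1 - tp$gamma)
    up <- c(1, u); vp <- c(0, v)
    for (t in 1:60) d[t] <- (if (t > 1) d[t - 1] else 0) +
      up[t] * tp$gamma + vp[t] * tp$delta
    expect_equal(u + v + d, rep(1, 60), tolerance = 1e-12)
    expect_true(all(diff(pr$pfs$surv) <= 1e-15))
    expect_true(all(diff(pr$os$surv) <= 1e-15))
    expect_true(all(os - u >= -1e-15))
  }
})

test_that("curve_mse pools squared differences over both endpoints", {
  tp <- transition_params(0.08, 0.01, 0.02, 0.05)
  m <- project_cohort(tp, 12)
  expect_equal(curve_mse(m, m), 0)

  # constant offset of 0.1 gives MSE 0.01
  off <- function(cv) km_curve(cv$time, c(1, pmax(cv$surv[-1] - 0.1, 0)))
  stopifnot(min(m$pfs$surv) > 0.1)  # no clipping in this fixture
  e <- list(pfs = off(m$pfs), os = off(m$os))
  expect_equal(curve_mse(m, e), 0.01, tolerance = 1e-12)

  # three-point fixture vs explicit sum
  mod <- list(pfs = km_curve(0:3, c(1, 0.9, 0.8, 0.7)),
              os = km_curve(0:3, c(1, 0.95, 0.9, 0.85)))
  emp <- list(pfs = km_curve(0:3, c(1, 0.85, 0.75, 0.6)),
              os = km_curve(0:3, c(1, 0.9, 0.8, 0.8)))
  want <- (sum((c(0.9, 0.8, 0.7) - c(0.85, 0.75, 0.6))^2) +
           sum((c(0.95, 0.9, 0.85) - c(0.9, 0.8, 0.8))^2)) / 6
  expect_equal(curve_mse(mod, emp), want)

  # endpoint weights
  want_w <- (2 * sum((c(0.9, 0.8, 0.7) - c(0.85, 0.75, 0.6))^2) +
             1 * sum((c(0.95, 0.9, 0.85) - c(0.9, 0.8, 0.8))^2)) / 9
  expect_equal(curve_mse(mod, emp, weights = c(2, 1)), want_w)

  expect_error(curve_mse(mod, emp, months = numeric(0)), "overlap")
})

test_that("grid search recovers on-grid truth exactly and ties break to the
           most constant hazard", {
  tp <- transition_params(0.08, 0.01, 0.02, 0.05)
  fit <- grid_search_fit(project_cohort(tp, 60), grid_spec(refine = 0))
  expect_equal(fit$params$alpha, 0.08, tolerance = 1e-9)
  expect_equal(fit$params$beta, 0.01, tolerance = 1e-9)
  expect_equal(fit$params$gamma, 0.02, tolerance = 1e-9)
  expect_equal(fit$params$delta, 0.05, tolerance = 1e-9)
  expect_lt(fit$mse, 1e-20)
  expect_true(fit$delta_identified)

  # flat curves: alpha = gamma = 0 recovered, delta unidentified at grid min
  flat <- list(pfs = km_curve(0:24, rep(1, 25)), os = km_curve(0:24, rep(1, 25)))
  fit <- grid_search_fit(flat, grid_spec(refine = 0))
  expect_equal(fit$params$alpha, 0)
  expect_equal(fit$params$beta, 0)   # tie-break: smallest |beta|
  expect_equal(fit$params$gamma, 0)
  expect_equal(fit$params$delta, 0)  # tie-break: grid minimum
  expect_false(fit$delta_identified)
  expect_equal(fit$mse, 0)
})

test_that("refinement pins off-grid truth to within one base grid step", {
  truth <- transition_params(0.083, 0.013, 0.021, 0.046)
  curves <- project_cohort(truth, 60)
  fit <- grid_search_fit(curves, grid_spec(refine = 1))
  expect_lt(abs(fit$params$alpha - truth$alpha), 0.005 + 1e-9)
  expect_lt(abs(fit$params$beta - truth$beta), 0.005 + 1e-9)
  expect_lt(abs(fit$params$gamma - truth$gamma), 0.005 + 1e-9)
  expect_lt(abs(fit$params$delta - truth$delta), 0.005 + 1e-9)
  # at least as good as truth rounded to the base grid
  rounded <- transition_params(0.085, 0.015, 0.02, 0.045)
  expect_lte(fit$mse, curve_mse(project_cohort(rounded, 60), curves))
})

test_that("returned MSE is optimal against random feasible grid points", {
  tp <- transition_params(0.067, -0.008, 0.024, 0.061)
  emp <- project_cohort(tp, 48)
  spec <- grid_spec(refine = 0)
  fit <- grid_search_fit(emp, spec)
  set.seed(99)
  for (i in 1:100) {
    cand <- transition_params(
      sample(seq(0, 0.25, 0.005), 1), sample(seq(-0.1, 0.1, 0.005), 1),
      sample(seq(0, 0.1, 0.005), 1), sample(seq(0, 0.25, 0.005), 1))
    expect_lte(fit$mse, curve_mse(project_cohort(cand, 48), emp) + 1e-15)
  }
})

test_that("parametric benchmark fits behave as maximum likelihood should", {
  set.seed(12)
  # exponential data: Weibull shape near 1
  ipd <- data.frame(time = rexp(2000, 1 / 12), event = 1)
  w <- parametric_benchmark_fit(ipd, km_estimate(ipd), "weibull")
  expect_lt(abs(w$pars[["shape"]] - 1), 0.1)

  # lognormal data: the correctly specified family fits at least as well
  ipd <- data.frame(time = rlnorm(2000, log(12), 0.6), event = 1)
  emp <- km_estimate(ipd)
  ln <- parametric_benchmark_fit(ipd, emp, "lognormal")
  wb <- parametric_benchmark_fit(ipd, emp, "weibull")
  expect_lte(ln$mse, wb$mse)

  expect_error(
    parametric_benchmark_fit(data.frame(time = c(1, 2), event = c(0, 0)),
                             emp, "weibull"),
    "at least one event")
})
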