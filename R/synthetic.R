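#' Default utility, cost and suspension tables
#'
#' State utilities (annual): nmCSPC 0.95, mCSPC (both strata) 0.85, nmCRPC
#' 0.9, mCRPC (both lines) 0.75, progressed mCRPC 0.6, death 0.  Treatment
#' disutilities (annual): abiraterone 0.021, apalutamide 0.019, cabazitaxel
#' 0.042, darolutamide 0.019, docetaxel 0.042, enzalutamide 0.022.  Monthly
#' costs (CAD): ADT 322, abiraterone 919, apalutamide 3401, cabazitaxel
#' 4134, darolutamide 3401, docetaxel 103, enzalutamide 3401, non-IV
#' management 92, IV management 455, end-of-life 1449/month over the
#' terminal 12 months (CAD 17,391 total).  The suspension model (beta
#' shapes a = 2, b = 2, scale 24 months, 9-month active phases) is a
#' synthetic placeholder and flagged as such; override it with fitted
#' values when available.
#'
#' @return list with `utilities` (state -> annual utility), `components`
#'   (drug component costs/disutilities), `costs` (named monthly costs),
#'   `eol_months` (12) and `suspension` (list `a`, `b`, `scale`,
#'   `active_months`, `synthetic = TRUE`).
#' @export
default_tables <- function() {
  list(
    utilities = c(nmCSPC = 0.95, mCSPC_low = 0.85, mCSPC_high = 0.85,
                  nmCRPC = 0.9, mCRPC_L1 = 0.75, mCRPC_L2 = 0.75,
                  progressed_mCRPC = 0.6, death = 0),
    components = .components,
    costs = c(adt = 322, abi = 919, apa = 3401, caba = 4134, daro = 3401,
              doce = 103, enza = 3401, management_noniv = 92,
              management_iv = 455, end_of_life_monthly = 1449),
    eol_months = 12L,
    suspension = list(a = 2, b = 2, scale = 24, active_months = 9L,
                      synthetic = TRUE)
  )
}

#' Specification of a synthetic trial
#'
#' @param truth a [transition_params()] generating the data.
#' @param n_patients trial size (`>= 10`).
#' @param follow_up administrative censoring time in months (`>= 12`).
#' @param dropout monthly dropout (random censoring) probability.
#' @param risk_interval months between numbers-at-risk rows.
#' @param seed RNG seed.
#' @return object of class `synthetic_trial_spec`.
#' @export
synthetic_trial_spec <- function(truth, n_patients = 500L, follow_up = 60L,
                                 dropout = 0.002, risk_interval = 6L,
                                 seed = 1L) {
  stopifnot(n_patients >= 10, follow_up >= 12, dropout >= 0, dropout < 1)
  structure(list(truth = truth, n_patients = as.integer(n_patients),
                 follow_up = as.integer(follow_up), dropout = dropout,
                 risk_interval = as.integer(risk_interval),
                 seed = as.integer(seed)),
            class = "synthetic_trial_spec")
}

#' Generate a synthetic trial: monthly PFS/OS curves with risk tables
#'
#' Simulates per-patient progression and death months under the truth
#' parameters (monthly progression `alpha (1+beta)^(t-1)`, pre-progression
#' death `gamma`, post-progression death `delta`), applies random dropout
#' and administrative censoring at `follow_up`, and emits Kaplan-Meier
#' PFS and OS curves with numbers-at-risk tables at the stated interval
#' plus the underlying individual patient data for oracle checks.
#' PFS events are the first of progression or death.  Seeded and
#' reproducible.
#'
#' @param spec a [synthetic_trial_spec()].
#' @return list with `pfs`, `os` ([km_curve()]s carrying risk tables),
#'   `ipd_pfs`, `ipd_os` (data frames `time`, `event`), `truth` and `spec`.
#' @export
generate_trial <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_patients
  Fup <- spec$follow_up
  tr <- spec$truth
  prog_m <- death_m <- rep(Inf, n)
  state <- rep(1L, n)  # 1 stable, 2 progressed, 3 dead
  tis <- rep(0L, n)
  for (m in seq_len(Fup)) {
    alive <- state != 3L
    if (!any(alive)) break
    tis[alive] <- tis[alive] + 1L
    st <- which(state == 1L)
    if (length(st)) {
      p <- pmin(tr$alpha * (1 + tr$beta)^(tis[st] - 1), 1 - tr$gamma)
      u <- runif(length(st))
      prog <- st[u < p]
      die <- st[u >= p & u < p + tr$gamma]
      if (length(prog)) {
        state[prog] <- 2L; prog_m[prog] <- m; tis[prog] <- 0L
      }
      if (length(die)) { state[die] <- 3L; death_m[die] <- m }
    }
    pr <- which(state == 2L & prog_m < m)  # at risk of post-progression death
    if (length(pr)) {
      die <- pr[runif(length(pr)) < tr$delta]
      if (length(die)) { state[die] <- 3L; death_m[die] <- m }
    }
  }
  cens <- if (spec$dropout > 0) rgeom(n, spec$dropout) + 1L else rep(Inf, n)
  cens <- pmin(cens, Fup)

  t_pfs <- pmin(prog_m, death_m)
  ipd_pfs <- data.frame(time = pmin(t_pfs, cens),
                        event = as.integer(t_pfs <= cens))
  ipd_os <- data.frame(time = pmin(death_m, cens),
                       event = as.integer(death_m <= cens))
  rt <- seq(0, Fup, by = spec$risk_interval)
  pfs <- km_estimate(ipd_pfs, label = "synthetic PFS", risk_times = rt)
  os <- km_estimate(ipd_os, label = "synthetic OS", risk_times = rt)
  list(pfs = pfs, os = os, ipd_pfs = ipd_pfs, ipd_os = ipd_os,
       truth = tr, spec = spec)
}

#' Generate a plausible transition-parameter catalogue
#'
#' Draws [transition_params()] for every (state, treatment) pair of the
#' catalogue, within clinically plausible monthly ranges (baseline
#' progression `alpha` up to 0.15, death probabilities `gamma`, `delta` in
#' `[0.002, 0.08]`, trend `beta` in `[-0.03, 0.03]` further capped so the
#' joint constraint holds over `horizon` months).  With `effect_ordering`
#' (default), a per-state baseline is drawn and ARPI-containing regimens
#' receive a multiplicative reduction of `alpha` and `gamma` relative to
#' ADT alone in the same state, chemotherapy-only regimens a smaller one,
#' so treatment efficacy is ordered the way the trial evidence orders it.
#'
#' @param catalogue treatment catalogue.
#' @param seed RNG seed.
#' @param effect_ordering enforce ARPI < ADT on `alpha` and `gamma`?
#' @param horizon months over which parameter validity is enforced (240).
#' @return named list keyed `"state|treatment"` of [transition_params()],
#'   class `param_catalogue`.
#' @export
generate_param_catalogue <- function(catalogue = default_catalogue(),
                                     seed = 1L, effect_ordering = TRUE,
                                     horizon = 240L) {
  set.seed(seed)
  out <- list()
  for (s in names(catalogue$availability)) {
    a_base <- runif(1, 0.05, 0.15)
    g_base <- runif(1, 0.01, 0.08)
    for (tr in catalogue$availability[[s]]) {
      if (effect_ordering && is_arpi(tr)) {
        m_a <- runif(1, 0.45, 0.85); m_g <- runif(1, 0.45, 0.85)
      } else if (effect_ordering && is_chemo(tr)) {
        m_a <- runif(1, 0.70, 1.00); m_g <- runif(1, 0.70, 1.00)
      } else {
        m_a <- 1; m_g <- 1
      }
      alpha <- max(0.01, a_base * m_a)
      gamma <- max(0.002, g_base * m_g)
      delta <- runif(1, 0.02, 0.08)
      b_max <- min(0.03, ((1 - gamma) / alpha)^(1 / (horizon - 1)) - 1)
      beta <- runif(1, -0.03, b_max)
      out[[paste(s, tr, sep = "|")]] <-
        transition_params(alpha, beta, gamma, delta, horizon = horizon)
    }
  }
  class(out) <- "param_catalogue"
  out
}

#' @export
print.param_catalogue <- function(x, ...) {
  cat("Transition-parameter catalogue:", length(x), "treatment-state pairs\n")
  invisible(x)
}
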