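#' Reconstruct individual patient data from a Kaplan-Meier curve
#'
#' Implements the interval-allocation scheme of Guyot et al. (2012): within
#' each numbers-at-risk interval, censoring times are spread uniformly and
#' event counts at each curve step are chosen so that the product-limit
#' estimate of the output reproduces the input survival at the curve's time
#' points, iterating the interval's censor count until the reconstructed
#' number at risk matches the published one at the next boundary.  After the
#' last risk-table row (or when no risk table is available and `n0` is
#' given), no censoring is assumed except administratively at the end of
#' follow-up.
#'
#' @param curve a [km_curve()].  If it carries no risk table, `n0` must give
#'   the initial sample size; censoring is then assumed administrative at
#'   last follow-up only and the output is flagged accordingly.
#' @param n0 initial sample size, required only without a risk table.
#' @param max_iter maximum censor-count adjustment iterations per interval.
#' @return data frame of class `ipd` with columns `time` (months) and
#'   `event` (1 = event, 0 = censored), one row per initial patient, and
#'   attribute `assumed_no_censoring` when no risk table was available.
#' @export
guyot_reconstruct <- function(curve, n0 = NULL, max_iter = 100L) {
  t_click <- curve$time
  s_click <- curve$surv
  no_risk <- is.null(curve$risk_time) || length(curve$risk_time) == 0L
  if (no_risk) {
    if (is.null(n0)) {
      stop("curve has no risk table; supply the initial sample size `n0`",
           call. = FALSE)
    }
    risk_time <- 0
    risk_n <- n0
  } else {
    risk_time <- curve$risk_time
    risk_n <- curve$risk_n
    if (risk_time[1L] > min(t_click)) {
      stop("risk table must start at or before the first curve time",
           call. = FALSE)
    }
  }
  n_int <- length(risk_time)
  t_max <- max(t_click, risk_time)

  ev_time <- ev_n <- numeric(0)     # events: time, count
  cs_time <- numeric(0)             # censor times (one entry each)
  km_run <- 1                       # product-limit estimate so far
  n_cur <- risk_n[1L]

  for (j in seq_len(n_int)) {
    if (n_cur <= 0) break
    lo <- risk_time[j]
    hi <- if (j < n_int) risk_time[j + 1L] else t_max + 1
    in_int <- which(t_click >= lo & t_click < hi & s_click < 1 - 1e-12)
    # drop clicks already matched (survival equal to running KM)
    last_interval <- j == n_int

    if (last_interval) {
      # no boundary to match: assume no censoring within the interval
      res <- allocate_interval(t_click[in_int], s_click[in_int],
                               n_cur, 0, lo, hi, km_run)
      ev_time <- c(ev_time, res$ev_time); ev_n <- c(ev_n, res$ev_n)
      km_run <- res$km; n_cur <- res$n_end
      break
    }

    n_next <- risk_n[j + 1L]
    # initial censor guess: expected at-risk at next boundary under no
    # censoring, minus the published number
    s_hi <- s_click[max(which(t_click < hi))]
    cens <- if (km_run > 0) max(0, round(n_cur * s_hi / km_run) - n_next)
            else max(0, n_cur - n_next)
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      res <- allocate_interval(t_click[in_int], s_click[in_int],
                               n_cur, cens, lo, hi, km_run)
      diff <- res$n_end - n_next
      if (diff == 0) { ok <- TRUE; break }
      cens_new <- cens + diff
      if (cens_new < 0) {
        if (cens == 0) break
        cens_new <- 0
      }
      if (cens_new == cens) break
      cens <- cens_new
    }
    if (!ok) {
      stop("risk table inconsistent with curve in interval [", lo, ", ", hi,
           "): implied negative event or censor count", call. = FALSE)
    }
    ev_time <- c(ev_time, res$ev_time); ev_n <- c(ev_n, res$ev_n)
    cs_time <- c(cs_time, res$cs_time)
    km_run <- res$km; n_cur <- res$n_end
  }

  times <- c(rep(ev_time, ev_n), cs_time, rep(t_max, n_cur))
  event <- c(rep(1, sum(ev_n)), rep(0, length(cs_time)), rep(0, n_cur))
  out <- data.frame(time = times, event = event)
  out <- out[order(out$time, -out$event), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ipd", "data.frame")
  attr(out, "assumed_no_censoring") <- no_risk
  out
}

# Allocate events and censors to the curve steps inside one risk interval.
# `cens` censor times are spread uniformly over (lo, hi); events at each step
# are chosen to match the target survival given the running product-limit
# estimate `km0` and `n0` patients at risk at interval start.  Censors leave
# the risk set in time order between steps.
allocate_interval <- function(tt, ss, n0, cens, lo, hi, km0) {
  cs <- if (cens > 0) lo + seq_len(cens) * (hi - lo) / (cens + 1) else numeric(0)
  km <- km0
  ev_t <- ev_n <- numeric(0)
  k <- length(tt)
  n <- n0 - sum(cs < (if (k > 0) tt[1L] else hi) - 1e-9)
  for (i in seq_len(k)) {
    if (n <= 0) break
    d <- round(n * (1 - ss[i] / km))
    d <- max(0, min(d, n))
    if (d > 0) {
      km <- km * (1 - d / n)
      ev_t <- c(ev_t, tt[i]); ev_n <- c(ev_n, d)
      n <- n - d
    }
    # censors falling before the next step leave the risk set now
    nxt <- if (i < k) tt[i + 1L] else hi
    n <- n - sum(cs >= tt[i] - 1e-9 & cs < nxt - 1e-9)
  }
  list(ev_time = ev_t, ev_n = ev_n, cs_time = cs, n_end = n, km = km)
}
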