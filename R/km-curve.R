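#' Kaplan-Meier curve objects
#'
#' A `km_curve` holds a survival step function at monthly resolution:
#' a label, a vector of times (months since state entry, starting at 0), the
#' survival probability at each time, and an optional numbers-at-risk table.
#'
#' @param time numeric vector of times in months, nondecreasing.  A point
#'   `(0, 1)` is prepended if absent.
#' @param surv survival probabilities in `[0, 1]`, nonincreasing.
#' @param label character identifier (trial / treatment / state / endpoint).
#' @param risk_time,risk_n optional numbers-at-risk table: times (months) and
#'   nonnegative, nonincreasing counts.
#'
#' @return an object of class `km_curve` with elements `label`, `time`,
#'   `surv`, `risk_time`, `risk_n`.
#' @export
km_curve <- function(time, surv, label = "curve",
                     risk_time = NULL, risk_n = NULL) {
  if (length(time) != length(surv)) {
    stop("`time` and `surv` must have the same length", call. = FALSE)
  }
  ord <- order(time)
  time <- as.numeric(time[ord])
  surv <- as.numeric(surv[ord])
  if (length(time) == 0L || time[1L] > 0) {
    time <- c(0, time)
    surv <- c(1, surv)
  }
  if (any(time < 0)) stop("times must be nonnegative", call. = FALSE)
  bad <- which(surv < 0 | surv > 1)
  if (length(bad)) {
    stop("survival outside [0, 1] at row ", bad[1L], " (time ",
         time[bad[1L]], ")", call. = FALSE)
  }
  if (abs(surv[1L] - 1) > 1e-12) {
    stop("survival at time 0 must be 1, got ", surv[1L], call. = FALSE)
  }
  nonmono <- which(diff(surv) > 1e-12)
  if (length(nonmono)) {
    stop("survival is non-monotone at row ", nonmono[1L] + 1L, " (time ",
         time[nonmono[1L] + 1L], ")", call. = FALSE)
  }
  if (!is.null(risk_time) || !is.null(risk_n)) {
    if (length(risk_time) != length(risk_n)) {
      stop("risk table times and counts must have the same length",
           call. = FALSE)
    }
    ord <- order(risk_time)
    risk_time <- as.numeric(risk_time[ord])
    risk_n <- as.numeric(risk_n[ord])
    if (any(risk_n < 0) || any(risk_n != round(risk_n))) {
      stop("numbers at risk must be nonnegative integers", call. = FALSE)
    }
    if (any(diff(risk_n) > 0)) {
      stop("numbers at risk must be nonincreasing in time", call. = FALSE)
    }
  }
  structure(
    list(label = label, time = time, surv = surv,
         risk_time = risk_time, risk_n = risk_n),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$label, "\n")
  cat("  ", length(x$time), "points, follow-up", max(x$time), "months,",
      "final survival", signif(min(x$surv), 4), "\n")
  if (!is.null(x$risk_time)) {
    cat("   risk table:", length(x$risk_time), "rows, initial n =",
        x$risk_n[1L], "\n")
  }
  invisible(x)
}

#' Evaluate a survival curve on a monthly grid
#'
#' Step-function (last observation carried forward) evaluation of a
#' `km_curve` at the requested months.  The model operates in 1-month
#' cycles, so empirical curves are put on this grid before fitting.
#'
#' @param curve a [km_curve()].
#' @param months numeric vector of months; defaults to
#'   `0:floor(max(curve$time))`.
#' @return numeric vector of survival probabilities, one per month.
#' @export
km_eval <- function(curve, months = NULL) {
  if (is.null(months)) months <- 0:floor(max(curve$time))
  idx <- findInterval(months, curve$time)
  out <- ifelse(idx == 0L, 1, curve$surv[pmax(idx, 1L)])
  as.numeric(out)
}

#' Read a digitized Kaplan-Meier curve from delimited files
#'
#' Reads a two-column table `time, survival` (header required; `surv` is
#' accepted for the second column) and, optionally, a separate risk table
#' `time, n_at_risk`.  A comment line of the form `# unit: years` (or
#' `weeks`) in the curve file converts times to months on read; the default
#' unit is months.  A point `(0, 1)` is prepended if absent and points are
#' sorted by time; validation errors name the offending row.
#'
#' @param path path to the curve CSV.
#' @param risk_path optional path to the risk-table CSV.
#' @param label curve label.
#' @return a validated [km_curve()].
#' @export
read_km_table <- function(path, risk_path = NULL, label = basename(path)) {
  first <- readLines(path, n = 1L)
  unit <- "months"
  if (grepl("^#", first)) {
    m <- regmatches(first, regexpr("unit:\\s*\\w+", first))
    if (length(m)) unit <- sub("unit:\\s*", "", m)
  }
  tab <- read.csv(path, comment.char = "#")
  names(tab) <- tolower(names(tab))
  if (!"time" %in% names(tab)) stop("curve file needs a `time` column")
  scol <- intersect(c("survival", "surv"), names(tab))
  if (!length(scol)) stop("curve file needs a `survival` column")
  fac <- switch(unit, months = 1, years = 12, weeks = 12 / 52,
                stop("unknown time unit: ", unit))
  rt <- rn <- NULL
  if (!is.null(risk_path)) {
    risk <- read.csv(risk_path, comment.char = "#")
    names(risk) <- tolower(names(risk))
    ncol_ <- intersect(c("n_at_risk", "n", "nrisk"), names(risk))
    if (!"time" %in% names(risk) || !length(ncol_)) {
      stop("risk file needs `time` and `n_at_risk` columns")
    }
    rt <- risk$time * fac
    rn <- risk[[ncol_[1L]]]
  }
  km_curve(tab$time * fac, tab[[scol[1L]]], label = label,
           risk_time = rt, risk_n = rn)
}

#' Product-limit estimate from individual patient data
#'
#' Thin wrapper around [survival::survfit()] returning a [km_curve()] with a
#' step at every event time, used for round-trip checks of the IPD
#' reconstruction.
#'
#' @param ipd data frame with columns `time` (months, nonnegative) and
#'   `event` (1 = event, 0 = censored).
#' @param label curve label.
#' @param risk_times optional times at which to attach a numbers-at-risk
#'   table computed from the IPD.
#' @return a [km_curve()].
#' @export
km_estimate <- function(ipd, label = "km", risk_times = NULL) {
  if (!nrow(ipd)) stop("empty IPD", call. = FALSE)
  if (any(ipd$time < 0)) stop("negative times in IPD", call. = FALSE)
  if (all(ipd$event == 0) && all(ipd$time == 0)) {
    stop("all records censored at time 0", call. = FALSE)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  rt <- rn <- NULL
  if (!is.null(risk_times)) {
    rt <- risk_times
    rn <- vapply(risk_times, function(t) sum(ipd$time >= t), numeric(1))
  }
  km_curve(c(0, fit$time), c(1, fit$surv), label = label,
           risk_time = rt, risk_n = rn)
}

#' Numbers at risk implied by individual patient data
#'
#' @param ipd data frame with `time` column.
#' @param times evaluation times (months).
#' @return integer vector: patients with `time >= t` for each `t`.
#' @export
n_at_risk <- function(ipd, times) {
  vapply(times, function(t) sum(ipd$time >= t), numeric(1))
}
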