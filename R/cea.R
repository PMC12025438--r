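#' Net health benefit
#'
#' `NHB = benefit - cost / CET`, in benefit units (QALYs or LYs).
#'
#' @param benefit total (or incremental) benefit, QALYs or LYs.
#' @param cost total (or incremental) cost, CAD.
#' @param cet cost-effectiveness threshold, CAD per benefit unit; `> 0`.
#' @return numeric NHB; vectorized over all arguments.
#' @export
compute_nhb <- function(benefit, cost, cet) {
  if (any(cet <= 0)) stop("CET must be positive", call. = FALSE)
  benefit - cost / cet
}

#' Rank treatment sequences by net health benefit
#'
#' @param results data frame with columns `label`, `benefit`, `cost` and
#'   optionally `arpi_use`, or a list of `cohort_result`s (ranked on the
#'   `measure`).
#' @param cet cost-effectiveness threshold (CAD per benefit unit).
#' @param reference label of the no-ARPI reference sequence for incremental
#'   columns.
#' @param measure `"qaly"` or `"ly"`, used when `results` are
#'   `cohort_result`s.
#' @return data frame of class `cea_table`, in descending NHB order (ties:
#'   lower cost, then label), with columns `rank`, `label`, `arpi_use`,
#'   `benefit`, `cost`, `nhb`, `incr_benefit`, `incr_cost`, `incr_nhb`.
#' @export
rank_sequences <- function(results, cet, reference,
                           measure = c("qaly", "ly")) {
  measure <- match.arg(measure)
  if (!is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, function(r) {
      data.frame(label = r$label, arpi_use = r$arpi_use,
                 benefit = if (measure == "qaly") r$mean_qaly else r$mean_ly,
                 cost = r$mean_cost, stringsAsFactors = FALSE)
    }))
  }
  if (!"arpi_use" %in% names(results)) results$arpi_use <- NA_character_
  if (!reference %in% results$label) {
    stop("reference sequence '", reference, "' not among the results",
         call. = FALSE)
  }
  results$nhb <- compute_nhb(results$benefit, results$cost, cet)
  ref <- results[results$label == reference, ][1L, ]
  results$incr_benefit <- results$benefit - ref$benefit
  results$incr_cost <- results$cost - ref$cost
  results$incr_nhb <- results$nhb - ref$nhb
  ord <- order(-results$nhb, results$cost, results$label)
  results <- results[ord, c("label", "arpi_use", "benefit", "cost", "nhb",
                            "incr_benefit", "incr_cost", "incr_nhb")]
  results <- cbind(rank = seq_len(nrow(results)), results)
  rownames(results) <- NULL
  attr(results, "cet") <- cet
  attr(results, "reference") <- reference
  class(results) <- c("cea_table", "data.frame")
  results
}

#' @export
print.cea_table <- function(x, digits = 2, ...) {
  cat("Sequence ranking at CET CAD", format(attr(x, "cet"), big.mark = ","),
      "per benefit unit (reference", attr(x, "reference"), ")\n")
  y <- as.data.frame(x)
  num <- c("benefit", "nhb", "incr_benefit", "incr_nhb")
  y[num] <- lapply(y[num], round, digits)
  y$cost <- round(y$cost)
  y$incr_cost <- round(y$incr_cost)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' For each of `iterations` bootstrap iterations, `iteration_size` patients
#' are resampled (with replacement) from each group's stored per-patient
#' outcomes; the group with the highest NHB of the iteration's mean benefit
#' and cost is the winner at each threshold.  The curve is the fraction of
#' iterations each group wins.  Ties are split deterministically in favour
#' of lower mean cost, then group order.
#'
#' @param outcomes named list of groups (e.g. ARPI timing groups); each
#'   element is a list with numeric per-patient vectors `benefit` and
#'   `cost` (pool the patients of the group's sequences).
#' @param cet_grid thresholds to evaluate (default 0 excluded:
#'   `seq(1000, 300000, by = 1000)`).
#' @param iterations number of bootstrap iterations (2000).
#' @param iteration_size patients resampled per group per iteration (100).
#' @param seed RNG seed; the curve is deterministic given it.
#' @return object of class `acceptability_curve`: matrix of win
#'   probabilities (thresholds x groups) with the CET grid as rownames.
#' @export
acceptability_curve <- function(outcomes, cet_grid = seq(1e3, 3e5, by = 1e3),
                                iterations = 2000L, iteration_size = 100L,
                                seed = 1L) {
  if (!length(cet_grid)) stop("empty CET grid", call. = FALSE)
  groups <- names(outcomes)
  for (g in groups) {
    if (length(outcomes[[g]]$benefit) < iteration_size) {
      stop("group '", g, "' has fewer than ", iteration_size,
           " stored patients", call. = FALSE)
    }
  }
  set.seed(seed)
  G <- length(groups)
  mb <- mc <- matrix(0, iterations, G, dimnames = list(NULL, groups))
  for (g in seq_len(G)) {
    n <- length(outcomes[[g]]$benefit)
    idx <- matrix(sample.int(n, iterations * iteration_size, replace = TRUE),
                  iterations, iteration_size)
    mb[, g] <- rowMeans(matrix(outcomes[[g]]$benefit[idx], iterations))
    mc[, g] <- rowMeans(matrix(outcomes[[g]]$cost[idx], iterations))
  }
  wins <- matrix(0, length(cet_grid), G,
                 dimnames = list(format(cet_grid, scientific = FALSE,
                                        trim = TRUE), groups))
  for (k in seq_along(cet_grid)) {
    nhb <- mb - mc / cet_grid[k]
    best <- max.col(nhb, ties.method = "first")
    # resolve exact ties by lower cost, then column order
    top <- nhb[cbind(seq_len(iterations), best)]
    for (i in seq_len(iterations)) {
      tied <- which(nhb[i, ] == top[i])
      if (length(tied) > 1L) best[i] <- tied[order(mc[i, tied], tied)][1L]
    }
    wins[k, ] <- tabulate(best, nbins = G) / iterations
  }
  structure(wins, cet = cet_grid, class = "acceptability_curve")
}

#' @export
print.acceptability_curve <- function(x, ...) {
  cet <- attr(x, "cet")
  cat("Acceptability curve over", length(cet), "thresholds (CAD",
      format(min(cet), big.mark = ","), "-",
      format(max(cet), big.mark = ","), ")\n")
  pick <- unique(round(seq(1, length(cet), length.out = 6)))
  print(round(unclass(x)[pick, , drop = FALSE], 3))
  invisible(x)
}

#' Plot an acceptability curve
#'
#' @param x an [acceptability_curve()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.acceptability_curve <- function(x, ...) {
  cet <- attr(x, "cet")
  graphics::matplot(cet / 1000, unclass(x), type = "l", lty = 1,
                    xlab = "CET (thousand CAD per benefit unit)",
                    ylab = "P(most cost-effective)", ylim = c(0, 1), ...)
  graphics::legend("right", colnames(x), lty = 1,
                   col = seq_len(ncol(x)), bty = "n")
  invisible(x)
}

#' Threshold at which a group becomes reliably cost-effective
#'
#' The lowest CET on the grid at which the group's acceptability exceeds
#' the coverage level (e.g. the CET baseline for supporting early ARPI
#' use).
#'
#' @param ac an [acceptability_curve()].
#' @param group group name (default `"early"`).
#' @param coverage required win probability (0.99).
#' @return the lowest qualifying CET, or `NA_real_` if never reached.
#' @export
tornado_threshold <- function(ac, group = "early", coverage = 0.99) {
  cet <- attr(ac, "cet")
  if (is.null(cet) || !length(cet)) stop("empty CET grid", call. = FALSE)
  hit <- which(ac[, group] > coverage)
  if (!length(hit)) return(NA_real_)
  cet[hit[1L]]
}

#' Payer and horizon sensitivity scenarios
#'
#' Resolves a named scenario into a run configuration: `horizon10` /
#' `horizon20` rescale the horizon to 120 / 240 months; `price_equalized`
#' lowers the monthly drug costs of apalutamide, darolutamide and
#' enzalutamide to abiraterone's; `us_va`, `us_private` and `uk_public`
#' swap in payer price tables (shipped as editable synthetic placeholders),
#' adjust the annual discount rate (3% US, 3.5% UK) and record the CAD
#' exchange rate used to compare thresholds (1.3698 CAD/USD, 1.7504
#' CAD/GBP).  Prices not overridden stay at base values.
#'
#' @param scenario scenario name.
#' @param config base [sim_config()].
#' @param tables base tables from [default_tables()].
#' @param price_override optional named vector of monthly drug costs (CAD)
#'   replacing the shipped placeholder tables for the payer scenarios.
#' @return list with `name`, `config` (adjusted), `tables` (adjusted),
#'   `fx` (CAD per local currency unit) and `currency`.
#' @export
apply_scenario <- function(scenario = c("base", "horizon10", "horizon20",
                                        "price_equalized", "us_va",
                                        "us_private", "uk_public"),
                           config = sim_config(),
                           tables = default_tables(),
                           price_override = NULL) {
  scenario <- match.arg(scenario)
  fx <- 1; currency <- "CAD"
  comp_prices <- function(tbl, prices) {
    i <- match(names(prices), tbl$components$name)
    tbl$components$monthly_cost[i[!is.na(i)]] <- prices[!is.na(i)]
    j <- match(names(prices), names(tbl$costs))
    tbl$costs[j[!is.na(j)]] <- prices[!is.na(j)]
    tbl
  }
  if (scenario == "horizon10") config$horizon <- 120L
  if (scenario == "horizon20") config$horizon <- 240L
  if (scenario == "price_equalized") {
    abi <- tables$components$monthly_cost[tables$components$name == "abi"]
    tables <- comp_prices(tables, c(apa = abi, daro = abi, enza = abi))
  }
  if (scenario %in% c("us_va", "us_private")) {
    config$annual_discount <- 0.03
    fx <- 1.3698; currency <- "USD"
    prices <- if (!is.null(price_override)) price_override else
      synthetic_payer_prices(scenario)
    tables <- comp_prices(tables, prices)
  }
  if (scenario == "uk_public") {
    config$annual_discount <- 0.035
    fx <- 1.7504; currency <- "GBP"
    prices <- if (!is.null(price_override)) price_override else
      synthetic_payer_prices(scenario)
    tables <- comp_prices(tables, prices)
  }
  list(name = scenario, config = config, tables = tables,
       fx = fx, currency = currency)
}

#' Synthetic placeholder payer price tables
#'
#' Stand-in monthly drug costs (already converted to CAD) for the US and UK
#' payer scenarios.  These are synthetic placeholders capturing the
#' qualitative pattern (generic abiraterone cheap for US public payers,
#' all drugs expensive for US private payers, abiraterone relatively dear
#' and enzalutamide relatively cheap for the UK); replace them with the
#' actual payer tables via the `price_override` argument of
#' [apply_scenario()] when available.
#'
#' @param scenario `"us_va"`, `"us_private"` or `"uk_public"`.
#' @return named numeric vector of monthly costs (CAD).
#' @export
synthetic_payer_prices <- function(scenario) {
  switch(scenario,
    us_va = c(abi = 700, apa = 5200, daro = 5200, enza = 5500,
              doce = 150, caba = 5000, adt = 400),
    us_private = c(abi = 5500, apa = 7500, daro = 7500, enza = 8000,
                   doce = 250, caba = 8500, adt = 600),
    uk_public = c(abi = 2400, apa = 3300, daro = 3300, enza = 2600,
                  doce = 120, caba = 4200, adt = 300),
    stop("unknown scenario: ", scenario, call. = FALSE))
}
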