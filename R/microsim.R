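#' Simulation configuration
#'
#' @param n_patients cohort size (200,000 by default).
#' @param horizon simulation horizon in months (180 = 15 years).
#' @param annual_discount annual discount rate for benefits and costs
#'   (0.015).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param p_low_risk probability that an nmCSPC progression routed to mCSPC
#'   enters the low-risk stratum (0.651).
#' @param p_nm_to_nmcrpc probability that an nmCSPC progression goes to
#'   nmCRPC instead of mCSPC (0 by default; exposed rather than invented).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 200000L, horizon = 180L,
                       annual_discount = 0.015, seed = 1L,
                       p_low_risk = 0.651, p_nm_to_nmcrpc = 0) {
  stopifnot(horizon >= 1, annual_discount >= 0, annual_discount < 1,
            n_patients >= 1)
  structure(list(n_patients = as.integer(n_patients),
                 horizon = as.integer(horizon),
                 annual_discount = annual_discount, seed = as.integer(seed),
                 p_low_risk = p_low_risk, p_nm_to_nmcrpc = p_nm_to_nmcrpc),
            class = "sim_config")
}

#' Discount factor for a calendar month
#'
#' `(1 + annual_rate)^(-month / 12)`: smooth monthly discounting consistent
#' with an annual rate.
#'
#' @param month calendar month index, `>= 0`; vectorized.
#' @param annual_rate annual discount rate.
#' @return numeric vector of factors.
#' @export
discount_factor <- function(month, annual_rate = 0.015) {
  stopifnot(all(month >= 0))
  (1 + annual_rate)^(-month / 12)
}

#' Sample a treatment-suspension length
#'
#' Intermittent nmCSPC treatment alternates 9-month active phases with
#' suspended phases whose length (months) is a scaled beta draw, rounded to
#' the nearest month with a minimum of one.
#'
#' @param model suspension model: list with `a`, `b` (beta shapes), `scale`
#'   (maximum suspension months) and `active_months`.
#' @param treatment regimen label; must be flagged intermittent in the
#'   catalogue.
#' @param n number of draws.
#' @param catalogue treatment catalogue.
#' @return integer vector of suspension lengths in months.
#' @export
sample_suspension <- function(model, treatment, n = 1,
                              catalogue = default_catalogue()) {
  if (!treatment %in% catalogue$intermittent) {
    stop("treatment '", treatment, "' is not taken intermittently",
         call. = FALSE)
  }
  pmax(1, round(model$scale * rbeta(n, model$a, model$b)))
}

# Resolve per-state engine inputs for one sequence.  States are indexed
# 1..7 (health_states() order, death implicit).
build_sim_inputs <- function(seq, params_catalogue, config,
                             tables = default_tables(),
                             catalogue = default_catalogue()) {
  states <- health_states()[1:7]
  asg <- seq$assignment
  alpha <- beta <- gamma <- numeric(7)
  cost_on <- cost_off <- util_on <- util_off <- util_susp <- numeric(7)
  cycles <- integer(7)
  intermit <- logical(7)
  comp <- catalogue$components

  comp_cost <- function(x) sum(comp$monthly_cost[match(x, comp$name)])
  comp_disut <- function(x) sum(comp$annual_disutility[match(x, comp$name)])

  for (i in seq_along(states)) {
    s <- states[i]
    if (s == "progressed_mCRPC") {
      cost_off[i] <- tables$costs[["management_noniv"]]
      util_off[i] <- tables$utilities[[s]] / 12
      util_susp[i] <- util_off[i]
      next
    }
    tr <- asg[[s]]
    if (is.null(tr)) next  # state unreachable under this sequence
    key <- paste(s, tr, sep = "|")
    pars <- params_catalogue[[key]]
    if (is.null(pars)) {
      stop("no transition parameters for (", s, ", ", tr, ")", call. = FALSE)
    }
    alpha[i] <- pars$alpha; beta[i] <- pars$beta; gamma[i] <- pars$gamma
    comps <- regimen_components(tr)
    chemo <- comps[comp$class[match(comps, comp$name)] == "chemo"]
    nonchemo <- setdiff(comps, chemo)
    adt <- tables$costs[["adt"]]
    noniv <- tables$costs[["management_noniv"]]
    iv <- tables$costs[["management_iv"]]
    cost_off[i] <- adt + comp_cost(nonchemo) + noniv
    cost_on[i] <- adt + comp_cost(comps) + iv
    u <- tables$utilities[[s]]
    util_off[i] <- (u - comp_disut(nonchemo)) / 12
    util_on[i] <- (u - comp_disut(comps)) / 12
    util_susp[i] <- u / 12
    if (length(chemo)) {
      cyc <- catalogue$chemo_cycles[[chemo[1L]]]
      cycles[i] <- if (length(cyc) > 1L) {
        cyc[[if (grepl("mCSPC", s)) "mCSPC" else "mCRPC"]]
      } else cyc
    }
    intermit[i] <- s == "nmCSPC" && tr %in% catalogue$intermittent
  }
  final_line <- if (!is.null(asg[["mCRPC_L2"]])) "mCRPC_L2" else "mCRPC_L1"
  fkey <- paste(final_line, asg[[final_line]], sep = "|")
  fpars <- params_catalogue[[fkey]]
  if (is.null(fpars)) {
    stop("no transition parameters for (", final_line, ", ",
         asg[[final_line]], ")", call. = FALSE)
  }
  list(start = match(seq$starting_state, states),
       alpha = alpha, beta = beta, gamma = gamma,
       delta_prog = fpars$delta,
       has_l2 = !is.null(asg[["mCRPC_L2"]]),
       cost_on = cost_on, cost_off = cost_off,
       cost_susp = tables$costs[["management_noniv"]],
       util_on = util_on, util_off = util_off, util_susp = util_susp,
       cycles = cycles, intermittent = intermit,
       suspension = tables$suspension,
       eol_monthly = tables$costs[["end_of_life_monthly"]],
       eol_months = tables$eol_months)
}

#' Microsimulate a patient cohort over one treatment sequence
#'
#' Simulates `config$n_patients` monthly patient paths through the
#' sequence's state machine and accrues discounted life-years, QALYs and
#' costs.  Within each state the competing monthly events (progression,
#' pre-progression death, stay) are resolved by a single uniform draw
#' partitioned as `[0, P_prog)`, `[P_prog, P_prog + gamma)`, remainder;
#' progressed mCRPC applies the final line's `delta`.  Intermittent nmCSPC
#' treatment alternates 9-month active phases with beta-distributed
#' suspensions that pause drug costs and treatment disutility but not the
#' hazards.  Terminal-care costs are added retrospectively over the last
#' (up to 12) progressed-mCRPC months of patients who die there.
#' Patients are simulated sequentially from a single seeded RNG stream, so
#' the result is bit-identical for a fixed seed.
#'
#' @param seq a [treatment_sequence()].
#' @param params_catalogue named list mapping `"state|treatment"` keys to
#'   [transition_params()] (see [generate_param_catalogue()]).
#' @param config a [sim_config()].
#' @param tables cost/utility tables from [default_tables()].
#' @param catalogue treatment catalogue.
#' @param keep_paths record per-month state/phase matrices (memory scales
#'   with `n_patients * horizon`; intended for small cohorts).
#' @return object of class `cohort_result`: sequence label and ARPI timing,
#'   means and per-patient vectors of discounted `qaly`, `ly`, `cost`,
#'   `death_month` (0 = alive at horizon), `occupancy` (states x months
#'   fractions, death row included) and `state_months` (patients x states
#'   months of occupancy, for standard errors of mean occupancy).  With
#'   `keep_paths`, matrices `path_state`, `path_tis`, `path_phase`.
#' @export
simulate_cohort <- function(seq, params_catalogue, config = sim_config(),
                            tables = default_tables(),
                            catalogue = default_catalogue(),
                            keep_paths = FALSE) {
  inp <- build_sim_inputs(seq, params_catalogue, config, tables, catalogue)
  disc <- discount_factor(seq_len(config$horizon), config$annual_discount)
  set.seed(config$seed)
  raw <- simulate_cohort_cpp(
    config$n_patients, config$horizon, inp$start,
    inp$alpha, inp$beta, inp$gamma, inp$delta_prog, inp$has_l2,
    config$p_low_risk, config$p_nm_to_nmcrpc,
    inp$cost_on, inp$cost_off, inp$cost_susp,
    inp$util_on, inp$util_off, inp$util_susp,
    inp$cycles, inp$intermittent,
    inp$suspension$a, inp$suspension$b, inp$suspension$scale,
    inp$suspension$active_months,
    inp$eol_monthly, inp$eol_months, disc, keep_paths)
  occ <- raw$occupancy / config$n_patients
  occ <- rbind(occ, dead = 1 - colSums(occ))
  rownames(occ) <- health_states()
  out <- list(label = seq$label, arpi_use = seq$arpi_use,
              starting_state = seq$starting_state,
              n = config$n_patients, horizon = config$horizon,
              mean_qaly = mean(raw$qaly), mean_ly = mean(raw$ly),
              mean_cost = mean(raw$cost),
              qaly = raw$qaly, ly = raw$ly, cost = raw$cost,
              death_month = raw$death_month, occupancy = occ,
              state_months = `colnames<-`(raw$state_months,
                                          health_states()[1:7]),
              config = config)
  if (keep_paths) {
    out$path_state <- raw$path_state
    out$path_tis <- raw$path_tis
    out$path_phase <- raw$path_phase
  }
  structure(out, class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("Cohort result for", x$label, "(", x$arpi_use, "ARPI use )\n")
  cat(sprintf("  n = %d, horizon %d months\n", x$n, x$horizon))
  cat(sprintf("  mean discounted QALY %.3f, LY %.3f, cost CAD %.0f\n",
              x$mean_qaly, x$mean_ly, x$mean_cost))
  invisible(x)
}

#' Simulate a single patient path
#'
#' Runs the cohort engine for one patient and returns the monthly
#' trajectory.  The months-in-state clock resets to 1 on each state entry
#' (semi-Markov); the path ends at death or the horizon.
#'
#' @inheritParams simulate_cohort
#' @return data frame of class `patient_path` with columns `month`, `state`,
#'   `months_in_state`, `treatment` and `phase`
#'   (`active` / `suspended` / `off_chemo`), plus attributes `death_month`,
#'   `qaly`, `ly`, `cost` (the engine's own accruals) and `label`.
#' @export
simulate_patient <- function(seq, params_catalogue, config = sim_config(),
                             tables = default_tables(),
                             catalogue = default_catalogue()) {
  config$n_patients <- 1L
  res <- simulate_cohort(seq, params_catalogue, config, tables, catalogue,
                         keep_paths = TRUE)
  st <- res$path_state[1L, ]
  alive <- which(st > 0)
  states <- health_states()[st[alive]]
  trt <- vapply(states, function(s) {
    tr <- seq$assignment[[s]]
    if (is.null(tr)) NA_character_ else tr
  }, character(1))
  path <- data.frame(
    month = alive,
    state = states,
    months_in_state = res$path_tis[1L, alive],
    treatment = unname(trt),
    phase = c("active", "suspended", "off_chemo")[res$path_phase[1L, alive] + 1L],
    stringsAsFactors = FALSE
  )
  class(path) <- c("patient_path", "data.frame")
  attr(path, "death_month") <- res$death_month[1L]
  attr(path, "qaly") <- res$qaly[1L]
  attr(path, "ly") <- res$ly[1L]
  attr(path, "cost") <- res$cost[1L]
  attr(path, "label") <- seq$label
  path
}

#' Accrue discounted QALYs and life-years along a patient path
#'
#' Monthly increment: (state annual utility minus the annual disutility of
#' the drug components taken that month) / 12, discounted at the calendar
#' month; treatment disutility is paused during suspended months and the
#' chemotherapy component's disutility stops with its cycles.  Life-years
#' accrue 1/12 per month alive.
#'
#' @param path a [simulate_patient()] path.
#' @param tables cost/utility tables.
#' @param config a [sim_config()] (for the discount rate).
#' @param catalogue treatment catalogue.
#' @return named numeric vector `c(qaly =, ly =)`.
#' @export
accrue_utility <- function(path, tables = default_tables(),
                           config = sim_config(),
                           catalogue = default_catalogue()) {
  if (!nrow(path)) return(c(qaly = 0, ly = 0))
  comp <- catalogue$components
  disc <- discount_factor(path$month, config$annual_discount)
  u <- vapply(seq_len(nrow(path)), function(i) {
    su <- tables$utilities[[path$state[i]]]
    d <- 0
    if (path$phase[i] != "suspended" && !is.na(path$treatment[i])) {
      comps <- regimen_components(path$treatment[i])
      if (path$phase[i] == "off_chemo") {
        comps <- comps[comp$class[match(comps, comp$name)] != "chemo"]
      }
      d <- sum(comp$annual_disutility[match(comps, comp$name)])
    }
    (su - d) / 12
  }, numeric(1))
  c(qaly = sum(u * disc), ly = sum(disc) / 12)
}

#' Accrue discounted costs along a patient path
#'
#' Per month: the drug costs of the components taken (the ADT backbone in
#' every non-suspended month, chemotherapy only during its fixed cycles),
#' IV management during chemotherapy-infusion months and non-IV management
#' otherwise; suspended months incur only non-IV management.  If the
#' patient dies in progressed mCRPC, terminal-care costs are added over the
#' last `min(12, months spent progressed)` months of life at those months'
#' discount factors.
#'
#' @inheritParams accrue_utility
#' @return total discounted cost (CAD).
#' @export
accrue_cost <- function(path, tables = default_tables(),
                        config = sim_config(),
                        catalogue = default_catalogue()) {
  if (!nrow(path)) return(0)
  comp <- catalogue$components
  cst <- tables$costs
  disc <- discount_factor(path$month, config$annual_discount)
  monthly <- vapply(seq_len(nrow(path)), function(i) {
    if (path$phase[i] == "suspended") return(cst[["management_noniv"]])
    if (is.na(path$treatment[i])) return(cst[["management_noniv"]])
    comps <- regimen_components(path$treatment[i])
    chemo <- comps[comp$class[match(comps, comp$name)] == "chemo"]
    on_chemo <- length(chemo) > 0 && path$phase[i] == "active"
    if (!on_chemo) comps <- setdiff(comps, chemo)
    cst[["adt"]] + sum(comp$monthly_cost[match(comps, comp$name)]) +
      if (on_chemo) cst[["management_iv"]] else cst[["management_noniv"]]
  }, numeric(1))
  total <- sum(monthly * disc)
  dm <- attr(path, "death_month")
  last <- nrow(path)
  if (!is.null(dm) && dm > 0 && path$state[last] == "progressed_mCRPC") {
    k <- min(tables$eol_months, path$months_in_state[last])
    months <- dm - seq_len(k) + 1L
    total <- total + sum(tables$costs[["end_of_life_monthly"]] *
                           discount_factor(months, config$annual_discount))
  }
  total
}

#' Deterministic cohort projection over a full treatment sequence
#'
#' The matrix analogue of the microsimulation: propagates the joint
#' (state, months-in-state) occupancy distribution through the sequence's
#' chained state machine, using the same monthly transition probabilities,
#' clamping and branch probabilities as the stochastic engine.  Serves as
#' the law-of-large-numbers oracle for [simulate_cohort()].
#'
#' @inheritParams simulate_cohort
#' @return list with `occupancy` (states x months fractions, death row
#'   included), `alive` (fraction alive per month), `mean_ly` (discounted)
#'   and `mean_ly_undiscounted`.
#' @export
project_sequence <- function(seq, params_catalogue, config = sim_config(),
                             tables = default_tables(),
                             catalogue = default_catalogue()) {
  inp <- build_sim_inputs(seq, params_catalogue, config, tables, catalogue)
  H <- config$horizon
  # occ[[s]][k]: mass in state s with months-in-state k (during this month)
  occ <- lapply(1:7, function(s) numeric(H + 1))
  occ[[inp$start]][1] <- 1
  occupancy <- matrix(0, 8, H, dimnames = list(health_states(), NULL))
  for (m in seq_len(H)) {
    for (s in 1:7) occupancy[s, m] <- sum(occ[[s]])
    occupancy[8, m] <- 1 - sum(occupancy[1:7, m])
    nxt <- lapply(1:7, function(s) numeric(H + 1))
    for (s in 1:7) {
      mass <- occ[[s]]
      ks <- which(mass > 0)
      if (!length(ks)) next
      if (s == 7) {
        nxt[[7]][ks + 1] <- nxt[[7]][ks + 1] + mass[ks] * (1 - inp$delta_prog)
        next
      }
      p <- pmin(inp$alpha[s] * (1 + inp$beta[s])^(ks - 1), 1 - inp$gamma[s])
      stay <- mass[ks] * (1 - p - inp$gamma[s])
      nxt[[s]][ks + 1] <- nxt[[s]][ks + 1] + stay
      prog <- sum(mass[ks] * p)
      if (prog > 0) {
        if (s == 1) {
          nxt[[4]][1] <- nxt[[4]][1] + prog * config$p_nm_to_nmcrpc
          rest <- prog * (1 - config$p_nm_to_nmcrpc)
          nxt[[2]][1] <- nxt[[2]][1] + rest * config$p_low_risk
          nxt[[3]][1] <- nxt[[3]][1] + rest * (1 - config$p_low_risk)
        } else if (s %in% 2:4) {
          nxt[[5]][1] <- nxt[[5]][1] + prog
        } else if (s == 5) {
          tgt <- if (inp$has_l2) 6 else 7
          nxt[[tgt]][1] <- nxt[[tgt]][1] + prog
        } else {
          nxt[[7]][1] <- nxt[[7]][1] + prog
        }
      }
    }
    occ <- nxt
  }
  alive <- colSums(occupancy[1:7, , drop = FALSE])
  disc <- discount_factor(seq_len(H), config$annual_discount)
  list(occupancy = occupancy, alive = alive,
       mean_ly = sum(alive * disc) / 12,
       mean_ly_undiscounted = sum(alive) / 12)
}
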