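# Shared fixtures: tiny parameter catalogues and hand-built patient paths.

# catalogue in which every treatment-state pair gets the same parameters
uniform_catalogue <- function(alpha = 0, beta = 0, gamma = 0, delta = 0,
                              catalogue = default_catalogue()) {
  out <- list()
  for (s in names(catalogue$availability)) {
    for (tr in catalogue$availability[[s]]) {
      out[[paste(s, tr, sep = "|")]] <-
        transition_params(alpha, beta, gamma, delta)
    }
  }
  class(out) <- "param_catalogue"
  out
}

# a minimal mCSPC-starting sequence
mcspc_sequence <- function(t1 = "abi", l1 = "doce", l2 = NULL,
                           state = "mCSPC_low") {
  asg <- setNames(list(t1, l1), c(state, "mCRPC_L1"))
  if (!is.null(l2)) asg$mCRPC_L2 <- l2
  treatment_sequence(state, asg)
}

nmcspc_sequence <- function(t0 = "adt", mid = "abi", l1 = "doce",
                            l2 = NULL) {
  asg <- list(nmCSPC = t0, mCSPC_low = mid, mCSPC_high = mid,
              nmCRPC = mid, mCRPC_L1 = l1)
  if (!is.null(l2)) asg$mCRPC_L2 <- l2
  treatment_sequence("nmCSPC", asg)
}

# hand-built patient path for the accrual functions
make_path <- function(months, state, treatment, phase,
                      months_in_state = seq_along(months),
                      death_month = 0) {
  p <- data.frame(month = months, state = state,
                  months_in_state = months_in_state,
                  treatment = treatment, phase = phase,
                  stringsAsFactors = FALSE)
  class(p) <- c("patient_path", "data.frame")
  attr(p, "death_month") <- death_month
  p
}

# independent brute-force product-limit estimator (test oracle)
brute_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n_at <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / n_at)
    surv[i] <- s
  }
  list(time = ut, surv = surv)
}
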