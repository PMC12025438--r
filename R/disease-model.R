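#' Health states of the disease model
#'
#' Advanced prostate cancer is modeled as nonmetastatic castration-sensitive
#' disease (nmCSPC), metastatic castration-sensitive disease stratified into
#' low and high risk (mCSPC_low, mCSPC_high), nonmetastatic castration
#' resistance (nmCRPC), two treatment lines of metastatic castration
#' resistance (mCRPC_L1, mCRPC_L2), a progressed terminal mCRPC state and
#' death.  Death is absorbing; progressed mCRPC transitions only to death.
#'
#' @return character vector of state names in model order.
#' @export
health_states <- function() {
  c("nmCSPC", "mCSPC_low", "mCSPC_high", "nmCRPC",
    "mCRPC_L1", "mCRPC_L2", "progressed_mCRPC", "death")
}

# component-level drug facts (costs CAD/month, disutilities utility/year)
.components <- data.frame(
  name = c("adt", "abi", "apa", "daro", "enza", "doce", "caba"),
  class = c("backbone", "arpi", "arpi", "arpi", "arpi", "chemo", "chemo"),
  monthly_cost = c(322, 919, 3401, 3401, 3401, 103, 4134),
  annual_disutility = c(0, 0.021, 0.019, 0.019, 0.022, 0.042, 0.042),
  stringsAsFactors = FALSE
)

#' Split a regimen label into drug components
#'
#' Regimen labels use lower-case drug stems joined by `" + "`
#' (e.g. `"doce + daro"`).  `"adt"` denotes the ADT backbone alone and has
#' no additional components; every regimen is given in combination with
#' ADT.
#'
#' @param treatment regimen label.
#' @return character vector of non-backbone component names.
#' @export
regimen_components <- function(treatment) {
  if (treatment == "adt") return(character(0))
  comps <- trimws(strsplit(treatment, "\\+")[[1]])
  unknown <- setdiff(comps, .components$name)
  if (length(unknown)) {
    stop("unknown treatment component: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  comps
}

regimen_has_class <- function(treatment, cls) {
  comps <- regimen_components(treatment)
  any(.components$class[match(comps, .components$name)] == cls)
}

#' Does a regimen contain an androgen receptor pathway inhibitor?
#' @param treatment regimen label.
#' @return logical.
#' @export
is_arpi <- function(treatment) regimen_has_class(treatment, "arpi")

#' Does a regimen contain chemotherapy?
#' @param treatment regimen label.
#' @return logical.
#' @export
is_chemo <- function(treatment) regimen_has_class(treatment, "chemo")

#' Default treatment catalogue
#'
#' Availability of regimens per health state, following the trial evidence
#' base: intermittent ADT or enzalutamide in nmCSPC (EMBARK); ADT, the four
#' ARPIs and ARPI+docetaxel combinations in mCSPC (docetaxel alone only in
#' high-risk disease); ADT or any ARPI in nmCRPC; abiraterone, enzalutamide
#' or docetaxel as first-line mCRPC; abiraterone, enzalutamide or
#' cabazitaxel after docetaxel.  Cabazitaxel is only used immediately after
#' docetaxel, mirroring its post-docetaxel trial evidence.
#'
#' @return object of class `pca_catalogue`: a list with `availability`
#'   (state -> regimen labels), `mcrpc_post_doce` (mCRPC options when
#'   docetaxel was given earlier in the sequence), `intermittent`
#'   (regimens taken intermittently in nmCSPC) and `chemo_cycles`
#'   (fixed chemotherapy cycle counts by component and setting).
#' @export
default_catalogue <- function() {
  arpis <- c("abi", "apa", "daro", "enza")
  combos <- c("doce + abi", "doce + daro", "doce + enza")
  structure(list(
    availability = list(
      nmCSPC = c("adt", "enza"),
      mCSPC_low = c("adt", arpis, combos),
      mCSPC_high = c("adt", arpis, "doce", combos),
      nmCRPC = c("adt", arpis),
      mCRPC_L1 = c("abi", "enza", "doce"),
      mCRPC_L2 = c("abi", "enza", "caba")
    ),
    mcrpc_post_doce = c("abi", "enza", "caba"),
    intermittent = c("adt", "enza"),
    chemo_cycles = list(doce = c(mCSPC = 6L, mCRPC = 10L), caba = 10L),
    components = .components
  ), class = "pca_catalogue")
}

#' @export
print.pca_catalogue <- function(x, ...) {
  cat("Treatment catalogue\n")
  for (s in names(x$availability)) {
    cat(sprintf("  %-12s %s\n", s, paste(x$availability[[s]], collapse = ", ")))
  }
  invisible(x)
}

#' Construct a treatment sequence
#'
#' A sequence assigns one regimen to each health state a patient can visit.
#' nmCSPC-starting sequences assign nmCSPC, a shared middle regimen for
#' mCSPC (both risk strata) and nmCRPC, and the mCRPC line(s); mCSPC-starting
#' sequences assign the starting mCSPC stratum and the mCRPC line(s).
#'
#' @param starting_state one of `"nmCSPC"`, `"mCSPC_low"`, `"mCSPC_high"`.
#' @param assignment named list/character vector mapping state names to
#'   regimen labels; `mCRPC_L2` is optional.
#' @return object of class `treatment_sequence` with fields
#'   `starting_state`, `assignment`, `label` (the field's tuple notation,
#'   e.g. `"(adt, abi, doce then caba)"`) and `arpi_use`.
#' @export
treatment_sequence <- function(starting_state, assignment) {
  starting_state <- match.arg(starting_state,
                              c("nmCSPC", "mCSPC_low", "mCSPC_high"))
  assignment <- as.list(assignment)
  needed <- if (starting_state == "nmCSPC") {
    c("nmCSPC", "mCSPC_low", "mCSPC_high", "nmCRPC", "mCRPC_L1")
  } else {
    c(starting_state, "mCRPC_L1")
  }
  missing <- setdiff(needed, names(assignment))
  if (length(missing)) {
    stop("sequence must assign a treatment for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (tr in unlist(assignment)) regimen_components(tr)  # name check
  x <- structure(list(starting_state = starting_state,
                      assignment = assignment, label = NULL,
                      arpi_use = NULL),
                 class = "treatment_sequence")
  x$label <- sequence_label(x)
  x$arpi_use <- classify_arpi_use(x)
  x
}

# states in the order a patient can visit them under a sequence
visited_states <- function(seq) {
  sts <- if (seq$starting_state == "nmCSPC") {
    c("nmCSPC", "mCSPC_low", "mCSPC_high", "nmCRPC", "mCRPC_L1", "mCRPC_L2")
  } else {
    c(seq$starting_state, "mCRPC_L1", "mCRPC_L2")
  }
  intersect(sts, names(seq$assignment))
}

sequence_label <- function(seq) {
  a <- seq$assignment
  mcrpc <- a[["mCRPC_L1"]]
  if (!is.null(a[["mCRPC_L2"]])) mcrpc <- paste(mcrpc, "then", a[["mCRPC_L2"]])
  parts <- if (seq$starting_state == "nmCSPC") {
    c(a[["nmCSPC"]], a[["mCSPC_low"]], mcrpc)
  } else {
    c(a[[seq$starting_state]], mcrpc)
  }
  paste0("(", paste(parts, collapse = ", "), ")")
}

#' @export
print.treatment_sequence <- function(x, ...) {
  cat("Treatment sequence", x$label, "from", x$starting_state,
      sprintf("[%s ARPI use]\n", x$arpi_use))
  invisible(x)
}

#' Classify a sequence's ARPI timing
#'
#' `"early"` if the starting state's regimen contains an ARPI (alone or in
#' combination), `"late"` if any later state's regimen does, `"none"`
#' otherwise.
#'
#' @param seq a [treatment_sequence()].
#' @return `"early"`, `"late"` or `"none"`.
#' @export
classify_arpi_use <- function(seq) {
  sts <- visited_states(seq)
  arpi <- vapply(sts, function(s) is_arpi(seq$assignment[[s]]), logical(1))
  if (arpi[[1L]]) return("early")
  if (any(arpi)) return("late")
  "none"
}

#' Validate a treatment sequence against the catalogue and sequencing rules
#'
#' Checks (i) every assigned regimen is available in its state,
#' (ii) no ARPI rechallenge: no ARPI-containing regimen in any state after a
#' state whose regimen contained an ARPI (cross-resistance), (iii) for
#' nmCSPC-starting sequences the mCSPC and nmCRPC assignments are the same
#' regimen (same-ARPI rule for late ARPI use), (iv) cabazitaxel only
#' immediately after docetaxel, and (v) second-line mCRPC only after
#' first-line docetaxel.
#'
#' @param seq a [treatment_sequence()].
#' @param catalogue a [default_catalogue()]-shaped catalogue.
#' @return character vector of violations (empty if valid), each naming the
#'   rule and the states involved.
#' @export
validate_sequence <- function(seq, catalogue = default_catalogue()) {
  v <- character(0)
  a <- seq$assignment
  sts <- visited_states(seq)
  prior_doce <- FALSE
  for (s in sts) {
    tr <- a[[s]]
    avail <- catalogue$availability[[s]]
    if (s == "mCRPC_L1" && prior_doce) {
      avail <- union(avail, catalogue$mcrpc_post_doce)
    }
    if (s == "mCRPC_L2") {
      if (a[["mCRPC_L1"]] != "doce") {
        v <- c(v, "second mCRPC line requires first-line docetaxel")
      }
      avail <- catalogue$availability$mCRPC_L2
    }
    if (!tr %in% avail) {
      v <- c(v, paste0("treatment '", tr, "' not available in ", s))
    }
    if (any(regimen_components(tr) == "caba") && !prior_doce) {
      v <- c(v, paste0("cabazitaxel in ", s, " without prior docetaxel"))
    }
    if (is_chemo(tr)) prior_doce <- TRUE
  }
  # rechallenge operates on treatment lines: for nmCSPC starts the shared
  # mCSPC/nmCRPC slot is a single line (a patient visits one of its states)
  lines <- treatment_lines(seq)
  arpi <- vapply(lines$treatment, is_arpi, logical(1))
  w <- which(arpi)
  if (length(w) && any(arpi[-seq_len(w[1L])])) {
    later <- lines$line[w[w > w[1L]]]
    v <- c(v, paste0("ARPI rechallenge: ARPI in ",
                     paste(later, collapse = ", "),
                     " after ARPI exposure in ", lines$line[w[1L]]))
  }
  if (seq$starting_state == "nmCSPC") {
    mids <- unlist(a[c("mCSPC_low", "mCSPC_high", "nmCRPC")])
    if (length(unique(mids)) != 1L) {
      v <- c(v, "mCSPC and nmCRPC must receive the same treatment")
    }
  }
  v
}

# successive treatment lines of a sequence (the shared mCSPC/nmCRPC slot of
# nmCSPC-starting sequences is one line)
treatment_lines <- function(seq) {
  a <- seq$assignment
  if (seq$starting_state == "nmCSPC") {
    line <- c("nmCSPC", "mCSPC/nmCRPC", "mCRPC_L1")
    trt <- c(a[["nmCSPC"]], a[["mCSPC_low"]], a[["mCRPC_L1"]])
  } else {
    line <- c(seq$starting_state, "mCRPC_L1")
    trt <- c(a[[seq$starting_state]], a[["mCRPC_L1"]])
  }
  if (!is.null(a[["mCRPC_L2"]])) {
    line <- c(line, "mCRPC_L2")
    trt <- c(trt, a[["mCRPC_L2"]])
  }
  list(line = line, treatment = trt)
}

#' Enumerate guideline-admissible treatment sequences
#'
#' Generates all sequences from a starting state that satisfy
#' [validate_sequence()]: availability per state, no ARPI rechallenge,
#' cabazitaxel only immediately post-docetaxel, a second mCRPC line only
#' after first-line docetaxel and, for nmCSPC starts, a shared mCSPC/nmCRPC
#' regimen with any ARPI use confined to the starting or middle slot.
#' Ordering is canonical: by ARPI timing (early, late, none), then
#' lexicographic label.
#'
#' @param catalogue a [default_catalogue()]-shaped catalogue.
#' @param starting_state starting health state.
#' @param expected optional expected count; when given, a difference is
#'   reported as a message (soft check -- the admissibility rules in the
#'   main sources under-determine the exact published counts).
#' @return list of [treatment_sequence()] objects.
#' @export
enumerate_sequences <- function(catalogue = default_catalogue(),
                                starting_state = "nmCSPC",
                                expected = NULL) {
  mcrpc_lines <- function(prior_arpi, prior_doce, arpi_ok = TRUE) {
    l1 <- catalogue$availability$mCRPC_L1
    if (prior_doce) l1 <- union(l1, catalogue$mcrpc_post_doce)
    l1 <- setdiff(l1, "caba")  # cabazitaxel only directly after docetaxel
    if (prior_arpi || !arpi_ok) l1 <- l1[!vapply(l1, is_arpi, logical(1))]
    out <- list()
    for (t1 in l1) {
      out[[length(out) + 1L]] <- list(mCRPC_L1 = t1)
      if (t1 == "doce") {
        l2 <- catalogue$availability$mCRPC_L2
        if (prior_arpi || !arpi_ok) l2 <- l2[!vapply(l2, is_arpi, logical(1))]
        for (t2 in l2) {
          out[[length(out) + 1L]] <- list(mCRPC_L1 = t1, mCRPC_L2 = t2)
        }
      }
    }
    out
  }

  seqs <- list()
  if (starting_state == "nmCSPC") {
    mid_opts <- Reduce(intersect,
                       catalogue$availability[c("mCSPC_low", "mCSPC_high",
                                                "nmCRPC")])
    for (t0 in catalogue$availability$nmCSPC) {
      mids <- mid_opts
      if (is_arpi(t0)) mids <- mids[!vapply(mids, is_arpi, logical(1))]
      for (tm in mids) {
        # any late ARPI must sit in the shared mCSPC/nmCRPC slot, so the
        # mCRPC lines of nmCSPC-starting sequences are chemotherapy-only
        for (tail in mcrpc_lines(prior_arpi = is_arpi(t0) || is_arpi(tm),
                                 prior_doce = FALSE, arpi_ok = FALSE)) {
          asg <- c(list(nmCSPC = t0, mCSPC_low = tm, mCSPC_high = tm,
                        nmCRPC = tm), tail)
          seqs[[length(seqs) + 1L]] <- treatment_sequence("nmCSPC", asg)
        }
      }
    }
  } else {
    for (t0 in catalogue$availability[[starting_state]]) {
      for (tail in mcrpc_lines(prior_arpi = is_arpi(t0),
                               prior_doce = is_chemo(t0))) {
        asg <- c(setNames(list(t0), starting_state), tail)
        seqs[[length(seqs) + 1L]] <- treatment_sequence(starting_state, asg)
      }
    }
  }
  timing <- vapply(seqs, function(s) s$arpi_use, character(1))
  labels <- vapply(seqs, function(s) s$label, character(1))
  ord <- order(match(timing, c("early", "late", "none")), labels)
  seqs <- seqs[ord]
  if (!is.null(expected) && length(seqs) != expected) {
    message("enumerated ", length(seqs), " sequences for ", starting_state,
            " (expected ", expected, ", diff ", length(seqs) - expected, ")")
  }
  seqs
}

#' Successor state on progression
#'
#' Progression advances a patient along the sequence's state machine:
#' nmCSPC branches to nmCRPC with probability `p_nmcrpc` (0 by default) and
#' otherwise to low-risk mCSPC with probability `p_low` (0.651) or high-risk
#' mCSPC; mCSPC and nmCRPC progress to first-line mCRPC; first-line mCRPC to
#' the second line if the sequence assigns one, else to progressed mCRPC;
#' the second line to progressed mCRPC.  Progressed mCRPC transitions only
#' to death and has no successor here.
#'
#' @param state current health state (not `"death"`).
#' @param seq a [treatment_sequence()].
#' @param u,u2 uniform draws for the nmCSPC branch (drawn if missing).
#' @param p_low probability that an nmCSPC progression routed to mCSPC
#'   enters the low-risk stratum.
#' @param p_nmcrpc probability that an nmCSPC progression goes to nmCRPC.
#' @return the successor state name.
#' @export
successor_state <- function(state, seq, u = runif(1), u2 = runif(1),
                            p_low = 0.651, p_nmcrpc = 0) {
  switch(state,
    nmCSPC = if (u < p_nmcrpc) "nmCRPC"
             else if (u2 < p_low) "mCSPC_low" else "mCSPC_high",
    mCSPC_low = ,
    mCSPC_high = ,
    nmCRPC = "mCRPC_L1",
    mCRPC_L1 = if (!is.null(seq$assignment[["mCRPC_L2"]])) "mCRPC_L2"
               else "progressed_mCRPC",
    mCRPC_L2 = "progressed_mCRPC",
    progressed_mCRPC = "death",
    death = stop("death is absorbing", call. = FALSE),
    stop("unknown state: ", state, call. = FALSE)
  )
}

#' Reference sequence without ARPI use
#'
#' The comparator for incremental outcomes: `(adt, adt, doce)` for
#' nmCSPC-starting patients and `(adt, doce)` for mCSPC-starting patients.
#'
#' @param starting_state starting health state.
#' @return a [treatment_sequence()].
#' @export
reference_sequence <- function(starting_state = "nmCSPC") {
  if (starting_state == "nmCSPC") {
    treatment_sequence("nmCSPC",
                       list(nmCSPC = "adt", mCSPC_low = "adt",
                            mCSPC_high = "adt", nmCRPC = "adt",
                            mCRPC_L1 = "doce"))
  } else {
    treatment_sequence(starting_state,
                       setNames(list("adt", "doce"),
                                c(starting_state, "mCRPC_L1")))
  }
}
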