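# ---------------------------------------------------------------------------
# Constrained generate-and-test calibration: express timing, steady-state
# and pool-size constraints, score trajectories against them, sample
# parameter space log-uniformly, and scan parameter sensitivity.
# ---------------------------------------------------------------------------

#' Define one calibration constraint
#'
#' @param kind `"steady_state"` (relative drift of a state over the run),
#'   `"phase_duration"` (hours of a phase), `"pool_size"` (amount of a
#'   state, or sum of states, averaged over a phase or the whole run) or
#'   `"ordering"` (event A before event B).
#' @param target for phase_duration one of G0/G1/S/G2/M or `"period"` /
#'   `"first_division"`; for pool_size / steady_state a (vector of)
#'   qualified state name(s); for ordering a character pair of event names
#'   from the timeline attributes.
#' @param window numeric `c(lo, hi)` the measured value must fall in.
#' @param cycle_selector `"first"`, `"subsequent"` or `"all"`.
#' @param during optional phase restricting a pool_size average.
#' @export
constraint <- function(kind = c("steady_state", "phase_duration",
                                "pool_size", "ordering"),
                       target, window, cycle_selector = "all",
                       during = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(window) == 2, window[1] <= window[2])
  structure(list(kind = kind, target = target, window = window,
                 cycle_selector = match.arg(cycle_selector,
                                            c("first", "subsequent", "all")),
                 during = during),
            class = "Constraint")
}

#' Bundle constraints into a set
#' @param ... `Constraint` objects (or a single list of them).
#' @export
constraint_set <- function(...) {
  cs <- list(...)
  if (length(cs) == 1 && !inherits(cs[[1]], "Constraint")) cs <- cs[[1]]
  stopifnot(all(vapply(cs, inherits, TRUE, "Constraint")))
  structure(cs, class = "ConstraintSet")
}

#' The default calibration constraint set
#'
#' Phase-duration windows are +/-20% around the nominal timings of the
#' calibrated model (initial G1 ~24 h, subsequent ~15 h; S ~8 h; initial G2
#' ~12 h, subsequent ~7 h; M ~4 h; steady cycling ~1.3 days), plus the
#' quiescent RNA-polymerase pool (~3e4, mostly sequestered) and the
#' replication-origin cap.
#' @export
default_constraints <- function() {
  w <- function(x) c(0.8, 1.2) * x
  constraint_set(
    constraint("phase_duration", "G1", w(24), "first"),
    constraint("phase_duration", "G1", w(15), "subsequent"),
    constraint("phase_duration", "S", w(8), "all"),
    constraint("phase_duration", "G2", w(12), "first"),
    constraint("phase_duration", "G2", w(7), "subsequent"),
    constraint("phase_duration", "M", w(4), "all"),
    constraint("phase_duration", "period", w(1.3), "subsequent"),
    constraint("pool_size",
               paste0("rnapol.", c("unfold", "sequestered", "active",
                                   "transcribing", "trash")),
               c(2.4e4, 3.6e4), "all"),
    constraint("pool_size", c("rc.dna_b", "rc.lic", "rc.trav"),
               c(0, 15000), "all"))
}

measure_constraint <- function(con, traj, tl) {
  sm <- phase_summary(tl)
  val <- switch(con$kind,
    phase_duration = {
      key <- switch(con$target,
        G1 = if (con$cycle_selector == "first") sm$first_g1_h else sm$g1_h,
        S = if (con$cycle_selector == "first") sm$s_first_h else sm$s_h,
        G2 = if (con$cycle_selector == "first") sm$first_g2_h else sm$g2_h,
        M = sm$m_h,
        period = sm$period_d,
        first_division = sm$first_division_d,
        stop("unknown phase target ", con$target))
      key
    },
    pool_size = {
      x <- if (length(con$target) == 1) traj$amounts[con$target, ] else
        colSums(traj$amounts[con$target, , drop = FALSE])
      if (!is.null(con$during)) {
        keep <- rep(FALSE, length(traj$times))
        for (i in which(tl$phase == con$during))
          keep <- keep | (traj$times >= tl$start[i] &
                            traj$times <= tl$end[i])
        if (!any(keep)) return(NA_real_)
        x <- x[keep]
      }
      if (identical(con$window[1], 0)) max(x) else mean(x)
    },
    steady_state = {
      x <- traj$amounts[con$target, ]
      abs(x[length(x)] - x[1]) / max(abs(x[1]), 1)
    },
    ordering = {
      ev <- function(nm) switch(nm,
        s_onset = if (nrow(attr(tl, "s_intervals"))) attr(tl, "s_intervals")[1, 1] else NA,
        cascade = if (length(attr(tl, "cascades"))) attr(tl, "cascades")[1] else NA,
        division = if (length(attr(tl, "divisions"))) attr(tl, "divisions")[1] else NA)
      a <- ev(con$target[1]); b <- ev(con$target[2])
      if (is.na(a) || is.na(b)) NA_real_ else as.numeric(a < b)
    })
  val
}

#' Score a trajectory against a constraint set
#'
#' The score is the sum of normalized violations: a measured value `v`
#' outside `[lo, hi]` contributes `(distance outside the window) /
#' (half-width)`; an unmeasurable target (absent phase) contributes a unit
#' violation with a reason.  Score 0 iff every constraint is satisfied.
#'
#' @param traj a `Trajectory`.
#' @param tl its `PhaseTimeline` (computed if missing).
#' @param cs a `ConstraintSet`.
#' @return list with `score` and `report` (one row per constraint with the
#'   measured value and pass/fail).
#' @export
evaluate_constraints <- function(traj, cs, tl = detect_phases(traj)) {
  rows <- lapply(cs, function(con) {
    v <- measure_constraint(con, traj, tl)
    half <- max((con$window[2] - con$window[1]) / 2, .Machine$double.eps)
    viol <- if (is.na(v)) 1
    else if (v < con$window[1]) (con$window[1] - v) / half
    else if (v > con$window[2]) (v - con$window[2]) / half
    else 0
    data.frame(kind = con$kind,
               target = paste(con$target, collapse = "+"),
               selector = con$cycle_selector,
               lo = con$window[1], hi = con$window[2], value = v,
               violation = viol, pass = viol == 0,
               reason = if (is.na(v)) "target unmeasurable" else "",
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(score = if (!is.null(report) && nrow(report)) sum(report$violation)
       else 0,
       report = report)
}

#' Seeded generate-and-test parameter search
#'
#' Samples each searched parameter log-uniformly over its range, scores the
#' resulting model with a user-supplied objective, and returns the best
#' parameter set with the full evaluation trace.  The search is
#' deterministic given the seed, and resumable from a previous trace.
#'
#' @param objective `function(param_list) -> score` (builds the model,
#'   simulates, evaluates constraints).  Build or integration failures
#'   should raise conditions; they are caught, scored `Inf` and logged.
#' @param search_space named list of `c(lo, hi)` ranges (positive).
#' @param seed integer seed.
#' @param budget number of evaluations.
#' @param trace optional previous trace to resume from.
#' @return list with `best` (parameter list), `best_score`, `trace`
#'   (data.frame: eval, score, one column per parameter).
#' @export
generate_and_test <- function(objective, search_space, seed, budget,
                              trace = NULL) {
  stopifnot(budget >= 1, length(search_space) >= 1)
  set.seed(seed)
  done <- if (is.null(trace)) 0L else nrow(trace)
  if (done > 0)  # replay the stream so resumed runs continue it
    invisible(stats::runif(done * length(search_space)))
  rows <- vector("list", budget)
  for (i in seq_len(budget)) {
    u <- stats::runif(length(search_space))
    par <- mapply(function(rg, ui) exp(log(rg[1]) +
                                         ui * (log(rg[2]) - log(rg[1]))),
                  search_space, u, SIMPLIFY = FALSE)
    sc <- tryCatch(objective(par), error = function(e) Inf)
    rows[[i]] <- cbind(data.frame(eval = done + i, score = sc),
                       as.data.frame(par))
  }
  new_trace <- rbind(trace, do.call(rbind, rows))
  best_i <- which.min(new_trace$score)   # ties: earliest evaluation
  best <- as.list(new_trace[best_i, -(1:2), drop = FALSE])
  list(best = best, best_score = new_trace$score[best_i],
       trace = new_trace)
}

#' Sensitivity scan of a scored parameter set
#'
#' Re-scores the objective with each parameter perturbed by +/- a fraction
#' and reports the score deltas, ranked; integration failures are recorded
#' as instabilities rather than crashes.
#'
#' @param objective `function(param_overrides) -> score`.
#' @param params named list of parameter values (the calibrated set).
#' @param perturbation relative perturbation (e.g. 0.2 for +/-20%).
#' @param base_score optional precomputed score of `params`.
#' @return data.frame: parameter, value, score_minus, score_plus, delta
#'   (max |score change|), unstable (logical), ranked by delta.
#' @export
sensitivity_scan <- function(objective, params, perturbation,
                             base_score = NULL) {
  if (is.null(base_score))
    base_score <- tryCatch(objective(params), error = function(e) Inf)
  rows <- lapply(names(params), function(nm) {
    one <- function(f) {
      p <- params; p[[nm]] <- p[[nm]] * f
      tryCatch(objective(p), error = function(e) NA_real_)
    }
    lo <- one(1 - perturbation); hi <- one(1 + perturbation)
    data.frame(parameter = nm, value = params[[nm]],
               score_base = base_score, score_minus = lo, score_plus = hi,
               delta = max(abs(c(lo, hi) - base_score), na.rm = FALSE),
               unstable = is.na(lo) || is.na(hi),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$delta[is.na(out$delta)] <- Inf
  out[order(-out$delta), ]
}
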