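# ---------------------------------------------------------------------------
# Stiff integration of a compiled model over days of simulated time, with
# discrete events: stimulus steps (mitogen/adhesion) and cell division
# (halving of every extensive state, triggered by the mitotic-exit root).
# ---------------------------------------------------------------------------

#' Stimulus schedule
#'
#' Step changes of the external signals (mitogen, adhesion) at given times.
#'
#' @param times seconds, non-decreasing.
#' @param signals character, `"mitogen"` or `"adhesion"`.
#' @param levels numeric in `[0, 1]`.
#' @return data.frame of class `StimulusSchedule`.
#' @export
stimulus_schedule <- function(times = numeric(), signals = character(),
                              levels = numeric()) {
  stopifnot(length(times) == length(signals),
            length(times) == length(levels),
            all(levels >= 0), all(levels <= 1))
  if (is.unsorted(times)) stop("stimulus times must be non-decreasing")
  structure(data.frame(time = times, signal = signals, level = levels,
                       stringsAsFactors = FALSE),
            class = c("StimulusSchedule", "data.frame"))
}

#' Default solver settings
#' @param rtol relative tolerance.
#' @param atol absolute tolerance (counts).
#' @param method a deSolve integrator capable of handling stiff systems
#'   and root events.
#' @param dt_report reporting interval in seconds.
#' @export
solver_settings <- function(rtol = 1e-6, atol = 1e-3, method = "lsoda",
                            dt_report = 600) {
  list(rtol = rtol, atol = atol, method = method, dt_report = dt_report)
}

#' Integrate a compiled model
#'
#' Integrates the stiff ODE system with deSolve, applying stimulus steps at
#' their scheduled times and firing the cell-division event whenever the
#' model's division trigger is satisfied (mitotic exit: the Cdc14
#' activation pulse, with APC(Cdh1) rebounding, Securin destroyed and DNA
#' replicated).  Integration is restarted after each discrete event.
#'
#' @param model a `CompiledModel`.  Optional element `division` (see
#'   [division_spec()]) enables the division event; optional element
#'   `signals` maps signal names to bookkeeping states.
#' @param schedule a [stimulus_schedule()] or `NULL`.
#' @param t_end end time, seconds.
#' @param solver a [solver_settings()] list.
#' @param x0 starting amounts (default: the model's initial state).
#' @return object of class `Trajectory`: `times` (seconds grid), `amounts`
#'   (states x times matrix), `event_log` (data.frame time/kind/detail),
#'   plus the model and solver settings.
#' @export
simulate_model <- function(model, schedule = NULL, t_end,
                           solver = solver_settings(),
                           x0 = initial_state(model)) {
  stopifnot(inherits(model, "CompiledModel"), t_end > 0)
  idx <- model$state_index
  div <- model$division
  log_env <- new.env(parent = emptyenv())
  log_env$rows <- list()
  log_evt <- function(time, kind, detail = "")
    log_env$rows[[length(log_env$rows) + 1L]] <-
      data.frame(time = time, kind = kind, detail = detail,
                 stringsAsFactors = FALSE)

  func <- function(t, y, parms) list(model$rhs(t, y))

  rootfun <- NULL
  eventfun <- NULL
  if (!is.null(div)) {
    ri <- idx[[div$root_state]]
    rootfun <- function(t, y, parms)
      pmax(y[ri], 0) / model$cell_size(y) - div$threshold
    eventfun <- function(t, y, parms) {
      # the integrator also calls the event function at the segment start;
      # only act when the root is actually satisfied
      if (abs(rootfun(t, y, parms)) > 1e-3 * max(div$threshold, 1))
        return(y)
      if (division_ready(y, model)) {
        y2 <- apply_division(y, model)
        log_evt(t, "division",
                sprintf("size %.3f -> %.3f", model$cell_size(y),
                        model$cell_size(y2)))
        y2
      } else {
        log_evt(t, "root_skipped", "division guards not satisfied")
        y
      }
    }
  }

  seg_bounds <- c(0, if (!is.null(schedule)) schedule$time, t_end)
  seg_bounds <- sort(unique(pmin(pmax(seg_bounds, 0), t_end)))
  grid_all <- NULL
  out_all <- NULL
  y <- x0
  for (si in seq_len(length(seg_bounds) - 1L)) {
    t0 <- seg_bounds[si]; t1 <- seg_bounds[si + 1L]
    if (!is.null(schedule)) {
      hit <- which(schedule$time == t0)
      for (h in hit) {
        qn <- model$signals[[schedule$signal[h]]]
        if (is.null(qn))
          stop(sprintf("model has no signal state for '%s'",
                       schedule$signal[h]))
        y[idx[[qn]]] <- schedule$level[h]
        log_evt(t0, "stimulus",
                sprintf("%s=%g", schedule$signal[h], schedule$level[h]))
      }
    }
    if (t1 <= t0) next
    times <- unique(c(seq(t0, t1, by = solver$dt_report), t1))
    out <- deSolve::ode(y = y, times = times, func = func, parms = NULL,
                        method = solver$method,
                        rtol = solver$rtol, atol = solver$atol,
                        events = if (!is.null(div))
                          list(func = eventfun, root = TRUE),
                        rootfun = rootfun,
                        maxsteps = 50000)
    if (attr(out, "istate")[1] < 0)
      stop(diagnose_failure(model, out))
    y <- out[nrow(out), -1]
    keep <- if (is.null(out_all)) seq_len(nrow(out)) else -1L
    out_all <- rbind(out_all, out[keep, , drop = FALSE])
  }

  times <- out_all[, 1]
  amounts <- t(out_all[, -1, drop = FALSE])
  rownames(amounts) <- model$states$qname
  neg <- apply(amounts, 1, min)
  bad <- which(neg < -10 * solver$atol)
  for (b in bad)
    log_evt(times[which.min(amounts[b, ])], "tolerance_warning",
            sprintf("%s reached %.3g", model$states$qname[b], neg[b]))
  amounts[amounts < 0] <- 0
  ev <- if (length(log_env$rows)) do.call(rbind, log_env$rows) else
    data.frame(time = numeric(), kind = character(), detail = character(),
               stringsAsFactors = FALSE)
  structure(list(times = times, amounts = amounts, event_log = ev,
                 model = model, solver = solver),
            class = "Trajectory")
}

diagnose_failure <- function(model, out) {
  y0 <- out[max(1, nrow(out) - 1), -1]
  y1 <- out[nrow(out), -1]
  dt <- out[nrow(out), 1] - out[max(1, nrow(out) - 1), 1]
  rel <- abs(y1 - y0) / pmax(abs(y0), 1)
  worst <- order(rel, decreasing = TRUE)[1:5]
  paste0("solver failure; fastest-varying states: ",
         paste(model$states$qname[worst], collapse = ", "),
         sprintf(" (over the last %.0f s)", dt))
}

#' Division trigger specification
#'
#' The division event fires when the declared root state's concentration
#' crosses its threshold (the Cdc14 activation pulse at mitotic exit)
#' while every guard condition holds (APC(Cdh1) rebound, Securin
#' destroyed) and DNA has been replicated.
#'
#' @param root_state qualified state whose concentration crossing
#'   `threshold` fires the event.
#' @param threshold concentration threshold for the root.
#' @param guards_above,guards_below named numeric vectors: qualified states
#'   whose concentrations must lie above/below the given values.
#' @param dna_state qualified state holding the DNA nucleotide count.
#' @param genome_nt nucleotides in one genome equivalent.
#' @param reset optional `function(x, model)` applied after halving
#'   (bookkeeping resets: replication-origin capacity).
#' @export
division_spec <- function(root_state, threshold, guards_above = numeric(),
                          guards_below = numeric(), dna_state = NULL,
                          genome_nt = NA_real_, reset = NULL) {
  list(root_state = root_state, threshold = threshold,
       guards_above = guards_above, guards_below = guards_below,
       dna_state = dna_state, genome_nt = genome_nt, reset = reset)
}

division_ready <- function(x, model) {
  div <- model$division
  if (is.null(div)) return(FALSE)
  sz <- model$cell_size(x)
  conc <- function(qn) max(x[model$state_index[[qn]]], 0) / sz
  for (qn in names(div$guards_above))
    if (conc(qn) < div$guards_above[[qn]]) return(FALSE)
  for (qn in names(div$guards_below))
    if (conc(qn) > div$guards_below[[qn]]) return(FALSE)
  if (!is.null(div$dna_state) &&
      x[model$state_index[[div$dna_state]]] < 1.8 * div$genome_nt)
    return(FALSE)
  TRUE
}

#' Apply the cell-division transformation to a state vector
#'
#' Every extensive state is multiplied by one half (so concentrations,
#' count/size, are unchanged); bookkeeping states (signals, origin
#' counters) are left alone and then reset through the model's declared
#' reset hook.  Triggering with unreplicated DNA (< 1.8 genome
#' equivalents) emits a warning.
#'
#' @param x state vector.
#' @param model the `CompiledModel` (supplies halving flags and reset
#'   hooks).
#' @return the post-division state vector.
#' @export
apply_division <- function(x, model) {
  div <- model$division
  if (!is.null(div) && !is.null(div$dna_state)) {
    dna <- x[model$state_index[[div$dna_state]]]
    if (dna < 1.8 * div$genome_nt)
      warning(sprintf("pathological division with %.2f genome equivalents",
                      dna / div$genome_nt))
  }
  x2 <- x
  h <- model$states$halve
  x2[h] <- x[h] * 0.5
  if (!is.null(div) && !is.null(div$reset)) x2 <- div$reset(x2, model)
  x2
}

#' Extract one state's time course from a trajectory
#' @param traj a `Trajectory`.
#' @param qname qualified state name (or vector; amounts are summed).
#' @return numeric vector along `traj$times`.
#' @export
traj_amount <- function(traj, qname) {
  miss <- setdiff(qname, rownames(traj$amounts))
  if (length(miss)) stop("unknown states: ", paste(miss, collapse = ", "))
  if (length(qname) == 1L) traj$amounts[qname, ] else
    colSums(traj$amounts[qname, , drop = FALSE])
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory: %d states, %d time points, %.2f days, %d events>\n",
              nrow(x$amounts), length(x$times),
              max(x$times) / 86400, nrow(x$event_log)))
  invisible(x)
}
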