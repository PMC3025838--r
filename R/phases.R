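# ---------------------------------------------------------------------------
# Extract the G0/G1/S/G2/M timeline from a trajectory: S phase from the
# DNA-synthesis slope, the G2/M boundary from the cycB/Cdk1-Cdc25C cascade
# (active nuclear cycB/Cdk1 crossing a threshold), division times from the
# event log.
# ---------------------------------------------------------------------------

#' Phase-detection thresholds
#' @param theta_S S phase is where the DNA-synthesis slope exceeds
#'   `theta_S` times the maximum synthesis rate of the run.
#' @param theta_M_frac the G2/M cascade time is when active nuclear
#'   cycB/Cdk1 crosses `theta_M_frac` times its peak.
#' @param min_S_h minimum S-interval length (hours) kept after
#'   thresholding.
#' @export
phase_thresholds <- function(theta_S = 0.01, theta_M_frac = 0.1,
                             min_S_h = 1)
  list(theta_S = theta_S, theta_M_frac = theta_M_frac, min_S_h = min_S_h)

#' Detect cell-cycle phases in a trajectory
#'
#' @param traj a `Trajectory` from [simulate_model()] of a model carrying
#'   `phase_states` (DNA nucleotide state and active nuclear cycB/Cdk1
#'   state).
#' @param thresholds a [phase_thresholds()] list.
#' @return a `PhaseTimeline`: data.frame with columns `phase`
#'   (G0/G1/S/G2/M), `start`, `end` (seconds), contiguous and
#'   non-overlapping, with attributes `divisions` (times), `cascades`
#'   (G2/M cascade times) and `s_intervals`.
#' @export
detect_phases <- function(traj, thresholds = phase_thresholds()) {
  stopifnot(inherits(traj, "Trajectory"))
  ps <- traj$model$phase_states
  if (is.null(ps)) stop("model carries no phase_states declaration")
  tt <- traj$times
  n <- length(tt)
  dna <- traj$amounts[ps$dna, ]
  cycb <- traj$amounts[ps$cycb_active, ]

  ## S phase: maximal intervals of high DNA-synthesis slope --------------
  slope <- c(diff(dna) / diff(tt), 0)
  # division drops are not synthesis
  slope[slope < 0] <- 0
  smax <- max(slope)
  in_s <- if (smax > 0) slope > thresholds$theta_S * smax else
    rep(FALSE, n)
  rl <- rle(in_s)
  ends <- cumsum(rl$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  s_int <- cbind(start = tt[starts[rl$values]], end = tt[ends[rl$values]])
  if (nrow(s_int))
    s_int <- s_int[(s_int[, 2] - s_int[, 1]) >=
                     thresholds$min_S_h * 3600, , drop = FALSE]

  divisions <- traj$event_log$time[traj$event_log$kind == "division"]
  onset <- traj$event_log$time[traj$event_log$kind == "stimulus" &
                                 grepl("mitogen=[^0]", traj$event_log$detail)]
  onset <- if (length(onset)) min(onset) else NA_real_

  ## G2/M cascade: upward crossings of the cycB/Cdk1 threshold ------------
  thr <- thresholds$theta_M_frac * max(cycb)
  up <- which(cycb[-1] >= thr & cycb[-n] < thr)
  cascades <- tt[up + 1]

  ## assemble contiguous timeline ----------------------------------------
  rows <- list()
  push <- function(phase, a, b) {
    if (b > a)
      rows[[length(rows) + 1L]] <<- data.frame(phase = phase, start = a,
                                               end = b,
                                               stringsAsFactors = FALSE)
  }
  cur <- tt[1]
  if (!is.na(onset) && onset > cur) {
    push("G0", cur, onset)
    cur <- onset
  }
  bounds <- sort(c(divisions, tt[n]))
  for (dv in bounds) {
    if (dv <= cur) next
    ss <- s_int[s_int[, 1] >= cur & s_int[, 1] < dv, , drop = FALSE]
    if (nrow(ss)) {
      s0 <- ss[1, 1]; s1 <- min(ss[nrow(ss), 2], dv)
      push("G1", cur, s0)
      push("S", s0, s1)
      casc <- cascades[cascades > s1 & cascades <= dv]
      if (length(casc) && dv %in% divisions) {
        push("G2", s1, casc[1])
        push("M", casc[1], dv)
      } else {
        push("G2", s1, dv)   # open interval: no cascade/division seen
      }
    } else {
      push("G1", cur, dv)    # no replication in this span
    }
    cur <- dv
  }
  tl <- if (length(rows)) do.call(rbind, rows) else
    data.frame(phase = character(), start = numeric(), end = numeric(),
               stringsAsFactors = FALSE)
  structure(tl, class = c("PhaseTimeline", "data.frame"),
            divisions = divisions, cascades = cascades,
            s_intervals = s_int, mitogen_onset = onset,
            t_end = tt[n])
}

#' Summary statistics of a phase timeline
#'
#' @param tl a `PhaseTimeline`.
#' @return list with elements `first_g1_h`, `g1_h` (mean over cycles after
#'   the first), `s_first_h`, `s_h`, `first_g2_h`, `g2_h`, `m_h`,
#'   `first_division_d`, `period_d` (mean inter-division interval after
#'   the first division), `n_divisions`.
#' @export
phase_summary <- function(tl) {
  stopifnot(inherits(tl, "PhaseTimeline"))
  dur_h <- (tl$end - tl$start) / 3600
  by_phase <- function(p) dur_h[tl$phase == p]
  complete_m <- tl$phase == "M" & tl$end %in% attr(tl, "divisions")
  divs <- attr(tl, "divisions")
  g1 <- by_phase("G1"); s <- by_phase("S"); g2 <- by_phase("G2")
  # drop a trailing open interval (run ended mid-phase)
  open_end <- !(tl$end %in% c(divs, tl$start)) & tl$end == attr(tl, "t_end")
  g1_closed <- dur_h[tl$phase == "G1" & !open_end]
  g2_closed <- dur_h[tl$phase == "G2" & !open_end]
  s_closed <- dur_h[tl$phase == "S" & !open_end]
  list(
    first_g1_h = if (length(g1_closed)) g1_closed[1] else NA_real_,
    g1_h = if (length(g1_closed) > 1) mean(g1_closed[-1]) else NA_real_,
    s_first_h = if (length(s_closed)) s_closed[1] else NA_real_,
    s_h = if (length(s_closed) > 1) mean(s_closed[-1]) else
      if (length(s_closed)) s_closed[1] else NA_real_,
    first_g2_h = if (length(g2_closed)) g2_closed[1] else NA_real_,
    g2_h = if (length(g2_closed) > 1) mean(g2_closed[-1]) else NA_real_,
    m_h = if (any(complete_m)) mean(dur_h[complete_m]) else NA_real_,
    first_division_d = if (length(divs)) divs[1] / 86400 else NA_real_,
    period_d = if (length(divs) > 1) mean(diff(divs)) / 86400 else NA_real_,
    n_divisions = length(divs))
}

#' @export
print.PhaseTimeline <- function(x, ...) {
  cat(sprintf("<PhaseTimeline: %d intervals, %d divisions>\n",
              nrow(x), length(attr(x, "divisions"))))
  df <- as.data.frame(x)
  df$start_d <- round(df$start / 86400, 3)
  df$end_d <- round(df$end / 86400, 3)
  df$hours <- round((df$end - df$start) / 3600, 2)
  print(df[, c("phase", "start_d", "end_d", "hours")])
  invisible(x)
}

#' Export a phase timeline as an interval table
#' @param tl a `PhaseTimeline`.
#' @param file optional path; written as TSV (phase, start_s, end_s) when
#'   given.
#' @return the interval data.frame, invisibly when written.
#' @export
timeline_table <- function(tl, file = NULL) {
  df <- data.frame(phase = tl$phase, start_s = tl$start, end_s = tl$end)
  if (!is.null(file)) {
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Export a trajectory in tidy long format
#' @param traj a `Trajectory`.
#' @param file optional CSV path.
#' @param states subset of qualified state names (default all).
#' @return data.frame with columns time_s, construct, state, amount.
#' @export
trajectory_table <- function(traj, file = NULL,
                             states = rownames(traj$amounts)) {
  sub <- traj$amounts[states, , drop = FALSE]
  parts <- strsplit(states, ".", fixed = TRUE)
  df <- data.frame(
    time_s = rep(traj$times, each = length(states)),
    construct = rep(vapply(parts, `[[`, "", 1L), times = length(traj$times)),
    state = rep(vapply(parts, function(p) paste(p[-1], collapse = "."), ""),
                times = length(traj$times)),
    amount = as.vector(sub))
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE)
    return(invisible(df))
  }
  df
}
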