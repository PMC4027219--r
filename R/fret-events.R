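# FRET efficiency, conversion-event detection and reversible/irreversible
# classification.
#
# A "FRET conversion event" is a precipitous drop in E = I_A/(I_D + I_A) with
# a simultaneous decrease in I_A and increase in I_D. Detection uses a matched
# step filter on E (difference of means over windows straddling a short
# transition gap) with per-channel anticorrelation checks scaled to a robust
# noise estimate (MAD of frame-to-frame differences). A simultaneous drop of
# both channels below the signal floor is a donor-bleach event, not a
# conversion.

#' Event-detection configuration
#'
#' @param delta_E_min Minimum FRET drop to call a conversion (default 0.3).
#' @param max_transition_frames Maximum frames the drop may take to complete
#'   (default 3).
#' @param min_dwell_frames Minimum frames the new level must persist; also the
#'   averaging window of the step filter (default 5).
#' @param anticorr_sigmas Required size, in robust noise SDs, of the
#'   acceptor-down and donor-up channel steps (default 3).
#' @param signal_floor Total-intensity floor below which both dyes are
#'   considered dark (counts; default 10).
#' @param recovery_tol Tolerance in E for recovery to the pre-event level
#'   (default 0.15).
#' @param recovery_window_s Recovery window (s) separating reversible from
#'   irreversible events; inclusive at the boundary (default 20).
#' @param min_event_duration_s Conversions that recover faster than this are
#'   discarded as acceptor blinks (cis dark states recover in well under a
#'   second, whereas breathing excursions last seconds; default 0.5).
#' @return List of class `event_config`.
#' @export
event_config <- function(delta_E_min = 0.3, max_transition_frames = 3L,
                         min_dwell_frames = 5L, anticorr_sigmas = 3,
                         signal_floor = 10, recovery_tol = 0.15,
                         recovery_window_s = 20, min_event_duration_s = 0.5) {
  stopifnot(delta_E_min > 0, max_transition_frames >= 1,
            min_dwell_frames >= 1, anticorr_sigmas >= 0, signal_floor >= 0,
            recovery_tol > 0, min_event_duration_s >= 0)
  if (recovery_window_s < 0) stop("recovery window must be non-negative")
  structure(list(delta_E_min = delta_E_min,
                 max_transition_frames = as.integer(max_transition_frames),
                 min_dwell_frames = as.integer(min_dwell_frames),
                 anticorr_sigmas = anticorr_sigmas,
                 signal_floor = signal_floor, recovery_tol = recovery_tol,
                 recovery_window_s = recovery_window_s,
                 min_event_duration_s = min_event_duration_s),
            class = "event_config")
}

#' FRET efficiency trajectory
#'
#' Computes `E_t = I_A / (I_D + I_A)` per frame; frames whose summed intensity
#' is at or below `signal_floor` (both dyes dark) are flagged undefined (`NA`)
#' rather than divided.
#'
#' @param traj A `molecule_trajectory`.
#' @param signal_floor Total-intensity floor in counts (default 10).
#' @return A `fret_trajectory`: list with `times` and `E` (NA where
#'   undefined).
#' @export
fret_efficiency <- function(traj, signal_floor = 10) {
  if (length(traj$I_D) != length(traj$I_A) ||
      length(traj$I_D) != length(traj$times))
    stop("times, I_D and I_A must have equal length")
  tot <- traj$I_D + traj$I_A
  E <- ifelse(tot > signal_floor, traj$I_A / tot, NA_real_)
  structure(list(times = traj$times, E = E), class = "fret_trajectory")
}

# trailing rolling mean: out[i] = mean(x[(i-w+1):i]), NA for i < w
.roll_mean <- function(x, w) {
  n <- length(x)
  if (n < w) return(rep(NA_real_, n))
  cs <- cumsum(x)
  out <- rep(NA_real_, n)
  out[w:n] <- (cs[w:n] - c(0, cs[seq_len(n - w)])) / w
  out
}

# first run of >= len consecutive TRUEs in x; 0 if none
.first_run <- function(x, len) {
  if (!any(x)) return(0L)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= len)
  if (!length(hit)) return(0L)
  ends[hit[1L]] - r$lengths[hit[1L]] + 1L
}

#' Detect FRET conversion events in one trajectory
#'
#' Finds abrupt drops in the FRET efficiency using a two-sided step statistic
#' (difference of `min_dwell_frames`-frame means across a
#' `max_transition_frames` gap). A candidate is accepted as a conversion only
#' if the acceptor decrease and donor increase co-occur, each exceeding
#' `anticorr_sigmas` robust noise SDs. A sustained drop of both channels below
#' `signal_floor` is reported as a `donor_bleach` event instead, and ends the
#' conversion search. For every conversion the recovery time — the first
#' instant E returns within `recovery_tol` of its pre-event level for at least
#' `min_dwell_frames` — is recorded when it exists.
#'
#' @param traj A `molecule_trajectory`.
#' @param eff Optional precomputed [fret_efficiency()]; computed from `traj`
#'   and `cfg$signal_floor` when `NULL`.
#' @param cfg An [event_config()].
#' @return `data.frame` with columns `onset_s`, `recovery_s`, `delta_E`,
#'   `kind` (`conversion` or `donor_bleach`), ordered by onset.
#' @export
detect_conversion_events <- function(traj, eff = NULL, cfg = event_config()) {
  stopifnot(inherits(cfg, "event_config"))
  if (is.null(eff)) eff <- fret_efficiency(traj, cfg$signal_floor)
  n <- length(eff$E)
  w <- cfg$min_dwell_frames
  g <- cfg$max_transition_frames
  times <- traj$times
  events <- data.frame(onset_s = numeric(0), recovery_s = numeric(0),
                       delta_E = numeric(0), kind = character(0))

  # donor bleach: first sustained dark stretch (>= w frames) of both channels
  dark <- (traj$I_D + traj$I_A) <= cfg$signal_floor
  db_start <- .first_run(dark, w)
  nd <- if (db_start > 0L) db_start - 1L else n
  if (db_start > 0L)
    events <- rbind(events, data.frame(onset_s = times[db_start],
                                       recovery_s = NA_real_,
                                       delta_E = NA_real_,
                                       kind = "donor_bleach"))

  if (nd >= 2L * w + g) {
    E <- eff$E[seq_len(nd)]
    # carry last defined value over short blink gaps
    if (anyNA(E)) {
      idx <- which(!is.na(E))
      if (length(idx) == 0L) return(events)
      if (idx[1L] > 1L) E[seq_len(idx[1L] - 1L)] <- E[idx[1L]]
      E <- E[cummax(ifelse(is.na(E), 0L, seq_len(nd)))]
    }
    A <- traj$I_A[seq_len(nd)]
    D <- traj$I_D[seq_len(nd)]

    m_pre_E <- .roll_mean(E, w)
    m_pre_A <- .roll_mean(A, w)
    m_pre_D <- .roll_mean(D, w)
    # post-window mean ending at i + g + w, i.e. starting after the gap
    shift_post <- function(m) c(m[(w + g + 1L):nd], rep(NA_real_, w + g))
    m_post_E <- shift_post(m_pre_E)
    m_post_A <- shift_post(m_pre_A)
    m_post_D <- shift_post(m_pre_D)

    d <- m_pre_E - m_post_E
    sig_A <- stats::mad(diff(A)) / sqrt(2)
    sig_D <- stats::mad(diff(D)) / sqrt(2)
    thr_A <- cfg$anticorr_sigmas * sig_A * sqrt(2 / w)
    thr_D <- cfg$anticorr_sigmas * sig_D * sqrt(2 / w)

    cand <- which(!is.na(d) & d >= cfg$delta_E_min &
                    (m_pre_A - m_post_A) >= thr_A &
                    (m_post_D - m_pre_D) >= thr_D)
    if (length(cand)) {
      grp <- cumsum(c(1L, diff(cand) > w))
      conv <- do.call(rbind, lapply(split(cand, grp), function(ix) {
        i0 <- ix[which.max(d[ix])]
        # refine onset to the steepest single-frame drop near the candidate
        lo <- max(1L, i0 - g); hi <- min(nd - 1L, i0 + g + w - 1L)
        j <- lo + which.min(E[(lo + 1L):(hi + 1L)] - E[lo:hi]) - 1L
        onset_idx <- j + 1L
        # recovery: E back within tolerance of the pre-event level, sustained
        pre_level <- m_pre_E[i0]
        rec <- NA_real_
        if (onset_idx < nd) {
          ok <- abs(E[(onset_idx + 1L):nd] - pre_level) <= cfg$recovery_tol
          rs <- .first_run(ok, w)
          if (rs > 0L) rec <- times[onset_idx + rs]
        }
        data.frame(onset_s = times[onset_idx], recovery_s = rec,
                   delta_E = d[i0], kind = "conversion")
      }))
      # drop conversions whose recovery search crossed a later event onset
      conv <- conv[order(conv$onset_s), , drop = FALSE]
      if (nrow(conv) > 1L) {
        nxt <- c(conv$onset_s[-1L], Inf)
        conv$recovery_s[!is.na(conv$recovery_s) & conv$recovery_s > nxt] <- NA_real_
      }
      # sub-second "conversions" are acceptor blinks, not breathing
      blinkish <- !is.na(conv$recovery_s) &
        (conv$recovery_s - conv$onset_s) < cfg$min_event_duration_s
      events <- rbind(events, conv[!blinkish, , drop = FALSE])
    }
  }
  events <- events[order(events$onset_s), , drop = FALSE]
  rownames(events) <- NULL
  events
}

#' Classify conversion events as reversible or irreversible
#'
#' A conversion that recovers to its pre-event FRET level within
#' `recovery_window_s` of its onset (inclusive) is `reversible` — attributed
#' to long-lived local DNA breathing; one that never recovers within the
#' observation window, or recovers later, is `irreversible` — attributed to
#' acceptor photobleaching. Donor-bleach events are labeled `unclassified`.
#'
#' @param events Event table from [detect_conversion_events()], time-ordered.
#' @param recovery_window_s Recovery window in seconds (default 20).
#' @return The event table with an added `label` column.
#' @export
classify_events <- function(events, recovery_window_s = 20) {
  if (recovery_window_s < 0) stop("recovery window must be non-negative")
  if (nrow(events) == 0L) {
    events$label <- character(0)
    return(events)
  }
  lab <- rep("unclassified", nrow(events))
  is_conv <- events$kind == "conversion"
  rec <- !is.na(events$recovery_s) &
    (events$recovery_s - events$onset_s) <= recovery_window_s + 1e-9
  lab[is_conv & rec] <- "reversible"
  lab[is_conv & !rec] <- "irreversible"
  events$label <- lab
  events
}

#' Field-level conversion-event summary
#'
#' Per experiment, computes the percentage of molecules exhibiting at least
#' one irreversible conversion and at least one reversible-only history; a
#' molecule with both classes counts once, as irreversible (photobleaching
#' terminates its observation), so total = irreversible + reversible exactly.
#' Reported values are means across experiments with their standard
#' deviations; with a single experiment the SDs are `NA`.
#'
#' @param events_by_molecule List of classified event tables (one per
#'   molecule, from [classify_events()]).
#' @param experiment_ids Optional vector (length = number of molecules)
#'   grouping molecules into experiments; default: one experiment.
#' @return Object of class `field_event_summary` with fields `n_molecules`,
#'   `n_experiments`, `pct_total`, `pct_irreversible`, `pct_reversible`,
#'   `sd_total`, `sd_irreversible`, `sd_reversible` and the per-experiment
#'   table.
#' @export
summarize_field <- function(events_by_molecule, experiment_ids = NULL) {
  n <- length(events_by_molecule)
  if (n == 0L) stop("empty molecule set")
  if (is.null(experiment_ids)) experiment_ids <- rep("exp1", n)
  stopifnot(length(experiment_ids) == n)

  has_irr <- vapply(events_by_molecule, function(ev)
    nrow(ev) > 0L && any(ev$kind == "conversion" & ev$label == "irreversible"),
    logical(1L))
  has_rev <- vapply(events_by_molecule, function(ev)
    nrow(ev) > 0L && any(ev$kind == "conversion" & ev$label == "reversible"),
    logical(1L))
  rev_only <- has_rev & !has_irr   # tie-break: irreversible wins

  per_exp <- do.call(rbind, lapply(split(seq_len(n), experiment_ids), function(ix) {
    data.frame(
      n_molecules = length(ix),
      pct_irreversible = 100 * mean(has_irr[ix]),
      pct_reversible = 100 * mean(rev_only[ix])
    )
  }))
  per_exp$pct_total <- per_exp$pct_irreversible + per_exp$pct_reversible
  per_exp <- cbind(experiment = rownames(per_exp), per_exp)
  rownames(per_exp) <- NULL

  n_exp <- nrow(per_exp)
  sd_or_na <- function(x) if (n_exp > 1L) stats::sd(x) else NA_real_
  structure(list(
    n_molecules = n, n_experiments = n_exp,
    pct_total = mean(per_exp$pct_total),
    pct_irreversible = mean(per_exp$pct_irreversible),
    pct_reversible = mean(per_exp$pct_reversible),
    sd_total = sd_or_na(per_exp$pct_total),
    sd_irreversible = sd_or_na(per_exp$pct_irreversible),
    sd_reversible = sd_or_na(per_exp$pct_reversible),
    per_experiment = per_exp
  ), class = "field_event_summary")
}

#' @export
print.field_event_summary <- function(x, ...) {
  cat(sprintf("<field_event_summary> %d molecules in %d experiment(s)\n",
              x$n_molecules, x$n_experiments))
  fmt <- function(m, s) if (is.na(s)) sprintf("%.1f%%", m)
    else sprintf("%.1f%% (SD %.2f)", m, s)
  cat("  total conversions:  ", fmt(x$pct_total, x$sd_total), "\n")
  cat("  irreversible:       ", fmt(x$pct_irreversible, x$sd_irreversible), "\n")
  cat("  reversible:         ", fmt(x$pct_reversible, x$sd_reversible), "\n")
  invisible(x)
}

#' Detect and classify events for a whole field
#'
#' Convenience wrapper: runs [detect_conversion_events()] and
#' [classify_events()] over a list of trajectories.
#'
#' @param trajs List of `molecule_trajectory` objects.
#' @param cfg An [event_config()].
#' @return Named list of classified event tables.
#' @export
classify_field_events <- function(trajs, cfg = event_config()) {
  lapply(trajs, function(tr)
    classify_events(detect_conversion_events(tr, cfg = cfg),
                    recovery_window_s = cfg$recovery_window_s))
}
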