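# Trajectory simulation: frame-level aggregation of the photophysics scheme.
# Bleach and blink hazards are per-second rates derived analytically from the
# per-cycle probabilities (k_eff, k_dark); event times are drawn as
# exponential/telegraph dwell sequences in continuous time and rasterized to
# the frame grid. Simulating the ~10^3-10^4 excitation cycles per frame
# individually would change nothing observable at 100-ms frames.

# continuous-time two-state telegraph: returns matrix of [on, off) intervals
# spent in state B (the "excursion"/"dark" state), starting in state A.
.telegraph_intervals <- function(rate_ab, rate_ba, duration) {
  if (rate_ab <= 0 || duration <= 0)
    return(matrix(numeric(0), ncol = 2L))
  t <- 0
  on <- numeric(0); off <- numeric(0)
  repeat {
    t <- t + stats::rexp(1L, rate_ab)
    if (t >= duration) break
    t_on <- t
    dwell <- if (rate_ba > 0) stats::rexp(1L, rate_ba) else Inf
    t <- t_on + dwell
    on <- c(on, t_on); off <- c(off, min(t, duration))
    if (t >= duration) break
  }
  cbind(on = on, off = off)
}

# state of a telegraph process on the frame grid (TRUE while in state B)
.rasterize_intervals <- function(intervals, times) {
  state <- logical(length(times))
  if (nrow(intervals) == 0L) return(state)
  for (i in seq_len(nrow(intervals)))
    state <- state | (times >= intervals[i, 1L] & times < intervals[i, 2L])
  state
}

#' Simulate one donor/acceptor trajectory
#'
#' Generates a two-channel intensity trajectory for a single surface-tethered
#' donor-acceptor pair. Acceptor photobleaching converts the pair permanently
#' from high to low FRET (acceptor falls to background, donor rises); donor
#' photobleaching drops both channels to background; cis blinking produces
#' transient dark frames in one channel; DNA-breathing excursions reversibly
#' move the FRET efficiency from `E_closed` toward `E_open`. All injected
#' events are recorded in the `truth` annotation table.
#'
#' @param donor,acceptor [photophysics_params()] for the two dyes (after any
#'   power scaling).
#' @param breathing [breathing_params()].
#' @param field [field_spec()] (only `dt` and `duration` are used; power
#'   scaling is applied by the caller, e.g. [simulate_field()]).
#' @param noise_model One of `"none"`, `"poisson"`, `"poisson_emgain"`.
#'   `"poisson"` applies shot noise to per-frame photon counts;
#'   `"poisson_emgain"` additionally applies the ~2x excess noise of
#'   electron-multiplying registers as a unit-mean gamma multiplier.
#' @param background Mean background counts per frame and channel (default 0).
#'
#' @return A `molecule_trajectory`: list with `times` (s), `I_D`, `I_A`
#'   (counts per frame) and `truth`, a data.frame with columns `kind`
#'   (`acceptor_bleach`, `donor_bleach`, `breathing_excursion`, `blink`),
#'   `onset_s`, `recovery_s` (NA when permanent).
#' @export
simulate_pair <- function(donor, acceptor, breathing, field,
                          noise_model = c("none", "poisson", "poisson_emgain"),
                          background = 0) {
  stopifnot(inherits(donor, "photophysics_params"),
            inherits(acceptor, "photophysics_params"),
            inherits(breathing, "breathing_params"),
            inherits(field, "field_spec"))
  noise_model <- match.arg(noise_model)
  dt <- field$dt; duration <- field$duration
  n_frames <- as.integer(round(duration / dt))
  if (n_frames < 1L) stop("duration shorter than one frame")
  times <- (seq_len(n_frames) - 1L) * dt

  k_D <- k_eff(donor); k_A <- k_eff(acceptor)
  if (!is.finite(k_D) || !is.finite(k_A)) stop("non-finite bleach hazard")
  T_D <- if (k_D > 0) stats::rexp(1L, k_D) else Inf
  T_A <- if (k_A > 0) stats::rexp(1L, k_A) else Inf

  dark_D <- .telegraph_intervals(k_dark(donor), donor$dark_recovery_rate, duration)
  dark_A <- .telegraph_intervals(k_dark(acceptor), acceptor$dark_recovery_rate, duration)
  open_iv <- .telegraph_intervals(breathing$open_rate, breathing$close_rate, duration)

  don_alive <- times < T_D
  acc_alive <- times < T_A
  don_dark <- .rasterize_intervals(dark_D, times)
  acc_dark <- .rasterize_intervals(dark_A, times)
  open_state <- .rasterize_intervals(open_iv, times)

  E <- ifelse(open_state, breathing$E_open, breathing$E_closed)
  I_tot <- donor$excitation_rate * dt * donor$quantum_yield_bright
  don_on <- don_alive & !don_dark
  acc_on <- acc_alive & !acc_dark
  I_A <- ifelse(don_on & acc_on, E * I_tot, 0)
  I_D <- ifelse(don_on, ifelse(acc_on, 1 - E, 1) * I_tot, 0)
  I_A <- I_A + background
  I_D <- I_D + background

  if (noise_model != "none") {
    I_A <- stats::rpois(n_frames, I_A)
    I_D <- stats::rpois(n_frames, I_D)
    if (noise_model == "poisson_emgain") {
      # EM register: each photoelectron amplified with exponential gain spread;
      # output ~ Gamma(shape = counts, scale = 1), variance twice the mean.
      I_A <- ifelse(I_A > 0, stats::rgamma(n_frames, shape = I_A, rate = 1), 0)
      I_D <- ifelse(I_D > 0, stats::rgamma(n_frames, shape = I_D, rate = 1), 0)
    }
  }

  truth <- .empty_truth()
  horizon <- min(T_D, duration)
  if (T_A < horizon)
    truth <- rbind(truth, data.frame(kind = "acceptor_bleach", onset_s = T_A,
                                     recovery_s = NA_real_))
  if (T_D < duration)
    truth <- rbind(truth, data.frame(kind = "donor_bleach", onset_s = T_D,
                                     recovery_s = NA_real_))
  add_iv <- function(truth, iv, kind, limit) {
    if (nrow(iv) == 0L) return(truth)
    keep <- iv[, 1L] < limit
    if (!any(keep)) return(truth)
    rbind(truth, data.frame(kind = kind, onset_s = iv[keep, 1L],
                            recovery_s = pmin(iv[keep, 2L], limit)))
  }
  truth <- add_iv(truth, open_iv, "breathing_excursion", min(T_A, horizon))
  truth <- add_iv(truth, dark_A, "blink", min(T_A, horizon))
  truth <- add_iv(truth, dark_D, "blink", horizon)
  truth <- truth[order(truth$onset_s), , drop = FALSE]
  rownames(truth) <- NULL

  structure(list(times = times, I_D = I_D, I_A = I_A, truth = truth),
            class = "molecule_trajectory")
}

.empty_truth <- function() {
  data.frame(kind = character(0), onset_s = numeric(0), recovery_s = numeric(0))
}

#' Simulate a field of molecules from a construct preset
#'
#' Draws `field$n_molecules` i.i.d. trajectories from the preset's calibrated
#' parameters (see [construct_preset()]); `field$power_scale` rescales the
#' excitation rate of both dyes before simulation, so the ensemble bleach
#' hazard scales linearly with laser power.
#'
#' @param field A [field_spec()].
#' @param preset A preset label accepted by [construct_preset()], or
#'   `"custom"`, in which case `params` must supply `donor`, `acceptor` and
#'   `breathing`.
#' @param noise_model Passed to [simulate_pair()].
#' @param params Optional custom parameter list (for `preset = "custom"`).
#' @param background Passed to [simulate_pair()].
#' @return A list of `molecule_trajectory` objects, one per molecule, with the
#'   simulation settings attached as attribute `"manifest"`.
#' @export
simulate_field <- function(field, preset = "iCy3/iCy5-duplex",
                           noise_model = "poisson", params = NULL,
                           background = 0) {
  stopifnot(inherits(field, "field_spec"))
  if (identical(preset, "custom")) {
    if (is.null(params)) stop("preset 'custom' requires a params list")
  } else {
    params <- construct_preset(preset)
  }
  if (!is.null(field$seed)) set.seed(field$seed)
  donor <- scale_power(params$donor, field$power_scale)
  acceptor <- scale_power(params$acceptor, field$power_scale)
  trajs <- vector("list", field$n_molecules)
  for (i in seq_len(field$n_molecules))
    trajs[[i]] <- simulate_pair(donor, acceptor, params$breathing, field,
                                noise_model = noise_model,
                                background = background)
  names(trajs) <- sprintf("mol%04d", seq_len(field$n_molecules))
  attr(trajs, "manifest") <- list(preset = preset, field = unclass(field),
                                  noise_model = noise_model)
  trajs
}

#' Draw i.i.d. exponential photobleach times
#'
#' Ensemble-level shortcut used by the survival analysis: bleach times under
#' the frame-level simulator are exponential with hazard [k_eff()] by
#' construction, so for survival-curve studies the times can be drawn
#' directly without rendering intensity frames.
#'
#' @param n Number of molecules.
#' @param rate_per_min Bleach hazard in min^-1 (e.g. `60 * k_eff(params)`).
#' @return Numeric vector of bleach times in minutes.
#' @export
simulate_bleach_times <- function(n, rate_per_min) {
  stopifnot(n >= 1, is.finite(rate_per_min), rate_per_min > 0)
  stats::rexp(n, rate_per_min)
}

#' Simulate a cohort with injected conversion events
#'
#' Generates trajectories at a fixed signal-to-noise ratio in which a chosen
#' fraction of molecules receives one irreversible conversion (acceptor
#' bleach at a uniformly drawn time) and a disjoint fraction one reversible
#' breathing excursion of fixed dwell. Used to measure detector sensitivity,
#' specificity and field-level event percentages against known truth.
#'
#' Event onsets are drawn uniformly over `[5, duration - 10]` s (irreversible)
#' and `[5, duration - rev_dwell_s - 10]` s (reversible) so every injected
#' event is in principle classifiable within the acquisition window.
#'
#' @param n Number of molecules.
#' @param frac_irreversible,frac_reversible Fractions of molecules receiving
#'   each event class; applied as exact disjoint counts (`round(n * frac)`).
#' @param dt,duration Frame interval and acquisition length (s).
#' @param snr Per-frame signal-to-noise ratio of the summed intensity under
#'   Poisson noise; total intensity is `snr^2` counts/frame.
#' @param E_closed Baseline FRET efficiency.
#' @param delta_E Drop magnitude of injected events.
#' @param rev_dwell_s Dwell of reversible excursions (s; default 4).
#' @param noise `TRUE` for Poisson shot noise.
#' @return List of `molecule_trajectory` objects; attribute `"injected"` is a
#'   data.frame (`molecule`, `class`) with class `irreversible`, `reversible`
#'   or `none`.
#' @export
simulate_conversion_cohort <- function(n, frac_irreversible, frac_reversible,
                                       dt = 0.1, duration = 120, snr = 10,
                                       E_closed = 0.75, delta_E = 0.5,
                                       rev_dwell_s = 4, noise = TRUE) {
  stopifnot(n >= 1, frac_irreversible >= 0, frac_reversible >= 0,
            frac_irreversible + frac_reversible <= 1, snr > 0,
            delta_E > 0, E_closed - delta_E >= 0)
  n_irr <- round(n * frac_irreversible)
  n_rev <- round(n * frac_reversible)
  picks <- sample.int(n, n_irr + n_rev)
  class <- rep("none", n)
  class[picks[seq_len(n_irr)]] <- "irreversible"
  if (n_rev > 0) class[picks[n_irr + seq_len(n_rev)]] <- "reversible"

  n_frames <- as.integer(round(duration / dt))
  times <- (seq_len(n_frames) - 1L) * dt
  I_tot <- snr^2
  E_low <- E_closed - delta_E

  trajs <- vector("list", n)
  for (i in seq_len(n)) {
    E <- rep(E_closed, n_frames)
    acc_on <- rep(TRUE, n_frames)
    truth <- .empty_truth()
    if (class[i] == "irreversible") {
      onset <- stats::runif(1L, 5, duration - 10)
      acc_on <- times < onset
      truth <- data.frame(kind = "acceptor_bleach", onset_s = onset,
                          recovery_s = NA_real_)
    } else if (class[i] == "reversible") {
      onset <- stats::runif(1L, 5, duration - rev_dwell_s - 10)
      open <- times >= onset & times < onset + rev_dwell_s
      E[open] <- E_low
      truth <- data.frame(kind = "breathing_excursion", onset_s = onset,
                          recovery_s = onset + rev_dwell_s)
    }
    I_A <- ifelse(acc_on, E * I_tot, 0)
    I_D <- ifelse(acc_on, (1 - E) * I_tot, I_tot)
    if (noise) {
      I_A <- stats::rpois(n_frames, I_A)
      I_D <- stats::rpois(n_frames, I_D)
    }
    trajs[[i]] <- structure(
      list(times = times, I_D = I_D, I_A = I_A, truth = truth),
      class = "molecule_trajectory")
  }
  names(trajs) <- sprintf("mol%05d", seq_len(n))
  attr(trajs, "injected") <- data.frame(molecule = names(trajs), class = class)
  trajs
}

#' @export
print.molecule_trajectory <- function(x, ...) {
  cat(sprintf("<molecule_trajectory> %d frames, dt = %g s, %d truth event(s)\n",
              length(x$times), if (length(x$times) > 1L) x$times[2L] - x$times[1L] else NA,
              nrow(x$truth)))
  invisible(x)
}
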