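# Photobleach survival analysis: active FRET-pair counts vs illumination time
# and single-exponential decay fitting (tau_B, k_B = 1/tau_B,
# t_1/2 = tau_B ln 2), plus the log-linear slope fit of log10(counts) vs time.

#' Count active FRET pairs over time
#'
#' Builds a survival curve of the number of molecules still "active" at each
#' time bin. Activity is defined at the molecule level: under
#' `rule = "acceptor_alive"` a pair is active until its first irreversible
#' conversion (acceptor bleach) or donor bleach; under `rule = "donor_alive"`
#' only donor bleach ends activity. Reversible events and blinking gaps do
#' not terminate activity.
#'
#' @param x Either a numeric vector of per-molecule death times in minutes
#'   (molecules that never die: `Inf`), or a list of classified event tables
#'   (from [classify_field_events()]; onsets in seconds).
#' @param duration_min Curve extent in minutes (required for numeric input;
#'   for event-table input defaults to the maximum death time observed).
#' @param bin_width_min Bin width in minutes (default 1/6, i.e. 10 s).
#' @param rule Activity rule (see above).
#' @param power_label Optional label (e.g. `"22 mW"`) carried on the curve.
#' @return A `survival_curve`: data.frame with `time_min` (bin centers) and
#'   `count`, plus attributes `bin_width_min` and `power_label`.
#' @export
count_active_pairs <- function(x, duration_min = NULL, bin_width_min = 1 / 6,
                               rule = c("acceptor_alive", "donor_alive"),
                               power_label = NA_character_) {
  rule <- match.arg(rule)
  if (is.list(x)) {
    if (length(x) == 0L) stop("empty input")
    death <- vapply(x, function(ev) {
      if (nrow(ev) == 0L) return(Inf)
      kill <- ev$kind == "donor_bleach"
      if (rule == "acceptor_alive")
        kill <- kill | (ev$kind == "conversion" & ev$label == "irreversible")
      if (!any(kill)) Inf else min(ev$onset_s[kill]) / 60
    }, numeric(1L))
  } else {
    death <- as.numeric(x)
    if (length(death) == 0L) stop("empty input")
  }
  if (is.null(duration_min)) {
    duration_min <- if (any(is.finite(death))) max(death[is.finite(death)])
      else stop("duration_min required when no molecule dies")
  }
  centers <- seq(bin_width_min / 2, duration_min, by = bin_width_min)
  counts <- vapply(centers, function(t) sum(death > t), numeric(1L))
  out <- data.frame(time_min = centers, count = counts)
  attr(out, "bin_width_min") <- bin_width_min
  attr(out, "power_label") <- power_label
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Fit a single-exponential photobleach decay
#'
#' Nonlinear least squares of `N(t) = N0 * exp(-t / tau_B)` to a survival
#' curve, initialized at `N0 =` first-bin count and `tau =` half the last
#' time. Also returns the independently fitted ordinary-least-squares slope
#' of `log10(count)` vs time over bins with `count >= 1` (log of zero is
#' undefined), with its standard error and R^2 — the two fit styles used to
#' characterize photobleach decays. Optionally weights the exponential fit by
#' `1/N` (Poisson counting weights).
#'
#' @param curve A `survival_curve` (or data.frame with `time_min`, `count`).
#' @param poisson_weights Use weights `1/max(count, 1)` in the exponential
#'   fit (default FALSE).
#' @return A `decay_fit`: list with `tau_B` (min), `k_B` (min^-1), `t_half`
#'   (min), `n0`, `log_slope` (min^-1), `sd_slope`, `r_squared` (of the log
#'   fit) and `power_label`.
#' @export
fit_exponential <- function(curve, poisson_weights = FALSE) {
  t <- curve$time_min
  N <- curve$count
  pos <- which(N > 0)
  if (length(pos) < 5L)
    stop("need at least 5 bins with positive counts")
  if (all(N == 0) || N[length(N)] >= N[1L])
    stop("curve does not decay; exponential fit not identifiable")
  dat <- data.frame(t = t, N = N)
  wts <- if (poisson_weights) 1 / pmax(N, 1) else rep(1, length(N))
  fit <- tryCatch(
    stats::nls(N ~ N0 * exp(-t / tau), data = dat,
               start = list(N0 = N[1L], tau = max(t) / 2), weights = wts,
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e)
      minpack.lm::nlsLM(N ~ N0 * exp(-t / tau), data = dat,
                        start = list(N0 = N[1L], tau = max(t) / 2),
                        weights = wts)
  )
  cf <- stats::coef(fit)
  tau <- unname(cf[["tau"]])
  if (!is.finite(tau) || tau <= 0)
    stop("exponential fit did not converge to a positive time constant")

  logfit <- stats::lm(log10(N) ~ t, data = dat[pos, , drop = FALSE])
  sm <- suppressWarnings(summary(logfit))   # noiseless input: perfect fit
  structure(list(
    tau_B = tau, k_B = 1 / tau, t_half = tau * log(2),
    n0 = unname(cf[["N0"]]),
    log_slope = unname(stats::coef(logfit)[["t"]]),
    sd_slope = unname(sm$coefficients["t", "Std. Error"]),
    r_squared = sm$r.squared,
    power_label = attr(curve, "power_label")
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit>\n")
  cat(sprintf("  tau_B = %.4g min   k_B = %.4g min^-1   t_1/2 = %.4g min\n",
              x$tau_B, x$k_B, x$t_half))
  cat(sprintf("  log10 fit: slope = %.4g min^-1 (SD %.2g), R^2 = %.4f\n",
              x$log_slope, x$sd_slope, x$r_squared))
  invisible(x)
}

#' Compare photobleach fits across laser powers
#'
#' Orders fits by laser power and reports time-constant ratios relative to
#' the highest power, flagging whether `tau_B` increases monotonically as
#' power decreases (the expected photo-stability gain at reduced excitation).
#'
#' @param fits List of `decay_fit` objects.
#' @param power_mw Numeric laser powers (mW), one per fit; duplicates are an
#'   error.
#' @return List with `table` (data.frame sorted by decreasing power:
#'   `power_mw`, `tau_B`, `k_B`, `t_half`, `tau_ratio`), `monotone` (logical)
#'   and `ties` (logical).
#' @export
compare_power_series <- function(fits, power_mw) {
  if (length(fits) < 2L) stop("need at least 2 fits to compare")
  stopifnot(length(power_mw) == length(fits))
  if (anyDuplicated(power_mw)) stop("duplicate power labels")
  ord <- order(power_mw, decreasing = TRUE)
  tab <- data.frame(
    power_mw = power_mw[ord],
    tau_B = vapply(fits[ord], `[[`, numeric(1L), "tau_B"),
    k_B = vapply(fits[ord], `[[`, numeric(1L), "k_B"),
    t_half = vapply(fits[ord], `[[`, numeric(1L), "t_half")
  )
  tab$tau_ratio <- tab$tau_B / tab$tau_B[1L]
  ties <- any(diff(tab$tau_B) == 0)
  monotone <- all(diff(tab$tau_B) > 0)
  list(table = tab, monotone = monotone, ties = ties)
}
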