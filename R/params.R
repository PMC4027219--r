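#' Photophysical parameter set for one cyanine dye
#'
#' Parameterizes a coarse-grained kinetic scheme for a polymethine (cyanine)
#' chromophore: excitation cycles drive photoisomerization to a twisted
#' intermediate, which branches either back to the bright all-trans ground
#' state, to a non-fluorescent cis ground state (blinking), or via intersystem
#' crossing to the triplet T1 from which irreversible photodegradation occurs.
#' Per-cycle probabilities are aggregated analytically into per-second hazards
#' (see [k_eff()]); cycle-level dynamics (microseconds) are never simulated.
#'
#' @param excitation_rate Expected excitation cycles per second at the
#'   reference laser power (s^-1).
#' @param p_isomerize Probability per excitation cycle of reaching the twisted
#'   intermediate (0-1).
#' @param rigidity Multiplicative suppression factor on `p_isomerize`
#'   (dimensionless, >= 0). 1 corresponds to the externally labeled reference;
#'   rigid internal insertion into the duplex backbone gives values < 1.
#' @param p_isc Probability of intersystem crossing to T1 given the twisted
#'   intermediate (0-1).
#' @param p_bleach_T1 Probability of irreversible photodegradation per T1
#'   visit (0-1).
#' @param p_cis Branching fraction twisted -> cis dark state (0-1).
#' @param dark_recovery_rate Thermal cis -> trans recovery rate (s^-1);
#'   the default 20 (50 ms dark states) reflects blinking suppressed by
#'   triplet-quencher/oxygen-scavenger buffers.
#' @param quantum_yield_bright Mean detected photons per excitation cycle in
#'   the bright state (dimensionless).
#'
#' @return An object of class `photophysics_params`.
#' @export
photophysics_params <- function(excitation_rate = 1e4,
                                p_isomerize = 3.617e-3,
                                rigidity = 1,
                                p_isc = 0.1,
                                p_bleach_T1 = 1e-3,
                                p_cis = 1e-4,
                                dark_recovery_rate = 20,
                                quantum_yield_bright = 0.4) {
  stopifnot(
    is.numeric(excitation_rate), length(excitation_rate) == 1L,
    is.finite(excitation_rate), excitation_rate >= 0,
    is.finite(rigidity), rigidity >= 0,
    is.finite(dark_recovery_rate), dark_recovery_rate >= 0,
    is.finite(quantum_yield_bright), quantum_yield_bright >= 0
  )
  for (p in list(p_isomerize = p_isomerize, p_isc = p_isc,
                 p_bleach_T1 = p_bleach_T1, p_cis = p_cis)) {
    if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
      stop("per-cycle probabilities must be single values in [0, 1]")
  }
  structure(
    list(excitation_rate = excitation_rate, p_isomerize = p_isomerize,
         rigidity = rigidity, p_isc = p_isc, p_bleach_T1 = p_bleach_T1,
         p_cis = p_cis, dark_recovery_rate = dark_recovery_rate,
         quantum_yield_bright = quantum_yield_bright),
    class = "photophysics_params"
  )
}

#' Effective photobleach hazard of a dye
#'
#' The per-second hazard of irreversible photodegradation implied by a
#' parameter set:
#' `k_eff = excitation_rate * rigidity * p_isomerize * p_isc * p_bleach_T1`.
#' Linear in `excitation_rate`, hence linear in laser power under
#' [scale_power()].
#'
#' @param params A [photophysics_params()] object.
#' @return Hazard in s^-1.
#' @export
k_eff <- function(params) {
  stopifnot(inherits(params, "photophysics_params"))
  params$excitation_rate * params$rigidity * params$p_isomerize *
    params$p_isc * params$p_bleach_T1
}

#' Dark-state (blinking) entry hazard of a dye
#'
#' Per-second hazard of entering the non-fluorescent cis state:
#' `excitation_rate * rigidity * p_isomerize * p_cis`.
#'
#' @param params A [photophysics_params()] object.
#' @return Hazard in s^-1.
#' @export
k_dark <- function(params) {
  stopifnot(inherits(params, "photophysics_params"))
  params$excitation_rate * params$rigidity * params$p_isomerize * params$p_cis
}

#' Rescale a parameter set to a different laser power
#'
#' Multiplies the excitation rate by `power_scale`, leaving all per-cycle
#' probabilities unchanged, so the effective bleach hazard scales linearly
#' with power. An optional exponent allows a sub- or super-linear power law
#' (`excitation_rate * power_scale^power_exponent`); the default is linear.
#'
#' @param params A [photophysics_params()] object.
#' @param power_scale Laser power relative to the reference (> 0), e.g.
#'   10/22 for 10 mW against a 22 mW reference.
#' @param power_exponent Exponent of the power dependence (default 1).
#' @return A rescaled `photophysics_params` object.
#' @export
scale_power <- function(params, power_scale, power_exponent = 1) {
  stopifnot(inherits(params, "photophysics_params"))
  if (!is.numeric(power_scale) || length(power_scale) != 1L ||
      !is.finite(power_scale) || power_scale <= 0)
    stop("power_scale must be a single positive number")
  params$excitation_rate <- params$excitation_rate * power_scale^power_exponent
  params
}

#' DNA-breathing parameters
#'
#' Two-state telegraph model for long-lived local duplex opening
#' ("breathing"): the construct switches between a closed conformation with
#' high FRET and an open conformation with lower FRET.
#'
#' @param open_rate Closed -> open rate (s^-1).
#' @param close_rate Open -> closed rate (s^-1). The default mean open dwell
#'   is 2 s, well inside the ~20 s recovery window used to call an excursion
#'   reversible.
#' @param E_closed FRET efficiency in the closed/native conformation (0-1).
#' @param E_open FRET efficiency in the open conformation (0-1, < `E_closed`).
#' @return An object of class `breathing_params`.
#' @export
breathing_params <- function(open_rate = 5e-4, close_rate = 0.5,
                             E_closed = 0.75, E_open = 0.25) {
  stopifnot(
    is.finite(open_rate), open_rate >= 0,
    is.finite(close_rate), close_rate >= 0,
    is.finite(E_closed), is.finite(E_open)
  )
  if (!(E_open >= 0 && E_open < E_closed && E_closed <= 1))
    stop("require 0 <= E_open < E_closed <= 1")
  structure(
    list(open_rate = open_rate, close_rate = close_rate,
         E_closed = E_closed, E_open = E_open),
    class = "breathing_params"
  )
}

#' Acquisition field specification
#'
#' Describes one imaging field: number of surface-tethered molecules, frame
#' interval, acquisition length, laser power relative to the 22 mW reference,
#' and RNG seed. Defaults mirror a typical run: 100-ms frames for 120 s with
#' ~400 donor/acceptor features per field.
#'
#' @param n_molecules Number of molecules (>= 1).
#' @param dt Frame interval in seconds (> 0; default 0.1).
#' @param duration Acquisition length in seconds (>= dt; default 120).
#' @param power_scale Excitation multiplier relative to the 22 mW reference.
#' @param seed Optional RNG seed; `NULL` uses the current RNG state.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(n_molecules = 400, dt = 0.1, duration = 120,
                       power_scale = 1, seed = NULL) {
  stopifnot(
    is.numeric(n_molecules), length(n_molecules) == 1L, n_molecules >= 1,
    is.numeric(dt), dt > 0, is.finite(dt),
    is.numeric(duration), is.finite(duration),
    is.numeric(power_scale), power_scale > 0
  )
  if (duration < dt) stop("duration must cover at least one frame")
  structure(
    list(n_molecules = as.integer(n_molecules), dt = dt, duration = duration,
         power_scale = power_scale, seed = seed),
    class = "field_spec"
  )
}

# Construct presets. Pair bleach hazard (acceptor + donor) reproduces the
# measured 22 mW photobleach rate constants; rigidity is expressed relative to
# the externally labeled duplex (rigidity 1), giving the ordering
# internal duplex < fork < p/t end < external. acceptor_share fixes how much
# of the pair hazard is carried by the acceptor (visible as an irreversible
# FRET conversion rather than a donor-bleach drop of both channels);
# breathing open-rates set the chance of >= 1 reversible excursion in 120 s.
.presets <- list(
  "eCy3/eCy5-duplex" = list(k_pair_min = 0.217, rigidity = 1.0,
                            acceptor_share = 0.90, open_rate = 4.98e-4),
  "iCy3/iCy5-duplex" = list(k_pair_min = 0.066, rigidity = 0.066 / 0.217,
                            acceptor_share = 0.04, open_rate = 2.5e-5),
  "endCy3/iCy5-pt"   = list(k_pair_min = 0.189, rigidity = 0.189 / 0.217,
                            acceptor_share = 0.47, open_rate = 2.71e-4),
  "iCy3/iCy5-fork"   = list(k_pair_min = 0.112, rigidity = 0.112 / 0.217,
                            acceptor_share = 0.45, open_rate = 2.37e-4)
)

#' Construct preset parameter sets
#'
#' Returns donor/acceptor [photophysics_params()] and [breathing_params()]
#' calibrated so that, at `power_scale = 1` (22 mW), the ensemble pair-bleach
#' rate constant equals the measured photobleach rate for that construct
#' (0.217, 0.066, 0.189 and 0.112 min^-1 for the externally labeled duplex,
#' internally labeled duplex, primer/template end-labeled and fork-labeled
#' constructs respectively).
#'
#' @param preset One of `"eCy3/eCy5-duplex"`, `"iCy3/iCy5-duplex"`,
#'   `"endCy3/iCy5-pt"`, `"iCy3/iCy5-fork"`.
#' @return List with elements `donor`, `acceptor` (`photophysics_params`),
#'   `breathing` (`breathing_params`) and `k_pair_min` (pair hazard, min^-1).
#' @export
construct_preset <- function(preset) {
  if (!is.character(preset) || length(preset) != 1L ||
      is.na(match(preset, names(.presets))))
    stop("unknown preset; choose one of: ",
         paste(names(.presets), collapse = ", "))
  p <- .presets[[preset]]
  base <- photophysics_params(rigidity = p$rigidity)
  # split the pair hazard between the two dyes via p_bleach_T1
  k_pair_s <- p$k_pair_min / 60
  k_one <- k_eff(base)                       # hazard if share were 1
  acceptor <- base
  acceptor$p_bleach_T1 <- base$p_bleach_T1 * p$acceptor_share * k_pair_s / k_one
  donor <- base
  donor$p_bleach_T1 <- base$p_bleach_T1 * (1 - p$acceptor_share) * k_pair_s / k_one
  list(
    donor = donor, acceptor = acceptor,
    breathing = breathing_params(open_rate = p$open_rate),
    k_pair_min = p$k_pair_min
  )
}

#' @export
print.photophysics_params <- function(x, ...) {
  cat("<photophysics_params>\n")
  cat(sprintf("  excitation_rate: %g /s  rigidity: %.4g\n",
              x$excitation_rate, x$rigidity))
  cat(sprintf("  p_isomerize: %g  p_isc: %g  p_bleach_T1: %g  p_cis: %g\n",
              x$p_isomerize, x$p_isc, x$p_bleach_T1, x$p_cis))
  cat(sprintf("  dark_recovery_rate: %g /s  quantum_yield_bright: %g\n",
              x$dark_recovery_rate, x$quantum_yield_bright))
  cat(sprintf("  k_eff (bleach): %.4g /s = %.4g /min\n",
              k_eff(x), 60 * k_eff(x)))
  invisible(x)
}
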