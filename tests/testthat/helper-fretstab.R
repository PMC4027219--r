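# Shared fixtures, built in code.

# Noise-free trajectory with piecewise-constant FRET efficiency.
# segments: data.frame(from_s, E); each segment holds E from from_s onward.
# Acceptor-dark segments are encoded with E = 0 (I_A -> 0, I_D -> I_tot);
# fully dark (donor-bleached) segments with E = NA (both channels -> 0).
make_step_traj <- function(segments, dt = 0.1, duration = 120, I_tot = 200) {
  n <- round(duration / dt)
  times <- (seq_len(n) - 1) * dt
  E <- rep(segments$E[1], n)
  for (i in seq_len(nrow(segments)))
    E[times >= segments$from_s[i]] <- segments$E[i]
  I_A <- ifelse(is.na(E), 0, E * I_tot)
  I_D <- ifelse(is.na(E), 0, (1 - E) * I_tot)
  structure(list(times = times, I_D = I_D, I_A = I_A,
                 truth = data.frame(kind = character(0), onset_s = numeric(0),
                                    recovery_s = numeric(0))),
            class = "molecule_trajectory")
}

# Dominant detected class of each molecule (irreversible wins ties).
detected_class <- function(classified_events) {
  vapply(classified_events, function(e) {
    if (!nrow(e)) return("none")
    if (any(e$kind == "conversion" & e$label == "irreversible")) "irreversible"
    else if (any(e$kind == "conversion" & e$label == "reversible")) "reversible"
    else "none"
  }, character(1L))
}

# Parameter set with a single bleach channel and everything else quiet.
quiet_params <- function(k_bleach_per_min = 0) {
  p <- photophysics_params(p_cis = 0)
  if (k_bleach_per_min == 0) {
    p$p_bleach_T1 <- 0
  } else {
    p$p_bleach_T1 <- p$p_bleach_T1 * (k_bleach_per_min / 60) / k_eff(p)
  }
  p
}

no_breathing <- function() breathing_params(open_rate = 0)
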