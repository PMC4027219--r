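Package: fretstab
Title: Photo-Stability Analysis of Single-Molecule FRET Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for single-molecule FRET (smFRET)
    photo-stability experiments on Cy3/Cy5-labeled DNA constructs. Provides a
    coarse-grained photophysics simulator (photoisomerization, triplet-gated
    bleaching, cis dark-state blinking, DNA-breathing FRET modulation) that
    generates per-molecule donor/acceptor intensity trajectories; an optional
    image-level path that renders two-channel TIRF-like movies and recovers
    trajectories by spot detection, channel pairing and aperture photometry;
    detection and reversible/irreversible classification of FRET conversion
    events; single-exponential photobleach survival analysis (tau_B, k_B,
    half-life, log-linear slope); and nearest-neighbor duplex melting
    temperature prediction with salt correction, dye-insertion handling,
    melting-curve Tm extraction and delta-Tm summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
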