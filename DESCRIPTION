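Package: spikefield
Title: Spike Train, LFP Spectral, and Spike-Field Coupling Analysis for
    Motor-Cortex Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for simultaneously recorded extracellular
    single units and local field potentials (LFPs): waveform-based
    classification of broad-spiking versus narrow-spiking units,
    interspike-interval pattern metrics (CV, mode, asymmetry index),
    peri-event time histograms around reach events with a trial-paired
    modulation test, multitaper (DPSS) power spectra and relative band
    power over canonical rodent cortical bands, spike-field coherence,
    and bandpass-Hilbert spike-LFP phase locking with circular statistics
    (Rayleigh test, mean angle, vector length). Includes a synthetic
    session generator with ground truth (1/f band-structured LFP,
    inhomogeneous Poisson spike trains with von Mises phase coupling and
    movement gain) so every stage is verifiable, plus session bundle
    persistence and group-level statistics (Mann-Whitney U, two-way and
    repeated-measures ANOVA with Bonferroni correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
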