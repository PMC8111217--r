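# spikefield

Analysis of simultaneously recorded extracellular single units and local
field potentials (LFPs), of the kind collected from layer 5 of rodent
primary motor cortex (M1) during rest and skilled forelimb reaching in
dopamine-intact versus unilaterally dopamine-depleted (6-OHDA,
hemiparkinsonian) animals. The package is aimed at systems
electrophysiologists who want the full spike/LFP statistics chain —
from waveform classification to spike-field phase locking — as tested,
scriptable R functions, plus a synthetic-session generator with ground
truth so every stage can be verified at the desk.

## What it computes

* **Unit classification** — trough-to-peak duration of the spike waveform
  (time from the global trough to the following positive peak) separates
  broad-spiking (BS, putative pyramidal, ~0.42 ms) from narrow-spiking
  (NS, putative interneuron, ~0.22 ms) units at a 0.32 ms boundary, with
  a refractory criterion (< 1% of ISIs under 2 ms). Threshold-based spike
  detection on broadband traces is included for synthetic data.
* **Firing-pattern metrics** — mean rate; ISI coefficient of variation
  CV = sd(ISI)/mean(ISI); ISI-histogram mode (5 ms bins); asymmetry
  index = mode/mean ISI.
* **PETHs** — peri-event rasters and 5 ms-bin PETHs around reach events,
  smoothed with a 5-point Gaussian; baseline over [−0.6, 0) s; trial-paired
  Wilcoxon signed-rank modulation test at α = 0.05.
* **LFP spectra** — zero-phase 0.5–200 Hz Butterworth + 50 Hz notch
  preprocessing; multitaper PSD (5 DPSS tapers, NW = 3, 0.5 s windows);
  relative power in the 0.7–12 / 12–35 / 35–70 / 70–100 / 100–200 Hz
  bands; Hann STFT spectrogram.
* **Spike-field coupling** — multitaper coherence
  C(f) = |S_xy|/√(S_xx·S_yy) between the binned spike train and the LFP;
  3rd-order Butterworth + Hilbert instantaneous phase (peaks = 0°,
  troughs = 180°); Rayleigh uniformity test; mean phase angle and vector
  length R ∈ [0, 1] with a ≥ 40-spike admissibility criterion.
* **Group statistics** — Mann–Whitney U (exact by enumeration for
  n+m ≤ 12), two-way and repeated-measures ANOVA, Bonferroni correction;
  `run_pipeline()` runs a whole cohort and reports the headline
  direction-of-effect comparisons.
* **Synthetic sessions** — 1/f band-structured LFP with exact injected
  band-power fractions, inhomogeneous-Poisson spike trains with von Mises
  phase coupling (vector length I₁(κ)/I₀(κ)) and movement gain, biphasic
  waveforms, event schedules, and a ground-truth table kept separate from
  the analysis inputs.

## Worked example

Simulate one dopamine-depleted-template session (2 BS + 1 NS units,
240 s), classify the units, and measure band power and 12–35 Hz phase
locking during movement:

```r
library(spikefield)

cfg <- synth_template("lesioned", seed = 42, n_bs = 2, n_ns = 1,
                      duration_s = 240)
s   <- gen_session(cfg)
s$bundle
#> <session_bundle synth_seed42 (lesioned): 1 LFP channel(s), 3 unit(s), 38 trial(s), 240 s>

rep <- analyze_session(s$bundle)
rep$classification[, c("unit_id", "trough_to_peak_ms", "mean_rate_hz",
                       "class_label", "refractory_ok")]
#>   unit_id trough_to_peak_ms mean_rate_hz class_label refractory_ok
#> 1     u01             0.425     4.120833          BS          TRUE
#> 2     u02             0.425     4.112500          BS          TRUE
#> 3     u03             0.225     7.254167          NS          TRUE

rep$band_power[, c("band", "fraction")]
#>      band fraction
#> 1  0.7-12    0.617
#> 2   12-35    0.235
#> 3   35-70    0.067
#> 4  70-100    0.022
#> 5 100-200    0.059

subset(rep$coupling, band == "12-35" & state == "movement",
       c(unit_id, class_label, n_spikes, vector_length, rayleigh_p, locked))
#>    unit_id class_label n_spikes vector_length rayleigh_p locked
#> 5      u01          BS      259         0.794   1.20e-88   TRUE
#> 11     u02          BS      230         0.820   7.68e-86   TRUE
#> 17     u03          NS      448         0.625   5.01e-86   TRUE
```

Reading the output: both BS units measure 0.425 ms trough-to-peak (the
0.42 ms template rounded to the 40 kHz sample grid) and fire near the
lesioned-template base rate of 4.15 spikes/s; the rest-state 12–35 Hz
("beta") relative power comes out at 0.235 against an injected 0.243; and
during movement the BS units are strongly phase-locked to the 12–35 Hz
band (vector lengths ≈ 0.8, the lesioned-template level, Rayleigh
p ≪ 0.05) with a preferred phase at the oscillation trough (≈ 180°).

A two-condition cohort runs through `run_pipeline()`:

```r
bundles <- c(
  lapply(1:10,   function(s) gen_session(synth_template("control",  seed = s))$bundle),
  lapply(101:110, function(s) gen_session(synth_template("lesioned", seed = s))$bundle))
report <- run_pipeline(bundles, out_dir = "report")
report$findings   # BS rate down, beta power up, BS beta locking up
```

A thin command-line front end with `simulate` / `analyze` / `compare`
subcommands lives at `inst/cli/spikefield.R`.

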