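---
title: "Methods: spike, LFP and spike-field analysis in spikefield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike, LFP and spike-field analysis in spikefield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikefield)
```

# What the package computes

`spikefield` analyzes sessions of simultaneously recorded extracellular
single units and local field potentials (LFPs) of the kind collected from
layer 5 of rodent primary motor cortex (M1) during rest and skilled
forelimb reaching, in both dopamine-intact and unilaterally
dopamine-depleted (hemiparkinsonian) animals. The analysis chain is:

1. **Unit classification** (`trough_to_peak`, `classify_unit`,
   `refractory_ok`): spike waveform trough-to-peak duration separates
   broad-spiking (BS, putative pyramidal) from narrow-spiking (NS,
   putative interneuron) units.
2. **Firing-pattern metrics** (`mean_rate`, `isi_cv`, `isi_mode`,
   `asymmetry_index`): interspike-interval (ISI) statistics per behavioral
   state.
3. **Peri-event time histograms** (`build_peth`, `modulation_test`):
   trial-aligned firing around reach events, with a paired test for
   movement-related rate modulation.
4. **LFP spectra** (`lfp_preprocess`, `multitaper_psd`,
   `relative_band_power`, `lfp_spectrogram`): multitaper power spectra and
   relative power in the bands 0.7–12, 12–35, 35–70, 70–100 and
   100–200 Hz.
5. **Spike-field coupling** (`spike_field_coherence`,
   `instantaneous_phase`, `phase_lock_summary`): multitaper coherence
   between spikes and LFP, and bandpass-Hilbert phase locking with
   circular statistics.
6. **Group statistics and orchestration** (`mann_whitney_u`,
   `group_compare`, `run_pipeline`): cohort-level comparisons of the
   per-unit and per-session metrics.

A synthetic-session generator (`gen_session` and friends) produces data
with the statistical structure these analyses assume, together with a
ground-truth table, so every stage is verifiable without access to
recordings.

# Unit classification

The trough-to-peak duration is measured on the mean waveform as the time
from the global minimum (the trough) to the maximum that follows it (the
second, positive deflection). This operationalizes the standard
definition deterministically; a snippet with no rise anywhere after its
trough is *non-canonical* and the unit is left `unclassified`.

The class boundary is fixed at **0.32 ms**, the midpoint of the canonical
class means (0.42 ms for BS, 0.22 ms for NS); ties go to BS. Published
work typically separates the classes by clusters in PCA space plus the
duration without stating an explicit boundary; the fixed midpoint is a
documented, reproducible substitute. `waveform_pca` provides the cluster
view as a diagnostic only — classification never depends on it, and
amplitude criteria are recorded but not used (no published amplitude
cutoff exists).

Units must also show a refractory period: a unit passes when fewer than
1% of its ISIs fall below 2 ms.

# ISI metrics

* `isi_cv`: *population* standard deviation of the ISIs over their mean
  (the choice of population vs sample SD is not standardized in the
  literature; fixed here for reproducibility). Exponential ISIs give
  CV = 1; gamma-distributed ISIs with shape $k$ give $1/\sqrt{k}$.
* `isi_mode`: center of the most populated bin of the ISI histogram,
  5 ms bins on [0, 1] s (the binning is a package choice — published mode
  values like "0.05" are reported without binning details); ties resolve
  to the smallest bin center, which is stable under jitter.
* `asymmetry_index`: mode / mean ISI. Near 1 for regular firing, well
  below 1 for irregular or bursty firing.

State-resolved metrics are computed by masking the train with the rest or
movement intervals of the session; ISIs then straddle the gaps between
intervals, but the 1 s histogram range discards almost all such
straddling intervals in practice.

# PETH and the modulation test

PETHs use 5 ms bins over a window of [−1.0, +1.5] s around the beam-break
event, with the trial-averaged rate smoothed by a 5-point Gaussian kernel.
Only "five-point Gaussian" is standard terminology; the kernel's width is
fixed here at $\sigma$ = 1 bin, normalized to sum 1 and truncated and
renormalized at the window edges (so smoothing conserves total rate mass
up to the two boundary bins). The baseline is the mean rate over
[−0.6, 0) s before the event; the movement rate is the mean rate inside
each trial's annotated movement window.

The modulation test is a trial-paired two-sided Wilcoxon signed-rank test
of movement-window rate against baseline rate at $\alpha = 0.05$ (the
literature leaves the test unnamed; a non-parametric paired test matches
the field's conventions). Two numerical details matter:

* Per-trial rates are counts divided by window widths. When many windows
  share a nominal width, floating-point rounding of `end - start` breaks
  exact ties between trials in a fixed pattern, which silently defeats
  the signed-rank tie correction and inflates the test's false-positive
  rate several-fold. Differences are therefore rounded to $10^{-9}$
  spikes/s before ranking, restoring exact zeros and ties without any
  effect on genuinely continuous rates.
* All-zero differences give $p = 1$ (not modulated).

With this handling the measured type-I error is 0.050–0.052 over 500
null simulations at $\alpha = 0.05$, for both 0.3 s and 1 s movement
windows (the test suite re-measures this).

# LFP spectral analysis

Preprocessing is a zero-phase 0.5–200 Hz Butterworth bandpass (4th order,
forward–backward) followed by a 50 Hz notch. The notch (Q = 30) is
applied spectrally — the magnitude response of the standard biquad notch
multiplied onto the FFT of the trace — which is exactly zero-phase and
avoids the multi-hundred-millisecond ring-down a high-Q IIR filter
exhibits at segment edges. Forward–backward filtering is a package
choice; phase handling is rarely stated in publications.

PSDs use the multitaper method with **5 DPSS tapers, time-bandwidth
product NW = 3, 0.5 s windows at 1 kHz**. The DPSS tapers are computed
from the standard symmetric tridiagonal eigenproblem and cached. Windows
are non-overlapping (the choice is not standardized; overlap only
correlates the averages). The one-sided density normalization makes the
integral of the PSD equal the signal variance (Parseval; verified to 5%
on white noise in the tests). Note the estimator's spectral concentration
is $W = NW/T = 6$ Hz: any spectral feature within 6 Hz of a band edge is
partially attributed to the neighboring band.

Relative band power divides each band's integrated power by the total
over the union of the five bands (0.7–200 Hz). (Published methods state
"1–200 Hz" while results state "0.7–200 Hz"; the band union is used so
that fractions can sum to 1.) Band edges are half-open [low, high) on
the discrete frequency grid. Rest-state band power in the pipeline
averages PSDs over 3 s blocks cut from the rest intervals.

The spectrogram is a Hann-tapered STFT (0.5 s windows, 50% overlap),
stored linear; log scaling is left to display code.

# Spike-field coupling

**Coherence.** The spike train is embedded as mean-centered 1 ms binned
counts at the LFP rate and the multitaper cross-spectrum against the LFP
is averaged over 0.5 s windows and 5 tapers:
$C(f) = |S_{xy}|/\sqrt{S_{xx}S_{yy}} \in [0,1]$ by construction, never
clipped. Band-mean coherence is the unweighted mean of $C(f)$ over
in-band frequencies. Admissibility requires at least 40 spikes and 10
windows of overlap. The pipeline computes coherence over the whole
session epoch (whether published values used whole epochs or
trial-concatenated segments is not stated; whole-epoch is the simpler
deterministic choice).

**Phase locking.** The LFP is bandpass-filtered with a 3rd-order
Butterworth (zero-phase) and the analytic-signal angle is mapped to
degrees in [0, 360). With this construction a band-limited oscillation's
peaks sit at 0° and troughs at 180° — the tests verify ±2° on a pure
cosine. Each spike takes the phase of the nearest LFP sample. The
Rayleigh uniformity test uses the refined exponential approximation
$p = \exp\{\sqrt{1+4n+4(n^2-R_n^2)} - (1+2n)\}$ ($R_n = nR$), validated
in the tests against a $10^5$-sample simulated null to Monte-Carlo
accuracy. A unit is *locked* in a band when it is admissible (≥ 40
spikes) and Rayleigh $p < 0.05$; the mean angle and vector length
$R \in [0,1]$ summarize the preferred phase and its concentration.

# Group statistics

`mann_whitney_u` computes $U = \sum_{ij}[x_i > y_j] + \tfrac12[x_i=y_j]$
with a two-sided exact p by full enumeration of all $\binom{n+m}{n}$
group assignments for $n+m \le 12$ (ties handled by the half-count
convention under enumeration, which closed-form tables cannot do), and a
tie-corrected normal approximation with continuity correction otherwise.
`group_compare` provides the two-way group × behavior ANOVA and the
repeated-measures ANOVA with a within-subject band factor (via
`stats::aov`; sphericity corrections are out of scope), plus
Bonferroni-corrected pairwise Mann–Whitney contrasts
($p_\mathrm{corr} = \min(1, k\,p)$, exactly). Significance is two-sided
$\alpha = 0.05$ throughout.

`run_pipeline` orchestrates everything over a cohort and reports three
headline direction-of-effect findings when both conditions are present:
BS rest rate (expected lower after dopamine depletion), 12–35 Hz relative
power (expected higher), and BS movement-epoch vector length at 12–35 Hz
(expected higher).

# The synthetic generator

`gen_lfp` synthesizes the LFP in the frequency domain: each band carries
Gaussian noise whose spectral density is a Hann envelope over the band
with a $1/f^{\alpha}$ tilt ($\alpha = 1$ by default), plus an optional
broadband $1/f^{\alpha}$ background carrying any residual fraction. Two
deliberate design choices:

* Each component's realized variance is rescaled to its target fraction
  exactly, so the injected fractions are ground truth rather than
  expectations.
* The Hann support is inset from each band edge by min(4 Hz, 0.35 ×
  band width) — about the analysis estimator's half-bandwidth $W = 6$ Hz.
  Without the inset, mainlobe smearing moves ~3% of total power across
  band edges and injected fractions are unrecoverable *by the estimator
  the analysis chain fixes*; with it, recovery is within ~0.01 for 300 s
  traces. Real LFPs have no such guard band: leakage across band edges is
  an irreducible property of 0.5 s multitaper windows, and passing the
  recovery tests says nothing about edge-adjacent power in real data.

A pure-tone mode (`component_mode = "tone"`) places one sinusoid at each
band's geometric center for analytic tests.

`gen_spike_train` draws spikes by thinning a homogeneous Poisson process
at the documented bound
$\lambda_{max} = r \cdot g_{max} \cdot e^{\kappa}/I_0(\kappa)$, with
conditional intensity
$\lambda(t) = r \cdot g(t)\cdot e^{\kappa\cos(\phi(t)-\mu)}/I_0(\kappa)$:
$r$ the base rate, $g(t)$ the movement gain inside movement windows,
$\phi(t)$ the instantaneous phase of the coupling band, $\kappa$ and
$\mu$ the von Mises concentration and preferred phase. Because the phase
of band-limited Gaussian noise is uniform over time, the spike phases are
von Mises and the recovered vector length equals $I_1(\kappa)/I_0(\kappa)$
(checked to ±0.02 at $10^5$ spikes using a deliberately fast calibration
unit — 100 spikes/s for ~1100 s — rather than a physiological one). A
2 ms absolute refractory period is imposed by default so synthetic units
satisfy the refractory criterion real sorted units must meet; it deletes
about $2\,\mathrm{ms} \times r$ of spikes and is disabled
(`refractory_ms = 0`) in coupling-calibration runs because
phase-dependent deletion at high rates biases $R$ downward.

`gen_waveforms` builds biphasic snippets (raised-cosine trough and peak
lobes) whose noiseless trough-to-peak equals the requested duration
rounded to the 40 kHz grid — 0.42 ms is representable as 17 samples
(0.425 ms) and 0.22 ms as 9 samples (0.225 ms).

The event schedule is a renewal process with uniform inter-event
intervals on [4, 8] s (trial pacing is unpublished; this is a
placeholder, not an inferred value), each event opening a movement window
of Gaussian length (mean 0.96 s control / 1.25 s lesioned, SD 0.1 s).
Rest intervals are the complement with a 0.5 s guard margin.

`synth_template` encodes the two study conditions: rest-state band
fractions (control 73.51 / 15.72 / 4.26%, lesioned 58.65 / 24.34 / 8.09%
for the first three bands; the two high bands are unpublished at rest and
split the remaining mass 2.31 : 7.07 as in the movement tables), BS/NS
base rates (4.76 / 7.62 control, 4.15 / 6.98 lesioned), movement gains
equal to the reaching/background rate ratios, and 12–35 Hz coupling with
$\kappa$ chosen so the movement-epoch vector lengths match the two
conditions ($R = 0.66 \Rightarrow \kappa = 1.8$;
$R = 0.80 \Rightarrow \kappa = 2.9$), preferred phase 180° (trough
firing). Per-unit biological scatter is lognormal (10% on rates, 8% on
$\kappa$). Sessions default to 360 s with 3 BS + 2 NS units — long
enough that each unit passes the 40-spike movement-epoch admissibility
criterion with margin, while a 20-session cohort analysis completes in a
few minutes on one core.

What the generator does *not* emulate: non-stationary rates and drifting
oscillation power, cross-frequency coupling, spike-sorting contamination
and waveform drift, volume-conducted artifacts, and behavioral
variability beyond the movement-window length. Green tests therefore
certify the estimators against their own model class, not against all
the failure modes of in vivo data.

# Determinism and problem sizes

Every generator takes an explicit seed and is bit-reproducible
(float32-quantized payloads make the on-disk round-trip exact).
Simulation sizes used by the verification suite — 300 s LFP traces for
band-power recovery, ~$10^5$ spikes for coupling calibration, 500 null
replicates for the type-I check, 10 + 10 sessions for the cohort run —
were chosen as the smallest sizes at which the tested tolerances are
comfortably inside sampling noise.

# Known limitations

* The 0.32 ms class boundary is a substitute for the unpublished
  cluster-plus-duration rule; units near the boundary are assigned, not
  flagged.
* Relative band power inherits the ±6 Hz estimator bandwidth: the
  0.7–12 Hz band is barely wider than the smoothing kernel, and a pure
  line anywhere inside it loses a few percent of its power across the
  edges (see the tolerance discussion in the tests).
* The repeated-measures ANOVA applies no sphericity correction.
* Coherence is computed over whole epochs; per-trial coherence with
  jackknife errors is out of scope.
* The Mann–Whitney normal approximation is used beyond $n+m = 12$;
  for heavily tied small samples the enumeration handles ties exactly,
  but the approximation's tie correction is asymptotic.
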