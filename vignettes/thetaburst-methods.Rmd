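---
title: "Methods: burst segmentation, theta phase and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst segmentation, theta phase and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetaburst)
```

This vignette documents the models, conventions and numerical choices behind
`thetaburst`, in the order a recording session flows through the pipeline.

## Burst definition and structure

A complex spike burst is a maximal run of at least two spikes whose
consecutive inter-spike intervals are all **no more than 15 ms** — the
comparison is inclusive, so a 15.000 ms gap still joins a burst. Every other
spike is a single spike, and the burst's timestamp is its first spike. The
rule induces a partition: each spike belongs to exactly one burst or to the
single-spike set, which `segment_bursts()` guarantees for every input (and
which the test suite checks against an independent brute-force scanner).

Burst structure is summarised three ways. The burst-length histogram
normalises per cell before pooling, so heavily bursting cells do not
dominate the population summary (median and quartiles across cells).
The accommodation profile pools ISIs by their order within bursts of a
given length; the *accommodation rate* is the slope of mean ISI against
order over the two intervals of 3-spike bursts, in ms per interval — a
compact scalar that distinguishes accommodating (positive) from
non-accommodating (flat) discharge. `post_event_conditional()` estimates how
a burst suppresses subsequent single-spike emission. The estimator is
hazard-style by default: for each bin of elapsed silence it reports the
probability that the *next* event is of the response class given the silence
reached that bin. A plain next-event histogram is available via
`estimator = "histogram"`; the hazard form is the default because it
separates the shape of the suppression from the overall event rate. The
silence clock starts at the last spike of the triggering burst.

## Theta phase conventions

Theta epochs are detected from the ratio of band power at 5–10 Hz to
1–4 Hz in non-overlapping 1 s windows, threshold 2, with sub-threshold
gaps closing epochs and epochs shorter than 1 s dropped. All three values
are defaults exposed in `detect_theta_epochs()`; they are conventional
rather than principled, and analyses that matter should be checked at
threshold 1.5–3.

Instantaneous phase is the angle of the analytic signal of the zero-phase
band-passed (Butterworth order 3, forward–backward) LFP, with reflective
padding to suppress edge transients. **The trough of the filtered signal
maps to 0°/360° and the peak to 180°.** Every phase number in the package
depends on this convention; it is chosen so that pyramidal-cell bursts,
which concentrate near the trough, have mean phases near 360°/0°.

Phase histograms correct for non-uniform phase occupancy: the count in each
of the 20 bins is divided by the fraction of LFP samples (within theta
epochs) falling in that bin times the bin count, then normalised to sum 1.
For events generated as a Poisson process in time this removes any
distortion of the underlying phase distribution — a property the suite
verifies on a deliberately distorted phase series. Bins with zero occupancy
are excluded and the histogram renormalised with a warning. The displayed
curve is smoothed with a circular Gaussian kernel (SD = 2 bins); the mean
phase, resultant length R and Rayleigh p are computed from the raw,
unsmoothed event phases. Whether the circular statistics should also be
occupancy-corrected is genuinely ambiguous; raw is the default and
`stats_corrected = TRUE` switches to inverse-occupancy weighting.

The Rayleigh p uses the standard large-sample approximation
`exp(sqrt(1 + 4n + 4(n² − (nR)²)) − (1 + 2n))`; its type-I error at
n = 50 is ~0.050 by Monte Carlo. Silverman's bootstrap modality test uses a
von Mises kernel density: the critical concentration is the largest κ whose
density still has at most `k_null` modes (binary search over κ, mode count
on a 256-point circular grid), bootstrap samples are drawn from the
critical-bandwidth density, and p is the fraction of bootstrap samples
whose critical bandwidth exceeds the observed one. A sample with resultant
length numerically 1 is degenerate and returns p = 1 by convention.

## Spectra

No installed package provides DPSS tapers or a continuous wavelet
transform, so both are implemented here. `dpss_tapers()` solves the
standard symmetric tridiagonal eigenproblem (tapers cached per
length/NW). `multitaper_psd()` averages tapered periodograms over
half-overlapping windows (NW = 3, window 1024 samples by default).
`morlet_cwt()` evaluates the complex Morlet wavelet (ω₀ = 6, the standard
time–frequency trade-off) by direct FFT convolution — appropriate for the
short curves (cross-correlograms) it is applied to.

## Pair synchrony

Burst-time cross-correlograms use ±200 ms lags with 10 ms bins, one bin
centred at lag 0, normalised per reference event. The theta-band content of
the pair-averaged CCG is the summed Morlet power at 5–10 Hz of the
mean-subtracted curve. Its significance comes from a permutation null:
each pair's target train is independently circularly shifted within the
session (preserving each train's own autostructure and event count), the
average CCG and its theta power recomputed, N = 1000 times by default, and
p is the add-one-corrected fraction of null powers at least as large as
observed. Neither the bin width nor the surrogate scheme is canonical;
both are exposed as arguments. The burst autocorrelogram (zero-lag bin
cleared of self-pairs) yields a rhythmicity index: theta-band Morlet power
over broadband 1–40 Hz power, which rises monotonically with the
phase-locking concentration of the underlying train.

## Place fields

Occupancy and rate maps use 2 × 2 cm pixels; the rectangular arena
(50 × 30 cm) is analysed on the 2-D grid, the circular track (Ø 60 cm) on a
1-D circularly wrapped angular axis with 2 cm bins. Frames with speed below
2 cm/s (immobility) are excluded from occupancy, and spikes emitted during
those frames are dropped symmetrically, so rate = count/time holds pixel by
pixel. Maps are not smoothed by default (an optional Gaussian flag exists);
fields are 4-connected components of pixels strictly above 1 Hz with at
least 2 pixels, and the largest field is the cell's primary field (a
`multi_field = "sum"` option covers multi-field cells). Sparsity and
information density follow the Skaggs conventions given in the README; both
are invariant to uniform rescaling of occupancy. Map correlations are
Pearson over jointly defined pixels, Fisher-z transformed with r clipped at
±0.999999 and flagged when at the clip.

Speed is the centred finite difference of boxcar-smoothed (0.4 s) position;
the boxcar pads by odd reflection so constant-velocity segments keep their
slope to the first frame. Running is speed > 3 cm/s, immobility < 2 cm/s;
2–3 cm/s frames belong to neither state but are retained for mapping.

## Optogenetic statistics

Entrainment fidelity divides the cumulative PSD within ±0.5 Hz of the
stimulation frequency by the cumulative theta-band (5–10 Hz) PSD per 10 s
window. A ±0.5 Hz band demands sub-Hz spectral resolution, so the LFP is
decimated to 125 Hz (Butterworth low-pass, order 6) before the NW = 3 /
1024-sample multitaper estimate — the window then spans 8.2 s with a
0.37 Hz taper bandwidth. Without the decimation the taper bandwidth at
1250 Hz would be 3.7 Hz and even a pure tone at the stimulation frequency
could not exceed fidelity ~0.25; with it, a pure tone reaches ~0.995 and
white noise the bandwidth ratio 1/5. For 12 Hz stimulation the denominator
band is extended by [11.5, 12.5] Hz so fidelity stays bounded by 1.

Light-responsive units are identified by the circular-shift permutation
test: A/B are the maximum 1 ms-bin spike counts in the 10 ms before/after
pulse onset; surrogate pulse trains are shifted by uniform random offsets
into the pre-stimulation baseline; `p₁ = P(Aᵢ > A_obs)` and
`p₂ = P(Bᵢ > B_obs)` with strict inequality and an add-one correction; a
cell is tagged when `p₂ < 0.05` and `p₁ ≥ 0.05` in at least one stimulation
epoch. Surrogate offsets are drawn on a 1 ms grid and all N shifts are
evaluated against a 1 ms baseline spike histogram through a single FFT
cross-correlation, which makes N = 10000 shifts cheap; the observed A/B use
exact event times. Two behaviours of this discrete rank statistic are worth
knowing. First, with strict `>` the realised false-positive rate of the p₂
criterion is 0.05 *plus one point mass* of the max-count distribution, so it
is visibly inflated when per-bin expected counts are small (sparse cells,
few pulses) and approaches the nominal level as counts grow; the
calibration experiment in the acceptance suite therefore uses a fast-firing
regime. Second, for a background-firing cell the pre-pulse screen p₁ is
itself approximately uniform, so any single epoch mis-screens ~5–10% of
genuine responders; reliability of the classification comes from the
≥ 1-of-2-epochs rule.

The pulse-window burst-spike test counts burst-class spikes inside (or, as
an option, within one pulse duration after) the 30 ms pulses and compares
against equally many randomly placed baseline windows; p is the two-sided
permutation rank.

## The synthetic benchmark

The generator produces what the analyses assume, with full ground truth,
and its defaults are the study conditions the package is validated under:
sessions of 600 s with 50 cells, theta at 7 Hz, alternating 40 s running /
20 s immobility blocks, trajectories as Ornstein–Uhlenbeck motion with
reflecting walls (25 frames/s), and LFP at 1250 Hz as a theta sinusoid
with slow amplitude/frequency jitter plus 1/f background noise, theta
present in both behavioural states (lower amplitude during immobility).

Each cell is an inhomogeneous point process. Burst events are thinned
Poisson with rate = burst-event rate × Gaussian place-field gain × von
Mises phase gain, both gains normalised to unit session mean so the
realised rate matches the nominal one; each event draws a length from a
geometric pmf and emits spikes with ISIs `isi_start + k·slope` (control)
or a constant, length-coupled ISI (mutant), jittered ±0.5 ms. Single
spikes are an independent place- and weakly phase-modulated Poisson
process, silenced for 55 ms after each burst. The `control` preset encodes
burst rate 0.23 Hz, single rate 0.80 Hz, mean ISI 7.42 ms (the ISI offset
is solved from this target given the pmf and slope), locking at 344° with
κ = 1, accommodation +1.5 ms/interval; the `mutant` preset encodes
0.24 Hz / 0.49 Hz / 6.67 ms, flat accommodation with inverse
length–frequency coupling (−0.5 ms per extra spike), longer bursts, and
κ = 0 during running but control-level locking during immobility. The
length-pmf decay ratios (0.2 control, 0.4 mutant over lengths 2–6) are
chosen so burst-spike and single rates compose to all-spike rates of
~1.31 / 1.12 Hz; length 7 is excluded because, with the accommodation
slope, its late intervals would breach the 15 ms burst definition
(configurations that would are rejected at construction).

Two dead times make the generator's intent recoverable by the analysis:
single spikes keep ≥ 16 ms from burst spikes and from each other, and a
burst event cannot begin within 16 ms of the previous burst's last spike.
Without them, a few percent of intended singles and bursts merge into
detected bursts and the emitted rates drift below their targets; with
them, detected segmentation recovers > 99% of intended bursts. The rate
lost to the dead time is compensated by a fixed-point rescaling of the
base rate (three passes). These dead times mirror real physiology —
post-burst suppression and the impossibility of overlapping bursts in one
cell — but they do mean the generator's single-spike process is not exactly
Poisson at short lags.

Everything is deterministic given the config seed; cells, trajectory and
LFP draw from seed offsets so any component can be regenerated alone.

What passing on this benchmark does *not* show: the generator has no
spike-sorting noise, no bursty interneurons, no phase precession, no
remapping, and its LFP is a single sinusoid plus 1/f noise rather than an
asymmetric theta waveform; conclusions about real data still require the
usual controls.

## Problem sizes and runtime choices

The validation suite runs populations of 10–50 cells over 300–600 s,
permutation tests at N = 60–1000, the Rayleigh calibration at 10⁴ draws,
and the optotag calibration at 500–1000 cells with N = 1000 shifts — sizes
at which every recovered parameter sits well inside its tolerance while the
whole suite stays in the minutes range on one CPU. The acceptance script
uses the same sizes and derives every RNG stream from its `--seed`
argument.
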