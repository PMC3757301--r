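---
title: "Quantifying dentate-gyrus electrophysiology: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dentate-gyrus electrophysiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgephys)
```

## Scope and rationale

The dentate gyrus (DG) gates cortical input to the hippocampus: granule
cells receive the perforant path, hilar mossy cells integrate granule-cell
output and return both direct excitation and disynaptic (feed-forward)
inhibition to the granule layer. Comparing genotypes in this circuit rests
on a small set of standard quantities: intrinsic membrane and firing
properties from current-clamp steps, miniature EPSC (mEPSC) frequency,
amplitude and kinetics, evoked field-potential metrics on a high-density
multielectrode array (MEA), and the ratio of evoked excitation to
inhibition (E/I) in single granule cells.

`dgephys` implements that quantification chain as reusable estimators, and
pairs every stage with a synthetic-data generator whose ground truth is
known exactly. Raw recordings from such studies are rarely deposited, so
the generators are first-class citizens: they define the conditions under
which each estimator is validated, and the test suite is parameter
recovery — set the generator to a published group value, run the pipeline,
require the value back.

The package's interface is its R functions together with this vignette and
`scripts/acceptance.R`; no separate shell tool is provided, as every
operation is a single function call on in-memory objects.

## Synthetic data: what is emulated, and what is not

**Current clamp.** `simulate_current_clamp()` integrates a leaky
integrate-and-fire membrane exactly (exponential update of
$dV/dt = (V_\mathrm{rest}-V)/\tau_m + I R_\mathrm{in}/\tau_m$) over the
standard protocol of 30 steps of 1 s from −100 pA in 10 pA increments.
When the noiseless trajectory crosses threshold, a stereotyped action
potential is pasted: a linear rise (0.5 ms) from threshold to the
overshoot peak, a linear fall (1 ms) to the afterhyperpolarization (AHP)
minimum, then passive relaxation. The steep rise guarantees a unique,
well-separated phase-plane threshold crossing, and the corner at the AHP
minimum places the first post-repolarization $dV/dt$ zero crossing exactly
there. Recording noise is *observational* — added to the returned sweep,
not to the spike dynamics — so ground-truth spike times, the closed-form
rheobase $(V_\mathrm{th}-V_\mathrm{rest})/R_\mathrm{in}$ and the true
input resistance are exact regardless of noise. Defaults describe a
wild-type-like mossy cell (396 MΩ, threshold gap giving ≈45 pA rheobase).
Sampling is 20 kHz, a conventional patch-clamp rate (the studies this
emulates do not state theirs).

What this does **not** capture: conductance-based spike shapes,
adaptation, sag, stochastic channel noise that couples into spike timing.
Passing recovery tests therefore shows the estimators are correct for the
stated membrane model, not that they are robust to every biological
waveform.

**Minis.** `synthesize_mini_trace()` draws Poisson onsets, truncated-
Gaussian amplitudes (redrawn at ≤0, avoiding sign flips), and pastes the
peak-normalized difference of exponentials
$g(t) \propto e^{-t/\tau_d}-e^{-t/\tau_r}$ as inward (negative)
deflections that sum linearly where they overlap — reproducing the
multipeak phenomenology of high-frequency mossy-cell recordings. Defaults
are the wild-type kinetics (decay τ 4.39 ms; rise constant inverted
numerically by `rise_tau_for_rise_time()` so the template's analytic
10–90% rise time is exactly 0.83 ms), 30 pA ± 5 pA amplitudes, 5 Hz, 2 pA
noise. Fixed onset/amplitude overrides support deterministic layouts for
calibration.

**Evoked pairs.** `synthesize_evoked_trains()` builds matched eEPSC
(−80 mV holding, inward) and eIPSC (0 mV, outward) trains on one time
base; pulse $k$ scales the first amplitude by a user depression profile
(first element 1). `depression_profile()` provides the
exponential-to-plateau family $s_k = p + (1-p)e^{-(k-1)/\tau}$ used to
emulate steady-state multiple-pulse depression. Default: 80 pulses at
40 Hz (a 2 s train).

**MEA.** `synthesize_mea_recording()` fills a 64 × 64 pixel grid sampled
at 7.7 kHz. Each stimulus inserts a smooth field-PSP template on each
region mask with the region's polarity — negative in the granule/molecular
layer (current sink), positive in the hilus (current source) — its peak
latency (defaults 5.0 and 7.8 ms, i.e. a 2.8 ms granule→hilus delay), and
a plateau amplitude scaled by a logistic input–output function of stimulus
intensity (half-maximum at `io_halfmax`; an `NA` intensity means a
calibrated shock delivering the plateau). Trains scale pulse $k$ linearly
from 1 to `last_over_first_ratio`. A saturating artifact covers all
channels for `artifact_duration` after each shock; parameter sets whose
response onset would fall inside the artifact are rejected. Masks are
1-based (row, column) coordinates, the R convention, linearized row-major.

All randomness flows from one user seed; sub-streams are derived with a
documented splitting scheme (`dgephys:::split_seed`), so regenerating one
component does not shift another.

## Estimators and their numerical choices

**Resting potential.** The 1-min zero-current trace is binned (0.5 mV
default — narrow enough to resolve sub-mV modes, wide enough for stable
counts) and a Gaussian is fitted to the counts by nonlinear least squares.
The fit is restricted to the contiguous bins around the dominant mode, so
a secondary mode (up/down states, bimodal cells) cannot drag the mean; a
secondary mode at ≥20% of the dominant count raises a multimodality
warning. A constant trace short-circuits to its mean; a non-convergent fit
errors, suggesting the median.

**Action potentials.** $V_s$ is the voltage at the first sample where the
smoothed (3-point moving average) central-difference $dV/dt$ exceeds
10 mV/ms, evaluated per AP epoch; epochs are delimited by upward crossings
of −20 mV to prevent double counting. Voltage values (threshold, peak,
amplitude, AHP) are read from the *raw* trace — smoothing stabilizes only
the derivative criterion, since filtering clips sharp peaks. The AHP is
the first post-repolarization $dV/dt$ zero crossing below $V_s$, searched
up to 50 ms past the peak; the half-amplitude width is interpolated
linearly at $V_s + \text{amplitude}/2$.

**Rheobase and F–I.** Rheobase is the injected current of the first step
(strictly increasing steps enforced) whose sweep contains a detected AP —
by construction on the protocol grid, and at most one 10 pA increment
above the closed-form LIF value. A cell that never spikes returns an
explicitly flagged undefined result. The F–I curve is AP count divided by
step duration, with subthreshold 0 Hz entries retained.

**Input resistance.** Ordinary least squares through the three
steady-state points (−10, 0, +10 pA; steady state = mean of the last
200 ms of each step, long after the ≈25 ms membrane relaxation). The slope
in mV/pA is reported in MΩ, with $R^2$ and a flag when $R^2 \le 0.95$.

**Mini detection.** Manual peak curation is replaced by a documented
automated detector: median-centring, polarity flip, a 0.25 ms moving
average, candidate local maxima, onset at the preceding smoothed valley,
local baseline as the median of the 5 ms before onset, and an 8 pA
baseline-to-peak threshold. Two candidates are separate events only if
the signal between them repolarizes by ≥25% of the preceding amplitude
(the multipeak rule, exposed as a parameter) **and** the second rises at
least the detection threshold above the intervening valley — without the
second condition, the natural decay of a large event supplies the 25%
drop and noise bumps riding the decay are counted as events. Events whose
pre-onset valley stays elevated are flagged `overlapping`.

**Averaging and kinetics.** 40–60 clean events — non-overlapping *and*
temporally isolated, so each snippet holds one clear rise and one clear
decay — are aligned at the 50%-of-peak rising crossing and averaged
pointwise. The 10–90% rise time uses linearly interpolated crossings with
a parabolic sub-sample peak refinement. The decay constant is a
monoexponential fitted on the 90→10% falling segment; the default fitter
regresses log-magnitude on time, which weights the segment evenly and, on
the difference-of-exponentials template, recovers the generating τ to
within 1% (a linear-space fit overweights the early, rise-contaminated
samples and biases τ by ≈2.4%). `method = "nls"` is available for noisy
data where log-transformation would distort the error structure.

**MEA metrics.** Per-pixel amplitude is the maximum deflection in the
post-blanking window (default 2 ms, covering the artifact), sign-resolved
by region polarity and averaged over 10 events. Region summaries use the
3 highest-amplitude pixels (deterministic, unlike random choice; explicit
coordinates may be passed). Peak times are parabolic-interpolated: at
7.7 kHz the bare sample grid would alias up to ±0.26 ms into a 2.8 ms
propagation difference, versus <0.1% after refinement. The area mean at
the point of highest response is the polarity-resolved mask mean at the
frame maximizing the mask-mean response, averaging ±1 frame; because our
frames are already voltage-calibrated, the conventional rescaling of
maximum image intensity to maximum voltage is the identity, and
implementing it literally through per-pixel maxima would only inject
extreme-value noise bias. The 20 Hz/5 s train depression ratio is
last-over-first area mean, so depression gives values below 1.

**Evoked E/I.** Pulse windows are `[pulse + 1 ms, next pulse)`. For trains
at ≥20 Hz the preceding pulse's tail overlaps the window, so the baseline
subtracted at the peak is the tail's monoexponential extrapolation
(toggleable); below 20 Hz a flat 1 ms pre-pulse baseline suffices. The E/I
ratio is excitatory over inhibitory amplitude for the first pulse
(`single`) or the mean over the final 10 pulses (`last10`); both are
scale-invariant by construction.

**Statistics.** Two-group contrasts use the classical equal-variance
two-tailed t-test (Welch behind a flag); identical zero-variance groups
return p = 1 by convention. Multi-group designs use one/two-way ANOVA with
Bonferroni-adjusted pairwise t-tests (pooled SD) or Kruskal–Wallis with
Dunn's rank post-hoc (tie-corrected, Bonferroni family-wise, since Dunn's
method does not itself fix an adjustment). The KS statistic
$D=\sup|ECDF_x-ECDF_y|$ uses the asymptotic Kolmogorov p-value by default
with an exact small-sample option. Pooling event values across cells
before a KS test inflates the effective n (each cell contributes many
correlated events); the package implements pooling as the field practices
it, and leaves the caveat here.

## Validation design

Every estimator is tested three ways: closed-form cases with zero noise
(Ohm's-law deflections, logistic midpoints, geometric depression
profiles), property-style invariants over seeded generator sweeps
(ECDF monotonicity, F–I monotonicity, propagation antisymmetry,
scale-invariance of E/I), and parameter recovery at published wild-type
group values — mEPSC decay τ 4.39 ms and rise 0.83 ms, input resistance
396 MΩ, granule→hilus propagation 2.8 ms, 20 Hz/5 s granule-layer
depression ratio 0.45, last-10 E/I 0.3, and the knockout hilar area mean
87.13 μV. Detection fidelity requires mini recall and precision ≥95% at
SNR 10 (20 seeds) and exact AP-count agreement with simulator truth on
every seed.

Type-I calibration runs 2000 null simulations: the t-test at n = 10 per
group (typical cell counts; rejection ≈0.049) and the KS test at the
pooled-event scale of n = 80 vs 75 with its exact null distribution
(≈0.0485). The KS test cannot be calibrated at n = 10 per group: its null
distribution there is lattice-valued and the largest achievable level
below 0.05 is ≈0.011, so a nominal-rate check at that size is
mathematically impossible rather than a software property.

Problem sizes were chosen to exercise the stated study conditions at full
scale where they are the point — the acceptance suite generates the
complete 64 × 64, 7.7 kHz, 20 Hz/5 s train (≈1.3 GB) — while module tests
use 16 × 16 grids and 1–2 s trains, which exercise identical code paths.

## Degenerate inputs and tie-breaks

Empty event lists propagate as zero frequency with empty (but well-typed)
distributions; a never-spiking cell flags rheobase undefined rather than
erroring; an all-zero region returns an area mean of 0 with a warning; a
zero inhibitory denominator flags the E/I ratio undefined; containers
missing units or sampling rate fail naming the field. Ties in rheobase
cannot occur (strict step ordering is enforced); equal-height mini peaks
within one event keep the earlier peak.

## Known limitations

The spike template is stereotyped, so AP-shape statistics (amplitude,
half-width, AHP) validate the measurement geometry, not biological
variability. The mini detector is threshold-based; deconvolution or
template matching would behave differently near threshold. MEA synthesis
has no volume-conduction crosstalk between regions and no spatial
amplitude gradients unless supplied per-pixel. ABF ingestion and spike
sorting are out of scope; the trace container is an R-native serialized
schema rather than a cross-language file format.
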