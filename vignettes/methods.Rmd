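---
title: "Models and methods behind embryotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind embryotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryotrace)
```

`embryotrace` implements the computational side of live RNA imaging with
CRISPR-dCas13 in zebrafish embryos: selecting repeat-carrying target
transcripts, quantifying allelic transcription traces, decomposing
expression noise, classifying mRNP motion from single-particle tracks,
timing nuclear export, and denoising spot movies. Because the original
microscopy movies are not a package-sized input, every analysis is paired
with a seeded generator that produces synthetic data with the statistical
structure the analysis assumes, plus the ground truth needed to test it.
This vignette records the models, the tunable parameters and the design
choices that were genuinely open.

## Repeat screen

dCas13 labelling of a single mRNA requires many copies of one ~20-nt
guide target on the same transcript. `find_repeat_clusters()` finds, on
the sense strand only (dCas13 binds the mRNA), clusters of k-mers in
which **every pair** of members differs by at most one substitution. For
a mismatch budget of one, such a cluster is exactly a set of windows that
are identical outside a single variable column, so clusters are found in
`O(n·k)` by hashing each window `k` times with one position masked — and
the result provably matches a brute-force all-pairs comparison, which the
test suite checks on small instances.

Two readings of "at most one mismatch" exist: the strict pairwise
criterion (default) and a star topology in which members need only be
within one mismatch of the cluster seed, so two members may differ at two
positions. Both are implemented (`topology =` `"pairwise"`/`"star"`);
pairwise is the default because it guarantees that any member can serve
as the guide with at most one mismatch against every copy.

Details worth knowing:

* Windows containing `N` are skipped entirely (`N` never matches).
  `U` is read as `T`. Only mismatch budgets 0 and 1 are supported — the
  biological rule is "at most one mismatch", and pairwise clusters at
  larger budgets are no longer single-column structures.
* Occurrences are made non-overlapping greedily left-to-right, ties
  broken by the smaller start. Coordinates are 0-based half-open
  internally and 1-based in reports.
* A planted repeat also creates *shifted* clusters: the window one base
  to the left of each copy repeats too, with the flank base as the single
  variable column. These are genuine clusters under the definition and
  are reported; candidate selection is unaffected because it looks at the
  maximum cluster size per transcript.
* `cross_gene_uniqueness_filter()` removes clusters whose occurrence
  sequences also occur in a different gene's clusters — exactly, or
  within one mismatch (`tolerant = TRUE`, default), since a near-identical
  cross-gene motif would still cross-react. Isoforms of one gene never
  trigger removal.
* `select_candidates()` flags transcripts with ≥ `min_repeats`
  (default 8) non-overlapping copies in one cluster and reports counts at
  thresholds 2 and 8. `expression_summary()` averages library-size
  normalized counts per cell type for screened transcripts.

## Trace quantification

The puncta signal is `ROI1_max`, the maximum inside a small disc at the
transcription site; the local background is `ROI2_mean`, the mean over
the surrounding annulus of three times the radius. The normalized
activity

$$\mathrm{activity} = \frac{\mathrm{ROI1}_{max} - \mathrm{ROI2}_{mean}}
{\mathrm{ROI2}_{mean}}$$

is dimensionless and exactly invariant to any gain applied to signal and
background together, which is why it corrects photobleaching: the test
suite verifies the cancellation to better than 1% on movies with
multiplicative decay, and exactly on trace tables. An unidentified
punctum is assigned its local background, i.e. activity 0. SNR is
`(peak − background mean) / background SD`.

**Initiation detection.** The original signals were scored manually; the
package uses the first time point exceeding a threshold for at least two
consecutive samples (debouncing single-frame spikes). The default
threshold is self-calibrating per trace — three times the MAD of the
pre-`t0` baseline (or the first five points when nothing precedes `t0`),
floored at 0.05 — with an absolute override available. Raising the
threshold can only delay detection, a property tested explicitly.

**Activation patterns.** Each cell is classified as `none`,
`one_allele`, `same_time` or `sequential`. No numeric criterion for "at
the same time" is stated anywhere; the default window is one sampling
interval (5 min by default) and is exposed so cohort results can be
reported as a function of the window.

**Plateau and memory.** Plateau time is the first time the 3-point
moving-average-smoothed trace reaches 90% of its own maximum — plateau
times are conventionally read off curves by eye, and 90%-of-max is a
stable explicit rule. Transcriptional memory is summarized as mean ± SD
of inter-allele initiation-time differences per cycle, compared across
cycles by Welch's two-tailed t test; two all-constant groups are handled
as a degenerate case (p = 1 when equal).

## Noise decomposition

The cumulative output of an allele is the plain sum of its normalized
activities over the cycle (grids are uniform, so the sum is proportional
to the integrated area; a `dt`-weighted variant exists). Extrinsic noise
— cell-wide fluctuations shared by both alleles — appears as correlation
between the two alleles' outputs across cells; intrinsic,
allele-autonomous noise as scatter off the diagonal. `allele_correlation()`
reports Pearson's r, Spearman's ρ and the regression slope;
`random_pair_control()` re-pairs allele 1 of each cell with allele 2 of a
random *different* cell (a derangement) and should destroy the
correlation, the package's null control.

Per-timepoint correlation curves are compared between cycles by a t test
on the collected correlation coefficients themselves; a Fisher-z option
exists but is off by default, deliberately reproducing the simpler
procedure rather than the more orthodox transform. Both raw and
per-timepoint mean absolute allele differences (with paired t tests) are
produced.

## Single-particle tracking

Tracks shorter than 20 consecutive frames (0.2 s at the 10-ms frame
interval) are discarded. The time-averaged MSD over all overlapping frame
pairs is fitted, over lags 1–10 by default, with

* the ballistic model $MSD(t) = (vt)^2$,
* the power law $MSD(t) = 2\,m\,D\,t^\alpha$ with image dimensionality
  $m = 2$ and anomalous exponent $\alpha \in (0, 2]$,
* the confinement model $MSD(t) = \frac{L^2}{3}(1 - e^{-t/\tau})$ with
  derived $D = L^2/(12\tau)$,

using Levenberg–Marquardt least squares with analytic starting values
($D_0$ from the lag-1 MSD, $L_0$ from the curve maximum, $\tau_0$ from
the half-plateau time).

**Classification.** A track whose minor/major principal
radius-of-gyration ratio is below 0.001 and whose maximum pairwise
displacement exceeds 2 µm is directed. Otherwise the power-law and
confinement fits compete on residual sum of squares; both models have two
free parameters, so an AIC ranking (available via `criterion = "aic"`)
is identical. Two refinements were forced by implementation experience:

* The confinement model is accepted only when its fitted τ lies within
  the fitted lag window (`require_saturation = TRUE`). In the τ → ∞
  limit the confinement model shadows any straight line with slope
  $L^2/3\tau$, so on noisy linear MSDs the raw RSS comparison is close
  to a coin flip; requiring visible saturation restores a clean
  separation without touching genuinely corralled tracks, whose τ is
  well inside the window.
* The stationary override (max displacement < 400 nm *and* D <
  0.03 µm²/s) tests the power-law D whichever model won. A flat,
  noise-dominated MSD drives the confined fit to τ → 0, making its
  derived $L^2/(12\tau)$ explode and masking truly immobile particles.

With these rules, per-class recall on synthetic cohorts of 100 tracks
per class at movie length (3000 frames, 10 ms — the acquisition length of
the tracking movies) is 100% at the nuclear Table-of-kinetics parameters;
at 1-s tracks the corralled/diffusive boundary degrades to roughly
70–90%, which is why classification benchmarks use full-length tracks.

**Parameter recovery** (`recover_motion_parameters()`) estimates each
parameter under its own model: per-track Brownian slope for diffusive D,
per-track ballistic fit for v, ensemble confinement fit for corralled
L, τ, D. Averaging per-track free-exponent D estimates is deliberately
avoided: the α–D coupling of the power law at short lags makes that mean
biased upward by on the order of 10%.

**Export events.** Docking is the first approach within 200 nm (the NPC
length scale: basket ~75 nm, central framework ~70 nm, cytoplasmic
filaments ~50 nm) of the nuclear boundary from the nuclear side; release
is the first cytoplasmic frame from which the boundary distance grows for
two consecutive frames. Transit = release − dock; under 1 s is fast, 1 s
and over slow, and a dock-to-release sub-track with gyration ratio
< 0.001 is a directed export, whose transit can also be estimated as
NPC length / speed. Boundaries are polylines (with a `nucleus_point`
disambiguating sides) or closed polygons (interior = nucleus).

## Denoising

The reconstruction objective is

$$\arg\min_g \|f - H \otimes g\|_2^2 + \lambda \|g\|_1
+ \mu \|\nabla g\|_2^2$$

with reflective boundary handling for both the convolution and the
forward-difference gradient. No solver, kernel or weights are prescribed
by the formulation, so the package chooses: proximal gradient descent
(ISTA) with optional FISTA acceleration restarted on any objective
increase, guaranteeing a monotone objective; an exact adjoint of the
reflective-padding convolution (a flipped-kernel convolution is *not*
exact at the borders and can break monotonicity at tight tolerances); a
conservative Lipschitz bound `2·mult·‖H‖₁² + 16µ` accounting for pixels
duplicated by the padding; and a default H of a normalized Gaussian with
SD 1.3 px. λ = 0.01 and µ = 0.1 are amplitude-dependent tuning knobs
for unit-scale images, not calibrated constants. The solver is tested
against a long-run oracle (objective within 0.1%) and a derivative-free
optimizer cross-check, and denoising is verified not to displace spot
centroids by more than a quarter pixel.

## Synthetic data: what it does and does not emulate

The generators define the study conditions for all desk-scale tests.

**Trajectories.** Diffusive steps are isotropic Gaussian with per-axis
variance $2 D \Delta t$; directed tracks add constant drift in a random
fixed direction; stationary tracks are a fixed point plus localization
noise (SD `sigma_loc`, default 20 nm in tests); every reported coordinate
gets independent localization noise. The corralled default is an
Ornstein–Uhlenbeck spring with per-axis stationary SD $L/\sqrt{12}$ and
relaxation $\tau = L^2/(12D)$: its MSD is *exactly* the single-exponential
confinement model, so the round trip generator → fit recovers D without
bias. A reflecting square box of side L (`corral_geometry = "box"`)
shares the plateau $L^2/3$ but relaxes multi-exponentially, and fitting
the single-exponential model to exact box-theory curves under-recovers
$D = L^2/(12\tau)$ by 11–15% at any lag window — a structural model
mismatch, which is why the spring corral is the default for a generator
whose purpose is to invert the fitted models. Directed cohorts use pure
drift ($D = 0$): the gyration-ratio < 0.001 definition of directed motion
admits essentially no transverse diffusion.

**Allele traces.** No generative model of these transcription traces is
established; the ramp-to-plateau form here is a deliberately simple
stand-in (no telegraph bursting, no k_on/k_off inference). Each cell gets
a shared log-normal extrinsic multiplier (SD 0.4 by default), each allele
an independent intrinsic multiplier (SD 0.2); allele 2 initiates after a
gamma-distributed offset with moments matched to the cohort being
emulated (gamma guarantees non-negative offsets when only mean ± SD are
reported); a configurable fraction of second alleles stays silent; raw
ROI values sit on a constant background (so pre-initiation activity is
~0) and signal and background decay together under bleaching. Traces are
sampled every 2 min over 300 min so that the slow de novo offset tail
(44.2 ± 33.5 min) stays inside the window; grid quantization adds ±1
sample of timing noise, small against the 2-standard-error tolerances
used. Passing tests on these cohorts shows the *pipeline* recovers what
the generator planted; it cannot validate the ramp-plateau form against
real transcription kinetics.

**Spot movies** are sums of 2-D Gaussian puncta, constant background and
i.i.d. Gaussian noise — no realistic PSF, no shot noise. They exist to
test ROI measurement, SNR and bleaching cancellation, not optics.

**Transcriptomes** embed repeat copies at recorded positions in uniform
random sequence; a chance exact 20-mer repeat in a few-kilobase random
decoy has negligible probability, so decoys are clean negatives.

## Problem sizes and tolerances

Test cohorts are sized for precision, not scale: 200 tracks × 100 frames
for parameter recovery (diffusive and directed within 5%, corralled D
within 10%), 100 tracks per class × 3000 frames for classification
recall (≥ 95%), 55 and 36 trace pairs for the memory cohorts (matching
the study's cell counts; tolerance two standard errors of the offset
distribution), 20-seed averages for SNR (±15%). Quantities that depend on
the original movies or external datasets — population percentages of the
motion classes, the 134/15 screened-transcript counts, observed export
times and correlation values — are represented by property-based checks
(oracle equivalence, planted-ground-truth recovery, invariances) rather
than numeric reproduction.

## Known limitations

* 2-D trajectories only; no 3-D NPC geometry or realistic optics.
* The repeat screen does not score guide thermodynamics or off-targets.
* Export-event scoring automates a protocol that is normally applied by
  eye; the dock/release rules encode that judgement explicitly.
* `run_pipeline()` drives the stages from one config with a JSON
  manifest; the package's function surface is the intended interface —
  there is no shell CLI beyond `scripts/acceptance.R`.
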