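---
title: "Profiling and connecting default mode network subsystems: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling and connecting default mode network subsystems: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Demanding external tasks usually deactivate the default mode network (DMN),
yet parts of it also activate during internally oriented cognition such as
semantic retrieval. Averaging a statistic over a whole region hides this:
within one subsystem some voxels can activate while others deactivate.
`dmnsubsys` implements an analysis chain built around a voxel-counting
statistic that keeps both directions visible, and follows it through to
resting-state connectivity and macroscale gradient space:

1. **Activation profiling.** Each participant's task-vs-implicit-baseline
   z-map is thresholded at ±τ and binarized; within each of three mutually
   exclusive DMN subsystems — medial temporal (MT), core, and frontotemporal
   (FT), defined by a labelled parcellation — the package reports the
   percentage of voxels activating (z ≥ τ) and deactivating (z ≤ −τ).
2. **Group statistics.** Condition-by-subsystem within-subject
   repeated-measures ANOVAs on those percentages, with partial η² and
   Bonferroni-corrected paired-t posthocs.
3. **Consensus seeds.** Per-voxel participant fractions of the binarized
   maps, combined across conditions and thresholded at 20%, intersected with
   the subsystem masks to give six seeds ({MT, Core, FT} ×
   {activation, deactivation}).
4. **Resting-state connectivity.** Denoised seed-to-voxel Pearson
   correlation maps (Fisher-z), paired contrasts between seeds, and
   cluster-extent familywise-error inference.
5. **Gradient localization.** Masked spatial correlation of each
   participant's connectivity maps with three whole-brain connectivity
   gradients, fed back into the same ANOVA machinery.

No participant-level fMRI is bundled; a synthetic-data module generates
every input with known ground truth, which is what the test suite and the
acceptance script exercise.

## The core statistic and its conventions

For a binarized map \(b\) and subsystem mask \(S\),
\[
  \text{pct} = 100 \cdot \frac{|b \cap S|}{|S|}.
\]

Conventions that needed fixing and why:

* **Inclusive boundary.** A voxel with \(z = \tau\) exactly counts as
  activating (and \(z = -\tau\) as deactivating). Any fixed rule would do;
  the inclusive one makes boundary tests exact, and no voxel can be in both
  masks for a single map.
* **Denominator.** The full subsystem size, not the per-participant valid
  voxel count. The synthetic generator produces full coverage so the two
  agree there; for real data with partial coverage `profile_zmap()` accepts
  a `denominator_mask`.
* **Thresholds.** τ = 1.96 by default, with 2.3 and 2.6 as robustness
  alternates. The percentage is monotone non-increasing in τ, which the
  suite asserts as a property.
* **Scale.** Percentages are kept at full float precision on a 0–100 scale;
  rounding happens only at presentation.

## Repeated-measures ANOVA

`rm_anova_within()` implements the classical within-subject partition
directly from cell means: each effect is tested against its own
effect-by-subject interaction,
\(F = \mathrm{MS}_\text{effect} / \mathrm{MS}_{\text{effect}\times S}\),
with uncorrected (sphericity-assuming) degrees of freedom, e.g.
\(F(a-1,\,(a-1)(n-1))\). Effect size is **partial η²**
\(= SS_\text{effect}/(SS_\text{effect}+SS_\text{error})\), and the output
labels it explicitly, since "η²" alone is ambiguous. A Greenhouse–Geisser
option exists but is off by default, matching the uncorrected-df reporting
convention this design targets. Two deliberate redundancies anchor
correctness: a single-factor two-level ANOVA must equal the squared paired
t (asserted to 1e-10), and the suite compares the full decomposition
against both `stats::aov(... Error(subject/...))` and a loop-based
brute-force sums-of-squares oracle.

`paired_t()` is the closed form \(t = \bar d/(s_d/\sqrt n)\), df \(= n-1\).
Zero-variance differences with nonzero mean yield an infinite t with
\(p = 0\) and a `degenerate` flag rather than an error, so voxelwise maps
stay computable; `t.test` would refuse such input, which is why the formula
is implemented directly (it cross-checks against `t.test` on regular
input). Bonferroni is \(\min(1, m\,p)\) with \(m\) supplied explicitly by
the caller (3 for the three subsystem contrasts).

## Consensus maps and seeds

Per condition, the participant fraction at each voxel is the mean of the
binary maps. Across conditions the package takes the **unweighted mean** of
the per-condition fraction maps and applies one 20% threshold: study sizes
differ (29/22/19/26 in the kind of multi-study design this targets), and
equal condition weighting is the reading most consistent with combining
"all conditions"; a `weights` argument provides the pooled-by-N alternative
for users who prefer it. The cutoff is inclusive (fraction ≥ 0.20), which
makes the 1-participant-in-5 case decidable. Seeds are the thresholded
activation/deactivation consensus masks intersected with each subsystem
mask; the activation and deactivation seeds of one subsystem may overlap,
and an empty seed is an error rather than a silent omission.

## Resting-state denoising

The chain is censor → CompCor → confound regression → bandpass:

* **Framewise displacement** uses the Power convention,
  \(\mathrm{FD}(t) = \sum|\Delta \text{trans}| + 50\,\text{mm}\sum|\Delta
  \text{rot}|\). Different toolboxes define FD differently; one convention
  with a configurable threshold (0.5 mm for resting censoring, 0.9 for
  task scrubbing) keeps behaviour predictable.
* **Global-signal spikes.** The censoring metric is the z-scored per-frame
  global mean, flagged at |z| > 3. Each flagged frame receives one spike
  regressor, so its residual is exactly zero after regression — the
  censoring is exact, not approximate. (No global-signal *regression* is
  performed.)
* **CompCor.** Within the noise ROI (a white-matter/CSF stand-in), voxel
  series are linearly detrended and variance-normalized; the top-k left
  singular vectors (k = 5 by default) are the component time series, unit
  norm, sign fixed so each component's largest-magnitude element is
  positive.
* **Bandpass.** A discrete-Fourier mask filter retaining 0.01–0.1 Hz
  (inclusive) and removing DC, applied per voxel. Regression runs *before*
  filtering rather than simultaneously; the leakage this order admits is
  bounded in the suite (out-of-band residual power < 1% on white noise).

## Connectivity contrasts and cluster inference

Seed series are extracted from fully denoised data (unweighted mean over
seed voxels); voxelwise Pearson r is Fisher-z transformed with |r| = 1
saturated to atanh(1 − 1e-7) so downstream t-tests stay finite, and
zero-variance voxels become missing rather than zero.

Cluster-extent inference is **sign-flip permutation** rather than
parametric random-field correction: clusters form at two-sided voxel
p < 0.001 on 6-connectivity (positive and negative exceedances clustered
separately), and each observed cluster's size is referred to the
permutation distribution of the maximum cluster size under random sign
flips of whole participants,
\(p_{\mathrm{FWE}} = (1 + \#\{\max_\text{perm} \ge s\})/(1 + n_\text{perm})\).
This avoids smoothness estimation entirely and is calibrated by simulation
in the acceptance suite (null familywise error within [0.01, 0.10] at
α = 0.05; a planted 50-voxel, 1.5 SD cluster at n = 20 is detected at
FWE p ≤ 0.05). Permutations are capped at the 2^n distinct sign patterns,
p-values are bounded below by 1/(n_perm + 1), and the RNG seed is part of
the configuration. Three seed contrasts are Bonferroni-corrected to 0.017.

## Gradient localization

Each participant's connectivity map is correlated with each gradient over
the voxels where mask, map, and gradient are all valid (at least 10
required). The analysis mask defaults to joint validity because no
canonical mask is implied by the operation itself; a cortex-only mask can
be supplied. Correlations are analysed directly by the
polarity (2) × subsystem (3) ANOVA, one per gradient — a Fisher-z option
exists but is off by default, since |r| stays well below saturation in
this use. Correlation is invariant to positive affine rescaling of either
input, so gradient units are immaterial.

## The synthetic generator

`simulation_spec()` fixes the emulated study conditions; the defaults are
chosen once and the tests run under them:

* **Grid and subsystems.** A 20³ grid with contiguous subsystem blocks of
  200 (MT), 800 (Core), 900 (FT) voxels — MT an order of magnitude smaller
  than the other two, echoing the real subsystem size ordering (2,680 /
  11,435 / 12,672 voxels on the 2 mm reference grid).
* **z-maps.** Planted activating voxels draw z ~ N(3.5, 0.5), deactivating
  z ~ N(−3.5, 0.5), remainder N(0, 1), so classification at τ = 1.96 of
  planted voxels is near-certain while the ~2.5% per-direction background
  tail of real thresholded maps is deliberately retained; recovery tests
  compare against planted-plus-background. Default planted fractions give
  stronger recall-than-reading activation in MT and Core and the strongest
  deactivation in Core.
* **Rest.** 180 frames at TR = 3 s (9 minutes) by default; the analysis
  drivers use 120 frames to keep the end-to-end run light. Latent seed
  signals are band-limited (0.01–0.1 Hz) unit-variance series; coupled
  voxels are β·latent + white noise with β = 0.5; a global nuisance
  component and a high-amplitude rank-2 noise ROI provide CompCor targets;
  motion files carry planted persistent steps so FD flags exactly the
  planted frames.
* **Gradients.** Orthogonalized low-order polynomials of the voxel
  coordinates, zero mean and unit variance within the mask — smooth,
  exactly orthogonal, deterministic.

What the generator does **not** emulate: hemodynamic convolution, realistic
spatial autocorrelation, anatomical geometry, inter-subsystem anatomical
adjacency structure. Passing tests therefore demonstrate the correctness
of the computations and the calibration of the inference under clean,
known-truth conditions — not robustness to the full messiness of real
fMRI.

`make_reference_atlas()` deserves a special note: it is a **synthetic
stand-in** for the publicly distributed 17-network parcellation, built on
the 91×109×91 2 mm grid with blocks of exactly the documented subsystem
sizes. It exercises the counting and resampling pathways at realistic
dimensions; reproducing the documented counts from the *real* atlas
requires downloading it and mapping its three DMN subnetwork labels to
MT/Core/FT via `build_atlas()` + `subsystem_voxel_counts()`.

## Numerical choices and degenerate inputs

* Grids compare equal when shapes match and affines agree within 1e-4 mm;
  every cross-volume operation asserts this.
* Nearest-neighbour resampling maps target voxel centres through the two
  affines (voxel-centre convention, no half-voxel shift) — categorical
  labels are never interpolated, so disjointness is preserved
  structurally and re-asserted after resampling.
* Out-of-brain voxels are NA in float volumes and 0 in binary volumes,
  distinguishing "no signal" from "signal 0" in correlations.
* Rank-deficient confound designs are refused with the collinear columns
  named; constant and duplicate confound columns are dropped before
  fitting.
* All simulations are pure functions of (spec, seed); problem sizes in the
  suite (20³ grids, n = 20 participants, 500 permutations, 100–1,000
  Monte-Carlo replicates) were chosen as the smallest at which the
  calibration bands are meaningfully testable.

## Known limitations

* First-level GLM estimation is out of scope: the pipeline starts from
  individual z-maps in a common space.
* Per-participant projection of the parcellation into native space is
  replaced by common-space masks.
* The permutation cluster inference is a documented divergence from
  parametric random-field cluster correction; with n < 8 participants the
  2^n cap makes its resolution coarse.
* The regress-then-filter order can reintroduce a bounded amount of
  out-of-band nuisance variance relative to simultaneous band-limited
  regression.
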