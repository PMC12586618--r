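---
title: "Articulatory kinematics from real-time vocal-tract MRI: methods"
author: "artikin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Articulatory kinematics from real-time vocal-tract MRI: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artikin)
```

# Overview

`artikin` implements a complete analysis chain for articulator kinematics
measured on midsagittal real-time MRI image series of speech:

1. **Grid and line profiles** — a measurement-line grid anchored on anatomical
   landmarks; each line's pixels over time form a space-by-time *line
   profile*.
2. **Gap detection** — air/tissue segmentation of the profiles with a
   constrained three-component Gaussian mixture, threshold from the dark
   component, and overlap-based tracking of the air gap per frame. The result
   is one *gap-width trajectory* per articulation site and repetition.
3. **Duration normalization** — trajectories are stretched or compressed to
   the cohort-median frame count by linear interpolation.
4. **Function-on-scalar regression** — per site, movement curves are modelled
   on group (adults who stutter, AWS, vs fluent speakers, FS) with a random
   time-varying subject effect.
5. **Dissimilarity clustering** — per repetition, the 15 pairwise
   spatiotemporal dissimilarities between the six sites (Simpson-rule L2);
   energy distances between subjects; Ward/complete hierarchical clustering;
   C-index choice of the cluster count; Fisher exact test of cluster-group
   independence; PCA with loadings; allocation scoring; and a TTR-only
   variant.

Because cohort MRI recordings of this kind are not freely redistributable, the
package ships a **synthetic vocal-tract phantom** generator that produces
trajectory cohorts — and optionally rendered image sequences — with known
ground truth. All quantitative guarantees quoted below are computed by the
test suite or by `scripts/acceptance.R`; nothing is asserted that the code
does not recompute.

# Coordinates, grid and sampling

Coordinates are `(row, col)`, 1-based, row increasing downward (image
convention). The baseline runs from the upper frontal edge of cervical
vertebra 4 (posterior) to the incisor-palate transition (anterior). Five
lines of exactly half the baseline length fan out clockwise from the baseline
midpoint:

| site   | angle | meaning                          |
|--------|-------|----------------------------------|
| TTR    | 0     | tongue tip retraction            |
| TT-TD  | 7.5   | tongue tip-to-teeth distance     |
| TT-ARD | 15    | tongue tip-to-alveolar ridge     |
| TB-PD1 | 60    | tongue body-to-palate (velar)    |
| TB-PD2 | 90    | tongue body-to-palate (velum)    |

The sixth line (LA, lip aperture) connects the upper and lower lip centers.
The historical 30/120/150-degree lines and the posterior baseline half are
constructible but unmapped; the posterior half records head motion rather
than articulation and is excluded from analysis by default. Because speakers
move between repetitions, `regridPerTrial()` rebuilds the grid per trial from
a landmark table referenced to the trial's first frame.

**Sampling rule.** Two profile readings are provided. `"bilinear"` samples
the continuous line at exact 1 px steps with bilinear interpolation — the
natural definition for oblique lines, exact for linear intensity fields
(verified to 1e-9 on ramp images). `"raster"` reads the raw grid pixels the
line lies on (nearest pixels at 1 px steps, consecutive duplicates
collapsed), the reading used by the original MATLAB-era toolboxes. The
distinction matters at air/tissue boundaries of a rasterized scene: bilinear
samples mix the two class values there, and whether a mixed sample falls
below the mixture threshold depends on lattice phase, so runs can be off by
about a pixel. Raster reading reproduces painted pixel classes exactly; it is
therefore the default in the extraction pipeline and the mode under which the
phantom ground-truth equality is exact. Bilinear extraction on the same
noiseless phantom shows a mean absolute width error well below 1 px,
concentrated entirely at run boundaries.

# Air/tissue segmentation

Grey values of one line profile are modelled as a three-component Gaussian
mixture — air (dark), uncertain (grey), matter (light) — fit by EM with an
ordered-means constraint: components are relabelled in ascending mean order
after every M-step. Initialization is deterministic at the 10/50/90
percentiles; convergence is a relative log-likelihood change below `tol`.
Component SDs are floored at 1e-3 of the data spread so that degenerate
profiles (e.g. exactly two grey levels on a noiseless phantom) stay
well-defined; such fits are flagged rather than fatal. The mixture is fit per
line profile by default; fitting per trial or per subject is a caller choice
(pass pooled values to `fitGmm3()`).

The binarization threshold is the smallest grey value above the dark mean at
which the dark component's weighted density drops below the sum of the other
two (density crossover). If the dark weight vanishes and no crossover exists,
the fallback `dark mean + 3 SD` is used and logged. Pixels strictly below the
threshold are air. Raising the threshold can only extend air runs (monotone),
which the suite checks property-style.

Gaps are tracked over frames by pixel-index overlap with the previously
retained gap; ties prefer the longer run, then the smaller start index. A
frame with no overlapping run is recorded as closed (width 0) while the last
open gap is remembered; on reopening, the candidate with the nearest midpoint
is taken. The interactive override of the original workflow is replaced by a
declarative table (frame to run index, or a forced threshold per site), and
every override is logged on the trajectory object. TTR is not a gap but the
tongue's extension: the run of tissue pixels from the line origin (baseline
midpoint) to the first tissue-to-air transition; a fully-tissue line
saturates at the line length and is flagged, an origin in air yields 0 with a
warning.

# Duration normalization

All retained trajectories are read off at the cohort-median frame count T*
using linear interpolation, with the source grid `[0, L-1]` mapped affinely
to `[0, T*-1]`; endpoints are preserved exactly and linear interpolation
cannot overshoot the source range. Durations are integer frame counts, so an
even-count median is rounded half-up. The median is taken jointly over the
cohort, not per group. Screening (stuttered or mispronounced trials, pauses
over 250 ms) is perceptual and enters as metadata flags; the assembly step
implements the bookkeeping: flagged-trial exclusion, optional dropping of
leading training repetitions, a cap of 10 analyzed repetitions per subject,
and a minimum-repetition rule, all logged.

# Function-on-scalar regression

Per site, widths are modelled as

$$y_{ij}(t) = \beta_0(t) + x_i\,\beta_1(t) + b_i(t) + \varepsilon_{ij}(t),$$

with $x_i = 1$ for AWS and $0$ for FS. A two-level ordinal group factor in
difference coding makes $\beta_1(t)$ the group mean-difference curve, so its
test is a test for a difference in the mean course. Curves are expanded in
cubic P-splines (B-splines with a second-order difference penalty,
`n_basis = min(25, T*/4)` by default); the subject curves $b_i(t)$ use a
factor-smooth basis with a ridge-type penalty; smoothing parameters are
selected by REML on the mixed-model representation (mgcv). Effective degrees
of freedom are the term-wise hat-matrix traces.

Two inference routes are provided. The Wald route uses mgcv's approximate
F-test of $\beta_1 \equiv 0$ with the term's edf. Because edf-based p-values
are approximations, the **permutation test is the primary calibrated
inference**: group labels are permuted at the subject level, the model is
refit with smoothing parameters held at their estimates, and
$p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})$. Under a null
simulation its rejection rate at $\alpha = 0.05$ sits inside [0.01, 0.10]
(200 simulated cohorts in the acceptance suite). One resolution property is
worth knowing: the complete label swap (complement) reproduces the observed
statistic exactly, so with $n$ subjects per group the attainable p-value
saturates near $2/\binom{2n}{n}$; cohorts of 8 + 8 subjects are used for the
power study for that reason.

Numerical notes: the unpenalized limit (`sp = c(0, 0)`, no subject term)
reproduces truth generated inside the spline span to machine precision; an
infinite penalty drives $\beta_1$ into the penalty null space (linear
functions for the default second-order penalty); and exact invariance under
swapping the reference group holds when the intercept curve is unpenalized —
with both curves penalized the two parametrizations penalize different
functions, so REML fits agree only approximately.

# Dissimilarities and clustering

The spatiotemporal dissimilarity between two site trajectories is the
L2 metric $\sqrt{\int (f-g)^2\,dt}$ approximated by Simpson's rule on the
common T* grid. Odd point counts use composite Simpson; even counts use
Simpson on the first T*-1 points plus a trapezoid on the last interval. All
quadrature weights are positive, so this is a weighted Euclidean norm — a
true metric, checked on random triples. The grid step is `dt = 1` frame:
absolute time scaling multiplies every dissimilarity and distance by a
constant and leaves all label-level outputs (cluster labels, k*, Fisher p,
variance shares, allocation) unchanged, which the suite verifies at a scale
factor of 3.7.

Per repetition, all 15 unordered site pairs are evaluated; the table is also
averaged per subject for the PCA. Subject-to-subject distances are **energy
distances**, $E = 2\,\mathrm{mean}\lVert a-b\rVert - \mathrm{mean}\lVert
a-a'\rVert - \mathrm{mean}\lVert b-b'\rVert$ with full $n^2$ within-averages.
Taken literally on per-subject means the within terms vanish and $E$
degenerates to twice the Euclidean distance between means; the default
`mode = "repetition"` therefore treats each subject as the empirical
distribution of its repetition-level 15-vectors (matrix-input energy
distance), and `mode = "mean"` implements the literal degenerate reading.
The two coincide exactly for single-repetition subjects.

Hierarchical clustering uses the Lance-Williams recurrence via
`stats::hclust`; "Ward's minimum variance" is `ward.D2` (applied to the
distances proper), with complete linkage as the named alternative; reports
carry the linkage used. The number of clusters minimizes the **C-index**
$(S_w - S_{min})/(S_{max} - S_{min})$ over a candidate range, ties toward
the smallest k; an all-equal distance matrix defines C = 0 with a flag, and a
flat-but-high C curve triggers a weak-structure warning. Cluster-group
independence is tested with the Fisher exact test (network-algorithm
enumeration up to n = 200, seeded Monte-Carlo with 2e5 draws beyond). PCA on
the subject-averaged table is unscaled by default — all 15 features share
width units — with standardization optional (constant columns are then
dropped and logged). Allocation accuracy generalizes the idea of
"incorrectly allocated" speakers: each cluster's predominant group is its
majority label, a subject is correct iff its group matches its cluster's
majority, and tied clusters have their members excluded from the denominator
as ambiguous. The TTR-only variant replaces the 15 pair features by the
integral of the TTR profile — the dissimilarity between TTR and a
hypothetical gap closed throughout the utterance, i.e. the Simpson L2 norm of
the TTR curve — and reuses the same distance/clustering chain.

# The synthetic phantom

`genTrajectories()` draws a cohort from a `CohortDesign`: each site trajectory
is a smooth base gesture (a baseline offset plus Gaussian bumps at
phoneme-target times of the pseudoword task), modulated by the subject's
group archetype, plus a smooth subject random curve (three Gaussian bumps
with N(0, subject_sd) amplitudes) and lightly smoothed per-frame repetition
noise, clipped at zero. Durations are integer frames, normally jittered
around the design mean with a floor of 20. Group differences are injected
primarily as altered TTR coupling — attenuated gesture amplitude
(`ttr_amp`) and a small relative timing shift (`ttr_shift`) — reflecting the
analysis' focus on dissimilarities between TTR and the other articulators.

Default study conditions: 17 FS and 15 AWS subjects, 8 repetitions,
utterances of 60 frames on average at 55 frames/s (the 9-spoke, TR 2.02 ms
radial acquisition yields 18.18 ms per image), subject SD 0.8 px, repetition
SD 0.5 px. Amplitude ranges per site are free parameters chosen to fit the
phantom geometry (gaps roughly 0-12 px, TTR around 13-20 px at 1.4 mm/px);
no per-site amplitude ranges are published for this task, so these are
package choices.

`renderPhantom()` paints each frame in three tissue classes on a 128 x 128,
1.4 mm/px scene: air background, an elliptic head region, an
uncertain-grey band, and the six measurement lines' pixel chains whose air
runs realize the (rounded) bundle widths for that frame. Ground truth is the
realized integer width table. Lines are painted with the TTR line last so
each line owns its pixels where the near-origin fan overlaps; gaps start at
least 12 px from the fan origin, where neighbouring chains are provably
disjoint (adjacent lines 7.5 degrees apart separate by more than sqrt(2) px
beyond ~11 px). Grey values are the class means plus optional per-class
spread and additive Gaussian noise — Gaussian, not Rician: the phantom's job
is to exercise the mixture segmentation, not to simulate MRI physics. With
zero noise the extraction chain recovers every programmed width exactly at
every frame and site (raster reading); with noise SD 5 on class means 60
apart the mean absolute width error stays at or below 1 px over a 100-frame
phantom.

**The three-archetype recovery design.** `threeGroupDesign()` plants the
cluster geometry the dissimilarity analysis is meant to resolve: two FS
archetypes with weak (`ttr_amp = 0.15`) and strong (`1.85`) TTR coupling and
an intermediate AWS archetype (`1.0`, shifted by 0.06). Separation is set
large relative to the between-subject spread (subject SD 0.25 px, repetition
SD 0.3 px): the recovery study validates the chain — selection of k = 3,
adjusted Rand index at or above 0.9 in at least 18 of 20 seeds, Fisher
p below 0.01 — not robustness to noise, which the two-archetype default
design (with realistic variability) probes instead. The C-index needs
within-cluster dissimilarity spread to stay below the archetype separation:
with overlapping clusters its curve flattens and larger k values win, which
is a property of the index, not of the implementation.

**What the phantom does not emulate.** Real anatomy and its variability;
head motion within a trial (the per-trial regrid supports between-trial
motion only); Rician noise, bias fields, reconstruction artefacts; acoustics
and perceptual fluency screening (exclusions enter as metadata flags).
Passing tests on the phantom therefore certify the computational chain and
its statistical calibration, not performance on clinical images.

# Problem sizes and determinism

The suite runs at deliberately reduced sizes chosen as package defaults: the
null calibration uses 200 cohorts of 4 + 4 subjects x 2 repetitions x 30
frames with 19 permutations (an exact 5% test); the power study 20 cohorts of
8 + 8 subjects with 119 permutations; the recovery study 20 seeds of the
18-subject three-archetype design; phantom checks use 2-4 trials of 30-100
frames. Every random draw flows from named integer seeds; fixed seeds make
bundles, rendered frames and pipeline outputs bit-reproducible, and
`runPipeline()` writes a manifest (package version, seed, config hash,
exclusion counts) sufficient to reproduce a run.

# Known limitations

- The Wald p-values inherit mgcv's edf approximations; use the permutation
  route for calibrated inference (and mind its resolution floor).
- Bilinear profile reading is the right choice for real images but cannot be
  pixel-exact against a rasterized ground truth; the raster reading is.
- The C-index discriminates k only when clusters are internally cohesive;
  with weak structure the package warns rather than refuses.
- `fisherExactRxC()` delegates to the network algorithm up to n = 200 and a
  seeded Monte-Carlo beyond; exact enumeration of very large sparse tables is
  out of scope.
- The phantom's geometry is schematic; its purpose is ground-truth testing.
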