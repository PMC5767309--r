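---
title: "petcad: methods, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{petcad: methods, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`petcad` is a region-based computer-aided diagnosis pipeline for
amyloid-PET-like volumes: denoise, parcellate into 116 atlas regions,
extract scale-invariant blob features per region, select significant
regions by Bonferroni-corrected two-sample t-tests on regional mean
uptake, and classify with a two-level SVM that reports a per-region
abnormality probability (local diagnosis) and a global NC/MCI call.
This vignette records the model, its assumptions, every tunable that
matters, and the design decisions taken where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Input contract

All volumes are NIfTI-1 scalar images already resampled to one common
template grid; the atlas is an integer label image on the same grid
(`check_grid_congruent()` is enforced before any cross-volume
operation, with a 1e-4 mm entrywise tolerance on the affine). No
registration, re-orientation or spatial normalization is performed —
those are upstream tool invocations, not part of this method. Voxel
indices in the R API are 1-based (the R convention); world coordinates
follow the NIfTI affine applied to 0-based indices, RAS+.

## Denoising

Each volume is decomposed with a separable multilevel symlet-8
transform, every detail subband is soft-thresholded at its own SURE
threshold, and the approximation band is left untouched.

* **Transform.** The orthonormal periodic DWT
  (`a_k = sum_j h_j x_{(2k+j) mod n}`). *Design decision:* periodic
  rather than symmetric extension, because symmetric extension with
  orthogonal filters does not admit perfect reconstruction without
  redundant coefficients; with periodic extension the constant-volume
  and intensity-shift invariances hold to machine precision, which the
  tests assert. Volumes whose axes are not even (at each level) and at
  least the filter length (16) at the deepest level get a shallower
  decomposition with a warning.
* **Depth** (`levels`, default 3, auto-capped): standard for 64–128
  voxel axes; on a 64^3 grid the cap is exactly 3, on 32^3 it is 2.
* **Noise estimate.** One global sigma =
  `median(|finest detail coefficients|) / 0.6745` (MAD). Because the
  transform is orthonormal, white noise has the same SD in every
  subband, so a single estimate serves all levels.
* **Threshold rule.** SURE per subband:
  `SURE(t) = n - 2 #(|w| <= t) + sum(min(w^2, t^2))` minimised over the
  candidate set `{0} U {|w_i|}`, ties towards the smaller threshold,
  with the classical hybrid fallback: when the signal energy
  `(sum(w^2) - n)/n` is below `(log2 n)^{3/2}/sqrt(n)` the SURE
  estimate is unreliable and the universal threshold `sqrt(2 log n)` is
  used; otherwise the SURE minimiser is capped at the universal
  threshold. An all-zero subband therefore receives the universal
  threshold (and remains zero after shrinkage).
* **Mode** (`apply_mode`): full 3D separable transform by default; a
  `slicewise-2d` mode is provided since the upstream description does
  not fix the dimensionality. Both satisfy the MSE-reduction property
  test.

## Parcellation

A voxel belongs wholly to its label (hard parcellation); label 0 is
background and never a region. Regional mean uptake is the plain
arithmetic mean over the region's voxels. If a user-supplied atlas
lacks some registry regions they are dropped with a warning and the
multiple-testing count `m` shrinks accordingly — the Bonferroni
denominator always equals the number of tests actually run. The
bundled phantom atlas always carries all 116.

## Blob features

The scale space is `L(x, sigma) = sigma^2 * Laplacian(G_sigma * I)`
computed by separable convolution with sampled Gaussian (and
second-derivative) kernels, radius `ceil(4 sigma)`, *symmetric*
boundary extension; second-derivative kernels are mean-centred so a
constant volume yields exactly zero response. Bright blobs (focal
uptake) give negative responses.

* **Scale ladder**: `sigma_k = 2^(k/3)` voxels, k = 0..9 (1 to 8
  voxels, third-octave spacing). Scales are in voxel units: inputs
  share one grid, so voxel units keep the phantom self-consistent.
  A ladder scale above a third of the smallest axis is refused.
* **Detection**: a voxel–scale pair is a blob when its |response| is a
  strict maximum over the 3x3x3x3 scale-space neighbourhood (80
  neighbours, borders clipped, ties broken towards the smallest
  scale-major linear index), at least `rel_threshold` (default 0.1) of
  the maximal |response| over the region's masked stack, and inside the
  region. The scale space is computed once on the whole volume and
  detection is masked afterwards, so region boundaries do not create
  smoothing artifacts. For an ideal Gaussian bump of width s0 the
  maximising scale is s0 * sqrt(2/3) (closed form), which the tests
  check to within one ladder step, and doubling s0 doubles the detected
  scale — the defining property of automatic scale selection.
* **Descriptor** (per region, fixed length 8): blob count, blob density
  (count / region voxels), max and mean |response|, mean and SD of blob
  sigma, mean intensity at blob centres, regional mean uptake. The
  upstream description leaves the vectorization open; this fixed-length
  summary captures count, strength, scale and uptake in a form an SVM
  can consume. *Default:* only bright blobs enter the statistics (dark
  blobs are returned by `detect_blobs()` but excluded, configurable
  via `include_dark`); with zero blobs the blob statistics are 0 by
  convention.

## Region selection

One two-sample t-test per region on regional mean uptake, MCI sample
vs. NC sample. *Design decisions:* pooled-variance Student's t (the
classical reading of "two-sample t-test"; Welch available via
`var_equal = FALSE`), two-sided p-values (a threshold was reported, not
a direction). Significance: `p < alpha_family / m` with
`alpha_family = 0.05` and `m` the number of regions tested (116 →
per-test level ≈ 0.00043). Degenerate inputs: zero pooled variance
with equal means gives t = 0, p = 1; with unequal means p = 0 plus a
warning.

## Two-level classifier

* **Level 1** — per selected region, a soft-margin C-SVM (default
  linear, C = 1; rbf and polynomial kernels available with
  gamma = 1/dim, degree 3, coef0 = 1) on the standardized 8-feature
  descriptor. Zero-variance features are dropped and recorded.
  Probabilities come from Platt's sigmoid
  `P(MCI | d) = 1 / (1 + exp(a d + b))` fitted on out-of-fold decision
  values from an internal stratified, seeded 3-fold split (falling back
  to in-sample values with the standard regularized targets when a
  fold lacks a class). Output is always strictly inside (0, 1).
* **Level 2** — a single SVM on the per-subject vector of level-1
  probabilities in a fixed region order. Probabilities (not raw
  decision values) are the level-2 input, matching the probabilistic
  reading of the first level. Global call: decision value >= 0 is MCI
  (ties favour the positive/screening class).
* **Solver.** SMO with maximal-violating-pair selection on the dense
  kernel matrix (cohorts here are tiny), C++ core, stopping when the
  maximal KKT violation is below 1e-3 (the LIBSVM default). No class
  weighting by default: the reference results (degenerate all-positive
  rows under weak kernels) are consistent with an unweighted SVM
  despite the 19/65 imbalance.
* **Evaluation.** LOSO, or stratified seeded K-fold (K = 2, 4 in the
  reference grid). Metrics (MCI positive): accuracy, specificity,
  sensitivity as percentages, rounded half-up to two decimals; the
  source tables appear truncated in places, so comparisons against
  printed cells use a ±0.02 tolerance.
* **Selection scope.** `selection_scope = "paper"` (default) selects
  regions once on the full cohort before cross-validation — this
  replicates the reference protocol but leaks test information into
  the selection. `"nested"` re-selects inside every training fold and
  is the methodologically sound alternative; the test suite audits
  that nested selection equals a from-scratch selection on each fold's
  training rows.

## The synthetic phantom

The phantom stands in for clinical scans that cannot be redistributed.
What it emulates: the study demography (19 NC + 65 MCI by default), a
brain-shaped support with baseline uptake (background 100, arbitrary
units), per-subject smooth multiplicative bias (quadratic polynomial,
peak ±5%) as nuisance structure, additive Gaussian noise (SD 10 = 10%
of background), and — in MCI — focal deposits: 3 Gaussian bumps per
affected region, width sigma = 2.5 voxels, peak = 4x noise SD
(`amplitude_factor = 4`), placed at seeded random voxels of the nine
regions the reference analysis reported significant. An NC and an MCI
subject sharing a seed differ only by the deposits.

Design decisions and admitted gaps:

* **Atlas geometry.** The 116 parcels are a deterministic balanced
  KD-style bisection of an ellipsoid (semi-axes 0.45 of each grid
  dimension), labelled in recursion order — not anatomy. Only the
  registry names and compartment cardinalities mirror the AAL atlas.
  A block-lattice-plus-merge construction was considered and rejected:
  it leaves tiny boundary cells and needs merge heuristics, while the
  bisection guarantees exactly 116 contiguous, near-equal parcels
  (≈860 voxels each at 64^3).
* **Deposits are clipped to their region.** Parcels are only ~10
  voxels across, so an untruncated bump with sigma 2.5 leaks
  appreciable mass into neighbours, which would make neighbouring
  regions significant for reasons of phantom geometry rather than
  method behaviour. Confining each deposit to its region keeps the
  planted ground truth exactly nine regions.
* **Uptake levels are engineering choices.** The source reports no
  quantitative uptake distributions; background/noise/amplitude
  defaults were chosen once as a strongly separable regime mirroring
  the reference's perfect separation, and were not revisited. A weak
  profile (`amplitude_factor = 1`) is bundled; note that even at 1x
  peak amplitude the integrated deposit mass still separates the
  groups perfectly in our hands — the profile weakens the effect but
  does not reach the partial-separability regime a real cohort would
  show. Users probing failure modes should lower `amplitude_factor`
  below ~0.3 or raise `noise_sd`.
* **Not emulated:** PET physics (scanner PSF, attenuation,
  partial-volume effects), anatomical variability, registration error,
  longitudinal change. A green test on the phantom therefore
  establishes the *software* behaves as specified under the stated
  statistical structure — not clinical performance.

## Numerical choices

* NIfTI I/O is a minimal self-contained NIfTI-1 reader/writer
  (float32/int16 output, sform affine; reads common integer/float
  types with scl scaling, sform > qform > pixdim precedence) — no R
  NIfTI package is assumed on the host.
* sym8 filter coefficients are frozen published constants; the QMF
  high-pass and reconstruction filters are derived from them.
* t-distribution tail probabilities come from R's `pt`.
* Metric rounding is half-up (not banker's), two decimals.
* Every randomized procedure (cohort simulation, K-fold shuffles,
  Platt's internal split) takes an explicit integer seed; per-subject
  streams are derived from the profile seed, so cohorts are bitwise
  reproducible.
* Fitted models serialize to JSON with a config fingerprint; loading
  refuses an artifact whose embedded hash does not match its config.

## Known limitations

* The periodic DWT boundary can smear structure across opposite volume
  faces; for brain-masked volumes (background 0 at the faces) the
  effect is negligible, but it is why the package insists on ≥ 8-voxel
  margins in practice.
* The SMO solver keeps the full kernel matrix in memory — appropriate
  for tens to hundreds of subjects, not thousands.
* `selection_scope = "paper"` is optimistically biased by
  construction; reported cross-validated numbers under it reproduce
  the reference protocol, not an unbiased generalization estimate.
* The phantom's perfect default separability means the headline
  100/100/100 is a software-correctness check, not evidence about
  clinical data.
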