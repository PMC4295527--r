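---
title: "Linking visual-dictionary models to voxel responses by searchlight variation partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking visual-dictionary models to voxel responses by searchlight variation partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Hierarchical models of visual recognition re-describe an image twice: first
with low-level oriented-gradient features, then with a *visual dictionary* of
intermediate-complexity templates. Two standard instantiations are HMAX
(Gabor filtering, local max pooling, template matching against randomly
sampled C1 patches, global max pooling) and the Bag of Visual Words model
(dense SIFT descriptors quantized against a k-means codebook). Both produce
one feature vector per stimulus at each hierarchical level. The question this
package addresses is *where in a volume of voxel responses, and to what
extent, each hierarchical level uniquely accounts for the response geometry* —
and how consistent that accounting is across subjects.

The comparison runs through representational dissimilarity matrices (RDMs):
for a stimulus set of T frames, each model level yields a T×T matrix of
pairwise Euclidean distances between feature vectors, and each brain location
yields a T×T Cityblock distance matrix `Y` between the 27-dimensional response
patterns of a 3×3×3 searchlight cube. Model and brain then live in a common
space of stimulus-pair dissimilarities.

## Distance-based variation partitioning

At each voxel the vectorized `Y` (strictly lower triangle, n(n−1)/2 entries)
is regressed on the vectorized predictor RDMs by ordinary least squares with
an intercept. Three nested regressions partition the explained variation
between two predictors `A` and `B`:

* `R²_full = R²(Y ~ A + B)`
* `unique_A = R²_full − R²(Y ~ B)`
* `unique_B = R²_full − R²(Y ~ A)`
* `shared = R²_full − unique_A − unique_B`, `residual = 1 − R²_full`

The three fractions sum to `R²_full` *by construction*; the package verifies
the identity to 1e-10 over random triples. Unique and shared fractions can be
slightly negative under suppression; they are reported raw (clamping is a
display choice, never applied before testing).

Significance per voxel comes from a Mantel-style permutation test: rows and
columns of `Y` are permuted simultaneously (stimulus-label exchange) while
the predictors stay fixed, and `p = (1 + #{perm ≥ observed})/(1 + n_perm)`.
One set of shuffles serves all four statistics of a voxel, which keeps their
nulls coherent and halves the work. Permuting vectorized entries
independently would destroy the distance structure of `Y` and is deliberately
not offered. Per-voxel permutation seeds derive from the master seed and the
voxel's linear index, so results are independent of iteration order and of
any parallel schedule.

Multiple comparisons are handled by cluster-extent correction: voxels with
`p < 0.05` are grouped under 6-neighbor connectivity (18/26 configurable) and
clusters below 25 voxels are dropped. The minimum size can be recalibrated
for any grid by `mc_cluster_size()`, which simulates independent-uniform null
p-maps (optionally smoothed Gaussian fields) and returns the smallest size
whose family-wise exceedance rate is below the target; on grids small enough
to enumerate exhaustively the Monte-Carlo answer matches the exact
distribution.

## Across-subject consistency

Per voxel we count the subjects whose surviving clusters cover it and compare
the (optionally smoothed, default Gaussian sd 1 voxel) count map against the
expected count E — the mean over masked voxels — with the frequency-count
chi-square `(O − E)²/E`. A voxel is flagged when the statistic exceeds the
upper-α quantile of the 1-df chi-square distribution *and* the deviation is
positive. A translation-permutation null (each subject's binary map randomly
circularly shifted in 3-D, max chi-square recorded per shuffle) is computed
alongside as a diagnostic. We do not use it as the significance rule: because
the shuffles preserve each subject's cluster extent, its threshold rises with
the fraction of the mask the clusters occupy, and at desk-scale simulation
sizes — where a planted region plus its searchlight halo can cover a quarter
of the interior mask — it becomes so conservative that genuinely shared
structure is never flagged. On brain-sized masks with small clusters the two
rules approach each other; both numbers are reported.

ROI summaries aggregate cluster-surviving voxels within an integer label
volume: the count of voxels significant in at least one subject, and the
maximum and mean explained variation (in percent) over subjects and their
significant voxels. Labels absent from the data produce zero rows rather
than errors, mirroring how atlas regions without signal are tabulated.

## The synthetic cohort: what it emulates, what it does not

No stimulus frames or voxel volumes are shipped; every analysis is exercised
on synthetic data with planted ground truth.

`generate_frames()` produces T stimuli (default 290, the size of the
reference stimulus set) from three visually distinct scene classes —
oriented gratings, low-pass noise textures, and composite "landscapes" with
a sky gradient, textured ground and rectangular structures. The classes give
both the Gabor/HMAX and SIFT/BoW representations a non-degenerate RDM
geometry (within-class distances below between-class distances), which pure
white-noise images would not.

`generate_subject()` plants signal at the response level, not the RDM level:
each voxel of the signal region receives one fixed random Gaussian
projection of the rows of each feature matrix, the projected time courses
are z-scored so the mixing weights `w_a`, `w_b` share a scale, and i.i.d.
Gaussian noise (`noise_sd`) is added per volume. The searchlight RDM
therefore arises through exactly the same computation as for real data.
Masked voxels outside the region are pure noise; a cohort shares the region,
weights and projections while noise stays independent per subject.

Deliberate omissions: no haemodynamic convolution (frames and volumes are
paired 1:1), no temporal autocorrelation (assumed removed upstream by
preprocessing), no motion or physiological artifacts, no spatial noise
correlation. Passing tests on this generator therefore demonstrate that the
statistical machinery recovers planted dissimilarity structure at realistic
noise levels — not that the models fit any particular real brain.

Default geometry is a 16³ grid with an inscribed ellipsoidal mask and a
centred 4×4×4 signal region, small enough that a five-subject cohort with
199 permutations per voxel runs in minutes on one CPU.

## Model parameters and defaults

HMAX. The image pyramid has 10 levels at factor 2^(−1/4) (≈4.75 octaves),
following the max-pooling lineage the model descends from; only the level
count is fixed by the reference configuration. The S1 bank holds 4
even-symmetric Gabor filters of 11 px (wavelength 0.8×size, envelope sd
0.4×size, aspect 0.3), zero-mean and L2-normalized; S1 responses are
absolute filter outputs (phase-invariant magnitude). C1 pools 10×10 windows
at stride 5 (50% overlap) over disjoint adjacent scale pairs, so 10 scales
give 5 bands. `f_gabor` is the C1 layer concatenated in fixed band →
orientation → column-major order; the C1 (rather than raw S1) reading of
the low-level representation is documented in `gabor_vector()`. S2
similarity is a Gaussian radial basis `exp(−d²/(2σ²n))` with σ = 1 and n
the patch element count, so a verbatim patch scores exactly 1; prototypes
(default P = 4096) are sampled uniformly without replacement from all
(frame, band, position, size) placements with sizes {4, 8, 12, 16} C1
cells.

BoW. Dense SIFT uses 16 px patches on a stride-8 grid — single-scale, the
common dense baseline — with the standard 4×4×8 trilinear soft binning,
Gaussian spatial weighting, L2 normalization, 0.2 clamping and
renormalization. The codebook (default M = 4000) is learned by Lloyd
iterations with k-means++ initialization, empty clusters re-seeded to the
farthest points, and a relative-inertia stopping rule of 1e-4 (max 300
iterations). Encoding is hard nearest-center assignment with ties broken by
lowest index; histograms are raw counts by default (so they sum exactly to
the descriptor count), with a frequency-normalized variant behind a flag
since both pooling conventions circulate.

All frames are resized bilinearly to one common size at ingestion — a
requirement, not a nicety, because Euclidean distances between concatenated
per-position features are undefined across unequal grids.

## Numerical choices and degenerate inputs

* R² of a constant target (zero total sum of squares) is defined as 0; a
  searchlight whose time series is constant thus yields p = 1 rather than
  an error.
* Near-collinear predictors (condition number > 1e10) fall back to a
  reduced-rank fit — the pseudo-inverse solution — with a warning; the
  identical-predictors edge case then cleanly yields zero unique fractions.
* Permutation comparisons use a 1e-12 tolerance so that an
  permutation-invariant statistic reports p = 1 exactly.
* The strictly-lower-triangle vectorization is row-major (entry (i, j),
  i > j, at position (i−1)(i−2)/2 + j); `rdm_unvectorize()` is its exact
  inverse, and asymmetry beyond 1e-9 is an error, not a silent averaging.
* Searchlights are interior-only: voxels whose cube leaves the mask are
  skipped and reported, never padded, so every analyzed voxel has the same
  pattern dimensionality.

## Problem sizes used by the test-suite and acceptance computations

The shipped checks run the full pipeline at sizes chosen to be
representative yet desk-scale: 30–40 stimulus frames of 64×64 px for the
statistical stages (the 290-frame, 128×128 reference configuration is
exercised where the quantity under test is a dimensional fact), dictionaries
of 6–32 prototypes and 12–64 words for feature-stage tests against the
4096/4000 reference sizes, cohorts of 5 subjects on 16³ grids with 199
permutations per voxel, and 3000 Monte-Carlo simulations for cluster-size
calibration. The null-calibration check places its 200 searchlights on a
stride-3 grid so the cubes do not overlap and the binomial reference band
for the rejection rate is valid. The acceptance codebook computation caps
Lloyd at 5 iterations: the reported quantity (the codebook dimensionality)
is fixed by initialization and invariant to further refinement.

## Known limitations

* Exactly two predictor families per partition; three-set partitioning and
  information-criterion model comparison are out of scope.
* Euclidean/Cityblock distances only — no correlation-distance or
  cross-validated RDMs.
* The spatial chi-square is one defensible reading of a spatial
  frequency-count statistic; alternatives (e.g. local neighborhood sums)
  exist and the translation-null diagnostic is reported to make the choice
  inspectable.
* OLS ignores the dependence among distance pairs sharing a stimulus; the
  permutation null absorbs this for inference, but the R² values themselves
  should be compared between models, not interpreted as absolute variance
  explained in an i.i.d. sense.
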