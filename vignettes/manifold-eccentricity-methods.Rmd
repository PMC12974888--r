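---
title: "Methods: Riemannian centering, manifold eccentricity, and reinstatement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Riemannian centering, manifold eccentricity, and reinstatement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis in one paragraph

`fcmanifold` tracks how the brain's large-scale functional organisation
reconfigures while people learn, unlearn, and relearn a visuomotor rotation
over two days. Per subject and task epoch, a regularised covariance matrix of
parcellated BOLD time series is treated as a point on the manifold of
symmetric positive-definite (SPD) matrices. Stable individual differences in
connectivity — which otherwise dominate any between-epoch comparison — are
removed by tangent-space centering under the affine-invariant metric. The
centered matrices are embedded into a low-dimensional connectivity manifold
whose coordinates are compared across all subjects and epochs after
Procrustes alignment to a common baseline template; each region's
*eccentricity* (Euclidean distance from the template centroid) indexes its
integration (low) versus segregation (high). Inference proceeds region-wise
(repeated-measures ANOVA with FDR control), at the ensemble level
(representational similarity of eccentricity patterns, testing whether the
Day 1 early-learning pattern is reinstated at Day 2 early relearning), and at
the network level (correlations with a behavioural Learning Score, assessed
with spatial spin permutations).

# Geometry

Covariance matrices live on the SPD cone, where the affine-invariant metric
`d(A, B) = ||log(A^{-1/2} B A^{-1/2})||_F` is the natural notion of distance:
it is invariant to joint congruence transforms, so re-expressing all signals
in a different basis does not change any distance. The package implements:

* `spd_power`, `spd_log`, `sym_exp` — eigendecomposition-based transforms
  (symmetric solvers; outputs re-symmetrized to stop asymmetry accumulating).
* `spd_geometric_mean` — the Karcher (Fréchet) mean, found by the standard
  fixed-point iteration `M <- M^{1/2} exp(mean_k log(M^{-1/2} S_k M^{-1/2})) M^{1/2}`
  with unit step, initialised at the log-Euclidean mean. Convergence is
  declared when the Frobenius norm of the mean tangent drops below `1e-8`
  (at most 50 iterations; non-convergence is an error carrying the residual).
  The solver, step size, and tolerance are package choices: the fixed-point
  map contracts quickly for the well-conditioned Ledoit–Wolf estimates this
  pipeline produces, and the log-Euclidean initialisation starts within its
  basin for every dataset we generate.
* `center_covariances` — the three-step subject centering. For subject *i*
  with epoch matrices `S_ij`: project each matrix to the tangent space at the
  subject's geometric mean, transport the tangent vector to the grand
  geometric mean with `G = S_gm^{1/2} S_i^{-1/2}`, and map back through the
  exponential map. Algebraically the composition is the congruence
  `S_ij^c = G S_ij G'`, an isometry of the metric, which is why the geometric
  mean of each subject's centered matrices lands exactly on the grand mean
  (the property the test suite checks to `1e-6`).

Near-singular inputs are guarded by an eigenvalue floor of `1e-10` times the
largest eigenvalue, applied (with a warning) before logarithms and negative
powers; genuinely non-positive-definite inputs are an error, never silently
repaired.

# From time series to eccentricity

1. **Standardisation** — each region's time series is z-scored with the
   population (`n`) denominator. The choice of denominator is immaterial to
   the covariance structure after standardisation.
2. **Epochs** — five equal 96-volume (48-trial, 2 volumes/trial) epochs per
   day: Baseline, Early/Late Learning, Early/Late Washout, after discarding
   the first 6 volumes of each scan. The task blocks fix the epoch length but
   not which 48 baseline/washout trials form the "early"/"late" windows; the
   package takes the first and last 96 post-discard volumes of the relevant
   block, which matches the ordinary reading of "early" and "late", and the
   windows are configurable.
3. **Covariance** — the Ledoit–Wolf shrinkage estimator (optimal analytic
   shrinkage toward a scaled identity). With 96 volumes over up to several
   hundred regions the sample covariance is rank-deficient; the shrinkage
   target guarantees a positive-definite estimate while leaving the
   between-region structure intact (the implementation matches
   scikit-learn's estimator to machine precision on a frozen fixture).
4. **Embedding** — per centered matrix: keep each row's top 10% of
   off-diagonal connections (`ceiling(0.10 * (n-1))` per row, ties broken
   toward the lower region index so results are reproducible; the diagonal is
   excluded and zeroed), build the cosine affinity between thresholded rows
   (negative affinities are kept: clipping would be an undocumented extra
   transform), and take the first three principal components of the
   column-centred affinity matrix. Eigenvector signs are fixed by making each
   component's largest-magnitude loading positive.
5. **Template and alignment** — the template manifold is built from the
   geometric mean over subjects of each subject's geometric mean of its two
   Baseline matrices. Every observation's embedding is aligned to the
   template by translation plus a best-fitting orthogonal rotation
   (no isotropic scaling — scaling would rescale eccentricity magnitudes
   across epochs and absorb exactly the contractions and expansions under
   study).
6. **Eccentricity** — the Euclidean distance of each aligned region from the
   *template's* centroid, which is the origin of the template space. Using a
   fixed centroid for all epochs is deliberate: per-epoch centroids would
   absorb the coordinated shifts being measured.

# Inference

* **Region-wise rmANOVA** — a 2 (Day) × 5 (Epoch) within-subject ANOVA per
  region with the classical effect-by-subject error strata and *no*
  sphericity correction, so the Epoch effect has `(4, 4(n-1))` degrees of
  freedom (and the 7-epoch similarity follow-up `(6, 6(n-1))`). The
  closed-form implementation is vectorised across regions and is checked in
  the tests against `aov()` with an `Error()` stratum.
* **FDR** — Benjamini–Hochberg step-up at `q = 0.05` (via `p.adjust`,
  verified against a brute-force threshold search).
* **Functional ensembles** — k-means (`k = 4`, 25 seeded restarts,
  best-inertia solution) on the significant regions' template coordinates;
  clusters are relabelled by descending size with ties broken by the lowest
  member region index, and annotated with their modal network.
* **Reinstatement RSA** — per subject, the Pearson (or, as a rank-based
  control, Spearman) correlation between the regional eccentricity pattern at
  Day 1 Early Learning and each of the seven subsequent learning-related
  epochs, restricted to an ensemble's regions; the omnibus is a one-way
  rmANOVA over the seven epochs, followed by one-tailed paired t-tests of
  "similarity to Day 2 Early Learning exceeds similarity to epoch X". The six
  one-tailed contrasts are reported without multiplicity correction, matching
  standard reporting for planned follow-ups after a significant omnibus.
* **Spin test** — network-level correlations between eccentricity change and
  a behavioural score are referred to a spatial permutation null: a uniform
  random rotation of the regions' unit-sphere centroids (mirrored across
  hemispheres; regions never cross the midline), greedy one-to-one
  nearest-neighbour reassignment, and recomputation of the network
  correlations. P-values use the add-one convention
  `(1 + #{|null| >= |obs|}) / (1 + n_perm)` so they are never zero, with
  BH-FDR across the seven networks. The exact rotation/matching variant in
  this family is not standardised; the greedy mirrored-rotation scheme used
  here preserves spatial autocorrelation, which is the property the null
  needs. When centroids are unavailable a plain label permutation can be
  requested explicitly and is flagged in the output.

# Behaviour

Trials with reaction times strictly below 100 ms or above 2000 ms, or without
movement initiation, are flagged (never deleted). Errors are averaged into
8-trial bins; bins whose trials are all excluded are linearly interpolated
before smoothing. Initial error is the median of a learning block's first 16
trials; savings is Day 1 initial error minus Day 2 initial error (degrees).
The adaptation proxy is `A = 45° − |error|` and the recall ratio
`RR = A(D2 early) / A(D1 late)` over the same 48-trial windows used for
imaging (the windows are configurable; the source protocol does not give
them numerically). When late Day 1 adaptation falls below the 5° stability
threshold, RR is undefined and the subject is excluded from RR correlations
only — the alternative reading (flooring the denominator) is available by
computing the proxy directly, but exclusion is the default because the
protocol's wording ties the threshold to interpretability of the ratio, not
to a censored value.

The **Learning Score** is the first functional principal component of the
smoothed two-day binned error curves: each curve is represented in a cubic
B-spline basis with 17 basis functions (equally spaced knots; a basis that
must be coarser than the bin grid) and a second-derivative roughness penalty
whose weight is chosen by generalized cross-validation over
`10^seq(-8, 2)` and recorded in the fit. Functional PCA is performed on the
smoothed curves under uniform quadrature weights; fPC1 loadings are
sign-fixed so that higher scores mean lower overall error, and the fast/slow
learner split is a strict-greater-than-median rule (equal halves at even n).

# The synthetic study

No raw data accompany the design, so validation rests on a generator whose
ground truth is known exactly. Its defaults define the study conditions used
throughout the package (24 subjects, 100 regions in 7 networks, 2 days × 5
epochs × 96 volumes):

* **Base covariance** — within-network blocks over a 0.05 between-network
  floor, with *network-specific* coupling (0.60 down to 0.16 across the seven
  networks) and a small fixed jitter. The heterogeneity is essential, not
  cosmetic: with equal blocks the affinity matrix's network contrasts are
  eigenvalue-degenerate, the retained 3-component subspace becomes an
  arbitrary rotation among them, and eccentricity is dominated by subspace
  flicker. Real cortical networks differ widely in coherence; the spread
  keeps the leading components (and therefore the template space) stable.
* **Effects in tangent space** — each subject's stable signature `D_i`
  (entry SD 0.10), each epoch's shared effect `E_j` (entry SD 0.01), and
  idiosyncratic per-observation noise (entry SD 0.01) are symmetric matrices
  added at the base point and mapped through the exponential map, so every
  generated covariance is SPD for any effect scale.
* **Planted contraction** — the ten Default-network target regions undergo a
  *graded dissolution* of their community profile during both days' Early
  Learning epochs: target *k* retains `r_k` of its within-network edges
  (graded from about half down to a fifth of them, realised exactly by a
  Havel–Hakimi degree construction), the dropped edges fall to the
  between-network floor, and a small diffuse gain (0.4 × effect size) spreads
  toward the weakly clustered networks. Two properties motivated this
  construction over the more obvious "raise between-network coupling"
  variants. First, confinement: because covariance perturbations are
  symmetric, routing a target's freed connectivity into any strongly
  clustered community measurably perturbs that community's members through
  shared-neighbourhood affinity; steering it toward the diffuse periphery
  keeps the perturbation confined to the targets. Second, pattern: a
  *uniform* contraction moves all targets equally and leaves nothing for
  pattern-similarity analysis to correlate; the graded dissolution imprints a
  reproducible spatial gradient across targets, which is exactly what the
  reinstatement analysis detects when the two days' Early Learning effects
  are set identical (`reinstatement = TRUE`).
* **Behaviour** — learning-block errors decay as `45°·exp(−rho_i·t)` with
  log-normal subject rates, a washout aftereffect of opposite sign decaying
  twice as fast, near-zero baseline error, Day 2 rates scaled by a savings
  factor of 1.5, and reaction times within the QC bounds except for a 1%
  contamination fraction.
* **Null switches** — `epoch_shuffle` hands each subject the ten epoch
  effects in an independently permuted order (with `reinstatement = FALSE`
  this makes epochs exchangeable across subjects, the null used to calibrate
  the omnibus), and `effect = "none"` removes the planted perturbation.

What the generator does *not* emulate: hemodynamics and temporal
autocorrelation (an AR(1) switch exists, but the pipeline does not model
autocorrelation either), motion and physiological artefacts, spatial
smoothness of the parcellation beyond network membership, and heavy-tailed
behavioural lapses. Passing tests therefore demonstrate that the
implementation recovers known structure through the full pipeline under the
stated statistical model — not that the pipeline is robust to every nuisance
in real fMRI.

# Problem sizes and numerical choices

The validation suite runs the silhouette experiment at the default 24 × 100
scale with strong subject effects (entry SD 0.18, the "subject effects
dominate epoch effects" condition), and the planted-effect experiments as 50
seeded replicates of the full pipeline at 14 subjects × 70 regions — 70
regions puts exactly ten regions per network so the Default network coincides
with the ten targets, and 14 subjects is a realistic single-site cohort at
which the region-wise tests have high power for the planted effect while
remaining insensitive to the method's small global spillover (any localized
connectivity change shifts the global eigenstructure slightly; at much larger
samples those ~0.05 eccentricity shifts in distant networks become formally
significant, which is a property of the manifold method itself worth knowing
about when interpreting real data).

Other numerical choices: all eigendecompositions use symmetric solvers;
Procrustes uses the SVD of the cross-covariance of centred coordinates;
k-means and the spin test take explicit seeds and restore the caller's RNG
state; permutation p-values are add-one; thresholding ties break toward lower
region indices; and every file format is plain text so that full runs are
byte-reproducible from the manifest (config + seeds), which the determinism
test checks via file checksums.

# Known limitations

* Eccentricity compresses a region's 3-coordinate displacement to a scalar;
  opposite movements along a component are indistinguishable in eccentricity
  alone (the embeddings are retained in the results for directional
  follow-up).
* The manifold is global: strong focal connectivity changes displace other
  regions slightly. The package reports region-level statistics with FDR
  control, but at very large samples "significant" need not mean "large".
* The Karcher mean solver assumes reasonably conditioned inputs, which
  Ledoit–Wolf shrinkage provides; raw sample covariances with `p > n` are
  singular and will be rejected.
* The spin test assumes unit-sphere centroids per hemisphere; subcortical
  structures without a spherical embedding need the label-permutation
  fallback, which does not preserve spatial autocorrelation.
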