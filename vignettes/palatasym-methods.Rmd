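---
title: "Quantifying directional and fluctuating asymmetry in 3D palatal shape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying directional and fluctuating asymmetry in 3D palatal shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palatasym)
```

## The problem

The hard palate is a bilaterally symmetric structure with a midline (the
median palatine suture), so its left and right halves can be compared within
a single individual. Deviations from perfect bilateral symmetry decompose
into *directional asymmetry* (DA) — a mean left–right difference shared by a
group, usually attributed to lateralized function such as chewing side
preference, tongue movement and speech — and *fluctuating asymmetry* (FA) —
random individual departures from the group's asymmetry pattern, commonly
read as a signal of developmental instability. `palatasym` implements the
full measurement chain for landmark data on such a structure: template
schema, superimposition, the object-symmetry decomposition, DA/FA statistics
at configuration and per-landmark resolution, and the surrounding battery of
group comparisons. Antisymmetry (bimodal asymmetry with no consistent
direction) is deliberately out of scope; no accepted multivariate method
exists for shape data.

## Data model

A configuration is a fixed set of 41 three-dimensional points: 5 anatomical
landmarks (Incisor, Ento-left, Ento-right, Post-foramen, Middle), 12 curve
semilandmarks on the left/right alveolar (cervical-line) curves and the
median suture, and 24 surface semilandmarks, 12 per hemi-palate. The schema
(`palate_schema()`) records each point's role, side and bilateral partner:
the pairing map is an involution whose fixed points are exactly the seven
midline landmarks (ids 1, 4, 5, 38–41). Everything downstream — mirroring,
relabelling, per-landmark tables — is driven by this schema, and a
user-supplied schema is validated against the same invariants (involution,
mirrored sides, matching roles). The curve anchoring (left curve between
landmarks 1 and 2, right between 1 and 3, median between 4 and 5) is one
reading of the template geometry and is configurable through the schema's
`curve_anchors` attribute.

## Superimposition

`gpa()` performs generalized Procrustes analysis: configurations are
centred, scaled to unit centroid size, and iteratively rotated to the
consensus until the consensus stabilizes (RMS change below 1e-10, at most
100 iterations — standard practice; the objective is non-increasing by
construction). Two choices deserve comment:

* **Rotations only, never reflections.** The Kabsch solution is
  sign-corrected to determinant +1. This is essential here: the reflected
  copies must remain reflected, otherwise the asymmetry signal is destroyed.
* **Frame fixing.** A Procrustes fit is only defined up to a global
  rotation. We fix the frame by rotating the consensus onto its principal
  axes with axis signs chosen by coordinate skewness, which makes the output
  deterministic and independent of how the input specimens happened to be
  oriented. For the doubled (originals + mirrored copies) fit,
  `symmetry_frame()` further rotates the shape space so that the consensus'
  symmetry plane is exactly x = 0 with the left side at negative x; in that
  frame reflection is literally "negate x and relabel", and the symmetric
  component of each individual is reflection-invariant to numerical
  precision.

One *pooled* superimposition of all originals and copies across groups is
the default, because between-group comparisons of DA and FA require a common
shape space; a per-group mode (`gpa_mode = "per_group"`) is available for
within-group analyses that want each group's own consensus.

## Semilandmark sliding

Semilandmarks carry deficient homology: their position along a curve or
across a surface is arbitrary. `slide_semilandmarks()` relaxes them by
minimizing the thin-plate-spline bending energy relative to a reference
(template or current consensus). Per iteration, curve points get one degree
of freedom along the local polyline tangent and surface points two in the
local tangent plane of the mesh; the energy-minimizing tangential
displacements have a closed-form generalized-least-squares solution, after
which points are projected back onto their curve or surface and the step is
accepted only if the energy decreased. The 3D TPS kernel is implemented with
the sign convention U(r) = −r, under which the bending-energy matrix is
positive semidefinite with the affine functions of the reference as its
exact null space — a requirement for the minimization to be well posed
(affine deformations cost nothing; energies are non-negative). During GPA,
sliding is interleaved with consensus updates when geometry is supplied. The
pipeline defaults to sliding off: its input configurations (digitized or
simulated) are treated as already relaxed against the template, which
mirrors how palate templates are produced in practice, and per-specimen
meshes are typically not available for a whole collection.

## The asymmetry decomposition

For each individual `i`, a mirrored copy is created by negating x and
relabelling paired landmarks, and both versions enter the joint GPA. With
aligned original \(O_i\) and reflected copy \(RR_i\):

* asymmetry vector: \(a_i = O_i - RR_i\)
* symmetric component: \((O_i + RR_i)/2\) (reflection-invariant)
* group DA vector: \(\bar d_k = \operatorname{mean}_{i \in k}(a_i)\), and
  the scalar \(DA_k = \lVert \bar d_k \rVert\) — identical whichever way
  round the difference is taken
* individual FA: \(FA_i = \lVert a_i - \bar d_k \rVert\)

Per-landmark values are the Euclidean norms of the corresponding three
coordinates, one scalar per landmark — 41 values per group for DA, 41 per
individual for FA, which is what makes the between-group ANOVA bookkeeping
come out at \(6 \times 41 - 6 = 240\) and \(183 \times 41 - 6 = 7497\)
residual degrees of freedom under the six-group, 183-individual design.

A note on sign conventions: defining \(a_i = O_i - RR_i\) and
\(\bar d_k\) as its group mean makes the FA deviations exactly centred
within each group; defining the group vector with the opposite sign would
leave FA deviations uncentred while changing no scalar (all reported
quantities are norms).

**Bias of the plain DA estimator.** \(\mathbb E\lVert\hat d\rVert^2 =
\lVert d\rVert^2 + \operatorname{tr}(\Sigma)/n\): the norm of a noisy mean
overestimates the norm of the truth, noticeably so when the true DA is small
relative to FA noise. `asym_decompose()` therefore also reports
`da_unbiased` \(= \sqrt{\max(0, \lVert\hat d\rVert^2 - \sum_i FA_i^2 /
(n(n-1)))}\), the standard unbiased-norm estimate. The plain norm remains
the headline DA (it is the conventional definition); the unbiased version is
what the parameter-recovery experiment uses, since proportionality across
injected magnitudes is only expected of an unbiased estimate.

## Statistical battery

* **Procrustes ANOVA of object symmetry** (`procrustes_anova_symmetry()`),
  per group: sums of squares over all landmark coordinates decompose into
  Individual (df \(n-1\)), Reflection = DA (df 1) and Individual ×
  Reflection = FA (df \(n-1\)); both F ratios use the interaction as error
  term. p-values are permutational: the reflection effect is tested by
  randomly swapping the two sides within each individual (a sign flip of
  \(a_i\) — the exchangeable operation under the no-DA null, and exact for
  sign-symmetric errors), the individual effect by residual randomization
  under the side-means-only reduced model. Reported p is
  (extreme + 1)/(permutations + 1), so 1/(B+1) is the attainable floor;
  999 permutations by default, 499 available where a coarser floor matches
  historical output.
* **Between-group DA/FA ANOVA + Tukey HSD** on the per-landmark scalars,
  with parametric F p-values (a permutation option exists): landmark-level
  values are treated as exchangeable replicates, exactly as in the source
  workflow. This ignores spatial autocorrelation among neighbouring
  landmarks and should be read as a descriptive comparison; the pipeline
  notes this caveat in its run log. Tukey intervals are Tukey–Kramer via the
  studentized range; a compatibility flag additionally Bonferroni-multiplies
  them (statistically redundant, off by default).
* **PERMANOVA and dispersion homogeneity** on the Procrustes distance
  matrix delegate to `vegan::adonis2` and `vegan::betadisper` +
  `permutest` (centroid type by default). The pipeline uses them as the
  pooling gate: collections are compared within each age group, and the
  sample is pooled when no group shows a significant collection difference.
* **Kruskal–Wallis + Dunn** across landmarks (midranks, tie-corrected
  variance, Bonferroni over all 820 landmark pairs), **Spearman** rank
  correlation of per-landmark DA profiles between groups, and
  **Mann–Whitney** sex comparisons (exact by enumeration for small untied
  samples, tie-corrected normal approximation with continuity correction
  otherwise). Sex tests are skipped for the youngest groups (labels I–III),
  where skeletal sex is unreliable, and for the indeterminate-sex
  individual.

Every stochastic routine takes an explicit seed; the pipeline derives one
seed per stage from its master seed, so identical configurations produce
byte-identical output tables.

## The synthetic generator

`simulate_population()` provides ground truth that real collections cannot:

* **Template geometry:** a triangulated half-ellipsoid dome (default
  semi-axes 25 × 25 × 12 mm — a 50 mm palate-like vault) with two lateral
  alveolar curves and a median-suture curve; curve semilandmarks are placed
  at exact 20%-arc-length spacing between their anchors, surface
  semilandmarks on a parametric grid of the right hemi-dome mirrored to the
  left, all points lying on their geometry.
* **Individuals:** template × group growth scale, plus symmetric individual
  variation (a random field symmetrized across the midline, SD 0.5 mm),
  plus half the antisymmetrized DA field of the group, plus half an
  antisymmetrized random FA field (SD 0.1 mm), plus isotropic measurement
  error (SD 0.05 mm, the accuracy of the structured-light scanner class the
  data emulate), then a random rigid motion and ±3% scale jitter so the
  superimposition is actually exercised.
* **Exact ground truth:** injected DA fields are antisymmetrized *and*
  projected orthogonal to the antisymmetric similarity generators
  (x-translation, rotations about the in-plane axes), so a Procrustes fit
  cannot absorb any of the injected magnitude; the generator records the
  expected Procrustes-unit DA (injected mm / template centroid size) for
  every group. Default group magnitudes (0.3, 0.5, 0.35, 0.25, 0.25,
  0.45 mm on the anterior surface and posterior molar landmarks) emulate
  the reported pattern of anterior-dominated asymmetry varying across
  growth stages; the growth model itself (isotropic scaling 0.55–1.0) is
  deliberately non-biological.
* The default group sizes follow the published design via
  `study_preset()`: 5/14/11/26/82/45 individuals (183 total) across six
  dental-eruption age classes, with the matching male/female/indeterminate
  and collection splits.

The generator stays in the small-perturbation regime (asymmetry ≤ 2% of
centroid size), where the Procrustes projection is near-linear and injected
and recovered quantities are directly comparable. What passing tests on
these data do *not* show: robustness to digitization error structure beyond
isotropic noise, to spatially correlated FA, to allometry beyond isotropic
growth, or to missing/mislabelled landmarks.

## Validation experiments and problem sizes

`da_recovery_experiment()` (defaults: magnitudes 0.25/0.5/1.0 mm on the
50 mm dome, 30 individuals per group, FA noise 0.1 mm, 20 replicates)
checks that pooled unbiased DA estimates scale proportionally with the
injected magnitude and that the reflection effect is detected at p ≤ 0.01
at the largest magnitude. `type1_calibration()` (200 null simulations per
test, 199 permutations each, 10 individuals per Procrustes-ANOVA null,
15 + 15 and 3 × 10 observations for the distance-based and rank tests)
estimates type-I error at the nominal 5% level for the reflection test,
PERMANOVA, dispersion homogeneity and Kruskal–Wallis. With 200 simulations
a rejection-rate estimate carries a binomial standard error of ≈ 0.015, so
individual estimates routinely land anywhere in roughly 0.02–0.08 even for
an exactly calibrated test — worth remembering when reading a single seeded
run. The full 183-individual pipeline with 199 permutations per test runs
in a few seconds; the whole validation suite in a few minutes on one CPU.

## Numerical choices and degenerate inputs

* GPA convergence: consensus RMS change < 1e-10, ≤ 100 iterations;
  non-convergence returns the fit flagged `converged = FALSE` with a
  warning rather than failing.
* Rank-deficient rotation problems (collinear configurations) are
  tie-broken toward the identity rotation.
* TPS systems with duplicated reference points raise an error naming the
  duplicates; references need ≥ 5 non-coplanar points.
* Sliding accepts a step only if the (projected) bending energy does not
  increase; the trace it returns is therefore non-increasing by
  construction. Near-singular tangent systems get a tiny ridge
  (1e-12 × scale) before solving.
* Degenerate mesh faces (zero area) are dropped at bundle construction and
  never used for projection; projections that leave the padded geometry
  bounding box raise an error instead of silently extrapolating.
* Zero-centroid-size and non-finite configurations are rejected at
  validation, reported rather than thrown where the contract is
  report-based.
* All landmark file writers emit full double precision (round trips are
  exact well below 1e-9 mm and byte-stable), and all table output is
  deterministic TSV.

## Known limitations

* The occlusal-plane construction used to define the midsagittal plane in
  the original digitization protocol is not reproduced; the operational
  substitute is the best-fit plane through the midline landmarks, which is
  equivalent for symmetric templates and testable.
* Landmark-level inference (Tables of DA/FA per landmark) inherits the
  exchangeability assumption discussed above.
* Sliding against per-specimen surface geometry requires those surfaces;
  without them the pipeline analyses configurations as digitized.
* The growth model of the generator is a stand-in, not a model of palatal
  biology; conclusions about real ontogenetic series require real data.
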