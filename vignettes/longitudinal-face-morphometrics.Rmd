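---
title: "Longitudinal analysis of dense facial quasi-landmarks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal analysis of dense facial quasi-landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morpholong)
```

## The problem

Orthodontic treatment, growth, ageing and many clinical interventions change
the soft-tissue face by fractions of a millimetre to a few millimetres over
months. Detecting and localizing such changes requires (i) dense
correspondence across faces and time points, (ii) a superimposition that
removes nuisance variation in position, orientation and size, and (iii)
statistics that respect the repeated-measures structure of longitudinal
imaging. `morpholong` implements this pipeline for spatially dense 3D
quasi-landmarks — surface points placed by template registration rather than
anatomical definition, corresponding across individuals by template index —
and ships a synthetic-cohort generator with exact ground truth so that every
stage of the pipeline can be validated without access to identifiable
patient imagery.

## Quasi-landmark mapping

Raw surface scans become landmark configurations by mapping a fixed
template (an anthropometric mask of k points) onto each target mesh:

1. a least-squares **similarity transform** (rotation, uniform scale,
   translation; never a reflection) aligning the template's five anchor
   landmarks — right exocanthus, left exocanthus, pronasale, right
   cheilion, left cheilion, digitized in that fixed order — to the
   subject's anchors;
2. a 3D **thin-plate-spline** warp with kernel U(r) = r through the five
   anchor pairs (exact at the anchors, affine-reproducing, minimal
   bending);
3. **closest-point projection** of every warped template point onto the
   target surface (exact point-to-triangle distances; equidistant
   triangles resolve to the lowest triangle index).

This mapper is deliberately transparent and deterministic. It is *not* a
re-implementation of dense iterative mesh registration toolchains: with
only five controls it recovers similarity-transformed faces essentially
exactly and normal-direction displacement well, but large smooth
subject-specific deformations can only be followed up to the accuracy of
the anchor-driven warp. Users with externally mapped configurations can
enter the pipeline directly through `read_configuration()`; a configurable
gate (default 30 mm anchor-to-surface distance) guards against gross
registration failure. An optional one-pass refinement was considered and
rejected: determinism and testability of the mapping stage were judged more
valuable than marginal fidelity gains that the downstream statistics do not
depend on.

## Symmetric-component Procrustes superimposition

Faces are bilaterally symmetric to good approximation, and treatment
questions here concern the symmetric part of shape. Each configuration is
therefore paired with its **reflected relabelled copy** (mirror across
x = 0, then swap left/right partner rows, `reflect_relabel()`), and the 2n
configurations are superimposed jointly by **Generalized Procrustes
Analysis**: center, scale to unit centroid size, rotate to the current mean
by SVD-based orthogonal Procrustes restricted to determinant +1,
re-estimate and renormalize the mean, iterate. The landmark-wise average of
each original and its reflection is the **symmetric component**, the input
to all downstream statistics. Asymmetry analysis is out of scope by
design.

Numerical choices:

- convergence tolerance 1e-10 on the RMS displacement of the mean shape,
  `max_iter = 100`; non-convergence returns a flagged partial result with a
  warning rather than an error;
- every configuration is fixed at unit centroid size each iteration
  (classic GPA, not the variable-scaling partial-Procrustes variant);
- reflections can enter only through `reflect_relabel()`; the rotation
  solver flips the smallest singular vector whenever the unconstrained
  optimum would be improper;
- **Procrustes distance** is the Euclidean norm of the coordinate-wise
  difference between superimposed shape coordinates. At the shape distances
  of dense facial data (~0.01) this differs from the full Procrustes chord
  distance at O(PD³), and it makes distances, distance matrices, and the
  coordinate-space sum-of-squares decomposition exactly consistent — the
  two-shape GPA distance agrees with a brute-force rotation-search
  superimposition to the tolerance of the search;
- **form coordinates** are shape coordinates multiplied by centroid size
  (mm); **millimetre reporting** of per-landmark change multiplies shape
  coordinates by the grand mean centroid size of the dataset. The
  rescaling rule is recorded in outputs (`mm_scale`), since other choices
  (per-subject size, median size) are defensible.

Internal landmark and face indices are 1-based throughout, the R
convention; PLY's 0-based and OBJ's 1-based face records are converted at
the file boundary. Only ASCII PLY is read or written, and binary PLY is
rejected explicitly rather than silently misread.

## Distance-matrix PERMANOVA with restricted permutations

Stage and treatment effects on the n x n matrix of pairwise Procrustes
distances are tested by permutational MANOVA: the distance matrix is
Gower-centered and partitioned by **sequential (Type I) sums of squares**
for the model `stage + group + stage:group`, fitted in that order via
projection matrices; pseudo-F is the usual ratio of term to residual mean
squares. For Euclidean distances this decomposition coincides exactly with
the coordinate-space linear-model decomposition (verified against both
explicit `lm()` refits and `vegan::adonis2`).

Longitudinal observations are exchangeable only within a subject, so
permutations are **restricted**:

- the stage and interaction terms shuffle stage labels *within each
  subject*;
- the group term permutes group labels *between subjects* (whole-subject
  exchange).

A within-subject shuffle cannot move a between-subject factor: its
permutation distribution for the group term is degenerate around the
observed value. Because published analyses of this kind nonetheless
report a single within-participant scheme, both modes are available
(`permutation_scheme(..., rules = ...)`); the split-rule default is the
package's own resolution of that ambiguity and is recorded in the output
attributes. Further conventions:

- p = (#\{F\* ≥ F_obs\} + 1) / (B + 1), identity permutation included, so
  p ≥ 1/(B+1) and p is never 0; the default B is 10,000;
- when the restricted permutation group has at most 1024 elements the
  exact p over the full enumeration is returned instead (automatic for,
  e.g., 5 subjects x 2 stages: 2^5 = 32 relabellings);
- ties in F are counted with a relative tolerance of 1e-8 so that exact
  enumeration is invariant to floating-point noise;
- subjects observed at a single stage contribute no shuffling and are
  reported via a message; subjects with missing stages shuffle only among
  their observed stages;
- a response with zero total sum of squares raises an error (pseudo-F
  undefined) instead of returning numbers;
- **partial R²** for a term is SS_term / (SS_term + SS_residual), the
  coefficient of partial determination; for orthogonal designs this equals
  the reduced-versus-full-model formulation
  (SSE_reduced − SSE_full)/SSE_reduced.

Post-hoc pairwise stage comparisons (`pairwise_posthoc()`) restrict to
subjects observed at both stages, report the Procrustes distance between
stage mean shapes, the stage partial R² and a within-subject permutation p.
The **per-landmark analysis** applies the same model to the three
coordinates of each landmark separately (computed in coordinate space,
identical to the distance formulation and far cheaper for thousands of
landmarks), reporting stage R², raw permutation p with
Benjamini–Hochberg-adjusted values alongside — raw p is the default for
display because dense p-maps are conventionally drawn unadjusted — and
mean displacement vectors and magnitudes in mm per stage pair. GPA spreads
a displacement concentrated at one landmark over all landmarks (the
Pinocchio effect); against a no-superimposition oracle this leakage stays
within ~5% for an isolated 2 mm displacement on the default template, which
bounds the localization bias of the heatmaps.

**Procrustes variance** (morphological disparity) of a group is the mean
squared distance of its members from the group mean (1/n convention).
Pairwise differences are tested by permuting the group-mean-centered
residual squared norms among observations; the reported ΔVar is signed
(a − b) while the test is two-sided on |ΔVar|. Groups of size one have a
defined variance but no test. **Form-space analyses** run the identical
machinery on shape × centroid size, so a pure size change that shape space
cannot see is detected in form space, and when all sizes are equal the
form pseudo-F and p reproduce the shape ones exactly.

## The synthetic cohort generator

`make_template()` samples a bilaterally symmetric face-like surface (an
ellipsoidal shell with nasal, labial and orbital relief at life-like
millimetre scale) on two mirrored structured half-grids, giving exact
symmetry, a triangulation, outward normals, parametric region labels
(buccal, temporal, labial, nasal, other) and the five canonical anchors.
The default half-grid gives k = 720 landmarks, a one-tenth-scale analogue
of a 7160-point anthropometric mask; statistical behaviour of the tests is
insensitive to k at this scale while runtime is not, and the full scale
remains available through `k_half`. An exactly even k with a structured
grid cannot hit every integer, so the default is the nearest achievable
size.

`simulate_cohort()` emulates a 43-subject, three-stage (T0/T1/T2) cohort
split 22/21 into extraction and non-extraction groups:

- a **stage displacement field** along outward surface normals, localized
  by region (defaults: buccal −1.5 mm and temporal −1.0 mm invagination,
  labial +1.5 mm protrusion with +0.5 mm extra in the lower lip), smoothed
  over the surface (Gaussian, 8 mm) and exactly symmetrized; the second
  interval (T1 to T2) is one sixth of the first, and either interval can be
  rescaled to an exact mean per-landmark magnitude via `target_mean_mm`;
  fields accumulate across stages by construction, so the T0 to T2 field is
  the sum of the interval fields;
- a smooth **per-subject deformation** (20 Gaussian radial-basis centers,
  25 mm bandwidth, symmetrized, scaled to 1.5 mm per-coordinate RMS),
  chosen so between-subject shape distances (~0.03) exceed stage-effect
  distances (~0.01) — the regime that motivates restricted permutations;
- iid landmark **noise** (0.2 mm per coordinate), the only asymmetric
  ingredient: configurations are exactly symmetric before noise;
- a random **nuisance similarity transform** per observation (rotation up
  to 15°, translation up to ±50 mm, scale 0.9–1.1), which GPA must remove
  — with all effects and noise at zero, superimposed shapes agree to
  below 1e-9;
- no group effect by default, matching a null treatment-modality effect;
  `group_effect_mm` injects one when needed.

All draws derive from one master seed in a fixed, documented order
(subject, then stage), so cohorts are byte-reproducible. The generator
stores every applied field as **ground truth**, including the implied
Procrustes distance between noise-free stage means (`ground_truth_pd()`),
which the pipeline estimate approaches as noise vanishes.

What the generator does *not* emulate: photorealistic texture, expression
and posture variation, scanner artefacts (holes, topological noise),
correlated (spatially smooth) measurement error, and demographic
covariates. Passing tests therefore demonstrate correctness of the
statistical machinery under a realistic geometry and effect structure, not
robustness to every pathology of clinical scan data.

## Validation design and problem sizes

The test suite checks each operation against an independent oracle (naive
summation, dense hand-built TPS solve, rotation-grid-plus-refinement
superimposition, explicit `lm()` refits, full permutation enumeration,
`vegan::adonis2` for the unrestricted decomposition) and the pipeline
end-to-end against generator ground truth. The calibration studies use
500 null cohorts of 20 subjects x 3 stages at k ≈ 100 with 199
permutations (stage-term rejection at α = 0.05 inside the binomial
95% band), 500 + 200 replicates for the disparity test's size and power,
and a 43-subject, k = 720 cohort with interval fields calibrated to
1.32 mm / 0.21 mm for effect recovery — sizes chosen so the whole suite
runs in minutes while leaving the Monte-Carlo bands tight enough to be
meaningful.

## Known limitations

- The five-anchor TPS mapper is a transparent stand-in for dense nonrigid
  surface registration; its fidelity to any particular external toolchain
  is not claimed, and configurations mapped by such tools can be imported
  directly.
- The Euclidean Procrustes-distance surrogate and the linear (non-tangent-
  projected) treatment of shape space are appropriate for the small shape
  distances of faces; they would need revisiting for high-disparity data.
- Sequential (Type I) sums of squares make term order meaningful; the
  fitting order is fixed at stage, group, stage:group and recorded in the
  output.
- The disparity permutation test exchanges residual magnitudes globally
  and, in the repeated-measures setting, treats observations as
  exchangeable under the null of equal variance; subject-level variance
  clustering is not modelled.
- Heatmap localization inherits GPA leakage (bounded above by the
  Pinocchio-effect checks); sharp region boundaries in the generator are a
  modelling choice exposed through its parameters.
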