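---
title: "Methods: network identification, group inference and response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network identification, group inference and response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`icnpred` implements a complete resting-state fMRI analysis chain for
two-group treatment studies: from cleaned BOLD series to group network
maps, individual back-reconstructions, between-network connectivity,
permutation-based group inference, and individual-level response
prediction. Because patient fMRI data of this kind are rarely shareable,
the package ships a synthetic-cohort generator with full ground truth, and
every stage is validated against what the generator planted.

## The data model

A cohort consists of N subjects, each a 4D BOLD series on a voxel grid
with a brain mask and repetition time TR. Subjects carry a binary
treatment-response label derived from pre/post symptom scores: a subject
is a *responder* when the total score dropped by at least 30% of its
pre-treatment value. The default synthetic cohort emulates a realistic
youth-PTSD treatment sample: 40 subjects (21 responders, 19
non-responders), T = 200 volumes at TR = 2.3 s, ages 8–17, about 65%
girls, baseline symptom scores with mean 56.1 and SD 23.25, and no
group differences in any covariate.

The generator plants K spherical networks with Gaussian-profile spatial
maps (peak height 1) on the grid, placed on a jittered lattice so that
pairwise spatial correlations stay below 0.3 — the separability group ICA
assumes. Per subject, network time courses are drawn from a multivariate
normal whose correlation matrix carries the group structure, then low-pass
filtered (Gaussian kernel, SD 1.5 TR) to mimic hemodynamic
autocorrelation, and standardized. Two effects can be planted:

* an **edge effect**: the Fisher-z correlation between two designated
  networks ("FPN"–"SMN" style) differs between groups by `delta_z`
  (default 0.5, carried by the non-responders — its real-world magnitude
  is unknown, so it is a free parameter with a deliberately detectable
  default);
* a **map effect**: the spatial map of one designated network ("STG"
  style) is perturbed by a fixed multivariate pattern whose sign depends
  on the group (per-voxel SD 0.15 relative to the blob peak), giving a
  distributed, multivariate group difference in the individual maps.

Voxel series are `maps × time-coursesᵀ` plus white noise (default SD 0.2)
plus a constant baseline intensity (default 100 a.u.). The baseline is
generator realism: real BOLD has a large positive mean, and the
grand-mean-scaling step is undefined without one. If an injected
correlation matrix is not positive definite it is repaired to the nearest
correlation matrix (with a message); an infeasible edge raises an error
naming it. Pre/post scores are drawn from truncated group-specific
percent-reduction distributions, so the 30% rule reproduces the requested
responder count for every seed. What the generator does **not** model:
hemodynamic response functions, head motion, physiological noise,
multi-site effects, spatial noise correlation. Passing tests therefore
demonstrate algorithmic correctness under the stated assumptions, not
robustness to real-data artefacts.

## Signal cleanup

Cleanup follows the standard post-minimal-preprocessing recipe: isotropic
Gaussian smoothing (FWHM 6 mm, converted through the voxel size,
edge-renormalized so constants are preserved), grand-mean scaling to
10000, and a single confound regression that combines WM/CSF regressors
with a discrete-cosine highpass basis (cutoff 128 s, giving
`k = floor(2·T·TR/128)` cosine functions — k = 7 at T = 200, TR = 2.3 s).
An intercept is always included. When a noise subspace has already been
removed from the data (ICA-AROMA-style regressors, accepted as any T×A
matrix), all nuisance columns are first residualized against it, which
provably makes the final residuals identical whether or not the noise
subspace had been subtracted beforehand — the non-reintroduction property.
Rank-deficient noise matrices are handled through an SVD-based projector.
Resampling to a coarser grid is treated as a performance knob, not a
semantic step, and is not implemented; smoothing operates at the
generator's voxel size.

## Network identification and back-reconstruction

Group networks come from **meta-ICA**: `n_runs` (default 25; desk-scale
runs here use 5) spatial ICA decompositions on subject-bootstrapped,
temporally concatenated data, each from a fresh random initialization,
followed by a final ICA on the pooled component maps. Before
concatenation each subject is reduced to its leading spatial principal
components (default `max(1.5k, k+5)`), the standard economy that makes
group ICA tractable; the reduction is computed once per subject and
reused across bootstrap runs. The ICA engine is a fixed-point iteration
(logcosh contrast, symmetric decorrelation, tolerance 1e-5, up to 500
iterations, up to three restarts per run). A run that still fails to
converge is counted; more than half failing aborts with diagnostics.
Maps are variance-normalized with the sign convention that the
largest-magnitude weight is positive. The component count is a data-scale
choice: 70 is the full-data default, while synthetic desk-scale runs use
the planted K.

Signal/noise **triage** is a deliberately simple, documented stand-in for
the semi-automatic classification used on real data: a component is noise
when more than half of its group time-course power lies above 0.1 Hz, or
when more than half of its map energy sits on the mask edge; a manual
override list always wins. These two heuristics capture the dominant real
failure modes (scanner/CSF edge artefacts, high-frequency noise) but are
not a reproduction of any published classifier.

Individual maps and time courses come from a **spatially constrained
one-unit ICA** (GIG-ICA style). For one subject with whitened spatial
data Z (columns orthonormal, scaled so unit weight vectors give
unit-variance spatial sources), the estimate maximizes

    |E[G(Zw)] − E[G(ν)]| + λ · corr(Zw, reference),   G = log cosh,

by projected gradient ascent with an adaptive step, initialized at the
least-squares projection of the reference onto the whitened basis
(λ = `constraint_weight`, default 1; tolerance 1e-6; max 500 iterations;
non-convergence returns the best iterate, flagged). Within a subject,
successive components are deflated against the already-extracted weight
vectors, keeping individual maps near-uncorrelated. The map is z-scaled
with a positive peak; the time course is the least-squares projection of
the data onto the map and follows the map's sign. On default synthetic
cohorts this recovers planted maps at r > 0.95 and planted time courses
at r > 0.9. Recovery is measured against the planted truth as the
pipeline sees it — maps passed through the same smoothing kernel, time
courses through the same cosine highpass — since smoothing and filtering
are deterministic parts of the model, not estimation error.

## Between-network connectivity

Network matrices are built from the individual time courses: full
matrices by Pearson correlation, partial matrices from the
ridge-regularized precision of the standardized time courses,
`P = (C + ρ·mean(diag(C))·I)⁻¹`, partial r = −P_ij/√(P_ii·P_jj), with
ρ = 0.1 by default (the regularization is scaled to the covariance
magnitude, following netmats practice; ρ = 0 reproduces the textbook
partial correlation). All correlations are Fisher r-to-z transformed
after clipping |r| at 1 − 1e-7, keeping z finite without materially
moving any realistic value; diagonals are zero. Edge vectors use the
strict lower triangle in fixed row-major order.

## Group inference

Group differences are tested with an OLS GLM per feature —
`[intercept | group | demeaned covariates]` (age, gender, baseline
severity as covariates of no interest) — and corrected by **synchronized
max-statistic permutations**: one group-label shuffle per permutation is
applied identically to every feature and family unit; the maximum of the
two-sided (optionally TFCE-enhanced) statistic over all features, signs
and units forms the null; `p_FWE = (1 + #{perm max ≥ observed}) /
(1 + n_perm)`, which includes the observed statistic and can never be
zero. Raw labels are permuted while covariates stay fixed — valid here
because the covariates are nuisance terms independent of group by design,
and the choice is recorded in the output metadata. Voxelwise map tests
use TFCE (H = 2, E = 0.5, 26-connectivity, step `max|stat|/100`, negative
tail enhanced separately); edge tests use the raw t, since edges have no
spatial neighbourhood. Permutation schemes accept explicit enumeration
matrices, which is how the package's tests compare against exhaustive
small-sample oracles.

## Response prediction

Each analysis family holds one feature set per signal network (the
individual map voxels) and one per netmat kind (edge vectors) — 48 + 2 =
50 sets at full scale. Per set, a linear-kernel SVM (cost 1.0 by default;
the cost is recorded in every output because no principled value is
known) is evaluated by **50×5-fold stratified cross-validation**: folds
are built by per-class round-robin after class-wise shuffling with the
cycle position carried across classes (so a 21/19 split yields folds of 8
with 4–5 responders), features are min-max rescaled to [−1, 1] with
parameters fitted on the training folds only (constant features map to 0,
test values extrapolate without clipping), and balanced accuracy, AUC
(midrank ties), sensitivity, specificity, PPV and NPV are computed per
test-fold evaluation and averaged over all 250 evaluations with SDs. A
test fold missing a class yields flagged, partially defined metrics that
are excluded from averaging. A leave-one-out mode pools the N held-out
predictions instead, which is why its sensitivity is an integer multiple
of 1/(number of responders).

Familywise correction over the analyses uses the same synchronized
max-statistic logic: each of `n_perm` (default 2000) permutations draws
one label shuffle, applies it to **every** feature set, recomputes the
repeated-CV mean balanced accuracy per set on the *same* CV partitions as
the observed statistic (that reuse is what keeps the correction
exchangeable), and records the maximum over sets. Because the null must
be affordable, `n_repeats_perm` can reduce the number of CV repeats used
inside the null; the observed statistic entering the p-value is then
computed on the same reduced partition set, while the reported metrics
always use all repeats. Internally the permutation loop replaces each
fold's rescaled feature matrix by an exact kernel factor (Z with
ZZᵀ = XXᵀ), so a linear SVM fit costs the same regardless of the feature
count — an algebraic identity, not an approximation.

Two diagnostic modes mirror common practice: **weight significance**
refits the full-data SVM under label permutations and normalizes each
weight by its permutation mean and SD, with either empirical or Gaussian
two-sided p-values; the output is flagged "visualization only", since it
describes the classifier, not generalization. **Single-voxel ablation**
selects, inside every training fold, the feature with the largest
two-sample |t| on the training data only, and trains/tests on that single
feature — the honest univariate baseline whose collapse to chance on
multivariate-only effects demonstrates the value of the multivariate
model (selection on the full data would leak and provably inflates
accuracy on null data, which the test suite checks).

## Numerical choices and degenerate inputs

* Fisher clipping 1 − 1e-7; ridge ρ = 0 on singular covariance raises an
  error advising ρ > 0; constant time courses are reported by component.
* Zero-variance subject data aborts reconstruction; all-zero statistic
  maps enhance to zero.
* The p-value convention `(1 + count)/(1 + n_perm)` is used everywhere.
* Determinism: every randomized stage takes a seed; cohort generation,
  meta-ICA, permutation schemes and CV partitions are bit-reproducible
  under fixed seeds, and derived stage seeds are recorded in the run
  manifest.

## Problem sizes used in tests

The test suite and the acceptance script run everything at desk scale,
chosen so the full chain completes in minutes on one core: grid
16×16×12, T = 200, K = 6, N = 40 for the default cohort (meta-ICA with 5
runs); smaller cohorts for module tests; calibration suites use 300
simulated null families with 99–199 permutations and reduced CV repeats.
These sizes are statements about the tests, not about the method — all
full-scale defaults (70 components, 25 meta-ICA runs, 2000/10000
permutations, 50 repeats) remain the configured defaults.

## Known limitations

* The triage heuristics are a stand-in; on real data the manual override
  list is the expected workflow.
* The meta-ICA resampling scheme (bootstrap over subjects) and run count
  are conventions; the literature does not fix them.
* The GIG-ICA objective is a faithful one-unit reformulation of the
  constrained-ICA idea, not a port of any particular toolbox; its
  constraint weight trades independence against reference fidelity.
* Label permutation with fixed covariates assumes covariates are
  group-independent nuisance; under strong covariate–group dependence a
  residual-based scheme would be preferable.
* The weight-significance statistic is a permutation-normalized weight,
  documented as such; "margin-aware" variants from the literature are not
  reproduced.
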