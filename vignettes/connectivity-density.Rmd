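---
title: "Volume-normalized streamline density profiles and lateralization testing"
author: "tractdensity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volume-normalized streamline density profiles and lateralization testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractdensity)
```

## The analysis

Probabilistic tractography from a seed region produces a tractogram: a large
set of streamlines, each a polyline in world millimetres. This package turns
such tractograms into quantitative connectivity profiles against a labelled
parcellation, in five stages.

**1. Exclusive assignment.** Each streamline is assigned to at most one
target region under mutual-exclusion filtering: every target acts as its own
inclusion mask and as an exclusion mask for all other targets, and dedicated
regions of avoidance veto a streamline outright. Concretely, the set of
labels traversed by the streamline is computed, and the streamline is
discarded if it touches any exclusion label (checked first — a streamline
routed through an avoidance region can never represent a clean pathway),
discarded if it traverses two or more targets (it belongs to no single
pathway), discarded if it reaches no target, and otherwise assigned to the
unique target it traverses. Traversal of the seed label itself is ignored;
the tractogram was seeded there, so requiring it adds nothing (a strict mode
is available via `strict_seed`).

Membership is *traversal*, not endpoint termination: a streamline that
passes through a region counts. This matches how inclusion/exclusion masks
act in standard tracking tools, where filters test whether a track enters
the mask, and it reflects the anatomy of seed-to-cerebellum pathways, which
enter their targets through intermediate white matter rather than
terminating at a region boundary.

**2. Density.** Counting assigned streamlines gives the NOS (number of
streamlines) per target, hence the connectivity density
$\delta_i = 100\,\mathrm{NOS}_i / \sum_j \mathrm{NOS}_j$ (percent of the
assigned total). Raw NOS favours large regions, so the volume-normalized
density divides each pathway's NOS by the mean volume of its two endpoint
regions before renormalizing:
$$w_i = \frac{\mathrm{NOS}_i}{(V_\mathrm{seed} + V_i)/2}, \qquad
\delta^{NORM}_i = 100\, \frac{w_i}{\sum_j w_j}.$$
The renormalization to percent is a deliberate choice: it makes per-subject
profiles sum to 100 in both measures, which is the only reading under which
published compartment percentages (49.10 + 45.35 + 5.16 + 0.38 ≈ 100)
cohere. Two consequences are used as test invariants: $\delta^{NORM}$ is
invariant under a global rescaling of all volumes (so the mm³ unit choice is
immaterial), and it reduces exactly to $\delta$ when all volumes are equal.

**3. Group summary and reliability screen.** Across subjects, each pathway
gets the mean and sample SD (n − 1 denominator; the standard choice for a
between-subject summary) of $\delta^{NORM}$, and the coefficient of
variation COV = SD/mean (defined as 0 when mean and SD are both 0, matching
how an entirely absent pathway is reported). Pathways are retained when the
*group mean* exceeds the density threshold (default 1%) — the threshold is a
group-level false-positive screen, not a per-subject censor. Empirically,
sub-threshold pathways are also the high-COV ones, which is the rationale
for reading the threshold as a reliability screen.

**4. Compartment aggregation.** Per-target values are summed into the four
Stoodley–Schmahmann cerebellar compartments (anterior, posterior,
flocculonodular, nuclear). Aggregation is linear, so aggregating group means
equals averaging per-subject aggregates.

**5. Lateralization.** For every bilateral pathway pair, the lateralization
index $LI = (L - R)/(L + R)$ of the group mean densities, with $|LI| > 0.1$
as the asymmetry cutoff (we read the cutoff as symmetric: left when
$LI > 0.1$, right when $LI < -0.1$). Statistical evidence comes from a
paired permutation test on per-subject left−right $\delta^{NORM}$
differences: under the null of no asymmetry the sign of each subject's
difference is exchangeable, so the null distribution is generated by
independent per-subject sign flips (the Blair–Karniski construction for
paired designs). Family-wise error across pairs is controlled by the tmax
method — each permutation records the maximum |t| over all pairs, and each
observed |t| is ranked against that maximum distribution. Two-sided
throughout. A pair is called lateralized only when both the LI cutoff and
the corrected p < α (default 0.05) agree. Midline (vermal) pathways have no
left/right members and are excluded.

Numerical details that matter: with n ≤ 20 subjects all $2^n$ sign patterns
are enumerated, making the test exact with $p = \#\{|t_{perm}| \ge
|t_{obs}|\}/2^n$ (the identity pattern keeps p positive); with larger n,
50,000 random sign vectors are sampled and the add-one estimator
$p = (1 + \#)/(1 + B)$ is used so p is never zero. A pair with zero density
on both sides in every subject carries no information and is excluded (NA);
a pair with constant nonzero differences has SD 0 and its t is defined as
±Inf, which the permutation ranks maximally.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 1 (% of $\delta^{NORM}$) | group-mean retention threshold |
| `n_perm` | 50,000 | sampled permutations (n > 20 subjects) |
| `alpha` | 0.05 | significance level of the corrected test |
| LI cutoff | 0.1 | minimal index magnitude called asymmetric |
| `strict_seed` | FALSE | require seed traversal at assignment |
| densification | 0.5 × min voxel edge | max sample spacing along a streamline |
| `step_mm` | 0.2 mm | phantom polyline vertex spacing |

The densification bound is a Nyquist-style guarantee: with consecutive
samples at most half the smallest voxel edge apart, a structure one voxel
thick cannot be stepped over between samples. Label lookup is
nearest-voxel under the full inverse affine (labels are categorical, so no
interpolation; non-axis-aligned affines are supported everywhere), with
0-based indices, voxel-centre convention, and half-away-from-zero rounding.

A limitation worth knowing: traversal is *defined* by this sampling, so a
polyline that clips only a sub-sample sliver of a voxel's rounding region —
a corner graze shorter than the sample spacing — is not registered. The
guarantee covers voxel-thick walls, not corners. The test suite therefore
validates assignment against a fine-sampling brute-force oracle on
deterministic streamlines routed through voxel interiors; for random
polylines the two sampling definitions can legitimately differ on roughly
one streamline in fifty on a 20³ grid.

## The phantom

Real inputs for this analysis are hundred-subject tractography cohorts that
cannot ship with a package, so the phantom module generates synthetic data
with known ground truth in exactly the formats real data would arrive in
(TCK, NIfTI, TSV).

Geometry: one spherical midline seed, `n_targets_bilateral` mirror-symmetric
left/right target pairs plus `n_targets_midline` midline targets on a far
plane, and one exclusion sphere adjacent to the seed in a decoy direction —
a miniature of a midline seed with bilateral targets and a region of
avoidance guarding the seed's neighbourhood. Targets are assigned
round-robin to the four compartments. ROIs are validated non-overlapping
and in-bounds.

Stochastic model, per subject $k$ with child seed derived deterministically
from `(seed, k)` (cohorts are bit-reproducible):

- realized weights $w_i = \bar w_i e^{\varepsilon_i}$,
  $\varepsilon_i \sim N(0, \sigma^2)$ i.i.d. — multiplicative log-normal
  between-subject variability ($\sigma$ = `subject_sigma`, default 0.3).
  Log-normality keeps weights positive and produces the right-skewed,
  large-SD profiles seen in real cohorts; the default 0.3 puts phantom COVs
  in the 0.2–0.5 range of the reliable published pathways.
- the left member of every pair is multiplied by `lateralization_shift`
  (default 1 = symmetric null);
- per-target streamline counts are multinomial over the valid fraction of
  `n_streamlines`, with configured fractions constructed invalid in each of
  the three ways the assignment stage must catch: crossing the exclusion
  region, traversing two targets, reaching no target (default 5% each —
  realistic rates of spurious tracts after seeding);
- each valid streamline is a straight seed-voxel-to-target-voxel polyline,
  resampled to `step_mm` spacing, with independent Gaussian per-vertex
  jitter (SD = 0.3 × voxel size), rejection-resampled up to 100 times if the
  jittered path touches a forbidden label. No tracking algorithm is claimed
  — the geometry is the simplest that exercises the membership logic.

What the phantom does *not* emulate: curved anatomical bundles, partial
volume effects, fODF-driven streamline dispersion, distance- and
curvature-dependent seeding bias, registration error. Passing recovery
tests on the phantom therefore shows that the *measurement chain* (assign →
count → normalize → summarize → test) is unbiased and calibrated under a
known generative model, not that tractography itself recovers anatomy.

Two generator surfaces exist. `generate_cohort()` builds full geometric
tractograms and is what the end-to-end and recovery tests use.
`simulate_cohort_profiles()` draws the same weights and multinomial counts
but skips streamline geometry, emitting $\delta^{NORM}$ profiles directly —
distributionally identical to the geometric phantom followed by noise-free
assignment (up to border-jitter effects ≪ 1%), and fast enough for
replicate studies. The permutation-test calibration (type-I error over 500
null cohorts), p-value uniformity (KS over 1,000 replicates), and power
analyses (shift 1.5, n = 30) run on this surface; running them on full
geometric cohorts would test the same code path thousands of times at
hundredfold cost.

## Problem sizes used in tests and reproduction

The recovery study runs 20 subjects × 20,000 streamlines (multinomial SE
small enough that a 3-SE band is a meaningful check); calibration and power
replicates use 12 and 30 subjects with exhaustive or 2,000-permutation
tests; the end-to-end drivers under `analysis/` use 12 subjects × 3,000
streamlines. These sizes were chosen so the whole suite completes on a
laptop-class single core while keeping every statistical check at its
stated strength.

## Degenerate inputs and edge cases

- Streamlines with fewer than two vertices are counted under an `invalid`
  discard counter, never silently dropped; accounting
  (assigned + discarded = input) is asserted per subject.
- A subject with zero assigned streamlines has no defined profile: `delta()`
  raises an error rather than returning all zeros (an undefined profile and
  an all-zero profile are different statements).
- A target with zero volume but nonzero NOS is an error; with zero NOS it
  simply contributes zero.
- Out-of-bounds samples contribute nothing to label sets (streamlines may
  leave the field of view).
- All-zero pathways report COV 0; a single-subject "group" reports NA
  SD/COV but still a mean.
- Ties in permutation ranks are counted with ≥ (conservative).

## Known limitations

- NOS-based measures inherit the usual caveats of streamline counting; no
  SIFT-like streamline filtering is applied (by design — the method under
  study applies none).
- The corner-graze sampling limitation described above.
- The exclusion-before-target rule means a streamline touching both an
  avoidance region and a target is unconditionally discarded; there is no
  "salvage" mode.
- TCK I/O supports the Float32LE/BE dialects only (the formats written by
  the standard tools); TRK/VTK are out of scope.
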