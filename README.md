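# tractdensity

Quantitative post-processing of diffusion-MRI tractography into
seed-to-parcellation connectivity density profiles, with reliability
screening and lateralization testing. The package implements the analysis
chain used to characterize structural connectivity between a midline seed
region (the periaqueductal gray, PAG) and a 34-region cerebellar
parcellation (deep nuclei, hemispheric lobules, vermal lobules), and ships a
synthetic tractogram phantom with known ground truth so the entire chain is
testable without imaging data.

It is aimed at researchers who already have whole-seed tractograms (MRtrix
TCK), a labelled parcellation (NIfTI), and a region table (TSV), and who
want per-subject density profiles, group summaries, and asymmetry tests out
of the other end.

## The measures

For each subject, every streamline is assigned exclusively to a single
target region: streamlines touching any region of avoidance are discarded,
as are streamlines traversing two or more targets (each target acts as
inclusion mask while all others act as exclusion masks) and streamlines
reaching no target. Counting assigned streamlines gives the NOS (number of
streamlines) per pathway, and from it:

- **Connectivity density** `δ_i = 100 · NOS_i / Σ_j NOS_j` — the pathway's
  share of the total, in percent.
- **Volume-normalized density**
  `δNORM_i = 100 · w_i / Σ_j w_j` with `w_i = NOS_i / ((V_seed + V_i)/2)` —
  each pathway's NOS scaled by the mean volume of its two endpoint ROIs,
  then renormalized to percent. This removes the bias of large regions
  collecting more streamlines; it is invariant to global volume rescaling
  and reduces to δ when all volumes are equal.
- **COV** = between-subject SD / mean of δNORM per pathway — the reliability
  screen; pathways with group mean δNORM ≤ 1% are flagged as unreliable
  (not retained).
- **Lateralization index** `LI = (L − R)/(L + R)` per bilateral pathway
  pair, with |LI| > 0.1 as the asymmetry cutoff, tested by a paired
  permutation test on per-subject left−right δNORM differences with
  family-wise tmax correction (50,000 sign-flip permutations, or exhaustive
  enumeration for ≤ 20 subjects; α = 0.05).

## Worked example

A twelve-subject phantom cohort, assigned and summarized:

```r
library(tractdensity)

cfg <- phantom_config(n_streamlines = 3000, subject_sigma = 0.3, seed = 1)
coh <- generate_cohort(cfg, n_subjects = 12)
profiles <- lapply(coh$subjects, function(s) {
  asg <- assign_streamlines(s$tractogram, coh$labels, coh$table)
  subject_profile(asg, coh$labels, coh$table)
})
summarize_group(profiles, threshold = 1.0)
```

The group summary has one row per target (here named by label id):

```
  target mean_delta_norm       sd       cov retained
1      2       21.415033 5.578798 0.2605085     TRUE
2      3       21.882353 6.281836 0.2870732     TRUE
3      4       10.490196 1.815856 0.1731003     TRUE
4      5       11.957516 1.652521 0.1381994     TRUE
5      6        6.254902 2.148029 0.3434153     TRUE
6      7        6.215686 1.435189 0.2308979     TRUE
7      8       15.584967 4.377984 0.2809107     TRUE
8      9        6.199346 2.022312 0.3262137     TRUE
```

`mean_delta_norm` is the group mean volume-normalized density in percent
(the column sums to 100), `cov` its between-subject coefficient of
variation, and `retained` the 1% threshold call. With the phantom's default
ground truth the expected profile is `(22.2, 22.2, 11.1, 11.1, 5.6, 5.6,
14.8, 7.4)` — the recovered means sit within sampling error of the truth.

The lateralization test on the same cohort (symmetric by construction):

```r
dn <- do.call(rbind, lapply(profiles, function(p) p$delta_norm))
pairs <- bilateral_pairs(coh$table)
tmax_permutation(dn[, as.character(pairs$left)],
                 dn[, as.character(pairs$right)], seed = 1)
```

```
  pair     li_group      t_stat p_uncorrected    p_tmax lateralized
1    2 -0.010793267 -0.15981811     0.8588867 0.9980469        none
2    4 -0.065366138 -1.78209940     0.1020508 0.2802734        none
3    6  0.003144654  0.07600862     0.9433594 1.0000000        none
```

No pair is called lateralized — the correct answer for a symmetric cohort.

The packaged reference table of published group densities is available via
`load_table1_fixture()` and the step-by-step analyses live under
`analysis/` (numbered scripts: phantom cohort → assignment → density
profiles → lateralization → published-table reanalysis), each writing its
tables under `results/`.

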