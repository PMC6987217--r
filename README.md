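# hmpdev — habitual motion path deviation and knee cartilage response

`hmpdev` is an R package for biomechanists studying how far a runner's knee
strays from its *habitual motion path* (HMP) — the frontal/transverse-plane
trajectory the joint follows during low-load movement — and whether that
deviation is associated with acute cartilage volume loss after prolonged
running.

## The method

1. **Baseline.** From ~10 half-squats, read the frontal (adduction) and
   transverse (internal-rotation) knee angles at a critical flexion angle of
   40° during the eccentric (descending) phase. Their per-subject means are
   the HMP baseline.
2. **Deviation.** For each running stride, read the same two angles at the
   40° rising crossing during the eccentric part of stance (stance detected
   from vertical ground-reaction force, ≥ 20 N). Per plane, the deviation is
   the absolute difference from the baseline; the overall score weights the
   transverse plane at one half:

   `Dev_tot = Dev_front + 0.5 · Dev_trans`  (degrees)

3. **Cartilage.** Pre/post-run volumes of seven knee sub-regions — patella
   (P), medial/lateral tibia (MT, LT), medial/lateral femoral condyles
   (MF, LF), and their central weight-bearing areas (CMF, CLF) — are turned
   into percent reductions `100·(pre − post)/pre` (normalisation by
   body mass × height cancels here and is reported separately).
4. **Statistics.** One-tailed *exact* Wilcoxon rank-sum (high- vs
   low-deviation halves of the cohort; p by full enumeration of rank
   assignments), dependent-sample t-tests (each subject's maximum- vs
   minimum-deviation shoe), simple linear regression of reduction on
   deviation, and Cohen's d with **unweighted** variance pooling,
   `d = (x̄_j − x̄_i)/√((s²_j + s²_i)/2)`.

Upstream of the angles, the package provides least-squares rigid-body pose
estimation from marker clouds (SVD/Kabsch, reflections rejected), Cardan
decomposition (flexion → adduction → internal rotation), zero-phase
low-pass filtering, and phase detection.

A fully seeded synthetic-cohort generator (`generate_cohort()`) emulates the
study design — 12 subjects × 3 footwear conditions (neutral, laterally
posted, medially posted), squats crossing 40°, running stances with a
2.5-body-weight force bump, and region reductions coupled linearly to
deviation — with ground truth attached, so the entire pipeline is testable
without any data download.

## Worked example

```r
library(hmpdev)
cfg    <- cohort_config(n_subjects = 12, n_strides_per_condition = 5, seed = 1)
cohort <- generate_cohort(cfg)
res    <- analyze_cohort(cohort, cohort$cartilage)
print(res)
```

```
<pipeline_result> 12 subjects | 300 trials used, 0 excluded
<study_result>
High group: S01, S02, S04, S05, S10, S11
Low group:  S03, S06, S07, S08, S09, S12

Group comparison (one-tailed rank-sum, high > low):
 region statistic     p_value         d magnitude significant
      P        57 0.001082251 2.2422229     large        TRUE
     MT        53 0.012987013 1.3803300     large        TRUE
     LT        57 0.001082251 2.7974404     large        TRUE
     MF        55 0.004329004 2.3574672     large        TRUE
     LF        50 0.046536797 1.2312573     large        TRUE
    CMF        47 0.120129870 0.9930652     large       FALSE
    CLF        53 0.012987013 1.5706119     large        TRUE
...
Regressions (reduction ~ overall deviation):
 region     slope r_squared      p_value significant
      P 0.3548148 0.8000436 8.620633e-05        TRUE
     MT 0.4069879 0.6499429 1.539698e-03        TRUE
...
```

Reading it: the cohort is split into high/low-deviation halves by the
overall score averaged over shoes; each region row reports the rank-sum
statistic (sum of high-group ranks, exact p ≤ 1/924 when fully separated),
the effect size, and the α = 0.05 decision. The regression slopes hover near
the generator's true coupling of 0.4 %/deg — the statistic the design is
meant to recover.

On-disk workflow (same pipeline, CSV in/out):

```r
write_cohort(cohort, "dataset/")
res <- run_pipeline("dataset/", analysis_config(), out_dir = "results/")
```

or from the shell via the bundled CLI:

```sh
Rscript inst/cli/hmp.R simulate --out dataset --seed 1
Rscript inst/cli/hmp.R pipeline --data dataset --out results
```

## Scope

Volumes are the input boundary (no MRI segmentation or image I/O); no
inverse dynamics, soft-tissue-artifact correction beyond the least-squares
rigid fit, or C3D reading (CSV is the interchange format). See
`vignettes/hmp-methods.Rmd` for modelling choices and limitations.
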