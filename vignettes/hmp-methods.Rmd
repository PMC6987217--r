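---
title: "Habitual motion path deviation: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitual motion path deviation: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmpdev)
```

## The model

The habitual motion path (HMP) hypothesis holds that each knee has a
preferred frontal/transverse-plane trajectory — shaped by bony anatomy and
passive tissue — that it follows during low-load flexion tasks, and that
running mechanics (or footwear) pushing the joint off this path load
cartilage regions less adapted to bearing it. `hmpdev` operationalises this
in three quantities:

* **HMP baseline** — per subject, the mean frontal (adduction) and
  transverse (internal-rotation) knee angles read at a *critical flexion
  angle* during the eccentric phase of repeated half-squats. One baseline
  per subject, regardless of footwear: the squat is performed in neutral
  sock shoes and represents the joint's unloaded preference.
* **HMP deviation** — per running stride, the same two angles are read at
  the first rising crossing of the critical angle inside the eccentric part
  of stance; per-plane deviations are *absolute* differences from the
  baseline, and the total is the weighted sum
  `Dev_tot = Dev_front + 0.5 · Dev_trans`. The half weight reflects the
  smaller transverse range of motion of the knee in running. Per condition,
  stride deviations are averaged component-wise (the total is linear, so
  averaging components or totals is equivalent — a property the tests pin).
* **Cartilage response** — percent volume reduction `100·(pre − post)/pre`
  in seven sub-regions (P, MT, LT, MF, LF, CMF, CLF), pre/post a prolonged
  run. Volumes may also be normalised by body mass × height; the ratio form
  of the percent reduction makes every downstream statistic invariant to
  this (and to any unit change), so the choice of normalisation operator
  cannot affect the analysis — it only affects reported normalised volumes.

Deviations are taken as absolute values per plane before entering the
weighted sum. The alternative — signed per-plane deviations — would let
frontal and transverse excursions in opposite directions cancel, producing
a "low deviation" label for a knee that is far off its path in both planes.
All group-level deviation statistics in this line of work are positive
magnitudes, which is only coherent under the absolute-value reading. The
signed variant is retained behind `analysis_config(signed_deviation =
TRUE)` for sensitivity analyses.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `critical_flexion_deg` | 40 | deg | protocol constant: the flexion at which non-sagittal angles are compared |
| `eq1_transverse_weight` | 0.5 | – | weight of the transverse deviation in the total score |
| `stance_threshold_N` | 20 | N | common treadmill noise floor for stance detection |
| `min_stance_s` | 0.1 | s | discards force blips shorter than a physiological stance |
| `filter_cutoff_angles_Hz` | 12 | Hz | common running-kinematics smoothing |
| `filter_cutoff_force_Hz` | 50 | Hz | preserves impact transients while denoising |
| `alpha` | 0.05 | – | significance level for every test |

The Cardan sequence is flexion (mediolateral axis) → adduction → internal
rotation, the standard joint-coordinate-style ordering; the exact segment
coordinate conventions of any particular marker model are injected upstream
(through the poses handed to `knee_angles_from_poses()`), not assumed here.
When several 40° crossings exist inside the eccentric phase, the *first*
rising crossing is used: the earliest loaded crossing, and a deterministic
tie-break. Angle traces are unwrapped before interpolation so ±360° jumps
cannot corrupt the crossing values.

## The statistical battery

* **Group comparison** — the cohort (even n, default 12) is split into
  high/low halves by overall deviation averaged over all shoes; per region,
  a one-tailed Wilcoxon rank-sum tests whether high deviators lose more
  cartilage. With ≤ 20 tie-free observations the p-value is **exact**: all
  `choose(n, n_x)` rank assignments are enumerated (924 for the 6 v 6
  design, trivially cheap and exact where the normal approximation is
  worst). Ties fall back to midranks with tie- and continuity-corrected
  normal approximation, and the result records which path was used — the
  exact distribution under ties is not well defined without a tie model.
* **Footwear comparison** — per region, a dependent-sample t-test between
  each subject's maximum- and minimum-deviation shoe. Two-tailed by
  default: only the group hypothesis is marked directional in the source
  analysis. Zero-variance differences are reported as not-computable rows
  rather than failing the battery.
* **Regression** — per region, OLS of shoe-averaged reduction on overall
  deviation, with the slope t-test and a 95% CI.
* **Effect sizes** — Cohen's d with the *unweighted* average of the two
  sample variances in the denominator, not the n-weighted pooled variance.
  The two coincide for equal group sizes but differ otherwise; a regression
  test pins the unweighted form. Thresholds: ≥ 0.2 small, ≥ 0.5 medium,
  ≥ 0.8 large.
* **No multiplicity correction** across the seven regions by default,
  matching how these region-wise comparisons are conventionally reported;
  `holm_correction = TRUE` adds Holm-adjusted
  columns.

## What the synthetic generator emulates — and what it does not

The generator states a world mirroring the study design: 12 recreational
runners (mass 70.9 ± 9.9 kg, height 1.77 ± 0.08 m), three footwear
conditions (neutral, laterally posted, medially posted), ten half-squats,
and a configurable number of strides per shoe (default 20; the source
protocol does not report its stride count).

* **Squats**: flexion is a raised cosine from ~5° to a peak drawn in
  [82°, 98°] — one rising and one falling 40° crossing, guaranteed.
* **Running stance**: flexion rises from 15–20° at contact to a 50° peak at
  40% of stance (an asymmetric `s²(1−s)³` bump; the 50° peak is a package
  choice that guarantees the protocol's 40° crossing), stance duration
  0.24–0.32 s, vertical force a smooth bump peaking at 2.5 body weights and
  exactly zero in flight. Force is generated on the motion-capture time
  base (one uniform time vector per trial).
* **Non-sagittal angles are affine functions of flexion**, equal to
  baseline (+ per-shoe offset when running) at 40°, plus additive Gaussian
  noise (default SD 0.5°). Modelling them against flexion rather than time
  makes the crossing values independent of movement speed — and because
  linear interpolation and linear filtering both preserve affine relations
  between series, a *noiseless* cohort round-trips through the full
  pipeline (filtering included) to machine precision. That is the
  end-to-end identity the acceptance suite asserts at 1e-9.
* **Per-shoe offsets**: per subject, a shared Normal(0, 2.5°) effect plus
  shoe-specific means (frontal 5.5/7.0/6.5°, transverse 6.0/8.0/7.0° for
  neutral/lateral/medial) and Normal(0, 1°) shoe noise, truncated at zero.
  The shared effect creates consistent high/low deviators; the resulting
  overall deviations span roughly 4–14°, the range reported for real
  cohorts.
* **Cartilage coupling**: per region, percent reduction =
  `alpha + beta · Dev_tot + noise`, truncated at zero, with `alpha ~
  Normal(2.5, 0.5)` % and `beta = 0.4` %/deg by default. Linear coupling is
  the modelling counterpart of analysing the relationship by simple linear
  regression; truncation encodes that loading cannot add cartilage volume
  within a session (measured volume increases remain representable through
  the analysis side, which never clips).

Not emulated: soft-tissue artefact beyond additive Gaussian noise, fatigue
drift across a 75-minute run, swing-phase knee kinematics (flexion is held
at its contact value outside stance — the analysis never looks there),
inter-region correlation of reductions, and measurement error in the
volumes themselves. A green recovery test therefore establishes that the
*pipeline* is faithful, not that real marker data are this benign.

Determinism: every trial derives its own seed from the cohort seed, the
subject index and the repetition index, so any single trial is reproducible
in isolation and a written dataset is byte-identical across runs
(`write_cohort()` formats numbers with `%.12g`, lossless at the declared
precisions).

## Numerical choices and degenerate inputs

* Rigid fits use the SVD (Kabsch) solution with the determinant corrected
  to +1: a reflection is never returned, even for noisy near-planar
  clouds. Collinear templates and mismatched point counts are errors; the
  residual RMS is reported so marker-compliance problems are visible.
* The Cardan decomposition warns (does not fail) within 1e-6 rad of gimbal
  lock; the round-trip identity is tested for |adduction| < 80°.
* The zero-phase low-pass is applied in the frequency domain with a squared
  Butterworth magnitude response — the gain of a forward-backward
  Butterworth pass — on a reflection-padded series. No phase distortion,
  length preserved, DC exactly preserved; a cutoff at or above Nyquist is
  an error. (The classical filter-design route was not available in the
  supported dependency set; the frequency-domain form meets the same
  contract and its passband/stopband behaviour is tested.)
* Tie-breaks are deterministic and warned about: equal condition totals
  resolve by the fixed order neutral → lateral → medial; equal overall
  deviations at the group boundary resolve by subject id.
* Exact squat crossings at a sample (flexion exactly 40°) return that
  sample's angles; otherwise the crossing fraction is interpolated
  linearly.
* Excluded trials (no crossing, no stance) are counted and logged with
  reasons; the pipeline never drops a trial silently.

## A note on group recovery

With the reference group statistics — overall deviations 12.5 ± 2.7° (high)
vs 6.2 ± 2.3° (low), six per group — the probability that a median split
recovers the true groups *intact* is only ≈ 0.50: recovery requires
min(high) > max(low), and the expected extreme order statistics of the two
distributions nearly coincide (12.5 − 1.267·2.7 ≈ 9.08 vs
6.2 + 1.267·2.3 ≈ 9.11). The test suite asserts the split agrees with this
order-statistic oracle case by case and that the simulated recovery rate
sits in the honest band around 0.50 — a deliberately red flag against any
expectation of near-certain recovery at these effect sizes. Group
*difference* detection is a different matter: at the implied d ≈ 2.51 the
one-tailed exact rank-sum rejects in ≈ 98% of simulated cohorts, while its
type-I error at α = 0.05 is the largest achievable exact level, ≈ 0.047.

## Known limitations

* CSV is the only trial interchange format; C3D files must be converted
  upstream (no C3D reader exists in the supported dependency set).
* The segment coordinate conventions embedded in a marker model are the
  caller's responsibility; the package decomposes whatever relative
  rotation it is given.
* The exact rank-sum path enumerates up to `choose(20, 10)` = 184,756
  assignments; beyond n = 20 it switches to the normal approximation.
* The generator's stance force is a single smooth bump: no impact peak,
  no anterior-posterior shear, no free moment.
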