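# engramflow

Simulation and analysis of early neurochemical correlates of motor
memory consolidation.

## What this is for

After practicing a new motor sequence, the brain keeps consolidating the
memory offline. Short-term shifts in the excitatory and inhibitory
neurotransmitters glutamate (Glu) and GABA in the primary motor cortex
(M1), measured with single-voxel MR spectroscopy in the first ~30
minutes after learning, are hypothesized to track the overnight
correlates of that consolidation: behavioral offline gains, changes in
M1–putamen functional connectivity, M1 gray-matter volume change, and a
multivoxel pattern-similarity correlate of memory reactivation.

`engramflow` is for methodologists and students of this literature: it
implements the full analysis chain as tested, reusable functions, and
pairs it with a seeded synthetic two-day cohort generator so the whole
pipeline can be exercised, calibrated and validated without any scan
data. The core quantitative pieces are:

- **Tissue-corrected MRS quantification** — water-scaled estimates are
  multiplied by `(43.3 f_gm + 35.88 f_wm + 5.556 f_csf)/(1 − f_csf)`
  (no metabolites in CSF, no T1 term, one T2 regime), with QC exclusion
  of linewidth > 15 Hz, SNR ≤ 30, and |value − mean| > 3 SD, and change
  features (immediate, 30-min, averaged) per subject and metabolite.
- **Behavior** — correct-sequence counts for the 4-1-3-2-4 tapping task
  from raw key-press streams (KMP-style scanner, oracle-tested), the
  early/late phase boundary from consecutive-block contrasts after a
  random-intercept + random-slope mixed model, and overnight gains
  `100 (day2 − day1_last)/day1_last`.
- **BOLD features** — integrated local correlation (ILC) maps
  (Gaussian-weighted neighborhood correlations, σ = 1 mm, truncated at
  3σ: the 26-neighborhood at 1.6 mm voxels), the engram-conjunction ROI
  (z > 3.1 on both the last practice block and the day-2 test block),
  Fisher-z MVLC patterns and the reactivation index
  r(task, post-rest) − r(task, pre-rest), and ROI-to-ROI connectivity.
- **Statistics** — residual-based partial correlations with controls
  and covariates, Steiger/Pearson–Filon comparisons of dependent
  correlations (including the pre-vs-post Glu–GABA coupling change),
  Fisher comparison of independent correlations, hand-rolled
  Benjamini–Hochberg FDR within hypothesis families, the 3×IQR outlier
  fence, and the `value ~ Time*Group + (time | ID)` mixed model.

## Worked example

Simulate a full two-day cohort (36 learners, 21 controls) at a small
BOLD grid and run every stage:

```r
library(engramflow)

rc <- run_config(
  cohort  = cohort_config(grid_shape = c(8, 8, 8), n_volumes_rest = 60,
                          tr = 2, master_seed = 42),
  effects = effect_spec()
)
rep <- run_all(rc)
print(rep)
#> engramflow pipeline report (seed 42 )
#>   overnight gain: 10.20 % (SE 1.97), 25 improved / 5 levelled / 6 declined
#>   learning plateau from block 4
#>   E-I coupling (Learning): r_pre = 0.211, r_post = 0.668, Z = 2.43, p = 0.015
#>   FDR-significant families: glu_fc_putamen_R, glu_gain

subset(rep$battery, family == "glu_gain", select = c(x, y, r, df, p, q))
#>        x    y     r df       p       q
#>  glu_imm gain 0.534 28 0.00236 0.00709
#>   glu_30 gain 0.400 27 0.03165 0.03165
#>  glu_avg gain 0.467 29 0.00810 0.01215
```

Reading the output: the simulated learning group improved 10.2%
overnight (the generator plants a 10.46% mean with realistic
between-subject spread, so a handful of subjects level off or decline);
the consecutive-block contrasts place the learning plateau at block 4;
the across-subject correlation between Glu and GABA strengthens from
r ≈ 0.21 at baseline to r ≈ 0.67 over the post-learning period
(dependent r-to-z Z = 2.43); and among the correlation families, the
planted Glu-change → overnight-gain family survives FDR while the
control families do not. Each battery row is a partial correlation
controlling for the other metabolite's change (and day-1 performance
for gain rows), FDR-corrected within its family.

Setting `out_dir` in `run_config()` additionally writes the full set of
tables (`metabolites.csv`, `metabolites_qc.csv`, `delta_features.csv`,
`behavior.csv`, `block_scores.csv`, `overnight_gains.csv`,
`gm_volumes.csv`, `fc_edges.csv`, `mvlc_similarity.csv`,
`correlation_battery.csv`, `phase_segmentation.json`, `report.json`,
`report.md`), which `validate_outputs()` checks for schema and
invariant violations.

All generators are deterministic under `master_seed`; the planted
effect structure (coupling 0.18 → 0.58, Glu–gain partial r = 0.45,
GABA(30 min)–ΔGM r = −0.48, connectivity and reactivation loadings
0.45) is calibrated analytically on the measurement scale — see the
methods vignette (`vignettes/methods.Rmd`) for the model, its
assumptions, and known limitations.

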