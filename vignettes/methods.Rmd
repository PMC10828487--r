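---
title: "Methods: simulating and analyzing early neurochemical correlates of motor memory consolidation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing early neurochemical correlates of motor memory consolidation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific problem

After a motor skill is practiced, the new memory keeps being processed
"offline". Early changes in the primary motor cortex (M1) — in the
excitatory transmitter glutamate (Glu) and the inhibitory transmitter
GABA, measurable with single-voxel MR spectroscopy — are hypothesized to
relate to the overnight consolidation of the skill: behavioral offline
gains, changes in M1–putamen functional connectivity, gray-matter volume
changes in M1, and a multivoxel correlate of memory reactivation.
`engramflow` implements this analysis chain end to end and couples it to
a seeded synthetic two-day cohort whose planted effect structure mirrors
the study design it emulates: a Learning group (n = 36) and a resting
Control group (n = 21); six MRS time points (baseline, four post scans
across the first ~30 minutes, day-2 baseline); twelve 30-s practice
blocks of the five-digit sequence 4-1-3-2-4 plus one day-2 test block;
pre/post/day-2 resting BOLD and a task run.

Because every effect is planted by construction, the pipeline can be
validated by parameter recovery: what passing tests show is that the
*methods* are correct and calibrated, not that any real brain behaves
this way.

## MRS quantification

Water-scaled metabolite estimates are converted to tissue-corrected
concentrations with

$$\mathrm{factor}(f_{gm}, f_{wm}, f_{csf}) =
\frac{43.3\, f_{gm} + 35.88\, f_{wm} + 5.556\, f_{csf}}{1 - f_{csf}},$$

using water concentrations of 43.3 M (gray matter), 35.88 M (white
matter) and 5.556 M (CSF). The denominator renormalizes for the
assumption that metabolites are absent from CSF; no T1 term is applied
(long-TR regime) and a single T2 regime is assumed for GM and WM. This
is the unique water-scaled form consistent with those assumptions; the
published description names the constants but not the equation, so the
formula is stated explicitly here and pinned by tests. Alternates
(no tissue correction; creatine-referenced ratios) are exposed as
pipeline switches for sensitivity analyses.

Quality control excludes measurements with water linewidth strictly
above 15 Hz FWHM, SNR at or below 30, or a concentration more than 3 SD
from the mean of all time-point measurements of that metabolite. The 3-SD
pool is all measurements within group by default (a `group_pooled`
switch exists; the description of the rule is ambiguous on this point
and the within-group reading avoids mistaking a group difference for an
artifact). CRLB is reported in the audit table but is not an exclusion
criterion. Change features per subject and metabolite are the immediate
change (first post scan − baseline), the 30-minute change (last post
scan − baseline), and the averaged change (mean of unflagged post scans −
baseline).

The four post-learning scans are placed at 0, 10, 20 and 30 minutes.
Only the span ("the first 30 minutes") is fixed by the design being
emulated; the uniform spacing is an assumption of this package.

## Behavior

A block's score is the number of completed 4-1-3-2-4 sequences in its
key-press stream, counted by a left-to-right scan. On a mismatch the
default scanner resets the cursor to the longest viable restart position
(a Knuth–Morris–Pratt failure function), so a doubled press does not
erase a partially correct continuation; completions are counted
non-overlapping. Because the original task description does not specify
mismatch handling, a `strict_reset` variant (cursor to the start,
mismatching press dropped) is also provided. The default scanner is
provably equivalent to greedy leftmost non-overlapping substring
counting, which is the brute-force oracle used in tests.

The early/late phase boundary is estimated by fitting a
random-intercept, random-slope linear mixed model of block score on
block (block categorical in the fixed part, a scaled continuous block
term in the random part) and performing uncorrected pairwise comparisons
between consecutive blocks; the late phase starts at the first block
from which no consecutive contrast is significant at α = 0.05 (all
later contrasts must also be non-significant). Overnight gain is
100 × (day-2 test − last day-1 block)/(last day-1 block).

## BOLD features

**ILC.** The integrated local correlation of a voxel is the
Gaussian-weighted average of the Pearson correlations between its time
course and those of neighboring voxels, with weights
$\exp(-d^2/2\sigma^2)$, $\sigma$ = 1 mm, truncated at $3\sigma$ and the
self-correlation excluded; distances are physical (voxel size in mm).
With 1.6 mm voxels the truncated support is exactly the 26-neighborhood,
i.e. each voxel's directly surrounding voxels. Edge voxels are
normalized by the available weight mass. The computation is defined
explicitly (rather than delegated to an external toolbox) precisely so
that a naive double-loop oracle exists; whether other implementations
include the center voxel or normalize differently is a dialect choice,
and this package's dialect is pinned by tests to 1e-10 against the
oracle.

**Engram ROI.** The M1 region of interest is the conjunction of voxels
with z > 3.1 in the GLM of the last day-1 practice block and in the
day-2 test block, with connected components (26-connectivity) below a
minimum cluster size removed. The GLM uses boxcars convolved with the
canonical double-gamma HRF (response peak 6 s, undershoot 16 s, ratio
1/6), a temporal-derivative regressor, an intercept and a linear drift;
cluster-level random-field inference is deliberately replaced by this
voxel threshold + cluster-size rule, since the ROI definition — not the
inference machinery — is what downstream stages need.

**MVLC reactivation.** The task pattern is the vector of Fisher-z ILC
values over the ROI voxels computed from the concatenated late-phase
task volumes (the first 5 volumes after each block onset are dropped as
hemodynamic transition; configurable). Rest patterns are computed the
same way from the pre- and post-learning rest runs. Patterns use a fixed
canonical voxel ordering (ascending linear array index), so element i
always refers to the same voxel. The reactivation index is
r(task, post-rest) − r(task, pre-rest).

**Connectivity.** ROI-to-ROI functional connectivity is the Fisher-z
transformed Pearson correlation of ROI-averaged time courses;
session differences are plain subtractions. "Overnight" changes are
day-2 rest minus post-learning rest; "short-term" changes are post
minus pre.

## Statistical battery

Partial correlations are residual-based: both variables are residualized
on the union of controls (the other metabolite's change, following the
design's "controlling for the other metabolite" rule) and covariates
(day-1 final performance for all gain correlations); df = n − 2 − k.
Dependent overlapping correlations are compared with Steiger's (1980) Z
using the Pearson–Filon covariance; dependent non-overlapping
correlations (the pre- vs post-learning Glu–GABA coupling) use the same
covariance algebra with Fisher z (the Raghunathan–Rosenthal–Rubin
form), signed so that Z > 0 means increased coupling; independent
correlations use the classical Fisher r-to-z comparison. The exact
variant used by general-purpose comparison software is not recoverable
from published values, so the variants here are stated and oracle-tested
(a resampling oracle for the dependent case). Benjamini–Hochberg FDR is
applied within hypothesis families (e.g. the three Glu–gain tests form
one family); the family structure is encoded in one place
(`engramflow:::.battery_spec`) and written into every battery row.
Non-metabolite continuous measures are screened with the 3×IQR fence
rule (linear-interpolation quartiles) before entering correlations.

The repeated-measures model for metabolite dynamics is
`value ~ Time * Group + (1 + time | ID)` fitted by REML with
Satterthwaite denominator df (Time categorical in the fixed part, scaled
continuous in the random part, which keeps the random-effects dimension
identifiable with six time points); a singular fit falls back to random
intercepts with a warning. Its type-I error for the Time × Group
interaction is verified by simulation from the model's own null — the
cohort generator's pre/post block-shift covariance is deliberately
richer than the fitted random-slope structure, so generator-based null
data would measure model misspecification rather than test calibration.

## The synthetic cohort

Subject-level structure is planted through a linear-latent model:
independent standard-normal basis components drive baselines (Glu–GABA
baseline correlation 0.18), change scores (delta = slope × (baseline −
mean) + group response + noise, slopes negative: regression to the
mean), scan-to-scan noise, and downstream outcomes. Because every
observable is a linear combination of the basis, every covariance is
available in closed form, and the generator *solves* for its
coefficients so that the planted correlations hold on the measurement
scale — e.g. the cross-correlation of the Glu and GABA change noises is
chosen so that the measured averaged post-period concentrations
correlate at exactly 0.58 in the Learning group (0.18 in Controls), and
the gain loadings are chosen so that the measured partial correlation
between averaged Glu change and overnight gain given GABA change is
exactly 0.45. Planted values follow the emulated study's reported
effects: mean overnight gain 10.46% (SE 1.8% at n = 36, hence a
between-subject SD of 10.8%), GABA(30 min)–ΔGM(M1) correlation −0.48,
baseline-dependence correlations near −0.5 (Glu, learning) and −0.7
(GABA, both groups).

Quantities that pass through the BOLD simulator (connectivity changes,
reactivation) are planted at the session-target level (latent loadings
0.55 for the Glu-connectivity link and 0.45 for reactivation) and are
attenuated by finite-run sampling noise; the realized subject-level
correlations come out near 0.2–0.45, matching the magnitude of the
effects the design assumes. The loadings are calibrated so that the
planted links remain *detectable* at the study's sample size after this
attenuation — a defining condition of the simulated study, since an
undetectably planted effect would validate nothing. The attenuation
itself is intentional: it is exactly what the measurement process does
to a latent effect.

Behavioral block scores follow a saturating curve — fractions (0.45,
0.80, 0.99) of the subject's plateau over blocks 1–3, plateau from block
4 — with AR(1) block-to-block noise (sd 2.5, autocorrelation 0.65).
The serial correlation reflects slow attention/arousal fluctuations in
real block performance and is a defining study condition of the
generator: it makes the iid-residual mixed-model contrasts conservative
per comparison, which is what keeps the all-suffix plateau rule's
changepoint recoverable (the package's recovery tests require boundary
= 4 in at least 90% of cohorts). Key-press streams encode the intended
count as contiguous copies of the target with doubled-press insertions
only at copy boundaries (a doubled symbol can never occur inside
4-1-3-2-4) plus an optional trailing partial prefix, so streams decode
to their intended counts exactly.

BOLD realism is limited to AR(1) voxel noise plus latent neighborhood
structure (a Voronoi parcellation of the M1 box with per-voxel loadings,
determined by a per-subject pattern seed) and uniform edge-latent
injections for connectivity; there are no physiological or motion
confounds, no registration errors, and no spatial autocorrelation beyond
the parcels. Conclusions about robustness to such confounds cannot be
drawn from these simulations.

## Problem sizes and numerical choices

The default cohort uses a 16^3 voxel grid and 120 rest volumes; the
simulation studies in the test suite and the recovery experiments use
8^3 grids, 60–80 rest volumes and TR = 2 s, sizes chosen so a full
50-cohort experiment is routine on a laptop while keeping every ROI at
or above the 10-voxel minimum for pattern analyses. Fisher-z values are
clipped at |ILC| = 1 − 1e-6 with a warning; zero-variance voxels
contribute correlation 0; session connectivity targets are clamped to
|z| ≤ 1.2 and the joint injection solve caps each |r| at 0.8 with a
feasibility rescale (the M1 mean carries all edge latents). Seeds are
derived per subject and stage from the master seed, so any stage can be
re-simulated independently and the whole pipeline is byte-deterministic
given its configuration.

## Known limitations

- The generator's pre/post block-shift covariance is richer than the
  random-slope LMM used for group-level metabolite dynamics; group-level
  F-tests on generator data are therefore mildly misspecified (as they
  would be on real data), and test calibration is instead verified under
  the model's own null.
- With ~15 hypothesis families each FDR-controlled at 0.05, some family
  is expected to fire by chance in roughly a third of null cohorts;
  "fully clean" null pipelines are correspondingly rare. This is a
  property of any battery of this breadth, not of the implementation.
- The reactivation index inherits substantial pattern-sampling noise at
  the simulated run lengths; its planted subject-level correlation with
  Glu change is attenuated to ~0.2 at the default sizes.
- Connectivity calibration approximates the conjunction ROI by the
  planted engram cube when solving injection weights; the realized
  session correlations deviate from their targets by a few percent.
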