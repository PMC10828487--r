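Package: engramflow
Title: Simulation and Analysis of Early Neurochemical Correlates of Motor
    Memory Consolidation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyze a two-day multimodal motor
    sequence learning cohort: tissue-corrected single-voxel MRS
    quantification of glutamate and GABA with quality-control exclusion
    rules, key-press scoring and learning-phase segmentation for a
    five-digit tapping task, integrated local correlation (ILC) maps and
    multivoxel pattern similarity as a correlate of offline memory
    reactivation, ROI-to-ROI functional connectivity, and a partial
    correlation battery with within-family false discovery rate control.
    A seeded synthetic cohort generator plants the assumed effect
    structure (regression-to-the-mean metabolite dynamics, post-learning
    excitation-inhibition coupling, metabolite-behavior and
    metabolite-plasticity correlations, reactivation pattern fidelity) so
    the full pipeline can be exercised and validated end to end without
    any scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
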