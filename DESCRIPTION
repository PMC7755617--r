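Package: hippoquant
Title: Quantitative Hippocampal Volumetry and T2 Relaxometry Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quantification of the two imaging biomarkers of
    hippocampal sclerosis: hippocampal volume loss and elevated quantitative
    T2 (qT2). Computes voxel-wise qT2 maps from dual effective-echo
    fast-spin-echo images via the two-point monoexponential fit, global
    hippocampal volume and qT2 with left:right ratios, and posterior-anterior
    long-axis cross-sectional area and qT2 profiles from binary hippocampal
    masks. Individual results are contextualised against normative reference
    ranges (mean +/- 1.96 SD) built from a healthy cohort and assembled into a
    structured quantitative report (QReport) rendered as self-contained HTML.
    Includes a synthetic dual-echo phantom generator with ground truth for
    end-to-end validation, and the complete reader-study statistical battery
    (accuracy, Cohen's kappa, McNemar, paired t with d_z and Hedges' g_z,
    Cronbach's alpha, ICC, repeated-measures and mixed ANOVA with partial eta
    squared) together with a parametric rater simulator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    EBImage,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
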