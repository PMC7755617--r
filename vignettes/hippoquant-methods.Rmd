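---
title: "Quantitative hippocampal volumetry and T2 relaxometry: models and methods"
author: "hippoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative hippocampal volumetry and T2 relaxometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippoquant)
```

## The clinical problem

Hippocampal sclerosis (HS) — neuronal loss and gliosis of the hippocampus —
is the commonest cause of temporal lobe epilepsy and is treatable by
resective surgery when correctly lateralised. Its two MRI biomarkers are
hippocampal volume loss and elevated T2 signal. Visual assessment misses
subtle disease: volume asymmetry is reliably seen by eye only at ratios of
about 0.7 or below, and bilateral disease removes the contralateral
reference entirely. This package quantifies both biomarkers from clinical
dual-echo acquisitions and hippocampal segmentations, contextualises them
against a normative cohort, and assembles the result into a structured
quantitative report (QReport). It also implements the full reader-study
statistical battery needed to validate such a report against a gold
standard, plus a parametric rater simulator.

Segmentation itself is out of scope: binary left/right hippocampal masks
are inputs, produced by whatever segmentation tool the site uses.

## Quantitative T2 from two effective echoes

With a dual effective-echo fast-spin-echo acquisition (defaults TE = 30 and
119 ms, TR 7600 ms) the signal at each voxel is modelled as monoexponential
decay, $S(TE) = S_0\,e^{-TE/T_2}$. Two echoes determine the two unknowns
exactly:

$$T_2 = \frac{TE_2 - TE_1}{\ln(S_1/S_2)},\qquad S_0 = S_1\,e^{TE_1/T_2}.$$

The closed form is preferred over iterative least squares because with two
points they coincide, and the closed form is exact and fast. Handling of
degenerate voxels is this package's own policy: a fit is *valid* only when
the signal decays ($S_1 > S_2$), the late echo exceeds a noise floor
($\varepsilon = 10^{-6}$ signal units), and the resulting T2 lies inside a
clamp range (default [1, 2000] ms). Invalid voxels carry a `NaN` sentinel
and a zero validity flag, so downstream summaries must mask explicitly —
failures are visible rather than silently clamped. The share of
non-physical and clamp-rejected voxels inside the hippocampal ROI is
reported as fit QC.

Additive Gaussian noise leaves the two-point estimator effectively unbiased
at hippocampal SNR: the validation suite checks a bias below 2 ms at
$\sigma/S_0 = 1\%$ over roughly 4000 mask voxels.

## Global metrics and left:right ratios

Volume is voxel count times voxel volume, exact. Global qT2 is the mean of
valid in-mask fits (median by configuration; the mean is the default
because the normative bands are Gaussian). Asymmetry is expressed as the
plain left:right ratio, $100\,L/R$, for both volume and qT2.

Clinical tabulations of unilateral disease sometimes order ratios
affected:unaffected instead; because that labelling is ambiguous for
normal and bilateral cases, the package always reports the plain
left:right ratio and, alongside it, the orientation-free asymmetry ratios
(min:max for volume, max:min for qT2) which quantify asymmetry magnitude
regardless of side.

## Long-axis profiles

HS can be focal along the hippocampal long axis. The package computes
posterior→anterior profiles of cross-sectional area and qT2:

1. The long axis is estimated as the leading principal component of the
   in-mask voxel world coordinates. This is a deliberate, self-contained
   stand-in for group-template alignment, which requires an external
   template database; it is deterministic and validated against phantom
   geometry (direction within 10 degrees of the generating centerline's
   chord). The sign is fixed so the direction points anterior (positive
   world +A component in RAS+); if the anterior component vanishes, the
   largest remaining world component decides.
2. Projections onto the axis are binned into `nBins` (default 20)
   equal-width bins spanning the [2.5, 97.5] percentile interval of
   projections, padded outwards to cover every voxel so the bins always
   partition the mask — robust to stray voxels at the tips while conserving
   volume exactly.
3. Per bin: volume (exact), cross-sectional area = volume / bin width, and
   mean qT2 over valid fits (`NaN` where a bin has none).

Positions are normalised to [0, 1] with 0 posterior, which is also the
cross-subject correspondence used by the normative profile bands (a
stand-in for template-based correspondence). The default of 20 bins gives
roughly 2 mm sampling on an adult hippocampus; it is configurable.

## Normative model and flags

From a reference cohort the model stores, per metric and per profile bin,
the mean and SD, with reference bands mean ± 1.96 SD — the conventional
95% interval used on the report figures. No age/sex covariates are
modelled: the intended reference is a single age-matched pool. A minimum
cohort size of 20 is enforced because SD estimates below that are unstable;
the shipped default model derives from a reference population of n = 111
and carries bands for the two ratio metrics only (left:right volume ratio
88.9–110.6%, qT2 ratio 93.7–104.2%); absolute volumes and qT2 are displayed
with an explicit "no reference" marker under that model.

Flagging is a pure function of the bands: each metric is low/high outside
its band. The overall impression names the implicated side (lower volume or
higher qT2) when a ratio is abnormal; when both sides are implicated, or
when the ratios are normal but both absolute volumes are low (or both qT2
high), it reports bilateral abnormality. The bilateral rule is this
package's explicit aggregation — bilateral disease can present with normal
ratios, which is exactly why absolute-value flags are needed — and is
labelled machine advice in the report, not a diagnosis.

Coverage calibration: healthy Gaussian draws evaluated against a model
built from an independent simulated cohort of 111 are flagged per metric at
5% ± 2% (10,000 draws). Note that any *single* finite reference cohort
carries SD-estimation noise, so one model's realised flag rate can sit a
few points off 5% even when the procedure is perfectly calibrated; the test
suite therefore also checks the rate averaged over replicate models.

## The QReport

The report is JSON-first: a deterministic document holding demographics
(age, gender, scan date, scanner, hospital — the non-identifying set, no
free-text history), fit QC, the six global metrics each paired with its
band or a no-reference marker, both profiles with per-bin bands, flags,
snapshot references and provenance (pipeline version, model cohort size and
seed). Raw values are stored unrounded; display values round ratios and
qT2 to one decimal and volumes to whole mm³. HTML rendering is a pure view:
every number shown exists in the JSON, figures are deterministic inline
SVG (subject curve in black over the blue normative band), and re-rendering
a fixed document is byte-identical. Segmentation snapshots are the three
orthogonal slices through each mask's centroid voxel with the mask boundary
(4-neighbour erosion difference) outlined.

## The synthetic phantom

Every stage is testable without data downloads via a phantom generator.
Each hippocampus is a curved tube: a cubic-spline "banana" centerline
(about 40 mm long), elliptical cross-section (default vertical flattening
0.75), and a sinusoidal taper towards both ends (end radius 0.35 of the
6 mm base radius). The curvature is deliberate so the principal-axis
extraction is non-trivially exercised. Pathology knobs:

* `atrophyFactor` scales the radius by its square root so total volume
  scales linearly with the factor (verified within 3% against voxel
  counts, and within 5% against the analytic tube integral
  $\pi a b \int r(s)^2\,ds$);
* `t2Elevation` multiplies T2 globally, or as a Gaussian bump in
  arc-position when a focal centre is set.

Signal synthesis applies the monoexponential model with the acquisition's
echo times plus i.i.d. additive Gaussian noise. Additive Gaussian rather
than Rician noise keeps the two-point fit unbiased at phantom SNR; a Rician
option is noted as future work. The background is a single tissue
ellipsoid (S0 800, T2 80 ms) with zero-signal exterior — the pipeline only
reads within masks, so richer anatomy would add nothing testable. All
randomness flows from one explicit seed with a documented draw order
(global size, left/right radius jitter, left/right T2 jitter, per-subject
noise seeds drawn up front), so regeneration is bit-identical.

Ground truth (exact mask volumes, generating mean T2, true long-axis T2
profile) is recorded per subject and written as a JSON sidecar next to the
NIfTI volumes, with a CSV manifest per cohort.

The reference-cohort generator draws between-subject variability as
overall size SD 4%, per-side radius SD 2% and per-side T2 SD 1.9%. These
were fixed once so that the induced left:right ratio spreads (volume ratio
SD ≈ 5.5%, qT2 ratio SD ≈ 2.7%) match the widths of the shipped normative
ratio bands, i.e. the generator emulates a healthy adult reference
population on the ratio scale. What the phantom does *not* emulate:
partial-volume effects, real hippocampal shape variation, B1/stimulated
echoes, scanner artefacts, or segmentation error (masks are exact by
construction). Passing phantom tests therefore demonstrates algorithmic
correctness of the quantification chain, not clinical performance on real
MRI.

## Reader-study statistics

The rating outcome is nominal with four categories (normal, right, left,
bilateral HS) plus 1–5 confidences for the normality and lateralisation
decisions. Conventions, chosen where the field admits variants:

* **Detection** collapses ratings to normal/abnormal: a wrong side on a
  true abnormal still counts as a true positive; lateralisation accuracy
  (exact category match on abnormal gold cases) is scored separately.
  Accuracy = 100 (TP+TN)/(TP+TN+FP+FN).
* **Cohen's kappa** is unweighted 4-category with chance agreement from
  marginal products; the outcome is nominal, so weighting has no natural
  order. Bands: 0.60–0.79 moderate, 0.80–0.90 strong, extended below
  (none/minimal/weak) and above (almost perfect) following the same scale
  family. Group kappa summaries are unweighted means over the group's
  raters.
* **McNemar** uses the exact two-sided binomial when the discordant count
  is below 25 and the continuity-corrected $\chi^2_1=(|b-c|-1)^2/(b+c)$
  otherwise; the variant switch is this package's policy since the test
  name alone does not fix one.
* **Paired contrasts** report $d_z$ (mean of differences over SD of
  differences), Hedges' $g_z = d_z(1 - 3/(4\,df-1))$, and the classical
  averaged-SD d, all labelled — the two d conventions differ numerically
  and are often conflated.
* **Reliability**: Cronbach's alpha on case-wise sums, and ICC under the
  two-way mixed-effects, consistency definition, single and average
  measures, computed from the two-way ANOVA mean squares; the model name
  is stamped into the output since "ICC" alone underdetermines the
  estimand. Ratings enter numerically coded (normal 0, right 1, left 2,
  bilateral 3).
* **Confidence ANOVA**: balanced repeated-measures / mixed designs only,
  via the standard error-stratum decomposition (within effects against
  their subject × factor strata, between effects against
  subject-within-group), with partial
  $\eta^2 = SS_{effect}/(SS_{effect}+SS_{error})$. Unbalanced input is
  rejected, never approximated. No multiple-testing correction is applied
  anywhere in the battery.

The simulator draws, per rater × case × condition, detection with a
per-group sensitivity/specificity (shifted by a report delta under the
with-report condition), exact lateralisation with probability λ (uniform
error among the remaining abnormal categories otherwise), and discretised
Gaussian confidences (clipped to 1..5) whose mean depends on correctness
and condition. The default design is 43 cases (23 normal, 6 left, 9 right,
5 bilateral HS) × 9 raters in three experience groups × 2 conditions = 774
records; the default operating point (sensitivity 0.875, specificity
0.874, lateralisation 0.835, report deltas +0.025/+0.076/+0.08) represents
a high-baseline reading panel whose accuracy moves from about 87.5% to
about 92.5% with the report. A simulator→analyzer round trip recovers the
generating sensitivity within 3 binomial standard errors over 200
replicate studies.

## Validation problem sizes and numerical choices

The shipped validation battery uses: noise-free and 1%-noise phantoms
(~4200 mask voxels), 100 random tube geometries for volume conservation,
100 seeded noisy phantoms for focal-lesion localisation (≥95 must localise
to the correct bin; the focal centre 0.5 lies on the shared edge of the
two central bins, so either counts), a 111-control normative model with
10,000 healthy draws, and 200 replicate simulated reader studies. Grid
tolerance is $10^{-5}$ on affine entries (absorbs header float noise
without hiding misregistration); NIfTI round trips are exact on data and
within $10^{-6}$ on affines; the long-axis fit requires at least 10 voxels
and a leading principal SD at least 5% above the second, otherwise the
input is rejected as degenerate.

## Known limitations

Principal-axis alignment approximates but does not replicate template
correspondence, so bin-wise positions are comparable across subjects only
in the normalised sense. The two-point fit cannot separate multi-component
T2 decay or correct stimulated echoes. The shipped normative bands cover
ratio metrics only and carry no covariate adjustment. The bilateral flag
rule is a display heuristic, not a validated classifier. The phantom's
noise is Gaussian, not Rician, and its masks are error-free.
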