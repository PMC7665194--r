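---
title: "The dynamic structure-function model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dynamic structure-function model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsfprog)
```

## The problem

Glaucoma damages the optic nerve (structure) and degrades the visual field
(function), and clinicians monitor both over time to detect progression.
Structural measurements — neuroretinal rim area (RA, mm²) from confocal
scanning laser ophthalmoscopy, or retinal nerve fiber layer thickness
(RNFLT, µm) from OCT — and functional measurements — static automated
perimetry (SAP) mean sensitivity (MS) or mean deviation (MD), both reported
in decibels — live on incommensurate scales and are usually trended
separately. `dsfprog` implements a joint approach: both components are
rescaled to *percent of mean normal* and each eye's visit history becomes a
trajectory of paired points $X_i = (f_i, s_i)$ in a two-dimensional plane.

## The two predictors

**DSF.** Given visits $X_1,\dots,X_k$ at times $t_1 < \dots < t_k$, the
dynamic structure-function model summarizes the series by a *centroid*
$C = \frac{1}{k}\sum_i X_i$ — an estimate of the current disease stage —
and a *velocity vector* built from the visit-to-visit difference quotients
$(X_{i+1}-X_i)/(t_{i+1}-t_i)$. Published descriptions of the model admit
two readings of the velocity: the narrative one (an *average* of all rates
of change) and a displayed formula that is a bare *sum* of the quotients. Both
are implemented (`velocity_rule = "mean"` / `"sum"`); the mean is the
default because it is the only reading with the units of a rate (percent
per year) and the only one that is stable in the number of visits. Every
output table echoes the variant used.

The extrapolation rule is likewise carried in two forms. The default,
`prediction_rule = "centroid_anchored"`, is

$$P = C + V\,(t_{\text{target}} - \bar t),$$

which anchors the prediction at the centroid's own time $\bar t$ (the mean
of the fitted visit times). Because the centroid of points on a line lies on
that line at $\bar t$, and the mean of the difference quotients of a line is
its slope, this rule reproduces noiseless linear trajectories *exactly* for
arbitrary visit spacing — a property the test suite asserts to 1e-9. The
alternative, `prediction_rule = "printed"`, reproduces the typeset formula
$P = C + V/(t_{\text{target}} - t_k)$ verbatim. We keep it selectable for
auditability but do not default to it: dividing a rate by a time interval is
dimensionally inconsistent, and the rule contradicts the accompanying
description of extrapolating from the centroid along the velocity. This is a
deliberate design decision, recorded here rather than hidden.

**OLSLR.** The comparator fits ordinary least squares lines over time to the
functional and structural components independently and evaluates both at the
target time. On noiseless lines it too is exact; the implementation is
cross-checked in the tests against a brute-force numerical minimizer of the
sum of squared residuals.

Prediction error (PE) is the Euclidean distance between the predicted and
observed pair, in percent of mean normal; it is the square root of the sum
of the squared per-component differences.

## Grid geometry and linear-domain averaging

SAP sensitivities are decibel quantities; averaging is done after conversion
to linear units, $10^{\mathrm{dB}/10}$ (1/Lambert), and MD is linearized the
same way. The 30-2 (76 points) and 24-2 (54 points) patterns are shipped as
explicit coordinate fixtures rather than constructed from an eccentricity
rule, because published boundary rules disagree and fixtures make the point
counts (76/74, 54/52 after removing the two points straddling the blind spot
at (15°, ±3°) temporal) directly testable. The 52 non-blind-spot 24-2 points
are a subset of the 30-2 pattern, so 24-2 summaries can be extracted from a
30-2 field.

Garway-Heath optic-disc sector labels are stored on the 24-2 fixture. The
central/temporal sector is the 4x4 block of points within 9° of fixation —
exactly the 16 points the central-region MS is defined over. The remaining
assignments follow the anatomical scheme of the published map (superior
field to inferior disc; nasal field via the temporal-retina arcuate bundles
to the infero/superotemporal disc poles; temporal field to the nasal disc):
they are a transcription of that scheme onto the 6° grid, and only the IT,
ST and central sectors are consumed by the analysis pipeline. Left eyes are
mirrored to right-eye orientation about the vertical midline before sector
assignment; published descriptions do not state how left eyes were
oriented, so this convention is our choice.

## Rescaling

Percent of mean normal is $100 \cdot \text{value}/\text{normal}$ with
default normals RA 1.44 mm², RNFLT 98.47 µm, linearized MD 1.06 1/L,
linearized MS 972.60 1/L. The linear-domain values are primary; their
decibel annotations are not exact $10^{x/10}$ counterparts of the printed
linear values (972.60 1/L vs 29.90 dB, which would give 977.2), so the
linear values are used verbatim and never re-derived from the dB
annotations. Sectoral RA/MS normals are not published; `mean_normals()`
deliberately ships no defaults for them, and the synthetic pipeline supplies
its own, because silently inventing normative constants would be worse than
requiring the user to state them.

## Quality control and cohort assembly

Visit-level reliability rules, strict inequalities as published: HRT images
with mean pixel height SD above 50 µm are excluded; visual fields with false
positives, false negatives or fixation losses above 33% are excluded; OCT
scans are usable only with signal strength strictly greater than 15 dB.
Boundary values (exactly 50 µm, exactly 33%) are kept; exactly 15 dB is
excluded. A record missing a QC field its modality requires is excluded with
reason `missing_qc` rather than passed through.

Eligibility is enforced per eye: at least 7 reliable visits with at least 3
months (0.25 y) between consecutive visits. An eye violating either rule is
dropped whole rather than having visits thinned: the eligibility criteria
are stated per eye, not as a visit-pruning rule, and whole-eye dropping keeps
the kept/excluded partition auditable. Whether the original analyses dropped
visits or eyes in this situation is not stated; this is a documented choice,
not an inference. Eyes — not patients — are the analysis unit, so both eyes
of a patient may enter and inter-eye correlation is not modelled; this is a
known limitation of the evaluation statistics.

## The evaluation protocol

`run_experiment()` predicts each eye's paired measurement at visits 4-7,
fitting each model to all preceding visits, and records the PE.
`compare_models()` then, per target visit (optionally per baseline
subgroup): computes each model's median PE with a distribution-free
order-statistic 95% CI; the percent of eyes where the first model's PE is
strictly lower; and a two-sided paired Wilcoxon signed-rank p at α = 0.05.
"Wilcoxon signed-rank test" underdetermines the procedure, so the classic
choices are made explicitly: zero differences are discarded; the exact
distribution is used for 25 or fewer untied pairs and the normal
approximation with continuity correction otherwise; and the test is
two-sided. No standard CI method for the median is implied either; the binomial
order-statistic interval is the default and a bootstrap percentile interval
was considered and rejected as a default for being seed-dependent.
`bland_altman()` provides limits-of-agreement analysis
(mean difference ± 1.96 SD) between paired PE vectors, e.g. DSF PEs from
30-2-derived versus 24-2-derived MS.

## The synthetic cohort generator

The studies this methodology was developed on are not publicly deposited, so
the package ships a generator whose defaults encode the cohort structure the
protocol expects: 7 visits per eye at 6-month intervals with ±1-month
uniform jitter (about 3-3.5 years of follow-up, comfortably inside the
reported multi-year windows); linear true decline in percent of mean normal
with per-eye rates drawn from N(-1.5, 1) %/yr; additive Gaussian measurement
noise with SD 2% per component (a few percent is a realistic test-retest
level for these indices once expressed on the percent scale); and a
121:97:175 mix of baseline strata (optic-neuropathy-alone, field-loss-alone,
both), which select whether the structural or functional baseline is the
damaged one (near 75%) or the spared one (near 95%). The strata are
sampling strata only — no pathophysiology is modelled. Raw instrument units
are emitted (mm², dB) so the full ingest/rescale path is exercised, and QC
metadata are drawn reliable by default with a configurable fraction of
visits made unreliable by pushing one QC field past its threshold.

In pointwise mode the generator emits 76-point dB fields whose linear-domain
mean over the 74 non-blind-spot points equals the visit's MS *exactly*:
per-point log-normal deviation factors (SD `point_scatter`, default 0.15)
are renormalized to preserve the linear mean, so global summaries are exact
while 24-2 and sectoral summaries genuinely differ from the 30-2 global, as
they do in real fields.

What the generator does *not* emulate — frequency-of-seeing perimetric
noise, eccentricity-dependent variability, learning and fatigue effects,
floor effects, censoring, treatment response, inter-eye correlation —
bounds what passing tests mean: they demonstrate correctness of the
machinery (exact recovery in the noiseless limit, unbiased velocity
recovery under Gaussian noise, calibrated QC rates), not clinical
performance on real cohorts. On this generator's linear-plus-Gaussian
trajectories both predictors are unbiased, so the DSF model's empirical
advantage on real clinical series should not be expected to reproduce here;
reproducing cohort-level results would require the original non-public
datasets.

## Numerical choices and problem sizes

Times are years from baseline; calendar dates should be converted at ingest
using actual day counts / 365.25. Duplicate visit times are rejected, not
merged. Linearized indices are floored at a tiny positive value (1e-3
percent) before dB conversion, since the log is undefined at zero. Exactness
properties are asserted at 1e-9; the OLSLR-versus-oracle agreement at 1e-6.
Validation simulations use 500 eyes for velocity recovery and determinism
checks and ~1e4 visits for QC-rate calibration — sizes at which binomial
and Monte-Carlo tolerances (|bias| < 0.3 %/yr at σ = 2%; excluded fraction
within ±2 percentage points of the configured 20%) are comfortably
discriminating, and a full run takes seconds.
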