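---
title: "Eye-movement digital biomarkers for depression-risk screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eye-movement digital biomarkers for depression-risk screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazedep)
```

## The screening problem

Depression alters how people allocate visual attention to emotional
material: attention is biased toward mood-congruent (sad, angry) faces and
away from happy and neutral ones, and psychomotor retardation slows and
shortens exploratory eye movements. `gazedep` implements an analysis
pipeline that turns raw free-viewing gaze recordings into *digital
biomarkers* of these phenomena and evaluates them as a screening
instrument for young adults at high risk of depression (HD, questionnaire
defined) versus low risk (LD).

The evaluation paradigm has four free-viewing tasks on a 1920 x 1080
display sampled at 60 Hz: (1) eight single European face photos, 5 s
each; (2) four 2 x 2 European face-photo matrices, 10 s each, with
neutral / angry / sad / happy in the four quadrants; (3) twelve single
Asian face photos, 5 s; (4) four 4 x 4 Asian matrices, 10 s. A complete
session therefore holds 28 gaze series. Stimuli are indexed
`Task n_P(m)` and matrix cells `Task n_P(m)y`.

## Biomarker definitions

All metrics operate on raw 60 Hz samples; no fixation/saccade event
detection (I-VT/I-DT) is applied, because the defining formulas are
sample-based. Let a stimulus presentation yield coordinates
$(x_i, y_i)$, $i = 1 \dots I$, at sampling rate $SR$.

**Single-face tasks (1, 3).** Five nested rectangular areas of interest:
overall (O) ⊇ face (F) ⊇ eye-to-mouth (EM) ⊇ eye-to-nose (EN) ⊇ eye (E).
Membership is the closed-inequality indicator
$f_{i,AOI} = \mathbf{1}[x_{min} \le x_i \le x_{max},\; y_{min} \le y_i \le y_{max}]$.

* Fixation time: $FT_{AOI} = \sum_i f_{i,AOI} / SR$ (seconds).
* Scan-path length: gaze inside an AOI splits into maximal runs of
  consecutive in-AOI samples ("tracks"); $SPL_{AOI} = \sum_j distance_j$,
  where $distance_j$ is the summed consecutive Euclidean step length
  within track $j$ (pixels).
* Average scanning speed: per-track speed $v_j = SR \cdot distance_j / k_j$
  ($k_j$ samples in the track); $ASS_{AOI} = \frac{1}{a}\sum_{j=1}^a v_j$
  (pixels/second), *missing* when no track exists ($a = 0$; dividing by
  zero tracks is undefined, and reporting 0 would fake an observation).
  Single-sample tracks contribute speed 0; excluding them instead would
  change ASS, so the convention is stated here and fixed.

That yields 3 metrics x 5 AOIs = 15 biomarkers per photo, 300 per
session. FT and SPL are provably monotone under AOI nesting; ASS is not.

**Matrix tasks (2, 4).** With per-cell viewing times $T_{(n,m)y}$ and the
matrix viewing time $T_{(n,m)}$:

* Fixation time per cell: $T_{(n,m)y}$, attributed to the cell's emotion.
* Attention level: per cell $AL = T_{(n,m)y} / T_{(n,m)}$; per emotion
  $AL_e = T_{(n,m)\_e} / T_{(n,m)}$ summed over that emotion's cells.
  One published formula assigns the sad numerator to the happy attention
  level, contradicting the metric's own name and every use of it in the
  results; we treat that as a typographical slip and compute
  emotion-matched levels.
* Attention shift: $AS_e = AL_e - AL_{neutral}$ for sad and happy.
* Attention times: the number of switch-and-return cycles into an
  emotion's cells. We require the excursion to touch a cell of a
  *different* emotion before the return counts (the definition speaks of
  switching "to" other-emotion photos); excursions touching only the
  background do not count. A flag
  (`require_different_emotion = FALSE`) counts every re-entry instead.

Both per-cell and per-matrix attention levels are emitted because the
published results reference both forms.

### Conventions and degenerate inputs

* Coordinates: origin top-left, x rightward, y downward, pixels;
  rectangle bounds inclusive on all four edges.
* Invalid samples (blinks, tracking loss, off-screen coordinates) are
  retained in the series but excluded from every membership count and
  distance sum, and they break track continuity. No interpolation or
  filtering is applied; gaps are flagged rather than repaired.
* $T_{(n,m)}$ is the *valid-sample* time by default, so tracking loss
  shrinks numerator and denominator coherently; a nominal-duration mode
  uses the scheduled 10 s instead.
* Timing is reconstructed from sample index as $t_i = i/SR$.
* AOI pixel bounds are configuration, not part of the paradigm
  definition: the packaged defaults centre a 1000 x 1000 px photo region
  with anatomically ordered nested feature boxes, and every extraction
  is parameterised by the AOI configuration used. The 4 x 4
  cell-to-emotion layout is likewise configuration; the packaged default
  is an arbitrary balanced layout (four cells per emotion) chosen once.

## Group comparison

For each biomarker, Levene's classic mean-centred test checks variance
homogeneity; the two-sample t-test is pooled when homogeneity holds
(Levene p >= 0.05) and Welch otherwise. The pooled variant reproduces
the published t values recomputed from the printed mean (SD) pairs, so
it is the default under homogeneity. Effect sizes are Cohen's d with the
pooled SD. The t statistic is oriented LD − HD (negative t means the HD
mean is larger), matching the published tables. Sex-type 2 x 2 tables
use Pearson's chi-square *without* Yates correction — with correction the
published sex comparison (9/20 vs 3/26, p = 0.052) is not reproduced
(p ≈ 0.10). Benjamini–Hochberg adjustment is applied per task family by
default; the exact family used in the source analysis is not recoverable
from the printed values, so a global mode is provided and neither mode
claims to reproduce the printed FDR column.

## Screening

Candidates are the biomarkers with unadjusted p < 0.05. Forward stepwise
binary logistic selection uses likelihood-ratio entry at 0.05 and
removal at 0.10 (the common statistical-package default; the source
analysis states only "forward selection"), with deterministic
name-order tie-breaks. Fits are maximum-likelihood IRLS
(`glm`, log-likelihood tolerance 1e-8); complete or quasi-complete
separation — plausible at n = 29 + 29 with several strong markers — is
detected and flagged rather than silently penalised, since plain
logistic regression is the stated model. Evaluation is in-sample, as in
the source analysis: per-marker ROC curves (direction oriented so
AUC >= 0.5, orientation recorded) and a combined ROC from the fitted
probabilities. The AUC is the trapezoidal area, identical to the
tie-corrected rank (Mann–Whitney) statistic; both are computed and
cross-checked. A cross-validated mode would go beyond the source
analysis and is deliberately not provided.

## Synthetic data

No participant data are distributed, so the package generates its own at
two levels.

**Feature level.** `simulate_feature_table()` draws each biomarker
independently from a Gaussian with the transcribed group mean and SD
(29 per group in the source study), clipped to the metric's domain
(FT in [0, duration], AL in [0, 1], SPL/ASS/AT >= 0). Independence is a
deliberate simplification — no between-biomarker covariance was
published — and a correlation-matrix hook exists for sensitivity
studies. Attention times are simulated as continuous by default because
the published tables report them as mean (SD); integer rounding is a
flag. Clipping matters: for biomarkers whose mass lies near a bound
(e.g. happy-face fixation times of 0.18 (0.22) s), the clipped
distribution's implied Cohen's d differs from the raw parameters' d by
up to ~0.15. `clipped_normal_moments()` and `spec_implied_d()` give the
exact generative moments, and the tests assert recovery against that
closed form (and against the raw d where clipping is negligible,
analytic shift < 0.02).

**Stream level.** `simulate_gaze_session()` scripts fixation dwells
(target chosen from per-emotion or per-AOI weights, jittered around a
uniform target point, clipped inside the target rectangle) connected by
constant-speed linear saccades, at 60 Hz. Realism is deliberately
minimal — no main-sequence saccade dynamics, no pupil signal — because
the extraction formulas are sample-based and only dwell placement
matters for testing. Default scales: dwell 0.45–0.6 s, jitter SD 3–4.5 px
(drift/microsaccade scale, which sets scan-path length near the
published ~1500–2700 px per 5 s photo), saccade speed 15000 px/s (about
350–400 deg/s at the acquisition geometry, so transitions cost only a
couple of samples). The generator returns bookkeeping (per-AOI dwell
sample counts, dwell path lengths, saccade/background sample counts)
against which extraction is tested with an exact sandwich bound: for
disjoint regions, dwell count <= extracted count <= dwell count +
saccade samples.

`calibrated_group_policies()` encodes the published effect directions:
the HD policy has a higher sad dwell weight and lower happy/neutral
weights (attention bias), rarely disengages from sad photos (longer sad
fixation time), and uses smaller jitter (shorter scan paths, slower
scanning — psychomotor retardation). These are direction calibrations
only; the stream-level generator makes no claim to reproduce published
magnitudes, which is why magnitude-matched cohorts come from the feature
level.

What passing tests do *not* show about real data: real gaze biomarkers
are correlated within subject, non-Gaussian near their bounds, and
contaminated by calibration drift; the in-sample combined AUC of the
source study (0.974) depends on the unreleased cohort and cannot be
reproduced or refuted from synthetic marginals. The screening-stage
tests therefore check *properties* (combined model dominating single
markers at the study's n; stepwise false-inclusion consistent with its
entry level on pure noise) rather than that number.

## Heat maps

`gaze_density()` accumulates one isotropic Gaussian bump per valid
sample on a downsampled grid (default 4 px cells), truncated at four
bandwidths. The default bandwidth is 40 px, roughly one degree of visual
angle at the 70 cm viewing distance and display geometry; it is a
smoothing choice, not a measurement. Intensities are additive (pooled
groups = sum of subjects) and peak-normalised only for colormapping
(green → yellow → red). Group maps pool raw samples by default;
averaging per-subject maps is available by composing per-subject
densities. Since the facial photographs are not redistributable,
overlays render onto schematic synthetic face placeholders with the same
AOI geometry.

## Numerical and testing choices

Every statistical primitive is checked against an independent oracle:
literal loop transcriptions of the metric formulas on random series,
brute-force pair counting for AUC, the step-up definition for BH,
`car::leveneTest` / `pROC` cross-checks, and direct Nelder–Mead
likelihood maximisation for the logistic fit. Simulation problem sizes
in the tests — 1000 random series for oracle equivalence, 10 cohorts of
n = 1000/group for effect-size recovery, 200 replicates at n = 29/group
for direction, dominance and null-selection rates, 10 cohorts of
n = 5000/group per effect size for the binormal AUC limit — were chosen
so each Monte-Carlo estimate's standard error is several times smaller
than the tolerance it is checked against, and they are fixed in the
tests rather than tuned.

Known limitations: no covariance structure at feature level; no
oculomotor realism at stream level; in-sample (optimistic) screening
evaluation by design; AOI geometry defaults are plausible but not the
source study's (unpublished) pixel bounds; stepwise logistic selection
is unstable at n = 58 and the selected set should be read as an
illustration of the procedure, not a reproducible marker panel.
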