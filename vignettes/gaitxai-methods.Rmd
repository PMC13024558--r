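---
title: "Methods: explainable two-stage analysis of Parkinsonian gait from VGRF signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explainable two-stage analysis of Parkinsonian gait from VGRF signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitxai)
```

## The analysis problem

Parkinson's disease (PD) degrades gait progressively, but the clinical
severity scale in routine use — the Hoehn & Yahr (H&Y) stage — is discrete
and partly subjective. Vertical ground reaction force (VGRF) recordings
from in-shoe pressure sensors capture the force the foot exerts on the
ground through every stride and are a candidate source of objective,
continuous digital biomarkers. `gaitxai` implements a two-stage analysis
of such recordings:

1. **Stage 1 — detection.** Windowed VGRF signals are classified PD vs
   control by three small sequence models under *repeated subject-wise*
   train/validation/test partitions, so that no subject ever contributes
   windows to more than one partition of a split. Subject-level leakage
   is the dominant cause of over-optimistic accuracy claims in biosignal
   work, and the package enforces its absence with hard assertions
   rather than convention.
2. **XAI consensus.** Integrated Gradients attributes each trained
   model's predictions to the 36 input features. Features in the top 20%
   of attribution within each (model × split) experiment are marked
   important; the *stability score* of a feature is the fraction of all
   experiments that marked it, and features scoring at least the
   consensus threshold (20%, inclusive) form the consensus biomarker
   set. Consensus features are then validated at the data level with
   Mann–Whitney U tests, Cliff's delta effect sizes (PD − CO
   orientation) and Benjamini–Hochberg FDR correction within the
   consensus family.
3. **Stage 2 — severity.** Subjects are summarized by the across-window
   mean and SD of their raw window features (72 values) and a
   gradient-boosted regressor (xgboost) predicts continuous H&Y stage
   under the same subject-wise splits; accuracy is reported as MAE,
   RMSE, R², and Spearman's ρ, with Cohen's f² = R²/(1 − R²) and
   noncentral-F post hoc power.

## Input representation

Records are whitespace-delimited text: a time column plus 18 channels
(8 left sensors, 8 right sensors, left and right total force), sampled
at 100 Hz. Records are cut into windows of 100 samples (1 s) with 50%
overlap; the trailing partial window is dropped. Within each window the
mean and standard deviation of each channel form an 18-token × 2-feature
representation: the mean carries force magnitude, the SD carries
within-window force variability. Channels are z-scored with statistics
fitted **on the training subjects of the current split only** — the
scope of normalization is a leakage surface too, and fitting it on the
full cohort would let test-set scale information into training.
Unnormalized (raw, Newton-scale) window features are kept alongside for
the data-level biomarker statistics, whose medians and IQRs are only
interpretable in physical units.

## The classifiers

The three backbones treat the 18 tokens as a sequence and share one
contract — input `(batch, 18, 2)`, output a PD probability — so
evaluation and attribution code is architecture-agnostic:

* `tcn`: three dilated causal convolution blocks (kernel 3, dilations
  1/2/4) with residual connections and mean pooling;
* `bigru_attn`: a bidirectional GRU with additive attention pooling;
* `fcnn_transformer`: per-token linear embedding, two pre-norm
  self-attention encoder layers (4 heads) with feed-forward blocks, mean
  pooling and an MLP head.

No published layer sizes exist for this analysis, so the defaults
(width 32, dropout 0.1) are declared choices, deliberately small enough
to train on a laptop CPU; every size is exposed in `model_spec()`.
Training uses AdamW (decoupled weight decay), weighted binary
cross-entropy with the positive-class weight set to `n_neg/n_pos` over
training windows, and early stopping on validation AUC with restoration
of the best-epoch parameters (defaults: learning rate 1e-3, weight decay
1e-4, batch 64, at most 100 epochs, patience 10).

The models and Integrated Gradients run on a small reverse-mode
automatic differentiation engine written in base R (`R/autodiff.R`):
a define-by-run tape of array operations with hand-derived
vector–Jacobian products, including fused GRU-cell and multi-head
attention nodes for speed. Its gradients are verified against finite
differences in the test suite, which is the property that matters for
both training and attribution.

## Integrated Gradients and the stability consensus

For a window $x$ and baseline $x'$, the attribution of feature $i$ is
the right-Riemann approximation

$$\mathrm{IG}_i = (x_i - x'_i)\,\frac{1}{m}\sum_{k=1}^{m}
  \left.\frac{\partial F}{\partial x_i}\right|_{x' + \frac{k}{m}(x - x')},$$

with $m = 50$ steps by default and the all-zero baseline, which in
normalized space is exactly the training-cohort channel mean — the
conventional "absence of signal" reference. Completeness
($\sum_i \mathrm{IG}_i \to F(x) - F(x')$) is tracked per run; the
attribution target is the predicted probability (the raw model output
can be selected instead, under which IG is exact for linear models at
any $m$ — a test-suite oracle). Per-experiment rankings use the mean of
$|\mathrm{IG}|$ over test windows; signed means are exported for
inspection.

The number of experiments is `n_splits × n_models` (15 at the reference
design of 5 splits and 3 architectures). The top-fraction cut uses
`ceiling` (top 20% of 36 features keeps 8) and ties at the cut break by
canonical feature order, so selection is deterministic. The consensus
threshold is inclusive: a feature selected in exactly 3 of 15
experiments scores 0.20 and is retained.

## Statistical validation choices

* **Mann–Whitney U** counts `x > y` pairs plus half the ties; the
  p-value is exact (full permutation enumeration, valid under ties)
  when `min(n, m) ≤ 8`, and a tie-corrected normal approximation with
  continuity correction otherwise.
* **Cliff's delta** is computed from ranks, identical to pair
  enumeration for any tie structure; orientation is PD − CO throughout,
  so "PD below control" is a negative delta.
* **BH-FDR** is applied within the consensus feature family only —
  those are the hypotheses actually advanced.
* **Paired Wilcoxon** comparisons of backbone AUCs over the repeated
  splits drop zero differences, average-rank ties, and use the exact
  signed-rank null for ≤ 20 effective pairs. Both one- and two-sided
  p-values are reported because at 5 repeats the smallest achievable
  two-sided p is 0.0625: a significance claim at α = 0.05 from 5 paired
  repeats is only reachable one-sided, and reporting both makes that
  visible instead of hiding it.
* **Sampling unit.** Table-style group summaries (medians, IQRs,
  deltas) are computed over windows, the unit in which the features are
  defined. Windows within a subject are correlated (they share the
  subject's gait), so window-level U tests overstate evidence; the
  null-calibration checks therefore run at the subject level
  (`unit = "subject"`), where the independence assumption of the test
  actually holds. Window-level p-values should be read as descriptive.
* **Repeat aggregation** reports mean, sample SD, and an empirical 95%
  CI from a seeded percentile bootstrap of the mean (10⁴ resamples) —
  with ~5 repeats no parametric interval is defensible.
* **Post hoc power** uses the noncentral F distribution with
  noncentrality λ = f²·n (Cohen's convention; conventions differ, so it
  is stated). With the full 72-dimensional subject feature vector as
  the predictor count, the analysis requires n > 73 evaluated subjects;
  below that the pipeline reports `NA` rather than a number the design
  cannot support, and the acceptance script frames power on the
  validated consensus-biomarker family instead.

## Stage-2 population

The literal reading — regress severity only on subjects the classifier
called PD — conflicts with reporting H&Y-0 subjects among severity
predictions, which requires controls in the regression. Both modes are
implemented; the default (`inclusive`) trains and evaluates on all
subjects with controls anchored at stage 0, and `classified` restricts
evaluation to stage-1-positive subjects. Severity predictions are
always out-of-sample: for each split the regressor trains on train+val
subjects and predicts the held-out test subjects, and a subject's
reported prediction averages over the splits in which it was held out.

## The synthetic cohort generator

No clinical data ships with the package; `generate_cohort()` produces a
cohort with the statistical structure the analysis assumes, plus the
ground truth needed for parameter-recovery tests. Defaults mirror the
reference cohort: 93 PD and 73 control subjects, PD stages drawn from
{1, 1.5, 2, 2.5, 3} with mean ≈ 2.3 and SD ≈ 0.6, 100 Hz sampling.

Each sensor's stride waveform is one or two raised-Gaussian bumps at
fixed phase within stance (heel sensors early, toe sensors late); the
per-foot total force is the sum of its 8 sensors before noise, and the
left and right feet are anti-phased by half a stride. Base amplitudes
were sized once so that control window SDs land in the tens-to-hundred
Newton range typical of per-sensor VGRF summaries. Per-subject
heterogeneity comes from a stride period drawn around 1.1 s (SD 0.06 s)
and a log-normal force scale (SD 0.10) standing in for body-weight
differences; cycles jitter in period (CV 0.02) and amplitude, and
Gaussian sensor noise (3 N) is added last, so swing-phase samples can
dip slightly below zero.

Severity `h` enters through two dials:

* `speed_slowing` (γ): stride period multiplied by `1 + γh` —
  parkinsonian slowing;
* `variability_suppression` (β): the cycle-to-cycle amplitude CV is
  multiplied by `1 − βh`, **and** each sensor's within-cycle dynamic
  range is contracted toward its mean force level by the same factor.
  The contraction is mean-preserving: window SD features fall with
  severity while window means stay centered. This is the generator's
  expression of rigid, low-variability PD force control, and it is what
  makes the characteristic pattern — variability features informative,
  mean features not — reproducible. Suppressing the cycle-to-cycle CV
  alone narrows the across-window *spread* of SD features but leaves
  their medians in place, which no rank test can see; the within-cycle
  contraction is therefore the load-bearing severity mechanism.

All randomness flows from one master seed; per-subject substreams are
derived by stable hashing of subject ids, so a subject's record does
not depend on generation order, and two runs from one config are
byte-identical.

**What the generator does not emulate:** joint kinematics, freezing
episodes, asymmetry between sides, sensor drift or saturation, and
multiple walking sessions per subject. Passing recovery tests on this
cohort demonstrates that the pipeline's machinery is correct and
recovers planted effects of realistic size — not that the reported
external-cohort accuracy figures would be reproduced on clinical data.

## Numerical and degenerate-input choices

* Window step = `round(L(1 − overlap))`, floored at 1; exact at the
  (100, 0.5) design point. Records shorter than one window raise a
  distinct `record too short` condition, not a silent empty result.
* Channel SDs below `epsilon` are replaced by 1, so constant channels
  normalize to 0 instead of exploding.
* Largest-remainder rounding assigns per-class split counts; remainder
  ties break in train/val/test order. Every partition must contain both
  classes or the split errors.
* Quantiles are linear-interpolation (R type 7); IQR values depend on
  this and it is stated wherever they are reported.
* Ties in attribution rankings and consensus ordering break by
  canonical feature name, never by hash order.
* `aggregate_repeats` requires ≥ 2 repeats (an SD of one value is
  undefined), and a one-class test set raises an explicit AUC error.

## Problem sizes used by the tests and the acceptance script

The package-scale study (166 subjects, 60 s records, 5 splits × 3
architectures, width 32) is the documented default of `run_config()`.
The automated checks run the same code on smaller instances chosen once:
recovery runs use 40 + 40 subjects with 12 s records, β = 0.3, γ = 0.1,
3 splits × 3 architectures and width-16 models; null-calibration runs
use 50 + 50 subjects, 10 s records, one architecture and 8 splits (5 in
the script); false-discovery calibration repeats 8 + 8-subject null
cohorts. These sizes give the checks adequate power while keeping a
full run in the minutes range on one CPU.

## Known limitations

* The severity effect sizes pinned by the recovery conditions (β = 0.3)
  are strong: at H&Y 3 the dynamic force range is 10% of a control's.
  Group separations on the synthetic cohort (AUC ≈ 1, |δ| ≈ 1) are
  therefore larger than the reference clinical values; the recovery
  checks are about mechanism and direction, not effect-size matching.
* Stage-1 window probabilities are not calibrated; the 0.5 decision
  threshold is a convention and sensitivity/specificity react to it.
  AUC is threshold-free and is the primary metric.
* The exact Mann–Whitney branch enumerates combinations and is limited
  to small groups by design; larger groups use the corrected normal
  approximation.
* Spearman p-values use the t approximation, adequate for n ≥ 10 but
  approximate below.
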