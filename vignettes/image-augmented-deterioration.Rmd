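---
title: "Augmenting deterioration indices with chest radiograph scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Augmenting deterioration indices with chest radiograph scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hospitals run EHR-based deterioration indices — the proprietary Epic
Deterioration Index (EDI) at 15-minute cadence, locally developed 4-hourly
indices, and the like — that score each inpatient's risk of clinical
deterioration: death or the need for ICU-level therapy (invasive or
non-invasive mechanical ventilation, heated high-flow nasal cannula, or IV
vasopressors). These indices see only structured EHR data. Chest radiographs
carry complementary information, but they arrive irregularly and cannot be
fed into a proprietary index. `xradi` implements a late-fusion augmentation
strategy: treat the existing index as an opaque score stream, obtain a
probability-like risk score per radiograph from any image model, align both
streams onto a common 4-hour prediction grid, and learn a tiny fusion
network on top. Two clinical uses drive the design: flagging **low-risk**
patients as candidates for early discharge (evaluated by negative predictive
value, NPV), and flagging **high-risk** patients (evaluated by AUROC).

The image model itself (a convolutional network over the radiograph) is out
of scope here: `xradi` accepts any per-radiograph score in [0, 1] and ships
a cohort simulator that plays the role of both modalities.

## The fusion model

Each prediction instance is a four-element vector:

* `image_score` — the most recent radiograph's risk score, carried forward;
* `index_score` — the deterioration-index value of the most recent completed
  4-hour interval (a 15-minute stream is first reduced by taking the maximum
  over each interval);
* `hours_since_xray` — staleness of the carried-forward image score;
* `hours_since_admit` — position in the hospitalization.

The two time covariates let the network discount stale radiographs and
early-admission noise. The model is a feed-forward network with a single
hidden layer of five rectified-linear units and a sigmoid output, trained
with binary cross-entropy at learning rate 0.001, with the checkpoint chosen
by lowest validation loss. Features are z-scored with training-set statistics
(the scale of hours vs probabilities differs by an order of magnitude, and
standardization stabilizes so small a network; the stored model carries the
standardizer so prediction is self-contained).

Two models are trained separately:

* **low-risk task** — instances every 4 hours from the first radiograph
  through hour 48; label: the hospitalization *ever* deteriorates.
* **high-risk task** — instances from the first radiograph through day 5
  (hour 120); label: deterioration within 120 h. The window containing the
  event and the window immediately before it are dropped, so the model never
  trains on the immediate pre-event period (label leakage).

### Timing conventions

Windows are half-open `[s, s + 4)` hours, admission-anchored. A prediction
"for" window `s` is issued at the window end, and every feature is a
function of data observed at or before `s`: the image feature uses
radiographs with time `<= s`, and the index feature uses the reduced value
of the completed interval `[s - 4, s)`. Wall-clock quirks of specific
deployed indices (e.g. predictions from 1 am to 9 pm only) are deliberately
not emulated; admission-anchored grids keep alignment and simulation simple
and do not change any of the protocol logic. Before the first radiograph the
combined model abstains (the plausible alternative — passing the raw index
through — is a property of the baseline, which in this package predicts on
*all* windows, so the comparison machinery covers both conventions).

### Optimizer

Only the learning rate (0.001) and the loss (BCE) are fixed by the method;
the optimizer is a design choice. Plain minibatch SGD at learning rate 0.001
demonstrably underfits within a 200-epoch budget — on linearly separable
toy data it plateaus near BCE 0.3, an order of magnitude above what so small
a problem should reach — because 0.001 is far below a workable SGD step for
features on unit scale. A learning rate of 0.001 is, however, exactly the
standard default of the adaptive-moment optimizer (Adam) in mainstream
deep-learning toolkits, so that is the default here (`optimizer = "adam"` in
`train_config()`; plain `"sgd"` remains available behind the flag). Training
is fully deterministic given the seed: seeded fan-in-scaled uniform
initialization, seeded shuffling, and batch-level updates in a fixed order.

## The synthetic cohort

Real cohorts of this kind are single-center EHR extracts with a proprietary
index and cannot be deposited. The simulator generates the three tables the
method consumes (hospitalizations, radiograph scores, index scores) with the
statistical structure the method assumes:

* a shared latent severity `s ~ N(0,1)` per patient, visible to both
  modalities;
* an image-specific latent `u ~ N(0,1)`, visible only to the radiograph;
* deterioration indicator `Bernoulli(plogis(qlogis(p_base) + w_s*s + w_u*u))`,
  event time uniform on (4 h, min(length of stay, 120 h)), event type
  multinomial metadata;
* index stream `plogis(a0 + a1*s + eps_t)` at 15-minute (or 4-hour) cadence;
* image score `plogis(b0 + b1*s + b2*u + eta)` at each radiograph time.

`w_u > 0` is the regime in which augmentation *should* help: the image
carries outcome signal the index cannot see. `w_u = 0` is the null regime in
which augmentation should neither help nor hurt.

Defaults are chosen once to mirror a plausible acute-dyspnea admission
cohort and are not tuned against test outcomes: base deterioration
probability 0.3 (the observed COVID-19 test-cohort rate was 30.4%);
event-type probabilities proportional to the published test-cohort mix
(death 1.3%, mechanical ventilation 2.9%, HHFNC 25.0%, IV vasopressors
1.3%, renormalized among deteriorators — metadata only, nothing downstream
reads the type); mean length of stay 120 h (4 h floor plus a gamma tail,
shape 2, a right-skewed stay distribution typical of inpatient cohorts);
first radiograph uniform within 48 h of admission; radiograph count
1 + Geometric with mean 1.8 total (matching roughly 1.8 images per
hospitalization in comparable cohorts — the true count distribution is not
published, so geometric is a one-parameter choice); latent loadings
`a1 = b1 = b2 = 1` and intercepts `a0 = b0 = -1.4` (scores centered near
0.2, the low-risk end where such indices live); observation noise sd 0.5 on
the logit scale for both modalities; 97% of admissions on supplemental
oxygen (the filters need occasional violations to be exercised). Per-patient
random substreams are derived from the seed and the patient index, so the
same patient index reproduces the same admission regardless of cohort size.

The simulator does **not** emulate vital-sign physiology, radiographic
phenotypes, repeated admissions, informative radiograph timing (sicker
patients being imaged more), or calibration drift of the underlying index. A
green end-to-end test therefore establishes that the pipeline recovers
image-specific signal *when it exists and is conditionally Gaussian on the
logit scale* — not that any particular hospital's index will be improved.

### Inclusion filters

As in the intended clinical cohort, hospitalizations are excluded if they
(a) never required supplemental oxygen, (b) had no radiograph within the
first 48 h, (c) deteriorated or were discharged within 4 h of presentation,
or (d) deteriorated before their first radiograph. Each exclusion is tagged
with the first matching reason in that order, and the tallies must sum back
to the input count. When a patient has multiple qualifying events, the
deterioration time is the first event.

## Evaluation protocol

* **Low-risk**: per hospitalization, the mean of all window predictions with
  window start before the evaluation time (24, 32, 40 or 48 h);
  hospitalizations deteriorating before that time are excluded. Patients are
  sorted by ascending aggregated risk (ties broken by hospitalization id for
  determinism) and the flagging threshold swept; for each count `k` of
  flagged patients the NPV is the fraction of flagged patients who never
  deteriorate. The headline count is the largest `k` with NPV at or above a
  target (0.95, 0.90). Because NPV is not monotone in `k`, a conservative
  `strict_prefix` variant (largest `k` with NPV never dipping below the
  target) is available; the default matches a single swept threshold.
* **High-risk**: per hospitalization, the maximum of all (already
  event-censored) window predictions; the metric is AUROC in its
  Mann–Whitney form (ties count one half), plus specificity at the highest
  threshold reaching sensitivity 0.8.
* **Uncertainty**: percentile bootstrap over hospitalizations (never over
  instances — the inferential unit is the admission), 1000 resamples,
  seeded; resamples that lose an outcome class are redrawn, and the run
  aborts if more than 10% of draws fail.
* **Baseline**: the index-only comparator is the raw stream reduced to the
  same grid and pushed through the *same* aggregation, sweep and bootstrap
  code, so comparisons are like-for-like. The baseline predicts from
  admission onward (it needs no radiograph), so its eligible patient pool
  can be slightly larger than the augmented model's; counts and fractions
  are reported against each model's own pool.
* An exponentially weighted moving average (`ewma_smooth()`) is provided for
  plotting NPV curves only; counts always use the raw curve.

## Pipeline and reproducibility

`run_pipeline()` simulates three *disjoint* cohorts (train / validation /
test; the validation cohort drives checkpoint selection and early stopping),
applies the filters, aligns, trains both task models, predicts on the test
cohort and evaluates augmented vs baseline. Every stage seed is derived from
the single pipeline seed, so a configuration reproduces its report
byte-for-byte. Stage row counts and exclusion tallies are logged to stderr
(optionally as JSON lines).

```{r, eval = FALSE}
library(xradi)
report <- run_pipeline(pipeline_config(n_train = 800, n_valid = 300,
                                       n_test = 600, seed = 1))
report
```

## Numerical choices and degenerate inputs

* Score streams must lie in [0, 1]; the simulator guarantees this through
  the logistic link, and the readers validate it.
* Grid reduction of an empty stream is an error; windows before the first
  observation are `NA` and instances needing them are dropped.
* A hospitalization with no valid prediction window yields an empty
  instance set with a warning, and is excluded from patient-level
  aggregation with a warning — never silently.
* Training on a single-class split is an error (the loss gradient carries
  no ranking information); non-finite losses or gradients abort with the
  epoch number rather than returning a half-trained model.
* Tie-breaks: NPV sweeps order by (score, hospitalization id); AUROC uses
  midranks; `specificity_at_sensitivity` scans thresholds from the highest.
* BCE is clamped at 1e-12 from both ends before taking logarithms.

## Known limitations

* The simulator's latents are Gaussian and act linearly on the logit scale;
  real severity dynamics are nonstationary and the index's own calibration
  varies across wards and epochs.
* Radiograph timing is outcome-independent in simulation; in practice
  imaging is ordered *because* a patient worsens, which inflates apparent
  image signal. Conclusions about real cohorts require real data.
* The evaluation excludes patients without an early radiograph from the
  augmented model's pool; deployment would fall back to the unaugmented
  index for them, a policy the baseline rows of the report quantify.
* The fusion network is deliberately tiny (31 free weights plus the
  standardizer); it cannot and should not model interactions beyond what
  four features support.
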