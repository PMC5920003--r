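---
title: "Scoring and modeling empathic accuracy from dyadic rating streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and modeling empathic accuracy from dyadic rating streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eapipe)
```

## The measurement problem

In an empathic-accuracy (EA) task a *perceiver* watches a video of a
*target* narrating an emotional autobiographical event and continuously
rates, with a dial on a 1–9 scale (1 extremely negative, 5 neutral, 9
extremely positive), how the target felt. The target has previously rated
their own video on the same dial. EA for one clip is the agreement between
the two rating streams, summarized as a correlation. In a
placebo-controlled alcohol-administration design, per-clip EA scores from
two beverage conditions are then compared with multilevel models, with a
hazardous-drinking questionnaire score (the revised AUDIT total over items
1–8, range 0–32, hazard cutoff 8) as a continuous moderator.

`eapipe` implements that full chain — stream preprocessing, per-clip
scoring with autoregressive handling of serial dependence, Fisher z
transformation, and moderated mixed-model inference — together with a
seeded synthetic-dyad generator so that every stage can be tested against a
known ground truth without access to raw study data.

## Preprocessing

Dial streams are averaged over half-open 5-second windows anchored at the
stream's first timestamp (`bin_stream()`, default `bin_s = 5`). Two
choices here were genuinely open:

* **Anchoring.** Bins are anchored at the first sample rather than at
  absolute recording time, on the view that streams start at clip onset.
  Binning is therefore invariant to a constant timestamp offset, which the
  test suite checks as a property.
* **Partial tails.** A trailing window covering less than a full bin of
  recording is dropped rather than averaged, so every retained bin mean
  summarizes the same duration. The recording is taken to extend one median
  inter-sample interval past the last sample; a 120-s clip at 1 Hz thus
  yields exactly 24 bins.

The first and final bin (i.e. the first and final 5 s of rating, where the
dial is typically still at rest or already released) are discarded
(`truncate_edges()`), leaving 22 bins for a 2-minute clip. Perceiver and
target series are paired from bin 0 and trimmed to the shorter common
length; mismatches above 2 bins are reported (`align_pair()`). Streams too
short to survive truncation are excluded with a logged reason, never
imputed — a constant or absent series carries no tracking information, and
imputing a zero score would bias condition means.

Presentation orders are produced by `sample_clip_order()` under the task's
constraints: no target more than twice, no more than two clips of the same
valence in a row. The sampler first draws uniform random permutations and
keeps the first feasible one (exactly uniform among feasible orders when it
succeeds); only tightly constrained sets fall back to backtracking with
randomized candidate order, which is near- but not exactly uniform. Every
returned order is verified in the tests against an independent brute-force
checker.

## Scoring: serial dependence, correlation, Fisher z

Binned affect ratings are strongly autocorrelated, which inflates the
sampling variability of a naive Pearson correlation between two streams.
The pipeline treats this with Yule–Walker autoregression, implemented from
first principles: biased sample autocovariances of the demeaned series
solved by the Levinson–Durbin recursion (`yule_walker_ar()`), which
guarantees a stationary fit. The recursion is cross-checked in the tests
against a direct linear solve of the Yule–Walker system and against
`stats::ar.yw`, to 1e-8.

`ea_correlation()` offers three estimators, because the phrase "the
Yule-Walker method" alone does not pin down the model structure:

* `naive` — plain Pearson correlation of the binned series;
* `prewhiten` — each series filtered by its own AR(p) fit, residuals
  correlated;
* `ar_error_model` (default) — the perceiver series regressed on the target
  with AR(p) errors, estimated in two stages: OLS residuals yield a
  Yule–Walker AR fit, both series are quasi-differenced by that filter, and
  the transformed series are correlated. This mirrors common autoregressive
  error-model practice in mixed-procedure statistical software, which is
  why it is the default; the other two remain configurable, and none is
  asserted to be the historically exact computation.

The default AR order is 1 (configurable 0–4, order 0 reduces everything to
`naive`); no automatic order selection is performed, keeping the pipeline
deterministic. A minimum of 3 paired bins is required; constant series are
flagged and excluded rather than returned as NaN.

Correlations are mapped to Fisher z (`fisher_z()`, `z = atanh(r)`) for
inference, with `|r|` clipped at 0.999 first: real binned dial data do
produce perfect per-clip correlations, which would map to infinite z. The
clip bound turns `r = 1` into `z = 3.80` while leaving `|r| < 0.999`
untouched (round-trip identity with `inverse_fisher_z()`).

## Inference: containment df, simple slopes, effect sizes

`fit_mixed_model()` fits `z ~ fixed + (1 | perceiver)` by REML through
`lme4`, but reports F tests with **containment (between–within)
denominator degrees of freedom** computed by the package: a between-subject
effect gets `n_subjects − p_between` (counting all between-subject
fixed-effect parameters, intercept included) and a within-subject effect
gets `n_subjects − 1`. This rule was chosen over Satterthwaite or
Kenward–Roger approximations because it is the convention that produces the
familiar integer df pattern for this design — with 54 subjects: (1, 52)
for a condition-only model, (1, 53) for a within-subject factor such as
clip valence or target sex, and 50 for the contrasts of a
condition × moderator model. A subject-level random intercept (and nothing
more) is the adopted covariance structure, for the same reason: it is the
structure under which that df pattern arises. Valence-specific analyses are
subset refits, not interaction contrasts.

The continuous moderator is grand-mean centered over subject-level scores
before forming the interaction. `simple_slopes()` evaluates the condition
contrast (alcohol − placebo) at the moderator mean ± 1 SD, using the
model's coefficient covariance and the containment df. Singular
random-intercept fits are downgraded to OLS with a message and a flag on
the result; nothing falls back silently.

The sign logic of the interaction deserves a note. With condition coded
`I[alcohol]` and the moderator standardized, the condition contrast at ±1
moderator SD is `beta_condition ± beta_interaction`. A deficit confined to
low-moderator perceivers — the pattern of interest in this design —
therefore corresponds to a *positive* interaction coefficient combined with
a negative condition coefficient, and that is how the generator defaults
are oriented.

Effect sizes are derived from the test statistics, not from raw means:
`d = 2·sqrt(F/df_den)` for single-df F tests and `d = 2·|t|/sqrt(df)` for
contrasts, because these conversions are the ones that connect a reported
F or t directly to a standardized between-group difference in this design.
The descriptive layer (`two_sample_t()`, `one_sample_t()`,
`cronbach_alpha()`, `score_audit()`, `drinking_summaries()`) works from
summary statistics so that baseline tables can be reproduced from printed
means and SDs. The two-sample default is the pooled Student test; Welch is
a flag. Reproducing printed t values from rounded summaries can differ in
the final digit, and for one baseline row the Welch statistic matches the
printed value while the pooled one is off by 0.01 — the tests document
this rather than hide it. No multiplicity correction is applied to the
post-hoc contrasts by default, matching how such contrasts are usually
reported in this literature.

## The synthetic-dyad generator

The generator is first-class, tested code, not a fixture. Its defaults
*are* the study conditions: 54 perceivers alternating 1:1 over two
conditions, 16 clips each (8 positive, 8 negative) drawn from a 20-clip
set (10 targets, half male, half female, one positive and one negative
clip each), roughly 2-minute clips sampled at 1 Hz. The dial rate is not
dictated by the task hardware, so 1 Hz was chosen once as a desk-scale
rate at which a 5-s bin still averages 5 samples.

Target trajectories are mean-reverting AR(1) processes (default
`ar_coef = 0.8`, `noise_sd = 0.5` dial units) around a valence-dependent
anchor — 6.5 for positive, 3.5 for negative clips, symmetric about the
neutral dial midpoint and far enough from the 1–9 bounds that clipping is
rare. Perceiver streams are correlation-calibrated mixtures: the (lagged,
standardized) target series plus independent AR(1) noise with matched
autocorrelation, mixed so the expected Pearson correlation equals the
requested `target_r`, then mapped back to the dial scale and clipped.
Clipping shrinks realized correlations slightly, which is why the
calibration tolerance is ±0.05 rather than exact; the tests verify the
calibration across `target_r ∈ {−0.8, −0.4, 0, 0.4, 0.8}` through the full
bin-truncate-align path.

Per perceiver × clip, the true tracking correlation is
`tanh(z)` with

```
z = z_intercept + beta_valence·I[positive] + beta_condition·I[alcohol]
    + beta_moderator·m + beta_interaction·I[alcohol]·m + u_perceiver + e
```

where `m` is the r-AUDIT score standardized by its stated mean/SD
(default 10.65/3.90, truncated to the instrument range 0–32),
`u ~ N(0, sd_perceiver²)` and `e ~ N(0, sd_residual²)`. Defaults
(`effect_spec()`): `z_intercept = 0.678` and `beta_valence = 0.133`, so
true tracking correlations average 0.59 for negative and 0.67 for positive
clips; `beta_condition = −0.10`, `beta_moderator = 0`,
`beta_interaction = +0.15` (deficit at low moderator scores, none at
high); `sd_perceiver = 0.2`, `sd_residual = 0.45` Fisher-z units. Note
that *observed* mean correlations from scored streams sit below the true
means: averaging `tanh` of a dispersed z (Jensen) and finite-bin
estimation noise both attenuate, and the pipeline reports what a scorer
would actually observe rather than the noiseless truth.

The questionnaire generator produces AUDIT items 1–8 that sum exactly to a
latent total (items 9–10 are generated but flagged unusable and excluded
from the revised total), DMQ-R subscales, SIAS totals, four urge-to-drink
ratings on 0–10, daily drink counts coupled to the AUDIT latent at
correlation 0.7, body weight, an SMAST inclusion flag, and
breath-alcohol readings at 10-min intervals (a Gaussian rise–fall profile
peaking near 0.25 mg/L about 21 min post-drink in the alcohol arm, zero
under placebo). `compute_vodka_volume()` implements both readings of a
per-weight dose — ml of ethanol per kg (`weight·dose/abv`) and grams per
kg (`weight·dose/(abv·density)`) — because the served-volume range
reported for this design does not exactly match either convention applied
to rounded weights; neither is asserted as the historical computation.

**What the generator does not emulate:** real dial inertia and reaction
lags (a lag parameter exists but defaults to 0), non-stationary affect
trajectories with narrative structure, perceiver drop-out or missing
segments, item-level AUDIT response psychology (items are an exact
allocation of the latent total with randomized transfers, so item-level
internal consistency is not realistic), and any pharmacokinetics beyond
the stored BAC profile. Passing tests therefore demonstrate that the
*pipeline* recovers known structure from data shaped like the study's —
not that real dial data satisfy the generator's assumptions.

## Two generator paths, and why

Stream-level synthesis (`generate_cohort()`) exercises the whole pipeline
but costs seconds per cohort. Calibration questions about the *inference*
stage alone — type-I error of the interaction test, bias of recovered
betas — need thousands of replicates and no streams, so
`simulate_ea_scores()` draws the per-pair Fisher-z scores directly from
the generative linear model. The test suite uses the score-level path for
the 1000-replicate null calibration of the 54 × 16 design and the
150-replicate parameter-recovery check at 200 subjects, and the
stream-level path for the generate→bin→truncate→score round trip (valence
means recovered within ±0.05 at 30 × 8, count conservation at 54 × 16)
and the design-level power check over 100 seeds. These problem sizes are
the package's chosen verification scale and are stated here so they can be
reproduced exactly.

## Numerical choices and degenerate inputs

* Correlation clipping at |r| = 0.999 before `atanh`; round trip exact
  below the bound.
* Biased (divide-by-n) autocovariances in Yule–Walker: positive-definite
  system, stationary fit, matching the standard estimator convention.
* Exact linear perceiver–target relations short-circuit the AR error model
  to r = ±1 (the OLS residuals are identically zero).
* Constant series, too-short clips, and missing streams become excluded
  rows with machine-readable reasons; classed conditions
  (`eapipe_too_short`, `eapipe_degenerate_series`, …) let callers handle
  them programmatically.
* Condition assignment alternates rather than randomizes, guaranteeing
  near-equal arms at small n.
* All randomness flows through a single integer seed via splittable child
  seeds, so identical configurations reproduce byte-identical CSV exports
  (the manifest records MD5 hashes to prove it).

## Limitations

The containment df rule is exact for the balanced single-random-intercept
design it was chosen for; heavily unbalanced data or crossed random
effects (e.g. for targets) would call for Satterthwaite or Kenward–Roger
df and a richer covariance structure, which this package deliberately does
not fit. The AR error-model correlation is a two-stage estimator, not full
GLS. And the generator's realism caveats above bound what any green test
here can claim about raw dial recordings.
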