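---
title: "Linguistic laws in gesture sequences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linguistic laws in gesture sequences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Two statistical regularities of human language have increasingly been looked
for in animal communication. **Zipf's law of brevity** predicts that the more
frequently a signal type is used, the shorter it tends to be. **Menzerath's
law** predicts that the larger a construct (here, a sequence of gestures),
the smaller its constituents (the individual gestures composing it). A
related **compression** argument says that the frequency-weighted mean
signal duration — the mean code length — should sit below what random
pairing of durations to frequencies would produce.

`gesturelaws` implements the full analysis pipeline for testing these laws
in timed streams of gesture tokens, as produced by video coding of great
ape communication: one row per gesture with signaller, recipient, date,
video, gesture type, gesture category (manual vs whole-body), duration form
(fixed vs loose), and start/end times on a video frame grid. Because
behavioural datasets of this kind are rarely redistributable, the package
also contains a generative simulator with known ground truth, so that every
stage — segmentation, summaries, permutation tests, hierarchical models —
can be validated end to end by parameter recovery rather than by
re-measuring wild animals.

## Sequence segmentation

Tokens are grouped into *rapid sequences* by an inter-token gap rule:
within a signaller and video, a token joins the current sequence when the
silent interval between it and the previous token is strictly less than the
threshold (default 1.0 s; a gap of exactly 1.000 s closes the sequence).
Single gestures are sequences of length one. Two measurement conventions
are supported for the gap — end-to-start (default; the interval "in
between" two tokens) and onset-to-onset — because coding protocols differ
and published descriptions are often ambiguous on this point. Overlapping
tokens (negative gaps) always join. A token whose end time could not be
coded terminates its sequence, since its gap to the next token is
undefined, and marks the sequence incomplete; `filter_complete()` then
drops every sequence containing any token of unknown duration, mirroring
the usual exclusion applied before duration-based analyses.

Two invariants are enforced by property tests: segmentation partitions the
token stream exactly (every token in exactly one sequence), and raising the
threshold can only merge, never split, sequences.

## Law-level statistics

**Brevity.** The repertoire table gives, per gesture type *i*, its token
count, dataset proportion `p_i`, and mean/median durations. The brevity
statistic is a rank correlation (Kendall's tau-b by default — durations are
heavily tied at frame resolution) between frequency and a per-type duration
summary, with the median as default summary. Significance comes from
permuting the duration vector across types while holding frequencies
fixed. Two-sided testing is the default, with a one-sided option in the
law's direction.

**Compression.** The observed mean code length is `L_obs = sum(p_i d_i)`
with `d_i` the per-type *mean* duration (so that, with `p_i` taken as token
proportions, `L_obs` equals the overall mean token duration — an identity
the tests assert exactly). The minimal attainable value `L_min` pairs the
largest `p` with the smallest `d` (sorted pairing), `L_max` the reverse.
The null distribution permutes `d` across types; the p-value is
`Pr(L* <= L_obs)`; the degree of optimization is
`eta = (L_rand_mean - L_obs) / (L_rand_mean - L_min)`.

**Exact vs Monte Carlo permutation.** When the number of types is small
enough that all `k!` pairings fit within the requested number of
permutations, both tests enumerate the pairings and return the exact
permutation probability; otherwise they sample and report the add-one
estimate `(r + 1)/(n_perm + 1)`, which can never be zero. Tests verify the
enumeration against an independent recursive enumerator.

**What the permutation null is.** Both tests condition on the observed
per-type duration summaries and treat them as exchangeable across types:
the null hypothesis is that the *type-level* duration vector is unrelated
to the frequency vector. This is not identical to a token-level null in
which every token duration is drawn from one common distribution: under
that stronger null, rare types carry noisier summaries than common ones
(and the sample median of a skewed distribution is biased by sample size),
so the type-level exchangeability the permutation scheme assumes is
violated by construction when type frequencies are very uneven. The
calibration checks in this package therefore simulate the null the tests
actually address — iid per-type duration summaries over study-scale
multinomial frequencies — and the caveat should be kept in mind when
interpreting borderline p-values on real repertoires with many rare types.

**Menzerath statistics.** One point per complete sequence (size, mean
member duration); a rank correlation of duration on size with a
permutation p-value (shuffling durations over sequences); and the
Menzerath–Altmann power law `d = a * n^b` fitted by least squares on the
log–log scale. Only the two-parameter form is fitted: with sequence sizes
spanning 1–6 the three-parameter form `a * n^b * exp(c n)` is not usefully
identifiable. All sequences of a single size make the correlation and fit
undefined; this is flagged rather than silently imputed.

**Reliability.** Intra-observer agreement for duration coding uses the
single-measure, two-way mixed, consistency intraclass correlation ICC(3,1)
with two coding occasions, computed from the two-way ANOVA mean squares as
`(MS_rows - MS_err) / (MS_rows + MS_err)`. The consistency form is immune
to an additive shift between occasions. It is cross-checked in the tests
against a base-R `aov`/`lm` decomposition.

## Hierarchical models

Two mixed-effects regressions of natural-log gesture duration are
specified, matching the structures used in field studies of gestural
linguistic laws:

* **Zipf-model**: `log(duration) ~ proportion + category + (1|signaller) +
  (1|sequence) + (1|gesture_type)`;
* **Menzerath-model**: `log(duration) ~ size + PWB + (1|signaller) +
  (1|sequence)`, where PWB is the proportion of whole-body gestures in the
  sequence, a control for the category composition of sequences.

Only tokens of complete sequences enter; type proportions are computed on
the analysed dataset after exclusions (and recomputed within a subset when
one is analysed). Where sources disagree on whether PWB (or gesture type)
is a fixed control or a random term in the Menzerath model, the
fixed-control specification is implemented, with `add_type_random = TRUE`
available to add the type intercept.

The backend is a Gaussian linear mixed model fitted by maximum likelihood
with `lme4`. The contract is the model *structure* — natural-log response,
the exact fixed and random terms, 95% intervals — not the estimation
machinery; a sampler-based backend with weakly informative priors would
estimate the same quantities and, at these sample sizes, the ML point
estimates and Wald intervals are the relevant frequentist analogue.
Singular fits (variance components estimated at zero, common for weak
date or sequence effects) are reported in the diagnostics rather than
treated as errors.

**Subsets.** Behavioural datasets are often dominated by one prolific
individual. `run_subset_analyses()` re-runs both models on the full data,
on the prolific individual alone, and on all others. For the
single-individual subset the signaller intercept is meaningless and is
replaced by a recording-date intercept, which also guards against
particularly prolific days dominating the fit.

**Full/null comparison.** Each model is compared with a null that removes
the fixed term of interest (proportion or size) while retaining controls
and random terms, by 10-fold cross-validation holding out whole sequences:
held-out tokens are scored under the marginal Gaussian density of a new
cluster (fixed-effect mean; variance equal to residual plus all
random-intercept variances). The reported `delta` is ELPD(null) −
ELPD(full), so negative values favour the full model, matching the usual
sign convention of leave-one-out criterion differences. Its uncertainty is
the classic K-fold standard error, `sqrt(K) * sd` of the fold-level
difference sums: with nested maximum-likelihood fits the pointwise
differences are smooth and a pointwise (loo-style) variance badly
understates the resampling spread, while fold sums are honest replicates.
Note the expected delta under a null effect is slightly *positive* (the
out-of-sample price of one useless parameter), not zero.

## The generator

`simulate_tokens()` is the generative mirror of the models above. On the
log scale,

```
log d = mu0 + beta_freq * p(type) + beta_size * n + beta_category * 1[whole-body]
        + u_signaller + u_sequence + u_type + u_date + resid
```

with independent Gaussian intercepts, after which durations are
exponentiated and quantized *up* to the video frame grid (0.04 s), never
below one frame. `p(type)` is the expected type proportion from the
configured weights, not the realized one, so the ground truth of
`beta_freq` is well defined. Sequence sizes are drawn from a configured
distribution; one prolific signaller receives a configured fraction of
sequences, the rest uniform; token types are iid draws from the weight
vector; within-sequence gaps are uniform on `(0, within_gap_max)` and
between-sequence gaps at least `between_gap_min`, so that segmentation at
any threshold between the two bounds reconstructs the simulated partition
exactly — an invariant the tests assert.

`default_study_config()` pins the defaults to the published study
structure: 16 signallers with the prolific one at 290/560 of tokens; 26
types (21 manual, 5 whole-body) with 1/rank frequency weights; 377
sequences with size distribution proportional to the printed per-length
totals (244, 82, 21, 3, 7, 2 over sizes 1–6, about 560 tokens in
expectation); generative slopes at the published point estimates
(`beta_size = -0.18`, `beta_freq = 0.9`); `mu0 = 0.7` and random-intercept /
residual standard deviations (0.25, 0.25, 0.35, 0.15, 0.6) chosen once so
the marginal durations are lognormal-like with median near 1.5 s and range
of order 0.04–15 s, matching the printed duration summaries. Six
mid-frequency types are marked as fixed duration form so that roughly a
fifth of tokens are fixed-form, matching the printed 456/560 loose share.
The inter-sequence gap bounds (0.9 s within, 5 s between) are free
parameters: the empirical gap distribution is not published, and nothing
downstream depends on them beyond the segmentation threshold sitting
between the bounds. `duane_study_config()` emulates the prolific
individual alone: one signaller, 196 sequences (about 290 tokens) over 30
recording dates, `beta_size = -0.23`.

Recording dates (with their own small variance component, sd 0.15) are
simulated per signaller so that the date-for-signaller random-term swap of
the single-individual analysis is exercisable against ground truth.

**What the generator does not emulate.** Persistence sequences built
through response-waiting (only rapid sequences are generated); differences
in repertoire composition between individuals (types are iid across the
whole stream); the long tail of per-individual productivity among
non-prolific signallers (uniform assignment); kinematic structure within a
gesture; and recipient behaviour. Passing recovery tests therefore show
that the pipeline estimates what it claims to estimate under the stated
hierarchical lognormal structure — not that real gesture data satisfy that
structure.

## Numerical choices and degenerate inputs

* A rank correlation on a constant vector is defined as 0 (no signal)
  rather than NaN.
* Permutation p-values use the add-one correction when sampled and the
  exact probability when enumerated.
* Frame quantization uses a `1e-9` backoff so exact frame multiples are
  not pushed up a frame; durations read from CSV are validated as frame
  multiples within a tolerance that absorbs decimal round-trips.
* Degenerate configurations (zero sequences, single type, zero variances)
  are legal and produce the obvious limits; they are tested.
* Fixed controls with no variation in a subset (all-manual data, constant
  PWB) are dropped from the formula rather than left to produce rank
  deficiency; random terms with fewer than two levels raise a structural
  error naming the term.

## Problem sizes used by the test suite

The suite validates at the study scale it emulates: single fits use one
simulated stream of about 560 tokens; recovery checks use 10
simulate-and-refit replicates per scenario; null calibration uses 500
simulated repertoires at 999 permutations; exactness checks enumerate
pairings for up to 5 types. These sizes were chosen to keep Monte Carlo
error comfortably inside the asserted bands for each property.

## Known limitations

* The ELPD comparison scores held-out tokens under the marginal density of
  a new cluster; partially-new-group predictive densities (new sequence,
  known signaller) are not used, which is conservative for both models
  equally.
* Wald intervals rely on large-sample normality of the fixed-effect
  estimates; at 26 types the Zipf proportion slope is weakly identified
  and its interval is wide, as in the published analyses.
* The permutation tests inherit the type-level exchangeability caveat
  described above.
* The Menzerath–Altmann fit weights each sequence equally; size classes
  with very few sequences (sizes 4–6 here) contribute little and the
  exponent is dominated by sizes 1–3.
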