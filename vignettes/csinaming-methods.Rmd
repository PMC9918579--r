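---
title: "Typed picture naming and cumulative semantic interference: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typed picture naming and cumulative semantic interference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The paradigm

In a continuous naming experiment, participants name a long sequence of
seemingly unrelated object pictures. Hidden in the sequence are semantic
categories (fish, fruit, seating furniture, ...) with five closely related
exemplars each. Naming latency increases approximately linearly with each
additional exemplar of a category that has already been named — the
*cumulative semantic interference* (CSI) effect, conventionally quantified
as the fixed-effect slope of the within-category *ordinal position*
(1–5) on reaction time (RT).

`csinaming` implements the full measurement pipeline for the *typed*
variant of this paradigm, where participants type each picture name on
their keyboard and the latency of the first keystroke is the RT. Typed
responses can be scored automatically, which removes the costly manual
annotation that spoken responses require. The package covers:

1. stimulus-list construction under lag constraints (`generate_trial_list`),
2. keystroke-log parsing and backspace-corrected reconstruction
   (`read_keylog`, `reconstruct_entries`),
3. automated correctness classification with string distances
   (`classify_entries`),
4. copy-typing speed/accuracy metrics (`typing_metrics`),
5. mixed-model analysis of RTs and errors (`fit_rt_model`,
   `fit_error_model`, `fit_log_lmm`, `within_subject_summary`),
6. simulation-based power analysis (`power_curve`), and
7. a synthetic-experiment generator with planted ground truth
   (`simulate_experiment`) that makes all of the above testable offline.

# Stimulus-list construction

The default design (`design_config()`) is the standard CSI layout: 24
categories × 5 exemplars plus 40 fillers, split into 8 blocks of 3
categories and 5 fillers (20 trials per block, 160 in total). Two
constraints shape a list:

* **Superordinate separation.** Categories sharing a superordinate
  category (fish and insects are both animals) should sit in blocks as
  far apart as possible. "As far apart as possible" is not a
  well-defined objective by itself; the package formalizes it as
  maximizing the summed pairwise block distance between
  same-superordinate categories. The optimum is found exhaustively when
  the assignment space is small and by seeded random-restart
  hill-climbing over pairwise swaps otherwise. For small designs the
  hill-climbing solution is verified against brute force in the test
  suite.

* **Lag constraints.** Within a block, consecutive members of the same
  category must be separated by at least 2 and at most 8 intervening
  items (fillers included). Lag is counted as the number of *intervening*
  items: positions 3 and 6 have lag 2.

Uniform rejection sampling over whole-block shuffles is hopeless here:
the admissible fraction of random permutations of the default block is
about 2 × 10⁻⁴, so a bounded retry budget would routinely be exhausted.
`randomize_block()` instead draws sequences by *constrained sequential
placement*: slots are filled left to right, drawing uniformly (weighted
by remaining counts) among items whose category respects the minimum
lag; a category is forced when its maximum-lag deadline or its
remaining-slot budget would otherwise be violated; dead ends trigger a
restart. About 90% of proposals succeed, the procedure is seeded and
reproducible, and every accepted sequence is re-checked by the
independent validator `validate_list()`. The sampler does not draw
*uniformly* from the admissible set (no practical exact sampler does);
what matters for the design is that constraints hold and that the
assignment of concrete exemplars to category slots is uniform, which it
is.

Trial positions and ordinal positions are 1-based throughout, matching R
indexing and the 1–5 position labels used in analysis.

# Keystroke logs and reconstruction

Browser-side capture scripts emit key events with millisecond
timestamps. Since no standard file format exists for such logs, the
package defines a JSON-lines dialect, one event per line:

```
{"pid":"s01","trial":3,"item":"kelle","key":"k","t":1043}
```

`key` follows the W3C `KeyboardEvent.key` vocabulary. On ingestion,
printable keys are upper-cased (participants type in capitals and see
capitals), named special keys map to `BACKSPACE`, `SPACE`, `ENTER`,
`SHIFT`, `CAPSLOCK`, and anything else (e.g. function keys) maps to
`OTHER`. Umlauts and ß stay distinct characters — the paradigm screens
for QWERTZ keyboards precisely so that these have direct keys.

Reconstruction (`reconstruct_entry`) replays a trial through a text
editor: printable keys append, backspace deletes (a no-op on an empty
buffer), and shift/caps lock contribute nothing. Terminal space/enter
runs — the keys used to submit a response — are stripped first. The raw
string (printable keys in typed order) is kept alongside the corrected
string because classification needs the *first typed character* before
correction. The first-keystroke latency is defined for any first event,
special keys included; trials are only used for RT analysis if they are
classified correct, which excludes special-key starts.

# Automated classification

The response classifier mirrors the decision rule used for typed
naming:

1. No keystrokes → incorrect, subtype `na`.
2. First key is space, backspace, caps lock or enter → incorrect,
   `special_key_start`; a first shift key → `shift_start` (reported
   separately because pressing shift is what a German typist would
   naturally do at a noun onset).
3. Otherwise the backspace-corrected entry is compared against the
   picture name and each *accepted naming alternative* (synonyms
   collected during norming). An alternative is matched instead of the
   name only when it starts with the entry's first character *and* is
   strictly closer; ties go to the picture name.
4. The trial is correct iff the first typed character — both before and
   after backspace correction — equals the matched target's first
   character, and the string distance is strictly below the threshold
   (default 0.3). Correct trials are subtyped `identical`, `corrected`
   (exact after ≥1 backspace), or `below_threshold`; incorrect trials
   are `first_letter_error`, `distance_exceeded`, or `combined`.

The primary distance is the **Jaro distance**, a [0, 1] metric tailored
to short human-typed strings: characters match if they agree within a
sliding window of `floor(max(|a|,|b|)/2) − 1` positions; with `m`
matches and `t` transposition pairs, similarity is
`(m/|a| + m/|b| + (m−t)/m)/3` and distance is its complement. It equals
the Jaro–Winkler distance with zero prefix weight. Normalized
Levenshtein and optimal-string-alignment distances are provided for
comparison; both are slightly more conservative at the same 0.3
cut-off. All three are implemented natively in C++ on Unicode code
points and are validated in the test suite against independently coded
textbook implementations (and `utils::adist` for Levenshtein) on 10,000
random pairs.

Worked examples (frozen in the tests): typing `KESSEL` for the picture
*KELLE* gives d ≈ 0.261 < 0.3 (correct); `GESCHIRR` for
*GESCHIRRSPÜLER* gives d ≈ 0.143 (correct); `PFEILE` for *FEILE* fails
the first-letter condition; `BUR⌫⌫⌫⌫SCHLOSS` is incorrect because the
first character changed between raw and corrected entry even though
`BURG` is an accepted alternative of *SCHLOSS*.

# Typing-test metrics

Copy-typing performance uses the five-character-word convention: the
produced character stream is cut into consecutive non-overlapping
5-character chunks aligned positionally with the target text. A chunk
counts as correct if its characters match the target and no backspace
fell into its production span. Accuracy is the percentage of correct
chunks; speed is correct chunks per minute of total production time,
where each chunk's time runs from the completion of the previous chunk
(trial onset for the first). Under this convention a perfect copy of
150 characters in exactly one minute scores 30 wpm at 100% accuracy.
Whether between-chunk pauses should be excluded from the denominator is
not settled by the convention's one-sentence description; the package
includes them (total-time reading), which is the stricter choice and
the one the forced example pins down.

# The generative model

The synthetic-data generator runs the analysis model forward, which is
what makes parameter-recovery testing meaningful:

* **RTs.** For a target trial at centred ordinal position `p`,
  `mu = 1298.49 + 41.68·p + u0s + u1s·p + u0c + u1c·p` (ms), with
  independent normal random intercepts/slopes for subjects and
  categories, and `RT ~ Gamma(shape k, mean mu)` — the gamma-identity
  model. Defaults are the typed-naming fixed effects. The original
  variance components are not published, so the random-effect SDs are
  free parameters with plausible defaults (150/15/40/12 ms); `k = 18`
  puts the trial-level SD near 300 ms. The identity link requires
  `mu > 0`; generation aborts with an instructive error otherwise.

* **Errors.** `P(error) = logistic(−2.74 + 0.15·p)` at raw position
  `p ∈ 1..5` (≈ 7% at position 1 rising to ≈ 12% at position 5, ≈ 9%
  marginally — the realistic range for this paradigm). The raw rather
  than centred position is used so that the marginal rate lands in that
  range; the recovered slope is unaffected by the parameterization.

* **Keystrokes.** Each trial's planned outcome is realized as an event
  stream: correct trials as exact, backspace-repaired, one-character
  near-miss, or alternative-name entries; incorrect trials as null,
  special-key start, shift start, first-letter substitution,
  distance-exceeded, or fully dissimilar entries. Wrong characters are
  drawn from an alphabet disjoint from the name alphabet, which *bounds
  the planted distances by construction* (a single interior substitution
  keeps d ≤ 2/(3·4) ≈ 0.17 < 0.3; garbage entries keep d ≥ 0.5): the
  generator's labels are ground truth, not merely high-probability
  outcomes. The first event lands exactly at the trial's generated RT.

What the generator does *not* emulate: real typing-error phonology and
orthography (errors are alphabet-random, not confusion-based), hardware
timing jitter, inter-keystroke dynamics beyond a folded-normal interval,
learning/fatigue across the session, and item-level effects beyond the
category random effect. Passing recovery tests therefore show that the
pipeline is correct and well-calibrated *under the stated model*, not
that the model captures every property of human data.

# Model fitting

`fit_rt_model()` fits the gamma GLMM with identity link and the crossed
maximal structure `rt ~ pos + (pos | subject) + (pos | category)`, with
ordinal position mean-centred *on the retained analysis rows* (the
natural choice once exclusions have been applied; only the intercept is
affected). Two Laplace-likelihood backends are provided and
cross-checked against each other in the tests (slopes agree within 1%):
`glmmTMB` (default — automatic differentiation makes it several times
faster, and it is started at the sample mean so the identity-link
likelihood is finite at the first evaluation) and `lme4::glmer`.
Fixed-effect inference is Wald throughout: `CI = estimate ± 1.96·SE`,
p-values from the standard normal — matching the convention for this
analysis. The log-RT linear mixed model (`fit_log_lmm`) reports
Satterthwaite p-values via `lmerTest`.

Non-convergence triggers a fixed reduction ladder, each step recorded in
the fit's trace: (1) raise the optimizer iteration cap to 2 × 10⁵,
(2) zero the random-effect correlations, (3) drop the subject slope,
(4) drop the category slope. The order "subject slope before category
slope" is a documented choice; with 24 categories and 30 subjects the
category slope is usually the better-identified term, and the
literature's reduced error models kept category slopes.

`within_subject_summary()` produces the condition means and
within-subject standard errors used for CSI plots: observations are
normalized by subtracting the subject mean and adding the grand mean,
and the per-position variance of normalized values is inflated by
`K/(K−1)` (K = number of positions) — the Morey correction for
within-participant designs.

`exclude_trials()` keeps the RT analysis to correct non-filler trials
and reports the accounting identity
`retained = total − fillers − errors + filler-errors` explicitly, so
published-style trial counts can be reproduced and audited.

# Power analysis

`power_curve()` estimates power by brute-force refitting: for each
(subjects, categories) grid point it simulates from the generative model
with the assumed effect, excludes error trials, refits the log-RT LMM,
and counts p < α. Non-convergent replicates count as non-significant
(conservative). The log-LMM is the default engine because refitting a
gamma-identity GLMM hundreds of times is slow and the log-scale effect
(≈ 0.03 per position for typed naming) is detected with essentially the
same power; gamma refits are available via `engine = "gamma"`. Reported
trial totals follow subjects × categories × 5. A 200-simulation run
gives ±~6-point binomial CIs and is the desk-scale default; 1000
simulations reproduce the conventional protocol. Because the true
variance components of the original studies are unpublished, power
curves computed from the defaults are statements about the generative
model's assumptions, not re-estimates of any specific study's power.

# Numerical choices and degenerate inputs

* Distances operate on code points; empty strings are handled by the
  definitions (two empty strings are identical; any string vs an empty
  one is maximally distant).
* Best-match ties resolve to the picture name (strict-inequality
  reading); an entry equal to both name and alternative is attributed to
  the name.
* Backspace on an empty buffer is a no-op; an entry whose characters
  were all deleted fails the first-letter condition and classifies as
  incorrect rather than erroring.
* A single-subject table has no within-subject SE and errors out.
* Constant RTs give a zero-variance log-LMM, which is flagged rather
  than silently reported.
* Convergence is judged by each backend's own diagnostics (gradient
  checks for lme4, positive-definite Hessian for glmmTMB); the ladder
  stops at the first converged structure.

# Problem sizes used in the test suite

The recovery and calibration checks run at the study's own scale: 200
replicates of a 30-subject × 24-category experiment for slope recovery
and CI coverage of the gamma model, 200 null simulations for the
type-I-error calibration of the power machinery, 10,000 random string
pairs for distance-oracle equivalence, and 1000 seeded randomizations
for the lag-constraint validator. These sizes were chosen so the whole
suite stays comfortably runnable on a laptop while keeping Monte-Carlo
error well below the tolerances being asserted.

# Known limitations

* The block-order objective and the constrained placement sampler are
  principled formalizations of informally described procedures; they do
  not reproduce any specific published list.
* The generator's error taxonomy is a mixture with fixed weights; real
  participants' error-type composition varies with typing skill.
* Gamma-identity GLMMs can be numerically delicate; the two backends and
  the ladder mitigate, but extremely small or quasi-separable data sets
  will end on reduced structures (and say so in the trace).
* Reproducing the deposited studies' exact numbers requires their data
  archives, which are not redistributed with the package.
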