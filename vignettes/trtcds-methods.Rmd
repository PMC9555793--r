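---
title: "Rule-based decision support for tinnitus retraining therapy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based decision support for tinnitus retraining therapy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trtcds)
```

## The clinical problem

Tinnitus retraining therapy (TRT) assigns each patient to one of five
treatment-protocol categories — C0 (tinnitus a minimal problem), C1
(significant tinnitus), C2 (tinnitus with significant hearing loss), C3
(hyperacusis-dominant) and C4 (prolonged exacerbation) — and then tunes a
highly individualized sound-therapy and counseling regimen over a sequence
of clinic visits. Both steps are expertise-bound: the category depends on
audiometry (pure-tone thresholds, loudness discomfort levels), a structured
interview and medical background, and the treatment (instrument model,
mixing point, follow-up mode, duration) is adjusted visit by visit against
the Tinnitus Handicap Inventory (THI).

`trtcds` implements a transparent, rule-based pipeline for both steps:
discover *decision rules* that map patient measurements to a category and
*action rules* that describe which treatment changes improved comparable
patients, translate both into an explainable knowledge base, and apply
forward-chaining inference to a new patient's facts.

## Decision rules

A decision rule is a conjunction of *cedents* (single attribute conditions:
equality, threshold, or half-open interval `[a;b)`) implying a category:

```
LL3(<15;20)) & T_An(>=8) => Category(1) | conf=94.4
```

Two statistics characterise a rule on a table of objects:

* **support** — the number of objects matching the antecedent (note: the
  antecedent alone, not antecedent-and-consequent), and
* **confidence** — the percentage of those objects that also carry the
  rule's category.

`mine_decision_rules()` enumerates antecedents level-wise (Apriori-style)
over attribute-equals-value items taken from a discretized table, pruning
by support. Because support is anti-monotone in the antecedent, the
enumeration is exhaustive: the output provably equals brute-force
enumeration over all conjunctions up to the length cap, which the test
suite verifies on hundreds of random tables. The minimum support is given
as a fraction of objects (default 1%) and converted to a count by ceiling;
the default confidence gate is 80%. Intervals come from
`discretize()`/`feature_table()` — equal-width, half-open, with per-attribute
width overrides (5 dB for audiometry, 0.5 for 0–10 Likert scores by
default). On-the-fly interval merging is deliberately out of scope; the
analyst chooses bin widths, and a planted threshold pattern is recovered by
aligning a bin edge with the threshold.

## Action rules

An action rule `[(ω) ∧ (α → β) ⇒ (θ → ψ)]` pairs a *stable context* ω
(attributes the clinician cannot change: demographics, etiology — but also
unchanged treatment context such as the instrument type) with a change of
*flexible* attributes from α to β that shifts the outcome θ (not better)
to ψ (better). The desired-effect attribute is the visit-to-visit change in
THI total score, falling back to the 0–10 tinnitus-awareness score when a
THI total is missing (`change_metrics()`); the package's sign convention is
`ch = previous − current`, so positive change is clinical improvement, and
a visit pair is labelled *better* when `ch ≥ 1` score point (the cut-off is
configurable; any THI decrease counts by default).

`mine_action_rules()` works on a visit-pair table (one row per consecutive
visit pair with before/after values of the flexible attributes). For a
candidate (ω, α→β) it evaluates two classification rules:

* **after-rule** `(ω ∧ after = β) ⇒ better`: its confidence is the
  probability the desired state holds once the action has been taken in
  context ω. This is the rule's **composite confidence**, and the rule's
  **expected gain** is the mean percent-change over the after-rule's
  supporting pairs. Both threshold gates (support and confidence) apply.
* **before-rule** `(ω ∧ before = α) ⇒ not better`: its support is the
  number of ω-pairs found in state α. Its confidence is computed over the
  subset of those pairs that *remained* in α — the counterfactual "what
  happened to comparable patients whose treatment was left unchanged".
  When every eligible pair took the action (full compliance) that subset
  is empty and the confidence is recorded as `NA`; the confidence gate is
  applied only when the counterfactual exists. This is a deliberate design
  choice: a literal confidence gate on all state-α pairs would make a
  uniformly effective, fully-complied-with action unminable, since the
  very pairs that prove the action works would count against the
  "not better before" rule.

Both before- and after-rule statistics are retained on the rule object so
alternative composites (e.g. products, lift-style contrasts) can be
reported without re-mining. One consequence of defining the composite
confidence purely on the after-state is that two actions with the same
(ω, β) but different α share confidence and gain; they differ only in which
patients they are *applicable* to at recommendation time, where the
patient's current facts must match α exactly.

## The knowledge translator

Mined or hand-curated rules enter the knowledge base through a small
rule-text dialect (see `parse_rule_text()`), chosen to be expressive enough
for every rule the pipeline produces: interval, threshold (including strict
`<`/`>`), equality and yes/no predicates, and `from->to` changes restricted
to flexible attributes. Parsing and serialization are mutually inverse —
property-tested on thousands of grammar-generated rules — so the dialect
doubles as a canonical storage format. Each encoded rule receives:

* a deterministic natural-language explanation, assembled one clause per
  cedent from the vocabulary's display phrases (e.g. `LL3` → "the left-ear
  loudness discomfort level at 3 kHz"; low problem-score intervals render
  as "not indicated as a problem"). Identical rules always yield
  byte-identical text; an attribute without a phrase falls back to its raw
  name.
* provenance (source file and line), an id, and the knowledge-base version
  tag.

Duplicates (same canonical premises and consequent) collapse keeping the
higher-confidence variant, mirroring the principle that only the
best-validated form of a pattern belongs in the knowledge base. The
knowledge base persists as JSON Lines: a header line carrying the version
tag — so even an empty knowledge base round-trips its version — followed
by one rule per line.

## Inference

`infer_diagnosis()` and `recommend_treatment()` run forward-chaining
pattern matching over a single patient's fact set. Design decisions:

* a missing fact leaves a cedent **unsatisfied** rather than unknown-true:
  the system never diagnoses from absent evidence;
* numeric cedents are evaluated against **raw values** (no
  re-discretization at match time), because curated rules mix `>=8` with
  interval forms; interval bounds are half-open (`LL3 = 91` does *not*
  match `LL3 in <85;91)`);
* per category, matched-rule confidences aggregate by **max** (not
  noisy-OR or voting): the reported confidence is always an actual rule's
  confidence, which keeps every prediction attributable to one explainable
  rule;
* ties break by category order C0 < … < C4, then rule id, so output is
  deterministic;
* treatment recommendations are ranked by expected gain, then confidence
  (confidence-first ranking is available via `rank_by`); an action whose
  to-state already holds is not recommended (its from-state fails).

The matcher pre-filters rules by an attribute index (alpha-memory style, in
the spirit of Rete networks); a full Rete network with join nodes is
unnecessary because fact sets describe a single entity. The binding
contract — indexed matching behaves identically to naive per-rule
evaluation — is enforced by a 1,000-trial randomized property test.

## The synthetic cohort generator

The original clinic registry is not distributable, so `generate_cohort()`
produces cohorts with the *structure* the mining assumes, at the same scale
(defaults: 555 patients, 3–8 visits each, ≈3,000 visits):

* a latent category per patient, drawn from a configurable mixture;
* category signatures reflecting the classical clinical picture: C2
  patients elderly with elevated pure-tone thresholds, C3 patients young
  (30–38) with depressed loudness discomfort levels and noise/stress
  backgrounds, C1 middle-aged with high tinnitus-distress scores and
  depression-related etiology;
* **planted decision rules**: a cedent conjunction is forced to hold with
  category-dependent probability calibrated (by Bayes' rule, from the
  mixture and the target confidence) so that the empirical rule confidence
  is the planted value in expectation; non-satisfiers get exactly one
  cedent broken. The default plants an elevated-L2/preserved-R6 pattern
  implying C2 at 87% confidence;
* **planted treatment effects** in `generate_visit_pairs()`: eligible
  pairs (context holds, before-state matches) take the action with a
  compliance probability and then improve at the planted rate, drawing the
  improvement from a truncated-normal percent-change distribution; all
  other pairs follow a mildly negative noise drift (mean −8%, sd 8), so
  spontaneous improvement is uncommon (~10–15% of untreated pairs), as is
  clinically typical for unmanaged tinnitus. The no-response LDL sentinel
  999 is emitted with probability 0.01 to exercise that code path.

All distributional parameters are package choices — declared, configurable
and fixed by the spec's seed; none are estimates from clinical data. What
passing tests show is therefore that the *pipeline* is correct and
well-calibrated (planted parameters are recovered within sampling error;
null cohorts yield essentially no spurious high-confidence action rules),
not that the generator reproduces real-world distributions: real registry
data is sparser, has correlated missingness, inconsistent entries and
drifting measurement practices that the generator deliberately does not
emulate.

Problem sizes used by the test suite are chosen so that sampling error is
small relative to the ±5-percentage-point recovery bands: 1,500 patients
for decision-rule recovery, 6,000 visit pairs for action-rule recovery, 20
seeds × 500 pairs for the null calibration, and exhaustive-enumeration
cross-checks on 200+ random tables of at most 8 attributes and 50 rows.

## Worked evaluation study

The package ships a compact reference knowledge base and five worked
patient cases (`trt_example_kb()`, `trt_eval_cases()`) spanning all five
categories and etiologies from noise exposure to medication side effects.
Running the evaluation harness reproduces the study figures the fixtures
encode: diagnostic accuracy 80% (the single miss is a case annotated at
the source as containing inconsistent interview/audiometric data, whose
recorded protocol nevertheless agrees with the system's prediction),
diagnostic coverage 100%, mean primary confidence 83.51%, and treatment
coverage 3 of 5 cases with the top recommendation for the noise-induced
case carrying a 41-percentage-point expected gain. The accuracy
denominator is all cases (an uncovered case counts as incorrect); a
covered-only variant is reported alongside. The mean confidence uses exact
stored confidences before display rounding, which is why the first case's
rule stores `conf=66.667` while printing as 66.7%.

```{r}
ed <- evaluate_diagnosis(trt_example_kb("diagnosis"), trt_eval_cases())
ed$cases[, c("case", "actual", "predicted", "confidence")]
round(ed$mean_primary_confidence, 2)
```

## Open design points, resolved

Several contracts were genuinely open and are fixed here as package
conventions:

* **Percent change** is relative to the *previous* visit (not baseline),
  consistent with the change score being defined visit-to-visit.
* The **"better" cut-off** defaults to any THI decrease (`ch ≥ 1`); no
  standard minimal clinically important difference is imposed, but the
  threshold is a parameter.
* **Imputation** of THI totals is linear interpolation on the
  visit-ordinal axis with nearest-value edge fill, every imputed cell
  flagged — a deterministic, auditable stand-in for model-based
  imputation.
* The follow-up level `"0"` (no follow-up contact) is kept verbatim as a
  categorical level rather than renamed, so curated rules round-trip
  unchanged.
* `LSD` is carried as an opaque numeric attribute: it appears in curated
  rules but has no documented definition, so the vocabulary deliberately
  leaves its phrase as the raw name.
* The before-state θ of an action rule's effect is the complement of the
  desired state ("not better").
* Chi-square feature ranking (`chi2_rank()`) uses the raw statistic, no
  continuity correction and no p-value — it is a ranking score, not a
  test — with all-zero rows/columns dropped before computation.

## Known limitations

* Decision-rule mining operates on discretized equality items; threshold
  rules spanning many bins are found only when a bin edge aligns with the
  threshold. This is a deliberate trade for exhaustive-enumeration
  equivalence.
* Composite action-rule confidence ignores the from-state (see above);
  rules recommending a transition never actually observed in the data can
  be emitted when the after-state is independently predictive. The
  retained before-rule statistics let a reviewer filter these.
* Explanations are template-generated; they are faithful (every clause is
  literally satisfied by the matched facts — asserted in the test suite)
  but not stylistically curated.
* No rule chaining: consequents never assert new facts, so the inference
  engine is a single-pass matcher by design.
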