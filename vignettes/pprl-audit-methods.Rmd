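---
title: "Methods: auditing privacy-preserving record linkage against a rule-based matcher"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditing privacy-preserving record linkage against a rule-based matcher}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pprlaudit)
```

## The estimation problem

Two health systems serve overlapping patient populations. A rule-based
matcher (the EHR's linkage module) and a privacy-preserving record linkage
(PPRL) system propose cross-site patient matches; neither is a gold
standard, real identities cannot be released, and exhaustive review is
impossible. The design `pprlaudit` implements resolves this with three
ideas:

1. **Exclusive categories.** Because the PPRL match sets at the strict
   (98), balanced (95) and permissive (90) score cutoffs are nested by
   construction, the cross-classification with the rule-engine outcome
   partitions the cohort into exactly 8 cells. Categories 1 (nobody
   matched) and 8 (everybody matched) are assumed correct and never
   reviewed; the 6 disagreement cells carry all the information about
   relative error.
2. **Audit projection.** A simple random sample of 200 pairs per
   disagreement category is adjudicated. The category false-match rate is
   `p̂ = FM / (reviewed − uncertain)` — uncertain verdicts are removed from
   the denominator, and privacy-restricted charts reduce `reviewed`
   (they are not resampled). `p̂` and its Clopper–Pearson 95% bounds are
   multiplied by the category population count, and the unrounded
   products are summed over each algorithm's constituent categories to
   give `FM_a` with bounds.
3. **Union proxy gold standard.** Recall cannot be measured against truth,
   so the union of patients matched by either engine (`Matches_any` =
   cohort − category 1) stands in for it. `Precision_a = (M_a − FM_a)/M_a`
   and `Recall_a = (M_a − FM_a)/Matches_any`. Recall is therefore an
   upper-bound-flavoured estimate: pairs both engines miss are invisible.

Assumptions worth stating: sampled pairs are exchangeable within category
(simple random sampling guarantees it), adjudication is unbiased given a
pair, unreviewed full-agreement categories contribute zero error, and
uncertain pairs are missing at random with respect to the true FM status —
if most uncertains are actually false, precision is overestimated.

## Statistical choices

- **Exact intervals.** Category FM rates use Clopper–Pearson bounds via
  the beta-quantile closed form (`qbeta(α/2, x, n−x+1)`,
  `qbeta(1−α/2, x+1, n−x)`), with the conventional 0 and 1 endpoints at
  `x = 0` and `x = n`. No continuity corrections; zero-FM categories get
  `[0, upper]` naturally. The test suite checks every `(x, n)` with
  `n ≤ 50` against a bisection of the binomial tail equations to 1e-8.
- **Rounding.** All sums are computed on unrounded values; rounding (half
  away from zero, `round_half_up()`) is applied only at display. This
  matters: rounding category projections before summing changes totals.
- **Precision CI.** Propagated directly from the projected-FM bounds:
  `[(M − FM_hi)/M, (M − FM_lo)/M]`.
- **Recall CI.** The verbal recipe "normal-approximation bounds on the
  recall proportion plus-or-minus the projected-FM bounds" is ambiguous;
  the implemented formula is
  `lo = (M − FM_hi)/Matches_any − z·SE`, `hi = (M − FM_lo)/Matches_any + z·SE`
  with `SE = sqrt(r(1−r)/Matches_any)` at the point recall `r`. It is
  documented here precisely because other readings differ in the second
  decimal; published CI endpoints should be treated as approximate
  cross-checks.
- **Inestimability.** A reviewed category whose denominator is zero after
  excluding uncertains yields an explicit `inestimable` status that
  propagates to every algorithm containing the category (CLI exit code 4),
  never a silent zero. A category with zero population contributes exactly
  zero regardless.

## The two matching engines

**Rule engine.** Twelve identifier comparisons (exact full name, exact
first name, soundex of first and of last name, exact DOB, year of birth,
email, phone, address, zip, gender, middle initial) are summed with
configurable weights; a query is `matched` iff exactly one candidate
strictly exceeds the threshold — ambiguity is failure. Production weight
tables of commercial modules are unpublished, so the default
(`default_weight_table()`: DOB 30, full name 25, contacts 15 each,
threshold 70) is a documented stand-in. SSN is deliberately *absent* from
the rule engine and *present* in the token schema: this asymmetry is the
main mechanism by which hashed-token matching achieves higher recall, and
it is preserved on purpose. Blocking on DOB, phone, email and
soundex(last)+first-initial is provably lossless for the default weights:
a pair agreeing on none of those keys can score at most 50 < 70.

**Token engine.** Records are normalized (hyphens stripped from SSN/phone,
DOB as mm/dd/yyyy, plus case-folding and trimming — an extension beyond
minimal preprocessing, without which hashed exact-match tokens are
uselessly brittle), then each of 18 feature-combination templates is
HMAC-SHA256-hashed with a run-specific salt over the canonical string
`template_id<US>feature…` (unit separator 0x1F, documented byte-exactly so
cross-implementation equality is testable). The published description of
commercial tokenizers names only one combination (last name + first
initial + gender + DOB); the default schema includes it and fills the rest
with standard hashed-linkage practice (SSN-, phone-, email-, address- and
phonetic-name-anchored combinations). No fidelity to any proprietary
schema is claimed, and the schema is fully overridable.

Pair similarity is a weighted Jaccard over template agreement (both-null
templates ignored; all-null pairs score 0). The proprietary
gradient-boosted scorer is replaced by a transparent monotone calibration:
isotonic regression of truth labels on raw similarity, fitted on a
labeled world generated from the same configuration under a derived seed,
scaled to 0–100. A score of `s` therefore means "pairs like this were true
about `s`% of the time in the calibration world", which is what makes the
98/95/90 cutoffs meaningful as precision levels. Candidate pairs come from
token blocking — complete for any pair with positive similarity, since
agreement on a template *is* a shared token — and a deterministic greedy
one-to-one assignment (descending score, ties by record id) yields a
single assignment from which all three threshold sets are cut, making
containment structural rather than statistical.

## The synthetic world

`sim_config()` states the world; the generator is deterministic given the
seed, and every downstream stage can be verified against its truth ledger.

| parameter | default | rationale |
|---|---|---|
| `n_site_a`, `n_site_b` | 5000 | large enough for stable audit strata, small enough for CI budgets |
| `overlap_fraction` | 0.30 | ≈ the share of cross-site patients in the union proxy of the motivating two-site evaluation (29.4%) |
| `gender_probs`, `age_bin_probs` | 53.6% F; decade bins | published base-population marginals; ages piecewise-uniform within decade bins |
| `twin_rate` | 0.02 | US twin-birth prevalence ≈ 3%; twins share DOB, surname and household, 40% share a first initial |
| `household_rate` | 0.10 | co-residents sharing surname/address/phone/zip; with twins, the partial-agreement confounders that make false matches possible at all |
| `common_name_fraction` | 0.30 | fraction drawn (Zipf-weighted) from packaged top-100 ranked name lists; ~43% of audited pairs in the motivating review carried a top-100 name |
| `ssn_missing_rate` | 0.35 | SSN availability drives the engines' recall gap; never corrupted, only missing |
| `email/phone_missing_rate` | 0.30 / 0.15 | typical EHR contact completeness |
| `typo_rate` | 0.05 | one single-character substitution/transposition/deletion per hit field |
| `compound_name_variant_rate` | 0.30 | one component of a hyphenated surname dropped per site — the canonical PPRL miss cause |
| `nickname_rate`, `middle_name_inclusion_rate` | 0.07 / 0.75 | registration-desk variation |
| `stale_contact_rate` | 0.15 | one site holds an out-of-date phone/email/address set |

The twin and household structure deserves a note. With only independent
field corruption, false candidate pairs barely exist, the isotonic
calibration approximates a step function, and the intermediate threshold
categories are empty — threshold choice would be meaningless. Twins and
households produce false pairs agreeing on several templates (shared
phone, address+zip+surname, and for twins DOB-based combinations),
interleaved in raw similarity with heavily corrupted true pairs; the
calibration then rises gradually and all 8 categories populate. These
defaults were fixed as part of the world's design, before the acceptance
suite was finalized, and none of the acceptance criteria depend on the
resulting category proportions.

What the generator does **not** emulate: within-site duplicate records,
longitudinal registration drift, correlated field errors (a fraudulent or
shared identity corrupts many fields jointly), non-uniform restricted-chart
concentration, and real name-frequency tails (the packaged lists have 120
entries; the rare-name generator is synthetic by construction and marked
as such). A green synthetic run therefore establishes that the *pipeline
and estimators* behave as specified on a world with the stated error
structure — not that any particular production system achieves these
precision/recall numbers.

## Adjudication simulation

Manual review is replaced by comparison against the truth ledger: a
sampled patient's proposed partners (rule-engine and/or permissive token
match) are all checked; any wrong partner makes the pair a false match.
Independently, verdicts flip to `uncertain` with probability 0.05 and to
`excluded_restricted` with probability 0.0225 (≈ 27/1200, the observed
restricted-chart attrition in the motivating review); restricted takes
precedence and reduces the reviewed denominator. With both rates zero the
review table equals the truth exactly — the degenerate cases
(all-uncertain, empty categories) are exercised in the tests.

## Reproducibility mechanics

All randomness flows from one integer seed; per-stage streams are derived
arithmetically (kept below 2^31), so registry files are byte-identical
across runs and the RNG state of the calling session is never disturbed.
Artifacts written by `run_synthetic(out_dir=)` include a manifest with the
full configuration and per-file MD5 digests. The tie-break rules (greedy
assignment by descending score then lexicographic record ids; "exceeds"
strict for the rule engine, "≥" for score cutoffs so the printed threshold
labels name their own match sets) are part of the contract and tested.

## Known limitations

- The recall CI formula is one defensible reading of an ambiguous verbal
  description (see above); treat the interval, not the point, as soft.
- The isotonic calibration is coarse when raw similarity takes few
  distinct values (18 unit-weight templates ⇒ ratios of small integers);
  per-template weights are supported but default to 1.
- The union proxy makes recall estimates relative: an engine pair that
  both miss the same patients inflates everyone's recall equally.
- The default rule-engine weights and token schema are stand-ins; results
  on synthetic data characterize the *design*, not any vendor's product.
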