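---
title: "DENTALE: model, design decisions, and what the synthetic validation establishes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DENTALE: model, design decisions, and what the synthetic validation establishes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentale)
```

## The instrument

DENTALE grades the late dental and maxillofacial effects of antineoplastic
treatment visible on a single orthopantomogram of a childhood-cancer
survivor. A human reader records findings; the package turns them into a
weighted total and a referral decision. The weights encode clinical
importance: condyles (3 per side) drive mandibular function; the ramus
(1 per side) matters less; canines (8) anchor reconstruction; incisors (6)
carry aesthetics; premolars and molars (4) are more replaceable. Four
per-tooth aspects — crown morphology, root morphology, crown–root ratio
(≥ 1:1 counted abnormal, because panoramic projection distorts absolute
lengths but preserves the ratio), and age-appropriate eruption — score one
point each on present teeth only: a missing tooth scores its presence
weight *instead of* its aspects, never both. Reduced alveolar bone and
tooth wear score one point per sextant; wear is unscorable in an edentulous
sextant. The base range is 0–158.

Two decision rules sit on top. First, the localized-pathology adjustment:
if any single sextant accumulates strictly more than 10 points, 5 points
are added once. This exists because borderline cases whose pathology is
confined to one sextant can otherwise slip under the referral cutoff while
still needing specialist care. Second, referral: final total ≥ 16.

## Parameters that matter

All live in `default_weights()` and are overridable via a key-value file:

* `sextant_adjustment_threshold = 10`, **strict** comparison. A sextant at
  exactly 10 adds nothing.
* `sextant_adjustment_bonus = 5`, applied **at most once** per assessment
  regardless of how many sextants qualify — the rule speaks of a single
  additional increment. `adjustment_per_sextant = TRUE` switches to
  per-sextant application for sensitivity analysis; under that switch the
  final total can exceed 158 + 5, which is why 0–158 is documented as the
  *base* range.
* `referral_threshold = 16`, **inclusive** (≥). Whether a score of exactly
  16 triggers referral is not fixed by the published description; the
  inclusive reading is consistent with a 100%-sensitivity operating point
  and is configurable.

A sextant's total for the adjustment counts the presence points of its
missing teeth, the aspect points of its present teeth, and its alveolar
and wear points. Condyle and ramus points are attributed to **no**
sextant: they are not sextant-localized anatomy, and the rule targets
dental pathology confined to one region. This attribution was a genuinely
open design point; it is explicit and fixed here.

Teeth lost for reasons that are not late effects (e.g. orthodontic
extraction) are handled by a free-text `exclusion_note`: an excluded tooth
contributes nothing and is left out of sextant totals. "Missing" itself is
a single status covering agenesis and extraction — pre-treatment dental
history is typically unavailable, so cause attribution is not modelled.
An unerupted but radiographically visible germ is `present` (possibly with
the eruption aspect flagged); only total radiographic absence is
`missing`.

## Reliability and accuracy statistics

`icc_two_way()` defaults to ICC(2,1): two-way random effects, absolute
agreement, single measure. The rationale: the raters are a sample of
possible dentists, each rates every radiograph, and the clinically
relevant unit is a single rater's score. Absolute agreement is the right
flavour because a systematic rater offset changes referral decisions even
when rankings agree. The estimate comes from the two-way ANOVA mean
squares; confidence bounds use the McGraw–Wong F-method; consistency and
average-measure variants are exposed for sensitivity analysis. Matrices
with missing cells are rejected rather than imputed, as are zero-variance
matrices.

`diagnostic_accuracy()` computes sensitivity, specificity, PPV and NPV
directly from a 2×2 table, with Wilson score intervals and one-decimal
percentages rounded half away from zero. A zero-denominator metric is
reported as not applicable — never silently 0 or 1. Note one documented
discrepancy in the source material for this instrument: the published
pre-refinement counts (50 true positives, 2 false positives, 3 false
negatives, 28 true negatives) arithmetically give 94.3% sensitivity and
93.3% specificity, not the adjacent published 100%/67.2%. This package
always computes from counts and makes no attempt to reconcile prose with
arithmetic.

`sweep_thresholds()` evaluates candidate referral cutoffs (default 14,
16, 18, 20) with the inclusive rule. Selection is safety-first: among
thresholds achieving sensitivity 1, take those with maximal specificity,
tie-broken to the smallest such threshold. The published selection
criterion is verbal ("identify every survivor the experts would refer,
while minimizing over-referral"); a literal "smallest threshold with
sensitivity 1" reading ignores over-referral entirely and would always
pick the lowest candidate, so the two-stage rule is used. The raw smallest
sensitivity-1 threshold is also reported on the sweep object.

## The synthetic cohort: what it emulates, what it does not

No generative model of late dental effects was published, so the
generator is this package's own stand-in, built to reproduce the two
regimes a screening pilot exposes:

* **Diffuse multi-item pathology.** Each subject draws a latent severity
  $s \in [0,1]$ from a two-component Beta mixture — a low-severity mode
  (Beta(2, 10)) and a high-severity mode (Beta(5, 3)) with mixture weight
  0.6 on the high mode, echoing a survivor cohort in which roughly
  two-thirds needed referral. Every scorable item is abnormal
  independently with probability $\mathrm{logit}^{-1}(a + b s)$; the
  per-item intercepts (−5 to −3.5) keep near-zero pathology at $s = 0$
  and the slopes (3.5–5.5) produce totals spanning essentially the whole
  usable range at high severity.
* **Single-sextant pathology.** With probability 0.15 a subject enters a
  localized regime: one random sextant gets severity boosted by 0.3,
  every item outside it (including the bony items) is forced normal.
  This is the "confined to one sextant" edge case that motivated the +5
  adjustment.

Expert labels are `severity > 0.4`, flipped with probability 0.02 — they
derive from the latent state, *not* from the score, so agreement between
score-based referral and expert labels is an empirical outcome, not a
tautology. Rater noise flips each binary finding with a per-item
probability (must be below 0.5), with an optional per-rater bias that
inflates false-alarm flips on aspect flags; invariant-violating flips are
repaired (aspects cleared on missing teeth, wear cleared in edentulous
sextants). Ages are drawn uniformly on 8–18 years; the lower bound keeps
all 28 permanent-tooth germs radiographically assessable per the shipped
eruption-age reference table (standard pediatric-dentistry reference
values, not study data; used only here and by the advisory helper
`flag_unexpected_eruption()`, never by the scorer).

These defaults were chosen once as a plausible stated world and are not
tuned to test outcomes. What a green synthetic test establishes: the
scorer, adjustment, referral rule, ICC and accuracy machinery behave
correctly on data with the assumed statistical structure. What it cannot
establish: the published reliability coefficients or operating
characteristics on real radiographs — the rater-level scores behind those
were never published, so the reliability acceptance battery is
property-based (oracle equivalence, perfect-agreement and rater-offset
behaviour, noise monotonicity on the 14-subject × 3-rater design) rather
than value-reproducing.

One test construction deserves a note: the threshold-recovery acceptance
check defines expert labels as `total >= 16` (self-consistency) and, per
its stated construction, requires positives at 16–17 and negatives at
14–15 to make the candidate thresholds distinguishable. Four hand-built
sentinel subjects with totals 14, 15, 16, 17 guarantee that band is
occupied in every replicate; the remaining 83 subjects per replicate come
from the generator defaults.

## Numerical choices and degenerate inputs

* Integer scores are exact doubles; no floating-point tolerance is needed
  in the scorer, and oracle-equivalence tests use exact equality.
* ICC: perfect agreement (residual and rater mean squares both zero)
  returns estimate 1 with a degenerate [1, 1] interval rather than NaN.
* Percent rounding is half away from zero (94.55 → 94.6), matching the
  one-decimal presentation convention.
* Degenerate label vectors (all positive or all negative) reject a sweep;
  replicates with degenerate labels are skipped and counted in
  `recovery_experiment()`.
* All randomness flows through explicit seeds; the generator restores the
  caller's RNG state (`generate_cohort()` is a pure function of params
  and seed).

## Known limitations

* The per-tooth aspect list (crown, root, crown–root ratio, eruption) is
  reconstructed from the instrument's published description; if the
  original scoring form carries additional items, `default_weights()`
  would need extending.
* Deciduous teeth, third molars, clinical (non-radiographic) findings and
  longitudinal change scores are out of scope by design.
* The synthetic generator models no biology (radiation dose, age at
  treatment); it emulates statistical structure only.
* Reliability of the instrument for clinicians other than dentists, and
  the +5 adjustment's behaviour beyond small pilots, are open questions a
  software package cannot answer.
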