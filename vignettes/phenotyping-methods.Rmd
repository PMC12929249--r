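---
title: "Phenotyping PWH visits: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping PWH visits: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolca)
```

## The problem and the modelling stance

People with HIV who fall out of regular care are more likely to have
unsuppressed viral loads and worse outcomes, but they are a heterogeneous
population: the factors predicting a care gap differ across subgroups.
`phenolca` operationalizes a visit-level phenotyping workflow: every attended
clinic visit is an observation described by categorical indicators drawn from
structured EHR fields and from rule-matched note topics; a latent class model
clusters visits into phenotypes; and care outcomes are then compared across
phenotypes. The unit of analysis is deliberately the *visit*, not the
patient — any prospective visit can be phenotyped on the spot — and
within-patient correlation is knowingly ignored in both the likelihood and
the outcome comparisons. This is a real limitation: standard errors are
anti-conservative to an unquantified degree, which is one reason the package
follows the conservative significance threshold `P < 0.001` in its profile
tables.

## The latent class model

With classes `c = 1..C`, items `j = 1..J` with `L_j` levels, prevalences
`π` and item-response probabilities `θ`, the likelihood of a visit is
`Σ_c π_c Π_j θ_{c,j,x_j}` (local independence). Estimation is plain EM:

* **E-step** computes posterior responsibilities in log space (a max-shifted
  log-sum-exp), so hundreds of items cannot underflow.
* **M-step** sets `π` to mean responsibilities and `θ` to
  responsibility-weighted level frequencies, then clips `θ` to
  `[1e-6, 1 − 1e-6]` and renormalizes. The clip prevents `log(0)` and
  absorbing boundaries; it is far below any scientifically meaningful
  probability resolution at cohort sizes in the thousands. A class whose
  total responsibility falls below `1e-8` raises an explicit degenerate-class
  error rather than silently collapsing.

Tunable parameters, with defaults and rationale:

| parameter | default | why |
|---|---|---|
| `n_restarts` | 20 | mixture likelihoods are multimodal; 20 random Dirichlet starts make the best-of-restarts log-likelihood stable on the benchmark problems in the tests |
| `tol` | 1e-6 (relative) | log-likelihood changes below one part in 10^6 are far under the sampling noise of any criterion comparison |
| `max_iter` | 1000 | near-degenerate models converge slowly; the cap is a guard, not an expected stop |
| `clip` | 1e-6 | see above |

Model selection fits `C = 1..10` and reports AIC, BIC, SABIC (Sclove's
`n* = (n+2)/24` adjustment) and CAIC; the selected `C` is the argmin of the
chosen criterion with ties broken toward the smaller model. The
selection object deliberately reports *all four curves*: in practice the
criteria keep improving slightly past the scientifically interpretable
class count, and the final choice is an elbow judgement the analyst must
make; the package automates only the argmin. Classes are relabelled by
descending prevalence after fitting (label switching makes raw indices
meaningless), and `align_classes()` resolves labels between two fits by an
exact minimum-cost permutation search (branch-and-bound over the pairwise
absolute-θ-difference cost matrix; exhaustive in effect, instant at C ≤ 10).

Ties in the maximum-posterior hard assignment go to the lower class index —
an arbitrary but deterministic and documented rule.

## Note-topic extraction

Topic extraction is exact token matching, not NLP: text is lowercased and
split on any non-alphanumeric run (so "HIV-1" yields "hiv", "1"), and a
topic is present when any include phrase occurs contiguously with no
exclusion term within ±3 *whole* tokens of the matched span, measured from
the span's outermost token on each side. Exclusions match whole tokens only
("nose" never negates). The default exclusion list is exactly
`{"no", "neg"}`; anything richer is configuration, because the authoritative
token lists for the original study are not public — the shipped 12-topic
lexicon is illustrative and user-replaceable. Widening the window can only
suppress mentions (monotonicity is property-tested), consistent with the
observation that a ±5-word window does not change results on real data. The
deliberate non-goals: no stemming, no section detection, no general negation
scope parsing. A brute-force matcher that enumerates every
(include-occurrence, exclude-occurrence) pair serves as the independent
oracle in the tests.

## Outcome definitions and boundary decisions

* **Primary LTFU** (per visit): the next attended visit is more than 365
  days later. When no next visit exists the package distinguishes two cases:
  if more than 365 days remain to the study end the gap is unclosable and
  the visit is LTFU; otherwise follow-up is insufficient and the visit is
  *non-evaluable*. Non-evaluable visits are excluded from outcome
  denominators by default; `boundary_rule = "count_as_not_ltfu"` restores
  the full-denominator alternative, because published analyses whose class
  sizes equal full denominators evidently evaluated every visit and the
  original boundary rule is not recoverable from the text.
* **NHAS retention**: retained at an index visit iff ≥2 attended visits more
  than 90 days apart (strict) fall within the 365-day period starting at the
  index visit, implemented as calendar days `d .. d+364`; the index visit
  counts as one of the two. The period endpoint is not fixed by the source
  definition; days 0–364 is the reading that makes the period exactly 365
  days long.
* **High viral load**: any sample with ≥200 copies/ml (boundary inclusive)
  drawn in `(visit_date, visit_date + 365]`. "In the 365 days following"
  reads most naturally as excluding day 0; `include_day0 = TRUE` flips that,
  since a same-day draw is arguably "following" the appointment.
* Retention history gives first-visit status precedence over the gap test:
  a visit that is, or immediately follows, the patient's first recorded
  visit cannot be classified by prior-year behaviour. This keeps the three
  levels mutually exclusive and exhaustive, and it counts index visits that
  are themselves first visits as `prev_visit_was_first` — the reading under
  which "new patient" classes are visible to the LCA.

Dates are ISO-8601 calendar dates throughout and all day arithmetic is exact
integer differences; there are no time zones.

## What the synthetic generator does and does not emulate

The generator draws a cohort from a *known* latent class world so that every
downstream stage has ground truth: patients carry a fixed class, age, sex;
visits follow a per-patient renewal process whose inter-visit gap is a
two-component mixture (short: uniform 30–180 days; long: uniform 400–700
days) with class-specific long-gap probability; indicators are
class-conditional Bernoulli draws; viral loads are ≥200 copies/ml with
class-specific probability; and notes are filler prose with planted include
tokens, negated ("no" immediately before the token) with probability
`negation_rate`. The default world copies the published six-class cohort
summaries: class mix proportional to the six reported class sizes, indicator
prevalences equal to the printed per-class percentages, per-class age
distributions, long-gap probabilities equal to the reported per-class LTFU
rates, and viral-load detection probabilities equal to the reported
per-class high-viral-load rates. Only 23 diagnosis indicators are printed in
the source summaries (the full 27-variable list is in a non-public
supplement), so the default schema carries those 23. `negation_rate`
defaults to 0.2 — roughly one in five topic mentions in clinical text is
negated, a typical figure for problem-oriented notes — and is fixed once;
the topic prevalences are treated as *planted* rates, so observed topic
prevalence is the planted rate × (1 − negation_rate).

Features of real data the generator does **not** emulate, and which a green
test therefore does not establish: within-patient evolution of indicators
(class and age are frozen per patient), realistic ICD-10 code strings
(pre-mapped indicators are emitted; the code→indicator map is exercised on
toy fixtures only), clinically plausible note prose, visit seasonality,
mortality or transfer of care, and any correlation between indicators beyond
what class membership induces.

Two structural facts about the stated world that the tests acknowledge
rather than hide:

* *Censoring bias.* The last drawn gap of each patient overshoots the study
  end, and short gaps overshoot less often, so naive LTFU prevalence among
  evaluable visits sits slightly below the class long-gap probability. The
  tests therefore check the labeler against the generator's per-visit
  intended status (exact on every evaluable visit) and check the intended
  rates over *all* visits against the long-gap probabilities (a clean
  binomial comparison).
* *Bayes ceiling.* On the documented 3-class benchmark (10 binary items,
  item probabilities 0.9/0.5/0.1, equal weights) the best possible
  assignment accuracy is 91.7% — computable in closed form from
  Binomial(10, p) tail sums — so the tests assert accuracy near that
  optimum, not above it.

## Numerical and reporting choices

* Odds ratios are cross-product ratios — identical to the single-predictor
  logistic MLE, which the tests verify against an iterative `glm` fit — with
  Wald intervals using `z = 1.959964` and log-scale SE `√(1/a+1/b+1/c+1/d)`.
  Zero cells are an error by default; an explicit Haldane `+0.5` switch is
  available and logged. One published value is knowingly not matched: the
  class-2 LTFU odds ratio recomputes to 1.56 from the printed counts while
  the source prints 1.57; the package reports the recomputed value.
* Pearson chi-squared uses no continuity correction (visit-level counts are
  large); Kruskal–Wallis applies the standard tie correction and returns
  `H = 0, p = 1` for all-identical data.
* All pipeline randomness flows from one top-level seed: the simulate stage
  uses it directly and the LCA stage uses `seed + 1000` (plus the class
  count per fitted `C`), keeping derived seeds far below 2³¹. Every pipeline
  output is MD5-hashed into a provenance manifest; determinism is tested by
  byte-identical reruns.

## Known limitations

Visit-level independence (no cluster-robust errors), a single imputation
policy (none — missing demographics are a hard error), an illustrative
default lexicon and diagnosis-code map, and a generator whose gap mixture is
a stand-in: nothing in the source characterizes real inter-visit gap
distributions, so the mixture is the minimal structure that produces
class-dependent LTFU, not an estimate of clinic behaviour.
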