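---
title: "Mining maternal morbidity profiles associated with in-hospital death"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining maternal morbidity profiles associated with in-hospital death}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`morbrules` implements a surveillance pipeline for maternal morbidity in
administrative hospital-claims data: claims are linked into episodes of
care, obstetric episodes of women of reproductive age are selected, every
recorded diagnosis is classified into a WHO-adapted scheme of twelve
morbidity groups, and association rules are mined that link morbidity-group
profiles to in-hospital death. This vignette is the package's own account of
the method: the model behind each stage, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the numerical
choices made where the design was open.

## The setting

In claims systems such as Brazil's SIH/SUS, one continuous hospitalization
may be billed as several claim records (AIHs): a claim discharged as a
*hospital stay* or an *interhospital transfer* is continued by a later
claim. Analysing claims as if they were hospitalizations would double-count
episodes and split diagnosis profiles, so the unit of analysis throughout
the package is the **episode of care**: a maximal chain of claims belonging
to one hospitalization.

In-hospital maternal death is rare — on the order of 3 per 10,000 obstetric
episodes — which rules out conventional frequent-pattern thresholds and
motivates the rare-rule configuration described below.

## Episode linkage

`link_episodes()` implements deterministic record linkage on the variables
available in deidentified claims: municipality of residence, patient date
of birth, and hospital code. Claims are blocked by (municipality, date of
birth), sorted by admission date, and chained greedily left to right. A
claim continues the episode of its predecessor when:

* the predecessor's discharge reason is `stay` or `transfer`;
* the gap between the predecessor's discharge and the claim's admission is
  0 or 1 days;
* for a `stay`, the hospital is unchanged (a `transfer` may change
  hospital).

Hospital code is a linkage variable, yet transfers must be allowed to cross
hospitals; enforcing hospital equality only for stay-continuations
preserves both requirements. Three further choices were genuinely open and
are fixed as follows:

* **Tie-breaking.** Claims with equal admission dates are ordered by
  discharge date, then claim id. Greedy chaining over a deterministic order
  makes the partition reproducible and invariant to input order (a tested
  property).
* **Negative gaps.** Overlapping stays (admission before the previous
  discharge) never chain; they are counted in the linkage log as
  data-quality findings rather than silently merged.
* **Chains through other discharge codes.** Only `stay`/`transfer`
  discharges continue an episode; a claim discharged `alive` followed by a
  same-day readmission starts a new episode.

The episode outcome is the discharge-reason class of the *last* claim, and
age is in completed calendar years at the episode's admission date.

## Cohort selection

`select_cohort()` keeps episodes that are obstetric (any ICD-10 chapter-XV
"O" diagnosis in any field of any claim, or an obstetric principal
procedure), with age 10–49 inclusive, and an outcome of discharged alive or
in-hospital death (episodes ending in transfer or other administrative
codes are not closed hospitalizations and are excluded). The three filters
commute and the selection is idempotent — both tested properties.

`confirm_deaths()` optionally cross-checks death-discharged episodes
against a mortality registry, removing deaths that cannot be matched. The
registry's matching keys are not standardised across systems; the package
matches on (date of birth, municipality) with the death date inside the
episode's stay extended one day past discharge to tolerate date-entry lag
(`grace_days`, configurable). The stage is off by default since arbitrary
inputs have no registry.

## Morbidity classification

Each ICD-10 code maps to one of 20 group/subgroup labels (twelve numbered
groups, some subdivided; there is no group 6, and group 13 "others" is the
residual). The shipped mapping is an adaptation of the WHO ICD-10 grouping
of maternal deaths to *morbidity* coding: codes that are causes of
hospitalization rather than death are folded into the corresponding groups,
whole non-obstetric chapters feed the non-obstetric complication subgroups
(respiratory, digestive, circulatory, anaemia, other), injury and
external-cause chapters form group 12, and R95–R99 form the unknown-cause
group.

Matching is by longest prefix on dot-less codes, with entries of one to
four characters: chapter letters cover whole-chapter groups (all of `J` is
respiratory), and longer entries override shorter ones (`O244` gestational
diabetes beats `O24` diabetes in pregnancy beats nothing; `E10`–`E14`
override chapter `E`). Codes matching no entry fall into group 13, so
classification is total — no diagnosis is ever dropped. The mapping ships
as a versioned CSV (`inst/extdata/morbidity_groups.csv`) and is
user-replaceable; no pipeline logic depends on a particular entry, which is
why the tests exercise classification through `classify_code()` rather than
against a fixed table.

An episode's **transaction** is the deduplicated set of group labels over
every diagnosis of every claim, plus exactly one outcome item (`DEATH` or
`ALIVE`). Classification is therefore independent of diagnosis order, claim
order, and repetition.

## Rule mining

The miner is a from-scratch level-wise Apriori over the transaction
database of `n` episodes. For a rule X → Y with antecedent itemset X and
outcome consequent Y:

* support(X→Y) = count(X ∪ Y) / n,
* confidence(X→Y) = count(X ∪ Y) / count(X),
* lift(X→Y) = confidence(X→Y) / support(Y).

Lift is 1 under independence; for a single-item antecedent it estimates the
risk ratio of death given the item (see the recovery analysis below).

Numerical and configuration choices:

* **Support floor.** Because death is rare, minimum support and confidence
  default to 1e-10. The fractional threshold is translated to the integer
  floor `max(1, ceiling(min_support * n))`, i.e. "observed at least once"
  at any realistic `n`; rarity is controlled downstream by the count
  filter, not by support.
* **Candidate generation.** Frequent (k−1)-itemsets sharing a (k−2)-prefix
  are joined and candidates are pruned unless every (k−1)-subset is
  frequent (anti-monotonicity, a tested invariant). Counting is done
  against the unique transaction profiles with multiplicity weights, which
  also lets very large databases stated as profile counts be represented
  without materialising every record.
* **Canonical order.** Itemsets are kept sorted by C-locale (radix) label
  order and result tables ordered by size then label, so output files are
  byte-reproducible.
* **Consequents.** Rules are generated only with an outcome item as
  consequent — the analysis surface is the discharge status, and
  restricting consequents avoids combinatorial blowup. Alive-consequent
  rules are generated and then removed by the lift filter (their lift is
  marginally below 1 whenever death-consequent lifts are above it). The
  empty-antecedent rule is not emitted; its lift is identically 1.
* **Zero-support consequents.** A configured consequent absent from the
  database would divide by zero; its rules are skipped with a warning.

Filtering, in order: lift ≥ 1.1; redundancy (a rule is redundant when a
same-consequent rule with a proper subset of its antecedent has confidence
at least as high — pruning is idempotent and validated against an
all-pairs oracle); count ≥ 4; and removal of rules whose antecedent
contains group 10 (childbirth), which marks the hospitalization type rather
than a morbidity. The order follows the narrative of the analysis it
reproduces; lift/count filters commute in any case, and each step's removal
count is logged.

## The synthetic-data generator

Real claims extracts cannot be bundled, so `generate_claims()` emulates the
structure the pipeline consumes, with known planted effects:

* one episode per synthetic patient (the unit of analysis is the episode;
  multi-episode patients are out of scope);
* morbidity items drawn independently per episode from per-item
  prevalences, with optional pairwise odds tilts for co-occurrence;
* in-hospital death with probability `baseline_death_prob` times the
  product of per-item relative risks, capped at 1. The multiplicative
  model is chosen deliberately: the lift of a single-item rule then
  estimates the planted risk ratio in closed form, giving an exact
  recovery target;
* episode splitting into chained claims with probability `transfer_prob`
  (default 0.011, so ≈98.9% of episodes are a single claim, matching the
  claims streams this emulates), intermediate discharge codes drawn from
  stay/transfer and admission gaps from {0, 1} days;
* every diagnosis is written as the representative ICD-10 code of its item,
  so the shipped mapping resolves it back exactly; the childbirth code is
  the principal diagnosis whenever group 10 is present, and every episode
  carries an obstetric procedure (the stream is an obstetric
  hospitalization stream by construction);
* claims are emitted in shuffled order so linkage cannot rely on input
  order, and the whole stream is reproducible from the seed.

Default prevalences put childbirth at 90% of episodes, direct obstetric
complications at the percent level and non-obstetric complications at the
per-mille level; the default death probability is 3e-4 per episode.

What the generator does **not** emulate: multiple episodes per woman,
seasonal or inter-annual structure, miscoded discharge reasons, diagnosis
codes outside the representative set, and coverage differences between
hospitals. Passing tests therefore demonstrate the correctness of the
pipeline's logic and the recoverability of planted effects under clean
conditions — not robustness to real-data coding noise.

## Planted-effect recovery: design of the experiments

For an item A with prevalence p, planted relative risk r and baseline death
probability b, the generator implies

* confidence(A→DEATH) = b·r,
* support(DEATH) = b·(1 + p(r − 1)),
* lift(A→DEATH) = r / (1 + p(r − 1)).

Two consequences drive the experiment design in the test suite:

1. **Attenuation.** Lift approaches r only when p(r − 1) is small; recovery
   experiments therefore plant the risk on a low-prevalence item (p = 0.01
   at r = 10 gives an expected lift of 9.17, an 8% attenuation inside the
   25% recovery band).
2. **Binomial error.** The standard error of the confidence estimate is
   governed by the number of deaths among carriers, ≈ n·p·b·r. At the
   surveillance baseline b = 3e-4 and n = 100,000 this is ~3 deaths —
   unmeasurable. Recovery experiments therefore raise the baseline to
   0.02–0.05 so that carriers contribute hundreds of deaths and the
   binomial error (≈5–7%) sits well inside the recovery band. The
   generator default stays at 3e-4; the elevated baseline is an explicit
   experiment configuration, not a default.

The null experiment plants no risk (r = 1 everywhere) on items at 10%
prevalence with b = 0.05, n = 100,000: each item's death rule then has lift
1 plus noise with SE ≈4.5%, and the lift ≥ 1.1 filter removes it in ≈98.6%
of replicates in expectation; the suite requires ≥95% over 20 replicates
and checks that the deviation from 1 shrinks between n = 10,000 and
n = 100,000.

## Problem sizes

The bundled experiments use 100,000 synthetic episodes for recovery and
null-filter replicates, 50,000 for the demo configuration, and 200,000
(with the death probability raised tenfold to 3e-3) for the narrative
analysis scripts under `analysis/` — a scaled-down emulation in which a few
hundred deaths make the planted group-level risk profile measurable, chosen
as a realistic desk-scale counterpart of a multi-million-episode national
extract. Oracle-equivalence tests run at ≤200 transactions over ≤12 items,
where exhaustive power-set enumeration is feasible.

## Known limitations

* The shipped morbidity mapping is an approximation assembled from the
  group definitions and the WHO structure, not a transcription of any
  specific national table; users with an authoritative table should supply
  it as CSV.
* Greedy chaining resolves ambiguous claim sequences (e.g. two admissions
  of the same patient block on the same day) deterministically, not
  probabilistically; pathological interleavings can split a true episode.
* Lift estimates for very rare profiles are noisy and the count ≥ 4 filter
  is a blunt guard; no confidence intervals are attached, matching the
  analysis surface this package reproduces.
* With consequents restricted to the discharge outcome, associations among
  morbidity groups themselves are visible only through the combination
  table, not as mined rules.
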