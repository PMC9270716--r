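---
title: "Methods: the case-based motivational-communication assessment engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the case-based motivational-communication assessment engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mccat)
library(dplyr)
```

## The assessment model

Motivational communication (MC) is a behaviour-change communication style
for health care providers, defined by 11 core competencies: 8 desirable
("positive") behaviours such as reflective listening, expressing empathy
and eliciting change-talk, and 3 undesirable ("negative") behaviours —
negatively judging or blaming, expressing hostility or impatience, and
being argumentative or confrontational. `mccat` implements the full
machinery of a computerized, rank-ordered multiple-choice assessment of
those competencies:

* a **case bank** of virtual-patient cases. A case is a sequence of 6–7
  conversational *exchanges*; in each exchange the provider chooses one of
  5 replies, ranked 1 (most MC-consistent) to 5 (least) and carrying
  consistency points +2, +1, 0, −1, −2. Replies are tagged with the
  competencies they demonstrate. Cases come in 4 *families* (A–D, one
  behavioural target each: physical inactivity, smoking, unhealthy diet,
  medication nonadherence), each family holding 4 structurally equivalent
  *variants*;
* randomized **assembly** of a four-case assessment form (one variant per
  family, case order and option order shuffled);
* the two-equation **scoring algorithm** (below);
* the **content-validation analytics** used when expert panels judge the
  bank's rank orders and competency tags;
* **reliability analytics**: Cronbach's alpha over the 25 item-rank slots
  and a parallel-form consistency ANOVA across a family's variants;
* a seeded **respondent simulator**, so every analysis in the package can
  be exercised end-to-end on synthetic data.

## The two scores

**Ranking score.** Each selection earns the points of its rank; the sum is
normalized by twice the number of exchanges and expressed as a percent:

$$
\text{ranking} \;=\; \frac{\sum_{r=1}^{5} c_r \, p_r}{2k}\times 100,
\qquad p = (+2,+1,0,-1,-2),
$$

where $c_r$ counts selections of rank $r$ and $k$ is the number of
exchanges (25 on a canonical form). The range is $[-100, 100]$; always
choosing rank 1 gives exactly 100.

**Global competency score.** For competency $c$, let $S_c$ be the number
of exchanges in which the respondent chose a reply tagged $c$, and $O_c$
the number of exchanges of the form offering $c$ at all (its
*opportunities*). Each positive competency contributes its selection ratio
times a weight proportional to its share of positive opportunities,

$$
w_c = 100\,\frac{O_c}{\sum_{c' \in \text{pos}} O_{c'}},\qquad
\text{contribution}_c = \frac{S_c}{O_c}\, w_c ,
$$

and the three negative competencies are pooled into a single block that is
subtracted:

$$
\text{global} = \sum_{c\,\in\,\text{pos}} \frac{S_c}{O_c} w_c
\;-\; \frac{\sum_{c\,\in\,\text{neg}} S_c}{\sum_{c\,\in\,\text{neg}} O_c}
\cdot 100\,\frac{\sum_{c\,\in\,\text{neg}} O_c}{\sum_{\text{all}} O_c}.
$$

Weighting by opportunity share mirrors how often each skill is actually
exercised in consultations: frequently usable skills carry more weight.
Three numerical consequences drove the design:

* the positive weights sum to 100, so a respondent who always selects
  every available positive tag and never a negative one scores exactly
  100 — the score has a hard ceiling;
* the score is additive over selections, so its exact theoretical minimum
  and maximum are found by optimizing each exchange independently
  (`theoretical_range()`); a brute-force enumeration oracle confirms this
  on small banks in the test suite;
* because the weights are proportional, the global score collapses
  algebraically to $100\,S^{+}/O^{+} - 100\,S^{-}/O_{\text{all}}$. The
  batch scorer (`score_cohort()`) uses this collapsed form for speed; the
  audit scorer (`score_competencies()`) evaluates the full per-competency
  sum, and the suite asserts the two paths agree to $10^{-12}$.

**Choices the published formulas leave open.** The printed form of the
ranking equation divides by a constant written "(50×100)"; read literally
it would confine scores to ±0.02%, which is inconsistent with scores
being reported on a 0–100 scale. We read it as ÷(2·25 exchanges), then
percent. Similarly, the per-competency "percentage of cases" factor is
read as the competency's share of opportunities, normalized over positive
competencies — the only reading we found under which the maximum is
exactly 100. The pooled negative block is weighted by the negative share
of *all* opportunities (not of negative opportunities only); that
convention is isolated in one internal function (`competency_weights()`)
so it can be swapped. A published theoretical minimum of −93.6 exists for
the original proprietary bank; it is not recomputable without that bank's
option-level content, so the package reports its own bank-specific exact
range instead (−33.3 to 100 for the canonical synthetic bank).

**Degenerate opportunity counts.** A competency can be absent from an
assembled form (providing-information-neutrally has only 2 opportunities
bank-wide). Its contribution is 0, it is flagged `assessed = FALSE`, and
the positive weights renormalize over the assessed competencies,
preserving the 100-point ceiling while avoiding division by zero.

## Opportunities and the census

An *opportunity* is an occasion to demonstrate a competency by selecting
a tagged reply. Counting can be done per tagged option or per exchange
offering the competency; the bank invariant that no competency tags two
options of the same exchange makes the two coincide, and that is also
what makes $S_c \le O_c$ and a perfect ratio of 1 attainable. The
canonical distribution (`canonical_opportunities()`) places 126
opportunities across 125 options in 25 exchanges — necessarily using
multi-tag options — with per-family totals 29/33/33/31 and per-competency
totals ranging from 2 to 24 (mean 11.45, sample SD 6.42).

## The synthetic fixture bank

The real case dialog is proprietary clinical content, so
`generate_fixture_bank()` builds a fully synthetic 16-case bank whose
*structure* reproduces the canonical design exactly: family exchange
counts 6/6/7/6, every variant structurally identical to its family's base
case, and per-case competency-opportunity counts matching the canonical
distribution. Texts are placeholder prose; charts are synthetic
demographics.

Tag placement is a design decision the canonical counts do not fix. The
generator places all positive tags of an exchange on its rank-1 option
and negative tags on rank-4/5 options (the schema itself allows positive
tags on ranks 1–3 and negative on 3–5). Rationale: rank order and tag
polarity then agree by construction — the most MC-consistent reply is the
one demonstrating the competencies, MC-inconsistent replies exhibit the
negative behaviours — the theoretical maximum of the bank is exactly 100,
and no rank-3 ("neither consistent nor inconsistent") option carries a
negative tag. The placement of *which* exchanges carry which competency is
randomized by the seed, subject to one-option-per-competency-per-exchange.

What the fixture does **not** emulate: real dialog semantics, within-case
difficulty drift, correlated tagging across exchanges, and any
respondent-by-content interaction. Tests passing on this bank validate
the engine's arithmetic and invariants, not the clinical content validity
of any particular case set.

## Assembly and reproducibility

`assemble_form()` seeds one RNG stream per form and draws in a fixed
order: variant per family (A→D, uniform), case presentation order, then
one option permutation per exchange. Identical `(bank, seed)` yields
identical forms, and the permutation is display-only — the suite checks
that scores are invariant to it. Uniformity of variant selection is
checked by Monte-Carlo (10,000 seeds, frequency 0.25 ± 0.02).

## Expert-panel validation analytics

Experts re-rank each exchange's five replies. A judgment is *good* at
deviation 0, *acceptable* at ±1, *poor* at ±2 or more (deviations beyond
the published ±2 definition are a fortiori poor). Percentages are
computed per option, pooled per exchange (the 25 "choice of response"
rows in which consensus tables are reported), then summarized as
unweighted per-case and overall means with sample SDs — reproducing the
published development-round table bundled as
`expert_agreement_rows()` to within the rounding of its inputs.

Competency-identification agreement has no published formula; we define
it as *recall* of the reference tag-set per expert and option, with
false-positive tags reported separately and unpenalized. The definition
lives in one function so an alternative (e.g. Jaccard) can be swapped in.
Decision rules: rank side — no modification iff good ≥ 70% and poor ≤
10%, or good+acceptable ≥ 90% and poor ≤ 10%; competency side — keep/add
at ≥ 70%, team discretion at 40–69%, delete at ≤ 30%. Identification
agreement strictly between 30% and 40% falls in a gap the published
criteria do not address; it is treated as delete and flagged
`gap_region`.

## Reliability analytics

**Cronbach's alpha** is computed from item *ranks* over the 25 slots
keyed by `(family, exchange_index)` — well-defined across respondents who
saw different variants precisely because variants are structurally
equivalent. The implementation uses the variance form
$\alpha = \tfrac{k}{k-1}(1 - \sum_i s_i^2 / s_T^2)$ with sample
variances; the tests cross-check it against an independent
covariance-matrix formula to $10^{-12}$, and degenerate (zero
total-variance) matrices report `NA` with a flag rather than 0. The
acceptance band .70–.95 is recorded on every report.

**Parallel-form consistency** is a one-way fixed-effects ANOVA of each
family's per-case scores across its 4 variants, per score type and
occasion (the published analysis reports exactly such cells; an
occasion-by-variant interaction is out of scope). Degenerate inputs are
resolved by convention: zero between-group sum of squares reports F = 0,
p = 1; positive between- with zero within-group variance reports F = ∞,
p = 0. Under a simulated null (structurally identical variants, common
skill) the test's type-I error at p < .05 is within 0.05 ± 0.02 over
1,000 replicate cohorts, and p-values are approximately uniform
(Kolmogorov–Smirnov distance < 0.05).

## The respondent simulator

`simulate_cohort()` draws each selection with probability proportional to
$\exp(\beta \cdot \text{points})$ — a softmax over the option's
MC-consistency points with a single nonnegative concentration parameter
$\beta$. $\beta = 0$ is uniform choice (expected ranking score 0, since
the points are symmetric about 0); $\beta \to \infty$ is deterministic
rank-1 choice (both scores 100). Utilities depend on points, not display
position, so the simulator is agnostic to option-order randomization.
Per-respondent heterogeneity is pluggable: pass a vector of skills or a
sampling function (e.g. a two-point mixture emulating pre/post-training
cohorts). Mean scores are strictly increasing in $\beta$ — checked
empirically over the grid $\beta \in \{0, 1, 3\}$ with 500 respondents
per level.

The simulator is deliberately content-free: it models *skill at
recognizing rank order*, not understanding of particular competencies, so
per-competency subscale differences between simulated cohorts carry no
meaning beyond their opportunity weights.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 10,000 seeds for assembly
uniformity; 1,000 randomized logs for scoring invariants; 1,000 replicate
cohorts of 24 respondents (the development study's sample size) for the
ANOVA type-I check; 2,000 uniform-choice respondents for the rank
histogram; and 3 × 500 respondents for skill recovery — sizes chosen so
each Monte-Carlo bound sits several standard errors from its threshold.
All internal arithmetic is double precision; printed scores are rounded
to one decimal only at display time. Comparisons against published
summary figures use a tolerance of 0.1 because the published per-row
inputs are themselves rounded to one decimal (their recomputed overall
mean, 61.276, prints as 61.3 — within 0.08 of the published 61.2).

## Worked example

```{r example}
bank <- generate_fixture_bank(seed = 1)
form <- assemble_form(bank, seed = 7)
log <- perfect_log(bank, form)
scores <- score_competencies(log, bank, form)
glance(scores)
tidy(scores)
theoretical_range(bank, form = form)
```

```{r cohort}
cohort <- simulate_cohort(bank, n = 24, beta = 1, occasions = 2, seed = 11)
rel <- consistency_report(cohort$logs, bank)
glance(rel)
head(tidy(rel))
```

## Known limitations

* The engine validates structure, not content: nothing here can assess
  whether a real case's dialog actually elicits the tagged competencies.
* The published student score tables and alpha values (.78/.80) depend on
  the proprietary bank and raw respondent data and are not recomputable
  here; the package instead verifies the *procedures* that produced them
  on synthetic data.
* Test–retest pairing across the two occasions is not modeled (occasions
  are simulated independently).
* The competency-identification agreement formula is a package choice
  (recall); published figures for that quantity may use a different,
  unstated definition.
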