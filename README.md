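# mccat

An assessment engine for scoring health-care-provider skill in
**motivational communication (MC)** — a behaviour-change communication
style built on 11 core competencies (8 desirable, e.g. reflective
listening, expressing empathy, eliciting change-talk; 3 undesirable, e.g.
negatively judging, expressing hostility, being argumentative). It is
aimed at researchers in health-professions assessment and psychometrics
who need a reproducible, automatically scored, case-based test of those
competencies, and at developers of such tools who need the surrounding
validation and reliability analytics.

The assessment presents a provider with 4 virtual-patient cases drawn at
random from a 16-case bank (4 families × 4 structurally equivalent
variants; one behavioural target per family: physical inactivity,
smoking, unhealthy diet, medication nonadherence). Each case is 6–7
conversational exchanges; in each exchange the provider picks one of 5
replies ranked 1 (most MC-consistent, +2 points) to 5 (least, −2
points), tagged with the competencies they demonstrate.

Two scores are computed per assessment. With $c_r$ the number of chosen
replies of rank $r$ and $k$ the number of exchanges:

$$\text{ranking score} = \frac{2c_1 + c_2 + 0c_3 - c_4 - 2c_5}{2k}\times 100$$

and, with $S_c$ / $O_c$ the selected / available opportunity counts for
competency $c$,

$$\text{global score} = \sum_{c\,\in\,\text{pos}} \frac{S_c}{O_c}\cdot
100\frac{O_c}{\sum_{\text{pos}} O}\;-\;
\frac{\sum_{\text{neg}} S_c}{\sum_{\text{neg}} O_c}\cdot
100\frac{\sum_{\text{neg}} O}{\sum_{\text{all}} O},$$

a weighted positive sum minus a pooled negative block, with a ceiling of
exactly 100. The package also implements the expert content-validation
analytics (good/acceptable/poor rank-agreement classification, consensus
summaries, modification decisions), reliability analytics (Cronbach's
alpha over item ranks, parallel-form consistency ANOVA across case
variants), a canonical synthetic fixture bank, a latent-skill respondent
simulator, and a small command-line tool.

## Worked example

```r
library(mccat)

bank <- generate_fixture_bank(seed = 1)   # canonical 16-case synthetic bank
bank
#> <mccat_bank> canonical synthetic fixture bank (version 1)
#>   cases:     16 (A, B, C, D)
#>   exchanges: 100
#>   options:   500

form <- assemble_form(bank, seed = 7)     # one randomized 4-case assessment
form
#> <mccat_form> form-7 (seed 7)
#>   cases (in order): C3, B3, A2, D4
#>   exchanges: 25

# an ideal respondent always picks the most MC-consistent reply
scores <- score_competencies(perfect_log(bank, form), bank, form)
scores
#> <mccat_scores> respondent ideal
#>   cases: C3, B3, A2, D4
#>   global competency score: 100.0
#>   ranking score:           100.0
#>   chosen ranks 1..5: 25 0 0 0 0

theoretical_range(bank)                   # exact achievable score range
#> # A tibble: 1 × 2
#>     min   max
#>   <dbl> <dbl>
#> 1 -33.3   100

# a simulated cohort of 24 respondents, two occasions, mid skill
cohort <- simulate_cohort(bank, n = 24, beta = 1, occasions = 2, seed = 11)
consistency_report(cohort$logs, bank)
#> <mccat_reliability>
#>   occasion 1: alpha = 0.23 over 25 items (24 respondents)
#>   occasion 2: alpha = 0.32 over 25 items (24 respondents)
#>   variant ANOVAs: 16 cells, 1 with p < .05
```

The global score of 100 reflects that the ideal respondent took every
positive-competency opportunity (each ratio $S_c/O_c = 1$, weights
summing to 100) and triggered no negative block; the ranking score of 100
is 25 rank-1 choices × 2 points over the 50-point maximum. The score
range shows this bank can punish a maximally MC-inconsistent respondent
down to −33.3. In the simulated cohort, the alpha values are low because
a *common* skill level leaves little between-respondent variance for the
items to agree on — heterogeneous-skill cohorts (`beta =` a vector or
sampling function) produce alphas inside the conventional .70–.95 band;
the near-absence of significant variant ANOVAs (1 cell of 16 at p < .05)
is the expected null behaviour for structurally identical variants.

Score reports, agreement reports and reliability reports all support
`tidy()`, `glance()` and `autoplot()`.

A command-line interface wrapping the same functions is installed at
`system.file("cli", "mccat", package = "mccat")`, with subcommands
`validate`, `census`, `fixture`, `assemble`, `score`, `simulate`,
`agreement`, `reliability`, `range`.

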