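---
title: "Constrained Bayesian model comparison for remember–know–new data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained Bayesian model comparison for remember–know–new data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rknbayes)
```

## The measurement problem

In a remember–know–new (RKN) recognition test, participants judge each test
item *old* or *new*, and subclassify *old* judgments as *remember* (conscious
recollection) or *know* (familiarity without recollection). A classic claim
for two distinct memory processes is a crossover: more remember responses for
studied words, more know responses for studied nonwords, with no lexicality
effect for unstudied lures. A rival single-process account treats
remember/know as two confidence criteria on one strength axis, and predicts
no lexicality effect anywhere once response bias is taken into account.

Remember and know response *rates* cannot be analysed as a factor: within a
condition they are negatively correlated by construction (every remember
response is one fewer know response), which is what makes the classic
ANOVA-with-response-as-factor analysis uninterpretable. `rknbayes` instead
models a single composite per participant $i$ and condition $j$, the scaled
difference

$$Y_{ij} = \frac{r_{ij} - k_{ij}}{r_{ij} + k_{ij} + n_{ij}},$$

where $r$, $k$, $n$ count remember, know and new responses, and conditions
are ordered old word, old nonword, new word, new nonword. $Y \in [-1, 1]$;
positive values mean a remember preference. The pipeline always computes
$Y$ from raw counts; the rounded-proportion entry path exists for checking
published summary tables, where recomputation can differ by one unit in the
second decimal because the printed inputs are themselves rounded.

## The competing models

Condition means are modelled as $Y_{ij} \sim \mathrm{N}(\mu_j, \sigma^2)$,
one observation per participant and condition with a common variance — a
deliberately spartan model (no participant random effect; see Limitations).
The registry encodes five accounts as constraints on
$\mu_1, \ldots, \mu_4$:

| model | constraints | reading |
|-------|-------------|---------|
| `M_u` | none | anything goes |
| `M_*` | $\mu_1 > \mu_2,\ \mu_3 = \mu_4$ | dual-process crossover pattern |
| `M_1` | $\mu_1 = \mu_2,\ \mu_3 = \mu_4$ | single-process criterion shift |
| `M_2` | $\mu_1 > \mu_2,\ \mu_3 > \mu_4$ | words promote remembering |
| `M_3` | $\mu_1 < \mu_2,\ \mu_3 < \mu_4$ | nonwords promote remembering |

## Priors and Bayes factors

The effect parametrisation follows the default-prior tradition for ANOVA
designs: a flat prior on the grand mean, the Jeffreys prior on $\sigma^2$,
and sum-to-zero condition effects with a joint $\mathrm{N}(0, g\sigma^2)$
prior, where $g$ carries the scaled inverse-chi-square prior implied by a
Cauchy distribution on standardized effects. The Cauchy scale defaults to
$\sqrt{2}/2 \approx 0.707$, the conventional default of this framework, and
is exposed as `g_prior(scale = )`. This construction makes every Bayes
factor invariant to location and scale changes of $Y$.

**Equality constraints** are implemented structurally, by collapsing design
columns so constrained conditions share one mean — not by point-mass priors.
For any equality structure the marginal likelihood integrates the grand
mean, effects and $\sigma^2$ analytically, leaving a one-dimensional
integral over $g$ evaluated by trapezoid quadrature on $\log g$: 401 nodes
spanning $10^{-6}$–$10^{6}$ relative to the squared prior scale. The
integrand is smooth with exponentially decaying tails, so trapezoid
quadrature on the log scale converges far faster than its textbook rate; in
tests the quadrature agrees with a dense two-dimensional $(g, \sigma^2)$
grid integrator to well below $10^{-3}$ log units. With all means collapsed
to one group the marginal is fully closed-form. Equality-only Bayes factors
therefore carry no Monte-Carlo error at all.

**Inequality constraints** use the encompassing approach: the Bayes factor
of an order-constrained model against its encompassing (equality-restricted
but order-free) model is the posterior probability that the constraints
hold divided by their prior probability. Under the symmetric effect prior
the means are exchangeable, so order constraints on disjoint pairs have
exact prior probability $(1/2)^m$ — $1/2$ for `M_*`, $1/4$ for `M_2` and
`M_3`; overlapping constraints fall back to prior Monte Carlo. Posterior
probabilities come from a Gibbs sampler over the fully conjugate
conditionals (means given $\sigma^2$ and $g$; $\sigma^2$; $g$), implemented
in compiled code and driven by R's RNG so runs are reproducible under
`set.seed`. An immediate consequence worth internalising: a pure-order
model can never beat `M_u` by more than the reciprocal of its prior
probability (2 or 4 here), because posterior probabilities cannot exceed 1.
The package asserts this bound on every run.

Default sampler settings are 4 chains of 20,000 iterations with 2,000
warm-up. The Monte-Carlo standard error of each log Bayes factor is
estimated by batch means on the constraint indicator (robust to the
autocorrelation of Gibbs draws), and split-$\hat R > 1.01$ triggers a
warning. If a posterior constraint probability is estimated as exactly
zero, the log Bayes factor is $-\infty$ with a flagged warning rather than
a silent value. Seeds are mandatory throughout the pipeline API.

```{r example, eval = FALSE}
trials <- generate_experiment("gardiner_java", participants = 53,
                              items = 30, seed = 1)
counts <- aggregate_counts(trials) |> exclude_below_chance()
Y <- scaled_difference_matrix(counts)
compare_models(Y, seed = 1)
```

## The legacy ANOVA

For comparability with the older literature, `rm_anova_2x2()` reproduces
the classic analysis: separate 2 × 2 within-subject ANOVAs
(item type × response type) on remember/know response frequencies, for old
items and for lures. Fitting goes through `stats::aov()` error strata; the
table reports Greenhouse–Geisser-corrected degrees of freedom — both factors
have two levels, so $\epsilon = 1$ exactly and the correction is the
identity, reported for completeness — and generalized eta squared
$\hat\eta^2_G = SS_e / (SS_e + SS_{subjects} + \sum SS_{error})$, the
recommended effect size for fully within designs. A `measure = "proportion"`
toggle exists because published descriptions of this analysis are ambiguous
between frequencies and proportions; frequencies are the default. The
implementation is validated against an independent hand-computed
sums-of-squares decomposition to $10^{-8}$ on $F$.

## What the synthetic generator emulates

`generate_experiment()` produces trial-level data with the structure the
analysis assumes: per participant, four conditions, a fixed number of items
per condition, and trinomial response counts. Its scientifically load-bearing
feature is **between-participant preference heterogeneity**: each participant
draws a single shift on the remember-vs-know log-odds, applied in every
condition (the new-response mass is untouched, and the remaining old-response
mass is renormalised). A shared shift induces the strong positive
cross-condition correlation of individual scaled differences that real RKN
data show, where some participants respond almost exclusively *remember* and
others almost exclusively *know*. The default heterogeneity SD of 1.5
log-odds units was fixed once on that qualitative ground: about 5% of
participants then sit beyond 20:1 odds, i.e. near-exclusive use of one
option, while accuracy (old/new) stays homogeneous — the observed
heterogeneity in this paradigm is response preference, not memory.

Because the logistic is nonlinear, averaging it over the preference
distribution shrinks every remember share towards one half; the generator
therefore calibrates a per-condition offset so the **condition-level mean**
proportions (and hence mean scaled differences) match the configured
baselines for any heterogeneity SD. Without this, a scenario built from a
published summary table would systematically miss that table's means.

Four named scenarios ship in `extdata/scenarios.yaml`: `gardiner_java` (the
original crossover pattern), `null_lexicality` (no lexicality effect),
`word_bias` and `nonword_bias` (a ±0.6 log-odds lexicality tilt of the null
baseline, matching the two ordered models). Scenario probabilities are taken
from printed, rounded tables and renormalised to the simplex at load; they
are approximate by construction.

The generator deliberately omits: item effects (the analysis model has
none), sequential or learning effects across test trials, accuracy
heterogeneity, and any generative dual-process cognitive model. Passing
recovery tests therefore show that the *statistical* machinery identifies
the data-generating mean pattern under realistic preference heterogeneity;
they say nothing about process-level claims, and real data may violate the
equal-variance and no-item-effect idealisations.

## Model recovery and problem sizes

`model_recovery()` closes the loop: simulate under each scenario, run the
full comparison, tabulate winners. The package's reference recovery study
uses 100 replicates per scenario at 50 participants and 25 items per
condition with a reduced sampler (2 chains of 5,000 iterations) — sizes
chosen so the whole study runs in minutes on one core while keeping the
Monte-Carlo error of each log Bayes factor near $10^{-2}$, an order of
magnitude below the log-Bayes-factor differences that decide winners at
these sample sizes. Under `null_lexicality` the single-process model `M_1`
wins well over half the replicates; under `gardiner_java` the crossover
model `M_*` wins a plurality, with both rates increasing in the number of
participants.

## Numerical and design choices

* **Prior scale notation.** Published descriptions of this default prior
  family sometimes typeset the scale ambiguously ("r = 2/2"); the package
  reads the conventional $\sqrt{2}/2$ and exposes the knob explicitly.
* **One $g$.** A single $g$ is shared by the (collapsed) effect vector, and
  each equality structure is parameterised by collapsing columns of one
  common design. Whether one instead re-derives an independent prior per
  structure is a genuinely open choice; the collapsed-column version is
  recorded here as this package's convention.
* **Sum-to-zero basis.** Effects live in an orthonormal basis of the
  sum-to-zero subspace; the isotropic prior makes the marginal likelihood
  invariant to the particular basis chosen.
* **Exclusion boundary.** Overall accuracy pools all trials (remember and
  know count as "old" answers); participants strictly below 50% are
  excluded, so a participant at exactly 50% is retained.
* **Degenerate inputs.** A participant–condition cell with no responses
  makes $Y$ undefined and is a hard error naming the cell; participants
  missing a whole condition are dropped with a warning (the mean-structure
  model needs a complete row); constant data make the marginal likelihood
  degenerate ($S = 0$) and non-finite values are rejected up front.
* **Ties.** $Y = 0$ exactly when $r = k$; no tie-breaking is ever needed
  downstream because the models constrain means, not individual values.

## Limitations

The observation model ignores the repeated-measures dependence beyond the
participant preference captured in $Y$ itself (no participant random effect
in the normal layer), exactly as in the analysis it implements; a
hierarchical extension is out of scope. The normal model for a bounded,
discrete-valued statistic is an approximation that degrades for very small
item counts. The ANOVA module covers only the 2 × 2 fully within design.
Bayes factors for order constraints inherit Monte-Carlo error from the
encompassing step; with extreme data the posterior constraint probability
can be estimated as zero, and more iterations are then the only remedy.
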