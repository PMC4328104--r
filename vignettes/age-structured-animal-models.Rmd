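---
title: "Age-structured animal models for cross-fostered pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-structured animal models for cross-fostered pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agemodel)
```

## The question and the model

Does the additive genetic variance expressed among offspring depend on
the age of their mother?  If older mothers transmit a depleted (or
different) sample of the population's alleles, the offspring of young
and old mothers form two "environments" in which heritable variation
can differ — formally a genotype-by-(maternal-)age interaction.

The estimation vehicle is the animal model: for record $i$ on
individual with pedigree position $q(i)$,

$$ y_i = \mathbf{x}_i'\beta + a_{q(i)} + o_{O(i)} + r_{R(i)} + q_{Q(i)} + e_i $$

with fixed effects (year, maternal age class, brood-size manipulation,
sex and/or a covariate such as body mass), iid random effects of
nest-of-origin $o$, nest-of-rearing $r$ and quartet $q$, and an
additive genetic effect $a$ whose covariance among individuals is
proportional to the numerator relationship matrix $A$ computed from
the pedigree.  To let the genetic variance depend on the *genetic*
mother's age class, $a$ carries a $2\times2$ age covariance matrix
$G$: the covariance between two records is
$G[g_i, g_j]\,A_{q(i)q(j)}$, where $g$ is the maternal age class
(young/old).  Four structures are supported:

* **iid** — a single $V_A$ ($G = V_A J$, $J$ the all-ones matrix);
* **group_r1** — $G = ss'$ with $s = (s_1, s_2)$, i.e. age-specific
  variances $V_{A1} = s_1^2$, $V_{A2} = s_2^2$ with the cross-age
  genetic correlation fixed at exactly 1 (the null hypothesis of a
  shared genetic basis);
* **group_unstructured** — $G = LL'$ with lower-triangular $L$ (free
  correlation $-1 \le r \le 1$);
* residuals iid or with age-specific variances (zero cross-class
  covariance, since no record belongs to both classes).

The same group machinery can be attached to the nest-of-rearing and
nest-of-origin terms (with correlation fixed at 1), which is how the
ladder distinguishes genuinely genetic age-heterogeneity from
age-dependent common-environment variance.

## REML engine

Estimation is restricted maximum likelihood on the dense covariance

$$ V(\theta) = \sum_k \left(G_k[g_i,g_j] \circ C_k\right) + R(\theta_E), \qquad
\ell_R = -\tfrac12\left[\log|V| + \log|X'V^{-1}X| + y'Py + (n-p)\log 2\pi\right] $$

where $C_k$ is the record-level kernel of term $k$ (the submatrix of
$A$, or a same-level indicator matrix) and $P$ is the REML projection.
Problem sizes here (a few hundred to ~1,100 records) make a dense
Cholesky of $V$ per evaluation cheap, so no sparse machinery is used.
Design choices that matter:

* **Parameterisation.** Variances and the rank-one scales $s$ are
  optimised on the log scale; the unstructured $G$ through its
  Cholesky entries.  Every iterate is therefore PSD by construction,
  and the $r = 1$ constraint is exact rather than penalised.
* **Gradients.** Analytic, via $\partial\ell_R/\partial\theta_k =
  -\tfrac12[\mathrm{tr}(P\,\partial V) - y'P\,\partial V\,Py]$, with
  the $2\times2$ structure of $\partial G$ exploited so each term
  costs one $O(n^2)$ pass.  The quasi-Newton optimiser (`L-BFGS-B`)
  uses these directly.
* **Multi-start.** Three starts by default: an equal split of the
  residual phenotypic variance across components plus two
  deterministically jittered variants; the best optimum is kept and
  then polished at a tight tolerance.  Determinism given the data is
  a design goal — no RNG is consumed during fitting.
* **Boundaries.** Variances are bounded below at $10^{-8}\,
  \mathrm{var}(y)$ during optimisation.  A component finishing below
  $10^{-5}\,\mathrm{var}(y)$ is treated as a boundary solution: it is
  snapped to exactly zero, the free parameters are re-optimised with
  it held there, and the component is reported as 0 with a boundary
  flag (standard errors are omitted for flagged components).  The
  snap is reverted if it costs more than $10^{-6}$ log-likelihood.
  This makes a model whose extra component vanishes reproduce the
  nested model's restricted likelihood exactly, so likelihood-ratio
  statistics are never spuriously negative.
* **Uncertainty.** The covariance of $\hat\theta$ comes from the
  observed information — central finite differences of the analytic
  gradient at the optimum — excluding boundary-pinned parameters,
  then mapped to the reporting scale (variances/covariances) by the
  delta method.

Likelihood *differences* are exact across models fitted to the same
records because the additive constant is fixed; absolute restricted
log-likelihoods are reported in the natural convention (the one lme4
uses), which need not match other software's internal constants.

## Inference layer

**Model ladders.** Each trait has a declared sequence of nested models
of increasing complexity — quartet, rearing, origin, additive,
age-structured additive, age-structured residual, and (for the immune
response) the unconstrained cross-age covariance and age-structured
nest effects — compared pairwise by likelihood-ratio tests.  Because a
variance tested against zero sits on the boundary of its parameter
space, the asymptotic null is a 50:50 mixture of $\chi^2_0$ and
$\chi^2_1$, whose p-value is exactly half the plain $\chi^2_1$
p-value.  Both conventions are always reported; the plain value is
the default because it is conservative.  One comparison in the immune
ladder (age-structured rearing *and* origin together) adds two
parameters; its degrees of freedom are computed from the actual
parameter-count difference.  The ladder's "selected" model follows a
forward rule at $\alpha = 0.05$; this is a convenience codification —
all comparisons are emitted and a user can apply any rule.

**Heritability.** $h^2_g = V_{A,g} / (V_{A,g} + V_O + V_R + V_Q +
V_{E,g})$ — the denominator is the sum of *all* estimated variance
components for the group, including the quartet variance even though
quartets are a design artifact; this matches the convention the
estimates are compared against.  Standard errors propagate the REML
covariance of the components through the ratio by a first-order delta
method; boundary-pinned components are treated as known constants.

**Wald tests.** Fixed-effect terms are tested by the chi-square Wald
statistic on their GLS coefficient block.  No denominator-degrees-of-
freedom adjustment is applied; with a few hundred records the test is
mildly anticonservative, which the test suite documents.  Fixed
effects are not part of this package's validation surface.

## What the generator emulates — and what it does not

`simulate_study()` produces complete studies with known truth:

* **Quartets.** Each quartet holds four brood-size- and date-matched
  nests, two with young (first-year) and two with old mothers.  The
  default design is 25 quartets of ~11-chick broods (~1,100
  experimental nestlings over three years); the immune-response
  analyses use 18 quartets of ~7 tested chicks (~500) over two years.
  Clutch sizes of experimental broods are a stated choice within the
  population's 6–17 egg range.
* **Split-brood cross-fostering.** Within each age-discordant nest
  pair, `floor(brood/2)` randomly chosen chicks swap rearing nests,
  so maternal age class of the genetic mother is balanced against the
  rearing environment by construction.
* **Brood-size manipulation.** Two nests per quartet (one per age
  class) receive three donor chicks from outside the quartets; donors
  exist in the pedigree but are excluded from the analysis table.
* **Breeding values.** The stacked $(a_{\mathrm{young}},
  a_{\mathrm{old}})$ vector is drawn from $N(0, G \otimes A)$ via
  Cholesky factors; a chick expresses the column matching its genetic
  mother's age class.  Phenotypes add iid origin/rearing/quartet
  effects, fixed effects, and an (optionally age-specific) residual.
  Covariate chains are simulated in dependency order (tarsus feeds
  the mass model, mass feeds the immune model) with independent
  genetic bases.
* **Recruitment.** Parents of later-year broods are recruits from
  earlier experimental broods where age and sex permit; each nestling
  enters the breeding pool with probability 0.2, the population's
  recruitment rate.  This is essential, not cosmetic: with unique
  founder parents only, the additive kernel among phenotyped chicks
  is exactly $\tfrac12 I + \tfrac12 M_{\mathrm{origin}}$, so $V_A$,
  $V_O$ and $V_E$ lie on an exactly flat likelihood ridge and the
  genetic variance is unidentifiable.  Cross-cohort links
  (parent–offspring, aunt–niece) break the ridge, exactly as
  recruitment does in the real population.
* **Extra-pair paternity.** `inject_extra_pair_paternity()` gives
  each nest, with probability 0.20, one chick whose *recorded* sire
  is replaced by another breeding male; true breeding values are
  untouched.  This reproduces field-realistic pedigree error (~3–4%
  of offspring) for the robustness experiment.

Not emulated: hatching-date phenology, survival or selection on
parents, assortative mating by age (absent in the source population),
immigration structure, repeated breeding by the same female, and
cross-trait genetic correlations.  Passing recovery tests on these
simulations therefore validates the estimator under the design's
assumptions; it cannot detect biases that arise from processes the
generator omits (e.g. selection-driven pedigree structure).

## Validation surface and problem sizes

The package validates itself by parameter recovery, using as
generating truth the fitted variance components reported for the blue
tit experiment this design emulates:

* 20 replicates of the 18-quartet immune-response design, fitted with
  the age-structured $r=1$ model: the mean $\hat V_{A,\mathrm{young}}$
  and $\hat V_{A,\mathrm{old}}$ are compared to the generating 0.06
  and 0.01 within twice their Monte-Carlo standard errors.  At this
  sample size the smaller old-mother variance carries a small
  downward finite-sample drift (of the order of 0.002, vanishing by
  ~50 quartets), which the tolerance may or may not absorb on a given
  seed sequence — the check is honest rather than tuned.
* 20 replicates of the 25-quartet design for tarsus and body mass,
  comparing mean $\hat h^2$ to the reference proportions (0.37,
  0.29).  Those references are rounded to two decimals — the exact
  ratios of the rounded components are 0.366 and 0.295 — so the
  comparisons include half a rounding unit.
* 50 paired refits (true vs corrupted pedigree) quantify the
  extra-pair-paternity bias of $h^2_{\mathrm{young}} -
  h^2_{\mathrm{old}}$; the mean relative bias must stay within 5% in
  magnitude and must not significantly inflate the difference.  The
  test suite runs this at a reduced 12-quartet scale; the acceptance
  script at the full 18-quartet scale.
* Property tests: the tabular-method $A$ agrees with a gene-dropping
  Monte-Carlo oracle; REML matches the closed-form balanced one-way
  oracle to $10^{-6}$ and lme4 on identity-kernel models to $10^{-4}$;
  ladders are monotone; the mixture p-value is exactly half the plain
  one; the age-heterogeneity test has at most nominal size under
  homogeneous truth.

## Known limitations

* Dense $O(n^3)$ algebra bounds practical problem sizes to a few
  thousand records — ample here, unsuitable for large pedigrees.
* The unstructured $G$ restricts $s$-scales to non-negative values on
  the rank-one path, so a cross-age correlation of exactly $-1$ is
  represented only through the Cholesky parameterisation.
* Wald tests are asymptotic (no Kenward–Roger-style small-sample
  correction).
* The forward selection rule is one possible codification; users
  comparing non-adjacent models should consult the full test table.
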