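---
title: "Modeling evasive response bias in randomized-response surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling evasive response bias in randomized-response surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrbias)
```

## The problem

Randomized response (RR) protects respondents to sensitive questions ("Have
you used anabolic steroids in the last 12 months?") by letting a randomizer
decide, with known probability, whether the recorded answer equals the true
answer. Individual answers are uninformative about the individual; the
population prevalence is recovered through the known misclassification
structure. In matrix notation the forward model is

$$\pi^* = P\,\pi,$$

where $\pi$ holds the true-category probabilities, $\pi^*$ the
observed-profile probabilities, and $P$ the transition matrix of conditional
probabilities $p_{r|t}$ of recording profile $r$ given true category $t$.
`rrbias` restricts to the symmetric design $p = p_{y|y} = p_{n|n}$, under
which Warner's design, the forced-response design and the unrelated-question
design all share the same $2\times2$ matrix

$$P_{2\times2} = \begin{pmatrix} p & q \\ q & p \end{pmatrix}, \qquad q = 1 - p .$$

Validation studies show RR does not fully remove evasive answering: a
fraction of respondents says "no" to everything, whatever the randomizer
demands. Those self-protective "no"-sayers bias prevalence estimates
downward. Correcting for them requires a spare degree of freedom, which a
saturated single-question design does not have. The package implements the
three designs that create one, and the models that spend it:

* **sub-samples design** — two groups with complementary randomization
  probabilities ($p$ and $q$); under adherence
  $\pi^*_{n|1} + \pi^*_{n|2} = 1$, and departures identify the evasive class;
* **multiple-questions design** — several sensitive attributes, with a
  log-linear constraint on the joint true distribution (independence for two
  questions, no three-way interaction for three) freeing the degree of
  freedom;
* **ever/last-year design** — two questions on the *same* attribute
  (lifetime and last 12 months). The true profile `ny` (never, yet last
  year) is impossible; this structural zero frees a degree of freedom
  without extra assumptions, and the design also estimates the last-year
  prevalence more efficiently than a lone last-year question.

Structural zeros are handled by *omitting columns*: parameter vectors always
live on the simplex of the admissible categories, never padded with
zero-probability columns.

## The models

Let $e$ denote the indicator of the all-"no" observed profile (one per
sub-sample block where applicable).

**Null model.** $\pi^* = P\pi$ over the adherent categories.

**Cheater-detection model (CDM).** Adds a latent category $c$ of respondents
who answer "no" irrespective of the randomizer and whose true status is
unknown: the transition matrix gains the column $e$, and
$\tau = (\tau_1,\dots,\tau_K,\tau_c)$ is a probability vector. The carrier
prevalence becomes an interval, $[\tau_y,\ \tau_y + \tau_c]$.

**SP-no model.** A mixture: with probability $\theta$ a respondent is a
self-protective no-sayer (profile forced to all-"no"), otherwise adherent,

$$\pi^* = (1-\theta)\,P\pi + \theta\,e .$$

The SP-no model and the CDM are reparameterizations of one another: with
$\tau_c = \theta$ and $\tau = (1-\theta)\pi$ they induce identical observed
distributions, so their maximized log-likelihoods, deviances and AICs
coincide, and `rr_cdm_to_spno()` / `rr_spno_to_cdm()` give the closed-form
parameter correspondences for the sub-samples design under the three
identifying assumptions about who the evasive respondents are (carriers and
non-carriers equally, only carriers, only non-carriers). The difference is
interpretive: the CDM reports interval estimates without assumptions about
the cheaters' true status; the SP-no model reports corrected point
estimates.

**SP(last-year) model.** Ever/last-year pairs admit a second bias
parameter: $\theta_{yy\to yn}$, the probability that a last-year carrier
whose randomized pair came out `yy` edits the last-year answer and reports
`yn`. Both parameters fold into the transition matrix (`rr_tm_sp_lastyear()`)
so that columns still sum to one. For several question blocks the package
builds the matrix as
$(1-\theta)\,\bigl(\bigotimes_b E_b(c)\bigr) + \theta\, e\,\mathbf 1'$,
where $E_b(c)$ is the per-block null matrix with the conditional edit
$c = \theta_{yy\to yn}/(1-\theta)$ moving $p^2$ of the `yy` column from the
`yy` to the `yn` row; for a single pair this reproduces the direct
definition entry by entry, and with two pairs the edit applies symmetrically
to both. A single pair cannot identify the model (it has only one degree of
freedom); at least one extra question is needed.

## Estimation

The fit maximizes the multinomial kernel
$\ell(\Phi \mid n) = n'\log \pi^*$ (per sub-sample block, a product
multinomial). Category probabilities are parameterized through the softmax
map with the first category as reference, which keeps them inside the
simplex while leaving the optimization unconstrained; under a log-linear
structure the softmax acts on the dummy-coded linear predictor, so the
log-linear parameters are estimated directly. The bias parameters are
estimated on their natural scale and are deliberately *not* transformed:
$\theta$ may go mildly negative (lower bound $-0.5$ by default, upper bound
1), because a boundary-free $\theta$ makes the detection test two-sided and
keeps standard errors meaningful near zero.

Numerical choices:

* **Optimizer.** PORT quasi-Newton (`nlminb`), relative tolerance
  $10^{-12}$, box bounds on the bias parameters only. BFGS as implemented in
  `optim` reproducibly stalls in the softmax-saturated region (it can walk a
  category weight to $e^{-100}$ where gradients vanish and terminate at a
  worse boundary point, even with an analytic gradient); PORT does not.
  Every fit in the test suite is cross-checked against an independent EM
  fixed-point iteration or an exhaustive simplex grid search.
* **Multi-start.** 20 seeded starts by default (configurable): one
  deterministic start at the uniform distribution with small positive bias
  parameters, the rest drawn from $N(0,1)$ effects and $U(0,0.3)$ bias
  values; the best objective wins, ties resolved by the lowest start index,
  followed by one polishing restart from the incumbent. Convergence is
  declared if the optimizer reports success, the (box-projected) gradient
  vanishes, or at least two starts agree on the optimum; fits near the
  boundary of the simplex otherwise warn.
* **Standard errors.** Delta method: the observed information on the
  working scale is computed by numerical differentiation (`pracma`),
  inverted, and propagated through the numerically differentiated map to
  the natural scale. Singular information (boundary solutions) is flagged
  and standard errors reported as unavailable rather than invented.
* **Goodness of fit.** $G^2 = 2\,n'\log(n/\hat n)$ with the convention
  $0\log 0 = 0$, referred to $\chi^2_{df}$ with $df$ = non-redundant cells
  (rows minus one per block) minus free parameters; $df = 0$ reports the
  statistic with an undefined p-value. Fitted frequencies reproduce block
  totals exactly.
* **AIC.** $2k - 2\ell$ with $k$ the number of free identified parameters
  (simplex dimension plus bias parameters). Only AIC *differences* and
  rankings are meaningful under any such counting convention, and only those
  are used or tested; absolute AIC values printed elsewhere for the same
  data may use a different constant.
* **Deviances near the boundary.** For sparse tables the null fit often has
  several categories estimated at zero. Reported deviances then depend
  delicately on convergence: evaluating $G^2$ at a slightly under-converged
  near-boundary solution can overstate it by several tenths. `rrbias`
  reports the deviance at the maximum-likelihood solution, verified against
  a multi-start EM on the equivalent mixture; for the nine-category null
  model of the second bundled survey this gives $G^2 = 9.00$ on 7 df, while
  evaluating the same statistic at previously circulated rounded estimates
  of that table gives 9.46.

## The simulator

`rr_simulate()` generates respondents one draw at a time with a documented
order (SP-no membership, true category, per-question evasion-then-randomizer
draws, last-year edits), so counts are bit-stable under a fixed seed, and
seeded calls restore the caller's RNG stream. SP-no membership is drawn
independently of the true category (the common-$\theta$ assumption) —
matching the fitted models exactly, so simulator expectations equal the
forward map (verified at $n = 10^6$) and simulation followed by fitting is
consistent.

**Item-specific evasion.** The sensitivity mechanism asks what happens when
one question (say, a newly added attribute) attracts *extra* evasion not
captured by the all-"no" class. Two mechanisms were considered. Editing the
*recorded* answer after randomization pushes that item's observed
"yes"-margin below $q$, the floor attainable at zero prevalence — outside
the model family — so the misfit spills into $\theta$ and the other
categories. Editing the *true* answer before randomization (an item carrier
responds to that question as a non-carrier would) is exactly equivalent to
reallocating true-category mass, and is therefore absorbed by the saturated
margin of the flagged item: its prevalence estimate shrinks by the factor
$(1-\text{evasion})$ while every other estimate, including $\theta$, stays
unbiased. The simulator implements the second mechanism, which is the one
that makes the sensitivity question well-posed; `rr_sensitivity_evasion()`
demonstrates the resulting pattern (verified in the test suite: flagged-item
prevalence underestimated, all other biases within Monte-Carlo error).

What the generator does *not* emulate: respondent covariates, panel
structure, per-category evasion probabilities drawn from the data, or
respondents who misunderstand instructions in ways other than all-"no"
evasion. Passing tests therefore show internal consistency of model,
estimator and simulator under the stated mechanisms — not that any real
survey satisfies them.

## Power analysis

`rr_power_grid()` estimates the Monte-Carlo power to detect
$\theta > 0$ for one ever/last-year pair, a pair plus a third dichotomous
question, and two pairs. True-category mass is $\pi_{never}$ on the
all-never category and $(1-\pi_{never})/k$ on each remaining category; all
questions use the same $p$ (default $5/6$). Decisions made where the
procedure was open:

* the detection test is the likelihood-ratio statistic
  $2(\ell_{\text{SP-no}} - \ell_{\text{null}})$ on 1 df at $\alpha = .05$,
  with negative $\hat\theta$ retained (two-sided); a Wald variant
  ($\hat\theta/\widehat{se}$) is available behind `test = "wald"`;
* 1,000 replicates per cell by default (rejection rates to about
  $\pm 1.5\%$); each cell runs on a sub-seed derived deterministically from
  the master seed, so cells are individually reproducible;
* per-replicate fits use two starts (the deterministic start plus one
  random), which the grid-search cross-checks show is sufficient for these
  small models; individual near-boundary replicates may report "singular
  convergence", which the drivers deliberately ignore since the
  likelihood-ratio statistic uses the best objective found.

Reference behaviour established by the test suite: the test holds its
nominal size at $\theta = 0$; power increases with $n$, $\theta$ and the
number of questions; under the most favorable condition studied
($\pi_{never} = .7$, $\theta = .2$) the two-pair design reaches 80% power
near $n = 200$, whereas a single pair needs roughly five times the sample.
`rr_efficiency_compare()` additionally shows the ever/last-year design
estimating the last-year prevalence with a smaller empirical standard error
than a single last-year question at matched $n$, and more power to detect
$\theta$ at $p = 2/3$ than at $p = 5/6$ (at the usual cost of less precise
prevalence estimates).

Problem sizes used in the shipped tests (grids of a few hundred to a
thousand replicates, samples of 200–2,000, one consistency check at
$n = 10^5$ and one at $10^6$) were chosen as the smallest sizes at which the
Monte-Carlo error bands above are decisive.

## The bundled surveys

`rr_study_fixture()` provides the observed profile frequencies of two Dutch
doping surveys, both with $p = 5/6$ for every question:

```{r fixtures}
rr_study_fixture("study1")
rr_study_fixture("study2")$counts
```

Study 1 (2,269 male gym users) asked an ever/last-year pair on anabolic
steroids and an ever question on SARMs; the collapsed variant
(`"study1_anabolics_collapsed"`) sums over the SARMs index in code, never by
retyping. Study 2 (1,050 elite athletes, 2014) asked two ever/last-year
pairs — anabolics and blood manipulations; two answer formats with identical
$p$ were pooled in the original analysis, and per-format counts are not
recoverable from the published table, so the fixture is pooled.

A worked analysis:

```{r study1}
s <- rr_study_fixture("study1_anabolics_collapsed")
rr_fit(s$design, s$counts, model = "null")
rr_fit(s$design, s$counts, model = "sp_no")
```

The null model estimates 4.3% former and 4.7% last-year users of anabolics
and fits well ($G^2_{(1)} = 1.22$); the SP-no correction estimates
$\hat\theta = .046$ (se $.041$), not significant for this pair alone. Adding
the SARMs question raises the evasion estimate to a significant 6.4%:

```{r study1-full}
s1 <- rr_study_fixture("study1")
rr_fit(s1$design, s1$counts, model = "sp_no", se = FALSE)
```

## Known limitations

* Only symmetric, complementary randomization probabilities are supported
  (the asymmetric general form is accepted for single $2\times2$ matrices);
  sub-samples with unequal $p$ and polytomous sensitive questions are out of
  scope, as is the crosswise family of designs, whose answer categories do
  not support all-"no" evasion modeling.
* Fully profile-specific SP-no probabilities $\theta_{t}$ are
  over-parameterized and rejected; only the identified constraints (common
  $\theta$; per-category $\theta_n/\theta_y$ for the sub-samples matrix; the
  last-year edit) are exposed.
* Ever/last-year designs with extra questions leave the joint adherent
  categories unrestricted — the degrees of freedom come from the structural
  zeros; the log-linear structures apply only to designs of separate single
  questions.
* Inference is maximum likelihood with delta-method standard errors
  throughout; no Bayesian posterior or bootstrap is provided, and no
  covariate regression structure.
* The all-"no" latent class is an assumption, not an observable; the
  sensitivity machinery quantifies robustness to one specific violation
  (item-specific evasion), not all of them.
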