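---
title: "Joint modelling of antenatal care and place of delivery: methods"
author: "bivmlogit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of antenatal care and place of delivery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Maternal health-care surveys record, for each woman, a pair of binary
outcomes that are strongly dependent: whether she attended the recommended
minimum of four antenatal-care (ANC) contacts, and whether she delivered in
a health facility rather than at home.  Women are sampled within
administrative zones, so observations are also clustered.  Analysing the
two outcomes with separate logistic regressions discards their dependence;
ignoring the nesting understates uncertainty and hides the zone-level share
of variation.  `bivmlogit` fits both features jointly: a bivariate logistic
regression whose association is a cell odds ratio, with a zone-level random
intercept, estimated by Laplace-approximated maximum likelihood.

## The model

For woman $i$ in zone $j$, let $Y_{1ij}$ indicate adequate ANC contact and
$Y_{2ij}$ facility delivery.  Conditional on the zone effect $u_j$, each
outcome has a marginal logistic regression

$$\operatorname{logit} p_{1ij} = x_{1ij}^\top\beta_1 + u_j, \qquad
  \operatorname{logit} p_{2ij} = x_{2ij}^\top\beta_2 + u_j, \qquad
  u_j \sim N(0, \sigma^2),$$

and the pair $(Y_{1ij}, Y_{2ij})$ follows the four-cell multinomial whose
cell probabilities $(p_{11}, p_{10}, p_{01}, p_{00})$ are the unique joint
distribution with margins $(p_{1ij}, p_{2ij})$ and cell odds ratio

$$\psi = \frac{p_{11}\,p_{00}}{p_{10}\,p_{01}}$$

— the Plackett (global odds-ratio) construction.  $\psi = 1$ is conditional
independence.  The log-likelihood of a unit is the log of the single cell
its outcome pair selects.

Three random-intercept structures are available:

* **shared** (default): one $u_j$ enters both predictors with a single
  $\sigma^2$.  This matches reporting a single intraclass correlation per
  model for the outcome pair, and is the most parsimonious way to give the
  two outcomes a common zone effect.
* **independent**: a pair $(u_{1j}, u_{2j})$ with separate variances.  With
  $\alpha = 0$ this factorises into two univariate logistic GLMMs, which the
  test suite exploits as an independent cross-check against `lme4::glmer`.
* **correlated**: the pair is bivariate normal with correlation $\rho$.

The association is parameterised as $\alpha = \log\psi$, intercept-only by
default (one association odds ratio for the whole table, matching how such
analyses report a single crude and a single adjusted association OR).  A
covariate-dependent $\alpha$ is deliberately not fitted: the data needed to
identify it well are rarely available at this design size, and the
reported quantity of interest is the scalar OR.

The random effects enter the *conditional* (marginal-per-outcome)
logits, and the joint cell is built from those conditional margins.  The
alternative — building the joint cell on the population-averaged scale —
is not used; consequently the crude odds ratio of a simulated table
exceeds $\exp(\alpha)$, because marginalising over a shared random
intercept adds association (the generator tests quantify this against a
large-sample brute-force oracle).

## Inverting the odds ratio: numerics

Given $(p_1, p_2, \psi)$, $p_{11}$ solves the quadratic
$(\psi-1)p_{11}^2 - a\,p_{11} + \psi p_1 p_2 = 0$ with
$a = 1 + (p_1+p_2)(\psi-1)$, taking the root inside the Fréchet bounds
$[\max(0, p_1+p_2-1), \min(p_1, p_2)]$.  The classical "$-$" root
$(a - \sqrt{a^2 - 4\psi(\psi-1)p_1p_2})/(2(\psi-1))$ cancels
catastrophically wherever the two terms are close — not only near
$\psi = 1$.  `plackett_cells()` therefore uses the algebraically
equivalent rationalised root

$$p_{11} = \frac{2\psi p_1 p_2}{a + \sqrt{a^2 - 4\psi(\psi-1)p_1p_2}}$$

wherever $a > 0$ (it is exact through $\psi = 1$), and the classical form
only where $a \le 0$, where that form is the cancellation-free one.  Below
$|\psi - 1| < 10^{-6}$ the dedicated limit-stable branch
(`cells_near_independence()`) is used on both sides of 1, and the two
branches agree to $10^{-12}$ at the threshold.  A bisection fallback on
the defining equation guards the (never observed in testing) case of a
root landing outside the Fréchet interval.  The round-trip
`cell_odds_ratio(plackett_cells(p1, p2, psi))` returns $\psi$ to
$10^{-10}$ over a grid spanning $\psi \in [0.01, 100]$.

## Estimation

The marginal likelihood integrates the zone effects out.  Per cluster the
integrand mode $\hat u_j$ is found by damped Newton iteration (analytic
first derivative through the Plackett inversion; curvature by central
differences of that gradient; per-cluster step halving; tolerance
$10^{-10}$ on the gradient, at most 100 iterations), and

$$\log \int e^{h_j(u)}\,du \approx h_j(\hat u_j) + \tfrac{d}{2}\log 2\pi
  - \tfrac12 \log\det(-H_j(\hat u_j)).$$

When $\sigma = 0$ the integral is degenerate and the fixed-effect
log-likelihood is returned exactly.  Adaptive Gauss–Hermite quadrature
(`agq_marginal_loglik()`, nodes recentred at $\hat u_j$ and rescaled by the
curvature; tensor grid for two-dimensional structures) is provided purely
as a numerical cross-check: one node reproduces the Laplace value
identically, and 15- versus 25-node values agree to $10^{-6}$ on the test
fixtures.

The outer maximisation is BFGS (`stats::optim`) on the unconstrained
parameterisation $(\beta_1, \beta_2, \alpha, \log\sigma\,[,\operatorname{atanh}\rho])$,
relative tolerance $10^{-8}$.  Starting values are deterministic and
documented: separate logistic fits for the $\beta$s (`stats::glm.fit`), the
crude $2\times2$ log odds ratio for $\alpha$ (Haldane–Anscombe 0.5
correction if a cell is empty), and for $\sigma$ a between-cluster moment
guess — the variance of cluster-level empirical logits minus its binomial
sampling part, replaced by 0.25 when degenerate.  Standard errors come from
the inverse of a finite-difference Hessian of the marginal log-likelihood
at the optimum (`stats::optimHess`); Wald z tests with significance at
0.05; derived quantities (ICC, association OR) get delta-method intervals.
A non-positive-definite observed information leaves estimates in place and
flags the SEs unavailable.

Sampling weights, when enabled (`weighted = TRUE`), multiply each unit's
log-likelihood term (pseudo-likelihood); the random-effect prior term is
unweighted.  Fitting is unweighted by default because the provenance of
published model tables with respect to weighting is typically unstated;
descriptive tables are always weighted.

## Intraclass correlation and information criteria

On the latent-logistic scale the unit-level residual variance is
$\pi^2/3 = 3.2899$ (conventionally displayed as 3.29), so

$$\mathrm{ICC} = \frac{\sigma^2}{\sigma^2 + \pi^2/3}.$$

$\mathrm{ICC}(\pi^2/3) = 0.5$ exactly, and inverting at 0.42 gives
$\sigma^2 = 2.382$.  `information_criteria()` uses
$\mathrm{AIC} = -2\ell + 2p$ and $\mathrm{BIC} = -2\ell + p\log n$ with
$n$ = the number of clusters by default — the level-2 unit count, the
convention of the mixed-model software family this model class comes from;
`bic_n = "units"` switches to the observation count.  The model ladder
(`model_ladder()`) fits null, individual-covariate, community-covariate and
full models and flags the AIC/BIC minimisers.

## The synthetic survey generator

`default_emdhs_config()` emulates the analyzable shape of a national
mini-DHS: 68 zones, negative-binomial zone sizes (mean 57.7, dispersion 8,
truncated below at 5, so the expected total is about 3,926 women),
covariates drawn independently per woman from survey-like marginals
(education 51/36/9/4%, wealth 42/19/39%, media exposure 64/36%), one
community covariate (residence, 26% urban) constant within zone, a shared
zone effect with $\sigma^2 = 2.38$ (null ICC 0.42) and
$\alpha = \log 6.381$.  True coefficients are a sparse subset of
survey-scale effects (education up, rich up, rural down) rather than a
full 30-term table, keeping recovery experiments identifiable at desk
scale; the intercepts ($-0.723$, $-0.099$) were solved once so that the
population-average prevalences match the observed 43% (adequate ANC) and
52.5% (facility delivery).  Outcomes are sampled by one uniform draw per
woman against the cumulative joint cells; everything is reproducible from
a single seed (`withr::with_seed`, no global state).

What the generator does **not** emulate: the two-stage EA/household
sampling design and its weights (weights default to 1; a lognormal jitter
rule exists to exercise the weighted descriptives), covariate–covariate
correlation (a survey's education and wealth are correlated; here they are
independent unless configured), zone-varying covariate distributions, and
any spatial structure between zones.  Passing recovery tests therefore
demonstrates correctness of the estimator under the model, not robustness
to design features real surveys add.

Because individual covariates are iid across zones, adjusting for them
cannot explain zone-level variance — but, by the non-collapsibility of the
logistic link, it *inflates* the conditional $\sigma^2$.  The published
ladder pattern (null ICC 0.42 falling to 0.29 in the full model) arises
when observed community covariates carry a real share of the between-zone
variance.  `ladder_config()` encodes exactly that condition: residual zone
variance 1.34 (ICC 0.29) plus a rural-residence effect of $-2.33$ on both
predictors, contributing $0.26 \times 0.74 \times 2.33^2 = 1.04$ of
explained zone variance, so a null model sees about 2.38 again (ICC 0.42).
The ladder validation experiments use this configuration.

## Validation experiments and problem sizes

The test suite validates each layer against an independent oracle: the
published $2\times2$ worked example recomputed from its printed counts
(OR 5.435, Woolf 95% CI 4.72–6.25); hand-computed chi-square values;
a 10,001-point trapezoid integration oracle for the Laplace approximation
(2% relative tolerance on small fixtures); a hand-written IRLS oracle for
the $(\psi = 1, \sigma = 0)$ reduction (coefficients to $10^{-4}$);
`lme4::glmer` for the factorising independent-structure case; and a
$10^6$-unit brute-force simulation (with bisection-solved cells) for the
generator's crude odds ratio.  The parameter-recovery experiment runs 20
seeded replicates at 68 zones with mean 30 women per zone — the package's
chosen desk-scale experiment size — and checks that $\alpha$ and
$\log\sigma^2$ have mean bias within 3 Monte-Carlo SEs of zero with at
least 80% Wald CI coverage.  The ladder experiment averages the null-minus-
full ICC difference over 10 seeds at 68 zones × mean 20 women.

## Known limitations

* Chi-square tests on weighted cross-tabs are design-naive (no Rao–Scott
  correction), and no survey-design variance estimation is provided.
* The Laplace approximation is known to shrink variance components
  slightly for binary data with small clusters; the AGQ cross-check
  quantifies this on fixtures, but fitting itself always uses Laplace.
* Missing covariate values are excluded from fitting (complete-case within
  the requested design) and shown as an explicit `"missing"` level in
  descriptives; no imputation.
* The association is a single global odds ratio; covariate-dependent
  association and three-level nesting are out of scope.
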