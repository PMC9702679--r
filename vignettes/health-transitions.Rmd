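---
title: "Modelling health transitions in ageing cohorts with panelmsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling health transitions in ageing cohorts with panelmsm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`panelmsm` implements a continuous-time, time-homogeneous Markov model on
three health states — good self-perceived health (1), poor self-perceived
health (2), and death (3) — for panel data from ageing surveys such as
SHARE. Four instantaneous transitions are allowed: deterioration
(1&rarr;2), recovery (2&rarr;1), and death from either live state
(1&rarr;3, 2&rarr;3). Death is absorbing. The generator matrix is

$$Q(z) = \begin{pmatrix} -(q_{12}+q_{13}) & q_{12} & q_{13} \\
q_{21} & -(q_{21}+q_{23}) & q_{23} \\ 0 & 0 & 0 \end{pmatrix},
\qquad q_{ih}(z) = q_{ih}^{(0)} \exp(\beta_{ih}^\top z),$$

where $z$ is a vector of dummy indicators for education (low, medium;
reference high), birth cohort (1920–1939, 1940–1949; reference 1950–1962)
and country group (Northern, Southern, Eastern; reference Central).
Gender is handled by stratification: women and men are fitted as two
independent models with the same structure, so every intensity and every
hazard ratio is gender-specific. That gives $4 + 4\times 7 = 32$ free
parameters per stratum. Under time-homogeneity the interval transition
probabilities are $P(t) = \exp(tQ)$.

The proportional (log-linear) form of the covariate effect is the standard
multistate convention: it guarantees positive intensities for any
coefficient value and makes $\exp(\beta)$ interpretable as a hazard ratio
on the transition in question. Time-homogeneity is an assumption, not a
fact about ageing; the cohort indicators absorb the dominant age trend by
construction (older cohorts are older at every observation time), which is
also why the model contains no separate age term. Predicted probabilities
for each of the 36 covariate profiles are invariant to the choice of
reference levels; coefficient tables are not, so the references above
(highest education, youngest cohort, largest country group) were fixed
once for interpretability and good baseline estimation.

## The likelihood for interval-censored panel data

Live states are observed only at interview dates $t_{ij}$; what happened
between interviews is unknown. The Markov property factorises each
subject's contribution over consecutive observation pairs:

$$L_i = \prod_j \Pr\!\left(S(t_{i,j+1}) \mid S(t_{ij})\right),$$

where a pair with both endpoints alive contributes the matrix-exponential
entry $P(\Delta t)[s_j, s_{j+1}]$. Death is different: its date is known
exactly (from end-of-life interviews and registers), so a terminal death
observation contributes a *density*, not an interval probability —
survival in some live state $h$ up to the death instant times the
instantaneous death intensity from $h$:

$$\sum_{h \in \{1,2\}} P(\Delta t)[s_j, h]\; q_{h3}.$$

A configuration switch (`fit_config(exact_death = FALSE)`) treats deaths
as ordinary interval-censored observations instead, which is appropriate
when only a between-waves death indicator, not a date, is available.
Log-likelihoods are accumulated as sums of logs throughout; a
zero-probability contribution yields `-Inf`, which the optimizer handles
as a rejected region (internally capped to keep finite-difference
gradients defined).

## Numerical choices

**Transition probabilities.** Because death is absorbing, only the
$2\times 2$ live-state block $A$ of $Q$ evolves, and its eigenvalues are
always real (the discriminant $(q_{12}{+}q_{13}{-}q_{21}{-}q_{23})^2 +
4q_{12}q_{21}$ is non-negative). `transition_probability_matrix()`
therefore uses the exact spectral closed form of $\exp(tA)$, with the
coincident-eigenvalue limit $e^{\lambda t}(I + t(A - \lambda I))$ used
below a discriminant of $10^{-18}$; the death column is the
row-stochastic complement. This is exact, and vectorises over interval
lengths — the property the likelihood exploits by grouping all observation
pairs by covariate profile (36 groups) and evaluating each group's
intervals in one vectorised call. The test suite checks this path against
two independent oracles: Padé scaling-and-squaring (`Matrix::expm`) to
$10^{-12}$ and integration of the Kolmogorov forward equations
(`deSolve`) to $10^{-8}$.

**Optimization.** Estimation maximises the log-likelihood over the
unconstrained scale (log baselines, raw coefficients) with BFGS (at most
500 iterations, relative tolerance $10^{-10}$) started from crude rates —
observed transition counts divided by exposure time in the starting state,
with a floor of $10^{-3}$/year for transitions never observed, whose
baselines are then held fixed rather than estimated (avoiding $-\infty$
drift). BFGS is followed by up to two Newton steps using the
central-difference Hessian (relative step $10^{-4}$), which drives the
score to its numerical floor; the same Hessian provides the covariance
matrix, with a pseudo-inverse fallback and a warning when it is
ill-conditioned. The convergence flag requires the max-norm of the score
to fall below $10^{-6} \max(1, |\ell|)$ — a relative criterion, because
with $|\ell| \sim 10^4$ the central-difference score itself carries
round-off noise near $10^{-6}$; in practice the Newton polish reaches
an absolute score norm around $10^{-7}$. Design columns with no variation
in a dataset are detected and their coefficients held at zero (they are
unidentifiable), which also makes single-profile datasets reduce exactly
to a four-parameter baseline fit.

**Confidence intervals for predictions.** The matrix exponential makes
delta-method gradients messy, so intervals for predicted probabilities
are simulation-based: $B = 1000$ draws from the asymptotic normal of the
parameter vector (eigendecomposition square root, clipping the tiny
negative eigenvalues a numerical Hessian can produce), percentiles
2.5/97.5 of each probability entry. Draws implying an intensity beyond
$e^{300}$/year for any profile would overflow downstream arithmetic and
are redrawn and counted. Point estimates never depend on the CI seed.
The default prediction interval is $t = 2$ years, the modal wave gap.

## What the synthetic generator emulates

Fitting the real survey requires registration-restricted data, so the
package ships a generator that reproduces the *structure* of that panel
with known truth:

* seven waves at 2004, 2007, 2009, 2011, 2013, 2015, 2017 (a three-year
  gap after wave 1, two-year gaps after);
* interview dates jittered uniformly by ±0.3 years around the wave year
  (fieldwork is spread within a year); the first interview anchors each
  subject's clock, so observed gaps are schedule gaps ± jitter;
* a 10% chance of skipping any scheduled wave (discontinuous
  participation) and 12% per-wave permanent attrition — together these
  give ≈3.7–3.8 observations per retained subject, matching the published
  average participation (3.76 women, 3.69 men);
* covariate composition drawn from the published sample margins
  (education ≈ 28.8/53.1/18.1% for women, 23.4/53.7/22.9% for men;
  cohorts ≈ a third each; country groups ≈ 42/12/22/24%), treated as
  independent margins because the joint distribution is not published;
* Eastern countries absent from wave 1 (entry at wave 2), entry deferred
  until a subject passes the lower age bound of 50;
* initial poor-health prevalence per profile with the published wave-1
  ordering (Northern lowest, Southern/Eastern highest), scaled by
  education and cohort;
* death dates generated exactly and reported only if the subject had at
  least one interview, was not already lost to attrition, and died within
  the study window.

True parameters default to values encoding the gradients the study
design expects to detect — deterioration and mortality hazard ratios
above 1 for low education, older cohorts and Eastern countries, recovery
ratios below 1 for the same groups — with 2-year deterioration
probabilities in a plausible range (≈0.14 for the reference female
profile, up to ≈0.45 for the most disadvantaged). These values are a
calibration of plausibility, not estimates of the restricted data.

What the generator does **not** emulate: measurement error in the
five-category response scale (states are read off the latent path
exactly), institutionalization, state-dependent attrition, within-group
country heterogeneity, and any covariate×country interaction. Passing
recovery tests therefore shows the estimator is correct for the model it
assumes — interval censoring, irregular schedules and exact deaths
included — not that the model is correct for any particular survey.

## Verification strategy and problem sizes

The package is verified at three levels, all run by the test suite:

1. **Oracles** for the probability machinery: closed two-state forms,
   `Matrix::expm`, forward-ODE integration, and the derivative identity
   between the exact-death density and the cumulative death probability.
2. **Monte-Carlo equivalence** of the trajectory simulator: empirical
   state frequencies of $10^5$ simulated paths match $\exp(tQ)$ within
   three binomial standard errors.
3. **End-to-end parameter recovery** at the study scale: cohorts of
   4000 subjects per stratum, refit over 10 replicates (alternating
   genders), pooling Wald-interval coverage across the 32 parameters —
   expected in the 90–99% band — and requiring each log hazard ratio's
   bias to sit within 3.5 Monte-Carlo standard errors of zero. Ten
   replicates keep the default suite to a few minutes; per-parameter
   coverage rates need more replication, for which
   `analysis/05_recover.R` runs the 50-replicate version.

## Known limitations

* Time-homogeneity: intensities do not depend on age or calendar time
  within a stratum; the cohort effect is a coarse surrogate.
* No misclassification layer: self-reports are taken at face value (a
  hidden-Markov extension would be the natural next step).
* The covariance of the estimates is the inverse observed-information
  approximation; with very sparse transitions (small samples) it can be
  ill-conditioned, which the fit reports rather than hides.
* Initial-state prevalence is conditioned on, not modelled: the
  likelihood starts at each subject's first interview.
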