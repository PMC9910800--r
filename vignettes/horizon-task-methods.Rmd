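---
title: "Modelling strategic exploration in the horizon task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling strategic exploration in the horizon task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(horizontask)
```

## The task and what the package models

The horizon task is a sequential two-option choice task used to dissociate
strategic exploration from simple decision noise. On every trial two reward
sources sit on the left and right of a screen. Each source pays an integer
number of juice drops between 0 and 10, drawn from a Gaussian with SD 1.5
around a per-trial true mean that lies between 3 and 7 drops; the two
options' means always differ. Before the first active choice the subject
passively receives four informative observations split 2/2 or 3/1 between
the sides (at least one per side), with exactly half of a session's trials
carrying the equal split. The *horizon* — how many choices remain — is
blocked in runs of five trials and alternates between short (1 choice) and
long (4 choices). After each active choice the subject either sees only the
chosen option's outcome (*partial feedback*) or both outcomes (*complete
feedback*, the unchosen one being counterfactual); the feedback regime is
fixed within a session.

Information gathered early in a long-horizon trial can improve later
choices, so an agent that explores *strategically* should tolerate lower
immediate expected value exactly when the horizon is long and choosing is
the only way to obtain information (partial feedback). The package provides
the four computational stages needed to quantify this: a task and agent
simulator, an ideal Bayesian observer, regression design builders for two
logistic choice models, and a hierarchical Bayesian fitting layer with
posterior-count inference, plus descriptive behavioural statistics.

## The ideal Bayesian observer

The observer treats each option's outcomes as i.i.d. draws from a
discretised Gaussian with known SD $\sigma$ (default 1.5 drops) and unknown
mean $\mu$ on a grid. For a candidate mean $\mu_j$ the likelihood of an
outcome $x$ on the integer support $\{0,\dots,10\}$ is the Gaussian kernel
evaluated at the support and normalised over it, so $\sum_x P(x\mid\mu_j)=1$
exactly. Given observations $x_1,\dots,x_n$,

$$P(\mu_j \mid x_{1:n}) \propto P(\mu_j)\prod_{i=1}^n P(x_i \mid \mu_j),
\qquad
P(x_{n+1} \mid x_{1:n}) = \sum_j P(x_{n+1}\mid\mu_j)\,P(\mu_j \mid x_{1:n}).$$

The option's *expected value* (EV) is the mean of this posterior predictive
and its *uncertainty* (U) is the predictive variance, in drops and drops²
respectively.

Numerical and design choices:

* **Mean grid.** Default $\mu_j \in \{0, 0.05, \dots, 10\}$. The grid spans
  the whole outcome range rather than the generative mean range because the
  observer only sees what is displayed and is not told where true means can
  fall; both bounds and step are configurable.
* **Prior.** Uniform over the grid. With a uniform prior the posterior is
  exactly the normalised likelihood product, which is also what one obtains
  when the prior cancels between numerator and denominator.
* **Likelihood discretisation.** The kernel is evaluated at the integer
  support and renormalised per candidate mean, rather than integrating
  bins; at $\sigma = 1.5$ the difference is second order and the choice
  gives exact normalisation by construction.
* **EV as the predictive mean.** For a symmetric predictive the mean and
  the mode coincide up to discretisation; the mean is used throughout
  because it is well defined for every observation set.
* **Log space.** Posteriors are accumulated as log-likelihood sums with a
  max-subtraction renormalisation. The test suite checks this
  implementation against a naive direct-enumeration oracle (no log space)
  to 1e-8 on random observation sets, and normalisation of posterior and
  predictive vectors to 1e-10.
* **Conjugate limit.** On a dense grid the predictive variance after $n$
  observations tracks the conjugate Gaussian closed form
  $\sigma^2(1 + 1/n)$; the bounded integer support shifts it by under 5%
  at $\sigma = 1.5$, a deviation the enumeration oracle quantifies exactly.

Three belief *streams* are maintained per trial: **baseline** (observation
phase only), **chosen** (baseline plus outcomes of one's own choices so
far) and **full** (chosen plus counterfactual outcomes; identical to
chosen under partial feedback). Beliefs used at choice $k$ never include
feedback from choice $k$ itself.

## The two choice models

**First choices** (choice 1 of every trial, both horizons) are modelled as

$$P(\text{right}) = \sigma\!\big(b_{SB} + b_{RB}\,RB + b_{hor}\,h +
b_{EV}\,\Delta EV + b_{U}\,\Delta U + b_{EV\times h}\,\Delta EV\,h +
b_{U\times h}\,\Delta U\,h\big)$$

with all differences right minus left, horizon coded $h=+1$ (short) /
$-1$ (long), and $RB \in \{+1,-1,0\}$ the side of the previous completed
trial's last choice (0 at the start of a session). A variant replaces the
uncertainty difference with the difference in the *number* of informative
observations, which carries the same information on first choices. Under
this coding, the short-minus-long difference in EV reliance is twice the
$b_{EV\times h}$ coefficient.

**Subsequent choices** (choices 2–4 of long-horizon trials) decompose the
current expected values into the observation-phase baseline and the
updates revealed since:

$$P(\text{right}) = \sigma\!\big(b_{SB} + b_{RB}\,RB +
b_{\Delta Ch}\,\Delta Chosen + b_{bEV}\,baselineEV +
b_{\Delta EVch}\,\Delta EVchosen + b_{bU}\,baselineU +
b_{\Delta Uch}\,\Delta Uchosen + b_{\Delta EVun}\,\Delta EVunchosen +
b_{\Delta Uun}\,\Delta Uunchosen\big)$$

where $\Delta EVchosen$/$\Delta Uchosen$ are the chosen-stream beliefs
minus baseline, $\Delta EVunchosen$/$\Delta Uunchosen$ are the full-stream
beliefs minus the chosen-stream beliefs (identically zero under partial
feedback, where they are dropped from the fitted schema), $\Delta Chosen$
is the signed right-minus-left count of choices so far within the trial,
and $RB$ codes the immediately preceding choice's side. The "preference
for the option most often chosen" reported for subsequent choices is
identified with $\Delta Chosen$; no separate column exists.

Two conventions the data do not pin down were fixed once: regressors are
left on their natural units by default (no z-scoring; coefficients are per
drop and per drop²), and $RB$ on the first choice of a session is 0. The
simulator's generative agent and the design builders share one regressor
constructor, so the fitted design is the exact inverse of the generative
linear predictor by construction.

## Hierarchical fitting and inference

Responses are Bernoulli-logit. Every regressor's coefficient is a fixed
effect per animal $\times$ feedback-condition cell; session-level
coefficient vectors are random effects drawn from per-animal,
per-coefficient independent Gaussians centred on the cell fixed effects.
Sampling is plain MCMC — the backend (JAGS) is an implementation detail
behind `fit_choice_model()` — with defaults of 12 chains and 1,000
retained iterations each after 1,000 warm-up samples; reduced settings
(2 chains, a few hundred iterations) are used for the test suite and are
adequate for the point summaries checked there.

Priors are weakly informative: Student-t(3, 0, 2.5) on fixed effects and
half-Student-t(3, 0, 2.5) on random-effect SDs. Inference is intended for
the likelihood-dominated regime, where the exact weakly-informative family
is immaterial; the single-session reduction is checked against an
unpenalised maximum-likelihood logistic fit in the tests. Random-effect
correlations across coefficients are not modelled (independent Gaussians
per coefficient).

Significance is by posterior counting: the one-sided p-value of a
hypothesised positive effect is the fraction of draws $\le 0$ (draws
exactly at zero count on the null side, conservatively), reported as
"<1/N" when no draw crosses. Group-level estimates average cell draws
across animals and/or conditions per draw; `contrast_draws()` implements
arbitrary weighted cell combinations, e.g. complete-minus-partial on
$b_{EV}$.

Convergence policy: split-$\widehat R$ (each chain split in half) and
effective sample size are reported for every monitored parameter; any
parameter with $\widehat R > 1.05$ or ESS < 400 flags the fit. Flags are
carried in the result and printed, never silently discarded — at reduced
test-scale settings the ESS criterion is routinely flagged, which is the
honest description of a short run. Designs with a globally constant
column, or in which a cheap pooled screen detects perfect separation, are
rejected with the offending column named; counterfactual columns that are
zero only within the partial cells of a mixed design are legitimate
(prior-dominated there) and pass.

## What the simulator does and does not emulate

`generate_session()` reproduces the task's generative statistics exactly:
alternating five-trial horizon blocks (randomised starting horizon), true
means independent-uniform on [3, 7] redrawn until distinct on a 0.05 grid,
an exactly balanced half/half allocation of 2/2 vs 3/1 information splits
shuffled across the session (a Bernoulli(0.5) split would only balance in
expectation), and integer outcomes obtained by rounding Gaussian draws
half-up and clamping to [0, 10] — the discrete-drops reading that gives
the observer a finite outcome support. Because rounding and clamping are
part of the generative model, the *pre-rounding* SD is 1.5 while the
recorded outcomes have slightly different moments; tests check the
pre-rounding draws.

`simulate_agent()` inverts the two choice models: at every choice point it
computes the current regressor row from the online belief streams, applies
the coefficient vector, and samples through a logistic mixed with a lapse
rate (default 0; the lapse exists only to stress-test fitting and has no
counterpart in the behavioural model). Sessions default to the study's
scale of three animals and about thirteen sessions per feedback condition.

What passing tests on these simulations do **not** show: the generator
contains no reaction times, no eye movements, no satiety or engagement
drift, no cross-session learning, and its agents apply one coefficient
vector stationarily. Recovery results therefore validate the estimation
machinery, not any claim that real behaviour is stationary or
lapse-free. Trial timing metadata are carried for completeness but never
enter any computation.

## Problem sizes and runtime choices

The package's own validation uses three scales, chosen to exercise the
study design while keeping a full run cheap:

* **Full-scale recovery** (one fit): 3 animals × 13 sessions × 150 trials
  per feedback condition, first-choice model (about 11,700 choices), with
  a condition-and-horizon-dependent EV weight (higher in complete than
  partial; a short/long gap in partial only). Group-level posterior means
  are required to land within ±0.3 of truth and the qualitative contrast
  pattern (a significant short>long EV gap in partial, none in complete)
  must reproduce.
* **Coverage replicates**: twenty refits at 3 animals × 4 sessions × 60
  trials per condition; nominal 95% intervals for group-level coefficients
  must cover truth at least 80% of the time (a deliberately loose bound at
  twenty replicates).
* **Counterfactual check**: complete-feedback sessions only, subsequent
  model, 3 animals × 6 sessions × 80 trials, requiring a positive
  counterfactual-update coefficient with posterior-count p < 0.05, and the
  structural zero of that column under partial feedback.

Reduced MCMC settings (2 chains, 200–300 warm-up, 300 retained draws) are
used for all of these; the paper-scale 12 × 1,000 default remains available
through `fit_config()`.

## Degenerate inputs and tie handling

Exact EV ties are excluded from accuracy denominators (detected to 1e-12
drops, below the smallest genuine EV gap between distinct small
observation sets, which is about 3e-5). Zero-variance inputs to the
session-level t test return an explicit degenerate result rather than an
error. Trend sessions in which the quantity is constant have undefined
slopes and are dropped with their identifiers reported. Empty psychometric
bins are reported as missing, never as zero. Session logs are validated on
read: a partial-feedback log with unchosen outcomes, a missing
observation, or an out-of-support value is rejected with a named
diagnostic.

## Known limitations

* The random-effect structure assumes independent per-coefficient
  Gaussians; correlated slopes would require a full covariance extension.
* The pooled perfect-separation screen is heuristic; pathological designs
  that separate only within one session can still reach the sampler (they
  surface through the convergence flags).
* The information-count model variant is only wired for first choices,
  where observation counts and uncertainty are monotonically related;
  subsequent choices always use the uncertainty parameterisation.
* In a joint fit over both feedback conditions the counterfactual
  coefficients of the partial cells are prior-dominated (their columns are
  structural zeros there): their draws wander the weak prior and dominate
  the convergence flags without affecting likelihood-informed parameters.
  Fit the complete condition alone when those coefficients are the target.
* No model comparison (WAIC/LOO) and no learning-rule (delta-rule)
  alternatives are provided; the observer is exact Bayes with no
  forgetting or volatility.
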