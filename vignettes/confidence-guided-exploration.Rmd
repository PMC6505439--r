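---
title: "Modelling confidence-guided exploration in a two-armed bandit"
author: "banditmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling confidence-guided exploration in a two-armed bandit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(banditmeta)
```

## The task

The package simulates and analyses a value-based learning task in which a
subject repeatedly faces a two-armed bandit. Each arm pays
`100 * Beta(alpha, beta)` points, with the shape pairs drawn per block from
five canonical distributions — (1,3), (2,3), (3,3), (3,2), (3,1) — giving
unimodal reward distributions with means of 25, 40, 50, 60 and 75 points and
different skews. A session comprises 600 trials grouped into blocks of 20–60
trials; each block draws a fresh pair of arms, so beliefs must be rebuilt.
Two trial types are randomly intermixed:

* **rating trials** — the subject reports a *value belief* (0–100 points)
  for an arm together with a *belief confidence* (how certain they are of
  that estimate);
* **choice trials** — the subject freely picks an arm, reports a *decision
  confidence* (how likely the choice was the better one), and then sees the
  outcome.

The two designs differ in the mix and in what rating trials show. The
rating-heavy design (`exp1`, 75% rating trials) reveals an outcome from a
randomly chosen arm before the rating. The choice-heavy design (`exp2`, 25%
rating trials) shows no outcome on rating trials but collects ratings for
*both* arms, leaving choice outcomes as the only source of evidence. All
simulated subjects share one schedule and one pre-generated outcome
sequence per schedule seed, mirroring a yoked experimental design.

## The agents

Three learning rules maintain, per arm, a value estimate $V$ and a
dispersion estimate $s$ (the latent quantity behind belief confidence):

* **Ideal observer** — $V$ is the running mean and $s$ the running sample
  SD of the outcomes observed for that arm. Reported belief confidence
  tracks the *standard error* $s/\sqrt{n}$: confidence is certainty about
  the mean, which sharpens with evidence even though the outcome SD itself
  does not shrink. (With fewer than two observations the state keeps its
  flat-prior dispersion, $100/\sqrt{12}$; reporting full certainty after a
  single outcome would be degenerate.)
* **Delta rule (RL)** — $V \leftarrow V + \eta\,(r - V)$ with learning rate
  $\eta$, and $s \leftarrow (1-\eta)\,s + \eta\,|r - V_{\text{pre}}|$: the
  dispersion is a recency-weighted average of absolute prediction errors,
  so surprising outcomes *lower* reported confidence — the signature
  anti-Bayesian confidence dynamic seen in human raters, where a large
  update is accompanied by a confidence drop.
* **Particle filter** — a sequential Monte-Carlo posterior over candidate
  arm values on a fixed uniform grid, reweighted by a beta observation
  model with concentration $\nu$ (`obs_concentration`), with systematic
  resampling (deterministic offset, so the filter is exactly reproducible)
  once the effective sample size falls below half the particle count. $V$
  and $s$ are the weighted particle mean and SD; $s$ contracts as the
  posterior concentrates.

Reports add Gaussian noise: value ratings (`rating_noise_sd` points, clipped
to the scale, recorded to 0.1 point) and confidences (`confidence_noise_sd`,
clipped to [0,1], recorded to 0.001). The map from dispersion to confidence
is linear with clipping, $c = \mathrm{clip}(1 - g\,s/100)$ with gain $g$
(`confidence_gain`); the true psychometric link is unknown, and a fixed
monotone-decreasing map is the simplest member of the admissible family.

Choices follow a softmax on the value difference plus an uncertainty bonus:

$$P(\text{choose lower-valued arm}) =
  \mathrm{logit}^{-1}\!\big({-\beta\,|\Delta V|/100} + \varphi\,(1 - C_{high})\big),$$

where $C_{high}$ is the latent belief confidence of the currently
higher-valued arm, $\beta$ the inverse temperature and $\varphi$
(`uncertainty_bonus`) the weight of uncertainty in exploration. Decision
confidence is a fixed linear readout of both arms' latent beliefs: the
chosen arm's value raises it, the unchosen arm's value lowers it, and
belief confidence in *either* arm raises it (the chosen arm's weighted more
heavily). Choice-trial reaction times are log-normal with a mean that
decreases with latent decision confidence, giving the standard negative
confidence–RT coupling; nothing further about motor generation is modelled.

### Default parameters and why

The generator's defaults define the simulated study conditions; they were
fixed once, against the behavioural benchmarks the task is known to
produce, and are not tuned per analysis:

| parameter | default | rationale |
|---|---|---|
| `learning_rate` | 0.3 | value estimates converge within a few outcomes, leaving a measurable early-block estimation-error excess |
| `confidence_gain` | 2.5 | spreads reported confidence over roughly the upper half of the scale, as subjects use it |
| `uncertainty_bonus` | 0.5 | mid-grid value of the exploration mechanism under study |
| `inverse_temperature` | 14 | yields exploration rates in the 15–25% range and ~85% objectively correct choices |
| `rating_noise_sd` | 3 points | keeps carried ratings a faithful proxy of the latent state while leaving realistic report scatter |
| `confidence_noise_sd` | 0.05 | same role for the confidence scales |
| `obs_concentration` | 12 | sharp enough that the beta likelihood's argmax bias (a skew effect) stays within the particle grid resolution |
| `n_particles` | 50 | grid spacing of 2 points; posterior summaries are insensitive beyond this |

Cohort heterogeneity is Gaussian on transformed scales (logit for the
learning rate, log for positive parameters, identity for the uncertainty
bonus, which may be zero or negative), clipped at the hard bounds; no
subject-level distribution is observable, so modest spreads were chosen
once.

### What the simulator does and does not emulate

It emulates: blocked schedules with shared gambles, the two rating/choice
mixes, beta rewards in points, ratings that sharpen with evidence, the
surprise-driven confidence drop, uncertainty-biased exploration, and
confidence-coupled RTs. It does **not** emulate: attentional lapses or
distraction (simulated RT outliers arise only from log-normal tails),
idiosyncratic scale use (anchoring, digit preference), sequential response
biases, or any neural quantity. Passing tests therefore certify the
*pipeline* — that each analysis recovers what the generative mechanism put
in — not that these mechanisms are the true account of human data.

## Preprocessing rules

* **RT exclusion**: per subject, choice trials outside mean ± 3 SD of that
  subject's choice RTs are removed, two-tailed (both fast lapses and slow,
  distracted responses); rating trials are never excluded. Subjects with
  fewer than three choice trials or zero RT variance are skipped with a
  warning.
* **Carry-forward**: each arm's most recent value and confidence rating is
  propagated onto later choice trials *within the same block only*; carried
  values reset at block boundaries because the reward distributions change
  there, so a stale rating refers to arms that no longer exist.
* **Exploration label**: choosing the arm most recently rated *strictly*
  lower. Ties are excluded rather than coin-flipped — the definition is a
  strict inequality and a tie identifies no lower-rated option.
* **Objective accuracy**: the chosen arm's running mean of all outcomes
  observed so far is at least the other arm's; ties count as correct (they
  are rare and a tie means no objectively wrong option existed).
* **Standardization**: within-subject z-scores divide by the population SD
  (n, not n−1) — fixed for reproducibility, immaterial at these sample
  sizes. Regression predictors are z-scored across the analysis data set
  before fitting, so coefficients are standardized.
* **Quantile bins**: per-subject quantile cut points (quintiles for the
  confidence analyses, quartiles for metacognition); heavy ties merge bins
  with a warning.

## Statistical models

`fit_hierarchical()` fits linear (lmer, via lmerTest for Satterthwaite
degrees of freedom) or logistic (glmer) mixed models by maximum likelihood
(`REML = FALSE`, so BICs are comparable across model ladders), with a
per-subject random intercept and random slopes for every fixed term.
Interaction predictors are products of the standardized components.

Two numerical choices matter here. First, the default random structure is
*uncorrelated* (diagonal) slopes: estimating the full slope-correlation
matrix of a seven-term model is near-singular and an order of magnitude
slower on designs of this size, while "random intercept and random slopes
for all regressors" is satisfied either way; the fully correlated structure
is available via `random = "full"`. Second, a fallback ladder (full →
diagonal → intercept-only → per-subject fits pooled by inverse variance)
handles non-convergence, and the result records which rung was actually
fitted — the fallback never happens silently.

The three front-line models are:

* **decision confidence** (rating-heavy design): carried value and
  confidence of the chosen and unchosen arm, their value interaction, plus
  objective accuracy and log RT as controls. The (log) within-block trial
  number is available as an optional control (`include_trial`) but excluded
  by default: the better-fitting specification omits it, and its effect is
  absorbed by the confidence terms.
* **exploration** (choice-heavy design): logistic model of the exploration
  flag on the carried confidence of the higher-rated arm, |ΔV|, and their
  interaction.
* **belief confidence**: reported confidence on the running SD (`sig_past`)
  and mean (`mu_past`) of outcomes observed so far for the rated arm, log
  trial number and arm, with the stated two- and three-way interactions.
  The `sig_past` slope is the per-subject index of normative uncertainty
  tracking; per-subject slopes (fixed + random) are exported for the
  metacognition link. Rows require at least two observed outcomes, since a
  single outcome has no dispersion.

`quintile_trend_anova()` is a one-way repeated-measures ANOVA on
per-subject bin means with a Greenhouse–Geisser sphericity correction
(epsilon from the sample covariance of the bin scores), partial eta
squared, and a linear polynomial-contrast F computed from per-subject
contrast scores. It is validated against an independent implementation on a
frozen fixture.

## Metacognitive efficiency

`fit_meta_d()` implements per-subject maximum-likelihood meta-d′ in the
equal-variance SDT framework: the "stimulus" is the objectively better arm
on that trial, the "response" the chosen arm, and confidence is binned into
K = 4 within-subject quartiles (K is configurable; it is not an empirically
fixed constant, and sensitivity to K should be checked rather than
assumed). The type-1 criterion is locked at its empirical relative position
(the meta-level criterion is `c·meta-d′/d′`), and meta-d′ with 2(K−1)
type-2 criteria maximize the multinomial likelihood of the
response-conditional confidence counts. Every cell is padded with `1/(2K)`
to guard degenerate margins, and the result records the padding, K, and an
`undefined` flag when d′ ≤ 0 (M-ratio is meaningless without positive
type-1 sensitivity).

This replaces a hierarchical-Bayesian group estimator with independent
per-subject MLE fits: simpler, dependency-free, and unbiased at the trial
counts simulated here, but without shrinkage — with few trials per subject,
individual M-ratios are noisier than a hierarchical posterior mean would
be. `tracking_vs_efficiency()` then correlates the per-subject `sig_past`
slope with log M-ratio.

## Model fitting and comparison

`agent_nll()` scores a trial log under any of the three agents: Gaussian
observation likelihoods of the value and confidence ratings around the
model's latent readouts (both arms where both were rated) plus the choice
policy's log-probability of each chosen arm, with latent states updated
exactly as in simulation and reset at block boundaries. Rating and choice
components enter with equal weight. Clipping and rounding of reports are
ignored in the density (a censored-Gaussian correction changes nothing at
these noise levels and costs a special case). The BIC sample size is the
number of scalar likelihood components. The likelihood core is compiled
(Rcpp) because model comparison evaluates it thousands of times; a pure-R
reference implementation built directly on the agents module is kept and
tested to agree with the compiled path, including the particle filter's
resampling arithmetic.

`fit_agent()` runs bounded multi-start L-BFGS-B (10 seeded restarts, the
first from the default parameters, the rest uniform in the parameter box);
`compare_agents()` fits every candidate per subject and ranks by summed
BIC. Because the generating model of real data is unknowable, the
package's acceptance instrument is a confusion study: cohorts simulated
from each model are refit with all models, and the generating model must
win.

## Problem sizes

The test suite and acceptance script use sizes a single CPU handles in
minutes, chosen as the package's own desk-scale defaults: cohorts of 12–30
subjects at 600 trials for the regression analyses (21 and 30, typical
cohort sizes for this paradigm), 50 subjects for learning-rate recovery, 20
replicate two-subject cohorts of 200 trials for the BIC confusion study,
and 10,000 trials for the SDT-ideal meta-d′ calibration. The
exploration-recovery study compares uncertainty-bonus levels on *paired*
cohorts (common master seeds), so the bonus is the only difference between
conditions; its effect on the standardized confidence slope is small by
construction (the bonus acts through the within-subject spread of carried
confidence), and pairing is what makes the monotone ordering detectable at
this scale.

## Known limitations

* The three agent families are canonical single members (one delta-rule
  variant, one particle filter with a fixed observation family), not a
  survey of all plausible variants; parameters are exposed so alternates
  can be added.
* Belief confidence in the exploration analysis is carried from the most
  recent rating and therefore lags the latent state; with fast learning
  dynamics this attenuates (and with strongly time-locked confidence,
  confounds) the measured uncertainty–exploration link. This is a property
  of the measurement design itself, not of the implementation.
* The two-stage regression fallback reports no BIC (the pooled fit has no
  single likelihood), so ladders that bottom out there cannot be compared
  by BIC.
* Real rating scales are bounded and discrete; the Gaussian report model
  treats them as continuous and uncensored.
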