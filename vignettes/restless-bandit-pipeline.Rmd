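---
title: "Modelling exploration-exploitation behavior on the restless bandit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling exploration-exploitation behavior on the restless bandit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restlessbandit)
```

## The task and its generating process

The package models behavior on a restless four-armed bandit: on each of 300
trials (four runs of 75) the subject picks one of four slot machines within
a 1.5 s response window and receives an integer payoff between 1 and 100
points. Each arm's latent mean payoff follows a decaying Gaussian random
walk,

$$\mu_{i,t+1} = \lambda\,\mu_{i,t} + (1-\lambda)\,\theta + \nu, \qquad
\nu \sim N(0, \sigma_d^2),$$

with decay $\lambda = 0.9836$ toward the center $\theta = 50$ and diffusion
noise $\sigma_d = 2.8$; the payoff shown is a Gaussian draw around the
latent mean ($\sigma_o = 4$), rounded to the nearest integer. Because the
best arm keeps changing, continued exploration is rational, which is what
makes the task a clean behavioral assay of the exploration-exploitation
tradeoff.

The process is a stationary AR(1): its long-run mean is $\theta$ and its
long-run variance $\sigma_d^2/(1-\lambda^2) \approx 241$ points². Two
choices in `generate_schedule()` are not dictated by the equation and are
therefore explicit design decisions:

* **Initial means** are drawn from the stationary distribution (seeded,
  overridable), so the first trials are statistically typical rather than
  transient.
* **Payoff bounds.** The walk itself is unbounded; only realized payoffs
  are kept in $[1, 100]$. The default folds out-of-range draws back by
  reflection *before* rounding, which avoids the probability mass that
  clamping piles onto the exact bounds; `boundary_mode = "clamp"` is
  available for comparison. Both modes guarantee every payoff lies in the
  bounds.

By default one fixed-seed schedule is shared by all simulated subjects, the
usual arrangement when a study wants payoff sequences comparable across
participants; per-subject schedules are a config switch.

## The Kalman-softmax choice model

Each subject is modelled as tracking a Gaussian belief (mean and variance
per arm) with a Kalman filter whose dynamics mirror the generating process.
Before trial $t$ the subject holds pre-choice means $m_i$ and variances
$v_i$. After choosing arm $c$ and observing reward $r$:

$$\kappa = \frac{v_c}{v_c + \hat\sigma_o^2}, \qquad
m_c \leftarrow m_c + \kappa (r - m_c), \qquad
v_c \leftarrow (1-\kappa)\,v_c,$$

and then every arm diffuses: $m_i \leftarrow \hat\lambda m_i +
(1-\hat\lambda)\hat\theta$, $v_i \leftarrow \hat\lambda^2 v_i +
\hat\sigma_d^2$. Unchosen arms keep their prior as posterior. Choice
probabilities are a softmax over the *pre-choice* means,
$P(i) \propto \exp(\beta m_i)$ — choice precedes outcome, so the current
trial's reward cannot inform it. $\beta$ is an inverse temperature in
1/points: $\beta = 0$ is a uniform chooser (per-trial negative
log-likelihood exactly $\ln 4$), large $\beta$ approaches the greedy
chooser.

Default parameter values are the best-fitting estimates for this task
family: $\hat\lambda = 0.8941$, $\hat\theta = 54.77$, $\hat\sigma_d = 6.32$,
$\hat\sigma_o = 0$, prior mean $67.78$, prior variance $8.18$. Two
consequences of $\hat\sigma_o = 0$ are worth spelling out:

* the Kalman gain is 1 — beliefs jump to each observed reward before
  diffusing — and the gain computation needs a guard for the $0/0$ limit
  (`pre_var = sigma_o = 0`), which we define as gain 1 with a $10^{-12}$
  floor in the denominator;
* the choice likelihood then depends only on $(\hat\lambda, \hat\theta,
  \hat\mu_0)$: the variance parameters drop out of the softmax entirely and
  become flat directions of the likelihood. The fitter leaves them near
  their starting values in that regime; recovery claims are accordingly
  made only for $\hat\lambda$ and $\beta$.

Missed trials (no response within the window) contribute no likelihood
term, but beliefs still undergo the diffusion step — time passes without an
observation. Whether the original analyses handled missed trials this way
is not recoverable; it is the natural filtering treatment, and at the
default 1% miss rate the alternative (freezing beliefs) moves the NLL by a
negligible amount. All $\beta m$ products go through max-subtracted
(log-sum-exp) normalization, so arbitrarily large inverse temperatures
cannot overflow.

The per-trial recursion and the likelihood are implemented in C++ (Rcpp),
as is usual for trial-level model likelihoods that sit inside an optimizer;
a naive, separately coded R walk serves as the oracle in the test suite.

## Maximum-likelihood fitting

`fit_bandit_model()` estimates one set of learning parameters shared by all
subjects with a per-subject $\beta$ — the hierarchy that matches reporting
one group-level set of learning parameters next to per-group softmax
means. The inner problem (each subject's $\beta$ given shared parameters)
is convex — the session NLL is a sum of log-sum-exps of functions linear in
$\beta$ — so each subject's $\beta$ is profiled out by safeguarded Newton
on $[0, 2]$ (1/points) to a $10^{-7}$ bracket. The outer problem over the
six shared parameters uses L-BFGS-B inside a box that keeps
$\hat\lambda \in (0, 1]$ and all variances nonnegative, with the
$\hat\sigma_o$ lower bound exactly 0 because the boundary is a legitimate
optimum. The surface is smooth but can be multimodal in
$(\hat\lambda, \hat\theta)$, so the fit restarts from seeded random points
inside the box (first start: the default parameter values); the best local
optimum wins, and refits with the same seed are bit-identical. A `fixed`
mask can pin any subset — useful both for likelihood-ratio-style
comparisons and for the flat directions noted above.

Parameter recovery at cohort scale (50 subjects × 300 trials, 20 replicate
cohorts, 2 restarts each — sizes chosen to make the recovery suite a
few-minute run) is part of the acceptance tests: $\hat\lambda$ is recovered
within ±0.05 and the cohort mean $\hat\beta$ within ±20% in every
replicate, with the fitted group means concentrating on the configured
0.19 / 0.17.

## Explore/exploit labelling

A trial is *exploitative* when the chosen arm's pre-choice mean is within
$10^{-9}$ points of the maximum across arms, *explorative* otherwise:
exploring means choosing an arm believed strictly inferior. The tolerance
implements tie-as-exploit — a tie means there is no arm "believed to have
the highest value" that the subject declined. On trial 1 all arms share the
prior, so the first responded trial is a tie and labels exploit; this
affects counts by at most one trial. Labels are invariant to adding a
constant to all belief means and are deterministic given the parameters.
Two self-consistency properties pin the classifier down: a near-greedy
agent labelled under its own parameters is ≥ 99% exploit, and a uniform
($\beta = 0$) agent explores 3/4 of the time in expectation (the argmax is
unique almost surely after trial 1).

## Decision efficiency and the mixed ANOVAs

Decision efficiency is total payoff divided by response time, in points per
second: per subject, the payoff total over responded trials divided by the
mean RT over responded trials. Missed trials stay out of both numerator
and denominator.

Splitting by choice type forces a decision the phrase "total payoff divided
by response time" leaves open, because cell totals scale with cell trial
counts. The package computes both readings — cell payoff **total** over
cell mean RT (the literal one, the default) and cell **per-trial mean**
payoff over cell mean RT — reports both in the `efficiency_table`, and runs
the ANOVA on the configured one. Subjects with an empty cell (e.g. a
near-greedy subject who never explored) carry no within-subject contrast
and are dropped from the ANOVA input by default.

The 2×2 mixed design (choice type within, group between, unbalanced groups
allowed) is partitioned the standard way: the group effect is tested
against the between-subject error on subject means; the condition effect
and interaction are tested against the subject-by-condition error, computed
from per-subject condition differences with sum-to-zero group coding. For
this layout that is the Type-III (unweighted-means) partition — under
unbalanced groups the condition effect is the unweighted mean of the
group-wise difference means, which is why the package computes the
partition itself rather than relying on `aov()`'s sequential sums of
squares; `aov()` agrees exactly in the balanced case and serves as a
cross-check in the tests, alongside a hand sums-of-squares oracle for the
unbalanced case. All three tests have df $(1, n-2)$.

## ROI second-level statistics

ROI activity enters as a table (subject × ROI × choice type); sphere
extraction from images is upstream of this package. The registry holds the
nine 8 mm spheres used by the analyses — vmPFC, bilateral FPC and IPS, a
right FPC sphere from a behavioral-switching study, dACC, and bilateral
locus coeruleus (MNI centers as published).

* **Condition contrast** (`roi_contrast`): the per-ROI explore-vs-exploit
  comparison pools the $n$ explore and $n$ exploit estimates as two
  independent samples (pooled-variance t, df $2n-2$). The df choice follows
  the reference table's df of 98 at $n = 50$, which implies pooling rather
  than pairing; a paired variant (df $n-1$) is available since pairing is
  what a fresh analysis would more likely do. Two-sided p-values by
  default, sidedness not being stated in the source convention.
* **Choice × group ANOVA** (`roi_mixed_anova`) delegates to the same mixed
  ANOVA as the behavioral analysis.
* **Efficiency regression** (`efficiency_regression`): OLS of per-subject
  efficiency on an intercept, a group indicator, and the 14 ROI × condition
  regressors of the seven non-LC spheres — df $(15, 34)$ at $n = 50$.
  Regressors are raw estimates (the published coefficient magnitudes
  suggest unstandardized regressors); `standardize = TRUE` is available.
  The adjusted-$R^2$ identity
  $1 - (1-R^2)(n-1)/(n-k-1)$ holds exactly on every fit, and coefficients
  match a normal-equations oracle to $10^{-8}$ in the tests.

## The synthetic cohort generator

The generator exists so that every stage is testable end to end without
any subject data. It emulates a two-group cohort: 24 entrepreneur-like and
26 manager-like subjects, each playing the shared 300-trial schedule
through the Kalman-softmax agent.

* **Inverse temperatures** are drawn per subject from group Gaussians
  truncated at 0, means 0.19 / 0.17 and SDs 0.08 / 0.09. The reported
  first-group SD of 0.8 is implausible next to the other group's 0.09 and
  a non-significant group comparison, and is treated as a typo for 0.08;
  the value is config-overridable rather than silently assumed.
* **Response times** are hierarchical lognormals. The printed RT summary
  rows are per-group statistics of *per-subject mean* RTs ($N = 24$ and
  $26$), so the targets 0.389 ± 0.043 s and 0.454 ± 0.095 s are planted as
  *between-subject* spread: each subject's mean RT is drawn from a
  lognormal moment-matched to its group's mean and SD, and trial RTs
  scatter lognormally around the subject mean with a within-subject SD of
  0.08 s — a realistic trial-to-trial jitter for a speeded two-alternative
  press, chosen once. The lognormal family provides positivity and right
  skew; draws are truncated to the response window. RTs are independent of
  choice type by default (an optional explore-increment knob would be the
  natural extension for power studies of the choice-type RT effect).
* **Miss rate** defaults to 1% of trials.
* **ROI tables** are built as baseline + subject intercept + planted
  condition effect + efficiency-coupled component + noise. Condition
  effects (explore − exploit) are positive in the fronto-parietal, dACC and
  LC spheres and negative in vmPFC, with magnitudes chosen so the pooled
  contrasts at $n = 50$, noise SD 1, land in the published t range. The
  switching-study FPC sphere instead carries the planted choice × group
  interaction: each subject's explore−exploit difference is drawn from its
  group Gaussian (means 0.67 / −0.15, SDs 1.60 / 1.18), with the
  efficiency-coupling variance discounted so realized difference SDs match
  the configured ones. The efficiency coupling adds
  `coupling × z(efficiency)` to selected ROI-condition cells, with
  efficiency z-scored *within* group so the coupling feeds the regression
  without disturbing the planted group contrasts.

Everything derives from one master seed: per-subject seeds are drawn from
it, identical seeds give identical cohorts (and files — the CSV writers
emit doubles at full precision precisely so that generator outputs
round-trip bit-identically), different seeds independent ones.

### What the generator does and does not emulate

Passing tests on synthetic cohorts show that the pipeline recovers planted
structure of the configured form: group RT gaps, softmax means, ROI
condition effects and the FPC interaction. They do not show that real
subjects satisfy the model's assumptions — trial RTs are independent of
choice type and belief state here, payoffs and RTs are conditionally
independent, learning parameters are truly shared across subjects, and ROI
activity is linear in efficiency with Gaussian noise. Real data violate
several of these in ways the statistics would feel (e.g. RT-choice-type
coupling is an empirical main effect in this task family).

### A note on the group-effect power under these conditions

The planted RT gap (0.389 ± 0.043 vs 0.454 ± 0.095 s) translates into an
efficiency gap of roughly 5,800 points/s against an emergent between-subject
efficiency SD of about 5,400 / 8,600 points/s per group — the reciprocal
transform from RT to efficiency inflates the slower, more variable group's
spread. At $n = 24/26$ that is a standardized difference near 0.8 and a
group-effect power just below 0.80: the acceptance suite's 100-replicate
power check lands within Monte-Carlo error of its 80% bar and can fall a
few replicates short, which we report as measured rather than retuning the
generator (on the RT scale itself the same gap gives a standardized
difference near 0.87, which is where an 80% expectation would come from —
the efficiency transform is what erodes it). The companion null check
(equal RT distributions) rejects at the nominal rate. Had the printed RT
SDs been planted as within-subject trial noise instead, between-subject
variance would all but vanish and the power check would be trivially 100% —
but the generated cohorts would then not emulate the printed per-group
spread at all, which is the property this generator is for.

## Problem sizes and runtimes

The test suite simulates at the study's native scale where the claim
depends on it (50 × 300 cohorts for recovery and power; 20 and 100
replicates respectively; 10^5-step process moments; 10^6-payoff bounds) and
at reduced scale for structural checks (6-13 subject cohorts for
round-trips and validation). The oracle-equivalence suites run 200
randomized small instances. The full suite is a matter of minutes on one
core; the acceptance script (payoff-process targets) runs in seconds.

## Known limitations

* The efficiency cell definition is genuinely ambiguous in its source;
  both readings are computed, but cross-study comparisons should state
  which one they use.
* With $\hat\sigma_o$ fitted to 0, variance-related parameters are not
  identifiable from choices; their fitted values are reported but carry no
  information.
* The pooled (df $2n-2$) ROI contrast treats within-subject condition
  estimates as independent samples; it matches the reference convention
  but is anticonservative when condition estimates correlate within
  subject — the paired variant is the statistically safer choice for new
  data.
* The generator plants no spatial correlation between ROIs beyond the
  shared efficiency coupling, no run structure in RTs, and no learning
  drift across runs.
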