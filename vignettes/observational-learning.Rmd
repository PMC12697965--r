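---
title: "Modelling partner selection and observational reinforcement learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling partner selection and observational reinforcement learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`oblearn` implements a complete analysis pipeline for a social-learning
experiment: participants watch two simulated partners play a three-armed
bandit, choose one of them, and then learn the bandit purely by observing
that partner's choices and outcomes.  This vignette describes the models
the package implements, the choices made where the design was open, and
what the synthetic-data generator does and does not emulate.

## The task

Every bandit in the experiment pays a unit reward with option
probabilities 0.25, 0.50 and 0.75.  A block consists of two 30-trial
passive-observation sequences (one partner with high decision noise, one
with low), a partner-selection choice, and a 60-trial observational phase
with the selected partner in which the participant's own outcomes are
never shown.  Partners are standard Q-learning agents (learning rate
0.3) that differ only in softmax inverse temperature: 1.5 (high noise),
20.0 (low noise), or 7.0 for the practice-block partner.  Partner Q
values start at 0.5, the midpoint of the unit reward scale; the task
description leaves partner initialisation open and this matches the
learner's own value initialisation.

## Observational-learning models

The Full model tracks two quantities per option: an action value $V_X$
learned from the partner's outcomes by a delta rule,
$V_X \leftarrow V_X + \alpha_V (R_t - V_X)$, and an action tendency
$A_X$ pulled toward the partner's choices,
$A_{chosen} \leftarrow A_{chosen} + \alpha_A (1 - A_{chosen})$ and
$A_{unchosen} \leftarrow A_{unchosen} + \alpha_A (0 - A_{unchosen})$.
Because the tendency update is an affine contraction toward a one-hot
vector, $\sum_X A_X = 1$ is conserved exactly — one of the algebraic
invariants the test suite checks to $10^{-12}$.  Choice probabilities
are a softmax with inverse temperature $\beta$ over the mixture
$Q_X = (1 - w_A) V_X + w_A A_X$; the imitation weight $w_A \in [0,1]$ is
the parameter of scientific interest.  The Action Learning and Reward
Learning models are the $w_A = 1$ and $w_A = 0$ boundaries with the
unused component removed; the nesting identities are tested as
properties.

Values start at $V = 1/2$, $A = 1/3$ per option, so the first-trial
choice distribution is exactly uniform.  State resets at every block
boundary (stimuli and probability assignments are re-randomised across
blocks), the partner's choice and outcome are incorporated *before* the
participant's same-trial choice is evaluated (the partner acts first on
screen), and the participant's own hidden outcome never updates state.

## Hierarchical fitting

Individual parameters are sampled on an unconstrained scale — logistic
transform for unit-interval parameters, exponential for $\beta$ — with
raw parameters drawn from population normals whose means have standard
normal priors and whose standard deviations have half-Cauchy(0, 3)
priors.  The sampler is an adaptive Metropolis-within-Gibbs scheme
written for this package:

* coordinate-wise random-walk proposals per participant, step sizes
  adapted during warmup toward ~35% acceptance;
* joint random-walk proposals whose per-participant covariance is
  learned from the warmup history (the within-participant posteriors of
  $w_A$ and $\alpha_A$ are strongly correlated, which coordinate moves
  traverse slowly);
* independence proposals drawn from the current population distribution,
  whose acceptance ratio reduces to the likelihood ratio — these move
  weakly identified participants (for instance a true $w_A \approx 0$
  with $\alpha_V \approx 0$, where the likelihood is nearly flat along
  $\alpha_A$) across ridges in a single step;
* conjugate Gibbs updates for the population means and slice sampling
  for the population standard deviations.

Chains are initialised at a jittered penalised-likelihood mode so that
short chains spend no iterations on the initial transient.  The
likelihood is evaluated in C++ for all participants per proposal batch.
Convergence is summarised by split R-hat and a crude autocorrelation
effective sample size per scalar parameter; any split R-hat above 1.05
is recorded as a warning on the fit object rather than an error, because
at the desk scales used for validation (4 chains of 200 + 200
iterations) occasional weakly identified simulated participants mix
slowly no matter the tuning.  Model comparison uses WAIC computed from
the per-trial, per-draw pointwise log-likelihood with log-sum-exp
stabilisation; per-trial (rather than per-participant) pointwise terms
are the standard construction and the package's choice.

## Synthetic data

`generate_study()` produces complete studies under the experiment's
conditions: 74 participants, 4 blocks, 30-trial passive sequences,
60-trial observational phases, rewards 0.25/0.50/0.75, learner
parameters drawn Beta(1.1, 1.1) (rates and weight) and Uniform(0, 30)
($\beta$), and the selected partner low-noise with probability 0.7 per
block.  Partner selection is an exogenous coin flip — exactly the
assumption of the recovery simulations — so synthetic selections carry
no information about learning style unless the `p_low_fun` hook plants
an association.  The practice individual-learning phase is generated by
a Q-learning agent using the participant's own reward-learning rate and
inverse temperature: some generative stand-in is required because the
predictability model is fitted to practice data, and reusing the
participant's parameters preserves the participant-specific role of that
fit.  Each participant consumes a random stream derived from the master
seed by a fixed offset, so enlarging a study never perturbs existing
participants.

What the generator does not emulate: reaction times, stimulus identity
and screen-position effects, sequential dependencies between blocks, or
any adaptive relation between observed partner behaviour and the
selection itself.  Passing tests therefore validate the *machinery*
(likelihoods, sampler, codings, pooling) and the internal consistency of
the analyses, not claims about human data.

## Partner metrics and regressions

Three block-level indices summarise each observed partner: performance
(total passive-phase reward), predictability (log-likelihood of the
partner's choices under the participant's own decision model — a
Q-learning model with a count-based information bonus $\kappa / N_X$,
fitted hierarchically to the practice phase with the same transforms and
priors), and information gain (the total bonus reduction
$\sum_t \kappa (1/N_X - 1/(N_X+1))$, which telescopes to
$\kappa \sum_X (1 - 1/(c_X + 1))$ over choice counts $c_X$).  Counts
start at one pseudo-observation so the bonus is finite before the first
choice, the only convention consistent with the decrement formula.  The
bonus enters at decision time only (it augments the value used for
choice, not the delta-rule target).

Selection analyses code the outcome as 1 when the left partner is
chosen, with +1/-1 codes for the high-noise partner's side (X1) and
presentation order (X2); the factor variant replaces X1 with
right-minus-left differences of the three indices, z-scored across all
participant-blocks pooled.  With this orientation a preference for the
low-noise partner appears as a negative X1 coefficient.  Learning-style
analyses fit one mixed logistic model per option — outcome 1 when the
participant chose that option, partner-choice code $C_t$, partner-reward
code $R_t$, moderated by the preference proportion $P$ (entered
uncentred, so marginal effects are reported at the observed levels 0,
0.25, 0.5, 0.75, 1) or the block-level noise indicator $D$ — and pool
each coefficient across options by inverse-variance weighting.  Mixed
models are delegated to `lme4::glmer`; if the random-effects fit fails
to converge the function falls back to a fixed-effects logistic
regression with cluster-robust (CR0) standard errors by participant and
flags the route in the output.  Coefficient tests use two-tailed t
statistics with degrees of freedom equal to the number of participants —
a reporting convention, not a derived quantity.

## Validation studies and problem sizes

Model recovery generates studies from each of the three models, fits all
three, and tabulates the WAIC winner into a confusion matrix; parameter
recovery correlates posterior-mean estimates with the generating values
and stratifies by simulated partner preference using the majority rule
(more than half of blocks; participants at an exact split are
discarded), post-stratifying the joint fit rather than refitting within
groups.  The package's validation suite runs these at desk scale — 10
participants, 2 blocks, 5 replicates per generating model, 4 chains of
200 + 200 iterations — with the full-scale settings (74 participants, 4
blocks, 40 replicates, 1000 + 1000 iterations) available through the run
configuration.  Replicate seeds derive deterministically from a master
seed.

Posterior predictive checks regenerate every participant's blocks under
the original conditions (same selected-partner noise level and trial
counts; partner streams are regenerated from the partner parameters
rather than replayed, since the conditions, not the realisations, are
fixed) and recompute the learning curve and, optionally, the pooled
learning-style effects.  Replicates can use posterior means or one
posterior draw per replicate; the draw variant is the fuller predictive
distribution — its spread includes parameter uncertainty — and is what
the self-consistency check uses.  A caveat documented here because it
shapes the test design: comparing a 60-trial curve pointwise against a
3-SD band is a 60-fold multiple comparison, so even a perfectly
calibrated check exceeds the band somewhere in a nontrivial fraction of
realisations, and with few observations per trial bin binomial
discreteness degrades the nominal calibration further.  The packaged
check therefore uses an originating study of 30 participants and 4
blocks (120 observations per trial bin), where the normal approximation
behind the band is sound.

## Numerical choices

Softmax probabilities are computed with max-subtraction; a $10^{-300}$
floor guards the log at extreme $\beta$.  Log-likelihoods accumulate in
log space.  The WAIC identity, tendency conservation, telescoping
information gain and nesting equalities are enforced by tests at
$10^{-12}$–$10^{-10}$.  Ties in the best option are broken toward the
lowest index (they cannot occur under the 0.25/0.50/0.75 structure).
Degenerate inputs error early with the offending row, column, trial or
index named.

## Limitations

The sampler is a random-walk scheme, not gradient-based: at the paper's
full scale it needs the full 1000 + 1000 iterations to mix well, and
weakly identified participants can still show split R-hat above 1.05 at
desk scale (recorded as warnings).  WAIC is the only model-comparison
criterion implemented.  The dynamic-weight (time-varying $w_A$) model
and directed-exploration partner policies are out of scope.  Because the
generator treats selection as exogenous, group contrasts of fitted
parameters on default synthetic data estimate a true effect of zero;
planted associations via the generator hooks are the way to exercise
those analyses end to end.
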