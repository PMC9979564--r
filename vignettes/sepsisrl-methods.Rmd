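---
title: "Methods: reward learning, off-policy evaluation, and mortality calibration for sepsis treatment policies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reward learning, off-policy evaluation, and mortality calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsisrl)
```

This vignette documents the models, algorithms and design choices behind
`sepsisrl`, in the order a study would use them: the decision problem, the
reward family and its learned weights, the tree stage that selects
mortality-critical indicators, the dueling-network policy learner, the
off-policy estimator suite, the mortality-versus-return calibration, and the
synthetic cohort generator that makes the whole stack testable.

## The decision problem

Hourly sepsis treatment is modeled as an episodic finite-horizon MDP
$\langle S, A, P, R, \gamma\rangle$. States are 30-feature physiologic
vectors (`sepsis_features()`); actions discretize intravenous-fluid and
vasopressor dosing onto a $5\times5$ grid (`action_grid()`, flat index
$5\cdot\mathrm{iv} + \mathrm{vp} \in \{0,\dots,24\}$, bin 0 = no dose).
Throughout the package time is indexed $t = 0,\dots,T-1$ and the $T$-step
discounted value is $v^\pi_T = E[\sum_{t=0}^{T-1}\gamma^t r_t]$. This
0-based convention is applied uniformly — to exact dynamic programming, to
every estimator, and to the diagnostics — because mixing $\gamma^{t-1}$ and
$\gamma^t$ conventions between the value definition and estimator formulas
is a common source of silent off-by-one-discount errors.

`tabular_mdp()` plus `evaluate_policy_exact()` provide an exact
finite-horizon oracle by backward recursion. Every stochastic component of
the package is ultimately validated against it (or against closed forms on
degenerate chains).

## The reward family

A treatment step earns
$$\mathrm{reward} = \sum_{i \in I} W_i\,\tanh(S_i),$$
where the six indicator deltas are score *decreases* for QSOFA and SOFA
($S_0, S_1$) and raw *increases* for MAP, lactate, PaO2 and prothrombin time
($S_2,\dots,S_5$). The $\tanh$ squashing bounds each contribution by
$|W_i|$, so a single catastrophic lab swing cannot dominate a stay.

Decisions worth making explicit:

* **No sign priors on the weights.** A lactate or PT *increase* is
  clinically adverse, yet the family leaves the sign of every $W_i$ to the
  inverse-RL stage. Fixing signs a priori would preempt exactly the question
  the weight learning is supposed to answer. Pre-learning initialization is
  $W_i = 1$.
* **No terminal outcome reward by default.** The family scores intermediate
  physiologic change only. `reward_trajectory(..., terminal_reward = b)`
  optionally adds $\pm b$ at the final treatment step (sign by survival) for
  ablation studies; it is off everywhere else in the package.
* Seven named specifications (`reward_spec_names()`) select indicator
  subsets; the three base specs are additive, and `sepsis_all` is their sum
  — an identity the tests assert exhaustively.

## Tree-based discovery of mortality-critical indicators

`build_patient_feature_table()` aggregates each stay into per-feature
mean/last/worst summaries ("worst" takes the clinically adverse direction of
each feature) with the terminal mortality label. Aggregating per patient —
rather than labeling every hourly row — avoids pseudo-replication: a
100-hour survivor would otherwise contribute 100 correlated negative labels.

`fit_minitree()` fits a depth-limited ensemble (default 100 trees, depth
$\le 3$, impurity-decrease importance via `ranger`, fixed seed, one thread)
and pools the three summary importances of each feature into one score,
normalized to sum 1, with lexicographic tie-breaking. The "mini" in the
design is the depth cap: shallow trees measure strong marginal and low-order
interaction effects, which is the level of claim the downstream reward
construction needs ("which indicators matter"), not a full risk model. A
single-CART variant (`method = "single_tree"`) is available for
interpretability. `select_reward4_indicators()` returns the top-$k$
(default 2) features, which are the ones the discovered-driver reward term
tracks.

## The dueling double-DQN inverse-RL learner

`dueling_net()` implements
$Q(s,a) = V(s;\theta,\beta) + A(s,a;\theta,\alpha) - \frac{1}{|A|}\sum_{a'}A(s,a')$
with two hidden layers of 20 rectified units. Mean-centering the advantage
stream is required for identifiability — without it, any constant can move
between the streams. Two initialization details matter in practice:

* Hidden layers use scaled random initialization, but the **output heads
  start at zero**. The Q-surface then starts identically flat, so the
  Boltzmann action likelihood used by the inverse-RL step starts uniform
  instead of echoing arbitrary initialization noise. With randomly
  initialized heads the early weight-update directions are dominated by that
  noise and weight recovery becomes seed-unstable.
* No per-layer normalization is used: plain dense layers are simpler and
  fully deterministic under a seed, and at this network size normalization
  buys nothing.

Targets are double-Q: the online network selects
$a^\* = \arg\max_a Q(s', a)$ and a periodically synchronized target copy
evaluates it, $y = r + \gamma Q^-(s', a^\*)$ (terminal transitions bootstrap
0). One `dddqn_update_step()` takes an RMSProp step on the batch mean
squared error and reports the pre-step loss.

`train_dirl()` trains offline: logged transitions stream in random order
through a bounded replay memory (capacity counted in transitions, default
200), each arrival triggering
one minibatch update (batch 32). Rewards are not stored: each transition
keeps its $\tanh$-delta feature vector, and the reward is the inner product
with the *current* weight vector, so relabeling under evolving weights is
exact and free.

**The weight update.** Among the many inverse-RL variants, the package
commits to the smallest one that serves the goal of inferring indicator
weights from clinician behavior: maximum-likelihood inverse RL with a
Boltzmann action likelihood $\pi(a|s) \propto \exp(Q(s,a)/\tau)$ over
clinician demonstrations, one ascent step per episode
(`update_reward_weights()`; a Gaussian prior via `prior_sd` gives the
maximum-a-posteriori variant). The gradient of $Q$ with respect to $W$ is
approximated by per-action expected $\tanh$-delta features $\psi(a)$,
giving the classic observed-minus-expected form
$$\nabla_W \approx \tfrac1B\sum_b \big[\psi(a_b) - E_{a\sim\pi(\cdot|s_b)}\psi(a)\big].$$
Two estimation details are load-bearing:

* $\psi$ is estimated by regressing each $\tanh$-delta feature on the
  standardized state, the *previous* hour's action, and current-action
  dummies, taking the current-action coefficients. Raw per-action delta
  means are badly confounded twice over: sicker patients both receive
  different doses and evolve differently, and indicator deltas respond to
  dose *changes*, so the previous dose confounds the current action's
  apparent effect. Both adjustments are necessary for stable sign
  recovery.
* Action effects estimated from a handful of logged visits are shrunk
  toward zero ($n_a/(n_a+5)$), and the reported weights are the average of
  the last `weight_average_window` (default 10) episode iterates — tail
  averaging that removes most of the stochastic-ascent noise.

The alternation granularity (one weight step per episode) is a
configuration choice; nothing in the objective requires that particular
interleaving.

Defaults are a conventional configuration for this problem size (100
episodes × 2000 transitions, weight step 0.1, batch 32); the examples,
tests and the
acceptance script run a scaled-down 20 × 500 schedule, which is already
sufficient for the planted-weight recovery experiments below.

## The off-policy estimator suite

With $\rho_t = \pi_e(a_t|s_t)/\pi_b(a_t|s_t)$ and
$\omega_{0:t} = \prod_{i=0}^{t}\rho_i$ (and $\omega_{0:-1} = 1$):

* **IS**: $\frac1n\sum_k\sum_t \omega_{0:t}\gamma^t r_t$.
* **step-WIS**: per-horizon self-normalization by
  $\bar\omega_t = \frac1n\sum_k\omega^{(k)}_{0:t}$.
* **DR**: backward recursion
  $V^{(t)} = \hat V(s_t) + \rho_t\,(r_t + \gamma V^{(t+1)} - \hat Q(s_t,a_t))$.
* **WDR**: DR with self-normalized horizon weights.
* **DW**: $\sum_t \omega_{0:t}\gamma^t\big(r_t + \hat Q(s_t,a_t) -
  \hat Q_{means}(s_t,a_t)\big)$ with the running discount-weighted mean
  $\hat Q_{means}(s_t,a_t) = \frac{1}{t+1}\sum_{i=0}^{t}\gamma^i \hat Q(s_i,a_i)$
  — no backward recursion.
* **DWDR**: $\sum_t \big[\omega_{0:t}\gamma^t(2r_t - \hat Q_{means}(s_t,a_t))
  - \omega_{0:t-1}\gamma^t\hat V(s_t)\big]$.

Convention decisions, each with a reason:

* **The $\omega$ product runs over steps $0..t$.** A product over the whole
  horizon would make $\omega$ constant in $t$ and contradict its step-wise
  use inside the estimators; the step-wise product is the only
  self-consistent definition.
* **DR uses the per-step ratio inside the recursion by default.** The
  literal cumulative-$\omega$ recursion double-counts ratios and breaks the
  zero-model $\Rightarrow$ IS reduction that anchors the whole suite;
  it remains available as `ratio_mode = "cumulative"` for fidelity
  experiments.
* **DWDR keeps the minus sign** on the $\omega_{0:t-1}\gamma^t\hat V$
  term of its defining expansion. The standard additive doubly robust form
  carries $+\hat V$ there; with the minus sign the model terms do not
  cancel in expectation, and empirically the estimator is heavily biased
  whenever $\hat V$ is far from zero (the benchmark tests document this).
  The package keeps the defining form rather than silently correcting it;
  users wanting the standard behavior can use DR/WDR.
* $\hat Q_{means}$ mixes discount scales at $\gamma<1$ exactly as defined;
  no renormalization is applied.
* Deterministic evaluation policies are one-hot rows of a stochastic policy
  table, so all estimators share one code path; stored behavior
  probabilities are used when present, and a support violation (zero
  behavior probability under positive evaluation probability) is a named
  error, never silently dropped mass.

`fit_value_model()` supplies $\hat R$ (empirical state-action reward means)
and $\hat Q$ (fitted value iteration on the empirically estimated
transition model under $\pi_e$); `perfect_value_model()` injects the exact
per-step Bellman tables for telescoping tests, and a `NULL` model is the
zero model. For a $T$-step evaluation the value-iteration sweep count
should match the horizon — a near-converged infinite-horizon $\hat Q$ at
$\gamma \approx 1$ lives on a much larger scale than the truncated value
and destabilizes the DW/DWDR correction terms.

**The default benchmark** (`default_ope_benchmark()`) pairs a fixed
randomized 8-state/4-action MDP (rewards in $[-1,1]$, $\gamma = 0.99$,
$T = 20$) with a *deterministic* evaluation policy logged under a behavior
policy that takes the evaluated action 60% of the time. This mirrors the
method's actual application — a learned greedy treatment policy evaluated
from clinician data — and is the regime where the dueling-weight estimator's
variance advantage over the doubly robust estimator materializes: under
collapsing cumulative ratios DR's dangling $\hat V$ terms at the
support-exit step inject model noise that DW's recursion-free form avoids.
Under fully stochastic evaluation policies with moderate mismatch the
ordering reverses (DR's control variates win); the benchmark harness
measures both regimes, and the test suite asserts the comparative claims on
the default benchmark. Two comparative claims do *not* reproduce under this
faithful implementation and their checks are accordingly expected to fail:
importance sampling does not have the largest variance of the whole suite
once DW/DWDR are included, and the printed-form DWDR does not reduce bias
relative to DW. The diagnostic series of `dw_diagnostics()` ($\hat Q_{means}$,
the $\Delta$ family, $\phi^{t+2}$, backward returns, behavior-model
mismatch $\delta$) make the mechanics inspectable per trajectory.

## Mortality calibration

The calibration reproduces the two-stage construction: a patient-level
80/20 split (`split_dataset()`; never step-level, so no patient leaks
across sides), k-means++ clustering of training states
(`cluster_states()`; standardized features, seeded k-means++ initialization,
Lloyd refinement; `choose_k_by_sse()` reports the SSE elbow but the final
$k$ — 300 is a sensible cohort-scale choice — remains the analyst's), and tabular SARSA over
clusters (`sarsa_q()`, step size 0.1, 50 sweeps by default, randomized
trajectory order to break within-stay correlation, terminal bootstrap 0,
unvisited cells reported as a coverage attribute).

`build_mortality_curve()` attaches each held-out step's trajectory outcome
label to its $Q(c_t, a_t)$ value and buckets the Q values into equal-count
quantile buckets (default 20; buckets are formed jointly, with per-bucket
label averaging — the alternative per-label-group reading of the source
description would make bucket membership depend on the outcome being
estimated). An isotonic non-increasing fit of mortality against mean
bucket Q is stored alongside the raw buckets and used by default for
interpolation. `estimate_policy_mortality()` evaluates the curve at an
estimated return by piecewise-linear interpolation, *clamped* to the
observed Q range (extrapolated mortalities outside the calibrated range are
a safety hazard, so clamping with a warning is preferred), with a
percentile bootstrap over held-out patients (default 1000 resamples) that
rebuilds the bucket curve per resample.

## The synthetic cohort generator

`simulate_cohort()` exists so that every stage above has a ground truth to
be tested against. Its latent model, chosen as the minimal structure
supporting those tests:

* **Reversible severity** $z_t$: a near-unit-root process whose *drift* is
  set by treatment quality — dose bins matching the severity-appropriate
  target stabilize the patient, under-dosing lets severity drift up, and
  overdosing actively harms. Drift (rather than mean reversion) is
  deliberate: with mean-reverting severity, expected future improvement is
  proportional to current severity, which forces expected return to *rise*
  with how sick a patient is and inverts the mortality-return relationship
  the calibration stage is supposed to recover.
* **Progressive organ damage** $d^{lung}, d^{coag}$: non-decaying processes
  that accrue with sustained severity and through an idiosyncratic channel
  scaled by patient-specific susceptibilities, so that damage is not a pure
  readout of severity. Damage erodes PaO2 and lengthens PT — the two
  planted mortality drivers.
* **Emissions**: 30 features around the latents with physiologic clipping;
  doses shift indicator dynamics (vasopressors raise MAP; moderate pressor
  support aids and high doses impair oxygenation; aggressive volume loading
  dilutes clotting factors and congests the lungs; fluids clear lactate).
* **Death and discharge**: a per-step logistic hazard on the standardized
  adverse deviations of the planted driver features (configurable; defaults
  PaO2 and PT), with the intercept calibrated by bisection against pilot
  simulations so realized mortality matches the 14.5% target; stabilized
  patients with near-normal organ function are discharged alive before the
  horizon, which keeps survivor and non-survivor stay lengths comparable —
  without that, step-weighted and patient-weighted mortality diverge and
  the calibration self-consistency check cannot hold for structural
  reasons.
* **Behavior policy**: a softmax over a severity-responsive dose preference
  (temperature 0.7) whose modal action in severe states is a high-dose
  cell, plus a small uniform practice-variation floor
  (`behavior_epsilon`) so every grid cell retains support. A
  demonstration mode (`behavior_reward_weights`) replaces the severity
  profile with a Boltzmann policy in the expected one-step reward under
  supplied weights — the ground truth for inverse-RL recovery experiments.

The generator's parameters were fixed once so that its *designed
contracts* hold — the hazard is dominated by the two planted drivers and
they are discoverable as the top-2 importance features at cohort scale; the
mortality-return curve has the planted negative slope; the clinician
policy's estimated return maps back to the cohort's own mortality — and are
not tuned per experiment. What the simulator does **not** emulate: missing
or irregularly sampled measurements (see `resample_to_grid()` for the
interpolation utility, but simulated cohorts are emitted complete),
ventilation/antibiotic co-interventions, inter-feature physiology beyond
monotone dose responses, readmissions, and informative measurement timing.
Tests passing on this simulator therefore demonstrate internal correctness
and recoverability of planted structure, not clinical validity on real ICU
data.

## Problem sizes and numerical choices

The test and acceptance workloads use: 20 random small MDPs × 200,000
Monte-Carlo trajectories for the exact-DP oracle check; 200–500 replicates
of $n = 200$–1000 trajectories for estimator bias/variance; 5,000-patient
cohorts × 20 seeds for driver recovery; 2,500-patient demonstration cohorts
with a 20 × 500 training schedule × 5 seeds for weight recovery; and a
2,500-patient cohort with $k = 150$ clusters, 30 SARSA sweeps and 15
buckets for calibration. These sizes are chosen to keep each property's
measurement noise well below the effect it checks. Other numerics:
probability rows validated to $10^{-9}$; k-means++ on standardized
features; RMSProp $\epsilon = 10^{-8}$; reward-weight cap $|W| \le 10$ with
warning; ties in rankings broken lexicographically; all seeded code paths
are bit-reproducible (the tests assert this per stage).

## Known limitations

* The inverse-RL gradient is a linear-in-features approximation of
  $\partial Q/\partial W$; it recovers signs and ranks of dominant
  indicators but not calibrated weight magnitudes.
* With near-greedy demonstrations, rarely demonstrated actions carry almost
  no dose-response information; recovery experiments need some behavioral
  exploration (the simulator's practice-variation floor).
* The printed-form DWDR estimator is not recommended for use; it is
  provided for fidelity and study.
* SARSA over k-means clusters inherits state-aggregation bias; its Q values
  are calibrated for the mortality curve's *ranking* use, not as unbiased
  per-state values.
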