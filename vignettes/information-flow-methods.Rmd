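---
title: "Quantifying information flow between brain, body and environment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying information flow between brain, body and environment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(loopflow)
```

## The question

An embodied agent can solve a task with its brain, with its body's
interaction with the environment, or with a mixture of both. `loopflow`
quantifies how the complexity of a task is distributed over these parts by
measuring, in bits, the strength of every directed connection in the
sensorimotor loop of a small simulated agent, after the agent's behaviour
has been optimized for the task.

The model system is a two-wheeled agent on a closed racetrack. Each wheel
spins either slow or fast, so there are four movements: both fast moves the
agent 0.6 length units straight ahead, both slow moves it 0.2, and a mixed
command rotates it 10 degrees toward the slow wheel and moves it 0.4. Two
whisker-like binary sensors, mounted at ±30° from the heading and anchored
at the body perimeter, report only whether they touch a wall. The agent
dies when its body circle touches a wall; the task is to stay alive.
Varying the sensor length changes how much of the task the morphology
solves: very short whiskers warn too late, very long ones touch the walls
almost everywhere and carry little information.

## The probabilistic model

The loop is a discrete time-homogeneous Markov process over world $W$,
sensors $S = (S^1, S^2)$, actuators $A = (A^1, A^2)$ and controller
$C = (C^1, C^2)$, all loop nodes binary. Because the agent has no access to
$W$, the world is marginalized out. Under the assumption that the
environment influences the loop only through the sensors, the marginal
process factorizes exactly as

$$P(s_t, a_t, c_t, s_{t+1}, a_{t+1}, c_{t+1}) =
  P(s_t, a_t, c_t)\,\prod_i P(a^i_{t+1} \mid s_t, c_t)\,
  \prod_j P(c^j_{t+1} \mid s_t, c_t)\, P(s_{t+1} \mid s_t, a_t),$$

which `intrinsic_from_world_model()` verifies by exact summation over the
world states (this assumption is not cosmetic: with a fully general initial
coupling $P(s, a, c \mid w)$ the product form fails, because the world
state can then correlate actuators and controller with the next sensor
reading even given $(s_t, a_t)$).

The environment enters through two Monte-Carlo estimated channels, sampled
once per sensor length from random-policy rollouts
(`sample_channels()`):

* the **sensor channel** $\gamma = \tilde P(S_{t+1} \mid S_t, A_t)$ and the
  induced initial coupling $\tilde P(S_t \mid A_t)$, and
* the **goal channel**
  $\tilde P(G \mid S_{t+2}, S_{t+1}, S_t, A_{t+2}, A_{t+1}, A_t)$, where
  $g = 1$ means the agent is alive after the window's two movements.

Rollouts draw uniformly random wheel commands from uniformly random
collision-free poses. Two sampling conventions had to be fixed that the
two-step model itself does not determine. First, transitions into death
contribute to the goal channel — that is its purpose — but not to
$\gamma$, because $\gamma$ conditions on the loop continuing (the
factorized planning model has no death state in $S$). Second, when an agent
dies mid-window, its pose freezes at the colliding pose; sensors are still
read there and actions are still drawn (but not executed) for the two
records needed to close the open goal windows, after which the walker
respawns. Episodes are capped at 500 records so that pose coverage stays
broad even when a random policy survives for long stretches. All counts
receive one pseudo-count per cell before normalization
(`smooth_and_normalize()`), which guarantees the strict positivity that the
framework assumes throughout, with negligible bias at $10^5$ or more
samples.

## Optimizing behaviour: planning as inference

The policy consists of the latent kernels
$\beta = P(A_{t+1} \mid S_t, C_t)$ (per actuator node) and
$\alpha = P(C_{t+1} \mid S_t, C_t)$ (per controller node), plus the free
initial components $P(A_t)$ and $P(C_t \mid A_t, S_t)$; the initial sensor
coupling is pinned to the sampled $\tilde P(S_t \mid A_t)$, so the agent is
not conditioned on any particular initial observation. These distributions
are optimized to maximize the two-step survival likelihood $P(g_1)$ by
expectation-maximization (`optimize_policy()`), which on this model is the
statistical realization of the information-geometric em-algorithm and is
monotone in $P(g_1)$ — the package asserts monotonicity to $10^{-12}$ on
every run, and the test suite checks each iteration against a brute-force
full-joint Bayes update.

The E-step conditions the two-step joint on survival; the M-step replaces
every free conditional simultaneously with the corresponding posterior
conditional, pooling the expected counts of both time slices for α and β
so that time homogeneity is preserved. Simultaneous updating is the
simplest scheme consistent with the model; since each M-step component
maximizes the same expected complete-data log-likelihood, monotonicity is
unaffected by the order. One implementation detail is worth recording:
$C_{t+2}$ is a leaf of the two-step graph, so its posterior conditional
given $(S_{t+1}, C_{t+1})$ equals the current α exactly, and the posterior
only needs to be materialized over the 14 remaining binary variables. This
is an algebraic identity, not an approximation, and is tested against the
full-joint computation.

Three controller architectures restrict which parents the policy kernels
may use: `fully_coupled` keeps all four connections S→A, C→A, S→C, C→C;
`controller_driven` removes S→A (no reactive shortcut — everything must
pass through the controller); `reactive` removes C→A (the controller
cannot influence behaviour). Masked parents are structurally absent: the
M-step marginalizes them out of the pooled posterior counts before
normalizing, so for instance the optimized β of a reactive agent is
exactly constant in $C$.

EM converges to local optima that depend on the random starting
distributions. This is used deliberately: many flat-Dirichlet restarts
probe different strategies with similar success probabilities. Restart
results are reported individually, and both the mean over restarts and the
best restart are available as summaries, since either aggregation is a
defensible reading of a multi-restart protocol.

## The seven measures

Each measure is the KL divergence from the optimized two-step joint (goal
variable marginalized out — the measures concern the loop, not the task)
to the closest member of a *split* product family lacking the measured
connections:

$$\Psi = \inf_{Q \in M} D(P \,\|\, Q).$$

Because both $P$ and the split families factorize along the loop graph,
every measure has a closed form as a sum of conditional mutual information
terms over both transitions, in bits:

| measure | closed form (per transition $\tau$) | meaning |
|---|---|---|
| $\Phi_T$ | $\sum_j I(C^j_{\tau+1}; C^{\setminus j}_\tau \mid C^j_\tau, S_\tau)$ | integrated information in the controller |
| $\Psi_S$ | $I(S_{\tau+1}; S_\tau \mid A_\tau)$ | morphological computation |
| $\Psi_R$ | $\sum_i I(A^i_{\tau+1}; S_\tau \mid C_\tau)$ | reactive control |
| $\Psi_A$ | $I(S_{\tau+1}; A_\tau \mid S_\tau)$ | action effect |
| $\Psi_{SI}$ | $\sum_j I(C^j_{\tau+1}; S_\tau \mid C_\tau)$ | sensory information |
| $\Psi_C$ | $\sum_i I(A^i_{\tau+1}; C_\tau \mid S_\tau)$ | control |
| $\Psi_{TIF}$ | $I(S_{\tau+1}; S_\tau, A_\tau) + \sum_i I(A^i_{\tau+1}; S_\tau, C_\tau) + \sum_j I(C^j_{\tau+1}; C_\tau, S_\tau)$ | total information flow |

`split_projection()` performs the minimization explicitly (alternating
minimization over the product family; the objective separates over
components, so a sweep converges immediately) and the test suite verifies
that the projection agrees with each closed form to $10^{-6}$ on random
factorized systems. The total information flow upper-bounds every other
measure because its split family is contained in all the others; the chain
rule of mutual information makes this an exact inequality, which is
asserted on every evaluated system.

## What the generator emulates, and what it does not

The simulator is the data-generating process of the study: there is no
external data. Its defaults are the study conditions — sensor lengths
0.5–2.75 in steps of 0.25, two binary sensors at ±30°, body radius 0.5, a
closed corridor track. The published track is only pictured, never given
as coordinates, so the default corridor (outer rounded rectangle 40 × 25,
corridor width 6, polygonized arcs) is this package's own choice, made
once: a closed circuit with straights and curves whose width makes the
sensor-length sweep span the regimes from "too short to warn" (0.5, reach
1.0 against a 0.6 fast step) to "almost always touching" (2.75, reach 3.25
against a half-width of 3). The mixed-move turn, described as
approximately 10°, is frozen to exactly 10° for reproducibility.
Consequently absolute measure magnitudes are tied to this geometry and are
*not* comparable against any particular published panel; only signs,
orderings and qualitative shapes transfer. Passing tests therefore show
that the pipeline reproduces the structural and qualitative claims — exact
kinematics, exact factorizations, monotone EM, structural zeros, the
upper bound, and the direction of the trends — not any absolute calibration
against a physical system.

## Numerical choices and problem sizes

* Dense exact arithmetic on probability tables; the largest joint (18
  binary loop variables plus the goal) has $2^{19}$ states, well within
  dense range, and normalization is preserved to $10^{-12}$ by every
  operation.
* Logarithms are base 2 everywhere ($0 \log 0 := 0$); all measures are in
  bits.
* Controller nodes are binary by default. The published description fixes
  sensors and wheels as binary; the controller cardinality is not stated,
  and binary nodes are the minimal choice that leaves two controller nodes
  with cross-connections to integrate.
* Desk-scale protocol (package defaults): $2 \times 10^5$ recorded samples
  per sensor length, 20 restarts, at least 200 EM iterations, stopping
  tolerance $10^{-5}$ on the likelihood change. The published protocol
  ($2 \times 10^7$ samples, 100 restarts, at least 1000 iterations) is
  available via `paper_scale = TRUE` or the corresponding arguments. The
  desk scale keeps a full fully-coupled sweep in the minutes range on one
  CPU while leaving the qualitative results stable.
* Smoothing: one pseudo-count per cell. The goal channel has 4096
  contexts, so at desk scale rare contexts leave noticeable smoothing mass;
  this biases unvisited contexts toward 50% survival but never removes the
  strict positivity the EM posterior requires.
* `split_projection()` defaults: tolerance $10^{-10}$, cap 5000 sweeps
  (two suffice for these separable families).
* Seeds: every stochastic stage takes an explicit seed; sampling for
  sensor length $L$ uses `seed + round(100 L)` so each length gets an
  independent, reproducible stream.

## A worked sweep

```{r sweep, eval = FALSE}
config <- sweep_config(architectures = "fully_coupled", seed = 1)
res <- run_sweep(config)
trend_statistics(res)
autoplot(res)
```

On the default track at desk scale the fully coupled sweep shows the
package's central qualitative result, which the test suite asserts: the
per-length mean of integrated information $\Phi_T$ is negatively rank-
correlated with sensor length while morphological computation $\Psi_S$ is
positively rank-correlated — the more the body–environment interaction
carries the task, the less information the controller integrates. The
same machinery exposes the accompanying diagnoses: $\Psi_C$ near zero
where the controller is behaviourally irrelevant, and the structural zeros
of the restricted architectures.

## Known limitations

* The track geometry, body radius and mount angles being package choices,
  absolute bit values are only meaningful relative to this configuration.
* The goal channel conflates "dead by t+2" windows with frozen-pose sensor
  readings after death; alternative conventions (e.g. discarding death
  windows' trailing slices) would change the channel in rarely-visited
  contexts.
* Monte-Carlo channels at desk scale leave smoothing-dominated rows in the
  goal channel; likelihoods are therefore mildly regularized toward 0.5 in
  unvisited regions.
* EM finds local optima by design; statements about "the" optimal policy
  are always statements about the best or the population of restarts.
* The framework assumes strictly positive distributions; degenerate
  hand-built kernels are supported by the table algebra (for oracles and
  edge cases) but not by the planner, which relies on smoothed channels.
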