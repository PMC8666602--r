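# loopflow

Information flow decomposition in the sensorimotor loop of an embodied
agent.

`loopflow` is for researchers in embodied cognition, information theory and
artificial life who want to quantify *where* the complexity of a task is
solved: in the agent's brain (controller), in its body's interaction with
the environment (morphology), or in the connections between them. The
package builds the complete pipeline around a toy model system — a
two-wheeled agent with binary whisker sensors that must avoid the walls of
a closed racetrack — and measures every directed information flow of its
sensorimotor loop in bits, on behaviour that has been optimized for
survival.

## The model and the measures

The loop over sensors S, actuators A and controller C (two binary nodes
each) is a time-homogeneous Markov process. Marginalizing the world state
out — the environment influences the loop only through the sensors — gives
the intrinsic process

P(s,a,c) · ∏ᵢ P(aⁱ′ | s,c) · ∏ⱼ P(cʲ′ | s,c) · P(s′ | s,a),

whose environment kernels are estimated by Monte-Carlo rollouts: the sensor
channel γ = P̃(S′ | S, A) and a goal channel P̃(G | S,A over three slices)
with g = 1 meaning the agent survives two movements. Behaviour is
optimized by *planning as inference*: the policy kernels
β = P(A′ | S, C) and α = P(C′ | S, C) plus the free initial components are
latent distributions, fitted by the (monotone) EM algorithm to maximize
P(g₁), from many random restarts, under one of three architectures
(`fully_coupled`, `controller_driven` — no S→A edge, `reactive` — no C→A
edge).

Each information-flow measure is a KL projection Ψ = inf_{Q∈M} D(P‖Q) onto
a split family M lacking the measured connections, and equals a closed-form
sum of conditional mutual informations (base-2):

- Φ_T — integrated information: Σ_τ Σ_j I(Cʲ_{τ+1}; C^{∖j}_τ | Cʲ_τ, S_τ)
- Ψ_S — morphological computation: Σ_τ I(S_{τ+1}; S_τ | A_τ)
- Ψ_R — reactive control: Σ_τ Σ_i I(Aⁱ_{τ+1}; S_τ | C_τ)
- Ψ_A — action effect: Σ_τ I(S_{τ+1}; A_τ | S_τ)
- Ψ_SI — sensory information: Σ_τ Σ_j I(Cʲ_{τ+1}; S_τ | C_τ)
- Ψ_C — control: Σ_τ Σ_i I(Aⁱ_{τ+1}; C_τ | S_τ)
- Ψ_TIF — total information flow (upper bound for all of the above)

Sweeping the sensor length from 0.5 to 2.75 changes how much of the task
the morphology absorbs; the central qualitative result is the antagonism
between Φ_T (falling with sensor length) and Ψ_S (rising).

## Worked example

```r
library(loopflow)

track <- default_track()
ch <- sample_channels(track, sensor_config(length = 1.5),
                      n_samples = 2e5, seed = 1)
ch$goal
#> <goal_channel> 173,757 windows, overall survival 0.8593

fits <- optimize_policy(ch, architecture("fully_coupled"),
                        n_restarts = 5, seed = 1)
fits[[1]]
#> <loop_fit> fully_coupled, P(g1) = 0.975943 after 400 iterations (converged)

measure_panel(build_loop_joint(fits[[1]]$policy, ch$sensor),
              sensor_length = 1.5, architecture = "fully_coupled")
#> # A tibble: 1 × 9
#>   sensor_length architecture  phi_T psi_S psi_R  psi_A psi_SI psi_C psi_TIF
#>           <dbl> <chr>         <dbl> <dbl> <dbl>  <dbl>  <dbl> <dbl>   <dbl>
#> 1           1.5 fully_coupled 0.189  2.19 0.455 0.0193  0.725 0.335    4.33
```

Under a random policy only 86% of three-step windows end alive; the
optimized policy survives 97.6% of the time. At this sensor length the
body–environment interaction carries most of the information
(Ψ_S ≈ 2.2 bits — the sensors predict themselves through the world), the
controller integrates comparatively little (Φ_T ≈ 0.19 bits), and the
total flow Ψ_TIF bounds every component. A full sweep is one call:

```r
res <- run_sweep(sweep_config(architectures = "fully_coupled", seed = 1))
trend_statistics(res)   # Spearman trends per measure vs sensor length
autoplot(res)           # per-measure panels
```

`tidy()` and `glance()` work on fits, `autoplot()` on tracks and sweep
results, and everything tabular is a tibble. A thin command-line wrapper
with `sample` / `optimize` / `measure` / `sweep` subcommands is installed
at `inst/cli/loopflow.R`; the sweep accepts a YAML config (schema in the
script header) and writes `results.csv`, `trends.json` and a `figures/`
directory.

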