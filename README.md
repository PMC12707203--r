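# wslscommons

Win-Stay, Lose-Shift (WSLS) self-organization of common-good usage.

A population of `Nu` users shares `Ng` congestible goods — servers in a
mobile network, grazing patches, transport lines — whose per-attempt
failure probability `P_i(F)(n_i)` rises with the number of simultaneous
users `n_i`. Users have no information beyond their own outcomes and never
communicate. Under WSLS each user keeps using its current good until it has
accumulated its *tolerance* of failures, then shifts to a random other
good. This package provides, for that setting:

* **Quality models** — the M/M/c/k server failure model
  `P(F) = P(L) + (1 − P(L)) P(D)` (blocking at a full `k`-place buffer,
  plus timeout exceedance of the round-trip delay `2d + wait + service`
  against `τ`), and generic monotone failure curves for non-queueing
  commons.
* **Mean-field dynamics** — the population flow
  `ṅ_i = −λ_u n_i P_i(F)(n_i) + (1/(Ng−1)) Σ_{j≠i} λ_u n_j P_j(F)(n_j)`,
  its tolerance-typed extension, trajectory integration with workload
  schedules, and equilibrium solvers for the balance conditions
  `n_1 P_1(F) = … = n_Ng P_Ng(F)` (and their typed analogues).
* **The equalized-quality ideal** — the ideal-free-style distribution `n*`
  at which every used good has the same failure probability `p*`,
  tolerance-vector design realizing it
  (`Σ_k Nu(k) T_i(k)/Σ_j T_j(k) = n_i*`), and hybrid-population theory:
  the critical selective fraction `γ_c = (Nu − Ng·n*_min)/Nu` and the
  selective weights for any `γ ≥ γ_c`.
* **A seeded discrete-event agent simulator** (C++ core) with fixed or
  *adaptive* per-good tolerance: agents estimate per-good failure rates
  from their own attempts (`x ← (1−β)x + β·T/R`) and move tolerance units
  toward their best-estimated good, which drives the whole population to
  the equalized-quality distribution without any coordination.

## Worked example

The benchmark system: 1000 users, three M/M/1/10 servers with capacities
{100, 200, 400} requests/s, latencies {10, 20, 30} ms, timeout 100 ms,
workload ρ = 0.75 (so each user emits λ_u = 0.525 requests/s).

```r
library(wslscommons)
sys <- table1_system(rho = 0.75)

solve_equilibrium(sys)
#> WSLS equilibrium (homogeneous population)
#>   n      : 133.610, 291.202, 575.188
#>   P(F)   : 0.07577, 0.03476, 0.01760
#>   mean failure probability: 0.03037 (balance residual 1.78e-15)

ideal_distribution(sys)
#> Equalized-quality ideal distribution
#>   n*  : 106.031, 280.399, 613.570
#>   common failure probability p*: 0.027620
```

The plain WSLS equilibrium overloads the small server (failure 7.6% there
vs 1.8% on the big one, mean 3.0%); the ideal distribution would equalize
everything at 2.76%. Selective tolerance gets there: a hybrid population
needs at least `γ_c = 68.2%` selective users
(`critical_selective_fraction(ideal_distribution(sys))`), and a fully
adaptive population finds it on its own:

```r
sim <- run_simulation(sim_config(sys, duration = 36000, mode = "adaptive",
                                 T0 = 5, beta = 0.1, seed = 11))
summary(sim)
#> steady state over last 3600 samples (smoothing 0.01):
#>   system failure probability: 0.02756
#>   occupancy: 105.92, 280.97, 613.11
#>   per-good failure: 0.02564, 0.02740, 0.02720
```

After ten simulated hours the agents' occupancies (105.9, 281.0, 613.1)
sit on `n*` and the system failure probability is within 0.2% of `p*` —
each agent acting only on its own failure counts.

## Command line

```sh
exec/wsls equilibrium --rho 0.75 --out results/eq
exec/wsls ideal --rho 0.75 --out results/ideal
exec/wsls simulate --config my.yaml --out results/run1
exec/wsls preset dynamic-load --seed 1 --out results/fig7
```

Presets: `wsls-basic` (tolerance-1 WSLS), `adaptive`, `multi-seed`
(15 replicates), `dynamic-load` (hourly workload schedule 0.75, 1.25,
0.75, 1.25, 0.75, 0.5, 0.25, 0.5, 0.75, 1). `--scale f` shrinks `Nu` and
all capacities proportionally (ρ preserved) for quick runs. Every output
directory contains a `manifest.json` (full config echo, seed, package
version) from which the run is reconstructible.

A config file is YAML with flat sections; all keys are optional (defaults
are the benchmark values above) and unknown keys are errors:

```yaml
system:
  Nu: 1000
  tau_ms: 100
  rho: 0.75          # or lambda_u (requests/s); never both
  latency: round-trip
servers:
  - {mu: 100, c: 1, k: 10, d_ms: 10}
  - {mu: 200, c: 1, k: 10, d_ms: 20}
  - {mu: 400, c: 1, k: 10, d_ms: 30}
population:
  tolerance: 5       # fixed-mode tolerance (scalar or per-server list)
learning:
  T0: 5              # initial adaptive tolerance per good
  x0: 0              # initial failure estimate
  beta: 0.1          # learning rate
run:
  mode: adaptive     # or fixed
  duration: 36000    # seconds
  seed: 1
  sample_dt: 1
  shift_rule: uniform
  schedule:          # optional piecewise workload
    - {length: 3600, rho: 0.75}
    - {length: 3600, rho: 1.25}
```

## Package layout

* `R/quality.R` — good/system specifications, M/M/c/k loss and delay.
* `R/meanfield.R` — flows, integration, equilibrium solvers.
* `R/ideal.R` — ideal distribution, tolerance design, hybrid theory.
* `R/simulator.R`, `src/simulator.cpp` — agent simulation and learning.
* `R/config.R`, `R/cli.R`, `exec/wsls` — configs, presets, CLI.
* `vignettes/wsls-commons-methods.Rmd` — models, assumptions, numerical
  choices, limitations.
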