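---
title: "Win-Stay, Lose-Shift self-organization over congestible commons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Win-Stay, Lose-Shift self-organization over congestible commons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wslscommons)
```

## The problem

A population of $N_u$ users shares $N_g$ congestible common goods — here,
servers behind a mobile network, but equally grazing patches, transport
lines, or water sources. Each good's per-attempt failure probability
$P_i^{(F)}(n_i)$ rises with the number of simultaneous users $n_i$. Users
know nothing about the goods and do not communicate; they only observe the
outcomes of their own usage attempts. The Win-Stay, Lose-Shift (WSLS) rule —
keep using your current good, move to a random other one after enough
failures — is about the least information-hungry strategy imaginable, and
this package studies how far it gets a population toward the ideal-free
distribution, in which every used good offers the same quality.

The package has four layers: analytic per-good *quality* models, *mean-field*
population dynamics with equilibrium solvers, the *equalized-quality ideal*
distribution with tolerance-vector design, and a seeded *discrete-event
agent simulation* with fixed or adaptive failure tolerance.

## Per-good quality: the M/M/c/k failure model

A server-backed good is an M/M/$c$/$k$ queue: aggregate Poisson arrivals at
rate $n_i \lambda_u$ (each of the $n_i$ users emits requests at rate
$\lambda_u$), exponential service at rate $\mu_i$ per processor, $c_i$
processors, $k_i$ total places, deterministic one-way latency $d_i$. An
attempt fails when the request is *lost* at a full buffer, or when the
response is *late*, i.e. the return delay exceeds the timeout $\tau$:

$$P_i^{(F)} = P_i^{(L)} + \left(1 - P_i^{(L)}\right) P_i^{(D)}.$$

$P^{(L)}$ is the stationary probability of $k$ in system (PASTA), computed
from the birth–death log-ratios so both tiny and huge offered loads are
stable. $P^{(D)}$ conditions an arrival on acceptance: finding $j$ in
system, its sojourn is Erlang$(j+1, \mu)$ for $c = 1$ (the general $c$ case
uses the hypoexponential wait-plus-service tail), and

$$P^{(D)} = \sum_{j=0}^{k-1} \tilde\pi_j \,
  \Pr\!\left[S_j > \tau - 2d\right],$$

with $\tilde\pi$ the arrival-conditioned non-blocked distribution. Tails are
evaluated through the regularized incomplete gamma function
(`stats::pgamma`), never by summing exponential series.

**Return-delay accounting.** The timeout is charged the *round-trip* latency
$2d_i$ plus the full sojourn (queueing wait plus service). We validated this
choice against the headline numbers the package reproduces: with round-trip
accounting the equalized-quality level of the benchmark system at workload
$\rho = 0.75$ is $p^* = 0.0276$, consistent with the adaptive simulation's
steady state; one-way accounting gives $p^* = 0.0203$, which is not. A
`latency_mode = "one-way"` switch is provided for sensitivity analysis.

**Continuous load.** Mean-field occupancies are continuous, so all queue
formulas accept real $n \ge 0$; at $n = 0$ the failure probability is the
isolated-request tail $e^{-\mu(\tau - 2d)}$, the quantity that decides which
goods the ideal distribution leaves unused.

The benchmark system used throughout (`table1_system()`) is: $N_u = 1000$,
three M/M/1/10 servers with $\mu = \{100, 200, 400\}$ requests/s,
$d = \{10, 20, 30\}$ ms, $\tau = 100$ ms, and workload
$\rho = N_u \lambda_u / \sum_i \mu_i$ (so $\rho = 1$ means
$\lambda_u = 0.7$ requests/s per user).

## Mean-field dynamics and equilibria

For a large homogeneous population the occupancy flow is

$$\dot n_i = -\lambda_u n_i P_i^{(F)}(n_i)
 + \frac{1}{N_g - 1}\sum_{j \neq i} \lambda_u n_j P_j^{(F)}(n_j),$$

whose rest points satisfy $n_1 P_1^{(F)} = \dots = n_{N_g} P_{N_g}^{(F)}$: a
common *failure flux* $\varphi$. With tolerance types — type $k$ accepts
$T_i(k)$ failures on good $i$ before shifting — each flow is divided by
$T_i(k)$ and failure probabilities are evaluated at the total occupancy. A
single type with constant tolerance only stretches time by $1/T$.

**Solvers.** `solve_equilibrium()` bisects on $\varphi$: each good's
$n_i(\varphi)$ is the monotone inverse of $n \mapsto n P_i^{(F)}(n)$
(`uniroot` on $[0, N_u]$), and $\sum_i n_i(\varphi)$ is increasing, so the
outer problem is one-dimensional. This exploits the monotonicity of the
failure curves, which is *asserted* on a grid, not presumed. The typed
solver uses the equilibrium closed form
$n_{ik} = N_u(k)\,(T_i(k)/P_i^{(F)})/\sum_j (T_j(k)/P_j^{(F)})$, which
depends only on the totals, and iterates it with adaptive damping from the
homogeneous equilibrium until the typed balance residual is below $10^{-8}$
(relative). Tests cross-check the bisection solver against an independent
damped Euler iteration of the flow started from uniform.

**Integration.** `integrate_trajectory()` wraps `deSolve::lsoda`
(`rtol = 1e-8`). Workload schedules are piecewise-constant in $\rho$;
integration restarts at each breakpoint so discontinuities are exact, and
the state is renormalized to $\sum_i n_i = N_u$ at output steps to suppress
drift. Stability of the equilibrium is covered by convergence tests (50
random starts), not symbolic Lyapunov machinery.

## The equalized-quality ideal and tolerance design

`ideal_distribution()` computes the occupancies $n^*$ at which every *used*
good has the same failure probability $p^*$ while every unused good would
exceed $p^*$ even empty. The algorithm is water-filling: bisection on $p^*$
with monotone inversion of each failure curve, a good being inactive iff its
zero-load failure limit already exceeds the candidate level.

A typed population attains $n^*$ iff its tolerance vectors satisfy
$\sum_k N_u(k)\, T_i(k)/\sum_j T_j(k) = n_i^*$ — only tolerance *ratios*
matter. `tolerance_profile_for()` constructs such a profile (all types
sharing weights $n_i^*/N_u$, always feasible) or verifies an arbitrary one
to $10^{-9}$. Integer tolerances for agent runs are produced by scaling rows
to a configured total (default $N_g T_0 = 15$) with largest-remainder
rounding. Ties at the minimum of $n^*$ are handled by assigning zero weight
to all tied goods.

A caution on interpretation: the equalized-quality distribution equalizes
per-good failure, it does not minimize the population mean. Under real
congestion ($\rho \gtrsim 0.75$ on the benchmark) it also lowers the mean
relative to the plain WSLS equilibrium, but at light load the two
allocations' means are within a percent of each other and the equalized one
can be marginally *higher*; the robust statement at all workloads is that
the ideal collapses the equilibrium's failure spread to a single level
lying inside it.

For a two-type population with a fraction $\gamma$ of selective users,
feasibility requires
$\gamma \ge \gamma_c = (N_u - N_g\, n^*_{\min})/N_u$;
`hybrid_tolerances()` returns the selective weights
$w_i = (n_i^* - (1-\gamma)N_u/N_g)/(\gamma N_u)$ and refuses $\gamma$ below
$\gamma_c$, quoting the required fraction.

## The discrete-event agent simulation

The simulator (`run_simulation()`, C++ core) executes the full stochastic
system: open-loop Poisson request streams per user (a user may have several
requests in flight, which the aggregate-Poisson queue model requires), FCFS
exponential service, blocking at full buffers, and outcome delivery after
the return latency. Failures are processed in event-time order; ties are
broken by insertion sequence, and one `mt19937_64` engine keyed by the
config seed (with hand-rolled uniform/exponential transforms) makes equal
seeds give bit-identical output across platforms.

Strategy bookkeeping is per *stay*: outcomes of requests emitted before a
shift still count in the metrics but never toward the new stay's failure
counter, since tolerance counters are reset on shifting and cross-good
attribution would corrupt their semantics. Shifts are instantaneous.

**Adaptive tolerance.** Each agent keeps per-good failure estimates
$x_i$ (initialized at $x_0 = 0$) and tolerances $T_i$ (initialized at
$T_0 = 5$). When its failure count on good $i$ reaches $T_i$ after $R$
observed attempts, it (1) smooths the estimate,
$x_i \leftarrow (1-\beta) x_i + \beta T_i / R$ with $\beta = 0.1$;
(2) moves one tolerance unit from $i$ to the good with the smallest
estimate, provided that estimate is strictly smaller and $T_i > 1$ (ties at
the minimum are broken uniformly at random — this matters at start-up, when
all estimates are still $x_0$); (3) shifts, uniformly at random by default,
or proportionally to tolerance under `shift_rule = "proportional"`. The
per-agent tolerance sum is invariant ($N_g T_0 = 15$ with three goods), so
each component stays in $[1, 13]$.

**Metrics.** Every `sample_dt` (default 1 s) the simulator records
instantaneous occupancies, per-good and system failure fractions over the
window, and population-mean tolerances. `summarize_steady_state()` applies
an exponential low-pass filter (constant 0.01) to the system failure series
and averages the trailing 10% of samples; coefficients of variation use a
trailing 2000 s window.

## What the experiments emulate, and what they do not

All inputs are configuration; the package generates its own experiments.
The benchmark conditions are the mobile-network scenario above, with
workloads $\rho \in \{0.25, \dots, 1.25\}$ and, for the dynamic-load
preset, an hourly $\rho$ schedule
$0.75, 1.25, 0.75, 1.25, 0.75, 0.5, 0.25, 0.5, 0.75, 1$. Latencies are
deterministic and users homogeneous in $\lambda_u$; correlated arrivals,
request retries, general service distributions and user mobility are out of
scope. Passing tests therefore show that the strategy self-organizes under
Markovian traffic with homogeneous users — not that it does so under heavy-
tailed service times or adversarial load.

Run lengths are choices of this package (the sources report none): 36000 s
for adaptive runs, which convergence diagnostics show is comfortably past
the tolerance-learning transient at $\rho = 0.75$ (the steady-state failure
level changes by under 2% between half and full duration); 3000–6000 s for
fixed-tolerance runs at moderate-to-high workload; and 80000 s at
$\rho = 0.25$, where shifts are rare and the population needs an order of
magnitude longer to reach its steady state — the same low-workload lag is
visible in the mean-field comparison, which is why agreement is tested on
time-averaged steady states only.

## Numerical choices and degenerate inputs

* Queue stationary distributions via log birth–death ratios; Erlang and
  hypoexponential tails via `pgamma` — both stable at extreme loads.
* Equilibrium and ideal solvers: 80–100 bisection halvings with inner
  `uniroot` tolerance $10^{-13} N_u$; balance residuals are checked after
  solving and reported on the result object.
* The typed self-consistency iteration halves its damping when the residual
  oscillates; it errors rather than returning an unconverged state.
* Mean-field agreement bands in tests are
  $\max(3\,\mathrm{s.e.}, 2\%)$ per good: with $N_u = 1000$ the mean-field
  approximation carries a genuine $O(1/N_u)$ finite-population offset
  (Jensen curvature of $n P^{(F)}(n)$ over the occupancy fluctuations,
  roughly 1–2 users at high workload), which the Monte-Carlo standard error
  of a long time average drops below; a pure 3-s.e. test would reject the
  model for a bias it does not claim to capture.
* A zero tolerance on an occupied good is an error in the typed flow; in
  the agent simulation a zero fixed tolerance is rejected at configuration
  time. Zero workload ($\lambda_u = 0$) freezes the population and is exact
  in both layers.
* `rho` requires all goods to be queue servers (total capacity must exist);
  mixed systems must specify `lambda_u`.

## Reduced-scale runs

`table1_system(scale = )` and the CLI `--scale` flag shrink $N_u$ and every
$\mu_i$ proportionally, preserving $\rho$ and the equilibrium *fractions*.
Note that scaling capacities changes service times relative to the fixed
timeout $\tau$, so failure *levels* differ from full scale (at scale 0.2 the
benchmark's equalized-quality level is $p^* \approx 0.5$, not $0.028$);
reduced-scale runs are for speed and for testing scale-free properties such
as the adaptive population's convergence to its own ideal level.

## Known limitations

* The hybrid closed forms cover two types; general multi-type designs are
  handled only through the attainability condition and its verifier.
* Multi-processor ($c > 1$) delay tails are implemented but the benchmark
  exercises $c = 1$; the $c > 1$ path is covered by shape tests only.
* The continuous-quality variant of WSLS (shift probability proportional to
  experienced quality degradation) is not implemented.
* Mean-field trajectories assume failure probabilities equilibrate
  instantly; at very low workload the simulated population lags the ODE, so
  transient comparisons there are not meaningful.
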