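---
title: "Inferring stochastic rate constants with simulated-likelihood ABC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring stochastic rate constants with simulated-likelihood ABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The inference problem

A discrete-state chemical reaction system with mass-action kinetics is a
continuous-time Markov jump process: reaction $j$ fires with propensity
$a_j(x)$ ($c_j$ for production from nothing, $c_j n_A$ for $A \to \dots$,
$c_j n_A n_B$ for $A + B \to \dots$, and $c_j n_A (n_A - 1)/2$ for
$2A \to \dots$ under the combinatorial convention). The data are a single
exact trajectory observed as copy-number snapshots $X_1, \dots, X_n$ on a
regular grid $t_l = l\,\Delta t$, with the initial state $X_0$ known. The
goal is the posterior of the rate-constant vector
$\theta = (c_1, \dots, c_p)$ under independent uniform priors
$U(0, A_j)$. The likelihood — a product of chemical-master-equation
transition densities — is intractable, so inference is likelihood-free
(ABC), with acceptance decided by comparing simulations to the data.

## The acceptance error models

All three samplers in `abc_fit()` share the per-time-point, per-species
discrepancy test: a simulated state $Y$ matches an observed state $X$ at
relative tolerance $\alpha$ when $|X_s - Y_s| \le \alpha X_s$ for every
species with $X_s > 0$ (and $Y_s = 0$ where $X_s = 0$, up to an optional
absolute floor).

* **Per-interval simulated likelihood (`sld1`).** The Markov property
  factorizes the likelihood into one transition density per interval. Each
  density is estimated empirically: $B$ replicates are restarted *from the
  observed state* $X_{l-1}$ and simulated for one step $\Delta t$. With
  $b_l$ the number of replicates failing the test at $t_l$, the fitness
  error is
  $\varepsilon = \frac{1}{N_0}\sum_{l=1}^{n} b_l / B$,
  where $N_0$ (`norm`) is the particle count of the nominal design. The
  error lies in $[0, n/N_0]$; the upper end is the *critical fitness
  tolerance* — at or above it every proposal is accepted. For the
  benchmark (100 particles, $B = 10$) this gives 0.1 at $n = 10$
  ($\Delta t = 3$) and 0.06 at $n = 6$ ($\Delta t = 5$). A proposal is
  accepted when $\varepsilon \le \epsilon_k$, so that schedules ending at
  the supremum accept everything and the mean count number is exactly one.
  Note the aggregate counts *failures* (small is good); the alternative
  sign convention would reward mismatch and cannot produce a converging
  sampler, which is how the convention was fixed.
* **Whole-trajectory per-time-point error (`sld2`).** Identical
  aggregation, but the $B$ replicates are full trajectories from $X_0$
  over $[0, T]$. Errors now compound along the trajectory instead of being
  reset at each observation, which makes the same $\alpha$ effectively
  stricter.
* **Generic ABC SMC baseline (`smc`).** Each replicate is reduced to one
  scalar trajectory distance (default: root mean square of
  $(X_{ls} - Y_{ls}) / \max(X_{ls}, 1)$ over all time points and species;
  the paper-era baseline leaves this distance open, so it is configurable)
  and a proposal is viable when at least one of $B$ replicates lands
  within $\epsilon_k$.

## The particle sampler

Iteration 1 draws proposals from the prior until $N$ are accepted, each
with weight $1/N$. Iteration $k > 1$ resamples a particle by weight,
perturbs it with a gaussian kernel of componentwise standard deviation
$\sigma_{k-1}$ (the previous population's sample spread; a uniform
$\pm\sigma$ kernel is available), rejects proposals outside the prior box
without consuming a proposal count, and otherwise evaluates the error
model. Accepted particles receive the sequential importance weight

$$ w_i^k \;\propto\; \pi(\theta_i)\, b_k(\theta_i) \Big/
   \sum_j w_j^{k-1} q(\theta_i \mid \theta_j, \sigma_{k-1}), $$

where $b_k(\theta_i) = \sum_l (B - b_l)$ is the particle's replicate
match count. The match-count factor follows the published weight formula;
`weight_bk = "none"` drops it (the plain hard-acceptance ABC-SMC weight),
which makes little practical difference because hard acceptance already
truncates poorly matching particles. The denominator includes the previous
weights $w_j^{k-1}$ — the standard sequential importance correction —
also where the generic-baseline pseudo-code omits them.

Two diagnostics summarize each iteration. The **mean count number** (MN)
is the average number of evaluated proposals per accepted particle — the
inverse acceptance rate. The **averaged error** (AE) is the sum over rate
constants of the relative errors of the estimated constants,
$AE_k = \sum_j |\hat\theta_{jk} - c_j| / c_j$ with $\hat\theta_k$ the
weighted posterior mean. An alternative reading — averaging the summed
relative errors over individual particles — is available as
`averaged_error(type = "population")`, but it is ruled out as the
benchmark's definition by a simple bound: among thousands of prior draws
from the benchmark's boxes the *smallest* summed relative error is about
1.1, so no accepted first-iteration population can average the reported
0.6 under that reading, while the point-estimate reading reproduces it.

## Random numbers and reproducibility

Simulation randomness comes from a dedicated xoshiro256\*\* generator.
Every simulation consumes an explicit substream derived by hashing a base
seed with structural indices — one substream per recording interval in
`ssa_simulate()`, per (interval, replicate) in the per-interval evaluator,
per (replicate, interval) in the whole-trajectory evaluators, and per
(iteration, particle, attempt) in the drivers. Consequences: fits are
bit-reproducible for a fixed seed; a grid simulation is bit-identical to
chaining `ssa_interval()` calls with `interval_seed()`; and an early
rejection never shifts the randomness of later proposals. At each
recording boundary the overshooting waiting time is discarded and redrawn,
which is statistically exact by memorylessness of the exponential. R's own
RNG (seeded from the same argument) drives only prior draws, resampling
and perturbation. The direct method draws two uniforms per event; an event
guard (`max_events`, default $10^8$) aborts runaway trajectories from
absurd prior draws.

## The synthetic benchmark and what it emulates

`simulate_observations()` reproduces the benchmark protocol: one exact SSA
trajectory at the network's stored rates, recorded every $\Delta t$. The
built-in systems are the published ones: `system1_network()` — reversible
dimerization with decay, $S = (10000, 0, 0)$,
$c = (0.1, 0.002, 0.5, 0.04)$, observed over $T = 30$ — and
`system2_network()` — a prokaryotic auto-regulatory gene network (five
species, eight reactions), initial copies $(10, 100, 100, 800, 100)$,
$c = (0.1, 0.7, 0.35, 0.01, 0.1, 0.9, 0.2, 0.01)$, observed over
$T = 50$ at $\Delta t = 1$. For coarser inference grids the fine
trajectory is thinned with `rebin()` rather than re-simulated, so all step
sizes share one underlying realization. The data are noise-free SSA
output: no measurement-error model is included, so passing benchmarks
demonstrates recovery from intrinsic stochasticity only, not robustness to
observation noise. As printed, reaction 7 of the gene network produces the
protein dimer directly (`r7_product = "P"` gives the conventional
translation reading); the reaction list is implemented exactly as printed
because the inference machinery is agnostic to the choice.

Two sampler-level choices resolve gaps the protocol leaves open: the
homodimerization propensity uses the combinatorial $c\,n(n-1)/2$ (a
`dimer = "full"` flag provides $c\,n(n-1)$ for cross-checks), and
out-of-box perturbations are redrawn without incrementing the proposal
count, which is the only convention under which schedules at the critical
tolerance yield MN exactly 1.

## Study sizes used by the tests

Full-scale reproduction (N = 100 particles, B = 10 replicates) of the
published tables is expensive, so the packaged tests and the acceptance
script run a reduced design chosen once: N = 20 particles (N = 10 for the
gene network), B = 5 replicates, with the published tolerance schedules
kept comparable by fixing the error normalization at the nominal
`norm = 100`. Medians over five seeds are reported where the protocol
calls for them. A validation run at the full published scale
($\Delta t = 3$, printed schedules) gave iteration-wise point-estimate AE
0.86, 0.90, 0.81, 0.67, 0.86 — the same range as the published
0.61, 0.50, 0.55, 0.72, 0.61 given seed-to-seed variability.

## Identifiability: what the dimerization benchmark can and cannot pin down

The fitness error of the dimerization system is *flat* along the ray
$c_3 / c_2 = \text{const}$: rescaling both by 0.6–2 changes
$\varepsilon$ by less than the replicate noise, because the fast
dimerization subsystem re-equilibrates well within one observation step,
so only the equilibrium ratio is visible in the transition densities. The
admissible ridge is truncated by the prior boxes, whose midpoints happen
to sit on the truth; a large population therefore self-centres and the
posterior-mean AE is small, while the width of the acceptance band grows
along the ridge, tilting small populations toward the high-rate end.
This is why the reduced-scale (N = 20) iteration-5 AE is systematically
above the full-scale value: particle impoverishment along a flat ridge,
not an error-model difference. Similarly, for the gene network at
$\Delta t = 2$ the whole-trajectory error of the *true* rates
(~0.214 at $\alpha = 0.095$) exceeds the final printed tolerance 0.2 —
trajectory decorrelation over $T = 50$ makes near-perfect pointwise
matches rare even for the generating parameters — so the tightest printed
schedules select for variance-suppressing parameter sets rather than the
truth. These are properties of the published protocol itself and are
reported by the tests as measured.

## Worked example

```{r example}
library(abcsld)

net <- system1_network()
obs <- rebin(simulate_observations(net, horizon = 30, dt = 1, seed = 7), 3)

fit <- abc_fit(obs, net, uniform_prior(c(0.5, 0.005, 1, 0.1)),
               algorithm = "sld1",
               epsilon = c(0.07, 0.06, 0.055, 0.05, 0.045),
               N = 20, B = 5, alpha = 0.05, norm = 100, seed = 1,
               true_rates = c(0.1, 0.002, 0.5, 0.04))
summary(fit)
plot(fit)                 # posterior histograms, final iteration
simulate(fit, nsim = 3)   # posterior-predictive trajectories
```

## Known limitations

* Exact SSA only: no tau-leaping, hybrid or parallel simulation, so
  full-scale gene-network runs are slow by design.
* The per-species zero-count rule (simulated count must be zero where the
  observed count is zero) is strict; `zero_floor` relaxes it.
* No adaptive tolerance selection: schedules are user-supplied, and badly
  chosen final tolerances can undercut even the true parameters (see the
  identifiability notes above).
* Priors are independent uniforms on $(0, A_j)$, as in the benchmarks.
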