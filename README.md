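# abcsld

Likelihood-free Bayesian inference of stochastic rate constants in
discrete-state mass-action reaction networks, using sequential Monte Carlo
particle samplers whose acceptance error is built from the **simulated
likelihood (transitional) density**.

## The problem and the method

Chemical reaction systems with low copy numbers are continuous-time Markov
jump processes; their likelihood — a product of chemical-master-equation
transition densities f(t_l, X_l | t_{l-1}, X_{l-1}; θ) — is intractable, so
rate constants θ = (c_1, …, c_p) must be inferred likelihood-free from
copy-number snapshots X_1, …, X_n observed every Δt. The package provides an
exact Gillespie direct-method simulator (Rcpp) and three ABC-SMC samplers
that propagate N parameter particles through a decreasing tolerance schedule
ε_1 > … > ε_K:

* **`sld1` (per-interval simulated likelihood):** each transition density is
  estimated by B replicates restarted *from the observed state* X_{l-1};
  with b_l replicates failing the per-species relative test
  |X_ls − Y_ls| ≤ α X_ls, the fitness error is
  ε = (1/N₀) Σ_l b_l / B and a proposal is accepted when ε ≤ ε_k.
* **`sld2` (whole-trajectory, per-time-point error):** the same error built
  from B full trajectories simulated from X_0.
* **`smc` (generic ABC-SMC baseline):** each replicate reduced to one
  whole-trajectory distance; a proposal is viable when any replicate lands
  within ε_k.

Accepted particles carry the sequential importance weight
w_i ∝ π(θ_i)·b_k(θ_i) / Σ_j w_j^{k−1} q(θ_i | θ_j, σ_{k−1}), with b_k the
replicate match count and q a gaussian (or uniform) kernel scaled by the
previous population's spread. Diagnostics: the **mean count number**
(proposals per acceptance) and the **averaged error**
AE_k = Σ_j |θ̂_jk − c_j| / c_j of the weighted posterior mean against the
generating rates.

Two published benchmark systems ship as built-ins: `system1_network()`
(reversible dimerization with decay, 3 species / 4 reactions, S(0) =
(10000, 0, 0)) and `system2_network()` (prokaryotic auto-regulatory gene
network, 5 species / 8 reactions). Networks can also be defined in
YAML/JSON via `read_network()`.

## Worked example

```r
library(abcsld)

net <- system1_network()                 # c = (0.1, 0.002, 0.5, 0.04)
obs <- rebin(simulate_observations(net, horizon = 30, dt = 1, seed = 7), 3)

fit <- abc_fit(obs, net, uniform_prior(c(0.5, 0.005, 1, 0.1)),
               algorithm = "sld1",
               epsilon = c(0.07, 0.06, 0.055, 0.05, 0.045),
               N = 20, B = 5, alpha = 0.05, norm = 100, seed = 1,
               true_rates = net$rates)
fit
#> ABC SLD (per-interval transitional density) fit
#>   20 particles, 5 iteration(s), B = 5, seed 1
#>   epsilon: 0.07, 0.06, 0.055, 0.05, 0.045
#>   alpha:   0.05, 0.05, 0.05, 0.05, 0.05
#>   posterior means (final iteration):
#>       c1       c2       c3       c4
#> 0.107500 0.003054 0.733000 0.041080

mean_count_number(fit)   # proposals consumed per accepted particle
#> [1] 121.65  11.30   8.05   7.85   7.75
round(averaged_error(fit), 4)  # summed relative error of the estimates
#> [1] 0.7665 0.9400 0.8969 0.7079 1.0949
```

The posterior means land near the generating rates (c1 and c4 within
about 8% and 3%); c2 and c3 are identified mostly through their ratio — the fast
dimerization subsystem re-equilibrates within one observation step, so the
fitness error is nearly flat along c3/c2 = const and those two marginals
stay wide. `plot(fit)` draws the weighted posterior histograms and
`simulate(fit)` returns posterior-predictive trajectories.

`norm` fixes the error normalization at the nominal design size (100
particles in the benchmarks) so that published tolerance schedules remain
comparable when running fewer particles.

A command-line front end over the same functions is included:

```sh
Rscript inst/scripts/abcsld.R simulate --system system1 --horizon 30 --dt 3 --seed 1 --out obs.csv
Rscript inst/scripts/abcsld.R infer --algorithm sld1 --system system1 --obs obs.csv \
    --epsilon 0.07,0.06,0.055,0.05,0.045 --alpha 0.05 --N 100 --B 10 --seed 1 --out out/
```

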