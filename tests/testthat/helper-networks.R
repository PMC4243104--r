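# Small networks used across the tests.

death_network <- function(c1 = 0.1, x0 = 10000) {
  reaction_network("A", list(reaction(c(A = 1), numeric(), rate = c1)),
                   initial_state = x0)
}

birth_death_network <- function(birth = 5, death = 0.5, x0 = 0) {
  reaction_network("A",
                   list(reaction(numeric(), c(A = 1), rate = birth),
                        reaction(c(A = 1), numeric(), rate = death)),
                   initial_state = x0)
}

# cheap single-parameter inference problem for driver-level tests
death_problem <- function(seed = 11, x0 = 50, c1 = 0.5, horizon = 4) {
  net <- death_network(c1 = c1, x0 = x0)
  obs <- simulate_observations(net, horizon, 1, seed = seed)
  list(net = net, obs = obs, prior = uniform_prior(2), truth = c1)
}

# deterministic fabricated observation/simulation fixtures
toy_obs <- function(n = 4, S = 2, seed = 1) {
  set.seed(seed)
  matrix(rpois(n * S, 50), n, S)
}

toy_sims <- function(obs, B, jitter, seed = 1) {
  set.seed(seed)
  lapply(seq_len(B), function(m)
    obs + matrix(sample(-jitter:jitter, length(obs), TRUE),
                 nrow(obs), ncol(obs)))
}
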