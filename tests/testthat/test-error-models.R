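# independent brute-force oracle for the per-time-point failure counts
oracle_failures <- function(obs, sims, alpha, zero_floor = 0) {
  n <- nrow(obs); b <- integer(n)
  for (l in seq_len(n)) for (m in seq_along(sims)) {
    ok <- TRUE
    for (s in seq_len(ncol(obs))) {
      X <- obs[l, s]; Y <- sims[[m]][l, s]
      if (X > 0) { if (abs(X - Y) > alpha * X) ok <- FALSE }
      else if (abs(Y) > zero_floor) ok <- FALSE
    }
    if (!ok) b[l] <- b[l] + 1L
  }
  b
}

test_that("the relative point test handles zeros and boundaries", {
  expect_true(point_test(c(100, 50), c(100, 50), alpha = 0.01))
  expect_false(point_test(100, 106, alpha = 0.05))      # 6 > 5
  expect_true(point_test(100, 105, alpha = 0.05))       # boundary passes
  expect_true(point_test(c(10000, 0, 0), c(9800, 0, 0), alpha = 0.05))
  expect_false(point_test(c(10000, 0, 0), c(9800, 1, 0), alpha = 0.05))
  expect_true(point_test(c(10000, 0, 0), c(9800, 1, 0), alpha = 0.05,
                         zero_floor = 1))
  expect_error(point_test(c(1, 2), c(1, 2, 3), alpha = 0.1), "length")
})

test_that("failure counts agree with the brute-force oracle", {
  obs <- toy_obs(n = 5, S = 3, seed = 21)
  for (jit in c(1, 4, 9)) {
    sims <- toy_sims(obs, B = 6, jitter = jit, seed = jit)
    for (alpha in c(0.02, 0.05, 0.12))
      expect_equal(failure_counts(obs, sims, alpha),
                   oracle_failures(obs, sims, alpha))
  }
  # extremes
  sims <- replicate(4, obs, simplify = FALSE)
  expect_equal(failure_counts(obs, sims, 0.05), rep(0L, 5))
  far <- lapply(sims, function(s) s + 1000)
  expect_equal(failure_counts(obs, far, 0.05), rep(4L, 5))
  # single failing replicate at one time point
  one <- sims
  one[[2]][2, 1] <- one[[2]][2, 1] * 2
  expect_equal(failure_counts(obs, one, 0.05), c(0L, 1L, 0L, 0L, 0L))
})

test_that("the per-interval fitness error matches its printed anchors", {
  # all-fail supremum is n / norm: the critical fitness tolerances
  expect_equal(fitness_error_alg1(rep(10, 10), B = 10, norm = 100), 0.1)
  expect_equal(fitness_error_alg1(rep(10, 6), B = 10, norm = 100), 0.06)
  expect_equal(fitness_error_alg1(rep(0, 10), B = 10, norm = 100), 0)
  expect_equal(fitness_error_alg1(c(5, rep(0, 9)), B = 10, norm = 100),
               0.005)
  expect_error(fitness_error_alg1(c(11, 0), B = 10, norm = 100), "0..B")
})

test_that("whole-trajectory error shares the aggregation core", {
  obs <- toy_obs(n = 25, S = 2, seed = 8)
  sims <- toy_sims(obs, B = 10, jitter = 6, seed = 9)
  b <- failure_counts(obs, sims, 0.05)
  expect_equal(fitness_error_alg2(obs, sims, 0.05, norm = 100),
               fitness_error_alg1(b, B = 10, norm = 100))
  # total mismatch at n = 25, B = 10, norm = 100 gives the 0.25 supremum
  far <- lapply(sims, function(s) s + 1e4)
  expect_equal(fitness_error_alg2(obs, far, 0.05, norm = 100), 0.25)
  # brute-force double loop over (m, l)
  manual <- sum(vapply(seq_along(sims), function(m)
    sum(vapply(1:25, function(l)
      !point_test(obs[l, ], sims[[m]][l, ], 0.05), TRUE)), numeric(1)))
  expect_equal(fitness_error_alg2(obs, sims, 0.05, norm = 100),
               manual / 10 / 100)
})

test_that("fitness error is monotone in alpha and replicate-permutation invariant", {
  obs <- toy_obs(n = 6, S = 3, seed = 31)
  sims <- toy_sims(obs, B = 8, jitter = 5, seed = 32)
  alphas <- c(0.01, 0.03, 0.05, 0.1, 0.2)
  errs <- vapply(alphas, function(a)
    fitness_error_alg2(obs, sims, a, norm = 100), numeric(1))
  expect_true(all(diff(errs) <= 0))
  bs <- vapply(alphas, function(a) sum(failure_counts(obs, sims, a)),
               numeric(1))
  expect_true(all(diff(bs) <= 0))
  freqs <- vapply(alphas, function(a)
    frequency_distribution(obs[1, ], do.call(rbind, lapply(sims, `[`, 1, )),
                           a), numeric(1))
  expect_true(all(diff(freqs) >= 0))
  perm <- sample(8)
  expect_equal(failure_counts(obs, sims[perm], 0.05),
               failure_counts(obs, sims, 0.05))
})

test_that("trajectory distances and match counts follow their definitions", {
  obs <- toy_obs(n = 4, S = 2, seed = 41)
  expect_equal(trajectory_distance(obs, obs), 0)
  sim <- obs + 5
  manual <- sqrt(mean((5 / pmax(obs, 1))^2))
  expect_equal(trajectory_distance(obs, sim), manual)
  expect_equal(trajectory_distance(obs, sim, "rms_absolute"), 5)
  sims <- toy_sims(obs, B = 7, jitter = 8, seed = 42)
  # oracle: direct per-replicate computation
  d <- vapply(sims, function(s)
    sqrt(mean(((obs - s) / pmax(obs, 1))^2)), numeric(1))
  for (eps in c(0.01, 0.05, 0.1, 1))
    expect_equal(abc_smc_match_count(obs, sims, eps), sum(d <= eps))
  expect_equal(abc_smc_match_count(obs, replicate(5, obs, simplify = FALSE),
                                   0), 5)
  # epsilon = 0 excludes any differing replicate
  expect_equal(abc_smc_match_count(obs, list(obs, obs + 1), 0), 1)
  # match_fraction flavour needs alpha
  expect_error(trajectory_distance(obs, sim, "match_fraction"), "alpha")
  expect_equal(trajectory_distance(obs, sim, "match_fraction", alpha = 1), 0)
})

test_that("the frequency distribution is the match fraction", {
  x <- c(100, 200)
  states <- rbind(c(100, 200), c(104, 196), c(120, 200), c(100, 260),
                  c(97, 206))
  expect_equal(frequency_distribution(x, states, alpha = 0.05), 3 / 5)
  expect_equal(frequency_distribution(x, states, alpha = 1), 1)
  expect_equal(frequency_distribution(x, states + 1000, alpha = 0.05), 0)
})
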