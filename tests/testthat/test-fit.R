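test_that("all three drivers are bit-reproducible under a fixed seed", {
  prob <- death_problem()
  for (alg in c("sld1", "sld2", "smc")) {
    eps <- if (alg == "smc") c(0.5, 0.4) else c(0.03, 0.025)
    a <- abc_fit(prob$obs, prob$net, prob$prior, alg, epsilon = eps,
                 N = 8, B = 3, alpha = 0.2, norm = 100, seed = 5,
                 true_rates = prob$truth)
    b <- abc_fit(prob$obs, prob$net, prob$prior, alg, epsilon = eps,
                 N = 8, B = 3, alpha = 0.2, norm = 100, seed = 5,
                 true_rates = prob$truth)
    expect_identical(a$iterations, b$iterations)
    c <- abc_fit(prob$obs, prob$net, prob$prior, alg, epsilon = eps,
                 N = 8, B = 3, alpha = 0.2, norm = 100, seed = 6)
    expect_false(identical(a$iterations[[1]]$theta, c$iterations[[1]]$theta))
  }
})

test_that("tolerances at the attainable maximum accept every proposal", {
  prob <- death_problem()   # n = 4, so the supremum is 4/norm
  for (alg in c("sld1", "sld2")) {
    f <- abc_fit(prob$obs, prob$net, prob$prior, alg,
                 epsilon = rep(4 / 100, 3), N = 10, B = 3, alpha = 0.05,
                 norm = 100, seed = 2)
    expect_equal(mean_count_number(f), rep(1, 3))
    # iteration-1 weights are uniform
    expect_equal(f$iterations[[1]]$weights, rep(0.1, 10))
  }
})

test_that("proposal counts follow the acceptance probability", {
  prob <- death_problem()
  # deterministic pattern: accept every other proposal
  flag <- new.env(); flag$i <- 0L
  f <- abc_fit(prob$obs, prob$net, prob$prior, "sld1", epsilon = 1,
               N = 6, seed = 3,
               .eval = function(theta, k, seed) {
                 flag$i <- flag$i + 1L
                 list(accept = flag$i %% 2 == 0)
               })
  expect_equal(f$iterations[[1]]$counts, rep(2L, 6))
  expect_equal(mean_count_number(f, 1), 2)
  # stochastic acceptance at rate p: MN is the geometric mean 1/p
  p <- 0.3
  f <- abc_fit(prob$obs, prob$net, prob$prior, "sld1", epsilon = 1,
               N = 500, seed = 4,
               .eval = function(theta, k, seed) list(accept = runif(1) < p))
  se <- sqrt((1 - p) / p^2 / 500)
  expect_lt(abs(mean_count_number(f, 1) - 1 / p), 4 * se)
})

test_that("with forced acceptance the first population is the prior", {
  prob <- death_problem()
  f <- abc_fit(prob$obs, prob$net, prob$prior, "sld1", epsilon = 1,
               N = 1000, seed = 9,
               .eval = function(theta, k, seed) list(accept = TRUE))
  ks <- suppressWarnings(
    stats::ks.test(f$iterations[[1]]$theta[, 1], "punif", 0, 2))
  expect_gt(ks$p.value, 0.01)
  expect_equal(sum(f$iterations[[1]]$weights), 1, tolerance = 1e-12)
})

test_that("lowering the final tolerance never eases acceptance", {
  prob <- death_problem()
  mn <- function(eps, s)
    mean_count_number(abc_fit(prob$obs, prob$net, prob$prior, "sld1",
                              epsilon = eps, N = 8, B = 3, alpha = 0.1,
                              norm = 100, seed = s), 1)
  loose <- vapply(1:10, function(s) mn(0.04, s), numeric(1))
  tight <- vapply(1:10, function(s) mn(0.02, s), numeric(1))
  expect_gte(median(tight), median(loose))
})

test_that("averaged error reductions match hand computations", {
  truth <- c(0.1, 0.002, 0.5, 0.04)
  fake <- structure(list(iterations = list(list(
    theta = matrix(truth, 1, byrow = TRUE), weights = 1)),
    true_rates = truth), class = "abc_fit")
  expect_equal(averaged_error(fake), 0)
  fake$iterations[[1]]$theta <- matrix(2 * truth, 1, byrow = TRUE)
  expect_equal(averaged_error(fake), 4)  # each relative error is 1
  expect_equal(averaged_error(fake, type = "population"), 4)
  # population averaging against a brute-force double loop
  set.seed(12)
  th <- matrix(runif(40, 0.01, 1), 10, 4)
  fake$iterations[[1]]$theta <- th
  fake$iterations[[1]]$weights <- rep(0.1, 10)
  manual <- mean(vapply(1:10, function(i)
    sum(abs(th[i, ] - truth) / truth), numeric(1)))
  expect_equal(averaged_error(fake, type = "population"), manual)
  manual_pt <- sum(abs(colMeans(th) - truth) / truth)
  expect_equal(averaged_error(fake), manual_pt)
  expect_error(averaged_error(fake, true_rates = c(0, 1, 1, 1)), "positive")
})

test_that("posterior histograms conserve mass and localize particles", {
  truth <- 0.5
  fake <- structure(list(iterations = list(list(
    theta = matrix(0.52, 1, 1), weights = 1)),
    prior = uniform_prior(1)), class = "abc_fit")
  h <- posterior_histogram(fake, 1, breaks = 10)
  expect_equal(sum(h$freq), 1)
  expect_equal(h$freq[6], 1)  # 0.52 falls in (0.5, 0.6]
  # uniform weights over bin centres give equal bars
  fake$iterations[[1]]$theta <- matrix(seq(0.05, 0.95, by = 0.1), 10, 1)
  fake$iterations[[1]]$weights <- rep(0.1, 10)
  h <- posterior_histogram(fake, 1, breaks = 10)
  expect_equal(h$freq, rep(0.1, 10))
})

test_that("the generic SMC sampler counts matches and weights by them", {
  prob <- death_problem()
  # huge tolerance: every replicate matches, uniform first-iteration weights
  f <- abc_fit(prob$obs, prob$net, prob$prior, "smc", epsilon = c(100, 100),
               N = 6, B = 4, seed = 8)
  expect_true(all(f$iterations[[1]]$bk == 4))
  expect_equal(f$iterations[[1]]$weights, rep(1 / 6, 6))
  expect_equal(mean_count_number(f), c(1, 1))
})

test_that("the fused per-interval evaluator agrees with the module surface", {
  net <- system1_network()
  obs <- rebin(simulate_observations(net, 30, 3, seed = 13), 3)
  obsmat <- rbind(obs$x0, obs$states)
  theta <- c(0.12, 0.0024, 0.6, 0.035)
  seed <- 991
  res <- abcsld:::cpp_eval_sld1(net$reactants, net$products, theta, obsmat,
                                3, 4, 0.05, 0, 1e9, seed, 1e8, FALSE)
  # rebuild the same replicates through the public interval simulator
  netp <- set_rates(net, theta)
  sims <- lapply(1:4, function(m) {
    t(vapply(1:10, function(l)
      ssa_interval(netp, obsmat[l, ], 0, 3,
                   seed = interval_seed(seed, l, m)),
      numeric(3)))
  })
  b <- failure_counts(obs$states, sims, alpha = 0.05)
  expect_equal(unlist(res$b), b, ignore_attr = TRUE)
  expect_equal(res$total_fail, sum(b))
  expect_equal(fitness_error_alg1(b, B = 4, norm = 100),
               res$total_fail / 4 / 100)
})

test_that("the fused whole-trajectory evaluator replays the grid simulator", {
  net <- system2_network()
  obs <- simulate_observations(net, 10, 2, seed = 14)
  obsmat <- rbind(obs$x0, obs$states)
  theta <- net$rates
  seed <- 313
  res <- abcsld:::cpp_eval_sld2(net$reactants, net$products, theta, obsmat,
                                2, 3, 0.1, 0, 1e9, seed, 1e8, FALSE)
  sims <- lapply(1:3, function(m)
    ssa_simulate(net, times = obs$times,
                 seed = interval_seed(seed, m))$states)
  expect_equal(fitness_error_alg2(obs$states, sims, alpha = 0.1, norm = 100),
               res$total_fail / 3 / 100)
})

test_that("acceptance stalls abort with partial results", {
  prob <- death_problem()
  expect_warning(
    f <- abc_fit(prob$obs, prob$net, prob$prior, "sld1",
                 epsilon = 1e-6, N = 4, B = 3, alpha = 1e-6, norm = 100,
                 seed = 1, max_attempts = 5),
    "stalled")
  expect_true(f$stalled)
  expect_length(f$iterations, 0)
})

test_that("varying alpha follows the tolerance schedule", {
  prob <- death_problem()
  f <- abc_fit(prob$obs, prob$net, prob$prior, "sld1",
               epsilon = c(0.04, 0.03), N = 4, B = 2, alpha = "vary",
               norm = 100, seed = 1)
  expect_equal(f$alpha, c(0.04, 0.03))
})

test_that("fit methods print, summarize, simulate and export", {
  prob <- death_problem()
  f <- abc_fit(prob$obs, prob$net, prob$prior, "sld1",
               epsilon = c(0.04, 0.03), N = 6, B = 3, alpha = 0.2,
               norm = 100, seed = 21, true_rates = prob$truth)
  expect_output(print(f), "posterior means")
  expect_output(print(summary(f)), "diagnostics")
  expect_length(coef(f), 1)
  trs <- simulate(f, nsim = 2, seed = 3)
  expect_length(trs, 2)
  expect_equal(trs[[1]]$times, prob$obs$times)
  dir <- withr::local_tempdir()
  paths <- write_populations(f, dir)
  expect_true(all(file.exists(paths)))
  pop <- read.csv(file.path(dir, "population_01.csv"))
  expect_equal(nrow(pop), 6)
  expect_equal(sum(pop$weight), 1, tolerance = 1e-12)
})
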