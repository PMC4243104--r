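#' Fit stochastic rate constants by ABC sequential Monte Carlo
#'
#' Infers the rate constants of a mass-action reaction network from copy
#' numbers observed on a regular time grid, by propagating a population of
#' `N` parameter particles through a decreasing fitness-tolerance schedule.
#' Three acceptance error models are available:
#'
#' * `"sld1"` -- per-interval simulated likelihood: for each observation
#'   interval, `B` replicates are restarted from the *observed* state at the
#'   previous time point (the Markov transitional-density factorization);
#'   the error is the normalized total of per-time-point failures of the
#'   relative discrepancy test at tolerance `alpha`
#'   (see [fitness_error_alg1()]).
#' * `"sld2"` -- whole-trajectory per-time-point error: `B` replicates are
#'   simulated from the known initial state over the full period and the
#'   same per-time-point failure total is used (see [fitness_error_alg2()]).
#' * `"smc"` -- generic ABC SMC baseline: each replicate is reduced to one
#'   whole-trajectory distance and a proposal is viable when at least one
#'   replicate lands within the tolerance (see [abc_smc_match_count()]).
#'
#' At iteration 1 proposals are drawn from the prior; later iterations
#' resample from the previous population by weight and perturb with a
#' gaussian or uniform kernel scaled by the previous population's
#' componentwise spread.  A proposal is accepted when its error is at most
#' `epsilon[k]`; sampling repeats until `N` particles are accepted.
#'
#' @param observations an `"observation_set"` (see
#'   [simulate_observations()], [read_observations()]).
#' @param network a [reaction_network()] giving the model structure; its
#'   stored rates are ignored during fitting.
#' @param prior an [uniform_prior()] with one bound per reaction.
#' @param algorithm `"sld1"`, `"sld2"` or `"smc"`.
#' @param epsilon decreasing vector of fitness tolerances, one per
#'   iteration.
#' @param N number of particles per population.
#' @param B number of simulation replicates per proposal (scalar or one per
#'   iteration).
#' @param alpha discrepancy tolerance of the per-time-point test: a scalar,
#'   a vector with one value per iteration, or `"vary"` for `alpha_k =
#'   epsilon[k]`.  For `algorithm = "smc"` it is only used by the
#'   `"match_fraction"` distance.
#' @param kernel perturbation kernel family, `"gaussian"` or `"uniform"`.
#' @param norm normalizing particle count of the fitness error (defaults to
#'   `N`).  Scaled-down reruns of a nominal design keep the nominal
#'   tolerance schedule comparable by passing the nominal particle count
#'   (e.g. `norm = 100`).
#' @param distance trajectory distance for `algorithm = "smc"`.
#' @param zero_floor absolute tolerance where an observed count is zero.
#' @param true_rates optional generating rates; when supplied the averaged
#'   error diagnostic is recorded per iteration.
#' @param seed integer seed; fits are bit-reproducible.
#' @param max_attempts per-particle proposal cap; exceeding it aborts the
#'   iteration with a warning and returns the completed populations.
#' @param max_events per-simulation event guard.
#' @param sigma_weighted use the weighted population variance for the
#'   perturbation scale.
#' @param weight_bk `"match_count"` (default) multiplies the importance
#'   weights of the SLD samplers (iterations after the first) by the
#'   particle's replicate match count `sum_l (B - b_l)`; `"none"` uses the
#'   plain sequential importance weight.
#' @param count_support_rejections whether proposals rejected for leaving
#'   the prior support increment the particle's proposal count (default
#'   `FALSE`, so that tolerances at the attainable maximum give a mean
#'   count number of exactly one).
#' @param verbose print per-iteration progress.
#' @param .eval internal override of the proposal evaluator (testing hook):
#'   `function(theta, k, seed)` returning at least `list(accept = )`.
#' @return An object of class `"abc_fit"`: populations (`theta`, normalized
#'   `weights`, proposal `counts`, spread `sigma` and, for `"smc"`, match
#'   counts `bk`) for each iteration, a `diagnostics` data frame with the
#'   mean count number `mn`, acceptance rate and averaged error `ae`, and
#'   the full configuration.  Methods: [print()], [summary()], [coef()]
#'   (weighted posterior means), [plot()] (posterior histograms) and
#'   [simulate()] (posterior-predictive trajectories).
#' @examples
#' \donttest{
#' net <- system1_network()
#' obs <- simulate_observations(net, horizon = 30, dt = 3, seed = 7)
#' fit <- abc_fit(obs, net, uniform_prior(c(0.5, 0.005, 1, 0.1)),
#'                algorithm = "sld1", epsilon = c(0.07, 0.06), N = 10,
#'                B = 5, alpha = 0.05, norm = 100, seed = 1,
#'                true_rates = c(0.1, 0.002, 0.5, 0.04))
#' coef(fit)
#' }
#' @export
abc_fit <- function(observations, network, prior,
                    algorithm = c("sld1", "sld2", "smc"),
                    epsilon, N = 100, B = 10, alpha = 0.05,
                    kernel = c("gaussian", "uniform"),
                    norm = N,
                    distance = c("rms_relative", "rms_absolute",
                                 "match_fraction"),
                    zero_floor = 0, true_rates = NULL, seed = 1L,
                    max_attempts = 1e6, max_events = 1e8,
                    sigma_weighted = FALSE,
                    weight_bk = c("match_count", "none"),
                    count_support_rejections = FALSE,
                    verbose = FALSE, .eval = NULL) {
  algorithm <- match.arg(algorithm)
  kernel <- match.arg(kernel)
  distance <- match.arg(distance)
  weight_bk <- match.arg(weight_bk)
  stopifnot(inherits(observations, "observation_set"),
            inherits(network, "reaction_network"),
            inherits(prior, "abc_prior"))
  K <- length(epsilon)
  if (K < 1 || any(epsilon <= 0))
    stop("'epsilon' must be a vector of positive tolerances", call. = FALSE)
  B <- rep_len(B, K)
  if (any(B < 1)) stop("'B' must be at least 1", call. = FALSE)
  p <- length(prior$upper)
  if (p != nrow(network$reactants))
    stop("prior dimension must equal the number of reactions", call. = FALSE)
  if (identical(alpha, "vary")) alpha <- epsilon
  if (!is.numeric(alpha)) stop("'alpha' must be numeric or \"vary\"",
                               call. = FALSE)
  alpha <- rep_len(alpha, K)
  if (!is.null(true_rates) && length(true_rates) != p)
    stop("'true_rates' must have one entry per reaction", call. = FALSE)

  obsmat <- rbind(observations$x0, observations$states)
  dt <- observations$dt
  n <- observations$n
  dimer_full <- network$dimer == "full"
  dist_code <- match(distance,
                     c("rms_relative", "rms_absolute", "match_fraction")) - 1L

  eval_proposal <- function(theta, k, sseed) {
    if (!is.null(.eval)) return(.eval(theta, k, sseed))
    max_fail <- epsilon[k] * norm * B[k] + 1e-9
    switch(algorithm,
      sld1 = cpp_eval_sld1(network$reactants, network$products, theta,
                           obsmat, dt, B[k], alpha[k], zero_floor, max_fail,
                           sseed, max_events, dimer_full),
      sld2 = cpp_eval_sld2(network$reactants, network$products, theta,
                           obsmat, dt, B[k], alpha[k], zero_floor, max_fail,
                           sseed, max_events, dimer_full),
      smc  = cpp_eval_smc(network$reactants, network$products, theta,
                          obsmat, dt, B[k], epsilon[k], dist_code, alpha[k],
                          zero_floor, sseed, max_events, dimer_full))
  }

  set.seed(seed)
  iterations <- vector("list", K)
  diagnostics <- data.frame(iteration = seq_len(K), mn = NA_real_,
                            accept_rate = NA_real_, ae = NA_real_,
                            elapsed = NA_real_)
  w_prev <- sigma_prev <- theta_prev <- NULL
  stalled <- FALSE

  for (k in seq_len(K)) {
    t0 <- proc.time()[["elapsed"]]
    theta_mat <- matrix(NA_real_, N, p)
    counts <- integer(N)
    bks <- integer(N)
    tfails <- numeric(N)
    for (i in seq_len(N)) {
      count <- 0L; attempt <- 0L; accepted <- FALSE
      while (!accepted) {
        attempt <- attempt + 1L
        if (attempt > max_attempts) break
        if (k == 1) {
          theta <- sample_prior(prior)
        } else {
          j <- resample_index(w_prev)
          theta <- perturb(theta_prev[j, ], sigma_prev, kernel)
          if (prior_density(prior, theta) == 0) {
            if (count_support_rejections) count <- count + 1L
            next
          }
        }
        count <- count + 1L
        sseed <- cpp_derive_seed(as.double(seed), c(k, i, attempt))
        res <- eval_proposal(theta, k, sseed)
        if (isTRUE(res$accept)) {
          accepted <- TRUE
          theta_mat[i, ] <- theta
          counts[i] <- count
          bks[i] <- if (!is.null(res$bk)) res$bk else B[k]
          tfails[i] <- if (!is.null(res$total_fail)) res$total_fail else 0
        }
      }
      if (!accepted) { stalled <- TRUE; break }
    }
    if (stalled) {
      warning(sprintf(paste0("acceptance stalled at iteration %d, particle ",
                             "%d (max_attempts = %g); returning the %d ",
                             "completed iteration(s)"),
                      k, i, max_attempts, k - 1L), call. = FALSE)
      iterations <- iterations[seq_len(k - 1L)]
      diagnostics <- diagnostics[seq_len(k - 1L), , drop = FALSE]
      break
    }

    weights <- if (algorithm == "smc") {
      base <- if (k == 1) rep(1, N)
              else compute_weights(theta_mat, theta_prev, w_prev, sigma_prev,
                                   prior, kernel) * N
      wk <- base * bks
      wk / sum(wk)
    } else {
      wk <- if (k == 1) rep(1 / N, N)
            else compute_weights(theta_mat, theta_prev, w_prev, sigma_prev,
                                 prior, kernel)
      if (weight_bk == "match_count" && k > 1) {
        wmc <- wk * (n * B[k] - tfails)
        # if no particle matched any replicate the factor is uninformative
        if (sum(wmc) > 0) wk <- wmc / sum(wmc)
      }
      wk
    }

    sigma_k <- population_sigma(theta_mat,
                                weights = if (sigma_weighted) weights)
    iterations[[k]] <- list(theta = theta_mat, weights = weights,
                            counts = counts, sigma = sigma_k,
                            bk = if (algorithm == "smc") bks)
    diagnostics$mn[k] <- mean(counts)
    diagnostics$accept_rate[k] <- 1 / mean(counts)
    if (!is.null(true_rates))
      diagnostics$ae[k] <- sum(abs(colSums(theta_mat * weights) - true_rates)
                               / true_rates)
    diagnostics$elapsed[k] <- proc.time()[["elapsed"]] - t0
    if (verbose)
      message(sprintf("iteration %d: MN = %.2f%s (%.1fs)", k,
                      diagnostics$mn[k],
                      if (!is.null(true_rates))
                        sprintf(", AE = %.4f", diagnostics$ae[k]) else "",
                      diagnostics$elapsed[k]))
    theta_prev <- theta_mat; w_prev <- weights; sigma_prev <- sigma_k
  }

  structure(list(call = match.call(), algorithm = algorithm,
                 network = network, prior = prior,
                 observations = observations,
                 epsilon = epsilon, alpha = alpha, B = B, N = N,
                 norm = norm, kernel = kernel, distance = distance,
                 zero_floor = zero_floor, seed = seed,
                 true_rates = true_rates, iterations = iterations,
                 diagnostics = diagnostics, stalled = stalled),
            class = "abc_fit")
}

#' Mean count number per iteration
#'
#' The averaged number of proposals consumed per accepted particle -- the
#' inverse acceptance rate, the main computational-cost diagnostic of the
#' samplers.
#'
#' @param fit an [abc_fit()] result.
#' @param k iteration index, or `NULL` for all iterations.
#' @return Numeric vector of mean count numbers.
#' @export
mean_count_number <- function(fit, k = NULL) {
  stopifnot(inherits(fit, "abc_fit"))
  mn <- fit$diagnostics$mn
  if (is.null(k)) mn else mn[k]
}

#' Averaged error of the estimated rate constants
#'
#' The sum over rate constants of the relative errors of the per-iteration
#' estimates against the generating values.  The default (`type = "point"`)
#' measures the weighted posterior mean of each iteration,
#' `AE_k = sum_j |thetahat_jk - c_j| / c_j`; `type = "population"` instead
#' averages the summed relative errors over the individual particles
#' (unweighted), which additionally charges the posterior spread.
#'
#' @param fit an [abc_fit()] result.
#' @param true_rates generating ("exact") rates; defaults to the ones stored
#'   in the fit.
#' @param k iteration index, or `NULL` for all iterations.
#' @param type `"point"` (error of the posterior-mean estimate, default) or
#'   `"population"` (particle-averaged error).
#' @return Numeric vector of averaged errors.
#' @export
averaged_error <- function(fit, true_rates = fit$true_rates, k = NULL,
                           type = c("point", "population")) {
  stopifnot(inherits(fit, "abc_fit"))
  type <- match.arg(type)
  if (is.null(true_rates))
    stop("'true_rates' must be supplied (none stored in the fit)",
         call. = FALSE)
  if (any(true_rates <= 0))
    stop("'true_rates' must be strictly positive", call. = FALSE)
  ae <- vapply(fit$iterations, function(it) {
    if (type == "point") {
      est <- colSums(it$theta * it$weights)
      sum(abs(est - true_rates) / true_rates)
    } else {
      mean(rowSums(abs(sweep(it$theta, 2, true_rates)) /
                   rep(true_rates, each = nrow(it$theta))))
    }
  }, numeric(1))
  if (is.null(k)) ae else ae[k]
}

#' Weighted posterior histogram of one rate constant
#'
#' Bins the accepted particles of one iteration over the prior support of
#' the chosen parameter, accumulating particle weights per bin; the returned
#' frequencies sum to one.
#'
#' @param fit an [abc_fit()] result.
#' @param parameter parameter (reaction) index.
#' @param k iteration index (defaults to the last).
#' @param breaks number of equal-width bins over `[0, upper_j]`.
#' @return List with `breaks`, bin midpoints `mids` and normalized
#'   frequencies `freq`.
#' @export
posterior_histogram <- function(fit, parameter, k = NULL, breaks = 20) {
  stopifnot(inherits(fit, "abc_fit"))
  if (is.null(k)) k <- length(fit$iterations)
  it <- fit$iterations[[k]]
  upper <- fit$prior$upper[parameter]
  edges <- seq(0, upper, length.out = breaks + 1)
  bin <- pmin(pmax(findInterval(it$theta[, parameter], edges,
                                rightmost.closed = TRUE), 1L), breaks)
  freq <- vapply(seq_len(breaks), function(b) sum(it$weights[bin == b]),
                 numeric(1))
  list(breaks = edges, mids = (edges[-1] + edges[-length(edges)]) / 2,
       freq = freq / sum(freq))
}
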