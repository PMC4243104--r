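#' Per-time-point discrepancy test
#'
#' The relative match test behind the simulated-likelihood error models:
#' a simulated state passes iff for every species
#' `|X_s - Y_s| <= alpha * X_s` when the observed count `X_s` is positive,
#' and `|Y_s| <= zero_floor` when `X_s` is zero (default: the simulated
#' count must also be zero).
#'
#' @param observed,simulated copy-number vectors of equal length.
#' @param alpha relative discrepancy tolerance.
#' @param zero_floor absolute tolerance applied where the observed count
#'   is zero.
#' @return `TRUE` (pass) or `FALSE`.
#' @examples
#' point_test(c(10000, 0, 0), c(9800, 0, 0), alpha = 0.05)  # TRUE
#' @export
point_test <- function(observed, simulated, alpha, zero_floor = 0) {
  if (length(observed) != length(simulated))
    stop("state vectors differ in length", call. = FALSE)
  pos <- observed > 0
  all(abs(observed[pos] - simulated[pos]) <= alpha * observed[pos]) &&
    all(abs(simulated[!pos]) <= zero_floor)
}

#' Per-time-point failure counts over simulation replicates
#'
#' For each observation time `l`, counts how many of the `B` simulation
#' replicates fail the [point_test()] against the observed state.
#'
#' @param observed `n x S` matrix of observed states (one row per
#'   observation time, initial state excluded).
#' @param sims list of `B` simulated `n x S` state matrices on the same grid.
#' @inheritParams point_test
#' @return Integer vector `b` of length `n`, each entry in `0..B`.
#' @export
failure_counts <- function(observed, sims, alpha, zero_floor = 0) {
  observed <- as.matrix(observed)
  n <- nrow(observed)
  b <- integer(n)
  for (m in seq_along(sims)) {
    sim <- as.matrix(sims[[m]])
    if (!all(dim(sim) == dim(observed)))
      stop("simulated matrix ", m, " has wrong dimensions", call. = FALSE)
    for (l in seq_len(n))
      if (!point_test(observed[l, ], sim[l, ], alpha, zero_floor))
        b[l] <- b[l] + 1L
  }
  b
}

#' Fitness error of the per-interval (transitional-density) scheme
#'
#' Aggregates the per-time-point failure counts into the scalar acceptance
#' error `epsilon = sum_l b_l / (B * norm)`, where `norm` is the particle
#' count of the nominal design (100 in the benchmarks).  The error lies in
#' `[0, n / norm]`; it is 0 iff every replicate matches at every time point
#' and attains `n / norm` iff every replicate fails everywhere, which is the
#' critical fitness tolerance above which every proposal is accepted
#' (0.1 for n = 10 and 0.06 for n = 6 at norm = 100).
#'
#' @param b per-time-point failure counts (from [failure_counts()]).
#' @param B number of simulation replicates per time point.
#' @param norm normalizing particle count.
#' @return The scalar fitness error.
#' @examples
#' fitness_error_alg1(rep(10, 10), B = 10, norm = 100)  # 0.1
#' @export
fitness_error_alg1 <- function(b, B, norm) {
  if (any(b < 0) || any(b > B))
    stop("failure counts must lie in 0..B", call. = FALSE)
  sum(b) / (B * norm)
}

#' Fitness error of the whole-trajectory per-time-point scheme
#'
#' Identical aggregation to [fitness_error_alg1()], but the replicates are
#' whole trajectories simulated from the known initial state over the full
#' observation period rather than per-interval restarts.
#'
#' @inheritParams failure_counts
#' @inheritParams fitness_error_alg1
#' @return The scalar fitness error.
#' @export
fitness_error_alg2 <- function(observed, sims, alpha, norm, zero_floor = 0) {
  fitness_error_alg1(failure_counts(observed, sims, alpha, zero_floor),
                     B = length(sims), norm = norm)
}

#' Whole-trajectory distance between simulation and data
#'
#' Scalar trajectory discrepancies for the generic ABC SMC baseline:
#' `"rms_relative"` (default) is the root mean square over all time points
#' and species of `(X - Y) / max(X, 1)`; `"rms_absolute"` drops the
#' normalization; `"match_fraction"` is the fraction of time points failing
#' the [point_test()] at tolerance `alpha`.
#'
#' @param observed `n x S` matrix of observed states.
#' @param simulated `n x S` simulated state matrix.
#' @param method distance flavour.
#' @inheritParams point_test
#' @return A single non-negative number.
#' @export
trajectory_distance <- function(observed, simulated,
                                method = c("rms_relative", "rms_absolute",
                                           "match_fraction"),
                                alpha = NULL, zero_floor = 0) {
  method <- match.arg(method)
  observed <- as.matrix(observed); simulated <- as.matrix(simulated)
  if (!all(dim(observed) == dim(simulated)))
    stop("matrices differ in dimension", call. = FALSE)
  if (method == "match_fraction") {
    if (is.null(alpha))
      stop("'alpha' is required for the match_fraction distance",
           call. = FALSE)
    fails <- vapply(seq_len(nrow(observed)), function(l)
      !point_test(observed[l, ], simulated[l, ], alpha, zero_floor), TRUE)
    return(mean(fails))
  }
  diff <- observed - simulated
  if (method == "rms_relative") diff <- diff / pmax(observed, 1)
  sqrt(mean(diff^2))
}

#' Replicate match count of the generic ABC SMC baseline
#'
#' Counts the simulation replicates whose whole-trajectory distance to the
#' data is within the fitness tolerance; a proposal is viable when the count
#' is positive, and the count enters the first-iteration weights.
#'
#' @inheritParams failure_counts
#' @param epsilon fitness tolerance on the trajectory distance.
#' @inheritParams trajectory_distance
#' @return Integer in `0..B`.
#' @export
abc_smc_match_count <- function(observed, sims, epsilon,
                                method = c("rms_relative", "rms_absolute",
                                           "match_fraction"),
                                alpha = NULL, zero_floor = 0) {
  method <- match.arg(method)
  sum(vapply(sims, function(sim)
    trajectory_distance(observed, sim, method, alpha, zero_floor) <= epsilon,
    TRUE))
}

#' Frequency-distribution estimate of the transitional density
#'
#' The fraction of simulation replicates whose state matches the observed
#' state under the [point_test()] -- the empirical (simulated-likelihood)
#' estimate of the transitional density mass at the observation.
#'
#' @param observed_state observed copy-number vector at one time point.
#' @param simulated_states `B x S` matrix of simulated states at that time.
#' @inheritParams point_test
#' @return A number in `[0, 1]`.
#' @export
frequency_distribution <- function(observed_state, simulated_states, alpha,
                                   zero_floor = 0) {
  simulated_states <- as.matrix(simulated_states)
  mean(vapply(seq_len(nrow(simulated_states)), function(m)
    point_test(observed_state, simulated_states[m, ], alpha, zero_floor),
    TRUE))
}
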