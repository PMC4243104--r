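#' Generate synthetic experimental observations
#'
#' Emulates the benchmark protocol: a single exact SSA trajectory of the
#' network at its stored ("exact") rate constants, recorded every `dt` time
#' units over `[0, horizon]`.  The initial state is treated as known and is
#' not itself an observation; the `n = horizon / dt` recorded states are what
#' the inference drivers fit.
#'
#' @param network a [reaction_network()] carrying the generating rates.
#' @param horizon total observation period `T`; `horizon / dt` must be a
#'   positive integer.
#' @param dt grid step between observations.
#' @param seed integer seed (bit-reproducible).
#' @param max_events event guard passed to [ssa_simulate()].
#' @return An object of class `"observation_set"`: list with `x0`, `dt`,
#'   `horizon`, `n`, `times`, `states` (n x species) and `species`.
#' @examples
#' obs <- simulate_observations(system1_network(), horizon = 30, dt = 3,
#'                              seed = 1)
#' obs$n  # 10
#' @export
simulate_observations <- function(network, horizon, dt, seed,
                                  max_events = 1e8) {
  n <- horizon / dt
  if (abs(n - round(n)) > 1e-9 || round(n) < 1)
    stop("'horizon' must be a positive integer multiple of 'dt'",
         call. = FALSE)
  n <- round(n)
  tr <- ssa_simulate(network, times = dt * seq_len(n), seed = seed,
                     max_events = max_events)
  new_observation_set(x0 = stats::setNames(network$initial_state,
                                           network$species),
                      dt = dt, states = tr$states)
}

new_observation_set <- function(x0, dt, states) {
  n <- nrow(states)
  structure(list(x0 = x0, dt = dt, horizon = dt * n, n = n,
                 times = dt * seq_len(n), states = states,
                 species = colnames(states)),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat("Observation set:", x$n, "observations, dt =", x$dt,
      ", horizon =", x$horizon, "\n")
  cat("  known initial state:",
      paste(x$species, x$x0, sep = " = ", collapse = ", "), "\n")
  print(head(cbind(time = x$times, x$states)))
  if (x$n > 6) cat("  ...\n")
  invisible(x)
}

#' Coarsen an observation grid
#'
#' Keeps exactly the observations at multiples of `new_dt` (which must be an
#' integer multiple of the current step); no interpolation and no
#' re-simulation, so different step sizes share one underlying trajectory.
#'
#' @param obs an `"observation_set"`.
#' @param new_dt the coarser step.
#' @return An `"observation_set"` with step `new_dt`.
#' @examples
#' obs <- simulate_observations(system1_network(), 30, 1, seed = 1)
#' rebin(obs, 5)$n  # 6
#' @export
rebin <- function(obs, new_dt) {
  stopifnot(inherits(obs, "observation_set"))
  k <- new_dt / obs$dt
  if (abs(k - round(k)) > 1e-9 || round(k) < 1)
    stop("'new_dt' must be an integer multiple of the current dt",
         call. = FALSE)
  k <- round(k)
  if (k == 1) return(obs)
  idx <- seq(k, obs$n, by = k)
  new_observation_set(obs$x0, new_dt, obs$states[idx, , drop = FALSE])
}

#' Read or write an observation-set CSV
#'
#' Same dialect as [write_trajectory()], with the known initial state stored
#' as the `time = 0` row so the round trip is lossless.
#'
#' @param obs an `"observation_set"`.
#' @param path CSV file path.
#' @return `read_observations()` returns an `"observation_set"`;
#'   `write_observations()` returns `path` invisibly.
#' @export
write_observations <- function(obs, path) {
  df <- data.frame(time = c(0, obs$times),
                   rbind(obs$x0, obs$states), check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  tr <- read_trajectory(path)
  if (tr$times[1] != 0)
    stop("observation CSV must start with the time = 0 initial state",
         call. = FALSE)
  dts <- diff(tr$times)
  if (max(abs(dts - dts[1])) > 1e-9)
    stop("observation times must lie on a regular grid", call. = FALSE)
  new_observation_set(x0 = stats::setNames(tr$states[1, ], tr$species),
                      dt = dts[1],
                      states = tr$states[-1, , drop = FALSE])
}
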