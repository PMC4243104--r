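#' Independent uniform prior on rate constants
#'
#' Each rate constant gets an independent U(0, upper_j) prior; `upper` is the
#' vector of box bounds (e.g. `c(0.5, 0.005, 1, 0.1)` for the dimerization
#' benchmark).
#'
#' @param upper strictly positive numeric vector of upper bounds.
#' @return An object of class `"abc_prior"`.
#' @export
uniform_prior <- function(upper) {
  if (any(upper <= 0) || any(!is.finite(upper)))
    stop("'upper' bounds must be finite and positive", call. = FALSE)
  structure(list(upper = as.numeric(upper)), class = "abc_prior")
}

#' @export
print.abc_prior <- function(x, ...) {
  cat("Componentwise uniform prior U(0, A), A =",
      paste(x$upper, collapse = ", "), "\n")
  invisible(x)
}

#' Draw parameter vectors from the prior
#'
#' @param prior an [uniform_prior()].
#' @param n number of draws.
#' @return For `n = 1` a parameter vector, otherwise an `n x p` matrix.
#'   Uses R's RNG (see [set.seed()]).
#' @export
sample_prior <- function(prior, n = 1) {
  p <- length(prior$upper)
  draws <- matrix(runif(n * p), n, p, byrow = TRUE) *
    rep(prior$upper, each = n)
  if (n == 1) drop(draws) else draws
}

#' Prior density of a parameter vector
#'
#' @param prior an [uniform_prior()].
#' @param theta parameter vector.
#' @return `prod(1 / upper)` inside the box, 0 outside.
#' @export
prior_density <- function(prior, theta) {
  if (any(theta <= 0) || any(theta >= prior$upper)) return(0)
  prod(1 / prior$upper)
}

#' Weighted resampling of a particle index
#'
#' @param weights normalized particle weights.
#' @param n number of indices to draw.
#' @return Integer indices drawn with probability `weights`.  Uses R's RNG.
#' @export
resample_index <- function(weights, n = 1) {
  if (all(weights == 0)) stop("all particle weights are zero", call. = FALSE)
  sample.int(length(weights), n, replace = TRUE, prob = weights)
}

#' Perturb a resampled particle
#'
#' Componentwise jitter scaled by the previous population's spread
#' `sigma`: gaussian `N(theta_j, sigma_j^2)` or uniform
#' `U(theta_j - sigma_j, theta_j + sigma_j)`.  Components with
#' `sigma_j = 0` are left unchanged.
#'
#' @param theta parameter vector to perturb.
#' @param sigma componentwise non-negative scale (standard deviation).
#' @param kernel `"gaussian"` or `"uniform"`.
#' @return Perturbed parameter vector (may fall outside the prior support;
#'   the caller rejects via [prior_density()]).  Uses R's RNG.
#' @export
perturb <- function(theta, sigma, kernel = c("gaussian", "uniform")) {
  kernel <- match.arg(kernel)
  if (any(sigma < 0)) stop("'sigma' must be non-negative", call. = FALSE)
  p <- length(theta)
  jitter <- if (kernel == "gaussian") rnorm(p, 0, sigma)
            else runif(p, -sigma, sigma)
  theta + jitter
}

#' Perturbation-kernel density
#'
#' Product of componentwise kernel densities of moving from `theta_from` to
#' `theta_to` under scale `sigma`.  A component with `sigma_j = 0` is a point
#' mass: factor 1 when the components are equal, 0 otherwise.
#'
#' @param theta_to,theta_from parameter vectors.
#' @inheritParams perturb
#' @return A single non-negative density value.
#' @export
kernel_density <- function(theta_to, theta_from, sigma,
                           kernel = c("gaussian", "uniform")) {
  kernel <- match.arg(kernel)
  if (any(sigma < 0)) stop("'sigma' must be non-negative", call. = FALSE)
  d <- theta_to - theta_from
  out <- 1
  for (j in seq_along(d)) {
    out <- out * if (sigma[j] == 0) {
      as.numeric(d[j] == 0)
    } else if (kernel == "gaussian") {
      dnorm(d[j], 0, sigma[j])
    } else {
      if (abs(d[j]) <= sigma[j]) 1 / (2 * sigma[j]) else 0
    }
    if (out == 0) return(0)
  }
  out
}

#' Sequential importance weights of an accepted population
#'
#' First iteration (`prev_theta = NULL`): uniform weights `1/N`.  Later
#' iterations: `w_i` proportional to `prior(theta_i)` divided by
#' `sum_j prev_weights_j * kernel_density(theta_i | prev_theta_j)`,
#' normalized to sum to one.
#'
#' @param theta `N x p` matrix of accepted parameter vectors.
#' @param prev_theta previous population matrix, or `NULL` at iteration 1.
#' @param prev_weights previous normalized weights.
#' @param sigma perturbation scale used this iteration (the previous
#'   population's spread).
#' @param prior an [uniform_prior()].
#' @inheritParams perturb
#' @return Normalized weight vector.
#' @export
compute_weights <- function(theta, prev_theta = NULL, prev_weights = NULL,
                            sigma = NULL, prior = NULL,
                            kernel = c("gaussian", "uniform")) {
  theta <- as_theta_matrix(theta)
  N <- nrow(theta)
  if (is.null(prev_theta)) return(rep(1 / N, N))
  kernel <- match.arg(kernel)
  prev_theta <- as_theta_matrix(prev_theta)
  w <- numeric(N)
  for (i in seq_len(N)) {
    denom <- 0
    for (j in seq_len(nrow(prev_theta)))
      denom <- denom + prev_weights[j] *
        kernel_density(theta[i, ], prev_theta[j, ], sigma, kernel)
    w[i] <- if (denom > 0) prior_density(prior, theta[i, ]) / denom else 0
  }
  if (sum(w) <= 0)
    stop("all importance weights are zero; the perturbation kernel cannot ",
         "reach the accepted particles from the previous population",
         call. = FALSE)
  w / sum(w)
}

#' Componentwise spread of a particle population
#'
#' The perturbation scale carried between iterations: the square root of the
#' componentwise sample variance of the accepted parameter vectors
#' (optionally weighted).
#'
#' @param theta `N x p` matrix of particles (`N >= 2`).
#' @param weights optional normalized weights for a weighted variance.
#' @return Componentwise standard-deviation vector.
#' @export
population_sigma <- function(theta, weights = NULL) {
  theta <- as_theta_matrix(theta)
  if (nrow(theta) < 2)
    stop("at least two particles are needed", call. = FALSE)
  if (is.null(weights)) return(sqrt(apply(theta, 2, var)))
  mu <- colSums(theta * weights)
  sqrt(colSums(weights * sweep(theta, 2, mu)^2) / (1 - sum(weights^2)))
}

as_theta_matrix <- function(theta) {
  if (is.matrix(theta)) theta else matrix(theta, ncol = 1)
}
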