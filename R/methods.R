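#' @export
print.abc_fit <- function(x, ...) {
  K <- length(x$iterations)
  cat("ABC", switch(x$algorithm,
                    sld1 = "SLD (per-interval transitional density)",
                    sld2 = "SLD (whole-trajectory, per-time-point error)",
                    smc = "SMC (whole-trajectory distance)"),
      "fit\n")
  cat(sprintf("  %d particles, %d iteration(s), B = %s, seed %d%s\n",
              x$N, K, paste(unique(x$B), collapse = "/"), x$seed,
              if (x$stalled) " [stalled]" else ""))
  cat("  epsilon:", paste(signif(x$epsilon, 4), collapse = ", "), "\n")
  cat("  alpha:  ", paste(signif(x$alpha, 4), collapse = ", "), "\n")
  if (K) {
    cat("  posterior means (final iteration):\n")
    print(signif(coef(x), 4))
  }
  invisible(x)
}

#' @export
coef.abc_fit <- function(object, k = NULL, ...) {
  if (is.null(k)) k <- length(object$iterations)
  it <- object$iterations[[k]]
  stats::setNames(colSums(it$theta * it$weights),
                  paste0("c", seq_len(ncol(it$theta))))
}

#' @export
summary.abc_fit <- function(object, ...) {
  K <- length(object$iterations)
  post <- t(vapply(seq_len(K), function(k) coef(object, k),
                   numeric(length(object$prior$upper))))
  sds <- t(vapply(seq_len(K), function(k) object$iterations[[k]]$sigma,
                  numeric(length(object$prior$upper))))
  structure(list(fit = object, posterior_means = post, sigma = sds,
                 diagnostics = object$diagnostics),
            class = "summary.abc_fit")
}

#' @export
print.summary.abc_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-iteration diagnostics:\n")
  print(transform(x$diagnostics,
                  mn = round(mn, 2), accept_rate = signif(accept_rate, 3),
                  ae = ifelse(is.na(ae), NA, round(ae, 4)),
                  elapsed = round(elapsed, 2)), row.names = FALSE)
  cat("\nWeighted posterior means by iteration:\n")
  print(signif(x$posterior_means, 4))
  invisible(x)
}

#' Posterior histograms of the estimated rate constants
#'
#' @param x an [abc_fit()] result.
#' @param parameters parameter indices to display (default all).
#' @param k iteration (default last).
#' @param breaks bins per histogram.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the list of [posterior_histogram()] results.
#' @export
plot.abc_fit <- function(x, parameters = seq_along(x$prior$upper),
                         k = NULL, breaks = 20, ...) {
  if (is.null(k)) k <- length(x$iterations)
  np <- length(parameters)
  op <- par(mfrow = c(ceiling(np / 2), min(np, 2)),
            mar = c(4, 4, 2, 1))
  on.exit(par(op))
  out <- lapply(parameters, function(j) {
    h <- posterior_histogram(x, j, k, breaks)
    barplot(h$freq, names.arg = signif(h$mids, 2),
            xlab = paste0("c", j), ylab = "posterior frequency",
            main = paste0("iteration ", k), border = NA, ...)
    if (!is.null(x$true_rates)) {
      at <- x$true_rates[j] / x$prior$upper[j] * breaks
      abline(v = at * 1.2, col = "red3", lty = 2)
    }
    h
  })
  invisible(out)
}

#' Posterior-predictive trajectories
#'
#' Draws particles from the final (or chosen) population by weight and
#' simulates each on the observation grid from the known initial state.
#'
#' @param object an [abc_fit()] result.
#' @param nsim number of trajectories.
#' @param seed integer seed for both the particle draws and the simulations.
#' @param k iteration to draw from (default last).
#' @param ... unused.
#' @return List of `"ssa_trajectory"` objects with the drawn `theta`
#'   attached as attribute `"theta"`.
#' @export
simulate.abc_fit <- function(object, nsim = 1, seed = 1L, k = NULL, ...) {
  if (is.null(k)) k <- length(object$iterations)
  it <- object$iterations[[k]]
  obs <- object$observations
  set.seed(seed)
  idx <- resample_index(it$weights, nsim)
  lapply(seq_len(nsim), function(r) {
    net <- set_rates(object$network, it$theta[idx[r], ])
    tr <- ssa_simulate(net, times = obs$times,
                       seed = interval_seed(seed, k, r),
                       initial_state = obs$x0)
    attr(tr, "theta") <- it$theta[idx[r], ]
    tr
  })
}

#' Export populations and diagnostics of a fit
#'
#' Writes one CSV per iteration (columns `iteration`, `particle`,
#' `theta_1..theta_p`, `weight`, `count`) plus a JSON sidecar with the
#' per-iteration spread `sigma`, the diagnostics table and the
#' configuration echo.
#'
#' @param fit an [abc_fit()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_populations <- function(fit, dir) {
  stopifnot(inherits(fit, "abc_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- length(fit$prior$upper)
  paths <- character(0)
  for (k in seq_along(fit$iterations)) {
    it <- fit$iterations[[k]]
    df <- data.frame(iteration = k, particle = seq_len(fit$N), it$theta,
                     weight = it$weights, count = it$counts)
    names(df)[2 + seq_len(p)] <- paste0("theta_", seq_len(p))
    f <- file.path(dir, sprintf("population_%02d.csv", k))
    write.csv(df, f, row.names = FALSE, quote = FALSE)
    paths <- c(paths, f)
  }
  side <- file.path(dir, "diagnostics.json")
  jsonlite::write_json(
    list(sigma = lapply(fit$iterations, `[[`, "sigma"),
         diagnostics = fit$diagnostics,
         config = list(algorithm = fit$algorithm, N = fit$N, B = fit$B,
                       epsilon = fit$epsilon, alpha = fit$alpha,
                       norm = fit$norm, kernel = fit$kernel,
                       distance = fit$distance, seed = fit$seed,
                       prior_upper = fit$prior$upper)),
    side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, side))
}
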