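# Hill dose-response fitting: multi-start nonlinear least squares with the
# classed model object and its methods.

#' Fit a Hill promoter-activation model to a dose-response curve
#'
#' Least-squares fit of `rate = k_max * p^h / (K^h + p^h)` to the paired
#' (input level, production rate) points of a dose-response curve, by
#' Levenberg-Marquardt minimization multi-started from a coarse grid of
#' initial values; the best-of-starts fit is returned.
#'
#' Default bounds: `k_max` in `(0, 10 * max(rate)]`, `h` in `[0.5, 20]`,
#' `K` in `(0, 2 * max(p53)]`.
#'
#' @param curve A [build_dose_response()] object, or a data.frame with
#'   columns `p53` and `rate` (at least 4 points spanning the
#'   half-activation region).
#' @param bounds Optional named list overriding the default box bounds, each
#'   element a `c(lower, upper)` pair for `k_max`, `h`, or `K`.
#' @param n_starts Approximate number of multi-start initial values.
#' @return An object of class `hill_fit` with components `params`
#'   ([hill_params()] holding the fitted `k_max`, `h`, `K`), `fit` (the
#'   underlying `nls` object of the winning start), `data` (the fitted
#'   points), `rss`, `n_starts_converged`. Supports `print()`, `summary()`,
#'   `coef()`, `predict()`, `fitted()`, `residuals()`, `plot()`, and
#'   `simulate()`.
#' @seealso [simulate_reporter()], [build_dose_response()],
#'   [fit_hill_trajectory()] for the trajectory-space cross-check.
#' @export
#' @examples
#' p <- seq(50, 700, length.out = 20)
#' truth <- hill_params(k_max = 135, h = 7.5, K = 407, gamma = 0)
#' fit <- fit_hill(data.frame(p53 = p, rate = hill_rate(p, truth)))
#' coef(fit)
fit_hill <- function(curve, bounds = NULL, n_starts = 36) {
  pts <- if (inherits(curve, "dose_response")) curve$points else curve
  if (!is.data.frame(pts) || !all(c("p53", "rate") %in% names(pts)))
    stop("'curve' must be a dose_response or data.frame with p53 and rate")
  pts <- pts[is.finite(pts$p53) & is.finite(pts$rate), , drop = FALSE]
  if (nrow(pts) < 4) stop("need at least 4 finite dose-response points")
  if (diff(range(pts$rate)) <= 1e-10 * max(abs(pts$rate), 1))
    stop("degenerate dose-response: all rates equal; Hill parameters are ",
         "unidentifiable")
  max_rate <- max(pts$rate)
  max_p <- max(pts$p53)
  b <- list(k_max = c(1e-8, 10 * max_rate), h = c(0.5, 20),
            K = c(1e-8, 2 * max_p))
  if (!is.null(bounds)) b <- utils::modifyList(b, bounds)

  # coarse multi-start grid
  starts <- expand.grid(
    k_max = max_rate * c(0.8, 1.2, 2),
    h = c(1, 3, 8, 15),
    K = stats::quantile(pts$p53, c(0.25, 0.5, 0.75), names = FALSE))
  starts <- starts[seq_len(min(nrow(starts), n_starts)), , drop = FALSE]
  lower <- c(b$k_max[1], b$h[1], b$K[1])
  upper <- c(b$k_max[2], b$h[2], b$K[2])
  for (j in 1:3) starts[[j]] <- pmin(pmax(starts[[j]], lower[j]), upper[j])
  starts <- unique(starts)
  best <- NULL; best_rss <- Inf; converged <- 0L
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        rate ~ k_max * p53^h / (K^h + p53^h), data = pts,
        start = as.list(starts[i, ]), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    converged <- converged + 1L
    rss <- sum(stats::residuals(fit)^2)
    if (rss < best_rss) { best <- fit; best_rss <- rss }
  }
  if (is.null(best)) stop("all optimizer starts failed")
  cf <- stats::coef(best)
  structure(
    list(params = hill_params(cf[["k_max"]], cf[["h"]], cf[["K"]],
                              gamma = 0, tau_d = if (inherits(curve, "dose_response"))
                                curve$tau_d else 2,
                              gamma_units = "per_h"),
         fit = best, data = pts, rss = best_rss,
         n_starts_converged = converged, mode = "rate"),
    class = "hill_fit")
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(k_max = object$params$k_max, h = object$params$h, K = object$params$K)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill promoter-activation fit (", x$mode, "-space, ",
      nrow(x$data), " points)\n", sep = "")
  print(round(coef(x), 4))
  cat("residual sum of squares:", format(x$rss, digits = 5), "\n")
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  out <- list(coefficients = coef(object), rss = object$rss,
              n = nrow(object$data), mode = object$mode,
              n_starts_converged = object$n_starts_converged)
  if (inherits(object$fit, "nls"))
    out$se <- tryCatch(summary(object$fit)$coefficients[, "Std. Error"],
                       error = function(e) NULL)
  class(out) <- "summary.hill_fit"
  out
}

#' @export
print.summary.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (%s-space), %d points, RSS = %.5g\n",
              x$mode, x$n, x$rss))
  tab <- rbind(estimate = x$coefficients)
  if (!is.null(x$se)) tab <- rbind(tab, `std. error` = x$se[names(x$coefficients)])
  print(t(tab))
  cat(x$n_starts_converged, "of the multi-start fits converged\n")
  invisible(x)
}

#' Predict production rates from a fitted Hill model
#'
#' @param object A [fit_hill()] object.
#' @param newdata Numeric vector of input levels, or a data.frame with a
#'   `p53` column; defaults to the fitted points.
#' @param ... Unused.
#' @return Predicted production rates (AU/h).
#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  p <- if (is.null(newdata)) object$data$p53
  else if (is.data.frame(newdata)) newdata$p53
  else newdata
  hill_rate(p, object$params)
}

#' @export
fitted.hill_fit <- function(object, ...) predict(object)

#' @export
residuals.hill_fit <- function(object, ...) {
  object$data$rate - fitted(object)
}

#' @export
plot.hill_fit <- function(x, ...) {
  graphics::plot(x$data$p53, x$data$rate, pch = 16, col = "grey40",
                 xlab = "delayed input level (AU)",
                 ylab = "production rate (AU/h)", ...)
  pp <- seq(0, max(x$data$p53) * 1.05, length.out = 200)
  graphics::lines(pp, predict(x, pp), lwd = 2)
  graphics::abline(v = x$params$K, h = x$params$k_max / 2, lty = 2,
                   col = "grey60")
  invisible(x)
}

#' Simulate reporter trajectories from a fitted Hill model
#'
#' Forward-simulates the delayed Hill reporter ODE under a supplied input
#' trace using the fitted parameters, optionally adding Gaussian measurement
#' noise per simulation.
#'
#' @param object A [fit_hill()] object.
#' @param nsim Number of simulated replicates.
#' @param seed Random seed for the noise.
#' @param p53 Input trace: numeric vector (with `times`) or [trace_set()].
#' @param times Sample times (h) when `p53` is a vector.
#' @param noise_sd Additive Gaussian noise sd (AU), default 0.
#' @param tau_d,gamma Override the delay (h) / decay (1/h) used in the
#'   simulation; default to the fit's delay and zero decay.
#' @param ... Unused.
#' @return A matrix with one column per replicate (vector input), or a list
#'   of [trace_set()]s.
#' @export
simulate.hill_fit <- function(object, nsim = 1, seed = NULL, p53, times = NULL,
                              noise_sd = 0, tau_d = NULL, gamma = NULL, ...) {
  pars <- object$params
  if (!is.null(tau_d)) pars$tau_d <- tau_d
  if (!is.null(gamma)) pars$gamma <- gamma
  base <- simulate_reporter(p53, pars, times = times)
  local_seed(seed, {
    if (inherits(base, "trace_set")) {
      lapply(seq_len(nsim), function(i) {
        out <- base
        if (noise_sd > 0)
          out$values <- out$values +
            matrix(stats::rnorm(length(out$values), sd = noise_sd),
                   nrow(out$values))
        out
      })
    } else {
      sapply(seq_len(nsim), function(i) {
        if (noise_sd > 0) base + stats::rnorm(length(base), sd = noise_sd)
        else base
      })
    }
  })
}

#' Fit Hill parameters in trajectory space
#'
#' Alternative fitting mode used to cross-check the dose-response fit:
#' minimizes the sum of squared differences between the observed reporter
#' trajectory and the forward-simulated delayed Hill ODE, over
#' `(k_max, h, K)` on a log scale.
#'
#' @param p53 Input trace (numeric vector or [trace_set()], averaged).
#' @param mcherry Observed reporter trace on the same grid.
#' @param times Sample times (h).
#' @param tau_d Delay (h), default 2.
#' @param gamma Reporter decay (1/h), default 0.
#' @param start Optional named vector of starting values `c(k_max=, h=, K=)`.
#' @param substeps Integration sub-steps per frame.
#' @return A `hill_fit` object with `mode = "trajectory"`.
#' @export
fit_hill_trajectory <- function(p53, mcherry, times = NULL, tau_d = 2,
                                gamma = 0, start = NULL, substeps = 4) {
  if (inherits(p53, "trace_set")) { times <- times %||% p53$times; p53 <- mean_trace(p53) }
  if (inherits(mcherry, "trace_set")) { times <- times %||% mcherry$times; mcherry <- mean_trace(mcherry) }
  if (is.null(times)) stop("'times' required")
  stopifnot(length(p53) == length(times), length(mcherry) == length(times))
  if (is.null(start)) {
    rate_guess <- max(production_rate(mcherry, times))
    start <- c(k_max = max(rate_guess, 1e-3), h = 4,
               K = stats::median(p53))
  }
  obj <- function(logpar) {
    pars <- hill_params(exp(logpar[1]), exp(logpar[2]), exp(logpar[3]),
                        gamma = gamma, tau_d = tau_d, gamma_units = "per_h")
    sim <- simulate_reporter(p53, pars, times = times,
                             initial_mcherry = mcherry[1],
                             substeps = substeps)
    sum((sim - mcherry)^2)
  }
  opt <- stats::optim(log(start), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  cf <- exp(opt$par)
  structure(
    list(params = hill_params(cf[[1]], cf[[2]], cf[[3]], gamma = gamma,
                              tau_d = tau_d, gamma_units = "per_h"),
         fit = opt,
         data = data.frame(p53 = p53, rate = production_rate(mcherry, times)),
         rss = opt$value, n_starts_converged = 1L, mode = "trajectory"),
    class = "hill_fit")
}

#' Serialize Hill parameters to JSON
#'
#' @param params A [hill_params()] object (or the `params` of a fit).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hill_params <- function(params, path) {
  if (inherits(params, "hill_fit")) params <- params$params
  stopifnot(inherits(params, "hill_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read Hill parameters from JSON
#'
#' @param path File written by [write_hill_params()].
#' @return A [hill_params()] object (`gamma` interpreted in 1/h).
#' @export
read_hill_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  hill_params(x$k_max, x$h, x$K, gamma = x$gamma, tau_d = x$tau_d,
              gamma_units = "per_h")
}
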