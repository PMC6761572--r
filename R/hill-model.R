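# Delayed Hill promoter-activation model: parameters, forward simulation,
# production-rate estimation, dose-response construction.

#' Promoter-activation model parameters
#'
#' Parameters of the delayed Hill model for reporter protein accumulation,
#' \deqn{d[mCherry]/dt = k_{max} \frac{p53(t-\tau_d)^h}{K^h + p53(t-\tau_d)^h}
#'   - \gamma\,[mCherry]}
#' where `k_max` is the maximal production rate, `h` the Hill coefficient,
#' `K` the input level at which the production rate is `k_max/2`, `gamma`
#' the reporter protein decay rate, and `tau_d` the transcription /
#' translation / maturation delay.
#'
#' @param k_max Maximal production rate (AU/h), >= 0.
#' @param h Hill coefficient (dimensionless), > 0.
#' @param K Half-activation input level (normalized AU), > 0.
#' @param gamma Reporter decay rate; by default in 1/min (the
#'   experimentally determined value is 6.7e-4 per min, i.e. 0.0402 per h)
#'   and converted internally to 1/h. Set `gamma_units = "per_h"` to pass a
#'   value already in 1/h.
#' @param tau_d Delay (h), default 2.
#' @param gamma_units Units of the supplied `gamma`.
#' @return An object of class `hill_params` storing `gamma` in 1/h.
#' @export
#' @examples
#' hill_params(k_max = 135, h = 7.5, K = 407)
hill_params <- function(k_max, h, K, gamma = 6.7e-4, tau_d = 2,
                        gamma_units = c("per_min", "per_h")) {
  gamma_units <- match.arg(gamma_units)
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  if (!num1(k_max) || k_max < 0) stop("'k_max' must be a single number >= 0")
  if (!num1(h) || h <= 0) stop("'h' must be a single number > 0")
  if (!num1(K) || K <= 0) stop("'K' must be a single number > 0")
  if (!num1(gamma) || gamma < 0) stop("'gamma' must be a single number >= 0")
  if (!num1(tau_d) || tau_d < 0) stop("'tau_d' must be a single number >= 0")
  if (gamma_units == "per_min") gamma <- gamma * 60
  structure(list(k_max = k_max, h = h, K = K, gamma = gamma, tau_d = tau_d),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<hill_params> k_max = %g AU/h, h = %g, K = %g AU, ",
    "gamma = %g /h, tau_d = %g h\n"),
    x$k_max, x$h, x$K, x$gamma, x$tau_d))
  invisible(x)
}

#' Hill production rate
#'
#' Evaluates `k_max * p^h / (K^h + p^h)`; monotone non-decreasing in `p`,
#' equal to `k_max/2` at `p = K`, saturating at `k_max`.
#'
#' @param p Input level(s) (normalized AU), >= 0.
#' @param params A [hill_params()] object (only `k_max`, `h`, `K` used).
#' @return Production rate(s) (AU/h).
#' @export
hill_rate <- function(p, params) {
  stopifnot(inherits(params, "hill_params"))
  ph <- (pmax(p, 0) / params$K)^params$h
  params$k_max * ph / (1 + ph)
}

#' Forward-simulate the delayed Hill reporter model
#'
#' Integrates the reporter ODE on the trace's frame grid with a fixed-step
#' 4th-order Runge-Kutta scheme, sub-stepping each frame interval. The
#' delayed input `p53(t - tau_d)` is obtained by linear interpolation of the
#' sampled trace; for `t < tau_d` the pre-history is clamped to the t = 0
#' value. With `gamma = 0` the output is non-decreasing.
#'
#' @param p53 A [trace_set()] (simulated per cell) or numeric vector of
#'   input values.
#' @param params A [hill_params()] object.
#' @param times Sample times (h), required when `p53` is a vector.
#' @param initial_mcherry Initial reporter level (AU), default 0.
#' @param substeps Runge-Kutta sub-steps per frame interval (default 10,
#'   i.e. a 2-min step at 20-min sampling).
#' @return Same shape as the input: a [trace_set()] with channel
#'   `"reporter"`, or a numeric vector.
#' @export
#' @examples
#' pars <- hill_params(k_max = 10, h = 4, K = 1, gamma = 0, tau_d = 0)
#' times <- seq(0, 5, by = 1 / 3)
#' simulate_reporter(rep(1, length(times)), pars, times = times)
simulate_reporter <- function(p53, params, times = NULL,
                              initial_mcherry = 0, substeps = 10) {
  stopifnot(inherits(params, "hill_params"))
  if (inherits(p53, "trace_set")) {
    vals <- apply(p53$values, 2, simulate_reporter, params = params,
                  times = p53$times, initial_mcherry = initial_mcherry,
                  substeps = substeps)
    if (n_cells(p53) == 0)
      vals <- matrix(numeric(0), length(p53$times), 0)
    meta <- p53$metadata
    meta$model <- unclass(params)
    return(trace_set(p53$times, vals, channel = "reporter",
                     cell_ids = p53$cell_ids, metadata = meta))
  }
  stopifnot(is.numeric(p53))
  if (is.null(times)) stop("'times' required for a plain vector")
  stopifnot(length(times) == length(p53), length(times) >= 2)
  if (!is.numeric(initial_mcherry) || initial_mcherry < 0)
    stop("'initial_mcherry' must be >= 0")
  pfun <- stats::approxfun(times, p53, rule = 2)
  delayed <- function(t) pfun(t - params$tau_d)  # rule=2 clamps pre-history
  f <- function(t, m) hill_rate(delayed(t), params) - params$gamma * m
  n <- length(times)
  out <- numeric(n)
  out[1] <- m <- initial_mcherry
  for (i in 2:n) {
    h_frame <- times[i] - times[i - 1]
    hh <- h_frame / substeps
    t <- times[i - 1]
    for (s in seq_len(substeps)) {
      k1 <- f(t, m)
      k2 <- f(t + hh / 2, m + hh / 2 * k1)
      k3 <- f(t + hh / 2, m + hh / 2 * k2)
      k4 <- f(t + hh, m + hh * k3)
      m <- m + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + hh
    }
    out[i] <- m
  }
  out
}

#' Production-rate series by finite differences
#'
#' Estimates the time derivative of a (smoothed) reporter trace by central
#' finite differences on interior frames and one-sided differences at the
#' ends.
#'
#' @param x Numeric vector of reporter values (>= 3 frames), or a
#'   [trace_set()] (per-cell columns).
#' @param times Sample times (h), required for a vector.
#' @return Derivative series (AU/h), same shape as the input values.
#' @export
production_rate <- function(x, times = NULL) {
  if (inherits(x, "trace_set")) {
    return(apply(x$values, 2, production_rate, times = x$times))
  }
  stopifnot(is.numeric(x))
  if (is.null(times)) stop("'times' required for a plain vector")
  n <- length(x)
  if (n < 3) stop("trace must have at least 3 frames")
  stopifnot(length(times) == n)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / (times[2] - times[1])
  d[n] <- (x[n] - x[n - 1]) / (times[n] - times[n - 1])
  i <- 2:(n - 1)
  d[i] <- (x[i + 1] - x[i - 1]) / (times[i + 1] - times[i - 1])
  d
}

#' Rescale a tagged-protein signal to the total-protein scale
#'
#' Fluorescent fusion reporters only capture the tagged fraction of the
#' protein pool; dividing by `venus_fraction` (tagged / total, from e.g.
#' quantitative western blotting) converts the fluorescence signal to the
#' total-protein scale. Linear: `normalize(a*x) = a*normalize(x)`.
#'
#' @param x Numeric vector/matrix or [trace_set()].
#' @param venus_fraction Tagged fraction of the total protein, in `(0, 1]`.
#' @return Rescaled values, same shape as `x`.
#' @export
normalize_p53_total <- function(x, venus_fraction = 1) {
  if (!is.numeric(venus_fraction) || length(venus_fraction) != 1L ||
      !is.finite(venus_fraction) || venus_fraction <= 0 ||
      venus_fraction > 1)
    stop("'venus_fraction' must be a single number in (0, 1]")
  if (inherits(x, "trace_set")) {
    x$values <- x$values / venus_fraction
    return(add_history(x, sprintf("normalize_p53_total(%g)", venus_fraction)))
  }
  x / venus_fraction
}

#' Build a promoter dose-response curve
#'
#' Pairs the delayed input level with the reporter production rate, frame by
#' frame: for each sample time `t` in `window` with `t >= tau_d`, emits the
#' point `(p53(t - tau_d), d[mCherry]/dt (t))`, the derivative estimated by
#' [production_rate()]. Reporter decay is ignored inside the analysis
#' window (the protein half-life is long compared to the default 15-h
#' window). Inputs are typically population-mean traces; a [trace_set()]
#' argument is averaged across cells first.
#'
#' @param p53 Input trace: numeric vector or [trace_set()] (averaged).
#' @param mcherry Reporter trace on the same grid: numeric vector or
#'   [trace_set()] (averaged).
#' @param times Sample times (h); taken from a trace set when available.
#' @param tau_d Delay (h), default 2.
#' @param window Analysis span (h), default `c(0, 15)`; must lie within the
#'   trace span.
#' @param venus_fraction Tagged fraction used to rescale the input to the
#'   total-protein scale via [normalize_p53_total()] (default 1: input
#'   already on the total scale, as for synthetic data).
#' @return An object of class `dose_response`: a list with `points`
#'   (data.frame `p53`, `rate`, `time`), `window`, `tau_d`,
#'   `venus_fraction`.
#' @export
build_dose_response <- function(p53, mcherry, times = NULL, tau_d = 2,
                                window = c(0, 15), venus_fraction = 1) {
  if (inherits(p53, "trace_set")) {
    times <- times %||% p53$times
    p53 <- mean_trace(p53)
  }
  if (inherits(mcherry, "trace_set")) {
    times <- times %||% mcherry$times
    mcherry <- mean_trace(mcherry)
  }
  if (is.null(times)) stop("'times' required")
  stopifnot(is.numeric(p53), is.numeric(mcherry),
            length(p53) == length(times), length(mcherry) == length(times))
  if (length(window) != 2 || window[1] >= window[2])
    stop("'window' must be an increasing pair of times")
  if (window[1] < times[1] - 1e-9 || window[2] > times[length(times)] + 1e-9)
    stop("'window' exceeds the trace span")
  if (!is.numeric(tau_d) || tau_d < 0) stop("'tau_d' must be >= 0")
  p53 <- normalize_p53_total(p53, venus_fraction)
  rate <- production_rate(mcherry, times)
  sel <- which(times >= max(window[1], tau_d) - 1e-9 &
                 times <= window[2] + 1e-9)
  pfun <- stats::approxfun(times, p53, rule = 2)
  pts <- data.frame(p53 = pfun(times[sel] - tau_d), rate = rate[sel],
                    time = times[sel])
  structure(list(points = pts, window = window, tau_d = tau_d,
                 venus_fraction = venus_fraction),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf(paste0(
    "<dose_response> %d points over window [%g, %g] h (delay %g h)\n",
    "  input range [%.3g, %.3g] AU, rate range [%.3g, %.3g] AU/h\n"),
    nrow(x$points), x$window[1], x$window[2], x$tau_d,
    min(x$points$p53), max(x$points$p53),
    min(x$points$rate), max(x$points$rate)))
  invisible(x)
}

#' @export
as.data.frame.dose_response <- function(x, ...) x$points

#' @export
plot.dose_response <- function(x, ...) {
  graphics::plot(x$points$p53, x$points$rate, pch = 16,
                 xlab = "delayed input level (AU)",
                 ylab = "production rate (AU/h)", ...)
  invisible(x)
}

#' Export a dose-response curve as a two-column delimited table
#'
#' @param x A [build_dose_response()] object.
#' @param path Output path (tab-separated, columns `p53`, `rate`).
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(x, path) {
  stopifnot(inherits(x, "dose_response"))
  utils::write.table(x$points[, c("p53", "rate")], file = path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
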