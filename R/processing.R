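# Post-segmentation trace processing: background subtraction, gap
# interpolation, smoothing, t0 normalization, pulse-count QC, cumulative
# signal.

#' Subtract the modal background intensity
#'
#' Estimates the background as the mode of a histogram of all supplied
#' values (the centre of the tallest bin, with bins centred so that integer
#' data fall on bin centres) and subtracts it, flooring at zero.
#'
#' @param x Numeric vector/matrix of intensities, or a [trace_set()].
#' @param bins Number of histogram bins (>= 2).
#' @return Same shape as `x`, background-subtracted and floored at 0.
#' @export
#' @examples
#' subtract_background(c(5, 5, 5, 9), bins = 4)
subtract_background <- function(x, bins = 100) {
  if (inherits(x, "trace_set")) {
    bg <- histogram_mode(as.vector(x$values), bins)
    x$values <- pmax(x$values - bg, 0)
    return(add_history(x, sprintf("subtract_background(bins=%d)", bins)))
  }
  pmax(x - histogram_mode(as.vector(x), bins), 0)
}

# internal: histogram mode (centre of tallest bin, bins centred on the data)
histogram_mode <- function(v, bins) {
  if (length(v) == 0 || all(!is.finite(v))) stop("empty input")
  v <- v[is.finite(v)]
  if (!is.numeric(bins) || length(bins) != 1L || bins < 2)
    stop("'bins' must be a single number >= 2")
  r <- range(v)
  if (diff(r) == 0) return(r[1])
  w <- diff(r) / bins
  breaks <- seq(r[1] - w / 2, r[2] + w / 2 + w * 1e-9, by = w)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Fill missing frames by linear interpolation
#'
#' Interior missing frames (NA) are filled by linear interpolation between
#' the nearest measured neighbours; leading/trailing gaps are filled with the
#' nearest measured value. Idempotent.
#'
#' @param x Numeric vector with NAs, or a [trace_set()] (applied per cell).
#' @param times Sample times, required when `x` is a vector (defaults to the
#'   frame index).
#' @return Same shape as `x` with no missing values.
#' @export
#' @examples
#' interpolate_gaps(c(2, NA, 4))
interpolate_gaps <- function(x, times = NULL) {
  if (inherits(x, "trace_set")) {
    x$values <- apply(x$values, 2, interpolate_gaps, times = x$times)
    return(add_history(x, "interpolate_gaps"))
  }
  stopifnot(is.numeric(x))
  if (is.null(times)) times <- seq_along(x)
  ok <- is.finite(x)
  if (sum(ok) == 0) stop("trace has no measured frames")
  if (all(ok)) return(x)
  if (sum(ok) == 1) return(rep(x[ok], length(x)))
  stats::approx(times[ok], x[ok], xout = times, rule = 2)$y
}

#' Smooth a trace with a centred moving average
#'
#' The default smoother is a centred moving average of odd `window` length
#' with symmetric edge shrinkage (the half-width shrinks near the ends so the
#' window stays centred); output length equals input length. A custom
#' smoother can be plugged in via `method`.
#'
#' @param x Numeric vector, or a [trace_set()] (applied per cell).
#' @param window Odd window length in frames (default 3 frames = 1 h at
#'   20-min sampling); must be `>= 1` and at most the trace length.
#' @param method `"ma"` (default) or a function `f(values, window)` returning
#'   a vector of the same length.
#' @return Smoothed values, same shape as `x`.
#' @export
#' @examples
#' smooth_traces(c(0, 0, 1, 0, 0), window = 3)
smooth_traces <- function(x, window = 3, method = "ma") {
  if (inherits(x, "trace_set")) {
    x$values <- apply(x$values, 2, smooth_traces, window = window,
                      method = method)
    return(add_history(x, sprintf("smooth(window=%d)", window)))
  }
  stopifnot(is.numeric(x))
  if (is.function(method)) return(method(x, window))
  if (!identical(method, "ma")) stop("unknown smoothing method")
  n <- length(x)
  if (window %% 2 == 0) stop("'window' must be odd")
  if (window < 1 || window > n) stop("'window' must be in [1, trace length]")
  if (window == 1) return(x)
  r <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    ri <- min(r, i - 1, n - i)  # symmetric shrinkage at the edges
    mean(x[(i - ri):(i + ri)])
  }, numeric(1))
}

#' Normalize a trace set to the mean first-frame level
#'
#' Divides every value by the cross-cell mean fluorescence at the first
#' timepoint, correcting for between-movie illumination differences. After
#' normalization the cross-cell mean at t = 0 equals 1.
#'
#' @param x A [trace_set()] with a positive cross-cell mean at t = 0.
#' @return The normalized [trace_set()].
#' @export
normalize_to_t0 <- function(x) {
  stopifnot(inherits(x, "trace_set"))
  if (n_cells(x) == 0) stop("empty trace set")
  divisor <- mean(x$values[1, ])
  if (!is.finite(divisor) || divisor <= 0)
    stop("cross-cell mean at t = 0 must be > 0 (got ", format(divisor), ")")
  x$values <- x$values / divisor
  x$metadata$t0_divisor <- divisor
  add_history(x, sprintf("normalize_to_t0(divisor=%.6g)", divisor))
}

# internal: local maxima (strict on the right, non-strict left edge of
# plateaus) and their topographic prominence
find_peaks <- function(v) {
  n <- length(v)
  if (n < 3) return(data.frame(index = integer(0), prominence = numeric(0)))
  # a plateau peak is counted once, at its rightmost sample
  idx <- which(v[2:(n - 1)] > v[3:n] & v[2:(n - 1)] >= v[1:(n - 2)]) + 1L
  if (!length(idx)) return(data.frame(index = integer(0),
                                      prominence = numeric(0)))
  prom <- vapply(idx, function(i) {
    left <- v[1:i]
    higher_l <- which(left[-length(left)] > v[i])
    lo_l <- if (length(higher_l)) min(v[(max(higher_l) + 1):i]) else min(left)
    right <- v[i:n]
    higher_r <- which(right[-1] > v[i])
    lo_r <- if (length(higher_r)) min(v[i:(i + min(higher_r))]) else min(right)
    v[i] - max(lo_l, lo_r)
  }, numeric(1))
  data.frame(index = idx, prominence = prom)
}

#' Count pulses in a trace by peak prominence
#'
#' A pulse is a local maximum whose topographic prominence exceeds
#' `prominence_frac` times the trace's dynamic range (max - min). A flat
#' trace has zero pulses.
#'
#' @param x Numeric vector of processed trace values.
#' @param prominence_frac Fraction of the dynamic range a peak must rise
#'   above its surroundings (default 0.2).
#' @return Integer pulse count.
#' @export
count_pulses <- function(x, prominence_frac = 0.2) {
  stopifnot(is.numeric(x))
  rng <- diff(range(x))
  if (!is.finite(rng) || rng == 0) return(0L)
  pk <- find_peaks(x)
  sum(pk$prominence > prominence_frac * rng)
}

#' Quality-control selection of compliant transcription-factor traces
#'
#' Keeps cells whose pulse count equals the number of completed on-phases of
#' the regimen ([expected_pulse_count()]) and whose largest frame-to-frame
#' jump stays below `spike_frac` of the trace's dynamic range (spike
#' rejection). Returns both partitions with per-cell rejection reasons.
#'
#' @param x A processed [trace_set()] (channel `"p53"` typically).
#' @param regimen The [regimen()] the cells were exposed to.
#' @param prominence_frac Pulse-counting prominence threshold, see
#'   [count_pulses()].
#' @param spike_frac Frame-to-frame jump threshold as a fraction of the
#'   dynamic range (default 0.5).
#' @return List with `kept` (a [trace_set()]) and `rejected` (data.frame
#'   `cell_id`, `reason`, `pulse_count`).
#' @export
qc_select <- function(x, regimen, prominence_frac = 0.2, spike_frac = 0.5) {
  stopifnot(inherits(x, "trace_set"), inherits(regimen, "pulse_regimen"))
  expected <- expected_pulse_count(regimen)
  reasons <- character(0); rej_ids <- character(0); rej_counts <- integer(0)
  keep <- logical(n_cells(x))
  for (j in seq_len(n_cells(x))) {
    v <- x$values[, j]
    cnt <- count_pulses(v, prominence_frac)
    rng <- diff(range(v))
    spike <- rng > 0 && max(abs(diff(v))) > spike_frac * rng
    if (spike) {
      rej_ids <- c(rej_ids, x$cell_ids[j]); reasons <- c(reasons, "spike")
      rej_counts <- c(rej_counts, cnt)
    } else if (cnt != expected) {
      rej_ids <- c(rej_ids, x$cell_ids[j])
      reasons <- c(reasons, sprintf("pulse_count_%d_expected_%d", cnt, expected))
      rej_counts <- c(rej_counts, cnt)
    } else keep[j] <- TRUE
  }
  kept <- x[which(keep)]
  kept <- add_history(kept, sprintf("qc_select(expected=%d)", expected))
  list(kept = kept,
       rejected = data.frame(cell_id = rej_ids, reason = reasons,
                             pulse_count = rej_counts,
                             stringsAsFactors = FALSE))
}

#' Cumulative signal (trapezoidal integral) of a trace
#'
#' Integrates the trace from time 0 to `t_end` by the trapezoid rule, with
#' linear interpolation when `t_end` falls between frames.
#'
#' @param x Numeric vector of trace values, or a [trace_set()] (returns one
#'   integral per cell).
#' @param times Sample times (h); taken from the trace set when `x` is one.
#' @param t_end Upper integration limit (h); defaults to the trace end. Must
#'   lie within the trace span.
#' @return Cumulative signal in AU.h (named vector for a trace set).
#' @export
cumulative_signal <- function(x, times = NULL, t_end = NULL) {
  if (inherits(x, "trace_set")) {
    out <- apply(x$values, 2, cumulative_signal, times = x$times,
                 t_end = t_end)
    return(out)
  }
  stopifnot(is.numeric(x))
  if (is.null(times)) stop("'times' required for a plain vector")
  stopifnot(length(times) == length(x))
  if (is.null(t_end)) t_end <- times[length(times)]
  if (t_end < times[1] || t_end > times[length(times)] + 1e-9)
    stop("'t_end' outside the trace span [", times[1], ", ",
         times[length(times)], "]")
  keep <- times <= t_end + 1e-12
  tt <- times[keep]; vv <- x[keep]
  if (t_end > tt[length(tt)] + 1e-12) {
    vend <- stats::approx(times, x, xout = t_end)$y
    tt <- c(tt, t_end); vv <- c(vv, vend)
  }
  pracma::trapz(tt, vv)
}
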