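# Promoter-activation metrics: responder classification, timing / magnitude /
# rate, matched cumulative-input rate comparison, group statistics.

#' Classify a reporter trace as responding or non-responding
#'
#' A cell is non-responding if its final activation level is less than two
#' times its minimum activation level; otherwise it responds. The ratio rule
#' requires a positive minimum; when the minimum is not positive (possible
#' after background subtraction) the function falls back to an absolute
#' rule, `final - min >= min_floor`, and emits a warning.
#'
#' Scale-invariant: multiplying a trace by a positive constant preserves the
#' label (under the ratio rule).
#'
#' @param x Numeric vector of processed reporter values.
#' @param min_floor Absolute increase (AU) required by the fallback rule,
#'   default 1.
#' @return Logical: `TRUE` for a responder.
#' @export
#' @examples
#' classify_responder(c(1, 1.5, 2.1))  # TRUE
#' classify_responder(c(1, 1.5, 1.9))  # FALSE
classify_responder <- function(x, min_floor = 1) {
  stopifnot(is.numeric(x), length(x) >= 2)
  lo <- min(x)
  final <- x[length(x)]
  if (lo <= 0) {
    warning("non-positive trace minimum; using absolute-increase rule ",
            "(final - min >= ", min_floor, ")")
    return((final - lo) >= min_floor)
  }
  final >= 2 * lo
}

#' Promoter activation metrics for a responding trace
#'
#' Computes the three activation metrics:
#' * `timing` -- time to half-maximal activation: the first time the trace
#'   crosses `baseline + (peak - baseline)/2`, linearly interpolated between
#'   frames;
#' * `magnitude` -- the level at half-maximal activation (the half-max level
#'   itself);
#' * `rate` -- initial accumulation rate: the least-squares slope of the
#'   trace between activation onset (first crossing of
#'   `baseline + onset_frac * (peak - baseline)`) and `timing`.
#'
#' `baseline` is the mean of the first `baseline_frames` frames and `peak`
#' the trace maximum.
#'
#' @param x Numeric vector of reporter values (a responding cell).
#' @param times Sample times (h).
#' @param baseline_frames Frames averaged for the baseline (default 3 = 1 h).
#' @param onset_frac Fraction of the dynamic range defining activation onset
#'   for the rate window (default 0.1).
#' @return Named list: `timing` (h), `magnitude` (AU), `rate` (AU/h),
#'   `baseline` (AU), `peak` (AU).
#' @export
#' @examples
#' tt <- seq(0, 24, by = 1 / 3)
#' compute_metrics(tt * 10, tt)  # linear ramp
compute_metrics <- function(x, times, baseline_frames = 3, onset_frac = 0.1) {
  stopifnot(is.numeric(x), is.numeric(times), length(x) == length(times),
            length(x) >= baseline_frames)
  baseline <- mean(x[seq_len(baseline_frames)])
  peak <- max(x)
  if (peak <= baseline)
    stop("no activation: trace peak (", format(peak),
         ") does not exceed baseline (", format(baseline), ")")
  cross_time <- function(level) {
    i <- which(x >= level)[1]
    if (is.na(i)) stop("trace never reaches level ", format(level))
    if (i == 1) return(times[1])
    t0 <- times[i - 1]; t1 <- times[i]
    v0 <- x[i - 1]; v1 <- x[i]
    t0 + (level - v0) / (v1 - v0) * (t1 - t0)
  }
  half <- baseline + (peak - baseline) / 2
  onset_level <- baseline + onset_frac * (peak - baseline)
  t_half <- cross_time(half)
  t_on <- cross_time(onset_level)
  # least-squares slope over [onset, timing], including the interpolated
  # boundary points so the window is exactly the spec'd interval
  inside <- times > t_on & times < t_half
  xs <- c(t_on, times[inside], t_half)
  ys <- c(onset_level, x[inside], half)
  dt <- if (length(times) > 1) times[2] - times[1] else 1
  rate <- if (diff(range(xs)) > dt / 100) {
    unname(stats::coef(stats::lm(ys ~ xs))[2])
  } else {
    # onset and half-max crossed essentially together (step-like or noisy
    # trace): fall back to the slope of the frame segment at the crossing
    j <- max(min(findInterval(t_half, times), length(x) - 1L), 1L)
    (x[j + 1] - x[j]) / (times[j + 1] - times[j])
  }
  list(timing = t_half, magnitude = half, rate = rate,
       baseline = baseline, peak = peak)
}

#' Per-cell promoter metrics for a trace set
#'
#' Applies [classify_responder()] to every cell and [compute_metrics()] to
#' the responders; non-responders carry the label with baseline and peak
#' only (metrics NA).
#'
#' @param x A processed reporter [trace_set()].
#' @param baseline_frames,onset_frac See [compute_metrics()].
#' @param min_floor See [classify_responder()].
#' @return data.frame with columns `cell_id`, `responder`, `timing_h`,
#'   `magnitude_au`, `rate_au_per_h`, `baseline_au`, `peak_au`.
#' @export
promoter_metrics <- function(x, baseline_frames = 3, onset_frac = 0.1,
                             min_floor = 1) {
  stopifnot(inherits(x, "trace_set"))
  if (n_cells(x) == 0) stop("empty trace set")
  rows <- lapply(seq_len(n_cells(x)), function(j) {
    v <- x$values[, j]
    resp <- classify_responder(v, min_floor = min_floor)
    base <- mean(v[seq_len(baseline_frames)])
    if (resp && max(v) > base) {
      m <- compute_metrics(v, x$times, baseline_frames, onset_frac)
      data.frame(cell_id = x$cell_ids[j], responder = TRUE,
                 timing_h = m$timing, magnitude_au = m$magnitude,
                 rate_au_per_h = m$rate, baseline_au = m$baseline,
                 peak_au = m$peak, stringsAsFactors = FALSE)
    } else {
      data.frame(cell_id = x$cell_ids[j], responder = resp,
                 timing_h = NA_real_, magnitude_au = NA_real_,
                 rate_au_per_h = NA_real_, baseline_au = base,
                 peak_au = max(v), stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Percentage of responding cells
#'
#' @param x A reporter [trace_set()], a [promoter_metrics()] data.frame, or
#'   a logical vector of responder labels.
#' @param ... Passed to [classify_responder()] when `x` is a trace set.
#' @return Percentage in `[0, 100]`.
#' @export
percent_responding <- function(x, ...) {
  labels <- if (inherits(x, "trace_set")) {
    if (n_cells(x) == 0) stop("empty trace set")
    apply(x$values, 2, classify_responder, ...)
  } else if (is.data.frame(x)) {
    if (nrow(x) == 0) stop("empty metrics table")
    x$responder
  } else if (is.logical(x)) {
    if (length(x) == 0) stop("empty label vector")
    x
  } else stop("unsupported input")
  100 * mean(labels)
}

#' Activation rate at matched cumulative input
#'
#' Compares promoter activation between dosing regimens at times of
#' equivalent cumulative transcription-factor exposure. Let `C*` be the
#' cumulative input of the reference regimen (typically long duration) at
#' its first pulse peak `t_peak_ref`. For the comparison regimen, `t_X` is
#' the earliest time its cumulative input reaches `C*`, and the activation
#' rate is the mean reporter slope between the comparison regimen's first
#' pulse peak and `t_X + tau_period`:
#' `rate = (mCherry(t_X + tau) - mCherry(t_peak_cmp)) / (t_X + tau - t_peak_cmp)`
#' with `tau = tau_period` the natural pulse period (5.5 h).
#'
#' Self-comparison identity: with identical input traces, `t_X = t_peak` and
#' the result is the plain mean slope over `[t_peak, t_peak + tau_period]`.
#'
#' @param p53_ref Reference-regimen mean input trace (vector or
#'   [trace_set()], averaged).
#' @param p53_cmp Comparison-regimen mean input trace on the same grid.
#' @param mcherry_cmp Comparison-regimen mean reporter trace on the same
#'   grid.
#' @param times Sample times (h).
#' @param tau_period Natural pulse period (h), default 5.5.
#' @param prominence_frac Peak-detection prominence for locating first pulse
#'   peaks, see [count_pulses()].
#' @return List with `rate` (AU/h) and `spec` (list `t_peak_ref`,
#'   `t_peak_cmp`, `t_X`, `tau_period`, `C_star`).
#' @export
matched_rate <- function(p53_ref, p53_cmp, mcherry_cmp, times = NULL,
                         tau_period = 5.5, prominence_frac = 0.2) {
  grab <- function(x) {
    if (inherits(x, "trace_set")) {
      times <<- times %||% x$times
      mean_trace(x)
    } else x
  }
  ref <- grab(p53_ref); cmp <- grab(p53_cmp); mch <- grab(mcherry_cmp)
  if (is.null(times)) stop("'times' required")
  stopifnot(length(ref) == length(times), length(cmp) == length(times),
            length(mch) == length(times))
  first_peak <- function(v) {
    pk <- find_peaks(v)
    pk <- pk[pk$prominence > prominence_frac * diff(range(v)), , drop = FALSE]
    if (nrow(pk) == 0) stop("no pulse peak found in input trace")
    times[pk$index[1]]
  }
  t_peak_ref <- first_peak(ref)
  t_peak_cmp <- first_peak(cmp)
  C_star <- cumulative_signal(ref, times, t_end = t_peak_ref)
  # earliest time the comparison cumulative input reaches C*
  cum_cmp <- pracma::cumtrapz(times, cmp)[, 1]
  i <- which(cum_cmp >= C_star)[1]
  if (is.na(i))
    stop("comparison regimen never reaches the reference cumulative input ",
         "within the trace span (attained ", format(max(cum_cmp)),
         " of ", format(C_star), ")")
  t_X <- if (i == 1) times[1] else {
    # linear interpolation of the cumulative integral within the frame
    times[i - 1] + (C_star - cum_cmp[i - 1]) /
      (cum_cmp[i] - cum_cmp[i - 1]) * (times[i] - times[i - 1])
  }
  t_end <- t_X + tau_period
  if (t_end > times[length(times)] + 1e-9)
    stop("t_X + tau_period (", format(t_end), " h) exceeds the trace span")
  if (t_end <= t_peak_cmp)
    stop("matched-rate interval is empty: t_X + tau_period <= t_peak_cmp")
  mfun <- stats::approxfun(times, mch)
  rate <- (mfun(t_end) - mfun(t_peak_cmp)) / (t_end - t_peak_cmp)
  list(rate = rate,
       spec = list(t_peak_ref = t_peak_ref, t_peak_cmp = t_peak_cmp,
                   t_X = t_X, tau_period = tau_period, C_star = C_star))
}

#' Two-sample comparison of metric groups
#'
#' Equal-variance two-sample t-test; differences with `p < 0.05` are flagged
#' significant.
#'
#' @param values_a,values_b Numeric vectors (each of length >= 2).
#' @param alpha Significance level, default 0.05.
#' @return List with `statistic`, `df`, `p_value`, `significant`,
#'   `mean_a`, `mean_b`.
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05) {
  stopifnot(is.numeric(values_a), is.numeric(values_b))
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 finite values")
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0)
    stop("degenerate groups: zero variance in both samples")
  tt <- stats::t.test(values_a, values_b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, significant = tt$p.value < alpha,
       mean_a = mean(values_a), mean_b = mean(values_b))
}

#' Export a promoter metrics table
#'
#' @param metrics A [promoter_metrics()] data.frame.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.table(metrics, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
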