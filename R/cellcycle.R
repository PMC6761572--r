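# Cell-cycle outcome scoring from geminin reporter traces.

#' Classify a geminin trace as arrest or progression
#'
#' The elevation threshold is relative: `basal_threshold_factor` times the
#' cell's own baseline (mean of the first `baseline_frames` frames), so the
#' classification is invariant to positive rescaling of the trace.
#' `basal_hours` is the total time the trace spends below the threshold;
#' a cell is `arrested` when it stays basal for more than `arrest_hours`
#' (default 25 h of a 40-h movie). Progressing cells are `pulsatile` when
#' the elevated signal returns to basal at least once before the trace end
#' (geminin is degraded at mitosis), otherwise `sustained`.
#'
#' @param x Numeric vector of geminin values, or a [trace_set()] (use
#'   [classify_cellcycle_set()] for per-cell tables).
#' @param times Sample times (h).
#' @param basal_threshold_factor Elevation threshold as a multiple of the
#'   per-cell baseline (> 1, default 1.5).
#' @param arrest_hours Basal-time threshold for arrest (h), default 25.
#' @param baseline_frames Frames averaged for the baseline (default 3).
#' @param require_span Minimum trace span (h), default 40; set `NULL` to
#'   analyse shorter traces.
#' @return List with `status` (one of `arrested`, `progressing_sustained`,
#'   `progressing_pulsatile`) and `basal_hours`.
#' @export
classify_cellcycle <- function(x, times, basal_threshold_factor = 1.5,
                               arrest_hours = 25, baseline_frames = 3,
                               require_span = 40) {
  stopifnot(is.numeric(x), is.numeric(times), length(x) == length(times))
  if (!is.null(require_span) &&
      times[length(times)] - times[1] < require_span - 1e-9)
    stop("trace spans ", times[length(times)] - times[1], " h; ",
         require_span, " h required (set require_span = NULL to override)")
  if (basal_threshold_factor <= 1)
    stop("'basal_threshold_factor' must be > 1")
  baseline <- mean(x[seq_len(min(baseline_frames, length(x)))])
  threshold <- basal_threshold_factor * baseline
  below <- x < threshold
  dt <- (times[length(times)] - times[1]) / (length(times) - 1)
  basal_hours <- min(sum(below) * dt, times[length(times)] - times[1])
  if (basal_hours > arrest_hours) {
    return(list(status = "arrested", basal_hours = basal_hours))
  }
  # pulsatile: the signal comes back down to basal after an elevated episode
  first_up <- which(!below)[1]
  returns <- !is.na(first_up) && any(below[first_up:length(below)])
  list(status = if (returns) "progressing_pulsatile"
       else "progressing_sustained",
       basal_hours = basal_hours)
}

#' Count annotated division events
#'
#' @param divisions Numeric vector of division times (h) for one cell, as
#'   carried in `trace_set$divisions`. Missing annotations are an error:
#'   division events come from tracking (or the synthetic generator), not
#'   from the trace values.
#' @param t_max Count events in `[0, t_max]` (default 40 h).
#' @return Integer count.
#' @export
count_divisions <- function(divisions, t_max = 40) {
  if (is.null(divisions))
    stop("no division annotations: supply division times from cell tracking ",
         "or the synthetic generator")
  stopifnot(is.numeric(divisions))
  sum(divisions >= 0 & divisions <= t_max)
}

#' Cell-cycle labels for every cell of a geminin trace set
#'
#' @param x A geminin [trace_set()] with optional division annotations.
#' @param ... Passed to [classify_cellcycle()].
#' @param t_max Division-counting window (h), default 40.
#' @return data.frame with columns `cell_id`, `status`, `divided`,
#'   `n_divisions`, `basal_hours`.
#' @export
classify_cellcycle_set <- function(x, ..., t_max = 40) {
  stopifnot(inherits(x, "trace_set"))
  if (n_cells(x) == 0) stop("empty trace set")
  rows <- lapply(seq_len(n_cells(x)), function(j) {
    id <- x$cell_ids[j]
    cl <- classify_cellcycle(x$values[, j], x$times, ...)
    div_times <- if (!is.null(x$divisions)) x$divisions[[id]] else NULL
    nd <- if (is.null(div_times)) 0L else count_divisions(div_times, t_max)
    data.frame(cell_id = id, status = cl$status, divided = nd > 0,
               n_divisions = nd, basal_hours = cl$basal_hours,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Population summary of cell-cycle outcomes
#'
#' @param labels A [classify_cellcycle_set()] data.frame (columns `status`
#'   and, if available, `divided`).
#' @return List with `percent_divided`, `percent_geminin_positive`
#'   (progressing, sustained or pulsatile), `n`, and `percent_by_status`
#'   (named vector over the three statuses, summing to 100).
#' @export
summarize_population <- function(labels) {
  if (!is.data.frame(labels) || nrow(labels) == 0)
    stop("need at least one labelled cell")
  statuses <- c("arrested", "progressing_sustained", "progressing_pulsatile")
  if (!all(labels$status %in% statuses))
    stop("unknown status values: ",
         paste(setdiff(labels$status, statuses), collapse = ", "))
  by_status <- 100 * vapply(statuses, function(s) mean(labels$status == s),
                            numeric(1))
  list(
    percent_divided = if ("divided" %in% names(labels))
      100 * mean(labels$divided) else NA_real_,
    percent_geminin_positive = 100 * mean(labels$status != "arrested"),
    n = nrow(labels),
    percent_by_status = by_status)
}

#' Export cell-cycle labels
#'
#' @param labels A [classify_cellcycle_set()] data.frame.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_cellcycle_labels <- function(labels, path) {
  utils::write.table(labels, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
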