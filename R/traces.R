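# Single-cell fluorescence trace containers and long-format table IO.

#' Construct a set of single-cell fluorescence traces
#'
#' A `trace_set` holds uniformly sampled fluorescence time series for one
#' channel, all cells sharing a common time grid (default frame interval
#' 20 min). It is the common currency of the processing, modelling, and
#' classification functions.
#'
#' @param times Numeric vector of sample times (h), strictly increasing with
#'   uniform spacing.
#' @param values Numeric matrix, `length(times)` rows by one column per cell
#'   (a vector is treated as a single cell).
#' @param channel Channel label, e.g. `"p53"`, `"reporter"`, `"geminin"`.
#' @param cell_ids Optional character vector of cell identifiers (defaults to
#'   `cell_001`, `cell_002`, ...).
#' @param divisions Optional named list mapping cell id to a numeric vector of
#'   division event times (h).
#' @param metadata List of free-form metadata. The generators record the
#'   regimen, the seed, and a `history` character vector of processing steps.
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(times, values, channel,
                      cell_ids = NULL, divisions = NULL, metadata = list()) {
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  stopifnot(is.numeric(times), is.numeric(values))
  if (nrow(values) != length(times))
    stop("'values' must have one row per time point")
  if (length(times) >= 2) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("'times' must be strictly increasing")
    if (diff(range(dt)) > 1e-6 * max(dt))
      stop("'times' must be uniformly spaced")
  }
  if (any(!is.finite(times))) stop("'times' must be finite")
  if (is.null(cell_ids)) {
    cell_ids <- if (ncol(values) > 0)
      sprintf("cell_%03d", seq_len(ncol(values))) else character(0)
  }
  stopifnot(length(cell_ids) == ncol(values))
  if (anyDuplicated(cell_ids)) stop("'cell_ids' must be unique")
  colnames(values) <- cell_ids
  if (!is.null(divisions)) {
    stopifnot(is.list(divisions))
    if (!all(names(divisions) %in% cell_ids))
      stop("'divisions' names must be cell ids")
  }
  if (is.null(metadata$history)) metadata$history <- character(0)
  structure(
    list(times = times, values = values, channel = channel,
         cell_ids = cell_ids, divisions = divisions, metadata = metadata),
    class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  span <- if (length(x$times)) range(x$times) else c(NA, NA)
  cat(sprintf("<trace_set> channel '%s': %d cells x %d frames (%g-%g h)\n",
              x$channel, n_cells(x), length(x$times), span[1], span[2]))
  if (length(x$metadata$history))
    cat("  processing:", paste(x$metadata$history, collapse = " -> "), "\n")
  invisible(x)
}

#' Number of cells in a trace set
#' @param x A [trace_set()].
#' @return Integer.
#' @export
n_cells <- function(x) {
  stopifnot(inherits(x, "trace_set"))
  ncol(x$values)
}

#' Subset a trace set by cell
#'
#' @param x A [trace_set()].
#' @param i Cell indices or ids.
#' @param ... Unused.
#' @return A [trace_set()] with the selected cells.
#' @export
`[.trace_set` <- function(x, i, ...) {
  ids <- if (is.character(i)) i else x$cell_ids[i]
  trace_set(x$times, x$values[, ids, drop = FALSE], x$channel,
            cell_ids = ids,
            divisions = if (!is.null(x$divisions))
              x$divisions[intersect(names(x$divisions), ids)],
            metadata = x$metadata)
}

#' Cross-cell mean trace
#'
#' @param x A [trace_set()].
#' @return Numeric vector, the per-frame mean across cells.
#' @export
mean_trace <- function(x) {
  stopifnot(inherits(x, "trace_set"))
  if (n_cells(x) == 0) stop("empty trace set")
  rowMeans(x$values)
}

# internal: frame interval (h)
frame_step <- function(x) {
  if (length(x$times) < 2) stop("trace set has fewer than 2 frames")
  (x$times[length(x$times)] - x$times[1]) / (length(x$times) - 1)
}

# internal: append a processing-history entry
add_history <- function(x, entry) {
  x$metadata$history <- c(x$metadata$history, entry)
  x
}

#' @export
as.data.frame.trace_set <- function(x, ...) {
  if (n_cells(x) == 0) {
    return(data.frame(cell_id = character(0), channel = character(0),
                      time_h = numeric(0), value_au = numeric(0),
                      division = integer(0)))
  }
  long <- data.frame(
    cell_id = rep(x$cell_ids, each = length(x$times)),
    channel = x$channel,
    time_h = rep(x$times, times = n_cells(x)),
    value_au = as.vector(x$values),
    division = 0L,
    stringsAsFactors = FALSE)
  if (!is.null(x$divisions)) {
    for (id in names(x$divisions)) {
      for (td in x$divisions[[id]]) {
        k <- which.min(abs(x$times - td))
        long$division[long$cell_id == id][k] <- 1L
      }
    }
  }
  long
}

#' @export
plot.trace_set <- function(x, main = NULL, ylab = "fluorescence (AU)", ...) {
  if (n_cells(x) == 0) stop("empty trace set")
  graphics::matplot(x$times, x$values, type = "l", lty = 1,
                    col = grDevices::grey(0.7), xlab = "time (h)", ylab = ylab,
                    main = main %||% sprintf("%s traces", x$channel), ...)
  graphics::lines(x$times, mean_trace(x), col = "red", lwd = 2)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trace set as a long-format delimited table
#'
#' One row per cell per frame with columns `cell_id`, `channel`, `time_h`,
#' `value_au`, `division` (0/1 flag at the frame nearest each division
#' event). Tab-separated, one header line, UTF-8. When `sidecar = TRUE`
#' the trace-set metadata (regimen name, seed, processing history) is written
#' to `<path>.json`.
#'
#' @param x A [trace_set()].
#' @param path Output file path.
#' @param sep Field separator (default tab; use `","` for CSV).
#' @param sidecar Write a JSON metadata sidecar next to the table?
#' @return `path`, invisibly.
#' @export
write_traces <- function(x, path, sep = "\t", sidecar = FALSE) {
  stopifnot(inherits(x, "trace_set"))
  utils::write.table(as.data.frame(x), file = path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  if (sidecar) {
    meta <- x$metadata
    meta$channel <- x$channel
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Read single-cell traces from a long-format delimited table
#'
#' Reads tables written by [write_traces()] (or equivalently structured
#' tab/comma-separated tables with columns `cell_id`, `channel`, `time_h`,
#' `value_au` and optionally `division`). All cells must share a common,
#' uniformly spaced time grid.
#'
#' @param path Input file path.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @param channel Optional channel to extract when the table holds several.
#' @return A [trace_set()], or a named list of them when the table contains
#'   multiple channels and `channel` is not given.
#' @export
read_traces <- function(path, sep = NULL, channel = NULL) {
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  long <- utils::read.table(path, sep = sep, header = TRUE,
                            stringsAsFactors = FALSE)
  required <- c("cell_id", "channel", "time_h", "value_au")
  if (!all(required %in% names(long)))
    stop("trace table must contain columns: ", paste(required, collapse = ", "))
  if (!is.null(channel)) long <- long[long$channel == channel, , drop = FALSE]
  if (nrow(long) == 0) stop("no rows to read", if (!is.null(channel))
    paste0(" for channel '", channel, "'") else "")
  chans <- unique(long$channel)
  build_one <- function(d) {
    times <- sort(unique(d$time_h))
    ids <- unique(d$cell_id)
    vals <- matrix(NA_real_, length(times), length(ids),
                   dimnames = list(NULL, ids))
    idx_t <- match(d$time_h, times)
    idx_c <- match(d$cell_id, ids)
    vals[cbind(idx_t, idx_c)] <- d$value_au
    divisions <- NULL
    if ("division" %in% names(d) && any(d$division == 1)) {
      dv <- d[d$division == 1, , drop = FALSE]
      divisions <- split(dv$time_h, dv$cell_id)
    }
    trace_set(times, vals, channel = d$channel[1], cell_ids = ids,
              divisions = divisions, metadata = list(source = path))
  }
  if (length(chans) == 1L) build_one(long)
  else {
    out <- lapply(split(long, long$channel), build_one)
    out
  }
}
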