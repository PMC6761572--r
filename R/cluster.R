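# K-means clustering of activation traces under the correlation distance,
# and frequency-filter classification of promoter response profiles.

#' Correlation distance between two traces
#'
#' `1 - Pearson correlation` of the two value series; 0 for identical (or
#' positively affine-related) traces, 2 for perfectly anti-correlated ones.
#'
#' @param a,b Numeric vectors of equal length, neither constant.
#' @return Distance in `[0, 2]`.
#' @export
correlation_distance <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b)) stop("traces must have equal length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation distance is undefined for a constant trace")
  1 - stats::cor(a, b)
}

#' K-means clustering of traces with the correlation distance
#'
#' Lloyd-style k-means on per-trace standardized series (centred, unit sd --
#' the representation under which correlation distance is a scaled Euclidean
#' distance), using `1 - cor` as the distance, restarted from several random
#' initial centroid draws; the restart with the lowest total within-cluster
#' distance (inertia) wins. Deterministic given `seed`. Ties in assignment
#' go to the lowest-index centroid; an emptied cluster is repaired by
#' re-seeding it with the point farthest from its centroid in the largest
#' cluster.
#'
#' @param x A [trace_set()] or a matrix with one row per cell.
#' @param k Number of clusters (default 4).
#' @param restarts Number of random restarts (default 5).
#' @param seed Random seed.
#' @param max_iter Iteration cap per restart.
#' @return An object of class `trace_clusters`: list with `cluster` (named
#'   integer vector in `1..k`), `k`, `centers` (k x frames matrix of
#'   standardized centroids), `inertia`, `distance = "correlation"`,
#'   `restarts`, `seed`.
#' @export
kmeans_traces <- function(x, k = 4, restarts = 5, seed = NULL,
                          max_iter = 100) {
  X <- if (inherits(x, "trace_set")) t(x$values) else as.matrix(x)
  ids <- rownames(X) %||% sprintf("cell_%03d", seq_len(nrow(X)))
  n <- nrow(X)
  if (n < k) stop("need at least k = ", k, " traces, got ", n)
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0))
    stop("constant trace(s) at row(s) ",
         paste(utils::head(which(sds == 0), 5), collapse = ", "),
         ": correlation distance undefined")
  Z <- (X - rowMeans(X)) / sds  # row-standardize

  dist_to <- function(centers) {
    # 1 - cor between every trace and every centroid
    1 - stats::cor(t(Z), t(centers))
  }
  run_once <- function() {
    centers <- Z[sample.int(n, k), , drop = FALSE]
    assign_old <- rep(0L, n)
    for (iter in seq_len(max_iter)) {
      D <- dist_to(centers)
      assign_new <- apply(D, 1, which.min)  # ties -> lowest index
      for (c_empty in setdiff(seq_len(k), unique(assign_new))) {
        big <- as.integer(names(which.max(table(assign_new))))
        members <- which(assign_new == big)
        far <- members[which.max(D[members, big])]
        centers[c_empty, ] <- Z[far, ]
        assign_new[far] <- c_empty
      }
      if (identical(assign_new, assign_old)) break
      assign_old <- assign_new
      for (c in seq_len(k)) {
        m <- Z[assign_new == c, , drop = FALSE]
        ctr <- colMeans(m)
        if (stats::sd(ctr) == 0) ctr <- m[1, ]  # degenerate mean: keep a member
        centers[c, ] <- ctr
      }
    }
    D <- dist_to(centers)
    assign_final <- apply(D, 1, which.min)
    list(cluster = assign_final, centers = centers,
         inertia = sum(D[cbind(seq_len(n), assign_final)]))
  }
  best <- local_seed(seed, {
    res <- NULL
    for (r in seq_len(restarts)) {
      cand <- run_once()
      if (is.null(res) || cand$inertia < res$inertia) res <- cand
    }
    res
  })
  cl <- stats::setNames(best$cluster, ids)
  structure(list(cluster = cl, k = k, centers = best$centers,
                 inertia = best$inertia, distance = "correlation",
                 restarts = restarts, seed = seed),
            class = "trace_clusters")
}

#' @export
print.trace_clusters <- function(x, ...) {
  cat(sprintf(
    "<trace_clusters> k = %d (%s distance, %d restarts), inertia %.4g\n",
    x$k, x$distance, x$restarts, x$inertia))
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Export cluster assignments
#'
#' @param x A [kmeans_traces()] result.
#' @param path Output path (tab-separated `cell_id`, `cluster`).
#' @return `path`, invisibly.
#' @export
write_clusters <- function(x, path) {
  stopifnot(inherits(x, "trace_clusters"))
  utils::write.table(
    data.frame(cell_id = names(x$cluster), cluster = unname(x$cluster)),
    file = path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify a frequency-response profile into a filter class
#'
#' Given one activation metric evaluated at low, natural, and high pulse
#' frequency, assigns the promoter's filter class with relative margin
#' `margin`:
#' * `band-pass`: the natural-frequency response exceeds both others by more
#'   than the margin;
#' * `low-pass`: low- and natural-frequency responses are comparable (within
#'   the margin) and both exceed the high-frequency response by more than
#'   the margin;
#' * `all-pass`: all three responses within the margin of their maximum;
#' * `unclassified` otherwise.
#'
#' Scale-invariant: multiplying the profile by a positive constant preserves
#' the class.
#'
#' @param profile Numeric vector `c(low, natural, high)` of non-negative
#'   metric values.
#' @param margin Relative tolerance (default 0.2).
#' @return One of `"band-pass"`, `"low-pass"`, `"all-pass"`,
#'   `"unclassified"`.
#' @export
#' @examples
#' classify_filter(c(1, 2, 1))  # band-pass
#' classify_filter(c(2, 2, 1))  # low-pass
#' classify_filter(c(1, 1, 1))  # all-pass
classify_filter <- function(profile, margin = 0.2) {
  stopifnot(is.numeric(profile), length(profile) == 3)
  if (any(!is.finite(profile))) stop("profile values must be finite")
  if (any(profile < 0)) stop("profile values must be non-negative")
  m_low <- profile[1]; m_nat <- profile[2]; m_high <- profile[3]
  d <- margin
  if (m_nat > (1 + d) * m_low && m_nat > (1 + d) * m_high) return("band-pass")
  if (min(m_low, m_nat) > (1 + d) * m_high &&
      abs(m_low - m_nat) <= d * max(m_low, m_nat)) return("low-pass")
  if (min(profile) >= (1 - d) * max(profile)) return("all-pass")
  "unclassified"
}

#' Frequency-response profile of a promoter metric
#'
#' Builds the `c(low, natural, high)` profile of one activation metric from
#' per-frequency [promoter_metrics()] tables (mean over responding cells),
#' ready for [classify_filter()].
#'
#' @param metrics_low,metrics_nat,metrics_high [promoter_metrics()] tables
#'   for the low-, natural-, and high-frequency regimens.
#' @param metric One of `"rate"`, `"magnitude"`, `"timing"`,
#'   `"percent_responding"`.
#' @return Named numeric vector `c(low =, natural =, high =)`.
#' @export
frequency_profile <- function(metrics_low, metrics_nat, metrics_high,
                              metric = c("rate", "magnitude", "timing",
                                         "percent_responding")) {
  metric <- match.arg(metric)
  col <- switch(metric, rate = "rate_au_per_h", magnitude = "magnitude_au",
                timing = "timing_h", percent_responding = NA)
  one <- function(m) {
    if (metric == "percent_responding") percent_responding(m)
    else mean(m[[col]][m$responder], na.rm = TRUE)
  }
  c(low = one(metrics_low), natural = one(metrics_nat),
    high = one(metrics_high))
}
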