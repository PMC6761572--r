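test_that("background subtraction removes the histogram mode and floors at 0", {
  expect_equal(subtract_background(c(5, 5, 5, 9), bins = 4), c(0, 0, 0, 4))
  expect_equal(subtract_background(rep(3.7, 10)), rep(0, 10))
  # bimodal input with a dominant low mode: agrees with a brute-force mode
  set.seed(1)
  v <- c(rnorm(300, 10, 0.5), rnorm(80, 50, 2))
  bg <- oracle_hist_mode(v, 100)
  out <- subtract_background(v, bins = 100)
  expect_equal(out, pmax(v - bg, 0), tolerance = 1e-9)
  expect_error(subtract_background(numeric(0)), "empty")
  expect_error(subtract_background(c(1, 2), bins = 1), "bins")
})

test_that("gap interpolation is linear inside, nearest at the ends, idempotent", {
  expect_equal(interpolate_gaps(c(2, NA, 4)), c(2, 3, 4))
  expect_equal(interpolate_gaps(c(0, NA, NA, 3)), c(0, 1, 2, 3))
  expect_equal(interpolate_gaps(c(NA, 5, 7, NA)), c(5, 5, 7, 7))
  v <- c(1, 2, 3)
  expect_identical(interpolate_gaps(v), v)
  gap <- c(1, NA, 5, NA, NA, 2)
  expect_equal(interpolate_gaps(interpolate_gaps(gap)),
               interpolate_gaps(gap))
  expect_error(interpolate_gaps(c(NA_real_, NA_real_)), "no measured")
  # trace-set variant records history
  tt <- frame_times(1)
  x <- trace_set(tt, matrix(c(2, NA, 4, 6), ncol = 1), "p53")
  expect_equal(as.numeric(interpolate_gaps(x)$values[2, 1]), 3)
  expect_match(interpolate_gaps(x)$metadata$history, "interpolate")
})

test_that("moving-average smoothing preserves length with edge shrinkage", {
  expect_equal(smooth_traces(c(0, 0, 1, 0, 0), window = 3),
               c(0, 1 / 3, 1 / 3, 1 / 3, 0))
  v <- rnorm(20)
  expect_identical(smooth_traces(v, window = 1), v)
  expect_equal(smooth_traces(rep(2, 10), window = 5), rep(2, 10))
  expect_error(smooth_traces(v, window = 4), "odd")
  expect_error(smooth_traces(v, window = 21), "trace length")
  # pluggable method
  expect_equal(smooth_traces(v, window = 3, method = function(x, w) x * 0),
               v * 0)
})

test_that("t0 normalization scales by the cross-cell first-frame mean", {
  tt <- frame_times(1)
  x <- trace_set(tt, cbind(c(2, 4, 6, 8), c(4, 6, 8, 10)), "p53")
  nx <- normalize_to_t0(x)
  expect_equal(unname(nx$values[1, ]), c(2 / 3, 4 / 3))
  expect_equal(mean(nx$values[1, ]), 1)
  single <- normalize_to_t0(trace_set(tt, matrix(c(5, 10, 15, 20)), "p53"))
  expect_equal(unname(single$values[, 1]), c(1, 2, 3, 4))
  zero <- trace_set(tt, matrix(c(0, 1, 2, 3)), "p53")
  expect_error(normalize_to_t0(zero), "> 0")
})

test_that("pulse counting applies the prominence rule", {
  expect_equal(count_pulses(rep(1, 50)), 0L)
  expect_gte(count_pulses(noiseless_p53("natural")$values[, 1]), 4L)
  # two clean pulses with a 10% ripple on top: ripple below 20% prominence
  tt <- seq(0, 4 * pi, length.out = 200)
  two <- pmax(sin(tt), 0) + 0.05 * sin(8 * tt)
  expect_equal(count_pulses(two, prominence_frac = 0.2), 2L)
})

test_that("QC keeps compliant traces and rejects spikes and wrong pulse counts", {
  reg <- make_regimen("natural")
  good <- noiseless_p53("natural", n_cells = 4)
  res <- qc_select(good, reg)
  expect_equal(n_cells(res$kept), 4)
  expect_equal(nrow(res$rejected), 0)

  # inject a single-frame spike ten times the amplitude into cell 2,
  # and make cell 3 flat (non-responsive)
  bad <- good
  bad$values[30, 2] <- 10 * max(good$values)
  bad$values[, 3] <- bad$values[1, 3]
  res2 <- qc_select(bad, reg)
  expect_setequal(res2$rejected$cell_id, c("cell_002", "cell_003"))
  expect_equal(res2$rejected$reason[res2$rejected$cell_id == "cell_002"],
               "spike")
  expect_match(res2$rejected$reason[res2$rejected$cell_id == "cell_003"],
               "pulse_count_0")
  expect_equal(res2$kept$cell_ids, c("cell_001", "cell_004"))
})

test_that("QC recovers the generator's compliant subset in a labelled mixture", {
  reg <- make_regimen("natural")
  compliant <- generate_p53_traces(reg, generator_config(
    n_cells = 10, amp_cv = 0.3, noise_sd = 2, seed = 7))
  res <- qc_select(compliant, reg)
  expect_gte(n_cells(res$kept), 8)  # low noise: nearly all pass
  flat <- trace_set(compliant$times,
                    matrix(50, length(compliant$times), 3), "p53",
                    cell_ids = c("flat_1", "flat_2", "flat_3"))
  mixed <- trace_set(compliant$times,
                     cbind(compliant$values, flat$values), "p53",
                     cell_ids = c(compliant$cell_ids, flat$cell_ids))
  res2 <- qc_select(mixed, reg)
  expect_true(all(flat$cell_ids %in% res2$rejected$cell_id))
  expect_setequal(res2$kept$cell_ids, res$kept$cell_ids)
})

test_that("cumulative signal matches closed forms and scales linearly", {
  tt <- frame_times(10)
  expect_equal(cumulative_signal(rep(3, length(tt)), tt), 30)
  expect_equal(cumulative_signal(tt / 10 * 8, tt), 8 * 10 / 2)
  expect_equal(cumulative_signal(rep(3, length(tt)), tt, t_end = 4.5), 13.5)
  expect_error(cumulative_signal(tt, tt, t_end = 11), "span")
  # triangular pulse area: analytic base * height / 2
  tri <- pmax(1 - abs(tt - 5) / 2, 0) * 6
  expect_equal(cumulative_signal(tri, tt), 0.5 * 4 * 6, tolerance = 1e-9)
  # pulse-train area equals the sum of per-pulse analytic areas
  reg <- make_regimen("low_frequency")
  cfg <- generator_config(n_cells = 1, amp_cv = 0, noise_sd = 0, dt = 1 / 30)
  ts <- generate_p53_traces(reg, cfg)
  lam <- log(2) / cfg$decay_halflife
  peak <- cfg$pulse_amp_mean * reg$t_on / cfg$rise_time
  area1 <- function(t_dec) {              # rise triangle + truncated decay
    peak * reg$t_on / 2 + peak / lam * (1 - exp(-lam * t_dec))
  }
  analytic <- cfg$basal * 24 +
    area1(21) + area1(10) +    # pulses at 0 and 11 h, tails run to 24 h
    peak * (2 / 3) * 2 / 2     # truncated pulse at 22 h, no decay phase
  expect_equal(cumulative_signal(ts$values[, 1], ts$times), analytic,
               tolerance = 0.01)
  # normalization scales integrals by the same divisor
  x <- trace_set(frame_times(6), cbind(2 + frame_times(6), 4 - frame_times(6) / 2),
                 "p53")
  pre <- cumulative_signal(x)
  post <- cumulative_signal(normalize_to_t0(x))
  expect_equal(post, pre / 3)
})
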