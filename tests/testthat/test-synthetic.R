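test_that("generation is deterministic given the seed and varies across seeds", {
  reg <- make_regimen("natural")
  a <- generate_p53_traces(reg, generator_config(n_cells = 5, seed = 3))
  b <- generate_p53_traces(reg, generator_config(n_cells = 5, seed = 3))
  c <- generate_p53_traces(reg, generator_config(n_cells = 5, seed = 4))
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
  expect_equal(a$metadata$seed, 3)
})

test_that("degenerate generator settings behave as specified", {
  reg <- make_regimen("natural")
  empty <- generate_p53_traces(reg, generator_config(n_cells = 0))
  expect_equal(n_cells(empty), 0)
  # no stochasticity: all cells identical, one pulse per period
  det <- generate_p53_traces(reg, generator_config(n_cells = 3, amp_cv = 0,
                                                   noise_sd = 0))
  expect_true(all(det$values[, 1] == det$values[, 2]))
  expect_equal(count_pulses(det$values[, 1]), 4L)
  expect_error(generator_config(noise_sd = -1), "negative")
  expect_error(generator_config(amp_cv = -0.1), "negative")
})

test_that("pulse amplitude modulation follows dose and on-phase duration", {
  cfg <- generator_config(n_cells = 1, amp_cv = 0, noise_sd = 0)
  pk <- function(nm) max(generate_p53_traces(make_regimen(nm), cfg)$values)
  expect_lt(pk("low_amplitude"), pk("natural"))
  expect_lt(pk("natural"), pk("high_amplitude"))
  # shortened exposure does not reach full amplitude; prolonged exposure does
  expect_lt(pk("high_frequency"), pk("natural"))
  expect_lt(pk("natural"), pk("long_duration"))
})

test_that("sample pulse-amplitude CV converges to the configured 0.70", {
  reg <- make_regimen("low_frequency")  # well-separated pulses
  cfg <- generator_config(n_cells = 500, amp_cv = 0.70, noise_sd = 0,
                          seed = 5)
  ts <- generate_p53_traces(reg, cfg)
  peaks <- unlist(lapply(pulse_starts(reg, completed_only = TRUE),
                         function(s) {
    win <- ts$times >= s & ts$times < s + reg$period
    apply(ts$values[win, , drop = FALSE], 2, max)
  })) - cfg$basal
  cv <- stats::sd(peaks) / mean(peaks)
  expect_equal(cv, 0.70, tolerance = 0.1 / 0.70)
})

test_that("reporter generation with zero noise is exactly the model output", {
  p53 <- noiseless_p53("natural", n_cells = 2)
  pars <- hill_params(135, 7.5, 407)
  rep0 <- generate_reporter_traces(p53, pars, noise_sd = 0)
  expect_identical(rep0$values,
                   simulate_reporter(p53, pars)$values)
  expect_equal(rep0$channel, "reporter")
  # k_max = 0: constant at the initial level
  flat <- generate_reporter_traces(p53, hill_params(0, 2, 100, gamma = 0),
                                   initial_mcherry = 7)
  expect_true(all(abs(flat$values - 7) < 1e-12))
  expect_error(generate_reporter_traces(rep0, pars), "channel 'p53'")
})

test_that("geminin generator honours the arrested fraction and annotates divisions", {
  allb <- generate_geminin_traces(20, frac_arrested = 1, seed = 9)
  expect_true(all(allb$metadata$truth$label == "arrested"))
  expect_null(allb$divisions)
  # arrested traces stay near basal for the whole movie
  expect_true(all(apply(allb$values, 2, max) < 20 * 1.5 + 10))

  none <- generate_geminin_traces(20, frac_arrested = 0, seed = 9)
  expect_true(all(none$metadata$truth$label != "arrested"))
  baseline <- colMeans(none$values[1:3, ])
  expect_true(all(apply(none$values, 2, max) > 1.5 * baseline))

  # divisions only ever belong to progressing (pulsatile) cells
  mix <- generate_geminin_traces(60, frac_arrested = 0.5, seed = 10)
  truth <- mix$metadata$truth
  div_ids <- names(mix$divisions)
  expect_true(all(truth$label[match(div_ids, truth$cell_id)] ==
                    "progressing_pulsatile"))
  expect_error(generate_geminin_traces(10, frac_arrested = 1.2), "0, 1")
})

test_that("feedback emulator reproduces the qualitative loop behaviour", {
  none <- regimen("untreated", dose = 0, t_on = 1, t_off = 0, total_time = 24)
  f0 <- simulate_feedback(none)
  expect_lt(diff(range(f0$p53$values)), 1e-3 * max(f0$p53$values))

  nat <- simulate_feedback(make_regimen("natural"))
  expect_gte(count_pulses(nat$p53$values[, 1]), 2L)

  expect_error(simulate_feedback(make_regimen("natural"),
                                 params = list(delta_m = -1)), "positive")
})
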