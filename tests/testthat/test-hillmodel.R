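mdm2_pars <- function(gamma = 0) hill_params(135, 7.5, 407, gamma = gamma,
                                             gamma_units = "per_h")
cdkn1a_pars <- function(gamma = 0) hill_params(40, 7, 490, gamma = gamma,
                                               gamma_units = "per_h")

test_that("the Hill term is monotone, half-maximal at K, and saturates", {
  pars <- mdm2_pars()
  expect_equal(hill_rate(407, pars), 135 / 2)
  p <- seq(0, 2000, by = 5)
  r <- hill_rate(p, pars)
  expect_true(all(diff(r) >= 0))
  expect_lte(max(r), 135)
  expect_equal(hill_rate(0, pars), 0)
  expect_equal(hill_rate(1e6, pars), 135, tolerance = 1e-6)
})

test_that("hill_params validates inputs and converts gamma units", {
  expect_equal(hill_params(1, 2, 3)$gamma, 6.7e-4 * 60)
  expect_equal(hill_params(1, 2, 3, gamma = 0.04, gamma_units = "per_h")$gamma,
               0.04)
  expect_error(hill_params(-1, 2, 3), "k_max")
  expect_error(hill_params(1, 0, 3), "'h'")
  expect_error(hill_params(1, 2, 0), "'K'")
  expect_error(hill_params(1, 2, 3, tau_d = -1), "tau_d")
})

test_that("reporter simulation matches analytic limits", {
  tt <- frame_times(15)
  # k_max = 0: constant at the initial level
  m0 <- simulate_reporter(rep(100, length(tt)),
                          hill_params(0, 2, 100, gamma = 0.1,
                                      gamma_units = "per_h"),
                          times = tt, initial_mcherry = 0)
  expect_true(all(m0 == 0))
  # constant input at K with gamma = 0: linear growth with slope k_max/2
  pars <- mdm2_pars()
  m1 <- simulate_reporter(rep(407, length(tt)), pars, times = tt)
  slope <- (m1[length(m1)] - m1[1]) / (tt[length(tt)] - tt[1])
  expect_equal(slope, 135 / 2, tolerance = 1e-3)
  # zero input with gamma > 0: exponential decay of the initial level
  pars2 <- hill_params(135, 7.5, 407, gamma = 0.25, gamma_units = "per_h")
  m2 <- simulate_reporter(rep(0, length(tt)), pars2, times = tt,
                          initial_mcherry = 80)
  expect_equal(m2, 80 * exp(-0.25 * tt), tolerance = 1e-6)
  # gamma = 0: non-decreasing
  p53 <- noiseless_p53("natural")$values[, 1]
  m3 <- simulate_reporter(p53, pars, times = frame_times(24))
  expect_true(all(diff(m3) >= -1e-12))
})

test_that("halving the integration step changes trajectories by < 0.1%", {
  p53 <- noiseless_p53("long_duration")
  pars <- mdm2_pars(gamma = 0.0402)
  a <- simulate_reporter(p53$values[, 1], pars, times = p53$times,
                         substeps = 10)
  b <- simulate_reporter(p53$values[, 1], pars, times = p53$times,
                         substeps = 20)
  expect_lt(max(abs(a - b)) / max(abs(b)), 1e-3)
})

test_that("production_rate reproduces derivatives of polynomial traces", {
  tt <- frame_times(10)
  expect_equal(production_rate(5 + 3 * tt, tt), rep(3, length(tt)))
  expect_equal(production_rate(rep(2, length(tt)), tt), rep(0, length(tt)))
  # quadratic: central differences are exact at interior points
  a <- 0.7
  d <- production_rate(a * tt^2, tt)
  interior <- 2:(length(tt) - 1)
  expect_equal(d[interior], 2 * a * tt[interior], tolerance = 1e-9)
  expect_error(production_rate(c(1, 2), c(0, 1)), "3 frames")
})

test_that("total-protein rescaling is a validated linear map", {
  v <- c(1, 2, 3)
  expect_identical(normalize_p53_total(v, 1), v)
  expect_equal(normalize_p53_total(v, 0.5), 2 * v)
  expect_equal(normalize_p53_total(3 * v, 0.5),
               3 * normalize_p53_total(v, 0.5))
  expect_error(normalize_p53_total(v, 0), "venus_fraction")
  expect_error(normalize_p53_total(v, 1.2), "venus_fraction")
})

test_that("dose-response points lie on the generating Hill curve", {
  p53 <- noiseless_p53("long_duration", dt = 1 / 12)
  pars <- mdm2_pars()
  mch <- simulate_reporter(p53, pars)
  dr <- build_dose_response(p53, mch, tau_d = 2, window = c(0, 15))
  expect_true(all(dr$points$time >= 2 & dr$points$time <= 15))
  dev <- abs(dr$points$rate - hill_rate(dr$points$p53, pars))
  expect_lt(max(dev) / 135, 0.05)          # worst case, at the decay sweep
  expect_lt(stats::median(dev) / 135, 0.005)
  # constant input: all points share one abscissa
  tt <- frame_times(20)
  drc <- build_dose_response(rep(300, length(tt)),
                             simulate_reporter(rep(300, length(tt)), pars,
                                               times = tt), times = tt)
  expect_equal(diff(range(drc$points$p53)), 0)
  # tau_d = 0 pairs same-frame values
  dr0 <- build_dose_response(p53, mch, tau_d = 0, window = c(0, 15))
  pfun <- stats::approxfun(p53$times, mean_trace(p53))
  expect_equal(dr0$points$p53, pfun(dr0$points$time))
  expect_error(build_dose_response(p53, mch, window = c(0, 30)), "span")
})

test_that("fit_hill recovers generating parameters from clean curve points", {
  for (pars in list(mdm2_pars(), cdkn1a_pars())) {
    p <- seq(50, 700, length.out = 25)
    fit <- fit_hill(data.frame(p53 = p, rate = hill_rate(p, pars)))
    expect_equal(unname(coef(fit)),
                 c(pars$k_max, pars$h, pars$K), tolerance = 1e-4)
  }
})

test_that("fit_hill rejects unidentifiable or undersized curves", {
  expect_error(fit_hill(data.frame(p53 = 1:10, rate = rep(5, 10))),
               "unidentifiable")
  expect_error(fit_hill(data.frame(p53 = 1:3, rate = 1:3)), "4")
})

test_that("hill_fit methods expose the fitted model coherently", {
  p <- seq(50, 700, length.out = 30)
  set.seed(2)
  pars <- mdm2_pars()
  fit <- fit_hill(data.frame(p53 = p,
                             rate = hill_rate(p, pars) * (1 + 0.02 * rnorm(30))))
  expect_named(coef(fit), c("k_max", "h", "K"))
  expect_equal(predict(fit, 407), unname(coef(fit)["k_max"]) / 2,
               tolerance = 0.05)
  expect_equal(length(residuals(fit)), 30)
  expect_equal(fitted(fit) + residuals(fit), fit$data$rate)
  s <- summary(fit)
  expect_s3_class(s, "summary.hill_fit")
  expect_true(all(is.finite(s$se)))
  expect_output(print(fit), "Hill promoter-activation fit")
  # simulate() produces reporter trajectories under the fitted params
  tt <- frame_times(10)
  sims <- simulate(fit, nsim = 2, seed = 1, p53 = rep(407, length(tt)),
                   times = tt, noise_sd = 1)
  expect_equal(dim(sims), c(length(tt), 2))
})

test_that("trajectory-space fitting cross-checks the rate-space fit", {
  p53 <- noiseless_p53("long_duration")
  pars <- mdm2_pars()
  mch <- simulate_reporter(p53, pars)
  traj <- fit_hill_trajectory(p53, mch, tau_d = 2, gamma = 0)
  expect_equal(unname(coef(traj)), c(135, 7.5, 407), tolerance = 0.05)
  expect_equal(traj$mode, "trajectory")
})

test_that("Hill parameter serialization round-trips", {
  pars <- hill_params(135, 7.5, 407, gamma = 0.0402, tau_d = 2,
                      gamma_units = "per_h")
  path <- tempfile(fileext = ".json")
  write_hill_params(pars, path)
  expect_equal(read_hill_params(path), pars)
  dr_path <- tempfile(fileext = ".tsv")
  write_dose_response(
    build_dose_response(rep(300, 10), seq(0, 9), times = 0:9, tau_d = 0,
                        window = c(0, 9)), dr_path)
  tab <- read.delim(dr_path)
  expect_named(tab, c("p53", "rate"))
})
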