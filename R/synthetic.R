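# Synthetic single-cell trace generators: pulsatile transcription-factor
# input, reporter output under the delayed Hill model, geminin cell-cycle
# reporter traces, and a minimal negative-feedback emulator.

# internal: evaluate code under a temporary RNG seed, restoring global state
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Configuration for the synthetic trace generators
#'
#' Collects the parameters of the phenomenological pulse-train emulator.
#' Defaults describe the study conditions the analysis assumes: about 50
#' usable cells per condition, per-pulse lognormal amplitude variability with
#' a coefficient of variation of 0.70, and 20-min sampling.
#'
#' The pulse shape is a linear rise at a fixed accumulation rate followed by
#' exponential decay after drug washout. `rise_time` (default 4 h) sets the
#' time needed to reach full amplitude, so an on-phase shorter than
#' `rise_time` yields a proportionally lower peak,
#' `A * min(t_on, rise_time) / rise_time`: protein accumulation speed is a
#' property of the cell, not of the dosing schedule, and a natural 3-h
#' exposure does not quite saturate it -- long-duration exposures therefore
#' reach higher amplitude than natural ones, matching the broad input range
#' that motivates using the long-duration condition for dose-response
#' construction.
#'
#' @param n_cells Number of cells to generate (>= 0).
#' @param basal Baseline fluorescence (AU).
#' @param pulse_amp_mean Mean pulse peak amplitude above baseline at the
#'   reference 10 uM dose (AU).
#' @param amp_cv Coefficient of variation of the per-pulse lognormal
#'   amplitude factor (dimensionless, >= 0).
#' @param rise_time Time to reach full pulse amplitude (h).
#' @param decay_halflife Post-washout exponential decay half-life (h).
#' @param noise_sd Additive Gaussian measurement noise sd (AU, >= 0).
#' @param seed Integer random seed recorded in all generated outputs.
#' @param dose_scale Amplitude scale factor per unit relative dose
#'   (dimensionless; amplitude is linear in dose relative to 10 uM).
#' @param dt Frame interval (h); default 1/3 h = 20 min.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_cells = 50, basal = 50, pulse_amp_mean = 650,
                             amp_cv = 0.70, rise_time = 4, decay_halflife = 1,
                             noise_sd = 10, seed = 1, dose_scale = 1,
                             dt = 1 / 3) {
  cfg <- list(n_cells = n_cells, basal = basal, pulse_amp_mean = pulse_amp_mean,
              amp_cv = amp_cv, rise_time = rise_time,
              decay_halflife = decay_halflife, noise_sd = noise_sd,
              seed = seed, dose_scale = dose_scale, dt = dt)
  num <- cfg[setdiff(names(cfg), "seed")]
  if (!all(vapply(num, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v), logical(1))))
    stop("generator_config parameters must be single finite numbers")
  if (n_cells < 0 || n_cells != round(n_cells)) stop("'n_cells' must be a non-negative integer")
  if (basal < 0 || pulse_amp_mean < 0 || amp_cv < 0 || noise_sd < 0 ||
      dose_scale < 0)
    stop("negative generator parameters are not allowed")
  if (rise_time <= 0 || decay_halflife <= 0 || dt <= 0)
    stop("'rise_time', 'decay_halflife' and 'dt' must be > 0")
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<generator_config> %d cells, basal %g AU, amplitude %g AU (CV %g),\n",
    "  rise %g h, decay half-life %g h, noise sd %g AU, dt %g h, seed %s\n"),
    x$n_cells, x$basal, x$pulse_amp_mean, x$amp_cv, x$rise_time,
    x$decay_halflife, x$noise_sd, x$dt, format(x$seed)))
  invisible(x)
}

# internal: deterministic pulse-train shape for one cell.
# amps: one amplitude per on-phase (AU above baseline at full rise).
pulse_train <- function(times, regimen, amps, rise_time, decay_halflife) {
  v <- numeric(length(times))
  starts <- pulse_starts(regimen)
  lambda <- log(2) / decay_halflife
  for (k in seq_along(starts)) {
    s <- starts[k]
    on_end <- min(s + regimen$t_on, regimen$total_time)
    rise_end <- min(s + rise_time, on_end)
    peak <- amps[k] * (rise_end - s) / rise_time
    rising <- times >= s & times < rise_end
    v[rising] <- v[rising] + amps[k] * (times[rising] - s) / rise_time
    holding <- times >= rise_end & times < on_end
    v[holding] <- v[holding] + peak
    decaying <- times >= on_end
    v[decaying] <- v[decaying] + peak * exp(-lambda * (times[decaying] - on_end))
  }
  v
}

#' Generate synthetic pulsatile transcription-factor traces
#'
#' Emulates single-cell p53-reporter pulse trains under a square-wave dosing
#' regimen. Each on-phase produces a pulse with peak amplitude
#' `basal + pulse_amp_mean * (dose/10) * dose_scale * L` (reached after
#' `rise_time`; truncated proportionally for shorter on-phases), where `L` is
#' drawn per pulse from a lognormal with mean 1 and CV `amp_cv`. The pulse
#' rises linearly during the on-phase and decays exponentially with half-life
#' `decay_halflife` after washout; additive Gaussian noise of sd `noise_sd`
#' is superimposed. Output is deterministic given `config$seed`.
#'
#' @param regimen A [regimen()] object.
#' @param config A [generator_config()].
#' @return A [trace_set()] with channel `"p53"`. Metadata records the
#'   regimen name, the seed, and the full config.
#' @export
#' @examples
#' ts <- generate_p53_traces(make_regimen("natural"),
#'                           generator_config(n_cells = 3, seed = 7))
#' ts
generate_p53_traces <- function(regimen, config = generator_config()) {
  stopifnot(inherits(regimen, "pulse_regimen"),
            inherits(config, "generator_config"))
  times <- seq(0, regimen$total_time, by = config$dt)
  starts <- pulse_starts(regimen)
  amp0 <- config$pulse_amp_mean * (regimen$dose / 10) * config$dose_scale
  sdlog <- sqrt(log(1 + config$amp_cv^2))
  vals <- local_seed(config$seed, {
    sapply(seq_len(config$n_cells), function(i) {
      L <- if (config$amp_cv > 0)
        stats::rlnorm(length(starts), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      else rep(1, length(starts))
      v <- config$basal +
        pulse_train(times, regimen, amp0 * L, config$rise_time,
                    config$decay_halflife)
      if (config$noise_sd > 0)
        v <- v + stats::rnorm(length(times), sd = config$noise_sd)
      v
    })
  })
  if (config$n_cells == 0) vals <- matrix(numeric(0), length(times), 0)
  trace_set(times, vals, channel = "p53",
            metadata = list(regimen = regimen$name, seed = config$seed,
                            config = unclass(config)))
}

#' Generate reporter traces from transcription-factor input
#'
#' Forward-simulates the delayed Hill promoter-activation model
#' ([simulate_reporter()]) for every cell of a transcription-factor trace
#' set and adds Gaussian measurement noise. With `noise_sd = 0` the result
#' is exactly the deterministic model output.
#'
#' @param p53_traces A [trace_set()] with channel `"p53"`.
#' @param params A [hill_params()] object.
#' @param noise_sd Additive Gaussian noise sd (AU).
#' @param seed Random seed for the noise (deterministic given seed).
#' @param initial_mcherry Initial reporter level (AU).
#' @return A [trace_set()] with channel `"reporter"`.
#' @export
generate_reporter_traces <- function(p53_traces, params, noise_sd = 0,
                                     seed = NULL, initial_mcherry = 0) {
  stopifnot(inherits(p53_traces, "trace_set"))
  if (!identical(p53_traces$channel, "p53"))
    stop("'p53_traces' must carry channel 'p53', got '",
         p53_traces$channel, "'")
  sim <- simulate_reporter(p53_traces, params,
                           initial_mcherry = initial_mcherry)
  if (noise_sd > 0) {
    sim$values <- local_seed(seed, sim$values +
      matrix(stats::rnorm(length(sim$values), sd = noise_sd),
             nrow(sim$values)))
  }
  sim$metadata$seed <- seed
  sim$metadata$noise_sd <- noise_sd
  sim
}

#' Generate synthetic geminin cell-cycle reporter traces
#'
#' Emulates 40-h geminin reporter traces for a population with a known
#' arrested fraction. Arrested cells stay at basal geminin for the whole
#' movie. Progressing cells show elevated geminin with either a sustained
#' pattern (rises and stays up, no division) or a pulsatile pattern
#' (elevated episodes terminated by divisions, at which geminin drops back
#' to basal). Division times are annotated on the traces and ground-truth
#' labels are returned in `metadata$truth`.
#'
#' @param n_cells Number of cells.
#' @param frac_arrested Fraction of arrested cells in `[0, 1]`. The arrested
#'   count is `round(frac_arrested * n_cells)`.
#' @param config A [generator_config()]; `basal` and `noise_sd` are reused
#'   on the geminin scale (defaults: basal 20 AU, noise 1 AU when left at
#'   the p53-scale defaults).
#' @param seed Random seed (overrides `config$seed` when given).
#' @param total_time Movie span (h), default 40.
#' @return A [trace_set()] with channel `"geminin"`, division annotations,
#'   and `metadata$truth` = data.frame(cell_id, label) with labels in
#'   `arrested`, `progressing_sustained`, `progressing_pulsatile`.
#' @export
generate_geminin_traces <- function(n_cells, frac_arrested,
                                    config = generator_config(
                                      basal = 20, noise_sd = 1),
                                    seed = NULL, total_time = 40) {
  if (!is.numeric(frac_arrested) || length(frac_arrested) != 1L ||
      !is.finite(frac_arrested) || frac_arrested < 0 || frac_arrested > 1)
    stop("'frac_arrested' must be a single number in [0, 1]")
  stopifnot(is.numeric(n_cells), n_cells >= 0, n_cells == round(n_cells))
  seed <- seed %||% config$seed
  times <- seq(0, total_time, by = config$dt)
  basal <- config$basal
  elevated <- basal * 5
  n_arr <- round(frac_arrested * n_cells)

  res <- local_seed(seed, {
    status <- c(rep("arrested", n_arr),
                sample(c("progressing_sustained", "progressing_pulsatile"),
                       n_cells - n_arr, replace = TRUE))
    status <- sample(status)  # shuffle cell order
    vals <- matrix(basal, length(times), n_cells)
    divisions <- list()
    ids <- sprintf("cell_%03d", seq_len(n_cells))
    ramp <- function(t0, dur = 1.5) pmin(pmax((times - t0) / dur, 0), 1)
    for (i in seq_len(max(n_cells, 0))) {
      st <- status[i]
      if (st == "progressing_sustained") {
        t0 <- stats::runif(1, 5, 12)
        vals[, i] <- basal + (elevated - basal) * ramp(t0)
      } else if (st == "progressing_pulsatile") {
        t0 <- stats::runif(1, 2, 6)
        d1 <- stats::runif(1, 10, 16)
        td1 <- t0 + d1
        ep1 <- (elevated - basal) * ramp(t0)
        ep1[times >= td1] <- 0
        v <- basal + ep1
        div <- td1
        t1 <- td1 + stats::runif(1, 3, 6)
        if (t1 < total_time - 2) {
          d2 <- stats::runif(1, 10, 16)
          td2 <- t1 + d2
          ep2 <- (elevated - basal) * ramp(t1)
          if (td2 < total_time - config$dt / 2) {
            ep2[times >= td2] <- 0
            div <- c(div, td2)
          }
          v <- v + ep2
        }
        vals[, i] <- v
        divisions[[ids[i]]] <- div
      }
    }
    if (config$noise_sd > 0)
      vals <- vals + matrix(stats::rnorm(length(vals), sd = config$noise_sd),
                            nrow(vals))
    list(vals = vals, status = status, divisions = divisions, ids = ids)
  })

  trace_set(times, res$vals, channel = "geminin", cell_ids = res$ids,
            divisions = if (length(res$divisions)) res$divisions else NULL,
            metadata = list(
              seed = seed,
              truth = data.frame(cell_id = res$ids, label = res$status,
                                 stringsAsFactors = FALSE)))
}

#' Default parameters for the negative-feedback emulator
#'
#' Rate constants of the minimal p53--MDM2 negative-feedback model used by
#' [simulate_feedback()]. Units: AU and hours; the drug input enters in uM.
#'
#' @return Named list of rate constants.
#' @export
feedback_params <- function() {
  list(beta_p = 100,   # p53 production (AU/h)
       alpha = 0.2,    # MDM2-mediated p53 degradation (1/(AU h))
       theta = 1,      # drug level halving MDM2 activity (uM)
       delta_p = 0.1,  # MDM2-independent p53 turnover (1/h)
       beta_m0 = 2,    # basal MDM2 production (AU/h)
       beta_m = 8,     # maximal p53-driven MDM2 production (AU/h)
       K_m = 250,      # p53 half-activation for MDM2 production (AU)
       h_m = 4,        # Hill coefficient of MDM2 production
       delta_m = 0.25) # MDM2 decay (1/h)
}

#' Simulate the p53--MDM2 negative-feedback loop under a dosing regimen
#'
#' A deliberately minimal, qualitative emulator of the feedback phenomenology:
#' the drug inhibits MDM2-mediated p53 degradation, p53 drives MDM2
#' production through a Hill term, and MDM2 decays first-order:
#' \deqn{dp/dt = \beta_p - \alpha M p / (1 + N(t)/\theta) - \delta_p p}
#' \deqn{dM/dt = \beta_{m0} + \beta_m p^{h}/(K_m^{h} + p^{h}) - \delta_m M}
#' Only directional behaviour is meaningful: repeated pulses under pulsatile
#' input, a low p53 fixed point without drug, and -- under a long-duration
#' input -- elevated MDM2 that suppresses the second p53 pulse (the
#' refractory period).
#'
#' @param regimen A [regimen()] object supplying the drug input `N(t)`.
#' @param params Named list of positive rate constants, see
#'   [feedback_params()].
#' @param dt Output frame interval (h), default 20 min.
#' @param init Optional named vector `c(p = , M = )` of initial levels;
#'   defaults to the drug-free fixed point found numerically.
#' @return Named list of two [trace_set()]s, `p53` and `mdm2`, on the frame
#'   grid.
#' @export
simulate_feedback <- function(regimen, params = feedback_params(),
                              dt = 1 / 3, init = NULL) {
  stopifnot(inherits(regimen, "pulse_regimen"))
  defaults <- feedback_params()
  params <- utils::modifyList(defaults, params[intersect(names(params),
                                                         names(defaults))])
  if (!all(vapply(params, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v) && v > 0, logical(1))))
    stop("all feedback rate constants must be single positive numbers")
  deriv <- function(t, y, p, drug) {
    N <- drug(t)
    hill <- y[1]^p$h_m / (p$K_m^p$h_m + y[1]^p$h_m)
    dp <- p$beta_p - p$alpha * y[2] * y[1] / (1 + N / p$theta) -
      p$delta_p * y[1]
    dM <- p$beta_m0 + p$beta_m * hill - p$delta_m * y[2]
    list(c(dp, dM))
  }
  if (is.null(init)) {
    # relax to the drug-free fixed point
    relax <- deSolve::ode(c(p = 10, M = 10), seq(0, 200, by = 1), deriv,
                          params, drug = function(t) 0, method = "rk4",
                          hini = 0.02)
    init <- c(p = unname(relax[nrow(relax), "p"]),
              M = unname(relax[nrow(relax), "M"]))
  }
  times <- seq(0, regimen$total_time, by = dt)
  drug <- function(t) {
    t <- pmin(pmax(t, 0), regimen$total_time)
    drug_input(regimen, t)
  }
  sol <- deSolve::ode(c(p = init[["p"]], M = init[["M"]]), times, deriv,
                      params, drug = drug, method = "rk4", hini = 0.01)
  meta <- list(regimen = regimen$name, params = params)
  list(p53 = trace_set(times, sol[, "p"], channel = "p53", metadata = meta),
       mdm2 = trace_set(times, sol[, "M"], channel = "mdm2", metadata = meta))
}
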