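# End-to-end pipeline: simulate -> process -> fit -> metrics -> cluster ->
# cell cycle, driven by a single config.

#' Run the analysis pipeline from a config
#'
#' Executes the requested stages in order on synthetic (or, for the
#' processing stages, previously written) trace data:
#' `simulate` (transcription-factor input + reporter), `process`
#' (smoothing, t0 normalization, pulse-count QC), `fit` (dose-response +
#' Hill fit), `metrics` (responder labels and activation metrics),
#' `cluster` (k-means of responder traces), `cellcycle` (geminin
#' simulation + arrest scoring). Each stage's failure is reported with the
#' stage name. Reruns with the same config and seed are identical.
#'
#' The config is a named list (or path to a YAML file) with elements:
#' \describe{
#'   \item{seed}{integer; seeds every stochastic stage.}
#'   \item{regimen}{canonical regimen name (see [make_regimen()]) or a list
#'     of `name`, `dose`, `t_on`, `t_off`.}
#'   \item{total_time}{experiment span (h), default 24.}
#'   \item{generator}{arguments for [generator_config()].}
#'   \item{model}{arguments for [hill_params()] (`k_max`, `h`, `K`,
#'     optional `gamma`, `tau_d`); used to simulate the reporter.}
#'   \item{reporter_noise_sd}{measurement noise on the reporter (AU).}
#'   \item{processing}{list: `smooth_window`, `prominence_frac`,
#'     `spike_frac`, `qc` (logical).}
#'   \item{fit}{list: `tau_d`, `window` (2-vector), `venus_fraction`.}
#'   \item{cluster}{list: `k`, `restarts`.}
#'   \item{cellcycle}{list: `frac_arrested`, `n_cells`,
#'     `threshold_factor`; stage skipped when absent.}
#'   \item{stages}{character vector of stages to run; default all
#'     applicable.}
#' }
#'
#' @param config Named list or path to a YAML config file.
#' @param out_dir Optional output directory; when given, trace tables,
#'   metrics, cluster assignments, fitted parameters, the population
#'   summary, and the resolved config are written there.
#' @return A list bundle with the per-stage results (`regimen`, `p53_raw`,
#'   `p53`, `reporter`, `qc`, `fit`, `metrics`, `clusters`, `geminin`,
#'   `cellcycle`, `summary`, `config`), invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(list(
    seed = 1, regimen = "natural", total_time = 24,
    generator = list(), model = list(k_max = 135, h = 7.5, K = 407),
    reporter_noise_sd = 0,
    processing = list(smooth_window = 3, prominence_frac = 0.2,
                      spike_frac = 0.5, qc = TRUE),
    fit = list(tau_d = 2, window = c(0, 15), venus_fraction = 1),
    cluster = list(k = 4, restarts = 5),
    stages = c("simulate", "process", "fit", "metrics", "cluster",
               "cellcycle")), config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  bundle <- list(config = cfg)

  bundle$regimen <- stage("regimen", {
    if (is.character(cfg$regimen))
      make_regimen(cfg$regimen, total_time = cfg$total_time)
    else do.call(regimen, utils::modifyList(cfg$regimen,
                                            list(total_time = cfg$total_time)))
  })

  if ("simulate" %in% cfg$stages) {
    bundle$p53_raw <- stage("simulate", {
      gen <- do.call(generator_config,
                     utils::modifyList(list(seed = cfg$seed), cfg$generator))
      generate_p53_traces(bundle$regimen, gen)
    })
    bundle$reporter <- stage("simulate", {
      pars <- do.call(hill_params, cfg$model)
      generate_reporter_traces(bundle$p53_raw, pars,
                               noise_sd = cfg$reporter_noise_sd,
                               seed = cfg$seed + 1L)
    })
  }

  if ("process" %in% cfg$stages && !is.null(bundle$p53_raw)) {
    smoothed <- stage("process", smooth_traces(
      bundle$p53_raw, window = cfg$processing$smooth_window))
    if (isTRUE(cfg$processing$qc)) {
      bundle$qc <- stage("process", qc_select(
        smoothed, bundle$regimen,
        prominence_frac = cfg$processing$prominence_frac,
        spike_frac = cfg$processing$spike_frac))
      bundle$p53 <- bundle$qc$kept
      bundle$reporter_kept <- bundle$reporter[bundle$p53$cell_ids]
    } else {
      bundle$p53 <- smoothed
      bundle$reporter_kept <- bundle$reporter
    }
  } else {
    bundle$p53 <- bundle$p53_raw
    bundle$reporter_kept <- bundle$reporter
  }

  if ("fit" %in% cfg$stages && !is.null(bundle$p53) &&
      n_cells(bundle$p53) > 0) {
    bundle$dose_response <- stage("fit", build_dose_response(
      bundle$p53, bundle$reporter_kept, tau_d = cfg$fit$tau_d,
      window = cfg$fit$window, venus_fraction = cfg$fit$venus_fraction))
    bundle$fit <- stage("fit", fit_hill(bundle$dose_response))
  }

  if ("metrics" %in% cfg$stages && !is.null(bundle$reporter_kept) &&
      n_cells(bundle$reporter_kept) > 0) {
    bundle$metrics <- stage("metrics", promoter_metrics(bundle$reporter_kept))
  }

  if ("cluster" %in% cfg$stages && !is.null(bundle$reporter_kept) &&
      n_cells(bundle$reporter_kept) >= cfg$cluster$k) {
    bundle$clusters <- stage("cluster", kmeans_traces(
      bundle$reporter_kept, k = cfg$cluster$k,
      restarts = cfg$cluster$restarts, seed = cfg$seed + 2L))
  }

  if ("cellcycle" %in% cfg$stages && !is.null(cfg$cellcycle)) {
    bundle$geminin <- stage("cellcycle", generate_geminin_traces(
      n_cells = cfg$cellcycle$n_cells %||% 100,
      frac_arrested = cfg$cellcycle$frac_arrested %||% 0.5,
      seed = cfg$seed + 3L))
    bundle$cellcycle <- stage("cellcycle", classify_cellcycle_set(
      bundle$geminin,
      basal_threshold_factor = cfg$cellcycle$threshold_factor %||% 1.5))
    bundle$summary <- stage("cellcycle",
                            summarize_population(bundle$cellcycle))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    stage("write", {
      yaml::write_yaml(cfg, p("config_resolved.yaml"))
      if (!is.null(bundle$p53_raw))
        write_traces(bundle$p53_raw, p("p53_traces.tsv"), sidecar = TRUE)
      if (!is.null(bundle$reporter))
        write_traces(bundle$reporter, p("reporter_traces.tsv"), sidecar = TRUE)
      if (!is.null(bundle$fit)) write_hill_params(bundle$fit,
                                                  p("hill_params.json"))
      if (!is.null(bundle$metrics)) write_metrics(bundle$metrics,
                                                  p("metrics.tsv"))
      if (!is.null(bundle$clusters)) write_clusters(bundle$clusters,
                                                    p("clusters.tsv"))
      if (!is.null(bundle$geminin))
        write_traces(bundle$geminin, p("geminin_traces.tsv"), sidecar = TRUE)
      if (!is.null(bundle$cellcycle))
        write_cellcycle_labels(bundle$cellcycle, p("cellcycle_labels.tsv"))
      if (!is.null(bundle$summary))
        jsonlite::write_json(bundle$summary, p("summary.json"),
                             auto_unbox = TRUE, digits = NA)
    })
  }
  invisible(bundle)
}
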