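# Square-wave drug dosing regimens (Nutlin-3 style pulse schedules).

.canonical_regimens <- list(
  natural        = list(dose = 10, t_on = 3,   t_off = 2.5),
  low_frequency  = list(dose = 10, t_on = 3,   t_off = 8),
  high_frequency = list(dose = 10, t_on = 2.5, t_off = 2),
  long_duration  = list(dose = 10, t_on = 8,   t_off = 3),
  low_amplitude  = list(dose = 5,  t_on = 3,   t_off = 2.5),
  high_amplitude = list(dose = 15, t_on = 3,   t_off = 2.5)
)

# accepted spellings -> canonical label
.regimen_aliases <- c(
  natural = "natural", natural_frequency = "natural", natural_dynamics = "natural",
  low_frequency = "low_frequency", low_freq = "low_frequency",
  high_frequency = "high_frequency", high_freq = "high_frequency",
  long_duration = "long_duration",
  short_duration = "low_frequency",  # the low-frequency regimen doubles as short duration
  low_amplitude = "low_amplitude",
  high_amplitude = "high_amplitude"
)

#' Construct a pulse dosing regimen
#'
#' A pulse regimen is a square-wave drug input: `dose` uM of drug for `t_on`
#' hours followed by drug-free medium for `t_off` hours, repeated until
#' `total_time`. The final cycle is truncated at `total_time` if it ends
#' mid-phase.
#'
#' @param name Label for the regimen.
#' @param dose Drug concentration during the on-phase (uM). Must be >= 0.
#' @param t_on On-phase duration (h). Must be > 0.
#' @param t_off Off-phase duration (h). Must be >= 0; `t_off = 0` gives a
#'   constant (sustained) input.
#' @param total_time Experiment span (h); 24 h for standard runs, 40 h for
#'   cell-cycle experiments.
#' @return An object of class `pulse_regimen` with fields `name`, `dose`,
#'   `t_on`, `t_off`, `total_time` and derived `period = t_on + t_off`.
#' @seealso [make_regimen()] for the six canonical regimens, [drug_input()]
#'   to evaluate the input, [write_regimen_config()] for serialization.
#' @export
#' @examples
#' r <- regimen("two_pulse", dose = 10, t_on = 8, t_off = 3, total_time = 24)
#' drug_input(r, c(1, 9, 12))
regimen <- function(name, dose, t_on, t_off, total_time = 24) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose < 0)
    stop("'dose' must be a single finite number >= 0")
  if (!is.numeric(t_on) || length(t_on) != 1L || !is.finite(t_on) || t_on <= 0)
    stop("'t_on' must be a single finite number > 0")
  if (!is.numeric(t_off) || length(t_off) != 1L || !is.finite(t_off) || t_off < 0)
    stop("'t_off' must be a single finite number >= 0")
  if (!is.numeric(total_time) || length(total_time) != 1L ||
      !is.finite(total_time) || total_time <= 0)
    stop("'total_time' must be a single finite number > 0")
  structure(
    list(name = name, dose = dose, t_on = t_on, t_off = t_off,
         total_time = total_time, period = t_on + t_off),
    class = "pulse_regimen"
  )
}

#' Canonical pulse regimens
#'
#' Builds one of the six canonical drug dosing regimens used to modulate
#' transcription-factor pulse amplitude, duration, or frequency:
#'
#' * `natural`: 10 uM, 3 h on / 2.5 h off (5.5-h period)
#' * `low_frequency`: 10 uM, 3 h on / 8 h off
#' * `high_frequency`: 10 uM, 2.5 h on / 2 h off
#' * `long_duration`: 10 uM, 8 h on / 3 h off
#' * `low_amplitude`: 5 uM with natural timing
#' * `high_amplitude`: 15 uM with natural timing
#'
#' @param name Regimen label (case-insensitive; spaces/hyphens accepted).
#' @param total_time Experiment span (h), default 24; use 40 for cell-cycle
#'   runs.
#' @return A [regimen()] object.
#' @export
#' @examples
#' make_regimen("natural")
#' make_regimen("high frequency", total_time = 40)
make_regimen <- function(name, total_time = 24) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- gsub("[ -]+", "_", tolower(trimws(name)))
  if (!key %in% names(.regimen_aliases)) {
    stop("unknown regimen '", name, "'; valid names are: ",
         paste(names(.canonical_regimens), collapse = ", "))
  }
  canon <- .regimen_aliases[[key]]
  p <- .canonical_regimens[[canon]]
  regimen(canon, dose = p$dose, t_on = p$t_on, t_off = p$t_off,
          total_time = total_time)
}

#' Evaluate the square-wave drug input of a regimen
#'
#' Returns the drug level at time `t`: `dose` when `t mod period < t_on`,
#' otherwise 0. The input is right-continuous at switch times (the value at
#' the switch instant belongs to the new phase), which makes sampling on a
#' regular frame grid unambiguous.
#'
#' @param regimen A [regimen()] object.
#' @param t Time(s) in hours; each must lie in `[0, total_time]`.
#' @return Numeric vector of drug levels (uM), one per element of `t`.
#' @export
#' @examples
#' nat <- make_regimen("natural")
#' drug_input(nat, c(0, 1, 3, 4, 5.5))
drug_input <- function(regimen, t) {
  stopifnot(inherits(regimen, "pulse_regimen"), is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0) || any(t > regimen$total_time))
    stop("'t' must lie within [0, ", regimen$total_time, "] h")
  phase <- t %% regimen$period
  # guard the periodic boundary against floating-point residue
  phase[regimen$period - phase < 1e-9] <- 0
  ifelse(phase < regimen$t_on, regimen$dose, 0)
}

#' Number of completed on-phases within a regimen's span
#'
#' Counts on-phases that both start and finish within `total_time`; this is
#' the pulse count expected of a compliant transcription-factor trace under
#' the regimen (a final truncated on-phase is not counted).
#'
#' @param regimen A [regimen()] object.
#' @return Integer count.
#' @export
expected_pulse_count <- function(regimen) {
  stopifnot(inherits(regimen, "pulse_regimen"))
  # starts at 0, period, 2*period, ...; completed if start + t_on <= total_time
  as.integer(floor((regimen$total_time - regimen$t_on) / regimen$period + 1e-9) + 1)
}

#' On-phase start times of a regimen
#'
#' @param regimen A [regimen()] object.
#' @param completed_only If `TRUE`, drop a final on-phase truncated by
#'   `total_time`.
#' @return Numeric vector of start times (h).
#' @export
pulse_starts <- function(regimen, completed_only = FALSE) {
  stopifnot(inherits(regimen, "pulse_regimen"))
  s <- seq(0, regimen$total_time - 1e-9, by = regimen$period)
  if (completed_only) s <- s[s + regimen$t_on <= regimen$total_time + 1e-9]
  s
}

#' @export
print.pulse_regimen <- function(x, ...) {
  cat(sprintf(
    "Pulse regimen '%s': %g uM, %g h on / %g h off (period %g h) over %g h\n",
    x$name, x$dose, x$t_on, x$t_off, x$period, x$total_time))
  invisible(x)
}

#' Write pulse regimens to a key/value config file
#'
#' Regimens are serialized as Debian-control-format records with fields
#' `name`, `dose_uM`, `t_on_h`, `t_off_h`, `total_time_h`, one record per
#' regimen. Numeric fields are written with full precision so that
#' [read_regimen_config()] round-trips bit-exactly.
#'
#' @param regimens A [regimen()] object or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_regimen_config <- function(regimens, path) {
  if (inherits(regimens, "pulse_regimen")) regimens <- list(regimens)
  stopifnot(all(vapply(regimens, inherits, logical(1), "pulse_regimen")))
  m <- do.call(rbind, lapply(regimens, function(r) {
    c(name = r$name,
      dose_uM = format(r$dose, digits = 17),
      t_on_h = format(r$t_on, digits = 17),
      t_off_h = format(r$t_off, digits = 17),
      total_time_h = format(r$total_time, digits = 17))
  }))
  write.dcf(m, file = path)
  invisible(path)
}

#' Read pulse regimens from a key/value config file
#'
#' @param path File written by [write_regimen_config()] (or hand-authored in
#'   the same format).
#' @return A list of [regimen()] objects, named by regimen name.
#' @export
read_regimen_config <- function(path) {
  m <- read.dcf(path)
  required <- c("name", "dose_uM", "t_on_h", "t_off_h", "total_time_h")
  if (!all(required %in% colnames(m)))
    stop("regimen config must contain fields: ", paste(required, collapse = ", "))
  out <- lapply(seq_len(nrow(m)), function(i) {
    regimen(unname(m[i, "name"]),
            dose = unname(as.numeric(m[i, "dose_uM"])),
            t_on = unname(as.numeric(m[i, "t_on_h"])),
            t_off = unname(as.numeric(m[i, "t_off_h"])),
            total_time = unname(as.numeric(m[i, "total_time_h"])))
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}
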