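#' Specification for synthetic scotopic flash-ERG recordings
#'
#' The flash response is modelled as a negative a-deflection followed by a
#' positive b-deflection, built from compactly supported raised-cosine
#' lobes whose analytic trough depth and trough-to-peak excursion equal the
#' requested amplitudes, plus i.i.d. Gaussian noise per repetition.
#'
#' @param sampling_rate_hz samples per second.
#' @param duration_ms record length.
#' @param stimulus_onset_ms flash time within the record.
#' @param a_amplitude_uv magnitude of the negative a-trough below baseline.
#' @param a_latency_ms onset-to-trough implicit time.
#' @param b_amplitude_uv trough-to-peak b-wave excursion.
#' @param b_latency_ms onset-to-peak implicit time.
#' @param n_repetitions number of repeated flashes recorded.
#' @param noise_sd_uv per-sample noise standard deviation.
#' @param intensity_log_cds_m2 flash intensity, one of 0.3, 0.6, 0.9, 1.2.
#' @param seed integer RNG seed.
#' @return object of class `erg_spec`.
#' @export
erg_spec <- function(sampling_rate_hz = 2000,
                     duration_ms = 250,
                     stimulus_onset_ms = 20,
                     a_amplitude_uv = 150,
                     a_latency_ms = 15,
                     b_amplitude_uv = 450,
                     b_latency_ms = 45,
                     n_repetitions = 16L,
                     noise_sd_uv = 20,
                     intensity_log_cds_m2 = 0.9,
                     seed = 1L) {
  spec <- structure(list(
    sampling_rate_hz = sampling_rate_hz,
    duration_ms = duration_ms,
    stimulus_onset_ms = stimulus_onset_ms,
    a_amplitude_uv = a_amplitude_uv,
    a_latency_ms = a_latency_ms,
    b_amplitude_uv = b_amplitude_uv,
    b_latency_ms = b_latency_ms,
    n_repetitions = as.integer(n_repetitions),
    noise_sd_uv = noise_sd_uv,
    intensity_log_cds_m2 = intensity_log_cds_m2,
    seed = as.integer(seed)
  ), class = "erg_spec")
  validate_erg_spec(spec)
  spec
}

validate_erg_spec <- function(spec) {
  s <- spec
  if (s$sampling_rate_hz <= 0) stop_field("sampling_rate_hz", "must be > 0")
  if (s$duration_ms <= 0) stop_field("duration_ms", "must be > 0")
  if (s$stimulus_onset_ms < 0 || s$stimulus_onset_ms >= s$duration_ms)
    stop_field("stimulus_onset_ms", "must lie inside the record")
  if (s$a_amplitude_uv < 0) stop_field("a_amplitude_uv", "must be >= 0")
  if (s$b_amplitude_uv < 0) stop_field("b_amplitude_uv", "must be >= 0")
  if (s$b_latency_ms <= s$a_latency_ms)
    stop_field("b_latency_ms", "must exceed a_latency_ms")
  if (s$stimulus_onset_ms + s$b_latency_ms >= s$duration_ms)
    stop_field("b_latency_ms", "b-peak must lie inside the record")
  if (s$n_repetitions < 1L) stop_field("n_repetitions", "must be >= 1")
  if (s$noise_sd_uv < 0) stop_field("noise_sd_uv", "must be >= 0")
  if (!s$intensity_log_cds_m2 %in% c(0.3, 0.6, 0.9, 1.2))
    stop_field("intensity_log_cds_m2",
               "must be one of 0.3, 0.6, 0.9, 1.2")
  invisible(spec)
}

# unimodal raised-cosine bump, support (c - w, c + w), peak 1 at t = c
rc_bump <- function(t, center, halfwidth) {
  u <- (t - center) / halfwidth
  ifelse(abs(u) < 1, cos(pi * u / 2)^2, 0)
}

# noiseless generating waveform relative to baseline 0; the a and b lobes
# have disjoint supports so trough depth and trough-to-peak excursion equal
# the spec amplitudes exactly
erg_waveform <- function(spec, t_ms) {
  tr <- t_ms - spec$stimulus_onset_ms
  gap <- spec$b_latency_ms - spec$a_latency_ms
  w_a <- min(0.45 * gap, 0.9 * spec$a_latency_ms)
  w_b <- min(0.45 * gap,
             0.9 * (spec$duration_ms - spec$stimulus_onset_ms -
                      spec$b_latency_ms))
  v <- numeric(length(t_ms))
  if (spec$a_amplitude_uv > 0) {
    v <- v - spec$a_amplitude_uv * rc_bump(tr, spec$a_latency_ms, w_a)
  }
  if (spec$b_amplitude_uv > 0) {
    peak <- spec$b_amplitude_uv -
      (if (spec$a_amplitude_uv > 0) spec$a_amplitude_uv else 0)
    v <- v + peak * rc_bump(tr, spec$b_latency_ms, w_b)
  }
  v
}

#' Generate repeated synthetic flash-ERG responses
#'
#' @param spec an [erg_spec()].
#' @return object of class `erg_trace`: list with `time_ms`, `voltage_uv`
#'   (samples x repetitions matrix), `stimulus_onset_ms`,
#'   `intensity_log_cds_m2`, `sampling_rate_hz` and `truth` (the spec).
#' @export
generate_erg_trace <- function(spec) {
  validate_erg_spec(spec)
  with_seed(spec$seed, {
    dt <- 1000 / spec$sampling_rate_hz
    t_ms <- seq(0, spec$duration_ms, by = dt)
    signal <- erg_waveform(spec, t_ms)
    v <- matrix(signal, length(t_ms), spec$n_repetitions)
    if (spec$noise_sd_uv > 0) {
      v <- v + matrix(rnorm(length(v), sd = spec$noise_sd_uv),
                      nrow(v), ncol(v))
    }
    colnames(v) <- sprintf("rep_%02d", seq_len(spec$n_repetitions))
    structure(list(
      time_ms = t_ms,
      voltage_uv = v,
      stimulus_onset_ms = spec$stimulus_onset_ms,
      intensity_log_cds_m2 = spec$intensity_log_cds_m2,
      sampling_rate_hz = spec$sampling_rate_hz,
      truth = spec
    ), class = "erg_trace")
  })
}

#' Specification for two-group measurement tables
#'
#' Emulates normalized protein-expression (densitometry or fluorescence
#' intensity) tables for the sarcoglycan-sarcospan subunits: a control
#' group and a second group whose per-subunit location is shifted by a
#' signed effect.
#'
#' @param n_per_group observations per group per subunit.
#' @param subunit_effects named numeric vector of signed location shifts in
#'   normalized-expression units (group 2 minus group 1).  The default
#'   plants the direction pattern seen in the knockout: alpha up; beta,
#'   gamma, delta, epsilon down; sarcospan slightly down.
#' @param baseline control-group location per subunit (recycled).
#' @param noise_sd within-group standard deviation (> 0).
#' @param distribution `"normal"` or `"lognormal"` (location shift applied
#'   on the measurement scale).
#' @param seed integer RNG seed.
#' @return object of class `group_spec`.
#' @export
group_spec <- function(n_per_group = 4L,
                       subunit_effects = c(alpha = 0.1320, beta = -0.1598,
                                           gamma = -0.7787, delta = -1.0802,
                                           epsilon = -0.0846,
                                           sspn = -0.1804),
                       baseline = 1.5,
                       noise_sd = 0.1,
                       distribution = c("normal", "lognormal"),
                       seed = 1L) {
  distribution <- match.arg(distribution)
  spec <- structure(list(
    n_per_group = as.integer(n_per_group),
    subunit_effects = subunit_effects,
    baseline = rep_len(baseline, length(subunit_effects)),
    noise_sd = noise_sd,
    distribution = distribution,
    seed = as.integer(seed)
  ), class = "group_spec")
  if (spec$n_per_group < 2L) stop_field("n_per_group", "must be >= 2")
  if (!length(subunit_effects) || is.null(names(subunit_effects)))
    stop_field("subunit_effects", "must be a named vector")
  if (spec$noise_sd <= 0) stop_field("noise_sd", "must be > 0")
  spec
}

#' Generate a two-group measurement table
#'
#' @param spec a [group_spec()].
#' @return data.frame with columns `group` (`"group1"`/`"group2"`),
#'   `subunit`, `value`; group-2 values are shifted by the per-subunit
#'   effect.
#' @export
generate_group_measurements <- function(spec) {
  stopifnot(inherits(spec, "group_spec"))
  with_seed(spec$seed, {
    n <- spec$n_per_group
    rows <- lapply(seq_along(spec$subunit_effects), function(i) {
      su <- names(spec$subunit_effects)[i]
      draw <- function(m) {
        if (spec$distribution == "normal") {
          rnorm(n, 0, spec$noise_sd) + m
        } else {
          m + spec$noise_sd *
            (exp(rnorm(n, 0, 1)) - exp(0.5)) / sqrt(exp(2) - exp(1))
        }
      }
      data.frame(
        group = rep(c("group1", "group2"), each = n),
        subunit = su,
        value = c(draw(spec$baseline[i]),
                  draw(spec$baseline[i] + spec$subunit_effects[i])),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}
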