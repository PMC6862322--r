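#' Average repeated flash responses into a single trace
#'
#' @param trace an `erg_trace` (see [generate_erg_trace()] or
#'   [read_erg_csv()]).
#' @return the same object with `voltage_uv` reduced to a one-column
#'   matrix holding the pointwise mean across repetitions.
#' @export
average_responses <- function(trace) {
  stopifnot(inherits(trace, "erg_trace"))
  v <- trace$voltage_uv
  if (!is.matrix(v) || nrow(v) != length(trace$time_ms)) {
    stop("average_responses: repetitions must share the time grid")
  }
  out <- trace
  out$voltage_uv <- matrix(rowMeans(v), ncol = 1,
                           dimnames = list(NULL, "mean"))
  out
}

#' Zero-phase bandpass filter for ERG traces
#'
#' Frequency-domain filtering with raised-cosine transition edges: exact
#' zero phase, DC removed.  The default 3-300 Hz band matches standard
#' flash-ERG amplifier settings.
#'
#' @param trace an `erg_trace`.
#' @param low_hz,high_hz passband edges.
#' @param transition_hz width of the raised-cosine transitions.
#' @return filtered `erg_trace`.
#' @export
bandpass <- function(trace, low_hz = 3, high_hz = 300, transition_hz = 2) {
  stopifnot(inherits(trace, "erg_trace"))
  fs <- trace$sampling_rate_hz
  if (fs <= 2 * high_hz) {
    stop(sprintf("bandpass: high edge %g Hz violates Nyquist at %g Hz",
                 high_hz, fs))
  }
  v <- trace$voltage_uv
  n <- nrow(v)
  freq <- (seq_len(n) - 1) / n * fs
  freq <- pmin(freq, fs - freq)   # two-sided spectrum frequencies
  ramp <- function(f, edge, width) {
    pmin(1, pmax(0, (f - edge + width) / width))
  }
  gain <- ramp(freq, low_hz, transition_hz) *
    (1 - ramp(freq, high_hz, transition_hz))
  gain[freq <= 1e-12] <- 0   # remove DC exactly
  filt <- Re(stats::mvfft(stats::mvfft(v) * gain, inverse = TRUE)) / n
  out <- trace
  out$voltage_uv <- filt
  dimnames(out$voltage_uv) <- dimnames(v)
  out
}

#' Extract a-wave and b-wave features from an averaged flash response
#'
#' Baseline is the mean pre-stimulus voltage.  The a-trough is the minimum
#' inside `(onset, onset + a_window_ms]`; a-amplitude is baseline minus
#' trough and a-latency (implicit time) runs from stimulus onset to the
#' trough.  The b-peak is the maximum after the trough up to
#' `onset + b_window_ms`; b-amplitude is measured trough-to-peak, or from
#' baseline when no a-trough is detected.  Deflections smaller than
#' `detection_floor_uv` raise the corresponding quality flag.
#'
#' @param trace an averaged `erg_trace` (single column).
#' @param a_window_ms,b_window_ms post-onset search windows.
#' @param detection_floor_uv smallest deflection accepted as a wave.
#' @return object of class `erg_features`: `a_amplitude_uv`,
#'   `a_latency_ms`, `b_amplitude_uv`, `b_latency_ms`, `baseline_uv`,
#'   `flags` (character vector, possibly empty).
#' @export
extract_ab_waves <- function(trace, a_window_ms = 50, b_window_ms = 150,
                             detection_floor_uv = 5) {
  stopifnot(inherits(trace, "erg_trace"))
  v <- trace$voltage_uv
  if (ncol(v) != 1L) {
    stop("extract_ab_waves: average the repetitions first")
  }
  v <- as.numeric(v)
  t <- trace$time_ms
  onset <- trace$stimulus_onset_ms
  pre <- t < onset
  baseline <- if (any(pre)) mean(v[pre]) else v[1]
  in_a <- t > onset & t <= onset + a_window_ms
  if (!any(in_a)) stop("extract_ab_waves: no post-onset samples")
  flags <- character(0)

  ia <- which(in_a)[which.min(v[in_a])]
  a_amp <- baseline - v[ia]
  a_lat <- t[ia] - onset
  a_present <- a_amp >= detection_floor_uv
  if (!a_present) {
    flags <- c(flags, "a_below_floor")
    a_amp <- max(0, a_amp)
  }

  in_b <- if (a_present) {
    t > t[ia] & t <= onset + b_window_ms
  } else {
    t > onset & t <= onset + b_window_ms
  }
  if (any(in_b)) {
    ib <- which(in_b)[which.max(v[in_b])]
    b_ref <- if (a_present) v[ia] else baseline
    b_amp <- v[ib] - b_ref
    b_lat <- t[ib] - onset
  } else {
    b_amp <- 0; b_lat <- NA_real_
  }
  if (!is.na(b_amp) && b_amp < detection_floor_uv) {
    flags <- c(flags, "b_below_floor")
    b_amp <- max(0, b_amp)
  }
  structure(list(
    a_amplitude_uv = a_amp,
    a_latency_ms = if (a_present) a_lat else NA_real_,
    b_amplitude_uv = b_amp,
    b_latency_ms = b_lat,
    baseline_uv = baseline,
    flags = flags
  ), class = "erg_features")
}

#' Summarise ERG features per intensity and group
#'
#' @param features data.frame with columns `group`, `eye`,
#'   `intensity_log_cds_m2` and feature columns (`a_amplitude_uv`,
#'   `a_latency_ms`, `b_amplitude_uv`, `b_latency_ms`).
#' @return data.frame with one row per group x intensity x feature holding
#'   `n`, `mean` and `sem`, ready for group comparisons.
#' @export
intensity_series <- function(features) {
  needed <- c("group", "intensity_log_cds_m2")
  if (!all(needed %in% names(features))) {
    stop("intensity_series: need columns group, intensity_log_cds_m2")
  }
  feat_cols <- intersect(
    c("a_amplitude_uv", "a_latency_ms", "b_amplitude_uv", "b_latency_ms"),
    names(features))
  if (!length(feat_cols)) stop("intensity_series: no feature columns")
  out <- list()
  for (fc in feat_cols) {
    agg <- aggregate(features[[fc]],
                     by = list(group = features$group,
                               intensity_log_cds_m2 =
                                 features$intensity_log_cds_m2),
                     FUN = function(z) c(n = length(z), mean = mean(z),
                                         sem = sd(z) / sqrt(length(z))))
    out[[fc]] <- data.frame(
      group = agg$group,
      intensity_log_cds_m2 = agg$intensity_log_cds_m2,
      feature = fc,
      n = agg$x[, "n"],
      mean = agg$x[, "mean"],
      sem = agg$x[, "sem"],
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$feature, res$group, res$intensity_log_cds_m2), ]
}
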