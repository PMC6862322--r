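#' Write an image as plain-text netpbm (ASCII PPM/PGM)
#'
#' RGB arrays are written as P3 (PPM), gray matrices as P2 (PGM).  Plain
#' netpbm is used instead of TIFF because it is a standard,
#' self-describing text format readable everywhere.  The pixel
#' calibration is recorded in a header comment.
#'
#' @param image `retina_image`, `gray_image`, RGB array or numeric matrix.
#' @param path output file path (conventionally `.ppm` / `.pgm`).
#' @param pixel_size_um calibration stored in the header when `image`
#'   carries none.
#' @return `path`, invisibly.
#' @export
write_pnm <- function(image, path, pixel_size_um = NULL) {
  if (inherits(image, "retina_image")) {
    pixel_size_um <- image$pixel_size_um
    image <- image$rgb
  } else if (inherits(image, "gray_image")) {
    pixel_size_um <- image$pixel_size_um
    image <- image$values
  }
  if (is.null(pixel_size_um)) pixel_size_um <- 1.0
  con <- file(path, "w")
  on.exit(close(con))
  if (length(dim(image)) == 3L) {
    nr <- dim(image)[1]; nc <- dim(image)[2]
    writeLines(c("P3",
                 sprintf("# pixel_size_um %g", pixel_size_um),
                 sprintf("%d %d", nc, nr), "255"), con)
    # interleave channels row-major: R G B per pixel
    px <- matrix(0L, 3L * nc, nr)
    for (k in 1:3) {
      px[seq(k, 3L * nc, by = 3L), ] <- t(round(image[, , k]))
    }
    writeLines(apply(px, 2, paste, collapse = " "), con)
  } else {
    nr <- nrow(image); nc <- ncol(image)
    writeLines(c("P2",
                 sprintf("# pixel_size_um %g", pixel_size_um),
                 sprintf("%d %d", nc, nr), "255"), con)
    writeLines(apply(round(t(image)), 2, paste, collapse = " "), con)
  }
  invisible(path)
}

#' Read a plain-text netpbm image (ASCII P2/P3)
#'
#' @param path file path.
#' @return a `gray_image` (P2) or `retina_image`-shaped list with `rgb`
#'   and `pixel_size_um` (P3); the calibration comes from the
#'   `pixel_size_um` header comment when present (else 1).
#' @export
read_pnm <- function(path) {
  lines <- readLines(path)
  magic <- trimws(lines[1])
  if (!magic %in% c("P2", "P3")) {
    stop("read_pnm: only ASCII P2/P3 netpbm supported")
  }
  psz <- 1.0
  cm <- grep("^#", lines, value = TRUE)
  hit <- regmatches(cm, regexpr("pixel_size_um\\s+[0-9.eE+-]+", cm))
  if (length(hit)) psz <- as.numeric(sub("pixel_size_um\\s+", "", hit[1]))
  body <- lines[-1]
  body <- body[!grepl("^#", body)]
  nums <- as.numeric(unlist(strsplit(paste(body, collapse = " "),
                                     "\\s+")))
  nums <- nums[is.finite(nums)]
  nc <- nums[1]; nr <- nums[2]
  vals <- nums[-(1:3)]
  if (magic == "P2") {
    gray_image(matrix(vals, nr, nc, byrow = TRUE), psz)
  } else {
    rgb <- array(0, dim = c(nr, nc, 3))
    for (k in 1:3) {
      rgb[, , k] <- matrix(vals[seq(k, length(vals), by = 3)],
                           nr, nc, byrow = TRUE)
    }
    structure(list(rgb = rgb, pixel_size_um = psz, ground_truth = NULL),
              class = "retina_image")
  }
}

#' Write ERG repetitions to CSV (`time_ms`, `rep_01`, ...)
#'
#' @param trace an `erg_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_erg_csv <- function(trace, path) {
  df <- data.frame(time_ms = trace$time_ms, trace$voltage_uv,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an ERG trace from CSV
#'
#' @param path CSV with `time_ms` plus one column per repetition.
#' @param stimulus_onset_ms,intensity_log_cds_m2 acquisition metadata not
#'   carried by the CSV.
#' @return an `erg_trace`.
#' @export
read_erg_csv <- function(path, stimulus_onset_ms,
                         intensity_log_cds_m2 = NA_real_) {
  df <- utils::read.csv(path, check.names = FALSE)
  t_ms <- df$time_ms
  v <- as.matrix(df[setdiff(names(df), "time_ms")])
  dt <- diff(t_ms)
  if (max(abs(dt - dt[1])) > 1e-6) stop("read_erg_csv: non-uniform sampling")
  structure(list(
    time_ms = t_ms, voltage_uv = v,
    stimulus_onset_ms = stimulus_onset_ms,
    intensity_log_cds_m2 = intensity_log_cds_m2,
    sampling_rate_hz = 1000 / dt[1],
    truth = NULL
  ), class = "erg_trace")
}

#' Write synthetic ground truth as JSON
#'
#' @param image a `retina_image` with attached ground truth.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(image, path) {
  gt <- image$ground_truth
  if (is.null(gt)) stop("write_ground_truth_json: no ground truth attached")
  out <- list(
    pixel_size_um = image$pixel_size_um,
    layer_names = gt$layer_names,
    layer_thicknesses_um = as.list(gt$layer_thicknesses_um),
    rupture_spans_um = gt$rupture_spans_um,
    nuclei_centers = gt$nuclei_centers,
    band_length_um = gt$band_length_um,
    landmark_t_um = gt$landmark_t_um
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the tunable physical and statistical parameters of the
#' batch/demo pipelines.  Serialize with [write_config()] /
#' [read_config()] (JSON).
#'
#' @param pixel_size_um default image calibration.
#' @param threshold discontinuity threshold (`"auto"` or a number).
#' @param min_width_um minimal rupture width counted.
#' @param calibration_nucleus_area_um2 `"auto"` or a number.
#' @param erg_a_window_ms,erg_b_window_ms a-/b-wave search windows.
#' @param pooled pooled (Student) vs Welch t.
#' @param family_m Bonferroni family size for layer-wise comparisons.
#' @param alpha significance level.
#' @param seed default RNG seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size_um = 1.0, threshold = "auto",
                            min_width_um = 5,
                            calibration_nucleus_area_um2 = "auto",
                            erg_a_window_ms = 50, erg_b_window_ms = 150,
                            pooled = TRUE, family_m = 8L, alpha = 0.05,
                            seed = 1L) {
  stopifnot(pixel_size_um > 0, min_width_um > 0,
            alpha > 0, alpha < 1)
  structure(list(
    pixel_size_um = pixel_size_um, threshold = threshold,
    min_width_um = min_width_um,
    calibration_nucleus_area_um2 = calibration_nucleus_area_um2,
    erg_a_window_ms = erg_a_window_ms, erg_b_window_ms = erg_b_window_ms,
    pooled = pooled, family_m = as.integer(family_m), alpha = alpha,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}
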