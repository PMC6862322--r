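#' Locate the arclength of a point on a fitted curve
#'
#' @param curve a [fit_retinal_curve()] result.
#' @param x_px,y_px 0-based pixel coordinates of the landmark.
#' @return arclength (um) of the nearest curve sample.
#' @export
curve_locate <- function(curve, x_px, y_px) {
  i <- which.min((curve$x_px - x_px)^2 + (curve$y_px - y_px)^2)
  curve$arclength_um[i]
}

#' Analyse one retinal cross-section end to end
#'
#' Runs luminance conversion, retina extraction, curve fitting, frailty
#' counting, thickness measurement and nuclei densitometry on a single
#' eye.  Synthetic images carry ground-truth layer labels, enabling all 8
#' per-layer thicknesses; file images fall back to luminance-class
#' segmentation (total, ONL, OPL, INL).
#'
#' @param image a `retina_image` (with or without ground truth).
#' @param landmark_px optional `(x, y)` 0-based pixel coordinates of the
#'   optic-nerve landmark; defaults to the ground-truth landmark or the
#'   curve midpoint.
#' @param config a [pipeline_config()].
#' @param use_truth_labels use ground-truth layer labels when present.
#' @return list with `thickness`, `frailty`, `densities`, `curve`.
#' @export
analyze_retina_image <- function(image, landmark_px = NULL,
                                 config = pipeline_config(),
                                 use_truth_labels = TRUE) {
  stopifnot(inherits(image, "retina_image"))
  gray <- rgb_to_luminance(image)
  fr <- frailty_index(
    image,
    threshold = if (identical(config$threshold, "auto")) NULL
                else config$threshold,
    min_width_um = config$min_width_um)
  curve <- fr$curve
  psz <- image$pixel_size_um
  gt <- image$ground_truth
  if (is.null(landmark_px)) {
    if (!is.null(gt)) {
      i <- which.min(abs(gt$midline_t_um - gt$landmark_t_um))
      landmark_px <- gt$midline_xy_um[i, ] / psz
    } else {
      landmark_px <- c(curve$x_px[length(curve$x_px) %/% 2],
                       curve$y_px[length(curve$y_px) %/% 2])
    }
  }
  landmark_t <- curve_locate(curve, landmark_px[1], landmark_px[2])
  labels <- if (use_truth_labels && !is.null(gt)) gt$labels else NULL
  thickness <- measure_thickness(curve, labels = labels, gray = gray,
                                 landmark_t_um = landmark_t)
  calib <- config$calibration_nucleus_area_um2
  densities <- tryCatch(
    nuclei_density_pipeline(
      image,
      calibration_nucleus_area_um2 = if (identical(calib, "auto")) NULL
                                     else calib),
    error = function(e) NULL)
  list(thickness = thickness, frailty = fr$frailty,
       densities = densities, curve = curve)
}

#' Batch morphometry over a manifest or an in-memory cohort
#'
#' Processes every eye, producing one results row per eye (all layer
#' thicknesses, total, rupture count, ONL/INL densities) and, when
#' exactly two groups are present, the group comparisons: Student's
#' t-tests per layer with Bonferroni correction, a t-test for total
#' thickness and densities, and the exact Wilcoxon / Hodges-Lehmann
#' contrast for the rupture count.  Row-level failures are recorded and
#' the batch continues.
#'
#' @param manifest CSV path or data.frame with columns `image_path`,
#'   `group`, `landmark_x_px`, `landmark_y_px`, `pixel_size_um`; or
#'   `NULL` when `images` is given.
#' @param images optional named list of `retina_image` objects.
#' @param groups group label per element of `images`.
#' @param config a [pipeline_config()].
#' @return list with `results` (data.frame), `comparisons` (list of
#'   `comparison_result`), `errors` (character).
#' @export
run_morphometry_batch <- function(manifest = NULL, images = NULL,
                                  groups = NULL,
                                  config = pipeline_config()) {
  if (is.null(manifest) && is.null(images)) {
    stop("run_morphometry_batch: need a manifest or images")
  }
  if (!is.null(manifest)) {
    if (is.character(manifest)) manifest <- utils::read.csv(manifest)
    needed <- c("image_path", "group", "landmark_x_px", "landmark_y_px",
                "pixel_size_um")
    if (!nrow(manifest) || !all(needed %in% names(manifest))) {
      stop("run_morphometry_batch: manifest needs columns ",
           paste(needed, collapse = ", "))
    }
    n <- nrow(manifest)
    groups <- manifest$group
  } else {
    n <- length(images)
    if (is.null(groups) || length(groups) != n) {
      stop("run_morphometry_batch: need one group label per image")
    }
  }
  layer_names <- retina_layer_names()
  rows <- vector("list", n)
  errors <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      if (!is.null(manifest)) {
        img <- read_pnm(manifest$image_path[i])
        img$pixel_size_um <- manifest$pixel_size_um[i]
        lm <- c(manifest$landmark_x_px[i], manifest$landmark_y_px[i])
        analyze_retina_image(img, landmark_px = lm, config = config)
      } else {
        analyze_retina_image(images[[i]], config = config)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("eye %d: %s", i, conditionMessage(res)))
      next
    }
    row <- as.list(res$thickness$per_layer_um)
    names(row) <- layer_names
    row$total_um <- res$thickness$total_um
    row$n_ruptures <- res$frailty$n_discontinuities
    row$onl_density <- if (!is.null(res$densities)) {
      res$densities$onl$density_per_100um2
    } else NA_real_
    row$inl_density <- if (!is.null(res$densities)) {
      res$densities$inl$density_per_100um2
    } else NA_real_
    rows[[i]] <- data.frame(eye = i, group = groups[i], row,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("run_morphometry_batch: every eye failed")
  results <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  comparisons <- NULL
  gl <- unique(results$group)
  if (length(gl) == 2L) {
    g1 <- results[results$group == gl[1], ]
    g2 <- results[results$group == gl[2], ]
    comparisons <- list()
    if (sum(!is.na(g1$total_um)) >= 2 && sum(!is.na(g2$total_um)) >= 2) {
      comparisons$total_thickness <-
        two_sample_t(g1$total_um, g2$total_um, pooled = config$pooled)
    }
    for (ln in layer_names) {
      a <- g1[[ln]]; b <- g2[[ln]]
      if (sum(!is.na(a)) >= 2 && sum(!is.na(b)) >= 2 &&
          (sd(a, na.rm = TRUE) > 0 || sd(b, na.rm = TRUE) > 0)) {
        r <- two_sample_t(a[!is.na(a)], b[!is.na(b)],
                          pooled = config$pooled)
        r$p_value <- min(1, r$p_value * config$family_m)
        r$correction <- "bonferroni"
        r$family_m <- config$family_m
        comparisons[[paste0("layer_", ln)]] <- r
      }
    }
    comparisons$ruptures <- hodges_lehmann(g1$n_ruptures, g2$n_ruptures)
    for (dn in c("onl_density", "inl_density")) {
      a <- g1[[dn]]; b <- g2[[dn]]
      if (sum(!is.na(a)) >= 2 && sum(!is.na(b)) >= 2) {
        comparisons[[dn]] <- two_sample_t(a[!is.na(a)], b[!is.na(b)],
                                          pooled = config$pooled)
      }
    }
  }
  list(results = results, comparisons = comparisons, errors = errors)
}

demo_image_spec <- function(genotype, seed, n_ruptures = 0L) {
  retina_spec(
    image_size_px = c(300L, 650L),
    pixel_size_um = 2.0,
    layer_thicknesses_um = reference_layer_profile(genotype),
    curvature = 0.03,
    n_ruptures = n_ruptures,
    rupture_width_um = 15,
    onl_density_per100um2 = if (genotype == "wt") 2.5 else 2.7,
    inl_density_per100um2 = if (genotype == "wt") 1.6 else 1.96,
    nucleus_radius_um = 2.0,
    noise_sd = 2.0,
    seed = seed
  )
}

#' Run the full synthetic demonstration study
#'
#' Generates a two-genotype synthetic cohort (wild-type-like and
#' knockout-like eyes), runs every pipeline stage - histomorphometry,
#' nuclei densitometry, scotopic ERG at four flash intensities, and
#' normalized protein-expression tables - and writes a summary report:
#' per-eye results, group comparisons for all layer, density and rupture
#' rows, per-intensity ERG feature summaries and per-subunit
#' Hodges-Lehmann contrasts.
#'
#' @param seed integer master seed; all stages derive from it.
#' @param out_dir output directory for CSV/JSON artifacts; `NULL` skips
#'   writing.
#' @param n_per_group eyes per genotype (desk-scale default 6).
#' @param config a [pipeline_config()].
#' @return list with `morphometry` (batch output), `erg_summary`,
#'   `erg_comparisons`, `protein_comparisons`, `report` (data.frame
#'   mirroring the structural-characteristics table).
#' @export
run_demo <- function(seed = 1L, out_dir = NULL, n_per_group = 6L,
                     config = pipeline_config(seed = seed)) {
  stopifnot(n_per_group >= 2L)
  sub <- with_seed(seed, sample.int(1e6, 4L))
  images <- list(); groups <- character(0)
  ko_ruptures <- with_seed(sub[1], pmin(18L, stats::rpois(n_per_group, 13)))
  for (i in seq_len(n_per_group)) {
    images[[length(images) + 1L]] <-
      generate_retina_image(demo_image_spec("wt", seed = sub[1] + i))
    groups <- c(groups, "WT")
  }
  for (i in seq_len(n_per_group)) {
    images[[length(images) + 1L]] <- generate_retina_image(
      demo_image_spec("ko", seed = sub[1] + 500L + i,
                      n_ruptures = ko_ruptures[i]))
    groups <- c(groups, "KO")
  }
  morpho <- run_morphometry_batch(images = images, groups = groups,
                                  config = config)

  # scotopic ERG: same spec for both genotypes (knock-out leaves retinal
  # function unchanged at this age)
  intensities <- c(0.3, 0.6, 0.9, 1.2)
  feats <- list()
  for (g in c("WT", "KO")) {
    for (i in seq_len(n_per_group)) {
      for (k in seq_along(intensities)) {
        amp_scale <- 0.7 + 0.1 * k   # response grows with flash intensity
        es <- erg_spec(a_amplitude_uv = 150 * amp_scale,
                       b_amplitude_uv = 450 * amp_scale,
                       intensity_log_cds_m2 = intensities[k],
                       seed = sub[2] + 1000L * (g == "KO") + 10L * i + k)
        f <- extract_ab_waves(average_responses(generate_erg_trace(es)),
                              a_window_ms = config$erg_a_window_ms,
                              b_window_ms = config$erg_b_window_ms)
        feats[[length(feats) + 1L]] <- data.frame(
          group = g, eye = i, intensity_log_cds_m2 = intensities[k],
          a_amplitude_uv = f$a_amplitude_uv,
          a_latency_ms = f$a_latency_ms,
          b_amplitude_uv = f$b_amplitude_uv,
          b_latency_ms = f$b_latency_ms, stringsAsFactors = FALSE)
      }
    }
  }
  feats <- do.call(rbind, c(feats, list(make.row.names = FALSE)))
  erg_summary <- intensity_series(feats)
  erg_comparisons <- list()
  for (k in seq_along(intensities)) {
    sel <- feats$intensity_log_cds_m2 == intensities[k]
    wt <- feats[sel & feats$group == "WT", ]
    ko <- feats[sel & feats$group == "KO", ]
    erg_comparisons[[sprintf("a_amp_%.1f", intensities[k])]] <-
      wilcoxon_exact(ko$a_amplitude_uv, wt$a_amplitude_uv)
    erg_comparisons[[sprintf("b_amp_%.1f", intensities[k])]] <-
      wilcoxon_exact(ko$b_amplitude_uv, wt$b_amplitude_uv)
  }

  # normalized protein-expression tables (KO = group2 vs WT = group1)
  tab <- generate_group_measurements(group_spec(seed = sub[3]))
  protein_comparisons <- list()
  for (su in unique(tab$subunit)) {
    a <- tab$value[tab$group == "group2" & tab$subunit == su]
    b <- tab$value[tab$group == "group1" & tab$subunit == su]
    protein_comparisons[[su]] <- hodges_lehmann(a, b)
  }

  report <- build_structure_report(morpho)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(morpho$results,
                     file.path(out_dir, "morphometry_results.csv"),
                     row.names = FALSE)
    utils::write.csv(report, file.path(out_dir, "structure_report.csv"),
                     row.names = FALSE)
    utils::write.csv(erg_summary, file.path(out_dir, "erg_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(feats, file.path(out_dir, "erg_features.csv"),
                     row.names = FALSE)
    utils::write.csv(tab, file.path(out_dir, "protein_measurements.csv"),
                     row.names = FALSE)
    write_config(config, file.path(out_dir, "config.json"))
    jsonlite::write_json(
      list(seed = seed,
           protein_median_differences = lapply(protein_comparisons,
                                               function(r) r$estimate),
           protein_p_values = lapply(protein_comparisons,
                                     function(r) r$p_value)),
      file.path(out_dir, "protein_comparisons.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(morphometry = morpho, erg_summary = erg_summary,
       erg_comparisons = erg_comparisons,
       protein_comparisons = protein_comparisons,
       erg_features = feats, report = report)
}

# one row per structural characteristic: total, the 8 layers, the two
# nuclei densities and the rupture count, with group summaries and p
build_structure_report <- function(morpho) {
  res <- morpho$results
  gl <- unique(res$group)
  cmp <- morpho$comparisons
  row_for <- function(label, col, kind, cmp_entry) {
    a <- res[res$group == gl[1], col]
    b <- res[res$group == gl[2], col]
    summ <- function(z) {
      if (kind == "median") {
        sprintf("%.1f ± %.1f", stats::median(z, na.rm = TRUE),
                stats::IQR(z, na.rm = TRUE))
      } else {
        sprintf("%.1f ± %.1f", mean(z, na.rm = TRUE),
                sd(z, na.rm = TRUE))
      }
    }
    data.frame(characteristic = label,
               group1 = summ(a), group2 = summ(b),
               p_value = if (!is.null(cmp_entry)) cmp_entry$p_value
                         else NA_real_,
               stringsAsFactors = FALSE)
  }
  rows <- list(row_for("Retinal thickness (um)", "total_um", "mean",
                       cmp$total_thickness))
  for (ln in retina_layer_names()) {
    rows[[length(rows) + 1L]] <-
      row_for(ln, ln, "mean", cmp[[paste0("layer_", ln)]])
  }
  rows[[length(rows) + 1L]] <-
    row_for("Nuclei density ONL (per 100 um2)", "onl_density", "mean",
            cmp$onl_density)
  rows[[length(rows) + 1L]] <-
    row_for("Nuclei density INL (per 100 um2)", "inl_density", "mean",
            cmp$inl_density)
  rows[[length(rows) + 1L]] <-
    row_for("Ruptures (solution of continuity)", "n_ruptures", "median",
            cmp$ruptures)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
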