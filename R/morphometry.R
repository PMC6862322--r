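#' Fit the retinal shape-and-direction curve through a band mask
#'
#' The retina in a cross-section is a long bowed band.  The curve is the
#' smoothed locus of band mid-points: mask pixels are rotated into their
#' principal-axis frame, mid-points are taken perpendicular to the major
#' axis in short bins, and a smoothing spline through them is sampled at
#' ~1 px steps.  Band fragments (e.g. at ruptures) are bridged by the
#' spline.
#'
#' @param mask a [extract_retina()] result, or a logical matrix plus
#'   `pixel_size_um`.
#' @param bin_px bin width along the principal axis for mid-point capture.
#' @param spar smoothing parameter handed to [stats::smooth.spline()];
#'   `NULL` lets generalized cross-validation choose.
#' @param rms_tol_px warn when the curve misses the mid-points by more
#'   than this root-mean-square distance.
#' @param pixel_size_um used when `mask` is a bare matrix.
#' @return object of class `retinal_curve`: `x_px`, `y_px` (0-based pixel
#'   coordinates of ~1 px spaced samples), `arclength_um` (strictly
#'   increasing), `tangent`, `normal` (unit vectors per sample) and
#'   `pixel_size_um`.
#' @export
fit_retinal_curve <- function(mask, bin_px = 2, spar = NULL,
                              rms_tol_px = 2, pixel_size_um = NULL) {
  if (inherits(mask, "retina_mask")) {
    psz <- mask$pixel_size_um
    m <- mask$mask
  } else {
    psz <- if (is.null(pixel_size_um)) 1.0 else pixel_size_um
    m <- mask
  }
  idx <- which(m)
  if (!length(idx)) stop("fit_retinal_curve: empty mask")
  nr <- nrow(m)
  # 0-based pixel-center coordinates
  x <- ((idx - 1L) %/% nr) + 0.5
  y <- ((idx - 1L) %% nr) + 0.5
  ctr <- c(mean(x), mean(y))
  cv <- stats::cov(cbind(x - ctr[1], y - ctr[2]))
  eg <- eigen(cv, symmetric = TRUE)
  if (sqrt(eg$values[1] / max(eg$values[2], 1e-12)) < 2) {
    stop("fit_retinal_curve: mask is not band-like (principal axis ratio < 2)")
  }
  e1 <- eg$vectors[, 1]; e2 <- eg$vectors[, 2]
  u <- (x - ctr[1]) * e1[1] + (y - ctr[2]) * e1[2]
  v <- (x - ctr[1]) * e2[1] + (y - ctr[2]) * e2[2]
  bin <- floor((u - min(u)) / bin_px)
  u_mid <- as.numeric(tapply(u, bin, mean))
  v_mid <- as.numeric(tapply(v, bin, mean))
  cnt <- as.numeric(tapply(u, bin, length))
  # bins that do not span the full band (rupture edges, band ends) have
  # biased mid-points; keep only well-filled bins
  full <- cnt >= 0.6 * stats::median(cnt)
  u_mid <- u_mid[full]; v_mid <- v_mid[full]; cnt <- cnt[full]
  if (length(u_mid) < 4L) stop("fit_retinal_curve: band too short")
  do_fit <- function(uu, vv, ww) {
    if (is.null(spar)) {
      stats::smooth.spline(uu, vv, w = ww, df = min(10, length(uu) - 1))
    } else {
      stats::smooth.spline(uu, vv, w = ww, spar = spar)
    }
  }
  fit <- do_fit(u_mid, v_mid, cnt)
  # robust pass: bins sliced obliquely by a rupture wedge carry strongly
  # biased mid-points; drop gross outliers and refit
  res <- predict(fit, u_mid)$y - v_mid
  keep <- abs(res) <= max(3 * stats::mad(res), 1)
  if (any(!keep) && sum(keep) >= 4L) {
    fit <- do_fit(u_mid[keep], v_mid[keep], cnt[keep])
    u_mid <- u_mid[keep]; v_mid <- v_mid[keep]
  }
  rms <- sqrt(mean((predict(fit, u_mid)$y - v_mid)^2))
  if (rms > rms_tol_px) {
    warning(sprintf("fit_retinal_curve: RMS mid-point distance %.2f px", rms))
  }
  us <- seq(min(u), max(u), by = 1)
  vs <- predict(fit, us)$y
  px <- ctr[1] + us * e1[1] + vs * e2[1]
  py <- ctr[2] + us * e1[2] + vs * e2[2]
  seg <- sqrt(diff(px)^2 + diff(py)^2)
  arc <- c(0, cumsum(seg)) * psz
  n <- length(px)
  tx <- c(px[2] - px[1], px[3:n] - px[1:(n - 2)], px[n] - px[n - 1])
  ty <- c(py[2] - py[1], py[3:n] - py[1:(n - 2)], py[n] - py[n - 1])
  tl <- sqrt(tx^2 + ty^2)
  tx <- tx / tl; ty <- ty / tl
  structure(list(
    x_px = px, y_px = py,
    arclength_um = arc,
    tangent = cbind(tx, ty),
    normal = cbind(-ty, tx),
    pixel_size_um = psz,
    rms_px = rms
  ), class = "retinal_curve")
}

#' Sample a band-averaged luminance profile along a retinal curve
#'
#' At each ~1 px arclength step the profile value is the mean luminance
#' over the segment of the curve normal spanning `+/- band_halfwidth_um`.
#' `band_halfwidth_um = 0` reduces to the nearest-pixel luminance on the
#' curve itself.  Samples leaving the image are clipped (with a warning).
#'
#' @param gray a [gray_image()].
#' @param curve a [fit_retinal_curve()] result.
#' @param band_halfwidth_um half-width of the averaged normal segment.
#' @return object of class `intensity_profile`: `position_um` (strictly
#'   increasing), `value`, `band_halfwidth_um`.
#' @export
sample_profile <- function(gray, curve, band_halfwidth_um = 0) {
  stopifnot(inherits(gray, "gray_image"), inherits(curve, "retinal_curve"))
  psz <- gray$pixel_size_um
  offs <- if (band_halfwidth_um > 0) {
    seq(-band_halfwidth_um, band_halfwidth_um, by = psz) / psz
  } else 0
  nr <- nrow(gray$values); nc <- ncol(gray$values)
  n <- length(curve$x_px)
  acc <- matrix(NA_real_, length(offs), n)
  clipped <- FALSE
  for (i in seq_along(offs)) {
    sx <- curve$x_px + offs[i] * curve$normal[, 1]
    sy <- curve$y_px + offs[i] * curve$normal[, 2]
    cc <- as.integer(round(sx + 0.5))
    rr <- as.integer(round(sy + 0.5))
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    if (!all(ok)) clipped <- TRUE
    acc[i, ok] <- gray$values[cbind(rr[ok], cc[ok])]
  }
  if (clipped) warning("sample_profile: curve band clipped at image bounds")
  structure(list(
    position_um = curve$arclength_um,
    value = colMeans(acc, na.rm = TRUE),
    band_halfwidth_um = band_halfwidth_um
  ), class = "intensity_profile")
}

#' Count luminance discontinuities (ruptures) along an intensity profile
#'
#' Positions whose band-averaged luminance exceeds the tissue level toward
#' the background by more than a threshold are flagged; flagged runs
#' closer together than `min_width_um` are merged (ties merge), runs
#' narrower than `min_width_um` are dropped, and the surviving runs are
#' the counted discontinuities (the frailty index).
#'
#' The default threshold is the midpoint between the tissue and background
#' luminance classes.  When `background` (the image background level) is
#' supplied, tissue level is the profile median and the cut is halfway to
#' `background` - the robust pipeline route.  Otherwise the two classes
#' are estimated from the profile itself by Otsu; a profile whose class
#' means differ by less than `bimodal_floor` is declared rupture-free.
#'
#' @param profile an [sample_profile()] result, or a list with
#'   `position_um` and `value`.
#' @param threshold luminance offset above tissue level that flags a
#'   position; `NULL` for the automatic midpoint rule.
#' @param min_width_um minimal rupture width retained (default 5 um, about
#'   one nucleus diameter).
#' @param background image background luminance (e.g. `mu_bg` from
#'   [luminance_classes()]).
#' @param bimodal_floor minimal tissue/background class separation for the
#'   profile-only automatic threshold.
#' @return object of class `frailty_result`: `n_discontinuities`,
#'   `spans_um` (disjoint sorted intervals), `threshold_used`.
#' @export
count_discontinuities <- function(profile, threshold = NULL,
                                  min_width_um = 5, background = NULL,
                                  bimodal_floor = 8) {
  pos <- profile$position_um
  val <- profile$value
  if (length(pos) < 3L) stop("count_discontinuities: profile too short")
  if (any(diff(pos) <= 0)) {
    stop("count_discontinuities: positions must be strictly increasing")
  }
  med <- stats::median(val)
  if (is.null(threshold)) {
    if (!is.null(background)) {
      threshold <- (background - med) / 2
    } else if (diff(range(val)) == 0) {
      threshold <- Inf
    } else {
      t0 <- otsu_threshold(val)
      mu_lo <- mean(val[val <= t0]); mu_hi <- mean(val[val > t0])
      threshold <- if (!is.finite(mu_hi) || mu_hi - mu_lo < bimodal_floor) {
        Inf   # no background-level class in the profile
      } else {
        (mu_lo + mu_hi) / 2 - med
      }
    }
  }
  flagged <- (val - med) > threshold
  runs <- flag_runs(flagged)
  spans <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start_um", "end_um")))
  if (nrow(runs)) {
    step <- stats::median(diff(pos))
    sp <- cbind(pos[runs[, 1]] - step / 2, pos[runs[, 2]] + step / 2)
    # merge runs separated by less than min_width (ties merge)
    merged <- sp[1, , drop = FALSE]
    for (i in seq_len(nrow(sp))[-1]) {
      if (sp[i, 1] - merged[nrow(merged), 2] <= min_width_um) {
        merged[nrow(merged), 2] <- sp[i, 2]
      } else {
        merged <- rbind(merged, sp[i, ])
      }
    }
    wide <- (merged[, 2] - merged[, 1]) >= min_width_um
    spans <- merged[wide, , drop = FALSE]
    colnames(spans) <- c("start_um", "end_um")
  }
  structure(list(
    n_discontinuities = nrow(spans),
    spans_um = spans,
    threshold_used = threshold
  ), class = "frailty_result")
}

#' Measure per-layer retinal thickness along curve normals
#'
#' Thickness is measured at sites placed around the optic-nerve landmark:
#' `sites_per_side` measurements centred 500 um (by default) to each side
#' of the landmark arclength, spaced `site_spacing_um` apart, emulating
#' repeated measurements per eye.  At each site the curve normal is
#' sampled at sub-pixel steps; per-layer thickness is the length of the
#' normal segment covered by that layer, averaged over sites.  Sites whose
#' normal meets no tissue (e.g. inside a rupture) are skipped and logged.
#'
#' Layer geometry comes either from a `labels` image (integer per-pixel
#' layer ids 1-8, e.g. synthetic ground truth) or, for real slides, from
#' luminance classes along the normal (`gray` route), which resolves the
#' band total plus the ONL/OPL/INL triplet only: the two dark
#' (hematoxylin-rich) runs are the nuclear layers - the wider one is the
#' ONL - and the bright gap between them is the OPL.
#'
#' @param curve a [fit_retinal_curve()] result.
#' @param labels integer matrix of per-pixel layer ids (0 = background).
#' @param gray a [gray_image()] (used when `labels` is `NULL`).
#' @param landmark_t_um arclength of the optic-nerve landmark on `curve`.
#' @param offsets_um site-group centres relative to the landmark.
#' @param sites_per_side measurements per offset.
#' @param site_spacing_um spacing between measurements of one group.
#' @param normal_halfwidth_um how far the normal is scanned to each side.
#' @param step_px sampling step along the normal, in pixels.
#' @return object of class `thickness_result`: `per_layer_um` (named, NA
#'   where unresolvable), `total_um`, `site_t_um`, `n_sites_used`,
#'   `skipped_sites`.
#' @export
measure_thickness <- function(curve, labels = NULL, gray = NULL,
                              landmark_t_um,
                              offsets_um = c(-500, 500),
                              sites_per_side = 3,
                              site_spacing_um = 25,
                              normal_halfwidth_um = 400,
                              step_px = 0.25) {
  stopifnot(inherits(curve, "retinal_curve"))
  if (is.null(labels) && is.null(gray)) {
    stop("measure_thickness: need `labels` or `gray`")
  }
  psz <- curve$pixel_size_um
  sites <- as.vector(vapply(offsets_um, function(o) {
    landmark_t_um + o +
      (seq_len(sites_per_side) - (sites_per_side + 1) / 2) * site_spacing_um
  }, numeric(sites_per_side)))
  layer_names <- retina_layer_names()
  step_um <- step_px * psz
  u <- seq(-normal_halfwidth_um, normal_halfwidth_um, by = step_um) / psz
  cls <- if (is.null(labels)) luminance_classes(gray$values) else NULL
  per_site <- matrix(NA_real_, length(layer_names), length(sites),
                     dimnames = list(layer_names, NULL))
  total_site <- rep(NA_real_, length(sites))
  skipped <- logical(length(sites))
  grid <- if (is.null(labels)) gray$values else labels
  nr <- nrow(grid); nc <- ncol(grid)
  present_layers <- if (!is.null(labels)) {
    which(tabulate(labels[labels > 0L], nbins = length(layer_names)) > 0L)
  } else integer(0)
  for (s in seq_along(sites)) {
    i <- which.min(abs(curve$arclength_um - sites[s]))
    if (abs(curve$arclength_um[i] - sites[s]) > 2 * psz) {
      skipped[s] <- TRUE
      next
    }
    sx <- curve$x_px[i] + u * curve$normal[i, 1]
    sy <- curve$y_px[i] + u * curve$normal[i, 2]
    cc <- as.integer(round(sx + 0.5))
    rr <- as.integer(round(sy + 0.5))
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    if (!is.null(labels)) {
      lay <- rep(0L, length(u))
      lay[ok] <- labels[cbind(rr[ok], cc[ok])]
      cnt <- tabulate(lay[lay > 0L], nbins = length(layer_names))
      # the normal must cross every layer present in the slide, without
      # interior background (a rupture edge would truncate layers)
      in_tissue <- which(lay > 0L)
      interior_gap <- length(in_tissue) > 0L &&
        (max(in_tissue) - min(in_tissue) + 1L - length(in_tissue)) >
          2 / step_px
      if (!any(lay > 0L) || any(cnt[present_layers] == 0L) ||
          interior_gap) {
        skipped[s] <- TRUE
        next
      }
      per_site[, s] <- cnt * step_um
      total_site[s] <- sum(cnt) * step_um
    } else {
      # tangential averaging of class indicators turns nuclei speckle
      # into contiguous nuclear bands, as seen at low magnification
      tang <- seq(-24, 24, by = psz) / psz
      tis_acc <- matrix(NA_real_, length(tang), length(u))
      drk_acc <- matrix(NA_real_, length(tang), length(u))
      for (w in seq_along(tang)) {
        wc <- as.integer(round(sx + tang[w] * curve$tangent[i, 1] + 0.5))
        wr <- as.integer(round(sy + tang[w] * curve$tangent[i, 2] + 0.5))
        wok <- wr >= 1L & wr <= nr & wc >= 1L & wc <= nc
        vals <- gray$values[cbind(wr[wok], wc[wok])]
        tis_acc[w, wok] <- as.numeric(vals <= cls$thr_bg)
        drk_acc[w, wok] <- if (is.na(cls$thr_dark)) 0 else
          as.numeric(vals <= cls$thr_dark)
      }
      res <- classify_normal_scan(colMeans(tis_acc, na.rm = TRUE),
                                  colMeans(drk_acc, na.rm = TRUE),
                                  step_um)
      if (is.null(res)) {
        skipped[s] <- TRUE
        next
      }
      per_site[, s] <- res$per_layer
      total_site[s] <- res$total
    }
  }
  used <- which(!skipped)
  if (!length(used)) {
    stop("measure_thickness: every site skipped (rupture or off-curve)")
  }
  per_layer <- rowMeans(per_site[, used, drop = FALSE], na.rm = FALSE)
  total <- if (!is.null(labels)) {
    sum(per_layer)
  } else {
    mean(total_site[used])
  }
  structure(list(
    per_layer_um = per_layer,
    total_um = total,
    site_t_um = sites,
    n_sites_used = length(used),
    skipped_sites = which(skipped)
  ), class = "thickness_result")
}

# class-fraction transitions along one normal scan: band extent from the
# tissue fraction, plus the dark-bright-dark ONL/OPL/INL triplet from the
# nuclei fraction; other layers are not luminance-separable on real
# slides and stay NA
classify_normal_scan <- function(tissue_frac, dark_frac, step_um,
                                 nuclear_floor = 0.15) {
  tissue <- !is.na(tissue_frac) & tissue_frac > 0.5
  if (!any(tissue)) return(NULL)
  band <- range(which(tissue))
  # interior background wider than ~5 um marks a rupture crossing
  if (sum(!tissue[band[1]:band[2]]) * step_um > 5) return(NULL)
  total <- (band[2] - band[1] + 1) * step_um
  per_layer <- rep(NA_real_, 8)
  names(per_layer) <- retina_layer_names()
  # light smoothing along the normal (~2 um) before thresholding
  k <- max(1L, round(2 / step_um))
  sm <- stats::filter(dark_frac, rep(1 / (2 * k + 1), 2 * k + 1),
                      sides = 2)
  sm[is.na(sm)] <- 0
  dark <- as.numeric(sm) >= nuclear_floor
  dark[-(band[1]:band[2])] <- FALSE
  runs <- flag_runs(dark)
  widths <- (runs[, 2] - runs[, 1] + 1) * step_um
  keep <- widths >= 3
  runs <- runs[keep, , drop = FALSE]
  widths <- widths[keep]
  if (nrow(runs) == 2) {
    onl <- which.max(widths)   # ONL is the thicker nuclear layer
    inl <- 3 - onl
    per_layer["ONL"] <- widths[onl]
    per_layer["INL"] <- widths[inl]
    per_layer["OPL"] <-
      (runs[max(onl, inl), 1] - runs[min(onl, inl), 2] - 1) * step_um
  }
  list(per_layer = per_layer, total = total)
}

#' Frailty index of a retinal image
#'
#' End-to-end rupture counting: luminance, retina extraction, curve fit,
#' band-averaged profile and discontinuity counting, with the
#' tissue/background midpoint threshold taken from the image-level
#' luminance classes.
#'
#' @param image a `retina_image` or rows x cols x 3 RGB array.
#' @param pixel_size_um pixel calibration when `image` is a bare array.
#' @param band_halfwidth_frac profile band half-width as a fraction of the
#'   estimated band thickness.
#' @param threshold fixed luminance threshold; `NULL` for automatic.
#' @param min_width_um minimal rupture width counted.
#' @return a list with the [count_discontinuities()] result (`frailty`),
#'   plus `curve`, `profile` and `mask`.
#' @export
frailty_index <- function(image, pixel_size_um = NULL,
                          band_halfwidth_frac = 0.35,
                          threshold = NULL, min_width_um = 5) {
  gray <- if (inherits(image, "gray_image")) image else
    rgb_to_luminance(if (is.null(pixel_size_um)) image else
      structure(list(rgb = image, pixel_size_um = pixel_size_um),
                class = "retina_image"))
  cls <- luminance_classes(gray$values)
  mask <- extract_retina(gray)
  curve <- fit_retinal_curve(mask)
  # mean band thickness from mask area over curve length
  thick_um <- sum(mask$mask) * gray$pixel_size_um^2 /
    max(curve$arclength_um)
  profile <- sample_profile(gray, curve,
                            band_halfwidth_um = band_halfwidth_frac * thick_um)
  frailty <- count_discontinuities(profile, threshold = threshold,
                                   min_width_um = min_width_um,
                                   background = cls$mu_bg)
  list(frailty = frailty, curve = curve, profile = profile, mask = mask)
}
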