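#' Binarize nuclei within a region of an H&E luminance image
#'
#' Pixels inside the region darker than the nuclear/cytoplasm Otsu cut
#' become 0 (nuclei); everything else becomes 255 (cytoplasm and
#' extracellular matrix).  A region whose luminance histogram has no
#' distinctly dark class yields an all-255 image with a warning; an
#' inverted-polarity input (dark class in the majority) is rejected.
#'
#' @param gray a [gray_image()].
#' @param region logical matrix (e.g. a [extract_retina()] mask's `mask`),
#'   or a `retina_mask`.
#' @return object of class `binary_nuclei`: `values` (matrix in {0, 255},
#'   255 outside the region), `pixel_size_um`, `region`.
#' @export
binarize_nuclei <- function(gray, region) {
  stopifnot(inherits(gray, "gray_image"))
  if (inherits(region, "retina_mask")) region <- region$mask
  stopifnot(is.logical(region), all(dim(region) == dim(gray$values)))
  if (!any(region)) stop("binarize_nuclei: empty region")
  v <- gray$values[region]
  cls <- luminance_classes(v)
  out <- matrix(255, nrow(gray$values), ncol(gray$values))
  if (is.na(cls$thr_dark)) {
    warning("binarize_nuclei: no nuclear (dark) class found; all 255")
  } else {
    dark_frac <- mean(v <= cls$thr_dark)
    if (dark_frac > 0.5) {
      stop("binarize_nuclei: dark class is the majority - inverted image?")
    }
    out[region & gray$values <= cls$thr_dark] <- 0
  }
  structure(list(values = out, pixel_size_um = gray$pixel_size_um,
                 region = region),
            class = "binary_nuclei")
}

# nuclei-pixel fraction per normal-offset bin along the curve, together
# with the linear pixel indices each bin touched
offset_profile <- function(binary, curve, halfwidth_um, bin_um = NULL) {
  psz <- binary$pixel_size_um
  if (is.null(bin_um)) bin_um <- 2 * psz   # OPL (>= 11 um) >> bin width
  offs_um <- seq(-halfwidth_um, halfwidth_um, by = psz)
  bins <- floor((offs_um + halfwidth_um) / bin_um)
  nr <- nrow(binary$values); nc <- ncol(binary$values)
  # all (offset x position) sample indices at once
  o_px <- offs_um / psz
  sx <- outer(o_px, curve$normal[, 1]) +
    matrix(curve$x_px, length(o_px), length(curve$x_px), byrow = TRUE)
  sy <- outer(o_px, curve$normal[, 2]) +
    matrix(curve$y_px, length(o_px), length(curve$y_px), byrow = TRUE)
  cc <- round(sx + 0.5)
  rr <- round(sy + 0.5)
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  ii_all <- (cc - 1) * nr + rr
  ub <- sort(unique(bins))
  frac <- rep(NA_real_, length(ub))
  centers <- rep(NA_real_, length(ub))
  idx_list <- vector("list", length(ub))
  for (bi in seq_along(ub)) {
    sel <- which(bins == ub[bi])
    ii <- unique(ii_all[sel, , drop = FALSE][ok[sel, , drop = FALSE]])
    ii <- ii[binary$region[ii]]
    idx_list[[bi]] <- ii
    centers[bi] <- mean(offs_um[sel])
    frac[bi] <- if (length(ii)) mean(binary$values[ii] == 0) else NA_real_
  }
  list(offset_um = centers, frac = frac, idx = idx_list)
}

#' Split the nuclear band into ONL and INL by segmenting the OPL
#'
#' Computes the nuclei-pixel fraction per normal-offset bin along the
#' retinal curve.  The two high-density bands are the nuclear layers; the
#' low-density valley between them is the outer plexiform layer.  The
#' nuclear band holding more nuclei (denser x wider) is labelled ONL -
#' the outer nuclear layer is the thicker, denser one - so labels follow
#' tissue content, not image orientation.
#'
#' @param binary a [binarize_nuclei()] result.
#' @param curve a [fit_retinal_curve()] result.
#' @param halfwidth_um how far to scan to each side of the curve.
#' @param peak_floor fraction of a band's peak density defining its extent.
#' @return list with `onl_idx`, `inl_idx` (linear pixel indices of the two
#'   nuclear-layer regions), `opl_offset_um` (OPL band centre offset),
#'   `profile` (offset/fraction table).
#' @export
segment_opl <- function(binary, curve, halfwidth_um = 200,
                        peak_floor = 0.35) {
  stopifnot(inherits(binary, "binary_nuclei"),
            inherits(curve, "retinal_curve"))
  prof <- offset_profile(binary, curve, halfwidth_um)
  f <- prof$frac
  f[is.na(f)] <- 0
  # light smoothing to de-speckle before peak finding
  fs <- stats::filter(f, rep(1 / 3, 3), sides = 2)
  fs[is.na(fs)] <- f[is.na(fs)]
  fs <- as.numeric(fs)
  n <- length(fs)
  is_peak <- c(FALSE, fs[2:(n - 1)] >= fs[1:(n - 2)] &
                 fs[2:(n - 1)] >= fs[3:n], FALSE) &
    fs > 0.3 * max(fs)
  peaks <- which(is_peak)
  if (length(peaks) >= 2) {
    # the two nuclear bands must be separated by a genuine low-density
    # valley (the OPL); local maxima within one band are not
    peaks <- peaks[order(fs[peaks], decreasing = TRUE)]
    p1 <- peaks[1]
    p2 <- NA_integer_
    for (cand in peaks[-1]) {
      rng <- sort(c(p1, cand))
      valley_v <- min(fs[rng[1]:rng[2]])
      if (valley_v < 0.5 * min(fs[p1], fs[cand])) {
        p2 <- cand
        break
      }
    }
    peaks <- if (is.na(p2)) p1 else sort(c(p1, p2))
  }
  if (length(peaks) < 2) {
    stop("segment_opl: fewer than two nuclear-density maxima found")
  }
  # centre of the minimal plateau between the peaks (the OPL valley is
  # flat; its middle, not its first bin, marks the plexiform midline)
  vrange <- peaks[1]:peaks[2]
  vmin <- min(fs[vrange])
  cand <- vrange[fs[vrange] <= vmin + 1e-9]
  valley <- cand[ceiling(length(cand) / 2)]
  band_of <- function(p) {
    floor_v <- peak_floor * fs[p]
    lo <- p; while (lo > 1 && fs[lo - 1] >= floor_v) lo <- lo - 1L
    hi <- p; while (hi < n && fs[hi + 1] >= floor_v) hi <- hi + 1L
    lo:hi
  }
  b1 <- band_of(peaks[1]); b2 <- band_of(peaks[2])
  b1 <- b1[b1 < valley]; b2 <- b2[b2 > valley]
  content <- function(b) sum(fs[b])
  if (content(b1) >= content(b2)) {
    onl_bins <- b1; inl_bins <- b2
  } else {
    onl_bins <- b2; inl_bins <- b1
  }
  list(
    onl_idx = unique(unlist(prof$idx[onl_bins])),
    inl_idx = unique(unlist(prof$idx[inl_bins])),
    opl_offset_um = prof$offset_um[valley],
    onl_offsets_um = range(prof$offset_um[onl_bins]),
    inl_offsets_um = range(prof$offset_um[inl_bins]),
    profile = data.frame(offset_um = prof$offset_um, nuclei_frac = prof$frac)
  )
}

#' Nuclei density of a region, per 100 square micrometers
#'
#' Counts all nuclei pixels in the region and converts the summed nuclear
#' area into a nucleus count through a calibration area per nucleus
#' (robust to clumped nuclei, which connected-component counting would
#' merge).  Density is `100 * count / region_area_um2`.
#'
#' @param binary a [binarize_nuclei()] result.
#' @param region_idx linear pixel indices of the region (e.g. `onl_idx`
#'   from [segment_opl()]), or a logical matrix.
#' @param calibration_nucleus_area_um2 area of one nucleus; `NULL`
#'   auto-calibrates as the median area of isolated (approximately round)
#'   nuclei components in the region.
#' @param method `"pixel"` (default; pixel area / calibration) or
#'   `"component"` (connected-component count).
#' @param overlap_correction with the pixel method, invert the
#'   Boolean-model coverage `p = 1 - exp(-lambda * A)` instead of the raw
#'   pixel sum: clumped nuclei share pixels, so the raw sum undercounts in
#'   dense layers (the ONL); the correction recovers the underlying
#'   intensity when nuclei positions are approximately independent.
#' @param layer optional label stored in the result.
#' @return object of class `nuclei_density_result`: `layer`,
#'   `nuclei_count`, `region_area_um2`, `density_per_100um2`,
#'   `calibration_nucleus_area_um2`.
#' @export
nuclei_density <- function(binary, region_idx,
                           calibration_nucleus_area_um2 = NULL,
                           method = c("pixel", "component"),
                           overlap_correction = FALSE,
                           layer = NA_character_) {
  method <- match.arg(method)
  stopifnot(inherits(binary, "binary_nuclei"))
  if (is.logical(region_idx)) region_idx <- which(region_idx)
  px_area <- binary$pixel_size_um^2
  area <- length(region_idx) * px_area
  if (area <= 0) stop("nuclei_density: empty region")
  nuc <- region_idx[binary$values[region_idx] == 0]
  if (!length(nuc)) {
    return(structure(list(layer = layer, nuclei_count = 0,
                          region_area_um2 = area, density_per_100um2 = 0,
                          calibration_nucleus_area_um2 =
                            calibration_nucleus_area_um2),
                     class = "nuclei_density_result"))
  }
  reg_mask <- matrix(FALSE, nrow(binary$values), ncol(binary$values))
  reg_mask[nuc] <- TRUE
  if (method == "component") {
    count <- max(label_components(reg_mask))
    calib <- calibration_nucleus_area_um2
  } else {
    calib <- calibration_nucleus_area_um2
    if (is.null(calib)) {
      calib <- auto_calibrate_nucleus_area(reg_mask, px_area)
    }
    if (overlap_correction) {
      p <- length(nuc) / length(region_idx)
      if (p >= 1) stop("nuclei_density: region saturated with nuclei")
      count <- -log(1 - p) * area / calib
    } else {
      count <- length(nuc) * px_area / calib
    }
  }
  structure(list(
    layer = layer,
    nuclei_count = count,
    region_area_um2 = area,
    density_per_100um2 = 100 * count / area,
    calibration_nucleus_area_um2 = calib
  ), class = "nuclei_density_result")
}

# single-nucleus area from isolated components: approximately square
# bounding box with high fill ratio (a lone disk); median of their areas
auto_calibrate_nucleus_area <- function(nuc_mask, px_area) {
  lab <- label_components(nuc_mask)
  k <- max(lab)
  if (k == 0) stop("nuclei_density: no components for auto-calibration")
  idx <- which(lab > 0L)
  comp <- lab[idx]
  nr <- nrow(lab)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  areas <- tabulate(comp, nbins = k)
  w <- tapply(cc, comp, function(z) diff(range(z)) + 1)
  h <- tapply(rr, comp, function(z) diff(range(z)) + 1)
  fill <- areas / (w * h)
  # a rasterized disk fills >= ~0.5 of its bounding box at small radii
  roundish <- areas >= 5 & abs(w - h) <= pmax(2, 0.3 * pmax(w, h)) &
    fill >= 0.5
  if (!any(roundish)) {
    stop("nuclei_density: no isolated round components; supply calibration")
  }
  stats::median(areas[roundish]) * px_area
}

#' Nuclei densities of the ONL and INL of a retinal image
#'
#' End-to-end density pipeline: luminance, retina extraction, curve fit,
#' nuclei binarization, OPL segmentation, then per-layer density.
#'
#' @param image a `retina_image` (or RGB array plus `pixel_size_um`).
#' @param pixel_size_um calibration when `image` is a bare array.
#' @param calibration_nucleus_area_um2 see [nuclei_density()].
#' @param halfwidth_um scan half-width around the curve.
#' @return list with `onl` and `inl` ([nuclei_density()] results) and the
#'   `segmentation`.
#' @export
nuclei_density_pipeline <- function(image, pixel_size_um = NULL,
                                    calibration_nucleus_area_um2 = NULL,
                                    halfwidth_um = 200) {
  gray <- if (inherits(image, "gray_image")) image else
    rgb_to_luminance(if (is.null(pixel_size_um)) image else
      structure(list(rgb = image, pixel_size_um = pixel_size_um),
                class = "retina_image"))
  mask <- extract_retina(gray)
  curve <- fit_retinal_curve(mask)
  binary <- binarize_nuclei(gray, mask)
  seg <- segment_opl(binary, curve, halfwidth_um = halfwidth_um)
  calib <- calibration_nucleus_area_um2
  if (is.null(calib)) {
    # calibrate single-nucleus area on the sparser nuclear band, where
    # isolated nuclei are common; the dense ONL is mostly clumps
    frac_of <- function(ii) mean(binary$values[ii] == 0)
    sparser <- if (frac_of(seg$onl_idx) <= frac_of(seg$inl_idx)) {
      seg$onl_idx
    } else {
      seg$inl_idx
    }
    m <- matrix(FALSE, nrow(binary$values), ncol(binary$values))
    m[sparser[binary$values[sparser] == 0]] <- TRUE
    calib <- auto_calibrate_nucleus_area(m, binary$pixel_size_um^2)
  }
  list(
    onl = nuclei_density(binary, seg$onl_idx, calib,
                         overlap_correction = TRUE, layer = "ONL"),
    inl = nuclei_density(binary, seg$inl_idx, calib,
                         overlap_correction = TRUE, layer = "INL"),
    segmentation = seg
  )
}
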