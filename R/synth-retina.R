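#' Reference retinal layer thickness profiles
#'
#' Per-layer mean thicknesses (um) for three-month-old wild-type and
#' Sgcd-null mouse retinas, ordered outer to inner: choroid/RPE,
#' photoreceptor outer and inner segments, outer nuclear, outer plexiform,
#' inner nuclear, inner plexiform and ganglion cell layers.  These are the
#' group means the synthetic generator plants by default.
#'
#' @param genotype `"wt"` or `"ko"`.
#' @return named numeric vector of layer thicknesses in um.
#' @export
reference_layer_profile <- function(genotype = c("wt", "ko")) {
  genotype <- match.arg(genotype)
  layers <- c("ChRPE", "PR_outer_segment", "PR_inner_segment", "ONL",
              "OPL", "INL", "IPL", "GCL")
  v <- switch(genotype,
    wt = c(42.6, 109.6, 135.8, 67.0, 19.9, 49.4, 53.6, 12.9),
    ko = c(24.7,  75.5,  83.1, 50.8, 11.2, 31.0, 32.9,  8.1)
  )
  names(v) <- layers
  v
}

retina_layer_names <- function() names(reference_layer_profile("wt"))

#' Specification for a synthetic H&E retinal cross-section
#'
#' Describes the stated world a synthetic slide is drawn from: a bowed,
#' layered retina band with background-colored ruptures crossing all
#' layers and nuclei planted in the nuclear layers at given densities.
#'
#' @param image_size_px integer `(rows, cols)`.
#' @param pixel_size_um physical pixel size, um/pixel.
#' @param layer_thicknesses_um named vector over the 8 layers, outer to
#'   inner (see [reference_layer_profile()]).
#' @param curvature dimensionless bow of the band midline: the sagitta of
#'   the circular arc as a fraction of the image width; 0 = straight.
#' @param n_ruptures number of planted full-thickness ruptures.
#' @param rupture_width_um width of each rupture band along the curve.
#' @param onl_density_per100um2,inl_density_per100um2 planted nuclei
#'   densities (nuclei per 100 um^2).
#' @param nucleus_radius_um radius of the drawn nuclear disks.
#' @param noise_sd grayscale-unit standard deviation of i.i.d. pixel noise.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return object of class `retina_spec`.
#' @export
retina_spec <- function(image_size_px = c(600L, 1200L),
                        pixel_size_um = 1.0,
                        layer_thicknesses_um = reference_layer_profile("wt"),
                        curvature = 0.03,
                        n_ruptures = 0L,
                        rupture_width_um = 20,
                        onl_density_per100um2 = 2.5,
                        inl_density_per100um2 = 1.6,
                        nucleus_radius_um = 2.0,
                        noise_sd = 2.0,
                        seed = 1L) {
  spec <- structure(list(
    image_size_px = as.integer(image_size_px),
    pixel_size_um = pixel_size_um,
    layer_thicknesses_um = layer_thicknesses_um,
    curvature = curvature,
    n_ruptures = as.integer(n_ruptures),
    rupture_width_um = rupture_width_um,
    onl_density_per100um2 = onl_density_per100um2,
    inl_density_per100um2 = inl_density_per100um2,
    nucleus_radius_um = nucleus_radius_um,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "retina_spec")
  validate_retina_spec(spec)
  spec
}

validate_retina_spec <- function(spec) {
  s <- spec
  if (length(s$image_size_px) != 2L || any(s$image_size_px < 16L))
    stop_field("image_size_px", "must be (rows, cols), each >= 16")
  if (!is.numeric(s$pixel_size_um) || s$pixel_size_um <= 0)
    stop_field("pixel_size_um", "must be > 0")
  th <- s$layer_thicknesses_um
  if (length(th) != 8L || is.null(names(th)) ||
      !identical(names(th), retina_layer_names()))
    stop_field("layer_thicknesses_um",
               paste("must be named over:",
                     paste(retina_layer_names(), collapse = ", ")))
  if (any(th < 0)) stop_field("layer_thicknesses_um", "must be >= 0")
  h_um <- s$image_size_px[1] * s$pixel_size_um
  if (sum(th) + 2 * retina_margin_um() > h_um)
    stop_field("layer_thicknesses_um",
               "layer stack plus margins exceeds image height")
  if (s$curvature < 0 || s$curvature > 0.4)
    stop_field("curvature", "must lie in [0, 0.4]")
  if (s$n_ruptures < 0) stop_field("n_ruptures", "must be >= 0")
  if (s$rupture_width_um <= 0) stop_field("rupture_width_um", "must be > 0")
  if (s$onl_density_per100um2 < 0)
    stop_field("onl_density_per100um2", "must be >= 0")
  if (s$inl_density_per100um2 < 0)
    stop_field("inl_density_per100um2", "must be >= 0")
  if (s$nucleus_radius_um <= 0) stop_field("nucleus_radius_um", "must be > 0")
  if (s$noise_sd < 0) stop_field("noise_sd", "must be >= 0")
  invisible(spec)
}

retina_margin_um <- function() 10

# H&E palette; fixed so luminance classes are stable for Otsu-style cuts
he_palette <- function() {
  list(background = c(245, 245, 245),
       eosin = c(230, 150, 170),
       nuclei = c(60, 40, 110))
}

# band geometry shared by the generator and the ground-truth accessors:
# a circular-arc midline (straight if curvature ~ 0), layers stacked as
# concentric arcs so radial (normal) thickness equals the planted values
retina_geometry <- function(spec) {
  rows <- spec$image_size_px[1]; cols <- spec$image_size_px[2]
  psz <- spec$pixel_size_um
  w_um <- cols * psz; h_um <- rows * psz
  total <- sum(spec$layer_thicknesses_um)
  y_mid <- h_um / 2
  s <- spec$curvature * w_um
  if (s < psz / 4) {
    list(curved = FALSE, w_um = w_um, h_um = h_um, total = total,
         y_mid = y_mid, length_um = w_um)
  } else {
    R <- ((w_um / 2)^2 + s^2) / (2 * s)
    if (R - total / 2 <= w_um / 2)
      stop_field("curvature", "too strong for this layer stack and width")
    x0 <- w_um / 2
    y0 <- (y_mid - s / 2) + R
    phi_max <- asin((w_um / 2) / R)
    list(curved = TRUE, w_um = w_um, h_um = h_um, total = total,
         y_mid = y_mid, R = R, x0 = x0, y0 = y0, phi_max = phi_max,
         length_um = 2 * R * phi_max)
  }
}

# map (arclength t along midline, depth d from outer boundary) -> (x, y) um
band_to_xy <- function(geom, t_um, d_um) {
  if (geom$curved) {
    phi <- (t_um - geom$length_um / 2) / geom$R
    rho <- geom$R + geom$total / 2 - d_um
    cbind(x = geom$x0 + rho * sin(phi), y = geom$y0 - rho * cos(phi))
  } else {
    cbind(x = t_um, y = geom$y_mid - geom$total / 2 + d_um)
  }
}

#' Generate a synthetic H&E retinal cross-section with ground truth
#'
#' Draws the stated world of a [retina_spec()]: an H&E-like RGB image of a
#' bowed layered retina, exactly `n_ruptures` background-colored gaps
#' crossing all layers, and nuclei planted in the ONL and INL by a seeded
#' point process at the requested densities.  Ground truth (layer label
#' grid, boundary curves, nuclei centers, rupture spans) is attached.
#'
#' @param spec a [retina_spec()].
#' @return object of class `retina_image`: list with `rgb`
#'   (rows x cols x 3 array, 0-255), `pixel_size_um` and `ground_truth`.
#' @export
generate_retina_image <- function(spec) {
  validate_retina_spec(spec)
  with_seed(spec$seed, generate_retina_image_impl(spec))
}

generate_retina_image_impl <- function(spec) {
  rows <- spec$image_size_px[1]; cols <- spec$image_size_px[2]
  psz <- spec$pixel_size_um
  th <- spec$layer_thicknesses_um
  geom <- retina_geometry(spec)
  total <- geom$total
  cum <- c(0, cumsum(th))

  xs <- (seq_len(cols) - 0.5) * psz
  ys <- (seq_len(rows) - 0.5) * psz
  if (geom$curved) {
    dx <- matrix(xs - geom$x0, rows, cols, byrow = TRUE)
    dy <- matrix(geom$y0 - ys, rows, cols)
    rho <- sqrt(dx^2 + dy^2)
    depth <- (geom$R + total / 2) - rho
    tcoord <- atan2(dx, dy) * geom$R + geom$length_um / 2
  } else {
    depth <- matrix(ys - (geom$y_mid - total / 2), rows, cols)
    tcoord <- matrix(xs, rows, cols, byrow = TRUE)
  }
  lab <- findInterval(depth, cum, left.open = TRUE)
  lab[lab > length(th)] <- 0L
  dim(lab) <- c(rows, cols)

  # ruptures: radial wedges of background, spans disjoint along the curve
  spans <- plant_rupture_spans(spec, geom)
  in_rupture <- matrix(FALSE, rows, cols)
  if (nrow(spans)) {
    for (i in seq_len(nrow(spans))) {
      in_rupture <- in_rupture |
        (tcoord >= spans[i, 1] & tcoord <= spans[i, 2])
    }
    lab[in_rupture & lab > 0L] <- 0L
  }

  nuclei <- plant_nuclei(spec, geom, cum, spans)

  pal <- he_palette()
  chan <- lapply(1:3, function(k) {
    m <- matrix(pal$background[k], rows, cols)
    m[lab > 0L] <- pal$eosin[k]
    m
  })
  # nuclei as filled disks
  if (nrow(nuclei)) {
    r_px <- max(1L, as.integer(round(spec$nucleus_radius_um / psz)))
    off <- disk_offsets(r_px)
    pr <- as.integer(round(nuclei$y_um / psz + 0.5))
    pc <- as.integer(round(nuclei$x_um / psz + 0.5))
    for (i in seq_len(nrow(off))) {
      rr <- pr + off$dy[i]; cc <- pc + off$dx[i]
      ok <- rr >= 1L & rr <= rows & cc >= 1L & cc <= cols
      ii <- (cc[ok] - 1L) * rows + rr[ok]
      ii <- ii[lab[ii] > 0L]
      for (k in 1:3) chan[[k]][ii] <- pal$nuclei[k]
    }
  }
  if (spec$noise_sd > 0) {
    for (k in 1:3) {
      chan[[k]] <- pmax(0, pmin(255,
        chan[[k]] + rnorm(rows * cols, sd = spec$noise_sd)))
    }
  }
  rgb <- array(0, dim = c(rows, cols, 3))
  for (k in 1:3) rgb[, , k] <- round(chan[[k]])

  # per-interface boundary height (um) at every column
  boundaries <- matrix(NA_real_, length(cum), cols)
  if (geom$curved) {
    for (k in seq_along(cum)) {
      Rk <- geom$R + total / 2 - cum[k]
      boundaries[k, ] <- geom$y0 - sqrt(pmax(0, Rk^2 - (xs - geom$x0)^2))
    }
  } else {
    for (k in seq_along(cum)) {
      boundaries[k, ] <- geom$y_mid - total / 2 + cum[k]
    }
  }

  mid_t <- seq(psz / 2, geom$length_um, by = psz)
  mid_xy <- band_to_xy(geom, mid_t, total / 2)

  structure(list(
    rgb = rgb,
    pixel_size_um = psz,
    ground_truth = list(
      labels = lab,
      layer_names = retina_layer_names(),
      layer_thicknesses_um = th,
      boundaries_um = boundaries,
      nuclei_centers = nuclei,
      rupture_spans_um = spans,
      midline_t_um = mid_t,
      midline_xy_um = mid_xy,
      band_length_um = geom$length_um,
      landmark_t_um = geom$length_um / 2,
      curvature = spec$curvature,
      spec = spec
    )
  ), class = "retina_image")
}

# disjoint rupture spans with center separation >= 4 widths (gap >= 3 widths)
plant_rupture_spans <- function(spec, geom) {
  n <- spec$n_ruptures
  w <- spec$rupture_width_um
  empty <- matrix(numeric(0), ncol = 2L,
                  dimnames = list(NULL, c("start_um", "end_um")))
  if (n == 0L) return(empty)
  edge <- 2 * w + 30
  minsep <- 4 * w
  usable <- geom$length_um - 2 * edge
  free <- usable - (n - 1) * minsep
  if (free <= 0)
    stop_field("n_ruptures",
               "cannot fit this many ruptures with 3-width separation")
  u <- sort(runif(n)) * free
  centers <- edge + u + (seq_len(n) - 1) * minsep
  cbind(start_um = centers - w / 2, end_um = centers + w / 2)
}

# seeded point process in the nuclear layers; Poisson counts at the
# requested density, uniform in (arclength, depth), resampled while a new
# disk overlaps an accepted one by more than ~60% of its area
plant_nuclei <- function(spec, geom, cum, spans) {
  r <- spec$nucleus_radius_um
  dens <- c(ONL = spec$onl_density_per100um2,
            INL = spec$inl_density_per100um2)
  lay_idx <- c(ONL = 4L, INL = 6L)
  out <- list()
  for (lay in names(dens)) {
    if (dens[[lay]] <= 0) next
    k <- lay_idx[[lay]]
    th_k <- cum[k + 1L] - cum[k]
    if (th_k <= 0) next
    # exact annular-sector area of the layer band
    if (geom$curved) {
      Rmid <- geom$R + geom$total / 2 - (cum[k] + cum[k + 1L]) / 2
      area <- th_k * 2 * geom$phi_max * Rmid
    } else {
      area <- th_k * geom$length_um
    }
    if (nrow(spans)) {
      area <- area - sum(spans[, 2] - spans[, 1]) * th_k
    }
    n <- rpois(1L, dens[[lay]] * area / 100)
    if (n == 0L) next
    d_lo <- cum[k] + min(r, th_k / 2)
    d_hi <- cum[k + 1L] - min(r, th_k / 2)
    acc_t <- numeric(0); acc_d <- numeric(0)
    min_d2 <- (0.64 * r)^2   # < this center distance ~ > 60% area overlap
    for (i in seq_len(n)) {
      for (try in 1:20) {
        t_i <- runif(1L, r, geom$length_um - r)
        if (nrow(spans) &&
            any(t_i > spans[, 1] - r & t_i < spans[, 2] + r)) next
        d_i <- if (d_hi > d_lo) runif(1L, d_lo, d_hi) else (d_lo + d_hi) / 2
        if (length(acc_t) &&
            any((acc_t - t_i)^2 + (acc_d - d_i)^2 < min_d2)) next
        break
      }
      acc_t <- c(acc_t, t_i); acc_d <- c(acc_d, d_i)
    }
    xy <- band_to_xy(geom, acc_t, acc_d)
    out[[lay]] <- data.frame(x_um = xy[, "x"], y_um = xy[, "y"],
                             t_um = acc_t, depth_um = acc_d,
                             layer = lay, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      t_um = numeric(0), depth_um = numeric(0),
                      layer = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
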