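#' Luminance (HSV value channel) of an RGB image
#'
#' Converts an 8-bit RGB image to the value channel of the HSV model,
#' i.e. the per-pixel maximum over the three channels, used throughout as
#' the luminance surrogate for H&E slides.  A Rec.601 luma alternative is
#' available via `method = "luma"`.
#'
#' @param image rows x cols x 3 numeric array with values in 0-255, or a
#'   `retina_image`.
#' @param method `"hsv_value"` (default) or `"luma"`.
#' @return object of class `gray_image`: list with `values` (matrix,
#'   0-255) and `pixel_size_um`.
#' @export
rgb_to_luminance <- function(image, method = c("hsv_value", "luma")) {
  method <- match.arg(method)
  psz <- 1.0
  if (inherits(image, "retina_image")) {
    psz <- image$pixel_size_um
    image <- image$rgb
  }
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("rgb_to_luminance: expected a rows x cols x 3 array")
  }
  if (min(image) < 0 || max(image) > 255) {
    stop("rgb_to_luminance: channel values must lie in [0, 255]")
  }
  v <- switch(method,
    hsv_value = pmax(image[, , 1], image[, , 2], image[, , 3]),
    luma = 0.299 * image[, , 1] + 0.587 * image[, , 2] +
      0.114 * image[, , 3]
  )
  gray_image(matrix(v, dim(image)[1], dim(image)[2]), psz)
}

#' Construct a gray image container
#'
#' @param values numeric matrix of luminance values in 0-255.
#' @param pixel_size_um physical pixel size.
#' @return object of class `gray_image`.
#' @export
gray_image <- function(values, pixel_size_um = 1.0) {
  stopifnot(is.matrix(values), pixel_size_um > 0)
  if (min(values) < -1e-9 || max(values) > 255 + 1e-9) {
    stop("gray_image: values must lie in [0, 255]")
  }
  structure(list(values = values, pixel_size_um = pixel_size_um),
            class = "gray_image")
}

#' Extract the retinal tissue band from a luminance image
#'
#' Without an ROI, tissue is every pixel darker than the tissue/background
#' luminance cut (see [luminance_classes()]); the binary mask is
#' morphologically closed (radius 3 px, bridging staining speckle while
#' leaving real tears intact) and components smaller than 5% of the
#' largest are dropped.  Ruptures genuinely fragment the band, so the
#' retained mask may hold several band fragments; for an intact retina it
#' is a single dominant component.  With an ROI polygon, the mask is the
#' rasterized polygon intersected with non-background pixels.
#'
#' @param gray a [gray_image()].
#' @param roi optional polygon, list or matrix with columns `x`, `y` in
#'   0-based pixel coordinates.
#' @param closing_radius_px radius of the morphological closing.
#' @return object of class `retina_mask`: list with `mask` (logical
#'   matrix), `pixel_size_um`, `provenance` and `thr_bg`.
#' @export
extract_retina <- function(gray, roi = NULL, closing_radius_px = 3L) {
  stopifnot(inherits(gray, "gray_image"))
  cls <- luminance_classes(gray$values)
  tissue <- gray$values <= cls$thr_bg
  provenance <- "auto"
  if (!is.null(roi)) {
    provenance <- "provided-roi"
    tissue <- tissue & rasterize_polygon(roi, dim(gray$values))
  }
  if (!any(tissue)) {
    stop(sprintf(
      "extract_retina: empty mask (background threshold %.1f, image range %.0f-%.0f)",
      cls$thr_bg, min(gray$values), max(gray$values)))
  }
  closed <- binary_close(tissue, closing_radius_px)
  lab <- label_components(closed)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= 0.05 * max(sizes))
  mask <- matrix(lab %in% keep, nrow(closed), ncol(closed))
  if (!any(mask)) {
    stop("extract_retina: no component survived cleanup")
  }
  structure(list(mask = mask, pixel_size_um = gray$pixel_size_um,
                 provenance = provenance, thr_bg = cls$thr_bg),
            class = "retina_mask")
}

# even-odd rule polygon rasterization; vertices in 0-based pixel coords
rasterize_polygon <- function(roi, dims) {
  if (is.list(roi) && !is.null(roi$x)) roi <- cbind(x = roi$x, y = roi$y)
  roi <- as.matrix(roi)
  if (ncol(roi) != 2L || nrow(roi) < 3L) {
    stop("roi must be a polygon with >= 3 (x, y) vertices")
  }
  nr <- dims[1]; nc <- dims[2]
  px <- roi[, 1]; py <- roi[, 2]
  out <- matrix(FALSE, nr, nc)
  # scanline fill at pixel centers (col - 0.5, row - 0.5 in 0-based coords)
  for (row in seq_len(nr)) {
    yc <- row - 0.5
    j <- length(px)
    xs <- numeric(0)
    for (i in seq_along(px)) {
      if ((py[i] > yc) != (py[j] > yc)) {
        xs <- c(xs, px[i] + (yc - py[i]) / (py[j] - py[i]) * (px[j] - px[i]))
      }
      j <- i
    }
    if (length(xs)) {
      xs <- sort(xs)
      for (k in seq(1, length(xs) - 1, by = 2)) {
        c0 <- max(1L, ceiling(xs[k] + 0.5))
        c1 <- min(nc, floor(xs[k + 1] + 0.5))
        if (c1 >= c0) out[row, c0:c1] <- TRUE
      }
    }
  }
  out
}
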