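make_density_image <- function(seed, onl = 2.5, inl = 1.6) {
  generate_retina_image(retina_spec(
    image_size_px = c(600L, 1200L), pixel_size_um = 1.0,
    curvature = 0.03, n_ruptures = 0L,
    onl_density_per100um2 = onl, inl_density_per100um2 = inl,
    noise_sd = 2, seed = seed))
}

test_that("binarization recovers the planted nuclear pixel fraction", {
  img <- make_density_image(51L)
  gray <- rgb_to_luminance(img)
  mask <- extract_retina(gray)
  bn <- binarize_nuclei(gray, mask)
  expect_true(all(bn$values %in% c(0, 255)))
  # planted fraction: dark nuclei pixels over the band
  lum0 <- pmax(img$rgb[, , 1], img$rgb[, , 2], img$rgb[, , 3])
  planted <- mean(lum0[img$ground_truth$labels > 0L] < 170)
  got <- mean(bn$values[mask$mask] == 0)
  expect_lt(abs(got - planted) / planted, 0.10)
})

test_that("a pure-eosin region binarizes to all 255 with a warning", {
  g <- gray_image(matrix(230 + rnorm(5000, 0, 1.5), 50, 100))
  region <- matrix(TRUE, 50, 100)
  expect_warning(bn <- binarize_nuclei(g, region), "no nuclear")
  expect_true(all(bn$values == 255))
})

test_that("inverted-polarity input is rejected", {
  # dark majority, bright minority - an inverted H&E image
  v <- matrix(255 - c(rep(230, 8000), rep(60, 2000)), 100, 100)
  g <- gray_image(v)
  expect_error(binarize_nuclei(g, matrix(TRUE, 100, 100)), "inverted")
})

test_that("OPL segmentation finds the planted plexiform valley", {
  img <- make_density_image(52L)
  gray <- rgb_to_luminance(img)
  mask <- extract_retina(gray)
  curve <- fit_retinal_curve(mask)
  bn <- binarize_nuclei(gray, mask)
  seg <- segment_opl(bn, curve)
  # true OPL midline offset from the band midline (depth of OPL centre
  # minus half stack); compare |offset| - the normal sign is data-driven
  th <- img$ground_truth$layer_thicknesses_um
  cum <- cumsum(th)
  true_off <- (cum["ONL"] + cum["OPL"]) / 2 - sum(th) / 2
  expect_lt(abs(abs(seg$opl_offset_um) - abs(true_off)), 3)
  # ONL band is on the opposite side of the OPL from the INL band
  expect_true(sign(mean(seg$onl_offsets_um) - seg$opl_offset_um) !=
                sign(mean(seg$inl_offsets_um) - seg$opl_offset_um))
})

test_that("ONL/INL labels follow nuclei content, not image orientation", {
  img <- make_density_image(53L)
  rot <- img
  for (k in 1:3) {
    rot$rgb[, , k] <- img$rgb[nrow(img$rgb):1, ncol(img$rgb):1, k]
  }
  d0 <- suppressWarnings(nuclei_density_pipeline(img))
  d1 <- suppressWarnings(nuclei_density_pipeline(rot))
  # ONL (denser) stays ONL after a 180-degree flip
  expect_equal(d1$onl$density_per_100um2, d0$onl$density_per_100um2,
               tolerance = 0.05)
  expect_gt(d0$onl$density_per_100um2, d0$inl$density_per_100um2)
})

test_that("a single nuclear band is a segmentation error", {
  img <- generate_retina_image(retina_spec(
    image_size_px = c(600L, 1200L), pixel_size_um = 1.0,
    curvature = 0.03, n_ruptures = 0L,
    onl_density_per100um2 = 2.5, inl_density_per100um2 = 0,
    noise_sd = 0, seed = 54L))
  gray <- rgb_to_luminance(img)
  mask <- extract_retina(gray)
  curve <- fit_retinal_curve(mask)
  bn <- binarize_nuclei(gray, mask)
  expect_error(segment_opl(bn, curve), "maxima")
})

test_that("density arithmetic identities hold", {
  # 100 um^2 region with exactly two disjoint nuclei of calibration area
  vals <- matrix(255, 10, 10)
  vals[2:3, 2:3] <- 0
  vals[7:8, 7:8] <- 0
  bn <- structure(list(values = vals, pixel_size_um = 1,
                       region = matrix(TRUE, 10, 10)),
                  class = "binary_nuclei")
  r <- nuclei_density(bn, matrix(TRUE, 10, 10),
                      calibration_nucleus_area_um2 = 4)
  expect_equal(r$nuclei_count, 2)
  expect_equal(r$density_per_100um2, 2)
  # empty region: density 0
  empty <- structure(list(values = matrix(255, 5, 5), pixel_size_um = 1,
                          region = matrix(TRUE, 5, 5)),
                     class = "binary_nuclei")
  expect_equal(nuclei_density(empty, matrix(TRUE, 5, 5),
                              4)$density_per_100um2, 0)
  # component counting agrees here
  expect_equal(nuclei_density(bn, matrix(TRUE, 10, 10), 4,
                              method = "component")$nuclei_count, 2)
})

test_that("nuclei counts are additive over disjoint sub-regions", {
  img <- make_density_image(55L)
  gray <- rgb_to_luminance(img)
  mask <- extract_retina(gray)
  bn <- binarize_nuclei(gray, mask)
  idx <- which(mask$mask)
  half1 <- idx[seq_len(length(idx) %/% 2)]
  half2 <- setdiff(idx, half1)
  c_all <- nuclei_density(bn, idx, 13)$nuclei_count
  c1 <- nuclei_density(bn, half1, 13)$nuclei_count
  c2 <- nuclei_density(bn, half2, 13)$nuclei_count
  expect_equal(c1 + c2, c_all, tolerance = 1e-12)
})

test_that("planting more nuclei never decreases the estimate", {
  d_lo <- suppressWarnings(nuclei_density_pipeline(
    make_density_image(56L, onl = 1.2, inl = 0.8)))
  d_hi <- suppressWarnings(nuclei_density_pipeline(
    make_density_image(56L, onl = 2.8, inl = 1.8)))
  expect_gt(d_hi$onl$density_per_100um2, d_lo$onl$density_per_100um2)
  expect_gt(d_hi$inl$density_per_100um2, d_lo$inl$density_per_100um2)
})

test_that("density is invariant to pixel-size rescaling of the same scene", {
  base <- retina_spec(image_size_px = c(600L, 1200L), pixel_size_um = 1.0,
                      curvature = 0.03, n_ruptures = 0L, noise_sd = 2,
                      seed = 57L)
  fine <- retina_spec(image_size_px = c(1200L, 2400L), pixel_size_um = 0.5,
                      curvature = 0.03, n_ruptures = 0L, noise_sd = 2,
                      seed = 57L)
  d1 <- suppressWarnings(nuclei_density_pipeline(generate_retina_image(base)))
  d2 <- suppressWarnings(nuclei_density_pipeline(generate_retina_image(fine)))
  expect_lt(abs(d1$onl$density_per_100um2 - d2$onl$density_per_100um2) /
              d1$onl$density_per_100um2, 0.15)
})
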