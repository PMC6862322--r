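test_that("a straight horizontal band yields its centerline within 1 px", {
  m <- matrix(FALSE, 100, 400)
  m[40:60, ] <- TRUE
  curve <- fit_retinal_curve(m, pixel_size_um = 2)
  expect_true(all(abs(curve$y_px - 50) < 1))
  expect_equal(max(curve$arclength_um), 2 * 399, tolerance = 0.01)
})

test_that("a circular-arc band recovers the planted radius within 5%", {
  spec <- frailty_spec(0L, seed = 31L, curvature = 0.1)
  img <- generate_retina_image(spec)
  curve <- fit_retinal_curve(extract_retina(rgb_to_luminance(img)))
  # planted midline radius in pixel units
  w_um <- 600 * 2.5
  s <- 0.1 * w_um
  r_true_px <- (((w_um / 2)^2 + s^2) / (2 * s)) / 2.5
  # independent algebraic circle fit through the curve samples
  fit <- kasa_circle_fit(curve$x_px, curve$y_px)
  expect_lt(abs(fit$r - r_true_px) / r_true_px, 0.05)
})

test_that("a filled square is rejected as not band-like", {
  m <- matrix(TRUE, 80, 80)
  expect_error(fit_retinal_curve(m), "band-like")
})

test_that("profiles are constant on uniform images and nearest-pixel at zero width", {
  g <- gray_image(matrix(137, 60, 300), pixel_size_um = 1)
  m <- matrix(FALSE, 60, 300)
  m[20:40, ] <- TRUE
  curve <- fit_retinal_curve(m, pixel_size_um = 1)
  prof <- sample_profile(g, curve, band_halfwidth_um = 8)
  expect_true(all(prof$value == 137))
  # zero halfwidth equals the nearest-pixel luminance along the curve
  g2 <- gray_image(matrix(rep(seq(0, 255, length.out = 300), each = 60),
                          60, 300), pixel_size_um = 1)
  p0 <- sample_profile(g2, curve, band_halfwidth_um = 0)
  nearest <- g2$values[cbind(round(curve$y_px + 0.5),
                             round(curve$x_px + 0.5))]
  expect_equal(p0$value, nearest)
})

test_that("profile values inside ruptures sit at background luminance", {
  img <- generate_retina_image(frailty_spec(4L, seed = 32L))
  fr <- suppressWarnings(frailty_index(img))
  spans <- img$ground_truth$rupture_spans_um
  L <- img$ground_truth$band_length_um
  prof <- fr$profile
  for (i in seq_len(nrow(spans))) {
    mid <- mean(spans[i, ])
    # fitted arclength may run in either direction
    sel <- which(pmin(abs(prof$position_um - mid),
                      abs(prof$position_um - (L - mid))) < 4)
    expect_gt(max(prof$value[sel]), 245 - 10)
  }
})

test_that("count_discontinuities implements flag/merge/drop exactly", {
  pos <- seq_len(400)
  base <- rep(200, 400)
  expect_identical(
    count_discontinuities(list(position_um = pos, value = base),
                          min_width_um = 5)$n_discontinuities, 0L)
  for (k in c(1L, 5L, 13L)) {
    v <- base
    starts <- 20 + (seq_len(k) - 1) * 25
    for (s in starts) v[s:(s + 9)] <- 250
    r <- count_discontinuities(list(position_um = pos, value = v),
                               threshold = 25, min_width_um = 5)
    expect_identical(r$n_discontinuities, k)
    expect_identical(nrow(r$spans_um), k)
  }
  # two plateaus separated by less than min_width merge into one
  v <- base
  v[100:109] <- 250
  v[113:122] <- 250
  r <- count_discontinuities(list(position_um = pos, value = v),
                             threshold = 25, min_width_um = 5)
  expect_identical(r$n_discontinuities, 1L)
  # runs narrower than min_width are dropped
  v <- base
  v[200:202] <- 250
  r <- count_discontinuities(list(position_um = pos, value = v),
                             threshold = 25, min_width_um = 5)
  expect_identical(r$n_discontinuities, 0L)
  # invalid positions
  expect_error(
    count_discontinuities(list(position_um = c(1, 3, 2), value = 1:3)),
    "increasing")
})

test_that("discontinuity count is non-increasing in the threshold", {
  img <- generate_retina_image(frailty_spec(6L, seed = 33L, noise_sd = 2))
  fr <- suppressWarnings(frailty_index(img))
  counts <- vapply(c(2, 5, 7.5, 10, 14, 20, 40), function(thr) {
    count_discontinuities(fr$profile, threshold = thr)$n_discontinuities
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("frailty recovery is exact on clean images (spot checks)", {
  for (n in c(0L, 7L)) {
    img <- generate_retina_image(frailty_spec(n, seed = 40L + n))
    fr <- suppressWarnings(frailty_index(img))
    expect_identical(fr$frailty$n_discontinuities, as.integer(n))
  }
})

test_that("thickness recovery from ground-truth labels is sub-pixel", {
  img <- generate_retina_image(profile_spec("wt", seed = 41L))
  th <- suppressWarnings(measure_truth_thickness(img))
  truth <- img$ground_truth$layer_thicknesses_um
  expect_true(all(abs(th$per_layer_um - truth) <= 2 * img$pixel_size_um))
  expect_equal(th$total_um, sum(th$per_layer_um))
})

test_that("flat bands give site-invariant thickness", {
  spec <- retina_spec(image_size_px = c(300L, 1200L), pixel_size_um = 1,
                      curvature = 0, n_ruptures = 0L,
                      layer_thicknesses_um =
                        reference_layer_profile("wt") * 0.5,
                      onl_density_per100um2 = 0,
                      inl_density_per100um2 = 0, noise_sd = 0, seed = 42L)
  img <- generate_retina_image(spec)
  gray <- rgb_to_luminance(img)
  curve <- fit_retinal_curve(extract_retina(gray))
  lm <- truth_landmark_px(img)
  t1 <- measure_thickness(curve, labels = img$ground_truth$labels,
                          landmark_t_um = curve_locate(curve, lm[1], lm[2]),
                          offsets_um = c(-400, 400))
  t2 <- measure_thickness(curve, labels = img$ground_truth$labels,
                          landmark_t_um = curve_locate(curve, lm[1], lm[2]),
                          offsets_um = c(-150, 150))
  expect_equal(t1$per_layer_um, t2$per_layer_um, tolerance = 0.02)
})

test_that("sites falling inside a rupture are skipped, not fabricated", {
  spec <- profile_spec("wt", seed = 43L, n_ruptures = 3L)
  img <- generate_retina_image(spec)
  gray <- rgb_to_luminance(img)
  curve <- fit_retinal_curve(extract_retina(gray))
  spans <- img$ground_truth$rupture_spans_um
  mid <- mean(spans[1, ])
  gt <- img$ground_truth
  i <- which.min(abs(gt$midline_t_um - mid))
  lm <- gt$midline_xy_um[i, ] / img$pixel_size_um
  t_rup <- curve_locate(curve, lm[1], lm[2])
  # one site group dead-centre in the rupture, one in clean tissue
  # (offset toward the band interior; arclength may run either way)
  interior <- if (t_rup > max(curve$arclength_um) / 2) -300 else 300
  th <- measure_thickness(curve, labels = gt$labels,
                          landmark_t_um = t_rup,
                          offsets_um = c(0, interior), sites_per_side = 1)
  expect_identical(th$n_sites_used, 1L)
  expect_length(th$skipped_sites, 1L)
  expect_true(all(abs(th$per_layer_um - gt$layer_thicknesses_um) <= 2))
  # all sites inside ruptures is a measurement error
  expect_error(
    measure_thickness(curve, labels = gt$labels, landmark_t_um = t_rup,
                      offsets_um = 0, sites_per_side = 1),
    "skipped")
})

test_that("rotating the image 180 degrees changes neither count nor thickness", {
  img <- generate_retina_image(frailty_spec(5L, seed = 44L, noise_sd = 2))
  rot <- img
  for (k in 1:3) {
    rot$rgb[, , k] <- img$rgb[nrow(img$rgb):1, ncol(img$rgb):1, k]
  }
  rot$ground_truth$labels <-
    img$ground_truth$labels[nrow(img$rgb):1, ncol(img$rgb):1]
  f0 <- suppressWarnings(frailty_index(img))
  f1 <- suppressWarnings(frailty_index(rot))
  expect_identical(f1$frailty$n_discontinuities,
                   f0$frailty$n_discontinuities)
})
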