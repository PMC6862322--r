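# desk-scale synthetic specs shared across tests

# small, fast frailty image: thin band, no nuclei, noiseless by default
frailty_spec <- function(n_ruptures, seed, noise_sd = 0,
                         curvature = 0.03, onl = 0, inl = 0) {
  retina_spec(
    image_size_px = c(160L, 600L),
    pixel_size_um = 2.5,
    layer_thicknesses_um = reference_layer_profile("wt") * 0.3,
    curvature = curvature,
    n_ruptures = n_ruptures,
    rupture_width_um = 20,
    onl_density_per100um2 = onl,
    inl_density_per100um2 = inl,
    noise_sd = noise_sd,
    seed = seed
  )
}

# full-resolution image with the reference layer profile planted
profile_spec <- function(genotype, seed, noise_sd = 0, n_ruptures = 0L,
                         curvature = 0.03) {
  retina_spec(
    image_size_px = c(600L, 1200L),
    pixel_size_um = 1.0,
    layer_thicknesses_um = reference_layer_profile(genotype),
    curvature = curvature,
    n_ruptures = n_ruptures,
    rupture_width_um = 20,
    noise_sd = noise_sd,
    seed = seed
  )
}

# ground-truth landmark in pixel coordinates
truth_landmark_px <- function(img) {
  gt <- img$ground_truth
  i <- which.min(abs(gt$midline_t_um - gt$landmark_t_um))
  gt$midline_xy_um[i, ] / img$pixel_size_um
}

# thickness via the fitted curve and ground-truth labels
measure_truth_thickness <- function(img) {
  gray <- rgb_to_luminance(img)
  curve <- fit_retinal_curve(extract_retina(gray))
  lm <- truth_landmark_px(img)
  measure_thickness(curve, labels = img$ground_truth$labels,
                    landmark_t_um = curve_locate(curve, lm[1], lm[2]))
}

# algebraic (Kasa) circle fit, used as an independent radius oracle
kasa_circle_fit <- function(x, y) {
  fit <- lm(I(x^2 + y^2) ~ x + y)
  b <- coef(fit)
  cx <- b["x"] / 2
  cy <- b["y"] / 2
  list(cx = unname(cx), cy = unname(cy),
       r = unname(sqrt(b[1] + cx^2 + cy^2)))
}

# exact tie-free two-sided rank-sum p from the null U distribution
oracle_ranksum_p <- function(a, b) {
  stopifnot(!anyDuplicated(c(a, b)))
  na <- length(a); nb <- length(b)
  u <- sum(rank(c(a, b))[seq_len(na)]) - na * (na + 1) / 2
  min(1, 2 * min(stats::pwilcox(u, na, nb),
                 stats::pwilcox(u - 1, na, nb, lower.tail = FALSE)))
}
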