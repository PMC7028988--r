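test_that("identical seeds give bit-identical ROIs, images and cohorts", {
  cfg <- small_roi_config(seed = 9, artifact_fraction = 0.1)
  a <- generate_roi_points(cfg, 1, 1)
  b <- generate_roi_points(cfg, 1, 1)
  expect_identical(a, b)

  ra <- render_roi_image(a$cells, cfg)
  rb <- render_roi_image(b$cells, cfg)
  expect_identical(ra$image$pixels, rb$image$pixels)
  expect_identical(ra$mask, rb$mask)

  small <- sim_config(n_patients = 6, rois_per_patient = c(2L, 3L),
                      image_shape = c(200L, 260L),
                      class_densities = c(CD8 = 4, PDL1 = 6, PD1 = 8,
                                          NEG = 20),
                      seed = 4)
  expect_identical(generate_cohort(small), generate_cohort(small))
})

test_that("zero densities give an empty cell table; absurd densities error", {
  cfg <- sim_config(image_shape = c(100L, 100L),
                    class_densities = c(CD8 = 0, NEG = 0), seed = 1)
  roi <- generate_roi_points(cfg, 1, 1)
  expect_equal(nrow(roi$cells), 0)

  over <- sim_config(image_shape = c(20L, 20L),
                     class_densities = c(NEG = 5000), seed = 1)
  expect_error(generate_roi_points(over, 1, 1), "exceed")
})

test_that("all generated cells lie inside the image bounds", {
  cfg <- small_roi_config(seed = 2, colocalization_strength = 3)
  for (r in 1:5) {
    roi <- generate_roi_points(cfg, 1, r)
    expect_true(all(roi$cells$x >= 0 & roi$cells$x <= 519))
    expect_true(all(roi$cells$y >= 0 & roi$cells$y <= 399))
  }
})

test_that("CSR placement matches the closed-form expectation and clustering raises h", {
  # complete spatial randomness: E[H] = E[n_i] E[n_j] P(pairwise dist < d)
  # for two uniform points in the W x H rectangle; the uncorrected
  # pi d^2 / A expectation overstates this by the edge deficit
  cfg <- sim_config(seed = 31, colocalization_strength = 0,
                    artifact_fraction = 0)  # full-size study conditions
  d_px <- microns_to_pixels(cfg$d_um, cfg$pixel_size_um)
  A <- prod(cfg$image_shape)
  dens <- cfg$class_densities
  lam_i <- dens[["CD8_PD1"]] + dens[["PD1"]]        # PD-1 carrying classes
  lam_j <- dens[["PDL1"]] + dens[["CD68_PDL1"]]     # PD-L1 carrying classes
  lam_N <- sum(dens)
  # oracle: numerical integration of the |dx|, |dy| triangular densities
  W <- cfg$image_shape[2]; H <- cfg$image_shape[1]
  g <- seq(0, d_px, length.out = 800)
  du <- g[2] - g[1]
  fx <- 2 * (W - g) / W^2
  fy <- 2 * (H - g) / H^2
  circ <- outer(g^2, g^2, `+`) < d_px^2
  p_pair <- sum(outer(fx, fy) * circ) * du^2
  expected_h_naive <- lam_i * lam_j * pi * d_px^2 / A / lam_N
  expected_h <- lam_i * lam_j * p_pair / lam_N
  expect_lt(expected_h, expected_h_naive)

  hs <- vapply(1:200, function(r) {
    roi <- generate_roi_points(cfg, 1, r)
    hid_count(roi$cells, "PD-1+", "PD-L1+", d_um = cfg$d_um,
              pixel_size_um = cfg$pixel_size_um)$h
  }, numeric(1))
  expect_gt(mean(hs), expected_h * 0.90)
  expect_lt(mean(hs), expected_h * 1.10)
  expect_lt(mean(hs), expected_h_naive)  # edge deficit direction

  # planted clustering strictly increases mean h (one-sided, p < 0.01)
  cfg_cl <- sim_config(seed = 31, colocalization_strength = 2,
                       artifact_fraction = 0)
  hs_cl <- vapply(1:100, function(r) {
    roi <- generate_roi_points(cfg_cl, 2, r)
    hid_count(roi$cells, "PD-1+", "PD-L1+", d_um = cfg$d_um,
              pixel_size_um = cfg$pixel_size_um)$h
  }, numeric(1))
  tt <- t.test(hs_cl, hs[1:100], alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("mean h rises monotonically with colocalization strength", {
  strengths <- c(0, 0.5, 1, 2, 4)
  mean_h <- vapply(strengths, function(s) {
    cfg <- small_roi_config(seed = 55, colocalization_strength = s)
    mean(vapply(1:50, function(r) {
      roi <- generate_roi_points(cfg, 1, r)
      hid_count(roi$cells, "PD-1+", "PD-L1+", d_um = cfg$d_um,
                pixel_size_um = cfg$pixel_size_um)$h
    }, numeric(1)))
  }, numeric(1))
  rho <- cor(strengths, mean_h, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("rendered truth masks reflect the artifact budget", {
  cfg0 <- small_roi_config(seed = 3, artifact_fraction = 0)
  roi <- generate_roi_points(cfg0, 1, 1)
  rend0 <- render_roi_image(roi$cells, cfg0)
  expect_true(all(rend0$mask == 1L))  # 100% tissue when nothing painted

  cfg1 <- small_roi_config(seed = 3, artifact_fraction = 0.15)
  rend1 <- render_roi_image(roi$cells, cfg1)
  expect_setequal(unique(as.vector(rend1$mask)), c(0L, 1L, 2L))
  planted <- mean(rend1$mask != 1L)
  expect_gt(planted, 0.05)
  expect_lt(planted, 0.3)
})

test_that("an empty ROI renders to sub-threshold noise with no detections", {
  cfg <- sim_config(image_shape = c(200L, 260L),
                    class_densities = c(NEG = 0), artifact_fraction = 0,
                    seed = 8)
  roi <- generate_roi_points(cfg, 1, 1)
  rend <- render_roi_image(roi$cells, cfg)
  det <- detect_nuclei(get_channel(rend$image, "DAPI"))
  expect_equal(nrow(det$centroids), 0)
})

test_that("survival simulator honours censoring and the planted hazard", {
  s0 <- simulate_survival(rep(0, 500), baseline_hazard = 0.01,
                          censoring_rate = 0, seed = 21)
  expect_true(all(s0$event == 1L))

  s40 <- simulate_survival(rep(0, 4000), baseline_hazard = 0.01,
                           censoring_rate = 0.4, seed = 22)
  expect_gt(mean(s40$event == 0L), 0.35)
  expect_lt(mean(s40$event == 0L), 0.45)

  # a positive log HR shortens event times
  fast <- simulate_survival(rep(log(3), 4000), baseline_hazard = 0.01,
                            censoring_rate = 0, seed = 23)
  slow <- simulate_survival(rep(0, 4000), baseline_hazard = 0.01,
                            censoring_rate = 0, seed = 24)
  expect_lt(median(fast$time_months) * 2, median(slow$time_months))
})

test_that("cohort generation plants the hazard in the requested stratum", {
  cfg <- sim_config(n_patients = 40, rois_per_patient = c(2L, 3L),
                    image_shape = c(200L, 260L),
                    class_densities = c(CD8 = 4, CD8_PD1 = 2, PDL1 = 8,
                                        PD1 = 10, NEG = 30),
                    censoring_rate = 0, seed = 12)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh$patients), 40)
  expect_true(all(coh$patients$event == 1L))
  expect_setequal(unique(coh$truth$true_group), c("high", "low"))
  # per-ROI features recompute to the stored patient medians
  for (p in c(1, 17, 40)) {
    sub <- coh$roi_features[coh$roi_features$patient_id == p, ]
    expect_equal(patient_hid(sub), coh$patients$hid[p])
  }
})
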