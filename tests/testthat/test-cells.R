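test_that("nuclear detection finds isolated blobs at their centroids", {
  # noise-only channel: nothing detected
  set.seed(6)
  noise <- matrix(abs(rnorm(120 * 150, 0, 0.02)), 120, 150)
  det0 <- detect_nuclei(noise)
  expect_equal(nrow(det0$centroids), 0)

  expect_error(detect_nuclei(matrix(c(1, NA, 1, 1), 2, 2)), "non-finite")

  # k well-separated blobs recovered with centroids within 2 px
  set.seed(7)
  for (rep in 1:10) {
    k <- sample(3:8, 1)
    cx <- runif(k, 15, 185); cy <- runif(k, 15, 135)
    while (any(as.matrix(dist(cbind(cx, cy))) + diag(Inf, k) < 20)) {
      cx <- runif(k, 15, 185); cy <- runif(k, 15, 135)
    }
    img <- blob_image(150, 200, cx, cy)
    det <- detect_nuclei(img)
    expect_equal(nrow(det$centroids), k)
    mt <- match_centroids(det$centroids, data.frame(x = cx, y = cy),
                          radius_px = 2)
    expect_equal(mt$n_matched, k)
  }
})

test_that("watershed splits two partially overlapping nuclei", {
  img <- blob_image(60, 80, c(32, 41), c(30, 30))  # touching, 9 px apart
  det <- detect_nuclei(img)
  expect_equal(nrow(det$centroids), 2)
})

test_that("detection is deterministic", {
  cfg <- small_roi_config(seed = 41)
  roi <- generate_roi_points(cfg, 1, 1)
  rend <- render_roi_image(roi$cells, cfg)
  dapi <- get_channel(rend$image, "DAPI")
  expect_identical(detect_nuclei(dapi), detect_nuclei(dapi))
})

test_that("cell expansion uses the forced 4 px radius and nearest-nucleus rule", {
  # 2 um at 0.495 um/px rounds to 4 px
  lab <- matrix(0L, 30, 30); lab[15, 15] <- 1L
  ex <- expand_cells(lab, radius_um = 2, pixel_size_um = 0.495)
  expect_equal(ex$radius_px, 4)
  # isolated single-pixel nucleus: expansion is the full Euclidean disc
  disc_px <- sum(outer((-4:4)^2, (-4:4)^2, `+`) <= 16)
  expect_equal(sum(ex$cell == 1L), disc_px)
  expect_equal(sum(ex$cytoplasm == 1L), disc_px - 1)
  expect_error(expand_cells(lab, radius_um = 0), "positive")
})

test_that("expansion stops at the equidistant boundary between cells", {
  lab <- matrix(0L, 40, 40)
  lab[20, 18] <- 1L  # nucleus 1
  lab[20, 21] <- 2L  # nucleus 2, 3 px to the right
  ex <- expand_cells(lab, radius_um = 2, pixel_size_um = 0.495)

  # oracle: per-pixel nearest nucleus pixel, ties to the lower label
  nuc <- which(lab > 0, arr.ind = TRUE)
  for (i in 1:40) for (j in 1:40) {
    d2 <- (nuc[, 1] - i)^2 + (nuc[, 2] - j)^2
    if (min(d2) <= 16) {
      winners <- lab[nuc[which(d2 == min(d2)), , drop = FALSE]]
      expect_identical(ex$cell[i, j], min(winners))
    } else {
      expect_identical(ex$cell[i, j], 0L)
    }
  }
  # compartments are disjoint
  expect_true(all(ex$cytoplasm[lab > 0] == 0L))
})

test_that("compartments partition pixels with no double ownership", {
  cfg <- small_roi_config(seed = 13)
  roi <- generate_roi_points(cfg, 1, 1)
  rend <- render_roi_image(roi$cells, cfg)
  det <- detect_nuclei(get_channel(rend$image, "DAPI"))
  ex <- expand_cells(det$labels, 2, 0.495)
  # nucleus pixels keep their own label in the cell map
  nz <- det$labels > 0
  expect_true(all(ex$cell[nz] == det$labels[nz]))
  expect_true(all(ex$cytoplasm[nz] == 0L))
  # every cytoplasm pixel belongs to exactly one cell
  cz <- ex$cytoplasm > 0
  expect_true(all(ex$cell[cz] == ex$cytoplasm[cz]))
})

test_that("intensity statistics match hand values and a per-pixel loop", {
  # two-compartment toy: nucleus = 2 px with values {1, 3}
  lab <- matrix(0L, 6, 6); lab[3, 3] <- 1L; lab[3, 4] <- 1L
  ch <- matrix(5, 6, 6); ch[3, 3] <- 1; ch[3, 4] <- 3
  img <- multiplex_image(array(ch, dim = c(6, 6, 1)), "DAPI", 0.495)
  comp <- list(nucleus = lab, cytoplasm = matrix(0L, 6, 6))
  cent <- data.frame(cell_id = 1L, x = 2.5, y = 2, area = 2L)
  tab <- measure_intensities(img, comp, cent)
  expect_equal(tab$nuc_DAPI_mean, 2)
  expect_equal(tab$nuc_DAPI_min, 1)
  expect_equal(tab$nuc_DAPI_max, 3)
  expect_equal(tab$nuc_DAPI_sd, 1)  # population sd of {1, 3}
  expect_true(tab$flag_empty_cytoplasm)
  expect_true(is.na(tab$cyto_DAPI_mean))

  # uniform channel: mean = min = max, sd = 0
  chu <- matrix(0.7, 6, 6)
  imgu <- multiplex_image(array(chu, dim = c(6, 6, 1)), "DAPI", 0.495)
  tabu <- measure_intensities(imgu, comp, cent)
  expect_equal(tabu$nuc_DAPI_mean, 0.7)
  expect_equal(tabu$nuc_DAPI_sd, 0)

  # random image and labels: stats equal an explicit per-pixel loop
  set.seed(33)
  lab2 <- matrix(sample(0:3, 400, replace = TRUE), 20, 20)
  ch2 <- matrix(runif(400), 20, 20)
  img2 <- multiplex_image(array(ch2, dim = c(20, 20, 1)), "CD8", 0.495)
  cent2 <- data.frame(cell_id = 1:3, x = 0, y = 0, area = tabulate(lab2)[1:3])
  tab2 <- measure_intensities(img2, list(nucleus = lab2,
                                         cytoplasm = matrix(0L, 20, 20)),
                              cent2)
  for (cid in 1:3) {
    v <- ch2[lab2 == cid]
    expect_equal(tab2$nuc_CD8_mean[cid], mean(v))
    expect_equal(tab2$nuc_CD8_min[cid], min(v))
    expect_equal(tab2$nuc_CD8_max[cid], max(v))
    expect_equal(tab2$nuc_CD8_sd[cid], sqrt(mean((v - mean(v))^2)))
  }
})

test_that("percentile rescaling maps the bounds to 0/1 and clips outside", {
  set.seed(2)
  px <- list(CD8 = rlnorm(5000, log(0.05), 1))
  b <- fit_rescale(px)
  expect_equal(b$low, unname(quantile(px$CD8, 0.01)))
  expect_equal(b$high, unname(quantile(px$CD8, 0.99)))
  expect_equal(apply_rescale(b$low, b, "CD8"), 0)
  expect_equal(apply_rescale(b$high, b, "CD8"), 1)
  expect_equal(apply_rescale((b$low + b$high) / 2, b, "CD8"), 0.5)
  expect_equal(apply_rescale(b$high * 10, b, "CD8"), 1)
  expect_equal(apply_rescale(-1, b, "CD8"), 0)
  # order preserving
  v <- sort(runif(50, b$low, b$high))
  expect_true(all(diff(apply_rescale(v, b, "CD8")) >= 0))

  expect_error(fit_rescale(list(CD8 = rep(1, 500))), "degenerate")
  expect_error(fit_rescale(list(CD8 = runif(50))), ">= 100 pixels")
})

test_that("positivity scoring applies the tie-positive threshold rule", {
  cells <- data.frame(cell_id = 1:3, cyto_CD8_mean = c(0.9, 0.5, 0.49))
  b <- data.frame(marker = "CD8", low = 0, high = 1)
  scored <- score_positivity(cells, b, c(CD8 = 0.5))
  expect_identical(scored$pos_CD8, c(TRUE, TRUE, FALSE))
  expect_error(score_positivity(cells, b, c(CD8 = 1.5)), "\\[0, 1\\]")

  # missing compartment stats propagate NA
  cells$cyto_CD8_mean[2] <- NA
  scored2 <- score_positivity(cells, b, c(CD8 = 0.5))
  expect_true(is.na(scored2$pos_CD8[2]))
})

test_that("phenotype membership follows the conjunction rule", {
  only_cd8 <- cells_at(0, 0, CD8 = TRUE)
  ph <- assign_phenotypes(only_cd8)
  expect_true(ph$member_CD8)
  expect_false(ph$member_CD8PD1)
  expect_equal(ph$phenotypes, "CD8+")

  both <- cells_at(0, 0, CD8 = TRUE, PD1 = TRUE)
  phb <- assign_phenotypes(both)
  expect_true(phb$member_CD8 && phb$member_PD1 && phb$member_CD8PD1)
  expect_equal(phb$phenotypes, "CD8+;CD8+PD-1+;PD-1+")

  # random flag table vs brute-force set construction
  set.seed(19)
  rnd <- random_cells(200)
  phr <- assign_phenotypes(rnd)
  expect_identical(phr$member_CD8PD1, rnd$pos_CD8 & rnd$pos_PD1)
  expect_identical(phr$member_CD68PDL1, rnd$pos_CD68 & rnd$pos_PDL1)
  expect_identical(phr$member_PDL1, rnd$pos_PDL1)
})

test_that("end-to-end recovery holds on clean synthetic ROIs", {
  counts_ratio <- c(); f1 <- c()
  for (s in 1:5) {
    cfg <- small_roi_config(seed = 300 + s)
    out <- segment_and_score(cfg)
    counts_ratio <- c(counts_ratio, nrow(out$cells) / nrow(out$truth))
    f1 <- c(f1, out$match$f1)
  }
  expect_lt(abs(mean(counts_ratio) - 1), 0.05)
  expect_gt(mean(f1), 0.9)
})
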