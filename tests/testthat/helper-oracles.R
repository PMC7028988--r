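# Independent oracles and fixture builders used across the suite.

# Brute-force HID count: full distance matrix over all cells, unordered
# pairs, strict < d. Written independently of the package's grid/loop code.
oracle_hid <- function(cells, phenotype_i, phenotype_j, d_px) {
  n <- nrow(cells)
  if (n < 2) return(0L)
  need_i <- list("CD8+" = "CD8", "CD8+PD-1+" = c("CD8", "PD1"),
                 "CD68+" = "CD68", "CD68+PD-L1+" = c("CD68", "PDL1"),
                 "PD-L1+" = "PDL1", "PD-1+" = "PD1")
  memb <- function(ph) {
    flags <- sapply(need_i[[ph]],
                    function(m) as.logical(cells[[paste0("pos_", m)]]))
    if (is.null(dim(flags))) flags else apply(flags, 1, all)
  }
  mi <- memb(phenotype_i); mj <- memb(phenotype_j)
  D <- as.matrix(stats::dist(cbind(cells$x, cells$y)))
  H <- 0L
  for (p in 1:(n - 1)) {
    for (q in (p + 1):n) {
      if (D[p, q] < d_px && ((mi[p] && mj[q]) || (mj[p] && mi[q]))) {
        H <- H + 1L
      }
    }
  }
  H
}

# Random cell table with arbitrary marker flags (possibly co-expressing).
random_cells <- function(n, width = 1392, height = 1040, seed = NULL,
                         p_flags = c(CD8 = 0.1, PD1 = 0.15, PDL1 = 0.12,
                                     CD68 = 0.05)) {
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(cell_id = seq_len(n),
                   roi_id = 1L, patient_id = 1L,
                   x = runif(n, 0, width - 1), y = runif(n, 0, height - 1))
  for (m in names(p_flags)) {
    df[[paste0("pos_", m)]] <- runif(n) < p_flags[[m]]
  }
  df
}

# Minimal cell table from explicit coordinates and phenotype flags.
cells_at <- function(x, y, CD8 = FALSE, PD1 = FALSE, PDL1 = FALSE,
                     CD68 = FALSE) {
  n <- length(x)
  data.frame(cell_id = seq_len(n), roi_id = 1L, patient_id = 1L,
             x = x, y = y,
             pos_CD8 = rep_len(CD8, n), pos_PD1 = rep_len(PD1, n),
             pos_PDL1 = rep_len(PDL1, n), pos_CD68 = rep_len(CD68, n))
}

# Noise-free DAPI-like image with Gaussian blobs at given 0-based centres.
blob_image <- function(h, w, cx, cy, sigma = 2.2, amp = 0.9) {
  img <- matrix(0, h, w)
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  for (i in seq_along(cx)) {
    img <- img + amp * exp(-((xs - cx[i])^2 + (ys - cy[i])^2) /
                             (2 * sigma^2))
  }
  img
}

# Shared sim configuration for reduced-size image tests: study-condition
# per-area densities on a 400 x 520 field.
small_roi_config <- function(seed, artifact_fraction = 0, ...) {
  scale <- (400 * 520) / (1040 * 1392)
  sim_config(image_shape = c(400L, 520L),
             class_densities = round(sim_config()$class_densities * scale),
             artifact_fraction = artifact_fraction, seed = seed, ...)
}

# Run segmentation + scoring on one rendered ROI; returns scored cells,
# detection match and the truth table.
segment_and_score <- function(cfg, patient_id = 1L, roi_id = 1L) {
  roi <- generate_roi_points(cfg, patient_id, roi_id)
  rend <- render_roi_image(roi$cells, cfg)
  det <- detect_nuclei(get_channel(rend$image, "DAPI"))
  comp <- expand_cells(det$labels, 2, cfg$pixel_size_um)
  cells <- measure_intensities(rend$image, comp, det$centroids,
                               roi_id = roi_id, patient_id = patient_id)
  mp <- lapply(c("CD8", "PD1", "PDL1", "CD68"),
               function(m) as.vector(get_channel(rend$image, m)))
  names(mp) <- c("CD8", "PD1", "PDL1", "CD68")
  bounds <- fit_rescale(mp)
  thr <- sapply(names(mp),
                function(m) apply_rescale(cfg$marker_threshold, bounds, m))
  cells <- score_positivity(cells, bounds, thr)
  match <- match_centroids(cells, roi$cells, radius_px = 3)
  list(cells = cells, truth = roi$cells, match = match, rend = rend,
       det = det)
}
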