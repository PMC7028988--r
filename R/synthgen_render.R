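# Rendering of synthetic ROIs: nuclear blobs on DAPI, cytoplasmic discs on
# the marker channels, autofluorescence baseline, plus planted artifacts
# (bright AF blobs, blurred patches, zero-signal margins) recorded in a
# ground-truth quality mask.

# Additive paint of a Gaussian blob into a matrix, clipped to bounds.
# cx, cy are 0-based pixel coordinates (x = column).
paint_gauss <- function(mat, cx, cy, sigma, amp) {
  h <- nrow(mat); w <- ncol(mat)
  r <- ceiling(3 * sigma)
  c0 <- round(cx); r0 <- round(cy)
  cols <- max(0, c0 - r):min(w - 1, c0 + r)
  rows <- max(0, r0 - r):min(h - 1, r0 + r)
  if (length(cols) == 0 || length(rows) == 0) return(mat)
  dx2 <- (cols - cx)^2
  dy2 <- (rows - cy)^2
  blob <- amp * exp(-(outer(dy2, dx2, `+`)) / (2 * sigma^2))
  mat[rows + 1, cols + 1] <- mat[rows + 1, cols + 1] + blob
  mat
}

# Additive paint of a hard disc.
paint_disc <- function(mat, cx, cy, radius, amp) {
  h <- nrow(mat); w <- ncol(mat)
  r <- ceiling(radius)
  c0 <- round(cx); r0 <- round(cy)
  cols <- max(0, c0 - r):min(w - 1, c0 + r)
  rows <- max(0, r0 - r):min(h - 1, r0 + r)
  if (length(cols) == 0 || length(rows) == 0) return(mat)
  inside <- outer((rows - cy)^2, (cols - cx)^2, `+`) <= radius^2
  sub <- mat[rows + 1, cols + 1]
  sub[inside] <- sub[inside] + amp
  mat[rows + 1, cols + 1] <- sub
  mat
}

# Set (not add) a disc region in an integer mask.
mask_disc <- function(mask, cx, cy, radius, value) {
  h <- nrow(mask); w <- ncol(mask)
  r <- ceiling(radius)
  c0 <- round(cx); r0 <- round(cy)
  cols <- max(0, c0 - r):min(w - 1, c0 + r)
  rows <- max(0, r0 - r):min(h - 1, r0 + r)
  if (length(cols) == 0 || length(rows) == 0) return(mask)
  inside <- outer((rows - cy)^2, (cols - cx)^2, `+`) <= radius^2
  sub <- mask[rows + 1, cols + 1]
  sub[inside] <- value
  mask[rows + 1, cols + 1] <- sub
  mask
}

#' Render a synthetic multichannel ROI image
#'
#' Draws the DAPI channel as Gaussian nuclear blobs at the cell centroids,
#' each marker channel as a cytoplasmic disc around the cells positive for
#' that marker (positive and negative intensities drawn from two overlapping
#' log-normal distributions, so threshold scoring is exercised with realistic
#' class overlap), a low autofluorescence baseline, and Gaussian read noise.
#' When \code{config$artifact_fraction > 0}, artifacts are planted and
#' recorded in the returned ground-truth quality mask: a zero-signal
#' background margin, locally blurred patches, and bright autofluorescent
#' blobs (emulating red blood cells / bubbles).
#'
#' @param cells Cell table from \code{\link{generate_roi_points}}.
#' @param config A \code{\link{sim_config}}.
#' @param seed Integer seed (defaults to a sub-seed of \code{config$seed}).
#' @return List with \code{image} (a \code{\link{multiplex_image}}),
#'   \code{mask} (ground-truth \code{quality_mask} matrix) and
#'   \code{intensity} (per cell x marker, the drawn raw amplitude).
#' @export
render_roi_image <- function(cells, config, seed = NULL) {
  validate_sim_config(config)
  h <- config$image_shape[1]
  w <- config$image_shape[2]
  if (nrow(cells) > 0 &&
      (any(cells$x < 0 | cells$x > w - 1) ||
       any(cells$y < 0 | cells$y > h - 1))) {
    stop("cell centroids must lie within the image bounds")
  }
  if (is.null(seed)) {
    rid <- if (nrow(cells) > 0) cells$roi_id[1] else 0L
    pid <- if (nrow(cells) > 0) cells$patient_id[1] else 0L
    seed <- derive_seed(config$seed, 11L, pid, rid)
  }
  set.seed(seed)

  n <- nrow(cells)
  planes <- lapply(CHANNELS, function(ch) matrix(0, h, w))
  names(planes) <- CHANNELS
  mask <- matrix(MASK_TISSUE, h, w)

  # nuclear and cytoplasmic geometry (pixels); the marker disc covers the
  # whole cell footprint (nucleus + 2 um expansion) with margin, so the
  # measured cytoplasm mean reflects the drawn amplitude
  nuc_sigma <- 2.2
  cyto_radius <- 9
  dapi_amp <- if (n > 0) pmax(stats::rnorm(n, 0.9, 0.08), 0.5) else numeric(0)

  # raw marker amplitudes: overlapping log-normals for positives/negatives
  amp <- matrix(0, nrow = n, ncol = length(MARKERS),
                dimnames = list(NULL, MARKERS))
  for (m in MARKERS) {
    pos <- as.logical(cells[[paste0("pos_", m)]])
    a <- numeric(n)
    a[pos] <- stats::rlnorm(sum(pos), meanlog = log(0.55), sdlog = 0.3)
    a[!pos] <- stats::rlnorm(sum(!pos), meanlog = log(0.02), sdlog = 0.35)
    amp[, m] <- a
  }

  for (i in seq_len(n)) {
    planes$DAPI <- paint_gauss(planes$DAPI, cells$x[i], cells$y[i],
                               nuc_sigma, dapi_amp[i])
    for (m in MARKERS) {
      planes[[m]] <- paint_disc(planes[[m]], cells$x[i], cells$y[i],
                                cyto_radius, amp[i, m])
    }
  }

  # autofluorescence baseline and read noise on every channel
  planes$AF <- planes$AF + 0.05
  for (ch in CHANNELS) {
    planes[[ch]] <- planes[[ch]] + matrix(stats::rnorm(h * w, 0, 0.02), h, w)
  }

  af <- config$artifact_fraction
  if (af > 0) {
    # zero-signal background margin on the left edge (~30% of the budget)
    mw <- round(0.3 * af * w)
    if (mw >= 1) {
      for (ch in CHANNELS) {
        planes[[ch]][, seq_len(mw)] <-
          matrix(stats::rnorm(h * mw, 0, 0.002), h, mw)
      }
      mask[, seq_len(mw)] <- MASK_BACKGROUND
    }
    # locally blurred patches (~20% of the budget); the blur kernel must
    # fit inside the patch
    patch <- max(32L, round(0.15 * min(h, w)))
    blur_sigma <- min(5, (patch - 1) / 7)
    n_patch <- max(0L, round(0.2 * af * h * w / patch^2))
    for (k in seq_len(n_patch)) {
      r0 <- sample.int(max(1L, h - patch), 1L)
      c0 <- sample.int(max(1L, w - patch), 1L)
      rows <- r0:(min(h, r0 + patch - 1))
      cols <- c0:(min(w, c0 + patch - 1))
      for (ch in CHANNELS) {
        planes[[ch]][rows, cols] <- ebi_gblur(planes[[ch]][rows, cols],
                                              sigma = blur_sigma)
      }
      mask[rows, cols] <- MASK_ARTIFACT
    }
    # bright autofluorescent blobs (~50% of the budget)
    rb <- max(8L, round(0.04 * min(h, w)))
    n_blob <- max(0L, round(0.5 * af * h * w / (pi * rb^2)))
    for (k in seq_len(n_blob)) {
      cx <- stats::runif(1, 0, w - 1)
      cy <- stats::runif(1, 0, h - 1)
      planes$AF <- paint_disc(planes$AF, cx, cy, rb, 0.9)
      mask <- mask_disc(mask, cx, cy, rb, MASK_ARTIFACT)
    }
  }

  px <- array(0, dim = c(h, w, length(CHANNELS)))
  for (ci in seq_along(CHANNELS)) px[, , ci] <- pmax(planes[[CHANNELS[ci]]], 0)
  list(image = multiplex_image(px, CHANNELS, config$pixel_size_um),
       mask = mask,
       intensity = amp)
}
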