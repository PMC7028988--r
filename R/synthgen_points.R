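#' Generate a synthetic ROI point pattern
#'
#' Places cells of each marker-combination class in one ROI. With
#' \code{colocalization_strength = 0} every cell is placed uniformly at
#' random over the field (complete spatial randomness). With positive
#' strength a parent-offspring (Thomas-like) process is used: a fraction
#' \code{1 - exp(-strength)} of CD8- or PD-1-carrying cells is placed within
#' \code{cluster_radius_um} of a randomly chosen PD-L1-carrying parent cell,
#' producing an excess of proximal pairs for the HID feature.
#'
#' @param config A \code{\link{sim_config}}.
#' @param patient_id,roi_id Identifiers stamped onto the rows (and mixed
#'   into the sub-seed, so every ROI is independently reproducible).
#' @param seed Integer seed; defaults to a sub-seed derived from
#'   \code{config$seed}, \code{patient_id} and \code{roi_id}.
#' @return List with \code{cells} (data.frame: cell_id, roi_id, patient_id,
#'   x, y, class, pos_CD8, pos_PD1, pos_PDL1, pos_CD68) and \code{truth}
#'   (the same centroids and class labels, as ground truth). Coordinates are
#'   0-based pixel positions, \code{x} the column.
#' @export
generate_roi_points <- function(config, patient_id = 1L, roi_id = 1L,
                                seed = NULL) {
  validate_sim_config(config)
  if (is.null(seed)) {
    seed <- derive_seed(config$seed, 7L, patient_id, roi_id)
  }
  h <- config$image_shape[1]
  w <- config$image_shape[2]
  dens <- config$class_densities
  if (sum(dens) > 0.25 * h * w) {
    stop("requested cell densities (", sum(dens),
         " expected cells) exceed what a ", h, "x", w,
         " pixel field can hold")
  }

  set.seed(seed)
  classes <- names(dens)
  n_per_class <- stats::rpois(length(dens), dens)
  names(n_per_class) <- classes
  n_total <- sum(n_per_class)

  cls <- rep(classes, n_per_class)
  flags <- class_marker_flags(classes)
  # uniform placement everywhere first
  x <- stats::runif(n_total, 0, w - 1)
  y <- stats::runif(n_total, 0, h - 1)

  p_clust <- 1 - exp(-config$colocalization_strength)
  if (p_clust > 0 && n_total > 0) {
    is_parent <- flags[cls, "PDL1"]
    is_offspring <- (flags[cls, "CD8"] | flags[cls, "PD1"]) & !is_parent
    parents <- which(is_parent)
    if (length(parents) > 0) {
      off <- which(is_offspring)
      move <- off[stats::runif(length(off)) < p_clust]
      if (length(move) > 0) {
        r_px <- config$cluster_radius_um / config$pixel_size_um
        par_idx <- parents[sample.int(length(parents), length(move),
                                      replace = TRUE)]
        # uniform in a disc around the parent, clipped to the field
        rr <- r_px * sqrt(stats::runif(length(move)))
        th <- stats::runif(length(move), 0, 2 * pi)
        x[move] <- pmin(pmax(x[par_idx] + rr * cos(th), 0), w - 1)
        y[move] <- pmin(pmax(y[par_idx] + rr * sin(th), 0), h - 1)
      }
    }
  }

  cells <- data.frame(
    cell_id = if (n_total > 0) seq_len(n_total) else integer(0),
    roi_id = rep(as.integer(roi_id), n_total),
    patient_id = rep(as.integer(patient_id), n_total),
    x = x, y = y,
    class = cls,
    stringsAsFactors = FALSE
  )
  for (m in MARKERS) {
    cells[[paste0("pos_", m)]] <- if (n_total > 0) unname(flags[cls, m]) else logical(0)
  }
  list(cells = cells,
       truth = cells[, c("cell_id", "x", "y", "class",
                         paste0("pos_", MARKERS))])
}
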