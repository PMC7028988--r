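# Per-cell, per-channel, per-compartment intensity statistics and the
# percentile rescaling + single-threshold scoring steps.

#' Measure per-cell compartment intensity statistics
#'
#' For every cell, channel and compartment (nucleus, cytoplasm) computes
#' mean, min, max and standard deviation of the member pixel intensities.
#' The sd convention is the population sd (divide by n). Cells with an
#' empty compartment get NA statistics there and are flagged.
#'
#' @param image A \code{\link{multiplex_image}}.
#' @param compartments Result of \code{\link{expand_cells}}.
#' @param centroids Centroid table from \code{\link{detect_nuclei}}.
#' @param roi_id,patient_id Identifiers stamped onto the rows.
#' @return Cell table: cell_id, roi_id, patient_id, x, y, area, then columns
#'   \code{<compartment>_<channel>_<stat>} (compartment in nuc/cyto), and
#'   \code{flag_empty_cytoplasm}.
#' @export
measure_intensities <- function(image, compartments, centroids,
                                roi_id = 1L, patient_id = 1L) {
  ids <- centroids$cell_id
  n <- length(ids)
  out <- data.frame(cell_id = ids,
                    roi_id = rep(as.integer(roi_id), n),
                    patient_id = rep(as.integer(patient_id), n),
                    x = centroids$x, y = centroids$y, area = centroids$area)
  comp_maps <- list(nuc = compartments$nucleus, cyto = compartments$cytoplasm)
  for (comp_name in names(comp_maps)) {
    lab_mat <- comp_maps[[comp_name]]
    idx <- which(lab_mat > 0)
    lab <- lab_mat[idx]
    for (ch in image$channel_names) {
      vals <- get_channel(image, ch)[idx]
      stats_df <- compartment_stats(vals, lab, ids)
      for (s in c("mean", "min", "max", "sd")) {
        out[[paste(comp_name, ch, s, sep = "_")]] <- stats_df[[s]]
      }
    }
  }
  out$flag_empty_cytoplasm <- is.na(out[[paste0("cyto_",
                                                image$channel_names[1],
                                                "_mean")]])
  out
}

# Grouped mean/min/max/population-sd for pixel values split by label.
compartment_stats <- function(vals, lab, ids) {
  res <- data.frame(mean = rep(NA_real_, length(ids)), min = NA_real_,
                    max = NA_real_, sd = NA_real_)
  if (length(vals) == 0) return(res)
  cnt <- as.vector(rowsum(rep(1, length(lab)), lab))
  sums <- as.vector(rowsum(vals, lab))
  sq <- as.vector(rowsum(vals^2, lab))
  present <- sort(unique(lab))
  m <- sums / cnt
  v <- pmax(sq / cnt - m^2, 0)
  mins <- vapply(split(vals, lab), min, numeric(1))
  maxs <- vapply(split(vals, lab), max, numeric(1))
  pos <- match(present, ids)
  ok <- !is.na(pos)
  res$mean[pos[ok]] <- m[ok]
  res$sd[pos[ok]] <- sqrt(v[ok])
  res$min[pos[ok]] <- mins[ok]
  res$max[pos[ok]] <- maxs[ok]
  res
}

#' Fit per-marker rescaling bounds
#'
#' The bounds are the 1st and 99th empirical percentiles
#' (linear-interpolation definition) of each marker's pixel intensities over
#' the entire analysis set, so the same intensity maps to the same rescaled
#' value in every image.
#'
#' @param marker_pixels Named list: marker -> numeric vector of pixel
#'   intensities pooled over all included ROIs (>= 100 pixels each).
#' @param probs Lower/upper percentile probabilities (default 0.01, 0.99).
#' @return data.frame (marker, low, high) of class \code{rescale_bounds}.
#' @export
fit_rescale <- function(marker_pixels, probs = c(0.01, 0.99)) {
  rows <- lapply(names(marker_pixels), function(m) {
    v <- marker_pixels[[m]]
    if (length(v) < 100) {
      stop("marker ", m, ": need >= 100 pixels to fit rescale bounds")
    }
    q <- stats::quantile(v, probs = probs, names = FALSE, type = 7)
    if (q[1] >= q[2]) {
      stop("degenerate rescale bounds for marker ", m,
           " (low == high): intensities are constant")
    }
    data.frame(marker = m, low = q[1], high = q[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rescale_bounds", class(out))
  out
}

#' Apply rescaling bounds
#'
#' Linear map low -> 0, high -> 1, clipped to [0, 1] outside.
#'
#' @param value Numeric vector of raw intensities.
#' @param bounds A \code{rescale_bounds} table (or one of its rows).
#' @param marker Marker name selecting the row of \code{bounds}.
#' @return Rescaled values in [0, 1].
#' @export
apply_rescale <- function(value, bounds, marker) {
  row <- bounds[bounds$marker == marker, ]
  if (nrow(row) != 1) stop("no rescale bounds for marker ", marker)
  pmin(pmax((value - row$low) / (row$high - row$low), 0), 1)
}

#' Score marker positivity with a single threshold per marker
#'
#' A cell is positive for a marker when the rescaled mean intensity in the
#' marker's primary compartment (cytoplasm/membrane for CD8, PD-1, PD-L1,
#' CD68; configurable) is at or above the marker's threshold. A value
#' exactly at the threshold scores positive. Cells with missing compartment
#' statistics are left NA for that marker and flagged.
#'
#' @param cells Cell table from \code{\link{measure_intensities}}.
#' @param bounds \code{rescale_bounds} from \code{\link{fit_rescale}}.
#' @param thresholds Named numeric vector, marker -> threshold on the
#'   rescaled [0, 1] scale.
#' @param compartment Named character vector, marker -> primary compartment
#'   (\code{"cyto"} or \code{"nuc"}); default cytoplasm for every marker.
#' @return \code{cells} with added columns \code{rescaled_<marker>} and
#'   logical \code{pos_<marker>}.
#' @export
score_positivity <- function(cells, bounds, thresholds,
                             compartment = NULL) {
  markers <- names(thresholds)
  if (is.null(compartment)) {
    compartment <- stats::setNames(rep("cyto", length(markers)), markers)
  }
  if (any(thresholds < 0 | thresholds > 1)) {
    stop("thresholds must lie in [0, 1] (rescaled scale)")
  }
  for (m in markers) {
    col <- paste(compartment[[m]], m, "mean", sep = "_")
    if (!col %in% names(cells)) {
      stop("cell table lacks intensity column ", col)
    }
    resc <- apply_rescale(cells[[col]], bounds, m)
    cells[[paste0("rescaled_", m)]] <- resc
    cells[[paste0("pos_", m)]] <- resc >= thresholds[[m]]
  }
  cells
}

#' Assign analysis phenotype memberships from marker flags
#'
#' Adds one logical membership column per analysis phenotype (a cell may
#' belong to several sets: any PD-1 flagged cell is a member of PD-1+, and
#' of CD8+PD-1+ when also CD8 flagged) plus a readable \code{phenotypes}
#' summary column.
#'
#' @param cells Cell table with \code{pos_<marker>} columns.
#' @return \code{cells} with \code{member_<phenotype>} columns and a
#'   \code{phenotypes} character column (";"-separated labels).
#' @export
assign_phenotypes <- function(cells) {
  member <- matrix(FALSE, nrow = nrow(cells), ncol = length(PHENOTYPES),
                   dimnames = list(NULL, names(PHENOTYPES)))
  for (ph in names(PHENOTYPES)) {
    member[, ph] <- phenotype_members(cells, ph)
  }
  for (ph in names(PHENOTYPES)) {
    cells[[paste0("member_", gsub("[+-]", "", ph))]] <- member[, ph]
  }
  cells$phenotypes <- apply(member, 1, function(r) {
    paste(names(PHENOTYPES)[r], collapse = ";")
  })
  cells
}

#' Match detected centroids against ground truth
#'
#' Greedy nearest-first one-to-one matching within a radius; reports
#' precision, recall and F1. Used to validate nuclear detection against the
#' generator's planted centroids.
#'
#' @param detected,truth data.frames with \code{x}, \code{y} columns.
#' @param radius_px Maximum match distance in pixels (default 3).
#' @return List: n_detected, n_truth, n_matched, precision, recall, f1,
#'   and \code{matches} (index pairs).
#' @export
match_centroids <- function(detected, truth, radius_px = 3) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0) {
    return(list(n_detected = nd, n_truth = nt, n_matched = 0L,
                precision = if (nd == 0) NA_real_ else 0,
                recall = if (nt == 0) NA_real_ else 0, f1 = 0,
                matches = matrix(integer(0), ncol = 2)))
  }
  dmat <- outer(detected$x, truth$x, `-`)^2 + outer(detected$y, truth$y, `-`)^2
  cand <- which(dmat <= radius_px^2, arr.ind = TRUE)
  ord <- order(dmat[cand])
  used_d <- logical(nd); used_t <- logical(nt)
  matches <- list()
  for (k in ord) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_d[i] && !used_t[j]) {
      used_d[i] <- TRUE; used_t[j] <- TRUE
      matches[[length(matches) + 1]] <- c(i, j)
    }
  }
  nm <- length(matches)
  precision <- nm / nd
  recall <- nm / nt
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(n_detected = nd, n_truth = nt, n_matched = nm,
       precision = precision, recall = recall, f1 = f1,
       matches = if (nm > 0) do.call(rbind, matches)
                 else matrix(integer(0), ncol = 2))
}
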