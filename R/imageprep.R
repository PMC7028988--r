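# Pixel-level quality classification and the ROI inclusion gate.
#
# Every pixel of an ROI is labelled background / tissue / artifact. ROIs
# with less than 30% useful tissue are excluded, and only cells whose
# centroid falls in useful tissue are analysed. The classifier is a plain
# function of the image, so a learned model can be slotted in anywhere a
# (image -> mask) function is accepted.

#' Rule-based pixel quality classifier
#'
#' Labels each pixel background, tissue or artifact:
#' \itemize{
#'   \item background: smoothed total signal (all channels) below
#'     \code{bg_threshold};
#'   \item artifact: smoothed autofluorescence above \code{af_threshold}
#'     (bright blobs: red blood cells, bubbles), or local sharpness --- the
#'     locally averaged squared high-pass response of the DAPI channel ---
#'     below \code{blur_threshold} inside otherwise-signalled regions
#'     (out-of-focus patches);
#'   \item tissue: everything else.
#' }
#' Regions of background or artifact smaller than \code{min_region_px}
#' pixels are reabsorbed into tissue (speckle removal).
#'
#' @param image A \code{\link{multiplex_image}} (or H x W x C array with
#'   the standard channel order).
#' @param params Named list overriding any of: \code{bg_threshold} (0.05),
#'   \code{af_threshold} (0.4), \code{blur_threshold} (1e-4),
#'   \code{smooth_sigma} (4), \code{sharp_sigma} (8),
#'   \code{min_region_px} (64). Defaults are calibrated on the synthetic
#'   generator's rendering model.
#' @return Integer H x W matrix with values 0 (background), 1 (tissue),
#'   2 (artifact).
#' @export
classify_tissue <- function(image, params = list()) {
  p <- utils::modifyList(list(bg_threshold = 0.05, af_threshold = 0.4,
                              blur_threshold = 1e-4, smooth_sigma = 4,
                              sharp_sigma = 8, min_region_px = 64), params)
  px <- if (inherits(image, "multiplex_image")) image$pixels else image
  chn <- if (inherits(image, "multiplex_image")) image$channel_names
         else CHANNELS
  h <- dim(px)[1]; w <- dim(px)[2]

  total <- apply(px, c(1, 2), sum)
  total_sm <- ebi_gblur(total, p$smooth_sigma)
  background <- total_sm < p$bg_threshold

  af_idx <- match("AF", chn)
  artifact <- matrix(FALSE, h, w)
  if (!is.na(af_idx)) {
    af_sm <- ebi_gblur(px[, , af_idx], p$smooth_sigma)
    artifact <- af_sm > p$af_threshold
  }
  dapi_idx <- match("DAPI", chn)
  if (!is.na(dapi_idx)) {
    dapi <- px[, , dapi_idx]
    hp <- dapi - ebi_gblur(dapi, 2)
    energy <- ebi_gblur(hp^2, p$sharp_sigma)
    artifact <- artifact | (energy < p$blur_threshold & !background)
  }

  mask <- matrix(MASK_TISSUE, h, w)
  mask[background] <- MASK_BACKGROUND
  mask[artifact & !background] <- MASK_ARTIFACT
  drop_small_regions(mask, p$min_region_px)
}

# Reabsorb background/artifact components below min_px into tissue.
drop_small_regions <- function(mask, min_px) {
  if (min_px <= 1) return(mask)
  for (lab in c(MASK_BACKGROUND, MASK_ARTIFACT)) {
    bin <- mask == lab
    if (!any(bin)) next
    cc <- EBImage::bwlabel(EBImage::Image(bin * 1))
    sizes <- tabulate(as.integer(EBImage::imageData(cc)))
    small <- which(sizes < min_px)
    if (length(small) > 0) {
      mask[EBImage::imageData(cc) %in% small] <- MASK_TISSUE
    }
  }
  mask
}

#' Pixel-wise accuracy of a predicted quality mask
#'
#' @param predicted,truth Integer label matrices of identical shape.
#' @return Fraction of pixels with identical labels, in [0, 1].
#' @export
evaluate_mask <- function(predicted, truth) {
  if (!all(dim(predicted) == dim(truth))) {
    stop("mask shapes differ: ", paste(dim(predicted), collapse = "x"),
         " vs ", paste(dim(truth), collapse = "x"))
  }
  mean(predicted == truth)
}

#' Fraction of useful tissue in a quality mask
#'
#' @param mask Integer label matrix.
#' @return (# tissue pixels) / (# all pixels). The denominator is all
#'   pixels, including background.
#' @export
useful_tissue_fraction <- function(mask) {
  mean(mask == MASK_TISSUE)
}

#' ROI inclusion gate
#'
#' An ROI is excluded when its useful-tissue fraction is strictly below the
#' threshold (default 30%); a fraction exactly at the threshold is included.
#'
#' @param masks Named list of quality masks (or a numeric vector of
#'   useful-tissue fractions, named by ROI id).
#' @param threshold Minimum useful-tissue fraction, in [0, 1].
#' @return data.frame with roi_id, useful_fraction, included.
#' @export
filter_rois <- function(masks, threshold = 0.30) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  fr <- if (is.numeric(masks)) masks
        else vapply(masks, useful_tissue_fraction, numeric(1))
  ids <- names(fr)
  if (is.null(ids)) ids <- as.character(seq_along(fr))
  data.frame(roi_id = ids,
             useful_fraction = unname(fr),
             included = unname(fr) >= threshold,
             stringsAsFactors = FALSE)
}

#' Keep only cells whose centroid lies in useful tissue
#'
#' The centroid is looked up at the nearest pixel (rounded coordinates).
#'
#' @param cells Cell table with 0-based \code{x}, \code{y} centroid columns.
#' @param mask Quality mask matrix of the cells' ROI.
#' @return The subset of \code{cells} whose centroid pixel is labelled
#'   tissue.
#' @export
filter_cells_by_mask <- function(cells, mask) {
  if (nrow(cells) == 0) return(cells)
  col <- round(cells$x) + 1
  row <- round(cells$y) + 1
  bad <- col < 1 | col > ncol(mask) | row < 1 | row > nrow(mask)
  if (any(bad)) {
    stop("cell centroid out of image bounds: cell_id ",
         paste(cells$cell_id[bad], collapse = ", "))
  }
  keep <- mask[cbind(row, col)] == MASK_TISSUE
  cells[keep, , drop = FALSE]
}
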