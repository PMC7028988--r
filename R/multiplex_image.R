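#' Multiplex image container
#'
#' A multichannel ROI image: an H x W x C array of nonnegative intensities,
#' ordered channel names, and the physical pixel size.
#'
#' @param pixels Numeric H x W x C array (rows = y, columns = x).
#' @param channel_names Character vector of length C.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @return An object of class \code{multiplex_image}.
#' @export
multiplex_image <- function(pixels, channel_names, pixel_size_um) {
  if (length(dim(pixels)) != 3) stop("pixels must be an H x W x C array")
  if (dim(pixels)[3] != length(channel_names)) {
    stop("number of channels (", dim(pixels)[3],
         ") does not match channel_names (", length(channel_names), ")")
  }
  if (any(!is.finite(pixels))) stop("pixel intensities must be finite")
  if (any(pixels < 0)) stop("pixel intensities must be >= 0")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  structure(list(pixels = pixels,
                 channel_names = as.character(channel_names),
                 pixel_size_um = pixel_size_um),
            class = "multiplex_image")
}

#' Extract one channel as a matrix
#' @param image A \code{multiplex_image}.
#' @param channel Channel name.
#' @return H x W numeric matrix.
#' @export
get_channel <- function(image, channel) {
  idx <- match(channel, image$channel_names)
  if (is.na(idx)) stop("no channel named ", channel)
  image$pixels[, , idx]
}

#' @export
print.multiplex_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat("multiplex_image: ", d[1], " x ", d[2], " px, ", d[3], " channels (",
      paste(x$channel_names, collapse = ", "), "), ",
      x$pixel_size_um, " um/px\n", sep = "")
  invisible(x)
}

# Isotropic Gaussian blur of a plain matrix via EBImage.
ebi_gblur <- function(mat, sigma) {
  EBImage::imageData(EBImage::gblur(EBImage::Image(mat), sigma = sigma))
}
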