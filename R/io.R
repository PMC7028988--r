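# File I/O: multi-page TIFF images (one page per channel, channel names in
# a sidecar), label/mask TIFFs, cell/cohort CSV tables, YAML configs.

#' Write a multiplex image as a multi-page TIFF
#'
#' One 32-bit float page per channel. Intensities are divided by a stored
#' scale factor so they fit the writer's [0, 1] range. Channel names, the
#' pixel size and the scale live in a plain-text sidecar
#' \code{<path>.channels.txt} (\code{pixel_size_um=<v>}, \code{scale=<v>},
#' then one channel name per line).
#'
#' @param image A \code{\link{multiplex_image}}.
#' @param path Output .tif path.
#' @export
write_multiplex_tiff <- function(image, path) {
  scale <- max(1, max(image$pixels))
  planes <- lapply(seq_along(image$channel_names),
                   function(i) image$pixels[, , i] / scale)
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, reduce = FALSE)
  writeLines(c(paste0("pixel_size_um=", format(image$pixel_size_um,
                                               digits = 17)),
               paste0("scale=", format(scale, digits = 17)),
               image$channel_names),
             paste0(path, ".channels.txt"))
  invisible(path)
}

#' Read a multiplex image written by \code{\link{write_multiplex_tiff}}
#'
#' @param path .tif path (expects the \code{.channels.txt} sidecar).
#' @return A \code{\link{multiplex_image}}.
#' @export
read_multiplex_tiff <- function(path) {
  planes <- tiff::readTIFF(path, all = TRUE)
  meta <- readLines(paste0(path, ".channels.txt"))
  pixel_size_um <- as.numeric(sub("^pixel_size_um=", "", meta[1]))
  scale <- as.numeric(sub("^scale=", "", meta[2]))
  channel_names <- meta[-(1:2)]
  px <- array(0, dim = c(nrow(planes[[1]]), ncol(planes[[1]]),
                         length(planes)))
  for (i in seq_along(planes)) px[, , i] <- planes[[i]] * scale
  multiplex_image(px, channel_names, pixel_size_um)
}

#' Write a quality/label mask as an 8-bit TIFF
#' @param mask Integer matrix with values 0-255.
#' @param path Output path.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a mask written by \code{\link{write_mask_tiff}}
#' @param path Input path.
#' @return Integer matrix.
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  storage.mode(m) <- "double"
  mi <- round(m * 255)
  storage.mode(mi) <- "integer"
  mi
}

#' Write a cell or cohort table as CSV
#' @param df data.frame.
#' @param path Output path.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a CSV table
#' @param path Input path.
#' @return data.frame.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
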