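#' Linear spectral unmixing by nonnegative least squares
#'
#' Decomposes a raw multispectral image into per-fluorophore abundance
#' channels using a spectral library (one column per fluorophore, including
#' tissue autofluorescence). Each pixel's spectrum is modelled as
#' \code{raw = library \%*\% abundances} with abundances constrained to be
#' nonnegative (abundances are physical concentrations).
#'
#' Implementation: the unconstrained least-squares solution is computed for
#' all pixels in one matrix operation; pixels whose solution violates the
#' nonnegativity constraint are re-solved exactly with the Lawson-Hanson
#' active-set algorithm.
#'
#' @param raw H x W x B array of raw band intensities, B >= number of
#'   fluorophores.
#' @param library B x F nonnegative matrix of reference emission spectra,
#'   with column names naming the fluorophores; columns must be linearly
#'   independent.
#' @param pixel_size_um Pixel size propagated to the result.
#' @return A \code{\link{multiplex_image}} whose channels are the abundance
#'   planes, named after the library columns.
#' @export
unmix <- function(raw, library, pixel_size_um = 0.495) {
  if (length(dim(raw)) != 3) stop("raw must be an H x W x B array")
  B <- dim(raw)[3]
  if (nrow(library) != B) {
    stop("library has ", nrow(library), " bands but raw image has ", B)
  }
  if (any(library < 0)) stop("library spectra must be nonnegative")
  zero_col <- colSums(abs(library)) == 0
  if (any(zero_col)) {
    stop("all-zero library column(s): ",
         paste(colnames(library)[zero_col], collapse = ", "))
  }
  qrL <- qr(library)
  if (qrL$rank < ncol(library)) {
    dropped <- colnames(library)[qrL$pivot[(qrL$rank + 1):ncol(library)]]
    stop("spectral library is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  if (is.null(colnames(library))) {
    colnames(library) <- paste0("F", seq_len(ncol(library)))
  }

  h <- dim(raw)[1]; w <- dim(raw)[2]; f <- ncol(library)
  Y <- matrix(raw, nrow = h * w, ncol = B)  # pixels x bands
  # unconstrained LS for every pixel at once: solve (L'L) A = L' Y'
  A <- t(solve(crossprod(library), crossprod(library, t(Y))))
  neg <- which(apply(A, 1, function(r) any(r < -1e-10)))
  for (p in neg) {
    A[p, ] <- pracma::lsqnonneg(library, Y[p, ])$x
  }
  A[A < 0] <- 0
  px <- array(A, dim = c(h, w, f))
  multiplex_image(px, colnames(library), pixel_size_um)
}

#' Mix abundance planes through a spectral library (forward model)
#'
#' Utility for building simulated raw multispectral stacks:
#' \code{raw[p] = library \%*\% abundances[p]} per pixel.
#'
#' @param abundances H x W x F array.
#' @param library B x F spectral library.
#' @return H x W x B array.
#' @export
spectral_mix <- function(abundances, library) {
  h <- dim(abundances)[1]; w <- dim(abundances)[2]
  A <- matrix(abundances, nrow = h * w)
  Y <- A %*% t(library)
  array(Y, dim = c(h, w, nrow(library)))
}
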