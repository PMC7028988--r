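#' Convert a distance in micrometres to pixels
#'
#' @param d_um Distance in micrometres.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @return Real-valued distance in pixels (no rounding).
#' @export
microns_to_pixels <- function(d_um, pixel_size_um) {
  if (any(d_um <= 0)) stop("d_um must be positive")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  d_um / pixel_size_um
}

#' Normalise an interaction count by the total cell count
#'
#' @param H Nonnegative interaction count.
#' @param N Total number of cells in the sample, regardless of phenotype.
#' @return h = H / N.
#' @export
hid_normalize <- function(H, N) {
  if (N <= 0) stop("N must be positive: an ROI with no cells cannot ",
                   "contribute an HID value")
  H / N
}

#' Hypothesised Interaction Distribution (HID) count for one ROI
#'
#' Counts the number H(i, j) of unordered pairs of distinct cells (k, l)
#' with k of phenotype i and l of phenotype j whose centroid Euclidean
#' distance is strictly less than d, then normalises by the total number N
#' of cells regardless of phenotype: h(i, j) = H(i, j) / N.
#'
#' A cell belonging to both phenotype sets (e.g. a PD-1+PD-L1+ cell when i
#' and j are PD-1+ and PD-L1+) can pair with any other qualifying cell but
#' never with itself; each unordered pair is counted once, so
#' H(i, j) = H(j, i).
#'
#' The default implementation bins cells on a grid of cell size d (a spatial
#' index) and only examines neighbouring bins; \code{method = "loop"} runs
#' the plain all-pairs enumeration. Both are exact and return identical
#' counts.
#'
#' @param cells Cell table with columns \code{x}, \code{y} (pixel
#'   coordinates) and marker flag columns \code{pos_<marker>}.
#' @param phenotype_i,phenotype_j Phenotype labels from
#'   \code{\link{phenotype_vocabulary}}.
#' @param d_um Proximity radius in micrometres (default 30, a neighbourhood
#'   of 2-3 cell diameters).
#' @param pixel_size_um Micrometres per pixel used to convert \code{d_um}
#'   into pixel units; distances are computed in pixel space with no
#'   rounding of d.
#' @param pairs If TRUE, also return the list of interacting cell-id pairs
#'   (for drawing interaction overlays).
#' @param method \code{"index"} (grid spatial index, default) or
#'   \code{"loop"} (plain O(n^2) enumeration).
#' @return List of class \code{hid_result}: \code{phenotype_i},
#'   \code{phenotype_j}, \code{d_um}, \code{H}, \code{N}, \code{h}, and
#'   optionally \code{pairs} (two-column matrix of cell ids).
#' @export
hid_count <- function(cells, phenotype_i, phenotype_j, d_um = 30,
                      pixel_size_um = 0.495, pairs = FALSE,
                      method = c("index", "loop")) {
  method <- match.arg(method)
  d_px <- microns_to_pixels(d_um, pixel_size_um)
  N <- nrow(cells)
  mi <- phenotype_members(cells, phenotype_i)
  mj <- phenotype_members(cells, phenotype_j)

  rel <- which(mi | mj)
  res <- if (length(rel) < 2) {
    list(H = 0L, pairs = matrix(integer(0), ncol = 2))
  } else {
    x <- cells$x[rel]; y <- cells$y[rel]
    a <- mi[rel]; b <- mj[rel]
    if (method == "loop") {
      hid_pairs_loop(x, y, a, b, d_px, pairs)
    } else {
      hid_pairs_grid(x, y, a, b, d_px, pairs)
    }
  }
  out <- list(phenotype_i = phenotype_i, phenotype_j = phenotype_j,
              d_um = d_um, pixel_size_um = pixel_size_um,
              H = res$H, N = N,
              h = if (N > 0) res$H / N else NA_real_)
  if (pairs) {
    pr <- res$pairs
    if (nrow(pr) > 0) {
      pr <- cbind(cells$cell_id[rel[pr[, 1]]], cells$cell_id[rel[pr[, 2]]])
    }
    colnames(pr) <- c("cell_i", "cell_j")
    out$pairs <- pr
  }
  class(out) <- "hid_result"
  out
}

#' @export
print.hid_result <- function(x, ...) {
  cat("HID ", x$phenotype_i, " ~ ", x$phenotype_j, " within ", x$d_um,
      " um: H = ", x$H, ", N = ", x$N, ", h = ", format(x$h), "\n", sep = "")
  invisible(x)
}

# Qualification rule for an unordered pair (p, q):
# (p in Ci and q in Cj) or (p in Cj and q in Ci).
hid_pairs_loop <- function(x, y, a, b, d_px, keep_pairs) {
  n <- length(x)
  d2 <- d_px^2
  H <- 0L
  pr <- if (keep_pairs) list() else NULL
  for (p in seq_len(n - 1)) {
    q <- (p + 1):n
    close <- (x[q] - x[p])^2 + (y[q] - y[p])^2 < d2
    qual <- close & ((a[p] & b[q]) | (b[p] & a[q]))
    H <- H + sum(qual)
    if (keep_pairs && any(qual)) {
      pr[[length(pr) + 1]] <- cbind(p, q[qual])
    }
  }
  list(H = as.integer(H),
       pairs = if (keep_pairs && length(pr) > 0) do.call(rbind, pr)
               else matrix(integer(0), ncol = 2))
}

# Grid spatial index: bin side = d, examine the half-neighbourhood of each
# occupied bin so each unordered pair is visited exactly once.
hid_pairs_grid <- function(x, y, a, b, d_px, keep_pairs) {
  n <- length(x)
  d2 <- d_px^2
  bx <- floor(x / d_px); by <- floor(y / d_px)
  key <- paste(bx, by)
  bins <- split(seq_len(n), key)
  bin_xy <- do.call(rbind, lapply(strsplit(names(bins), " ", fixed = TRUE),
                                  as.numeric))
  lookup <- stats::setNames(seq_along(bins), names(bins))
  # offsets covering each neighbouring bin pair once
  offs <- rbind(c(1, -1), c(1, 0), c(1, 1), c(0, 1))
  H <- 0L
  pr <- if (keep_pairs) list() else NULL

  add_pairs <- function(p_idx, q_idx, same_bin) {
    if (same_bin) {
      m <- length(p_idx)
      if (m < 2) return(NULL)
      cmb <- utils::combn(p_idx, 2)
      ps <- cmb[1, ]; qs <- cmb[2, ]
    } else {
      if (length(p_idx) == 0 || length(q_idx) == 0) return(NULL)
      g <- expand.grid(p = p_idx, q = q_idx)
      ps <- g$p; qs <- g$q
    }
    close <- (x[ps] - x[qs])^2 + (y[ps] - y[qs])^2 < d2
    qual <- close & ((a[ps] & b[qs]) | (b[ps] & a[qs]))
    H <<- H + sum(qual)
    if (keep_pairs && any(qual)) {
      pr[[length(pr) + 1]] <<- cbind(pmin(ps[qual], qs[qual]),
                                     pmax(ps[qual], qs[qual]))
    }
    NULL
  }

  for (bi in seq_along(bins)) {
    idx <- bins[[bi]]
    add_pairs(idx, NULL, same_bin = TRUE)
    for (oi in seq_len(nrow(offs))) {
      nb_key <- paste(bin_xy[bi, 1] + offs[oi, 1],
                      bin_xy[bi, 2] + offs[oi, 2])
      nb <- lookup[nb_key]
      if (!is.na(nb)) add_pairs(idx, bins[[nb]], same_bin = FALSE)
    }
  }
  list(H = as.integer(H),
       pairs = if (keep_pairs && length(pr) > 0) do.call(rbind, pr)
               else matrix(integer(0), ncol = 2))
}

#' Aggregate per-ROI HID values to a patient-level scalar
#'
#' @param roi_results Either a list of \code{hid_result} objects or a
#'   data.frame with columns \code{H}, \code{N}, \code{h} (one row per
#'   included ROI of one patient).
#' @param aggregator \code{"median"} (default, parallel to the per-patient
#'   median used for cell densities), \code{"mean"}, or \code{"pooled"}
#'   (sum of H over ROIs divided by sum of N).
#' @return Patient-level scalar HID feature.
#' @export
patient_hid <- function(roi_results,
                        aggregator = c("median", "mean", "pooled")) {
  aggregator <- match.arg(aggregator)
  if (is.data.frame(roi_results)) {
    df <- roi_results
  } else {
    df <- do.call(rbind, lapply(roi_results, function(r)
      data.frame(H = r$H, N = r$N, h = r$h)))
  }
  if (is.null(df) || nrow(df) == 0) {
    stop("patient has no included ROIs; flag as missing and exclude")
  }
  switch(aggregator,
         median = stats::median(df$h),
         mean = mean(df$h),
         pooled = hid_normalize(sum(df$H), sum(df$N)))
}

#' HID over a sweep of proximity radii
#'
#' @inheritParams hid_count
#' @param d_um_grid Vector of radii (um).
#' @return data.frame with one row per radius (d_um, H, N, h).
#' @export
hid_sweep <- function(cells, phenotype_i, phenotype_j, d_um_grid,
                      pixel_size_um = 0.495) {
  do.call(rbind, lapply(d_um_grid, function(d) {
    r <- hid_count(cells, phenotype_i, phenotype_j, d_um = d,
                   pixel_size_um = pixel_size_um)
    data.frame(d_um = d, H = r$H, N = r$N, h = r$h)
  }))
}
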