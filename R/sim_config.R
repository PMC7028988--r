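#' Simulation configuration
#'
#' Builds the configuration object for the synthetic-data generator. The
#' defaults emulate the study conditions of a mid-size oropharyngeal cancer
#' multiplex-immunofluorescence cohort: 72 patients, 10-20 ROIs per patient,
#' 1392x1040 px fields at 0.495 um/px, and per-ROI phenotype abundances
#' consistent with reported median population fractions (roughly 6.6% CD8+,
#' 1.5% CD8+PD-1+, 3.1% CD68+, 1.1% CD68+PD-L1+, 9% PD-L1+, 12.7% PD-1+ of
#' ~300 cells per ROI).
#'
#' Cell classes are exclusive marker combinations (a \code{CD8_PD1} cell
#' carries both the CD8 and PD-1 flags); analysis phenotypes are derived
#' from the flags downstream.
#'
#' @param n_patients Number of patients in a simulated cohort.
#' @param rois_per_patient Integer range \code{c(min, max)}; the per-patient
#'   ROI count is drawn uniformly from it.
#' @param image_shape \code{c(height, width)} of a rendered ROI, in pixels.
#' @param pixel_size_um Physical pixel size in micrometres per pixel.
#' @param class_densities Named numeric vector: expected cells per ROI for
#'   each exclusive marker-combination class. Class names are marker symbols
#'   joined by \code{_}; \code{NEG} is the marker-negative class.
#' @param colocalization_strength Nonnegative scalar controlling how strongly
#'   CD8/PD-1 cells cluster around PD-L1+ cells. 0 means independent
#'   (complete spatial randomness); the fraction of offspring cells placed
#'   near a parent is \code{1 - exp(-strength)}.
#' @param cluster_radius_um Radius (um) of the parent-offspring placement
#'   disc used when clustering.
#' @param planted_log_hr Planted log hazard ratio for the high-vs-low HID
#'   patient group.
#' @param effect_stratum Which patients the planted HID effect applies to:
#'   \code{"all"}, \code{"hpv_negative"} or \code{"hpv_positive"}.
#' @param hpv_log_hr Log hazard ratio for HPV-negative vs HPV-positive
#'   disease (HPV-negative tumours carry the worse prognosis; default
#'   log(3.3)).
#' @param baseline_hazard Baseline event rate, events per month, for an
#'   HPV-positive low-HID patient.
#' @param censoring_rate Expected fraction of patients censored, in [0, 1].
#' @param hpv_positive_fraction Fraction of simulated patients that are
#'   HPV-positive.
#' @param artifact_fraction Fraction of rendered image area occupied by
#'   planted artifacts and background margins, in [0, 1].
#' @param hid_pair Character pair \code{c(i, j)} of analysis phenotypes used
#'   as the cohort's HID feature.
#' @param d_um HID proximity radius in micrometres.
#' @param marker_threshold Design positivity threshold on the raw amplitude
#'   scale of the rendered marker channels; the generator draws
#'   positive/negative cell amplitudes from two overlapping log-normal
#'   distributions (meanlog log 0.55 / log 0.02, sdlog 0.3 / 0.35) that this
#'   value separates with a small, deliberate error rate. The equivalent
#'   per-marker threshold on the rescaled [0, 1] scale is
#'   \code{apply_rescale(marker_threshold, bounds, marker)} once the
#'   dataset's rescale bounds are fitted.
#' @param seed Integer master seed; all randomness derives from it.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_patients = 72,
                       rois_per_patient = c(10L, 20L),
                       image_shape = c(1040L, 1392L),
                       pixel_size_um = 0.495,
                       class_densities = c(CD8 = 15, CD8_PD1 = 5,
                                           CD68 = 6, CD68_PDL1 = 3,
                                           PDL1 = 24, PD1 = 33, NEG = 214),
                       colocalization_strength = 1,
                       cluster_radius_um = 15,
                       planted_log_hr = log(3),
                       effect_stratum = c("hpv_negative", "all",
                                          "hpv_positive"),
                       hpv_log_hr = log(3.3),
                       baseline_hazard = 0.004,
                       censoring_rate = 0.4,
                       hpv_positive_fraction = 0.5,
                       artifact_fraction = 0.1,
                       hid_pair = c("PD-1+", "PD-L1+"),
                       d_um = 30,
                       marker_threshold = 0.15,
                       seed = 1L) {
  effect_stratum <- match.arg(effect_stratum)
  cfg <- list(
    n_patients = as.integer(n_patients),
    rois_per_patient = as.integer(rois_per_patient),
    image_shape = as.integer(image_shape),
    pixel_size_um = pixel_size_um,
    class_densities = class_densities,
    colocalization_strength = colocalization_strength,
    cluster_radius_um = cluster_radius_um,
    planted_log_hr = planted_log_hr,
    effect_stratum = effect_stratum,
    hpv_log_hr = hpv_log_hr,
    baseline_hazard = baseline_hazard,
    censoring_rate = censoring_rate,
    hpv_positive_fraction = hpv_positive_fraction,
    artifact_fraction = artifact_fraction,
    hid_pair = hid_pair,
    d_um = d_um,
    marker_threshold = marker_threshold,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_patients < 1) stop("n_patients must be >= 1")
  if (length(cfg$rois_per_patient) != 2 ||
      any(cfg$rois_per_patient < 1) ||
      cfg$rois_per_patient[1] > cfg$rois_per_patient[2]) {
    stop("rois_per_patient must be an increasing positive integer range")
  }
  if (length(cfg$image_shape) != 2 || any(cfg$image_shape <= 0)) {
    stop("image_shape must be two positive integers (height, width)")
  }
  if (cfg$pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (any(cfg$class_densities < 0)) stop("class densities must be >= 0")
  if (is.null(names(cfg$class_densities)) ||
      any(!nzchar(names(cfg$class_densities)))) {
    stop("class_densities must be a named vector")
  }
  for (fr in c("censoring_rate", "hpv_positive_fraction",
               "artifact_fraction")) {
    v <- cfg[[fr]]
    if (v < 0 || v > 1) stop(fr, " must lie in [0, 1]")
  }
  if (cfg$colocalization_strength < 0) {
    stop("colocalization_strength must be >= 0")
  }
  if (cfg$cluster_radius_um <= 0) stop("cluster_radius_um must be positive")
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (cfg$d_um <= 0) stop("d_um must be positive")
  if (cfg$marker_threshold <= 0) stop("marker_threshold must be positive")
  bad <- setdiff(cfg$hid_pair, names(PHENOTYPES))
  if (length(bad) > 0) stop("unknown phenotype in hid_pair: ",
                            paste(bad, collapse = ", "))
  invisible(cfg)
}

# Marker flags carried by each exclusive simulation class.
class_marker_flags <- function(class_names) {
  out <- matrix(FALSE, nrow = length(class_names), ncol = length(MARKERS),
                dimnames = list(class_names, MARKERS))
  for (i in seq_along(class_names)) {
    if (identical(class_names[i], "NEG")) next
    parts <- strsplit(class_names[i], "_", fixed = TRUE)[[1]]
    bad <- setdiff(parts, MARKERS)
    if (length(bad) > 0) stop("unknown marker in class name: ",
                              class_names[i])
    out[i, parts] <- TRUE
  }
  out
}
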