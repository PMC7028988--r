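# End-to-end orchestration: image prep -> segmentation/scoring -> HID ->
# cohort statistics, with a run manifest recording configuration and
# per-stage attrition counts.

#' Pipeline configuration
#'
#' @param data_dir Directory holding the input data (as written by
#'   \code{\link{make_demo_data}}: per-ROI TIFFs named
#'   \code{p<patient>_r<roi>.tif} and \code{clinical.csv}).
#' @param out_dir Results directory (created; refuses to overwrite an
#'   existing non-empty results directory unless \code{overwrite = TRUE}).
#' @param pixel_size_um Micrometres per pixel.
#' @param d_um HID proximity radii in micrometres (default 30).
#' @param rescale_probs Percentile pair for intensity rescaling.
#' @param inclusion_threshold Minimum useful-tissue fraction for an ROI.
#' @param marker_thresholds Named vector of per-marker positivity
#'   thresholds on the rescaled scale.
#' @param hid_pairs List of phenotype pairs to compute HID for.
#' @param hid_aggregator Within-patient HID aggregation.
#' @param density_phenotypes Phenotypes for percent-positive densities.
#' @param stratify_cut_density,stratify_cut_hid Stratification cut for the
#'   density and the HID survival grids.
#' @param classifier_params,detect_params Parameter lists passed to
#'   \code{\link{classify_tissue}} and \code{\link{detect_nuclei}}.
#' @param seed Integer seed recorded in the manifest.
#' @param overwrite Allow writing into an existing non-empty out_dir.
#' @return Validated list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(data_dir, out_dir,
                            pixel_size_um = 0.495,
                            d_um = 30,
                            rescale_probs = c(0.01, 0.99),
                            inclusion_threshold = 0.30,
                            marker_thresholds = c(CD8 = 0.25, PD1 = 0.25,
                                                  PDL1 = 0.25, CD68 = 0.25),
                            hid_pairs = list(c("CD8+", "PD-L1+"),
                                             c("PD-1+", "PD-L1+")),
                            hid_aggregator = "median",
                            density_phenotypes = phenotype_vocabulary(),
                            stratify_cut_density = "median",
                            stratify_cut_hid = "mean",
                            classifier_params = list(),
                            detect_params = list(),
                            seed = 1L,
                            overwrite = FALSE) {
  cfg <- list(data_dir = data_dir, out_dir = out_dir,
              pixel_size_um = pixel_size_um, d_um = d_um,
              rescale_probs = rescale_probs,
              inclusion_threshold = inclusion_threshold,
              marker_thresholds = marker_thresholds,
              hid_pairs = hid_pairs, hid_aggregator = hid_aggregator,
              density_phenotypes = density_phenotypes,
              stratify_cut_density = stratify_cut_density,
              stratify_cut_hid = stratify_cut_hid,
              classifier_params = classifier_params,
              detect_params = detect_params,
              seed = as.integer(seed), overwrite = overwrite)
  class(cfg) <- "pipeline_config"
  if (cfg$inclusion_threshold < 0 || cfg$inclusion_threshold > 1) {
    stop("inclusion_threshold must lie in [0, 1]")
  }
  if (any(cfg$rescale_probs < 0) || any(cfg$rescale_probs > 1) ||
      cfg$rescale_probs[1] >= cfg$rescale_probs[2]) {
    stop("rescale_probs must be an increasing pair in [0, 1]")
  }
  if (any(cfg$marker_thresholds < 0 | cfg$marker_thresholds > 1)) {
    stop("marker_thresholds must lie in [0, 1]")
  }
  if (any(cfg$d_um <= 0)) stop("d_um must be positive")
  cfg
}

#' Run the full analysis pipeline
#'
#' Stages: (1) read each ROI image, classify pixel quality and apply the
#' useful-tissue inclusion gate; (2) detect nuclei, expand cells, measure
#' compartment intensities; (3) fit dataset-wide rescale bounds, score
#' marker positivity, assign phenotypes, and drop cells outside useful
#' tissue; (4) compute per-ROI and per-patient HID features and
#' percent-positive densities; (5) cohort survival tables. Every
#' intermediate table is written to \code{out_dir} along with a YAML run
#' manifest of per-stage counts.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Invisibly, a list with the manifest and the main tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$data_dir)) {
    stop("data_dir does not exist: ", config$data_dir)
  }
  if (dir.exists(config$out_dir) &&
      length(list.files(config$out_dir)) > 0 && !config$overwrite) {
    stop("out_dir exists and is not empty; refusing to mix runs: ",
         config$out_dir)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  clinical <- read_table_csv(file.path(config$data_dir, "clinical.csv"))
  tifs <- sort(list.files(config$data_dir, pattern = "^p\\d+_r\\d+\\.tif$",
                          full.names = TRUE))
  if (length(tifs) == 0) stop("stage imageprep: no ROI images found in ",
                              config$data_dir)

  # stage 1: quality masks + inclusion gate
  roi_meta <- list(); masks <- list()
  for (tf in tifs) {
    nm <- sub("\\.tif$", "", basename(tf))
    ids <- as.integer(strsplit(sub("^p", "", nm), "_r")[[1]])
    img <- read_multiplex_tiff(tf)
    mask <- classify_tissue(img, config$classifier_params)
    masks[[nm]] <- mask
    roi_meta[[nm]] <- data.frame(roi = nm, patient_id = ids[1],
                                 roi_id = ids[2], path = tf,
                                 useful_fraction = useful_tissue_fraction(mask),
                                 stringsAsFactors = FALSE)
  }
  roi_meta <- do.call(rbind, roi_meta)
  gate <- filter_rois(stats::setNames(roi_meta$useful_fraction,
                                      roi_meta$roi),
                      config$inclusion_threshold)
  roi_meta$included <- gate$included
  write_table_csv(roi_meta[, c("roi", "patient_id", "roi_id",
                               "useful_fraction", "included")],
                  file.path(config$out_dir, "roi_inclusion.csv"))

  # stage 2: segmentation + intensity measurement on included ROIs
  all_cells <- list()
  marker_pixels <- stats::setNames(vector("list", length(MARKERS)), MARKERS)
  for (nm in roi_meta$roi[roi_meta$included]) {
    row <- roi_meta[roi_meta$roi == nm, ]
    img <- read_multiplex_tiff(row$path)
    det <- detect_nuclei(get_channel(img, "DAPI"), config$detect_params)
    if (nrow(det$centroids) == 0) next
    comp <- expand_cells(det$labels, radius_um = 2,
                         pixel_size_um = config$pixel_size_um)
    cells <- measure_intensities(img, comp, det$centroids,
                                 roi_id = row$roi_id,
                                 patient_id = row$patient_id)
    cells <- filter_cells_by_mask(cells, masks[[nm]])
    all_cells[[nm]] <- cells
    tissue_idx <- which(masks[[nm]] == MASK_TISSUE)
    for (m in MARKERS) {
      marker_pixels[[m]] <- c(marker_pixels[[m]],
                              get_channel(img, m)[tissue_idx])
    }
  }
  if (length(all_cells) == 0) {
    stop("stage cells: no cells detected in any included ROI")
  }
  cells <- do.call(rbind, c(all_cells, list(make.row.names = FALSE)))

  # stage 3: rescale, score, phenotype
  bounds <- fit_rescale(marker_pixels, config$rescale_probs)
  cells <- score_positivity(cells, bounds, config$marker_thresholds)
  cells <- assign_phenotypes(cells)
  write_table_csv(cells, file.path(config$out_dir, "cells.csv"))
  write_table_csv(bounds, file.path(config$out_dir, "rescale_bounds.csv"))

  # stage 4: per-ROI / per-patient features
  feat_rows <- list()
  key <- interaction(cells$patient_id, cells$roi_id, drop = TRUE)
  for (k in levels(key)) {
    sub <- cells[key == k, ]
    rowf <- data.frame(patient_id = sub$patient_id[1],
                       roi_id = sub$roi_id[1], n_cells = nrow(sub))
    for (ph in config$density_phenotypes) {
      rowf[[paste0("pct_", gsub("[+-]", "", ph))]] <-
        100 * mean(phenotype_members(sub, ph))
    }
    for (pair in config$hid_pairs) {
      r <- hid_count(sub, pair[1], pair[2], d_um = config$d_um[1],
                     pixel_size_um = config$pixel_size_um)
      tag <- paste0("hid_", gsub("[+-]", "", pair[1]), "_",
                    gsub("[+-]", "", pair[2]))
      rowf[[tag]] <- r$h
    }
    feat_rows[[k]] <- rowf
  }
  roi_features <- do.call(rbind, c(feat_rows, list(make.row.names = FALSE)))
  write_table_csv(roi_features, file.path(config$out_dir,
                                          "roi_features.csv"))

  feat_cols <- setdiff(names(roi_features),
                       c("patient_id", "roi_id", "n_cells"))
  pat_rows <- lapply(split(roi_features, roi_features$patient_id),
                     function(df) {
    out <- data.frame(patient_id = df$patient_id[1], n_rois = nrow(df))
    for (fc in feat_cols) {
      agg <- if (startsWith(fc, "hid_")) config$hid_aggregator else "median"
      out[[fc]] <- switch(agg, median = stats::median(df[[fc]]),
                          mean = mean(df[[fc]]))
    }
    out
  })
  patient_features <- do.call(rbind, c(pat_rows,
                                       list(make.row.names = FALSE)))
  write_table_csv(patient_features,
                  file.path(config$out_dir, "patient_features.csv"))

  # stage 5: cohort statistics
  patients <- merge(clinical, patient_features, by = "patient_id")
  hid_cols <- feat_cols[startsWith(feat_cols, "hid_")]
  dens_cols <- setdiff(feat_cols, hid_cols)
  tables <- list(
    density = run_tables(patients, dens_cols,
                         cut = config$stratify_cut_density),
    hid = run_tables(patients, hid_cols, cut = config$stratify_cut_hid))
  for (tn in names(tables)) {
    tb <- tables[[tn]]
    if (!is.null(tb$distribution)) {
      write_table_csv(tb$distribution,
                      file.path(config$out_dir,
                                paste0(tn, "_distribution.csv")))
    }
    if (!is.null(tb$cox)) {
      write_table_csv(tb$cox,
                      file.path(config$out_dir, paste0(tn, "_cox.csv")))
    }
    if (!is.null(tb$km)) {
      write_table_csv(tb$km,
                      file.path(config$out_dir, paste0(tn, "_km.csv")))
    }
  }

  manifest <- list(
    seed = config$seed,
    pixel_size_um = config$pixel_size_um,
    d_um = config$d_um,
    inclusion_threshold = config$inclusion_threshold,
    marker_thresholds = as.list(config$marker_thresholds),
    hid_aggregator = config$hid_aggregator,
    counts = list(rois_total = nrow(roi_meta),
                  rois_included = sum(roi_meta$included),
                  rois_excluded = sum(!roi_meta$included),
                  cells_retained = nrow(cells),
                  patients_analysed = nrow(patients)),
    outputs = sort(list.files(config$out_dir))
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(list(manifest = manifest, cells = cells,
                 roi_features = roi_features,
                 patient_features = patient_features, tables = tables))
}

#' Write a small demonstration dataset
#'
#' Simulates a compact cohort (default 6 patients x 4 ROIs at reduced field
#' size), renders every ROI to a multi-page TIFF with its ground-truth mask,
#' and writes the clinical table, the true cell tables and the generator
#' configuration, so the full pipeline can be run end-to-end in minutes.
#'
#' @param out_dir Output directory (created).
#' @param seed Integer seed.
#' @param n_patients,n_rois,image_shape Size of the demo cohort.
#' @return Invisibly, the generator \code{\link{sim_config}} used.
#' @export
make_demo_data <- function(out_dir, seed = 1L, n_patients = 6,
                           n_rois = 4, image_shape = c(260, 348)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scale <- prod(image_shape) / (1040 * 1392)
  cfg <- sim_config(n_patients = n_patients,
                    rois_per_patient = c(n_rois, n_rois),
                    image_shape = image_shape,
                    class_densities = pmax(
                      round(sim_config()$class_densities * scale * 4), 1),
                    artifact_fraction = 0.08,
                    seed = seed)
  truth_cells <- list()
  for (p in seq_len(n_patients)) {
    for (r in seq_len(n_rois)) {
      roi <- generate_roi_points(cfg, patient_id = p, roi_id = r)
      rend <- render_roi_image(roi$cells, cfg)
      stem <- sprintf("p%d_r%d", p, r)
      write_multiplex_tiff(rend$image, file.path(out_dir,
                                                 paste0(stem, ".tif")))
      write_mask_tiff(rend$mask, file.path(out_dir,
                                           paste0(stem, "_truthmask.tif")))
      truth_cells[[stem]] <- roi$cells
    }
  }
  write_table_csv(do.call(rbind, c(truth_cells,
                                   list(make.row.names = FALSE))),
                  file.path(out_dir, "true_cells.csv"))

  # clinical records with the planted HID-dependent hazard
  hid_value <- vapply(seq_len(n_patients), function(p) {
    rows <- lapply(seq_len(n_rois), function(r) {
      res <- hid_count(truth_cells[[sprintf("p%d_r%d", p, r)]],
                       cfg$hid_pair[1], cfg$hid_pair[2], d_um = cfg$d_um,
                       pixel_size_um = cfg$pixel_size_um)
      data.frame(H = res$H, N = res$N, h = res$h)
    })
    patient_hid(do.call(rbind, rows))
  }, numeric(1))
  set.seed(derive_seed(seed, 13L))
  hpv <- ifelse(stats::runif(n_patients) < cfg$hpv_positive_fraction,
                "positive", "negative")
  grp <- hid_value > mean(hid_value)
  log_hr <- cfg$planted_log_hr * grp * (hpv == "negative") +
    cfg$hpv_log_hr * (hpv == "negative")
  surv <- simulate_survival(log_hr, cfg$baseline_hazard,
                            cfg$censoring_rate,
                            seed = derive_seed(seed, 17L))
  write_table_csv(data.frame(patient_id = seq_len(n_patients),
                             time_months = surv$time_months,
                             event = surv$event, hpv_status = hpv),
                  file.path(out_dir, "clinical.csv"))
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "sim_config.yaml"))
  writeLines(c("Synthetic demonstration dataset (all data simulated).",
               "p<patient>_r<roi>.tif           multi-page ROI image",
               "p<patient>_r<roi>_truthmask.tif ground-truth quality mask",
               "true_cells.csv                  planted cells + marker flags",
               "clinical.csv                    simulated survival records",
               "sim_config.yaml                 generator configuration"),
             file.path(out_dir, "README.txt"))
  invisible(cfg)
}
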