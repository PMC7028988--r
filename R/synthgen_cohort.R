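#' Simulate right-censored survival times from an exponential PH model
#'
#' Event times are exponential with per-subject rate
#' \code{baseline_hazard * exp(log_hr)}; independent exponential censoring is
#' calibrated so that the expected censored fraction equals
#' \code{censoring_rate} for each subject.
#'
#' @param log_hr Numeric vector of per-subject log hazard ratios (0 for the
#'   baseline group).
#' @param baseline_hazard Baseline event rate, events per month.
#' @param censoring_rate Expected censored fraction in [0, 1); 0 disables
#'   censoring.
#' @param seed Optional integer seed.
#' @return data.frame with \code{time_months} and \code{event} (1 = event
#'   observed, 0 = censored).
#' @export
simulate_survival <- function(log_hr, baseline_hazard = 0.004,
                              censoring_rate = 0.4, seed = NULL) {
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop("censoring_rate must lie in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(log_hr)
  rate <- baseline_hazard * exp(log_hr)
  t_event <- stats::rexp(n, rate)
  if (censoring_rate > 0) {
    # censoring rate c_i chosen so P(censor) = censoring_rate per subject
    c_rate <- rate * censoring_rate / (1 - censoring_rate)
    t_cens <- stats::rexp(n, c_rate)
    data.frame(time_months = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens))
  } else {
    data.frame(time_months = t_event, event = rep(1L, n))
  }
}

#' Generate a synthetic patient cohort with a planted HID-dependent hazard
#'
#' For each patient, draws a set of ROI point patterns, computes the true
#' patient-level HID feature \code{h(i, j)} for \code{config$hid_pair}
#' (median over ROIs by default), assigns the high/low group by the cohort
#' mean of the feature, and draws survival times from an exponential
#' proportional-hazards model whose log hazard is
#' \code{planted_log_hr * 1[high]} (applied in \code{config$effect_stratum})
#' plus \code{hpv_log_hr} for HPV-negative patients.
#'
#' @param config A \code{\link{sim_config}}.
#' @param keep_cells Keep every ROI's cell table in the result (memory-heavy
#'   for large cohorts; needed to rerun the pipeline end-to-end).
#' @param aggregator Within-patient aggregation of per-ROI h: \code{"median"}
#'   (default), \code{"mean"} or \code{"pooled"}.
#' @return List with \code{patients} (patient_id, time_months, event,
#'   hpv_status, hid feature, n_rois), \code{roi_features} (per-ROI H, N, h),
#'   \code{truth} (true_patient_hid, true_group), and optionally
#'   \code{cells}.
#' @export
generate_cohort <- function(config, keep_cells = FALSE,
                            aggregator = c("median", "mean", "pooled")) {
  validate_sim_config(config)
  aggregator <- match.arg(aggregator)
  set.seed(derive_seed(config$seed, 3L))
  n <- config$n_patients
  hpv <- ifelse(stats::runif(n) < config$hpv_positive_fraction,
                "positive", "negative")
  n_rois <- sample(seq(config$rois_per_patient[1],
                       config$rois_per_patient[2]), n, replace = TRUE)

  roi_rows <- list()
  all_cells <- if (keep_cells) list() else NULL
  hid_value <- numeric(n)
  for (p in seq_len(n)) {
    H_sum <- 0; N_sum <- 0; hs <- numeric(n_rois[p])
    for (r in seq_len(n_rois[p])) {
      roi <- generate_roi_points(config, patient_id = p, roi_id = r)
      res <- hid_count(roi$cells, config$hid_pair[1], config$hid_pair[2],
                       d_um = config$d_um,
                       pixel_size_um = config$pixel_size_um)
      hs[r] <- res$h
      H_sum <- H_sum + res$H
      N_sum <- N_sum + res$N
      roi_rows[[length(roi_rows) + 1]] <-
        data.frame(patient_id = p, roi_id = r, H = res$H, N = res$N,
                   h = res$h)
      if (keep_cells) all_cells[[length(all_cells) + 1]] <- roi$cells
    }
    hid_value[p] <- switch(aggregator,
                           median = stats::median(hs),
                           mean = mean(hs),
                           pooled = if (N_sum > 0) H_sum / N_sum else NA_real_)
  }

  true_group <- ifelse(hid_value > mean(hid_value), "high", "low")
  in_stratum <- switch(config$effect_stratum,
                       all = rep(TRUE, n),
                       hpv_negative = hpv == "negative",
                       hpv_positive = hpv == "positive")
  log_hr <- config$planted_log_hr * (true_group == "high") * in_stratum +
    config$hpv_log_hr * (hpv == "negative")
  surv <- simulate_survival(log_hr, config$baseline_hazard,
                            config$censoring_rate,
                            seed = derive_seed(config$seed, 5L))

  patients <- data.frame(
    patient_id = seq_len(n),
    time_months = surv$time_months,
    event = surv$event,
    hpv_status = hpv,
    hid = hid_value,
    n_rois = n_rois,
    stringsAsFactors = FALSE
  )
  out <- list(patients = patients,
              roi_features = do.call(rbind, roi_rows),
              truth = list(true_patient_hid = hid_value,
                           true_group = true_group))
  if (keep_cells) out$cells <- do.call(rbind, all_cells)
  out
}
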