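# Cohort-level statistics: percent-positive densities, high/low
# stratification, Kaplan-Meier with Greenwood variance, Mantel-Haenszel
# log-rank, univariate Cox regression, and one-sided Mann-Whitney
# comparisons.

#' Percent positive cells per ROI
#'
#' @param cells Cell table with marker flags and \code{roi_id}.
#' @param phenotype Label from \code{\link{phenotype_vocabulary}}.
#' @return data.frame (roi_id, n_cells, n_pos, pct). ROIs appear only if
#'   they have at least one cell.
#' @export
percent_positive <- function(cells, phenotype) {
  member <- phenotype_members(cells, phenotype)
  rois <- split(member, cells$roi_id)
  data.frame(roi_id = names(rois),
             n_cells = vapply(rois, length, integer(1)),
             n_pos = vapply(rois, sum, numeric(1)),
             pct = 100 * vapply(rois, mean, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Patient-level density: median of per-ROI percentages
#'
#' @param roi_pct Numeric vector of per-ROI percent-positive values for one
#'   patient (ROIs with no cells are skipped upstream).
#' @return Median percentage.
#' @export
patient_density <- function(roi_pct) {
  if (length(roi_pct) == 0) stop("patient has no evaluable ROIs")
  stats::median(roi_pct)
}

#' Stratify patients into high/low groups
#'
#' High means strictly greater than the cut statistic (median or mean of
#' the values in the analysis population); ties at the cut go to low.
#'
#' @param values Numeric vector, one value per patient.
#' @param cut \code{"median"} or \code{"mean"}.
#' @return Character vector \code{"high"}/\code{"low"}.
#' @export
stratify <- function(values, cut = c("median", "mean")) {
  cut <- match.arg(cut)
  if (length(values) < 2) stop("need >= 2 patients to stratify")
  if (length(unique(values)) == 1) {
    stop("all values identical: no stratification possible")
  }
  cs <- if (cut == "median") stats::median(values) else mean(values)
  ifelse(values > cs, "high", "low")
}

#' Kaplan-Meier estimator with Greenwood variance
#'
#' Product-limit estimate of the survival function. Subjects censored at an
#' event time remain at risk at that time. The variance is Greenwood's
#' formula: Var[S(t)] = S(t)^2 * sum_{t_i <= t} d_i / (n_i (n_i - d_i)).
#'
#' @param times Nonnegative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return data.frame of class \code{km_fit}, one row per distinct event
#'   time: time, n_risk, n_event, survival, var_greenwood, se.
#' @export
km_estimate <- function(times, events) {
  if (any(times < 0)) stop("survival times must be >= 0")
  if (length(times) != length(events)) stop("times/events length mismatch")
  ev_times <- sort(unique(times[events == 1]))
  n_risk <- vapply(ev_times, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) sum(times == t & events == 1),
                    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  gterm <- ifelse(n_risk > n_event,
                  n_event / (n_risk * (n_risk - n_event)), Inf)
  var_g <- surv^2 * cumsum(gterm)
  var_g[surv == 0] <- NA_real_  # Greenwood undefined once S(t) = 0
  out <- data.frame(time = ev_times, n_risk = n_risk, n_event = n_event,
                    survival = surv, var_greenwood = var_g,
                    se = sqrt(var_g))
  class(out) <- c("km_fit", class(out))
  out
}

#' Mantel-Haenszel log-rank test for two groups
#'
#' Chi-square statistic from the observed-vs-hypergeometric-expected event
#' tables at each distinct event time; p from the chi-square distribution
#' with 1 df.
#'
#' @param times,events Follow-up times and event indicators.
#' @param group Two-level group labels.
#' @return List: statistic, p, n per group, events per group.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) stop("need exactly 2 non-empty groups")
  if (sum(events) == 0) stop("no events observed: log-rank undefined")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group, rho = 0)
  stat <- sd$chisq
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       n = as.vector(sd$n),
       observed = as.vector(sd$obs),
       expected = as.vector(sd$exp))
}

#' Univariate Cox proportional-hazards regression
#'
#' Fits the Cox partial likelihood (Efron tie handling by default) for one
#' binary covariate and reports the hazard ratio with Wald 95% CI and
#' p-value. Monotone-likelihood fits (complete separation) are flagged and
#' the CI reported as unbounded.
#'
#' @param times,events Follow-up times and event indicators.
#' @param x Binary covariate (two-level factor, logical or 0/1; the hazard
#'   ratio is for the second level vs the first).
#' @param ties Tie handling, \code{"efron"} (default) or \code{"breslow"}.
#' @return List: hr, ci_lower, ci_upper, p, coef, se, n, n_event,
#'   separation flag.
#' @export
cox_univariate <- function(times, events, x, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  xf <- as.factor(x)
  if (nlevels(droplevels(xf)) != 2) {
    stop("covariate must have exactly 2 non-empty levels")
  }
  ev_per_level <- tapply(events, xf, sum)
  if (any(ev_per_level == 0)) {
    stop("each covariate level needs >= 1 observed event")
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ xf, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  s <- summary(fit)
  co <- s$coefficients
  list(hr = unname(co[1, "exp(coef)"]),
       ci_lower = if (separation) 0 else unname(s$conf.int[1, "lower .95"]),
       ci_upper = if (separation) Inf else unname(s$conf.int[1, "upper .95"]),
       p = unname(co[1, "Pr(>|z|)"]),
       coef = unname(co[1, "coef"]),
       se = unname(co[1, "se(coef)"]),
       n = length(times), n_event = sum(events),
       separation = separation)
}

#' One-sided Mann-Whitney U test
#'
#' Exact enumeration for small untied samples, tie-corrected normal
#' approximation otherwise (the behaviour of \code{stats::wilcox.test}).
#' \code{alternative = "less"} tests that A is stochastically smaller
#' than B.
#'
#' @param a,b Numeric samples.
#' @param alternative \code{"less"}, \code{"greater"} or
#'   \code{"two.sided"}.
#' @return List: U (statistic for sample a), p.
#' @export
mann_whitney <- function(a, b, alternative = c("less", "greater",
                                               "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(a, b,
                                            alternative = alternative))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Kolmogorov-Smirnov normality diagnostic
#'
#' Reported alongside group comparisons as a diagnostic only; it never
#' changes which test is run (group comparisons always use Mann-Whitney).
#'
#' @param x Numeric sample.
#' @return List: statistic, p (KS test against a normal with the sample's
#'   moments).
#' @export
ks_normality <- function(x) {
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x),
                                        stats::sd(x)))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Cohort report tables
#'
#' Builds the standard report for a cohort: per-feature median values with
#' a one-sided Mann-Whitney comparison of HPV-positive vs HPV-negative
#' patients (densities table); univariate Cox grids for the whole cohort
#' and both HPV subgroups, with patients stratified high/low by the chosen
#' cut within the analysis population being tested; and Kaplan-Meier curve
#' data with Greenwood standard errors per stratum for each feature in the
#' HPV-negative subgroup. Significance is flagged at alpha = 0.05; no
#' multiple-testing correction is applied and the number of tests run is
#' reported.
#'
#' @param patients data.frame with patient_id, time_months, event,
#'   hpv_status, and one numeric column per feature.
#' @param features Character vector of feature column names.
#' @param cut Stratification cut, \code{"median"} (densities) or
#'   \code{"mean"} (HID features).
#' @param cut_population \code{"analysis"} (cut computed within the
#'   population being tested, default) or \code{"cohort"} (whole-cohort
#'   cut reused in subgroups).
#' @param alpha Significance level (default 0.05).
#' @return List: \code{distribution} (per-feature medians + MW p),
#'   \code{cox} (feature x population grid of HR, CI, p),
#'   \code{km} (curve data per feature/stratum in the HPV-negative
#'   subgroup), \code{n_tests}, \code{alpha}, \code{notes}.
#' @export
run_tables <- function(patients, features, cut = c("median", "mean"),
                       cut_population = c("analysis", "cohort"),
                       alpha = 0.05) {
  cut <- match.arg(cut)
  cut_population <- match.arg(cut_population)
  notes <- character(0)
  n_tests <- 0L
  if (nrow(patients) < 2) {
    return(list(distribution = NULL, cox = NULL, km = NULL,
                n_tests = 0L, alpha = alpha,
                notes = "insufficient patients (n < 2): no tests run"))
  }
  pops <- list(all = rep(TRUE, nrow(patients)),
               hpv_positive = patients$hpv_status == "positive",
               hpv_negative = patients$hpv_status == "negative")

  dist_rows <- list(); cox_rows <- list(); km_list <- list()
  for (f in features) {
    if (!f %in% names(patients)) {
      notes <- c(notes, paste0("feature '", f, "' missing: omitted"))
      next
    }
    v <- patients[[f]]
    pos <- v[pops$hpv_positive]; neg <- v[pops$hpv_negative]
    mw <- if (length(pos) > 0 && length(neg) > 0) {
      n_tests <- n_tests + 1L
      mann_whitney(neg, pos, alternative = "less")  # tests HPV+ > HPV-
    } else list(U = NA_real_, p = NA_real_)
    ks <- if (length(v) >= 3 && stats::sd(v) > 0) ks_normality(v)
          else list(statistic = NA_real_, p = NA_real_)
    dist_rows[[f]] <- data.frame(
      feature = f,
      median_all = stats::median(v),
      median_hpv_positive = if (length(pos)) stats::median(pos) else NA_real_,
      median_hpv_negative = if (length(neg)) stats::median(neg) else NA_real_,
      mw_p = mw$p, ks_normality_p = ks$p,
      stringsAsFactors = FALSE)

    cohort_cut_groups <- tryCatch(stratify(v, cut), error = function(e) NULL)
    for (pop in names(pops)) {
      sel <- pops[[pop]]
      row <- data.frame(feature = f, population = pop, hr = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        p = NA_real_, n = sum(sel),
                        significant = NA, stringsAsFactors = FALSE)
      res <- tryCatch({
        grp <- if (cut_population == "analysis") {
          stratify(v[sel], cut)
        } else {
          if (is.null(cohort_cut_groups)) stop("no cohort cut")
          cohort_cut_groups[sel]
        }
        cox_univariate(patients$time_months[sel], patients$event[sel],
                       factor(grp, levels = c("low", "high")))
      }, error = function(e) {
        notes <<- c(notes, paste0(f, " / ", pop, ": ", conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) {
        n_tests <- n_tests + 1L
        row$hr <- res$hr; row$ci_lower <- res$ci_lower
        row$ci_upper <- res$ci_upper; row$p <- res$p
        row$significant <- res$p < alpha
      }
      cox_rows[[paste(f, pop)]] <- row
    }

    # KM curves with Greenwood error bars in the HPV-negative subgroup
    sel <- pops$hpv_negative
    if (sum(sel) >= 4) {
      km_f <- tryCatch({
        grp <- if (cut_population == "analysis") stratify(v[sel], cut)
               else cohort_cut_groups[sel]
        do.call(rbind, lapply(c("low", "high"), function(g) {
          gi <- grp == g
          if (sum(gi) == 0 || sum(patients$event[sel][gi]) == 0) {
            return(NULL)
          }
          km <- km_estimate(patients$time_months[sel][gi],
                            patients$event[sel][gi])
          cbind(feature = f, stratum = g, as.data.frame(km))
        }))
      }, error = function(e) NULL)
      if (!is.null(km_f)) km_list[[f]] <- km_f
    }
  }
  list(distribution = do.call(rbind, c(dist_rows, list(make.row.names = FALSE))),
       cox = do.call(rbind, c(cox_rows, list(make.row.names = FALSE))),
       km = if (length(km_list)) do.call(rbind, km_list) else NULL,
       n_tests = n_tests, alpha = alpha, notes = notes)
}
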