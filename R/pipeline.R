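#' Run the incidence analysis end-to-end
#'
#' Sequences the full analysis over an ensemble of diseases: baseline cancer
#' exclusions, first-primary-event-per-chapter extraction, per-disease
#' left-truncated right-censored dataset construction, maximum-likelihood
#' fitting, Kaplan--Meier offset adjustment and chi-square screening with an
#' FDR correction, sporadic/late-onset classification, and relative
#' risk/aging-rate tables.  Deterministic given inputs; every exclusion is
#' recorded in the manifest.
#'
#' @param subjects data.frame: `id`, `entry_age`, `exit_age`, covariates.
#' @param episodes data.frame: `id`, `age`, `code`, `primary`.
#' @param diseases named list of ICD-10 code-sets (names = disease ids).
#' @param schema optional [covariate_schema()] for adjusted fits.
#' @param family `"weibull"` (default, used for classification), `"nsm"`,
#'   or `"both"`.
#' @param fdr_level FDR level for the GOF screen; `m_threshold` exclusion
#'   threshold on the effective number of steps.
#' @param output_dir optional directory; when given, every result table is
#'   written there as CSV (figures are rendered from those tables).
#' @return list: `fits`, `gof` (per-disease assessment rows), `datasets`,
#'   `classification`, `aging` (long RR/RAR table, `NULL` without schema),
#'   `manifest` (counts at each filter stage).
#' @export
run_pipeline <- function(subjects, episodes, diseases, schema = NULL,
                         family = c("weibull", "nsm", "both"),
                         fdr_level = 0.05, m_threshold = 0.8,
                         output_dir = NULL) {
  family <- match.arg(family)
  families <- if (family == "both") c("weibull", "nsm") else family
  stopifnot(length(diseases) > 0, !is.null(names(diseases)))

  subj <- apply_baseline_exclusions(subjects, episodes)
  fe <- first_event_per_chapter(subj, episodes)

  fits <- list(); datasets <- list(); rows <- list(); skipped <- character(0)
  for (id in names(diseases)) {
    dat <- build_disease_dataset(diseases[[id]], subj, fe, episodes)
    datasets[[id]] <- dat
    if (sum(dat$status) < 2L) {
      skipped <- c(skipped, id)
      message("disease '", id, "' skipped: fewer than 2 events")
      next
    }
    for (fam in families) {
      fit <- tryCatch(fit_multistage(dat, family = fam, schema = schema),
                      error = function(e) e)
      key <- paste(id, fam, sep = ".")
      if (inherits(fit, "error")) {
        skipped <- c(skipped, key)
        message("fit failed for '", key, "': ", conditionMessage(fit))
        next
      }
      km <- kaplan_meier_delayed_entry(dat)
      H1 <- estimate_H1(fit$model, km)
      gof <- chisq_gof(fit$model, adjust_km(km, H1))
      fits[[key]] <- fit
      rows[[key]] <- data.frame(
        disease = id, family = fam, m = fit$model$m, L = fit$model$L,
        se_m = fit$estimates$se[1L], loglik = fit$loglik,
        n_events = fit$n_events, H1 = H1,
        gof_statistic = gof$statistic, gof_df = gof$df,
        gof_p = gof$p_value, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no disease could be fitted")
  assessment <- do.call(rbind, rows)
  rownames(assessment) <- NULL
  # FDR across diseases, within family
  assessment$gof_q <- NA_real_
  for (fam in families) {
    i <- assessment$family == fam
    if (any(i)) assessment$gof_q[i] <- fdr_adjust(assessment$gof_p[i])
  }
  inc <- Map(inclusion_filter, assessment$m, assessment$gof_q,
             MoreArgs = list(m_threshold = m_threshold,
                             fdr_level = fdr_level))
  assessment$included <- vapply(inc, `[[`, TRUE, "included")
  assessment$exclusion_reason <- vapply(inc, `[[`, "", "reason")

  # classification on the reporting family (Weibull when both were fitted)
  report_fam <- families[1L]
  fam_rows <- assessment[assessment$family == report_fam, , drop = FALSE]
  cls <- NULL
  if (sum(fam_rows$included) >= 3L) {
    fam_fits <- fits[paste(fam_rows$disease, report_fam, sep = ".")]
    names(fam_fits) <- fam_rows$disease
    chap <- vapply(fam_rows$disease,
                   function(id) icd10_chapter(diseases[[id]][1L]), "")
    cls <- classification_table(
      fam_fits, chapters = chap,
      included = stats::setNames(fam_rows$included, fam_rows$disease))
  }

  aging <- NULL
  if (!is.null(schema)) {
    fam_fits <- fits[paste(fam_rows$disease, report_fam, sep = ".")]
    names(fam_fits) <- fam_rows$disease
    aging <- aging_rate_table(fam_fits[fam_rows$included])
    if (!is.null(aging) && !is.null(cls))
      aging$tertile <- cls$tertile[match(aging$disease, cls$disease)]
  }

  manifest <- list(
    n_subjects_in = nrow(subjects),
    n_excluded_prior_cancer = length(attr(subj, "excluded_ids")),
    n_subjects_analysed = nrow(subj),
    diseases_in = length(diseases),
    diseases_skipped = skipped,
    n_included = sum(assessment$included),
    n_excluded_gof = sum(grepl("gof", assessment$exclusion_reason)),
    n_excluded_m = sum(grepl("m_below_threshold", assessment$exclusion_reason)),
    families = families, fdr_level = fdr_level, m_threshold = m_threshold)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(assessment, file.path(output_dir, "assessment.csv"),
                     row.names = FALSE)
    if (!is.null(cls))
      utils::write.csv(cls, file.path(output_dir, "classification.csv"),
                       row.names = FALSE)
    if (!is.null(aging))
      utils::write.csv(aging, file.path(output_dir, "aging_rates.csv"),
                       row.names = FALSE)
    write_fit_table(fits, file.path(output_dir, "fits.csv"))
  }

  list(fits = fits, gof = assessment, datasets = datasets,
       classification = cls, aging = aging, manifest = manifest)
}

logH_at <- function(fit, t_ref) {
  # log H(t_ref) at baseline, with a delta-method SE from (log m, log L)
  m <- fit$model$m; L <- fit$model$L
  val <- m * (log(t_ref) - log(L))
  grad <- c(m * (log(t_ref) - log(L)), -m)   # d/d(log m), d/d(log L)
  vc <- fit$vcov_log[1:2, 1:2]
  se <- sqrt(drop(t(grad) %*% vc %*% grad))
  c(value = val, se = se)
}

#' Stratified fits and displacement / slope contrasts
#'
#' Fits the model separately in each stratum of a single factor (no other
#' adjustment) and reports, against the first (reference) stratum, the
#' vertical displacement of the log cumulative hazard at a reference age
#' (`delta_logH`; an increase in the rates of disease processes displaces
#' the log--log line upwards) and the change in slope (`delta_m`; losing a
#' rate-limiting step reduces the slope).
#'
#' @param data cohort data.frame.
#' @param stratifier name of the column to stratify by (e.g. smoking or
#'   diabetes status); must be non-missing for all subjects.
#' @param family model family.
#' @param t_ref reference age for the displacement (default: mean event
#'   age).
#' @param min_events strata with fewer events are skipped with a message.
#' @return data.frame, one row per stratum: n, n_events, m, se_m, logH_ref,
#'   se_logH, delta_m, se_delta_m, delta_logH, se_delta_logH.
#' @export
stratified_comparison <- function(data, stratifier, family = "weibull",
                                  t_ref = NULL, min_events = 10L) {
  stopifnot(stratifier %in% names(data))
  if (anyNA(data[[stratifier]])) stop("stratifier has missing values")
  if (is.null(t_ref)) t_ref <- mean(data$exit_age[data$status == 1])
  strata <- if (is.factor(data[[stratifier]])) levels(data[[stratifier]])
            else unique(data[[stratifier]])
  rows <- list(); fits <- list()
  for (s in strata) {
    d <- data[data[[stratifier]] == s, , drop = FALSE]
    if (sum(d$status) < min_events) {
      message("stratum '", s, "' skipped: fewer than ", min_events, " events")
      next
    }
    fit <- fit_multistage(d, family = family)
    lh <- logH_at(fit, t_ref)
    fits[[s]] <- fit
    rows[[s]] <- data.frame(
      stratum = s, n = nrow(d), n_events = fit$n_events,
      m = fit$model$m, se_m = fit$estimates$se[1L],
      logH_ref = lh[["value"]], se_logH = lh[["se"]],
      stringsAsFactors = FALSE)
  }
  if (length(rows) < 1L) stop("no stratum had enough events")
  out <- do.call(rbind, rows)
  ref <- out[1L, ]
  out$delta_m <- out$m - ref$m
  out$se_delta_m <- sqrt(out$se_m^2 + ref$se_m^2)
  out$delta_logH <- out$logH_ref - ref$logH_ref
  out$se_delta_logH <- sqrt(out$se_logH^2 + ref$se_logH^2)
  out[1L, c("delta_m", "se_delta_m", "delta_logH", "se_delta_logH")] <- 0
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "t_ref") <- t_ref
  out
}

#' Log cumulative hazard versus log age, by stratum
#'
#' The multistage diagnostic plot: the offset-adjusted Kaplan--Meier log
#' cumulative hazard against log age appears as a straight line of slope
#' `m` under a Weibull multistage model; risk factors that raise process
#' rates displace lines vertically, and factors that remove rate-limiting
#' steps reduce the slope.  Pointwise 95% intervals are dashed; the
#' parametric fit overlays as a straight line.
#'
#' @param data cohort data.frame.
#' @param stratifier optional stratifying column; `NULL` for one stratum.
#' @param family model family for the overlays.
#' @param min_events strata with fewer events are dropped with a warning.
#' @return a ggplot object; the plotted table is attached as
#'   `attr(, "table")`.
#' @export
loglog_plot <- function(data, stratifier = NULL, family = "weibull",
                        min_events = 10L) {
  strata <- if (is.null(stratifier)) list(all = data)
            else split(data, data[[stratifier]])
  tabs <- list(); lines <- list()
  for (s in names(strata)) {
    d <- strata[[s]]
    if (sum(d$status) < min_events) {
      warning("stratum '", s, "' dropped: fewer than ", min_events, " events")
      next
    }
    fit <- fit_multistage(d, family = family)
    km <- kaplan_meier_delayed_entry(d)
    adj <- adjust_km(km, estimate_H1(fit$model, km))
    H <- -log(adj$surv_adj)
    se_logH <- sqrt(adj$var_adj) / adj$surv_adj / H  # delta method on log H
    tabs[[s]] <- data.frame(stratum = s, age = adj$time, logH = log(H),
                            lo = log(H) - 1.96 * se_logH,
                            hi = log(H) + 1.96 * se_logH)
    grid <- seq(min(adj$time), max(adj$time), length.out = 50)
    lines[[s]] <- data.frame(stratum = s, age = grid,
                             logH = log(model_cumhaz(fit$model, grid)))
  }
  if (length(tabs) == 0L) stop("no stratum had enough events")
  tab <- do.call(rbind, tabs); fitline <- do.call(rbind, lines)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = log(.data$age), y = .data$logH,
                                         colour = .data$stratum)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lo), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$hi), linetype = "dashed") +
    ggplot2::geom_line(data = fitline) +
    ggplot2::labs(x = "log(age)", y = "log(H(age)), adjusted",
                  colour = stratifier) +
    ggplot2::theme_bw()
  attr(p, "table") <- tab
  p
}
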