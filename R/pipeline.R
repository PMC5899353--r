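# Cohort orchestration: per-exam METV extraction, merge with survival records,
# and the standard biomarker analyses (hazard-ratio table at quartile
# cut-points, covariate-adjusted Cox with Harrell's C, correlations,
# Kaplan-Meier curves), with per-exam fault isolation and a run manifest.

#' Survival analyses for a biomarker table
#'
#' The analysis half of the pipeline, usable on its own when METV (and
#' optionally FTV) values already exist: quartile cut-points with a
#' Mantel-Haenszel hazard ratio, log-rank test and Kaplan-Meier curves at each
#' of Q1/Q2/Q3; a Cox model adjusted for the given covariates with Harrell's C
#' of its linear predictor; and, when a comparator biomarker is present,
#' the Pearson correlation between the two and the bootstrap non-inferiority
#' bound. Subjects with unknown hormone-receptor status are excluded from the
#' Cox fit (complete-case; the count is reported) but kept everywhere else.
#'
#' @param data Data frame with survival columns and the biomarker.
#' @param biomarker Biomarker column name (default `metv_mm3`).
#' @param covariates Adjustment covariates for the Cox model.
#' @param comparator Optional comparator biomarker column (e.g. `ftv_cm3`).
#' @param time,event Column names.
#' @param n_boot Bootstrap resamples for the C CI and non-inferiority bound.
#' @param boot_seed Seed for all bootstraps.
#' @param unknown_label Category of `hr_status` treated as missing in the Cox
#'   fit.
#' @return A list of tibbles: `cutpoints`, `hr_table`, `logrank_table`,
#'   `km_curves`, `cox` (the `metv_cox` object), `cstat`, and (with a
#'   comparator) `correlation` and `noninferiority`.
#' @export
cohort_survival_analysis <- function(data, biomarker = "metv_mm3",
                                     covariates = c("age", "race", "hr_status"),
                                     comparator = NULL,
                                     time = "rfs_days", event = "event",
                                     n_boot = 1000, boot_seed = 1L,
                                     unknown_label = "unknown") {
  if (!biomarker %in% names(data)) {
    abort(sprintf("Biomarker column '%s' not found.", biomarker),
          class = "metvolume_input_error")
  }
  vals <- data[[biomarker]]
  cuts <- quartile_cutpoints(vals)

  hr_rows <- list(); lr_rows <- list(); km_rows <- list()
  for (ql in names(cuts)) {
    d <- data
    d$biomarker_group <- dichotomize(vals, cuts[[ql]])
    hr_rows[[ql]] <- tryCatch(
      mh_hazard_ratio(d, "biomarker_group", time = time, event = event,
                      cutpoint_value = unname(cuts[[ql]]), cutpoint_label = ql),
      error = function(e) tibble::tibble(hr = NA_real_, ci_low = NA_real_,
                                         ci_high = NA_real_,
                                         cutpoint_value = unname(cuts[[ql]]),
                                         cutpoint_label = ql,
                                         n_high = sum(d$biomarker_group == "high"),
                                         n_low = sum(d$biomarker_group == "low"),
                                         events_high = NA_integer_,
                                         events_low = NA_integer_))
    lr_rows[[ql]] <- dplyr::mutate(
      tryCatch(logrank_test(d, "biomarker_group", time = time, event = event),
               error = function(e) tibble::tibble(chisq = NA_real_, df = 1L,
                                                  p.value = NA_real_)),
      cutpoint_label = ql)
    km <- km_estimate(d, time = time, event = event, group = "biomarker_group")
    km$cutpoint_label <- ql
    km_rows[[ql]] <- km
  }

  cox_data <- data
  if ("hr_status" %in% covariates && "hr_status" %in% names(cox_data)) {
    cox_data$hr_status[cox_data$hr_status == unknown_label] <- NA
  }
  # covariates without variation (possible in small cohorts) carry no
  # information and would make the design singular; drop them, audibly
  cc <- stats::complete.cases(cox_data[c(time, event, biomarker, covariates)])
  constant <- covariates[vapply(covariates, function(cv) {
    length(unique(cox_data[[cv]][cc])) < 2L
  }, logical(1))]
  if (length(constant)) {
    inform(paste0("Dropping constant covariate(s) from the Cox model: ",
                  paste(constant, collapse = ", ")))
    covariates <- setdiff(covariates, constant)
  }
  cox <- fit_cox(cox_data, c(biomarker, covariates), time = time, event = event)
  cstat <- harrell_c(predict(cox), cox$data_used, time = time, event = event,
                     n_boot = n_boot, boot_seed = boot_seed)

  out <- list(
    cutpoints = tibble::tibble(cutpoint_label = names(cuts),
                               cutpoint_value = unname(cuts)),
    hr_table = dplyr::bind_rows(hr_rows),
    logrank_table = dplyr::bind_rows(lr_rows),
    km_curves = dplyr::bind_rows(km_rows),
    cox = cox,
    cstat = dplyr::mutate(cstat, n_used = cox$n_used, n_dropped = cox$n_dropped)
  )
  if (!is.null(comparator) && comparator %in% names(data) &&
      !all(is.na(data[[comparator]]))) {
    both <- !is.na(vals) & !is.na(data[[comparator]])
    out$correlation <- dplyr::mutate(
      pearson_r(vals[both], data[[comparator]][both]),
      biomarker = biomarker, comparator = comparator)
    out$noninferiority <- noninferiority_lower_bound(
      data[both, , drop = FALSE], biomarker, comparator,
      cutpoint_label = "Q3", time = time, event = event,
      n_boot = n_boot, boot_seed = boot_seed)
  }
  out
}

resolve_exams <- function(exams) {
  if (is.character(exams) && length(exams) == 1L && dir.exists(exams)) {
    files <- sort(list.files(exams, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
    out <- list()
    for (f in files) {
      ex <- tryCatch(suppressWarnings(read_exam(f)), error = function(e) e)
      if (inherits(ex, "dce_exam")) out[[ex$exam_id]] <- ex
      else out[[basename(f)]] <- ex  # keep the failure for the manifest
    }
    return(out)
  }
  lapply(exams, function(e) if (inherits(e, "phantom_exam")) e$exam else e)
}

#' Run the METV pipeline over a cohort
#'
#' For every exam with a seed point, extracts METV; per-exam failures are
#' quarantined in the manifest and never abort the run. The METV table is then
#' merged with the cohort's survival records by subject/exam id and analyzed
#' with [cohort_survival_analysis()]. Deterministic given the configuration
#' seeds; rerunning with the same inputs writes byte-identical CSV outputs.
#'
#' @param exams Named list of [dce_exam()]/`phantom_exam` objects, or a
#'   directory of 4D NIfTI exams with sidecars.
#' @param seeds Seed-point table (`exam_id`, 0-based `z`, `y`, `x`) or a CSV
#'   path.
#' @param cohort Cohort table (see [read_cohort()]) or a CSV path; matched to
#'   exams via `subject_id == exam_id`.
#' @param config A [metv_config()].
#' @param covariates Cox adjustment covariates.
#' @param comparator Optional comparator biomarker column in the cohort table.
#' @param n_boot,boot_seed Bootstrap settings for [cohort_survival_analysis()].
#' @param out_dir If non-`NULL`, results are written there as CSV/JSON.
#' @return A list: `metv_table`, `merged`, `analysis` (see
#'   [cohort_survival_analysis()]), `manifest`.
#' @export
run_cohort <- function(exams, seeds, cohort, config = metv_config(),
                       covariates = c("age", "race", "hr_status"),
                       comparator = NULL, n_boot = 1000, boot_seed = 1L,
                       out_dir = NULL) {
  exams <- resolve_exams(exams)
  if (is.character(seeds)) seeds <- read_seed_points(seeds)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  cohort <- validate_cohort(tibble::as_tibble(cohort))

  manifest <- list()
  rows <- list()
  unmatched <- setdiff(seeds$exam_id, names(exams))
  for (id in unmatched) {
    manifest[[id]] <- list(exam_id = id, status = "failed",
                           reason = "no exam for this seed point")
  }
  for (i in seq_len(nrow(seeds))) {
    id <- seeds$exam_id[i]
    if (id %in% unmatched) next
    ex <- exams[[id]]
    if (!inherits(ex, "dce_exam")) {
      manifest[[id]] <- list(exam_id = id, status = "failed",
                             reason = conditionMessage(ex))
      next
    }
    res <- tryCatch(
      withCallingHandlers(
        exam_metv(ex, c(seeds$z[i], seeds$y[i], seeds$x[i]), config),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(res, "error")) {
      manifest[[id]] <- list(exam_id = id, status = "failed",
                             reason = conditionMessage(res))
    } else {
      manifest[[id]] <- list(exam_id = id,
                             status = if (res$degenerate) "degenerate" else "ok",
                             reason = "")
      rows[[id]] <- tidy(res)
    }
  }
  if (!length(rows)) {
    abort("No exam produced a METV value.", class = "metvolume_pipeline_error")
  }
  metv_table <- dplyr::bind_rows(rows)

  merged <- dplyr::inner_join(cohort,
                              dplyr::rename(metv_table, subject_id = "exam_id"),
                              by = "subject_id")
  if (nrow(merged) == 0) {
    abort("Empty merged cohort: no subject_id matches an analyzed exam_id.",
          class = "metvolume_pipeline_error")
  }
  analysis <- cohort_survival_analysis(merged, biomarker = "metv_mm3",
                                       covariates = covariates,
                                       comparator = comparator,
                                       n_boot = n_boot, boot_seed = boot_seed)
  manifest_tbl <- dplyr::bind_rows(lapply(manifest, tibble::as_tibble))
  out <- list(metv_table = metv_table, merged = merged,
              analysis = analysis, manifest = manifest_tbl)
  if (!is.null(out_dir)) write_results(out, config, out_dir)
  out
}

write_results <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$metv_table, file.path(out_dir, "metv.csv"), row.names = FALSE)
  a <- result$analysis
  utils::write.csv(a$hr_table, file.path(out_dir, "hazard_ratios.csv"), row.names = FALSE)
  utils::write.csv(a$logrank_table, file.path(out_dir, "logrank.csv"), row.names = FALSE)
  utils::write.csv(a$cstat, file.path(out_dir, "cstatistic.csv"), row.names = FALSE)
  utils::write.csv(a$km_curves, file.path(out_dir, "km_curves.csv"), row.names = FALSE)
  if (!is.null(a$correlation)) {
    utils::write.csv(a$correlation, file.path(out_dir, "correlations.csv"), row.names = FALSE)
  }
  if (!is.null(a$noninferiority)) {
    utils::write.csv(a$noninferiority, file.path(out_dir, "noninferiority.csv"),
                     row.names = FALSE)
  }
  prov <- list(package = "metvolume",
               version = as.character(utils::packageVersion("metvolume")),
               timestamp = format(Sys.time(), tz = "UTC"),
               config = unclass(config),
               manifest = result$manifest)
  jsonlite::write_json(prov, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
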