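#' Specify a synthetic survival cohort
#'
#' Describes a cohort whose recurrence hazard depends on the true most-enhancing
#' tumor volume (METV). Event times are exponential with hazard
#' `baseline_hazard * exp(beta_metv * coded METV)` (proportional hazards hold
#' exactly); subjects whose event time exceeds the administrative follow-up
#' window are censored at the window. Covariates are drawn per the defaults of
#' a neoadjuvant breast-cancer trial population: age normal(49, 8) truncated to
#' \[27, 68\], and hormone-receptor status with frequencies 78:41:40:3 for
#' HR+/HER2-, HER2+, triple-negative and unknown.
#'
#' @param n_subjects Number of subjects, > 0.
#' @param metv_meanlog,metv_sdlog Log-normal parameters of the true core-volume
#'   distribution in mm\eqn{^3} (defaults span the tens-to-thousands of
#'   mm\eqn{^3} seen for most-enhancing cores).
#' @param beta_metv Log hazard ratio per unit of the coded METV.
#' @param metv_coding Either `"threshold"` (default; the coded covariate is the
#'   indicator that METV is at or above the `coding_quantile` sample quantile,
#'   mirroring quartile cut-point analyses) or `"log"` (continuous log-METV).
#' @param coding_quantile Quantile defining the threshold coding (default 0.75,
#'   the highest-quartile cut).
#' @param age_mean,age_sd,age_range Truncated-normal age model (years).
#' @param race_probs Named category frequencies for race, summing to 1.
#' @param hr_status_probs Named category frequencies for hormone-receptor
#'   status, summing to 1.
#' @param baseline_hazard Exponential baseline hazard per day, > 0.
#' @param followup_days Administrative censoring window in days, >= 0. The
#'   default window and hazard give roughly the 28% event fraction of
#'   multicenter neoadjuvant trials.
#' @param rng_seed Integer seed.
#' @param exam_cnr Feature-space contrast-to-noise ratio used when phantom
#'   exams are generated for the cohort (see [noise_sigma_for_cnr()]).
#' @param exam_shell_mm,exam_margin_mm Geometry of per-subject phantoms (see
#'   [phantom_spec_for_core()]).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects,
                        metv_meanlog = log(300), metv_sdlog = 0.8,
                        beta_metv = 0,
                        metv_coding = c("threshold", "log"),
                        coding_quantile = 0.75,
                        age_mean = 49, age_sd = 8, age_range = c(27, 68),
                        race_probs = c(white = 0.8, black = 0.2),
                        hr_status_probs = c(`HR+/HER2-` = 78, `HER2+` = 41,
                                            triple_negative = 40, unknown = 3) / 162,
                        baseline_hazard = 1.1e-4,
                        followup_days = 3000,
                        rng_seed = 1L,
                        exam_cnr = 5,
                        exam_shell_mm = 2.5,
                        exam_margin_mm = 6) {
  metv_coding <- match.arg(metv_coding)
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    abort("`n_subjects` must be > 0.", class = "metvolume_input_error")
  }
  stopifnot_scalar_number(baseline_hazard, "baseline_hazard", positive = TRUE)
  if (followup_days < 0) {
    abort("`followup_days` must be >= 0.", class = "metvolume_input_error")
  }
  for (p in list(race_probs, hr_status_probs)) {
    if (is.null(names(p)) || abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      abort("Category frequencies must be named, non-negative and sum to 1.",
            class = "metvolume_input_error")
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         metv_meanlog = metv_meanlog, metv_sdlog = metv_sdlog,
         beta_metv = beta_metv, metv_coding = metv_coding,
         coding_quantile = coding_quantile,
         age_mean = age_mean, age_sd = age_sd, age_range = age_range,
         race_probs = race_probs, hr_status_probs = hr_status_probs,
         baseline_hazard = baseline_hazard, followup_days = followup_days,
         rng_seed = as.integer(rng_seed),
         exam_cnr = exam_cnr, exam_shell_mm = exam_shell_mm,
         exam_margin_mm = exam_margin_mm),
    class = "cohort_spec"
  )
}

# truncated normal via rejection; deterministic under the enclosing seed
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic cohort (and optionally its phantom exams)
#'
#' Draws true core volumes, covariates and survival outcomes per a
#' [cohort_spec()]. With `make_exams = TRUE`, a phantom exam is generated for
#' each subject with a core matching the drawn volume; the subject's
#' `metv_true_mm3` is then the realized (voxel-count) core volume and the
#' hazard uses the realized value, so image-derived estimates can be compared
#' against exactly the quantity that generated the outcomes.
#'
#' @param spec A [cohort_spec()].
#' @param make_exams Generate a `phantom_exam` per subject (slower).
#' @return A list with `subjects` (a tibble: `subject_id`, `rfs_days`, `event`
#'   coded 1 = recurrence / 0 = censored, `age`, `race`, `hr_status`,
#'   `metv_true_mm3`, `metv_coded`) and `exams` (named list of
#'   [generate_exam()] results, or `NULL`).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(50, beta_metv = log(3), rng_seed = 7))
#' head(coh$subjects)
generate_cohort <- function(spec, make_exams = FALSE) {
  if (!inherits(spec, "cohort_spec")) {
    abort("`spec` must be a cohort_spec.", class = "metvolume_input_error")
  }
  n <- spec$n_subjects
  out <- with_seed(spec$rng_seed, {
    vols <- rlnorm(n, spec$metv_meanlog, spec$metv_sdlog)
    age <- rtruncnorm(n, spec$age_mean, spec$age_sd,
                      spec$age_range[1], spec$age_range[2])
    race <- sample(names(spec$race_probs), n, replace = TRUE, prob = spec$race_probs)
    hrs <- sample(names(spec$hr_status_probs), n, replace = TRUE,
                  prob = spec$hr_status_probs)
    list(vols = vols, age = age, race = race, hrs = hrs)
  })
  ids <- sprintf("S%04d", seq_len(n))

  exams <- NULL
  if (make_exams) {
    exams <- lapply(seq_len(n), function(i) {
      sp <- phantom_spec_for_core(out$vols[i],
                                  shell_mm = spec$exam_shell_mm,
                                  margin_mm = spec$exam_margin_mm,
                                  cnr = spec$exam_cnr,
                                  rng_seed = derive_seed(spec$rng_seed, paste0("exam", i)))
      generate_exam(sp, exam_id = ids[i])
    })
    names(exams) <- ids
    # hazard uses the realized (discrete) core volume
    out$vols <- unname(vapply(exams, function(e) e$true_core_volume_mm3, numeric(1)))
  }

  coded <- switch(spec$metv_coding,
    threshold = as.numeric(out$vols >= quantile(out$vols, spec$coding_quantile, type = 7)),
    log = log(out$vols)
  )
  haz <- spec$baseline_hazard * exp(spec$beta_metv * coded)
  surv <- with_seed(derive_seed(spec$rng_seed, "survival"), {
    t_event <- rexp(n, rate = haz)
    event <- t_event <= spec$followup_days
    list(rfs = pmin(t_event, spec$followup_days), event = as.integer(event))
  })

  subjects <- tibble::tibble(
    subject_id = ids,
    rfs_days = surv$rfs,
    event = surv$event,
    age = out$age,
    race = out$race,
    hr_status = out$hrs,
    metv_true_mm3 = out$vols,
    metv_coded = coded
  )
  list(subjects = subjects, exams = exams)
}
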