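# Survival-association statistics for volumetric biomarkers: Pearson
# correlation, quartile cut-points, Kaplan-Meier estimation, log-rank tests,
# Mantel-Haenszel hazard ratios, covariate-adjusted Cox models with Harrell's
# C, and a bootstrap non-inferiority bound.

#' Pearson correlation between two biomarkers
#'
#' Sample correlation with a two-sided p-value from the t transform with
#' `n - 2` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors (n >= 3, finite, non-constant).
#' @return A tibble with `estimate`, `p.value`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must have equal length >= 3.", class = "metvolume_input_error")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("Non-finite values in correlation input.", class = "metvolume_input_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Zero variance: correlation undefined.", class = "metvolume_input_error")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}

#' Quartile cut-points of a biomarker
#'
#' 25th, 50th and 75th percentiles under linear interpolation (quantile type
#' 7). [dichotomize()] labels subjects at or above a cut-point as `"high"`, so
#' ties at the cut-point go to the high group.
#'
#' @param values Numeric vector, n >= 4, finite.
#' @return Named numeric `c(Q1 = , Q2 = , Q3 = )`.
#' @export
#' @examples
#' quartile_cutpoints(1:8)  # 2.75 4.50 6.25
quartile_cutpoints <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4 || any(!is.finite(values))) {
    abort("Need at least 4 finite values.", class = "metvolume_input_error")
  }
  if (max(values) == min(values)) {
    warn("All values identical: quartile groups are degenerate.")
  }
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  setNames(q, c("Q1", "Q2", "Q3"))
}

#' @rdname quartile_cutpoints
#' @param cutpoint The threshold; values `>= cutpoint` are `"high"`.
#' @return `dichotomize` returns a factor with levels `c("low", "high")`.
#' @export
dichotomize <- function(values, cutpoint) {
  factor(ifelse(values >= cutpoint, "high", "low"), levels = c("low", "high"))
}

surv_cols <- function(data, time, event) {
  t <- data[[time]]
  e <- data[[event]]
  if (is.null(t) || is.null(e)) {
    abort(sprintf("Columns '%s' and '%s' are required.", time, event),
          class = "metvolume_input_error")
  }
  if (any(t < 0) || any(!is.finite(t))) {
    abort("Survival times must be finite and >= 0.", class = "metvolume_input_error")
  }
  if (!all(e %in% c(0, 1))) {
    abort("Event flags must be 0 (censored) or 1 (event).", class = "metvolume_input_error")
  }
  list(time = as.numeric(t), event = as.integer(e))
}

#' Kaplan-Meier estimate of recurrence-free survival
#'
#' Product-limit estimator \eqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i/n_i)};
#' censored subjects leave the risk set after their time. With a `group`
#' column, one curve per group is returned in a single tibble.
#'
#' @param data Data frame of subject records.
#' @param time,event Column names (defaults `rfs_days`, `event` with 1 =
#'   recurrence, 0 = censored).
#' @param group Optional grouping column name.
#' @return A tibble of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival` (and `group` if requested); rows at all
#'   distinct observed times, the estimator stepping only at event times.
#' @export
km_estimate <- function(data, time = "rfs_days", event = "event", group = NULL) {
  sc <- surv_cols(data, time, event)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(sc$time, sc$event) ~ 1)
    out <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                          n_event = fit$n.event, n_censor = fit$n.censor,
                          survival = fit$surv)
  } else {
    g <- data[[group]]
    out <- dplyr::bind_rows(lapply(split(seq_along(g), g), function(ix) {
      fit <- survival::survfit(survival::Surv(sc$time[ix], sc$event[ix]) ~ 1)
      tibble::tibble(group = g[ix][1], time = fit$time, n_risk = fit$n.risk,
                     n_event = fit$n.event, n_censor = fit$n.censor,
                     survival = fit$surv)
    }))
  }
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic: observed minus expected events summed over
#' event times with hypergeometric variances, referred to \eqn{\chi^2(1)}.
#'
#' @param data Data frame of subject records.
#' @param group Column name of a two-level grouping.
#' @param time,event Column names.
#' @return A tibble with `chisq`, `df`, `p.value`, and per-group observed and
#'   expected event counts.
#' @export
logrank_test <- function(data, group, time = "rfs_days", event = "event") {
  sc <- surv_cols(data, time, event)
  g <- factor(data[[group]])
  if (nlevels(g) != 2L || any(table(g) == 0)) {
    abort("`group` must have exactly two non-empty levels.",
          class = "metvolume_input_error")
  }
  if (sum(sc$event) == 0) {
    abort("No events: log-rank test undefined.", class = "metvolume_input_error")
  }
  sd <- survival::survdiff(survival::Surv(sc$time, sc$event) ~ g)
  if (!is.finite(sd$chisq)) {
    abort("Zero log-rank variance: no comparable risk sets.",
          class = "metvolume_input_error")
  }
  tibble::tibble(chisq = sd$chisq, df = 1L, p.value = 1 - pchisq(sd$chisq, 1),
                 obs_1 = sd$obs[1], obs_2 = sd$obs[2],
                 exp_1 = sd$exp[1], exp_2 = sd$exp[2],
                 level_1 = levels(g)[1], level_2 = levels(g)[2])
}

#' Mantel-Haenszel hazard ratio at a cut-point
#'
#' \eqn{HR = (O_h/E_h) / (O_l/E_l)} with observed and expected event counts
#' from the log-rank machinery; the confidence interval uses the standard
#' observed/expected variance on the log scale,
#' \eqn{SE(\log HR) = \sqrt{1/E_h + 1/E_l}}.
#'
#' @param data Data frame of subject records.
#' @param high Column name of a logical (or `"high"`/`"low"` factor from
#'   [dichotomize()]) marking the high-biomarker group.
#' @param time,event Column names.
#' @param conf_level Confidence level (default 0.95).
#' @param cutpoint_value,cutpoint_label Carried into the output for
#'   book-keeping (e.g. the volume threshold and `"Q3"`).
#' @return A one-row tibble with `hr`, `ci_low`, `ci_high`, `cutpoint_value`,
#'   `cutpoint_label`, group sizes and event counts.
#' @export
mh_hazard_ratio <- function(data, high, time = "rfs_days", event = "event",
                            conf_level = 0.95,
                            cutpoint_value = NA_real_, cutpoint_label = NA_character_) {
  sc <- surv_cols(data, time, event)
  h <- data[[high]]
  if (is.factor(h) || is.character(h)) h <- as.character(h) == "high"
  h <- as.logical(h)
  if (all(h) || all(!h)) {
    abort("Both groups must be non-empty.", class = "metvolume_input_error")
  }
  g <- factor(ifelse(h, "high", "low"), levels = c("low", "high"))
  ev <- tapply(sc$event, g, sum)
  if (any(ev == 0)) {
    abort(sprintf("Unstable hazard ratio: no events in the %s group.",
                  paste(names(ev)[ev == 0], collapse = " and ")),
          class = "metvolume_hr_error")
  }
  sd <- survival::survdiff(survival::Surv(sc$time, sc$event) ~ g)
  O <- sd$obs; E <- sd$exp  # index 1 = low, 2 = high
  if (any(E <= 0)) {
    abort(sprintf("Zero expected event count (E_low = %.3g, E_high = %.3g).",
                  E[1], E[2]), class = "metvolume_hr_error")
  }
  hr <- (O[2] / E[2]) / (O[1] / E[1])
  se <- sqrt(1 / E[2] + 1 / E[1])
  zc <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(hr = unname(hr),
                 ci_low = unname(hr * exp(-zc * se)),
                 ci_high = unname(hr * exp(zc * se)),
                 cutpoint_value = cutpoint_value,
                 cutpoint_label = cutpoint_label,
                 n_high = sum(h), n_low = sum(!h),
                 events_high = unname(ev["high"]), events_low = unname(ev["low"]))
}

#' Covariate-adjusted Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood with the Efron tie correction,
#' reference-coding categorical covariates. Rows with missing values in any
#' required column are dropped (complete-case) and counted. A rank-deficient
#' design is an error naming the collinear columns; a monotone partial
#' likelihood (perfect separation) is flagged in `flags`, not silently
#' returned.
#'
#' @param data Data frame of subject records.
#' @param covariates Character vector of covariate column names (categorical
#'   columns are treated as factors).
#' @param time,event Column names.
#' @return An object of class `metv_cox` wrapping the `survival::coxph` fit,
#'   with `n_used`, `n_dropped` and `flags`.
#' @export
fit_cox <- function(data, covariates, time = "rfs_days", event = "event") {
  keep <- c(time, event, covariates)
  missing_cols <- setdiff(keep, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "metvolume_input_error")
  }
  df <- as.data.frame(data)[keep]
  cc <- complete.cases(df)
  df <- df[cc, , drop = FALSE]
  sc <- surv_cols(df, time, event)
  if (sum(sc$event) < 1) {
    abort("No events: Cox model undefined.", class = "metvolume_input_error")
  }
  for (cv in covariates) {
    if (is.character(df[[cv]])) df[[cv]] <- factor(df[[cv]])
    if (is.factor(df[[cv]])) df[[cv]] <- droplevels(df[[cv]])
  }
  constant <- covariates[vapply(covariates, function(cv) {
    length(unique(df[[cv]])) < 2L
  }, logical(1))]
  if (length(constant)) {
    abort(paste0("Constant covariate(s) cannot enter the model: ",
                 paste(constant, collapse = ", ")),
          class = "metvolume_input_error")
  }
  mm <- stats::model.matrix(
    as.formula(paste("~", paste(sprintf("`%s`", covariates), collapse = " + "))), df)
  mm <- mm[, -1, drop = FALSE]
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
    abort(paste0("Rank-deficient design; collinear column(s): ",
                 paste(dropped, collapse = ", ")),
          class = "metvolume_input_error")
  }
  fml <- as.formula(paste0("survival::Surv(`", time, "`, `", event, "`) ~ ",
                           paste(sprintf("`%s`", covariates), collapse = " + ")))
  flags <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converged before", conditionMessage(w))) {
        flags <<- c(flags, paste("monotone likelihood:", conditionMessage(w)))
      } else {
        flags <<- c(flags, conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    })
  structure(list(fit = fit, n_used = nrow(df), n_dropped = sum(!cc),
                 flags = flags, covariates = covariates,
                 time = time, event = event, data_used = df),
            class = "metv_cox")
}

#' @export
print.metv_cox <- function(x, ...) {
  cat(sprintf("<metv_cox: %d subjects used (%d dropped), %d event(s)>\n",
              x$n_used, x$n_dropped, x$fit$nevent))
  print(coef(x$fit))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @rdname fit_cox
#' @param x A `metv_cox` fit.
#' @param conf_level Confidence level for coefficient intervals.
#' @param ... Unused.
#' @export
tidy.metv_cox <- function(x, conf_level = 0.95, ...) {
  s <- summary(x$fit, conf.int = conf_level)$coefficients
  ci <- confint(x$fit, level = conf_level)
  tibble::tibble(term = rownames(s),
                 estimate = s[, "coef"],
                 std.error = s[, "se(coef)"],
                 statistic = s[, "z"],
                 p.value = s[, "Pr(>|z|)"],
                 conf.low = ci[, 1],
                 conf.high = ci[, 2])
}

#' @rdname fit_cox
#' @export
glance.metv_cox <- function(x, ...) {
  tibble::tibble(n = x$n_used, n_dropped = x$n_dropped,
                 n_event = x$fit$nevent,
                 log_partial_likelihood = x$fit$loglik[2],
                 converged = is.null(x$fit$info),
                 flagged = length(x$flags) > 0)
}

#' Linear predictor (risk score) of a fitted Cox model
#'
#' @param object A `metv_cox` fit.
#' @param newdata Data to score (defaults to the complete-case rows the model
#'   was fitted on).
#' @param ... Unused.
#' @return Numeric risk scores (higher = shorter expected survival).
#' @export
predict.metv_cox <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data_used
  unname(predict(object$fit, newdata = newdata, type = "lp"))
}

#' Harrell's concordance statistic for censored survival
#'
#' The fraction of comparable subject pairs in which the subject with the
#' shorter survival has the higher risk score. A pair is comparable when the
#' smaller of the two times is an event (pairs with tied times are not
#' comparable); tied risk scores count 1/2. The confidence interval is a
#' seeded subject-level percentile bootstrap.
#'
#' @param scores Numeric risk score per subject (higher = higher risk).
#' @param data Data frame with the survival columns.
#' @param time,event Column names.
#' @param n_boot Bootstrap resamples for the CI (0 skips the CI).
#' @param conf_level Confidence level.
#' @param boot_seed Seed for the bootstrap.
#' @return A one-row tibble with `c`, `ci_low`, `ci_high`,
#'   `n_comparable_pairs`.
#' @export
harrell_c <- function(scores, data, time = "rfs_days", event = "event",
                      n_boot = 1000, conf_level = 0.95, boot_seed = 1L) {
  sc <- surv_cols(data, time, event)
  if (length(scores) != length(sc$time)) {
    abort("`scores` must have one entry per subject.", class = "metvolume_input_error")
  }
  cstat <- function(s, t, e) {
    conc <- 0; comp <- 0
    for (i in which(e == 1L)) {
      later <- t > t[i]
      comp <- comp + sum(later)
      conc <- conc + sum(later & (s < s[i])) + 0.5 * sum(later & (s == s[i]))
    }
    if (comp == 0) return(c(NA_real_, 0))
    c(conc / comp, comp)
  }
  full <- cstat(scores, sc$time, sc$event)
  if (full[2] == 0) {
    abort("No comparable pairs: concordance undefined.", class = "metvolume_input_error")
  }
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    n <- length(scores)
    boots <- with_seed(boot_seed, {
      vapply(seq_len(n_boot), function(b) {
        ix <- sample.int(n, n, replace = TRUE)
        cstat(scores[ix], sc$time[ix], sc$event[ix])[1]
      }, numeric(1))
    })
    alpha <- (1 - conf_level) / 2
    ci <- unname(quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE, type = 7))
  }
  tibble::tibble(c = full[1], ci_low = ci[1], ci_high = ci[2],
                 n_comparable_pairs = as.integer(full[2]))
}

#' Bootstrap non-inferiority lower bound for two biomarkers
#'
#' Compares the Mantel-Haenszel hazard ratios of two biomarkers dichotomized at
#' the same quartile cut-point. For each bootstrap resample (subjects with
#' replacement) both cut-points are recomputed, both hazard ratios are
#' re-estimated, and their difference (first minus second biomarker) is
#' recorded; the non-inferiority bound is the lower end of the one-sided 90%
#' confidence interval, i.e. the 10th percentile of the bootstrap differences.
#' A resample in which either dichotomized group is event-free is redrawn (the
#' count is reported). A bound at or above the margin 0 supports
#' non-inferiority of the first biomarker.
#'
#' @param data Data frame containing both biomarker columns for every subject.
#' @param biomarker,comparator Column names of the two biomarkers (e.g. METV
#'   and FTV).
#' @param cutpoint_label `"Q1"`, `"Q2"` or `"Q3"`.
#' @param time,event Column names.
#' @param n_boot Bootstrap iterations (>= 100; default 1000).
#' @param boot_seed Seed.
#' @param max_redraw Safety cap on redraws per resample.
#' @return A one-row tibble: `lower_bound_90`, `n_boot`, `n_redrawn`,
#'   `hr_biomarker`, `hr_comparator`, `noninferior` (logical vs margin 0).
#' @export
noninferiority_lower_bound <- function(data, biomarker, comparator,
                                       cutpoint_label = "Q3",
                                       time = "rfs_days", event = "event",
                                       n_boot = 1000, boot_seed = 1L,
                                       max_redraw = 1000) {
  cutpoint_label <- match.arg(cutpoint_label, c("Q1", "Q2", "Q3"))
  if (n_boot < 100) {
    abort("`n_boot` must be >= 100.", class = "metvolume_input_error")
  }
  b1 <- data[[biomarker]]; b2 <- data[[comparator]]
  if (any(is.na(b1)) || any(is.na(b2))) {
    abort("Every record must carry both biomarkers.", class = "metvolume_input_error")
  }
  sc <- surv_cols(data, time, event)
  df <- data.frame(t = sc$time, e = sc$event, b1 = b1, b2 = b2)
  qi <- c(Q1 = 0.25, Q2 = 0.5, Q3 = 0.75)[[cutpoint_label]]

  hr_at_cut <- function(d, col) {
    cut <- quantile(d[[col]], qi, type = 7, names = FALSE)
    high <- d[[col]] >= cut
    if (all(high) || all(!high)) return(NA_real_)
    ev <- tapply(d$e, high, sum)
    if (length(ev) < 2 || any(ev == 0)) return(NA_real_)
    g <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
    sd <- survival::survdiff(survival::Surv(d$t, d$e) ~ g)
    (sd$obs[2] / sd$exp[2]) / (sd$obs[1] / sd$exp[1])
  }

  hr1 <- hr_at_cut(df, "b1")
  hr2 <- hr_at_cut(df, "b2")
  n <- nrow(df)
  n_redrawn <- 0L
  diffs <- with_seed(boot_seed, {
    vapply(seq_len(n_boot), function(b) {
      for (r in seq_len(max_redraw)) {
        d <- df[sample.int(n, n, replace = TRUE), ]
        h1 <- hr_at_cut(d, "b1")
        h2 <- hr_at_cut(d, "b2")
        if (!is.na(h1) && !is.na(h2)) return(h1 - h2)
        n_redrawn <<- n_redrawn + 1L
      }
      abort("Could not draw a resample with events in every group.",
            class = "metvolume_input_error")
    }, numeric(1))
  })
  lb <- unname(quantile(diffs, 0.10, type = 7))
  tibble::tibble(lower_bound_90 = lb, n_boot = as.integer(n_boot),
                 n_redrawn = n_redrawn,
                 hr_biomarker = hr1, hr_comparator = hr2,
                 noninferior = lb >= 0)
}
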