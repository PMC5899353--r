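test_that("quartile cut-points use linear interpolation and ties go high", {
  q <- quartile_cutpoints(1:8)
  expect_equal(unname(q), c(2.75, 4.5, 6.25))
  expect_named(q, c("Q1", "Q2", "Q3"))
  g <- dichotomize(c(1, 4.5, 7), 4.5)
  expect_equal(as.character(g), c("low", "high", "high"))  # tie at cut -> high
  expect_equal(levels(g), c("low", "high"))
  expect_error(quartile_cutpoints(c(1, 2, 3)), class = "metvolume_input_error")
  expect_warning(quartile_cutpoints(rep(2, 5)), "identical")
})

test_that("pearson correlation matches the definitional arithmetic", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  r <- pearson_r(x, y)
  # independent arithmetic from the definition
  rxy <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- rxy * sqrt((5 - 2) / (1 - rxy^2))
  expect_equal(r$estimate, rxy)
  expect_equal(r$p.value, 2 * stats::pt(-abs(tstat), df = 3))
  expect_equal(r$n, 5L)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), class = "metvolume_input_error")
  expect_error(pearson_r(1:2, 1:2), class = "metvolume_input_error")
})

test_that("the product-limit estimator matches the hand-computed curve", {
  d <- data.frame(rfs_days = 1:5, event = c(1, 0, 1, 0, 1))
  km <- km_estimate(d)
  expect_equal(km$time, 1:5)
  expect_equal(km$survival, c(0.8, 0.8, 0.8 * (1 - 1/3), 0.8 * (1 - 1/3), 0))
  expect_equal(km$n_risk, 5:1)
  expect_equal(km$n_event, c(1, 0, 1, 0, 1))
  expect_equal(km$n_censor, c(0, 1, 0, 1, 0))
})

test_that("the product-limit estimator matches the oracle on random data", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(10:40, 1)
    t <- sample(1:15, n, replace = TRUE)  # ties included
    e <- rbinom(n, 1, 0.6)
    if (sum(e) == 0) e[1] <- 1L
    km <- km_estimate(data.frame(rfs_days = t, event = e))
    o <- km_oracle(t, e)
    got <- km[km$n_event > 0, ]
    expect_equal(got$time, o$time)
    expect_equal(got$survival, o$survival)
  }
})

test_that("grouped curves split the risk sets by group", {
  d <- data.frame(rfs_days = c(1, 2, 3, 4), event = c(1, 1, 1, 0),
                  grp = c("a", "a", "b", "b"))
  km <- km_estimate(d, group = "grp")
  expect_equal(km$survival[km$group == "a"], c(0.5, 0))
  expect_equal(km$survival[km$group == "b"], c(0.5, 0.5))
})

test_that("the log-rank statistic matches the hand-built O-E/variance table", {
  # group A: events at 1 and 2; group B: censored at 3 and 4.
  # t=1: n=4, nA=2 -> E_A += 1/2,  V += 1*(2/4)*(2/4)*(4-1)/(4-1) = 1/4
  # t=2: n=3, nA=1 -> E_A += 1/3,  V += 1*(1/3)*(2/3)*(3-1)/(3-1) = 2/9
  # O_A = 2, E_A = 5/6, V = 17/36, chisq = (2 - 5/6)^2 / (17/36)
  d <- data.frame(rfs_days = c(1, 2, 3, 4), event = c(1, 1, 0, 0),
                  grp = c("A", "A", "B", "B"))
  lr <- logrank_test(d, "grp")
  expect_equal(lr$chisq, (2 - 5/6)^2 / (17/36), tolerance = 1e-8)
  expect_equal(lr$obs_1, 2)
  expect_equal(lr$exp_1, 5/6, tolerance = 1e-8)
  expect_equal(lr$df, 1L)
  expect_equal(lr$p.value, 1 - stats::pchisq(lr$chisq, 1))
})

test_that("identical groups give a null log-rank test and unit hazard ratio", {
  base <- data.frame(rfs_days = c(2, 4, 6, 8, 10, 12),
                     event = c(1, 1, 0, 1, 0, 1))
  d <- rbind(base, base)
  d$grp <- rep(c("low", "high"), each = 6)
  lr <- logrank_test(d, "grp")
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  hr <- mh_hazard_ratio(d, "grp")
  expect_equal(hr$hr, 1, tolerance = 1e-12)
  expect_true(hr$ci_low < 1 && hr$ci_high > 1)
})

test_that("swapping the group labels inverts the hazard ratio", {
  set.seed(12)
  d <- data.frame(rfs_days = rexp(40, 0.1), event = rbinom(40, 1, 0.7),
                  h = rep(c(TRUE, FALSE), 20))
  d$hs <- !d$h
  hr1 <- mh_hazard_ratio(d, "h")$hr
  hr2 <- mh_hazard_ratio(d, "hs")$hr
  expect_equal(hr1 * hr2, 1, tolerance = 1e-10)
})

test_that("a zero-event group makes the hazard ratio an explicit error", {
  d <- data.frame(rfs_days = c(1, 2, 3, 4), event = c(1, 1, 0, 0),
                  h = c(FALSE, FALSE, TRUE, TRUE))
  expect_error(mh_hazard_ratio(d, "h"), class = "metvolume_hr_error")
  expect_error(mh_hazard_ratio(d, "h2"))  # missing column
  d$event <- c(1, 1, 1, 1)
  d$h <- rep(TRUE, 4)
  expect_error(mh_hazard_ratio(d, "h"), class = "metvolume_input_error")
})

test_that("Harrell's C equals exhaustive pair enumeration", {
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(5:30, 1)
    t <- sample(1:12, n, replace = TRUE)       # tied times occur
    e <- rbinom(n, 1, 0.6)
    s <- sample(seq(0, 2, 0.5), n, replace = TRUE)  # tied scores occur
    if (sum(e) == 0) e[which.min(t)] <- 1L
    o <- cindex_oracle(s, t, e)
    if (o$n_comparable == 0) next
    got <- harrell_c(s, data.frame(rfs_days = t, event = e), n_boot = 0)
    expect_equal(got$c, o$c)
    expect_equal(got$n_comparable_pairs, o$n_comparable)
  }
})

test_that("a perfectly anti-concordant score attains C = 1", {
  t <- c(3, 7, 1, 9, 5)
  d <- data.frame(rfs_days = t, event = rep(1, 5))
  got <- harrell_c(-t, d, n_boot = 0)  # higher risk = shorter survival, always
  expect_equal(got$c, 1)
  expect_equal(got$n_comparable_pairs, choose(5, 2))
})

test_that("the bootstrap C interval is seeded and reproducible", {
  set.seed(14)
  d <- data.frame(rfs_days = rexp(50, 0.05), event = rbinom(50, 1, 0.6))
  s <- rnorm(50)
  a <- harrell_c(s, d, n_boot = 200, boot_seed = 9)
  b <- harrell_c(s, d, n_boot = 200, boot_seed = 9)
  expect_identical(a, b)
  expect_true(a$ci_low <= a$c && a$c <= a$ci_high)
})

test_that("the Cox fit maximizes the partial likelihood", {
  t <- c(2, 5, 7, 11, 13, 17)
  e <- c(1, 1, 0, 1, 1, 0)
  x <- c(1, 0, 1, 1, 0, 0)
  # untied times: maximize the standard partial likelihood by direct search
  nll <- function(beta) {
    ll <- 0
    for (i in which(e == 1)) {
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[t >= t[i]])))
    }
    -ll
  }
  opt <- stats::optimize(nll, c(-5, 5), tol = 1e-9)
  fit <- fit_cox(data.frame(rfs_days = t, event = e, biomarker = x), "biomarker")
  expect_equal(unname(stats::coef(fit$fit)), opt$minimum, tolerance = 1e-5)
  td <- tidy(fit)
  expect_equal(td$term, "biomarker")
  expect_true(td$conf.low < td$estimate && td$estimate < td$conf.high)
  gl <- glance(fit)
  expect_equal(gl$n, 6L)
  expect_equal(gl$n_event, 4)
  expect_length(predict(fit), 6L)
})

test_that("Cox input problems are reported, not papered over", {
  set.seed(3)
  d <- data.frame(rfs_days = rexp(30, 0.1), event = rbinom(30, 1, 0.7),
                  a = rnorm(30))
  d$b <- 2 * d$a  # collinear
  err <- expect_error(fit_cox(d, c("a", "b")), class = "metvolume_input_error")
  expect_match(conditionMessage(err), "b")
  d$b <- rnorm(30)
  d$b[4] <- NA
  fit <- fit_cox(d, c("a", "b"))
  expect_equal(fit$n_used, 29L)
  expect_equal(fit$n_dropped, 1L)
  d0 <- d
  d0$event <- 0L
  expect_error(fit_cox(d0, "a"), class = "metvolume_input_error")
  d$race <- "white"  # constant covariate: named in a typed error
  err <- expect_error(fit_cox(d, c("a", "race")),
                      class = "metvolume_input_error")
  expect_match(conditionMessage(err), "race")
})

test_that("a biomarker compared with itself has a bootstrap bound of zero", {
  coh <- generate_cohort(cohort_spec(60, beta_metv = log(3), rng_seed = 4L))$subjects
  coh$a <- coh$metv_true_mm3
  coh$b <- coh$metv_true_mm3
  nb <- noninferiority_lower_bound(coh, "a", "b", n_boot = 100, boot_seed = 2)
  expect_equal(nb$lower_bound_90, 0)
  expect_true(nb$noninferior)
  expect_equal(nb$hr_biomarker, nb$hr_comparator)
  nb2 <- noninferiority_lower_bound(coh, "a", "b", n_boot = 100, boot_seed = 2)
  expect_identical(nb, nb2)
  expect_error(noninferiority_lower_bound(coh, "a", "b", n_boot = 50),
               class = "metvolume_input_error")
})

test_that("survival inputs are validated", {
  d <- data.frame(rfs_days = c(-1, 2), event = c(1, 0))
  expect_error(km_estimate(d), class = "metvolume_input_error")
  d <- data.frame(rfs_days = c(1, 2), event = c(1, 2))
  expect_error(km_estimate(d), class = "metvolume_input_error")
  expect_error(km_estimate(data.frame(x = 1)), class = "metvolume_input_error")
})
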