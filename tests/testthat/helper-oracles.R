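# Independent brute-force oracles used to validate the package implementations.
# These deliberately avoid the package's vectorized code paths: everything is
# written as explicit loops over the defining equations.

# Fuzzy c-means by the literal update equations, starting from an explicit
# initial membership matrix (rows are normalized first).
fcm_oracle <- function(x, c = 2L, m = 2, tol = 1e-5, max_iter = 200L, u_init) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  u <- as.matrix(u_init)
  u <- u / rowSums(u)
  obj <- numeric(0)
  converged <- FALSE
  v <- matrix(0, c, p)
  for (it in seq_len(max_iter)) {
    um <- u^m
    for (i in seq_len(c)) {
      num <- rep(0, p)
      den <- 0
      for (k in seq_len(n)) {
        num <- num + um[k, i] * x[k, ]
        den <- den + um[k, i]
      }
      v[i, ] <- num / den
    }
    d2 <- matrix(0, n, c)
    for (k in seq_len(n)) {
      for (i in seq_len(c)) d2[k, i] <- sum((x[k, ] - v[i, ])^2)
    }
    u_new <- matrix(0, n, c)
    for (k in seq_len(n)) {
      if (any(d2[k, ] == 0)) {
        z <- d2[k, ] == 0
        u_new[k, z] <- 1 / sum(z)
      } else {
        for (i in seq_len(c)) {
          u_new[k, i] <- 1 / sum((d2[k, i] / d2[k, ])^(1 / (m - 1)))
        }
      }
    }
    obj <- c(obj, sum(u_new^m * d2))
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(memberships = u, centroids = v, objective_trace = obj, converged = converged)
}

# Product-limit estimator at the distinct event times.
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ts, survival = surv)
}

# Harrell's C by exhaustive pair enumeration.
cindex_oracle <- function(scores, time, event) {
  conc <- 0
  comp <- 0
  n <- length(scores)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      a <- if (time[i] < time[j]) i else j  # earlier of the pair
      b <- if (time[i] < time[j]) j else i
      if (event[a] != 1) next
      comp <- comp + 1
      if (scores[a] > scores[b]) {
        conc <- conc + 1
      } else if (scores[a] == scores[b]) {
        conc <- conc + 0.5
      }
    }
  }
  list(c = conc / comp, n_comparable = comp)
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# A compact noise-free phantom used across tests.
small_phantom <- function(...) {
  generate_exam(phantom_spec(grid_shape = c(32, 32, 32),
                             tumor_radii_mm = c(9, 9, 9),
                             core_radii_mm = c(4, 4, 4), ...))
}

# Crop a full-grid truth mask to the VOI of a metv_result / segmentation.
crop_to_voi <- function(truth, offset, dims) {
  truth[offset[1] + seq_len(dims[1]),
        offset[2] + seq_len(dims[2]),
        offset[3] + seq_len(dims[3])]
}
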