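#' Fuzzy c-means clustering of kinetic feature vectors
#'
#' Unsupervised fuzzy c-means with the classic alternating updates: centroids
#' \deqn{v_i = \sum_k u_{ik}^m x_k / \sum_k u_{ik}^m} and memberships
#' \deqn{u_{ik} = 1 / \sum_j (\|x_k - v_i\| / \|x_k - v_j\|)^{2/(m-1)},}
#' minimizing the objective \eqn{J = \sum_i \sum_k u_{ik}^m \|x_k - v_i\|^2}.
#' A point that coincides with a centroid gets membership 1 for that cluster
#' (split equally if it coincides with several). Memberships are initialized
#' from a symmetric Dirichlet draw under `rng_seed`, so runs are reproducible;
#' iteration stops when the largest membership change falls below `tol`.
#'
#' @param x Feature matrix (`n` points by `p` features) or a
#'   [relative_enhancement()] result.
#' @param c Number of clusters, >= 2.
#' @param m Fuzziness exponent, > 1.
#' @param tol Convergence tolerance on `max |U_new - U_old|`, > 0.
#' @param max_iter Maximum number of iterations.
#' @param rng_seed Seed for the membership initialization (ignored when
#'   `u_init` is given).
#' @param u_init Optional `n x c` initial membership matrix (rows are
#'   normalized internally).
#' @return An object of class `fcm_result`: `memberships` (`n x c`, rows sum to
#'   1), `centroids` (`c x p`), `objective_trace` (non-increasing), `n_iter`,
#'   `converged`.
#' @export
#' @examples
#' x <- c(0, 0, 1, 1, 10, 10, 11, 11)
#' f <- fcm_cluster(x, c = 2, rng_seed = 1)
#' sort(f$centroids[, 1])  # near 0.5 and 10.5
fcm_cluster <- function(x, c = 2L, m = 2, tol = 1e-5, max_iter = 200L,
                        rng_seed = 0L, u_init = NULL) {
  if (inherits(x, "kinetic_features")) x <- x$matrix
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  c <- as.integer(c)
  if (c < 2L) abort("`c` must be >= 2.", class = "metvolume_input_error")
  if (m <= 1) abort("`m` must be > 1.", class = "metvolume_input_error")
  stopifnot_scalar_number(tol, "tol", positive = TRUE)
  if (n < c) {
    abort(sprintf("Cannot form %d clusters from %d points.", c, n),
          class = "metvolume_degenerate_input_error")
  }
  if (nrow(unique(x)) < c) {
    abort(sprintf("Fewer than %d distinct points.", c),
          class = "metvolume_degenerate_input_error")
  }
  if (is.null(u_init)) {
    u <- with_seed(rng_seed, matrix(rexp(n * c), n, c))
  } else {
    u <- as.matrix(u_init)
    if (!identical(dim(u), c(n, c))) {
      abort("`u_init` must be an n x c matrix.", class = "metvolume_input_error")
    }
  }
  u <- u / rowSums(u)

  xsq <- rowSums(x^2)
  expo <- -1 / (m - 1)
  obj <- numeric(max_iter)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    um <- u^m
    v <- crossprod(um, x) / colSums(um)                         # c x p
    d2 <- xsq - 2 * x %*% t(v) + rep(rowSums(v^2), each = n)    # n x c
    d2[d2 < 0] <- 0
    w <- d2^expo                                                 # Inf where d2 == 0
    u_new <- w / rowSums(w)
    sing <- which(!is.finite(rowSums(w)))
    if (length(sing)) {
      z <- d2[sing, , drop = FALSE] == 0
      u_new[sing, ] <- z / rowSums(z)
    }
    obj[it] <- sum(u_new^m * d2)
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  structure(
    list(memberships = u, centroids = v, objective_trace = obj[seq_len(it)],
         n_iter = it, converged = converged, m = m, tol = tol),
    class = "fcm_result"
  )
}

#' @export
print.fcm_result <- function(x, ...) {
  cat(sprintf("<fcm_result: %d points, %d clusters, %d iteration(s), %s>\n",
              nrow(x$memberships), ncol(x$memberships), x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  cat("centroids:\n"); print(x$centroids)
  invisible(x)
}
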