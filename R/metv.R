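#' Pipeline configuration
#'
#' Collects every tunable of the per-exam METV pipeline with its default. The
#' same fuzzy c-means settings are used for both clustering stages unless
#' stage-2 overrides are given.
#'
#' @param half_width_mm VOI half-width in mm (see [extract_voi()]).
#' @param epsilon Denominator floor for relative enhancement.
#' @param c,m,tol,max_iter,seed Fuzzy c-means settings (see [fcm_cluster()]).
#' @param connectivity,fill_holes,min_enhancement Mask post-processing (see
#'   [select_tumor_mask()]).
#' @param c2 Cluster count for the stage-2 (most-enhancing) clustering.
#' @param separation_tol Minimum stage-2 centroid separation below which the
#'   clustering is declared degenerate.
#' @return An object of class `metv_config`.
#' @export
metv_config <- function(half_width_mm = 30, epsilon = 1,
                        c = 2L, m = 2, tol = 1e-5, max_iter = 200L, seed = 0L,
                        connectivity = 26, fill_holes = TRUE,
                        min_enhancement = 0.3,
                        c2 = 2L, separation_tol = 1e-6) {
  structure(list(half_width_mm = half_width_mm, epsilon = epsilon,
                 c = as.integer(c), m = m, tol = tol,
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 connectivity = connectivity, fill_holes = fill_holes,
                 min_enhancement = min_enhancement,
                 c2 = as.integer(c2), separation_tol = separation_tol),
            class = "metv_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `voi.half_width_mm`, `features.epsilon`, `fcm.c`, `fcm.m`,
#' `fcm.tol`, `fcm.max_iter`, `fcm.seed`, `fcm.c2`, `mask.connectivity`,
#' `mask.fill_holes`, `mask.min_enhancement`. Missing keys keep their defaults.
#'
#' @param path YAML file.
#' @return A [metv_config()].
#' @export
metv_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- metv_config()
  take <- function(cur, val) if (is.null(val)) cur else val
  cfg$half_width_mm <- take(cfg$half_width_mm, y$voi$half_width_mm)
  cfg$epsilon <- take(cfg$epsilon, y$features$epsilon)
  for (k in c("c", "m", "tol", "max_iter", "seed", "c2")) {
    cfg[[k]] <- take(cfg[[k]], y$fcm[[k]])
  }
  cfg$connectivity <- take(cfg$connectivity, y$mask$connectivity)
  cfg$fill_holes <- take(cfg$fill_holes, y$mask$fill_holes)
  cfg$min_enhancement <- take(cfg$min_enhancement, y$mask$min_enhancement)
  cfg
}

#' Isolate the most-enhancing voxels within a segmented tumor
#'
#' Runs a second fuzzy c-means on the kinetic curves of only the voxels inside
#' the stage-1 tumor mask. The most-enhancing cluster is the one whose centroid
#' attains the greatest peak relative enhancement over the post-contrast times;
#' its hard-assigned voxels form the core mask. No spatial connectivity is
#' imposed: the most-enhancing voxels need not be contiguous, and METV is their
#' aggregate volume. If the tumor holds fewer than `c2` distinct kinetic
#' curves, or the stage-2 centroids collapse onto each other, the clustering is
#' degenerate: the whole tumor is returned as the core with `degenerate = TRUE`
#' and a warning, keeping cohort runs total while making the event auditable.
#'
#' @param seg A [select_tumor_mask()] result.
#' @param features The [relative_enhancement()] features of the same VOI.
#' @param config A [metv_config()].
#' @return A list: `core_mask` (logical, VOI coordinates, subset of the tumor
#'   mask), `n_core_voxels`, `centroid_curves` (stage-2 centroids, one row per
#'   cluster), `degenerate`, `fcm` (the stage-2 `fcm_result`, or `NULL` when
#'   degenerate).
#' @export
most_enhancing_core <- function(seg, features, config = metv_config()) {
  if (!inherits(seg, "tumor_segmentation")) {
    abort("`seg` must be a tumor_segmentation.", class = "metvolume_input_error")
  }
  inmask <- as.vector(seg$mask)
  if (!any(inmask)) {
    abort("Tumor mask is empty.", class = "metvolume_segmentation_error")
  }
  x <- features$matrix[inmask, , drop = FALSE]
  degenerate_core <- function(reason) {
    warn(sprintf("Degenerate stage-2 clustering (%s); METV falls back to the whole tumor.",
                 reason))
    list(core_mask = seg$mask, n_core_voxels = sum(inmask),
         centroid_curves = matrix(colMeans(x), 1), degenerate = TRUE, fcm = NULL)
  }
  if (nrow(x) < config$c2) return(degenerate_core("tumor smaller than cluster count"))
  fcm2 <- tryCatch(
    fcm_cluster(x, c = config$c2, m = config$m, tol = config$tol,
                max_iter = config$max_iter, rng_seed = config$seed),
    metvolume_degenerate_input_error = function(e) NULL
  )
  if (is.null(fcm2)) return(degenerate_core("identical kinetic curves"))
  v <- fcm2$centroids
  sep <- min(stats::dist(v))
  if (sep < config$separation_tol) return(degenerate_core("centroid separation below tolerance"))
  peak <- apply(v, 1, max)
  core_cl <- which.max(peak)
  u <- fcm2$memberships
  rowmax <- do.call(pmax, lapply(seq_len(ncol(u)), function(j) u[, j]))
  in_core <- u[, core_cl] >= rowmax
  core_mask <- array(FALSE, features$dims)
  core_mask[inmask] <- in_core
  list(core_mask = core_mask, n_core_voxels = sum(in_core),
       centroid_curves = v, degenerate = FALSE, fcm = fcm2)
}

#' Aggregate volume of a voxel mask
#'
#' METV is the number of most-enhancing voxels times the voxel volume
#' `dz * dy * dx`, in mm\eqn{^3}. An empty mask is an error, never silently 0.
#'
#' @param core_mask Logical array.
#' @param spacing_mm Voxel spacing `(dz, dy, dx)` in mm, all > 0.
#' @return Volume in mm\eqn{^3}.
#' @export
#' @examples
#' m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
#' compute_metv(m, c(2, 1, 1))  # 2 mm^3
compute_metv <- function(core_mask, spacing_mm) {
  spacing_mm <- as.numeric(spacing_mm)
  if (any(spacing_mm <= 0)) {
    abort("`spacing_mm` must be positive.", class = "metvolume_input_error")
  }
  n <- sum(core_mask)
  if (n == 0) {
    abort("Empty core mask: METV is undefined.", class = "metvolume_segmentation_error")
  }
  n * prod(spacing_mm)
}

with_stage <- function(stage, expr) {
  withCallingHandlers(expr, error = function(e) {
    if (is.null(attr(e, "metv_stage"))) {
      e$message <- sprintf("[stage %s] %s", stage, conditionMessage(e))
      attr(e, "metv_stage") <- stage
      stop(e)
    }
  })
}

#' Most-enhancing tumor volume of one exam
#'
#' The full per-exam pipeline: extract a VOI around the seed point, compute
#' per-voxel relative-enhancement kinetic curves, partition the VOI into tumor
#' and non-tumor by fuzzy c-means, keep the seeded connected tumor component,
#' run a second fuzzy c-means inside the tumor to isolate the most-enhancing
#' voxels, and report their aggregate volume. Fully deterministic given the
#' configuration seeds; errors carry the failing stage in their message.
#'
#' @param exam A [dce_exam()].
#' @param seed 0-based `(z, y, x)` voxel coordinate near the tumor center.
#' @param config A [metv_config()].
#' @return An object of class `metv_result` with `metv_mm3`, `n_core_voxels`,
#'   `core_mask` (VOI coordinates), `centroid_curves`, `degenerate`,
#'   `tumor_n_voxels`, `tumor_volume_mm3`, `voi_offset`, `segmentation`,
#'   `exam_id`.
#' @export
#' @examples
#' ph <- generate_exam(phantom_spec(grid_shape = c(32, 32, 32),
#'                                  tumor_radii_mm = c(9, 9, 9),
#'                                  core_radii_mm = c(4, 4, 4)))
#' res <- exam_metv(ph$exam, ph$seed_point_truth, metv_config(half_width_mm = 14))
#' res$metv_mm3 == ph$true_core_volume_mm3
exam_metv <- function(exam, seed, config = metv_config()) {
  voi <- with_stage("extract_voi", extract_voi(exam, seed, config$half_width_mm))
  feats <- with_stage("relative_enhancement", relative_enhancement(voi, config$epsilon))
  fcm1 <- with_stage("fcm_cluster", fcm_cluster(feats, c = config$c, m = config$m,
                                                tol = config$tol,
                                                max_iter = config$max_iter,
                                                rng_seed = config$seed))
  seg <- with_stage("select_tumor_mask",
                    select_tumor_mask(fcm1, feats, voi, seed,
                                      connectivity = config$connectivity,
                                      fill_holes = config$fill_holes,
                                      min_enhancement = config$min_enhancement))
  core <- with_stage("most_enhancing_core", most_enhancing_core(seg, feats, config))
  metv <- with_stage("compute_metv", compute_metv(core$core_mask, exam$spacing_mm))
  structure(
    list(metv_mm3 = metv,
         n_core_voxels = core$n_core_voxels,
         core_mask = core$core_mask,
         centroid_curves = core$centroid_curves,
         degenerate = core$degenerate,
         tumor_n_voxels = seg$n_voxels,
         tumor_volume_mm3 = seg$n_voxels * prod(exam$spacing_mm),
         voi_offset = voi$offset,
         segmentation = seg,
         times_min = exam$times_min,
         exam_id = exam$exam_id),
    class = "metv_result"
  )
}

#' @export
print.metv_result <- function(x, ...) {
  cat(sprintf("<metv_result '%s'>\n", x$exam_id))
  cat(sprintf("  METV: %.1f mm^3 (%d voxels%s)\n", x$metv_mm3, x$n_core_voxels,
              if (x$degenerate) ", DEGENERATE: whole tumor" else ""))
  cat(sprintf("  tumor: %.1f mm^3 (%d voxels)\n", x$tumor_volume_mm3, x$tumor_n_voxels))
  invisible(x)
}

#' @rdname exam_metv
#' @param x A `metv_result`.
#' @param ... Unused.
#' @export
tidy.metv_result <- function(x, ...) {
  tibble::tibble(exam_id = x$exam_id,
                 metv_mm3 = x$metv_mm3,
                 n_core_voxels = x$n_core_voxels,
                 tumor_volume_mm3 = x$tumor_volume_mm3,
                 degenerate = x$degenerate)
}
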