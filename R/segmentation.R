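# Stage-1 tumor segmentation: hard-assign FCM memberships, keep the seeded
# connected component, fill enclosed holes.

# Linear-index flood fill on a logical 3D array. The array is embedded in a
# FALSE border one voxel thick, so every frontier voxel has all its neighbours
# in-bounds and linear offsets cannot wrap between rows or slices.
flood_component <- function(mask, start, connectivity = 26) {
  d <- dim(mask)
  dp <- d + 2L
  mp <- array(FALSE, dp)
  mp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  offs <- neighbor_offsets(dp, connectivity)
  startp <- as.integer(start) + 2L  # 0-based start -> 1-based in padded array
  lin <- (startp[3] - 1L) * dp[1] * dp[2] + (startp[2] - 1L) * dp[1] + startp[1]
  maskv <- as.logical(mp)
  visited <- logical(length(maskv))
  if (!maskv[lin]) {
    return(array(FALSE, d))
  }
  visited[lin] <- TRUE
  frontier <- lin
  while (length(frontier)) {
    nb <- unique(as.vector(outer(frontier, offs, `+`)))
    nb <- nb[maskv[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  array(visited, dp)[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
}

neighbor_offsets <- function(dp, connectivity) {
  if (connectivity == 26) {
    g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
    g <- g[!(g$dz == 0 & g$dy == 0 & g$dx == 0), ]
    as.integer(g$dz + g$dy * dp[1] + g$dx * dp[1] * dp[2])
  } else if (connectivity == 6) {
    as.integer(c(-1, 1, -dp[1], dp[1], -dp[1] * dp[2], dp[1] * dp[2]))
  } else {
    abort("`connectivity` must be 6 or 26.", class = "metvolume_input_error")
  }
}

# Fill cavities fully enclosed by the mask: flood the background (6-connected)
# from a border layer; background voxels not reached are holes.
fill_enclosed_holes <- function(mask) {
  d <- dim(mask)
  dp <- d + 2L
  bg <- array(TRUE, dp)
  bg[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- !mask
  offs <- neighbor_offsets(dp, 6)
  bgv <- as.logical(bg)
  visited <- logical(length(bgv))
  visited[1L] <- TRUE  # padded corner, always background
  frontier <- 1L
  while (length(frontier)) {
    nb <- unique(as.vector(outer(frontier, offs, `+`)))
    nb <- nb[nb >= 1L & nb <= length(bgv)]
    nb <- nb[bgv[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  reached <- array(visited, dp)[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
  mask | (!mask & !reached)
}

#' Select the tumor mask from a stage-1 clustering
#'
#' Hard-assigns every VOI voxel to its maximum-membership cluster (ties go to
#' the tumor cluster), identifies the tumor cluster as the one whose centroid
#' has the greater first post-contrast relative enhancement, keeps the
#' 26-connected component of tumor-labeled voxels containing the seed (or, if
#' the seed voxel itself was not labeled tumor, the component nearest the
#' seed), and fills fully enclosed holes. If the winning centroid's early
#' enhancement falls below `min_enhancement`, no enhancing lesion is present in
#' the VOI and a segmentation-failure error is raised rather than returning a
#' spurious mask.
#'
#' @param fcm A [fcm_cluster()] result on the VOI's kinetic features.
#' @param features The [relative_enhancement()] features the clustering used.
#' @param voi The [extract_voi()] result.
#' @param seed 0-based `(z, y, x)` seed in exam coordinates (as passed to
#'   [extract_voi()]).
#' @param connectivity 26 (default) or 6.
#' @param fill_holes Fill enclosed holes in the component (default `TRUE`).
#' @param min_enhancement Minimum first post-contrast relative enhancement the
#'   tumor-cluster centroid must reach, a guard against seeding in
#'   non-enhancing tissue.
#' @return An object of class `tumor_segmentation`: `mask` (logical array in
#'   VOI coordinates), `tumor_cluster_id`, `fcm`, `n_voxels`, plus the VOI
#'   bookkeeping needed downstream.
#' @export
select_tumor_mask <- function(fcm, features, voi, seed,
                              connectivity = 26, fill_holes = TRUE,
                              min_enhancement = 0.3) {
  if (!inherits(fcm, "fcm_result")) {
    abort("`fcm` must be an fcm_result.", class = "metvolume_input_error")
  }
  if (!inherits(features, "kinetic_features")) {
    abort("`features` must be kinetic_features.", class = "metvolume_input_error")
  }
  d <- features$dims
  u <- fcm$memberships
  if (nrow(u) != prod(d)) {
    abort("Clustering does not cover the VOI's voxels.", class = "metvolume_input_error")
  }
  first_enh <- fcm$centroids[, 1]
  tumor_cl <- which.max(first_enh)
  if (sum(first_enh == max(first_enh)) > 1L) {
    tumor_cl <- which(first_enh == max(first_enh))[1]
    warn("Tied centroid enhancement; taking the lower cluster index as tumor.")
  }
  if (first_enh[tumor_cl] < min_enhancement) {
    abort(sprintf(
      "Segmentation failure: no enhancing lesion in the VOI (max centroid early enhancement %.3f < %.3f). Check the seed point.",
      first_enh[tumor_cl], min_enhancement),
      class = "metvolume_segmentation_error")
  }
  rowmax <- do.call(pmax, lapply(seq_len(ncol(u)), function(j) u[, j]))
  is_tumor <- u[, tumor_cl] >= rowmax  # ties resolve to the tumor cluster
  if (!any(is_tumor)) {
    abort("Segmentation failure: tumor cluster is empty after hard assignment.",
          class = "metvolume_segmentation_error")
  }
  lab <- array(is_tumor, d)

  seed_voi <- as.integer(seed) - voi$offset
  start <- seed_voi + 1L  # 1-based
  if (!lab[start[1], start[2], start[3]]) {
    idx <- which(lab, arr.ind = TRUE)
    w_mm <- t(t(idx - rep(1, 3)) * voi$spacing_mm)
    seed_mm <- seed_voi * voi$spacing_mm
    start <- as.integer(idx[which.min(colSums((t(w_mm) - seed_mm)^2)), ])
  }
  comp <- flood_component(lab, start - 1L, connectivity = connectivity)
  if (fill_holes) comp <- fill_enclosed_holes(comp)
  structure(
    list(mask = comp,
         tumor_cluster_id = tumor_cl,
         fcm = fcm,
         n_voxels = sum(comp),
         voi_offset = voi$offset,
         spacing_mm = voi$spacing_mm,
         exam_id = voi$exam_id),
    class = "tumor_segmentation"
  )
}

#' @export
print.tumor_segmentation <- function(x, ...) {
  cat(sprintf("<tumor_segmentation '%s': %d voxels (%.1f mm^3), cluster %d>\n",
              x$exam_id, x$n_voxels, x$n_voxels * prod(x$spacing_mm),
              x$tumor_cluster_id))
  invisible(x)
}
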