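#' Extract a body's surface points
#'
#' Surface voxels are body voxels with at least one face-adjacent
#' (6-connectivity) neighbour outside the body; the grid border counts
#' as outside. Returned points are the world coordinates of the surface
#' voxel centers — no sub-voxel interpolation is attempted, so distances
#' derived from these points carry an honest +/- sqrt(3) * spacing
#' discretization error.
#'
#' @param m A [label_mask()].
#' @param body Body name present in the label table.
#' @return n x 3 matrix of world points (mm), ordered lexicographically
#'   by voxel index.
#' @export
extract_surface_points <- function(m, body) {
  bm <- body_mask(m, body)
  surf <- boundary6(bm)
  idx <- which(surf, arr.ind = TRUE) - 1L
  if (nrow(idx) == 0L) {
    stop(sprintf("body '%s' has no voxels", body), call. = FALSE)
  }
  pts <- voxel_to_world(m, idx)
  colnames(pts) <- c("x", "y", "z")
  pts
}

# Chunked exact nearest-neighbour distances from each row of `a` to the
# point set `b`; returns list(dist, j) with the index of the (first)
# nearest b point. Equals the brute-force all-pairs minimum exactly.
nn_dist <- function(a, b, chunk = 2048L) {
  nb2 <- rowSums(b^2)
  n <- nrow(a)
  dist <- numeric(n); jmin <- integer(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    ac <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(ac^2), nb2, "+") - 2 * tcrossprod(ac, b)
    j <- max.col(-d2, ties.method = "first")
    dist[s:e] <- sqrt(pmax(d2[cbind(seq_len(e - s + 1L), j)], 0))
    jmin[s:e] <- j
  }
  list(dist = dist, j = jmin)
}

lex_order <- function(p) order(p[, 1], p[, 2], p[, 3])

#' Joint-gap distance spanned by a dowel
#'
#' The joint gap is the closest Euclidean distance between the two
#' opposing bone surfaces, restricted to surface points lying inside the
#' dowel cylinder (closest-pair reading: for an oblique dowel the gap is
#' still the true surface-to-surface distance, not the longer traversal
#' along the axis). Ties are broken deterministically by the
#' lexicographically smallest pair of world coordinates.
#'
#' @param surf_a,surf_b n x 3 matrices of surface points (mm), one per
#'   body (e.g. from [extract_surface_points()]).
#' @param roi The dowel, from [build_cylinder()].
#' @param specimen,trajectory Identifiers carried into the result.
#' @param contact_spacing_mm Optional voxel spacing; when the gap does
#'   not exceed it the surfaces are in (or near) face contact, which is
#'   reported with a caveat message since center-to-center distances
#'   cannot fall below one spacing.
#' @return Object of class `gap_result`: `gap_mm`, `point_a`, `point_b`,
#'   `n_a`, `n_b`, identifiers.
#' @export
joint_gap_distance <- function(surf_a, surf_b, roi,
                               specimen = NA_character_,
                               trajectory = roi$trajectory$name,
                               contact_spacing_mm = NULL) {
  a <- restrict_to_cylinder(surf_a, roi, "first")
  b <- restrict_to_cylinder(surf_b, roi, "second")
  # lexicographic pre-sort makes the reported closest pair deterministic
  a <- a[lex_order(a), , drop = FALSE]
  b <- b[lex_order(b), , drop = FALSE]
  nn <- nn_dist(a, b)
  gap <- min(nn$dist)
  cand <- which(nn$dist <= gap + 1e-12)
  i <- cand[1L]
  res <- structure(list(specimen = specimen, trajectory = trajectory,
                        gap_mm = gap,
                        point_a = unname(a[i, ]),
                        point_b = unname(b[nn$j[i], ]),
                        n_a = nrow(a), n_b = nrow(b)),
                   class = "gap_result")
  if (!is.null(contact_spacing_mm) &&
      gap <= max(contact_spacing_mm) + 1e-9) {
    message(sprintf(
      "trajectory %s: surfaces are in voxel-face contact (gap %.3f mm = one voxel spacing; true gap may be 0)",
      trajectory, gap))
  }
  res
}

restrict_to_cylinder <- function(pts, roi, which_body) {
  pts <- rbind_points(pts)
  keep <- points_in_cylinder(roi, pts)
  if (!any(keep)) {
    stop(sprintf(
      "trajectory does not span the joint: no %s-body surface points inside dowel '%s'",
      which_body, roi$trajectory$name), call. = FALSE)
  }
  pts[keep, , drop = FALSE]
}

#' @export
print.gap_result <- function(x, ...) {
  cat(sprintf("<gap_result> %s: gap %.3f mm (%d vs %d surface points in dowel)\n",
              x$trajectory, x$gap_mm, x$n_a, x$n_b))
  invisible(x)
}

#' Per-point joint-gap map within a dowel
#'
#' For every first-surface point inside the dowel, the distance to its
#' nearest second-surface point inside the dowel. The minimum of the
#' field equals [joint_gap_distance()] exactly.
#'
#' @inheritParams joint_gap_distance
#' @return Data frame with columns `x`, `y`, `z` (the first-surface
#'   point, mm) and `distance` (mm), suitable for point-cloud export.
#' @export
gap_map <- function(surf_a, surf_b, roi) {
  a <- restrict_to_cylinder(surf_a, roi, "first")
  b <- restrict_to_cylinder(surf_b, roi, "second")
  a <- a[lex_order(a), , drop = FALSE]
  nn <- nn_dist(a, b)
  data.frame(x = a[, 1], y = a[, 2], z = a[, 3], distance = nn$dist)
}
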