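#' Implant trajectory defined by a fiducial pair
#'
#' @param name Trajectory name, one of `top`, `middle`, `bottom` (lateral)
#'   or `PL1`, `PL2` (posterolateral).
#' @param side Anatomical side, `"left"` or `"right"`.
#' @param start,end World coordinates (mm) of the proximal entry fiducial
#'   and the projected distal implant tip.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(name, side, start, end) {
  name <- match.arg(name, c("top", "middle", "bottom", "PL1", "PL2"))
  side <- match.arg(side, c("left", "right"))
  start <- as.numeric(start); end <- as.numeric(end)
  stopifnot(length(start) == 3L, length(end) == 3L)
  stopifnot_finite(c(start, end), "fiducial coordinates")
  if (sqrt(sum((end - start)^2)) <= 0) {
    stop("start and end fiducials coincide: degenerate trajectory axis",
         call. = FALSE)
  }
  structure(list(name = name, side = side, start = start, end = end),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s (%s): (%s) -> (%s) mm\n", x$name, x$side,
              paste(format(x$start, digits = 4), collapse = ", "),
              paste(format(x$end, digits = 4), collapse = ", ")))
  invisible(x)
}

#' Build the virtual cylindrical dowel for a trajectory
#'
#' The dowel is the closed finite cylinder whose axis is the segment
#' between the two fiducials — it does not extend beyond either landmark
#' — with the given diameter (12 mm by default, the implant size the
#' analysis models).
#'
#' @param t A [trajectory()].
#' @param diameter_mm Cylinder diameter in mm (> 0).
#' @return Object of class `cylinder_roi` with fields `trajectory`,
#'   `diameter_mm`, `radius_mm`, `axis` (unit vector), `length_mm`.
#' @export
build_cylinder <- function(t, diameter_mm = 12) {
  stopifnot(inherits(t, "trajectory"))
  if (!is.finite(diameter_mm) || diameter_mm <= 0) {
    stop("diameter must be > 0", call. = FALSE)
  }
  d <- t$end - t$start
  len <- sqrt(sum(d^2))
  if (len <= 0) stop("degenerate trajectory axis", call. = FALSE)
  structure(list(trajectory = t, diameter_mm = diameter_mm,
                 radius_mm = diameter_mm / 2, axis = d / len,
                 length_mm = len),
            class = "cylinder_roi")
}

#' @export
print.cylinder_roi <- function(x, ...) {
  cat(sprintf("<cylinder_roi> %s: diameter %.1f mm, length %.1f mm\n",
              x$trajectory$name, x$diameter_mm, x$length_mm))
  invisible(x)
}

#' Test world points for membership in a dowel
#'
#' A point belongs to the dowel iff its perpendicular distance from the
#' axis is `<= radius` (closed boundary) and its axial projection falls
#' in `[0, length]`.
#'
#' @param roi A [build_cylinder()] result.
#' @param p n x 3 matrix (or length-3 vector) of world points in mm.
#' @return Logical vector of length n.
#' @export
points_in_cylinder <- function(roi, p) {
  p <- rbind_points(p)
  w <- sweep(p, 2L, roi$trajectory$start, "-")
  t_ax <- as.vector(w %*% roi$axis)
  perp2 <- rowSums(w^2) - t_ax^2
  tol <- 1e-7
  t_ax >= -tol & t_ax <= roi$length_mm + tol &
    perp2 <= roi$radius_mm^2 + tol
}

#' Materialize a dowel as a voxel mask
#'
#' A voxel is included iff its *center* satisfies the cylinder membership
#' test (whole-voxel counting, no partial-volume weighting). A dowel
#' lying entirely outside the grid yields an all-`FALSE` mask with a
#' warning, not an error.
#'
#' @param roi A [build_cylinder()] result.
#' @param v A [voxel_volume()] or [label_mask()] sharing the dowel's
#'   world frame.
#' @return Logical 3D array congruent with `v`.
#' @export
cylinder_mask <- function(roi, v) {
  g <- geometry_of(v)
  s <- roi$trajectory$start - v$origin
  # direction columns scaled by spacing give world offsets per index step
  dcol <- v$direction * rep(v$spacing, each = 3L)
  # axial projection t = (c - start) . axis is separable across axes
  a_ax <- as.vector(crossprod(dcol, roi$axis))   # per-axis contribution
  t0 <- -sum(s * roi$axis)
  t_ax <- t0 +
    outer(outer((seq_len(g$dim[1]) - 1) * a_ax[1],
                (seq_len(g$dim[2]) - 1) * a_ax[2], "+"),
          (seq_len(g$dim[3]) - 1) * a_ax[3], "+")
  # squared distance from start: |c - start|^2, also separable because
  # direction columns are orthonormal
  off <- as.vector(crossprod(v$direction, s)) / v$spacing # start, index units
  d2 <- outer(outer(((seq_len(g$dim[1]) - 1) - off[1])^2 * v$spacing[1]^2,
                    ((seq_len(g$dim[2]) - 1) - off[2])^2 * v$spacing[2]^2,
                    "+"),
              ((seq_len(g$dim[3]) - 1) - off[3])^2 * v$spacing[3]^2, "+")
  perp2 <- d2 - t_ax^2
  tol <- 1e-7
  mask <- t_ax >= -tol & t_ax <= roi$length_mm + tol &
    perp2 <= roi$radius_mm^2 + tol
  if (!any(mask)) {
    warning(sprintf("dowel '%s' does not intersect the voxel grid",
                    roi$trajectory$name), call. = FALSE)
  }
  mask
}

#' Split a dowel mask by anatomical body
#'
#' Partitions the cylinder voxels by the label mask: one boolean grid per
#' labelled body (pairwise disjoint; union = cylinder intersected with
#' the labelled bodies) plus an `extra_osseous` grid for cylinder voxels
#' outside every body.
#'
#' @param mask Logical 3D array (e.g. from [cylinder_mask()]).
#' @param m A [label_mask()] congruent with `mask`.
#' @return Named list: one logical array per body in `m`'s table, plus
#'   `extra_osseous`.
#' @export
split_by_body <- function(mask, m) {
  stopifnot(inherits(m, "label_mask"), is.logical(mask))
  if (!all(dim(mask) == dim(m$labels))) {
    stop("dowel mask and label mask are not congruent", call. = FALSE)
  }
  out <- lapply(m$table, function(lab) mask & m$labels == lab)
  names(out) <- names(m$table)
  known <- m$labels %in% m$table
  out$extra_osseous <- mask & !array(known, dim = dim(mask))
  out
}

#' Read and write fiducial pairs as JSON
#'
#' Fiducials travel as a JSON list of
#' `{name, side, start:[x,y,z], end:[x,y,z]}` objects, coordinates in
#' world mm.
#'
#' @param trajectories Named or unnamed list of [trajectory()] objects.
#' @param path JSON file path.
#' @return `read_fiducials()` returns a named list of trajectories.
#' @export
write_fiducials <- function(trajectories, path) {
  recs <- lapply(trajectories, function(t) {
    list(name = t$name, side = t$side, start = t$start, end = t$end)
  })
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fiducials
#' @export
read_fiducials <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(recs, function(r) {
    trajectory(r$name, r$side, unlist(r$start), unlist(r$end))
  })
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}
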