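#' Digital phantom specification
#'
#' Defines the synthetic scene used to exercise the full analysis without
#' clinical CT data: two slab-like bodies ("ilium" and "sacrum"), each
#' with a cortical-HU shell and a cancellous-HU core, separated by a
#' planar joint gap filled with soft-tissue HU. The grid's x axis is the
#' gap normal (lateral to medial), y runs anterior to posterior, and z is
#' vertical. A posterior region of the joint may be given a wider gap
#' (the ligamentous portion crossed by posterolateral trajectories), and
#' the sacral face may be tilted about the vertical axis so the gap
#' widens linearly along y.
#'
#' Nominal gaps are snapped to the voxel grid so the center-to-center
#' distance between opposing boundary voxels equals `round(gap/spacing)`
#' voxels exactly; at `gap_mm = 0` the bodies are in face contact
#' (adjacent voxel centers one spacing apart).
#'
#' @param shape Grid extents (voxels), length 3.
#' @param spacing_mm Voxel size in mm (scalar or length 3).
#' @param gap_mm Nominal joint gap (mm) in the anterior region crossed by
#'   the lateral trajectories.
#' @param posterior_gap_mm Gap (mm) in the posterior (ligamentous) region
#'   crossed by the posterolateral trajectories; wider than the anterior
#'   gap by default.
#' @param tilt_deg Tilt of the sacral joint face about the vertical axis
#'   (degrees); 0 keeps both faces parallel.
#' @param margin_mm Background margin between the bodies and the grid
#'   edge (mm).
#' @param joint_x_frac Fractional x position of the ilium-side joint face.
#' @param posterior_frac Fractional y position where the posterior gap
#'   region begins.
#' @param shell_mm Cortical shell thickness per body (named, mm).
#' @param hu_cortical,hu_cancellous,hu_marrow,hu_soft_tissue,hu_background
#'   Mean HU of each material; `hu_cancellous` may be named per body.
#' @param marrow_fraction Fraction of core voxels replaced by
#'   sub-threshold "marrow" HU, so the ROI total exceeds the
#'   cortical + cancellous count as in real bone.
#' @param noise_sd SD of additive i.i.d. Gaussian acquisition noise (HU).
#' @param oblique_deg Angle of the posterolateral trajectory axes from
#'   the gap normal (degrees).
#' @param inserts For [make_calibration_phantom()]: list of
#'   `list(hu=, center=c(x,y) mm, radius= mm)` cylindrical inserts.
#'   Defaults to two inserts at the cancellous and cortical calibration
#'   densities (219 and 867 HU).
#' @param seed Mandatory RNG seed; identical spec + seed gives a
#'   voxelwise-identical phantom.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 72, 72), spacing_mm = 0.6,
                         gap_mm = 1.2, posterior_gap_mm = 4.8,
                         tilt_deg = 0, margin_mm = 1.0,
                         joint_x_frac = 0.45, posterior_frac = 0.55,
                         shell_mm = c(ilium = 1.8, sacrum = 0.6),
                         hu_cortical = 1400,
                         hu_cancellous = c(ilium = 450, sacrum = 330),
                         hu_marrow = 100, hu_soft_tissue = 30,
                         hu_background = -800, marrow_fraction = 0.5,
                         noise_sd = 5, oblique_deg = 40,
                         inserts = NULL, seed) {
  if (missing(seed) || !is.finite(seed)) {
    stop("a finite integer `seed` is mandatory", call. = FALSE)
  }
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 4L))
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
  if (gap_mm < 0 || posterior_gap_mm < 0) {
    stop("gap must be >= 0", call. = FALSE)
  }
  if (length(shell_mm) == 1L) {
    shell_mm <- c(ilium = unname(shell_mm), sacrum = unname(shell_mm))
  }
  shell_mm <- shell_mm[c("ilium", "sacrum")]
  if (anyNA(shell_mm) || any(shell_mm <= 0)) {
    stop("shell_mm must give a positive thickness for ilium and sacrum",
         call. = FALSE)
  }
  if (length(hu_cancellous) == 1L) {
    hu_cancellous <- c(ilium = unname(hu_cancellous),
                       sacrum = unname(hu_cancellous))
  }
  hu_cancellous <- hu_cancellous[c("ilium", "sacrum")]
  if (!(hu_cortical > max(hu_cancellous) &&
        min(hu_cancellous) > hu_soft_tissue)) {
    stop("HU ordering violated: need cortical > cancellous > soft tissue",
         call. = FALSE)
  }
  if (marrow_fraction < 0 || marrow_fraction >= 1) {
    stop("marrow_fraction must be in [0, 1)", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(inserts)) {
    xl <- shape[1] * spacing_mm[1]; yl <- shape[2] * spacing_mm[2]
    r <- min(4, xl / 6, yl / 6)
    inserts <- list(list(hu = 219, center = c(0.3 * xl, 0.5 * yl), radius = r),
                    list(hu = 867, center = c(0.7 * xl, 0.5 * yl), radius = r))
  }
  structure(list(shape = shape, spacing_mm = spacing_mm, gap_mm = gap_mm,
                 posterior_gap_mm = posterior_gap_mm, tilt_deg = tilt_deg,
                 margin_mm = margin_mm, joint_x_frac = joint_x_frac,
                 posterior_frac = posterior_frac, shell_mm = shell_mm,
                 hu_cortical = hu_cortical, hu_cancellous = hu_cancellous,
                 hu_marrow = hu_marrow, hu_soft_tissue = hu_soft_tissue,
                 hu_background = hu_background,
                 marrow_fraction = marrow_fraction, noise_sd = noise_sd,
                 oblique_deg = oblique_deg, inserts = inserts,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Index-space geometry shared by the phantom builder and the landmark
# generator. All indices are 0-based; gaps are snapped so that opposing
# boundary-voxel centers are exactly k*spacing apart.
phantom_geometry <- function(spec) {
  sp <- spec$spacing_mm
  n <- spec$shape
  len <- n * sp
  m <- spec$margin_mm
  lo <- ceiling(m / sp - 1e-9)
  hi <- ceiling((len - m) / sp - 1e-9) - 1
  if (any(hi <= lo)) stop("margin leaves no room for bodies", call. = FALSE)
  x_face <- spec$joint_x_frac * len[1]
  iL <- ceiling(x_face / sp[1] - 1e-9) - 1          # last ilium column
  k_ant <- max(1L, as.integer(round(spec$gap_mm / sp[1])))
  k_post <- max(1L, as.integer(round(spec$posterior_gap_mm / sp[1])))
  iS_ant <- iL + k_ant                               # first sacrum column
  iS_post <- iL + k_post
  n_sh <- pmax(1L, as.integer(round(spec$shell_mm / sp[1])))
  names(n_sh) <- names(spec$shell_mm)
  min_depth <- 2L * n_sh + 2L
  if (iL - lo[1] + 1L < min_depth[["ilium"]]) {
    stop("ilium too thin for its cortical shell (gap/joint position too large for grid)",
         call. = FALSE)
  }
  if (hi[1] - max(iS_ant, iS_post) + 1L < min_depth[["sacrum"]]) {
    stop("sacrum too thin: joint gap too large for the grid", call. = FALSE)
  }
  y_split <- m + spec$posterior_frac * (len[2] - 2 * m)
  j_split <- ceiling(y_split / sp[2] - 1e-9)         # first posterior row
  list(sp = sp, len = len, lo = lo, hi = hi, iL = iL,
       k_ant = k_ant, k_post = k_post, iS_ant = iS_ant, iS_post = iS_post,
       n_sh = n_sh, j_split = j_split, y_split = y_split,
       gap_center_ant = k_ant * sp[1], gap_center_post = k_post * sp[1])
}

#' Generate a two-body joint phantom
#'
#' Builds the labelled HU volume described by a [phantom_spec()]: two
#' slab bodies with cortical shells and cancellous cores (a configurable
#' fraction of core voxels is sub-threshold "marrow"), a soft-tissue
#' joint gap, and additive Gaussian noise. Ground-truth voxel counts and
#' achieved gap widths are attached as attribute `"ground_truth"`.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `volume` ([voxel_volume()]) and `mask`
#'   ([label_mask()] with bodies `ilium` = 1, `sacrum` = 2).
#' @export
make_two_body_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_geometry(spec)
  n <- spec$shape
  labels <- array(0L, dim = n)
  jj <- (g$lo[2]):(g$hi[2]); kk <- (g$lo[3]):(g$hi[3])
  labels[(g$lo[1]:g$iL) + 1L, jj + 1L, kk + 1L] <- 1L
  tilt <- tan(spec$tilt_deg * pi / 180)
  y_anchor <- (spec$margin_mm + g$y_split) / 2
  for (j in jj) {
    base <- if (j < g$j_split) g$iS_ant else g$iS_post
    off <- as.integer(round(tilt * (j * g$sp[2] - y_anchor) / g$sp[1]))
    iS <- min(max(base + off, g$iL + 1L), g$hi[1] - 1L)
    labels[(iS:g$hi[1]) + 1L, j + 1L, kk + 1L] <- 2L
  }
  hu <- array(spec$hu_background, dim = n)
  inbox <- array(FALSE, dim = n)
  inbox[(g$lo[1]:g$hi[1]) + 1L, jj + 1L, kk + 1L] <- TRUE
  hu[inbox & labels == 0L] <- spec$hu_soft_tissue

  truth <- list()
  marrow_idx <- list()
  with_seed(spec$seed, {
    for (body in c("ilium", "sacrum")) {
      lab <- if (body == "ilium") 1L else 2L
      bm <- labels == lab
      core <- erode6(bm, g$n_sh[[body]])
      n_core <- sum(core)
      if (n_core == 0L) {
        stop(sprintf("cortical shell thicker than the %s body", body),
             call. = FALSE)
      }
      shell <- bm & !core
      hu[shell] <- spec$hu_cortical
      hu[core] <- spec$hu_cancellous[[body]]
      n_marrow <- as.integer(round(spec$marrow_fraction * n_core))
      ci <- which(core)
      mi <- if (n_marrow > 0L) sort(sample(ci, n_marrow)) else integer(0)
      hu[mi] <- spec$hu_marrow
      truth[[body]] <- list(n_total = sum(bm), n_cortical = sum(shell),
                            n_cancellous = n_core - n_marrow,
                            n_marrow = n_marrow)
    }
    if (spec$noise_sd > 0) {
      hu <- hu + array(stats::rnorm(prod(n), 0, spec$noise_sd), dim = n)
    }
  })
  truth$gap_center_mm <- g$gap_center_ant
  truth$posterior_gap_center_mm <- g$gap_center_post
  truth$gap_nominal_mm <- spec$gap_mm
  vol <- voxel_volume(hu, g$sp)
  msk <- label_mask(labels, c(ilium = 1L, sacrum = 2L), g$sp)
  structure(list(volume = vol, mask = msk),
            ground_truth = truth, geometry = g, spec = spec,
            class = "sij_phantom")
}

#' @export
print.sij_phantom <- function(x, ...) {
  gt <- attr(x, "ground_truth")
  cat(sprintf("<sij_phantom> %s voxels; anterior gap %.2f mm, posterior %.2f mm (center convention)\n",
              paste(dim(x$volume$data), collapse = "x"),
              gt$gap_center_mm, gt$posterior_gap_center_mm))
  invisible(x)
}

#' Generate a density-calibration phantom
#'
#' Cylindrical inserts of uniform, known HU (by default the cancellous
#' and cortical calibration densities 219 and 867 HU) embedded in a
#' uniform background, mirroring the density phantoms scanned alongside
#' specimens to calibrate the classification thresholds.
#'
#' @param spec A [phantom_spec()] with at least one entry in `inserts`.
#' @return List with `volume` and `mask`; inserts are labelled
#'   `calibration_insert_1`, `calibration_insert_2`, ...
#' @export
make_calibration_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(spec$inserts) < 1L) {
    stop("at least one calibration insert must be defined", call. = FALSE)
  }
  n <- spec$shape; sp <- spec$spacing_mm
  xc <- (seq_len(n[1]) - 1) * sp[1]
  yc <- (seq_len(n[2]) - 1) * sp[2]
  zc <- (seq_len(n[3]) - 1) * sp[3]
  m <- spec$margin_mm
  z_ok <- zc >= m & zc < n[3] * sp[3] - m
  if (!any(z_ok)) z_ok <- rep(TRUE, n[3])
  labels <- array(0L, dim = n)
  hu <- array(spec$hu_background, dim = n)
  for (k in seq_along(spec$inserts)) {
    ins <- spec$inserts[[k]]
    d2 <- outer((xc - ins$center[1])^2, (yc - ins$center[2])^2, "+")
    disc <- d2 <= ins$radius^2 + 1e-9
    if (!any(disc)) {
      stop(sprintf("calibration insert %d lies outside the grid", k),
           call. = FALSE)
    }
    sel <- array(FALSE, dim = n)
    sel[, , z_ok] <- disc
    if (any(labels[sel] != 0L)) {
      stop(sprintf("calibration insert %d overlaps another insert", k),
           call. = FALSE)
    }
    labels[sel] <- k
    hu[sel] <- ins$hu
  }
  if (spec$noise_sd > 0) {
    with_seed(spec$seed,
              hu <- hu + array(stats::rnorm(prod(n), 0, spec$noise_sd),
                               dim = n))
  }
  tab <- stats::setNames(seq_along(spec$inserts),
                         paste0("calibration_insert_", seq_along(spec$inserts)))
  list(volume = voxel_volume(hu, sp), mask = label_mask(labels, tab, sp))
}

#' Generate trajectory landmarks for a phantom
#'
#' Emulates the fiducial pairs a surgeon would place for the five implant
#' trajectories: the three lateral dowels (top/middle/bottom) cross the
#' joint parallel to the gap normal at the anterior crossing region,
#' while the two posterolateral dowels (PL1/PL2) cross obliquely (at
#' `oblique_deg` from the normal) through the posterior, typically
#' wider-gap region. Each pair starts outside the ilium on its entry side
#' and ends inside the sacrum.
#'
#' @param spec The [phantom_spec()] the phantom was generated from.
#' @param trajectories Subset of `c("top","middle","bottom","PL1","PL2")`.
#' @param phantom Optional phantom from [make_two_body_phantom()] (same
#'   spec); when supplied, each trajectory's dowel is verified to
#'   intersect both bodies and an error is raised otherwise.
#' @param diameter_mm Dowel diameter used for the verification (mm).
#' @param side Anatomical side recorded on the trajectories.
#' @return Named list of [trajectory()] objects.
#' @export
make_trajectory_landmarks <- function(spec,
                                      trajectories = c("top", "middle",
                                                       "bottom", "PL1", "PL2"),
                                      phantom = NULL, diameter_mm = 12,
                                      side = "left") {
  stopifnot(inherits(spec, "phantom_spec"))
  trajectories <- match.arg(trajectories,
                            c("top", "middle", "bottom", "PL1", "PL2"),
                            several.ok = TRUE)
  g <- phantom_geometry(spec)
  sp <- g$sp; m <- spec$margin_mm
  x_start <- max(0, (g$lo[1] - 1)) * sp[1]
  y_lat <- (m + g$y_split) / 2
  y_pl <- (g$y_split + g$len[2] - m) / 2
  z_mid <- g$len[3] / 2
  zh <- (g$len[3] - 2 * m) / 2
  dz <- max(0, min(10, zh - diameter_mm / 2 - 1))
  x_end_lat <- (g$iS_ant + 0.7 * (g$hi[1] - g$iS_ant)) * sp[1]
  phi <- spec$oblique_deg * pi / 180
  # posterolateral dowels descend in z while crossing, keeping a constant
  # y inside the posterior gap region
  axis_pl <- c(cos(phi), 0, -sin(phi))
  q_x <- (g$iL + g$iS_post) / 2 * sp[1]
  x_end_pl <- (g$iS_post + 0.6 * (g$hi[1] - g$iS_post)) * sp[1]

  make_one <- function(name) {
    if (name %in% c("top", "middle", "bottom")) {
      z <- z_mid + switch(name, top = dz, middle = 0, bottom = -dz)
      trajectory(name, side, c(x_start, y_lat, z), c(x_end_lat, y_lat, z))
    } else {
      z <- z_mid + switch(name, PL1 = dz / 2, PL2 = -dz / 2)
      q <- c(q_x, y_pl, z)
      L2 <- min((x_end_pl - q_x) / cos(phi), (z - m - 2) / sin(phi))
      L1 <- min((q_x - x_start) / cos(phi),
                (g$len[3] - sp[3] - z) / sin(phi))
      if (L2 <= 0 || L1 <= 0) {
        stop(sprintf("oblique trajectory %s does not fit the grid", name),
             call. = FALSE)
      }
      trajectory(name, side, q - L1 * axis_pl, q + L2 * axis_pl)
    }
  }
  out <- stats::setNames(lapply(trajectories, make_one), trajectories)
  if (!is.null(phantom)) {
    for (tr in out) {
      roi <- build_cylinder(tr, diameter_mm)
      cm <- suppressWarnings(cylinder_mask(roi, phantom$volume))
      parts <- split_by_body(cm, phantom$mask)
      if (sum(parts$ilium) == 0L || sum(parts$sacrum) == 0L) {
        stop(sprintf("trajectory %s fails to intersect both bodies",
                     tr$name), call. = FALSE)
      }
    }
  }
  out
}
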