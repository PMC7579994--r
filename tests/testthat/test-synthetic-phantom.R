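test_that("same spec and seed give voxelwise-identical phantoms", {
  sp <- small_spec(seed = 7, noise_sd = 5)
  p1 <- make_two_body_phantom(sp)
  p2 <- make_two_body_phantom(sp)
  expect_identical(p1$volume$data, p2$volume$data)
  expect_identical(p1$mask$labels, p2$mask$labels)
})

test_that("noise-free phantoms contain exactly the stated HU values", {
  sp <- small_spec(seed = 3)
  ph <- make_two_body_phantom(sp)
  got <- sort(unique(as.vector(ph$volume$data)))
  want <- sort(unique(c(sp$hu_background, sp$hu_soft_tissue, sp$hu_marrow,
                        unname(sp$hu_cancellous), sp$hu_cortical)))
  expect_identical(got, want)
})

test_that("constructed gap is exact between boundary voxel centers", {
  # brute force over all pairs of boundary-voxel centers, small grid
  sp <- small_spec(seed = 5, shape = c(48, 20, 20), gap_mm = 6,
                   posterior_gap_mm = 6, spacing_mm = 0.5)
  ph <- make_two_body_phantom(sp)
  sa <- extract_surface_points(ph$mask, "ilium")
  sb <- extract_surface_points(ph$mask, "sacrum")
  expect_equal(oracle_min_dist(sa, sb), 6.0, tolerance = 1e-9)
})

test_that("bodies in face contact at nominal gap zero", {
  sp <- small_spec(seed = 5, shape = c(48, 20, 20), gap_mm = 0,
                   posterior_gap_mm = 0, spacing_mm = 0.5)
  ph <- make_two_body_phantom(sp)
  # adjacent voxel centers: one spacing apart under the center convention
  sa <- extract_surface_points(ph$mask, "ilium")
  sb <- extract_surface_points(ph$mask, "sacrum")
  expect_equal(oracle_min_dist(sa, sb), 0.5, tolerance = 1e-9)
  expect_equal(attr(ph, "ground_truth")$gap_nominal_mm, 0)
})

test_that("calibration inserts have exact means noise-free, unbiased under noise", {
  one_insert <- list(list(hu = 219, center = c(7.2, 7.2), radius = 5))
  sp0 <- phantom_spec(shape = c(48, 48, 24), spacing_mm = 0.3, noise_sd = 0,
                      inserts = one_insert, seed = 1)
  cal <- make_calibration_phantom(sp0)
  ins <- body_mask(cal$mask, "calibration_insert_1")
  expect_gt(sum(ins), 1e4)
  expect_equal(mean(cal$volume$data[ins]), 219, tolerance = 1e-12)

  # with sigma = 3 noise, the ROI mean stays within 3 standard errors
  for (s in 1:5) {
    spn <- phantom_spec(shape = c(48, 48, 24), spacing_mm = 0.3,
                        noise_sd = 3, inserts = one_insert, seed = s)
    caln <- make_calibration_phantom(spn)
    m <- mean(caln$volume$data[body_mask(caln$mask, "calibration_insert_1")])
    expect_lt(abs(m - 219), 1)
  }
})

test_that("degenerate phantom requests are rejected", {
  expect_error(make_calibration_phantom(small_spec(seed = 1, inserts = list())),
               "at least one")
  overlapping <- list(list(hu = 219, center = c(10, 10), radius = 5),
                      list(hu = 867, center = c(13, 10), radius = 5))
  expect_error(
    make_calibration_phantom(small_spec(seed = 1, inserts = overlapping)),
    "overlaps")
  expect_error(make_two_body_phantom(small_spec(seed = 1, gap_mm = 25,
                                                posterior_gap_mm = 25)),
               "too large|too thin")
  expect_error(make_two_body_phantom(small_spec(seed = 1,
                                                shell_mm = c(ilium = 8, sacrum = 8))),
               "shell")
  expect_error(phantom_spec(hu_cortical = 100, seed = 1), "ordering")
  expect_error(phantom_spec(), "seed")
})

test_that("trajectory landmarks cross both bodies with the stated geometry", {
  sp <- small_spec(seed = 9, noise_sd = 5)
  ph <- make_two_body_phantom(sp)
  fids <- make_trajectory_landmarks(sp, phantom = ph)
  expect_named(fids, c("top", "middle", "bottom", "PL1", "PL2"))
  normal <- c(1, 0, 0)
  for (nm in names(fids)) {
    roi <- build_cylinder(fids[[nm]])
    ang <- acos(abs(sum(roi$axis * normal))) * 180 / pi
    if (nm %in% c("top", "middle", "bottom")) {
      expect_lt(ang, 5)
    } else {
      expect_equal(ang, sp$oblique_deg, tolerance = 1e-6)
    }
    parts <- split_by_body(cylinder_mask(roi, ph$volume), ph$mask)
    expect_gte(sum(parts$ilium), 100)
    expect_gte(sum(parts$sacrum), 100)
    # end fiducial sits inside the sacrum; start outside both bodies
    iend <- round(world_to_voxel(ph$mask, fids[[nm]]$end)) + 1
    expect_identical(ph$mask$labels[iend[1], iend[2], iend[3]], 2L)
    istart <- round(world_to_voxel(ph$mask, fids[[nm]]$start)) + 1
    if (all(istart >= 1 & istart <= dim(ph$mask$labels))) {
      expect_identical(ph$mask$labels[istart[1], istart[2], istart[3]], 0L)
    }
  }
})

test_that("body voxel counts scale with spacing^-3", {
  spA <- small_spec(seed = 2, shape = c(64, 48, 48), spacing_mm = 0.5)
  spB <- small_spec(seed = 2, shape = c(128, 96, 96), spacing_mm = 0.25)
  gtA <- attr(make_two_body_phantom(spA), "ground_truth")
  gtB <- attr(make_two_body_phantom(spB), "ground_truth")
  for (body in c("ilium", "sacrum")) {
    vA <- gtA[[body]]$n_total * 0.5^3
    vB <- gtB[[body]]$n_total * 0.25^3
    expect_lt(abs(vA - vB) / vB, 0.02)
  }
})

test_that("downstream metrics recover the constructed ground truth", {
  th <- density_thresholds()
  for (s in 1:5) {
    set.seed(s)
    g <- runif(1, 1, 8)
    sp <- small_spec(seed = s, gap_mm = g, posterior_gap_mm = g)
    ph <- make_two_body_phantom(sp)
    gt <- attr(ph, "ground_truth")
    # noise-free bone fraction equals constructed voxel proportions exactly
    for (body in c("ilium", "sacrum")) {
      mt <- compute_roi_metrics(ph$volume, body_mask(ph$mask, body), th)
      expect_identical(mt$n_total, gt[[body]]$n_total)
      expect_identical(mt$n_cortical, gt[[body]]$n_cortical)
      expect_identical(mt$n_cancellous, gt[[body]]$n_cancellous)
      want_bf <- (gt[[body]]$n_cortical + gt[[body]]$n_cancellous) /
        gt[[body]]$n_total
      expect_equal(mt$bone_fraction, want_bf, tolerance = 1e-12)
    }
    # joint gap recovered within the sqrt(3)*spacing discretization bound
    fid <- make_trajectory_landmarks(sp, "middle", phantom = ph)
    roi <- build_cylinder(fid$middle)
    gr <- joint_gap_distance(extract_surface_points(ph$mask, "ilium"),
                             extract_surface_points(ph$mask, "sacrum"), roi)
    expect_lte(abs(gr$gap_mm - g), sqrt(3) * 0.5)
  }
})
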