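test_that("surface extraction: cube, single voxel, and analytic slab area", {
  labs <- array(0L, dim = c(5, 5, 5))
  labs[2:4, 2:4, 2:4] <- 1L
  m <- label_mask(labs, c(ilium = 1L), 1)
  expect_identical(nrow(extract_surface_points(m, "ilium")), 26L)

  labs1 <- array(0L, dim = c(3, 3, 3)); labs1[2, 2, 2] <- 1L
  m1 <- label_mask(labs1, c(ilium = 1L), 1)
  expect_identical(nrow(extract_surface_points(m1, "ilium")), 1L)
  expect_error(extract_surface_points(m1, "femur"), "unknown body")

  # slab of 30 x 20 x 20 mm at 0.5 mm: count ~ area / spacing^2
  labs2 <- array(0L, dim = c(70, 50, 50))
  labs2[2:61, 2:41, 2:41] <- 1L
  m2 <- label_mask(labs2, c(sacrum = 1L), 0.5)
  n_surf <- nrow(extract_surface_points(m2, "sacrum"))
  area <- 2 * (30 * 20 + 20 * 20 + 20 * 30)
  expect_lt(abs(n_surf - area / 0.25) / (area / 0.25), 0.05)
})

test_that("gap is the closest surface pair inside the dowel, even oblique", {
  sp <- small_spec(seed = 8, gap_mm = 6, posterior_gap_mm = 6)
  ph <- make_two_body_phantom(sp)
  sa <- extract_surface_points(ph$mask, "ilium")
  sb <- extract_surface_points(ph$mask, "sacrum")
  fid <- make_trajectory_landmarks(sp, "middle", phantom = ph)
  roi <- build_cylinder(fid$middle)
  g1 <- joint_gap_distance(sa, sb, roi)
  expect_lte(abs(g1$gap_mm - 6), sqrt(3) * 0.5)
  expect_equal(sqrt(sum((g1$point_a - g1$point_b)^2)), g1$gap_mm,
               tolerance = 1e-9)
  expect_true(all(points_in_cylinder(roi, rbind(g1$point_a, g1$point_b))))

  # dowel at 60 degrees to the gap normal: still the closest-pair
  # distance, not the longer along-axis traversal (g / cos60 = 2g)
  geom_mid <- g1$point_a + c(3, 0, 0)
  ax <- c(cos(pi / 3), sin(pi / 3), 0)
  tro <- trajectory("PL1", "left", geom_mid - 14 * ax, geom_mid + 14 * ax)
  g2 <- joint_gap_distance(sa, sb, build_cylinder(tro))
  expect_lte(abs(g2$gap_mm - 6), sqrt(3) * 0.5)

  # matches the brute-force all-pairs oracle exactly
  a_in <- sa[points_in_cylinder(roi, sa), , drop = FALSE]
  b_in <- sb[points_in_cylinder(roi, sb), , drop = FALSE]
  expect_equal(g1$gap_mm, oracle_min_dist(a_in, b_in), tolerance = 1e-12)
})

test_that("gap is symmetric and strictly monotone in the constructed gap", {
  gaps <- c(1, 2, 4, 8)
  got <- numeric(length(gaps))
  for (i in seq_along(gaps)) {
    sp <- small_spec(seed = 40 + i, gap_mm = gaps[i], posterior_gap_mm = gaps[i])
    ph <- make_two_body_phantom(sp)
    sa <- extract_surface_points(ph$mask, "ilium")
    sb <- extract_surface_points(ph$mask, "sacrum")
    roi <- build_cylinder(make_trajectory_landmarks(sp, "middle",
                                                    phantom = ph)$middle)
    gab <- joint_gap_distance(sa, sb, roi)
    gba <- joint_gap_distance(sb, sa, roi)
    expect_identical(gab$gap_mm, gba$gap_mm)
    got[i] <- gab$gap_mm
  }
  expect_true(all(diff(got) > 0))
  expect_true(all(abs(got - gaps) <= sqrt(3) * 0.5))
})

test_that("gap map is consistent, near-constant for parallel slabs", {
  sp <- small_spec(seed = 17, gap_mm = 4, posterior_gap_mm = 4)
  ph <- make_two_body_phantom(sp)
  sa <- extract_surface_points(ph$mask, "ilium")
  sb <- extract_surface_points(ph$mask, "sacrum")
  # short dowel spanning only the joint region, so the restricted ilium
  # surface is its joint-facing face
  fid <- make_trajectory_landmarks(sp, "middle", phantom = ph)$middle
  mid <- (fid$start + fid$end) / 2
  shift <- c(6, 0, 0)
  roi <- build_cylinder(trajectory("middle", "left", mid - shift, mid + shift))
  fld <- gap_map(sa, sb, roi)
  gr <- joint_gap_distance(sa, sb, roi)
  expect_identical(min(fld$distance), gr$gap_mm)
  expect_lte(max(fld$distance) - min(fld$distance), 2 * 0.5)
})

test_that("a tilted joint face makes the gap field grow along the tilt axis", {
  sp <- small_spec(seed = 23, gap_mm = 2, posterior_gap_mm = 2,
                   tilt_deg = 15, shape = c(72, 64, 48))
  ph <- make_two_body_phantom(sp)
  sa <- extract_surface_points(ph$mask, "ilium")
  sb <- extract_surface_points(ph$mask, "sacrum")
  fid <- make_trajectory_landmarks(sp, "middle", phantom = ph)$middle
  mid <- (fid$start + fid$end) / 2
  roi <- build_cylinder(trajectory("middle", "left", mid - c(8, 0, 0),
                                   mid + c(8, 0, 0)), 10)
  fld <- gap_map(sa, sb, roi)
  fit <- lm(distance ~ y, data = fld)
  slope <- coef(fit)[["y"]]
  # gap widens ~ sin(tilt) per mm of y for the wedge construction
  expect_gt(slope, 0.5 * sin(15 * pi / 180))
  expect_lt(slope, 1.5 * sin(15 * pi / 180))
})

test_that("face contact reports one-spacing gap with a caveat message", {
  sp <- small_spec(seed = 29, gap_mm = 0, posterior_gap_mm = 0)
  ph <- make_two_body_phantom(sp)
  sa <- extract_surface_points(ph$mask, "ilium")
  sb <- extract_surface_points(ph$mask, "sacrum")
  roi <- build_cylinder(make_trajectory_landmarks(sp, "middle",
                                                  phantom = ph)$middle)
  expect_message(
    gr <- joint_gap_distance(sa, sb, roi, contact_spacing_mm = 0.5),
    "contact")
  expect_equal(gr$gap_mm, 0.5, tolerance = 1e-9)
})

test_that("a dowel missing one body raises a does-not-span error", {
  sp <- small_spec(seed = 33)
  ph <- make_two_body_phantom(sp)
  sa <- extract_surface_points(ph$mask, "ilium")
  sb <- extract_surface_points(ph$mask, "sacrum")
  # entirely on the ilium side of the joint
  tr <- trajectory("top", "left", c(2, 12, 12), c(6, 12, 12))
  expect_error(joint_gap_distance(sa, sb, build_cylinder(tr)),
               "does not span")
})
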