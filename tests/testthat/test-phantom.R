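# phantom_generator: teeth, seated pairs, voxelized scenes, margin images

test_that("make_tooth is deterministic, watertight, and parametric", {
  s1 <- make_tooth(tooth_phantom_spec("premolar", seed = 4), pitch = 0.2)
  s2 <- make_tooth(tooth_phantom_spec("premolar", seed = 4), pitch = 0.2)
  expect_identical(s1$vertices, s2$vertices)
  expect_identical(s1$faces, s2$faces)
  expect_true(is_watertight(s1))

  wide <- make_tooth(tooth_phantom_spec("premolar", crown_width = 16,
                                        seed = 4), pitch = 0.2)
  bb1 <- diff(range(s1$vertices[, 1]))
  bb2 <- diff(range(wide$vertices[, 1]))
  expect_equal(bb2 / bb1, 2, tolerance = 0.05)

  inc <- make_tooth(tooth_phantom_spec("incisor", seed = 5), pitch = 0.2)
  expect_true(is_watertight(inc))
  expect_error(tooth_phantom_spec("premolar", crown_width = -1),
               "parameter error")
})

test_that("make_seated_pair realizes the prescribed gap field exactly", {
  tooth <- make_tooth(tooth_phantom_spec("premolar", seed = 8), pitch = 0.18)
  crown <- isolate_crown(make_tooth(tooth_phantom_spec("incisor", seed = 9),
                                    pitch = 0.18),
                         c(0, 0, 2), c(0, 0, 1))
  placed <- apply_transform(crown, place_over_target(crown, tooth))

  pair <- make_seated_pair(tooth, placed,
                           gap_field_spec("uniform", mean = 100, sd = 0),
                           pitch = 0.09)
  expect_true(is_watertight(pair$veneer))
  Vi <- pair$veneer$vertices[pair$intaglio, , drop = FALSE]
  expect_gt(nrow(Vi), 100)
  d_um <- 1000 * veneerfit:::cpp_grid_point_mesh_dist(
    Vi, tooth$vertices, tooth$faces, 0.5)
  expect_lt(max(abs(d_um - 100)), 1)

  # zero gap: intaglio coincides with the tooth surface
  pair0 <- make_seated_pair(tooth, placed,
                            gap_field_spec("uniform", mean = 0, sd = 0),
                            pitch = 0.09)
  Vi0 <- pair0$veneer$vertices[pair0$intaglio, , drop = FALSE]
  d0 <- veneerfit:::cpp_grid_point_mesh_dist(Vi0, tooth$vertices,
                                             tooth$faces, 0.5)
  expect_lt(max(d0), 1e-3)

  # seeded normal field regenerates identically
  gs <- gap_field_spec("normal", mean = 100, sd = 50, seed = 17)
  pa <- make_seated_pair(tooth, placed, gs, pitch = 0.12)
  pb <- make_seated_pair(tooth, placed, gs, pitch = 0.12)
  expect_identical(pa$veneer$vertices, pb$veneer$vertices)
  expect_identical(pa$gap_truth, pb$gap_truth)
})

test_that("gap field statistics match the spec within Monte-Carlo error", {
  g <- veneerfit:::gap_field_fun(gap_field_spec("normal", mean = 100,
                                                sd = 50, seed = 3))
  set.seed(30)
  pts <- matrix(runif(3e4, -5, 5), ncol = 3)
  vals <- g(pts[, 1], pts[, 2], pts[, 3]) * 1000
  # truncated-at-0 normal(100, 50): mean ~ 100.4, sd slightly below 50
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 100), 3 * se + 2)
  expect_equal(sd(vals), 50, tolerance = 0.1)
  expect_true(all(vals >= 0))
})

test_that("voxelize_scene labels phases and is deterministic", {
  ball <- sphere_mesh(0.4, center = c(0.5, 0.5, 0.5), pitch = 0.02,
                      name = "enamel")
  sc <- voxelize_scene(list(enamel = ball),
                       scan_spec(spacing = 0.0128, noise_sd = 0,
                                 blur_fwhm = 0))
  frac <- sum(sc$labels == 1) * 0.0128^3
  expect_equal(frac, 4 / 3 * pi * 0.4^3, tolerance = 0.03)
  # noise 0, blur 0: exactly piecewise-constant two-level volume
  expect_identical(sort(unique(as.numeric(sc$volume$data))), c(0, 1))

  sc2 <- voxelize_scene(list(enamel = ball),
                        scan_spec(spacing = 0.0128, noise_sd = 0.05,
                                  blur_fwhm = 0.03, seed = 6))
  sc3 <- voxelize_scene(list(enamel = ball),
                        scan_spec(spacing = 0.0128, noise_sd = 0.05,
                                  blur_fwhm = 0.03, seed = 6))
  expect_identical(sc2$volume$data, sc3$volume$data)

  expect_error(voxelize_scene(list(mystery = ball), scan_spec()),
               "unknown label")
})

test_that("margin images render three sides consistent with the gap truth", {
  tooth <- make_tooth(tooth_phantom_spec("premolar", seed = 10), pitch = 0.18)
  crown <- isolate_crown(make_tooth(tooth_phantom_spec("incisor", seed = 11),
                                    pitch = 0.18),
                         c(0, 0, 2), c(0, 0, 1))
  placed <- apply_transform(crown, place_over_target(crown, tooth))
  pair <- make_seated_pair(tooth, placed,
                           gap_field_spec("uniform", mean = 50, sd = 0),
                           pitch = 0.09)
  for (side in c("cervical", "mesial", "distal")) {
    img <- render_margin_image(tooth, pair, side, pixel_size = 5, seed = 2)
    expect_gt(nrow(img), 0)
    m <- measure_marginal_gap(img, attr(img, "pixel_size"), side)
    # uniform 50 um pair: measured separation within one pixel
    expect_true(all(abs(m$readings - 50) <= 5))
    expect_equal(attr(img, "side"), side)
  }
})

test_that("uCT scan of a seated pair recovers the gap end-to-end", {
  # cropped labial window at true uCT spacing (full tooth would be ~1500^3)
  tooth <- make_tooth(tooth_phantom_spec("premolar", seed = 12,
                                         bumpiness = 0), pitch = 0.15)
  crown <- isolate_crown(make_tooth(tooth_phantom_spec("incisor", seed = 13),
                                    pitch = 0.15),
                         c(0, 0, 2), c(0, 0, 1))
  placed <- apply_transform(crown, place_over_target(crown, tooth))
  pair <- make_seated_pair(tooth, placed,
                           gap_field_spec("uniform", mean = 150, sd = 0),
                           pitch = 0.08)
  ctr <- colMeans(tooth$vertices)
  roi <- list(lo = c(ctr[1] + 2.2, ctr[2] - 0.5, 4.2),
              hi = c(ctr[1] + 4.2, ctr[2] + 0.5, 5.2))
  sc <- voxelize_scene(list(enamel = tooth, resin = pair$veneer),
                       scan_spec(spacing = 0.0128, noise_sd = 0.02,
                                 blur_fwhm = 0, seed = 3), bbox = roi)
  seg <- segment_gap_indirect(sc$volume, closing_radius = 0.3)
  gm <- compute_thickness_map(reconstruct_gap_model(seg$combined, seg$enamel))
  expect_gt(length(gm$thickness), 100)
  expect_lt(abs(median(gm$thickness) - 150), 2 * 12.8)
})
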