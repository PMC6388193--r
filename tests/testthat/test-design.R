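# veneer_design: crown isolation, mirroring, placement, Booleans,
# thickness, blockout, bevel

test_that("isolate_crown cuts and caps watertight", {
  cu <- box_mesh(c(0, 0, 0), c(2, 2, 2))
  half <- isolate_crown(cu, c(0, 0, 1), c(0, 0, 1), pitch = 0.03)
  expect_true(is_watertight(half))
  expect_equal(mesh_volume(half), 4, tolerance = 0.02)

  # plane below the mesh: returned unchanged
  same <- isolate_crown(cu, c(0, 0, -5), c(0, 0, 1))
  expect_identical(same$vertices, cu$vertices)
  expect_error(isolate_crown(cu, c(0, 0, 5), c(0, 0, 1)), "empty-result")

  sp <- sphere_mesh(5, pitch = 0.1)
  hemi <- isolate_crown(sp, c(0, 0, 0), c(0, 0, 1), pitch = 0.05)
  expect_true(is_watertight(hemi))
  expect_equal(mesh_volume(hemi), 2 / 3 * pi * 125, tolerance = 0.01)
})

test_that("mirror_mesh is an isometric involution", {
  tet <- triangle_mesh(matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1),
                              ncol = 3, byrow = TRUE),
                       matrix(c(1, 3, 2, 1, 2, 4, 2, 3, 4, 1, 4, 3),
                              ncol = 3, byrow = TRUE), "tet")
  pl <- list(point = c(0.3, -0.2, 0.1), normal = c(1, 2, 3))
  m2 <- mirror_mesh(mirror_mesh(tet, pl$point, pl$normal), pl$point, pl$normal)
  expect_equal(m2$vertices, tet$vertices, tolerance = 1e-12)
  expect_equal(mesh_volume(mirror_mesh(tet, pl$point, pl$normal)),
               mesh_volume(tet), tolerance = 1e-12)

  # hand-computed reflection of one vertex across x = 0.5
  r <- mirror_mesh(tet, c(0.5, 0, 0), c(1, 0, 0))
  expect_equal(r$vertices[1, ], c(1, 0, 0))     # (0,0,0) -> (1,0,0)
  expect_equal(r$vertices[2, ], c(0, 0, 0))     # (1,0,0) -> (0,0,0)
  expect_true(is_watertight(r))
  expect_error(mirror_mesh(tet, c(0, 0, 0), c(0, 0, 0)), "zero")
})

test_that("place_over_target aligns and reports overlap", {
  tooth <- make_tooth(tooth_phantom_spec("premolar", seed = 2), pitch = 0.2)
  # identical meshes: identity up to axis-sign convention
  tf0 <- place_over_target(tooth, tooth, crown_frac = 1)
  placed0 <- apply_transform(tooth, tf0)
  expect_lt(max(abs(placed0$vertices - tooth$vertices)), 0.3)

  # translated target: translation component recovered
  shifted <- transform_mesh(tooth, diag(3), c(1, 2, 3))
  tf1 <- place_over_target(tooth, shifted, crown_frac = 1)
  expect_equal(tf1$rotation, diag(3), tolerance = 1e-6)
  expect_equal(tf1$translation, c(1, 2, 3), tolerance = 1e-6)

  # phantom incisor over phantom premolar: substantial overlap
  crown <- isolate_crown(make_tooth(tooth_phantom_spec("incisor", seed = 3),
                                    pitch = 0.2),
                         c(0, 0, 2), c(0, 0, 1))
  tf <- place_over_target(crown, tooth)
  expect_gt(attr(tf, "overlap"), 0.5)

  # explicit mode returns the user transform untouched
  u <- rigid_transform(diag(3), c(0, 1, 0))
  tfe <- place_over_target(crown, tooth, mode = "explicit", user_transform = u)
  expect_identical(tfe$translation, u$translation)
})

test_that("boolean operations match analytic volumes", {
  cu <- box_mesh(c(0, 0, 0), c(1, 1, 1))
  inner <- box_mesh(c(0.25, 0.25, 0.25), c(0.75, 0.75, 0.75))
  sub <- boolean_subtract(cu, inner, pitch = 0.02)
  expect_true(is_watertight(sub))
  expect_equal(mesh_volume(sub), 0.875, tolerance = 0.005)

  far <- box_mesh(c(5, 5, 5), c(6, 6, 6))
  expect_equal(mesh_volume(boolean_subtract(cu, far, pitch = 0.02)), 1,
               tolerance = 0.005)

  # sphere-sphere lens volume (r1 = 4, r2 = 3, d = 3)
  r1 <- 4; r2 <- 3; dd <- 3
  a <- sphere_mesh(r1, pitch = 0.1)
  b <- sphere_mesh(r2, center = c(dd, 0, 0), pitch = 0.1)
  lens <- pi * (r1 + r2 - dd)^2 *
    (dd^2 + 2 * dd * r2 - 3 * r2^2 + 2 * dd * r1 + 6 * r2 * r1 - 3 * r1^2) /
    (12 * dd)
  int <- boolean_intersect(a, b, pitch = 0.04)
  expect_equal(mesh_volume(int), lens, tolerance = 0.01)

  # non-watertight input is rejected by name
  open <- triangle_mesh(cu$vertices, cu$faces[1:10, ], "openmesh")
  expect_error(boolean_subtract(open, inner), "openmesh")
})

test_that("volume conservation holds on seeded blob pairs", {
  for (seed in 1:5) {
    a <- blob_mesh(2 * seed)
    b <- transform_mesh(blob_mesh(2 * seed + 1), diag(3),
                        c(0.8, -0.4, 0.5))
    va <- mesh_volume(a)
    vs <- mesh_volume(boolean_subtract(a, b, pitch = 0.05))
    vi <- mesh_volume(boolean_intersect(a, b, pitch = 0.05))
    expect_equal(vs + vi, va, tolerance = 0.005)
  }
})

test_that("check_thickness measures a spherical shell wall", {
  shell <- boolean_subtract(sphere_mesh(5, pitch = 0.12),
                            sphere_mesh(4.5, pitch = 0.12), pitch = 0.05)
  rep <- check_thickness(shell, min_thickness = 0.5)
  expect_equal(median(rep$thickness), 0.5, tolerance = 0.05)
  expect_equal(check_thickness(shell, 0)$violating_area_fraction, 0)
  expect_equal(check_thickness(shell, 2)$violating_area_fraction, 1)
  open <- triangle_mesh(shell$vertices, shell$faces[-1, ], "open")
  expect_error(check_thickness(open), "watertight")
})

test_that("remove_undercuts relieves a deliberate undercut (and only then)", {
  tooth <- boolean_subtract(box_mesh(c(0, 0, 0), c(5, 5, 5), "tooth"),
                            box_mesh(c(4, 1, 2), c(5.3, 4, 2.6), "notch"),
                            pitch = 0.05)
  tooth_dil <- offset_mesh(tooth, 0.1, pitch = 0.05)
  veneer <- boolean_subtract(box_mesh(c(4, 0, 0), c(6, 5, 5), "ven"),
                             tooth_dil, pitch = 0.05)
  sw0 <- sweep_test(veneer, tooth, c(0, 0, 1), pitch = 0.05)
  expect_false(sw0$pass)

  relieved <- remove_undercuts(veneer, tooth, c(0, 0, 1), clearance = 0.05,
                               pitch = 0.05)
  sw1 <- sweep_test(relieved, tooth, c(0, 0, 1), pitch = 0.05)
  expect_true(sw1$pass)
  expect_lte(mesh_volume(relieved), mesh_volume(veneer))

  # idempotence on the already-relieved veneer
  again <- remove_undercuts(relieved, tooth, c(0, 0, 1), clearance = 0.05,
                            pitch = 0.05)
  expect_lt(abs(mesh_volume(again) - mesh_volume(relieved)) /
              mesh_volume(relieved), 1e-3)

  # undercut-free veneer comes back unchanged (smooth shell over a ball)
  ball <- sphere_mesh(3, pitch = 0.08)
  cap <- local({  # analytic spherical cap shell: outer 3.6, inner 3.15
    xs <- seq(-3.9, 3.9, by = 0.05)
    d <- rep(length(xs), 3)
    X <- array(rep(xs, times = d[2] * d[3]), d)
    Y <- array(rep(rep(xs, each = d[1]), times = d[3]), d)
    Z <- array(rep(xs, each = d[1] * d[2]), d)
    rr <- sqrt(X^2 + Y^2 + Z^2)
    mesh_from_field(pmax(rr - 3.6, 3.15 - rr, 0.5127 - Z), rep(0.05, 3),
                    rep(xs[1], 3), iso = 0, inside_below = TRUE, "cap")
  })
  relieved2 <- remove_undercuts(cap, ball, c(0, 0, 1), clearance = 0.05,
                                pitch = 0.04)
  expect_lt(abs(mesh_volume(relieved2) - mesh_volume(cap)) / mesh_volume(cap),
            1e-3)
  expect_error(remove_undercuts(cap, ball, c(0, 0, 0)), "zero insertion")
})

test_that("bevel_edges removes the analytic chamfer wedge", {
  th <- 17 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  cu <- transform_mesh(box_mesh(c(0, 0, 0), c(2, 2, 2)), Rz)

  expect_identical(bevel_edges(cu, 0), cu)
  expect_error(bevel_edges(cu, 3), "band exceeds")

  bev <- bevel_edges(cu, 0.5, 45, c(0, 0, 1), pitch = 0.015)
  expect_true(is_watertight(bev))
  removed <- mesh_volume(cu) - mesh_volume(bev)
  analytic <- 8 * 0.5^2 / 2 - 4 * 0.5^3 / 3
  expect_equal(removed, analytic, tolerance = 0.02)
  expect_lte(mesh_volume(bev), mesh_volume(cu))
})

test_that("the full design pipeline yields a valid, reproducible veneer", {
  tooth <- make_tooth(tooth_phantom_spec("premolar", seed = 6), pitch = 0.18)
  incisor <- make_tooth(tooth_phantom_spec("incisor", seed = 7), pitch = 0.18)
  des <- design_veneer(incisor, tooth,
                       cervical_plane = list(point = c(0, 0, 2),
                                             normal = c(0, 0, 1)),
                       pitch = 0.09)
  expect_true(is_watertight(des$veneer))
  expect_gt(mesh_volume(des$veneer), 0)
  expect_true(des$sweep$pass)
  vint <- boolean_intersect(des$veneer, tooth, pitch = 0.09)
  expect_lt(mesh_volume(vint), 1e-3 * mesh_volume(des$veneer))
  # contained in the placed crown dilated by one print layer (50 um):
  # subtracting the dilated crown leaves essentially nothing
  grown <- offset_mesh(des$incisor_crown, 0.05, pitch = 0.09)
  outside <- boolean_subtract(des$veneer, grown, pitch = 0.09)
  expect_lt(mesh_volume(outside), 1e-3 * mesh_volume(des$veneer))

  # byte-identical STL on repeat with identical inputs and config
  d2 <- design_veneer(incisor, tooth,
                      cervical_plane = list(point = c(0, 0, 2),
                                            normal = c(0, 0, 1)),
                      pitch = 0.09)
  p1 <- file.path(tempdir(), "v1.stl"); p2 <- file.path(tempdir(), "v2.stl")
  write_mesh(des$veneer, p1); write_mesh(d2$veneer, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})
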