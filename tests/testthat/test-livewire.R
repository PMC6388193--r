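# livewire_segmentation: edge costs, minimal paths, contours, variational
# surface, rasterization, surface extraction

test_that("edge_cost is 1 - g/gmax with the documented fallback", {
  # vertical step edge: minimal cost along the edge column
  img <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
  cost <- edge_cost(img)
  expect_true(all(cost >= 0 & cost <= 1))
  expect_lt(max(cost[, 4:5]), min(cost[, c(1, 8)]))

  expect_equal(edge_cost(matrix(3, 5, 5)), matrix(1, 5, 5))

  set.seed(31)
  img <- matrix(runif(64), 8)
  g <- veneerfit:::gradient_magnitude2(img)
  expect_equal(edge_cost(img), 1 - g / max(g))
  expect_error(edge_cost(matrix(1, 1, 5)), "2 x 2")
})

test_that("minimal_cost_path follows forced geometry and checks bounds", {
  u <- matrix(1, 7, 9)
  p <- minimal_cost_path(u, c(4, 2), c(4, 8))
  expect_equal(p$path[, 1], rep(4, 7))
  expect_equal(p$path[, 2], 2:8)
  expect_equal(p$cost, 6)

  # zero-cost corridor on row 2
  corr <- matrix(1, 6, 10)
  corr[2, ] <- 0
  p2 <- minimal_cost_path(corr, c(2, 1), c(2, 10))
  expect_true(all(p2$path[, 1] == 2))
  expect_equal(p2$cost, 0)

  expect_error(minimal_cost_path(u, c(0, 1), c(2, 2)), "bounds")
  expect_error(minimal_cost_path(u, c(2, 2), c(2, 2)), "differ")
})

test_that("F* equals the Dijkstra oracle on random grids (property)", {
  set.seed(42)
  for (trial in 1:40) {
    nr <- sample(8:12, 1); nc <- sample(8:12, 1)
    cost <- matrix(runif(nr * nc), nr)
    s <- c(sample(nr, 1), sample(nc, 1))
    e <- c(sample(nr, 1), sample(nc, 1))
    if (all(s == e)) next
    got <- minimal_cost_path(cost, s, e)$cost
    expect_equal(got, dijkstra_cost(cost, s, e), tolerance = 1e-12)
    # reversal invariance of the accumulated cost
    expect_equal(got, minimal_cost_path(cost, e, s)$cost, tolerance = 1e-12)
  }
})

test_that("trace_contour snaps to a disc boundary within a pixel", {
  n <- 64; cx <- 32.5; cy <- 32.5; r <- 20
  ii <- outer(1:n, rep(1, n)); jj <- outer(rep(1, n), 1:n)
  img <- 1 / (1 + exp((sqrt((ii - cx)^2 + (jj - cy)^2) - r) / 0.7))
  set.seed(4)
  img <- img + matrix(rnorm(n * n, 0, 0.02), n)
  ang <- c(0.4, 2.0, 3.6, 5.2)
  anchors <- round(cbind(cx + r * cos(ang), cy + r * sin(ang)))
  ct <- trace_contour(img, anchors, window = intensity_window(0.1, 0.9))
  d <- abs(sqrt((ct$points[, 1] - cx)^2 + (ct$points[, 2] - cy)^2) - r)
  expect_lt(max(d), 1)

  # reversed anchors: same point set, reversed orientation
  ct2 <- trace_contour(img, anchors[4:1, ], window = intensity_window(0.1, 0.9))
  key <- function(p) sort(paste(p[, 1], p[, 2]))
  expect_equal(key(ct2$points), key(ct$points))
  expect_equal(sign(veneerfit:::polygon_area(ct$points)),
               -sign(veneerfit:::polygon_area(ct2$points)))

  expect_error(trace_contour(img, anchors[1:2, ]), "contour error")
})

test_that("variational surface interpolates and reconstructs a sphere", {
  p <- 0.2; r <- 5
  frame <- voxel_volume(array(0, c(61, 61, 61)), rep(p, 3), rep(-6, 3))
  cs <- great_circle_contours(r, frame)
  surf <- fit_variational_surface(cs, frame)

  # interpolation condition at the on-surface constraints
  on_idx <- which(abs(sqrt(rowSums(surf$centers^2)) - r) < 1e-6)
  vals <- evaluate_surface(surf, surf$centers[on_idx, ])
  expect_lt(max(abs(vals)), 1e-6)

  # zero level set within 0.5 voxel of the analytic sphere (radial sampling)
  th <- seq(0.05, pi - 0.05, length.out = 24)
  ph <- seq(0, 2 * pi, length.out = 48)
  g <- expand.grid(th = th, ph = ph)
  dirs <- cbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
  lo <- rep(r - 1, nrow(dirs)); hi <- rep(r + 1, nrow(dirs))
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    v <- evaluate_surface(surf, dirs * mid)
    lo <- ifelse(v < 0, mid, lo); hi <- ifelse(v < 0, hi, mid)
  }
  expect_lt(max(abs((lo + hi) / 2 - r)), 0.5 * p)

  # translation equivariance: contours of the shifted sphere give the
  # shifted implicit function (shift on the frame's slice lattice)
  shift <- c(0.6, -0.4, 0.2)
  surf2 <- fit_variational_surface(
    great_circle_contours(r, frame, center = shift), frame)
  set.seed(8)
  probes <- matrix(runif(60, -4, 4), ncol = 3)
  expect_equal(evaluate_surface(surf2, sweep(probes, 2, shift, "+")),
               evaluate_surface(surf, probes), tolerance = 1e-6)
})

test_that("rasterize_mask and extract_surface_mesh recover analytic solids", {
  p <- 0.2; r <- 5
  frame <- voxel_volume(array(0, c(61, 61, 61)), rep(p, 3), rep(-6, 3))
  surf <- fit_variational_surface(great_circle_contours(r, frame), frame)
  mask <- rasterize_mask(surf, frame)
  expect_equal(mask_vol <- sum(mask$data) * p^3, 4 / 3 * pi * r^3,
               tolerance = 0.03)
  expect_identical(dim(mask$data), dim(frame$data))

  # empty intersection -> all-false mask
  far_frame <- voxel_volume(array(0, c(8, 8, 8)), rep(p, 3), c(50, 50, 50))
  expect_false(any(rasterize_mask(surf, far_frame)$data))

  # complemented sign convention is the logical NOT
  neg <- surf
  neg$weights <- -neg$weights
  neg$polynomial <- -neg$polynomial
  expect_identical(rasterize_mask(neg, frame)$data, !mask$data)

  mesh <- extract_surface_mesh(mask)
  expect_true(is_watertight(mesh))
  expect_equal(mesh_area(mesh), 4 * pi * r^2, tolerance = 0.05)

  # vertices stay within one voxel diagonal of the mask boundary
  dv <- abs(sqrt(rowSums(mesh$vertices^2)) - r)
  expect_lt(max(dv), sqrt(3) * p)

  # single isolated voxel -> small closed mesh with Euler characteristic 2
  m1 <- array(FALSE, c(7, 7, 7)); m1[4, 4, 4] <- TRUE
  tiny <- extract_surface_mesh(binary_mask(m1, frame), smooth_sigma = 0)
  expect_true(is_watertight(tiny))
  ne <- nrow(tiny$faces) * 3 / 2
  expect_equal(nrow(tiny$vertices) - ne + nrow(tiny$faces), 2)
  expect_error(extract_surface_mesh(binary_mask(array(FALSE, c(5, 5, 5)),
                                                frame)),
               "empty")

  # rasterize(extract(rasterize(S))) keeps Dice >= 0.97 with the original
  again <- voxelize_mesh(mesh, frame)
  dice <- 2 * sum(again$data & mask$data) / (sum(again$data) + sum(mask$data))
  expect_gt(dice, 0.97)
})

test_that("segment_tooth recovers a ball from livewire contours", {
  v <- ball_volume(r = 5, spacing = 0.2, n = 61)
  mkanchors <- function(axis) {
    ang <- c(0, pi / 2, pi, 3 * pi / 2) + 0.3
    pts <- cbind(31 + 25 * cos(ang), 31 + 25 * sin(ang))
    list(axis = axis, slice = 31L, points = round(pts))
  }
  mesh <- segment_tooth(v, lapply(1:3, mkanchors),
                        window = intensity_window(0.1, 0.9))
  expect_true(is_watertight(mesh))
  expect_equal(mesh_volume(mesh), 4 / 3 * pi * 125, tolerance = 0.03)
})
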