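# imaging_io: volumes, preprocessing filters, DICOM, STL

test_that("window_normalize is the piecewise-linear clamp", {
  w <- intensity_window(100, 300, 0, 1)
  v <- voxel_volume(array(100, c(4, 4, 4)), c(0.2, 0.2, 0.2))
  expect_equal(unique(as.numeric(window_normalize(v, w)$data)), 0)
  v$data[] <- 200
  expect_equal(unique(as.numeric(window_normalize(v, w)$data)), 0.5)

  # per-voxel agreement with direct formula evaluation
  set.seed(11)
  a <- array(runif(4^3, 0, 400), c(4, 4, 4))
  v$data <- a
  got <- window_normalize(v, w)$data
  ref <- (pmin(pmax(a, 100), 300) - 100) / 200
  expect_equal(got, ref)
  expect_equal(window_normalize(v, w)$spacing, v$spacing)
  expect_error(intensity_window(5, 5), "low")
})

test_that("median_filter matches the brute-force sorted-neighborhood median", {
  # impulse removal and identity
  a <- array(0, c(5, 5, 5)); a[3, 3, 3] <- 10
  v <- voxel_volume(a, rep(0.1, 3))
  expect_equal(max(median_filter(v, 1)$data), 0)
  const <- voxel_volume(array(7, c(4, 4, 4)), rep(0.1, 3))
  expect_equal(median_filter(const, 1)$data, const$data)
  expect_error(median_filter(v, 0), "radius")

  set.seed(21)
  a <- array(runif(216), c(6, 6, 6))
  got <- median_filter(a, 1)
  brute <- array(0, dim(a))
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    ii <- pmin(pmax((i - 1):(i + 1), 1), 6)
    jj <- pmin(pmax((j - 1):(j + 1), 1), 6)
    kk <- pmin(pmax((k - 1):(k + 1), 1), 6)
    brute[i, j, k] <- median(a[ii, jj, kk])
  }
  expect_equal(got, brute)
})

test_that("filters preserve the frame and commute with axis permutation", {
  set.seed(5)
  v <- voxel_volume(array(runif(5 * 6 * 7), c(5, 6, 7)), c(0.1, 0.2, 0.3),
                    origin = c(1, 2, 3))
  w <- intensity_window(0.2, 0.8)
  for (f in list(function(x) window_normalize(x, w),
                 function(x) median_filter(x, 1))) {
    out <- f(v)
    expect_identical(dim(out$data), dim(v$data))
    expect_identical(out$spacing, v$spacing)
    expect_identical(out$origin, v$origin)
  }
  # permutation commutation (use an isotropic cube so axes are exchangeable)
  v2 <- voxel_volume(array(runif(6^3), c(6, 6, 6)), rep(0.1, 3))
  perm <- c(3, 1, 2)
  ref <- aperm(median_filter(v2, 1)$data, perm)
  v2p <- voxel_volume(aperm(v2$data, perm), rep(0.1, 3))
  expect_equal(median_filter(v2p, 1)$data, ref)
  expect_equal(aperm(window_normalize(v2, w)$data, perm),
               window_normalize(v2p, w)$data)
})

test_that("crop_roi preserves the world frame and composes", {
  set.seed(3)
  v <- voxel_volume(array(runif(8 * 9 * 10), c(8, 9, 10)), c(0.2, 0.2, 0.2),
                    origin = c(-1, 0, 2))
  full <- crop_roi(v, list(c(1, 8), c(1, 9), c(1, 10)))
  expect_equal(full$data, v$data)
  expect_equal(full$origin, v$origin)

  cr <- crop_roi(v, list(c(3, 7), c(2, 8), c(4, 10)))
  expect_equal(cr$data[1, 1, 1], v$data[3, 2, 4])
  expect_equal(voxel_to_world(cr, cbind(1, 1, 1)),
               voxel_to_world(v, cbind(3, 2, 4)))

  nested <- crop_roi(crop_roi(v, list(c(2, 8), c(1, 9), c(3, 10))),
                     list(c(2, 6), c(2, 8), c(2, 7)))
  direct <- crop_roi(v, list(c(3, 7), c(2, 8), c(4, 9)))
  expect_equal(nested$data, direct$data)
  expect_equal(nested$origin, direct$origin)
  expect_error(crop_roi(v, list(c(0, 5), c(1, 9), c(1, 10))), "bounds")
})

test_that("MetaImage volumes round-trip", {
  set.seed(7)
  v <- voxel_volume(array(runif(1000), c(10, 10, 10)), c(0.2, 0.2, 0.2),
                    origin = c(1, -2, 0.5))
  path <- file.path(tempdir(), "rt.mhd")
  write_volume(v, path)
  back <- load_volume(path)
  expect_equal(back$data, v$data)
  expect_equal(back$spacing, v$spacing)
  expect_equal(back$origin, v$origin)
  expect_error(load_volume(file.path(tempdir(), "nope.mhd")), "exist")
})

test_that("DICOM series load with correct spacing and order", {
  set.seed(13)
  arr <- array(sample(0:4000, 10 * 12 * 5, TRUE), c(10, 12, 5))
  dir <- dcm_write_series(file.path(tempdir(), "dcmser"), arr)
  v <- load_volume(dir)
  expect_identical(dim(v$data), dim(arr))
  expect_equal(v$spacing, c(0.2, 0.2, 0.2))   # slice interval 0.2 mm
  expect_equal(v$data, arr + 0.0)

  # heterogeneous pixel spacing across the series -> metadata error
  dir2 <- dcm_write_series(file.path(tempdir(), "dcmbad"), arr,
                           px_override = c(0.3, 0.3))
  expect_error(load_volume(dir2), "metadata")
})

test_that("STL read/write round-trips both dialects", {
  cube <- box_mesh(c(0, 0, 0), c(1, 1, 1), "unitcube")
  pb <- file.path(tempdir(), "cube_bin.stl")
  pa <- file.path(tempdir(), "cube_asc.stl")
  write_mesh(cube, pb)
  write_mesh(cube, pa, ascii = TRUE)

  rb <- read_mesh(pb)
  ra <- read_mesh(pa)
  expect_equal(nrow(rb$faces), 12)
  expect_equal(nrow(ra$faces), 12)
  # vertex sets agree across dialects and with the source (float32 write)
  key <- function(m) sort(apply(round(m$vertices, 5), 1, paste, collapse = ","))
  expect_equal(key(rb), key(cube))
  expect_equal(key(ra), key(rb))
  expect_equal(mesh_volume(rb), 1, tolerance = 1e-6)
  expect_true(is_watertight(rb))

  # write(read(x)) is idempotent byte-for-byte
  p2 <- file.path(tempdir(), "cube_bin2.stl")
  write_mesh(rb, p2)
  r2 <- read_mesh(p2)
  expect_equal(r2$vertices, rb$vertices)
  expect_equal(r2$faces, rb$faces)

  # truncated binary file -> format error
  bytes <- readBin(pb, "raw", file.size(pb))
  pt <- file.path(tempdir(), "trunc.stl")
  writeBin(bytes[1:100], pt)
  expect_error(read_mesh(pt), "malformed|truncated")
})
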