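# Shared fixture builders: analytic solids, phantom scenes, oracles.
# Everything is generated in code; no stored fixtures.

# axis-aligned box as an indexed triangle mesh (12 faces, outward normals)
box_mesh <- function(lo, hi, name = "box") {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  f <- matrix(c(1, 3, 4, 1, 4, 2, 5, 6, 8, 5, 8, 7,
                1, 2, 6, 1, 6, 5, 3, 7, 8, 3, 8, 4,
                1, 5, 7, 1, 7, 3, 2, 4, 8, 2, 8, 6),
              ncol = 3, byrow = TRUE)
  triangle_mesh(v, f, name)
}

# sphere mesh from its implicit function (watertight by construction)
sphere_mesh <- function(r, center = c(0, 0, 0), pitch = 0.1, name = "sphere") {
  xs <- seq(-r - 4 * pitch, r + 4 * pitch, by = pitch)
  d <- rep(length(xs), 3)
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(xs, each = d[1]), times = d[3]), d)
  Z <- array(rep(xs, each = d[1] * d[2]), d)
  m <- mesh_from_field(sqrt(X^2 + Y^2 + Z^2) - r, rep(pitch, 3),
                       rep(xs[1], 3), iso = 0, inside_below = TRUE,
                       name = name)
  transform_mesh(m, diag(3), center)
}

# random blobby superellipsoid solid (seeded) for Boolean property tests
blob_mesh <- function(seed, pitch = 0.12) {
  set.seed(seed)
  ax <- runif(3, 1.5, 3)
  m <- runif(1, 2, 4)
  ctr <- runif(3, -0.5, 0.5)
  xs <- seq(-4, 4, by = pitch)
  d <- rep(length(xs), 3)
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(xs, each = d[1]), times = d[3]), d)
  Z <- array(rep(xs, each = d[1] * d[2]), d)
  f <- (abs((X - ctr[1]) / ax[1])^m + abs((Y - ctr[2]) / ax[2])^m +
          abs((Z - ctr[3]) / ax[3])^m)^(1 / m) - 1
  mesh_from_field(f, rep(pitch, 3), rep(xs[1], 3), iso = 0,
                  inside_below = TRUE, name = paste0("blob", seed))
}

# independent Dijkstra oracle on the livewire pixel graph
# (symmetric step cost: mean of the two pixel costs x step length)
dijkstra_cost <- function(cost, start, end) {
  nr <- nrow(cost); nc <- ncol(cost); n <- nr * nc
  id <- function(r, c) (c - 1) * nr + r
  dist <- rep(Inf, n)
  dist[id(start[1], start[2])] <- 0
  done <- rep(FALSE, n)
  dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  dl <- c(sqrt(2), 1, sqrt(2), 1, 1, sqrt(2), 1, sqrt(2))
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u]) || done[u]) break
    done[u] <- TRUE
    if (u == id(end[1], end[2])) break
    r <- (u - 1) %% nr + 1; c <- (u - 1) %/% nr + 1
    for (m in 1:8) {
      rr <- r + dr[m]; cc <- c + dc[m]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      v <- id(rr, cc)
      alt <- dist[u] + 0.5 * (cost[r, c] + cost[rr, cc]) * dl[m]
      if (alt < dist[v]) dist[v] <- alt
    }
    if (all(done)) break
  }
  dist[id(end[1], end[2])]
}

# a ball volume at given spacing with a soft intensity edge
ball_volume <- function(r = 5, spacing = 0.2, n = 61, noise = 0.02,
                        seed = 1) {
  xs <- (seq_len(n) - (n + 1) / 2) * spacing
  d <- c(n, n, n)
  X <- array(rep(xs, times = n * n), d)
  Y <- array(rep(rep(xs, each = n), times = n), d)
  Z <- array(rep(xs, each = n * n), d)
  vol <- 1 / (1 + exp((sqrt(X^2 + Y^2 + Z^2) - r) / (0.5 * spacing)))
  if (noise > 0) {
    set.seed(seed)
    vol <- vol + array(rnorm(n^3, 0, noise), d)
  }
  voxel_volume(vol, rep(spacing, 3), rep(xs[1], 3))
}

# three orthogonal great-circle contours of a sphere centered at `center`
# (world mm; per-axis coordinates must lie on slice planes of the frame)
great_circle_contours <- function(r, frame, n = 64, center = c(0, 0, 0)) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[1:n]
  mk <- function(axis) {
    others <- setdiff(1:3, axis)
    w <- matrix(rep(center, each = n), n, 3)
    w[, others[1]] <- center[others[1]] + r * cos(ang)
    w[, others[2]] <- center[others[2]] + r * sin(ang)
    idx2 <- sweep(w[, others, drop = FALSE], 2,
                  frame$origin[others], "-") /
      rep(frame$spacing[others], each = n) + 1
    slice <- as.integer(round((center[axis] - frame$origin[axis]) /
                                frame$spacing[axis])) + 1L
    planar_contour(axis, slice, idx2)
  }
  contour_set(list(mk(1), mk(2), mk(3)))
}

# slab scene: enamel block | air gap | resin block, for the uCT route
slab_scene <- function(gap_um, spacing = 0.0128, extent = 1.0,
                       seed = 2, noise_sd = 0.02) {
  g <- gap_um / 1000
  enamel <- box_mesh(c(0, 0, 0), c(extent, extent, 0.6), "enamel")
  resin <- box_mesh(c(0, 0, 0.6 + g), c(extent, extent, 1.2 + g), "resin")
  voxelize_scene(list(enamel = enamel, resin = resin),
                 scan_spec(spacing = spacing, noise_sd = noise_sd,
                           blur_fwhm = 0, seed = seed))
}

# fully enclosed gap: enamel core inside a resin box, gap ring between
enclosed_gap_scene <- function(gap_um = 100, spacing = 0.0128, seed = 3) {
  g <- gap_um / 1000
  outer <- box_mesh(c(0, 0, 0), c(1.4, 1.4, 1.4), "resin")
  cavity <- box_mesh(c(0.4 - g, 0.4 - g, 0.4 - g),
                     c(1.0 + g, 1.0 + g, 1.0 + g), "cavity")
  core <- box_mesh(c(0.4, 0.4, 0.4), c(1.0, 1.0, 1.0), "enamel")
  voxelize_scene(list(resin = outer, air_gap = cavity, enamel = core),
                 scan_spec(spacing = spacing, noise_sd = 0.02,
                           blur_fwhm = 0, seed = seed))
}

# independent minimal DICOM writer (explicit VR little endian), used only
# to build fixtures the package reader is tested against
dcm_write_slice <- function(path, mat, px_sp = c(0.2, 0.2),
                            ipp = c(0, 0, 0), thick = 0.2,
                            drop_pixel_spacing = FALSE) {
  elem <- function(group, el, vr, payload) {
    g <- writeBin(as.integer(group), raw(), size = 2, endian = "little")
    e <- writeBin(as.integer(el), raw(), size = 2, endian = "little")
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- writeBin(as.integer(length(payload)), raw(), size = 4,
                      endian = "little")
      c(g, e, charToRaw(vr), as.raw(c(0, 0)), len, payload)
    } else {
      len <- writeBin(as.integer(length(payload)), raw(), size = 2,
                      endian = "little")
      c(g, e, charToRaw(vr), len, payload)
    }
  }
  pad <- function(s) {
    r <- charToRaw(s)
    if (length(r) %% 2) c(r, as.raw(32)) else r
  }
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  body <- c(elem(0x0018, 0x0050, "DS", pad(format(thick))),
            elem(0x0020, 0x0032, "DS", pad(paste(ipp, collapse = "\\"))),
            elem(0x0028, 0x0010, "US", u16(nrow(mat))),
            elem(0x0028, 0x0011, "US", u16(ncol(mat))))
  if (!drop_pixel_spacing)
    body <- c(body, elem(0x0028, 0x0030, "DS",
                         pad(paste(px_sp, collapse = "\\"))))
  body <- c(body,
            elem(0x0028, 0x0100, "US", u16(16)),
            elem(0x0028, 0x0103, "US", u16(0)),
            elem(0x7fe0, 0x0010, "OW",
                 writeBin(as.integer(t(mat)), raw(), size = 2,
                          endian = "little")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(body, con)
  invisible(path)
}

# write a DICOM series for a volume array (x = columns, y = rows)
dcm_write_series <- function(dir, arr, spacing = c(0.2, 0.2, 0.2),
                             px_override = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_len(dim(arr)[3])) {
    sp <- if (!is.null(px_override) && k == dim(arr)[3]) px_override
          else spacing[2:1]
    dcm_write_slice(file.path(dir, sprintf("slice%03d.dcm", k)),
                    t(arr[, , k]), px_sp = sp,
                    ipp = c(0, 0, (k - 1) * spacing[3]), thick = spacing[3])
  }
  dir
}
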