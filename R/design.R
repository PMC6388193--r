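# Veneer design: crown isolation, mirroring, placement, Boolean subtraction,
# thickness check, undercut blockout, edge bevel.
#
# Boolean operations use a voxel-remesh kernel: inputs are pre-cleaned,
# voxelized on a shared grid (pitch = max extent / 220, clamped to
# [0.02, 0.25] mm), combined with mask logic, and re-triangulated by
# marching tetrahedra. Robust for arbitrary watertight inputs at the cost
# of a resolution-limited surface; the pitch used is attached to results
# as attribute "pitch".

mesh_bbox <- function(mesh) {
  list(lo = apply(mesh$vertices, 2, min), hi = apply(mesh$vertices, 2, max))
}

# shared axis-aligned grid covering all meshes plus padding
common_frame <- function(meshes, pitch, pad = NULL) {
  if (is.null(pad)) pad <- 3 * pitch
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (m in meshes) {
    b <- mesh_bbox(m)
    lo <- pmin(lo, b$lo); hi <- pmax(hi, b$hi)
  }
  # the irrational sub-voxel shift keeps voxel centers (and thus the
  # parity-fill rays) generic with respect to mesh lattices produced by
  # earlier voxel-remesh steps at the same pitch
  lo <- lo - pad - 0.2649618 * pitch; hi <- hi + pad
  dims <- pmax(as.integer(ceiling((hi - lo) / pitch)) + 1L, 2L)
  list(dims = dims, spacing = rep(pitch, 3), origin = lo)
}

vox_array <- function(mesh, frame) {
  array(cpp_voxelize_mesh(mesh$vertices, mesh$faces - 1L,
                          frame$origin, frame$spacing,
                          as.integer(frame$dims)),
        frame$dims)
}

mask_mesh <- function(arr, frame, name = "") {
  mesh_from_field(array(as.numeric(arr), dim(arr)), frame$spacing,
                  frame$origin, iso = 0.5, inside_below = FALSE, name = name)
}

default_pitch <- function(meshes, target_cells = 220) {
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (m in meshes) {
    b <- mesh_bbox(m)
    lo <- pmin(lo, b$lo); hi <- pmax(hi, b$hi)
  }
  ext <- max(hi - lo)
  min(max(ext / target_cells, 0.02), 0.25)
}

require_watertight <- function(mesh, label) {
  if (!is_watertight(mesh))
    stop(sprintf("geometry error: mesh '%s' is not watertight",
                 if (nzchar(mesh$name)) mesh$name else label))
}

#' Rigid transform
#'
#' Proper rotation plus translation; an optional mirror plane carries a
#' reflection separately so `rotation` always has determinant +1.
#'
#' @param rotation 3x3 orthonormal matrix, det +1
#' @param translation length-3 vector in mm
#' @param mirror_plane optional `list(point =, normal =)`
#' @return a `rigid_transform`
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            mirror_plane = NULL) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 mirror_plane = mirror_plane),
            class = "rigid_transform")
}

#' Apply a rigid transform (and optional mirror) to a mesh
#'
#' The mirror plane, when present, is applied first, then the rotation and
#' translation.
#'
#' @param mesh a [triangle_mesh()]
#' @param tf a [rigid_transform()]
#' @return transformed [triangle_mesh()]
#' @export
apply_transform <- function(mesh, tf) {
  out <- mesh
  if (!is.null(tf$mirror_plane))
    out <- mirror_mesh(out, tf$mirror_plane$point, tf$mirror_plane$normal)
  transform_mesh(out, tf$rotation, tf$translation)
}

#' Isolate the crown of a tooth mesh
#'
#' Keeps the portion of the mesh on the normal side of the cervical plane
#' and caps the cut cross-section so the result stays watertight. If the
#' whole mesh already lies on the normal side the input is returned
#' unchanged; a plane that leaves nothing is an error.
#'
#' @param tooth a watertight [triangle_mesh()]
#' @param plane_point point on the cervical plane (mm)
#' @param plane_normal normal pointing toward the crown
#' @param pitch voxel pitch for the cut (mm); NULL chooses automatically
#' @return a watertight [triangle_mesh()] of the crown
#' @export
isolate_crown <- function(tooth, plane_point, plane_normal, pitch = NULL) {
  require_watertight(tooth, "tooth")
  n <- as.numeric(plane_normal)
  nl <- sqrt(sum(n^2))
  if (nl == 0) stop("zero plane normal")
  n <- n / nl
  side <- as.numeric(tooth$vertices %*% n - sum(n * as.numeric(plane_point)))
  if (all(side >= 0)) return(tooth)
  if (all(side <= 0)) stop("empty-result error: plane misses the mesh")
  if (is.null(pitch)) pitch <- default_pitch(list(tooth))
  fr <- common_frame(list(tooth), pitch)
  # intersect the signed body field (positive inside, exact near the
  # surface) with the analytic half-space: sub-voxel cut placement
  body <- -signed_distance_grid(tooth, fr, refine_sel = function(d0)
    which(abs(d0) < 2.5 * pitch))
  xs <- fr$origin[1] + (seq_len(fr$dims[1]) - 1) * pitch
  ys <- fr$origin[2] + (seq_len(fr$dims[2]) - 1) * pitch
  zs <- fr$origin[3] + (seq_len(fr$dims[3]) - 1) * pitch
  d <- fr$dims
  plane <- array(rep(xs, times = d[2] * d[3]), d) * n[1] +
    array(rep(rep(ys, each = d[1]), times = d[3]), d) * n[2] +
    array(rep(zs, each = d[1] * d[2]), d) * n[3] -
    sum(n * as.numeric(plane_point))
  fld <- pmin(body, plane)
  if (!any(fld > 0)) stop("empty-result error: plane misses the mesh")
  res <- mesh_from_field(fld, fr$spacing, fr$origin, iso = 0,
                         inside_below = FALSE,
                         name = paste0(tooth$name, "_crown"))
  attr(res, "pitch") <- pitch
  res
}

#' Mirror a mesh across a plane
#'
#' Reflects vertices across the plane and flips face winding so normals
#' stay outward; volume is preserved.
#'
#' @param mesh a [triangle_mesh()]
#' @param plane_point point on the mirror plane (mm)
#' @param plane_normal plane normal (any nonzero length)
#' @return mirrored [triangle_mesh()]
#' @export
mirror_mesh <- function(mesh, plane_point, plane_normal) {
  n <- as.numeric(plane_normal)
  nl <- sqrt(sum(n^2))
  if (nl == 0) stop("parameter error: zero mirror normal")
  n <- n / nl
  p <- as.numeric(plane_point)
  R <- diag(3) - 2 * tcrossprod(n)
  V <- sweep(mesh$vertices, 2, p, "-") %*% t(R)
  V <- sweep(V, 2, p, "+")
  triangle_mesh(V, mesh$faces[, c(1, 3, 2), drop = FALSE], mesh$name)
}

principal_axes <- function(V) {
  pc <- prcomp(V, center = TRUE, scale. = FALSE)
  R <- pc$rotation
  sdev <- pc$sdev
  # fix signs deterministically: long axis toward +z, second toward +x
  for (c in 1:3) {
    ref <- c(0, 0, 0); ref[(c %% 3) + 1] <- 1
    dominant <- which.max(abs(R[, c]))
    if (R[dominant, c] < 0) R[, c] <- -R[, c]
  }
  if (det(R) < 0) R[, 3] <- -R[, 3]
  list(R = R, sdev = sdev)
}

#' Place an incisor crown over the target premolar
#'
#' Auto mode aligns the crown centroid to the centroid of the premolar's
#' crown portion (top `crown_frac` of the tooth along its long axis) and
#' matches principal axes (long axis to long axis, with a deterministic
#' sign convention that preserves the labial direction). Explicit mode
#' returns the user transform. The achieved overlap, intersection volume
#' over crown volume, is attached as attribute `"overlap"`.
#'
#' @param crown incisor crown [triangle_mesh()] (already mirrored)
#' @param tooth target premolar [triangle_mesh()]
#' @param mode "auto" or "explicit"
#' @param user_transform a [rigid_transform()] for explicit mode
#' @param crown_frac fraction of the tooth height treated as crown
#' @param pitch voxel pitch for overlap measurement
#' @return a [rigid_transform()] with attribute "overlap"
#' @export
place_over_target <- function(crown, tooth, mode = c("auto", "explicit"),
                              user_transform = NULL, crown_frac = 0.4,
                              pitch = NULL) {
  mode <- match.arg(mode)
  if (nrow(crown$vertices) == 0 || nrow(tooth$vertices) == 0)
    stop("empty mesh")
  if (mode == "explicit") {
    if (is.null(user_transform)) stop("explicit mode needs user_transform")
    tf <- user_transform
  } else {
    pa_c <- principal_axes(crown$vertices)
    pa_t <- principal_axes(tooth$vertices)
    iso_c <- pa_c$sdev[1] / max(pa_c$sdev[3], 1e-12)
    R <- if (iso_c < 1.05) {
      warning("degenerate principal axes; falling back to centroid alignment")
      diag(3)
    } else pa_t$R %*% t(pa_c$R)
    # target: centroid of the tooth's crown portion along its long axis
    long <- pa_t$R[, 1]
    h <- as.numeric(tooth$vertices %*% long)
    cut <- quantile(h, 1 - crown_frac)
    crown_pts <- tooth$vertices[h >= cut, , drop = FALSE]
    target_ctr <- colMeans(crown_pts)
    src_ctr <- colMeans(crown$vertices)
    tf <- rigid_transform(R, target_ctr - as.numeric(R %*% src_ctr))
  }
  placed <- apply_transform(crown, tf)
  ov <- tryCatch({
    if (is.null(pitch)) pitch <- default_pitch(list(placed, tooth), 140)
    fr <- common_frame(list(placed, tooth), pitch)
    a <- vox_array(placed, fr); b <- vox_array(tooth, fr)
    if (sum(a) == 0) 0 else sum(a & b) / sum(a)
  }, error = function(e) NA_real_)
  attr(tf, "overlap") <- ov
  tf
}

# shared voxel-boolean driver
boolean_op <- function(a, b, op, pitch = NULL, name = "") {
  require_watertight(a, "A")
  require_watertight(b, "B")
  a <- clean_mesh(a); b <- clean_mesh(b)
  if (is.null(pitch)) pitch <- default_pitch(list(a, b))
  fr <- common_frame(list(a, b), pitch)
  ma <- vox_array(a, fr); mb <- vox_array(b, fr)
  mo <- switch(op,
               subtract = ma & !mb,
               intersect = ma & mb,
               union = ma | mb)
  if (!any(mo))
    return(structure(triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3), name),
                     pitch = pitch))
  res <- mask_mesh(mo, fr, name = name)
  attr(res, "pitch") <- pitch
  res
}

#' Boolean subtraction of meshes (A minus B)
#'
#' Voxel-remesh Boolean: both watertight inputs are rasterized on a shared
#' grid, the masks combined, and the result re-triangulated. An empty
#' result (B swallows A) is returned as an empty mesh, not an error.
#'
#' @param a,b watertight [triangle_mesh()] objects
#' @param pitch voxel pitch in mm; NULL picks `max extent / 220`,
#'   clamped to `[0.02, 0.25]`
#' @return watertight [triangle_mesh()] of closure(A \ B), with the pitch
#'   used attached as attribute "pitch"
#' @export
boolean_subtract <- function(a, b, pitch = NULL) {
  boolean_op(a, b, "subtract", pitch,
             name = paste0(a$name, "_minus_", b$name))
}

#' Boolean intersection of meshes
#' @inheritParams boolean_subtract
#' @return watertight [triangle_mesh()] of A intersected with B
#' @export
boolean_intersect <- function(a, b, pitch = NULL) {
  boolean_op(a, b, "intersect", pitch,
             name = paste0(a$name, "_and_", b$name))
}

#' Boolean union of meshes
#' @inheritParams boolean_subtract
#' @return watertight [triangle_mesh()] of A united with B
#' @export
boolean_union <- function(a, b, pitch = NULL) {
  boolean_op(a, b, "union", pitch, name = paste0(a$name, "_or_", b$name))
}

#' Offset (inflate or deflate) a watertight mesh
#'
#' Voxel-remesh offset: the signed-distance field of the mesh is extracted
#' at iso level `-delta`, moving the surface outward by `delta` (inward if
#' negative). Used for cement-space clearance around the tooth.
#'
#' @param mesh watertight [triangle_mesh()]
#' @param delta offset in mm (positive = outward)
#' @param pitch voxel pitch (NULL: automatic)
#' @return offset [triangle_mesh()]
#' @export
offset_mesh <- function(mesh, delta, pitch = NULL) {
  require_watertight(mesh, "mesh")
  if (is.null(pitch)) pitch <- default_pitch(list(mesh))
  fr <- common_frame(list(mesh), pitch, pad = abs(delta) + 4 * pitch)
  d <- signed_distance_grid(mesh, fr, refine_sel = function(d0)
    which(abs(d0 - delta) < 2.5 * pitch))   # exact where the offset falls
  res <- mesh_from_field(d, fr$spacing, fr$origin, iso = delta,
                         inside_below = TRUE, name = mesh$name)
  attr(res, "pitch") <- pitch
  res
}

vertex_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # area-weighted
  vn <- matrix(0, nrow(V), 3)
  for (c in 1:3) {
    agg <- rowsum(fn, group = F[, c])
    vn[as.integer(rownames(agg)), ] <- vn[as.integer(rownames(agg)), ] + agg
  }
  len <- sqrt(rowSums(vn^2)); len[len == 0] <- 1
  vn / len
}

# neighbor-average normals a few times; voxel-remeshed surfaces have
# staircase normals and inward rays need a stable direction
smooth_vertex_normals <- function(mesh, iters = 8L) {
  vn <- vertex_normals(mesh)
  F <- mesh$faces
  from <- c(F[, 1], F[, 2], F[, 3], F[, 2], F[, 3], F[, 1])
  to <- c(F[, 2], F[, 3], F[, 1], F[, 1], F[, 2], F[, 3])
  deg <- tabulate(from, nbins = nrow(mesh$vertices))
  deg[deg == 0] <- 1
  for (it in seq_len(iters)) {
    acc <- rowsum(vn[to, , drop = FALSE], group = from)
    vn2 <- vn
    vn2[as.integer(rownames(acc)), ] <- acc / deg[as.integer(rownames(acc))]
    vn <- 0.5 * vn + 0.5 * vn2
    len <- sqrt(rowSums(vn^2)); len[len == 0] <- 1
    vn <- vn / len
  }
  vn
}

#' Check the wall thickness of a veneer
#'
#' Wall thickness at a surface point is measured by casting a ray inward
#' (opposite the outward vertex normal) to the first hit on the opposite
#' wall. At most `max_samples` vertices are sampled (deterministic,
#' evenly strided).
#'
#' @param veneer watertight [triangle_mesh()]
#' @param min_thickness threshold in mm (default 0.5, typical DLP printing
#'   floor)
#' @param max_samples cap on sampled vertices
#' @return a `thickness_report`: per-vertex thickness (mm), `min`, and
#'   `violating_area_fraction` (fraction of sampled points below threshold)
#' @export
check_thickness <- function(veneer, min_thickness = 0.5, max_samples = 2000L) {
  require_watertight(veneer, "veneer")
  V <- veneer$vertices
  vn <- smooth_vertex_normals(veneer)
  n <- nrow(V)
  pick <- unique(as.integer(round(seq(1, n, length.out = min(n, max_samples)))))
  th <- cpp_ray_thickness(V, veneer$faces,
                          V[pick, , drop = FALSE], -vn[pick, , drop = FALSE],
                          eps = 1e-9)
  ok <- is.finite(th)
  th <- th[ok]
  if (length(th) == 0) stop("geometry error: no thickness samples")
  structure(list(thickness = th, vertex_index = pick[ok],
                 min = min(th),
                 min_thickness = min_thickness,
                 violating_area_fraction = mean(th < min_thickness)),
            class = "thickness_report")
}

#' @export
print.thickness_report <- function(x, ...) {
  cat(sprintf(paste0("thickness_report: %d samples, min %.3f mm, ",
                     "median %.3f mm, %.1f%% below %.2f mm\n"),
              length(x$thickness), x$min, median(x$thickness),
              100 * x$violating_area_fraction, x$min_thickness))
  invisible(x)
}

rotation_to_z <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  v <- c(a[2] * z[3] - a[3] * z[2], a[3] * z[1] - a[1] * z[3],
         a[1] * z[2] - a[2] * z[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * z)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    return(diag(c(1, -1, -1)))      # 180 deg about x
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

#' Remove undercuts by blockout along the insertion axis
#'
#' Relieves the veneer's intaglio so the veneer can translate along
#' `insertion_axis` away from the tooth without interpenetration. The
#' blockout envelope is the tooth swept opposite the removal direction
#' (the standard dental-CAD shadow region); the veneer is trimmed to its
#' complement, so material is only ever removed.
#'
#' @param veneer,tooth watertight [triangle_mesh()] objects
#' @param insertion_axis unit vector: direction the veneer moves to come
#'   off the tooth
#' @param clearance blockout clearance in mm: the swept envelope is the
#'   tooth dilated by this amount, so the relieved intaglio keeps a
#'   seating clearance along the whole path. Keep it below the design's
#'   cement-space clearance so an already-relieved veneer is untouched.
#' @param pitch voxel pitch in mm (NULL: automatic)
#' @return the relieved veneer [triangle_mesh()]
#' @export
remove_undercuts <- function(veneer, tooth, insertion_axis,
                             clearance = 0.04, pitch = NULL) {
  require_watertight(veneer, "veneer")
  require_watertight(tooth, "tooth")
  axis <- as.numeric(insertion_axis)
  al <- sqrt(sum(axis^2))
  if (al == 0) stop("parameter error: zero insertion axis")
  axis <- axis / al
  R <- rotation_to_z(axis)
  vz <- transform_mesh(veneer, R)
  tz <- transform_mesh(tooth, R)
  if (is.null(pitch)) pitch <- default_pitch(list(vz, tz))
  fr <- common_frame(list(vz, tz), pitch, pad = clearance + 4 * pitch)
  # signed fields: veneer body positive inside; tooth distance positive
  # outside, refined where the blockout envelope surface falls
  body <- -signed_distance_grid(vz, fr, refine_sel = function(d0)
    which(abs(d0) < 2.5 * pitch))
  D <- signed_distance_grid(tz, fr, refine_sel = function(d0)
    which(abs(d0 - clearance) < 2.5 * pitch))
  # swept clearance: distance to the tooth translated upward by any t >= 0
  # equals the running minimum of D from the top down
  nz <- fr$dims[3]
  S <- D
  for (k in (nz - 1):1) S[, , k] <- pmin(S[, , k], S[, , k + 1])
  fld <- pmin(body, S - clearance)
  if (!any(fld > 0)) stop("design error: blockout removes the whole veneer")
  res <- mesh_from_field(fld, fr$spacing, fr$origin, iso = 0,
                         inside_below = FALSE, name = veneer$name)
  res <- transform_mesh(res, t(R))
  attr(res, "pitch") <- pitch
  res
}

#' Sweep (path-of-insertion) test
#'
#' Translates the veneer along the insertion axis in `stations` steps over
#' `travel` mm and measures the intersection volume with the tooth at each
#' station. Seating is possible iff every station is interference-free.
#'
#' @param veneer,tooth watertight [triangle_mesh()] objects
#' @param insertion_axis removal direction (unit length not required)
#' @param travel total sweep distance in mm
#' @param stations number of translated copies tested
#' @param pitch voxel pitch (NULL: automatic)
#' @return list: `pass` (logical), `max_interference_mm3`, per-station
#'   volumes
#' @export
sweep_test <- function(veneer, tooth, insertion_axis, travel = 2,
                       stations = 20, pitch = NULL) {
  axis <- as.numeric(insertion_axis)
  axis <- axis / sqrt(sum(axis^2))
  R <- rotation_to_z(axis)
  vz <- transform_mesh(veneer, R)
  tz <- transform_mesh(tooth, R)
  if (is.null(pitch)) pitch <- default_pitch(list(vz, tz))
  # pad frame upward to accommodate the sweep
  fr <- common_frame(list(vz, tz), pitch, pad = 3 * pitch)
  fr$dims[3] <- fr$dims[3] + as.integer(ceiling(travel / pitch))
  mv <- vox_array(vz, fr)
  mt <- vox_array(tz, fr)
  nz <- fr$dims[3]
  shifts <- unique(pmax(0L, as.integer(round(
    seq(0, travel, length.out = stations) / pitch))))
  vols <- vapply(shifts, function(s) {
    if (s == 0) return(sum(mv & mt) * pitch^3)
    kk <- seq_len(nz - s)
    # veneer raised by s voxels: its material at slice k came from k - s
    sum(mv[, , kk] & mt[, , kk + s]) * pitch^3
  }, 0.0)
  list(pass = all(vols == 0), max_interference_mm3 = max(vols),
       station_shift_mm = shifts * pitch, interference_mm3 = vols)
}

#' Bevel the cervical margin edge of a veneer
#'
#' Chamfers a band of width `band` above the veneer's margin (its lowest
#' extent along the insertion axis): at height h above the margin, material
#' within lateral depth `(band - h) * tan(angle)` of the outer boundary is
#' removed. Watertightness is preserved and volume can only decrease.
#'
#' @param veneer watertight [triangle_mesh()]
#' @param margin_band band height in mm (> 0; 0 returns the input)
#' @param angle chamfer angle in degrees (45 = depth equals height)
#' @param insertion_axis axis defining "up"; margin is the lowest rim
#' @param pitch voxel pitch (NULL: automatic)
#' @return beveled [triangle_mesh()]
#' @export
bevel_edges <- function(veneer, margin_band = 0.3, angle = 45,
                        insertion_axis = c(0, 0, 1), pitch = NULL) {
  require_watertight(veneer, "veneer")
  if (margin_band < 0) stop("parameter error: negative band")
  if (margin_band == 0) return(veneer)
  axis <- as.numeric(insertion_axis)
  axis <- axis / sqrt(sum(axis^2))
  R <- rotation_to_z(axis)
  vz <- transform_mesh(veneer, R)
  b <- mesh_bbox(vz)
  if (margin_band >= (b$hi[3] - b$lo[3]))
    stop("parameter error: band exceeds veneer height")
  if (is.null(pitch)) pitch <- default_pitch(list(vz))
  fr <- common_frame(list(vz), pitch)
  mv <- vox_array(vz, fr)
  # signed field (positive inside) with exact mesh distance in a narrow
  # band: gives sub-voxel surface placement free of voxel-phase bias
  body <- -signed_distance_grid(vz, fr, refine_sel = function(d0)
    which(abs(d0) < 2.5 * pitch))
  zs <- fr$origin[3] + (seq_len(fr$dims[3]) - 1) * pitch
  zmin <- b$lo[3]    # the true margin plane is the mesh's lowest extent
  tana <- tan(angle * pi / 180)
  fld <- body
  ks <- which(zs - zmin >= -pitch & zs - zmin < margin_band)
  slat_above <- NULL
  for (k in rev(ks)) {
    h <- zs[k] - zmin
    depth <- (margin_band - max(h, 0)) * tana
    sl <- mv[, , k]
    if (any(sl)) {
      d2o <- cpp_edt_sq(as.logical(!sl), as.integer(c(dim(sl), 1L)),
                        c(pitch, pitch, 1))
      d2i <- cpp_edt_sq(as.logical(sl), as.integer(c(dim(sl), 1L)),
                        c(pitch, pitch, 1))
      slat_above <- matrix(sqrt(d2o) - sqrt(d2i), dim(sl)[1])  # + inside
    }
    # empty slices below the margin inherit the profile from above so the
    # chamfer field stays finite and continuous down to the margin plane
    if (is.null(slat_above)) next
    fld[, , k] <- pmin(fld[, , k], slat_above - depth)
  }
  if (!any(fld > 0)) stop("parameter error: bevel removed the whole veneer")
  res <- mesh_from_field(fld, fr$spacing, fr$origin, iso = 0,
                         inside_below = FALSE, name = veneer$name)
  res <- transform_mesh(res, t(R))
  attr(res, "pitch") <- pitch
  res
}

#' Run the full veneer design pipeline
#'
#' Mirrors and isolates the contralateral incisor crown, places it over
#' the premolar, subtracts the premolar, and finishes the veneer in the
#' fixed order: undercut removal, edge bevel, thickness inspection.
#'
#' @param incisor contralateral incisor [triangle_mesh()]
#' @param tooth target premolar [triangle_mesh()]
#' @param mirror_plane `list(point =, normal =)` or NULL to skip mirroring
#' @param cervical_plane `list(point =, normal =)` or NULL to use the
#'   incisor as supplied
#' @param insertion_axis removal direction (default labial, +x)
#' @param min_thickness printing floor in mm
#' @param bevel_band,bevel_angle chamfer parameters
#' @param clearance cement-space clearance in mm: the tooth is inflated by
#'   this amount before subtraction so the finished veneer seats with a
#'   uniform cement gap and never interpenetrates the tooth
#' @param placement NULL for auto, or an explicit [rigid_transform()]
#' @param pitch voxel pitch for all Boolean steps
#' @return a `veneer_design`: fields incisor_crown, target_tooth,
#'   placement, veneer, insertion_axis, min_thickness, thickness_report,
#'   sweep
#' @export
design_veneer <- function(incisor, tooth, mirror_plane = NULL,
                          cervical_plane = NULL,
                          insertion_axis = c(1, 0, 0),
                          min_thickness = 0.5,
                          bevel_band = 0.3, bevel_angle = 45,
                          clearance = 0.12,
                          placement = NULL, pitch = 0.07) {
  crown <- incisor
  if (!is.null(mirror_plane))
    crown <- mirror_mesh(crown, mirror_plane$point, mirror_plane$normal)
  if (!is.null(cervical_plane))
    crown <- isolate_crown(crown, cervical_plane$point,
                           cervical_plane$normal, pitch = pitch)
  tf <- if (is.null(placement)) {
    place_over_target(crown, tooth, mode = "auto", pitch = pitch)
  } else {
    place_over_target(crown, tooth, mode = "explicit",
                      user_transform = placement, pitch = pitch)
  }
  placed <- apply_transform(crown, tf)
  tooth_sub <- if (clearance > 0) {
    offset_mesh(tooth, clearance, pitch = pitch)
  } else tooth
  veneer <- boolean_subtract(placed, tooth_sub, pitch = pitch)
  if (nrow(veneer$faces) == 0)
    stop("design error: subtraction left no material")
  veneer <- remove_undercuts(veneer, tooth, insertion_axis,
                             clearance = clearance / 2, pitch = pitch)
  veneer <- bevel_edges(veneer, bevel_band, bevel_angle, insertion_axis,
                        pitch = pitch)
  veneer$name <- "veneer"
  rep_th <- check_thickness(veneer, min_thickness)
  sw <- sweep_test(veneer, tooth, insertion_axis, pitch = attr(veneer, "pitch"))
  structure(list(incisor_crown = placed, target_tooth = tooth,
                 placement = tf, veneer = veneer,
                 insertion_axis = insertion_axis / sqrt(sum(insertion_axis^2)),
                 min_thickness = min_thickness,
                 thickness_report = rep_th, sweep = sw),
            class = "veneer_design")
}

#' @export
print.veneer_design <- function(x, ...) {
  cat(sprintf("veneer_design: veneer volume %.3f mm^3, overlap %.2f, sweep %s\n",
              mesh_volume(x$veneer),
              attr(x$placement, "overlap"),
              if (x$sweep$pass) "pass" else "FAIL"))
  invisible(x)
}
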