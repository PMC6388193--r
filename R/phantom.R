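# Synthetic phantoms: parametric teeth, seated veneers with prescribed gap
# fields, noisy CBCT/uCT-like voxelizations, and rendered margin images,
# all with ground truth. Phantom teeth are superellipsoid composites —
# enough to exercise every geometric operator; anatomical realism is a
# non-goal.

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Tooth phantom specification
#'
#' Dimensions follow typical permanent-tooth anatomy: premolar crown about
#' 8 mm wide and 8 mm high with two cusps, maxillary central incisor crown
#' wider and taller with a flattened labial face; single tapered root.
#'
#' @param kind "premolar" or "incisor"
#' @param crown_width,crown_depth,crown_height crown extents in mm
#'   (defaults per kind)
#' @param root_length,root_taper root length (mm) and apical taper (0-1)
#' @param bumpiness surface perturbation amplitude in mm
#' @param seed integer; same seed gives an identical mesh
#' @return a `tooth_phantom_spec`
#' @export
tooth_phantom_spec <- function(kind = c("premolar", "incisor"),
                               crown_width = NULL, crown_depth = NULL,
                               crown_height = NULL, root_length = 13,
                               root_taper = 0.7, bumpiness = 0.05,
                               seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(crown_width)) crown_width <- if (kind == "premolar") 8 else 9.5
  if (is.null(crown_depth)) crown_depth <- if (kind == "premolar") 7.5 else 8
  if (is.null(crown_height)) crown_height <- if (kind == "premolar") 8 else 11
  dims <- c(crown_width, crown_depth, crown_height, root_length)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("parameter error: non-positive dimension")
  if (root_taper < 0 || root_taper >= 1) stop("root_taper must be in [0,1)")
  if (bumpiness < 0) stop("parameter error: negative bumpiness")
  structure(list(kind = kind, crown_width = crown_width,
                 crown_depth = crown_depth, crown_height = crown_height,
                 root_length = root_length, root_taper = root_taper,
                 bumpiness = bumpiness, seed = as.integer(seed)),
            class = "tooth_phantom_spec")
}

# implicit field for a spec, negative inside; approximately mm-scaled
tooth_implicit <- function(spec) {
  a <- spec$crown_width / 2
  b <- spec$crown_depth / 2
  ch <- spec$crown_height
  L <- spec$root_length
  m <- 3
  bump <- NULL
  if (spec$bumpiness > 0) {
    bump <- with_seed(spec$seed, {
      nq <- 4L
      dirs <- matrix(rnorm(3 * nq), nq, 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      list(k = dirs * (2 * pi / runif(nq, 1.6, 3.2)),
           phase = runif(nq, 0, 2 * pi),
           amp = spec$bumpiness / nq)
    })
  }
  se <- function(x, y, z, ax, by, cz, zc) {
    r <- (abs(x / ax)^m + abs(y / by)^m + abs((z - zc) / cz)^m)^(1 / m)
    (r - 1) * min(ax, by, cz)
  }
  function(x, y, z) {
    # crown body centered at z = ch/2
    f <- se(x, y, z, a, b, ch / 2, ch / 2)
    if (spec$kind == "premolar") {
      # two cusps astride the central fissure
      f <- pmin(f, se(x - 0.3 * a, y, z, 0.45 * a, 0.85 * b, 0.25 * ch, 0.78 * ch))
      f <- pmin(f, se(x + 0.3 * a, y, z, 0.45 * a, 0.85 * b, 0.25 * ch, 0.78 * ch))
    } else {
      # flatten the labial (+x) face; thin toward the incisal edge
      f <- pmax(f, x - 0.72 * a)
    }
    # tapered root from z = 0 down to z = -L
    r0 <- 0.62 * min(a, b)
    rz <- r0 * (1 - spec$root_taper * pmin(pmax(-z / L, 0), 1))
    fr <- (sqrt((x / rz)^2 + (y / rz)^2) - 1) * r0
    fr <- pmax(fr, z - 0.5, -z - L)
    f <- pmin(f, fr)
    if (!is.null(bump)) {
      s <- 0
      for (q in seq_along(bump$phase))
        s <- s + sin(bump$k[q, 1] * x + bump$k[q, 2] * y + bump$k[q, 3] * z +
                       bump$phase[q])
      f <- f + bump$amp * s
    }
    f
  }
}

eval_on_grid <- function(fun, frame) {
  xs <- frame$origin[1] + (seq_len(frame$dims[1]) - 1) * frame$spacing[1]
  ys <- frame$origin[2] + (seq_len(frame$dims[2]) - 1) * frame$spacing[2]
  zs <- frame$origin[3] + (seq_len(frame$dims[3]) - 1) * frame$spacing[3]
  X <- array(rep(xs, times = frame$dims[2] * frame$dims[3]), frame$dims)
  Y <- array(rep(rep(ys, each = frame$dims[1]), times = frame$dims[3]), frame$dims)
  Z <- array(rep(zs, each = frame$dims[1] * frame$dims[2]), frame$dims)
  array(fun(as.numeric(X), as.numeric(Y), as.numeric(Z)), frame$dims)
}

#' Generate a phantom tooth mesh
#'
#' Evaluates the spec's implicit model on a grid and extracts the zero
#' level set: premolars get a two-cusp superellipsoid crown with a tapered
#' root, incisors a taller crown with a flattened labial (+x) face. The
#' crown occupies z in [0, crown_height], the root z < 0. Deterministic
#' per seed; the implicit function is attached as attribute "implicit".
#'
#' @param spec a [tooth_phantom_spec()] (or arguments for one)
#' @param pitch grid pitch in mm for surface extraction
#' @return a watertight [triangle_mesh()]
#' @export
make_tooth <- function(spec = tooth_phantom_spec(), pitch = 0.15) {
  if (!inherits(spec, "tooth_phantom_spec"))
    stop("spec must be a tooth_phantom_spec")
  f <- tooth_implicit(spec)
  pad <- 4 * pitch + spec$bumpiness
  lo <- c(-spec$crown_width / 2 - pad, -spec$crown_depth / 2 - pad,
          -spec$root_length - pad)
  hi <- c(spec$crown_width / 2 + pad, spec$crown_depth / 2 + pad,
          1.05 * spec$crown_height + pad)
  dims <- as.integer(ceiling((hi - lo) / pitch)) + 1L
  frame <- list(dims = dims, spacing = rep(pitch, 3), origin = lo)
  fld <- eval_on_grid(f, frame)
  mesh <- mesh_from_field(fld, frame$spacing, frame$origin, iso = 0,
                          inside_below = TRUE,
                          name = sprintf("%s_s%d", spec$kind, spec$seed))
  attr(mesh, "implicit") <- f
  attr(mesh, "spec") <- spec
  mesh
}

#' Gap field specification
#'
#' Spatial model of the tooth-veneer gap: `uniform` (constant), `normal`
#' (smooth random field with the given marginal mean/SD and correlation
#' length `wavelength`, truncated below), or `sinusoidal` (mean plus a
#' sine of amplitude `sd` along z).
#'
#' @param model "uniform", "normal", or "sinusoidal"
#' @param mean,sd marginal mean and SD (or sine amplitude) in um
#' @param wavelength spatial wavelength / correlation length in mm
#' @param truncation lower truncation in um (>= 0)
#' @param seed integer
#' @return a `gap_field_spec`
#' @export
gap_field_spec <- function(model = c("uniform", "normal", "sinusoidal"),
                           mean = 100, sd = 50, wavelength = 3,
                           truncation = 0, seed = 1L) {
  model <- match.arg(model)
  if (mean < 0 || sd < 0 || truncation < 0 || wavelength <= 0)
    stop("parameter error: invalid gap field parameters")
  structure(list(model = model, mean = mean, sd = sd,
                 wavelength = wavelength, truncation = truncation,
                 seed = as.integer(seed)),
            class = "gap_field_spec")
}

# returns g(x,y,z) in mm, already truncated
gap_field_fun <- function(spec) {
  mean_mm <- spec$mean / 1000
  sd_mm <- spec$sd / 1000
  tr_mm <- spec$truncation / 1000
  raw <- switch(spec$model,
    uniform = function(x, y, z) rep(mean_mm, length(x)),
    sinusoidal = function(x, y, z)
      mean_mm + sd_mm * sin(2 * pi * z / spec$wavelength),
    normal = {
      modes <- with_seed(spec$seed, {
        nq <- 12L
        dirs <- matrix(rnorm(3 * nq), nq, 3)
        dirs <- dirs / sqrt(rowSums(dirs^2))
        list(k = dirs * (2 * pi / spec$wavelength),
             phase = runif(nq, 0, 2 * pi), nq = nq)
      })
      function(x, y, z) {
        s <- 0
        for (q in seq_len(modes$nq))
          s <- s + cos(modes$k[q, 1] * x + modes$k[q, 2] * y +
                         modes$k[q, 3] * z + modes$phase[q])
        mean_mm + sd_mm * s * sqrt(2 / modes$nq)
      }
    })
  function(x, y, z) pmax(raw(x, y, z), tr_mm)
}

# signed distance on a grid from a mesh: coarse voxel EDT everywhere;
# exact mesh distance recomputed at nodes selected by `refine_sel`
# (a function of the coarse field returning an index vector)
signed_distance_grid <- function(mesh, frame, refine_sel = NULL) {
  inside <- array(cpp_voxelize_mesh(mesh$vertices, mesh$faces - 1L,
                                    frame$origin, frame$spacing,
                                    as.integer(frame$dims)), frame$dims)
  dpos <- sqrt(cpp_edt_sq(as.logical(inside), as.integer(frame$dims),
                          frame$spacing))
  dneg <- sqrt(cpp_edt_sq(as.logical(!inside), as.integer(frame$dims),
                          frame$spacing))
  d <- array(dpos - dneg, frame$dims)   # positive outside
  if (!is.null(refine_sel)) {
    sel <- refine_sel(d)
    if (length(sel)) {
      idx <- arrayInd(sel, frame$dims)
      pts <- sweep(sweep(idx - 1, 2, frame$spacing, "*"), 2, frame$origin, "+")
      de <- cpp_grid_point_mesh_dist(pts, mesh$vertices, mesh$faces,
                                     cell = 4 * max(frame$spacing))
      d[sel] <- ifelse(inside[sel], -de, de)
    }
  }
  d
}

# trilinear interpolation of a grid field at world points
interp_grid <- function(arr, frame, pts) {
  u <- sweep(sweep(pts, 2, frame$origin, "-"), 2, frame$spacing, "/")
  i0 <- floor(u)
  i0[i0 < 0] <- 0
  for (c in 1:3) i0[, c] <- pmin(i0[, c], frame$dims[c] - 2)
  t <- u - i0
  out <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (dx * t[, 1] + (1 - dx) * (1 - t[, 1])) *
         (dy * t[, 2] + (1 - dy) * (1 - t[, 2])) *
         (dz * t[, 3] + (1 - dz) * (1 - t[, 3]))
    out <- out + w * arr[cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1,
                               i0[, 3] + dz + 1)]
  }
  out
}

#' Build a seated veneer with a prescribed gap field
#'
#' The veneer intaglio is the tooth surface offset outward by the realized
#' gap field; the outer surface comes from `veneer_outer` (optionally
#' inflated by `outer_offset`); the solid is clipped to the labial side of
#' `clip_plane` so cervical, mesial, and distal margins exist. Gap values
#' that would be negative after truncation are clamped to zero with a
#' warning.
#'
#' @param tooth watertight [triangle_mesh()] (the seated premolar)
#' @param veneer_outer watertight [triangle_mesh()] enclosing the labial
#'   crown face (e.g. a placed incisor crown)
#' @param gap a [gap_field_spec()]
#' @param pitch construction grid pitch in mm (controls intaglio accuracy)
#' @param outer_offset outward inflation of the outer surface in mm
#' @param clip_plane `list(point=, normal=)`; default keeps the labial
#'   half-space x > tooth centroid
#' @return list: `veneer` ([triangle_mesh()]), `gap_truth` (um per veneer
#'   vertex, NA off the intaglio), `intaglio` (logical per vertex),
#'   `gap_fun` (the realized field, mm)
#' @export
make_seated_pair <- function(tooth, veneer_outer, gap = gap_field_spec(),
                             pitch = 0.06, outer_offset = 0.2,
                             clip_plane = NULL) {
  g <- gap_field_fun(gap)
  if (is.null(clip_plane)) {
    ctr <- colMeans(tooth$vertices)
    clip_plane <- list(point = ctr, normal = c(1, 0, 0))
  }
  nrm <- clip_plane$normal / sqrt(sum(clip_plane$normal^2))
  b <- mesh_bbox(veneer_outer)
  lo <- b$lo - 4 * pitch - 0.2649618 * pitch; hi <- b$hi + 4 * pitch
  # the veneer lives on the positive side of the clip plane; when the plane
  # is axis-aligned, drop the grid's far side to save memory and time
  ax <- which(abs(abs(nrm) - 1) < 1e-12)
  if (length(ax) == 1) {
    if (nrm[ax] > 0) lo[ax] <- max(lo[ax], clip_plane$point[ax] - 4 * pitch)
    else hi[ax] <- min(hi[ax], clip_plane$point[ax] + 4 * pitch)
  }
  dims <- as.integer(ceiling((hi - lo) / pitch)) + 1L
  frame <- list(dims = dims, spacing = rep(pitch, 3), origin = lo)

  xs <- frame$origin[1] + (seq_len(dims[1]) - 1) * pitch
  ys <- frame$origin[2] + (seq_len(dims[2]) - 1) * pitch
  zs <- frame$origin[3] + (seq_len(dims[3]) - 1) * pitch
  X <- array(rep(xs, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(zs, each = dims[1] * dims[2]), dims)
  gv <- array(g(as.numeric(X), as.numeric(Y), as.numeric(Z)), dims)
  if (any(gv < 0)) {
    warning("gap realization negative after truncation; clamped to 0")
    gv <- pmax(gv, 0)
  }
  side <- (X - clip_plane$point[1]) * nrm[1] +
    (Y - clip_plane$point[2]) * nrm[2] + (Z - clip_plane$point[3]) * nrm[3]

  d_outer <- signed_distance_grid(veneer_outer, frame)
  # exact tooth distance only where the intaglio iso-surface can fall
  d_tooth <- signed_distance_grid(tooth, frame, refine_sel = function(d0)
    which(abs(d0 - gv) < 4 * pitch & side > -4 * pitch &
            d_outer < outer_offset + 4 * pitch))

  fld <- pmax(d_outer - outer_offset, gv - d_tooth, -side)
  veneer <- mesh_from_field(fld, frame$spacing, frame$origin,
                            iso = 0, inside_below = TRUE, name = "veneer")
  if (nrow(veneer$faces) == 0)
    stop("veneer_outer does not enclose the tooth's labial face")

  # classify intaglio vertices by the active constraint: away from the
  # outer surface and the clip plane, the offset constraint is the surface
  V <- veneer$vertices
  do_v <- interp_grid(d_outer, frame, V) - outer_offset
  side_v <- sweep(V, 2, clip_plane$point, "-") %*% nrm
  intaglio <- do_v < -3 * pitch & as.numeric(side_v) > 3 * pitch
  # snap intaglio vertices exactly onto the offset surface: project to the
  # nearest tooth point and place the vertex the prescribed gap away along
  # the projection direction (two passes for spatially varying fields)
  if (any(intaglio)) {
    sel <- which(intaglio)
    for (pass in 1:2) {
      cp <- cpp_grid_closest_point(V[sel, , drop = FALSE],
                                   tooth$vertices, tooth$faces,
                                   cell = 6 * pitch)
      dirs <- V[sel, , drop = FALSE] - cp$points
      dl <- sqrt(rowSums(dirs^2))
      ok <- dl > 1e-9
      gs <- pmax(g(V[sel, 1], V[sel, 2], V[sel, 3]), 0)
      V[sel[ok], ] <- cp$points[ok, , drop = FALSE] +
        dirs[ok, , drop = FALSE] / dl[ok] * gs[ok]
    }
    veneer$vertices <- V
  }
  gvv <- pmax(g(V[, 1], V[, 2], V[, 3]), 0)
  truth <- ifelse(intaglio, gvv * 1000, NA_real_)
  list(veneer = veneer, gap_truth = truth, intaglio = intaglio, gap_fun = g)
}

#' Scan specification for scene voxelization
#'
#' @param spacing isotropic voxel size in mm (0.2 CBCT-like, 0.0128
#'   uCT-like)
#' @param intensities named phase intensities; must include `background`,
#'   other names match the labels passed to [voxelize_scene()]. Defaults
#'   mirror uCT radiodensity ordering: enamel > resin > air gap.
#' @param noise_sd additive Gaussian noise SD (intensity units)
#' @param blur_fwhm Gaussian blur FWHM in mm (partial-volume surrogate)
#' @param seed integer
#' @return a `scan_spec`
#' @export
scan_spec <- function(spacing = 0.0128,
                      intensities = c(background = 0, enamel = 1,
                                      resin = 0.55, air_gap = 0.05),
                      noise_sd = 0.02, blur_fwhm = 0, seed = 1L) {
  if (spacing <= 0) stop("spacing must be > 0")
  if (is.null(names(intensities)) || !"background" %in% names(intensities))
    stop("intensities must be named and include 'background'")
  if (anyDuplicated(intensities))
    stop("phase intensities must be distinct")
  structure(list(spacing = spacing, intensities = intensities,
                 noise_sd = noise_sd, blur_fwhm = blur_fwhm,
                 seed = as.integer(seed)),
            class = "scan_spec")
}

#' Voxelize a labelled scene of meshes
#'
#' Inside-tests each mesh on a shared grid (later meshes override earlier
#' ones), assigns phase intensities, then applies Gaussian blur and
#' additive Gaussian noise per the scan spec. The ground-truth label mask
#' is returned alongside.
#'
#' @param meshes named list of watertight [triangle_mesh()]; names must
#'   appear in `scan$intensities`
#' @param scan a [scan_spec()]
#' @param bbox optional `list(lo=, hi=)` region of interest in mm;
#'   default covers all meshes with padding
#' @return list: `volume` ([voxel_volume()]), `labels` (integer array, 0 =
#'   background, i = i-th mesh), `label_names`
#' @export
voxelize_scene <- function(meshes, scan = scan_spec(), bbox = NULL) {
  if (is.null(names(meshes)) || any(!nzchar(names(meshes))))
    stop("meshes must be a named list")
  unknown <- setdiff(names(meshes), names(scan$intensities))
  if (length(unknown))
    stop("parameter error: unknown label(s) ", paste(unknown, collapse = ", "))
  p <- scan$spacing
  if (is.null(bbox)) {
    lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
    for (m in meshes) {
      bb <- mesh_bbox(m); lo <- pmin(lo, bb$lo); hi <- pmax(hi, bb$hi)
    }
    lo <- lo - 3 * p - 0.2649618 * p; hi <- hi + 3 * p
  } else {
    lo <- bbox$lo; hi <- bbox$hi
  }
  dims <- pmax(as.integer(ceiling((hi - lo) / p)) + 1L, 2L)
  if (prod(dims) > 6e8) stop("scene too large at this spacing; crop a ROI")
  labels <- array(0L, dims)
  for (i in seq_along(meshes)) {
    inside <- cpp_voxelize_mesh(meshes[[i]]$vertices, meshes[[i]]$faces - 1L,
                                lo, rep(p, 3), as.integer(dims))
    labels[inside] <- i
  }
  inten <- array(scan$intensities[["background"]], dims)
  for (i in seq_along(meshes))
    inten[labels == i] <- scan$intensities[[names(meshes)[i]]]
  if (scan$blur_fwhm > 0) {
    sig <- scan$blur_fwhm / (2 * sqrt(2 * log(2))) / p
    inten <- array(cpp_gaussian_blur3(as.numeric(inten), as.integer(dims),
                                      rep(sig, 3)), dims)
  }
  if (scan$noise_sd > 0)
    inten <- inten + with_seed(scan$seed,
                               array(rnorm(prod(dims), 0, scan$noise_sd), dims))
  list(volume = voxel_volume(inten, rep(p, 3), lo),
       labels = labels, label_names = names(meshes))
}

# margin station points: intaglio-edge vertices extreme in the side
# direction, binned along the margin
margin_stations <- function(pair, tooth, side, n_bins = 40L) {
  V <- pair$veneer$vertices
  ok <- which(pair$intaglio)
  if (length(ok) < n_bins) stop("render error: veneer absent on side ", side)
  Vi <- V[ok, , drop = FALSE]
  if (side == "cervical") {
    along <- Vi[, 2]; extreme <- -Vi[, 3]
  } else if (side == "mesial") {
    along <- Vi[, 3]; extreme <- Vi[, 2]
  } else {
    along <- Vi[, 3]; extreme <- -Vi[, 2]
  }
  rng <- quantile(along, c(0.25, 0.75))
  bins <- cut(along, breaks = seq(rng[1], rng[2], length.out = n_bins + 1),
              labels = FALSE)
  sel <- ok[vapply(seq_len(n_bins), function(b) {
    cand <- which(bins == b)
    if (!length(cand)) return(NA_integer_)
    cand[which.max(extreme[cand])]
  }, 0L)]
  sel <- sel[!is.na(sel)]
  if (length(sel) < 6) stop("render error: veneer absent on side ", side)
  sel
}

#' Render a synthetic margin image
#'
#' Emulates a calibrated stereomicroscope view of one veneer margin: the
#' true gap profile along the margin is measured geometrically (distance
#' from intaglio-edge stations to the tooth surface), then drawn as a
#' two-phase-plus-background raster in which the tooth and veneer edges
#' are separated by that profile. The profile is attached as attribute
#' `"gap_truth_um"`, the calibration as `"pixel_size"`.
#'
#' @param tooth tooth [triangle_mesh()]
#' @param pair result of [make_seated_pair()]
#' @param side "cervical", "mesial", or "distal"
#' @param pixel_size um per pixel (default 5, 50x-magnification scale)
#' @param width_px image width in pixels
#' @param noise_sd additive noise SD (intensity units)
#' @param seed integer for the noise
#' @return numeric matrix (rows across the margin, columns along it) with
#'   attributes `pixel_size`, `gap_truth_um`, `side`
#' @export
render_margin_image <- function(tooth, pair,
                                side = c("cervical", "mesial", "distal"),
                                pixel_size = 5, width_px = 240L,
                                noise_sd = 0.02, seed = 1L) {
  side <- match.arg(side)
  sel <- margin_stations(pair, tooth, side)
  pts <- pair$veneer$vertices[sel, , drop = FALSE]
  gap_um <- cpp_grid_point_mesh_dist(pts, tooth$vertices, tooth$faces,
                                     cell = 0.5) * 1000
  # order stations along the margin and interpolate to pixel columns
  ord <- order(if (side == "cervical") pts[, 2] else pts[, 3])
  gap_um <- gap_um[ord]
  prof <- stats::approx(seq_along(gap_um), gap_um, n = width_px)$y
  gpx <- pmax(round(prof / pixel_size), 0)
  wall_px <- as.integer(round(600 / pixel_size))      # 0.6 mm veneer wall
  nr <- as.integer(max(gpx) + 2 * wall_px + 10)
  rt <- wall_px                                        # tooth edge row
  img <- matrix(0.05, nr, width_px)
  for (cc in seq_len(width_px)) {
    img[1:rt, cc] <- 1.0                               # tooth
    v0 <- rt + gpx[cc]
    img[v0:min(v0 + wall_px, nr), cc] <- 0.55          # veneer
  }
  if (noise_sd > 0)
    img <- img + with_seed(seed, matrix(rnorm(length(img), 0, noise_sd),
                                        nrow = nr))
  attr(img, "pixel_size") <- pixel_size
  attr(img, "gap_truth_um") <- prof
  attr(img, "side") <- side
  img
}

#' Generate a batch of seated veneer phantoms
#'
#' Builds `n` premolar/incisor pairs (seeds derived from `seed`), seats a
#' veneer on each with the requested gap field, and renders the three
#' margin images per veneer. This is the synthetic analogue of the
#' 15-specimen study batch.
#'
#' @param n number of veneers (study: 15)
#' @param gap_mean,gap_sd gap field mean and SD in um (study-level
#'   conditions: 100 and 50)
#' @param gap_model gap field model (default "normal")
#' @param seed master seed
#' @param pitch seating-construction pitch in mm
#' @param pixel_size margin image calibration, um/px
#' @param out_dir optional directory: writes STLs and a ground-truth JSON
#'   manifest
#' @return list of per-veneer records: tooth, pair, margin images by side,
#'   gap spec; plus `manifest` when `out_dir` is given
#' @export
make_phantom_batch <- function(n = 15L, gap_mean = 100, gap_sd = 50,
                               gap_model = "normal", seed = 7L,
                               pitch = 0.08, pixel_size = 5,
                               out_dir = NULL) {
  records <- vector("list", n)
  for (i in seq_len(n)) {
    si <- as.integer(seed) + i
    tooth <- make_tooth(tooth_phantom_spec("premolar", seed = si))
    incisor <- make_tooth(tooth_phantom_spec("incisor", seed = si + 1000L))
    crown <- isolate_crown(incisor, plane_point = c(0, 0, 2.0),
                           plane_normal = c(0, 0, 1))
    tf <- place_over_target(crown, tooth, mode = "auto")
    placed <- apply_transform(crown, tf)
    gspec <- gap_field_spec(gap_model, mean = gap_mean, sd = gap_sd,
                            truncation = 0, seed = si)
    pair <- make_seated_pair(tooth, placed, gspec, pitch = pitch)
    imgs <- lapply(c("cervical", "mesial", "distal"), function(s)
      render_margin_image(tooth, pair, s, pixel_size = pixel_size,
                          seed = si + 5000L))
    names(imgs) <- c("cervical", "mesial", "distal")
    records[[i]] <- list(tooth = tooth, pair = pair, images = imgs,
                         gap_spec = gspec, seed = si)
  }
  out <- list(records = records, n = n, gap_mean = gap_mean, gap_sd = gap_sd,
              seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(n = n, gap_mean_um = gap_mean, gap_sd_um = gap_sd,
                     seed = seed, veneers = list())
    for (i in seq_len(n)) {
      tp <- file.path(out_dir, sprintf("tooth_%02d.stl", i))
      vp <- file.path(out_dir, sprintf("veneer_%02d.stl", i))
      write_mesh(records[[i]]$tooth, tp)
      write_mesh(records[[i]]$pair$veneer, vp)
      manifest$veneers[[i]] <- list(
        tooth = basename(tp), veneer = basename(vp),
        seed = records[[i]]$seed,
        gap_truth_um = list(
          cervical = attr(records[[i]]$images$cervical, "gap_truth_um"),
          mesial = attr(records[[i]]$images$mesial, "gap_truth_um"),
          distal = attr(records[[i]]$images$distal, "gap_truth_um")))
    }
    mp <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
    out$manifest <- mp
  }
  out
}
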