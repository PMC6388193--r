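# Livewire segmentation: gradient-cost pixel graph, F* minimal-cost paths,
# orthogonal contour sets, variational implicit surface, mask and mesh.

#' Construct a binary mask aligned to a volume frame
#'
#' @param data logical 3D array
#' @param frame a [voxel_volume()] (or list with spacing/origin) the mask
#'   is aligned to; the mask copies its spacing and origin
#' @return an object of class `binary_mask`
#' @export
binary_mask <- function(data, frame) {
  if (length(dim(data)) != 3L) stop("mask data must be a 3D array")
  structure(list(data = data, spacing = frame$spacing, origin = frame$origin),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("binary_mask %d x %d x %d, %d voxels set (%.3g mm^3)\n",
              d[1], d[2], d[3], sum(x$data),
              sum(x$data) * prod(x$spacing)))
  invisible(x)
}

is_binary_mask <- function(x) inherits(x, "binary_mask")

#' Voxel-count volume of a binary mask
#'
#' @param mask a [binary_mask()]
#' @return volume in mm^3 (set voxels times voxel volume)
#' @export
mask_volume_mm3 <- function(mask) sum(mask$data) * prod(mask$spacing)

#' Livewire edge cost of a slice
#'
#' Cost `c = 1 - g / g_max` where `g` is the gradient magnitude by central
#' differences (one-sided at borders) and `g_max` the slice maximum, so
#' strong edges have low cost. A constant slice (g_max = 0) returns uniform
#' cost 1 — the documented fallback, not an error.
#'
#' @param slice_image 2D numeric matrix
#' @return matrix of costs in [0, 1]
#' @export
edge_cost <- function(slice_image) {
  if (!is.matrix(slice_image) || nrow(slice_image) < 2 || ncol(slice_image) < 2)
    stop("slice must be at least 2 x 2")
  g <- gradient_magnitude2(slice_image)
  gmax <- max(g)
  if (gmax == 0) return(matrix(1, nrow(slice_image), ncol(slice_image)))
  1 - g / gmax
}

gradient_magnitude2 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- img; gy <- img
  gx[2:(nr - 1), ] <- (img[3:nr, ] - img[1:(nr - 2), ]) / 2
  gx[1, ] <- img[2, ] - img[1, ]
  gx[nr, ] <- img[nr, ] - img[nr - 1, ]
  gy[, 2:(nc - 1)] <- (img[, 3:nc] - img[, 1:(nc - 2)]) / 2
  gy[, 1] <- img[, 2] - img[, 1]
  gy[, nc] <- img[, nc] - img[, nc - 1]
  sqrt(gx^2 + gy^2)
}

#' Minimal-cost path between two pixels
#'
#' Computes the globally minimal accumulated-cost path on the 8-connected
#' pixel graph by the F* raster-scan dynamic program (forward/backward
#' sweeps to convergence, Dijkstra-equivalent). A step between two pixels
#' costs the mean of their costs times the geometric step length (sqrt(2)
#' for diagonal moves), so the accumulated cost is invariant under
#' endpoint reversal. Ties are broken by a fixed neighbor scan order.
#'
#' @param cost 2D cost matrix (e.g. from [edge_cost()])
#' @param start,end pixels as `c(row, col)`, 1-based
#' @return list with `path` (n x 2 matrix of row/col) and `cost` (total)
#' @export
minimal_cost_path <- function(cost, start, end) {
  if (!is.matrix(cost)) stop("cost must be a matrix")
  start <- as.integer(start); end <- as.integer(end)
  chk <- function(p) length(p) == 2 && all(!is.na(p)) &&
    p[1] >= 1 && p[1] <= nrow(cost) && p[2] >= 1 && p[2] <= ncol(cost)
  if (!chk(start) || !chk(end)) stop("endpoints out of bounds")
  if (all(start == end)) stop("start and end must differ")
  res <- cpp_fstar_path(cost, start - 1L, end - 1L)
  list(path = res$path + 1L, cost = res$cost)
}

#' Planar contour
#'
#' An ordered closed polygon on one orthogonal slice plane of a volume.
#' The first point is not repeated at the end; closure is implied.
#'
#' @param plane_axis axis index 1..3 the slice is orthogonal to
#' @param plane_index 1-based slice index along that axis
#' @param points n x 2 matrix of in-slice pixel coordinates
#'   (coordinates along the two remaining axes, in index units)
#' @return a `planar_contour`
#' @export
planar_contour <- function(plane_axis, plane_index, points) {
  points <- matrix(as.numeric(points), ncol = 2)
  if (nrow(points) >= 2 &&
      all(points[1, ] == points[nrow(points), ]))
    points <- points[-nrow(points), , drop = FALSE]
  if (nrow(unique(points)) < 3) stop("contour needs >= 3 distinct points")
  structure(list(plane_axis = as.integer(plane_axis),
                 plane_index = as.integer(plane_index),
                 points = points),
            class = "planar_contour")
}

#' Contour set
#'
#' @param contours list of [planar_contour()] spanning >= 2 distinct axes
#' @param tooth_label identifier
#' @return a `contour_set`
#' @export
contour_set <- function(contours, tooth_label = "tooth") {
  axes <- unique(vapply(contours, `[[`, 0L, "plane_axis"))
  if (length(axes) < 2) stop("contour set must span >= 2 distinct plane axes")
  structure(list(contours = contours, tooth_label = tooth_label),
            class = "contour_set")
}

#' Trace a livewire contour on a slice
#'
#' Preprocesses the slice (intensity windowing then median filter),
#' computes the edge-cost field, and chains minimal-cost paths between
#' consecutive anchors (and last back to first) into one closed contour.
#'
#' @param slice_image 2D numeric matrix
#' @param anchors n x 2 matrix of anchor pixels (row, col), n >= 3
#' @param window an [intensity_window()] (NULL skips windowing)
#' @param median_radius radius for the median filter (0 skips it)
#' @param plane_axis,plane_index slice bookkeeping for the returned contour
#' @return a [planar_contour()]
#' @export
trace_contour <- function(slice_image, anchors, window = NULL,
                          median_radius = 1L, plane_axis = 3L,
                          plane_index = 1L) {
  anchors <- matrix(as.integer(round(anchors)), ncol = 2)
  if (nrow(unique(anchors)) < 3) stop("contour error: need >= 3 distinct anchors")
  img <- slice_image
  if (!is.null(window)) img <- window_normalize(img, window)
  if (median_radius >= 1) img <- median_filter(img, median_radius)
  cost <- edge_cost(img)
  pts <- NULL
  n <- nrow(anchors)
  for (s in seq_len(n)) {
    a <- anchors[s, ]
    b <- anchors[if (s == n) 1L else s + 1L, ]
    seg <- minimal_cost_path(cost, a, b)$path
    pts <- rbind(pts, seg[-nrow(seg), , drop = FALSE])  # drop joint duplicate
  }
  pts <- pts[c(TRUE, rowSums(abs(diff(pts))) > 0), , drop = FALSE]
  if (nrow(unique(pts)) < 3 || abs(polygon_area(pts)) < 0.5)
    stop("contour error: degenerate polygon")
  planar_contour(plane_axis, plane_index, pts)
}

polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

# in-slice (u,v) for axis -> world 3D; slice axes are the two other axes
# in increasing order, e.g. plane_axis 3 -> (u, v) = (axis1, axis2).
contour_points_world <- function(contour, frame) {
  ax <- contour$plane_axis
  others <- setdiff(1:3, ax)
  idx <- matrix(0, nrow(contour$points), 3)
  idx[, others[1]] <- contour$points[, 1]
  idx[, others[2]] <- contour$points[, 2]
  idx[, ax] <- contour$plane_index
  voxel_to_world(frame, idx)
}

# inward 2D normals of a closed polygon (pointing into the enclosed region)
contour_inward_normals <- function(points) {
  n <- nrow(points)
  nxt <- points[c(2:n, 1), , drop = FALSE]
  prv <- points[c(n, 1:(n - 1)), , drop = FALSE]
  tang <- nxt - prv
  len <- sqrt(rowSums(tang^2)); len[len == 0] <- 1
  tang <- tang / len
  nrm <- cbind(-tang[, 2], tang[, 1])   # left normal
  if (polygon_area(points) < 0) nrm <- -nrm  # make it inward for CCW/CW alike
  ctr <- colMeans(points)
  # orient toward centroid (robust for the convex-ish tooth outlines here)
  flip <- rowSums(nrm * sweep(points, 2, ctr, "-")) > 0
  nrm[flip, ] <- -nrm[flip, ]
  nrm
}

#' Implicit surface from orthogonal contours (variational interpolation)
#'
#' Builds interpolation constraints from a contour set — value 0 at contour
#' points (on-surface), value -1 at points displaced inward along the 2D
#' contour normals by `normal_offset` — and solves the variational
#' (bending-energy minimizing) interpolation system with the triharmonic
#' kernel `|r|^3` plus a linear polynomial. The zero level set of the
#' returned function is the tooth surface; the function is negative inside.
#'
#' @param contours a [contour_set()]
#' @param frame the [voxel_volume()] the contour indices refer to
#' @param normal_offset inward displacement in mm for off-surface
#'   constraints (default: one voxel)
#' @param subsample keep every k-th contour point (controls system size)
#' @return an `implicit_surface` with fields centers, weights, polynomial,
#'   kernel_tag
#' @export
fit_variational_surface <- function(contours, frame,
                                    normal_offset = NULL, subsample = 1L) {
  if (!inherits(contours, "contour_set")) stop("contours must be a contour_set")
  if (is.null(normal_offset)) normal_offset <- min(frame$spacing)
  on_pts <- NULL; off_pts <- NULL
  for (ct in contours$contours) {
    p <- ct$points
    keep <- seq(1, nrow(p), by = max(1L, as.integer(subsample)))
    p <- p[keep, , drop = FALSE]
    ax <- ct$plane_axis
    others <- setdiff(1:3, ax)
    sp2 <- frame$spacing[others]
    nrm <- contour_inward_normals(p)
    p_in <- p + nrm * (normal_offset / rep(sp2, each = nrow(p)))
    to_world <- function(pp) {
      idx <- matrix(0, nrow(pp), 3)
      idx[, others[1]] <- pp[, 1]
      idx[, others[2]] <- pp[, 2]
      idx[, ax] <- ct$plane_index
      voxel_to_world(frame, idx)
    }
    on_pts <- rbind(on_pts, to_world(p))
    off_pts <- rbind(off_pts, to_world(p_in))
  }
  centers <- rbind(on_pts, off_pts)
  values <- c(rep(0, nrow(on_pts)), rep(-1, nrow(off_pts)))
  # deduplicate constraint points (exact system would be singular)
  key <- paste(round(centers[, 1], 9), round(centers[, 2], 9),
               round(centers[, 3], 9))
  keep <- !duplicated(key)
  centers <- centers[keep, , drop = FALSE]
  values <- values[keep]
  n <- nrow(centers)
  if (n < 10) stop("need >= 10 constraints")

  D <- as.matrix(dist(centers))
  A <- D^3
  P <- cbind(1, centers)
  M <- rbind(cbind(A, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- c(values, rep(0, 4))
  sol <- tryCatch(solve(M, rhs), error = function(e) {
    sol <- tryCatch(qr.solve(M, rhs, tol = 1e-12), error = function(e2) NULL)
    if (is.null(sol)) stop("numerical error: singular interpolation system")
    sol
  })
  surf <- structure(list(centers = centers, weights = sol[1:n],
                         polynomial = sol[n + 1:4],
                         kernel_tag = "triharmonic"),
                    class = "implicit_surface")
  resid <- max(abs(evaluate_surface(surf, centers) - values))
  scale <- max(abs(values), 1)
  if (resid > 1e-6 * scale * max(1, n))
    warning(sprintf("interpolation residual %.3g above tolerance", resid))
  surf
}

#' Evaluate an implicit surface
#'
#' @param surface an `implicit_surface` from [fit_variational_surface()]
#' @param points n x 3 matrix of world coordinates in mm
#' @return numeric vector of implicit values (negative inside)
#' @export
evaluate_surface <- function(surface, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_rbf_eval(surface$centers, surface$weights, surface$polynomial, points)
}

#' Rasterize an implicit surface to a binary mask
#'
#' A voxel is inside iff the implicit value at its center is negative.
#'
#' @param surface an `implicit_surface`
#' @param frame a [voxel_volume()] giving the target grid
#' @return a [binary_mask()]
#' @export
rasterize_mask <- function(surface, frame) {
  d <- dim(frame$data)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  w <- voxel_to_world(frame, idx)
  vals <- evaluate_surface(surface, w)
  binary_mask(array(vals < 0, d), frame)
}

#' Extract a surface mesh from a binary mask
#'
#' Gaussian-smooths the 0/1 indicator (sigma in voxels) and triangulates
#' the 0.5 iso-surface by marching tetrahedra, in world (mm) coordinates.
#' Masks that do not touch the grid boundary give watertight meshes.
#'
#' @param mask a [binary_mask()]
#' @param smooth_sigma indicator smoothing in voxels (0 disables)
#' @param name mesh label
#' @return a [triangle_mesh()]
#' @export
extract_surface_mesh <- function(mask, smooth_sigma = 1.0, name = "") {
  if (!is_binary_mask(mask)) stop("mask must be a binary_mask")
  if (!any(mask$data)) stop("extraction error: empty mask")
  # embed in one layer of background so masks touching the grid boundary
  # still yield closed (capped) meshes
  d0 <- dim(mask$data)
  d <- d0 + 2L
  ind <- array(0, d)
  ind[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- mask$data
  if (smooth_sigma > 0)
    ind <- array(cpp_gaussian_blur3(as.numeric(ind), as.integer(d),
                                    rep(smooth_sigma, 3)), d)
  mesh_from_field(ind, mask$spacing, mask$origin - mask$spacing,
                  iso = 0.5, inside_below = FALSE, name = name)
}
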