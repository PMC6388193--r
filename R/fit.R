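# Fit assessment: marginal gap from calibrated margin images, internal
# adaptation from micro-CT volumes (indirect gap segmentation, 3D local
# thickness), summary statistics, and one-way ANOVA.

# --- marginal protocol ------------------------------------------------------

#' Measure the marginal gap on a calibrated margin image
#'
#' Formalizes the stereomicroscope protocol: the image is segmented into
#' background, veneer, and tooth by intensity (3-class split, brightest
#' class = tooth, middle = veneer), both margin edges are traced, and at
#' `n_stations` evenly spaced stations along the margin the shortest
#' pixel distance from the tooth edge to the veneer region is recorded and
#' converted to micrometres.
#'
#' @param margin_image numeric matrix; rows run across the margin, columns
#'   along it
#' @param pixel_size calibration in um per pixel
#' @param side one of "cervical", "mesial", "distal"
#' @param n_stations readings per image (default 6, the study protocol)
#' @param thresholds optional length-2 increasing vector splitting
#'   background / veneer / tooth intensities; NULL = automatic
#' @return a `marginal_gap_measurement`: side, readings (um), pixel_size,
#'   image_id
#' @export
measure_marginal_gap <- function(margin_image, pixel_size,
                                 side = c("cervical", "mesial", "distal"),
                                 n_stations = 6L, thresholds = NULL,
                                 image_id = "") {
  side <- match.arg(side)
  img <- margin_image
  if (!is.matrix(img)) stop("margin_image must be a matrix")
  if (is.null(thresholds)) thresholds <- auto_thresholds2(img)
  if (length(thresholds) != 2L || diff(thresholds) <= 0)
    stop("thresholds must be two increasing values")
  tooth <- img > thresholds[2]
  veneer <- img > thresholds[1] & !tooth
  if (!any(tooth) || !any(veneer))
    stop("detection error: could not find two margin edges")
  usable <- which(colSums(tooth) > 0 & colSums(veneer) > 0)
  if (length(usable) < n_stations)
    stop("parameter error: margin shorter than n_stations")
  stations <- usable[unique(as.integer(round(
    seq(1, length(usable), length.out = n_stations))))]
  if (length(stations) < n_stations)
    stop("parameter error: margin shorter than n_stations")
  # distance (in px) from each pixel to the nearest veneer pixel
  d2 <- cpp_edt_sq(as.logical(veneer),
                   as.integer(c(nrow(img), ncol(img), 1L)), c(1, 1, 1))
  dpx <- matrix(sqrt(d2), nrow(img))
  readings <- vapply(stations, function(cc) {
    rt <- max(which(tooth[, cc]))           # tooth edge pixel at the station
    dpx[rt, cc] * pixel_size
  }, 0.0)
  structure(list(side = side, readings = readings, pixel_size = pixel_size,
                 image_id = image_id),
            class = "marginal_gap_measurement")
}

# two thresholds splitting three intensity classes; deterministic 1D k-means
auto_thresholds2 <- function(img) {
  v <- as.numeric(img)
  cen <- unname(quantile(v, c(0.05, 0.5, 0.95)))
  if (length(unique(cen)) < 3) stop("detection error: single-region image")
  for (it in 1:50) {
    b1 <- (cen[1] + cen[2]) / 2
    b2 <- (cen[2] + cen[3]) / 2
    g1 <- v <= b1; g3 <- v > b2
    g2 <- !g1 & !g3
    if (!any(g1) || !any(g2) || !any(g3)) break
    new_cen <- c(mean(v[g1]), mean(v[g2]), mean(v[g3]))
    if (max(abs(new_cen - cen)) < 1e-10) { cen <- new_cen; break }
    cen <- new_cen
  }
  c((cen[1] + cen[2]) / 2, (cen[2] + cen[3]) / 2)
}

# --- micro-CT internal adaptation ------------------------------------------

in_range_mask <- function(vol, range) {
  vol$data >= range[1] & vol$data <= range[2]
}

binary_dilate <- function(arr, spacing, radius_mm) {
  d2 <- cpp_edt_sq(as.logical(arr), as.integer(dim(arr)), spacing)
  array(d2 <= radius_mm^2 + 1e-12, dim(arr))
}

binary_erode <- function(arr, spacing, radius_mm) {
  # pad with one background layer: outside the grid counts as background,
  # otherwise erosion never bites at the volume boundary
  d0 <- dim(arr); d <- d0 + 2L
  padded <- array(FALSE, d)
  padded[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- arr
  d2 <- cpp_edt_sq(as.logical(!padded), as.integer(d), spacing)
  out <- array(d2 > radius_mm^2 + 1e-12, d)
  out[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1), drop = FALSE]
}

binary_close <- function(arr, spacing, radius_mm) {
  # pad by the closing radius so the dilation can extend past the grid
  # before eroding; otherwise the closing bites inward from the boundary
  p <- as.integer(ceiling(radius_mm / min(spacing))) + 2L
  d0 <- dim(arr); d <- d0 + 2L * p
  big <- array(FALSE, d)
  ix <- lapply(1:3, function(a) (p + 1L):(p + d0[a]))
  big[ix[[1]], ix[[2]], ix[[3]]] <- arr
  big <- binary_dilate(big, spacing, radius_mm)
  big <- binary_erode(big, spacing, radius_mm)
  big[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

#' Indirect gap segmentation from a micro-CT volume
#'
#' Implements the indirect protocol for a seated veneer: the solid phases
#' and the radiolucent gap are captured together as one entity by
#' thresholding followed by morphological closing (the closing bridges the
#' thin air gap sandwiched between tooth and veneer); the hard-tissue mask
#' is thresholded separately; the gap is their voxel-level set difference
#' `combined AND NOT enamel`.
#'
#' @param volume a [voxel_volume()] (uCT-like)
#' @param combined_threshold length-2 intensity range for the combined
#'   entity before closing; NULL = automatic (everything above the
#'   air/solid split)
#' @param enamel_threshold length-2 intensity range for the solid mask
#'   subtracted back out; NULL = same automatic split
#' @param closing_radius closing ball radius in mm; NULL = 2x the expected
#'   gap, here defaulted to 0.4 mm (2 x 200 um, the study cutoff)
#' @return list of three [binary_mask()]: `combined`, `enamel`, `gap`
#' @export
segment_gap_indirect <- function(volume, combined_threshold = NULL,
                                 enamel_threshold = NULL,
                                 closing_radius = NULL) {
  if (!is_voxel_volume(volume)) stop("volume must be a voxel_volume")
  if (is.null(combined_threshold) || is.null(enamel_threshold)) {
    th <- auto_thresholds2(matrix(volume$data, nrow = 1))
    if (is.null(combined_threshold)) combined_threshold <- c(th[1], Inf)
    if (is.null(enamel_threshold)) enamel_threshold <- c(th[1], Inf)
  }
  if (is.null(closing_radius)) closing_radius <- 0.4
  solid <- in_range_mask(volume, combined_threshold)
  combined <- binary_close(solid, volume$spacing, closing_radius)
  enamel <- in_range_mask(volume, enamel_threshold)
  if (!all(combined | !enamel))
    warning("protocol warning: enamel mask is not a subset of the combined entity")
  gap <- combined & !enamel
  list(combined = binary_mask(combined, volume),
       enamel = binary_mask(enamel, volume),
       gap = binary_mask(gap, volume))
}

#' Reconstruct the 3D gap model
#'
#' Meshes the combined and enamel masks, subtracts the enamel model from
#' the combined model (mesh Boolean), and carries the voxel-level gap mask
#' alongside. Only the largest connected component is kept; components
#' under `min_component` voxels are discarded as noise. An empty gap gives
#' an empty model, not an error.
#'
#' @param combined,enamel aligned [binary_mask()] objects
#' @param min_component minimum component size in voxels
#' @return a `gap_model`: fields `mask` ([binary_mask()]), `mesh`
#'   ([triangle_mesh()]), `thickness` (filled by
#'   [compute_thickness_map()])
#' @export
reconstruct_gap_model <- function(combined, enamel, min_component = 10L) {
  if (!identical(dim(combined$data), dim(enamel$data)))
    stop("masks are not aligned")
  gap <- combined$data & !enamel$data
  if (!any(gap)) {
    return(structure(list(mask = binary_mask(gap, combined),
                          mesh = triangle_mesh(matrix(0, 0, 3),
                                               matrix(0L, 0, 3), "gap"),
                          thickness = numeric(0)),
                     class = "gap_model"))
  }
  lab <- array(cpp_label_components(as.logical(gap), as.integer(dim(gap))),
               dim(gap))
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  if (sizes[keep] < min_component) {
    gap[] <- FALSE
  } else {
    gap <- lab == keep
  }
  mask <- binary_mask(gap, combined)
  mesh <- if (any(gap)) {
    mc <- extract_surface_mesh(binary_mask(combined$data, combined),
                               smooth_sigma = 0.8, name = "combined")
    me <- extract_surface_mesh(binary_mask(enamel$data, enamel),
                               smooth_sigma = 0.8, name = "enamel")
    boolean_subtract(mc, me, pitch = min(combined$spacing))
  } else {
    triangle_mesh(matrix(0, 0, 3), matrix(0L, 0, 3), "gap")
  }
  mesh$name <- "gap"
  structure(list(mask = mask, mesh = mesh, thickness = numeric(0)),
            class = "gap_model")
}

#' @export
print.gap_model <- function(x, ...) {
  nv <- sum(x$mask$data)
  cat(sprintf("gap_model: %d gap voxels (%.4g mm^3 voxel-route, %.4g mm^3 mesh-route)\n",
              nv, mask_volume_mm3(x$mask), mesh_volume(x$mesh)))
  if (length(x$thickness))
    cat(sprintf("  thickness: median %.1f um, IQR %.1f-%.1f um\n",
                median(x$thickness),
                quantile(x$thickness, 0.25), quantile(x$thickness, 0.75)))
  invisible(x)
}

#' Compute the local thickness map of a gap model
#'
#' Local thickness at a voxel is the diameter of the largest ball fully
#' inside the gap that contains the voxel (inscribed-sphere definition,
#' distance-transform based), reported in micrometres. A half-voxel border
#' correction is applied on each side so a single-voxel gap reads one
#' voxel. Requires near-isotropic spacing.
#'
#' @param gap a `gap_model` from [reconstruct_gap_model()]
#' @return the `gap_model` with `thickness` filled (one value per gap
#'   voxel, in um) and a `thickness_grid` array (NA outside the gap)
#' @export
compute_thickness_map <- function(gap) {
  if (!inherits(gap, "gap_model")) stop("gap must be a gap_model")
  mask <- gap$mask
  if (!any(mask$data)) {
    gap$thickness <- numeric(0)
    return(gap)
  }
  sp <- mask$spacing
  if (max(sp) / min(sp) > 1.01)
    stop("thickness map requires isotropic spacing")
  s <- mean(sp)
  d2 <- cpp_edt_sq(as.logical(!mask$data), as.integer(dim(mask$data)),
                   c(1, 1, 1))                      # voxel units
  rvox <- sqrt(d2)
  rvox[!mask$data] <- 0
  dia_vox <- cpp_local_thickness(as.numeric(rvox), as.integer(dim(mask$data)))
  th_mm <- (dia_vox - 1) * s                        # center-to-center minus
  th_mm[th_mm < s & dia_vox > 0] <- s               # a voxel each side; floor
  grid <- array(NA_real_, dim(mask$data))
  grid[mask$data] <- th_mm[as.logical(mask$data)] * 1000
  gap$thickness <- grid[mask$data]
  gap$thickness_grid <- grid
  gap
}

#' Export the gap model as STL plus a per-voxel thickness table
#'
#' Writes the gap mesh as STL and a CSV with one row per gap voxel (world
#' coordinates in mm plus local thickness in um) — the file pair behind
#' the color-coded adaptation map.
#'
#' @param gap a `gap_model` with thickness computed
#' @param stl_path,csv_path output paths
#' @return invisible list of the two paths
#' @export
export_thickness_map <- function(gap, stl_path, csv_path) {
  if (!length(gap$thickness)) stop("empty thickness field")
  write_mesh(gap$mesh, stl_path)
  idx <- which(gap$mask$data, arr.ind = TRUE)
  w <- sweep(sweep(idx - 1, 2, gap$mask$spacing, "*"), 2,
             gap$mask$origin, "+")
  utils::write.csv(data.frame(x = w[, 1], y = w[, 2], z = w[, 3],
                              thickness_um = gap$thickness_grid[idx]),
                   csv_path, row.names = FALSE)
  invisible(list(stl = stl_path, csv = csv_path))
}

# --- statistics -------------------------------------------------------------

#' Summarize gap values
#'
#' Mean, sample SD (n-1), median, quartiles (linear interpolation between
#' order statistics), and the fraction of values below the clinical
#' cutoff.
#'
#' @param values gap widths in um (>= 1 value)
#' @param cutoff clinical acceptability cutoff in um (default 200, the
#'   study value)
#' @return a `gap_statistics` object
#' @export
summarize_gap <- function(values, cutoff = 200) {
  values <- as.numeric(values)
  if (length(values) < 1L || any(is.na(values)))
    stop("parameter error: need >= 1 finite value")
  q <- unname(quantile(values, c(0.25, 0.75), type = 7))
  structure(list(mean = mean(values),
                 sd = if (length(values) > 1) sd(values) else 0,
                 median = median(values),
                 iqr = c(q1 = q[1], q3 = q[2]),
                 fraction_below_cutoff = mean(values < cutoff),
                 cutoff = cutoff, n = length(values)),
            class = "gap_statistics")
}

#' @export
print.gap_statistics <- function(x, ...) {
  cat(sprintf("gap: mean %.1f +/- %.1f um, median %.1f (IQR %.1f-%.1f), %.0f%% < %g um (n=%d)\n",
              x$mean, x$sd, x$median, x$iqr[1], x$iqr[2],
              100 * x$fraction_below_cutoff, x$cutoff, x$n))
  invisible(x)
}

#' Aggregate per-sample medians
#'
#' Computes each sample's median, then the mean, SD, and IQR across
#' samples — the "average median" convention of the internal-adaptation
#' report. With a single sample the SD is reported as 0 with
#' `sd_defined = FALSE`.
#'
#' @param samples list of numeric vectors (per-sample gap values, um)
#' @return list: `medians`, `mean`, `sd`, `sd_defined`, `iqr`
#' @export
aggregate_per_sample_medians <- function(samples) {
  if (!is.list(samples) || length(samples) < 1L)
    stop("parameter error: need >= 1 sample")
  med <- vapply(samples, function(v) {
    if (length(v) < 1) stop("parameter error: empty sample")
    median(as.numeric(v))
  }, 0.0)
  q <- unname(quantile(med, c(0.25, 0.75), type = 7))
  list(medians = med,
       mean = mean(med),
       sd = if (length(med) > 1) sd(med) else 0,
       sd_defined = length(med) > 1,
       iqr = c(q1 = q[1], q3 = q[2]))
}

#' One-way ANOVA
#'
#' Classic fixed-effects one-way analysis of variance from sums of
#' squares: `F = (SSB/dfB) / (SSW/dfW)`, p from the upper tail of the F
#' distribution.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 values
#' @return an `anova_result`: f_statistic, df_between, df_within, p_value
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("parameter error: need >= 2 groups")
  if (any(vapply(groups, length, 0L) < 2L))
    stop("parameter error: each group needs >= 2 values")
  all_v <- unlist(groups)
  if (max(all_v) == min(all_v))
    stop("degenerate-variance error: all values identical")
  k <- length(groups)
  n <- length(all_v)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0.0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0.0))
  if (ssw == 0)
    stop("degenerate-variance error: no within-group variance")
  dfb <- k - 1L
  dfw <- n - k
  f <- (ssb / dfb) / (ssw / dfw)
  structure(list(f_statistic = f, df_between = dfb, df_within = dfw,
                 p_value = pf(f, dfb, dfw, lower.tail = FALSE)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  invisible(x)
}
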