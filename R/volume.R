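# VoxelVolume: 3D scalar image with physical spacing and origin.
# World convention (shared by every module): right-handed frame, mm units,
# voxel (i,j,k) center at origin + (c(i,j,k) - 1) * spacing.

#' Construct a voxel volume
#'
#' A `voxel_volume` is a 3D scalar grid with a physical frame: per-axis
#' voxel edge length (`spacing`, mm) and the world position of the center
#' of voxel (1,1,1) (`origin`, mm).
#'
#' @param data numeric 3D array (intensities, arbitrary units)
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0)
#' @param origin numeric length-3, world position of the first voxel center
#' @return an object of class `voxel_volume`
#' @export
voxel_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (any(dim(data) < 2L)) stop("grid dimensions must be >= 2 per axis")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("origin must have length 3")
  structure(list(data = data + 0.0, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("voxel_volume %d x %d x %d, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

is_voxel_volume <- function(x) inherits(x, "voxel_volume")

#' World coordinates of voxel centers
#'
#' @param vol a [voxel_volume()]
#' @param idx integer matrix (n x 3) of 1-based voxel indices
#' @return numeric matrix (n x 3) of world positions in mm
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Intensity window
#'
#' Parameters of the piecewise-linear intensity windowing filter: input
#' values at or below `low` map to `out_low`, at or above `high` to
#' `out_high`, linearly in between.
#'
#' @param low,high input window bounds (low < high)
#' @param out_low,out_high output range (out_low < out_high)
#' @return an `intensity_window` object
#' @export
intensity_window <- function(low, high, out_low = 0, out_high = 1) {
  if (!is.finite(low) || !is.finite(high) || low >= high)
    stop("invalid window: low must be < high")
  if (out_low >= out_high) stop("invalid window: out_low must be < out_high")
  structure(list(low = low, high = high,
                 out_low = out_low, out_high = out_high),
            class = "intensity_window")
}

#' Window-normalize a volume
#'
#' Applies piecewise-linear intensity windowing: clamp to `[low, high]`,
#' then rescale linearly to `[out_low, out_high]`. The grid frame is
#' unchanged.
#'
#' @param vol a [voxel_volume()] (or plain array/matrix)
#' @param w an [intensity_window()]
#' @return object of the same type with remapped intensities
#' @export
window_normalize <- function(vol, w) {
  if (!inherits(w, "intensity_window")) stop("w must be an intensity_window")
  f <- function(x) {
    t <- (pmin(pmax(x, w$low), w$high) - w$low) / (w$high - w$low)
    w$out_low + t * (w$out_high - w$out_low)
  }
  if (is_voxel_volume(vol)) {
    vol$data <- array(f(vol$data), dim(vol$data))
    vol
  } else {
    out <- f(vol)
    if (!is.null(dim(vol))) dim(out) <- dim(vol)
    out
  }
}

#' Median filter a volume
#'
#' Replaces each voxel by the median of its cubic `(2*radius+1)^3`
#' neighborhood; borders use nearest-value (replicate) padding. 2D inputs
#' (matrices) are treated as single-slice volumes.
#'
#' @param vol a [voxel_volume()], 3D array, or matrix
#' @param radius neighborhood radius in voxels (>= 1)
#' @return filtered object of the same type
#' @export
median_filter <- function(vol, radius = 1L) {
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L) stop("radius must be >= 1")
  apply3 <- function(a) {
    d <- dim(a)
    array(cpp_median_filter3(as.numeric(a), as.integer(d), radius), d)
  }
  if (is_voxel_volume(vol)) {
    vol$data <- apply3(vol$data)
    vol
  } else if (length(dim(vol)) == 3L) {
    apply3(vol)
  } else if (is.matrix(vol)) {
    a <- array(vol, c(dim(vol), 1L))
    matrix(apply3(a), nrow(vol), ncol(vol))
  } else stop("vol must be a voxel_volume, 3D array, or matrix")
}

#' Crop a region of interest
#'
#' Extracts the sub-volume `bounds` (inclusive 1-based index ranges per
#' axis), shifting the origin so retained voxels keep their world
#' coordinates.
#'
#' @param vol a [voxel_volume()]
#' @param bounds list of three length-2 integer vectors `c(from, to)`
#' @return cropped [voxel_volume()]
#' @export
crop_roi <- function(vol, bounds) {
  if (!is_voxel_volume(vol)) stop("vol must be a voxel_volume")
  if (!is.list(bounds) || length(bounds) != 3L)
    stop("bounds must be a list of 3 index ranges")
  d <- dim(vol$data)
  for (ax in 1:3) {
    b <- bounds[[ax]]
    if (length(b) != 2L || any(is.na(b)) || b[1] > b[2] ||
        b[1] < 1L || b[2] > d[ax])
      stop(sprintf("bounds out of range on axis %d", ax))
  }
  lo <- vapply(bounds, function(b) as.integer(b[1]), integer(1))
  hi <- vapply(bounds, function(b) as.integer(b[2]), integer(1))
  sub <- vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  voxel_volume(sub, vol$spacing, vol$origin + (lo - 1) * vol$spacing)
}

# --- simple raster format (MetaImage-style .mhd header + .raw payload) ------

#' Write a volume in MetaImage format
#'
#' Writes a `.mhd` text header plus a sidecar `.raw` little-endian payload
#' (element type MET_DOUBLE or MET_FLOAT).
#'
#' @param vol a [voxel_volume()]
#' @param path output path ending in `.mhd`
#' @param element "double" or "float"
#' @return `path`, invisibly
#' @export
write_volume <- function(vol, path, element = c("double", "float")) {
  if (!is_voxel_volume(vol)) stop("vol must be a voxel_volume")
  element <- match.arg(element)
  if (!grepl("\\.mhd$", path)) stop("path must end in .mhd")
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  d <- dim(vol$data)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.10g %.10g %.10g",
            vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    sprintf("Offset = %.10g %.10g %.10g",
            vol$origin[1], vol$origin[2], vol$origin[3]),
    sprintf("ElementType = %s",
            if (element == "double") "MET_DOUBLE" else "MET_FLOAT"),
    sprintf("ElementDataFile = %s", raw_name))
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  writeBin(as.numeric(vol$data), con,
           size = if (element == "double") 8L else 4L, endian = "little")
  invisible(path)
}

read_mhd_volume <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  get <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) return(default)
    vals[i]
  }
  d <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  sp <- as.numeric(strsplit(get("ElementSpacing", "1 1 1"), "\\s+")[[1]])
  org <- as.numeric(strsplit(get("Offset", "0 0 0"), "\\s+")[[1]])
  et <- get("ElementType", "MET_DOUBLE")
  sz <- switch(et, MET_DOUBLE = 8L, MET_FLOAT = 4L, MET_SHORT = 2L,
               MET_USHORT = 2L, MET_UCHAR = 1L,
               stop("unsupported ElementType: ", et))
  what <- if (et %in% c("MET_DOUBLE", "MET_FLOAT")) numeric() else integer()
  raw_file <- file.path(dirname(path), get("ElementDataFile"))
  if (!file.exists(raw_file)) stop("missing raw payload: ", raw_file)
  con <- file(raw_file, "rb")
  on.exit(close(con))
  n <- prod(d)
  v <- readBin(con, what, n = n, size = sz, endian = "little",
               signed = !(et %in% c("MET_USHORT", "MET_UCHAR")) || sz > 2)
  if (length(v) < n) stop("truncated raw payload in ", raw_file)
  voxel_volume(array(as.numeric(v), d), sp, org)
}

#' Load a volume from disk
#'
#' Reads either a MetaImage (`.mhd` + `.raw`) volume or a DICOM series
#' directory. For DICOM, slices are ordered by their position along the
#' slice normal and the inter-slice distance supplies the z spacing;
#' heterogeneous in-plane spacing across the series is a metadata error.
#'
#' @param path file (`.mhd`) or directory (DICOM series)
#' @param kind "auto", "mhd", or "dicom"
#' @return a [voxel_volume()]
#' @export
load_volume <- function(path, kind = c("auto", "mhd", "dicom")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (kind == "auto")
    kind <- if (dir.exists(path)) "dicom" else "mhd"
  if (kind == "mhd") read_mhd_volume(path) else read_dicom_series(path)
}
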