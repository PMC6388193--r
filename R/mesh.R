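# TriangleMesh container and STL I/O (binary default, ASCII accepted).

#' Construct a triangle mesh
#'
#' @param vertices numeric matrix (n x 3), coordinates in mm
#' @param faces integer matrix (m x 3), 1-based vertex indices
#' @param name optional label
#' @return an object of class `triangle_mesh`
#' @export
triangle_mesh <- function(vertices, faces, name = "") {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces, name = as.character(name)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh '%s': %d vertices, %d faces", x$name,
              nrow(x$vertices), nrow(x$faces)))
  if (nrow(x$faces) > 0) {
    cat(sprintf(", volume %.4g mm^3, %s", mesh_volume(x),
                if (is_watertight(x)) "watertight" else "open"))
  }
  cat("\n")
  invisible(x)
}

is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

#' Signed enclosed volume of a mesh (divergence theorem)
#'
#' Positive for watertight meshes with outward-oriented faces.
#'
#' @param mesh a [triangle_mesh()]
#' @return volume in mm^3
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  if (nrow(F) == 0) return(0)
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Total surface area of a mesh
#'
#' @param mesh a [triangle_mesh()]
#' @return area in mm^2
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  if (nrow(F) == 0) return(0)
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Watertightness predicate
#'
#' A mesh is watertight when every edge is shared by exactly two faces
#' with opposite traversal direction (closed, consistently oriented,
#' manifold surface).
#'
#' @param mesh a [triangle_mesh()]
#' @return logical
#' @export
is_watertight <- function(mesh) {
  F <- mesh$faces
  if (nrow(F) == 0) return(FALSE)
  he_from <- c(F[, 1], F[, 2], F[, 3])
  he_to   <- c(F[, 2], F[, 3], F[, 1])
  nv <- nrow(mesh$vertices)
  fwd <- (he_from - 1) * nv + he_to
  rev <- (he_to - 1) * nv + he_from
  if (anyDuplicated(fwd)) return(FALSE)          # non-manifold / repeated edge
  all(fwd %in% rev)                              # every half-edge has a twin
}

#' Clean a mesh
#'
#' Merges duplicate vertices (within `tol`), drops unused vertices and
#' degenerate (repeated-index or zero-area) faces. Pre-cleaning of Boolean
#' inputs uses this.
#'
#' @param mesh a [triangle_mesh()]
#' @param tol merge tolerance in mm
#' @return cleaned [triangle_mesh()]
#' @export
clean_mesh <- function(mesh, tol = 1e-9) {
  V <- mesh$vertices; F <- mesh$faces
  if (nrow(V) == 0) return(mesh)
  key <- paste(round(V[, 1] / tol), round(V[, 2] / tol), round(V[, 3] / tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])
  V2 <- V[first, , drop = FALSE]
  F2 <- matrix(remap[F], ncol = 3)
  ok <- F2[, 1] != F2[, 2] & F2[, 2] != F2[, 3] & F2[, 1] != F2[, 3]
  F2 <- F2[ok, , drop = FALSE]
  used <- sort(unique(as.vector(F2)))
  F3 <- matrix(match(F2, used), ncol = 3)
  triangle_mesh(V2[used, , drop = FALSE], F3, mesh$name)
}

#' Apply an affine map to mesh vertices
#'
#' @param mesh a [triangle_mesh()]
#' @param rotation 3x3 linear part
#' @param translation length-3 offset in mm
#' @param flip_faces reverse face winding (needed when det(rotation) < 0)
#' @return transformed [triangle_mesh()]
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                           flip_faces = det(rotation) < 0) {
  V <- mesh$vertices %*% t(rotation)
  V <- sweep(V, 2, translation, "+")
  F <- mesh$faces
  if (flip_faces) F <- F[, c(1, 3, 2), drop = FALSE]
  triangle_mesh(V, F, mesh$name)
}

# --- STL I/O ----------------------------------------------------------------

#' Read an STL mesh (binary or ASCII)
#'
#' Dialect is auto-detected. Duplicate vertices across facets are welded
#' exactly, so solids written by any STL producer come back as indexed
#' meshes.
#'
#' @param path STL file path
#' @return a [triangle_mesh()]
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  sz <- file.size(path)
  if (sz < 15) stop("malformed STL: file too short")
  head_raw <- readBin(path, "raw", n = min(sz, 512))
  starts_solid <- identical(rawToChar(head_raw[1:5]), "solid")
  is_binary <- !starts_solid
  if (starts_solid && sz >= 84) {
    # "solid" headers are legal in binary STL; trust the facet count
    n <- readBin(head_raw[81:84], "integer", size = 4, endian = "little")
    if (!is.na(n) && n >= 0 && 84 + 50 * n == sz) is_binary <- TRUE
  }
  if (is_binary) read_stl_binary(path) else read_stl_ascii(path)
}

read_stl_binary <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 80)
  n <- readBin(con, "integer", size = 4, endian = "little")
  if (is.na(n) || n < 0 || 84 + n * 50 > sz)
    stop("malformed STL: truncated binary file")
  tri <- matrix(0, n, 9)
  for (t in seq_len(n)) {
    rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    if (length(rec) < 12) stop("malformed STL: truncated facet record")
    tri[t, ] <- rec[4:12]
    readBin(con, "raw", n = 2)
  }
  stl_index(tri, name = sub("\\.stl$", "", basename(path), ignore.case = TRUE))
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex\\s", lines, value = TRUE)
  nfacet <- length(grep("^\\s*facet\\s", lines))
  if (length(vx) == 0 || length(vx) %% 3 != 0 || length(vx) != 3 * nfacet)
    stop("malformed STL: inconsistent ASCII facet structure")
  coords <- t(vapply(strsplit(trimws(vx), "\\s+"),
                     function(p) as.numeric(p[2:4]), numeric(3)))
  if (any(!is.finite(coords))) stop("malformed STL: non-numeric vertex")
  tri <- matrix(t(coords), ncol = 9, byrow = TRUE)
  stl_index(tri, name = sub("\\.stl$", "", basename(path), ignore.case = TRUE))
}

stl_index <- function(tri, name = "") {
  # tri: n x 9 (v1 v2 v3 flattened); weld exactly equal vertices
  pts <- matrix(as.vector(t(tri)), ncol = 3, byrow = TRUE)
  key <- paste(pts[, 1], pts[, 2], pts[, 3])
  first <- !duplicated(key)
  remap <- match(key, key[first])
  triangle_mesh(pts[first, , drop = FALSE],
                matrix(remap, ncol = 3, byrow = TRUE), name)
}

#' Write an STL mesh
#'
#' Binary STL by default (compact, the printer-facing dialect); ASCII on
#' request. Output is deterministic: identical meshes give byte-identical
#' files.
#'
#' @param mesh a [triangle_mesh()]
#' @param path output path
#' @param ascii write ASCII STL instead of binary
#' @return `path`, invisibly
#' @export
write_mesh <- function(mesh, path, ascii = FALSE) {
  if (!is_triangle_mesh(mesh)) stop("mesh must be a triangle_mesh")
  V <- mesh$vertices; F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  if (ascii) {
    fmt <- function(p) sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])
    out <- c(sprintf("solid %s", mesh$name))
    for (t in seq_len(nrow(F))) {
      out <- c(out,
               sprintf("  facet normal %s", fmt(nrm[t, ])),
               "    outer loop",
               sprintf("      vertex %s", fmt(V[F[t, 1], ])),
               sprintf("      vertex %s", fmt(V[F[t, 2], ])),
               sprintf("      vertex %s", fmt(V[F[t, 3], ])),
               "    endloop",
               "  endfacet")
    }
    out <- c(out, sprintf("endsolid %s", mesh$name))
    writeLines(out, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", substr(paste0("veneerfit ", mesh$name), 1, 80)))
    writeBin(hdr[1:80], con)
    writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
    for (t in seq_len(nrow(F))) {
      writeBin(as.numeric(c(nrm[t, ], V[F[t, 1], ], V[F[t, 2], ], V[F[t, 3], ])),
               con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

# --- grid <-> mesh bridges --------------------------------------------------

#' Voxelize a mesh on a volume frame
#'
#' Marks every voxel whose center lies inside the (watertight) mesh, by
#' parity counting of ray crossings.
#'
#' @param mesh a [triangle_mesh()]
#' @param frame a [voxel_volume()] supplying grid shape, spacing, origin
#' @return a [binary_mask()]
#' @export
voxelize_mesh <- function(mesh, frame) {
  d <- dim(frame$data)
  inside <- cpp_voxelize_mesh(mesh$vertices, mesh$faces - 1L,
                              frame$origin, frame$spacing, as.integer(d))
  binary_mask(array(inside, d), frame)
}

#' Extract the iso-surface of a scalar field
#'
#' Marching-tetrahedra triangulation of the level set, welded to a
#' watertight mesh when the level set is closed inside the grid.
#'
#' @param field 3D numeric array
#' @param spacing,origin grid frame (mm)
#' @param iso iso-level
#' @param inside_below if TRUE the enclosed region is `field < iso`
#'   (implicit-function convention), else `field > iso` (indicator
#'   convention)
#' @param name mesh label
#' @return a [triangle_mesh()]
#' @export
mesh_from_field <- function(field, spacing, origin, iso = 0,
                            inside_below = TRUE, name = "") {
  d <- dim(field)
  res <- cpp_marching_tetra(as.numeric(field), as.integer(d),
                            as.numeric(origin), as.numeric(spacing),
                            iso, inside_below)
  # weld vertices that coincide where the field hits the iso-level exactly
  # on a grid node (several cut edges then emit the same point)
  clean_mesh(triangle_mesh(res$vertices, res$faces, name),
             tol = 1e-7 * min(spacing))
}
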