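# Minimal DICOM series reader: explicit-VR little-endian, single-frame
# grayscale slices. Covers the subset clinical CBCT exports use; anything
# else is rejected with a metadata error rather than guessed at.

dicom_read_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  u16 <- function(at) readBin(raw[at:(at + 1L)], "integer", size = 2,
                              endian = "little", signed = FALSE)
  u32 <- function(at) readBin(raw[at:(at + 3L)], "integer", size = 4,
                              endian = "little")
  tags <- list()
  n <- length(raw)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("implicit-VR or corrupt element in ", path)
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); hdr <- 12L
    } else {
      len <- u16(pos + 6L); hdr <- 8L
    }
    if (len < 0L || pos + hdr + len - 1L > n)
      stop("truncated DICOM element in ", path)
    key <- sprintf("%04x,%04x", group, elem)
    body <- if (len > 0L) raw[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    tags[[key]] <- list(vr = vr, bytes = body)
    pos <- pos + hdr + len
  }
  tags
}

dicom_str <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  trimws(rawToChar(t$bytes))
}

dicom_ds <- function(tags, key) {
  s <- dicom_str(tags, key)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dicom_us <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  readBin(t$bytes, "integer", size = 2, endian = "little", signed = FALSE)
}

read_dicom_series <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory: ", dir)
  slices <- lapply(files, dicom_read_file)

  rows <- unique(vapply(slices, function(t) dicom_us(t, "0028,0010"), 0L))
  cols <- unique(vapply(slices, function(t) dicom_us(t, "0028,0011"), 0L))
  if (length(rows) != 1L || length(cols) != 1L)
    stop("metadata error: heterogeneous slice dimensions")

  ps <- lapply(slices, function(t) dicom_ds(t, "0028,0030"))
  if (any(vapply(ps, is.null, TRUE)))
    stop("metadata error: missing PixelSpacing")
  ps_mat <- do.call(rbind, ps)
  if (nrow(unique(round(ps_mat, 9))) != 1L)
    stop("metadata error: heterogeneous PixelSpacing across series")
  pixel_spacing <- ps[[1]]  # (row spacing, column spacing)

  ipp <- lapply(slices, function(t) dicom_ds(t, "0020,0032"))
  zpos <- if (!any(vapply(ipp, is.null, TRUE))) {
    vapply(ipp, `[`, 0.0, 3)
  } else {
    sl <- vapply(slices, function(t) {
      v <- dicom_ds(t, "0020,1041")
      if (is.null(v)) NA_real_ else v[1]
    }, 0.0)
    if (any(is.na(sl))) stop("metadata error: no slice position information")
    sl
  }
  ord <- order(zpos)
  slices <- slices[ord]
  zpos <- zpos[ord]

  nz <- length(slices)
  if (nz >= 2L) {
    dz <- diff(zpos)
    if (max(dz) - min(dz) > 1e-6 * max(abs(dz)) + 1e-9)
      stop("metadata error: non-uniform slice interval")
    z_spacing <- dz[1]
  } else {
    st <- dicom_ds(slices[[1]], "0018,0050")
    if (is.null(st)) stop("metadata error: single slice without SliceThickness")
    z_spacing <- st[1]
  }

  bits <- dicom_us(slices[[1]], "0028,0100")
  if (is.null(bits)) bits <- 16L
  signed_rep <- identical(dicom_us(slices[[1]], "0028,0103"), 1L)

  arr <- array(0.0, c(cols, rows, nz))
  for (k in seq_len(nz)) {
    px <- slices[[k]][["7fe0,0010"]]
    if (is.null(px)) stop("metadata error: missing PixelData")
    v <- readBin(px$bytes, "integer", n = rows * cols,
                 size = bits / 8L, endian = "little",
                 signed = if (bits <= 8L) FALSE else signed_rep)
    # DICOM stores row-major (column index fastest); x = column, y = row
    arr[, , k] <- matrix(as.numeric(v), nrow = cols, ncol = rows)
  }
  origin3 <- if (!any(vapply(ipp, is.null, TRUE))) ipp[[ord[1]]] else c(0, 0, zpos[1])
  voxel_volume(arr,
               spacing = c(pixel_spacing[2], pixel_spacing[1], z_spacing),
               origin = origin3)
}
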