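# Minimal DICOM support: an explicit-VR little-endian reader for
# single-series slice directories, and a matching secondary-capture writer
# used to exchange synthetic volumes. Only the geometry and pixel tags the
# package needs are interpreted; everything else is skipped by length.

dcm_uid_root <- "1.2.826.0.1.3680043.10.9431"

dcm_pad <- function(raw, pad = as.raw(0L)) {
  if (length(raw) %% 2L == 1L) c(raw, pad) else raw
}

dcm_element <- function(group, element, vr, value) {
  head <- writeBin(as.integer(c(group, element)), raw(), size = 2,
                   endian = "little")
  body <- switch(vr,
    UI = dcm_pad(charToRaw(value)),
    CS = , DS = , IS = dcm_pad(charToRaw(value), as.raw(0x20)),
    US = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    UL = writeBin(as.integer(value), raw(), size = 4, endian = "little"),
    OW = value,
    stop("unsupported VR ", vr))
  if (vr %in% c("OB", "OW")) {
    len <- writeBin(length(body), raw(), size = 4, endian = "little")
    c(head, charToRaw(vr), as.raw(c(0, 0)), len, body)
  } else {
    len <- writeBin(as.integer(length(body)), raw(), size = 2, endian = "little")
    c(head, charToRaw(vr), len, body)
  }
}

dcm_ds <- function(x) paste(formatC(x, format = "fg", digits = 10), collapse = "\\")

#' Write a volume as a synthetic DICOM series
#'
#' Writes one explicit-VR little-endian secondary-capture file per sagittal
#' slice (slices along the first grid axis). Intended for interchange and
#' for exercising the DICOM reading path with synthetic data; intensities
#' must be non-negative integers below 2^16 (the mask / two-level phantom
#' images qualify).
#'
#' @param grid a [voxel_grid()] with integer-valued intensities.
#' @param dir output directory (created if needed).
#' @param series_uid DICOM series instance UID (a fixed synthetic default).
#' @return `dir`, invisibly.
#' @export
write_dicom_series <- function(grid, dir,
                               series_uid = paste0(dcm_uid_root, ".1.1")) {
  stopifnot(inherits(grid, "voxel_grid"))
  vals <- grid$values
  if (max(abs(vals - round(vals))) > 1e-6 || min(vals) < 0 || max(vals) > 65535)
    stop("DICOM writer requires integer intensities in [0, 65535]")
  vals <- round(vals)
  dims <- dim(vals)
  s <- grid$spacing
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_len(dims[1])) {
    slice <- vals[i, , ]                       # ny x nz
    pix <- writeBin(as.integer(as.vector(slice)), raw(), size = 2,
                    endian = "little")
    ipp <- c(grid$origin[1] + (i - 0.5) * s[1],
             grid$origin[2] + 0.5 * s[2],
             grid$origin[3] + 0.5 * s[3])
    sop_uid <- paste0(series_uid, ".", i)
    meta <- c(
      dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
    meta <- c(dcm_element(0x0002, 0x0000, "UL", length(meta)), meta)
    body <- c(
      dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.7"),
      dcm_element(0x0008, 0x0018, "UI", sop_uid),
      dcm_element(0x0008, 0x0060, "CS", "MR"),
      dcm_element(0x0018, 0x0050, "DS", dcm_ds(s[1])),
      dcm_element(0x0018, 0x0088, "DS", dcm_ds(s[1])),
      dcm_element(0x0020, 0x000E, "UI", series_uid),
      dcm_element(0x0020, 0x0013, "IS", as.character(i)),
      dcm_element(0x0020, 0x0032, "DS", dcm_ds(ipp)),
      dcm_element(0x0020, 0x0037, "DS", dcm_ds(c(0, 1, 0, 0, 0, 1))),
      dcm_element(0x0028, 0x0002, "US", 1L),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", dims[3]),   # Rows (axis 3)
      dcm_element(0x0028, 0x0011, "US", dims[2]),   # Columns (axis 2)
      dcm_element(0x0028, 0x0030, "DS", dcm_ds(c(s[3], s[2]))),
      dcm_element(0x0028, 0x0100, "US", 16L),
      dcm_element(0x0028, 0x0101, "US", 16L),
      dcm_element(0x0028, 0x0102, "US", 15L),
      dcm_element(0x0028, 0x0103, "US", 0L),
      dcm_element(0x7FE0, 0x0010, "OW", pix))
    con <- file(file.path(dir, sprintf("slice_%04d.dcm", i)), "wb")
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(c(meta, body), con)
    close(con)
  }
  invisible(dir)
}

dcm_parse_file <- function(path) {
  raw <- readBin(path, raw(), n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop(path, " is not a DICOM file (missing DICM marker)")
  pos <- 133L
  u16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  u32 <- function(at) u16(at) + 65536 * u16(at + 2L)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  out <- list()
  while (pos + 7L <= length(raw)) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L)
      data_at <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      data_at <- pos + 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements not supported")
    key <- sprintf("%04X,%04X", group, element)
    val_raw <- if (len > 0) raw[data_at:(data_at + len - 1L)] else raw(0)
    if (key %in% c("0002,0010", "0008,0018", "0020,000E", "0020,0032",
                   "0018,0050", "0018,0088", "0028,0030")) {
      while (length(val_raw) && val_raw[length(val_raw)] %in% as.raw(c(0L, 32L)))
        val_raw <- val_raw[-length(val_raw)]
      out[[key]] <- rawToChar(val_raw)
    } else if (key %in% c("0028,0010", "0028,0011")) {
      out[[key]] <- as.integer(val_raw[1]) + 256L * as.integer(val_raw[2])
    } else if (key == "7FE0,0010") {
      out[[key]] <- val_raw
    }
    pos <- data_at + len
  }
  out
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no files in DICOM directory ", dir)
  slices <- lapply(files, dcm_parse_file)
  ts <- unique(vapply(slices, function(s) s[["0002,0010"]] %||% "", ""))
  if (!all(ts == "1.2.840.10008.1.2.1"))
    stop("only explicit-VR little-endian DICOM is supported")
  series <- unique(vapply(slices, function(s) s[["0020,000E"]] %||% "", ""))
  if (length(series) != 1)
    stop("directory contains ", length(series), " DICOM series; expected one")
  ipp <- t(vapply(slices, function(s) {
    v <- s[["0020,0032"]]
    if (is.null(v)) stop("DICOM slice missing ImagePositionPatient")
    as.numeric(strsplit(v, "\\\\")[[1]])
  }, numeric(3)))
  ord <- order(ipp[, 1])
  slices <- slices[ord]
  ipp <- ipp[ord, , drop = FALSE]
  rows <- unique(vapply(slices, `[[`, 1L, "0028,0010"))
  cols <- unique(vapply(slices, `[[`, 1L, "0028,0011"))
  if (length(rows) != 1 || length(cols) != 1)
    stop("inconsistent slice dimensions in series")
  ps <- slices[[1]][["0028,0030"]]
  if (is.null(ps)) stop("DICOM series missing PixelSpacing")
  ps <- as.numeric(strsplit(ps, "\\\\")[[1]])   # row spacing \ col spacing
  nslice <- length(slices)
  step <- if (nslice > 1) {
    d <- diff(ipp[, 1])
    if (max(d) - min(d) > 1e-4) stop("non-uniform slice positions in series")
    mean(d)
  } else {
    st <- slices[[1]][["0018,0088"]] %||% slices[[1]][["0018,0050"]]
    if (is.null(st)) stop("single-slice series missing slice spacing")
    as.numeric(st)
  }
  vals <- array(0, dim = c(nslice, cols, rows))
  for (i in seq_len(nslice)) {
    pr <- slices[[i]][["7FE0,0010"]]
    if (is.null(pr)) stop("DICOM slice missing PixelData")
    v <- readBin(pr, integer(), n = rows * cols, size = 2, signed = FALSE,
                 endian = "little")
    vals[i, , ] <- v
  }
  spacing <- c(step, ps[2], ps[1])
  origin <- c(ipp[1, 1] - 0.5 * spacing[1],
              ipp[1, 2] - 0.5 * spacing[2],
              ipp[1, 3] - 0.5 * spacing[3])
  if (max(spacing) - min(spacing) > 1e-6 * max(spacing))
    message("note: anisotropic voxel spacing (",
            paste(signif(spacing, 4), collapse = " x "), " mm)")
  voxel_grid(vals, spacing, origin)
}
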