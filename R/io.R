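#' Read a volumetric image
#'
#' Accepts a NIfTI-1 file (`.nii` / `.nii.gz`) or a directory containing a
#' single DICOM series (one file per slice). DICOM slices are sorted by
#' their position along the slice axis and must share one series UID;
#' missing spacing information is an error. Anisotropic spacing is allowed
#' and reported with a notice.
#'
#' The grid origin is mapped so that voxel `(i, j, k)` keeps its centre at
#' `origin + (i + 0.5) * spacing` (see [voxel_grid()]).
#'
#' @param path file or directory path.
#' @return A [voxel_grid()].
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 3L) stop("expected a 3D volume")
  vals <- array(as.vector(vals), dim = dim(vals))  # drop header attributes
  spacing <- as.numeric(RNifti::pixdim(img))[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume is missing voxel spacing")
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (!inherits(xf, "try-error")) abs(xf[1:3, 4]) - 0.5 * spacing
            else c(0, 0, 0)
  if (max(spacing) - min(spacing) > 1e-6 * max(spacing))
    message("note: anisotropic voxel spacing (",
            paste(signif(spacing, 4), collapse = " x "), " mm)")
  voxel_grid(vals, spacing, origin)
}

#' Write a volume or mask as NIfTI-1
#'
#' Masks are stored as uint8, intensity images as 32-bit float (or the
#' given datatype). The affine is diagonal with the grid spacing, offset so
#' the voxel-centre convention round-trips through [read_volume()].
#'
#' @param grid a [voxel_grid()] or [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI datatype override (default: `"uint8"` for masks,
#'   `"float"` otherwise).
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path, datatype = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  is_mask <- inherits(grid, "binary_mask")
  vals <- grid$values
  if (is_mask) storage.mode(vals) <- "integer"
  if (is.null(datatype)) datatype <- if (is_mask) "uint8" else "float"
  affine <- diag(4)
  diag(affine)[1:3] <- grid$spacing
  affine[1:3, 4] <- grid$origin + 0.5 * grid$spacing
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read / write manual trace polygons
#'
#' The trace interchange format is a small JSON document:
#' \preformatted{{"patient": "P01", "rater": 1, "side": "left",
#'  "slices": [{"index": 12, "polygons": [[[x, y], ...], ...]}, ...]}}
#' Slice indices are 0-based along the first (sagittal) grid axis; polygon
#' vertices are mm coordinates in the slice plane (axes 2 and 3 of the
#' volume). Polygons are closed implicitly (a repeated final vertex is
#' dropped) and need at least 3 vertices.
#'
#' @param path JSON file path.
#' @return `read_traces`: an object of class `trace_set` (a list with
#'   `patient`, `rater`, `side`, `slices`).
#' @export
read_traces <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  validate_traces(x)
}

#' @rdname read_traces
#' @param traces a `trace_set` (or compatible list).
#' @export
write_traces <- function(traces, path) {
  traces <- validate_traces(traces)
  out <- unclass(traces)
  out$slices <- lapply(out$slices, function(sl) {
    sl$polygons <- lapply(sl$polygons, function(pg)
      lapply(seq_len(nrow(pg)), function(i) pg[i, ]))
    sl
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

validate_traces <- function(x) {
  stopifnot(is.list(x), !is.null(x$slices))
  x$rater <- as.integer(x$rater %||% NA_integer_)
  x$side <- as.character(x$side %||% NA_character_)
  x$slices <- lapply(x$slices, function(sl) {
    sl$index <- as.integer(sl$index)
    sl$polygons <- lapply(sl$polygons, function(pg) {
      pg <- do.call(rbind, lapply(pg, as.numeric))
      if (nrow(pg) > 3 && all(pg[1, ] == pg[nrow(pg), ]))
        pg <- pg[-nrow(pg), , drop = FALSE]
      if (nrow(pg) < 3) stop("polygon needs >= 3 vertices")
      pg
    })
    sl
  })
  class(x) <- "trace_set"
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# even-odd (crossing number) point-in-polygon, vectorized over points
points_in_polygon <- function(px, py, poly) {
  inside <- rep(FALSE, length(px))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

segments_intersect <- function(poly) {
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1), , drop = FALSE])
  ccw <- function(a, b, c)
    (c[2] - a[2]) * (b[1] - a[1]) > (b[2] - a[2]) * (c[1] - a[1])
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next
      a <- seg[i, 1:2]; b <- seg[i, 3:4]; c <- seg[j, 1:2]; d <- seg[j, 3:4]
      if (ccw(a, c, d) != ccw(b, c, d) && ccw(a, b, c) != ccw(a, b, d))
        return(TRUE)
    }
  }
  FALSE
}

#' Rasterize per-slice trace polygons into a binary mask
#'
#' For every traced slice, voxel centres inside a polygon (even-odd rule)
#' are set `TRUE`; multiple polygons on one slice are OR-combined. The fill
#' is invariant to vertex ordering. Polygons reaching outside the slice are
#' clipped with a warning; self-intersecting polygons are filled by the
#' even-odd rule with a warning.
#'
#' @param traces a `trace_set` (see [read_traces()]).
#' @param grid the [voxel_grid()] supplying the mask geometry.
#' @return A [binary_mask()] aligned with `grid`, carrying the trace's
#'   `side` and `rater` labels.
#' @export
traces_to_mask <- function(traces, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  traces <- validate_traces(unclass(traces))
  dims <- dim(grid$values)
  mask <- array(FALSE, dim = dims)
  cy <- voxel_centers(grid, 2)
  cz <- voxel_centers(grid, 3)
  ylim <- grid$origin[2] + c(0, dims[2] * grid$spacing[2])
  zlim <- grid$origin[3] + c(0, dims[3] * grid$spacing[3])
  py <- rep(cy, times = dims[3])
  pz <- rep(cz, each = dims[2])
  for (sl in traces$slices) {
    if (sl$index < 0 || sl$index >= dims[1])
      stop(sprintf("slice index %d outside volume (0..%d)", sl$index, dims[1] - 1))
    plane <- rep(FALSE, dims[2] * dims[3])
    for (pg in sl$polygons) {
      if (min(pg[, 1]) < ylim[1] || max(pg[, 1]) > ylim[2] ||
          min(pg[, 2]) < zlim[1] || max(pg[, 2]) > zlim[2])
        warning(sprintf("polygon on slice %d extends outside the grid; clipped",
                        sl$index))
      if (nrow(pg) > 3 && segments_intersect(pg))
        warning(sprintf("self-intersecting polygon on slice %d; even-odd fill",
                        sl$index))
      plane <- plane | points_in_polygon(py, pz, pg)
    }
    mask[sl$index + 1L, , ] <- mask[sl$index + 1L, , ] |
      array(plane, dim = dims[2:3])
  }
  binary_mask(mask, grid$spacing, grid$origin,
              side = traces$side %||% NA_character_,
              rater = traces$rater %||% NA_integer_)
}
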