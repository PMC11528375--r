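#' Volumetric image container
#'
#' A `voxel_grid` holds a 3D scalar image together with its physical
#' geometry: the voxel spacing in mm along each axis and the mm offset of
#' the grid origin. Voxel `(i, j, k)` (0-based) covers the half-open cube
#' `[i*s, (i+1)*s)` so its centre sits at `origin + (i + 0.5) * spacing`.
#' Slices along the first array axis are sagittal by convention.
#'
#' @param values 3D numeric array of intensities.
#' @param spacing numeric length-3, mm per voxel along each axis (all > 0).
#' @param origin numeric length-3, mm offset of the grid (default 0).
#' @return An object of class `voxel_grid` with elements `values`,
#'   `spacing` and `origin`.
#' @export
voxel_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (any(dim(values) < 2L))
    stop("grid must have at least 2 voxels per axis")
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be positive and finite on all axes")
  if (any(!is.finite(values)))
    stop("grid intensities must be finite")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' Binary segmentation mask
#'
#' A logical grid sharing `voxel_grid` geometry, optionally labelled with
#' the hemisphere (`"left"`/`"right"`) and the rater (1 or 2) that produced
#' the trace.
#'
#' @param values 3D logical array.
#' @param spacing,origin grid geometry as in [voxel_grid()].
#' @param side optional hemisphere label, `"left"` or `"right"`.
#' @param rater optional rater label, 1 or 2.
#' @return An object of class `binary_mask` (inherits `voxel_grid`).
#' @export
binary_mask <- function(values, spacing, origin = c(0, 0, 0),
                        side = NA_character_, rater = NA_integer_) {
  if (!is.logical(values)) {
    storage.mode(values) <- "logical"
  }
  if (!is.na(side) && !side %in% c("left", "right"))
    stop("`side` must be \"left\" or \"right\"")
  g <- voxel_grid(array(TRUE, dim = dim(values)), spacing, origin)
  g$values <- values
  g$side <- as.character(side)
  g$rater <- as.integer(rater)
  class(g) <- c("binary_mask", "voxel_grid")
  g
}

#' Signed distance field ("digital twin")
#'
#' The implicit representation of one hippocampus: a scalar field `phi`
#' on a voxel grid, in mm, negative inside the structure and zero on its
#' boundary. Fields are tagged with their provenance: initialised straight
#' from a mask (`"init-from-mask"`) or produced by level-set evolution
#' (`"evolved"`).
#'
#' @param phi 3D numeric array, mm units, negative inside.
#' @param spacing,origin grid geometry as in [voxel_grid()].
#' @param provenance `"init-from-mask"` or `"evolved"`.
#' @return An object of class `level_set_field` (inherits `voxel_grid`).
#' @export
level_set_field <- function(phi, spacing, origin = c(0, 0, 0),
                            provenance = c("init-from-mask", "evolved")) {
  provenance <- match.arg(provenance)
  g <- voxel_grid(phi, spacing, origin)
  if (!any(g$values < 0) || !any(g$values > 0))
    stop("a level-set field must have both interior (phi < 0) and exterior (phi > 0) voxels")
  g$provenance <- provenance
  class(g) <- c("level_set_field", "voxel_grid")
  g
}

#' Closed triangulated surface
#'
#' @param vertices n x 3 numeric matrix of vertex positions in mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices, oriented
#'   counter-clockwise seen from outside (signed volume > 0).
#' @param normals optional n x 3 matrix of per-vertex unit normals;
#'   computed (area-weighted) when missing.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("`vertices` and `faces` must have 3 columns")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "surface_mesh")
  m$normals <- if (is.null(normals)) vertex_normals(m) else as.matrix(normals)
  m
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm\n",
              class(x)[1], paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

#' Physical coordinates of voxel centres along one axis
#'
#' @param grid a `voxel_grid`.
#' @param axis axis index (1-3).
#' @return numeric vector of centre positions in mm.
#' @export
voxel_centers <- function(grid, axis) {
  n <- dim(grid$values)[axis]
  grid$origin[axis] + (seq_len(n) - 0.5) * grid$spacing[axis]
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-9))
}

#' Euclidean distance transform of a mask
#'
#' Exact distance (mm) from every voxel centre to the nearest `TRUE` voxel
#' centre, honouring anisotropic spacing.
#'
#' @param mask a `binary_mask` (or logical array with `spacing` given).
#' @param spacing spacing override when `mask` is a bare array.
#' @return numeric array of distances in mm (`Inf` where the mask is empty).
#' @export
distance_transform <- function(mask, spacing = NULL) {
  if (inherits(mask, "voxel_grid")) {
    spacing <- mask$spacing
    mask <- mask$values
  }
  d2 <- .edt_sq_cpp(as.logical(mask), dim(mask), as.numeric(spacing))
  array(sqrt(d2), dim = dim(mask))
}

#' Dice overlap of two voxel sets
#'
#' @param a,b logical arrays or `binary_mask`es of identical shape.
#' @return Dice coefficient in [0, 1] (1 when both are empty).
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "voxel_grid")) a <- a$values
  if (inherits(b, "voxel_grid")) b <- b$values
  stopifnot(identical(dim(a), dim(b)))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Erode a mask by a physical distance
#'
#' Keeps voxels whose centre lies deeper than `depth_mm` inside the mask
#' (measured by the exact distance transform of the background).
#'
#' @param mask a `binary_mask`.
#' @param depth_mm erosion depth in mm.
#' @return eroded `binary_mask`.
#' @export
erode_mask <- function(mask, depth_mm) {
  d_out <- distance_transform(binary_mask(!mask$values, mask$spacing, mask$origin))
  out <- mask
  out$values <- mask$values & (d_out > depth_mm)
  out
}
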