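# Shared phantom fixtures, built once per test run. All geometry is
# generated in code; nothing is read from disk.

..fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(..fx[[name]])) ..fx[[name]] <- builder()
  ..fx[[name]]
}

sphere_fixture <- function() fx("sphere", function() {
  ph <- make_phantom(phantom_spec("sphere", r = 9.2, spacing = 0.5),
                     noise_sd = 0)
  ph$field <- reinitialize_sdf(ph$mask)
  ph$mesh <- extract_mesh(ph$field)
  ph
})

ellipsoid_fixture <- function() fx("ellipsoid", function() {
  ph <- make_phantom(phantom_spec("ellipsoid", a = 20, b = 15, c = 10,
                                  spacing = 0.5,
                                  rotation = rotation_xyz(c(0.5, -0.3, 0.7))),
                     noise_sd = 0)
  ph$field <- reinitialize_sdf(ph$mask)
  ph$mesh <- extract_mesh(ph$field)
  ph
})

capsule_fixture <- function() fx("capsule", function() {
  ph <- make_phantom(phantom_spec("capsule", r = 5, L = 20, spacing = 0.5,
                                  rotation = rotation_xyz(c(0.3, 0.5, 0.2))),
                     noise_sd = 0)
  ph$field <- reinitialize_sdf(ph$mask)
  ph$mesh <- extract_mesh(ph$field)
  ph
})

# closed axis-aligned box mesh (12 triangles, outward orientation)
box_mesh <- function(side = c(20, 20, 20), origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(x = c(0, side[1]), y = c(0, side[2]),
                             z = c(0, side[3])))
  v <- sweep(v, 2, origin, `+`)
  # vertex order from expand.grid: index = 1 + x + 2y + 4z (x fastest)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0 face (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = 1 face (+z)
    c(1, 2, 5), c(2, 6, 5),   # y = 0 (-y)
    c(3, 7, 4), c(4, 7, 8),   # y = 1 (+y)
    c(1, 5, 3), c(3, 5, 7),   # x = 0 (-x)
    c(2, 4, 6), c(4, 8, 6))   # x = 1 (+x)
  surface_mesh(v, f)
}

# direct voxelization of an axis-aligned solid box into a mask
box_mask <- function(lengths, spacing = 0.5, margin = 4) {
  dims <- ceiling(lengths / spacing) + 2 * margin
  arr <- array(FALSE, dims)
  idx <- lapply(1:3, function(a) {
    ctr <- (seq_len(dims[a]) - 0.5) * spacing
    which(ctr > margin * spacing & ctr < margin * spacing + lengths[a])
  })
  arr[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  binary_mask(arr, rep(spacing, 3))
}

euler_characteristic <- function(mesh) {
  e <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  ne <- nrow(unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))))
  nrow(mesh$vertices) - ne + nrow(mesh$faces)
}
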