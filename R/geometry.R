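# Core geometric containers: scalar image volumes with voxel-to-world
# affines (RAS+ world, mm) and rigid/affine world-to-world transforms.
# The anterior-posterior (AP) anatomical axis is world +y throughout;
# voxel indices are 0-based internally.

MODALITIES <- c("T1", "PD", "T2echo", "qT2", "distance", "mask")

#' Construct an image volume
#'
#' An `image_volume` is a 3-D scalar grid together with a 4x4 voxel-to-world
#' affine (RAS+ convention, millimetres, 0-based voxel indices) and a
#' modality tag. It is the common carrier for T1-weighted images, dual-echo
#' signals, qT2 maps, AP distance maps and masks.
#'
#' @param data 3-D numeric array of voxel values.
#' @param affine 4x4 voxel-to-world matrix; last row must be `(0,0,0,1)` and
#'   the 3x3 block must have strictly positive column norms (voxel spacings).
#' @param modality one of `"T1"`, `"PD"`, `"T2echo"`, `"qT2"`, `"distance"`,
#'   `"mask"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, affine = diag(4), modality = "T1") {
  if (length(dim(data)) == 4L && dim(data)[4] == 1L) {
    data <- array(data, dim(data)[1:3])
  }
  if (length(dim(data)) != 3L) {
    stop("unsupported-input: image data must be a 3-D array", call. = FALSE)
  }
  affine <- check_affine(affine)
  modality <- match.arg(modality, MODALITIES)
  structure(list(data = data, affine = affine, modality = modality),
            class = "image_volume")
}

check_affine <- function(affine) {
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L)) ||
      max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-8) {
    stop("geometry error: affine must be 4x4 with last row (0,0,0,1)",
         call. = FALSE)
  }
  d <- abs(det(affine[1:3, 1:3]))
  if (!is.finite(d) || d < 1e-12) {
    stop("geometry error: affine is not invertible", call. = FALSE)
  }
  if (any(voxel_spacing_affine(affine) <= 0)) {
    stop("geometry error: voxel spacings must be strictly positive",
         call. = FALSE)
  }
  affine
}

voxel_spacing_affine <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s> %s voxels, spacing %s mm\n", x$modality,
              paste(dim(x$data), collapse = "x"),
              paste(sprintf("%.2f", voxel_spacing(x)), collapse = "x")))
  invisible(x)
}

#' Voxel spacings of a volume
#'
#' Column norms of the 3x3 block of the affine, in mm.
#' @param volume an `image_volume`.
#' @return Numeric length-3 vector of spacings (mm).
#' @export
voxel_spacing <- function(volume) voxel_spacing_affine(volume$affine)

#' Volume of one voxel in cubic millimetres
#'
#' The product of the three voxel spacings, e.g. 1.00 mm^3 for a 1-mm
#' isotropic T1 grid and 0.74 mm^3 for a 0.43 x 0.43 x 4.00 mm coronal
#' dual-echo grid. Invariant under rigid transforms of the affine.
#'
#' @param volume an `image_volume`.
#' @return Scalar voxel volume (mm^3).
#' @export
voxel_volume <- function(volume) prod(voxel_spacing(volume))

#' Construct an axis-aligned grid geometry
#'
#' Convenience constructor for a world-centred axis-aligned grid: the affine
#' is `diag(spacing)` with the origin placed so the grid centre is at
#' `centre` (world mm).
#'
#' @param dims integer length-3 voxel counts.
#' @param spacing numeric length-3 voxel spacings (mm).
#' @param centre world coordinates of the grid centre (mm).
#' @param modality modality tag for the (zero-filled) volume.
#' @return An `image_volume` of zeros with the requested geometry.
#' @export
make_grid <- function(dims, spacing = c(1, 1, 1), centre = c(0, 0, 0),
                      modality = "mask") {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L), all(spacing > 0))
  affine <- diag(c(spacing, 1))
  affine[1:3, 4] <- centre - spacing * (dims - 1) / 2
  image_volume(array(0, dims), affine, modality)
}

# world coordinates (n x 3) of 0-based voxel indices (n x 3)
voxel_to_world <- function(affine, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  sweep(ijk %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], "+")
}

# n x 3 matrix of world coordinates for every voxel of a grid (column-major)
grid_world_coords <- function(volume) {
  d <- dim(volume$data)
  ijk <- cbind(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  )
  voxel_to_world(volume$affine, ijk)
}

# world y coordinate (AP, mm) of coronal slice j (1-based index)
slice_ap_position <- function(volume, j) {
  voxel_to_world(volume$affine, cbind(0, j - 1, 0))[, 2]
}

## ---- transforms -----------------------------------------------------------

#' Construct a world-to-world transform
#'
#' @param matrix 4x4 homogeneous matrix mapping world (mm, RAS+) to world.
#' @param kind `"rigid"`, `"affine"` or `"composite"`. Rigid transforms must
#'   have an orthonormal 3x3 block with determinant +1.
#' @return An object of class `world_transform`.
#' @export
world_transform <- function(matrix = diag(4), kind = "affine") {
  matrix <- check_affine(matrix)
  kind <- match.arg(kind, c("rigid", "affine", "composite"))
  if (kind == "rigid") {
    R <- matrix[1:3, 1:3]
    if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6) {
      stop("geometry error: rigid transform block must be a proper rotation",
           call. = FALSE)
    }
  }
  structure(list(matrix = matrix, kind = kind), class = "world_transform")
}

#' @export
print.world_transform <- function(x, ...) {
  cat(sprintf("<world_transform %s>\n", x$kind))
  print(round(x$matrix, 4))
  invisible(x)
}

#' Identity transform
#' @return A rigid `world_transform` equal to the identity.
#' @export
identity_transform <- function() world_transform(diag(4), "rigid")

#' Compose transforms (right-to-left application)
#'
#' `compose_transforms(a, b)` applies `b` first, then `a`; composition is
#' associative.
#' @param ... `world_transform` objects, outermost first.
#' @return A `world_transform` (kind `"rigid"` if all inputs are rigid,
#'   otherwise `"composite"`).
#' @export
compose_transforms <- function(...) {
  ts <- list(...)
  m <- Reduce(`%*%`, lapply(ts, function(t) t$matrix))
  kind <- if (all(vapply(ts, function(t) t$kind == "rigid", logical(1))))
    "rigid" else "composite"
  world_transform(m, kind)
}

#' Invert a transform
#' @param transform a `world_transform`.
#' @return The inverse `world_transform`.
#' @export
invert_transform <- function(transform) {
  world_transform(solve(transform$matrix), transform$kind)
}

# rotation matrices about world axes; angles in degrees
rot3 <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Build a rigid transform from Euler angles and a translation
#'
#' Rotation (Rz Ry Rx order, degrees) about `centre`, followed by
#' `translation` (mm).
#'
#' @param angles_deg rotations about the world x, y, z axes (degrees).
#' @param translation world translation (mm).
#' @param centre rotation centre (world mm).
#' @return A rigid `world_transform`.
#' @export
rigid_transform <- function(angles_deg = c(0, 0, 0),
                            translation = c(0, 0, 0),
                            centre = c(0, 0, 0)) {
  R <- rot3(angles_deg)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- centre - R %*% centre + translation
  world_transform(m, "rigid")
}

# affine parameterization used by the registration optimizer:
# p = (rx, ry, rz [deg], tx, ty, tz [mm], log-scales sx sy sz, shears xy xz yz)
params_to_affine <- function(p, centre = c(0, 0, 0)) {
  p <- c(p, rep(0, 12 - length(p)))
  R <- rot3(p[1:3])
  S <- diag(exp(p[7:9]))
  H <- diag(3)
  H[1, 2] <- p[10]; H[1, 3] <- p[11]; H[2, 3] <- p[12]
  A <- R %*% S %*% H
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4] <- centre - A %*% centre + p[4:6]
  m
}

#' Construct a segmentation
#'
#' A grid-aligned hippocampal mask with values in `[0, 1]` (fractional after
#' resampling; the binarized view is `values >= 0.5`) and a side label.
#'
#' @param data 3-D array of values in `[0, 1]`.
#' @param affine 4x4 voxel-to-world matrix.
#' @param side `"left"` or `"right"`.
#' @return An object of classes `segmentation` and `image_volume`.
#' @export
segmentation <- function(data, affine = diag(4), side = c("left", "right")) {
  side <- match.arg(side)
  if (min(data) < -1e-6 || max(data) > 1 + 1e-6) {
    stop("segmentation values must lie in [0, 1]", call. = FALSE)
  }
  v <- image_volume(data, affine, "mask")
  v$side <- side
  class(v) <- c("segmentation", "image_volume")
  v
}

binarize <- function(seg, threshold = 0.5) seg$data >= threshold

same_grid <- function(a, b, tol = 1e-5) {
  all(dim(a$data) == dim(b$data)) && max(abs(a$affine - b$affine)) < tol
}
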