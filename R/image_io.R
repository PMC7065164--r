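# NIfTI reading/writing (via RNifti) and resampling.

#' Read a NIfTI volume
#'
#' Reads a 3-D NIfTI-1 file (`.nii` / `.nii.gz`). The on-disk sform/qform is
#' used as the voxel-to-world affine (NIfTI's RAS+ mm convention, 0-based
#' voxel indices). 4-D files are accepted only with a singleton last axis.
#'
#' @param path path to the file.
#' @param modality modality tag to attach (default `"T1"`).
#' @return An [image_volume()].
#' @export
load_volume <- function(path, modality = "T1") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L) {
    if (d[4] != 1L) {
      stop("unsupported-input: 4-D multi-frame images are not supported",
           call. = FALSE)
    }
    img <- img[, , , 1, drop = TRUE]
    d <- d[1:3]
  }
  if (length(d) != 3L) {
    stop("unsupported-input: expected a 3-D image", call. = FALSE)
  }
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  image_volume(array(as.numeric(img), d), aff, modality)
}

#' Load a segmentation from NIfTI
#'
#' @param path path to a single-label NIfTI mask.
#' @param side `"left"` or `"right"`.
#' @return A [segmentation()].
#' @export
load_segmentation <- function(path, side) {
  v <- load_volume(path, "mask")
  segmentation(pmin(pmax(v$data, 0), 1), v$affine, side)
}

#' Write a volume to NIfTI
#'
#' @param volume an `image_volume` (or `segmentation`).
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  # sform only: it stores the full 3x4 matrix exactly, whereas the
  # quaternion qform cannot carry shears and loses anisotropic spacing here
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume onto a reference grid
#'
#' Pulls `volume` back onto the grid of `reference` under the world-to-world
#' `transform` (which maps the volume's world onto the reference's world).
#' Nearest-neighbour interpolation is appropriate for masks and labels,
#' trilinear for scalar maps. Voxels falling outside the source field of
#' view receive `fill` (0 for masks, `NA` for qT2/distance maps by default).
#'
#' @param volume the source `image_volume` or `segmentation`.
#' @param transform a `world_transform` (default identity).
#' @param reference an `image_volume` defining the output grid.
#' @param interp `"linear"` or `"nearest"`.
#' @param fill out-of-field value; default 0 for masks, `NA` otherwise.
#' @return An `image_volume` (or `segmentation`) on the reference grid.
#' @export
resample <- function(volume, transform = identity_transform(), reference,
                     interp = c("linear", "nearest"), fill = NULL) {
  interp <- match.arg(interp)
  if (is.null(fill)) fill <- if (volume$modality == "mask") 0 else NA_real_
  dims_out <- dim(reference$data)
  if (any(dims_out < 1L)) stop("geometry error: degenerate reference grid",
                               call. = FALSE)
  m <- solve(volume$affine) %*% solve(transform$matrix) %*% reference$affine
  out <- resample_core(as.numeric(volume$data), dim(volume$data), m,
                       as.integer(dims_out),
                       if (interp == "nearest") 0L else 1L, fill)
  out <- array(out, dims_out)
  if (inherits(volume, "segmentation")) {
    segmentation(pmin(pmax(out, 0), 1), reference$affine, volume$side)
  } else {
    image_volume(out, reference$affine, volume$modality)
  }
}
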