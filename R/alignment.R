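# Long-axis reorientation, AP distance maps and groupwise masks.

#' Principal long axis of a segmentation
#'
#' First principal component of the in-mask (binarized at 0.5) voxel world
#' coordinates, with the sign fixed so the axis has a non-negative AP (+y)
#' component.
#'
#' @param seg a [segmentation()] with at least 10 in-mask voxels.
#' @param min_elongation minimum first/second eigenvalue ratio below which
#'   the axis is considered degenerate (default 1.2).
#' @return List with `axis` (unit length-3), `values` (eigenvalue triple)
#'   and `centroid` (world mm).
#' @export
principal_axis <- function(seg, min_elongation = 1.2) {
  idx <- which(binarize(seg), arr.ind = TRUE) - 1L
  if (nrow(idx) < 10) {
    stop("precondition error: need >= 10 in-mask voxels", call. = FALSE)
  }
  w <- voxel_to_world(seg$affine, idx)
  e <- eigen(stats::cov(w), symmetric = TRUE)
  if (e$values[1] / e$values[2] < min_elongation) {
    stop("degenerate-axis error: mask is not elongated (eigenvalue ratio ",
         sprintf("%.2f)", e$values[1] / e$values[2]), call. = FALSE)
  }
  ax <- e$vectors[, 1]
  if (ax[2] < 0) ax <- -ax
  list(axis = ax, values = e$values, centroid = colMeans(w))
}

# minimal rotation taking unit vector v onto unit vector w
rotation_between <- function(v, w) {
  v <- v / sqrt(sum(v^2)); w <- w / sqrt(sum(w^2))
  c_ <- sum(v * w)
  axis <- c(v[2] * w[3] - v[3] * w[2],
            v[3] * w[1] - v[1] * w[3],
            v[1] * w[2] - v[2] * w[1])
  s <- sqrt(sum(axis^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite: rotate pi about any orthogonal axis
    axis <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- axis - sum(axis * v) * v
    axis <- axis / sqrt(sum(axis^2))
    s <- 0; c_ <- -1
  } else {
    axis <- axis / s
  }
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

#' Rigid reorientation of the hippocampal long axes onto the AP axis
#'
#' Estimates both hippocampal long axes by PCA, averages them, and returns
#' the rigid transform (rotation about the mid-centroid) that maps the mean
#' axis onto world +y. The residual roll about +y is fixed by mapping the
#' left-to-right centroid direction onto world +x, so the midsagittal plane
#' ends up vertical.
#'
#' @param volume the subject volume (carried along for provenance; the
#'   transform is derived from the segmentations).
#' @param seg_left,seg_right the two hippocampal [segmentation()]s.
#' @param max_disagreement_deg error if the two long axes disagree by more
#'   than this angle (default 45).
#' @return A rigid `world_transform` mapping subject world onto AP-aligned
#'   world.
#' @export
reorient_to_ap <- function(volume, seg_left, seg_right,
                           max_disagreement_deg = 45) {
  pl <- principal_axis(seg_left)
  pr <- principal_axis(seg_right)
  ang <- acos(min(1, abs(sum(pl$axis * pr$axis)))) * 180 / pi
  if (ang > max_disagreement_deg) {
    stop(sprintf(
      "alignment-failure error: left/right long axes disagree by %.1f deg",
      ang), call. = FALSE)
  }
  v <- pl$axis + pr$axis
  v <- v / sqrt(sum(v^2))
  R1 <- rotation_between(v, c(0, 1, 0))
  lr <- R1 %*% (pr$centroid - pl$centroid)
  theta <- atan2(lr[3], lr[1]) # roll about +y taking lr into +x
  Ry <- rbind(c(cos(theta), 0, sin(theta)),
              c(0, 1, 0),
              c(-sin(theta), 0, cos(theta)))
  R <- Ry %*% R1
  centre <- (pl$centroid + pr$centroid) / 2
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- centre - R %*% centre
  world_transform(m, "rigid")
}

#' AP distance map of an AP-aligned template
#'
#' Assigns every voxel of coronal slice `k` (1-based, counted from the most
#' posterior slice) the constant value `k * (AP spacing)` mm, so a 218-slice
#' 1-mm template carries distances 1-218 mm from posterior to anterior.
#'
#' @param template an `image_volume` in AP-aligned orientation.
#' @return An `image_volume` with modality `"distance"`.
#' @export
build_distance_map <- function(template) {
  d <- dim(template$data)
  dy <- voxel_spacing(template)[2]
  vals <- rep(seq_len(d[2]) * dy, each = d[1])
  arr <- array(rep(vals, d[3]), d)
  image_volume(arr, template$affine, "distance")
}

#' Propagate a distance map into subject space
#'
#' Trilinear resampling of the template distance map through the
#' template-to-subject transform; voxels outside the template field of view
#' become `NA` so downstream averages ignore them.
#'
#' @param dmap the template [build_distance_map()] output.
#' @param template_to_subject `world_transform` from template world to
#'   subject world.
#' @param subject_grid an `image_volume` defining the subject grid.
#' @return An `image_volume` with modality `"distance"` on the subject grid.
#' @export
propagate_distance_map <- function(dmap, template_to_subject, subject_grid) {
  resample(dmap, template_to_subject, subject_grid, "linear", fill = NA_real_)
}

#' Per-slice mean AP distances within a segmentation
#'
#' For each coronal slice of the subject grid containing in-mask voxels, the
#' mean of the propagated distances over those voxels, giving the mapping
#' from subject slice index to template AP position. Warns when more than
#' 10% of in-mask voxels fall outside the propagated field, and when the
#' means are not strictly increasing with slice index (a sign of failed
#' alignment).
#'
#' @param propagated the [propagate_distance_map()] output, on the same grid
#'   as `seg`.
#' @param seg the subject [segmentation()].
#' @return A data frame (`slice_distance_table`) with `slice`,
#'   `distance_mm`, `n_voxels`.
#' @export
slice_distance_table <- function(propagated, seg) {
  if (!same_grid(propagated, seg)) {
    stop("geometry error: distance map and segmentation grids differ",
         call. = FALSE)
  }
  m <- binarize(seg)
  dv <- propagated$data
  n_out <- sum(m & !is.finite(dv))
  if (n_out > 0.1 * sum(m)) {
    warning(sprintf(
      "propagation warning: %.0f%% of in-mask voxels outside distance field",
      100 * n_out / sum(m)))
  }
  d <- dim(dv)
  rows <- lapply(seq_len(d[2]), function(j) {
    mj <- m[, j, ]
    vj <- dv[, j, ][mj]
    vj <- vj[is.finite(vj)]
    if (!length(vj)) return(NULL)
    data.frame(slice = j, distance_mm = mean(vj), n_voxels = length(vj))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) {
    stop("empty-input error: segmentation is empty", call. = FALSE)
  }
  if (any(diff(tab$distance_mm) <= 0)) {
    warning("alignment-failure warning: slice distances not strictly increasing")
  }
  class(tab) <- c("slice_distance_table", "data.frame")
  tab
}

#' Groupwise majority-vote mask
#'
#' A voxel enters the group mask when it is included in at least
#' `threshold` (default half) of the individual segmentations; a voxel in
#' exactly half of them is included.
#'
#' @param segs non-empty list of [segmentation()]s on the template grid.
#' @param threshold inclusion fraction (default 0.5).
#' @return A [segmentation()] on the template grid.
#' @export
majority_mask <- function(segs, threshold = 0.5) {
  if (!length(segs)) stop("empty-input error: no segmentations", call. = FALSE)
  ref <- segs[[1]]
  acc <- array(0, dim(ref$data))
  for (s in segs) {
    if (!same_grid(s, ref)) {
      stop("geometry error: segmentations must share the template grid",
           call. = FALSE)
    }
    acc <- acc + binarize(s)
  }
  frac <- acc / length(segs)
  segmentation(array(as.numeric(frac >= threshold), dim(acc)),
               ref$affine, ref$side)
}
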