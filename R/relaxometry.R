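# Two-point mono-exponential T2 estimation from a dual-echo acquisition and
# masked qT2 summaries with partial-volume exclusion.

#' Voxelwise quantitative T2 from a dual-echo pair
#'
#' For a mono-exponential decay sampled at two echo times the closed-form
#' estimator is `qT2 = (TE2 - TE1) / ln(S(TE1) / S(TE2))`. Voxels with a
#' non-positive signal at either echo, a non-decaying signal
#' (`S(TE2) >= S(TE1)`), or an estimate at or above `ceiling_ms`
#' (CSF-dominated) are marked invalid rather than clamped.
#'
#' @param echo1,echo2 co-registered `image_volume`s on the same grid.
#' @param te1,te2 echo times in ms, `te2 > te1 > 0`.
#' @param ceiling_ms upper validity bound for qT2 (default 1000 ms).
#' @return A `qt2_result`: `qt2` (an `image_volume`, invalid voxels `NA`),
#'   `valid` (logical array), `reason` (integer array: 0 valid,
#'   1 nonpositive-signal, 2 nondecaying, 3 above-ceiling),
#'   `excluded_voxel_count`, `echo_times`.
#' @export
fit_qt2 <- function(echo1, echo2, te1 = 30, te2 = 119, ceiling_ms = 1000) {
  if (!(te2 > te1 && te1 > 0)) {
    stop("precondition error: echo times must satisfy TE2 > TE1 > 0",
         call. = FALSE)
  }
  if (!same_grid(echo1, echo2)) {
    stop("geometry error: echo volumes must share one grid", call. = FALSE)
  }
  s1 <- echo1$data
  s2 <- echo2$data
  reason <- array(0L, dim(s1))
  reason[s1 <= 0 | s2 <= 0] <- 1L
  reason[reason == 0L & s2 >= s1] <- 2L
  qt2 <- array(NA_real_, dim(s1))
  ok <- reason == 0L
  qt2[ok] <- (te2 - te1) / log(s1[ok] / s2[ok])
  reason[ok & qt2 >= ceiling_ms] <- 3L
  qt2[reason != 0L] <- NA_real_
  valid <- reason == 0L
  structure(list(
    qt2 = image_volume(qt2, echo1$affine, "qT2"),
    valid = valid, reason = reason,
    excluded_voxel_count = sum(!valid),
    echo_times = c(te1, te2), ceiling_ms = ceiling_ms
  ), class = "qt2_result")
}

#' @export
print.qt2_result <- function(x, ...) {
  cat(sprintf("<qt2_result> TE %g/%g ms, %d voxels excluded\n",
              x$echo_times[1], x$echo_times[2], x$excluded_voxel_count))
  invisible(x)
}

# one-voxel 6-neighbourhood erosion of a binary array
erode1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, ax, by) {
    r <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by > 0) {
      idx_dst[[ax]] <- (1 + by):d[ax]; idx_src[[ax]] <- 1:(d[ax] - by)
    } else {
      idx_dst[[ax]] <- 1:(d[ax] + by); idx_src[[ax]] <- (1 - by):d[ax]
    }
    r[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    r
  }
  for (ax in 1:3) {
    out <- out & shift(mask, ax, 1L) & shift(mask, ax, -1L)
  }
  out
}

#' Masked qT2 summaries with partial-volume exclusion
#'
#' Resamples the hippocampal segmentation onto the qT2 grid (trilinear,
#' yielding a per-voxel mask fraction) and keeps only interior voxels whose
#' fraction is at least `min_fraction` (default 0.99) — i.e. partial-volume
#' voxels at the hippocampal boundary are excluded. If fewer than
#' `min_voxels` survive, the fallback is a one-voxel erosion of the
#' binarized mask. Returns the whole-structure mean and per-coronal-slice
#' means over valid voxels; slices with no valid voxel are `NA`, never zero.
#'
#' @param result a [fit_qt2()] result.
#' @param seg a [segmentation()] (any grid; resampled internally).
#' @param pv_policy list with `min_fraction` and `min_voxels`.
#' @return A list: `mean_ms`, `n_voxels`, and `slices` (data frame with
#'   `slice`, `qt2_ms`, `n_valid`, `seg_volume_mm3` — the segmentation
#'   volume per slice used later as regional weights).
#' @export
masked_qt2 <- function(result, seg,
                       pv_policy = list(min_fraction = 0.99,
                                        min_voxels = 10)) {
  qv <- result$qt2
  frac <- if (same_grid(seg, qv)) seg
          else resample(seg, identity_transform(), qv, "linear")
  keep <- frac$data >= pv_policy$min_fraction
  if (sum(keep) < pv_policy$min_voxels) {
    keep <- erode1(binarize(frac))
  }
  use <- keep & result$valid
  if (!any(use)) {
    stop("empty-input error: segmentation contains no valid qT2 voxels",
         call. = FALSE)
  }
  vals <- qv$data
  d <- dim(vals)
  vv <- voxel_volume(qv)
  slice_stats <- lapply(seq_len(d[2]), function(j) {
    u <- use[, j, ]
    n <- sum(u)
    data.frame(
      slice = j,
      qt2_ms = if (n > 0) mean(vals[, j, ][u]) else NA_real_,
      n_valid = n,
      seg_volume_mm3 = sum(frac$data[, j, ]) * vv
    )
  })
  slices <- do.call(rbind, slice_stats)
  slices <- slices[slices$n_valid > 0 | slices$seg_volume_mm3 > 0, ]
  list(mean_ms = mean(vals[use]), n_voxels = sum(use), slices = slices)
}
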