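# AP profiles: TIV-corrected cross-sectional areas, discrete qT2 points,
# region partitioning by the CSA-stability rule, and regional metrics.

#' Construct a profile
#'
#' Paired (AP position, value) sequences for one hippocampus. Continuous
#' profiles live on a uniform 1-mm grid; discrete qT2 profiles carry one
#' point per acquired coronal slice.
#'
#' @param positions strictly ascending AP positions (mm).
#' @param values CSA (mm^2, `>= 0`) or qT2 (ms, `> 0`) values.
#' @param modality `"CSA"` or `"qT2"`.
#' @param side `"left"` or `"right"`.
#' @param subject subject identifier.
#' @param sampling `"continuous-1mm"` or `"discrete-slice"`.
#' @return An object of class `profile_ap`.
#' @export
new_profile <- function(positions, values, modality = c("CSA", "qT2"),
                        side = c("left", "right"), subject = NA_character_,
                        sampling = c("continuous-1mm", "discrete-slice")) {
  modality <- match.arg(modality)
  sampling <- match.arg(sampling)
  side <- match.arg(side)
  stopifnot(length(positions) == length(values), length(positions) >= 1)
  if (any(diff(positions) <= 0)) {
    stop("profile positions must be strictly ascending", call. = FALSE)
  }
  if (modality == "CSA" && any(values < -1e-9)) {
    stop("CSA values must be non-negative", call. = FALSE)
  }
  if (modality == "qT2" && any(values <= 0)) {
    stop("qT2 values must be positive", call. = FALSE)
  }
  structure(list(positions = as.numeric(positions),
                 values = as.numeric(values),
                 modality = modality, side = side, subject = subject,
                 sampling = sampling),
            class = "profile_ap")
}

#' @export
print.profile_ap <- function(x, ...) {
  cat(sprintf("<profile %s %s> %d points, AP %.0f-%.0f mm (%s)\n",
              x$modality, x$side, length(x$positions), min(x$positions),
              max(x$positions), x$sampling))
  invisible(x)
}

# linear interpolation of a profile at arbitrary positions (NA outside)
profile_at <- function(profile, at) {
  if (length(profile$positions) == 1L) {
    out <- rep(NA_real_, length(at))
    out[abs(at - profile$positions) < 1e-9] <- profile$values
    return(out)
  }
  approx(profile$positions, profile$values, xout = at, rule = 1)$y
}

#' TIV-corrected CSA profile from a segmentation and distance table
#'
#' Per occupied coronal slice, the raw CSA is the sum of (fractional) mask
#' values times the in-plane voxel area; TIV ratio correction multiplies by
#' `tiv_ref / tiv`. Slice CSAs are paired with the slice mean AP distances
#' and linearly interpolated onto the uniform 1-mm grid spanned by the
#' distances.
#'
#' @param seg the subject [segmentation()].
#' @param table a [slice_distance_table()] on the same grid.
#' @param tiv subject total intracranial volume (mL), `> 0`.
#' @param tiv_ref reference (normative cohort mean) TIV; identical
#'   correction is applied to CSAs and volumes so profiles integrate to
#'   corrected volumes.
#' @param grid_step profile grid step in mm (default 1).
#' @return A continuous [new_profile()] with attribute `"slices"` holding
#'   the per-slice (distance, CSA) pairs.
#' @export
csa_profile <- function(seg, table, tiv, tiv_ref = tiv, grid_step = 1) {
  stopifnot(tiv > 0, tiv_ref > 0)
  d <- dim(seg$data)
  sp <- voxel_spacing(seg)
  in_plane <- sp[1] * sp[3]
  areas <- vapply(seq_len(d[2]), function(j) sum(seg$data[, j, ]) * in_plane,
                  numeric(1))
  occ <- intersect(which(areas > 0), table$slice)
  if (!length(occ)) {
    stop("empty-input error: segmentation is empty", call. = FALSE)
  }
  dist <- table$distance_mm[match(occ, table$slice)]
  if (any(diff(dist) <= 0)) {
    stop("alignment-failure error: slice distances not strictly increasing",
         call. = FALSE)
  }
  csa <- areas[occ] * (tiv_ref / tiv)
  if (length(occ) == 1L) {
    grid <- dist
    vals <- csa
  } else {
    grid <- seq(ceiling(min(dist) / grid_step) * grid_step,
                floor(max(dist) / grid_step) * grid_step, by = grid_step)
    vals <- approx(dist, csa, xout = grid, rule = 1)$y
  }
  p <- new_profile(grid, pmax(vals, 0), "CSA", seg$side,
                   sampling = "continuous-1mm")
  attr(p, "slices") <- data.frame(slice = occ, distance_mm = dist,
                                  csa_mm2 = csa)
  p
}

#' Discrete qT2 profile from per-slice means and a distance table
#'
#' One (distance, qT2) point per coronal slice having at least `min_voxels`
#' valid (non-partial-volume) voxels; slices below that are omitted, not
#' zeroed.
#'
#' @param slice_means the `slices` data frame from [masked_qt2()].
#' @param table a [slice_distance_table()] on the dual-echo grid.
#' @param side `"left"` or `"right"`.
#' @param min_voxels minimum valid voxels per slice point (default 5).
#' @return A discrete [new_profile()] with attribute `"weights"`: the
#'   per-point segmentation volume (mm^3) used for regional weighting.
#' @export
qt2_profile <- function(slice_means, table, side, min_voxels = 5) {
  m <- merge(slice_means, table, by = "slice")
  m <- m[!is.na(m$qt2_ms) & m$n_valid >= min_voxels, ]
  m <- m[order(m$distance_mm), ]
  if (!nrow(m)) {
    stop("empty-input error: no usable qT2 slices", call. = FALSE)
  }
  p <- new_profile(m$distance_mm, m$qt2_ms, "qT2", side,
                   sampling = "discrete-slice")
  attr(p, "weights") <- m$seg_volume_mm3
  p
}

#' Partition the AP extent into tail, body and head
#'
#' The body is the maximal contiguous run of normative-grid points where the
#' absolute CSA slope (central difference; one-sided at the endpoints) is
#' below `slope_threshold`; the tail is everything posterior of it, the head
#' everything anterior. Among equal-length maximal runs the more posterior
#' one is taken. A profile stable everywhere yields zero-length tail and
#' head with `degenerate = TRUE` (the only case where zero-length regions
#' are allowed); no stable point at all is an error.
#'
#' @param normative_csa a [build_normative()] model (modality CSA), or any
#'   list with `grid` and `mu`.
#' @param slope_threshold stability rule in mm^2/mm (default 2).
#' @return An object of class `region_partition`: `side`, boundary
#'   positions `tail_body` and `body_head` (mm), `lengths` (named tail /
#'   body / head, mm), `degenerate`.
#' @export
partition_regions <- function(normative_csa, slope_threshold = 2) {
  x <- normative_csa$grid
  mu <- normative_csa$mu
  n <- length(x)
  stopifnot(n >= 3)
  slope <- numeric(n)
  slope[1] <- (mu[2] - mu[1]) / (x[2] - x[1])
  slope[n] <- (mu[n] - mu[n - 1]) / (x[n] - x[n - 1])
  slope[2:(n - 1)] <- (mu[3:n] - mu[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  stable <- abs(slope) < slope_threshold
  if (!any(stable)) {
    stop("no-body error: no grid point satisfies the stability criterion",
         call. = FALSE)
  }
  r <- rle(stable)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])] # ties: first = most posterior
  i0 <- starts[best]
  i1 <- ends[best]
  structure(list(
    side = normative_csa$side %||% NA_character_,
    tail_body = x[i0], body_head = x[i1],
    lengths = c(tail = x[i0] - x[1], body = x[i1] - x[i0],
                head = x[n] - x[i1]),
    degenerate = (i0 == 1L && i1 == n),
    slope_threshold = slope_threshold
  ), class = "region_partition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf(
    "<region_partition %s> tail|body %.0f mm, body|head %.0f mm (t/b/h %s mm)%s\n",
    x$side, x$tail_body, x$body_head,
    paste(round(x$lengths), collapse = "/"),
    if (x$degenerate) " [degenerate: stable everywhere]" else ""))
  invisible(x)
}

# region label of positions under a partition (tail|body|head)
region_of <- function(partition, positions) {
  ifelse(positions < partition$tail_body, "tail",
         ifelse(positions < partition$body_head, "body", "head"))
}

#' Whole and regional volumes and qT2 for one subject
#'
#' Regional volumes integrate the CSA profile over each region (`sum CSA *
#' grid step`); regional qT2 averages the slicewise qT2 values weighted by
#' the segmentation volume in each slice, each slice assigned to the region
#' containing its mean AP distance. A region containing no qT2 slice gets
#' `NA`.
#'
#' @param profile a continuous CSA [new_profile()].
#' @param partition a [partition_regions()] result.
#' @param qt2_points optional discrete qT2 [qt2_profile()].
#' @param qt2_weights per-point segmentation volumes (mm^3); defaults to the
#'   profile's `"weights"` attribute.
#' @param tiv subject TIV (mL), carried through for reporting.
#' @return An object of class `subject_metrics`: `tiv_ml`,
#'   `whole_volume_ml`, `regional_volumes_ml` (tail/body/head),
#'   `whole_qt2_ms`, `regional_qt2_ms`.
#' @export
region_metrics <- function(profile, partition, qt2_points = NULL,
                           qt2_weights = NULL, tiv = NA_real_) {
  stopifnot(profile$modality == "CSA")
  dx <- if (length(profile$positions) > 1) diff(profile$positions)[1] else 1
  reg <- region_of(partition, profile$positions)
  vol <- vapply(c("tail", "body", "head"), function(r) {
    sum(profile$values[reg == r]) * dx / 1000
  }, numeric(1))
  whole <- sum(profile$values) * dx / 1000
  rq <- c(tail = NA_real_, body = NA_real_, head = NA_real_)
  wq <- NA_real_
  if (!is.null(qt2_points)) {
    w <- qt2_weights %||% attr(qt2_points, "weights")
    if (is.null(w)) w <- rep(1, length(qt2_points$values))
    qreg <- region_of(partition, qt2_points$positions)
    for (r in names(rq)) {
      i <- qreg == r
      if (any(i)) rq[r] <- sum(qt2_points$values[i] * w[i]) / sum(w[i])
    }
    wq <- sum(qt2_points$values * w) / sum(w)
  }
  structure(list(tiv_ml = tiv, whole_volume_ml = whole,
                 regional_volumes_ml = vol, whole_qt2_ms = wq,
                 regional_qt2_ms = rq, side = profile$side),
            class = "subject_metrics")
}

#' @export
print.subject_metrics <- function(x, ...) {
  cat(sprintf(
    "<subject_metrics %s> volume %.2f mL (t/b/h %s), qT2 %s ms\n",
    x$side, x$whole_volume_ml,
    paste(sprintf("%.2f", x$regional_volumes_ml), collapse = "/"),
    if (is.na(x$whole_qt2_ms)) "-" else sprintf("%.1f", x$whole_qt2_ms)))
  invisible(x)
}
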