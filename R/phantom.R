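# Synthetic hippocampus phantom: curved elongated bilateral masks following
# a parametric CSA profile, mono-exponential dual-echo signals, rigid poses,
# focal lesions, and population variability. Every downstream stage of the
# pipeline is validated against the ground truth this generator retains.

#' Phantom specification
#'
#' Parameter set for one synthetic subject. The default cross-sectional-area
#' (CSA) profile is piecewise linear along the long axis: a tapering
#' posterior tail, a stable body plateau (|slope| < 2 mm^2/mm by
#' construction), and an anterior head that bulges then tapers. Defaults are
#' calibrated so a typical subject has a hippocampal volume of ~2.9 mL and
#' tissue T2 of 115 ms, the centre of the healthy-control regime for 3-T
#' hippocampal imaging.
#'
#' @param length_mm total long-axis extent of the hippocampus (mm).
#' @param csa_tail,csa_body,csa_peak,csa_tip CSA (mm^2) at the posterior
#'   end, over the body plateau, at the head peak, and at the anterior tip.
#' @param tail_len,body_len,head_rise_len lengths (mm) of the tail ramp, the
#'   body plateau and the head rise; the head fall occupies the remainder.
#' @param aspect in-plane ellipse aspect ratio (left-right over
#'   superior-inferior semi-axis).
#' @param arc_radius_mm radius of the mild circular arc of the centreline in
#'   the sagittal plane; `Inf` gives a straight tube.
#' @param lateral_offset_mm distance of each hippocampus from the midline.
#' @param t2_tissue,t2_background tissue T2 values (ms) inside the
#'   hippocampus and in the remaining head tissue.
#' @param s0 proton-density signal scale.
#' @param noise_sd additive Gaussian noise sd on the echo signals.
#' @param te echo times `(TE1, TE2)` in ms; defaults 30/119.
#' @param tiv_ml total intracranial volume (mL).
#' @param csa_scale multiplicative scaling of the CSA profile (between-
#'   subject size variation).
#' @param pose rigid pose: `list(angles_deg = c(rx, ry, rz), translation =
#'   c(tx, ty, tz))` mapping the canonical AP-aligned phantom into scanner
#'   orientation.
#' @param lesion optional focal lesion: `list(centre_mm, extent_mm,
#'   atrophy_fraction, delta_t2)`; positions in canonical long-axis mm from
#'   the posterior end. `atrophy_fraction` in `[0, 1]` shrinks CSA inside the
#'   band; `delta_t2` (ms) is added to tissue T2 there.
#' @param shape `"profile"` (default piecewise CSA tube) or `"ellipsoid"`
#'   (analytic ellipsoid with `ellipsoid_semiaxes`, used as an exact oracle).
#' @param ellipsoid_semiaxes semi-axes (AP, left-right, superior-inferior)
#'   in mm for `shape = "ellipsoid"`.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(length_mm = 45,
                         csa_tail = 10, csa_body = 68, csa_peak = 118,
                         csa_tip = 5,
                         tail_len = 8, body_len = 14, head_rise_len = 8,
                         aspect = 1.8,
                         arc_radius_mm = 90,
                         lateral_offset_mm = 14,
                         t2_tissue = 115, t2_background = 80,
                         s0 = 1000, noise_sd = 10,
                         te = c(30, 119),
                         tiv_ml = 1450,
                         csa_scale = 1,
                         pose = list(angles_deg = c(0, 0, 0),
                                     translation = c(0, 0, 0)),
                         lesion = NULL,
                         shape = c("profile", "ellipsoid"),
                         ellipsoid_semiaxes = c(25, 10, 8),
                         seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(length_mm > 0, t2_tissue > 0, t2_background > 0, noise_sd >= 0,
            tiv_ml > 0, csa_scale > 0, aspect > 0,
            tail_len + body_len + head_rise_len < length_mm)
  if (!is.null(lesion)) {
    stopifnot(lesion$atrophy_fraction >= 0, lesion$atrophy_fraction <= 1,
              lesion$extent_mm > 0)
    if (is.null(lesion$delta_t2)) lesion$delta_t2 <- 0
  }
  spec <- list(length_mm = length_mm, csa_tail = csa_tail,
               csa_body = csa_body, csa_peak = csa_peak, csa_tip = csa_tip,
               tail_len = tail_len, body_len = body_len,
               head_rise_len = head_rise_len, aspect = aspect,
               arc_radius_mm = arc_radius_mm,
               lateral_offset_mm = lateral_offset_mm,
               t2_tissue = t2_tissue, t2_background = t2_background,
               s0 = s0, noise_sd = noise_sd, te = te, tiv_ml = tiv_ml,
               csa_scale = csa_scale, pose = pose, lesion = lesion,
               shape = shape, ellipsoid_semiaxes = ellipsoid_semiaxes,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

#' Ground-truth CSA profile function of a phantom spec
#'
#' Returns the analytic CSA (mm^2) as a function of canonical long-axis
#' position `u` (mm from the posterior end), including subject scaling and
#' any implanted atrophic lesion.
#'
#' @param spec a [phantom_spec()].
#' @param lesioned apply the lesion's atrophy (default `TRUE`).
#' @return A vectorized function `u -> CSA`.
#' @export
base_csa_profile <- function(spec, lesioned = TRUE) {
  force(spec); force(lesioned)
  function(u) {
    L <- spec$length_mm
    if (spec$shape == "ellipsoid") {
      ax <- spec$ellipsoid_semiaxes
      v <- pi * ax[2] * ax[3] * (1 - ((u - ax[1]) / ax[1])^2)
      v[u < 0 | u > 2 * ax[1]] <- 0
      v <- pmax(v, 0)
    } else {
      t1 <- spec$tail_len
      t2 <- t1 + spec$body_len
      t3 <- t2 + spec$head_rise_len
      v <- numeric(length(u))
      idx <- u >= 0 & u < t1
      v[idx] <- spec$csa_tail + (spec$csa_body - spec$csa_tail) * u[idx] / t1
      idx <- u >= t1 & u < t2
      v[idx] <- spec$csa_body
      idx <- u >= t2 & u < t3
      v[idx] <- spec$csa_body +
        (spec$csa_peak - spec$csa_body) * (u[idx] - t2) / (t3 - t2)
      idx <- u >= t3 & u <= L
      v[idx] <- spec$csa_peak +
        (spec$csa_tip - spec$csa_peak) * (u[idx] - t3) / (L - t3)
    }
    v <- v * spec$csa_scale
    if (lesioned && !is.null(spec$lesion)) {
      les <- spec$lesion
      band <- u >= les$centre_mm - les$extent_mm / 2 &
        u <= les$centre_mm + les$extent_mm / 2
      v[band] <- v[band] * (1 - les$atrophy_fraction)
    }
    v
  }
}

# evaluate expr under a fixed seed without disturbing the caller's RNG
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# superior displacement (mm) of the centreline at long-axis position u
arc_offset <- function(spec, u) {
  R <- spec$arc_radius_mm
  if (!is.finite(R) || spec$shape == "ellipsoid") return(rep(0, length(u)))
  d <- u - spec$length_mm / 2
  R - sqrt(pmax(R^2 - d^2, 0))
}

# canonical coordinates of world points under the inverse of the spec pose
canonical_coords <- function(spec, world) {
  R <- rot3(spec$pose$angles_deg)
  shifted <- sweep(world, 2, spec$pose$translation)
  shifted %*% R # = t(t(R) %*% t(shifted)): inverse rotation
}

# in-tube membership for one side on given canonical coordinates
tube_membership <- function(spec, canon, side, lesioned = TRUE) {
  sgn <- if (side == "right") 1 else -1
  prof <- base_csa_profile(spec, lesioned = lesioned)
  L <- if (spec$shape == "ellipsoid") 2 * spec$ellipsoid_semiaxes[1]
       else spec$length_mm
  aspect <- if (spec$shape == "ellipsoid")
    spec$ellipsoid_semiaxes[2] / spec$ellipsoid_semiaxes[3]
  else spec$aspect
  u <- canon[, 2] + L / 2
  csa <- prof(u)
  ok <- csa > 0
  a <- sqrt(csa * aspect / pi)
  b <- a / aspect
  dx <- canon[, 1] - sgn * spec$lateral_offset_mm
  dz <- canon[, 3] - arc_offset(spec, u)
  inc <- ok & (dx / a)^2 + (dz / b)^2 <= 1
  inc[!ok] <- FALSE
  inc
}

# fractional in-plane coverage of the tube on a grid: membership averaged
# over subdiv x subdiv in-plane subvoxel offsets (edge partial volume)
tube_fraction <- function(spec, grid, side, posed = TRUE, subdiv = 3L) {
  world <- grid_world_coords(grid)
  offs <- (seq_len(subdiv) - (subdiv + 1) / 2) / subdiv
  ex <- grid$affine[1:3, 1]
  ez <- grid$affine[1:3, 3]
  acc <- numeric(nrow(world))
  for (ox in offs) {
    for (oz in offs) {
      w <- sweep(world, 2, ox * ex + oz * ez, "+")
      canon <- if (posed) canonical_coords(spec, w) else w
      acc <- acc + tube_membership(spec, canon, side)
    }
  }
  acc / (subdiv * subdiv)
}

#' Generate a phantom hippocampal mask with ground truth
#'
#' Builds the binary mask of one hippocampus on the given grid, posed
#' according to the spec's rigid pose, plus the ground-truth per-slice CSA
#' of the *unposed* (canonical, AP-aligned) mask on the same grid: per
#' coronal slice, in-plane voxel area times voxel count.
#'
#' @param spec a [phantom_spec()].
#' @param grid an `image_volume` supplying the output geometry (in-plane
#'   spacing should be <= 1 mm for T1-like grids).
#' @param side `"left"` or `"right"`.
#' @param subdiv in-plane subvoxel sampling factor for edge partial volume
#'   (default 3; `1` gives a purely binary mask).
#' @return A list with `seg` (a [segmentation()] with fractional edge
#'   voxels; binarized view is `values >= 0.5`) and `truth`, a data frame
#'   with columns `slice` (1-based coronal index), `u_mm` (canonical
#'   long-axis position of the slice centre), `csa_mm2` (in-plane voxel
#'   area times binarized voxel count of the unposed mask) and
#'   `csa_frac_mm2` (fractional-coverage CSA).
#' @export
make_mask <- function(spec, grid, side = c("left", "right"), subdiv = 3L) {
  side <- match.arg(side)
  sp <- voxel_spacing(grid)
  d <- dim(grid$data)
  L <- if (spec$shape == "ellipsoid") 2 * spec$ellipsoid_semiaxes[1]
       else spec$length_mm
  yr <- range(slice_ap_position(grid, c(1, d[2])))
  if (-L / 2 < yr[1] - sp[2] / 2 || L / 2 > yr[2] + sp[2] / 2) {
    stop("geometry error: profile extent exceeds the grid", call. = FALSE)
  }
  posed <- tube_fraction(spec, grid, side, posed = TRUE, subdiv = subdiv)
  seg <- segmentation(array(posed, d), grid$affine, side)

  identity_pose <- all(spec$pose$angles_deg == 0) &&
    all(spec$pose$translation == 0)
  truth_frac <- if (identity_pose) posed
                else tube_fraction(spec, grid, side, posed = FALSE,
                                   subdiv = subdiv)
  counts <- apply(array(truth_frac >= 0.5, d), 2, sum)
  frac_sum <- apply(array(truth_frac, d), 2, sum)
  occupied <- which(frac_sum > 0)
  truth <- data.frame(
    slice = occupied,
    u_mm = slice_ap_position(grid, occupied) + L / 2,
    csa_mm2 = counts[occupied] * sp[1] * sp[3],
    csa_frac_mm2 = frac_sum[occupied] * sp[1] * sp[3]
  )
  list(seg = seg, truth = truth)
}

# head (whole-cranium stand-in) ellipsoid membership on canonical coords
head_membership <- function(canon, semi = c(28, 36, 28)) {
  (canon[, 1] / semi[1])^2 + (canon[, 2] / semi[2])^2 +
    (canon[, 3] / semi[3])^2 <= 1
}

#' Generate a T1-like structural volume
#'
#' A simple head phantom on the 1-mm grid: a bright cranial ellipsoid with a
#' few internal structures of distinct intensity (so intensity-based
#' registration has gradients to work with), hippocampal tissue at reduced
#' intensity, and a little seeded Gaussian noise.
#'
#' @param spec a [phantom_spec()].
#' @param grid output geometry (default 64 x 80 x 64 at 1 mm, world-centred).
#' @return An `image_volume` with modality `"T1"`.
#' @export
make_t1_like <- function(spec, grid = NULL) {
  if (is.null(grid)) grid <- make_grid(c(64, 80, 64), c(1, 1, 1))
  d <- dim(grid$data)
  world <- grid_world_coords(grid)
  canon <- canonical_coords(spec, world)
  img <- numeric(nrow(canon))
  img[head_membership(canon)] <- 100
  deep <- (canon[, 1] / 4)^2 + (canon[, 2] / 10)^2 + (canon[, 3] / 4)^2 <= 1
  img[deep] <- 140
  for (sgn in c(-1, 1)) {
    vent <- ((canon[, 1] - sgn * 5) / 3)^2 + (canon[, 2] / 12)^2 +
      ((canon[, 3] - 10) / 4)^2 <= 1
    img[vent] <- 20
  }
  hip <- tube_membership(spec, canon, "left") |
    tube_membership(spec, canon, "right")
  img[hip] <- 70
  img <- with_local_seed(spec$seed + 11L,
                         img + rnorm(length(img), 0, 2))
  image_volume(array(img, d), grid$affine, "T1")
}

#' Generate a dual-echo PD/T2 pair
#'
#' Voxelwise mono-exponential signals `S(TE) = S0 exp(-TE / T2)` with tissue
#' T2 inside the hippocampi (plus any lesion `delta_t2` inside its band),
#' background T2 in the remaining head, and zero signal outside, plus
#' additive Gaussian noise of sd `noise_sd`. Deterministic given the spec
#' and its seed.
#'
#' @param spec a [phantom_spec()] (`te[2] > te[1] > 0` required).
#' @param grid output geometry; default a coronal grid of 0.43 x 4.00 x
#'   0.43 mm voxels (in-plane 0.43 mm, 4-mm coronal slices) covering the
#'   hippocampi.
#' @return A list with `echo1` and `echo2` (`image_volume`s, modality
#'   `"T2echo"`) and the ground-truth `t2` field as an `image_volume`.
#' @export
make_dual_echo <- function(spec, grid = NULL) {
  te <- spec$te
  if (!(te[2] > te[1] && te[1] > 0)) {
    stop("precondition error: echo times must satisfy TE2 > TE1 > 0",
         call. = FALSE)
  }
  if (is.null(grid)) {
    grid <- make_grid(c(148, 16, 100), c(0.43, 4.0, 0.43))
  }
  d <- dim(grid$data)
  world <- grid_world_coords(grid)
  canon <- canonical_coords(spec, world)
  t2 <- numeric(nrow(canon))
  t2[head_membership(canon)] <- spec$t2_background
  hip <- tube_membership(spec, canon, "left") |
    tube_membership(spec, canon, "right")
  t2[hip] <- spec$t2_tissue
  if (!is.null(spec$lesion) && spec$lesion$delta_t2 != 0) {
    u <- canon[, 2] + spec$length_mm / 2
    band <- hip & u >= spec$lesion$centre_mm - spec$lesion$extent_mm / 2 &
      u <= spec$lesion$centre_mm + spec$lesion$extent_mm / 2
    t2[band] <- t2[band] + spec$lesion$delta_t2
  }
  s0 <- ifelse(t2 > 0, spec$s0, 0)
  sig <- function(tev) ifelse(t2 > 0, s0 * exp(-tev / pmax(t2, 1e-9)), 0)
  e1 <- with_local_seed(spec$seed + 23L,
                        sig(te[1]) + rnorm(length(t2), 0, spec$noise_sd))
  e2 <- with_local_seed(spec$seed + 29L,
                        sig(te[2]) + rnorm(length(t2), 0, spec$noise_sd))
  list(
    echo1 = image_volume(array(e1, d), grid$affine, "T2echo"),
    echo2 = image_volume(array(e2, d), grid$affine, "T2echo"),
    t2 = image_volume(array(t2, d), grid$affine, "qT2")
  )
}

#' Generate one complete phantom subject
#'
#' @param spec a [phantom_spec()].
#' @param t1_grid,pd_grid geometries for the T1-like/mask volumes and the
#'   dual-echo pair; defaults as in [make_t1_like()] / [make_dual_echo()].
#' @param with_t1 generate the T1-like structural image (needed for
#'   registration-based pipelines; masks and echoes alone suffice for
#'   profile studies).
#' @return An object of class `phantom_subject`: volumes, segmentations and
#'   a `truth` list (per-slice CSA tables, T2 value, lesion, TIV, pose,
#'   spec).
#' @export
make_phantom_subject <- function(spec, t1_grid = NULL, pd_grid = NULL,
                                 with_t1 = TRUE) {
  if (is.null(t1_grid)) t1_grid <- make_grid(c(64, 80, 64), c(1, 1, 1))
  left <- make_mask(spec, t1_grid, "left")
  right <- make_mask(spec, t1_grid, "right")
  echoes <- make_dual_echo(spec, pd_grid)
  subj <- list(
    t1 = if (with_t1) make_t1_like(spec, t1_grid) else NULL,
    echo1 = echoes$echo1, echo2 = echoes$echo2,
    mask_left = left$seg, mask_right = right$seg,
    truth = list(csa_left = left$truth, csa_right = right$truth,
                 profile_fun = base_csa_profile(spec),
                 t2_tissue = spec$t2_tissue, t2_field = echoes$t2,
                 lesion = spec$lesion, tiv_ml = spec$tiv_ml,
                 pose = spec$pose, csa_scale = spec$csa_scale),
    spec = spec
  )
  class(subj) <- "phantom_subject"
  subj
}

#' @export
print.phantom_subject <- function(x, ...) {
  cat(sprintf(
    "<phantom_subject> length %.0f mm, T2 %.1f ms, TIV %.0f mL%s\n",
    x$spec$length_mm, x$spec$t2_tissue, x$spec$tiv_ml,
    if (is.null(x$spec$lesion)) "" else ", lesioned"))
  invisible(x)
}

#' Generate a phantom population
#'
#' Draws `n` independent subjects from a template spec with multiplicative
#' CSA scaling, additive tissue-T2 offsets, TIV draws and random rigid
#' poses. The raw CSA scale includes a `tiv_i / tiv_ml` factor so that
#' hippocampal size covaries with head size and the TIV ratio correction
#' removes that component, as it does in real cohorts.
#'
#' @param n number of subjects (>= 2).
#' @param spec template [phantom_spec()].
#' @param variability list with `csa_scale_sd` (relative), `t2_sd` (ms),
#'   `tiv_sd_ml` (mL); defaults 0.08 / 3.5 / 120 emulate a healthy-control
#'   cohort whose corrected volumes span roughly 2.4-3.4 mL and whole-
#'   hippocampus qT2 roughly 108-124 ms.
#' @param pose_range list with `angles_deg` and `translation_mm` half-ranges
#'   for the uniform random pose draws; set both to 0 for identity poses.
#' @param seed population seed.
#' @param images generate image volumes (`TRUE`) or only the per-subject
#'   specs and truth (`FALSE`, cheap, for profile-level studies).
#' @param with_t1 passed to [make_phantom_subject()].
#' @return A list of `phantom_subject` (or of `phantom_spec` when
#'   `images = FALSE`).
#' @export
make_population <- function(n, spec = phantom_spec(),
                            variability = list(csa_scale_sd = 0.08,
                                               t2_sd = 3.5,
                                               tiv_sd_ml = 120),
                            pose_range = list(angles_deg = 12,
                                              translation_mm = 4),
                            seed = 1L, images = TRUE, with_t1 = TRUE) {
  stopifnot(n >= 2)
  defaults <- list(csa_scale_sd = 0.08, t2_sd = 3.5, tiv_sd_ml = 120)
  variability <- utils::modifyList(defaults, variability)
  pose_range <- utils::modifyList(list(angles_deg = 12, translation_mm = 4),
                                  pose_range)
  draws <- with_local_seed(as.integer(seed), list(
    scale_dev = rnorm(n, 0, variability$csa_scale_sd),
    t2_dev = rnorm(n, 0, variability$t2_sd),
    tiv = spec$tiv_ml + rnorm(n, 0, variability$tiv_sd_ml),
    ang = matrix(runif(3 * n, -pose_range$angles_deg,
                       pose_range$angles_deg), ncol = 3),
    trl = matrix(runif(3 * n, -pose_range$translation_mm,
                       pose_range$translation_mm), ncol = 3),
    seeds = sample.int(.Machine$integer.max %/% 2L, n)))
  scale_dev <- draws$scale_dev; t2_dev <- draws$t2_dev; tiv <- draws$tiv
  ang <- draws$ang; trl <- draws$trl; seeds <- draws$seeds
  lapply(seq_len(n), function(i) {
    s <- spec
    s$csa_scale <- spec$csa_scale * (1 + scale_dev[i]) * (tiv[i] / spec$tiv_ml)
    s$t2_tissue <- spec$t2_tissue + t2_dev[i]
    s$tiv_ml <- tiv[i]
    s$pose <- list(angles_deg = ang[i, ], translation = trl[i, ])
    s$seed <- seeds[i]
    if (images) make_phantom_subject(s, with_t1 = with_t1) else s
  })
}

#' Simulate a cohort of profiles directly (no images)
#'
#' Draws profiles on a fixed 1-mm grid from a Gaussian generative model:
#' `v_i(x) = scale_i * mu0(x) + e_i(x)`, `scale_i ~ N(1, scale_sd^2)`,
#' `e_i(x) ~ N(0, noise_sd(x)^2)` independent across positions. Used for
#' statistical validation of the normative machinery where the imaging path
#' is not under test.
#'
#' @param n number of profiles.
#' @param positions grid positions (mm).
#' @param mu0 baseline mean: function of position or numeric vector.
#' @param noise_sd pointwise noise sd: scalar, vector, or function of
#'   position.
#' @param scale_sd sd of the per-subject multiplicative scale (default 0).
#' @param modality,side profile labels.
#' @param seed integer seed.
#' @return A list of [profile objects][new_profile].
#' @export
simulate_profile_cohort <- function(n, positions, mu0, noise_sd = 0,
                                    scale_sd = 0, modality = "CSA",
                                    side = "left", seed = 1L) {
  mu <- if (is.function(mu0)) mu0(positions) else rep_len(mu0, length(positions))
  sdv <- if (is.function(noise_sd)) noise_sd(positions)
         else rep_len(noise_sd, length(positions))
  with_local_seed(as.integer(seed), {
    scales <- 1 + rnorm(n, 0, scale_sd)
    lapply(seq_len(n), function(i) {
      new_profile(positions, scales[i] * mu + rnorm(length(mu), 0, sdv),
                  modality = modality, side = side,
                  subject = sprintf("sim%03d", i),
                  sampling = "continuous-1mm")
    })
  })
}
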