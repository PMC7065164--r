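# Intensity-based rigid/affine registration (normalized cross-correlation,
# multi-resolution Nelder-Mead) with optional cost-function masking, plus
# iterative groupwise template construction. Nonlinear refinement is a
# pluggable interface; the default pipeline is affine-only.

# block-mean decimation along one axis (axis put first, then reshaped)
axis_decimate <- function(arr, f, axis) {
  d <- dim(arr)
  n2 <- d[axis] %/% f
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  a <- a[seq_len(n2 * f), , , drop = FALSE]
  dim(a) <- c(f, n2 * prod(d[-axis]))
  a <- colMeans(a)
  dim(a) <- c(n2, d[perm[2]], d[perm[3]])
  aperm(a, order(perm))
}

# antialiased (block-mean) downsample of a volume by integer factor f
downsample_volume <- function(volume, f) {
  if (f <= 1) return(volume)
  dat <- volume$data
  for (ax in 1:3) dat <- axis_decimate(dat, f, ax)
  aff <- volume$affine
  aff[1:3, 4] <- as.numeric(voxel_to_world(aff, matrix((f - 1) / 2, 1, 3)))
  aff[1:3, 1:3] <- aff[1:3, 1:3] * f
  image_volume(dat, aff, volume$modality)
}

#' Register one volume to another (rigid or affine)
#'
#' Maximizes normalized cross-correlation between the fixed volume and the
#' transformed moving volume over a rigid (6-parameter) or full affine
#' (12-parameter: rotation, translation, log-scales, shears)
#' parameterization, using gradient-free Nelder-Mead at a coarse-to-fine
#' series of resolutions. When `exclusion_mask` is given, the similarity is
#' evaluated only outside it (cost-function masking), so pathology inside
#' the masked structure cannot bias the alignment.
#'
#' @param moving,fixed `image_volume`s; the result maps moving world onto
#'   fixed world.
#' @param kind `"rigid"` or `"affine"`.
#' @param exclusion_mask optional [segmentation()] on the fixed grid whose
#'   voxels are excluded from the similarity.
#' @param levels integer downsampling factors, coarse to fine (default
#'   `c(4, 2)`).
#' @param maxit Nelder-Mead iteration budget per level.
#' @param init optional initial parameter vector (from a previous stage).
#' @return List with `transform` (a `world_transform`), `similarity`
#'   (final NCC) and `params`.
#' @export
register_volumes <- function(moving, fixed, kind = c("rigid", "affine"),
                             exclusion_mask = NULL, levels = c(4, 2),
                             maxit = 300, init = NULL) {
  kind <- match.arg(kind)
  npar <- if (kind == "rigid") 6L else 12L
  p <- numeric(npar)
  if (!is.null(init)) p[seq_along(init)] <- init
  centre <- as.numeric(
    voxel_to_world(fixed$affine, matrix((dim(fixed$data) - 1) / 2, 1)))
  parscale <- c(1, 1, 1, 1, 1, 1, 0.05, 0.05, 0.05, 0.02, 0.02, 0.02)[1:npar]
  sim <- NA_real_
  for (f in levels) {
    fx <- downsample_volume(fixed, f)
    use <- rep(TRUE, length(fx$data))
    if (!is.null(exclusion_mask)) {
      ex <- downsample_volume(exclusion_mask, f)
      use <- as.logical(ex$data < 0.5)
    }
    fixed_vals <- as.numeric(fx$data)
    cost <- function(q) {
      tm <- params_to_affine(q, centre)
      m <- solve(moving$affine) %*% solve(tm) %*% fx$affine
      w <- resample_core(as.numeric(moving$data), dim(moving$data), m,
                         dim(fx$data), 1L, NA_real_)
      v <- ncc_masked(fixed_vals, as.numeric(w), use)
      if (!is.finite(v)) return(1e3)
      -v
    }
    opt <- stats::optim(p, cost, method = "Nelder-Mead",
                        control = list(maxit = maxit,
                                       parscale = parscale,
                                       reltol = 1e-8))
    p <- opt$par
    sim <- -opt$value
  }
  tr <- world_transform(params_to_affine(p, centre),
                        if (kind == "rigid") "rigid" else "affine")
  list(transform = tr, similarity = sim, params = p)
}

#' Register a subject to the template
#'
#' Rigid, then full affine registration (the affine warm-started from the
#' rigid solution), with the similarity evaluated only outside the
#' template-space hippocampal exclusion mask, followed by an optional
#' nonlinear plug-in. The plug-in, when supplied, is called as
#' `nonlinear(moving, fixed, exclusion_mask, affine_transform)` and must
#' return a list with `forward` and `inverse` transform objects; no default
#' implementation is provided and the standard pipeline is affine-only.
#'
#' @param subject_t1 the subject volume.
#' @param template the group template volume.
#' @param exclusion_mask optional hippocampus [segmentation()] in template
#'   space (cost-function masking).
#' @param nonlinear optional plug-in function (see above).
#' @param min_similarity registration-quality error threshold on the final
#'   NCC (default 0.1).
#' @param levels,maxit passed to [register_volumes()].
#' @return List with `forward` and `inverse` `world_transform`s,
#'   `similarity`, and `nonlinear` (plug-in result or `NULL`).
#' @export
register_subject <- function(subject_t1, template, exclusion_mask = NULL,
                             nonlinear = NULL, min_similarity = 0.1,
                             levels = c(4, 2), maxit = 300) {
  rig <- register_volumes(subject_t1, template, "rigid", exclusion_mask,
                          levels, maxit)
  aff <- register_volumes(subject_t1, template, "affine", exclusion_mask,
                          levels, maxit, init = rig$params)
  if (!is.finite(aff$similarity) || aff$similarity < min_similarity) {
    stop(sprintf(
      "registration-quality error: final similarity %.3f below %.3f",
      aff$similarity, min_similarity), call. = FALSE)
  }
  nl <- NULL
  if (!is.null(nonlinear)) {
    nl <- nonlinear(subject_t1, template, exclusion_mask, aff$transform)
  }
  list(forward = aff$transform, inverse = invert_transform(aff$transform),
       similarity = aff$similarity, nonlinear = nl)
}

#' Iterative groupwise template construction
#'
#' Builds a population template by iterated registration and averaging: the
#' initial template is the voxelwise mean of the inputs on the first
#' subject's grid; at each of `n_affine` iterations every subject is
#' affinely registered to the current template (warm-started from the
#' previous iteration), resampled, and the template re-averaged. A
#' nonlinear plug-in, when given, is applied after the affine iterations.
#' If the mean similarity decreases on two consecutive iterations the
#' best-so-far template is returned with a convergence warning.
#'
#' @param t1s list of at least two `image_volume`s.
#' @param n_affine number of affine iterations (default 10).
#' @param nonlinear optional plug-in, as in [register_subject()].
#' @param levels,maxit passed to [register_volumes()].
#' @return List with `template` (an `image_volume`), `transforms` (per
#'   subject, subject world to template world), and `similarity` (mean NCC
#'   per iteration).
#' @export
build_group_template <- function(t1s, n_affine = 10, nonlinear = NULL,
                                 levels = c(4, 2), maxit = 300) {
  n <- length(t1s)
  if (n < 2) stop("precondition error: need >= 2 subjects", call. = FALSE)
  ref <- t1s[[1]]
  avg_on_ref <- function(vols, trs) {
    acc <- array(0, dim(ref$data))
    for (i in seq_len(n)) {
      acc <- acc + resample(vols[[i]], trs[[i]], ref, "linear", fill = 0)$data
    }
    image_volume(acc / n, ref$affine, ref$modality)
  }
  trs <- replicate(n, identity_transform(), simplify = FALSE)
  params <- vector("list", n)
  template <- avg_on_ref(t1s, trs)
  sims <- numeric(0)
  best <- list(template = template, transforms = trs, sim = -Inf)
  declines <- 0L
  for (it in seq_len(n_affine)) {
    sim_it <- numeric(n)
    for (i in seq_len(n)) {
      r <- register_volumes(t1s[[i]], template, "affine",
                            levels = levels, maxit = maxit,
                            init = params[[i]])
      trs[[i]] <- r$transform
      params[[i]] <- r$params
      sim_it[i] <- r$similarity
    }
    template <- avg_on_ref(t1s, trs)
    sims <- c(sims, mean(sim_it))
    if (mean(sim_it) > best$sim) {
      best <- list(template = template, transforms = trs,
                   sim = mean(sim_it))
      declines <- 0L
    } else {
      declines <- declines + 1L
      if (declines >= 2L) {
        warning("convergence warning: similarity decreased on two ",
                "consecutive iterations; returning best-so-far template")
        return(list(template = best$template, transforms = best$transforms,
                    similarity = sims))
      }
    }
  }
  if (!is.null(nonlinear)) {
    for (i in seq_len(n)) {
      nl <- nonlinear(t1s[[i]], template, NULL, trs[[i]])
      trs[[i]] <- nl$forward
    }
    template <- avg_on_ref(t1s, trs)
  }
  list(template = template, transforms = trs, similarity = sims)
}
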