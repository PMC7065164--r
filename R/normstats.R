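# Normative modelling along the AP axis: kernel-weighted local mean/sd
# curves, individual abnormality flagging against the mu +/- 1.96 sigma
# band, pointwise Bonferroni-corrected group tests, scan-rescan variability
# and per-point abnormality percentages.

# Kernel-weighted local-linear statistics of pooled samples (x, v) on a
# grid: at each grid point, Gaussian weights w = exp(-(x-g)^2 / (2 h^2)),
# mu from the weighted linear fit in (x - g), sigma from the reliability-
# weighted sd of its residuals. Where the kernel support has no x spread
# (e.g. h -> 0 on identical grids) the fit falls back to the local constant,
# so the estimator degenerates to the per-point sample mean and sd.
kernel_local_stats <- function(x, v, grid, bandwidth) {
  W <- exp(-0.5 * (outer(grid, x, "-") / bandwidth)^2)
  W[W < 1e-12] <- 0
  D <- -outer(grid, x, "-") # d_i = x_i - g
  sw <- rowSums(W)
  sd_ <- rowSums(W * D)
  sdd <- rowSums(W * D^2)
  sv <- as.numeric(W %*% v)
  sdv <- as.numeric((W * D) %*% v)
  svv <- as.numeric(W %*% v^2)
  det <- sw * sdd - sd_^2
  spread_ok <- det / pmax(sw^2, .Machine$double.eps) > 1e-9
  slope <- ifelse(spread_ok, (sw * sdv - sd_ * sv) / ifelse(det > 0, det, 1),
                  0)
  mu <- (sv - slope * sd_) / sw
  rss <- svv - 2 * mu * sv - 2 * slope * sdv + mu^2 * sw +
    2 * mu * slope * sd_ + slope^2 * sdd
  denom <- sw - rowSums(W^2) / sw
  sigma <- sqrt(pmax(rss, 0) / pmax(denom, .Machine$double.eps))
  sigma[denom <= 0] <- 0
  list(mu = mu, sigma = sigma, n_eff = sw)
}

#' Build a normative model from control profiles
#'
#' At each point of a uniform 1-mm AP grid, the local mean and sd of all
#' pooled profile samples are computed with Gaussian kernel weights
#' `w = exp(-(x - g)^2 / (2 h^2))`: `mu` is the kernel-weighted local-linear
#' estimate and `sigma` the reliability-weighted sd of its residuals, so a
#' cohort of identical profiles has `sigma = 0` wherever the profile is
#' locally linear, and the estimator degenerates to the per-point sample
#' mean/sd as `h -> 0` on identical-grid data. The normal range is
#' `mu +/- z sigma` with `z = 1.96`. Grid points whose effective support
#' (sum of kernel weights) falls below `min_support` are truncated with a
#' warning.
#'
#' @param profiles list of at least `min_profiles` [new_profile()]s of one
#'   side and modality.
#' @param bandwidth kernel bandwidth `h` in mm (default 2).
#' @param grid_step grid step in mm (default 1).
#' @param z normal-range multiplier (default 1.96).
#' @param min_support minimum effective support per grid point (default 10).
#' @param min_profiles minimum cohort size (default 10).
#' @return An object of class `normative_model`: `side`, `modality`,
#'   `grid`, `mu`, `sigma`, `n_eff`, `z`, `bandwidth`.
#' @export
build_normative <- function(profiles, bandwidth = 2, grid_step = 1,
                            z = 1.96, min_support = 10, min_profiles = 10) {
  if (length(profiles) < min_profiles) {
    stop(sprintf("precondition error: need >= %d profiles", min_profiles),
         call. = FALSE)
  }
  side <- unique(vapply(profiles, `[[`, character(1), "side"))
  modality <- unique(vapply(profiles, `[[`, character(1), "modality"))
  if (length(side) != 1L || length(modality) != 1L) {
    stop("profiles must share one side and one modality", call. = FALSE)
  }
  x <- unlist(lapply(profiles, `[[`, "positions"))
  v <- unlist(lapply(profiles, `[[`, "values"))
  grid <- seq(ceiling(min(x) / grid_step) * grid_step,
              floor(max(x) / grid_step) * grid_step, by = grid_step)
  st <- kernel_local_stats(x, v, grid, bandwidth)
  mu <- st$mu; sigma <- st$sigma; sw <- st$n_eff
  keep <- sw >= min_support
  if (!all(keep)) {
    warning(sprintf(
      "support truncated: %d of %d grid points below minimum effective support",
      sum(!keep), length(grid)))
  }
  if (!any(keep)) {
    stop("empty-input error: no grid point reaches the minimum support",
         call. = FALSE)
  }
  structure(list(side = side, modality = modality,
                 grid = grid[keep], mu = mu[keep], sigma = sigma[keep],
                 n_eff = sw[keep], z = z, bandwidth = bandwidth),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf(
    "<normative_model %s %s> AP %.0f-%.0f mm, band mu +/- %.2f sigma (h = %g mm)\n",
    x$modality, x$side, min(x$grid), max(x$grid), x$z, x$bandwidth))
  invisible(x)
}

# model mu/sigma linearly interpolated at arbitrary positions
model_at <- function(model, at) {
  list(mu = approx(model$grid, model$mu, xout = at, rule = 1)$y,
       sigma = approx(model$grid, model$sigma, xout = at, rule = 1)$y)
}

#' Compare an individual profile to the normative model
#'
#' One-sided flags per the clinical reading of hippocampal sclerosis: a CSA
#' point is atrophic when it falls below `mu - z sigma`; a qT2 point is
#' elevated when it exceeds `mu + z sigma`. Continuous CSA profiles are
#' compared at every model grid point; discrete qT2 profiles at their own
#' slice positions against the model interpolated there.
#'
#' @param profile a [new_profile()] of the model's side and modality.
#' @param model a [build_normative()] model.
#' @return An `abnormality_report`: data frame (`position`, `value`, `mu`,
#'   `sigma`, `flag`) with attributes `fraction_abnormal`, `direction`,
#'   `modality`, `side`.
#' @export
compare_individual <- function(profile, model) {
  if (profile$modality != model$modality || profile$side != model$side) {
    stop("profile and model must share side and modality", call. = FALSE)
  }
  if (profile$sampling == "continuous-1mm") {
    at <- model$grid
    val <- profile_at(profile, at)
  } else {
    at <- profile$positions
    val <- profile$values
  }
  ms <- model_at(model, at)
  ok <- !is.na(val) & !is.na(ms$mu)
  if (!any(ok)) {
    stop("empty-input error: profile and model supports do not overlap",
         call. = FALSE)
  }
  direction <- if (model$modality == "CSA") "low" else "high"
  flag <- rep(NA, length(at))
  flag[ok] <- if (direction == "low") {
    val[ok] < ms$mu[ok] - model$z * ms$sigma[ok]
  } else {
    val[ok] > ms$mu[ok] + model$z * ms$sigma[ok]
  }
  rep_df <- data.frame(position = at, value = val, mu = ms$mu,
                       sigma = ms$sigma, flag = flag)
  rep_df <- rep_df[ok, ]
  structure(rep_df,
            fraction_abnormal = mean(rep_df$flag),
            direction = direction, modality = model$modality,
            side = model$side, subject = profile$subject,
            class = c("abnormality_report", "data.frame"))
}

#' Flag a whole-hippocampus scalar against control values
#'
#' @param value subject scalar (e.g. TIV-corrected volume in mL or whole
#'   qT2 in ms).
#' @param control_values control cohort scalars.
#' @param direction `"low"` (atrophy) or `"high"` (T2 elevation).
#' @param z normal-range multiplier (default 1.96).
#' @return List with `flag`, `range` (the normal range), `mean`, `sd`.
#' @export
compare_whole <- function(value, control_values, direction = c("low", "high"),
                          z = 1.96) {
  direction <- match.arg(direction)
  m <- mean(control_values)
  s <- sd(control_values)
  rng <- c(m - z * s, m + z * s)
  flag <- if (direction == "low") value < rng[1] else value > rng[2]
  list(flag = flag, range = rng, mean = m, sd = s)
}

# interpolate a list of profiles onto one grid -> matrix (profiles x points)
profiles_to_matrix <- function(profiles, grid) {
  do.call(rbind, lapply(profiles, profile_at, at = grid))
}

#' Pointwise two-sample comparison of patient and control profiles
#'
#' All profiles are linearly interpolated onto a common 1-mm grid (the
#' overlap of the two groups' supports); at each point a Welch two-sample
#' two-sided t-test compares the groups, and significance is declared at
#' `p < alpha / m` with `m` the number of points actually tested
#' (Bonferroni). Points where either group has fewer than two values are
#' skipped and recorded.
#'
#' @param controls,patients lists of [new_profile()]s.
#' @param alpha familywise level (default 0.01).
#' @param grid_step grid step in mm.
#' @return A data frame (`position`, `n_control`, `n_patient`, `t`, `p`,
#'   `flag`) with attributes `fraction_significant`, `m_tested`, `alpha`.
#' @export
group_pointwise_test <- function(controls, patients, alpha = 0.01,
                                 grid_step = 1) {
  rng <- function(ps) range(unlist(lapply(ps, `[[`, "positions")))
  r <- c(max(rng(controls)[1], rng(patients)[1]),
         min(rng(controls)[2], rng(patients)[2]))
  if (r[1] >= r[2]) stop("empty-input error: no common support", call. = FALSE)
  grid <- seq(ceiling(r[1] / grid_step) * grid_step,
              floor(r[2] / grid_step) * grid_step, by = grid_step)
  mc <- profiles_to_matrix(controls, grid)
  mp <- profiles_to_matrix(patients, grid)
  res <- lapply(seq_along(grid), function(i) {
    a <- mc[, i][!is.na(mc[, i])]
    b <- mp[, i][!is.na(mp[, i])]
    if (length(a) < 2 || length(b) < 2 || (sd(a) == 0 && sd(b) == 0)) {
      return(data.frame(position = grid[i], n_control = length(a),
                        n_patient = length(b), t = NA_real_, p = NA_real_))
    }
    tt <- t.test(b, a, var.equal = FALSE)
    data.frame(position = grid[i], n_control = length(a),
               n_patient = length(b), t = unname(tt$statistic),
               p = tt$p.value)
  })
  out <- do.call(rbind, res)
  m <- sum(!is.na(out$p))
  out$flag <- !is.na(out$p) & out$p < alpha / m
  structure(out,
            fraction_significant = mean(out$flag[!is.na(out$p)]),
            m_tested = m, alpha = alpha,
            class = c("pointwise_test", "data.frame"))
}

#' Regional two-sample comparison with Bonferroni over the three regions
#'
#' Welch t-tests of a regional metric (volume or qT2) between patients and
#' controls in tail, body and head, at level `alpha / 3`.
#'
#' @param control_values,patient_values numeric matrices or data frames with
#'   columns `tail`, `body`, `head` (one row per subject).
#' @param alpha familywise level (default 0.01).
#' @return Data frame with `region`, `t`, `p`, `flag` (significant at
#'   `alpha / 3`).
#' @export
group_region_test <- function(control_values, patient_values, alpha = 0.01) {
  regions <- c("tail", "body", "head")
  res <- lapply(regions, function(r) {
    a <- control_values[, r][!is.na(control_values[, r])]
    b <- patient_values[, r][!is.na(patient_values[, r])]
    tt <- t.test(b, a, var.equal = FALSE)
    data.frame(region = r, t = unname(tt$statistic), p = tt$p.value,
               flag = tt$p.value < alpha / length(regions))
  })
  do.call(rbind, res)
}

#' Group-average profile with normative-style band
#'
#' Applies the same kernel machinery as [build_normative()] to a patient
#' group (e.g. left, right or bilateral disease groups), with a lower
#' minimum cohort size.
#'
#' @param group list of at least 2 profiles of one side/modality.
#' @param ... passed to [build_normative()] (`bandwidth`, `z`,
#'   `min_support`, ...).
#' @return A `normative_model` describing the group.
#' @export
group_average_profiles <- function(group, ...) {
  args <- list(...)
  if (is.null(args$min_profiles)) args$min_profiles <- 2
  if (is.null(args$min_support)) args$min_support <- 2
  do.call(build_normative, c(list(profiles = group), args))
}

#' Scan-rescan variability of profiles
#'
#' Subtracts each subject's two profiles pointwise and applies the kernel
#' estimator to the pooled differences, yielding the per-point sd of
#' (scan1 - scan2); pairs are compared only on the overlap of their
#' supports.
#'
#' @param pairs list of `list(a, b)` profile pairs (>= 5 pairs).
#' @param bandwidth kernel bandwidth in mm (default 2).
#' @param grid_step grid step in mm.
#' @return Data frame with `position`, `sd_diff`, `n_eff`.
#' @export
scan_rescan_variability <- function(pairs, bandwidth = 2, grid_step = 1) {
  if (length(pairs) < 5) {
    stop("precondition error: need >= 5 scan-rescan pairs", call. = FALSE)
  }
  xs <- numeric(0); ds <- numeric(0)
  for (p in pairs) {
    lo <- max(min(p[[1]]$positions), min(p[[2]]$positions))
    hi <- min(max(p[[1]]$positions), max(p[[2]]$positions))
    if (lo > hi) next # mismatched supports: pair skipped
    at <- seq(ceiling(lo / grid_step) * grid_step,
              floor(hi / grid_step) * grid_step, by = grid_step)
    d <- profile_at(p[[1]], at) - profile_at(p[[2]], at)
    ok <- !is.na(d)
    xs <- c(xs, at[ok]); ds <- c(ds, d[ok])
  }
  if (!length(xs)) stop("empty-input error: no overlapping pairs",
                        call. = FALSE)
  grid <- seq(min(xs), max(xs), by = grid_step)
  st <- kernel_local_stats(xs, ds, grid, bandwidth)
  data.frame(position = grid, sd_diff = st$sigma, n_eff = st$n_eff)
}

#' Percentage of individuals abnormal at each AP point
#'
#' @param reports non-empty list of [compare_individual()] reports sharing a
#'   grid.
#' @return Data frame with `position`, `n` (individuals with data),
#'   `n_flagged`, `fraction`.
#' @export
percent_abnormal <- function(reports) {
  if (!length(reports)) {
    stop("empty-input error: no abnormality reports", call. = FALSE)
  }
  pos <- sort(unique(unlist(lapply(reports, `[[`, "position"))))
  n <- integer(length(pos)); nf <- integer(length(pos))
  for (r in reports) {
    i <- match(r$position, pos)
    has <- !is.na(r$flag)
    n[i[has]] <- n[i[has]] + 1L
    nf[i[has]] <- nf[i[has]] + as.integer(r$flag[has])
  }
  data.frame(position = pos, n = n, n_flagged = nf,
             fraction = ifelse(n > 0, nf / n, NA_real_))
}
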