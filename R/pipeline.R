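# End-to-end orchestration: reorientation, template construction,
# registration, distance propagation, profiling, normative modelling and
# individual comparison, with optional on-disk outputs and a run manifest.

#' Pipeline configuration
#'
#' Bundles the tunable constants of the profiling pipeline. Defaults follow
#' the standard acquisition and analysis regime: echo times 30/119 ms, a
#' 1-mm profile grid, the mu +/- 1.96 sigma normal range, the 2 mm^2/mm
#' CSA-stability rule for the body, pointwise tests at alpha = 0.01 with
#' Bonferroni correction, and a 2-mm kernel bandwidth.
#'
#' @param te echo times (ms).
#' @param z normal-range multiplier.
#' @param grid_step profile grid step (mm).
#' @param slope_threshold body-stability rule (mm^2/mm).
#' @param alpha pointwise familywise level.
#' @param bandwidth normative kernel bandwidth (mm).
#' @param tiv_ref reference TIV (mL); `NULL` = control-cohort mean.
#' @param n_affine groupwise template iterations.
#' @param min_support minimum normative support per grid point.
#' @param min_profiles minimum control cohort size for the normative model.
#' @param pv_policy partial-volume policy for [masked_qt2()].
#' @param levels,maxit registration resolution schedule and iteration
#'   budget.
#' @param seed integer seed for any stochastic component.
#' @param out_dir optional output directory for CSV/JSON artefacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(te = c(30, 119), z = 1.96, grid_step = 1,
                            slope_threshold = 2, alpha = 0.01,
                            bandwidth = 2, tiv_ref = NULL, n_affine = 10,
                            min_support = 10, min_profiles = 10,
                            pv_policy = list(min_fraction = 0.99,
                                             min_voxels = 10),
                            levels = c(4, 2), maxit = 300,
                            seed = 1L, out_dir = NULL) {
  stopifnot(te[2] > te[1], te[1] > 0, z > 0, grid_step > 0,
            slope_threshold > 0, alpha > 0, bandwidth > 0)
  structure(list(te = te, z = z, grid_step = grid_step,
                 slope_threshold = slope_threshold, alpha = alpha,
                 bandwidth = bandwidth, tiv_ref = tiv_ref,
                 n_affine = n_affine, min_support = min_support,
                 min_profiles = min_profiles, pv_policy = pv_policy,
                 levels = levels, maxit = maxit, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

subject_tiv <- function(s) {
  if (!is.null(s$tiv)) s$tiv else s$truth$tiv_ml
}

# profiles + metrics for one subject. CSA is measured on the subject's
# coronal slices after rigid reorientation (masks resampled through
# `reorient`); qT2 stays on the native acquired coronal slices, with the
# distance map propagated through the full template-to-native transform.
profile_one_subject <- function(subject, reorient, to_template, dmap,
                                config, tiv_ref) {
  full_fwd <- compose_transforms(to_template, reorient)
  dprop_t1 <- NULL
  out <- list()
  qt2 <- fit_qt2(subject$echo1, subject$echo2, config$te[1], config$te[2])
  dprop_pd <- propagate_distance_map(dmap, invert_transform(full_fwd),
                                     subject$echo1)
  for (side in c("left", "right")) {
    seg <- subject[[paste0("mask_", side)]]
    seg_r <- resample(seg, reorient, seg, "linear")
    if (is.null(dprop_t1)) {
      dprop_t1 <- propagate_distance_map(dmap, invert_transform(to_template),
                                         seg_r)
    }
    tab <- slice_distance_table(dprop_t1, seg_r)
    csa <- csa_profile(seg_r, tab, tiv = subject_tiv(subject),
                       tiv_ref = tiv_ref, grid_step = config$grid_step)
    mq <- masked_qt2(qt2, seg, config$pv_policy)
    seg_pd <- resample(seg, identity_transform(), subject$echo1, "linear")
    tab_pd <- slice_distance_table(dprop_pd, seg_pd)
    qp <- qt2_profile(mq$slices, tab_pd, side)
    out[[side]] <- list(csa = csa, qt2 = qp, whole_qt2 = mq$mean_ms,
                        table = tab)
  }
  out
}

#' Run the full profiling pipeline
#'
#' Executes the five stages on in-memory subjects (e.g. phantom subjects or
#' volumes loaded with [load_volume()]): (1) long-axis reorientation and
#' groupwise template construction from the controls, (2) registration of
#' each scan to the template (cost-masked for patients) and AP distance
#' propagation, (3) the normative CSA/qT2 database, (4) patient group
#' averages, and (5) individual patient comparison against the normative
#' range. Each subject is a list with `t1`, `echo1`, `echo2`, `mask_left`,
#' `mask_right` and `tiv` (phantom subjects carry TIV in their truth).
#' A failing subject is skipped with a recorded error; remaining subjects
#' complete.
#'
#' @param controls list of control subjects (defines the normative data).
#' @param patients optional list of patient subjects.
#' @param config a [pipeline_config()].
#' @return A list with `template`, `distance_map`, `models` (per
#'   side/modality normative models), `partitions`, `control_profiles`,
#'   `control_metrics`, `patient_profiles`, `patient_reports`,
#'   `group_models`, `errors`, and `manifest`.
#' @export
run_pipeline <- function(controls, patients = list(),
                         config = pipeline_config()) {
  set.seed(config$seed)
  errors <- list()
  # stage 1: reorient and build template
  reo <- lapply(controls, function(s) {
    reorient_to_ap(s$t1, s$mask_left, s$mask_right)
  })
  reo_t1 <- lapply(seq_along(controls), function(i) {
    resample(controls[[i]]$t1, reo[[i]], controls[[i]]$t1, "linear",
             fill = 0)
  })
  tpl <- build_group_template(reo_t1, n_affine = config$n_affine,
                              levels = config$levels, maxit = config$maxit)
  # subject -> template: template transform after reorientation
  fwd <- lapply(seq_along(controls), function(i) {
    compose_transforms(tpl$transforms[[i]], reo[[i]])
  })
  dmap <- build_distance_map(tpl$template)
  tiv_ref <- config$tiv_ref %||%
    mean(vapply(controls, subject_tiv, numeric(1)))

  # stage 2-3: control profiles and normative models
  control_profiles <- vector("list", length(controls))
  for (i in seq_along(controls)) {
    control_profiles[[i]] <- tryCatch(
      profile_one_subject(controls[[i]], reo[[i]], tpl$transforms[[i]],
                          dmap, config, tiv_ref),
      error = function(e) {
        errors[[length(errors) + 1L]] <<-
          list(stage = "profile", subject = i, group = "control",
               message = conditionMessage(e))
        NULL
      })
  }
  ok <- !vapply(control_profiles, is.null, logical(1))
  control_profiles <- control_profiles[ok]
  models <- list()
  partitions <- list()
  for (side in c("left", "right")) {
    csa_list <- lapply(control_profiles, function(p) p[[side]]$csa)
    qt2_list <- lapply(control_profiles, function(p) p[[side]]$qt2)
    models[[paste0("csa_", side)]] <-
      build_normative(csa_list, bandwidth = config$bandwidth,
                      grid_step = config$grid_step, z = config$z,
                      min_support = config$min_support,
                      min_profiles = min(config$min_profiles,
                                         length(csa_list)))
    models[[paste0("qt2_", side)]] <-
      build_normative(qt2_list, bandwidth = config$bandwidth,
                      grid_step = config$grid_step, z = config$z,
                      min_support = config$min_support,
                      min_profiles = min(config$min_profiles,
                                         length(qt2_list)))
    partitions[[side]] <- partition_regions(models[[paste0("csa_", side)]],
                                            config$slope_threshold)
  }
  control_metrics <- lapply(control_profiles, function(p) {
    lapply(c(left = "left", right = "right"), function(side) {
      region_metrics(p[[side]]$csa, partitions[[side]], p[[side]]$qt2)
    })
  })

  # template-space hippocampal exclusion mask for patient registration
  excl <- NULL
  segs_tpl <- list()
  for (i in seq_along(controls)) {
    for (side in c("left", "right")) {
      segs_tpl[[length(segs_tpl) + 1L]] <-
        resample(controls[[i]][[paste0("mask_", side)]], fwd[[i]],
                 tpl$template, "nearest")
    }
  }
  if (length(segs_tpl)) excl <- majority_mask(segs_tpl)

  # stages 2, 4, 5 for patients
  patient_profiles <- list()
  patient_reports <- list()
  for (i in seq_along(patients)) {
    res <- tryCatch({
      s <- patients[[i]]
      r <- reorient_to_ap(s$t1, s$mask_left, s$mask_right)
      t1r <- resample(s$t1, r, s$t1, "linear", fill = 0)
      reg <- register_subject(t1r, tpl$template, exclusion_mask = excl,
                              levels = config$levels, maxit = config$maxit)
      prof <- profile_one_subject(s, r, reg$forward, dmap, config, tiv_ref)
      reports <- lapply(c(left = "left", right = "right"), function(side) {
        list(csa = compare_individual(prof[[side]]$csa,
                                      models[[paste0("csa_", side)]]),
             qt2 = compare_individual(prof[[side]]$qt2,
                                      models[[paste0("qt2_", side)]]))
      })
      list(profiles = prof, reports = reports)
    }, error = function(e) {
      errors[[length(errors) + 1L]] <<-
        list(stage = "patient", subject = i, group = "patient",
             message = conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      patient_profiles[[length(patient_profiles) + 1L]] <- res$profiles
      patient_reports[[length(patient_reports) + 1L]] <- res$reports
    }
  }
  group_models <- list()
  if (length(patient_profiles) >= 2) {
    for (side in c("left", "right")) {
      group_models[[paste0("csa_", side)]] <- group_average_profiles(
        lapply(patient_profiles, function(p) p[[side]]$csa),
        bandwidth = config$bandwidth, z = config$z)
    }
  }
  result <- list(template = tpl$template, distance_map = dmap,
                 transforms = fwd, models = models, partitions = partitions,
                 control_profiles = control_profiles,
                 control_metrics = control_metrics,
                 patient_profiles = patient_profiles,
                 patient_reports = patient_reports,
                 group_models = group_models, tiv_ref = tiv_ref,
                 errors = errors, config = config)
  if (!is.null(config$out_dir)) {
    result$manifest <- write_pipeline_outputs(result, config$out_dir)
  }
  result
}

#' Serialize a normative model to CSV (+ JSON header)
#'
#' @param model a `normative_model`.
#' @param path_csv output CSV path (`position_mm, mu, sigma, n_eff`).
#' @param path_json optional JSON header path (side, modality, z,
#'   bandwidth).
#' @return `path_csv`, invisibly.
#' @export
write_normative <- function(model, path_csv, path_json = NULL) {
  write.csv(data.frame(position_mm = model$grid, mu = model$mu,
                       sigma = model$sigma, n_eff = model$n_eff),
            path_csv, row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(list(side = model$side, modality = model$modality,
                              z = model$z, bandwidth = model$bandwidth),
                         path_json, auto_unbox = TRUE)
  }
  invisible(path_csv)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(result$models)) {
    write_normative(result$models[[nm]],
                    file.path(out_dir, paste0("normative_", nm, ".csv")),
                    file.path(out_dir, paste0("normative_", nm, ".json")))
  }
  prof_rows <- list()
  for (i in seq_along(result$control_profiles)) {
    for (side in c("left", "right")) {
      p <- result$control_profiles[[i]][[side]]$csa
      prof_rows[[length(prof_rows) + 1L]] <-
        data.frame(subject = i, side = side, position_mm = p$positions,
                   csa_mm2 = p$values)
    }
  }
  write.csv(do.call(rbind, prof_rows),
            file.path(out_dir, "control_csa_profiles.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    lapply(result$partitions, function(p) {
      list(tail_body_mm = p$tail_body, body_head_mm = p$body_head,
           lengths_mm = as.list(p$lengths))
    }),
    file.path(out_dir, "partitions.json"), auto_unbox = TRUE, digits = NA)
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    files = as.list(tools::md5sum(files)),
    config = result$config[setdiff(names(result$config), "out_dir")],
    n_controls = length(result$control_profiles),
    n_patients = length(result$patient_profiles))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Profile figure: subject profile over the normative band
#'
#' Renders the standard profile view: the normative band as a shaded
#' region, the continuous CSA profile as a line (or discrete qT2 values as
#' point markers), abnormal points highlighted, and the tail|body and
#' body|head transitions as vertical dotted lines. The x axis runs
#' posterior to anterior (P-A).
#'
#' @param profile a [new_profile()].
#' @param model the matching `normative_model`.
#' @param report optional [compare_individual()] report (flags the abnormal
#'   points).
#' @param partition optional [partition_regions()] result.
#' @return A `ggplot` object.
#' @export
plot_profile <- function(profile, model = NULL, report = NULL,
                         partition = NULL) {
  df <- data.frame(position = profile$positions, value = profile$values)
  ylab <- if (profile$modality == "CSA") "CSA (mm²)" else "qT2 (ms)"
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                        y = .data$value))
  if (!is.null(model)) {
    band <- data.frame(position = model$grid,
                       lo = model$mu - model$z * model$sigma,
                       hi = model$mu + model$z * model$sigma)
    g <- g + ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$position, ymin = .data$lo, ymax = .data$hi),
      inherit.aes = FALSE, fill = "steelblue", alpha = 0.3)
  }
  g <- if (profile$sampling == "continuous-1mm") {
    g + ggplot2::geom_line(linewidth = 0.7)
  } else {
    g + ggplot2::geom_point(shape = 4, size = 2)
  }
  if (!is.null(report) && any(report$flag, na.rm = TRUE)) {
    ab <- report[which(report$flag), ]
    g <- g + ggplot2::geom_point(
      data = data.frame(position = ab$position, value = ab$value),
      colour = "red", size = 1.5)
  }
  if (!is.null(partition)) {
    g <- g + ggplot2::geom_vline(
      xintercept = c(partition$tail_body, partition$body_head),
      linetype = "dotted")
  }
  g + ggplot2::labs(x = "P-A position (mm)", y = ylab,
                    title = sprintf("%s, %s hippocampus", profile$modality,
                                    profile$side)) +
    ggplot2::theme_minimal()
}

#' Render a profile figure to file
#'
#' @inheritParams plot_profile
#' @param file output path (`.png` / `.svg` / `.pdf`).
#' @param width,height figure size in inches.
#' @return `file`, invisibly.
#' @export
render_profile_figure <- function(profile, model = NULL, report = NULL,
                                  partition = NULL, file,
                                  width = 6, height = 4) {
  g <- plot_profile(profile, model, report, partition)
  ggplot2::ggsave(file, g, width = width, height = height, dpi = 150)
  invisible(file)
}
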