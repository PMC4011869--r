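#' Generate a longitudinal synthetic study
#'
#' Builds a full desk-scale study emulating the monitoring design: each
#' subject is a jittered copy of the mandible template, deformed to every
#' timepoint by the growth model (4-week intervals, T1..T12 by default).
#' Per-subject rate jitter, a small left-right asymmetry shear, and
#' measurement noise on the manual landmarks are drawn from the model's
#' seed, so the same model reproduces the identical study bit-for-bit.
#'
#' @param n_subjects Number of subjects (default 8).
#' @param n_timepoints Number of four-week timepoints (default 12).
#' @param model A [growth_model()].
#' @param out_dir Optional directory; when given, meshes (binary PLY),
#'   the ground-truth/manual landmark CSV and a JSON manifest are written.
#' @param overwrite Refuse to write into an existing non-empty `out_dir`
#'   unless TRUE.
#' @param resolution Template resolution (vertices), default 1800.
#' @return A `study_dataset`: list with `subjects`, `timepoints`, `meshes`
#'   (nested list `[[subject]][[t]]`), `truth` (landmark tibble,
#'   source `truth`), `manual` (noisy manual-code landmarks,
#'   source `manual`), `volumes_cm3` (tibble) and `manifest`.
#' @export
generate_study <- function(n_subjects = 8, n_timepoints = 12,
                           model = growth_model(),
                           out_dir = NULL, overwrite = FALSE,
                           resolution = 1800) {
  stopifnot(n_subjects >= 1, n_timepoints >= 2)
  if (!is.null(out_dir) && dir.exists(out_dir) &&
      length(list.files(out_dir)) > 0 && !overwrite)
    stop("output directory exists and is not empty; pass overwrite = TRUE")
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(model$seed)

  template <- generate_template_mesh(resolution = resolution)
  truth0 <- template_ground_truth(template)
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  meshes <- stats::setNames(vector("list", n_subjects), subjects)
  truth_all <- list(); manual_all <- list(); vol_rows <- list()
  for (si in seq_along(subjects)) {
    subj <- subjects[si]
    # per-subject template variant: size/rate jitter + small asymmetry shear
    size_fac <- exp(stats::rnorm(1, 0, 0.03))
    rate_scale <- c(ap = exp(stats::rnorm(1, 0, model$subject_sd)),
                    si = exp(stats::rnorm(1, 0, model$subject_sd)),
                    ml = exp(stats::rnorm(1, 0, model$subject_sd)))
    shear <- if (model$asymmetry_sd > 0)
      stats::rnorm(1, 0, model$asymmetry_sd) / max(abs(template$vertices[, 1])) else 0
    tmpl_s <- template
    tmpl_s$vertices <- tmpl_s$vertices * size_fac
    tmpl_s$vertices[, 2] <- tmpl_s$vertices[, 2] + shear * tmpl_s$vertices[, 1]
    lm_s <- truth0
    lm_xyz <- as.matrix(lm_s[, c("x_mm", "y_mm", "z_mm")]) * size_fac
    lm_xyz[, 2] <- lm_xyz[, 2] + shear * lm_xyz[, 1]
    lm_s$x_mm <- lm_xyz[, 1]; lm_s$y_mm <- lm_xyz[, 2]; lm_s$z_mm <- lm_xyz[, 3]
    attr(tmpl_s, "manual_anchors") <- attr(template, "manual_anchors")
    meshes[[subj]] <- vector("list", n_timepoints)
    for (t in seq_len(n_timepoints)) {
      g <- grow_mesh(tmpl_s, model, t, n_timepoints, landmarks = lm_s,
                     rate_scale = rate_scale)
      meshes[[subj]][[t]] <- g$mesh
      tr <- g$landmarks
      tr$subject <- subj; tr$timepoint <- t
      truth_all[[length(truth_all) + 1L]] <- tr
      man <- tr[tr$code %in% c("AMF", "MMF", "PMF", "NO"), ]
      if (model$noise_sd > 0) {
        jit <- matrix(stats::rnorm(3 * nrow(man), 0, model$noise_sd), ncol = 3)
        man$x_mm <- man$x_mm + jit[, 1]
        man$y_mm <- man$y_mm + jit[, 2]
        man$z_mm <- man$z_mm + jit[, 3]
      }
      man$source <- "manual"
      manual_all[[length(manual_all) + 1L]] <- man
      vol_rows[[length(vol_rows) + 1L]] <- tibble::tibble(
        subject = subj, timepoint = t, volume_cm3 = mesh_volume(g$mesh))
    }
  }
  truth <- dplyr::bind_rows(truth_all)
  manual <- dplyr::bind_rows(manual_all)
  volumes <- dplyr::bind_rows(vol_rows)
  cols <- c("subject", "timepoint", "code", "side", "x_mm", "y_mm", "z_mm", "source")
  truth <- truth[, cols]
  manual <- manual[, cols]
  manifest <- list(
    n_subjects = n_subjects, n_timepoints = n_timepoints,
    interval_weeks = 4, seed = model$seed,
    model = list(region_rates = model$region_rates,
                 rate_constant = model$rate_constant,
                 noise_sd = model$noise_sd,
                 asymmetry_sd = model$asymmetry_sd,
                 subject_sd = model$subject_sd),
    resolution = resolution, subjects = subjects
  )
  ds <- structure(list(subjects = subjects, timepoints = seq_len(n_timepoints),
                       meshes = meshes, truth = truth, manual = manual,
                       volumes_cm3 = volumes, manifest = manifest),
                  class = "study_dataset")
  if (!is.null(out_dir)) write_study(ds, out_dir)
  ds
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("study_dataset: %d subjects x %d timepoints (%d meshes), %d landmark rows\n",
              length(x$subjects), length(x$timepoints),
              length(x$subjects) * length(x$timepoints), nrow(x$truth)))
  invisible(x)
}

#' Write a study to disk
#'
#' Writes one binary PLY per subject-timepoint, `landmarks_truth.csv`,
#' `landmarks_manual.csv` and `manifest.json` into `out_dir`.
#'
#' @param study A `study_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (subj in study$subjects) for (t in study$timepoints) {
    fn <- sprintf("%s_T%02d.ply", subj, t)
    write_mesh(study$meshes[[subj]][[t]], file.path(out_dir, fn))
    files <- c(files, fn)
  }
  utils::write.csv(study$truth, file.path(out_dir, "landmarks_truth.csv"), row.names = FALSE)
  utils::write.csv(study$manual, file.path(out_dir, "landmarks_manual.csv"), row.names = FALSE)
  manifest <- c(study$manifest, list(mesh_files = files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
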