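# End-to-end pipeline: simulate -> landmarks -> measure -> growth -> stats.

pipeline_config_defaults <- function() {
  list(
    seed = 1L,
    n_subjects = 8L,
    n_timepoints = 12L,
    resolution = 1800L,
    noise_sd = 0,
    asymmetry_sd = 0,
    subject_sd = 0.04,
    rate_constant = 0.2,
    landmark_source = "auto",   # auto | truth
    side_select = "L",
    alpha = 0.05,
    make_plots = TRUE
  )
}

#' Build / validate a pipeline configuration
#'
#' Either pass options directly, or a YAML file with the same keys.
#' Unknown keys are rejected.
#'
#' @param ... Named options overriding the defaults (see
#'   `pipeline_config_defaults()`).
#' @param yaml_file Optional YAML file of options.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., yaml_file = NULL) {
  cfg <- pipeline_config_defaults()
  over <- list(...)
  if (!is.null(yaml_file)) {
    if (!file.exists(yaml_file)) stop("config file not found: ", yaml_file)
    over <- utils::modifyList(yaml::read_yaml(yaml_file), over)
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, over)
  stopifnot(cfg$n_subjects >= 1, cfg$n_timepoints >= 2,
            cfg$landmark_source %in% c("auto", "truth"),
            cfg$side_select %in% c("L", "R", "mean"),
            cfg$alpha > 0, cfg$alpha < 1)
  structure(cfg, class = "pipeline_config")
}

#' Run the full growth-analysis pipeline
#'
#' Simulates (or reuses) a study, detects landmarks on every mesh, measures
#' the parameter inventory, computes growth summaries and the
#' orientation-group statistics, and optionally writes a report bundle
#' (JSON stats + CSV tables + figures).
#'
#' @param config A [pipeline_config()].
#' @param study Optional pre-built `study_dataset` (skips simulation).
#' @param out_dir Optional report directory.
#' @return List with `study`, `measurements`, `summaries`, `groups`,
#'   `anova`, `volumes` and (if written) `files`.
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL,
                         out_dir = NULL) {
  t0 <- Sys.time()
  log_stage <- function(stage)
    message(sprintf("[mandigrow] %-10s %.1fs", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  if (is.null(study)) {
    model <- growth_model(noise_sd = config$noise_sd,
                          asymmetry_sd = config$asymmetry_sd,
                          subject_sd = config$subject_sd,
                          rate_constant = config$rate_constant,
                          seed = config$seed)
    study <- generate_study(config$n_subjects, config$n_timepoints, model,
                            resolution = config$resolution)
  }
  log_stage("simulate")
  measurements <- measure_study(study, landmark_source = config$landmark_source)
  log_stage("measure")
  summaries <- study_growth_summaries(measurements, side_select = config$side_select)
  groups <- group_summary(summaries)
  anova <- rm_anova_orientation(groups$by_subject, alpha = config$alpha)
  log_stage("stats")
  res <- list(study = study, measurements = measurements,
              summaries = summaries, groups = groups, anova = anova,
              volumes = study$volumes_cm3, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      measurements = file.path(out_dir, "measurements.csv"),
      summaries = file.path(out_dir, "growth_summaries.csv"),
      group_means = file.path(out_dir, "group_means.csv"),
      stats = file.path(out_dir, "stats_report.json")
    )
    utils::write.csv(measurements, files["measurements"], row.names = FALSE)
    utils::write.csv(summaries, files["summaries"], row.names = FALSE)
    utils::write.csv(groups$group_means, files["group_means"], row.names = FALSE)
    jsonlite::write_json(list(
      config = unclass(config),
      group_means = groups$group_means,
      subgroup_means = groups$subgroup_means,
      anova = list(F = anova$F, df = as.list(anova$df), p = anova$p,
                   gg_epsilon = anova$gg_epsilon, p_gg = anova$p_gg,
                   bonferroni_alpha = anova$bonferroni_alpha,
                   pairwise = anova$pairwise)
    ), files["stats"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (isTRUE(config$make_plots)) {
      plots <- pipeline_figures(res)
      for (nm in names(plots)) {
        fp <- file.path(out_dir, paste0(nm, ".pdf"))
        ggplot2::ggsave(fp, plots[[nm]], width = 8, height = 6)
        files[nm] <- fp
      }
    }
    res$files <- files
    log_stage("report")
  }
  res
}

#' Standard pipeline figures
#'
#' Builds the descriptive figures for a pipeline result: per-group
#' inter-marker distances over time, monthly changes, percent-of-change
#' curves, angles, and volume growth.
#'
#' @param result A [run_pipeline()] result.
#' @return Named list of ggplot objects.
#' @export
pipeline_figures <- function(result) {
  m <- result$measurements
  side <- result$config$side_select %||% "L"
  dist <- m[m$units == "cm" & m$side %in% c(side, "Bi"), ]
  dist_avg <- dplyr::summarise(
    dplyr::group_by(dist, .data$parameter, .data$group, .data$timepoint),
    value = mean(.data$value), .groups = "drop")
  p_dist <- ggplot2::ggplot(dist_avg,
      ggplot2::aes(x = .data$timepoint, y = .data$value,
                   colour = .data$parameter)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::labs(x = "timepoint (months)", y = "inter-marker distance (cm)") +
    ggplot2::theme_minimal() + ggplot2::theme(legend.position = "bottom")
  monthly <- dplyr::mutate(
    dplyr::arrange(dplyr::group_by(dist_avg, .data$parameter), .data$timepoint),
    change = .data$value - dplyr::lag(.data$value))
  p_monthly <- ggplot2::ggplot(monthly[!is.na(monthly$change), ],
      ggplot2::aes(x = .data$timepoint, y = .data$change,
                   colour = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "timepoint (months)", y = "monthly change (cm)") +
    ggplot2::theme_minimal() + ggplot2::theme(legend.position = "bottom")
  pct <- dplyr::mutate(dplyr::group_by(dist_avg, .data$parameter),
    pct = 100 * (.data$value - .data$value[.data$timepoint == 1]) /
      (.data$value[.data$timepoint == max(.data$timepoint)] -
       .data$value[.data$timepoint == 1]))
  p_pct <- ggplot2::ggplot(pct,
      ggplot2::aes(x = .data$timepoint, y = .data$pct,
                   colour = .data$parameter)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 50, linetype = 2) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "timepoint (months)", y = "percent of total change (%)") +
    ggplot2::theme_minimal() + ggplot2::theme(legend.position = "bottom")
  ang <- m[m$units == "deg" & m$side %in% c("mean", "Bi"), ]
  ang_avg <- dplyr::summarise(
    dplyr::group_by(ang, .data$parameter, .data$timepoint),
    value = mean(.data$value), .groups = "drop")
  p_ang <- ggplot2::ggplot(ang_avg,
      ggplot2::aes(x = .data$timepoint, y = .data$value,
                   colour = .data$parameter)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "timepoint (months)", y = "inter-segmental angle (deg)") +
    ggplot2::theme_minimal()
  vol_avg <- dplyr::summarise(
    dplyr::group_by(result$volumes, .data$timepoint),
    value = mean(.data$volume_cm3), .groups = "drop")
  p_vol <- ggplot2::ggplot(vol_avg,
      ggplot2::aes(x = .data$timepoint, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "timepoint (months)", y = "mandibular volume (cm^3)") +
    ggplot2::theme_minimal()
  list(fig_distances = p_dist, fig_monthly_change = p_monthly,
       fig_percent_change = p_pct, fig_angles = p_ang, fig_volume = p_vol)
}
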