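# Longitudinal growth summaries and the orientation-effect statistics.

#' Growth summary of one parameter series
#'
#' For a series v1..vT measured at monthly (4-week) intervals:
#' total change `delta = vT - v1`; normalized total change `N = delta / v1`
#' (scale-free); monthly changes `d_t = v_t - v_{t-1}`; percent-of-change
#' `p_t = 100 (v_t - v1) / delta` (cumulative growth as a percentage of the
#' total change); and the half-growth month, the first timepoint with
#' `p_t >= 50` (no interpolation).
#'
#' @param values Numeric vector v1..vT (T >= 2, no missing values).
#' @return List with `initial`, `final`, `total_change`,
#'   `normalized_total_change`, `monthly_change` (length T, NA at t = 1),
#'   `percent_of_change` (length T), `half_growth_month`, and
#'   `percent_defined` (FALSE when the total change is 0).
#' @export
growth_summary <- function(values) {
  v <- as.numeric(values)
  if (anyNA(v)) stop("missing timepoint in parameter series")
  Tn <- length(v)
  if (Tn < 2) stop("parameter series needs at least 2 timepoints")
  delta <- v[Tn] - v[1]
  if (v[1] <= 0) stop("initial value must be positive for normalized change")
  monthly <- c(NA_real_, diff(v))
  if (delta != 0) {
    pct <- 100 * (v - v[1]) / delta
    half <- which(pct >= 50)[1]
    list(initial = v[1], final = v[Tn], total_change = delta,
         normalized_total_change = delta / v[1],
         monthly_change = monthly, percent_of_change = pct,
         half_growth_month = half, percent_defined = TRUE)
  } else {
    list(initial = v[1], final = v[Tn], total_change = 0,
         normalized_total_change = 0,
         monthly_change = monthly, percent_of_change = rep(NA_real_, Tn),
         half_growth_month = NA_integer_, percent_defined = FALSE)
  }
}

#' Growth summaries for a measured study table
#'
#' Applies [growth_summary()] to every (subject, parameter, side) series of
#' a long measurement table.
#'
#' @param measurements Long tibble from [measure_study()].
#' @param side_select Side to analyse for unilateral parameters: `"L"`
#'   (default, matching per-side reporting), `"R"`, or `"mean"`.
#' @return Tibble with one row per subject x parameter: initial, final,
#'   total and normalized total change, half-growth month.
#' @export
study_growth_summaries <- function(measurements, side_select = "L") {
  keep <- measurements$side %in% c(side_select, "Bi")
  df <- measurements[keep, ]
  sp <- split(df, list(df$subject, df$parameter), drop = TRUE)
  rows <- lapply(sp, function(d) {
    d <- d[order(d$timepoint), ]
    if (any(duplicated(d$timepoint)))
      stop("duplicate timepoints for ", d$parameter[1])
    gs <- growth_summary(d$value)
    tibble::tibble(subject = d$subject[1], parameter = d$parameter[1],
                   group = d$group[1], subgroup = d$subgroup[1],
                   units = d$units[1],
                   initial = gs$initial, final = gs$final,
                   total_change = gs$total_change,
                   normalized_total_change = gs$normalized_total_change,
                   half_growth_month = gs$half_growth_month)
  })
  dplyr::bind_rows(rows)
}

#' Orientation-group means of normalized total change
#'
#' Per-subject group means (unweighted over the member parameters), then
#' the across-subject mean and SD per orientation group; nested AP
#' subgroups are summarised the same way when present.
#'
#' @param summaries Tibble from [study_growth_summaries()] (distance
#'   parameters only are used).
#' @return List with `by_subject` (subject x group means), `group_means`
#'   (group, mean, sd, n_parameters) and `subgroup_means`.
#' @export
group_summary <- function(summaries) {
  d <- summaries[summaries$group %in% c("AP", "SI", "AI", "ML"), ]
  if (nrow(d) == 0) stop("no distance parameters in any orientation group")
  by_subj <- dplyr::summarise(
    dplyr::group_by(d, .data$subject, .data$group),
    value = mean(.data$normalized_total_change), .groups = "drop")
  gm <- dplyr::summarise(
    dplyr::group_by(by_subj, .data$group),
    mean = mean(.data$value), sd = stats::sd(.data$value), .groups = "drop")
  npar <- dplyr::summarise(
    dplyr::group_by(d[!duplicated(paste(d$parameter)), ], .data$group),
    n_parameters = dplyr::n(), .groups = "drop")
  gm <- dplyr::left_join(gm, npar, by = "group")
  sg <- d[!is.na(d$subgroup), ]
  subgroup_means <- NULL
  if (nrow(sg)) {
    by_subj_sg <- dplyr::summarise(
      dplyr::group_by(sg, .data$subject, .data$subgroup),
      value = mean(.data$normalized_total_change), .groups = "drop")
    subgroup_means <- dplyr::summarise(
      dplyr::group_by(by_subj_sg, .data$subgroup),
      mean = mean(.data$value), sd = stats::sd(.data$value), .groups = "drop")
  }
  list(by_subject = by_subj, group_means = gm, subgroup_means = subgroup_means)
}

#' One-way repeated-measures ANOVA across orientation groups
#'
#' Tests the effect of orientation (AP, SI, ML, AI) on the per-subject
#' normalized total changes (subject-level group means) with a within-
#' subject one-way ANOVA. Reports the F statistic, degrees of freedom,
#' p value, the Greenhouse-Geisser sphericity correction, and — when the
#' orientation effect is significant at `alpha` — all pairwise paired
#' t-tests against the Bonferroni-corrected threshold `alpha / n_pairs`
#' (0.05 / 6 = 0.008333… for four groups).
#'
#' @param by_subject Tibble with columns `subject`, `group`, `value`
#'   (one value per subject per group), e.g. `group_summary()$by_subject`.
#' @param alpha Significance level for the omnibus test (default 0.05).
#' @return An `anova_report` list: `effect`, `F`, `df`, `p`,
#'   `gg_epsilon`, `p_gg`, `bonferroni_alpha`, `pairwise` (tibble).
#' @export
rm_anova_orientation <- function(by_subject, alpha = 0.05) {
  df <- as.data.frame(by_subject)
  need <- c("subject", "group", "value")
  if (!all(need %in% names(df))) stop("need columns subject, group, value")
  wide <- tidyr::pivot_wider(tibble::as_tibble(df[, need]),
                             names_from = "group", values_from = "value")
  if (anyNA(wide)) stop("missing cells: every subject needs one value per group")
  groups <- setdiff(names(wide), "subject")
  n <- nrow(wide); k <- length(groups)
  if (n < 3) stop("repeated-measures ANOVA needs at least 3 subjects")
  df$subject <- factor(df$subject)
  df$group <- factor(df$group)
  fit <- stats::aov(value ~ group + Error(subject / group), data = df)
  tab <- summary(fit)[["Error: subject:group"]][[1]]
  Fstat <- tab["group", "F value"]
  df1 <- tab["group", "Df"]
  df2 <- tab["Residuals", "Df"]
  p <- tab["group", "Pr(>F)"]
  # degenerate strata (e.g. all groups identical within every subject) can
  # leave aov with a 0/0 F or float-noise sums of squares
  Ym <- as.matrix(wide[, groups])
  ssg <- n * sum((colMeans(Ym) - mean(Ym))^2)
  ss_tot <- sum((Ym - mean(Ym))^2)
  if (ssg <= 1e-12 * max(ss_tot, 1e-300)) {
    Fstat <- 0; p <- 1
  } else if (!is.finite(Fstat)) {
    Fstat <- Inf; p <- 0
  }
  # Greenhouse-Geisser epsilon from the within-subject covariance matrix
  Y <- as.matrix(wide[, groups])
  S <- stats::cov(Y)
  C <- diag(k) - 1 / k
  Sc <- C %*% S %*% C
  eig_tr <- sum(diag(Sc))
  eps <- eig_tr^2 / ((k - 1) * sum(Sc^2))
  if (!is.finite(eps)) eps <- 1
  eps <- min(1, max(1 / (k - 1), eps))
  p_gg <- if (is.finite(Fstat)) stats::pf(Fstat, df1 * eps, df2 * eps, lower.tail = FALSE) else 0
  pairs <- utils::combn(groups, 2)
  n_pairs <- ncol(pairs)
  bonf <- alpha / n_pairs
  pairwise <- NULL
  if (!is.na(p) && p < alpha) {
    rows <- lapply(seq_len(n_pairs), function(j) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      tt <- stats::t.test(Y[, g1], Y[, g2], paired = TRUE)
      tibble::tibble(pair = paste0(g1, "-", g2),
                     t = unname(tt$statistic), p = tt$p.value,
                     bonferroni_alpha = bonf,
                     significant = tt$p.value < bonf)
    })
    pairwise <- dplyr::bind_rows(rows)
  }
  structure(list(effect = "orientation", F = unname(Fstat),
                 df = c(num = df1, den = df2), p = unname(p),
                 gg_epsilon = eps, p_gg = unname(p_gg),
                 alpha = alpha, bonferroni_alpha = bonf,
                 pairwise = pairwise),
            class = "anova_report")
}

#' @export
print.anova_report <- function(x, ...) {
  cat(sprintf("repeated-measures ANOVA (%s): F(%g, %g) = %.3f, p = %.4g\n",
              x$effect, x$df["num"], x$df["den"], x$F, x$p))
  cat(sprintf("  Greenhouse-Geisser epsilon = %.3f, corrected p = %.4g\n",
              x$gg_epsilon, x$p_gg))
  if (!is.null(x$pairwise)) {
    cat(sprintf("  pairwise paired t-tests (Bonferroni alpha = %.6f):\n",
                x$bonferroni_alpha))
    print(as.data.frame(x$pairwise), row.names = FALSE)
  } else {
    cat("  omnibus test not significant; pairwise comparisons not performed\n")
  }
  invisible(x)
}

#' Cumulative radiation dose budget
#'
#' @param per_scan_dose_uSv Equivalent (or effective) dose per scan in
#'   microsieverts.
#' @param n_scans Number of scans.
#' @return Cumulative dose in millisieverts.
#' @export
dose_budget <- function(per_scan_dose_uSv, n_scans) {
  stopifnot(per_scan_dose_uSv >= 0, n_scans >= 0)
  per_scan_dose_uSv * n_scans / 1000
}
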