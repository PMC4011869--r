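#' Anisotropic, saturating mandibular growth model
#'
#' Describes region- and direction-dependent growth over the monitoring
#' period. Each region carries a triple of unitless fractional total growth
#' rates along the anatomical axes (AP = x, SI = z, ML = y): a rate of 1.4
#' means that coordinate differences inside that region grow by 140% of
#' their initial value over the full period. The time course is a
#' saturating exponential `tau(t) = (1 - exp(-k (t-1))) / (1 - exp(-k (T-1)))`
#' with `tau(1) = 0` and `tau(T) = 1`; the default rate constant
#' `k = 0.2 / month` puts roughly half of the total change before month 4,
#' the fastest growth in the first months.
#'
#' Default rates emulate a growing miniature-pig mandible: ramus (and its
#' condylar/coronoid processes) growing faster than the body, superoinferior
#' and anteroposterior directions faster than mediolateral.
#'
#' @param region_rates Named list of regions (`anterior`, `body`, `ramus`,
#'   `condyle`, `coronoid`), each a named numeric `c(ap=, si=, ml=)` of
#'   non-negative fractional growth rates.
#' @param rate_constant Saturation rate constant, 1/month (default 0.2).
#' @param noise_sd Landmark measurement jitter SD in mm (default 0: noise-free).
#' @param asymmetry_sd Left-right perturbation scale in mm (default 0).
#' @param subject_sd Between-subject multiplicative jitter SD on all rates
#'   (default 0.04).
#' @param seed Integer seed; the model is fully deterministic given the seed.
#' @return An object of class `growth_model`.
#' @export
growth_model <- function(region_rates = default_region_rates(),
                         rate_constant = 0.2,
                         noise_sd = 0,
                         asymmetry_sd = 0,
                         subject_sd = 0.04,
                         seed = 1L) {
  stopifnot(rate_constant > 0, noise_sd >= 0, asymmetry_sd >= 0, subject_sd >= 0)
  for (r in region_rates) {
    if (!all(c("ap", "si", "ml") %in% names(r)))
      stop("each region rate needs named components ap, si, ml")
    if (any(unlist(r) < 0)) stop("growth rates must be non-negative")
  }
  structure(list(region_rates = region_rates, rate_constant = rate_constant,
                 noise_sd = noise_sd, asymmetry_sd = asymmetry_sd,
                 subject_sd = subject_sd, seed = as.integer(seed)),
            class = "growth_model")
}

#' @rdname growth_model
#' @export
default_region_rates <- function() {
  list(
    anterior = c(ap = 1.30, si = 1.05, ml = 0.45),
    body     = c(ap = 1.20, si = 1.05, ml = 0.55),
    ramus    = c(ap = 1.45, si = 1.42, ml = 0.80),
    condyle  = c(ap = 1.42, si = 1.40, ml = 0.75),
    coronoid = c(ap = 1.46, si = 1.44, ml = 0.75)
  )
}

#' Saturating growth time curve
#'
#' @param t Timepoint(s), 1..T.
#' @param n_timepoints Total number of timepoints T (default 12).
#' @param rate_constant Saturation rate constant in 1/month.
#' @return Fraction of total growth reached at `t`; 0 at t = 1, 1 at t = T,
#'   monotone non-decreasing.
#' @export
growth_time_curve <- function(t, n_timepoints = 12, rate_constant = 0.2) {
  stopifnot(all(t >= 1), all(t <= n_timepoints), n_timepoints >= 2)
  (1 - exp(-rate_constant * (t - 1))) / (1 - exp(-rate_constant * (n_timepoints - 1)))
}

# soft region weight fields evaluated at template coordinates.
# Regions overlap smoothly (logistic blends over bounding-box fractions) so
# the deformation field is crack-free; weights sum to 1 at every point.
region_weights <- function(points, bbox) {
  x <- points[, 1]; z <- points[, 3]
  dx <- bbox$xmax - bbox$xmin
  dz <- bbox$zmax - bbox$zmin
  ant <- logistic((x - (bbox$xmin + 0.72 * dx)) / (0.06 * dx))
  ram <- logistic(((bbox$xmin + 0.32 * dx) - x) / (0.06 * dx))
  body <- pmax(0, 1 - ant - ram)
  upper <- logistic((z - (bbox$zmin + 0.78 * dz)) / (0.05 * dz))
  post <- logistic(((bbox$xmin + 0.14 * dx) - x) / (0.04 * dx))
  condyle <- ram * upper * post
  coronoid <- ram * upper * (1 - post)
  ramus <- ram * (1 - upper)
  w <- cbind(anterior = ant, body = body, ramus = ramus,
             condyle = condyle, coronoid = coronoid)
  w / rowSums(w)
}

mesh_bbox <- function(points) {
  list(xmin = min(points[, 1]), xmax = max(points[, 1]),
       ymin = min(points[, 2]), ymax = max(points[, 2]),
       zmin = min(points[, 3]), zmax = max(points[, 3]))
}

# per-point per-axis growth factors 1 + tau * sum_r w_r(p) rate_r[axis]
growth_factors <- function(points, model, tau, bbox,
                           rate_scale = c(ap = 1, si = 1, ml = 1)) {
  w <- region_weights(points, bbox)
  regions <- colnames(w)
  R <- do.call(rbind, lapply(regions, function(r) model$region_rates[[r]][c("ap", "ml", "si")]))
  # column order: x = ap, y = ml, z = si
  R <- sweep(R, 2, c(rate_scale[["ap"]], rate_scale[["ml"]], rate_scale[["si"]]), "*")
  1 + tau * (w %*% R)
}

#' Deform the template to a later timepoint
#'
#' Applies the region- and direction-weighted coordinate scaling
#' `p' = p * (1 + tau(t) * s(p))` (per axis, about the origin) to the mesh
#' vertices and transports the ground-truth landmarks with exactly the same
#' deformation. With all region rates equal and isotropic this reduces to a
#' global similarity transform.
#'
#' @param template Template [triangle_mesh()] in the canonical frame
#'   (from [generate_template_mesh()]).
#' @param model A [growth_model()].
#' @param t Timepoint in 1..`n_timepoints` (t = 1 returns the template).
#' @param n_timepoints Total timepoints (default 12).
#' @param landmarks Ground-truth landmark table to transport (tibble with
#'   `x_mm,y_mm,z_mm`); defaults to the template's own ground truth from
#'   [template_ground_truth()].
#' @param rate_scale Optional per-axis multiplier on all rates (used for
#'   per-subject jitter).
#' @param rederive_gonion The gonion is a constructed landmark that
#'   migrates along the border under non-homogeneous growth, so each scan's
#'   true GO is the three-plane construction evaluated on that scan's
#'   noise-free surface (TRUE, default); the other 16 anatomically fixed
#'   points are transported exactly by the deformation.
#' @return List with `mesh` (deformed, watertight) and `landmarks`
#'   (ground-truth table at timepoint `t`).
#' @export
grow_mesh <- function(template, model, t, n_timepoints = 12,
                      landmarks = NULL, rate_scale = c(ap = 1, si = 1, ml = 1),
                      rederive_gonion = TRUE) {
  stopifnot(t >= 1, t <= n_timepoints)
  if (is.null(landmarks)) landmarks <- template_ground_truth(template)
  tau <- growth_time_curve(t, n_timepoints, model$rate_constant)
  bbox <- mesh_bbox(template$vertices)
  mesh <- template
  fac_v <- growth_factors(template$vertices, model, tau, bbox, rate_scale)
  mesh$vertices <- template$vertices * fac_v
  lm_xyz <- as.matrix(landmarks[, c("x_mm", "y_mm", "z_mm")])
  fac_l <- growth_factors(lm_xyz, model, tau, bbox, rate_scale)
  lm_new <- lm_xyz * fac_l
  landmarks$x_mm <- lm_new[, 1]
  landmarks$y_mm <- lm_new[, 2]
  landmarks$z_mm <- lm_new[, 3]
  if (!is_watertight(mesh))
    stop("grown mesh lost watertightness; deformation too aggressive")
  if (rederive_gonion && tau > 0 && any(landmarks$code == "GO")) {
    rois <- default_landmark_rois(mesh)
    for (s in c("L", "R")) {
      i <- which(landmarks$code == "GO" & landmarks$side == s)
      if (!length(i)) next
      go <- tryCatch(
        detect_gonion(mesh, rois[[paste0("ramus_border_", s)]],
                      rois[[paste0("corpus_border_", s)]], s),
        error = function(e) {
          warning("gonion construction failed on grown mesh (",
                  conditionMessage(e), "); keeping transported point")
          NULL
        })
      if (!is.null(go))
        landmarks[i, c("x_mm", "y_mm", "z_mm")] <-
          as.list(as.numeric(go[1, c("x_mm", "y_mm", "z_mm")]))
    }
  }
  list(mesh = mesh, landmarks = landmarks)
}
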