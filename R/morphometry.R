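# Morphometric parameter inventory and measurement.
#
# Twenty-five inter-marker distances in four orientation groups (AP
# anteroposterior, SI superoinferior, AI anteroinferior, ML mediolateral),
# two inter-segmental angles, and the bone volume. Distances are reported
# in cm, angles in degrees, volume in cm^3. The AP group carries nested
# subgroups (Mandible, Anterior (Body), Posterior (Ramus)) used for
# subgroup means.

#' Default segment catalog
#'
#' The standard inventory of distance and angle definitions. `side_rule`
#' is `same` (both endpoints on one side, measured per side), `bilateral`
#' (left code to right code, the `Bi-` pairs), or `midline` (midline GT to
#' a lateral code, per side). The two angles are LP-GO-AMF (vertex GO, per
#' side) and Bi-GO-GT (vertex GT, rays to left and right GO).
#'
#' @return List with tibbles `distances` (name, group, subgroup, code_a,
#'   code_b, side_rule) and `angles` (name, vertex code and the two ray
#'   codes with side rules).
#' @export
segment_catalog <- function() {
  d <- tibble::tribble(
    ~name,      ~group, ~subgroup,          ~code_a, ~code_b, ~side_rule,
    "AMF-GO",   "AP",   "Mandible",         "AMF",   "GO",    "same",
    "GO-PMF",   "AP",   "Mandible",         "GO",    "PMF",   "same",
    "NO-PMF",   "AP",   "Anterior (Body)",  "NO",    "PMF",   "same",
    "MMF-PMF",  "AP",   "Anterior (Body)",  "MMF",   "PMF",   "same",
    "AMF-MMF",  "AP",   "Anterior (Body)",  "AMF",   "MMF",   "same",
    "AMF-NO",   "AP",   "Anterior (Body)",  "AMF",   "NO",    "same",
    "CP-MP",    "AP",   "Posterior (Ramus)","CP",    "MP",    "same",
    "GO-NO",    "AP",   "Posterior (Ramus)","GO",    "NO",    "same",
    "CP-LP",    "AP",   "Posterior (Ramus)","CP",    "LP",    "same",
    "GO-CP",    "SI",   NA,                 "GO",    "CP",    "same",
    "GO-LP",    "SI",   NA,                 "GO",    "LP",    "same",
    "GO-MP",    "SI",   NA,                 "GO",    "MP",    "same",
    "GT-CP",    "AI",   NA,                 "GT",    "CP",    "midline",
    "GT-LP",    "AI",   NA,                 "GT",    "LP",    "midline",
    "AMF-CP",   "AI",   NA,                 "AMF",   "CP",    "same",
    "GT-MP",    "AI",   NA,                 "GT",    "MP",    "midline",
    "AMF-LP",   "AI",   NA,                 "AMF",   "LP",    "same",
    "AMF-MP",   "AI",   NA,                 "AMF",   "MP",    "same",
    "Bi-AMF",   "ML",   NA,                 "AMF",   "AMF",   "bilateral",
    "Bi-PMF",   "ML",   NA,                 "PMF",   "PMF",   "bilateral",
    "Bi-CP",    "ML",   NA,                 "CP",    "CP",    "bilateral",
    "Bi-MP",    "ML",   NA,                 "MP",    "MP",    "bilateral",
    "Bi-MMF",   "ML",   NA,                 "MMF",   "MMF",   "bilateral",
    "Bi-LP",    "ML",   NA,                 "LP",    "LP",    "bilateral",
    "Bi-GO",    "ML",   NA,                 "GO",    "GO",    "bilateral"
  )
  a <- tibble::tribble(
    ~name,        ~ray1, ~vertex, ~ray2, ~side_rule,
    "LP-GO-AMF",  "LP",  "GO",    "AMF", "same",      # vertex GO, per side
    "Bi-GO-GT",   "GO",  "GT",    "GO",  "bilateral"  # vertex GT, rays to L/R GO
  )
  list(distances = d, angles = a)
}

#' Inter-marker distance
#'
#' Euclidean distance between the two endpoints of a catalog definition,
#' after side-rule resolution, in cm.
#'
#' @param landmarks Landmark tibble for one subject-timepoint.
#' @param definition One row of `segment_catalog()$distances`.
#' @param side For `same`/`midline` rules, which side (`"L"` or `"R"`).
#' @return Distance in cm.
#' @export
inter_marker_distance <- function(landmarks, definition, side = "L") {
  ab <- resolve_endpoints(landmarks, definition, side)
  d <- sqrt(sum((ab$a - ab$b)^2)) / 10
  if (d == 0) warning(sprintf("degenerate zero distance for %s", definition$name))
  d
}

resolve_endpoints <- function(landmarks, definition, side) {
  rule <- definition$side_rule
  if (rule == "bilateral") {
    a <- landmark_xyz(landmarks, definition$code_a, "L")
    b <- landmark_xyz(landmarks, definition$code_b, "R")
  } else if (rule == "midline") {
    a <- landmark_xyz(landmarks, definition$code_a, "M")
    b <- landmark_xyz(landmarks, definition$code_b, side)
  } else {
    a <- landmark_xyz(landmarks, definition$code_a, side)
    b <- landmark_xyz(landmarks, definition$code_b, side)
  }
  list(a = a, b = b)
}

#' Inter-segmental angle
#'
#' Angle in degrees at the middle-listed vertex between the rays to the two
#' outer landmarks.
#'
#' @param landmarks Landmark tibble for one subject-timepoint.
#' @param definition One row of `segment_catalog()$angles`.
#' @param side For per-side angles, which side.
#' @return Angle in degrees, in (0, 180].
#' @export
inter_segment_angle <- function(landmarks, definition, side = "L") {
  if (definition$side_rule == "bilateral") {
    v <- landmark_xyz(landmarks, definition$vertex, "M")
    r1 <- landmark_xyz(landmarks, definition$ray1, "L")
    r2 <- landmark_xyz(landmarks, definition$ray2, "R")
  } else {
    v <- landmark_xyz(landmarks, definition$vertex, side)
    r1 <- landmark_xyz(landmarks, definition$ray1, side)
    r2 <- landmark_xyz(landmarks, definition$ray2, side)
  }
  u <- r1 - v; w <- r2 - v
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  if (nu < 1e-12 || nw < 1e-12)
    stop(sprintf("angle %s degenerate: a ray point coincides with the vertex",
                 definition$name))
  acos(min(1, max(-1, sum(u * w) / (nu * nw)))) * 180 / pi
}

#' Measure all catalog parameters for one subject-timepoint
#'
#' Computes every catalog distance (per-side L and R plus the side mean for
#' unilateral definitions; a single value for bilateral ones), both angles,
#' and the mesh volume. Output is long format.
#'
#' @param landmarks Complete 17-landmark tibble.
#' @param mesh Watertight [triangle_mesh()] (NULL to skip volume).
#' @param catalog Catalog from [segment_catalog()].
#' @return Tibble with columns `parameter`, `group`, `subgroup`, `side`,
#'   `value`, `units`.
#' @export
measure_all <- function(landmarks, mesh = NULL, catalog = segment_catalog()) {
  validate_landmark_set(landmarks)
  rows <- list()
  for (i in seq_len(nrow(catalog$distances))) {
    def <- catalog$distances[i, ]
    if (def$side_rule == "bilateral") {
      v <- tryCatch(inter_marker_distance(landmarks, def),
                    error = function(e) stop(def$name, ": ", conditionMessage(e)))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        parameter = def$name, group = def$group, subgroup = def$subgroup,
        side = "Bi", value = v, units = "cm")
    } else {
      vl <- inter_marker_distance(landmarks, def, "L")
      vr <- inter_marker_distance(landmarks, def, "R")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        parameter = def$name, group = def$group, subgroup = def$subgroup,
        side = c("L", "R", "mean"), value = c(vl, vr, (vl + vr) / 2),
        units = "cm")
    }
  }
  for (i in seq_len(nrow(catalog$angles))) {
    def <- catalog$angles[i, ]
    if (def$side_rule == "bilateral") {
      v <- inter_segment_angle(landmarks, def)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        parameter = def$name, group = "Angle", subgroup = NA_character_,
        side = "Bi", value = v, units = "deg")
    } else {
      vl <- inter_segment_angle(landmarks, def, "L")
      vr <- inter_segment_angle(landmarks, def, "R")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        parameter = def$name, group = "Angle", subgroup = NA_character_,
        side = c("L", "R", "mean"), value = c(vl, vr, (vl + vr) / 2),
        units = "deg")
    }
  }
  if (!is.null(mesh)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      parameter = "Volume", group = "Volume", subgroup = NA_character_,
      side = "Bi", value = mesh_volume(mesh), units = "cm3")
  }
  dplyr::bind_rows(rows)
}

#' Measure a whole study
#'
#' Runs landmark detection (or uses provided landmark tables) and
#' [measure_all()] on every subject-timepoint of a study.
#'
#' @param study A `study_dataset` from [generate_study()].
#' @param landmark_source `"auto"` runs the detectors on each mesh and
#'   merges the study's manual-code landmarks; `"truth"` uses the
#'   ground-truth tables directly (no detection).
#' @param catalog Catalog from [segment_catalog()].
#' @param volume Include mesh volume (default TRUE).
#' @return Long tibble with columns `subject`, `timepoint`, `parameter`,
#'   `group`, `subgroup`, `side`, `value`, `units`.
#' @export
measure_study <- function(study, landmark_source = c("auto", "truth"),
                          catalog = segment_catalog(), volume = TRUE) {
  landmark_source <- match.arg(landmark_source)
  out <- list()
  for (subj in study$subjects) for (t in study$timepoints) {
    mesh <- study$meshes[[subj]][[t]]
    lm <- if (landmark_source == "truth") {
      study$truth[study$truth$subject == subj & study$truth$timepoint == t, ]
    } else {
      auto <- detect_all_landmarks(mesh)
      man <- study$manual[study$manual$subject == subj & study$manual$timepoint == t, ]
      merge_landmarks(auto, man)
    }
    m <- measure_all(lm, if (volume) mesh else NULL, catalog)
    m$subject <- subj; m$timepoint <- t
    out[[length(out) + 1L]] <- m
  }
  res <- dplyr::bind_rows(out)
  res[, c("subject", "timepoint", "parameter", "group", "subgroup",
          "side", "value", "units")]
}
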