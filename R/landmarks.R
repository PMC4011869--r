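# Automatic anatomical landmark detection.
#
# Nine landmark codes are tracked (17 points: 8 bilateral codes + midline GT):
#   LP/MP  lateral/medial condylar poles  — extremal points in the condyle ROI
#   CP     coronoid process               — curvature maximum in the coronoid ROI
#   GT     genial tubercle                — posterior extremal on the lingual chin
#   GO     gonion                         — three-plane tangent construction
#   AMF/MMF/PMF/NO                        — manual (ingested from CSV)
# Coarse regions of interest stand in for the manual "gross position"
# pre-identification; precise rules then operate inside them.

LANDMARK_CODES <- c("LP", "MP", "CP", "GO", "AMF", "MMF", "PMF", "NO", "GT")
BILATERAL_CODES <- setdiff(LANDMARK_CODES, "GT")

landmark_row <- function(code, side, point, source) {
  tibble::tibble(code = code, side = side,
                 x_mm = point[1], y_mm = point[2], z_mm = point[3],
                 source = source)
}

#' Extract one landmark's coordinates from a landmark table
#'
#' @param landmarks Landmark tibble with columns `code`, `side`, `x_mm`,
#'   `y_mm`, `z_mm`.
#' @param code Landmark code (e.g. `"GO"`).
#' @param side `"L"`, `"R"` or `"M"`.
#' @return Numeric length-3 point (mm).
#' @export
landmark_xyz <- function(landmarks, code, side) {
  i <- which(landmarks$code == code & landmarks$side == side)
  if (length(i) == 0L)
    stop(sprintf("landmark (%s, %s) missing from set", code, side))
  if (length(i) > 1L)
    stop(sprintf("duplicate landmark (%s, %s)", code, side))
  as.numeric(landmarks[i, c("x_mm", "y_mm", "z_mm")])
}

#' Validate a complete 17-landmark set
#'
#' @param landmarks Landmark tibble.
#' @return Invisibly TRUE; errors describe what is missing or duplicated.
#' @export
validate_landmark_set <- function(landmarks) {
  want <- rbind(expand.grid(code = BILATERAL_CODES, side = c("L", "R"),
                            stringsAsFactors = FALSE),
                data.frame(code = "GT", side = "M"))
  have <- paste(landmarks$code, landmarks$side)
  dup <- have[duplicated(have)]
  if (length(dup)) stop("duplicate landmark entries: ", paste(unique(dup), collapse = ", "))
  miss <- setdiff(paste(want$code, want$side), have)
  if (length(miss)) stop("missing landmark entries: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Default procedural regions of interest
#'
#' ROIs are axis-aligned boxes in the canonical frame, expressed as
#' fractions of the mesh bounding box so they adapt to overall size. They
#' implement the coarse localisation that precedes the precise landmark
#' rules and can be overridden through the pipeline configuration.
#'
#' @param mesh A [triangle_mesh()] in the canonical frame.
#' @return Named list of [mesh_roi()]: `condyle_L/R`, `coronoid_L/R`, `gt`,
#'   `ramus_border_L/R`, `corpus_border_L/R`.
#' @export
default_landmark_rois <- function(mesh) {
  b <- mesh_bbox(mesh$vertices)
  dx <- b$xmax - b$xmin; dy <- b$ymax - b$ymin; dz <- b$zmax - b$zmin
  side_box <- function(side, ...) {
    lims <- list(...)
    if (side == "L") { lims$ymin <- 0.28 * b$ymax; lims$ymax <- Inf }
    else { lims$ymin <- -Inf; lims$ymax <- 0.28 * b$ymin }
    defaults <- list(xmin = -Inf, xmax = Inf, zmin = -Inf, zmax = Inf)
    mesh_roi(box = utils::modifyList(defaults, lims))
  }
  rois <- list()
  for (s in c("L", "R")) {
    rois[[paste0("condyle_", s)]] <- side_box(s,
      xmax = b$xmin + 0.18 * dx, zmin = b$zmax - 0.30 * dz)
    rois[[paste0("coronoid_", s)]] <- side_box(s,
      xmin = b$xmin + 0.18 * dx, xmax = b$xmin + 0.50 * dx,
      zmin = b$zmax - 0.35 * dz)
    rois[[paste0("ramus_border_", s)]] <- side_box(s,
      xmax = b$xmin + 0.10 * dx,
      zmin = b$zmin + 0.40 * dz, zmax = b$zmin + 0.72 * dz)
    rois[[paste0("corpus_border_", s)]] <- side_box(s,
      xmin = b$xmin + 0.45 * dx, xmax = b$xmin + 0.75 * dx,
      zmax = b$zmin + 0.12 * dz)
  }
  rois$gt <- mesh_roi(box = list(
    xmin = b$xmax - 0.40 * dx, xmax = Inf,
    ymin = -0.04 * dy, ymax = 0.04 * dy,
    zmin = -Inf, zmax = Inf))
  rois
}

#' Detect the condylar poles (LP, MP)
#'
#' LP is the most lateral point of the condyle (extremal along +y on the
#' left, -y on the right); MP the most medial point, extremal along the
#' opposite direction within the same ROI.
#'
#' @param mesh A [triangle_mesh()].
#' @param condyle_roi ROI isolating the condyle of this side.
#' @param side `"L"` or `"R"`.
#' @return Landmark tibble with rows LP and MP (source `auto`).
#' @export
detect_condyle_poles <- function(mesh, condyle_roi, side) {
  stopifnot(side %in% c("L", "R"))
  lateral <- if (side == "L") c(0, 1, 0) else c(0, -1, 0)
  lp <- extremal_point(mesh, lateral, condyle_roi)
  mp <- extremal_point(mesh, -lateral, condyle_roi)
  if (sum(lp$point * lateral) <= sum(mp$point * lateral))
    warning("condyle ROI degenerate: LP not strictly more lateral than MP")
  if (side == "L" && mp$point[2] < 0 || side == "R" && mp$point[2] > 0)
    warning("condyle ROI touches the midline; MP may be ambiguous")
  rbind(landmark_row("LP", side, lp$point, "auto"),
        landmark_row("MP", side, mp$point, "auto"))
}

#' Detect the coronoid process (CP)
#'
#' The vertex of maximal discrete Gaussian curvature within the coronoid
#' ROI (ties broken by lowest vertex index).
#'
#' @param mesh A [triangle_mesh()].
#' @param coronoid_roi ROI isolating the coronoid process of this side.
#' @param side `"L"` or `"R"`.
#' @param curvature Optional precomputed [discrete_curvature()] result.
#' @return Landmark tibble with one CP row.
#' @export
detect_coronoid_process <- function(mesh, coronoid_roi, side, curvature = NULL) {
  idx <- roi_indices(mesh, coronoid_roi)
  if (is.null(curvature)) curvature <- discrete_curvature(mesh)
  k <- curvature$curvature[idx]
  if (all(!is.finite(k)) || max(k, na.rm = TRUE) < 1e-6)
    stop("no protrusion in ROI: coronoid curvature maximum below tolerance")
  best <- idx[which(k >= max(k, na.rm = TRUE) - 1e-12)]
  i <- min(best)
  landmark_row("CP", side, mesh$vertices[i, ], "auto")
}

#' Detect the genial tubercle (GT)
#'
#' The most posterior (-x extremal) point within the lingual anterior
#' midline ROI; midline code (side `"M"`).
#'
#' @param mesh A [triangle_mesh()].
#' @param gt_roi ROI on the lingual anterior midline region.
#' @return Landmark tibble with one GT row.
#' @export
detect_genial_tubercle <- function(mesh, gt_roi) {
  p <- extremal_point(mesh, c(-1, 0, 0), gt_roi)
  landmark_row("GT", "M", p$point, "auto")
}

#' Detect the gonion (GO) by the three-plane construction
#'
#' A first plane is laid tangent to the posterior ramus border (outward
#' posterior), a second tangent to the inferior corpus border (outward
#' inferior). The plane bisecting their exterior (obtuse) wedge is
#' intersected with the surface; among intersection-curve points near the
#' gonial corner, GO is the one closest to the two planes' intersection
#' line (ties broken by lowest position along the curve).
#'
#' @param mesh A [triangle_mesh()].
#' @param ramus_border_roi ROI over the posterior ramus border (this side).
#' @param corpus_border_roi ROI over the inferior corpus border (this side).
#' @param side `"L"` or `"R"`.
#' @param neighborhood_mm Ring radius (mm) around the two ROIs within which
#'   intersection-curve points are considered; default 10% of the bounding
#'   box diagonal (scales with the growing mandible).
#' @param outward_posterior,outward_inferior Outward direction hints for the
#'   two support planes.
#' @return Landmark tibble with one GO row; attributes `planes` (list of
#'   the three planes) for inspection.
#' @export
detect_gonion <- function(mesh, ramus_border_roi, corpus_border_roi, side,
                          neighborhood_mm = NULL,
                          outward_posterior = c(-1, 0, 0),
                          outward_inferior = c(0, 0, -1)) {
  if (is.null(neighborhood_mm)) {
    ext <- apply(mesh$vertices, 2, function(x) diff(range(x)))
    neighborhood_mm <- 0.18 * sqrt(sum(ext^2))
  }
  plane_a <- support_plane(mesh, ramus_border_roi, outward_posterior)
  plane_b <- support_plane(mesh, corpus_border_roi, outward_inferior)
  plane_c <- bisecting_plane(plane_a, plane_b)
  line <- plane_intersection_line(plane_a, plane_b)
  polys <- plane_surface_intersection(mesh, plane_c)
  if (!length(polys)) stop("no gonial edge intersection: bisector misses the mesh")
  roi_pts <- mesh$vertices[unique(c(roi_indices(mesh, ramus_border_roi),
                                    roi_indices(mesh, corpus_border_roi))), , drop = FALSE]
  best <- NULL
  for (pl in polys) {
    pts <- pl$points
    n <- nrow(pts)
    segs <- if (pl$closed) cbind(seq_len(n), c(seq_len(n)[-1], 1L))
            else cbind(seq_len(n - 1L), seq_len(n)[-1L])
    for (r in seq_len(nrow(segs))) {
      p <- pts[segs[r, 1], ]; q <- pts[segs[r, 2], ]
      # closest point of segment pq to the corner neighborhood gate
      mid <- (p + q) / 2
      dgate <- min(sqrt(rowSums(sweep(roi_pts, 2, mid)^2)))
      if (dgate > neighborhood_mm) next
      # minimize distance to line over the segment (closed form)
      w <- q - p
      dline <- function(x) {
        rel <- x - line$point
        perp <- rel - sum(rel * line$direction) * line$direction
        sqrt(sum(perp^2))
      }
      wp <- w - sum(w * line$direction) * line$direction
      relp <- (p - line$point)
      relp <- relp - sum(relp * line$direction) * line$direction
      denom <- sum(wp^2)
      tt <- if (denom < 1e-300) 0 else max(0, min(1, -sum(relp * wp) / denom))
      x <- p + tt * w
      d <- dline(x)
      if (is.null(best) || d < best$d - 1e-12) best <- list(d = d, x = x)
    }
  }
  if (is.null(best))
    stop("no gonial edge intersection within the corner neighborhood")
  lm <- landmark_row("GO", side, best$x, "auto")
  attr(lm, "planes") <- list(ramus = plane_a, corpus = plane_b, bisector = plane_c)
  lm
}

#' Detect all automatic landmarks on one mesh
#'
#' Runs the LP/MP, CP, GT and GO detectors on both sides with the given
#' (default procedural) ROIs.
#'
#' @param mesh A [triangle_mesh()] in the canonical frame.
#' @param rois ROI list as from [default_landmark_rois()].
#' @return Landmark tibble with 9 rows (LP, MP, CP, GO per side + GT),
#'   source `auto`.
#' @export
detect_all_landmarks <- function(mesh, rois = default_landmark_rois(mesh)) {
  curv <- discrete_curvature(mesh)
  out <- list()
  for (s in c("L", "R")) {
    out[[length(out) + 1L]] <- detect_condyle_poles(mesh, rois[[paste0("condyle_", s)]], s)
    out[[length(out) + 1L]] <- detect_coronoid_process(mesh, rois[[paste0("coronoid_", s)]], s, curv)
    go <- detect_gonion(mesh, rois[[paste0("ramus_border_", s)]],
                        rois[[paste0("corpus_border_", s)]], s)
    attr(go, "planes") <- NULL
    out[[length(out) + 1L]] <- go
  }
  out[[length(out) + 1L]] <- detect_genial_tubercle(mesh, rois$gt)
  dplyr::bind_rows(out)
}

#' Ground-truth landmark set of a template mesh
#'
#' The template's automatic landmarks (detected on the clean template) plus
#' its manual anchor positions, tagged as source `truth`. These are the
#' points the growth deformation transports exactly.
#'
#' @param template Template mesh from [generate_template_mesh()].
#' @return Landmark tibble with 17 rows.
#' @export
template_ground_truth <- function(template) {
  auto <- detect_all_landmarks(template)
  anchors <- attr(template, "manual_anchors")
  if (is.null(anchors)) stop("template lacks manual_anchors attribute")
  man <- tibble::tibble(code = anchors$code, side = anchors$side,
                        x_mm = anchors$x_mm, y_mm = anchors$y_mm,
                        z_mm = anchors$z_mm, source = "truth")
  auto$source <- "truth"
  res <- dplyr::bind_rows(auto, man)
  validate_landmark_set(res)
  res
}

#' Load manually placed landmarks from CSV
#'
#' Reads the landmark CSV schema (`subject,timepoint,code,side,x_mm,y_mm,
#' z_mm,source`), validates codes and coordinates, and snaps each point to
#' the nearest mesh vertex when within the snap tolerance; farther points
#' are rejected with their distance. Duplicate (code, side) rows within one
#' subject-timepoint are an error.
#'
#' @param path CSV path.
#' @param mesh Optional [triangle_mesh()] to snap/validate against (one
#'   subject-timepoint file). When NULL, no surface check is performed.
#' @param snap_mm Snap tolerance in mm (default 1.0).
#' @return List with `landmarks` (accepted rows, source `manual`) and
#'   `rejected` (rows with a `reason` column).
#' @export
load_manual_landmarks <- function(path, mesh = NULL, snap_mm = 1.0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("code", "side", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("landmark CSV lacks columns: ", paste(miss, collapse = ", "))
  key0 <- character(0)
  if (all(c("subject", "timepoint") %in% names(df)))
    key0 <- paste(df$subject, df$timepoint)
  else key0 <- rep("", nrow(df))
  key <- paste(key0, df$code, df$side)
  if (anyDuplicated(key))
    stop("duplicate (code, side) rows in manual landmark file: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  reasons <- rep(NA_character_, nrow(df))
  bad_code <- !(df$code %in% LANDMARK_CODES)
  reasons[bad_code] <- "unknown landmark code"
  bad_xyz <- !stats::complete.cases(df[, c("x_mm", "y_mm", "z_mm")])
  reasons[bad_xyz & is.na(reasons)] <- "missing coordinate"
  if (!is.null(mesh)) {
    for (i in which(is.na(reasons))) {
      p <- as.numeric(df[i, c("x_mm", "y_mm", "z_mm")])
      d2 <- rowSums(sweep(mesh$vertices, 2, p)^2)
      j <- which.min(d2)
      d <- sqrt(d2[j])
      if (d > snap_mm) {
        reasons[i] <- sprintf("point %.2f mm off surface (tolerance %.2f mm)", d, snap_mm)
      } else {
        df[i, c("x_mm", "y_mm", "z_mm")] <- mesh$vertices[j, ]
      }
    }
  }
  ok <- is.na(reasons)
  accepted <- tibble::as_tibble(df[ok, , drop = FALSE])
  accepted$source <- "manual"
  rejected <- df[!ok, , drop = FALSE]
  rejected$reason <- reasons[!ok]
  list(landmarks = accepted, rejected = tibble::as_tibble(rejected))
}

#' Merge automatic and manual landmark tables
#'
#' @param auto Landmark tibble from [detect_all_landmarks()].
#' @param manual Accepted manual landmark tibble.
#' @return Combined tibble; errors if a (code, side) appears in both.
#' @export
merge_landmarks <- function(auto, manual) {
  both <- intersect(paste(auto$code, auto$side), paste(manual$code, manual$side))
  if (length(both))
    stop("landmarks present in both auto and manual sets: ",
         paste(both, collapse = ", "))
  dplyr::bind_rows(auto, manual[, intersect(names(manual), names(auto))])
}
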