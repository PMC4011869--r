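#' Oriented plane in 3D
#'
#' A plane through `point` with unit `normal`. The normal defines the
#' positive (outward) side; signed distances are `normal . x - offset`.
#'
#' @param point Length-3 point on the plane (mm).
#' @param normal Length-3 normal vector (normalized internally).
#' @return An object of class `mg_plane` with `point`, `normal` and `offset`.
#' @export
mg_plane <- function(point, normal) {
  normal <- unit_vector(as.numeric(normal))
  point <- as.numeric(point)
  structure(list(point = point, normal = normal, offset = sum(normal * point)),
            class = "mg_plane")
}

#' @export
print.mg_plane <- function(x, ...) {
  cat(sprintf("plane: n = (%.6f, %.6f, %.6f), n.x = %.6f\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

plane_signed_distance <- function(plane, points) {
  as.vector(as.matrix(points) %*% plane$normal) - plane$offset
}

#' Supporting (tangent) plane of a mesh region
#'
#' Finds the plane tangent to the region of interest from the `outward`
#' side: all ROI vertices lie on the non-outward side (within tolerance)
#' and the plane touches the extreme contact set. The contact set is the
#' shell of ROI vertices within `contact_band` of the extreme along
#' `outward`; its shape decides the plane's normal:
#' a planar contact patch gives its own best-fit normal (oriented toward
#' `outward`), a line-like contact (a border ridge) is completed with the
#' outward direction (normal = `outward` minus its component along the
#' contact line — the edge-plus-direction completion), and a point contact
#' gives `outward` itself. The plane is then placed on the outermost ROI
#' vertex along that normal, so the support property holds by construction.
#' A fully coplanar ROI yields its common plane directly.
#'
#' @param mesh A [triangle_mesh()].
#' @param roi A [mesh_roi()] or integer vector of vertex indices.
#' @param outward Length-3 direction the plane faces (need not be unit).
#' @param tol Tolerances from [mg_tolerances()].
#' @param contact_band Thickness (mm) of the contact shell along `outward`;
#'   default 1% of the ROI diameter (at least the geometric tolerance).
#'   Operationalizes contact with a rounded anatomical border of finite
#'   sharpness.
#' @return An [mg_plane()] with normal within 90 degrees of `outward`.
#' @export
support_plane <- function(mesh, roi, outward, tol = mg_tolerances(),
                          contact_band = NULL) {
  outward <- unit_vector(as.numeric(outward))
  idx <- roi_indices(mesh, roi)
  X <- mesh$vertices[idx, , drop = FALSE]
  if (nrow(X) < 3L) stop("support_plane needs at least 3 ROI vertices")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0)
  scale <- max(sv$d[1], 1e-12)
  if (sv$d[2] < 1e-9 * scale)
    stop("ROI vertices are collinear; supporting plane undefined")
  if (sv$d[3] < 1e-9 * scale) {
    # coplanar region: its own plane, oriented toward `outward`
    nrm <- sv$v[, 3]
    if (sum(nrm * outward) < 0) nrm <- -nrm
    return(mg_plane(ctr, nrm))
  }
  diam <- sqrt(sum((apply(X, 2, max) - apply(X, 2, min))^2))
  if (is.null(contact_band))
    contact_band <- max(tol$geometric, 0.01 * diam)
  s <- as.vector(X %*% outward)
  h <- max(s)
  C <- X[s >= h - contact_band, , drop = FALSE]
  n <- outward
  if (nrow(C) >= 2L) {
    Cc <- sweep(C, 2, colMeans(C))
    cs <- svd(Cc, nu = 0)
    if (cs$d[1] > contact_band) {
      if (nrow(C) >= 3L && cs$d[2] > 0.25 * cs$d[1]) {
        # planar contact patch: its own normal
        n <- cs$v[, 3]
        if (sum(n * outward) < 0) n <- -n
      } else {
        # line-like contact (border ridge): edge + direction completion
        ell <- cs$v[, 1]
        n <- outward - sum(outward * ell) * ell
        if (vec_norm(n) < 1e-9)
          stop("contact line parallel to outward; supporting plane undefined")
        n <- unit_vector(n)
      }
    }
  }
  if (sum(n * outward) <= 0)
    stop("no supporting plane faces the outward direction")
  off <- as.vector(X %*% n)
  i_touch <- which.max(off)
  pl <- mg_plane(X[i_touch, ], n)
  sd <- plane_signed_distance(pl, X)
  if (max(sd) > tol$geometric)
    stop(sprintf("support property violated by %.3g mm", max(sd)))
  pl
}

#' Plane bisecting the wedge where two outward normals diverge
#'
#' Given two non-parallel planes with outward normals, returns the plane
#' containing their intersection line whose dihedral angles to both inputs
#' are equal, and which bisects the wedge on the side into which both
#' outward normals point (the exterior corner; for the gonial construction
#' this is the obtuse wedge behind/below the mandibular angle).
#'
#' @param p1,p2 [mg_plane()] objects.
#' @param tol Tolerances from [mg_tolerances()].
#' @return An [mg_plane()].
#' @export
bisecting_plane <- function(p1, p2, tol = mg_tolerances()) {
  n1 <- p1$normal; n2 <- p2$normal
  c12 <- sum(n1 * n2)
  if (abs(c12) >= 1 - 1e-9)
    stop("planes are parallel; bisecting plane (gonion construction) is degenerate")
  # point on the intersection line
  d1 <- p1$offset; d2 <- p2$offset
  denom <- 1 - c12^2
  x0 <- ((d1 - d2 * c12) * n1 + (d2 - d1 * c12) * n2) / denom
  nb <- unit_vector(n1 - n2)
  mg_plane(x0, nb)
}

#' Intersection line of two planes
#'
#' @param p1,p2 [mg_plane()] objects (non-parallel).
#' @return List with `point` and unit `direction`.
#' @export
plane_intersection_line <- function(p1, p2) {
  n1 <- p1$normal; n2 <- p2$normal
  c12 <- sum(n1 * n2)
  if (abs(c12) >= 1 - 1e-9) stop("planes are parallel; no intersection line")
  d1 <- p1$offset; d2 <- p2$offset
  denom <- 1 - c12^2
  x0 <- ((d1 - d2 * c12) * n1 + (d2 - d1 * c12) * n2) / denom
  list(point = x0, direction = unit_vector(cross3(n1, n2)))
}

#' Intersection of a plane with a triangle mesh surface
#'
#' Computes the cross-section curve(s): for every triangle crossed by the
#' plane the chord segment is extracted, and segments are chained into
#' ordered polylines via shared mesh edges. Closed loops are marked.
#'
#' @param mesh A [triangle_mesh()].
#' @param plane An [mg_plane()].
#' @param tol Tolerances from [mg_tolerances()].
#' @return A list of polylines; each is a list with `points` (k x 3 matrix)
#'   and `closed` (logical). Empty list when the plane misses the surface.
#' @export
plane_surface_intersection <- function(mesh, plane, tol = mg_tolerances()) {
  v <- mesh$vertices
  f <- mesh$faces
  s <- plane_signed_distance(plane, v)
  # nudge exact-on-plane vertices to the positive side: keeps crossings
  # unambiguous and a single tangent vertex produces no segment, not a crash
  s[abs(s) < tol$geometric * 1e-3] <- tol$geometric * 1e-3
  s1 <- s[f[, 1]]; s2 <- s[f[, 2]]; s3 <- s[f[, 3]]
  crossed <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(crossed)) return(list())
  ff <- f[crossed, , drop = FALSE]
  segs_a <- character(0); segs_b <- character(0)
  pts_env <- new.env(parent = emptyenv())
  edge_point_key <- function(i, j, si, sj) {
    lo <- min(i, j); hi <- max(i, j)
    key <- paste0(lo, "_", hi)
    if (is.null(pts_env[[key]])) {
      t <- si / (si - sj)   # interpolation from i toward j
      p <- v[i, ] + t * (v[j, ] - v[i, ])
      pts_env[[key]] <- p
    }
    key
  }
  seg_list <- vector("list", nrow(ff))
  for (r in seq_len(nrow(ff))) {
    tri <- ff[r, ]
    sv <- s[tri]
    keys <- character(0)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      i <- tri[e[1]]; j <- tri[e[2]]
      if (sign(s[i]) != sign(s[j]))
        keys <- c(keys, edge_point_key(i, j, s[i], s[j]))
    }
    if (length(keys) == 2L) seg_list[[r]] <- keys
  }
  seg_list <- seg_list[!vapply(seg_list, is.null, logical(1))]
  if (!length(seg_list)) return(list())
  # chain segments into polylines over shared edge keys
  allkeys <- unique(unlist(seg_list))
  adj <- new.env(parent = emptyenv())
  for (i in seq_along(seg_list)) {
    k <- seg_list[[i]]
    adj[[k[1]]] <- c(adj[[k[1]]], i)
    adj[[k[2]]] <- c(adj[[k[2]]], i)
  }
  used <- rep(FALSE, length(seg_list))
  polylines <- list()
  walk <- function(start_seg, start_key) {
    chain <- start_key
    seg <- start_seg
    key <- start_key
    repeat {
      used[seg] <<- TRUE
      k2 <- setdiff(seg_list[[seg]], key)
      if (length(k2) == 0L) k2 <- key   # degenerate segment
      chain <- c(chain, k2[1])
      key <- k2[1]
      nxt <- setdiff(adj[[key]], which(used))
      nxt <- nxt[!used[nxt]]
      if (!length(nxt)) break
      seg <- nxt[1]
    }
    chain
  }
  # open chains first (endpoints with degree 1)
  deg <- vapply(allkeys, function(k) length(adj[[k]]), integer(1))
  for (k in allkeys[deg == 1L]) {
    segs <- adj[[k]]
    segs <- segs[!used[segs]]
    if (!length(segs)) next
    chain <- walk(segs[1], k)
    polylines[[length(polylines) + 1L]] <-
      list(keys = chain, closed = FALSE)
  }
  # remaining are cycles
  while (any(!used)) {
    seg <- which(!used)[1]
    chain <- walk(seg, seg_list[[seg]][1])
    polylines[[length(polylines) + 1L]] <-
      list(keys = chain, closed = TRUE)
  }
  lapply(polylines, function(pl) {
    pts <- do.call(rbind, lapply(pl$keys, function(k) pts_env[[k]]))
    closed <- pl$closed
    if (closed && nrow(pts) > 1 &&
        sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2)) < tol$geometric)
      pts <- pts[-nrow(pts), , drop = FALSE]
    list(points = pts, closed = closed)
  })
}

polyline_length <- function(pl) {
  pts <- pl$points
  n <- nrow(pts)
  if (n < 2) return(0)
  d <- sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2)))
  if (pl$closed) d <- d + sqrt(sum((pts[1, ] - pts[n, ])^2))
  d
}
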