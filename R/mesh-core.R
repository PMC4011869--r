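#' Triangle surface mesh
#'
#' Construct a triangle mesh from a vertex matrix and a face index matrix.
#' Vertices are 3D points in millimetres; faces are triples of 1-based vertex
#' indices. Faces are expected to be consistently oriented; use
#' [orient_mesh()] to enforce outward orientation by the signed-volume
#' convention.
#'
#' @param vertices Numeric matrix, n x 3, in mm.
#' @param faces Integer matrix, m x 3, 1-based vertex indices.
#' @param validate Check for degenerate faces and index range (default TRUE).
#' @return An object of class `triangle_mesh` with elements `vertices` and
#'   `faces`.
#' @export
triangle_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (validate) {
    if (nrow(faces) > 0) {
      if (min(faces) < 1L || max(faces) > nrow(vertices))
        stop("face indices out of range")
      a <- face_areas(vertices, faces)
      if (any(a <= 1e-12))
        stop(sprintf("%d degenerate face(s) with area <= 1e-12 mm^2", sum(a <= 1e-12)))
    }
    if (anyNA(vertices)) stop("vertices contain NA")
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  wt <- is_watertight(x)
  cat(sprintf("triangle_mesh: %d vertices, %d faces, %s\n",
              nrow(x$vertices), nrow(x$faces),
              if (wt) sprintf("watertight (Euler characteristic %d)", euler_characteristic(x))
              else "not watertight"))
  invisible(x)
}

face_areas <- function(vertices, faces) {
  p1 <- vertices[faces[, 1], , drop = FALSE]
  p2 <- vertices[faces[, 2], , drop = FALSE]
  p3 <- vertices[faces[, 3], , drop = FALSE]
  0.5 * sqrt(rowSums(cross3_rows(p2 - p1, p3 - p1)^2))
}

# undirected edge table: one row per face edge, with canonical (lo,hi) key
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2])
  hi <- pmax(e[, 1], e[, 2])
  cbind(lo = lo, hi = hi)
}

#' Is a mesh watertight?
#'
#' A mesh is watertight (closed 2-manifold) when every undirected edge is
#' shared by exactly two faces.
#'
#' @param mesh A [triangle_mesh()].
#' @return Logical scalar.
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(FALSE)
  e <- mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  all(table(key) == 2L)
}

#' Euler characteristic V - E + F
#'
#' For a closed genus-g surface the Euler characteristic is `2 - 2g`
#' (2 for a topological sphere).
#'
#' @param mesh A [triangle_mesh()].
#' @return Integer.
#' @export
euler_characteristic <- function(mesh) {
  e <- mesh_edges(mesh)
  n_edges <- nrow(unique(e))
  used <- sort(unique(as.vector(mesh$faces)))
  length(used) - n_edges + nrow(mesh$faces)
}

signed_volume_mm3 <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(rowSums(p1 * cross3_rows(p2, p3))) / 6
}

#' Enforce outward face orientation
#'
#' Makes the orientation of all faces consistent by region-growing across
#' shared edges, then flips all faces if the signed volume is negative, so
#' that the divergence-theorem volume of a closed mesh is positive.
#'
#' @param mesh A [triangle_mesh()].
#' @return The re-oriented mesh.
#' @export
orient_mesh <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  if (nf == 0L) return(mesh)
  # adjacency via undirected edges
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fid <- rep(seq_len(nf), 3L)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  grp <- split(seq_along(key), key)
  adj <- vector("list", nf)
  for (g in grp) {
    if (length(g) == 2L) {
      f1 <- fid[g[1]]; f2 <- fid[g[2]]
      adj[[f1]] <- c(adj[[f1]], f2)
      adj[[f2]] <- c(adj[[f2]], f1)
    }
  }
  visited <- rep(FALSE, nf)
  for (seed in seq_len(nf)) {
    if (visited[seed]) next
    visited[seed] <- TRUE
    queue <- seed
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      cf <- f[cur, ]
      # directed edges of current face
      de <- rbind(cf[c(1, 2)], cf[c(2, 3)], cf[c(3, 1)])
      for (nb in adj[[cur]]) {
        if (visited[nb]) next
        nbf <- f[nb, ]
        nde <- rbind(nbf[c(1, 2)], nbf[c(2, 3)], nbf[c(3, 1)])
        # consistent orientation: the shared edge appears in opposite directions
        same_dir <- any(apply(de, 1, function(d)
          any(nde[, 1] == d[1] & nde[, 2] == d[2])))
        if (same_dir) f[nb, ] <- nbf[c(1, 3, 2)]
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  m2 <- triangle_mesh(mesh$vertices, f, validate = FALSE)
  if (signed_volume_mm3(m2) < 0) m2$faces <- m2$faces[, c(1, 3, 2), drop = FALSE]
  m2
}

#' Mesh volume in cubic centimetres
#'
#' Computes the enclosed volume of a watertight, outward-oriented triangle
#' mesh by the divergence theorem (sum of signed tetrahedra against the
#' origin), converting mm^3 to cm^3.
#'
#' @param mesh A [triangle_mesh()], watertight and outward-oriented.
#' @return Volume in cm^3 (positive).
#' @export
mesh_volume <- function(mesh) {
  if (!is_watertight(mesh))
    stop("mesh_volume requires a watertight mesh (an edge is not shared by exactly 2 faces)")
  v <- signed_volume_mm3(mesh)
  if (v <= 0)
    stop("signed volume is non-positive; mesh is not outward-oriented (run orient_mesh first)")
  v / 1000
}

#' Connected components of a mesh
#'
#' @param mesh A [triangle_mesh()].
#' @return A list of `triangle_mesh` objects, one per face-connected component.
#' @export
mesh_components <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  e <- mesh_edges(mesh)
  fid <- rep(seq_len(nf), 3L)
  key <- paste(e[, 1], e[, 2])
  comp <- seq_len(nf)
  # union-find over faces sharing an edge
  find <- function(i) { while (comp[i] != i) { comp[i] <<- comp[comp[i]]; i <- comp[i] }; i }
  grp <- split(fid, key)
  for (g in grp) if (length(g) > 1L) {
    r <- find(g[1])
    for (j in g[-1]) { rj <- find(j); if (rj != r) comp[rj] <- r }
  }
  roots <- vapply(seq_len(nf), find, integer(1))
  lapply(split(seq_len(nf), roots), function(idx) {
    ff <- f[idx, , drop = FALSE]
    used <- sort(unique(as.vector(ff)))
    remap <- match(ff, used)
    dim(remap) <- dim(ff)
    triangle_mesh(mesh$vertices[used, , drop = FALSE], remap, validate = FALSE)
  })
}

#' Region of interest on a mesh
#'
#' Either an explicit vertex-index set, or an axis-aligned box predicate in
#' the canonical anatomical frame (+x anterior, +y subject-left, +z superior).
#' Box limits may be `-Inf`/`Inf`.
#'
#' @param indices Integer vector of vertex indices (optional).
#' @param box Named list/vector with `xmin,xmax,ymin,ymax,zmin,zmax` (optional).
#' @return An object of class `mesh_roi`.
#' @export
mesh_roi <- function(indices = NULL, box = NULL) {
  if (is.null(indices) && is.null(box))
    stop("mesh_roi needs either indices or a box")
  if (!is.null(box)) {
    box <- as.list(box)
    need <- c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax")
    miss <- setdiff(need, names(box))
    if (length(miss)) stop("box is missing: ", paste(miss, collapse = ", "))
  }
  structure(list(indices = if (!is.null(indices)) as.integer(indices) else NULL,
                 box = box), class = "mesh_roi")
}

#' Resolve an ROI to vertex indices on a mesh
#'
#' @param mesh A [triangle_mesh()].
#' @param roi A [mesh_roi()] or plain integer vector.
#' @return Integer vector of vertex indices.
#' @export
roi_indices <- function(mesh, roi) {
  if (is.numeric(roi)) return(as.integer(roi))
  stopifnot(inherits(roi, "mesh_roi"))
  idx <- roi$indices %||% seq_len(nrow(mesh$vertices))
  if (!is.null(roi$box)) {
    v <- mesh$vertices
    b <- roi$box
    keep <- v[, 1] >= b$xmin & v[, 1] <= b$xmax &
            v[, 2] >= b$ymin & v[, 2] <= b$ymax &
            v[, 3] >= b$zmin & v[, 3] <= b$zmax
    idx <- intersect(idx, which(keep))
  }
  if (length(idx) == 0L) stop("region of interest is empty on this mesh")
  as.integer(idx)
}

#' Extremal vertex along a direction
#'
#' Returns the ROI vertex maximizing the dot product with `direction`.
#' Ties (within the geometric tolerance) are broken by the lowest vertex
#' index, for reproducibility.
#'
#' @param mesh A [triangle_mesh()].
#' @param direction Length-3 direction vector (need not be unit).
#' @param roi A [mesh_roi()] or integer vector; defaults to all vertices.
#' @param tol Tolerances from [mg_tolerances()].
#' @return List with `index` (vertex id) and `point` (length-3 position, mm).
#' @export
extremal_point <- function(mesh, direction, roi = NULL, tol = mg_tolerances()) {
  d <- unit_vector(as.numeric(direction))
  idx <- if (is.null(roi)) seq_len(nrow(mesh$vertices)) else roi_indices(mesh, roi)
  s <- as.vector(mesh$vertices[idx, , drop = FALSE] %*% d)
  smax <- max(s)
  cand <- idx[s >= smax - tol$geometric]
  i <- min(cand)
  list(index = i, point = mesh$vertices[i, ])
}

#' Discrete Gaussian curvature (angle deficit)
#'
#' Per-vertex Gaussian curvature estimated as the angle deficit
#' `2*pi - sum(incident angles)` normalized by one third of the incident
#' triangle area. On a closed mesh the deficits sum to `2*pi*chi`
#' (Gauss-Bonnet). Vertices on boundary edges are flagged and given `NA`.
#'
#' @param mesh A [triangle_mesh()].
#' @return List with `curvature` (per-vertex, 1/mm^2), `area` (mixed area,
#'   mm^2) and `boundary` (logical flags).
#' @export
discrete_curvature <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  if (length(setdiff(seq_len(n), unique(as.vector(f)))) > 0)
    stop("mesh has isolated vertices; curvature undefined")
  ang_sum <- numeric(n)
  area_sum <- numeric(n)
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  a <- face_areas(v, f)
  ang <- function(u, w) {
    cu <- sqrt(rowSums(u^2)); cw <- sqrt(rowSums(w^2))
    cosang <- rowSums(u * w) / (cu * cw)
    acos(pmin(1, pmax(-1, cosang)))
  }
  a1 <- ang(p2 - p1, p3 - p1)
  a2 <- ang(p1 - p2, p3 - p2)
  a3 <- ang(p1 - p3, p2 - p3)
  # Meyer mixed area: Voronoi area for non-obtuse triangles, area/2 at the
  # obtuse corner and area/4 at the others for obtuse ones
  l1sq <- rowSums((p3 - p2)^2)   # edge opposite vertex 1
  l2sq <- rowSums((p1 - p3)^2)
  l3sq <- rowSums((p2 - p1)^2)
  cot <- function(x) cos(x) / pmax(sin(x), 1e-300)
  obtuse <- pmax(a1, a2, a3) > pi / 2
  mixed <- matrix(0, nrow(f), 3)
  # non-obtuse: Voronoi area at vertex k = 1/8 (l_j^2 cot a_j + l_i^2 cot a_i)
  mixed[!obtuse, 1] <- (l2sq[!obtuse] * cot(a2[!obtuse]) + l3sq[!obtuse] * cot(a3[!obtuse])) / 8
  mixed[!obtuse, 2] <- (l3sq[!obtuse] * cot(a3[!obtuse]) + l1sq[!obtuse] * cot(a1[!obtuse])) / 8
  mixed[!obtuse, 3] <- (l1sq[!obtuse] * cot(a1[!obtuse]) + l2sq[!obtuse] * cot(a2[!obtuse])) / 8
  if (any(obtuse)) {
    ao <- a[obtuse]
    amat <- cbind(a1, a2, a3)[obtuse, , drop = FALSE]
    for (k in 1:3)
      mixed[obtuse, k] <- ifelse(amat[, k] > pi / 2, ao / 2, ao / 4)
  }
  for (k in 1:3) {
    aa <- list(a1, a2, a3)[[k]]
    idx <- f[, k]
    s <- rowsum(cbind(aa, mixed[, k]), idx)
    at <- as.integer(rownames(s))
    ang_sum[at] <- ang_sum[at] + s[, 1]
    area_sum[at] <- area_sum[at] + s[, 2]
  }
  e <- mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1L]
  boundary <- rep(FALSE, n)
  if (length(bkey)) {
    bverts <- unique(as.integer(unlist(strsplit(bkey, " "))))
    boundary[bverts] <- TRUE
  }
  kg <- (2 * pi - ang_sum) / area_sum
  kg[boundary] <- NA_real_
  list(curvature = kg, area = area_sum, boundary = boundary)
}

#' Apply a rigid motion (or general affine map) to a mesh
#'
#' @param mesh A [triangle_mesh()].
#' @param rotation 3 x 3 matrix applied on the left.
#' @param translation Length-3 vector.
#' @return Transformed mesh.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, -as.numeric(translation), "-")
  m <- mesh
  m$vertices <- v
  m
}
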