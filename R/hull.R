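# Incremental (quickhull-style) 3D convex hull.
#
# Returns the hull facets of a point set as outward-oriented vertex triples.
# Only facet planes are needed downstream (supporting-plane queries), so the
# implementation favours robustness of the support property over producing a
# perfectly simplicial complex on degenerate inputs.

convex_hull_facets <- function(points, tol = NULL) {
  P <- as.matrix(points)
  n <- nrow(P)
  if (n < 4L) stop("convex hull needs at least 4 points")
  scale <- max(apply(P, 2, function(x) diff(range(x))), 1)
  if (is.null(tol)) tol <- 1e-10 * scale

  # --- initial tetrahedron from extreme points ---
  ext <- c(apply(P, 2, which.min), apply(P, 2, which.max))
  best <- c(ext[1], ext[4]); bd <- -1
  for (a in ext) for (b in ext) {
    d <- sum((P[a, ] - P[b, ])^2)
    if (d > bd) { bd <- d; best <- c(a, b) }
  }
  i1 <- best[1]; i2 <- best[2]
  if (bd < tol^2) stop("all points coincide; hull undefined")
  u <- P[i2, ] - P[i1, ]
  rel <- sweep(P, 2, P[i1, ])
  proj <- rel %*% u / sum(u^2)
  perp <- rel - proj %*% t(u)
  d2 <- rowSums(perp^2)
  i3 <- which.max(d2)
  if (d2[i3] < tol^2) stop("points are collinear; hull undefined")
  nrm <- cross3(P[i2, ] - P[i1, ], P[i3, ] - P[i1, ])
  nrm <- unit_vector(nrm)
  h <- as.vector(rel %*% nrm)
  i4 <- which.max(abs(h))
  if (abs(h[i4]) < tol) stop("points are coplanar; hull undefined")
  interior <- colMeans(P[c(i1, i2, i3, i4), , drop = FALSE])

  faces <- list()   # each: list(v = c(a,b,c), n = normal, d = offset, alive = TRUE, out = integer(), far = NA)
  mk_face <- function(a, b, c) {
    nn <- cross3(P[b, ] - P[a, ], P[c, ] - P[a, ])
    ln <- vec_norm(nn)
    if (ln < 1e-300) return(NULL)
    nn <- nn / ln
    dd <- sum(nn * P[a, ])
    if (sum(nn * interior) > dd) { tmp <- b; b <- c; c <- tmp; nn <- -nn; dd <- -dd }
    list(v = c(a, b, c), n = nn, d = dd, alive = TRUE, out = integer(0))
  }
  for (tri in list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4)))
    faces[[length(faces) + 1L]] <- mk_face(tri[1], tri[2], tri[3])

  assign_points <- function(face_ids, pts) {
    if (!length(pts)) return()
    for (fi in face_ids) {
      f <- faces[[fi]]
      if (!f$alive) next
      s <- as.vector(P[pts, , drop = FALSE] %*% f$n) - f$d
      sel <- s > tol
      if (any(sel)) {
        faces[[fi]]$out <<- c(faces[[fi]]$out, pts[sel])
        pts <- pts[!sel]
        if (!length(pts)) break
      }
    }
  }
  assign_points(seq_along(faces), setdiff(seq_len(n), c(i1, i2, i3, i4)))

  repeat {
    pending <- which(vapply(faces, function(f) f$alive && length(f$out) > 0L, logical(1)))
    if (!length(pending)) break
    fi <- pending[1]
    f <- faces[[fi]]
    s <- as.vector(P[f$out, , drop = FALSE] %*% f$n) - f$d
    p <- f$out[which.max(s)]
    # visible faces: all alive faces that see p
    alive_ids <- which(vapply(faces, `[[`, logical(1), "alive"))
    vis <- alive_ids[vapply(alive_ids, function(j)
      sum(faces[[j]]$n * P[p, ]) - faces[[j]]$d > tol, logical(1))]
    if (!length(vis)) { faces[[fi]]$out <- setdiff(f$out, p); next }
    # horizon: directed edges of visible faces whose reverse is not visible
    dir_edges <- do.call(rbind, lapply(vis, function(j) {
      v <- faces[[j]]$v
      rbind(v[c(1, 2)], v[c(2, 3)], v[c(3, 1)])
    }))
    ekey <- paste(dir_edges[, 1], dir_edges[, 2])
    rkey <- paste(dir_edges[, 2], dir_edges[, 1])
    horizon <- dir_edges[!(rkey %in% ekey), , drop = FALSE]
    orphan <- unique(unlist(lapply(vis, function(j) faces[[j]]$out)))
    orphan <- setdiff(orphan, p)
    for (j in vis) { faces[[j]]$alive <- FALSE; faces[[j]]$out <- integer(0) }
    new_ids <- integer(0)
    for (r in seq_len(nrow(horizon))) {
      nf <- mk_face(horizon[r, 1], horizon[r, 2], p)
      if (is.null(nf)) next
      faces[[length(faces) + 1L]] <- nf
      new_ids <- c(new_ids, length(faces))
    }
    assign_points(new_ids, orphan)
  }

  alive <- faces[vapply(faces, `[[`, logical(1), "alive")]
  list(
    facets = do.call(rbind, lapply(alive, `[[`, "v")),
    normals = do.call(rbind, lapply(alive, `[[`, "n")),
    offsets = vapply(alive, `[[`, numeric(1), "d")
  )
}
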