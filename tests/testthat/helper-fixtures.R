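# Geometric fixtures built in code: cube, subdivided-octahedron sphere,
# cone, extruded fillet wedge, seeded star-shaped blobs, random rigid motions.

cube_mesh <- function(edge = 10, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(c(0, edge), c(0, edge), c(0, edge)))
  v <- sweep(v, 2, -as.numeric(origin), "-")
  colnames(v) <- NULL
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  orient_mesh(triangle_mesh(v, f))
}

octa_sphere_mesh <- function(r = 5, n = 3, center = c(0, 0, 0)) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (k in seq_len(n)) {
    nf <- nrow(f); ekey <- new.env(parent = emptyenv())
    newf <- matrix(0L, 4L * nf, 3L)
    mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (is.null(ekey[[key]])) {
        m <- v[i, ] + v[j, ]
        v <<- rbind(v, m / sqrt(sum(m^2)))
        ekey[[key]] <- nrow(v)
      }
      ekey[[key]]
    }
    for (t in seq_len(nf)) {
      a <- f[t, 1]; b <- f[t, 2]; c0 <- f[t, 3]
      ab <- mid(a, b); bc <- mid(b, c0); ca <- mid(c0, a)
      newf[4L * t - 3L, ] <- c(a, ab, ca)
      newf[4L * t - 2L, ] <- c(ab, b, bc)
      newf[4L * t - 1L, ] <- c(ca, bc, c0)
      newf[4L * t, ] <- c(ab, bc, ca)
    }
    f <- newf
  }
  orient_mesh(triangle_mesh(sweep(v * r, 2, -as.numeric(center), "-"), f))
}

# tall cone with a shallow base: apex is the unambiguous curvature maximum
cone_mesh <- function(height = 9, radius = 5, base_depth = 0.5, n = 16) {
  th <- 2 * pi * (0:(n - 1)) / n
  base <- cbind(radius * cos(th), radius * sin(th), 0)
  v <- rbind(c(0, 0, height), base, c(0, 0, -base_depth))
  f <- rbind(cbind(1, 1 + (1:n), 1 + c(2:n, 1)),
             cbind(n + 2, 1 + c(2:n, 1), 1 + (1:n)))
  orient_mesh(triangle_mesh(v, f))
}

# Exterior right-angle corner between the planes x = 0 (outward -x) and
# z = 0 (outward -z), rounded by a quarter-cylinder fillet of radius r along
# y. Closed prism. The three-plane construction has the closed-form gonion
# at (r (1 - 1/sqrt(2)), y, r (1 - 1/sqrt(2))), distance r (sqrt(2) - 1)
# from the corner line.
fillet_wedge_mesh <- function(r = 5, width = 30, extent = 25, n_arc = 24) {
  phi <- seq(0, pi / 2, length.out = n_arc)
  arc <- cbind(r - r * sin(phi), r - r * cos(phi))   # from (0, r) to (r, 0)
  profile <- rbind(c(0, extent), arc, c(extent, 0),
                   c(extent, extent))
  np <- nrow(profile)
  v0 <- cbind(profile[, 1], 0, profile[, 2])
  v1 <- cbind(profile[, 1], width, profile[, 2])
  v <- rbind(v0, v1)
  side <- do.call(rbind, lapply(seq_len(np), function(i) {
    j <- if (i == np) 1L else i + 1L
    rbind(c(i, j, np + i), c(j, np + j, np + i))
  }))
  # cap fans from the last profile vertex (the convex outer corner)
  cap0 <- do.call(rbind, lapply(seq_len(np - 2L), function(i)
    c(np, i, i + 1L)))
  cap1 <- do.call(rbind, lapply(seq_len(np - 2L), function(i)
    c(2L * np, np + i + 1L, np + i)))
  orient_mesh(triangle_mesh(v, rbind(side, cap0, cap1)))
}

# star-shaped random blob around the origin: smooth radial modulation of a
# subdivided octahedron sphere; always watertight genus 0
random_blob_mesh <- function(seed, r0 = 8, amp = 0.25, n = 3) {
  set.seed(seed)
  a <- stats::rnorm(6, 0, 1)
  s <- octa_sphere_mesh(1, n)
  u <- s$vertices
  mod <- 1 + amp * (a[1] * u[, 1] * u[, 2] + a[2] * u[, 2] * u[, 3] +
                    a[3] * u[, 1] * u[, 3] + a[4] * (u[, 1]^2 - u[, 3]^2) +
                    a[5] * sin(2 * u[, 1]) * u[, 2] + a[6] * u[, 1] * u[, 2] * u[, 3])
  s$vertices <- u * (r0 * pmax(0.4, mod))
  orient_mesh(s)
}

random_rotation <- function(seed) {
  set.seed(seed)
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_d <- qr(M)
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

expect_points_close <- function(p, q, tol = 1e-6) {
  expect_lt(sqrt(sum((as.numeric(p) - as.numeric(q))^2)), tol)
}

# shared template fixture (built once per test run)
template_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_template_mesh(resolution = 2600)
    cache
  }
})
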