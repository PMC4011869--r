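# Supporting planes, plane bisection, plane-surface intersection.

test_that("support plane of the cube bottom face is z = 0 with normal -z", {
  m <- cube_mesh(10)
  roi <- mesh_roi(box = list(xmin = -Inf, xmax = Inf, ymin = -Inf, ymax = Inf,
                             zmin = -Inf, zmax = 0.5))
  pl <- support_plane(m, roi, c(0, 0, -1))
  expect_points_close(pl$normal, c(0, 0, -1), 1e-9)
  expect_lt(abs(pl$offset), 1e-9)
})

test_that("support property holds on random blobs for random outward directions", {
  for (seed in 1:4) {
    blob <- random_blob_mesh(seed)
    set.seed(seed + 100)
    d <- unit_vector(stats::rnorm(3))
    pl <- support_plane(blob, seq_len(nrow(blob$vertices)), d)
    sd <- mandigrow:::plane_signed_distance(pl, blob$vertices)
    expect_lte(max(sd), 1e-6)
    expect_gt(max(sd), -1e-6)        # the plane touches the surface
    expect_gt(sum(pl$normal * d), 0) # faces outward
  }
})

test_that("support plane is at least as aligned as every convex-hull facet", {
  # hull-enumeration oracle: no facet of the ROI's convex hull may beat the
  # returned plane's alignment with the outward direction
  blob <- random_blob_mesh(7, n = 2)
  set.seed(42)
  for (k in 1:3) {
    d <- unit_vector(stats::rnorm(3))
    pl <- support_plane(blob, seq_len(nrow(blob$vertices)), d)
    hull <- mandigrow:::convex_hull_facets(blob$vertices)
    best_facet <- max(as.vector(hull$normals %*% d))
    expect_gte(sum(pl$normal * d), best_facet - 1e-9)
  }
})

test_that("collinear ROIs are rejected; coplanar ROIs give their own plane", {
  line_pts <- cbind(1:5, 1:5, 1:5)
  m <- triangle_mesh(rbind(line_pts, c(0, 0, 1), c(1, 0, 0)),
                     matrix(c(1, 6, 7), 1), validate = FALSE)
  expect_error(support_plane(m, 1:5, c(0, 0, 1)), "collinear")
  sq <- cube_mesh(4)
  roi <- which(sq$vertices[, 3] == 0)
  pl <- support_plane(sq, roi, c(0, 0, -1))
  expect_points_close(pl$normal, c(0, 0, -1), 1e-9)
})

test_that("bisecting plane of x=0 and y=0 contains the z-axis and (1,1,0)", {
  b <- bisecting_plane(mg_plane(c(0, 0, 0), c(1, 0, 0)),
                       mg_plane(c(0, 0, 0), c(0, 1, 0)))
  expect_lt(abs(sum(b$normal * c(0, 0, 1))), 1e-12)     # contains z-axis
  expect_lt(abs(sum(b$normal * c(1, 1, 0)) / sqrt(2)), 1e-12)
  expect_lt(abs(b$offset), 1e-12)
})

test_that("bisecting plane is symmetric in its arguments and rejects parallels", {
  p1 <- mg_plane(c(1, 2, 3), c(0.2, -0.5, 1))
  p2 <- mg_plane(c(-1, 0, 2), c(1, 0.3, -0.2))
  b12 <- bisecting_plane(p1, p2)
  b21 <- bisecting_plane(p2, p1)
  expect_lt(min(vec_norm(b12$normal - b21$normal),
                vec_norm(b12$normal + b21$normal)), 1e-12)
  expect_lt(abs(abs(b12$offset) - abs(b21$offset)), 1e-9)
  expect_error(bisecting_plane(p1, mg_plane(c(5, 5, 5), p1$normal)), "parallel")
})

test_that("bisector makes equal dihedral angles with both planes (random pairs)", {
  set.seed(7)
  for (k in 1:20) {
    n1 <- unit_vector(stats::rnorm(3)); n2 <- unit_vector(stats::rnorm(3))
    if (abs(sum(n1 * n2)) > 0.99) next
    p1 <- mg_plane(stats::rnorm(3), n1)
    p2 <- mg_plane(stats::rnorm(3), n2)
    b <- bisecting_plane(p1, p2)
    a1 <- acos(min(1, abs(sum(b$normal * n1))))
    a2 <- acos(min(1, abs(sum(b$normal * n2))))
    expect_lt(abs(a1 - a2), 1e-9)
    # contains the intersection line
    ln <- plane_intersection_line(p1, p2)
    expect_lt(abs(sum(b$normal * ln$point) - b$offset), 1e-9)
    expect_lt(abs(sum(b$normal * ln$direction)), 1e-9)
  }
})

test_that("cube cross-section at z = 5 is one closed square loop of perimeter 40", {
  m <- cube_mesh(10)
  ps <- plane_surface_intersection(m, mg_plane(c(0, 0, 5), c(0, 0, 1)))
  expect_length(ps, 1L)
  expect_true(ps[[1]]$closed)
  expect_equal(mandigrow:::polyline_length(ps[[1]]), 40, tolerance = 1e-9)
})

test_that("plane tangent at a single vertex yields no crossing, not a crash", {
  m <- cube_mesh(10)
  ps <- plane_surface_intersection(m, mg_plane(c(0, 0, 0), unit_vector(c(-1, -1, -1))))
  # at most a degenerate point-like remnant at the grazed corner
  expect_true(length(ps) == 0L ||
                all(vapply(ps, mandigrow:::polyline_length, numeric(1)) < 1e-6))
  expect_length(plane_surface_intersection(m, mg_plane(c(0, 0, 50), c(0, 0, 1))), 0L)
})

test_that("off-center sphere section length matches the chord-circle circumference", {
  s <- octa_sphere_mesh(6, 4)
  h <- 2.5
  ps <- plane_surface_intersection(s, mg_plane(c(0, 0, h), c(0, 0, 1)))
  expect_length(ps, 1L)
  expect_true(ps[[1]]$closed)
  expect_equal(mandigrow:::polyline_length(ps[[1]]),
               2 * pi * sqrt(36 - h^2), tolerance = 0.01 * 2 * pi * sqrt(36 - h^2))
})
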