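# Automatic landmark detectors and manual-landmark ingestion.

test_that("condyle poles of an ellipsoid are the analytic lateral/medial extremes", {
  ell <- octa_sphere_mesh(1, 3, center = c(0, 20, 0))
  ell$vertices <- sweep(sweep(ell$vertices, 2, c(0, 20, 0)) %*% diag(c(4, 6, 5)),
                        2, -c(0, 20, 0), "-")
  lm <- detect_condyle_poles(ell, seq_len(nrow(ell$vertices)), "L")
  expect_equal(landmark_xyz(lm, "LP", "L"), c(0, 26, 0), tolerance = 1e-9)
  expect_equal(landmark_xyz(lm, "MP", "L"), c(0, 14, 0), tolerance = 1e-9)
})

test_that("LP/MP swap sides exactly on the mirrored mandible", {
  tm <- template_fixture()
  mir <- tm
  mir$vertices <- tm$vertices %*% diag(c(1, -1, 1))
  mir$faces <- tm$faces[, c(1, 3, 2)]
  lm <- detect_all_landmarks(tm)
  lm_m <- detect_all_landmarks(mir)
  for (code in c("LP", "MP", "CP", "GO")) for (s in c("L", "R")) {
    other <- if (s == "L") "R" else "L"
    expect_points_close(landmark_xyz(lm, code, s) * c(1, -1, 1),
                        landmark_xyz(lm_m, code, other), 1e-6)
  }
  expect_points_close(landmark_xyz(lm, "GT", "M") * c(1, -1, 1),
                      landmark_xyz(lm_m, "GT", "M"), 1e-6)
})

test_that("coronoid detection picks the lower-index spike of an exact tie", {
  # two identical cone spikes on a plate: deterministic tie-break
  c1 <- cone_mesh(8, 3, 0.4, 12)
  c2 <- cone_mesh(8, 3, 0.4, 12)
  c2$vertices <- sweep(c2$vertices, 2, -c(20, 0, 0), "-")
  both <- triangle_mesh(rbind(c1$vertices, c2$vertices),
                        rbind(c1$faces, c2$faces + nrow(c1$vertices)))
  lm <- detect_coronoid_process(both, seq_len(nrow(both$vertices)), "L")
  expect_equal(landmark_xyz(lm, "CP", "L"), c(0, 0, 8), tolerance = 1e-12)
  lm2 <- detect_coronoid_process(both, seq_len(nrow(both$vertices)), "L")
  expect_identical(lm, lm2)    # deterministic
})

test_that("an all-flat ROI is rejected as lacking a protrusion", {
  g <- expand.grid(x = 0:6, y = 0:6)
  v <- cbind(g$x, g$y, 0)
  f <- do.call(rbind, lapply(0:5, function(i) do.call(rbind, lapply(0:5, function(j) {
    a <- i * 7 + j + 1; b <- a + 1; cc <- a + 7; d <- a + 8
    rbind(c(a, b, d), c(a, d, cc))
  }))))
  flat <- triangle_mesh(v, f)
  interior <- which(v[, 1] > 0 & v[, 1] < 6 & v[, 2] > 0 & v[, 2] < 6)
  expect_error(detect_coronoid_process(flat, interior, "L"), "no protrusion")
})

test_that("genial tubercle is the posterior-most bump vertex in its ROI", {
  tm <- template_fixture()
  rois <- default_landmark_rois(tm)
  gt <- detect_genial_tubercle(tm, rois$gt)
  p <- landmark_xyz(gt, "GT", "M")
  expect_equal(p[2], 0, tolerance = 1e-9)   # midline
  idx <- roi_indices(tm, rois$gt)
  expect_equal(p[1], min(tm$vertices[idx, 1]), tolerance = 1e-9)
})

test_that("gonion on the quarter-cylinder fillet matches the closed form", {
  r <- 5
  w <- fillet_wedge_mesh(r = r, width = 30, extent = 25, n_arc = 40)
  ramus_roi <- which(w$vertices[, 1] < 1e-9 & w$vertices[, 3] > r - 1e-9)
  corpus_roi <- which(w$vertices[, 3] < 1e-9 & w$vertices[, 1] > r - 1e-9)
  go <- detect_gonion(w, ramus_roi, corpus_roi, "L", neighborhood_mm = 50)
  p <- landmark_xyz(go, "GO", "L")
  expected_xz <- r * (1 - 1 / sqrt(2))
  expect_lt(abs(p[1] - expected_xz), 1e-3 * r)
  expect_lt(abs(p[3] - expected_xz), 1e-3 * r)
  # distance to the corner line equals r (sqrt(2) - 1)
  expect_lt(abs(sqrt(p[1]^2 + p[3]^2) - r * (sqrt(2) - 1)), 1e-3 * r)
  # brute-force oracle over all bisector-intersection points
  planes <- attr(go, "planes")
  polys <- plane_surface_intersection(w, planes$bisector)
  ln <- plane_intersection_line(planes$ramus, planes$corpus)
  dmin <- Inf
  for (pl in polys) for (i in seq_len(nrow(pl$points))) {
    rel <- pl$points[i, ] - ln$point
    perp <- rel - sum(rel * ln$direction) * ln$direction
    dmin <- min(dmin, sqrt(sum(perp^2)))
  }
  expect_lt(abs(sqrt(p[1]^2 + p[3]^2) - dmin), 1e-6)
})

test_that("gonion scales exactly under isotropic scaling", {
  r <- 5
  w <- fillet_wedge_mesh(r = r)
  ramus_roi <- which(w$vertices[, 1] < 1e-9 & w$vertices[, 3] > r - 1e-9)
  corpus_roi <- which(w$vertices[, 3] < 1e-9 & w$vertices[, 1] > r - 1e-9)
  go1 <- landmark_xyz(detect_gonion(w, ramus_roi, corpus_roi, "L",
                                    neighborhood_mm = 50), "GO", "L")
  s <- 2.5
  ws <- w; ws$vertices <- w$vertices * s
  go2 <- landmark_xyz(detect_gonion(ws, ramus_roi, corpus_roi, "L",
                                    neighborhood_mm = 50 * s), "GO", "L")
  expect_points_close(go2, go1 * s, 1e-6)
})

test_that("detectors are rigid-motion equivariant with transformed hints", {
  tm <- template_fixture()
  R <- random_rotation(3)
  tr <- c(4, -7, 2)
  moved <- transform_mesh(tm, R, tr)
  rois <- default_landmark_rois(tm)
  # LP: extremal along transformed lateral direction equals moved template LP
  idx <- roi_indices(tm, rois$condyle_L)
  lp0 <- extremal_point(tm, c(0, 1, 0), idx)
  lp1 <- extremal_point(moved, as.vector(R %*% c(0, 1, 0)), idx)
  expect_identical(lp0$index, lp1$index)
  expect_points_close(as.numeric(R %*% lp0$point) + tr, lp1$point, 1e-9)
  # GO with transformed outward hints
  go0 <- landmark_xyz(detect_gonion(tm, rois$ramus_border_L, rois$corpus_border_L, "L"),
                      "GO", "L")
  go1 <- landmark_xyz(
    detect_gonion(moved, roi_indices(tm, rois$ramus_border_L),
                  roi_indices(tm, rois$corpus_border_L), "L",
                  outward_posterior = as.vector(R %*% c(-1, 0, 0)),
                  outward_inferior = as.vector(R %*% c(0, 0, -1))),
    "GO", "L")
  expect_points_close(as.numeric(R %*% go0) + tr, go1, 1e-6)
})

test_that("manual landmark ingestion validates, snaps and reports rejections", {
  tm <- template_fixture()
  truth <- template_ground_truth(tm)
  man <- truth[truth$code %in% c("AMF", "MMF", "PMF", "NO"), ]
  path <- withr::local_tempfile(fileext = ".csv")
  off <- man
  off$x_mm[1] <- off$x_mm[1] + 0.4   # within snap tolerance
  bad <- off[1, ]; bad$code <- "XXX"; bad$side <- "L"
  far <- off[2, ]; far$code <- "NO"; far$side <- "M"; far$x_mm <- far$x_mm + 50
  utils::write.csv(rbind(off, bad, far), path, row.names = FALSE)
  res <- load_manual_landmarks(path, tm)
  expect_equal(nrow(res$landmarks), 8L)
  expect_equal(nrow(res$rejected), 2L)
  expect_match(res$rejected$reason[res$rejected$code == "XXX"], "unknown")
  expect_match(res$rejected$reason[2], "off surface")
  # snapped back onto the surface
  expect_points_close(as.numeric(res$landmarks[1, c("x_mm", "y_mm", "z_mm")]),
                      as.numeric(man[1, c("x_mm", "y_mm", "z_mm")]), 1e-9)
  auto <- detect_all_landmarks(tm)
  merged <- merge_landmarks(auto, res$landmarks)
  expect_silent(validate_landmark_set(merged))
  expect_equal(nrow(merged), 17L)
  expect_error(merge_landmarks(auto, auto), "both")
  dup <- rbind(man, man[1, ])
  utils::write.csv(dup, path, row.names = FALSE)
  expect_error(load_manual_landmarks(path, tm), "duplicate")
})

test_that("noise-free recovery: every auto landmark matches ground truth", {
  st <- generate_study(n_subjects = 1, n_timepoints = 4,
                       model = growth_model(seed = 21), resolution = 1800)
  for (t in st$timepoints) {
    det <- detect_all_landmarks(st$meshes[[1]][[t]])
    tr <- st$truth[st$truth$timepoint == t, ]
    for (i in seq_len(nrow(det))) {
      expect_lt(sqrt(sum((as.numeric(det[i, c("x_mm", "y_mm", "z_mm")]) -
                            landmark_xyz(tr, det$code[i], det$side[i]))^2)),
                0.5)
    }
  }
})
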