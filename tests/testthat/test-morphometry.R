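# Segment catalog, distances, angles, full measurement.

make_lm <- function(code, side, x, y, z) {
  tibble::tibble(code = code, side = side, x_mm = x, y_mm = y, z_mm = z,
                 source = "truth")
}

test_that("inter-marker distance is Euclidean in cm with side-rule resolution", {
  lm <- rbind(make_lm("AMF", "L", 0, 0, 0), make_lm("GO", "L", 30, 40, 0))
  cat <- segment_catalog()
  def <- cat$distances[cat$distances$name == "AMF-GO", ]
  expect_equal(inter_marker_distance(lm, def, "L"), 5.0)
  lm2 <- rbind(make_lm("AMF", "L", 1, 2, 3), make_lm("AMF", "R", 1, 2, 3))
  defb <- cat$distances[cat$distances$name == "Bi-AMF", ]
  expect_warning(d0 <- inter_marker_distance(lm2, defb), "degenerate")
  expect_equal(d0, 0)
  expect_error(inter_marker_distance(lm, def, "R"), "missing")
})

test_that("inter-segmental angles cover right, straight and equilateral cases", {
  cat <- segment_catalog()
  def <- cat$angles[cat$angles$name == "LP-GO-AMF", ]
  lm <- rbind(make_lm("GO", "L", 0, 0, 0), make_lm("LP", "L", 1, 0, 0),
              make_lm("AMF", "L", 0, 0, 1))
  expect_equal(inter_segment_angle(lm, def, "L"), 90)
  lm$x_mm[lm$code == "AMF"] <- -1; lm$z_mm[lm$code == "AMF"] <- 0
  expect_equal(inter_segment_angle(lm, def, "L"), 180)
  lm2 <- rbind(make_lm("GO", "L", 0, 0, 0), make_lm("LP", "L", 1, 0, 0),
               make_lm("AMF", "L", 0.5, sqrt(3) / 2, 0))
  expect_equal(inter_segment_angle(lm2, def, "L"), 60, tolerance = 1e-9)
  lm3 <- rbind(make_lm("GO", "L", 0, 0, 0), make_lm("LP", "L", 0, 0, 0),
               make_lm("AMF", "L", 1, 1, 1))
  expect_error(inter_segment_angle(lm3, def, "L"), "coincides")
})

test_that("the default catalog matches the standard inventory", {
  cat <- segment_catalog()
  expect_equal(nrow(cat$distances), 25L)
  expect_equal(sum(cat$distances$group == "AP"), 9L)
  expect_equal(sum(cat$distances$group == "SI"), 3L)
  expect_equal(sum(cat$distances$group == "AI"), 6L)
  expect_equal(sum(cat$distances$group == "ML"), 7L)
  expect_equal(sum(cat$distances$side_rule == "bilateral"), 7L)
  expect_equal(nrow(cat$angles), 2L)
  expect_equal(sum(!is.na(cat$distances$subgroup)), 9L)   # AP subgroups
})

test_that("measure_all resolves all 25 distances plus angles and volume", {
  tm <- template_fixture()
  lm <- template_ground_truth(tm)
  m <- measure_all(lm, tm)
  dist_names <- unique(m$parameter[m$units == "cm"])
  expect_length(dist_names, 25L)
  uni <- m[m$units == "cm" & m$side %in% c("L", "R", "mean"), ]
  expect_true(all(table(uni$parameter) == 3L))
  expect_equal(sum(m$units == "deg"), 4L)   # LP-GO-AMF L/R/mean + Bi-GO-GT
  expect_equal(sum(m$parameter == "Volume"), 1L)
  expect_true(all(m$value[m$units == "cm"] > 0))
  ang <- m$value[m$units == "deg"]
  expect_true(all(ang > 0 & ang < 180))
  # bilateral symmetry of the template: left equals right
  left <- uni$value[uni$side == "L"]; right <- uni$value[uni$side == "R"]
  expect_equal(left, right, tolerance = 1e-9)
  # single-pair catalog
  small <- segment_catalog()
  small$distances <- small$distances[small$distances$name == "GO-CP", ]
  small$angles <- small$angles[0, ]
  m2 <- measure_all(lm, tm, small)
  expect_setequal(unique(m2$parameter), c("GO-CP", "Volume"))
})

test_that("measurements are rigid-motion invariant and scale with units", {
  tm <- template_fixture()
  lm <- template_ground_truth(tm)
  m0 <- measure_all(lm, tm)
  R <- random_rotation(8); tr <- c(12, -4, 6)
  tm2 <- transform_mesh(tm, R, tr)
  xyz <- as.matrix(lm[, c("x_mm", "y_mm", "z_mm")]) %*% t(R)
  lm2 <- lm
  lm2$x_mm <- xyz[, 1] + tr[1]; lm2$y_mm <- xyz[, 2] + tr[2]; lm2$z_mm <- xyz[, 3] + tr[3]
  m1 <- measure_all(lm2, tm2)
  expect_equal(m1$value, m0$value, tolerance = 1e-9)
  # isotropic x10: distances x10, volume x1000, angles unchanged
  tm3 <- tm; tm3$vertices <- tm$vertices * 10
  lm3 <- lm
  lm3$x_mm <- lm$x_mm * 10; lm3$y_mm <- lm$y_mm * 10; lm3$z_mm <- lm$z_mm * 10
  m3 <- measure_all(lm3, tm3)
  f <- ifelse(m0$units == "cm", 10, ifelse(m0$units == "cm3", 1000, 1))
  expect_equal(m3$value, m0$value * f, tolerance = 1e-9)
})

test_that("missing endpoints propagate with the parameter name attached", {
  tm <- template_fixture()
  lm <- template_ground_truth(tm)
  expect_error(measure_all(lm[lm$code != "GO", ], tm), "missing landmark")
})
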