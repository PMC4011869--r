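# Synthetic mandible template, growth deformation, study generation.

test_that("template is a watertight, bilaterally symmetric genus-0 surface", {
  tm <- template_fixture()
  expect_true(is_watertight(tm))
  expect_identical(euler_characteristic(tm), 2L)
  v <- tm$vertices
  mirrored <- v %*% diag(c(1, -1, 1))
  nn <- vapply(seq_len(nrow(v)), function(i)
    min(sqrt(rowSums(sweep(v, 2, mirrored[i, ])^2))), numeric(1))
  expect_lt(max(nn), 1e-6)
  expect_lt(max(abs(colMeans(v))), 1e-6)   # canonical frame: centroid origin
})

test_that("template volume matches the voxel-count oracle within 2%", {
  tm <- template_fixture()
  expect_equal(voxel_count_volume(tm, 0.2), mesh_volume(tm), tolerance = 0.02)
})

test_that("unmeetable resolution fails explicitly", {
  expect_error(generate_template_mesh(resolution = 200), "resolution")
})

test_that("growth at t = 1 is the identity and the time curve saturates", {
  tm <- template_fixture()
  g <- grow_mesh(tm, growth_model(), 1)
  expect_equal(g$mesh$vertices, tm$vertices, tolerance = 1e-12)
  tau <- growth_time_curve(1:12)
  expect_equal(tau[1], 0)
  expect_equal(tau[12], 1)
  expect_true(all(diff(tau) > 0))
  expect_true(all(diff(diff(tau)) < 0))      # decelerating monthly growth
  expect_gt(tau[4], 0.5)                     # about half the change by month 4
  expect_lt(tau[4], 0.6)
})

test_that("equal isotropic rates give an exact similarity at every timepoint", {
  tm <- template_fixture()
  r <- 0.8
  iso <- growth_model(region_rates = lapply(default_region_rates(), function(x)
    c(ap = r, si = r, ml = r)))
  truth <- template_ground_truth(tm)
  for (t in c(4, 12)) {
    g <- grow_mesh(tm, iso, t, landmarks = truth)
    s <- 1 + r * growth_time_curve(t)
    expect_equal(g$mesh$vertices, tm$vertices * s, tolerance = 1e-9)
    # every inter-landmark distance multiplied by exactly the same factor
    p0 <- as.matrix(truth[, c("x_mm", "y_mm", "z_mm")])
    p1 <- as.matrix(g$landmarks[, c("x_mm", "y_mm", "z_mm")])
    d0 <- as.matrix(stats::dist(p0)); d1 <- as.matrix(stats::dist(p1))
    expect_equal(d1, d0 * s, tolerance = 1e-6)
    # conservation under similarity: angles unchanged
    m0 <- measure_all(truth, catalog = segment_catalog())
    lm1 <- g$landmarks
    m1 <- measure_all(lm1, catalog = segment_catalog())
    a0 <- m0$value[m0$units == "deg"]; a1 <- m1$value[m1$units == "deg"]
    expect_lt(max(abs(a1 - a0)), 1e-6)
  }
})

test_that("doubling ramus SI over body AP makes ramus-height growth dominate", {
  tm <- template_fixture()
  rates <- list(
    anterior = c(ap = 0.5, si = 0.5, ml = 0.5),
    body     = c(ap = 0.5, si = 0.5, ml = 0.5),
    ramus    = c(ap = 0.5, si = 1.0, ml = 0.5),
    condyle  = c(ap = 0.5, si = 1.0, ml = 0.5),
    coronoid = c(ap = 0.5, si = 1.0, ml = 0.5)
  )
  g <- grow_mesh(tm, growth_model(region_rates = rates), 12)
  cat <- segment_catalog()
  def_si <- cat$distances[cat$distances$name == "GO-CP", ]
  def_ap <- cat$distances[cat$distances$name == "AMF-MMF", ]
  truth <- template_ground_truth(tm)
  n_si <- inter_marker_distance(g$landmarks, def_si) /
    inter_marker_distance(truth, def_si) - 1
  n_ap <- inter_marker_distance(g$landmarks, def_ap) /
    inter_marker_distance(truth, def_ap) - 1
  expect_gt(n_si, n_ap)
})

test_that("generate_study produces the full factorial design deterministically", {
  model <- growth_model(seed = 5)
  st1 <- generate_study(n_subjects = 2, n_timepoints = 3, model = model,
                        resolution = 1200)
  expect_length(st1$subjects, 2L)
  expect_equal(nrow(st1$truth), 2 * 3 * 17)
  expect_true(all(table(st1$truth$subject, st1$truth$timepoint) == 17))
  st2 <- generate_study(n_subjects = 2, n_timepoints = 3, model = model,
                        resolution = 1200)
  expect_identical(st1$truth, st2$truth)
  expect_identical(st1$manifest, st2$manifest)
  expect_identical(st1$meshes[[1]][[3]]$vertices, st2$meshes[[1]][[3]]$vertices)
  # noise-free volumes strictly increase with timepoint
  for (s in st1$subjects) {
    v <- st1$volumes_cm3$volume_cm3[st1$volumes_cm3$subject == s]
    expect_true(all(diff(v) > 0))
  }
})

test_that("two-timepoint studies reduce to a single-interval change", {
  st <- generate_study(n_subjects = 1, n_timepoints = 2,
                       model = growth_model(seed = 3), resolution = 1200)
  m <- measure_study(st, landmark_source = "truth", volume = FALSE)
  s <- study_growth_summaries(m)
  expect_true(all(s$total_change == s$final - s$initial))
  expect_true(all(s$half_growth_month[s$total_change != 0] == 2))
})

test_that("study files round-trip through the PLY/CSV/JSON bundle", {
  dir <- withr::local_tempdir()
  st <- generate_study(n_subjects = 1, n_timepoints = 2,
                       model = growth_model(seed = 9), resolution = 1200,
                       out_dir = file.path(dir, "study"))
  files <- list.files(file.path(dir, "study"))
  expect_true(all(c("S01_T01.ply", "S01_T02.ply", "landmarks_truth.csv",
                    "landmarks_manual.csv", "manifest.json") %in% files))
  back <- read_mesh(file.path(dir, "study", "S01_T02.ply"))
  expect_lt(max(abs(back$vertices - st$meshes[[1]][[2]]$vertices)), 1e-6)
  expect_error(generate_study(n_subjects = 1, n_timepoints = 2,
                              model = growth_model(seed = 9), resolution = 1200,
                              out_dir = file.path(dir, "study")),
               "overwrite")
})
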