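# Longitudinal growth summaries and orientation statistics.

test_that("normalized total change reproduces the reference ramus-height example", {
  # series with initial 2.99 cm and final 7.40 cm
  v <- seq(2.99, 7.40, length.out = 12)
  gs <- growth_summary(v)
  expect_equal(gs$normalized_total_change, (7.40 - 2.99) / 2.99, tolerance = 1e-12)
  expect_equal(round(gs$normalized_total_change, 2), 1.47)
})

test_that("constant and linear series have the stated closed forms", {
  gs0 <- growth_summary(rep(4.2, 12))
  expect_equal(gs0$total_change, 0)
  expect_equal(gs0$normalized_total_change, 0)
  expect_true(all(gs0$monthly_change[-1] == 0))
  expect_false(gs0$percent_defined)
  expect_true(is.na(gs0$half_growth_month))
  gs <- growth_summary(1:12)
  expect_true(all(gs$monthly_change[-1] == 1))
  expect_equal(gs$half_growth_month, 7L)
  expect_equal(gs$percent_of_change[4], 100 * 3 / 11, tolerance = 1e-12)
  expect_equal(gs$percent_of_change[1], 0)
  expect_equal(gs$percent_of_change[12], 100)
})

test_that("monthly changes telescope and summaries are unit- and scale-free", {
  set.seed(31)
  for (k in 1:5) {
    v <- cumsum(abs(stats::rnorm(12))) + 1
    gs <- growth_summary(v)
    expect_equal(sum(gs$monthly_change[-1]), gs$total_change, tolerance = 1e-12)
    c0 <- stats::runif(1, 0.1, 10)
    gs_scaled <- growth_summary(v * c0)
    expect_equal(gs_scaled$normalized_total_change, gs$normalized_total_change,
                 tolerance = 1e-12)
    expect_equal(gs_scaled$percent_of_change, gs$percent_of_change,
                 tolerance = 1e-9)
  }
  expect_error(growth_summary(c(1, NA, 3)), "missing")
  expect_error(growth_summary(5), "at least 2")
})

test_that("group means over the bundled reference table reproduce its printed values", {
  arith <- growth_reference_arithmetic()
  g <- arith$groups
  expect_equal(g$recomputed[g$name == "AP"], 1.32, tolerance = 0.005)
  expect_equal(g$recomputed[g$name == "Posterior (Ramus)"], 1.45, tolerance = 0.005)
  expect_true(all(abs(g$deviation) <= 0.01))
  # single-member group behavior
  s <- tibble::tibble(subject = "S01", parameter = "GO-CP", group = "SI",
                      subgroup = NA, units = "cm", initial = 1, final = 2,
                      total_change = 1, normalized_total_change = 1,
                      half_growth_month = 4)
  gm <- group_summary(s)
  expect_equal(gm$group_means$mean, 1)
  expect_true(is.na(gm$group_means$sd))
})

test_that("rm-ANOVA degenerates to F = 0, p = 1 when groups are identical", {
  d <- tibble::tibble(subject = rep(sprintf("S%d", 1:5), each = 4),
                      group = rep(c("AP", "SI", "AI", "ML"), 5),
                      value = rep(stats::runif(5), each = 4))
  a <- rm_anova_orientation(d)
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  expect_null(a$pairwise)
})

test_that("rm-ANOVA F equals the sums-of-squares oracle to 1e-9", {
  set.seed(61)
  for (k in 1:3) {
    Y <- matrix(stats::rnorm(32, mean = rep(c(0, 0.5, 1, 0.2), each = 8)), 8, 4)
    colnames(Y) <- c("AP", "SI", "AI", "ML")
    d <- tibble::tibble(subject = rep(sprintf("S%d", 1:8), times = 4),
                        group = rep(colnames(Y), each = 8),
                        value = as.vector(Y))
    a <- rm_anova_orientation(d)
    grand <- mean(Y)
    ssg <- 8 * sum((colMeans(Y) - grand)^2)
    sss <- 4 * sum((rowMeans(Y) - grand)^2)
    sse <- sum((Y - grand)^2) - ssg - sss
    F_oracle <- (ssg / 3) / (sse / 21)
    expect_lt(abs(a$F - F_oracle), 1e-9)
    expect_equal(a$df, c(num = 3, den = 21))
  }
})

test_that("pairwise tests appear only after a significant omnibus and use 0.05/6", {
  set.seed(77)
  subj_eff <- stats::rnorm(8, 0, 0.02)
  d <- tibble::tibble(subject = rep(sprintf("S%d", 1:8), times = 4),
                      group = rep(c("AP", "SI", "AI", "ML"), each = 8),
                      value = rep(c(1.3, 1.35, 1.15, 0.6), each = 8) +
                        rep(subj_eff, 4) + stats::rnorm(32, 0, 0.02))
  a <- rm_anova_orientation(d)
  expect_lt(a$p, 0.05)
  expect_equal(nrow(a$pairwise), 6L)
  expect_equal(a$bonferroni_alpha, 0.05 / 6)
  expect_lt(abs(a$bonferroni_alpha - 0.0082), 2e-4)   # printed 2 s.f. form
  pair_sets <- strsplit(a$pairwise$pair, "-")
  has_pair <- function(g1, g2)
    a$pairwise$significant[vapply(pair_sets, setequal, logical(1), c(g1, g2))]
  expect_true(has_pair("AP", "ML"))
  expect_true(has_pair("SI", "ML"))
  expect_error(rm_anova_orientation(d[d$subject %in% c("S1", "S2"), ]),
               "at least 3")
  expect_error(rm_anova_orientation(d[-1, ]), "missing cells")
})

test_that("dose budget arithmetic matches the published cumulative doses", {
  expect_equal(dose_budget(263, 12), 3.156)
  expect_equal(dose_budget(182.1, 12), 2.1852)
  expect_equal(round(dose_budget(182.1, 12), 3), 2.185)
  expect_equal(dose_budget(500, 0), 0)
  expect_error(dose_budget(-1, 2))
})
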