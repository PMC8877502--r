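test_that("Laurdan ratios divide pointwise and reject zero denominators", {
  df <- data.frame(temperature = c(15, 30, 45),
                   f440 = c(2, 1, 0.5), f490 = c(1, 1, 1))
  got <- laurdan_ratio(df)
  expect_equal(got$ratio, c(2, 1, 0.5))

  same <- laurdan_ratio(data.frame(temperature = 1:4, f440 = 3, f490 = 3))
  expect_true(all(same$ratio == 1))

  # monotone inputs give monotone ratios
  set.seed(2)
  f440 <- sort(runif(10, 1, 5), decreasing = TRUE)
  dec <- laurdan_ratio(data.frame(temperature = 1:10, f440 = f440, f490 = 2))
  expect_true(all(diff(dec$ratio) < 0))

  expect_error(
    laurdan_ratio(data.frame(temperature = 1, f440 = 1, f490 = 0)),
    class = "ticdiff_config_error"
  )
})

test_that("acyl percentages exclude the internal standard and sum to 100", {
  got <- acyl_percentages(c("C16:0" = 30, "C18:1" = 50, "C18:3n3" = 20))
  expect_equal(got$percentage, c(30, 50, 20))
  expect_equal(sum(got$percentage), 100, tolerance = 1e-6)

  one <- acyl_percentages(c("C18:1" = 7.3))
  expect_equal(one$percentage, 100)

  # with the C17:1 internal standard present in the table
  with_is <- acyl_percentages(
    c("C16:0" = 30, "C17:1" = 999, "C18:1" = 50, "C18:3n3" = 20)
  )
  expect_false("C17:1" %in% with_is$chain)
  expect_equal(sum(with_is$percentage), 100, tolerance = 1e-6)
  expect_equal(with_is$rel_internal_standard, c(30, 50, 20) / 999)

  # chain ratios agree whether computed from percentages or raw areas
  set.seed(6)
  for (i in 1:5) {
    areas <- setNames(runif(4, 1, 100),
                      c("C16:0", "C18:1", "C18:2", "C18:3n3"))
    p <- acyl_percentages(areas)
    r_pct <- p$percentage[p$chain == "C18:1"] /
      p$percentage[p$chain == "C18:3n3"]
    expect_equal(r_pct, unname(areas["C18:1"] / areas["C18:3n3"]),
                 tolerance = 1e-12)
  }

  expect_error(acyl_percentages(c("C16:0" = 0, "C18:1" = 0)),
               class = "ticdiff_config_error")
})

test_that("relative ergosterol is scale-invariant and referenced to 100%", {
  expect_equal(ergosterol_relative(sterol_normalized(1.2, 1),
                                   sterol_normalized(2.0, 1)), 60)
  expect_equal(ergosterol_relative(1.5, 1.5), 100)
  set.seed(11)
  for (i in 1:10) {
    a <- runif(4, 0.1, 10)  # sample erg/IS, reference erg/IS areas
    g1 <- runif(1, 0.5, 20); g2 <- runif(1, 0.5, 20)
    base <- ergosterol_relative(sterol_normalized(a[1], a[2]),
                                sterol_normalized(a[3], a[4]))
    scaled <- ergosterol_relative(sterol_normalized(g1 * a[1], g1 * a[2]),
                                  sterol_normalized(g2 * a[3], g2 * a[4]))
    expect_equal(base, scaled, tolerance = 1e-12)
  }
  expect_error(ergosterol_relative(1, 0), class = "ticdiff_config_error")
})

test_that("catalase units follow the unit definition and scale correctly", {
  expect_equal(catalase_units(30, 2, 0.5), 30)
  expect_equal(catalase_units(1, 1, 1), 1)
  set.seed(13)
  for (i in 1:5) {
    u <- runif(3, 0.1, 50)
    expect_equal(catalase_units(u[1], u[2], 2 * u[3]),
                 catalase_units(u[1], u[2], u[3]) / 2, tolerance = 1e-12)
  }
  expect_error(catalase_units(10, 0, 1), class = "ticdiff_config_error")
})

test_that("relative ROS normalises to protein and ignores fluorometer gain", {
  expect_equal(ros_relative(5, 2, 5, 2), 100)
  expect_equal(ros_relative(1.5, 1, 1, 1), 150)
  set.seed(15)
  for (i in 1:5) {
    v <- runif(4, 0.1, 10)
    gain <- runif(1, 0.5, 50)
    expect_equal(ros_relative(v[1], v[2], v[3], v[4]),
                 ros_relative(gain * v[1], v[2], gain * v[3], v[4]),
                 tolerance = 1e-12)
  }
  expect_error(ros_relative(1, 0, 1, 1), class = "ticdiff_config_error")
})

test_that("assay comparison offers pooled (default) and Welch variants", {
  set.seed(19)
  x <- c(rnorm(4, 45.8, 3), rnorm(4, 95.5, 20))
  g <- rep(c("WT", "mutant"), each = 4)
  pooled <- assay_compare(x, g, pooled = TRUE)
  welch <- assay_compare(x, g, pooled = FALSE)
  expect_equal(pooled$df, 6)
  expect_lt(welch$df, 6)
  expect_equal(pooled$estimate,
               mean(x[g == pooled$group1]) - mean(x[g == pooled$group2]),
               tolerance = 1e-12)
})
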