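test_that("the six-protein fixture reproduces the hand-worked arithmetic", {
  des <- two_strain_design(2)
  e <- 0.1
  lg <- rbind(
    P1 = c(10 + e, 10 - e, 10 + e, 10 - e),
    P2 = c(10 - e, 10 + e, 10 - e, 10 + e),
    P3 = c(12 + e, 12 - e, 12 + e, 12 - e),
    P4 = c(12 - e, 12 + e, 12 - e, 12 + e),
    P5 = c(11, 11, 11, 11),
    P6 = c(10, 10, 12, 12)
  )
  colnames(lg) <- c("WT_r1", "WT_r2", "mut_r1", "mut_r2")
  res <- wstat_diff(tic_matrix(lg, des))

  # independent spreadsheet-style recomputation
  r_pool <- c(c(.2, -.2, .2, -.2, 0, 0), c(.2, -.2, .2, -.2, 0, 0))
  noise <- sd(r_pool)
  expect_equal(attr(res, "noise"), noise, tolerance = 1e-12)
  # z0 = z1 = (0,0,0,0,0,2); centering subtracts 1/3
  z0c <- c(rep(-1 / 3, 5), 5 / 3)
  expect_equal(res$mean_diff, (z0c + z0c) / 2, tolerance = 1e-12)
  expect_equal(res$snr, abs(2 * z0c) / noise, tolerance = 1e-12)

  # the shifted protein attains the maximum snr and is flagged up
  expect_equal(res$protein_id[which.max(res$snr)], "P6")
  expect_gte(abs(res$mean_diff[res$protein_id == "P6"]), 1)
  expect_equal(res$direction[res$protein_id == "P6"], "more-abundant")
  expect_equal(sum(res$flagged), 1L)
})

test_that("degenerate replicate populations raise a statistical error", {
  des <- two_strain_design(2)
  lg <- matrix(10, nrow = 5, ncol = 4,
               dimnames = list(paste0("P", 1:5),
                               c("WT_r1", "WT_r2", "mut_r1", "mut_r2")))
  expect_error(wstat_diff(tic_matrix(lg, des)),
               class = "ticdiff_stat_error")
  expect_error(wstat_diff(tic_matrix(lg[, 1:3], two_strain_design(1))),
               class = "ticdiff_design_error")
})

test_that("difference populations are centred and run offsets cancel", {
  des <- two_strain_design(2)
  set.seed(12)
  lg <- matrix(rnorm(400 * 4, 10, 1), ncol = 4,
               dimnames = list(NULL, des$sample_id))
  res <- wstat_diff(tic_matrix(lg, des))
  expect_lt(abs(mean(res$mean_diff)), 1e-9)

  lg_off <- lg
  lg_off[, "mut_r2"] <- lg_off[, "mut_r2"] + 5
  res_off <- wstat_diff(tic_matrix(lg_off, des))
  expect_equal(res$snr, res_off$snr, tolerance = 1e-9)
  expect_equal(res$mean_diff, res_off$mean_diff, tolerance = 1e-9)
  expect_equal(res$flagged, res_off$flagged)
})

test_that("fold-change filter keeps |mean_diff| >= cutoff inclusively", {
  res <- tibble::tibble(
    protein_id = sprintf("P%02d", 1:10),
    mean_diff = c(1.0, -1.0, 0.99, -0.99, 2.5, 0.5, -3, 0, 0.999999, 1.2)
  )
  kept <- fold_change_filter(res, 1)
  expect_equal(nrow(kept), 5L)
  expect_true("P01" %in% kept$protein_id)  # exactly two-fold retained
  expect_false("P03" %in% kept$protein_id)
  expect_error(fold_change_filter(res, -1), class = "ticdiff_config_error")
})

test_that("null calibration of the S/N rule sits just under 5%", {
  frac <- null_calibration(100000, seed = 23, procedure = "wstat")
  analytic <- 2 * (1 - pnorm(2.8 / sqrt(2)))
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.055)
  # 3 Monte-Carlo SEs around the analytic tail probability
  expect_lt(abs(frac - analytic), 3 * sqrt(analytic * (1 - analytic) / 1e5))
})

test_that("power is monotone in effect size and flagged signs are correct", {
  des <- two_strain_design(2)
  set.seed(77)
  n <- 1500
  noise_mat <- matrix(rnorm(n * 4, 0, 0.3), ncol = 4)
  base <- rnorm(n, 10, 2)
  power <- vapply(c(0.25, 0.5, 1, 2), function(delta) {
    # up-shift a subset of proteins in the mutant runs
    lg2 <- base + noise_mat
    idx <- seq_len(150)
    lg2[idx, 3:4] <- lg2[idx, 3:4] + delta
    colnames(lg2) <- des$sample_id
    res2 <- wstat_diff(tic_matrix(lg2, des), fc_cutoff = 0)
    expect_true(all(res2$direction[idx][res2$flagged[idx]] ==
                      "more-abundant"))
    mean(res2$flagged[idx])
  }, double(1))
  expect_true(all(diff(power) >= 0))
  expect_gt(power[4], 0.9)
})

test_that("snr and mean_diff are invariant to the arbitrary replicate pairing", {
  # z0 + z1 contains every between-strain difference once under either
  # pairing, so only the per-replicate columns change
  des <- two_strain_design(2)
  set.seed(3)
  lg <- matrix(rnorm(200 * 4, 10, 0.5), ncol = 4,
               dimnames = list(NULL, des$sample_id))
  res_m <- wstat_diff(tic_matrix(lg, des), pairing = "matched")
  res_c <- wstat_diff(tic_matrix(lg, des), pairing = "crossed")
  expect_equal(attr(res_m, "noise"), attr(res_c, "noise"))
  expect_equal(res_m$snr, res_c$snr, tolerance = 1e-12)
  expect_equal(res_m$mean_diff, res_c$mean_diff, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(res_m$z0, res_c$z0)))
})
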