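test_that("a zero horizon yields zero change everywhere", {
  dd <- degenerate_draws()
  grid <- generate_covariate_grid(3, 3, type = "uniform")
  pred <- predict_recovery_map(dd$survivors, dd$recruits, grid,
                               wide_moments(), horizon = 0, n_rep = 5,
                               seed = 1)
  expect_true(all(pred$flux == 0))
  expect_true(all(net_recovery(pred$flux) == 0))
})

test_that("degenerate draws give identical replicates and zero CV", {
  dd <- degenerate_draws()
  grid <- generate_covariate_grid(4, 5, type = "uniform")
  pred <- predict_recovery_map(dd$survivors, dd$recruits, grid,
                               wide_moments(), n_rep = 10, seed = 1)
  for (r in 2:10)
    expect_equal(pred$flux[, , r], pred$flux[, , 1])
  s <- summarize_grid(pred)
  expect_true(all(s$cv == 0))
  expect_true(all(s$net_sd == 0))
  # uniform covariates: spatially constant medians
  expect_length(unique(s$net_median), 1)
  expect_length(unique(s$cSg_median), 1)
})

test_that("net recovery is the sum of the five cumulative changes", {
  expect_equal(net_recovery(c(10, -4, 3, 2, -1)), 10)
  expect_equal(net_recovery(rep(0, 5)), 0)
  dd <- degenerate_draws()
  grid <- generate_covariate_grid(3, 4, type = "gradient")
  pred <- predict_recovery_map(dd$survivors, dd$recruits, grid,
                               wide_moments(), n_rep = 4, seed = 2)
  net <- net_recovery(pred$flux)
  manual <- apply(pred$flux, c(1, 3), sum)
  expect_equal(net, manual)
  # summation commutes with replicate means
  s <- summarize_grid(pred)
  per_flux_mean <- apply(pred$flux, c(1, 2), mean)
  expect_equal(s$net_mean, rowSums(per_flux_mean))
})

test_that("the loss scenario drives the survivor-loss asymptote constraint", {
  dd <- degenerate_draws()
  grid <- generate_covariate_grid(2, 2, type = "uniform")
  pred <- predict_recovery_map(dd$survivors, dd$recruits, grid,
                               wide_moments(), loss = 40, n_rep = 3,
                               seed = 3)
  # acs_min is 60% of the pixel's pre-disturbance stock
  expect_equal(pred$acs_min, 0.6 * grid$acs0)
  for (r in 1:3) {
    p <- pred$params[[r]]
    expect_equal(p$a_sl, -(p$a_sg + pred$acs_min))
    expect_equal(p$a_rl, -(p$a_rr + p$a_rg))
  }
})

test_that("predictions are invariant to pixel ordering and reproducible", {
  sf <- shared_fits()
  grid <- generate_covariate_grid(3, 3, type = "gradient")
  mom <- covariate_moments(sf$data$covariates)
  p1 <- suppressWarnings(
    predict_recovery_map(sf$survivors, sf$recruits, grid, mom, n_rep = 8,
                         seed = 9))
  perm <- sample(nrow(grid))
  p2 <- suppressWarnings(
    predict_recovery_map(sf$survivors, sf$recruits, grid[perm, ], mom,
                         n_rep = 8, seed = 9))
  expect_equal(p2$flux, p1$flux[perm, , , drop = FALSE])
  p3 <- suppressWarnings(
    predict_recovery_map(sf$survivors, sf$recruits, grid, mom, n_rep = 8,
                         seed = 9))
  expect_identical(p1$flux, p3$flux)
  # net recovery correlates with the survivors' growth field (statistic
  # must be computable on a gradient grid)
  s <- summarize_grid(p3)
  rho <- cor(s$net_median, s$cSg_median)
  expect_true(is.finite(rho))
})

test_that("pixel covariates outside the calibration range warn but run", {
  sf <- shared_fits()
  mom <- covariate_moments(sf$data$covariates)
  # all covariates at their calibration means, then push one out of range
  grid <- data.frame(row = c(1, 1, 2, 2), col = c(1, 2, 1, 2),
                     acs0 = mom$mean[mom$covariate == "acs0"],
                     prec = mom$max[mom$covariate == "prec"] * 2,
                     seas = mom$mean[mom$covariate == "seas"],
                     bd = mom$mean[mom$covariate == "bd"])
  expect_warning(
    predict_recovery_map(sf$survivors, sf$recruits, grid, mom, n_rep = 3,
                         seed = 1),
    "extrapolation")
})

test_that("regional summaries aggregate pixels and flag late horizons", {
  dd <- degenerate_draws()
  grid <- generate_covariate_grid(3, 3, type = "gradient")
  pred <- predict_recovery_map(dd$survivors, dd$recruits, grid,
                               wide_moments(), n_rep = 4, seed = 5)
  rs <- regional_summary(pred, list(one = 5L, all = rep(TRUE, 9)),
                         horizons = c(0, 10, 35))
  # single-pixel region equals that pixel's summary
  s <- summarize_grid(pred)
  expect_equal(rs$summary$net_mean_pixels[1], s$net_median[5])
  expect_equal(rs$summary$net_sd_pixels[2], sd(s$net_median))
  expect_true(all(rs$summary$survivors_share >= 0 &
                    rs$summary$survivors_share <= 1))
  # horizons beyond the calibration period are flagged
  tr <- rs$trajectories
  expect_true(all(tr$out_of_calibration[tr$t == 35]))
  expect_false(any(tr$out_of_calibration[tr$t <= 30]))
  expect_error(regional_summary(pred, list(bad = integer(0))), "empty")
  expect_error(regional_summary(pred, list(bad = 99L)), "extent")
})

test_that("survivors' share is total when recruits contribute nothing", {
  # recruit asymptotes at (near) zero: all gain comes from survivors
  dd <- degenerate_draws(alpha0_Rr = 1e-12, alpha0_Rg = 1e-12)
  grid <- generate_covariate_grid(2, 2, type = "uniform")
  pred <- predict_recovery_map(dd$survivors, dd$recruits, grid,
                               wide_moments(), n_rep = 3, seed = 1)
  rs <- regional_summary(pred, list(all = rep(TRUE, 4)))
  expect_equal(rs$summary$survivors_share, 1, tolerance = 1e-9)
})

test_that("single-pixel prediction matches the map pathway", {
  dd <- degenerate_draws()
  px <- data.frame(acs0 = 250, prec = 2000, seas = 60, bd = 1.2)
  reps <- pixel_predict(px, dd$survivors, dd$recruits, wide_moments(),
                        n_rep = 4, seed = 3)
  expect_equal(dim(reps), c(4L, 5L))
  g <- data.frame(row = 1, col = 1, px)
  pm <- predict_recovery_map(dd$survivors, dd$recruits, g, wide_moments(),
                             n_rep = 4, seed = 3)
  expect_equal(unname(reps), unname(t(pm$flux[1, , ])))
})
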