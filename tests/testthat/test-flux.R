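test_that("recovery start is the windowed post-logging ACS minimum", {
  # minimum inside the window
  r <- detect_recovery_start(c(1, 3, 5), c(200, 180, 185), logging_time = 0)
  expect_false(r$excluded)
  expect_equal(r$t0, 3)
  expect_equal(r$acs_min, 180)
  # global minimum after the window: plot excluded
  r <- detect_recovery_start(c(1, 3, 6), c(200, 190, 150), logging_time = 0)
  expect_true(r$excluded)
  expect_match(r$reason, "after the window")
  # strictly increasing series: first post-logging census wins
  r <- detect_recovery_start(c(-1, 1, 2, 8), c(250, 200, 210, 240),
                             logging_time = 0)
  expect_false(r$excluded)
  expect_equal(r$t0, 1)
  # no post-logging census at all
  r <- detect_recovery_start(c(-2, -1), c(250, 251), logging_time = 0)
  expect_true(r$excluded)
})

test_that("cohorts partition trees and membership is sticky", {
  cs <- toy_censuses()
  membership <- c(a = "survivor", b = "survivor")
  coh <- classify_cohorts(cs$prev, cs$curr, membership)
  expect_equal(coh$survivors, "a")
  expect_equal(coh$dead_survivors, "b")
  expect_equal(coh$new_recruits, "c")   # 18 -> 21 cm crossing
  expect_length(coh$dead_recruits, 0)
  expect_equal(unname(coh$membership["c"]), "recruit")
  # recruit death in a later interval feeds recruits' loss
  nxt <- transform(cs$curr, status = c("alive", "dead", "dead", "alive"))
  coh2 <- classify_cohorts(cs$curr, nxt, coh$membership)
  expect_equal(coh2$dead_recruits, "c")
  # a recruit measured back under the threshold stays a recruit
  shrunk <- transform(cs$curr, dbh = c(32, 25, 19.5, 16))
  coh3 <- classify_cohorts(cs$curr, shrunk, coh$membership)
  expect_equal(unname(coh3$membership["c"]), "recruit")
  expect_true("c" %in% coh3$recruits_alive)
})

test_that("interval fluxes reproduce a hand tally and its sign convention", {
  # one survivor grows 1.0 -> 1.2, one survivor of 0.8 dies, one recruit
  # enters at 0.3, on one hectare
  prev <- data.frame(tree_id = c("s1", "s2", "r1"),
                     dbh = c(30, 28, 18), status = "alive",
                     acs = c(1.0, 0.8, 0.2))
  curr <- data.frame(tree_id = c("s1", "s2", "r1"),
                     dbh = c(31, 28, 21),
                     status = c("alive", "dead", "alive"),
                     acs = c(1.2, NA, 0.3))
  coh <- classify_cohorts(prev, curr, c(s1 = "survivor", s2 = "survivor"))
  f <- interval_fluxes(prev, curr, coh, area = 1)
  expect_equal(f, c(Rr = 0.3, Rg = 0, Rl = 0, Sg = 0.2, Sl = -0.8))
  # nothing happened: all five are zero
  coh0 <- classify_cohorts(prev, prev, c(s1 = "survivor", s2 = "survivor"))
  expect_equal(unname(interval_fluxes(prev, prev, coh0, area = 1)),
               rep(0, 5))
  # area division
  f2 <- interval_fluxes(prev, curr, coh, area = 0.5)
  expect_equal(f2[["Sl"]], -1.6)
})

test_that("cumulative series are running sums starting at zero", {
  flux <- data.frame(t = c(0, 1, 2, 3),
                     Rr = c(0, 0.3, 0.2, 0.1), Rg = c(0, 0, 0.1, 0.2),
                     Rl = c(0, 0, -0.05, -0.1), Sg = c(0, 2, 1.5, 1),
                     Sl = c(0, -1, 0, -2))
  cf <- cumulative_fluxes(flux)
  expect_equal(cf$cRr, c(0, 0.3, 0.5, 0.6))
  # telescoping: difference of cumulative equals the interval value
  for (v in c("Rr", "Rg", "Rl", "Sg", "Sl"))
    expect_equal(diff(cf[[paste0("c", v)]]), flux[[v]][-1])
  # cumulative loss is non-increasing
  expect_true(all(diff(cf$cSl) <= 0))
})

test_that("disturbance intensity is the percent stock drop at recovery start", {
  expect_equal(disturbance_intensity(200, 120), 40)
  expect_equal(disturbance_intensity(200, 200), 0)
  expect_warning(z <- disturbance_intensity(200, 210), "clamped")
  expect_equal(z, 0)
  expect_equal(disturbance_intensity(200, 210, clamp = FALSE), -5)
})

test_that("inventory decomposition agrees with the generator's own tally", {
  gen <- generate_inventory(n_plots = 2, target_acs = 180, loss = c(30, 55),
                            n_censuses = 6, seed = 11)
  fx <- decompose_fluxes(gen$inventory, gen$wd, gen$sites, gen$plots)
  expect_s3_class(fx, "flux_series")
  tly <- gen$tally
  for (p in unique(tly$plot_id)) {
    a <- as.data.frame(fx)[fx$plot_id == p, c("t", "Rr", "Rg", "Rl", "Sg", "Sl")]
    b <- tly[tly$plot_id == p, c("t", "Rr", "Rg", "Rl", "Sg", "Sl")]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b, tolerance = 1e-12)
  }
  # sign conventions on every interval
  expect_true(all(fx$Sg >= 0 & fx$Rr >= 0 & fx$Rg >= 0))
  expect_true(all(fx$Sl <= 0 & fx$Rl <= 0))
  # cumulative columns are running sums
  for (p in unique(fx$plot_id)) {
    sub <- as.data.frame(fx)[fx$plot_id == p, ]
    expect_equal(sub$cSg, cumsum(sub$Sg))
    expect_equal(sub$cRl, cumsum(sub$Rl))
  }
  # weights are proportional to area with mean one
  m <- flux_meta(fx)
  expect_equal(mean(m$weight), 1)
  expect_equal(m$weight, m$area / mean(m$area))
})

test_that("interval mass balance: stock change equals the sum of the five fluxes", {
  gen <- generate_inventory(n_plots = 1, target_acs = 150, loss = 40,
                            n_censuses = 6, seed = 3)
  inv <- gen$inventory
  fx <- decompose_fluxes(inv, gen$wd, gen$sites, gen$plots)
  m <- flux_meta(fx)
  # recompute plot ACS directly at each census
  times <- sort(unique(inv$census_time[inv$census_time >= m$t0]))
  acs <- vapply(times, function(tt) {
    cen <- inv[inv$census_time == tt & inv$status == "alive" &
                 inv$dbh >= 20, ]
    plot_acs(cen, gen$wd, E = gen$sites$E, area = gen$plots$area[1],
             site_id = "SYN")
  }, 0)
  net <- as.data.frame(fx)$Rr + fx$Rg + fx$Rl + fx$Sg + fx$Sl
  expect_equal(net[-1], diff(acs), tolerance = 1e-10)
})

test_that("plots with late minima or missing censuses are excluded with reasons", {
  gen <- generate_inventory(n_plots = 2, target_acs = 150, seed = 2)
  inv <- gen$inventory
  # push one plot's minimum beyond the window by killing everything late
  late <- inv$plot_id == "SYN-P2" & inv$census_time == 6
  inv$status[late] <- "dead"
  fx <- decompose_fluxes(inv, gen$wd, gen$sites, gen$plots)
  excl <- attr(fx, "excluded")
  expect_named(excl, "SYN-P2")
  expect_match(unname(excl), "after the window")
  expect_false("SYN-P2" %in% flux_meta(fx)$plot_id)
})
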