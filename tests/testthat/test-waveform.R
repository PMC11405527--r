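test_that("waveform simulation conserves energy and is linear", {
  # single point at the centre: unit Gaussian bump at its height
  one <- canopy_cloud(matrix(c(0, 0, 12), 1, 3))
  wf <- simulate_waveform(one, c(0, 0))
  expect_equal(sum(wf$amplitude), 1, tolerance = 1e-9)
  expect_lt(abs(wf$heights[which.max(wf$amplitude)] - 12), wf$bin_height)

  # energy equals total footprint-weighted point mass
  cl <- generate_stand(stand_params(tree_density = 200), seed = 2)
  wf2 <- simulate_waveform(cl, c(0, 0))
  d2 <- cl$points[, 1]^2 + cl$points[, 2]^2
  expect_equal(sum(wf2$amplitude), sum(exp(-d2 / (2 * 6.25^2))),
               tolerance = 1e-6)

  # doubling every point doubles the amplitude exactly
  dbl <- canopy_cloud(rbind(cl$points, cl$points))
  wf3 <- simulate_waveform(dbl, c(0, 0))
  expect_equal(wf3$amplitude, 2 * wf2$amplitude, tolerance = 1e-9)

  # two well-separated layers produce two modes
  layers <- canopy_cloud(cbind(runif(400, -5, 5), runif(400, -5, 5),
                               rep(c(0, 30), each = 200)))
  wf4 <- simulate_waveform(layers, c(0, 0))
  dens <- wf4$amplitude
  peaks <- which(diff(sign(diff(dens))) == -2) + 1
  modes <- wf4$heights[peaks[order(dens[peaks], decreasing = TRUE)][1:2]]
  expect_equal(sort(round(modes)), c(0, 30), tolerance = 1)

  expect_error(simulate_waveform(one, c(1e5, 1e5)), "no energy")
})

test_that("RH profiles follow the bottom-up cumulative-energy convention", {
  # all energy at one height: every percentile equals that height
  spike <- make_waveform(heights = c(4.5, 5, 5.5), amplitude = c(0, 1, 0))
  rh <- rh_profile(spike)
  expect_true(all(rh == 5))

  # equal spikes at 0 and 30 m: RHp = 0 up to 50%, 30 beyond
  two <- make_waveform(heights = seq(0, 30, 0.5),
                       amplitude = c(1, rep(0, 59), 1))
  rh2 <- rh_profile(two)
  expect_true(all(rh2[paste0("rh", 1:50)] == 0))
  expect_true(all(rh2[paste0("rh", 51:100)] == 30))

  # monotone non-decreasing for arbitrary waveforms
  set.seed(6)
  wf <- make_waveform(seq(-2, 35, 0.15),
                      amplitude = runif(length(seq(-2, 35, 0.15))))
  expect_true(all(diff(rh_profile(wf)) >= 0))

  # RH100 of a simulated waveform sits within 3 pulse sigmas of the top point
  cl <- generate_stand(stand_params(tree_density = 250), seed = 3)
  wf2 <- simulate_waveform(cl, c(0, 0), pulse_sigma = 2.35)
  expect_lt(abs(rh_profile(wf2)[["rh100"]] - max(cl$points[, 3])), 3 * 2.35)
})

test_that("geolocation matching recovers planted offsets", {
  p <- stand_params(tree_density = 200, canopy_point_density = 6,
                    understory_fraction = 0)
  cl <- generate_stand(p, seed = 20)
  centers <- cbind(runif(10, -8, 8), runif(10, -8, 8))
  observed <- lapply(seq_len(nrow(centers)), function(i)
    simulate_waveform(apply_offset(cl, 2, -1, 0.5), centers[i, ]))
  grid <- list(dx = -2:2, dy = -2:2, dz = seq(-1, 1, 0.5))

  res <- match_geolocation(observed, cl, grid)
  expect_equal(c(res$dx, res$dy, res$dz), c(2, -1, 0.5))
  expect_gt(res$mean_r, 0.999)
  expect_true(filter_crossovers(res))

  # self-match at zero offset
  obs0 <- lapply(1:10, function(i) simulate_waveform(cl, centers[i, ]))
  res0 <- match_geolocation(obs0, cl, grid)
  expect_equal(c(res0$dx, res0$dy, res0$dz), c(0, 0, 0))
  expect_gt(res0$mean_r, 0.999)

  # a grid excluding the true offset scores strictly below the self-match
  res_off <- match_geolocation(observed, cl,
                               list(dx = -2:0, dy = 0:2, dz = 0))
  expect_lt(res_off$mean_r, res$mean_r)

  expect_error(match_geolocation(observed, cl,
                                 list(dx = numeric(0), dy = 0, dz = 0)),
               "empty search grid")
})

test_that("offset recovery is within one grid step across seeded fixtures", {
  # planted sub-grid offsets over 20 fixtures; median |error| <= 1 step/axis
  grid <- list(dx = -2:2, dy = -2:2, dz = seq(-1, 1, 0.5))
  err <- t(vapply(1:20, function(s) {
    set.seed(100 + s)
    truth <- c(sample(-1:1, 2, replace = TRUE), sample(seq(-0.5, 0.5, 0.5), 1))
    p <- stand_params(tree_density = 180, canopy_point_density = 5,
                      understory_fraction = 0)
    cl <- generate_stand(p, seed = 200 + s)
    centers <- cbind(runif(10, -8, 8), runif(10, -8, 8))
    obs <- lapply(seq_len(10), function(i)
      simulate_waveform(apply_offset(cl, truth[1], truth[2], truth[3]),
                        centers[i, ]))
    res <- match_geolocation(obs, cl, grid)
    abs(c(res$dx, res$dy, res$dz) - truth)
  }, numeric(3)))
  expect_lte(median(err[, 1]), 1)
  expect_lte(median(err[, 2]), 1)
  expect_lte(median(err[, 3]), 0.5)
})

test_that("crossover retention applies the shot-count and correlation floors", {
  expect_false(filter_crossovers(list(n_shots = 9, mean_r = 0.99)))
  expect_false(filter_crossovers(list(n_shots = 50, mean_r = 0.74)))
  expect_true(filter_crossovers(list(n_shots = 10, mean_r = 0.75)))
  expect_true(filter_crossovers(list(n_shots = 30, mean_r = 0.9)))
})

test_that("the shot quality filter matches its truth table", {
  expect_true(quality_filter(passing_quality()))
  expect_true(quality_filter(passing_quality(sensitivity = 0.96)))
  expect_false(quality_filter(passing_quality(sensitivity = 0.96,
                                              in_tropics = TRUE)))
  expect_true(quality_filter(passing_quality(sensitivity = 0.985,
                                             in_tropics = TRUE)))
  expect_false(quality_filter(passing_quality(rx_maxamp = 7.9,
                                              sd_corrected = 1)))
  expect_true(quality_filter(passing_quality(rx_maxamp = 8.1,
                                             sd_corrected = 1)))
  expect_false(quality_filter(passing_quality(algorithm_run_flag = 0)))
  expect_false(quality_filter(passing_quality(degrade_flag = 1)))
  expect_false(quality_filter(passing_quality(water_persistence = 10)))
  expect_false(quality_filter(passing_quality(urban_proportion = 50)))
  expect_false(quality_filter(passing_quality(pft_class = 7)))
  expect_true(quality_filter(passing_quality(pft_class = 11)))

  # vectorised over data-frame rows
  df <- rbind(as.data.frame(passing_quality()),
              as.data.frame(passing_quality(degrade_flag = 1)))
  expect_equal(quality_filter(df), c(TRUE, FALSE))

  # a missing field is an error, never a silent pass
  rec <- passing_quality()
  rec$sensitivity <- NULL
  expect_error(quality_filter(rec), "missing quality fields")
  rec2 <- passing_quality(sensitivity = NA)
  expect_error(quality_filter(rec2), "NA in quality field")
})
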