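test_that("grid aggregation excludes short canopies and conserves counts", {
  shots <- data.frame(
    x = c(5, 6, 15, 25, 26), y = c(5, 6, 5, 5, 6),
    wsci = c(8, 10, 6, 7, 9), rh98 = c(20, 25, 5, 12, 30),
    pi_relative = c(0.1, 0.2, 0.3, 0.4, 0.5))
  agg <- grid_aggregate(shots, cell_size = 10)
  # the rh98 = 5 shot is excluded (strictly greater than 5 m qualifies)
  expect_equal(sum(agg$n), 4)
  c1 <- agg[agg$cell_x == 0 & agg$cell_y == 0, ]
  expect_equal(c1$mean_wsci, 9)
  expect_equal(c1$mean_pi_relative, 0.15)
  # single-shot cell equals the shot
  expect_equal(agg$mean_wsci[agg$cell_x == 2 & agg$cell_y == 0],
               mean(c(7, 9)))
  # mean decomposition: averaging the halves' means equals the cell mean
  half <- (mean(c(8)) + mean(c(10))) / 2
  expect_equal(c1$mean_wsci, half)
  expect_warning(out <- grid_aggregate(shots[shots$rh98 < 1, ], 10),
                 "no qualifying shots")
  expect_equal(nrow(out), 0)
})

test_that("PCA / PCR recovers planted factor structure", {
  set.seed(50)
  n <- 5000
  f1 <- runif(n); f2 <- runif(n)
  A <- c(wsci = 1.0, cover = 0.8, rh98 = 0.9, pai = 0.5, fhd = 0.7, agbd = 0.3)
  B <- c(wsci = 0.3, cover = 0.1, rh98 = 0.4, pai = 0.9, fhd = 0.2, agbd = 1.0)
  metrics <- as.data.frame(mapply(function(a, b) a * f1 + b * f2, A, B))
  # noiseless rank-2 fixture: lm emits perfect-fit warnings by design
  res <- suppressWarnings(pca_pcr(metrics, ncomp = 3))
  # oracle: population covariance of the min-max standardized combos
  As <- A / (A + B); Bs <- B / (A + B)
  pop <- (outer(As, As) + outer(Bs, Bs)) / 12
  shares <- sort(eigen(pop, symmetric = TRUE)$values, decreasing = TRUE)
  shares <- shares / sum(shares)
  expect_lt(max(abs(res$explained[1:3] - shares[1:3])), 0.02)
  # rank-2 data: two components explain everything, PCR is exact
  expect_gt(sum(res$explained[1:2]), 0.999)
  expect_gt(res$pcr_r2, 0.999)

  # rank-1 latent: PC1 explains 100%, PCR R^2 = 1
  m1 <- as.data.frame(sapply(c(1, 0.5, 2, 0.8, 1.5), function(a) a * f1))
  names(m1) <- c("wsci", "cover", "rh98", "pai", "fhd")
  r1 <- suppressWarnings(pca_pcr(m1, ncomp = 3))
  expect_gt(r1$explained[1], 0.999)
  expect_gt(r1$pcr_r2, 0.999)

  # PCR with all components equals the full linear fit, and R^2 is monotone
  # (noise on every column keeps the predictor set full-rank, so no
  # components are numerically degenerate)
  set.seed(51)
  noisy <- as.data.frame(lapply(metrics, function(v) v + rnorm(n, 0, 0.05)))
  rfull <- pca_pcr(noisy, ncomp = 5)
  lmfit <- lm(wsci ~ ., data = as.data.frame(lapply(noisy, function(v)
    (v - min(v)) / diff(range(v)))))
  expect_equal(rfull$pcr_r2_full, summary(lmfit)$r.squared, tolerance = 1e-9)
  r_k <- vapply(1:5, function(k) pca_pcr(noisy, ncomp = k)$pcr_r2, numeric(1))
  expect_true(all(diff(r_k) >= -1e-12))

  const <- metrics
  const$cover <- 1
  expect_error(pca_pcr(const), "degenerate standardization")
})

test_that("per-cell scaling fits recover exact lines and reject pure noise", {
  set.seed(60)
  h <- runif(200, 5, 40)
  exact <- data.frame(cell_id = "a", rh98 = h, wsci = 1.3 * log(h) + 2)
  f <- suppressWarnings(pixel_scaling_fit(exact))
  expect_equal(f$slope, 1.3, tolerance = 1e-9)
  expect_equal(f$intercept, 2, tolerance = 1e-9)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_false(f$excluded)

  # duplicating every shot leaves the fit unchanged
  f2 <- suppressWarnings(pixel_scaling_fit(rbind(exact, exact)))
  expect_equal(f2$slope, f$slope, tolerance = 1e-12)
  expect_equal(f2$intercept, f$intercept, tolerance = 1e-12)

  # under the null (wsci independent of height) the t-test excludes the
  # cell about 95% of the time
  excl <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    cells <- data.frame(cell_id = "n", rh98 = runif(100, 5, 40),
                        wsci = rnorm(100))
    pixel_scaling_fit(cells)$excluded
  }, logical(1))
  expect_gt(mean(excl), 0.90)
  expect_lt(mean(excl), 0.99)

  # small cells and degenerate heights are excluded with a reason
  tiny <- pixel_scaling_fit(exact[1:10, ])
  expect_true(tiny$excluded)
  expect_match(tiny$reason, "fit floor")
  flat <- data.frame(cell_id = "f", rh98 = rep(20, 40), wsci = rnorm(40))
  expect_match(pixel_scaling_fit(flat)$reason, "zero height variance")
})

test_that("robust scaling resists contamination that biases least squares", {
  set.seed(70)
  n <- 2000
  h <- runif(n, 5, 45)
  clean <- data.frame(biome = "temperate", rh98 = h,
                      wsci = 1.0 * log(h) + 2 + rnorm(n, 0, 0.3))
  # noiseless line: robust and OLS coincide
  line <- data.frame(biome = "x", rh98 = h, wsci = 1.3 * log(h) + 2)
  rb <- robust_biome_scaling(line, biome_col = "biome")
  ols <- coef(lm(wsci ~ log(rh98), line))
  expect_lt(abs(rb$slope - ols[2]), 1e-6)

  # gross outliers concentrated in short stands drag OLS but not IRLS
  dirty <- clean
  short <- order(dirty$rh98)[1:(n / 10)]
  dirty$wsci[short] <- dirty$wsci[short] + 10
  slope_clean <- robust_biome_scaling(clean)$slope
  slope_rob <- robust_biome_scaling(dirty)$slope
  slope_ols <- coef(lm(wsci ~ log(rh98), dirty))[2]
  expect_lt(abs(slope_rob - slope_clean) / slope_clean, 0.05)
  expect_gt(abs(slope_ols - slope_clean) / slope_clean, 0.05)

  # planted biome-specific exponents are recovered within 5%
  set.seed(71)
  two <- rbind(
    data.frame(biome = "tropical", rh98 = runif(n, 5, 45)),
    data.frame(biome = "temperate", rh98 = runif(n, 5, 45)))
  slopes <- c(tropical = 1.0, temperate = 1.3)
  two$wsci <- slopes[two$biome] * log(two$rh98) + 2 + rnorm(2 * n, 0, 0.3)
  est <- robust_biome_scaling(two)
  expect_lt(abs(est$slope[est$biome == "tropical"] - 1.0), 0.05)
  expect_lt(abs(est$slope[est$biome == "temperate"] - 1.3), 0.065)

  expect_error(robust_biome_scaling(clean[1:50, ]), "fewer than")
})
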