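test_that("footprint clipping uses a strict radius and is idempotent", {
  xyz <- rbind(c(12.49, 0, 5), c(12.51, 0, 5), c(0, 0, 1), c(-3, 4, 2))
  cl <- canopy_cloud(xyz)
  clipped <- footprint_clip(cl, c(0, 0), 25)
  expect_equal(nrow(clipped$points), 3)
  expect_false(any(clipped$points[, 1] == 12.51))
  expect_equal(footprint_clip(clipped, c(0, 0), 25)$points, clipped$points)
  expect_error(footprint_clip(cl, c(1000, 1000), 25), "empty footprint")
})

test_that("voxel thinning hits its target count and collapses duplicates", {
  # identical points collapse to a single voxel centroid
  dup <- canopy_cloud(matrix(rep(c(1, 2, 3), 40), ncol = 3, byrow = TRUE))
  expect_equal(nrow(voxel_thin(dup, 5)$points), 1)

  # sparse clouds pass through untouched
  set.seed(1)
  sparse <- canopy_cloud(cbind(runif(50), runif(50), runif(50)))
  expect_identical(voxel_thin(sparse, 100)$points, sparse$points)

  # dense cloud thinned to within 10% of the target
  set.seed(2)
  dense <- canopy_cloud(cbind(runif(20000, 0, 25), runif(20000, 0, 25),
                              runif(20000, 0, 20)))
  thin <- voxel_thin(dense, 3000)
  expect_lt(abs(nrow(thin$points) - 3000) / 3000, 0.10 + 1e-9)

  # thinning again at the chosen edge and origin changes nothing (each
  # centroid stays in its own voxel)
  edge <- attr(thin, "voxel_edge")
  origin <- attr(thin, "voxel_origin")
  again <- wsci:::voxelize(thin$points, edge, origin)
  expect_equal(nrow(again), nrow(thin$points))
})

test_that("voxel thinning makes the index density-invariant", {
  # the same uniform scene scanned at 1x and 2x point density should give
  # nearly the same CE_XYZ after thinning to a common target
  set.seed(3)
  n1 <- 8000
  base <- cbind(runif(2 * n1, -12, 12), runif(2 * n1, -12, 12),
                runif(2 * n1, 0, 18))
  cl1 <- canopy_cloud(base[1:n1, ])
  cl2 <- canopy_cloud(base)
  ce1 <- ce_components(cl1, target_count = 2000)
  ce2 <- ce_components(cl2, target_count = 2000)
  expect_lt(abs(ce1$ce_xyz - ce2$ce_xyz) / ce1$ce_xyz, 0.02)
})

test_that("grid entropy matches closed forms and rejects degenerate input", {
  expect_error(ce_2d(matrix(1, 10, 2)), "degenerate")
  expect_error(ce_2d(matrix(c(1, 2), 1, 2)), "two points")

  # dense regular fill of the unit square: uniform density has differential
  # entropy ln(1) = 0; the KDE smooths over the boundary, which adds a
  # positive bias of order bandwidth * perimeter / area
  g <- as.matrix(expand.grid(u = seq(0, 1, 0.02), v = seq(0, 1, 0.02)))
  e_sq <- ce_2d(g, s = 0.02)
  expect_lt(abs(e_sq - 0), 0.35)
  expect_equal(attr(e_sq, "normalization"), 1, tolerance = 0.05)

  # a tight cluster with a fixed bandwidth is a single Gaussian: closed-form
  # differential entropy ln(2*pi*e*h^2); the lattice stops 3 bandwidths out,
  # which clips a fraction of a percent of the Gaussian tail mass
  set.seed(4)
  h <- 0.5
  cl <- matrix(rnorm(2 * 400, sd = 0.01), ncol = 2)
  e_g <- ce_2d(cl, s = 0.05, bandwidth = h)
  expect_equal(as.numeric(e_g), log(2 * pi * exp(1) * h^2), tolerance = 0.03)
})

test_that("grid entropy agrees with brute-force integration on small clouds", {
  set.seed(5)
  cases <- list(
    cbind(runif(150, 0, 8), runif(150, 0, 8)),
    cbind(rnorm(200, 0, 2), rnorm(200, 0, 1)),
    cbind(c(rnorm(100, -3, 0.8), rnorm(100, 3, 0.8)), rnorm(200, 0, 1.5))
  )
  for (uv in cases) {
    e <- ce_2d(uv, s = 0.10)
    h <- attr(e, "bandwidth")
    oracle <- brute_ce2d(uv, h, mesh = 0.05)
    expect_lt(abs(as.numeric(e) - oracle) / abs(oracle), 0.01)
  }
})

test_that("component assembly obeys the Euclidean and averaging identities", {
  ce <- canopy_entropy(3, 4, 0)
  expect_equal(ce$ce_xyz, 5, tolerance = 1e-12)
  expect_equal(canopy_entropy(1, 4, 2)$ce_z, 3, tolerance = 1e-12)
  # identity holds by construction on measured components too
  cl <- generate_stand(stand_params(tree_density = 250), seed = 9)
  m <- ce_components(footprint_clip(cl, c(0, 0), 25), target_count = 800)
  expect_equal(m$ce_xyz^2, m$ce_xy^2 + m$ce_xz^2 + m$ce_yz^2,
               tolerance = 1e-9)
  expect_equal(m$ce_z, (m$ce_xz + m$ce_yz) / 2, tolerance = 1e-12)
})

test_that("the index is invariant to translation and equivariant to rotation", {
  cl <- generate_stand(stand_params(tree_density = 250), seed = 10)
  cl <- footprint_clip(cl, c(0, 0), 25)
  base <- ce_components(cl, target_count = 800)

  shifted <- apply_offset(cl, 113.7, -48.2, 0)
  m <- ce_components(shifted, target_count = 800)
  expect_lt(abs(m$ce_xyz - base$ce_xyz), 1e-6)

  # 90-degree rotation about z swaps the two vertical planes
  rot <- cl
  rot$points <- cbind(-cl$points[, 2], cl$points[, 1], cl$points[, 3])
  colnames(rot$points) <- c("x", "y", "z")
  r <- ce_components(rot, target_count = 800)
  expect_equal(r$ce_xy, base$ce_xy, tolerance = 0.01 * abs(base$ce_xy))
  expect_equal(r$ce_xz, base$ce_yz, tolerance = 0.01 * abs(base$ce_yz))
  expect_equal(r$ce_yz, base$ce_xz, tolerance = 0.01 * abs(base$ce_xz))
  expect_equal(r$ce_xyz, base$ce_xyz, tolerance = 0.01 * abs(base$ce_xyz))
})

test_that("mean CE_Z grows with layering and mean CE_XY with stem density", {
  seeds <- 1:10
  ce_for <- function(layers, density, seed) {
    p <- stand_params(tree_density = density, n_layers = layers,
                      understory_fraction = 0.05)
    cl <- footprint_clip(generate_stand(p, seed = seed), c(0, 0), 25)
    ce_components(cl, target_count = 700)
  }
  one <- lapply(seeds, function(s) ce_for(1, 300, s))
  three <- lapply(seeds, function(s) ce_for(3, 300, s))
  expect_gt(mean(vapply(three, `[[`, numeric(1), "ce_z")),
            mean(vapply(one, `[[`, numeric(1), "ce_z")))

  lo <- lapply(seeds, function(s) ce_for(1, 120, s))
  hi <- lapply(seeds, function(s) ce_for(1, 500, s))
  expect_gt(mean(vapply(hi, `[[`, numeric(1), "ce_xy")),
            mean(vapply(lo, `[[`, numeric(1), "ce_xy")))
})
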