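#' Stand generation parameters
#'
#' Bundle of parameters describing a synthetic multi-layer forest stand over a
#' circular lidar footprint. Heights are in metres, densities in trees per
#' hectare (trees) or points per square metre (ground / crown surface).
#'
#' @param footprint_diameter Footprint diameter (m). GEDI-like footprints are
#'   25 m across.
#' @param tree_density Stem density (trees/ha) per vertical stratum within
#'   the footprint disk; a stand with `n_layers` strata carries
#'   `n_layers * tree_density` stems in total, reflecting the higher stem
#'   counts of multi-layered forests.
#' @param height_law Distribution of (top-layer) tree heights. A list with a
#'   `family` element, one of `"normal"`, `"lognormal"`, `"uniform"`,
#'   `"constant"`, and its parameters: `mean`/`sd` (normal), `meanlog`/`sdlog`
#'   (lognormal), `min`/`max` (uniform), `value` (constant).
#' @param n_layers Number of distinct vertical strata. Trees are assigned to a
#'   stratum uniformly at random; a tree in stratum `l` of `L` has its drawn
#'   height scaled by `0.3 + 0.7 * l/L`, so the top stratum carries the full
#'   drawn height and lower strata form mid-storey and understory layers.
#' @param crown_archetype `"cone"` (conifer) or `"ellipsoid"` (broadleaf).
#' @param understory_fraction Fraction in `[0,1]` of canopy points re-allocated
#'   to a 0.3--2 m shrub layer.
#' @param ground_point_density Ground returns per square metre.
#' @param canopy_point_density Crown returns per square metre of crown surface.
#' @param noise_sd Gaussian ranging noise (m) added to all z coordinates.
#' @param pft_label Plant functional type label: `"EBT"`, `"DBT"`, `"ENT"`,
#'   or `"GSW"`.
#' @param site_id Site identifier carried through to downstream tables.
#' @return An object of class `stand_params` (a validated list).
#' @examples
#' p <- stand_params(tree_density = 400, n_layers = 2)
#' cloud <- generate_stand(p, seed = 1)
#' @export
stand_params <- function(footprint_diameter = 25,
                         tree_density = 400,
                         height_law = list(family = "normal", mean = 25, sd = 6),
                         n_layers = 1,
                         crown_archetype = c("ellipsoid", "cone"),
                         understory_fraction = 0.1,
                         ground_point_density = 4,
                         canopy_point_density = 12,
                         noise_sd = 0.05,
                         pft_label = c("EBT", "DBT", "ENT", "GSW"),
                         site_id = "site-1") {
  crown_archetype <- match.arg(crown_archetype)
  pft_label <- match.arg(pft_label)
  stopifnot(
    footprint_diameter > 0,
    tree_density >= 0,
    n_layers >= 1,
    understory_fraction >= 0, understory_fraction <= 1,
    ground_point_density >= 0,
    canopy_point_density >= 0,
    noise_sd >= 0,
    is.list(height_law), !is.null(height_law$family)
  )
  structure(
    list(footprint_diameter = footprint_diameter,
         tree_density = tree_density,
         height_law = height_law,
         n_layers = as.integer(n_layers),
         crown_archetype = crown_archetype,
         understory_fraction = understory_fraction,
         ground_point_density = ground_point_density,
         canopy_point_density = canopy_point_density,
         noise_sd = noise_sd,
         pft_label = pft_label,
         site_id = site_id),
    class = "stand_params")
}

#' Point cloud container
#'
#' Light container for a ground-normalised lidar point cloud: a three-column
#' matrix of x, y, z coordinates (m) plus the ground elevation and a
#' normalisation flag (z measured as height above ground).
#'
#' @param xyz Matrix or data frame with columns x, y, z (m).
#' @param ground_elevation Ground elevation (m); 0 for normalised clouds.
#' @param normalized Logical; whether z is height above ground.
#' @return An object of class `canopy_cloud`.
#' @export
canopy_cloud <- function(xyz, ground_elevation = 0, normalized = TRUE) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("xyz must have three columns (x, y, z)")
  colnames(xyz) <- c("x", "y", "z")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in point cloud")
  structure(list(points = xyz,
                 ground_elevation = ground_elevation,
                 normalized = normalized),
            class = "canopy_cloud")
}

#' @export
print.canopy_cloud <- function(x, ...) {
  n <- nrow(x$points)
  cat("canopy_cloud:", n, "points\n")
  if (n > 0) {
    r <- apply(x$points, 2, range)
    cat(sprintf("  x: [%.2f, %.2f] m  y: [%.2f, %.2f] m  z: [%.2f, %.2f] m\n",
                r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
  }
  cat("  ground elevation:", x$ground_elevation, "m;",
      if (isTRUE(x$normalized)) "height-normalized" else "absolute z", "\n")
  invisible(x)
}

draw_heights <- function(law, n) {
  fam <- law$family
  h <- switch(fam,
    normal = stats::rnorm(n, law$mean, law$sd),
    lognormal = stats::rlnorm(n, law$meanlog, law$sdlog),
    uniform = stats::runif(n, law$min, law$max),
    constant = rep(law$value, n),
    stop("unknown height_law family: ", fam))
  pmax(h, 2)  # a tree shorter than 2 m is kept as a sapling, not dropped
}

height_law_mean <- function(law) {
  switch(law$family,
    normal = law$mean,
    lognormal = exp(law$meanlog + law$sdlog^2 / 2),
    uniform = (law$min + law$max) / 2,
    constant = law$value,
    stop("unknown height_law family: ", law$family))
}

# Sample points on (and inside) a single crown solid. Cone: apex at height h,
# base radius r at h - depth. Ellipsoid: semi-axes (r, r, depth/2), centred at
# h - depth/2. Surface points dominate; `interior` is the interior fraction.
sample_crown <- function(archetype, h, r, depth, n, interior = 0.3) {
  if (n < 1) return(matrix(numeric(0), 0, 3))
  n_int <- round(n * interior)
  n_srf <- n - n_int
  if (archetype == "cone") {
    # lateral surface: area element proportional to distance from apex
    u <- sqrt(stats::runif(n_srf))          # fraction of depth below apex
    th <- stats::runif(n_srf, 0, 2 * pi)
    srf <- cbind(u * r * cos(th), u * r * sin(th), h - u * depth)
    ui <- stats::runif(n_int)^(1 / 3)       # uniform in cone volume
    ri <- ui * r * sqrt(stats::runif(n_int))
    thi <- stats::runif(n_int, 0, 2 * pi)
    int <- cbind(ri * cos(thi), ri * sin(thi), h - ui * depth)
  } else {
    # ellipsoid surface via scaled sphere directions
    v <- matrix(stats::rnorm(3 * n_srf), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    srf <- cbind(v[, 1] * r, v[, 2] * r, h - depth / 2 + v[, 3] * depth / 2)
    vi <- matrix(stats::rnorm(3 * n_int), ncol = 3)
    vi <- vi / sqrt(rowSums(vi^2)) * stats::runif(n_int)^(1 / 3)
    int <- cbind(vi[, 1] * r, vi[, 2] * r, h - depth / 2 + vi[, 3] * depth / 2)
  }
  rbind(srf, int)
}

#' Generate a synthetic forest stand point cloud
#'
#' Simulates a ground-normalised lidar point cloud for a multi-layer forest
#' stand over a circular footprint: a noisy ground plane at z = 0, one crown
#' point set per tree (cone or ellipsoid archetype, surface plus interior
#' points), and an optional understory shrub layer. Tree stems are placed
#' uniformly over the footprint disk; per-tree heights follow
#' `params$height_law`, scaled by stratum to create `n_layers` distinct
#' vertical layers.
#'
#' @param params A [stand_params()] object.
#' @param seed Integer seed; identical `(params, seed)` give identical clouds.
#' @return A [canopy_cloud()] with a `trees` attribute (data frame of stem
#'   x/y, height, layer) and a `params` attribute.
#' @export
generate_stand <- function(params, seed = 1L) {
  stopifnot(inherits(params, "stand_params"))
  if (params$tree_density <= 0 && params$ground_point_density <= 0)
    stop("empty stand: all point densities are zero")
  set.seed(seed)
  R <- params$footprint_diameter / 2
  area_m2 <- pi * R^2

  # tree_density is per vertical stratum: stratified stands carry canopy,
  # mid-storey and understory stems on top of each other
  n_trees <- stats::rpois(1, params$tree_density * area_m2 / 1e4 *
                            params$n_layers)
  pts <- list()
  trees <- data.frame(x = numeric(0), y = numeric(0),
                      height = numeric(0), layer = integer(0))
  if (n_trees > 0 && params$canopy_point_density > 0) {
    rr <- R * sqrt(stats::runif(n_trees))
    th <- stats::runif(n_trees, 0, 2 * pi)
    tx <- rr * cos(th); ty <- rr * sin(th)
    layer <- sample.int(params$n_layers, n_trees, replace = TRUE)
    h_top <- draw_heights(params$height_law, n_trees)
    # stratum L sits at the canopy top; lower strata are understory and
    # mid-storey trees at fixed fractions of the drawn height, so adding
    # layers adds vegetation below the canopy instead of shrinking it
    h <- h_top * (0.3 + 0.7 * layer / params$n_layers)
    h <- pmax(h, 2)
    rad_coef <- if (params$crown_archetype == "cone") 0.08 else 0.11
    dep_frac <- if (params$crown_archetype == "cone") 0.55 else 0.45
    for (i in seq_len(n_trees)) {
      r_cr <- max(0.6, rad_coef * h[i])
      depth <- max(1, dep_frac * h[i])
      surf <- if (params$crown_archetype == "cone") {
        pi * r_cr * sqrt(r_cr^2 + depth^2)
      } else {
        4 * pi * (r_cr * sqrt(r_cr * depth / 2))  # rough ellipsoid area proxy
      }
      n_pts <- max(8L, stats::rpois(1, params$canopy_point_density * surf))
      cr <- sample_crown(params$crown_archetype, h[i], r_cr, depth, n_pts)
      cr[, 1] <- cr[, 1] + tx[i]
      cr[, 2] <- cr[, 2] + ty[i]
      pts[[length(pts) + 1L]] <- cr
    }
    trees <- data.frame(x = tx, y = ty, height = h, layer = layer)
  }

  canopy <- if (length(pts)) do.call(rbind, pts) else matrix(numeric(0), 0, 3)

  # understory: re-allocate a fraction of canopy points into a shrub layer
  if (nrow(canopy) > 0 && params$understory_fraction > 0) {
    n_und <- round(nrow(canopy) * params$understory_fraction)
    if (n_und > 0) {
      rr <- R * sqrt(stats::runif(n_und))
      th <- stats::runif(n_und, 0, 2 * pi)
      und <- cbind(rr * cos(th), rr * sin(th), stats::runif(n_und, 0.3, 2))
      canopy <- rbind(canopy, und)
    }
  }

  n_grd <- stats::rpois(1, params$ground_point_density * area_m2)
  ground <- if (n_grd > 0) {
    rr <- R * sqrt(stats::runif(n_grd))
    th <- stats::runif(n_grd, 0, 2 * pi)
    cbind(rr * cos(th), rr * sin(th), 0)
  } else matrix(numeric(0), 0, 3)

  xyz <- rbind(canopy, ground)
  if (nrow(xyz) == 0) stop("empty stand: no points generated")
  if (params$noise_sd > 0) {
    nz <- stats::rnorm(nrow(xyz), 0, params$noise_sd)
    xyz[, 3] <- pmax(xyz[, 3] + nz, -3 * params$noise_sd)
  }
  out <- canopy_cloud(xyz)
  attr(out, "trees") <- trees
  attr(out, "params") <- params
  out
}

#' Footprint-level auxiliary structure metrics
#'
#' Derives footprint summaries analogous to the standard waveform products:
#' canopy cover fraction (occupancy of a 1-m horizontal grid by points above
#' 2 m), a canopy height proxy (98th height percentile), a foliage height
#' diversity analogue (Shannon entropy of the 1-m vertical point histogram of
#' canopy points), a plant-area-index analogue derived from cover through a
#' Beer-Lambert transform, and a biomass analogue proportional to
#' height-squared times cover. Only the rank structure of the PAI/AGBD
#' analogues is meaningful.
#'
#' @param cloud A ground-normalised [canopy_cloud()].
#' @param canopy_min Height (m) above which points count as canopy (default 2).
#' @return A one-row data frame with columns `cover`, `rh98`, `fhd`, `pai`,
#'   `agbd`.
#' @export
footprint_metrics <- function(cloud, canopy_min = 2) {
  stopifnot(inherits(cloud, "canopy_cloud"))
  if (!isTRUE(cloud$normalized)) stop("cloud must be height-normalized")
  p <- cloud$points
  if (nrow(p) == 0) stop("empty cloud")
  can <- p[p[, 3] > canopy_min, , drop = FALSE]
  if (nrow(can) == 0) {
    return(data.frame(cover = 0, rh98 = unname(stats::quantile(p[, 3], 0.98)),
                      fhd = 0, pai = 0, agbd = 0))
  }
  # cover: occupied fraction of 1-m cells, over cells touched by any point
  cell_all <- unique(paste(floor(p[, 1]), floor(p[, 2])))
  cell_can <- unique(paste(floor(can[, 1]), floor(can[, 2])))
  cover <- length(cell_can) / length(cell_all)
  h98 <- unname(stats::quantile(p[, 3], 0.98))
  counts <- tabulate(floor(can[, 3]) + 1L)
  pr <- counts[counts > 0] / sum(counts)
  fhd <- -sum(pr * log(pr))
  pai <- -log(1 - 0.98 * cover) * 2
  agbd <- 0.5 * h98^2 * cover
  data.frame(cover = cover, rh98 = h98, fhd = fhd, pai = pai, agbd = agbd)
}

#' Rigid translation of a point cloud
#'
#' Applies a known (dx, dy, dz) shift; used to plant geolocation offsets that
#' [match_geolocation()] must recover.
#'
#' @param cloud A [canopy_cloud()].
#' @param dx,dy,dz Offsets in metres.
#' @return The translated cloud (attributes preserved).
#' @export
apply_offset <- function(cloud, dx = 0, dy = 0, dz = 0) {
  stopifnot(inherits(cloud, "canopy_cloud"),
            is.finite(dx), is.finite(dy), is.finite(dz))
  out <- cloud
  out$points[, 1] <- out$points[, 1] + dx
  out$points[, 2] <- out$points[, 2] + dy
  out$points[, 3] <- out$points[, 3] + dz
  out
}
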