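#' Clip a point cloud to a circular footprint
#'
#' Retains points whose horizontal distance to the footprint centre is
#' strictly less than `diameter / 2`. The strict inequality makes clipping
#' deterministic: a point exactly on the rim is excluded.
#'
#' @param cloud A [canopy_cloud()].
#' @param center Numeric length-2, footprint centre (x, y) in metres.
#' @param diameter Footprint diameter (m), default 25.
#' @return The clipped [canopy_cloud()].
#' @export
footprint_clip <- function(cloud, center = c(0, 0), diameter = 25) {
  stopifnot(inherits(cloud, "canopy_cloud"), diameter > 0, length(center) == 2)
  p <- cloud$points
  d2 <- (p[, 1] - center[1])^2 + (p[, 2] - center[2])^2
  keep <- d2 < (diameter / 2)^2
  if (!any(keep)) stop("empty footprint: no points within the clip radius")
  out <- cloud
  out$points <- p[keep, , drop = FALSE]
  out
}

# Occupied-voxel centroids at edge length `edge`. The grid is anchored at
# `origin` (default: the cloud's own minimum corner, which makes thinning
# invariant under rigid translation); re-voxelising the centroids with the
# same edge and origin is the identity.
voxelize <- function(p, edge, origin = NULL) {
  if (is.null(origin)) origin <- apply(p, 2, min)
  key <- paste(floor((p[, 1] - origin[1]) / edge),
               floor((p[, 2] - origin[2]) / edge),
               floor((p[, 3] - origin[3]) / edge))
  cx <- rowsum(p, key)
  n <- as.vector(rowsum(rep(1, nrow(p)), key))
  cx / n
}

#' Adaptive voxel thinning of a point cloud
#'
#' Reduces a point cloud to approximately `target_count` points by replacing
#' each occupied voxel with its centroid, choosing the voxel edge length by
#' bisection so the retained count is within 10% of
#' `min(target_count, nrow(cloud))`. This makes the downstream entropy index
#' comparable across point clouds of very different densities. Clouds already
#' at or below the target are returned unchanged.
#'
#' @param cloud A [canopy_cloud()].
#' @param target_count Desired number of retained points (default 5000).
#' @param max_iter Bisection iteration cap.
#' @return The thinned [canopy_cloud()] with attribute `voxel_edge`.
#' @export
voxel_thin <- function(cloud, target_count = 5000, max_iter = 50) {
  stopifnot(inherits(cloud, "canopy_cloud"), target_count >= 1)
  p <- cloud$points
  n <- nrow(p)
  target <- min(target_count, n)
  if (n <= target_count) return(cloud)

  origin <- apply(p, 2, min)
  ext <- max(apply(p, 2, function(v) diff(range(v))), 1e-6)
  lo <- 1e-4          # edge so small every point keeps its own voxel
  hi <- ext           # edge so large everything collapses to a handful
  best <- NULL; best_gap <- Inf
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    vc <- voxelize(p, mid, origin)
    k <- nrow(vc)
    gap <- abs(k - target) / target
    if (gap < best_gap) { best <- list(vc = vc, edge = mid); best_gap <- gap }
    if (gap <= 0.10) break
    if (k > target) lo <- mid else hi <- mid
  }
  out <- cloud
  out$points <- unname(best$vc)
  colnames(out$points) <- c("x", "y", "z")
  attr(out, "voxel_edge") <- best$edge
  attr(out, "voxel_origin") <- origin
  out
}

# Silverman/Scott multivariate rule-of-thumb bandwidth for one axis of a 2D
# sample: sigma * n^(-1/6), with sigma the robust min(sd, IQR/1.34).
bw_axis <- function(x) {
  n <- length(x)
  sdx <- stats::sd(x)
  iqr <- stats::IQR(x) / 1.34
  sig <- if (iqr > 0) min(sdx, iqr) else sdx
  sig * n^(-1 / 6)
}

#' Grid-entropy of a 2D point projection
#'
#' Evaluates an isotropic Gaussian kernel density estimate of the projected
#' points on a regular lattice of spacing `s` (default 10 cm) covering the
#' data extent padded by three bandwidths, and returns the grid entropy
#' \deqn{CE_{2d} = -\sum_i \rho_i \ln(\rho_i)\, s^2}{CE2d = -sum(rho_i ln(rho_i) s^2)}
#' in nats, where \eqn{\rho_i} is the density at lattice node *i*. This is a
#' Riemann-sum estimate of the differential entropy of the smoothed point
#' density. Bandwidth defaults to the multivariate rule of thumb
#' (robust sigma times n^(-1/6) per axis, combined geometrically into one
#' isotropic value); pass `bandwidth` to override.
#'
#' @param uv Two-column matrix of projected coordinates (m).
#' @param s Lattice spacing (m), default 0.10.
#' @param bandwidth Optional isotropic Gaussian kernel bandwidth (m).
#' @param min_density Lattice nodes with density below this are dropped from
#'   the sum (they contribute nothing and destabilise the logarithm).
#' @return Entropy in nats, with attributes `bandwidth`, `normalization`
#'   (the lattice sum of rho * s^2, which should be close to 1) and `n_nodes`.
#' @examples
#' set.seed(1)
#' uv <- cbind(runif(500, 0, 10), runif(500, 0, 10))
#' ce_2d(uv)
#' @export
ce_2d <- function(uv, s = 0.10, bandwidth = NULL, min_density = 1e-12) {
  uv <- as.matrix(uv)
  stopifnot(ncol(uv) == 2, s > 0)
  n <- nrow(uv)
  if (n < 2) stop("at least two points are required")
  if (all(uv[, 1] == uv[1, 1]) && all(uv[, 2] == uv[1, 2]))
    stop("degenerate 2D support: all points identical")
  h <- if (is.null(bandwidth)) {
    hh <- sqrt(bw_axis(uv[, 1]) * bw_axis(uv[, 2]))
    if (!is.finite(hh) || hh <= 0) hh <- s  # e.g. points on a line
    hh
  } else bandwidth
  gu <- seq(min(uv[, 1]) - 3 * h, max(uv[, 1]) + 3 * h, by = s)
  gv <- seq(min(uv[, 2]) - 3 * h, max(uv[, 2]) + 3 * h, by = s)
  # separable Gaussian kernel: density grid = A %*% t(B) / (n 2 pi h^2),
  # chunked over points to bound memory
  rho <- matrix(0, length(gu), length(gv))
  idx <- split(seq_len(n), ceiling(seq_len(n) / 20000))
  for (ii in idx) {
    A <- exp(-outer(gu, uv[ii, 1], "-")^2 / (2 * h^2))
    B <- exp(-outer(gv, uv[ii, 2], "-")^2 / (2 * h^2))
    rho <- rho + A %*% t(B)
  }
  rho <- rho / (n * 2 * pi * h^2)
  norm <- sum(rho) * s^2
  keep <- rho > min_density
  ce <- -sum(rho[keep] * log(rho[keep])) * s^2
  structure(ce, bandwidth = h, normalization = norm,
            n_nodes = length(gu) * length(gv))
}

#' Canopy-entropy components container
#'
#' Assembles the planar entropies into the composite index:
#' `ce_z = (ce_xz + ce_yz) / 2` (vertical complexity, the mean of the two
#' vertical planes) and `ce_xyz = sqrt(ce_xy^2 + ce_xz^2 + ce_yz^2)` (the 3D
#' canopy entropy).
#'
#' @param ce_xy,ce_xz,ce_yz Planar grid entropies (nats).
#' @return An object of class `canopy_entropy`: a named list with elements
#'   `ce_xy`, `ce_xz`, `ce_yz`, `ce_z`, `ce_xyz`.
#' @export
canopy_entropy <- function(ce_xy, ce_xz, ce_yz) {
  ce_xy <- as.numeric(ce_xy)
  ce_xz <- as.numeric(ce_xz)
  ce_yz <- as.numeric(ce_yz)
  structure(list(ce_xy = ce_xy, ce_xz = ce_xz, ce_yz = ce_yz,
                 ce_z = (ce_xz + ce_yz) / 2,
                 ce_xyz = sqrt(ce_xy^2 + ce_xz^2 + ce_yz^2)),
            class = "canopy_entropy")
}

#' @export
print.canopy_entropy <- function(x, ...) {
  cat(sprintf(
    "canopy entropy (nats): CE_XYZ = %.3f  [CE_XY = %.3f, CE_XZ = %.3f, CE_YZ = %.3f, CE_Z = %.3f]\n",
    x$ce_xyz, x$ce_xy, x$ce_xz, x$ce_yz, x$ce_z))
  invisible(x)
}

#' @export
as.data.frame.canopy_entropy <- function(x, ...) {
  data.frame(ce_xy = x$ce_xy, ce_xz = x$ce_xz, ce_yz = x$ce_yz,
             ce_z = x$ce_z, ce_xyz = x$ce_xyz)
}

#' 3D canopy entropy of a footprint point cloud
#'
#' Computes the full complexity index for one footprint: the cloud is voxel
#' thinned to a density-independent point count, projected onto the XY, XZ and
#' YZ planes, the grid entropy of each projection is measured with [ce_2d()],
#' and the components are combined with [canopy_entropy()].
#'
#' @param cloud A footprint-clipped, ground-normalised [canopy_cloud()].
#' @param s Lattice spacing (m) for the density grids, default 0.10.
#' @param target_count Voxel-thinning target (default 5000 points).
#' @param bandwidth Optional fixed kernel bandwidth passed to [ce_2d()].
#' @return A [canopy_entropy()] object.
#' @examples
#' cloud <- generate_stand(stand_params(tree_density = 300), seed = 3)
#' ce_components(cloud, target_count = 1000)
#' @export
ce_components <- function(cloud, s = 0.10, target_count = 5000,
                          bandwidth = NULL) {
  stopifnot(inherits(cloud, "canopy_cloud"))
  thin <- voxel_thin(cloud, target_count)
  p <- thin$points
  canopy_entropy(
    ce_xy = ce_2d(p[, c(1, 2)], s = s, bandwidth = bandwidth),
    ce_xz = ce_2d(p[, c(1, 3)], s = s, bandwidth = bandwidth),
    ce_yz = ce_2d(p[, c(2, 3)], s = s, bandwidth = bandwidth))
}
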