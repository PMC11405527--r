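# Independent brute-force oracle for the grid entropy: evaluates the same
# Gaussian KDE pointwise (plain loop over mesh columns, no separable matmul)
# and integrates -rho*log(rho) over a fine mesh.
brute_ce2d <- function(uv, h, mesh = 0.02, pad = 3) {
  u <- uv[, 1]; v <- uv[, 2]
  gu <- seq(min(u) - pad * h, max(u) + pad * h, by = mesh)
  gv <- seq(min(v) - pad * h, max(v) + pad * h, by = mesh)
  n <- length(u)
  total <- 0
  for (i in seq_along(gu)) {
    rho <- vapply(gv, function(y)
      sum(exp(-((gu[i] - u)^2 + (y - v)^2) / (2 * h^2))), numeric(1)) /
      (n * 2 * pi * h^2)
    keep <- rho > 1e-12
    total <- total - sum(rho[keep] * log(rho[keep])) * mesh^2
  }
  total
}

if (!exists("%||%")) `%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built waveform object for rh_profile tests
make_waveform <- function(heights, amplitude, ground = 0, bin = NULL) {
  structure(list(heights = heights, amplitude = amplitude,
                 bin_height = if (is.null(bin)) {
                   if (length(heights) > 1) diff(heights[1:2]) else 1
                 } else bin,
                 ground_elevation = ground, center = c(0, 0)),
            class = "wsci_waveform")
}

# default shot-quality record that passes every filter
passing_quality <- function(...) {
  rec <- list(algorithm_run_flag = 1, degrade_flag = 0,
              water_persistence = 0, urban_proportion = 0,
              rx_maxamp = 100, sd_corrected = 1,
              sensitivity = 0.99, pft_class = 2, in_tropics = FALSE)
  mods <- list(...)
  rec[names(mods)] <- mods
  rec
}
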