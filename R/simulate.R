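#' Draw site-level parameters for synthetic training tables
#'
#' Sites represent distinct geographic ALS campaigns. Each site has a mean
#' canopy height drawn uniformly on 18--32 m, spanning young temperate to
#' tall tropical stands, and an identifier. Site draws are separated from row
#' draws so that additional footprints can later be generated for the same
#' sites (e.g. an exchangeable conformal holdout).
#'
#' @param n_sites Number of sites.
#' @param seed Integer seed.
#' @param pft Plant functional type label assigned to all sites.
#' @return Data frame with columns `site_id`, `mu_height`, `pft`.
#' @export
simulate_rh_sites <- function(n_sites = 10, seed = 1L, pft = "EBT") {
  set.seed(seed)
  data.frame(site_id = sprintf("S%02d", seq_len(n_sites)),
             mu_height = stats::runif(n_sites, 18, 32),
             pft = pft,
             stringsAsFactors = FALSE)
}

#' Simulate a synthetic RH-to-complexity training table
#'
#' Generates footprint rows with plausible monotone RH percentile profiles and
#' canopy-entropy targets tied to them through smooth structural
#' relationships. Canopy top height is normal around the site mean (sd 10 m,
#' truncated at 3 m); the RH profile follows a Beta-CDF shape of per-row
#' random curvature plus small measurement noise, forced monotone. The
#' vertical component `ce_z` grows with log canopy height and the profile's
#' foliage-height-diversity analogue; the horizontal component `ce_xy` depends
#' more weakly (and nonlinearly) on the profile, mimicking the weaker
#' constraint a vertical-only waveform places on horizontal structure;
#' `ce_xyz` combines the components. With `heteroskedastic = TRUE` the
#' vertical noise scales inversely with the signal, reproducing the larger
#' relative errors of low-complexity footprints.
#'
#' @param n Number of rows (footprints).
#' @param sites Site table from [simulate_rh_sites()].
#' @param seed Integer seed for the row draws.
#' @param heteroskedastic Use signal-dependent vertical noise (default TRUE).
#' @return Data frame with columns `site_id`, `pft`, `rh0` ... `rh100`,
#'   `ce_xy`, `ce_z`, `ce_xyz`.
#' @examples
#' sites <- simulate_rh_sites(5, seed = 1)
#' tab <- simulate_rh_table(200, sites, seed = 2)
#' @export
simulate_rh_table <- function(n, sites, seed = 1L, heteroskedastic = TRUE) {
  stopifnot(is.data.frame(sites), all(c("site_id", "mu_height") %in% names(sites)))
  set.seed(seed)
  idx <- sample(nrow(sites), n, replace = TRUE)
  H <- pmax(3, stats::rnorm(n, sites$mu_height[idx], 10))
  shape <- stats::runif(n, 1.2, 4)
  p <- (0:100) / 100
  rh <- t(vapply(seq_len(n),
                 function(i) H[i] * stats::pbeta(p, shape[i], 1.6),
                 numeric(101)))
  rh <- rh + matrix(stats::rnorm(n * 101, 0, 0.1), n)
  rh <- t(apply(rh, 1, cummax))
  rh[, 1] <- 0
  colnames(rh) <- paste0("rh", 0:100)

  # foliage-height-diversity analogue of each profile: entropy of the energy
  # fraction deposited between consecutive RH percentiles
  fhd <- apply(rh, 1, function(r) {
    d <- diff(r); s <- sum(d)
    if (s <= 0) return(0)
    d <- d[d > 0] / s
    -sum(d * log(d))
  })

  ce_z_mean <- 1.0 + 1.1 * log1p(H) + 0.6 * fhd
  ce_xy_mean <- 3.0 + 1.0 * stats::plogis((rh[, 34] - 4) / 3) + 0.4 * fhd
  sd_z <- if (heteroskedastic) 0.35 / pmax(ce_z_mean / 4, 0.6) else 0.25
  ce_z <- ce_z_mean + stats::rnorm(n, 0, sd_z)
  ce_xy <- ce_xy_mean + stats::rnorm(n, 0, 0.40)
  ce_xyz <- sqrt(ce_xy^2 + 2 * ce_z^2) + stats::rnorm(n, 0, 0.12)

  pft <- if ("pft" %in% names(sites)) sites$pft[idx] else "EBT"
  cbind(data.frame(site_id = sites$site_id[idx], pft = pft,
                   stringsAsFactors = FALSE),
        as.data.frame(rh),
        data.frame(ce_xy = ce_xy, ce_z = ce_z, ce_xyz = ce_xyz))
}

#' Names of the RH feature columns
#' @return Character vector `rh0` ... `rh100`.
#' @export
rh_names <- function() paste0("rh", 0:100)
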