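#' Simulate a large-footprint lidar waveform from a point cloud
#'
#' Each point contributes energy `exp(-d^2 / (2 * footprint_sigma^2))` where
#' `d` is its horizontal distance to the footprint centre (the Gaussian
#' footprint illumination), binned by height and convolved with a Gaussian
#' system pulse of standard deviation `pulse_sigma`. Total waveform energy
#' equals the total point weight: the pulse kernel is normalised and the
#' height range padded so no energy is lost at the ends.
#'
#' @param cloud A [canopy_cloud()].
#' @param center Footprint centre (x, y) in metres.
#' @param footprint_sigma Footprint illumination sigma (m). Default 6.25 m,
#'   i.e. a 25-m nominal diameter treated as +/- 2 sigma.
#' @param pulse_sigma Vertical pulse sigma (m), default 2.35.
#' @param bin_height Waveform bin size (m), default 0.15.
#' @return An object of class `wsci_waveform`: list with `heights` (ascending
#'   bin centres, same vertical datum as the cloud), `amplitude`,
#'   `bin_height`, `ground_elevation`, `center`.
#' @examples
#' cloud <- generate_stand(stand_params(), seed = 1)
#' wf <- simulate_waveform(cloud)
#' @export
simulate_waveform <- function(cloud, center = c(0, 0),
                              footprint_sigma = 6.25,
                              pulse_sigma = 2.35,
                              bin_height = 0.15) {
  stopifnot(inherits(cloud, "canopy_cloud"),
            footprint_sigma > 0, pulse_sigma >= 0, bin_height > 0)
  p <- cloud$points
  if (nrow(p) == 0) stop("empty cloud")
  d2 <- (p[, 1] - center[1])^2 + (p[, 2] - center[2])^2
  w <- exp(-d2 / (2 * footprint_sigma^2))
  if (sum(w) < 1e-12) stop("no energy in footprint: cloud too far from center")

  pad <- 4 * pulse_sigma + bin_height
  lo <- min(p[, 3]) - pad
  hi <- max(p[, 3]) + pad
  edges <- seq(lo, hi + bin_height, by = bin_height)
  centers <- edges[-length(edges)] + bin_height / 2
  bin <- findInterval(p[, 3], edges, rightmost.closed = TRUE)
  amp <- numeric(length(centers))
  acc <- rowsum(w, bin)
  amp[as.integer(rownames(acc))] <- as.vector(acc)

  if (pulse_sigma > 0) {
    kr <- ceiling(4 * pulse_sigma / bin_height)
    kern <- stats::dnorm(seq(-kr, kr) * bin_height, sd = pulse_sigma)
    kern <- kern / sum(kern)
    n <- length(amp)
    padded <- c(numeric(kr), amp, numeric(kr))
    sm <- stats::filter(padded, kern, sides = 2)
    # fold the tails back in so that energy is conserved exactly
    sm[is.na(sm)] <- 0
    amp <- as.numeric(sm[(kr + 1):(kr + n)])
    amp[1] <- amp[1] + sum(sm[seq_len(kr)])
    amp[n] <- amp[n] + sum(sm[(kr + n + 1):length(sm)])
  }
  structure(list(heights = centers, amplitude = amp,
                 bin_height = bin_height,
                 ground_elevation = cloud$ground_elevation,
                 center = center),
            class = "wsci_waveform")
}

#' @export
print.wsci_waveform <- function(x, ...) {
  cat(sprintf("wsci_waveform: %d bins of %.2f m, heights [%.2f, %.2f] m, energy %.3f\n",
              length(x$heights), x$bin_height, min(x$heights), max(x$heights),
              sum(x$amplitude)))
  invisible(x)
}

#' Relative-height (RH) profile of a waveform
#'
#' Computes the 101 RH percentiles RH0..RH100: RHp is the smallest bin height
#' at which the cumulative waveform energy, integrated from the bottom of the
#' waveform upward, reaches at least p% of the total, expressed relative to
#' the ground elevation. The waveform support is first delimited by a signal
#' threshold — leading and trailing bins below `signal_threshold` times the
#' peak amplitude are treated as outside the signal — so that the percentiles
#' (RH0 and RH100 in particular) track the start and end of the returned
#' signal rather than the infinite tails of the system pulse.
#'
#' @param wf A `wsci_waveform` (or any list with `heights`, `amplitude`,
#'   `ground_elevation`).
#' @param signal_threshold Fraction of the peak amplitude delimiting the
#'   signal support (default 0.01).
#' @return An object of class `rh_profile`: a named numeric vector
#'   `rh0 ... rh100` (m above ground), non-decreasing in the percentile.
#' @export
rh_profile <- function(wf, signal_threshold = 0.01) {
  stopifnot(!is.null(wf$heights), !is.null(wf$amplitude))
  total <- sum(wf$amplitude)
  if (total <= 0) stop("waveform has no energy")
  cum <- cumsum(wf$amplitude)
  thr <- (0:100) / 100 * total
  idx <- vapply(thr, function(t) which(cum >= t - 1e-12 * total)[1], 1L)
  supp <- range(which(wf$amplitude >= signal_threshold * max(wf$amplitude)))
  idx <- pmin(pmax(idx, supp[1]), supp[2])
  rh <- wf$heights[idx] - (wf$ground_elevation %||% 0)
  names(rh) <- paste0("rh", 0:100)
  structure(rh, class = c("rh_profile", "numeric"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rh_profile <- function(x, ...) {
  cat(sprintf("RH profile (m): rh25 = %.2f, rh50 = %.2f, rh75 = %.2f, rh98 = %.2f, rh100 = %.2f\n",
              x[["rh25"]], x[["rh50"]], x[["rh75"]], x[["rh98"]], x[["rh100"]]))
  invisible(x)
}

# Pearson correlation between an observed waveform and a simulated one whose
# heights have been shifted by dz, aligned on the observed height grid;
# non-overlapping bins are zero-padded.
wf_correlation <- function(obs, sim, dz) {
  sim_amp <- stats::approx(sim$heights + dz, sim$amplitude,
                           xout = obs$heights, yleft = 0, yright = 0,
                           rule = 2)$y
  sim_amp[!is.finite(sim_amp)] <- 0
  if (stats::sd(sim_amp) == 0 || stats::sd(obs$amplitude) == 0) return(0)
  stats::cor(obs$amplitude, sim_amp)
}

#' Recover geolocation offsets by waveform correlation
#'
#' Exhaustively searches a grid of candidate (dx, dy, dz) offsets applied to
#' the ALS point cloud, simulating a waveform at each observed shot centre and
#' scoring the candidate by the mean Pearson correlation between observed and
#' simulated waveforms across shots. Returns the offset maximising the mean
#' correlation; ties are broken by the smallest offset norm, then
#' lexicographically on (dx, dy, dz).
#'
#' @param observed List of `wsci_waveform` objects, each carrying its nominal
#'   footprint `center`.
#' @param cloud The ALS [canopy_cloud()] to be shifted.
#' @param search List with numeric vectors `dx`, `dy`, `dz` (m) defining the
#'   candidate offset grid. Default: dx, dy in \[-20, 20\] step 1 m and dz in
#'   \[-5, 5\] step 0.25 m.
#' @param footprint_sigma,pulse_sigma,bin_height Simulator settings, matching
#'   [simulate_waveform()].
#' @return An object of class `offset_result`: list with `dx`, `dy`, `dz`,
#'   `mean_r`, `n_shots`, `retained` (see [filter_crossovers()]).
#' @export
match_geolocation <- function(observed, cloud,
                              search = list(dx = seq(-20, 20, 1),
                                            dy = seq(-20, 20, 1),
                                            dz = seq(-5, 5, 0.25)),
                              footprint_sigma = 6.25, pulse_sigma = 2.35,
                              bin_height = 0.15) {
  stopifnot(length(observed) >= 1, inherits(cloud, "canopy_cloud"))
  if (!length(search$dx) || !length(search$dy) || !length(search$dz))
    stop("empty search grid")
  n_shots <- length(observed)
  best <- NULL
  for (dx in search$dx) for (dy in search$dy) {
    # shifting the cloud by (dx, dy) equals simulating at center - (dx, dy)
    sims <- lapply(observed, function(o)
      tryCatch(simulate_waveform(cloud, center = o$center - c(dx, dy),
                                 footprint_sigma = footprint_sigma,
                                 pulse_sigma = pulse_sigma,
                                 bin_height = bin_height),
               error = function(e) NULL))
    for (dz in search$dz) {
      rs <- mapply(function(o, s) if (is.null(s)) 0 else wf_correlation(o, s, dz),
                   observed, sims)
      mr <- mean(rs)
      cand <- c(dx, dy, dz)
      if (is.null(best) || mr > best$mean_r + 1e-12 ||
          (abs(mr - best$mean_r) <= 1e-12 && offset_preferred(cand, best$off))) {
        best <- list(mean_r = mr, off = cand)
      }
    }
  }
  structure(list(dx = best$off[1], dy = best$off[2], dz = best$off[3],
                 mean_r = best$mean_r, n_shots = n_shots,
                 retained = n_shots >= 10 && best$mean_r >= 0.75),
            class = "offset_result")
}

offset_preferred <- function(a, b) {
  na <- sum(a^2); nb <- sum(b^2)
  if (na != nb) return(na < nb)
  for (i in 1:3) if (a[i] != b[i]) return(a[i] < b[i])
  FALSE
}

#' @export
print.offset_result <- function(x, ...) {
  cat(sprintf("offset: dx = %g m, dy = %g m, dz = %g m; mean r = %.3f over %d shots (%s)\n",
              x$dx, x$dy, x$dz, x$mean_r, x$n_shots,
              if (x$retained) "retained" else "removed"))
  invisible(x)
}

#' Crossover retention rule
#'
#' A crossover (a set of shots matched against one ALS acquisition) is
#' retained only when it has at least 10 shots and a mean Pearson correlation
#' of at least 0.75 between observed and simulated waveforms.
#'
#' @param result An `offset_result` from [match_geolocation()], or a list with
#'   `n_shots` and `mean_r`.
#' @return Logical: retained?
#' @export
filter_crossovers <- function(result) {
  stopifnot(!is.null(result$n_shots), !is.null(result$mean_r))
  isTRUE(result$n_shots >= 10 && result$mean_r >= 0.75)
}

#' Shot quality filter
#'
#' Applies the standard shot-selection rules for high-fidelity footprints:
#' processing flags clean (`algorithm_run_flag == 1`, `degrade_flag == 0`),
#' non-urban non-water surface (`water_persistence < 10`,
#' `urban_proportion < 50`), waveform amplitude well above noise
#' (`rx_maxamp > 8 * sd_corrected`), high beam sensitivity
#' (`> 0.95`, tightened to `> 0.98` in the tropics), and a tree-covered
#' plant functional type (`pft_class` in 1--6 or 11).
#'
#' @param rec A list or one-row data frame with fields `algorithm_run_flag`,
#'   `degrade_flag`, `water_persistence`, `urban_proportion`, `rx_maxamp`,
#'   `sd_corrected`, `sensitivity`, `pft_class`, `in_tropics`. A data frame
#'   with several rows is filtered row-wise.
#' @return Logical vector: does each record pass?
#' @export
quality_filter <- function(rec) {
  fields <- c("algorithm_run_flag", "degrade_flag", "water_persistence",
              "urban_proportion", "rx_maxamp", "sd_corrected",
              "sensitivity", "pft_class", "in_tropics")
  missing <- setdiff(fields, names(rec))
  if (length(missing))
    stop("missing quality fields: ", paste(missing, collapse = ", "))
  for (f in fields) if (any(is.na(rec[[f]])))
    stop("NA in quality field: ", f)
  sens_thr <- ifelse(as.logical(rec$in_tropics), 0.98, 0.95)
  rec$algorithm_run_flag == 1 &
    rec$degrade_flag == 0 &
    rec$water_persistence < 10 &
    rec$urban_proportion < 50 &
    rec$rx_maxamp > 8 * rec$sd_corrected &
    rec$sensitivity > sens_thr &
    rec$pft_class %in% c(1, 2, 3, 4, 5, 6, 11)
}
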