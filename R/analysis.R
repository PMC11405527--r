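#' Aggregate WSCI shots onto a grid
#'
#' Computes per-cell arithmetic means of predicted complexity and relative
#' interval size over square cells, after excluding non-forest shots (canopy
#' height `rh98 <= height_min`). Cell counts are recorded so that aggregation
#' conserves the number of qualifying shots.
#'
#' @param shots Data frame with columns `x`, `y`, `wsci`, `rh98` and
#'   optionally `pi_relative`.
#' @param cell_size Cell edge in the units of `x`/`y`.
#' @param height_min Minimum canopy height (m); shots at or below are
#'   excluded (default 5).
#' @return Data frame keyed by `cell_x`, `cell_y` with `mean_wsci`,
#'   `mean_pi_relative`, `n`.
#' @export
grid_aggregate <- function(shots, cell_size, height_min = 5) {
  stopifnot(all(c("x", "y", "wsci", "rh98") %in% names(shots)), cell_size > 0)
  keep <- shots$rh98 > height_min
  if (!any(keep)) {
    warning("no qualifying shots (all rh98 <= ", height_min, " m)")
    return(data.frame(cell_x = numeric(0), cell_y = numeric(0),
                      mean_wsci = numeric(0), mean_pi_relative = numeric(0),
                      n = integer(0)))
  }
  s <- shots[keep, , drop = FALSE]
  cx <- floor(s$x / cell_size); cy <- floor(s$y / cell_size)
  key <- paste(cx, cy)
  cnt <- rowsum(rep(1L, nrow(s)), key)        # rows sorted by key
  n <- as.vector(cnt)
  mw <- as.vector(rowsum(s$wsci, key)) / n
  mp <- if ("pi_relative" %in% names(s))
    as.vector(rowsum(s$pi_relative, key)) / n else rep(NA_real_, length(n))
  ki <- do.call(rbind, strsplit(rownames(cnt), " "))
  data.frame(cell_x = as.numeric(ki[, 1]), cell_y = as.numeric(ki[, 2]),
             mean_wsci = mw, mean_pi_relative = mp, n = as.integer(n))
}

#' Variance partition of structure metrics by PCA and principal-component
#' regression
#'
#' Standardises the canopy-structure metrics to the `[0, 1]` range, runs a
#' principal component analysis, and regresses WSCI on the first `ncomp`
#' components (principal-component regression). Two decompositions are
#' reported: one including WSCI among the PCA inputs (variance shares) and
#' one excluding it (PCR of WSCI on components built from the other metrics
#' only, quantifying how much complexity variation the other metrics jointly
#' recover).
#'
#' @param metrics Data frame containing `wsci` plus the companion metrics
#'   (e.g. `cover`, `rh98`, `pai`, `fhd`, `agbd`).
#' @param ncomp Number of leading components for the PCR (default 3).
#' @return List with `loadings`, `explained` (variance shares of the PCA
#'   including WSCI), `pcr_r2` (R-squared of WSCI on the first `ncomp`
#'   components excluding WSCI), `pcr_r2_full` (same with all components),
#'   `explained_nowsci`.
#' @export
pca_pcr <- function(metrics, ncomp = 3) {
  stopifnot(is.data.frame(metrics), "wsci" %in% names(metrics),
            nrow(metrics) >= 3)
  num <- metrics[vapply(metrics, is.numeric, TRUE)]
  rng <- vapply(num, function(v) diff(range(v)), numeric(1))
  if (any(rng == 0))
    stop("degenerate standardization: constant column ",
         names(num)[which(rng == 0)[1]])
  std <- as.data.frame(lapply(num, function(v) (v - min(v)) / diff(range(v))))
  pca_all <- stats::prcomp(std, center = TRUE, scale. = FALSE)
  explained <- pca_all$sdev^2 / sum(pca_all$sdev^2)

  std_no <- std[, setdiff(names(std), "wsci"), drop = FALSE]
  pca_no <- stats::prcomp(std_no, center = TRUE, scale. = FALSE)
  expl_no <- pca_no$sdev^2 / sum(pca_no$sdev^2)
  scores <- pca_no$x
  k <- min(ncomp, ncol(scores))
  fit_k <- stats::lm(metrics$wsci ~ scores[, seq_len(k), drop = FALSE])
  fit_all <- stats::lm(metrics$wsci ~ scores)
  list(loadings = pca_all$rotation, explained = explained,
       explained_nowsci = expl_no,
       pcr_r2 = summary(fit_k)$r.squared,
       pcr_r2_full = summary(fit_all)$r.squared,
       ncomp = k)
}

#' Complexity-height scaling fit per grid cell
#'
#' For each cell, fits ordinary least squares of `wsci` on `ln(rh98)` — the
#' power-law scaling of complexity with canopy height — and flags cells
#' excluded by the two-tailed slope t-test (`p > 0.05`), by an insufficient
#' shot count, or by degenerate height variance.
#'
#' @param shots Data frame with `wsci`, `rh98` and a `cell_id` column.
#' @param fit_floor Minimum shots per cell (default 30).
#' @param p_max Slope significance threshold (default 0.05).
#' @return Data frame, one row per cell: `cell_id`, `slope`, `intercept`,
#'   `r2`, `p_value`, `n_shots`, `excluded`, `reason`.
#' @export
pixel_scaling_fit <- function(shots, fit_floor = 30, p_max = 0.05) {
  stopifnot(all(c("wsci", "rh98", "cell_id") %in% names(shots)))
  cells <- split(shots, shots$cell_id)
  out <- lapply(names(cells), function(id) {
    s <- cells[[id]]
    n <- nrow(s)
    base <- data.frame(cell_id = id, slope = NA_real_, intercept = NA_real_,
                       r2 = NA_real_, p_value = NA_real_, n_shots = n,
                       excluded = TRUE, reason = "", stringsAsFactors = FALSE)
    if (n < fit_floor) { base$reason <- "below fit floor"; return(base) }
    lx <- log(s$rh98)
    if (stats::var(lx) == 0) { base$reason <- "zero height variance"; return(base) }
    fit <- stats::lm(s$wsci ~ lx)
    sm <- summary(fit)
    base$slope <- unname(stats::coef(fit)[2])
    base$intercept <- unname(stats::coef(fit)[1])
    base$r2 <- sm$r.squared
    base$p_value <- sm$coefficients[2, 4]
    if (is.na(base$p_value) || base$p_value > p_max) {
      base$reason <- "slope not significant"
    } else {
      base$excluded <- FALSE
    }
    base
  })
  do.call(rbind, out)
}

#' Robust biome-level complexity-height scaling
#'
#' Fits the scaling of complexity with log canopy height per biome by
#' iteratively reweighted least squares with Tukey's biweight (redescending)
#' loss, which suppresses gross outliers that bias ordinary least squares.
#'
#' @param shots Data frame with `wsci`, `rh98` and a biome label column.
#' @param biome_col Name of the biome column (default `"biome"`).
#' @param c_tukey Tukey biweight tuning constant (default 4.685).
#' @param maxit Maximum IRLS iterations (default 50).
#' @param acc Convergence tolerance (default 1e-6).
#' @param min_shots Minimum shots per biome (default 100).
#' @return Data frame per biome: `biome`, `slope`, `intercept`, `n_shots`,
#'   `converged`.
#' @export
robust_biome_scaling <- function(shots, biome_col = "biome",
                                 c_tukey = 4.685, maxit = 50, acc = 1e-6,
                                 min_shots = 100) {
  stopifnot(all(c("wsci", "rh98", biome_col) %in% names(shots)))
  out <- lapply(split(shots, shots[[biome_col]]), function(s) {
    if (nrow(s) < min_shots)
      stop("biome ", s[[biome_col]][1], " has fewer than ", min_shots, " shots")
    ols <- stats::lm(wsci ~ log(rh98), data = s)
    co <- stats::coef(ols)
    converged <- TRUE
    # an (almost) exact fit leaves no residual scale to reweight against:
    # the robust fit is the least-squares fit
    if (stats::sd(stats::residuals(ols)) > 1e-8 * stats::sd(s$wsci)) {
      fit <- MASS::rlm(wsci ~ log(rh98), data = s, psi = MASS::psi.bisquare,
                       c = c_tukey, maxit = maxit, acc = acc)
      if (!fit$converged)
        stop("IRLS did not converge for biome ", s[[biome_col]][1],
             " after ", maxit, " iterations")
      co <- stats::coef(fit)
      converged <- fit$converged
    }
    data.frame(biome = s[[biome_col]][1],
               slope = unname(co[2]), intercept = unname(co[1]),
               n_shots = nrow(s), converged = converged,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
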