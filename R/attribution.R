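#' Shapley feature contributions for WSCI predictions
#'
#' Exact path-dependent tree-Shapley contributions of each RH feature to each
#' prediction, plus the base value (expected model output), computed in
#' double precision by walking the fitted trees. Local accuracy holds: the
#' base value plus the 101 contributions reproduces the prediction.
#'
#' @param object A fitted `wsci` object.
#' @param newdata Rows with RH features (and PFT column if multi-PFT).
#' @param pft Optional single PFT label overriding the PFT column.
#' @return Matrix with `nrow(newdata)` rows and 102 columns: `rh0 ... rh100`
#'   and `base`.
#' @export
shap_contributions <- function(object, newdata, pft = NULL) {
  stopifnot(inherits(object, "wsci"))
  X <- wsci_matrix(newdata)
  pfts <- if (!is.null(pft)) rep(pft, nrow(X))
          else if (length(object$bundles) == 1L) rep(names(object$bundles), nrow(X))
          else as.character(newdata[[object$pft_col]])
  out <- matrix(NA_real_, nrow(X), 102,
                dimnames = list(NULL, c(rh_names(), "base")))
  pred <- numeric(nrow(X))
  for (pf in unique(pfts)) {
    b <- bundle_for(object, pf)
    i <- pfts == pf
    out[i, ] <- treeshap_contrib(b$pb, X[i, , drop = FALSE])
    pred[i] <- predict_trees(b$pb, X[i, , drop = FALSE])
  }
  attr(out, "prediction") <- pred
  out
}

#' Accumulate feature importance into waveform strata
#'
#' Averages the absolute Shapley contribution of each RH feature over a set
#' of predictions and sums the per-feature importances into three waveform
#' strata: lower (`rh0`--`rh33`, boundary inclusive), middle (`rh34`--`rh66`)
#' and upper (`rh67`--`rh100`), normalised to fractions.
#'
#' @param contributions Matrix from [shap_contributions()] (the `base` column
#'   is ignored if present).
#' @return Object of class `strata_importance`: named numeric
#'   `c(lower, middle, upper)` summing to 1, with attribute `per_feature`.
#' @export
strata_importance <- function(contributions) {
  contributions <- as.matrix(contributions)
  feat <- intersect(colnames(contributions), rh_names())
  if (length(feat) != 101)
    stop("contributions must carry columns rh0..rh100")
  imp <- colMeans(abs(contributions[, feat, drop = FALSE]))
  total <- sum(imp)
  if (total <= 0) stop("no importance mass: all contributions are zero")
  p <- 0:100
  s <- c(lower = sum(imp[p <= 33]),
         middle = sum(imp[p > 33 & p <= 66]),
         upper = sum(imp[p > 66])) / total
  structure(s, per_feature = imp, class = c("strata_importance", "numeric"))
}

#' @export
print.strata_importance <- function(x, ...) {
  cat(sprintf("strata importance: lower %.3f, middle %.3f, upper %.3f\n",
              x[["lower"]], x[["middle"]], x[["upper"]]))
  invisible(x)
}

#' Gridded RGB composite of strata importance
#'
#' Averages per-shot strata fractions over square grid cells and maps lower /
#' middle / upper to the R / G / B bands, each band rescaled linearly to its
#' observed range across cells (min-max stretch). Cells without shots hold
#' `NA`.
#'
#' @param shots Data frame with columns `x`, `y`, `lower`, `middle`, `upper`.
#' @param cell_size Cell edge (m or degrees, matching `x`/`y` units).
#' @return A 3D array `[rows, cols, band]` with bands R, G, B in `[0, 1]`;
#'   attributes `extent` (xmin, xmax, ymin, ymax), `cell_size`, and
#'   `means` (the unscaled per-cell stratum means, same shape).
#' @export
strata_composite <- function(shots, cell_size) {
  stopifnot(all(c("x", "y", "lower", "middle", "upper") %in% names(shots)),
            cell_size > 0)
  cx <- floor(shots$x / cell_size)
  cy <- floor(shots$y / cell_size)
  xs <- seq(min(cx), max(cx)); ys <- seq(min(cy), max(cy))
  dims <- c(length(ys), length(xs))
  means <- array(NA_real_, c(dims, 3),
                 dimnames = list(NULL, NULL, c("lower", "middle", "upper")))
  key <- paste(cx, cy)
  agg <- rowsum(as.matrix(shots[, c("lower", "middle", "upper")]), key)
  n <- as.vector(rowsum(rep(1, nrow(shots)), key))
  agg <- agg / n
  ki <- do.call(rbind, strsplit(rownames(agg), " "))
  ri <- match(as.integer(ki[, 2]), ys)
  ci <- match(as.integer(ki[, 1]), xs)
  for (bnd in 1:3) means[cbind(ri, ci, bnd)] <- agg[, bnd]
  scaled <- means
  for (bnd in 1:3) {
    v <- means[, , bnd]
    rng <- range(v, na.rm = TRUE)
    scaled[, , bnd] <- if (diff(rng) > 0) (v - rng[1]) / diff(rng)
                       else v * 0 + 0.5
  }
  structure(scaled,
            extent = c(xmin = min(cx) * cell_size,
                       xmax = (max(cx) + 1) * cell_size,
                       ymin = min(cy) * cell_size,
                       ymax = (max(cy) + 1) * cell_size),
            cell_size = cell_size, means = means)
}
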