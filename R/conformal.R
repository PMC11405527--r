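#' Finite-sample conformal nonconformity quantile
#'
#' Returns the `ceiling((n + 1) * (1 - alpha))`-th smallest value of the
#' absolute residuals (capped at the maximum when the rank exceeds `n`), the
#' split-conformal quantile guaranteeing marginal coverage `>= 1 - alpha`
#' under exchangeability.
#'
#' @param abs_residuals Non-negative nonconformity scores.
#' @param alpha Miscoverage level.
#' @return The quantile (same units as the residuals).
#' @export
conformal_quantile <- function(abs_residuals, alpha = 0.05) {
  stopifnot(length(abs_residuals) >= 1, all(abs_residuals >= 0),
            alpha >= 0, alpha < 1)
  r <- sort(abs_residuals)
  k <- ceiling((length(r) + 1) * (1 - alpha))
  r[min(k, length(r))]
}

#' Mondrian split-conformal calibration
#'
#' Calibrates per-bin nonconformity quantiles for a fitted WSCI model on rows
#' from sites never used in training. The predicted value is the Mondrian
#' taxonomy: calibration predictions are cut into `n_bins` equal-count bins,
#' bins with fewer than `min_bin` rows are merged with a neighbour, and each
#' bin receives its own finite-sample quantile of the absolute residuals.
#' Binning on the prediction (rather than the unobservable truth) keeps the
#' intervals deployable while absorbing heteroskedastic residual spread.
#'
#' @param object A fitted `wsci` object.
#' @param newdata Calibration rows (disjoint sites from training).
#' @param alpha Miscoverage level (default 0.05, i.e. 95% intervals).
#' @param n_bins Initial number of equal-count bins (default 10).
#' @param min_bin Minimum calibration rows per bin (default 20).
#' @return The `wsci` object with a `calibration` element (per PFT: bin
#'   edges, per-bin quantiles `q`, counts; plus `alpha`).
#' @export
calibrate_mondrian <- function(object, newdata, alpha = 0.05, n_bins = 10,
                               min_bin = 20) {
  stopifnot(inherits(object, "wsci"), alpha >= 0, alpha < 1, n_bins >= 1)
  target <- object$target
  if (!target %in% names(newdata))
    stop("calibration rows lack the target column ", target)
  pft <- if (length(object$bundles) == 1L) {
    rep(names(object$bundles), nrow(newdata))
  } else {
    as.character(newdata[[object$pft_col]])
  }
  cal <- list(alpha = alpha, per_pft = list())
  for (pf in unique(pft)) {
    rows <- newdata[pft == pf, , drop = FALSE]
    if (nrow(rows) < 2 * min_bin)
      stop("too few calibration rows for PFT ", pf, " (", nrow(rows),
           " < ", 2 * min_bin, ")")
    b <- bundle_for(object, pf)
    pred <- predict_trees(b$pb, wsci_matrix(rows))
    res <- abs(rows[[target]] - pred)
    nb <- max(1L, min(n_bins, floor(length(res) / min_bin)))
    edges <- unique(stats::quantile(pred, (0:nb) / nb, names = FALSE))
    edges[1] <- -Inf; edges[length(edges)] <- Inf
    bin_of <- pmin(pmax(findInterval(pred, edges, all.inside = TRUE), 1L),
                   length(edges) - 1L)
    # merge undersized bins with their smaller neighbour
    repeat {
      counts <- tabulate(bin_of, length(edges) - 1L)
      small <- which(counts < min_bin)
      if (!length(small) || length(edges) <= 2L) break
      bi <- small[1]
      drop <- if (bi == 1L) 2L
              else if (bi == length(counts)) bi
              else if (counts[bi - 1] <= counts[bi + 1]) bi else bi + 1L
      edges <- edges[-drop]
      bin_of <- pmin(pmax(findInterval(pred, edges, all.inside = TRUE), 1L),
                     length(edges) - 1L)
    }
    counts <- tabulate(bin_of, length(edges) - 1L)
    q <- vapply(seq_len(length(edges) - 1L), function(bb)
      conformal_quantile(res[bin_of == bb], alpha), numeric(1))
    cal$per_pft[[pf]] <- list(edges = edges, q = q, counts = counts)
  }
  object$calibration <- cal
  object
}

#' Conformal prediction intervals
#'
#' Produces `prediction +/- q_b` intervals where `q_b` is the calibrated
#' nonconformity quantile of the Mondrian bin containing the prediction.
#' Predictions falling outside every calibrated bin use the nearest bin's
#' quantile and are flagged in the `extrapolated` attribute. The relative
#' size is `(upper - lower) / fit` where the centre is positive.
#'
#' @param object A calibrated `wsci` object (see [calibrate_mondrian()]).
#' @param newdata Rows with RH features (and PFT column if multi-PFT).
#' @return Data frame with columns `fit`, `lwr`, `upr`, `relative`.
#' @export
predict_interval <- function(object, newdata) {
  stopifnot(inherits(object, "wsci"))
  if (is.null(object$calibration))
    stop("model is not conformally calibrated; run calibrate_mondrian() first")
  X <- wsci_matrix(newdata)
  pft <- if (length(object$bundles) == 1L) {
    rep(names(object$bundles), nrow(X))
  } else {
    as.character(newdata[[object$pft_col]])
  }
  fit <- lwr <- upr <- numeric(nrow(X))
  extra <- logical(nrow(X))
  for (pf in unique(pft)) {
    b <- bundle_for(object, pf)
    cal <- object$calibration$per_pft[[pf]]
    if (is.null(cal)) stop("no calibration for PFT ", pf)
    i <- which(pft == pf)
    p <- predict_trees(b$pb, X[i, , drop = FALSE])
    nb <- length(cal$q)
    raw <- findInterval(p, cal$edges, all.inside = TRUE)
    bb <- pmin(pmax(raw, 1L), nb)
    fit[i] <- p
    lwr[i] <- p - cal$q[bb]
    upr[i] <- p + cal$q[bb]
    extra[i] <- p < cal$edges[1] | p > cal$edges[nb + 1L]
  }
  out <- data.frame(fit = fit, lwr = lwr, upr = upr,
                    relative = ifelse(fit > 0, (upr - lwr) / fit, NA_real_))
  attr(out, "extrapolated") <- extra
  out
}

#' Empirical interval coverage on a holdout set
#'
#' Fraction of holdout targets falling inside their conformal intervals.
#' Under exchangeability of holdout and calibration rows the expected
#' coverage is at least `1 - alpha`.
#'
#' @param object A calibrated `wsci` object.
#' @param newdata Holdout rows carrying the target column.
#' @return Coverage fraction in `[0, 1]`.
#' @export
empirical_coverage <- function(object, newdata) {
  if (nrow(newdata) == 0) stop("empty holdout")
  target <- object$target
  if (!target %in% names(newdata)) stop("holdout lacks target column ", target)
  pi <- predict_interval(object, newdata)
  mean(newdata[[target]] >= pi$lwr & newdata[[target]] <= pi$upr)
}
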