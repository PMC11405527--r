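#' Site-blocked cross-validation folds
#'
#' Assigns every row of a training table to one of `k` folds such that all
#' rows of a site share a fold (spatial blocking: validation folds contain
#' only geographic locations unseen in training folds). Sites are assigned
#' greedily in random order, largest first, each to the currently smallest
#' fold, which balances fold sizes by row count.
#'
#' @param data Training table with a site column.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the site shuffle.
#' @param site_col Name of the site column (default `"site_id"`).
#' @return Integer vector of fold labels, one per row.
#' @export
spatial_folds <- function(data, k = 5, seed = 1L, site_col = "site_id") {
  sites <- table(data[[site_col]])
  if (length(sites) < k)
    stop("fewer distinct sites (", length(sites), ") than folds (", k, ")")
  set.seed(seed)
  ord <- names(sites)[sample(length(sites))]
  ord <- ord[order(-sites[ord])]            # largest first, random ties
  load <- numeric(k)
  fold_of <- integer(0)
  for (s in ord) {
    f <- which.min(load)
    load[f] <- load[f] + sites[[s]]
    fold_of[s] <- f
  }
  unname(fold_of[as.character(data[[site_col]])])
}

#' Hyperparameter grid for boosted-tree models
#'
#' Expands the Cartesian grid over the five tuned hyperparameters: number of
#' estimators (trees), subsample fraction of rows, feature fraction per tree,
#' maximum tree depth and learning rate. The default 3 x 2 x 2 x 3 x 2 grid is
#' deliberately small; pass vectors to widen it. `min_child_weight` and
#' `lambda` are fixed regularisers applied to every configuration.
#'
#' @param n_estimators,subsample,feature_fraction,max_depth,learning_rate
#'   Vectors of candidate values.
#' @param min_child_weight,lambda Scalar regularisers.
#' @return Data frame, one row per configuration.
#' @export
wsci_grid <- function(n_estimators = c(60, 100, 150),
                      subsample = c(0.7, 1),
                      feature_fraction = c(0.7, 1),
                      max_depth = c(1, 2, 3),
                      learning_rate = c(0.05, 0.1),
                      min_child_weight = 20,
                      lambda = 5) {
  g <- expand.grid(n_estimators = n_estimators, subsample = subsample,
                   feature_fraction = feature_fraction, max_depth = max_depth,
                   learning_rate = learning_rate,
                   KEEP.OUT.ATTRS = FALSE)
  stopifnot(all(g$subsample > 0 & g$subsample <= 1),
            all(g$feature_fraction > 0 & g$feature_fraction <= 1),
            all(g$n_estimators >= 1), all(g$max_depth >= 1),
            all(g$learning_rate > 0))
  g$min_child_weight <- min_child_weight
  g$lambda <- lambda
  g
}

xgb_params <- function(cfg, seed) {
  list(objective = "reg:squarederror",
       max_depth = cfg$max_depth,
       eta = cfg$learning_rate,
       subsample = cfg$subsample,
       colsample_bytree = cfg$feature_fraction,
       min_child_weight = cfg$min_child_weight %||% 1,
       lambda = cfg$lambda %||% 1,
       nthread = 1,
       seed = seed)
}

fit_booster <- function(X, y, cfg, seed) {
  xgboost::xgb.train(xgb_params(cfg, seed),
                     xgboost::xgb.DMatrix(X, label = y),
                     nrounds = cfg$n_estimators, verbose = 0)
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))
r_squared <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)

cv_config <- function(X, y, fold, cfg, seed) {
  ks <- sort(unique(fold))
  m <- matrix(NA_real_, length(ks), 4,
              dimnames = list(NULL, c("rmse_tr", "rmse_val", "r2_tr", "r2_val")))
  for (i in seq_along(ks)) {
    tr <- fold != ks[i]
    fit <- fit_booster(X[tr, , drop = FALSE], y[tr], cfg, seed)
    pt <- predict(fit, X[tr, , drop = FALSE])
    pv <- predict(fit, X[!tr, , drop = FALSE])
    m[i, ] <- c(rmse(y[tr], pt), rmse(y[!tr], pv),
                r_squared(y[tr], pt), r_squared(y[!tr], pv))
  }
  colMeans(m)
}

gap_pct <- function(tr, val, type) {
  if (type == "relative") abs(tr - val) / abs(tr) * 100 else abs(tr - val) * 100
}

#' Spatially cross-validated hyperparameter search
#'
#' Evaluates every configuration of `grid` by k-fold site-blocked
#' cross-validation, keeps only configurations whose mean train-versus-
#' validation gaps in RMSE and R-squared are both below `gap_limit` percent
#' (the generalisation constraint), and among those returns the one with the
#' smallest mean validation RMSE. Ties are broken by fewer estimators, then
#' smaller depth.
#'
#' @param data Training table containing RH feature columns, the target and a
#'   site column.
#' @param target Target column: `"ce_xyz"`, `"ce_xy"` or `"ce_z"`.
#' @param grid Configuration grid from [wsci_grid()].
#' @param k Number of folds.
#' @param seed Integer seed (folds, subsampling, fitting).
#' @param gap_limit Admissibility threshold in percent (default 5).
#' @param gap_type `"relative"` (default, gap / training metric) or
#'   `"absolute"` (difference in metric units x 100).
#' @param site_col Site column name.
#' @return List with `params` (the selected configuration row), `cv` (per-
#'   configuration metrics with gaps and admissibility), `gap_rmse`,
#'   `gap_r2` of the selected configuration.
#' @export
grid_search_select <- function(data, target = "ce_xyz", grid = wsci_grid(),
                               k = 5, seed = 1L, gap_limit = 5,
                               gap_type = c("relative", "absolute"),
                               site_col = "site_id") {
  gap_type <- match.arg(gap_type)
  stopifnot(nrow(grid) >= 1, target %in% names(data))
  X <- as.matrix(data[, rh_names()])
  y <- data[[target]]
  fold <- spatial_folds(data, k = k, seed = seed, site_col = site_col)
  cv <- grid
  cv$rmse_tr <- cv$rmse_val <- cv$r2_tr <- cv$r2_val <- NA_real_
  for (i in seq_len(nrow(grid))) {
    met <- cv_config(X, y, fold, grid[i, ], seed)
    cv$rmse_tr[i] <- met["rmse_tr"]; cv$rmse_val[i] <- met["rmse_val"]
    cv$r2_tr[i] <- met["r2_tr"]; cv$r2_val[i] <- met["r2_val"]
  }
  cv$gap_rmse <- gap_pct(cv$rmse_tr, cv$rmse_val, gap_type)
  cv$gap_r2 <- gap_pct(cv$r2_tr, cv$r2_val, gap_type)
  cv$admissible <- cv$gap_rmse < gap_limit & cv$gap_r2 < gap_limit
  adm <- which(cv$admissible)
  if (!length(adm))
    stop("no admissible configuration: every grid point exceeds the ",
         gap_limit, "% train/validation gap limit")
  ord <- adm[order(cv$rmse_val[adm], cv$n_estimators[adm], cv$max_depth[adm])]
  sel <- ord[1]
  list(params = grid[sel, ], cv = cv,
       gap_rmse = cv$gap_rmse[sel], gap_r2 = cv$gap_r2[sel])
}

#' Fit WSCI models from RH metrics
#'
#' The central fitting function: trains one gradient-boosted regression model
#' per plant functional type (PFT) present in `data`, predicting the chosen
#' canopy-entropy target (`ce_xyz`, i.e. WSCI, `ce_xy` or `ce_z`) from the
#' 101 RH percentile features. Hyperparameters are either selected per PFT by
#' the spatially cross-validated [grid_search_select()] (the default) or
#' supplied directly. Conformal calibration can be attached afterwards with
#' [calibrate_mondrian()].
#'
#' @param data Training table with columns `site_id`, a PFT column, the RH
#'   features `rh0 ... rh100` and the target.
#' @param target `"ce_xyz"`, `"ce_xy"` or `"ce_z"`.
#' @param params Optional configuration (one-row data frame, as a row of
#'   [wsci_grid()]); when `NULL` a grid search selects it per PFT.
#' @param grid Grid used when `params` is `NULL`.
#' @param k Cross-validation folds for the search.
#' @param seed Integer seed threaded to folds, subsampling and fitting.
#' @param min_rows Minimum rows per PFT; smaller strata are refused with a
#'   warning (configurable floor).
#' @param gap_limit,gap_type Passed to [grid_search_select()].
#' @param pft_col,site_col Column names.
#' @return An object of class `wsci`: list with `target`, `bundles` (one per
#'   PFT: booster, params, CV metrics, gaps, seed), `seed`, `call`.
#' @examples
#' sites <- simulate_rh_sites(6, seed = 1)
#' tab <- simulate_rh_table(600, sites, seed = 2)
#' fit <- wsci_fit(tab, params = wsci_grid(100, 0.7, 0.7, 2, 0.1), seed = 1)
#' predict(fit, tab[1:3, ])
#' @export
wsci_fit <- function(data, target = c("ce_xyz", "ce_xy", "ce_z"),
                     params = NULL, grid = wsci_grid(), k = 5, seed = 1L,
                     min_rows = 100, gap_limit = 5,
                     gap_type = c("relative", "absolute"),
                     pft_col = "pft", site_col = "site_id") {
  target <- match.arg(target)
  gap_type <- match.arg(gap_type)
  stopifnot(all(rh_names() %in% names(data)), target %in% names(data))
  if (anyNA(data[, rh_names()])) stop("missing RH values in training table")
  pfts <- unique(as.character(data[[pft_col]]))
  bundles <- list()
  for (pf in pfts) {
    rows <- data[data[[pft_col]] == pf, , drop = FALSE]
    if (nrow(rows) < min_rows) {
      warning("PFT ", pf, ": only ", nrow(rows), " rows (< ", min_rows,
              "); refusing to fit")
      next
    }
    if (is.null(params)) {
      sel <- grid_search_select(rows, target = target, grid = grid, k = k,
                                seed = seed, gap_limit = gap_limit,
                                gap_type = gap_type, site_col = site_col)
      cfg <- sel$params
      cvm <- sel
    } else {
      cfg <- params[1, , drop = FALSE]
      cvm <- NULL
    }
    X <- as.matrix(rows[, rh_names()])
    y <- rows[[target]]
    booster <- fit_booster(X, y, cfg, seed)
    pb <- parse_booster(booster, rh_names())
    pt <- predict_trees(pb, X)
    bundles[[pf]] <- list(
      pft = pf, target = target, booster = booster, pb = pb, params = cfg,
      n_train = nrow(rows),
      train_rmse = rmse(y, pt), train_r2 = r_squared(y, pt),
      cv = cvm, seed = seed,
      train = list(y = y, fitted = pt, site_id = rows[[site_col]]))
  }
  if (!length(bundles)) stop("no PFT stratum had enough rows to fit")
  structure(list(target = target, bundles = bundles, seed = seed,
                 pft_col = pft_col, site_col = site_col,
                 calibration = NULL, call = match.call()),
            class = "wsci")
}

wsci_matrix <- function(newdata) {
  miss <- setdiff(rh_names(), names(newdata))
  if (length(miss))
    stop("newdata lacks RH features (expected rh0..rh100); missing e.g. ",
         miss[1])
  as.matrix(newdata[, rh_names()])
}

bundle_for <- function(object, pft) {
  b <- object$bundles[[pft]]
  if (is.null(b)) stop("no fitted model for PFT ", pft)
  b
}

#' Predict canopy complexity from RH metrics
#'
#' @param object A fitted [wsci_fit()] object.
#' @param newdata Data frame with columns `rh0 ... rh100` and (when several
#'   PFT models are fitted) the PFT column.
#' @param interval `"none"` for point predictions, `"conformal"` for Mondrian
#'   split-conformal intervals (requires [calibrate_mondrian()] first).
#' @param ... Unused.
#' @return Numeric vector of predictions (nats), or a data frame with columns
#'   `fit`, `lwr`, `upr`, `relative` when `interval = "conformal"`.
#' @export
predict.wsci <- function(object, newdata, interval = c("none", "conformal"),
                         ...) {
  interval <- match.arg(interval)
  X <- wsci_matrix(newdata)
  pft <- if (length(object$bundles) == 1L) {
    rep(names(object$bundles), nrow(X))
  } else {
    as.character(newdata[[object$pft_col]])
  }
  fit <- numeric(nrow(X))
  for (pf in unique(pft)) {
    b <- bundle_for(object, pf)
    i <- pft == pf
    fit[i] <- predict_trees(b$pb, X[i, , drop = FALSE])
  }
  if (interval == "none") return(fit)
  predict_interval(object, newdata)
}

#' @export
print.wsci <- function(x, ...) {
  cat("WSCI boosted-regression fit; target:", x$target, "\n")
  for (b in x$bundles) {
    cat(sprintf("  %s: n = %d, train RMSE = %.3f, train R2 = %.3f", b$pft,
                b$n_train, b$train_rmse, b$train_r2))
    if (!is.null(b$cv))
      cat(sprintf(", CV val RMSE = %.3f (gaps %.1f%% / %.1f%%)",
                  min(b$cv$cv$rmse_val[b$cv$cv$admissible]),
                  b$cv$gap_rmse, b$cv$gap_r2))
    cat("\n")
  }
  if (!is.null(x$calibration))
    cat(sprintf("  conformal calibration attached (alpha = %g)\n",
                x$calibration$alpha))
  invisible(x)
}

#' @export
summary.wsci <- function(object, ...) {
  rows <- do.call(rbind, lapply(object$bundles, function(b) {
    data.frame(pft = b$pft, target = b$target, n = b$n_train,
               n_estimators = b$params$n_estimators,
               max_depth = b$params$max_depth,
               learning_rate = b$params$learning_rate,
               train_rmse = b$train_rmse, train_r2 = b$train_r2,
               cv_gap_rmse = if (is.null(b$cv)) NA_real_ else b$cv$gap_rmse,
               cv_gap_r2 = if (is.null(b$cv)) NA_real_ else b$cv$gap_r2)
  }))
  rownames(rows) <- NULL
  structure(list(target = object$target, table = rows,
                 calibrated = !is.null(object$calibration)),
            class = "summary.wsci")
}

#' @export
print.summary.wsci <- function(x, ...) {
  cat("WSCI model summary (target:", x$target, ")\n")
  print(x$table, row.names = FALSE)
  cat(if (x$calibrated) "Conformal calibration: attached\n"
      else "Conformal calibration: none\n")
  invisible(x)
}

#' @export
residuals.wsci <- function(object, ...) {
  unlist(lapply(object$bundles, function(b) b$train$y - b$train$fitted),
         use.names = FALSE)
}

#' Observed-versus-predicted plot for a WSCI fit
#'
#' @param x A fitted `wsci` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.wsci <- function(x, ...) {
  obs <- unlist(lapply(x$bundles, function(b) b$train$y), use.names = FALSE)
  fit <- unlist(lapply(x$bundles, function(b) b$train$fitted), use.names = FALSE)
  graphics::plot(obs, fit, xlab = paste("observed", x$target, "(nats)"),
                 ylab = paste("predicted", x$target, "(nats)"),
                 pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor("steelblue", 0.5), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
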