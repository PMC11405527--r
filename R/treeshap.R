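# Double-precision tree traversal and exact path-dependent TreeSHAP for the
# fitted boosted ensembles. xgboost's built-in contribution predictor runs in
# single precision, which is too coarse for the local-accuracy contract
# (base + sum(contributions) == prediction to ~1e-12 here); the trees are
# therefore dumped once and walked in R doubles.

# round doubles to their nearest float32-representable value, since the
# boosted trees compare features against float32 split thresholds
as_float32 <- function(x) {
  dim_x <- dim(x)
  out <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
                 "numeric", n = length(x), size = 4L)
  dim(out) <- dim_x
  dimnames(out) <- dimnames(x)
  out
}

parse_booster <- function(booster, feature_names) {
  raw <- xgboost::xgb.save.raw(booster, raw_format = "json")
  mod <- jsonlite::fromJSON(rawToChar(raw), simplifyVector = TRUE)
  base_score <- as.numeric(mod$learner$learner_model_param$base_score)
  mt <- mod$learner$gradient_booster$model$trees
  trees <- lapply(seq_along(mt$id), function(t) {
    left <- mt$left_children[[t]]
    right <- mt$right_children[[t]]
    is_leaf <- left == -1L
    list(
      is_leaf = is_leaf,
      feature = ifelse(is_leaf, NA_integer_, mt$split_indices[[t]] + 1L),
      # thresholds are float32 in the model; align the stored doubles so
      # that comparisons reproduce the engine bit-for-bit
      split = ifelse(is_leaf, NA_real_, as_float32(mt$split_conditions[[t]])),
      yes = ifelse(is_leaf, NA_integer_, left + 1L),
      no = ifelse(is_leaf, NA_integer_, right + 1L),
      # at leaves, split_conditions holds the leaf weight
      value = ifelse(is_leaf, mt$split_conditions[[t]], NA_real_),
      cover = mt$sum_hessian[[t]])
  })
  list(trees = trees, base_score = base_score,
       feature_names = feature_names)
}

# expected output of one tree under the cover-weighted leaf distribution
tree_expected <- function(tree) {
  ev <- function(j) {
    if (tree$is_leaf[j]) return(tree$value[j])
    (tree$cover[tree$yes[j]] * ev(tree$yes[j]) +
     tree$cover[tree$no[j]] * ev(tree$no[j])) / tree$cover[j]
  }
  ev(1L)
}

# double-precision ensemble prediction (yes branch when x < split),
# vectorised over rows one tree at a time
predict_trees <- function(pb, X) {
  X <- as_float32(X)
  n <- nrow(X)
  out <- rep(pb$base_score, n)
  for (tree in pb$trees) {
    j <- rep(1L, n)
    active <- which(!tree$is_leaf[j])
    while (length(active)) {
      ja <- j[active]
      xv <- X[cbind(active, tree$feature[ja])]
      j[active] <- ifelse(xv < tree$split[ja], tree$yes[ja], tree$no[ja])
      active <- active[!tree$is_leaf[j[active]]]
    }
    out <- out + tree$value[j]
  }
  out
}

# --- path-dependent TreeSHAP (per tree, per observation) ------------------
# The path `m` is a matrix with columns d (feature), z (zero fraction),
# o (one fraction), w (permutation weight).

shap_extend <- function(m, pz, po, pi) {
  L <- nrow(m)
  m <- rbind(m, c(pi, pz, po, if (L == 0) 1 else 0))
  if (L > 0) for (i in L:1) {
    m[i + 1, 4] <- m[i + 1, 4] + po * m[i, 4] * i / (L + 1)
    m[i, 4] <- pz * m[i, 4] * (L + 1 - i) / (L + 1)
  }
  m
}

shap_unwind <- function(m, k) {
  L <- nrow(m)
  o <- m[k, 3]; z <- m[k, 2]
  n <- m[L, 4]
  if (L > 1) for (j in (L - 1):1) {
    if (o != 0) {
      tmp <- m[j, 4]
      m[j, 4] <- n * L / (j * o)
      n <- tmp - m[j, 4] * z * (L - j) / L
    } else {
      m[j, 4] <- m[j, 4] * L / (z * (L - j))
    }
  }
  if (k < L) m[k:(L - 1), 1:3] <- m[(k + 1):L, 1:3, drop = FALSE]
  m[-L, , drop = FALSE]
}

shap_unwound_sum <- function(m, k) {
  L <- nrow(m)
  o <- m[k, 3]; z <- m[k, 2]
  n <- m[L, 4]
  total <- 0
  if (L > 1) for (j in (L - 1):1) {
    if (o != 0) {
      tmp <- n * L / (j * o)
      total <- total + tmp
      n <- m[j, 4] - tmp * z * (L - j) / L
    } else {
      total <- total + m[j, 4] * L / (z * (L - j))
    }
  }
  total
}

tree_shap_one <- function(tree, x, nfeat) {
  phi <- numeric(nfeat)
  recurse <- function(j, m, pz, po, pi) {
    m <- shap_extend(m, pz, po, pi)
    if (tree$is_leaf[j]) {
      L <- nrow(m)
      if (L > 1) for (i in 2:L) {
        w <- shap_unwound_sum(m, i)
        phi[m[i, 1]] <<- phi[m[i, 1]] + w * (m[i, 3] - m[i, 2]) * tree$value[j]
      }
    } else {
      f <- tree$feature[j]
      hot <- if (x[f] < tree$split[j]) tree$yes[j] else tree$no[j]
      cold <- if (hot == tree$yes[j]) tree$no[j] else tree$yes[j]
      iz <- 1; io <- 1
      k <- which(m[, 1] == f)
      if (length(k)) {
        k <- k[1]
        iz <- m[k, 2]; io <- m[k, 3]
        m <- shap_unwind(m, k)
      }
      recurse(hot, m, iz * tree$cover[hot] / tree$cover[j], io, f)
      recurse(cold, m, iz * tree$cover[cold] / tree$cover[j], 0, f)
    }
  }
  recurse(1L, matrix(numeric(0), 0, 4), 1, 1, 0L)
  phi
}

# contributions matrix (n x nfeat + base column) for a parsed booster
treeshap_contrib <- function(pb, X) {
  X <- as_float32(X)
  nfeat <- length(pb$feature_names)
  n <- nrow(X)
  out <- matrix(0, n, nfeat + 1,
                dimnames = list(NULL, c(pb$feature_names, "base")))
  base <- pb$base_score + sum(vapply(pb$trees, tree_expected, numeric(1)))
  out[, nfeat + 1] <- base
  for (tree in pb$trees) {
    for (r in seq_len(n)) {
      out[r, seq_len(nfeat)] <- out[r, seq_len(nfeat)] +
        tree_shap_one(tree, X[r, ], nfeat)
    }
  }
  out
}
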