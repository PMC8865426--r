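#' Marker discovery by boosted stumps and Shapley attribution
#'
#' Features from every layer are concatenated (layer-qualified names) and a
#' gradient-boosted ensemble of depth-1 trees (stumps) with logistic loss
#' is trained one-vs-rest per cluster, on a random 80% subset of the
#' features, with hyperparameters picked by random search under 5-fold
#' cross-validation. Because every tree is a stump, the Shapley attribution
#' of the ensemble is exact and cheap: a stump splitting feature f
#' contributes `leaf(x) - E[leaf]` (expectation over the training
#' background) to feature f and nothing to any other feature. Scores are
#' reported per (feature, cluster) as the mean absolute attribution, in
#' log-odds units, over the samples of that cluster; features scoring above
#' 1 are flagged as markers.
#'
#' @name interpret-module
NULL

# One regression stump on gradient/hessian statistics (second-order
# boosting step); returns NULL when no admissible split improves the loss.
fit_stump <- function(x, g, h, min_leaf, reg = 1.0) {
  o <- order(x)
  xs <- x[o]; gs <- g[o]; hs <- h[o]
  n <- length(x)
  cg <- cumsum(gs); ch <- cumsum(hs)
  G <- cg[n]; H <- ch[n]
  pos <- which(diff(xs) > 0)                      # split after position i
  pos <- pos[pos >= min_leaf & (n - pos) >= min_leaf]
  if (!length(pos)) return(NULL)
  gl <- cg[pos]; hl <- ch[pos]
  gain <- gl^2 / (hl + reg) + (G - gl)^2 / (H - hl + reg) - G^2 / (H + reg)
  b <- which.max(gain)
  if (gain[b] <= 1e-12) return(NULL)
  i <- pos[b]
  list(threshold = (xs[i] + xs[i + 1]) / 2,
       vL = gl[b] / (hl[b] + reg),
       vR = (G - gl[b]) / (H - hl[b] + reg),
       gain = gain[b])
}

gb_fit <- function(X, y, n_trees = 50, learning_rate = 0.1, min_leaf = 5,
                   reg = 1.0) {
  stopifnot(is.matrix(X), length(y) == nrow(X), all(y %in% c(0, 1)))
  pbar <- min(max(mean(y), 1e-6), 1 - 1e-6)
  f0 <- log(pbar / (1 - pbar))
  Fv <- rep(f0, nrow(X))
  trees <- vector("list", n_trees)
  kept <- 0L
  for (t in seq_len(n_trees)) {
    p <- 1 / (1 + exp(-Fv))
    g <- y - p
    h <- pmax(p * (1 - p), 1e-6)
    best <- NULL; best_j <- NA_integer_
    for (j in seq_len(ncol(X))) {
      st <- fit_stump(X[, j], g, h, min_leaf, reg)
      if (!is.null(st) && (is.null(best) || st$gain > best$gain)) {
        best <- st; best_j <- j
      }
    }
    if (is.null(best)) break
    kept <- kept + 1L
    trees[[kept]] <- list(feature = best_j, threshold = best$threshold,
                          vL = best$vL, vR = best$vR)
    step <- ifelse(X[, best_j] <= best$threshold, best$vL, best$vR)
    Fv <- Fv + learning_rate * step
  }
  list(f0 = f0, trees = trees[seq_len(kept)], learning_rate = learning_rate)
}

gb_predict <- function(model, X) {
  Fv <- rep(model$f0, nrow(X))
  for (tr in model$trees) {
    Fv <- Fv + model$learning_rate *
      ifelse(X[, tr$feature] <= tr$threshold, tr$vL, tr$vR)
  }
  Fv
}

# Exact per-feature Shapley attribution of a stump ensemble (log-odds
# units), background expectation taken over `bg`.
gb_shapley <- function(model, X, bg = X) {
  phi <- matrix(0, nrow = nrow(X), ncol = ncol(X), dimnames = dimnames(X))
  for (tr in model$trees) {
    piL <- mean(bg[, tr$feature] <= tr$threshold)
    ev <- piL * tr$vL + (1 - piL) * tr$vR
    v <- ifelse(X[, tr$feature] <= tr$threshold, tr$vL, tr$vR)
    phi[, tr$feature] <- phi[, tr$feature] + model$learning_rate * (v - ev)
  }
  phi
}

# Multiclass accuracy of one-vs-rest stump ensembles under k-fold CV.
gb_cv_score <- function(X, y, cfg, n_folds, seed) {
  n <- nrow(X)
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  classes <- sort(unique(y))
  correct <- 0L
  for (f in seq_len(n_folds)) {
    tr_idx <- folds != f
    scores <- sapply(classes, function(cl) {
      m <- gb_fit(X[tr_idx, , drop = FALSE], as.numeric(y[tr_idx] == cl),
                  n_trees = cfg$n_trees, learning_rate = cfg$learning_rate,
                  min_leaf = cfg$min_leaf)
      gb_predict(m, X[!tr_idx, , drop = FALSE])
    })
    if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1)
    pred <- classes[max.col(scores, ties.method = "first")]
    correct <- correct + sum(pred == y[!tr_idx])
  }
  correct / n
}

#' Per-cluster feature importance
#'
#' @param layers Named list of numeric matrices (samples x features) over a
#'   shared roster; missing entries are imputed to the feature median for
#'   the classifier.
#' @param labels Integer cluster labels, one per sample (>= 2 clusters).
#' @param feature_fraction Fraction of features used for training (default
#'   0.8, drawn at random).
#' @param n_search Random-search iterations for hyperparameters (default 8).
#' @param n_folds Cross-validation folds (default 5; reduced with a warning
#'   when a cluster has fewer samples than folds).
#' @param flag_threshold Attribution threshold above which a feature is
#'   flagged as a marker (default 1, in log-odds units).
#' @param seed Integer seed; fixed seed gives an identical table.
#' @return An object of class `importance_table`: data frame with columns
#'   `feature`, `layer`, `cluster`, `score`, `used`, `flagged`, plus the
#'   chosen hyperparameters as attribute `config`.
#' @export
feature_importance <- function(layers, labels, feature_fraction = 0.8,
                               n_search = 8, n_folds = 5, flag_threshold = 1,
                               seed = 1) {
  stopifnot(is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || any(!nzchar(names(layers)))) {
    names(layers) <- sprintf("layer%d", seq_along(layers))
  }
  n <- nrow(layers[[1]])
  stopifnot(length(labels) == n)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("at least 2 clusters required", call. = FALSE)

  cols <- list(); layer_of <- character(0)
  for (nm in names(layers)) {
    m <- layers[[nm]]
    stopifnot(nrow(m) == n)
    if (is.null(colnames(m))) colnames(m) <- sprintf("F%d", seq_len(ncol(m)))
    colnames(m) <- paste(nm, colnames(m), sep = ".")
    cols[[nm]] <- m
    layer_of <- c(layer_of, rep(nm, ncol(m)))
  }
  X <- do.call(cbind, cols)
  # median imputation so stumps see every sample
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) {
      med <- stats::median(X[, j], na.rm = TRUE)
      X[miss, j] <- if (is.na(med)) 0 else med
    }
  }

  min_cl <- min(table(labels))
  if (min_cl < n_folds) {
    warning(sprintf("smallest cluster has %d sample(s); reducing CV folds", min_cl),
            call. = FALSE)
    n_folds <- max(2L, min_cl)
  }

  seeds <- derive_seeds(seed, 3L)
  p <- ncol(X)
  n_train <- max(1L, round(feature_fraction * p))
  train_feats <- sort(with_seed(seeds[1], sample.int(p, n_train)))
  Xt <- X[, train_feats, drop = FALSE]

  cfgs <- with_seed(seeds[2], lapply(seq_len(n_search), function(i) {
    list(n_trees = sample(c(30L, 50L, 80L, 120L), 1),
         learning_rate = stats::runif(1, 0.05, 0.3),
         min_leaf = sample(c(3L, 5L, 10L), 1))
  }))
  cv_seeds <- derive_seeds(seeds[3], n_search + 1L)
  cv <- vapply(seq_along(cfgs), function(i) {
    gb_cv_score(Xt, labels, cfgs[[i]], n_folds, cv_seeds[i])
  }, numeric(1))
  best_cfg <- cfgs[[which.max(cv)]]

  score_mat <- matrix(0, nrow = p, ncol = length(classes),
                      dimnames = list(colnames(X), as.character(classes)))
  for (ci in seq_along(classes)) {
    m <- gb_fit(Xt, as.numeric(labels == classes[ci]),
                n_trees = best_cfg$n_trees,
                learning_rate = best_cfg$learning_rate,
                min_leaf = best_cfg$min_leaf)
    phi <- gb_shapley(m, Xt)
    members <- labels == classes[ci]
    sc <- colMeans(abs(phi[members, , drop = FALSE]))
    score_mat[train_feats, ci] <- sc
  }

  out <- data.frame(
    feature = rep(colnames(X), times = length(classes)),
    layer = rep(layer_of, times = length(classes)),
    cluster = rep(classes, each = p),
    score = as.vector(score_mat),
    used = rep(seq_len(p) %in% train_feats, times = length(classes)),
    row.names = NULL
  )
  out$flagged <- out$score > flag_threshold
  structure(out, config = best_cfg, cv_accuracy = max(cv),
            class = c("importance_table", "data.frame"))
}
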