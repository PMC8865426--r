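# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately naive (double loops, exhaustive search)
# and must stay independent of the package code paths it checks.

# Wrap one or more symmetric similarity matrices (optionally with masks)
# into a MultiplexNetwork without going through build_network().
toy_network <- function(A_list, W_list = NULL) {
  if (is.matrix(A_list)) A_list <- list(A_list)
  n <- nrow(A_list[[1]])
  ids <- sprintf("S%d", seq_len(n))
  layers <- lapply(seq_along(A_list), function(i) {
    A <- A_list[[i]]
    W <- if (is.null(W_list)) matrix(1, n, n) else W_list[[i]]
    present <- diag(W) == 1
    structure(list(A = A, W = W, n_layer = sum(present),
                   lambda = sum(present)^(-2),
                   metric = "euclidean-rbf", name = sprintf("l%d", i)),
              class = "SimilarityLayer")
  })
  names(layers) <- sprintf("l%d", seq_along(layers))
  structure(list(layers = layers, sample_ids = ids, t = length(layers)),
            class = "MultiplexNetwork")
}

# Random symmetric similarity-like matrix from random points (well posed,
# positive, diag 1).
random_similarity <- function(n, dim = 3) {
  X <- matrix(rnorm(n * dim), n, dim)
  A <- exp(-as.matrix(dist(X))^2 / 2)
  dimnames(A) <- NULL
  A
}

# Entry-by-entry objective oracle.
naive_objective <- function(A_list, W_list, lambdas, H, S_list, eta) {
  lambdas <- unname(lambdas)
  total <- 0
  n <- nrow(H)
  for (l in seq_along(A_list)) {
    recon <- H %*% S_list[[l]] %*% t(H)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (W_list[[l]][i, j] == 1) {
        total <- total + lambdas[l] * (A_list[[l]][i, j] - recon[i, j])^2
      }
    }
  }
  total + eta * sum(H^2)
}

# Naive multiplicative-update oracles, written straight from the formulas.
naive_update_S <- function(H, S, A, W, guard = 1e-12) {
  num <- t(H) %*% (W * A) %*% H
  den <- t(H) %*% (W * (H %*% S %*% t(H))) %*% H
  S * num / (den + guard)
}

naive_update_H <- function(H, S_list, A_list, W_list, lambdas, eta,
                           guard = 1e-12) {
  num <- 0 * H
  den <- 0 * H
  for (l in seq_along(A_list)) {
    num <- num + lambdas[l] * (W_list[[l]] * A_list[[l]]) %*% H %*% S_list[[l]]
    den <- den + lambdas[l] *
      (W_list[[l]] * (H %*% S_list[[l]] %*% t(H))) %*% H %*% S_list[[l]]
  }
  H * num / (den + 0.5 * eta * H + guard)
}

# Exhaustive minimum-normalized-cut bipartition of a small graph.
exhaustive_min_ncut <- function(A) {
  n <- nrow(A)
  stopifnot(n <= 12)
  d <- rowSums(A)
  best <- NULL
  best_val <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    side <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    cut <- sum(A[side, !side])
    vol1 <- sum(d[side]); vol2 <- sum(d[!side])
    if (vol1 == 0 || vol2 == 0) next
    val <- cut / vol1 + cut / vol2
    if (val < best_val - 1e-12) {
      best_val <- val
      best <- side
    }
  }
  list(side = best, value = best_val)
}

# Projected-gradient local solver for the single-layer tri-factorization,
# used as a random-restart oracle for solver quality.
pgd_solve <- function(A, lambda, eta, H, S, iters = 300) {
  step <- 0.1
  obj <- function(H, S) lambda * sum((A - H %*% S %*% t(H))^2) + eta * sum(H^2)
  L <- obj(H, S)
  for (i in seq_len(iters)) {
    R <- A - H %*% S %*% t(H)
    gH <- -4 * lambda * (R %*% H %*% S) + 2 * eta * H
    gS <- -2 * lambda * crossprod(H, R %*% H)
    repeat {
      Hn <- pmax(H - step * gH, 0)
      Sn <- pmax(S - step * gS, 0)
      Ln <- obj(Hn, Sn)
      if (Ln <= L || step < 1e-12) break
      step <- step / 2
    }
    if (Ln > L) break
    converged <- (L - Ln) < 1e-13 * (1 + L)
    H <- Hn; S <- Sn; L <- Ln
    if (converged) break
    step <- step * 1.3
  }
  L
}

# Naive cophenetic distances from an hclust merge table (tree traversal,
# independent of stats::cophenetic).
naive_cophenetic <- function(hc) {
  n <- length(hc$order)
  members <- vector("list", nrow(hc$merge))
  D <- matrix(0, n, n)
  for (m in seq_len(nrow(hc$merge))) {
    grab <- function(x) if (x < 0) -x else members[[x]]
    left <- grab(hc$merge[m, 1])
    right <- grab(hc$merge[m, 2])
    D[left, right] <- hc$height[m]
    D[right, left] <- hc$height[m]
    members[[m]] <- c(left, right)
  }
  D
}

# Block consensus matrix: within-block value `hi`, between `lo`.
block_consensus <- function(sizes, hi = 1, lo = 0) {
  lab <- rep(seq_along(sizes), times = sizes)
  C <- ifelse(outer(lab, lab, `==`), hi, lo)
  diag(C) <- 1
  C
}

# Standardize each layer of a cohort and build the multiplex network.
cohort_network <- function(cohort, ...) {
  build_network(lapply(cohort$layers, standardize), ...)
}

# Reduced-scale end-to-end clustering method used in simulation tests:
# prepare -> small resampled ensemble -> consensus -> Normalized Cut.
consensus_method <- function(r, n_runs = 5, max_iter = 150, seed = 17) {
  function(cohort) {
    net <- cohort_network(cohort)
    ens <- run_resampled(net, r, n_runs = n_runs, max_iter = max_iter,
                         seed = seed)
    C <- suppressWarnings(weighted_consensus(ens))
    ncut_labels(C, r, seed = seed + 1L)
  }
}
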