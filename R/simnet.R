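#' Patient-similarity network construction
#'
#' Each omics layer is summarized as a symmetric n x n similarity matrix
#' `A` with entries in `[0, 1]`, together with a binary availability mask
#' `W` (`W[i, j] = 0` where the similarity could not be computed: a sample
#' absent from the layer, or too few commonly observed features for the
#' pair). Layers over a shared sample roster form a multiplex network.
#'
#' @name simnet
NULL

new_similarity_layer <- function(A, W, metric, name = "layer") {
  present <- diag(W) == 1
  n_layer <- sum(present)
  structure(
    list(A = A, W = W, n_layer = n_layer,
         lambda = if (n_layer > 0) n_layer^(-2) else 0,
         metric = metric, name = name),
    class = "SimilarityLayer"
  )
}

#' @export
print.SimilarityLayer <- function(x, ...) {
  cat(sprintf("SimilarityLayer '%s' (%s): %d/%d samples present, lambda = %.3g\n",
              x$name, x$metric, x$n_layer, nrow(x$A), x$lambda))
  invisible(x)
}

#' Missing-data-aware pairwise Euclidean distances
#'
#' For samples i and j with common observed feature set `C_ij` out of `p`
#' features, the squared distance is inflated by the overlap:
#' `rho^2(i, j) = (p / |C_ij|) * sum_{m in C_ij} (f_im - f_jm)^2`,
#' which reduces to the plain squared Euclidean distance for complete data.
#' A pair sharing fewer than `min_overlap_fraction * p` observed features is
#' unavailable (`NA`). The diagonal is 0 for samples with any observed
#' feature; a sample with no observed features has every entry unavailable.
#'
#' @param m Standardized numeric matrix, samples x features, `NA` allowed.
#' @param min_overlap_fraction Minimum fraction of commonly observed
#'   features required for a pairwise distance (default 0.1).
#' @return An n x n matrix of distances `rho` with `NA` for unavailable
#'   pairs.
#' @export
pairwise_distance <- function(m, min_overlap_fraction = 0.1) {
  check_feature_matrix(m)
  stopifnot_scalar(min_overlap_fraction, "min_overlap_fraction", min = 0, max = 1)
  n <- nrow(m); p <- ncol(m)
  obs <- !is.na(m)
  x0 <- m; x0[!obs] <- 0
  o <- matrix(as.numeric(obs), nrow = n)
  cross <- tcrossprod(x0)                    # sum_m x_im x_jm over common m
  sq <- tcrossprod(x0^2, o)                  # sum over common m of x_im^2
  overlap <- tcrossprod(o)
  ss <- sq + t(sq) - 2 * cross
  ss[ss < 0] <- 0                            # numerical jitter
  d2 <- ifelse(overlap > 0, (p / overlap) * ss, NA_real_)
  min_overlap <- max(1, min_overlap_fraction * p)
  d2[overlap < min_overlap] <- NA_real_
  diag(d2) <- ifelse(rowSums(obs) > 0, 0, NA_real_)
  absent <- rowSums(obs) == 0
  if (any(absent)) {
    warning(sprintf("%d sample(s) with no observed features: all their distances unavailable",
                    sum(absent)), call. = FALSE)
  }
  out <- sqrt(d2)
  dimnames(out) <- list(rownames(m), rownames(m))
  out
}

#' Local scaling factors from nearest-neighbor distances
#'
#' `eps_i` is the mean of the `K` smallest available off-diagonal distances
#' from sample i (its K nearest neighbors). When fewer than `K` neighbors
#' are available, all available neighbors are used with a warning; a sample
#' with no available neighbor gets `eps_i = NA`.
#'
#' @param D Distance matrix from [pairwise_distance()].
#' @param K Number of nearest neighbors (default 10% of samples, at least 1).
#' @export
local_scale <- function(D, K = max(1L, round(0.1 * nrow(D)))) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  stopifnot_scalar(K, "K", min = 1, integer = TRUE)
  n <- nrow(D)
  eps <- rep(NA_real_, n)
  short <- 0L
  for (i in seq_len(n)) {
    d <- D[i, -i]
    d <- d[!is.na(d)]
    if (length(d) == 0L) next
    if (length(d) < K) short <- short + 1L
    kk <- min(K, length(d))
    eps[i] <- mean(sort(d, method = "radix")[seq_len(kk)])
  }
  if (short > 0L) {
    warning(sprintf("%d sample(s) had fewer than K = %d available neighbors; used all available",
                    short, K), call. = FALSE)
  }
  names(eps) <- rownames(D)
  eps
}

#' Locally-scaled radial-basis similarity
#'
#' `A(i, j) = exp(-rho^2(i, j) / (mu * eps_i * eps_j))` with the diagonal
#' forced to 1 for samples present in the layer. Entries with unavailable
#' distances or scales get mask 0. Degenerate `eps = 0` (duplicate points)
#' follows the continuity convention: similarity 1 at distance 0, and 0 at
#' any positive distance.
#'
#' @param D Distance matrix.
#' @param eps Local scale vector from [local_scale()].
#' @param mu Kernel bandwidth multiplier (default 0.5).
#' @param name Layer name.
#' @return A `SimilarityLayer`.
#' @export
rbf_similarity <- function(D, eps, mu = 0.5, name = "layer") {
  stopifnot(is.matrix(D), length(eps) == nrow(D))
  stopifnot_scalar(mu, "mu", min = 1e-12)
  denom <- mu * outer(eps, eps)
  A <- exp(-D^2 / denom)
  # eps == 0 duplicates: exp(-x/0): 0/0 at D==0 -> 1; c/0 -> 0
  zero_eps <- which(denom == 0, arr.ind = TRUE)
  if (nrow(zero_eps)) {
    A[zero_eps] <- ifelse(D[zero_eps] == 0, 1, 0)
  }
  A[is.na(D) | is.na(denom)] <- NA_real_
  present <- !is.na(eps)
  diag(A) <- ifelse(present, 1, NA_real_)
  W <- matrix(as.numeric(!is.na(A)), nrow = nrow(A), dimnames = dimnames(D))
  A[is.na(A)] <- NA_real_
  dimnames(A) <- dimnames(D)
  new_similarity_layer(A, W, metric = "euclidean-rbf", name = name)
}

#' Correlation-based similarity
#'
#' Computes cosine, Pearson, or Spearman association between sample feature
#' vectors over their commonly observed features, then maps the raw score
#' `r` in `[-1, 1]` to `(1 + r) / 2` in `[0, 1]`. The pairwise feature
#' overlap rule from [pairwise_distance()] applies; zero-variance vectors
#' under pearson/spearman (or zero-norm vectors under cosine) produce
#' unavailable entries.
#'
#' @param m Numeric matrix, samples x features.
#' @param metric One of `"cosine"`, `"pearson"`, `"spearman"`.
#' @param min_overlap_fraction Minimum common-feature fraction (default 0.1).
#' @param name Layer name.
#' @return A `SimilarityLayer`.
#' @export
correlation_similarity <- function(m, metric = c("cosine", "pearson", "spearman"),
                                   min_overlap_fraction = 0.1, name = "layer") {
  check_feature_matrix(m)
  metric <- match.arg(metric)
  n <- nrow(m); p <- ncol(m)
  obs <- !is.na(m)
  o <- matrix(as.numeric(obs), nrow = n)
  overlap <- tcrossprod(o)
  min_overlap <- max(2, min_overlap_fraction * p)

  if (metric == "cosine") {
    x0 <- m; x0[!obs] <- 0
    cross <- tcrossprod(x0)
    sq <- tcrossprod(x0^2, o)     # norm over common features, pair-specific
    denom <- sqrt(sq * t(sq))
    r <- ifelse(denom > 0, cross / denom, NA_real_)
  } else {
    r <- suppressWarnings(
      stats::cor(t(m), use = "pairwise.complete.obs",
                 method = if (metric == "pearson") "pearson" else "spearman"))
  }
  r[overlap < min_overlap] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  A <- (1 + r) / 2
  present <- rowSums(obs) > 0
  diag(A) <- ifelse(present, 1, NA_real_)
  W <- matrix(as.numeric(!is.na(A)), nrow = n, dimnames = dimnames(A))
  dimnames(A) <- list(rownames(m), rownames(m))
  dimnames(W) <- dimnames(A)
  new_similarity_layer(A, W, metric = metric, name = name)
}

#' Build a multiplex similarity network from feature matrices
#'
#' Unifies the sample rosters of all layers (union of sample ids, in first
#' appearance order), computes one similarity layer per feature matrix, and
#' attaches per-layer weights `lambda_i = n_i^-2` correcting for unequal
#' numbers of available entries across layers. Samples absent from a layer
#' get all-zero mask rows/columns in it.
#'
#' @param layers Named list of numeric matrices (samples x features, rownames
#'   = sample ids). Matrices should be standardized when using the RBF
#'   metric.
#' @param metric Similarity metric per layer (recycled): `"euclidean-rbf"`,
#'   `"cosine"`, `"pearson"`, or `"spearman"`.
#' @param mu RBF bandwidth multiplier (default 0.5).
#' @param k_frac Nearest-neighbor fraction for local scaling (default 0.1 of
#'   the samples present in the layer).
#' @param min_overlap_fraction Minimum common-feature fraction per pair.
#' @return A `MultiplexNetwork`: list with `layers` (list of
#'   `SimilarityLayer`), `sample_ids`, and `t` (layer count).
#' @export
build_network <- function(layers, metric = "euclidean-rbf", mu = 0.5,
                          k_frac = 0.1, min_overlap_fraction = 0.1) {
  stopifnot(is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || any(!nzchar(names(layers)))) {
    names(layers) <- sprintf("layer%d", seq_along(layers))
  }
  metric <- rep_len(metric, length(layers))
  roster <- character(0)
  for (m in layers) {
    check_feature_matrix(m)
    if (is.null(rownames(m))) stop("layer matrices need sample-id rownames", call. = FALSE)
    roster <- union(roster, rownames(m))
  }
  n <- length(roster)
  sims <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    m <- layers[[li]]
    full <- matrix(NA_real_, nrow = n, ncol = ncol(m),
                   dimnames = list(roster, colnames(m)))
    full[rownames(m), ] <- m
    if (metric[li] == "euclidean-rbf") {
      D <- suppressWarnings(pairwise_distance(full, min_overlap_fraction))
      n_here <- sum(rowSums(!is.na(full)) > 0)
      K <- max(1L, round(k_frac * n_here))
      eps <- suppressWarnings(local_scale(D, K))
      sims[[li]] <- rbf_similarity(D, eps, mu = mu, name = names(layers)[li])
    } else {
      sims[[li]] <- correlation_similarity(full, metric = metric[li],
                                           min_overlap_fraction = min_overlap_fraction,
                                           name = names(layers)[li])
    }
  }
  names(sims) <- names(layers)
  covered <- Reduce(`+`, lapply(sims, function(s) diag(s$W)))
  if (any(covered == 0)) {
    warning(sprintf("%d sample(s) have no data in any layer", sum(covered == 0)),
            call. = FALSE)
  }
  structure(list(layers = sims, sample_ids = roster, t = length(sims)),
            class = "MultiplexNetwork")
}

#' @export
print.MultiplexNetwork <- function(x, ...) {
  cat(sprintf("MultiplexNetwork: %d samples, %d layer(s)\n",
              length(x$sample_ids), x$t))
  for (l in x$layers) print(l)
  invisible(x)
}

#' Subset a multiplex network to a set of samples
#'
#' Restricts every layer's similarity matrix and mask to the given sample
#' indices and recomputes `n_layer` and `lambda` on the subset.
#'
#' @param network A `MultiplexNetwork`.
#' @param idx Integer sample indices to keep.
#' @export
subset_network <- function(network, idx) {
  stopifnot(inherits(network, "MultiplexNetwork"))
  layers <- lapply(network$layers, function(l) {
    new_similarity_layer(l$A[idx, idx, drop = FALSE],
                         l$W[idx, idx, drop = FALSE],
                         metric = l$metric, name = l$name)
  })
  structure(list(layers = layers, sample_ids = network$sample_ids[idx],
                 t = length(layers)),
            class = "MultiplexNetwork")
}
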