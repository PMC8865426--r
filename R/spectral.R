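#' Single-layer spectral clustering with eigengap rank selection
#'
#' A single similarity layer is clustered through the symmetric normalized
#' Laplacian `L = I - D^-1/2 A D^-1/2`: eigenvalues are sorted ascending,
#' the cluster count is the position of the largest consecutive eigenvalue
#' gap (excluding the connectivity gap between the trivial zero eigenvalue
#' and its successor; a flat spectrum beyond the first eigenvalue selects
#' k = 1), and the samples are partitioned by k-means on the row-normalized
#' leading eigenvectors.
#'
#' @param A A `SimilarityLayer` or a symmetric non-negative matrix;
#'   unavailable entries are treated as 0 with a warning.
#' @param k Optional fixed cluster count; when absent, chosen by eigengap.
#' @param max_k Largest cluster count considered by the eigengap rule
#'   (default 10).
#' @param seed Integer seed for k-means.
#' @param nstart k-means restarts (default 50).
#' @return An object of class `spectral_result`: `labels`, `chosen_k`,
#'   `eigenvalues` (ascending, in `[0, 2]` up to numerical error).
#' @export
spectral_cluster <- function(A, k = NULL, max_k = 10, seed = 1, nstart = 50) {
  if (inherits(A, "SimilarityLayer")) {
    M <- A$A
    M[A$W == 0 | is.na(M)] <- 0
  } else {
    M <- A
    if (anyNA(M)) {
      warning("unavailable similarity entries treated as 0", call. = FALSE)
      M[is.na(M)] <- 0
    }
  }
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  n <- nrow(M)
  d <- rowSums(M)
  if (any(d <= 0)) {
    bad <- if (!is.null(rownames(M))) rownames(M)[d <= 0][1] else which(d <= 0)[1]
    stop(sprintf("isolated sample with zero degree: %s", bad), call. = FALSE)
  }
  dm <- 1 / sqrt(d)
  Lsym <- diag(n) - M * outer(dm, dm)
  es <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  ev <- rev(es$values)                       # ascending
  vecs <- es$vectors[, rev(seq_len(n)), drop = FALSE]

  if (is.null(k)) {
    kmax <- min(max_k, n - 1L)
    # gap g_j = ev[j+1] - ev[j]; exclude j = 1 (connectivity gap)
    gaps <- ev[seq_len(kmax) + 1L] - ev[seq_len(kmax)]
    if (kmax < 2L || all(gaps[-1L] <= 1e-10)) {
      k <- 1L
    } else {
      k <- which.max(gaps[-1L]) + 1L
    }
  }
  stopifnot_scalar(k, "k", min = 1, max = n, integer = TRUE)
  if (k == 1L) {
    labels <- stats::setNames(rep(1L, n), rownames(M))
  } else {
    V <- vecs[, seq_len(k), drop = FALSE]
    rn <- sqrt(rowSums(V^2))
    rn[rn == 0] <- 1
    V <- V / rn
    km <- with_seed(seed, stats::kmeans(V, centers = k, nstart = nstart,
                                        iter.max = 100))
    labels <- stats::setNames(as.integer(km$cluster), rownames(M))
  }
  structure(list(labels = labels, chosen_k = as.integer(k), eigenvalues = ev),
            class = "spectral_result")
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf("spectral_result: k = %d over %d samples\n",
              x$chosen_k, length(x$labels)))
  invisible(x)
}
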