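#' Consensus clustering over resampled factorizations
#'
#' The multiplicative-update solver is sensitive to initial conditions and
#' to the exact sample set, so the final labels come from an ensemble:
#' repeated factorizations on random 95% sample subsets (with coverage of
#' every sample guaranteed), a consensus matrix weighting each run by its
#' residual error, Normalized-Cut partitioning of the consensus, and the
#' PAC / cophenetic-correlation stability metrics for rank selection.
#'
#' @name consensus-module
NULL

#' Resample-and-refactorize ensemble
#'
#' Runs the solver `n_runs` times, each on a random subset holding
#' `round(keep_fraction * n)` samples, with the per-run randomness confined
#' to (a) the sample subset and (b) a fresh multiplicative perturbation of
#' the diagonal SVD-based `S_i` initialization (the `H` initialization stays
#' deterministic). Any sample never drawn is forced into the final runs so
#' each sample is clustered at least once.
#'
#' @param network A `MultiplexNetwork`.
#' @param r Target rank.
#' @param n_runs Number of runs (default 60).
#' @param keep_fraction Fraction of samples kept per run (default 0.95).
#' @param eta,tol,max_iter Solver settings, see [factorize()].
#' @param seed Integer seed.
#' @return A `RunEnsemble`: list of `runs` (each with `idx`, `labels`,
#'   `RE`), plus `n`, `r`, `n_runs`, `keep_fraction`.
#' @export
run_resampled <- function(network, r, n_runs = 60, keep_fraction = 0.95,
                          eta = 0.1, tol = 1e-7, max_iter = 500, seed = 1) {
  stopifnot(inherits(network, "MultiplexNetwork"))
  stopifnot_scalar(n_runs, "n_runs", min = 1, integer = TRUE)
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1) {
    stop("`keep_fraction` must lie in (0, 1]", call. = FALSE)
  }
  n <- length(network$sample_ids)
  m <- max(1L, round(keep_fraction * n))
  seeds <- derive_seeds(seed, n_runs + 1L)

  subsets <- with_seed(seeds[n_runs + 1L], {
    lapply(seq_len(n_runs), function(x) sort(sample.int(n, m)))
  })
  # coverage guarantee: push never-sampled samples into the last runs
  uncovered <- setdiff(seq_len(n), unique(unlist(subsets)))
  ri <- n_runs
  for (s in uncovered) {
    drop_pos <- which(!subsets[[ri]] %in% uncovered)[1L]
    subsets[[ri]][drop_pos] <- s
    subsets[[ri]] <- sort(subsets[[ri]])
    ri <- if (ri > 1L) ri - 1L else n_runs
  }

  runs <- vector("list", n_runs)
  for (x in seq_len(n_runs)) {
    idx <- subsets[[x]]
    sub <- subset_network(network, idx)
    init <- svd_init(sub, r)
    init$S0_list <- with_seed(seeds[x], lapply(init$S0_list, function(S) {
      diag(S) <- diag(S) * stats::runif(r, 0.5, 1.5)  # fresh random S start
      S
    }))
    fit <- factorize(sub, r, eta = eta, tol = tol, max_iter = max_iter,
                     init = init)
    runs[[x]] <- list(idx = idx, labels = fit$labels, RE = fit$RE)
  }
  structure(list(runs = runs, n = n, r = as.integer(r), n_runs = n_runs,
                 keep_fraction = keep_fraction),
            class = "RunEnsemble")
}

#' Residual-weighted consensus matrix
#'
#' Each run `x` contributes a co-clustering indicator `C(x)` over the pairs
#' it sampled, weighted by `weight(x) = (M - RE(x)) / (M - N)` with
#' `M = max RE`, `N = min RE` (the worst run gets weight 0; if all runs tie,
#' every weight is 1). Each consensus entry is normalized by the summed
#' weights of the runs in which both samples were present; a pair never
#' co-sampled (or covered only by zero-weight runs) is set to 0 with a
#' warning.
#'
#' @param ensemble A `RunEnsemble`.
#' @param run_idx Optional integer subset of runs to aggregate (all by
#'   default).
#' @return Symmetric n x n consensus matrix with entries in `[0, 1]`.
#' @export
weighted_consensus <- function(ensemble, run_idx = NULL) {
  stopifnot(inherits(ensemble, "RunEnsemble"))
  runs <- ensemble$runs
  if (!is.null(run_idx)) runs <- runs[run_idx]
  if (length(runs) == 0L) stop("no runs selected", call. = FALSE)
  re <- vapply(runs, function(x) x$RE, numeric(1))
  M <- max(re); N <- min(re)
  w <- if (M > N) (M - re) / (M - N) else rep(1, length(re))
  n <- ensemble$n
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (x in seq_along(runs)) {
    idx <- runs[[x]]$idx
    lab <- runs[[x]]$labels
    co <- outer(lab, lab, `==`) * 1
    num[idx, idx] <- num[idx, idx] + w[x] * co
    den[idx, idx] <- den[idx, idx] + w[x]
  }
  undefined <- den == 0
  if (any(undefined)) {
    warning(sprintf("%d consensus entr(ies) undefined (never co-sampled with positive weight); set to 0",
                    sum(undefined & upper.tri(undefined))), call. = FALSE)
  }
  C <- ifelse(undefined, 0, num / ifelse(den == 0, 1, den))
  C
}

#' Normalized-Cut labels from a consensus matrix
#'
#' Spectral relaxation of the Normalized Cut: embed via the top `r`
#' eigenvectors of the symmetrically normalized affinity
#' `D^-1/2 C D^-1/2`, row-normalize, and run k-means with many restarts
#' under a fixed seed.
#'
#' @param C Symmetric non-negative matrix.
#' @param r Number of clusters.
#' @param seed Integer seed.
#' @param nstart k-means restarts (default 50).
#' @return Integer labels in `1..r`.
#' @export
ncut_labels <- function(C, r, seed = 1, nstart = 50) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  stopifnot_scalar(r, "r", min = 1, integer = TRUE)
  n <- nrow(C)
  if (r == 1L) return(stats::setNames(rep(1L, n), rownames(C)))
  d <- rowSums(C)
  if (any(d <= 0)) {
    warning("zero-degree sample(s) in consensus matrix; tiny uniform affinity added",
            call. = FALSE)
    C <- C + 1e-8
    d <- rowSums(C)
  }
  dm <- 1 / sqrt(d)
  Lsym <- C * outer(dm, dm)
  es <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  V <- es$vectors[, seq_len(r), drop = FALSE]
  rn <- sqrt(rowSums(V^2))
  rn[rn == 0] <- 1
  V <- V / rn
  km <- with_seed(seed, stats::kmeans(V, centers = r, nstart = nstart,
                                      iter.max = 100))
  stats::setNames(as.integer(km$cluster), rownames(C))
}

#' Proportion of ambiguously clustered pairs
#'
#' Fraction of strictly off-diagonal upper-triangle consensus entries lying
#' strictly inside the open interval `(0.1, 0.9)`. Lower is more stable.
#'
#' @param C Consensus matrix with entries in `[0, 1]`.
#' @export
pac <- function(C) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (nrow(C) < 2L) stop("PAC requires at least 2 samples", call. = FALSE)
  v <- C[upper.tri(C)]
  mean(v > 0.1 & v < 0.9)
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - C`;
#' the CCC is the Pearson correlation between the cophenetic distances of
#' that tree and `1 - C` over all upper-triangle pairs. `NA` when the
#' dissimilarity is constant (zero variance).
#'
#' @param C Consensus matrix with entries in `[0, 1]`.
#' @export
ccc <- function(C) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C), nrow(C) >= 3L)
  d <- stats::as.dist(1 - C)
  if (stats::sd(d) == 0) return(NA_real_)
  hc <- stats::hclust(d, method = "average")
  coph <- stats::cophenetic(hc)
  if (stats::sd(coph) == 0) return(NA_real_)
  stats::cor(as.vector(d), as.vector(coph))
}

#' Rank selection by consensus stability
#'
#' For every candidate rank, builds the run ensemble, derives the final
#' labels from the consensus over all runs, and assesses stability on
#' `n_subsets` consensus matrices built from random run subsets (default
#' size 50 of 60). Ranks with median PAC below `pac_threshold` and median
#' CCC above `ccc_threshold` are recommended; the choice stays advisory.
#'
#' @param network A `MultiplexNetwork`.
#' @param ranks Integer vector of candidate ranks.
#' @param n_runs,keep_fraction,eta,tol,max_iter See [run_resampled()].
#' @param subset_size Runs per stability subset (default 50, capped at
#'   `n_runs`).
#' @param n_subsets Number of random run subsets (default 10).
#' @param pac_threshold,ccc_threshold Recommendation rule (defaults 0.1 and
#'   0.95).
#' @param seed Integer seed.
#' @return An object of class `rank_selection`: `summary` data frame
#'   (`rank`, `median_pac`, `median_ccc`, `recommended`), per-rank `labels`,
#'   `pac_dist` / `ccc_dist` matrices, and `consensus` list.
#' @export
select_rank <- function(network, ranks, n_runs = 60, keep_fraction = 0.95,
                        eta = 0.1, tol = 1e-7, max_iter = 500,
                        subset_size = 50, n_subsets = 10,
                        pac_threshold = 0.1, ccc_threshold = 0.95, seed = 1) {
  stopifnot(length(ranks) >= 1)
  n <- length(network$sample_ids)
  ranks <- as.integer(ranks)
  keep <- ranks < n
  if (!all(keep)) {
    warning("skipping rank(s) >= number of samples", call. = FALSE)
    ranks <- ranks[keep]
    if (!length(ranks)) stop("no admissible rank", call. = FALSE)
  }
  subset_size <- min(subset_size, n_runs)
  seeds <- derive_seeds(seed, length(ranks))
  labels <- list(); consensus <- list()
  pac_dist <- matrix(NA_real_, nrow = n_subsets, ncol = length(ranks),
                     dimnames = list(NULL, as.character(ranks)))
  ccc_dist <- pac_dist
  for (ri in seq_along(ranks)) {
    r <- ranks[ri]
    sub_seeds <- derive_seeds(seeds[ri], n_subsets + 2L)
    ens <- run_resampled(network, r, n_runs = n_runs,
                         keep_fraction = keep_fraction, eta = eta, tol = tol,
                         max_iter = max_iter, seed = sub_seeds[n_subsets + 1L])
    Cfull <- weighted_consensus(ens)
    labels[[as.character(r)]] <- ncut_labels(Cfull, r,
                                             seed = sub_seeds[n_subsets + 2L])
    consensus[[as.character(r)]] <- Cfull
    for (b in seq_len(n_subsets)) {
      take <- with_seed(sub_seeds[b], sample.int(n_runs, subset_size))
      Cb <- suppressWarnings(weighted_consensus(ens, run_idx = take))
      pac_dist[b, ri] <- pac(Cb)
      ccc_dist[b, ri] <- ccc(Cb)
    }
  }
  med_pac <- apply(pac_dist, 2, stats::median, na.rm = TRUE)
  med_ccc <- apply(ccc_dist, 2, stats::median, na.rm = TRUE)
  summary <- data.frame(rank = ranks, median_pac = med_pac,
                        median_ccc = med_ccc,
                        recommended = med_pac < pac_threshold &
                          !is.na(med_ccc) & med_ccc > ccc_threshold,
                        row.names = NULL)
  structure(list(summary = summary, labels = labels, consensus = consensus,
                 pac_dist = pac_dist, ccc_dist = ccc_dist),
            class = "rank_selection")
}

#' @export
print.rank_selection <- function(x, ...) {
  cat("Consensus stability by rank:\n")
  print(x$summary, row.names = FALSE)
  rec <- x$summary$rank[x$summary$recommended]
  if (length(rec)) {
    cat("Recommended rank(s):", paste(rec, collapse = ", "), "\n")
  } else {
    cat("No rank meets the stability rule (PAC < 0.1, CCC > 0.95)\n")
  }
  invisible(x)
}

#' Within-cluster similarity score for a labeling
#'
#' `s = sum_j sum_clusters sim(cluster, A_j) / n_j^2`, where `sim` sums the
#' available similarity entries over all unordered within-cluster sample
#' pairs (diagonal excluded) and `n_j` is the number of samples present in
#' layer j.
#'
#' @param network A `MultiplexNetwork`.
#' @param labels Integer labels over the roster.
#' @export
within_cluster_similarity <- function(network, labels) {
  stopifnot(length(labels) == length(network$sample_ids))
  s <- 0
  for (l in network$layers) {
    if (l$n_layer == 0) next
    layer_sum <- 0
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < 2) next
      Ai <- l$A[idx, idx]
      Wi <- l$W[idx, idx]
      v <- (Ai * Wi)[upper.tri(Ai)]
      layer_sum <- layer_sum + sum(v, na.rm = TRUE)
    }
    s <- s + layer_sum / l$n_layer^2
  }
  s
}

#' Sparsity-weight selection
#'
#' Clusters the network once per candidate `eta` (via the resampled
#' consensus pipeline) and scores each labeling by
#' [within_cluster_similarity()]; the candidate with the highest score wins,
#' ties preferring the smaller `eta`.
#'
#' @param network A `MultiplexNetwork`.
#' @param etas Numeric vector of candidates (default `c(0.01, 0.1, 1)`;
#'   includes the default sparsity weight 0.1).
#' @param r Target rank.
#' @param n_runs,keep_fraction,tol,max_iter,seed See [run_resampled()].
#' @return List with `eta` (chosen), `scores` data frame, `labels` per
#'   candidate.
#' @export
select_eta <- function(network, etas = c(0.01, 0.1, 1), r, n_runs = 20,
                       keep_fraction = 0.95, tol = 1e-7, max_iter = 500,
                       seed = 1) {
  stopifnot(length(etas) >= 1)
  etas <- sort(as.numeric(etas))
  seeds <- derive_seeds(seed, length(etas) * 2L)
  scores <- numeric(length(etas))
  labels <- list()
  for (i in seq_along(etas)) {
    ens <- run_resampled(network, r, n_runs = n_runs,
                         keep_fraction = keep_fraction, eta = etas[i],
                         tol = tol, max_iter = max_iter, seed = seeds[2 * i - 1])
    C <- weighted_consensus(ens)
    lab <- ncut_labels(C, r, seed = seeds[2 * i])
    labels[[i]] <- lab
    scores[i] <- within_cluster_similarity(network, lab)
  }
  best <- which.max(scores)     # first max -> smallest eta on ties
  list(eta = etas[best],
       scores = data.frame(eta = etas, s_eta = scores),
       labels = stats::setNames(labels, as.character(etas)))
}
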