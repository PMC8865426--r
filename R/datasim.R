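#' Synthetic multi-layer cohorts with known cluster structure
#'
#' The generator emulates the validation design used throughout the package:
#' `k` isotropic Gaussian blobs in `p` dimensions form a noiseless ground
#' truth, independent Gaussian noise is layered on per data type, and whole
#' samples can be dropped from individual layers to emulate partially
#' overlapping omics assays.
#'
#' A `SyntheticCohort` is a list with elements `layers` (named list of
#' samples x features matrices sharing one roster; a sample missing from a
#' layer has an all-`NA` row there), `truth` (integer cluster labels named by
#' sample), and the generating parameters `n`, `p`, `k`, `blob_sd`,
#' `noise_sd` (per layer), `missing_fraction` (per layer) and `seed`.
#'
#' @name datasim
NULL

new_synthetic_cohort <- function(layers, truth, n, p, k, blob_sd, seed,
                                 noise_sd = NULL, missing_fraction = NULL) {
  if (is.null(noise_sd)) noise_sd <- stats::setNames(rep(0, length(layers)), names(layers))
  if (is.null(missing_fraction)) {
    missing_fraction <- stats::setNames(rep(0, length(layers)), names(layers))
  }
  structure(
    list(layers = layers, truth = truth, n = n, p = p, k = k,
         blob_sd = blob_sd, noise_sd = noise_sd,
         missing_fraction = missing_fraction, seed = seed),
    class = "SyntheticCohort"
  )
}

#' Generate an isotropic Gaussian-blob cohort
#'
#' Draws `n` samples around `k` well-separated cluster centers in `p`
#' dimensions and returns a single-layer cohort. Centers are drawn
#' uniformly from the conventional `[-10, 10]` box per coordinate (under
#' the cohort seed), which spreads the between-cluster signal across all
#' `p` features -- a requirement for the separation to survive per-feature
#' standardization downstream -- and are rescaled up if needed so the
#' minimum pairwise center distance is at least `max(10 * blob_sd, 1)`,
#' keeping the noiseless problem unambiguous even at small `p`. Cluster
#' sizes are as equal as divisibility allows.
#'
#' @param n Number of samples (`n >= k`).
#' @param p Number of features per layer.
#' @param k Number of clusters.
#' @param blob_sd Within-cluster per-coordinate standard deviation (>= 0).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @return A `SyntheticCohort` with one layer named `"layer1"`.
#' @examples
#' ch <- make_blobs(n = 30, p = 5, k = 3, blob_sd = 0.5, seed = 1)
#' table(ch$truth)
#' @export
make_blobs <- function(n, p, k, blob_sd = 0.5, seed = 1) {
  stopifnot_scalar(n, "n", min = 1, integer = TRUE)
  stopifnot_scalar(p, "p", min = 1, integer = TRUE)
  stopifnot_scalar(k, "k", min = 1, integer = TRUE)
  stopifnot_scalar(blob_sd, "blob_sd", min = 0)
  if (k > n) stop("`k` must not exceed `n`", call. = FALSE)
  n <- as.integer(n); p <- as.integer(p); k <- as.integer(k)

  # minimum pairwise center distance, floored at 1 so blob_sd = 0 still
  # gives distinct centers
  sep <- max(10 * blob_sd, 1)

  # sizes differ by at most one sample
  bounds <- floor(n * (0:k) / k)
  truth <- rep(seq_len(k), times = diff(bounds))

  x <- with_seed(seed, {
    centers <- matrix(stats::runif(k * p, -10, 10), nrow = k, ncol = p)
    if (k > 1L) {
      dmin <- min(stats::dist(centers))
      if (dmin == 0) stop("degenerate center draw", call. = FALSE)
      if (dmin < sep) centers <- centers * (sep / dmin)
    }
    noise <- matrix(stats::rnorm(n * p, sd = blob_sd), nrow = n, ncol = p)
    centers[truth, , drop = FALSE] + noise
  })
  sample_ids <- sprintf("S%d", seq_len(n))
  dimnames(x) <- list(sample_ids, sprintf("F%d", seq_len(p)))
  names(truth) <- sample_ids

  new_synthetic_cohort(layers = list(layer1 = x), truth = truth,
                       n = n, p = p, k = k, blob_sd = blob_sd, seed = seed)
}

#' Duplicate a cohort layer
#'
#' Copies an existing layer under a new name so that independent noise or
#' missingness can then be applied per data type.
#'
#' @param cohort A `SyntheticCohort`.
#' @param from Name or index of the layer to copy.
#' @param name Name of the new layer.
#' @export
duplicate_layer <- function(cohort, from = 1L, name = NULL) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  layer <- resolve_layer(cohort, from)
  if (is.null(name)) name <- sprintf("layer%d", length(cohort$layers) + 1L)
  cohort$layers[[name]] <- cohort$layers[[layer]]
  cohort$noise_sd[name] <- cohort$noise_sd[[layer]]
  cohort$missing_fraction[name] <- cohort$missing_fraction[[layer]]
  cohort
}

resolve_layer <- function(cohort, layer) {
  if (is.character(layer)) {
    if (!layer %in% names(cohort$layers)) {
      stop(sprintf("no layer named '%s'", layer), call. = FALSE)
    }
    return(layer)
  }
  stopifnot_scalar(layer, "layer", min = 1, integer = TRUE)
  if (layer > length(cohort$layers)) stop("layer index out of range", call. = FALSE)
  names(cohort$layers)[layer]
}

#' Add Gaussian noise to one cohort layer
#'
#' Adds independent `N(0, noise_sd^2)` noise entrywise to the chosen layer;
#' other layers and missing entries are untouched.
#'
#' @param cohort A `SyntheticCohort`.
#' @param layer Layer name or index.
#' @param noise_sd Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @export
add_noise <- function(cohort, layer, noise_sd, seed = 1) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  stopifnot_scalar(noise_sd, "noise_sd", min = 0)
  nm <- resolve_layer(cohort, layer)
  if (noise_sd > 0) {
    x <- cohort$layers[[nm]]
    eps <- with_seed(seed, matrix(stats::rnorm(length(x), sd = noise_sd),
                                  nrow = nrow(x)))
    keep_na <- is.na(x)
    x <- x + eps
    x[keep_na] <- NA_real_
    cohort$layers[[nm]] <- x
  }
  cohort$noise_sd[nm] <- sqrt(cohort$noise_sd[[nm]]^2 + noise_sd^2)
  cohort
}

#' Remove a random fraction of samples from one layer
#'
#' Flags `floor(fraction * n)` samples, chosen uniformly without replacement,
#' as fully absent (all-`NA` rows) in the chosen layer only. The roster and
#' every other layer are unchanged, emulating a sample that was simply not
#' assayed on that platform.
#'
#' @param cohort A `SyntheticCohort`.
#' @param layer Layer name or index.
#' @param fraction Fraction of samples to drop, in `[0, 1)`.
#' @param seed Integer seed.
#' @export
drop_samples <- function(cohort, layer, fraction, seed = 1) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction >= 1) {
    stop("`fraction` must be a single number in [0, 1)", call. = FALSE)
  }
  nm <- resolve_layer(cohort, layer)
  n_drop <- floor(fraction * cohort$n)
  if (n_drop > 0) {
    idx <- with_seed(seed, sample.int(cohort$n, n_drop))
    cohort$layers[[nm]][idx, ] <- NA_real_
  }
  cohort$missing_fraction[nm] <- fraction
  cohort
}

#' Two-layer noisy cohort used by the simulation experiments
#'
#' Builds one ground-truth blob matrix and derives two data types from it by
#' adding independent Gaussian noise per layer, matching the noise-robustness
#' simulation design (two distinctly separable blobs, `sd = 0.5`, 200 samples
#' by 400 features by default).
#'
#' @param n,p,k,blob_sd Passed to [make_blobs()].
#' @param noise_sd Numeric vector of length 2: per-layer noise standard
#'   deviations.
#' @param seed Integer seed.
#' @export
make_two_layer_cohort <- function(n = 200, p = 400, k = 2, blob_sd = 0.5,
                                  noise_sd = c(1.5, 1.5), seed = 1) {
  stopifnot(length(noise_sd) == 2L)
  seeds <- derive_seeds(seed, 3L)
  ch <- make_blobs(n, p, k, blob_sd, seed = seeds[1])
  ch <- duplicate_layer(ch, from = "layer1", name = "layer2")
  ch <- add_noise(ch, "layer1", noise_sd[1], seed = seeds[2])
  ch <- add_noise(ch, "layer2", noise_sd[2], seed = seeds[3])
  ch
}

#' Noise-robustness sweep experiment
#'
#' For each value in `sweep`, builds `reps` independent two-layer cohorts
#' (layer 1 noise = `base_noise`, layer 2 noise = the sweep value), runs the
#' supplied clustering callable on each, and reports the median adjusted Rand
#' index against the known truth. A callable failure on a replicate is
#' recorded (as `NA`) rather than fatal; if every replicate of a sweep value
#' fails, an error is raised.
#'
#' @param base_noise Noise standard deviation of the fixed layer.
#' @param sweep Numeric vector of noise standard deviations for the varied
#'   layer.
#' @param reps Replicates per sweep value (>= 1).
#' @param method Function `f(cohort)` returning one cluster label per sample
#'   in roster order.
#' @param seed Integer master seed.
#' @param n,p,k,blob_sd Cohort geometry, defaulting to the standard
#'   simulation design.
#' @return A data frame with columns `noise_sd`, `median_ari`, `n_failed`.
#' @export
noise_sweep_experiment <- function(base_noise, sweep, reps, method, seed = 1,
                                   n = 200, p = 400, k = 2, blob_sd = 0.5) {
  stopifnot_scalar(reps, "reps", min = 1, integer = TRUE)
  stopifnot(is.function(method), length(sweep) >= 1)
  seeds <- matrix(derive_seeds(seed, length(sweep) * reps),
                  nrow = length(sweep))
  out <- data.frame(noise_sd = as.numeric(sweep), median_ari = NA_real_,
                    n_failed = 0L)
  for (i in seq_along(sweep)) {
    aris <- rep(NA_real_, reps)
    for (j in seq_len(reps)) {
      ch <- make_two_layer_cohort(n = n, p = p, k = k, blob_sd = blob_sd,
                                  noise_sd = c(base_noise, sweep[i]),
                                  seed = seeds[i, j])
      aris[j] <- tryCatch(ari(method(ch), ch$truth),
                          error = function(e) NA_real_)
    }
    out$n_failed[i] <- sum(is.na(aris))
    if (all(is.na(aris))) {
      stop(sprintf("all %d replicates failed at sweep value %g", reps, sweep[i]),
           call. = FALSE)
    }
    out$median_ari[i] <- stats::median(aris, na.rm = TRUE)
  }
  out
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("SyntheticCohort: %d samples, %d features/layer, %d clusters\n",
              x$n, x$p, x$k))
  for (nm in names(x$layers)) {
    miss <- sum(rowSums(!is.na(x$layers[[nm]])) == 0)
    cat(sprintf("  %s: noise sd %.3g, %d samples fully absent\n",
                nm, x$noise_sd[[nm]], miss))
  }
  invisible(x)
}
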