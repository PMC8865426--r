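#' Per-layer preprocessing
#'
#' Feature matrices are plain numeric matrices with samples in rows and
#' features in columns; `NA` marks a missing measurement. The recommended
#' pipeline order is filter -> transform -> standardize, applied to each
#' data type separately. Batch adjustment is deliberately not implemented:
#' matrices are expected to be batch-corrected upstream if batch structure
#' is known.
#'
#' @name preprocess
NULL

check_feature_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("expected a numeric matrix (samples x features)", call. = FALSE)
  }
  if (!is.null(rownames(m)) && anyDuplicated(rownames(m))) {
    stop("duplicate sample ids in matrix", call. = FALSE)
  }
  if (!is.null(colnames(m)) && anyDuplicated(colnames(m))) {
    stop("duplicate feature ids in matrix", call. = FALSE)
  }
  invisible(TRUE)
}

#' Remove features or samples with too many missing values
#'
#' Drops every feature (or sample) whose fraction of missing entries exceeds
#' `max_missing_fraction`; survivors keep their original order. The default
#' threshold of 0.1 removes rows/columns with more than 10% missing values.
#'
#' @param m Numeric matrix, samples x features.
#' @param max_missing_fraction Threshold in `[0, 1]`; strictly greater
#'   fractions are removed.
#' @param axis `"features"` (columns) or `"samples"` (rows).
#' @export
filter_missing <- function(m, max_missing_fraction = 0.1,
                           axis = c("features", "samples")) {
  check_feature_matrix(m)
  stopifnot_scalar(max_missing_fraction, "max_missing_fraction", min = 0, max = 1)
  axis <- match.arg(axis)
  if (axis == "features") {
    frac <- colMeans(is.na(m))
    keep <- frac <= max_missing_fraction
    if (!any(keep)) {
      stop(sprintf("all features exceed the %.3g missing-fraction threshold",
                   max_missing_fraction), call. = FALSE)
    }
    m[, keep, drop = FALSE]
  } else {
    frac <- rowMeans(is.na(m))
    keep <- frac <= max_missing_fraction
    if (!any(keep)) {
      stop(sprintf("all samples exceed the %.3g missing-fraction threshold",
                   max_missing_fraction), call. = FALSE)
    }
    m[keep, , drop = FALSE]
  }
}

#' Convert methylation beta values to M-values
#'
#' Applies the entrywise logit-type transform `M = log2(beta / (1 - beta))`
#' after clipping beta values into `[clip_eps, 1 - clip_eps]`, since the
#' transform is undefined at 0 and 1. Missing entries propagate.
#'
#' @param m Numeric matrix of beta values in `[0, 1]`, samples x features.
#' @param clip_eps Small positive clipping constant (default `1e-6`).
#' @export
beta_to_m <- function(m, clip_eps = 1e-6) {
  check_feature_matrix(m)
  stopifnot_scalar(clip_eps, "clip_eps", min = 1e-300, max = 0.5)
  rng <- range(m, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("beta values must lie in [0, 1] before clipping", call. = FALSE)
  }
  b <- pmin(pmax(m, clip_eps), 1 - clip_eps)
  out <- log2(b / (1 - b))
  out[is.na(m)] <- NA_real_
  out
}

#' Log-based count transform
#'
#' A documented surrogate for a variance-stabilizing transform of
#' non-negative count data: per-sample median-of-ratios size factors
#' (reference = geometric mean of each feature across samples, over features
#' with a positive geometric mean) followed by `log2(x / sf + 1)`. The
#' transform is monotone in the counts within each sample, and scaling all
#' counts of one sample by a constant leaves its transformed values
#' unchanged (up to the `+1` offset).
#'
#' @param m Numeric matrix of non-negative counts, samples x features.
#' @export
count_transform <- function(m) {
  check_feature_matrix(m)
  if (any(m < 0, na.rm = TRUE)) {
    stop("count matrix must be non-negative", call. = FALSE)
  }
  # reference = geometric mean per feature; size factor = median of the
  # sample's positive ratios to the reference (linear scale)
  logref <- apply(m, 2, function(x) mean(log(x[!is.na(x)])))
  usable <- is.finite(logref)           # features with all-positive counts
  ref <- exp(logref)
  sf <- rep(1, nrow(m))
  if (any(usable)) {
    for (i in seq_len(nrow(m))) {
      ratios <- m[i, usable] / ref[usable]
      ratios <- ratios[!is.na(ratios) & ratios > 0]
      if (length(ratios)) sf[i] <- stats::median(ratios)
    }
  }
  log2(sweep(m, 1, sf, "/") + 1)
}

#' Standardize features to zero mean and unit variance
#'
#' Per-feature z-scores computed over non-missing entries with the sample
#' (n-1) standard deviation. Features with zero variance (or fewer than two
#' observed values) carry no information for similarity construction and are
#' dropped with a warning.
#'
#' @param m Numeric matrix, samples x features.
#' @export
standardize <- function(m) {
  check_feature_matrix(m)
  mu <- colMeans(m, na.rm = TRUE)
  nobs <- colSums(!is.na(m))
  sdv <- apply(m, 2, stats::sd, na.rm = TRUE)
  bad <- nobs < 2L | is.na(sdv) | sdv == 0
  if (any(bad)) {
    warning(sprintf("dropping %d constant or under-observed feature(s)",
                    sum(bad)), call. = FALSE)
    if (all(bad)) stop("no feature with positive variance remains", call. = FALSE)
    m <- m[, !bad, drop = FALSE]
    mu <- mu[!bad]; sdv <- sdv[!bad]
  }
  sweep(sweep(m, 2, mu, "-"), 2, sdv, "/")
}
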