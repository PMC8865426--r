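#' External cluster-agreement indices
#'
#' Standard chance-corrected and information-theoretic comparisons of two
#' labelings over the same samples, used by the simulation experiments and
#' the `evaluate` subcommand.
#'
#' @name evaluate-module
NULL

check_label_pair <- function(a, b) {
  if (length(a) != length(b)) stop("labelings differ in length", call. = FALSE)
  if (length(a) < 2L) stop("at least 2 samples required", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("labels must not contain NA", call. = FALSE)
  invisible(TRUE)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions via the contingency
#' formula; 1 for identical partitions (up to relabeling), ~0 for
#' independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @export
ari <- function(a, b) {
  check_label_pair(a, b)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)    # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Normalized mutual information
#'
#' Mutual information between the two partitions normalized by the
#' arithmetic mean of their entropies; 0 when either partition is trivial.
#'
#' @param a,b Label vectors of equal length.
#' @export
nmi <- function(a, b) {
  check_label_pair(a, b)
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 || hb == 0) return(0)
  pij <- tab[tab > 0]
  eij <- outer(pa, pb)[tab > 0]
  mi <- sum(pij * log(pij / eij))
  mi / mean(c(ha, hb))
}

#' Cluster purity
#'
#' Fraction of samples whose cluster's majority class matches their class:
#' `purity = (1/n) sum_clusters max_class |cluster intersect class|`.
#'
#' @param a Cluster labels.
#' @param b Reference class labels.
#' @export
purity <- function(a, b) {
  check_label_pair(a, b)
  tab <- table(a, b)
  sum(apply(tab, 1, max)) / length(a)
}

#' Compare two labelings with all indices
#'
#' @param a,b Label vectors of equal length.
#' @return List with `ari`, `nmi`, `purity`, and the `contingency` table.
#' @export
label_comparison <- function(a, b) {
  check_label_pair(a, b)
  list(ari = ari(a, b), nmi = nmi(a, b), purity = purity(a, b),
       contingency = table(a, b))
}
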