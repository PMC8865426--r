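#' Masked joint symmetric tri-factorization
#'
#' The multiplex network's similarity matrices are jointly approximated as
#' `A_i ~ H S_i H'` with a shared non-negative factor `H` (n x r) and
#' layer-specific non-negative cores `S_i` (r x r), by minimizing
#'
#' `L = sum_i lambda_i || W_i o (A_i - H S_i H') ||_F^2 + eta ||H||_F^2`
#'
#' where `o` is the entrywise product, `W_i` masks unavailable similarity
#' entries out of the loss, `lambda_i = n_i^-2` balances layers of unequal
#' size, and `eta` penalizes `||H||_F^2` to encourage near-one-hot rows.
#' The solver alternates multiplicative updates for every `S_i` and for `H`
#' from an SVD-based initialization until the relative objective change
#' drops below `tol`.
#'
#' @name factorize-module
NULL

# Extract masked layer arrays once: A0 = W o A (NA -> 0), W numeric.
masked_layers <- function(network) {
  lapply(network$layers, function(l) {
    A0 <- l$A
    A0[l$W == 0 | is.na(A0)] <- 0
    list(A0 = A0, W = l$W, lambda = l$lambda)
  })
}

#' Joint factorization objective
#'
#' Evaluates `L = sum_i lambda_i ||W_i o (A_i - H S_i H')||_F^2 +
#' eta ||H||_F^2`; unavailable entries contribute nothing.
#'
#' @param network A `MultiplexNetwork`.
#' @param H n x r non-negative matrix.
#' @param S_list List of r x r non-negative matrices, one per layer.
#' @param eta Sparsity penalty weight (>= 0).
#' @export
snmtf_objective <- function(network, H, S_list, eta = 0.1) {
  ml <- masked_layers(network)
  if (length(S_list) != length(ml)) stop("one S per layer required", call. = FALSE)
  fit <- 0
  for (i in seq_along(ml)) {
    R <- ml[[i]]$W * (ml[[i]]$A0 - H %*% S_list[[i]] %*% t(H))
    fit <- fit + ml[[i]]$lambda * sum(R^2)
  }
  fit + eta * sum(H^2)
}

#' SVD-based initialization
#'
#' `H0` is the entrywise absolute value of the `r` leading left singular
#' vectors of the mask-aware mean similarity matrix (mean over layers of
#' the available entries; entries available nowhere are 0). Each `S0_i` is
#' diagonal with the `r` leading absolute singular values of `A_i`
#' (unavailable entries as 0). Exact zeros are lifted to a tiny positive
#' value because multiplicative updates cannot escape them.
#'
#' @param network A `MultiplexNetwork`.
#' @param r Target rank (1 <= r <= n).
#' @return List with `H0` and `S0_list`.
#' @export
svd_init <- function(network, r) {
  n <- length(network$sample_ids)
  stopifnot_scalar(r, "r", min = 1, integer = TRUE)
  if (r > n) stop("rank r exceeds the number of samples", call. = FALSE)
  ml <- masked_layers(network)
  num <- Reduce(`+`, lapply(ml, function(x) x$A0))
  den <- Reduce(`+`, lapply(ml, function(x) x$W))
  Abar <- ifelse(den > 0, num / den, 0)
  sv <- svd(Abar, nu = r, nv = 0)
  H0 <- abs(sv$u[, seq_len(r), drop = FALSE])
  if (sum(sv$d > 1e-12) < r) {
    warning("requested rank exceeds numerical rank of the mean similarity; zero columns padded",
            call. = FALSE)
  }
  S0_list <- lapply(ml, function(x) {
    d <- svd(x$A0, nu = 0, nv = 0)$d
    diag(abs(d[seq_len(r)]), nrow = r)
  })
  list(H0 = lift_zeros(H0), S0_list = lapply(S0_list, lift_zeros))
}

# Multiplicative updates stall at exact zeros; lift them to a tiny
# positive value relative to the mean positive entry.
lift_zeros <- function(x, rel = 1e-8) {
  pos <- x[x > 0]
  floor_val <- if (length(pos)) rel * mean(pos) else rel
  x[x < floor_val] <- floor_val
  x
}

#' One multiplicative update of a layer core S_i
#'
#' `S' = S o [H'(W o A)H] / [H'(W o (H S H'))H + guard]`; non-negativity is
#' preserved and an exact factorization is a fixed point.
#'
#' @param H n x r factor.
#' @param S r x r core.
#' @param A0 Masked similarity (`W o A`, zeros where unavailable).
#' @param W Availability mask.
#' @export
update_S <- function(H, S, A0, W) {
  HtWAH <- crossprod(H, A0 %*% H)
  recon <- W * (H %*% S %*% t(H))
  HtWRH <- crossprod(H, recon %*% H)
  S * HtWAH / (HtWRH + .DENOM_GUARD)
}

#' One multiplicative update of the shared factor H
#'
#' `H' = H o [sum_i lambda_i (W_i o A_i) H S_i] /
#' [sum_i lambda_i (W_i o (H S_i H')) H S_i + 0.5 eta H + guard]`.
#'
#' @param H n x r factor.
#' @param S_list Layer cores.
#' @param ml Masked layer list from `masked_layers()` (or a
#'   `MultiplexNetwork`).
#' @param eta Sparsity weight.
#' @export
update_H <- function(H, S_list, ml, eta = 0.1) {
  if (inherits(ml, "MultiplexNetwork")) ml <- masked_layers(ml)
  num <- matrix(0, nrow = nrow(H), ncol = ncol(H))
  den <- matrix(0, nrow = nrow(H), ncol = ncol(H))
  for (i in seq_along(ml)) {
    HS <- H %*% S_list[[i]]
    num <- num + ml[[i]]$lambda * (ml[[i]]$A0 %*% HS)
    recon <- ml[[i]]$W * tcrossprod(HS, H)
    den <- den + ml[[i]]$lambda * (recon %*% HS)
  }
  H * num / (den + 0.5 * eta * H + .DENOM_GUARD)
}

#' Solve the joint tri-factorization
#'
#' Alternates [update_S()] over all layers and [update_H()] from the
#' SVD-based initialization, tracking the objective every iteration, until
#' the relative change `|L(i+1) - L(i)| / L(i+1)` falls below `tol` or
#' `max_iter` is reached. The residual error `RE` (the data-fit term of the
#' final objective) is reported alongside.
#'
#' @param network A `MultiplexNetwork`.
#' @param r Target rank.
#' @param eta Sparsity weight (default 0.1).
#' @param tol Relative-change convergence threshold (default 1e-7).
#' @param max_iter Iteration budget (default 500).
#' @param init Optional list with `H0`, `S0_list` overriding [svd_init()].
#' @return An object of class `snmtf_fit`: `H`, `S_list`, `objective`
#'   (per-iteration trace, starting at the initial point), `RE`,
#'   `iterations`, `converged`, `labels` (argmax of `H` rows), `eta`, `r`.
#' @export
factorize <- function(network, r, eta = 0.1, tol = 1e-7, max_iter = 500,
                      init = NULL) {
  stopifnot(inherits(network, "MultiplexNetwork"))
  stopifnot_scalar(eta, "eta", min = 0)
  stopifnot_scalar(tol, "tol", min = 1e-300)
  stopifnot_scalar(max_iter, "max_iter", min = 1, integer = TRUE)
  if (is.null(init)) init <- svd_init(network, r)
  H <- init$H0
  S_list <- init$S0_list
  ml <- masked_layers(network)
  for (i in seq_along(ml)) ml[[i]]$complete <- all(ml[[i]]$W == 1)

  layer_fit <- function(i, H, S) {
    R <- ml[[i]]$A0 - H %*% S %*% t(H)
    if (!ml[[i]]$complete) R <- ml[[i]]$W * R
    ml[[i]]$lambda * sum(R^2)
  }
  obj_one <- function(H, S_list) {
    fit <- 0
    for (i in seq_along(ml)) fit <- fit + layer_fit(i, H, S_list[[i]])
    fit + eta * sum(H^2)
  }

  # Multiplicative steps for the symmetric (quartic-in-H) problem are not
  # monotone in general; damp a rejected step by halving the exponent of
  # the update ratio (H o ratio^gamma), which keeps the fixed points and,
  # for small enough gamma, follows the negative gradient. Returns the
  # accepted point and its objective value.
  damp <- function(old, cand, L_old, objective_fn) {
    ratio <- cand / old
    ratio[!is.finite(ratio)] <- 1   # exact zeros are absorbing states
    gamma <- 1
    for (half in 1:30) {
      new <- old * ratio^gamma
      L_new <- objective_fn(new)
      if (L_new <= L_old * (1 + 1e-12)) return(list(x = new, L = L_new))
      gamma <- gamma / 2
    }
    list(x = old, L = L_old)
  }

  trace <- numeric(max_iter + 1L)
  trace[1L] <- obj_one(H, S_list)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    for (i in seq_along(ml)) {
      cand <- update_S(H, S_list[[i]], ml[[i]]$A0, ml[[i]]$W)
      st <- damp(S_list[[i]], cand, layer_fit(i, H, S_list[[i]]),
                 function(S) layer_fit(i, H, S))
      S_list[[i]] <- st$x
    }
    L_pre <- obj_one(H, S_list)
    cand <- update_H(H, S_list, ml, eta = eta)
    ht <- damp(H, cand, L_pre, function(Hn) obj_one(Hn, S_list))
    H <- ht$x
    L <- ht$L
    if (L > trace[it] * (1 + 1e-8) + 1e-12) {
      stop(sprintf("objective increased at iteration %d (%.6g -> %.6g): update bug",
                   it, trace[it], L), call. = FALSE)
    }
    trace[it + 1L] <- L
    if (abs(trace[it + 1L] - trace[it]) / max(trace[it + 1L], .DENOM_GUARD) < tol) {
      converged <- TRUE
      break
    }
  }
  trace <- trace[seq_len(it + 1L)]
  RE <- 0
  for (i in seq_along(ml)) {
    R <- ml[[i]]$W * (ml[[i]]$A0 - H %*% S_list[[i]] %*% t(H))
    RE <- RE + ml[[i]]$lambda * sum(R^2)
  }
  rownames(H) <- network$sample_ids
  structure(
    list(H = H, S_list = S_list, objective = trace, RE = RE,
         iterations = it, converged = converged,
         labels = hard_labels(H), eta = eta, r = as.integer(r)),
    class = "snmtf_fit"
  )
}

#' Cluster labels from the shared factor
#'
#' Assigns each sample to the column of `H` holding its row maximum; ties
#' break toward the smallest column index. An all-zero row is assigned to
#' cluster 1 with a warning.
#'
#' @param H n x r non-negative matrix.
#' @return Integer labels in `1..r`, named by the rownames of `H`.
#' @export
hard_labels <- function(H) {
  stopifnot(is.matrix(H), ncol(H) >= 1)
  zero_rows <- rowSums(H != 0) == 0
  if (any(zero_rows)) {
    warning(sprintf("%d all-zero row(s) in H assigned to cluster 1", sum(zero_rows)),
            call. = FALSE)
  }
  lab <- max.col(H, ties.method = "first")
  names(lab) <- rownames(H)
  lab
}

#' @export
print.snmtf_fit <- function(x, ...) {
  cat(sprintf("snmtf_fit: rank %d, eta %.3g, %d iteration(s), %s\n",
              x$r, x$eta, x$iterations,
              if (x$converged) "converged" else "iteration limit reached"))
  cat(sprintf("  objective %.6g, residual error %.6g\n",
              x$objective[length(x$objective)], x$RE))
  invisible(x)
}
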