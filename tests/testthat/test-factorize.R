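test_that("snmtf_objective matches the naive double-loop oracle", {
  set.seed(21)
  n <- 5
  A1 <- random_similarity(n); A2 <- random_similarity(n)
  W1 <- matrix(rbinom(n^2, 1, 0.8), n); W1 <- W1 * t(W1); diag(W1) <- 1
  W2 <- matrix(1, n, n)
  net <- toy_network(list(A1, A2), list(W1, W2))
  H <- matrix(runif(n * 2), n, 2)
  S_list <- list(matrix(runif(4), 2, 2), matrix(runif(4), 2, 2))
  lambdas <- vapply(net$layers, function(l) l$lambda, numeric(1))

  expect_equal(snmtf_objective(net, H, S_list, eta = 0.3),
               naive_objective(list(A1, A2), list(W1, W2), lambdas,
                               H, S_list, eta = 0.3),
               tolerance = 1e-12)

  # H = 0, S = 0, eta = 0: L = lambda * ||W o A||_F^2
  z <- matrix(0, n, 2)
  zs <- list(matrix(0, 2, 2))
  net1 <- toy_network(A1, list(W1))
  expect_equal(snmtf_objective(net1, z, zs, eta = 0),
               net1$layers[[1]]$lambda * sum((W1 * A1)^2))

  # exact factorization with eta = 0 -> 0
  Hx <- matrix(runif(n * 2), n, 2)
  Sx <- crossprod(matrix(runif(4), 2, 2))
  Ax <- Hx %*% Sx %*% t(Hx)
  netx <- toy_network(Ax)
  expect_equal(snmtf_objective(netx, Hx, list(Sx), eta = 0), 0,
               tolerance = 1e-12)

  expect_error(snmtf_objective(net, H, S_list[1], eta = 0), "one S per layer")
})

test_that("svd_init matches the analytic SVD on simple cases and is deterministic", {
  ones <- matrix(1, 2, 2)
  net <- toy_network(ones)
  init <- svd_init(net, 1)
  expect_equal(unname(init$H0[, 1]), c(0.7071, 0.7071), tolerance = 1e-4)
  expect_equal(init$S0_list[[1]][1, 1], 2, tolerance = 1e-8)

  # identical layers: mean matrix equals each layer
  A <- random_similarity(6)
  expect_equal(svd_init(toy_network(list(A, A)), 3)$H0,
               svd_init(toy_network(A), 3)$H0)

  # deterministic and strictly positive (zero-lifted)
  i1 <- svd_init(toy_network(A), 2)
  i2 <- svd_init(toy_network(A), 2)
  expect_identical(i1, i2)
  expect_true(all(i1$H0 > 0))
  expect_true(all(i1$S0_list[[1]] > 0))

  expect_error(svd_init(toy_network(A), 7), "exceeds")
  expect_warning(svd_init(toy_network(matrix(0, 3, 3) + diag(0, 3)), 2),
                 "rank")
})

test_that("update_S follows the printed rule: oracle match, fixed point, absorption", {
  set.seed(4)
  n <- 4
  H <- matrix(runif(n * 2), n, 2)
  S <- matrix(runif(4), 2, 2)
  A <- random_similarity(n)
  W <- matrix(rbinom(n^2, 1, 0.7), n); W <- pmax(W, t(W)); diag(W) <- 1
  A0 <- W * A
  expect_equal(update_S(H, S, A0, W), naive_update_S(H, S, A, W),
               tolerance = 1e-12)

  # exact factorization is a fixed point (complete mask)
  Sx <- crossprod(matrix(runif(4), 2, 2))
  Ax <- H %*% Sx %*% t(H)
  Wx <- matrix(1, n, n)
  expect_equal(update_S(H, Sx, Ax, Wx), Sx, tolerance = 1e-6)

  # S = 0 is absorbing
  expect_equal(update_S(H, matrix(0, 2, 2), A0, W), matrix(0, 2, 2))
})

test_that("update_H follows the printed rule: oracle match, fixed point, shrinkage", {
  set.seed(5)
  n <- 5
  H <- matrix(runif(n * 2), n, 2)
  A1 <- random_similarity(n); A2 <- random_similarity(n)
  W1 <- matrix(1, n, n)
  W2 <- matrix(rbinom(n^2, 1, 0.8), n); W2 <- pmax(W2, t(W2)); diag(W2) <- 1
  S_list <- list(crossprod(matrix(runif(4), 2, 2)),
                 crossprod(matrix(runif(4), 2, 2)))
  net <- toy_network(list(A1, A2), list(W1, W2))
  lambdas <- vapply(net$layers, function(l) l$lambda, numeric(1))
  expect_equal(update_H(H, S_list, net, eta = 0.2),
               naive_update_H(H, S_list, list(A1, A2), list(W1, W2),
                              lambdas, eta = 0.2),
               tolerance = 1e-12)

  # exact single-layer factorization: eta = 0 fixed point,
  # eta > 0 shrinks every entry
  Ax <- H %*% S_list[[1]] %*% t(H)
  netx <- toy_network(Ax)
  expect_equal(update_H(H, S_list[1], netx, eta = 0), H, tolerance = 1e-6)
  H_shrunk <- update_H(H, S_list[1], netx, eta = 0.5)
  expect_true(all(H_shrunk <= H + 1e-12))
})

test_that("factorize descends monotonically and recovers separable structure", {
  # noiseless 2-blob cohort: argmax labels hit the truth
  ch <- make_blobs(40, 25, 2, 0.5, seed = 6)
  net <- cohort_network(ch)
  fit <- factorize(net, r = 2)
  expect_equal(ari(fit$labels, ch$truth), 1.0)
  expect_true(all(fit$H >= 0))
  expect_true(all(fit$S_list[[1]] >= 0))

  # trace non-increasing, RE consistent with final objective
  expect_true(all(diff(fit$objective) <= 1e-8 * fit$objective[-1] + 1e-12))
  L_final <- fit$objective[length(fit$objective)]
  expect_lt(abs(L_final - (fit$RE + fit$eta * sum(fit$H^2))),
            1e-10 * (1 + L_final))

  # converged flag consistent with the trace's last relative change
  tr <- fit$objective
  last_rel <- abs(diff(tail(tr, 2))) / tail(tr, 1)
  expect_identical(fit$converged, last_rel < 1e-7)

  # monotone descent over random masked instances
  set.seed(30)
  for (rep in 1:25) {
    n <- 6
    A <- random_similarity(n)
    W <- matrix(rbinom(n^2, 1, 0.75), n); W <- pmax(W, t(W)); diag(W) <- 1
    netr <- toy_network(A, list(W))
    f <- factorize(netr, r = 2, max_iter = 60)
    expect_true(all(diff(f$objective) <= 1e-8 * f$objective[-1] + 1e-12))
  }
})

test_that("masked entries never influence the factorization", {
  set.seed(31)
  n <- 8
  A <- random_similarity(n)
  W <- matrix(rbinom(n^2, 1, 0.6), n); W <- pmax(W, t(W)); diag(W) <- 1
  net1 <- toy_network(A, list(W))
  A_perturbed <- A
  A_perturbed[W == 0] <- 99
  net2 <- toy_network(A_perturbed, list(W))

  H <- matrix(runif(n * 2), n, 2)
  S <- matrix(runif(4), 2, 2)
  expect_identical(snmtf_objective(net1, H, list(S), 0.1),
                   snmtf_objective(net2, H, list(S), 0.1))
  f1 <- factorize(net1, 2, max_iter = 40)
  f2 <- factorize(net2, 2, max_iter = 40)
  expect_identical(f1$H, f2$H)
  expect_identical(f1$S_list, f2$S_list)
  expect_identical(f1$objective, f2$objective)
})

test_that("eta = 0 fixed points satisfy symmetric-NMF stationarity (KKT)", {
  set.seed(32)
  for (rep in 1:3) {
    n <- 10
    A <- random_similarity(n)
    net <- toy_network(A)
    fit <- factorize(net, 2, eta = 0, tol = 1e-13, max_iter = 20000)
    H <- fit$H; S <- fit$S_list[[1]]
    lambda <- n^(-2)
    R <- A - H %*% S %*% t(H)
    gH <- -4 * lambda * (R %*% H %*% S)
    gS <- -2 * lambda * crossprod(H, R %*% H)
    # scale = the larger of the factor and gradient magnitudes, so the
    # complementarity residual must sit four orders below whichever side
    # of min(x, |g|) is active
    expect_lt(max(pmin(H, abs(gH))), 1e-4 * max(H, abs(gH)))
    expect_lt(max(pmin(S, abs(gS))), 1e-4 * max(S, abs(gS)))
  }
})

test_that("hard_labels takes the row argmax with first-column tie-break", {
  H <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.2, 0.7))
  rownames(H) <- c("a", "b", "c")
  expect_identical(hard_labels(H), c(a = 1L, b = 1L, c = 2L))
  expect_warning(lab <- hard_labels(rbind(c(0, 0), c(1, 0))), "all-zero")
  expect_equal(lab[1], 1L, ignore_attr = TRUE)
})
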