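# Hand-built ensembles for consensus arithmetic tests.
fake_ensemble <- function(runs, n, r = 2) {
  structure(list(runs = runs, n = n, r = r, n_runs = length(runs),
                 keep_fraction = 1), class = "RunEnsemble")
}

test_that("run_resampled covers every sample with the stated subset sizes", {
  ch <- make_blobs(40, 15, 2, 0.5, seed = 9)
  net <- cohort_network(ch)

  ens <- run_resampled(net, 2, n_runs = 10, keep_fraction = 0.95,
                       max_iter = 60, seed = 3)
  expect_equal(ens$n_runs, 10L)
  sizes <- vapply(ens$runs, function(x) length(x$idx), integer(1))
  expect_true(all(sizes == round(0.95 * 40)))       # 38 of 40 per run
  expect_setequal(sort(unique(unlist(lapply(ens$runs, `[[`, "idx")))), 1:40)
  for (run in ens$runs) {
    expect_equal(length(run$labels), length(run$idx))
    expect_gte(run$RE, 0)
  }

  # keep_fraction = 1: every run sees all samples
  full <- run_resampled(net, 2, n_runs = 2, keep_fraction = 1,
                        max_iter = 40, seed = 3)
  expect_true(all(vapply(full$runs, function(x) length(x$idx), integer(1)) == 40))

  # determinism under seed
  ens2 <- run_resampled(net, 2, n_runs = 10, keep_fraction = 0.95,
                        max_iter = 60, seed = 3)
  expect_identical(ens, ens2)

  expect_error(run_resampled(net, 2, n_runs = 0), "n_runs")
  expect_error(run_resampled(net, 2, keep_fraction = 0), "keep_fraction")
})

test_that("weighted_consensus reproduces the printed weighting formula", {
  # RE = (2, 4, 6) -> weights (1, 0.5, 0)
  runs <- list(
    list(idx = 1:4, labels = c(1L, 1L, 2L, 2L), RE = 2),
    list(idx = 1:4, labels = c(1L, 2L, 2L, 2L), RE = 4),
    list(idx = 1:4, labels = c(2L, 2L, 2L, 2L), RE = 6)
  )
  C <- weighted_consensus(fake_ensemble(runs, 4))
  # hand-computed: weights (1, .5, 0), total 1.5
  # pair (1,2): co-clustered in run1 only -> 1/1.5
  expect_equal(C[1, 2], 1 / 1.5)
  # pair (3,4): co-clustered in all runs -> (1 + .5)/1.5 = 1
  expect_equal(C[3, 4], 1)
  # pair (2,3): run1 separates, run2 joins -> 0.5/1.5
  expect_equal(C[2, 3], 0.5 / 1.5)
  expect_equal(C, t(C))
  expect_true(all(diag(C) == 1))

  # all runs tie on RE -> all weights 1 (plain co-clustering frequency);
  # pair (1,2) is joined by runs 1 and 3, separated by run 2
  runs_eq <- lapply(runs, function(x) { x$RE <- 3; x })
  Ceq <- weighted_consensus(fake_ensemble(runs_eq, 4))
  expect_equal(Ceq[1, 2], 2 / 3)

  # single run: degenerate weight 1
  C1 <- weighted_consensus(fake_ensemble(runs[1], 4))
  expect_equal(C1[1, 2], 1)

  # never co-sampled pair -> 0 with warning
  part <- list(
    list(idx = 1:2, labels = c(1L, 1L), RE = 1),
    list(idx = 3:4, labels = c(1L, 1L), RE = 2)
  )
  expect_warning(Cp <- weighted_consensus(fake_ensemble(part, 4)), "undefined")
  expect_equal(Cp[1, 3], 0)
})

test_that("consensus entries stay in [0,1] and stability behaves as expected", {
  set.seed(40)
  for (rep in 1:5) {
    runs <- lapply(1:6, function(x) {
      idx <- sort(sample.int(10, 8))
      list(idx = idx, labels = sample(1:2, 8, replace = TRUE),
           RE = runif(1))
    })
    C <- suppressWarnings(weighted_consensus(fake_ensemble(runs, 10)))
    expect_true(all(C >= 0 & C <= 1))
  }

  # perfectly stable ensemble: PAC 0 and CCC 1 on the induced consensus
  lab <- rep(1:2, each = 5)
  runs <- lapply(1:5, function(x) list(idx = 1:10, labels = lab, RE = x))
  C <- weighted_consensus(fake_ensemble(runs, 10))
  expect_equal(pac(C), 0)
  expect_equal(ccc(C), 1)

  # increasing run agreement never increases PAC
  mixed <- list(
    list(idx = 1:10, labels = lab, RE = 1),
    list(idx = 1:10, labels = c(lab[-1], 1L), RE = 1),
    list(idx = 1:10, labels = sample(lab), RE = 1)
  )
  agreeing <- list(
    list(idx = 1:10, labels = lab, RE = 1),
    list(idx = 1:10, labels = lab, RE = 1),
    list(idx = 1:10, labels = c(lab[-1], 1L), RE = 1)
  )
  expect_lte(pac(weighted_consensus(fake_ensemble(agreeing, 10))),
             pac(weighted_consensus(fake_ensemble(mixed, 10))))
})

test_that("pac counts the open ambiguity interval on the upper triangle", {
  expect_equal(pac(block_consensus(c(3, 3))), 0)       # all entries in {0,1}
  C_half <- matrix(0.5, 4, 4); diag(C_half) <- 1
  expect_equal(pac(C_half), 1)

  # entries (0.05, 0.5, 0.95, 0.2, 0.5, 0.95): 3 of 6 inside (0.1, 0.9)
  C <- diag(4)
  vals <- c(0.05, 0.5, 0.95, 0.2, 0.5, 0.95)
  C[upper.tri(C)] <- vals
  C <- C + t(C); diag(C) <- 1
  expect_equal(pac(C), 0.5)

  # boundary values are not ambiguous (open interval)
  Cb <- diag(3); Cb[upper.tri(Cb)] <- c(0.1, 0.9, 0.9)
  Cb <- Cb + t(Cb); diag(Cb) <- 1
  expect_equal(pac(Cb), 0)

  expect_error(pac(matrix(1, 1, 1)), "at least 2")
})

test_that("ccc matches an independent cophenetic construction", {
  expect_equal(ccc(block_consensus(c(4, 4))), 1)       # perfect two-block
  expect_true(is.na(ccc(matrix(0.5, 5, 5) + diag(0.5, 5))))  # constant dissim

  set.seed(41)
  C <- (random_similarity(6) + 1) / 2
  diag(C) <- 1
  d <- 1 - C
  hc <- hclust(as.dist(d), method = "average")
  coph_oracle <- naive_cophenetic(hc)
  expect_equal(as.matrix(cophenetic(hc)), coph_oracle, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(ccc(C),
               cor(as.dist(d), as.dist(coph_oracle)),
               tolerance = 1e-10)
})

test_that("ncut_labels recovers blocks and matches exhaustive search on toys", {
  C <- block_consensus(c(4, 4))
  lab <- ncut_labels(C, 2, seed = 1)
  expect_equal(ari(lab, rep(1:2, each = 4)), 1)
  expect_equal(unname(ncut_labels(C, 1)), rep(1L, 8))

  set.seed(42)
  for (rep in 1:5) {
    n <- sample(6:8, 1)
    n1 <- sample(2:(n - 2), 1)
    C <- block_consensus(c(n1, n - n1), hi = 1, lo = 0.05)
    noise <- matrix(runif(n^2, 0, 0.15), n)
    C <- pmin(pmax(C + (noise + t(noise)) / 2, 0), 1)
    diag(C) <- 1
    truth_side <- exhaustive_min_ncut(C)$side
    lab <- ncut_labels(C, 2, seed = rep)
    expect_equal(ari(lab, as.integer(truth_side) + 1L), 1)
  }
})

test_that("select_rank reports per-rank stability with a single-rank edge case", {
  ch <- make_blobs(30, 12, 2, 0.5, seed = 13)
  net <- cohort_network(ch)
  rs <- select_rank(net, ranks = 2, n_runs = 8, subset_size = 6,
                    n_subsets = 4, max_iter = 60, seed = 5)
  expect_equal(nrow(rs$summary), 1L)
  expect_equal(rs$summary$rank, 2L)
  expect_true(all(rs$pac_dist >= 0 & rs$pac_dist <= 1))
  expect_equal(length(rs$labels[["2"]]), 30)

  expect_warning(select_rank(net, ranks = c(2, 30), n_runs = 4,
                             subset_size = 4, n_subsets = 2, max_iter = 30,
                             seed = 5),
                 "skipping")
})

test_that("within-cluster similarity score matches a double loop; select_eta picks argmax", {
  A <- block_consensus(c(3, 3), hi = 0.9, lo = 0.1)
  diag(A) <- 1
  net <- toy_network(A)
  lab <- rep(1:2, each = 3)
  s <- within_cluster_similarity(net, lab)
  oracle <- 0
  for (cl in 1:2) {
    idx <- which(lab == cl)
    for (i in idx) for (j in idx) if (i < j) oracle <- oracle + A[i, j]
  }
  oracle <- oracle / 6^2
  expect_equal(s, oracle, tolerance = 1e-12)

  # single candidate is returned as-is
  ch <- make_blobs(24, 10, 2, 0.5, seed = 14)
  netc <- cohort_network(ch)
  sel <- select_eta(netc, etas = 0.1, r = 2, n_runs = 4, max_iter = 40,
                    seed = 2)
  expect_equal(sel$eta, 0.1)
  expect_equal(nrow(sel$scores), 1L)

  # default candidate set includes the default sparsity weight 0.1
  expect_true(0.1 %in% eval(formals(select_eta)$etas))
})
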