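test_that("identical blocks reach a first canonical correlation of 1", {
  set.seed(10)
  x <- matrix(rnorm(120), 30, 4)
  b1 <- prepare_block(x)
  b2 <- prepare_block(x)
  m <- fit_scca(b1, b2, c1 = 2, c2 = 2, n_modes = 1)
  expect_equal(m$canonical_correlations[1], 1, tolerance = 1e-6)
})

test_that("loose penalties with full covariance reproduce classical CCA", {
  for (seed in 1:5) {
    set.seed(seed)
    x1 <- matrix(rnorm(30 * 4), 30, 4) %*% matrix(rnorm(16), 4, 4)
    x2 <- matrix(rnorm(30 * 5), 30, 5) %*% matrix(rnorm(25), 5, 5)
    b1 <- prepare_block(x1)
    b2 <- prepare_block(x2)
    m <- fit_scca(b1, b2, c1 = 2, c2 = sqrt(5), n_modes = 1,
                  cov_structure = "full")
    expect_equal(m$canonical_correlations[1],
                 cca_first_cor_oracle(b1$matrix, b2$matrix),
                 tolerance = 1e-6)
  }
})

test_that("weight vectors satisfy the L1 and L2 budgets at every mode", {
  pair <- null_block_pair(40, 8, 12, seed = 11)
  for (c1 in c(1, 1.6, 2.8)) {
    m <- fit_scca(pair$b1, pair$b2, c1 = c1, c2 = 2, n_modes = 4)
    for (mode in m$modes) {
      expect_lte(sum(abs(mode$u)), c1 + 1e-6)
      expect_lte(sum(abs(mode$v)), 2 + 1e-6)
      expect_lte(sqrt(sum(mode$u^2)), 1 + 1e-9)
      expect_lte(sqrt(sum(mode$v^2)), 1 + 1e-9)
    }
  }
})

test_that("an active L1 penalty zeroes some weights", {
  pair <- null_block_pair(40, 10, 15, seed = 12)
  m <- fit_scca(pair$b1, pair$b2, c1 = 1.2, c2 = 1.2, n_modes = 1)
  expect_gt(sum(m$modes[[1]]$u == 0), 0)
  expect_gt(sum(m$modes[[1]]$v == 0), 0)
})

test_that("the alternating objective is monotonically non-decreasing", {
  pair <- null_block_pair(35, 6, 9, seed = 13)
  m <- fit_scca(pair$b1, pair$b2, c1 = 1.5, c2 = 1.8, n_modes = 2,
                trace = TRUE)
  for (tr in m$objective_traces)
    expect_true(all(diff(tr) > -1e-9))
})

test_that("permuting participants identically in both blocks changes nothing", {
  pair <- null_block_pair(30, 5, 7, seed = 14)
  m1 <- fit_scca(pair$b1, pair$b2, c1 = 1.5, c2 = 1.5, n_modes = 3)
  set.seed(99)
  idx <- sample(30)
  b1p <- data_block(pair$b1$matrix[idx, ], pair$b1$variable_names,
                    pair$b1$participant_ids[idx], state = "standardized")
  b2p <- data_block(pair$b2$matrix[idx, ], pair$b2$variable_names,
                    pair$b2$participant_ids[idx], state = "standardized")
  m2 <- fit_scca(b1p, b2p, c1 = 1.5, c2 = 1.5, n_modes = 3)
  for (k in 1:3) {
    expect_equal(m1$modes[[k]]$u, m2$modes[[k]]$u, tolerance = 1e-10)
    expect_equal(m1$modes[[k]]$v, m2$modes[[k]]$v, tolerance = 1e-10)
  }
})

test_that("fits are deterministic given data, penalties and seed", {
  pair <- null_block_pair(30, 6, 8, seed = 15)
  m1 <- fit_scca(pair$b1, pair$b2, c1 = 1.4, c2 = 1.4, n_modes = 3, seed = 2)
  m2 <- fit_scca(pair$b1, pair$b2, c1 = 1.4, c2 = 1.4, n_modes = 3, seed = 2)
  expect_identical(m1$canonical_correlations, m2$canonical_correlations)
  expect_identical(m1$modes[[2]]$u, m2$modes[[2]]$u)
  # sign convention: the largest-|weight| entry of u is positive
  for (m in m1$modes) expect_gt(m$u[which.max(abs(m$u))], 0)
})

test_that("projection reproduces the training canonical correlation", {
  pair <- null_block_pair(40, 6, 9, seed = 16)
  m <- fit_scca(pair$b1, pair$b2, c1 = 1.7, c2 = 2, n_modes = 3)
  for (k in 1:3) {
    pr <- project(m, pair$b1, pair$b2, k)
    expect_equal(cor(pr$variate1, pr$variate2),
                 m$modes[[k]]$canonical_correlation, tolerance = 1e-10)
  }
})

test_that("a unit weight entry makes the variate equal that column", {
  pair <- null_block_pair(20, 4, 5, seed = 17)
  m <- fit_scca(pair$b1, pair$b2, c1 = 1.5, c2 = 1.5, n_modes = 1)
  m$modes[[1]]$u <- c(1, 0, 0, 0)
  pr <- project(m, pair$b1, pair$b2, 1)
  expect_equal(pr$variate1, unname(pair$b1$matrix[, 1]))
})

test_that("projection rejects mismatched variable sets", {
  pair <- null_block_pair(20, 4, 5, seed = 18)
  m <- fit_scca(pair$b1, pair$b2, c1 = 1.5, c2 = 1.5, n_modes = 1)
  wrong <- pair$b1
  wrong$variable_names[2] <- "intruder"
  colnames(wrong$matrix)[2] <- "intruder"
  expect_error(project(m, wrong, pair$b2, 1), "intruder")
})

test_that("variance shares normalize to one and track a rank-1 cross-product", {
  pair <- null_block_pair(30, 5, 7, seed = 19)
  m1 <- fit_scca(pair$b1, pair$b2, c1 = 1.5, c2 = 1.5, n_modes = 1)
  expect_equal(variance_explained(m1), 1)
  # block 2 built from a single column of block 1: X1'X2 has rank 1
  set.seed(20)
  z <- rnorm(40)
  x1 <- unname(cbind(z, matrix(rnorm(40 * 2), 40, 2)))
  x2 <- outer(z, c(1, -2, 0.5))
  b1 <- prepare_block(x1)
  # x2 columns are collinear but not constant
  b2 <- prepare_block(x2 + matrix(rnorm(120, sd = 1e-8), 40, 3))
  m <- fit_scca(b1, b2, c1 = sqrt(3), c2 = sqrt(3), n_modes = 3)
  sh <- variance_explained(m)
  expect_equal(sum(sh), 1, tolerance = 1e-9)
  expect_gt(sh[1], 0.999)
})

test_that("a planted sparse mode is recovered with high cosine similarity", {
  spec <- synthetic_spec(n_participants = 500)
  g <- generate_blocks(spec, seed = 7)
  b1 <- prepare_block(g$nonimaging$matrix)
  b2 <- prepare_block(g$thickness$matrix)
  m <- fit_scca(b1, b2, c1 = 1.7, c2 = 2, n_modes = 1)
  expect_gt(abs(sum(m$modes[[1]]$u * g$truth$u[, 1])), 0.9)
  expect_gt(abs(sum(m$modes[[1]]$v * g$truth$v[, 1])), 0.9)
})

test_that("cumulative shares over ten modes exceed 0.99 by mode 7", {
  # seven planted modes of decaying strength over a low residual noise
  # floor: all cross-block structure lives in the leading seven deflation
  # steps, reproducing the truncate-at->99% logic
  rhos <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3)
  pm <- lapply(1:7, function(k)
    planted_mode(sparse_loading(24, (3 * k - 2):(3 * k)),
                 sparse_loading(62, (4 * k - 3):(4 * k)),
                 latent_correlation = rhos[k]))
  spec <- synthetic_spec(n_participants = 400, planted_modes = pm,
                         noise_sd = c(0.15, 0.15))
  g <- generate_blocks(spec, seed = 23)
  b1 <- prepare_block(g$nonimaging$matrix)
  b2 <- prepare_block(g$thickness$matrix)
  m <- fit_scca(b1, b2, n_modes = 10)
  cum <- cumsum(variance_explained(m))
  expect_gt(cum[7], 0.99)
  expect_equal(cum[10], 1, tolerance = 1e-9)
})

test_that("penalty bounds and mode counts are enforced", {
  pair <- null_block_pair(20, 4, 5, seed = 24)
  expect_error(fit_scca(pair$b1, pair$b2, c1 = 0.5, c2 = 1.5), "c1")
  expect_error(fit_scca(pair$b1, pair$b2, c1 = 1.5, c2 = 3), "c2")
  expect_error(fit_scca(pair$b1, pair$b2, c1 = 1.5, c2 = 1.5,
                        n_modes = 5), "n_modes")
})

test_that("select_penalties returns an in-bounds pair with its score grid", {
  spec <- synthetic_spec(n_participants = 60)
  g <- generate_blocks(spec, seed = 25)
  b1 <- prepare_block(g$nonimaging$matrix)
  b2 <- prepare_block(g$thickness$matrix)
  sel <- select_penalties(b1, b2, K = 2, seed = 3)
  expect_gte(sel$c1, 1); expect_lte(sel$c1, sqrt(24))
  expect_gte(sel$c2, 1); expect_lte(sel$c2, sqrt(62))
  expect_equal(nrow(sel$grid), 9)
})
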