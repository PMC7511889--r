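test_that("duplicated participants have near-zero leave-one-out influence", {
  # every participant appears twice, so dropping one copy leaves the
  # association intact (a planted mode keeps the optimum well-defined)
  spec <- synthetic_spec(n_participants = 14, planted_modes = list(
    planted_mode(sparse_loading(24, 1:3), sparse_loading(62, 1:4),
                 latent_correlation = 0.9, strength1 = 2, strength2 = 2)))
  g <- generate_blocks(spec, seed = 40)
  b1 <- prepare_block(rbind(g$nonimaging$matrix, g$nonimaging$matrix),
                      participant_ids = paste0("s", 1:28))
  b2 <- prepare_block(rbind(g$thickness$matrix, g$thickness$matrix),
                      participant_ids = paste0("s", 1:28))
  loo <- leave_one_out(b1, b2, c1 = 1.7, c2 = 2, n_modes = 1)
  expect_lt(max(abs(loo$influence_mode1)), 0.05)
  expect_false(any(is.na(loo$influence_mode1)))
})

test_that("an adversarial outlier participant is flagged", {
  set.seed(41)
  n <- 30
  x1 <- matrix(rnorm(n * 6), n, 6)
  x2 <- matrix(rnorm(n * 8), n, 8)
  # one participant alone creates a cross-block association
  x1 <- rbind(x1, c(8, 8, rnorm(4)))
  x2 <- rbind(x2, c(8, 8, 8, rnorm(5)))
  ids <- paste0("s", 1:(n + 1))
  b1 <- prepare_block(x1, participant_ids = ids)
  b2 <- prepare_block(x2, participant_ids = ids)
  loo <- leave_one_out(b1, b2, c1 = 1.4, c2 = 1.4, n_modes = 1)
  expect_true(loo$flagged[loo$participant_id == "s31"])
  expect_lte(sum(loo$flagged), 3)
})

test_that("clean planted-mode data produces only rare, weak flags", {
  # the 3-SD screen on a mildly skewed influence distribution fires on a
  # few per cent of clean participants by chance; what distinguishes
  # clean data from an outlier-driven mode is that flags stay rare and
  # the flagged influences stay small in absolute terms
  runs <- lapply(1:5, function(i) {
    spec <- synthetic_spec(n_participants = 47, planted_modes = list(
      planted_mode(sparse_loading(24, 1:3), sparse_loading(62, 1:4),
                   latent_correlation = 0.8, strength1 = 1.5,
                   strength2 = 1.5)))
    g <- generate_blocks(spec, seed = 420 + i)
    b1 <- prepare_block(g$nonimaging$matrix)
    b2 <- prepare_block(g$thickness$matrix)
    leave_one_out(b1, b2, c1 = 1.7, c2 = 2, n_modes = 1)
  })
  flagged_fraction <- mean(unlist(lapply(runs, `[[`, "flagged")))
  expect_lt(flagged_fraction, 0.05)
  expect_lt(max(abs(unlist(lapply(runs, `[[`, "influence_mode1")))), 0.25)
})

test_that("noiseless rank-1 association shows no split-half overfitting", {
  set.seed(43)
  spec <- synthetic_spec(n_participants = 120,
                         planted_modes = list(planted_mode(
                           u = rnorm(24), v = rnorm(62),
                           latent_correlation = 1,
                           strength1 = 20, strength2 = 20)),
                         noise_sd = c(0.01, 0.01))
  g <- generate_blocks(spec, seed = 43)
  b1 <- prepare_block(g$nonimaging$matrix)
  b2 <- prepare_block(g$thickness$matrix)
  # halves of near-collinear noiseless columns can cycle between
  # equivalent sparse supports; the flagged iterate is still valid
  rep_ <- suppressWarnings(
    split_half(b1, b2, c1 = 2, c2 = 2.5, n_modes = 1,
               n_resamples = 40, seed = 9))
  expect_lt(abs(rep_$overfit_index[1]), 0.01)
  expect_gt(mean(rep_$splithalf_r[, 1]), 0.99)
})

test_that("pure noise at study size shows large overfitting", {
  pair <- null_block_pair(47, 24, 62, seed = 44)
  rep_ <- split_half(pair$b1, pair$b2, n_modes = 1, n_resamples = 60,
                     seed = 10)
  expect_lt(abs(mean(rep_$splithalf_r[, 1], na.rm = TRUE)), 0.2)
  expect_gt(mean(rep_$train_r[, 1], na.rm = TRUE), 0.4)
  expect_gt(rep_$overfit_index[1], 0.3)
})

test_that("rr_score is 1 on the full sample and flip-invariant", {
  pair <- null_block_pair(40, 6, 9, seed = 45)
  m <- fit_scca(pair$b1, pair$b2, c1 = 1.8, c2 = 2, n_modes = 2)
  expect_equal(rr_score(m, pair$b1, pair$b2, 1), 1, tolerance = 1e-10)
  flipped <- m
  flipped$modes[[1]]$u <- -m$modes[[1]]$u
  flipped$modes[[1]]$v <- -m$modes[[1]]$v
  expect_equal(rr_score(flipped, pair$b1, pair$b2, 1, reference = m),
               rr_score(m, pair$b1, pair$b2, 1), tolerance = 1e-10)
})

test_that("rr_score degrades toward planted vs null data and handles degeneracy", {
  # on data carrying the planted association the test loadings reproduce
  # the reference loading structure almost perfectly; on unrelated data
  # the score drops toward its weight-driven baseline
  spec <- synthetic_spec(n_participants = 300, planted_modes = list(
    planted_mode(sparse_loading(24, 1:3), sparse_loading(62, 1:4),
                 latent_correlation = 0.9, strength1 = 2, strength2 = 2)))
  g <- generate_blocks(spec, seed = 46)
  b1 <- prepare_block(g$nonimaging$matrix)
  b2 <- prepare_block(g$thickness$matrix)
  m <- fit_scca(b1, b2, c1 = 1.7, c2 = 2, n_modes = 1)
  g2 <- generate_blocks(spec, seed = 47)
  same <- rr_score(m, prepare_block(g2$nonimaging$matrix),
                   prepare_block(g2$thickness$matrix), 1)
  null_pair <- null_block_pair(300, 24, 62, seed = 48)
  unrelated <- rr_score(m, null_pair$b1, null_pair$b2, 1)
  expect_gt(same, 0.9)
  expect_gt(same, unrelated)
  # degenerate test variate: all-constant block
  const <- matrix(0, 10, 24)
  expect_true(is.na(rr_score(m, const,
                             matrix(rnorm(10 * 62), 10, 62), 1)))
})

test_that("the split-half report is bit-reproducible given the seed", {
  pair <- null_block_pair(30, 6, 8, seed = 48)
  r1 <- split_half(pair$b1, pair$b2, c1 = 1.6, c2 = 1.8, n_modes = 2,
                   n_resamples = 15, seed = 11)
  r2 <- split_half(pair$b1, pair$b2, c1 = 1.6, c2 = 1.8, n_modes = 2,
                   n_resamples = 15, seed = 11)
  expect_identical(r1$splithalf_r, r2$splithalf_r)
  expect_identical(r1$rr, r2$rr)
  expect_identical(r1$mode_matching, r2$mode_matching)
})

test_that("a strong planted mode dominates a weak one in reliability", {
  spec <- synthetic_spec(n_participants = 200, planted_modes = list(
    planted_mode(sparse_loading(24, 1:3), sparse_loading(62, 1:4),
                 latent_correlation = 0.8, strength1 = 1.5,
                 strength2 = 1.5),
    planted_mode(sparse_loading(24, 10:12), sparse_loading(62, 20:23),
                 latent_correlation = 0.4, strength1 = 0.8,
                 strength2 = 0.8)))
  g <- generate_blocks(spec, seed = 49)
  b1 <- prepare_block(g$nonimaging$matrix)
  b2 <- prepare_block(g$thickness$matrix)
  rep_ <- split_half(b1, b2, c1 = 1.7, c2 = 2, n_modes = 2,
                     n_resamples = 100, seed = 12)
  expect_gt(mean(rep_$splithalf_r[, 1], na.rm = TRUE),
            mean(rep_$splithalf_r[, 2], na.rm = TRUE))
  expect_gt(rep_$rr_mean[1], rep_$rr_mean[2])
})

test_that("the overfitting index shrinks with sample size", {
  spec <- synthetic_spec(n_participants = 160)
  g <- generate_blocks(spec, seed = 50)
  b1 <- prepare_block(g$nonimaging$matrix)
  b2 <- prepare_block(g$thickness$matrix)
  curve <- sample_size_check(b1, b2, c1 = 1.7, c2 = 2, n_modes = 1,
                             n_grid = c(30, 160), n_resamples = 40,
                             seed = 13)
  expect_gt(curve$overfit_mode1[1], curve$overfit_mode1[2])
  expect_true(attr(curve, "verdict") %in% c("marginal", "substantial"))
})

test_that("a noiseless strong signal yields a flat overfitting curve", {
  spec <- synthetic_spec(n_participants = 120,
                         planted_modes = list(planted_mode(
                           u = rnorm(24), v = rnorm(62),
                           latent_correlation = 1,
                           strength1 = 20, strength2 = 20)),
                         noise_sd = c(0.01, 0.01))
  g <- generate_blocks(spec, seed = 51)
  b1 <- prepare_block(g$nonimaging$matrix)
  b2 <- prepare_block(g$thickness$matrix)
  # tiny subsampled halves of near-collinear noiseless columns can cycle
  # between equivalent sparse supports; the flagged iterate is still valid
  curve <- suppressWarnings(
    sample_size_check(b1, b2, c1 = 2, c2 = 2.5, n_modes = 1,
                      n_grid = c(30, 120), n_resamples = 25,
                      seed = 14))
  expect_lt(max(abs(curve$overfit_mode1)), 0.02)
  expect_equal(attr(curve, "verdict"), "marginal")
})
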