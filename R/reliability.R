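## Reliability battery: leave-one-out influence, split-half weight
## transfer, redundancy-reliability (RR) scores, and a sample-size /
## overfitting check. CCA modes permute and flip sign freely across
## refits, so every resampled model is matched to the reference
## full-sample model by maximal absolute cosine of the concatenated
## weight vectors (greedy assignment) and sign-aligned before averaging.

concat_weights <- function(model) {
  vapply(model$modes, function(m) c(m$u, m$v),
         numeric(length(model$modes[[1]]$u) + length(model$modes[[1]]$v)))
}

## Greedy match of resample modes (columns of W) to reference modes
## (columns of Wref) by |cosine|; returns for each reference mode the
## matched resample mode and the alignment sign.
match_modes <- function(Wref, W) {
  K <- ncol(Wref)
  cosm <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    ni <- sqrt(sum(Wref[, i]^2)); nj <- sqrt(sum(W[, j]^2))
    cosm[i, j] <- if (ni == 0 || nj == 0) 0
                  else sum(Wref[, i] * W[, j]) / (ni * nj)
  }
  perm <- integer(K)
  sgn <- numeric(K)
  absc <- abs(cosm)
  for (step in seq_len(K)) {
    ij <- arrayInd(which.max(absc), dim(absc))
    i <- ij[1]; j <- ij[2]
    perm[i] <- j
    sgn[i] <- if (cosm[i, j] >= 0) 1 else -1
    absc[i, ] <- -Inf
    absc[, j] <- -Inf
  }
  list(perm = perm, sign = sgn, cosine = vapply(seq_len(K), function(i)
    cosm[i, perm[i]], numeric(1)))
}

## Loadings of test-set variables on test-set variates for one mode,
## concatenated over both blocks. NULL when a variate is degenerate.
test_loadings <- function(x1, x2, u, v) {
  t1 <- drop(x1 %*% u)
  t2 <- drop(x2 %*% v)
  if (stats::sd(t1) == 0 || stats::sd(t2) == 0) return(NULL)
  l1 <- suppressWarnings(drop(stats::cor(x1, t1)))
  l2 <- suppressWarnings(drop(stats::cor(x2, t2)))
  c(l1, l2)
}

#' Redundancy-reliability (RR) score of a mode on a test set
#'
#' Measures whether a held-out set reproduces a mode's variable-to-variate
#' correlation structure: every variable of both blocks is correlated with
#' its block's test-set variate (computed from `model`'s weights), and the
#' resulting test loading vector is correlated with the reference
#' full-sample loading vector. A score of 1 means identical loading
#' structure; 0 means no shared structure. The score is invariant to
#' jointly flipping a mode's weight signs in either model.
#'
#' @param model the (training) model whose weights project the test set.
#' @param test_block1,test_block2 held-out blocks (matrices or
#'   [data_block()]s) with the model's variables.
#' @param mode_index 1-based mode number.
#' @param reference model providing the full-sample loading vectors;
#'   defaults to `model` itself.
#' @param reference_mode mode of `reference` to compare against (differs
#'   from `mode_index` when resampled modes have been permuted by
#'   matching); defaults to `mode_index`.
#' @return a score in `[0, 1]` (absolute correlation, so the score is
#'   invariant to joint sign flips of a mode's weights), or `NA` when a
#'   test variate has zero variance (degenerate case, skipped by callers).
#' @export
rr_score <- function(model, test_block1, test_block2, mode_index = 1L,
                     reference = model, reference_mode = mode_index) {
  stopifnot(inherits(model, "scca_model"),
            inherits(reference, "scca_model"))
  x1 <- as_block_matrix(test_block1)
  x2 <- as_block_matrix(test_block2)
  if (nrow(x1) < 5) stop("rr_score needs at least 5 test participants")
  k <- as.integer(mode_index)
  kr <- as.integer(reference_mode)
  tl <- test_loadings(x1, x2, model$modes[[k]]$u, model$modes[[k]]$v)
  if (is.null(tl)) return(NA_real_)
  ref <- c(reference$loadings1[, kr], reference$loadings2[, kr])
  keep <- is.finite(tl) & is.finite(ref)
  if (sum(keep) < 3 || stats::sd(tl[keep]) == 0 ||
      stats::sd(ref[keep]) == 0)
    return(NA_real_)
  abs(stats::cor(tl[keep], ref[keep]))
}

#' Leave-one-out influence of each participant
#'
#' Refits the sparse CCA with each participant removed and records how
#' much every tested mode's canonical correlation moves (full-sample r
#' minus drop-one r, after mode matching). Participants whose influence
#' deviates from the mean influence by more than `flag_sd` standard
#' deviations on any mode are flagged, screening for outlier-dominated
#' modes.
#'
#' @param block1,block2 standardized aligned [data_block()]s (n >= 10).
#' @param c1,c2,n_modes,cov_structure fitting configuration, held fixed.
#' @param flag_sd flagging threshold in SD units of the influence
#'   distribution.
#' @return data frame with one row per participant: influence per mode and
#'   a `flagged` column; the full-sample model in `attr(, "model")`.
#' @export
leave_one_out <- function(block1, block2, c1 = NULL, c2 = NULL,
                          n_modes = 7L,
                          cov_structure = c("diagonal", "full"),
                          flag_sd = 3) {
  cov_structure <- match.arg(cov_structure)
  check_aligned(block1, block2)
  n <- nrow(block1$matrix)
  if (n < 10) stop("leave-one-out needs at least 10 participants")
  if (is.null(c1)) c1 <- default_penalty(ncol(block1$matrix))
  if (is.null(c2)) c2 <- default_penalty(ncol(block2$matrix))
  full <- fit_scca(block1, block2, c1 = c1, c2 = c2, n_modes = n_modes,
                   cov_structure = cov_structure)
  Wref <- concat_weights(full)
  infl <- matrix(NA_real_, n, n_modes)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    b1 <- prepare_block(block1$matrix[keep, , drop = FALSE],
                        block1$variable_names, block1$participant_ids[keep])
    b2 <- prepare_block(block2$matrix[keep, , drop = FALSE],
                        block2$variable_names, block2$participant_ids[keep])
    m <- fit_scca(b1, b2, c1 = c1, c2 = c2, n_modes = n_modes,
                  cov_structure = cov_structure)
    mm <- match_modes(Wref, concat_weights(m))
    infl[i, ] <- full$canonical_correlations -
      m$canonical_correlations[mm$perm]
  }
  mu <- colMeans(infl)
  sdv <- apply(infl, 2, stats::sd)
  sdv[sdv == 0] <- Inf # identical refits: nothing can be flagged
  flagged <- rowSums(abs(sweep(sweep(infl, 2, mu, "-"), 2, sdv, "/"))
                     > flag_sd) > 0
  out <- data.frame(participant_id = block1$participant_ids, infl,
                    flagged = flagged, stringsAsFactors = FALSE)
  names(out)[2:(n_modes + 1)] <- paste0("influence_mode", seq_len(n_modes))
  attr(out, "model") <- full
  out
}

#' Split-half weight-transfer reliability
#'
#' Randomly splits the sample in half `n_resamples` times, fits the sparse
#' CCA on each training half, applies the training weights to the held-out
#' half, and records per mode (after matching/sign-aligning to the
#' full-sample model): the training canonical correlation, the held-out
#' variate correlation, and the RR-score against the full-sample loadings.
#' The overfitting index is the mean gap between training and held-out
#' correlations. Degenerate halves (a constant column in training) are
#' redrawn and counted.
#'
#' @param block1,block2 standardized aligned [data_block()]s (n >= 20).
#' @param c1,c2,n_modes,cov_structure fitting configuration.
#' @param n_resamples number of random half-splits.
#' @param seed integer seed driving all splits.
#' @param model optional precomputed full-sample model (must match the
#'   configuration); refit when `NULL`.
#' @return object of class `reliability_report` with matrices
#'   `train_r`, `splithalf_r`, `rr` (resamples x modes) and summaries
#'   `rr_mean`, `rr_sd`, `overfit_index` per mode.
#' @export
split_half <- function(block1, block2, c1 = NULL, c2 = NULL, n_modes = 7L,
                       cov_structure = c("diagonal", "full"),
                       n_resamples = 10000L, seed = 1L, model = NULL) {
  cov_structure <- match.arg(cov_structure)
  check_aligned(block1, block2)
  n <- nrow(block1$matrix)
  if (n < 20) stop("split-half reliability needs at least 20 participants")
  if (is.null(c1)) c1 <- default_penalty(ncol(block1$matrix))
  if (is.null(c2)) c2 <- default_penalty(ncol(block2$matrix))
  if (is.null(model))
    model <- fit_scca(block1, block2, c1 = c1, c2 = c2, n_modes = n_modes,
                      cov_structure = cov_structure)
  Wref <- concat_weights(model)
  n_resamples <- as.integer(n_resamples)
  train_r <- matrix(NA_real_, n_resamples, n_modes)
  test_r <- matrix(NA_real_, n_resamples, n_modes)
  rr <- matrix(NA_real_, n_resamples, n_modes)
  match_perms <- matrix(NA_integer_, n_resamples, n_modes)
  n_train <- ceiling(n / 2) # training gets the larger half when n is odd
  redraws <- 0L
  set.seed(seed)
  for (b in seq_len(n_resamples)) {
    repeat {
      tr <- sample.int(n, n_train)
      sp <- train_test_standardize(block1, block2, tr,
                                   setdiff(seq_len(n), tr))
      if (!is.null(sp)) break
      redraws <- redraws + 1L
      if (redraws > 100 * n_resamples)
        stop("could not draw a non-degenerate split")
    }
    m <- fit_scca(sp$train1, sp$train2, c1 = c1, c2 = c2,
                  n_modes = n_modes, cov_structure = cov_structure)
    mm <- match_modes(Wref, concat_weights(m))
    match_perms[b, ] <- mm$perm
    x1te <- sp$test1$matrix
    x2te <- sp$test2$matrix
    for (k in seq_len(n_modes)) {
      j <- mm$perm[k]
      train_r[b, k] <- m$canonical_correlations[j]
      t1 <- drop(x1te %*% (mm$sign[k] * m$modes[[j]]$u))
      t2 <- drop(x2te %*% (mm$sign[k] * m$modes[[j]]$v))
      if (stats::sd(t1) > 0 && stats::sd(t2) > 0)
        test_r[b, k] <- stats::cor(t1, t2)
      rr[b, k] <- rr_score(m, x1te, x2te, j, reference = model,
                           reference_mode = k)
    }
  }
  structure(list(train_r = train_r, splithalf_r = test_r, rr = rr,
                 rr_mean = colMeans(rr, na.rm = TRUE),
                 rr_sd = apply(rr, 2, stats::sd, na.rm = TRUE),
                 overfit_index = colMeans(train_r - test_r, na.rm = TRUE),
                 mode_matching = match_perms,
                 n_resamples = n_resamples, redraws = redraws,
                 seed = seed, penalties = c(c1 = c1, c2 = c2),
                 model = model),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  K <- length(x$rr_mean)
  cat(sprintf("Split-half reliability: %d resamples (seed %d, %d redraws)\n",
              x$n_resamples, x$seed, x$redraws))
  print(data.frame(mode = seq_len(K),
                   mean_train_r = round(colMeans(x$train_r, na.rm = TRUE), 3),
                   mean_test_r = round(colMeans(x$splithalf_r,
                                                na.rm = TRUE), 3),
                   overfit_index = round(x$overfit_index, 3),
                   rr_mean = round(x$rr_mean, 3),
                   rr_sd = round(x$rr_sd, 3)), row.names = FALSE)
  invisible(x)
}

#' Sample-size adequacy / overfitting curve
#'
#' Computes the split-half overfitting index at a grid of subsample sizes,
#' tracing how the gap between in-sample and held-out variate correlations
#' shrinks with n. The study's sample is judged `"marginal"` overfitting
#' when the mode-1 index at the largest grid n falls below `threshold`.
#'
#' @param block1,block2 standardized aligned [data_block()]s.
#' @param c1,c2,n_modes,cov_structure fitting configuration.
#' @param n_grid increasing vector of subsample sizes (each <= n).
#' @param n_resamples split-half resamples per grid point.
#' @param seed integer seed.
#' @param threshold overfitting index below which the largest-n point is
#'   flagged `"marginal"` (otherwise `"substantial"`).
#' @return data frame with one row per grid n and one overfit-index column
#'   per mode; the verdict in `attr(, "verdict")`.
#' @export
sample_size_check <- function(block1, block2, c1 = NULL, c2 = NULL,
                              n_modes = 2L,
                              cov_structure = c("diagonal", "full"),
                              n_grid = NULL, n_resamples = 100L, seed = 1L,
                              threshold = 0.1) {
  cov_structure <- match.arg(cov_structure)
  check_aligned(block1, block2)
  n <- nrow(block1$matrix)
  if (is.null(n_grid)) n_grid <- unique(pmin(c(24L, 32L, n), n))
  n_grid <- sort(unique(as.integer(n_grid)))
  if (max(n_grid) > n) stop("n_grid exceeds the available sample size")
  if (min(n_grid) < 20) stop("split-half needs subsamples of at least 20")
  set.seed(seed)
  rows <- lapply(seq_along(n_grid), function(i) {
    ni <- n_grid[i]
    idx <- if (ni == n) seq_len(n) else sample.int(n, ni)
    b1 <- prepare_block(block1$matrix[idx, , drop = FALSE],
                        block1$variable_names, block1$participant_ids[idx])
    b2 <- prepare_block(block2$matrix[idx, , drop = FALSE],
                        block2$variable_names, block2$participant_ids[idx])
    rep_i <- split_half(b1, b2, c1 = c1, c2 = c2, n_modes = n_modes,
                        cov_structure = cov_structure,
                        n_resamples = n_resamples,
                        seed = seed + i)
    rep_i$overfit_index
  })
  out <- data.frame(n = n_grid, do.call(rbind, rows))
  names(out)[-1] <- paste0("overfit_mode", seq_len(n_modes))
  attr(out, "verdict") <- if (out[nrow(out), 2] < threshold) "marginal"
                          else "substantial"
  out
}
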