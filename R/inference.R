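#' Permutation significance test for canonical modes
#'
#' Builds a null distribution for each mode's canonical correlation by
#' shuffling the rows of the second block relative to the first
#' (participant relabeling, which preserves each block's internal
#' covariance), refitting the full sparse CCA with the same penalties on
#' every permuted data set, and comparing mode k's observed correlation
#' with mode k's permuted correlations. P-values use the add-one rule
#' `(1 + #\{null >= observed\}) / (1 + B)`, so the smallest attainable
#' p-value is `1/(B+1)`.
#'
#' With `method = "maxT"` the null statistic is the maximum permuted
#' correlation over all tested modes, giving family-wise control across
#' modes.
#'
#' @param block1,block2 standardized aligned [data_block()]s.
#' @param c1,c2 L1 penalties, held fixed across permutations (the test
#'   addresses the association, not the tuning).
#' @param n_modes_tested how many leading modes to refit and test.
#' @param n_perm number of permutations `B`.
#' @param alpha significance threshold used for the `significant` flag.
#' @param method `"modewise"` (mode k observed vs mode k null) or
#'   `"maxT"`.
#' @param seed integer seed for the permutation stream.
#' @param cov_structure,tol,max_iter passed to the fitting routine.
#' @return object of class `permutation_result`: a data frame of per-mode
#'   observed correlations, p-values and significance flags, with the null
#'   matrix (`B` x modes) in `attr(, "null_distribution")`.
#' @export
permutation_test <- function(block1, block2, c1 = NULL, c2 = NULL,
                             n_modes_tested = 7L, n_perm = 10000L,
                             alpha = 0.05,
                             method = c("modewise", "maxT"),
                             seed = 1L,
                             cov_structure = c("diagonal", "full"),
                             tol = 1e-6, max_iter = 500L) {
  method <- match.arg(method)
  cov_structure <- match.arg(cov_structure)
  if (block1$state == "raw" || block2$state == "raw")
    stop("blocks must be standardized; use prepare_block()")
  check_aligned(block1, block2)
  n_perm <- as.integer(n_perm)
  if (n_perm < 99)
    warning("n_perm = ", n_perm, " gives coarse p-value resolution ",
            "(minimum attainable p = ", signif(1 / (n_perm + 1), 3), ")")
  n <- nrow(block1$matrix)
  p1 <- ncol(block1$matrix)
  if (is.null(c1)) c1 <- default_penalty(p1)
  if (is.null(c2)) c2 <- default_penalty(ncol(block2$matrix))
  K <- as.integer(n_modes_tested)

  observed <- fit_scca(block1, block2, c1 = c1, c2 = c2, n_modes = K,
                       cov_structure = cov_structure, tol = tol,
                       max_iter = max_iter)
  obs_r <- observed$canonical_correlations

  X1 <- block1$matrix
  X2 <- block2$matrix
  if (cov_structure == "full") {
    W1 <- inv_sqrt_sym(crossprod(X1) / (n - 1), "first")
    W2 <- inv_sqrt_sym(crossprod(X2) / (n - 1), "second")
    X1w <- X1 %*% W1
  } else {
    X1w <- X1
  }

  set.seed(seed)
  null_r <- matrix(NA_real_, n_perm, K)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    X2p <- X2[idx, , drop = FALSE]
    X2pw <- if (cov_structure == "full") X2p %*% W2 else X2p
    Z <- crossprod(X1w, X2pw) / (n - 1)
    fit <- scca_fit_cross(Z, c1, c2, K, tol, max_iter)
    U <- fit$U; V <- fit$V
    if (cov_structure == "full") {
      U <- W1 %*% U
      V <- W2 %*% V
    }
    T1 <- X1 %*% U
    T2 <- X2p %*% V
    for (k in seq_len(K)) {
      s1 <- stats::sd(T1[, k]); s2 <- stats::sd(T2[, k])
      null_r[b, k] <- if (s1 == 0 || s2 == 0) 0
                      else stats::cor(T1[, k], T2[, k])
    }
  }

  pvals <- vapply(seq_len(K), function(k) {
    null_k <- if (method == "maxT") apply(null_r, 1, max) else null_r[, k]
    (1 + sum(null_k >= obs_r[k])) / (1 + n_perm)
  }, numeric(1))

  res <- data.frame(mode_index = seq_len(K), observed_r = obs_r,
                    p_value = pvals, significant = pvals < alpha,
                    B = n_perm, seed = seed)
  attr(res, "null_distribution") <- null_r
  attr(res, "method") <- method
  attr(res, "model") <- observed
  class(res) <- c("permutation_result", "data.frame")
  res
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: B = %d (%s), seed = %d\n",
              x$B[1], attr(x, "method"), x$seed[1]))
  print(data.frame(mode = x$mode_index,
                   observed_r = round(x$observed_r, 4),
                   p = signif(x$p_value, 4),
                   significant = x$significant), row.names = FALSE)
  invisible(x)
}
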