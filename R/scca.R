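## Sparse CCA by L1-penalized matrix decomposition (PMD) of the
## cross-product matrix Z = X1' X2, with successive rank-1 deflation.
## Each mode solves
##   max u' Z v   s.t. ||u||2 <= 1, ||v||2 <= 1, ||u||1 <= c1, ||v||1 <= c2
## by alternating soft-thresholded power iterations; the soft-threshold
## level is found by bisection so the L1 budget is met exactly.

soft_threshold <- function(a, lambda) {
  sign(a) * pmax(abs(a) - lambda, 0)
}

## Project a vector onto {w : ||w||2 <= 1, ||w||1 <= c} along the
## soft-threshold path: w(lambda) = S(a, lambda) / ||S(a, lambda)||2.
## ||w(lambda)||1 is continuous and non-increasing in lambda, so bisection
## on lambda in [0, max|a|) meets the budget.
l1_unit_project <- function(a, c) {
  ab <- abs(a)
  l2 <- sqrt(sum(ab * ab))
  if (l2 == 0) return(a)
  if (sum(ab) / l2 <= c) return(a / l2)
  lambda <- l1_threshold_exact(ab, c)
  if (is.na(lambda)) lambda <- l1_threshold_bisect(ab, c)
  s <- ab - lambda
  s <- s * (s > 0) * sign(a)
  n2 <- sum(s * s)
  if (n2 > 0) {
    w <- s / sqrt(n2)
    if (sum(abs(w)) <= c + 1e-9) return(w)
  }
  # tied maxima with c below sqrt(#ties): the soft-threshold path cannot
  # split the tie; the limit solution puts all weight on one entry
  w <- numeric(length(a))
  i <- which.max(ab)
  w[i] <- sign(a[i])
  w
}

## Exact soft-threshold level: with the |a| values sorted descending and
## the top k entries active, ||w(lambda)||1 = c reduces to a quadratic in
## lambda on each inter-breakpoint interval. Returns NA on numerically
## degenerate instances (handled by bisection).
l1_threshold_exact <- function(ab, c) {
  o <- sort.int(ab, decreasing = TRUE, method = "quick")
  p <- length(o)
  S1 <- cumsum(o)
  S2 <- cumsum(o * o)
  # L1/L2 ratio evaluated at the lower end of each interval (lambda =
  # o[k+1], k entries active); non-decreasing in k. Zero-length intervals
  # (tied breakpoints) yield non-finite ratios and are skipped.
  k_idx <- 1:(p - 1)
  lam <- o[-1L]
  num <- S1[k_idx] - k_idx * lam
  den2 <- S2[k_idx] - (2 * lam) * S1[k_idx] + k_idx * (lam * lam)
  g <- suppressWarnings(num / sqrt(den2))
  g[den2 <= 1e-300 | !is.finite(g)] <- -Inf
  k <- match(TRUE, g >= c)
  if (is.na(k)) k <- p
  lo_int <- if (k < p) o[k + 1] else 0
  hi_int <- o[k]
  A <- k * (k - c^2)
  B <- -2 * S1[k] * (k - c^2)
  C <- S1[k]^2 - c^2 * S2[k]
  if (abs(A) < 1e-12 * max(1, abs(B))) {
    if (B == 0) return(NA_real_)
    lambda <- -C / B
    if (lambda >= lo_int - 1e-12 && lambda <= hi_int + 1e-12)
      return(min(max(lambda, lo_int), hi_int))
    return(NA_real_)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) {
    if (disc > -1e-10 * max(B^2, 1)) disc <- 0 else return(NA_real_)
  }
  roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  eps <- 1e-10 * max(hi_int, 1)
  ok <- roots >= lo_int - eps & roots <= hi_int + eps
  if (!any(ok)) return(NA_real_)
  # the L1 ratio is decreasing in lambda; the valid root is the one in
  # the bracket (take the larger if both qualify numerically)
  min(max(max(roots[ok]), lo_int), hi_int)
}

l1_threshold_bisect <- function(ab, c) {
  lo <- 0
  hi <- max(ab)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    s <- ab - mid
    s <- s * (s > 0)
    n2 <- sum(s * s)
    if (n2 > 0 && sum(s) / sqrt(n2) > c) lo <- mid else hi <- mid
    if (hi - lo < 1e-13 * max(hi, 1)) break
  }
  hi
}

## Rank-1 penalized decomposition of a working matrix Z.
## Returns u, v, d and convergence info.
pmd_rank1 <- function(Z, c1, c2, tol = 1e-6, max_iter = 500L,
                      trace = FALSE) {
  sv <- svd(Z, nu = 0, nv = 1)
  # project the initial singular vector into the feasible set so the
  # alternating objective is monotone from the first step
  v <- l1_unit_project(sv$v[, 1], c2)
  u <- rep(0, nrow(Z))
  obj_trace <- if (trace) numeric(0) else NULL
  converged <- FALSE
  iter <- 0L
  obj_prev <- -Inf
  repeat {
    iter <- iter + 1L
    u_old <- u; v_old <- v
    u <- l1_unit_project(drop(Z %*% v), c1)
    if (trace) obj_trace <- c(obj_trace, sum(u * drop(Z %*% v)))
    zu <- drop(crossprod(Z, u))
    v <- l1_unit_project(zu, c2)
    obj <- sum(v * zu)
    if (trace) obj_trace <- c(obj_trace, obj)
    if (max(abs(u - u_old)) < tol && max(abs(v - v_old)) < tol) {
      converged <- TRUE
      break
    }
    # plateau: equivalent tied optima can oscillate in the weights at a
    # numerically constant objective
    if (abs(obj - obj_prev) < 1e-12 * max(1, abs(obj)) && iter > 2) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
    if (iter >= max_iter) break
  }
  d <- drop(crossprod(u, Z %*% v))
  list(u = u, v = v, d = d, converged = converged, iterations = iter,
       objective_trace = obj_trace)
}

## Symmetric inverse square root of a covariance matrix (for
## cov_structure = "full" whitening).
inv_sqrt_sym <- function(S, label) {
  eg <- eigen(S, symmetric = TRUE)
  if (min(eg$values) < 1e-10 * max(eg$values))
    stop("within-block covariance of the ", label,
         " block is (near-)singular; cov_structure = \"full\" needs ",
         "n to exceed the block dimensions")
  eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
}

## Fit on a precomputed working matrix; shared by fit_scca and the fast
## permutation path. Returns raw (possibly whitened-basis) factors.
scca_fit_cross <- function(Z, c1, c2, n_modes, tol, max_iter,
                           trace = FALSE) {
  p1 <- nrow(Z); p2 <- ncol(Z)
  U <- matrix(0, p1, n_modes)
  V <- matrix(0, p2, n_modes)
  d <- numeric(n_modes)
  converged <- logical(n_modes)
  traces <- if (trace) vector("list", n_modes) else NULL
  for (k in seq_len(n_modes)) {
    fk <- pmd_rank1(Z, c1, c2, tol = tol, max_iter = max_iter,
                    trace = trace)
    U[, k] <- fk$u; V[, k] <- fk$v; d[k] <- fk$d
    converged[k] <- fk$converged
    if (trace) traces[[k]] <- fk$objective_trace
    Z <- Z - fk$d * tcrossprod(fk$u, fk$v)
  }
  list(U = U, V = V, d = d, converged = converged, traces = traces)
}

default_penalty <- function(p, frac = 0.35) 1 + frac * (sqrt(p) - 1)

#' Fit a sparse canonical correlation model
#'
#' Computes `n_modes` successive sparse canonical modes of two
#' participant-aligned standardized blocks by L1-penalized matrix
#' decomposition of the cross-product matrix, deflating the fitted rank-1
#' component between modes. Each weight vector satisfies an L2 bound of 1
#' and an L1 bound (`c1`, `c2`); with an active L1 penalty some weights
#' are exactly zero.
#'
#' With `cov_structure = "full"` each block is first whitened by its
#' within-block covariance, so that in the loose-penalty limit
#' (`c = sqrt(p)`) the first mode coincides with classical CCA; this
#' requires more participants than variables per block. The default
#' `"diagonal"` applies the penalized decomposition to the raw
#' cross-product, which is the standard sparse-CCA formulation and works
#' when variables outnumber participants.
#'
#' Sign convention: each mode is flipped jointly (both `u` and `v`) so the
#' largest-magnitude entry of `u` is positive; the canonical correlation
#' keeps its natural sign.
#'
#' @param block1,block2 standardized [data_block()]s with identical
#'   participant order.
#' @param c1,c2 L1 bounds per block, in `[1, sqrt(p)]`; `NULL` uses a
#'   moderate default, `1 + 0.35 (sqrt(p) - 1)`.
#' @param n_modes number of modes to extract.
#' @param tol convergence tolerance on the maximum absolute weight change.
#' @param max_iter maximum alternating iterations per mode; non-convergence
#'   warns and returns the current iterate flagged in `$converged`.
#' @param cov_structure `"diagonal"` (penalized decomposition of the raw
#'   cross-product) or `"full"` (whitened; classical-CCA limit).
#' @param seed optional integer; the solver is deterministic, the seed only
#'   matters for degenerate ties in the initial singular vector.
#' @param trace if `TRUE`, store the per-iteration objective values.
#' @return an object of class `scca_model` with one entry per mode:
#'   weight vectors `u`/`v` (keyed by variable name), singular value `d` of
#'   the deflated cross-product, `canonical_correlation`, and
#'   `variance_explained_share` (`d_k^2 / sum d_j^2` over computed modes).
#'   The model also stores the full-sample loading matrices (correlation of
#'   every variable with its block's variate), used by the reliability
#'   battery.
#' @references Witten, D. M., Tibshirani, R., & Hastie, T. (2009). A
#'   penalized matrix decomposition, with applications to sparse principal
#'   components and canonical correlation analysis. Biostatistics, 10(3).
#' @export
fit_scca <- function(block1, block2, c1 = NULL, c2 = NULL, n_modes = 10L,
                     tol = 1e-6, max_iter = 500L,
                     cov_structure = c("diagonal", "full"), seed = NULL,
                     trace = FALSE) {
  cov_structure <- match.arg(cov_structure)
  if (!inherits(block1, "data_block")) block1 <- prepare_block(block1)
  if (!inherits(block2, "data_block")) block2 <- prepare_block(block2)
  if (block1$state == "raw" || block2$state == "raw")
    stop("blocks must be standardized; use prepare_block()")
  check_aligned(block1, block2)
  X1 <- block1$matrix; X2 <- block2$matrix
  n <- nrow(X1); p1 <- ncol(X1); p2 <- ncol(X2)
  if (is.null(c1)) c1 <- default_penalty(p1)
  if (is.null(c2)) c2 <- default_penalty(p2)
  if (c1 < 1 || c1 > sqrt(p1) + 1e-9)
    stop("c1 must lie in [1, sqrt(p1)] = [1, ", round(sqrt(p1), 3), "]")
  if (c2 < 1 || c2 > sqrt(p2) + 1e-9)
    stop("c2 must lie in [1, sqrt(p2)] = [1, ", round(sqrt(p2), 3), "]")
  n_modes <- as.integer(n_modes)
  if (n_modes < 1 || n_modes > min(p1, p2))
    stop("n_modes must be in [1, min(p1, p2)]")
  if (!is.null(seed)) set.seed(seed)

  if (cov_structure == "full") {
    W1 <- inv_sqrt_sym(crossprod(X1) / (n - 1), "first")
    W2 <- inv_sqrt_sym(crossprod(X2) / (n - 1), "second")
    Z <- crossprod(X1 %*% W1, X2 %*% W2) / (n - 1)
  } else {
    Z <- crossprod(X1, X2) / (n - 1)
  }

  fit <- scca_fit_cross(Z, c1, c2, n_modes, tol, max_iter, trace = trace)
  if (!all(fit$converged))
    warning("mode(s) ", paste(which(!fit$converged), collapse = ", "),
            " did not converge in ", max_iter, " iterations")

  U <- fit$U; V <- fit$V
  if (cov_structure == "full") {
    U <- W1 %*% U
    V <- W2 %*% V
    # map back to the original variable basis; renormalize to unit L2
    # (the variate correlation is scale-invariant)
    U <- sweep(U, 2, pmax(sqrt(colSums(U^2)), 1e-300), "/")
    V <- sweep(V, 2, pmax(sqrt(colSums(V^2)), 1e-300), "/")
  }

  # joint sign flip: largest-|weight| entry of u positive
  for (k in seq_len(n_modes)) {
    i <- which.max(abs(U[, k]))
    if (length(i) && U[i, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }

  T1 <- X1 %*% U
  T2 <- X2 %*% V
  r <- vapply(seq_len(n_modes), function(k) {
    if (stats::sd(T1[, k]) == 0 || stats::sd(T2[, k]) == 0) return(NA_real_)
    stats::cor(T1[, k], T2[, k])
  }, numeric(1))
  d2 <- fit$d^2
  share <- if (sum(d2) > 0) d2 / sum(d2) else rep(NA_real_, n_modes)

  # full-sample loadings: correlation of each variable with its variate
  load1 <- suppressWarnings(stats::cor(X1, T1))
  load2 <- suppressWarnings(stats::cor(X2, T2))

  rownames(U) <- block1$variable_names
  rownames(V) <- block2$variable_names
  modes <- lapply(seq_len(n_modes), function(k) {
    structure(list(index = k, u = U[, k], v = V[, k], d = fit$d[k],
                   canonical_correlation = r[k],
                   variance_explained_share = share[k],
                   converged = fit$converged[k]),
              class = "scca_mode")
  })
  structure(list(modes = modes, penalties = c(c1 = c1, c2 = c2),
                 n_modes = n_modes,
                 cov_structure = cov_structure,
                 prep = paste0("block1: ", block1$state,
                               "; block2: ", block2$state),
                 variable_names1 = block1$variable_names,
                 variable_names2 = block2$variable_names,
                 loadings1 = load1, loadings2 = load2,
                 d = fit$d, canonical_correlations = r,
                 variance_explained_share = share,
                 objective_traces = fit$traces),
            class = "scca_model")
}

#' @export
print.scca_model <- function(x, ...) {
  cat(sprintf("scca_model: %d modes, penalties c1 = %.3f, c2 = %.3f (%s)\n",
              x$n_modes, x$penalties["c1"], x$penalties["c2"],
              x$cov_structure))
  df <- data.frame(mode = seq_len(x$n_modes),
                   d = round(x$d, 4),
                   canonical_r = round(x$canonical_correlations, 4),
                   var_share = round(x$variance_explained_share, 4),
                   nnz_u = vapply(x$modes, function(m) sum(m$u != 0), 0L),
                   nnz_v = vapply(x$modes, function(m) sum(m$v != 0), 0L))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Per-mode variance-explained shares
#'
#' Shares are defined on the squared singular values of the successively
#' deflated cross-product matrices, normalized over the computed modes
#' (so they sum to 1). The cumulative share drives the decision of how
#' many leading modes to carry into permutation and reliability testing.
#'
#' @param model a fitted [fit_scca()] model.
#' @return numeric vector of shares, one per computed mode.
#' @export
variance_explained <- function(model) {
  stopifnot(inherits(model, "scca_model"))
  model$variance_explained_share
}

#' Project blocks onto a fitted mode
#'
#' Applies a mode's weight vectors to (possibly held-out) blocks with the
#' model's variable sets, returning the pair of participant-level variates.
#' On the training blocks the Pearson correlation of the two variates
#' equals the stored canonical correlation.
#'
#' @param model a fitted [fit_scca()] model.
#' @param block1,block2 [data_block()]s (or matrices) whose variables match
#'   the model's, in the same order.
#' @param mode_index 1-based mode number.
#' @return data frame with `participant_id`, `variate1`, `variate2`.
#' @export
project <- function(model, block1, block2, mode_index = 1L) {
  stopifnot(inherits(model, "scca_model"))
  x1 <- as_block_matrix(block1)
  x2 <- as_block_matrix(block2)
  nm1 <- if (inherits(block1, "data_block")) block1$variable_names
         else colnames(x1)
  nm2 <- if (inherits(block2, "data_block")) block2$variable_names
         else colnames(x2)
  if (!is.null(nm1) && !identical(nm1, model$variable_names1))
    stop("block 1 variables differ from the model's: ",
         paste(union(setdiff(nm1, model$variable_names1),
                     setdiff(model$variable_names1, nm1)), collapse = ", "))
  if (!is.null(nm2) && !identical(nm2, model$variable_names2))
    stop("block 2 variables differ from the model's: ",
         paste(union(setdiff(nm2, model$variable_names2),
                     setdiff(model$variable_names2, nm2)), collapse = ", "))
  k <- as.integer(mode_index)
  if (k < 1 || k > model$n_modes) stop("mode_index out of range")
  ids <- if (inherits(block1, "data_block")) block1$participant_ids
         else rownames(x1)
  if (is.null(ids)) ids <- paste0("p", seq_len(nrow(x1)))
  data.frame(participant_id = ids,
             variate1 = drop(x1 %*% model$modes[[k]]$u),
             variate2 = drop(x2 %*% model$modes[[k]]$v),
             stringsAsFactors = FALSE)
}

## Standardize a train/test split with the training moments: the training
## half is z-scored on its own moments and the held-out half reuses them,
## so held-out projections are genuinely out-of-sample. Returns NULL when
## a training column is constant (degenerate split).
train_test_standardize <- function(block1, block2, tr, te) {
  out <- vector("list", 4)
  names(out) <- c("train1", "test1", "train2", "test2")
  for (b in 1:2) {
    blk <- if (b == 1) block1 else block2
    xtr <- blk$matrix[tr, , drop = FALSE]
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2, stats::sd)
    if (any(sdv < 1e-12)) return(NULL)
    std <- function(x) sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
    out[[2 * b - 1]] <- data_block(std(xtr), blk$variable_names,
                                   blk$participant_ids[tr],
                                   state = "standardized")
    out[[2 * b]] <- data_block(std(blk$matrix[te, , drop = FALSE]),
                               blk$variable_names, blk$participant_ids[te],
                               state = "raw")
  }
  out
}

#' Choose L1 penalties by out-of-sample variate correlation
#'
#' Evaluates a small grid of `(c1, c2)` pairs by repeatedly splitting the
#' sample in half, fitting the first mode on the training half and scoring
#' the Pearson correlation of the projected variates on the held-out half;
#' the pair maximizing the mean out-of-sample correlation wins.
#'
#' @param block1,block2 standardized aligned [data_block()]s.
#' @param grid_frac fractions of the feasible range `[1, sqrt(p)]` to try
#'   per block.
#' @param K number of random half-splits per grid point.
#' @param seed integer seed driving the splits.
#' @param rule `"1se"` (default) picks the sparsest pair whose mean score
#'   is within one standard error of the best; `"best"` picks the maximum
#'   score outright.
#' @param ... further arguments passed to [fit_scca()].
#' @return list with `c1`, `c2`, and the score `grid` (data frame).
#' @export
select_penalties <- function(block1, block2,
                             grid_frac = c(0.10, 0.25, 0.50), K = 3L,
                             seed = 1L, rule = c("1se", "best"), ...) {
  rule <- match.arg(rule)
  if (block1$state == "raw" || block2$state == "raw")
    stop("blocks must be standardized; use prepare_block()")
  check_aligned(block1, block2)
  p1 <- ncol(block1$matrix); p2 <- ncol(block2$matrix)
  n <- nrow(block1$matrix)
  c1s <- 1 + grid_frac * (sqrt(p1) - 1)
  c2s <- 1 + grid_frac * (sqrt(p2) - 1)
  grid <- expand.grid(c1 = c1s, c2 = c2s)
  set.seed(seed)
  splits <- lapply(seq_len(K), function(i) sample(n, ceiling(n / 2)))
  scores <- lapply(seq_len(nrow(grid)), function(g) {
    vapply(splits, function(tr) {
      te <- setdiff(seq_len(n), tr)
      sp <- train_test_standardize(block1, block2, tr, te)
      if (is.null(sp)) return(0)
      m <- fit_scca(sp$train1, sp$train2, c1 = grid$c1[g], c2 = grid$c2[g],
                    n_modes = 1L, ...)
      pr <- project(m, sp$test1, sp$test2, 1L)
      if (stats::sd(pr$variate1) == 0 || stats::sd(pr$variate2) == 0)
        return(0)
      stats::cor(pr$variate1, pr$variate2)
    }, numeric(1))
  })
  grid$score <- vapply(scores, mean, numeric(1))
  best <- which.max(grid$score)
  if (rule == "1se") {
    se <- stats::sd(scores[[best]]) / sqrt(K)
    ok <- grid$score >= grid$score[best] - se
    sparsity <- grid$c1 / sqrt(p1) + grid$c2 / sqrt(p2)
    cand <- which(ok)
    best <- cand[which.min(sparsity[cand])]
  }
  list(c1 = grid$c1[best], c2 = grid$c2[best], grid = grid)
}
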