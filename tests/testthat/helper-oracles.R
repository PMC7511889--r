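# Independent brute-force oracles used across the suite. These are written
# with explicit loops / base building blocks on purpose, so they share no
# code path with the package implementation they check.

# Eight task measures computed by explicit trial loops.
brute_force_profile <- function(task, id) {
  rows <- task[task$participant_id == id & !is.na(task$likelihood), ]
  lk <- rows$likelihood
  mu <- sum(lk) / length(lk)
  s <- sqrt(sum((lk - mu)^2) / (length(lk) - 1))
  z <- numeric(length(lk))
  for (i in seq_along(lk)) z[i] <- (lk[i] - mu) / s
  chars <- c("student", "elderly", "business", "alcoholic")
  bias <- numeric(4)
  for (ci in 1:4) {
    des <- c(); und <- c()
    for (i in seq_len(nrow(rows))) {
      if (rows$character[i] == chars[ci]) {
        if (rows$valence[i] == "desirable") des <- c(des, z[i])
        else und <- c(und, z[i])
      }
    }
    bias[ci] <- mean(des) - mean(und)
  }
  des_raw <- c(); und_raw <- c()
  for (i in seq_len(nrow(rows))) {
    if (rows$valence[i] == "desirable") des_raw <- c(des_raw, lk[i])
    else und_raw <- c(und_raw, lk[i])
  }
  c(desirable_avg = mean(des_raw), undesirable_avg = mean(und_raw),
    bias_student = bias[1], bias_elderly = bias[2],
    bias_business = bias[3], bias_alcoholic = bias[4],
    warmth_bias = bias[1] + bias[2] - bias[3] - bias[4],
    bias_magnitude = bias[1] + bias[2] + bias[3] - bias[4])
}

# A varied (non-degenerate) random task table.
random_task_table <- function(n, seed, missing_fraction = 0) {
  spec <- synthetic_spec(n_participants = n,
                         task_params = list(missing_fraction = missing_fraction))
  generate_task_responses(spec, seed = seed)
}

# Random standardized block pair with independent entries.
null_block_pair <- function(n, p1, p2, seed) {
  set.seed(seed)
  list(b1 = prepare_block(matrix(rnorm(n * p1), n, p1)),
       b2 = prepare_block(matrix(rnorm(n * p2), n, p2)))
}

# First classical canonical correlation via the generalized-eigenvalue
# route (whitened cross-covariance SVD), independent of the package.
cca_first_cor_oracle <- function(x1, x2) {
  s11 <- stats::cov(x1); s22 <- stats::cov(x2)
  s12 <- stats::cov(x1, x2)
  isqrt <- function(s) {
    e <- eigen(s, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), nrow(s)) %*% t(e$vectors)
  }
  svd(isqrt(s11) %*% s12 %*% isqrt(s22))$d[1]
}

# factor loading that induces correlation rho between two variables
# sharing one latent factor: cor = loading^2
rho_to_loading <- function(rho) sqrt(rho)
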