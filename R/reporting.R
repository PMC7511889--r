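#' Covariate-adjusted post hoc correlations
#'
#' For each selected measure and each region, computes the partial Pearson
#' correlation controlling for the supplied covariates: both sides are
#' residualized on the covariates plus intercept and the residuals are
#' correlated. P-values come from the t distribution with `n - 2 - q`
#' degrees of freedom (q = number of covariates). Exactly collinear
#' covariates (e.g. BMI alongside height and weight) are handled with a
#' pseudoinverse and a warning rather than an error.
#'
#' @param measures [data_block()] or matrix of behavioral measures.
#' @param thickness [data_block()] or matrix of regional thickness values.
#' @param covariates complete numeric covariate table aligned with the
#'   participants; missing values abort with the offending participants.
#' @param p_threshold uncorrected p-value below which a pair is marked as
#'   passing.
#' @return data frame with one row per (measure, region) pair:
#'   `measure_name`, `region_name`, `partial_r`, `p_uncorrected`,
#'   `passes`.
#' @export
posthoc_correlations <- function(measures, thickness, covariates,
                                 p_threshold = 0.001) {
  x <- as_block_matrix(measures)
  y <- as_block_matrix(thickness)
  mnames <- if (inherits(measures, "data_block")) measures$variable_names
            else colnames(x)
  rnames <- if (inherits(thickness, "data_block")) thickness$variable_names
            else colnames(y)
  if (is.null(mnames)) mnames <- paste0("measure", seq_len(ncol(x)))
  if (is.null(rnames)) rnames <- paste0("region", seq_len(ncol(y)))
  if (nrow(x) != nrow(y)) stop("measures and thickness rows differ")
  n <- nrow(x)
  q <- ncol(as.matrix(covariates))
  df <- n - 2 - q
  if (df < 1) stop("not enough participants for ", q, " covariates")
  rx <- residualize_columns(x, covariates, allow_collinear = TRUE)
  ry <- residualize_columns(y, covariates, allow_collinear = TRUE)
  pr <- suppressWarnings(stats::cor(rx, ry))
  pr <- pmin(pmax(pr, -1), 1)
  # a variable fully explained by the covariates has no residual signal:
  # its partial correlations are 0 by convention, not numerical noise
  degx <- apply(rx, 2, stats::sd) < 1e-10 * pmax(apply(x, 2, stats::sd), 1)
  degy <- apply(ry, 2, stats::sd) < 1e-10 * pmax(apply(y, 2, stats::sd), 1)
  pr[degx, ] <- 0
  pr[, degy] <- 0
  tstat <- pr * sqrt(df / pmax(1 - pr^2, .Machine$double.eps))
  pval <- 2 * stats::pt(-abs(tstat), df)
  out <- data.frame(
    measure_name = rep(mnames, times = length(rnames)),
    region_name = rep(rnames, each = length(mnames)),
    partial_r = as.vector(pr),
    p_uncorrected = as.vector(pval),
    stringsAsFactors = FALSE)
  out$passes <- out$p_uncorrected < p_threshold
  out
}

#' Per-mode weight tables with a reporting threshold
#'
#' Emits, for every mode of a fitted model, the full weight table (every
#' variable of both blocks, one weight column per mode — the shape used
#' for supplementary reporting) plus, per mode, the variables whose
#' absolute weight exceeds `threshold`, sorted by descending magnitude
#' (the main-text convention). "More than `threshold`" is read on the
#' absolute value, since negative contributors are reported alongside
#' positive ones.
#'
#' @param model fitted [fit_scca()] model.
#' @param threshold absolute-weight reporting cutoff; 0 returns every
#'   variable in the selected tables too.
#' @return list with `full` (data frame: `variable`, `block`, one
#'   `weight_modeK` column per mode) and `selected` (list of per-mode data
#'   frames: `variable`, `block`, `weight`).
#' @export
weight_table <- function(model, threshold = 0.2) {
  stopifnot(inherits(model, "scca_model"))
  K <- model$n_modes
  U <- vapply(model$modes, function(m) m$u,
              numeric(length(model$variable_names1)))
  V <- vapply(model$modes, function(m) m$v,
              numeric(length(model$variable_names2)))
  U <- matrix(U, ncol = K); V <- matrix(V, ncol = K)
  full <- data.frame(
    variable = c(model$variable_names1, model$variable_names2),
    block = rep(c("block1", "block2"),
                c(length(model$variable_names1),
                  length(model$variable_names2))),
    rbind(U, V), stringsAsFactors = FALSE)
  names(full)[-(1:2)] <- paste0("weight_mode", seq_len(K))
  selected <- lapply(seq_len(K), function(k) {
    w <- c(U[, k], V[, k])
    sel <- if (threshold <= 0) rep(TRUE, length(w)) else abs(w) > threshold
    df <- data.frame(variable = full$variable[sel],
                     block = full$block[sel], weight = w[sel],
                     stringsAsFactors = FALSE)
    df[order(-abs(df$weight)), , drop = FALSE]
  })
  names(selected) <- paste0("mode", seq_len(K))
  list(full = full, selected = selected)
}
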