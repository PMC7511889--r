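#' Construct a data block
#'
#' A data block is a participants x variables numeric matrix with ordered
#' variable names and participant identifiers, plus a record of the
#' preparation state (`"raw"`, `"standardized"`, or
#' `"residualized+standardized"`). Two blocks entering the sparse CCA must
#' share identical participant identifiers in identical order.
#'
#' @param x numeric matrix or data frame, participants in rows.
#' @param variable_names character vector of column labels; defaults to the
#'   column names of `x`.
#' @param participant_ids character vector of row identifiers; defaults to
#'   the row names of `x`, or `p1..pn` when absent.
#' @param state preparation state of the matrix.
#' @return an object of class `data_block`.
#' @export
data_block <- function(x, variable_names = colnames(x),
                       participant_ids = rownames(x),
                       state = c("raw", "standardized",
                                 "residualized+standardized")) {
  state <- match.arg(state)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(variable_names))
    variable_names <- paste0("v", seq_len(ncol(x)))
  if (is.null(participant_ids))
    participant_ids <- paste0("p", seq_len(nrow(x)))
  if (length(variable_names) != ncol(x))
    stop("variable_names length does not match the number of columns")
  if (length(participant_ids) != nrow(x))
    stop("participant_ids length does not match the number of rows")
  if (anyDuplicated(variable_names))
    stop("duplicated variable names")
  if (anyDuplicated(participant_ids))
    stop("duplicated participant ids")
  if (state != "raw") {
    if (anyNA(x)) stop("prepared block contains missing values")
    mu <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    if (any(abs(mu) > 1e-8) || any(abs(sdv - 1) > 1e-8))
      stop("block declared '", state,
           "' but columns are not mean-0 / SD-1 within 1e-8")
  }
  dimnames(x) <- list(participant_ids, variable_names)
  structure(list(matrix = x, variable_names = variable_names,
                 participant_ids = participant_ids, state = state),
            class = "data_block")
}

#' @export
print.data_block <- function(x, ...) {
  cat(sprintf("data_block: %d participants x %d variables [%s]\n",
              nrow(x$matrix), ncol(x$matrix), x$state))
  invisible(x)
}

#' @export
dim.data_block <- function(x) dim(x$matrix)

as_block_matrix <- function(block) {
  if (inherits(block, "data_block")) return(block$matrix)
  x <- as.matrix(block)
  storage.mode(x) <- "double"
  x
}

## Residualize columns of y on covariates + intercept.  With
## allow_collinear = TRUE an exactly collinear covariate set is handled by
## the Moore-Penrose pseudoinverse (with a warning) instead of aborting.
residualize_columns <- function(y, covariates, allow_collinear = FALSE) {
  cmat <- as.matrix(covariates)
  storage.mode(cmat) <- "double"
  if (anyNA(cmat)) {
    bad <- rownames(cmat)[apply(is.na(cmat), 1, any)]
    if (is.null(bad)) bad <- which(apply(is.na(cmat), 1, any))
    stop("missing covariate values for participants: ",
         paste(bad, collapse = ", "))
  }
  if (nrow(cmat) != nrow(y))
    stop("covariate rows (", nrow(cmat),
         ") do not match participants (", nrow(y), ")")
  design <- cbind(`(Intercept)` = 1, cmat)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    if (!allow_collinear)
      stop("rank-deficient covariate design (rank ", qrd$rank,
           " < ", ncol(design), " columns)")
    warning("collinear covariates; residualizing with a pseudoinverse")
    beta <- MASS::ginv(design) %*% y
    return(y - design %*% beta)
  }
  y - design %*% qr.coef(qrd, y)
}

#' Prepare a data block for sparse CCA
#'
#' Optionally residualizes every column on a covariate table (ordinary
#' least squares with intercept), then z-scores every column (sample SD,
#' n-1 denominator). Constant columns abort with the offending variable
#' name, since a z-score is undefined for them.
#'
#' @param x numeric matrix or data frame, participants in rows.
#' @param variable_names,participant_ids see [data_block()].
#' @param covariates optional numeric matrix/data frame of covariates,
#'   rows aligned with `x`.
#' @return a standardized `data_block`.
#' @examples
#' b <- prepare_block(matrix(rnorm(60), 20, 3))
#' colMeans(b$matrix)  # ~0
#' @export
prepare_block <- function(x, variable_names = colnames(x),
                          participant_ids = rownames(x), covariates = NULL) {
  raw <- data_block(x, variable_names, participant_ids, state = "raw")
  y <- raw$matrix
  if (anyNA(y)) stop("block contains missing values; impute or drop first")
  sdv <- apply(y, 2, stats::sd)
  if (any(sdv == 0))
    stop("constant column(s): ",
         paste(raw$variable_names[sdv == 0], collapse = ", "))
  state <- "standardized"
  if (!is.null(covariates)) {
    y <- residualize_columns(y, covariates, allow_collinear = FALSE)
    state <- "residualized+standardized"
  }
  mu <- colMeans(y)
  y <- sweep(y, 2, mu, "-")
  sdv <- sqrt(colSums(y^2) / (nrow(y) - 1))
  if (any(sdv < 1e-12))
    stop("constant column(s) after preparation: ",
         paste(raw$variable_names[sdv < 1e-12], collapse = ", "))
  y <- sweep(y, 2, sdv, "/")
  data_block(y, raw$variable_names, raw$participant_ids, state = state)
}

check_aligned <- function(block1, block2) {
  if (!identical(block1$participant_ids, block2$participant_ids)) {
    d1 <- setdiff(block1$participant_ids, block2$participant_ids)
    d2 <- setdiff(block2$participant_ids, block1$participant_ids)
    if (length(d1) || length(d2))
      stop("participant sets differ; only in block 1: ",
           paste(d1, collapse = ", "), "; only in block 2: ",
           paste(d2, collapse = ", "))
    stop("participants are ordered differently in the two blocks")
  }
  invisible(TRUE)
}

# a subset of a standardized block is no longer exactly standardized,
# hence state "raw"
subset_block <- function(block, idx) {
  data_block(block$matrix[idx, , drop = FALSE], block$variable_names,
             block$participant_ids[idx], state = "raw")
}
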