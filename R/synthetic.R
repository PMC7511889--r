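## Synthetic study generator: two participant-aligned blocks with planted
## sparse cross-block latent modes, a covariate table, and raw
## likelihood-rating task responses. Defaults reproduce the study shape
## the pipeline is designed for: 47 participants, a 24-variable
## behavioral/questionnaire block, and 62 regional mean cortical
## thickness values (DKT parcellation).

#' The 62 DKT cortical region labels
#'
#' @return character vector of 62 region names (31 per hemisphere,
#'   Desikan-Killiany-Tourville parcellation).
#' @export
dkt_regions <- function() {
  readLines(system.file("extdata", "dkt62_regions.txt",
                        package = "braincca"))
}

#' Names of the 24 default non-imaging variables
#'
#' Eight task-derived bias measures plus sixteen questionnaire scale
#' scores (comparative optimism, trait optimism/pessimism, behavioral
#' inhibition/activation, emotion regulation, affect, self-esteem and the
#' Big Five).
#'
#' @return character vector of length 24.
#' @export
nonimaging_variables <- function() {
  c(paste0("task_", BIAS_PROFILE_COLUMNS), questionnaire_variables())
}

questionnaire_variables <- function() {
  c("cos_optimism", "cos_pessimism", "lot_optimism", "lot_pessimism",
    "bis_total", "bas_total", "erq_reappraisal", "erq_suppression",
    "panas_positive", "panas_negative", "rses_total",
    "bfi_extraversion", "bfi_agreeableness", "bfi_conscientiousness",
    "bfi_neuroticism", "bfi_openness")
}

#' Describe one planted cross-block mode
#'
#' @param u,v loading vectors over the two blocks (normalized internally
#'   to unit L2; zeros define the sparse support).
#' @param latent_correlation correlation in `[0, 1]` between the two
#'   blocks' latent factors for this mode.
#' @param strength1,strength2 factor loadings scaling the latent signal
#'   into each block, in noise-SD units.
#' @return a `planted_mode` list.
#' @export
planted_mode <- function(u, v, latent_correlation = 0.7,
                         strength1 = 1, strength2 = 1) {
  if (latent_correlation < 0 || latent_correlation > 1)
    stop("latent_correlation must lie in [0, 1]")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("planted loadings must be nonzero")
  structure(list(u = u / nu, v = v / nv,
                 latent_correlation = latent_correlation,
                 strength1 = strength1, strength2 = strength2),
            class = "planted_mode")
}

#' Sparse unit-norm loading vector
#'
#' @param p vector length.
#' @param support indices of the nonzero entries.
#' @param values nonzero values (recycled); normalized to unit L2.
#' @return numeric vector of length `p`.
#' @export
sparse_loading <- function(p, support, values = 1) {
  u <- numeric(p)
  u[support] <- values
  u / sqrt(sum(u^2))
}

#' Synthetic study specification
#'
#' Collects every knob of the generator. Defaults mirror the target study
#' shape: 47 participants, 24 non-imaging variables, 62 thickness
#' regions, one planted sparse mode (3 of 24 and 4 of 62 nonzero
#' loadings, latent correlation 0.7) and unit noise. Task parameters
#' place the per-character mean ratings so the group-level optimism
#' biases are similarly positive for the student and elderly characters,
#' smaller for the businessperson and negative for the alcoholic
#' character.
#'
#' @param n_participants,n_nonimaging,n_regions dimensions.
#' @param planted_modes list of [planted_mode()]s; `NULL` plants the
#'   default single mode, `list()` plants none (null model).
#' @param noise_sd length-2 noise SD, one per block.
#' @param covariate_effects optional list with entries among `age`, `sex`,
#'   `height`, `weight`, `bmi`: length-`n_regions` loading vectors added
#'   to the thickness block (per SD of the covariate).
#' @param task_params list: `character_means` (4 x 2 matrix of desirable/
#'   undesirable mean ratings, rows student, elderly, business,
#'   alcoholic), `participant_sd`, `noise_sd`, `missing_fraction`,
#'   `degenerate_fraction` (share of all-50 responders planted to
#'   exercise cleaning).
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_participants = 47L, n_nonimaging = 24L,
                           n_regions = 62L, planted_modes = NULL,
                           noise_sd = c(1, 1), covariate_effects = NULL,
                           task_params = NULL) {
  if (is.null(planted_modes)) {
    # graded loadings: real latent effects are not exactly equal across
    # their supporting variables
    planted_modes <- list(planted_mode(
      u = sparse_loading(n_nonimaging, n_nonimaging - c(2L, 1L, 0L),
                         c(1, 0.8, 0.6)),
      v = sparse_loading(n_regions, seq_len(4L), c(1, 0.85, 0.7, 0.55)),
      latent_correlation = 0.7))
  }
  for (pm in planted_modes) {
    if (!inherits(pm, "planted_mode")) stop("planted_modes entries must be planted_mode objects")
    if (length(pm$u) != n_nonimaging || length(pm$v) != n_regions)
      stop("planted loading lengths do not match the block dimensions")
  }
  if (length(planted_modes) > min(n_nonimaging, n_regions))
    stop("more planted modes than min(p1, p2)")
  defaults <- list(
    character_means = matrix(c(68, 38, 67, 39, 58, 48, 44, 58),
                             nrow = 4, byrow = TRUE,
                             dimnames = list(TASK_CHARACTERS,
                                             c("desirable", "undesirable"))),
    participant_sd = 8, noise_sd = 12,
    missing_fraction = 0.01, degenerate_fraction = 0)
  if (!is.null(task_params)) defaults[names(task_params)] <- task_params
  structure(list(n_participants = as.integer(n_participants),
                 n_nonimaging = as.integer(n_nonimaging),
                 n_regions = as.integer(n_regions),
                 planted_modes = planted_modes,
                 noise_sd = rep(noise_sd, length.out = 2),
                 covariate_effects = covariate_effects,
                 task_params = defaults),
            class = "synthetic_spec")
}

#' Generate the two analysis blocks, covariates and ground truth
#'
#' Draws, per planted mode k, a standard-normal latent factor pair
#' `(z_k, z'_k)` with the configured correlation, builds
#' `block1 = sum_k a_k z_k u_k' + noise` and
#' `block2 = sum_k b_k z'_k v_k' + noise`, optionally adds covariate
#' effects to the thickness block, and maps thickness columns affinely
#' onto a plausible cortical-thickness scale (means about 2.0-3.3 mm, SD
#' 0.12 mm) with DKT region labels. The returned truth record contains
#' everything needed to score loading recovery, support precision/recall
#' and latent-correlation recovery.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; the output is bit-reproducible given the
#'   seed.
#' @return list with raw `nonimaging` and `thickness` [data_block()]s,
#'   a `covariates` data frame (age, sex, height, weight, bmi) and
#'   `truth` (loading matrices, latent correlations, strengths, factors).
#' @export
generate_blocks <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed)
  n <- spec$n_participants
  p1 <- spec$n_nonimaging
  p2 <- spec$n_regions
  K <- length(spec$planted_modes)
  X1 <- matrix(stats::rnorm(n * p1, sd = spec$noise_sd[1]), n, p1)
  X2 <- matrix(stats::rnorm(n * p2, sd = spec$noise_sd[2]), n, p2)
  Zl <- matrix(0, n, max(K, 1))
  Zl2 <- matrix(0, n, max(K, 1))
  for (k in seq_len(K)) {
    pm <- spec$planted_modes[[k]]
    z <- stats::rnorm(n)
    rho <- pm$latent_correlation
    z2 <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
    Zl[, k] <- z; Zl2[, k] <- z2
    X1 <- X1 + pm$strength1 * tcrossprod(z, pm$u)
    X2 <- X2 + pm$strength2 * tcrossprod(z2, pm$v)
  }

  ids <- sprintf("sub%03d", seq_len(n))
  sex <- stats::rbinom(n, 1, 0.4) # 1 = male
  age <- round(pmin(pmax(stats::rnorm(n, 23.1, 4.0), 19), 36), 1)
  height <- round(stats::rnorm(n, 165 + 13 * sex, 6), 1)
  weight <- round(stats::rnorm(n, 60 + 12 * sex, 7), 1)
  covariates <- data.frame(participant_id = ids, age = age, sex = sex,
                           height = height, weight = weight,
                           bmi = round(weight / (height / 100)^2, 2),
                           stringsAsFactors = FALSE)
  if (!is.null(spec$covariate_effects)) {
    for (nm in names(spec$covariate_effects)) {
      cv <- covariates[[nm]]
      if (is.null(cv)) stop("unknown covariate effect: ", nm)
      beta <- spec$covariate_effects[[nm]]
      if (length(beta) != p2)
        stop("covariate effect '", nm, "' must have length ", p2)
      X2 <- X2 + tcrossprod(drop(scale(cv)), beta)
    }
  }

  # affine map onto a plausible mm scale; strictly monotone per column, so
  # standardization recovers the planted structure exactly
  region_mu <- stats::runif(p2, 2.0, 3.3)
  X2 <- sweep(sweep(X2, 2, 0.12, "*"), 2, region_mu, "+")

  vn1 <- if (p1 == 24L) nonimaging_variables() else paste0("ni", seq_len(p1))
  vn2 <- if (p2 == 62L) dkt_regions() else paste0("region", seq_len(p2))
  truth <- list(
    u = vapply(spec$planted_modes, `[[`, numeric(p1), "u"),
    v = vapply(spec$planted_modes, `[[`, numeric(p2), "v"),
    latent_correlation = vapply(spec$planted_modes, `[[`, numeric(1),
                                "latent_correlation"),
    strength1 = vapply(spec$planted_modes, `[[`, numeric(1), "strength1"),
    strength2 = vapply(spec$planted_modes, `[[`, numeric(1), "strength2"),
    z1 = Zl[, seq_len(K), drop = FALSE],
    z2 = Zl2[, seq_len(K), drop = FALSE],
    noise_sd = spec$noise_sd, seed = seed)
  list(nonimaging = data_block(X1, vn1, ids),
       thickness = data_block(X2, vn2, ids),
       covariates = covariates, truth = truth)
}

#' Generate raw task responses
#'
#' Builds 128 trials per participant (4 characters x 32 events, 16
#' desirable and 16 undesirable): rating = character/valence mean +
#' participant effect + noise, clipped to the 0-100 analog scale.
#' Configurable fractions of unanswered trials and of degenerate all-50
#' responders exercise the cleaning rules.
#'
#' @param spec a [synthetic_spec()] (only `n_participants` and
#'   `task_params` are used).
#' @param seed integer seed.
#' @param participant_effects optional length-`n` numeric vector of
#'   participant rating shifts (defaults to draws with SD
#'   `task_params$participant_sd`).
#' @return long-format task-table data frame.
#' @export
generate_task_responses <- function(spec, seed = 1L,
                                    participant_effects = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(seed + 1000003L) # distinct stream from generate_blocks
  tp <- spec$task_params
  n <- spec$n_participants
  ids <- sprintf("sub%03d", seq_len(n))
  if (is.null(participant_effects))
    participant_effects <- stats::rnorm(n, 0, tp$participant_sd)
  grid <- expand.grid(event_id = seq_len(32L),
                      character = TASK_CHARACTERS,
                      stringsAsFactors = FALSE)
  grid$valence <- ifelse(grid$event_id <= 16L, "desirable", "undesirable")
  out <- do.call(rbind, lapply(seq_len(n), function(i) {
    mu <- tp$character_means[cbind(grid$character, grid$valence)]
    lk <- mu + participant_effects[i] + stats::rnorm(nrow(grid), 0,
                                                     tp$noise_sd)
    lk <- pmin(pmax(lk, 0), 100)
    data.frame(participant_id = ids[i], character = grid$character,
               event_id = grid$event_id, valence = grid$valence,
               likelihood = lk, stringsAsFactors = FALSE)
  }))
  n_degen <- round(tp$degenerate_fraction * n)
  if (n_degen > 0) {
    degen <- sample(ids, n_degen)
    out$likelihood[out$participant_id %in% degen] <- 50
  }
  if (tp$missing_fraction > 0) {
    miss <- stats::runif(nrow(out)) < tp$missing_fraction
    out$likelihood[miss] <- NA_real_
  }
  rownames(out) <- NULL
  out
}

#' Write a complete synthetic study to disk
#'
#' Emits the four pipeline inputs (task responses, questionnaire scores,
#' thickness table, covariates) as CSV plus the ground truth as JSON.
#' The questionnaire CSV carries the 16 scale scores (the planted block-1
#' loadings live on these variables in the default spec: the 8
#' task-derived measures are recomputed from the raw ratings by the
#' scores stage, so a planted loading cannot be routed through them
#' exactly).
#'
#' @param spec a [synthetic_spec()] with 24 non-imaging variables.
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return invisibly, the named list of file paths.
#' @export
simulate_study <- function(spec = synthetic_spec(), dir, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_nonimaging != 24L)
    stop("simulate_study expects the 24-variable non-imaging layout")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  blocks <- generate_blocks(spec, seed = seed)
  task <- generate_task_responses(spec, seed = seed)
  quest <- data.frame(participant_id = blocks$nonimaging$participant_ids,
                      blocks$nonimaging$matrix[, 9:24, drop = FALSE],
                      stringsAsFactors = FALSE, row.names = NULL)
  thick <- data.frame(participant_id = blocks$thickness$participant_ids,
                      blocks$thickness$matrix,
                      stringsAsFactors = FALSE, row.names = NULL)
  paths <- list(task = file.path(dir, "task_responses.csv"),
                questionnaire = file.path(dir, "questionnaire.csv"),
                thickness = file.path(dir, "thickness.csv"),
                covariates = file.path(dir, "covariates.csv"),
                truth = file.path(dir, "truth.json"))
  utils::write.csv(task, paths$task, row.names = FALSE, na = "")
  utils::write.csv(quest, paths$questionnaire, row.names = FALSE)
  utils::write.csv(thick, paths$thickness, row.names = FALSE)
  utils::write.csv(blocks$covariates, paths$covariates, row.names = FALSE)
  truth <- blocks$truth
  truth$z1 <- NULL; truth$z2 <- NULL
  jsonlite::write_json(truth, paths$truth, digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
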