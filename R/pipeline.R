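## Pipeline orchestration and shared tabular I/O. The package is a
## library: the configuration object plus run_pipeline() are the single
## entry point that chains scores -> prepare -> fit -> permute ->
## reliability -> posthoc -> report and writes a JSON manifest.

#' Read a participants x variables table
#'
#' CSV or TSV (sniffed from the header line) with the first column
#' `participant_id` and one header-named numeric column per variable.
#'
#' @param path file path.
#' @return data frame with `participant_id` first.
#' @export
read_block_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  if (names(df)[1] != "participant_id")
    stop("first column of ", path, " must be participant_id")
  df$participant_id <- as.character(df$participant_id)
  df
}

#' Pipeline configuration
#'
#' Collects input paths (or in-memory data frames) and every analysis
#' setting with the study's default values: 10 fitted modes, 7 tested
#' modes, 10000 permutations and split-half resamples, alpha 0.05, post
#' hoc p threshold 0.001, reporting weight threshold 0.2.
#'
#' @param task,questionnaire,thickness file paths or data frames (task in
#'   long format, the others participants x variables with a
#'   `participant_id` column).
#' @param covariates optional path or data frame (used by the post hoc
#'   stage; when absent that stage is skipped).
#' @param penalties optional `c(c1, c2)`; `NULL` tunes them with
#'   [select_penalties()].
#' @param n_modes,n_modes_tested,n_perm,n_resamples,alpha,posthoc_p,weight_threshold
#'   analysis settings (see Details above for defaults).
#' @param seed integer master seed for every random stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(task, questionnaire, thickness,
                            covariates = NULL, penalties = NULL,
                            n_modes = 10L, n_modes_tested = 7L,
                            n_perm = 10000L, n_resamples = 10000L,
                            alpha = 0.05, posthoc_p = 0.001,
                            weight_threshold = 0.2, seed = 1L) {
  counts <- c(n_modes = n_modes, n_modes_tested = n_modes_tested,
              n_perm = n_perm, n_resamples = n_resamples)
  if (any(counts < 1)) stop("all counts must be positive")
  if (n_modes_tested > n_modes)
    stop("n_modes_tested cannot exceed n_modes")
  for (thr in c(alpha = alpha, posthoc_p = posthoc_p)) {
    if (thr <= 0 || thr >= 1) stop("thresholds must lie in (0, 1)")
  }
  structure(list(task = task, questionnaire = questionnaire,
                 thickness = thickness, covariates = covariates,
                 penalties = penalties, n_modes = as.integer(n_modes),
                 n_modes_tested = as.integer(n_modes_tested),
                 n_perm = as.integer(n_perm),
                 n_resamples = as.integer(n_resamples), alpha = alpha,
                 posthoc_p = posthoc_p,
                 weight_threshold = weight_threshold,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Every key of [pipeline_config()] may appear in the file; arguments
#' passed through `...` override their YAML counterparts.
#'
#' @param path YAML file path.
#' @param ... overrides, as in [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  conf <- yaml::read_yaml(path)
  over <- list(...)
  conf[names(over)] <- over
  do.call(pipeline_config, conf)
}

load_table <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: task scoring and cleaning; block
#' preparation (standardization); penalty selection when not fixed;
#' sparse CCA fit of `n_modes` modes; truncation to `n_modes_tested`
#' leading modes; permutation significance; split-half reliability with
#' RR-scores and leave-one-out influence; covariate-adjusted post hoc
#' correlations (when covariates are given); weight tables. All outputs
#' are written under `out_dir` together with a JSON manifest recording
#' the configuration, seed and output paths. Given identical
#' configuration and seed the outputs are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (config$n_perm < 99)
    warning("n_perm = ", config$n_perm,
            " gives coarse p-value resolution; 99 or more is recommended")

  task <- validate_task_table(load_table(config$task, read_task_table))
  quest <- load_table(config$questionnaire, read_block_table)
  thick <- load_table(config$thickness, read_block_table)
  covar <- if (!is.null(config$covariates))
    load_table(config$covariates, read_block_table) else NULL

  # stage 1: scores
  cleaned <- clean_task_table(task)
  prof <- bias_profiles(cleaned$table)

  # participant alignment across all inputs
  ids <- Reduce(intersect, list(prof$participant_id,
                                quest$participant_id,
                                thick$participant_id))
  all_ids <- unique(c(prof$participant_id, quest$participant_id,
                      thick$participant_id))
  if (length(ids) < 3)
    stop("fewer than 3 participants shared across inputs; misaligned: ",
         paste(setdiff(all_ids, ids), collapse = ", "))
  ids <- sort(ids)
  prof <- prof[match(ids, prof$participant_id), , drop = FALSE]
  quest <- quest[match(ids, quest$participant_id), , drop = FALSE]
  thick <- thick[match(ids, thick$participant_id), , drop = FALSE]
  if (!is.null(covar)) {
    missing_cov <- setdiff(ids, covar$participant_id)
    if (length(missing_cov))
      stop("covariates missing for participants: ",
           paste(missing_cov, collapse = ", "))
    covar <- covar[match(ids, covar$participant_id), , drop = FALSE]
  }

  nonimg <- cbind(stats::setNames(prof[-1],
                                  paste0("task_", names(prof)[-1])),
                  quest[-1])
  rownames(nonimg) <- ids
  thick_m <- as.matrix(thick[-1])
  rownames(thick_m) <- ids

  # stage 2: prepare
  block1 <- prepare_block(nonimg)
  block2 <- prepare_block(thick_m)

  # stage 3: penalties + fit
  if (is.null(config$penalties)) {
    sel <- select_penalties(block1, block2, seed = config$seed)
    penalties <- c(sel$c1, sel$c2)
  } else {
    penalties <- as.numeric(config$penalties)
  }
  model <- fit_scca(block1, block2, c1 = penalties[1], c2 = penalties[2],
                    n_modes = config$n_modes, seed = config$seed)
  cumshare <- cumsum(variance_explained(model))

  # stage 4: permutation inference on the tested leading modes
  perm <- permutation_test(block1, block2, c1 = penalties[1],
                           c2 = penalties[2],
                           n_modes_tested = config$n_modes_tested,
                           n_perm = config$n_perm, alpha = config$alpha,
                           seed = config$seed)

  # stage 5: reliability
  reli <- split_half(block1, block2, c1 = penalties[1], c2 = penalties[2],
                     n_modes = config$n_modes_tested,
                     n_resamples = config$n_resamples,
                     seed = config$seed)
  loo <- leave_one_out(block1, block2, c1 = penalties[1],
                       c2 = penalties[2],
                       n_modes = config$n_modes_tested)

  # stage 6: post hoc covariate-adjusted correlations
  posthoc <- NULL
  if (!is.null(covar)) {
    cov_m <- as.matrix(covar[setdiff(names(covar), "participant_id")])
    posthoc <- posthoc_correlations(block1, block2, cov_m,
                                    p_threshold = config$posthoc_p)
  }

  # stage 7: report
  wt <- weight_table(model, threshold = config$weight_threshold)

  paths <- list()
  wr <- function(obj, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(obj, p, row.names = FALSE)
    paths[[name]] <<- p
    p
  }
  wr(prof, "bias_profiles.csv")
  wr(wt$full, "weights_full.csv")
  for (k in seq_along(wt$selected))
    wr(wt$selected[[k]], sprintf("weights_mode%d_selected.csv", k))
  wr(as.data.frame(perm), "permutation.csv")
  wr(loo, "leave_one_out.csv")
  if (!is.null(posthoc)) wr(posthoc, "posthoc.csv")
  reli_json <- list(n_resamples = reli$n_resamples, seed = reli$seed,
                    redraws = reli$redraws,
                    mean_train_r = colMeans(reli$train_r, na.rm = TRUE),
                    mean_test_r = colMeans(reli$splithalf_r, na.rm = TRUE),
                    overfit_index = reli$overfit_index,
                    rr_mean = reli$rr_mean, rr_sd = reli$rr_sd)
  p <- file.path(out_dir, "reliability.json")
  jsonlite::write_json(reli_json, p, digits = NA, auto_unbox = TRUE)
  paths[["reliability.json"]] <- p
  p <- file.path(out_dir, "cleaning_report.json")
  jsonlite::write_json(list(
    excluded_participants = cleaned$report$excluded_participants,
    excluded_trial_fraction = cleaned$report$excluded_trial_fraction),
    p, digits = NA, auto_unbox = TRUE)
  paths[["cleaning_report.json"]] <- p

  model_json <- list(
    penalties = stats::setNames(as.numeric(penalties), c("c1", "c2")),
    n_modes = model$n_modes,
    canonical_correlations = model$canonical_correlations,
    variance_explained_share = model$variance_explained_share,
    cumulative_share = cumshare,
    modes = lapply(model$modes, function(m) list(
      index = m$index, d = m$d,
      canonical_correlation = m$canonical_correlation,
      u = as.list(stats::setNames(m$u, model$variable_names1)),
      v = as.list(stats::setNames(m$v, model$variable_names2)))))
  p <- file.path(out_dir, "model.json")
  jsonlite::write_json(model_json, p, digits = NA, auto_unbox = TRUE)
  paths[["model.json"]] <- p

  manifest <- list(
    package_version = as.character(utils::packageVersion("braincca")),
    seed = config$seed,
    n_participants = length(ids),
    config = list(n_modes = config$n_modes,
                  n_modes_tested = config$n_modes_tested,
                  n_perm = config$n_perm,
                  n_resamples = config$n_resamples,
                  alpha = config$alpha, posthoc_p = config$posthoc_p,
                  weight_threshold = config$weight_threshold,
                  penalties = as.numeric(penalties)),
    outputs = paths)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}
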