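## Social-optimism-bias task scoring: clean raw likelihood ratings and
## derive the eight per-participant task measures.

TASK_CHARACTERS <- c("student", "elderly", "business", "alcoholic")
WARM_CHARACTERS <- c("student", "elderly")

BIAS_PROFILE_COLUMNS <- c("desirable_avg", "undesirable_avg",
                          "bias_student", "bias_elderly", "bias_business",
                          "bias_alcoholic", "warmth_bias", "bias_magnitude")

validate_task_table <- function(task) {
  need <- c("participant_id", "character", "event_id", "valence",
            "likelihood")
  miss <- setdiff(need, names(task))
  if (length(miss))
    stop("task table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(task) == 0) stop("task table is empty")
  task$participant_id <- as.character(task$participant_id)
  task$character <- as.character(task$character)
  task$valence <- as.character(task$valence)
  bad_char <- setdiff(unique(task$character), TASK_CHARACTERS)
  if (length(bad_char))
    stop("unknown character(s): ", paste(bad_char, collapse = ", "))
  bad_val <- setdiff(unique(task$valence), c("desirable", "undesirable"))
  if (length(bad_val))
    stop("unknown valence label(s): ", paste(bad_val, collapse = ", "))
  lk <- task$likelihood
  if (any(!is.na(lk) & (lk < 0 | lk > 100)))
    stop("likelihood ratings outside [0, 100]")
  task
}

#' Read a long-format task-response table
#'
#' Expects header columns `participant_id`, `character` (student, elderly,
#' business, alcoholic), `event_id`, `valence` (desirable, undesirable)
#' and `likelihood` (0-100 visual-analog rating; empty field = no answer).
#' Comma or tab separation is sniffed from the first line.
#'
#' @param path file path.
#' @return validated task-table data frame.
#' @export
read_task_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  task <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE,
                            na.strings = c("", "NA"))
  validate_task_table(task)
}

#' Clean a task-response table
#'
#' Applies the two cleaning rules for the likelihood-rating task:
#' participants who lean on the scale's anchor/default values are
#' excluded, and unanswered trials are dropped. A rating is flagged when
#' it rounds to 1, 50 or 99 (extreme or default answers on the 0-100
#' analog scale); by default the three flag values are pooled into one
#' per-participant proportion (over that participant's answered trials),
#' and participants whose proportion exceeds the sample mean plus
#' `z_threshold` standard deviations are removed. `pooled = FALSE` applies
#' the rule separately per flag value and excludes the union.
#'
#' @param raw task-table data frame (see [read_task_table()]).
#' @param z_threshold positive SD multiplier of the exclusion rule.
#' @param flag_values integer rating values counted as flags.
#' @param pooled pool flag values into one proportion (default) or apply
#'   one rule per value.
#' @return list with `table` (cleaned task table) and `report` (class
#'   `cleaning_report`: excluded participants with the rule that fired,
#'   the fraction of trials dropped as missing, and per-participant flag
#'   proportions).
#' @export
clean_task_table <- function(raw, z_threshold = 3,
                             flag_values = c(1, 50, 99), pooled = TRUE) {
  raw <- validate_task_table(raw)
  if (z_threshold <= 0) stop("z_threshold must be positive")
  answered <- raw[!is.na(raw$likelihood), , drop = FALSE]
  ids <- sort(unique(raw$participant_id))
  rounded <- round(answered$likelihood)
  prop_of <- function(vals) {
    fl <- tapply(rounded %in% vals, answered$participant_id, mean)
    out <- stats::setNames(rep(0, length(ids)), ids)
    out[names(fl)] <- as.numeric(fl)
    out
  }
  pooled_prop <- prop_of(flag_values)
  excluded <- character(0)
  rule <- character(0)
  apply_rule <- function(prop, label) {
    thr <- mean(prop) + z_threshold * stats::sd(prop)
    hits <- names(prop)[prop > thr & !is.na(prop)]
    if (length(hits)) {
      excluded <<- c(excluded, hits)
      rule <<- c(rule, rep(label, length(hits)))
    }
  }
  if (pooled) {
    apply_rule(pooled_prop, sprintf("pooled{%s} > mean + %g SD",
                                    paste(flag_values, collapse = ","),
                                    z_threshold))
  } else {
    for (v in flag_values)
      apply_rule(prop_of(v), sprintf("value %g > mean + %g SD",
                                     v, z_threshold))
  }
  keep_ids <- setdiff(ids, excluded)
  if (length(keep_ids) < 3)
    stop("fewer than 3 participants remain after exclusion (",
         length(keep_ids), "); check the data or the threshold")
  cleaned <- answered[answered$participant_id %in% keep_ids, , drop = FALSE]
  rownames(cleaned) <- NULL
  n_missing <- sum(is.na(raw$likelihood[raw$participant_id %in% keep_ids]))
  n_raw_kept <- sum(raw$participant_id %in% keep_ids)
  report <- structure(list(
    excluded_participants = data.frame(
      participant_id = unique(excluded),
      rule = rule[!duplicated(excluded)],
      stringsAsFactors = FALSE),
    excluded_trial_fraction = if (n_raw_kept > 0) n_missing / n_raw_kept
                              else 0,
    flag_proportions = data.frame(participant_id = ids,
                                  flag_proportion = as.numeric(pooled_prop),
                                  stringsAsFactors = FALSE)),
    class = "cleaning_report")
  list(table = cleaned, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("Cleaning: %d participant(s) excluded; %.2f%% of trials dropped as unanswered\n",
              nrow(x$excluded_participants),
              100 * x$excluded_trial_fraction))
  if (nrow(x$excluded_participants))
    print(x$excluded_participants, row.names = FALSE)
  invisible(x)
}

#' Eight task measures for one participant
#'
#' Computes the task's bias profile: raw-scale mean likelihoods for
#' desirable and undesirable events (across all characters); one optimism
#' bias per character, defined on ratings z-standardized across all of the
#' participant's answered trials (sample SD) as mean(desirable z) minus
#' mean(undesirable z); the warmth bias (student + elderly biases minus
#' businessperson + alcoholic biases); and the overall bias magnitude
#' (student + elderly + businessperson biases plus the inverted alcoholic
#' bias, the alcoholic bias typically being a pessimism bias).
#'
#' @param cleaned cleaned task table (see [clean_task_table()]).
#' @param participant participant identifier.
#' @return named numeric vector with elements `desirable_avg`,
#'   `undesirable_avg`, `bias_student`, `bias_elderly`, `bias_business`,
#'   `bias_alcoholic`, `warmth_bias`, `bias_magnitude`.
#' @export
compute_bias_profile <- function(cleaned, participant) {
  cleaned <- validate_task_table(cleaned)
  rows <- cleaned[cleaned$participant_id == as.character(participant) &
                    !is.na(cleaned$likelihood), , drop = FALSE]
  if (nrow(rows) == 0) stop("no trials for participant ", participant)
  for (ch in TASK_CHARACTERS) {
    for (vl in c("desirable", "undesirable")) {
      if (!any(rows$character == ch & rows$valence == vl))
        stop("participant ", participant, " has no ", vl,
             " trials for character '", ch, "'")
    }
  }
  lk <- rows$likelihood
  s <- stats::sd(lk)
  if (s == 0)
    stop("participant ", participant,
         " has zero rating variance; z-scores are undefined")
  z <- (lk - mean(lk)) / s
  bias <- vapply(TASK_CHARACTERS, function(ch) {
    des <- rows$character == ch & rows$valence == "desirable"
    und <- rows$character == ch & rows$valence == "undesirable"
    mean(z[des]) - mean(z[und])
  }, numeric(1))
  out <- c(
    desirable_avg = mean(lk[rows$valence == "desirable"]),
    undesirable_avg = mean(lk[rows$valence == "undesirable"]),
    bias_student = unname(bias["student"]),
    bias_elderly = unname(bias["elderly"]),
    bias_business = unname(bias["business"]),
    bias_alcoholic = unname(bias["alcoholic"]),
    warmth_bias = unname(bias["student"] + bias["elderly"] -
                           bias["business"] - bias["alcoholic"]),
    bias_magnitude = unname(bias["student"] + bias["elderly"] +
                              bias["business"] - bias["alcoholic"]))
  out
}

#' Bias profiles for every participant
#'
#' @param cleaned cleaned task table.
#' @return data frame, one row per participant, with `participant_id` and
#'   the eight profile columns.
#' @export
bias_profiles <- function(cleaned) {
  ids <- sort(unique(as.character(cleaned$participant_id)))
  prof <- t(vapply(ids, function(id) compute_bias_profile(cleaned, id),
                   numeric(8)))
  out <- data.frame(participant_id = ids, prof, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out)[-1] <- BIAS_PROFILE_COLUMNS
  out
}
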