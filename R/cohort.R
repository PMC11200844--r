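# Cohort construction: CONSORT-style exclusions, analysis subsets, and
# burden labels (government screening indicator + expert panel majority).

psi_flag_cols <- paste0("psi_", 1:10)
expert_vote_cols <- paste0("expert_vote_", 1:3)

#' Apply CONSORT exclusion filters
#'
#' Two exclusions, assessed in order: (1) records lacking the values needed
#' to compute the burden score; (2) among the survivors, records where
#' either the caregiver or the care recipient is under 18.  A record
#' failing both is counted only under the first reason.
#'
#' @param records assessment record data.frame (see the package data
#'   dictionary); must carry the nine scoring-item columns plus
#'   `caregiver_age` and `recipient_age`.
#' @return object of class `consort_filter`: list with `included`
#'   (data.frame), `excluded_missing_score` and `excluded_under18` (counts).
#'   Counts plus included rows always sum to the input row count.
#' @export
apply_consort_filters <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  ex <- extract_items(records)
  has_score <- ex$complete
  # ages may be NA; treat unknown age as not demonstrably under 18
  under18 <- (!is.na(records$caregiver_age) & records$caregiver_age < 18) |
    (!is.na(records$recipient_age) & records$recipient_age < 18)
  keep <- has_score & !under18
  res <- list(
    included = records[keep, , drop = FALSE],
    excluded_missing_score = sum(!has_score),
    excluded_under18 = sum(has_score & under18)
  )
  class(res) <- "consort_filter"
  res
}

#' @export
print.consort_filter <- function(x, ...) {
  n_in <- nrow(x$included) + x$excluded_missing_score + x$excluded_under18
  cat("CONSORT filter report\n")
  cat(sprintf("  assessed:                 %d\n", n_in))
  cat(sprintf("  excluded, missing score:  %d\n", x$excluded_missing_score))
  cat(sprintf("  excluded, under 18:       %d\n", x$excluded_under18))
  cat(sprintf("  included:                 %d\n", nrow(x$included)))
  invisible(x)
}

#' Select the label-validation subset
#'
#' Records assessed on/after 2022-01-01 whose screening-indicator flags are
#' present (the indicator was only collected from 2022 on).
#'
#' @param records CONSORT-filtered record data.frame.
#' @return row subset of `records`.
#' @export
select_validation_subset <- function(records) {
  d <- as.Date(records$assessment_date)
  post2022 <- !is.na(d) & d >= as.Date("2022-01-01")
  has_psi <- rowSums(is.na(as.matrix(records[, psi_flag_cols, drop = FALSE]))) == 0
  records[post2022 & has_psi, , drop = FALSE]
}

#' Select the reassessed subset
#'
#' Records with a complete reassessment: a reassessment date plus a full
#' set of reassessment scoring items.
#'
#' @param records CONSORT-filtered record data.frame.
#' @return row subset of `records`.
#' @export
select_reassessed_subset <- function(records) {
  has_date <- !is.na(records$reassessment_date)
  ex <- extract_items(records, prefix = "reassess_")
  records[has_date & ex$complete, , drop = FALSE]
}

#' Expert-panel majority vote
#'
#' @param votes numeric/logical vector of exactly three 0/1 votes, or a
#'   3-column matrix/data.frame (one row per case).
#' @return binary label(s): 1 iff at least two votes are 1.
#' @export
expert_majority <- function(votes) {
  if (is.data.frame(votes)) votes <- as.matrix(votes)
  if (is.matrix(votes)) {
    if (ncol(votes) != 3) {
      stop("expert_majority: expected exactly 3 votes per case, got ",
           ncol(votes), call. = FALSE)
    }
    v <- votes
  } else {
    if (length(votes) != 3) {
      stop("expert_majority: expected exactly 3 votes, got ",
           length(votes), call. = FALSE)
    }
    v <- matrix(as.numeric(votes), nrow = 1)
  }
  if (any(is.na(v)) || !all(v %in% c(0, 1))) {
    stop("expert_majority: votes must be binary 0/1", call. = FALSE)
  }
  out <- as.integer(rowSums(v) >= 2)
  if (!is.matrix(votes)) out[1] else out
}

#' Screening-indicator (PSI) label
#'
#' The official positivity rule behind the ten-question government
#' screening indicator is not public, so the rule is configurable.  The
#' default flags a case when any indicator is positive (`k = 1`); `k`
#' raises the requirement to "at least k of 10 positive".
#'
#' @param indicators vector of exactly ten 0/1 flags, or a 10-column
#'   matrix/data.frame (one row per case).
#' @param k minimum number of positive flags for a positive label.
#' @return binary label(s).
#' @export
psi_label <- function(indicators, k = 1) {
  if (is.data.frame(indicators)) indicators <- as.matrix(indicators)
  vec_in <- !is.matrix(indicators)
  if (vec_in) {
    if (length(indicators) != 10) {
      stop("psi_label: expected exactly 10 indicator flags, got ",
           length(indicators), call. = FALSE)
    }
    indicators <- matrix(as.numeric(indicators), nrow = 1)
  } else if (ncol(indicators) != 10) {
    stop("psi_label: expected exactly 10 indicator flags per case, got ",
         ncol(indicators), call. = FALSE)
  }
  if (any(is.na(indicators)) || !all(indicators %in% c(0, 1))) {
    stop("psi_label: indicator flags must be binary 0/1", call. = FALSE)
  }
  stopifnot(k >= 1, k <= 10)
  out <- as.integer(rowSums(indicators) >= k)
  if (vec_in) out[1] else out
}

#' Combine expert and screening labels
#'
#' @param expert,psi equal-length binary label vectors.
#' @return data.frame with columns `expert_label`, `psi_label`,
#'   `union_label`, `intersection_label`.
#' @export
combine_labels <- function(expert, psi) {
  stopifnot(length(expert) == length(psi))
  expert <- as.integer(expert); psi <- as.integer(psi)
  if (!all(expert %in% c(0, 1)) || !all(psi %in% c(0, 1))) {
    stop("combine_labels: labels must be binary 0/1", call. = FALSE)
  }
  data.frame(
    expert_label = expert,
    psi_label = psi,
    union_label = as.integer(expert | psi),
    intersection_label = as.integer(expert & psi)
  )
}

#' Attach burden labels to a validation-subset table
#'
#' Derives the expert-majority and screening-indicator labels from their
#' vote/flag columns and appends all four label columns.
#'
#' @param records validation-subset data.frame carrying `psi_1..psi_10`
#'   and `expert_vote_1..expert_vote_3`.
#' @param psi_k positivity rule passed to [psi_label()].
#' @return `records` with label columns appended.
#' @export
attach_labels <- function(records, psi_k = 1) {
  ev <- as.matrix(records[, expert_vote_cols, drop = FALSE])
  pf <- as.matrix(records[, psi_flag_cols, drop = FALSE])
  lab <- combine_labels(expert_majority(ev), psi_label(pf, k = psi_k))
  cbind(records, lab)
}
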