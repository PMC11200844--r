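# Scoring rubric for the nine-item CSI-based caregiver burden score.
#
# Nine intake-assessment items are mapped onto Caregiver Strain Index
# concepts; two are six-level ordinals contributing 0..1 in 0.2 steps and
# seven are yes/no items contributing 0 or 1.  The total therefore lives on
# the grid {0.0, 0.2, ..., 9.0}.

#' Per-item scoring rubric
#'
#' A named list mapping each scoring item to its level-to-increment table.
#' Kept as one data constant (rather than logic spread through code) so the
#' rubric can be audited at a glance.
#'
#' @format Named list; each element is a named numeric vector mapping a
#'   category level to its score increment.
#' @export
score_rubric <- list(
  alone_duration = c(
    over_9h = 0, "6_to_9h" = 0.2, "3_to_6h" = 0.4,
    "1_to_3h" = 0.6, under_1h = 0.8, cannot_be_alone = 1.0
  ),
  physical_burden = c(no = 0, yes = 1),
  sleep_disturbance = c(no = 0, yes = 1),
  qol_self_rating = c(
    excellent = 0, very_good = 0.2, good = 0.4,
    fair = 0.6, bad = 0.8, very_bad = 1.0
  ),
  other_family_care = c(no = 0, yes = 1),
  behavior_distress = c(no = 0, yes = 1),
  emotional_behavioral_issues = c(no = 0, yes = 1),
  work_affected = c(no = 0, yes = 1),
  cannot_cope = c(no = 0, yes = 1)
)

#' Names of the nine scoring items
#' @export
score_item_names <- names(score_rubric)

#' Compute the CSI-based burden score
#'
#' Sums the per-item increments of the nine scoring items.  Input is one or
#' more complete item sets; records with missing or unrecognized levels are
#' rejected (upstream cohort filtering is responsible for removing
#' incomplete records before scoring).
#'
#' @param items A data.frame (or list coercible to one) with one column per
#'   scoring item, named as in [score_rubric], holding character levels.
#' @return Numeric vector of scores, each a multiple of 0.2 in \[0, 9\].
#' @examples
#' score_items(data.frame(
#'   alone_duration = "6_to_9h", physical_burden = "yes",
#'   sleep_disturbance = "yes", qol_self_rating = "fair",
#'   other_family_care = "no", behavior_distress = "no",
#'   emotional_behavioral_issues = "no", work_affected = "no",
#'   cannot_cope = "no"
#' )) # 2.8
#' @export
score_items <- function(items) {
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  missing_cols <- setdiff(score_item_names, names(items))
  if (length(missing_cols) > 0) {
    stop("score_items: missing item column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  total <- numeric(nrow(items))
  for (item in score_item_names) {
    lv <- as.character(items[[item]])
    map <- score_rubric[[item]]
    inc <- unname(map[lv])
    bad <- is.na(inc)
    if (any(bad)) {
      offending <- unique(lv[bad])
      stop(sprintf(
        "score_items: invalid level(s) for '%s': %s (valid: %s)",
        item,
        paste(ifelse(is.na(offending), "<NA>", offending), collapse = ", "),
        paste(names(map), collapse = ", ")
      ), call. = FALSE)
    }
    total <- total + inc
  }
  total
}

#' Extract scoring items from assessment records
#'
#' Pulls the nine scoring-item columns out of a wide assessment record
#' table and reports, per record, which required fields are missing or hold
#' invalid levels.  A record is never partially scored: it is either fully
#' extractable or listed in the missing report.
#'
#' @param records data.frame of assessment records containing the scoring
#'   item columns (possibly with NAs / invalid entries).
#' @param prefix optional column-name prefix (e.g. `"reassess_"`) selecting
#'   an alternative item block such as the reassessment items.
#' @return list with elements:
#'   \describe{
#'     \item{items}{data.frame of the nine item columns for complete
#'       records only (row-subset of `records`, original row order).}
#'     \item{complete}{logical vector, one per input record.}
#'     \item{missing_report}{list (one element per incomplete record, named
#'       by row index) of the character vector of missing/invalid fields.}
#'   }
#' @export
extract_items <- function(records, prefix = "") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  cols <- paste0(prefix, score_item_names)
  absent <- setdiff(cols, names(records))
  if (length(absent) > 0) {
    stop("extract_items: records lack required column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  bad <- matrix(FALSE, n, length(cols),
                dimnames = list(NULL, score_item_names))
  for (i in seq_along(cols)) {
    lv <- as.character(records[[cols[i]]])
    valid <- names(score_rubric[[score_item_names[i]]])
    bad[, i] <- is.na(lv) | !(lv %in% valid)
  }
  complete <- rowSums(bad) == 0
  incomplete_idx <- which(!complete)
  missing_report <- lapply(incomplete_idx, function(i) {
    score_item_names[bad[i, ]]
  })
  names(missing_report) <- as.character(incomplete_idx)
  items <- records[complete, cols, drop = FALSE]
  names(items) <- score_item_names
  list(items = items, complete = complete, missing_report = missing_report)
}

#' Score assessment records
#'
#' Convenience wrapper: extracts items from a record table and appends a
#' `score` column (NA for records whose items are incomplete or invalid).
#'
#' @inheritParams extract_items
#' @return `records` with an added numeric `score` column.
#' @export
score_records <- function(records, prefix = "") {
  ex <- extract_items(records, prefix = prefix)
  out_col <- if (prefix == "") "score" else paste0(prefix, "score")
  records[[out_col]] <- NA_real_
  if (nrow(ex$items) > 0) {
    records[[out_col]][ex$complete] <- score_items(ex$items)
  }
  records
}

#' Enumerate all attainable item combinations and scores
#'
#' Exhaustively enumerates every combination of the nine item levels
#' (6 x 6 x 2^7 = 4,608) and computes each score.  Used for rubric audits:
#' the attainable score set is exactly the 46-value grid {0, 0.2, ..., 9}.
#'
#' @return data.frame of all item combinations with their `score`.
#' @export
enumerate_rubric <- function() {
  levels_list <- lapply(score_rubric, names)
  grid <- expand.grid(levels_list, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$score <- score_items(grid)
  grid
}
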