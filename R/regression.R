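# Mass-univariate covariate-adjusted OLS screening of burden risk factors,
# and change-score regressions measuring long-term-care service impact.
#
# Every model shares the same eight adjustment covariates; one model is fit
# per candidate feature (or per service), with complete-case analysis per
# model and classical homoskedastic standard errors.

#' The eight adjustment covariates
#' @export
covariate_names <- c(
  "recipient_gender", "recipient_age", "disability_certificate",
  "dementia", "foreign_caregiver", "cms_level",
  "caregiver_relationship", "caregiver_age"
)

# Dummy-code the covariate block; caregiver_relationship uses its most
# frequent level as the reference (treatment coding).
covariate_design <- function(records) {
  stopifnot(all(covariate_names %in% names(records)))
  rel <- as.character(records$caregiver_relationship)
  ref <- names(sort(table(rel), decreasing = TRUE))[1]
  lv <- c(ref, setdiff(sort(unique(rel)), ref))
  relf <- factor(rel, levels = lv)
  num_cols <- setdiff(covariate_names, "caregiver_relationship")
  X <- as.matrix(
    as.data.frame(lapply(records[num_cols], as.numeric))
  )
  if (nlevels(relf) > 1) {
    D <- stats::model.matrix(~relf)[, -1, drop = FALSE]
    colnames(D) <- paste0("caregiver_relationship_", lv[-1])
    X <- cbind(X, D)
  }
  X
}

#' Ordinary least squares with classical inference
#'
#' Fits y = intercept + design b by least squares and reports the
#' coefficient table with classical (homoskedastic) standard errors and
#' two-sided t-test p-values.  Rank-deficient columns are dropped (pivoting)
#' and reported in the `dropped` attribute.
#'
#' @param y numeric response.
#' @param design numeric matrix or data.frame of regressors (no intercept
#'   column; one is added).
#' @return data.frame with columns `term`, `beta`, `se`, `t_stat`,
#'   `p_value`, `n_used`; attribute `dropped` lists aliased terms and
#'   attribute `sigma` the residual standard error.
#' @export
ols_fit <- function(y, design) {
  X <- cbind(`(Intercept)` = 1, as.matrix(design))
  if (is.null(colnames(X)) || any(colnames(X)[-1] == "")) {
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))
  }
  keep <- stats::complete.cases(X, y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  if (n <= ncol(X)) {
    stop("ols_fit: need more observations than parameters", call. = FALSE)
  }
  qr_x <- qr(X)
  dropped <- character(0)
  if (qr_x$rank < ncol(X)) {
    drop_idx <- qr_x$pivot[(qr_x$rank + 1):ncol(X)]
    dropped <- colnames(X)[drop_idx]
    X <- X[, -drop_idx, drop = FALSE]
    qr_x <- qr(X)
  }
  beta <- qr.coef(qr_x, y)
  resid <- y - X %*% beta
  df <- n - ncol(X)
  sigma2 <- sum(resid^2) / df
  XtX_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * diag(XtX_inv))
  t_stat <- beta / se
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  out <- data.frame(
    term = colnames(X), beta = unname(beta), se = unname(se),
    t_stat = unname(t_stat), p_value = unname(p), n_used = n,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "dropped") <- dropped
  attr(out, "sigma") <- sqrt(sigma2)
  out
}

#' Screen candidate risk factors for caregiver burden
#'
#' Fits one covariate-adjusted linear model per feature:
#' score ~ feature + the eight covariates, with complete cases per model,
#' and returns one row per feature (the feature term only), sorted by
#' p-value.  Constant or aliased features are skipped and listed in the
#' `skipped` attribute.
#'
#' @param records scored record data.frame (needs `score`, the covariates,
#'   and the feature columns).
#' @param feature_list character vector of feature column names; default:
#'   all columns starting with `"feat_"`.
#' @param response response column name (default `"score"`).
#' @return data.frame of [ols_fit()] rows (feature terms only, one per
#'   feature) sorted by `p_value`, with a `skipped` attribute.
#' @export
screen_risk_factors <- function(records, feature_list = NULL,
                                response = "score") {
  if (is.null(feature_list)) {
    feature_list <- grep("^feat_", names(records), value = TRUE)
  }
  stopifnot(length(feature_list) > 0, response %in% names(records))
  Z <- covariate_design(records)
  # drop covariate columns that are degenerate on their own (constant, or
  # aliased with other covariates) once, so a later rank deficiency in a
  # feature model implicates the feature itself
  qz <- qr(cbind(1, Z))
  if (qz$rank < ncol(Z) + 1) {
    bad <- setdiff(qz$pivot[-seq_len(qz$rank)], 1L) - 1L
    Z <- Z[, -bad, drop = FALSE]
  }
  y <- as.numeric(records[[response]])
  rows <- vector("list", length(feature_list))
  skipped <- character(0)
  for (i in seq_along(feature_list)) {
    f <- feature_list[i]
    x <- as.numeric(records[[f]])
    cc <- !is.na(x) & !is.na(y) & stats::complete.cases(Z)
    if (sum(cc) < ncol(Z) + 3 || length(unique(x[cc])) < 2) {
      skipped <- c(skipped, f)
      next
    }
    design <- cbind(x, Z[cc, , drop = FALSE])
    colnames(design)[1] <- f
    fit <- ols_fit(y[cc], design)
    # any rank deficiency (the feature itself, or a covariate it aliases)
    # breaks the adjusted interpretation: skip, don't report
    if (length(attr(fit, "dropped")) > 0) {
      skipped <- c(skipped, f)
      next
    }
    rows[[i]] <- fit[fit$term == f, , drop = FALSE]
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(term = character(0), beta = numeric(0),
                      se = numeric(0), t_stat = numeric(0),
                      p_value = numeric(0), n_used = integer(0))
  } else {
    out <- out[order(out$p_value), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  out
}

#' Summarize a screening table
#'
#' Counts features significant at raw `alpha`, split by coefficient sign.
#' A Benjamini-Hochberg adjusted count is reported alongside (never
#' replacing) the raw-p convention, since the screen runs hundreds of
#' unadjusted tests.
#'
#' @param table output of [screen_risk_factors()].
#' @param alpha significance level (default 0.05).
#' @return list: `n_features`, `n_significant`, `n_positive`, `n_negative`,
#'   `n_significant_bh`, `alpha`.
#' @export
significance_summary <- function(table, alpha = 0.05) {
  sig <- table$p_value < alpha
  p_bh <- stats::p.adjust(table$p_value, method = "BH")
  list(
    n_features = nrow(table),
    n_significant = sum(sig),
    n_positive = sum(sig & table$beta > 0),
    n_negative = sum(sig & table$beta < 0),
    n_significant_bh = sum(p_bh < alpha),
    alpha = alpha
  )
}

#' Count service-utilization events per case within the observation window
#'
#' @param records reassessed record data.frame (`case_id`,
#'   `assessment_date`, `reassessment_date`).
#' @param events service-event data.frame (`case_id`, `service_code`,
#'   `event_date`).
#' @return matrix: rows = cases (in `records` order), columns = service
#'   codes, entries = event counts inside \[assessment, reassessment\].
#' @export
count_service_usage <- function(records, events) {
  codes <- sort(unique(as.character(events$service_code)))
  counts <- matrix(0L, nrow(records), length(codes),
                   dimnames = list(NULL, codes))
  if (nrow(events) == 0 || length(codes) == 0) return(counts)
  a <- as.Date(records$assessment_date)
  r <- as.Date(records$reassessment_date)
  idx <- match(events$case_id, records$case_id)
  ok <- !is.na(idx)
  ed <- as.Date(events$event_date[ok])
  idx <- idx[ok]
  in_win <- ed >= a[idx] & ed <= r[idx]
  tab <- table(factor(records$case_id[idx[in_win]],
                      levels = records$case_id),
                factor(events$service_code[ok][in_win], levels = codes))
  counts[, ] <- as.integer(tab)
  counts
}

#' Service-impact change-score regressions
#'
#' For each service used by at least `min_unique` unique cases, fits
#' change-in-score ~ usage count + the eight covariates on the reassessed
#' subset.  The change score is the reassessment score minus the initial
#' score; usage is the count of that service's utilization events inside
#' the case's observation window.
#'
#' @param records reassessed, scored records (needs `score` and
#'   `reassess_score`).
#' @param events service-event data.frame (`case_id`, `service_code`,
#'   `category`, `event_date`).
#' @param min_unique minimum number of unique using cases (default 30).
#' @return data.frame: one row per eligible service with `term` (service
#'   code), `category`, `noc` (number of unique using cases), `beta`, `se`,
#'   `t_stat`, `p_value`, `n_used`; attribute `excluded` lists services
#'   below the eligibility floor.
#' @export
service_impact_regression <- function(records, events, min_unique = 30) {
  if (!"score" %in% names(records)) records <- score_records(records)
  if (!"reassess_score" %in% names(records)) {
    records <- score_records(records, prefix = "reassess_")
  }
  delta <- as.numeric(records$reassess_score) - as.numeric(records$score)
  counts <- count_service_usage(records, events)
  Z <- covariate_design(records)
  cat_map <- unique(data.frame(
    service_code = as.character(events$service_code),
    category = as.character(events$category),
    stringsAsFactors = FALSE
  ))
  noc <- colSums(counts > 0)
  eligible <- names(noc)[noc >= min_unique]
  excluded <- setdiff(colnames(counts), eligible)
  rows <- lapply(eligible, function(s) {
    design <- cbind(counts[, s], Z)
    colnames(design)[1] <- s
    fit <- ols_fit(delta, design)
    row <- fit[fit$term == s, , drop = FALSE]
    row$noc <- noc[[s]]
    row$category <- cat_map$category[match(s, cat_map$service_code)]
    row
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(0), beta = numeric(0),
                      se = numeric(0), t_stat = numeric(0),
                      p_value = numeric(0), n_used = integer(0),
                      noc = integer(0), category = character(0))
  } else {
    out <- out[order(out$p_value), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "excluded") <- excluded
  out
}
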