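# Time-to-first-service analysis: sample construction from event logs,
# Kaplan-Meier curves by burden group, log-rank tests, and Cox proportional
# hazards with the continuous burden score as exposure.
#
# The estimators themselves are delegated to the survival package (Efron
# tie handling for Cox); this module owns the observation-window semantics.

#' Build time-to-first-use survival samples for one service
#'
#' The observation window runs from the initial assessment to the
#' reassessment.  The event is the first utilization of `service` inside
#' the window; cases without one are censored at the reassessment.  Events
#' dated before the assessment are ignored, and events after the
#' reassessment leave the case censored (both are counted in the `ignored`
#' attribute).  A first use on the assessment day itself gets duration 0.5
#' days to keep durations positive.
#'
#' @param records reassessed, scored record data.frame.
#' @param events service-event data.frame.
#' @param service service code to analyze.
#' @param bcp cut-point for the high/not-high grouping (default 4.4).
#' @return data.frame: `case_id`, `duration` (days), `event` (0/1),
#'   `group` (`"high"`/`"not_high"`), `score`, plus the covariate columns.
#' @export
build_time_to_first <- function(records, events, service, bcp = 4.4) {
  a <- as.Date(records$assessment_date)
  r <- as.Date(records$reassessment_date)
  window <- as.numeric(r - a)
  ev <- events[as.character(events$service_code) == service, , drop = FALSE]
  idx <- match(ev$case_id, records$case_id)
  ok <- !is.na(idx)
  ev <- ev[ok, , drop = FALSE]; idx <- idx[ok]
  day <- as.numeric(as.Date(ev$event_date) - a[idx])
  before <- day < 0
  after <- day > window[idx]
  usable <- !before & !after
  first_day <- rep(NA_real_, nrow(records))
  if (any(usable)) {
    agg <- tapply(day[usable], idx[usable], min)
    first_day[as.integer(names(agg))] <- as.numeric(agg)
  }
  has_event <- !is.na(first_day)
  duration <- ifelse(has_event, pmax(first_day, 0.5), window)
  out <- data.frame(
    case_id = records$case_id,
    duration = duration,
    event = as.integer(has_event),
    group = dichotomize(records$score, bcp),
    score = as.numeric(records$score),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, records[, covariate_names, drop = FALSE])
  attr(out, "ignored") <- c(before_assessment = sum(before),
                            after_reassessment = sum(after))
  out
}

#' Dichotomize scores at the best cut-off point
#'
#' "High burden" means strictly above the cut-point (a score exactly at the
#' cut-point is not high).
#'
#' @param scores numeric score vector.
#' @param bcp cut-point.
#' @return character vector, `"high"` / `"not_high"`.
#' @export
dichotomize <- function(scores, bcp) {
  ifelse(as.numeric(scores) > bcp, "high", "not_high")
}

#' Kaplan-Meier product-limit estimator
#'
#' @param samples data.frame with `duration` and `event` (see
#'   [build_time_to_first()]).
#' @return data.frame step function: `time`, `n_risk`, `n_event`, `surv`;
#'   right-continuous with S(0) = 1.
#' @export
kaplan_meier <- function(samples) {
  stopifnot(nrow(samples) > 0)
  fit <- survival::survfit(
    survival::Surv(duration, event) ~ 1, data = samples
  )
  data.frame(time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' @param samples_a,samples_b survival-sample data.frames (non-empty).
#' @return list: `statistic` (chi-square, 1 df), `p_value`.
#' @export
logrank <- function(samples_a, samples_b) {
  stopifnot(nrow(samples_a) > 0, nrow(samples_b) > 0)
  df <- rbind(
    data.frame(duration = samples_a$duration, event = samples_a$event,
               g = "a"),
    data.frame(duration = samples_b$duration, event = samples_b$event,
               g = "b")
  )
  if (sum(df$event) == 0) {
    stop("logrank: no events in either group", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(duration, event) ~ g, data = df)
  list(statistic = unname(sd$chisq),
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit with the score as continuous exposure
#'
#' Partial-likelihood maximization with Efron tie handling, adjusting for
#' the eight covariates (or any supplied subset).  Reports the per-unit-
#' score hazard ratio with Wald 95% CI and p-value.
#'
#' @param samples output of [build_time_to_first()].
#' @param covariates character vector of adjustment columns present in
#'   `samples`; `character(0)` fits the score alone.
#' @return list of class `cox_result`: `hr`, `ci_low`, `ci_high`,
#'   `p_value`, `log_hr`, `se`, `n`, `n_events`, and `fit` (the underlying
#'   `coxph` object).
#' @export
cox_fit <- function(samples, covariates = covariate_names) {
  if (sum(samples$event) < 1) {
    stop("cox_fit: at least one event required", call. = FALSE)
  }
  if (length(unique(samples$score)) < 2) {
    stop("cox_fit: exposure (score) does not vary", call. = FALSE)
  }
  dat <- samples
  if ("caregiver_relationship" %in% covariates) {
    dat$caregiver_relationship <- factor(dat$caregiver_relationship)
  }
  rhs <- paste(c("score", covariates), collapse = " + ")
  form <- stats::as.formula(paste("survival::Surv(duration, event) ~", rhs))
  notes <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(form, data = dat, ties = "efron"),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  # monotone likelihood (separation): fatal if it concerns the exposure,
  # otherwise recorded and reported with the result
  if (any(grepl("infinite", notes))) {
    idx <- suppressWarnings(as.integer(
      sub(".*variable\\s+(\\d+).*", "\\1", grep("infinite", notes,
                                                value = TRUE))))
    terms_hit <- names(stats::coef(fit))[idx[!is.na(idx)]]
    if ("score" %in% terms_hit) {
      stop("cox_fit: monotone likelihood (perfect separation) in the score ",
           "exposure", call. = FALSE)
    }
  }
  b <- stats::coef(fit)[["score"]]
  se <- sqrt(stats::vcov(fit)["score", "score"])
  if (!is.finite(b) || !is.finite(se)) {
    stop("cox_fit: non-finite estimate; model did not converge",
         call. = FALSE)
  }
  z <- b / se
  structure(
    list(hr = exp(b), ci_low = exp(b - 1.96 * se),
         ci_high = exp(b + 1.96 * se),
         p_value = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
         log_hr = b, se = se,
         n = nrow(samples), n_events = sum(samples$event),
         notes = notes, fit = fit),
    class = "cox_result"
  )
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf(
    "Cox PH: HR per unit score = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
    x$hr, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  n = %d, events = %d\n", x$n, x$n_events))
  invisible(x)
}

#' Most frequently utilized services
#'
#' Ranks services by the number of unique using cases; ties broken by total
#' event count, then lexicographically by code.
#'
#' @param events service-event data.frame.
#' @param k number of services to return (default 10); a `k` beyond the
#'   catalogue returns every service.
#' @return character vector of service codes, most used first.
#' @export
top_services <- function(events, k = 10) {
  if (nrow(events) == 0) return(character(0))
  code <- as.character(events$service_code)
  uniq <- tapply(as.character(events$case_id), code,
                 function(x) length(unique(x)))
  tot <- table(code)[names(uniq)]
  ord <- order(-as.numeric(uniq), -as.numeric(tot), names(uniq))
  utils::head(names(uniq)[ord], k)
}
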