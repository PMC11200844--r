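# Tabular I/O, schema checks, logging, and the end-to-end pipeline tying
# the stages together: cohort -> score -> validate -> screen -> survival ->
# impact.  Plain UTF-8 CSV with ISO dates and empty-string/NA tokens; every
# stage logs its row counts so the CONSORT trail is auditable.

log_info <- function(fmt, ..., logfile = NULL) {
  msg <- sprintf(paste0("[careburden] ", fmt), ...)
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
  invisible(NULL)
}

#' The assessment-table data dictionary
#'
#' Column-level schema of the assessments CSV: name, type, allowed levels
#' (for categoricals) and whether the column is required.  The feature
#' block (`feat_*`, free-form numeric/binary columns) is documented as a
#' wildcard row.
#'
#' @return data.frame with columns `column`, `type`, `levels`, `required`,
#'   `description`.
#' @export
data_dictionary <- function() {
  path <- system.file("extdata", "data_dictionary.csv",
                      package = "careburden")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

required_assessment_cols <- function() {
  c("case_id", "assessment_date", "reassessment_date",
    covariate_names, score_item_names,
    paste0("reassess_", score_item_names),
    psi_flag_cols, expert_vote_cols)
}

#' Validate a table against the shipped schema
#'
#' @param df data.frame to check.
#' @param kind `"assessments"` or `"events"`.
#' @return `df`, invisibly; stops with column-level diagnostics on
#'   violations.
#' @export
validate_schema <- function(df, kind = c("assessments", "events")) {
  kind <- match.arg(kind)
  need <- if (kind == "assessments") required_assessment_cols() else
    c("case_id", "service_code", "category", "event_date")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s table is missing required column(s): %s",
                 kind, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Read an assessments CSV
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_assessments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  validate_schema(df, "assessments")
}

#' Read a service-events CSV
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  validate_schema(df, "events")
}

#' Write a simulated study to disk
#'
#' @param sim output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return paths of the written files (assessments.csv, events.csv,
#'   truth.json), invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pa <- file.path(dir, "assessments.csv")
  pe <- file.path(dir, "events.csv")
  pt <- file.path(dir, "truth.json")
  utils::write.csv(sim$records, pa, row.names = FALSE, na = "")
  utils::write.csv(sim$events, pe, row.names = FALSE, na = "")
  truth <- sim$truth
  truth$reassessment$counts <- NULL   # matrix; too bulky for the sidecar
  jsonlite::write_json(truth, pt, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(assessments = pa, events = pe, truth = pt))
}

#' Default pipeline configuration
#'
#' @param assessments,events input CSV paths or in-memory data.frames.
#' @param out_dir output directory (`NULL`: nothing written).
#' @param alpha screening significance level.
#' @param bcp high-burden cut-point; `NULL` selects it by Youden's index on
#'   the validation subset's intersection label.
#' @param min_unique_cases service-impact eligibility floor.
#' @param top_k number of services for the survival stage.
#' @param psi_k screening-indicator positivity rule (see [psi_label()]).
#' @param seed recorded for provenance (the analysis itself is
#'   deterministic).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(assessments, events, out_dir = NULL,
                            alpha = 0.05, bcp = NULL,
                            min_unique_cases = 30, top_k = 10,
                            psi_k = 1, seed = 1L) {
  stopifnot(alpha > 0, min_unique_cases > 0, top_k > 0)
  structure(list(assessments = assessments, events = events,
                 out_dir = out_dir, alpha = alpha, bcp = bcp,
                 min_unique_cases = min_unique_cases, top_k = top_k,
                 psi_k = psi_k, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes cohort filtering, scoring, label validation, risk-factor
#' screening, time-to-first-service survival analysis, and service-impact
#' regression, logging row counts at every stage.  Results are returned as
#' one report list and, when `out_dir` is set, written as `results.json`
#' plus per-stage CSV tables.
#'
#' @param config a [pipeline_config()].
#' @return report list: `consort`, `score_summary`, `validation`, `screen`,
#'   `survival`, `impact`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  records <- if (is.character(config$assessments)) {
    read_assessments(config$assessments)
  } else validate_schema(config$assessments, "assessments")
  events <- if (is.character(config$events)) {
    read_events(config$events)
  } else validate_schema(config$events, "events")
  log_info("input: %d assessment records, %d service events",
           nrow(records), nrow(events))

  # cohort + scoring
  fr <- apply_consort_filters(records)
  log_info("CONSORT: %d assessed -> %d included (%d missing-score, %d under-18)",
           nrow(records), nrow(fr$included),
           fr$excluded_missing_score, fr$excluded_under18)
  inc <- score_records(fr$included)
  score_summary <- list(
    n = nrow(inc), mean = mean(inc$score), sd = stats::sd(inc$score),
    quartiles = unname(stats::quantile(inc$score, c(.25, .5, .75))),
    min = min(inc$score), max = max(inc$score)
  )

  # validation
  val <- select_validation_subset(inc)
  log_info("validation subset: %d records", nrow(val))
  validation <- NULL
  bcp <- config$bcp
  if (nrow(val) > 0) {
    val <- attach_labels(val, psi_k = config$psi_k)
    kap <- cohens_kappa(val$psi_label, val$expert_label)
    metrics <- lapply(
      c(expert = "expert_label", psi = "psi_label",
        union = "union_label", intersection = "intersection_label"),
      function(col) {
        if (length(unique(val[[col]])) < 2) return(NULL)
        label_metrics(val$score, val[[col]])
      })
    if (is.null(bcp) && !is.null(metrics$intersection)) {
      bcp <- metrics$intersection$threshold_used
      log_info("Youden cut-point (intersection label): %.2f", bcp)
    }
    validation <- list(
      n = nrow(val),
      prevalence = list(expert = mean(val$expert_label),
                        psi = mean(val$psi_label)),
      kappa = unclass(kap)[c("kappa", "ci_low", "ci_high")],
      metrics = metrics
    )
  }
  if (is.null(bcp)) bcp <- 4.4

  # risk-factor screening on the non-validation included records
  reg <- inc[!(inc$case_id %in% val$case_id), , drop = FALSE]
  log_info("screening subset: %d records", nrow(reg))
  screen_tab <- screen_risk_factors(reg)
  screen <- list(table = screen_tab,
                 summary = significance_summary(screen_tab, config$alpha))
  log_info("screened %d features: %d significant at alpha=%.2f",
           nrow(screen_tab), screen$summary$n_significant, config$alpha)

  # survival on the reassessed subset
  rea <- select_reassessed_subset(inc)
  rea <- score_records(rea, prefix = "reassess_")
  log_info("reassessed subset: %d records", nrow(rea))
  services <- top_services(events, config$top_k)
  surv_rows <- list(); km_list <- list()
  for (sv in services) {
    samp <- build_time_to_first(rea, events, sv, bcp = bcp)
    if (sum(samp$event) == 0) next
    cx <- cox_fit(samp)
    lr <- tryCatch(
      logrank(samp[samp$group == "high", ], samp[samp$group == "not_high", ]),
      error = function(e) list(statistic = NA, p_value = NA))
    surv_rows[[sv]] <- data.frame(
      service = sv, n = cx$n, n_events = cx$n_events, hr = cx$hr,
      ci_low = cx$ci_low, ci_high = cx$ci_high, p_value = cx$p_value,
      logrank_p = lr$p_value, stringsAsFactors = FALSE)
    km_list[[sv]] <- lapply(split(samp, samp$group), kaplan_meier)
  }
  surv_tab <- do.call(rbind, surv_rows); rownames(surv_tab) <- NULL
  survival_res <- list(bcp = bcp, table = surv_tab, km = km_list)

  # service impact
  impact_tab <- service_impact_regression(rea, events,
                                          min_unique = config$min_unique_cases)
  log_info("impact regressions: %d eligible services (floor %d)",
           nrow(impact_tab), config$min_unique_cases)

  report <- list(consort = list(
                   assessed = nrow(records),
                   excluded_missing_score = fr$excluded_missing_score,
                   excluded_under18 = fr$excluded_under18,
                   included = nrow(inc),
                   validation = nrow(val), reassessed = nrow(rea)),
                 score_summary = score_summary,
                 validation = validation,
                 screen = screen,
                 survival = survival_res,
                 impact = impact_tab,
                 config = unclass(config))
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$screen$table,
                   file.path(out_dir, "screen.csv"), row.names = FALSE)
  utils::write.csv(report$impact,
                   file.path(out_dir, "impact.csv"), row.names = FALSE)
  if (!is.null(report$survival$table)) {
    utils::write.csv(report$survival$table,
                     file.path(out_dir, "survival.csv"), row.names = FALSE)
    km_rows <- do.call(rbind, unlist(lapply(
      names(report$survival$km), function(sv) {
        lapply(names(report$survival$km[[sv]]), function(g) {
          cbind(service = sv, group = g, report$survival$km[[sv]][[g]])
        })
      }), recursive = FALSE))
    utils::write.csv(km_rows, file.path(out_dir, "km_curves.csv"),
                     row.names = FALSE)
  }
  json <- report
  json$screen$table <- NULL          # shipped as CSV
  json$survival$km <- NULL
  jsonlite::write_json(json, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  log_info("report written to %s", out_dir)
  invisible(out_dir)
}
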