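# Synthetic cohort generator.
#
# Emulates the statistical structure of a (restricted) Taiwanese LTC
# assessment dataset: a CONSORT-sized cohort with demographics, a ~303-column
# feature block, nine scoring items on the 0.2 grid, screening-indicator
# flags and expert votes for a post-2022 validation subset, service-event
# logs with proportional-hazards first-use times, and reassessments whose
# change scores respond to service usage.
#
# Model: a case's raw burden is linear in its features and covariates plus
# Gaussian noise; the observed score is that value rounded to the 0.2 grid
# and clamped to [0, 9]; the nine items are a random decomposition of the
# grid score consistent with the rubric.  Labels are thresholded Gaussian
# latents sharing the standardized score; first-use hazards are exponential
# with a per-unit-score log hazard ratio.  Every injected parameter is
# returned in a ground-truth sidecar for recovery testing.

# Evaluate code under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Calibrated constants (see calibrate_generator() and scripts/calibrate.R;
# produced once at seed 0, n = 200,000, then frozen here).
.calibrated <- list(
  score_intercept = 2.11347103,  # overall grid-score mean 4.21
  score_noise_sd = 1.53008578,   # grid-score SD 1.71
  b_expert = 0.58505859,         # AUROC(score -> expert majority) 0.77
  tau_vote = 0.64721680,         # expert-majority prevalence 0.25
  b_psi = 0.42978516,            # AUROC(score -> any-flag PSI) 0.72
  tau_flag = 1.94287109,         # PSI prevalence 0.12
  c_shared = 0.74591947,         # kappa(PSI, expert) 0.402
  validation_score_shift = -0.19445801,  # validation-subset mean 4.03
  # raw-scale feature slopes hitting the published capped-scale betas
  # (same order as the feature_effects table)
  raw_beta = c(0.74826172, 0.53574951, 0.51574951, 0.38439941, 0.31374512,
               0.30366211, 0.23251099, -0.07052734, 2.69638062, 2.67152344,
               2.67102539)
)

#' Default synthetic-cohort configuration
#'
#' All calibrated parameters of the synthetic cohort.  Defaults reproduce
#' the published cohort arithmetic (32,955 assessed; 4,437 missing-score and
#' 183 under-18 exclusions; 1,791 validation and 7,471 reassessed cases) and
#' the published summary statistics (score mean 4.21 / SD 1.71, expert
#' prevalence 25%, screening-indicator prevalence 12%, kappa 0.402, AUROC
#' 0.77 / 0.72) via constants frozen from the shipped calibration routine
#' ([calibrate_generator()]).  Feature effects, per-unit-score hazard
#' ratios, and service-impact slopes default to the published estimates,
#' which downstream recovery tests treat as ground truth.
#'
#' @param seed integer RNG seed.
#' @param n_total cohort size.
#' @param n_missing_score,n_under18 sizes of the two exclusion subsets
#'   (disjoint by construction).
#' @param n_validation post-2022 subset with screening-indicator flags.
#' @param n_reassessed reassessed subset (drawn outside the validation
#'   subset).
#' @param n_features total feature-block width (effect features plus
#'   independent null features).
#' @return list of class `generator_config`.
#' @export
default_generator_config <- function(seed = 1L,
                                     n_total = 32955L,
                                     n_missing_score = 4437L,
                                     n_under18 = 183L,
                                     n_validation = 1791L,
                                     n_reassessed = 7471L,
                                     n_features = 303L) {
  feature_effects <- data.frame(
    name = c("feat_multi_care", "feat_work_schedule_adjustment",
             "feat_leave_from_work", "feat_married",
             "feat_recipient_lack_of_energy", "feat_full_time_work",
             "feat_caregiver_recent_health_issue", "feat_independent_bathing",
             "feat_bpsd_verbal_aggression_freq",
             "feat_bpsd_object_destruction", "feat_bpsd_delusions_freq"),
    prevalence = c(0.18, 0.30, 0.22, 0.58, 0.35, 0.28, 0.25, 0.30,
                   0.012, 0.015, 0.015),
    beta = c(0.74, 0.53, 0.51, 0.38, 0.31, 0.30, 0.23, -0.07,
             2.60, 2.58, 2.58),
    stringsAsFactors = FALSE
  )
  # Raw-scale slopes whose capped-grid-scale regression coefficients equal
  # `beta`: the observed score is clamped to [0, 9], which attenuates large
  # effects (mainly the rare BPSD items pushing carriers into the ceiling),
  # so the injected raw slope must be slightly larger than the target
  # coefficient.  Solved by calibrate_generator() and frozen here.
  feature_effects$raw_beta <- .calibrated$raw_beta
  # service catalogue: first-use probabilities sized so realized
  # unique-user counts match the published NoC (out of 7,471), hazard
  # ratios per unit score for the three published significant services,
  # and change-score slopes for the five published impact services.
  services <- data.frame(
    service_code = c("basic_body_care", "household_assistance",
                     "transport_medical", "accompanied_outings",
                     "companion", "home_respite", "daytime_care_full",
                     "nutritional_meal", "prof_nursing_guidance",
                     "aux_medical", "institutional_respite",
                     "turning_patting", "patrol"),
    category = c("I", "I", "III", "I", "I", "IV", "I", "other", "II",
                 "I", "IV", "I", "I"),
    p_first = c(0.45, 0.40, 0.30, 0.25, 0.18, 0.16,
                545 / 7471, 442 / 7471, 0.08,
                254 / 7471, 0.03, 153 / 7471, 99 / 7471),
    log_hr = c(0, 0, 0, log(1.065), log(1.116), log(1.114),
               0, 0, 0, 0, 0, 0, 0),
    sessions_per_day = c(0.30, 0.25, 0.04, 0.06, 0.08, 0.05,
                         0.60, 0.70, 0.02, 0.30, 0.01, 0.50, 0.40),
    impact_slope = c(0, 0, 0, 0, 0, 0,
                     -2.78e-3, -1.36e-3, 0, -4.38e-3, 0,
                     -2.31e-3, 1.58e-3),
    stringsAsFactors = FALSE
  )
  cfg <- list(
    seed = as.integer(seed),
    n_total = as.integer(n_total),
    n_missing_score = as.integer(n_missing_score),
    n_under18 = as.integer(n_under18),
    n_validation = as.integer(n_validation),
    n_reassessed = as.integer(n_reassessed),
    n_features = as.integer(n_features),
    # score model (frozen calibration)
    score_intercept = .calibrated$score_intercept,
    score_noise_sd = .calibrated$score_noise_sd,
    # The published validation subset (post-2022, screening-indicator era)
    # scores lower than the full cohort (printed mean 4.03 vs 4.21); the
    # cut-point validation happens on that subset, so the shift matters.
    validation_score_shift = .calibrated$validation_score_shift,
    score_mu = 4.21,          # standardization constants for label latents
    score_sd = 1.71,
    # covariate true effects (score units)
    covariate_effects = list(
      recipient_gender = 0.05, recipient_age = 0.004,
      disability_certificate = 0.10, dementia = 0.25,
      foreign_caregiver = -0.35, cms_level = 0.12, caregiver_age = 0.003,
      caregiver_relationship = c(adult_child = 0, spouse = 0.20,
                                 child_in_law = 0.05, other = -0.10)
    ),
    feature_effects = feature_effects,
    # label model (b_* frozen by calibration; noise scales are design
    # constants the calibration conditions on)
    b_expert = .calibrated$b_expert,
    tau_vote = .calibrated$tau_vote,
    vote_noise = 0.5,
    b_psi = .calibrated$b_psi,
    tau_flag = .calibrated$tau_flag,
    flag_noise = 0.5,
    c_shared = .calibrated$c_shared,
    # survival / impact
    services = services,
    window_days = c(300, 400),
    delta_noise_sd = 0.8,
    # study calendar
    study_start = as.Date("2019-08-01"),
    psi_era_start = as.Date("2022-01-01"),
    study_end = as.Date("2022-12-31")
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (n_missing_score + n_under18 + n_validation + n_reassessed > n_total) {
      stop("generator config: subset sizes exceed n_total", call. = FALSE)
    }
    if (score_noise_sd <= 0 || delta_noise_sd <= 0) {
      stop("generator config: noise SDs must be positive", call. = FALSE)
    }
    if (any(feature_effects$prevalence <= 0) ||
        any(feature_effects$prevalence >= 1)) {
      stop("generator config: feature prevalences must be in (0,1)",
           call. = FALSE)
    }
    if (any(services$p_first <= 0) || any(services$p_first >= 1)) {
      stop("generator config: first-use probabilities must be in (0,1)",
           call. = FALSE)
    }
    if (n_features < nrow(feature_effects)) {
      stop("generator config: n_features smaller than the effect list",
           call. = FALSE)
    }
  })
  invisible(cfg)
}

# --- building blocks ------------------------------------------------------

gen_covariates <- function(n) {
  data.frame(
    recipient_gender = stats::rbinom(n, 1, 0.55),
    recipient_age = pmin(pmax(round(stats::rnorm(n, 76, 12)), 20), 103),
    disability_certificate = stats::rbinom(n, 1, 0.35),
    dementia = stats::rbinom(n, 1, 0.22),
    foreign_caregiver = stats::rbinom(n, 1, 0.10),
    cms_level = sample(1:8, n, replace = TRUE,
                       prob = c(.06, .14, .18, .18, .16, .12, .10, .06)),
    caregiver_relationship = sample(
      c("adult_child", "spouse", "child_in_law", "other"), n,
      replace = TRUE, prob = c(.45, .30, .10, .15)),
    caregiver_age = pmin(pmax(round(stats::rnorm(n, 58, 13)), 20), 90),
    stringsAsFactors = FALSE
  )
}

gen_features <- function(n, cfg) {
  fe <- cfg$feature_effects
  n_eff <- nrow(fe)
  n_null <- cfg$n_features - n_eff
  X_eff <- vapply(fe$prevalence,
                  function(p) stats::rbinom(n, 1, p), integer(n))
  colnames(X_eff) <- fe$name
  n_null_bin <- max(0L, n_null - floor(n_null / 7))   # a slice of ordinals
  n_null_ord <- n_null - n_null_bin
  null_prev <- stats::runif(n_null_bin, 0.03, 0.60)
  X_nb <- vapply(null_prev, function(p) stats::rbinom(n, 1, p), integer(n))
  X_no <- vapply(seq_len(n_null_ord),
                 function(i) sample(0:4, n, replace = TRUE), integer(n))
  X <- cbind(X_eff, X_nb, X_no)
  colnames(X) <- c(fe$name,
                   sprintf("feat_null_bin_%03d", seq_len(n_null_bin)),
                   sprintf("feat_null_ord_%03d", seq_len(n_null_ord)))
  X
}

linear_predictor <- function(cov, X, cfg) {
  ce <- cfg$covariate_effects
  lin <- ce$recipient_gender * cov$recipient_gender +
    ce$recipient_age * cov$recipient_age +
    ce$disability_certificate * cov$disability_certificate +
    ce$dementia * cov$dementia +
    ce$foreign_caregiver * cov$foreign_caregiver +
    ce$cms_level * cov$cms_level +
    ce$caregiver_age * cov$caregiver_age +
    unname(ce$caregiver_relationship[cov$caregiver_relationship])
  fe <- cfg$feature_effects
  lin + as.numeric(X[, fe$name, drop = FALSE] %*% fe$raw_beta)
}

# round a raw burden value to the 0.2 grid and clamp to [0, 9];
# returns integer grid units in 0..45
to_grid_units <- function(s_raw) {
  pmin(pmax(as.integer(round(5 * s_raw)), 0L), 45L)
}

# Randomly decompose grid units u (0..45) into the nine rubric items:
# alone-duration units a in 0..5, QoL units q in 0..5, and k of the seven
# binary items set (5 units each), with a + q + 5k = u.  Uniform over the
# feasible (k, a) pairs, then a uniform choice of which binaries are set.
decompose_score_items <- function(u) {
  n <- length(u)
  stopifnot(all(u >= 0L & u <= 45L))
  k_lo <- pmax(0L, as.integer(ceiling((u - 10L) / 5)))
  k_hi <- pmin(7L, u %/% 5L)
  k <- k_lo + as.integer(floor(stats::runif(n) * (k_hi - k_lo + 1L)))
  r <- u - 5L * k
  a_lo <- pmax(0L, r - 5L); a_hi <- pmin(5L, r)
  a <- a_lo + as.integer(floor(stats::runif(n) * (a_hi - a_lo + 1L)))
  q <- r - a
  # choose which k of the 7 binary items are positive
  U <- matrix(stats::runif(n * 7), n, 7)
  R <- t(apply(U, 1, rank))
  B <- R <= k    # k random columns per row
  alone_levels <- names(score_rubric$alone_duration)
  qol_levels <- names(score_rubric$qol_self_rating)
  bin_names <- setdiff(score_item_names,
                       c("alone_duration", "qol_self_rating"))
  out <- data.frame(alone_duration = alone_levels[a + 1L],
                    qol_self_rating = qol_levels[q + 1L],
                    stringsAsFactors = FALSE)
  for (j in seq_along(bin_names)) {
    out[[bin_names[j]]] <- ifelse(B[, j], "yes", "no")
  }
  out[, score_item_names]
}

# --- main operations ------------------------------------------------------

#' Generate the synthetic assessment cohort
#'
#' Draws `n_total` assessment records: demographics and covariates, the
#' ~303-column feature block, scoring items decomposed from the linear
#' burden model, designated missing-score and under-18 exclusion subsets,
#' and assessment dates placing exactly the designated validation subset in
#' the post-2022 screening-indicator era.  Label, event and reassessment
#' columns are created empty; see [generate_labels()],
#' [generate_service_events()] and [generate_reassessment()].
#'
#' @param config a [default_generator_config()] list.
#' @return list: `records` (data.frame) and `truth` (ground-truth sidecar:
#'   raw scores, subset indices, and every injected parameter).
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  with_seed(config$seed, {
    n <- config$n_total
    cov <- gen_covariates(n)
    X <- gen_features(n, config)
    lin <- linear_predictor(cov, X, config)
    s_raw <- config$score_intercept + lin +
      stats::rnorm(n, 0, config$score_noise_sd)

    # disjoint designated subsets
    perm <- sample.int(n)
    n_excl <- config$n_missing_score + config$n_under18
    idx_missing <- perm[seq_len(config$n_missing_score)]
    idx_under18 <- perm[config$n_missing_score + seq_len(config$n_under18)]
    idx_included <- if (n_excl > 0) perm[-seq_len(n_excl)] else perm
    idx_validation <- sort(sample(idx_included, config$n_validation))
    idx_rest <- setdiff(idx_included, idx_validation)
    idx_reassessed <- sort(sample(idx_rest, config$n_reassessed))

    # screening-era (validation) cases score lower, per the published
    # subset summaries; items are decomposed from the shifted score
    s_raw[idx_validation] <- s_raw[idx_validation] +
      config$validation_score_shift
    u <- to_grid_units(s_raw)
    items <- decompose_score_items(u)

    # under-18: give the caregiver a minor's age (items stay complete)
    cov$caregiver_age[idx_under18] <- sample(15:17, config$n_under18,
                                             replace = TRUE)
    # missing score values: blank 1-3 random items per record
    for (i in idx_missing) {
      n_blank <- sample(1:3, 1)
      items[i, sample(score_item_names, n_blank)] <- NA_character_
    }

    # dates: validation subset in the screening-indicator era, rest before
    pre_days <- as.integer(config$psi_era_start - config$study_start) - 1L
    post_days <- as.integer(config$study_end - config$psi_era_start)
    adate <- config$study_start +
      sample.int(pre_days, n, replace = TRUE) - 1L
    adate[idx_validation] <- config$psi_era_start +
      sample.int(post_days, config$n_validation, replace = TRUE) - 1L

    window <- round(stats::runif(config$n_reassessed,
                                 config$window_days[1],
                                 config$window_days[2]))
    rdate <- as.Date(rep(NA, n))
    rdate[idx_reassessed] <- adate[idx_reassessed] + window

    records <- data.frame(
      case_id = sprintf("case_%06d", seq_len(n)),
      assessment_date = as.character(adate),
      reassessment_date = as.character(rdate),
      cov, items,
      stringsAsFactors = FALSE
    )
    for (col in paste0("reassess_", score_item_names)) {
      records[[col]] <- NA_character_
    }
    for (col in c(psi_flag_cols, expert_vote_cols)) {
      records[[col]] <- NA_integer_
    }
    records <- cbind(records, as.data.frame(X))

    truth <- list(
      s_raw = s_raw, grid_units = u, lin = lin,
      idx_missing = idx_missing, idx_under18 = idx_under18,
      idx_included = sort(idx_included),
      idx_validation = idx_validation, idx_reassessed = idx_reassessed,
      window = window,
      feature_effects = config$feature_effects,
      covariate_effects = config$covariate_effects,
      services = config$services,
      score_intercept = config$score_intercept,
      score_noise_sd = config$score_noise_sd
    )
    list(records = records, truth = truth)
  })
}

#' Generate screening-indicator flags and expert votes
#'
#' For every record assessed in the screening-indicator era (on/after the
#' configured start, 2022-01-01 by default), draws ten indicator flags and
#' three expert votes from Gaussian latents that load on the standardized
#' burden score plus a shared non-score component (caregiver self-report
#' signal seen by both instruments but not by the score) plus independent
#' noise.  Calibrated loadings/thresholds reproduce the published
#' prevalences, AUROCs and kappa.
#'
#' @param records cohort record data.frame from [generate_cohort()].
#' @param config generator configuration.
#' @return `records` with `psi_1..psi_10` and `expert_vote_1..3` filled for
#'   the screening-era rows.
#' @export
generate_labels <- function(records, config) {
  with_seed(config$seed + 1L, {
    scored <- score_records(records)
    era <- !is.na(records$assessment_date) &
      as.Date(records$assessment_date) >= config$psi_era_start &
      !is.na(scored$score)
    m <- sum(era)
    if (m == 0) return(records)
    lstd <- (scored$score[era] - config$score_mu) / config$score_sd
    be <- config$b_expert; bp <- config$b_psi; cs <- config$c_shared
    eta <- stats::rnorm(m)
    w_e <- be * lstd + cs * eta +
      sqrt(max(0, 1 - be^2 - cs^2)) * stats::rnorm(m)
    w_p <- bp * lstd + cs * eta +
      sqrt(max(0, 1 - bp^2 - cs^2)) * stats::rnorm(m)
    for (j in 1:3) {
      records[[expert_vote_cols[j]]][era] <-
        as.integer(w_e + config$vote_noise * stats::rnorm(m) >
                     config$tau_vote)
    }
    for (k in 1:10) {
      records[[psi_flag_cols[k]]][era] <-
        as.integer(w_p + config$flag_noise * stats::rnorm(m) >
                     config$tau_flag)
    }
    records
  })
}

#' Generate the service-utilization event log
#'
#' For every reassessed case and every catalogued service, draws an
#' exponential first-use time whose rate is the service baseline tilted by
#' exp(log-HR x (score - population mean)); first uses beyond the case's
#' observation window are not emitted (censoring arises naturally).  Users
#' accrue recurrent events at the service's session rate until the window
#' closes.
#'
#' @param records cohort record data.frame (reassessment dates set).
#' @param config generator configuration.
#' @return data.frame event log: `case_id`, `service_code`, `category`,
#'   `event_date`.
#' @export
generate_service_events <- function(records, config) {
  with_seed(config$seed + 2L, {
    scored <- score_records(records)
    re <- which(!is.na(records$reassessment_date) & !is.na(scored$score))
    n <- length(re)
    if (n == 0) {
      return(data.frame(case_id = character(0), service_code = character(0),
                        category = character(0), event_date = character(0),
                        stringsAsFactors = FALSE))
    }
    adate <- as.Date(records$assessment_date[re])
    window <- as.numeric(as.Date(records$reassessment_date[re]) - adate)
    score <- scored$score[re]
    mean_window <- mean(config$window_days)
    out <- vector("list", nrow(config$services))
    for (s in seq_len(nrow(config$services))) {
      sv <- config$services[s, ]
      base_rate <- -log(1 - sv$p_first) / mean_window
      rate <- base_rate * exp(sv$log_hr * (score - config$score_mu))
      t_first <- stats::rexp(n, rate)
      used <- t_first <= window
      if (!any(used)) next
      iu <- which(used)
      n_extra <- stats::rpois(length(iu),
                              sv$sessions_per_day *
                                (window[iu] - t_first[iu]))
      rows_per_case <- 1L + n_extra
      case_rep <- rep(iu, rows_per_case)
      day <- numeric(sum(rows_per_case))
      pos <- 1L
      for (j in seq_along(iu)) {
        i <- iu[j]
        d <- c(t_first[i],
               if (n_extra[j] > 0) {
                 sort(stats::runif(n_extra[j], t_first[i], window[i]))
               })
        day[pos:(pos + rows_per_case[j] - 1L)] <- d
        pos <- pos + rows_per_case[j]
      }
      out[[s]] <- data.frame(
        case_id = records$case_id[re][case_rep],
        service_code = sv$service_code,
        category = sv$category,
        event_date = as.character(adate[case_rep] + floor(day)),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
    rownames(out) <- NULL
    out
  })
}

#' Generate reassessment scoring items
#'
#' For every reassessed case, the true change in burden is the sum of the
#' per-service impact slopes times that case's usage counts inside the
#' window, plus Gaussian noise; the reassessment score is the initial score
#' plus that change, re-gridded and decomposed into items.
#'
#' @param records cohort record data.frame (reassessment dates set).
#' @param events event log from [generate_service_events()].
#' @param config generator configuration.
#' @return list: `records` with `reassess_*` item columns filled, and
#'   `truth` (per-reassessed-case usage counts, true deltas, slopes).
#' @export
generate_reassessment <- function(records, events, config) {
  with_seed(config$seed + 3L, {
    scored <- score_records(records)
    re <- which(!is.na(records$reassessment_date) & !is.na(scored$score))
    n <- length(re)
    if (n == 0) return(list(records = records, truth = NULL))
    sub <- records[re, , drop = FALSE]
    counts <- count_service_usage(sub, events)
    slopes <- config$services$impact_slope[
      match(colnames(counts), config$services$service_code)]
    slopes[is.na(slopes)] <- 0
    delta_true <- as.numeric(counts %*% slopes) +
      stats::rnorm(n, 0, config$delta_noise_sd)
    u2 <- to_grid_units(scored$score[re] + delta_true)
    items2 <- decompose_score_items(u2)
    for (col in score_item_names) {
      records[[paste0("reassess_", col)]][re] <- items2[[col]]
    }
    truth <- list(idx = re, counts = counts, delta_true = delta_true,
                  slopes = stats::setNames(slopes, colnames(counts)),
                  delta_noise_sd = config$delta_noise_sd)
    list(records = records, truth = truth)
  })
}

#' Simulate a full study dataset
#'
#' Composes [generate_cohort()], [generate_labels()],
#' [generate_service_events()] and [generate_reassessment()] into one
#' deterministic draw.
#'
#' @param config generator configuration (default:
#'   `default_generator_config()`).
#' @return list: `records`, `events`, `truth` (cohort truth plus a
#'   `reassessment` element), `config`.
#' @export
simulate_study <- function(config = default_generator_config()) {
  coh <- generate_cohort(config)
  records <- generate_labels(coh$records, config)
  events <- generate_service_events(records, config)
  rea <- generate_reassessment(records, events, config)
  truth <- coh$truth
  truth$reassessment <- rea$truth
  list(records = rea$records, events = events, truth = truth,
       config = config)
}
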