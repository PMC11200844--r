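# Shared fixture builders.  Everything is generated in code; no files.

# A minimal complete item set at the rubric minimum; override fields to
# build specific cases.
base_items <- function(...) {
  it <- data.frame(
    alone_duration = "over_9h", physical_burden = "no",
    sleep_disturbance = "no", qol_self_rating = "excellent",
    other_family_care = "no", behavior_distress = "no",
    emotional_behavioral_issues = "no", work_affected = "no",
    cannot_cope = "no", stringsAsFactors = FALSE
  )
  ov <- list(...)
  for (k in names(ov)) it[[k]] <- ov[[k]]
  it
}

# Minimal assessment-record table: n complete records at the item minimum
# with adult ages; override columns afterwards to create exclusions.
base_records <- function(n = 5) {
  rec <- cbind(
    data.frame(case_id = "c000",
               assessment_date = "2020-06-01",
               reassessment_date = NA_character_,
               recipient_gender = 1L, recipient_age = 80L,
               disability_certificate = 0L, dementia = 0L,
               foreign_caregiver = 0L, cms_level = 4L,
               caregiver_relationship = "adult_child",
               caregiver_age = 55L, stringsAsFactors = FALSE),
    base_items()
  )[rep(1, n), ]
  rownames(rec) <- NULL
  rec$case_id <- sprintf("c%03d", seq_len(n))
  for (col in paste0("reassess_", score_item_names)) {
    rec[[col]] <- rep(NA_character_, n)
  }
  for (col in c(paste0("psi_", 1:10), paste0("expert_vote_", 1:3))) {
    rec[[col]] <- rep(NA_integer_, n)
  }
  rec
}

# Small, fast generator configuration for pipeline-level tests.
small_config <- function(seed = 11, ...) {
  default_generator_config(seed = seed, n_total = 1500,
                           n_missing_score = 150, n_under18 = 20,
                           n_validation = 400, n_reassessed = 700, ...)
}

# A fresh validation subset (n = 1,791 labelled screening-era records)
# under the default label model; used to check calibration targets by
# Monte Carlo, since a single draw cannot resolve the stated bands.
draw_validation_subset <- function(seed) {
  cfg <- default_generator_config(seed = seed, n_total = 1900,
                                  n_missing_score = 0, n_under18 = 0,
                                  n_validation = 1791, n_reassessed = 100)
  rec <- generate_labels(generate_cohort(cfg)$records, cfg)
  inc <- score_records(apply_consort_filters(rec)$included)
  attach_labels(select_validation_subset(inc))
}

# The full default-size simulation is expensive (~20 s); build it once per
# test run and share it between the acceptance tests.
.sim_cache <- new.env(parent = emptyenv())
get_default_sim <- function(seed = 1L) {
  key <- paste0("seed_", seed)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_study(default_generator_config(seed = seed))
  }
  .sim_cache[[key]]
}
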