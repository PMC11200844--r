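# Oracles: hand product-limit arithmetic, hand observed-minus-expected
# log-rank tables, and direct maximization of a hand-written Cox partial
# likelihood (tie-free, where Efron/Breslow/exact coincide).

make_samples <- function(duration, event, score = NULL) {
  n <- length(duration)
  s <- base_records(n)
  s$duration <- duration
  s$event <- event
  s$score <- if (is.null(score)) rep(5, n) else score
  s$group <- dichotomize(s$score, 4.4)
  s
}

logrank_oracle <- function(d1, e1, d2, e2) {
  times <- sort(unique(c(d1[e1 == 1], d2[e2 == 1])))
  o_minus_e <- 0; v <- 0
  for (t in times) {
    n1 <- sum(d1 >= t); n2 <- sum(d2 >= t); nt <- n1 + n2
    ev1 <- sum(d1 == t & e1 == 1); evt <- ev1 + sum(d2 == t & e2 == 1)
    o_minus_e <- o_minus_e + ev1 - evt * n1 / nt
    if (nt > 1) v <- v + evt * (n1 / nt) * (n2 / nt) * (nt - evt) / (nt - 1)
  }
  o_minus_e^2 / v
}

cox_logpl <- function(b, duration, event, x) {
  # tie-free partial likelihood, one covariate
  ll <- 0
  for (i in which(event == 1)) {
    risk <- duration >= duration[i]
    ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
  }
  ll
}

test_that("time-to-first-use samples honor the observation window", {
  rec <- base_records(5)
  rec$assessment_date <- "2020-01-01"
  rec$reassessment_date <- "2020-12-26"       # 360-day window
  rec$score <- c(5, 5, 3, 5, 5)
  ev <- data.frame(
    case_id = c("c001", "c002", "c002", "c004", "c004", "c005"),
    service_code = "respite", category = "IV",
    event_date = c("2020-04-10",                  # day 100
                   "2020-02-20", "2020-04-01",    # days 50 and 90: first=50
                   "2019-12-15",                  # before assessment
                   "2021-02-01",                  # after reassessment
                   "2020-01-01"),                 # assessment day -> 0.5
    stringsAsFactors = FALSE)
  s <- build_time_to_first(rec, ev, "respite")
  expect_equal(s$duration, c(100, 50, 360, 360, 0.5))
  expect_equal(s$event, c(1L, 1L, 0L, 0L, 1L))
  expect_equal(s$group, c("high", "high", "not_high", "high", "high"))
  ign <- attr(s, "ignored")
  expect_equal(unname(ign["before_assessment"]), 1)
  expect_equal(unname(ign["after_reassessment"]), 1)
})

test_that("dichotomize uses strict inequality at the cut-point", {
  expect_equal(dichotomize(c(4.6, 4.4, 0.0), 4.4),
               c("high", "not_high", "not_high"))
})

test_that("Kaplan-Meier matches hand product-limit arithmetic", {
  # durations (2, 4+, 6): S = 2/3 on [2,6), then 0
  km <- kaplan_meier(make_samples(c(2, 4, 6), c(1, 0, 1)))
  expect_equal(km$time, c(2, 4, 6))
  expect_equal(km$surv, c(2 / 3, 2 / 3, 0))
  # all censored: S stays 1
  km1 <- kaplan_meier(make_samples(c(3, 5), c(0, 0)))
  expect_true(all(km1$surv == 1))
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(31)
  d <- sample(1:50, 25, replace = TRUE)
  km <- kaplan_meier(make_samples(d, rep(1, 25)))
  for (i in seq_along(km$time)) {
    expect_equal(km$surv[i], mean(d > km$time[i]))
  }
})

test_that("log-rank matches the hand observed-expected oracle", {
  a <- make_samples(c(1, 3, 5), c(1, 1, 1))
  b <- make_samples(c(2, 4, 6), c(1, 1, 0))
  lr <- logrank(a, b)
  expect_equal(lr$statistic,
               logrank_oracle(a$duration, a$event, b$duration, b$event),
               tolerance = 1e-9)
  # identical groups: statistic 0
  lr0 <- logrank(a, a)
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_error(logrank(make_samples(3, 0), make_samples(4, 0)), "no events")
  # strongly separated hazards at moderate n
  set.seed(32)
  fast <- make_samples(rexp(150, 1), rep(1, 150))
  slow <- make_samples(rexp(150, 0.2), rep(1, 150))
  expect_lt(logrank(fast, slow)$p_value, 0.001)
})

test_that("cox_fit equals grid-maximized partial likelihood (n <= 20)", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(8:20, 1)
    x <- round(rnorm(n, 0, 1), 2)
    d <- round(rexp(n, exp(0.5 * x)), 6)       # tie-free a.s.
    ev <- rbinom(n, 1, 0.8)
    if (sum(ev) < 2 || length(unique(x)) < 2) next
    s <- make_samples(d, ev, score = x)
    fit <- cox_fit(s, covariates = character(0))
    opt <- optimize(function(b) -cox_logpl(b, d, ev, x), c(-8, 8),
                    tol = 1e-9)
    expect_equal(fit$log_hr, opt$minimum, tolerance = 1e-4)
  }
})

test_that("cox HR approximates the exponential rate ratio (no censoring)", {
  set.seed(34)
  x <- rep(c(0, 1), each = 300)
  d <- rexp(600, ifelse(x == 1, 0.9, 0.3))
  s <- make_samples(d, rep(1, 600), score = x)
  fit <- cox_fit(s, covariates = character(0))
  rate_ratio <- (300 / sum(d[x == 1])) / (300 / sum(d[x == 0]))
  expect_equal(fit$log_hr, log(rate_ratio), tolerance = 0.15)
  expect_equal(fit$hr, exp(fit$log_hr))
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
})

test_that("cox_fit null exposure gives HR near 1 and rejects degeneracy", {
  set.seed(35)
  s <- make_samples(rexp(400, 0.5), rbinom(400, 1, 0.7),
                    score = rnorm(400))
  fit <- cox_fit(s, covariates = character(0))
  expect_true(fit$ci_low < 1 && 1 < fit$ci_high)
  expect_error(cox_fit(make_samples(c(1, 2), c(0, 0))), "at least one event")
  expect_error(cox_fit(make_samples(c(1, 2), c(1, 1), score = c(3, 3))),
               "does not vary")
})

test_that("top_services ranks by unique cases, then events, then code", {
  ev <- data.frame(
    case_id = c("a", "b", "c",          # svc1: 3 cases, 3 events
                "a", "a", "b",          # svc2: 2 cases, 3 events
                "a", "b"),              # svc3: 2 cases, 2 events
    service_code = c("svc1", "svc1", "svc1",
                     "svc2", "svc2", "svc2", "svc3", "svc3"),
    category = "I",
    event_date = "2020-06-01", stringsAsFactors = FALSE)
  expect_equal(top_services(ev), c("svc1", "svc2", "svc3"))
  expect_equal(top_services(ev, k = 2), c("svc1", "svc2"))
  expect_equal(top_services(ev[0, ]), character(0))
})
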