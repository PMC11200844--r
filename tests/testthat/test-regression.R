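test_that("ols_fit recovers exact linear data and the intercept-only mean", {
  x <- 1:10
  fit <- ols_fit(2 * x + 1, cbind(x = x))
  expect_equal(fit$beta[fit$term == "x"], 2)
  expect_equal(fit$beta[fit$term == "(Intercept)"], 1)
  y <- c(3, 5, 8, 9)
  fit0 <- ols_fit(y, matrix(numeric(0), nrow = 4, ncol = 0))
  expect_equal(fit0$beta, mean(y))
})

test_that("ols_fit equals the normal-equation oracle on random instances", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(10:50, 1); p <- sample(1:5, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("v", 1:p)))
    y <- rnorm(n)
    fit <- ols_fit(y, X)
    Xi <- cbind(1, X)
    beta_o <- solve(t(Xi) %*% Xi, t(Xi) %*% y)   # normal equations
    resid <- y - Xi %*% beta_o
    s2 <- sum(resid^2) / (n - p - 1)
    se_o <- sqrt(s2 * diag(solve(t(Xi) %*% Xi)))
    expect_equal(fit$beta, as.numeric(beta_o), tolerance = 1e-8)
    expect_equal(fit$se, as.numeric(se_o), tolerance = 1e-8)
    expect_equal(fit$t_stat, fit$beta / fit$se)
    expect_equal(fit$p_value,
                 2 * pt(abs(fit$t_stat), n - p - 1, lower.tail = FALSE))
  }
})

test_that("rank-deficient columns are dropped and reported", {
  set.seed(22)
  x <- rnorm(30)
  X <- cbind(a = x, b = x, c = rnorm(30))   # b aliased with a
  fit <- ols_fit(rnorm(30), X)
  expect_equal(attr(fit, "dropped"), "b")
  expect_setequal(fit$term, c("(Intercept)", "a", "c"))
})

test_that("screening recovers an injected effect and skips bad features", {
  set.seed(23)
  n <- 2000
  rec <- base_records(n)
  rec$cms_level <- sample(1:8, n, replace = TRUE)
  rec$caregiver_relationship <- sample(c("spouse", "adult_child"), n,
                                       replace = TRUE)
  rec$feat_target <- rbinom(n, 1, 0.3)
  rec$feat_noise <- rbinom(n, 1, 0.5)
  rec$feat_constant <- 1
  rec$feat_alias <- rec$cms_level          # duplicates a covariate
  rec$score <- 2 + 0.8 * rec$feat_target + 0.1 * rec$cms_level + rnorm(n)
  tab <- screen_risk_factors(rec)
  expect_setequal(attr(tab, "skipped"), c("feat_constant", "feat_alias"))
  row <- tab[tab$term == "feat_target", ]
  expect_lt(abs(row$beta - 0.8), 1.96 * row$se)
  expect_lt(row$p_value, 1e-10)
  expect_gt(tab$p_value[tab$term == "feat_noise"], 0.001)
  expect_equal(tab$p_value, sort(tab$p_value))   # sorted by p
})

test_that("significance summary counts by sign with a BH companion", {
  tab <- data.frame(term = letters[1:5],
                    beta = c(1, -2, 3, -4, 5),
                    p_value = c(0.01, 0.04, 0.2, 0.001, 1))
  s <- significance_summary(tab, alpha = 0.05)
  expect_equal(s$n_significant, 3)
  expect_equal(s$n_positive, 1)   # a (beta  1, p 0.01)
  expect_equal(s$n_negative, 2)   # b, d (beta -2 and -4)
  expect_equal(s$n_significant_bh,
               sum(p.adjust(tab$p_value, "BH") < 0.05))
  expect_equal(significance_summary(
    data.frame(term = "a", beta = 1, p_value = 1))$n_significant, 0)
})

test_that("null features show nominal type-I error under a fixed seed", {
  # scaled down from the spec's 10,000 replicates to 1,200 null features
  # on n = 400 records; binomial SE of the rate is ~0.006
  set.seed(24)
  n <- 400
  rec <- base_records(n)
  rec$cms_level <- sample(1:8, n, replace = TRUE)
  rec$score <- rnorm(n, 4, 1.7)
  F <- matrix(rbinom(n * 1200, 1, 0.3), n, 1200,
              dimnames = list(NULL, paste0("feat_n", 1:1200)))
  rec <- cbind(rec, F)
  tab <- screen_risk_factors(rec)
  rate <- mean(tab$p_value < 0.05)
  expect_gt(rate, 0.05 - 0.02)
  expect_lt(rate, 0.05 + 0.02)
})

test_that("usage counting respects the observation window", {
  rec <- base_records(2)
  rec$assessment_date <- "2020-01-01"
  rec$reassessment_date <- "2020-12-31"
  ev <- data.frame(
    case_id = c("c001", "c001", "c001", "c002", "c999"),
    service_code = "meal", category = "other",
    event_date = c("2019-12-31",   # before window: ignored
                   "2020-01-01", "2020-06-01",  # inside
                   "2021-01-05",   # after window: ignored
                   "2020-06-01"),  # unknown case: ignored
    stringsAsFactors = FALSE)
  cnt <- count_service_usage(rec, ev)
  expect_equal(as.integer(cnt[, "meal"]), c(2L, 0L))
})

test_that("service-impact regression enforces the unique-case floor", {
  set.seed(25)
  n <- 300
  rec <- base_records(n)
  rec$assessment_date <- "2020-01-01"
  rec$reassessment_date <- "2020-12-01"
  rec$cms_level <- sample(1:8, n, replace = TRUE)
  users <- sample(n, 60)
  counts <- rpois(60, 40) + 1
  ev <- data.frame(
    case_id = rep(rec$case_id[users], counts),
    service_code = "svc_a", category = "I",
    event_date = "2020-06-01", stringsAsFactors = FALSE)
  # a second service with only 29 unique users: must be excluded
  ev29 <- data.frame(case_id = rec$case_id[sample(n, 29)],
                     service_code = "svc_b", category = "I",
                     event_date = "2020-06-01", stringsAsFactors = FALSE)
  events <- rbind(ev, ev29)
  slope <- -0.02
  cnt <- count_service_usage(rec, events)
  delta <- slope * cnt[, "svc_a"] + rnorm(n, 0, 0.3)
  rec$score <- 4
  rec$reassess_score <- 4 + delta
  tab <- service_impact_regression(rec, events, min_unique = 30)
  expect_equal(tab$term, "svc_a")
  expect_equal(attr(tab, "excluded"), "svc_b")
  expect_equal(tab$noc, 60)
  expect_lt(abs(tab$beta - slope), 1.96 * tab$se)
  # zero-usage cohort -> empty table
  empty <- service_impact_regression(
    rec, events[0, , drop = FALSE], min_unique = 30)
  expect_equal(nrow(empty), 0)
})
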