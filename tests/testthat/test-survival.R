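test_that("Cox fit equals the brute-force partial-likelihood maximizer", {
  # alternating covariate so the partial likelihood has a finite maximum
  time <- c(1, 2, 3, 4)
  event <- c(1, 1, 1, 1)
  x <- c(1, 0, 1, 0)
  for (ties in c("efron", "breslow")) {
    f <- cox_fit(x, time, event, ties = ties)
    expect_lt(abs(f$beta - cox_oracle_beta(x, time, event, ties)), 1e-3)
  }
})

test_that("Cox oracle agreement holds with ties and censoring", {
  set.seed(23)
  for (rep in 1:10) {
    n <- 6
    time <- sample(1:4, n, replace = TRUE)   # forces tied event times
    event <- rbinom(n, 1, 0.8)
    if (sum(event) < 2) event[1:2] <- 1
    x <- round(rnorm(n), 1)
    if (var(x) == 0) x[1] <- x[1] + 1
    for (ties in c("efron", "breslow")) {
      f <- cox_fit(x, time, event, ties = ties)
      if (abs(f$beta) < 4.5) # keep clear of the oracle's search boundary
        expect_lt(abs(f$beta - cox_oracle_beta(x, time, event, ties)),
                  1e-3)
    }
  }
})

test_that("degenerate Cox inputs are flagged or rejected", {
  expect_error(cox_fit(1:4, c(1, 2, 3, 4), c(0, 0, 0, 0)),
               "at least one event")
  f <- cox_fit(rep(2, 4), c(1, 2, 3, 4), c(1, 1, 1, 0))
  expect_false(f$informative)
  expect_equal(f$HR, 1)
  expect_equal(f$se, Inf)
})

test_that("multivariate fit adjusts for age and grade", {
  d <- simulate_two_group_survival(60, 60, hr = 2.5, seed = 5)
  covars <- data.frame(age = round(runif(120, 25, 50)),
                       grade = sample(1:3, 120, replace = TRUE))
  f <- cox_fit(as.numeric(d$group == "high"), d$time, d$event,
               covariates = covars)
  expect_identical(f$model, "multivariate")
  expect_true(f$ci[1] < f$HR && f$HR < f$ci[2])
  expect_gt(f$HR, 1)
})

test_that("permutation P respects its formula bounds and reproducibility", {
  d <- simulate_two_group_survival(30, 30, hr = 8, censoring_fraction = 0,
                                   seed = 2)
  x <- as.numeric(d$group == "high")
  p <- permutation_pvalue(x, d$time, d$event, B = 99, seed = 7)
  # a strong association beats every permutation: P at the 1/(B+1) floor
  expect_equal(p$perm_p, 1 / 100)
  p2 <- permutation_pvalue(x, d$time, d$event, B = 99, seed = 7)
  expect_identical(p$perm_p, p2$perm_p)
  expect_gte(p$perm_p, 1 / (99 + 1))
  expect_error(permutation_pvalue(x, d$time, d$event, B = 0), "B must be")
})

test_that("Kaplan-Meier estimate matches hand product-limit computations", {
  k <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(k$time, c(1, 2, 3))
  expect_equal(k$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(k$median, 2)  # smallest t with S <= 0.5
  # censoring at 2: risk sets 3 then 1
  k2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(k2$time, c(1, 3))
  expect_equal(k2$surv, c(2 / 3, 0))
  # all censored: S stays at 1, median undefined
  k3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_length(k3$time, 0)
  expect_true(is.na(k3$median))
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(3)
  time <- rexp(40, 0.1)
  k <- km_estimate(time, rep(1, 40))
  ecdf_surv <- vapply(k$time, function(t) mean(time > t), numeric(1))
  expect_equal(k$surv, ecdf_surv)
  expect_equal(km_oracle(time, rep(1, 40))$surv, k$surv)
})

test_that("log-rank matches hand computation and the Cox score test", {
  # identical groups: statistic 0
  lr0 <- logrank_test(c(1, 2, 1, 2), c(1, 1, 1, 1), c("a", "a", "b", "b"))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  # toy: A events at 1,2; B events at 3,4
  # risk sets: t=1 (2A,2B) E_A=.5; t=2 (1A,2B) E_A=1/3; t=3,4: no A at risk
  # O_A - E_A = 2 - 5/6; V = sum of hypergeometric variances
  time <- c(1, 2, 3, 4); event <- rep(1, 4)
  group <- c("A", "A", "B", "B")
  v <- (2 * 2) / (4^2) + (1 * 2) / (3^2)
  chisq_hand <- (2 - 5 / 6)^2 / v
  lr <- logrank_test(time, event, group)
  expect_equal(lr$chisq, chisq_hand, tolerance = 1e-10)
  expect_equal(lr$df, 1)
  expect_error(logrank_test(time, event, rep("a", 4)), "two non-empty")
})

test_that("log-rank is calibrated under the null", {
  ps <- vapply(1:200, function(s) {
    set.seed(s + 1000)
    time <- rexp(100, 0.05)
    event <- rbinom(100, 1, 0.8)
    logrank_test(time, event, rep(c("a", "b"), 50))$p
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.02)
})

test_that("risk scores split the cohort at the median with ties low", {
  beta <- c(m1 = 0.5, m2 = -0.25)
  exprs <- rbind(m1 = c(1:10), m2 = rep(0, 10))
  colnames(exprs) <- sprintf("s%02d", 1:10)
  rs <- risk_score(beta, exprs)
  expect_equal(sum(rs$group == "high"), 5)
  expect_equal(sum(rs$group == "low"), 5)
  expect_equal(rs$score, 0.5 * (1:10))
  # ties at the median go low
  exprs2 <- rbind(m1 = c(1, 2, 2, 3), m2 = rep(0, 4))
  colnames(exprs2) <- sprintf("s%d", 1:4)
  rs2 <- risk_score(beta, exprs2)
  expect_equal(unname(table(rs2$group)["low"]), 3)
  # all-zero coefficients: degenerate flag
  rs3 <- risk_score(c(m1 = 0), exprs)
  expect_true(attr(rs3, "degenerate"))
  expect_true(all(rs3$group == "low"))
  expect_error(risk_score(c(absent = 1), exprs), "missing")
})

test_that("signature assembly recovers planted prognostic miRNAs", {
  betas <- stats::setNames(c(0.8, -0.8, 0.7, -0.7),
                           sprintf("miR-sim-%03d", 1:4))
  hits <- vapply(1:3, function(s) {
    cfg <- survival_config(n_tumor = 300, betas = betas, seed = s,
                           n_mirna = 24)
    co <- simulate_cohort(cfg)
    x <- tumor_log2(co)
    covars <- data.frame(age = co$samples$age, grade = co$samples$grade)
    sig <- build_signature(x, co$samples$os_months, co$samples$os_event,
                           covariates = covars, alpha = 0.05, B = 99,
                           seed = s)
    found <- intersect(sig$members$feature, names(betas))
    false_pos <- setdiff(sig$members$feature, names(betas))
    # labels follow the sign of the planted log hazard
    lab <- sig$members[sig$members$feature %in% names(betas), ]
    expect_true(all((betas[lab$feature] < 0) ==
                      (lab$label == "protective")))
    length(found) >= 3 && length(false_pos) <= 1
  }, logical(1))
  expect_gte(sum(hits), 2)
})

test_that("no significant candidate yields an explicit empty signature", {
  cfg <- survival_config(n_tumor = 40, seed = 9, n_mirna = 5)
  co <- simulate_cohort(cfg)
  sig <- build_signature(tumor_log2(co), co$samples$os_months,
                         co$samples$os_event, alpha = 1e-6, B = 19,
                         seed = 1)
  expect_s3_class(sig, "signature_def")
  expect_equal(nrow(sig$members), 0)
  expect_output(print(sig), "Empty signature")
})

test_that("group hazard ratio reports Cox, KM medians and log-rank", {
  d <- simulate_two_group_survival(40, 40, hr = 3, censoring_fraction = 0.2,
                                   seed = 4)
  groups <- data.frame(sample = seq_len(80), group = d$group)
  g <- group_hazard_ratio(groups, d$time, d$event)
  expect_gt(g$cox$HR, 1.5)
  expect_true(g$medians[["high"]] < g$medians[["low"]])
  expect_lt(g$logrank$p, 0.05)
  # identical survival in both groups: HR near 1
  d0 <- simulate_two_group_survival(50, 50, hr = 1, seed = 11)
  g0 <- group_hazard_ratio(data.frame(group = d0$group), d0$time, d0$event)
  expect_lt(abs(log(g0$cox$HR)), 0.5)
  # binary toy with no censoring agrees with the grid-search oracle
  tt <- c(1, 2, 3, 4, 5, 6)
  ee <- rep(1, 6)
  gg <- c("high", "low", "high", "low", "high", "low")
  gfit <- group_hazard_ratio(data.frame(group = gg), tt, ee)
  expect_lt(abs(gfit$cox$beta -
                  cox_oracle_beta(as.numeric(gg == "high"), tt, ee)), 1e-3)
})

test_that("log-rank equals the Cox score test for a binary covariate", {
  set.seed(31)
  for (rep in 1:5) {
    time <- round(rexp(30, 0.1), 2)
    event <- rbinom(30, 1, 0.7)
    if (sum(event) < 2) event[1:2] <- 1
    group <- rep(c("a", "b"), 15)
    lr <- logrank_test(time, event, group)
    sc <- survival::coxph(survival::Surv(time, event) ~ I(group == "b"))
    expect_equal(lr$chisq, sc$score, tolerance = 1e-8)
  }
})
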