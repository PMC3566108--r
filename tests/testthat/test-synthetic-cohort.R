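test_that("identical config and seed give a bit-identical cohort", {
  cfg <- tiny_config(seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$mirna_counts, b$mirna_counts)
  expect_identical(a$mrna_counts, b$mrna_counts)
  expect_identical(a$samples, b$samples)
  c2 <- simulate_cohort(tiny_config(seed = 100))
  expect_false(identical(a$mirna_counts, c2$mirna_counts))
})

test_that("cohort structure satisfies its invariants", {
  co <- simulate_cohort(tiny_config(seed = 5))
  expect_true(all(co$mirna_counts >= 0))
  expect_true(all(co$mirna_counts == round(co$mirna_counts)))
  expect_true(all(co$samples$tissue %in% c("normal", "tumor", "mets")))
  tum <- co$samples$tissue == "tumor"
  expect_true(all(co$samples$os_months[tum] > 0))
  # matched pairs share patient ids across the normal/tumor classes
  matched <- names(which(table(co$samples$patient) == 2))
  expect_length(matched, 4)
  for (p in matched)
    expect_setequal(co$samples$tissue[co$samples$patient == p],
                    c("normal", "tumor"))
})

test_that("null planted effects give near-zero empirical logFC", {
  co <- simulate_cohort(tiny_config(seed = 7, n_normal = 60, n_tumor = 60,
                                    n_mets = 0, n_matched_pairs = 0))
  x <- log2(co$mirna_counts + 1)
  tum <- co$samples$tissue == "tumor"
  diff <- rowMeans(x[, tum]) - rowMeans(x[, !tum])
  se <- sqrt(apply(x[, tum], 1, var) / 60 + apply(x[, !tum], 1, var) / 60)
  expect_true(mean(abs(diff) < 3 * se) > 0.9)
})

test_that("a planted tumor shift is recovered within 3 standard errors", {
  cfg <- tiny_config(seed = 11, n_normal = 60, n_tumor = 60, n_mets = 0,
                     n_matched_pairs = 0,
                     planted_de = data.frame(probe = "miR-sim-001",
                                             comparison = "N_vs_T",
                                             logFC = 2.29))
  co <- simulate_cohort(cfg)
  x <- log2(co$mirna_counts["miR-sim-001", ] + 1)
  tum <- co$samples$tissue == "tumor"
  est <- mean(x[tum]) - mean(x[!tum])
  se <- sqrt(var(x[tum]) / 60 + var(x[!tum]) / 60)
  expect_lt(abs(est - 2.29), 3 * se)
})

test_that("duplicate or unknown planted probes are rejected", {
  expect_error(tiny_config(planted_de = data.frame(
    probe = "nope", comparison = "N_vs_T", logFC = 1)), "unknown probes")
  expect_error(simulation_config(n_normal = 2, n_tumor = 2, n_mets = 0,
                                 n_matched_pairs = 0,
                                 survival = list(betas = c(bad = 1),
                                                 baseline_hazard = 0.01,
                                                 censoring_fraction = 0)),
               "miRNA probe ids")
})

test_that("null survival betas give HR near 1 with nominal CI coverage", {
  covered <- vapply(1:50, function(s) {
    co <- simulate_cohort(survival_config(n_tumor = 60, seed = s))
    x <- tumor_log2(co)[1, ]
    f <- cox_fit(x, co$samples$os_months, co$samples$os_event)
    f$ci[1] <= 1 && 1 <= f$ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("zero censoring fraction yields events for every subject", {
  co <- simulate_cohort(survival_config(n_tumor = 40, censoring = 0,
                                        seed = 3))
  expect_true(all(co$samples$os_event == 1))
  expect_true(all(co$samples$ddfs_event == 1))
})

test_that("censoring tuner approximates the requested fraction", {
  fracs <- vapply(1:20, function(s) {
    co <- simulate_cohort(survival_config(n_tumor = 200, censoring = 0.3,
                                          seed = s))
    mean(co$samples$os_event == 0)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.3), 0.03)
})

test_that("a doubled hazard doubles the event rate (exponential closed form)", {
  # binary x in {0,1} with beta = ln 2: event-time rates are h0 and 2*h0,
  # so the ratio of mean event rates (1/mean time) estimates 2.
  set.seed(42)
  h0 <- 0.001  # small baseline hazard
  t0 <- rexp(20000, h0)
  t1 <- rexp(20000, h0 * exp(log(2)))
  expect_lt(abs(mean(t0) / mean(t1) - 2), 0.1)
  # and the generator reproduces this: plant beta = ln 2 on a miRNA whose
  # log2 expression is two-valued via near-zero noise and planted shift
  co <- simulate_cohort(survival_config(n_tumor = 3000, betas = c(
    "miR-sim-001" = log(2)), censoring = 0, noise_sd = 2, seed = 8))
  x <- tumor_log2(co)[1, ]
  f <- cox_fit(x, co$samples$os_months, co$samples$os_event)
  expect_lt(abs(f$HR - 2), 0.1)
})

test_that("no survival model gives an all-censored cohort with warning", {
  cfg <- tiny_config(seed = 2)
  cfg$survival <- NULL
  co <- simulate_expression(cfg)
  expect_warning(co <- simulate_survival(cfg, co), "all censored")
  tum <- co$samples$tissue == "tumor"
  expect_true(all(co$samples$os_event[tum] == 0))
})

test_that("target predictions emit planted pairs exactly when no decoys", {
  pp <- data.frame(mirna = c("miR-sim-001", "miR-sim-002"),
                   gene = c("GENE001", "GENE002"),
                   slope = -1, noise_sd = 0.1)
  cfg <- tiny_config(seed = 4, planted_pairs = pp, n_decoy_pairs = 0)
  pred <- generate_target_predictions(cfg)
  expect_identical(pred$mirna, pp$mirna)
  expect_identical(pred$gene, pp$gene)
  cfg2 <- tiny_config(seed = 4, planted_pairs = pp, n_decoy_pairs = 25)
  pred2 <- generate_target_predictions(cfg2)
  expect_equal(nrow(pred2), 27)
  expect_equal(anyDuplicated(paste(pred2$mirna, pred2$gene)), 0)
})

test_that("a planted pair with slope -1 and low noise is near-perfectly
          anti-correlated", {
  pp <- data.frame(mirna = "miR-sim-001", gene = "GENE001",
                   slope = -1, noise_sd = 0.1)
  co <- simulate_cohort(tiny_config(seed = 6, n_normal = 0, n_tumor = 50,
                                    n_mets = 0, n_matched_pairs = 0,
                                    planted_pairs = pp))
  r <- cor(log2(co$mirna_counts["miR-sim-001", ] + 1),
           log2(co$mrna_counts["GENE001", ] + 1))
  # r = slope * sd(x) / sd(y) with sd(y) = sqrt(slope^2 sd(x)^2 + noise^2)
  expect_lt(r, -0.9)
})

test_that("write_cohort/read_cohort round-trips the tables losslessly", {
  co <- simulate_cohort(tiny_config(seed = 13, n_decoy_pairs = 5,
                                    planted_pairs = data.frame(
                                      mirna = "miR-sim-001", gene = "GENE001",
                                      slope = -1, noise_sd = 0.2)))
  dir <- withr::local_tempdir()
  write_cohort(co, dir, rcc = TRUE)
  back <- read_cohort(dir)
  expect_identical(back$mirna_counts, co$mirna_counts)
  expect_identical(back$negctrl_counts, co$negctrl_counts)
  expect_equal(back$samples$sample, co$samples$sample)
  expect_equal(back$samples$os_months, co$samples$os_months)
  expect_equal(back$predictions, co$predictions)
  # RCC-like files carry the per-sample counts in their Code_Summary
  rcc <- readLines(file.path(dir, "rcc", paste0(co$samples$sample[1], ".rcc")))
  expect_true(any(grepl("^Endogenous,miR-sim-001,", rcc)))
})

test_that("two-group survival generator hits the requested hazard ratio", {
  hrs <- vapply(1:30, function(s) {
    d <- simulate_two_group_survival(100, 100, hr = 2, seed = s)
    f <- cox_fit(as.numeric(d$group == "high"), d$time, d$event)
    f$HR
  }, numeric(1))
  expect_lt(abs(mean(hrs) - 2) / 2, 0.05)
})
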