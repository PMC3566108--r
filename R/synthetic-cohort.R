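#' Configure a synthetic three-tissue-class cohort
#'
#' Builds the configuration object consumed by [simulate_cohort()]. The
#' generator emulates the data structure of an nCounter-style profiling
#' study of triple-negative breast cancer: miRNA and mRNA count matrices
#' over three tissue classes (adjacent normal, primary tumor, nodal
#' metastasis), per-sample negative-control probes, matched normal/tumor
#' pairs sharing a patient id, proportional-hazards survival for tumor
#' samples, and planted miRNA:mRNA regulatory pairs. Defaults mirror a
#' cohort of 59 normal, 165 tumor and 54 metastasis samples with 55
#' matched pairs.
#'
#' Expression model: per-probe baseline log2 means are drawn uniformly
#' from `baseline_log2_range`; planted log2 fold changes shift the class
#' means (sign convention: second class minus first, classes ordered
#' normal < tumor < mets, so `N_vs_T` shifts tumor, `N_vs_M` and `T_vs_M`
#' shift mets); matched patients add a shared random intercept; Gaussian
#' noise with `noise_sd` is added on the log2 scale and counts are
#' `round(2^x)`. Negative controls are Poisson with mean `negctrl_mean`.
#'
#' Survival model: event times for tumor samples are exponential with
#' hazard `h0 * exp(sum(beta_i * x_i))` where `x_i` is true log2
#' expression, so `exp(beta)` is the hazard ratio per 2-fold expression
#' change. Censoring is independent uniform on `[0, T_max]` with `T_max`
#' tuned to achieve approximately `censoring_fraction`.
#'
#' @param n_normal,n_tumor,n_mets samples per tissue class (nonnegative,
#'   at least 2 in total).
#' @param n_matched_pairs matched normal/tumor pairs sharing a patient id
#'   (`<= min(n_normal, n_tumor)`).
#' @param n_mirna,n_mrna,n_negctrl probe counts (positive).
#' @param planted_de `NULL` or data frame with columns `probe`,
#'   `comparison` (one of `"N_vs_T"`, `"N_vs_M"`, `"T_vs_M"`) and `logFC`
#'   (log2 units). Probes may be miRNA or mRNA ids.
#' @param noise_sd per-sample log2 noise SD (> 0).
#' @param baseline_log2_range range of per-probe baseline log2 means.
#' @param survival `NULL` for no survival model (all-censored cohort,
#'   with a warning) or a list with elements `betas` (named numeric, log
#'   hazard per log2 unit; names are miRNA probe ids; may be empty),
#'   `baseline_hazard` (events per month) and `censoring_fraction`
#'   (in `[0, 1)`).
#' @param planted_pairs `NULL` or data frame with columns `mirna`,
#'   `gene`, `slope` and `noise_sd`: the gene's log2 expression is
#'   `baseline + slope * (x_mirna - mean(x_mirna)) + noise`.
#' @param n_decoy_pairs decoy miRNA:gene pairs emitted by
#'   [generate_target_predictions()] in addition to the planted ones.
#' @param age_range,grade_levels sampling ranges for the age (years) and
#'   ordinal tumor grade covariates; drawn independently of expression.
#' @param negctrl_mean Poisson mean of negative-control counts.
#' @param patient_intercept_sd SD of the shared per-patient log2
#'   intercept for matched pairs.
#' @param seed integer seed; identical config and seed give a
#'   bit-identical cohort.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
simulation_config <- function(n_normal = 59, n_tumor = 165, n_mets = 54,
                              n_matched_pairs = 55,
                              n_mirna = 200, n_mrna = 150, n_negctrl = 6,
                              planted_de = NULL,
                              noise_sd = 0.5,
                              baseline_log2_range = c(4, 10),
                              survival = list(betas = numeric(0),
                                              baseline_hazard = 0.01,
                                              censoring_fraction = 0.2),
                              planted_pairs = NULL,
                              n_decoy_pairs = 0,
                              age_range = c(25, 70),
                              grade_levels = 1:3,
                              negctrl_mean = 5,
                              patient_intercept_sd = 0.3,
                              seed = 1L) {
  cfg <- list(n_normal = as.integer(n_normal), n_tumor = as.integer(n_tumor),
              n_mets = as.integer(n_mets),
              n_matched_pairs = as.integer(n_matched_pairs),
              n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
              n_negctrl = as.integer(n_negctrl),
              planted_de = planted_de, noise_sd = noise_sd,
              baseline_log2_range = baseline_log2_range,
              survival = survival, planted_pairs = planted_pairs,
              n_decoy_pairs = as.integer(n_decoy_pairs),
              age_range = age_range, grade_levels = grade_levels,
              negctrl_mean = negctrl_mean,
              patient_intercept_sd = patient_intercept_sd,
              seed = as.integer(seed))
  cfg$mirna_ids <- sprintf("miR-sim-%03d", seq_len(cfg$n_mirna))
  cfg$mrna_ids <- sprintf("GENE%03d", seq_len(cfg$n_mrna))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  n_class <- c(cfg$n_normal, cfg$n_tumor, cfg$n_mets)
  if (any(n_class < 0) || sum(n_class) < 2)
    stop("class sizes must be nonnegative with at least 2 samples in total")
  if (cfg$n_matched_pairs > min(cfg$n_normal, cfg$n_tumor))
    stop("n_matched_pairs exceeds min(n_normal, n_tumor)")
  if (any(c(cfg$n_mirna, cfg$n_mrna, cfg$n_negctrl) < 1))
    stop("probe counts must be positive")
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0)
    stop("noise_sd must be > 0")
  all_ids <- c(cfg$mirna_ids, cfg$mrna_ids)
  if (!is.null(cfg$planted_de)) {
    stopifnot(all(c("probe", "comparison", "logFC") %in% names(cfg$planted_de)))
    if (!all(cfg$planted_de$comparison %in% c("N_vs_T", "N_vs_M", "T_vs_M")))
      stop("planted_de comparison must be one of N_vs_T, N_vs_M, T_vs_M")
    missing <- setdiff(cfg$planted_de$probe, all_ids)
    if (length(missing))
      stop("planted_de references unknown probes: ",
           paste(missing, collapse = ", "))
  }
  if (!is.null(cfg$survival)) {
    sv <- cfg$survival
    if (!is.null(sv$betas) && length(sv$betas)) {
      if (is.null(names(sv$betas)) ||
          !all(names(sv$betas) %in% cfg$mirna_ids))
        stop("survival betas must be named by existing miRNA probe ids")
    }
    if (sv$baseline_hazard <= 0) stop("baseline_hazard must be > 0")
    if (sv$censoring_fraction < 0 || sv$censoring_fraction >= 1)
      stop("censoring_fraction must be in [0, 1)")
  }
  if (!is.null(cfg$planted_pairs)) {
    pp <- cfg$planted_pairs
    stopifnot(all(c("mirna", "gene", "slope", "noise_sd") %in% names(pp)))
    if (!all(pp$mirna %in% cfg$mirna_ids) || !all(pp$gene %in% cfg$mrna_ids))
      stop("planted_pairs references unknown probes")
    if (anyDuplicated(pp$gene))
      stop("each gene may be driven by at most one planted miRNA")
  }
  invisible(cfg)
}

# Map planted comparison logFCs onto per-class mean shifts (normal is the
# reference class; T_vs_M composes on top of any N_vs_T shift).
planted_shift_matrix <- function(cfg, ids) {
  shifts <- matrix(0, nrow = length(ids), ncol = 3,
                   dimnames = list(ids, c("normal", "tumor", "mets")))
  pd <- cfg$planted_de
  if (is.null(pd)) return(shifts)
  pd <- pd[pd$probe %in% ids, , drop = FALSE]
  for (k in seq_len(nrow(pd))) {
    p <- pd$probe[k]; fc <- pd$logFC[k]
    switch(pd$comparison[k],
           N_vs_T = {
             shifts[p, "tumor"] <- shifts[p, "tumor"] + fc
             shifts[p, "mets"]  <- shifts[p, "mets"] + fc
           },
           N_vs_M = shifts[p, "mets"] <- shifts[p, "mets"] + fc,
           T_vs_M = shifts[p, "mets"] <- shifts[p, "mets"] + fc)
  }
  # N_vs_T also shifted mets so that a pure N_vs_T effect is a tumor-lineage
  # effect carried into the metastasis unless T_vs_M says otherwise; N_vs_M
  # and T_vs_M act on mets only. Composition is additive.
  shifts
}

#' Simulate the expression part of a synthetic cohort
#'
#' Generates miRNA, mRNA and negative-control count matrices plus sample
#' annotations according to the model described in [simulation_config()].
#' Used by [simulate_cohort()]; exposed for tests that need expression
#' without survival.
#'
#' @param config a `sim_config` object.
#' @return A list of class `sim_cohort` with elements `mirna_counts`,
#'   `mrna_counts`, `negctrl_counts` (probes x samples integer matrices),
#'   `samples` (data frame: `sample`, `tissue`, `patient`, `age`,
#'   `grade`) and `truth` (planted shifts, true log2 expression, pair
#'   slopes).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr::with_seed(cfg$seed, {
    tissue <- rep(c("normal", "tumor", "mets"),
                  c(cfg$n_normal, cfg$n_tumor, cfg$n_mets))
    n <- length(tissue)
    sample_ids <- sprintf("S%03d", seq_len(n))
    # matched pairs: first n_matched_pairs normals and tumors share patients
    patient <- sprintf("P%03d", seq_len(n))
    if (cfg$n_matched_pairs > 0) {
      idx_n <- which(tissue == "normal")[seq_len(cfg$n_matched_pairs)]
      idx_t <- which(tissue == "tumor")[seq_len(cfg$n_matched_pairs)]
      patient[idx_t] <- patient[idx_n]
    }
    pat_eff <- stats::rnorm(length(unique(patient)), 0,
                            cfg$patient_intercept_sd)
    names(pat_eff) <- unique(patient)
    # patient intercept only matters where a patient contributes 2 samples
    shared <- patient %in% names(which(table(patient) > 1))
    intercept <- ifelse(shared, pat_eff[patient], 0)

    sim_block <- function(ids) {
      base <- stats::runif(length(ids), cfg$baseline_log2_range[1],
                           cfg$baseline_log2_range[2])
      shifts <- planted_shift_matrix(cfg, ids)
      mu <- base + shifts[, tissue, drop = FALSE]
      x <- mu + matrix(stats::rnorm(length(ids) * n, 0, cfg$noise_sd),
                       nrow = length(ids)) +
        matrix(intercept, nrow = length(ids), ncol = n, byrow = TRUE)
      dimnames(x) <- list(ids, sample_ids)
      x
    }
    x_mir <- sim_block(cfg$mirna_ids)
    x_rna <- sim_block(cfg$mrna_ids)
    # planted miRNA:mRNA pairs: the gene tracks the miRNA linearly
    if (!is.null(cfg$planted_pairs)) {
      pp <- cfg$planted_pairs
      for (k in seq_len(nrow(pp))) {
        xm <- x_mir[pp$mirna[k], ]
        base_g <- mean(x_rna[pp$gene[k], ])
        x_rna[pp$gene[k], ] <- base_g + pp$slope[k] * (xm - mean(xm)) +
          stats::rnorm(n, 0, pp$noise_sd[k])
      }
    }
    to_counts <- function(x) {
      cnt <- round(2^x)
      cnt[cnt < 0] <- 0
      storage.mode(cnt) <- "integer"
      cnt
    }
    negctrl <- matrix(stats::rpois(cfg$n_negctrl * n, cfg$negctrl_mean),
                      nrow = cfg$n_negctrl,
                      dimnames = list(sprintf("NEG%02d",
                                              seq_len(cfg$n_negctrl)),
                                      sample_ids))
    storage.mode(negctrl) <- "integer"
    samples <- data.frame(
      sample = sample_ids, tissue = tissue, patient = patient,
      age = round(stats::runif(n, cfg$age_range[1], cfg$age_range[2])),
      grade = sample(cfg$grade_levels, n, replace = TRUE),
      stringsAsFactors = FALSE)
    structure(list(
      mirna_counts = to_counts(x_mir),
      mrna_counts = to_counts(x_rna),
      negctrl_counts = negctrl,
      samples = samples,
      truth = list(planted_de = cfg$planted_de,
                   planted_pairs = cfg$planted_pairs,
                   betas = if (is.null(cfg$survival)) numeric(0)
                           else cfg$survival$betas,
                   log2_mirna = x_mir, log2_mrna = x_rna)),
      class = "sim_cohort")
  })
}

# Find the uniform-censoring horizon giving the requested expected
# censoring fraction for the drawn event times: P(C < T_i) with
# C ~ U(0, Tmax) is min(T_i, Tmax)/Tmax.
tune_censoring_horizon <- function(event_times, frac) {
  if (frac <= 0) return(Inf)
  f <- function(tm) mean(pmin(event_times, tm)) / tm - frac
  upper <- max(event_times) / frac + 1
  stats::uniroot(f, lower = min(event_times) * 1e-6, upper = upper,
                 tol = 1e-8)$root
}

#' Attach proportional-hazards survival annotations to a cohort
#'
#' Draws overall-survival (OS) and distant-disease-free-survival (DDFS)
#' times for the tumor samples from an exponential proportional-hazards
#' model, `h(t) = h0 * exp(sum(beta_i * x_i))`, with `x_i` the true log2
#' expression of the miRNAs named in the survival spec, so that
#' `exp(beta_i)` is the hazard ratio per 2-fold expression change. The
#' two endpoints are independent draws from the same hazard. Independent
#' uniform censoring is tuned to the configured fraction.
#'
#' @param config a `sim_config` object.
#' @param cohort the result of [simulate_expression()].
#' @return The cohort with columns `os_months`, `os_event`,
#'   `ddfs_months`, `ddfs_event` added to `$samples` (NA for non-tumor
#'   samples).
#' @export
simulate_survival <- function(config, cohort) {
  stopifnot(inherits(config, "sim_config"), inherits(cohort, "sim_cohort"))
  cfg <- config
  tum <- which(cohort$samples$tissue == "tumor")
  nt <- length(tum)
  add_na <- function(df) {
    df$os_months <- df$ddfs_months <- NA_real_
    df$os_event <- df$ddfs_event <- NA_integer_
    df
  }
  cohort$samples <- add_na(cohort$samples)
  if (nt == 0) return(cohort)
  if (is.null(cfg$survival)) {
    warning("no survival model configured: tumor samples are all censored")
    cohort$samples$os_months[tum] <- cohort$samples$ddfs_months[tum] <- 120
    cohort$samples$os_event[tum] <- cohort$samples$ddfs_event[tum] <- 0L
    return(cohort)
  }
  sv <- cfg$survival
  lp <- rep(0, nt)
  if (length(sv$betas)) {
    x <- cohort$truth$log2_mirna[names(sv$betas), tum, drop = FALSE]
    lp <- as.numeric(crossprod(x, sv$betas))
  }
  rate <- sv$baseline_hazard * exp(lp)
  withr::with_seed(cfg$seed + 77003L, {
    draw <- function() {
      t_ev <- stats::rexp(nt, rate)
      tmax <- tune_censoring_horizon(t_ev, sv$censoring_fraction)
      if (is.finite(tmax)) {
        cens <- stats::runif(nt, 0, tmax)
        list(time = pmin(t_ev, cens), event = as.integer(t_ev <= cens))
      } else {
        list(time = t_ev, event = rep(1L, nt))
      }
    }
    os <- draw(); ddfs <- draw()
    cohort$samples$os_months[tum] <- os$time
    cohort$samples$os_event[tum] <- os$event
    cohort$samples$ddfs_months[tum] <- ddfs$time
    cohort$samples$ddfs_event[tum] <- ddfs$event
  })
  cohort
}

#' Generate a target-prediction table for a simulated cohort
#'
#' Emits every planted miRNA:gene pair plus `n_decoy_pairs` decoys drawn
#' uniformly (seeded) from the unplanted miRNA x gene combinations, in
#' the two-column format consumed by [load_predictions()]. Decoys carry
#' no planted expression association and calibrate the anti-correlation
#' stage's false-discovery behaviour.
#'
#' @param config a `sim_config` object.
#' @return data frame with columns `mirna`, `gene`.
#' @export
generate_target_predictions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  planted <- if (is.null(cfg$planted_pairs))
    data.frame(mirna = character(), gene = character()) else
    data.frame(mirna = cfg$planted_pairs$mirna, gene = cfg$planted_pairs$gene,
               stringsAsFactors = FALSE)
  if (cfg$n_decoy_pairs > 0) {
    withr::with_seed(cfg$seed + 90001L, {
      all_pairs <- expand.grid(mirna = cfg$mirna_ids, gene = cfg$mrna_ids,
                               stringsAsFactors = FALSE)
      key <- paste(all_pairs$mirna, all_pairs$gene)
      free <- all_pairs[!key %in% paste(planted$mirna, planted$gene), ]
      take <- free[sample.int(nrow(free), min(cfg$n_decoy_pairs, nrow(free))), ]
      planted <- rbind(planted, take)
    })
  }
  rownames(planted) <- NULL
  planted
}

#' Simulate a complete synthetic cohort
#'
#' Runs [simulate_expression()], [simulate_survival()] and
#' [generate_target_predictions()] for one configuration. Identical
#' config and seed yield a bit-identical cohort.
#'
#' @param config a `sim_config` object.
#' @return A `sim_cohort` list with the expression matrices, annotated
#'   samples, `predictions` and ground `truth`.
#' @examples
#' cfg <- simulation_config(n_normal = 10, n_tumor = 10, n_mets = 0,
#'                          n_matched_pairs = 0, n_mirna = 20, n_mrna = 10,
#'                          seed = 7)
#' cohort <- simulate_cohort(cfg)
#' dim(cohort$mirna_counts)
#' @export
simulate_cohort <- function(config) {
  cohort <- simulate_expression(config)
  cohort <- simulate_survival(config, cohort)
  cohort$predictions <- generate_target_predictions(config)
  cohort
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic cohort:", ncol(x$mirna_counts), "samples (",
      paste(names(table(x$samples$tissue)), table(x$samples$tissue),
            collapse = ", "), ");",
      nrow(x$mirna_counts), "miRNA,", nrow(x$mrna_counts), "mRNA,",
      nrow(x$negctrl_counts), "negative-control probes\n")
  invisible(x)
}

write_count_tsv <- function(mat, path) {
  df <- data.frame(probe = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_count_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "integer"
  mat
}

#' Write a simulated cohort to plain-text files
#'
#' Writes TSV count matrices (`mirna_counts.tsv`, `mrna_counts.tsv`,
#' `negctrl_counts.tsv`; probes in rows, first column `probe`), the
#' sample-annotation TSV (`samples.tsv`), the prediction table
#' (`predictions.tsv`) and a JSON ground-truth file (`truth.json`). The
#' files round-trip losslessly through [read_cohort()]. With
#' `rcc = TRUE` also writes one RCC-like CSV per sample (sections
#' `Header`, `Sample_Attributes` and `Code_Summary` with columns
#' CodeClass, Name, Accession, Count).
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @param rcc also write per-sample RCC-like files under `dir/rcc/`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, rcc = FALSE) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_tsv(cohort$mirna_counts, file.path(dir, "mirna_counts.tsv"))
  write_count_tsv(cohort$mrna_counts, file.path(dir, "mrna_counts.tsv"))
  write_count_tsv(cohort$negctrl_counts, file.path(dir, "negctrl_counts.tsv"))
  utils::write.table(cohort$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$predictions))
    utils::write.table(cohort$predictions, file.path(dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$log2_mirna <- NULL  # reproducible from config; keep files small
  truth$log2_mrna <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (rcc) write_rcc_files(cohort, file.path(dir, "rcc"))
  invisible(dir)
}

write_rcc_files <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in colnames(cohort$mirna_counts)) {
    path <- file.path(dir, paste0(s, ".rcc"))
    code <- rbind(
      data.frame(CodeClass = "Endogenous", Name = rownames(cohort$mirna_counts),
                 Accession = rownames(cohort$mirna_counts),
                 Count = cohort$mirna_counts[, s]),
      data.frame(CodeClass = "Negative", Name = rownames(cohort$negctrl_counts),
                 Accession = rownames(cohort$negctrl_counts),
                 Count = cohort$negctrl_counts[, s]))
    lines <- c("<Header>", "FileVersion,1.7", "</Header>",
               "<Sample_Attributes>", paste0("ID,", s), "</Sample_Attributes>",
               "<Code_Summary>", "CodeClass,Name,Accession,Count",
               paste(code$CodeClass, code$Name, code$Accession, code$Count,
                     sep = ","),
               "</Code_Summary>")
    writeLines(lines, path)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @return a `sim_cohort` list (without the true log2 matrices, which are
#'   not serialized).
#' @export
read_cohort <- function(dir) {
  res <- list(
    mirna_counts = read_count_tsv(file.path(dir, "mirna_counts.tsv")),
    mrna_counts = read_count_tsv(file.path(dir, "mrna_counts.tsv")),
    negctrl_counts = read_count_tsv(file.path(dir, "negctrl_counts.tsv")),
    samples = utils::read.delim(file.path(dir, "samples.tsv"),
                                stringsAsFactors = FALSE))
  pred_path <- file.path(dir, "predictions.tsv")
  if (file.exists(pred_path))
    res$predictions <- utils::read.delim(pred_path, stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "truth.json")
  if (file.exists(truth_path))
    res$truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  structure(res, class = "sim_cohort")
}

#' Simulate a two-group survival cohort with a known group hazard ratio
#'
#' Draws exponential event times for a high-risk and a low-risk group
#' with hazards `h0 * hr` and `h0`, applies uniform censoring tuned to
#' `censoring_fraction`, and returns the records. Used to study the
#' recovery of high- vs low-risk signature hazard ratios at cohort sizes
#' of interest.
#'
#' @param n_high,n_low group sizes.
#' @param hr true hazard ratio (high vs low).
#' @param baseline_hazard events per month in the low-risk group.
#' @param censoring_fraction expected fraction censored.
#' @param seed integer seed.
#' @return data frame with columns `group` (`"high"`/`"low"`), `time`,
#'   `event`.
#' @export
simulate_two_group_survival <- function(n_high, n_low, hr,
                                        baseline_hazard = 0.01,
                                        censoring_fraction = 0.3,
                                        seed = 1L) {
  stopifnot(n_high > 0, n_low > 0, hr > 0)
  withr::with_seed(as.integer(seed), {
    group <- rep(c("high", "low"), c(n_high, n_low))
    rate <- baseline_hazard * ifelse(group == "high", hr, 1)
    t_ev <- stats::rexp(length(group), rate)
    tmax <- tune_censoring_horizon(t_ev, censoring_fraction)
    if (is.finite(tmax)) {
      cens <- stats::runif(length(group), 0, tmax)
      data.frame(group = group, time = pmin(t_ev, cens),
                 event = as.integer(t_ev <= cens))
    } else {
      data.frame(group = group, time = t_ev, event = 1L)
    }
  })
}
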