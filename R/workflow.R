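# 32-bit FNV-1a over the serialized config; cheap content fingerprint
# recorded in every artifact so outputs can be traced to their config.
fnv1a_hash <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  p <- 16777619
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply in doubles, split to stay below 2^53
    h0 <- h %% 65536
    h1 <- h %/% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Build a pipeline configuration
#'
#' Accepts either a YAML file path or a named list. A configuration
#' either names input files (`counts`, `negctrl_counts`, `annotations`,
#' optionally `predictions`, all TSV as written by [write_cohort()]) or
#' contains a `simulate` block of [simulation_config()] arguments. A
#' `seed` is mandatory: every stochastic stage derives its own child
#' seed from it by fixed offsets, so stages are independently
#' reproducible.
#'
#' @param config a YAML path or a named list. Recognized analysis
#'   settings (with defaults): `alpha` (0.05), `use_p` ("raw"),
#'   `permutations` (1000), `endpoint` ("OS"), `age_max` (NULL: no
#'   age-subset filter), `top_k` (20), `cluster_r` (NULL) or `cluster_k`
#'   (4), `min_below_frac` (0.5), `iqr_min` (0.5), `norm_method`
#'   ("quantile"), `max_candidates` (NULL).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(alpha = 0.05, use_p = "raw", permutations = 1000,
                   endpoint = "OS", age_max = NULL, top_k = 20,
                   cluster_r = NULL, cluster_k = 4,
                   min_below_frac = 0.5, iqr_min = 0.5,
                   norm_method = "quantile", max_candidates = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$seed)) stop("config must set a seed")
  config$seed <- as.integer(config$seed)
  has_sim <- !is.null(config$simulate)
  if (!has_sim) {
    needed <- c("counts", "negctrl_counts", "annotations")
    missing <- needed[!vapply(needed, function(f)
      !is.null(config[[f]]) && file.exists(config[[f]]), logical(1))]
    if (length(missing))
      stop("config must either contain a `simulate` block or existing ",
           "input paths; missing: ", paste(missing, collapse = ", "))
  }
  if (!config$endpoint %in% c("OS", "DDFS"))
    stop("endpoint must be OS or DDFS")
  structure(config, class = c("pipeline_config", "list"))
}

stage_seed <- function(config, stage) {
  offs <- c(simulate = 0L, diffexpr = 11L, survival = 23L,
            integration = 37L, clustering = 53L)
  (config$seed + offs[[stage]] * 1009L) %% .Machine$integer.max
}

write_stage_tsv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# trisign config_hash=%s seed=%d", hash, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: simulate (optional), preprocess,
#' differential expression with Venn partitioning, survival signature
#' with risk-group comparison, miRNA:mRNA anti-correlation, and
#' clustering; writes every table to `dir` stamped with the config hash
#' and seed, plus a plain-text `log.txt` with stage timings. Reruns with
#' the same config and seed are byte-identical.
#'
#' @param config a `pipeline_config` (or anything [pipeline_config()]
#'   accepts).
#' @param dir output directory.
#' @return list of stage results (`cohort`, `preprocess`, `de`, `venn`,
#'   `signature`, `risk`, `group_hr`, `pairs`, `clusters`), invisibly
#'   annotated with `config` and `hash`.
#' @export
run_pipeline <- function(config, dir) {
  config <- pipeline_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hash <- fnv1a_hash(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                      digits = NA, null = "null"))
  seed <- config$seed
  log_lines <- character(0)
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) {
    line <- sprintf("[%7.2fs] %s", proc.time()[["elapsed"]] - t0,
                    sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  fail <- function(stage, e)
    stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
         call. = FALSE)

  ## stage: inputs -------------------------------------------------------
  cohort <- tryCatch({
    if (!is.null(config$simulate)) {
      say("simulate: generating synthetic cohort")
      args <- config$simulate
      args$seed <- stage_seed(config, "simulate")
      if (!is.null(args$planted_de))
        args$planted_de <- as.data.frame(args$planted_de)
      if (!is.null(args$planted_pairs))
        args$planted_pairs <- as.data.frame(args$planted_pairs)
      if (!is.null(args$survival)) args$survival$betas <-
          unlist(args$survival$betas)
      cohort <- simulate_cohort(do.call(simulation_config, args))
      write_cohort(cohort, file.path(dir, "cohort"))
      cohort
    } else {
      say("load: reading cohort tables")
      res <- list(
        mirna_counts = read_count_tsv(config$counts),
        negctrl_counts = read_count_tsv(config$negctrl_counts),
        samples = utils::read.delim(config$annotations,
                                    stringsAsFactors = FALSE))
      if (!is.null(config$mrna_counts))
        res$mrna_counts <- read_count_tsv(config$mrna_counts)
      if (!is.null(config$predictions))
        res$predictions <- load_predictions(config$predictions)
      structure(res, class = "sim_cohort")
    }
  }, error = function(e) fail("input", e))
  if (identical(config$simulate_only, TRUE)) {
    writeLines(log_lines, file.path(dir, "log.txt"))
    return(invisible(list(cohort = cohort, config = config, hash = hash)))
  }

  ## stage: preprocess ---------------------------------------------------
  pp <- tryCatch({
    say("preprocess: filter + %s normalization", config$norm_method)
    res <- list(mirna = preprocess_counts(
      cohort$mirna_counts, cohort$negctrl_counts,
      min_below_frac = config$min_below_frac, iqr_min = config$iqr_min,
      method = config$norm_method, invariant_ids = config$invariant_ids))
    if (!is.null(cohort$mrna_counts))
      res$mrna <- preprocess_counts(
        cohort$mrna_counts, cohort$negctrl_counts,
        min_below_frac = config$min_below_frac, iqr_min = config$iqr_min,
        method = config$norm_method, invariant_ids = config$invariant_ids)
    res
  }, error = function(e) fail("preprocess", e))

  ## stage: diffexpr -----------------------------------------------------
  de <- tryCatch({
    say("diffexpr: linear models over %d miRNA features",
        nrow(pp$mirna$exprs))
    de_mirna <- run_diffexpr(pp$mirna$exprs, cohort$samples$tissue)
    de_mrna <- if (!is.null(pp$mrna))
      run_diffexpr(pp$mrna$exprs, cohort$samples$tissue) else NULL
    calls <- call_de(de_mirna, alpha = config$alpha, use = config$use_p)
    venn <- venn_partition(calls)
    write_stage_tsv(de_mirna, file.path(dir, "de_mirna.tsv"), hash, seed)
    if (!is.null(de_mrna))
      write_stage_tsv(de_mrna, file.path(dir, "de_mrna.tsv"), hash, seed)
    write_stage_tsv(venn, file.path(dir, "venn.tsv"), hash, seed)
    list(mirna = de_mirna, mrna = de_mrna, calls = calls, venn = venn)
  }, error = function(e) fail("diffexpr", e))

  ## stage: survival -----------------------------------------------------
  surv <- tryCatch({
    ann <- cohort$samples
    tum <- ann$tissue == "tumor" & !is.na(ann$os_months)
    if (!is.null(config$age_max)) tum <- tum & ann$age <= config$age_max
    if (!any(tum)) {
      say("survival: no tumor samples with survival data; skipping")
      NULL
    } else {
      time <- if (config$endpoint == "OS") ann$os_months[tum] else
        ann$ddfs_months[tum]
      event <- if (config$endpoint == "OS") ann$os_event[tum] else
        ann$ddfs_event[tum]
      cand <- pp$mirna$exprs[, ann$sample[tum], drop = FALSE]
      if (!is.null(config$max_candidates) &&
          nrow(cand) > config$max_candidates) {
        ord <- order(apply(cand, 1, stats::var), decreasing = TRUE)
        cand <- cand[sort(ord[seq_len(config$max_candidates)]), ,
                     drop = FALSE]
      }
      say("survival: %s signature over %d candidates, %d tumors, B=%d",
          config$endpoint, nrow(cand), sum(tum), config$permutations)
      covars <- data.frame(age = ann$age[tum], grade = ann$grade[tum])
      sig <- build_signature(cand, time, event, covariates = covars,
                             alpha = config$alpha,
                             B = config$permutations,
                             seed = stage_seed(config, "survival"))
      write_stage_tsv(sig$candidates, file.path(dir, "cox_candidates.tsv"),
                      hash, seed)
      jsonlite::write_json(
        list(endpoint = config$endpoint, members = sig$members,
             config_hash = hash, seed = seed),
        file.path(dir, "signature.json"), auto_unbox = TRUE, digits = NA)
      if (nrow(sig$members)) {
        risk <- risk_score(sig, cand)
        ghr <- group_hazard_ratio(risk, time, event)
        write_stage_tsv(risk, file.path(dir, "risk_groups.tsv"), hash, seed)
        km_df <- do.call(rbind, lapply(names(ghr$km), function(g)
          data.frame(group = g, time = ghr$km[[g]]$time,
                     surv = ghr$km[[g]]$surv,
                     n_risk = ghr$km[[g]]$n_risk)))
        write_stage_tsv(km_df, file.path(dir, "km_curves.tsv"), hash, seed)
        jsonlite::write_json(
          list(HR = ghr$cox$HR, ci = ghr$cox$ci, p = ghr$cox$p,
               logrank_p = ghr$logrank$p, medians = as.list(ghr$medians),
               config_hash = hash, seed = seed),
          file.path(dir, "group_hr.json"), auto_unbox = TRUE, digits = NA)
        list(signature = sig, risk = risk, group_hr = ghr,
             time = time, event = event)
      } else {
        say("survival: empty signature")
        list(signature = sig, risk = NULL, group_hr = NULL)
      }
    }
  }, error = function(e) fail("survival", e))

  ## stage: integration --------------------------------------------------
  pairs <- tryCatch({
    if (is.null(pp$mrna) || is.null(cohort$predictions) ||
        !nrow(cohort$predictions)) {
      say("integration: no mRNA matrix or predictions; skipping")
      NULL
    } else {
      say("integration: anti-correlation over %d predicted pairs",
          nrow(cohort$predictions))
      tum_ids <- cohort$samples$sample[cohort$samples$tissue == "tumor"]
      pr <- anticorrelated_pairs(
        pp$mirna$exprs[, intersect(colnames(pp$mirna$exprs), tum_ids),
                       drop = FALSE],
        pp$mrna$exprs[, intersect(colnames(pp$mrna$exprs), tum_ids),
                      drop = FALSE],
        cohort$predictions, top_k = config$top_k, de = de$mirna)
      if (!is.null(de$mrna) && nrow(pr)) {
        d <- de$mrna[de$mrna$comparison == "N_vs_T", ]
        pr$gene_logFC <- d$logFC[match(pr$gene, d$feature)]
      }
      write_stage_tsv(pr, file.path(dir, "correlation_pairs.tsv"),
                      hash, seed)
      pr
    }
  }, error = function(e) fail("integration", e))

  ## stage: clustering ---------------------------------------------------
  clusters <- tryCatch({
    x <- if (!is.null(pp$mrna)) pp$mrna$exprs else pp$mirna$exprs
    say("clustering: %d features x %d samples", nrow(x), ncol(x))
    dmat <- spearman_distance(x, axis = "rows")
    hc <- average_linkage(dmat)
    r <- if (!is.null(config$cluster_r)) config$cluster_r else
      threshold_for_clusters(hc, min(config$cluster_k, nrow(x)))
    cl <- cut_tree_at_correlation(hc, r)
    assign <- data.frame(feature = names(cl), cluster = as.integer(cl),
                         stringsAsFactors = FALSE)
    write_stage_tsv(assign, file.path(dir, "clusters.tsv"), hash, seed)
    merges <- data.frame(left = hc$merge[, 1], right = hc$merge[, 2],
                         height = hc$height)
    write_stage_tsv(merges, file.path(dir, "dendrogram.tsv"), hash, seed)
    list(tree = hc, assignment = assign, r_threshold = r)
  }, error = function(e) fail("clustering", e))

  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("done")
  writeLines(log_lines, file.path(dir, "log.txt"))
  invisible(list(cohort = cohort, preprocess = pp, de = de,
                 survival = surv, pairs = pairs, clusters = clusters,
                 config = config, hash = hash))
}

#' Summarize a completed pipeline run
#'
#' Produces a one-page plain-text summary: differential-expression counts
#' per comparison, Venn region sizes, signature members with hazard
#' ratios and permutation P values, the high- vs low-risk group hazard
#' ratio with Kaplan-Meier medians, the top anti-correlated pairs and
#' cluster sizes.
#'
#' @param results the list returned by [run_pipeline()].
#' @param file optional path to write the report to.
#' @return character vector of report lines, invisibly when `file` is
#'   given.
#' @export
write_report <- function(results, file = NULL) {
  fmt <- function(x, d = 2) formatC(x, format = "f", digits = d)
  lines <- c(sprintf("trisign run report (config %s, seed %d)",
                     results$hash, results$config$seed), "")
  de <- results$de
  if (!is.null(de)) {
    counts <- vapply(de$calls, nrow, integer(1))
    lines <- c(lines, "Differentially expressed miRNAs:",
               sprintf("  %s: %d", names(counts), counts),
               "Venn region sizes:",
               sprintf("  %s: %d", names(venn_region_sizes(de$venn)),
                       venn_region_sizes(de$venn)), "")
  }
  sv <- results$survival
  if (is.null(sv)) {
    lines <- c(lines, "Survival: not run", "")
  } else if (!nrow(sv$signature$members)) {
    lines <- c(lines, "Survival: no signature (no candidate passed alpha)",
               "")
  } else {
    m <- sv$signature$members
    lines <- c(lines,
               sprintf("Survival signature (%s), %d members:",
                       results$config$endpoint, nrow(m)),
               sprintf("  %s: HR %s (%s-%s), perm P %s, %s", m$feature,
                       fmt(m$uni_HR), fmt(m$uni_ci_low), fmt(m$uni_ci_high),
                       fmt(m$perm_p, 4), m$label))
    g <- sv$group_hr
    lines <- c(lines,
               sprintf("  High vs low risk: HR %s (95%% CI %s-%s), P %s",
                       fmt(g$cox$HR), fmt(g$cox$ci[1]), fmt(g$cox$ci[2]),
                       fmt(g$cox$p, 4)),
               sprintf("  Median survival high/low: %s / %s months",
                       fmt(g$medians[["high"]], 1),
                       fmt(g$medians[["low"]], 1)),
               sprintf("  Log-rank P: %s", fmt(g$logrank$p, 4)), "")
  }
  pr <- results$pairs
  if (!is.null(pr) && nrow(pr)) {
    top <- utils::head(pr[order(pr$r), ], 10)
    lines <- c(lines, "Top anti-correlated miRNA:mRNA pairs:",
               sprintf("  %s ~ %s: r %s", top$mirna, top$gene,
                       fmt(top$r)), "")
  } else {
    lines <- c(lines, "Integration: no pairs retained or not run", "")
  }
  cl <- results$clusters
  if (!is.null(cl)) {
    sizes <- table(cl$assignment$cluster)
    lines <- c(lines,
               sprintf("Clusters at r >= %s: %d clusters of sizes %s",
                       fmt(cl$r_threshold), length(sizes),
                       paste(as.integer(sizes), collapse = ", ")))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
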