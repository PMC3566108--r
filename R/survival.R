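#' Univariate or covariate-adjusted Cox proportional-hazards fit
#'
#' Fits a Cox model for one expression covariate `x` (log2 units), so
#' `exp(beta)` is the hazard ratio per 2-fold expression change, with
#' optional clinical adjustment covariates (e.g. age and ordinal tumor
#' grade). The partial likelihood is maximized by Newton-Raphson with
#' the Efron tie correction by default (Breslow available). A constant
#' `x` yields a flagged non-informative result (`beta = 0`, `SE = Inf`,
#' `HR = 1`) rather than an error.
#'
#' @param x numeric covariate vector (one value per sample).
#' @param time,event survival times (> 0) and event indicators (0/1).
#' @param covariates optional data frame of adjustment covariates
#'   aligned with the samples.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param feature optional feature label carried into the result.
#' @return object of class `cox_result`: list with `feature`, `beta`,
#'   `se`, `HR`, `ci` (95% Wald), `z`, `p`, `model`
#'   (`"univariate"`/`"multivariate"`), `converged`, `informative`,
#'   `n`, `n_event`, and `perm_p` (NA until [permutation_pvalue()]).
#' @export
cox_fit <- function(x, time, event, covariates = NULL,
                    ties = c("efron", "breslow"), feature = NA_character_) {
  ties <- match.arg(ties)
  stopifnot(length(x) == length(time), length(time) == length(event))
  if (!is.null(covariates)) stopifnot(nrow(covariates) == length(x))
  if (sum(event) < 1) stop("at least one event is required")
  if (any(time <= 0)) stop("survival times must be positive")
  res <- list(feature = feature, n = length(x), n_event = sum(event),
              model = if (is.null(covariates)) "univariate" else
                "multivariate",
              ties = ties, perm_p = NA_real_)
  if (stats::var(x) == 0) {
    res <- c(res, list(beta = 0, se = Inf, HR = 1, ci = c(0, Inf),
                       z = 0, p = 1, converged = TRUE, informative = FALSE))
    class(res) <- "cox_result"
    return(res)
  }
  dat <- data.frame(time = time, event = event, x = x)
  form <- survival::Surv(time, event) ~ x
  if (!is.null(covariates)) {
    dat <- cbind(dat, covariates)
    form <- stats::as.formula(paste("survival::Surv(time, event) ~ x +",
                                    paste(colnames(covariates),
                                          collapse = " + ")))
  }
  fit <- withCallingHandlers(
    survival::coxph(form, data = dat, ties = ties,
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) invokeRestart("muffleWarning"))
  beta <- unname(stats::coef(fit)["x"])
  se <- sqrt(diag(fit$var))[1]
  z <- beta / se
  res <- c(res, list(
    beta = beta, se = se, HR = exp(beta),
    ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
    z = z, p = 2 * stats::pnorm(-abs(z)),
    converged = is.null(fit$info) && fit$iter < 50,
    informative = TRUE))
  class(res) <- "cox_result"
  res
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf(
    "Cox fit%s (%s, %s ties): HR %.3f (95%% CI %.3f-%.3f), Wald P %.3g%s\n",
    if (is.na(x$feature)) "" else paste0(" [", x$feature, "]"),
    x$model, x$ties, x$HR, x$ci[1], x$ci[2], x$p,
    if (is.na(x$perm_p)) "" else sprintf(", permutation P %.3g", x$perm_p)))
  invisible(x)
}

# Fast Wald z for a single covariate via the survival internals; used in
# the permutation loop where formula-interface overhead dominates.
cox_z <- function(x, time, event, ties) {
  # near-separation makes the Newton steps noisy; the Wald z itself stays
  # finite and comparable across permutations, so silence the fitter
  fit <- suppressWarnings(survival::coxph.fit(matrix(x, ncol = 1),
                             survival::Surv(time, event),
                             strata = NULL, offset = NULL, init = 0,
                             control = survival::coxph.control(iter.max = 25),
                             weights = NULL, method = ties,
                             rownames = seq_along(x)))
  fit$coefficients[1] / sqrt(fit$var[1, 1])
}

#' Permutation P value for a Cox association
#'
#' Jointly permutes the (time, event) pairs across samples `B` times,
#' refits the Cox model, and reports
#' `P = (1 + #permutations with |z| >= |z_obs|) / (B + 1)`. The smallest
#' attainable value is `1 / (B + 1)`.
#'
#' @param x covariate vector.
#' @param time,event survival data.
#' @param B number of permutations (>= 1).
#' @param seed integer seed (required for reproducibility).
#' @param ties tie correction, as in [cox_fit()].
#' @return list with `perm_p`, `z_obs` and `B`.
#' @export
permutation_pvalue <- function(x, time, event, B = 10000, seed = 1L,
                               ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (B < 1) stop("B must be >= 1")
  z_obs <- cox_z(x, time, event, ties)
  n <- length(time)
  hits <- withr::with_seed(as.integer(seed), {
    sum(vapply(seq_len(B), function(b) {
      idx <- sample.int(n)
      zp <- tryCatch(cox_z(x, time[idx], event[idx], ties),
                     error = function(e) Inf)
      abs(zp) >= abs(z_obs)
    }, logical(1)))
  })
  list(perm_p = (1 + hits) / (B + 1), z_obs = z_obs, B = B)
}

#' Assemble a prognostic miRNA signature
#'
#' For each candidate miRNA, fits the univariate Cox model with a
#' permutation P value and the multivariate model adjusted for the
#' clinical covariates (age and tumor grade in the reference analysis).
#' Signature members are the candidates significant in both: univariate
#' permutation `P < alpha` and multivariate Wald `P < alpha`. Member
#' coefficients are the multivariate betas; the protective
#' (univariate HR < 1) / risk-associated (HR > 1) labels follow the
#' univariate hazard ratio.
#'
#' @param exprs log2 expression matrix (miRNAs x samples), rows are the
#'   candidate set (e.g. all expressed miRNAs in tumor samples).
#' @param time,event survival data for the same samples.
#' @param covariates data frame of adjustment covariates (may be NULL
#'   for unadjusted "multivariate" fits).
#' @param alpha significance level for both filters.
#' @param B permutations per candidate.
#' @param seed integer seed; candidate-specific seeds are derived from
#'   it.
#' @param ties tie correction.
#' @return object of class `signature_def`: list with `members` (data
#'   frame: `feature`, `beta`, `uni_HR`, `uni_ci_low`, `uni_ci_high`,
#'   `perm_p`, `multi_p`, `label`) and `candidates` (the full
#'   per-candidate table).
#' @export
build_signature <- function(exprs, time, event, covariates = NULL,
                            alpha = 0.05, B = 1000, seed = 1L,
                            ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  exprs <- as.matrix(exprs)
  rows <- lapply(seq_len(nrow(exprs)), function(i) {
    x <- exprs[i, ]
    uni <- cox_fit(x, time, event, ties = ties,
                   feature = rownames(exprs)[i])
    if (!uni$informative)
      return(data.frame(feature = uni$feature, beta = 0, uni_HR = 1,
                        uni_ci_low = 0, uni_ci_high = Inf, perm_p = 1,
                        multi_p = 1, label = "noninformative",
                        stringsAsFactors = FALSE))
    pp <- permutation_pvalue(x, time, event, B = B,
                             seed = as.integer(seed) + i, ties = ties)
    multi <- cox_fit(x, time, event, covariates = covariates, ties = ties,
                     feature = rownames(exprs)[i])
    data.frame(feature = uni$feature, beta = multi$beta, uni_HR = uni$HR,
               uni_ci_low = uni$ci[1], uni_ci_high = uni$ci[2],
               perm_p = pp$perm_p, multi_p = multi$p,
               label = if (uni$HR < 1) "protective" else "risk-associated",
               stringsAsFactors = FALSE)
  })
  candidates <- do.call(rbind, rows)
  members <- candidates[candidates$perm_p < alpha &
                          candidates$multi_p < alpha &
                          candidates$label != "noninformative", ,
                        drop = FALSE]
  rownames(members) <- NULL
  structure(list(members = members, candidates = candidates,
                 alpha = alpha, B = B), class = "signature_def")
}

#' @export
print.signature_def <- function(x, ...) {
  if (!nrow(x$members)) {
    cat("Empty signature (no candidate passed alpha =", x$alpha, ")\n")
  } else {
    cat("Prognostic signature with", nrow(x$members), "miRNAs:\n")
    print(x$members, digits = 3)
  }
  invisible(x)
}

#' Risk scores and high/low risk groups from a signature
#'
#' The per-sample risk score is the linear predictor
#' `sum_i beta_i * x_i` over the signature members' log2 expression.
#' Samples are split at the cohort median score: strictly above the
#' median is high risk; scores at or below the median (including ties at
#' the median) are low risk.
#'
#' @param signature a `signature_def` (or a named numeric vector of
#'   coefficients).
#' @param exprs log2 expression matrix containing every signature miRNA.
#' @return data frame with columns `sample`, `score`, `group`
#'   (`"high"`/`"low"`); attributes `split` (the median) and `degenerate`
#'   (TRUE when all scores are equal, in which case all samples are low
#'   risk).
#' @export
risk_score <- function(signature, exprs) {
  beta <- if (inherits(signature, "signature_def"))
    stats::setNames(signature$members$beta, signature$members$feature)
  else signature
  if (!length(beta)) stop("signature has no members")
  missing <- setdiff(names(beta), rownames(exprs))
  if (length(missing))
    stop("signature miRNAs missing from expression matrix: ",
         paste(missing, collapse = ", "))
  score <- as.numeric(crossprod(exprs[names(beta), , drop = FALSE], beta))
  split <- stats::median(score)
  degenerate <- stats::var(score) == 0
  group <- ifelse(score > split, "high", "low")
  out <- data.frame(sample = colnames(exprs), score = score, group = group,
                    stringsAsFactors = FALSE)
  attr(out, "split") <- split
  attr(out, "degenerate") <- degenerate
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time,event survival data.
#' @return object of class `km_curve`: list with `time` (ascending event
#'   times), `surv` (step values of S(t)), `n_risk`, `n_event`, and
#'   `median` (smallest time with `S(t) <= 0.5`, NA when S never reaches
#'   0.5).
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1, length(time) == length(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  s <- fit$surv[keep]
  t_ev <- fit$time[keep]
  med <- if (any(s <= 0.5)) t_ev[which(s <= 0.5)[1]] else NA_real_
  structure(list(time = t_ev, surv = s, n_risk = fit$n.risk[keep],
                 n_event = fit$n.event[keep], median = med,
                 n = length(time)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve over", x$n, "samples,", sum(x$n_event),
      "events; median survival",
      if (is.na(x$median)) "not reached" else sprintf("%.1f", x$median),
      "\n")
  invisible(x)
}

#' Log-rank test between survival groups
#'
#' Standard observed-minus-expected log-rank statistic over the pooled
#' event times, with a chi-square reference on `k - 1` degrees of
#' freedom for `k` groups.
#'
#' @param time,event survival data.
#' @param group group labels (>= 2 non-empty groups).
#' @return list with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2)
    stop("need at least two non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(droplevels(group)) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Hazard ratio between high- and low-risk groups
#'
#' Univariate Cox fit on the high-vs-low indicator (high = 1), with
#' per-group Kaplan-Meier curves and medians and the log-rank P value.
#'
#' @param groups data frame from [risk_score()] (or any data frame with
#'   a `group` column of `"high"`/`"low"`).
#' @param time,event survival data aligned with `groups`.
#' @param ties tie correction.
#' @return list with `cox` (a `cox_result`), `km` (named list of
#'   `km_curve` for high and low), `medians` (named numeric) and
#'   `logrank` (as [logrank_test()]).
#' @export
group_hazard_ratio <- function(groups, time, event,
                               ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  g <- groups$group
  if (!all(g %in% c("high", "low"))) stop("groups must be high/low")
  if (!all(c("high", "low") %in% g)) stop("both groups must be non-empty")
  ind <- as.numeric(g == "high")
  cox <- cox_fit(ind, time, event, ties = ties, feature = "high_vs_low")
  km <- lapply(stats::setNames(c("high", "low"), c("high", "low")),
               function(lv) km_estimate(time[g == lv], event[g == lv]))
  list(cox = cox,
       km = km,
       medians = vapply(km, function(k) k$median, numeric(1)),
       logrank = logrank_test(time, event, g))
}
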