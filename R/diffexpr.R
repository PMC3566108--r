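#' Build a group-means design matrix for the three tissue classes
#'
#' One indicator column per tissue class present, in the order normal,
#' tumor, mets; optionally plus patient-block columns for matched
#' analyses (treatment-coded against the first patient).
#'
#' @param tissue character vector of per-sample classes.
#' @param patient optional per-sample patient ids for a matched
#'   (patient-blocked) design.
#' @return design matrix (samples x coefficients), full column rank.
#' @export
design_matrix <- function(tissue, patient = NULL) {
  lev <- intersect(c("normal", "tumor", "mets"), unique(tissue))
  if (length(lev) < 2) stop("need at least two tissue classes")
  f <- factor(tissue, levels = lev)
  X <- stats::model.matrix(~ 0 + f)
  colnames(X) <- lev
  if (!is.null(patient)) {
    p <- factor(patient)
    if (nlevels(p) > 1)
      X <- cbind(X, stats::model.matrix(~ p)[, -1, drop = FALSE])
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  X
}

#' Fit per-feature linear models
#'
#' Ordinary least squares of every row of the expression matrix on a
#' common design matrix. With a group-means design the coefficients are
#' exactly the class means and the residual variance is the pooled
#' within-class variance.
#'
#' @param x expression matrix (features x samples).
#' @param design design matrix (samples x coefficients), full rank, with
#'   residual degrees of freedom >= 1.
#' @return list with `coefficients` (features x coefficients), `sigma2`
#'   (residual variances), `df_residual`, `xtx_inv` (the
#'   `solve(crossprod(design))` needed for contrast standard errors) and
#'   `design`.
#' @export
fit_linear_model <- function(x, design) {
  x <- as.matrix(x)
  design <- as.matrix(design)
  if (nrow(design) != ncol(x)) stop("design rows must match samples")
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) stop("design matrix is rank deficient")
  df <- nrow(design) - ncol(design)
  if (df < 1) stop("no residual degrees of freedom")
  beta <- t(qr.coef(qrX, t(x)))
  resid <- x - beta %*% t(design)
  sigma2 <- rowSums(resid^2) / df
  list(coefficients = beta, sigma2 = sigma2, df_residual = df,
       xtx_inv = chol2inv(qr.R(qrX)), design = design)
}

#' Estimate contrasts from a linear-model fit
#'
#' @param fit result of [fit_linear_model()].
#' @param contrasts coefficients x contrasts numeric matrix (named
#'   columns).
#' @return list with `logFC` (features x contrasts) and `se_unscaled`
#'   (per-contrast `sqrt(c' (X'X)^-1 c)`, to be multiplied by the
#'   residual or moderated SD).
#' @export
contrast_fit <- function(fit, contrasts) {
  contrasts <- as.matrix(contrasts)
  if (nrow(contrasts) != ncol(fit$coefficients))
    stop("contrast rows must match design coefficients")
  logFC <- fit$coefficients %*% contrasts
  se_unscaled <- sqrt(diag(t(contrasts) %*% fit$xtx_inv %*% contrasts))
  list(logFC = logFC, se_unscaled = se_unscaled)
}

# Invert the trigamma function by Newton iteration on 1/x scaling
# (monotone decreasing; same scheme as standard empirical-Bayes code).
trigamma_inverse <- function(y) {
  vapply(y, function(v) {
    if (v <= 0) return(Inf)
    if (v > 1e7) return(1 / sqrt(v))
    x <- 0.5 + 1 / v
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / v) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderation of residual variances
#'
#' Shrinks per-feature residual variances toward a common prior.
#' Assuming `s2 ~ s02 * F(df, d0)`, the prior degrees of freedom `d0` and
#' prior variance `s02` are estimated by method of moments on `log(s2)`
#' (matching the mean and variance of the log-F distribution); the
#' posterior variance is `(d0 * s02 + df * s2) / (d0 + df)`. Moderated
#' t-statistics for supplied contrasts are computed with `d0 + df`
#' degrees of freedom. If the observed log-variances are less dispersed
#' than chi-square sampling noise alone explains, `d0 = Inf` and every
#' posterior variance equals `s02`.
#'
#' @param sigma2 per-feature residual variances.
#' @param df residual degrees of freedom (scalar).
#' @param logFC optional features x contrasts effect matrix.
#' @param se_unscaled optional per-contrast unscaled SE (see
#'   [contrast_fit()]).
#' @param d0,s02 optional overrides of the estimated hyperparameters
#'   (e.g. `d0 = 0` gives ordinary t-statistics).
#' @return list with `d0`, `s02`, `s2_post` and, when contrasts are
#'   supplied, `t` (moderated t), `df_total` and `p` (two-sided).
#' @export
ebayes_moderate <- function(sigma2, df, logFC = NULL, se_unscaled = NULL,
                            d0 = NULL, s02 = NULL) {
  if (any(sigma2 < 0)) stop("variances must be nonnegative")
  if (is.null(d0) || is.null(s02)) {
    s2 <- pmax(sigma2, 1e-300)
    z <- log(s2)
    e <- z - digamma(df / 2) + log(df / 2)
    n <- length(e)
    if (n < 2) stop("need >= 2 features to estimate the variance prior")
    ev <- mean((e - mean(e))^2) * n / (n - 1) - trigamma(df / 2)
    if (ev > 0) {
      est_d0 <- 2 * trigamma_inverse(ev)
      est_s02 <- exp(mean(e) + digamma(est_d0 / 2) - log(est_d0 / 2))
    } else {
      est_d0 <- Inf
      est_s02 <- exp(mean(e))
    }
    if (is.null(d0)) d0 <- est_d0
    if (is.null(s02)) s02 <- est_s02
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(sigma2)) else
    (d0 * s02 + df * sigma2) / (d0 + df)
  out <- list(d0 = d0, s02 = s02, s2_post = s2_post)
  if (!is.null(logFC)) {
    logFC <- as.matrix(logFC)
    tval <- sweep(logFC / sqrt(s2_post), 2, se_unscaled, `/`)
    df_total <- d0 + df
    out$t <- tval
    out$df_total <- df_total
    out$p <- 2 * stats::pt(-abs(tval),
                           df = if (is.infinite(df_total)) 1e8 else df_total)
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: values sorted ascending get
#' `q_i = min_{j >= i} n * p_j / j`, capped at 1, returned in input
#' order. Delegates to [stats::p.adjust()] after validating the input.
#'
#' @param p numeric vector of P values in `[0, 1]`.
#' @return adjusted P values.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("P values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential expression across the three tissue classes
#'
#' Fits per-feature linear models on a group-means design and estimates
#' the pairwise contrasts among the tissue classes present (sign
#' convention: second class minus first, i.e. `N_vs_T` is tumor minus
#' normal, so a miRNA up-regulated in tumor has positive logFC).
#' Variances are moderated by [ebayes_moderate()] and P values adjusted
#' by [bh_adjust()] within each comparison.
#'
#' @param x log2 expression matrix (features x samples).
#' @param tissue per-sample tissue class (`"normal"`, `"tumor"`,
#'   `"mets"`).
#' @param patient optional patient ids for a matched, patient-blocked
#'   design.
#' @return data frame of class `de_table` with columns `feature`,
#'   `comparison`, `logFC`, `t`, `df`, `P`, `adjP`.
#' @examples
#' cfg <- simulation_config(n_normal = 10, n_tumor = 10, n_mets = 0,
#'                          n_matched_pairs = 0, n_mirna = 40, n_mrna = 10,
#'                          planted_de = data.frame(probe = "miR-sim-001",
#'                            comparison = "N_vs_T", logFC = 2),
#'                          seed = 11)
#' cohort <- simulate_cohort(cfg)
#' de <- run_diffexpr(log2(cohort$mirna_counts + 1), cohort$samples$tissue)
#' head(de[order(de$P), ])
#' @export
run_diffexpr <- function(x, tissue, patient = NULL) {
  X <- design_matrix(tissue, patient)
  lev <- intersect(c("normal", "tumor", "mets"), colnames(X))
  pairs <- list(N_vs_T = c("normal", "tumor"),
                N_vs_M = c("normal", "mets"),
                T_vs_M = c("tumor", "mets"))
  pairs <- Filter(function(p) all(p %in% lev), pairs)
  if (!length(pairs)) stop("no estimable pairwise comparison")
  C <- vapply(pairs, function(p) {
    v <- numeric(ncol(X)); names(v) <- colnames(X)
    v[p[2]] <- 1; v[p[1]] <- -1
    v
  }, numeric(ncol(X)))
  fit <- fit_linear_model(x, X)
  cf <- contrast_fit(fit, C)
  eb <- ebayes_moderate(fit$sigma2, fit$df_residual,
                        logFC = cf$logFC, se_unscaled = cf$se_unscaled)
  res <- do.call(rbind, lapply(colnames(C), function(cn) {
    data.frame(feature = rownames(x), comparison = cn,
               logFC = cf$logFC[, cn], t = eb$t[, cn], df = eb$df_total,
               P = eb$p[, cn], adjP = bh_adjust(eb$p[, cn]),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  class(res) <- c("de_table", "data.frame")
  res
}

#' Call differentially expressed features per comparison
#'
#' A feature is called in a comparison when its P value is strictly below
#' `alpha`; `use` selects raw or BH-adjusted P values (raw by default,
#' with the adjusted values always present in the table). Directions are
#' the sign of the logFC.
#'
#' @param de a `de_table` from [run_diffexpr()].
#' @param alpha significance cutoff.
#' @param use `"raw"` or `"adjusted"` P values.
#' @return named list (one element per comparison) of data frames with
#'   columns `feature`, `logFC`, `direction` (`"up"`/`"down"`).
#' @export
call_de <- function(de, alpha = 0.05, use = c("raw", "adjusted")) {
  use <- match.arg(use)
  pcol <- if (use == "raw") "P" else "adjP"
  out <- lapply(split(de, de$comparison), function(d) {
    hit <- d[[pcol]] < alpha
    data.frame(feature = d$feature[hit], logFC = d$logFC[hit],
               direction = ifelse(d$logFC[hit] > 0, "up", "down"),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out[intersect(c("N_vs_T", "N_vs_M", "T_vs_M"), names(out))]
}

#' Partition three DE sets into the 7 exclusive Venn regions
#'
#' @param de_sets named list of per-comparison DE calls as returned by
#'   [call_de()] (character vectors of features are also accepted).
#'   Missing comparisons are treated as empty.
#' @return data frame with one row per feature in the union: `feature`,
#'   `region` (comparisons joined by `+`), and one direction column per
#'   comparison (`"up"`, `"down"` or `""`). Regions are pairwise
#'   disjoint and their union is the union of the three sets.
#' @export
venn_partition <- function(de_sets) {
  comps <- c("N_vs_T", "N_vs_M", "T_vs_M")
  feats <- dirs <- stats::setNames(vector("list", 3), comps)
  for (cn in comps) {
    s <- de_sets[[cn]]
    if (is.null(s)) {
      feats[[cn]] <- character(0)
      dirs[[cn]] <- character(0)
    } else if (is.character(s)) {
      feats[[cn]] <- s
      dirs[[cn]] <- stats::setNames(rep("", length(s)), s)
    } else {
      feats[[cn]] <- s$feature
      dirs[[cn]] <- stats::setNames(as.character(s$direction), s$feature)
    }
  }
  universe <- sort(unique(unlist(feats)))
  if (!length(universe))
    return(data.frame(feature = character(), region = character(),
                      N_vs_T = character(), N_vs_M = character(),
                      T_vs_M = character(), stringsAsFactors = FALSE))
  member <- vapply(comps, function(cn) universe %in% feats[[cn]],
                   logical(length(universe)))
  member <- matrix(member, ncol = 3, dimnames = list(universe, comps))
  region <- apply(member, 1, function(m) paste(comps[m], collapse = "+"))
  dir_cols <- vapply(comps, function(cn) {
    d <- rep("", length(universe))
    hit <- member[, cn]
    d[hit] <- dirs[[cn]][universe[hit]]
    d
  }, character(length(universe)))
  out <- data.frame(feature = universe, region = unname(region),
                    dir_cols, row.names = NULL, stringsAsFactors = FALSE)
  colnames(out)[3:5] <- comps
  out
}

#' Sizes of the 7 Venn regions
#'
#' @param partition result of [venn_partition()].
#' @return named integer vector over the 7 region labels.
#' @export
venn_region_sizes <- function(partition) {
  comps <- c("N_vs_T", "N_vs_M", "T_vs_M")
  labels <- unlist(lapply(1:3, function(k)
    utils::combn(comps, k, paste, collapse = "+")))
  counts <- stats::setNames(integer(length(labels)), labels)
  tb <- table(partition$region)
  counts[names(tb)] <- as.integer(tb)
  counts
}
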