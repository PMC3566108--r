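#' Log2-transform raw counts
#'
#' Applies optional per-probe correction factors multiplicatively to the
#' counts, then transforms to `log2(count + 1)`. The pseudocount keeps
#' zero counts finite on the log scale.
#'
#' @param counts nonnegative count matrix (probes x samples).
#' @param correction_factors optional named positive vector of per-probe
#'   scaling factors (defaults to 1 for probes not listed).
#' @return matrix of log2 expression, same dimensions and dimnames.
#' @export
log_transform <- function(counts, correction_factors = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (!is.null(correction_factors)) {
    if (is.null(names(correction_factors)) || is.null(rownames(counts)))
      stop("correction factors and counts must both be named by probe")
    if (any(correction_factors <= 0))
      stop("correction factors must be positive")
    cf <- rep(1, nrow(counts))
    names(cf) <- rownames(counts)
    hit <- intersect(names(correction_factors), rownames(counts))
    cf[hit] <- correction_factors[hit]
    counts <- counts * cf
  }
  log2(counts + 1)
}

#' Per-sample detection threshold from negative-control probes
#'
#' The threshold for one sample is the mean of its negative-control
#' probe values plus twice their sample standard deviation (n-1
#' denominator), computed on whatever scale the values are given
#' (use log2-transformed controls to filter a log2 matrix).
#'
#' @param negctrl numeric vector of negative-control values for one
#'   sample (length >= 2), or a matrix (controls x samples) for which
#'   one threshold per column is returned.
#' @return numeric threshold (or vector of per-sample thresholds).
#' @export
detection_threshold <- function(negctrl) {
  if (is.matrix(negctrl)) {
    if (nrow(negctrl) < 2) stop("need >= 2 negative-control probes")
    return(apply(negctrl, 2, detection_threshold))
  }
  if (length(negctrl) < 2) stop("need >= 2 negative-control values")
  mean(negctrl) + 2 * stats::sd(negctrl)
}

#' Remove undetected and invariant features
#'
#' Drops a feature when (a) its value is below the per-sample detection
#' threshold in at least `min_below_frac` of the samples, or (b) its
#' interquartile range across samples is below `iqr_min` (a feature with
#' IQR exactly `iqr_min` is kept). The removal reasons are recorded in
#' the `"removed"` attribute of the result.
#'
#' @param x expression matrix (features x samples).
#' @param thresholds per-sample detection thresholds, one per column
#'   (see [detection_threshold()]).
#' @param min_below_frac fraction of samples below threshold at which a
#'   feature is declared undetected.
#' @param iqr_min minimum interquartile range (same units as `x`).
#' @return filtered matrix with attribute `removed`: a data frame with
#'   columns `feature`, `undetected`, `invariant`.
#' @export
filter_features <- function(x, thresholds, min_below_frac = 0.5,
                            iqr_min = 0.5) {
  x <- as.matrix(x)
  if (length(thresholds) != ncol(x))
    stop("need one threshold per sample")
  below <- sweep(x, 2, thresholds, `<`)
  undetected <- rowMeans(below) >= min_below_frac
  iqrs <- apply(x, 1, stats::IQR)
  invariant <- iqrs < iqr_min
  drop <- undetected | invariant
  if (all(drop)) stop("all features removed by filtering")
  removed <- data.frame(feature = rownames(x)[drop],
                        undetected = undetected[drop],
                        invariant = invariant[drop],
                        row.names = NULL, stringsAsFactors = FALSE)
  out <- x[!drop, , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Quantile normalization
#'
#' Forces every sample (column) to share one empirical distribution: the
#' across-sample mean of the sorted columns. Tied values within a column
#' receive the mean of the reference values at their tied ranks, so the
#' output is invariant to how ties are ordered.
#'
#' @param x numeric matrix (features x samples), no missing values, at
#'   least 2 samples.
#' @return normalized matrix, same dimensions and dimnames.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need >= 2 samples")
  if (anyNA(x)) stop("missing values are not supported")
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    assigned <- numeric(length(col))
    assigned[order(col)] <- ref
    # average the reference values over each group of tied input values
    out[, j] <- stats::ave(assigned, match(col, col))
  }
  out
}

#' Normalize samples to a set of invariant probes
#'
#' Per sample, subtracts the deviation of the mean of the invariant
#' probes' values from their grand mean, so the invariant set becomes
#' constant (in mean) across samples.
#'
#' @param x log2 expression matrix (features x samples).
#' @param invariant_ids row names of the invariant probes.
#' @return normalized matrix.
#' @export
normalize_to_invariants <- function(x, invariant_ids) {
  x <- as.matrix(x)
  hit <- intersect(invariant_ids, rownames(x))
  if (!length(hit)) stop("no invariant probe found in the matrix")
  m <- colMeans(x[hit, , drop = FALSE])
  sweep(x, 2, m - mean(m))
}

#' Preprocess raw cohort counts to a filtered, normalized log2 matrix
#'
#' The fixed stage order is: correction factors, log2 transform (of both
#' endogenous and negative-control counts), per-sample detection
#' thresholds from the log2 controls, detection + IQR filtering, then
#' normalization (quantile, or invariant-set). Thresholds are computed
#' on the log2 scale, and filtering precedes normalization so that
#' undetected probes cannot contaminate the reference quantiles.
#'
#' @param counts endogenous count matrix (probes x samples).
#' @param negctrl_counts negative-control count matrix (same samples).
#' @param correction_factors optional named per-probe scaling factors.
#' @param min_below_frac,iqr_min filtering parameters, see
#'   [filter_features()].
#' @param method `"quantile"` or `"invariant"` normalization.
#' @param invariant_ids probes for `method = "invariant"`.
#' @return list with elements `exprs` (normalized log2 matrix),
#'   `thresholds` (per-sample detection thresholds) and `removed` (the
#'   filter report).
#' @examples
#' cfg <- simulation_config(n_normal = 8, n_tumor = 8, n_mets = 0,
#'                          n_matched_pairs = 0, n_mirna = 30, n_mrna = 10,
#'                          seed = 3)
#' cohort <- simulate_cohort(cfg)
#' pp <- preprocess_counts(cohort$mirna_counts, cohort$negctrl_counts)
#' dim(pp$exprs)
#' @export
preprocess_counts <- function(counts, negctrl_counts,
                              correction_factors = NULL,
                              min_below_frac = 0.5, iqr_min = 0.5,
                              method = c("quantile", "invariant"),
                              invariant_ids = NULL) {
  method <- match.arg(method)
  if (nrow(negctrl_counts) < 1)
    stop("at least one negative-control probe is required")
  x <- log_transform(counts, correction_factors)
  neg <- log_transform(negctrl_counts)
  thr <- detection_threshold(neg)
  x <- filter_features(x, thr, min_below_frac = min_below_frac,
                       iqr_min = iqr_min)
  removed <- attr(x, "removed")
  x <- switch(method,
              quantile = quantile_normalize(x),
              invariant = normalize_to_invariants(x, invariant_ids))
  list(exprs = x, thresholds = thr, removed = removed)
}
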