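#' Load a miRNA-to-gene target-prediction table
#'
#' Reads a two-column TSV (miRNA, gene); a header row is detected when
#' the first line's fields are (case-insensitively) `mirna`/`mirna id`
#' and `gene`/`target`. Duplicated pairs are stored once; ids are passed
#' through unvalidated and matched against expression matrices later.
#'
#' @param file path to the TSV file.
#' @return data frame of class `target_pairs` with columns `mirna`,
#'   `gene`, unique rows.
#' @export
load_predictions <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- data.frame(mirna = character(), gene = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("target_pairs", "data.frame")
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2)
  if (length(bad))
    stop("malformed prediction row (expected 2 tab-separated fields) at line ",
         bad[1])
  first <- tolower(trimws(fields[[1]]))
  if (first[1] %in% c("mirna", "mir", "mirna_id") ||
      first[2] %in% c("gene", "target", "gene_symbol"))
    fields <- fields[-1]
  m <- do.call(rbind, fields)
  out <- unique(data.frame(mirna = trimws(m[, 1]), gene = trimws(m[, 2]),
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("target_pairs", "data.frame")
  out
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3. A constant vector
#'   has no defined correlation and yields `NA` (never 0).
#' @return correlation coefficient in `[-1, 1]`, or `NA`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

#' Target-filtered miRNA:mRNA anti-correlation
#'
#' For every predicted miRNA:gene pair present in both matrices, computes
#' the Pearson correlation across the matched samples (intersection of
#' the column names), keeps the negatively correlated pairs, and per
#' miRNA retains the `top_k` most anti-correlated genes (ranked
#' ascending by r). When a differential-expression table is supplied,
#' the pair's miRNA and gene logFCs for `logfc_comparison` are attached,
#' reproducing the published correlation-table layout (miRNA, miRNA
#' logFC, gene symbol, gene logFC, correlation).
#'
#' @param mirna_exprs,mrna_exprs log2 expression matrices; columns are
#'   sample ids; the matched set is their intersection (>= 3 samples
#'   required). Typically the tumor-sample columns.
#' @param predictions a `target_pairs` table (see [load_predictions()]).
#' @param top_k genes retained per miRNA (ranked by ascending r).
#' @param de optional `de_table` from [run_diffexpr()] supplying logFCs.
#' @param logfc_comparison which comparison's logFC to attach.
#' @return data frame of class `correlation_pairs` with columns `mirna`,
#'   `mirna_logFC`, `gene`, `gene_logFC`, `r`, sorted by miRNA then
#'   ascending r.
#' @export
anticorrelated_pairs <- function(mirna_exprs, mrna_exprs, predictions,
                                 top_k = 20, de = NULL,
                                 logfc_comparison = "N_vs_T") {
  if (!nrow(predictions)) stop("predictions are empty")
  shared <- intersect(colnames(mirna_exprs), colnames(mrna_exprs))
  if (length(shared) < 3) stop("need >= 3 matched samples")
  mm <- mirna_exprs[, shared, drop = FALSE]
  gg <- mrna_exprs[, shared, drop = FALSE]
  pred <- predictions[predictions$mirna %in% rownames(mm) &
                        predictions$gene %in% rownames(gg), , drop = FALSE]
  r <- vapply(seq_len(nrow(pred)), function(k)
    pearson_correlation(mm[pred$mirna[k], ], gg[pred$gene[k], ]),
    numeric(1))
  keep <- !is.na(r) & r < 0
  pred <- pred[keep, , drop = FALSE]
  r <- r[keep]
  out <- do.call(rbind, lapply(split(seq_along(r), pred$mirna), function(idx) {
    idx <- idx[order(r[idx])]
    idx <- idx[seq_len(min(top_k, length(idx)))]
    data.frame(mirna = pred$mirna[idx], gene = pred$gene[idx], r = r[idx],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(mirna = character(), gene = character(),
                      r = numeric(), stringsAsFactors = FALSE)
  lookup_fc <- function(ids) {
    if (is.null(de)) return(rep(NA_real_, length(ids)))
    d <- de[de$comparison == logfc_comparison, ]
    d$logFC[match(ids, d$feature)]
  }
  out <- data.frame(mirna = out$mirna, mirna_logFC = lookup_fc(out$mirna),
                    gene = out$gene, gene_logFC = lookup_fc(out$gene),
                    r = out$r, row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$mirna, out$r), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("correlation_pairs", "data.frame")
  out
}

#' Three-tissue trend opposition between a miRNA and a gene
#'
#' Counts in how many of the three pairwise comparisons (in a declared,
#' consistent order, e.g. N_vs_T, N_vs_M, T_vs_M) the miRNA and gene
#' logFCs have strictly opposite signs. A zero logFC has sign 0 and is
#' never counted as opposed. The flag is `"anti-trend"` for 3/3 opposed
#' comparisons, `"mostly anti"` for 2, `"mixed"` for 1 and `"none"` for
#' 0.
#'
#' @param mirna_logfc,gene_logfc numeric triples of logFCs over the same
#'   three comparisons in the same order.
#' @return list with `opposed` (0-3) and `flag`.
#' @export
trend_opposition <- function(mirna_logfc, gene_logfc) {
  stopifnot(length(mirna_logfc) == 3, length(gene_logfc) == 3)
  sm <- sign(mirna_logfc)
  sg <- sign(gene_logfc)
  opposed <- sum(sm != 0 & sg != 0 & sm == -sg)
  flag <- c("none", "mixed", "mostly anti", "anti-trend")[opposed + 1]
  list(opposed = as.integer(opposed), flag = flag)
}
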