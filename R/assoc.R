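#' Relative expression from qRT-PCR Ct triplicates
#'
#' Standard relative quantification: `dCt = mean(target Ct) - mean(reference
#' Ct)` over the technical triplicates, relative expression `2^(-dCt)`
#' against the reference gene (ACTB in the MGMT assay this package models).
#' Missing replicate values are dropped with a warning and the mean taken
#' over the remaining values.
#'
#' @param target_ct,reference_ct Numeric Ct triplicates (length 1-3 used
#'   values; `NA`s allowed).
#' @return Positive relative expression (scalar).
#' @examples
#' relative_expression(c(25, 25, 25), c(25, 25, 25))  # 1
#' relative_expression(c(26, 26, 26), c(25, 25, 25))  # 0.5
#' @export
relative_expression <- function(target_ct, reference_ct) {
  stopifnot(is.numeric(target_ct), is.numeric(reference_ct),
            length(target_ct) >= 1L, length(target_ct) <= 3L,
            length(reference_ct) >= 1L, length(reference_ct) <= 3L)
  if (anyNA(target_ct) || anyNA(reference_ct)) {
    warning("missing Ct replicate(s); mean taken over available values",
            call. = FALSE)
  }
  t_m <- mean(target_ct, na.rm = TRUE)
  r_m <- mean(reference_ct, na.rm = TRUE)
  if (!is.finite(t_m) || !is.finite(r_m)) {
    stop("no finite Ct values in a triplicate", call. = FALSE)
  }
  2 ^ (-(t_m - r_m))
}

#' Read a qRT-PCR expression CSV
#'
#' Expects columns `sample_id, ct_target_1..3, ct_ref_1..3` and computes each
#' sample's relative expression with [relative_expression()].
#'
#' @param path CSV path.
#' @return A tibble with `sample_id` and `relative_expression`.
#' @export
read_expression <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", paste0("ct_target_", 1:3), paste0("ct_ref_", 1:3))
  if (!all(need %in% names(x))) {
    stop(sprintf("'%s': expected columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  rel <- vapply(seq_len(nrow(x)), function(i) {
    relative_expression(unlist(x[i, paste0("ct_target_", 1:3)]),
                        unlist(x[i, paste0("ct_ref_", 1:3)]))
  }, numeric(1))
  tibble::tibble(sample_id = x$sample_id, relative_expression = rel)
}

#' Correlate each CpG's methylation with expression
#'
#' Per CpG (column), the Pearson correlation between methylation frequency
#' and log2 relative expression across samples, on pairwise-complete
#' observations. A CpG is `selected` iff `|r|` is strictly above the
#' threshold — the criterion used to pick CpGs for clustering. CpGs with
#' fewer than `min_n` complete pairs or zero variance are flagged unusable
#' and never selected. p-values are reported for transparency; selection is
#' on r alone.
#'
#' @param methylation Samples x CpGs numeric matrix (fractions; `NA` where a
#'   site was filtered out in a sample).
#' @param expression Positive relative expression per sample.
#' @param threshold Absolute-r selection threshold (default 0.7, strict).
#' @param log2_expression Correlate against `log2(expression)` (default) or
#'   the raw scale.
#' @param min_n Minimum complete pairs per CpG (default 4).
#' @return A tibble with one row per CpG: `cpg, r, p, n, selected, usable,
#'   reason`.
#' @export
correlate_cpgs <- function(methylation, expression, threshold = 0.7,
                           log2_expression = TRUE, min_n = 4L) {
  methylation <- as.matrix(methylation)
  stopifnot(nrow(methylation) == length(expression), threshold > 0)
  y_all <- if (log2_expression) log2(expression) else expression
  rows <- lapply(seq_len(ncol(methylation)), function(j) {
    x <- methylation[, j]
    ok <- !is.na(x) & !is.na(y_all)
    n <- sum(ok)
    if (n < min_n) {
      return(data.frame(cpg = colnames(methylation)[j], r = NA_real_,
                        p = NA_real_, n = n, selected = FALSE,
                        usable = FALSE, reason = "too_few_samples"))
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y_all[ok]) == 0) {
      return(data.frame(cpg = colnames(methylation)[j], r = NA_real_,
                        p = NA_real_, n = n, selected = FALSE,
                        usable = FALSE, reason = "zero_variance"))
    }
    ct <- stats::cor.test(x[ok], y_all[ok], method = "pearson")
    data.frame(cpg = colnames(methylation)[j], r = unname(ct$estimate),
               p = ct$p.value, n = n,
               selected = abs(unname(ct$estimate)) > threshold,
               usable = TRUE, reason = NA_character_)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Correlation between a region's mean methylation and expression
#'
#' Averages methylation over the CpG columns named (or indexed) by `columns`
#' per sample, then reports the Pearson correlation of that aggregate with
#' log2 relative expression — the exon-1-vs-expression and
#' intron-1-vs-expression summary view.
#'
#' @param methylation Samples x CpGs matrix.
#' @param expression Positive relative expression per sample.
#' @param columns Column names or indices forming the region.
#' @param log2_expression See [correlate_cpgs()].
#' @param min_n Minimum usable samples (default 4); fewer is an error.
#' @return A list with `r`, `p` and `n`.
#' @export
aggregate_correlation <- function(methylation, expression, columns,
                                  log2_expression = TRUE, min_n = 4L) {
  methylation <- as.matrix(methylation)
  agg <- rowMeans(methylation[, columns, drop = FALSE], na.rm = TRUE)
  y <- if (log2_expression) log2(expression) else expression
  ok <- is.finite(agg) & is.finite(y)
  if (sum(ok) < min_n) {
    stop(sprintf("aggregate correlation needs >= %d usable samples, have %d",
                 min_n, sum(ok)), call. = FALSE)
  }
  if (stats::sd(agg[ok]) == 0 || stats::sd(y[ok]) == 0) {
    stop("aggregate correlation undefined: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(agg[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Hierarchically cluster selected CpGs and samples
#'
#' Agglomerative clustering of CpGs (columns) and samples (rows) on
#' Euclidean distance with average linkage (the common heatmap default;
#' configurable), with the deterministic leaf ordering of [stats::hclust()]
#' (ties broken by input order). Distances use pairwise-complete
#' observations; a pair of rows/columns sharing no observation is an error.
#'
#' @param methylation Samples x CpGs matrix; typically restricted to the
#'   CpGs selected by [correlate_cpgs()].
#' @param k Number of clusters to cut (default 2, the position-dependent
#'   exon/intron split the MGMT panel shows).
#' @param method Linkage passed to [stats::hclust()] (default `"average"`).
#' @return A list of class `cluster_result`: `cpg_hclust`, `sample_hclust`,
#'   `cpg_clusters`, `sample_clusters`, `cpg_order`, `sample_order`.
#' @export
cluster_methylation <- function(methylation, k = 2L, method = "average") {
  methylation <- as.matrix(methylation)
  stopifnot(nrow(methylation) >= 2L, ncol(methylation) >= 2L)
  d_cpg <- stats::dist(t(methylation))   # pairwise-complete, rescaled
  d_sample <- stats::dist(methylation)
  if (anyNA(d_cpg) || anyNA(d_sample)) {
    stop("a pair of rows/columns shares no observed value; distance undefined",
         call. = FALSE)
  }
  hc_cpg <- stats::hclust(d_cpg, method = method)
  hc_sample <- stats::hclust(d_sample, method = method)
  structure(list(
    cpg_hclust = hc_cpg, sample_hclust = hc_sample,
    cpg_clusters = stats::cutree(hc_cpg, k = k),
    sample_clusters = stats::cutree(hc_sample, k = k),
    cpg_order = hc_cpg$labels[hc_cpg$order],
    sample_order = hc_sample$labels[hc_sample$order]),
    class = "cluster_result")
}
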