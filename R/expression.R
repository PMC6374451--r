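#' Two-group differential expression on FPKM
#'
#' Per-gene Welch test between two sample groups with Benjamini-Hochberg
#' correction across genes. By default the test runs on
#' `log2(FPKM + epsilon)` (variance-stabilising); the fold change is always
#' computed on the raw scale as
#' `(mean_cmp + epsilon) / (mean_ref + epsilon)`, matching the ">2 / <0.5"
#' threshold semantics. Genes are labelled `up` when `q < q_max` and
#' `fold_change > fc_up`, `down` when `q < q_max` and
#' `fold_change < fc_down`, otherwise `ns`. Genes untestable in either group
#' keep missing p/q and are `ns`.
#'
#' @param expr Expression matrix (genes x samples, FPKM).
#' @param sheet Sample sheet data.frame.
#' @param reference,comparison Group labels; orientation as in
#'   [diff_methylation()].
#' @param q_max,fc_up,fc_down Significance and fold-change thresholds
#'   (defaults 0.05, 2, 0.5).
#' @param epsilon Pseudocount added before log transform and in the
#'   fold-change ratio (default 0.1 FPKM).
#' @param test_scale `"log2"` (default) or `"raw"`: the scale the Welch test
#'   runs on. The fold change is unaffected.
#' @param min_fpkm Optional expression floor: genes whose mean FPKM is below
#'   this in both groups are reported untestable (default 0 = off).
#' @return Data.frame with `gene_id`, `n_ref`, `n_cmp`, `log2_fc`,
#'   `fold_change`, `t_stat`, `df`, `p`, `q`, `label`.
#' @export
de_test <- function(expr, sheet, reference, comparison, q_max = 0.05,
                    fc_up = 2, fc_down = 0.5, epsilon = 0.1,
                    test_scale = c("log2", "raw"), min_fpkm = 0) {
  test_scale <- match.arg(test_scale)
  cols <- group_columns(expr, sheet, reference, comparison)
  xr <- expr[, cols$ref, drop = FALSE]
  xc <- expr[, cols$cmp, drop = FALSE]
  x <- if (test_scale == "log2") log2(expr + epsilon) else expr
  res <- row_welch(x, cols$ref, cols$cmp)
  names(res)[names(res) == "feature_id"] <- "gene_id"
  m_ref <- rowMeans(xr, na.rm = TRUE)
  m_cmp <- rowMeans(xc, na.rm = TRUE)
  fold_change <- (m_cmp + epsilon) / (m_ref + epsilon)
  if (min_fpkm > 0) {
    low <- m_ref < min_fpkm & m_cmp < min_fpkm
    res$p[low] <- NA_real_
    res$t_stat[low] <- NA_real_
    res$df[low] <- NA_real_
  }
  res$q <- bh_adjust(res$p)
  res$fold_change <- fold_change
  res$log2_fc <- log2(fold_change)
  label <- rep("ns", nrow(res))
  ok <- !is.na(res$q)
  label[ok & res$q < q_max & fold_change > fc_up] <- "up"
  label[ok & res$q < q_max & fold_change < fc_down] <- "down"
  res$label <- label
  res[, c("gene_id", "n_ref", "n_cmp", "log2_fc", "fold_change", "t_stat",
          "df", "p", "q", "label")]
}
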