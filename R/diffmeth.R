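#' Welch's t-test for one feature
#'
#' Unpaired two-sided Welch (unequal-variance) t-test comparing a comparison
#' group against a reference group. The effect is reported as
#' `delta = mean(cmp) - mean(ref)`, so demethylation in the comparison group
#' is negative.
#'
#' @param values_ref Numeric vector for the reference group (NA allowed).
#' @param values_cmp Numeric vector for the comparison group (NA allowed).
#' @return A list with `delta`, `t_stat`, `df` (Welch-Satterthwaite degrees
#'   of freedom), `p` (two-sided), `n_ref`, `n_cmp`. Features with fewer than
#'   two non-missing values per group, or with zero variance in both groups,
#'   are untestable: `t_stat`, `df` and `p` are `NA`.
#' @export
welch_test <- function(values_ref, values_cmp) {
  res <- row_welch(rbind(f = c(values_ref, values_cmp)),
                   ref_cols = seq_along(values_ref),
                   cmp_cols = length(values_ref) + seq_along(values_cmp))
  list(delta = res$delta, t_stat = res$t_stat, df = res$df, p = res$p,
       n_ref = res$n_ref, n_cmp = res$n_cmp)
}

# Vectorised row-wise Welch test. x: features x samples matrix; ref_cols /
# cmp_cols: column indices or names. Missing values excluded pairwise.
row_welch <- function(x, ref_cols, cmp_cols) {
  xr <- x[, ref_cols, drop = FALSE]
  xc <- x[, cmp_cols, drop = FALSE]
  n1 <- rowSums(!is.na(xr))
  n2 <- rowSums(!is.na(xc))
  m1 <- rowMeans(xr, na.rm = TRUE)
  m2 <- rowMeans(xc, na.rm = TRUE)
  v1 <- rowSums((xr - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((xc - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  se2 <- v1 / n1 + v2 / n2
  testable <- n1 >= 2 & n2 >= 2 & se2 > 0
  tstat <- df <- p <- rep(NA_real_, nrow(x))
  tstat[testable] <- (m2[testable] - m1[testable]) / sqrt(se2[testable])
  df[testable] <- se2[testable]^2 /
    ((v1 / n1)[testable]^2 / (n1[testable] - 1) +
       (v2 / n2)[testable]^2 / (n2[testable] - 1))
  p[testable] <- 2 * stats::pt(abs(tstat[testable]), df[testable],
                               lower.tail = FALSE)
  delta <- m2 - m1
  delta[n1 == 0 | n2 == 0] <- NA_real_
  data.frame(feature_id = rownames(x), n_ref = n1, n_cmp = n2,
             delta = delta, t_stat = tstat, df = df, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment. `m` is the number of non-missing
#' p-values; missing entries are passed through as missing.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Vector of q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(p_values))
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

#' Per-probe differential methylation
#'
#' Runs an unpaired Welch test on every probe between two sample groups and
#' adjusts p-values with Benjamini-Hochberg across all testable probes.
#' Untestable probes (insufficient data or no variance) are reported with
#' missing p and q, never dropped.
#'
#' @param beta Beta-value matrix (probes x samples).
#' @param sheet Sample sheet data.frame (`sample_id`, `group_label`).
#' @param reference,comparison Group labels; `delta` is comparison minus
#'   reference.
#' @param probes Optional probe id subset to test (default all rows).
#' @return A data.frame with `probe_id`, `n_ref`, `n_cmp`, `delta`, `t_stat`,
#'   `df`, `p`, `q`.
#' @export
diff_methylation <- function(beta, sheet, reference, comparison,
                             probes = rownames(beta)) {
  cols <- group_columns(beta, sheet, reference, comparison)
  res <- row_welch(beta[probes, , drop = FALSE], cols$ref, cols$cmp)
  names(res)[names(res) == "feature_id"] <- "probe_id"
  res$q <- bh_adjust(res$p)
  res
}

#' Classify probes by significance and effect size
#'
#' Labels each tested feature `hypo` (q below `q_max` and delta below
#' `-delta_min`), `hyper` (q below `q_max` and delta above
#' `delta_min_hyper`), otherwise `ns`. Inequalities are strict, matching the
#' "methylation difference > 0.2" convention. The stricter volcano profile
#' used for replication-timing analysis sets `delta_min = 0.4` with no hyper
#' side (`delta_min_hyper = Inf`).
#'
#' @param results Data.frame from [diff_methylation()] (needs `delta`, `q`).
#' @param q_max Significance threshold on the BH q-value (default 0.05).
#' @param delta_min Minimum absolute group difference on the hypo side
#'   (default 0.2).
#' @param delta_min_hyper Minimum difference on the hyper side (defaults to
#'   `delta_min`; use `Inf` to disable hyper labels).
#' @return `results` with an added `label` column
#'   (`"hypo"`/`"hyper"`/`"ns"`). Untestable features are `ns`.
#' @export
classify_probes <- function(results, q_max = 0.05, delta_min = 0.2,
                            delta_min_hyper = delta_min) {
  ok <- !is.na(results$q) & !is.na(results$delta)
  label <- rep("ns", nrow(results))
  label[ok & results$q < q_max & results$delta < -delta_min] <- "hypo"
  label[ok & results$q < q_max & results$delta > delta_min_hyper] <- "hyper"
  results$label <- label
  results
}

#' CpG-context breakdown of labelled probes
#'
#' Cross-tabulates differential-methylation labels against CpG-island
#' context (Island / Shore / Shelf / OpenSea).
#'
#' @param labeled Data.frame from [classify_probes()] (needs `probe_id`,
#'   `label`).
#' @param annotation Probe annotation data.frame.
#' @return A list with `counts` (3 x 4 contingency table of label x context)
#'   and `proportions` (rows normalised to sum to 1; NaN row if a label is
#'   empty).
#' @export
cpg_context_breakdown <- function(labeled, annotation) {
  missing <- setdiff(labeled$probe_id, annotation$probe_id)
  if (length(missing)) {
    stop("probes absent from annotation: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) " ..." else "")
  }
  ctx <- annotation$cpg_context[match(labeled$probe_id, annotation$probe_id)]
  counts <- table(factor(labeled$label, levels = c("hypo", "hyper", "ns")),
                  factor(ctx, levels = cpg_context_levels()))
  names(dimnames(counts)) <- c("label", "context")
  proportions <- sweep(counts, 1L, rowSums(counts), "/")
  list(counts = counts, proportions = proportions)
}
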