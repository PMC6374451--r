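#' Map genes to their promoter probes
#'
#' A probe belongs to a gene's promoter when its annotation carries one of
#' the features `TSS1500`, `TSS200`, `5'UTR` or `1stExon` for that gene.
#' The manifest's semicolon-delimited multi-gene dialect is parsed, so one
#' probe can contribute to several genes; genes with no promoter probe are
#' absent from the result.
#'
#' @param annotation Probe annotation data.frame with parallel
#'   `gene_symbols` / `feature_groups` columns.
#' @return Named list: gene symbol -> character vector of probe ids.
#' @export
promoter_probe_sets <- function(annotation) {
  promoter_features <- c("TSS1500", "TSS200", "5'UTR", "1stExon")
  genes <- strsplit(annotation$gene_symbols, ";", fixed = TRUE)
  feats <- strsplit(annotation$feature_groups, ";", fixed = TRUE)
  n_each <- lengths(genes)
  if (any(n_each != lengths(feats))) {
    bad <- annotation$probe_id[n_each != lengths(feats)]
    stop("gene_symbols and feature_groups out of step for probe(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  long <- data.frame(probe_id = rep(annotation$probe_id, n_each),
                     gene = unlist(genes, use.names = FALSE),
                     feature = unlist(feats, use.names = FALSE),
                     stringsAsFactors = FALSE)
  long <- long[long$feature %in% promoter_features & long$gene != "", ,
               drop = FALSE]
  sets <- split(long$probe_id, long$gene)
  lapply(sets, unique)
}

#' Summarise promoter methylation by the top-25% rule
#'
#' For each gene: rank its promoter probes by the absolute difference of
#' group mean beta-values, keep the top `ceil(top_fraction * n)` (at least
#' one; ties broken by probe id), average the selected probes per sample to
#' get a promoter methylation score, then Welch-test the scores between
#' groups and adjust across genes with Benjamini-Hochberg.
#'
#' @param beta Beta-value matrix (probes x samples).
#' @param sheet Sample sheet data.frame.
#' @param gene_probes Named list gene -> promoter probe ids, from
#'   [promoter_probe_sets()]. Probes absent from `beta` are ignored; genes
#'   left with no probe are dropped.
#' @param reference,comparison Group labels; `promoter_delta` is comparison
#'   minus reference.
#' @param top_fraction Fraction of most-different probes averaged (default
#'   0.25).
#' @param ranking `"absolute"` (default) or `"signed"`: whether probes are
#'   ranked by |mean difference| or by the signed difference (most negative
#'   first).
#' @return Data.frame with `gene`, `n_promoter_probes`, `n_selected`,
#'   `selected_probes` (semicolon-joined), `promoter_delta`, `t_stat`, `df`,
#'   `promoter_p`, `promoter_q`. A sample whose selected probes are all
#'   missing gets a missing score for that gene.
#' @export
summarize_promoter <- function(beta, sheet, gene_probes, reference,
                               comparison, top_fraction = 0.25,
                               ranking = c("absolute", "signed")) {
  ranking <- match.arg(ranking)
  cols <- group_columns(beta, sheet, reference, comparison)
  gene_probes <- lapply(gene_probes, intersect, rownames(beta))
  gene_probes <- gene_probes[lengths(gene_probes) > 0L]
  if (length(gene_probes) == 0L) stop("no gene has promoter probes in beta")
  genes <- names(gene_probes)

  scores <- matrix(NA_real_, nrow = length(genes), ncol = ncol(beta),
                   dimnames = list(genes, colnames(beta)))
  n_probes <- n_selected <- integer(length(genes))
  selected <- character(length(genes))
  for (i in seq_along(genes)) {
    probes <- sort(gene_probes[[i]], method = "radix")
    x <- beta[probes, , drop = FALSE]
    d <- rowMeans(x[, cols$cmp, drop = FALSE], na.rm = TRUE) -
      rowMeans(x[, cols$ref, drop = FALSE], na.rm = TRUE)
    key <- if (ranking == "absolute") -abs(d) else d
    ord <- order(key, probes, method = "radix")
    n_sel <- max(1L, as.integer(ceiling(top_fraction * length(probes))))
    sel <- probes[ord][seq_len(n_sel)]
    scores[i, ] <- colMeans(x[sel, , drop = FALSE], na.rm = TRUE)
    n_probes[i] <- length(probes)
    n_selected[i] <- n_sel
    selected[i] <- paste(sel, collapse = ";")
  }
  scores[is.nan(scores)] <- NA_real_

  res <- row_welch(scores, cols$ref, cols$cmp)
  data.frame(gene = genes,
             n_promoter_probes = n_probes,
             n_selected = n_selected,
             selected_probes = selected,
             promoter_delta = res$delta,
             t_stat = res$t_stat,
             df = res$df,
             promoter_p = res$p,
             promoter_q = bh_adjust(res$p),
             stringsAsFactors = FALSE)
}

#' Starburst classification of methylation-expression pairs
#'
#' Joint classification of promoter methylation change and expression
#' change. A gene is `up_with_demethylation` when all of: expression
#' `q < q_max` and `fold_change > fc_min`, promoter `q < q_max` and
#' `promoter_delta < -delta_min`. `down_with_hypermethylation` is the mirror
#' (`fold_change < 1/fc_min`, `promoter_delta > delta_min`); everything else
#' is `other`. Only genes with both a promoter summary and an expression
#' result are classified.
#'
#' @param promoters Data.frame from [summarize_promoter()].
#' @param expression Data.frame from [de_test()].
#' @param q_max,delta_min,fc_min Thresholds (defaults 0.05, 0.2, 2).
#' @return Data.frame with `gene`, `fold_change`, `log2_fc`,
#'   `expression_q`, `promoter_delta`, `promoter_q`, `category`, plus signed
#'   `-log10 q` plot axes (`signed_log_q_expression`,
#'   `signed_log_q_promoter`; sign follows the direction of change).
#' @export
starburst_classify <- function(promoters, expression, q_max = 0.05,
                               delta_min = 0.2, fc_min = 2) {
  common <- intersect(promoters$gene, expression$gene_id)
  pm <- promoters[match(common, promoters$gene), ]
  ex <- expression[match(common, expression$gene_id), ]
  up <- !is.na(ex$q) & ex$q < q_max & ex$fold_change > fc_min &
    !is.na(pm$promoter_q) & pm$promoter_q < q_max &
    pm$promoter_delta < -delta_min
  down <- !is.na(ex$q) & ex$q < q_max & ex$fold_change < 1 / fc_min &
    !is.na(pm$promoter_q) & pm$promoter_q < q_max &
    pm$promoter_delta > delta_min
  category <- rep("other", length(common))
  category[up] <- "up_with_demethylation"
  category[down] <- "down_with_hypermethylation"
  data.frame(gene = common,
             fold_change = ex$fold_change,
             log2_fc = ex$log2_fc,
             expression_q = ex$q,
             promoter_delta = pm$promoter_delta,
             promoter_q = pm$promoter_q,
             category = category,
             signed_log_q_expression = sign(ex$log2_fc) * -log10(ex$q),
             signed_log_q_promoter = sign(pm$promoter_delta) *
               -log10(pm$promoter_q),
             stringsAsFactors = FALSE)
}

#' Per-probe promoter demethylation scan
#'
#' For each upregulated gene, lists the individual promoter probes that are
#' significantly demethylated (probe `q < q_max` and `delta < -delta_min`),
#' instead of relying on the averaged promoter score. Genes with at least
#' one such probe are flagged.
#'
#' @param upregulated_genes Character vector of gene symbols.
#' @param diffmeth_results Data.frame from [diff_methylation()].
#' @param gene_probes Named list gene -> promoter probe ids.
#' @param q_max,delta_min Thresholds (defaults 0.05, 0.2).
#' @return Named list: gene -> character vector of passing probe ids; only
#'   genes with a non-empty set appear.
#' @export
per_probe_promoter_scan <- function(upregulated_genes, diffmeth_results,
                                    gene_probes, q_max = 0.05,
                                    delta_min = 0.2) {
  pass <- diffmeth_results$probe_id[
    !is.na(diffmeth_results$q) & diffmeth_results$q < q_max &
      !is.na(diffmeth_results$delta) & diffmeth_results$delta < -delta_min]
  out <- lapply(upregulated_genes, function(g) {
    probes <- gene_probes[[g]]
    if (is.null(probes)) character(0) else
      sort(intersect(probes, pass), method = "radix")
  })
  names(out) <- upregulated_genes
  out[lengths(out) > 0L]
}
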