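#' Filter probes for clustering
#'
#' Removes probes targeting the X and Y chromosomes and probes with a common
#' SNP within five base pairs of (or at) the targeted CpG, the standard
#' pre-clustering exclusion for Infinium arrays.
#'
#' @param annotation Probe annotation data.frame with `sex_chromosome` and
#'   `snp_within_5bp` logical columns.
#' @return Character vector of retained probe ids.
#' @export
filter_probes <- function(annotation) {
  keep <- !annotation$sex_chromosome & !annotation$snp_within_5bp
  out <- annotation$probe_id[keep]
  if (length(out) == 0L) message("filter_probes: no probes retained")
  out
}

#' Select the most variable probes
#'
#' Ranks probes by the sample standard deviation of their beta-values
#' (denominator n-1, missing excluded pairwise) and returns the top `k`.
#' Ties are broken by probe id in lexicographic (C-locale) order. Probes with
#' fewer than two non-missing values cannot be ranked and are excluded.
#'
#' @param beta Beta-value matrix (probes x samples).
#' @param k Number of probes to return (default 10000, capped at the number
#'   of rankable probes).
#' @return Character vector of probe ids, most variable first.
#' @export
select_top_variable <- function(beta, k = 10000) {
  n <- rowSums(!is.na(beta))
  rankable <- n >= 2L
  if (any(!rankable)) {
    message("select_top_variable: excluding ", sum(!rankable),
            " probe(s) with <2 non-missing values")
  }
  x <- beta[rankable, , drop = FALSE]
  mu <- rowMeans(x, na.rm = TRUE)
  sdv <- sqrt(rowSums((x - mu)^2, na.rm = TRUE) / (n[rankable] - 1))
  if (k > length(sdv)) stop("k exceeds the number of rankable probes")
  ord <- order(-sdv, rownames(x), method = "radix")
  rownames(x)[ord][seq_len(k)]
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of samples over the selected probes, using
#' Euclidean distance and the ward.D2 linkage convention (Ward's criterion
#' on unsquared distances, as in `hclust`). Cutting the dendrogram yields
#' `k` groups. Probes with any missing value across the clustered samples
#' are dropped with a message.
#'
#' @param beta Beta-value matrix (probes x samples).
#' @param probes Probe ids to cluster on (e.g. from
#'   [select_top_variable()]).
#' @param k Number of clusters (1 <= k <= number of samples).
#' @return An object of class `cluster_assignment`: a list with
#'   `assignment` (named integer vector, sample -> cluster 1..k), `hclust`
#'   (the dendrogram as an `stats::hclust` object), `k` and
#'   `selected_probes` (probes actually used, after missing-value drops).
#' @export
hierarchical_cluster <- function(beta, probes, k) {
  if (k < 1L) stop("k must be >= 1")
  if (k > ncol(beta)) stop("k exceeds the number of samples")
  x <- beta[probes, , drop = FALSE]
  complete <- rowSums(is.na(x)) == 0L
  if (any(!complete)) {
    message("hierarchical_cluster: dropping ", sum(!complete),
            " probe(s) with missing values")
    x <- x[complete, , drop = FALSE]
  }
  if (nrow(x) == 0L) stop("no complete probes left to cluster on")
  hc <- stats::hclust(stats::dist(t(x), method = "euclidean"),
                      method = "ward.D2")
  assignment <- stats::cutree(hc, k = k)
  structure(list(assignment = assignment, hclust = hc, k = k,
                 selected_probes = rownames(x)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment: ", length(x$assignment), " samples in ", x$k,
      " cluster(s) over ", length(x$selected_probes), " probes\n", sep = "")
  print(table(cluster = x$assignment))
  invisible(x)
}
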