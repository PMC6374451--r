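#' Annotate probes with replication-timing values
#'
#' Looks up the replication-timing value at each probe position. Probe
#' positions are 1-based; track intervals are 0-based half-open (bedGraph),
#' so a probe at position `p` falls in the interval with
#' `start <= p - 1 < end`. When several tracks are supplied (e.g. Repli-seq
#' profiles from two neural-progenitor lines) their values at each probe are
#' averaged; a probe missing from any gap in a track contributes only the
#' tracks that cover it. Probes covered by no track get a missing value.
#'
#' @param annotation Probe annotation data.frame (`probe_id`, `chrom`,
#'   `pos`).
#' @param track A replication-timing track data.frame (from
#'   [read_rt_track()]) or a list of such tracks.
#' @return A data.frame with `probe_id`, `rt_value` (NA when uncovered) and
#'   `rt_category` (all `"unassigned"` until [categorize_rt()] is applied).
#' @export
annotate_probes_rt <- function(annotation, track) {
  tracks <- if (is.data.frame(track)) list(track) else track
  probe_gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = annotation$pos, width = 1L))
  vals <- matrix(NA_real_, nrow = nrow(annotation), ncol = length(tracks))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    missing_chrom <- setdiff(unique(annotation$chrom), unique(tr$chrom))
    if (length(missing_chrom)) {
      warning("chromosome(s) absent from replication-timing track: ",
              paste(missing_chrom, collapse = ", "),
              "; their probes are unassigned")
    }
    # bedGraph [start, end) -> 1-based closed [start + 1, end]
    tr_gr <- GenomicRanges::GRanges(
      seqnames = tr$chrom,
      ranges = IRanges::IRanges(start = tr$start + 1L, end = tr$end))
    hits <- GenomicRanges::findOverlaps(probe_gr, tr_gr, select = "first")
    vals[, i] <- tr$value[hits]
  }
  rt_value <- rowMeans(vals, na.rm = TRUE)
  rt_value[is.nan(rt_value)] <- NA_real_
  data.frame(probe_id = annotation$probe_id, rt_value = rt_value,
             rt_category = "unassigned", stringsAsFactors = FALSE)
}

#' Median-based replication-timing thresholds
#'
#' The late/early cutpoints are the medians of the strictly negative and
#' strictly positive replication-timing values respectively; zeros belong to
#' neither sign and are excluded. Even-length medians are the midpoint of
#' the central pair.
#'
#' @param rt_values Numeric vector of signed replication-timing values (NA
#'   ignored).
#' @return Named numeric vector `c(late_cut = ..., early_cut = ...)`.
#' @export
compute_rt_thresholds <- function(rt_values) {
  rt_values <- rt_values[!is.na(rt_values)]
  neg <- rt_values[rt_values < 0]
  pos <- rt_values[rt_values > 0]
  if (length(neg) == 0L || length(pos) == 0L) {
    stop("need at least one strictly negative and one strictly positive ",
         "replication-timing value")
  }
  c(late_cut = stats::median(neg), early_cut = stats::median(pos))
}

#' Categorise probes by replication timing
#'
#' Assigns `late` when `rt_value <= late_cut`, `intermediate` when
#' `late_cut < rt_value <= early_cut`, `early` when `rt_value > early_cut`;
#' both boundaries are inclusive on the lower category. Probes without a
#' replication-timing value stay `unassigned`.
#'
#' @param rt_annotation Data.frame from [annotate_probes_rt()].
#' @param thresholds Named vector with `late_cut` and `early_cut`
#'   (`late_cut < early_cut`), e.g. from [compute_rt_thresholds()].
#' @return `rt_annotation` with `rt_category` filled in.
#' @export
categorize_rt <- function(rt_annotation, thresholds) {
  late_cut <- thresholds[["late_cut"]]
  early_cut <- thresholds[["early_cut"]]
  if (!(late_cut < early_cut)) stop("late_cut must be below early_cut")
  v <- rt_annotation$rt_value
  cat <- rep("unassigned", length(v))
  cat[!is.na(v) & v <= late_cut] <- "late"
  cat[!is.na(v) & v > late_cut & v <= early_cut] <- "intermediate"
  cat[!is.na(v) & v > early_cut] <- "early"
  rt_annotation$rt_category <- cat
  rt_annotation
}

#' Enrichment of demethylated probes by replication timing
#'
#' Tests whether a set of demethylated probes is distributed across the
#' late / intermediate / early categories differently from a comparator set,
#' with a Pearson chi-square test (no continuity correction). The
#' comparator is either all annotated probes (`mode = "all"`, mirroring the
#' published comparison, whose columns overlap) or the non-demethylated
#' complement (`mode = "complement"`, whose columns are independent). The
#' late-membership odds ratio is always computed on the complement 2x2
#' table (late vs not-late), so it is identical in both modes.
#'
#' @param demeth_probe_ids Character vector of demethylated probe ids (must
#'   be a subset of the annotated probes).
#' @param rt_annotation Categorised data.frame from [categorize_rt()];
#'   `unassigned` probes are excluded.
#' @param mode `"all"` (default) or `"complement"`.
#' @return An object of class `rt_enrichment`: list with `table` (3x2
#'   counts), `chi_square_stat`, `df`, `p`, `stdres` (standardised
#'   residuals), `odds_ratio_late`, `mode`. Zero-margin rows are dropped
#'   with a warning and `df` recomputed.
#' @export
rt_enrichment_test <- function(demeth_probe_ids, rt_annotation,
                               mode = c("all", "complement")) {
  mode <- match.arg(mode)
  ann <- rt_annotation[rt_annotation$rt_category != "unassigned", ,
                       drop = FALSE]
  extra <- setdiff(demeth_probe_ids, ann$probe_id)
  if (length(extra)) {
    stop("demethylated probes not among assigned annotated probes: ",
         paste(utils::head(extra, 10L), collapse = ", "))
  }
  is_demeth <- ann$probe_id %in% demeth_probe_ids
  cat <- factor(ann$rt_category, levels = c("late", "intermediate", "early"))
  demeth_col <- table(cat[is_demeth])
  other_col <- if (mode == "all") table(cat) else table(cat[!is_demeth])
  tab <- cbind(demethylated = as.integer(demeth_col),
               comparator = as.integer(other_col))
  rownames(tab) <- levels(cat)
  use <- rowSums(tab) > 0
  if (any(!use)) {
    warning("dropping empty replication-timing categorie(s): ",
            paste(rownames(tab)[!use], collapse = ", "))
  }
  test <- stats::chisq.test(tab[use, , drop = FALSE], correct = FALSE)
  # odds ratio of late membership, always on the independent partition
  comp <- table(cat[!is_demeth])
  a <- as.numeric(demeth_col[["late"]])
  b <- sum(demeth_col) - a
  cc <- as.numeric(comp[["late"]])
  d <- sum(comp) - cc
  structure(list(table = tab,
                 chi_square_stat = unname(test$statistic),
                 df = unname(test$parameter),
                 p = test$p.value,
                 stdres = test$stdres,
                 odds_ratio_late = (a * d) / (b * cc),
                 mode = mode),
            class = "rt_enrichment")
}

#' @export
print.rt_enrichment <- function(x, ...) {
  cat("Replication-timing enrichment (mode = ", x$mode, ")\n", sep = "")
  print(x$table)
  cat(sprintf("chi-square = %.4g, df = %d, p = %.3g\n",
              x$chi_square_stat, x$df, x$p))
  cat(sprintf("late-membership odds ratio = %.4g\n", x$odds_ratio_late))
  invisible(x)
}

#' Volcano-plot data with replication-timing colouring
#'
#' Convenience table joining differential-methylation effect sizes with
#' replication-timing categories for volcano-style plotting.
#'
#' @param results Data.frame from [diff_methylation()].
#' @param rt_annotation Categorised data.frame from [categorize_rt()].
#' @return Data.frame with `probe_id`, `delta`, `neg_log10_q`,
#'   `rt_category`.
#' @export
rt_volcano_data <- function(results, rt_annotation) {
  cat <- rt_annotation$rt_category[match(results$probe_id,
                                         rt_annotation$probe_id)]
  data.frame(probe_id = results$probe_id,
             delta = results$delta,
             neg_log10_q = -log10(results$q),
             rt_category = ifelse(is.na(cat), "unassigned", cat),
             stringsAsFactors = FALSE)
}
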