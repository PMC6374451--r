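#' Read a fusion candidate junction table
#'
#' Long-format TSV with one row per junction read: `candidate_id`, `gene5`,
#' `chrom5`, `pos5`, `gene3`, `chrom3`, `pos3`, `matched_bases_5`,
#' `matched_bases_3`. A candidate with no reads is a single row with missing
#' matched-base counts.
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame in the layout above.
#' @export
read_fusion_candidates <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  needed <- c("candidate_id", "gene5", "chrom5", "pos5", "gene3", "chrom3",
              "pos3", "matched_bases_5", "matched_bases_3")
  missing_cols <- setdiff(needed, colnames(df))
  if (length(missing_cols)) {
    stop("fusion table missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(stats::na.omit(c(df$matched_bases_5, df$matched_bases_3)) < 0)) {
    stop("matched base counts must be >= 0")
  }
  if (any(df$pos5 < 1 | df$pos3 < 1)) stop("breakpoint positions are 1-based")
  df
}

#' Filter fusion candidates
#'
#' Applies the junction-read filter: a read supports a candidate when it has
#' at least `min_match` aligned bases on each side of the junction; a
#' candidate is called when strictly more than `min_reads_exclusive`
#' supporting reads span the breakpoint and, for intrachromosomal
#' candidates, the breakpoints are at least `min_intra_distance` apart
#' (suppressing read-through transcripts between neighbouring genes).
#'
#' `failed_rules` decomposes a rejection: `read_through` (same chromosome,
#' distance below the minimum), `min_reads` (too few spanning reads
#' regardless of match quality), `min_match` (enough reads but too few pass
#' the per-read match rule). A candidate passes iff no rule failed.
#'
#' @param candidates Long-format data.frame from
#'   [read_fusion_candidates()] or [generate_fusion_candidates()].
#' @param min_match Minimum matched bases required on each side of the
#'   junction (inclusive; default 12).
#' @param min_reads_exclusive Supporting reads must exceed this count
#'   (strict; default 4, i.e. at least 5 reads).
#' @param min_intra_distance Minimum breakpoint distance on one chromosome
#'   (default 100000 bp); interchromosomal candidates are exempt.
#' @param count_all_reads If TRUE, the read-count rule is applied to all
#'   spanning reads rather than only those passing the match rule (default
#'   FALSE, the stricter reading).
#' @return Data.frame with `candidate_id`, `n_reads`, `n_supporting_reads`,
#'   `intra_distance` (NA for interchromosomal), `pass`, `failed_rules`
#'   (comma-joined, empty when passing).
#' @export
filter_fusions <- function(candidates, min_match = 12,
                           min_reads_exclusive = 4,
                           min_intra_distance = 100000,
                           count_all_reads = FALSE) {
  ids <- unique(candidates$candidate_id)
  out <- lapply(ids, function(id) {
    cand <- candidates[candidates$candidate_id == id, , drop = FALSE]
    has_read <- !is.na(cand$matched_bases_5) & !is.na(cand$matched_bases_3)
    n_reads <- sum(has_read)
    supporting <- has_read & cand$matched_bases_5 >= min_match &
      cand$matched_bases_3 >= min_match
    n_supporting <- sum(supporting)
    n_counted <- if (count_all_reads) n_reads else n_supporting
    intra <- cand$chrom5[1L] == cand$chrom3[1L]
    dist <- if (intra) abs(cand$pos5[1L] - cand$pos3[1L]) else NA_real_
    failed <- character(0)
    if (intra && dist < min_intra_distance) failed <- c(failed, "read_through")
    if (n_reads <= min_reads_exclusive) {
      failed <- c(failed, "min_reads")
    } else if (n_counted <= min_reads_exclusive) {
      failed <- c(failed, "min_match")
    }
    data.frame(candidate_id = id, n_reads = n_reads,
               n_supporting_reads = n_supporting, intra_distance = dist,
               pass = length(failed) == 0L,
               failed_rules = paste(failed, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
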