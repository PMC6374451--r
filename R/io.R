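#' Read a beta-value matrix
#'
#' Reads a probes x samples matrix of Infinium methylation beta-values from a
#' TSV file. The first column holds probe identifiers, the header row holds
#' sample identifiers, and cells are numeric beta-values in \[0, 1\] or the
#' missing token `"NA"`. Missing values are kept as `NA` and are never
#' imputed; downstream statistics exclude them pairwise.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix with probe ids as rownames and sample ids as
#'   colnames. Values are validated to lie in \[0, 1\].
#' @seealso [write_table()] for the inverse operation,
#'   [read_expression_matrix()] for the FPKM analogue.
#' @export
read_beta_matrix <- function(path) {
  m <- read_matrix_tsv(path, id_name = "probe_id")
  validate_beta_matrix(m)
  m
}

#' Read a gene expression matrix
#'
#' Reads a genes x samples matrix of FPKM values (fragments per kilobase of
#' exon per million mapped reads) from a TSV file with the same layout as
#' [read_beta_matrix()]. Values must be non-negative.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix with gene ids as rownames, sample ids as colnames.
#' @export
read_expression_matrix <- function(path) {
  m <- read_matrix_tsv(path, id_name = "gene_id")
  validate_expression_matrix(m)
  m
}

read_matrix_tsv <- function(path, id_name) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  if (ncol(df) < 2L) {
    stop("expected an id column plus at least one sample column in ", path)
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate ", id_name, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample_id: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in ", path)
  rownames(m) <- ids
  m
}

#' @keywords internal
validate_beta_matrix <- function(m) {
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("beta-value outside [0,1]: probe ", rownames(m)[bad[1L, 1L]],
         ", sample ", colnames(m)[bad[1L, 2L]],
         " (value ", m[bad[1L, , drop = FALSE]], ")")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate probe ids")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids")
  invisible(m)
}

#' @keywords internal
validate_expression_matrix <- function(m) {
  bad <- which(!is.na(m) & m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("negative FPKM: gene ", rownames(m)[bad[1L, 1L]],
         ", sample ", colnames(m)[bad[1L, 2L]])
  }
  invisible(m)
}

#' Read a probe annotation table
#'
#' Reads a manifest-like probe annotation TSV with columns `probe_id`,
#' `chrom`, `pos` (1-based coordinate of the target CpG), `cpg_context`,
#' `gene_symbols`, `feature_groups`, `snp_within_5bp`, `sex_chromosome`.
#'
#' `gene_symbols` / `feature_groups` follow the 450K manifest dialect:
#' parallel semicolon-delimited lists, so a probe annotated
#' `"GENE1;GENE2"` / `"TSS200;Body"` sits in the TSS200 of GENE1 and the body
#' of GENE2. CpG context is normalised: `N_Shore`/`S_Shore` collapse to
#' `Shore`, `N_Shelf`/`S_Shelf` to `Shelf`, and a blank context means
#' `OpenSea`.
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame with the columns above; `cpg_context` is one of
#'   `"Island"`, `"Shore"`, `"Shelf"`, `"OpenSea"`.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  needed <- c("probe_id", "chrom", "pos", "cpg_context", "gene_symbols",
              "feature_groups", "snp_within_5bp", "sex_chromosome")
  missing_cols <- setdiff(needed, colnames(df))
  if (length(missing_cols)) {
    stop("probe annotation missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, needed]
  df$probe_id <- as.character(df$probe_id)
  if (anyDuplicated(df$probe_id)) {
    stop("duplicate probe_id: ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "))
  }
  df$pos <- as.integer(df$pos)
  if (any(is.na(df$pos) | df$pos < 1L)) {
    stop("probe positions must be integers >= 1 (1-based)")
  }
  df$cpg_context <- normalize_cpg_context(df$cpg_context)
  df$gene_symbols <- ifelse(is.na(df$gene_symbols), "", df$gene_symbols)
  df$feature_groups <- ifelse(is.na(df$feature_groups), "", df$feature_groups)
  df$snp_within_5bp <- as.logical(df$snp_within_5bp)
  df$sex_chromosome <- as.logical(df$sex_chromosome)
  if (any(is.na(df$snp_within_5bp)) || any(is.na(df$sex_chromosome))) {
    stop("snp_within_5bp / sex_chromosome flags must be TRUE or FALSE")
  }
  df
}

#' @keywords internal
normalize_cpg_context <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == ""] <- "OpenSea"
  x[x %in% c("N_Shore", "S_Shore")] <- "Shore"
  x[x %in% c("N_Shelf", "S_Shelf")] <- "Shelf"
  x[x %in% c("Open sea", "Open_sea", "open_sea")] <- "OpenSea"
  ok <- x %in% cpg_context_levels()
  if (any(!ok)) {
    stop("unknown cpg_context value(s): ",
         paste(unique(x[!ok]), collapse = ", "))
  }
  x
}

cpg_context_levels <- function() c("Island", "Shore", "Shelf", "OpenSea")

#' Read a replication-timing bedGraph track
#'
#' Reads a standard 4-column bedGraph file (chrom, start, end, value) in
#' 0-based half-open coordinates. Positive values mark early-replicating
#' domains, negative values late-replicating domains. Intervals are sorted
#' within each chromosome; zero-length and overlapping intervals are
#' rejected.
#'
#' @param path Path to a bedGraph file (no track header lines).
#' @return A data.frame with columns `chrom`, `start`, `end`, `value`,
#'   sorted by chromosome then start.
#' @export
read_rt_track <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$value <- as.numeric(df$value)
  validate_rt_track(df)
}

#' @keywords internal
validate_rt_track <- function(df) {
  bad <- df$start >= df$end
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("replication-timing interval with start >= end: ",
         df$chrom[i], ":", df$start[i], "-", df$end[i])
  }
  df <- df[order(df$chrom, df$start, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  same_chrom <- df$chrom[-1L] == df$chrom[-nrow(df)]
  overlap <- same_chrom & df$start[-1L] < df$end[-nrow(df)]
  if (nrow(df) > 1L && any(overlap)) {
    i <- which(overlap)[1L]
    stop("overlapping replication-timing intervals: ",
         df$chrom[i], ":", df$start[i], "-", df$end[i], " and ",
         df$chrom[i + 1L], ":", df$start[i + 1L], "-", df$end[i + 1L])
  }
  df
}

#' Read a sample sheet
#'
#' Reads a TSV with columns `sample_id`, `group_label` and optionally
#' `pair_id` (linking initial/recurrent samples from one patient).
#'
#' @param path Path to a tab-separated file.
#' @return A data.frame with `sample_id`, `group_label` and, when present,
#'   `pair_id`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  if (!all(c("sample_id", "group_label") %in% colnames(df))) {
    stop("sample sheet needs columns sample_id and group_label")
  }
  df$sample_id <- as.character(df$sample_id)
  df$group_label <- as.character(df$group_label)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  keep <- intersect(c("sample_id", "group_label", "pair_id"), colnames(df))
  df[, keep, drop = FALSE]
}

#' Write a table or matrix as TSV
#'
#' Writes matrices (with an id column reconstructed from rownames) and
#' data.frames as tab-separated text. Numeric columns are formatted to at
#' most `digits` significant digits so outputs are diffable; pass
#' `digits = NA` for full precision.
#'
#' @param x A matrix or data.frame.
#' @param path Output path.
#' @param id_name Name of the id column used when `x` is a matrix with
#'   rownames (default `"id"`).
#' @param digits Significant digits for numeric columns (default 6; `NA`
#'   keeps full precision).
#' @return Invisibly, the path written.
#' @export
write_table <- function(x, path, id_name = "id", digits = 6) {
  if (is.matrix(x)) {
    df <- data.frame(rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- id_name
    rownames(df) <- NULL
    x <- df
  }
  if (!is.na(digits)) {
    num <- vapply(x, is.numeric, logical(1L))
    x[num] <- lapply(x[num], function(v) signif(v, digits))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a bedGraph track
#'
#' @param track A replication-timing data.frame as from [read_rt_track()].
#' @param path Output path.
#' @return Invisibly, the path written.
#' @export
write_rt_track <- function(track, path) {
  utils::write.table(track[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# Group column lookup shared by the two-group statistics. Checks the sample
# sheet covers the matrix columns exactly once per sample.
group_columns <- function(m, sheet, reference, comparison) {
  for (g in c(reference, comparison)) {
    if (!g %in% sheet$group_label) stop("group not in sample sheet: ", g)
  }
  ref_ids <- sheet$sample_id[sheet$group_label == reference]
  cmp_ids <- sheet$sample_id[sheet$group_label == comparison]
  missing <- setdiff(c(ref_ids, cmp_ids), colnames(m))
  if (length(missing)) {
    stop("samples in sheet but not in matrix: ",
         paste(missing, collapse = ", "))
  }
  list(ref = ref_ids, cmp = cmp_ids)
}
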