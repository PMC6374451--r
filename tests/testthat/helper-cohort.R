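# Shared default cohort (seed 1), generated once per test run and reused by
# the recovery tests, plus small builders for toy inputs.

.cohort_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.cohort_cache$cohort)) {
    .cohort_cache$cohort <- generate_cohort(simulation_config(rng_seed = 1))
  }
  .cohort_cache$cohort
}

# Small beta matrix + sheet with explicit group means, for hand-computable
# two-group statistics.
toy_two_group <- function(values_ref, values_cmp, probe_ids = NULL) {
  stopifnot(nrow(values_ref) == nrow(values_cmp))
  m <- cbind(values_ref, values_cmp)
  colnames(m) <- c(paste0("R", seq_len(ncol(values_ref))),
                   paste0("D", seq_len(ncol(values_cmp))))
  rownames(m) <- if (is.null(probe_ids)) {
    sprintf("p%02d", seq_len(nrow(m)))
  } else {
    probe_ids
  }
  sheet <- data.frame(
    sample_id = colnames(m),
    group_label = rep(c("C1", "C3"), c(ncol(values_ref), ncol(values_cmp))),
    stringsAsFactors = FALSE)
  list(beta = m, sheet = sheet)
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
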