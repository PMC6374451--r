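#' Simulation configuration
#'
#' Builds and validates the configuration for [generate_cohort()]. Defaults
#' emulate a hypermethylated (G-CIMP-like) reference group of 20 samples and
#' a partially demethylated comparison group of 9 samples whose planted
#' demethylation is concentrated in late-replicating, open-sea probes, plus
#' promoter-coupled expression up-shifts for a small set of planted genes.
#'
#' @param n_probes Number of array probes (default 10000).
#' @param n_genes Number of genes in the expression matrix (default 1000).
#' @param n_samples_ref,n_samples_cmp Samples in the reference and
#'   demethylated groups (defaults 20 and 9).
#' @param fraction_island,fraction_shore,fraction_shelf CpG-context mixture;
#'   the open-sea fraction is the remainder (defaults 0.30 / 0.23 / 0.10).
#' @param rt_domain_length Length in bp of one replication-timing domain
#'   (default 1e6).
#' @param n_rt_domains Number of alternating early/late domains tiling the
#'   single synthetic chromosome (default 50; chromosome length is
#'   `n_rt_domains * rt_domain_length`).
#' @param rt_profile `"blocks"` (piecewise-constant +/-`rt_amplitude`,
#'   default) or `"sine"` (smooth, creating an intermediate class under
#'   median thresholds).
#' @param rt_amplitude Magnitude of the replication-timing signal (default
#'   1).
#' @param planted_demeth_delta Beta-value drop applied to planted probes in
#'   the demethylated group (default 0.5, deep enough that planted probes
#'   clear both the 0.2 and 0.4 methylation-difference profiles above the
#'   noise; 0 gives a null cohort).
#' @param late_demeth_prob,early_demeth_prob Per-probe probability of
#'   planted demethylation for probes in late / early replicating domains
#'   (defaults 0.3 and 0.02).
#' @param n_planted_promoter_genes Genes whose promoter probes are forcibly
#'   demethylated and whose expression is up-shifted (default 3).
#' @param planted_expression_log2fc Log2 fold change planted on those genes
#'   (default 2).
#' @param beta_noise_concentration Concentration of the beta-shaped
#'   per-sample noise (shape1 + shape2; default 50, i.e. sd about 0.06 at
#'   mean 0.8).
#' @param expression_noise_sd Per-sample standard deviation of log2 FPKM
#'   around the gene mean (default 0.25).
#' @param contamination Fraction of a normal-brain-like methylation profile
#'   mixed into every sample (default 0; no published value to calibrate).
#' @param rng_seed Mandatory integer seed; all outputs are reproducible
#'   given the seed.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_probes = 10000, n_genes = 1000,
                              n_samples_ref = 20, n_samples_cmp = 9,
                              fraction_island = 0.30, fraction_shore = 0.23,
                              fraction_shelf = 0.10, rt_domain_length = 1e6,
                              n_rt_domains = 50,
                              rt_profile = c("blocks", "sine"),
                              rt_amplitude = 1,
                              planted_demeth_delta = 0.5,
                              late_demeth_prob = 0.3,
                              early_demeth_prob = 0.02,
                              n_planted_promoter_genes = 3,
                              planted_expression_log2fc = 2,
                              beta_noise_concentration = 50,
                              expression_noise_sd = 0.25,
                              contamination = 0,
                              rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is mandatory")
  cfg <- list(n_probes = as.integer(n_probes), n_genes = as.integer(n_genes),
              n_samples_ref = as.integer(n_samples_ref),
              n_samples_cmp = as.integer(n_samples_cmp),
              fraction_island = fraction_island,
              fraction_shore = fraction_shore,
              fraction_shelf = fraction_shelf,
              rt_domain_length = rt_domain_length,
              n_rt_domains = as.integer(n_rt_domains),
              rt_profile = match.arg(rt_profile),
              rt_amplitude = rt_amplitude,
              planted_demeth_delta = planted_demeth_delta,
              late_demeth_prob = late_demeth_prob,
              early_demeth_prob = early_demeth_prob,
              n_planted_promoter_genes = as.integer(n_planted_promoter_genes),
              planted_expression_log2fc = planted_expression_log2fc,
              beta_noise_concentration = beta_noise_concentration,
              expression_noise_sd = expression_noise_sd,
              contamination = contamination,
              rng_seed = as.integer(rng_seed))
  probs <- c(cfg$late_demeth_prob, cfg$early_demeth_prob, cfg$contamination,
             cfg$fraction_island, cfg$fraction_shore, cfg$fraction_shelf)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$fraction_island + cfg$fraction_shore + cfg$fraction_shelf >= 1) {
    stop("context fractions must leave room for open-sea probes")
  }
  if (cfg$planted_demeth_delta < 0 || cfg$planted_demeth_delta >= 1) {
    stop("planted_demeth_delta must lie in [0, 1)")
  }
  if (cfg$n_probes < 10L || cfg$n_genes < 1L) stop("cohort too small")
  if (cfg$n_samples_ref < 2L || cfg$n_samples_cmp < 2L) {
    stop("need at least two samples per group")
  }
  if (cfg$beta_noise_concentration <= 0) stop("concentration must be > 0")
  if (is.na(cfg$rng_seed)) stop("rng_seed must be an integer")
  structure(cfg, class = "simulation_config")
}

# Baseline group-mean beta by CpG context: hypermethylated G-CIMP-like
# reference (islands most methylated). Normal-brain profile used only for
# the contamination mixing option (islands largely unmethylated).
context_base_beta <- c(Island = 0.80, Shore = 0.75, Shelf = 0.72,
                      OpenSea = 0.70)
context_normal_beta <- c(Island = 0.15, Shore = 0.45, Shelf = 0.60,
                         OpenSea = 0.70)
# Probability that a probe of each context lands in an early-replicating
# domain: islands cluster in early, open sea in late chromatin.
context_early_prob <- c(Island = 0.85, Shore = 0.70, Shelf = 0.40,
                        OpenSea = 0.30)

#' Generate a synthetic methylation-expression cohort with ground truth
#'
#' Simulates one synthetic chromosome tiled with alternating early/late
#' replication-timing domains, places probes with CpG-context structure
#' (islands enriched in early domains and at promoters), draws beta-values
#' from beta-shaped noise around hypermethylated reference means, plants
#' demethylation in the comparison group with replication-timing-dependent
#' probability, couples a small set of planted genes to promoter
#' demethylation plus expression up-shift, and records the full ground
#' truth.
#'
#' @param config A [simulation_config()].
#' @return A list of class `sim_cohort` with elements `beta` (matrix),
#'   `annotation` (probe annotation data.frame), `track`
#'   (replication-timing data.frame), `expression` (FPKM matrix), `sheet`
#'   (sample sheet) and `truth` (list: `groups`, `demeth_probes`,
#'   `rt_category` at generation time, `planted_genes`, and the
#'   configuration used).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$rng_seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  chrom <- "chrS"
  chrom_len <- cfg$n_rt_domains * cfg$rt_domain_length

  ## replication-timing track
  if (cfg$rt_profile == "blocks") {
    starts <- (seq_len(cfg$n_rt_domains) - 1) * cfg$rt_domain_length
    values <- ifelse(seq_len(cfg$n_rt_domains) %% 2 == 1,
                     cfg$rt_amplitude, -cfg$rt_amplitude)
    track <- data.frame(chrom = chrom, start = starts,
                        end = starts + cfg$rt_domain_length, value = values)
  } else {
    # smooth profile sampled in 10 bins per domain; period = two domains,
    # phased so odd domains are positive (early) on average
    bin <- cfg$rt_domain_length / 10
    starts <- seq(0, chrom_len - bin, by = bin)
    mids <- starts + bin / 2
    values <- cfg$rt_amplitude *
      sin(pi * mids / cfg$rt_domain_length)
    track <- data.frame(chrom = chrom, start = starts, end = starts + bin,
                        value = values)
  }
  domain_early <- seq_len(cfg$n_rt_domains) %% 2 == 1

  ## probe contexts and positions
  ctx_probs <- c(cfg$fraction_island, cfg$fraction_shore, cfg$fraction_shelf,
                 1 - cfg$fraction_island - cfg$fraction_shore -
                   cfg$fraction_shelf)
  ctx <- sample(cpg_context_levels(), cfg$n_probes, replace = TRUE,
                prob = ctx_probs)
  in_early <- stats::rbinom(cfg$n_probes, 1L,
                            context_early_prob[ctx]) == 1L
  early_domains <- which(domain_early)
  late_domains <- which(!domain_early)
  domain <- integer(cfg$n_probes)
  domain[in_early] <- sample(early_domains, sum(in_early), replace = TRUE)
  domain[!in_early] <- sample(late_domains, sum(!in_early), replace = TRUE)
  offset <- sample.int(cfg$rt_domain_length, cfg$n_probes, replace = TRUE)
  pos <- (domain - 1) * cfg$rt_domain_length + offset  # 1-based
  # unique positions, probes ordered along the chromosome
  while (anyDuplicated(pos)) {
    dup <- duplicated(pos)
    pos[dup] <- (domain[dup] - 1) * cfg$rt_domain_length +
      sample.int(cfg$rt_domain_length, sum(dup), replace = TRUE)
  }
  ord <- order(pos)
  pos <- pos[ord]
  ctx <- ctx[ord]
  in_early <- in_early[ord]
  probe_ids <- sprintf("cg%08d", seq_len(cfg$n_probes))
  rt_truth <- ifelse(in_early, "early", "late")

  ## gene promoters
  gene_ids <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  promoter_feature_pool <- c("TSS1500", "TSS200", "5'UTR", "1stExon")
  n_pp <- sample(2:6, cfg$n_genes, replace = TRUE)
  weights <- c(Island = 5, Shore = 2, Shelf = 1, OpenSea = 1)[ctx]
  pool <- sample.int(cfg$n_probes, sum(n_pp), replace = FALSE,
                     prob = weights)
  gene_of <- rep(seq_len(cfg$n_genes), n_pp)
  gene_symbols <- feature_groups <- character(cfg$n_probes)
  feat <- sample(promoter_feature_pool, sum(n_pp), replace = TRUE)
  gene_symbols[pool] <- gene_ids[gene_of]
  feature_groups[pool] <- feat
  # occasional multi-gene probes (manifest dialect), always a Body entry so
  # promoter membership is unchanged
  multi <- sample(pool, max(1L, round(0.02 * length(pool))))
  extra_gene <- sample(gene_ids, length(multi), replace = TRUE)
  gene_symbols[multi] <- paste(gene_symbols[multi], extra_gene, sep = ";")
  feature_groups[multi] <- paste(feature_groups[multi], "Body", sep = ";")
  # gene-body-only probes, excluded from promoters
  body_pool <- sample(setdiff(seq_len(cfg$n_probes), pool),
                      round(0.10 * cfg$n_probes))
  gene_symbols[body_pool] <- sample(gene_ids, length(body_pool),
                                    replace = TRUE)
  feature_groups[body_pool] <- "Body"

  annotation <- data.frame(probe_id = probe_ids, chrom = chrom,
                           pos = as.integer(pos),
                           cpg_context = ctx, gene_symbols = gene_symbols,
                           feature_groups = feature_groups,
                           snp_within_5bp = FALSE, sex_chromosome = FALSE,
                           stringsAsFactors = FALSE)

  ## planted demethylation
  rt_at_probe <- annotate_probes_rt(annotation, track)$rt_value
  plant_prob <- ifelse(rt_at_probe < 0, cfg$late_demeth_prob,
                       cfg$early_demeth_prob)
  planted <- stats::rbinom(cfg$n_probes, 1L, plant_prob) == 1L
  planted_genes <- character(0)
  if (cfg$n_planted_promoter_genes > 0L) {
    eligible <- which(n_pp >= 2L)
    planted_gene_idx <- sample(eligible,
                               min(cfg$n_planted_promoter_genes,
                                   length(eligible)))
    planted_genes <- gene_ids[planted_gene_idx]
    planted[pool[gene_of %in% planted_gene_idx]] <- TRUE
  }
  if (cfg$planted_demeth_delta == 0) planted[] <- FALSE

  ## beta matrix
  sample_ids <- c(sprintf("REF%02d", seq_len(cfg$n_samples_ref)),
                  sprintf("DEM%02d", seq_len(cfg$n_samples_cmp)))
  groups <- rep(c("C1", "C3"), c(cfg$n_samples_ref, cfg$n_samples_cmp))
  mu_ref <- context_base_beta[ctx]
  mu_cmp <- ifelse(planted,
                   pmax(mu_ref - cfg$planted_demeth_delta, 0.02), mu_ref)
  if (cfg$contamination > 0) {
    mu_norm <- context_normal_beta[ctx]
    mu_ref <- (1 - cfg$contamination) * mu_ref + cfg$contamination * mu_norm
    mu_cmp <- (1 - cfg$contamination) * mu_cmp + cfg$contamination * mu_norm
  }
  conc <- cfg$beta_noise_concentration
  beta <- matrix(NA_real_, nrow = cfg$n_probes, ncol = length(sample_ids),
                 dimnames = list(probe_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    mu <- if (groups[j] == "C1") mu_ref else mu_cmp
    beta[, j] <- stats::rbeta(cfg$n_probes, mu * conc, (1 - mu) * conc)
  }

  ## expression matrix
  gene_base_log2 <- stats::rnorm(cfg$n_genes, mean = log2(20), sd = 1.5)
  expr_log2 <- matrix(
    gene_base_log2 + stats::rnorm(cfg$n_genes * length(sample_ids),
                                  sd = cfg$expression_noise_sd),
    nrow = cfg$n_genes, ncol = length(sample_ids),
    dimnames = list(gene_ids, sample_ids))
  if (length(planted_genes)) {
    expr_log2[planted_genes, groups == "C3"] <-
      expr_log2[planted_genes, groups == "C3"] +
      cfg$planted_expression_log2fc
  }
  expression <- 2^expr_log2

  sheet <- data.frame(sample_id = sample_ids, group_label = groups,
                      pair_id = NA_character_, stringsAsFactors = FALSE)

  truth <- list(groups = stats::setNames(groups, sample_ids),
                demeth_probes = probe_ids[planted],
                rt_category = stats::setNames(rt_truth, probe_ids),
                planted_genes = planted_genes,
                config = cfg)
  structure(list(beta = beta, annotation = annotation, track = track,
                 expression = expression, sheet = sheet, truth = truth),
            class = "sim_cohort")
}

#' Generate synthetic fusion candidates with decoys
#'
#' Builds a junction-read table in which every true fusion satisfies all
#' three calling rules and every decoy violates exactly one named rule:
#' `too_few_reads` has exactly four well-matched spanning reads,
#' `read_through` sits on one chromosome under 100,000 bp apart with ample
#' good reads, and `low_match` has ample reads that all fail the 12-base
#' rule on the 3' side. Randomness derives from `rng_seed + 1` so the table
#' is independent of, but reproducible with, the cohort draw.
#'
#' @param config A [simulation_config()].
#' @param n_true Number of true fusions (default 3).
#' @return List with `candidates` (long-format read table as in
#'   [read_fusion_candidates()]) and `truth` (data.frame: `candidate_id`,
#'   `is_true`, `decoy_class`, `expected_failed_rule`).
#' @export
generate_fusion_candidates <- function(config, n_true = 3) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$rng_seed + 1L, {
    rows <- list()
    truth <- list()
    mk_reads <- function(id, g5, c5, p5, g3, c3, p3, m5, m3) {
      data.frame(candidate_id = id, gene5 = g5, chrom5 = c5, pos5 = p5,
                 gene3 = g3, chrom3 = c3, pos3 = p3,
                 matched_bases_5 = m5, matched_bases_3 = m3,
                 stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_true)) {
      id <- sprintf("FUS%02d", i)
      n_reads <- sample(5:10, 1L)
      inter <- i %% 2 == 0
      c5 <- sample(paste0("chr", 1:22), 1L)
      c3 <- if (inter) sample(setdiff(paste0("chr", 1:22), c5), 1L) else c5
      p5 <- sample.int(9e7, 1L) + 6000000L  # room for the intra offset
      p3 <- if (inter) sample.int(1e8, 1L) else
        p5 + sample(100000:5000000, 1L) * sample(c(-1L, 1L), 1L)
      rows[[id]] <- mk_reads(id, sprintf("G5_%02d", i), c5, p5,
                             sprintf("G3_%02d", i), c3, p3,
                             sample(12:40, n_reads, replace = TRUE),
                             sample(12:40, n_reads, replace = TRUE))
      truth[[id]] <- data.frame(candidate_id = id, is_true = TRUE,
                                decoy_class = NA_character_,
                                expected_failed_rule = NA_character_,
                                stringsAsFactors = FALSE)
    }
    decoys <- list(
      too_few_reads = function(id) {
        c5 <- "chr3"
        mk_reads(id, "DG5a", c5, sample.int(1e8, 1L), "DG3a", "chr9",
                 sample.int(1e8, 1L),
                 sample(12:40, 4L, replace = TRUE),
                 sample(12:40, 4L, replace = TRUE))
      },
      read_through = function(id) {
        c5 <- "chr7"
        p5 <- sample.int(1e8, 1L)
        mk_reads(id, "DG5b", c5, p5, "DG3b", c5,
                 p5 + sample(5000:99999, 1L),
                 sample(12:40, 6L, replace = TRUE),
                 sample(12:40, 6L, replace = TRUE))
      },
      low_match = function(id) {
        mk_reads(id, "DG5c", "chr2", sample.int(1e8, 1L), "DG3c", "chr11",
                 sample.int(1e8, 1L),
                 sample(12:40, 6L, replace = TRUE),
                 sample(5:11, 6L, replace = TRUE))
      })
    rule_of <- c(too_few_reads = "min_reads", read_through = "read_through",
                 low_match = "min_match")
    for (cls in names(decoys)) {
      id <- paste0("DECOY_", cls)
      rows[[id]] <- decoys[[cls]](id)
      truth[[id]] <- data.frame(candidate_id = id, is_true = FALSE,
                                decoy_class = cls,
                                expected_failed_rule = rule_of[[cls]],
                                stringsAsFactors = FALSE)
    }
    list(candidates = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
  })
}

#' Write every artifact of a synthetic cohort to a directory
#'
#' @param cohort A `sim_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of the files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    beta = write_table(cohort$beta, file.path(dir, "beta.tsv"),
                       id_name = "probe_id", digits = 6),
    annotation = write_table(cohort$annotation,
                             file.path(dir, "probe_annotation.tsv")),
    track = write_rt_track(cohort$track, file.path(dir, "rt_track.bedgraph")),
    expression = write_table(cohort$expression,
                             file.path(dir, "expression.tsv"),
                             id_name = "gene_id", digits = 6),
    sheet = write_table(cohort$sheet, file.path(dir, "sample_sheet.tsv")))
  invisible(paths)
}
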