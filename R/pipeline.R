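#' Pipeline run configuration
#'
#' Collects inputs, group definitions and every analysis threshold (defaults
#' as published) for [run_all()]. Either `sim` (a [simulation_config()]) or
#' `inputs` (named paths: `beta`, `annotation`, `track`, `expression`,
#' `sheet`, optionally `fusions`) must be given.
#'
#' @param out_dir Output directory for stage TSVs and the report.
#' @param sim Optional [simulation_config()]; when present the cohort is
#'   simulated.
#' @param inputs Optional named list of input paths (used when `sim` is
#'   NULL).
#' @param reference,comparison Group labels compared (defaults `"C1"`,
#'   `"C3"` — the simulated cohort's labels).
#' @param k_clusters Clusters cut from the sample dendrogram (default 2).
#' @param top_n_probes Variance-selected probes for clustering (default
#'   10000, capped at the filtered probe count).
#' @param q_max Significance threshold used throughout (default 0.05).
#' @param delta_count Minimum |delta beta| for hypo/hyper probe counts
#'   (default 0.2).
#' @param delta_rt Minimum demethylation used for the replication-timing
#'   volcano profile (default 0.4, hypo side only).
#' @param fc_up,fc_down Expression fold-change thresholds (defaults 2, 0.5).
#' @param promoter_fraction Top fraction of most-different promoter probes
#'   averaged (default 0.25).
#' @param fusion_min_match,fusion_min_reads,fusion_min_distance Fusion
#'   filter thresholds (defaults 12, 4, 100000).
#' @param seed Run seed; mandatory when simulating.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir, sim = NULL, inputs = NULL,
                       reference = "C1", comparison = "C3", k_clusters = 2,
                       top_n_probes = 10000, q_max = 0.05, delta_count = 0.2,
                       delta_rt = 0.4, fc_up = 2, fc_down = 0.5,
                       promoter_fraction = 0.25, fusion_min_match = 12,
                       fusion_min_reads = 4, fusion_min_distance = 100000,
                       seed = NULL) {
  if (is.null(sim) && is.null(inputs)) {
    stop("either a simulation config or input paths are required")
  }
  if (!is.null(sim) && is.null(seed)) seed <- sim$rng_seed
  if (!is.null(sim) && is.null(sim$rng_seed)) stop("seed mandatory")
  thresholds <- c(top_n_probes = top_n_probes, q_max = q_max,
                  delta_count = delta_count, delta_rt = delta_rt,
                  fc_up = fc_up, fc_down = fc_down,
                  promoter_fraction = promoter_fraction,
                  fusion_min_match = fusion_min_match,
                  fusion_min_reads = fusion_min_reads,
                  fusion_min_distance = fusion_min_distance)
  if (q_max < 0 || any(thresholds[names(thresholds) != "q_max"] <= 0)) {
    stop("thresholds must be positive (q_max may be 0)")
  }
  structure(list(out_dir = out_dir, sim = sim, inputs = inputs,
                 reference = reference, comparison = comparison,
                 k_clusters = as.integer(k_clusters),
                 thresholds = as.list(thresholds), seed = seed),
            class = "run_config")
}

#' Run the full demethylation analysis pipeline
#'
#' Orchestrates simulate (or load) -> probe filtering and clustering ->
#' differential methylation (count and replication-timing profiles) ->
#' replication-timing annotation, thresholds and enrichment (both
#' comparator modes) -> differential expression -> promoter integration
#' (starburst + per-probe scan) -> fusion filtering. Every stage output is
#' written as TSV under `config$out_dir`; the same configuration and seed
#' reproduce the identical report.
#'
#' @param config A [run_config()].
#' @return An object of class `run_report`: summary counts per stage, the
#'   replication-timing thresholds and enrichment tests, the starburst gene
#'   list, fusion calls, the thresholds used, a file manifest and a config
#'   hash.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  th <- config$thresholds
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    t0 <- Sys.time()
    value <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    value
  }

  truth <- NULL
  if (!is.null(config$sim)) {
    cohort <- stage("simulate", generate_cohort(config$sim))
    fus <- stage("simulate_fusions", generate_fusion_candidates(config$sim))
    fusion_candidates <- fus$candidates
    truth <- cohort$truth
    truth$fusions <- fus$truth
    write_cohort(cohort, file.path(config$out_dir, "cohort"))
  } else {
    cohort <- stage("load", list(
      beta = read_beta_matrix(config$inputs$beta),
      annotation = read_probe_annotation(config$inputs$annotation),
      track = read_rt_track(config$inputs$track),
      expression = read_expression_matrix(config$inputs$expression),
      sheet = read_sample_sheet(config$inputs$sheet)))
    fusion_candidates <- if (!is.null(config$inputs$fusions)) {
      read_fusion_candidates(config$inputs$fusions)
    }
  }
  beta <- cohort$beta
  annotation <- cohort$annotation
  sheet <- cohort$sheet

  ## clustering
  clust <- stage("cluster", {
    kept <- filter_probes(annotation)
    top <- select_top_variable(beta[kept, , drop = FALSE],
                               k = min(th$top_n_probes, length(kept)))
    hierarchical_cluster(beta, top, k = config$k_clusters)
  })
  write_table(data.frame(sample_id = names(clust$assignment),
                         cluster = unname(clust$assignment)),
              file.path(config$out_dir, "clusters.tsv"))
  write_table(data.frame(merge1 = clust$hclust$merge[, 1L],
                         merge2 = clust$hclust$merge[, 2L],
                         height = clust$hclust$height),
              file.path(config$out_dir, "dendrogram.tsv"))

  ## differential methylation
  dm <- stage("diffmeth", {
    res <- diff_methylation(beta, sheet, config$reference, config$comparison)
    classify_probes(res, q_max = th$q_max, delta_min = th$delta_count)
  })
  write_table(dm, file.path(config$out_dir, "diffmeth.tsv"))
  context <- cpg_context_breakdown(dm, annotation)
  dm_rt_profile <- classify_probes(dm, q_max = th$q_max,
                                   delta_min = th$delta_rt,
                                   delta_min_hyper = Inf)

  ## replication timing
  rt <- stage("rt_enrich", {
    ann_rt <- annotate_probes_rt(annotation, cohort$track)
    thresholds <- compute_rt_thresholds(ann_rt$rt_value)
    ann_rt <- categorize_rt(ann_rt, thresholds)
    demeth <- dm_rt_profile$probe_id[dm_rt_profile$label == "hypo"]
    demeth <- intersect(demeth,
                        ann_rt$probe_id[ann_rt$rt_category != "unassigned"])
    list(annotation = ann_rt, thresholds = thresholds, demeth = demeth,
         test_all = if (length(demeth))
           rt_enrichment_test(demeth, ann_rt, mode = "all"),
         test_complement = if (length(demeth))
           rt_enrichment_test(demeth, ann_rt, mode = "complement"))
  })
  write_table(rt$annotation, file.path(config$out_dir, "rt_annotation.tsv"))
  write_table(rt_volcano_data(dm, rt$annotation),
              file.path(config$out_dir, "rt_volcano.tsv"))

  ## expression
  de <- stage("de", de_test(cohort$expression, sheet, config$reference,
                            config$comparison, q_max = th$q_max,
                            fc_up = th$fc_up, fc_down = th$fc_down))
  write_table(de, file.path(config$out_dir, "expression_de.tsv"))

  ## promoter integration
  integ <- stage("integrate", {
    gene_probes <- promoter_probe_sets(annotation)
    promoters <- summarize_promoter(beta, sheet, gene_probes,
                                    config$reference, config$comparison,
                                    top_fraction = th$promoter_fraction)
    star <- starburst_classify(promoters, de, q_max = th$q_max,
                               delta_min = th$delta_count,
                               fc_min = th$fc_up)
    scan <- per_probe_promoter_scan(de$gene_id[de$label == "up"], dm,
                                    gene_probes, q_max = th$q_max,
                                    delta_min = th$delta_count)
    list(promoters = promoters, star = star, scan = scan)
  })
  write_table(integ$promoters,
              file.path(config$out_dir, "promoter_summary.tsv"))
  write_table(integ$star, file.path(config$out_dir, "starburst.tsv"))

  ## fusions
  fusion_calls <- NULL
  if (!is.null(fusion_candidates)) {
    fusion_calls <- stage("fusions", filter_fusions(
      fusion_candidates, min_match = th$fusion_min_match,
      min_reads_exclusive = th$fusion_min_reads,
      min_intra_distance = th$fusion_min_distance))
    write_table(fusion_calls, file.path(config$out_dir, "fusion_calls.tsv"))
  }

  cfg_path <- file.path(config$out_dir, "run_config.yaml")
  yaml::write_yaml(serializable_config(config), cfg_path)
  starburst_genes <-
    integ$star$gene[integ$star$category == "up_with_demethylation"]

  report <- structure(list(
    n_samples = ncol(beta),
    n_probes = nrow(beta),
    cluster_sizes = as.integer(table(clust$assignment)),
    n_hypo = sum(dm$label == "hypo"),
    n_hyper = sum(dm$label == "hyper"),
    context_counts = context$counts,
    rt_thresholds = rt$thresholds,
    rt_test_all = rt$test_all,
    rt_test_complement = rt$test_complement,
    n_up = sum(de$label == "up"),
    n_down = sum(de$label == "down"),
    starburst_genes = sort(starburst_genes),
    scan_genes = sort(names(integ$scan)),
    fusion_calls = fusion_calls,
    truth = truth,
    thresholds = th,
    seed = config$seed,
    manifest = sort(list.files(config$out_dir, recursive = TRUE)),
    config_hash = unname(tools::md5sum(cfg_path)),
    version = as.character(utils::packageVersion("gcimpdemeth"))),
    class = "run_report")
  saveRDS_path <- file.path(config$out_dir, "report.txt")
  writeLines(utils::capture.output(print(report)), saveRDS_path)
  report
}

# Drop non-scalar members so the config hashes/serialises stably.
serializable_config <- function(config) {
  list(reference = config$reference, comparison = config$comparison,
       k_clusters = config$k_clusters, thresholds = config$thresholds,
       seed = config$seed,
       sim = if (!is.null(config$sim)) unclass(config$sim),
       inputs = config$inputs)
}

#' @export
print.run_report <- function(x, ...) {
  cat("== demethylation pipeline report (gcimpdemeth ", x$version, ") ==\n",
      sep = "")
  cat("samples:", x$n_samples, " probes:", x$n_probes,
      " seed:", x$seed, "\n")
  cat("clusters:", paste(x$cluster_sizes, collapse = "/"), "\n")
  cat("hypomethylated probes:", x$n_hypo,
      " hypermethylated probes:", x$n_hyper, "\n")
  cat("RT thresholds: late <=", format(x$rt_thresholds[["late_cut"]]),
      ", early >", format(x$rt_thresholds[["early_cut"]]), "\n")
  if (!is.null(x$rt_test_all)) {
    cat(sprintf("RT enrichment (all): chi2 = %.4g, p = %.3g\n",
                x$rt_test_all$chi_square_stat, x$rt_test_all$p))
    cat(sprintf(
      "RT enrichment (complement): chi2 = %.4g, p = %.3g, OR = %.3g\n",
      x$rt_test_complement$chi_square_stat, x$rt_test_complement$p,
      x$rt_test_complement$odds_ratio_late))
  } else {
    cat("RT enrichment: no demethylated probes at these thresholds\n")
  }
  cat("genes up:", x$n_up, " down:", x$n_down, "\n")
  cat("starburst (up with demethylation):",
      if (length(x$starburst_genes)) paste(x$starburst_genes, collapse = ", ")
      else "none", "\n")
  cat("per-probe promoter scan flags:",
      if (length(x$scan_genes)) paste(x$scan_genes, collapse = ", ")
      else "none", "\n")
  if (!is.null(x$fusion_calls)) {
    cat("fusion candidates passing:", sum(x$fusion_calls$pass), "of",
        nrow(x$fusion_calls), "\n")
  }
  cat("config hash:", x$config_hash, "\n")
  invisible(x)
}
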