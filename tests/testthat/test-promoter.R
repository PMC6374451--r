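promoter_annotation <- function() {
  data.frame(
    probe_id = sprintf("cg%02d", 1:12),
    gene_symbols = c("GENE1", "GENE1;GENE2", "GENE2", "GENE1", "GENE3",
                     "GENE3", "", "GENE4", "GENE4", "GENE4", "GENE4",
                     "GENE5"),
    feature_groups = c("TSS200", "TSS200;1stExon", "5'UTR", "Body",
                       "TSS1500", "1stExon", "", "TSS200", "TSS1500",
                       "5'UTR", "1stExon", "Body"),
    stringsAsFactors = FALSE)
}

test_that("promoter probe sets follow the four-feature rule", {
  sets <- promoter_probe_sets(promoter_annotation())
  # brute-force expectation
  expect_identical(sets$GENE1, c("cg01", "cg02"))  # Body cg04 excluded
  expect_identical(sets$GENE2, c("cg02", "cg03"))  # multi-mapped probe
  expect_identical(sets$GENE3, c("cg05", "cg06"))
  expect_identical(sets$GENE4, sprintf("cg%02d", 8:11))
  expect_null(sets$GENE5)  # Body-only gene absent
})

test_that("top-25% promoter aggregation matches a hand computation", {
  # 5 promoter probes, per-probe group differences -0.5 -0.4 -0.1 -0.05 0
  ref <- matrix(c(0.9, 0.9, 0.8, 0.8, 0.7, 0.7, 0.6, 0.6, 0.5, 0.5),
                nrow = 5, byrow = TRUE)
  cmp <- ref + c(-0.5, -0.4, -0.1, -0.05, 0)
  toy <- toy_two_group(ref, cmp)
  gene_probes <- list(G1 = rownames(toy$beta))
  ps <- summarize_promoter(toy$beta, toy$sheet, gene_probes, "C1", "C3")
  expect_identical(ps$n_selected, 2L)  # ceil(0.25 * 5)
  expect_identical(ps$selected_probes, "p01;p02")
  # promoter delta = mean of the two selected per-probe differences
  expect_equal(ps$promoter_delta, (-0.5 - 0.4) / 2, tolerance = 1e-12)

  # 8 probes -> ceil(2.0) = 2 selected; single probe -> itself
  toy8 <- toy_two_group(matrix(0.8, 8, 2),
                        matrix(0.8 - (1:8) / 20, 8, 2))
  ps8 <- summarize_promoter(toy8$beta, toy8$sheet,
                            list(G = rownames(toy8$beta)), "C1", "C3")
  expect_identical(ps8$n_selected, 2L)
  ps1 <- summarize_promoter(toy8$beta, toy8$sheet, list(G = "p03"),
                            "C1", "C3")
  expect_identical(ps1$selected_probes, "p03")
  expect_equal(ps1$promoter_delta, -3 / 20, tolerance = 1e-12)
})

test_that("promoter summary is invariant to probe input order", {
  withr::with_seed(29, {
    toy <- toy_two_group(matrix(runif(10 * 3, 0.6, 0.9), 10),
                         matrix(runif(10 * 2, 0.2, 0.9), 10))
    gp <- list(G1 = rownames(toy$beta)[1:6], G2 = rownames(toy$beta)[7:10])
    a <- summarize_promoter(toy$beta, toy$sheet, gp, "C1", "C3")
    gp_shuffled <- lapply(gp, sample)
    b <- summarize_promoter(toy$beta[sample(10), ], toy$sheet, gp_shuffled,
                            "C1", "C3")
    expect_equal(a, b)
  })
})

test_that("starburst categories follow the joint criteria", {
  promoters <- data.frame(
    gene = c("A", "B", "C", "D"),
    promoter_delta = c(-0.3, -0.3, 0.3, -0.1),
    promoter_q = c(0.01, 0.2, 0.01, 0.01),
    stringsAsFactors = FALSE)
  expression <- data.frame(
    gene_id = c("A", "B", "C", "D", "E"),
    fold_change = c(3, 3, 0.2, 3, 5),
    log2_fc = log2(c(3, 3, 0.2, 3, 5)),
    q = c(0.01, 0.01, 0.01, 0.01, 0.01),
    stringsAsFactors = FALSE)
  star <- starburst_classify(promoters, expression)
  got <- setNames(star$category, star$gene)
  expect_identical(unname(got["A"]), "up_with_demethylation")
  expect_identical(unname(got["B"]), "other")  # promoter q fails
  expect_identical(unname(got["C"]), "down_with_hypermethylation")
  expect_identical(unname(got["D"]), "other")  # delta too small
  expect_false("E" %in% star$gene)  # no promoter summary
})

test_that("the per-probe scan equals a brute-force filter", {
  dm <- data.frame(
    probe_id = sprintf("cg%02d", 1:5),
    delta = c(-0.5, -0.3, -0.1, -0.4, -0.6),
    q = c(0.01, 0.01, 0.01, 0.2, 0.01),
    stringsAsFactors = FALSE)
  gp <- list(G1 = sprintf("cg%02d", 1:5), G2 = "cg03", G3 = "cg04")
  scan <- per_probe_promoter_scan(c("G1", "G2", "G3"), dm, gp)
  expect_identical(scan$G1, c("cg01", "cg02", "cg05"))
  expect_false("G2" %in% names(scan))  # delta too small
  expect_false("G3" %in% names(scan))  # q too large
  # lowering delta_min only grows the lists
  scan0 <- per_probe_promoter_scan(c("G1", "G2", "G3"), dm, gp,
                                   delta_min = 0)
  expect_true(all(scan$G1 %in% scan0$G1))
  expect_true("G2" %in% names(scan0))
})

test_that("starburst genes are a subset of per-probe scan flags", {
  co <- default_cohort()
  gp <- promoter_probe_sets(co$annotation)
  dm <- diff_methylation(co$beta, co$sheet, "C1", "C3")
  de <- de_test(co$expression, co$sheet, "C1", "C3")
  promoters <- summarize_promoter(co$beta, co$sheet, gp, "C1", "C3")
  star <- starburst_classify(promoters, de)
  up_genes <- star$gene[star$category == "up_with_demethylation"]
  scan <- per_probe_promoter_scan(de$gene_id[de$label == "up"], dm, gp)
  expect_true(all(up_genes %in% names(scan)))
})
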