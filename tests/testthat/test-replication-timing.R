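toy_track <- function() {
  data.frame(chrom = "chr1", start = c(0, 1000), end = c(1000, 2000),
             value = c(-1.2, 0.9), stringsAsFactors = FALSE)
}

toy_annotation <- function(pos, chrom = "chr1") {
  data.frame(probe_id = sprintf("cg%03d", seq_along(pos)), chrom = chrom,
             pos = pos, stringsAsFactors = FALSE)
}

test_that("probes pick up the covering interval's value", {
  ann <- toy_annotation(c(500, 1000, 1001, 2001))
  rt <- annotate_probes_rt(ann, toy_track())
  # position p maps to 0-based p-1, so 1000 is still in [0,1000)
  expect_equal(rt$rt_value, c(-1.2, -1.2, 0.9, NA))
  expect_identical(rt$rt_category, rep("unassigned", 4))
})

test_that("interval lookup matches a linear-scan oracle", {
  withr::with_seed(13, {
    track <- data.frame(chrom = rep(c("chr1", "chr2"), each = 5),
                        start = rep(seq(0, 4000, 1000), 2),
                        end = rep(seq(1000, 5000, 1000), 2),
                        value = round(rnorm(10), 3))
    pos <- sample.int(6000, 20)  # positions past 5000 fall in gaps
    chrom <- sample(c("chr1", "chr2", "chr3"), 20, replace = TRUE)
    ann <- toy_annotation(pos, chrom)
    expect_warning(rt <- annotate_probes_rt(ann, track), "chr3")
    expect_equal(rt$rt_value, oracle_rt_lookup(pos, chrom, track))
  })
})

test_that("multiple tracks are averaged at each probe", {
  ann <- toy_annotation(c(500, 1500))
  t1 <- toy_track()
  t2 <- toy_track(); t2$value <- c(-0.8, 0.1)
  rt <- annotate_probes_rt(ann, list(t1, t2))
  expect_equal(rt$rt_value, c((-1.2 - 0.8) / 2, (0.9 + 0.1) / 2))
})

test_that("median thresholds come from the sign subsets", {
  expect_equal(compute_rt_thresholds(c(-2, -1, 1, 2)),
               c(late_cut = -1.5, early_cut = 1.5))
  # zeros belong to neither median
  expect_equal(compute_rt_thresholds(c(-2, -1, 0, 0, 1, 2)),
               c(late_cut = -1.5, early_cut = 1.5))
  withr::with_seed(17, {
    v <- rnorm(1001)
    th <- compute_rt_thresholds(v)
    neg <- sort(v[v < 0]); pos <- sort(v[v > 0])
    mid <- function(s) if (length(s) %% 2) s[(length(s) + 1) / 2] else
      (s[length(s) / 2] + s[length(s) / 2 + 1]) / 2
    expect_equal(unname(th), c(mid(neg), mid(pos)), tolerance = 1e-12)
  })
  expect_error(compute_rt_thresholds(c(1, 2, 3)), "negative")
})

test_that("category boundaries follow the printed inequalities", {
  th <- c(late_cut = -0.4599, early_cut = 0.80074)
  rt <- data.frame(probe_id = paste0("cg", 1:5),
                   rt_value = c(-0.4599, -0.46, 0.80074, 0.80074 + 1e-9, NA),
                   rt_category = "unassigned", stringsAsFactors = FALSE)
  got <- categorize_rt(rt, th)$rt_category
  expect_identical(got, c("late", "late", "intermediate", "early",
                          "unassigned"))
  expect_error(categorize_rt(rt, c(late_cut = 1, early_cut = -1)), "below")
})

test_that("chi-square enrichment matches the closed-form 2x2 example", {
  # 80/20 late split among demethylated vs 50/50 among the rest; the empty
  # early category is dropped with a warning, leaving the hand 2x2
  rt <- data.frame(
    probe_id = sprintf("cg%03d", 1:200),
    rt_value = 0,
    rt_category = c(rep("late", 80), rep("intermediate", 20),
                    rep("late", 50), rep("intermediate", 50)),
    stringsAsFactors = FALSE)
  demeth <- rt$probe_id[1:100]
  expect_warning(res <- rt_enrichment_test(demeth, rt, mode = "complement"),
                 "early")
  hand <- oracle_chisq(matrix(c(80, 20, 50, 50), nrow = 2))
  expect_equal(res$chi_square_stat, hand$stat, tolerance = 1e-10)
  expect_equal(res$df, 1)
  expect_equal(res$p, hand$p, tolerance = 1e-10)
  expect_identical(res$odds_ratio_late, (80 * 50) / (20 * 50))

  # complement columns partition the annotated probes
  expect_identical(sum(res$table), 200L)
})

test_that("identical category proportions give a null chi-square", {
  rt <- data.frame(
    probe_id = sprintf("cg%03d", 1:120),
    rt_value = 0,
    rt_category = rep(c("late", "intermediate", "early"), 40),
    stringsAsFactors = FALSE)
  res <- rt_enrichment_test(rt$probe_id[1:30], rt, mode = "all")
  expect_equal(res$chi_square_stat, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
})

test_that("enrichment is invariant to probe input order", {
  withr::with_seed(19, {
    rt <- data.frame(
      probe_id = sprintf("cg%03d", 1:150),
      rt_value = 0,
      rt_category = sample(c("late", "intermediate", "early"), 150, TRUE),
      stringsAsFactors = FALSE)
    demeth <- sample(rt$probe_id, 40)
    a <- rt_enrichment_test(demeth, rt, mode = "complement")
    b <- rt_enrichment_test(sample(demeth), rt[sample(150), ],
                            mode = "complement")
    expect_equal(a$chi_square_stat, b$chi_square_stat, tolerance = 1e-12)
    expect_equal(a$odds_ratio_late, b$odds_ratio_late)
  })
})

test_that("synthetic two-level track thresholds equal the level values", {
  co <- default_cohort()
  rt <- annotate_probes_rt(co$annotation, co$track)
  th <- compute_rt_thresholds(rt$rt_value)
  expect_identical(unname(th), c(-1, 1))
})
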