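test_that("welch_test matches hand cases and the closed-form oracle", {
  same <- welch_test(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(same$delta, 0)
  expect_equal(same$t_stat, 0)
  expect_equal(same$p, 1)

  ref <- c(0.80, 0.82, 0.78, 0.81)
  cmp <- c(0.40, 0.45, 0.38, 0.43)
  got <- welch_test(ref, cmp)
  expect_equal(got$delta, -0.3875, tolerance = 1e-12)
  exp <- oracle_welch(ref, cmp)
  expect_equal(got$t_stat, exp$t_stat, tolerance = 1e-10)
  expect_equal(got$df, exp$df, tolerance = 1e-10)
  expect_equal(got$p, exp$p, tolerance = 1e-10)

  # swapping groups negates delta and t, preserves p
  rev <- welch_test(cmp, ref)
  expect_equal(rev$delta, -got$delta)
  expect_equal(rev$t_stat, -got$t_stat)
  expect_equal(rev$p, got$p)
})

test_that("welch_test agrees with stats::t.test over random cases", {
  withr::with_seed(7, {
    for (i in 1:30) {
      n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
      ref <- rnorm(n1); cmp <- rnorm(n2, mean = runif(1, -1, 1))
      if (i %% 3 == 0) ref[sample(n1, 1)] <- NA
      got <- welch_test(ref, cmp)
      tt <- t.test(cmp, ref, var.equal = FALSE)
      expect_equal(got$t_stat, unname(tt$statistic), tolerance = 1e-10)
      expect_equal(got$df, unname(tt$parameter), tolerance = 1e-10)
      expect_equal(got$p, tt$p.value, tolerance = 1e-10)
    }
  })
})

test_that("insufficient or constant data is untestable, never dropped", {
  one <- welch_test(c(0.5), c(0.1, 0.2, 0.3))
  expect_true(is.na(one$p))
  expect_equal(one$delta, 0.2 - 0.5)

  flat <- welch_test(c(0.4, 0.4, 0.4), c(0.4, 0.4))
  expect_true(is.na(flat$p))

  toy <- toy_two_group(matrix(0.4, 2, 3), matrix(0.4, 2, 2))
  res <- diff_methylation(toy$beta, toy$sheet, "C1", "C3")
  expect_identical(nrow(res), 2L)
  expect_true(all(is.na(res$p)) && all(is.na(res$q)))
  expect_identical(classify_probes(res)$label, c("ns", "ns"))
})

test_that("bh_adjust reproduces the step-up procedure", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::with_seed(11, {
    p <- runif(200)^2
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in sorted order
    expect_true(all(q >= p))

    p[c(3, 50)] <- NA
    q2 <- bh_adjust(p)
    expect_true(all(is.na(q2[c(3, 50)])))
    expect_equal(q2[!is.na(p)], oracle_bh(p[!is.na(p)]), tolerance = 1e-12)
  })
})

test_that("probe classification follows the published thresholds", {
  res <- data.frame(probe_id = c("a", "b", "c", "d"),
                    delta = c(-0.25, -0.25, -0.9, 0.3),
                    q = c(0.01, 0.01, 0.2, 0.01))
  expect_identical(classify_probes(res, delta_min = 0.2)$label,
                   c("hypo", "hypo", "ns", "hyper"))
  # stricter volcano profile: |delta| > 0.4, hypo side only
  expect_identical(
    classify_probes(res, delta_min = 0.4, delta_min_hyper = Inf)$label,
    c("ns", "ns", "ns", "ns"))
  # partition property: each testable probe gets exactly one label
  expect_true(all(classify_probes(res)$label %in% c("hypo", "hyper", "ns")))
})

test_that("CpG-context breakdown equals a brute-force tally", {
  labeled <- data.frame(
    probe_id = paste0("cg", 1:6),
    label = c("hypo", "hypo", "hyper", "ns", "ns", "hypo"))
  ann <- data.frame(
    probe_id = paste0("cg", 1:6),
    cpg_context = c("OpenSea", "OpenSea", "Island", "Shore", "Shelf",
                    "Island"),
    stringsAsFactors = FALSE)
  bd <- cpg_context_breakdown(labeled, ann)
  for (lab in c("hypo", "hyper", "ns")) {
    for (ctx in c("Island", "Shore", "Shelf", "OpenSea")) {
      expect_identical(
        unname(bd$counts[lab, ctx]),
        as.integer(sum(labeled$label == lab & ann$cpg_context == ctx)))
    }
  }
  expect_equal(unname(bd$proportions["hypo", "OpenSea"]), 2 / 3)

  all_ns <- transform(labeled, label = "ns")
  expect_true(all(cpg_context_breakdown(all_ns, ann)$counts["hypo", ] == 0))
  expect_error(cpg_context_breakdown(
    data.frame(probe_id = "cgX", label = "ns"), ann), "cgX")
})

test_that("hypomethylation concentrates in open sea on the default cohort", {
  co <- default_cohort()
  res <- classify_probes(diff_methylation(co$beta, co$sheet, "C1", "C3"))
  bd <- cpg_context_breakdown(res, co$annotation)
  hypo_prop <- bd$proportions["hypo", ]
  expect_identical(names(which.max(hypo_prop)), "OpenSea")
  # and the planted set is recovered nearly completely at these thresholds
  recovered <- res$probe_id[res$label == "hypo"]
  expect_gte(mean(co$truth$demeth_probes %in% recovered), 0.90)
})
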