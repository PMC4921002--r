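test_that("MAF estimation counts alleles over called samples", {
  calls <- c(rep("AA", 49), rep("AB", 42), rep("BB", 9))
  expect_equal(estimate_maf(calls), 0.30)
  expect_equal(estimate_maf(rep("AA", 10)), 0)
  expect_equal(estimate_maf(c(rep("AA", 50), rep("BB", 50))), 0.5)
  # NC excluded; all-NC is undefined
  expect_equal(estimate_maf(c("AA", "AA", "NC", "NC")), 0)
  expect_true(is.na(estimate_maf(rep("NC", 5))))
  # minor allele flips so the estimate never exceeds 0.5
  expect_equal(estimate_maf(c(rep("BB", 49), rep("AB", 42), rep("AA", 9))), 0.30)
})

test_that("partition rule reproduces the boundary truth table", {
  cases <- list(
    # maf, n_ks, expected
    list(0.06, c(100, 50, 10), "g1"),
    list(0.05, c(1, 1, 198), "g1"),    # boundary: maf threshold inclusive
    list(0.049999, c(3, 50, 100), "g2"),
    list(0.04, c(3, 50, 100), "g2"),   # boundary: n_ks = b1 qualifies
    list(0.04, c(10, 50, 100), "g3"),  # boundary: n_ks = b2 does not
    list(0.04, c(9, 50, 100), "g2"),
    list(0.04, c(2, 50, 100), "g3"),
    list(0.01, c(1, 10, 189), "g3"),
    list(0.04, c(0, 50, 100), "g3"),   # zero-count clusters never qualify
    list(NA_real_, c(0, 0, 0), "g3")   # undefined MAF routes to g3
  )
  for (cs in cases)
    expect_equal(partition_snps(cs[[1]], matrix(cs[[2]], 1, 3)), cs[[3]],
                 info = paste("maf", cs[[1]], paste(cs[[2]], collapse = ",")))
})

test_that("partition is exhaustive, disjoint and monotone in its knobs", {
  set.seed(55)
  maf <- runif(500, 0, 0.5)
  maf[sample(500, 20)] <- NA
  nks <- matrix(rpois(1500, 8), 500, 3)
  g <- partition_snps(maf, nks)
  expect_true(all(g %in% c("g1", "g2", "g3")))

  # raising b2 never shrinks g2
  g_wide <- partition_snps(maf, nks, b2 = 20)
  expect_true(all(g_wide[g == "g2"] != "g1"))
  expect_gte(sum(g_wide == "g2"), sum(g == "g2"))

  # raising b1 never grows g2
  g_hi <- partition_snps(maf, nks, b1 = 8)
  expect_lte(sum(g_hi == "g2"), sum(g == "g2"))

  # raising the MAF threshold never shrinks g2 u g3
  g_thr <- partition_snps(maf, nks, maf_threshold = 0.10)
  expect_gte(sum(g_thr != "g1"), sum(g != "g1"))
})

test_that("call rate, concordance and accuracy match counting oracles", {
  set.seed(66)
  g_pool <- c("AA", "AB", "BB", "NC")
  calls_a <- data.frame(
    snp = rep(sprintf("rs%d", 1:8), each = 25),
    sample = rep(sprintf("s%d", 1:25), 8),
    genotype = sample(g_pool, 200, replace = TRUE, prob = c(.4, .3, .2, .1)),
    pr = runif(200), model = "GMM")
  calls_b <- calls_a
  calls_b$genotype <- sample(g_pool, 200, replace = TRUE,
                             prob = c(.4, .3, .2, .1))

  expect_equal(call_rate(calls_a), oracle_call_rate(calls_a$genotype))
  expect_equal(call_rate(data.frame(snp = "x", sample = letters[1:10],
                                    genotype = c(rep("AA", 9), "NC"),
                                    pr = 1)), 90)
  expect_equal(call_rate(data.frame(snp = "x", sample = letters[1:4],
                                    genotype = rep("NC", 4), pr = NA)), 0)

  expect_equal(concordance(calls_a, calls_b),
               oracle_concordance(calls_a$genotype, calls_b$genotype))
  expect_equal(concordance(calls_a, calls_a), 100)
  # symmetry
  expect_equal(concordance(calls_a, calls_b), concordance(calls_b, calls_a))
  # one mismatch among 4 joint calls -> 75
  a4 <- data.frame(snp = "x", sample = letters[1:5],
                   genotype = c("AA", "AA", "AB", "BB", "NC"), pr = 1)
  b4 <- data.frame(snp = "x", sample = letters[1:5],
                   genotype = c("AA", "AB", "AB", "BB", "AA"), pr = 1)
  expect_equal(concordance(a4, b4), 75)
  all_nc <- a4; all_nc$genotype <- "NC"
  expect_warning(cc <- concordance(all_nc, b4), "no jointly called")
  expect_true(is.na(cc))

  truth <- data.frame(snp = calls_a$snp, sample = calls_a$sample,
                      genotype = sample(c("AA", "AB", "BB"), 200, TRUE))
  ok <- calls_a$genotype != "NC"
  expect_equal(accuracy(calls_a, truth),
               100 * mean(calls_a$genotype[ok] == truth$genotype[ok]))
  expect_equal(accuracy(calls_a, data.frame(snp = calls_a$snp,
                                            sample = calls_a$sample,
                                            genotype = calls_a$genotype)), 100)
  # 1 of 5 wrong -> 80
  t5 <- data.frame(snp = "x", sample = letters[1:5],
                   genotype = c("AA", "AA", "AB", "BB", "BB"))
  c5 <- data.frame(snp = "x", sample = letters[1:5],
                   genotype = c("AA", "AA", "AB", "BB", "AB"), pr = 1)
  expect_equal(accuracy(c5, t5), 80)
})

test_that("HWE chi-square test behaves at the canonical fixtures", {
  # exact HWE counts: statistic 0, p = 1, pass
  g <- c(rep("AA", 81), rep("AB", 18), rep("BB", 1))
  res <- hwe_test(g, alpha = 1e-4)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p.value, 1)
  expect_false(res$fail)

  # gross violation: no heterozygotes at 50/50 alleles; statistic 100
  g2 <- c(rep("AA", 50), rep("BB", 50))
  res2 <- hwe_test(g2, alpha = 1e-4)
  expect_equal(res2$statistic, 100, tolerance = 1e-9)
  expect_true(res2$fail)

  # monomorphic passes by definition
  res3 <- hwe_test(rep("AA", 40))
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p.value, 1)

  # small populations are skipped with a warning
  expect_warning(res4 <- hwe_test(c("AA", "AB", "BB"),
                                  populations = rep("tiny", 3)),
                 "fewer than")
  expect_equal(nrow(res4), 0L)

  # per-population stratification
  g5 <- c(rep("AA", 40), rep("AB", 20), rep("BB", 40))
  pops <- rep(c("P1", "P2"), 50)
  res5 <- hwe_test(g5, pops, alpha = 1e-4)
  expect_equal(nrow(res5), 2L)

  # exact test agrees qualitatively with chi-square on the fixtures
  ex1 <- hwe_test(g, method = "exact")
  expect_gt(ex1$p.value, 0.5)
  ex2 <- hwe_test(g2, method = "exact", alpha = 1e-4)
  expect_true(ex2$fail)
})

test_that("run_md routes, annotates and reproduces deterministically", {
  specs <- study_panel_specs(n_common = 8, n_g2 = 2, n_g3 = 2, n = 120,
                             seed = 3)
  panel <- simulate_panel(specs, populations = 2, seed = 3)
  cfg <- md_config(seed = 3, dp_n_iter = 600, dp_burn_in = 200)
  fit <- run_md(panel$dataset, cfg)

  s <- fit$snp_summary
  expect_equal(nrow(s), 12L)
  expect_true(all(s$group %in% c("g1", "g2", "g3")))
  expect_true(all(s$model %in% c("GMM", "DP-GMM", "DP-Ref")))
  # routing-to-model consistency
  expect_true(all(s$model[s$group == "g1"] == "GMM"))
  expect_true(all(s$model[s$group == "g2"] == "DP-GMM"))
  expect_true(all(s$model[s$group == "g3"] %in% c("DP-Ref", "DP-GMM")))
  # per-SNP bookkeeping: cluster sizes plus NC cover every observed cell
  expect_equal(s$n_AA + s$n_AB + s$n_BB + s$n_NC,
               unname(n_obs(panel$dataset)))

  fit2 <- run_md(panel$dataset, cfg)
  expect_identical(fit$calls, fit2$calls)
  expect_identical(fit$snp_summary, fit2$snp_summary)

  # raising b1 moves rare SNPs from g2 toward g3, never the reverse
  fit_b1 <- run_md(panel$dataset,
                   md_config(seed = 3, b1 = 8, dp_n_iter = 600,
                             dp_burn_in = 200))
  expect_lte(sum(fit_b1$snp_summary$group == "g2"), sum(s$group == "g2"))
  expect_gte(sum(fit_b1$snp_summary$group == "g3"), sum(s$group == "g3"))
})

test_that("an HWE-conformant panel rarely fails the HWE screen", {
  # all SNPs genotype-sampled from HWE frequencies (no pinned rare
  # regimes, which violate HWE by construction)
  set.seed(31)
  specs <- lapply(1:30, function(j)
    snp_sim_spec(maf = runif(1, 0.1, 0.4), n = 200, outlier_frac = 0))
  names(specs) <- sprintf("H%02d", 1:30)
  panel <- simulate_panel(specs, populations = 2, seed = 31)
  fit <- run_md(panel$dataset, md_config(seed = 31))
  hw <- hwe_failures(fit, alpha = 1e-4)
  # 60 population-level tests at alpha = 1e-4: binomial 99% bound
  expect_lte(sum(hw$n_fail), qbinom(0.99, 60, 1e-4) + 1)
})

test_that("degenerate and missing cells surface as NC, never abort", {
  df <- data.frame(
    snp = rep(c("ok", "weird"), each = 6),
    sample = rep(sprintf("s%d", 1:6), 2),
    r = c(1800, 1810, 1000, 990, 200, 210, 0, 5, 5, 4, 6, 5),
    g = c(200, 190, 1000, 1010, 1800, 1790, 0, 5, 5, 6, 4, 5))
  df <- df[-12, ]  # (weird, s6) missing
  ds <- intensity_dataset(df)
  fit <- suppressWarnings(run_md(ds, md_config(seed = 1, dp_n_iter = 200,
                                               dp_burn_in = 50)))
  calls <- fit$calls
  # the (0,0) degenerate cell is NC
  expect_equal(calls$genotype[calls$snp == "weird" & calls$sample == "s1"],
               "NC")
  # missing cell is absent from calls but summary still covers 5 cells
  expect_equal(nrow(calls[calls$snp == "weird", ]), 5L)
  expect_equal(sum(fit$snp_summary[2, c("n_AA", "n_AB", "n_BB", "n_NC")]), 5)
})

test_that("md_fit methods print and summarize without error", {
  specs <- study_panel_specs(n_common = 4, n_g2 = 1, n_g3 = 1, n = 80,
                             seed = 9)
  panel <- simulate_panel(specs, seed = 9)
  fit <- run_md(panel$dataset, md_config(seed = 9, dp_n_iter = 400,
                                         dp_burn_in = 100))
  expect_output(print(fit), "M-D genotype calls")
  expect_output(print(summary(fit)), "call rate")
  expect_s3_class(summary(fit), "summary.md_fit")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calls(fit, path)
  expect_equal(nrow(read_calls(path)), nrow(fit$calls))
  write_snp_summary(fit, path)
  expect_equal(nrow(read_snp_summary(path)), 6L)
})
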