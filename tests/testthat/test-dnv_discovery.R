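trio_samples <- c("P1", "D1", "M1")

test_that("Mendelian candidate detection requires het child, homref parents", {
  co <- mini_cohort(trio_samples, list(
    list(pos = 100, gt = c(P1 = 1), ad_ref = c(P1 = 10), ad_alt = c(P1 = 10)),
    list(pos = 200, gt = c(P1 = 2), ad_ref = c(P1 = 0), ad_alt = c(P1 = 40)),
    list(pos = 300, gt = c(P1 = 1, D1 = 1), ad_alt = c(P1 = 10, D1 = 10)),
    list(pos = 400, gt = c(P1 = 1), ad_alt = c(P1 = 10))))
  co$calls$gt[4, "M1"] <- NA  # missing parent -> skipped
  cand <- detect_mendelian_candidates(co, mini_trio_df())
  expect_equal(cand$pos, 100)
  expect_equal(attr(cand, "n_skipped_missing"), 1)
})

test_that("read-support boundaries follow keep-at-30%, remove-above-5%", {
  co <- mini_cohort(trio_samples, list(
    list(pos = 100, gt = c(P1 = 1), ad_ref = c(P1 = 14), ad_alt = c(P1 = 6)),
    list(pos = 200, gt = c(P1 = 1), ad_ref = c(P1 = 15), ad_alt = c(P1 = 5)),
    list(pos = 300, gt = c(P1 = 1), ad_ref = c(P1 = 10, D1 = 18),
         ad_alt = c(P1 = 10, D1 = 2)),
    list(pos = 400, gt = c(P1 = 1), ad_ref = c(P1 = 10, M1 = 19),
         ad_alt = c(P1 = 10, M1 = 1))))
  tdf <- mini_trio_df()
  cand <- apply_dnv_filters(detect_mendelian_candidates(co, tdf), co, tdf)
  # 6/20 = 0.30 kept (boundary); 5/20 = 0.25 removed
  expect_equal(cand$filter_proband_support[cand$pos == 100], "pass")
  expect_equal(cand$filter_proband_support[cand$pos == 200], "fail")
  # father 2/20 = 0.10 > 5% removed; mother 1/20 = 0.05 kept (boundary)
  expect_equal(cand$filter_parent_support[cand$pos == 300], "fail")
  expect_equal(cand$filter_parent_support[cand$pos == 400], "pass")
  expect_equal(cand$status[cand$pos == 400], "pass")
})

test_that("filters without inputs record not-evaluable and cannot fail", {
  co <- mini_cohort(trio_samples, list(
    list(pos = 100, gt = c(P1 = 1), ad_ref = c(P1 = 10), ad_alt = c(P1 = 10))))
  co$calls$ad_ref[1, "D1"] <- NA
  co$calls$ad_alt[1, "D1"] <- NA
  co$calls$min_bq[1, ] <- NA
  co$calls$ad_alt_fwd[1, ] <- NA
  tdf <- mini_trio_df()
  cand <- apply_dnv_filters(detect_mendelian_candidates(co, tdf), co, tdf)
  expect_equal(cand$filter_parent_support, "not-evaluable")
  expect_equal(cand$filter_base_quality, "not-evaluable")
  expect_equal(cand$filter_strand_bias, "not-evaluable")
  expect_equal(cand$status, "pass")
})

test_that("class, MAF and base-quality filters behave at their boundaries", {
  co <- mini_cohort(trio_samples, list(
    list(pos = 100, gt = c(P1 = 1), ad_alt = c(P1 = 25), ad_ref = c(P1 = 25),
         class = "other"),
    list(pos = 200, gt = c(P1 = 1), ad_alt = c(P1 = 25), ad_ref = c(P1 = 25),
         af = 0.01, af_absent = FALSE),
    list(pos = 300, gt = c(P1 = 1), ad_alt = c(P1 = 25), ad_ref = c(P1 = 25),
         af = 0.009, af_absent = FALSE),
    list(pos = 400, gt = c(P1 = 1), ad_alt = c(P1 = 25), ad_ref = c(P1 = 25),
         min_bq = c(P1 = 15))))
  tdf <- mini_trio_df()
  cand <- apply_dnv_filters(detect_mendelian_candidates(co, tdf), co, tdf)
  expect_equal(cand$filter_class[cand$pos == 100], "fail")
  expect_equal(cand$filter_maf[cand$pos == 200], "fail")   # strict < 1%
  expect_equal(cand$filter_maf[cand$pos == 300], "pass")
  expect_equal(cand$filter_base_quality[cand$pos == 400], "fail")
})

test_that("strand bias fails only on strongly skewed read tables", {
  co <- mini_cohort(trio_samples, list(
    list(pos = 100, gt = c(P1 = 1), ad_ref = c(P1 = 200), ad_alt = c(P1 = 60)),
    list(pos = 200, gt = c(P1 = 1), ad_ref = c(P1 = 200), ad_alt = c(P1 = 60))))
  # site 1: alt reads all on one strand; site 2: balanced
  co$calls$ad_alt_fwd[1, "P1"] <- 60; co$calls$ad_alt_rev[1, "P1"] <- 0
  tdf <- mini_trio_df()
  cand <- apply_dnv_filters(detect_mendelian_candidates(co, tdf), co, tdf)
  expect_equal(cand$filter_strand_bias[cand$pos == 100], "fail")
  expect_equal(cand$filter_strand_bias[cand$pos == 200], "pass")
})

test_that("singleton filter counts proband genotypes cohort-wide", {
  samples <- c("P1", "D1", "M1", "P2", "D2", "M2")
  tdf <- rbind(mini_trio_df(),
               mini_trio_df(proband = "P2", father = "D2", mother = "M2"))
  co <- mini_cohort(samples, list(
    list(pos = 100, gt = c(P1 = 1, P2 = 1),
         ad_ref = c(P1 = 20, P2 = 20), ad_alt = c(P1 = 20, P2 = 20)),
    list(pos = 200, gt = c(P1 = 1),
         ad_ref = c(P1 = 20), ad_alt = c(P1 = 20))))
  cand <- apply_dnv_filters(detect_mendelian_candidates(co, tdf), co, tdf)
  expect_equal(cand$filter_singleton[cand$pos == 100], c("fail", "fail"))
  expect_equal(cand$filter_singleton[cand$pos == 200], "pass")
  # consequence: no two passing candidates share chrom:pos:alt
  pass <- cand[cand$status == "pass", ]
  expect_false(any(duplicated(paste(pass$chrom, pass$pos, pass$alt))))
})

test_that("the pass set is invariant to candidate order and equals the
           conjunction of independent predicates", {
  sim <- simulate_cohort(sim_config(n_trios = 8, n_inherited_sites = 150,
                                    missed_het_rate = 0.01, seed = 19))
  tdf <- trios(sim$ped)
  cand <- detect_mendelian_candidates(sim$cohort, tdf)
  filt <- apply_dnv_filters(cand, sim$cohort, tdf)
  set.seed(20)
  perm <- sample(nrow(cand))
  filt_p <- apply_dnv_filters(cand[perm, ], sim$cohort, tdf)
  expect_equal(filt_p$status, filt$status[perm])
  fail_any <- apply(
    filt[paste0("filter_", c("class", "singleton", "maf", "proband_support",
                             "parent_support", "base_quality",
                             "strand_bias"))] == "fail", 1, any)
  expect_equal(filt$status == "fail", unname(fail_any))
})

test_that("per-proband cap flags only probands over the limit", {
  cand <- data.frame(proband = c(rep("A", 6), rep("B", 3)),
                     status = "pass", stringsAsFactors = FALSE)
  flags <- per_proband_cap(cand)
  expect_true(flags$flagged[flags$proband == "A"])
  expect_false(flags$flagged[flags$proband == "B"])

  t1 <- load_table1()
  t1$status <- "pass"
  flags1 <- per_proband_cap(t1)
  expect_equal(max(flags1$n_pass), 3)
  expect_false(any(flags1$flagged))

  empty <- per_proband_cap(data.frame(proband = character(),
                                      status = character()))
  expect_equal(nrow(empty), 0)
})

test_that("deleteriousness tiers use a strict CADD > 20 boundary", {
  expect_equal(classify_deleteriousness(c(29.8, 20.0, 19.9, NA)),
               c("top1pct", "below", "below", "unscored"))
  t1 <- load_table1()
  expect_equal(sum(classify_deleteriousness(t1$cadd_phred) == "top1pct"), 13)
})

test_that("candidate summary reproduces the published per-proband histogram", {
  t1 <- load_table1()
  summ <- summarize_candidates(t1, table1_probands())
  expect_equal(as.integer(summ$count_histogram), c(15, 10, 9, 2))
  expect_equal(unname(summ$class_counts),
               c(17L, 0L, 3L, 14L))  # missense, nonsense, splice, synonymous
  empty <- summarize_candidates(t1[0, ], sprintf("S%02d", 1:36))
  expect_equal(as.integer(empty$count_histogram), 36)
})

test_that("synthetic cohort: candidates cover all spiked truth DNVs", {
  sim <- simulate_cohort(sim_config(n_trios = 12, n_inherited_sites = 150,
                                    seed = 23))
  qc <- filter_variants(sim$cohort)
  tdf <- trios(sim$ped)
  cand <- detect_mendelian_candidates(qc$cohort, tdf)
  ck <- paste(cand$proband, cand$chrom, cand$pos, cand$alt)
  key_sites <- paste(qc$cohort$sites$chrom, qc$cohort$sites$pos)
  # every spiked DNV whose three trio calls are non-missing after QC
  # appears as a candidate
  for (i in seq_len(nrow(sim$truth$dnvs))) {
    d <- sim$truth$dnvs[i, ]
    s <- match(paste(d$chrom, d$pos), key_sites)
    if (is.na(s)) next
    tr <- tdf[tdf$proband == d$proband, ]
    calls <- qc$cohort$calls$gt[s, c(tr$proband, tr$father, tr$mother)]
    if (any(is.na(calls))) next
    expect_true(paste(d$proband, d$chrom, d$pos, d$alt) %in% ck)
  }
})
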