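# Literature-table preprocessing and the four-stage novelty flow.

test_that("reference preprocessing drops sex chromosomes, short records and excluded studies", {
  db <- rbind(mk_refs("X", 100, 5000, "loss"),
              mk_refs("1", 100, 108, "loss"),          # 9 bp
              mk_refs("1", 100, 109, "loss"),          # 10 bp, boundary kept
              mk_refs("2", 100, 5000, "gain", study = "hgdp"),
              mk_refs("3", 100, 5000, "gain"))
  out <- preprocess_ref_table(db)
  expect_equal(nrow(out), 2)
  expect_equal(out$chrom, c("1", "3"))
  expect_equal(size_bp(out$start[1], out$end[1]), 10)
})

test_that("gain/loss observation counts drop empty records and re-derive the type", {
  db <- rbind(mk_refs("1", 100, 5000, "both", gain_count = 0, loss_count = 0),
              mk_refs("1", 100, 5000, "loss", gain_count = 3, loss_count = 0),
              mk_refs("1", 100, 5000, "gain", gain_count = 0, loss_count = 2),
              mk_refs("1", 100, 5000, "loss", gain_count = 1, loss_count = 4),
              mk_refs("2", 100, 5000, "both"))   # no counts: kept as declared
  out <- preprocess_ref_table(db)
  expect_equal(nrow(out), 4)
  expect_equal(out$type, c("gain", "loss", "both", "both"))
  # oracle: brute-force rule over a random constructed table
  set.seed(71)
  rnd <- mk_refs("1", s <- sample.int(1e6, 60), s + sample.int(1e5, 60),
                 sample(c("loss", "gain", "both"), 60, TRUE),
                 gain_count = sample(c(NA, 0:3), 60, TRUE),
                 loss_count = sample(c(NA, 0:3), 60, TRUE))
  out2 <- preprocess_ref_table(rnd)
  g <- ifelse(is.na(rnd$gain_count), 0, rnd$gain_count)
  l <- ifelse(is.na(rnd$loss_count), 0, rnd$loss_count)
  has <- !is.na(rnd$gain_count) | !is.na(rnd$loss_count)
  expect_equal(nrow(out2), sum(!(has & g == 0 & l == 0)))
})

test_that("merged databases apply the region type rule and match brute force", {
  db <- rbind(mk_refs("1", c(100, 100), c(500, 500), "loss"),
              mk_refs("2", c(100, 300), c(400, 600), c("gain", "both")))
  out <- build_merged_db(db, overlap_criterion("any"))
  expect_equal(nrow(out), 2)
  expect_equal(out$n_members[out$chrom == "1"], 2L)
  expect_equal(out$type[out$chrom == "2"], "both")
  expect_equal(unique(out$cohort), "normal")
  set.seed(72)
  big <- fuzz_records(1000, types = c("loss", "gain", "both"))
  big$cohort <- "normal"; big$study <- "litA"
  expect_equal(nrow(build_merged_db(big, overlap_criterion("any"))),
               nrow(oracle_schedule_merge(big, overlap_criterion("any"))))
})

test_that("screening eliminates on type-comparable qualifying overlap only", {
  db <- rbind(mk_refs("1", 100, 500, "both"),
              mk_refs("2", 100, 500, "gain"))
  regions <- build_merged_db(db, overlap_criterion("any"))
  calls <- rbind(mk_calls("1", 200, 300, "gain"),    # vs both: eliminated
                 mk_calls("2", 200, 300, "loss"),    # vs gain only: kept
                 mk_calls("3", 200, 300, "loss"))    # nothing on chr3: kept
  res <- screen_vs_db(calls, regions, overlap_criterion("any"))
  expect_equal(nrow(res$kept), 2)
  expect_equal(nrow(res$eliminated), 1)
  expect_equal(res$eliminated$blame, "1:100-500")
  # screens match a brute-force all-pairs check on random input
  set.seed(73)
  rnd_calls <- mk_calls("1", s <- sample.int(5000, 80),
                        s + sample.int(400, 80),
                        sample(c("loss", "gain"), 80, TRUE))
  rnd_db <- build_merged_db(
    mk_refs("1", s2 <- sample.int(5000, 40), s2 + sample.int(400, 40),
            sample(c("loss", "gain", "both"), 40, TRUE)),
    overlap_criterion("pct_either", 0.4))
  res2 <- screen_vs_db(rnd_calls, rnd_db, overlap_criterion("pct_either", 0.4))
  brute_elim <- vapply(seq_len(nrow(rnd_calls)), function(i) {
    any(vapply(seq_len(nrow(rnd_db)), function(j) {
      meets_criterion(rnd_calls[i, ], rnd_db[j, ],
                      overlap_criterion("pct_either", 0.4))
    }, logical(1)))
  }, logical(1))
  expect_equal(nrow(res2$eliminated), sum(brute_elim))
  expect_equal(res2$kept$start, rnd_calls$start[!brute_elim])
})

test_that("case-only exclusion removes case calls matching control calls of the same type", {
  case <- rbind(mk_calls("1", 100, 200, "gain", cohort = "case"),
                mk_calls("2", 100, 200, "gain", cohort = "case"))
  ctrl <- rbind(mk_calls("1", 150, 250, "gain", subject_id = "c1",
                         cohort = "control"),
                mk_calls("2", 150, 250, "loss", subject_id = "c1",
                         cohort = "control"))
  res <- case_only(case, ctrl, overlap_criterion("any"))
  expect_equal(nrow(res$kept), 1)
  expect_equal(res$kept$chrom, "2")  # loss control does not match gain case
})

test_that("a planted design moves through the four stages with hand-computed fates", {
  crit <- overlap_criterion("any")
  # normals literature: loss region on chr1, gain region on chr2
  normals <- rbind(mk_refs("1", 1000, 2000, "loss"),
                   mk_refs("2", 1000, 2000, "gain"))
  # scz literature: a gain on chr4 (not in normals), a loss on chr1
  # (inside the normals loss region, so it drops out of the scz-lit db)
  scz <- rbind(mk_refs("4", 1000, 2000, "gain", cohort = "scz"),
               mk_refs("1", 1200, 1800, "loss", cohort = "scz"))
  calls <- rbind(
    mk_calls("1", 1500, 2500, "loss", subject_id = "k1", cohort = "case"),
    # dies stage 1 (normals loss region)
    mk_calls("2", 1500, 1800, "gain", subject_id = "k1", cohort = "case"),
    # dies stage 1 (normals gain region)
    mk_calls("3", 100, 900, "loss", subject_id = "k2", cohort = "case"),
    # dies stage 2 (control call below)
    mk_calls("3", 200, 800, "loss", subject_id = "c9", cohort = "control"),
    # control survivor, excluded from case-only counts
    mk_calls("4", 1500, 1900, "gain", subject_id = "k2", cohort = "case"),
    # dies stage 4 (scz-lit gain on chr4)
    mk_calls("1", 1100, 1900, "loss", subject_id = "k3", cohort = "case"),
    # dies stage 1; note the chr1 scz-lit loss cannot kill anyone because
    # it is itself removed from the scz-lit db by the normals screen
    mk_calls("5", 100, 600, "gain", subject_id = "k3", cohort = "case"))
    # survives everything
  rep <- run_novelty_flow(calls, normals, scz, crit)
  sc <- rep$stage_counts
  expect_equal(sc$total, c(7, 4, 2, 1))
  expect_equal(sc$loss, c(4, 2, 0, 0))
  expect_equal(sc$gain, c(3, 2, 2, 1))
  expect_equal(rep$survivors$chrom, "5")
  expect_equal(rep$fates$fate,
               c("in_normals_db", "in_normals_db", "in_study_controls",
                 "control_subject", "in_scz_lit", "in_normals_db",
                 "survived"))
  expect_equal(nrow(rep$scz_lit_regions), 1)
  expect_equal(rep$scz_lit_regions$chrom, "4")
})

test_that("stage counts are non-increasing and screens are monotone in the database", {
  set.seed(74)
  for (i in 1:20) {
    calls <- mk_calls("1", s <- sample.int(5000, 30), s + sample.int(300, 30),
                      sample(c("loss", "gain"), 30, TRUE),
                      subject_id = sample(c("a", "b", "c"), 30, TRUE),
                      cohort = sample(c("case", "control"), 30, TRUE))
    normals <- mk_refs("1", s2 <- sample.int(5000, 15),
                       s2 + sample.int(300, 15),
                       sample(c("loss", "gain", "both"), 15, TRUE))
    scz <- mk_refs("1", s3 <- sample.int(5000, 5), s3 + sample.int(300, 5),
                   sample(c("loss", "gain"), 5, TRUE), cohort = "scz")
    rep <- run_novelty_flow(calls, normals, scz, overlap_criterion("any"))
    expect_true(all(diff(rep$stage_counts$total) <= 0))
    # a larger normals DB never increases stage-1 survivors
    rep2 <- run_novelty_flow(calls, rbind(normals, mk_refs(
      "1", 1, 5300, "both")), scz, overlap_criterion("any"))
    expect_lte(rep2$stage_counts$total[2], rep$stage_counts$total[2])
    # every eliminated call carries exactly one blame
    elim <- rep$fates[!rep$fates$fate %in% c("survived", "control_subject"), ]
    expect_true(all(!is.na(elim$blame)))
  }
})

test_that("loosening any to pct_either never lowers stage-1 survivor counts", {
  set.seed(75)
  for (i in 1:20) {
    calls <- mk_calls("1", s <- sample.int(4000, 25), s + sample.int(400, 25),
                      sample(c("loss", "gain"), 25, TRUE), cohort = "case")
    normals <- mk_refs("1", s2 <- sample.int(4000, 12),
                       s2 + sample.int(400, 12),
                       sample(c("loss", "gain", "both"), 12, TRUE))
    scz <- mk_refs("1", 1, 10, "loss", cohort = "scz")
    n_any <- run_novelty_flow(calls, normals, scz,
                              overlap_criterion("any"))$stage_counts$total[2]
    n_pct <- run_novelty_flow(calls, normals, scz,
                              overlap_criterion("pct_either", 0.4)
                              )$stage_counts$total[2]
    expect_gte(n_pct, n_any)
  }
})

test_that("empty inputs give an all-zero report and a lone novel call passes through", {
  crit <- overlap_criterion("any")
  rep0 <- run_novelty_flow(empty <- as_cnv_calls(
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               type = character())),
    mk_refs("1", 100, 200, "loss"), mk_refs("2", 100, 200, "loss",
                                            cohort = "scz"), crit)
  expect_equal(rep0$stage_counts$total, rep(0, 4))
  one <- mk_calls("9", 100, 200, "gain", cohort = "case")
  rep1 <- run_novelty_flow(one, mk_refs("1", 100, 200, "loss"),
                           mk_refs("2", 100, 200, "loss", cohort = "scz"),
                           crit)
  expect_equal(rep1$stage_counts$total, c(1, 1, 1, 1))
  expect_equal(nrow(rep1$survivors), 1)
})
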