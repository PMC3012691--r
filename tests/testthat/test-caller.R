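# Segmentation, event-rule classification and post-call filters.

noise_free_array <- function(runs, n_markers = 400, seed = 101) {
  cfg <- small_array_cfg(n_markers = n_markers)
  map <- simulate_array(cfg, seed = seed)$map
  truth <- truth_at(map, runs)
  arr <- simulate_array(cfg, seed = seed, truth = truth)
  list(cfg = cfg, arr = arr, truth = truth)
}

test_that("a clean deletion run is segmented with exact probe boundaries", {
  fx <- noise_free_array(list(list(first = 50, last = 64,
                                   state = "homo_del")))
  track <- fx$arr$signals
  cand <- segment_candidates(track)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$first, 50)
  expect_equal(cand$last, 64)
  expect_equal(cand$n_probes, 15)
  expect_equal(cand$direction, "low")
  expect_equal(cand$start, fx$arr$map$pos[50])
  expect_equal(cand$end, fx$arr$map$pos[64])
})

test_that("a flat neutral track yields no candidates and no calls", {
  fx <- noise_free_array(list())
  expect_equal(nrow(segment_candidates(fx$arr$signals)), 0)
  expect_equal(nrow(call_cnvs(fx$arr$signals)), 0)
})

test_that("events separated by neutral probes segment into distinct runs", {
  fx <- noise_free_array(list(list(first = 20, last = 34, state = "homo_del"),
                              list(first = 45, last = 59, state = "gain"),
                              list(first = 80, last = 94, state = "hemi_del")))
  cand <- segment_candidates(fx$arr$signals)
  # brute-force: runs of probes whose state mean differs from 0
  st <- rep(0, 400)
  st[20:34] <- -2; st[45:59] <- 0.35; st[80:94] <- -0.5
  r <- rle(sign(st)); ends <- cumsum(r$lengths)
  exp_first <- (ends - r$lengths + 1)[r$values != 0]
  exp_last <- ends[r$values != 0]
  expect_equal(cand$first, exp_first)
  expect_equal(cand$last, exp_last)
})

test_that("classification applies the three event rules with their bounds", {
  fx <- noise_free_array(list(list(first = 20, last = 34, state = "homo_del"),
                              list(first = 60, last = 74, state = "hemi_del"),
                              list(first = 100, last = 114, state = "gain")))
  calls <- call_cnvs(fx$arr$signals)
  expect_equal(nrow(calls), 3)
  expect_equal(calls$type, c("loss", "loss", "gain"))
  expect_equal(calls$start, fx$arr$map$pos[c(20, 60, 100)])
  expect_equal(calls$end, fx$arr$map$pos[c(34, 74, 114)])
  expect_equal(calls$n_probes, rep(15L, 3))
})

test_that("rule thresholds gate marginal segments", {
  fx <- noise_free_array(list(list(first = 50, last = 64,
                                   state = "homo_del")))
  track <- fx$arr$signals
  run <- data.frame(chrom = "1", first = 50, last = 64,
                    start = track$pos[50], end = track$pos[64],
                    n_probes = 15L)
  # 12 probes, mean LRR -2.2: homozygous rule
  track2 <- track; track2$lrr[50:64] <- -2.2
  expect_equal(classify_segment(run, track2)$type, "loss")
  # 5 probes at -0.5: fails homozygous LRR bound and hemizygous 10-probe min
  run5 <- run; run5$last <- 54; run5$end <- track$pos[54]; run5$n_probes <- 5L
  track3 <- track; track3$lrr[50:54] <- -0.5
  expect_null(classify_segment(run5, track3))
  # mean LRR +0.40 with BAF deviation 0.12 at het SNPs: gain
  track4 <- track
  track4$lrr[50:64] <- 0.40
  track4$genotype[50:64] <- "AB"
  track4$baf[50:64] <- 0.5 + 0.12
  expect_equal(classify_segment(run, track4)$type, "gain")
  # same gain signal but BAF deviation below 0.05 fails (strict >)
  track5 <- track4; track5$baf[50:64] <- 0.53125  # dev 0.03125, float-exact
  expect_null(classify_segment(run, track5))
  # hemizygous rule rejects het proportion at exactly 10%
  track6 <- track
  track6$lrr[50:64] <- -0.5
  track6$genotype[50:64] <- c("AB", rep(c("AA", "BB", "AA"), 4), "AA", "BB")
  expect_equal(sum(track6$genotype[50:64] == "AB") / 15, 1 / 15)
  expect_equal(classify_segment(run, track6)$type, "loss")
  track6$genotype[50:51] <- "AB"  # not a het prop below 10% any more
  expect_null(classify_segment(run, track6))
})

test_that("a gain-like segment with no heterozygous SNPs fails closed", {
  fx <- noise_free_array(list())
  track <- fx$arr$signals
  run <- data.frame(chrom = "1", first = 50, last = 64,
                    start = track$pos[50], end = track$pos[64],
                    n_probes = 15L)
  track$lrr[50:64] <- 0.4
  track$genotype[50:64] <- "NP"
  track$baf[50:64] <- NA
  expect_null(classify_segment(run, track))
})

test_that("noise-free implants are recovered exactly with no spurious calls", {
  runs <- list(list(first = 10, last = 24, state = "homo_del"),
               list(first = 60, last = 74, state = "gain"),
               list(first = 120, last = 134, state = "hemi_del"),
               list(first = 200, last = 202, state = "homo_del"),
               list(first = 300, last = 314, state = "homo_del"))
  fx <- noise_free_array(runs, seed = 103)
  calls <- call_cnvs(fx$arr$signals)
  m <- match_truth(calls, fx$truth)
  expect_equal(m$recall, 1)
  expect_equal(m$fdr, 0)
  expect_equal(nrow(calls), length(runs))
  expect_equal(calls$start, fx$truth$start[order(fx$truth$start)])
  expect_equal(calls$end, fx$truth$end[order(fx$truth$end)])
})

test_that("15-probe homozygous deletions are recovered at LRR noise SD 0.2", {
  cfg <- small_array_cfg(n_markers = 2000, lrr_sd = 0.2, baf_sd = 0.03)
  map <- simulate_array(cfg, seed = 107)$map
  runs <- lapply(0:49, function(k)
    list(first = 10 + k * 39, last = 24 + k * 39, state = "homo_del"))
  truth <- truth_at(map, runs)
  arr <- simulate_array(cfg, seed = 107, truth = truth)
  m <- match_truth(call_cnvs(arr$signals), truth)
  expect_gte(m$recall, 0.95)
})

test_that("filters keep boundary values and match brute-force refiltering", {
  calls <- mk_calls("1", c(100, 100, 100), c(108, 109, 120),
                    type = c("loss", "loss", "gain"),
                    n_probes = c(3L, 5L, 10L),
                    confidence = c(29.99, 30, 45))
  expect_equal(filter_min_probes(calls, 5)$n_probes, c(5L, 10L))
  expect_equal(filter_min_probes(calls, 1), calls)
  expect_error(filter_min_probes(calls, 0))
  expect_equal(filter_min_size(calls, 10)$end, c(109, 120))  # 9 bp dropped
  expect_equal(nrow(filter_confidence(calls, 30)), 2)        # 29.99 dropped
  expect_error(filter_confidence(transform(calls, confidence = NA), 30))

  set.seed(51)
  rnd <- mk_calls("2", s <- sample.int(1e5, 100), s + sample.int(5e4, 100),
                  type = sample(c("loss", "gain"), 100, TRUE),
                  n_probes = sample.int(20, 100, TRUE),
                  confidence = runif(100, 0, 60))
  expect_equal(filter_min_probes(rnd, 10),
               rnd[rnd$n_probes >= 10, ], ignore_attr = TRUE)
  expect_equal(filter_min_size(rnd, 20000),
               rnd[(rnd$end - rnd$start + 1) >= 20000, ], ignore_attr = TRUE)
  expect_equal(filter_confidence(rnd, 30),
               rnd[rnd$confidence >= 30, ], ignore_attr = TRUE)
})

test_that("filters are idempotent and commute", {
  set.seed(52)
  rnd <- mk_calls("3", s <- sample.int(1e5, 80), s + sample.int(5e4, 80),
                  type = sample(c("loss", "gain"), 80, TRUE),
                  n_probes = sample.int(20, 80, TRUE),
                  confidence = runif(80, 0, 60))
  f1 <- function(x) filter_min_probes(x, 5)
  f2 <- function(x) filter_min_size(x, 1e4)
  f3 <- function(x) filter_confidence(x, 30)
  expect_equal(f1(f1(rnd)), f1(rnd))
  expect_equal(f2(f2(rnd)), f2(rnd))
  expect_equal(f1(f2(f3(rnd))), f3(f2(f1(rnd))), ignore_attr = TRUE)
})

test_that("centromere splitting divides spanning calls and conserves flanks", {
  cen <- data.frame(chrom = c("1", "2"), cen_start = c(1000, 5000),
                    cen_end = c(2000, 6000))
  calls <- mk_calls("1", c(500, 100, 1200, 2500), c(2500, 900, 1800, 3000),
                    type = "loss", subject_id = "s1")
  out <- suppressWarnings(split_at_centromere(calls, cen))
  # spanning call -> two pieces; left-of, inside, right-of handled
  expect_equal(nrow(out), 4)  # 2 pieces + unchanged left + unchanged right
  pieces <- out[out$start %in% c(500, 2001), ]
  expect_equal(pieces$end[pieces$start == 500], 999)
  expect_equal(pieces$start[pieces$end == 2500], 2001)
  # covered bases outside the centromere are conserved for the split call
  expect_equal(size_bp(500, 999) + size_bp(2001, 2500),
               size_bp(500, 2500) - size_bp(1000, 2000))
  expect_error(split_at_centromere(mk_calls("7", 1, 10, "loss"), cen),
               "centromere")
})

test_that("probe counts of split calls are recomputed from the track", {
  fx <- noise_free_array(list())
  map <- fx$arr$map
  cen <- data.frame(chrom = "1", cen_start = map$pos[100] + 1,
                    cen_end = map$pos[110] - 1)
  calls <- mk_calls("1", map$pos[90], map$pos[120], "loss",
                    subject_id = "case001")
  out <- split_at_centromere(calls, cen, track = fx$arr$signals)
  expect_equal(nrow(out), 2)
  expect_equal(out$n_probes, c(11L, 11L))  # probes 90..100 and 110..120
  expect_warning(split_at_centromere(calls, cen), "NA")
  # a single spanning call in a multi-call set: all others unchanged
  many <- rbind(calls, mk_calls("1", map$pos[1], map$pos[50], "gain",
                                subject_id = "case001"))
  out2 <- split_at_centromere(many, cen, track = fx$arr$signals)
  expect_equal(nrow(out2), 3)
})
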