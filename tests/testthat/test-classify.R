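# The four classification rules.

decane <- mol(strrep("C", 10), "decane")
hexane <- mol(strrep("C", 6), "hexane")
pentadecane <- mol(strrep("C", 15), "pentadecane")

test_that("SSF terminates at the first match with the best score", {
  idx <- build_index(list(hexane))
  p <- classify_ssf(decane, idx, threshold_set(0.5, 0.51))
  expect_equal(p$label, "biological")
  expect_equal(p$evidence$direction, "substructure")
  expect_equal(p$evidence$score, 0.6)
  expect_equal(p$n_comparisons, 1)
})

test_that("SSF on an identical scaffold matches with score 1", {
  idx <- build_index(list(mol("OCC", "scaf")))
  p <- classify_ssf(mol("CCO", "cand"), idx, threshold_set(0.9, 0.9))
  expect_equal(p$label, "biological")
  expect_equal(p$evidence$score, 1)
})

test_that("SSF with an empty window is nonbiological at zero comparisons", {
  idx <- build_index(list(mol("CCC", "tiny")))
  p <- classify_ssf(decane, idx, threshold_set(0.5, 0.51))
  expect_equal(p$label, "nonbiological")
  expect_equal(p$n_comparisons, 0)
})

test_that("SSSF sums the best scores per direction against sumThr", {
  idx <- build_index(list(hexane, pentadecane))
  p <- classify_sssf(decane, idx, threshold_set(0.5, 0.51, sum_thr = 1.2))
  expect_equal(p$evidence$sc_sub, 0.6)
  expect_equal(p$evidence$sc_super, 10 / 15)
  expect_equal(p$label, "biological")  # 1.267 >= 1.2
  # no matches: sum 0 below any positive cutoff
  idx0 <- build_index(list(mol("C#CC#CC#CC#C", "yne")))
  p0 <- classify_sssf(decane, idx0, threshold_set(0.5, 0.51, sum_thr = 0.1))
  expect_equal(p0$label, "nonbiological")
  expect_equal(p0$evidence$sum_score, 0)
  # identity contributes 1 in the substructure direction only
  idx1 <- build_index(list(mol(strrep("C", 10), "self")))
  p1 <- classify_sssf(decane, idx1, threshold_set(0.5, 0.51, sum_thr = 1.0))
  expect_equal(p1$evidence$sc_sub, 1)
  expect_equal(p1$evidence$sc_super, 0)
  expect_equal(p1$label, "biological")
})

test_that("binned rules resolve thresholds by atom-count bin", {
  idx <- build_index(list(hexane, pentadecane))
  bins <- default_bin_scheme(threshold_set(0.5, 0.51, sum_thr = 1.2))
  expect_equal(bins$bins$lo, c(4L, 14L, 24L, 34L, 44L))
  expect_equal(bins$bins$hi, c(13L, 23L, 33L, 43L, 53L))
  expect_equal(bin_of(bins, 9), 1)
  expect_equal(bin_of(bins, 14), 2)
  expect_true(is.na(bin_of(bins, 54)))
  # per-bin thresholds equal to global ones reduce to the global rules
  p_ssb <- classify_ssb(decane, idx, bins)
  p_ssf <- classify_ssf(decane, idx, threshold_set(0.5, 0.51))
  expect_equal(p_ssb$label, p_ssf$label)
  expect_equal(p_ssb$evidence$score, p_ssf$evidence$score)
  expect_equal(p_ssb$bin, 1)
  p_sssb <- classify_sssb(decane, idx, bins)
  p_sssf <- classify_sssf(decane, idx, threshold_set(0.5, 0.51, sum_thr = 1.2))
  expect_equal(p_sssb$label, p_sssf$label)
  expect_equal(p_sssb$evidence$sum_score, p_sssf$evidence$sum_score)
  # raising the bin's sumThr flips the decision
  bins13 <- default_bin_scheme(threshold_set(0.5, 0.51, sum_thr = 1.3))
  expect_equal(classify_sssb(decane, idx, bins13)$label, "nonbiological")
})

test_that("candidates outside the bin range are refused explicitly", {
  big <- mol(strrep("C", 54), "big")
  idx <- build_index(list(hexane))
  p <- classify_ssb(big, idx, default_bin_scheme(threshold_set(0.5, 0.5)))
  expect_equal(p$status, "out_of_range")
  expect_true(is.na(p$label))
})

test_that("early termination agrees with an exhaustive window scan", {
  set.seed(41)
  for (i in 1:25) {
    ds <- make_labeled_dataset(fixture_spec(
      seed = 1000 + i, n_scaffolds = 10, scaffold_count_range = c(4, 16),
      n_bio = 4, n_syn = 2))
    idx <- build_index(ds$scaffolds)
    thr <- threshold_set(stats::runif(1, 0.3, 1), stats::runif(1, 0.3, 1))
    for (cand in c(ds$bio, ds$syn)) {
      p <- classify_ssf(cand, idx, thr)
      win <- select_and_order(idx, cand, thr$sub_thr, thr$super_thr)
      all_matches <- Filter(Negate(is.null), lapply(
        win$ordered_ids, function(s) match_pair(cand, idx$scaffolds[[s]])))
      if (length(all_matches) == 0) {
        expect_equal(p$label, "nonbiological")
      } else {
        expect_equal(p$label, "biological")
        expect_equal(p$evidence$score,
                     max(vapply(all_matches, `[[`, 0, "score")))
      }
    }
  }
})

test_that("decisions are monotone in the thresholds", {
  set.seed(57)
  ds <- make_labeled_dataset(fixture_spec(seed = 9, n_scaffolds = 12,
                                          scaffold_count_range = c(4, 18),
                                          n_bio = 6, n_syn = 3))
  idx <- build_index(ds$scaffolds)
  for (cand in c(ds$bio, ds$syn)) {
    labels <- vapply(c(0.2, 0.5, 0.8, 1.0), function(st) {
      classify_ssf(cand, idx, threshold_set(st, 0.5))$label
    }, "")
    # raising subThr can only lose matches: biological never reappears
    expect_false(any(labels == "biological" &
                       c("", head(labels, -1)) == "nonbiological"))
    sums <- vapply(c(0.3, 0.8, 1.3, 1.8), function(su) {
      classify_sssf(cand, idx, threshold_set(0.5, 0.5, sum_thr = su))$label
    }, "")
    expect_false(any(sums == "biological" &
                       c("", head(sums, -1)) == "nonbiological"))
  }
})

test_that("classification is deterministic", {
  ds <- make_labeled_dataset(fixture_spec(seed = 2, n_scaffolds = 8,
                                          scaffold_count_range = c(4, 14),
                                          n_bio = 4, n_syn = 2))
  idx <- build_index(ds$scaffolds)
  thr <- threshold_set(0.5, 0.5, sum_thr = 1.0)
  a <- classify_set(c(ds$bio, ds$syn), idx, "sssf", thr)
  b <- classify_set(c(ds$bio, ds$syn), idx, "sssf", thr)
  expect_identical(a, b)
})

test_that("threshold and bin configuration round-trips through JSON", {
  tf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    subThr = 0.5, superThr = 0.51, sumThr = 1.2,
    bins = data.frame(lo = c(4, 14, 24, 34, 44), hi = c(13, 23, 33, 43, 53),
                      subThr = 0.5, superThr = 0.51, sumThr = 1.2)
  ), tf, auto_unbox = TRUE)
  cfg <- read_config(tf)
  expect_equal(cfg$thresholds$sub_thr, 0.5)
  expect_equal(cfg$thresholds$sum_thr, 1.2)
  expect_equal(nrow(cfg$bins$bins), 5)
  expect_equal(bin_of(cfg$bins, 44), 5)
})
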