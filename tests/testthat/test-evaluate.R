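# Metrics, cutoff tuning, nested CV, LOOCV.

test_that("metrics match brute-force recomputation from prediction lists", {
  set.seed(77)
  for (i in 1:10) {
    truth <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    pred <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    cc <- confusion_counts(
      tp = sum(truth & pred), fp = sum(!truth & pred),
      tn = sum(!truth & !pred), fn = sum(truth & !pred)
    )
    m <- compute_metrics(cc)
    if (!any(truth) || all(truth)) next
    expect_equal(m$sens, mean(pred[truth]))
    expect_equal(m$spec, mean(!pred[!truth]))
    n <- 40
    # MCC as the Pearson correlation of two binary vectors
    if (stats::sd(pred) > 0) {
      expect_equal(m$mcc, stats::cor(as.numeric(truth), as.numeric(pred)),
                   tolerance = 1e-12)
    }
  }
})

test_that("degenerate MCC denominators are flagged and reported as zero", {
  m <- compute_metrics(confusion_counts(tp = 0, fp = 0, tn = 5, fn = 5))
  expect_equal(m$mcc, 0)
  expect_true(m$mcc_undefined)
  expect_error(compute_metrics(confusion_counts(0, 5, 5, 0)), "no positive")
})

test_that("cutoff tuning follows the SENS = SPEC rule on the score grid", {
  t1 <- tune_cutoff(c(0.9, 0.8), c(0.1, 0.2))
  expect_equal(as.numeric(t1), 0.8)
  expect_equal(attr(t1, "sens"), 1)
  expect_equal(attr(t1, "spec"), 1)
  t2 <- tune_cutoff(c(1.0), c(0.0))
  expect_equal(as.numeric(t2), 1.0)
  t3 <- tune_cutoff(c(0.5, 0.5), c(0.5, 0.5))
  expect_true(attr(t3, "degenerate"))
  # overlapping scores: the balanced cutoff
  t4 <- tune_cutoff(c(0.2, 0.6, 0.8, 0.9), c(0.1, 0.3, 0.4, 0.7))
  sens <- mean(c(0.2, 0.6, 0.8, 0.9) >= as.numeric(t4))
  spec <- mean(c(0.1, 0.3, 0.4, 0.7) < as.numeric(t4))
  grid <- sort(unique(c(0.2, 0.6, 0.8, 0.9, 0.1, 0.3, 0.4, 0.7)))
  diffs <- vapply(grid, function(t) {
    abs(mean(c(0.2, 0.6, 0.8, 0.9) >= t) - mean(c(0.1, 0.3, 0.4, 0.7) < t))
  }, 0)
  expect_equal(abs(sens - spec), min(diffs))
})

test_that("the match table agrees with direct pairwise matching", {
  ds <- make_labeled_dataset(fixture_spec(seed = 21, n_scaffolds = 8,
                                          scaffold_count_range = c(4, 14),
                                          n_bio = 6, n_syn = 6))
  mt <- match_table(c(ds$bio, ds$syn), ds$scaffolds)
  for (cand in c(ds$bio, ds$syn)) {
    for (sc in ds$scaffolds) {
      m <- match_pair(cand, sc)
      row <- mt[mt$candidate_id == cand$id & mt$scaffold_id == sc$id, ]
      if (is.null(m)) {
        expect_equal(nrow(row), 0)
      } else {
        expect_equal(nrow(row), 1)
        expect_equal(row$direction, m$direction)
        expect_equal(row$score, m$score)
      }
    }
  }
  # no synthetic candidate matches any scaffold, by construction
  expect_false(any(mt$candidate_id %in% vapply(ds$syn, `[[`, "", "id")))
})

test_that("the window-filtered fast path equals the scanning classifiers", {
  set.seed(91)
  ds <- make_labeled_dataset(fixture_spec(seed = 8, n_scaffolds = 14,
                                          scaffold_count_range = c(4, 20),
                                          n_bio = 10, n_syn = 10))
  idx <- build_index(ds$scaffolds)
  cands <- c(ds$bio, ds$syn)
  ids <- vapply(cands, `[[`, "", "id")
  acs <- vapply(cands, `[[`, 0L, "atom_count")
  mt <- match_table(cands, ds$scaffolds)
  allowed <- vapply(ds$scaffolds, `[[`, "", "id")
  ms <- scaffmatch:::.match_summary(mt, ids, acs, allowed)
  for (i in 1:10) {
    st <- sample(seq(0.1, 1, by = 0.05), 1)
    pt <- sample(seq(0.1, 1, by = 0.05), 1)
    fast <- scaffmatch:::.ssf_labels(ms, st, pt)
    slow <- vapply(cands, function(cand) {
      classify_ssf(cand, idx, threshold_set(st, pt))$label == "biological"
    }, TRUE)
    expect_equal(unname(fast), unname(slow))
    fast_sums <- scaffmatch:::.sss_sums(ms, st, pt)
    slow_sums <- vapply(cands, function(cand) {
      classify_sssf(cand, idx,
                    threshold_set(st, pt, sum_thr = 2))$evidence$sum_score
    }, 0)
    expect_equal(unname(fast_sums), unname(slow_sums))
  }
})

test_that("nested CV is deterministic under a fixed seed", {
  ds <- make_labeled_dataset(fixture_spec(seed = 4, n_scaffolds = 16,
                                          scaffold_count_range = c(4, 20),
                                          n_bio = 14, n_syn = 14))
  a <- run_nested_cv(ds$bio, ds$syn, "ssf", repeats = 1, seed = 99)
  b <- run_nested_cv(ds$bio, ds$syn, "ssf", repeats = 1, seed = 99)
  expect_identical(a$per_repeat, b$per_repeat)
})

test_that("nested CV refuses classes too small for the fold structure", {
  ds <- make_labeled_dataset(fixture_spec(seed = 5, n_scaffolds = 8,
                                          scaffold_count_range = c(4, 14),
                                          n_bio = 4, n_syn = 4))
  expect_error(run_nested_cv(ds$bio, ds$syn, "ssf"), "at least 10")
})

test_that("a separable fixture yields perfect nested-CV accuracy", {
  # every biological candidate strictly contains a scaffold that remains
  # in the index after the leakage guard; synthetics match nothing
  ds <- make_labeled_dataset(fixture_spec(seed = 13, n_scaffolds = 20,
                                          scaffold_count_range = c(4, 24),
                                          n_bio = 20, n_syn = 20,
                                          containment_fraction = 1))
  # candidates are not scaffolds here: the index is the scaffold list
  idx <- build_index(ds$scaffolds)
  thr <- threshold_set(0.5, 0.5)
  preds <- classify_set(c(ds$bio, ds$syn), idx, "ssf", thr)
  truth <- rep(c(TRUE, FALSE), c(20, 20))
  expect_equal(preds$label[truth], rep("biological", 20))
  expect_equal(preds$label[!truth], rep("nonbiological", 20))
})

test_that("LOOCV meets its structural contract on nested families", {
  scafs <- lapply(4:13, function(n) make_family("alkane-chain", n))
  res <- run_loocv(scafs, "ssf", threshold_set(0.5, 0.5),
                   eval_range = c(4, 53))
  expect_equal(res$n_classifications, 10)
  expect_true(all(res$index_sizes == 9))
  expect_equal(res$fraction_biological, 1.0)
  # pairwise containment-free scaffolds are never promoted
  free <- list(mol("CCCC", "butane"), mol("CC(C)C", "isobutane"),
               mol("C#CC#C", "diyne"), mol("c1ccccc1", "benzene"),
               mol("OCCO", "glycol"))
  res0 <- run_loocv(free, "ssf", threshold_set(0.1, 0.1))
  expect_equal(res0$fraction_biological, 0.0)
  expect_error(run_loocv(list(mol("CC", "x")), "ssf",
                         threshold_set(0.5, 0.5)), "at least 2")
})

test_that("LOOCV evaluates only in-range scaffolds but keeps all indexed", {
  scafs <- c(lapply(6:10, function(n) make_family("alcohol", n)),
             list(make_family("alcohol", 20, id = "oversize")))
  res <- run_loocv(scafs, "ssf", threshold_set(0.5, 0.5),
                   eval_range = c(4, 12))
  expect_equal(res$n_classifications, 5)
  expect_true(all(res$index_sizes == 5))  # oversize scaffold stays indexed
  expect_false("oversize" %in% res$predictions$id)
})

test_that("CV reports serialize to TSV and JSON", {
  ds <- make_labeled_dataset(fixture_spec(seed = 6, n_scaffolds = 16,
                                          scaffold_count_range = c(4, 20),
                                          n_bio = 12, n_syn = 12))
  cv <- run_nested_cv(ds$bio, ds$syn, "ssf", repeats = 1, seed = 3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_cv_report(cv, tsv, js)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), 1)
  agg <- jsonlite::read_json(js)
  expect_equal(agg$mean$sens, unname(cv$aggregate$mean["sens"]))
})
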