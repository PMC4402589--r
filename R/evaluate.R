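# Accuracy metrics, sensitivity-equals-specificity threshold tuning,
# repeated nested cross-validation, and leave-one-out experiments over a
# scaffold list.

#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer counts of true positives,
#'   false positives, true negatives, false negatives ("positive" =
#'   biological).
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = unname(tp), fp = unname(fp), tn = unname(tn),
              fn = unname(fn))
  stopifnot(all(counts >= 0))
  structure(as.list(counts), class = "confusion_counts")
}

#' Sensitivity, specificity and Matthews correlation coefficient
#'
#' `SENS = TP / (TP + FN)`, `SPEC = TN / (TN + FP)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TN+FN)(TN+FP)(TP+FN)(TP+FP))`.
#' When any MCC denominator factor is zero the coefficient is reported
#' as 0 with the `mcc_undefined` flag set (a widespread convention for
#' the degenerate case).
#'
#' @param cc a `confusion_counts` object.
#' @return A `classifier_metrics` list: `sens`, `spec`, `mcc`,
#'   `mcc_undefined`.
#' @export
compute_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  if (tp + fn == 0) stop("no positive examples: sensitivity undefined")
  if (tn + fp == 0) stop("no negative examples: specificity undefined")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  denom2 <- (tn + fn) * (tn + fp) * (tp + fn) * (tp + fp)
  if (denom2 == 0) {
    mcc <- 0
    undef <- TRUE
  } else {
    mcc <- (tp * tn - fp * fn) / sqrt(denom2)
    undef <- FALSE
  }
  structure(list(sens = sens, spec = spec, mcc = mcc, mcc_undefined = undef),
            class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf("SENS = %.4f  SPEC = %.4f  MCC = %.4f%s\n", x$sens, x$spec,
              x$mcc, if (x$mcc_undefined) " (undefined, reported as 0)" else ""))
  invisible(x)
}

.counts_from_scores <- function(scores_bio, scores_syn, cutoff) {
  confusion_counts(
    tp = sum(scores_bio >= cutoff), fn = sum(scores_bio < cutoff),
    tn = sum(scores_syn < cutoff), fp = sum(scores_syn >= cutoff)
  )
}

#' Tune a score cutoff by the sensitivity-equals-specificity rule
#'
#' Scans the grid of observed score values and selects the cutoff `t`
#' (classification rule: score `>= t` is biological) minimizing
#' `|SENS(t) - SPEC(t)|`; ties are broken by larger MCC, then by the
#' smaller cutoff.  If every score in both classes is identical, that
#' value is returned with the `degenerate` attribute set.
#'
#' @param scores_bio,scores_syn non-empty numeric score vectors for the
#'   biological and synthetic classes.
#' @return The cutoff, with attributes `sens`, `spec`, `mcc`, and
#'   `degenerate`.
#' @export
tune_cutoff <- function(scores_bio, scores_syn) {
  stopifnot(length(scores_bio) > 0, length(scores_syn) > 0)
  grid <- sort(unique(c(scores_bio, scores_syn)))
  if (length(grid) == 1) {
    return(structure(grid, sens = 1, spec = 0, mcc = 0, degenerate = TRUE))
  }
  best <- NULL
  for (t in grid) {
    m <- compute_metrics(.counts_from_scores(scores_bio, scores_syn, t))
    cand <- list(t = t, diff = abs(m$sens - m$spec), mcc = m$mcc,
                 sens = m$sens, spec = m$spec)
    if (is.null(best) ||
        cand$diff < best$diff - 1e-12 ||
        (abs(cand$diff - best$diff) <= 1e-12 && cand$mcc > best$mcc + 1e-12)) {
      best <- cand
    }
  }
  structure(best$t, sens = best$sens, spec = best$spec, mcc = best$mcc,
            degenerate = FALSE)
}

# --- precomputed match tables -----------------------------------------

#' Exhaustive candidate-by-scaffold match table
#'
#' Runs [match_pair()] for every candidate/scaffold pair and collects
#' the matches.  This threshold-independent table is the workhorse of
#' the cross-validation tuner: for any thresholds, a candidate's window
#' matches are just the rows whose scaffold atom count falls inside the
#' window bounds.
#'
#' @param candidates,scaffolds lists of `molecule` objects.
#' @return Data frame: candidate_id, scaffold_id, direction,
#'   candidate_ac, scaffold_ac, score.  Zero rows when nothing matches.
#' @export
match_table <- function(candidates, scaffolds) {
  rows <- list()
  k <- 0L
  for (cand in candidates) {
    for (sc in scaffolds) {
      if (identical(cand$id, sc$id)) next
      m <- match_pair(cand, sc)
      if (!is.null(m)) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          candidate_id = cand$id, scaffold_id = sc$id,
          direction = m$direction, candidate_ac = cand$atom_count,
          scaffold_ac = sc$atom_count, score = m$score,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (k == 0) {
    return(data.frame(candidate_id = character(0), scaffold_id = character(0),
                      direction = character(0), candidate_ac = integer(0),
                      scaffold_ac = integer(0), score = numeric(0)))
  }
  do.call(rbind, rows)
}

# Per-candidate summary of the (allowed-restricted) match table: for
# each candidate the matched scaffold atom counts and scores by
# direction.  A substructure row is in-window iff scaffold_ac >= minAC,
# a superstructure row iff scaffold_ac <= maxAC, so the window-filtered
# decision for any thresholds needs only these vectors.  Equivalent to
# the scanning classifiers (asserted by property tests).
.match_summary <- function(mt, cand_ids, cand_acs, allowed) {
  mt <- mt[mt$scaffold_id %in% allowed, , drop = FALSE]
  sub_rows <- split(seq_len(nrow(mt))[mt$direction == "substructure"],
                    mt$candidate_id[mt$direction == "substructure"])
  super_rows <- split(seq_len(nrow(mt))[mt$direction == "superstructure"],
                      mt$candidate_id[mt$direction == "superstructure"])
  n <- length(cand_ids)
  sub_acs <- super_acs <- sub_scores <- super_scores <- vector("list", n)
  for (i in seq_len(n)) {
    r <- sub_rows[[cand_ids[i]]]
    sub_acs[[i]] <- mt$scaffold_ac[r]; sub_scores[[i]] <- mt$score[r]
    r <- super_rows[[cand_ids[i]]]
    super_acs[[i]] <- mt$scaffold_ac[r]; super_scores[[i]] <- mt$score[r]
  }
  list(
    acs = cand_acs,
    sub_acs = sub_acs, sub_scores = sub_scores,
    super_acs = super_acs, super_scores = super_scores,
    max_sub_ac = vapply(sub_acs, function(x) if (length(x)) max(x) else -Inf, 0),
    min_super_ac = vapply(super_acs, function(x) if (length(x)) min(x) else Inf, 0)
  )
}

# first-match labels for all candidates at one threshold pair
.ssf_labels <- function(ms, sub_thr, super_thr) {
  min_ac <- pmax(1, floor(ms$acs * sub_thr))
  max_ac <- ceiling(ms$acs / super_thr)
  (ms$max_sub_ac >= min_ac) | (ms$min_super_ac <= max_ac)
}

# best-substructure + best-superstructure sum scores at one pair
.sss_sums <- function(ms, sub_thr, super_thr) {
  min_ac <- pmax(1, floor(ms$acs * sub_thr))
  max_ac <- ceiling(ms$acs / super_thr)
  vapply(seq_along(ms$acs), function(i) {
    in_sub <- ms$sub_acs[[i]] >= min_ac[i]
    in_super <- ms$super_acs[[i]] <= max_ac[i]
    sc_sub <- if (any(in_sub)) max(ms$sub_scores[[i]][in_sub]) else 0
    sc_super <- if (any(in_super)) max(ms$super_scores[[i]][in_super]) else 0
    sc_sub + sc_super
  }, 0)
}

# Grid tuning of (sub_thr, super_thr) by the SENS = SPEC rule for the
# first-match classifiers.  Ties: larger MCC, then larger sub_thr
# (smaller windows), then larger super_thr.
.tune_pair_grid <- function(ms_bio, ms_syn, grid = seq(0.05, 1, by = 0.05)) {
  best <- NULL
  for (s in grid) {
    for (p in grid) {
      lb <- .ssf_labels(ms_bio, s, p)
      ls <- .ssf_labels(ms_syn, s, p)
      m <- compute_metrics(confusion_counts(
        tp = sum(lb), fn = sum(!lb), tn = sum(!ls), fp = sum(ls)))
      cand <- list(sub_thr = s, super_thr = p,
                   diff = abs(m$sens - m$spec), mcc = m$mcc)
      if (is.null(best) ||
          cand$diff < best$diff - 1e-12 ||
          (abs(cand$diff - best$diff) <= 1e-12 &&
           (cand$mcc > best$mcc + 1e-12 ||
            (abs(cand$mcc - best$mcc) <= 1e-12 &&
             (cand$sub_thr > best$sub_thr ||
              (cand$sub_thr == best$sub_thr &&
               cand$super_thr > best$super_thr)))))) {
        best <- cand
      }
    }
  }
  best
}

# Stratified fold assignment: molecules are shuffled, stably grouped by
# atom-count bin, and dealt round-robin into folds in one continuous
# pass so every fold is populated whenever n >= n_folds while strata
# stay spread across folds.
.fold_assign <- function(acs, n_folds, bin_lo = 4, bin_width = 10) {
  ord <- sample(seq_along(acs))
  ord <- ord[order((acs[ord] - bin_lo) %/% bin_width)]
  folds <- integer(length(acs))
  folds[ord] <- rep_len(seq_len(n_folds), length(acs))
  folds
}

# run RNG-consuming code under a seed without disturbing the caller's
# random state
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Tune thresholds on one validation set (fast path).  Returns a list
# with sub_thr, super_thr and (for sum-score methods) sum_thr.
.tune_on_fold <- function(ms_bio, ms_syn, method) {
  pair <- .tune_pair_grid(ms_bio, ms_syn)
  out <- list(sub_thr = pair$sub_thr, super_thr = pair$super_thr,
              sum_thr = NA_real_)
  if (method %in% c("sssf", "sssb")) {
    sb <- .sss_sums(ms_bio, pair$sub_thr, pair$super_thr)
    ss <- .sss_sums(ms_syn, pair$sub_thr, pair$super_thr)
    ct <- tune_cutoff(sb, ss)
    # sum_thr is a cutoff on scores in [0, 2]; clamp away from 0
    out$sum_thr <- max(as.numeric(ct), 1e-9)
  }
  out
}

.subset_summary <- function(ms, keep) {
  list(acs = ms$acs[keep],
       sub_acs = ms$sub_acs[keep], sub_scores = ms$sub_scores[keep],
       super_acs = ms$super_acs[keep], super_scores = ms$super_scores[keep],
       max_sub_ac = ms$max_sub_ac[keep], min_super_ac = ms$min_super_ac[keep])
}

#' Repeated nested cross-validation of a classification method
#'
#' Each repeat splits the pooled biological and synthetic compounds
#' into two stratified outer folds.  On each outer-training half a
#' 5-fold inner cross-validation tunes the thresholds: every inner fold
#' is evaluated with the scaffold list restricted to the biological
#' training compounds outside that fold, and the threshold where
#' sensitivity equals specificity is recorded; the five fold cutoffs
#' are averaged and applied to the outer test half, whose biological
#' members are likewise excluded from the scaffold list (leakage
#' guard, asserted structurally on every fold).  Confusion counts are
#' pooled over the two outer folds, giving one set of metrics per
#' repeat; means and sample standard deviations are reported across
#' repeats.
#'
#' For the two-threshold first-match rules the "score where SENS =
#' SPEC" is realized as a grid search over
#' `(sub_thr, super_thr)` in `{0.05, ..., 1}^2` (step 0.05) minimizing
#' `|SENS - SPEC|` (ties: larger MCC, then larger `sub_thr`); for the
#' sum-score rules the pair is fixed the same way and `sum_thr` is then
#' tuned on the observed sum-score grid by [tune_cutoff()].  Binned
#' methods (`ssb`, `sssb`) tune one threshold set per atom-count bin,
#' falling back to the global tuning when a bin lacks both classes.
#'
#' @param bio,syn lists of curated `molecule` objects; the biological
#'   compounds double as the scaffold list.
#' @param method `"ssf"`, `"sssf"`, `"ssb"` or `"sssb"`.
#' @param repeats number of independent CV experiments.
#' @param seed integer seed; repeat r uses derived seed `seed + r`.
#' @param bin_range,n_bins atom-count binning for the binned methods.
#' @param permute_labels if `TRUE`, the pooled compounds are randomly
#'   relabeled (class sizes preserved) independently in every repeat — a
#'   permutation null under which the expected MCC is 0.
#' @return A `cv_result`: per-repeat thresholds and metrics plus
#'   aggregate means and standard deviations.
#' @export
run_nested_cv <- function(bio, syn, method = c("ssf", "sssf", "ssb", "sssb"),
                          repeats = 15, seed = 1,
                          bin_range = c(4, 53), n_bins = 5,
                          permute_labels = FALSE) {
  method <- match.arg(method)
  stopifnot(repeats >= 1)
  if (length(bio) < 10 || length(syn) < 10)
    stop("each class needs at least 10 compounds for 2-fold outer / ",
         "5-fold inner cross-validation")
  pool <- c(bio, syn)
  pool_ids <- vapply(pool, `[[`, "", "id")
  if (anyDuplicated(pool_ids)) stop("duplicate molecule ids")
  pool_acs <- vapply(pool, `[[`, 0L, "atom_count")
  n_bio <- length(bio)
  binned <- method %in% c("ssb", "sssb")
  bin_width <- (bin_range[2] - bin_range[1] + 1) / n_bins

  # threshold-independent structure matches, computed once; under label
  # permutation any compound can end up in the scaffold list
  mt <- match_table(pool, if (permute_labels) pool else bio)

  per_repeat <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    per_repeat[[r]] <- .with_seed(seed + r, {
      b_idx <- seq_len(n_bio)
      if (permute_labels) b_idx <- sample(length(pool), n_bio)
      s_idx <- setdiff(seq_along(pool), b_idx)
      bio_ids <- pool_ids[b_idx]; bio_acs <- pool_acs[b_idx]
      syn_ids <- pool_ids[s_idx]; syn_acs <- pool_acs[s_idx]

      outer_bio <- .fold_assign(bio_acs, 2, bin_range[1], bin_width)
      outer_syn <- .fold_assign(syn_acs, 2, bin_range[1], bin_width)
      cc_total <- c(tp = 0, fp = 0, tn = 0, fn = 0)
      thr_log <- list()
      for (e in 1:2) {
        tr_b <- which(outer_bio != e); te_b <- which(outer_bio == e)
        tr_s <- which(outer_syn != e); te_s <- which(outer_syn == e)
        inner_b <- .fold_assign(bio_acs[tr_b], 5, bin_range[1], bin_width)
        inner_s <- .fold_assign(syn_acs[tr_s], 5, bin_range[1], bin_width)
        fold_thr <- vector("list", 5)
        for (v in 1:5) {
          vb <- tr_b[inner_b == v]; vs <- tr_s[inner_s == v]
          if (length(vb) == 0 || length(vs) == 0)
            stop("class too small: an inner fold has no members of one class")
          allowed <- bio_ids[setdiff(tr_b, vb)]
          stopifnot(!any(bio_ids[vb] %in% allowed))
          ms_b <- .match_summary(mt, bio_ids[vb], bio_acs[vb], allowed)
          ms_s <- .match_summary(mt, syn_ids[vs], syn_acs[vs], allowed)
          fold_thr[[v]] <- .tune_fold_thresholds(
            ms_b, ms_s, method, binned, bin_range, n_bins, bin_width)
        }
        avg <- .average_fold_thresholds(fold_thr)
        thr_log[[e]] <- avg
        allowed <- bio_ids[tr_b]
        stopifnot(!any(bio_ids[te_b] %in% allowed))
        ms_b <- .match_summary(mt, bio_ids[te_b], bio_acs[te_b], allowed)
        ms_s <- .match_summary(mt, syn_ids[te_s], syn_acs[te_s], allowed)
        lb <- .apply_thresholds(ms_b, avg, method, binned, bin_range, bin_width)
        ls <- .apply_thresholds(ms_s, avg, method, binned, bin_range, bin_width)
        cc_total <- cc_total + c(tp = sum(lb), fp = sum(ls),
                                 tn = sum(!ls), fn = sum(!lb))
      }
      m <- compute_metrics(confusion_counts(cc_total["tp"], cc_total["fp"],
                                            cc_total["tn"], cc_total["fn"]))
      g <- .global_thresholds(thr_log)
      data.frame(repeat_id = r, sub_thr = unname(g["sub_thr"]),
                 super_thr = unname(g["super_thr"]),
                 sum_thr = unname(g["sum_thr"]),
                 sens = m$sens, spec = m$spec, mcc = m$mcc)
    })
  }
  per_repeat <- do.call(rbind, per_repeat)
  rownames(per_repeat) <- NULL
  agg <- list(
    mean = colMeans(per_repeat[, c("sens", "spec", "mcc")]),
    sd = apply(per_repeat[, c("sens", "spec", "mcc")], 2, stats::sd)
  )
  structure(
    list(method = method, repeats = repeats, seed = seed,
         per_repeat = per_repeat, aggregate = agg),
    class = "cv_result"
  )
}

# labels for a candidate summary under averaged (possibly binned)
# thresholds
.apply_thresholds <- function(ms, avg, method, binned, bin_range, bin_width) {
  is_sum <- method %in% c("sssf", "sssb")
  vapply(seq_along(ms$acs), function(i) {
    mi <- .subset_summary(ms, i)
    thr <- if (binned && !is.null(avg$bins)) {
      b <- floor((ms$acs[i] - bin_range[1]) / bin_width) + 1
      avg$bins[[max(1, min(length(avg$bins), b))]]
    } else {
      avg$global
    }
    if (is_sum) .sss_sums(mi, thr$sub_thr, thr$super_thr) >= thr$sum_thr
    else .ssf_labels(mi, thr$sub_thr, thr$super_thr)
  }, TRUE)
}

# one inner fold: tune globally, and per bin for the binned methods
.tune_fold_thresholds <- function(ms_b, ms_s, method, binned,
                                  bin_range, n_bins, bin_width) {
  base_method <- if (method %in% c("ssf", "ssb")) "ssf" else "sssf"
  global <- .tune_on_fold(ms_b, ms_s, base_method)
  if (!binned) return(list(global = global, bins = NULL))
  bins <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    lo <- bin_range[1] + (b - 1) * bin_width
    hi <- lo + bin_width - 1
    in_b <- ms_b$acs >= lo & ms_b$acs <= hi
    in_s <- ms_s$acs >= lo & ms_s$acs <= hi
    bins[[b]] <- if (any(in_b) && any(in_s)) {
      .tune_on_fold(.subset_summary(ms_b, in_b), .subset_summary(ms_s, in_s),
                    base_method)
    } else {
      global  # too few compounds in the bin: inherit the global tuning
    }
  }
  list(global = global, bins = bins)
}

.average_fold_thresholds <- function(fold_thr) {
  avg1 <- function(lst) {
    list(sub_thr = mean(vapply(lst, `[[`, 0, "sub_thr")),
         super_thr = mean(vapply(lst, `[[`, 0, "super_thr")),
         sum_thr = mean(vapply(lst, `[[`, 0, "sum_thr")))
  }
  global <- avg1(lapply(fold_thr, `[[`, "global"))
  bins <- NULL
  if (!is.null(fold_thr[[1]]$bins)) {
    n_bins <- length(fold_thr[[1]]$bins)
    bins <- lapply(seq_len(n_bins), function(b) {
      avg1(lapply(fold_thr, function(f) f$bins[[b]]))
    })
  }
  list(global = global, bins = bins)
}

.global_thresholds <- function(thr_log) {
  g <- lapply(thr_log, `[[`, "global")
  c(sub_thr = mean(vapply(g, `[[`, 0, "sub_thr")),
    super_thr = mean(vapply(g, `[[`, 0, "super_thr")),
    sum_thr = mean(vapply(g, `[[`, 0, "sum_thr")))
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> method ", x$method, ", ", x$repeats, " repeats\n", sep = "")
  cat(sprintf("  SENS %.3f (sd %.3f)  SPEC %.3f (sd %.3f)  MCC %.3f (sd %.3f)\n",
              x$aggregate$mean["sens"], x$aggregate$sd["sens"],
              x$aggregate$mean["spec"], x$aggregate$sd["spec"],
              x$aggregate$mean["mcc"], x$aggregate$sd["mcc"]))
  invisible(x)
}

#' Write a cross-validation report
#'
#' Per-repeat thresholds and metrics as TSV plus the aggregate as JSON.
#'
#' @param cv a `cv_result`.
#' @param tsv_path,json_path output paths (either may be `NULL`).
#' @return Invisibly, `cv`.
#' @export
write_cv_report <- function(cv, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(cv, "cv_result"))
  if (!is.null(tsv_path))
    utils::write.table(cv$per_repeat, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(method = cv$method, repeats = cv$repeats, seed = cv$seed,
           mean = as.list(cv$aggregate$mean), sd = as.list(cv$aggregate$sd)),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(cv)
}

#' Leave-one-out experiments over a scaffold list
#'
#' Every scaffold whose atom count lies in `eval_range` is removed from
#' the index in turn and classified against the remaining scaffolds;
#' scaffolds outside the range stay in the index throughout (they can
#' still be matched as superstructures) but are never themselves
#' evaluated.  Reports the fraction predicted biological overall and
#' per atom-count bin.
#'
#' @param scaffolds list of curated `molecule` objects (>= 2).
#' @param method `"ssf"`, `"sssf"`, `"ssb"` or `"sssb"`.
#' @param thr_or_bins a `threshold_set` or `bin_scheme` matching the
#'   method.
#' @param eval_range atom-count interval of scaffolds to evaluate.
#' @param n_bins number of equal-width reporting bins over `eval_range`.
#' @return A `loocv_result`: `fraction_biological`,
#'   `n_classifications`, `index_sizes`, per-scaffold `predictions`,
#'   and `per_bin` breakdown.
#' @export
run_loocv <- function(scaffolds, method = c("ssf", "sssf", "ssb", "sssb"),
                      thr_or_bins, eval_range = c(4, 53), n_bins = 5) {
  method <- match.arg(method)
  if (length(scaffolds) < 2) stop("need at least 2 scaffolds for LOOCV")
  acs <- vapply(scaffolds, `[[`, 0L, "atom_count")
  eval_idx <- which(acs >= eval_range[1] & acs <= eval_range[2])
  rows <- vector("list", length(eval_idx))
  index_sizes <- integer(length(eval_idx))
  for (j in seq_along(eval_idx)) {
    i <- eval_idx[j]
    idx <- build_index(scaffolds[-i])
    index_sizes[j] <- length(idx)
    p <- .classify_one(scaffolds[[i]], idx, method, thr_or_bins)
    ev <- p$evidence
    best <- NULL
    if (method %in% c("ssf", "ssb")) best <- ev
    else if (!is.null(ev)) {
      if (!is.null(ev$sub)) best <- ev$sub
      if (!is.null(ev$super) &&
          (is.null(best) || ev$super$score > best$score)) best <- ev$super
    }
    rows[[j]] <- data.frame(
      id = scaffolds[[i]]$id, atom_count = acs[i],
      label = p$label,
      scaffold_id = if (is.null(best)) NA_character_ else best$scaffold_id,
      score = if (is.null(best)) NA_real_ else best$score,
      n_comparisons = p$n_comparisons,
      stringsAsFactors = FALSE
    )
  }
  preds <- do.call(rbind, rows)
  bin_width <- (eval_range[2] - eval_range[1] + 1) / n_bins
  preds$bin <- pmin(n_bins,
                    floor((preds$atom_count - eval_range[1]) / bin_width) + 1)
  per_bin <- do.call(rbind, lapply(split(preds, preds$bin), function(d) {
    data.frame(bin = d$bin[1], n = nrow(d),
               fraction_biological = mean(d$label == "biological"))
  }))
  rownames(per_bin) <- NULL
  structure(
    list(fraction_biological = mean(preds$label == "biological"),
         n_classifications = nrow(preds), index_sizes = index_sizes,
         predictions = preds, per_bin = per_bin, method = method),
    class = "loocv_result"
  )
}

#' @export
print.loocv_result <- function(x, ...) {
  cat("<loocv_result> ", x$n_classifications, " experiments [", x$method,
      sprintf("]: %.1f%% predicted biological\n",
              100 * x$fraction_biological), sep = "")
  invisible(x)
}
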