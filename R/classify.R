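# The four classification rules: SSF (first match in the sorted window),
# SSSF (sum of best substructure and superstructure scores against
# sumThr), and their per-atom-count-bin variants SSB and SSSB.

#' Threshold set for window construction and classification
#'
#' `sub_thr` and `super_thr` bound the scaffold window (see
#' [min_atom_count()]); `sum_thr` is the cutoff on
#' `Sc_sub + Sc_super` used by the sum-score rules (SSSF/SSSB) only.
#'
#' @param sub_thr substructure threshold in (0, 1].
#' @param super_thr superstructure threshold in (0, 1].
#' @param sum_thr sum-score cutoff in (0, 2], or `NULL` for the
#'   first-match rules.
#' @return A `threshold_set`.
#' @export
threshold_set <- function(sub_thr, super_thr, sum_thr = NULL) {
  if (sub_thr <= 0 || sub_thr > 1) stop("sub_thr must be in (0, 1]")
  if (super_thr <= 0 || super_thr > 1) stop("super_thr must be in (0, 1]")
  if (!is.null(sum_thr) && (sum_thr <= 0 || sum_thr > 2))
    stop("sum_thr must be in (0, 2]")
  structure(list(sub_thr = sub_thr, super_thr = super_thr,
                 sum_thr = sum_thr),
            class = "threshold_set")
}

#' Per-atom-count-bin threshold scheme
#'
#' Bins partition an atom-count range; each bin carries its own
#' threshold set.  `default_bin_scheme()` builds the equal-width
#' five-bin partition of [4, 53] (4-13, 14-23, 24-33, 34-43, 44-53)
#' with one threshold set replicated across bins.
#'
#' @param bins data frame with columns `lo`, `hi`, `sub_thr`,
#'   `super_thr` and optionally `sum_thr`; bins must be contiguous and
#'   non-overlapping.
#' @return A `bin_scheme`.
#' @export
bin_scheme <- function(bins) {
  stopifnot(is.data.frame(bins),
            all(c("lo", "hi", "sub_thr", "super_thr") %in% names(bins)))
  bins <- bins[order(bins$lo), , drop = FALSE]
  if (any(bins$hi < bins$lo)) stop("bin with hi < lo")
  if (nrow(bins) > 1 && any(bins$lo[-1] != bins$hi[-nrow(bins)] + 1))
    stop("bins must partition the range contiguously")
  if (is.null(bins$sum_thr)) bins$sum_thr <- NA_real_
  rownames(bins) <- NULL
  structure(list(bins = bins), class = "bin_scheme")
}

#' @rdname bin_scheme
#' @param thr a `threshold_set` replicated across all bins.
#' @param n_bins number of equal-width bins.
#' @param range atom-count range covered by the scheme.
#' @export
default_bin_scheme <- function(thr, n_bins = 5, range = c(4, 53)) {
  stopifnot(inherits(thr, "threshold_set"))
  width <- (range[2] - range[1] + 1) / n_bins
  lo <- range[1] + floor(width * (seq_len(n_bins) - 1))
  hi <- c(lo[-1] - 1, range[2])
  bin_scheme(data.frame(
    lo = as.integer(lo), hi = as.integer(hi),
    sub_thr = thr$sub_thr, super_thr = thr$super_thr,
    sum_thr = if (is.null(thr$sum_thr)) NA_real_ else thr$sum_thr
  ))
}

#' Bin index of an atom count
#'
#' @param scheme a `bin_scheme`.
#' @param ac heavy-atom count.
#' @return 1-based bin index, or `NA` if `ac` is outside the scheme.
#' @export
bin_of <- function(scheme, ac) {
  stopifnot(inherits(scheme, "bin_scheme"))
  hit <- which(scheme$bins$lo <= ac & ac <= scheme$bins$hi)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

.bin_thresholds <- function(scheme, b) {
  row <- scheme$bins[b, ]
  threshold_set(row$sub_thr, row$super_thr,
                if (is.na(row$sum_thr)) NULL else row$sum_thr)
}

new_prediction <- function(candidate_id, label, method, evidence,
                           n_comparisons, status = "ok", bin = NA_integer_) {
  structure(
    list(candidate_id = candidate_id, label = label, method = method,
         evidence = evidence, n_comparisons = n_comparisons,
         status = status, bin = bin),
    class = "prediction"
  )
}

#' @export
print.prediction <- function(x, ...) {
  cat("<prediction> ", x$candidate_id, " [", x$method, "]: ",
      if (is.na(x$label)) x$status else x$label, sep = "")
  if (!is.na(x$label) && x$label == "biological" && !is.null(x$evidence$score))
    cat(sprintf(" (Sc = %.4f via %s)", x$evidence$score,
                x$evidence$scaffold_id))
  cat("  [", x$n_comparisons, " comparisons]\n", sep = "")
  invisible(x)
}

#' Classify by first match in the sorted scaffold window (SSF)
#'
#' Scans the proximity-ordered window and stops at the first scaffold
#' that matches the candidate in either direction; the candidate is
#' then predicted biological with that match as evidence.  If the
#' window is exhausted without a match the candidate is predicted
#' nonbiological.  Because of the proximity ordering, the first match
#' encountered is the best-scoring match available in the window.
#'
#' @param candidate a curated `molecule`.
#' @param index a `scaffold_index`.
#' @param thr a `threshold_set`.
#' @return A `prediction`.
#' @export
classify_ssf <- function(candidate, index, thr) {
  stopifnot(inherits(thr, "threshold_set"))
  win <- select_and_order(index, candidate, thr$sub_thr, thr$super_thr)
  n <- 0L
  for (sid in win$ordered_ids) {
    n <- n + 1L
    m <- match_pair(candidate, index$scaffolds[[sid]])
    if (!is.null(m)) {
      return(new_prediction(candidate$id, "biological", "ssf", m, n))
    }
  }
  new_prediction(candidate$id, "nonbiological", "ssf", NULL, n)
}

#' Classify by summed best scores in the window (SSSF)
#'
#' Finds the best substructure score `Sc_sub` and the best
#' superstructure score `Sc_super` among the window scaffolds (a
#' missing direction contributes 0) and predicts biological iff
#' `Sc_sub + Sc_super >= sum_thr`.  The proximity ordering lets each
#' direction stop at its first hit: no scaffold further out can score
#' higher in that direction.
#'
#' @inheritParams classify_ssf
#' @return A `prediction`; evidence holds the best match per direction.
#' @export
classify_sssf <- function(candidate, index, thr) {
  stopifnot(inherits(thr, "threshold_set"))
  if (is.null(thr$sum_thr)) stop("classify_sssf requires sum_thr")
  win <- select_and_order(index, candidate, thr$sub_thr, thr$super_thr)
  best_sub <- NULL
  best_super <- NULL
  n <- 0L
  for (sid in win$ordered_ids) {
    sc_ac <- index$counts[[sid]]
    # a direction already resolved needs no further scaffolds: the first
    # hit per direction is the best by the proximity ordering
    need_sub <- is.null(best_sub) && sc_ac <= candidate$atom_count
    need_super <- is.null(best_super) && sc_ac >= candidate$atom_count
    if (!need_sub && !need_super) next
    n <- n + 1L
    m <- match_pair(candidate, index$scaffolds[[sid]])
    if (!is.null(m)) {
      if (m$direction == "substructure" && is.null(best_sub)) best_sub <- m
      if (m$direction == "superstructure" && is.null(best_super)) best_super <- m
    }
    if (!is.null(best_sub) && !is.null(best_super)) break
  }
  sc_sub <- if (is.null(best_sub)) 0 else best_sub$score
  sc_super <- if (is.null(best_super)) 0 else best_super$score
  label <- if (sc_sub + sc_super >= thr$sum_thr) "biological" else "nonbiological"
  ev <- list(sub = best_sub, super = best_super,
             sc_sub = sc_sub, sc_super = sc_super,
             sum_score = sc_sub + sc_super)
  new_prediction(candidate$id, label, "sssf", ev, n)
}

#' Per-bin first-match and sum-score classification (SSB, SSSB)
#'
#' Resolves the candidate's atom-count bin and applies [classify_ssf()]
#' (SSB) or [classify_sssf()] (SSSB) with that bin's thresholds.
#' Candidates outside the bin scheme's range are refused with status
#' `"out_of_range"` and an `NA` label.
#'
#' @param candidate a curated `molecule`.
#' @param index a `scaffold_index`.
#' @param bins a `bin_scheme`.
#' @return A `prediction` carrying the resolved bin.
#' @export
classify_ssb <- function(candidate, index, bins) {
  stopifnot(inherits(bins, "bin_scheme"))
  b <- bin_of(bins, candidate$atom_count)
  if (is.na(b)) {
    return(new_prediction(candidate$id, NA_character_, "ssb", NULL, 0L,
                          status = "out_of_range"))
  }
  p <- classify_ssf(candidate, index, .bin_thresholds(bins, b))
  p$method <- "ssb"
  p$bin <- b
  p
}

#' @rdname classify_ssb
#' @export
classify_sssb <- function(candidate, index, bins) {
  stopifnot(inherits(bins, "bin_scheme"))
  b <- bin_of(bins, candidate$atom_count)
  if (is.na(b)) {
    return(new_prediction(candidate$id, NA_character_, "sssb", NULL, 0L,
                          status = "out_of_range"))
  }
  p <- classify_sssf(candidate, index, .bin_thresholds(bins, b))
  p$method <- "sssb"
  p$bin <- b
  p
}

.classify_one <- function(candidate, index, method, thr_or_bins) {
  switch(method,
    ssf = classify_ssf(candidate, index, thr_or_bins),
    sssf = classify_sssf(candidate, index, thr_or_bins),
    ssb = classify_ssb(candidate, index, thr_or_bins),
    sssb = classify_sssb(candidate, index, thr_or_bins),
    stop("unknown method: ", method)
  )
}

#' Classify a set of candidates
#'
#' @param candidates list of `molecule` objects.
#' @param index a `scaffold_index`.
#' @param method one of `"ssf"`, `"sssf"`, `"ssb"`, `"sssb"`.
#' @param thr_or_bins a `threshold_set` (ssf/sssf) or `bin_scheme`
#'   (ssb/sssb).
#' @return Data frame: one row per candidate with id, canonical SMILES,
#'   atom count, bin, label, direction, matched scaffold, score, and
#'   number of comparisons.
#' @export
classify_set <- function(candidates, index,
                         method = c("ssf", "sssf", "ssb", "sssb"),
                         thr_or_bins) {
  method <- match.arg(method)
  rows <- lapply(candidates, function(cand) {
    p <- .classify_one(cand, index, method, thr_or_bins)
    ev <- p$evidence
    if (method %in% c("ssf", "ssb")) {
      direction <- if (is.null(ev)) NA_character_ else ev$direction
      scaffold_id <- if (is.null(ev)) NA_character_ else ev$scaffold_id
      score <- if (is.null(ev)) NA_real_ else ev$score
    } else {
      best <- NULL
      if (!is.null(ev)) {
        if (!is.null(ev$sub)) best <- ev$sub
        if (!is.null(ev$super) &&
            (is.null(best) || ev$super$score > best$score)) best <- ev$super
      }
      direction <- if (is.null(best)) NA_character_ else best$direction
      scaffold_id <- if (is.null(best)) NA_character_ else best$scaffold_id
      score <- if (is.null(ev)) NA_real_ else ev$sum_score
    }
    data.frame(
      id = cand$id,
      canonical_smiles = cand$canonical_form,
      atom_count = cand$atom_count,
      bin = p$bin,
      label = p$label,
      status = p$status,
      direction = direction,
      scaffold_id = scaffold_id,
      score = score,
      n_comparisons = p$n_comparisons,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write predictions as TSV
#'
#' @param predictions data frame from [classify_set()].
#' @param path output file path.
#' @param header optional named list echoed as `# key: value` comment
#'   lines (configuration, seed, bin boundaries).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    for (k in names(header))
      writeLines(sprintf("# %s: %s", k,
                         paste(format(header[[k]]), collapse = " ")), con)
  }
  utils::write.table(predictions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a threshold/bin configuration from JSON
#'
#' The document holds global `subThr`, `superThr`, optional `sumThr`,
#' and an optional `bins` array of objects with `lo`, `hi`, `subThr`,
#' `superThr`, `sumThr`.
#'
#' @param path JSON file path.
#' @return A list with elements `thresholds` (`threshold_set`) and
#'   `bins` (`bin_scheme` or `NULL`).
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  thr <- threshold_set(cfg$subThr, cfg$superThr, cfg$sumThr)
  bins <- NULL
  if (!is.null(cfg$bins)) {
    b <- as.data.frame(cfg$bins)
    names(b)[names(b) == "subThr"] <- "sub_thr"
    names(b)[names(b) == "superThr"] <- "super_thr"
    names(b)[names(b) == "sumThr"] <- "sum_thr"
    bins <- bin_scheme(b)
  }
  list(thresholds = thr, bins = bins)
}
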