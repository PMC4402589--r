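# Scaffold set keyed by atom count; candidate-specific windows bounded
# by the substructure/superstructure thresholds, ordered by atom-count
# proximity.

#' Build an atom-count-keyed scaffold index
#'
#' Scaffolds are stored in buckets keyed by heavy-atom count, preserving
#' input order within a bucket.  Scaffolds of any size are accepted;
#' those above a candidate-set ceiling (e.g. the 54-80 atom scaffolds
#' kept alongside a 4-53 atom evaluation range) simply participate only
#' through superstructure matches, which the window produces naturally.
#'
#' @param scaffolds non-empty list of `molecule` objects with unique ids
#'   and (when available) unique canonical forms; run [curate()] first.
#' @return A `scaffold_index`.
#' @seealso [select_and_order()], [write_scaffold_index()]
#' @export
build_index <- function(scaffolds) {
  if (length(scaffolds) == 0) stop("empty scaffold list")
  stopifnot(all(vapply(scaffolds, is_molecule, TRUE)))
  ids <- vapply(scaffolds, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate scaffold ids")
  forms <- vapply(scaffolds, `[[`, "", "canonical_form")
  forms <- forms[!is.na(forms)]
  if (anyDuplicated(forms))
    stop("duplicate scaffold structures (same canonical form); curate first")
  counts <- vapply(scaffolds, `[[`, 0L, "atom_count")
  names(scaffolds) <- ids
  structure(
    list(
      scaffolds = scaffolds,
      counts = stats::setNames(counts, ids),
      by_count = split(ids, counts),
      count_range = range(counts)
    ),
    class = "scaffold_index"
  )
}

#' @export
print.scaffold_index <- function(x, ...) {
  cat("<scaffold_index> ", length(x$scaffolds), " scaffolds, atom counts ",
      x$count_range[1], "-", x$count_range[2], "\n", sep = "")
  invisible(x)
}

#' @export
length.scaffold_index <- function(x) length(x$scaffolds)

#' Window bounds from the atom-count thresholds
#'
#' `min_atom_count()` gives the smallest scaffold size that can still
#' meet the substructure threshold for a candidate of `ac` heavy atoms:
#' `floor(ac * sub_thr)`, clamped to at least 1.  `max_atom_count()`
#' gives the largest scaffold size that can meet the superstructure
#' threshold: `ceiling(ac / super_thr)`.  Any scaffold whose atom count
#' falls inside `[minAC, maxAC]` — and only such a scaffold — can yield
#' a match scoring at or above the corresponding threshold.
#'
#' @param ac candidate heavy-atom count (>= 1).
#' @param sub_thr substructure threshold in (0, 1].
#' @param super_thr superstructure threshold in (0, 1].
#' @return Integer atom-count bound.
#' @examples
#' min_atom_count(9, 0.5)    # 4
#' max_atom_count(9, 0.51)   # 18
#' @export
min_atom_count <- function(ac, sub_thr) {
  stopifnot(ac >= 1)
  if (sub_thr <= 0 || sub_thr > 1) stop("sub_thr must be in (0, 1]")
  max(1L, as.integer(floor(ac * sub_thr)))
}

#' @rdname min_atom_count
#' @export
max_atom_count <- function(ac, super_thr) {
  stopifnot(ac >= 1)
  if (super_thr <= 0 || super_thr > 1) stop("super_thr must be in (0, 1]")
  as.integer(ceiling(ac / super_thr))
}

#' Select and proximity-order the scaffold window for a candidate
#'
#' Collects every scaffold whose atom count lies in
#' `[min_atom_count(ac, sub_thr), max_atom_count(ac, super_thr)]` and
#' orders them by `|AC(scaffold) - AC(candidate)|` ascending, ties at
#' equal distance going to the larger count first (for a 9-atom
#' candidate: 9, 10, 8, 11, 7, ...).  Within one atom-count bucket the
#' stable input order of the index is kept.  Scanning this ordering and
#' stopping at the first match is guaranteed to return the best-scoring
#' match in the window.
#'
#' @param index a `scaffold_index`.
#' @param candidate a `molecule`, or directly a heavy-atom count.
#' @param sub_thr,super_thr thresholds in (0, 1].
#' @return A `scaffold_window`: candidate id, atom count, `min_ac`,
#'   `max_ac`, and `ordered_ids`.
#' @export
select_and_order <- function(index, candidate, sub_thr, super_thr) {
  stopifnot(inherits(index, "scaffold_index"))
  if (is_molecule(candidate)) {
    ac <- candidate$atom_count
    cid <- candidate$id
  } else {
    ac <- as.integer(candidate)
    cid <- NA_character_
  }
  min_ac <- min_atom_count(ac, sub_thr)
  max_ac <- max_atom_count(ac, super_thr)
  avail <- as.integer(names(index$by_count))
  cw <- avail[avail >= min_ac & avail <= max_ac]
  cw <- cw[order(abs(cw - ac), -cw)]
  ordered_ids <- as.character(unlist(index$by_count[as.character(cw)],
                                     use.names = FALSE))
  structure(
    list(candidate_id = cid, candidate_ac = ac, min_ac = min_ac,
         max_ac = max_ac, ordered_ids = ordered_ids),
    class = "scaffold_window"
  )
}

#' @export
print.scaffold_window <- function(x, ...) {
  cat("<scaffold_window> candidate AC ", x$candidate_ac, ", window [",
      x$min_ac, ", ", x$max_ac, "], ", length(x$ordered_ids),
      " scaffolds\n", sep = "")
  invisible(x)
}

#' Serialize / reload a scaffold index as TSV
#'
#' Columns: id, canonical SMILES, atom count.  Reloading re-parses the
#' SMILES, so the graphs are reconstructed identically.
#'
#' @param index a `scaffold_index`.
#' @param path TSV file path.
#' @return `write_scaffold_index()` returns `path` invisibly;
#'   `read_scaffold_index()` returns a `scaffold_index`.
#' @export
write_scaffold_index <- function(index, path) {
  stopifnot(inherits(index, "scaffold_index"))
  df <- data.frame(
    id = names(index$scaffolds),
    canonical_smiles = vapply(index$scaffolds, `[[`, "", "canonical_form"),
    atom_count = unname(index$counts),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scaffold_index
#' @export
read_scaffold_index <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  mols <- .parse_smiles_strings(df$canonical_smiles, df$id)
  rep <- attr(mols, "parse_report")
  if (any(rep$status != "ok"))
    stop("unparsable records in scaffold index file: ",
         paste(rep$id[rep$status != "ok"], collapse = ", "))
  build_index(mols)
}
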