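# Exact substructure / superstructure containment and the atom-count
# similarity score.

#' Exact substructure test
#'
#' Tests whether `small` embeds into `large` as an exact substructure:
#' an injective mapping of atoms preserving element symbol and formal
#' charge, carrying every bond of `small` onto a bond of `large` of the
#' same type (single, double, triple, or aromatic; no order-relaxed
#' matching).  Hydrogens are implicit and take no part in the mapping.
#' The relation is reflexive: every molecule is a substructure of
#' itself.
#'
#' The test is run as a VF2 subgraph isomorphism on subdivided coloured
#' graphs (one vertex per atom plus one per bond), which makes the
#' embedding a true monomorphism: extra bonds of `large` between mapped
#' atoms do not block a match.
#'
#' @param small,large `molecule` objects.
#' @return `TRUE` iff `small` is an exact substructure of `large`.
#' @seealso [match_pair()], [similarity_score()]
#' @export
is_substructure <- function(small, large) {
  stopifnot(is_molecule(small), is_molecule(large))
  if (small$atom_count > large$atom_count) return(FALSE)
  igraph::subgraph_isomorphic(small$graph, large$graph, method = "vf2")
}

#' Atom-count similarity score of a matched pair
#'
#' For a substructure relation `r` within `q`, the score is
#' `AC(r) / AC(q)`: the heavy-atom count of the smaller structure over
#' that of the larger.  Scores lie in (0, 1], reaching 1 only for
#' identical structures.
#'
#' @param r the contained (smaller) molecule.
#' @param q the containing (larger) molecule.
#' @param check verify the containment precondition (default `TRUE`).
#'   Skipping the check is only appropriate when containment was already
#'   established, e.g. by [match_pair()].
#' @return Numeric score in (0, 1].
#' @export
similarity_score <- function(r, q, check = TRUE) {
  stopifnot(is_molecule(r), is_molecule(q))
  if (r$atom_count > q$atom_count)
    stop("similarity_score: 'r' has more atoms than 'q'; not a substructure")
  if (check && !is_substructure(r, q))
    stop("similarity_score: 'r' is not a substructure of 'q'")
  r$atom_count / q$atom_count
}

new_match_result <- function(direction, scaffold_id, score) {
  structure(
    list(direction = direction, scaffold_id = scaffold_id, score = score),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match> ", x$direction, " vs ", x$scaffold_id,
      sprintf(" (Sc = %.4f)\n", x$score), sep = "")
  invisible(x)
}

#' Match a candidate against one scaffold
#'
#' A pair matches if the scaffold is an exact substructure of the
#' candidate (direction `"substructure"`) or the candidate is an exact
#' substructure of the scaffold (direction `"superstructure"`).  The
#' similarity score is the smaller atom count over the larger.
#' Identical structures are reported as a substructure match with score
#' 1.
#'
#' @param candidate,scaffold `molecule` objects.
#' @return A `match_result` (direction, scaffold id, score) or `NULL`
#'   when neither direction embeds.
#' @export
match_pair <- function(candidate, scaffold) {
  stopifnot(is_molecule(candidate), is_molecule(scaffold))
  if (scaffold$atom_count <= candidate$atom_count &&
      is_substructure(scaffold, candidate)) {
    return(new_match_result(
      "substructure", scaffold$id,
      similarity_score(scaffold, candidate, check = FALSE)
    ))
  }
  if (candidate$atom_count <= scaffold$atom_count &&
      is_substructure(candidate, scaffold)) {
    return(new_match_result(
      "superstructure", scaffold$id,
      similarity_score(candidate, scaffold, check = FALSE)
    ))
  }
  NULL
}
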