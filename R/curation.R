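# Dataset curation filters with a per-rule report.

.rule_tags <- c(
  "element", "atom_count", "polymer", "charge", "duplicate", "disjoint"
)

# charge exceptions: quaternary amines (N+ with four single bonds to
# heavy atoms) and sulfonium ions (S+ with three single bonds)
.charge_allowed <- function(m) {
  charged <- which(m$atoms$charge != 0)
  if (length(charged) == 0) return(TRUE)
  for (i in charged) {
    el <- m$atoms$element[i]
    ch <- m$atoms$charge[i]
    deg_single <- sum((m$bonds$from == i | m$bonds$to == i) & m$bonds$order == 1)
    deg_all <- sum(m$bonds$from == i | m$bonds$to == i)
    ok <- (el == "N" && ch == 1L && deg_single == 4 && deg_all == 4) ||
      (el == "S" && ch == 1L && deg_single == 3 && deg_all == 3)
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Curate a molecule set
#'
#' Applies the standard filters in a fixed order, attributing each
#' removal to the first rule that fails:
#' 1. elements outside the allowed set (C, H, N, O, P, S by default);
#' 2. heavy-atom count below `min_atoms` or above `max_atoms`;
#' 3. polymers, detected from source-record markers (repeat-unit Sgroup
#'    lines, wildcard/attachment atoms) — no heuristic repeat detection;
#' 4. structures carrying any atom with nonzero formal charge, unless
#'    every charged atom is a quaternary amine (N+ with four single
#'    bonds to heavy atoms) or a sulfonium ion (S+ with three);
#' 5. duplicate structures by canonical SMILES (first occurrence kept);
#' 6. disjoint (multi-fragment) structures.
#'
#' Scaffold lists conventionally use `max_atoms = 80`; candidate and
#' training sets use 53.
#'
#' @param mols list of `molecule` objects.
#' @param min_atoms,max_atoms inclusive heavy-atom bounds (rule 2).
#' @param allowed_elements element symbols admitted by rule 1.
#' @return A `curation_report`: `input_count`, `kept` (molecule list),
#'   `removed` (data frame id/rule/detail), `rule_counts`.
#' @export
curate <- function(mols, min_atoms = 4, max_atoms = 53,
                   allowed_elements = c("C", "H", "N", "O", "P", "S")) {
  kept <- list()
  kept_forms <- character(0)
  removed <- list()
  for (m in mols) {
    rule <- NA_character_
    detail <- ""
    bad_el <- setdiff(unique(m$atoms$element), allowed_elements)
    if (length(bad_el) > 0) {
      rule <- "element"; detail <- paste(bad_el, collapse = ",")
    } else if (m$atom_count < min_atoms || m$atom_count > max_atoms) {
      rule <- "atom_count"; detail <- as.character(m$atom_count)
    } else if (isTRUE(m$polymer_marker)) {
      rule <- "polymer"; detail <- "repeat-unit/attachment marker"
    } else if (!.charge_allowed(m)) {
      rule <- "charge"
      detail <- paste0("net ", sum(m$atoms$charge))
    } else if (!is.na(m$canonical_form) && m$canonical_form %in% kept_forms) {
      rule <- "duplicate"; detail <- m$canonical_form
    } else if (!is_connected(m)) {
      rule <- "disjoint"; detail <- ""
    }
    if (is.na(rule)) {
      kept[[length(kept) + 1]] <- m
      if (!is.na(m$canonical_form))
        kept_forms <- c(kept_forms, m$canonical_form)
    } else {
      removed[[length(removed) + 1]] <- data.frame(
        id = m$id, rule = rule, detail = detail, stringsAsFactors = FALSE
      )
    }
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(id = character(0), rule = character(0), detail = character(0))
  rule_counts <- stats::setNames(
    vapply(.rule_tags, function(r) sum(removed$rule == r), 0L), .rule_tags
  )
  structure(
    list(input_count = length(mols), kept = kept, removed = removed,
         rule_counts = rule_counts),
    class = "curation_report"
  )
}

#' @export
print.curation_report <- function(x, ...) {
  cat("<curation_report> ", x$input_count, " in, ", length(x$kept),
      " kept, ", nrow(x$removed), " removed\n", sep = "")
  nz <- x$rule_counts[x$rule_counts > 0]
  if (length(nz))
    cat("  removed by rule:",
        paste(names(nz), nz, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a curation report as TSV
#'
#' @param report a `curation_report`.
#' @param path output path for the removal table (id, rule, detail).
#' @param kept_path optional path for the kept set as a SMILES file.
#' @return `path`, invisibly.
#' @export
write_curation_report <- function(report, path, kept_path = NULL) {
  stopifnot(inherits(report, "curation_report"))
  utils::write.table(report$removed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(kept_path)) write_smiles(report$kept, kept_path)
  invisible(path)
}
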