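# Molecule data model: heavy-atom labelled graphs with canonical SMILES.
#
# All structure perception (canonicalization, aromaticity, Kekule bond
# orders, formal charges) is delegated to Open Babel via ChemmineOB; SDF
# blocks are read back with ChemmineR.  The package only assembles the
# resulting atom/bond tables into an igraph object used for matching.

# Element symbols, used to give every (element, charge) pair a stable
# integer colour for graph matching.  "*" covers wildcard/attachment
# pseudo-atoms so polymer records survive parsing long enough to be
# reported by the curation filters.
.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "*", "R", "D", "T"
)

.atom_colour <- function(element, charge) {
  idx <- match(element, .element_symbols)
  # unrecognized pseudo-atoms (e.g. "Du" dummies) share the wildcard
  # colour; curation removes them before any matching happens
  idx[is.na(idx)] <- match("*", .element_symbols)
  as.integer(idx * 1000L + charge + 500L)
}

.bond_colour <- function(order) as.integer(500000L + order)

# Subdivided matching graph: one vertex per heavy atom (coloured by
# element and formal charge) plus one vertex per bond (coloured by bond
# order, 4 = aromatic), each bond vertex joined to its two endpoints.
# A VF2 subgraph isomorphism between two such graphs is exactly a
# bond-order-preserving monomorphism between the underlying molecular
# graphs: because atoms are never adjacent to atoms in the subdivided
# form, induced and non-induced embeddings coincide, so plain VF2 gives
# chemical substructure semantics (extra bonds in the larger molecule
# between mapped atoms are permitted).
.matching_graph <- function(atoms, bonds) {
  n_at <- nrow(atoms)
  n_bd <- nrow(bonds)
  g <- igraph::make_empty_graph(n = n_at + n_bd, directed = FALSE)
  if (n_bd > 0) {
    bv <- n_at + seq_len(n_bd)
    g <- igraph::add_edges(g, as.integer(rbind(bv, bonds$from, bv, bonds$to)))
  }
  igraph::V(g)$color <- c(
    .atom_colour(atoms$element, atoms$charge),
    if (n_bd > 0) .bond_colour(bonds$order) else integer(0)
  )
  g
}

.validate_bonds <- function(atoms, bonds) {
  n <- nrow(atoms)
  if (nrow(bonds) == 0) return(invisible(TRUE))
  if (any(bonds$from < 1 | bonds$from > n | bonds$to < 1 | bonds$to > n))
    stop("bond endpoint references a non-existent atom")
  if (any(bonds$from == bonds$to))
    stop("self-loop bond")
  key <- paste(pmin(bonds$from, bonds$to), pmax(bonds$from, bonds$to))
  if (anyDuplicated(key))
    stop("duplicate bond between the same atom pair")
  if (!all(bonds$order %in% 1:4))
    stop("bond order must be 1, 2, 3 or 4 (aromatic)")
  invisible(TRUE)
}

#' Construct a molecule from atom and bond tables
#'
#' Builds a `molecule` object directly from a heavy-atom table and a bond
#' table, bypassing SMILES/SDF parsing.  Intended for programmatic graph
#' construction (e.g. randomized matcher tests); molecules built this way
#' carry no canonical SMILES (`canonical_form` is `NA`) and cannot be
#' written to chemical file formats.
#'
#' @param atoms data frame with columns `element` (symbol), `charge`
#'   (integer formal charge) and optionally `aromatic` (logical).
#' @param bonds data frame with columns `from`, `to` (1-based atom
#'   indices) and `order` (1, 2, 3, or 4 for aromatic).  May have zero
#'   rows.
#' @param id molecule identifier.
#' @return A `molecule` object.
#' @examples
#' # propane as a raw graph
#' m <- as_molecule(
#'   atoms = data.frame(element = c("C", "C", "C"), charge = 0L),
#'   bonds = data.frame(from = c(1, 2), to = c(2, 3), order = 1L),
#'   id = "propane"
#' )
#' atom_count(m)
#' @export
as_molecule <- function(atoms, bonds, id = "mol") {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1, is.data.frame(bonds))
  atoms <- data.frame(
    element = as.character(atoms$element),
    charge = if (is.null(atoms$charge)) 0L else as.integer(atoms$charge),
    aromatic = if (is.null(atoms$aromatic)) FALSE else as.logical(atoms$aromatic),
    stringsAsFactors = FALSE
  )
  if (nrow(bonds) > 0) {
    bonds <- data.frame(
      from = as.integer(bonds$from), to = as.integer(bonds$to),
      order = as.integer(bonds$order)
    )
  } else {
    bonds <- data.frame(from = integer(0), to = integer(0), order = integer(0))
  }
  .validate_bonds(atoms, bonds)
  new_molecule(id = id, atoms = atoms, bonds = bonds, canonical_form = NA_character_)
}

new_molecule <- function(id, atoms, bonds, canonical_form,
                         polymer_marker = FALSE) {
  structure(
    list(
      id = id,
      atoms = atoms,
      bonds = bonds,
      canonical_form = canonical_form,
      atom_count = nrow(atoms),
      polymer_marker = isTRUE(polymer_marker),
      graph = .matching_graph(atoms, bonds)
    ),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", x$id, ": ", x$atom_count, " heavy atoms, ",
      nrow(x$bonds), " bonds", sep = "")
  if (!is.na(x$canonical_form)) cat("  ", x$canonical_form, sep = "")
  cat("\n")
  invisible(x)
}

is_molecule <- function(x) inherits(x, "molecule")

.ob_convert <- function(from, to, text) {
  out <- tryCatch(ChemmineOB::convertFormat(from, to, source = text),
                  error = function(e) "")
  if (is.null(out)) out <- ""
  out
}

#' Canonical SMILES of a molecule or SMILES string
#'
#' Canonicalization (including aromaticity perception) is performed by
#' Open Babel, so Kekule and aromatic notations of the same structure,
#' and any permutation of the input atom order, yield identical strings.
#'
#' @param x a `molecule` (its stored canonical form is returned) or a
#'   single SMILES string to canonicalize.
#' @return Canonical SMILES string.
#' @export
canonicalize <- function(x) {
  if (is_molecule(x)) {
    if (is.na(x$canonical_form))
      stop("molecule '", x$id, "' was built without a canonical form")
    return(x$canonical_form)
  }
  stopifnot(is.character(x), length(x) == 1)
  out <- .ob_convert("SMI", "CAN", x)
  if (!nzchar(out)) stop("could not parse SMILES: ", x)
  sub("[\t\n ].*$", "", out)
}

#' Heavy-atom (or all-atom) count of a molecule
#'
#' @param m a `molecule`.
#' @param mode `"heavy"` (default) counts non-hydrogen atoms only;
#'   `"all"` additionally counts implicit and explicit hydrogens.
#' @return Integer atom count.
#' @export
atom_count <- function(m, mode = c("heavy", "all")) {
  stopifnot(is_molecule(m))
  mode <- match.arg(mode)
  if (mode == "heavy") return(m$atom_count)
  if (is.na(m$canonical_form))
    stop("all-atom count requires a molecule parsed from SMILES/SDF")
  sdf <- ChemmineOB::convertFormat(
    "SMI", "SDF", source = m$canonical_form,
    options = data.frame(names = "h", args = "", stringsAsFactors = FALSE)
  )
  counts_line <- strsplit(sdf, "\n", fixed = TRUE)[[1]][4]
  as.integer(substr(counts_line, 1, 3))
}

#' Is the heavy-atom graph connected?
#'
#' Molecules written with dot-disconnected SMILES (or multi-fragment SDF
#' records) have more than one component and are rejected by the
#' curation filters.
#'
#' @param m a `molecule`.
#' @return `TRUE` iff the heavy-atom graph has exactly one connected
#'   component.
#' @export
is_connected <- function(m) {
  stopifnot(is_molecule(m))
  igraph::is_connected(m$graph)
}

# --- parsing -----------------------------------------------------------

# Open Babel MOL2 records: element and bond tables including the
# aromatic bond perception that MDL SDF cannot carry (SDF is written
# kekulized).  No installed R package reads MOL2, so the
# whitespace-delimited sections are split here directly.
.mol2_records <- function(text) {
  recs <- strsplit(text, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]]
  recs <- recs[nzchar(trimws(recs))]
  lapply(recs, function(rec) {
    lines <- strsplit(rec, "\n", fixed = TRUE)[[1]]
    sect <- function(tag) {
      i <- which(lines == paste0("@<TRIPOS>", tag))
      if (length(i) == 0) return(character(0))
      j <- grep("^@<TRIPOS>", lines)
      j <- j[j > i]
      end <- if (length(j)) j[1] - 1 else length(lines)
      if (end < i + 1) return(character(0))
      out <- lines[(i + 1):end]
      out[nzchar(trimws(out))]
    }
    atom_rows <- strsplit(trimws(sect("ATOM")), "[[:space:]]+")
    bond_rows <- strsplit(trimws(sect("BOND")), "[[:space:]]+")
    list(
      element = vapply(atom_rows, function(r) r[2], ""),
      bonds = if (length(bond_rows)) data.frame(
        from = vapply(bond_rows, function(r) as.integer(r[2]), 0L),
        to = vapply(bond_rows, function(r) as.integer(r[3]), 0L),
        type = vapply(bond_rows, function(r) r[4], "")
      ) else data.frame(from = integer(0), to = integer(0), type = character(0))
    )
  })
}

# Formal charges from the `M  CHG` property lines of MDL SDF records
# (the authoritative V2000 charge representation; the atom-line charge
# code is a deprecated duplicate whose field position whitespace
# tokenizers misread when valence fields are present).
.sdf_record_charges <- function(rec_lines, n_atoms) {
  charges <- rep(0L, n_atoms)
  for (ln in grep("^M  CHG", rec_lines, value = TRUE)) {
    toks <- strsplit(trimws(sub("^M  CHG", "", ln)), "[[:space:]]+")[[1]]
    toks <- as.integer(toks)
    n <- toks[1]
    for (k in seq_len(n)) {
      charges[toks[2 * k]] <- toks[2 * k + 1]
    }
  }
  charges
}

# Build molecules from a vector of already-canonical SMILES.  One batch
# conversion each to MOL2 (elements, bonds, aromatic perception) and
# SDF (formal charges via `M  CHG`); the two atom orders are identical
# because both are written from the same Open Babel molecule, which is
# asserted per record via the atom counts.
.build_from_canonical <- function(smiles, ids, polymer = NULL) {
  stopifnot(length(smiles) == length(ids))
  if (length(smiles) == 0) return(list())
  if (is.null(polymer)) polymer <- grepl("*", smiles, fixed = TRUE)

  sdf_text <- .ob_convert("SMI", "SDF", paste(smiles, collapse = "\n"))
  mol2_text <- .ob_convert("SMI", "MOL2", paste(smiles, collapse = "\n"))
  sdf_recs <- .split_sdf_records(strsplit(sdf_text, "\n", fixed = TRUE)[[1]])
  mol2 <- .mol2_records(mol2_text)
  if (length(sdf_recs) != length(smiles) || length(mol2) != length(smiles))
    stop("internal: record count changed during format conversion")

  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    m2 <- mol2[[i]]
    n_at <- length(m2$element)
    counts_line <- sdf_recs[[i]][4]
    if (as.integer(substr(counts_line, 1, 3)) != n_at)
      stop("internal: SDF/MOL2 atom count disagreement for record ", ids[i])
    charges <- .sdf_record_charges(sdf_recs[[i]], n_at)
    bonds <- data.frame(
      from = m2$bonds$from, to = m2$bonds$to,
      order = vapply(m2$bonds$type, function(t) switch(
        t, "1" = 1L, "2" = 2L, "3" = 3L, "ar" = 4L, "am" = 1L, 1L), 0L,
        USE.NAMES = FALSE)
    )
    aromatic_atoms <- rep(FALSE, n_at)
    if (nrow(bonds) > 0) {
      ar <- m2$bonds$type == "ar"
      aromatic_atoms[unique(c(bonds$from[ar], bonds$to[ar]))] <- TRUE
    }
    atoms <- data.frame(
      element = m2$element, charge = charges,
      aromatic = aromatic_atoms, stringsAsFactors = FALSE
    )
    .validate_bonds(atoms, bonds)
    out[[i]] <- new_molecule(
      id = ids[i], atoms = atoms, bonds = bonds,
      canonical_form = smiles[i], polymer_marker = polymer[i]
    )
  }
  out
}

# Parse a character vector of SMILES strings (with ids) into molecules,
# canonicalizing each record individually so failures can be attributed.
.parse_smiles_strings <- function(smiles, ids, polymer = NULL) {
  n <- length(smiles)
  status <- character(n)
  message <- character(n)
  canon <- character(n)
  for (i in seq_len(n)) {
    out <- .ob_convert("SMI", "CAN", smiles[i])
    if (!nzchar(out)) {
      status[i] <- "error"
      message[i] <- "unparsable SMILES"
    } else {
      status[i] <- "ok"
      message[i] <- ""
      canon[i] <- sub("[\t\n ].*$", "", out)
    }
  }
  ok <- status == "ok"
  if (is.null(polymer)) polymer <- grepl("*", smiles, fixed = TRUE)
  mols <- .build_from_canonical(canon[ok], ids[ok], polymer[ok])
  report <- data.frame(id = ids, status = status, message = message,
                       stringsAsFactors = FALSE)
  structure(mols, parse_report = report)
}

.split_sdf_records <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0) ends <- length(lines)
  starts <- c(1, head(ends, -1) + 1)
  Map(function(s, e) lines[s:e], starts, ends)
}

#' Parse molecules from a SMILES or SDF file
#'
#' SMILES files hold one record per line (`SMILES [id]`, whitespace
#' separated); SDF files are MDL V2000.  Every record is canonicalized
#' with Open Babel on input, so aromaticity is perceived uniformly and
#' hydrogens are made implicit.  Records that fail to parse are not
#' silently dropped: they are listed in the parse report attached as
#' attribute `"parse_report"` (a data frame of id, status, message).
#'
#' @param path path to the input file.
#' @param format `"smiles"` or `"sdf"`.
#' @return List of `molecule` objects with attribute `parse_report`.
#' @seealso [write_smiles()], [curate()]
#' @export
parse_molecules <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    toks <- strsplit(trimws(lines), "[[:space:]]+")
    smiles <- vapply(toks, `[[`, "", 1)
    ids <- vapply(seq_along(toks), function(i) {
      if (length(toks[[i]]) >= 2) paste(toks[[i]][-1], collapse = " ")
      else sprintf("mol_%d", i)
    }, "")
    return(.parse_smiles_strings(smiles, ids))
  }
  lines <- readLines(path, warn = FALSE)
  recs <- .split_sdf_records(lines)
  smiles <- character(length(recs))
  ids <- character(length(recs))
  polymer <- logical(length(recs))
  status <- character(length(recs))
  msg <- character(length(recs))
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    title <- trimws(rec[1])
    ids[i] <- if (nzchar(title)) title else sprintf("mol_%d", i)
    # polymer markers live in the source record, not the parsed graph
    polymer[i] <- any(grepl("^M  STY", rec)) ||
      any(grepl("(^|[[:space:]])(\\*|R#)([[:space:]]|$)", rec))
    out <- .ob_convert("SDF", "CAN", paste(c(rec, "$$$$"), collapse = "\n"))
    if (!nzchar(out)) {
      status[i] <- "error"; msg[i] <- "unparsable SDF record"
    } else {
      status[i] <- "ok"; msg[i] <- ""
      smiles[i] <- sub("[\t\n ].*$", "", out)
    }
  }
  ok <- status == "ok"
  mols <- .build_from_canonical(smiles[ok], ids[ok], polymer[ok])
  report <- data.frame(id = ids, status = status, message = msg,
                       stringsAsFactors = FALSE)
  structure(mols, parse_report = report)
}

#' Write molecules as a SMILES file
#'
#' One record per line: canonical SMILES, a tab, and the molecule id.
#'
#' @param mols list of `molecule` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_smiles <- function(mols, path) {
  lines <- vapply(mols, function(m) {
    if (is.na(m$canonical_form))
      stop("molecule '", m$id, "' has no canonical form; cannot be written")
    paste0(m$canonical_form, "\t", m$id)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a parse report as TSV
#'
#' @param mols result of [parse_molecules()] (the report travels as the
#'   `"parse_report"` attribute) or a report data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parse_report <- function(mols, path) {
  rep <- if (is.data.frame(mols)) mols else attr(mols, "parse_report")
  if (is.null(rep)) stop("no parse report attached")
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
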