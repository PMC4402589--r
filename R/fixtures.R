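# Deterministic synthetic molecule families and labeled datasets, so
# matching, windowing, classification, cross-validation, and
# leave-one-out experiments can all be exercised without any external
# structure database.

.family_min <- c("alkane-chain" = 1L, "alcohol" = 2L, "acid" = 3L,
                 "ether-branch" = 4L)

.family_smiles <- function(kind, n_heavy) {
  switch(kind,
    "alkane-chain" = strrep("C", n_heavy),
    "alcohol" = paste0(strrep("C", n_heavy - 1), "O"),
    "acid" = paste0(strrep("C", n_heavy - 3), "C(=O)O"),
    "ether-branch" = paste0("CC(C)O", strrep("C", n_heavy - 4)),
    stop("unknown family kind: ", kind)
  )
}

# alternating single/triple carbon chains: contain no two consecutive
# single C-C bonds, so no saturated scaffold of >= 3 atoms can embed,
# and their triple bonds embed in no saturated scaffold
.alkyne_smiles <- function(n_heavy) {
  stopifnot(n_heavy >= 1)
  if (n_heavy %% 2 == 0) strrep("C#C", n_heavy / 2)
  else paste0("C", strrep("C#C", (n_heavy - 1) / 2))
}

#' Deterministic nested molecule families
#'
#' Each family kind is a chain-growing series in which the n-atom
#' member is an exact substructure of every larger member: plain alkane
#' chains, primary alcohols (chain with a terminal hydroxyl), carboxylic
#' acids (chain capped by `C(=O)O`), and branched ethers (isopropyl
#' ether head `CC(C)O` with a growing tail).  Minimum sizes are 1, 2, 3
#' and 4 heavy atoms respectively.
#'
#' @param kind one of `"alkane-chain"`, `"alcohol"`, `"acid"`,
#'   `"ether-branch"`.
#' @param n_heavy exact heavy-atom count of the member.
#' @param id molecule id (defaults to `<kind>_<n>`).
#' @return A `molecule`.
#' @examples
#' make_family("alkane-chain", 3)  # propane
#' @export
make_family <- function(kind = c("alkane-chain", "alcohol", "acid",
                                 "ether-branch"),
                        n_heavy, id = NULL) {
  kind <- match.arg(kind)
  if (n_heavy < .family_min[[kind]])
    stop("family '", kind, "' needs at least ", .family_min[[kind]],
         " heavy atoms")
  if (is.null(id)) id <- sprintf("%s_%d", kind, n_heavy)
  mols <- .parse_smiles_strings(.family_smiles(kind, n_heavy), id)
  m <- mols[[1]]
  stopifnot(m$atom_count == n_heavy)
  m
}

#' Specification for a labeled fixture dataset
#'
#' The defaults describe a desk-scale emulation of a scaffold-based
#' training setup: a scaffold list spanning a range of atom counts,
#' equal-sized biological and synthetic candidate sets with matched
#' atom-count distributions, and biological candidates that contain a
#' scaffold by construction.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_count_range inclusive atom-count range of scaffolds.
#' @param n_bio,n_syn candidate set sizes.
#' @param containment_fraction fraction of biological candidates built
#'   as strict superstructures of a scaffold; the rest are copies of a
#'   scaffold (identical structure, new id).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1, n_scaffolds = 24,
                         scaffold_count_range = c(4, 30),
                         n_bio = 32, n_syn = 32,
                         containment_fraction = 1.0) {
  stopifnot(n_scaffolds >= 1, n_bio >= 0, n_syn >= 0,
            containment_fraction >= 0, containment_fraction <= 1,
            scaffold_count_range[1] >= 4,
            scaffold_count_range[2] >= scaffold_count_range[1])
  structure(
    list(seed = seed, n_scaffolds = n_scaffolds,
         scaffold_count_range = scaffold_count_range,
         n_bio = n_bio, n_syn = n_syn,
         containment_fraction = containment_fraction),
    class = "fixture_spec"
  )
}

#' Generate a labeled scaffold/biological/synthetic dataset
#'
#' Scaffolds are distinct members of the nested families of
#' [make_family()].  Biological candidates are strict superstructures
#' of a randomly chosen scaffold (same family, 1-4 more atoms, capped
#' at 53) with probability `containment_fraction`, otherwise structural
#' copies of a scaffold.  Synthetic candidates are alternating-triple-
#' bond carbon chains — a motif structurally disjoint from all family
#' scaffolds, so their non-containment is provable rather than
#' probabilistic — with atom counts exactly matching the biological
#' set's histogram.  Ground-truth labels are certified at generation
#' time by running the matcher over every synthetic/scaffold pair and
#' every constructed biological containment.
#'
#' @param spec a [fixture_spec()].
#' @return A `fixture_dataset` list with elements `scaffolds`, `bio`,
#'   `syn` (molecule lists) and `spec`.
#' @export
make_labeled_dataset <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  lo <- spec$scaffold_count_range[1]
  hi <- spec$scaffold_count_range[2]
  kinds <- names(.family_min)
  combos <- expand.grid(kind = kinds, n = lo:hi, stringsAsFactors = FALSE)
  combos <- combos[combos$n >= .family_min[combos$kind], , drop = FALSE]
  if (nrow(combos) < spec$n_scaffolds)
    stop("infeasible fixture spec: only ", nrow(combos),
         " distinct family members in the atom-count range, need ",
         spec$n_scaffolds)
  .with_seed(spec$seed, {
    pick <- combos[sample(nrow(combos), spec$n_scaffolds), , drop = FALSE]
    scaffolds <- lapply(seq_len(nrow(pick)), function(i) {
      make_family(pick$kind[i], pick$n[i], id = sprintf("scaf_%03d", i))
    })
    bio <- vector("list", spec$n_bio)
    parent <- integer(spec$n_bio)
    for (j in seq_len(spec$n_bio)) {
      i <- sample(nrow(pick), 1)
      parent[j] <- i
      if (stats::runif(1) < spec$containment_fraction) {
        k <- sample(1:4, 1)
        n_new <- min(pick$n[i] + k, 53L)
        if (n_new <= pick$n[i]) n_new <- pick$n[i] + 1L  # keep it strict
        bio[[j]] <- make_family(pick$kind[i], n_new,
                                id = sprintf("bio_%03d", j))
      } else {
        m <- make_family(pick$kind[i], pick$n[i], id = sprintf("bio_%03d", j))
        bio[[j]] <- m
      }
    }
    bio_counts <- vapply(bio, `[[`, 0L, "atom_count")
    syn <- lapply(seq_len(spec$n_syn), function(j) {
      n <- bio_counts[((j - 1) %% max(1, length(bio_counts))) + 1]
      mols <- .parse_smiles_strings(.alkyne_smiles(n), sprintf("syn_%03d", j))
      mols[[1]]
    })
    # certify the ground truth with the matcher itself
    for (j in seq_len(spec$n_bio)) {
      if (is.null(match_pair(bio[[j]], scaffolds[[parent[j]]])))
        stop("internal: biological candidate ", j,
             " does not match its source scaffold")
    }
    for (s in syn) {
      for (sc in scaffolds) {
        if (!is.null(match_pair(s, sc)))
          stop("internal: synthetic candidate ", s$id,
               " matches scaffold ", sc$id)
      }
    }
    structure(list(scaffolds = scaffolds, bio = bio, syn = syn, spec = spec),
              class = "fixture_dataset")
  })
}

#' @export
print.fixture_dataset <- function(x, ...) {
  cat("<fixture_dataset> ", length(x$scaffolds), " scaffolds, ",
      length(x$bio), " biological, ", length(x$syn),
      " synthetic candidates (seed ", x$spec$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a fixture dataset to SMILES files plus a manifest
#'
#' Writes `scaffolds.smi`, `bio.smi`, `syn.smi` and `manifest.json`
#' (spec echo plus MD5 checksums of the three files) into `dir`.
#' Identical specs produce byte-identical outputs.
#'
#' @param ds a `fixture_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture_files <- function(ds, dir) {
  stopifnot(inherits(ds, "fixture_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("scaffolds.smi", "bio.smi", "syn.smi"))
  write_smiles(ds$scaffolds, paths[1])
  write_smiles(ds$bio, paths[2])
  write_smiles(ds$syn, paths[3])
  manifest <- list(
    spec = unclass(ds$spec),
    checksums = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                        basename(paths)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
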