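# Independent brute-force substructure oracle and random molecule
# generators used to cross-check the VF2-based matcher.  The oracle
# enumerates injective atom mappings directly on the atom/bond tables
# and shares no code with the package's matching path.

oracle_substructure <- function(small, large) {
  pa <- small$atoms; pb <- small$bonds
  ta <- large$atoms; tb <- large$bonds
  n_p <- nrow(pa); n_t <- nrow(ta)
  if (n_p > n_t) return(FALSE)
  adj <- matrix(0L, n_t, n_t)
  if (nrow(tb) > 0) for (k in seq_len(nrow(tb))) {
    adj[tb$from[k], tb$to[k]] <- tb$order[k]
    adj[tb$to[k], tb$from[k]] <- tb$order[k]
  }
  padj <- matrix(0L, n_p, n_p)
  if (nrow(pb) > 0) for (k in seq_len(nrow(pb))) {
    padj[pb$from[k], pb$to[k]] <- pb$order[k]
    padj[pb$to[k], pb$from[k]] <- pb$order[k]
  }
  used <- rep(FALSE, n_t)
  map <- integer(n_p)
  recurse <- function(i) {
    if (i > n_p) return(TRUE)
    for (t in seq_len(n_t)) {
      if (used[t]) next
      if (pa$element[i] != ta$element[t] || pa$charge[i] != ta$charge[t]) next
      ok <- TRUE
      for (j in seq_len(i - 1)) {
        if (padj[i, j] != 0L && adj[t, map[j]] != padj[i, j]) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        used[t] <<- TRUE
        map[i] <<- t
        if (recurse(i + 1)) return(TRUE)
        used[t] <<- FALSE
      }
    }
    FALSE
  }
  recurse(1)
}

# random connected labelled graph as a molecule object (chemical
# validity is irrelevant for matcher equivalence tests)
random_graph_molecule <- function(n, id = "rnd",
                                  elements = c("C", "C", "C", "N", "O"),
                                  orders = c(1L, 1L, 1L, 2L)) {
  atoms <- data.frame(
    element = sample(elements, n, replace = TRUE),
    charge = 0L
  )
  if (n == 1) {
    return(as_molecule(atoms, data.frame(from = integer(0), to = integer(0),
                                         order = integer(0)), id = id))
  }
  from <- integer(n - 1)
  to <- integer(n - 1)
  for (i in 2:n) {
    from[i - 1] <- if (i == 2) 1L else sample(i - 1, 1)
    to[i - 1] <- i
  }
  bonds <- data.frame(from = from, to = to,
                      order = sample(orders, n - 1, replace = TRUE))
  # a few extra edges beyond the spanning tree
  n_extra <- sample(0:2, 1)
  if (n_extra > 0 && n >= 3) {
    have <- paste(pmin(bonds$from, bonds$to), pmax(bonds$from, bonds$to))
    all_pairs <- expand.grid(a = seq_len(n), b = seq_len(n))
    all_pairs <- all_pairs[all_pairs$a < all_pairs$b, ]
    free <- all_pairs[!paste(all_pairs$a, all_pairs$b) %in% have, ]
    if (nrow(free) > 0) {
      pick <- free[sample(nrow(free), min(n_extra, nrow(free))), ]
      bonds <- rbind(bonds, data.frame(
        from = pick$a, to = pick$b,
        order = sample(orders, nrow(pick), replace = TRUE)
      ))
    }
  }
  as_molecule(atoms, bonds, id = id)
}

# random connected subgraph of a molecule, as a molecule (guaranteed
# substructure of its source)
random_subgraph_molecule <- function(m, k, id = "sub") {
  n <- nrow(m$atoms)
  stopifnot(k <= n)
  keep <- integer(0)
  frontier <- sample(n, 1)
  while (length(keep) < k) {
    keep <- c(keep, frontier)
    if (length(keep) == k) break
    nbr <- unique(c(
      m$bonds$to[m$bonds$from %in% keep],
      m$bonds$from[m$bonds$to %in% keep]
    ))
    nbr <- setdiff(nbr, keep)
    if (length(nbr) == 0) break
    frontier <- nbr[sample(length(nbr), 1)]
  }
  keep <- sort(keep)
  idx <- match(seq_len(n), keep)
  b <- m$bonds[m$bonds$from %in% keep & m$bonds$to %in% keep, , drop = FALSE]
  as_molecule(
    data.frame(element = m$atoms$element[keep], charge = m$atoms$charge[keep]),
    data.frame(from = idx[b$from], to = idx[b$to], order = b$order),
    id = id
  )
}

# shorthand: parse one SMILES into a molecule
mol <- function(smiles, id = smiles) {
  scaffmatch:::.parse_smiles_strings(smiles, id)[[1]]
}
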