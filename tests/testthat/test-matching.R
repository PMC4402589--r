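# Substructure/superstructure containment and the similarity score.

test_that("containment matches chemical intuition on known pairs", {
  cases <- list(
    list("CC", "CCC", TRUE),              # chain embedding
    list("c1ccccc1", "C1CCCCC1", FALSE),  # aromatic vs saturated ring
    list("CC(=O)O", "CC(=O)C(=O)O", TRUE),# acetic in pyruvic acid
    list("c1ccccc1", "Cc1ccccc1", TRUE),  # benzene in toluene
    list("c1ccccc1", "c1ccc2ccccc2c1", TRUE),  # benzene in naphthalene
    list("CCC", "C1CC1", TRUE),           # path into ring: extra bond allowed
    list("C1CC1", "CCC", FALSE),
    list("CCO", "CCN", FALSE),            # element mismatch
    list("C=C", "CC", FALSE),             # bond order mismatch
    list("CCO", "CCO", TRUE)              # reflexivity
  )
  for (cs in cases) {
    expect_equal(is_substructure(mol(cs[[1]]), mol(cs[[2]])), cs[[3]],
                 info = paste(cs[[1]], "in", cs[[2]]))
  }
})

test_that("Kekule and aromatic input notations match identically", {
  expect_true(is_substructure(mol("C1=CC=CC=C1"), mol("Cc1ccccc1")))
  expect_true(is_substructure(mol("c1ccccc1"), mol("CC1=CC=CC=C1")))
})

test_that("formal charge must match between mapped atoms", {
  expect_false(is_substructure(mol("C[N+](C)C"), mol("CN(C)C")))
  expect_true(is_substructure(mol("C[N+](C)C"), mol("C[N+](C)(C)C")))
})

test_that("similarity score is the atom-count ratio with its contract", {
  expect_equal(similarity_score(mol("CCCCC"), mol("CCCCCCCCCC")), 0.5)
  expect_equal(similarity_score(mol("CCO"), mol("CCO")), 1.0)
  expect_error(similarity_score(mol("CCCC"), mol("CC")), "more atoms")
  expect_error(similarity_score(mol("CCO"), mol("CCCN")), "not a substructure")
})

test_that("match_pair reports direction, scaffold id and score", {
  propane <- mol("CCC", "propane")
  ethane <- mol("CC", "ethane")
  m <- match_pair(propane, ethane)
  expect_equal(m$direction, "substructure")
  expect_equal(m$scaffold_id, "ethane")
  expect_equal(m$score, 2 / 3)
  m2 <- match_pair(ethane, propane)
  expect_equal(m2$direction, "superstructure")
  expect_equal(m2$score, 2 / 3)
  expect_null(match_pair(mol("c1ccccc1"), mol("c1ccncc1", "pyridine")))
  # identical structures: substructure direction, score 1
  m3 <- match_pair(mol("CCO", "cand"), mol("OCC", "scaf"))
  expect_equal(m3$direction, "substructure")
  expect_equal(m3$score, 1)
})

test_that("matcher agrees with the brute-force oracle on random graphs", {
  set.seed(71)
  n_agree <- 0L
  for (i in 1:150) {
    big <- random_graph_molecule(sample(4:8, 1), id = "big")
    # mix guaranteed-substructure and unrelated random patterns
    small <- if (i %% 2 == 0) {
      random_subgraph_molecule(big, sample(2:4, 1), id = "small")
    } else {
      random_graph_molecule(sample(2:6, 1), id = "small")
    }
    got <- is_substructure(small, big)
    want <- oracle_substructure(small, big)
    expect_equal(got, want, info = paste("case", i))
    n_agree <- n_agree + (got == want)
  }
  expect_equal(n_agree, 150L)
})

test_that("containment is antisymmetric up to canonical identity", {
  pairs <- list(c("CCO", "OCC"), c("c1ccccc1", "C1=CC=CC=C1"),
                c("CC(C)O", "OC(C)C"))
  for (p in pairs) {
    a <- mol(p[1]); b <- mol(p[2])
    expect_true(is_substructure(a, b) && is_substructure(b, a))
    expect_identical(a$canonical_form, b$canonical_form)
  }
})

test_that("containment is transitive along nested families", {
  for (kind in c("alkane-chain", "alcohol", "acid", "ether-branch")) {
    lo <- max(4, scaffmatch:::.family_min[[kind]])
    a <- make_family(kind, lo)
    b <- make_family(kind, lo + 2)
    c3 <- make_family(kind, lo + 5)
    expect_true(is_substructure(a, b))
    expect_true(is_substructure(b, c3))
    expect_true(is_substructure(a, c3))
  }
})

test_that("match scores lie in (0, 1]; score 1 needs equal atom counts", {
  set.seed(5)
  for (i in 1:30) {
    a <- make_family("alkane-chain", sample(4:12, 1), id = "a")
    b <- make_family("alcohol", sample(4:12, 1), id = "b")
    m <- match_pair(a, b)
    if (!is.null(m)) {
      expect_gt(m$score, 0)
      expect_lte(m$score, 1)
      if (m$score == 1) expect_equal(a$atom_count, b$atom_count)
    }
  }
})
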