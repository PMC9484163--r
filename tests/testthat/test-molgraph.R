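# SMILES parsing and the 39-dimensional atom featurization.

test_that("atom feature vectors have the documented block structure", {
  expect_identical(sum(ATOM_FEATURE_BLOCKS), 39L)
  v <- featurizeAtom("C", 4, 0, "unspecified", 0, "sp3", FALSE, 12.011)
  expect_length(v, 39)
  # one-hot blocks: exactly one 1 per categorical block for an in-vocabulary
  # atom, and the positions follow the frozen category orderings
  blocks <- split(seq_len(39), rep(seq_along(ATOM_FEATURE_BLOCKS),
                                   ATOM_FEATURE_BLOCKS))
  for (b in blocks[1:6]) expect_equal(sum(v[b]), 1)
  expect_equal(which(v[blocks[[1]]] == 1), 1L)       # C first in vocabulary
  expect_equal(which(v[blocks[[2]]] == 1), 5L)       # degree 4 -> slot 5
  expect_equal(which(v[blocks[[3]]] == 1), 3L)       # charge 0 -> slot 3
  expect_equal(which(v[blocks[[6]]] == 1), 3L)       # sp3 -> slot 3
  expect_equal(v[39], 12.011 / 200)
})

test_that("out-of-range descriptor values warn or error per block", {
  expect_warning(featurizeAtom("Zz", 1, 0, "unspecified", 0, "sp3", FALSE,
                               10), "not in vocabulary")
  expect_warning(featurizeAtom("C", 7, 0, "unspecified", 0, "sp3", FALSE,
                               12, atomIndex = 3L), "atom 3")
  expect_warning(featurizeAtom("C", 4, 3, "unspecified", 0, "sp3", FALSE,
                               12), "clamped")
  expect_error(featurizeAtom("C", 4, 0, "weird", 0, "sp3", FALSE, 12),
               "chirality")
  expect_error(featurizeAtom("C", 4, 0, "unspecified", 0, "sp4", FALSE, 12),
               "hybridization")
})

test_that("simple molecules parse to the expected graphs", {
  eth <- molFromSmiles("CC")
  expect_equal(atomCount(eth), 2L)
  expect_equal(adjacency(eth), matrix(c(0, 1, 1, 0), 2))

  benz <- molFromSmiles("c1ccccc1")
  expect_equal(atomCount(benz), 6L)
  ringBonds <- adjacency(benz)[adjacency(benz) > 0]
  expect_true(all(ringBonds == 1.5))
  expect_equal(sum(adjacency(benz) > 0) / 2, 6)   # six aromatic ring bonds
  aromCol <- sum(ATOM_FEATURE_BLOCKS[1:6]) + 1L
  expect_equal(atomFeatures(benz)[, aromCol], rep(1, 6))

  meth <- molFromSmiles("C")
  expect_equal(atomCount(meth), 1L)
  expect_true(all(adjacency(meth) == 0))
})

test_that("invalid SMILES raise a parse error naming the string", {
  expect_error(molFromSmiles("C(("), "C\\(\\(")
  expect_error(molFromSmiles("C1CC"), "unclosed ring")
  expect_error(molFromSmiles("qq"), "invalid SMILES")
})

test_that("perception matches frozen rdkit references", {
  # Expectations below were computed once with rdkit 2024.09 on the same
  # strings (degree, bound hydrogens, aromatic flags, bond orders).
  asp <- molFromSmiles("CC(=O)Oc1ccccc1C(=O)O")   # aspirin
  info <- asp@atomInfo
  expect_equal(info$degree, c(1, 3, 1, 2, 3, 2, 2, 2, 2, 3, 3, 1, 1))
  expect_equal(info$nH, c(3, 0, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0, 1))
  expect_equal(info$aromatic,
               c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
                 TRUE, FALSE, FALSE, FALSE))
  A <- adjacency(asp)
  expect_equal(A[1, 2], 1); expect_equal(A[2, 3], 2)
  expect_equal(A[5, 6], 1.5); expect_equal(A[5, 10], 1.5)
  expect_equal(A[11, 12], 2); expect_equal(A[11, 13], 1)
  # total bond order: 6 aromatic (1.5) + 2 double + 5 single
  expect_equal(sum(A) / 2, 6 * 1.5 + 2 * 2 + 5 * 1)

  eto <- molFromSmiles("CCO")
  expect_equal(eto@atomInfo$nH, c(3, 2, 1))
  expect_equal(eto@atomInfo$hybridization, c("sp3", "sp3", "sp3"))

  acn <- molFromSmiles("CC#N")                     # acetonitrile
  expect_equal(acn@atomInfo$hybridization, c("sp3", "sp", "sp"))
  expect_equal(adjacency(acn)[2, 3], 3)

  chiral <- molFromSmiles("C[C@H](N)C(=O)O")       # L-alanine
  expect_equal(chiral@atomInfo$chirality[2], "CCW")
  expect_equal(chiral@atomInfo$nH[2], 1)
  charged <- molFromSmiles("C[N+](C)(C)C")
  expect_equal(charged@atomInfo$charge[2], 1)
})

test_that("parsing is deterministic and permutation-consistent", {
  g1 <- molFromSmiles("CC(=O)Oc1ccccc1C(=O)O")
  g2 <- molFromSmiles("CC(=O)Oc1ccccc1C(=O)O")
  expect_identical(atomFeatures(g1), atomFeatures(g2))
  expect_identical(adjacency(g1), adjacency(g2))

  # equivalent SMILES written from the other end of the molecule: the graph
  # must agree up to a simultaneous row/column permutation
  a <- molFromSmiles("CCO")
  b <- molFromSmiles("OCC")
  perm <- c(3, 2, 1)
  expect_equal(atomFeatures(b), atomFeatures(a)[perm, ])
  expect_equal(adjacency(b), adjacency(a)[perm, perm])
})

test_that("adjacency total equals twice the bond-order sum", {
  for (smi in c("CC", "c1ccccc1", "CC#N", "CC(=O)OC", "C1CCNCC1",
                "c1ccc(F)cc1", "C=CC=C")) {
    g <- molFromSmiles(smi)
    A <- adjacency(g)
    expect_equal(max(abs(A - t(A))), 0)
    expect_true(all(diag(A) == 0))
    expect_true(all(A %in% c(0, 1, 1.5, 2, 3)))
    # each bond contributes its order twice to the matrix total
    orders <- A[upper.tri(A)]
    expect_equal(sum(A), 2 * sum(orders))
  }
})

test_that("graph cache round-trips bit-identically", {
  gs <- molsFromSmiles(c("CCO", "c1ccccc1"))
  path <- tempfile(fileext = ".rds")
  saveGraphCache(gs, path)
  back <- loadGraphCache(path)
  expect_identical(lapply(back, atomFeatures), lapply(gs, atomFeatures))
})
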