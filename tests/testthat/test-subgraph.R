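# SMILES pair encoding vocabulary learning and substructure extraction.

test_that("vocabulary learning handles the degenerate corpora", {
  v1 <- learnVocab(rep("CCO", 100), maxVocab = 1, minFrequency = 2)
  expect_equal(nrow(v1@merges), 1L)
  expect_equal(v1@merges$first, "C")   # "C","C" and "C","O" tie; lexicographic
  expect_equal(v1@merges$second, "C")
  expect_equal(v1@merges$frequency, 100L)

  v2 <- learnVocab(rep("CCO", 3), minFrequency = 10)
  expect_equal(nrow(v2@merges), 0L)

  expect_error(learnVocab(character()), "configuration error")
  expect_error(learnVocab(rep("CC", 3), maxVocab = 0), "configuration error")
})

test_that("merge learning agrees with a brute-force BPE oracle", {
  corpus <- c(rep("c1ccccc1CC", 50), rep("CCO", 50))
  v <- learnVocab(corpus, maxVocab = 5, minFrequency = 2)
  ref <- oracleBpe(corpus, 5, 2)
  expect_equal(nrow(v@merges), length(ref))
  for (i in seq_along(ref)) {
    expect_equal(v@merges$first[i], ref[[i]][1])
    expect_equal(v@merges$second[i], ref[[i]][2])
    expect_equal(v@merges$frequency[i], as.integer(ref[[i]][3]))
  }
})

test_that("tokenize-then-detokenize reproduces the input exactly", {
  corpus <- c(rep("c1ccc(F)cc1CCNC", 20), rep("CC(=O)OC", 20),
              rep("C1CCNCC1CO", 20))
  v <- learnVocab(corpus, maxVocab = 30, minFrequency = 3)
  for (smi in unique(corpus)) {
    tk <- applyVocab(smi, v)
    expect_identical(paste(tk$token, collapse = ""), smi)
  }
})

test_that("substructure extraction maps tokens to the atoms they span", {
  v <- learnVocab(rep("CCO", 10), maxVocab = 1, minFrequency = 2)  # token CC
  g <- molFromSmiles("CCO")
  ss <- extractSubstructures(g, v, nMax = 8)
  expect_equal(ss@tokens, "CC")
  expect_equal(ss@atomIndices[[1]], c(1L, 2L))

  expect_equal(length(extractSubstructures(g, v, nMax = 0)@tokens), 0L)
  gm <- molFromSmiles("C")
  expect_equal(length(extractSubstructures(gm, v, nMax = 8)@tokens), 0L)
})

test_that("extraction is deterministic and respects the atom range", {
  corpus <- c(rep("C1CCNCC1CC", 30), rep("c1ccccc1CC", 30), rep("CCOC", 30))
  v <- learnVocab(corpus, maxVocab = 40, minFrequency = 3)
  for (smi in unique(corpus)) {
    g <- molFromSmiles(smi)
    s1 <- extractSubstructures(g, v, 8)
    s2 <- extractSubstructures(g, v, 8)
    expect_identical(s1@tokens, s2@tokens)
    expect_identical(s1@atomIndices, s2@atomIndices)
    all_idx <- unlist(s1@atomIndices)
    expect_true(all(all_idx >= 1 & all_idx <= atomCount(g)))
    expect_true(all(vapply(s1@atomIndices, length, 1L) >= 2L))
    if (length(s1@frequencies) > 1)
      expect_true(all(diff(s1@frequencies) <= 0))
  }
})

test_that("induced subgraphs keep parent features and internal bonds", {
  g <- molFromSmiles("CCO")
  sub <- inducedSubgraph(g, c(2, 3))
  expect_equal(atomCount(sub), 2L)
  expect_equal(atomFeatures(sub), atomFeatures(g)[2:3, ])
  expect_equal(adjacency(sub)[1, 2], 1)

  full <- inducedSubgraph(g, 1:3)
  expect_identical(adjacency(full), adjacency(g))

  # ring-closure bond internal to the span must survive induction
  ring <- molFromSmiles("C1CCNCC1")
  sub6 <- inducedSubgraph(ring, 1:6)
  expect_equal(adjacency(sub6)[1, 6], 1)

  expect_error(inducedSubgraph(g, c(1, 7)), "out of range")
  expect_error(inducedSubgraph(g, 2), "at least 2")
})

test_that("random induced subgraphs satisfy the graph invariants", {
  set.seed(42)
  g <- molFromSmiles("CC(=O)Oc1ccccc1C(=O)O")
  for (rep in 1:20) {
    idx <- sample(atomCount(g), sample(2:atomCount(g), 1))
    sub <- inducedSubgraph(g, idx)
    expect_true(validObject(sub))
    A <- adjacency(sub)
    expect_equal(max(abs(A - t(A))), 0)
    expect_true(all(A %in% c(0, 1, 1.5, 2, 3)))
  }
})

test_that("vocabulary files round-trip bit-exactly", {
  corpus <- c(rep("CCOC", 20), rep("c1ccccc1", 20))
  v <- learnVocab(corpus, maxVocab = 10, minFrequency = 3)
  path <- tempfile(fileext = ".tsv")
  writeVocabulary(v, path)
  back <- readVocabulary(path)
  expect_identical(back@merges, v@merges)
  expect_identical(back@tokens, v@tokens)
  expect_identical(back@minFrequency, v@minFrequency)
  g <- molFromSmiles("CCOC")
  expect_identical(extractSubstructures(g, back, 8)@atomIndices,
                   extractSubstructures(g, v, 8)@atomIndices)
})
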