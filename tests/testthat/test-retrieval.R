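# Lookup-table construction, discrepant-key queries, re-ranking, and
# cumulative retrieval success.

test_that("lookup tables collapse duplicates and index sentences", {
  v <- fixtureVocab()
  mols <- c("CCO", "OCC", "c1ccccc1", "C1=CC=CC=C1", "CC(=O)O")
  tab <- buildLookup(mols, v)
  expect_identical(length(tab@smiles), 3L)   # two pairs are duplicates
  empty <- buildLookup(character(), v)
  expect_identical(length(empty@smiles), 0L)
  # skip-and-log unparseable entries
  expect_message(tab2 <- buildLookup(c("CCO", "bad$$$"), v), "skipped")
  expect_identical(length(tab2@smiles), 1L)
})

test_that("exact queries return discrepancy zero, near misses their count", {
  v <- fixtureVocab()
  mols <- moleculeLibrary()[1:50]
  tab <- buildLookup(mols, v)
  sent <- tab@sentences[7]
  hits <- queryLookup(tab, sent, v)
  expect_identical(hits$discrepancy[1], 0L)
  expect_true(tab@smiles[7] %in% hits$smiles[hits$discrepancy == 0L])
  expect_true(all(diff(hits$discrepancy) >= 0L))
  # perturbing the query by dropping one key gives discrepancy 1 to the
  # original entry
  ks <- tab@sets[[7]]
  q1 <- encodeMolecule(ks[-1], v)
  h1 <- queryLookup(tab, q1, v)
  expect_identical(h1$discrepancy[h1$smiles == tab@smiles[7]][1], 1L)
  # and a 2-key perturbation is found at discrepancy 2
  q2 <- encodeMolecule(ks[-(1:2)], v)
  h2 <- queryLookup(tab, q2, v, max_discrepancy = 4L)
  expect_identical(h2$discrepancy[h2$smiles == tab@smiles[7]][1], 2L)
  expect_error(queryLookup(tab, "zzz", v), "zzz")
})

test_that("discrepancy is a metric on key sets", {
  disc <- function(a, b) length(setdiff(a, b)) + length(setdiff(b, a))
  A <- c(1L, 2L, 3L); B <- c(2L, 3L, 4L); C <- c(5L, 6L)
  expect_identical(disc(A, B), disc(B, A))
  expect_identical(disc(A, A), 0L)
  expect_lte(disc(A, C), disc(A, B) + disc(B, C))
})

test_that("re-ranking puts the reference first with score 1", {
  cand <- c("CCO", "CCCO", "c1ccccc1O")
  r <- rerankCandidates(cand, "CCO")
  expect_identical(r$smiles[1], "CCO")
  expect_identical(r$score[1], 1)
  expect_true(all(diff(r$score) <= 0))
  # order invariant to input permutation (up to ties)
  r2 <- rerankCandidates(rev(cand), "CCO")
  expect_identical(r2$smiles[1], "CCO")
  expect_identical(sort(r$score), sort(r2$score))
  # hand-computed scores from the package fingerprints
  fps <- keySets(computeECFP(c("CCO", cand), 2, 2048))
  hand <- vapply(2:4, function(i) {
    inter <- length(intersect(fps[[1]], fps[[i]]))
    inter / (length(fps[[1]]) + length(fps[[i]]) - inter)
  }, numeric(1))
  expect_equal(r$score, sort(hand, decreasing = TRUE))
  expect_error(rerankCandidates(cand, "bad$$$"), "bad")
})

test_that("retrieval success is exact at k=0 and monotone in k", {
  v <- fixtureVocab()
  mols <- unique(canonicalSmiles(moleculeLibrary()))[1:60]
  tab <- buildLookup(mols, v)
  # truths present in the table, predictions = their exact sentences
  idx <- match(canonicalSmiles(mols[1:10]), tab@smiles)
  preds <- tab@sentences[idx]
  rs <- retrievalSuccess(tab, preds, mols[1:10], v)
  expect_identical(rs$success_pct[rs$k == 0], 100)
  expect_true(all(diff(rs$success_pct) >= 0))
  # a perturbed prediction needs a higher k
  ks <- tab@sets[[idx[1]]]
  pred2 <- encodeMolecule(ks[-(1:2)], v)
  rs2 <- retrievalSuccess(tab, pred2, mols[1], v)
  expect_identical(rs2$success_pct[rs2$k < 2], c(0, 0))
  expect_identical(rs2$success_pct[rs2$k == 2], 100)
  # truths absent from the table are never retrievable
  rs3 <- retrievalSuccess(tab, preds[1], "C(F)(F)C(F)(F)C(F)F", v)
  expect_true(all(rs3$success_pct == 0))
})
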