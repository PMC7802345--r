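# Key profiling, curation thresholds, and the lettered-word vocabulary.

test_that("profileKeys counts molecules containing each key", {
  p1 <- profileKeys("CCO", "MACCS")
  expect_true(all(p1$counts %in% c(0L, 1L)))
  expect_identical(p1$n_molecules, 1L)
  p2 <- profileKeys(c("CCO", "CCO"), "MACCS")
  expect_identical(p2$counts, p1$counts * 2L)
  expect_true(all(keyFrequencies(p2) >= 0 & keyFrequencies(p2) <= 1))

  # exact counts on a 10-molecule fixture, against per-molecule membership
  corpus <- moleculeLibrary()[seq(5, 140, by = 15)]
  prof <- profileKeys(corpus, "MACCS")
  sets <- keySets(computeMACCS(corpus))
  brute <- vapply(1:166, function(k)
    sum(vapply(sets, function(s) k %in% s, logical(1))), integer(1))
  expect_identical(unname(prof$counts), brute)
})

test_that("profileKeys skips unparseable entries and fails when all fail", {
  expect_warning(p <- profileKeys(c("CCO", "bad$$$"), "MACCS"), "skipped")
  expect_identical(p$n_molecules, 1L)
  expect_error(suppressWarnings(profileKeys(c("bad$$$", "worse$$$"))),
               "no corpus entry")
})

test_that("curateKeys applies the three drop criteria", {
  mk <- function(counts, n) structure(
    list(counts = stats::setNames(counts, 1:166), n_molecules = n,
         backend = "MACCS", skipped = 0L),
    class = "keyFrequencyProfile")
  # all thresholds 0 and no zero-count keys: identity on all 166 keys
  full <- mk(rep(50L, 166L), 100L)
  expect_identical(curateKeys(full, full, 0, 0), 1:166)
  # a key that never occurs in the primary corpus is always removed
  one0 <- mk(c(0L, rep(50L, 165L)), 100L)
  expect_false(1L %in% curateKeys(one0, rare_primary = 0))
  # profiles built so exactly 40 keys fail -> 126 survivors:
  # 5 never occur, 9 rare in primary, 26 rare only in reference
  counts <- rep(5000L, 166L)
  counts[1:5] <- 0L
  counts[6:14] <- 1L                     # primary freq 1e-4 < 1e-3
  primary <- mk(counts, 10000L)
  refCounts <- rep(5000L, 166L)
  refCounts[15:40] <- 1L                 # reference freq 1e-4 < 1e-3
  reference <- mk(refCounts, 10000L)
  kept <- curateKeys(primary, reference, rare_primary = 1e-3,
                     rare_reference = 1e-3)
  expect_identical(kept, 41:166)
  expect_length(kept, 126L)
  # raising any threshold never increases the retained count
  for (th in c(0, 1e-4, 1e-3, 1e-2, 0.6)) {
    k2 <- curateKeys(primary, reference, rare_primary = th,
                     rare_reference = 1e-3)
    expect_lte(length(k2), length(curateKeys(primary, reference,
                                             rare_primary = 0,
                                             rare_reference = 1e-3)))
  }
  # explicit key list bypasses thresholding
  expect_identical(curateKeys(primary, reference, keep = c(3L, 1L)),
                   c(1L, 3L))
  expect_error(curateKeys(primary, reference, rare_primary = 2),
               "\\[0, 1\\]")
})

test_that("the lettered vocabulary covers 126 keys with 42+84 words", {
  v <- syntheticVocab()          # 126 keys, counts decreasing with key
  expect_length(retainedKeys(v), 126L)
  w <- keyWords(v)
  expect_identical(anyDuplicated(w), 0L)
  nch <- nchar(w)
  expect_identical(sum(nch == 1L), 42L)
  expect_identical(sum(nch == 2L), 84L)
  expect_true(all(nch %in% 1:2))
  # suffix arithmetic: 42 of each suffix
  expect_identical(sum(grepl("x$", w) & nch == 2L), 42L)
  expect_identical(sum(grepl("z$", w) & nch == 2L), 42L)
  # rank -> word convention
  byRank <- w[order(keyRanks(v)[names(w)])]
  expect_identical(unname(byRank[c(1, 22, 43, 85)]), c("E", "e", "Ex", "Ez"))
  expect_identical(unname(byRank[c(2, 21, 42)]), c("T", "V", "v"))
  # ranks are a permutation
  expect_identical(sort(as.integer(keyRanks(v))), 1:126)
})

test_that("rank ties break toward the lower key index", {
  counts <- stats::setNames(integer(166), 1:166)
  counts[c(10, 20, 30)] <- 7L
  prof <- structure(list(counts = counts, n_molecules = 10L,
                         backend = "MACCS", skipped = 0L),
                    class = "keyFrequencyProfile")
  v <- buildVocabulary(c(30L, 10L, 20L), prof)
  r <- keyRanks(v)
  expect_lt(r[["10"]], r[["20"]])
  expect_lt(r[["20"]], r[["30"]])
  expect_error(buildVocabulary(c(10L, 10L), prof), "duplicate")
})

test_that("vocabularies above 126 keys fall back to rank words", {
  counts <- stats::setNames(rep(1L, 166L), 1:166)
  prof <- structure(list(counts = counts, n_molecules = 2L,
                         backend = "MACCS", skipped = 0L),
                    class = "keyFrequencyProfile")
  v <- buildVocabulary(1:140, prof)
  expect_true(all(grepl("^w[0-9]+$", keyWords(v))))
})

test_that("vocabulary files are byte-stable and round-trip", {
  v <- syntheticVocab()
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  writeVocabulary(v, f1)
  writeVocabulary(v, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  v2 <- readVocabulary(f1)
  expect_identical(retainedKeys(v2), retainedKeys(v))
  expect_identical(keyWords(v2), keyWords(v))
  expect_identical(keyRanks(v2), keyRanks(v))
})
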