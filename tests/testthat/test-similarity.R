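# Tanimoto / Tversky / Dice metrics, the pair-matching rule, and band
# histograms.

test_that("tanimoto agrees with direct set arithmetic", {
  expect_identical(tanimotoSimilarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(tanimotoSimilarity(c(1, 2), c(3, 4)), 0)
  expect_identical(tanimotoSimilarity(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_warning(z <- tanimotoSimilarity(integer(), integer()), "empty")
  expect_identical(z, 0)
})

test_that("tversky special cases and the worked example hold", {
  expect_equal(tverskySimilarity(c(1, 2, 3), c(2, 3, 4), 0.1, 0.9), 2 / 3)
  expect_error(tverskySimilarity(1:3, 2:4, -1, 1), "non-negative")
  expect_identical(tverskySimilarity(1:3, 1:3, 7, 9), 1)
})

test_that("metric properties hold on 1000 random key-set pairs", {
  set.seed(909)
  pairs <- replicate(1000, list(
    r = sort(sample.int(166L, sample(1:40, 1))),
    p = sort(sample.int(166L, sample(1:40, 1)))), simplify = FALSE)
  for (pr in pairs) {
    tc <- tanimotoSimilarity(pr$r, pr$p)
    expect_gte(tc, 0); expect_lte(tc, 1)
    expect_identical(tc, tanimotoSimilarity(pr$p, pr$r))
    expect_equal(tverskySimilarity(pr$r, pr$p, 1, 1), tc)
    expect_equal(diceSimilarity(pr$r, pr$p),
                 tverskySimilarity(pr$r, pr$p, 0.5, 0.5))
    expect_identical(tc == 1, setequal(pr$r, pr$p))
  }
})

test_that("matchPairs follows the combinatorial pairing table", {
  A <- c(1L, 2L, 3L); B <- c(10L, 11L); C <- c(1L, 2L, 4L)
  # crossed assignment recovers a perfect double match
  m <- matchPairs(list(A, B), list(B, A))
  expect_identical(m$score, 1)
  expect_identical(unname(m$assignment[, "predicted"]), c(2L, 1L))
  # 2 truths vs 1 prediction: best single pair
  m2 <- matchPairs(list(A, B), list(C))
  expect_equal(m2$score, tanimotoSimilarity(A, C))
  expect_identical(unname(m2$assignment[, "true"]), 1L)
  # 1 vs 1 identical
  expect_identical(matchPairs(list(A), list(A))$score, 1)
  expect_error(matchPairs(list(), list(A)), "non-empty")
  expect_error(matchPairs(list(A, B, C), list(A)), "1 or 2")
})

test_that("matchPairs equals brute-force assignment maximization", {
  set.seed(410)
  bruteBest <- function(truth, predicted) {
    nt <- length(truth); np <- length(predicted)
    if (nt == 2 && np == 2) {
      s1 <- (tanimotoSimilarity(truth[[1]], predicted[[1]]) +
             tanimotoSimilarity(truth[[2]], predicted[[2]])) / 2
      s2 <- (tanimotoSimilarity(truth[[1]], predicted[[2]]) +
             tanimotoSimilarity(truth[[2]], predicted[[1]])) / 2
      max(s1, s2)
    } else {
      max(vapply(seq_len(nt), function(i)
        max(vapply(seq_len(np), function(j)
          tanimotoSimilarity(truth[[i]], predicted[[j]]), numeric(1))),
        numeric(1)))
    }
  }
  for (i in 1:500) {
    truth <- replicate(sample(1:2, 1),
                       sort(sample.int(60L, sample(1:15, 1))),
                       simplify = FALSE)
    predicted <- replicate(sample(1:2, 1),
                           sort(sample.int(60L, sample(1:15, 1))),
                           simplify = FALSE)
    expect_equal(matchPairs(truth, predicted)$score,
                 suppressWarnings(bruteBest(truth, predicted)))
  }
})

test_that("band histograms partition the corpus and summaries match", {
  scores <- c(0, 0.2, 0.5, 0.69, 0.7, 0.85, 0.9, 0.99, 1, 1)
  out <- bandOutcome(scores)
  expect_identical(sum(evalBands(out)), length(scores))
  expect_identical(unname(evalBands(out)),
                   c(2L, 2L, 2L, 2L, 2L))   # 0.85 joins the band below it
  s <- evalSummary(out)
  expect_equal(s$exact_pct, 20)
  expect_equal(s$bioactively_similar_pct, 20)
  expect_equal(s$ge_085_pct, 50)
  expect_equal(s$mean_score, mean(scores))
  # all-exact corpus
  allx <- bandOutcome(rep(1, 5))
  expect_equal(evalSummary(allx)$exact_pct, 100)
  expect_equal(evalSummary(allx)$mean_score, 1)
})

test_that("corpusSuccess is permutation-invariant", {
  set.seed(77)
  truths <- replicate(20, list(sort(sample.int(50L, 8))), simplify = FALSE)
  preds <- replicate(20, list(sort(sample.int(50L, 8))), simplify = FALSE)
  a <- corpusSuccess(truths, preds)
  perm <- sample(20)
  b <- corpusSuccess(truths[perm], preds[perm])
  expect_identical(sort(evalScores(a)), sort(evalScores(b)))
  expect_identical(evalBands(a), evalBands(b))
  expect_error(corpusSuccess(list(), list()), "empty")
})
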