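# Reaction parsing and the curation cascade.

test_that("reaction lines parse into canonical components", {
  corp <- parseReactions("CCO.CC(=O)O>>CCOC(C)=O")
  rec <- reactionRecords(corp)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$product, canonicalSmiles("CCOC(C)=O"))
  expect_identical(sort(rec$reactants[[1]]),
                   sort(canonicalSmiles(c("CCO", "CC(=O)O"))))
  expect_identical(rec$nReactants, 2L)
  # reagents in the middle field are discarded
  corp2 <- parseReactions("CCO>[Na+]>CCBr")
  expect_identical(reactionRecords(corp2)$nReactants, 1L)
  # multi-product records are flagged, then dropped by the filter
  corp3 <- parseReactions("CCO>>CCBr.CCI")
  expect_identical(reactionRecords(corp3)$nProducts, 2L)
  expect_identical(nrow(reactionRecords(filterSingleProduct(corp3))), 0L)
})

test_that("malformed lines are skipped and counted", {
  lines <- c(sprintf("CCO>>CCO%s", strrep("C", 1:5)), "garbage", "CC>>",
             sprintf("CCN>>CCN%s", strrep("C", 1:5)))
  lines[3] <- "CCO.CC(=O)O>>CCOC(C)=O"
  expect_message(corp <- parseReactions(lines), "2 malformed")
  expect_identical(curationReport(corp)$parsed, 10L)
  expect_identical(curationReport(corp)$parse_failed, 2L)
  expect_identical(curationReport(corp)$input, 12L)
})

test_that("the cascade filters work on a constructed corpus", {
  v <- fixtureVocab()
  syn <- makeReactionCorpus(60, seed = 5, vocab = v,
                            dup_rate = 0.1, twin_rate = 0.1,
                            multi_reactant_rate = 0.08, long_count = 3L,
                            injective_violations = 4L)
  planted <- syn$planted
  cur <- curateEncoded(syn$corpus)
  rep <- curationReport(cur)
  expect_identical(rep$duplicates_removed, planted$duplicates)
  expect_identical(rep$internal_twins_removed, planted$twins)
  expect_identical(rep$too_many_reactants_removed, planted$multi_reactant)
  expect_identical(rep$too_long_removed, planted$too_long)
  expect_identical(rep$injective_collapsed, planted$injective)
  expect_identical(rep$final, 60L)
  # the final map is injective
  expect_identical(anyDuplicated(reactionRecords(cur)$src), 0L)
})

test_that("individual filters honour their contracts", {
  mk <- function(src, tgt, nR = 1L) {
    new("ReactionCorpus",
        records = data.frame(product = paste0("p", seq_along(src)),
                             nProducts = 1L,
                             reactants = I(rep(list(character()),
                                               length(src))),
                             nReactants = nR, src = src, tgt = tgt,
                             stringsAsFactors = FALSE),
        report = list())
  }
  # duplicates: first occurrence kept
  d <- dedupePairs(mk(c("A B", "A B", "C"), c("X", "X", "Y")))
  expect_identical(nrow(reactionRecords(d)), 2L)
  expect_identical(curationReport(d)$duplicates_removed, 1L)
  # twins: exact token-sequence equality
  t <- removeInternalTwins(mk(c("A B", "A B"), c("A B", "B A")))
  expect_identical(reactionRecords(t)$tgt, "B A")
  # reactant count
  rc <- filterReactantCount(mk(c("A", "B"), c("X", "Y"), nR = c(2L, 3L)))
  expect_identical(reactionRecords(rc)$src, "A")
  # pair length: inclusive bound, separator counted
  long99 <- paste(rep("A", 49), collapse = " ")
  exact100 <- mk(paste(rep("A", 50), collapse = " "),
                 paste(rep("B", 50), collapse = " "))
  over <- mk(paste(rep("A", 51), collapse = " "),
             paste(rep("B", 50), collapse = " "))
  expect_identical(nrow(reactionRecords(filterPairLength(exact100))), 1L)
  expect_identical(nrow(reactionRecords(filterPairLength(over))), 0L)
  expect_identical(nrow(reactionRecords(filterPairLength(mk("A", "B")))), 1L)
})

test_that("injective collapse keeps the shortest target, ties lexicographic", {
  mk <- function(src, tgt) new("ReactionCorpus",
    records = data.frame(product = paste0("p", seq_along(src)),
                         nProducts = 1L,
                         reactants = I(rep(list(character()), length(src))),
                         nReactants = 1L, src = src, tgt = tgt,
                         stringsAsFactors = FALSE),
    report = list())
  c1 <- collapseInjective(mk(c("S", "S", "T"),
                             c("A B C D E F G", "A B C D", "X")))
  expect_identical(sort(reactionRecords(c1)$tgt), c("A B C D", "X"))
  # tie on length: lexicographically smallest token sequence wins
  c2 <- collapseInjective(mk(c("S", "S"), c("B A", "A B")))
  expect_identical(reactionRecords(c2)$tgt, "A B")
  # already injective: identity
  c3 <- collapseInjective(mk(c("S", "T"), c("A", "B")))
  expect_identical(nrow(reactionRecords(c3)), 2L)
  expect_identical(curationReport(c3)$injective_collapsed, 0L)
  # property: no source maps to two targets afterwards
  set.seed(31)
  src <- sample(LETTERS[1:8], 60, replace = TRUE)
  tgt <- vapply(1:60, function(i)
    paste(sample(letters, sample(1:6, 1)), collapse = " "), character(1))
  out <- reactionRecords(collapseInjective(mk(src, tgt)))
  expect_identical(anyDuplicated(out$src), 0L)
  # brute-force check of the winner within one group
  grp <- which(src == src[1])
  lens <- sentenceLength(tgt[grp])
  best <- grp[order(lens, gsub(" ", "\x01", tgt[grp]))][1]
  expect_true(tgt[best] %in% out$tgt[out$src == src[1]])
})

test_that("two-reactant targets are ordered by descending length", {
  v <- fixtureVocab()
  sep <- specialTokens()[["SEP"]]
  lines <- "CCO.CC(=O)Oc1ccccc1C(=O)O>>CCOC(C)=O"
  corp <- encodeReactions(filterSingleProduct(parseReactions(lines)), v)
  tgt <- reactionRecords(corp)$tgt
  segs <- strsplit(tgt, paste0(" ", sep, " "), fixed = TRUE)[[1]]
  expect_identical(length(segs), 2L)
  expect_gte(sentenceLength(segs[1]), sentenceLength(segs[2]))
})

test_that("dataset splits are seeded, sized, and disjoint", {
  v <- fixtureVocab()
  syn <- makeReactionCorpus(100, seed = 8, vocab = v)
  cur <- curateEncoded(syn$corpus)
  sp1 <- splitDataset(cur, seed = 4)
  sp2 <- splitDataset(cur, seed = 4)
  expect_identical(sp1$combined$train$src, sp2$combined$train$src)
  expect_identical(nrow(sp1$combined$test), 10L)
  expect_identical(nrow(sp1$combined$val), 9L)
  expect_identical(nrow(sp1$combined$train), 81L)
  allSrc <- c(sp1$combined$train$src, sp1$combined$val$src,
              sp1$combined$test$src)
  expect_identical(sort(allSrc), sort(reactionRecords(cur)$src))
  # single/double subsets partition by reactant count
  expect_true(all(sp1$single$train$nReactants == 1L))
  expect_true(all(sp1$double$train$nReactants == 2L))
})

test_that("sentence files are byte-identical across reruns", {
  v <- fixtureVocab()
  syn <- makeReactionCorpus(30, seed = 12, vocab = v)
  cur <- curateEncoded(syn$corpus)
  d1 <- tempfile(); d2 <- tempfile()
  writeSentenceFiles(cur, d1, "run")
  writeSentenceFiles(cur, d2, "run")
  for (f in c("run-src.txt", "run-tgt.txt")) {
    a <- file.path(d1, f); b <- file.path(d2, f)
    expect_identical(readBin(a, "raw", file.size(a)),
                     readBin(b, "raw", file.size(b)))
  }
})
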