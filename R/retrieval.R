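# Mapping predicted fragment sentences back to real molecules: an indexed
# lookup table over a molecule database, near-miss search by discrepant-key
# count (symmetric difference of key sets), and re-ranking of equivalent
# candidates with a circular fingerprint.

#' Build a fingerprint lookup table
#'
#' One entry per canonical SMILES; each entry stores the molecule's curated
#' key set, its sentence ("language representation"), and contributes to an
#' inverted key -> entries index used for near-miss queries. Unparseable
#' entries are skipped and logged.
#'
#' @param smiles character vector of molecules.
#' @param vocab a [KeyVocabulary].
#' @return a [LookupTable].
#' @export
buildLookup <- function(smiles, vocab) {
  can <- canonicalSmiles(smiles, onError = "na")
  if (any(is.na(can)))
    message(sprintf("skipped %d unparseable molecule(s)", sum(is.na(can))))
  can <- unique(can[!is.na(can)])
  if (!length(can))
    return(new("LookupTable", smiles = character(), sets = list(),
               sentences = character(), invIndex = list(),
               vocabHash = .vocabHash(vocab)))
  ks <- computeMACCS(can)
  sets <- lapply(ks@sets, function(s) s[s %in% vocab@retainedKeys])
  sentences <- encodeMolecule(ks, vocab)
  inv <- split(rep(seq_along(sets), lengths(sets)),
               as.character(unlist(sets)))
  new("LookupTable", smiles = can, sets = sets, sentences = sentences,
      invIndex = inv, vocabHash = .vocabHash(vocab))
}

# Discrepancy (symmetric-difference size) between a query key set and every
# table entry that could fall within maxK, via the inverted index.
.discrepancies <- function(table, qset, maxK) {
  counts <- integer(length(table@smiles))
  for (k in as.character(qset)) {
    hit <- table@invIndex[[k]]
    if (!is.null(hit)) counts[hit] <- counts[hit] + 1L
  }
  lens <- lengths(table@sets)
  cand <- which(counts > 0L | lens + length(qset) <= maxK)
  disc <- length(qset) + lens[cand] - 2L * counts[cand]
  keep <- disc <= maxK
  list(idx = cand[keep], disc = disc[keep])
}

#' Query the lookup table with a predicted sentence
#'
#' Decodes the sentence to a key set and returns every entry within
#' `max_discrepancy` discrepant keys (symmetric-difference size), sorted by
#' ascending discrepancy (ties keep table order). An exact sentence match
#' has discrepancy 0.
#'
#' @param table a [LookupTable].
#' @param sentence predicted sentence (space-joined tokens); must decode to
#'   a single molecule segment.
#' @param max_discrepancy maximum discrepant keys (default 4).
#' @param vocab the [KeyVocabulary] the table was built with.
#' @return data.frame with `smiles`, `discrepancy`, `sentence`.
#' @export
queryLookup <- function(table, sentence, vocab, max_discrepancy = 4L) {
  segs <- decodeSentence(sentence, vocab)
  if (length(segs) != 1L)
    stop("query sentence must describe a single molecule")
  hits <- .discrepancies(table, segs[[1L]], max_discrepancy)
  o <- order(hits$disc)
  data.frame(smiles = table@smiles[hits$idx][o],
             discrepancy = hits$disc[o],
             sentence = table@sentences[hits$idx][o],
             stringsAsFactors = FALSE)
}

#' Re-rank retrieval candidates with a circular fingerprint
#'
#' Molecules sharing one curated key set are indistinguishable to the
#' lookup; a higher-resolution circular (Morgan) fingerprint breaks the tie.
#' Candidates are ordered by descending Tanimoto similarity to the
#' reference; the sort is stable, so ties keep input order.
#'
#' @param candidates character vector of SMILES.
#' @param reference reference SMILES (at inference time typically the query
#'   product; in evaluation the true reactant).
#' @param radius,nbits circular-fingerprint parameters (defaults 2, 2048).
#' @return data.frame with `smiles` and `score`, best first.
#' @export
rerankCandidates <- function(candidates, reference, radius = 2L,
                             nbits = 2048L) {
  if (!length(candidates))
    return(data.frame(smiles = character(), score = numeric()))
  ref <- computeECFP(reference, radius, nbits)@sets[[1L]]
  fps <- computeECFP(candidates, radius, nbits)@sets
  score <- vapply(fps, function(s)
    suppressWarnings(tanimotoSimilarity(ref, s)), numeric(1))
  o <- order(-score)
  data.frame(smiles = candidates[o], score = score[o],
             stringsAsFactors = FALSE)
}

#' Cumulative retrieval success by discrepancy level
#'
#' For each prediction, measures how many discrepant keys separate it from
#' its true reactant's table entry, and reports the cumulative fraction of
#' predictions retrievable within k discrepant keys for k = 0..`maxK`.
#' Predictions whose true reactant is absent from the table are never
#' retrievable.
#'
#' @param table a [LookupTable].
#' @param predictedSentences character vector of predicted single-molecule
#'   sentences.
#' @param truths character vector of true reactant SMILES, aligned.
#' @param vocab the [KeyVocabulary].
#' @param maxK largest discrepancy level reported.
#' @return data.frame with `k`, `n_retrievable`, `success_pct`
#'   (non-decreasing in k).
#' @export
retrievalSuccess <- function(table, predictedSentences, truths, vocab,
                             maxK = 4L) {
  stopifnot(length(predictedSentences) == length(truths))
  can <- canonicalSmiles(truths, onError = "na")
  pos <- match(can, table@smiles)
  disc <- rep(NA_integer_, length(truths))
  for (i in seq_along(truths)) {
    if (is.na(pos[i])) next
    q <- decodeSentence(predictedSentences[i], vocab)
    if (length(q) != 1L) next
    e <- table@sets[[pos[i]]]
    disc[i] <- length(setdiff(q[[1L]], e)) + length(setdiff(e, q[[1L]]))
  }
  k <- 0:maxK
  nr <- vapply(k, function(kk) sum(!is.na(disc) & disc <= kk), integer(1))
  data.frame(k = k, n_retrievable = nr,
             success_pct = 100 * nr / length(truths))
}
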