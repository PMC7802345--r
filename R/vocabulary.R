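# Key-occurrence profiling, dictionary curation, and the lettered-word
# vocabulary: frequency ranks over the reaction corpus, the 21 most frequent
# English letters in both cases for ranks 1-42, and "x"/"z" suffixes for the
# remaining 84 ranks, covering the default 126 curated MACCS keys.

# Standard English letter-frequency order, most frequent first.
.LETTER_ORDER <- c("E", "T", "A", "O", "I", "N", "S", "H", "R", "D", "L",
                   "C", "U", "M", "W", "F", "G", "Y", "P", "B", "V")

#' Profile key occurrences over a molecule corpus
#'
#' Counts, for every fingerprint key, in how many corpus molecules it is on.
#' Unparseable entries are skipped with a warning; the call fails only if no
#' entry parses.
#'
#' @param smiles character vector of SMILES.
#' @param backend `"MACCS"` or `"ECFP"`.
#' @param radius,nbits ECFP parameters (ignored for MACCS).
#' @return list of class `keyFrequencyProfile`: `counts` (named integer over
#'   all keys of the backend, MACCS 1..166), `n_molecules`, `backend`,
#'   `skipped`.
#' @export
profileKeys <- function(smiles, backend = c("MACCS", "ECFP"), radius = 2L,
                        nbits = 2048L) {
  backend <- match.arg(backend)
  stopifnot(length(smiles) > 0L)
  sets <- vector("list", length(smiles))
  ok <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    ks <- try(if (backend == "MACCS") computeMACCS(smiles[i])
              else computeECFP(smiles[i], radius, nbits), silent = TRUE)
    if (inherits(ks, "try-error")) next
    sets[[i]] <- ks@sets[[1L]]
    ok[i] <- TRUE
  }
  if (!any(ok)) stop("no corpus entry could be parsed")
  if (any(!ok))
    warning(sprintf("skipped %d unparseable entr%s", sum(!ok),
                    if (sum(!ok) == 1L) "y" else "ies"))
  keySpace <- if (backend == "MACCS") 1:166 else 0:(nbits - 1L)
  counts <- tabulate(match(unlist(sets[ok]), keySpace), length(keySpace))
  names(counts) <- keySpace
  structure(list(counts = counts, n_molecules = sum(ok), backend = backend,
                 skipped = sum(!ok)),
            class = "keyFrequencyProfile")
}

#' Normalized key frequencies of a profile
#' @param profile a `keyFrequencyProfile` from [profileKeys()].
#' @return named numeric in `[0,1]` (count / n_molecules).
#' @export
keyFrequencies <- function(profile) {
  profile$counts / profile$n_molecules
}

#' Curate the key dictionary by occurrence thresholds
#'
#' Drops keys that never occur in the primary (reaction) corpus, keys whose
#' primary normalized frequency falls below `rare_primary`, and keys whose
#' normalized frequency in the reference (drug-like) corpus falls below
#' `rare_reference`. Survivors are returned in ascending key order. An
#' explicit `keep` list bypasses all thresholding.
#'
#' @param primary key profile of the reaction corpus.
#' @param reference key profile of the reference molecule corpus (optional;
#'   when `NULL` only the primary criteria apply).
#' @param rare_primary,rare_reference frequency cutoffs in `[0,1]`.
#' @param keep optional explicit integer vector of key indices to retain.
#' @return integer vector of retained key indices, ascending.
#' @export
curateKeys <- function(primary, reference = NULL, rare_primary = 1e-4,
                       rare_reference = 1e-4, keep = NULL) {
  if (!is.null(keep)) {
    keep <- as.integer(keep)
    if (anyDuplicated(keep)) stop("explicit key list contains duplicates")
    return(sort(keep))
  }
  if (rare_primary < 0 || rare_primary > 1 ||
      rare_reference < 0 || rare_reference > 1)
    stop("curation thresholds must lie in [0, 1]")
  if (!is.null(reference) && !identical(primary$backend, reference$backend))
    stop("profiles must share a backend")
  fp <- keyFrequencies(primary)
  ok <- primary$counts > 0L & fp >= rare_primary
  if (!is.null(reference)) {
    fr <- keyFrequencies(reference)[names(fp)]
    ok <- ok & !is.na(fr) & fr >= rare_reference
  }
  sort(as.integer(names(fp)[ok]))
}

# Lettered words for ranks 1..126: 21 uppercase, 21 lowercase, then the same
# 42 suffixed "x" (ranks 43-84) and "z" (ranks 85-126).
.letteredWords <- function(n) {
  base <- c(.LETTER_ORDER, tolower(.LETTER_ORDER))
  words <- c(base, paste0(base, "x"), paste0(base, "z"))
  if (n > length(words)) stop("lettered scheme covers at most 126 words")
  words[seq_len(n)]
}

#' Build the rank-ordered lettered vocabulary
#'
#' Ranks the retained keys by their primary-corpus frequency (rank 1 = most
#' frequent; ties broken by ascending key index) and assigns each a word:
#' the 21 most frequent English letters in upper case for ranks 1-21, lower
#' case for 22-42, the same 42 letters suffixed "x" for 43-84 and "z" for
#' 85-126. More than 126 retained keys fall back to `w<rank>` words.
#'
#' @param retained integer vector of retained key indices.
#' @param profile the primary `keyFrequencyProfile` used for ranking.
#' @param thresholds optional list recorded for provenance.
#' @return a [KeyVocabulary].
#' @export
buildVocabulary <- function(retained, profile, thresholds = list()) {
  retained <- as.integer(retained)
  if (anyDuplicated(retained)) stop("duplicate keys in retained list")
  retained <- sort(retained)
  counts <- profile$counts[as.character(retained)]
  if (anyNA(counts)) stop("retained key missing from the frequency profile")
  ord <- order(-counts, retained)
  ranks <- integer(length(retained))
  ranks[ord] <- seq_along(retained)
  names(ranks) <- as.character(retained)
  words <- if (length(retained) <= 126L) .letteredWords(length(retained))
           else paste0("w", seq_along(retained))
  wordByKey <- character(length(retained))
  wordByKey[ord] <- words
  names(wordByKey) <- as.character(retained)
  new("KeyVocabulary", backend = profile$backend, retainedKeys = retained,
      ranks = ranks, words = wordByKey,
      curation = c(thresholds, list(n_molecules = profile$n_molecules)))
}

#' Write / read a vocabulary as JSON
#'
#' The file has stable field and key order (backend, retained_keys, rank,
#' word, curation_thresholds), so rebuilding from the same profiles gives a
#' byte-identical file.
#'
#' @param vocab a [KeyVocabulary].
#' @param path file path.
#' @export
writeVocabulary <- function(vocab, path) {
  keys <- as.character(vocab@retainedKeys)
  obj <- list(backend = vocab@backend,
              retained_keys = vocab@retainedKeys,
              rank = as.list(stats::setNames(unname(vocab@ranks[keys]), keys)),
              word = as.list(stats::setNames(unname(vocab@words[keys]), keys)),
              curation_thresholds = vocab@curation)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname writeVocabulary
#' @export
readVocabulary <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  keys <- as.integer(x$retained_keys)
  new("KeyVocabulary", backend = x$backend, retainedKeys = keys,
      ranks = stats::setNames(as.integer(unlist(x$rank)), names(x$rank)),
      words = stats::setNames(as.character(unlist(x$word)), names(x$word)),
      curation = as.list(x$curation_thresholds))
}
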