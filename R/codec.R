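# Encode key sets as fragment sentences and decode sentences back to key
# sets. Encoding drops keys outside the curated dictionary (information loss
# by design) and orders words by ascending frequency rank; decoding inverts
# the word map and splits multi-molecule sentences at the separator.

#' Encode key sets as fragment sentences
#'
#' Keeps the intersection of each key set with the retained keys and writes
#' the corresponding words most-frequent-first (ascending rank). Keys
#' outside the curated dictionary are silently dropped.
#'
#' @param keysets a [KeySetList], or a single integer vector of key indices.
#' @param vocab a [KeyVocabulary] over the same backend.
#' @return character vector of space-joined sentences (one per key set); an
#'   empty intersection gives an empty string.
#' @export
encodeMolecule <- function(keysets, vocab) {
  sets <- if (is(keysets, "KeySetList")) {
    if (keysets@backend != vocab@backend)
      stop("key set backend does not match the vocabulary")
    keysets@sets
  } else list(as.integer(keysets))
  vapply(sets, function(s) {
    s <- s[s %in% vocab@retainedKeys]
    if (!length(s)) return("")
    r <- vocab@ranks[as.character(s)]
    paste(vocab@words[as.character(s)][order(r)], collapse = " ")
  }, character(1))
}

#' Decode a fragment sentence back to key set(s)
#'
#' Inverts the word mapping; the separator token splits a two-reactant
#' sentence into one key set per molecule. For any key set `k`,
#' `decodeSentence(encodeMolecule(k, v), v)` returns `k` intersected with
#' the retained keys. Duplicate words collapse (a key set is a set).
#'
#' @param sentence character scalar (space-joined) or character vector of
#'   tokens.
#' @param vocab a [KeyVocabulary].
#' @return list of sorted integer key vectors, one per molecule segment.
#' @export
decodeSentence <- function(sentence, vocab) {
  tok <- if (length(sentence) == 1L && (grepl(" ", sentence) ||
                                        !nzchar(sentence)))
    strsplit(sentence, " ", fixed = TRUE)[[1L]]
  else as.character(sentence)
  tok <- tok[nzchar(tok)]
  sep <- unname(specialTokens()["SEP"])
  keyByWord <- stats::setNames(as.integer(names(vocab@words)),
                               unname(vocab@words))
  segBreak <- cumsum(tok == sep)
  segs <- split(tok[tok != sep], segBreak[tok != sep])
  nSeg <- sum(tok == sep) + 1L
  out <- rep(list(integer()), nSeg)
  for (i in seq_along(segs)) {
    w <- segs[[i]]
    k <- keyByWord[w]
    if (anyNA(k))
      stop("unknown token(s) in sentence: ",
           paste(unique(w[is.na(k)]), collapse = ", "), call. = FALSE)
    out[[as.integer(names(segs)[i]) + 1L]] <- sort(unique(unname(k)))
  }
  out
}

#' Token length of sentences
#'
#' @param sentences character vector of space-joined sentences.
#' @return integer vector; the separator counts as one token, an empty
#'   string has length 0.
#' @export
sentenceLength <- function(sentences) {
  vapply(strsplit(sentences, " ", fixed = TRUE),
         function(t) sum(nzchar(t)), integer(1))
}
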