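#' @import methods
NULL

#' KeySetList: fingerprint key sets for a batch of molecules
#'
#' A `KeySetList` holds, for each molecule, the sorted indices of the on bits
#' of a structural fingerprint, together with the backend that produced them.
#' MACCS key sets use 1-based key numbers 1..166 (the undefined key 0 never
#' appears); ECFP key sets use 0-based folded bit indices in `[0, nbits)`.
#'
#' @slot sets list of sorted, duplicate-free integer vectors (one per molecule).
#' @slot backend `"MACCS"` or `"ECFP"`.
#' @slot radius integer; atom-environment radius (ECFP only, `NA` for MACCS).
#' @slot nbits integer; folded length (ECFP only, `NA` for MACCS).
#' @slot ids character; molecule identifiers (typically input SMILES).
#' @exportClass KeySetList
setClass("KeySetList",
  representation(sets = "list", backend = "character",
                 radius = "integer", nbits = "integer", ids = "character"),
  prototype(sets = list(), backend = "MACCS",
            radius = NA_integer_, nbits = NA_integer_, ids = character()))

setValidity("KeySetList", function(object) {
  if (!object@backend %in% c("MACCS", "ECFP"))
    return("backend must be 'MACCS' or 'ECFP'")
  if (length(object@ids) && length(object@ids) != length(object@sets))
    return("ids length must match number of key sets")
  lo <- if (object@backend == "MACCS") 1L else 0L
  hi <- if (object@backend == "MACCS") 166L else object@nbits - 1L
  for (s in object@sets) {
    if (!is.integer(s)) return("key sets must be integer vectors")
    if (anyDuplicated(s)) return("key indices must be unique")
    if (is.unsorted(s)) return("key indices must be sorted")
    if (length(s) && (min(s) < lo || max(s) > hi))
      return(sprintf("key index outside valid range [%d, %d]", lo, hi))
  }
  if (object@backend == "ECFP" &&
      (is.na(object@radius) || is.na(object@nbits)))
    return("ECFP key sets need radius and nbits")
  TRUE
})

#' KeyVocabulary: curated, rank-ordered lettered-word vocabulary
#'
#' Maps each retained fingerprint key to a frequency rank (1 = most frequent)
#' and a short lettered "word". With the default curation the vocabulary has
#' 126 words: 42 single letters (upper and lower case of the 21 most frequent
#' English letters) plus the same 42 suffixed with "x" (ranks 43-84) and "z"
#' (ranks 85-126).
#'
#' @slot backend fingerprint backend the vocabulary was built over.
#' @slot retainedKeys integer; curated key indices in ascending order.
#' @slot ranks named integer; key index -> rank (1 = most frequent).
#' @slot words named character; key index -> word (bijective).
#' @slot curation list; thresholds and profile provenance for reproducibility.
#' @exportClass KeyVocabulary
setClass("KeyVocabulary",
  representation(backend = "character", retainedKeys = "integer",
                 ranks = "integer", words = "character", curation = "list"))

setValidity("KeyVocabulary", function(object) {
  k <- object@retainedKeys
  if (is.unsorted(k, strictly = TRUE))
    return("retainedKeys must be strictly ascending")
  if (!identical(sort(as.integer(object@ranks)), seq_along(k)))
    return("ranks must be a permutation of 1..|retainedKeys|")
  if (!setequal(names(object@ranks), as.character(k)) ||
      !setequal(names(object@words), as.character(k)))
    return("ranks and words must be named by the retained keys")
  if (anyDuplicated(object@words))
    return("word mapping must be a bijection on retained keys")
  TRUE
})

#' ReactionCorpus: parsed and encoded product-reactant records
#'
#' Each record is one single-product reaction: the product SMILES, the
#' reactant SMILES (1 or 2 after curation), and the encoded source (product)
#' and target (reactant, separator-joined) sentences as space-delimited token
#' strings. A per-stage curation report records how many records each filter
#' removed, and telescopes exactly.
#'
#' @slot records data.frame with columns `product`, `reactants` (list column),
#'   `nReactants`, `src`, `tgt`.
#' @slot report list of named per-stage counts.
#' @exportClass ReactionCorpus
setClass("ReactionCorpus",
  representation(records = "data.frame", report = "list"),
  prototype(records = data.frame(), report = list()))

setValidity("ReactionCorpus", function(object) {
  need <- c("product", "reactants", "nReactants", "src", "tgt")
  if (nrow(object@records) && !all(need %in% names(object@records)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  TRUE
})

#' Seq2SeqModel: LSTM encoder-decoder with attention
#'
#' Weights live in a named list of matrices; the architecture (embedding
#' dimension, hidden width, layers, directionality, attention flavour) is in
#' `config`. Training history (per-epoch loss, learning rate, validation
#' similarity bands) accumulates in `trainLog`.
#'
#' @slot params named list of numeric matrices/vectors.
#' @slot config list; see [modelConfig()].
#' @slot vocabSize integer; token vocabulary size including specials.
#' @slot vocabHash character; hash of the vocabulary the model was built for.
#' @slot trainLog data.frame of per-epoch metrics.
#' @exportClass Seq2SeqModel
setClass("Seq2SeqModel",
  representation(params = "list", config = "list", vocabSize = "integer",
                 vocabHash = "character", trainLog = "data.frame"),
  prototype(trainLog = data.frame(), vocabHash = NA_character_))

#' LookupTable: fingerprint-to-molecule retrieval index
#'
#' One entry per canonical SMILES: the molecule's curated key set, its
#' sentence ("language representation"), and an inverted key -> entry index
#' used for near-miss search by discrepant-key count.
#'
#' @slot smiles character; canonical SMILES, unique.
#' @slot sets list of integer key sets (curated).
#' @slot sentences character; space-joined encoded sentences.
#' @slot invIndex list; key index (character) -> integer entry ids.
#' @slot vocabHash character; hash of the vocabulary used to encode entries.
#' @exportClass LookupTable
setClass("LookupTable",
  representation(smiles = "character", sets = "list", sentences = "character",
                 invIndex = "list", vocabHash = "character"))

#' EvalOutcome: per-record matched similarities and corpus summary
#'
#' @slot scores numeric in `[0,1]`; matched similarity per test record.
#' @slot assignments list of 2-column matrices (true index, predicted index).
#' @slot bands named integer; counts per similarity band.
#' @slot summary list with `exact_pct`, `bioactively_similar_pct`,
#'   `ge_085_pct`, `mean_score`, `n`.
#' @exportClass EvalOutcome
setClass("EvalOutcome",
  representation(scores = "numeric", assignments = "list",
                 bands = "integer", summary = "list"))

setMethod("show", "KeySetList", function(object) {
  cat(sprintf("KeySetList of %d molecule(s), backend %s", length(object@sets),
              object@backend))
  if (object@backend == "ECFP")
    cat(sprintf(" (radius %d, %d bits)", object@radius, object@nbits))
  cat("\n")
  n <- min(3L, length(object@sets))
  for (i in seq_len(n))
    cat(sprintf("  [%d] %d keys: %s%s\n", i, length(object@sets[[i]]),
                paste(utils::head(object@sets[[i]], 8L), collapse = " "),
                if (length(object@sets[[i]]) > 8L) " ..." else ""))
  if (length(object@sets) > n) cat("  ...\n")
})

setMethod("show", "KeyVocabulary", function(object) {
  cat(sprintf("KeyVocabulary: %d retained %s keys\n",
              length(object@retainedKeys), object@backend))
  r <- object@ranks[order(object@ranks)]
  top <- utils::head(names(r), 5L)
  cat("  top-ranked keys:",
      paste(sprintf("%s=%s", top, object@words[top]), collapse = " "), "\n")
})

setMethod("show", "ReactionCorpus", function(object) {
  cat(sprintf("ReactionCorpus: %d record(s)\n", nrow(object@records)))
  if (length(object@report))
    cat("  report:", paste(sprintf("%s=%s", names(object@report),
        unlist(object@report)), collapse = " "), "\n")
})

setMethod("show", "Seq2SeqModel", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf(
    "Seq2SeqModel: %d-layer %s encoder, hidden %d, %s attention, %d parameters\n",
    object@config$num_layers,
    if (object@config$bidirectional) "bidirectional" else "unidirectional",
    object@config$hidden_units, object@config$attention, np))
  if (nrow(object@trainLog))
    cat(sprintf("  trained %d epoch(s), last loss %.4f\n",
                max(object@trainLog$epoch),
                utils::tail(object@trainLog$loss, 1L)))
})

setMethod("show", "LookupTable", function(object) {
  cat(sprintf("LookupTable: %d entries\n", length(object@smiles)))
})

setMethod("show", "EvalOutcome", function(object) {
  s <- object@summary
  cat(sprintf(
    "EvalOutcome over %d record(s): exact %.1f%%, 0.85<Tc<1 %.1f%%, mean Tc %.3f\n",
    s$n, s$exact_pct, s$bioactively_similar_pct, s$mean_score))
})

#' @describeIn KeySetList number of molecules
#' @param x a `KeySetList`
#' @export
setMethod("length", "KeySetList", function(x) length(x@sets))

#' Extract key sets / entries
#' @param x a `KeySetList`
#' @param i index vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "KeySetList", function(x, i, j, ..., drop = TRUE) {
  initialize(x, sets = x@sets[i],
             ids = if (length(x@ids)) x@ids[i] else character())
})

#' Key indices of a KeySetList
#'
#' @param x a `KeySetList`
#' @return list of sorted integer vectors, one per molecule.
#' @export
keySets <- function(x) {
  stopifnot(is(x, "KeySetList"))
  x@sets
}

#' Fingerprint backend of an object
#' @param x a `KeySetList` or `KeyVocabulary`
#' @return `"MACCS"` or `"ECFP"`.
#' @export
fpBackend <- function(x) x@backend

#' Retained key indices of a vocabulary
#' @param vocab a `KeyVocabulary`
#' @export
retainedKeys <- function(vocab) vocab@retainedKeys

#' Key-to-word mapping of a vocabulary
#' @param vocab a `KeyVocabulary`
#' @return named character vector, names are key indices.
#' @export
keyWords <- function(vocab) vocab@words

#' Key frequency ranks of a vocabulary
#' @param vocab a `KeyVocabulary`
#' @return named integer vector, names are key indices; 1 = most frequent.
#' @export
keyRanks <- function(vocab) vocab@ranks

#' Curation report of a reaction corpus
#' @param corpus a `ReactionCorpus`
#' @return named list of per-stage record counts.
#' @export
curationReport <- function(corpus) corpus@report

#' Records of a reaction corpus
#' @param corpus a `ReactionCorpus`
#' @return data.frame with product, reactants, nReactants, src, tgt.
#' @export
reactionRecords <- function(corpus) corpus@records

#' Per-epoch training log of a model
#' @param model a `Seq2SeqModel`
#' @export
trainLog <- function(model) model@trainLog

#' Per-record matched similarity scores
#' @param outcome an `EvalOutcome`
#' @export
evalScores <- function(outcome) outcome@scores

#' Similarity-band histogram
#' @param outcome an `EvalOutcome`
#' @return named integer vector of band counts.
#' @export
evalBands <- function(outcome) outcome@bands

#' Corpus-level evaluation summary
#' @param outcome an `EvalOutcome`
#' @return list with `exact_pct`, `bioactively_similar_pct`, `ge_085_pct`,
#'   `mean_score`, `n`.
#' @export
evalSummary <- function(outcome) outcome@summary

# Special tokens shared across the package. SEP is the en dash the sentence
# files use between two reactants.
#' Special tokens of the fragment language
#'
#' @return named character vector with `PAD`, `SOS`, `EOS`, `SEP`. The four
#'   specials occupy the first four token ids of every model vocabulary.
#' @export
specialTokens <- function() {
  c(PAD = "<pad>", SOS = "<s>", EOS = "</s>", SEP = "–")
}
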