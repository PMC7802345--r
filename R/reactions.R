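# Reaction-SMILES parsing and the curation cascade that turns a raw corpus
# into aligned product -> reactant sentence pairs:
#   parse -> single-product -> encode -> dedupe -> internal twins ->
#   reactant count -> pair length -> injective collapse -> split.
# Every stage updates a telescoping report (counts removed per filter).

.emptyRecords <- function() {
  data.frame(product = character(), nProducts = integer(),
             reactants = I(list()), nReactants = integer(),
             src = character(), tgt = character(),
             stringsAsFactors = FALSE)
}

#' Parse a reaction-SMILES corpus
#'
#' Accepts `reactants>reagents>products` lines ("." separates molecules in a
#' field). Reagents are discarded; all components are canonicalized.
#' Malformed lines or lines with unparseable SMILES are skipped and logged
#' with their line number; multi-product records are kept but flagged so
#' [filterSingleProduct()] can drop them.
#'
#' @param lines character vector of reaction SMILES, or a file path when
#'   `file = TRUE`.
#' @param file read `lines` as a path.
#' @return a [ReactionCorpus] (records not yet encoded); the report carries
#'   `input`, `parsed` and `parse_failed`.
#' @examples
#' parseReactions("CCO.CC(=O)O>>CCOC(C)=O")
#' @export
parseReactions <- function(lines, file = FALSE) {
  if (file) lines <- readLines(lines, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- vector("list", length(lines))
  failed <- integer()
  for (i in seq_along(lines)) {
    fields <- strsplit(trimws(lines[i]), ">", fixed = TRUE)[[1L]]
    if (length(fields) != 3L || !nzchar(fields[1L]) || !nzchar(fields[3L])) {
      failed <- c(failed, i)
      next
    }
    reac <- strsplit(fields[1L], ".", fixed = TRUE)[[1L]]
    prod <- strsplit(fields[3L], ".", fixed = TRUE)[[1L]]
    reacCan <- canonicalSmiles(reac, onError = "na")
    prodCan <- canonicalSmiles(prod, onError = "na")
    if (anyNA(reacCan) || anyNA(prodCan) || !length(reacCan) ||
        !length(prodCan)) {
      failed <- c(failed, i)
      next
    }
    rows[[i]] <- data.frame(product = prodCan[1L],
                            nProducts = length(prodCan),
                            reactants = I(list(reacCan)),
                            nReactants = length(reacCan),
                            src = NA_character_, tgt = NA_character_,
                            stringsAsFactors = FALSE)
  }
  if (length(failed))
    message(sprintf("skipped %d malformed line(s): %s", length(failed),
                    paste(utils::head(failed, 10L), collapse = ", ")))
  rec <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rec)) rec <- .emptyRecords()
  new("ReactionCorpus", records = rec,
      report = list(input = length(lines), parsed = nrow(rec),
                    parse_failed = length(failed)))
}

#' Keep only single-product reactions
#'
#' @param corpus a [ReactionCorpus] from [parseReactions()].
#' @return the filtered corpus; the report gains `single_product_kept`.
#' @export
filterSingleProduct <- function(corpus) {
  keep <- corpus@records$nProducts == 1L
  corpus@records <- corpus@records[keep, , drop = FALSE]
  corpus@report$single_product_kept <- sum(keep)
  corpus
}

# Order reactant sentences by descending token length; ties lexicographic on
# the token sequence (token-wise string comparison).
.orderReactants <- function(sentences) {
  if (length(sentences) < 2L) return(seq_along(sentences))
  len <- sentenceLength(sentences)
  key <- vapply(strsplit(sentences, " ", fixed = TRUE),
                function(t) paste(t, collapse = "\x01"), character(1))
  order(-len, key, method = "radix")
}

#' Encode reaction records as sentence pairs
#'
#' Computes the product (source) and reactant (target) sentences with
#' [encodeMolecule()]. Multi-reactant targets are ordered by descending
#' sentence length and joined with the separator token.
#'
#' @param corpus a [ReactionCorpus].
#' @param vocab a [KeyVocabulary].
#' @return the corpus with `src`/`tgt` filled (reactant lists reordered to
#'   match the target sentence).
#' @export
encodeReactions <- function(corpus, vocab) {
  rec <- corpus@records
  if (!nrow(rec)) return(corpus)
  sep <- unname(specialTokens()["SEP"])
  uniq <- unique(c(rec$product, unlist(rec$reactants)))
  keysets <- computeMACCS(uniq)
  sentByS <- stats::setNames(encodeMolecule(keysets, vocab), uniq)
  rec$src <- unname(sentByS[rec$product])
  for (i in seq_len(nrow(rec))) {
    rs <- sentByS[rec$reactants[[i]]]
    o <- .orderReactants(unname(rs))
    rec$reactants[[i]] <- rec$reactants[[i]][o]
    rec$tgt[i] <- paste(unname(rs)[o], collapse = paste0(" ", sep, " "))
  }
  corpus@records <- rec
  corpus
}

#' Remove duplicated product-reactant pairs
#'
#' Identity is the encoded (source, target) sentence pair; the first
#' occurrence is kept.
#'
#' @param corpus an encoded [ReactionCorpus].
#' @export
dedupePairs <- function(corpus) {
  key <- paste(corpus@records$src, corpus@records$tgt, sep = "\x02")
  keep <- !duplicated(key)
  corpus@records <- corpus@records[keep, , drop = FALSE]
  corpus@report$duplicates_removed <- sum(!keep)
  corpus
}

#' Remove internal twins
#'
#' Internal twins are records whose product and reactant sentences are
#' identical token for token (separator included): the chemical change is
#' invisible at the resolution of the curated keys.
#'
#' @param corpus an encoded [ReactionCorpus].
#' @export
removeInternalTwins <- function(corpus) {
  twin <- corpus@records$src == corpus@records$tgt
  corpus@records <- corpus@records[!twin, , drop = FALSE]
  corpus@report$internal_twins_removed <- sum(twin)
  corpus
}

#' Drop reactions with too many reactants
#'
#' @param corpus a [ReactionCorpus].
#' @param max_reactants maximum reactant count kept (default 2).
#' @export
filterReactantCount <- function(corpus, max_reactants = 2L) {
  keep <- corpus@records$nReactants <= max_reactants
  corpus@records <- corpus@records[keep, , drop = FALSE]
  corpus@report$too_many_reactants_removed <- sum(!keep)
  corpus
}

#' Drop over-long sentence pairs
#'
#' The pair length is the token count of source plus target (the separator
#' counts as one token); pairs are kept when the length is at most
#' `max_len` (inclusive bound).
#'
#' @param corpus an encoded [ReactionCorpus].
#' @param max_len maximum pair length (default 100).
#' @export
filterPairLength <- function(corpus, max_len = 100L) {
  len <- sentenceLength(corpus@records$src) +
    sentenceLength(corpus@records$tgt)
  keep <- len <= max_len
  corpus@records <- corpus@records[keep, , drop = FALSE]
  corpus@report$too_long_removed <- sum(!keep)
  corpus
}

#' Collapse one-to-many product mappings to an injective map
#'
#' When one source sentence maps to several distinct target sentences, only
#' the record with the shortest target (fewest tokens; ties broken by the
#' lexicographically smallest token sequence) is kept, so the resulting
#' source -> target map is a function.
#'
#' @param corpus an encoded [ReactionCorpus].
#' @export
collapseInjective <- function(corpus) {
  rec <- corpus@records
  if (!nrow(rec)) {
    corpus@report$injective_collapsed <- 0L
    return(corpus)
  }
  len <- sentenceLength(rec$tgt)
  key <- vapply(strsplit(rec$tgt, " ", fixed = TRUE),
                function(t) paste(t, collapse = "\x01"), character(1))
  ord <- order(rec$src, len, key, method = "radix")
  keepFirst <- !duplicated(rec$src[ord])
  keep <- sort(ord[keepFirst])
  corpus@report$injective_collapsed <- nrow(rec) - length(keep)
  corpus@records <- rec[keep, , drop = FALSE]
  corpus
}

#' Run the full curation cascade
#'
#' Applies, in order: single-product filter, encoding, duplicate removal,
#' internal-twin removal, reactant-count filter, pair-length filter,
#' injective collapse. The report telescopes exactly:
#' `final = single_product_kept - removals - collapses`.
#'
#' @param corpus a parsed [ReactionCorpus].
#' @param vocab a [KeyVocabulary].
#' @param max_reactants,max_len filter parameters.
#' @return the curated, encoded corpus.
#' @export
curateReactions <- function(corpus, vocab, max_reactants = 2L,
                            max_len = 100L) {
  corpus <- filterSingleProduct(corpus)
  corpus <- encodeReactions(corpus, vocab)
  corpus <- dedupePairs(corpus)
  corpus <- removeInternalTwins(corpus)
  corpus <- filterReactantCount(corpus, max_reactants)
  corpus <- filterPairLength(corpus, max_len)
  corpus <- collapseInjective(corpus)
  corpus@report$final <- nrow(corpus@records)
  stopifnot(corpus@report$final ==
              corpus@report$single_product_kept -
              corpus@report$duplicates_removed -
              corpus@report$internal_twins_removed -
              corpus@report$too_many_reactants_removed -
              corpus@report$too_long_removed -
              corpus@report$injective_collapsed)
  corpus
}

#' Split a curated corpus into train/validation/test sets
#'
#' Seeded shuffle, 90/10 train/test; the validation set is 10% of the
#' training set, disjoint from it. The split is performed independently for
#' the single-reactant subset, the double-reactant subset, and the combined
#' corpus.
#'
#' @param corpus a curated [ReactionCorpus].
#' @param seed split seed.
#' @return nested list `(single|double|combined) x (train|val|test)` of
#'   record data frames.
#' @export
splitDataset <- function(corpus, seed = 1L) {
  rec <- corpus@records
  splitOne <- function(df) {
    n <- nrow(df)
    ord <- sample.int(n)
    nTest <- floor(n / 10)
    test <- ord[seq_len(nTest)]
    rest <- ord[setdiff(seq_len(n), seq_len(nTest))]
    nVal <- floor(length(rest) / 10)
    val <- rest[seq_len(nVal)]
    train <- rest[setdiff(seq_along(rest), seq_len(nVal))]
    list(train = df[train, , drop = FALSE], val = df[val, , drop = FALSE],
         test = df[test, , drop = FALSE])
  }
  set.seed(seed)
  single <- splitOne(rec[rec$nReactants == 1L, , drop = FALSE])
  double <- splitOne(rec[rec$nReactants == 2L, , drop = FALSE])
  combined <- splitOne(rec)
  list(single = single, double = double, combined = combined)
}

#' Write aligned sentence files and the curation report
#'
#' Writes `<prefix>-src.txt` / `<prefix>-tgt.txt` (one space-joined sentence
#' per line, aligned by line number) and `<prefix>-report.json`.
#'
#' @param corpus an encoded [ReactionCorpus] (or a record data.frame).
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
writeSentenceFiles <- function(corpus, dir, prefix = "corpus") {
  rec <- if (is(corpus, "ReactionCorpus")) corpus@records else corpus
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ps <- file.path(dir, paste0(prefix, "-src.txt"))
  pt <- file.path(dir, paste0(prefix, "-tgt.txt"))
  writeLines(rec$src, ps, useBytes = TRUE)
  writeLines(rec$tgt, pt, useBytes = TRUE)
  paths <- c(ps, pt)
  if (is(corpus, "ReactionCorpus") && length(corpus@report)) {
    pr <- file.path(dir, paste0(prefix, "-report.json"))
    writeLines(jsonlite::toJSON(corpus@report, auto_unbox = TRUE,
                                pretty = TRUE), pr)
    paths <- c(paths, pr)
  }
  invisible(paths)
}
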