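# Set-based similarity between fragment key sets, the combinatorial
# pair-matching rule for 1-2 reactant predictions, and corpus-level
# success-rate bands.

.asKeyVec <- function(x) {
  if (is(x, "KeySetList")) {
    if (length(x@sets) != 1L)
      stop("expected a single key set")
    x@sets[[1L]]
  } else as.integer(x)
}

.checkBackends <- function(r, p) {
  if (is(r, "KeySetList") && is(p, "KeySetList") && r@backend != p@backend)
    stop("key sets come from different fingerprint backends")
}

#' Tanimoto similarity between two key sets
#'
#' `|r intersect p| / (|r| + |p| - |r intersect p|)`. Identical non-empty
#' sets score 1; disjoint sets score 0. Two empty sets score 0 (with a
#' warning): an empty prediction carries no structural information.
#'
#' @param r,p integer key vectors (or single-molecule [KeySetList]s on the
#'   same backend).
#' @return similarity in `[0,1]`.
#' @examples
#' tanimotoSimilarity(c(1, 2, 3), c(2, 3, 4))  # 0.5
#' @export
tanimotoSimilarity <- function(r, p) {
  .checkBackends(r, p)
  r <- .asKeyVec(r); p <- .asKeyVec(p)
  i <- length(intersect(r, p))
  u <- length(r) + length(p) - i
  if (u == 0L) {
    warning("both key sets empty; similarity defined as 0")
    return(0)
  }
  i / u
}

#' Tversky index between two key sets
#'
#' `|r&p| / (|r&p| + alpha|r-p| + beta|p-r|)`; `alpha = beta = 1` recovers
#' Tanimoto, `alpha = beta = 0.5` the Sorensen-Dice coefficient.
#'
#' @inheritParams tanimotoSimilarity
#' @param alpha,beta non-negative weights on the two set differences.
#' @export
tverskySimilarity <- function(r, p, alpha = 1, beta = 1) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be non-negative")
  .checkBackends(r, p)
  r <- .asKeyVec(r); p <- .asKeyVec(p)
  i <- length(intersect(r, p))
  den <- i + alpha * length(setdiff(r, p)) + beta * length(setdiff(p, r))
  if (den == 0) {
    warning("both key sets empty; similarity defined as 0")
    return(0)
  }
  i / den
}

#' @rdname tverskySimilarity
#' @export
diceSimilarity <- function(r, p) tverskySimilarity(r, p, 0.5, 0.5)

.metricFun <- function(metric = c("tanimoto", "dice", "tversky"),
                       alpha = 1, beta = 1) {
  metric <- match.arg(metric)
  switch(metric,
         tanimoto = function(r, p) tanimotoSimilarity(r, p),
         dice = function(r, p) diceSimilarity(r, p),
         tversky = function(r, p) tverskySimilarity(r, p, alpha, beta))
}

#' Match predicted reactant sets against ground truth
#'
#' Implements the combinatorial pairing rule for one- and two-reactant
#' predictions: with two predictions against two truths, both bijective
#' assignments are evaluated and the one with the higher mean pair
#' similarity wins (the mean is returned, so an exact match requires both
#' pairs to be exact); with unequal counts every cross pair is evaluated and
#' the single best pair similarity is returned.
#'
#' @param truth,predicted lists of integer key vectors (1 or 2 each).
#' @param metric `"tanimoto"`, `"dice"` or `"tversky"`.
#' @param alpha,beta Tversky weights (used when `metric = "tversky"`).
#' @return list with `score` and `assignment` (2-column matrix of true /
#'   predicted indices).
#' @export
matchPairs <- function(truth, predicted, metric = "tanimoto",
                       alpha = 1, beta = 1) {
  if (!is.list(truth)) truth <- list(.asKeyVec(truth))
  if (!is.list(predicted)) predicted <- list(.asKeyVec(predicted))
  if (!length(truth) || !length(predicted))
    stop("truth and predicted reactant lists must be non-empty")
  if (length(truth) > 2L || length(predicted) > 2L)
    stop("the pairing rule is defined for 1 or 2 reactants per side")
  f <- .metricFun(metric, alpha, beta)
  sim <- function(a, b) suppressWarnings(f(truth[[a]], predicted[[b]]))
  if (length(truth) == 2L && length(predicted) == 2L) {
    straight <- (sim(1, 1) + sim(2, 2)) / 2
    crossed <- (sim(1, 2) + sim(2, 1)) / 2
    if (crossed > straight)
      list(score = crossed, assignment = cbind(true = 1:2, predicted = 2:1))
    else
      list(score = straight, assignment = cbind(true = 1:2, predicted = 1:2))
  } else {
    pairs <- expand.grid(true = seq_along(truth),
                         predicted = seq_along(predicted))
    s <- mapply(sim, pairs$true, pairs$predicted)
    b <- which.max(s)
    list(score = s[b],
         assignment = cbind(true = pairs$true[b],
                            predicted = pairs$predicted[b]))
  }
}

#' Similarity configuration for corpus evaluation
#'
#' @param metric similarity metric for pair matching.
#' @param alpha,beta Tversky weights.
#' @param bands strictly increasing inner thresholds in (0,1) delimiting the
#'   similarity histogram.
#' @return validated list of class `similarityConfig`.
#' @export
similarityConfig <- function(metric = c("tanimoto", "dice", "tversky"),
                             alpha = 1, beta = 1,
                             bands = c(0.50, 0.70, 0.85)) {
  metric <- match.arg(metric)
  if (any(diff(bands) <= 0) || any(bands <= 0) || any(bands >= 1))
    stop("bands must be strictly increasing within (0, 1)")
  structure(list(metric = metric, alpha = alpha, beta = beta, bands = bands),
            class = "similarityConfig")
}

#' Evaluate a prediction corpus
#'
#' Scores every (truth, prediction) record with [matchPairs()] and
#' aggregates: counts per similarity band (the top band is split into the
#' strict "bioactively similar" band `0.85 < Tc < 1` and exact matches
#' `Tc = 1`), the exact-match percentage, and the mean matched similarity.
#'
#' @param truths list of truth reactant lists (each a list of 1-2 integer
#'   key vectors).
#' @param predictions list of predicted reactant lists, aligned with
#'   `truths`.
#' @param config a [similarityConfig()].
#' @return an [EvalOutcome].
#' @export
corpusSuccess <- function(truths, predictions, config = similarityConfig()) {
  stopifnot(length(truths) == length(predictions))
  if (!length(truths)) stop("empty outcome list")
  res <- lapply(seq_along(truths), function(i)
    matchPairs(truths[[i]], predictions[[i]], config$metric, config$alpha,
               config$beta))
  scores <- vapply(res, `[[`, numeric(1), "score")
  out <- bandOutcome(scores, config)
  out@assignments <- lapply(res, `[[`, "assignment")
  out
}

#' Band histogram and summary from matched scores
#'
#' @param scores numeric vector of matched similarities in `[0,1]`.
#' @param config a [similarityConfig()].
#' @return an [EvalOutcome] (with empty assignments).
#' @export
bandOutcome <- function(scores, config = similarityConfig()) {
  b <- config$bands
  edges <- c(-Inf, b, 1)
  labs <- c(sprintf("<%.2f", b[1L]),
            sprintf("[%.2f,%.2f)", utils::head(b, -1L), utils::tail(b, -1L)),
            sprintf("(%.2f,1)", b[length(b)]), "=1")
  # the band right below the top threshold is closed at that threshold
  labs[length(b)] <- sub(")$", "]", labs[length(b)])
  counts <- integer(length(labs))
  # lower bands are [edge_i, edge_{i+1}); the top threshold closes its band
  # so every score falls in exactly one bin
  for (i in seq_len(length(b) - 1L))
    counts[i + 1L] <- sum(scores >= b[i] & scores < b[i + 1L])
  counts[1L] <- sum(scores < b[1L])
  counts[length(b) + 1L] <- sum(scores > b[length(b)] & scores < 1)
  counts[length(b) + 2L] <- sum(scores == 1)
  # scores exactly at the top threshold belong to the band below it
  counts[length(b)] <- counts[length(b)] + sum(scores == b[length(b)])
  names(counts) <- labs
  top <- b[length(b)]
  new("EvalOutcome", scores = scores, assignments = list(),
      bands = counts,
      summary = list(exact_pct = 100 * mean(scores == 1),
                     bioactively_similar_pct =
                       100 * mean(scores > top & scores < 1),
                     ge_085_pct = 100 * mean(scores >= top),
                     mean_score = mean(scores),
                     n = length(scores)))
}
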