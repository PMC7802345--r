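# Synthetic fixtures: a packaged drug-like molecule library, a fixture
# vocabulary over it, and a rule-based reaction generator whose "chemistry"
# is a deterministic transformation of curated key sets. The toy rules never
# inspect atoms -- exactly like the translation machinery they exercise --
# so a corpus generated here has the statistical structure the method
# assumes (trigger-conditioned substructural edits, 1-2 reactants, rank-
# ordered sentences) without any download.

# 25 scaffolds x 8 substituents = 200 small drug-like molecules. The
# substituent is appended to the scaffold's last written atom.
.SCAFFOLDS <- c(
  "c1ccccc1", "c1ccc2ccccc2c1", "c1ccncc1", "c1cncnc1", "c1ccc2[nH]ccc2c1",
  "c1ccoc1", "c1ccsc1", "c1ccc2ncccc2c1", "C1CCCCC1", "C1CCNCC1",
  "C1CCOC1", "C1CCNC1", "CC(C)", "CCCCC", "CC(=O)N",
  "CC(=O)O", "c1ccccc1O", "c1ccccc1N", "c1ccccc1C(=O)N", "C1CNCCN1",
  "OC1CCCCC1", "CC(N)C(=O)O", "c1ccc(F)cc1", "c1ccc(Cl)cc1", "COc1ccccc1")
.SUBSTITUENTS <- c("", "C", "CC", "O", "OC", "N", "Cl", "C#N")

#' The packaged drug-like molecule library
#'
#' 200 small molecules produced by decorating 25 scaffolds (aromatic,
#' heteroaromatic and aliphatic cores) with 8 substituents. All parse with
#' the toolkit.
#'
#' @return character vector of 200 SMILES.
#' @export
moleculeLibrary <- function() {
  as.vector(outer(.SCAFFOLDS, .SUBSTITUENTS, paste0))
}

#' Sample a molecule corpus
#'
#' Seeded sampling (with replacement) from [moleculeLibrary()].
#'
#' @param n corpus size.
#' @param seed RNG seed.
#' @return character vector of `n` SMILES.
#' @export
makeMoleculeCorpus <- function(n, seed = 1L) {
  set.seed(seed)
  sample(moleculeLibrary(), n, replace = TRUE)
}

#' Fixture vocabulary over the packaged library
#'
#' Profiles MACCS keys over the 200-molecule library and retains the (at
#' most) 126 most frequent non-zero keys, so the lettered-word scheme always
#' applies. Deterministic: no RNG involved.
#'
#' @param maxKeys retained-key cap (default 126).
#' @return a [KeyVocabulary].
#' @export
fixtureVocabulary <- function(maxKeys = 126L) {
  prof <- profileKeys(moleculeLibrary(), "MACCS")
  nz <- names(prof$counts)[prof$counts > 0L]
  ord <- nz[order(-prof$counts[nz], as.integer(nz))]
  keep <- sort(as.integer(utils::head(ord, maxKeys)))
  buildVocabulary(keep, prof, thresholds = list(scheme = "fixture-top126"))
}

#' Define a toy substructural reaction rule
#'
#' A rule fires on product key sets containing its `trigger` key (a `NA`
#' trigger marks the default rule) and transforms the set deterministically:
#' `drop` keys are removed, `add` keys inserted, `toggle` keys flipped
#' (guaranteeing the target differs from the source even when adds are
#' already present). Two-reactant rules split the transformed set: reactant
#' one takes the keys in `part`, reactant two the rest plus `extra`.
#'
#' @param id rule identifier.
#' @param trigger key index or `NA`.
#' @param drop,add,toggle integer key vectors.
#' @param split logical; produce two reactants.
#' @param part,extra split parameters (see above).
#' @return list of class `toyRule`.
#' @export
toyRule <- function(id, trigger = NA_integer_, drop = integer(),
                    add = integer(), toggle = integer(), split = FALSE,
                    part = integer(), extra = integer()) {
  structure(list(id = id, trigger = as.integer(trigger),
                 drop = as.integer(drop), add = as.integer(add),
                 toggle = as.integer(toggle), split = isTRUE(split),
                 part = as.integer(part), extra = as.integer(extra)),
            class = "toyRule")
}

#' Apply a toy rule to a product key set
#'
#' @param rule a [toyRule()].
#' @param keyset sorted integer vector (curated keys).
#' @return list of 1 or 2 reactant key sets.
#' @export
applyToyRule <- function(rule, keyset) {
  k <- setdiff(keyset, rule$drop)
  k <- union(k, rule$add)
  flip <- intersect(k, rule$toggle)
  k <- sort(union(setdiff(k, flip), setdiff(rule$toggle, keyset)))
  if (!rule$split) return(list(k))
  r1 <- sort(intersect(k, rule$part))
  r2 <- sort(union(setdiff(k, rule$part), rule$extra))
  list(r1, r2)
}

#' Pick the rule that fires on a key set
#'
#' Rules are tried in order; the first whose trigger key is present wins,
#' otherwise the default (`NA`-trigger) rule applies.
#'
#' @param rules list of [toyRule()]s (exactly one with `NA` trigger).
#' @param keyset integer key vector.
#' @return the selected rule.
#' @export
selectToyRule <- function(rules, keyset) {
  for (r in rules) if (!is.na(r$trigger) && r$trigger %in% keyset) return(r)
  for (r in rules) if (is.na(r$trigger)) return(r)
  stop("no default rule defined")
}

#' The default five toy rules over a vocabulary
#'
#' Four trigger-conditioned rules (one of them two-reactant) plus a default
#' toggle rule. Trigger ranks are chosen so each rule fires on a sizeable
#' share of the library; the two-reactant rule partitions the key set at a
#' rank threshold (a prefix/suffix split of the rank-ordered sentence),
#' which is the kind of fixed partition a substructure-level reaction
#' induces.
#'
#' @param vocab a [KeyVocabulary].
#' @return list of 5 [toyRule()]s.
#' @export
defaultToyRules <- function(vocab) {
  byRank <- function(r) {
    keys <- as.integer(names(vocab@ranks))
    keys[match(pmin(r, length(keys)), vocab@ranks)]
  }
  nk <- length(vocab@retainedKeys)
  part <- as.integer(names(vocab@ranks))[vocab@ranks <= round(nk * 0.12)]
  list(
    toyRule(1L, trigger = byRank(22L), drop = byRank(22L),
            add = byRank(round(nk * 0.55))),
    toyRule(2L, trigger = byRank(26L), drop = byRank(c(26L, 5L)),
            add = byRank(round(nk * 0.6))),
    toyRule(3L, trigger = byRank(12L), drop = byRank(12L),
            add = byRank(round(c(nk * 0.65, nk * 0.7)))),
    toyRule(4L, trigger = byRank(9L), drop = byRank(9L), split = TRUE,
            part = part, extra = byRank(round(nk * 0.75))),
    toyRule(5L, toggle = byRank(round(nk * 0.5)))
  )
}

# Encode reactant key sets as a separator-joined target sentence, reactants
# ordered by descending sentence length (ties lexicographic).
.encodeTarget <- function(sets, vocab) {
  s <- vapply(sets, function(k) encodeMolecule(k, vocab), character(1))
  sep <- unname(specialTokens()["SEP"])
  paste(s[.orderReactants(s)], collapse = paste0(" ", sep, " "))
}

#' Generate a rule-based synthetic reaction corpus
#'
#' Draws product key sets from the packaged library (with a few seeded key
#' toggles for diversity), applies the first firing rule, and encodes both
#' sides with the fixture vocabulary. Optional contamination plants known
#' numbers of duplicates, internal twins, 3-reactant records, over-long
#' pairs and injectivity violations, for exercising the curation cascade;
#' the planted counts are returned so reports can be checked exactly.
#'
#' @param n number of clean base records (distinct source sentences).
#' @param rules list of [toyRule()]s.
#' @param seed RNG seed.
#' @param vocab a [KeyVocabulary] (default [fixtureVocabulary()]).
#' @param dup_rate,twin_rate,multi_reactant_rate per-record contamination
#'   probabilities.
#' @param long_count,injective_violations planted record counts.
#' @param perturb maximum random key toggles applied to each product.
#' @return list with `corpus` (a [ReactionCorpus], encoded, uncurated),
#'   `labels` (rule id per base record), `products` / `reactants` (key-set
#'   lists for the base records) and `planted` counts.
#' @export
makeReactionCorpus <- function(n, rules = NULL, seed = 1L, vocab = NULL,
                               dup_rate = 0, twin_rate = 0,
                               multi_reactant_rate = 0, long_count = 0L,
                               injective_violations = 0L, perturb = 4L) {
  if (is.null(vocab)) vocab <- fixtureVocabulary()
  if (is.null(rules)) rules <- defaultToyRules(vocab)
  set.seed(seed)
  lib <- moleculeLibrary()
  libSets <- lapply(keySets(computeMACCS(lib)), function(s)
    s[s %in% vocab@retainedKeys])
  ret <- vocab@retainedKeys
  # perturbation toggles are frequency-weighted: corpus diversity lives
  # mostly in common substructures, as in real molecule collections
  keyFreq <- tabulate(match(unlist(libSets), ret), length(ret)) + 1L
  seen <- new.env(parent = emptyenv())
  rows <- list(); labels <- integer(); prods <- list(); reacts <- list()
  # balanced rule exposure: products are rejection-sampled so each rule
  # contributes a comparable share (the rule remains a deterministic
  # function of the product key set)
  ruleIds <- vapply(rules, `[[`, integer(1), "id")
  ruleCount <- stats::setNames(integer(length(ruleIds)),
                               as.character(ruleIds))
  ruleCap <- ceiling(1.2 * n / length(rules))
  tries <- 0L
  while (length(rows) < n && tries < 400L * n) {
    tries <- tries + 1L
    K <- libSets[[sample.int(length(libSets), 1L)]]
    nt <- sample.int(perturb + 1L, 1L) - 1L
    if (nt > 0L) {
      tog <- sample(ret, nt, prob = keyFreq)
      K <- sort(union(setdiff(K, tog), setdiff(tog, K)))
    }
    if (length(K) < 6L) next
    src <- encodeMolecule(K, vocab)
    if (!nzchar(src) || !is.null(seen[[src]])) next
    rule <- selectToyRule(rules, K)
    # soft cap; lifted when the remaining draws would otherwise stall
    if (ruleCount[[as.character(rule$id)]] >= ruleCap &&
        tries < 200L * n) next
    sets <- applyToyRule(rule, K)
    if (any(!vapply(sets, length, integer(1)))) next
    tgt <- .encodeTarget(sets, vocab)
    if (tgt == src) next
    if (sentenceLength(src) + sentenceLength(tgt) > 100L) next
    seen[[src]] <- TRUE
    rows[[length(rows) + 1L]] <- c(src = src, tgt = tgt,
                                   nR = length(sets))
    ruleCount[[as.character(rule$id)]] <-
      ruleCount[[as.character(rule$id)]] + 1L
    labels <- c(labels, rule$id)
    prods[[length(prods) + 1L]] <- K
    reacts[[length(reacts) + 1L]] <- sets
  }
  if (length(rows) < n)
    stop("could not generate the requested number of distinct records")
  base <- do.call(rbind, rows)
  df <- data.frame(product = sprintf("synthetic_p%04d", seq_len(n)),
                   nProducts = 1L,
                   reactants = I(rep(list(character()), n)),
                   nReactants = as.integer(base[, "nR"]),
                   src = base[, "src"], tgt = base[, "tgt"],
                   type = "base", rule = labels, stringsAsFactors = FALSE)
  planted <- list(duplicates = 0L, twins = 0L, multi_reactant = 0L,
                  too_long = 0L, injective = 0L)
  extra <- list()
  addRow <- function(src, tgt, nR, type) {
    extra[[length(extra) + 1L]] <<- data.frame(
      product = sprintf("synthetic_x%04d", length(extra) + 1L),
      nProducts = 1L, reactants = I(list(character())),
      nReactants = as.integer(nR), src = src, tgt = tgt, type = type,
      rule = NA_integer_, stringsAsFactors = FALSE)
  }
  if (dup_rate > 0) {
    which_dup <- which(stats::runif(n) < dup_rate)
    planted$duplicates <- length(which_dup)
    for (i in which_dup) addRow(df$src[i], df$tgt[i], df$nReactants[i], "dup")
  }
  if (twin_rate > 0) {
    nTwin <- sum(stats::runif(n) < twin_rate)
    made <- 0L; guard <- 0L
    while (made < nTwin && guard < 200L * nTwin) {
      guard <- guard + 1L
      K <- sort(sample(ret, sample(8:20, 1L)))
      s <- encodeMolecule(K, vocab)
      if (!nzchar(s) || !is.null(seen[[s]])) next
      seen[[s]] <- TRUE
      addRow(s, s, 1L, "twin")
      made <- made + 1L
    }
    planted$twins <- made
  }
  if (multi_reactant_rate > 0) {
    nMulti <- sum(stats::runif(n) < multi_reactant_rate)
    made <- 0L; guard <- 0L
    while (made < nMulti && guard < 200L * nMulti) {
      guard <- guard + 1L
      K <- sort(sample(ret, sample(12:24, 1L)))
      s <- encodeMolecule(K, vocab)
      if (!nzchar(s) || !is.null(seen[[s]])) next
      g <- vocab@ranks[as.character(K)] %% 3L
      parts <- split(K, g)
      if (length(parts) < 3L || any(!lengths(parts))) next
      t3 <- .encodeTarget(unname(parts), vocab)
      if (sentenceLength(s) + sentenceLength(t3) > 100L) next
      seen[[s]] <- TRUE
      addRow(s, t3, 3L, "multi")
      made <- made + 1L
    }
    planted$multi_reactant <- made
  }
  if (long_count > 0L) {
    made <- 0L; guard <- 0L
    while (made < long_count && guard < 500L * long_count) {
      guard <- guard + 1L
      K <- sort(sample(ret, min(length(ret), sample(52:60, 1L))))
      s <- encodeMolecule(K, vocab)
      if (!nzchar(s) || !is.null(seen[[s]])) next
      sets <- applyToyRule(selectToyRule(rules, K), K)
      if (any(!lengths(sets))) next
      t2 <- .encodeTarget(sets, vocab)
      if (t2 == s) next
      if (sentenceLength(s) + sentenceLength(t2) <= 100L) next
      seen[[s]] <- TRUE
      addRow(s, t2, length(sets), "long")
      made <- made + 1L
    }
    planted$too_long <- made
  }
  if (injective_violations > 0L) {
    idx <- sample.int(n, min(injective_violations, n))
    for (i in idx) {
      # a longer alternative target for an existing source
      kt <- utils::tail(reacts[[i]], 1L)[[1L]]
      ktBig <- sort(union(kt, setdiff(ret, kt)[seq_len(3L)]))
      alt <- .encodeTarget(c(utils::head(reacts[[i]], -1L), list(ktBig)),
                           vocab)
      if (alt == df$tgt[i] || alt == df$src[i]) next
      addRow(df$src[i], alt, df$nReactants[i], "inj")
      planted$injective <- planted$injective + 1L
    }
  }
  rec <- rbind(df, if (length(extra)) do.call(rbind, extra))
  rec <- rec[sample.int(nrow(rec)), , drop = FALSE]
  rownames(rec) <- NULL
  corpus <- new("ReactionCorpus",
                records = rec[, setdiff(names(rec), "type")],
                report = list(input = nrow(rec), parsed = nrow(rec),
                              single_product_kept = nrow(rec)))
  # records carry a `rule` column (NA for planted contamination)
  list(corpus = corpus, labels = labels, products = prods,
       reactants = reacts, planted = planted, vocab = vocab,
       types = rec$type)
}

#' Curate an already-encoded corpus
#'
#' Runs the post-encoding stages of the cascade (duplicates, internal
#' twins, reactant count, pair length, injective collapse) on a corpus
#' whose `src`/`tgt` sentences are already filled -- e.g. one produced by
#' [makeReactionCorpus()].
#'
#' @param corpus an encoded [ReactionCorpus].
#' @param max_reactants,max_len filter parameters.
#' @return the curated corpus with a telescoping report.
#' @export
curateEncoded <- function(corpus, max_reactants = 2L, max_len = 100L) {
  input <- nrow(corpus@records)
  corpus <- dedupePairs(corpus)
  corpus <- removeInternalTwins(corpus)
  corpus <- filterReactantCount(corpus, max_reactants)
  corpus <- filterPairLength(corpus, max_len)
  corpus <- collapseInjective(corpus)
  corpus@report$final <- nrow(corpus@records)
  stopifnot(corpus@report$final ==
              input - corpus@report$duplicates_removed -
              corpus@report$internal_twins_removed -
              corpus@report$too_many_reactants_removed -
              corpus@report$too_long_removed -
              corpus@report$injective_collapsed)
  corpus
}
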