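# Shared fixtures, built once per test run. The fixture vocabulary profiles
# the packaged 200-molecule library (a few seconds of toolkit work), so it
# is cached in the session.

.fixtureEnv <- new.env(parent = emptyenv())

fixtureVocab <- function() {
  if (is.null(.fixtureEnv$vocab)) .fixtureEnv$vocab <- fixtureVocabulary()
  .fixtureEnv$vocab
}

# A deterministic vocabulary over an arbitrary retained-key list with
# counts decreasing in key order (rank i = i-th smallest retained key).
syntheticVocab <- function(keys = 41:166) {
  keys <- sort(as.integer(keys))
  counts <- integer(166)
  names(counts) <- 1:166
  counts[as.character(keys)] <- rev(seq_along(keys)) * 10L
  prof <- structure(list(counts = counts, n_molecules = max(counts) + 1L,
                         backend = "MACCS", skipped = 0L),
                    class = "keyFrequencyProfile")
  buildVocabulary(keys, prof)
}

# Random MACCS-range key sets for property tests.
randomKeySets <- function(n, seed, maxKeys = 166L) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    sort(sample.int(maxKeys, sample(1:40, 1L))))
}

# A tiny trained-from-scratch model is expensive; tests that need one build
# their own with explicit small configs.
tinyModelConfig <- function(...) {
  args <- utils::modifyList(list(embedding_dim = 8L, hidden_units = 6L,
                                 num_layers = 1L, dropout = 0), list(...))
  do.call(modelConfig, args)
}
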