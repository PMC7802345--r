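# Encoder-decoder translator: configuration, parameter initialization,
# SGD training loop with gradient clipping and lr decay, greedy decoding.
# The numerical core (BPTT through the Bi-LSTM + Luong attention) lives in
# src/seq2seq.cpp; everything random is driven by the R RNG so runs are
# reproducible from a single seed.

#' Model architecture configuration
#'
#' Defaults mirror the reference architecture: 2 bidirectional LSTM layers
#' of 2000 hidden units, 126-dimensional embeddings, global Luong attention,
#' dropout 0.1. Toy models shrink `hidden_units`/`num_layers`.
#'
#' @param embedding_dim dense word-vector dimension.
#' @param hidden_units LSTM hidden width per direction.
#' @param num_layers stacked LSTM layers (encoder and decoder).
#' @param bidirectional use a bidirectional encoder.
#' @param attention `"global"` (attend all source positions) or `"local"`
#'   (Luong predictive alignment with a Gaussian-weighted window).
#' @param local_window half-width D of the local attention window.
#' @param dropout inter-layer dropout fraction in `[0,1)`.
#' @param input_feed feed the attentional state into the next decoder step
#'   (Luong's input-feeding extension; off by default, matching the base
#'   global-attention model).
#' @return validated list of class `modelConfig`.
#' @export
modelConfig <- function(embedding_dim = 126L, hidden_units = 2000L,
                        num_layers = 2L, bidirectional = TRUE,
                        attention = c("global", "local"), local_window = 10L,
                        dropout = 0.1, input_feed = FALSE) {
  attention <- match.arg(attention)
  stopifnot(embedding_dim >= 1, hidden_units >= 1, num_layers >= 1,
            local_window >= 1, dropout >= 0, dropout < 1)
  structure(list(embedding_dim = as.integer(embedding_dim),
                 hidden_units = as.integer(hidden_units),
                 num_layers = as.integer(num_layers),
                 bidirectional = isTRUE(bidirectional),
                 attention = attention,
                 local_window = as.integer(local_window),
                 dropout = as.numeric(dropout),
                 input_feed = isTRUE(input_feed)),
            class = "modelConfig")
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: plain SGD with initial
#' learning rate 4.0 decayed by 0.85 every three epochs, gradient-norm
#' clipping at 0.25, batch size 64, at least 30 epochs.
#'
#' @param lr initial learning rate.
#' @param lr_decay multiplicative decay factor.
#' @param decay_every epochs between decays.
#' @param clip_norm global gradient-norm ceiling.
#' @param batch_size sentences per SGD step.
#' @param min_epochs minimum epochs to train.
#' @param epochs epochs to run (defaults to `min_epochs`).
#' @param seed RNG seed controlling init order, shuffling and dropout.
#' @return validated list of class `trainConfig`.
#' @export
trainConfig <- function(lr = 4.0, lr_decay = 0.85, decay_every = 3L,
                        clip_norm = 0.25, batch_size = 64L, min_epochs = 30L,
                        epochs = min_epochs, seed = 1L) {
  stopifnot(lr > 0, lr_decay > 0, lr_decay <= 1, decay_every >= 1,
            clip_norm > 0, batch_size >= 1, epochs >= 1)
  structure(list(lr = lr, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every),
                 clip_norm = clip_norm, batch_size = as.integer(batch_size),
                 min_epochs = as.integer(min_epochs),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "trainConfig")
}

#' Learning rate at a given epoch
#'
#' `lr * lr_decay^floor((epoch - 1) / decay_every)`: with the defaults,
#' epochs 1-3 run at 4.0 and epoch 4 at 4.0 x 0.85.
#'
#' @param tc a [trainConfig()].
#' @param epoch epoch number (1-based).
#' @export
learningRate <- function(tc, epoch) {
  tc$lr * tc$lr_decay^floor((epoch - 1) / tc$decay_every)
}

#' Ordered model token table of a vocabulary
#'
#' The four special tokens (PAD, SOS, EOS, separator) followed by the
#' lettered words in rank order; a model built for this vocabulary has
#' `length(tokenTable(vocab))` token ids.
#'
#' @param vocab a [KeyVocabulary].
#' @return character vector of tokens in id order.
#' @export
tokenTable <- function(vocab) {
  sp <- specialTokens()
  w <- vocab@words[order(vocab@ranks[names(vocab@words)])]
  c(unname(sp), unname(w))
}

.tokenTable <- tokenTable

.vocabHash <- function(vocab) {
  as.character(fnvHash(paste(vocab@backend,
                             paste(vocab@retainedKeys, collapse = ","),
                             paste(.tokenTable(vocab), collapse = " "),
                             sep = "|")))
}

.initMat <- function(nr, nc, scale = 0.08) {
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

#' Build a sequence-to-sequence translation model
#'
#' Initializes all weights uniformly in (-0.08, 0.08) from the current R RNG
#' state (`set.seed()` before calling for reproducible builds). The encoder
#' final states are bridged to the decoder initial states through a learned
#' tanh projection per layer.
#'
#' @param vocabSize token vocabulary size including the four specials
#'   (PAD, SOS, EOS, SEP), which occupy the first four ids.
#' @param config a [modelConfig()].
#' @param vocab optional [KeyVocabulary]; records its hash so checkpoints and
#'   corpora can be cross-checked.
#' @return a [Seq2SeqModel].
#' @examples
#' set.seed(1)
#' m <- seq2seqModel(20L, modelConfig(embedding_dim = 8, hidden_units = 4,
#'                                    num_layers = 1))
#' nParameters(m)
#' @export
seq2seqModel <- function(vocabSize, config = modelConfig(), vocab = NULL) {
  vocabSize <- as.integer(vocabSize)
  if (vocabSize < 4L) stop("vocabSize must be >= 4 (special tokens included)")
  d <- config$embedding_dim; H <- config$hidden_units
  L <- config$num_layers; dirs <- if (config$bidirectional) 2L else 1L
  encDim <- H * dirs
  p <- list(E = .initMat(d, vocabSize))
  for (l in seq_len(L)) {
    inDim <- if (l == 1L) d else encDim
    for (dir in if (dirs == 2L) c("f", "b") else "f") {
      p[[sprintf("encW_%d_%s", l, dir)]] <- .initMat(4L * H, inDim)
      p[[sprintf("encU_%d_%s", l, dir)]] <- .initMat(4L * H, H)
      p[[sprintf("encb_%d_%s", l, dir)]] <- stats::runif(4L * H, -0.08, 0.08)
    }
    p[[sprintf("brh_%d", l)]] <- .initMat(H, encDim)
    p[[sprintf("brc_%d", l)]] <- .initMat(H, encDim)
    # with input feeding the decoder's first layer sees the embedding
    # concatenated with the previous step's attentional state
    inDec <- if (l == 1L) d + (if (isTRUE(config$input_feed)) H else 0L)
             else H
    p[[sprintf("decW_%d", l)]] <- .initMat(4L * H, inDec)
    p[[sprintf("decU_%d", l)]] <- .initMat(4L * H, H)
    p[[sprintf("decb_%d", l)]] <- stats::runif(4L * H, -0.08, 0.08)
  }
  p$Wa <- .initMat(H, encDim)
  p$Wc <- .initMat(H, encDim + H)
  p$bc <- stats::runif(H, -0.08, 0.08)
  p$Wo <- .initMat(vocabSize, H)
  p$bo <- stats::runif(vocabSize, -0.08, 0.08)
  if (config$attention == "local") {
    p$Wp <- .initMat(H, H)
    p$vp <- stats::runif(H, -0.08, 0.08)
  }
  new("Seq2SeqModel", params = p, config = unclass(config),
      vocabSize = vocabSize,
      vocabHash = if (is.null(vocab)) NA_character_ else .vocabHash(vocab))
}

#' Number of trainable parameters
#' @param model a [Seq2SeqModel].
#' @export
nParameters <- function(model) {
  sum(vapply(model@params, length, integer(1)))
}

.cppConfig <- function(model) {
  c(model@config, list(vocab_size = model@vocabSize))
}

# Sentences (space-joined token strings) -> list of 0-based id vectors.
.sentenceIds <- function(sentences, tokenTable) {
  lapply(strsplit(sentences, " ", fixed = TRUE), function(tok) {
    tok <- tok[nzchar(tok)]
    id <- match(tok, tokenTable)
    if (anyNA(id))
      stop("unknown token(s): ", paste(unique(tok[is.na(id)]), collapse = ", "),
           call. = FALSE)
    as.integer(id - 1L)
  })
}

# Pad a list of id vectors into a time-major matrix (PAD = 0), appending EOS
# when asked (targets carry EOS; sources do not).
.padBatch <- function(ids, appendEOS = FALSE) {
  if (appendEOS) ids <- lapply(ids, function(v) c(v, 2L))
  len <- vapply(ids, length, integer(1))
  Tm <- max(len, 1L)
  m <- matrix(0L, Tm, length(ids))
  for (b in seq_along(ids)) if (len[b]) m[seq_len(len[b]), b] <- ids[[b]]
  list(mat = m, len = len)
}

#' Train a model with SGD, clipping and lr decay
#'
#' Teacher-forced cross-entropy training. Each epoch the corpus is
#' reshuffled (seeded), the scheduled learning rate is applied, every
#' gradient is clipped to `clip_norm` by global L2 norm, and -- when a
#' validation set and vocabulary are supplied -- the validation sentences
#' are greedily decoded and scored with the matched Tanimoto rule, giving
#' the per-epoch similarity bands of the training log.
#'
#' @param model a [Seq2SeqModel].
#' @param src,tgt character vectors of aligned source/target sentences
#'   (space-joined tokens).
#' @param tconf a [trainConfig()].
#' @param vocab a [KeyVocabulary] (required for validation scoring).
#' @param valSrc,valTgt optional validation sentences.
#' @param checkpointDir optional directory; per-epoch checkpoints are saved
#'   there and `best.rds` tracks the best validation mean similarity.
#' @param verbose print one line per epoch.
#' @return the trained [Seq2SeqModel] with `trainLog` filled.
#' @export
trainSeq2Seq <- function(model, src, tgt, tconf = trainConfig(),
                         vocab = NULL, valSrc = NULL, valTgt = NULL,
                         checkpointDir = NULL, verbose = FALSE) {
  stopifnot(is(model, "Seq2SeqModel"), length(src) == length(tgt))
  if (length(src) == 0L) stop("empty training corpus")
  tokenTable <- if (!is.null(vocab)) .tokenTable(vocab) else NULL
  if (!is.null(tokenTable) && length(tokenTable) != model@vocabSize)
    stop("vocabulary size does not match the model")
  ids <- function(x) {
    if (!is.null(tokenTable)) .sentenceIds(x, tokenTable)
    else lapply(strsplit(x, " ", fixed = TRUE),
                function(v) as.integer(v[nzchar(v)]))
  }
  srcIds <- ids(src); tgtIds <- ids(tgt)
  maxId <- max(unlist(c(srcIds, tgtIds)), 3L)
  if (maxId >= model@vocabSize) stop("token id outside model vocabulary")
  cfg <- .cppConfig(model)
  params <- model@params
  set.seed(tconf$seed)
  n <- length(srcIds)
  log <- list()
  bestVal <- -Inf
  srcLenAll <- lengths(srcIds)
  for (epoch in seq_len(tconf$epochs)) {
    lr <- learningRate(tconf, epoch)
    # shuffle, then sort by source length inside pools of 8 batches so
    # batches stay homogeneous in length (less padding) but remain random
    ord <- sample.int(n)
    pool <- 8L * tconf$batch_size
    ord <- unlist(lapply(split(ord, ceiling(seq_along(ord) / pool)),
                         function(ix) ix[order(srcLenAll[ix])]),
                  use.names = FALSE)
    starts <- seq(1L, n, by = tconf$batch_size)
    starts <- starts[sample.int(length(starts))]
    epochLoss <- 0; epochTok <- 0
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + tconf$batch_size - 1L, n)]
      sb <- .padBatch(srcIds[idx], appendEOS = FALSE)
      tb <- .padBatch(tgtIds[idx], appendEOS = TRUE)
      res <- cppS2SLossGrad(params, cfg, sb$mat, sb$len, tb$mat, tb$len,
                            TRUE, TRUE, sample.int(.Machine$integer.max, 1L))
      g <- res$grads
      gnorm <- sqrt(sum(vapply(g, function(x) sum(x^2), numeric(1))))
      scale <- if (gnorm > tconf$clip_norm) tconf$clip_norm / gnorm else 1.0
      for (nm in names(g)) params[[nm]] <- params[[nm]] - lr * scale * g[[nm]]
      epochLoss <- epochLoss + res$loss * res$ntokens
      epochTok <- epochTok + res$ntokens
    }
    row <- data.frame(epoch = epoch, lr = lr, loss = epochLoss / epochTok,
                      val_exact_pct = NA_real_, val_mean_score = NA_real_,
                      val_ge085_pct = NA_real_)
    if (!is.null(valSrc) && length(valSrc) && !is.null(vocab)) {
      model@params <- params
      pred <- translateSentences(model, valSrc, vocab = vocab)
      sc <- vapply(seq_along(valSrc), function(i) {
        ts <- decodeSentence(strsplit(valTgt[i], " ")[[1L]], vocab)
        ps <- decodeSentence(strsplit(pred[i], " ")[[1L]], vocab)
        if (!length(ps) || all(!vapply(ps, length, integer(1)))) return(0)
        matchPairs(ts, ps)$score
      }, numeric(1))
      row$val_exact_pct <- 100 * mean(sc == 1)
      row$val_mean_score <- mean(sc)
      row$val_ge085_pct <- 100 * mean(sc >= 0.85)
      if (!is.null(checkpointDir)) {
        dir.create(checkpointDir, showWarnings = FALSE, recursive = TRUE)
        model@trainLog <- do.call(rbind, c(log, list(row)))
        saveCheckpoint(model, file.path(checkpointDir,
                                        sprintf("epoch_%03d.rds", epoch)))
        if (row$val_mean_score > bestVal) {
          bestVal <- row$val_mean_score
          saveCheckpoint(model, file.path(checkpointDir, "best.rds"))
        }
      }
    } else if (!is.null(checkpointDir)) {
      dir.create(checkpointDir, showWarnings = FALSE, recursive = TRUE)
      model@params <- params
      saveCheckpoint(model, file.path(checkpointDir,
                                      sprintf("epoch_%03d.rds", epoch)))
    }
    log[[epoch]] <- row
    if (verbose)
      message(sprintf("epoch %d: lr %.3f loss %.4f%s", epoch, lr, row$loss,
                      if (!is.na(row$val_exact_pct))
                        sprintf(" val-exact %.1f%%", row$val_exact_pct)
                      else ""))
  }
  model@params <- params
  model@trainLog <- do.call(rbind, log)
  model
}

#' Teacher-forced cross-entropy on a corpus (no parameter update)
#'
#' @inheritParams trainSeq2Seq
#' @return mean per-token cross-entropy.
#' @export
sequenceLoss <- function(model, src, tgt, vocab = NULL) {
  tokenTable <- if (!is.null(vocab)) .tokenTable(vocab) else NULL
  ids <- function(x) {
    if (!is.null(tokenTable)) .sentenceIds(x, tokenTable)
    else lapply(strsplit(x, " ", fixed = TRUE),
                function(v) as.integer(v[nzchar(v)]))
  }
  sb <- .padBatch(ids(src), FALSE)
  tb <- .padBatch(ids(tgt), TRUE)
  cppS2SLossGrad(model@params, .cppConfig(model), sb$mat, sb$len, tb$mat,
                 tb$len, FALSE, FALSE, 0L)$loss
}

#' Translate source sentences by greedy decoding
#'
#' Decodes each sentence with argmax token selection until EOS or `maxLen`
#' tokens; the decoder is deterministic for fixed weights. A prediction may
#' contain at most one reactant separator: everything from a second
#' separator on is truncated.
#'
#' @param model a trained [Seq2SeqModel].
#' @param sentences character vector of source sentences.
#' @param vocab the [KeyVocabulary] the sentences are written in.
#' @param maxLen decode length cap.
#' @return character vector of predicted target sentences.
#' @export
translateSentences <- function(model, sentences, vocab, maxLen = 102L) {
  tokenTable <- .tokenTable(vocab)
  if (length(tokenTable) != model@vocabSize)
    stop("vocabulary size does not match the model")
  ids <- .sentenceIds(sentences, tokenTable)
  cfg <- .cppConfig(model)
  sep <- unname(specialTokens()["SEP"])
  vapply(ids, function(v) {
    if (!length(v)) return("")
    out <- cppS2SDecode(model@params, cfg, v, as.integer(maxLen), FALSE)
    tok <- tokenTable[out$tokens + 1L]
    sepPos <- which(tok == sep)
    if (length(sepPos) >= 2L) tok <- tok[seq_len(sepPos[2L] - 1L)]
    paste(tok, collapse = " ")
  }, character(1))
}

#' Attention context and weights for one decoder state
#'
#' Computes the Luong attention distribution of a single decoder hidden
#' state over a set of encoder states, using the model's attention
#' parameters. Weights are non-negative and sum to one over the attended
#' positions; global mode attends every source position, local mode a
#' Gaussian-weighted window of half-width `local_window` around a predicted
#' center.
#'
#' @param model a [Seq2SeqModel].
#' @param encStates numeric matrix, one column per source position
#'   (`hidden_units * directions` rows).
#' @param h numeric vector, the decoder top-layer hidden state.
#' @return list with `context` (numeric vector) and `weights`.
#' @export
attentionContext <- function(model, encStates, h) {
  stopifnot(is.matrix(encStates), ncol(encStates) >= 1L)
  res <- cppAttentionStep(encStates, as.numeric(h), model@params,
                          .cppConfig(model), ncol(encStates))
  list(context = as.numeric(res$context), weights = as.numeric(res$weights))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing list (architecture config, vocabulary
#' hash, weights, training log) written with `saveRDS`.
#'
#' @param model a [Seq2SeqModel].
#' @param path file path.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(config = model@config, vocabSize = model@vocabSize,
               vocabHash = model@vocabHash, params = model@params,
               trainLog = model@trainLog), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  new("Seq2SeqModel", params = x$params, config = x$config,
      vocabSize = as.integer(x$vocabSize), vocabHash = x$vocabHash,
      trainLog = x$trainLog)
}
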