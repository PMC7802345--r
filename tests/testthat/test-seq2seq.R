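# Model construction, attention contract, gradients, training mechanics,
# and greedy decoding.

test_that("model initialization is seeded and shaped by the config", {
  set.seed(5)
  m1 <- seq2seqModel(12L, tinyModelConfig())
  set.seed(5)
  m2 <- seq2seqModel(12L, tinyModelConfig())
  expect_identical(m1@params, m2@params)
  # unidirectional config has no reverse-direction parameters
  set.seed(5)
  uni <- seq2seqModel(12L, tinyModelConfig(bidirectional = FALSE))
  expect_false(any(grepl("_b$", names(uni@params))))
  expect_true(any(grepl("_b$", names(m1@params))))
  expect_error(seq2seqModel(3L), "vocabSize")
})

test_that("parameter count matches the closed-form formula", {
  V <- 10L; d <- 7L; H <- 8L
  encDim <- 2L * H
  base <- d * V +                                 # embedding
    2L * (4L * H * d + 4L * H * H + 4L * H) +     # encoder, two directions
    2L * (H * encDim) +                           # bridge h and c
    (4L * H * H + 4L * H) +                       # decoder U, b
    H * encDim +                                  # attention Wa
    H * (encDim + H) + H +                        # Wc, bc
    V * H + V                                     # output layer
  set.seed(1)
  m <- seq2seqModel(V, modelConfig(embedding_dim = d, hidden_units = H,
                                   num_layers = 1L, bidirectional = TRUE,
                                   dropout = 0))
  expect_identical(nParameters(m), base + 4L * H * d)
  # input feeding widens the decoder's first layer by H
  set.seed(1)
  mf <- seq2seqModel(V, modelConfig(embedding_dim = d, hidden_units = H,
                                    num_layers = 1L, bidirectional = TRUE,
                                    dropout = 0, input_feed = TRUE))
  expect_identical(nParameters(mf), base + 4L * H * (d + H))
})

test_that("attention weights form a masked probability distribution", {
  set.seed(3)
  m <- seq2seqModel(12L, tinyModelConfig())
  H <- m@config$hidden_units
  encDim <- 2L * H
  enc <- matrix(rnorm(encDim * 5), encDim, 5)
  h <- rnorm(H)
  at <- attentionContext(m, enc, h)
  expect_equal(sum(at$weights), 1, tolerance = 1e-6)
  expect_true(all(at$weights >= 0))
  expect_length(at$context, encDim)
  # single source position gets weight exactly 1
  at1 <- attentionContext(m, enc[, 1, drop = FALSE], h)
  expect_equal(at1$weights, 1)
  expect_equal(at1$context, enc[, 1], tolerance = 1e-12)
})

test_that("general-score attention reduces to dot-score softmax with Wa = I", {
  set.seed(4)
  m <- seq2seqModel(12L, modelConfig(embedding_dim = 8, hidden_units = 4,
                                     num_layers = 1, bidirectional = FALSE,
                                     dropout = 0))
  m@params$Wa <- diag(4)
  enc <- cbind(c(1, 0, 0, 0), c(0, 2, 0, 0), c(0.5, 0.5, 0, 0))
  h <- c(1, 1, 0, 0)
  at <- attentionContext(m, enc, h)
  scores <- as.numeric(t(enc) %*% h)       # dot scores by hand
  expect_equal(at$weights, exp(scores) / sum(exp(scores)), tolerance = 1e-12)
  expect_equal(at$context, as.numeric(enc %*% at$weights), tolerance = 1e-12)
})

test_that("local attention restricts and reweights the window", {
  set.seed(6)
  m <- seq2seqModel(12L, tinyModelConfig(attention = "local",
                                         local_window = 2))
  H <- m@config$hidden_units
  enc <- matrix(rnorm(2 * H * 9), 2 * H, 9)
  at <- attentionContext(m, enc, rnorm(H))
  expect_equal(sum(at$weights), 1, tolerance = 1e-6)
  # at most 2D+1 positions can carry weight
  expect_lte(sum(at$weights > 1e-12), 2 * 2 + 1)
})

test_that("analytic gradients match numerical differentiation", {
  for (cfg in list(tinyModelConfig(),
                   tinyModelConfig(bidirectional = FALSE),
                   tinyModelConfig(num_layers = 2),
                   tinyModelConfig(num_layers = 2, input_feed = TRUE),
                   tinyModelConfig(attention = "local", local_window = 2))) {
    set.seed(42)
    m <- seq2seqModel(9L, cfg)
    cc <- c(m@config, list(vocab_size = m@vocabSize))
    src <- matrix(c(4L, 5L, 6L, 7L, 5L, 6L, 0L, 0L), 4, 2)
    tgt <- matrix(c(6L, 5L, 4L, 2L, 7L, 2L, 0L, 0L), 4, 2)
    sl <- c(4L, 2L); tl <- c(4L, 2L)
    r <- fragretro:::cppS2SLossGrad(m@params, cc, src, sl, tgt, tl,
                                    FALSE, TRUE, 1L)
    eps <- 1e-5
    set.seed(7)
    for (nm in names(m@params)) {
      i <- sample(length(m@params[[nm]]), 1L)
      pp <- m@params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      lp <- fragretro:::cppS2SLossGrad(pp, cc, src, sl, tgt, tl,
                                       FALSE, FALSE, 1L)$loss
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      lm <- fragretro:::cppS2SLossGrad(pp, cc, src, sl, tgt, tl,
                                       FALSE, FALSE, 1L)$loss
      num <- (lp - lm) / (2 * eps)
      ana <- r$grads[[nm]][i]
      expect_lt(abs(num - ana), 1e-4 + 1e-3 * max(abs(num), abs(ana)))
    }
  }
})

test_that("one tiny SGD step tracks the first-order loss prediction", {
  set.seed(10)
  m <- seq2seqModel(9L, tinyModelConfig())
  cc <- c(m@config, list(vocab_size = m@vocabSize))
  src <- matrix(c(4L, 5L, 6L, 0L), 4, 1)
  tgt <- matrix(c(5L, 4L, 2L, 0L), 4, 1)
  r <- fragretro:::cppS2SLossGrad(m@params, cc, src, 3L, tgt, 3L,
                                  FALSE, TRUE, 1L)
  lr <- 1e-4
  g2 <- sum(vapply(r$grads, function(x) sum(x^2), numeric(1)))
  p2 <- m@params
  for (nm in names(r$grads)) p2[[nm]] <- p2[[nm]] - lr * r$grads[[nm]]
  l2 <- fragretro:::cppS2SLossGrad(p2, cc, src, 3L, tgt, 3L,
                                   FALSE, FALSE, 1L)$loss
  predicted <- r$loss - lr * g2
  expect_lt(abs(l2 - predicted), 1e-6 + 1e-3 * lr * g2)
})

test_that("the learning-rate schedule decays stepwise", {
  tc <- trainConfig()
  expect_identical(learningRate(tc, 1), 4.0)
  expect_identical(learningRate(tc, 3), 4.0)
  expect_identical(learningRate(tc, 4), 4.0 * 0.85)
  expect_identical(learningRate(tc, 7), 4.0 * 0.85^2)
  expect_error(trainConfig(lr = -1), "lr")
  expect_error(trainConfig(lr_decay = 0), "lr_decay")
})

test_that("a tiny model memorizes 20 pairs and decodes deterministically", {
  v <- syntheticVocab()
  set.seed(88)
  keysets <- lapply(1:20, function(i) sort(sample(retainedKeys(v), 10)))
  src <- vapply(keysets, function(k) encodeMolecule(k, v), character(1))
  tgt <- vapply(keysets, function(k)
    encodeMolecule(sort(c(setdiff(k, k[1]), 41L)), v), character(1))
  set.seed(11)
  m <- seq2seqModel(length(tokenTable(v)),
                    modelConfig(embedding_dim = 32, hidden_units = 64,
                                num_layers = 1, dropout = 0))
  m <- trainSeq2Seq(m, src, tgt,
                    trainConfig(lr = 2, lr_decay = 1, clip_norm = 5,
                                batch_size = 4, epochs = 150, seed = 5),
                    vocab = v)
  # loss stayed finite at every epoch (clipping prevents explosions)
  expect_true(all(is.finite(trainLog(m)$loss)))
  pred <- translateSentences(m, src, v)
  expect_identical(pred, tgt)
  # determinism: repeated decoding gives identical output
  expect_identical(translateSentences(m, src, v), pred)
  # length cap is honoured
  short <- translateSentences(m, src[1], v, maxLen = 3L)
  expect_lte(sentenceLength(short), 3L)
})

test_that("training rejects inconsistent inputs", {
  v <- syntheticVocab()
  set.seed(2)
  m <- seq2seqModel(length(tokenTable(v)), tinyModelConfig())
  expect_error(trainSeq2Seq(m, character(), character(), trainConfig()),
               "empty")
  expect_error(trainSeq2Seq(m, "E unknowntoken", "E",
                            trainConfig(epochs = 1), vocab = v),
               "unknown token")
  set.seed(2)
  small <- seq2seqModel(10L, tinyModelConfig())
  expect_error(trainSeq2Seq(small, "E", "T", trainConfig(epochs = 1),
                            vocab = v), "does not match|vocabulary")
})

test_that("checkpoints round-trip the model", {
  set.seed(14)
  m <- seq2seqModel(12L, tinyModelConfig())
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(m, f)
  m2 <- loadCheckpoint(f)
  expect_identical(m2@params, m@params)
  expect_identical(m2@config, m@config)
  expect_identical(m2@vocabSize, m@vocabSize)
})
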