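# End-to-end pipeline driver: curate -> encode -> train -> translate ->
# evaluate -> retrieve, with a run manifest (config + input hashes) and
# per-stage caching keyed on that manifest.

#' Assemble a pipeline run configuration
#'
#' @param workdir output directory for all artifacts.
#' @param reactions path to a reaction-SMILES file, or `NULL` to generate a
#'   synthetic corpus.
#' @param synthetic list of arguments for [makeReactionCorpus()] (used when
#'   `reactions` is `NULL`).
#' @param referenceMolecules optional SMILES file for the reference
#'   (drug-like) profile used in curation.
#' @param rare_primary,rare_reference curation thresholds.
#' @param keyList optional explicit retained-key list (bypasses curation).
#' @param model a [modelConfig()].
#' @param train a [trainConfig()].
#' @param similarity a [similarityConfig()].
#' @param lookup optional SMILES file to build a retrieval table from.
#' @param max_reactants,max_len curation-cascade parameters.
#' @param seed master seed (splits; training has its own seed).
#' @return list of class `runConfig`.
#' @export
runConfig <- function(workdir, reactions = NULL,
                      synthetic = list(n = 500L, seed = 7L),
                      referenceMolecules = NULL, rare_primary = 1e-4,
                      rare_reference = 1e-4, keyList = NULL,
                      model = modelConfig(), train = trainConfig(),
                      similarity = similarityConfig(), lookup = NULL,
                      max_reactants = 2L, max_len = 100L, seed = 1L) {
  structure(list(workdir = workdir, reactions = reactions,
                 synthetic = synthetic,
                 referenceMolecules = referenceMolecules,
                 rare_primary = rare_primary,
                 rare_reference = rare_reference, keyList = keyList,
                 model = unclass(model), train = unclass(train),
                 similarity = unclass(similarity), lookup = lookup,
                 max_reactants = max_reactants, max_len = max_len,
                 seed = as.integer(seed)),
            class = "runConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level fields mirror the arguments of [runConfig()]; `model`, `train`
#' and `similarity` are nested maps.
#'
#' @param path YAML file.
#' @return a `runConfig` list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n:` key as boolean FALSE; map it back
  if (!is.null(y$synthetic))
    names(y$synthetic)[names(y$synthetic) == "FALSE"] <- "n"
  args <- y[setdiff(names(y), c("model", "train", "similarity"))]
  if (!is.null(y$model)) args$model <- do.call(modelConfig, y$model)
  if (!is.null(y$train)) args$train <- do.call(trainConfig, y$train)
  if (!is.null(y$similarity))
    args$similarity <- do.call(similarityConfig, y$similarity)
  do.call(runConfig, args)
}

.configHash <- function(config) {
  as.character(fnvHash(jsonlite::toJSON(config, auto_unbox = TRUE,
                                        digits = NA, force = TRUE)))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full retrosynthesis pipeline
#'
#' Stages: corpus assembly (file or synthetic), vocabulary construction,
#' curation cascade, dataset split, model training, greedy translation of
#' the test set, matched-similarity evaluation, and (optionally) lookup
#' retrieval of the predictions. Every stage logs its record counts; all
#' artifacts plus a manifest (config hash and input hashes) land in
#' `config$workdir`. A rerun with an identical config and inputs reuses the
#' cached curated corpus and reproduces the manifest.
#'
#' @param config a [runConfig()] or path to a YAML file.
#' @param verbose log per-stage progress.
#' @return list with `vocab`, `corpus`, `split`, `model`, `predictions`,
#'   `evaluation` ([EvalOutcome]), `retrieval` (or `NULL`), `manifest`.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- readRunConfig(config)
  wd <- config$workdir
  dir.create(wd, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  inputHashes <- list()
  for (f in c(config$reactions, config$referenceMolecules, config$lookup))
    if (!is.null(f)) {
      if (!file.exists(f)) stop("missing input path: ", f, call. = FALSE)
      inputHashes[[f]] <- unname(tools::md5sum(f))
    }
  manifest <- list(config_hash = .configHash(config),
                   input_hashes = inputHashes, stages = list())
  manifestPath <- file.path(wd, "manifest.json")

  synth <- NULL
  if (is.null(config$reactions)) {
    say("stage corpus: generating synthetic reaction corpus")
    synth <- .stage("corpus", do.call(makeReactionCorpus, config$synthetic))
    vocab <- synth$vocab
    corpus <- synth$corpus
  } else {
    say("stage corpus: parsing %s", config$reactions)
    corpus <- .stage("corpus",
                     parseReactions(config$reactions, file = TRUE))
    vocab <- NULL
  }

  if (is.null(vocab)) {
    say("stage vocabulary: profiling and curating keys")
    vocab <- .stage("vocabulary", {
      mols <- unique(c(corpus@records$product,
                       unlist(corpus@records$reactants)))
      primary <- profileKeys(mols, "MACCS")
      reference <- if (!is.null(config$referenceMolecules))
        profileKeys(readLines(config$referenceMolecules, warn = FALSE),
                    "MACCS")
      retained <- curateKeys(primary, reference,
                             rare_primary = config$rare_primary,
                             rare_reference = config$rare_reference,
                             keep = config$keyList)
      buildVocabulary(retained, primary,
                      thresholds = list(
                        rare_primary = config$rare_primary,
                        rare_reference = config$rare_reference))
    })
  }
  writeVocabulary(vocab, file.path(wd, "vocabulary.json"))

  cacheKey <- manifest$config_hash
  cachePath <- file.path(wd, "curated.rds")
  cached <- NULL
  if (file.exists(cachePath)) {
    cached <- readRDS(cachePath)
    if (!identical(cached$key, cacheKey)) cached <- NULL
  }
  if (!is.null(cached)) {
    say("stage curate: reusing cached curated corpus")
    corpus <- cached$corpus
  } else {
    say("stage curate: running the curation cascade")
    corpus <- .stage("curate", {
      if (is.null(synth))
        curateReactions(corpus, vocab, config$max_reactants, config$max_len)
      else curateEncoded(corpus, config$max_reactants, config$max_len)
    })
    saveRDS(list(key = cacheKey, corpus = corpus), cachePath)
  }
  manifest$stages$curate <- corpus@report
  writeSentenceFiles(corpus, wd, "curated")

  say("stage split: %d curated records", nrow(corpus@records))
  split <- .stage("split", splitDataset(corpus, seed = config$seed))
  sets <- split$combined
  manifest$stages$split <- lapply(split, function(s)
    lapply(s, nrow))

  say("stage train: %d train / %d val / %d test", nrow(sets$train),
      nrow(sets$val), nrow(sets$test))
  model <- .stage("train", {
    set.seed(config$train$seed)
    m <- seq2seqModel(length(.tokenTable(vocab)),
                      structure(config$model, class = "modelConfig"),
                      vocab = vocab)
    trainSeq2Seq(m, sets$train$src, sets$train$tgt,
                 structure(config$train, class = "trainConfig"),
                 vocab = vocab, valSrc = sets$val$src,
                 valTgt = sets$val$tgt, verbose = verbose)
  })
  saveCheckpoint(model, file.path(wd, "model.rds"))
  utils::write.csv(model@trainLog, file.path(wd, "train_log.csv"),
                   row.names = FALSE)

  say("stage translate: decoding %d test sentences", nrow(sets$test))
  predictions <- .stage("translate",
                        translateSentences(model, sets$test$src, vocab))

  say("stage evaluate")
  evaluation <- .stage("evaluate", {
    truths <- lapply(sets$test$tgt, decodeSentence, vocab = vocab)
    preds <- lapply(predictions, function(p)
      if (nzchar(p)) decodeSentence(p, vocab) else list(integer()))
    corpusSuccess(truths, preds,
                  structure(config$similarity, class = "similarityConfig"))
  })
  writeEvalReport(evaluation, wd, "evaluation")

  retrieval <- NULL
  if (!is.null(config$lookup)) {
    say("stage retrieve")
    retrieval <- .stage("retrieve", {
      table <- buildLookup(readLines(config$lookup, warn = FALSE), vocab)
      firstSeg <- vapply(predictions, function(p) {
        tok <- strsplit(p, " ", fixed = TRUE)[[1L]]
        sep <- which(tok == unname(specialTokens()["SEP"]))
        paste(if (length(sep)) tok[seq_len(sep[1L] - 1L)] else tok,
              collapse = " ")
      }, character(1))
      keep <- nzchar(firstSeg)
      lapply(which(keep), function(i)
        queryLookup(table, firstSeg[i], vocab))
    })
  }

  manifest$stages$evaluation <- evaluation@summary
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             manifestPath)
  list(vocab = vocab, corpus = corpus, split = split, model = model,
       predictions = predictions, evaluation = evaluation,
       retrieval = retrieval, manifest = manifest)
}

#' Write an evaluation report (JSON summary + per-record CSV)
#'
#' @param outcome an [EvalOutcome].
#' @param dir output directory.
#' @param prefix file prefix.
#' @export
writeEvalReport <- function(outcome, dir, prefix = "evaluation") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(jsonlite::toJSON(list(summary = outcome@summary,
                                   bands = as.list(outcome@bands)),
                              auto_unbox = TRUE, pretty = TRUE, digits = NA),
             file.path(dir, paste0(prefix, ".json")))
  utils::write.csv(data.frame(record = seq_along(outcome@scores),
                              score = outcome@scores),
                   file.path(dir, paste0(prefix, "_scores.csv")),
                   row.names = FALSE)
  invisible(NULL)
}
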