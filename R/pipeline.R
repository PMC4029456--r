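## End-to-end orchestration: data -> negatives -> features -> CV grid
## (-> validation, importance, ablation), with one global seed fanned out
## deterministically to every stage and a machine-readable report.

pipelineStage <- function(name, expr) {
  message(sprintf("[%s] running", name))
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, under per-stage seeds derived from \code{config@seed}:
#' data acquisition (synthetic generation or file loading), negative
#' sampling length-matched to the positives, feature-matrix construction
#' per requested feature set, the cross-validated (feature set x model)
#' grid, and optionally the zero-mark external-validation analog, shadow
#' importance and mark ablation.  When \code{config@outDir} is set, feature
#' tables (TSV), a JSON report and a JSON run manifest are written; reports
#' are byte-identical across runs with the same configuration and seed.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @return list with elements \code{grid} (data.frame of CV results),
#'   \code{features} (named list of \linkS4class{EnhancerFeatureSet}),
#'   \code{validation}, \code{importance}, \code{ablation} (NULL when not
#'   requested) and \code{manifest}.
#' @export
runPipeline <- function(config) {
  seed <- config@seed
  trap <- trapParams()

  data <- pipelineStage("data", {
    if (!is.null(config@synthetic)) {
      syn <- config@synthetic
      syn@seed <- stageSeed(seed, 1L)
      ds <- generateDataset(syn)
      list(genome = ds@genome, positives = ds@positives, pwms = ds@pwms,
           tracks = ds@tracks, synthetic = syn, dataset = ds)
    } else {
      p <- config@paths
      genome <- readGenomeFasta(p$genome)
      positives <- readBed(p$positives, label = "positive")
      tracks <- stats::setNames(
        lapply(seq_along(p$tracks), function(i)
          readBedGraph(p$tracks[[i]], mark = names(p$tracks)[i])),
        names(p$tracks))
      list(genome = genome, positives = positives,
           pwms = readJasparPfm(p$pfm), tracks = tracks, synthetic = NULL)
    }
  })

  regions <- pipelineStage("sampler", {
    lenStats <- fitLengthDistribution(data$positives)
    negatives <- sampleNegatives(data$genome, samplerSpec(
      n = length(data$positives), lengthMean = lenStats[["mean"]],
      lengthSd = lenStats[["sd"]],
      exclusions = list(positives = data$positives),
      seed = stageSeed(seed, 2L)))
    c(data$positives, negatives)
  })

  features <- pipelineStage("features", {
    stats::setNames(lapply(config@featureSets, function(set)
      buildFeatureMatrix(data$genome, data$tracks, data$pwms, regions,
                         featureSet = set, params = trap)),
      config@featureSets)
  })

  models <- config@models
  if (is.character(models))
    models <- stats::setNames(lapply(models, modelSpec), models)
  else if (is.null(names(models)))
    names(models) <- vapply(models, function(m) m@kind, character(1))

  grid <- pipelineStage("crossval", {
    cv <- config@cv
    cv@seed <- stageSeed(seed, 3L)
    rows <- list()
    for (set in names(features)) {
      for (mk in names(models)) {
        ms <- models[[mk]]
        ms@seed <- stageSeed(seed, 1000L + length(rows))
        res <- crossValidate(ms, features[[set]], cv)
        rows[[length(rows) + 1L]] <- data.frame(
          featureSet = set, model = mk, meanAuc = meanAuc(res),
          sdAuc = sdAuc(res), meanError = meanError(res),
          sdError = sdError(res), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  validation <- NULL
  if (isTRUE(config@validation)) {
    validation <- pipelineStage("validation", {
      if (is.null(data$synthetic))
        stop("the zero-mark validation analog requires a synthetic config")
      valConfig <- data$synthetic
      valConfig@seed <- stageSeed(seed, 4L)
      valConfig@effectSizes <- rep(0, length(valConfig@effectSizes))
      valDs <- prefixChromNames(generateDataset(valConfig, pwms = data$pwms))
      valNeg <- sampleNegatives(valDs@genome, samplerSpec(
        n = length(valDs@positives),
        lengthMean = fitLengthDistribution(valDs@positives)[["mean"]],
        lengthSd = fitLengthDistribution(valDs@positives)[["sd"]],
        exclusions = list(positives = valDs@positives),
        seed = stageSeed(seed, 5L)))
      valRegions <- c(valDs@positives, valNeg)
      rows <- list()
      for (set in names(features)) {
        for (mk in names(models)) {
          ms <- models[[mk]]
          ms@seed <- stageSeed(seed, 2000L + length(rows))
          model <- trainModel(ms, features[[set]])
          res <- externalValidate(model, valRegions, valDs@genome,
                                  valDs@tracks, data$pwms,
                                  trainingRegions = regions, params = trap)
          rows[[length(rows) + 1L]] <- data.frame(
            featureSet = set, model = mk, auc = res$auc, error = res$error,
            stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    })
  }

  importance <- NULL
  if (!is.null(config@importance)) {
    importance <- pipelineStage("importance", {
      impSpec <- config@importance
      impSpec@seed <- stageSeed(seed, 6L)
      target <- if ("ALL" %in% names(features)) features[["ALL"]]
                else features[[1L]]
      repeatedImportance(target, impSpec)
    })
  }

  ablation <- NULL
  if (!is.null(config@ablation)) {
    ablation <- pipelineStage("ablation", {
      target <- if ("ALL" %in% names(features)) features[["ALL"]]
                else features[[1L]]
      if (config@ablation@mode == "iterative_tf") {
        impSpec <- if (!is.null(config@importance)) config@importance
                   else importanceSpec()
        impSpec@seed <- stageSeed(seed, 7L)
        iterativeTfElimination(target, impSpec, config@ablation@model,
                               config@ablation@cv)
      } else {
        ranking <- if (!is.null(importance)) importanceRanking(importance)
                   else {
                     impSpec <- importanceSpec(nRepetitions = 5L,
                                               seed = stageSeed(seed, 7L))
                     importanceRanking(repeatedImportance(target, impSpec))
                   }
        ablationCurve(target, config@ablation, ranking)
      }
    })
  }

  manifest <- list(
    package = "enhancerPred",
    version = as.character(utils::packageVersion("enhancerPred")),
    seed = seed,
    stageSeeds = list(data = stageSeed(seed, 1L),
                      sampler = stageSeed(seed, 2L),
                      crossval = stageSeed(seed, 3L),
                      validation = stageSeed(seed, 4L)),
    featureSets = config@featureSets, models = names(models),
    cv = list(k = config@cv@k, reversed = config@cv@reversed,
              stratified = config@cv@stratified),
    synthetic = if (!is.null(config@synthetic))
      configAsList(config@synthetic) else NULL)

  report <- list(grid = grid, features = features, validation = validation,
                 importance = importance, ablation = ablation,
                 manifest = manifest)

  if (!is.na(config@outDir)) {
    pipelineStage("report", {
      dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
      for (set in names(features))
        writeFeatureTable(features[[set]],
                          file.path(config@outDir,
                                    sprintf("features_%s.tsv", set)))
      json <- list(grid = grid, validation = validation,
                   importance = if (!is.null(importance)) list(
                     meanZ = as.list(importanceZ(importance)),
                     decisions = as.list(as.character(
                       importanceDecisions(importance))),
                     expectedFalseDiscoveries =
                       expectedFalseDiscoveries(importance)) else NULL,
                   ablation = ablation, manifest = manifest)
      jsonlite::write_json(json, file.path(config@outDir, "report.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      jsonlite::write_json(manifest, file.path(config@outDir,
                                               "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    })
  }
  report
}
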