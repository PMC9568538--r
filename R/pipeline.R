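#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end run: input source (a directory of
#' face images plus an AU or label CSV, or a synthetic fixture spec), the
#' backbone, the INCA range and mode, cross-validation settings, and
#' optional per-class under-sampling.
#'
#' @param outputDir directory for run artifacts (created if absent).
#' @param imagesDir directory of pre-cropped face images (PNG/JPEG) named
#'   \code{<id>.png}; ignored when \code{synth} is given.
#' @param auCsv per-frame action-unit CSV (dialect of
#'   \code{\link{readAUTable}}) used to label the images.
#' @param synth a \code{\link{synthSpec}}; if given, images and labels are
#'   generated in memory and \code{imagesDir}/\code{auCsv} are ignored.
#' @param backboneSeed,inputSide,featureDim toy-backbone parameters (see
#'   \code{\link{toyBackbone}}); any \linkS4class{Backbone} can be passed
#'   directly as \code{backbone}.
#' @param backbone optional \linkS4class{Backbone} overriding the toy one.
#' @param incaLo,incaHi INCA candidate-length range.
#' @param mode \code{"faithful"} (normalize and rank once on the full
#'   matrix) or \code{"no-leakage"} (per-fold refitting).
#' @param cvFolds,cvSeed cross-validation folds and seed.
#' @param undersampleTargets optional per-class targets for
#'   \code{\link{balanceUndersample}}.
#' @param undersampleSeed seed for the under-sampling stage.
#' @param ncaIterations NCA gradient steps (see \code{\link{ncaRank}}).
#' @param stopAfter optional stage name after which to stop
#'   (\code{"label"}, \code{"balance"}, \code{"features"}, \code{"select"},
#'   \code{"evaluate"}, \code{"metrics"}).
#' @param resumeFrom optional stage name to resume from, reloading earlier
#'   artifacts from \code{outputDir}.
#' @return list of class \code{runConfig}.
#' @export
runConfig <- function(outputDir,
                      imagesDir = NULL, auCsv = NULL, synth = NULL,
                      backboneSeed = 1L, inputSide = 56L, featureDim = 50L,
                      backbone = NULL,
                      incaLo = 10L, incaHi = 60L,
                      mode = c("faithful", "no-leakage"),
                      cvFolds = 10L, cvSeed = 1L,
                      undersampleTargets = NULL, undersampleSeed = 1L,
                      ncaIterations = 100L,
                      stopAfter = NULL, resumeFrom = NULL) {
    mode <- match.arg(mode)
    stages <- pipelineStages()
    if (!is.null(stopAfter) && !stopAfter %in% stages)
        validationError("unknown stage '%s'", stopAfter)
    if (!is.null(resumeFrom) && !resumeFrom %in% stages)
        validationError("unknown stage '%s'", resumeFrom)
    if (is.null(synth)) {
        if (is.null(imagesDir) || is.null(auCsv))
            validationError("either 'synth' or both 'imagesDir' and 'auCsv' are required")
        if (!dir.exists(imagesDir)) ioError("imagesDir not found: %s", imagesDir)
        if (!file.exists(auCsv)) ioError("auCsv not found: %s", auCsv)
    }
    structure(list(
        outputDir = outputDir, imagesDir = imagesDir, auCsv = auCsv,
        synth = synth, backboneSeed = as.integer(backboneSeed),
        inputSide = as.integer(inputSide), featureDim = as.integer(featureDim),
        backbone = backbone, incaLo = as.integer(incaLo),
        incaHi = as.integer(incaHi), mode = mode,
        cvFolds = as.integer(cvFolds), cvSeed = as.integer(cvSeed),
        undersampleTargets = undersampleTargets,
        undersampleSeed = as.integer(undersampleSeed),
        ncaIterations = as.integer(ncaIterations),
        stopAfter = stopAfter, resumeFrom = resumeFrom), class = "runConfig")
}

pipelineStages <- function() {
    c("label", "balance", "features", "select", "evaluate", "metrics")
}

stageLog <- function(stage, fmt, ...) {
    message(sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, sprintf(fmt, ...)))
}

runStage <- function(stage, code) {
    stageLog(stage, "start")
    out <- withCallingHandlers(
        tryCatch(code, error = function(e) {
            cls <- class(e)[1]
            msg <- sprintf("stage '%s' failed: %s", stage, conditionMessage(e))
            stop(structure(class = unique(c(cls, "error", "condition")),
                           list(message = msg, call = NULL)))
        }),
        warning = function(w) invokeRestart("muffleWarning"))
    stageLog(stage, "done")
    out
}

#' Run the full pain-classification pipeline
#'
#' Stages, in order: \code{label} (PSPI scoring and class grouping),
#' \code{balance} (optional seeded under-sampling), \code{features}
#' (resize, strip decomposition, backbone extraction, concatenation),
#' \code{select} (min-max normalization, NCA ranking, INCA prefix
#' selection), \code{evaluate} (k = 1 Manhattan kNN with stratified
#' ten-fold CV, pooled confusion matrix), \code{metrics} (full metric
#' suite). Artifacts written to \code{outputDir}: \code{labels.csv},
#' \code{features.csv}, \code{selection.json}, \code{confusion.csv},
#' \code{metrics.json} and \code{manifest.json}. Runs are idempotent:
#' identical config and inputs give byte-identical artifacts.
#'
#' @param config a \code{\link{runConfig}}.
#' @return invisible list with the in-memory artifacts (labels, feature
#'   set, selection, confusion, metrics).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "runConfig"))
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$outputDir, f)
    stages <- pipelineStages()
    from <- if (is.null(config$resumeFrom)) 1L else
        match(config$resumeFrom, stages)
    until <- if (is.null(config$stopAfter)) length(stages) else
        match(config$stopAfter, stages)
    active <- function(st) {
        i <- match(st, stages)
        i >= from && i <= until
    }
    state <- list()

    synthData <- NULL
    if (!is.null(config$synth)) {
        synthData <- runStage("synth", genFaceImages(config$synth))
    }

    ## -- label ---------------------------------------------------------
    if (active("label")) {
        state$labels <- runStage("label", {
            if (!is.null(synthData)) {
                data.frame(id = synthData$ids,
                           pspi = NA_integer_,
                           class_index = as.integer(synthData$classes) - 1L,
                           class_label = as.character(synthData$classes),
                           stringsAsFactors = FALSE)
            } else {
                labelAUTable(readAUTable(config$auCsv))
            }
        })
        writeLabels(state$labels, out("labels.csv"))
    } else if (from > match("label", stages)) {
        state$labels <- utils::read.csv(out("labels.csv"), stringsAsFactors = FALSE)
    }

    ## -- balance -------------------------------------------------------
    if (active("balance")) {
        state$labels <- runStage("balance", {
            if (is.null(config$undersampleTargets)) state$labels
            else balanceUndersample(state$labels, config$undersampleTargets,
                                    config$undersampleSeed)
        })
        writeLabels(state$labels, out("labels.csv"))
    }
    if (until < match("features", stages)) return(invisible(state))

    ## -- features ------------------------------------------------------
    if (active("features")) {
        state$features <- runStage("features", {
            bb <- if (!is.null(config$backbone)) config$backbone else
                toyBackbone(config$backboneSeed, config$inputSide,
                            config$featureDim)
            cls <- factor(state$labels$class_label, levels = painClassLabels())
            if (!is.null(synthData)) {
                keep <- match(state$labels$id, synthData$ids)
                faces <- lapply(synthData$images[keep],
                                function(im) resizeFace(im, 224L))
                buildFeatureSet(faces, cls, bb, ids = state$labels$id)
            } else {
                paths <- file.path(config$imagesDir,
                                   paste0(state$labels$id, ".png"))
                missing <- !file.exists(paths)
                if (any(missing))
                    ioError("missing image(s): %s",
                            paste(utils::head(paths[missing], 3), collapse = ", "))
                buildFeatureSet(paths, cls, bb, ids = state$labels$id)
            }
        })
        writeFeatureCSV(state$features, out("features.csv"))
    } else if (from > match("features", stages)) {
        state$features <- readFeatureCSV(out("features.csv"))
    }
    if (until < match("select", stages)) return(invisible(state))

    ## -- select --------------------------------------------------------
    y <- painClass(state$features)
    Xraw <- featureMatrix(state$features)
    cv <- cvSpec(config$cvFolds, config$cvSeed)
    if (active("select")) {
        state$selection <- runStage("select", {
            if (config$mode == "faithful") {
                norm <- minmaxNormalize(Xraw)
                rk <- ncaRank(norm$X, y, iterations = config$ncaIterations)
                incaSelect(norm$X, y, rk, lo = config$incaLo,
                           hi = config$incaHi, cv = cv)
            } else {
                incaSelectStrict(Xraw, y, lo = config$incaLo,
                                 hi = config$incaHi, cv = cv,
                                 iterations = config$ncaIterations)
            }
        })
        writeSelection(state$selection, out("selection.json"))
    } else if (from > match("select", stages)) {
        state$selection <- readSelection(out("selection.json"))
    }
    if (until < match("evaluate", stages)) return(invisible(state))

    ## -- evaluate ------------------------------------------------------
    if (active("evaluate") || active("metrics")) {
        state$cvResult <- runStage("evaluate", {
            Xsel <- minmaxNormalize(Xraw)$X[, state$selection@selected,
                                            drop = FALSE]
            crossValidate(Xsel, y, cv = cv, k = 1L)
        })
        writeConfusion(state$cvResult$confusion, out("confusion.csv"))
        utils::write.csv(
            data.frame(id = rownames(Xraw), fold = state$cvResult$folds),
            out("folds.csv"), row.names = FALSE, quote = FALSE)
    }
    if (until < match("metrics", stages)) return(invisible(state))

    ## -- metrics -------------------------------------------------------
    state$metrics <- runStage("metrics", overallMetrics(state$cvResult$confusion))
    writeMetricReport(state$cvResult$confusion, out("metrics.json"))

    manifest <- list(
        package = as.character(utils::packageVersion("painstrips")),
        mode = config$mode,
        seeds = list(backbone = config$backboneSeed, cv = config$cvSeed,
                     undersample = config$undersampleSeed,
                     synth = if (!is.null(config$synth)) config$synth$seed),
        config = list(incaLo = config$incaLo, incaHi = config$incaHi,
                      cvFolds = config$cvFolds,
                      featureDim = config$featureDim,
                      inputSide = config$inputSide,
                      ncaIterations = config$ncaIterations,
                      synth = if (!is.null(config$synth)) unclass(config$synth)))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(state)
}
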