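#' Read a feature-table CSV
#'
#' The on-disk format is a plain CSV with a header row: first column
#' \code{sample_id}, a \code{label} column in {0, 1}, and every other column
#' a numeric examination item. An empty cell or \code{NA} marks a missing
#' measurement. Parsing is locale-independent (decimal point only).
#'
#' @param path Path to the CSV file.
#' @return An \linkS4class{ExaminationTable}.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("sample_id,label,alt,ast", "s1,0,1.5,NA", "s2,1,2.5,7"), f)
#' readFeatureTable(f)
#' @export
readFeatureTable <- function(path) {
    if (!file.exists(path)) stop(sprintf("no such file: %s", path))
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = c("NA", ""))
    if (!"sample_id" %in% colnames(df)[1])
        stop("schema error: first column must be 'sample_id'")
    if (!"label" %in% colnames(df))
        stop("schema error: required column 'label' is absent")
    cn <- colnames(df)
    itemCols <- cn[!cn %in% c("sample_id", "label")]
    if (anyDuplicated(itemCols))
        stop(sprintf("schema error: duplicate item name(s): %s",
                     paste(unique(itemCols[duplicated(itemCols)]),
                           collapse = ", ")))
    if (anyDuplicated(df$sample_id))
        stop(sprintf("schema error: duplicate sample id(s): %s",
                     paste(unique(df$sample_id[duplicated(df$sample_id)]),
                           collapse = ", ")))
    lab <- df$label
    if (anyNA(lab) || !all(lab %in% c("0", "1")))
        stop("schema error: 'label' must be 0 or 1 for every sample")
    vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(itemCols),
                   dimnames = list(NULL, itemCols))
    for (j in itemCols) {
        raw <- df[[j]]
        num <- suppressWarnings(as.numeric(raw))
        bad <- !is.na(raw) & is.na(num)
        if (any(bad))
            stop(sprintf("schema error: non-numeric value '%s' in item '%s' (sample %s)",
                         raw[which(bad)[1]], j, df$sample_id[which(bad)[1]]))
        vals[, j] <- num
    }
    ExaminationTable(vals, labels = as.integer(lab), itemNames = itemCols,
                     sampleIds = df$sample_id)
}

#' Write a feature-table CSV
#'
#' Inverse of \code{\link{readFeatureTable}}: missing cells are written as
#' \code{NA}. A write/read round trip reproduces the table.
#'
#' @param table An \linkS4class{ExaminationTable}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(table, path) {
    vals <- featureMatrix(table)
    vals[missingMask(table)] <- NA_real_
    df <- data.frame(sample_id = colnames(table),
                     label = as.integer(sampleLabels(table)),
                     check.names = FALSE)
    df <- cbind(df, as.data.frame(vals, check.names = FALSE))
    write.csv(df, path, row.names = FALSE, na = "NA", quote = FALSE)
    invisible(path)
}

#' Resolved pipeline run configuration
#'
#' Every field has a default except the input path; the resolved
#' configuration is echoed into the run manifest so any run can be
#' reproduced from its manifest alone.
#'
#' @param input Path to the input feature-table CSV (required).
#' @param outDir Output directory (default \code{"clinfm_run"}).
#' @param L Number of selected items (default 30).
#' @param selectionScope \code{"fold"} or \code{"global"}.
#' @param folds Number of CV folds (default 5).
#' @param reference Ablation reference row (default \code{"second-order"}).
#' @param reporting \code{"fold-mean"} or \code{"pooled"}.
#' @param balanceClasses Subsample to equal group sizes first (default TRUE).
#' @param valFraction Early-stopping split fraction (default 0.1).
#' @param seed Integer seed for every random choice in the run.
#' @param learningRate,batchSize,maxEpochs,patience,K See
#'   \code{\link{trainConfig}}.
#' @param logLevel \code{"info"} or \code{"quiet"}.
#' @return A list of class \code{"runConfig"}.
#' @export
runConfig <- function(input, outDir = "clinfm_run", L = 30L,
                      selectionScope = "fold", folds = 5L,
                      reference = "second-order", reporting = "fold-mean",
                      balanceClasses = TRUE, valFraction = 0.1, seed = 1L,
                      learningRate = 0.01, batchSize = 32L,
                      maxEpochs = 200L, patience = 20L, K = 10L,
                      logLevel = "info") {
    if (missing(input)) stop("configuration error: 'input' path is required")
    structure(list(input = input, outDir = outDir, L = as.integer(L),
                   selectionScope = selectionScope,
                   folds = as.integer(folds), reference = reference,
                   reporting = reporting, balanceClasses = balanceClasses,
                   valFraction = valFraction, seed = as.integer(seed),
                   learningRate = learningRate,
                   batchSize = as.integer(batchSize),
                   maxEpochs = as.integer(maxEpochs),
                   patience = as.integer(patience), K = as.integer(K),
                   logLevel = logLevel),
              class = "runConfig")
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline on a feature-table CSV
#'
#' Executes balance, normalize, select, train, and cross-validated
#' evaluation, then writes everything a re-run or an audit needs into
#' \code{outDir}: the model archive (\code{model.json}), per-fold and summary
#' metric reports (CSV), the resolved run manifest (\code{manifest.yaml},
#' including the input file's MD5), and a plain-text log with one line per
#' stage recording row/column counts.
#'
#' @param config A \code{\link{runConfig}}.
#' @return Invisibly, a list with the output paths and the
#'   \code{"cvResult"}.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "runConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    logPath <- file.path(config$outDir, "run.log")
    logCon <- file(logPath, open = "wt")
    on.exit(close(logCon))
    logLine <- function(...) {
        msg <- sprintf(...)
        writeLines(msg, logCon)
        if (identical(config$logLevel, "info")) message(msg)
    }

    table <- .stage("read", readFeatureTable(config$input))
    logLine("read: %d patients x %d items from %s",
            ncol(table), nrow(table), config$input)

    if (config$balanceClasses) {
        table <- .stage("balance", classBalance(table, seed = config$seed))
        lab <- sampleLabels(table)
        logLine("balance: %d patients (%d per class)", ncol(table),
                sum(lab == 1L))
    }

    tc <- trainConfig(learningRate = config$learningRate,
                      batchSize = config$batchSize,
                      maxEpochs = config$maxEpochs,
                      patience = config$patience, K = config$K,
                      seed = config$seed)
    cv <- .stage("evaluate",
                 crossValidate(table, L = config$L, k = config$folds,
                               config = tc, seed = config$seed,
                               selectionScope = config$selectionScope,
                               reporting = config$reporting,
                               valFraction = config$valFraction))
    logLine("evaluate: %d-fold CV mean accuracy %.4f", config$folds,
            cv$meanMetrics[["accuracy"]])

    model <- .stage("train",
                    fitModel(table, L = config$L, config = tc,
                             valFraction = config$valFraction))
    logLine("train: final model on %d patients, L = %d, K = %d",
            ncol(table), config$L, config$K)

    modelPath <- file.path(config$outDir, "model.json")
    writeModel(model, modelPath)
    perFoldPath <- file.path(config$outDir, "metrics_per_fold.csv")
    write.csv(cv$perFold, perFoldPath, row.names = FALSE, quote = FALSE)
    summaryPath <- file.path(config$outDir, "metrics_summary.csv")
    smry <- data.frame(metric = names(cv$meanMetrics),
                       mean = unname(cv$meanMetrics),
                       iqr = unname(cv$iqr),
                       pooled = unname(unlist(cv$pooled[.metricNames])))
    write.csv(smry, summaryPath, row.names = FALSE, quote = FALSE)

    manifestPath <- file.path(config$outDir, "manifest.yaml")
    manifest <- unclass(config)
    manifest$input_md5 <- unname(tools::md5sum(config$input))
    manifest$fold_assignment <- as.integer(cv$folds)
    yaml::write_yaml(manifest, manifestPath)
    logLine("output: %s", config$outDir)

    invisible(list(model = modelPath, perFold = perFoldPath,
                   summary = summaryPath, manifest = manifestPath,
                   log = logPath, cv = cv, fittedModel = model))
}

#' Re-run a pipeline from a manifest
#'
#' Reads a \code{manifest.yaml} written by \code{\link{runPipeline}} and
#' replays the run with the recorded configuration; with the same input file
#' the metric reports are byte-identical.
#'
#' @param manifestPath Path to a run manifest.
#' @param outDir Output directory for the replay (default: the manifest's).
#' @return As \code{\link{runPipeline}}.
#' @export
replayRun <- function(manifestPath, outDir = NULL) {
    m <- yaml::read_yaml(manifestPath)
    cfg <- runConfig(input = m$input,
                     outDir = if (is.null(outDir)) m$outDir else outDir,
                     L = m$L, selectionScope = m$selectionScope,
                     folds = m$folds, reference = m$reference,
                     reporting = m$reporting,
                     balanceClasses = m$balanceClasses,
                     valFraction = m$valFraction, seed = m$seed,
                     learningRate = m$learningRate, batchSize = m$batchSize,
                     maxEpochs = m$maxEpochs, patience = m$patience,
                     K = m$K, logLevel = m$logLevel)
    runPipeline(cfg)
}
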