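#' Fit a second-order classification model on a table
#'
#' End-to-end single fit: per-item min-max statistics and ANOVA F ranking are
#' computed on the given patients (optionally a training subset), the top-L
#' items are selected, and the classifier is trained on the selected,
#' normalized feature matrix. The returned \linkS4class{FMModel} carries the
#' normalization statistics and selected item names, so prediction on new
#' tables is self-contained and never refits anything.
#'
#' @param table An \linkS4class{ExaminationTable}.
#' @param L Number of items to select.
#' @param config A \code{\link{trainConfig}}.
#' @param rows Patients to fit on (default all).
#' @param valFraction Fraction of fitting patients held out (stratified) for
#'   early stopping; 0 disables early stopping.
#' @param freeze Component freezing for ablation; see \code{\link{fmTrain}}.
#' @return An \linkS4class{FMModel}.
#' @examples
#' sim <- simulateExamTable(nPerClass = 40, nItems = 10, missingRate = 0.2,
#'                          seed = 11)
#' mod <- fitModel(sim$table, L = 5, config = trainConfig(maxEpochs = 20))
#' mod
#' @export
fitModel <- function(table, L, config = trainConfig(),
                     rows = seq_len(ncol(table)), valFraction = 0,
                     freeze = "none") {
    idx <- seq_len(ncol(table))[rows]
    stats <- fitMinMax(table, idx)
    Zfit <- applyMinMax(table[, idx], stats)
    rk <- selectTopL(anovaFScores(Zfit), L)
    S <- selectFeatures(Zfit, rk)
    y <- sampleLabels(Zfit)
    val <- .valSplit(y, valFraction, config$seed)
    if (length(val)) {
        fit <- fmTrain(S[-val, , drop = FALSE], y[-val], config,
                       SVal = S[val, , drop = FALSE], yVal = y[val],
                       freeze = freeze)
    } else {
        fit <- fmTrain(S, y, config, freeze = freeze)
    }
    sel <- rk@selected
    methods::new("FMModel", version = "1.0", params = fit$params,
                 itemNames = rownames(table)[sel],
                 itemMin = unname(stats$itemMin[sel]),
                 itemMax = unname(stats$itemMax[sel]),
                 seed = config$seed, history = fit$history,
                 config = list(L = as.integer(L), K = config$K,
                               learningRate = config$learningRate,
                               batchSize = config$batchSize,
                               maxEpochs = config$maxEpochs,
                               patience = config$patience,
                               freeze = freeze,
                               valFraction = valFraction))
}

setMethod("show", "FMModel", function(object) {
    cat(sprintf("FMModel (v%s): L = %d selected items, K = %d latent factors\n",
                object@version, length(object@itemNames),
                ncol(object@params@factors)))
    cat("items:", paste(head(object@itemNames, 5L), collapse = ", "),
        if (length(object@itemNames) > 5L) "..." else "", "\n")
    if (nrow(object@history))
        cat(sprintf("final training loss: %.4f (%d epochs)\n",
                    object@history$trainLoss[nrow(object@history)],
                    nrow(object@history)))
})

#' Predict diagnosis risk for new patients
#'
#' Applies the stored min-max statistics (with clipping into [0, 1] and
#' zero-imputation of missing cells), selects the model's items by name, and
#' runs the forward pass. Item columns may appear in any order in the new
#' table; they are matched by name. Nothing is refitted.
#'
#' @param object An \linkS4class{FMModel}.
#' @param table An \linkS4class{ExaminationTable} containing every item the
#'   model uses (cells may be missing).
#' @return A data.frame with one row per patient: \code{sample_id},
#'   component scores \code{e} and \code{r}, logit \code{o}, probability
#'   \code{p}, and hard label \code{yhat} (1 exactly when p >= 0.5).
#' @examples
#' sim <- simulateExamTable(nPerClass = 30, nItems = 8, seed = 2)
#' mod <- fitModel(sim$table, L = 4, config = trainConfig(maxEpochs = 10))
#' head(predictRisk(mod, sim$table))
#' @export
predictRisk <- function(object, table) {
    need <- object@itemNames
    have <- rownames(table)
    absent <- setdiff(need, have)
    if (length(absent))
        stop(sprintf("required item column(s) absent from table: %s",
                     paste(absent, collapse = ", ")))
    sub <- table[match(need, have), , drop = FALSE]
    vals <- SummarizedExperiment::assay(sub, "exam")
    miss <- SummarizedExperiment::assay(sub, "missing")
    rng <- object@itemMax - object@itemMin
    z <- (vals - object@itemMin) / ifelse(rng > 0, rng, 1)
    z[rng == 0, ] <- 0
    z <- pmin(pmax(z, 0), 1)
    z[miss] <- 0
    out <- fmForward(t(z), object@params)
    cbind(data.frame(sample_id = colnames(table)), out)
}

#' @describeIn predictRisk \code{predict} method alias.
#' @param ... Unused.
#' @export
setMethod("predict", "FMModel", function(object, table, ...)
    predictRisk(object, table))

#' Write a model archive
#'
#' Serializes an \linkS4class{FMModel} as a single JSON document: a manifest
#' (format version, L, K, seed, selected item names, normalization minima and
#' maxima) plus the numeric parameter arrays. Doubles are written with 17
#' significant digits so a read/write round trip reproduces every array
#' bit-exactly.
#'
#' @param model An \linkS4class{FMModel}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeModel <- function(model, path) {
    doc <- list(format_version = model@version,
                L = length(model@itemNames),
                K = ncol(model@params@factors),
                seed = model@seed,
                item_names = model@itemNames,
                item_min = model@itemMin,
                item_max = model@itemMax,
                weights = model@params@weights,
                bias = model@params@bias,
                factors = model@params@factors,
                config = model@config)
    writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                                matrix = "rowmajor"), path)
    invisible(path)
}

#' Read a model archive
#'
#' @param path Path to a JSON archive written by \code{\link{writeModel}}.
#' @return An \linkS4class{FMModel} (training history is not part of the
#'   archive and comes back empty).
#' @export
readModel <- function(path) {
    doc <- jsonlite::fromJSON(path)
    V <- doc$factors
    if (!is.matrix(V))
        V <- matrix(as.numeric(V), nrow = doc$L, ncol = doc$K, byrow = TRUE)
    methods::new("FMModel", version = doc$format_version,
                 params = FMParams(as.numeric(doc$weights),
                                   as.numeric(doc$bias), V),
                 itemNames = as.character(doc$item_names),
                 itemMin = as.numeric(doc$item_min),
                 itemMax = as.numeric(doc$item_max),
                 seed = as.integer(doc$seed),
                 history = data.frame(),
                 config = as.list(doc$config))
}
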