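#' Confusion counts for binary predictions
#'
#' @param yTrue,yPred Binary vectors (0/1) of equal length; class 1 is the
#'   positive diagnosis.
#' @return Named integer vector with \code{tp}, \code{tn}, \code{fp},
#'   \code{fn}; the four counts always sum to the number of samples.
#' @examples
#' confusionCounts(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 1, 0, 0))
#' @export
confusionCounts <- function(yTrue, yPred) {
    if (length(yTrue) != length(yPred))
        stop("prediction and truth must have equal length")
    if (!all(yTrue %in% c(0, 1)) || !all(yPred %in% c(0, 1)))
        stop("confusion counts require binary (0/1) inputs")
    c(tp = sum(yTrue == 1 & yPred == 1),
      tn = sum(yTrue == 0 & yPred == 0),
      fp = sum(yTrue == 0 & yPred == 1),
      fn = sum(yTrue == 1 & yPred == 0))
}

#' Classification metrics from confusion counts
#'
#' Accuracy = (TP+TN)/total, Precision = TP/(TP+FP), Recall = TP/(TP+FN),
#' F1 = 2PR/(P+R) (the harmonic mean of precision and recall). A ratio with
#' a zero denominator is reported as 0 with a warning rather than NaN, so
#' degenerate folds do not poison a cross-validation summary.
#'
#' @param counts Named vector as returned by \code{\link{confusionCounts}}.
#' @return One-row data.frame with \code{accuracy}, \code{precision},
#'   \code{recall}, \code{f1} and the four source counts.
#' @examples
#' classMetrics(c(tp = 3, tn = 2, fp = 1, fn = 0))
#' @export
classMetrics <- function(counts) {
    tp <- counts[["tp"]]; tn <- counts[["tn"]]
    fp <- counts[["fp"]]; fn <- counts[["fn"]]
    total <- tp + tn + fp + fn
    if (total <= 0) stop("no evaluated samples")
    rat <- function(num, den, what) {
        if (den == 0) {
            warning(sprintf("%s undefined (zero denominator); reporting 0", what))
            0
        } else num / den
    }
    acc <- (tp + tn) / total
    prec <- rat(tp, tp + fp, "precision")
    rec <- rat(tp, tp + fn, "recall")
    f1 <- if (prec + rec == 0) {
        warning("f1 undefined (precision + recall = 0); reporting 0")
        0
    } else 2 * prec * rec / (prec + rec)
    data.frame(accuracy = acc, precision = prec, recall = rec, f1 = f1,
               tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Label-stratified fold assignment
#'
#' Shuffles each class with the seeded generator and deals it across k folds
#' as evenly as possible; leftover samples rotate across folds between
#' classes, so overall fold sizes also differ by at most one. Every sample
#' lands in exactly one fold, and within each class fold counts differ by at
#' most one.
#'
#' @param labels Binary label vector.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k, one per sample.
#' @examples
#' table(stratifiedFolds(rep(c(0, 1), each = 357), k = 5, seed = 1))
#' @export
stratifiedFolds <- function(labels, k = 5L, seed = 1L) {
    n <- length(labels)
    if (min(table(labels)) < k)
        stop(sprintf("need at least %d samples per class for %d folds", k, k))
    set.seed(seed)
    fold <- integer(n)
    cursor <- 0L
    for (cls in sort(unique(labels))) {
        idx <- which(labels == cls)
        idx <- idx[sample.int(length(idx))]
        m <- length(idx)
        sizes <- rep(m %/% k, k)
        rem <- m %% k
        if (rem > 0L) {
            extra <- ((cursor + seq_len(rem) - 1L) %% k) + 1L
            sizes[extra] <- sizes[extra] + 1L
            cursor <- cursor + rem
        }
        fold[idx] <- rep(seq_len(k), times = sizes)
    }
    fold
}

.metricNames <- c("accuracy", "precision", "recall", "f1")

#' Stratified k-fold cross-validation of the full pipeline
#'
#' For each fold: min-max statistics and the ANOVA F ranking are fitted on
#' the k-1 training folds (default scope), the top-L items are selected, the
#' classifier is trained (with a stratified slice of the training folds held
#' out for early stopping), and metrics are computed on the untouched test
#' fold. \code{selectionScope = "global"} instead fits normalization and
#' selection once on all patients before splitting, reproducing a single
#' global item set at the cost of mild leakage.
#'
#' @param table An \linkS4class{ExaminationTable}.
#' @param L Number of items to select.
#' @param k Number of folds (default 5).
#' @param config A \code{\link{trainConfig}}.
#' @param seed Seed for the fold assignment (default: the config seed).
#' @param selectionScope \code{"fold"} (default) or \code{"global"}.
#' @param reporting \code{"fold-mean"} (default): metrics per fold, then
#'   averaged; \code{"pooled"}: one confusion matrix over all held-out
#'   predictions.
#' @param freeze Component freezing for ablation; see \code{\link{fmTrain}}.
#' @param valFraction Fraction of training-fold patients used for early
#'   stopping (default 0.1).
#' @return A list of class \code{"cvResult"}: \code{perFold} (per-fold
#'   metric rows), \code{meanMetrics}, \code{iqr} (interquartile range per
#'   metric across folds), \code{pooled} metrics, \code{folds} (assignment
#'   vector), \code{predictions}, and the call settings.
#' @examples
#' sim <- simulateExamTable(nPerClass = 30, nItems = 8, seed = 4)
#' cv <- crossValidate(sim$table, L = 4,
#'                     config = trainConfig(maxEpochs = 15), seed = 4)
#' cv$meanMetrics
#' @export
crossValidate <- function(table, L, k = 5L, config = trainConfig(),
                          seed = config$seed,
                          selectionScope = c("fold", "global"),
                          reporting = c("fold-mean", "pooled"),
                          freeze = "none", valFraction = 0.1) {
    selectionScope <- match.arg(selectionScope)
    reporting <- match.arg(reporting)
    y <- sampleLabels(table)
    folds <- stratifiedFolds(y, k, seed)

    globalModelArgs <- NULL
    if (selectionScope == "global") {
        stats <- fitMinMax(table)
        Zall <- applyMinMax(table, stats)
        rkAll <- selectTopL(anovaFScores(Zall), L)
        globalModelArgs <- list(stats = stats, ranking = rkAll)
    }

    perFold <- NULL
    preds <- data.frame(sample_id = colnames(table), fold = folds,
                        yTrue = as.integer(y), p = NA_real_,
                        yhat = NA_integer_)
    for (f in seq_len(k)) {
        trainIdx <- which(folds != f)
        testIdx <- which(folds == f)
        if (selectionScope == "fold") {
            stats <- fitMinMax(table, trainIdx)
            rk <- selectTopL(anovaFScores(
                applyMinMax(table[, trainIdx], stats)), L)
        } else {
            stats <- globalModelArgs$stats
            rk <- globalModelArgs$ranking
        }
        Ztr <- applyMinMax(table[, trainIdx], stats)
        Str <- selectFeatures(Ztr, rk)
        ytr <- y[trainIdx]
        val <- .valSplit(ytr, valFraction, config$seed + f)
        fit <- if (length(val))
            fmTrain(Str[-val, , drop = FALSE], ytr[-val], config,
                    SVal = Str[val, , drop = FALSE], yVal = ytr[val],
                    freeze = freeze)
        else fmTrain(Str, ytr, config, freeze = freeze)
        Zte <- applyMinMax(table[, testIdx], stats)
        out <- fmForward(selectFeatures(Zte, rk), fit$params)
        preds$p[testIdx] <- out$p
        preds$yhat[testIdx] <- out$yhat
        mrow <- classMetrics(confusionCounts(y[testIdx], out$yhat))
        perFold <- rbind(perFold, cbind(data.frame(fold = f), mrow))
    }
    meanMetrics <- colMeans(perFold[, .metricNames])
    iqr <- vapply(perFold[, .metricNames], IQR, numeric(1))
    pooled <- classMetrics(confusionCounts(preds$yTrue, preds$yhat))
    structure(list(perFold = perFold, meanMetrics = meanMetrics, iqr = iqr,
                   pooled = pooled, folds = folds, predictions = preds,
                   metrics = if (reporting == "fold-mean") meanMetrics
                             else unlist(pooled[.metricNames]),
                   L = L, k = k, seed = seed, reporting = reporting,
                   selectionScope = selectionScope, freeze = freeze,
                   config = config),
              class = "cvResult")
}

#' @export
print.cvResult <- function(x, ...) {
    cat(sprintf("%d-fold stratified CV (L = %d, %s scope, %s reporting)\n",
                x$k, x$L, x$selectionScope, x$reporting))
    m <- rbind(mean = x$meanMetrics, IQR = x$iqr)
    print(round(m, 4))
    invisible(x)
}

#' Relative improvement of one metric row over another
#'
#' 100 * (full - reference) / reference, per metric. Values are returned at
#' full precision; round to two decimals for reporting.
#'
#' @param full,reference Named numeric vectors (or one-row data.frames) with
#'   entries \code{accuracy}, \code{precision}, \code{recall}, \code{f1};
#'   every reference entry must be positive.
#' @return Named numeric vector of percentages.
#' @examples
#' full <- c(accuracy = 0.8900, precision = 0.8837,
#'           recall = 0.9212, f1 = 0.9020)
#' ref <- c(accuracy = 0.8167, precision = 0.8362,
#'          recall = 0.8303, f1 = 0.8327)
#' round(relativeImprovement(full, ref), 2)
#' @export
relativeImprovement <- function(full, reference) {
    pick <- function(x) {
        x <- unlist(x)[.metricNames]
        if (anyNA(x)) stop("metric rows need accuracy/precision/recall/f1")
        x
    }
    a <- pick(full)
    b <- pick(reference)
    if (any(b <= 0)) stop("reference metrics must be positive")
    100 * (a - b) / b
}

#' Component ablation with relative-improvement reporting
#'
#' Cross-validates three variants under the identical fold assignment and
#' seed: the first-order-only model (latent factors frozen at zero), the
#' interaction-only model (first-order weights and bias frozen at zero), and
#' the full model. Relative improvements of the full model are computed
#' against a reference row: the interaction-only row by default, or the
#' per-metric best of the two component rows (\code{reference = "best"}).
#'
#' @inheritParams crossValidate
#' @param reference \code{"second-order"} (default), \code{"first-order"},
#'   or \code{"best"}.
#' @return A list of class \code{"ablationReport"}: \code{rows} (metric rows
#'   for the three variants), \code{improvement} (percentages), the three
#'   \code{cvResult}s, and the settings.
#' @examples
#' sim <- simulateExamTable(nPerClass = 25, nItems = 6, seed = 9)
#' ab <- ablate(sim$table, L = 6, config = trainConfig(maxEpochs = 10))
#' ab$rows
#' @export
ablate <- function(table, L, k = 5L, config = trainConfig(),
                   seed = config$seed,
                   reference = c("second-order", "first-order", "best"),
                   selectionScope = "fold", reporting = "fold-mean",
                   valFraction = 0.1) {
    reference <- match.arg(reference)
    run <- function(freeze)
        crossValidate(table, L, k, config, seed,
                      selectionScope = selectionScope,
                      reporting = reporting, freeze = freeze,
                      valFraction = valFraction)
    cvFirst <- run("factors")
    cvSecond <- run("linear")
    cvFull <- run("none")
    stopifnot(identical(cvFirst$folds, cvFull$folds),
              identical(cvSecond$folds, cvFull$folds))
    rows <- rbind(`first-order` = cvFirst$metrics,
                  `second-order` = cvSecond$metrics,
                  full = cvFull$metrics)
    ref <- switch(reference,
                  "second-order" = rows["second-order", ],
                  "first-order" = rows["first-order", ],
                  best = pmax(rows["first-order", ], rows["second-order", ]))
    improvement <- relativeImprovement(rows["full", ], ref)
    structure(list(rows = rows, improvement = improvement,
                   reference = reference,
                   cv = list(firstOrder = cvFirst, secondOrder = cvSecond,
                             full = cvFull),
                   L = L, k = k, seed = seed),
              class = "ablationReport")
}

#' @export
print.ablationReport <- function(x, ...) {
    cat(sprintf("Component ablation (%d-fold CV, L = %d)\n", x$k, x$L))
    print(round(x$rows, 4))
    cat(sprintf("improvement of full over %s row (%%):\n", x$reference))
    print(round(x$improvement, 2))
    invisible(x)
}

#' Coarse-then-fine search over the number of selected features
#'
#' Walks L upward in steps of \code{step} (default 10) until the mean CV
#' accuracy drops by more than \code{tol} below its running maximum, then
#' refines in steps of 1 over the bracket around the best coarse L. Returns
#' the L maximizing mean CV accuracy; ties go to the smaller L.
#'
#' @inheritParams crossValidate
#' @param LRange Integer range \code{c(min, max)} of L values to consider.
#' @param step Coarse step (default 10).
#' @param tol Accuracy drop treated as "noticeable" (default 0.01).
#' @param evaluator Function \code{function(L) -> mean accuracy}; defaults
#'   to running \code{\link{crossValidate}} and reading the mean accuracy.
#'   Injectable so the search logic can be verified against an exhaustive
#'   scan of an arbitrary accuracy landscape.
#' @return A list of class \code{"lSearch"}: \code{perL} (data.frame of L
#'   and mean accuracy, in evaluation order), \code{chosenL},
#'   \code{coarseLs}, \code{fineLs}.
#' @export
searchFeatureNumber <- function(table = NULL, LRange, k = 5L,
                                config = trainConfig(),
                                seed = config$seed, step = 10L, tol = 0.01,
                                evaluator = NULL, ...) {
    if (length(LRange) != 2L || LRange[1] > LRange[2] || LRange[1] < 1L)
        stop("LRange must be c(min, max) with 1 <= min <= max")
    if (is.null(evaluator)) {
        if (is.null(table)) stop("either a table or an evaluator is required")
        evaluator <- function(L)
            unname(crossValidate(table, L, k, config, seed, ...)$meanMetrics["accuracy"])
    }
    cache <- new.env(parent = emptyenv())
    eval1 <- function(L) {
        key <- as.character(L)
        if (is.null(cache[[key]])) cache[[key]] <- evaluator(L)
        cache[[key]]
    }
    coarseLs <- seq(LRange[1], LRange[2], by = step)
    runMax <- -Inf
    visited <- integer(0)
    for (L in coarseLs) {
        acc <- eval1(L)
        visited <- c(visited, L)
        if (acc < runMax - tol) break
        runMax <- max(runMax, acc)
    }
    accs <- vapply(visited, eval1, numeric(1))
    bestCoarse <- visited[which.max(accs)]
    fineLs <- seq(max(LRange[1], bestCoarse - step + 1L),
                  min(LRange[2], bestCoarse + step - 1L))
    for (L in setdiff(fineLs, visited)) eval1(L)
    allLs <- sort(unique(c(visited, fineLs)))
    allAcc <- vapply(allLs, eval1, numeric(1))
    chosen <- allLs[which.max(allAcc)]   # which.max takes the first maximum
    structure(list(perL = data.frame(L = allLs, accuracy = allAcc),
                   chosenL = chosen, coarseLs = visited, fineLs = fineLs,
                   tol = tol, step = step),
              class = "lSearch")
}

#' @export
print.lSearch <- function(x, ...) {
    cat(sprintf("feature-number search: chose L = %d (max mean accuracy %.4f)\n",
                x$chosenL, max(x$perL$accuracy)))
    invisible(x)
}
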