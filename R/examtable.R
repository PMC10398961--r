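#' Construct an examination table
#'
#' Builds an \linkS4class{ExaminationTable} from a patient-by-item value
#' matrix. Cells that are \code{NA} (or flagged in \code{missing}) are treated
#' as "item not measured for this patient".
#'
#' @param values Numeric matrix, patients as rows and examination items as
#'   columns (the orientation of the on-disk CSV; internally the object is
#'   stored items-by-patients, following assay convention).
#' @param labels Binary vector (0/1), one entry per patient; 1 is the positive
#'   diagnosis.
#' @param itemNames Character vector of unique item names; defaults to
#'   \code{colnames(values)}.
#' @param sampleIds Character vector of unique patient identifiers; defaults
#'   to \code{rownames(values)} or \code{"S0001"}-style ids.
#' @param missing Logical matrix like \code{values}; defaults to
#'   \code{is.na(values)}.
#' @return An \linkS4class{ExaminationTable}.
#' @examples
#' x <- matrix(c(1, 2, NA, 4, 5, 6), nrow = 3,
#'             dimnames = list(NULL, c("alt", "ast")))
#' et <- ExaminationTable(x, labels = c(0, 1, 1))
#' featureMatrix(et)
#' @export
ExaminationTable <- function(values, labels, itemNames = colnames(values),
                             sampleIds = rownames(values),
                             missing = is.na(values)) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(itemNames))
        itemNames <- sprintf("item_%03d", seq_len(ncol(values)))
    if (is.null(sampleIds))
        sampleIds <- sprintf("S%04d", seq_len(nrow(values)))
    if (!is.matrix(missing)) missing <- as.matrix(missing)
    labels <- as.integer(labels)
    vals <- t(values)
    miss <- t(missing) | is.na(vals)
    dimnames(vals) <- list(itemNames, sampleIds)
    dimnames(miss) <- dimnames(vals)
    if (nrow(vals) > 0 && ncol(vals) > 0 && any(rowSums(!miss) == 0))
        stop(sprintf("item(s) missing for every patient: %s",
                     paste(itemNames[rowSums(!miss) == 0], collapse = ", ")))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exam = vals, missing = miss),
        colData = S4Vectors::DataFrame(label = labels, row.names = sampleIds))
    methods::new("ExaminationTable", se)
}

#' @rdname examValues
#' @aliases examValues,ExaminationTable-method
#' @export
setMethod("examValues", "ExaminationTable", function(x)
    SummarizedExperiment::assay(x, "exam"))

#' @rdname missingMask
#' @aliases missingMask,ExaminationTable-method
#' @export
setMethod("missingMask", "ExaminationTable", function(x)
    t(SummarizedExperiment::assay(x, "missing")))

#' @rdname sampleLabels
#' @aliases sampleLabels,ExaminationTable-method
#' @export
setMethod("sampleLabels", "ExaminationTable", function(x)
    setNames(as.integer(SummarizedExperiment::colData(x)$label), colnames(x)))

#' @rdname featureMatrix
#' @aliases featureMatrix,ExaminationTable-method
#' @export
setMethod("featureMatrix", "ExaminationTable", function(x)
    t(SummarizedExperiment::assay(x, "exam")))

#' @rdname itemNames
#' @aliases itemNames,ExaminationTable-method
#' @export
setMethod("itemNames", "ExaminationTable", function(x) rownames(x))

#' @rdname itemNames
#' @aliases itemNames,FMModel-method
#' @export
setMethod("itemNames", "FMModel", function(x) x@itemNames)

setMethod("show", "ExaminationTable", function(object) {
    methods::callNextMethod()
    lab <- sampleLabels(object)
    miss <- SummarizedExperiment::assay(object, "missing")
    cat(sprintf("labels: %d positive / %d negative; missing cells: %.1f%%\n",
                sum(lab == 1L), sum(lab == 0L), 100 * mean(miss)))
})

setMethod("show", "NormalizedExamTable", function(object) {
    methods::callNextMethod()
    cat(sprintf("normalized to [0,1]; %d constant item(s)\n",
                sum(object@itemMin == object@itemMax)))
})

#' Subsample to exact class balance
#'
#' Returns a table in which both diagnosis groups have the size of the
#' minority group. All minority rows are kept; majority rows are chosen by
#' seeded uniform subsampling without replacement. Patient order is otherwise
#' preserved. An already balanced table is returned unchanged.
#'
#' @param table An \linkS4class{ExaminationTable} containing both classes.
#' @param seed Integer seed for the majority subsample.
#' @return An \linkS4class{ExaminationTable} with equal label counts.
#' @examples
#' sim <- simulateExamTable(nPerClass = 20, nItems = 6, seed = 1)
#' tab <- sim$table[, 1:30]           # unbalance by dropping patients
#' table(sampleLabels(classBalance(tab, seed = 1)))
#' @export
classBalance <- function(table, seed = 1L) {
    lab <- sampleLabels(table)
    counts <- c(sum(lab == 0L), sum(lab == 1L))
    if (any(counts == 0L))
        stop("cannot balance single-class data")
    if (counts[1] == counts[2])
        return(table)
    minority <- if (counts[1] < counts[2]) 0L else 1L
    nKeep <- min(counts)
    majIdx <- which(lab != minority)
    set.seed(seed)
    keepMaj <- sort(sample(majIdx, nKeep))
    keep <- sort(c(which(lab == minority), keepMaj))
    table[, keep]
}
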