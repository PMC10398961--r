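#' Fit per-item min-max statistics
#'
#' Computes the per-item minimum and maximum over a designated subset of
#' patients, ignoring missing cells. These statistics define the min-max
#' transform z = (x - min) / (max - min); fitting them on training patients
#' only (and applying them to held-out patients) avoids information leakage
#' across a cross-validation split.
#'
#' @param table An \linkS4class{ExaminationTable}.
#' @param rows Integer or logical subset of patients to fit on (default all).
#' @return A list with named numeric vectors \code{itemMin} and
#'   \code{itemMax} and a logical \code{constant} flag per item
#'   (\code{TRUE} where min equals max).
#' @examples
#' et <- ExaminationTable(matrix(c(1, 2, 3, 5, NA, 7), nrow = 3,
#'                        dimnames = list(NULL, c("a", "b"))),
#'                        labels = c(0, 1, 1))
#' fitMinMax(et)
#' @export
fitMinMax <- function(table, rows = seq_len(ncol(table))) {
    idx <- seq_len(ncol(table))[rows]
    if (length(idx) == 0L)
        stop("cannot fit normalization statistics on an empty patient subset")
    vals <- SummarizedExperiment::assay(table, "exam")[, idx, drop = FALSE]
    miss <- SummarizedExperiment::assay(table, "missing")[, idx, drop = FALSE]
    nObs <- rowSums(!miss)
    if (any(nObs == 0L))
        stop(sprintf("item(s) with no measured value in the fitting subset: %s",
                     paste(rownames(table)[nObs == 0L], collapse = ", ")))
    vals[miss] <- NA_real_
    itemMin <- apply(vals, 1L, min, na.rm = TRUE)
    itemMax <- apply(vals, 1L, max, na.rm = TRUE)
    list(itemMin = itemMin, itemMax = itemMax,
         constant = itemMax == itemMin)
}

#' Apply min-max normalization
#'
#' Transforms every measured cell to z = (x - min) / (max - min), clips the
#' result into [0, 1] (held-out values can fall outside the training range),
#' maps constant items (max = min) to 0, and imputes missing cells to 0 while
#' keeping them flagged in the mask. A zero feature contributes nothing to
#' either term of the second-order classifier, so this imputation makes an
#' unmeasured item silent rather than informative.
#'
#' @param table An \linkS4class{ExaminationTable}.
#' @param stats A list with \code{itemMin} and \code{itemMax} as returned by
#'   \code{\link{fitMinMax}} (vectors may also be passed via \code{itemMin=}
#'   and \code{itemMax=}).
#' @param itemMin,itemMax Alternative to \code{stats}: explicit vectors.
#' @return A \linkS4class{NormalizedExamTable}.
#' @examples
#' et <- ExaminationTable(matrix(c(1, 2, 3), ncol = 1,
#'                        dimnames = list(NULL, "a")), labels = c(0, 1, 1))
#' featureMatrix(applyMinMax(et, fitMinMax(et)))
#' @export
applyMinMax <- function(table, stats = NULL, itemMin = stats$itemMin,
                        itemMax = stats$itemMax) {
    if (length(itemMin) != nrow(table) || length(itemMax) != nrow(table))
        stop("normalization statistics do not match the table's items")
    vals <- SummarizedExperiment::assay(table, "exam")
    miss <- SummarizedExperiment::assay(table, "missing")
    rng <- itemMax - itemMin
    z <- (vals - itemMin) / ifelse(rng > 0, rng, 1)
    z[rng == 0, ] <- 0
    z <- pmin(pmax(z, 0), 1)
    z[miss] <- 0
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exam = z, missing = miss),
        colData = SummarizedExperiment::colData(table))
    methods::new("NormalizedExamTable", se,
                 itemMin = setNames(as.numeric(itemMin), rownames(table)),
                 itemMax = setNames(as.numeric(itemMax), rownames(table)))
}

#' Fit and apply min-max normalization in one step
#'
#' @inheritParams fitMinMax
#' @return A \linkS4class{NormalizedExamTable} covering all patients, with
#'   statistics fitted on \code{rows}.
#' @export
normalizeTable <- function(table, rows = seq_len(ncol(table))) {
    applyMinMax(table, fitMinMax(table, rows))
}

#' @export
setMethod("[", "NormalizedExamTable", function(x, i, j, ..., drop = TRUE) {
    out <- methods::callNextMethod()
    if (!missing(i)) {
        ii <- seq_along(x@itemMin)
        names(ii) <- names(x@itemMin)
        ii <- ii[i]
        out@itemMin <- x@itemMin[ii]
        out@itemMax <- x@itemMax[ii]
    }
    out
})
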