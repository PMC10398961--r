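#' @import methods
#' @importFrom stats IQR median plogis pf quantile rbinom rnorm runif setNames
#' @importFrom utils read.csv write.csv head modifyList
NULL

#' Patient-by-item examination table
#'
#' An \code{ExaminationTable} holds a clinical examination-item matrix together
#' with an explicit missingness mask and a binary diagnosis label per patient.
#' It extends \linkS4class{SummarizedExperiment} with the Bioconductor
#' orientation: examination items are rows, patients are columns. Two assays
#' are carried: \code{"exam"} (numeric item values; \code{NA} allowed only at
#' masked cells) and \code{"missing"} (logical; \code{TRUE} where the item was
#' not measured for that patient). \code{colData} carries the \code{label}
#' column (1 = positive diagnosis, 0 = negative).
#'
#' Missingness is first-class here because different patients receive
#' different examination panels, so most cells of a several-hundred-item table
#' are empty; every downstream computation (normalization statistics, ANOVA F
#' scores) is defined over non-missing cells only.
#'
#' @seealso \code{\link{ExaminationTable}} (constructor),
#'   \code{\link{featureMatrix}}, \code{\link{sampleLabels}},
#'   \code{\link{classBalance}}
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass ExaminationTable
setClass("ExaminationTable", contains = "SummarizedExperiment")

.validExaminationTable <- function(object) {
    msg <- character(0)
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("exam", "missing") %in% an))
        return("assays must contain 'exam' and 'missing'")
    vals <- SummarizedExperiment::assay(object, "exam")
    miss <- SummarizedExperiment::assay(object, "missing")
    if (!is.logical(miss) || !identical(dim(vals), dim(miss)))
        msg <- c(msg, "'missing' must be a logical mask with the dimensions of 'exam'")
    cd <- SummarizedExperiment::colData(object)
    if (!("label" %in% colnames(cd))) {
        msg <- c(msg, "colData must contain a 'label' column")
    } else {
        lab <- cd$label
        if (anyNA(lab) || !all(lab %in% c(0L, 1L)))
            msg <- c(msg, "labels must be 0 or 1 with no NA")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "item names (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (is.logical(miss) && identical(dim(vals), dim(miss))) {
        if (any(is.na(vals[!miss])))
            msg <- c(msg, "non-missing cells must hold numeric values (no NA)")
    }
    if (length(msg)) msg else TRUE
}
setValidity("ExaminationTable", .validExaminationTable)

#' Min-max normalized examination table
#'
#' A \code{NormalizedExamTable} is an \linkS4class{ExaminationTable} whose
#' \code{"exam"} assay has been compressed into [0, 1] by per-item min-max
#' normalization, with masked (missing) cells imputed to 0. The per-item
#' minima and maxima used for the transform are stored so that test-time data
#' can be normalized with training-time statistics.
#'
#' @slot itemMin,itemMax Named numeric vectors (one entry per item) holding
#'   the normalization statistics, computed over non-missing cells of the rows
#'   they were fitted on.
#' @seealso \code{\link{fitMinMax}}, \code{\link{applyMinMax}},
#'   \code{\link{normalizeTable}}
#' @exportClass NormalizedExamTable
setClass("NormalizedExamTable",
    contains = "ExaminationTable",
    representation(itemMin = "numeric", itemMax = "numeric"))

setValidity("NormalizedExamTable", function(object) {
    msg <- character(0)
    vals <- SummarizedExperiment::assay(object, "exam")
    if (anyNA(vals))
        msg <- c(msg, "normalized values must be complete (missing cells imputed)")
    else if (length(vals) && (min(vals) < 0 || max(vals) > 1))
        msg <- c(msg, "normalized values must lie in [0, 1]")
    if (length(object@itemMin) != nrow(object) ||
        length(object@itemMax) != nrow(object))
        msg <- c(msg, "itemMin/itemMax must have one entry per item")
    else if (any(object@itemMin > object@itemMax))
        msg <- c(msg, "itemMin must not exceed itemMax")
    if (length(msg)) msg else TRUE
})

#' Univariate ANOVA F-value feature ranking
#'
#' Per-item F statistics for the two diagnosis groups, the corresponding
#' F-distribution tail probabilities (survival function), the ranking
#' permutation (descending F, ties broken by ascending original index), and
#' the currently selected top-L index set.
#'
#' @slot fValues Named numeric vector of F statistics (\code{Inf} marks a
#'   zero within-group variance with separated means).
#' @slot tailProbs Upper-tail probabilities of the F statistics.
#' @slot ranking Integer permutation of item indices, best first.
#' @slot selected Integer vector, the first L entries of \code{ranking}
#'   (empty until \code{\link{selectTopL}} is applied).
#' @seealso \code{\link{anovaFScores}}, \code{\link{selectTopL}}
#' @exportClass FeatureRanking
setClass("FeatureRanking",
    representation(fValues = "numeric", tailProbs = "numeric",
                   ranking = "integer", selected = "integer"))

setValidity("FeatureRanking", function(object) {
    m <- length(object@fValues)
    msg <- character(0)
    if (length(object@tailProbs) != m)
        msg <- c(msg, "tailProbs must match fValues in length")
    if (!identical(sort(object@ranking), seq_len(m)))
        msg <- c(msg, "ranking must be a permutation of item indices")
    if (length(object@selected) > m ||
        !identical(object@selected, head(object@ranking, length(object@selected))))
        msg <- c(msg, "selected must be the leading entries of ranking")
    if (length(msg)) msg else TRUE
})

#' Parameters of the second-order classifier
#'
#' The factorization-machine parameterization: a first-order weight per
#' selected feature, a scalar bias, and an L-by-K matrix of latent factors
#' whose row inner products give the pairwise interaction weights.
#'
#' @slot weights Numeric vector of first-order weights (length L).
#' @slot bias Scalar bias.
#' @slot factors L-by-K numeric matrix of latent factors.
#' @seealso \code{\link{FMParams}}, \code{\link{fmForward}}, \code{\link{fmTrain}}
#' @exportClass FMParams
setClass("FMParams",
    representation(weights = "numeric", bias = "numeric", factors = "matrix"))

setValidity("FMParams", function(object) {
    msg <- character(0)
    if (length(object@bias) != 1L) msg <- c(msg, "bias must be a scalar")
    if (nrow(object@factors) != length(object@weights))
        msg <- c(msg, "factors must have one row per weight")
    if (ncol(object@factors) < 1L || length(object@weights) < 1L)
        msg <- c(msg, "need L >= 1 features and K >= 1 latent factors")
    if (!all(is.finite(object@weights)) || !all(is.finite(object@bias)) ||
        !all(is.finite(object@factors)))
        msg <- c(msg, "all parameters must be finite")
    if (length(msg)) msg else TRUE
})

#' Fitted second-order classification model
#'
#' Bundles everything inference needs: the trained \linkS4class{FMParams},
#' the names of the selected items, and the per-item normalization statistics
#' fitted on the training rows. \code{\link{predictRisk}} (also available as
#' the \code{predict} method) applies the stored transform and never refits
#' anything, so a model archive is self-contained.
#'
#' @slot version Archive format version string.
#' @slot params Trained \linkS4class{FMParams}.
#' @slot itemNames Names of the L selected examination items, in model order.
#' @slot itemMin,itemMax Training-time normalization statistics for those items.
#' @slot seed Integer seed the fit was run under.
#' @slot history Per-epoch loss history (data.frame) from training.
#' @slot config Resolved training configuration (list).
#' @seealso \code{\link{fitModel}}, \code{\link{writeModel}}, \code{\link{readModel}}
#' @exportClass FMModel
setClass("FMModel",
    representation(version = "character", params = "FMParams",
                   itemNames = "character", itemMin = "numeric",
                   itemMax = "numeric", seed = "integer",
                   history = "data.frame", config = "list"))

setValidity("FMModel", function(object) {
    L <- length(object@params@weights)
    if (length(object@itemNames) != L ||
        length(object@itemMin) != L || length(object@itemMax) != L)
        return("itemNames/itemMin/itemMax must match the number of model features")
    if (anyDuplicated(object@itemNames))
        return("selected item names must be unique")
    TRUE
})
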