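#' Examination values in assay orientation
#'
#' @param x An \linkS4class{ExaminationTable}.
#' @return Numeric matrix, items as rows and patients as columns (the assay
#'   orientation). Raw tables hold \code{NA} at missing cells; normalized
#'   tables hold imputed zeros there.
#' @export
setGeneric("examValues", function(x) standardGeneric("examValues"))

#' Missingness mask in modelling orientation
#'
#' @param x An \linkS4class{ExaminationTable}.
#' @return Logical matrix, patients as rows and items as columns; \code{TRUE}
#'   marks a cell that was never measured.
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' Binary diagnosis labels
#'
#' @param x An \linkS4class{ExaminationTable}.
#' @return Named integer vector, 1 for the positive class, 0 otherwise.
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' Feature matrix in modelling orientation
#'
#' @param x An \linkS4class{ExaminationTable}.
#' @return Numeric matrix, patients as rows and items as columns (the
#'   transpose of the \code{"exam"} assay).
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Names of the examination items
#'
#' @param x An \linkS4class{ExaminationTable} or \linkS4class{FMModel}.
#' @return Character vector of item (feature) names.
#' @export
setGeneric("itemNames", function(x) standardGeneric("itemNames"))

#' Selected item indices of a feature ranking
#'
#' @param x A \linkS4class{FeatureRanking}.
#' @return Integer vector of the currently selected item indices (best first).
#' @export
setGeneric("selectedItems", function(x) standardGeneric("selectedItems"))
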