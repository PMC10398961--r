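#' Univariate ANOVA F scores per examination item
#'
#' For each item, computes the one-way two-group ANOVA F statistic
#' F = MS_between / MS_within (df1 = 1, df2 = n - 2, with n the item's
#' non-missing count) comparing the positive and negative diagnosis groups,
#' together with the upper-tail probability of the corresponding F
#' distribution (its survival function). Imputed zeros at masked cells are
#' excluded: only genuinely measured values enter the statistic. With two
#' groups the F statistic is the squared two-sample (pooled) t statistic.
#'
#' Degenerate items are resolved deterministically: zero within-group
#' variance with separated group means gives \code{Inf} (tail probability 0,
#' ranked first); zero within-group variance with equal means gives 0; an
#' item whose measured cells all fall in one diagnosis group gives 0 with a
#' warning (no between-group contrast exists).
#'
#' @param Z A \linkS4class{NormalizedExamTable} (any
#'   \linkS4class{ExaminationTable} works; the statistic is
#'   normalization-invariant up to affine rescaling of each item).
#' @return A \linkS4class{FeatureRanking} with per-item \code{fValues},
#'   \code{tailProbs}, and the ranking permutation (descending F, ties broken
#'   by ascending item index). No items are selected yet; see
#'   \code{\link{selectTopL}}.
#' @examples
#' sim <- simulateExamTable(nPerClass = 40, nItems = 8, seed = 3)
#' rk <- anovaFScores(normalizeTable(sim$table))
#' head(rk@fValues[rk@ranking])
#' @export
anovaFScores <- function(Z) {
    y <- sampleLabels(Z)
    if (length(unique(y)) < 2L)
        stop("both diagnosis groups must be present")
    if (length(y) < 3L)
        stop("need at least 3 patients for a within-group variance")
    vals <- SummarizedExperiment::assay(Z, "exam")
    obs <- !SummarizedExperiment::assay(Z, "missing")
    v <- vals
    v[!obs] <- 0

    grp1 <- y == 1L
    n1 <- rowSums(obs[, grp1, drop = FALSE])
    n0 <- rowSums(obs[, !grp1, drop = FALSE])
    s1 <- rowSums(v[, grp1, drop = FALSE])
    s0 <- rowSums(v[, !grp1, drop = FALSE])
    q1 <- rowSums(v[, grp1, drop = FALSE]^2)
    q0 <- rowSums(v[, !grp1, drop = FALSE]^2)
    n <- n0 + n1

    oneGroup <- n0 == 0L | n1 == 0L
    if (any(oneGroup))
        warning(sprintf("item(s) measured in only one group, F set to 0: %s",
                        paste(rownames(Z)[oneGroup], collapse = ", ")))
    m0 <- ifelse(n0 > 0, s0 / n0, 0)
    m1 <- ifelse(n1 > 0, s1 / n1, 0)
    m <- (s0 + s1) / n
    ssb <- n0 * (m0 - m)^2 + n1 * (m1 - m)^2
    ssw <- pmax((q0 - n0 * m0^2) + (q1 - n1 * m1^2), 0)
    df2 <- n - 2L

    scale <- (q0 + q1) + 1
    zeroWithin <- ssw <= .Machine$double.eps * scale
    f <- numeric(nrow(Z))
    tails <- numeric(nrow(Z))
    ok <- !oneGroup & !zeroWithin & df2 > 0L
    f[ok] <- ssb[ok] / (ssw[ok] / df2[ok])
    tails[ok] <- pf(f[ok], 1, df2[ok], lower.tail = FALSE)
    sep <- !oneGroup & zeroWithin & ssb > .Machine$double.eps * scale
    f[sep] <- Inf
    tails[sep] <- 0
    rest <- !ok & !sep
    f[rest] <- 0
    tails[rest] <- 1
    names(f) <- rownames(Z)

    methods::new("FeatureRanking", fValues = f, tailProbs = tails,
                 ranking = order(-f, seq_along(f)), selected = integer(0))
}

#' Select the top-L items of a ranking
#'
#' Marks the L items with the largest F statistics as selected (ties broken
#' by ascending original item index). The selected set is applied to a table
#' with \code{\link{selectFeatures}}, which slices out the L-column feature
#' matrix fed to the classifier.
#'
#' @param ranking A \linkS4class{FeatureRanking}.
#' @param L Number of items to keep, between 1 and the item count.
#' @return The ranking with its \code{selected} slot set to the top L
#'   indices, best first.
#' @examples
#' rk <- methods::new("FeatureRanking",
#'                    fValues = c(a = 1, b = 3, c = 2),
#'                    tailProbs = c(0.3, 0.1, 0.2),
#'                    ranking = c(2L, 3L, 1L), selected = integer(0))
#' selectedItems(selectTopL(rk, 2))
#' @export
selectTopL <- function(ranking, L) {
    m <- length(ranking@fValues)
    if (length(L) != 1L || !is.finite(L) || L != round(L) || L < 1 || L > m)
        stop(sprintf("L must be an integer in [1, %d]", m))
    ranking@selected <- ranking@ranking[seq_len(L)]
    methods::validObject(ranking)
    ranking
}

#' @rdname selectedItems
#' @aliases selectedItems,FeatureRanking-method
#' @export
setMethod("selectedItems", "FeatureRanking", function(x) x@selected)

setMethod("show", "FeatureRanking", function(object) {
    cat(sprintf("FeatureRanking over %d items; %d selected\n",
                length(object@fValues), length(object@selected)))
    top <- head(object@ranking, 5L)
    cat("top items:", paste(sprintf("%s (F=%.3g)",
        names(object@fValues)[top], object@fValues[top]), collapse = ", "),
        "\n")
})

#' Slice the selected feature matrix out of a table
#'
#' Maps any conforming table to the N-by-L selected feature matrix S, in
#' ranking order, preserving patient order. Column names record the selected
#' item names so a fitted model can later find its features by name.
#'
#' @param table An \linkS4class{ExaminationTable} (normally a
#'   \linkS4class{NormalizedExamTable}).
#' @param ranking A \linkS4class{FeatureRanking} with a non-empty selection.
#' @return Numeric matrix, patients as rows, the L selected items as columns.
#' @export
selectFeatures <- function(table, ranking) {
    if (length(ranking@selected) == 0L)
        stop("no items selected; apply selectTopL first")
    if (length(ranking@fValues) != nrow(table))
        stop("ranking does not match the table's items")
    featureMatrix(table)[, ranking@selected, drop = FALSE]
}
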