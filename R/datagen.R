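#' Simulate a sparse clinical examination table
#'
#' Generates a synthetic patient-by-item table with the statistical structure
#' the second-order classifier assumes: nonnegative item values on wildly
#' heterogeneous scales, heavy completely-at-random missingness, and a binary
#' diagnosis label driven by planted first-order and pairwise-interaction
#' effects. It stands in for a private hospital cohort of roughly 350
#' laboratory items with a few hundred patients per diagnosis group, and lets
#' every downstream stage (normalization, feature selection, training,
#' cross-validation, ablation) be exercised with known ground truth.
#'
#' Item j is drawn as |N(mu_j, sigma_j)| with per-item scale log-uniform over
#' [0.01, 1000], mimicking laboratory panels whose units range from fractions
#' to thousands. The label mechanism is logistic in effects computed on the
#' min-max normalized latent values after standardization over the generated
#' pool (z-scores of the normalized values), so effect sizes are scale-free
#' logit contributions per standard deviation: a planted linear effect
#' contributes beta * a_j and a planted interaction gamma * a_i * a_j, with
#' a the standardized normalized value and each coefficient a random sign
#' times the requested effect size, plus N(0, noiseSd) logit noise. The
#' centering makes planted interactions (near-)orthogonal to first-order
#' signal, so an interaction-only table separates a full second-order model
#' from a purely linear one. Patients are
#' generated until both groups reach \code{nPerClass} and the first
#' \code{nPerClass} of each are kept, so the output is exactly balanced.
#' Missingness is then applied uniformly at random at rate
#' \code{missingRate}, never leaving an item with no measured patient.
#'
#' @param nPerClass Patients per diagnosis group (default 357, the balanced
#'   cohort size the pipeline targets).
#' @param nItems Number of examination items (default 350).
#' @param nInformativeLinear Number of items with a planted first-order
#'   effect (default 25, capped at \code{nItems} for small tables).
#' @param nInteractionPairs Number of distinct item pairs with a planted
#'   pairwise effect (default 10, capped at \code{nItems / 3} for small
#'   tables).
#' @param linearEffectSize,interactionEffectSize Logit-scale magnitudes of
#'   the planted effects, per standard deviation of the (standardized)
#'   normalized item values.
#' @param missingRate Fraction of cells masked, in [0, 1).
#' @param noiseSd Standard deviation of the logit noise (>= 0).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list with \code{table} (an \linkS4class{ExaminationTable} with
#'   \code{2 * nPerClass} patients) and \code{truth}, the generating ground
#'   truth: \code{linearItems}, \code{linearCoef}, \code{pairs} (two-column
#'   index matrix), \code{pairCoef}, and \code{seed}.
#' @examples
#' sim <- simulateExamTable(nPerClass = 30, nItems = 12, seed = 42)
#' sim$table
#' sim$truth$linearItems
#' @export
simulateExamTable <- function(nPerClass = 357L, nItems = 350L,
                              nInformativeLinear = min(25L, nItems),
                              nInteractionPairs = min(10L, nItems %/% 3L),
                              linearEffectSize = 1,
                              interactionEffectSize = 2,
                              missingRate = 0.5, noiseSd = 0.5,
                              seed = 1L) {
    .checkCount <- function(x, nm, min = 0L) {
        if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
            stop(sprintf("invalid configuration: '%s' must be an integer >= %d", nm, min))
    }
    .checkCount(nPerClass, "nPerClass", 1L)
    .checkCount(nItems, "nItems", 1L)
    .checkCount(nInformativeLinear, "nInformativeLinear")
    .checkCount(nInteractionPairs, "nInteractionPairs")
    if (nInformativeLinear > nItems)
        stop("invalid configuration: 'nInformativeLinear' exceeds 'nItems'")
    if (nInteractionPairs > 0L && nItems < 2L)
        stop("invalid configuration: 'nInteractionPairs' needs at least two items")
    if (nInteractionPairs > nItems * (nItems - 1L) / 2L)
        stop("invalid configuration: 'nInteractionPairs' exceeds the number of distinct pairs")
    if (!is.finite(missingRate) || missingRate < 0 || missingRate >= 1)
        stop("invalid configuration: 'missingRate' must lie in [0, 1)")
    if (!is.finite(noiseSd) || noiseSd < 0)
        stop("invalid configuration: 'noiseSd' must be >= 0")
    if (!is.finite(linearEffectSize) || !is.finite(interactionEffectSize))
        stop("invalid configuration: effect sizes must be finite")
    .checkCount(seed, "seed")

    set.seed(seed)
    itemScale <- 10^runif(nItems, -2, 3)
    mu <- itemScale
    sigma <- 0.5 * itemScale

    linIdx <- if (nInformativeLinear > 0L)
        sort(sample.int(nItems, nInformativeLinear)) else integer(0)
    linCoef <- sample(c(-1, 1), nInformativeLinear, replace = TRUE) *
        linearEffectSize
    pairs <- matrix(integer(0), ncol = 2L)
    if (nInteractionPairs > 0L) {
        seen <- character(0)
        pairs <- matrix(0L, nrow = nInteractionPairs, ncol = 2L)
        i <- 1L
        while (i <= nInteractionPairs) {
            p <- sort(sample.int(nItems, 2L))
            key <- paste(p, collapse = "-")
            if (!key %in% seen) {
                seen <- c(seen, key)
                pairs[i, ] <- p
                i <- i + 1L
            }
        }
    }
    pairCoef <- sample(c(-1, 1), nInteractionPairs, replace = TRUE) *
        interactionEffectSize

    # Grow a patient pool until both groups are filled; normalization of the
    # latent values (for the label mechanism) is always computed on the full
    # pool so the generative model is self-consistent.
    nGen <- max(4L * nPerClass, 16L)
    X <- matrix(numeric(0), ncol = nItems)
    repeat {
        nNew <- nGen - nrow(X)
        Xnew <- abs(matrix(rnorm(nNew * nItems, mean = rep(mu, each = nNew),
                                 sd = rep(sigma, each = nNew)),
                           nrow = nNew, ncol = nItems))
        X <- rbind(X, Xnew)
        cmin <- apply(X, 2L, min)
        cmax <- apply(X, 2L, max)
        rng <- pmax(cmax - cmin, .Machine$double.eps)
        Zn <- sweep(sweep(X, 2L, cmin), 2L, rng, "/")
        A <- scale(Zn)
        eta <- drop(A[, linIdx, drop = FALSE] %*% linCoef)
        if (nInteractionPairs > 0L)
            eta <- eta + drop((A[, pairs[, 1L], drop = FALSE] *
                               A[, pairs[, 2L], drop = FALSE]) %*% pairCoef)
        eta <- eta + rnorm(nrow(X), sd = noiseSd)
        y <- rbinom(nrow(X), 1L, plogis(eta))
        if (sum(y == 1L) >= nPerClass && sum(y == 0L) >= nPerClass) break
        nGen <- 2L * nGen
    }
    keep <- sort(c(which(y == 1L)[seq_len(nPerClass)],
                   which(y == 0L)[seq_len(nPerClass)]))
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
    n <- length(keep)

    miss <- matrix(runif(n * nItems) < missingRate, nrow = n)
    allMissing <- which(colSums(!miss) == 0L)
    for (j in allMissing)
        miss[sample.int(n, 1L), j] <- FALSE

    vals <- X
    vals[miss] <- NA_real_
    tab <- ExaminationTable(vals, labels = y,
                            itemNames = sprintf("item_%03d", seq_len(nItems)),
                            sampleIds = sprintf("S%04d", seq_len(n)))
    truth <- list(linearItems = linIdx, linearCoef = linCoef,
                  pairs = pairs, pairCoef = pairCoef, seed = as.integer(seed))
    list(table = tab, truth = truth)
}
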