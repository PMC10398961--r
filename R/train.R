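#' Training configuration
#'
#' Collects the optimization settings of the second-order classifier. The
#' defaults are the reference configuration of the pipeline: Adam with
#' standard moment decay, learning rate 0.01, mini-batches of 32, logit-scale
#' binary cross-entropy, at most 200 epochs with patience-20 early stopping
#' on a validation loss when a validation set is supplied, and K = 10 latent
#' factors.
#'
#' @param learningRate Positive step size (default 0.01).
#' @param batchSize Mini-batch size (default 32); the final short batch of an
#'   epoch is used, not dropped, so small datasets train deterministically.
#' @param maxEpochs Maximum number of epochs (default 200).
#' @param patience Early-stopping patience in epochs, applied only when a
#'   validation set is given (default 20).
#' @param K Number of latent factors of the interaction term (default 10).
#' @param seed Integer seed for initialization and epoch shuffling.
#' @param beta1,beta2,epsilon Adam moment decays and stabilizer.
#' @param initFactorSd Standard deviation of the N(0, sd) factor
#'   initialization (default 0.01); first-order weights and bias start at 0.
#' @return A list of class \code{"trainConfig"}.
#' @export
trainConfig <- function(learningRate = 0.01, batchSize = 32L,
                        maxEpochs = 200L, patience = 20L, K = 10L,
                        seed = 1L, beta1 = 0.9, beta2 = 0.999,
                        epsilon = 1e-8, initFactorSd = 0.01) {
    if (!is.finite(learningRate) || learningRate < 0)
        stop("learningRate must be >= 0")
    if (batchSize < 1L) stop("batchSize must be >= 1")
    if (K < 1L) stop("K must be >= 1")
    structure(list(learningRate = learningRate,
                   batchSize = as.integer(batchSize),
                   maxEpochs = as.integer(maxEpochs),
                   patience = as.integer(patience), K = as.integer(K),
                   seed = as.integer(seed), beta1 = beta1, beta2 = beta2,
                   epsilon = epsilon, initFactorSd = initFactorSd),
              class = "trainConfig")
}

.adamStep <- function(state, grad, cfg) {
    state$t <- state$t + 1L
    state$m <- cfg$beta1 * state$m + (1 - cfg$beta1) * grad
    state$v <- cfg$beta2 * state$v + (1 - cfg$beta2) * grad^2
    mhat <- state$m / (1 - cfg$beta1^state$t)
    vhat <- state$v / (1 - cfg$beta2^state$t)
    state$delta <- cfg$learningRate * mhat / (sqrt(vhat) + cfg$epsilon)
    state
}

#' Train the second-order classifier
#'
#' Mini-batch Adam on the logit-scale binary cross-entropy. Latent factors
#' initialize as N(0, initFactorSd^2) under the configured seed (breaking the
#' symmetry of the interaction term without inflating it); first-order
#' weights and the bias initialize at zero. Epoch order is reshuffled with
#' the seeded generator, so identical seed and data give bit-identical
#' parameter trajectories. When a validation set is supplied, the parameters
#' at the best validation loss are returned and training stops after
#' \code{patience} epochs without improvement; otherwise the final-epoch
#' parameters are returned.
#'
#' For component ablation the two terms can be frozen at zero:
#' \code{freeze = "factors"} trains the first-order-only model and
#' \code{freeze = "linear"} trains the interaction-only model.
#'
#' @param S N-by-L training feature matrix (normalized, selected features).
#' @param y Binary training labels; both classes must be present.
#' @param config A \code{\link{trainConfig}}.
#' @param SVal,yVal Optional validation set for early stopping.
#' @param freeze One of \code{"none"}, \code{"factors"}, \code{"linear"}.
#' @return A list with \code{params} (\linkS4class{FMParams}),
#'   \code{history} (data.frame: epoch, trainLoss, valLoss), and
#'   \code{bestEpoch}.
#' @examples
#' sim <- simulateExamTable(nPerClass = 40, nItems = 6, missingRate = 0,
#'                          linearEffectSize = 4, nInteractionPairs = 0,
#'                          seed = 5)
#' Z <- normalizeTable(sim$table)
#' fit <- fmTrain(featureMatrix(Z), sampleLabels(Z),
#'                trainConfig(maxEpochs = 30, seed = 5))
#' tail(fit$history, 1)
#' @export
fmTrain <- function(S, y, config = trainConfig(), SVal = NULL, yVal = NULL,
                    freeze = c("none", "factors", "linear")) {
    freeze <- match.arg(freeze)
    S <- as.matrix(S)
    n <- nrow(S)
    L <- ncol(S)
    if (length(y) != n) stop("labels must match the feature matrix rows")
    if (length(unique(y)) < 2L)
        stop("training data must contain both classes")
    hasVal <- !is.null(SVal)
    if (hasVal && length(yVal) != nrow(SVal))
        stop("validation labels must match the validation matrix rows")

    set.seed(config$seed)
    w <- numeric(L)
    b <- 0
    V <- if (freeze == "linear" || freeze == "none")
        matrix(rnorm(L * config$K, sd = config$initFactorSd), L, config$K)
    else matrix(0, L, config$K)
    st <- function(x) list(m = x * 0, v = x * 0, t = 0L)
    aw <- st(w); ab <- st(b); aV <- st(V)

    history <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                          valLoss = numeric(0))
    best <- list(loss = Inf, w = w, b = b, V = V, epoch = 0L)
    wait <- 0L
    nBatches <- ceiling(n / config$batchSize)

    for (epoch in seq_len(config$maxEpochs)) {
        perm <- sample.int(n)
        for (bi in seq_len(nBatches)) {
            idx <- perm[(((bi - 1L) * config$batchSize) + 1L):
                        min(bi * config$batchSize, n)]
            gr <- fmGradients(S[idx, , drop = FALSE], y[idx],
                              FMParams(w, b, V))
            if (freeze != "linear") {
                aw <- .adamStep(aw, gr$weights, config)
                w <- w - aw$delta
                ab <- .adamStep(ab, gr$bias, config)
                b <- b - ab$delta
            }
            if (freeze != "factors") {
                aV <- .adamStep(aV, gr$factors, config)
                V <- V - aV$delta
            }
        }
        trainLoss <- bceWithLogits(
            fmForward(S, FMParams(w, b, V))$o, y)
        valLoss <- if (hasVal)
            bceWithLogits(fmForward(as.matrix(SVal), FMParams(w, b, V))$o,
                          yVal) else NA_real_
        if (!is.finite(trainLoss))
            stop(sprintf("non-finite training loss at epoch %d (lr=%g); aborting",
                         epoch, config$learningRate))
        history <- rbind(history, data.frame(epoch = epoch,
                                             trainLoss = trainLoss,
                                             valLoss = valLoss))
        if (hasVal) {
            if (valLoss < best$loss) {
                best <- list(loss = valLoss, w = w, b = b, V = V,
                             epoch = epoch)
                wait <- 0L
            } else {
                wait <- wait + 1L
                if (wait >= config$patience) break
            }
        }
    }
    if (hasVal && best$epoch > 0L) {
        w <- best$w; b <- best$b; V <- best$V
        bestEpoch <- best$epoch
    } else bestEpoch <- nrow(history)
    list(params = FMParams(w, b, V), history = history,
         bestEpoch = bestEpoch)
}

#' Stratified split of training rows for early stopping
#'
#' @param y Binary labels.
#' @param fraction Fraction held out per class (rounded down, at least 1 when
#'   possible).
#' @param seed Integer seed.
#' @return Integer vector of held-out row indices (possibly empty).
#' @keywords internal
.valSplit <- function(y, fraction, seed) {
    if (fraction <= 0) return(integer(0))
    set.seed(seed)
    out <- integer(0)
    for (cls in unique(y)) {
        idx <- which(y == cls)
        k <- max(1L, floor(fraction * length(idx)))
        if (k >= length(idx)) next
        out <- c(out, sample(idx, k))
    }
    sort(out)
}
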