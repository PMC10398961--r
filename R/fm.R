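#' Construct second-order classifier parameters
#'
#' @param weights Numeric vector of first-order weights (length L).
#' @param bias Scalar bias.
#' @param factors L-by-K matrix of latent factors; the interaction weight of
#'   feature pair (i, j) is the inner product of rows i and j.
#' @return An \linkS4class{FMParams} object.
#' @examples
#' FMParams(weights = c(0.5, -1), bias = 0.1,
#'          factors = matrix(0, nrow = 2, ncol = 3))
#' @export
FMParams <- function(weights, bias = 0, factors) {
    methods::new("FMParams", weights = as.numeric(weights),
                 bias = as.numeric(bias), factors = as.matrix(factors))
}

.checkS <- function(S, L) {
    S <- as.matrix(S)
    if (ncol(S) != L)
        stop(sprintf("feature matrix has %d columns but the model expects %d",
                     ncol(S), L))
    S
}

#' First-order (linear) score
#'
#' E_n = sum_i S[n, i] * w[i] + b: the linear-regression component of the
#' classifier, capturing direct feature-outcome associations.
#'
#' @param S N-by-L feature matrix (patients as rows).
#' @param params An \linkS4class{FMParams}.
#' @return Numeric N-vector of linear scores.
#' @examples
#' p <- FMParams(c(0.5, -1), 0.1, matrix(0, 2, 1))
#' firstOrder(matrix(c(1, 2), nrow = 1), p)   # -1.4
#' @export
firstOrder <- function(S, params) {
    S <- .checkS(S, length(params@weights))
    unname(drop(S %*% params@weights)) + params@bias
}

#' Second-order (pairwise cross-feature) score
#'
#' Computes the factorization-machine interaction score
#' R_n = sum_{i<j} <v_i, v_j> S[n,i] S[n,j] in O(L*K) per patient via the
#' square-of-sum minus sum-of-squares identity: with C1 = (S V) had (S V) and
#' C2 = (S had S)(V had V) (had = elementwise product),
#' R_n = 1/2 * sum_k (C1[n,k] - C2[n,k]). With a single feature (L = 1) there
#' are no pairs and the score is exactly zero.
#'
#' @param S N-by-L feature matrix.
#' @param factors L-by-K latent factor matrix (or an
#'   \linkS4class{FMParams}, whose factors are used).
#' @return Numeric N-vector of interaction scores.
#' @examples
#' secondOrder(matrix(c(1, 1), nrow = 1), matrix(c(1, 1), nrow = 2))  # 1
#' @export
secondOrder <- function(S, factors) {
    if (methods::is(factors, "FMParams")) factors <- factors@factors
    factors <- as.matrix(factors)
    S <- .checkS(S, nrow(factors))
    SV <- S %*% factors
    unname(0.5 * (rowSums(SV * SV) -
                  drop((S * S) %*% (factors * factors) %*%
                       rep(1, ncol(factors)))))
}

#' Forward pass of the second-order classifier
#'
#' Chains the two score components and the decision head: logits O = E + R,
#' probabilities P = sigmoid(O), and hard labels Yhat = 1 exactly when
#' P >= 0.5 (the boundary goes to the positive class).
#'
#' @param S N-by-L feature matrix.
#' @param params An \linkS4class{FMParams}.
#' @return A data.frame with columns \code{e}, \code{r}, \code{o}, \code{p},
#'   \code{yhat}, one row per patient; \code{o} is exactly \code{e + r}.
#' @examples
#' p <- FMParams(c(0, 0), 0, matrix(0, 2, 2))
#' fmForward(matrix(1, 1, 2), p)   # o = 0, p = 0.5, yhat = 1
#' @export
fmForward <- function(S, params) {
    e <- firstOrder(S, params)
    r <- secondOrder(S, params@factors)
    o <- e + r
    p <- plogis(o)
    data.frame(e = e, r = r, o = o, p = p,
               yhat = as.integer(p >= 0.5))
}

#' Binary cross-entropy on logits
#'
#' Mean over samples of log(1 + exp(-(2y - 1) O)), evaluated in the
#' numerically stable form max(O, 0) - O y + log1p(exp(-|O|)); no overflow
#' for logits up to magnitude ~1e3 and beyond.
#'
#' @param o Numeric vector of logits.
#' @param y Binary labels (0/1), same length.
#' @return Scalar mean loss.
#' @examples
#' bceWithLogits(0, 1)    # log(2)
#' bceWithLogits(50, 1)   # ~ 0
#' @export
bceWithLogits <- function(o, y) {
    if (length(o) != length(y))
        stop("logits and labels must have equal length")
    if (anyNA(y) || !all(y %in% c(0, 1)))
        stop("labels must be 0 or 1")
    mean(pmax(o, 0) - o * y + log1p(exp(-abs(o))))
}

#' Analytic gradients of the mean loss
#'
#' Closed-form gradient of \code{\link{bceWithLogits}} composed with the
#' forward pass, averaged over the batch: with g_n = (P_n - y_n) / N,
#' d/dw = S' g, d/db = sum(g), and
#' d/dV[i,k] = sum_n g_n (S[n,i] (S V)[n,k] - V[i,k] S[n,i]^2).
#'
#' @param S N-by-L feature matrix.
#' @param y Binary labels.
#' @param params An \linkS4class{FMParams}.
#' @return List with components \code{weights}, \code{bias}, \code{factors}
#'   matching the parameter shapes.
#' @export
fmGradients <- function(S, y, params) {
    S <- .checkS(S, length(params@weights))
    V <- params@factors
    SV <- S %*% V
    o <- drop(S %*% params@weights) + params@bias +
        0.5 * (rowSums(SV * SV) - drop((S * S) %*% (V * V) %*% rep(1, ncol(V))))
    g <- (plogis(o) - y) / length(y)
    list(weights = unname(drop(crossprod(S, g))),
         bias = sum(g),
         factors = unname(crossprod(S, SV * g) -
                          V * drop(crossprod(S * S, g))))
}
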