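# Independent oracles and small fixture builders shared across tests.

# O(L^2) brute-force pairwise interaction sum: sum_{i<j} <v_i, v_j> x_i x_j.
bruteForceSecondOrder <- function(S, V) {
    n <- nrow(S)
    L <- ncol(S)
    out <- numeric(n)
    if (L < 2L) return(out)
    for (m in seq_len(n)) {
        for (i in seq_len(L - 1L)) {
            for (j in (i + 1L):L) {
                out[m] <- out[m] + sum(V[i, ] * V[j, ]) * S[m, i] * S[m, j]
            }
        }
    }
    out
}

# Explicit between/within mean-squares F for one two-group column.
bruteForceF <- function(x, g) {
    x0 <- x[g == 0]
    x1 <- x[g == 1]
    n0 <- length(x0)
    n1 <- length(x1)
    n <- n0 + n1
    m0 <- mean(x0)
    m1 <- mean(x1)
    m <- mean(x)
    ssb <- n0 * (m0 - m)^2 + n1 * (m1 - m)^2
    ssw <- sum((x0 - m0)^2) + sum((x1 - m1)^2)
    (ssb / 1) / (ssw / (n - 2))
}

# Central finite differences of the mean BCE loss in every parameter.
finiteDiffGradients <- function(S, y, params, h = 1e-6) {
    f <- function(w, b, V)
        bceWithLogits(fmForward(S, FMParams(w, b, V))$o, y)
    w <- params@weights
    b <- params@bias
    V <- params@factors
    gw <- vapply(seq_along(w), function(i) {
        wp <- w; wm <- w
        wp[i] <- w[i] + h
        wm[i] <- w[i] - h
        (f(wp, b, V) - f(wm, b, V)) / (2 * h)
    }, numeric(1))
    gb <- (f(w, b + h, V) - f(w, b - h, V)) / (2 * h)
    gV <- V * 0
    for (i in seq_len(nrow(V))) {
        for (k in seq_len(ncol(V))) {
            Vp <- V; Vm <- V
            Vp[i, k] <- V[i, k] + h
            Vm[i, k] <- V[i, k] - h
            gV[i, k] <- (f(w, b, Vp) - f(w, b, Vm)) / (2 * h)
        }
    }
    list(weights = gw, bias = gb, factors = gV)
}

normRelErr <- function(a, b) {
    max(abs(a - b)) / max(abs(b), 1e-8)
}

# Small deterministic table built in code (no fixture files).
toyTable <- function(values, labels, itemNames = NULL) {
    if (is.null(itemNames))
        itemNames <- sprintf("it%02d", seq_len(ncol(values)))
    ExaminationTable(values, labels = labels, itemNames = itemNames,
                     sampleIds = sprintf("s%03d", seq_len(nrow(values))))
}

# Printed component-ablation metric rows used by the improvement arithmetic.
ablationTableRows <- function() {
    list(firstOrder = c(accuracy = 0.8067, precision = 0.8022,
                        recall = 0.8606, f1 = 0.8303),
         secondOrder = c(accuracy = 0.8167, precision = 0.8362,
                         recall = 0.8303, f1 = 0.8327),
         full = c(accuracy = 0.8900, precision = 0.8837,
                  recall = 0.9212, f1 = 0.9020))
}
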