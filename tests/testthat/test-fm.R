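test_that("the first-order term is the row-wise affine score", {
    p <- FMParams(c(0, 0), bias = 0.7, factors = matrix(0, 2, 2))
    expect_equal(firstOrder(matrix(rnorm(6), 3, 2), p), rep(0.7, 3))

    p2 <- FMParams(c(0.5, -1), bias = 0.1, factors = matrix(0, 2, 1))
    expect_equal(firstOrder(matrix(c(1, 2), 1, 2), p2), -1.4)

    set.seed(1)
    for (rep in 1:20) {
        n <- sample(1:8, 1); L <- sample(1:10, 1)
        S <- matrix(rnorm(n * L), n, L)
        w <- rnorm(L); b <- rnorm(1)
        p3 <- FMParams(w, b, matrix(0, L, 1))
        oracle <- vapply(seq_len(n),
                         function(i) sum(S[i, ] * w) + b, numeric(1))
        expect_equal(firstOrder(S, p3), oracle, tolerance = 1e-12)
    }
    expect_error(firstOrder(matrix(0, 1, 3), p2), "expects 2")
})

test_that("the O(LK) interaction term equals the brute-force pairwise sum", {
    # zero factors and a single feature both give exactly zero
    expect_equal(secondOrder(matrix(rnorm(8), 4, 2), matrix(0, 2, 3)),
                 rep(0, 4))
    expect_equal(secondOrder(matrix(rnorm(4), 4, 1),
                             matrix(rnorm(3), 1, 3)),
                 rep(0, 4))
    # hand-computed instance: C1 = 4, C2 = 2, R = 1
    expect_equal(secondOrder(matrix(c(1, 1), 1, 2), matrix(c(1, 1), 2, 1)), 1)

    set.seed(2)
    for (rep in 1:100) {
        n <- sample(1:6, 1); L <- sample(2:8, 1); K <- sample(1:5, 1)
        S <- matrix(rnorm(n * L), n, L)
        V <- matrix(rnorm(L * K), L, K)
        expect_equal(secondOrder(S, V), bruteForceSecondOrder(S, V),
                     tolerance = 1e-9)
    }
})

test_that("the forward pass composes the two terms with a sigmoid head", {
    p0 <- FMParams(c(0, 0), 0, matrix(0, 2, 2))
    out0 <- fmForward(matrix(1, 1, 2), p0)
    expect_equal(out0$o, 0)
    expect_equal(out0$p, 0.5)
    expect_identical(out0$yhat, 1L)   # boundary goes to the positive class

    pb <- FMParams(c(log(3), 0), 0, matrix(0, 2, 1))
    expect_equal(fmForward(matrix(c(1, 0), 1, 2), pb)$p, 0.75)

    set.seed(3)
    for (rep in 1:10) {
        n <- sample(1:5, 1); L <- sample(2:6, 1); K <- sample(1:4, 1)
        S <- matrix(rnorm(n * L), n, L)
        p <- FMParams(rnorm(L), rnorm(1), matrix(rnorm(L * K), L, K))
        out <- fmForward(S, p)
        e <- firstOrder(S, p)
        r <- secondOrder(S, p@factors)
        expect_identical(out$o, e + r)                      # exact additivity
        expect_equal(out$p, 1 / (1 + exp(-(e + r))), tolerance = 1e-12)
        expect_identical(out$yhat, as.integer(out$p >= 0.5))
    }
})

test_that("component zeroing isolates each term exactly", {
    set.seed(4)
    S <- matrix(rnorm(12), 4, 3)
    w <- rnorm(3); b <- rnorm(1); V <- matrix(rnorm(6), 3, 2)
    expect_identical(fmForward(S, FMParams(w, b, V * 0))$o,
                     firstOrder(S, FMParams(w, b, V * 0)))
    expect_identical(fmForward(S, FMParams(w * 0, 0, V))$o,
                     secondOrder(S, V))
})

test_that("probability is strictly increasing in the logit", {
    o <- sort(rnorm(100, sd = 5))
    p <- fmForward(matrix(o, ncol = 1),
                   FMParams(1, 0, matrix(0, 1, 1)))$p
    expect_true(all(diff(p) > 0))
})

test_that("logit-scale cross entropy is exact, stable, and validated", {
    expect_equal(bceWithLogits(0, 1), log(2))
    expect_lt(bceWithLogits(50, 1), 1e-20)
    expect_true(is.finite(bceWithLogits(c(-1000, 1000), c(1, 0))))

    set.seed(5)
    for (rep in 1:20) {
        n <- sample(1:20, 1)
        o <- runif(n, -20, 20)
        y <- rbinom(n, 1, 0.5)
        p <- plogis(o)
        naive <- -mean(y * log(p) + (1 - y) * log(1 - p))
        # the naive form itself loses ~1e-8 relative precision near |o| = 20
        # (catastrophic cancellation in 1 - p), so compare at 1e-7
        expect_equal(bceWithLogits(o, y), naive, tolerance = 1e-7)
    }
    expect_error(bceWithLogits(c(0, 1), c(1, 2)), "labels")
    expect_error(bceWithLogits(c(0, 1), 1), "length")
})

test_that("analytic gradients match central finite differences", {
    set.seed(6)
    for (rep in 1:15) {
        n <- sample(2:8, 1); L <- sample(2:5, 1); K <- sample(1:4, 1)
        S <- matrix(rnorm(n * L), n, L)
        y <- rbinom(n, 1, 0.5)
        p <- FMParams(rnorm(L), rnorm(1),
                      matrix(rnorm(L * K, sd = 0.5), L, K))
        ga <- fmGradients(S, y, p)
        gn <- finiteDiffGradients(S, y, p)
        for (nm in names(ga))
            expect_lt(normRelErr(ga[[nm]], gn[[nm]]), 1e-5)
    }
})

test_that("gradients match a hand-computed single-sample instance", {
    # one sample, L = 2, K = 1: o = w1 s1 + w2 s2 + b + v1 v2 s1 s2
    s1 <- 2; s2 <- -1
    w <- c(0.5, -0.25); b <- 0.1; v <- c(0.3, -0.2)
    o <- w[1] * s1 + w[2] * s2 + b + v[1] * v[2] * s1 * s2
    pr <- plogis(o)
    y <- 1
    g <- pr - y
    ga <- fmGradients(matrix(c(s1, s2), 1, 2), y,
                      FMParams(w, b, matrix(v, 2, 1)))
    expect_equal(ga$weights, g * c(s1, s2), tolerance = 1e-12)
    expect_equal(ga$bias, g, tolerance = 1e-12)
    expect_equal(drop(ga$factors), g * c(v[2] * s1 * s2, v[1] * s1 * s2),
                 tolerance = 1e-12)
})

test_that("gradients vanish at a saturated correct fit", {
    S <- matrix(c(1, -1), 2, 1) * 100
    y <- c(1, 0)
    p <- FMParams(1, 0, matrix(0, 1, 1))   # logits +-100, both correct
    g <- fmGradients(S, y, p)
    expect_lt(max(abs(unlist(g))), 1e-8)
})

test_that("training fits a linearly separable fixture to zero error", {
    set.seed(7)
    n <- 120
    x <- c(rnorm(n / 2, -2, 0.3), rnorm(n / 2, 2, 0.3))
    y <- rep(c(0L, 1L), each = n / 2)
    S <- cbind(x, rnorm(n, sd = 0.1))
    fit <- fmTrain(S, y, trainConfig(seed = 1, maxEpochs = 200))
    expect_lt(tail(fit$history$trainLoss, 1), 0.1)
    expect_equal(mean(fmForward(S, fit$params)$yhat == y), 1.0)
})

test_that("training is deterministic and inert at zero learning rate", {
    set.seed(8)
    S <- matrix(rnorm(60), 20, 3)
    y <- rbinom(20, 1, 0.5)
    y[1:2] <- c(0L, 1L)
    f1 <- fmTrain(S, y, trainConfig(seed = 3, maxEpochs = 15))
    f2 <- fmTrain(S, y, trainConfig(seed = 3, maxEpochs = 15))
    expect_identical(f1$history, f2$history)
    expect_identical(f1$params@factors, f2$params@factors)

    f0 <- fmTrain(S, y, trainConfig(seed = 3, maxEpochs = 5,
                                    learningRate = 0))
    set.seed(3)
    V0 <- matrix(rnorm(3 * 10, sd = 0.01), 3, 10)
    expect_identical(f0$params@weights, rep(0, 3))
    expect_identical(f0$params@bias, 0)
    expect_identical(f0$params@factors, V0)

    expect_error(fmTrain(S, rep(1L, 20), trainConfig()), "both classes")
})

test_that("frozen components stay at zero during ablation training", {
    set.seed(9)
    S <- matrix(rnorm(80), 20, 4)
    y <- rep(c(0L, 1L), 10)
    fFirst <- fmTrain(S, y, trainConfig(seed = 1, maxEpochs = 10),
                      freeze = "factors")
    expect_true(all(fFirst$params@factors == 0))
    expect_false(all(fFirst$params@weights == 0))
    fSecond <- fmTrain(S, y, trainConfig(seed = 1, maxEpochs = 10),
                       freeze = "linear")
    expect_true(all(fSecond$params@weights == 0))
    expect_identical(fSecond$params@bias, 0)
    expect_false(all(fSecond$params@factors == 0))
})

test_that("prediction reproduces training-time scores and is name-based", {
    sim <- simulateExamTable(nPerClass = 30, nItems = 10, missingRate = 0.2,
                             seed = 10)
    mod <- fitModel(sim$table, L = 5, config = trainConfig(maxEpochs = 15))
    pred <- predictRisk(mod, sim$table)
    # recompute the training-time forward pass by hand
    z <- normalizeTable(sim$table)
    S <- featureMatrix(z)[, match(itemNames(mod), itemNames(z)), drop = FALSE]
    expect_equal(pred$p, fmForward(S, mod@params)$p, tolerance = 1e-12)

    # permuting item order leaves predictions identical (selection by name)
    perm <- sample(nrow(sim$table))
    permTab <- sim$table[perm, ]
    predPerm <- predictRisk(mod, permTab)
    expect_identical(pred$p, predPerm$p)

    # predict is an alias
    expect_identical(predict(mod, sim$table)$p, pred$p)

    # a missing required item errors by name
    drop1 <- sim$table[setdiff(itemNames(sim$table), itemNames(mod)[1]), ]
    expect_error(predictRisk(mod, drop1), itemNames(mod)[1])
})

test_that("an all-missing patient scores sigmoid(bias)", {
    sim <- simulateExamTable(nPerClass = 20, nItems = 6, missingRate = 0,
                             seed = 12)
    mod <- fitModel(sim$table, L = 3, config = trainConfig(maxEpochs = 10))
    vals <- matrix(NA_real_, nrow = 2, ncol = 6,
                   dimnames = list(NULL, itemNames(sim$table)))
    vals[2, ] <- 1   # second patient keeps the table valid columns-wise
    newTab <- ExaminationTable(vals, labels = c(0, 1),
                               itemNames = itemNames(sim$table),
                               sampleIds = c("p1", "p2"))
    pred <- predictRisk(mod, newTab)
    expect_equal(pred$p[1], plogis(mod@params@bias), tolerance = 1e-12)
})

test_that("model archives round-trip bit-exactly", {
    sim <- simulateExamTable(nPerClass = 20, nItems = 8, seed = 13)
    mod <- fitModel(sim$table, L = 4, config = trainConfig(maxEpochs = 10))
    path <- tempfile(fileext = ".json")
    writeModel(mod, path)
    back <- readModel(path)
    expect_identical(back@params@weights, mod@params@weights)
    expect_identical(back@params@bias, mod@params@bias)
    expect_identical(back@params@factors, unname(mod@params@factors))
    expect_identical(back@itemNames, mod@itemNames)
    expect_identical(back@itemMin, mod@itemMin)
    expect_identical(back@itemMax, mod@itemMax)
    # predictions from the restored archive are identical
    expect_identical(predictRisk(back, sim$table)$p,
                     predictRisk(mod, sim$table)$p)
})
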