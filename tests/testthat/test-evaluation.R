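test_that("confusion counts follow the positive-class convention", {
    cc <- confusionCounts(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 1, 0, 0))
    expect_identical(cc, c(tp = 3L, tn = 2L, fp = 1L, fn = 0L))

    perfect <- confusionCounts(c(1, 0, 1), c(1, 0, 1))
    expect_identical(perfect[["fp"]], 0L)
    expect_identical(perfect[["fn"]], 0L)

    allOnes <- confusionCounts(c(1, 0, 0, 1), rep(1, 4))
    expect_identical(allOnes[["tn"]], 0L)
    expect_identical(allOnes[["fp"]], 2L)

    expect_error(confusionCounts(c(1, 2), c(1, 0)), "binary")
    expect_error(confusionCounts(c(1, 0), c(1, 0, 1)), "length")
})

test_that("metrics compute the standard ratios with degenerate-case fallbacks", {
    m <- classMetrics(c(tp = 3, tn = 2, fp = 1, fn = 0))
    expect_equal(m$accuracy, 5 / 6)
    expect_equal(m$precision, 0.75)
    expect_equal(m$recall, 1.0)
    expect_equal(m$f1, 6 / 7)

    expect_warning(m0 <- classMetrics(c(tp = 0, tn = 5, fp = 0, fn = 2)),
                   "precision")
    expect_equal(m0$precision, 0)

    set.seed(1)
    for (rep in 1:50) {
        cc <- c(tp = sample(1:30, 1), tn = sample(1:30, 1),
                fp = sample(1:30, 1), fn = sample(1:30, 1))
        m <- classMetrics(cc)
        total <- sum(cc)
        expect_equal(m$accuracy, (cc[["tp"]] + cc[["tn"]]) / total)
        # F1 is the harmonic mean of precision and recall
        expect_equal(m$f1, 2 / (1 / m$precision + 1 / m$recall),
                     tolerance = 1e-12)
        expect_true(all(unlist(m[c("accuracy", "precision",
                                   "recall", "f1")]) >= 0 &
                        unlist(m[c("accuracy", "precision",
                                   "recall", "f1")]) <= 1))
    }
})

test_that("stratified folds partition the cohort evenly", {
    y <- rep(c(0L, 1L), each = 357)
    f <- stratifiedFolds(y, k = 5, seed = 1)
    expect_identical(sort(unique(f)), 1:5)
    sizes <- as.integer(table(f))
    expect_identical(sort(sizes, decreasing = TRUE),
                     c(143L, 143L, 143L, 143L, 142L))
    # stratification within +-1 per class
    for (cls in 0:1) {
        cnt <- table(f[y == cls])
        expect_lte(max(cnt) - min(cnt), 1)
    }
    # every sample in exactly one fold is implied by f being a full vector
    expect_identical(length(f), length(y))
    expect_identical(stratifiedFolds(y, 5, seed = 1), f)   # determinism
    expect_false(identical(stratifiedFolds(y, 5, seed = 2), f))
    expect_error(stratifiedFolds(c(0L, 1L), k = 5), "at least")
})

test_that("fold partition properties hold across random label vectors", {
    set.seed(2)
    for (rep in 1:25) {
        n1 <- sample(5:60, 1)
        n0 <- sample(5:60, 1)
        y <- sample(c(rep(0L, n0), rep(1L, n1)))
        f <- stratifiedFolds(y, k = 5, seed = rep)
        expect_identical(sort(unique(f)), 1:5)
        expect_lte(max(table(f)) - min(table(f)), 1)
        for (cls in 0:1)
            expect_lte(max(table(f[y == cls])) - min(table(f[y == cls])), 1)
    }
})

test_that("per-fold metrics are invariant to a carried row permutation", {
    set.seed(3)
    y <- rbinom(40, 1, 0.5)
    yhat <- rbinom(40, 1, 0.5)
    folds <- stratifiedFolds(y, 5, seed = 1)
    perm <- sample(40)
    for (f in 1:5) {
        a <- classMetrics(confusionCounts(y[folds == f], yhat[folds == f]))
        b <- classMetrics(confusionCounts(y[perm][folds[perm] == f],
                                          yhat[perm][folds[perm] == f]))
        expect_equal(a, b)
    }
})

test_that("cross-validation is deterministic and leak-free in fold scope", {
    sim <- simulateExamTable(nPerClass = 30, nItems = 8, seed = 5)
    cfg <- trainConfig(maxEpochs = 10, seed = 5)
    cv1 <- crossValidate(sim$table, L = 4, config = cfg, seed = 5)
    cv2 <- crossValidate(sim$table, L = 4, config = cfg, seed = 5)
    expect_identical(cv1$perFold, cv2$perFold)
    expect_identical(cv1$folds, cv2$folds)
    # every patient is predicted exactly once
    expect_false(anyNA(cv1$predictions$p))
    expect_identical(sort(unique(cv1$folds)), 1:5)
    # mean metrics are the column means of the fold rows
    expect_equal(unname(cv1$meanMetrics["accuracy"]),
                 mean(cv1$perFold$accuracy))
})

test_that("relative improvement reproduces the printed ablation arithmetic", {
    rows <- ablationTableRows()
    imp <- relativeImprovement(rows$full, rows$secondOrder)
    expect_equal(unname(round(imp, 2)), c(8.98, 5.68, 10.95, 8.32))

    expect_equal(unname(relativeImprovement(rows$full, rows$full)),
                 rep(0, 4))

    set.seed(4)
    for (rep in 1:20) {
        a <- runif(4, 0.1, 1)
        b <- runif(4, 0.1, 1)
        names(a) <- names(b) <- c("accuracy", "precision", "recall", "f1")
        expect_equal(unname(relativeImprovement(a, b)), 100 * (a - b) / b,
                     ignore_attr = TRUE, tolerance = 1e-12)
    }
    bad <- c(accuracy = 0, precision = 1, recall = 1, f1 = 1)
    expect_error(relativeImprovement(rows$full, bad), "positive")
})

test_that("ablation reuses identical folds and reports the improvement", {
    sim <- simulateExamTable(nPerClass = 25, nItems = 6, seed = 6)
    ab <- ablate(sim$table, L = 6, config = trainConfig(maxEpochs = 8),
                 seed = 6)
    expect_identical(rownames(ab$rows), c("first-order", "second-order",
                                          "full"))
    expect_identical(ab$cv$firstOrder$folds, ab$cv$full$folds)
    expect_identical(ab$cv$secondOrder$folds, ab$cv$full$folds)
    expect_equal(ab$improvement,
                 relativeImprovement(ab$rows["full", ],
                                     ab$rows["second-order", ]))
    # component freezing really reached the trainer
    expect_identical(ab$cv$firstOrder$freeze, "factors")
    expect_identical(ab$cv$secondOrder$freeze, "linear")
})

test_that("the coarse/fine feature-number search matches exhaustive search", {
    # synthetic single-peak accuracy landscapes over <= 60 candidate L
    landscape <- function(M, peak, width)
        function(L) 0.9 - ((L - peak) / width)^2
    set.seed(7)
    for (rep in 1:10) {
        M <- sample(30:60, 1)
        peak <- sample(5:(M - 3), 1)
        acc <- landscape(M, peak, M)
        sr <- searchFeatureNumber(LRange = c(1L, M), evaluator = acc)
        exhaustive <- which.max(vapply(1:M, acc, numeric(1)))
        expect_identical(sr$chosenL, as.integer(exhaustive))
    }

    # monotone-increasing accuracy returns the upper bound
    up <- searchFeatureNumber(LRange = c(1L, 47L),
                              evaluator = function(L) 0.5 + 0.005 * L)
    expect_identical(up$chosenL, 47L)

    # exact ties resolve to the smaller L
    tied <- searchFeatureNumber(LRange = c(1L, 30L),
                                evaluator = function(L)
                                    if (L %in% c(8, 12)) 0.9 else 0.5)
    expect_identical(tied$chosenL, 8L)

    expect_error(searchFeatureNumber(LRange = c(5L, 2L),
                                     evaluator = function(L) 0.5),
                 "LRange")
})
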