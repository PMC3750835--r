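test_that("binormal ROC matches its closed form and preserves orientation", {
    # moment injection: mu0 = 0, sd0 = 1, mu1 = sqrt(2), sd1 = 1
    roc <- binormalROCFromMoments(0, 1, sqrt(2), 1)
    expect_equal(roc@Az, pnorm(1), tolerance = 1e-12)
    expect_equal(roc@a, sqrt(2), tolerance = 1e-12)
    expect_equal(roc@b, 1, tolerance = 1e-12)
    expect_gte(nrow(roc@curve), 201)

    # identical samples: Az exactly 0.5
    set.seed(1)
    x <- rnorm(50)
    expect_equal(binormalROC(x, x)@Az, 0.5, tolerance = 1e-15)

    # orientation is not auto-flipped: lower cancer scores give Az < 0.5
    set.seed(2)
    expect_lt(binormalROC(rnorm(100, -1), rnorm(100, 1))@Az, 0.5)

    expect_error(binormalROC(c(1, 1, 1), rnorm(10)), "zero variance")
    expect_error(binormalROC(1, rnorm(10)), "at least 2")
})

test_that("binormal Az converges to the population value on Gaussian samples", {
    set.seed(77)
    n <- 1e4
    mu0 <- 0; sd0 <- 1; mu1 <- 1.2; sd1 <- 1.5
    healthy <- rnorm(n, mu0, sd0)
    cancer <- rnorm(n, mu1, sd1)
    target <- pnorm((mu1 - mu0) / sqrt(sd0^2 + sd1^2))
    roc <- binormalROC(cancer, healthy)
    expect_equal(roc@Az, target, tolerance = 0.01)
    # nonparametric cross-check: empirical AUC within 0.02 of binormal Az
    expect_equal(empiricalROC(cancer, healthy)$auc, roc@Az, tolerance = 0.02)
})

test_that("empirical AUC is the scaled Mann-Whitney statistic", {
    # hand-enumerated pairs: {3,5} vs {1,4} -> wins 3 of 4
    expect_equal(empiricalROC(c(3, 5), c(1, 4))$auc, 0.75)
    expect_equal(empiricalROC(c(3, 5), c(1, 4))$auc, pairCountAUC(c(3, 5), c(1, 4)))

    expect_equal(empiricalROC(c(5, 6), c(1, 2))$auc, 1.0)   # separated
    expect_equal(empiricalROC(rep(2, 5), rep(2, 7))$auc, 0.5)  # all ties

    set.seed(8)
    cancer <- sample(1:10, 15, replace = TRUE)
    healthy <- sample(1:10, 12, replace = TRUE)
    expect_equal(empiricalROC(cancer, healthy)$auc,
                 pairCountAUC(cancer, healthy))
    # independent library oracle on the same scores
    if (requireNamespace("pROC", quietly = TRUE)) {
        expect_equal(empiricalROC(cancer, healthy)$auc,
                     as.numeric(pROC::auc(pROC::roc(
                         response = rep(c(1, 0), c(15, 12)),
                         predictor = c(cancer, healthy), quiet = TRUE,
                         direction = "<"))))
    }
    expect_error(empiricalROC(numeric(0), 1:3), "nonempty")
})

test_that("empirical AUC is invariant under strictly increasing transforms", {
    set.seed(13)
    cancer <- rlnorm(200, 1); healthy <- rlnorm(300, 0.3)
    base <- empiricalROC(cancer, healthy)$auc
    for (f in list(function(x) 3 * x + 2, log, sqrt, function(x) x^3))
        expect_equal(empiricalROC(f(cancer), f(healthy))$auc, base)
})

test_that("Fisher separability follows the mean-gap formula", {
    set.seed(3)
    x <- rnorm(500)
    expect_lt(separability(x, x), 0.01)   # identical distributions ~ 0
    # exact moments via degenerate-free construction
    expect_equal(separability(c(1, 3), c(-1, 1)), 4 / (2 + 2))
    # monotone in the mean gap at fixed variances
    seps <- vapply(seq(0, 3, by = 0.5), function(gap)
        separability(x + gap, x), numeric(1))
    expect_true(all(diff(seps) >= 0))
    expect_error(separability(rep(1, 3), rep(1, 4)), "zero total variance")
})

test_that("ML classifier pools voxels and uses biased-denominator SDs", {
    mk <- function(vals, labs, id = "c1") {
        caseData(id, scalarMap(array(vals, c(length(vals), 1, 1))),
                 labelMap(array(labs, c(length(labs), 1, 1))))
    }
    # degenerate classes trigger the SD floor (logged)
    expect_message(
        model <- fitMLClassifier(list(mk(c(1, 1, 1, 3, 3, 3),
                                         c(1L, 1L, 1L, 2L, 2L, 2L)))),
        "SD floor")
    expect_identical(unname(model@classMeans), c(1, 3))
    expect_true(all(model@classSDs > 0))

    # duplication idempotence: pooling two identical cases changes nothing
    set.seed(10)
    vals <- c(rnorm(20, 11), rnorm(20, 13))
    labs <- rep(c(1L, 2L), each = 20)
    m1 <- fitMLClassifier(list(mk(vals, labs)))
    m2 <- fitMLClassifier(list(mk(vals, labs, "a"), mk(vals, labs, "b")))
    expect_equal(m1@classMeans, m2@classMeans, tolerance = 1e-14)
    expect_equal(m1@classSDs, m2@classSDs, tolerance = 1e-14)

    # biased (maximum-likelihood) denominator, not n - 1
    expect_equal(unname(m1@classSDs[["healthy"]]),
                 sqrt(mean((vals[1:20] - mean(vals[1:20]))^2)),
                 tolerance = 1e-14)

    # law of large numbers: pooled estimates approach generating parameters
    set.seed(11)
    n <- 1e5
    big <- mk(c(rnorm(n, 15, 2), rnorm(n, 19, 1)), rep(c(1L, 2L), each = n))
    mb <- fitMLClassifier(list(big))
    # within 3 standard errors of the generating values
    expect_lt(abs(mb@classMeans[["healthy"]] - 15), 3 * 2 / sqrt(n))
    expect_lt(abs(mb@classMeans[["cancer"]] - 19), 3 * 1 / sqrt(n))
    expect_lt(abs(mb@classSDs[["healthy"]] - 2), 3 * 2 / sqrt(2 * n))
    expect_lt(abs(mb@classSDs[["cancer"]] - 1), 3 * 1 / sqrt(2 * n))

    expect_error(fitMLClassifier(list(mk(rnorm(5, 10), rep(1L, 5)))),
                 "both classes")
})

test_that("ML classification compares class densities without priors", {
    model <- new("ClassifierModel",
                 classMeans = c(healthy = 1, cancer = 3),
                 classSDs = c(healthy = 0.5, cancer = 0.5),
                 nVoxels = c(healthy = 10, cancer = 10))
    probe <- c(0.5, 1.9, 2.1, 3.5, 2.0 + 1e-9)
    map <- scalarMap(array(probe, c(5, 1, 1)))
    mask <- labelMap(array(c(1L, 1L, 2L, 2L, 2L), c(5, 1, 1)))
    res <- classifyVoxels(model, map, mask)
    # equal SDs: boundary at the midpoint of the means (2.0)
    expect_identical(as.vector(res$classMap), c(1L, 1L, 2L, 2L, 2L))
    expect_equal(res$metrics@accuracy, 1)

    # unequal SDs: two decision boundaries; compare against direct density
    # evaluation at 5 probe values
    model2 <- new("ClassifierModel",
                  classMeans = c(healthy = 0, cancer = 1),
                  classSDs = c(healthy = 3, cancer = 0.5),
                  nVoxels = c(healthy = 10, cancer = 10))
    probe2 <- c(-4, -1, 1, 2.5, 6)
    expected <- ifelse(dnorm(probe2, 1, 0.5) > dnorm(probe2, 0, 3), 2L, 1L)
    res2 <- classifyVoxels(model2, array(probe2, c(5, 1, 1)),
                           labelMap(array(1L, c(5, 1, 1)),
                                    legend = c(`1` = "healthy prostate")))
    expect_identical(as.vector(res2$classMap), expected)

    expect_error(classifyVoxels(model, scalarMap(array(1, c(2, 2, 2))),
                                labelMap(array(1L, c(3, 3, 3)))),
                 "share one grid")
})

test_that("confusion-count identities hold exactly", {
    m <- evalMetrics(TP = 7, FP = 2, TN = 11, FN = 3)
    expect_identical(m@sensitivity, 7 / 10)
    expect_identical(m@specificity, 11 / 13)
    expect_identical(m@accuracy, 18 / 23)
    # accuracy is the prevalence-weighted mix of sensitivity and specificity
    prev <- (m@TP + m@FN) / 23
    expect_equal(m@accuracy, prev * m@sensitivity + (1 - prev) * m@specificity,
                 tolerance = 1e-15)
    expect_error(evalMetrics(-1, 0, 2, 3), "nonnegative")
})

test_that("LOOCV tallies match an independent fold-by-fold oracle", {
    # two identical perfectly separated cases: all metrics 1
    mk <- function(vals, labs, id) {
        caseData(id, scalarMap(array(vals, c(length(vals), 1, 1))),
                 labelMap(array(labs, c(length(labs), 1, 1))))
    }
    set.seed(20)
    vals <- c(rnorm(30, 10, 0.3), rnorm(30, 20, 0.3))
    labs <- rep(c(1L, 2L), each = 30)
    res <- loocv(list(mk(vals, labs, "a"), mk(vals, labs, "b")))
    expect_equal(res$pooled@sensitivity, 1)
    expect_equal(res$pooled@specificity, 1)
    expect_equal(res$pooled@accuracy, 1)

    # three seeded overlapping cases against the hand tally
    set.seed(21)
    folds <- lapply(1:3, function(k)
        list(healthy = rnorm(40, 0, 1), cancer = rnorm(25, 1.5, 1.2)))
    cases <- lapply(1:3, function(k)
        mk(c(folds[[k]]$healthy, folds[[k]]$cancer) + 10,
           rep(c(1L, 2L), c(40, 25)), paste0("case", k)))
    # shift by +10 keeps ScalarMap nonnegative; the classifier is
    # translation-covariant so the tally on unshifted folds must agree
    res3 <- loocv(cases)
    tally <- tallyLOOCV(lapply(folds, function(f)
        list(healthy = f$healthy + 10, cancer = f$cancer + 10)))
    expect_identical(c(TP = res3$pooled@TP, FP = res3$pooled@FP,
                       TN = res3$pooled@TN, FN = res3$pooled@FN), tally)
    # pooled counts equal the sum over folds
    expect_equal(res3$pooled@TP, sum(vapply(res3$perCase, slot, numeric(1), "TP")))
    expect_equal(res3$pooled@FN, sum(vapply(res3$perCase, slot, numeric(1), "FN")))

    expect_error(loocv(list(mk(vals, labs, "a"))), "at least 2")
})

test_that("score extraction and orientation are consistent", {
    vals <- array(as.numeric(1:8), c(2, 2, 2))
    lab <- labelMap(array(c(0L, 1L, 1L, 2L, 0L, 1L, 2L, 2L), c(2, 2, 2)))
    sc <- extractScores(scalarMap(vals), lab)
    expect_identical(sc$healthy, c(2, 3, 6))
    expect_identical(sc$cancer, c(4, 7, 8))
    expect_identical(orientScores(vals, "CDI"), vals)
    expect_identical(orientScores(vals, "ADC"), -vals)
})
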