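#' Construct evaluation metrics from confusion counts
#'
#' @param TP,FP,TN,FN confusion counts with cancer as the positive class.
#' @return an [EvalMetrics-class] with sensitivity = TP/(TP+FN),
#'   specificity = TN/(TN+FP) and accuracy = (TP+TN)/total.
#' @export
evalMetrics <- function(TP, FP, TN, FN) {
    new("EvalMetrics", TP = as.numeric(TP), FP = as.numeric(FP),
        TN = as.numeric(TN), FN = as.numeric(FN),
        sensitivity = TP / (TP + FN),
        specificity = TN / (TN + FP),
        accuracy = (TP + TN) / (TP + FP + TN + FN))
}

#' Construct a case (score map plus labels) for evaluation
#'
#' @param caseId case identifier.
#' @param scoreMap a [ScalarMap-class] of voxel scores, oriented so that
#'   higher means more cancer-like (negate ADC maps first, see
#'   [orientScores()]).
#' @param labelMap a [LabelMap-class] on the same grid.
#' @return a [CaseData-class].
#' @export
caseData <- function(caseId, scoreMap, labelMap) {
    new("CaseData", caseId = as.character(caseId), scoreMap = scoreMap,
        labelMap = labelMap)
}

#' Extract class score vectors from a map and its labels
#'
#' @param map a [ScalarMap-class] (or bare 3D array).
#' @param labels a [LabelMap-class] on the same grid.
#' @param healthyLabel,cancerLabel integer codes of the two classes
#'   (defaults 1 and 2).
#' @return list with numeric vectors `healthy` and `cancer`.
#' @export
extractScores <- function(map, labels, healthyLabel = 1L, cancerLabel = 2L) {
    vals <- if (is(map, "ScalarMap")) map@values else map
    lab <- labels@labels
    if (!identical(dim(vals), dim(lab)))
        stop("map and label map must share one grid")
    list(healthy = as.vector(vals[lab == healthyLabel]),
         cancer = as.vector(vals[lab == cancerLabel]))
}

#' Orient voxel scores so that higher means more cancer-like
#'
#' CDI maps are used as-is (cancer is hyperintense); ADC maps are negated
#' (cancer is hypointense, i.e. restricted diffusion has a lower apparent
#' diffusion coefficient).
#'
#' @param values numeric vector or array of map values.
#' @param mapKind `"CDI"` or `"ADC"`.
#' @return oriented values (`values` for CDI, `-values` for ADC).
#' @export
orientScores <- function(values, mapKind = c("CDI", "ADC")) {
    mapKind <- match.arg(mapKind)
    if (mapKind == "ADC") -values else values
}

## binormal ROC --------------------------------------------------------------

#' Binormal ROC from class moments
#'
#' The binormal model takes the class-conditional score distributions as
#' Gaussian. With class 0 = healthy, class 1 = cancer (positives), the ROC
#' parameters are `a = (mu1 - mu0) / sd1` and `b = sd0 / sd1`, and the area
#' under the curve is `Az = pnorm(a / sqrt(1 + b^2)) =
#' pnorm((mu1 - mu0) / sqrt(sd0^2 + sd1^2))`. Orientation is not
#' auto-flipped: `mu1 < mu0` yields `Az < 0.5`.
#'
#' @param mu0,sd0 mean and SD of the healthy-class scores.
#' @param mu1,sd1 mean and SD of the cancer-class scores.
#' @param nPoints number of curve samples (>= 201); thresholds span the two
#'   class distributions, plus the (+Inf, -Inf) endpoints.
#' @return an [ROCResult-class].
#' @examples
#' binormalROCFromMoments(0, 1, sqrt(2), 1)   # Az = pnorm(1) ~ 0.8413
#' @export
binormalROCFromMoments <- function(mu0, sd0, mu1, sd1, nPoints = 201L) {
    if (!is.finite(sd0) || !is.finite(sd1) || sd0 <= 0 || sd1 <= 0)
        stop("class standard deviations must be positive (zero variance?)")
    nPoints <- max(as.integer(nPoints), 201L)
    a <- (mu1 - mu0) / sd1
    b <- sd0 / sd1
    Az <- stats::pnorm(a / sqrt(1 + b^2))
    lohi <- range(mu0 - 5 * sd0, mu0 + 5 * sd0, mu1 - 5 * sd1, mu1 + 5 * sd1)
    thr <- c(Inf, seq(lohi[2L], lohi[1L], length.out = nPoints - 2L), -Inf)
    fpr <- stats::pnorm(thr, mean = mu0, sd = sd0, lower.tail = FALSE)
    tpr <- stats::pnorm(thr, mean = mu1, sd = sd1, lower.tail = FALSE)
    curve <- cbind(threshold = thr, fpr = fpr, tpr = tpr)
    new("ROCResult", a = a, b = b, Az = Az, curve = curve,
        moments = c(mu0 = mu0, sd0 = sd0, mu1 = mu1, sd1 = sd1))
}

#' Binormal ROC analysis of two score samples
#'
#' Fits Gaussian class-conditional distributions by sample mean and SD and
#' returns the binormal ROC (see [binormalROCFromMoments()] for the model).
#'
#' @param scoresCancer numeric scores of cancer voxels (positives), >= 2
#'   values with nonzero variance.
#' @param scoresHealthy numeric scores of healthy voxels, >= 2 values with
#'   nonzero variance.
#' @param nPoints number of curve samples (>= 201).
#' @return an [ROCResult-class].
#' @export
binormalROC <- function(scoresCancer, scoresHealthy, nPoints = 201L) {
    for (s in list(scoresCancer, scoresHealthy)) {
        if (length(s) < 2L) stop("each class needs at least 2 scores")
        if (stats::sd(s) == 0) stop("class scores have zero variance")
    }
    binormalROCFromMoments(mean(scoresHealthy), stats::sd(scoresHealthy),
                           mean(scoresCancer), stats::sd(scoresCancer),
                           nPoints = nPoints)
}

#' Empirical (nonparametric) ROC curve and AUC
#'
#' The empirical AUC equals the Mann-Whitney U statistic scaled to
#' \\[0, 1\\]: the fraction of (cancer, healthy) pairs in which the cancer
#' score is higher, with ties counted half. Serves as a distribution-free
#' cross-check of the binormal fit.
#'
#' @param scoresCancer numeric scores of cancer voxels (positives), nonempty.
#' @param scoresHealthy numeric scores of healthy voxels, nonempty.
#' @return list with `auc` (numeric) and `curve` (matrix with columns
#'   `threshold`, `fpr`, `tpr`, stepping through the observed scores).
#' @examples
#' empiricalROC(c(3, 5), c(1, 4))$auc   # 0.75
#' @export
empiricalROC <- function(scoresCancer, scoresHealthy) {
    n1 <- length(scoresCancer); n0 <- length(scoresHealthy)
    if (!n1 || !n0) stop("both score lists must be nonempty")
    r <- rank(c(scoresCancer, scoresHealthy))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    auc <- U / (n1 * n0)
    thr <- c(Inf, sort(unique(c(scoresCancer, scoresHealthy)),
                       decreasing = TRUE))
    fpr <- vapply(thr, function(t) mean(scoresHealthy >= t), numeric(1))
    tpr <- vapply(thr, function(t) mean(scoresCancer >= t), numeric(1))
    list(auc = auc, curve = cbind(threshold = thr, fpr = fpr, tpr = tpr))
}

#' Fisher class-separability of two score samples
#'
#' The squared mean difference over the summed variances,
#' `(mu1 - mu0)^2 / (sd0^2 + sd1^2)`: zero for identical distributions,
#' increasing in the mean gap at fixed spread.
#'
#' @param scoresCancer,scoresHealthy numeric score vectors, nonempty with
#'   finite variance; the pooled variance must be nonzero.
#' @return numeric scalar, the Fisher ratio (dimensionless).
#' @export
separability <- function(scoresCancer, scoresHealthy) {
    if (!length(scoresCancer) || !length(scoresHealthy))
        stop("both score lists must be nonempty")
    v0 <- if (length(scoresHealthy) > 1L) stats::var(scoresHealthy) else 0
    v1 <- if (length(scoresCancer) > 1L) stats::var(scoresCancer) else 0
    if (!is.finite(v0) || !is.finite(v1))
        stop("scores must have finite variance")
    if (v0 + v1 == 0) stop("zero total variance")
    (mean(scoresCancer) - mean(scoresHealthy))^2 / (v0 + v1)
}

## ML classifier & LOOCV -----------------------------------------------------

.mlSD <- function(x) sqrt(mean((x - mean(x))^2))   # biased-denominator MLE

#' Fit the two-class Gaussian maximum-likelihood classifier
#'
#' Pools voxel intensities of each class across the training cases
#' (each voxel counts once) and fits per-class Gaussians by maximum
#' likelihood: sample mean and biased-denominator SD. Degenerate classes
#' get an SD floor of `1e-12 * (|mean| + 1)` (logged via a message).
#'
#' @param train list of [CaseData-class]; the pooled voxels must contain
#'   both classes.
#' @param healthyLabel,cancerLabel integer codes of the two classes.
#' @return a [ClassifierModel-class].
#' @export
fitMLClassifier <- function(train, healthyLabel = 1L, cancerLabel = 2L) {
    if (is(train, "CaseData")) train <- list(train)
    pools <- list(healthy = numeric(0), cancer = numeric(0))
    for (cs in train) {
        sc <- extractScores(cs@scoreMap, cs@labelMap, healthyLabel, cancerLabel)
        pools$healthy <- c(pools$healthy, sc$healthy)
        pools$cancer <- c(pools$cancer, sc$cancer)
    }
    if (!length(pools$healthy) || !length(pools$cancer))
        stop("training pool must contain both classes")
    mns <- vapply(pools, mean, numeric(1))
    sds <- vapply(pools, .mlSD, numeric(1))
    floorSD <- 1e-12 * (abs(mns) + 1)
    if (any(sds < floorSD)) {
        message("fitMLClassifier: SD floor applied to class(es): ",
                paste(names(sds)[sds < floorSD], collapse = ", "))
        sds <- pmax(sds, floorSD)
    }
    new("ClassifierModel", classMeans = mns, classSDs = sds,
        nVoxels = vapply(pools, length, numeric(1)))
}

#' Classify gland voxels and score against the true labels
#'
#' Each voxel labelled healthy or cancer in the mask is assigned the class
#' whose fitted Gaussian density is higher at its intensity (pure maximum
#' likelihood, no class priors). Metrics are computed from the confusion
#' counts with cancer as the positive class.
#'
#' @param model a [ClassifierModel-class].
#' @param map a [ScalarMap-class] of voxel scores on the mask's grid.
#' @param mask a [LabelMap-class] with the true labels.
#' @param healthyLabel,cancerLabel integer codes of the two classes.
#' @return list with `classMap` (3D integer array: 0 outside the gland,
#'   otherwise the predicted label) and `metrics` (an [EvalMetrics-class]).
#' @export
classifyVoxels <- function(model, map, mask, healthyLabel = 1L,
                           cancerLabel = 2L) {
    validObject(model)
    vals <- if (is(map, "ScalarMap")) map@values else map
    lab <- mask@labels
    if (!identical(dim(vals), dim(lab)))
        stop("map and mask must share one grid")
    inGland <- lab == healthyLabel | lab == cancerLabel
    x <- vals[inGland]
    llCancer <- stats::dnorm(x, model@classMeans[["cancer"]],
                             model@classSDs[["cancer"]], log = TRUE)
    llHealthy <- stats::dnorm(x, model@classMeans[["healthy"]],
                              model@classSDs[["healthy"]], log = TRUE)
    pred <- ifelse(llCancer > llHealthy, cancerLabel, healthyLabel)
    classMap <- array(0L, dim = dim(vals))
    classMap[inGland] <- as.integer(pred)
    truth <- lab[inGland]
    metrics <- evalMetrics(
        TP = sum(pred == cancerLabel & truth == cancerLabel),
        FP = sum(pred == cancerLabel & truth == healthyLabel),
        TN = sum(pred == healthyLabel & truth == healthyLabel),
        FN = sum(pred == healthyLabel & truth == cancerLabel))
    list(classMap = classMap, metrics = metrics)
}

#' Leave-one-out cross-validation over cases
#'
#' For each case the classifier is fitted on all remaining cases and
#' evaluated on the held-out case. Pooled metrics are computed from the
#' summed confusion counts across folds.
#'
#' @param cases list of >= 2 [CaseData-class] objects.
#' @param healthyLabel,cancerLabel integer codes of the two classes.
#' @return list with `perCase` (named list of [EvalMetrics-class]) and
#'   `pooled` (an [EvalMetrics-class] from the summed counts).
#' @export
loocv <- function(cases, healthyLabel = 1L, cancerLabel = 2L) {
    if (length(cases) < 2L) stop("LOOCV needs at least 2 cases")
    perCase <- list()
    tot <- c(TP = 0, FP = 0, TN = 0, FN = 0)
    for (k in seq_along(cases)) {
        model <- fitMLClassifier(cases[-k], healthyLabel, cancerLabel)
        held <- cases[[k]]
        res <- classifyVoxels(model, held@scoreMap, held@labelMap,
                              healthyLabel, cancerLabel)
        m <- res$metrics
        perCase[[held@caseId]] <- m
        tot <- tot + c(TP = m@TP, FP = m@FP, TN = m@TN, FN = m@FN)
    }
    list(perCase = perCase,
         pooled = evalMetrics(tot[["TP"]], tot[["FP"]], tot[["TN"]],
                              tot[["FN"]]))
}
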