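# Independent oracles, deliberately naive, against which the package's
# vectorised implementations are checked.

# Brute-force CDI estimator: for every voxel, enumerate the in-bounds box
# neighborhood with nested loops, multiply the in-range signals per
# neighbor, and average.
bruteForceCDI <- function(signal, bvalues, qalpha, qbeta, radii) {
    d <- dim(signal)
    I <- which(bvalues >= qalpha & bvalues <= qbeta)
    out <- array(NA_real_, dim = d[1:3])
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
        acc <- 0; cnt <- 0
        for (xx in max(1, x - radii[1]):min(d[1], x + radii[1]))
        for (yy in max(1, y - radii[2]):min(d[2], y + radii[2]))
        for (zz in max(1, z - radii[3]):min(d[3], z + radii[3])) {
            p <- 1
            for (i in I) p <- p * signal[xx, yy, zz, i]
            acc <- acc + p
            cnt <- cnt + 1
        }
        out[x, y, z] <- acc / cnt
    }
    out
}

# Closed-form OLS slope on (b, ln S) pairs for one voxel.
olsADC <- function(b, S) {
    l <- log(S)
    -sum((b - mean(b)) * (l - mean(l))) / sum((b - mean(b))^2)
}

# Mean of a Rician(nu, sigma) by numerical integration of its density,
# using the exponentially scaled Bessel I0 to avoid overflow.
ricianMean <- function(nu, sigma) {
    f <- function(x) {
        z <- x * nu / sigma^2
        x * (x / sigma^2) * exp(-(x - nu)^2 / (2 * sigma^2)) *
            besselI(z, 0, expon.scaled = TRUE)
    }
    stats::integrate(f, 0, nu + 12 * sigma, rel.tol = 1e-10)$value
}

# Pair-counting AUC: fraction of (cancer, healthy) pairs won, ties half.
pairCountAUC <- function(cancer, healthy) {
    wins <- 0
    for (c in cancer) for (h in healthy)
        wins <- wins + (c > h) + 0.5 * (c == h)
    wins / (length(cancer) * length(healthy))
}

# Fold-by-fold LOOCV tally built directly on score vectors, independent of
# the package's CaseData plumbing: fits pooled-class Gaussians (biased SD)
# on the training folds, classifies the held-out fold by density
# comparison, and sums the confusion counts.
tallyLOOCV <- function(folds) {
    tot <- c(TP = 0, FP = 0, TN = 0, FN = 0)
    mlsd <- function(x) sqrt(mean((x - mean(x))^2))
    for (k in seq_along(folds)) {
        trainH <- unlist(lapply(folds[-k], `[[`, "healthy"))
        trainC <- unlist(lapply(folds[-k], `[[`, "cancer"))
        mH <- mean(trainH); sH <- max(mlsd(trainH), 1e-12 * (abs(mH) + 1))
        mC <- mean(trainC); sC <- max(mlsd(trainC), 1e-12 * (abs(mC) + 1))
        isCancer <- function(x)
            stats::dnorm(x, mC, sC, log = TRUE) > stats::dnorm(x, mH, sH, log = TRUE)
        predC <- isCancer(folds[[k]]$cancer)
        predH <- isCancer(folds[[k]]$healthy)
        tot <- tot + c(TP = sum(predC), FP = sum(predH),
                       TN = sum(!predH), FN = sum(!predC))
    }
    tot
}

# A small random DWI stack for I/O and estimator tests.
randomStack <- function(dims, bvalues, seed, spacing = c(1, 1, 1)) {
    set.seed(seed)
    arr <- array(stats::runif(prod(dims) * length(bvalues), 10, 1000),
                 dim = c(dims, length(bvalues)))
    dwiStack(arr, bvalues, spacing = spacing)
}

# CaseData built from a seeded default phantom: CDI or negated-ADC scores.
phantomCase <- function(seed, kind = c("CDI", "ADC")) {
    kind <- match.arg(kind)
    ph <- generatePhantom(defaultProstateSpec(seed = seed))
    map <- if (kind == "CDI") computeCDI(ph$stack) else computeADC(ph$stack)
    vals <- orientScores(mapValues(map), kind)
    caseData(paste0("case", seed),
             scalarMap(vals, spacing(map),
                       provenance = list(map_kind = "score",
                                         oriented_from = kind)),
             ph$labels)
}
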