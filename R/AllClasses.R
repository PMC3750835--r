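#' @import methods
NULL

#' GradientConfig: diffusion gradient-pulse configurations
#'
#' A vectorised container for Stejskal-Tanner pulsed-gradient spin-echo
#' configurations. Each element holds the gradient pulse strength `G` (T/m),
#' the pulse duration `delta` (s) and the leading-edge separation of the two
#' pulses `Delta` (s). All slots have equal length; the object behaves like a
#' parameter table with one row per acquisition.
#'
#' @slot G numeric, gradient pulse strength in T/m (>= 0).
#' @slot delta numeric, gradient pulse duration in s (> 0).
#' @slot Delta numeric, time between the gradient pulses in s (> 0), with
#'   `Delta - delta/3 > 0` so the derived b-value is nonnegative.
#'
#' @seealso [gradientConfig()], [bValue()], [configFromBValues()]
#' @export
setClass("GradientConfig",
    representation(G = "numeric", delta = "numeric", Delta = "numeric"))

setValidity("GradientConfig", function(object) {
    n <- length(object@G)
    if (length(object@delta) != n || length(object@Delta) != n)
        return("slots 'G', 'delta' and 'Delta' must have equal length")
    if (any(!is.finite(object@G)) || any(object@G < 0))
        return("'G' must be finite and >= 0 (T/m)")
    if (any(!is.finite(object@delta)) || any(object@delta <= 0))
        return("'delta' must be finite and > 0 (s)")
    if (any(!is.finite(object@Delta)) || any(object@Delta <= 0))
        return("'Delta' must be finite and > 0 (s)")
    if (any(object@Delta - object@delta / 3 <= 0))
        return("'Delta' must exceed delta/3 (otherwise the b-value would be negative)")
    TRUE
})

#' DWIStack: a 4D multi-b-value diffusion-weighted MRI stack
#'
#' Magnitude DWI signal on a regular voxel grid, one 3D volume per
#' acquisition, with the b-value of each acquisition and the voxel spacing.
#' The fourth array dimension is the acquisition axis.
#'
#' @slot signal 4D numeric array, nonnegative magnitude signal, indexed
#'   (x, y, z, acquisition).
#' @slot bvalues numeric, one b-value (s/mm^2) per acquisition; length equals
#'   `dim(signal)[4]`.
#' @slot spacing numeric length 3, voxel dimensions in mm.
#' @slot orientation 4x4 voxel-to-world affine, or a 0x0 matrix when unknown;
#'   carried through unchanged by all operations.
#'
#' @seealso [dwiStack()], [readDWI()], [computeCDI()], [computeADC()]
#' @export
setClass("DWIStack",
    representation(signal = "array", bvalues = "numeric",
                   spacing = "numeric", orientation = "matrix"))

setValidity("DWIStack", function(object) {
    d <- dim(object@signal)
    if (length(d) != 4L)
        return("'signal' must be a 4D array (x, y, z, acquisition)")
    if (any(d[1:3] < 1L))
        return("spatial dimensions must be >= 1")
    if (any(object@signal < 0, na.rm = TRUE))
        return("'signal' must be nonnegative (magnitude MR data)")
    if (any(!is.finite(object@signal)))
        return("'signal' must be finite")
    if (length(object@bvalues) != d[4L])
        return(sprintf("length(bvalues) [%d] must equal the number of volumes [%d]",
                       length(object@bvalues), d[4L]))
    if (any(!is.finite(object@bvalues)) || any(object@bvalues < 0))
        return("'bvalues' must be finite and >= 0 (s/mm^2)")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        return("'spacing' must be 3 positive voxel dimensions (mm)")
    if (!identical(dim(object@orientation), c(0L, 0L)) &&
        !identical(dim(object@orientation), c(4L, 4L)))
        return("'orientation' must be a 4x4 affine or a 0x0 matrix")
    TRUE
})

#' ScalarMap: a derived 3D parameter map (CDI or ADC)
#'
#' @slot values 3D numeric array of map values; nonnegative when the map is
#'   a CDI or ADC map (oriented score maps, e.g. negated ADC, may be
#'   negative).
#' @slot spacing numeric length 3, voxel dimensions in mm.
#' @slot provenance list describing how the map was produced: `map_kind`
#'   ("CDI" or "ADC") plus the parameters used (`b_range` or `omega`,
#'   `neighborhood_voxels`, normalisation, floored-voxel counts, ...).
#'
#' @seealso [computeCDI()], [computeADC()], [writeMap()], [readMap()]
#' @export
setClass("ScalarMap",
    representation(values = "array", spacing = "numeric", provenance = "list"))

setValidity("ScalarMap", function(object) {
    if (length(dim(object@values)) != 3L)
        return("'values' must be a 3D array")
    if (any(!is.finite(object@values)))
        return("'values' must be finite")
    # CDI and ADC maps are nonnegative by construction; derived score maps
    # (e.g. negated ADC) may be negative
    if (isTRUE(object@provenance$map_kind %in% c("CDI", "ADC")) &&
        any(object@values < 0))
        return("map values must be >= 0")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        return("'spacing' must be 3 positive voxel dimensions (mm)")
    TRUE
})

#' LabelMap: integer tissue labels on a voxel grid
#'
#' @slot labels 3D integer array of tissue codes.
#' @slot spacing numeric length 3, voxel dimensions in mm.
#' @slot legend named character vector mapping label code (name) to tissue
#'   name; by default 0 = background, 1 = healthy prostate, 2 = cancer.
#'
#' @seealso [labelMap()], [readLabels()], [writeLabels()]
#' @export
setClass("LabelMap",
    representation(labels = "array", spacing = "numeric", legend = "character"))

setValidity("LabelMap", function(object) {
    if (length(dim(object@labels)) != 3L)
        return("'labels' must be a 3D array")
    if (!is.integer(object@labels))
        return("'labels' must be integer-valued")
    present <- sort(unique(as.vector(object@labels)))
    known <- suppressWarnings(as.integer(names(object@legend)))
    if (any(is.na(known)))
        return("legend names must be integer label codes")
    missing <- setdiff(present, known)
    if (length(missing))
        return(sprintf("label code(s) %s present but absent from legend",
                       paste(missing, collapse = ", ")))
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        return("'spacing' must be 3 positive voxel dimensions (mm)")
    TRUE
})

#' TissueParams: mono-exponential signal parameters of one tissue
#'
#' @slot S0 numeric scalar, baseline signal at b = 0 (arbitrary units, > 0).
#' @slot D numeric scalar, diffusivity in mm^2/s (>= 0).
#'
#' @seealso [tissueParams()], [phantomSpec()]
#' @export
setClass("TissueParams", representation(S0 = "numeric", D = "numeric"))

setValidity("TissueParams", function(object) {
    if (length(object@S0) != 1L || !is.finite(object@S0) || object@S0 <= 0)
        return("'S0' must be a single positive number")
    if (length(object@D) != 1L || !is.finite(object@D) || object@D < 0)
        return("'D' must be a single nonnegative number (mm^2/s)")
    TRUE
})

#' PhantomSpec: a synthetic multi-b-value DWI phantom specification
#'
#' Describes a prostate-like digital phantom: an ellipsoidal gland of healthy
#' tissue inside a fluid-like background, spherical lesions of restricted
#' diffusion inside the gland, per-tissue mono-exponential decay parameters,
#' Rician noise scale and RNG seed.
#'
#' @slot shape integer length 3, grid dimensions in voxels.
#' @slot spacing numeric length 3, voxel dimensions in mm.
#' @slot bvalues numeric, b-values (s/mm^2) of the simulated acquisitions.
#' @slot tissues named list of [TissueParams-class], keyed by label code.
#' @slot lesions data.frame with columns `x`, `y`, `z` (1-based centre voxel),
#'   `radius` (mm) and `label` (integer code).
#' @slot gland list with `center` (1-based voxel triple) and `semiaxes`
#'   (mm triple) of the healthy-gland ellipsoid.
#' @slot noiseSigma numeric scalar >= 0, Rician noise scale in signal units.
#' @slot seed integer scalar, RNG seed for the noise realisation.
#'
#' @seealso [phantomSpec()], [defaultProstateSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec",
    representation(shape = "integer", spacing = "numeric", bvalues = "numeric",
                   tissues = "list", lesions = "data.frame", gland = "list",
                   noiseSigma = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
    if (length(object@shape) != 3L || any(object@shape < 1L))
        return("'shape' must be 3 positive voxel counts")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        return("'spacing' must be 3 positive voxel dimensions (mm)")
    if (!length(object@bvalues) || any(!is.finite(object@bvalues)) ||
        any(object@bvalues < 0))
        return("'bvalues' must be nonnegative and nonempty")
    if (is.null(names(object@tissues)) ||
        any(is.na(suppressWarnings(as.integer(names(object@tissues))))))
        return("'tissues' must be a list named by integer label codes")
    if (!all(vapply(object@tissues, is, logical(1), "TissueParams")))
        return("every 'tissues' entry must be a TissueParams object")
    needed <- c("x", "y", "z", "radius", "label")
    if (!all(needed %in% names(object@lesions)))
        return("'lesions' must have columns x, y, z, radius, label")
    if (nrow(object@lesions) &&
        (any(object@lesions$radius <= 0) || any(!is.finite(object@lesions$radius))))
        return("lesion radii must be positive (mm)")
    if (!all(c("center", "semiaxes") %in% names(object@gland)))
        return("'gland' must have 'center' and 'semiaxes'")
    if (length(object@gland$center) != 3L || length(object@gland$semiaxes) != 3L ||
        any(object@gland$semiaxes <= 0))
        return("'gland' center/semiaxes must be length-3 with positive semiaxes")
    codes <- as.integer(names(object@tissues))
    refd <- unique(c(0L, 1L, as.integer(object@lesions$label)))
    miss <- setdiff(refd, codes)
    if (length(miss))
        return(sprintf("label code(s) %s referenced but have no TissueParams",
                       paste(miss, collapse = ", ")))
    if (length(object@noiseSigma) != 1L || !is.finite(object@noiseSigma) ||
        object@noiseSigma < 0)
        return("'noiseSigma' must be a single nonnegative number")
    if (length(object@seed) != 1L || is.na(object@seed))
        return("'seed' must be a single integer")
    # every lesion sphere must fit strictly inside the gland ellipsoid
    if (nrow(object@lesions)) {
        for (k in seq_len(nrow(object@lesions))) {
            les <- object@lesions[k, ]
            dmm <- (c(les$x, les$y, les$z) - object@gland$center) * object@spacing
            shrunk <- object@gland$semiaxes - les$radius
            if (any(shrunk <= 0) || sum((dmm / shrunk)^2) >= 1)
                return(sprintf("lesion %d (radius %.3g mm) does not fit inside the gland ellipsoid",
                               k, les$radius))
        }
    }
    TRUE
})

#' BRange: a diffusion-weighting (b-value) range
#'
#' The closed interval of b-values whose acquisitions enter the CDI signal
#' mixing. The study default is \\[0, 2000\\] s/mm^2.
#'
#' @slot qalpha numeric scalar, lower bound (s/mm^2).
#' @slot qbeta numeric scalar, upper bound (s/mm^2), `>= qalpha`.
#'
#' @seealso [bRange()], [computeCDI()]
#' @export
setClass("BRange", representation(qalpha = "numeric", qbeta = "numeric"))

setValidity("BRange", function(object) {
    if (length(object@qalpha) != 1L || length(object@qbeta) != 1L ||
        !is.finite(object@qalpha) || !is.finite(object@qbeta))
        return("bounds must be single finite numbers")
    if (object@qalpha < 0) return("'qalpha' must be >= 0")
    if (object@qalpha > object@qbeta) return("'qalpha' must be <= 'qbeta'")
    TRUE
})

#' NeighborhoodSpec: the local spatial sub-volume of the CDI estimator
#'
#' The sub-volume V(x) over which joint signal statistics are pooled, either
#' as explicit per-axis voxel half-widths or as a physical extent converted
#' to voxels via the grid spacing. A physical extent may be read as the side
#' of a cube in mm (`unit = "mm"`) or as a volume in mm^3 (`unit = "mm3"`);
#' both readings of the study's "7 mm^3" sub-volume are supported.
#'
#' @slot mode character, `"voxel_radius"` or `"physical_size"`.
#' @slot radii integer length 3, per-axis half-widths in voxels (a half-width
#'   of 1 on every axis is a 3x3x3 cube); used when mode is `"voxel_radius"`.
#' @slot size numeric scalar, physical extent; used when mode is
#'   `"physical_size"`.
#' @slot unit character, `"mm"` (cube side) or `"mm3"` (volume).
#'
#' @seealso [neighborhoodSpec()], [neighborhoodVoxels()], [computeCDI()]
#' @export
setClass("NeighborhoodSpec",
    representation(mode = "character", radii = "integer",
                   size = "numeric", unit = "character"))

setValidity("NeighborhoodSpec", function(object) {
    if (!object@mode %in% c("voxel_radius", "physical_size"))
        return("'mode' must be 'voxel_radius' or 'physical_size'")
    if (object@mode == "voxel_radius") {
        if (length(object@radii) != 3L || any(is.na(object@radii)) ||
            any(object@radii < 0L))
            return("'radii' must be 3 nonnegative integers")
    } else {
        if (length(object@size) != 1L || !is.finite(object@size) ||
            object@size <= 0)
            return("'size' must be a single positive number")
        if (!object@unit %in% c("mm", "mm3"))
            return("'unit' must be 'mm' (cube side) or 'mm3' (volume)")
    }
    TRUE
})

#' ROCResult: a binormal ROC fit
#'
#' @slot a numeric, binormal intercept `(mu1 - mu0) / sigma1` (class 1 =
#'   cancer = positives).
#' @slot b numeric, binormal slope `sigma0 / sigma1`.
#' @slot Az numeric, area under the binormal ROC,
#'   `pnorm(a / sqrt(1 + b^2))`.
#' @slot curve numeric matrix with columns `threshold`, `fpr`, `tpr`;
#'   endpoints (0,0) and (1,1), TPR nondecreasing in FPR.
#' @slot moments named numeric with the fitted class moments
#'   (`mu0`, `sd0`, `mu1`, `sd1`).
#'
#' @seealso [binormalROC()], [empiricalROC()]
#' @export
setClass("ROCResult",
    representation(a = "numeric", b = "numeric", Az = "numeric",
                   curve = "matrix", moments = "numeric"))

setValidity("ROCResult", function(object) {
    closed <- stats::pnorm(object@a / sqrt(1 + object@b^2))
    if (abs(object@Az - closed) > 1e-12)
        return("Az must equal pnorm(a / sqrt(1 + b^2)) to 1e-12")
    cv <- object@curve
    if (!all(c("threshold", "fpr", "tpr") %in% colnames(cv)))
        return("curve must have columns threshold, fpr, tpr")
    if (abs(cv[1L, "fpr"]) > 0 || abs(cv[1L, "tpr"]) > 0 ||
        abs(cv[nrow(cv), "fpr"] - 1) > 0 || abs(cv[nrow(cv), "tpr"] - 1) > 0)
        return("curve endpoints must be (0,0) and (1,1)")
    if (is.unsorted(cv[, "fpr"]) || any(diff(cv[, "tpr"]) < -1e-12))
        return("TPR must be nondecreasing in FPR")
    TRUE
})

#' ClassifierModel: a two-class Gaussian maximum-likelihood voxel classifier
#'
#' Per-class Gaussian intensity statistics (maximum-likelihood estimates:
#' sample mean and biased-denominator SD) of healthy and cancerous voxels
#' pooled across training cases.
#'
#' @slot classMeans named numeric (`healthy`, `cancer`), map-intensity units.
#' @slot classSDs named numeric (`healthy`, `cancer`), all > 0 (a floor of
#'   `1e-12 * (|mean| + 1)` is applied to degenerate classes and logged).
#' @slot nVoxels named numeric, training voxel counts per class.
#'
#' @seealso [fitMLClassifier()], [classifyVoxels()]
#' @export
setClass("ClassifierModel",
    representation(classMeans = "numeric", classSDs = "numeric",
                   nVoxels = "numeric"))

setValidity("ClassifierModel", function(object) {
    cls <- c("healthy", "cancer")
    if (!all(cls %in% names(object@classMeans)) ||
        !all(cls %in% names(object@classSDs)))
        return("classMeans and classSDs must be named 'healthy' and 'cancer'")
    if (any(!is.finite(object@classSDs)) || any(object@classSDs <= 0))
        return("class standard deviations must be positive")
    TRUE
})

#' CaseData: one case's score map with its tissue labels
#'
#' @slot caseId character scalar identifying the case.
#' @slot scoreMap a [ScalarMap-class] of voxel scores (e.g. a CDI map, or a
#'   negated-then-shifted ADC map).
#' @slot labelMap a [LabelMap-class] on the same grid; voxels labelled
#'   healthy (1) and cancer (2) within the gland enter training/evaluation.
#'
#' @seealso [caseData()], [fitMLClassifier()], [loocv()]
#' @export
setClass("CaseData",
    representation(caseId = "character", scoreMap = "ScalarMap",
                   labelMap = "LabelMap"))

setValidity("CaseData", function(object) {
    if (length(object@caseId) != 1L || !nzchar(object@caseId))
        return("'caseId' must be a nonempty string")
    if (!identical(dim(object@scoreMap@values), dim(object@labelMap@labels)))
        return("score map and label map must share one grid")
    TRUE
})

#' EvalMetrics: sensitivity, specificity and accuracy from confusion counts
#'
#' Cancer is the positive class. All three rates are exact rational numbers
#' of the counts: sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' accuracy = (TP+TN)/(TP+FP+TN+FN).
#'
#' @slot TP,FP,TN,FN numeric confusion counts.
#' @slot sensitivity,specificity,accuracy numeric rates in \\[0, 1\\].
#'
#' @seealso [evalMetrics()], [classifyVoxels()], [loocv()]
#' @export
setClass("EvalMetrics",
    representation(TP = "numeric", FP = "numeric", TN = "numeric",
                   FN = "numeric", sensitivity = "numeric",
                   specificity = "numeric", accuracy = "numeric"))

setValidity("EvalMetrics", function(object) {
    cnt <- c(object@TP, object@FP, object@TN, object@FN)
    if (any(cnt < 0) || any(cnt != round(cnt)))
        return("confusion counts must be nonnegative integers")
    tot <- sum(cnt)
    if (tot == 0) return("at least one voxel is required")
    ok <- function(x, y) (is.nan(y) && is.nan(x)) || isTRUE(x == y)
    if (!ok(object@sensitivity, object@TP / (object@TP + object@FN)))
        return("sensitivity must equal TP/(TP+FN)")
    if (!ok(object@specificity, object@TN / (object@TN + object@FP)))
        return("specificity must equal TN/(TN+FP)")
    if (!ok(object@accuracy, (object@TP + object@TN) / tot))
        return("accuracy must equal (TP+TN)/total")
    TRUE
})
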