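#' Voxel spacing of a gridded object
#'
#' @param x a [DWIStack-class], [ScalarMap-class] or [LabelMap-class].
#' @return numeric length 3, voxel dimensions in mm.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' b-values of an object
#'
#' For a [GradientConfig-class], the Stejskal-Tanner b-value derived from
#' each pulse configuration; for a [DWIStack-class], the recorded per-volume
#' b-values.
#'
#' @param x a [GradientConfig-class] or [DWIStack-class].
#' @return numeric vector of b-values in s/mm^2.
#' @export
setGeneric("bValue", function(x) standardGeneric("bValue"))

#' Map values of a derived parameter map
#'
#' @param x a [ScalarMap-class].
#' @return the 3D numeric array of map values.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' Provenance metadata of a derived map
#'
#' @param x a [ScalarMap-class].
#' @return a list of the parameters that produced the map.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Signal array of a DWI stack
#'
#' @param x a [DWIStack-class].
#' @return the 4D numeric signal array, indexed (x, y, z, acquisition).
#' @export
setGeneric("dwiSignal", function(x) standardGeneric("dwiSignal"))

#' Label array of a label map
#'
#' @param x a [LabelMap-class].
#' @return the 3D integer label array.
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))

#' Legend of a label map
#'
#' @param x a [LabelMap-class].
#' @return named character vector mapping label code to tissue name.
#' @export
setGeneric("labelLegend", function(x) standardGeneric("labelLegend"))

## spacing ------------------------------------------------------------------

#' @describeIn spacing spacing of a DWI stack
#' @export
setMethod("spacing", "DWIStack", function(x) x@spacing)

#' @describeIn spacing spacing of a derived map
#' @export
setMethod("spacing", "ScalarMap", function(x) x@spacing)

#' @describeIn spacing spacing of a label map
#' @export
setMethod("spacing", "LabelMap", function(x) x@spacing)

## accessors ----------------------------------------------------------------

#' @describeIn bValue recorded b-values of a stack
#' @export
setMethod("bValue", "DWIStack", function(x) x@bvalues)

#' @rdname mapValues
#' @export
setMethod("mapValues", "ScalarMap", function(x) x@values)

#' @rdname provenance
#' @export
setMethod("provenance", "ScalarMap", function(x) x@provenance)

#' @rdname dwiSignal
#' @export
setMethod("dwiSignal", "DWIStack", function(x) x@signal)

#' @rdname labelArray
#' @export
setMethod("labelArray", "LabelMap", function(x) x@labels)

#' @rdname labelLegend
#' @export
setMethod("labelLegend", "LabelMap", function(x) x@legend)

## length / show ------------------------------------------------------------

#' @describeIn GradientConfig number of pulse configurations
#' @param x a `GradientConfig`.
#' @export
setMethod("length", "GradientConfig", function(x) length(x@G))

setMethod("show", "GradientConfig", function(object) {
    cat(sprintf("GradientConfig with %d configuration(s)\n", length(object)))
    n <- min(length(object), 6L)
    if (n) {
        df <- data.frame(G_T_per_m = object@G[seq_len(n)],
                         delta_s = object@delta[seq_len(n)],
                         Delta_s = object@Delta[seq_len(n)],
                         b_s_per_mm2 = bValue(object)[seq_len(n)])
        print(df, row.names = FALSE)
        if (length(object) > n) cat("...\n")
    }
})

setMethod("show", "DWIStack", function(object) {
    d <- dim(object@signal)
    cat(sprintf("DWIStack: %d x %d x %d voxels, %d acquisition(s)\n",
                d[1], d[2], d[3], d[4]))
    cat(sprintf("  b-values (s/mm^2): %s\n",
                paste(format(object@bvalues), collapse = ", ")))
    cat(sprintf("  spacing (mm): %s\n",
                paste(format(object@spacing), collapse = " x ")))
})

setMethod("show", "ScalarMap", function(object) {
    d <- dim(object@values)
    kind <- object@provenance$map_kind
    cat(sprintf("ScalarMap%s: %d x %d x %d voxels\n",
                if (is.null(kind)) "" else paste0(" [", kind, "]"),
                d[1], d[2], d[3]))
    cat(sprintf("  range: [%.6g, %.6g]\n",
                min(object@values), max(object@values)))
    cat(sprintf("  spacing (mm): %s\n",
                paste(format(object@spacing), collapse = " x ")))
})

setMethod("show", "LabelMap", function(object) {
    d <- dim(object@labels)
    cat(sprintf("LabelMap: %d x %d x %d voxels\n", d[1], d[2], d[3]))
    tab <- table(object@labels)
    for (code in names(tab))
        cat(sprintf("  %s (%s): %d voxel(s)\n", code,
                    object@legend[[code]], tab[[code]]))
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf("PhantomSpec: %s voxels at %s mm, %d b-value(s), %d lesion(s)\n",
                paste(object@shape, collapse = " x "),
                paste(format(object@spacing), collapse = " x "),
                length(object@bvalues), nrow(object@lesions)))
    cat(sprintf("  noise sigma: %g, seed: %d\n", object@noiseSigma, object@seed))
})

setMethod("show", "ROCResult", function(object) {
    cat(sprintf("Binormal ROC: a = %.4f, b = %.4f, Az = %.4f\n",
                object@a, object@b, object@Az))
})

setMethod("show", "ClassifierModel", function(object) {
    cat("Two-class Gaussian ML classifier\n")
    for (cls in c("healthy", "cancer"))
        cat(sprintf("  %s: mean %.6g, sd %.6g (n = %g)\n", cls,
                    object@classMeans[[cls]], object@classSDs[[cls]],
                    object@nVoxels[[cls]]))
})

setMethod("show", "EvalMetrics", function(object) {
    cat(sprintf("EvalMetrics: sens %.4f, spec %.4f, acc %.4f (TP %g FP %g TN %g FN %g)\n",
                object@sensitivity, object@specificity, object@accuracy,
                object@TP, object@FP, object@TN, object@FN))
})
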