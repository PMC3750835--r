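#' Construct tissue signal parameters
#'
#' @param S0 baseline signal at b = 0 (arbitrary units, > 0).
#' @param D diffusivity in mm^2/s (>= 0).
#' @return a [TissueParams-class].
#' @export
tissueParams <- function(S0, D) new("TissueParams", S0 = as.numeric(S0),
                                    D = as.numeric(D))

#' Construct a phantom specification
#'
#' @param shape grid dimensions in voxels (length 3).
#' @param spacing voxel dimensions in mm (length 3).
#' @param bvalues b-values of the simulated acquisitions (s/mm^2).
#' @param tissues named list of [TissueParams-class], keyed by label code;
#'   must cover background (0), healthy (1) and every lesion label.
#' @param lesions data.frame with columns `x`, `y`, `z` (1-based centre
#'   voxel), `radius` (mm), `label` (integer code).
#' @param gland list with `center` (voxel triple) and `semiaxes` (mm triple)
#'   of the healthy-gland ellipsoid.
#' @param noiseSigma Rician noise scale, same units as `S0` (>= 0).
#' @param seed integer RNG seed for the noise realisation.
#' @return a validated [PhantomSpec-class].
#' @export
phantomSpec <- function(shape, spacing, bvalues, tissues, lesions, gland,
                        noiseSigma, seed) {
    new("PhantomSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
        bvalues = as.numeric(bvalues), tissues = tissues,
        lesions = as.data.frame(lesions), gland = gland,
        noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
}

#' The default prostate-like phantom
#'
#' A 64 x 64 x 16 grid at 1.56 x 1.56 x 3.5 mm spacing (the study cohort's
#' median in-plane resolution and slice thickness) with acquisitions at
#' b = 0, 100, 1000 and 2000 s/mm^2 — spanning the ADC b-value set
#' Omega = \\{0, 100, 1000\\} and both endpoints of the CDI diffusion range
#' \\[0, 2000\\]. The healthy gland is an ellipsoid with diffusivity
#' D = 1.5e-3 mm^2/s; two lesion spheres (radius 4 and 6 mm) carry
#' restricted diffusion, D = 0.7e-3 mm^2/s. Both gland and lesions have
#' S0 = 1000; the background is dim and fluid-like (S0 = 100,
#' D = 3.0e-3 mm^2/s). The Rician noise scale is S0/20 = 50, i.e. SNR 20
#' at b = 0.
#'
#' @param seed integer RNG seed for the noise realisation.
#' @return a [PhantomSpec-class].
#' @examples
#' spec <- defaultProstateSpec(seed = 1)
#' spec
#' @export
defaultProstateSpec <- function(seed = 1L) {
    phantomSpec(
        shape = c(64L, 64L, 16L),
        spacing = c(1.56, 1.56, 3.5),
        bvalues = c(0, 100, 1000, 2000),
        tissues = list(
            `0` = tissueParams(S0 = 100,  D = 3.0e-3),
            `1` = tissueParams(S0 = 1000, D = 1.5e-3),
            `2` = tissueParams(S0 = 1000, D = 0.7e-3)),
        lesions = data.frame(
            x = c(26, 38), y = c(28, 35), z = c(8, 8),
            radius = c(4, 6), label = c(2L, 2L)),
        gland = list(center = c(32.5, 32.5, 8.5), semiaxes = c(22, 18, 14)),
        noiseSigma = 50,
        seed = seed)
}

## geometry ------------------------------------------------------------------

.phantomLabels <- function(spec) {
    d <- spec@shape
    sp <- spec@spacing
    xs <- (seq_len(d[1]) - spec@gland$center[1]) * sp[1]
    ys <- (seq_len(d[2]) - spec@gland$center[2]) * sp[2]
    zs <- (seq_len(d[3]) - spec@gland$center[3]) * sp[3]
    ax <- spec@gland$semiaxes
    e <- outer(outer((xs / ax[1])^2, (ys / ax[2])^2, `+`), (zs / ax[3])^2, `+`)
    lab <- array(0L, dim = d)
    lab[e <= 1] <- 1L
    for (k in seq_len(nrow(spec@lesions))) {
        les <- spec@lesions[k, ]
        lx <- (seq_len(d[1]) - les$x) * sp[1]
        ly <- (seq_len(d[2]) - les$y) * sp[2]
        lz <- (seq_len(d[3]) - les$z) * sp[3]
        r2 <- outer(outer(lx^2, ly^2, `+`), lz^2, `+`)
        lab[r2 <= les$radius^2] <- as.integer(les$label)
    }
    lab
}

.withSeed <- function(seed, expr) {
    glob <- globalenv()
    had <- exists(".Random.seed", envir = glob, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = glob, inherits = FALSE)
    on.exit(if (had) assign(".Random.seed", old, envir = glob)
            else if (exists(".Random.seed", envir = glob, inherits = FALSE))
                rm(".Random.seed", envir = glob))
    set.seed(seed)
    expr
}

#' Generate a synthetic multi-b-value DWI phantom
#'
#' The noiseless signal at a voxel with label l for an acquisition at
#' b-value b is `S0(l) * exp(-b * D(l))` (mono-exponential decay). The
#' observed magnitude signal is Rician: `sqrt((S + e1)^2 + e2^2)` with `e1`,
#' `e2` independent zero-mean Gaussians of scale `noiseSigma`, drawn from a
#' generator seeded with the spec's seed — so identical specs give
#' bit-identical phantoms.
#'
#' @param spec a [PhantomSpec-class].
#' @return a list with elements `stack` (a [DWIStack-class]) and `labels`
#'   (a [LabelMap-class]).
#' @examples
#' ph <- generatePhantom(defaultProstateSpec(seed = 7))
#' ph$stack
#' @export
generatePhantom <- function(spec) {
    validObject(spec)
    lab <- .phantomLabels(spec)
    codes <- as.integer(names(spec@tissues))
    S0 <- vapply(spec@tissues, function(t) t@S0, numeric(1))
    D <- vapply(spec@tissues, function(t) t@D, numeric(1))
    idx <- match(as.vector(lab), codes)
    nb <- length(spec@bvalues)
    d4 <- c(spec@shape, nb)
    sig <- array(0, dim = d4)
    nvox <- prod(spec@shape)
    for (i in seq_len(nb))
        sig[, , , i] <- S0[idx] * exp(-spec@bvalues[i] * D[idx])
    if (spec@noiseSigma > 0) {
        sig <- .withSeed(spec@seed, {
            e1 <- array(stats::rnorm(nvox * nb, 0, spec@noiseSigma), dim = d4)
            e2 <- array(stats::rnorm(nvox * nb, 0, spec@noiseSigma), dim = d4)
            sqrt((sig + e1)^2 + e2^2)
        })
    }
    list(stack = dwiStack(sig, spec@bvalues, spacing = spec@spacing),
         labels = labelMap(lab, spacing = spec@spacing))
}

## structured-text spec files -----------------------------------------------

#' Read a phantom specification from a structured-text (YAML/JSON) file
#'
#' The file mirrors the [PhantomSpec-class] fields: `shape`, `spacing`,
#' `bvalues`, `tissues` (map of label code to `{S0, D}`), `lesions` (list of
#' `{x, y, z, radius, label}`), `gland` (`{center, semiaxes}`),
#' `noise_sigma`, `seed`. Fields left out default to the corresponding
#' [defaultProstateSpec()] values.
#'
#' @param path path to a YAML (or JSON) spec file.
#' @param seed seed overriding the file's `seed` field, if not `NULL`.
#' @return a [PhantomSpec-class].
#' @export
readPhantomSpec <- function(path, seed = NULL) {
    # YAML 1.1 would read a bare `y` key (lesion centre) as a boolean
    handlers <- list(
        "bool#yes" = function(x) if (tolower(x) == "y") "y" else TRUE,
        "bool#no"  = function(x) if (tolower(x) == "n") "n" else FALSE)
    raw <- yaml::read_yaml(path, handlers = handlers)
    def <- defaultProstateSpec(seed = raw$seed %||% 1L)
    tissues <- if (is.null(raw$tissues)) def@tissues else
        lapply(raw$tissues, function(t) tissueParams(t$S0, t$D))
    lesions <- if (is.null(raw$lesions)) def@lesions else
        do.call(rbind, lapply(raw$lesions, as.data.frame))
    gland <- raw$gland %||% def@gland
    phantomSpec(
        shape = raw$shape %||% def@shape,
        spacing = raw$spacing %||% def@spacing,
        bvalues = raw$bvalues %||% def@bvalues,
        tissues = tissues, lesions = lesions, gland = gland,
        noiseSigma = raw$noise_sigma %||% def@noiseSigma,
        seed = seed %||% raw$seed %||% def@seed)
}
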