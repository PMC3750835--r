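#' Construct a diffusion-weighting range
#'
#' @param qalpha lower b-value bound (s/mm^2), >= 0.
#' @param qbeta upper b-value bound (s/mm^2), >= `qalpha`. The study default
#'   is \\[0, 2000\\].
#' @return a [BRange-class].
#' @export
bRange <- function(qalpha = 0, qbeta = 2000) {
    new("BRange", qalpha = as.numeric(qalpha), qbeta = as.numeric(qbeta))
}

#' Construct a neighborhood specification
#'
#' Either give explicit per-axis voxel half-widths (`radii`), or a physical
#' extent (`size`) with its reading: `unit = "mm"` treats `size` as the side
#' of a cube, `unit = "mm3"` as a volume whose cube root is the side.
#'
#' @param radii integer length 3, per-axis half-widths in voxels; the default
#'   (1, 1, 1) is a 3x3x3 cube.
#' @param size physical extent (ignored when `radii` is given explicitly).
#' @param unit `"mm"` (cube side) or `"mm3"` (volume).
#' @return a [NeighborhoodSpec-class].
#' @examples
#' neighborhoodSpec()                      # 3x3x3 voxel cube
#' neighborhoodSpec(size = 7, unit = "mm") # 7 mm cube, converted via spacing
#' @export
neighborhoodSpec <- function(radii = c(1L, 1L, 1L), size = NULL,
                             unit = c("mm", "mm3")) {
    if (!is.null(size)) {
        unit <- match.arg(unit)
        new("NeighborhoodSpec", mode = "physical_size", radii = integer(0),
            size = as.numeric(size), unit = unit)
    } else {
        new("NeighborhoodSpec", mode = "voxel_radius",
            radii = as.integer(radii), size = numeric(0), unit = "mm")
    }
}

#' Convert a neighborhood specification to voxel half-widths
#'
#' In `voxel_radius` mode the radii pass through unchanged. In
#' `physical_size` mode the physical extent is converted to the smallest
#' per-axis half-widths whose spanned physical box covers it: the half-extent
#' `side/2` is divided by the axis spacing and rounded up.
#'
#' @param neighborhood a [NeighborhoodSpec-class].
#' @param spacing numeric length 3, voxel dimensions in mm.
#' @return integer length 3, per-axis half-widths in voxels.
#' @examples
#' neighborhoodVoxels(neighborhoodSpec(size = 7, unit = "mm"),
#'                    spacing = c(1.56, 1.56, 3.5))   # (3, 3, 1)
#' @export
neighborhoodVoxels <- function(neighborhood, spacing) {
    validObject(neighborhood)
    if (length(spacing) != 3L || any(spacing <= 0))
        stop("'spacing' must be 3 positive voxel dimensions (mm)")
    if (neighborhood@mode == "voxel_radius")
        return(neighborhood@radii)
    side <- if (neighborhood@unit == "mm3")
        neighborhood@size^(1 / 3) else neighborhood@size
    as.integer(ceiling((side / 2) / spacing))
}

## separable clipped box mean ------------------------------------------------

# Sliding-window sum along the first array axis with window [i-r, i+r]
# clipped at the edges, via cumulative sums. All entries are nonnegative in
# the CDI use, so the cumsum differences stay well conditioned.
.runSumFirst <- function(A, r) {
    if (r == 0L) return(A)
    d <- dim(A)
    n <- d[1L]
    cs <- apply(A, c(2L, 3L), cumsum)       # dims preserved for n > 1
    if (n == 1L) dim(cs) <- d
    cs0 <- array(0, dim = c(n + 1L, d[2L], d[3L]))   # cs0[k] = cs[k - 1]
    cs0[-1L, , ] <- cs
    hi <- pmin(seq_len(n) + r, n)
    lo <- pmax(seq_len(n) - r, 1L)          # cs0[lo] is the sum before the window
    cs[hi, , , drop = FALSE] - cs0[lo, , , drop = FALSE]
}

# Mean over the axis-aligned box neighborhood with half-widths `radii`,
# clipped at the volume boundary (mean over the in-bounds count).
.boxMean3D <- function(A, radii) {
    d <- dim(A)
    S <- A
    for (ax in 1:3) {
        S <- .runSumFirst(S, radii[ax])
        S <- aperm(S, c(2, 3, 1))
    }
    cnt <- lapply(1:3, function(ax) {
        i <- seq_len(d[ax])
        pmin(i + radii[ax], d[ax]) - pmax(i - radii[ax], 1L) + 1
    })
    N <- outer(outer(cnt[[1]], cnt[[2]]), cnt[[3]])
    S / N
}

## CDI -----------------------------------------------------------------------

#' Compute the correlated diffusion imaging (CDI) map
#'
#' CDI characterises each voxel by the local joint correlation of signal
#' attenuation across acquisitions whose b-values fall in a diffusion range
#' \\[q_alpha, q_beta\\]: the expectation, under the joint distribution of the
#' in-range signals over a local spatial sub-volume V(x), of the product of
#' those signals. With the empirical (plug-in) distribution over the
#' sub-volume this is
#'
#'   C(x) = (1 / |V(x)|) * sum over x' in V(x) of  prod over i in I of S_i(x')
#'
#' where I = \\{i : q_alpha <= b_i <= q_beta\\} and V(x) is the box
#' neighborhood clipped at the volume boundary (|V(x)| counts in-bounds
#' voxels only; no padding is fabricated). Raw magnitude signals enter the
#' product by default; `normalizeB0 = TRUE` divides every volume voxelwise
#' by the mean b = 0 volume first.
#'
#' @param stack a [DWIStack-class].
#' @param brange a [BRange-class]; default \\[0, 2000\\] s/mm^2.
#' @param neighborhood a [NeighborhoodSpec-class]; default a 3x3x3 voxel
#'   cube.
#' @param normalizeB0 logical; divide by the b = 0 volume before mixing.
#'   Requires a b = 0 acquisition. Recorded in provenance.
#' @return a [ScalarMap-class] with `map_kind = "CDI"`; provenance records
#'   the in-range acquisition indices, the b-range and the neighborhood.
#' @examples
#' ph <- generatePhantom(defaultProstateSpec(seed = 1))
#' cdi <- computeCDI(ph$stack)
#' cdi
#' @export
computeCDI <- function(stack, brange = bRange(0, 2000),
                       neighborhood = neighborhoodSpec(),
                       normalizeB0 = FALSE) {
    validObject(stack); validObject(brange)
    d <- dim(stack@signal)
    I <- which(stack@bvalues >= brange@qalpha & stack@bvalues <= brange@qbeta)
    if (!length(I))
        stop("no acquisitions in diffusion range [",
             brange@qalpha, ", ", brange@qbeta, "]")
    radii <- neighborhoodVoxels(neighborhood, stack@spacing)
    if (any(radii >= d[1:3]))
        stop("neighborhood half-widths (", paste(radii, collapse = ","),
             ") must be smaller than the grid dimensions")
    sig <- stack@signal
    if (normalizeB0) {
        ib0 <- which(abs(stack@bvalues) < 1e-6)
        if (!length(ib0)) stop("normalizeB0 requires a b = 0 acquisition")
        b0 <- apply(sig[, , , ib0, drop = FALSE], 1:3, mean)
        b0[b0 <= 0] <- 1e-6 * max(sig)
        for (i in seq_len(d[4L])) sig[, , , i] <- sig[, , , i] / b0
    }
    P <- sig[, , , I[1L]]
    for (j in I[-1L]) P <- P * sig[, , , j]
    dim(P) <- d[1:3]
    C <- .boxMean3D(P, radii)
    scalarMap(C, spacing = stack@spacing, provenance = list(
        map_kind = "CDI",
        b_range = c(brange@qalpha, brange@qbeta),
        acquisition_indices = I,
        acquisition_bvalues = stack@bvalues[I],
        neighborhood_voxels = radii,
        normalized_b0 = normalizeB0))
}

## ADC -----------------------------------------------------------------------

#' Compute the apparent diffusion coefficient (ADC) map
#'
#' Per voxel, an ordinary least-squares fit of ln S against b over the
#' acquisitions whose b-values match the set Omega; the ADC is the negated
#' slope, clamped below at 0 (in mm^2/s). Voxels with any nonpositive
#' signal in Omega have those signals replaced by a floor of
#' `1e-6 * max(signal)` before the log; the floored voxel count is recorded
#' in provenance. The study's ADC baseline uses
#' Omega = \\{0, 100, 1000\\} s/mm^2.
#'
#' @param stack a [DWIStack-class].
#' @param omega numeric, b-values of the acquisitions to fit (>= 2 values),
#'   each matching a stack b-value within 1e-6.
#' @return a [ScalarMap-class] with `map_kind = "ADC"`.
#' @examples
#' ph <- generatePhantom(defaultProstateSpec(seed = 1))
#' adc <- computeADC(ph$stack)
#' adc
#' @export
computeADC <- function(stack, omega = c(0, 100, 1000)) {
    validObject(stack)
    if (length(omega) < 2L)
        stop("'omega' needs at least 2 b-values for a slope fit")
    idx <- vapply(omega, function(b) {
        j <- which(abs(stack@bvalues - b) <= 1e-6)
        if (!length(j))
            stop("omega b-value ", b, " s/mm^2 is absent from the stack")
        j[1L]
    }, integer(1))
    d <- dim(stack@signal)
    nvox <- prod(d[1:3])
    S <- matrix(stack@signal[, , , idx], nrow = nvox, ncol = length(idx))
    floorVal <- 1e-6 * max(stack@signal)
    bad <- S <= 0
    nFloored <- sum(rowSums(bad) > 0)
    if (nFloored > 0) {
        message(sprintf("computeADC: floored signal in %d voxel(s)", nFloored))
        S[bad] <- floorVal
    }
    b <- as.numeric(omega)
    bc <- b - mean(b)
    L <- log(S)
    L <- L - rowMeans(L)   # centring makes constant-signal slopes exactly 0
    slope <- as.vector(L %*% bc) / sum(bc^2)
    adc <- pmax(-slope, 0)
    dim(adc) <- d[1:3]
    scalarMap(adc, spacing = stack@spacing, provenance = list(
        map_kind = "ADC",
        omega = b,
        acquisition_indices = idx,
        floored_voxels = nFloored))
}
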