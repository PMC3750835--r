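#' Construct a DWI stack
#'
#' @param signal 4D nonnegative numeric array, indexed (x, y, z, acquisition).
#' @param bvalues numeric, one b-value (s/mm^2) per volume.
#' @param spacing numeric length 3, voxel dimensions in mm.
#' @param orientation optional 4x4 voxel-to-world affine.
#' @return a [DWIStack-class].
#' @export
dwiStack <- function(signal, bvalues, spacing = c(1, 1, 1),
                     orientation = NULL) {
    if (is.null(orientation))
        orientation <- matrix(numeric(0), 0L, 0L)
    new("DWIStack", signal = signal, bvalues = as.numeric(bvalues),
        spacing = as.numeric(spacing), orientation = orientation)
}

#' Construct a derived scalar map
#'
#' @param values 3D nonnegative numeric array.
#' @param spacing numeric length 3, voxel dimensions in mm.
#' @param provenance list of parameters that produced the map (at least
#'   `map_kind`).
#' @return a [ScalarMap-class].
#' @export
scalarMap <- function(values, spacing = c(1, 1, 1), provenance = list()) {
    new("ScalarMap", values = values, spacing = as.numeric(spacing),
        provenance = provenance)
}

#' Construct a label map
#'
#' @param labels 3D integer array of tissue codes.
#' @param spacing numeric length 3, voxel dimensions in mm.
#' @param legend named character vector mapping code to tissue name; defaults
#'   to the codes present, using the standard legend (0 background, 1 healthy
#'   prostate, 2 cancer) where applicable.
#' @return a [LabelMap-class].
#' @export
labelMap <- function(labels, spacing = c(1, 1, 1), legend = NULL) {
    storage.mode(labels) <- "integer"
    if (is.null(legend)) {
        std <- c(`0` = "background", `1` = "healthy prostate", `2` = "cancer")
        present <- as.character(sort(unique(as.vector(labels))))
        legend <- ifelse(present %in% names(std), std[present],
                         paste("tissue", present))
        names(legend) <- present
    }
    new("LabelMap", labels = labels, spacing = as.numeric(spacing),
        legend = legend)
}

## FSL-style .bval sidecar ---------------------------------------------------

#' Read an FSL-style .bval sidecar
#'
#' A .bval file holds whitespace-separated numeric b-values in s/mm^2, one
#' per 4D volume index, on one or several lines.
#'
#' @param path path to the .bval file.
#' @return numeric vector of b-values.
#' @export
readBVal <- function(path) {
    if (!file.exists(path)) stop("bval file not found: ", path)
    toks <- scan(path, what = character(), quiet = TRUE)
    vals <- suppressWarnings(as.numeric(toks))
    if (!length(vals) || any(is.na(vals)))
        stop("bval file does not parse to numbers: ", path)
    vals
}

#' Write an FSL-style .bval sidecar
#'
#' @param bvalues numeric b-values in s/mm^2.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBVal <- function(bvalues, path) {
    writeLines(paste(format(bvalues, trim = TRUE, scientific = FALSE),
                     collapse = " "), path)
    invisible(path)
}

## NIfTI helpers -------------------------------------------------------------

.niftiWrite <- function(arr, spacing, path, datatype, descrip = "",
                        orientation = NULL) {
    ref <- list(pixdim = c(-1, spacing, rep(1, 7 - length(spacing))),
                descrip = substr(descrip, 1L, 79L))  # NIfTI-1 descrip limit
    img <- RNifti::asNifti(arr, reference = ref, datatype = datatype)
    if (!is.null(orientation) && identical(dim(orientation), c(4L, 4L)))
        RNifti::sform(img) <- structure(orientation, code = 2L)
    RNifti::writeNifti(img, path)
    invisible(path)
}

.niftiRead <- function(path) {
    if (!file.exists(path)) stop("NIfTI file not found: ", path)
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    data <- array(as.vector(img), dim = dim(img))   # plain array, no image class
    list(data = data,
         spacing = pd[seq_len(min(3L, length(pd)))],
         xform = matrix(as.vector(RNifti::xform(img)), 4L, 4L))
}

.sidecarPath <- function(path) {
    sub("\\.nii(\\.gz)?$", ".json", path)
}

## stacks --------------------------------------------------------------------

#' Read a 4D DWI stack with its b-value sidecar
#'
#' Reads a 4D NIfTI-1 volume and an FSL-style .bval sidecar and assembles a
#' validated [DWIStack-class]. Negative voxels (which resampled clinical
#' magnitude data can contain) are clamped to 0, and the clamped count is
#' reported via a message.
#'
#' @param volumePath path to the 4D NIfTI-1 file (.nii or .nii.gz).
#' @param bvalPath path to the .bval sidecar; one value per volume.
#' @return a [DWIStack-class].
#' @export
readDWI <- function(volumePath, bvalPath) {
    nii <- .niftiRead(volumePath)
    arr <- nii$data
    if (length(dim(arr)) != 4L)
        stop(sprintf("expected a 4D volume, got %dD: %s",
                     length(dim(arr)), volumePath))
    bvals <- readBVal(bvalPath)
    if (length(bvals) != dim(arr)[4L])
        stop(sprintf("volume has %d acquisitions but bval sidecar has %d values",
                     dim(arr)[4L], length(bvals)))
    neg <- sum(arr < 0)
    if (neg > 0) {
        message(sprintf("readDWI: clamped %d negative voxel(s) to 0", neg))
        arr[arr < 0] <- 0
    }
    dwiStack(arr, bvals, spacing = nii$spacing, orientation = nii$xform)
}

#' Write a DWI stack and its .bval sidecar
#'
#' @param stack a [DWIStack-class].
#' @param volumePath output NIfTI-1 path (.nii or .nii.gz).
#' @param bvalPath output .bval path.
#' @return `volumePath`, invisibly.
#' @export
writeDWI <- function(stack, volumePath, bvalPath) {
    validObject(stack)
    orient <- if (identical(dim(stack@orientation), c(4L, 4L)))
        stack@orientation else NULL
    .niftiWrite(stack@signal, stack@spacing, volumePath, datatype = "float",
                descrip = "multi-b-value DWI", orientation = orient)
    writeBVal(stack@bvalues, bvalPath)
    invisible(volumePath)
}

## maps ----------------------------------------------------------------------

#' Write a derived map to NIfTI-1 with a JSON provenance sidecar
#'
#' Map values are stored as 32-bit floats. The provenance is serialised both
#' into the NIfTI description field (truncated to the format's 79-character
#' limit) and into a JSON sidecar next to the volume (same stem, `.json`).
#'
#' @param map a [ScalarMap-class].
#' @param path output NIfTI-1 path.
#' @return `path`, invisibly.
#' @export
writeMap <- function(map, path) {
    validObject(map)
    prov <- map@provenance
    desc <- paste0(prov$map_kind %||% "map", " ",
                   if (!is.null(prov$b_range))
                       paste0("[", paste(prov$b_range, collapse = ","), "]")
                   else if (!is.null(prov$omega))
                       paste0("omega={", paste(prov$omega, collapse = ","), "}")
                   else "")
    .niftiWrite(map@values, map@spacing, path, datatype = "float",
                descrip = desc)
    jsonlite::write_json(prov, .sidecarPath(path), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}

#' Read a derived map written by [writeMap()]
#'
#' @param path NIfTI-1 path; the JSON provenance sidecar is read if present.
#' @return a [ScalarMap-class].
#' @export
readMap <- function(path) {
    nii <- .niftiRead(path)
    if (length(dim(nii$data)) != 3L)
        stop(sprintf("expected a 3D map, got %dD: %s",
                     length(dim(nii$data)), path))
    side <- .sidecarPath(path)
    prov <- if (file.exists(side))
        jsonlite::read_json(side, simplifyVector = TRUE) else list()
    scalarMap(nii$data, spacing = nii$spacing, provenance = prov)
}

## labels --------------------------------------------------------------------

#' Read an integer tissue label map
#'
#' @param path NIfTI-1 path holding integer-valued voxels.
#' @return a [LabelMap-class]; non-integer voxel values are an error.
#' @export
readLabels <- function(path) {
    nii <- .niftiRead(path)
    arr <- nii$data
    if (length(dim(arr)) != 3L)
        stop(sprintf("expected a 3D label volume, got %dD: %s",
                     length(dim(arr)), path))
    if (any(arr != round(arr)))
        stop("label volume contains non-integer voxel values: ", path)
    labelMap(arr, spacing = nii$spacing)
}

#' Write a label map to NIfTI-1
#'
#' Labels are stored as 16-bit integers so they round-trip exactly.
#'
#' @param labels a [LabelMap-class].
#' @param path output NIfTI-1 path.
#' @return `path`, invisibly.
#' @export
writeLabels <- function(labels, path) {
    validObject(labels)
    .niftiWrite(labels@labels, labels@spacing, path, datatype = "int16",
                descrip = "tissue labels")
    invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
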