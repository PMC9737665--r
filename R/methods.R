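#' @describeIn CentroidSpectrum-class retention time (minutes).
#' @param object,x a `CentroidSpectrum`.
#' @param ... ignored.
#' @exportMethod rtime
setMethod("rtime", "CentroidSpectrum", function(object, ...) object@rtime)

#' @describeIn CentroidSpectrum-class centroid m/z vector.
#' @exportMethod mz
setMethod("mz", "CentroidSpectrum", function(object, ...) object@mz)

#' @describeIn CentroidSpectrum-class centroid intensity vector.
#' @exportMethod intensity
setMethod("intensity", "CentroidSpectrum", function(object, ...)
    object@intensity)

#' @describeIn CentroidSpectrum-class acquisition polarity.
#' @exportMethod polarity
setMethod("polarity", "CentroidSpectrum", function(object) object@polarity)

setMethod("length", "CentroidSpectrum", function(x) length(x@mz))

setMethod("show", "CentroidSpectrum", function(object) {
    cat("CentroidSpectrum:", length(object@mz), "peaks at RT",
        sprintf("%.3f min", object@rtime),
        sprintf("[%s mode]\n", object@polarity))
})

#' @describeIn MsRun-class run identifier.
#' @param object,x an `MsRun`.
#' @exportMethod runId
setMethod("runId", "MsRun", function(object) object@runId)

#' @describeIn MsRun-class list of scans.
#' @exportMethod scans
setMethod("scans", "MsRun", function(object) object@scans)

#' @describeIn MsRun-class acquisition polarity.
#' @exportMethod polarity
setMethod("polarity", "MsRun", function(object) object@polarity)

#' @describeIn MsRun-class scan retention times (minutes).
#' @exportMethod rtime
setMethod("rtime", "MsRun", function(object, ...)
    vapply(object@scans, function(s) s@rtime, numeric(1)))

setMethod("length", "MsRun", function(x) length(x@scans))

setMethod("show", "MsRun", function(object) {
    rts <- rtime(object)
    cat("MsRun \"", object@runId, "\": ", length(object@scans),
        " scans [", object@polarity, " mode]", sep = "")
    if (length(rts))
        cat(sprintf(", RT %.2f-%.2f min", min(rts), max(rts)))
    cat("\n")
})

#' @describeIn Eic-class intensity-weighted m/z center.
#' @param object an `Eic`.
#' @exportMethod mzCenter
setMethod("mzCenter", "Eic", function(object) object@mzCenter)

#' @describeIn Eic-class per-scan point table.
#' @exportMethod chromPoints
setMethod("chromPoints", "Eic", function(object) object@points)

#' @describeIn Eic-class originating run.
#' @exportMethod runId
setMethod("runId", "Eic", function(object) object@runId)

#' @describeIn Eic-class acquisition polarity.
#' @exportMethod polarity
setMethod("polarity", "Eic", function(object) object@polarity)

setMethod("length", "Eic", function(x) nrow(x@points))

setMethod("show", "Eic", function(object) {
    cat(sprintf("Eic m/z %.5f: %d points, RT %.2f-%.2f min (run %s)\n",
                object@mzCenter, nrow(object@points),
                min(object@points$rt), max(object@points$rt), object@runId))
})

#' @describeIn Ms2Spectrum-class precursor m/z.
#' @param object,x an `Ms2Spectrum`.
#' @param ... ignored.
#' @exportMethod precursorMz
setMethod("precursorMz", "Ms2Spectrum", function(object) object@precursorMz)

#' @describeIn Ms2Spectrum-class fragment m/z vector.
#' @exportMethod mz
setMethod("mz", "Ms2Spectrum", function(object, ...) object@mz)

#' @describeIn Ms2Spectrum-class fragment intensity vector.
#' @exportMethod intensity
setMethod("intensity", "Ms2Spectrum", function(object, ...) object@intensity)

#' @describeIn Ms2Spectrum-class acquisition polarity.
#' @exportMethod polarity
setMethod("polarity", "Ms2Spectrum", function(object) object@polarity)

setMethod("show", "Ms2Spectrum", function(object) {
    cat(sprintf("Ms2Spectrum precursor m/z %.4f [%s]: %d fragments\n",
                object@precursorMz, object@polarity, length(object@mz)))
})

#' FeatureTable accessors
#'
#' Convenience accessors on top of the usual
#' \pkg{SummarizedExperiment} API.
#'
#' @param x a [FeatureTable-class].
#' @return `featureMz`/`featureRt`: numeric vectors of consensus m/z and RT;
#'   `intensityMatrix`: the feature-by-run area matrix; `statusMatrix`: the
#'   matching status matrix; `runGroups`: the `"vector"`/`"enzyme"` label per
#'   run column.
#' @name FeatureTable-accessors
#' @export
featureMz <- function(x) rowData(x)$mz

#' @rdname FeatureTable-accessors
#' @export
featureRt <- function(x) rowData(x)$rt

#' @rdname FeatureTable-accessors
#' @export
intensityMatrix <- function(x) assay(x, "intensity")

#' @rdname FeatureTable-accessors
#' @export
statusMatrix <- function(x) assay(x, "status")

#' @rdname FeatureTable-accessors
#' @export
runGroups <- function(x) setNames(as.character(colData(x)$group),
                                  colnames(x))

setMethod("show", "FeatureTable", function(object) {
    st <- assay(object, "status")
    cat("FeatureTable:", nrow(object), "features x", ncol(object), "runs [",
        S4Vectors::metadata(object)$polarity, "mode]\n")
    cat("  groups:", paste(sprintf("%s=%s", colData(object)$run,
                                   colData(object)$group), collapse = ", "),
        "\n")
    cat(sprintf("  cells: %d detected, %d gap-filled, %d missing\n",
                sum(st == "detected"), sum(st == "gap_filled"),
                sum(st == "missing")))
})

setMethod("show", "DecarbReport", function(object) {
    cat("DecarbReport\n")
    for (p in names(object@ranked))
        cat(sprintf("  %s mode: %d features ranked, %d calls\n", p,
                    nrow(object@ranked[[p]]),
                    if (is.null(object@calls[[p]])) 0L
                    else nrow(object@calls[[p]])))
    cat("  substrate/product pairs:", nrow(object@pairs), "\n")
    if (nrow(object@panel))
        cat("  targeted panel analytes:", nrow(object@panel), "\n")
})
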