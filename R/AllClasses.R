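#' @import methods
#' @importFrom stats quantile rnorm rlnorm runif rexp median setNames
#' @importFrom utils read.csv write.csv head tail
NULL

.valid_polarity <- function(p) {
    if (length(p) != 1L || !p %in% c("positive", "negative"))
        return("polarity must be \"positive\" or \"negative\"")
    NULL
}

#' A single centroided MS1 scan
#'
#' One centroided mass spectrum: retention time, polarity and the centroid
#' peak list as parallel `mz`/`intensity` vectors sorted by m/z.
#'
#' @slot rtime retention time of the scan, in minutes.
#' @slot polarity `"positive"` or `"negative"`.
#' @slot mz numeric, centroid m/z values, sorted increasing.
#' @slot intensity numeric, centroid intensities (>= 0), parallel to `mz`.
#'
#' @seealso [CentroidSpectrum()] for the constructor, [detectMasses()].
#' @exportClass CentroidSpectrum
setClass("CentroidSpectrum",
    representation(rtime = "numeric", polarity = "character",
                   mz = "numeric", intensity = "numeric"),
    prototype(rtime = 0, polarity = "positive",
              mz = numeric(), intensity = numeric()))

setValidity("CentroidSpectrum", function(object) {
    msg <- character()
    if (length(object@mz) != length(object@intensity))
        msg <- c(msg, "mz and intensity must have equal length")
    if (is.unsorted(object@mz))
        msg <- c(msg, "mz must be sorted increasing")
    if (length(object@intensity) && any(object@intensity < 0))
        msg <- c(msg, "intensities must be >= 0")
    msg <- c(msg, .valid_polarity(object@polarity))
    if (length(msg)) msg else TRUE
})

#' @param rtime,polarity,mz,intensity see the slot descriptions.
#' @rdname CentroidSpectrum-class
#' @export
CentroidSpectrum <- function(rtime, mz, intensity, polarity = "positive") {
    o <- order(mz)
    new("CentroidSpectrum", rtime = as.numeric(rtime), polarity = polarity,
        mz = as.numeric(mz)[o], intensity = as.numeric(intensity)[o])
}

#' An LC-MS run
#'
#' An RT-ordered list of [CentroidSpectrum-class] scans from one sample
#' injection, plus run identifier, polarity and free-form metadata
#' (instrument settings, group label and the like).
#'
#' @slot runId character scalar sample/run identifier.
#' @slot polarity `"positive"` or `"negative"`; all scans must agree.
#' @slot scans list of [CentroidSpectrum-class], RT-ordered.
#' @slot metadata named list of run-level metadata.
#'
#' @exportClass MsRun
setClass("MsRun",
    representation(runId = "character", polarity = "character",
                   scans = "list", metadata = "list"),
    prototype(runId = "run", polarity = "positive", scans = list(),
              metadata = list()))

setValidity("MsRun", function(object) {
    msg <- .valid_polarity(object@polarity)
    rts <- vapply(object@scans, function(s) s@rtime, numeric(1))
    if (is.unsorted(rts)) msg <- c(msg, "scans must be RT-ordered")
    if (length(msg)) msg else TRUE
})

#' @param runId,polarity,scans,metadata see the slot descriptions.
#' @rdname MsRun-class
#' @export
MsRun <- function(scans, runId = "run", polarity = "positive",
                  metadata = list()) {
    new("MsRun", runId = runId, polarity = polarity, scans = scans,
        metadata = metadata)
}

#' An extracted ion chromatogram
#'
#' An ion trace built from one run: the intensity-weighted m/z center and a
#' per-scan point table (`scan`, `rt`, `mz`, `intensity`), RT-ordered.
#'
#' @slot mzCenter intensity-weighted mean m/z of the member points.
#' @slot runId the run the trace was extracted from.
#' @slot polarity acquisition polarity.
#' @slot points data.frame with columns `scan`, `rt`, `mz`, `intensity`.
#'
#' @seealso [buildEics()], [smoothEic()], [resolveFeatures()]
#' @exportClass Eic
setClass("Eic",
    representation(mzCenter = "numeric", runId = "character",
                   polarity = "character", points = "data.frame"))

setValidity("Eic", function(object) {
    msg <- .valid_polarity(object@polarity)
    need <- c("scan", "rt", "mz", "intensity")
    if (!all(need %in% names(object@points)))
        msg <- c(msg, "points must have columns scan, rt, mz, intensity")
    else if (is.unsorted(object@points$rt))
        msg <- c(msg, "points must be RT-ordered")
    if (length(msg)) msg else TRUE
})

#' A product-ion (MS2) spectrum
#'
#' @slot precursorMz precursor ion m/z.
#' @slot polarity `"positive"` or `"negative"`.
#' @slot mz fragment m/z values, sorted increasing.
#' @slot intensity fragment intensities (>= 0).
#'
#' @seealso [cosineScore()], [identifyMs2()]
#' @exportClass Ms2Spectrum
setClass("Ms2Spectrum",
    representation(precursorMz = "numeric", polarity = "character",
                   mz = "numeric", intensity = "numeric"))

setValidity("Ms2Spectrum", function(object) {
    msg <- .valid_polarity(object@polarity)
    if (length(object@mz) != length(object@intensity))
        msg <- c(msg, "mz and intensity must have equal length")
    if (is.unsorted(object@mz))
        msg <- c(msg, "fragment mz must be sorted increasing")
    if (length(object@intensity) && any(object@intensity < 0))
        msg <- c(msg, "intensities must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @param precursorMz,polarity,mz,intensity see the slot descriptions.
#' @rdname Ms2Spectrum-class
#' @export
Ms2Spectrum <- function(precursorMz, mz, intensity, polarity = "positive") {
    o <- order(mz)
    new("Ms2Spectrum", precursorMz = as.numeric(precursorMz),
        polarity = polarity, mz = as.numeric(mz)[o],
        intensity = as.numeric(intensity)[o])
}

#' Cross-sample aligned feature table
#'
#' Features aligned across runs, stored as a
#' [SummarizedExperiment::SummarizedExperiment-class]: rows are consensus
#' features (rowData columns `mz`, `rt`), columns are runs (colData columns
#' `run`, `group` with levels `"vector"`/`"enzyme"`), and two assays hold the
#' per-run peak areas (`"intensity"`) and the fill status (`"status"`, one of
#' `"detected"`, `"gap_filled"`, `"missing"`). The acquisition polarity is
#' kept in `metadata(x)$polarity`; positive- and negative-mode tables are
#' never merged.
#'
#' @seealso [joinAlign()], [gapFill()], [filterDuplicates()], [rankRatios()]
#' @exportClass FeatureTable
#' @import SummarizedExperiment
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
    msg <- character()
    if (!all(c("intensity", "status") %in% assayNames(object)))
        msg <- c(msg, "assays \"intensity\" and \"status\" are required")
    if (!all(c("mz", "rt") %in% names(rowData(object))))
        msg <- c(msg, "rowData must have columns mz and rt")
    if (!all(c("run", "group") %in% names(colData(object))))
        msg <- c(msg, "colData must have columns run and group")
    else if (!all(colData(object)$group %in% c("vector", "enzyme")))
        msg <- c(msg, "group labels must be \"vector\" or \"enzyme\"")
    if (length(msg)) msg else TRUE
})

#' Pipeline result container
#'
#' Everything one end-to-end analysis produced: the aligned tables, ranked
#' vector/enzyme ratio records and candidate calls per polarity, the CO2-loss
#' substrate/product pairs with annotations, the targeted panel result (if
#' any), the echoed configuration and a per-stage count log.
#'
#' @slot tables named list of [FeatureTable-class], one per polarity.
#' @slot ranked named list of ratio-record data.frames (see [rankRatios()]).
#' @slot calls named list of candidate-call data.frames.
#' @slot pairs data.frame of substrate/product pairs (see
#'   [pairDecarboxylation()]), with annotation columns.
#' @slot panel data.frame from [panelCompare()] or a zero-row placeholder.
#' @slot config the fully-resolved configuration list.
#' @slot log data.frame of per-stage input/output counts.
#'
#' @seealso [runUntargeted()], [runTargeted()], [writeReport()]
#' @exportClass DecarbReport
setClass("DecarbReport",
    representation(tables = "list", ranked = "list", calls = "list",
                   pairs = "data.frame", panel = "data.frame",
                   config = "list", log = "data.frame"))
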