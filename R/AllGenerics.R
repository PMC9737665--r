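#' @importFrom ProtGenerics mz intensity rtime polarity precursorMz
NULL

#' Accessor generics
#'
#' Small accessor generics for the classes in this package, following the
#' usual mass-spectrometry container conventions (`mz()`, `intensity()`,
#' `rtime()`, `polarity()` and `precursorMz()` are re-exported from
#' \pkg{ProtGenerics}).
#'
#' @param object an object of one of the package's classes.
#' @name accessors
#' @aliases runId scans mzCenter chromPoints
NULL

#' @rdname accessors
#' @export
setGeneric("runId", function(object) standardGeneric("runId"))

#' @rdname accessors
#' @export
setGeneric("scans", function(object) standardGeneric("scans"))

#' @rdname accessors
#' @export
setGeneric("mzCenter", function(object) standardGeneric("mzCenter"))

#' @rdname accessors
#' @export
setGeneric("chromPoints", function(object) standardGeneric("chromPoints"))
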