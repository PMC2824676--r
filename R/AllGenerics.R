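#' @rdname CompetedTrack-class
#' @param x a \code{CompetedTrack}.
#' @export
setGeneric("keptFeatures", function(x) standardGeneric("keptFeatures"))

#' @rdname CompetedTrack-class
#' @export
setGeneric("eliminatedFeatures",
    function(x) standardGeneric("eliminatedFeatures"))

#' @rdname ExactMatchSet-class
#' @param x an object.
#' @export
setGeneric("matchLevels", function(x) standardGeneric("matchLevels"))

#' @rdname ExactMatchSet-class
#' @export
setGeneric("orientations", function(x) standardGeneric("orientations"))

#' @rdname CoverageChart-class
#' @param x an object.
#' @export
setGeneric("chartValues", function(x) standardGeneric("chartValues"))

#' Query identifier of an object
#' @param x an object with a query slot.
#' @export
setGeneric("queryName", function(x) standardGeneric("queryName"))

#' @rdname CentromereSim-class
#' @param x a \code{CentromereSim}.
#' @export
setGeneric("simGenome", function(x) standardGeneric("simGenome"))

#' @rdname CentromereSim-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' Serialize a display model to SVG
#' @param x a \code{DisplayModel}.
#' @return single character string holding the SVG document.
#' @export
setGeneric("toSVG", function(x) standardGeneric("toSVG"))

#' Serialize a display model to PostScript
#' @param x a \code{DisplayModel}.
#' @return single character string holding the PostScript document.
#' @export
setGeneric("toPostscript", function(x) standardGeneric("toPostscript"))
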