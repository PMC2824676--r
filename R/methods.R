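# Accessors and show methods for the core S4 containers.

#' @rdname ExactMatchSet-class
#' @export
setMethod("length", "ExactMatchSet", function(x) length(x@first))

#' @rdname ExactMatchSet-class
#' @export
setMethod("matchLevels", "ExactMatchSet", function(x) x@level)

#' @rdname ExactMatchSet-class
#' @export
setMethod("orientations", "ExactMatchSet", function(x) x@orientation)

#' @rdname ExactMatchSet-class
#' @export
setMethod("queryName", "ExactMatchSet", function(x) x@query)

#' Interval accessors for ExactMatchSet
#'
#' \code{firstRanges}/\code{secondRanges} return the two paired interval
#' sets; \code{matchLengths} the per-pair match length.
#'
#' @param x an \code{ExactMatchSet}.
#' @return \code{IRanges} or an integer vector.
#' @export
firstRanges <- function(x) x@first

#' @rdname firstRanges
#' @export
secondRanges <- function(x) x@second

#' @rdname firstRanges
#' @export
matchLengths <- function(x) width(x@first)

#' @rdname ExactMatchSet-class
#' @param i index
#' @param j,drop,... ignored
#' @export
setMethod("[", "ExactMatchSet", function(x, i, j, ..., drop = FALSE) {
    new("ExactMatchSet", query = x@query, first = x@first[i],
        second = x@second[i], orientation = x@orientation[i],
        level = x@level[i])
})

#' @rdname ExactMatchSet-class
#' @param object an \code{ExactMatchSet}.
#' @export
setMethod("show", "ExactMatchSet", function(object) {
    n <- length(object)
    cat("ExactMatchSet for query '", object@query, "' with ", n,
        " match pair(s)\n", sep = "")
    if (n > 0) {
        cat("  direct: ", sum(object@orientation == "direct"),
            "  inverted: ", sum(object@orientation == "inverted"),
            "  length range: [", min(width(object@first)), ", ",
            max(width(object@first)), "]\n", sep = "")
    }
    invisible(object)
})

#' @rdname ExactMatchSet-class
#' @param row.names,optional,... passed on
#' @export
setMethod("as.data.frame", "ExactMatchSet",
    function(x, row.names = NULL, optional = FALSE, ...) {
        data.frame(
            query = rep(x@query, length(x)),
            aStart = start(x@first), aEnd = end(x@first),
            bStart = start(x@second), bEnd = end(x@second),
            length = width(x@first),
            orientation = x@orientation,
            level = x@level,
            stringsAsFactors = FALSE)
    })

#' @rdname CompetedTrack-class
#' @export
setMethod("keptFeatures", "CompetedTrack", function(x) x@kept)

#' @rdname CompetedTrack-class
#' @export
setMethod("eliminatedFeatures", "CompetedTrack", function(x) x@eliminated)

#' @rdname CompetedTrack-class
#' @export
setMethod("queryName", "CompetedTrack", function(x) x@query)

#' @rdname CompetedTrack-class
#' @param object a \code{CompetedTrack}.
#' @export
setMethod("show", "CompetedTrack", function(object) {
    cat("CompetedTrack for query '", object@query, "' (mode: ",
        object@params$mode, ", allowance: ", object@params$allowance,
        " nt)\n  kept: ", length(object@kept), "  eliminated: ",
        length(object@eliminated), "\n", sep = "")
    invisible(object)
})

#' @rdname CoverageChart-class
#' @export
setMethod("chartValues", "CoverageChart", function(x) x@values)

#' @rdname CoverageChart-class
#' @export
setMethod("length", "CoverageChart", function(x) length(x@values))

#' y-axis maximum of a chart (largest value present)
#' @param x a \code{CoverageChart}.
#' @export
chartYMax <- function(x) if (length(x@values)) max(x@values) else 0

#' Chart set ("foreground"/"background") of a chart
#' @param x a \code{CoverageChart}.
#' @export
chartSet <- function(x) x@set

#' @rdname CoverageChart-class
#' @param object a \code{CoverageChart}.
#' @export
setMethod("show", "CoverageChart", function(object) {
    cat("CoverageChart '", object@name, "' (", object@set, ", ",
        object@color, "): ", length(object@values),
        " nt, y-max ", chartYMax(object), "\n", sep = "")
    invisible(object)
})

#' @rdname DisplayModel-class
#' @export
setMethod("queryName", "DisplayModel", function(x) x@query)

#' @rdname DisplayModel-class
#' @param object a \code{DisplayModel}.
#' @export
setMethod("show", "DisplayModel", function(object) {
    nm <- if (is.null(object@matches)) 0L else
        sum(!is.na(matchLevels(object@matches)))
    cat("DisplayModel '", object@query, "' (", object@length, " nt, ",
        object@ntPerPixel, " nt/px)\n",
        "  ticks: ", nrow(object@ticks),
        "  gap bars: ", nrow(object@gapBars),
        "  charts: ", length(object@charts),
        "  masks: ", if (is.null(object@maskTrack)) 0L else
            length(keptFeatures(object@maskTrack)),
        "  HSPs: ", if (is.null(object@hspTrack)) 0L else
            length(keptFeatures(object@hspTrack)),
        "  placed matches: ", nm, "\n", sep = "")
    invisible(object)
})

#' @rdname CentromereSim-class
#' @export
setMethod("simGenome", "CentromereSim", function(x) x@genome)

#' @rdname CentromereSim-class
#' @export
setMethod("groundTruth", "CentromereSim", function(x) {
    list(segments = x@segments, junctions = x@junctions,
         insertions = x@insertions, satellites = x@satellites)
})

#' @rdname CentromereSim-class
#' @param object a \code{CentromereSim}.
#' @export
setMethod("show", "CentromereSim", function(object) {
    cat("CentromereSim: ", length(object@genome), " nt (seed ", object@seed,
        ")\n  insertions: ", nrow(object@insertions),
        "  junctions: ", nrow(object@junctions),
        "  annotated segments: ", nrow(object@segments), "\n", sep = "")
    invisible(object)
})
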