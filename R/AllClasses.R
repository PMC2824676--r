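#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom IRanges IRanges start end width coverage
#' @importFrom GenomicRanges GRanges seqnames strand
#' @importClassesFrom IRanges IRanges
#' @importClassesFrom GenomicRanges GRanges
NULL

setClassUnion("ExactMatchSetOrNULL", "NULL")

#' Set of maximal exact repeat pairs within one query sequence
#'
#' Each entry pairs two equal-length intervals of the query that match
#' exactly, either on the same strand (\code{direct}) or as reverse
#' complements (\code{inverted}). Intervals are canonicalized so the
#' first interval starts at or before the second. Coordinates are 1-based
#' inclusive. The \code{level} slot holds drawing levels assigned by
#' \code{\link{layoutMatchLevels}} (1 = top; \code{NA} = not yet laid out
#' or dropped).
#'
#' @slot query query sequence identifier.
#' @slot first,second \code{IRanges} of the paired intervals.
#' @slot orientation character, \code{"direct"} or \code{"inverted"}.
#' @slot level integer drawing level per match.
#' @exportClass ExactMatchSet
setClass("ExactMatchSet",
    representation(
        query = "character",
        first = "IRanges",
        second = "IRanges",
        orientation = "character",
        level = "integer"
    )
)
setIs("ExactMatchSet", "ExactMatchSetOrNULL")

setValidity("ExactMatchSet", function(object) {
    n <- length(object@first)
    if (length(object@second) != n || length(object@orientation) != n ||
        length(object@level) != n)
        return("slot lengths differ")
    if (n == 0L) return(TRUE)
    if (!all(object@orientation %in% c("direct", "inverted")))
        return("orientation must be 'direct' or 'inverted'")
    if (!all(width(object@first) == width(object@second)))
        return("paired intervals must have equal width")
    if (any(start(object@first) > start(object@second)))
        return("matches must be canonical (first start <= second start)")
    TRUE
})

#' Construct an ExactMatchSet
#'
#' @param first,second \code{IRanges} of equal length and width.
#' @param orientation character vector, \code{"direct"}/\code{"inverted"}.
#' @param query query identifier (single string).
#' @param level optional integer drawing levels.
#' @return An \code{ExactMatchSet}.
#' @export
ExactMatchSet <- function(first = IRanges(), second = IRanges(),
                          orientation = character(0), query = "query",
                          level = rep(NA_integer_, length(first))) {
    new("ExactMatchSet", query = query, first = first, second = second,
        orientation = as.character(orientation), level = as.integer(level))
}

#' Result of competing overlapping homology features
#'
#' Holds the outcome of the annotation competition for a single query:
#' the features that survived (\code{kept}, sorted by start) and those
#' removed (\code{eliminated}), each eliminated feature carrying the index
#' of the kept feature that displaced it. In \code{blast} mode only
#' features from different databases compete; in \code{crossmatch} mode
#' every pair competes.
#'
#' @slot query query sequence identifier.
#' @slot kept \code{GRanges} of surviving features.
#' @slot eliminated \code{GRanges} of removed features; metadata column
#'   \code{eliminator} indexes into \code{kept}.
#' @slot params list with \code{allowance}, \code{mode}, \code{dbPriority}.
#' @exportClass CompetedTrack
setClass("CompetedTrack",
    representation(
        query = "character",
        kept = "GRanges",
        eliminated = "GRanges",
        params = "list"
    )
)

setValidity("CompetedTrack", function(object) {
    if (length(object@query) != 1L) return("query must be a single id")
    if (length(object@eliminated) > 0L &&
        is.null(object@eliminated$eliminator))
        return("eliminated features must carry an 'eliminator' column")
    TRUE
})

#' Per-nucleotide annotation chart
#'
#' One numerical value per query nucleotide, assigned to either the
#' foreground or background chart set (the two sets are drawn with
#' independent y-axes, background underneath).
#'
#' @slot name chart identifier.
#' @slot set \code{"foreground"} or \code{"background"}.
#' @slot values non-negative numeric vector, one value per nucleotide.
#' @slot color drawing color.
#' @exportClass CoverageChart
setClass("CoverageChart",
    representation(
        name = "character",
        set = "character",
        values = "numeric",
        color = "character"
    )
)

setValidity("CoverageChart", function(object) {
    if (!object@set %in% c("foreground", "background"))
        return("set must be 'foreground' or 'background'")
    if (length(object@values) && any(object@values < 0))
        return("chart values must be non-negative")
    TRUE
})

#' Renderer-independent description of one query display
#'
#' Assembles, in vertical order, everything drawn for one query: the
#' ruler (1 kb tick marks with absolute and gap-relative labels, grey
#' assembly-gap bars), the two chart sets, the competed cross_match mask
#' boxes, the competed BLAST HSP arrows, and the leveled exact-match
#' lines (direct red, inverted blue). Serialize with \code{\link{toSVG}}
#' or \code{\link{toPostscript}}.
#'
#' @slot query query identifier.
#' @slot length query length in nucleotides.
#' @slot ntPerPixel horizontal scale (nucleotides per pixel).
#' @slot ticks data.frame of tick positions and labels.
#' @slot gapBars data.frame of grey-bar positions (one row per bar).
#' @slot gaps data.frame of gap intervals.
#' @slot charts list of \code{CoverageChart}.
#' @slot chartSets list with per-set y-axis maxima.
#' @slot maskTrack,hspTrack \code{CompetedTrack} or \code{NULL}.
#' @slot matches \code{ExactMatchSet} or \code{NULL} (with levels).
#' @slot params list of rendering parameters.
#' @exportClass DisplayModel
setClass("DisplayModel",
    representation(
        query = "character",
        length = "integer",
        ntPerPixel = "numeric",
        ticks = "data.frame",
        gapBars = "data.frame",
        gaps = "data.frame",
        charts = "list",
        chartSets = "list",
        maskTrack = "ANY",
        hspTrack = "ANY",
        matches = "ANY",
        params = "list"
    )
)

setValidity("DisplayModel", function(object) {
    if (object@length < 1L) return("length must be positive")
    if (nrow(object@ticks) && (any(object@ticks$pos < 1) ||
        any(object@ticks$pos > object@length)))
        return("tick positions outside [1, length]")
    if (nrow(object@ticks) && any(object@ticks$pos %% 1000L != 0L))
        return("ticks must sit at exact 1 kb multiples")
    TRUE
})

#' Synthetic centromere with ground truth
#'
#' A simulated repeat-rich sequence: random single-copy flanks, a central
#' tandem satellite array, and nested retroelement insertions
#' (LTR-internal-LTR), together with a complete log of every segment,
#' insertion and repeat junction in final coordinates. The log is the
#' ground truth against which annotation, junction detection and marker
#' discovery are checked.
#'
#' @slot genome \code{DNAString} of the simulated sequence.
#' @slot segments data.frame of annotated segments
#'   (start, end, family, part, elementId).
#' @slot junctions data.frame of ground-truth junction boundaries.
#' @slot insertions data.frame, one row per insertion (order, family,
#'   position, length, ltrDivergence, LTR coordinates).
#' @slot satellites data.frame of satellite array coordinates.
#' @slot templates list of element template sequences per family.
#' @slot seed integer seed the corpus was generated from.
#' @exportClass CentromereSim
setClass("CentromereSim",
    representation(
        genome = "ANY",
        segments = "data.frame",
        junctions = "data.frame",
        insertions = "data.frame",
        satellites = "data.frame",
        templates = "list",
        seed = "integer"
    )
)
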