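# Display-model assembly and level layout for exact-match lines.
# Panel order, top to bottom: ruler (ticks + gap bars), charts
# (background set under foreground), cross_match mask boxes, BLAST HSP
# arrows, leveled exact-match lines.

#' Assign drawing levels to exact matches
#'
#' Matches are processed longest first; each takes the highest (topmost)
#' level on which its full horizontal extent -- both intervals plus the
#' connector between them -- collides with nothing already placed.
#' Matches that fit on no level within \code{maxLevels} are dropped
#' (level \code{NA}).
#'
#' @param matches an \code{\link{ExactMatchSet}}.
#' @param maxLevels number of available levels (default 30; level 1 is
#'   the top).
#' @return the \code{ExactMatchSet} with the \code{level} slot filled;
#'   dropped matches have level \code{NA} and their count is available
#'   as \code{attr(, "dropped")} on the level vector returned by
#'   \code{\link{matchLevels}}.
#' @export
layoutMatchLevels <- function(matches, maxLevels = 30L) {
    n <- length(matches)
    if (maxLevels < 1L) stop("maxLevels must be >= 1")
    lev <- rep(NA_integer_, n)
    if (n == 0L) { matches@level <- lev; return(matches) }
    extLo <- pmin(start(matches@first), start(matches@second))
    extHi <- pmax(end(matches@first), end(matches@second))
    ord <- order(-width(matches@first), extLo)
    levLo <- vector("list", maxLevels)   # occupied extents per level
    levHi <- vector("list", maxLevels)
    for (i in ord) {
        for (l in seq_len(maxLevels)) {
            occLo <- levLo[[l]]; occHi <- levHi[[l]]
            if (is.null(occLo) ||
                !any(occLo <= extHi[i] & occHi >= extLo[i])) {
                lev[i] <- l
                levLo[[l]] <- c(occLo, extLo[i])
                levHi[[l]] <- c(occHi, extHi[i])
                break
            }
        }
    }
    matches@level <- lev
    matches
}

#' Number of matches dropped by the level layout
#' @param x an \code{\link{ExactMatchSet}} with levels assigned.
#' @export
droppedMatches <- function(x) sum(is.na(matchLevels(x)))

#' Assemble the display model for one query
#'
#' Builds the renderer-independent description of a query's figure:
#' ruler ticks at every 1 kb with absolute and gap-relative labels,
#' grey gap bars (one per complete 100-N block of each assembly gap),
#' the two chart sets, competed cross_match mask boxes, competed BLAST
#' HSP arrows with query and subject coordinates, and leveled
#' exact-match lines.
#'
#' @param query query identifier.
#' @param length query length (nt).
#' @param gaps gap table from \code{\link{detectGaps}} (or \code{NULL}).
#' @param charts list of \code{\link{CoverageChart}} (or \code{NULL}).
#' @param maskTrack competed cross_match \code{\link{CompetedTrack}} (or
#'   \code{NULL}).
#' @param hspTrack competed BLAST \code{\link{CompetedTrack}} (or
#'   \code{NULL}).
#' @param matches \code{\link{ExactMatchSet}} (or \code{NULL}); levels
#'   are assigned here if not already.
#' @param ntPerPixel horizontal scale.
#' @param maxLevels drawing levels for exact matches (default 30).
#' @param colors optional named color overrides (subject -> color).
#' @return A \code{\link{DisplayModel}}.
#' @export
buildDisplay <- function(query, length, gaps = NULL, charts = NULL,
                         maskTrack = NULL, hspTrack = NULL,
                         matches = NULL, ntPerPixel = 50,
                         maxLevels = 30L, colors = NULL) {
    length <- as.integer(length)
    for (tr in list(maskTrack, hspTrack)) {
        if (!is.null(tr) && queryName(tr) != query)
            stop("track query '", queryName(tr),
                 "' does not match display query '", query, "'")
    }
    if (!is.null(matches) && length(matches) &&
        queryName(matches) != query)
        stop("match query does not match display query")

    tickPos <- seq.int(1000L, length, by = 1000L)
    ticks <- data.frame(
        pos = tickPos,
        label = format(tickPos, big.mark = ",", trim = TRUE,
                       scientific = FALSE),
        rel = if (length(tickPos)) gapRelativeCoord(tickPos, gaps, length)
              else integer(0),
        stringsAsFactors = FALSE)

    gapBars <- data.frame(pos = integer(0), gap = integer(0))
    if (!is.null(gaps) && nrow(gaps)) {
        rows <- lapply(seq_len(nrow(gaps)), function(k) {
            nb <- gaps$nBars[k]
            if (nb < 1L) return(NULL)
            # one bar centered on each complete 100-N block
            data.frame(pos = gaps$start[k] + 100L * seq_len(nb) - 50L,
                       gap = k)
        })
        rows <- rows[!vapply(rows, is.null, logical(1))]
        if (length(rows)) gapBars <- do.call(rbind, rows)
    }

    if (!is.null(matches) && length(matches) &&
        all(is.na(matchLevels(matches))))
        matches <- layoutMatchLevels(matches, maxLevels)

    chartList <- if (is.null(charts)) list() else charts
    new("DisplayModel", query = query, length = length,
        ntPerPixel = as.numeric(ntPerPixel),
        ticks = ticks, gapBars = gapBars,
        gaps = if (is.null(gaps)) data.frame() else gaps,
        charts = chartList,
        chartSets = assembleChartSets(chartList),
        maskTrack = maskTrack, hspTrack = hspTrack, matches = matches,
        params = list(maxLevels = as.integer(maxLevels),
                      colors = colors))
}
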