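# Per-nucleotide coverage charts from read placements, stratified by
# mapping multiplicity, organized into foreground/background chart sets
# with independent y-axes.

#' Read a read-placement table
#'
#' Six tab-separated columns: \code{read_id}, \code{query_id},
#' \code{start}, \code{end} (1-based inclusive query coordinates),
#' \code{hits_in_query} (number of placements of the read within this
#' query), \code{hits_in_genome} (number of placements genome-wide).
#' \code{hits_in_genome >= hits_in_query >= 1} must hold.
#'
#' @param path path to the TSV (a header line is permitted).
#' @return data.frame of placements.
#' @export
readPlacements <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) != 6L)
        stop("placement TSV must have 6 columns, got ", ncol(df))
    if (is.character(df[[3]])) {      # header line present
        df <- df[-1, , drop = FALSE]
        for (j in 3:6) df[[j]] <- as.integer(df[[j]])
    }
    names(df) <- c("read_id", "query_id", "start", "end",
                   "hits_in_query", "hits_in_genome")
    if (any(df$hits_in_query < 1L) ||
        any(df$hits_in_genome < df$hits_in_query))
        stop("placement multiplicities must satisfy ",
             "hits_in_genome >= hits_in_query >= 1")
    df
}

#' Standard mapping-multiplicity filters
#'
#' The three categories used for ChIP coverage displays, expressed as
#' thresholds on (hits within the query, hits genome-wide):
#' \code{unique} keeps reads placed once in the query and at most twice
#' genome-wide; \code{multi} allows any multiplicity within the query
#' but still at most two genome-wide placements; \code{all} is
#' unrestricted. The categories are nested (unique within multi within
#' all), so coverage values are pointwise monotone across them.
#'
#' @param name \code{"unique"}, \code{"multi"} or \code{"all"}.
#' @return list with \code{maxQueryHits} and \code{maxGenomeHits}.
#' @export
placementFilter <- function(name = c("unique", "multi", "all")) {
    switch(match.arg(name),
        unique = list(maxQueryHits = 1L, maxGenomeHits = 2L),
        multi = list(maxQueryHits = Inf, maxGenomeHits = 2L),
        all = list(maxQueryHits = Inf, maxGenomeHits = Inf))
}

#' Build a per-nucleotide coverage chart
#'
#' \code{values[i]} is the number of placements passing the filter
#' whose interval covers position i -- a nucleotide covered by two
#' reads gets the value 2.
#'
#' @param placements placement data.frame (see
#'   \code{\link{readPlacements}}), all on one query.
#' @param queryLength query length in nt.
#' @param filter a filter name (see \code{\link{placementFilter}}) or a
#'   list with \code{maxQueryHits}/\code{maxGenomeHits}.
#' @param name chart name.
#' @param set \code{"foreground"} or \code{"background"}.
#' @param color drawing color.
#' @return A \code{\link{CoverageChart}}.
#' @export
buildCoverage <- function(placements, queryLength, filter = "all",
                          name = "coverage", set = "foreground",
                          color = "red") {
    if (is.character(filter)) filter <- placementFilter(filter)
    if (nrow(placements)) {
        if (length(unique(placements$query_id)) > 1L)
            stop("placements mix query ids")
        if (any(placements$start < 1L) ||
            any(placements$end > queryLength))
            stop("placement outside query bounds")
        keep <- placements$hits_in_query <= filter$maxQueryHits &
            placements$hits_in_genome <= filter$maxGenomeHits
        placements <- placements[keep, , drop = FALSE]
    }
    values <- if (nrow(placements)) {
        cov <- coverage(IRanges(placements$start, placements$end),
                        width = queryLength)
        as.integer(cov)
    } else rep(0L, queryLength)
    new("CoverageChart", name = name, set = set,
        values = as.numeric(values), color = color)
}

#' Assemble charts into foreground and background sets
#'
#' Groups charts by their set tag and computes each set's shared
#' y-axis maximum (the largest value over all member charts). The
#' background set is drawn first, underneath the foreground.
#'
#' @param charts list of \code{\link{CoverageChart}} objects.
#' @return list with elements \code{foreground} and \code{background},
#'   each a list of \code{charts} and \code{yMax}.
#' @export
assembleChartSets <- function(charts) {
    pick <- function(setName) {
        sel <- Filter(function(ch) ch@set == setName, charts)
        list(charts = sel,
             yMax = if (length(sel)) max(vapply(sel, chartYMax, numeric(1)))
                    else 0)
    }
    list(foreground = pick("foreground"), background = pick("background"))
}

#' Export a chart as bedGraph
#'
#' @param chart a \code{\link{CoverageChart}}.
#' @param query query identifier (bedGraph chromosome).
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
chartToBedGraph <- function(chart, query, path) {
    r <- rle(chart@values)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gr <- GRanges(query, IRanges(starts, ends), score = r$values)
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}
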