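# Query sequence input, assembly-gap detection, gap-relative coordinates
# and tiling of long sequences into overlapping analysis windows.
# All coordinates are 1-based inclusive.

#' Read query sequences from FASTA
#'
#' Wraps \code{\link[Biostrings]{readDNAStringSet}} and checks that the
#' sequences contain only A, C, G, T and N (case-insensitive); other
#' characters are an input error. Sequences are upper-cased.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return A \code{DNAStringSet}.
#' @export
readQuerySequences <- function(path) {
    seqs <- Biostrings::readDNAStringSet(path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    freq <- Biostrings::alphabetFrequency(seqs)
    ok <- c("A", "C", "G", "T", "N")
    bad <- rowSums(freq[, !colnames(freq) %in% ok, drop = FALSE])
    if (any(bad > 0))
        stop("sequence(s) contain non-ACGTN characters: ",
             paste(names(seqs)[bad > 0], collapse = ", "))
    seqs
}

#' Detect assembly gaps (runs of Ns)
#'
#' Every maximal run of at least \code{threshold} consecutive N
#' characters is reported as one gap. Gaps are drawn in the ruler as a
#' stack of grey vertical bars, one bar per complete 100-N block
#' (\code{nBars = floor(width / 100)}), so a 1,000-N run yields 10 bars
#' and a 100-N run yields 1.
#'
#' @param seq a \code{DNAString}, character string, or single-element
#'   \code{DNAStringSet}.
#' @param threshold minimum run length (default 100; must be >= 1).
#' @return data.frame with columns \code{start}, \code{end} (1-based
#'   inclusive), \code{width} and \code{nBars}, sorted by position.
#' @export
detectGaps <- function(seq, threshold = 100L) {
    if (threshold < 1) stop("threshold must be >= 1")
    s <- .asSequenceString(seq)
    if (!nzchar(s))
        return(data.frame(start = integer(0), end = integer(0),
                          width = integer(0), nBars = integer(0)))
    m <- gregexpr("N+", s)[[1]]
    if (m[1] == -1L)
        return(data.frame(start = integer(0), end = integer(0),
                          width = integer(0), nBars = integer(0)))
    w <- attr(m, "match.length")
    keep <- w >= threshold
    start <- as.integer(m[keep])
    w <- as.integer(w[keep])
    data.frame(start = start, end = start + w - 1L, width = w,
               nBars = as.integer(w %/% 100L))
}

.asSequenceString <- function(seq) {
    if (is(seq, "DNAStringSet")) {
        stopifnot(length(seq) == 1L)
        seq <- seq[[1]]
    }
    toupper(as.character(seq))
}

#' Gap-relative coordinates
#'
#' For each position, the number of nucleotides counted from the end of
#' the nearest gap ending at or before that position; positions before
#' any gap keep their absolute coordinate, and positions inside a gap
#' report 0. Shown as the secondary value under each ruler tick mark.
#'
#' @param pos integer vector of 1-based positions.
#' @param gaps gap table from \code{\link{detectGaps}}.
#' @param seqLength optional sequence length for bounds checking.
#' @return integer vector of the same length as \code{pos}.
#' @export
gapRelativeCoord <- function(pos, gaps, seqLength = NULL) {
    pos <- as.integer(pos)
    if (any(pos < 1L)) stop("positions must be >= 1")
    if (!is.null(seqLength) && any(pos > seqLength))
        stop("position beyond sequence end")
    if (is.null(gaps) || nrow(gaps) == 0L) return(pos)
    gaps <- gaps[order(gaps$start), , drop = FALSE]
    idx <- findInterval(pos, gaps$end)         # last gap with end <= pos
    rel <- ifelse(idx == 0L, pos, pos - gaps$end[pmax(idx, 1L)])
    inside <- vapply(pos, function(p)
        any(p >= gaps$start & p <= gaps$end), logical(1))
    rel[inside] <- 0L
    as.integer(rel)
}

#' Tile a long sequence into overlapping windows
#'
#' Windows advance by \code{window - overlap}; the final window is
#' truncated at the region end (and generation stops as soon as a window
#' reaches it). With the defaults (210 kb windows, 10 kb overlap) any
#' feature of 10 kb or less is drawn whole in at least one window.
#'
#' @param length region length in nt.
#' @param window window size in nt.
#' @param overlap overlap between consecutive windows (must be smaller
#'   than \code{window}).
#' @param origin 1-based coordinate of the first position of the region.
#' @return data.frame with 1-based inclusive columns \code{start},
#'   \code{end} and a \code{tile} index.
#' @export
tileSequence <- function(length, window = 210000L, overlap = 10000L,
                         origin = 1L) {
    if (overlap >= window)
        stop("overlap must be smaller than window")
    if (length < 1) stop("length must be positive")
    last <- origin + length - 1
    starts <- integer(0); ends <- integer(0)
    s <- origin
    repeat {
        e <- min(s + window - 1, last)
        starts <- c(starts, s); ends <- c(ends, e)
        if (e >= last) break
        s <- s + (window - overlap)
    }
    data.frame(tile = seq_along(starts), start = as.integer(starts),
               end = as.integer(ends))
}

#' Export tiles as BED
#'
#' Writes the tile table as a BED track (BED is 0-based half-open; the
#' conversion is handled by \code{rtracklayer}).
#'
#' @param tiles tile table from \code{\link{tileSequence}}.
#' @param query query identifier used as the BED chromosome name.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
tilesToBed <- function(tiles, query, path) {
    gr <- GRanges(query, IRanges(tiles$start, tiles$end),
                  name = sprintf("%s.tile%d", query, tiles$tile))
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}
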