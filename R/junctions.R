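# Repeat-junction detection, junction-pair marker candidates, LTR-pair
# identification from exact-match structure, and K2P insertion dating.

#' Detect repeat junctions on a classified track
#'
#' A repeat junction is the boundary created where a mobile element
#' inserted into another sequence: two adjacent kept features of
#' different repeat classes, separated by at most \code{gapTolerance}
#' unannotated nucleotides. By default classes are compared at the
#' family level (\code{byFamily = TRUE}), so the internal LTR/CDS
#' structure of a single element does not register as a junction --
#' junctions mark element boundaries, not element anatomy. The junction
#' position is the last base of the left feature when the features abut,
#' or the midpoint of the unannotated gap otherwise.
#'
#' @param track a classified \code{\link{CompetedTrack}} (see
#'   \code{\link{classifyFeatures}}).
#' @param gapTolerance maximum unannotated nt between the two features
#'   (default 50).
#' @param byFamily compare repeat classes at the family level.
#' @return data.frame with columns \code{query}, \code{position}
#'   (1-based; the boundary lies after this base), \code{leftClass},
#'   \code{rightClass}, \code{leftIndex}, \code{rightIndex}, \code{gap}.
#' @export
detectJunctions <- function(track, gapTolerance = 50L, byFamily = TRUE) {
    kept <- if (is(track, "CompetedTrack")) track@kept else track
    query <- if (is(track, "CompetedTrack")) track@query
             else as.character(seqnames(kept)[1])
    empty <- data.frame(query = character(0), position = integer(0),
                        leftClass = character(0), rightClass = character(0),
                        leftIndex = integer(0), rightIndex = integer(0),
                        gap = integer(0), stringsAsFactors = FALSE)
    if (length(kept) < 2L) return(empty)
    if (is.null(kept$repeatClass))
        stop("track is not classified; run classifyFeatures() first")
    o <- order(start(kept), end(kept))
    kept <- kept[o]
    cls <- if (byFamily) kept$family else kept$repeatClass
    n <- length(kept)
    i <- seq_len(n - 1L)
    gap <- start(kept)[i + 1L] - end(kept)[i] - 1L
    hit <- gap >= 0L & gap <= gapTolerance & cls[i] != cls[i + 1L]
    if (!any(hit)) return(empty)
    i <- i[hit]
    gap <- gap[hit]
    pos <- end(kept)[i] + (gap + 1L) %/% 2L
    data.frame(query = query, position = as.integer(pos),
               leftClass = kept$repeatClass[i],
               rightClass = kept$repeatClass[i + 1L],
               leftIndex = o[i], rightIndex = o[i + 1L],
               gap = as.integer(gap), stringsAsFactors = FALSE)
}

#' Pair nearby junctions into single-copy marker candidates
#'
#' Each junction sequence is potentially unique even when both flanking
#' repeats are high-copy; two junctions close enough for a PCR amplicon
#' to span them form a single-copy marker candidate. All junction pairs
#' no more than \code{maxSpan} nucleotides apart (default 2,500) are
#' reported once, sorted by span.
#'
#' @param junctions junction table from \code{\link{detectJunctions}}.
#' @param maxSpan maximum distance (nt) between the two junction
#'   positions.
#' @return data.frame with columns \code{query}, \code{positionA},
#'   \code{positionB}, \code{span}, \code{classesA}, \code{classesB}.
#' @export
findMarkerCandidates <- function(junctions, maxSpan = 2500L) {
    empty <- data.frame(query = character(0), positionA = integer(0),
                        positionB = integer(0), span = integer(0),
                        classesA = character(0), classesB = character(0),
                        stringsAsFactors = FALSE)
    if (is.null(junctions) || nrow(junctions) < 2L) return(empty)
    j <- junctions[order(junctions$position), , drop = FALSE]
    n <- nrow(j)
    rows <- list()
    for (a in seq_len(n - 1L)) {
        for (b in seq.int(a + 1L, n)) {
            span <- j$position[b] - j$position[a]
            if (span > maxSpan) break
            rows[[length(rows) + 1L]] <- data.frame(
                query = j$query[a],
                positionA = j$position[a], positionB = j$position[b],
                span = as.integer(span),
                classesA = paste(j$leftClass[a], j$rightClass[a],
                                 sep = "|"),
                classesB = paste(j$leftClass[b], j$rightClass[b],
                                 sep = "|"),
                stringsAsFactors = FALSE)
        }
    }
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    out[order(out$span, out$positionA), , drop = FALSE]
}

#' Identify candidate LTR pairs from exact-match structure
#'
#' A retroelement's two LTRs are identical at insertion, so a young
#' element shows up as a long direct exact match whose two intervals
#' flank an internal region of element-like size. Direct matches of
#' length at least \code{minLtrLength} whose internal span lies within
#' \code{internalRange} are reported; short periodic satellite matches
#' fail the length filter, and inverted matches are never LTR pairs.
#' Optionally the internal span must overlap a CDS-classified segment
#' of a classified track.
#'
#' @param matches an \code{\link{ExactMatchSet}}.
#' @param minLtrLength minimum LTR (match) length, default 300 nt.
#' @param internalRange numeric length-2 vector: allowed internal span
#'   (nt) between the two LTR intervals, default 1,000 to 25,000.
#' @param cdsTrack optional classified \code{CompetedTrack}; when given
#'   and \code{requireCds} is \code{TRUE}, the internal span must
#'   overlap a feature with \code{part == "CDS"}.
#' @param requireCds enforce the CDS-overlap constraint.
#' @return data.frame with columns \code{leftStart}, \code{leftEnd},
#'   \code{rightStart}, \code{rightEnd}, \code{matchLength},
#'   \code{internalStart}, \code{internalEnd}, \code{internalSpan}.
#' @export
identifyLtrPairs <- function(matches, minLtrLength = 300L,
                             internalRange = c(1000L, 25000L),
                             cdsTrack = NULL, requireCds = FALSE) {
    df <- as.data.frame(matches)
    df <- df[df$orientation == "direct" & df$length >= minLtrLength, ,
             drop = FALSE]
    empty <- data.frame(leftStart = integer(0), leftEnd = integer(0),
                        rightStart = integer(0), rightEnd = integer(0),
                        matchLength = integer(0), internalStart = integer(0),
                        internalEnd = integer(0), internalSpan = integer(0),
                        stringsAsFactors = FALSE)
    if (!nrow(df)) return(empty)
    internalStart <- df$aEnd + 1L
    internalEnd <- df$bStart - 1L
    span <- internalEnd - internalStart + 1L
    keep <- span >= internalRange[1] & span <= internalRange[2]
    df <- df[keep, , drop = FALSE]
    internalStart <- internalStart[keep]; internalEnd <- internalEnd[keep]
    span <- span[keep]
    if (!nrow(df)) return(empty)
    if (requireCds) {
        if (is.null(cdsTrack))
            stop("requireCds = TRUE needs a classified cdsTrack")
        kept <- if (is(cdsTrack, "CompetedTrack")) cdsTrack@kept
                else cdsTrack
        cds <- kept[kept$part == "CDS"]
        ov <- vapply(seq_len(nrow(df)), function(k)
            any(start(cds) <= internalEnd[k] & end(cds) >= internalStart[k]),
            logical(1))
        df <- df[ov, , drop = FALSE]
        internalStart <- internalStart[ov]; internalEnd <- internalEnd[ov]
        span <- span[ov]
        if (!nrow(df)) return(empty)
    }
    data.frame(leftStart = df$aStart, leftEnd = df$aEnd,
               rightStart = df$bStart, rightEnd = df$bEnd,
               matchLength = df$length,
               internalStart = internalStart, internalEnd = internalEnd,
               internalSpan = as.integer(span), stringsAsFactors = FALSE)
}

#' Kimura two-parameter distance between aligned sequences
#'
#' Over the ungapped, unambiguous (A/C/G/T on both sides) columns of an
#' alignment, let P be the transition proportion and Q the transversion
#' proportion. The K2P distance is
#' \deqn{\kappa = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q).}
#' Columns containing gaps or ambiguity codes are excluded from the
#' denominator, so padding an alignment with gap columns leaves the
#' distance unchanged.
#'
#' @param a,b equal-length aligned sequences (characters; \code{-} for
#'   gaps).
#' @return list with \code{kappa}, \code{P}, \code{Q} and \code{sites}
#'   (number of columns used).
#' @examples
#' kimura2p("ACGT", "ACGT")  # kappa 0
#' @export
kimura2p <- function(a, b) {
    a <- toupper(as.character(a)); b <- toupper(as.character(b))
    if (nchar(a) != nchar(b))
        stop("aligned sequences must have equal length")
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    use <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
    n <- sum(use)
    if (n == 0L)
        stop("no ungapped, unambiguous columns in the alignment")
    ca <- ca[use]; cb <- cb[use]
    purine <- c("A", "G")
    diff <- ca != cb
    transition <- diff & ((ca %in% purine) == (cb %in% purine))
    P <- sum(transition) / n
    Q <- sum(diff & !transition) / n
    if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
        stop("K2P distance undefined: 2P + Q >= 1 or Q >= 0.5")
    kappa <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
    list(kappa = kappa, P = P, Q = Q, sites = n)
}

#' Globally align two LTR sequences
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap open
#' -5, gap extend -1 by default) via
#' \code{\link[Biostrings]{pairwiseAlignment}}, returning the two gapped
#' strings ready for \code{\link{kimura2p}}.
#'
#' @param a,b nucleotide sequences (character or \code{DNAString}).
#' @param match,mismatch,gapOpening,gapExtension scoring parameters
#'   (costs are given as positive numbers for the gap penalties).
#' @return character vector of length 2: the aligned, gapped sequences.
#' @export
alignLtrs <- function(a, b, match = 1, mismatch = -1, gapOpening = 5,
                      gapExtension = 1) {
    sm <- Biostrings::nucleotideSubstitutionMatrix(
        match = match, mismatch = mismatch, baseOnly = TRUE)
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(toupper(as.character(a))),
        Biostrings::DNAString(toupper(as.character(b))),
        type = "global", substitutionMatrix = sm,
        gapOpening = gapOpening, gapExtension = gapExtension)
    c(as.character(Biostrings::alignedPattern(aln)),
      as.character(Biostrings::alignedSubject(aln)))
}

#' Date an LTR pair
#'
#' Extracts the two LTR intervals from the query sequence, aligns them
#' globally, and computes the K2P distance -- the standard proxy for
#' time since insertion (the two LTRs were identical when the element
#' inserted).
#'
#' @param seq the query sequence (character or \code{DNAString}).
#' @param pair one row of the table from \code{\link{identifyLtrPairs}}
#'   (or any list with leftStart/leftEnd/rightStart/rightEnd).
#' @return the \code{\link{kimura2p}} result list.
#' @export
dateLtrPair <- function(seq, pair) {
    s <- .asSequenceString(seq)
    left <- substr(s, pair$leftStart, pair$leftEnd)
    right <- substr(s, pair$rightStart, pair$rightEnd)
    aln <- alignLtrs(left, right)
    kimura2p(aln[1], aln[2])
}

#' Order LTR pairs by insertion age
#'
#' Youngest first: ascending K2P distance, ties broken by the longer
#' exact-match length first (longer match lines between LTRs correlate
#' with younger elements).
#'
#' @param pairs data.frame with columns \code{kappa} and
#'   \code{matchLength}.
#' @return the reordered data.frame.
#' @export
ageOrder <- function(pairs) {
    if (is.null(pairs) || nrow(pairs) == 0L) return(pairs)
    pairs[order(pairs$kappa, -pairs$matchLength), , drop = FALSE]
}

#' Export LTR pairs as GFF3 with their K2P distance
#'
#' Writes one \code{repeat_region} feature per LTR-pair span (left LTR
#' start to right LTR end) with \code{kappa}, \code{matchLength} and
#' the LTR coordinates in the attributes.
#'
#' @param pairs table from \code{\link{identifyLtrPairs}}, optionally
#'   with a \code{kappa} column (see \code{\link{dateLtrPair}}).
#' @param query query identifier.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
ltrPairsToGff3 <- function(pairs, query, path) {
    gr <- GRanges(query, IRanges(pairs$leftStart, pairs$rightEnd))
    mcols(gr) <- S4Vectors::DataFrame(
        source = "RepeatJunctions", type = "repeat_region",
        ID = sprintf("ltrpair%03d", seq_len(nrow(pairs))),
        kappa = if (is.null(pairs$kappa)) NA_real_ else pairs$kappa,
        matchLength = pairs$matchLength,
        leftLtrEnd = pairs$leftEnd, rightLtrStart = pairs$rightStart)
    rtracklayer::export(gr, path, format = "GFF3")
    invisible(path)
}

#' Export junctions or markers as BED
#'
#' @param junctions table from \code{\link{detectJunctions}}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
junctionsToBed <- function(junctions, path) {
    gr <- GRanges(junctions$query,
                  IRanges(junctions$position, junctions$position),
                  name = paste(junctions$leftClass, junctions$rightClass,
                               sep = "|"))
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}
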