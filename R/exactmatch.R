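# Built-in maximal exact match finder, so exact-repeat structure can be
# computed without any external aligner. The search itself runs in
# compiled code (seed-and-extend over a k-mer index with per-diagonal
# skip lists); this wrapper validates input and canonicalizes output.

#' Find maximal exact repeat pairs within a sequence
#'
#' Reports every maximal repeated substring pair of length at least
#' \code{minLength}, both direct (same strand) and inverted (reverse
#' complement). A pair is maximal when extending it by one position on
#' either side breaks the match. N characters match nothing (not even
#' other Ns), so matches never span assembly gaps. Pairs are
#' canonicalized with the left interval first, and the degenerate case
#' of an interval paired with itself is excluded.
#'
#' @param seq a \code{DNAString}, character string, or single-record
#'   \code{DNAStringSet}; only A/C/G/T/N allowed (case-insensitive).
#' @param minLength minimum match length (default 100 nt).
#' @param query query identifier stored on the result.
#' @return An \code{\link{ExactMatchSet}} sorted by first-interval
#'   start.
#' @examples
#' findExactMatches("ACGTACGT", minLength = 4)
#' @export
findExactMatches <- function(seq, minLength = 100L, query = "query") {
    s <- .asSequenceString(seq)
    if (grepl("[^ACGTN]", s))
        stop("sequence contains non-ACGTN characters")
    df <- .mem_pairs_cpp(s, as.integer(minLength))
    if (!nrow(df)) return(ExactMatchSet(query = query))
    o <- order(df$a_start, df$b_start, -df$length)
    df <- df[o, , drop = FALSE]
    ExactMatchSet(
        first = IRanges(df$a_start + 1L, width = df$length),
        second = IRanges(df$b_start + 1L, width = df$length),
        orientation = ifelse(df$inverted == 1L, "inverted", "direct"),
        query = query)
}
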