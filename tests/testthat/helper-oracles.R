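# Independent oracles and fixture builders used across the suite.
# These deliberately re-derive results by a different route than the
# package implementation (full pairwise comparison matrices, double
# loops, per-position counts).

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force maximal repeated pair enumeration: build the full n x n
# character-agreement matrix and read maximal runs off every diagonal.
bruteExactMatches <- function(s, minLen) {
    x <- strsplit(toupper(s), "")[[1]]
    n <- length(x)
    okx <- x %in% c("A", "C", "G", "T")
    runPairs <- function(y, oky) {
        E <- outer(x, y, "==") & outer(okx, oky, "&")
        out <- list()
        for (d in (-(n - 1)):(n - 1)) {
            i <- max(1, 1 - d):min(n, n - d)
            v <- E[cbind(i, i + d)]
            r <- rle(v)
            ends <- cumsum(r$lengths)
            starts <- ends - r$lengths + 1
            for (k in which(r$values & r$lengths >= minLen))
                out[[length(out) + 1]] <-
                    c(i[starts[k]], i[starts[k]] + d, r$lengths[k])
        }
        if (length(out)) do.call(rbind, out) else
            matrix(integer(0), ncol = 3)
    }
    dmat <- runPairs(x, okx)
    dmat <- dmat[dmat[, 1] < dmat[, 2], , drop = FALSE]
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    y <- rev(unname(comp[x]))
    imat <- runPairs(y, rev(okx))
    if (nrow(imat)) {
        p2 <- n - (imat[, 2] + imat[, 3] - 1) + 1
        lo <- pmin(imat[, 1], p2)
        hi <- pmax(imat[, 1], p2)
        keep <- lo < hi
        imat <- unique(cbind(lo[keep], hi[keep], imat[keep, 3]))
    } else imat <- matrix(integer(0), ncol = 3)
    list(direct = dmat, inverted = imat)
}

matchKeys <- function(ms, orient) {
    df <- as.data.frame(ms)
    df <- df[df$orientation == orient, , drop = FALSE]
    sort(paste(df$aStart, df$bStart, df$length))
}

bruteKeys <- function(mat) {
    if (!nrow(mat)) return(character(0))
    sort(paste(mat[, 1], mat[, 2], mat[, 3]))
}

# Straightforward ranked-sweep competition over a plain data.frame,
# independent of the GRanges-based implementation.
bruteCompete <- function(df, allowance, mode) {
    ord <- order(-(df$end - df$start + 1), -df$score,
                 match(df$db, unique(df$db)), df$start)
    keptRows <- integer(0)
    for (i in ord) {
        ok <- TRUE
        for (j in keptRows) {
            if (mode == "blast" && df$db[j] == df$db[i]) next
            ov <- min(df$end[j], df$end[i]) - max(df$start[j], df$start[i]) + 1
            if (ov > allowance) { ok <- FALSE; break }
        }
        if (ok) keptRows <- c(keptRows, i)
    }
    sort(keptRows)
}

randomFeatureSet <- function(n, span = 5000, dbs = c("A", "B", "C")) {
    st <- sample.int(span, n, replace = TRUE)
    w <- sample.int(800, n, replace = TRUE)
    df <- data.frame(start = st, end = st + w,
                     db = sample(dbs, n, replace = TRUE),
                     score = round(stats::runif(n, 10, 500), 1))
    df
}

featuresFromDf <- function(df, query = "q") {
    gr <- GenomicRanges::GRanges(query,
        IRanges::IRanges(df$start, df$end))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        db = df$db, subject = paste0(df$db, "#part"),
        sStart = 1L, sEnd = 1L, score = df$score, evidence = "blast")
    gr
}

# Per-position membership count, the definition of coverage.
bruteCoverage <- function(starts, ends, len) {
    v <- integer(len)
    for (k in seq_along(starts))
        v[starts[k]:ends[k]] <- v[starts[k]:ends[k]] + 1L
    v
}

# Minimal classified track from explicit segments.
trackFromSegments <- function(df, query = "q") {
    gr <- featuresFromDf(data.frame(start = df$start, end = df$end,
                                    db = df$family, score = 100), query)
    gr$subject <- paste0(df$family, "#", df$part)
    tr <- methods::new("CompetedTrack", query = query, kept = gr,
        eliminated = RepeatJunctions:::.emptyFeatures(),
        params = list(allowance = 0L, mode = "blast", dbPriority = NULL))
    classifyFeatures(tr)
}

mkPlacements <- function(starts, ends, hq = 1L, hg = 1L, query = "q") {
    data.frame(read_id = sprintf("r%d", seq_along(starts)),
               query_id = query, start = starts, end = ends,
               hits_in_query = rep_len(hq, length(starts)),
               hits_in_genome = rep_len(hg, length(starts)),
               stringsAsFactors = FALSE)
}

mkMatches <- function(aStarts, bStarts, lens,
                      orient = rep("direct", length(aStarts))) {
    ExactMatchSet(IRanges::IRanges(aStarts, width = lens),
                  IRanges::IRanges(bStarts, width = lens), orient,
                  query = "q")
}
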