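# Homology-evidence ingestion: BLAST 12-column tabular output,
# cross_match alignment lines, and MUMmer show-coords style tables.
# Features are normalized into a GRanges with 1-based inclusive query
# coordinates, minus strand when the subject coordinates are reversed.

.emptyFeatures <- function() {
    gr <- GRanges()
    mcols(gr) <- S4Vectors::DataFrame(
        db = character(0), subject = character(0),
        sStart = integer(0), sEnd = integer(0),
        score = numeric(0), evidence = character(0))
    gr
}

.makeFeatures <- function(query, qs, qe, strand, db, subject, ss, se,
                          score, evidence) {
    gr <- GRanges(query, IRanges(qs, qe), strand = strand)
    mcols(gr) <- S4Vectors::DataFrame(
        db = db, subject = subject, sStart = as.integer(ss),
        sEnd = as.integer(se), score = as.numeric(score),
        evidence = evidence)
    gr
}

.readEvidenceLines <- function(x) {
    if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE)
    else unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

#' Parse BLAST tabular output
#'
#' Reads standard 12-column nucleotide BLAST tabular output (qseqid,
#' sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart,
#' send, evalue, bitscore). HSPs with E-value above \code{evalueCutoff}
#' are dropped. Reversed subject coordinates (sstart > send) mark a
#' minus-strand HSP; subject coordinates are stored in ascending order.
#'
#' @param x path to a tabular file, or a character string/vector of
#'   tabular lines.
#' @param dbName database name recorded on every feature.
#' @param evalueCutoff keep HSPs with E-value <= this cutoff.
#' @return \code{GRanges} of homology features (metadata columns:
#'   \code{db}, \code{subject}, \code{sStart}, \code{sEnd}, \code{score},
#'   \code{evidence = "blast"}).
#' @export
readBlastTabular <- function(x, dbName, evalueCutoff = Inf) {
    lines <- .readEvidenceLines(x)
    keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
    lineNo <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) return(.emptyFeatures())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 12L))
        stop("malformed BLAST tabular row at line ",
             lineNo[which(nf != 12L)[1]], " (expected 12 columns, got ",
             nf[nf != 12L][1], ")")
    m <- do.call(rbind, fields)
    num <- function(j) {
        v <- suppressWarnings(as.numeric(m[, j]))
        if (anyNA(v))
            stop("malformed numeric field in BLAST row at line ",
                 lineNo[which(is.na(v))[1]])
        v
    }
    qs <- num(7); qe <- num(8); ss <- num(9); se <- num(10)
    ev <- num(11); bits <- num(12)
    keepE <- ev <= evalueCutoff
    if (!any(keepE)) return(.emptyFeatures())
    qs <- qs[keepE]; qe <- qe[keepE]; ss <- ss[keepE]; se <- se[keepE]
    bits <- bits[keepE]
    qid <- m[keepE, 1]; sid <- m[keepE, 2]
    strand <- ifelse(ss > se, "-", "+")
    .makeFeatures(qid, pmin(qs, qe), pmax(qs, qe), strand,
                  dbName, sid, pmin(ss, se), pmax(ss, se), bits, "blast")
}

#' Score-equivalence filter for BLAST features
#'
#' Keeps HSPs whose score is at least \code{fraction} of a perfect
#' complete match to their subject (subject length times the match
#' reward). A fraction of 0.9 corresponds to requiring a score within
#' 10\% of a perfect complete match, which separates closely related
#' repeat subfamilies.
#'
#' @param features \code{GRanges} from \code{\link{readBlastTabular}}.
#' @param subjectLengths named integer vector of subject lengths.
#' @param fraction required fraction in (0, 1].
#' @param reward per-nucleotide match reward (default 1).
#' @return the filtered \code{GRanges}.
#' @export
applyScoreEquivalence <- function(features, subjectLengths, fraction,
                                  reward = 1) {
    if (fraction <= 0 || fraction > 1)
        stop("fraction must lie in (0, 1]")
    len <- subjectLengths[features$subject]
    if (anyNA(len))
        stop("missing subject length(s): ",
             paste(unique(features$subject[is.na(len)]), collapse = ", "))
    features[features$score >= fraction * len * reward]
}

#' Parse cross_match alignment output
#'
#' Parses the standard cross_match alignment lines
#' (\code{score pdiv pdel pins query qstart qend (qleft) subject sstart
#' send (sleft)}; complement alignments carry a \code{C} before the
#' subject and reversed subject fields). Non-alignment lines (headers,
#' summaries, blanks) are ignored; a line that starts like an alignment
#' but cannot be parsed is an error.
#'
#' @param x path or character lines.
#' @param dbName masking-database name recorded on every feature.
#' @return \code{GRanges} of features with \code{evidence =
#'   "crossmatch"}.
#' @export
readCrossmatch <- function(x, dbName) {
    lines <- .readEvidenceLines(x)
    out <- vector("list", length(lines))
    for (i in seq_along(lines)) {
        ln <- trimws(lines[i])
        if (!nzchar(ln)) next
        f <- .splitFields(ln)
        # alignment lines start: score %div %del %ins query qstart qend
        if (length(f) < 7 || is.na(suppressWarnings(as.numeric(f[1]))) ||
            is.na(suppressWarnings(as.numeric(f[2]))))
            next
        score <- as.numeric(f[1])
        qid <- f[5]
        qs <- suppressWarnings(as.integer(f[6]))
        qe <- suppressWarnings(as.integer(f[7]))
        if (is.na(qs) || is.na(qe))
            stop("unrecognized cross_match line layout at line ", i,
                 ": ", lines[i])
        rest <- f[-(1:8)]                     # drop fields up to (qleft)
        if (length(rest) >= 4 && rest[1] == "C") {
            sid <- rest[2]
            nums <- suppressWarnings(as.integer(gsub("[()]", "", rest[3:5])))
            if (anyNA(nums))
                stop("unrecognized cross_match line layout at line ", i)
            ss <- min(nums[2], nums[3]); se <- max(nums[2], nums[3])
            strand <- "-"
        } else if (length(rest) >= 3) {
            sid <- rest[1]
            nums <- suppressWarnings(as.integer(gsub("[()]", "", rest[2:3])))
            if (anyNA(nums))
                stop("unrecognized cross_match line layout at line ", i)
            ss <- nums[1]; se <- nums[2]
            strand <- "+"
        } else {
            stop("unrecognized cross_match line layout at line ", i)
        }
        out[[i]] <- .makeFeatures(qid, qs, qe, strand, dbName, sid,
                                  ss, se, score, "crossmatch")
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out)) return(.emptyFeatures())
    do.call(c, out)
}

#' Parse MUMmer show-coords style exact-match tables
#'
#' Reads tabular output of a self-comparison (columns start1 end1 start2
#' end2 length1 length2 [identity ...]). The trivial full-length
#' self-hit and any hit pairing an interval with itself are removed;
#' mirror duplicates are canonicalized so the first interval starts at
#' or before the second; matches shorter than \code{minLength} are
#' dropped. Reversed second-interval coordinates mark an inverted
#' (reverse-complement) match.
#'
#' @param x path or character lines.
#' @param minLength minimum match length kept (default 100).
#' @param query query identifier for the resulting set.
#' @return An \code{\link{ExactMatchSet}}.
#' @export
readMummerCoords <- function(x, minLength = 100L, query = "query") {
    lines <- .readEvidenceLines(x)
    rows <- list()
    for (i in seq_along(lines)) {
        ln <- trimws(lines[i])
        if (!nzchar(ln)) next
        ln <- gsub("|", " ", ln, fixed = TRUE)
        f <- .splitFields(ln)
        if (length(f) < 6) next
        v <- suppressWarnings(as.numeric(f[1:6]))
        if (anyNA(v)) next
        if (any(v[1:4] %% 1 != 0) || any(v[1:4] < 1))
            stop("malformed coordinates at line ", i, ": ", lines[i])
        rows[[length(rows) + 1L]] <- v
    }
    if (!length(rows))
        return(ExactMatchSet(query = query))
    m <- do.call(rbind, rows)
    s1 <- as.integer(m[, 1]); e1 <- as.integer(m[, 2])
    s2 <- as.integer(m[, 3]); e2 <- as.integer(m[, 4])
    inverted <- s2 > e2
    lo2 <- pmin(s2, e2); hi2 <- pmax(s2, e2)
    len <- e1 - s1 + 1L
    keep <- len >= minLength & !(s1 == lo2 & e1 == hi2)  # drop self-hits
    s1 <- s1[keep]; e1 <- e1[keep]; lo2 <- lo2[keep]; hi2 <- hi2[keep]
    inverted <- inverted[keep]; len <- len[keep]
    if (!length(s1)) return(ExactMatchSet(query = query))
    aS <- pmin(s1, lo2); bS <- pmax(s1, lo2)
    key <- paste(aS, bS, len, inverted)
    dup <- duplicated(key)
    aS <- aS[!dup]; bS <- bS[!dup]; len <- len[!dup]
    inverted <- inverted[!dup]
    o <- order(aS, bS)
    ExactMatchSet(
        first = IRanges(aS[o], width = len[o]),
        second = IRanges(bS[o], width = len[o]),
        orientation = ifelse(inverted[o], "inverted", "direct"),
        query = query)
}

# ---- canonical feature TSV + GFF3 export --------------------------------

.FEATURE_TSV_COLS <- c("query", "start", "end", "strand", "db", "subject",
                       "sStart", "sEnd", "score", "evidence")

#' Serialize homology features to the canonical internal TSV
#'
#' Column order: query, start, end, strand, db, subject, sStart, sEnd,
#' score, evidence. \code{featuresFromTsv} inverts the operation
#' exactly.
#'
#' @param features feature \code{GRanges}.
#' @param path destination path, or \code{NULL} to return the lines.
#' @return \code{path} (or the TSV lines), invisibly.
#' @export
featuresToTsv <- function(features, path = NULL) {
    df <- data.frame(
        query = as.character(seqnames(features)),
        start = start(features), end = end(features),
        strand = as.character(strand(features)),
        db = features$db, subject = features$subject,
        sStart = features$sStart, sEnd = features$sEnd,
        score = features$score, evidence = features$evidence,
        stringsAsFactors = FALSE)
    lines <- c(paste(.FEATURE_TSV_COLS, collapse = "\t"),
               do.call(sprintf,
                       c(list("%s\t%d\t%d\t%s\t%s\t%s\t%d\t%d\t%s\t%s"),
                         df[1:8], list(format(df$score, trim = TRUE)),
                         df[10])))
    if (is.null(path)) return(invisible(lines))
    writeLines(lines, path)
    invisible(path)
}

#' @rdname featuresToTsv
#' @param x path or character lines of a canonical feature TSV.
#' @export
featuresFromTsv <- function(x) {
    lines <- .readEvidenceLines(x)
    if (length(lines) < 1L || !identical(strsplit(lines[1], "\t")[[1]],
                                         .FEATURE_TSV_COLS))
        stop("not a canonical feature TSV (bad header)")
    if (length(lines) == 1L) return(.emptyFeatures())
    df <- utils::read.table(text = lines[-1], sep = "\t",
                            col.names = .FEATURE_TSV_COLS,
                            comment.char = "", quote = "",
                            stringsAsFactors = FALSE)
    .makeFeatures(df$query, df$start, df$end, df$strand, df$db,
                  df$subject, df$sStart, df$sEnd, df$score, df$evidence)
}

#' Export features as GFF3
#'
#' @param features feature \code{GRanges}.
#' @param path destination path.
#' @param source value for the GFF3 source column.
#' @return \code{path}, invisibly.
#' @export
featuresToGff3 <- function(features, path, source = "RepeatJunctions") {
    gr <- features
    mcols(gr) <- S4Vectors::DataFrame(
        source = source,
        type = ifelse(gr$evidence == "crossmatch", "repeat_region",
                      "match_part"),
        score = gr$score,
        ID = sprintf("feat%05d", seq_along(gr)),
        Name = gr$subject,
        db = gr$db,
        subject_start = gr$sStart,
        subject_end = gr$sEnd)
    rtracklayer::export(gr, path, format = "GFF3")
    invisible(path)
}
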