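# Synthetic-centromere simulator with full ground truth: tandem
# satellite arrays, an element library with subfamily variants, nested
# LTR-retroelement insertions, homology evidence and ChIP-like read
# placements. Every stage of the pipeline is testable against the
# logged truth without external binaries or downloads.

.BASES <- c("A", "C", "G", "T")

.randSeq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                              collapse = "")

# substitute each position independently with probability `rate`,
# uniformly to one of the three other bases
.mutateSeq <- function(seq, rate) {
    if (rate <= 0) return(seq)
    ch <- strsplit(seq, "")[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    if (length(hit)) {
        repl <- vapply(ch[hit], function(b)
            sample(setdiff(.BASES, b), 1L), character(1))
        ch[hit] <- repl
    }
    paste(ch, collapse = "")
}

#' Simulate a tandem satellite array
#'
#' Head-to-tail copies of a monomer, each copy independently mutated at
#' the given divergence rate. Deterministic for a fixed seed.
#'
#' @param monomerLength monomer length in nt (default 156, a typical
#'   centromeric-satellite scale).
#' @param copies number of tandem copies (>= 1).
#' @param divergence per-position substitution rate applied to each
#'   copy.
#' @param monomer optional explicit monomer sequence.
#' @param seed optional RNG seed.
#' @return list with \code{sequence}, \code{monomer} and a
#'   \code{coords} data.frame (copy, start, end; 1-based within the
#'   array).
#' @export
makeSatelliteArray <- function(monomerLength = 156L, copies,
                               divergence = 0, monomer = NULL,
                               seed = NULL) {
    if (copies < 1L) stop("copies must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    if (is.null(monomer)) monomer <- .randSeq(monomerLength)
    monomerLength <- nchar(monomer)
    units <- vapply(seq_len(copies), function(i)
        .mutateSeq(monomer, divergence), character(1))
    ends <- cumsum(nchar(units))
    list(sequence = paste(units, collapse = ""),
         monomer = monomer,
         coords = data.frame(copy = seq_len(copies),
                             start = ends - nchar(units) + 1L,
                             end = ends))
}

#' Create an element template (LTR + internal sequence)
#'
#' Templates model an LTR-retroelement family: a terminal repeat
#' sequence and a CDS-bearing internal sequence. A subfamily variant is
#' derived from a parent template by mutating both parts at the given
#' divergence (emulating parental variants of a family).
#'
#' @param family family name.
#' @param ltrLength,internalLength sequence lengths (nt); LTR length
#'   must be >= 100.
#' @param parent optional parent template to derive a variant from.
#' @param divergence substitution rate from the parent, in [0, 0.3].
#' @return list with \code{family}, \code{ltr}, \code{internal}.
#' @export
newElementTemplate <- function(family, ltrLength = 1500L,
                               internalLength = 5000L, parent = NULL,
                               divergence = 0) {
    if (divergence < 0 || divergence > 0.3)
        stop("divergence must lie in [0, 0.3]")
    if (is.null(parent)) {
        if (ltrLength < 100L) stop("LTR length must be >= 100")
        list(family = family, ltr = .randSeq(ltrLength),
             internal = .randSeq(internalLength))
    } else {
        list(family = family,
             ltr = .mutateSeq(parent$ltr, divergence),
             internal = .mutateSeq(parent$internal, divergence))
    }
}

.emptySegments <- function() {
    data.frame(start = integer(0), end = integer(0),
               family = character(0), part = character(0),
               elementId = integer(0), stringsAsFactors = FALSE)
}

.emptyJunctions <- function() {
    data.frame(position = integer(0), leftFamily = character(0),
               rightFamily = character(0), insertion = integer(0),
               stringsAsFactors = FALSE)
}

.emptyInsertions <- function() {
    data.frame(order = integer(0), family = character(0),
               position = integer(0), length = integer(0),
               ltrDivergence = numeric(0),
               leftLtrStart = integer(0), leftLtrEnd = integer(0),
               rightLtrStart = integer(0), rightLtrEnd = integer(0),
               elementSeq = character(0), stringsAsFactors = FALSE)
}

# shift all logged coordinates >= p right by L nucleotides
.shiftTruth <- function(sim, p, L) {
    sh <- function(v) ifelse(v >= p, v + L, v)
    sg <- sim@segments
    if (nrow(sg)) {
        # a segment containing p is split by the caller; others shift whole
        sg$start <- sh(sg$start); sg$end <- sh(sg$end)
        sim@segments <- sg
    }
    j <- sim@junctions
    if (nrow(j)) { j$position <- sh(j$position); sim@junctions <- j }
    ins <- sim@insertions
    if (nrow(ins)) {
        for (col in c("position", "leftLtrStart", "leftLtrEnd",
                      "rightLtrStart", "rightLtrEnd"))
            ins[[col]] <- sh(ins[[col]])
        sim@insertions <- ins
    }
    sat <- sim@satellites
    if (nrow(sat)) {
        # an array containing p widens; arrays right of p shift whole
        sat$end <- sh(sat$end)
        sat$start <- sh(sat$start)
        sim@satellites <- sat
    }
    sim
}

#' Initialize an empty simulated centromere
#'
#' Builds the base sequence: a random left flank, a central tandem
#' satellite array (family \code{CentC}), and a random right flank.
#' Element templates for the requested retroelement families are
#' generated. Call \code{\link{insertElement}} (or
#' \code{\link{simulateCentromere}}) to add nested insertions.
#'
#' @param seed RNG seed for the whole corpus.
#' @param flankLength length of each random single-copy flank (nt).
#' @param satelliteCopies number of satellite monomer copies.
#' @param monomerLength satellite monomer length (nt).
#' @param satelliteDivergence per-copy substitution rate of the array.
#' @param families character vector of element family names.
#' @param ltrLength,internalLength element template dimensions (nt).
#' @return A \code{\link{CentromereSim}}.
#' @export
newCentromereSim <- function(seed = 1L, flankLength = 20000L,
                             satelliteCopies = 40L, monomerLength = 156L,
                             satelliteDivergence = 0.05,
                             families = c("CRM1", "CRM2", "CRM3"),
                             ltrLength = 1500L, internalLength = 5000L) {
    set.seed(seed)
    left <- .randSeq(flankLength)
    sat <- makeSatelliteArray(monomerLength, satelliteCopies,
                              satelliteDivergence)
    right <- .randSeq(flankLength)
    genome <- Biostrings::DNAString(paste0(left, sat$sequence, right))
    satStart <- flankLength + 1L
    satEnd <- flankLength + nchar(sat$sequence)
    segments <- data.frame(start = satStart, end = satEnd,
                           family = "CentC", part = "SAT",
                           elementId = 0L, stringsAsFactors = FALSE)
    templates <- stats::setNames(lapply(families, function(f)
        newElementTemplate(f, ltrLength, internalLength)), families)
    templates[["CentC"]] <- list(family = "CentC", monomer = sat$monomer)
    new("CentromereSim", genome = genome, segments = segments,
        junctions = .emptyJunctions(), insertions = .emptyInsertions(),
        satellites = data.frame(start = satStart, end = satEnd),
        templates = templates, seed = as.integer(seed))
}

#' Insert a retroelement into a simulated centromere
#'
#' Inserts LTR-internal-LTR at the given position (the element occupies
#' \code{position .. position + length - 1}; the former occupant of
#' \code{position} moves right). The right LTR is independently mutated
#' at rate \code{ltrDivergence}, emulating post-insertion divergence
#' used for dating. All previously logged coordinates are shifted, the
#' host segment is split, and the two repeat junctions created by the
#' insertion are logged. No target-site duplication is modeled.
#'
#' @param sim a \code{\link{CentromereSim}}.
#' @param family element family (must have a template in \code{sim}).
#' @param position 1-based insertion point; must lie strictly inside an
#'   annotated segment for the junctions to be detectable, and inside
#'   the genome in any case.
#' @param ltrDivergence substitution rate applied to the right LTR.
#' @return the updated \code{CentromereSim}.
#' @export
insertElement <- function(sim, family, position, ltrDivergence = 0) {
    tpl <- sim@templates[[family]]
    if (is.null(tpl) || is.null(tpl$ltr))
        stop("no element template for family '", family, "'")
    n <- length(sim@genome)
    p <- as.integer(position)
    if (p < 1L || p > n) stop("insertion position out of range")
    ltr1 <- tpl$ltr
    ltr2 <- .mutateSeq(tpl$ltr, ltrDivergence)
    elem <- paste0(ltr1, tpl$internal, ltr2)
    L <- nchar(elem)
    ltrLen <- nchar(ltr1)
    intLen <- nchar(tpl$internal)

    # host segment (if any) containing the insertion point
    sg <- sim@segments
    hostIdx <- which(sg$start < p & sg$end >= p)
    host <- if (length(hostIdx)) sg[hostIdx[1], ] else NULL

    gs <- as.character(sim@genome)
    sim@genome <- Biostrings::DNAString(
        paste0(substr(gs, 1L, p - 1L), elem, substr(gs, p, n)))
    sim <- .shiftTruth(sim, p, L)
    sg <- sim@segments

    ord <- nrow(sim@insertions) + 1L
    if (!is.null(host)) {
        # split the (already shifted) host segment around the element
        hi <- which(sg$start == host$start & sg$end == host$end + L &
                    sg$family == host$family & sg$part == host$part)[1]
        sg <- sg[-hi, , drop = FALSE]
        sg <- rbind(sg,
            data.frame(start = host$start, end = p - 1L,
                       family = host$family, part = host$part,
                       elementId = host$elementId,
                       stringsAsFactors = FALSE),
            data.frame(start = p + L, end = host$end + L,
                       family = host$family, part = host$part,
                       elementId = host$elementId,
                       stringsAsFactors = FALSE))
    }
    sg <- rbind(sg, data.frame(
        start = c(p, p + ltrLen, p + ltrLen + intLen),
        end = c(p + ltrLen - 1L, p + ltrLen + intLen - 1L, p + L - 1L),
        family = family, part = c("LTR", "CDS", "LTR"),
        elementId = ord, stringsAsFactors = FALSE))
    sim@segments <- sg[order(sg$start), , drop = FALSE]

    if (!is.null(host)) {
        sim@junctions <- rbind(sim@junctions, data.frame(
            position = c(p - 1L, p + L - 1L),
            leftFamily = c(host$family, family),
            rightFamily = c(family, host$family),
            insertion = ord, stringsAsFactors = FALSE))
    }
    sim@insertions <- rbind(sim@insertions, data.frame(
        order = ord, family = family, position = p, length = L,
        ltrDivergence = ltrDivergence,
        leftLtrStart = p, leftLtrEnd = p + ltrLen - 1L,
        rightLtrStart = p + ltrLen + intLen,
        rightLtrEnd = p + L - 1L,
        elementSeq = elem, stringsAsFactors = FALSE))
    methods::validObject(sim)
    sim
}

#' Simulate a nested-insertion centromere corpus
#'
#' Builds the base sequence and performs \code{nInsertions} nested
#' insertions. Each insertion picks a random annotated host segment
#' (satellite or previously inserted element), a position strictly
#' inside it, and an element family different from the host family --
#' so every insertion creates exactly two detectable repeat junctions.
#' LTR divergences are taken from \code{ltrDivergences} (recycled),
#' assigned in insertion order, so a decreasing vector yields an
#' age ladder with the oldest element inserted first.
#'
#' @param seed RNG seed; the whole corpus is a deterministic function
#'   of it.
#' @param nInsertions number of nested insertions.
#' @param ltrDivergences per-insertion right-LTR substitution rates.
#' @param ... passed to \code{\link{newCentromereSim}}.
#' @return A \code{\link{CentromereSim}}.
#' @export
simulateCentromere <- function(seed = 1L, nInsertions = 20L,
                               ltrDivergences = 0, ...) {
    sim <- newCentromereSim(seed = seed, ...)
    div <- rep_len(ltrDivergences, max(nInsertions, 1L))
    families <- setdiff(names(sim@templates), "CentC")
    for (k in seq_len(nInsertions)) {
        sg <- sim@segments[sim@segments$end - sim@segments$start >= 1L, ,
                           drop = FALSE]
        host <- sg[sample.int(nrow(sg), 1L), ]
        p <- host$start + sample.int(host$end - host$start, 1L)
        fam <- sample(setdiff(families, host$family), 1L)
        sim <- insertElement(sim, fam, p, div[k])
    }
    sim
}

#' Emit synthetic homology evidence and read placements
#'
#' Writes, into \code{dir}: the genome FASTA, one BLAST-tabular file
#' per element/satellite family (one HSP per ground-truth visible
#' segment; coordinates exact at \code{noise = 0}, jittered by up to
#' \code{noise} nt otherwise), optional short decoy HSPs from a decoy
#' database, a cross_match-format mask file covering all repeat
#' segments, a read-placement TSV (reads drawn uniformly from
#' \code{enrichedInterval} to emulate centromeric chromatin
#' enrichment; repeat-derived reads carry high mapping multiplicity),
#' and the ground truth as GFF3.
#'
#' @param sim a \code{\link{CentromereSim}}.
#' @param dir output directory (created if needed).
#' @param noise maximum absolute coordinate jitter (nt) on HSP ends.
#' @param nDecoys number of short decoy HSPs nested inside true
#'   segments.
#' @param nReads number of simulated read placements.
#' @param readLength simulated read length (nt).
#' @param enrichedInterval length-2 vector restricting read placement
#'   (default: the central third of the genome).
#' @return list of file paths (\code{genome}, \code{blast} [named by
#'   family], \code{crossmatch}, \code{placements}, \code{truth}).
#' @export
emitEvidence <- function(sim, dir, noise = 0, nDecoys = 0L,
                         nReads = 2000L, readLength = 300L,
                         enrichedInterval = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    qid <- "simQuery"
    n <- length(sim@genome)
    genomePath <- file.path(dir, "genome.fa")
    seqs <- Biostrings::DNAStringSet(as.character(sim@genome))
    names(seqs) <- qid
    Biostrings::writeXStringSet(seqs, genomePath)

    sg <- sim@segments
    jitter <- function(v, lo, hi) {
        if (noise <= 0) return(v)
        pmin(pmax(v + sample.int(2L * noise + 1L, length(v),
                                 replace = TRUE) - noise - 1L, lo), hi)
    }
    tplLen <- function(fam, part) {
        tpl <- sim@templates[[fam]]
        if (part == "LTR") nchar(tpl$ltr)
        else if (part == "CDS") nchar(tpl$internal)
        else nchar(tpl$monomer)
    }
    blastPaths <- character(0)
    for (fam in unique(sg$family)) {
        rows <- sg[sg$family == fam, , drop = FALSE]
        qs <- jitter(rows$start, 1L, n)
        qe <- jitter(rows$end, 1L, n)
        len <- qe - qs + 1L
        sLen <- mapply(tplLen, rows$family, rows$part)
        lines <- sprintf(
            "%s\t%s\t%.2f\t%d\t0\t0\t%d\t%d\t%d\t%d\t%s\t%d",
            qid, paste0(fam, "#", rows$part), 100, len, qs, qe,
            1L, pmin(len, sLen), "1e-180", 2L * len)
        path <- file.path(dir, paste0("blast_", fam, ".tsv"))
        writeLines(lines, path)
        blastPaths[fam] <- path
    }
    if (nDecoys > 0L) {
        big <- sg[sg$end - sg$start + 1L >= 400L, , drop = FALSE]
        nd <- min(nDecoys, nrow(big) * 10L)
        pickR <- big[sample.int(nrow(big), nd, replace = TRUE), ,
                     drop = FALSE]
        dLen <- 150L
        ds <- pickR$start +
            vapply(pickR$end - pickR$start - dLen,
                   function(m) sample.int(m, 1L), integer(1))
        path <- file.path(dir, "blast_decoy.tsv")
        writeLines(sprintf(
            "%s\t%s\t%.2f\t%d\t0\t0\t%d\t%d\t%d\t%d\t%s\t%d",
            qid, "decoy#other", 90, dLen, ds, ds + dLen - 1L,
            1L, dLen, "1e-20", dLen), path)
        blastPaths["decoy"] <- path
    }

    cmPath <- file.path(dir, "crossmatch.txt")
    cmLines <- sprintf(
        "%d %.2f %.2f %.2f %s %d %d (%d) %s %d %d (%d)",
        2L * (sg$end - sg$start + 1L), 0, 0, 0, qid, sg$start, sg$end,
        n - sg$end, paste0(sg$family, "#", sg$part), 1L,
        sg$end - sg$start + 1L, 0L)
    writeLines(cmLines, cmPath)

    if (is.null(enrichedInterval))
        enrichedInterval <- c(floor(n / 3), floor(2 * n / 3))
    lo <- enrichedInterval[1]; hi <- enrichedInterval[2] - readLength
    starts <- lo + sample.int(max(hi - lo, 1L), nReads, replace = TRUE) - 1L
    ends <- pmin(starts + readLength - 1L, n)
    inRepeat <- vapply(starts, function(s)
        any(sg$start <= s + readLength - 1L & sg$end >= s), logical(1))
    isSat <- vapply(seq_along(starts), function(i)
        any(sg$start <= ends[i] & sg$end >= starts[i] &
            sg$family == "CentC"), logical(1))
    hitsGenome <- ifelse(isSat, 50L, ifelse(inRepeat, 10L, 1L))
    hitsQuery <- ifelse(isSat, 5L, 1L)
    plPath <- file.path(dir, "placements.tsv")
    writeLines(sprintf("read%05d\t%s\t%d\t%d\t%d\t%d",
                       seq_along(starts), qid, starts, ends,
                       hitsQuery, hitsGenome), plPath)

    truthPath <- file.path(dir, "truth.gff3")
    gr <- GRanges(qid, IRanges(sg$start, sg$end))
    mcols(gr) <- S4Vectors::DataFrame(
        source = "simulate", type = "repeat_region",
        Name = paste0(sg$family, "/", sg$part),
        elementId = sg$elementId)
    rtracklayer::export(gr, truthPath, format = "GFF3")

    list(genome = genomePath, blast = blastPaths, crossmatch = cmPath,
         placements = plPath, truth = truthPath)
}
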