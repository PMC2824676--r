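# Parameters-file handling: a single sectioned plain-text file drives the
# whole pipeline. Dialect: `[section]` headers, `key = value` lines, `#`
# comments; repeated keys accumulate (used for per-database lines).

.RJ_SECTIONS <- c("general", "ncbi-blast", "wu-blast", "blast-colors",
                  "crossmatch-colors", "charts")

.RJ_GENERAL_DEFAULTS <- list(
    query = "",
    output_dir = ".",
    nt_per_pixel = 50,
    inter_db_overlap_allowance_nt = 0L,
    gap_run_threshold_nt = 100L,
    tile_window_nt = 210000L,
    tile_overlap_nt = 10000L,
    min_exact_match_nt = 100L,
    max_match_levels = 30L,
    junction_gap_tolerance_nt = 50L,
    max_marker_span_nt = 2500L
)

.splitFields <- function(value) strsplit(trimws(value), "[[:space:]]+")[[1]]

.isColor <- function(x) {
    grepl("^#[0-9a-fA-F]{6}$", x) | x %in% grDevices::colors()
}

#' Parse the six-section parameters file
#'
#' Reads the plain-text parameters file that configures every pipeline
#' stage. The file holds six sections: \code{[general]} (paths, display
#' scale, overlap allowance, gap threshold, tiling), \code{[ncbi-blast]}
#' and \code{[wu-blast]} (one \code{db = name path evalue
#' [score_fraction] [priority]} line per subject database),
#' \code{[blast-colors]} (\code{color = db:subject color} and
#' \code{subrange = db:subject start end color} lines),
#' \code{[crossmatch-colors]} (\code{db = name path color} lines) and
#' \code{[charts]} (\code{chart = name set color path} lines, where
#' \code{set} is \code{foreground} or \code{background}). Section order
#' is irrelevant; \code{#} starts a comment. Omitted optional keys in
#' \code{[general]} take documented defaults (overlap allowance 0 nt,
#' gap run threshold 100 nt, tile window 210,000 nt, tile overlap
#' 10,000 nt, minimum exact match 100 nt, 30 match levels).
#'
#' @param path path to the parameters file.
#' @return A list of class \code{rjParams} with elements \code{general},
#'   \code{ncbiBlast}, \code{wuBlast}, \code{blastColors},
#'   \code{crossmatchDbs} and \code{charts}.
#' @seealso \code{\link{writeParamsTemplate}}
#' @export
parseParameters <- function(path) {
    if (!file.exists(path))
        stop("parameters file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)

    section <- NA_character_
    acc <- stats::setNames(
        lapply(.RJ_SECTIONS, function(x) list()), .RJ_SECTIONS)
    seen <- character(0)
    for (i in seq_along(lines)) {
        ln <- lines[i]
        if (!nzchar(ln)) next
        if (grepl("^\\[.+\\]$", ln)) {
            section <- sub("^\\[(.+)\\]$", "\\1", ln)
            if (!section %in% .RJ_SECTIONS)
                stop("unknown section '", section, "' at line ", i)
            seen <- union(seen, section)
            next
        }
        if (is.na(section))
            stop("key outside any section at line ", i)
        if (!grepl("=", ln, fixed = TRUE))
            stop("expected 'key = value' at line ", i, ": ", ln)
        key <- trimws(sub("=.*$", "", ln))
        val <- trimws(sub("^[^=]*=", "", ln))
        acc[[section]] <- c(acc[[section]],
                            stats::setNames(list(val), key))
    }
    missing <- setdiff(.RJ_SECTIONS, seen)
    if (length(missing))
        stop("missing mandatory section(s): ",
             paste0("[", missing, "]", collapse = ", "))

    general <- .RJ_GENERAL_DEFAULTS
    gl <- acc[["general"]]
    for (key in names(gl)) {
        if (!key %in% names(general))
            stop("unknown key '", key, "' in [general]")
        default <- general[[key]]
        general[[key]] <- if (is.character(default)) gl[[key]]
            else if (is.integer(default)) as.integer(gl[[key]])
            else as.numeric(gl[[key]])
    }
    if (is.na(general$nt_per_pixel) || general$nt_per_pixel <= 0)
        stop("nt_per_pixel must be a positive number")
    if (general$inter_db_overlap_allowance_nt < 0)
        stop("inter_db_overlap_allowance_nt must be non-negative")
    if (general$gap_run_threshold_nt < 1)
        stop("gap_run_threshold_nt must be >= 1")
    if (general$tile_overlap_nt >= general$tile_window_nt)
        stop("tile_overlap_nt must be smaller than tile_window_nt")

    parseDbs <- function(entries, engine) {
        entries <- entries[names(entries) == "db"]
        if (!length(entries))
            return(data.frame(name = character(0), path = character(0),
                              evalue = numeric(0), scoreFraction = numeric(0),
                              priority = integer(0), engine = character(0),
                              stringsAsFactors = FALSE))
        rows <- lapply(entries, function(v) {
            f <- .splitFields(v)
            if (length(f) < 3)
                stop("db line needs at least 'name path evalue': ", v)
            ev <- as.numeric(f[3])
            if (is.na(ev) || ev <= 0)
                stop("E-value cutoff must be a positive real: ", v)
            sf <- if (length(f) >= 4) as.numeric(f[4]) else NA_real_
            if (!is.na(sf) && (sf <= 0 || sf > 1))
                stop("score fraction must lie in (0, 1]: ", v)
            data.frame(name = f[1], path = f[2], evalue = ev,
                       scoreFraction = sf,
                       priority = if (length(f) >= 5) as.integer(f[5])
                                  else NA_integer_,
                       engine = engine, stringsAsFactors = FALSE)
        })
        do.call(rbind, c(rows, list(make.row.names = FALSE)))
    }
    ncbi <- parseDbs(acc[["ncbi-blast"]], "ncbi")
    wu <- parseDbs(acc[["wu-blast"]], "wu")
    allNames <- c(ncbi$name, wu$name)
    if (anyDuplicated(allNames))
        stop("duplicate db_name across BLAST sections: ",
             paste(unique(allNames[duplicated(allNames)]), collapse = ", "))

    bc <- acc[["blast-colors"]]
    colorRows <- lapply(bc[names(bc) == "color"], function(v) {
        f <- .splitFields(v)
        if (length(f) != 2 || !grepl(":", f[1]))
            stop("color line must be 'db:subject color': ", v)
        ds <- strsplit(f[1], ":", fixed = TRUE)[[1]]
        data.frame(db = ds[1], subject = ds[2], color = f[2],
                   stringsAsFactors = FALSE)
    })
    subrangeRows <- lapply(bc[names(bc) == "subrange"], function(v) {
        f <- .splitFields(v)
        if (length(f) != 4 || !grepl(":", f[1]))
            stop("subrange line must be 'db:subject start end color': ", v)
        ds <- strsplit(f[1], ":", fixed = TRUE)[[1]]
        data.frame(db = ds[1], subject = ds[2],
                   start = as.integer(f[2]), end = as.integer(f[3]),
                   color = f[4], stringsAsFactors = FALSE)
    })
    blastColors <- list(
        subjectColors = if (length(colorRows)) do.call(rbind, colorRows)
            else data.frame(db = character(0), subject = character(0),
                            color = character(0), stringsAsFactors = FALSE),
        subrangeColors = if (length(subrangeRows)) do.call(rbind, subrangeRows)
            else data.frame(db = character(0), subject = character(0),
                            start = integer(0), end = integer(0),
                            color = character(0), stringsAsFactors = FALSE))
    allCols <- c(blastColors$subjectColors$color,
                 blastColors$subrangeColors$color)
    if (length(allCols) && !all(.isColor(allCols)))
        stop("invalid color(s): ",
             paste(allCols[!.isColor(allCols)], collapse = ", "))
    sr <- blastColors$subrangeColors
    if (nrow(sr)) {
        if (any(sr$end < sr$start)) stop("subrange end before start")
        bySubj <- split(sr, paste(sr$db, sr$subject))
        for (grp in bySubj) {
            if (nrow(grp) > 1) {
                o <- order(grp$start)
                if (any(grp$start[o][-1] <= grp$end[o][-nrow(grp)]))
                    stop("overlapping subranges for subject ",
                         grp$subject[1])
            }
        }
    }

    cm <- acc[["crossmatch-colors"]]
    cmRows <- lapply(cm[names(cm) == "db"], function(v) {
        f <- .splitFields(v)
        if (length(f) != 3)
            stop("crossmatch db line must be 'name path color': ", v)
        if (!.isColor(f[3])) stop("invalid color: ", f[3])
        data.frame(name = f[1], path = f[2], color = f[3],
                   stringsAsFactors = FALSE)
    })
    crossmatchDbs <- if (length(cmRows)) do.call(rbind, cmRows)
        else data.frame(name = character(0), path = character(0),
                        color = character(0), stringsAsFactors = FALSE)

    ch <- acc[["charts"]]
    chRows <- lapply(ch[names(ch) == "chart"], function(v) {
        f <- .splitFields(v)
        if (length(f) != 4)
            stop("chart line must be 'name set color path': ", v)
        if (!f[2] %in% c("foreground", "background"))
            stop("chart set must be foreground or background: ", v)
        if (!.isColor(f[3])) stop("invalid color: ", f[3])
        data.frame(name = f[1], set = f[2], color = f[3], path = f[4],
                   stringsAsFactors = FALSE)
    })
    charts <- if (length(chRows)) do.call(rbind, chRows)
        else data.frame(name = character(0), set = character(0),
                        color = character(0), path = character(0),
                        stringsAsFactors = FALSE)

    structure(list(general = general, ncbiBlast = ncbi, wuBlast = wu,
                   blastColors = blastColors, crossmatchDbs = crossmatchDbs,
                   charts = charts),
              class = "rjParams")
}

#' @export
print.rjParams <- function(x, ...) {
    cat("Repeat-annotation parameters\n")
    cat("  query:", x$general$query, "\n")
    cat("  NCBI BLAST dbs:", nrow(x$ncbiBlast),
        " WU-BLAST dbs:", nrow(x$wuBlast),
        " cross_match dbs:", nrow(x$crossmatchDbs),
        " charts:", nrow(x$charts), "\n")
    cat("  allowance:", x$general$inter_db_overlap_allowance_nt,
        "nt  gap threshold:", x$general$gap_run_threshold_nt,
        "nt  tiling:", x$general$tile_window_nt, "/",
        x$general$tile_overlap_nt, "nt\n")
    invisible(x)
}

#' Write a commented parameters-file template
#'
#' Emits a template with all six sections, one commented line per field,
#' populated with the package defaults and example database entries. The
#' written file re-parses successfully with
#' \code{\link{parseParameters}}.
#'
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writeParamsTemplate <- function(path) {
    tpl <- c(
        "# Parameters file: six sections configure the whole pipeline.",
        "# Lines starting with '#' are comments. key = value per line.",
        "",
        "[general]",
        "# Path to the FASTA file of query sequences.",
        "query = queries.fa",
        "# Directory that receives all output files.",
        "output_dir = .",
        "# Horizontal display scale: nucleotides drawn per pixel.",
        "nt_per_pixel = 50",
        "# Overlap (nt) tolerated between kept features of different databases.",
        "inter_db_overlap_allowance_nt = 0",
        "# Minimum run of Ns reported as an assembly gap (grey bars).",
        "gap_run_threshold_nt = 100",
        "# Long queries are cut into windows of this size ...",
        "tile_window_nt = 210000",
        "# ... overlapping by this many nt so short features are drawn whole.",
        "tile_overlap_nt = 10000",
        "# Minimum length of exact repeated matches to report.",
        "min_exact_match_nt = 100",
        "# Number of drawing levels for exact-match lines.",
        "max_match_levels = 30",
        "# Max unannotated nt between features still forming a junction.",
        "junction_gap_tolerance_nt = 50",
        "# Max distance (nt) between two junctions paired into one marker.",
        "max_marker_span_nt = 2500",
        "",
        "[ncbi-blast]",
        "# One subject database per line: db = name path evalue [score_fraction] [priority]",
        "db = exampleRepeats repeats.fa 1e-10",
        "",
        "[wu-blast]",
        "# Same layout; score_fraction keeps HSPs scoring at least that",
        "# fraction of a perfect complete match to the subject (e.g. 0.9).",
        "db = exampleLtrs ltrs.fa 1e-10 0.9",
        "",
        "[blast-colors]",
        "# Per-subject colors: color = db:subject color",
        "color = exampleRepeats:CentC green",
        "# Optional per-subrange colors: subrange = db:subject start end color",
        "subrange = exampleLtrs:CRM1 1 1500 blue",
        "",
        "[crossmatch-colors]",
        "# Masking databases: db = name path color",
        "db = exampleMask mask.fa grey",
        "",
        "[charts]",
        "# Per-nucleotide charts: chart = name set color path",
        "# set is 'foreground' or 'background' (independent y-axes).",
        "chart = uniqueReads foreground red placements.tsv",
        "")
    writeLines(tpl, path)
    invisible(path)
}
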