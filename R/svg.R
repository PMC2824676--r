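# SVG serialization of the display model. The output is deterministic
# (no timestamps, fixed number formatting) and structural: every drawn
# element carries a class and data-coordinates so the figure can be
# asserted on by XML parsing.

.RJ_STYLE <- list(
    margin = 40, rulerY = 30, tickH = 8,
    chartTop = 60, chartH = 100,
    maskTop = 190, maskH = 24,
    hspTop = 240, hspH = 24,
    matchTop = 300, levelH = 6,
    gapBarColor = "grey", directColor = "red", invertedColor = "blue",
    defaultMaskColor = "darkgrey", defaultHspColor = "steelblue")

.xmlEscape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
}

.fmt <- function(x) sprintf("%.2f", x)

.featureColor <- function(subject, colors, fallback) {
    if (!is.null(colors) && subject %in% names(colors))
        colors[[subject]] else fallback
}

#' @describeIn toSVG render a \code{DisplayModel} as an SVG 1.1 document
#' @export
setMethod("toSVG", "DisplayModel", function(x) {
    st <- .RJ_STYLE
    px <- function(pos) (pos - 1) / x@ntPerPixel + st$margin
    width <- px(x@length + 1L) + st$margin
    nLevels <- x@params$maxLevels
    height <- st$matchTop + (nLevels + 1L) * st$levelH + st$margin
    out <- c(sprintf(paste0(
        '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
        'width="%s" height="%s" data-query="%s" data-length="%d" ',
        'data-nt-per-pixel="%s">'),
        .fmt(width), .fmt(height), .xmlEscape(x@query), x@length,
        .fmt(x@ntPerPixel)))

    # ---- ruler ----------------------------------------------------------
    out <- c(out, '<g class="ruler">',
        sprintf('<line class="baseline" x1="%s" y1="%d" x2="%s" y2="%d" stroke="black"/>',
                .fmt(px(1)), st$rulerY, .fmt(px(x@length)), st$rulerY))
    if (nrow(x@ticks)) {
        out <- c(out, sprintf(paste0(
            '<line class="tick" x1="%s" y1="%d" x2="%s" y2="%d" ',
            'stroke="black" data-pos="%d"/>',
            '<text class="tick-label" x="%s" y="%d" font-size="7">%s</text>',
            '<text class="tick-rel-label" x="%s" y="%d" font-size="7">%d</text>'),
            .fmt(px(x@ticks$pos)), st$rulerY - st$tickH,
            .fmt(px(x@ticks$pos)), st$rulerY, x@ticks$pos,
            .fmt(px(x@ticks$pos)), st$rulerY - st$tickH - 2,
            .xmlEscape(x@ticks$label),
            .fmt(px(x@ticks$pos)), st$rulerY + 10, x@ticks$rel))
    }
    if (nrow(x@gapBars)) {
        out <- c(out, sprintf(paste0(
            '<rect class="gap-bar" x="%s" y="%d" width="2" height="%d" ',
            'fill="%s" data-pos="%d"/>'),
            .fmt(px(x@gapBars$pos)), st$rulerY - st$tickH - 12,
            st$tickH + 12, st$gapBarColor, x@gapBars$pos))
    }
    out <- c(out, '</g>')

    # ---- charts (background set first, then foreground) -----------------
    out <- c(out, '<g class="charts">')
    for (setName in c("background", "foreground")) {
        cs <- x@chartSets[[setName]]
        if (is.null(cs) || !length(cs$charts)) next
        yMax <- max(cs$yMax, 1)
        for (ch in cs$charts) {
            # one point per pixel column: max value within the column
            n <- length(ch@values)
            bins <- ceiling(seq_len(n) / x@ntPerPixel)
            vmax <- tapply(ch@values, bins, max)
            bx <- st$margin + (as.numeric(names(vmax)) - 0.5)
            by <- st$chartTop + st$chartH - vmax / yMax * st$chartH
            pts <- paste(paste0(.fmt(bx), ",", .fmt(by)), collapse = " ")
            out <- c(out, sprintf(paste0(
                '<polyline class="chart %s" fill="none" stroke="%s" ',
                'data-name="%s" data-ymax="%s" points="%s"/>'),
                setName, ch@color, .xmlEscape(ch@name),
                format(chartYMax(ch), trim = TRUE), pts))
        }
    }
    out <- c(out, '</g>')

    # ---- cross_match mask boxes -----------------------------------------
    out <- c(out, '<g class="masks">')
    if (!is.null(x@maskTrack)) {
        kept <- keptFeatures(x@maskTrack)
        if (length(kept)) {
            colors <- vapply(kept$subject, .featureColor,
                             character(1), colors = x@params$colors,
                             fallback = st$defaultMaskColor)
            out <- c(out, sprintf(paste0(
                '<rect class="mask-box" x="%s" y="%d" width="%s" ',
                'height="%d" fill="%s" data-start="%d" data-end="%d" ',
                'data-subject="%s"/>',
                '<text class="mask-label" x="%s" y="%d" ',
                'font-size="6">%d-%d</text>'),
                .fmt(px(start(kept))), st$maskTop,
                .fmt(width(kept) / x@ntPerPixel), st$maskH, colors,
                start(kept), end(kept), .xmlEscape(kept$subject),
                .fmt(px(start(kept))), st$maskTop + st$maskH + 8,
                start(kept), end(kept)))
        }
    }
    out <- c(out, '</g>')

    # ---- BLAST HSP arrows (kept overlaps drawn shorter over longer) -----
    out <- c(out, '<g class="hsps">')
    if (!is.null(x@hspTrack)) {
        kept <- keptFeatures(x@hspTrack)
        if (length(kept)) {
            kept <- kept[order(-width(kept))]   # shorter drawn last, on top
            colors <- vapply(kept$subject, .featureColor,
                             character(1), colors = x@params$colors,
                             fallback = st$defaultHspColor)
            x1 <- px(start(kept)); x2 <- px(end(kept) + 1L)
            yT <- st$hspTop; yM <- st$hspTop + st$hspH / 2
            yB <- st$hspTop + st$hspH
            head <- pmin(6, (x2 - x1) / 3)
            minus <- as.character(strand(kept)) == "-"
            pts <- ifelse(!minus,
                sprintf("%s,%d %s,%d %s,%s %s,%d %s,%d",
                        .fmt(x1), yT, .fmt(x2 - head), yT, .fmt(x2),
                        .fmt(yM), .fmt(x2 - head), yB, .fmt(x1), yB),
                sprintf("%s,%d %s,%d %s,%s %s,%d %s,%d",
                        .fmt(x2), yT, .fmt(x1 + head), yT, .fmt(x1),
                        .fmt(yM), .fmt(x1 + head), yB, .fmt(x2), yB))
            out <- c(out, sprintf(paste0(
                '<polygon class="hsp-arrow" points="%s" fill="%s" ',
                'data-start="%d" data-end="%d" data-strand="%s" ',
                'data-db="%s" data-subject="%s" data-subject-start="%d" ',
                'data-subject-end="%d"/>',
                '<text class="hsp-label" x="%s" y="%d" font-size="6">',
                'q:%d-%d s:%d-%d</text>'),
                pts, colors, start(kept), end(kept),
                as.character(strand(kept)), .xmlEscape(kept$db),
                .xmlEscape(kept$subject), kept$sStart, kept$sEnd,
                .fmt(x1), st$hspTop + st$hspH + 8,
                start(kept), end(kept), kept$sStart, kept$sEnd))
        }
    }
    out <- c(out, '</g>')

    # ---- exact-match lines ----------------------------------------------
    out <- c(out, '<g class="matches">')
    if (!is.null(x@matches) && length(x@matches)) {
        m <- x@matches
        lev <- matchLevels(m)
        for (i in which(!is.na(lev))) {
            y <- st$matchTop + (lev[i] - 1L) * st$levelH
            col <- if (m@orientation[i] == "direct") st$directColor
                   else st$invertedColor
            a1 <- px(start(m@first)[i]); a2 <- px(end(m@first)[i] + 1L)
            b1 <- px(start(m@second)[i]); b2 <- px(end(m@second)[i] + 1L)
            out <- c(out, sprintf(paste0(
                '<g class="match %s" data-level="%d" data-a-start="%d" ',
                'data-a-end="%d" data-b-start="%d" data-b-end="%d" ',
                'data-length="%d">',
                '<line class="match-interval" x1="%s" y1="%d" x2="%s" ',
                'y2="%d" stroke="%s"/>',
                '<line class="match-connector" x1="%s" y1="%d" x2="%s" ',
                'y2="%d" stroke="%s" stroke-dasharray="3,2"/>',
                '<line class="match-interval" x1="%s" y1="%d" x2="%s" ',
                'y2="%d" stroke="%s"/></g>'),
                m@orientation[i], lev[i],
                start(m@first)[i], end(m@first)[i],
                start(m@second)[i], end(m@second)[i], width(m@first)[i],
                .fmt(a1), y, .fmt(a2), y, col,
                .fmt(a2), y, .fmt(b1), y, col,
                .fmt(b1), y, .fmt(b2), y, col))
        }
    }
    out <- c(out, '</g>', '</svg>')
    paste(out, collapse = "\n")
})

#' Write a display model to an SVG file
#'
#' @param model a \code{\link{DisplayModel}}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writeSVG <- function(model, path) {
    writeLines(toSVG(model), path)
    invisible(path)
}
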