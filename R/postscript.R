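# PostScript (Level 2) serialization of the display model, mirroring
# the SVG geometry. Output is deterministic plain text.

#' @describeIn toPostscript render a \code{DisplayModel} as PostScript
#' @export
setMethod("toPostscript", "DisplayModel", function(x) {
    st <- .RJ_STYLE
    px <- function(pos) (pos - 1) / x@ntPerPixel + st$margin
    width <- px(x@length + 1L) + st$margin
    nLevels <- x@params$maxLevels
    height <- st$matchTop + (nLevels + 1L) * st$levelH + st$margin
    # PostScript y runs upward; flip against the page height
    fy <- function(y) .fmt(height - y)
    out <- c(
        "%!PS-Adobe-2.0 EPSF-2.0",
        sprintf("%%%%BoundingBox: 0 0 %d %d",
                ceiling(width), ceiling(height)),
        sprintf("%%%%Title: %s", x@query),
        "/l { moveto lineto stroke } bind def",
        "/b { newpath moveto dup 0 rlineto exch 0 exch rlineto neg 0 rlineto closepath fill } bind def",
        "0 setgray 0.5 setlinewidth")

    out <- c(out, sprintf("%s %s %s %s l",
        .fmt(px(1)), fy(st$rulerY), .fmt(px(x@length)), fy(st$rulerY)))
    if (nrow(x@ticks))
        out <- c(out, sprintf("%s %s %s %s l",
            .fmt(px(x@ticks$pos)), fy(st$rulerY - st$tickH),
            .fmt(px(x@ticks$pos)), fy(st$rulerY)))
    if (nrow(x@gapBars))
        out <- c(out, "0.6 setgray",
            sprintf("2 %d %s %s b", st$tickH + 12,
                    .fmt(px(x@gapBars$pos)),
                    fy(st$rulerY - st$tickH - 12 + st$tickH + 12)),
            "0 setgray")

    if (!is.null(x@maskTrack)) {
        kept <- keptFeatures(x@maskTrack)
        if (length(kept))
            out <- c(out, "0.7 setgray",
                sprintf("%s %d %s %s b",
                        .fmt(width(kept) / x@ntPerPixel), st$maskH,
                        .fmt(px(start(kept))),
                        fy(st$maskTop + st$maskH)),
                "0 setgray")
    }
    if (!is.null(x@hspTrack)) {
        kept <- keptFeatures(x@hspTrack)
        if (length(kept))
            out <- c(out, "0.3 setgray",
                sprintf("%s %d %s %s b",
                        .fmt(width(kept) / x@ntPerPixel), st$hspH,
                        .fmt(px(start(kept))), fy(st$hspTop + st$hspH)),
                "0 setgray")
    }
    if (!is.null(x@matches) && length(x@matches)) {
        m <- x@matches
        lev <- matchLevels(m)
        for (i in which(!is.na(lev))) {
            y <- st$matchTop + (lev[i] - 1L) * st$levelH
            rgb <- if (m@orientation[i] == "direct") "1 0 0" else "0 0 1"
            out <- c(out, sprintf("%s setrgbcolor", rgb),
                sprintf("%s %s %s %s l",
                        .fmt(px(start(m@first)[i])), fy(y),
                        .fmt(px(end(m@first)[i] + 1L)), fy(y)),
                "[3 2] 0 setdash",
                sprintf("%s %s %s %s l",
                        .fmt(px(end(m@first)[i] + 1L)), fy(y),
                        .fmt(px(start(m@second)[i])), fy(y)),
                "[] 0 setdash",
                sprintf("%s %s %s %s l",
                        .fmt(px(start(m@second)[i])), fy(y),
                        .fmt(px(end(m@second)[i] + 1L)), fy(y)))
        }
        out <- c(out, "0 setgray")
    }
    c(out, "showpage") |> paste(collapse = "\n")
})

#' Write a display model to a PostScript file
#'
#' @param model a \code{\link{DisplayModel}}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writePostscript <- function(model, path) {
    writeLines(toPostscript(model), path)
    invisible(path)
}
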