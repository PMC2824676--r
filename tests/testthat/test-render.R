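test_that("level layout puts the longest on top and packs greedily", {
    one <- layoutMatchLevels(mkMatches(1, 500, 100))
    expect_equal(matchLevels(one), 1L)

    two <- layoutMatchLevels(mkMatches(c(1, 2001), c(500, 2500),
                                       c(100, 100)))
    expect_equal(matchLevels(two), c(1L, 1L))   # disjoint extents share

    # overlapping matches cascade down one level each
    n <- 31
    m <- mkMatches(seq(1, by = 10, length.out = n),
                   seq(5000, by = 10, length.out = n),
                   seq(1000, 400, length.out = n))
    laid <- layoutMatchLevels(m, maxLevels = 30)
    lev <- matchLevels(laid)
    expect_equal(droppedMatches(laid), 1L)
    expect_equal(sort(lev[!is.na(lev)]), 1:30)
    # the longest match sits on the top level
    expect_equal(lev[which.max(matchLengths(m))], 1L)
})

test_that("no two matches on a level overlap horizontally", {
    set.seed(41)
    for (rep in 1:10) {
        k <- sample(5:20, 1)
        a <- sample.int(5000, k)
        b <- a + sample(200:3000, k, replace = TRUE)
        L <- sample(50:400, k, replace = TRUE)
        laid <- layoutMatchLevels(mkMatches(a, b, L), maxLevels = 5)
        df <- as.data.frame(laid)
        df <- df[!is.na(df$level), ]
        df$lo <- pmin(df$aStart, df$bStart)
        df$hi <- pmax(df$aEnd, df$bEnd)
        for (l in unique(df$level)) {
            sub <- df[df$level == l, ]
            if (nrow(sub) > 1) {
                o <- order(sub$lo)
                expect_true(all(sub$lo[o][-1] > sub$hi[o][-nrow(sub)]))
            }
        }
        # greedy minimality: each match could not sit on a higher level
        for (i in seq_len(nrow(df))) {
            if (df$level[i] == 1) next
            longer <- df[df$length > df$length[i] |
                         (df$length == df$length[i] & df$lo < df$lo[i]), ]
            for (l in seq_len(df$level[i] - 1)) {
                sub <- longer[longer$level == l, ]
                expect_true(any(sub$lo <= df$hi[i] & sub$hi >= df$lo[i]))
            }
        }
    }
})

test_that("display model assembles ruler, bars and panels", {
    seqStr <- paste0(strrep("A", 104500), strrep("N", 1000),
                     strrep("C", 104500))
    gaps <- detectGaps(seqStr)
    model <- buildDisplay("q", 210000, gaps = gaps)
    expect_equal(nrow(model@ticks), 210)
    expect_true(all(model@ticks$pos %% 1000 == 0))
    expect_equal(nrow(model@gapBars), 10)
    # gap-relative labels reset after the gap
    expect_equal(model@ticks$rel[model@ticks$pos == 106000],
                 106000 - 105500)

    bare <- buildDisplay("q", 5000)
    expect_equal(nrow(bare@gapBars), 0)
    expect_length(bare@charts, 0)
    expect_null(bare@hspTrack)
})

test_that("SVG structure mirrors the model and is deterministic", {
    skip_if_not_installed("xml2")
    set.seed(2)
    df <- data.frame(start = c(101, 1001, 5001), end = c(900, 3000, 6500),
                     db = c("A", "B", "A"), score = c(5, 7, 9))
    hsp <- classifyFeatures(competeFeatures(featuresFromDf(df), 0,
                                            "blast"))
    maskDf <- data.frame(start = c(201, 4001), end = c(1200, 5200),
                         db = "mask", score = 2)
    mask <- competeFeatures(featuresFromDf(maskDf), 0, "crossmatch")
    mask@kept$evidence <- "crossmatch"
    m <- layoutMatchLevels(mkMatches(c(1, 50), c(3000, 4000),
                                     c(400, 200),
                                     c("direct", "inverted")))
    ch <- buildCoverage(mkPlacements(c(1, 10), c(500, 700)), 8000, "all",
                        "cov", "background", "grey")
    gaps <- detectGaps(paste0(strrep("A", 6900), strrep("N", 300),
                              strrep("C", 800)))
    model <- buildDisplay("q", 8000, gaps = gaps, charts = list(ch),
                          maskTrack = mask, hspTrack = hsp, matches = m,
                          ntPerPixel = 10)
    svg <- toSVG(model)
    expect_identical(svg, toSVG(model))     # byte-identical re-render
    doc <- xml2::read_xml(svg)
    ns <- c(s = "http://www.w3.org/2000/svg")
    count <- function(xp) length(xml2::xml_find_all(doc, xp, ns))
    expect_equal(count("//s:rect[@class='gap-bar']"), sum(gaps$nBars))
    expect_equal(count("//s:rect[@class='mask-box']"),
                 length(keptFeatures(mask)))
    expect_equal(count("//s:polygon[@class='hsp-arrow']"),
                 length(keptFeatures(hsp)))
    expect_equal(count("//s:line[@class='tick']"), 8)
    expect_equal(count("//s:g[@class='match direct']"), 1)
    expect_equal(count("//s:g[@class='match inverted']"), 1)
    direct <- xml2::xml_find_first(doc, "//s:g[@class='match direct']",
                                   ns)
    strokes <- xml2::xml_attr(
        xml2::xml_find_all(direct, ".//s:line", ns), "stroke")
    expect_true(all(strokes == "red"))
    inv <- xml2::xml_find_first(doc, "//s:g[@class='match inverted']", ns)
    expect_true(all(xml2::xml_attr(
        xml2::xml_find_all(inv, ".//s:line", ns), "stroke") == "blue"))
    # connector is dashed, intervals solid
    dashed <- xml2::xml_find_all(doc, "//s:line[@class='match-connector']",
                                 ns)
    expect_true(all(!is.na(xml2::xml_attr(dashed, "stroke-dasharray"))))
    expect_equal(count("//s:polyline[@class='chart background']"), 1)
})

test_that("PostScript output is deterministic and complete", {
    m <- layoutMatchLevels(mkMatches(1, 1000, 300))
    model <- buildDisplay("q", 2000, matches = m, ntPerPixel = 10)
    ps <- toPostscript(model)
    expect_identical(ps, toPostscript(model))
    expect_match(ps, "^%!PS-Adobe", all = FALSE)
    expect_match(ps, "1 0 0 setrgbcolor", fixed = TRUE, all = FALSE)
    expect_match(ps, "showpage", all = FALSE)
})
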