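test_that("junctions form between adjacent features of different families", {
    tr <- trackFromSegments(data.frame(
        start = c(1, 1001), end = c(1000, 2500),
        family = c("CentC", "CRM1"), part = c("SAT", "LTR")))
    j <- detectJunctions(tr, gapTolerance = 50)
    expect_equal(nrow(j), 1)
    expect_equal(j$position, 1000L)
    expect_equal(j$leftClass, "CentC/SAT")
    expect_equal(j$rightClass, "CRM1/LTR")
    expect_equal(j$gap, 0L)

    # single feature: nothing
    single <- trackFromSegments(data.frame(start = 1, end = 1000,
                                           family = "CentC", part = "SAT"))
    expect_equal(nrow(detectJunctions(single)), 0)

    # same family on both sides: no junction (element anatomy)
    anatomy <- trackFromSegments(data.frame(
        start = c(1, 1001), end = c(1000, 2000),
        family = c("CRM1", "CRM1"), part = c("LTR", "CDS")))
    expect_equal(nrow(detectJunctions(anatomy)), 0)
    expect_equal(nrow(detectJunctions(anatomy, byFamily = FALSE)), 1)
})

test_that("junction gaps respect the tolerance and midpoint rule", {
    mk <- function(gap) trackFromSegments(data.frame(
        start = c(1, 1001 + gap), end = c(1000, 2000 + gap),
        family = c("CentC", "CRM2"), part = c("SAT", "LTR")))
    j <- detectJunctions(mk(40), gapTolerance = 50)
    expect_equal(nrow(j), 1)
    expect_equal(j$gap, 40L)
    expect_equal(j$position, 1000L + 20L)   # midpoint of the gap
    expect_equal(nrow(detectJunctions(mk(60), gapTolerance = 50)), 0)
})

test_that("marker candidates pair junctions within the span limit", {
    jt <- function(pos) data.frame(
        query = "q", position = pos,
        leftClass = "CentC/SAT", rightClass = "CRM1/LTR",
        leftIndex = 1L, rightIndex = 2L, gap = 0L,
        stringsAsFactors = FALSE)
    m <- findMarkerCandidates(rbind(jt(1000), jt(3200)))
    expect_equal(nrow(m), 1)
    expect_equal(m$span, 2200L)
    expect_equal(nrow(findMarkerCandidates(rbind(jt(1000), jt(3700)))), 0)
    m3 <- findMarkerCandidates(rbind(jt(100), jt(900), jt(2000)))
    expect_equal(nrow(m3), 3)
    expect_equal(m3$span, c(800L, 1100L, 1900L))  # sorted ascending
})

test_that("marker candidates equal the brute-force double loop", {
    set.seed(55)
    for (rep in 1:10) {
        pos <- sort(sample.int(30000, 25))
        jt <- data.frame(query = "q", position = pos,
                         leftClass = "a", rightClass = "b",
                         leftIndex = 1L, rightIndex = 2L, gap = 0L)
        got <- findMarkerCandidates(jt, 2500)
        want <- 0L
        for (a in seq_along(pos)) for (b in seq_along(pos))
            if (b > a && pos[b] - pos[a] <= 2500) want <- want + 1L
        expect_equal(nrow(got), want)
        expect_true(all(got$span <= 2500))
        expect_false(any(duplicated(paste(got$positionA, got$positionB))))
    }
})

test_that("K2P distance matches the closed form and excludes gaps", {
    id <- kimura2p("ACGTACGT", "ACGTACGT")
    expect_equal(id$kappa, 0)

    # 100 columns, 10 transitions (A<->G), no transversions
    a <- paste(rep("A", 100), collapse = "")
    b <- paste(c(rep("G", 10), rep("A", 90)), collapse = "")
    k <- kimura2p(a, b)
    expect_equal(k$P, 0.1)
    expect_equal(k$Q, 0)
    expect_equal(k$kappa, -0.5 * log(0.8), tolerance = 1e-12)

    # padding with gap columns leaves the distance unchanged
    k2 <- kimura2p(paste0(a, "----"), paste0(b, "ACGT"))
    expect_equal(k2$kappa, k$kappa)
    expect_equal(k2$sites, 100)

    expect_error(kimura2p("AC", "ACG"), "equal length")
    expect_error(kimura2p("----", "ACGT"), "no ungapped")
    # saturated transitions: 2P + Q >= 1
    expect_error(kimura2p(strrep("A", 10), strrep("G", 10)), "undefined")
})

test_that("K2P is symmetric, exceeds raw divergence, and matches ape", {
    skip_if_not_installed("ape")
    set.seed(8)
    for (rep in 1:10) {
        n <- 400
        a <- randomSeq(n)
        bch <- strsplit(a, "")[[1]]
        hit <- which(stats::runif(n) < 0.15)
        bch[hit] <- vapply(bch[hit], function(x)
            sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
        b <- paste(bch, collapse = "")
        k1 <- kimura2p(a, b)
        k2 <- kimura2p(b, a)
        expect_equal(k1$kappa, k2$kappa)
        raw <- k1$P + k1$Q
        if (raw > 0) expect_gt(k1$kappa, raw)
        ref <- ape::dist.dna(ape::as.DNAbin(
            matrix(c(strsplit(tolower(a), "")[[1]],
                     strsplit(tolower(b), "")[[1]]),
                   nrow = 2, byrow = TRUE)), model = "K80")
        expect_equal(k1$kappa, as.numeric(ref), tolerance = 1e-9)
    }
})

test_that("LTR pairs are identified from direct match structure", {
    set.seed(3)
    sim <- newCentromereSim(seed = 3, flankLength = 3000,
                            satelliteCopies = 10,
                            ltrLength = 1500, internalLength = 5000)
    sim <- insertElement(sim, "CRM1", 2000, ltrDivergence = 0)
    m <- findExactMatches(simGenome(sim), minLength = 100)
    pairs <- identifyLtrPairs(m, minLtrLength = 300,
                              internalRange = c(1000, 25000))
    expect_equal(nrow(pairs), 1)
    ins <- groundTruth(sim)$insertions
    # the maximal match contains the LTR pair (it may extend a base or
    # two where the flanking context happens to agree)
    expect_lte(pairs$leftStart, ins$leftLtrStart)
    expect_gte(pairs$rightEnd, ins$rightLtrEnd)
    expect_gte(pairs$matchLength, 1500L)
    expect_lte(pairs$matchLength, 1510L)
    k <- dateLtrPair(simGenome(sim), pairs[1, ])
    expect_equal(k$kappa, 0)

    # inverted matches are never LTR pairs
    inv <- ExactMatchSet(IRanges(1, 500), IRanges(5001, 5500),
                         "inverted")
    expect_equal(nrow(identifyLtrPairs(inv, 300)), 0)

    # short periodic satellite matches fail the length filter
    sat <- makeSatelliteArray(monomerLength = 156, copies = 8,
                              divergence = 0)
    msat <- findExactMatches(sat$sequence, minLength = 100)
    expect_equal(nrow(identifyLtrPairs(msat, minLtrLength = 300,
                                       internalRange = c(1000, 25000))),
                 0)
})

test_that("LTR pairs export as GFF3 with kappa attributes", {
    path <- withr::local_tempfile(fileext = ".gff3")
    pairs <- data.frame(leftStart = 100L, leftEnd = 599L,
                        rightStart = 5600L, rightEnd = 6099L,
                        matchLength = 500L, internalStart = 600L,
                        internalEnd = 5599L, internalSpan = 5000L,
                        kappa = 0.0175)
    ltrPairsToGff3(pairs, "q", path)
    body <- grep("^[^#]", readLines(path), value = TRUE)
    expect_length(body, 1)
    expect_match(body, "kappa=0.0175")
    f <- strsplit(body, "\t")[[1]]
    expect_equal(f[4:5], c("100", "6099"))
})

test_that("age ordering is by kappa then match length", {
    pairs <- data.frame(kappa = c(0.0346, 0.0320, 0.0175, 0.0017),
                        matchLength = c(100, 100, 100, 100))
    expect_equal(ageOrder(pairs)$kappa, c(0.0017, 0.0175, 0.032, 0.0346))
    ties <- data.frame(kappa = c(0.01, 0.01), matchLength = c(50, 900))
    expect_equal(ageOrder(ties)$matchLength, c(900, 50))
    expect_equal(nrow(ageOrder(pairs[0, ])), 0)
})
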