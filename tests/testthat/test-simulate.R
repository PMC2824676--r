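test_that("satellite arrays have the right geometry and divergence", {
    sat <- makeSatelliteArray(monomerLength = 156, copies = 10,
                              divergence = 0, seed = 4)
    expect_equal(nchar(sat$sequence), 1560)
    expect_equal(nrow(sat$coords), 10)
    expect_true(all(vapply(seq_len(10), function(k)
        substr(sat$sequence, sat$coords$start[k], sat$coords$end[k]) ==
            sat$monomer, logical(1))))

    one <- makeSatelliteArray(monomerLength = 156, copies = 1,
                              divergence = 0, seed = 4)
    expect_length(findExactMatches(one$sequence, 156), 0)

    # pairwise monomer identity ~ (1 - d)^2 + cross-hits, within 3 sigma
    div <- makeSatelliteArray(monomerLength = 400, copies = 12,
                              divergence = 0.05, seed = 9)
    m1 <- strsplit(substr(div$sequence, 1, 400), "")[[1]]
    ids <- vapply(2:12, function(k) {
        mk <- strsplit(substr(div$sequence, div$coords$start[k],
                              div$coords$end[k]), "")[[1]]
        mean(m1 == mk)
    }, numeric(1))
    # each copy differs from the monomer at rate d; two mutated copies
    # agree at ~ (1-d)^2 + small back-coincidence
    expElems <- (1 - 0.05)^2 + 2 * 0.05 * 0.05 / 3
    sigma <- sqrt(expElems * (1 - expElems) / (400 * 11))
    expect_lt(abs(mean(ids) - expElems), 3 * sigma + 0.01)
})

test_that("insertion bookkeeping round-trips against the genome", {
    sim <- newCentromereSim(seed = 21, flankLength = 5000,
                            satelliteCopies = 20)
    satEnd0 <- sim@satellites$end
    sim <- insertElement(sim, "CRM1", 5600, ltrDivergence = 0)
    gt <- groundTruth(sim)
    ins <- gt$insertions
    expect_equal(nrow(ins), 1)
    # logged element sequence is exactly what sits in the genome
    g <- as.character(simGenome(sim))
    expect_identical(substr(g, ins$position, ins$position + ins$length - 1),
                     ins$elementSeq)
    # the two LTR intervals are identical at divergence 0
    expect_identical(substr(g, ins$leftLtrStart, ins$leftLtrEnd),
                     substr(g, ins$rightLtrStart, ins$rightLtrEnd))
    # two junctions logged at the element boundaries
    expect_equal(gt$junctions$position,
                 c(ins$position - 1L, ins$position + ins$length - 1L))
    # satellite array shifted right by the element length
    expect_equal(sim@satellites$end, satEnd0 + ins$length)
    # segments tile the annotated region without overlap
    sg <- gt$segments
    expect_true(all(sg$end >= sg$start))
    o <- order(sg$start)
    expect_true(all(sg$start[o][-1] > sg$end[o][-nrow(sg)]))

    expect_error(insertElement(sim, "CRM1", 10^9), "out of range")
    expect_error(insertElement(sim, "nosuch", 100), "template")
})

test_that("nested insertion splits the host LTR and its exact match", {
    sim <- newCentromereSim(seed = 33, flankLength = 4000,
                            satelliteCopies = 10)
    sim <- insertElement(sim, "CRM1", 4500, 0)   # into the satellite
    ins1 <- groundTruth(sim)$insertions[1, ]
    # insert a CRM2 into the left LTR of the CRM1
    mid <- ins1$leftLtrStart + 700L
    sim <- insertElement(sim, "CRM2", mid, 0)
    gt <- groundTruth(sim)
    expect_equal(nrow(gt$junctions), 4)
    expect_equal(gt$junctions$insertion, c(1L, 1L, 2L, 2L))
    # the CRM1 left-LTR segment is now split into two LTR pieces
    crm1Ltr <- gt$segments[gt$segments$family == "CRM1" &
                           gt$segments$part == "LTR", ]
    expect_equal(nrow(crm1Ltr), 3)
    # the full-length CRM1 LTR pair is no longer an exact match pair,
    # but the CRM2 pair is intact
    m <- findExactMatches(simGenome(sim), 300)
    pairs <- identifyLtrPairs(m, 300, c(1000, 25000))
    # (the maximal match may extend a base or two into identical context)
    ins2 <- gt$insertions[2, ]
    expect_true(any(pairs$leftStart <= ins2$leftLtrStart &
                    pairs$rightEnd >= ins2$rightLtrEnd &
                    pairs$matchLength >= 1500))
    expect_false(any(pairs$matchLength == nchar(sim@templates$CRM1$ltr) &
                     pairs$leftStart == gt$insertions$leftLtrStart[1]))
})

test_that("LTR divergence is recovered by K2P dating", {
    set.seed(61)
    sim <- newCentromereSim(seed = 61, flankLength = 4000,
                            satelliteCopies = 10)
    sim <- insertElement(sim, "CRM1", 4500, ltrDivergence = 0.02)
    ins <- groundTruth(sim)$insertions[1, ]
    k <- dateLtrPair(simGenome(sim), list(
        leftStart = ins$leftLtrStart, leftEnd = ins$leftLtrEnd,
        rightStart = ins$rightLtrStart, rightEnd = ins$rightLtrEnd))
    sigma <- sqrt(0.02 * 0.98 / 1500)
    expect_lt(abs(k$kappa - 0.02), 3 * sigma)
})

test_that("the corpus is a deterministic function of the seed", {
    s1 <- simulateCentromere(seed = 12, nInsertions = 5,
                             flankLength = 3000, satelliteCopies = 15)
    s2 <- simulateCentromere(seed = 12, nInsertions = 5,
                             flankLength = 3000, satelliteCopies = 15)
    expect_identical(as.character(simGenome(s1)),
                     as.character(simGenome(s2)))
    expect_identical(groundTruth(s1), groundTruth(s2))
    s3 <- simulateCentromere(seed = 13, nInsertions = 5,
                             flankLength = 3000, satelliteCopies = 15)
    expect_false(identical(as.character(simGenome(s1)),
                           as.character(simGenome(s3))))
})

test_that("noise-free evidence reproduces ground-truth classes", {
    dir <- withr::local_tempdir()
    sim <- simulateCentromere(seed = 44, nInsertions = 8,
                              flankLength = 5000, satelliteCopies = 30)
    ev <- emitEvidence(sim, dir, noise = 0)
    feats <- do.call(c, unname(lapply(names(ev$blast), function(f)
        readBlastTabular(ev$blast[[f]], f))))
    tr <- classifyFeatures(competeFeatures(feats, 0, "blast"))
    kept <- keptFeatures(tr)
    sg <- groundTruth(sim)$segments
    expect_equal(length(kept), nrow(sg))
    o <- order(start(kept))
    expect_equal(start(kept)[o], sg$start[order(sg$start)])
    expect_equal(kept$family[o],
                 sg$family[order(sg$start)])
    # cross_match mask evidence parses and competes cleanly too
    cm <- readCrossmatch(ev$crossmatch, "mask")
    expect_equal(length(cm), nrow(sg))
})

test_that("decoy HSPs are eliminated and enrichment bounds placements", {
    dir <- withr::local_tempdir()
    sim <- simulateCentromere(seed = 77, nInsertions = 6,
                              flankLength = 5000, satelliteCopies = 30)
    n <- length(simGenome(sim))
    ev <- emitEvidence(sim, dir, noise = 0, nDecoys = 15,
                       enrichedInterval = c(10000, 20000))
    feats <- do.call(c, unname(lapply(names(ev$blast), function(f)
        readBlastTabular(ev$blast[[f]], f))))
    tr <- competeFeatures(feats, allowance = 0, mode = "blast")
    expect_false(any(keptFeatures(tr)$db == "decoy"))
    expect_true(all(eliminatedFeatures(tr)$db == "decoy"))

    pl <- readPlacements(ev$placements)
    cov <- chartValues(buildCoverage(pl, n, "all"))
    expect_true(all(cov[seq_len(9999)] == 0))
    expect_true(all(cov[20001:n] == 0))
    expect_gt(max(cov[10000:20000]), 0)
})
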