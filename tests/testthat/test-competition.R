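test_that("longer HSPs eliminate shorter cross-database overlaps", {
    df <- data.frame(start = c(1, 301), end = c(500, 600),
                     db = c("A", "B"), score = c(500, 300))
    tr <- competeFeatures(featuresFromDf(df), allowance = 50, mode = "blast")
    expect_length(keptFeatures(tr), 1)
    expect_equal(keptFeatures(tr)$db, "A")
    expect_length(eliminatedFeatures(tr), 1)
    expect_equal(eliminatedFeatures(tr)$eliminator, 1L)

    # overlap within the allowance: both kept
    df2 <- data.frame(start = c(1, 471), end = c(500, 770),
                      db = c("A", "B"), score = c(500, 300))
    tr2 <- competeFeatures(featuresFromDf(df2), allowance = 50,
                           mode = "blast")
    expect_length(keptFeatures(tr2), 2)
})

test_that("same-database HSPs stack instead of eliminating", {
    df <- data.frame(start = c(1, 421), end = c(500, 720),
                     db = c("sat", "sat"), score = c(500, 300))
    tr <- competeFeatures(featuresFromDf(df), allowance = 50,
                          mode = "blast")
    expect_length(keptFeatures(tr), 2)

    # crossmatch mode: everything competes, shorter eliminated
    trc <- competeFeatures(featuresFromDf(df), allowance = 50,
                           mode = "crossmatch")
    expect_length(keptFeatures(trc), 1)
    expect_equal(width(keptFeatures(trc)), 500)
})

test_that("disjoint features are all kept; mixed queries are rejected", {
    df <- data.frame(start = c(1, 600, 1200), end = c(500, 1100, 1700),
                     db = c("A", "B", "A"), score = c(1, 2, 3))
    tr <- competeFeatures(featuresFromDf(df), allowance = 0,
                          mode = "blast")
    expect_length(keptFeatures(tr), 3)
    expect_length(eliminatedFeatures(tr), 0)

    mixed <- suppressWarnings(
        c(featuresFromDf(df[1, ], "q1"), featuresFromDf(df[2, ], "q2")))
    expect_error(competeFeatures(mixed), "mix query ids")
})

test_that("competition matches the brute-force ranked sweep", {
    set.seed(23)
    for (rep in 1:60) {
        df <- randomFeatureSet(sample(1:50, 1))
        allowance <- sample(c(0, 25, 100), 1)
        mode <- sample(c("blast", "crossmatch"), 1)
        tr <- competeFeatures(featuresFromDf(df), allowance, mode)
        keptIdx <- bruteCompete(df, allowance, mode)
        gotKeys <- sort(paste(start(keptFeatures(tr)),
                              end(keptFeatures(tr)),
                              keptFeatures(tr)$db))
        wantKeys <- sort(paste(df$start[keptIdx], df$end[keptIdx],
                               df$db[keptIdx]))
        expect_identical(gotKeys, wantKeys)
        expect_silent(checkCompetitionInvariant(tr))
        # every input feature lands in exactly one of kept/eliminated
        expect_equal(length(keptFeatures(tr)) +
                     length(eliminatedFeatures(tr)), nrow(df))
    }
})

test_that("competition is idempotent; a saturating allowance keeps all", {
    set.seed(77)
    for (rep in 1:20) {
        df <- randomFeatureSet(40)
        tr <- competeFeatures(featuresFromDf(df), 25, "blast")
        again <- competeFeatures(keptFeatures(tr), 25, "blast")
        expect_equal(length(keptFeatures(again)),
                     length(keptFeatures(tr)))
        expect_length(eliminatedFeatures(again), 0)

        # an allowance at least the longest feature disables elimination
        full <- competeFeatures(featuresFromDf(df),
                                max(df$end - df$start + 1), "crossmatch")
        expect_length(keptFeatures(full), nrow(df))
    }
})

test_that("classification maps subjects, subranges and unknowns", {
    df <- data.frame(start = c(1, 600, 1200), end = c(500, 1100, 1700),
                     db = "crm", score = 1)
    gr <- featuresFromDf(df)
    gr$subject <- c("CRM2#LTR", "CRM1full", "mystery")
    gr$sStart <- c(1L, 100L, 1L)
    gr$sEnd <- c(400L, 1200L, 50L)
    tr <- methods::new("CompetedTrack", query = "q", kept = gr,
        eliminated = RepeatJunctions:::.emptyFeatures(),
        params = list(allowance = 0L, mode = "blast", dbPriority = NULL))
    sub <- data.frame(subject = "CRM1full", start = 1, end = 1500,
                      family = "CRM1", part = "LTR")
    out <- keptFeatures(classifyFeatures(tr, subranges = sub))
    expect_equal(out$repeatClass,
                 c("CRM2/LTR", "CRM1/LTR", "other"))
    expect_equal(out$family, c("CRM2", "CRM1", "other"))
})

test_that("elimination audit records eliminator and overlap", {
    df <- data.frame(start = c(1, 301), end = c(500, 600),
                     db = c("A", "B"), score = c(500, 300))
    tr <- competeFeatures(featuresFromDf(df), allowance = 0, mode = "blast")
    audit <- eliminationAudit(tr)
    expect_equal(nrow(audit), 1)
    expect_equal(audit$overlap, 200L)
    expect_equal(audit$eliminatorDb, "A")
})
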