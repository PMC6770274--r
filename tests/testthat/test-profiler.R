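test_that("fragment extraction reconstructs template intervals", {
    # mates at 1-based 100 and 200, read length 50: fragment [99, 250)
    idx <- demoIndex()
    sam <- writeRawSam(c(
        "t1\t99\tgraft_chr1\t100\t60\t50M\t=\t200\t151\t*\t*",
        "t1\t147\tgraft_chr1\t200\t60\t50M\t=\t100\t-151\t*\t*"), idx)
    fr <- extractFragments(sam, idx)
    expect_length(fr, 1L)
    expect_identical(GenomicRanges::start(fr), 100L)
    expect_identical(GenomicRanges::end(fr), 250L)
    expect_identical(GenomicRanges::width(fr), 151L)
    expect_identical(fr$genome, "graft")
    expect_identical(fr$compartment, "nuclear")
})

test_that("orphan and low-quality records are skipped with counters", {
    idx <- demoIndex()
    sam <- writeRawSam(c(
        "orphan\t0\tgraft_chr1\t500\t60\t50M\t*\t0\t0\t*\t*",
        "low\t99\thost_chr1\t100\t5\t50M\t=\t200\t151\t*\t*",
        "low\t147\thost_chr1\t200\t5\t50M\t=\t100\t-151\t*\t*"), idx)
    fr <- extractFragments(sam, idx, minMapq = 20)
    expect_length(fr, 0L)
    sk <- S4Vectors::metadata(fr)$skipped
    expect_identical(unname(sk["unpaired"]), 1L)
    expect_identical(unname(sk["lowMapq"]), 1L)
})

test_that("size profiles report exact counts, mode, tie rule and mean", {
    p <- profileFromCounts(c("166" = 100, "144" = 80))
    expect_identical(nFragments(p), 180L)
    expect_equal(modalLength(p), 166)
    expect_equal(meanLength(profileFromCounts(c("100" = 1, "200" = 1))), 150)
    # tie resolves to the smaller length
    expect_equal(modalLength(profileFromCounts(c("169" = 5, "144" = 5))), 144)
    expect_equal(modalLength(profileFromCounts(c("169" = 6, "144" = 5))), 169)
    # all-equal lengths: mean is that length
    expect_equal(meanLength(profileFromCounts(c("120" = 7))), 120)
    # empty profile is flagged undefined
    empty <- sizeHistogramFromLengths(integer(0))
    expect_identical(nFragments(empty), 0L)
    expect_true(is.na(modalLength(empty)))
    expect_true(is.na(meanLength(empty)))
    # windowed mean restricts the support
    pw <- profileFromCounts(c("100" = 1, "200" = 1, "900" = 2))
    expect_equal(meanLength(pw, window = c(30, 500)), 150)
})

test_that("periodicity detection recovers constructed comb spacings", {
    lens <- 30:1000
    mkComb <- function(step) {
        y <- rep(100, length(lens))
        for (p in seq(53, 150, by = step))
            y <- y + 300 * exp(-0.5 * ((lens - p) / 1.5)^2)
        sizeHistogramFromLengths(rep(lens, times = as.integer(round(y))))
    }
    r106 <- detectPeriodicity(mkComb(10.6))
    expect_true(r106@ok)
    expect_lt(abs(r106@period - 10.6), 0.1 + 1e-9)
    r10 <- detectPeriodicity(mkComb(10))
    expect_lt(abs(r10@period - 10.0), 0.1 + 1e-9)

    # sparse region is flagged, not guessed
    sparse <- sizeHistogramFromLengths(rep(c(60L, 80L, 100L), 5))
    expect_false(detectPeriodicity(sparse)@ok)
})

test_that("fractional-lag search agrees with integer-lag brute force on integer periods", {
    lens <- 30:1000
    for (step in c(9, 10, 12, 13)) {
        y <- rep(50, length(lens))
        for (p in seq(52, 150, by = step))
            y <- y + 400 * exp(-0.5 * ((lens - p) / 1.5)^2)
        prof <- sizeHistogramFromLengths(rep(lens, times = as.integer(y)))
        det <- detectPeriodicity(prof)
        # brute force: integer-lag normalized autocorrelation of the
        # log-detrended region signal
        sel <- lens >= 50 & lens <= 150
        d <- log1p(y[sel]) -
            as.numeric(stats::filter(log1p(y[sel]), rep(1 / 21, 21), sides = 2))
        d <- d[!is.na(d)]
        ac <- vapply(8:14, function(k) {
            a <- d[seq_len(length(d) - k)]; b <- d[-seq_len(k)]
            sum(a * b) / sqrt(sum(a^2) * sum(b^2))
        }, numeric(1))
        expect_lt(abs(det@period - (8:14)[which.max(ac)]), 0.11)
    }
})

test_that("simulated tumor ladder yields its 10.6 bp period and 144 bp mode", {
    m <- fragmentLengthModel("nucleosomal_ladder", modalLength = 144,
                             modalSd = 3, ladderPeriod = 10.6,
                             ladderMin = 50, ladderWeight = 0.3)
    set.seed(1)
    prof <- sizeHistogramFromLengths(drawFragmentLengths(m, 1e5))
    expect_lte(abs(modalLength(prof) - 144), 1)
    per <- detectPeriodicity(prof)
    expect_true(per@ok)
    expect_lt(abs(per@period - 10.6), 0.3)
})

test_that("mt abundance normalization is a plain per-genome ratio", {
    expect_equal(normalizedMtAbundance(0, 1000), 0)
    expect_equal(normalizedMtAbundance(10, 1000), 0.01)
    expect_error(normalizedMtAbundance(5, 0), "> 0")
    # subsampling stability: halving fragments moves the ratio by less
    # than 3 binomial SEs
    set.seed(31)
    mt <- 2000L; nuc <- 40000L
    r0 <- normalizedMtAbundance(mt, nuc)
    mtSub <- rbinom(1, mt, 0.5); nucSub <- rbinom(1, nuc, 0.5)
    r1 <- normalizedMtAbundance(mtSub, nucSub)
    se <- r0 * sqrt(1 / (mt * 0.5) + 1 / (nuc * 0.5))
    expect_lt(abs(r1 - r0), 3 * se)
})

test_that("mixing in a shorter component strictly lowers the mean", {
    base <- rep(169L, 5000)
    short <- rep(144L, 1000)
    expect_lt(meanLength(sizeHistogramFromLengths(c(base, short))),
              meanLength(sizeHistogramFromLengths(base)))
    set.seed(32)
    g <- drawFragmentLengths(fragmentLengthModel("gamma", meanLength = 143), 5000)
    s <- drawFragmentLengths(fragmentLengthModel("gamma", meanLength = 109), 2000)
    expect_lt(meanLength(sizeHistogramFromLengths(c(g, s))),
              meanLength(sizeHistogramFromLengths(g)))
})

test_that("graft mito fragments are shorter than host mito fragments", {
    gm <- fragmentLengthModel("gamma", meanLength = 109, shape = 8)
    hm <- fragmentLengthModel("gamma", meanLength = 143, shape = 8)
    for (s in 1:5) {
        set.seed(s)
        expect_lt(mean(drawFragmentLengths(gm, 1e4)),
                  mean(drawFragmentLengths(hm, 1e4)))
    }
})

test_that("per-group profile totals conserve the non-ambiguous fragment count", {
    cfg <- smallDemoConfig(seed = 33, nNuclear = 4000)
    idx <- demoIndex(cfg)
    sim <- simulateFragments(cfg)
    sam <- tempfile(fileext = ".sam")
    emitAlignments(sim$fragments, idx, sam)
    fr <- extractFragments(sam, idx, minMapq = 0)
    groups <- expand.grid(g = c("graft", "host"), c = c("nuclear", "mito"),
                          stringsAsFactors = FALSE)
    tot <- sum(vapply(seq_len(nrow(groups)), function(i)
        nFragments(sizeHistogram(fr, groups$g[i], groups$c[i])), integer(1)))
    expect_identical(tot, sum(fr$genome != "ambiguous"))
})
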