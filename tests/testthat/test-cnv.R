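test_that("tiling drops trailing partial bins and enforces width", {
    b <- tileBins(c(chrA = 12000))
    expect_length(b, 2L)
    expect_identical(GenomicRanges::start(b), c(1L, 5001L))
    expect_true(all(GenomicRanges::width(b) == 5000L))
    expect_length(tileBins(c(chrA = 4999)), 0L)
    expect_length(tileBins(c(chrA = 1e6)), 200L)
    expect_error(tileBins(c(chrA = 1e4), width = 0), "> 0")
})

test_that("fragments are assigned to the bin holding their midpoint", {
    bins <- tileBins(c(chrA = 20000))
    # 0-based [4990, 5010): midpoint 5000 -> second bin
    fr <- GenomicRanges::GRanges("chrA", IRanges::IRanges(4991, 5010))
    counted <- countFragmentsInBins(fr, bins)
    expect_identical(counted$count, c(0L, 1L, 0L, 0L))

    empty <- countFragmentsInBins(GenomicRanges::GRanges(), bins)
    expect_true(all(empty$count == 0L))

    off <- GenomicRanges::GRanges("chrA", IRanges::IRanges(19990, 20100))
    suppressWarnings(GenomeInfoDb::seqlengths(off) <- c(chrA = 20000))
    expect_error(countFragmentsInBins(off, bins), "outside contig")
})

test_that("uniform placement gives Poisson-consistent bin counts", {
    cfg <- smallDemoConfig(seed = 51, nNuclear = 1e5, tumorFraction = 0)
    cfg@cnvRegion <- list()
    sim <- simulateFragments(cfg)
    hn <- sim$fragments[sim$fragments$genome == "host" &
                        sim$fragments$compartment == "nuclear"]
    bins <- countFragmentsInBins(hn, tileBins(c(host_chr1 = 2e6)))
    lambda <- sum(bins$count) / length(bins)
    env <- qpois(c(5e-5, 1 - 5e-5), lambda)
    expect_true(all(bins$count >= env[1] & bins$count <= env[2]))
})

test_that("gain test matches the hand-enumerated 1/84 toy exactly", {
    bins <- tileBins(c(chrA = 45000))
    bins$count <- c(5L, 6L, 4L, 10L, 12L, 11L, 5L, 6L, 5L)
    res <- mannWhitneyGain(bins, "chrA:15001-30000")
    expect_identical(res@method, "exact")
    expect_equal(res@U, 18)
    expect_equal(res@pValue, 1 / 84)
    # independent oracle: full enumeration over C(9, 3) assignments
    expect_equal(res@pValue,
                 permutationGainP(c(10, 12, 11), c(5, 6, 4, 5, 6, 5)))
})

test_that("identical constant counts give p = 1", {
    bins <- tileBins(c(chrA = 45000))
    bins$count <- rep(7L, 9L)
    res <- mannWhitneyGain(bins, "chrA:15001-30000")
    expect_equal(res@pValue, 1)
})

test_that("permutation p agrees with the exact U-distribution tail when tie-free", {
    set.seed(52)
    for (rep in 1:10) {
        m <- sample(3:5, 1); n <- sample(3:6, 1)
        vals <- sample(1:100, m + n)
        x <- vals[1:m]; y <- vals[-(1:m)]
        U <- sum(outer(x, y, ">"))
        expect_equal(permutationGainP(x, y),
                     cfFragmentomics:::exactUTailP(U, m, n))
    }
})

test_that("normal approximation tracks the exact tail within 0.01", {
    # no-tie sweep over the one-sided gain tail, all m, n >= 3 with
    # m * n <= 400
    worst <- 0
    for (m in 3:20) for (n in 3:20) {
        if (m * n > 400) next
        for (U in ceiling(m * n / 2):(m * n)) {
            d <- abs(cfFragmentomics:::exactUTailP(U, m, n) -
                     cfFragmentomics:::normalUTailP(U, m, n))
            worst <- max(worst, d)
        }
    }
    expect_lt(worst, 0.01)
})

test_that("fold-2 gain over twenty bins is detected", {
    cfg <- smallDemoConfig(seed = 53, nNuclear = 1e5, tumorFraction = 1)
    sim <- simulateFragments(cfg)
    gn <- sim$fragments[sim$fragments$genome == "graft" &
                        sim$fragments$compartment == "nuclear"]
    bins <- countFragmentsInBins(gn, tileBins(c(graft_chr1 = 2e6)))
    res <- mannWhitneyGain(bins, "graft_chr1:1000001-1100000",
                           flankBinsPerSide = 20)
    expect_identical(res@nRegionBins, 20L)
    expect_identical(res@nFlankBins, 40L)
    expect_lt(res@pValue, 0.05)
})
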