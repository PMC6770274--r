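test_that("tumor fraction controls the graft share of nuclear fragments", {
    cfg0 <- smallDemoConfig(seed = 3, nNuclear = 2000, tumorFraction = 0)
    sim0 <- simulateFragments(cfg0)
    nuc0 <- sim0$fragments[sim0$fragments$compartment == "nuclear"]
    expect_identical(sum(nuc0$genome == "graft"), 0L)

    cfg5 <- smallDemoConfig(seed = 4, nNuclear = 2e5, tumorFraction = 0.5)
    sim5 <- simulateFragments(cfg5)
    nuc5 <- sim5$fragments[sim5$fragments$compartment == "nuclear"]
    share <- mean(nuc5$genome == "graft")
    expect_lt(abs(share - 0.5), 0.005)
})

test_that("fragment counts are conserved and truth mirrors the config", {
    cfg <- smallDemoConfig(seed = 6, nNuclear = 3000)
    sim <- simulateFragments(cfg)
    expect_length(sim$fragments, 3000 + 3000 + 1500)
    ct <- sim$truth$counts
    expect_identical(ct$nuclearGraft + ct$nuclearHost, 3000L)
    expect_identical(ct$mitoGraft, 3000L)
    expect_identical(ct$mitoHost, 1500L)
    expect_equal(sim$truth$expectedVaf, cfg@tumorFraction / 2)
    tab <- table(sim$fragments$genome, sim$fragments$compartment)
    expect_equal(unname(tab["graft", "mito"]), 3000)
    expect_equal(unname(tab["host", "mito"]), 1500)
})

test_that("invalid tumor fractions are rejected", {
    expect_error(smallDemoConfig(tumorFraction = 1.5), "\\[0, 1\\]")
    expect_error(smallDemoConfig(tumorFraction = -0.1), "\\[0, 1\\]")
})

test_that("copy-gain region doubles in-region bin intensity (fold = 2)", {
    cfg <- smallDemoConfig(seed = 8, nNuclear = 1e5, tumorFraction = 1)
    sim <- simulateFragments(cfg)
    gn <- sim$fragments[sim$fragments$genome == "graft" &
                        sim$fragments$compartment == "nuclear"]
    bins <- countFragmentsInBins(gn, tileBins(c(graft_chr1 = 2e6)))
    reg <- cfg@cnvRegion
    inReg <- GenomicRanges::start(bins) > reg$start &
        GenomicRanges::end(bins) <= reg$end
    ratio <- mean(bins$count[inReg]) / mean(bins$count[!inReg])
    # Poisson oracle: expected ratio exactly 2; relative SE of each mean
    # at these counts keeps the ratio within ~10%
    expect_lt(abs(ratio - 2), 0.2)
})

test_that("simulation outputs are byte-identical under config + seed", {
    cfg <- smallDemoConfig(seed = 9, nNuclear = 1500)
    idx <- demoIndex(cfg)
    paths <- replicate(2, {
        sim <- simulateFragments(cfg)
        sam <- tempfile(fileext = ".sam")
        emitAlignments(sim$fragments, idx, sam)
        tsv <- tempfile(fileext = ".tsv")
        vcf <- tempfile(fileext = ".vcf")
        emitVariantPileups(cfg, tsv, vcf)
        c(sam = sam, tsv = tsv, vcf = vcf)
    })
    for (k in rownames(paths))
        expect_identical(unname(tools::md5sum(paths[k, 1])),
                         unname(tools::md5sum(paths[k, 2])))
})

test_that("pileups follow the heterozygous binomial model", {
    # theta = 0, no error: every alternate count is zero
    cfg0 <- smallDemoConfig(seed = 10, nNuclear = 0, tumorFraction = 0)
    pu0 <- emitVariantPileups(cfg0)
    expect_true(all(pu0$alt_count == 0))
    expect_true(all(!pu0$normal))

    # demo regime: pooled VAF near theta / 2 = 0.048
    cfg <- smallDemoConfig(seed = 11, nNuclear = 0)
    pu <- emitVariantPileups(cfg)
    pooled <- sum(pu$alt_count) / sum(pu$alt_count + pu$ref_count)
    expect_lt(abs(pooled - 0.048), 0.004)
})

test_that("truth VCF round-trips through the variant reader", {
    cfg <- smallDemoConfig(seed = 12, nNuclear = 0)
    vcf <- tempfile(fileext = ".vcf")
    emitVariantPileups(cfg, NULL, vcf)
    sites <- readSitesVcf(vcf)
    expect_identical(sites$contig, cfg@snvSites$contig)
    expect_identical(sites$pos, as.integer(cfg@snvSites$pos))
    expect_identical(sites$ref, cfg@snvSites$ref)
    expect_identical(sites$alt, cfg@snvSites$alt)
})
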