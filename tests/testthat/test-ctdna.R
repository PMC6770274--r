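mkSites <- function(vafs, depth = 1000) {
    alt <- round(vafs * depth)
    data.frame(contig = "graft_chr1", pos = seq_along(vafs),
               ref = "A", alt = "T",
               ref_count = depth - alt, alt_count = alt,
               primary = TRUE, met1 = FALSE, met2 = FALSE,
               cfdna = alt > 0, normal = FALSE)
}

test_that("tumor-specific site selection applies all three filters", {
    sites <- mkSites(c(0.05, 0.05, 0.05))
    sites$normal[1] <- TRUE                        # germline-contaminated
    sites$alt_count[2] <- 1L                       # below min_alt
    sites$primary[3] <- FALSE; sites$met1[3] <- TRUE  # met-only is fine
    kept <- selectTumorSpecificSites(sites, minDepth = 10, minAlt = 2)
    expect_identical(kept$pos, 3L)

    lowDepth <- mkSites(0.5, depth = 8)
    expect_identical(nrow(selectTumorSpecificSites(lowDepth)), 0L)
})

test_that("site VAF is the alternate fraction of the pileup depth", {
    expect_equal(computeSiteVaf(95, 5), 0.05)
    expect_equal(computeSiteVaf(0, 10), 1)
    expect_equal(computeSiteVaf(9520, 480), 0.048)
    expect_error(computeSiteVaf(0, 0), "zero depth")
})

test_that("ctDNA fraction is twice the mean VAF, capped at one", {
    # the heterozygous worked example: mean VAF 4.80% -> fraction 9.6%
    est <- estimateCtdnaFraction(mkSites(rep(0.048, 28), depth = 10000),
                                 nBootstrap = 100, seed = 1)
    expect_equal(ctdnaFraction(est), 0.096)
    expect_equal(meanVaf(est), 0.048)

    expect_equal(ctdnaFraction(
        estimateCtdnaFraction(mkSites(rep(0, 5)), nBootstrap = 10, seed = 1)), 0)
    est3 <- estimateCtdnaFraction(mkSites(c(0.1, 0.2, 0.3)),
                                  nBootstrap = 10, seed = 1)
    expect_equal(meanVaf(est3), 0.2)
    expect_equal(ctdnaFraction(est3), 0.4)
    # cap at 1 for VAFs above 0.5
    estHi <- estimateCtdnaFraction(mkSites(c(0.6, 0.7)),
                                   nBootstrap = 10, seed = 1)
    expect_equal(ctdnaFraction(estHi), 1)
    expect_error(
        estimateCtdnaFraction(data.frame(ref_count = numeric(0),
                                         alt_count = numeric(0))),
        "at least one")

    # identity property: homogeneous VAF v gives exactly 2v
    for (v in c(0.01, 0.123, 0.25)) {
        e <- estimateCtdnaFraction(mkSites(rep(v, 7)), nBootstrap = 10,
                                   seed = 2)
        expect_equal(ctdnaFraction(e), 2 * v)
    }
})

test_that("estimator is unbiased across tumor fractions", {
    for (theta in c(0.02, 0.05, 0.1, 0.3)) {
        set.seed(round(1000 * theta))
        ests <- vapply(seq_len(200), function(i) {
            alt <- rbinom(28, 1000, theta / 2)
            sites <- data.frame(ref_count = 1000 - alt, alt_count = alt)
            min(1, 2 * mean(computeSiteVaf(sites$ref_count, sites$alt_count)))
        }, numeric(1))
        expect_lt(abs(mean(ests) - theta), 0.01)
    }
})

test_that("bootstrap CI covers the truth at near-nominal rate", {
    theta <- 0.1
    set.seed(99)
    covered <- vapply(seq_len(100), function(i) {
        alt <- rbinom(28, 1000, theta / 2)
        est <- estimateCtdnaFraction(
            data.frame(ref_count = 1000 - alt, alt_count = alt),
            nBootstrap = 500)
        ci <- ctdnaCI(est)
        ci[["lo"]] <= theta && theta <= ci[["hi"]]
    }, logical(1))
    expect_gte(mean(covered), 0.90)
})

test_that("simulated truth sites are recovered by the selection filter", {
    recovered <- vapply(1:20, function(s) {
        cfg <- demoSimulationConfig(seed = s, nNuclear = 0,
                                    tumorFraction = 0.1, snvDepth = 1000)
        pu <- emitVariantPileups(cfg)
        nrow(selectTumorSpecificSites(pu, minDepth = 10, minAlt = 2))
    }, numeric(1))
    expect_true(all(recovered >= 27))
})

test_that("mutation overlap counts and Jaccard indices are exact", {
    key <- function(p) data.frame(contig = "c", pos = p, ref = "A", alt = "T")
    ov <- mutationOverlap(list(met1 = key(1:3), met2 = key(1:3)))
    expect_equal(ov$jaccard, 1)
    ov0 <- mutationOverlap(list(a = key(1:3), b = key(4:6)))
    expect_equal(ov0$shared, 0)
    expect_equal(ov0$jaccard, 0)
    ovH <- mutationOverlap(list(a = key(1:3), b = key(2:4)))
    expect_equal(ovH$shared, 2)
    expect_equal(ovH$jaccard, 0.5)
    # shared count bounded by the smaller set
    expect_lte(ovH$shared, min(ovH$nA, ovH$nB))
    expect_error(mutationOverlap(list(only = key(1))), "two tissues")
})
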