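test_that("Welch test matches closed-form arithmetic", {
    same <- welchTTest(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same@statistic, 0)
    expect_equal(same@pValue, 1)

    r <- welchTTest(c(1, 2, 3), c(4, 5, 6))
    # closed form: t = (2 - 5) / sqrt(1/3 + 1/3), Welch-Satterthwaite df
    se2 <- var(c(1, 2, 3)) / 3 + var(c(4, 5, 6)) / 3
    tOracle <- (2 - 5) / sqrt(se2)
    dfOracle <- se2^2 / ((var(c(1, 2, 3)) / 3)^2 / 2 +
                         (var(c(4, 5, 6)) / 3)^2 / 2)
    expect_equal(r@statistic, tOracle, tolerance = 1e-12)
    expect_equal(r@statistic, -3.674, tolerance = 1e-3)
    expect_equal(r@df, dfOracle)
    expect_equal(r@df, 4)
    expect_equal(r@pValue, 2 * pt(tOracle, dfOracle), tolerance = 1e-12)
    expect_equal(r@pValue, 0.0213, tolerance = 1e-2)

    # symmetry up to the sign of t
    rBA <- welchTTest(c(4, 5, 6), c(1, 2, 3))
    expect_equal(rBA@statistic, -r@statistic)
    expect_equal(rBA@pValue, r@pValue)

    expect_error(welchTTest(1, c(1, 2)), "at least two")
    degenerate <- welchTTest(c(2, 2, 2), c(2, 2, 2))
    expect_false(degenerate@ok)
})

test_that("cancer-vs-healthy mt-length contrast has power at cohort scale", {
    hits <- sum(vapply(1:20, function(s) {
        set.seed(s)
        a <- rnorm(46, 109.15, 15)  # cancer patients
        b <- rnorm(4, 142.62, 10)   # healthy controls
        welchTTest(a, b)@pValue < 0.05
    }, logical(1)))
    expect_gte(hits, 18)
})

test_that("Pearson correlation handles exact and noisy linear relations", {
    expect_equal(pearsonCorrelation(1:3, c(2, 4, 6))@r, 1)
    expect_equal(pearsonCorrelation(1:3, c(3, 2, 1))@r, -1)
    expect_error(pearsonCorrelation(1:3, c(5, 5, 5)), "zero variance")
    expect_error(pearsonCorrelation(1:2, 1:2), "three complete")

    # affine invariance of |r|
    set.seed(61)
    x <- rnorm(20); y <- 2 * x + rnorm(20, 0, 0.5)
    r0 <- pearsonCorrelation(x, y)@r
    expect_equal(pearsonCorrelation(10 * x + 3, y)@r, r0)

    for (s in 1:20) {
        set.seed(s)
        x <- runif(16, 0, 10)
        y <- -2 * x + rnorm(16)
        res <- pearsonCorrelation(x, y)
        expect_lt(res@r, -0.9)
        expect_lt(res@pValue, 0.05)
    }
})

test_that("ctDNA dichotomization splits strictly at the threshold", {
    tiny <- data.frame(ctdna_percent = c(4, 6),
                       mean_mt_length = c(160, 150))
    d <- dichotomizeByCtdna(tiny)
    expect_identical(nrow(d$high), 1L)
    expect_identical(nrow(d$low), 1L)
    expect_null(d$comparison)

    allLow <- data.frame(ctdna_percent = c(1, 2, 3),
                         mean_mt_length = c(160, 161, 162))
    dl <- dichotomizeByCtdna(allLow)
    expect_identical(nrow(dl$high), 0L)
    expect_null(dl$comparison)

    # boundary: exactly 5% goes to the low group
    dEdge <- dichotomizeByCtdna(data.frame(ctdna_percent = c(5, 5.01),
                                           mean_mt_length = c(1, 2)))
    expect_identical(nrow(dEdge$high), 1L)
    expect_equal(dEdge$high$ctdna_percent, 5.01)
})

test_that("high-ctDNA samples show shorter mt-cfDNA with power", {
    hits <- sum(vapply(1:20, function(s) {
        set.seed(s)
        co <- data.frame(
            ctdna_percent = rep(c(8, 2), each = 8),
            mean_mt_length = c(rnorm(8, 153.62, 6), rnorm(8, 164.36, 6)))
        d <- dichotomizeByCtdna(co)
        d$comparison@meanA < d$comparison@meanB &&
            d$comparison@pValue < 0.05
    }, logical(1)))
    expect_gte(hits, 18)
})

test_that("longitudinal tracking records per-interval directions and reversal", {
    s <- trackPatient(data.frame(patient_id = "P5", timepoint = 1:4,
                                 mean_mt_length = c(150, 160, 140, 130)))
    expect_identical(s@directions, c(1L, -1L, -1L))
    expect_true(s@reversal)

    mono <- trackPatient(data.frame(timepoint = 1:4,
                                    mean_mt_length = c(150, 152, 155, 160)))
    expect_false(mono@reversal)

    expect_error(trackPatient(data.frame(timepoint = c(1, 1),
                                         mean_mt_length = c(1, 2))),
                 "duplicate timepoint")

    # epsilon noise on a constant series: directions are the noise signs
    set.seed(62)
    eps <- rnorm(3, 0, 1e-3)
    vals <- 150 + c(0, cumsum(eps))
    sN <- trackPatient(data.frame(timepoint = 1:4, mean_mt_length = vals))
    expect_identical(sN@directions, as.integer(sign(eps)))
})

test_that("simulated cohorts link shorter mt-cfDNA to tumor burden", {
    hits <- sum(vapply(1:10, function(s) {
        co <- simulateCohort(seed = s)
        res <- pearsonCorrelation(co$tumor_size, co$mean_mt_length,
                                  c("tumor_size", "mean_mt_length"))
        res@r < 0 && res@pValue < 0.05
    }, logical(1)))
    expect_gte(hits, 9)

    co <- simulateCohort(seed = 1)
    expect_identical(nrow(co), 48L)
    # a quarter of cancer samples lack ctDNA percentage; the correlation
    # still works pairwise-complete
    expect_identical(sum(is.na(co$ctdna_percent[co$group == "cancer"])), 4L)
    res <- pearsonCorrelation(co$ctdna_percent, co$mean_mt_length)
    expect_identical(res@n, 12L)
})
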