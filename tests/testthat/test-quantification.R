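test_that("occupancy pmf reproduces the digital single-cell fractions", {
    p <- occupancyPmf(1)
    expect_identical(round(100 * p@p0), 37)
    expect_identical(round(100 * p@pGe1), 63)
    expect_identical(round(100 * p@pGe2), 26)

    p0 <- occupancyPmf(0)
    expect_equal(p0@p0, 1)
    expect_equal(p0@pGe1, 0)
    expect_equal(p0@pGe2, 0)

    for (lam in c(0.01, 0.3, 1, 2.7, 10)) {
        p <- occupancyPmf(lam)
        expect_lt(abs(p@p0 + p@p1 + p@pGe2 - 1), 1e-12)
        expect_lt(abs(p@pGe1 - (1 - p@p0)), 1e-12)
    }
    expect_error(occupancyPmf(-1), ">= 0")
})

test_that("lambda from the negative fraction matches the closed form", {
    expect_identical(lambdaFromNegativeFraction(100, 100), 0)
    ## frozen high-precision value for 3679 negatives of 10000
    expect_equal(lambdaFromNegativeFraction(3679, 10000),
                 0.999944116871408, tolerance = 1e-12)
    expect_error(lambdaFromNegativeFraction(0, 7000), "8.85")

    ## round trip with the pmf across the p0 range
    for (p0 in c(0.01, 0.2, 0.5, 0.9, 0.99)) {
        lam <- lambdaFromNegativeFraction(round(1e6 * p0), 1e6)
        expect_lt(abs(occupancyPmf(lam)@p0 - p0), 1e-10)
    }
})

test_that("concentration estimates, CIs and volume scaling behave", {
    res <- concentrationWithCI(3679, 10000, 2.8)
    expect_equal(concentration(res), 1000 * 0.999944116871408 / 2.8,
                 tolerance = 1e-9)
    expect_true(ci95(res)[1] < concentration(res) &&
                concentration(res) < ci95(res)[2])

    ## all-negative run: concentration 0 with a zero lower bound
    res0 <- concentrationWithCI(500, 500, 2.8)
    expect_equal(concentration(res0), 0)
    expect_equal(ci95(res0)[1], 0)

    ## linear in 1 / partitionVolume (exact)
    r1 <- concentrationWithCI(4000, 9000, 2.8)
    r2 <- concentrationWithCI(4000, 9000, 1.4)
    expect_equal(concentration(r2), 2 * concentration(r1), tolerance = 1e-12)
    expect_equal(ci95(r2), 2 * ci95(r1), tolerance = 1e-12)

    ## bootstrap alternative honours the same contract
    rb <- concentrationWithCI(4000, 9000, 2.8, ciMethod = "bootstrap",
                              seed = 5)
    expect_equal(concentration(rb), concentration(r1))
    expect_true(ci95(rb)[1] < concentration(rb) &&
                concentration(rb) < ci95(rb)[2])
})

test_that("lambda estimator is nearly unbiased at realistic partition counts", {
    for (lam in c(0.1, 0.5, 1, 3)) {
        lamHat <- vapply(1:120, function(s) {
            k <- simulatePartitions(1000 * lam / 2.8, 2.8, 7000,
                                    seed = 10000 * lam + s)
            lambdaFromNegativeFraction(sum(k == 0), length(k))
        }, numeric(1))
        expect_lt(abs(mean(lamHat) - lam) / lam, 0.02)
    }
})

test_that("sphere volume and partition arithmetic match the closed forms", {
    expect_equal(volumeFromDiameter(175), 2.80616218797213, tolerance = 1e-12)
    expect_equal(round(volumeFromDiameter(175), 1), 2.8)
    expect_identical(volumeFromDiameter(0), 0)
    expect_equal(volumeFromDiameter(100), 0.5235988, tolerance = 1e-6)
    expect_error(volumeFromDiameter(-5), ">= 0")

    expect_identical(theoreticalPartitionCount(20, 2.806), 7127L)
    expect_gte(theoreticalPartitionCount(20, 2.806), 7000L)
    expect_identical(theoreticalPartitionCount(1, 1), 1000L)
    expect_identical(theoreticalPartitionCount(20, 2.8), 7142L)
})

test_that("dynamic range bounds are ordered, monotone in n, and scale with volume", {
    dr <- dynamicRange(7000, 2.8)
    expect_true(dr@lod <= dr@lowerQuant && dr@lowerQuant < dr@upperQuant)
    ## upper bound on the order of 1e3 copies/uL for the standard design
    expect_gt(dr@upperQuant, 1e3)
    expect_lt(dr@upperQuant, 1e4)

    dr2 <- dynamicRange(14000, 2.8)
    expect_gt(dr2@upperQuant, dr@upperQuant)
    expect_lt(dr2@lod, dr@lod)

    ## halving the diameter (volume / 8) multiplies the upper bound by 8
    dr8 <- dynamicRange(7000, 2.8 / 8)
    expect_equal(dr8@upperQuant, 8 * dr@upperQuant, tolerance = 1e-9)

    for (n in c(100L, 1000L, 20000L)) for (v in c(0.5, 2.8, 10)) {
        d <- dynamicRange(n, v)
        expect_true(d@lod <= d@lowerQuant && d@lowerQuant < d@upperQuant)
    }
})

test_that("occupancy goodness of fit pools tails and calibrates under the null", {
    ## observed matching expectation (to integer rounding) -> chi2 near 0
    lam <- 1; n <- 1000
    expv <- n * dpois(0:5, lam); expv[6] <- n * (1 - ppois(4, lam))
    g <- occupancyGoodnessOfFit(round(expv), lam = lam)
    expect_lt(g$chi2, 0.1)
    expect_gt(g$p_value, 0.99)
    expect_true(all(g$expected >= 1))

    ## null calibration: Poisson data rarely rejected
    pvals <- vapply(1:100, function(s) {
        k <- withr::with_seed(s, rpois(10000, 1))
        occupancyGoodnessOfFit(tabulate(k + 1L, nbins = max(k) + 1L))$p_value
    }, numeric(1))
    expect_gte(mean(pvals > 0.01), 0.95)

    ## small-sample design runs and pools (mirrors a 79-compartment count)
    k79 <- withr::with_seed(79, rpois(79, 1))
    g79 <- occupancyGoodnessOfFit(tabulate(k79 + 1L, nbins = max(k79) + 1L))
    expect_true(all(g79$expected >= 1))
    expect_gt(g79$p_value, 0)
})
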