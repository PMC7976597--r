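test_that("sampled diameters honour the requested mean, CV and degenerate cases", {
    sp0 <- SceneParams(nCompartments = 40, diameterCV = 0, seed = 2)
    d0 <- compartments(sampleCompartments(sp0))$diameter_um
    expect_true(all(d0 == sp0@diameterMean))

    ## lognormal moments: pool several seeds for a stable estimate
    d <- unlist(lapply(1:10, function(s)
        compartments(sampleCompartments(
            SceneParams(nCompartments = 200, imageWidth = 2500,
                        imageHeight = 2500, seed = s)))$diameter_um))
    expect_equal(mean(d), 175, tolerance = 0.01)
    cv <- 100 * sd(d) / mean(d)
    expect_gt(cv, 4.5); expect_lt(cv, 5.5)
})

test_that("occupancies are Poisson and zero lambda means empty compartments", {
    spz <- SceneParams(nCompartments = 30, occupancyLambda = 0, seed = 5)
    expect_true(all(compartments(sampleCompartments(spz))$n_entities == 0))

    ## fraction empty at lambda = 1 vs the exact pmf, binomial tolerance
    ne <- unlist(lapply(1:25, function(s)
        compartments(sampleCompartments(
            SceneParams(nCompartments = 400, imageWidth = 3500,
                        imageHeight = 3500, seed = 100 + s)))$n_entities))
    n <- length(ne)
    p0 <- exp(-1)
    expect_lt(abs(mean(ne == 0) - p0), 3 * sqrt(p0 * (1 - p0) / n))

    ## full histogram vs exact pmf: total variation < 0.02 at n = 1e4
    ks <- 0:max(ne)
    obs <- tabulate(ne + 1L, nbins = length(ks)) / n
    expv <- dpois(ks, 1); expv[length(expv)] <- 1 - ppois(max(ks) - 1, 1)
    expect_lt(sum(abs(obs - expv)) / 2, 0.02)
})

test_that("placement is margin-respecting, in-bounds and seed-deterministic", {
    sp <- noiselessScene(n = 60, seed = 11)
    gt <- sampleCompartments(sp)
    df <- compartments(gt)
    rpx <- df$diameter_um / (2 * sp@pixelSize)
    expect_true(checkNonOverlap(gt, marginPx = 2))
    expect_true(all(df$center_x - rpx >= 2 & df$center_y - rpx >= 2))
    expect_true(all(df$center_x + rpx <= sp@imageWidth - 1 - 2))
    expect_true(all(df$center_y + rpx <= sp@imageHeight - 1 - 2))
    expect_identical(df, compartments(sampleCompartments(sp)))

    ## impossible packing errors out naming the achievable fraction
    tooMany <- SceneParams(nCompartments = 500, imageWidth = 300,
                           imageHeight = 300, seed = 1)
    expect_error(sampleCompartments(tooMany, maxAttempts = 50L),
                 "packing fraction")
})

test_that("rendering is exact without noise and bit-reproducible with it", {
    sp <- noiselessScene(n = 0, seed = 4)
    imgs <- renderTwoChannel(sampleCompartments(sp), sp)
    expect_true(all(imgs$ref == sp@background))
    expect_true(all(imgs$sig == sp@background))

    sp1 <- SceneParams(nCompartments = 1, imageWidth = 120,
                       imageHeight = 120, occupancyLambda = 5,
                       diameterCV = 0, diameterMean = 150, noiseSD = 0,
                       seed = 8)
    gt1 <- sampleCompartments(sp1)
    expect_true(compartments(gt1)$is_positive[1])
    im1 <- renderTwoChannel(gt1, sp1)
    px <- compartments(gt1)
    inDisk <- im1$sig[abs(row(im1$sig) - 1 - px$center_y) < 5 &
                      abs(col(im1$sig) - 1 - px$center_x) < 5]
    expect_true(all(inDisk == sp1@sigIntensityPositive))

    spn <- SceneParams(nCompartments = 20, noiseSD = 50, seed = 13)
    gtn <- sampleCompartments(spn)
    a <- renderTwoChannel(gtn, spn)
    b <- renderTwoChannel(gtn, spn)
    expect_identical(a, b)
    expect_true(all(a$ref >= 0 & a$ref <= 65535))
})

test_that("spot rendering validates cellSpotSigma", {
    sp <- noiselessScene(n = 5, seed = 3, cellSpotSigma = 0)
    gt <- sampleCompartments(sp)
    expect_error(renderTwoChannel(gt, sp, mode = "spots"), "cellSpotSigma")
})

test_that("heating conserves volume and entities, merges and evaporates correctly", {
    sp <- noiselessScene(n = 100, seed = 21, imageWidth = 1800,
                         imageHeight = 1800)
    gt <- sampleCompartments(sp)

    ## identity when nothing happens
    gtId <- simulateHeating(gt, 0, 0, seed = 1)
    expect_equal(compartments(gtId), compartments(gt))

    ## equal-diameter merge gives d * 2^(1/3): two compartments only
    two <- new("GroundTruth", pixelSize = 5, compartments = data.frame(
        id = 1:2, center_x = c(100, 140), center_y = c(100, 100),
        diameter_um = c(150, 150), n_entities = c(1L, 2L),
        is_positive = c(TRUE, TRUE)))
    m <- simulateHeating(two, 1, 0, seed = 1)
    expect_equal(nrow(compartments(m)), 1L)
    expect_equal(compartments(m)$diameter_um, 150 * 2^(1 / 3))
    expect_equal(compartments(m)$n_entities, 3L)

    ## volume conservation under pure merging, entity conservation always
    v0 <- sum(compartments(gt)$diameter_um^3)
    gtM <- simulateHeating(gt, 0.3, 0, seed = 2)
    expect_lt(abs(sum(compartments(gtM)$diameter_um^3) - v0) / v0, 1e-12)
    expect_identical(sum(compartments(gtM)$n_entities),
                     sum(compartments(gt)$n_entities))

    ## evaporation scales every diameter by (1 - f)^(1/3)
    gtE <- simulateHeating(gt, 0, 0.2, seed = 3)
    expect_equal(compartments(gtE)$diameter_um,
                 compartments(gt)$diameter_um * 0.8^(1 / 3))

    ## combined heating broadens the size distribution (CV goes up)
    gtH <- simulateHeating(gt, 0.1, 0.05, seed = 4)
    cvBefore <- cvPercent(sizeStatistics(compartments(gt)$diameter_um))
    cvAfter <- cvPercent(sizeStatistics(compartments(gtH)$diameter_um))
    expect_gt(cvAfter, cvBefore)

    expect_error(simulateHeating(gt, -0.1, 0, 1), "mergeProb")
    expect_error(simulateHeating(gt, 0, 1, 1), "evapFraction")
})

test_that("simulated partition counts follow the concentration-lambda conversion", {
    expect_true(all(simulatePartitions(0, 2.8, 500, seed = 1) == 0))

    ## lambda = ln 2 -> half the partitions empty, binomial tolerance
    conc <- 1000 * log(2) / 2.8
    cnt <- simulatePartitions(conc, 2.8, 10000, seed = 42)
    expect_lt(abs(mean(cnt == 0) - 0.5), 3 * sqrt(0.25 / 10000))
    expect_identical(cnt, simulatePartitions(conc, 2.8, 10000, seed = 42))

    ## round trip: estimator CI covers the truth in most seeded replicates
    covered <- vapply(1:200, function(s) {
        k <- simulatePartitions(200, 2.8, 2000, seed = s)
        res <- concentrationWithCI(sum(k == 0), length(k), 2.8)
        ci <- ci95(res)
        ci[1] <= 200 && 200 <= ci[2]
    }, logical(1))
    expect_gte(mean(covered), 0.90)
})
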