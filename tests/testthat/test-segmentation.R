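test_that("blank and constant images yield zero detections with a warning", {
    expect_warning(det <- detectCompartments(matrix(100, 50, 50), 5, 50, 400),
                   "constant")
    expect_identical(nrow(det), 0L)
})

test_that("a single rendered disk is recovered with sub-pixel geometry", {
    sp <- SceneParams(nCompartments = 1, imageWidth = 200, imageHeight = 200,
                      diameterMean = 175, diameterCV = 0, noiseSD = 0,
                      seed = 6)
    gt <- sampleCompartments(sp)
    imgs <- renderTwoChannel(gt, sp)
    det <- detectCompartments(imgs$ref, 5, 50, 400)
    expect_identical(nrow(det), 1L)
    expect_lt(abs(det$radius_px - 17.5), 1)
    tr <- compartments(gt)
    expect_lt(abs(det$center_x - tr$center_x), 1)
    expect_lt(abs(det$center_y - tr$center_y), 1)
    expect_gte(det$circularity, 0.85)
    expect_lte(det$circularity, 1)
})

test_that("detection count and diameters match ground truth on noiseless scenes", {
    for (s in c(1L, 7L, 19L)) {
        sp <- noiselessScene(n = 50, seed = s)
        gt <- sampleCompartments(sp)
        imgs <- renderTwoChannel(gt, sp)
        det <- detectCompartments(imgs$ref, sp@pixelSize, 80, 350)
        expect_identical(nrow(det), 50L)
        idx <- matchToTruth(det, gt)
        expect_identical(sort(idx), 1:50)
        errPx <- (det$diameter_um -
                  compartments(gt)$diameter_um[idx]) / sp@pixelSize
        expect_lt(max(abs(errPx)), 2)
    }
})

test_that("intensity ratios are exact on noiseless renders and invariant to gain", {
    sp <- noiselessScene(n = 30, seed = 9, occupancyLambda = 1)
    gt <- sampleCompartments(sp)
    imgs <- renderTwoChannel(gt, sp)
    det <- detectCompartments(imgs$ref, 5, 80, 350)
    det <- measureIntensities(det, imgs$ref, imgs$sig)
    idx <- matchToTruth(det, gt)
    truthPos <- compartments(gt)$is_positive[idx]
    expRatio <- ifelse(truthPos, sp@sigIntensityPositive,
                       sp@sigIntensityNegative) / sp@refIntensityMean
    expect_equal(det$ratio, expRatio, tolerance = 1e-10)

    ## identity channel -> all ratios 1
    detId <- measureIntensities(det, imgs$ref, imgs$ref)
    expect_true(all(abs(detId$ratio - 1) < 1e-12))

    ## common multiplicative gain on both channels leaves ratios unchanged
    detG <- measureIntensities(det, imgs$ref * 3, imgs$sig * 3)
    expect_equal(detG$ratio, det$ratio, tolerance = 1e-12)

    expect_error(measureIntensities(det, imgs$ref, imgs$sig[1:10, ]),
                 "shape")
})

test_that("noisy per-compartment ratios stay within propagated error", {
    sp <- SceneParams(nCompartments = 30, seed = 14, occupancyLambda = 1,
                      noiseSD = 0.05 * 8000)
    gt <- sampleCompartments(sp)
    imgs <- renderTwoChannel(gt, sp)
    det <- detectCompartments(imgs$ref, 5, 80, 350)
    det <- measureIntensities(det, imgs$ref, imgs$sig)
    idx <- matchToTruth(det, gt)
    truth <- ifelse(compartments(gt)$is_positive[idx],
                    sp@sigIntensityPositive,
                    sp@sigIntensityNegative) / sp@refIntensityMean
    ## disk-mean noise: sd_ratio ~ (noise/sqrt(npix)) * sqrt(1 + r^2)/ref
    npix <- pi * (det$radius_px - 2)^2
    sdRatio <- sp@noiseSD / sqrt(npix) *
        sqrt(1 + truth^2) / sp@refIntensityMean
    expect_true(all(abs(det$ratio - truth) < 4 * sdRatio))
})

test_that("spot counting matches constructed ground truth and merges close spots", {
    sigmaPx <- 0.5  # 2.5 um at 5 um/px
    comp <- data.frame(center_x = 60, center_y = 60, radius_px = 20)

    ## zero spots
    img0 <- diskWithSpots(120, 120, 60, 60, 20, base = 1000,
                          spotXY = matrix(numeric(), ncol = 2),
                          amp = 5000, sigmaPx = sigmaPx)
    expect_identical(
        countCellsInCompartment(img0, comp, 5, spotSigma = 2.5), 0L)

    ## k = 1..5 well-separated spots recovered exactly
    ring <- function(k) cbind(60 + 10 * cos(2 * pi * seq_len(k) / k),
                              60 + 10 * sin(2 * pi * seq_len(k) / k))
    for (k in 1:5) {
        img <- diskWithSpots(120, 120, 60, 60, 20, base = 1000,
                             spotXY = ring(k), amp = 5000,
                             sigmaPx = sigmaPx)
        expect_identical(
            countCellsInCompartment(img, comp, 5, spotSigma = 2.5,
                                    minSeparation = 10), as.integer(k))
    }

    ## two spots closer than minSeparation merge into one count
    close2 <- rbind(c(58, 60), c(61, 60))
    imgC <- diskWithSpots(120, 120, 60, 60, 20, base = 1000,
                          spotXY = close2, amp = 5000, sigmaPx = sigmaPx)
    expect_identical(
        countCellsInCompartment(imgC, comp, 5, spotSigma = 2.5,
                                minSeparation = 25), 1L)
})

test_that("size statistics match hand computations and the whisker rule", {
    expect_error(sizeStatistics(numeric()), "diameter")

    st0 <- sizeStatistics(c(150, 150, 150))
    expect_equal(st0@meanDiameter, 150)
    expect_equal(cvPercent(st0), 0)

    st <- sizeStatistics(c(100, 200))
    expect_equal(st@meanDiameter, 150)
    expect_equal(st@sdDiameter, 70.71068, tolerance = 1e-6)
    expect_equal(cvPercent(st), 47.14045, tolerance = 1e-6)

    ## CV recovered from a lognormal population of stated CV
    lp <- list(sdlog = sqrt(log(1 + 0.05^2)))
    set.seed(31)
    d <- rlnorm(5000, log(175) - lp$sdlog^2 / 2, lp$sdlog)
    cv <- cvPercent(sizeStatistics(d))
    expect_gt(cv, 4.5); expect_lt(cv, 5.5)

    ## outliers are exactly the points outside [p10, p90] (brute force)
    set.seed(32)
    for (i in 1:10) {
        x <- rlnorm(200, 5, 0.3)
        st <- sizeStatistics(x)
        q <- quantile(x, c(0.1, 0.9), type = 7, names = FALSE)
        expect_setequal(st@outliers, x[x < q[1] | x > q[2]])
    }

    ## CV is invariant under uniform scaling
    x <- rlnorm(100, 5, 0.2)
    for (cfac in c(0.2, 3, 117)) {
        expect_equal(cvPercent(sizeStatistics(x * cfac)),
                     cvPercent(sizeStatistics(x)), tolerance = 1e-12)
    }
})
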