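#' Construct scene parameters for the synthetic compartment generator
#'
#' The generator emulates the statistical structure of a digital
#' compartment assay: circular compartments with lognormally distributed
#' diameters of given mean and CV, Poisson occupancy at a stated mean
#' `occupancyLambda`, and a two-level positive/negative intensity model in
#' the signal channel over a uniform reference channel. Defaults follow the
#' conditions of a typical Gelbead run: 175 um mean diameter at 5 \% CV
#' (2.8 nL partitions), one cell per compartment on average, and a 16-bit
#' camera scale.
#'
#' @param imageWidth,imageHeight image size in pixels.
#' @param pixelSize um per pixel (> 0).
#' @param nCompartments number of compartments to place.
#' @param diameterMean mean diameter, um.
#' @param diameterCV diameter CV as a fraction (0.05 = 5 \%).
#' @param occupancyLambda mean entities per compartment.
#' @param refIntensityMean reference-channel in-compartment level, ADU.
#' @param sigIntensityNegative,sigIntensityPositive signal-channel levels
#'   for negative and positive compartments, ADU.
#' @param background background level, ADU.
#' @param noiseSD additive Gaussian noise sd, ADU.
#' @param cellSpotSigma Gaussian sigma of one rendered cell spot, um.
#' @param seed integer seed driving every draw of the scene.
#' @return a validated [SceneParams-class] object.
#' @examples
#' sp <- SceneParams(nCompartments = 50, seed = 1)
#' gt <- sampleCompartments(sp)
#' nrow(compartments(gt))
#' @export
SceneParams <- function(imageWidth = 1200L, imageHeight = 1200L,
                        pixelSize = 5, nCompartments = 50L,
                        diameterMean = 175, diameterCV = 0.05,
                        occupancyLambda = 1,
                        refIntensityMean = 10000,
                        sigIntensityNegative = 1000,
                        sigIntensityPositive = 8000,
                        background = 200, noiseSD = 50,
                        cellSpotSigma = 2.5, seed = 1L) {
    new("SceneParams",
        imageWidth = as.integer(imageWidth),
        imageHeight = as.integer(imageHeight),
        pixelSize = as.numeric(pixelSize),
        nCompartments = as.integer(nCompartments),
        diameterMean = as.numeric(diameterMean),
        diameterCV = as.numeric(diameterCV),
        occupancyLambda = as.numeric(occupancyLambda),
        refIntensityMean = as.numeric(refIntensityMean),
        sigIntensityNegative = as.numeric(sigIntensityNegative),
        sigIntensityPositive = as.numeric(sigIntensityPositive),
        background = as.numeric(background),
        noiseSD = as.numeric(noiseSD),
        cellSpotSigma = as.numeric(cellSpotSigma),
        seed = as.integer(seed))
}

#' Sample a ground-truthed field of compartments
#'
#' Draws `nCompartments` diameters from a lognormal with the requested
#' mean and CV (a zero CV yields identical diameters), assigns each
#' compartment an independent Poisson(`occupancyLambda`) entity count, and
#' places the compartments in the image by rejection sampling so that
#' every pair of rims and every rim-to-border gap keeps at least a 2 px
#' margin. Placement, diameters and occupancies are deterministic given
#' the seed in `params`.
#'
#' @param params a [SceneParams-class] object.
#' @param maxAttempts rejection-sampling budget per compartment.
#' @return a [GroundTruth-class] object.
#' @export
sampleCompartments <- function(params, maxAttempts = 10000L) {
    stopifnot(is(params, "SceneParams"))
    validObject(params)
    n <- params@nCompartments
    w <- params@imageWidth; h <- params@imageHeight
    margin <- 2  # px clearance, rim to rim and rim to border

    diams <- withLocalSeed(params@seed, step = 1L, {
        if (params@diameterCV == 0) rep(params@diameterMean, n)
        else {
            lp <- lognormalFromMeanCV(params@diameterMean, params@diameterCV)
            rlnorm(n, lp$meanlog, lp$sdlog)
        }
    })
    nEnt <- withLocalSeed(params@seed, step = 2L,
                          rpois(n, params@occupancyLambda))

    rpx <- diams / (2 * params@pixelSize)
    if (n > 0 && any(2 * rpx + 2 * margin > pmin(w, h)))
        stop("compartments larger than the image at the requested pixel size")

    cx <- numeric(n); cy <- numeric(n)
    if (n > 0) withLocalSeed(params@seed, step = 3L, {
        ## place large compartments first: improves packing success
        ord <- order(rpx, decreasing = TRUE)
        placedX <- numeric(0); placedY <- numeric(0); placedR <- numeric(0)
        for (i in ord) {
            r <- rpx[i]
            ok <- FALSE
            for (a in seq_len(maxAttempts)) {
                x <- runif(1, r + margin, w - 1 - r - margin)
                y <- runif(1, r + margin, h - 1 - r - margin)
                if (!length(placedX) ||
                    all((placedX - x)^2 + (placedY - y)^2 >
                        (placedR + r + margin)^2)) {
                    ok <- TRUE; break
                }
            }
            if (!ok) {
                frac <- sum(pi * placedR^2) / (w * h)
                stop(sprintf(
                    paste("placement failed after %d attempts at packing",
                          "fraction %.2f; reduce nCompartments or enlarge",
                          "the image"), maxAttempts, frac))
            }
            placedX <- c(placedX, x); placedY <- c(placedY, y)
            placedR <- c(placedR, r)
            cx[i] <- x; cy[i] <- y
        }
    })

    df <- data.frame(id = seq_len(n), center_x = cx, center_y = cy,
                     diameter_um = diams, n_entities = as.integer(nEnt),
                     is_positive = nEnt > 0)
    new("GroundTruth", compartments = df, pixelSize = params@pixelSize)
}

## Additive rendering of one uniform disk onto img (matrix [y+1, x+1]).
.paintDisk <- function(img, cx, cy, rpx, level) {
    px <- diskPixels(nrow(img), ncol(img), cx, cy, rpx)
    img[px] <- level
    img
}

#' Render a ground-truth scene as a two-channel micrograph
#'
#' Produces the reference channel (uniform disks of `refIntensityMean`
#' over background: the calcein/FITC picture of every compartment) and the
#' signal channel (TXR/FAM-like), where positive compartments render at
#' `sigIntensityPositive` and negatives at `sigIntensityNegative`. With
#' `mode = "spots"` the signal channel instead renders each compartment's
#' entities as Gaussian spots of sigma `cellSpotSigma` over the negative
#' in-compartment level, for cell-counting work. Both channels receive
#' i.i.d. Gaussian noise of sd `noiseSD` and are clipped to the unsigned
#' 16-bit range. Deterministic given the seed in `params`.
#'
#' @param gt a [GroundTruth-class] object consistent with `params`.
#' @param params the [SceneParams-class] the scene was generated from.
#' @param mode `"disks"` (default) or `"spots"`.
#' @return list with numeric matrices `ref` and `sig` (rows = y, cols = x,
#'   ADU) and, in spot mode, `spot_centers` (per-compartment list of
#'   0-based spot coordinates).
#' @export
renderTwoChannel <- function(gt, params, mode = c("disks", "spots")) {
    mode <- match.arg(mode)
    stopifnot(is(gt, "GroundTruth"), is(params, "SceneParams"))
    df <- compartments(gt)
    w <- params@imageWidth; h <- params@imageHeight
    if (nrow(df)) {
        rpx <- df$diameter_um / (2 * params@pixelSize)
        if (any(df$center_x - rpx < -0.5) || any(df$center_x + rpx > w - 0.5) ||
            any(df$center_y - rpx < -0.5) || any(df$center_y + rpx > h - 0.5))
            stop("ground truth does not fit the image size in params")
    }
    if (mode == "spots" && params@cellSpotSigma <= 0)
        stop("spot rendering requires cellSpotSigma > 0")

    ref <- matrix(params@background, nrow = h, ncol = w)
    sig <- matrix(params@background, nrow = h, ncol = w)
    spotCenters <- vector("list", nrow(df))

    if (nrow(df)) {
        rpx <- df$diameter_um / (2 * params@pixelSize)
        for (i in seq_len(nrow(df))) {
            ref <- .paintDisk(ref, df$center_x[i], df$center_y[i], rpx[i],
                              params@refIntensityMean)
            lvl <- if (mode == "disks" && df$is_positive[i])
                params@sigIntensityPositive else params@sigIntensityNegative
            sig <- .paintDisk(sig, df$center_x[i], df$center_y[i], rpx[i], lvl)
        }
        if (mode == "spots") {
            sigmaPx <- params@cellSpotSigma / params@pixelSize
            amp <- params@sigIntensityPositive
            spotCenters <- withLocalSeed(params@seed, step = 4L, {
                lapply(seq_len(nrow(df)), function(i) {
                    k <- df$n_entities[i]
                    if (k == 0L) return(matrix(numeric(), ncol = 2L))
                    rin <- max(rpx[i] - 3 * sigmaPx, 0.5)
                    th <- runif(k, 0, 2 * pi)
                    rr <- rin * sqrt(runif(k))
                    cbind(x = df$center_x[i] + rr * cos(th),
                          y = df$center_y[i] + rr * sin(th))
                })
            })
            for (i in seq_len(nrow(df))) {
                sc <- spotCenters[[i]]
                if (!nrow(sc)) next
                for (j in seq_len(nrow(sc))) {
                    x0 <- sc[j, 1]; y0 <- sc[j, 2]
                    ext <- ceiling(4 * sigmaPx)
                    xs <- max(0, floor(x0 - ext)):min(w - 1, ceiling(x0 + ext))
                    ys <- max(0, floor(y0 - ext)):min(h - 1, ceiling(y0 + ext))
                    g <- outer(ys - y0, xs - x0,
                               function(dy, dx) exp(-(dx^2 + dy^2) /
                                                    (2 * sigmaPx^2)))
                    sig[ys + 1L, xs + 1L] <- sig[ys + 1L, xs + 1L] + amp * g
                }
            }
        }
    }

    if (params@noiseSD > 0) {
        noise <- withLocalSeed(params@seed, step = 5L,
                               list(r = rnorm(length(ref), 0, params@noiseSD),
                                    s = rnorm(length(sig), 0, params@noiseSD)))
        ref <- ref + noise$r
        sig <- sig + noise$s
    }
    ref <- pmin(pmax(ref, 0), 65535)
    sig <- pmin(pmax(sig, 0), 65535)
    out <- list(ref = ref, sig = sig)
    if (mode == "spots") out$spot_centers <- spotCenters
    out
}

#' Apply a heating protocol to a compartment population
#'
#' Emulates the two thermal degradation routes of emulsion compartments:
#' merging of adjacent pairs and aqueous evaporation. Each unordered
#' nearest-neighbour pair merges with probability `mergeProb` into one
#' compartment whose diameter conserves volume, (d1^3 + d2^3)^(1/3), at
#' the volume-weighted centroid, carrying the summed entity count. Every
#' surviving compartment then loses `evapFraction` of its volume, scaling
#' its diameter by (1 - evapFraction)^(1/3).
#'
#' @param gt a [GroundTruth-class] object.
#' @param mergeProb per-pair merge probability in [0, 1].
#' @param evapFraction volume fraction lost to evaporation, in [0, 1).
#' @param seed integer seed.
#' @return a new [GroundTruth-class]; merged compartments may overlap
#'   their neighbours (heated emulsions do).
#' @export
simulateHeating <- function(gt, mergeProb, evapFraction, seed) {
    stopifnot(is(gt, "GroundTruth"))
    stopIfNot(mergeProb >= 0 && mergeProb <= 1,
              "mergeProb must be in [0, 1]")
    stopIfNot(evapFraction >= 0 && evapFraction < 1,
              "evapFraction must be in [0, 1)")
    df <- compartments(gt)
    if (nrow(df) >= 2L && mergeProb > 0) {
        ## adjacency: mutual or one-sided nearest neighbours, each
        ## compartment merging at most once
        d <- as.matrix(dist(cbind(df$center_x, df$center_y)))
        diag(d) <- Inf
        nn <- apply(d, 1L, which.min)
        pairs <- unique(t(apply(cbind(seq_len(nrow(df)), nn), 1L, sort)))
        merged <- withLocalSeed(seed, step = 6L,
                                runif(nrow(pairs)) < mergeProb)
        used <- logical(nrow(df))
        drop <- integer(0)
        for (p in seq_len(nrow(pairs))) {
            if (!merged[p]) next
            i <- pairs[p, 1L]; j <- pairs[p, 2L]
            if (used[i] || used[j]) next
            used[i] <- used[j] <- TRUE
            v1 <- df$diameter_um[i]^3; v2 <- df$diameter_um[j]^3
            df$diameter_um[i] <- (v1 + v2)^(1 / 3)
            df$center_x[i] <- (v1 * df$center_x[i] + v2 * df$center_x[j]) /
                (v1 + v2)
            df$center_y[i] <- (v1 * df$center_y[i] + v2 * df$center_y[j]) /
                (v1 + v2)
            df$n_entities[i] <- df$n_entities[i] + df$n_entities[j]
            drop <- c(drop, j)
        }
        if (length(drop)) df <- df[-drop, , drop = FALSE]
    }
    if (evapFraction > 0)
        df$diameter_um <- df$diameter_um * (1 - evapFraction)^(1 / 3)
    df$is_positive <- df$n_entities > 0L
    df$id <- seq_len(nrow(df))
    rownames(df) <- NULL
    new("GroundTruth", compartments = df, pixelSize = gt@pixelSize)
}

#' Simulate per-partition template copy counts
#'
#' Draws i.i.d. Poisson counts for `nPartitions` partitions at the
#' occupancy implied by a target concentration:
#' lambda = concentration * partitionVolume / 1000 (the nL-to-uL
#' conversion), the forward model that digital quantification inverts.
#'
#' @param concentration target concentration, copies per uL (>= 0).
#' @param partitionVolume partition volume, nL (> 0).
#' @param nPartitions number of partitions (>= 1).
#' @param seed integer seed.
#' @return integer vector of per-partition copy counts.
#' @examples
#' counts <- simulatePartitions(200, 2.8, 7000, seed = 1)
#' mean(counts)  # about 200 * 2.8 / 1000 = 0.56
#' @export
simulatePartitions <- function(concentration, partitionVolume, nPartitions,
                               seed) {
    stopIfNot(.scalarNum(concentration) && concentration >= 0,
              "concentration must be >= 0")
    stopIfNot(.scalarNum(partitionVolume) && partitionVolume > 0,
              "partitionVolume must be > 0")
    stopIfNot(.scalarInt(nPartitions) && nPartitions >= 1,
              "nPartitions must be >= 1")
    lam <- concentration * partitionVolume / 1000
    withLocalSeed(seed, step = 7L, rpois(nPartitions, lam))
}
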