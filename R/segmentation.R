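## Compartment detection and measurement on the reference channel.
##
## Pipeline: Otsu threshold -> fill holes -> connected components ->
## per-component watershed splitting when a component is not disk-like ->
## circularity and size filters. Images are numeric matrices indexed
## [y + 1, x + 1] with 0-based pixel-centre coordinates reported.

.toEBI <- function(m) EBImage::Image(t(m))

## Chain-code perimeter with Vossepoel-Smeulders step weights; the raw
## boundary-pixel count underestimates circular perimeters badly enough to
## push 4*pi*A/P^2 above 1.2 for digitized disks.
.contourPerimeter <- function(oc) {
    if (nrow(oc) < 2L) return(1)
    d <- rbind(diff(oc), oc[1L, ] - oc[nrow(oc), ])
    axial <- rowSums(abs(d)) == 1
    0.948 * sum(axial) + 1.340 * sum(!axial)
}

## Features of every labelled component: centroid (0-based), area,
## circularity (clamped at 1), border contact.
.componentFeatures <- function(labImg) {
    nlab <- max(labImg)
    if (nlab == 0L)
        return(data.frame(label = integer(), center_x = numeric(),
                          center_y = numeric(), area = numeric(),
                          circularity = numeric(),
                          touches_border = logical()))
    mo <- EBImage::computeFeatures.moment(labImg)
    sh <- EBImage::computeFeatures.shape(labImg)
    oc <- EBImage::ocontour(labImg)
    per <- vapply(oc, .contourPerimeter, numeric(1))
    lm <- EBImage::imageData(labImg)  # dims (x, y)
    edgeLabs <- unique(c(lm[1L, ], lm[dim(lm)[1L], ], lm[, 1L],
                         lm[, dim(lm)[2L]]))
    circ <- pmin(4 * pi * sh[, "s.area"] / per^2, 1)
    data.frame(label = seq_len(nlab),
               center_x = mo[, "m.cx"] - 1,
               center_y = mo[, "m.cy"] - 1,
               area = sh[, "s.area"],
               circularity = circ,
               touches_border = seq_len(nlab) %in% edgeLabs)
}

#' Detect circular compartments in a reference-channel image
#'
#' Segments the reference (e.g. FITC/calcein) channel by Otsu
#' thresholding, hole filling and connected-component labelling; a
#' component that is not disk-like (circularity below `minCircularity`)
#' is re-segmented by a distance-map watershed so touching compartments
#' split. Detections are filtered to `dMin <= diameter <= dMax` — the
#' upper bound also removes chamber loading ports, which image as much
#' larger bright circles — and to `circularity >= minCircularity`.
#' Compartments touching the image border are kept but flagged; size
#' statistics should exclude them.
#'
#' @param refImage numeric matrix (rows = y, cols = x), intensity in ADU.
#' @param pixelSize um per pixel.
#' @param dMin,dMax diameter acceptance window, um.
#' @param minCircularity minimum 4*pi*A/P^2 kept (default 0.85).
#' @return data.frame with one row per detection: `id`, `center_x`,
#'   `center_y` (0-based px), `radius_px`, `diameter_um`, `circularity`,
#'   `touches_border`, plus `mean_ref`, `mean_sig`, `ratio` columns
#'   initialised to `NA` for [measureIntensities()] to fill. A constant
#'   (blank or saturated) image yields zero rows with a warning.
#' @export
detectCompartments <- function(refImage, pixelSize, dMin, dMax,
                               minCircularity = 0.85) {
    stopIfNot(is.matrix(refImage) && length(refImage) > 0,
              "refImage must be a non-empty matrix")
    stopIfNot(.scalarNum(pixelSize) && pixelSize > 0,
              "pixelSize must be > 0")
    stopIfNot(dMin < dMax, "need dMin < dMax")

    empty <- data.frame(id = integer(), center_x = numeric(),
                        center_y = numeric(), radius_px = numeric(),
                        diameter_um = numeric(), circularity = numeric(),
                        touches_border = logical(), mean_ref = numeric(),
                        mean_sig = numeric(), ratio = numeric())
    rng <- range(refImage)
    if (diff(rng) == 0) {
        warning("constant image: no compartments detected")
        return(empty)
    }

    img01 <- (refImage - rng[1L]) / diff(rng)
    ebi <- .toEBI(img01)
    thr <- EBImage::otsu(ebi)
    bw <- EBImage::fillHull(ebi > thr)
    lab <- EBImage::bwlabel(bw)

    feats <- .componentFeatures(lab)
    ## watershed-split components too irregular to be one compartment
    ## (touching beads fused by thresholding)
    bad <- feats$label[feats$circularity < minCircularity &
                       feats$area >= pi * (dMin / (2 * pixelSize))^2]
    if (length(bad)) {
        lm <- EBImage::imageData(lab)
        keepMask <- lm > 0 & !(lm %in% bad)
        splitMask <- lm %in% bad
        dm <- EBImage::distmap(EBImage::Image(splitMask,
                                              dim = dim(lm)))
        ws <- EBImage::watershed(dm, tolerance = 1)
        relab <- EBImage::bwlabel(EBImage::Image(keepMask, dim = dim(lm)))
        wsd <- EBImage::imageData(ws)
        nKeep <- max(relab)
        merged <- EBImage::imageData(relab)
        merged[wsd > 0] <- wsd[wsd > 0] + nKeep
        lab <- EBImage::Image(merged, dim = dim(lm))
        feats <- .componentFeatures(lab)
    }

    feats$radius_px <- sqrt(feats$area / pi)
    feats$diameter_um <- 2 * feats$radius_px * pixelSize
    keep <- feats$diameter_um >= dMin & feats$diameter_um <= dMax &
        feats$circularity >= minCircularity
    feats <- feats[keep, , drop = FALSE]
    if (!nrow(feats)) return(empty)
    data.frame(id = seq_len(nrow(feats)),
               center_x = feats$center_x, center_y = feats$center_y,
               radius_px = feats$radius_px,
               diameter_um = feats$diameter_um,
               circularity = feats$circularity,
               touches_border = feats$touches_border,
               mean_ref = NA_real_, mean_sig = NA_real_,
               ratio = NA_real_, row.names = NULL)
}

#' Measure per-compartment channel intensities and their ratio
#'
#' Fills `mean_ref`, `mean_sig` and `ratio` (mean_sig / mean_ref, the
#' TXR/FITC-style normalisation) for every detected compartment. Means
#' are taken over the disk eroded by `erodePx` pixels, avoiding the dim
#' rim where the compartment edge mixes with background. The ratio is
#' left `NA` when the reference mean does not exceed the background
#' estimate (by default the median of pixels outside all compartments).
#'
#' @param comps detection table from [detectCompartments()].
#' @param refImage,sigImage numeric matrices of identical shape.
#' @param erodePx rim erosion in pixels (default 2).
#' @param background background level for the ratio-defined check;
#'   `NULL` (default) estimates it from pixels outside all compartments.
#' @return `comps` with intensity columns filled.
#' @export
measureIntensities <- function(comps, refImage, sigImage, erodePx = 2L,
                               background = NULL) {
    stopIfNot(identical(dim(refImage), dim(sigImage)),
              "refImage and sigImage must have the same shape")
    stopIfNot(erodePx >= 0, "erodePx must be >= 0")
    if (!nrow(comps)) return(comps)
    if (is.null(background)) {
        outside <- matrix(TRUE, nrow(refImage), ncol(refImage))
        for (i in seq_len(nrow(comps))) {
            px <- diskPixels(nrow(refImage), ncol(refImage),
                             comps$center_x[i], comps$center_y[i],
                             comps$radius_px[i])
            outside[px] <- FALSE
        }
        background <- if (any(outside)) median(refImage[outside]) else 0
    }
    for (i in seq_len(nrow(comps))) {
        r <- max(comps$radius_px[i] - erodePx, 1)
        px <- diskPixels(nrow(refImage), ncol(refImage),
                         comps$center_x[i], comps$center_y[i], r)
        mr <- mean(refImage[px]); ms <- mean(sigImage[px])
        comps$mean_ref[i] <- mr
        comps$mean_sig[i] <- ms
        comps$ratio[i] <- if (mr > background) ms / mr else NA_real_
    }
    comps
}

#' Count cell spots inside one compartment
#'
#' Counts fluorescent entities rendered or imaged as compact spots inside
#' a compartment: the signal channel is Gaussian-smoothed at the expected
#' spot scale, local maxima inside the eroded disk are found above an
#' adaptive prominence threshold (median in-disk level plus a fraction of
#' the in-disk dynamic range, with a robust-noise floor), and maxima
#' closer than `minSeparation` are merged into one count.
#'
#' @param sigImage numeric matrix, signal channel.
#' @param compartment one row of a [detectCompartments()] table.
#' @param pixelSize um per pixel.
#' @param spotSigma expected spot sigma, um.
#' @param minSeparation minimum centre-to-centre spot distance, um.
#' @param erodePx rim erosion in pixels.
#' @return integer spot count.
#' @export
countCellsInCompartment <- function(sigImage, compartment, pixelSize,
                                    spotSigma, minSeparation = 2 * spotSigma,
                                    erodePx = 2L) {
    stopIfNot(spotSigma > 0, "spotSigma must be > 0")
    sigmaPx <- spotSigma / pixelSize
    sm <- EBImage::gblur(.toEBI(sigImage), sigma = max(sigmaPx / 2, 0.5))
    sm <- t(EBImage::imageData(sm))

    r <- max(compartment$radius_px - erodePx, 1)
    px <- diskPixels(nrow(sigImage), ncol(sigImage),
                     compartment$center_x, compartment$center_y, r)
    vals <- sm[px]
    med <- median(vals); mx <- max(vals)
    noise <- stats::mad(vals)
    if (mx - med <= max(8 * noise, 1e-9)) return(0L)
    thr <- med + 0.3 * (mx - med)

    cand <- px[vals > thr, , drop = FALSE]
    candVal <- vals[vals > thr]
    ## local maxima on the smoothed image (8-neighbourhood, >=)
    isMax <- vapply(seq_len(nrow(cand)), function(i) {
        rr <- cand[i, 1L]; cc <- cand[i, 2L]
        nb <- sm[max(1, rr - 1):min(nrow(sm), rr + 1),
                 max(1, cc - 1):min(ncol(sm), cc + 1)]
        sm[rr, cc] >= max(nb)
    }, logical(1))
    cand <- cand[isMax, , drop = FALSE]
    candVal <- candVal[isMax]
    if (!nrow(cand)) return(0L)

    ## non-maximum suppression: strongest peak wins within minSeparation
    sepPx <- minSeparation / pixelSize
    ord <- order(candVal, decreasing = TRUE)
    kept <- matrix(numeric(), ncol = 2L)
    for (i in ord) {
        p <- cand[i, , drop = FALSE]
        if (!nrow(kept) ||
            all((kept[, 1L] - p[1L])^2 + (kept[, 2L] - p[2L])^2 >= sepPx^2))
            kept <- rbind(kept, p)
    }
    nrow(kept)
}

#' Size-distribution statistics of a compartment population
#'
#' Summarises a vector of diameters the way monodispersity of an emulsion
#' is reported: mean, sample (n-1) standard deviation, CV in percent, the
#' 10th/25th/75th/90th percentiles (linear interpolation), and the
#' diameters falling strictly outside the [p10, p90] whiskers as
#' outliers.
#'
#' @param diameters numeric vector of diameters, um.
#' @return a [SizeStats-class] object; with a single diameter the sd, CV
#'   and percentile-based fields are `NA`.
#' @examples
#' st <- sizeStatistics(c(100, 200))
#' cvPercent(st)  # 47.14
#' @export
sizeStatistics <- function(diameters) {
    stopIfNot(length(diameters) >= 1L, "at least one diameter is required")
    stopIfNot(all(is.finite(diameters)) && all(diameters > 0),
              "diameters must be finite and > 0")
    n <- length(diameters)
    m <- mean(diameters)
    if (n >= 2L) {
        s <- sd(diameters)
        cv <- 100 * s / m
        qs <- quantile(diameters, c(0.10, 0.25, 0.75, 0.90),
                       type = 7, names = FALSE)
        out <- diameters[diameters < qs[1L] | diameters > qs[4L]]
    } else {
        s <- NA_real_; cv <- NA_real_; qs <- rep(NA_real_, 4L)
        out <- numeric()
    }
    new("SizeStats", n = as.integer(n), meanDiameter = m, sdDiameter = s,
        cv = cv, p10 = qs[1L], p25 = qs[2L], p75 = qs[3L], p90 = qs[4L],
        outliers = out)
}
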