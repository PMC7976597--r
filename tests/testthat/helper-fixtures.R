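## Shared fixtures: small noiseless scenes and a truth-matching helper.

noiselessScene <- function(n = 50L, seed = 1L, cv = 0.05, ...) {
    SceneParams(nCompartments = n, seed = seed, diameterCV = cv,
                noiseSD = 0, ...)
}

## Match each detection to its nearest ground-truth compartment; returns
## the truth row indices.
matchToTruth <- function(det, gt) {
    df <- compartments(gt)
    vapply(seq_len(nrow(det)), function(i)
        which.min((df$center_x - det$center_x[i])^2 +
                  (df$center_y - det$center_y[i])^2), integer(1))
}

## Paint one uniform disk plus Gaussian spots at given 0-based centres:
## a hand-built image so spot-counting tests control their own geometry.
diskWithSpots <- function(w, h, cx, cy, rpx, base, spotXY, amp, sigmaPx,
                          bg = 200) {
    img <- matrix(bg, nrow = h, ncol = w)
    for (y in 0:(h - 1)) {
        inside <- (0:(w - 1) - cx)^2 + (y - cy)^2 <= rpx^2
        img[y + 1, inside] <- base
    }
    if (length(spotXY)) for (j in seq_len(nrow(spotXY))) {
        for (y in 0:(h - 1)) {
            g <- amp * exp(-((0:(w - 1) - spotXY[j, 1])^2 +
                             (y - spotXY[j, 2])^2) / (2 * sigmaPx^2))
            img[y + 1, ] <- img[y + 1, ] + g
        }
    }
    img
}
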