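## Internal helpers shared across modules.

## Run expr with a locally seeded RNG, restoring the caller's stream.
## Every stochastic operation derives its own sub-stream from (seed, step)
## so adding operations never perturbs draws made by earlier ones.
withLocalSeed <- function(seed, expr, step = 0L) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
        stop("seed must be a single finite number")
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed((as.integer(seed) + 1013L * as.integer(step)) %% .Machine$integer.max)
    force(expr)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

## 0-based pixel-centre disk membership on a [y+1, x+1]-indexed matrix.
## Returns a logical matrix of the same shape.
diskMask <- function(nrowY, ncolX, cx, cy, radiusPx) {
    xs <- matrix(0:(ncolX - 1L), nrow = nrowY, ncol = ncolX, byrow = TRUE)
    ys <- matrix(0:(nrowY - 1L), nrow = nrowY, ncol = ncolX)
    (xs - cx)^2 + (ys - cy)^2 <= radiusPx^2
}

## Indices (row, col) of disk pixels restricted to a bounding box, cheap
## for many small disks in a big image.
diskPixels <- function(nrowY, ncolX, cx, cy, radiusPx) {
    x0 <- max(0L, floor(cx - radiusPx)); x1 <- min(ncolX - 1L, ceiling(cx + radiusPx))
    y0 <- max(0L, floor(cy - radiusPx)); y1 <- min(nrowY - 1L, ceiling(cy + radiusPx))
    if (x1 < x0 || y1 < y0)
        return(matrix(integer(), ncol = 2L,
                      dimnames = list(NULL, c("row", "col"))))
    xs <- x0:x1; ys <- y0:y1
    g <- expand.grid(y = ys, x = xs)
    keep <- (g$x - cx)^2 + (g$y - cy)^2 <= radiusPx^2
    cbind(row = g$y[keep] + 1L, col = g$x[keep] + 1L)
}

## Wilson 95% score interval for a binomial proportion.
wilsonInterval <- function(k, n, conf = 0.95) {
    if (n == 0L) return(c(NA_real_, NA_real_))
    z <- qnorm(1 - (1 - conf) / 2)
    p <- k / n
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    ## exact endpoints at the boundary counts (guards rounding in the
    ## equal centre/half cancellation)
    lo <- if (k == 0) 0 else max(0, centre - half)
    hi <- if (k == n) 1 else min(1, centre + half)
    c(lo, hi)
}

## Lognormal parameters matching a target arithmetic mean and CV.
lognormalFromMeanCV <- function(meanVal, cv) {
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(meanVal) - sdlog^2 / 2
    list(meanlog = meanlog, sdlog = sdlog)
}

#' Check that no two compartments overlap
#'
#' Verifies the placement guarantee of [sampleCompartments()]: the
#' centre-to-centre distance of every pair exceeds the sum of their radii
#' (plus an optional margin). Returns `TRUE`/`FALSE`.
#'
#' @param gt a [GroundTruth-class] object.
#' @param marginPx extra clearance required between rims, in pixels.
#' @return logical scalar.
#' @export
checkNonOverlap <- function(gt, marginPx = 0) {
    df <- compartments(gt)
    n <- nrow(df)
    if (n < 2L) return(TRUE)
    rpx <- df$diameter_um / (2 * gt@pixelSize)
    d <- as.matrix(dist(cbind(df$center_x, df$center_y)))
    lim <- outer(rpx, rpx, "+") + marginPx
    up <- upper.tri(d)
    all(d[up] > lim[up])
}
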