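#' Fit a two-component Gaussian mixture and derive a bright/dark threshold
#'
#' When positive and negative compartments are hard to separate by eye,
#' the distribution of normalised intensities (signal/reference ratios, or
#' raw signal means for single-channel runs) is modelled as a mixture of
#' two Gaussians fitted by expectation-maximisation. The decision
#' threshold is the density-intersection point between the two component
#' means — the cut that minimises expected misclassification under the
#' fitted model — falling back to the midpoint of the means when no
#' intersection lies between them.
#'
#' EM details: k-means (2 centres) initialisation, relative log-likelihood
#' tolerance 1e-8, 500-iteration cap. The fit is reported as
#' non-converged when the iteration cap is hit or when the components
#' overlap heavily (separation index |muPos - muNeg| / sqrt(sdNeg * sdPos)
#' below 2), in which case the threshold should be reviewed manually.
#'
#' @param values numeric vector of per-compartment intensities (n >= 20;
#'   smaller samples must use a manual threshold).
#' @return a [ThresholdFit-class] object.
#' @examples
#' set.seed(1)
#' v <- c(rnorm(1000, 1, 0.1), rnorm(1000, 3, 0.1))
#' fit <- fitBimodalThreshold(v)
#' threshold(fit)  # about 2
#' @export
fitBimodalThreshold <- function(values) {
    values <- values[is.finite(values)]
    stopIfNot(length(values) >= 20L,
              "need at least 20 values; use a manual threshold below that")
    if (sd(values) < 1e-12 * max(1, abs(mean(values))))
        stop("no bimodal structure: values are (near-)constant")

    km <- withLocalSeed(271828L, kmeans(values, centers = 2L, nstart = 5L))
    ord <- order(km$centers)
    mu <- as.numeric(km$centers[ord])
    grp <- match(km$cluster, ord)
    sdv <- vapply(1:2, function(g) {
        s <- sd(values[grp == g])
        if (!is.finite(s) || s < 1e-8) s <- sd(values) / 10
        s
    }, numeric(1))
    w <- max(min(mean(grp == 1L), 0.99), 0.01)

    n <- length(values)
    ll0 <- -Inf; iter <- 0L; converged <- FALSE
    repeat {
        iter <- iter + 1L
        d1 <- w * dnorm(values, mu[1L], sdv[1L])
        d2 <- (1 - w) * dnorm(values, mu[2L], sdv[2L])
        tot <- d1 + d2
        tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
        ll <- sum(log(tot))
        if (is.finite(ll0) && abs(ll - ll0) <= 1e-8 * abs(ll0)) {
            converged <- TRUE
            break
        }
        if (iter >= 500L) break
        ll0 <- ll
        r1 <- d1 / tot
        n1 <- sum(r1)
        w <- max(min(n1 / n, 1 - 1e-6), 1e-6)
        mu[1L] <- sum(r1 * values) / n1
        mu[2L] <- sum((1 - r1) * values) / (n - n1)
        sdv[1L] <- sqrt(sum(r1 * (values - mu[1L])^2) / n1)
        sdv[2L] <- sqrt(sum((1 - r1) * (values - mu[2L])^2) / (n - n1))
        sdv[sdv < 1e-8] <- 1e-8
        if (mu[1L] > mu[2L]) {  # keep the negative component first
            mu <- rev(mu); sdv <- rev(sdv); w <- 1 - w
        }
    }

    thr <- .densityIntersection(w, mu[1L], sdv[1L], 1 - w, mu[2L], sdv[2L])
    sep <- abs(mu[2L] - mu[1L]) / sqrt(sdv[1L] * sdv[2L])
    if (sep < 2) converged <- FALSE
    new("ThresholdFit", muNeg = mu[1L], muPos = mu[2L], sdNeg = sdv[1L],
        sdPos = sdv[2L], weightNeg = w, threshold = thr, separation = sep,
        converged = converged)
}

## Point between m1 < m2 where the two weighted normal densities are
## equal; closed-form roots of the log-density difference (quadratic in x).
.densityIntersection <- function(w1, m1, s1, w2, m2, s2) {
    mid <- (m1 + m2) / 2
    if (abs(s1 - s2) < 1e-12 * (s1 + s2)) {
        if (abs(w1 - w2) < 1e-12) return(mid)
        x <- mid + s1^2 * log(w1 / w2) / (m2 - m1)
        return(if (x > m1 && x < m2) x else mid)
    }
    a <- 1 / s2^2 - 1 / s1^2
    b <- 2 * (m1 / s1^2 - m2 / s2^2)
    cc <- m2^2 / s2^2 - m1^2 / s1^2 + 2 * log((w1 * s2) / (w2 * s1))
    disc <- b^2 - 4 * a * cc
    if (disc < 0) return(mid)
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    inside <- roots[roots > m1 & roots < m2]
    if (length(inside)) inside[1L] else mid
}

#' Call compartments positive or negative at a threshold
#'
#' Applies `is_positive <- value > threshold` (strictly: a value exactly
#' at the threshold is called negative, the conservative choice for
#' concentration estimation) and summarises the calls with a 95 \% Wilson
#' score interval for the positive fraction.
#'
#' @param comps detection table with intensity columns filled, or any
#'   data.frame holding the classification variable.
#' @param threshold decision threshold (same units as the values).
#' @param mode `"ratio"` classifies on the `ratio` column (two-channel
#'   phenotyping); `"signal"` on `mean_sig` (single-channel gdPCR/gdLAMP).
#' @return list with `comps` (the table plus an `is_positive` column;
#'   rows with an undefined classification value are dropped with a
#'   warning) and `summary`, a [CallSummary-class].
#' @export
classifyCompartments <- function(comps, threshold,
                                 mode = c("ratio", "signal")) {
    mode <- match.arg(mode)
    col <- if (mode == "ratio") "ratio" else "mean_sig"
    stopIfNot(col %in% names(comps),
              sprintf("comps must contain a '%s' column", col))
    stopIfNot(.scalarNum(threshold), "threshold must be a single number")
    vals <- comps[[col]]
    if (anyNA(vals)) {
        warning(sum(is.na(vals)),
                " compartment(s) with undefined ", col, " dropped")
        comps <- comps[!is.na(vals), , drop = FALSE]
        vals <- vals[!is.na(vals)]
    }
    comps$is_positive <- vals > threshold
    n <- nrow(comps); k <- sum(comps$is_positive)
    cs <- new("CallSummary", nTotal = as.integer(n),
              nPositive = as.integer(k),
              fractionPositive = if (n > 0) k / n else NA_real_,
              ci95 = wilsonInterval(k, n))
    list(comps = comps, summary = cs)
}

#' Positive fraction over an incubation time course
#'
#' Applies one fixed threshold to the compartment tables of successive
#' timepoints (e.g. a viability-dye incubation series) and returns the
#' positive fraction with its Wilson interval at each time. A single
#' shared threshold keeps timepoints comparable.
#'
#' @param tables named or unnamed list of compartment tables, one per
#'   timepoint.
#' @param times numeric vector of timepoints (e.g. hours), same length.
#' @param threshold decision threshold applied to all timepoints.
#' @param mode passed to [classifyCompartments()].
#' @return data.frame with columns `time`, `n_total`, `n_positive`,
#'   `fraction_positive`, `ci_lo`, `ci_hi`; an empty table at a timepoint
#'   yields `n_total = 0` and `NA` fraction.
#' @export
positiveFractionTimecourse <- function(tables, times, threshold,
                                       mode = c("ratio", "signal")) {
    mode <- match.arg(mode)
    stopIfNot(length(tables) >= 1L, "need at least one timepoint")
    stopIfNot(length(tables) == length(times),
              "tables and times must have equal length")
    rows <- lapply(seq_along(tables), function(i) {
        tb <- tables[[i]]
        if (is.null(tb) || !nrow(tb))
            return(data.frame(time = times[i], n_total = 0L,
                              n_positive = 0L,
                              fraction_positive = NA_real_,
                              ci_lo = NA_real_, ci_hi = NA_real_))
        cs <- classifyCompartments(tb, threshold, mode)$summary
        data.frame(time = times[i], n_total = cs@nTotal,
                   n_positive = cs@nPositive,
                   fraction_positive = cs@fractionPositive,
                   ci_lo = cs@ci95[1L], ci_hi = cs@ci95[2L])
    })
    do.call(rbind, rows)
}
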