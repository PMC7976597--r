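#' Poisson occupancy probabilities of a digital compartment assay
#'
#' Exact Poisson probabilities of a compartment containing 0, exactly 1,
#' at least 1 and at least 2 entities at mean occupancy `lam`. At
#' `lam = 1` these give the familiar digital single-cell figures: 37 \%
#' empty, 63 \% occupied, 26 \% multiply occupied (after rounding to whole
#' percent).
#'
#' @param lam mean entities per compartment (>= 0).
#' @return an [OccupancyPmf-class] object.
#' @examples
#' p <- occupancyPmf(1)
#' round(100 * c(p@p0, p@pGe1, p@pGe2))  # 37 63 26
#' @export
occupancyPmf <- function(lam) {
    stopIfNot(.scalarNum(lam) && lam >= 0, "lam must be a single value >= 0")
    p0 <- dpois(0L, lam)
    p1 <- dpois(1L, lam)
    new("OccupancyPmf", lam = lam, p0 = p0, p1 = p1,
        pGe1 = 1 - p0, pGe2 = 1 - p0 - p1)
}

#' Estimate mean occupancy from the negative-partition fraction
#'
#' The digital-assay inversion lambda = -ln(nNegative / nTotal): the
#' fraction of dark partitions estimates the Poisson zero class, from
#' which the mean copies per partition follows. A run with no negative
#' partitions is saturated — only the lower bound ln(nTotal) (from fewer
#' than one expected negative) can be stated, and an error carrying that
#' bound is raised.
#'
#' @param nNegative,nTotal negative and total partition counts.
#' @return lambda, mean copies per partition (0 when all partitions are
#'   negative).
#' @examples
#' lambdaFromNegativeFraction(3679, 10000)  # about 1.0
#' @export
lambdaFromNegativeFraction <- function(nNegative, nTotal) {
    stopIfNot(.scalarInt(nTotal) && nTotal >= 1, "nTotal must be >= 1")
    stopIfNot(.scalarInt(nNegative) && nNegative >= 0 && nNegative <= nTotal,
              "need 0 <= nNegative <= nTotal")
    if (nNegative == 0)
        stop(sprintf(
            "saturated: no negative partitions; lambda exceeds ln(%d) = %.3f",
            as.integer(nTotal), log(nTotal)))
    -log(nNegative / nTotal)
}

#' Digital concentration estimate with a 95\% confidence interval
#'
#' Converts digital counts to a concentration in copies per microlitre:
#' c = 1000 * lambda / v with v the partition volume in nanolitres. The
#' interval uses the asymptotic (delta-method) variance of the lambda
#' estimator, var(lambda_hat) = (1 - p0) / (nTotal * p0) with
#' p0 = nNegative / nTotal, transformed to concentration units; a
#' seeded percentile bootstrap over partition counts is available as an
#' alternative under the same contract.
#'
#' @param nNegative,nTotal partition counts.
#' @param partitionVolume partition volume, nL.
#' @param ciMethod `"asymptotic"` (default) or `"bootstrap"`.
#' @param nBoot,seed bootstrap replicates and seed (bootstrap only).
#' @return a [DigitalResult-class] object.
#' @examples
#' res <- concentrationWithCI(3679, 10000, 2.8)
#' concentration(res)  # about 357 copies/uL
#' @export
concentrationWithCI <- function(nNegative, nTotal, partitionVolume,
                                ciMethod = c("asymptotic", "bootstrap"),
                                nBoot = 2000L, seed = 1L) {
    ciMethod <- match.arg(ciMethod)
    stopIfNot(.scalarNum(partitionVolume) && partitionVolume > 0,
              "partitionVolume must be > 0")
    if (nNegative == nTotal) {
        return(new("DigitalResult", nTotal = as.integer(nTotal),
                   nNegative = as.integer(nNegative), lambdaHat = 0,
                   partitionVolume = partitionVolume, concentration = 0,
                   ci95 = c(0, 1000 * 3 / nTotal / partitionVolume)))
    }
    lam <- lambdaFromNegativeFraction(nNegative, nTotal)
    scale <- 1000 / partitionVolume
    if (ciMethod == "asymptotic") {
        p0 <- nNegative / nTotal
        se <- sqrt((1 - p0) / (nTotal * p0))
        lamCI <- lam + c(-1, 1) * qnorm(0.975) * se
    } else {
        p0 <- nNegative / nTotal
        lamCI <- withLocalSeed(seed, step = 8L, {
            negB <- stats::rbinom(nBoot, nTotal, p0)
            negB[negB == 0L] <- 1L  # saturated resample: use the bound
            quantile(-log(negB / nTotal), c(0.025, 0.975), names = FALSE)
        })
    }
    lamCI[1L] <- max(lamCI[1L], 0)
    new("DigitalResult", nTotal = as.integer(nTotal),
        nNegative = as.integer(nNegative), lambdaHat = lam,
        partitionVolume = partitionVolume, concentration = scale * lam,
        ci95 = scale * lamCI)
}

#' Volume of a spherical compartment from its diameter
#'
#' v = (pi/6) d^3 * 1e-6 nL for d in micrometres. A 175 um droplet holds
#' 2.8 nL, the partition volume of the standard design.
#'
#' @param d diameter, um (>= 0; vectorised).
#' @return volume(s) in nanolitres.
#' @examples
#' volumeFromDiameter(175)  # 2.81 nL
#' @export
volumeFromDiameter <- function(d) {
    stopIfNot(all(is.finite(d)) && all(d >= 0), "d must be finite and >= 0")
    (pi / 6) * d^3 * 1e-6
}

#' Number of partitions a reaction volume can theoretically yield
#'
#' floor(1000 * reactionVolume / partitionVolume): a standard 20 uL
#' reaction split into 2.8 nL partitions yields more than 7000.
#'
#' @param reactionVolume reaction volume, uL (> 0).
#' @param partitionVolume partition volume, nL (> 0).
#' @return integer partition count.
#' @export
theoreticalPartitionCount <- function(reactionVolume, partitionVolume) {
    stopIfNot(.scalarNum(reactionVolume) && reactionVolume > 0,
              "reactionVolume must be > 0")
    stopIfNot(.scalarNum(partitionVolume) && partitionVolume > 0,
              "partitionVolume must be > 0")
    as.integer(floor(1000 * reactionVolume / partitionVolume))
}

#' Theoretical dynamic range of a digital assay design
#'
#' Computes, from the partition count and volume alone, the
#' concentration span a digital assay can quantify under explicit,
#' pluggable criteria:
#' \itemize{
#'   \item LOD: smallest concentration giving at least
#'     `minPositives` positive partitions with probability
#'     `detectConfidence` (binomial in n and p = 1 - exp(-lambda));
#'   \item lower quantification bound: smallest concentration at which
#'     the relative width of the expected-counts 95 \% CI of
#'     [concentrationWithCI()] drops to `maxRelCIWidth`;
#'   \item upper quantification bound: largest concentration still
#'     leaving `minExpectedNegatives` expected negative partitions.
#' }
#'
#' @param nPartitions number of partitions (>= 10).
#' @param partitionVolume partition volume, nL.
#' @param minPositives,detectConfidence,maxRelCIWidth,minExpectedNegatives
#'   the criteria; defaults 3, 0.95, 0.25, 3.
#' @return a [DynamicRange-class] object with the criteria echoed.
#' @examples
#' dynamicRange(7000, 2.8)  # upper bound on the order of 1e3 copies/uL
#' @export
dynamicRange <- function(nPartitions, partitionVolume,
                         minPositives = 3L, detectConfidence = 0.95,
                         maxRelCIWidth = 0.25, minExpectedNegatives = 3) {
    stopIfNot(.scalarInt(nPartitions) && nPartitions >= 10,
              "nPartitions must be >= 10")
    stopIfNot(.scalarNum(partitionVolume) && partitionVolume > 0,
              "partitionVolume must be > 0")
    toConc <- function(lam) 1000 * lam / partitionVolume
    n <- nPartitions

    ## LOD: P(#positives >= minPositives) >= detectConfidence, monotone
    ## increasing in lambda -> bisection
    pDetect <- function(lam) {
        p <- 1 - exp(-lam)
        1 - pbinom(minPositives - 1L, n, p)
    }
    lo <- 1e-9; hi <- 1
    while (pDetect(hi) < detectConfidence) hi <- hi * 2
    for (i in 1:200) {
        mid <- (lo + hi) / 2
        if (pDetect(mid) >= detectConfidence) hi <- mid else lo <- mid
    }
    lodLam <- hi

    ## lower quantification bound: relative CI width (expected counts)
    ## = 2 * 1.96 * sqrt((1 - p0) / (n p0)) / lambda, decreasing in lambda
    ## decreasing in lambda up to its minimum, then degrading again as
    ## negatives run out; search only the decreasing branch
    relWidth <- function(lam) {
        p0 <- exp(-lam)
        2 * qnorm(0.975) * sqrt((1 - p0) / (n * p0)) / lam
    }
    upperLam <- log(n / minExpectedNegatives)
    opt <- stats::optimize(relWidth, c(1e-9, upperLam))
    if (opt$objective > maxRelCIWidth) {
        ## criterion unattainable at this partition count: report the
        ## best-precision point instead (criteria list shows the rule)
        lowerLam <- opt$minimum
    } else {
        lo <- 1e-9; hi <- opt$minimum
        for (i in 1:200) {
            mid <- (lo + hi) / 2
            if (relWidth(mid) <= maxRelCIWidth) hi <- mid else lo <- mid
        }
        lowerLam <- hi
    }
    lowerLam <- min(max(lowerLam, lodLam), 0.99 * upperLam)

    new("DynamicRange", nPartitions = as.integer(n),
        partitionVolume = partitionVolume,
        lod = toConc(lodLam), lowerQuant = toConc(lowerLam),
        upperQuant = toConc(upperLam),
        criteria = list(minPositives = minPositives,
                        detectConfidence = detectConfidence,
                        maxRelCIWidth = maxRelCIWidth,
                        minExpectedNegatives = minExpectedNegatives))
}

#' Chi-square goodness of fit of observed occupancies to a Poisson law
#'
#' Compares an occupancy histogram (counts of compartments containing
#' k = 0, 1, 2, ... entities) to Poisson expectations. With
#' `lam = "fit"` the rate is the maximum-likelihood estimate (the sample
#' mean), costing one degree of freedom. Highest-k bins are pooled (the
#' last bin absorbing the upper tail mass) until every expected count is
#' at least 1, for small-sample stability.
#'
#' @param observed integer vector of counts for k = 0, 1, 2, ...
#' @param lam a fixed rate, or `"fit"` (default) for the MLE.
#' @return list with `lambda_used`, `observed` and `expected` (pooled),
#'   `chi2`, `dof`, `p_value`.
#' @export
occupancyGoodnessOfFit <- function(observed, lam = "fit") {
    stopIfNot(all(observed >= 0) && all(observed == round(observed)),
              "observed must be non-negative integer counts")
    n <- sum(observed)
    stopIfNot(n >= 10, "need at least 10 observations in total")
    ks <- seq_along(observed) - 1L
    fitted <- identical(lam, "fit")
    lamUsed <- if (fitted) sum(ks * observed) / n else {
        stopIfNot(.scalarNum(lam) && lam >= 0, "lam must be >= 0 or 'fit'")
        lam
    }
    expected <- n * dpois(ks, lamUsed)
    ## last bin absorbs the upper tail, then pool from the top until every
    ## expected cell >= 1
    expected[length(expected)] <- n * (1 - ppois(max(ks) - 1L, lamUsed))
    obs <- as.numeric(observed)
    while (length(expected) > 2L && expected[length(expected)] < 1) {
        k <- length(expected)
        expected[k - 1L] <- expected[k - 1L] + expected[k]
        obs[k - 1L] <- obs[k - 1L] + obs[k]
        expected <- expected[-k]; obs <- obs[-k]
    }
    chi2 <- sum((obs - expected)^2 / expected)
    dof <- max(length(obs) - 1L - as.integer(fitted), 1L)
    list(lambda_used = lamUsed, observed = obs, expected = expected,
         chi2 = chi2, dof = dof,
         p_value = pchisq(chi2, dof, lower.tail = FALSE))
}
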