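#' Binomial blood-sample observation of the mature pool
#'
#' For each clone and scheduled time t_j, the whole-animal mature population
#' m_i(t_j) is rounded to the nearest integer (ties to even) and the sampled
#' count drawn as s_i ~ Binomial(m_i, eta_j). The binomial form is the
#' small-fraction approximation of sampling without replacement, under which
#' clone draws are independent.
#'
#' @param mature a [MatureTrajectory-class]
#' @param schedule a [SamplingSchedule-class]; times must lie within the
#'   trajectory grid span
#' @param seed optional seed
#' @return a [SampleTable-class] with totals and richness computed
#' @examples
#' p <- ModelParams(cH0 = 5, K = 500, hspcInit = numeric())
#' st <- drawEngraftment(5, 5, h0Init = p@h00)
#' tr <- simulateHSC(p, st, tMax = 200, seed = 3)
#' mt <- assembleMature(tr, p, seq(0, 200))
#' sampleCounts(mt, SamplingSchedule(c(1, 3, 6), eta = 1e-3), seed = 4)
#' @export
sampleCounts <- function(mature, schedule, seed = NULL) {
    stopifnot(is(mature, "MatureTrajectory"),
              is(schedule, "SamplingSchedule"))
    tDays <- monthsToDays(schedule@timesMonths)
    if (min(tDays) < min(mature@tGrid) - 1e-9 ||
        max(tDays) > max(mature@tGrid) + 1e-9)
        stop("schedule times outside the trajectory grid span")
    nT <- length(tDays)
    C <- nrow(mature@m)
    cts <- matrix(0L, C, nT)
    withSeed(seed, {
        for (j in seq_len(nT)) {
            mAt <- interpColumns(mature@m, mature@tGrid, tDays[j])
            size <- as.integer(round(mAt))
            cts[, j] <- rbinom(C, size, schedule@etaJ[j])
        }
    })
    SampleTable(cts, timesMonths = schedule@timesMonths,
                cloneIds = mature@cloneIds)
}

# linear interpolation of every row of m at a single time point
interpColumns <- function(m, tGrid, t) {
    if (!nrow(m)) return(numeric())
    j <- findInterval(t, tGrid, all.inside = TRUE)
    w <- (t - tGrid[j]) / (tGrid[j + 1] - tGrid[j])
    m[, j] * (1 - w) + m[, j + 1] * w
}

#' Expected tagged sampled population S(t)
#'
#' Deterministic expectation of the sampled total: given the whole-animal
#' mature population M(t) (tagged plus untagged), the tagged sampled total
#' is S(t) = (H*/H) eta M(t), and the all-cell sampled total is eta M(t).
#' Both variants are returned and labelled, since published totals are
#' reported both ways.
#'
#' @param M total mature population path (numeric vector), or a
#'   [MatureTrajectory-class] from which colSums(m) + m0 is taken
#' @param params a [ModelParams-class] supplying eta and the tagged
#'   fraction H*/H
#' @return data.frame with columns `tagged` ((H*/H) eta M) and
#'   `total` (eta M)
#' @examples
#' expectedTaggedTotal(2e11, ModelParams())  # ~7e5 tagged cells sampled
#' @export
expectedTaggedTotal <- function(M, params) {
    if (is(M, "MatureTrajectory")) M <- colSums(M@m) + M@m0
    data.frame(tagged = params@taggedFraction * params@eta * M,
               total = params@eta * M)
}

#' Clone detection probability under binomial sampling
#'
#' A clone of whole-animal size m is seen in a sample with probability
#' 1 - (1 - eta)^m; small clones are easily missed at eta ~ 1e-5.
#'
#' @param m whole-animal clone size(s)
#' @param eta sampling fraction
#' @return detection probability for each `m`
#' @export
detectionProbability <- function(m, eta) {
    if (any(eta < 0 | eta > 1)) stop("eta must be in [0, 1]")
    1 - (1 - eta)^pmax(round(m), 0)
}
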