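#' Generate a ground-truthed synthetic clone-abundance table
#'
#' Runs the full forward model end-to-end: engraftment, the coupled
#' stochastic HSC birth-death process, Poisson differentiation events,
#' deterministic burst amplification to the mature pool (including the
#' transplanted-HSPC bursts and the untagged pool), and binomial sampling
#' at the scheduled times. Replaying the same (params, schedule, seed)
#' reproduces the identical table.
#'
#' @param params a [ModelParams-class]
#' @param schedule a [SamplingSchedule-class]
#' @param seed master seed
#' @param dropEmpty drop clones never observed in any sample from the
#'   returned table (they remain in the ground truth), mimicking real count
#'   tables which only list detected barcodes
#' @param gridDt mature-grid spacing in days
#' @return list(table = [SampleTable-class], truth = [GroundTruth-class])
#' @examples
#' ps <- makePreset("small_test")
#' ds <- generateDataset(ps$params, ps$schedule, seed = 42)
#' ds$table
#' @export
generateDataset <- function(params, schedule, seed = 1, dropEmpty = TRUE,
                            gridDt = 1) {
    stopifnot(is(params, "ModelParams"), is(schedule, "SamplingSchedule"))
    tMax <- max(monthsToDays(schedule@timesMonths)) + gridDt
    init <- drawEngraftment(cH = max(1, params@cH0),
                            nEngrafted = params@cH0,
                            h0Init = params@h00,
                            mode = "all_ones",
                            seed = deriveSeed(seed, 1))
    traj <- simulateHSC(params, init, tMax = tMax,
                        seed = deriveSeed(seed, 2), gridDt = gridDt)
    tGrid <- seq(0, tMax, by = gridDt)
    mat <- assembleMature(traj, params, tGrid)
    tab <- sampleCounts(mat, schedule, seed = deriveSeed(seed, 3))
    tDays <- monthsToDays(schedule@timesMonths)
    mAt <- vapply(tDays, function(tt) interpColumns(mat@m, tGrid, tt),
                  numeric(nrow(mat@m)))
    mAt <- matrix(mAt, nrow = nrow(mat@m),
                  dimnames = list(mat@cloneIds, colnames(tab)))
    nHsc <- length(traj@hInit)
    prov <- mat@origins
    prov$n_events <- c(lengths(traj@diffEvents),
                       rep(1L, nrow(prov) - nHsc))
    truth <- new("GroundTruth", params = params, schedule = schedule,
                 seed = as.numeric(seed), provenance = prov,
                 diffEvents = traj@diffEvents, matureAtSample = mAt)
    if (dropEmpty) {
        keep <- rowSums(cloneCounts(tab)) > 0
        tab <- SampleTable(cloneCounts(tab)[keep, , drop = FALSE],
                           timesMonths = schedule@timesMonths,
                           cloneIds = rownames(tab)[keep])
    }
    list(table = tab, truth = truth)
}

#' Reference parameter presets
#'
#' `"ZH33"` carries the granulocyte parameter set and 15-point sampling
#' schedule for animal ZH33, including the published per-time sampling
#' multipliers eta(t_j)/eta. `"small_test"` scales the system down (~20x:
#' C_h0 = 120, K = 1.2e4, L = 10, 8 time points over 12 months, eta raised
#' to 0.01 so that clones remain detectable at the reduced mature pool) so
#' the full pipeline runs in seconds; it is the workhorse of the test
#' suite.
#'
#' @param name "ZH33" or "small_test"
#' @return list(params = [ModelParams-class],
#'   schedule = [SamplingSchedule-class])
#' @export
makePreset <- function(name = c("ZH33", "small_test")) {
    name <- match.arg(name)
    if (name == "ZH33") {
        mult <- c(1, 2.03, 1.07, 0.94, 0.68, 1.25, 0.61, 0.83, 1.29, 1.29,
                  1.01, 1.01, 0.99, 1.14, 0.83)
        times <- c(1, 2, 3, 4.5, 6.5, 9.5, 12, 14, 21, 28, 30, 38, 43, 46,
                   49)
        params <- ModelParams(rH0 = 0.08, muH = 0.02, alpha = 0.016,
                              K = 2.5e5, cH0 = 2500, rN = 2, muN = 0,
                              omega = 0.2, L = 22L, muM = 0.185,
                              eta = 1e-5, etaAdjust = mult,
                              hspcInit = c("0" = 800, "1" = 1600,
                                           "2" = 3200),
                              taggedFraction = 0.35)
        schedule <- SamplingSchedule(times, eta = params@eta,
                                     multipliers = mult)
    } else {
        times <- c(0.5, 1, 2, 3, 5, 7, 9, 12)
        params <- ModelParams(rH0 = 0.08, muH = 0.02, alpha = 0.016,
                              K = 1.2e4, cH0 = 120, rN = 2, muN = 0,
                              omega = 0.2, L = 10L, muM = 0.185,
                              eta = 0.01,
                              hspcInit = c("0" = 40, "1" = 80,
                                           "2" = 160),
                              taggedFraction = 0.35)
        schedule <- SamplingSchedule(times, eta = params@eta)
    }
    list(params = params, schedule = schedule)
}
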