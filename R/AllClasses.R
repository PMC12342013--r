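#' Model parameters for the hybrid clonal-hematopoiesis model
#'
#' Holds every rate and capacity of the full model. All rates are per day,
#' populations in cells. Defaults are the granulocyte fit for animal ZH33
#' (see [makePreset()]).
#'
#' @slot rH0 intrinsic HSC self-renewal rate r_h(0) (/day, >= 0; zero gives
#'   the pure-death limit)
#' @slot muH HSC death rate (/day, >= 0)
#' @slot alpha HSC asymmetric differentiation rate (/day, >= 0)
#' @slot K niche carrying capacity (cells, > 0)
#' @slot cH0 initial number of tagged HSC clones C_h(0) (>= 0)
#' @slot h00 initial untagged HSC population h_0(0) (>= 0)
#' @slot rN progenitor division rate (/day, > 0)
#' @slot muN progenitor death rate (/day, >= 0)
#' @slot omega terminal differentiation rate of last-generation progenitors
#'   (/day, > 0)
#' @slot L proliferative potential: number of progenitor generations
#'   (integer >= 1)
#' @slot muM mature-cell turnover rate (/day, > 0)
#' @slot eta mean sampling fraction (0 < eta <= 1)
#' @slot etaAdjust optional per-time-point multipliers eta(t_j)/eta
#' @slot hspcInit named numeric: number of transplanted progenitor (HSPC)
#'   clones per origin generation, names are generations 0..L
#' @slot taggedFraction fraction of engrafted HSCs that carry a barcode,
#'   H*/H in (0, 1]
#'
#' @seealso [ModelParams()]
#' @exportClass ModelParams
setClass("ModelParams",
    slots = c(
        rH0 = "numeric", muH = "numeric", alpha = "numeric", K = "numeric",
        cH0 = "numeric", h00 = "numeric",
        rN = "numeric", muN = "numeric", omega = "numeric", L = "integer",
        muM = "numeric", eta = "numeric", etaAdjust = "numeric",
        hspcInit = "numeric", taggedFraction = "numeric"))

setValidity("ModelParams", function(object) {
    msg <- character()
    sc1 <- function(x, nm) if (length(slot(object, x)) != 1 ||
        !is.finite(slot(object, x))) c(nm) else character()
    for (s in c("rH0", "muH", "alpha", "K", "cH0", "h00", "rN", "muN",
                "omega", "muM", "eta", "taggedFraction"))
        msg <- c(msg, sc1(s, sprintf("'%s' must be a finite scalar", s)))
    if (length(msg)) return(msg)
    if (object@rH0 < 0) msg <- c(msg, "rH0 must be >= 0")
    if (object@muH < 0) msg <- c(msg, "muH must be >= 0")
    if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
    if (object@K <= 0) msg <- c(msg, "K must be > 0")
    if (object@cH0 < 0) msg <- c(msg, "cH0 must be >= 0")
    if (object@h00 < 0) msg <- c(msg, "h00 must be >= 0")
    if (object@rN <= 0) msg <- c(msg, "rN must be > 0")
    if (object@muN < 0) msg <- c(msg, "muN must be >= 0")
    if (object@omega <= 0) msg <- c(msg, "omega must be > 0")
    if (length(object@L) != 1 || object@L < 1L)
        msg <- c(msg, "L must be an integer >= 1")
    if (object@muM <= 0) msg <- c(msg, "muM must be > 0")
    if (object@eta <= 0 || object@eta > 1)
        msg <- c(msg, "eta must be in (0, 1]")
    if (object@taggedFraction <= 0 || object@taggedFraction > 1)
        msg <- c(msg, "taggedFraction must be in (0, 1]")
    if (length(object@hspcInit)) {
        gen <- suppressWarnings(as.numeric(names(object@hspcInit)))
        if (any(is.na(gen)) || any(gen < 0) || any(gen > object@L))
            msg <- c(msg, "hspcInit generations must satisfy 0 <= l <= L")
        if (any(object@hspcInit < 0))
            msg <- c(msg, "hspcInit counts must be >= 0")
    }
    if (length(object@etaAdjust) && any(object@etaAdjust <= 0))
        msg <- c(msg, "etaAdjust multipliers must be > 0")
    if (length(msg)) msg else TRUE
})

#' Blood-sampling schedule
#'
#' Sampling times in months together with the absolute per-time sampling
#' fractions eta(t_j) (mean fraction times per-time multiplier).
#'
#' @slot timesMonths strictly increasing sampling times (months)
#' @slot etaJ per-time sampling fractions, each in [0, 1]
#' @exportClass SamplingSchedule
setClass("SamplingSchedule",
    slots = c(timesMonths = "numeric", etaJ = "numeric"))

setValidity("SamplingSchedule", function(object) {
    msg <- character()
    if (length(object@timesMonths) < 1)
        msg <- c(msg, "at least one sampling time required")
    if (any(diff(object@timesMonths) <= 0))
        msg <- c(msg, "sampling times must be strictly increasing")
    if (length(object@etaJ) != length(object@timesMonths))
        msg <- c(msg, "etaJ must match timesMonths in length")
    if (any(object@etaJ < 0 | object@etaJ > 1))
        msg <- c(msg, "etaJ must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Clone-by-time abundance table
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a single integer
#' `counts` assay (rows = barcode clones, columns = sampling time points).
#' `colData` stores the sampling time in months plus the per-sample totals
#' S(t_j) and richness C_s(t_j); validity recomputes both from the matrix.
#'
#' @exportClass SampleTable
setClass("SampleTable", contains = "SummarizedExperiment")

setValidity("SampleTable", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is missing")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be nonnegative")
    if (any(cts != round(cts))) msg <- c(msg, "counts must be integers")
    cd <- SummarizedExperiment::colData(object)
    need <- c("time_months", "total", "richness")
    if (!all(need %in% colnames(cd)))
        return(paste("colData must contain", paste(need, collapse = ", ")))
    if (ncol(cts) > 1 && any(diff(cd$time_months) <= 0))
        msg <- c(msg, "sampling times must be strictly increasing")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate clone identifiers")
    tot <- if (nrow(cts)) unname(colSums(cts)) else rep(0, ncol(cts))
    ric <- if (nrow(cts)) unname(colSums(cts > 0)) else rep(0, ncol(cts))
    if (!isTRUE(all.equal(tot, unname(cd$total))))
        msg <- c(msg, "stored totals do not match column sums")
    if (!isTRUE(all.equal(ric, unname(cd$richness))))
        msg <- c(msg, "stored richness does not match nonzero counts")
    if (length(msg)) msg else TRUE
})

#' Engraftment initial condition for the HSC pool
#'
#' @slot hInit integer vector of initial tagged clone sizes h_i(0)
#' @slot h0Init initial untagged HSC population (deterministic, real-valued)
#' @exportClass EngraftmentState
setClass("EngraftmentState",
    slots = c(hInit = "integer", h0Init = "numeric"))

setValidity("EngraftmentState", function(object) {
    msg <- character()
    if (any(object@hInit < 0)) msg <- c(msg, "clone sizes must be >= 0")
    if (length(object@h0Init) != 1 || object@h0Init < 0)
        msg <- c(msg, "h0Init must be a nonnegative scalar")
    if (length(msg)) msg else TRUE
})

#' Stochastic HSC trajectory
#'
#' Event-resolved output of the Gillespie simulation: jump times with the
#' affected clone and the population change, the untagged pool tabulated on a
#' uniform grid, and (once drawn) the per-clone differentiation event times.
#'
#' @slot eventLog data.frame with columns time, clone (1-based index),
#'   delta (+1 birth / -1 death)
#' @slot hInit initial tagged clone sizes
#' @slot gridT uniform time grid (days)
#' @slot h0Grid untagged population on `gridT`
#' @slot hstarGrid total tagged population on `gridT`
#' @slot hFinal final tagged clone sizes
#' @slot tMax simulation horizon (days)
#' @slot diffEvents list (one numeric vector per clone) of differentiation
#'   event times T_k
#' @exportClass HSCTrajectory
setClass("HSCTrajectory",
    slots = c(eventLog = "data.frame", hInit = "integer", gridT = "numeric",
              h0Grid = "numeric", hstarGrid = "numeric", hFinal = "integer",
              tMax = "numeric", diffEvents = "list"))

setValidity("HSCTrajectory", function(object) {
    msg <- character()
    ev <- object@eventLog
    if (!all(c("time", "clone", "delta") %in% names(ev)))
        return("eventLog needs columns time, clone, delta")
    if (nrow(ev) && (min(ev$time) < 0 || max(ev$time) > object@tMax))
        msg <- c(msg, "event times outside [0, tMax]")
    if (nrow(ev) && is.unsorted(ev$time))
        msg <- c(msg, "event times must be nondecreasing")
    if (any(object@hFinal < 0)) msg <- c(msg, "negative final population")
    if (sum(object@hInit) + sum(ev$delta) != sum(object@hFinal))
        msg <- c(msg, "event deltas inconsistent with final populations")
    if (length(object@diffEvents)) {
        rng <- range(c(0, unlist(object@diffEvents, use.names = FALSE)))
        if (rng[1] < 0 || rng[2] > object@tMax)
            msg <- c(msg, "differentiation times outside [0, tMax]")
    }
    if (length(msg)) msg else TRUE
})

#' Mature-cell response to a single differentiation event
#'
#' Deterministic burst m(t) of mature cells produced by one founding cell of
#' generation `originGeneration` (0 for an HSC-derived progenitor, > 0 for a
#' transplanted HSPC), tabulated on a uniform grid.
#'
#' @slot tGrid uniform time grid (days), starting at 0
#' @slot values m(t) on the grid
#' @slot originGeneration generation of the founding cell
#' @slot dt grid spacing (days)
#' @slot totalYield integral of mu_m * m(t) dt: total mature cells ever
#'   produced (equals 2^(L - l0) when mu_n = 0)
#' @exportClass BurstKernel
setClass("BurstKernel",
    slots = c(tGrid = "numeric", values = "numeric",
              originGeneration = "integer", dt = "numeric",
              totalYield = "numeric"))

setValidity("BurstKernel", function(object) {
    msg <- character()
    if (length(object@tGrid) != length(object@values))
        msg <- c(msg, "grid and values differ in length")
    if (length(object@values) && abs(object@values[1]) > 1e-12)
        msg <- c(msg, "m(0) must be 0")
    if (any(object@values < -1e-12)) msg <- c(msg, "m(t) must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Per-clone mature-cell trajectories
#'
#' @slot tGrid uniform time grid (days)
#' @slot m matrix, clones x time, mature population m_i(t)
#' @slot m0 untagged mature population on the grid
#' @slot cloneIds clone identifiers (rownames of `m`)
#' @slot origins data.frame(clone_id, origin, generation) describing whether
#'   each clone descends from an engrafted HSC or a transplanted HSPC
#' @exportClass MatureTrajectory
setClass("MatureTrajectory",
    slots = c(tGrid = "numeric", m = "matrix", m0 = "numeric",
              cloneIds = "character", origins = "data.frame"))

setValidity("MatureTrajectory", function(object) {
    msg <- character()
    if (nrow(object@m) != length(object@cloneIds))
        msg <- c(msg, "m must have one row per clone")
    if (ncol(object@m) != length(object@tGrid))
        msg <- c(msg, "m must have one column per grid time")
    if (length(object@m) && min(object@m) < -1e-9)
        msg <- c(msg, "mature populations must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Per-clone summary statistics (clone cloud)
#'
#' One record per clone detected in the chosen time window: mean sampled
#' abundance, population standard deviation (divisor J, zeros included) and,
#' after [kdeDensity()], the local clone density rho_i.
#'
#' @slot records data.frame(clone_id, mean, sd, density)
#' @slot windowMonths c(lo, hi) window applied to sampling times
#' @slot jEffective number of time points inside the window
#' @slot transform coordinate transform used for the KDE
#'   ("log10p" = log10(1 + x), or "linear")
#' @slot bandwidth KDE bandwidth in transformed coordinates (NA before KDE)
#' @slot densityFun evaluable density (function of an n x 2 matrix in data
#'   coordinates), or NULL before KDE
#' @exportClass CloneCloud
setClass("CloneCloud",
    slots = c(records = "data.frame", windowMonths = "numeric",
              jEffective = "integer", transform = "character",
              bandwidth = "numeric", densityFun = "ANY"))

setValidity("CloneCloud", function(object) {
    msg <- character()
    need <- c("clone_id", "mean", "sd", "density")
    if (!all(need %in% names(object@records)))
        return(paste("records needs columns", paste(need, collapse = ", ")))
    if (any(object@records$sd < 0)) msg <- c(msg, "sd must be >= 0")
    if (anyDuplicated(object@records$clone_id))
        msg <- c(msg, "duplicate clone records")
    if (length(msg)) msg else TRUE
})

#' Weighted k-means compression of a clone cloud
#'
#' @slot centers k x 2 matrix of cluster centers in (mean, sd) space,
#'   possibly in transformed coordinates (see `transform`)
#' @slot weights fraction of clones per cluster (sums to 1)
#' @slot k selected cluster count
#' @slot inertiaCurve data.frame(k, distortion) over the candidate range
#' @slot transform coordinate system of `centers`
#' @exportClass ClusterSet
setClass("ClusterSet",
    slots = c(centers = "matrix", weights = "numeric", k = "integer",
              inertiaCurve = "data.frame", transform = "character"))

setValidity("ClusterSet", function(object) {
    msg <- character()
    if (nrow(object@centers) != length(object@weights))
        msg <- c(msg, "one weight per center required")
    if (any(object@weights < 0)) msg <- c(msg, "weights must be >= 0")
    if (length(object@weights) &&
        abs(sum(object@weights) - 1) > 1e-8)
        msg <- c(msg, "weights must sum to 1")
    if (length(object@centers) && any(!is.finite(object@centers)))
        msg <- c(msg, "centers must be finite")
    if (length(msg)) msg else TRUE
})

#' Earth mover's distance result
#'
#' @slot distance normalized minimal transport cost (>= 0)
#' @slot flow optimal flow matrix f[k, l] >= 0
#' @exportClass EMDResult
setClass("EMDResult", slots = c(distance = "numeric", flow = "matrix"))

setValidity("EMDResult", function(object) {
    msg <- character()
    if (object@distance < -1e-12) msg <- c(msg, "distance must be >= 0")
    if (length(object@flow) && min(object@flow) < -1e-9)
        msg <- c(msg, "flows must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Result of the staged fitting pipeline
#'
#' @slot bestParams selected [ModelParams-class]
#' @slot stageRecords named list of per-stage records (candidate grids,
#'   objectives, selections, or a "skipped" marker)
#' @slot etaMultipliers fitted per-time-point eta(t_j)/eta adjustments
#' @slot finalEmd EMD of the selected candidate (>= 0)
#' @slot replicates stochastic simulation replicates per candidate
#' @slot seed master seed the pipeline was run with
#' @exportClass FitResult
setClass("FitResult",
    slots = c(bestParams = "ModelParams", stageRecords = "list",
              etaMultipliers = "numeric", finalEmd = "numeric",
              replicates = "integer", seed = "numeric"))

setValidity("FitResult", function(object) {
    if (length(object@finalEmd) == 1 && is.finite(object@finalEmd) &&
        object@finalEmd < -1e-12) return("finalEmd must be >= 0")
    TRUE
})

#' Ground truth sidecar for a synthetic dataset
#'
#' @slot params generating [ModelParams-class]
#' @slot schedule generating [SamplingSchedule-class]
#' @slot seed master seed (replaying params/schedule/seed reproduces the
#'   identical table)
#' @slot provenance data.frame(clone_id, origin, generation, n_events)
#' @slot diffEvents per-clone differentiation times (HSC clones)
#' @slot matureAtSample matrix of true m_i(t_j) at the sampling times
#' @exportClass GroundTruth
setClass("GroundTruth",
    slots = c(params = "ModelParams", schedule = "SamplingSchedule",
              seed = "numeric", provenance = "data.frame",
              diffEvents = "list", matureAtSample = "matrix"))
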