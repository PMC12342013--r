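#' Construct model parameters
#'
#' Defaults are the granulocyte parameter set for animal ZH33: mu_h = 0.02,
#' r_h(0) = 0.08, C_h(0) = 2500, K = 2.5e5, alpha = 0.016, r_n = 2, L = 22,
#' mu_n = 0, mu_m = 0.185, omega = 0.2, eta = 1e-5, transplanted HSPC clones
#' C_n(l = 0, 1, 2) = (800, 1600, 3200), tagged fraction 0.35.
#'
#' The untagged initial pool defaults to the GFP+ bookkeeping
#' h_0(0) = C_h(0) * (1/taggedFraction - 1), so that tagged cells make up
#' `taggedFraction` of the engrafted HSC pool.
#'
#' @param rH0,muH,alpha,K,cH0,rN,muN,omega,L,muM,eta model rates and
#'   capacities, all rates per day (see [ModelParams-class])
#' @param h00 initial untagged HSC count; default derived from
#'   `taggedFraction`
#' @param etaAdjust optional per-time-point multipliers eta(t_j)/eta
#' @param hspcInit named numeric vector: transplanted HSPC clones per origin
#'   generation (names "0", "1", ...), each clone starting as one cell
#' @param taggedFraction fraction H*/H of tagged cells among engrafted HSCs
#' @return a validated [ModelParams-class] object
#' @examples
#' p <- ModelParams(cH0 = 120, K = 1.2e4)
#' p
#' @export
ModelParams <- function(rH0 = 0.08, muH = 0.02, alpha = 0.016, K = 2.5e5,
                        cH0 = 2500, h00 = NULL, rN = 2, muN = 0,
                        omega = 0.2, L = 22L, muM = 0.185, eta = 1e-5,
                        etaAdjust = numeric(),
                        hspcInit = c("0" = 800, "1" = 1600, "2" = 3200),
                        taggedFraction = 0.35) {
    if (is.null(h00)) h00 <- cH0 * (1 / taggedFraction - 1)
    new("ModelParams", rH0 = rH0, muH = muH, alpha = alpha, K = K,
        cH0 = cH0, h00 = h00, rN = rN, muN = muN, omega = omega,
        L = as.integer(L), muM = muM, eta = eta, etaAdjust = etaAdjust,
        hspcInit = hspcInit, taggedFraction = taggedFraction)
}

#' Update selected fields of a ModelParams object
#'
#' @param params a [ModelParams-class]
#' @param ... named fields to replace (constructor argument names)
#' @param rederiveH00 when TRUE (default) and `h00` is not given explicitly,
#'   recompute h_0(0) from cH0 and taggedFraction
#' @return updated [ModelParams-class]
#' @export
updateParams <- function(params, ..., rederiveH00 = TRUE) {
    upd <- list(...)
    cur <- paramsAsList(params)
    for (nm in names(upd)) {
        if (!nm %in% names(cur)) stop("unknown parameter: ", nm)
        cur[[nm]] <- upd[[nm]]
    }
    if (rederiveH00 && !"h00" %in% names(upd)) cur$h00 <- NULL
    do.call(ModelParams, cur)
}

#' Convert ModelParams to/from a plain named list
#'
#' Used by the config and fit-report readers/writers; the list element names
#' are the constructor arguments of [ModelParams()].
#'
#' @param params a [ModelParams-class]
#' @return `paramsAsList`: a named list with every field of the object
#' @export
paramsAsList <- function(params) {
    stopifnot(is(params, "ModelParams"))
    list(rH0 = params@rH0, muH = params@muH, alpha = params@alpha,
         K = params@K, cH0 = params@cH0, h00 = params@h00, rN = params@rN,
         muN = params@muN, omega = params@omega, L = params@L,
         muM = params@muM, eta = params@eta, etaAdjust = params@etaAdjust,
         hspcInit = params@hspcInit, taggedFraction = params@taggedFraction)
}

#' @rdname paramsAsList
#' @param x a named list as produced by `paramsAsList`
#' @export
paramsFromList <- function(x) {
    x <- x[!vapply(x, is.null, logical(1))]
    if (!is.null(x$etaAdjust)) x$etaAdjust <- as.numeric(x$etaAdjust)
    if (!is.null(x$hspcInit)) {
        h <- unlist(x$hspcInit)
        x$hspcInit <- setNames(as.numeric(h), names(h))
    }
    do.call(ModelParams, x)
}

setMethod("show", "ModelParams", function(object) {
    cat("ModelParams (rates /day)\n")
    cat(sprintf("  HSC:        rH0 = %g, muH = %g, alpha = %g, K = %g\n",
                object@rH0, object@muH, object@alpha, object@K))
    cat(sprintf("  clones:     C_h(0) = %g tagged, h_0(0) = %g untagged",
                object@cH0, object@h00))
    cat(sprintf(" (tagged fraction %g)\n", object@taggedFraction))
    cat(sprintf("  progenitor: rN = %g, muN = %g, omega = %g, L = %d\n",
                object@rN, object@muN, object@omega, object@L))
    cat(sprintf("  mature:     muM = %g;  sampling eta = %g\n",
                object@muM, object@eta))
    if (length(object@hspcInit))
        cat("  HSPC clones:",
            paste(sprintf("C_n(%s) = %g", names(object@hspcInit),
                          object@hspcInit), collapse = ", "), "\n")
})

#' Construct a sampling schedule
#'
#' @param timesMonths strictly increasing sampling times in months
#' @param eta mean sampling fraction
#' @param multipliers per-time multipliers eta(t_j)/eta (default all 1)
#' @return a [SamplingSchedule-class]
#' @examples
#' SamplingSchedule(c(1, 2, 3, 6, 12), eta = 1e-5)
#' @export
SamplingSchedule <- function(timesMonths, eta = 1e-5,
                             multipliers = rep(1, length(timesMonths))) {
    new("SamplingSchedule", timesMonths = timesMonths,
        etaJ = eta * multipliers)
}

#' @rdname cloneburst-generics
setMethod("sampleTimes", "SamplingSchedule",
          function(x, ...) x@timesMonths)

setMethod("show", "SamplingSchedule", function(object) {
    cat("SamplingSchedule:", length(object@timesMonths), "time points,",
        sprintf("%g-%g months\n", min(object@timesMonths),
                max(object@timesMonths)))
    cat("  eta(t_j):", paste(signif(object@etaJ, 3), collapse = " "), "\n")
})

# Build a SamplingSchedule from a ModelParams (eta + etaAdjust) and times.
scheduleFromParams <- function(params, timesMonths) {
    mult <- params@etaAdjust
    if (!length(mult)) mult <- rep(1, length(timesMonths))
    if (length(mult) != length(timesMonths))
        stop("etaAdjust length does not match the sampling times")
    SamplingSchedule(timesMonths, eta = params@eta, multipliers = mult)
}
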