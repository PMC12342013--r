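#' Draw the engraftment initial condition
#'
#' Models the transplant bottleneck: `nEngrafted` barcoded cells land in the
#' niche out of `hStar` injected tagged cells carrying `cH` distinct
#' barcodes. In `"multinomial"` mode the engrafted cells are thrown into the
#' `cH` equally likely barcode boxes (the marginal engraftment distribution
#' obtained by averaging the hypergeometric draw over the symmetric
#' multinomial injection) and empty boxes are dropped; in `"all_ones"` mode
#' each engrafted clone starts from exactly one cell, the simplification
#' appropriate when the engraftment fraction is small.
#'
#' @param cH barcode richness of the injected pool (>= 1)
#' @param nEngrafted number of tagged cells that engraft
#' @param hStar number of tagged cells injected (checked when given)
#' @param mode "all_ones" (default) or "multinomial"
#' @param h0Init untagged engrafted population (deterministic)
#' @param seed optional seed; when NULL the current RNG state is used
#' @return an [EngraftmentState-class]
#' @examples
#' drawEngraftment(cH = 10, nEngrafted = 10)         # ten singleton clones
#' drawEngraftment(cH = 4, nEngrafted = 100, mode = "multinomial", seed = 1)
#' @export
drawEngraftment <- function(cH, nEngrafted, hStar = NULL,
                            mode = c("all_ones", "multinomial"),
                            h0Init = 0, seed = NULL) {
    mode <- match.arg(mode)
    if (cH < 1) stop("cH must be >= 1")
    if (!is.null(hStar) && nEngrafted > hStar)
        stop("nEngrafted exceeds the number of injected tagged cells")
    h <- withSeed(seed, {
        if (mode == "all_ones") rep(1L, nEngrafted)
        else {
            counts <- as.integer(rmultinom(1, nEngrafted, rep(1, cH)))
            counts[counts > 0]
        }
    })
    new("EngraftmentState", hInit = as.integer(h), h0Init = h0Init)
}

# logistic coefficients: dh/dt = a*h - b*h^2
logisticCoef <- function(params) {
    list(a = params@rH0 - params@muH, b = params@rH0 / params@K)
}

#' Expected total HSC population under logistic regulation
#'
#' Closed-form solution of dh/dt = r_h(0) (1 - h/K) h - mu_h h. With
#' r_h(0) > mu_h the population approaches the effective capacity
#' K (1 - mu_h / r_h(0)); with r_h(0) <= mu_h it decays to zero.
#'
#' @param t time(s) in days, >= 0
#' @param params a [ModelParams-class]
#' @param hTotal0 initial total population; defaults to
#'   cH0 + h00 from `params`
#' @return expected population at each `t`
#' @examples
#' p <- ModelParams()
#' logisticMean(c(0, 30, 300, 1e5), p)
#' @export
logisticMean <- function(t, params, hTotal0 = params@cH0 + params@h00) {
    if (any(t < 0)) stop("t must be >= 0")
    co <- logisticCoef(params)
    a <- co$a; b <- co$b
    if (hTotal0 == 0) return(rep(0, length(t)))
    if (abs(a) < 1e-14) return(hTotal0 / (1 + b * hTotal0 * t))
    e <- exp(a * t)
    out <- a * hTotal0 * e / (a + b * hTotal0 * (e - 1))
    # a > 0 and t -> Inf gives exp overflow; limit is the fixed point a/b
    big <- !is.finite(e)
    if (any(big)) out[big] <- if (a > 0) a / b else 0
    out
}

# integral of the logistic mean from 0 to t (closed form)
logisticMeanIntegral <- function(t, params, hTotal0) {
    co <- logisticCoef(params)
    a <- co$a; b <- co$b
    if (hTotal0 == 0) return(rep(0, length(t)))
    if (abs(a) < 1e-14) return(log1p(b * hTotal0 * t) / b)
    e <- expm1(a * t)
    arg <- 1 + b * hTotal0 * e / a
    out <- log(arg) / b
    big <- !is.finite(e) | !is.finite(arg)
    if (any(big)) {
        # large-t asymptote: integral ~ (a/b) * t + const
        if (a > 0) {
            cst <- log(b * hTotal0 / a) / b
            out[big] <- a * t[big] / b + cst
        } else out[big] <- log(1 - b * hTotal0 / a) / b
    }
    out
}

# psi(t) = exp(-int_0^t (r_h(t') - mu_h) dt') on the logistic mean path
richnessPsi <- function(t, params, hTotal0) {
    I <- logisticMeanIntegral(t, params, hTotal0)
    exp(-(params@rH0 - params@muH) * t + (params@rH0 / params@K) * I)
}

#' Expected tagged-clone richness E[C_h(t)]
#'
#' Generating-function result for the expected number of surviving clones in
#' a birth-death process whose per-cell birth rate r_h(t) is evaluated on the
#' deterministic logistic mean path: E[C_h(t)] = C_h(0) / (psi(t) + phi(t))
#' with psi(t) = exp(-int (r_h - mu_h)) and phi(t) = int r_h psi. The
#' implementation uses the equivalent form psi + phi = 1 + mu_h int_0^t psi,
#' which makes the result exactly nonincreasing in t and equal to C_h(0)
#' for all t when mu_h = 0.
#'
#' @inheritParams logisticMean
#' @param tol relative quadrature tolerance for int psi
#' @return expected clone count at each `t`, bounded by `cH0`
#' @examples
#' expectedRichness(c(0, 300, 1470), ModelParams())
#' @export
expectedRichness <- function(t, params, hTotal0 = params@cH0 + params@h00,
                             tol = 1e-5) {
    if (any(t < 0)) stop("t must be >= 0")
    if (params@muH == 0) return(rep(params@cH0, length(t)))
    tmax <- max(t, 1e-6)
    quad <- function(n) {
        g <- seq(0, tmax, length.out = n)
        psi <- richnessPsi(g, params, hTotal0)
        cs <- c(0, cumsum((psi[-1] + psi[-n]) / 2 * diff(g)))
        approx(g, cs, xout = t, rule = 2)$y
    }
    n <- max(8001L, min(40001L, as.integer(tmax * 20) + 1L))
    I1 <- quad(n); I2 <- quad(2L * n - 1L)
    relerr <- max(abs(I2 - I1) / pmax(abs(I2), 1e-12))
    if (relerr > 1e-4)
        stop(sprintf(
            "richness quadrature did not converge (rel. err %.3g > 1e-4)",
            relerr))
    if (relerr > tol)
        warning(sprintf("richness quadrature tolerance %.1g not reached
  (achieved %.3g)", tol, relerr))
    params@cH0 / (1 + params@muH * I2)
}

#' Simulate the coupled HSC birth-death process (Gillespie)
#'
#' Exact jump simulation of the tagged HSC clones: each cell proliferates at
#' the clamped logistic rate max(0, r_h(0) (1 - h/K)) and dies at rate mu_h,
#' where h(t) is the total pool including the untagged population, which is
#' propagated deterministically on the same clock. Extinct clones stay
#' extinct. After the birth-death path is drawn, per-clone differentiation
#' event times are sampled from the inhomogeneous Poisson process of
#' intensity alpha * h_i(t) (asymmetric differentiation: events do not
#' deplete the HSC count).
#'
#' @param params a [ModelParams-class]
#' @param init an [EngraftmentState-class]
#' @param tMax horizon in days (> 0)
#' @param seed optional master seed; per-clone differentiation streams are
#'   derived from it so they are reproducible independent of processing
#'   order
#' @param gridDt spacing (days) of the grid on which the untagged pool and
#'   tagged total are tabulated
#' @param dtMax rates are refreshed at least this often (days)
#' @param drawDiff draw differentiation times (skipped when alpha = 0)
#' @return an [HSCTrajectory-class]
#' @examples
#' st <- drawEngraftment(cH = 50, nEngrafted = 50, h0Init = 100)
#' tr <- simulateHSC(ModelParams(cH0 = 50, K = 1000), st, tMax = 100,
#'                   seed = 7)
#' tr
#' @export
simulateHSC <- function(params, init, tMax, seed = NULL, gridDt = 1,
                        dtMax = 0.2, drawDiff = TRUE) {
    stopifnot(is(params, "ModelParams"), is(init, "EngraftmentState"))
    if (tMax <= 0) stop("tMax must be > 0")
    res <- withSeed(seed, cpp_simulate_hsc(
        init@hInit, init@h0Init, params@rH0, params@muH, params@K,
        tMax, dtMax, gridDt))
    ev <- data.frame(time = res$time, clone = res$clone, delta = res$delta)
    traj <- new("HSCTrajectory", eventLog = ev, hInit = init@hInit,
                gridT = res$grid_t, h0Grid = res$h0_grid,
                hstarGrid = res$hstar_grid, hFinal = res$h_final,
                tMax = tMax, diffEvents = list())
    if (drawDiff && params@alpha > 0) {
        C <- length(init@hInit)
        master <- if (is.null(seed)) {
            as.integer(runif(1, 0, .Machine$integer.max))
        } else as.integer(seed)
        de <- vector("list", C)
        byClone <- split(seq_len(nrow(ev)), factor(ev$clone, levels = 1:C))
        for (i in seq_len(C)) {
            idx <- byClone[[i]]
            path <- data.frame(
                t_start = c(0, ev$time[idx]),
                t_end = c(ev$time[idx], tMax),
                h = c(init@hInit[i], init@hInit[i] + cumsum(ev$delta[idx])))
            de[[i]] <- drawDifferentiationTimes(
                path, params@alpha, seed = deriveSeed(master, i))
        }
        traj@diffEvents <- de
    } else if (drawDiff) {
        traj@diffEvents <- rep(list(numeric()), length(init@hInit))
    }
    validObject(traj)
    traj
}

#' Sample differentiation event times for one clone
#'
#' Exact sampling of the inhomogeneous Poisson process with intensity
#' alpha * h_i(t) on a piecewise-constant population path: within each
#' segment the process is homogeneous, so the number of events is Poisson
#' with mean alpha * h * length and the events are uniform in the segment.
#' The expected total event count is alpha * int h_i dt.
#'
#' @param clonePath data.frame with columns t_start, t_end, h (the
#'   piecewise-constant population)
#' @param alpha differentiation rate (/day, >= 0)
#' @param seed optional seed
#' @return sorted numeric vector of event times
#' @export
drawDifferentiationTimes <- function(clonePath, alpha, seed = NULL) {
    if (alpha < 0) stop("alpha must be >= 0")
    stopifnot(all(c("t_start", "t_end", "h") %in% names(clonePath)))
    if (alpha == 0 || !nrow(clonePath)) return(numeric())
    withSeed(seed, {
        len <- clonePath$t_end - clonePath$t_start
        keep <- len > 0 & clonePath$h > 0
        if (!any(keep)) numeric()
        else {
            t0 <- clonePath$t_start[keep]
            len <- len[keep]
            n <- rpois(length(len), alpha * clonePath$h[keep] * len)
            tot <- sum(n)
            if (tot == 0) numeric()
            else {
                idx <- rep.int(seq_along(n), n)
                sort(t0[idx] + runif(tot) * len[idx])
            }
        }
    })
}

#' @rdname cloneburst-generics
setMethod("clonePath", "HSCTrajectory", function(x, clone, ...) {
    ev <- x@eventLog
    idx <- which(ev$clone == clone)
    data.frame(
        t_start = c(0, ev$time[idx]),
        t_end = c(ev$time[idx], x@tMax),
        h = c(x@hInit[clone], x@hInit[clone] + cumsum(ev$delta[idx])))
})

#' @rdname cloneburst-generics
setMethod("totalPath", "HSCTrajectory", function(x, ...) {
    data.frame(time = x@gridT, hstar = x@hstarGrid, h0 = x@h0Grid,
               total = x@hstarGrid + x@h0Grid)
})

#' @rdname cloneburst-generics
setMethod("diffEvents", "HSCTrajectory", function(x, ...) x@diffEvents)

setMethod("show", "HSCTrajectory", function(object) {
    cat("HSCTrajectory:", length(object@hInit), "tagged clones,",
        nrow(object@eventLog), "birth/death events over",
        object@tMax, "days\n")
    cat(sprintf("  tagged  h*: %d -> %d cells (%d surviving clones)\n",
                sum(object@hInit), sum(object@hFinal),
                sum(object@hFinal > 0)))
    cat(sprintf("  untagged h0: %.1f -> %.1f cells\n",
                object@h0Grid[1], tail(object@h0Grid, 1)))
    if (length(object@diffEvents))
        cat("  differentiation events:",
            sum(lengths(object@diffEvents)), "\n")
})
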