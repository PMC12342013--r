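#' Progenitor cascade populations from a single founding cell
#'
#' Closed-form solution of the linear transit-amplifying cascade seeded with
#' one generation-`origin` cell at t = 0, all generations sharing division
#' rate r_n and death rate mu_n:
#' n^(l)(t) = (2 r_n t)^(l - l0) / (l - l0)! * exp(-(r_n + mu_n) t).
#'
#' @param t time(s) in days
#' @param gen generation l to evaluate, origin <= l <= L - 1 (the terminal
#'   generation L is handled by [terminalPopulation()])
#' @param params a [ModelParams-class]
#' @param origin generation l0 of the founding cell
#' @return n^(l)(t) at each `t`
#' @examples
#' p <- ModelParams()
#' cascadePopulation(c(0, 1, 5), gen = 3, p)
#' @export
cascadePopulation <- function(t, gen, params, origin = 0L) {
    gen <- as.integer(gen); origin <- as.integer(origin)
    if (gen < origin || gen > params@L - 1L)
        stop("gen must satisfy origin <= gen <= L - 1")
    if (any(t < 0)) stop("t must be >= 0")
    k <- gen - origin
    rate <- params@rN + params@muN
    out <- numeric(length(t))
    pos <- t > 0
    if (k == 0) {
        out[pos] <- exp(-rate * t[pos])
        out[!pos] <- 1
    } else {
        out[pos] <- exp(k * log(2 * params@rN * t[pos]) - lfactorial(k) -
                        rate * t[pos])
    }
    out
}

#' Terminal-generation population of a single burst
#'
#' Population n^(L)(t) of last-generation progenitors after one founding
#' generation-`origin` cell at t = 0, with G = L - origin effective
#' generations:
#' n^(L)(t) = exp(-(omega + mu_n) t) / (G-1)! * (2 r_n / (r_n - omega))^G *
#' int_0^((r_n - omega) t) z^(G-1) e^(-z) dz,
#' evaluated through the regularized lower incomplete gamma function (stable
#' at L = 22 where naive factorial forms overflow). The r_n = omega
#' degeneracy is resolved by the analytic Erlang limit
#' (2 r_n t)^G e^(-(r_n + mu_n) t) / G!; for omega > r_n the cascade is
#' integrated numerically.
#'
#' @inheritParams cascadePopulation
#' @return n^(L)(t) at each `t`; 0 at t = 0
#' @examples
#' terminalPopulation(c(0, 5, 10, 20), ModelParams())
#' @export
terminalPopulation <- function(t, params, origin = 0L) {
    origin <- as.integer(origin)
    if (origin >= params@L) stop("origin must be < L")
    if (any(t < 0)) stop("t must be >= 0")
    G <- params@L - origin
    rn <- params@rN; om <- params@omega; mn <- params@muN
    if (abs(rn - om) < 1e-9 * rn) {
        out <- numeric(length(t))
        pos <- t > 0
        out[pos] <- exp(G * log(2 * rn * t[pos]) - lfactorial(G) -
                        (rn + mn) * t[pos])
        return(out)
    }
    if (om > rn) return(cascadeOde(t, params, origin)[, G + 1L])
    # log-space: -(omega+mu_n) t + G log(2 r_n / (r_n - omega)) + log P(G, x)
    out <- numeric(length(t))
    pos <- t > 0
    x <- (rn - om) * t[pos]
    out[pos] <- exp(-(om + mn) * t[pos] + G * log(2 * rn / (rn - om)) +
                    pgamma(x, shape = G, log.p = TRUE))
    out
}

# numerical integration of the full cascade ODE (origin .. L), used for the
# omega > r_n branch and as an internal fallback; returns a matrix with one
# column per generation origin..L evaluated at the requested times
cascadeOde <- function(t, params, origin = 0L) {
    G <- params@L - as.integer(origin)
    rn <- params@rN; mn <- params@muN; om <- params@omega
    deriv <- function(tt, y, p) {
        dy <- numeric(G + 1L)
        dy[1] <- -(rn + mn) * y[1]
        if (G > 1)
            for (k in 2:G) dy[k] <- 2 * rn * y[k - 1] - (rn + mn) * y[k]
        dy[G + 1L] <- 2 * rn * y[G] - (om + mn) * y[G + 1L]
        list(dy)
    }
    y0 <- c(1, numeric(G))
    tt <- sort(unique(c(0, t)))
    sol <- deSolve::ode(y0, tt, deriv, NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    sol[match(t, tt), -1, drop = FALSE]
}

#' Mature-cell burst kernel for one differentiation event
#'
#' Deterministic mature-cell response m(t) = omega int_0^t n^(L)(t')
#' exp(-mu_m (t - t')) dt' to a single founding generation-`origin` cell,
#' tabulated on a uniform grid. The convolution is advanced with an
#' exponential-integrator step on a fine internal grid, then resampled to
#' the requested spacing. The grid is auto-extended until the burst has
#' decayed below `eps` times its maximum (capped; a remaining-mass warning
#' is emitted if the cap is hit).
#'
#' @param params a [ModelParams-class]
#' @param origin generation of the founding cell
#' @param tMax initial grid horizon in days (NULL: estimated from the burst
#'   timescales (L - origin)/r_n and 1/mu_m)
#' @param dt grid spacing of the returned kernel (days)
#' @param eps truncation threshold relative to max(m)
#' @return a [BurstKernel-class]; `totalYield` stores int mu_m m dt
#'   including the exponential tail beyond the grid
#' @examples
#' k <- matureBurstKernel(ModelParams(L = 10L))
#' totalYield(k)  # ~2^10 when mu_n = 0
#' @export
matureBurstKernel <- function(params, origin = 0L, tMax = NULL, dt = 1,
                              eps = 1e-9) {
    if (dt <= 0) stop("dt must be > 0")
    origin <- as.integer(origin)
    G <- params@L - origin
    if (G < 1) stop("origin must be < L")
    if (is.null(tMax))
        tMax <- ceiling(4 * G / params@rN + 10 / params@muM)
    dtFine <- min(dt, 0.05)
    om <- params@omega; mm <- params@muM
    tFine <- seq(0, tMax, by = dtFine)
    nL <- terminalPopulation(tFine, params, origin)
    stepDecay <- exp(-mm * dtFine)
    m <- numeric(length(tFine))
    for (ext in seq_len(40)) {
        # m[i+1] = e^(-mu_m dt) m[i] + omega dt/2 (e^(-mu_m dt) nL[i] + nL[i+1])
        inc <- om * dtFine / 2 * (stepDecay * nL[-length(nL)] + nL[-1])
        for (i in seq_along(inc)) m[i + 1L] <- stepDecay * m[i] + inc[i]
        if (m[length(m)] < eps * max(m)) break
        # extend the grid and continue the recursion from the current end
        tExtra <- seq(tFine[length(tFine)] + dtFine,
                      tFine[length(tFine)] + tMax, by = dtFine)
        nL <- c(nL, terminalPopulation(tExtra, params, origin))
        tFine <- c(tFine, tExtra)
        m <- c(m, numeric(length(tExtra)))
    }
    mEnd <- m[length(m)]
    if (mEnd >= eps * max(m))
        warning(sprintf(
            "burst unresolved at t = %.0f d: m(end)/max(m) = %.2g (mass deficit ~%.3g cells)",
            tFine[length(tFine)], mEnd / max(m), mEnd))
    # total mature production, including the exponential tail beyond the grid
    # (valid because n^(L) is negligible there, so int_T^inf mu_m m = m(T))
    yield <- mm * trapz(tFine, m) + mEnd
    tOut <- seq(0, tFine[length(tFine)], by = dt)
    vOut <- approx(tFine, m, xout = tOut, rule = 2)$y
    vOut[1] <- 0
    new("BurstKernel", tGrid = tOut, values = vOut,
        originGeneration = origin, dt = dt, totalYield = yield)
}

#' @rdname cloneburst-generics
setMethod("totalYield", "BurstKernel", function(x, ...) x@totalYield)

setMethod("show", "BurstKernel", function(object) {
    cat(sprintf(
        "BurstKernel: origin generation %d, %d points (dt = %g d)\n",
        object@originGeneration, length(object@tGrid), object@dt))
    cat(sprintf("  peak %.4g cells at t = %.1f d; total yield %.6g\n",
                max(object@values),
                object@tGrid[which.max(object@values)], object@totalYield))
})

# linear convolution via FFT; returns the first length(x) lags
fftConvolve <- function(x, y) {
    n <- length(x) + length(y) - 1L
    N <- nextn(n, 2)
    z <- Re(fft(fft(c(x, numeric(N - length(x)))) *
               fft(c(y, numeric(N - length(y)))), inverse = TRUE)) / N
    z[seq_along(x)]
}

# spread event times onto a uniform grid as two-point linearly weighted
# impulses; summing the shifted kernel with linear interpolation is then
# exactly a discrete convolution of these weights with the tabulated kernel
eventImpulses <- function(eventTimes, tGrid) {
    n <- length(tGrid)
    dt <- tGrid[2] - tGrid[1]
    w <- numeric(n)
    if (!length(eventTimes)) return(w)
    pos <- (eventTimes - tGrid[1]) / dt
    q <- floor(pos)
    f <- pos - q
    idx <- c(q + 1, q + 2)
    val <- c(1 - f, f)
    keep <- idx >= 1 & idx <= n & val > 0
    if (any(keep)) {
        rs <- rowsum(val[keep], idx[keep])
        w[as.integer(rownames(rs))] <- rs[, 1]
    }
    w
}

#' Superpose burst responses over a sequence of differentiation events
#'
#' By linearity of the cascade, the mature population of a clone is the sum
#' of single-event kernels shifted to its differentiation times:
#' m_i(t) = sum_k m(t - T_k). The kernel is linearly interpolated between
#' grid points; events beyond the grid are ignored with a notice.
#'
#' @param eventTimes differentiation event times T_k (days)
#' @param kernel a [BurstKernel-class]
#' @param tGrid uniform output grid (days)
#' @return m_i(t) on `tGrid`
#' @export
superposeBursts <- function(eventTimes, kernel, tGrid) {
    stopifnot(is(kernel, "BurstKernel"))
    dt <- tGrid[2] - tGrid[1]
    if (any(abs(diff(tGrid) - dt) > 1e-9)) stop("tGrid must be uniform")
    late <- eventTimes > max(tGrid)
    if (any(late)) {
        message(sum(late), " event(s) beyond the grid ignored")
        eventTimes <- eventTimes[!late]
    }
    if (!length(eventTimes)) return(numeric(length(tGrid)))
    kv <- approx(kernel@tGrid, kernel@values, xout = seq(0, max(tGrid), by = dt),
                 yleft = 0, yright = 0)$y
    w <- eventImpulses(eventTimes, tGrid)
    out <- fftConvolve(w, kv)
    pmax(out, 0)
}

#' Assemble per-clone mature-cell trajectories
#'
#' Applies the burst superposition to every clone: tagged HSC clones get one
#' kernel per differentiation event; transplanted HSPC clones get a single
#' generation-l burst at t = 0; the untagged pool is the expected-value
#' convolution m_0(t) = int_0^t alpha h0(t') m_kernel(t - t') dt' of the
#' deterministic untagged HSC path with the origin-0 kernel.
#'
#' @param trajectory an [HSCTrajectory-class] (with differentiation events
#'   drawn) covering `tGrid`
#' @param params a [ModelParams-class]
#' @param tGrid uniform output grid in days (spacing <= 1 day recommended;
#'   coarser grids trigger a warning)
#' @return a [MatureTrajectory-class]
#' @export
assembleMature <- function(trajectory, params, tGrid) {
    stopifnot(is(trajectory, "HSCTrajectory"), is(params, "ModelParams"))
    dt <- tGrid[2] - tGrid[1]
    if (any(abs(diff(tGrid) - dt) > 1e-9)) stop("tGrid must be uniform")
    if (dt > 1 + 1e-9)
        warning("grid spacing > 1 day poorly resolves bursts")
    if (max(tGrid) > trajectory@tMax + 1e-9)
        stop("trajectory does not cover tGrid")
    n <- length(tGrid)
    C <- length(trajectory@hInit)
    if (C && length(trajectory@diffEvents) != C)
        stop("trajectory has no differentiation events; rerun simulateHSC")

    kernel0 <- matureBurstKernel(params, 0L, dt = dt)
    kv0 <- approx(kernel0@tGrid, kernel0@values, xout = tGrid,
                  yleft = 0, yright = 0)$y

    hscIds <- sprintf("HSC_%05d", seq_len(C))
    m <- matrix(0, nrow = 0, ncol = n)
    if (C) {
        m <- matrix(0, nrow = C, ncol = n)
        K <- fft(c(kv0, numeric(nextn(2L * n - 1L, 2) - n)))
        N <- length(K)
        chunk <- 256L
        for (s in seq(1L, C, by = chunk)) {
            e <- min(s + chunk - 1L, C)
            W <- vapply(s:e, function(i) {
                ev <- trajectory@diffEvents[[i]]
                eventImpulses(ev[ev <= max(tGrid)], tGrid)
            }, numeric(n))
            Wp <- rbind(W, matrix(0, N - n, ncol(W)))
            conv <- Re(stats::mvfft(stats::mvfft(Wp) * K, inverse = TRUE)) / N
            m[s:e, ] <- t(pmax(conv[seq_len(n), , drop = FALSE], 0))
        }
    }
    origins <- data.frame(clone_id = hscIds,
                          origin = rep("HSC", C),
                          generation = rep(NA_integer_, C),
                          stringsAsFactors = FALSE)

    # transplanted HSPC clones: one burst each at t = 0, origin generation l
    hspc <- params@hspcInit[params@hspcInit > 0]
    for (gname in names(hspc)) {
        gen <- as.integer(gname)
        kg <- matureBurstKernel(params, gen, dt = dt)
        row <- approx(kg@tGrid, kg@values, xout = tGrid,
                      yleft = 0, yright = 0)$y
        cnt <- as.integer(hspc[[gname]])
        ids <- sprintf("HSPC_g%d_%05d", gen, seq_len(cnt))
        m <- rbind(m, matrix(rep(row, each = cnt), nrow = cnt))
        origins <- rbind(origins, data.frame(
            clone_id = ids, origin = "HSPC", generation = gen,
            stringsAsFactors = FALSE))
    }

    # untagged pool: expected-value convolution of alpha * h0(t) with kernel
    m0 <- numeric(n)
    if (params@alpha > 0) {
        h0 <- approx(trajectory@gridT, trajectory@h0Grid, xout = tGrid,
                     rule = 2)$y
        w0 <- params@alpha * h0 * dt
        w0[c(1, n)] <- w0[c(1, n)] / 2
        m0 <- pmax(fftConvolve(w0, kv0), 0)
    }
    rownames(m) <- origins$clone_id
    new("MatureTrajectory", tGrid = tGrid, m = m, m0 = m0,
        cloneIds = origins$clone_id, origins = origins)
}

#' @rdname cloneburst-generics
setMethod("cloneIds", "MatureTrajectory", function(x, ...) x@cloneIds)

setMethod("show", "MatureTrajectory", function(object) {
    cat("MatureTrajectory:", nrow(object@m), "clones on",
        length(object@tGrid), "grid points\n")
    tot <- colSums(object@m) + object@m0
    cat(sprintf("  total M(t): %.3g at t = %g d (untagged share %.0f%%)\n",
                tot[length(tot)], max(object@tGrid),
                100 * object@m0[length(tot)] / max(tot[length(tot)], 1e-12)))
})
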