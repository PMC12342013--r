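#' Default configuration for the staged fitting pipeline
#'
#' Grids default to about one decade around the ZH33 reference values (or
#' around `baseParams` when supplied); every grid is user-overridable. The
#' staged search automates the by-hand estimation workflow: richness first,
#' then the transplanted-HSPC burst, then the sampled totals, then per-time
#' sampling adjustments, and finally the EMD refinement.
#'
#' @param baseParams [ModelParams-class] carrying the fixed values (mu_n and
#'   mu_m defaults are kept fixed: r_n >> mu_n ~ 0, mu_m = 0.185/day for
#'   granulocytes) and grid anchors
#' @return a named list of grids and knobs
#' @export
defaultFitConfig <- function(baseParams = ModelParams()) {
    list(
        baseParams = baseParams,
        richness = list(
            cH0Factors = c(1, 1.07, 1.25, 1.5, 2),
            rH0 = baseParams@rH0 * c(0.5, 1, 2),
            muH = pmax(1e-4, baseParams@muH * c(0.25, 1, 4)),
            KFactors = c(0.1, 1, 10),   # times the K = 100 C_h(0) anchor
            topQ = 4L),
        hspc = list(
            gens = as.integer(names(baseParams@hspcInit)),
            rN = baseParams@rN * c(0.5, 1, 2),
            L = unique(pmax(2L, baseParams@L + c(-4L, 0L, 4L))),
            omega = baseParams@omega * c(0.5, 1, 2),
            etaFactors = c(0.5, 1, 2),
            topQ = 2L,
            minTransient = 5L),
        alphaRange = baseParams@alpha * c(1 / 20, 20),
        etaClip = c(0.25, 4),
        emd = list(topQ = 3L, kRange = NULL),
        windowMonths = c(2, Inf))
}

# cumulative richness over the post-window samples
cumulativeRichness <- function(table, after = 2) {
    tm <- sampleTimes(table)
    cts <- cloneCounts(table)[, tm > after, drop = FALSE]
    if (!ncol(cts)) return(0L)
    sum(rowSums(cts) > 0)
}

#' Stage 1: constrain (C_h0, r_h0, mu_h, K) from richness decay
#'
#' Anchors the tagged clone count from below by the cumulative post-2-month
#' richness (granulocyte richness after ~2 months arises solely from
#' engrafted HSC clones) and the capacity by K ~ 100 C_h(0) (+/- one decade).
#' Candidates are scored by the squared error between the expected-richness
#' curve E[C_h(t_j)] and the observed per-sample richness, with the
#' detection fraction profiled out as a free scale in (0, 1]; this scores
#' the decay shape, which is what r_h0, mu_h and K control.
#'
#' @param data a [SampleTable-class] with at least 3 post-2-month samples
#' @param config see [defaultFitConfig()]
#' @return data.frame of top candidates (cH0, rH0, muH, K, scale, sse),
#'   with the richness bound as attribute "bound"
#' @export
stageRichness <- function(data, config = defaultFitConfig()) {
    tm <- sampleTimes(data)
    post <- tm > 2
    if (sum(post) < 3) stop("need at least 3 post-2-month samples")
    bound <- cumulativeRichness(data, 2)
    obs <- sampleRichness(data)[post]
    tDays <- monthsToDays(tm[post])
    cfg <- config$richness
    base <- config$baseParams
    grid <- expand.grid(cH0 = bound * cfg$cH0Factors, rH0 = cfg$rH0,
                        muH = cfg$muH, KF = cfg$KFactors)
    grid <- grid[grid$rH0 > grid$muH, , drop = FALSE]
    if (!nrow(grid)) stop("richness grid empty: all candidates violate ",
                          "rH0 > muH")
    res <- lapply(seq_len(nrow(grid)), function(i) {
        g <- grid[i, ]
        K <- 100 * g$cH0 * g$KF
        p <- updateParams(base, cH0 = g$cH0, rH0 = g$rH0, muH = g$muH,
                          K = K)
        ch <- expectedRichness(tDays, p)
        sc <- min(1, sum(obs * ch) / sum(ch^2))
        c(cH0 = g$cH0, rH0 = g$rH0, muH = g$muH, K = K, scale = sc,
          sse = sum((obs - sc * ch)^2))
    })
    res <- as.data.frame(do.call(rbind, res))
    res <- res[order(res$sse), , drop = FALSE]
    out <- head(res, cfg$topQ)
    rownames(out) <- NULL
    attr(out, "bound") <- bound
    out
}

# clones seen only in the early window (t <= after months): HSPC suspects
transientClones <- function(table, after = 2) {
    tm <- sampleTimes(table)
    cts <- cloneCounts(table)
    early <- rowSums(cts[, tm <= after, drop = FALSE]) > 0
    late <- rowSums(cts[, tm > after, drop = FALSE]) > 0
    which(early & !late)
}

# local maxima of a KDE of log10(1 + x), largest positions first
abundancePeaks <- function(x, minHeight = 0.05) {
    if (length(x) < 5) return(numeric())
    d <- stats::density(log10(1 + x))
    y <- d$y
    i <- which(diff(sign(diff(y))) == -2) + 1L
    i <- i[y[i] > minHeight * max(y)]
    sort(d$x[i], decreasing = TRUE)
}

#' Stage 2: transplanted-HSPC burst against the first sample
#'
#' Small clones that appear early and vanish are attributed to transplanted
#' partially differentiated progenitors (HSPCs). With alpha = 0 the model's
#' first-sample abundance of a generation-l HSPC clone is eta * m_l(t_1);
#' the stage grids (r_n, L, omega, eta) and matches these predicted
#' positions to the modes of the transient-clone abundance distribution,
#' then estimates the per-generation clone multipliers C_n(l) by nearest-
#' mode assignment corrected for the detection probability. The quartet
#' (r_n, L, omega, eta) is identified only up to the documented compensation
#' family -- the objective depends on them solely through eta * m_l(t_1) --
#' and the returned record says so.
#'
#' @param data a [SampleTable-class]
#' @param candidates stage-1 candidate data.frame
#' @param config see [defaultFitConfig()]
#' @return list with `combos` (data.frame over (rN, L, omega, eta) and the
#'   estimated hspcInit), `status`, and `transient` clone count
#' @export
stageHspcBurst <- function(data, candidates, config = defaultFitConfig()) {
    cfg <- config$hspc
    base <- config$baseParams
    tm <- sampleTimes(data)
    t1 <- monthsToDays(tm[1])
    trans <- transientClones(data, 2)
    x <- cloneCounts(data)[trans, 1]
    x <- x[x > 0]
    if (length(x) < cfg$minTransient) {
        return(list(status = "no_hspc", transient = length(x),
                    combos = data.frame(rN = base@rN, L = base@L,
                                        omega = base@omega, eta = base@eta,
                                        objective = NA_real_),
                    hspcInit = list(numeric())))
    }
    peaks <- abundancePeaks(x)
    if (!length(peaks)) {
        return(list(status = "underdetermined", transient = length(x),
                    combos = data.frame(rN = base@rN, L = base@L,
                                        omega = base@omega, eta = base@eta,
                                        objective = NA_real_),
                    hspcInit = list(base@hspcInit)))
    }
    gens <- cfg$gens
    if (!length(gens)) gens <- 0:2
    grid <- expand.grid(rN = cfg$rN, L = cfg$L, omega = cfg$omega,
                        eta = base@eta * cfg$etaFactors)
    scored <- lapply(seq_len(nrow(grid)), function(i) {
        g <- grid[i, ]
        p <- updateParams(base, rN = g$rN, L = as.integer(g$L),
                          omega = g$omega, eta = g$eta, alpha = 0)
        mAtT1 <- vapply(gens, function(l0) {
            k <- matureBurstKernel(p, as.integer(l0), dt = 0.5)
            approx(k@tGrid, k@values, xout = t1, yleft = 0, yright = 0)$y
        }, numeric(1))
        pred <- log10(1 + g$eta * mAtT1)       # descending in generation
        nUse <- min(length(peaks), length(pred))
        obj <- sum((peaks[seq_len(nUse)] - pred[seq_len(nUse)])^2)
        # nearest-mode assignment, detection-corrected multipliers
        lx <- log10(1 + x)
        assign <- apply(outer(lx, pred, function(a, b) abs(a - b)), 1,
                        which.min)
        nl <- tabulate(assign, nbins = length(gens))
        pdet <- detectionProbability(mAtT1, g$eta)
        cn <- ifelse(pdet > 1e-6, nl / pdet, 0)
        list(obj = obj, cn = setNames(round(cn), as.character(gens)))
    })
    obj <- vapply(scored, `[[`, numeric(1), "obj")
    ord <- order(obj)[seq_len(min(cfg$topQ, nrow(grid)))]
    combos <- cbind(grid[ord, , drop = FALSE],
                    objective = obj[ord])
    rownames(combos) <- NULL
    list(status = "ok", transient = length(x), peaks = peaks,
         combos = combos,
         hspcInit = lapply(scored[ord], `[[`, "cn"),
         note = paste("(rN, L, omega, eta) enter the objective only",
                      "through eta * m_l(t1): compensation family"))
}

# deterministic expected tagged sampled totals S(t_j) for a parameter set,
# split into the alpha-proportional HSC part and the HSPC transient part
expectedTotalsParts <- function(params, tDaysSample, multipliers = NULL) {
    tMax <- max(tDaysSample)
    grid <- seq(0, tMax, by = min(1, max(tDaysSample) / 200))
    k0 <- matureBurstKernel(params, 0L, dt = grid[2] - grid[1])
    kv <- approx(k0@tGrid, k0@values, xout = grid, yleft = 0, yright = 0)$y
    hbarStar <- params@taggedFraction * logisticMean(grid, params)
    w <- hbarStar * (grid[2] - grid[1])
    w[c(1, length(w))] <- w[c(1, length(w))] / 2
    mHsc <- fftConvolve(w, kv)     # per unit alpha
    mHspc <- numeric(length(grid))
    hspc <- params@hspcInit[params@hspcInit > 0]
    for (g in names(hspc)) {
        kg <- matureBurstKernel(params, as.integer(g), dt = grid[2] - grid[1])
        mHspc <- mHspc + hspc[[g]] *
            approx(kg@tGrid, kg@values, xout = grid, yleft = 0,
                   yright = 0)$y
    }
    etaJ <- params@eta * (if (is.null(multipliers))
        rep(1, length(tDaysSample)) else multipliers)
    A <- etaJ * approx(grid, mHsc, xout = tDaysSample, rule = 2)$y
    B <- etaJ * approx(grid, mHspc, xout = tDaysSample, rule = 2)$y
    list(A = A, B = B)  # S(t_j) = alpha * A + B
}

#' Stage 3: least-squares fit of alpha to the sampled totals
#'
#' The expected tagged sampled total is linear in the HSC differentiation
#' rate, S(t_j) = alpha A_j + B_j (A: convolution of the tagged logistic
#' mean with the burst kernel, B: HSPC transient), so the least-squares
#' alpha has the closed form sum(A (S_hat - B)) / sum(A^2), clipped to the
#' configured range.
#'
#' @param data a [SampleTable-class]
#' @param candidates list of [ModelParams-class] candidates
#' @param config see [defaultFitConfig()]
#' @return list of candidates with `alpha` set, plus a record data.frame
#' @export
stageTotalsLsq <- function(data, candidates,
                           config = defaultFitConfig()) {
    sHat <- as.numeric(sampleTotals(data))
    tDays <- monthsToDays(sampleTimes(data))
    rng <- config$alphaRange
    out <- list(); rec <- NULL
    for (p in candidates) {
        parts <- tryCatch(expectedTotalsParts(p, tDays),
                          error = function(e) NULL)
        if (is.null(parts)) next
        aHat <- sum(parts$A * (sHat - parts$B)) / sum(parts$A^2)
        if (!is.finite(aHat)) {
            message("non-finite totals objective; candidate discarded")
            next
        }
        aHat <- min(max(aHat, rng[1]), rng[2])
        sse <- sum((sHat - aHat * parts$A - parts$B)^2)
        out[[length(out) + 1L]] <- updateParams(p, alpha = aHat)
        rec <- rbind(rec, data.frame(alpha = aHat, sse = sse))
    }
    if (!length(out)) stop("all candidates failed the totals stage")
    list(candidates = out, record = rec)
}

#' Stage 4: per-time-point sampling-fraction adjustments
#'
#' Month-to-month fluctuations of the sampled totals beyond the model's
#' intrinsic noise are absorbed into per-time multipliers
#' eta(t_j)/eta = S_hat(t_j)/S(t_j), clipped to a band and renormalized to
#' geometric mean 1 so that eta keeps its meaning as the mean fraction.
#'
#' @param data a [SampleTable-class]
#' @param params fitted [ModelParams-class]
#' @param config see [defaultFitConfig()]
#' @return numeric vector of multipliers, one per time point
#' @export
stageEtaAdjust <- function(data, params, config = defaultFitConfig()) {
    sHat <- as.numeric(sampleTotals(data))
    tDays <- monthsToDays(sampleTimes(data))
    parts <- expectedTotalsParts(params, tDays)
    s <- params@alpha * parts$A + parts$B
    clip <- config$etaClip
    mult <- rep(1, length(s))
    ok <- s > 0
    mult[ok] <- pmin(pmax(sHat[ok] / s[ok], clip[1]), clip[2])
    if (any(!ok & sHat > 0)) {
        warning("model predicts S(t_j) = 0 where data are positive; ",
                "multiplier capped")
        mult[!ok & sHat > 0] <- clip[2]
    }
    mult <- mult / exp(mean(log(mult)))
    mult
}

#' Stage 5: EMD refinement over the surviving candidates
#'
#' For each candidate, simulates full synthetic datasets, compresses their
#' clone clouds by k-means with elbow selection, and averages the Earth
#' mover's distance to the data's cluster set; the minimizer wins. The
#' whole stage is deterministic given (data, config, seed).
#'
#' @param data a [SampleTable-class]
#' @param candidates list of [ModelParams-class] (with etaAdjust set)
#' @param replicates simulated datasets per candidate
#' @param seed master seed
#' @param config see [defaultFitConfig()]
#' @return a [FitResult-class]
#' @export
stageEmdSearch <- function(data, candidates, replicates = 3L, seed = 1,
                           config = defaultFitConfig()) {
    if (!length(candidates)) stop("candidate set is empty")
    win <- config$windowMonths
    cloudD <- kdeDensity(cloneSummary(data, window = win))
    n <- nrow(cloneRecords(cloudD))
    kRange <- config$emd$kRange
    if (is.null(kRange)) kRange <- 2:max(5, min(40, floor(n / 4)))
    Pset <- kmeansWithElbow(cloudD, kRange, seed = deriveSeed(seed, 0))
    tm <- sampleTimes(data)
    emd <- numeric(length(candidates))
    for (ci in seq_along(candidates)) {
        p <- candidates[[ci]]
        sched <- scheduleFromParams(p, tm)
        vals <- vapply(seq_len(replicates), function(r) {
            sim <- generateDataset(p, sched,
                                   seed = deriveSeed(seed, ci * 1000 + r))
            cl <- cloneSummary(sim$table, window = win)
            nn <- nrow(cloneRecords(cl))
            if (nn < max(kRange) + 1) return(NA_real_)
            Q <- kmeansWithElbow(kdeDensity(cl), kRange,
                                 seed = deriveSeed(seed, ci * 1000 + r))
            earthMoversDistance(Pset, Q)@distance
        }, numeric(1))
        emd[ci] <- mean(vals, na.rm = TRUE)
    }
    if (all(!is.finite(emd))) stop("all candidates failed simulation")
    best <- which.min(emd)
    list(best = best, emd = emd, dataClusters = Pset)
}

#' Run the full staged fitting pipeline
#'
#' Automates the staged estimation: (1) richness decay constrains
#' (C_h0, r_h0, mu_h, K) with K anchored at 100 C_h(0); (2) the early
#' transient fixes the HSPC composition and a feasible (r_n, L, omega, eta)
#' family; (3) least squares on the sampled totals fixes alpha; (4) per-time
#' eta multipliers absorb residual total fluctuations; (5) EMD between
#' clustered clone clouds selects the final candidate. One adjust-refine
#' pass is performed.
#'
#' @param data a [SampleTable-class]
#' @param config see [defaultFitConfig()]
#' @param seed master seed (the pipeline is deterministic given data,
#'   config and seed)
#' @param replicates simulation replicates per candidate in the EMD stage
#' @return a [FitResult-class]
#' @export
fitPipeline <- function(data, config = defaultFitConfig(), seed = 1,
                        replicates = 3L) {
    base <- config$baseParams
    s1 <- stageRichness(data, config)
    s2 <- stageHspcBurst(data, s1, config)
    # cross stage-1 candidates with stage-2 combos
    cand <- list()
    for (i in seq_len(nrow(s1))) {
        for (j in seq_len(nrow(s2$combos))) {
            g <- s2$combos[j, ]
            cand[[length(cand) + 1L]] <- updateParams(
                base, cH0 = s1$cH0[i], rH0 = s1$rH0[i], muH = s1$muH[i],
                K = s1$K[i], rN = g$rN, L = as.integer(g$L),
                omega = g$omega, eta = g$eta,
                hspcInit = s2$hspcInit[[j]])
        }
    }
    s3 <- stageTotalsLsq(data, cand, config)
    ord <- order(s3$record$sse)
    keep <- ord[seq_len(min(config$emd$topQ, length(ord)))]
    cand <- s3$candidates[keep]
    # one adjust -> refine pass: eta multipliers per candidate, then EMD
    cand <- lapply(cand, function(p)
        updateParams(p, etaAdjust = stageEtaAdjust(data, p, config)))
    s5 <- stageEmdSearch(data, cand, replicates = replicates, seed = seed,
                         config = config)
    bp <- cand[[s5$best]]
    new("FitResult", bestParams = bp,
        stageRecords = list(
            richness = s1,
            hspc = s2[c("status", "transient", "combos", "note")],
            totals = s3$record[keep, , drop = FALSE],
            emd = data.frame(candidate = seq_along(s5$emd),
                             emd = s5$emd)),
        etaMultipliers = bp@etaAdjust,
        finalEmd = s5$emd[s5$best],
        replicates = as.integer(replicates), seed = as.numeric(seed))
}

#' @rdname cloneburst-generics
setMethod("bestParams", "FitResult", function(x, ...) x@bestParams)

#' @rdname cloneburst-generics
setMethod("stageRecords", "FitResult", function(x, ...) x@stageRecords)

#' @rdname cloneburst-generics
setMethod("etaMultipliers", "FitResult", function(x, ...)
    x@etaMultipliers)

setMethod("show", "FitResult", function(object) {
    cat("FitResult: final EMD =", signif(object@finalEmd, 4),
        sprintf("(%d replicates/candidate, seed %g)\n",
                object@replicates, object@seed))
    show(object@bestParams)
    cat("  eta multipliers:",
        paste(signif(object@etaMultipliers, 3), collapse = " "), "\n")
})
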