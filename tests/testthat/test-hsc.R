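test_that("engraftment draws respect mode, totals, and occupancy", {
    e <- drawEngraftment(cH = 2500, nEngrafted = 2500)
    expect_length(e@hInit, 2500)
    expect_true(all(e@hInit == 1L))
    # one box: the whole engrafted mass lands in a single clone
    e1 <- drawEngraftment(cH = 1, nEngrafted = 37, mode = "multinomial",
                          seed = 3)
    expect_equal(e1@hInit, 37L)
    expect_error(drawEngraftment(cH = 10, nEngrafted = 5, hStar = 3),
                 "exceeds")
    # occupancy expectation: E[occupied] = C_H (1 - (1 - 1/C_H)^n)
    set.seed(21)
    CH <- 1e4; nEng <- 1e3
    occ <- replicate(300, length(drawEngraftment(
        cH = CH, nEngrafted = nEng, mode = "multinomial")@hInit))
    expected <- CH * (1 - (1 - 1 / CH)^nEng)
    se <- sd(occ) / sqrt(length(occ))
    expect_lt(abs(mean(occ) - expected), 3 * se)
})

test_that("logistic mean hits its initial condition, fixed point and limit", {
    p <- ModelParams(rH0 = 0.08, muH = 0.02, K = 2.5e5)
    h0 <- 7000
    expect_equal(logisticMean(0, p, h0), h0)
    pfix <- ModelParams(muH = 0, K = 1e4)
    expect_equal(logisticMean(c(0, 5, 50, 500), pfix, 1e4), rep(1e4, 4))
    expect_equal(logisticMean(1e5, p, h0), 2.5e5 * (1 - 0.02 / 0.08),
                 tolerance = 1e-8)
    expect_equal(logisticMean(1e9, p, h0), 187500)  # overflow-guarded limit
    expect_error(logisticMean(-1, p, h0), "t must be")
    # decay when r_h0 <= mu_h is valid, not an error
    pdec <- ModelParams(rH0 = 0.01, muH = 0.05, hspcInit = numeric())
    expect_lt(logisticMean(500, pdec, 1000), 1)
})

test_that("expected richness: initial value, mu_h = 0 identity, monotone", {
    p <- ModelParams(cH0 = 2500)
    expect_equal(expectedRichness(0, p), 2500)
    p0 <- ModelParams(muH = 0, cH0 = 800)
    expect_equal(expectedRichness(c(0, 100, 1000), p0), rep(800, 3))
    tt <- seq(0, 1500, by = 50)
    ch <- expectedRichness(tt, p)
    expect_true(all(diff(ch) <= 1e-9))
    expect_true(all(ch <= p@cH0 + 1e-9))
    expect_error(expectedRichness(-5, p), "t must be")
})

test_that("clamped growth without death is nondecreasing and capped at K", {
    p <- ModelParams(rH0 = 0.2, muH = 0, alpha = 0, K = 150, cH0 = 1,
                     h00 = 0, hspcInit = numeric())
    init <- drawEngraftment(1, 1, h0Init = 0)
    tr <- simulateHSC(p, init, tMax = 400, seed = 5)
    path <- clonePath(tr, 1)
    expect_true(all(diff(path$h) >= 0))
    expect_lte(max(path$h), 150)
    expect_gt(max(path$h), 100)  # reaches the vicinity of K
})

test_that("pure death matches the exponential extinction law", {
    # 1e4 independent singleton clones in one run (r_h0 = 0 decouples them)
    p <- ModelParams(rH0 = 0, muH = 0.04, alpha = 0, K = 1e9, cH0 = 1e4,
                     h00 = 0, hspcInit = numeric())
    init <- drawEngraftment(1e4, 1e4, h0Init = 0)
    tr <- simulateHSC(p, init, tMax = 30, seed = 6)
    pSurv <- exp(-0.04 * 30)
    nSurv <- sum(tr@hFinal > 0)
    se <- sqrt(1e4 * pSurv * (1 - pSurv))
    expect_lt(abs(nSurv - 1e4 * pSurv), 3 * se)
    # conservation under bookkeeping
    expect_equal(sum(tr@hInit) + sum(tr@eventLog$delta), sum(tr@hFinal))
    expect_true(all(tr@hFinal >= 0))
})

test_that("trajectories are reproducible from the master seed", {
    p <- makePreset("small_test")$params
    init <- drawEngraftment(p@cH0, p@cH0, h0Init = p@h00)
    t1 <- simulateHSC(p, init, tMax = 120, seed = 11)
    t2 <- simulateHSC(p, init, tMax = 120, seed = 11)
    expect_identical(t1@eventLog, t2@eventLog)
    expect_identical(t1@diffEvents, t2@diffEvents)
    t3 <- simulateHSC(p, init, tMax = 120, seed = 12)
    expect_false(identical(t1@eventLog, t3@eventLog))
})

test_that("differentiation times follow the inhomogeneous Poisson law", {
    expect_error(drawDifferentiationTimes(
        data.frame(t_start = 0, t_end = 1, h = 1), alpha = -1), "alpha")
    expect_length(drawDifferentiationTimes(
        data.frame(t_start = 0, t_end = 100, h = 5), alpha = 0), 0)
    # constant h = 1 on [0, 100], alpha = 0.016: counts ~ Poisson(1.6)
    path <- data.frame(t_start = 0, t_end = 100, h = 1)
    set.seed(31)
    n <- replicate(1e4, length(drawDifferentiationTimes(path, 0.016)))
    expect_lt(abs(mean(n) - 1.6), 3 * sqrt(1.6 / 1e4))
    expect_lt(abs(var(n) - 1.6), 4 * sqrt(2 * 1.6^2 / 1e4 + 1.6 / 1e4))
    # doubling the population doubles the event density
    path2 <- data.frame(t_start = c(0, 50), t_end = c(50, 100), h = c(1, 2))
    set.seed(32)
    ev <- unlist(replicate(1e4, drawDifferentiationTimes(path2, 0.016),
                           simplify = FALSE))
    nBefore <- sum(ev < 50); nAfter <- sum(ev >= 50)
    ratio <- nAfter / nBefore
    expect_lt(abs(ratio - 2), 3 * ratio * sqrt(1 / nBefore + 1 / nAfter))
})

test_that("per-clone event streams do not depend on processing order", {
    p <- makePreset("small_test")$params
    init <- drawEngraftment(30, 30, h0Init = p@h00)
    p30 <- updateParams(p, cH0 = 30)
    tr <- simulateHSC(p30, init, tMax = 90, seed = 44)
    # re-deriving a single clone's stream in isolation reproduces it
    i <- 7L
    redo <- drawDifferentiationTimes(clonePath(tr, i), p@alpha,
                                     seed = cloneburst:::deriveSeed(44, i))
    expect_identical(tr@diffEvents[[i]], redo)
})
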