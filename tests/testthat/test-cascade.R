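test_that("cascade closed form matches hand-derived values", {
    p <- ModelParams(rN = 2, muN = 0)
    expect_equal(cascadePopulation(0, gen = 0, p, origin = 0), 1)
    expect_equal(cascadePopulation(0, gen = 3, p, origin = 3), 1)
    # one generation downstream: n = 2 r_n t e^(-r_n t) at mu_n = 0
    expect_equal(cascadePopulation(1, gen = 1, p, origin = 0), 4 * exp(-2),
                 tolerance = 1e-12)
    o <- oracleCascade(1, rN = 2, muN = 0, omega = 0.2, L = 22, origin = 0)
    expect_equal(cascadePopulation(1, gen = 1, p, origin = 0),
                 unname(o[1, 2]), tolerance = 1e-8)
    expect_error(cascadePopulation(1, gen = 22, p), "gen must")
    expect_error(cascadePopulation(1, gen = 2, p, origin = 3), "gen must")
})

test_that("full cascade matches the ODE oracle to 1e-6 at L = 22", {
    p <- ModelParams(rN = 2, muN = 0, omega = 0.2, L = 22L)
    tt <- seq(0.2, 40, length.out = 50)
    o <- oracleCascade(tt, 2, 0, 0.2, 22, 0)
    for (g in c(0, 1, 5, 12, 21)) {
        cf <- cascadePopulation(tt, g, p, 0)
        keep <- o[, g + 1] > 1e-30
        expect_lt(max(abs(cf - o[, g + 1])[keep] / o[keep, g + 1]), 1e-6)
    }
    cfL <- terminalPopulation(tt, p, 0)
    keep <- o[, 23] > 1e-30
    expect_lt(max(abs(cfL - o[, 23])[keep] / o[keep, 23]), 1e-6)
})

test_that("terminal population: t = 0, L = 1 closed form, degenerate limit", {
    p1 <- ModelParams(L = 1L, muN = 0, rN = 2, omega = 0.2,
                      hspcInit = numeric())
    expect_equal(terminalPopulation(0, p1), 0)
    tt <- seq(0, 30, by = 0.5)
    expected <- 2 * 2 / (2 - 0.2) * (exp(-0.2 * tt) - exp(-2 * tt))
    expect_equal(terminalPopulation(tt, p1), expected, tolerance = 1e-10)
    # r_n = omega resolved by the Erlang limit, continuous in omega
    pd <- ModelParams(L = 8L, rN = 1, omega = 1, muN = 0,
                      hspcInit = numeric())
    pn <- ModelParams(L = 8L, rN = 1, omega = 1 - 1e-7, muN = 0,
                      hspcInit = numeric())
    expect_equal(terminalPopulation(c(1, 5, 20), pd),
                 terminalPopulation(c(1, 5, 20), pn), tolerance = 1e-5)
    # omega > r_n branch agrees with the oracle
    po <- ModelParams(L = 5L, rN = 0.5, omega = 2, muN = 0,
                      hspcInit = numeric())
    o <- oracleCascade(c(2, 10), 0.5, 0, 2, 5, 0)
    expect_equal(terminalPopulation(c(2, 10), po), o[, 6],
                 tolerance = 1e-6)
    expect_error(terminalPopulation(1, p1, origin = 1L), "origin")
})

test_that("flux conservation: 2^(L - l0) cells per founding cell at mu_n = 0", {
    p <- ModelParams(L = 12L, rN = 2, omega = 0.2, muN = 0, muM = 0.185)
    tt <- seq(0, 400, by = 0.02)
    termFlux <- p@omega * cloneburst:::trapz(tt, terminalPopulation(tt, p))
    expect_equal(termFlux, 2^12, tolerance = 1e-3)
    k0 <- matureBurstKernel(p, 0L)
    expect_equal(totalYield(k0), 2^12, tolerance = 1e-3)
    k2 <- matureBurstKernel(p, 2L)
    expect_equal(totalYield(k0) / totalYield(k2), 4, tolerance = 1e-3)
    expect_equal(k0@values[1], 0)
    # with progenitor death the yield is strictly smaller
    kd <- matureBurstKernel(updateParams(p, muN = 0.1), 0L)
    expect_lt(totalYield(kd), 2^12 * 0.999)
})

test_that("kernel peak time grows with L and shrinks with r_n", {
    base <- ModelParams(muN = 0, hspcInit = numeric())
    peakT <- function(p) {
        k <- matureBurstKernel(p, 0L, dt = 0.1)
        k@tGrid[which.max(k@values)]
    }
    pk <- vapply(c(6L, 12L, 22L), function(L)
        peakT(updateParams(base, L = L)), numeric(1))
    expect_true(all(diff(pk) > 0))
    pr <- vapply(c(1, 2, 4), function(r)
        peakT(updateParams(base, rN = r)), numeric(1))
    expect_true(all(diff(pr) < 0))
})

test_that("burst superposition is linear and exact", {
    p <- ModelParams(L = 10L, hspcInit = numeric())
    tGrid <- seq(0, 300, by = 1)
    k <- matureBurstKernel(p, 0L, dt = 1)
    expect_equal(superposeBursts(numeric(), k, tGrid),
                 numeric(length(tGrid)))
    one <- superposeBursts(20, k, tGrid)
    two <- superposeBursts(c(20, 20), k, tGrid)
    expect_equal(two, 2 * one, tolerance = 1e-9)
    # response to concatenated event lists is the sum of responses
    a <- c(5, 40.3, 120.7); b <- c(33.1, 200)
    expect_equal(superposeBursts(c(a, b), k, tGrid),
                 superposeBursts(a, k, tGrid) +
                     superposeBursts(b, k, tGrid), tolerance = 1e-9)
    expect_message(late <- superposeBursts(c(20, 500), k, tGrid),
                   "beyond the grid")
    expect_equal(late, one, tolerance = 1e-9)
})

test_that("pulse intermittency: CV of m(t) falls as events become frequent", {
    p <- ModelParams(L = 10L, hspcInit = numeric())
    k <- matureBurstKernel(p, 0L, dt = 1)
    tGrid <- seq(0, 2000, by = 1)
    cvOf <- function(rate, seed) {
        set.seed(seed)
        ev <- cumsum(rexp(10 * rate * 2000, rate))
        ev <- ev[ev < 2000]
        m <- superposeBursts(ev, k, tGrid)
        m <- m[tGrid > 200]  # burn-in
        sd(m) / mean(m)
    }
    cvSlow <- cvOf(0.02, 1)   # alpha h << mu_m: separated pulses
    cvFast <- cvOf(2, 2)      # alpha h >> mu_m: merged bursts
    expect_gt(cvSlow, 3 * cvFast)
    # slow regime shows distinct pulses: maxima reach far above the mean
    set.seed(3)
    ev <- cumsum(rexp(20, 0.01)); ev <- ev[ev < 1500]
    m <- superposeBursts(ev, k, tGrid)
    expect_gt(max(m), 5 * mean(m[tGrid > 200]))
})

test_that("assembled mature pool: zero case and HSPC transient collapse", {
    # alpha = 0 and no HSPCs: nothing is ever produced
    p0 <- ModelParams(alpha = 0, cH0 = 5, K = 500, hspcInit = numeric())
    init <- drawEngraftment(5, 5, h0Init = p0@h00)
    tr <- simulateHSC(p0, init, tMax = 150, seed = 9)
    mt <- assembleMature(tr, p0, seq(0, 150))
    expect_equal(max(mt@m), 0)
    expect_equal(max(mt@m0), 0)
    # HSPC-only transplant: a burst then collapse to zero (early-richness
    # mechanism: HSPC clones vanish without HSC renewal)
    ph <- ModelParams(alpha = 0, cH0 = 5, K = 500, L = 10L,
                      hspcInit = c("0" = 8, "1" = 16, "2" = 32))
    trh <- simulateHSC(ph, init, tMax = 400, seed = 9)
    mth <- assembleMature(trh, ph, seq(0, 400))
    tot <- colSums(mth@m)
    expect_gt(max(tot), 1000)               # the transient burst
    expect_lt(tot[length(tot)], 1e-3)       # extinguished afterwards
    expect_equal(sum(mth@origins$origin == "HSPC"), 56)
})
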