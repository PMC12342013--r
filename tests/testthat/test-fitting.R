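ps <- makePreset("small_test")
dsFit <- generateDataset(ps$params, ps$schedule, seed = 101)
cfgFit <- defaultFitConfig(ps$params)

test_that("richness stage anchors C_h0 and K and applies the bound", {
    s1 <- stageRichness(dsFit$table, cfgFit)
    bound <- attr(s1, "bound")
    expect_equal(bound, cloneburst:::cumulativeRichness(dsFit$table))
    expect_true(all(s1$cH0 >= bound))
    expect_true(all(s1$cH0 <= 2 * ps$params@cH0))
    # K stays on the 100 C_h(0) anchor, within the +/- one decade grid
    kf <- s1$K / (100 * s1$cH0)
    expect_true(all(vapply(kf, function(f)
        any(abs(f - c(0.1, 1, 10)) < 1e-9), logical(1))))
    # needs enough post-2-month samples
    early <- SampleTable(cloneCounts(dsFit$table)[, 1:3],
                         timesMonths = sampleTimes(dsFit$table)[1:3])
    expect_error(stageRichness(early, cfgFit), "post-2-month")
})

test_that("with no richness decay the smallest mu_h wins", {
    p0 <- updateParams(ps$params, muH = 0)
    ds0 <- generateDataset(p0, ps$schedule, seed = 77)
    s1 <- stageRichness(ds0$table, cfgFit)
    expect_equal(s1$muH[1], min(cfgFit$richness$muH))
})

test_that("HSPC stage recovers generation multipliers within a factor 2", {
    s1 <- stageRichness(dsFit$table, cfgFit)
    s2 <- stageHspcBurst(dsFit$table, s1, cfgFit)
    expect_equal(s2$status, "ok")
    truth <- ps$params@hspcInit
    est <- s2$hspcInit[[1]]
    expect_equal(names(est), names(truth))
    total <- sum(est) / sum(truth)
    expect_gt(total, 0.5); expect_lt(total, 2)
    for (g in names(truth)) {
        expect_gt(est[[g]], truth[[g]] / 2.5)
        expect_lt(est[[g]], truth[[g]] * 2.5)
    }
})

test_that("HSPC stage selects ~0 clones when the truth has none", {
    p0 <- updateParams(ps$params, hspcInit = numeric())
    ds0 <- generateDataset(p0, ps$schedule, seed = 55)
    s1 <- stageRichness(ds0$table, cfgFit)
    s2 <- stageHspcBurst(ds0$table, s1, cfgFit)
    expect_equal(s2$status, "no_hspc")
    expect_equal(sum(s2$hspcInit[[1]]), 0)
})

test_that("omega and eta compensate exactly through eta * m(t1)", {
    # single origin generation: pick eta2 so that eta2 m2(t1) = eta1 m1(t1);
    # the stage objective must then be identical for the two combos
    cfg <- cfgFit
    t1 <- monthsToDays(sampleTimes(dsFit$table)[1])
    m1 <- approx(matureBurstKernel(updateParams(ps$params, omega = 0.2),
                                   0L, dt = 0.5)@tGrid,
                 matureBurstKernel(updateParams(ps$params, omega = 0.2),
                                   0L, dt = 0.5)@values, t1)$y
    m2 <- approx(matureBurstKernel(updateParams(ps$params, omega = 0.35),
                                   0L, dt = 0.5)@tGrid,
                 matureBurstKernel(updateParams(ps$params, omega = 0.35),
                                   0L, dt = 0.5)@values, t1)$y
    cfg$hspc$gens <- 0L
    cfg$hspc$rN <- ps$params@rN
    cfg$hspc$L <- ps$params@L
    cfg$hspc$omega <- c(0.2, 0.35)
    cfg$hspc$etaFactors <- c(1, m1 / m2)
    cfg$hspc$topQ <- 8L
    s1 <- stageRichness(dsFit$table, cfg)
    s2 <- stageHspcBurst(dsFit$table, s1, cfg)
    co <- s2$combos
    o1 <- co$objective[abs(co$omega - 0.2) < 1e-9 &
                       abs(co$eta - ps$params@eta) < 1e-12]
    o2 <- co$objective[abs(co$omega - 0.35) < 1e-9 &
                       abs(co$eta - ps$params@eta * m1 / m2) < 1e-12]
    expect_equal(o1, o2, tolerance = 1e-8)
})

test_that("totals stage is ~linear: doubling the counts doubles alpha", {
    cand <- list(ps$params)
    s3 <- stageTotalsLsq(dsFit$table, cand, cfgFit)
    a1 <- s3$candidates[[1]]@alpha
    expect_gt(a1, ps$params@alpha / 2)
    expect_lt(a1, ps$params@alpha * 2)
    doubled <- SampleTable(2L * cloneCounts(dsFit$table),
                           timesMonths = sampleTimes(dsFit$table))
    a2 <- stageTotalsLsq(doubled, cand, cfgFit)$candidates[[1]]@alpha
    expect_gt(a2 / a1, 1.6); expect_lt(a2 / a1, 2.4)
})

test_that("eta multipliers are exact on matching data and renormalized", {
    tDays <- monthsToDays(sampleTimes(dsFit$table))
    parts <- cloneburst:::expectedTotalsParts(ps$params, tDays)
    pred <- round(ps$params@alpha * parts$A + parts$B)
    ideal <- SampleTable(matrix(as.integer(pred), 1),
                         timesMonths = sampleTimes(dsFit$table))
    mult <- stageEtaAdjust(ideal, ps$params, cfgFit)
    expect_equal(mult, rep(1, length(mult)), tolerance = 0.01)
    multReal <- stageEtaAdjust(dsFit$table, ps$params, cfgFit)
    expect_equal(exp(mean(log(multReal))), 1, tolerance = 1e-12)
    # S = 0 with positive data: flagged and capped
    pDead <- updateParams(ps$params, alpha = 0, hspcInit = numeric())
    expect_warning(m0 <- stageEtaAdjust(dsFit$table, pDead, cfgFit),
                   "capped")
    expect_true(all(is.finite(m0)))
})

test_that("planted eta fluctuations are recovered from the totals", {
    set.seed(9)
    planted <- exp(rnorm(8, 0, 0.35))
    planted <- planted / exp(mean(log(planted)))
    pM <- updateParams(ps$params, etaAdjust = planted)
    sched <- cloneburst:::scheduleFromParams(pM, ps$schedule@timesMonths)
    dsM <- generateDataset(pM, sched, seed = 400)
    est <- stageEtaAdjust(dsM$table, ps$params, cfgFit)
    expect_gt(cor(log(est), log(planted)), 0.8)
})

test_that("the pipeline is deterministic and the best EMD is the minimum", {
    f1 <- fitPipeline(dsFit$table, cfgFit, seed = 202, replicates = 2)
    f2 <- fitPipeline(dsFit$table, cfgFit, seed = 202, replicates = 2)
    expect_equal(paramsAsList(bestParams(f1)), paramsAsList(bestParams(f2)))
    expect_equal(f1@finalEmd, f2@finalEmd)
    rec <- stageRecords(f1)
    expect_equal(f1@finalEmd, min(rec$emd$emd))
    expect_gte(f1@finalEmd, 0)
    expect_true(all(c("richness", "hspc", "totals", "emd") %in%
                    names(rec)))
    # identifiability is surfaced, not hidden
    expect_match(rec$hspc$note, "compensation")
})
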