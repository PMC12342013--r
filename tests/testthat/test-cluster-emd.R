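test_that("elbow selection recovers planted blobs and validates inputs", {
    set.seed(55)
    cloud <- makeBlobCloud()
    cs <- kmeansWithElbow(cloud, kRange = 1:10, seed = 1)
    expect_equal(cs@k, 3L)
    expect_equal(sum(clusterWeights(cs)), 1)
    expect_true(all(clusterWeights(cs) > 0.2))  # ~equal occupancy
    d <- cs@inertiaCurve$distortion
    expect_true(all(diff(cummin(d)) <= 0))
    expect_error(kmeansWithElbow(cloud, kRange = 2:4), "width")
    expect_error(kmeansWithElbow(makeCloud(cbind(1:5, 1:5)), 1:10),
                 "fewer points")
})

test_that("compression of a ZH33-scale cloud is insensitive to the exact k", {
    # the elbow k* is convention-dependent (elbow rule, coordinates,
    # k-range); what matters downstream -- and what holds for the real
    # animals -- is that the EMD objective barely moves over a broad band
    # of cluster counts
    ps <- makePreset("ZH33")
    ds <- generateDataset(ps$params, ps$schedule, seed = 57)
    ds2 <- generateDataset(ps$params, ps$schedule, seed = 58)
    cl <- cloneSummary(ds$table)
    cs <- kmeansWithElbow(cl, kRange = 2:60, seed = 2)
    expect_gte(cs@k, 4L)    # a sane, nontrivial compression
    expect_lte(cs@k, 60L)
    tp <- cloneburst:::kdeTransform(
        as.matrix(cloneRecords(cl)[, c("mean", "sd")]), "log10p")
    tp2 <- cloneburst:::kdeTransform(
        as.matrix(cloneRecords(cloneSummary(ds2$table))[, c("mean", "sd")]),
        "log10p")
    mk <- function(pts, k, seed) {
        set.seed(seed)
        f <- kmeans(pts, k, nstart = 10, iter.max = 100)
        clusterSet(f$centers,
                   as.numeric(table(factor(f$cluster, 1:k))) / nrow(pts),
                   "log10p")
    }
    P30 <- mk(tp, 30, 1); P50 <- mk(tp, 50, 1); Q40 <- mk(tp2, 40, 2)
    scale <- sd(tp[, 1])
    # the two compressions of the same cloud nearly coincide ...
    expect_lt(earthMoversDistance(P30, P50)@distance, 0.15 * scale)
    # ... and score an independent replicate almost identically
    e30 <- earthMoversDistance(P30, Q40)@distance
    e50 <- earthMoversDistance(P50, Q40)@distance
    expect_lt(abs(e30 - e50), 0.3 * mean(c(e30, e50)))
})

test_that("EMD worked examples match brute-force enumeration", {
    P <- clusterSet(rbind(c(0, 0), c(1, 0)), c(0.5, 0.5))
    Q <- clusterSet(rbind(c(0, 0)), 1)
    # 2x1: the only feasible flow ships everything to the single sink,
    # cost = 0.5 * 0 + 0.5 * 1
    expect_equal(earthMoversDistance(P, Q)@distance, 0.5,
                 tolerance = 1e-9)
    expect_equal(earthMoversDistance(P, P)@distance, 0, tolerance = 1e-9)
    A <- clusterSet(rbind(c(0, 0)), 1)
    B <- clusterSet(rbind(c(3, 4)), 1)
    expect_equal(earthMoversDistance(A, B)@distance, 5, tolerance = 1e-9)
    r <- earthMoversDistance(P, Q)
    expect_true(all(r@flow >= 0))
    expect_equal(sum(r@flow), 1, tolerance = 1e-8)
    expect_equal(rowSums(r@flow), c(0.5, 0.5), tolerance = 1e-8)
})

test_that("EMD agrees with an LP oracle and behaves as a metric", {
    set.seed(60)
    for (i in 1:25) {
        P <- randomClusterSet(); Q <- randomClusterSet()
        d <- as.matrix(dist(rbind(P@centers, Q@centers)))
        d <- d[seq_along(P@weights), length(P@weights) +
                   seq_along(Q@weights), drop = FALSE]
        mine <- earthMoversDistance(P, Q)@distance
        expect_equal(mine, oracleEMD(P@weights, Q@weights, d),
                     tolerance = 1e-7)
        expect_equal(mine, earthMoversDistance(Q, P)@distance,
                     tolerance = 1e-9)
    }
    for (i in 1:25) {
        P <- randomClusterSet(); Q <- randomClusterSet()
        R <- randomClusterSet()
        pq <- earthMoversDistance(P, Q)@distance
        qr <- earthMoversDistance(Q, R)@distance
        pr <- earthMoversDistance(P, R)@distance
        expect_lte(pr, pq + qr + 1e-9)
    }
})

test_that("EMD falls monotonically as Q slides toward P", {
    set.seed(61)
    P <- clusterSet(matrix(runif(10), 5), rep(0.2, 5))
    Q0 <- clusterSet(P@centers + 2, rep(0.2, 5))
    lam <- seq(0, 1, by = 0.25)
    e <- vapply(lam, function(l) {
        Q <- clusterSet(P@centers + 2 * (1 - l), rep(0.2, 5))
        earthMoversDistance(P, Q)@distance
    }, numeric(1))
    expect_true(all(diff(e) < 1e-9))
    expect_lt(e[length(e)], 1e-9)
})
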