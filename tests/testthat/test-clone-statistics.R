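test_that("clone summaries use the population SD over all windowed points", {
    st <- SampleTable(rbind(c(5, 5, 5, 5), c(0, 0, 0, 8)), c(3, 6, 9, 12),
                      cloneIds = c("flat", "spike"))
    rec <- cloneRecords(cloneSummary(st))
    expect_equal(rec$mean, c(5, 2))
    expect_equal(rec$sd, c(0, sqrt(12)))  # divisor J, zeros included
    # permuting time columns leaves (mean, sd) unchanged
    st2 <- SampleTable(rbind(c(5, 5, 5, 5), c(8, 0, 0, 0)), c(3, 6, 9, 12),
                       cloneIds = c("flat", "spike"))
    expect_equal(cloneRecords(cloneSummary(st2))[, c("mean", "sd")],
                 rec[, c("mean", "sd")])
})

test_that("the window drops early samples and undetected clones", {
    st <- SampleTable(rbind(c(9, 0, 0, 0), c(1, 2, 2, 2)),
                      c(1, 3, 6, 9), cloneIds = c("early", "late"))
    cl <- cloneSummary(st)                    # default: t > 2 months
    expect_equal(cloneRecords(cl)$clone_id, "late")
    expect_equal(cl@jEffective, 3L)
    full <- cloneSummary(st, window = c(0, Inf))
    expect_equal(nrow(cloneRecords(full)), 2)
    expect_error(cloneSummary(st, window = c(8, Inf)), "at least 2")
})

test_that("sd is bounded by mean * sqrt(J - 1) on nonnegative counts", {
    set.seed(77)
    for (i in 1:40) {
        J <- sample(3:12, 1)
        cts <- matrix(rpois(5 * J, sample(c(0.5, 3, 50), 1)), 5)
        cts[1, ] <- c(J * 7, rep(0, J - 1))   # single-spike extremal case
        st <- SampleTable(cts, seq(3, by = 1, length.out = J))
        rec <- cloneRecords(cloneSummary(st))
        expect_true(all(rec$sd <= rec$mean * sqrt(J - 1) + 1e-9))
    }
    # the bound is attained by the single-spike series
    stx <- SampleTable(matrix(c(12, 0, 0, 0), 1), c(3, 4, 5, 6))
    r <- cloneRecords(cloneSummary(stx))
    expect_equal(r$sd, r$mean * sqrt(3), tolerance = 1e-12)
})

test_that("the KDE integrates to one and recovers a planted density", {
    set.seed(8)
    pts <- cbind(rnorm(1000, 5, 0.4), abs(rnorm(1000, 3, 0.4)))
    cl <- kdeDensity(makeCloud(pts))
    # numerical integral over a wide box in the (linear) transformed plane
    gx <- seq(0, 10, length.out = 201); gy <- seq(0, 8, length.out = 201)
    dens <- cl@densityFun(as.matrix(expand.grid(gx, gy)))
    integral <- sum(dens) * diff(gx)[1] * diff(gy)[1]
    expect_equal(integral, 1, tolerance = 1e-3)
    # mode within 3 bandwidths of the blob center
    rec <- cloneRecords(cl)
    mode <- rec[which.max(rec$density), ]
    expect_lt(sqrt((mode$mean - 5)^2 + (mode$sd - 3)^2), 3 * cl@bandwidth)
    expect_equal(max(rec$density_norm), 1, tolerance = 0.05)
})

test_that("two equal planted blobs yield near-equal density maxima", {
    set.seed(9)
    pts <- rbind(cbind(rnorm(500, 2, 0.2), rnorm(500, 2, 0.2)),
                 cbind(rnorm(500, 8, 0.2), rnorm(500, 8, 0.2)))
    cl <- kdeDensity(makeCloud(abs(pts)))
    rec <- cloneRecords(cl)
    peak1 <- max(rec$density[rec$mean < 5])
    peak2 <- max(rec$density[rec$mean > 5])
    expect_lt(abs(peak1 / peak2 - 1), 0.1)
})

test_that("densities are order-invariant and rise under duplication", {
    set.seed(10)
    pts <- cbind(runif(200, 1, 9), runif(200, 1, 9))
    c1 <- kdeDensity(makeCloud(pts))
    perm <- sample(200)
    c2 <- kdeDensity(makeCloud(pts[perm, ]))
    expect_equal(cloneRecords(c2)$density, cloneRecords(c1)$density[perm],
                 tolerance = 1e-10)
    # duplicating a point raises the local density there
    cl3 <- kdeDensity(makeCloud(rbind(pts, pts[1, ], pts[1, ])))
    expect_gt(cloneRecords(cl3)$density[1] *
                  (202 / 200),   # undo the 1/n renormalization
              cloneRecords(c1)$density[1])
    expect_warning(kdeDensity(makeCloud(matrix(rep(c(2, 3), each = 5), 5))),
                   "degenerate")
})
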