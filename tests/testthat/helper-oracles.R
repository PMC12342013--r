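# Independent oracles and fixture builders for the test suite.

# High-accuracy numerical integration of the full progenitor cascade
# (generations l0..L), independent of the package's closed forms and of its
# own ODE fallback (different tolerances, explicit construction here).
oracleCascade <- function(t, rN, muN, omega, L, origin = 0L) {
    G <- L - origin
    deriv <- function(tt, y, parms) {
        dy <- numeric(G + 1L)
        dy[1] <- -(rN + muN) * y[1]
        if (G > 1)
            for (k in 2:G) dy[k] <- 2 * rN * y[k - 1] - (rN + muN) * y[k]
        dy[G + 1L] <- 2 * rN * y[G] - (omega + muN) * y[G + 1L]
        list(dy)
    }
    tt <- sort(unique(c(0, t)))
    sol <- deSolve::ode(c(1, numeric(G)), tt, deriv, NULL,
                        method = "lsoda", rtol = 1e-11, atol = 1e-100)
    sol[match(t, tt), -1, drop = FALSE]
}

# LP oracle for the Earth mover's distance, via the general-purpose simplex
# in the boot package (equality-constrained transportation formulation).
oracleEMD <- function(w, v, d) {
    k <- length(w); l <- length(v)
    a <- as.vector(d)
    A3 <- matrix(0, k + l, k * l)
    for (i in seq_len(k)) for (j in seq_len(l)) {
        A3[i, (j - 1) * k + i] <- 1
        A3[k + j, (j - 1) * k + i] <- 1
    }
    # one marginal constraint is redundant for a balanced problem
    s <- boot::simplex(a = a, A3 = A3[-1, , drop = FALSE],
                       b3 = c(w, v)[-1], maxi = FALSE)
    unname(s$value) / sum(w)
}

# build a CloneCloud directly from (mean, sd) points, bypassing cloneSummary
makeCloud <- function(pts, transform = "linear") {
    new("CloneCloud",
        records = data.frame(
            clone_id = sprintf("c%05d", seq_len(nrow(pts))),
            mean = pts[, 1], sd = pts[, 2], density = NA_real_,
            stringsAsFactors = FALSE),
        windowMonths = c(0, Inf), jEffective = 2L, transform = transform,
        bandwidth = NA_real_, densityFun = NULL)
}

# three well-separated planted Gaussian blobs in (mean, sd) space
makeBlobCloud <- function(nPer = 60, centers = rbind(c(2, 1), c(8, 1),
                                                     c(5, 6)),
                          spread = 0.15) {
    pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
        cbind(rnorm(nPer, centers[i, 1], spread),
              rnorm(nPer, centers[i, 2], spread))))
    makeCloud(abs(pts))
}

# random weighted point set for EMD property tests
randomClusterSet <- function(kMax = 6) {
    k <- sample(2:kMax, 1)
    w <- runif(k); w <- w / sum(w)
    clusterSet(matrix(runif(2 * k), k), w)
}
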