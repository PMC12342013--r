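#' k-means compression of a clone cloud with elbow selection
#'
#' Runs k-means (multi-start, k-means++-like behaviour via `nstart` random
#' starts of [stats::kmeans()]) for every k in `kRange`, records the
#' distortion score (total within-cluster sum of squares), and selects k*
#' by the elbow of the distortion curve: the point of maximal discrete
#' curvature of the axis-normalized curve (default), or the "kneedle"
#' point farthest below the end-to-end chord (the rule used by common
#' elbow visualizers). The curve is made nonincreasing (running minimum)
#' before differencing, since departures from monotonicity are pure
#' multi-start noise. The selected k* depends on the elbow convention and
#' on `kRange`; downstream EMD comparisons are insensitive to it over a
#' broad range. Cluster weights are occupancy fractions, summing to 1. The goal of the compression is
#' dimension reduction of the clone cloud before EMD comparison, not the
#' discovery of real subpopulations.
#'
#' @param cloud a [CloneCloud-class]; clustering is done in the cloud's
#'   transformed coordinates (log10(1+x) by default)
#' @param kRange candidate cluster counts (width >= 3 required to locate an
#'   elbow)
#' @param seed optional seed (the selection is deterministic given it)
#' @param nstart random restarts per k
#' @param method elbow rule, "curvature" or "kneedle"
#' @return a [ClusterSet-class] at the selected k*
#' @export
kmeansWithElbow <- function(cloud, kRange = 2:60, seed = NULL,
                            nstart = 10, method = c("curvature", "kneedle")) {
    stopifnot(is(cloud, "CloneCloud"))
    method <- match.arg(method)
    kRange <- sort(unique(as.integer(kRange)))
    if (length(kRange) < 3 || diff(range(kRange)) < 3)
        stop("kRange must span a width of at least 3 to locate an elbow")
    pts <- kdeTransform(as.matrix(cloud@records[, c("mean", "sd")]),
                        cloud@transform)
    n <- nrow(pts)
    if (n < max(kRange))
        stop("cloud has fewer points (", n, ") than max(kRange)")
    fits <- withSeed(seed, lapply(kRange, function(k) {
        suppressWarnings(kmeans(pts, centers = k, nstart = nstart,
                                iter.max = 100))
    }))
    distortion <- vapply(fits, function(f) f$tot.withinss, numeric(1))
    kStar <- elbowIndex(kRange, distortion, method)
    fit <- fits[[which(kRange == kStar)]]
    w <- as.numeric(table(factor(fit$cluster, levels = seq_len(kStar)))) / n
    centers <- fit$centers
    colnames(centers) <- c("mean", "sd")
    new("ClusterSet", centers = centers, weights = w, k = as.integer(kStar),
        inertiaCurve = data.frame(k = kRange, distortion = distortion),
        transform = cloud@transform)
}

# elbow of a (noisily) decreasing distortion curve
elbowIndex <- function(k, d, method) {
    d <- cummin(d)  # departures from monotonicity are multi-start noise
    x <- (k - k[1]) / (k[length(k)] - k[1])
    rng <- max(d) - min(d)
    y <- if (rng > 0) (d - min(d)) / rng else rep(0, length(d))
    if (method == "kneedle") {
        # distance below the end-to-end chord of the normalized curve
        chord <- y[1] + (y[length(y)] - y[1]) * x
        k[which.max(chord - y)]
    } else {
        # discrete curvature |y''| / (1 + y'^2)^(3/2) at interior points
        i <- 2:(length(k) - 1)
        d1 <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
        d2 <- 2 * ((y[i + 1] - y[i]) / (x[i + 1] - x[i]) -
                   (y[i] - y[i - 1]) / (x[i] - x[i - 1])) /
              (x[i + 1] - x[i - 1])
        k[i][which.max(abs(d2) / (1 + d1^2)^1.5)]
    }
}

#' @rdname cloneburst-generics
setMethod("clusterCenters", "ClusterSet", function(x, ...) x@centers)

#' @rdname cloneburst-generics
setMethod("clusterWeights", "ClusterSet", function(x, ...) x@weights)

setMethod("show", "ClusterSet", function(object) {
    cat("ClusterSet: k* =", object@k, "clusters",
        sprintf("(%s coordinates)\n", object@transform))
    cat(sprintf("  weights: %.3g-%.3g (sum %.6g)\n",
                min(object@weights), max(object@weights),
                sum(object@weights)))
})

#' Build a ClusterSet directly from centers and weights
#'
#' Mostly for tests and worked examples; weights are renormalized to sum
#' to 1.
#'
#' @param centers k x 2 matrix of (mean, sd) centers
#' @param weights nonnegative weights
#' @param transform coordinate label (default "linear")
#' @return a [ClusterSet-class]
#' @export
clusterSet <- function(centers, weights, transform = "linear") {
    centers <- matrix(centers, ncol = 2)
    colnames(centers) <- c("mean", "sd")
    weights <- weights / sum(weights)
    new("ClusterSet", centers = centers, weights = weights,
        k = nrow(centers),
        inertiaCurve = data.frame(k = integer(), distortion = numeric()),
        transform = transform)
}

#' Earth mover's distance between weighted cluster sets
#'
#' Solves the balanced transportation linear program
#' min sum f[k,l] d[k,l] over flows f >= 0 with row sums w_k, column sums
#' w_l and total flow 1, by the transportation simplex, and returns the
#' normalized EMD sum(f d) / sum(f). The distance is symmetric, zero iff
#' the two weighted point sets coincide, and a metric on equal-mass sets.
#'
#' @param P,Q [ClusterSet-class] objects; weights are renormalized to sum
#'   to 1 (the equal-mass requirement)
#' @param metric ground distance between centers; only "euclidean" is
#'   implemented, taken in the sets' coordinate system
#' @return an [EMDResult-class] (flows below 1e-12 clamped to 0)
#' @examples
#' P <- clusterSet(rbind(c(0, 0), c(1, 0)), c(0.5, 0.5))
#' Q <- clusterSet(rbind(c(0, 0)), 1)
#' earthMoversDistance(P, Q)@distance  # 0.5
#' @export
earthMoversDistance <- function(P, Q, metric = "euclidean") {
    stopifnot(is(P, "ClusterSet"), is(Q, "ClusterSet"))
    metric <- match.arg(metric)
    if (P@transform != Q@transform)
        warning("comparing cluster sets in different coordinate systems")
    w <- P@weights / sum(P@weights)
    v <- Q@weights / sum(Q@weights)
    d <- as.matrix(dist(rbind(P@centers, Q@centers)))
    d <- d[seq_along(w), length(w) + seq_along(v), drop = FALSE]
    sol <- transportSimplex(w, v, d)
    flow <- sol$flow
    flow[flow < 1e-12] <- 0
    res <- new("EMDResult",
               distance = sum(flow * d) / max(sum(flow), 1e-300),
               flow = flow)
    validObject(res)
    res
}

# Transportation simplex (northwest-corner start + MODI pivoting) for the
# balanced problem: supplies w, demands v (both summing to the same total),
# cost matrix d. Supplies are perturbed by tiny distinct amounts to avoid
# degenerate pivoting; the perturbation (~1e-11) is far below the reporting
# clamp.
transportSimplex <- function(w, v, d, maxIter = 20000L) {
    k <- length(w); l <- length(v)
    if (abs(sum(w) - sum(v)) > 1e-6)
        stop("transportation LP infeasible: mass mismatch ",
             abs(sum(w) - sum(v)))
    del <- 1e-11 * max(sum(w), 1)
    w <- w + del * seq_len(k)
    v <- v * (sum(w) / sum(v))
    # northwest-corner initial basic feasible solution
    flow <- matrix(0, k, l)
    basic <- matrix(FALSE, k, l)
    i <- 1L; j <- 1L
    wr <- w; vr <- v
    while (i <= k && j <= l) {
        x <- min(wr[i], vr[j])
        flow[i, j] <- x
        basic[i, j] <- TRUE
        wr[i] <- wr[i] - x
        vr[j] <- vr[j] - x
        if (i == k && j == l) break
        if (wr[i] <= vr[j] && i < k) i <- i + 1L else j <- j + 1L
    }
    for (iter in seq_len(maxIter)) {
        # duals on the basis tree: u_i + t_j = d_ij for basic cells
        u <- rep(NA_real_, k); tt <- rep(NA_real_, l)
        u[1] <- 0
        repeat {
            done <- TRUE
            for (ii in seq_len(k)) if (!is.na(u[ii])) {
                jj <- which(basic[ii, ] & is.na(tt))
                if (length(jj)) { tt[jj] <- d[ii, jj] - u[ii]; done <- FALSE }
            }
            for (jj in seq_len(l)) if (!is.na(tt[jj])) {
                ii <- which(basic[, jj] & is.na(u))
                if (length(ii)) { u[ii] <- d[ii, jj] - tt[jj]; done <- FALSE }
            }
            if (done) break
        }
        red <- d - outer(u, tt, "+")
        red[basic] <- 0
        ent <- which.min(red)
        if (red[ent] >= -1e-10) break
        i0 <- (ent - 1L) %% k + 1L
        j0 <- (ent - 1L) %/% k + 1L
        cyc <- transportCycle(basic, i0, j0)
        minus <- cyc[seq(2, nrow(cyc), by = 2), , drop = FALSE]
        theta <- min(flow[minus])
        sgn <- rep(c(1, -1), length.out = nrow(cyc))
        for (r in seq_len(nrow(cyc)))
            flow[cyc[r, 1], cyc[r, 2]] <-
                flow[cyc[r, 1], cyc[r, 2]] + sgn[r] * theta
        leave <- minus[which.min(flow[minus]), , drop = FALSE]
        basic[leave] <- FALSE
        flow[leave] <- 0
        basic[i0, j0] <- TRUE
        if (iter == maxIter)
            stop("transportation simplex did not converge")
    }
    list(flow = flow, cost = sum(flow * d))
}

# unique alternating cycle closed by the entering cell (i0, j0): a BFS path
# from row i0 to column j0 through the basis tree, returned as cells in
# cycle order starting with the entering cell
transportCycle <- function(basic, i0, j0) {
    k <- nrow(basic); l <- ncol(basic)
    # nodes: rows 1..k, cols k+1..k+l
    parent <- rep(NA_integer_, k + l)
    seen <- rep(FALSE, k + l)
    queue <- i0
    seen[i0] <- TRUE
    target <- k + j0
    while (length(queue)) {
        node <- queue[1]; queue <- queue[-1]
        if (node == target) break
        if (node <= k) {
            nb <- k + which(basic[node, ])
        } else {
            nb <- which(basic[, node - k])
        }
        nb <- nb[!seen[nb]]
        seen[nb] <- TRUE
        parent[nb] <- node
        queue <- c(queue, nb)
    }
    if (!seen[target]) stop("basis is not a spanning tree")
    path <- target
    while (path[1] != i0) path <- c(parent[path[1]], path)
    # consecutive node pairs are basic cells; prepend the entering cell
    cells <- matrix(c(i0, j0), 1, 2)
    for (r in seq_len(length(path) - 1)) {
        a <- path[r]; b <- path[r + 1]
        cells <- rbind(cells,
                       if (a <= k) c(a, b - k) else c(b, a - k))
    }
    cells
}
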