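#' Per-clone mean and standard deviation of sampled abundance
#'
#' Each clone detected at least once inside the time window is summarized by
#' the mean and the population standard deviation (divisor J, not J - 1) of
#' its counts over ALL windowed time points -- zeros included, since a clone
#' absent from a sample is a measured zero.
#'
#' The default window keeps times > 2 months, the regime where sampled
#' richness reflects engrafted HSC clones rather than the transplanted HSPC
#' transient; use `window = c(0, Inf)` for the full record.
#'
#' @param table a [SampleTable-class]
#' @param window c(lo, hi): keep time points with lo < t_j <= hi (months)
#' @return a [CloneCloud-class] without densities (see [kdeDensity()])
#' @examples
#' st <- SampleTable(matrix(c(0, 0, 0, 8), 1), c(3, 6, 9, 12))
#' cloneRecords(cloneSummary(st))  # mean 2, sd sqrt(12)
#' @export
cloneSummary <- function(table, window = c(2, Inf)) {
    stopifnot(is(table, "SampleTable"))
    tm <- sampleTimes(table)
    keep <- tm > window[1] & tm <= window[2]
    if (sum(keep) < 2)
        stop("window must select at least 2 time points (selected ",
             sum(keep), ")")
    cts <- cloneCounts(table)[, keep, drop = FALSE]
    J <- ncol(cts)
    det <- rowSums(cts) > 0
    cts <- cts[det, , drop = FALSE]
    mu <- rowMeans(cts)
    sdev <- sqrt(rowMeans((cts - mu)^2))
    rec <- data.frame(clone_id = rownames(cts), mean = unname(mu),
                      sd = unname(sdev), density = NA_real_,
                      stringsAsFactors = FALSE)
    new("CloneCloud", records = rec, windowMonths = window,
        jEffective = as.integer(J), transform = "log10p",
        bandwidth = NA_real_, densityFun = NULL)
}

#' @rdname cloneburst-generics
setMethod("cloneRecords", "CloneCloud", function(x, ...) x@records)

setMethod("show", "CloneCloud", function(object) {
    r <- object@records
    cat("CloneCloud:", nrow(r), "clones over", object@jEffective,
        sprintf("time points (window %g-%g months)\n",
                object@windowMonths[1], object@windowMonths[2]))
    if (nrow(r))
        cat(sprintf("  mean abundance: %.3g-%.3g; KDE %s\n",
                    min(r$mean), max(r$mean),
                    if (is.na(object@bandwidth)) "not yet evaluated"
                    else sprintf("bandwidth %.3g (%s coords)",
                                 object@bandwidth, object@transform)))
})

# map (mean, sd) data coordinates into the KDE plane
kdeTransform <- function(xy, transform) {
    if (transform == "log10p") log10(1 + xy) else xy
}

#' Kernel density estimate of the clone cloud
#'
#' Isotropic Gaussian KDE over the (mean, SD) clone cloud with a single
#' common bandwidth (Silverman's rule as the stand-in for the
#' MISE-minimizing choice). The density is estimated in log10(1 + x)
#' coordinates by default, because clone sizes span about four decades and a
#' single bandwidth is only meaningful on a homogenized scale; linear-space
#' estimation is available via the cloud's `transform` ("linear").
#'
#' The returned density integrates to 1 over the transformed plane; the
#' `density_norm` column holds the max-normalized variant used for
#' reporting.
#'
#' @param cloud a [CloneCloud-class] from [cloneSummary()] (>= 2 points)
#' @param bandwidthRule only "silverman" is implemented:
#'   h = sqrt((var(u) + var(v))/2) * n^(-1/6) for the two transformed
#'   coordinates u, v
#' @return the cloud with `density` (and `density_norm`) filled in, the
#'   bandwidth recorded, and an evaluable density in `densityFun` (a
#'   function of an n x 2 matrix of (mean, sd) points in data coordinates)
#' @export
kdeDensity <- function(cloud, bandwidthRule = "silverman") {
    stopifnot(is(cloud, "CloneCloud"))
    bandwidthRule <- match.arg(bandwidthRule)
    pts <- as.matrix(cloud@records[, c("mean", "sd")])
    n <- nrow(pts)
    if (n < 2) stop("KDE needs at least 2 points")
    tp <- kdeTransform(pts, cloud@transform)
    h <- sqrt((var(tp[, 1]) + var(tp[, 2])) / 2) * n^(-1 / 6)
    if (!is.finite(h) || h <= 0) {
        warning("degenerate cloud (all points identical): point mass")
        h <- 1e-8
    }
    u <- tp[, 1]; v <- tp[, 2]
    evalTransformed <- function(q) {
        # mean of Gaussian kernels, chunked to bound memory
        out <- numeric(nrow(q))
        step <- 2048L
        for (s in seq(1L, nrow(q), by = step)) {
            e <- min(s + step - 1L, nrow(q))
            d2 <- outer(q[s:e, 1], u, "-")^2 + outer(q[s:e, 2], v, "-")^2
            out[s:e] <- rowMeans(exp(-d2 / (2 * h^2))) / (2 * pi * h^2)
        }
        out
    }
    densityFun <- function(xy) {
        xy <- matrix(xy, ncol = 2)
        evalTransformed(kdeTransform(xy, cloud@transform))
    }
    rho <- evalTransformed(tp)
    # max over a fine grid spanning the cloud, for the normalized variant
    gx <- seq(min(u) - 3 * h, max(u) + 3 * h, length.out = 128)
    gy <- seq(min(v) - 3 * h, max(v) + 3 * h, length.out = 128)
    gmax <- max(evalTransformed(as.matrix(expand.grid(gx, gy))), rho)
    cloud@records$density <- rho
    cloud@records$density_norm <- rho / gmax
    cloud@bandwidth <- h
    cloud@densityFun <- densityFun
    validObject(cloud)
    cloud
}

#' Export a clone cloud as a plain data.frame / TSV
#'
#' @param cloud a [CloneCloud-class]
#' @param path optional file; when given, writes TSV and returns the path
#' @return the records data.frame (invisibly when writing)
#' @export
exportCloneCloud <- function(cloud, path = NULL) {
    rec <- cloneRecords(cloud)
    if (is.null(path)) return(rec)
    write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
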