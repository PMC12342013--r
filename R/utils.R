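#' Convert sampling times between months and days
#'
#' All model rates are per day while sampling schedules are reported in
#' months; the package uses the fixed convention 1 month = 30 days
#' everywhere.
#'
#' @param months,days times to convert
#' @return numeric vector of converted times
#' @export
monthsToDays <- function(months) months * 30

#' @rdname monthsToDays
#' @export
daysToMonths <- function(days) days / 30

# Derive a reproducible sub-seed from a master seed and a stream index.
# Keeps everything below 2^31 so it is a valid R integer seed. The fixed
# integer recurrence makes per-clone streams independent of the order in
# which clones are processed.
deriveSeed <- function(master, stream) {
    master <- as.numeric(master) %% 2147483647
    s <- (master * 48271 + 101 * as.numeric(stream) + 12345) %% 2147483629
    as.integer(s)
}

# Run `expr` with a locally set seed (or with the current RNG state when
# seed is NULL), restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# trapezoidal integral on a (possibly non-uniform) grid
trapz <- function(x, y) {
    n <- length(x)
    if (n < 2) return(0)
    sum((y[-1] + y[-n]) * diff(x)) / 2
}
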