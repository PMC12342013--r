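#' Construct a clone-by-time sample table
#'
#' @param counts integer matrix, clones x time points
#' @param timesMonths sampling times (months), one per column
#' @param cloneIds optional clone labels (default from rownames)
#' @return a [SampleTable-class]
#' @examples
#' st <- SampleTable(matrix(c(1, 0, 2, 2, 0, 5), 3, byrow = TRUE),
#'                   timesMonths = c(1, 2),
#'                   cloneIds = c("bc1", "bc2", "bc3"))
#' sampleRichness(st)
#' @export
SampleTable <- function(counts, timesMonths, cloneIds = rownames(counts)) {
    counts <- as.matrix(counts)
    if (is.null(cloneIds)) cloneIds <- if (nrow(counts))
        sprintf("clone_%04d", seq_len(nrow(counts))) else character()
    storage.mode(counts) <- "integer"
    rownames(counts) <- cloneIds
    colnames(counts) <- sprintf("t%g", timesMonths)
    cd <- S4Vectors::DataFrame(
        time_months = timesMonths,
        total = if (nrow(counts)) unname(colSums(counts))
                else rep(0L, ncol(counts)),
        richness = if (nrow(counts)) unname(colSums(counts > 0))
                   else rep(0L, ncol(counts)),
        row.names = colnames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    new("SampleTable", se)
}

#' @rdname cloneburst-generics
setMethod("sampleTimes", "SampleTable", function(x, ...)
    SummarizedExperiment::colData(x)$time_months)

#' @rdname cloneburst-generics
setMethod("cloneCounts", "SampleTable", function(x, ...)
    SummarizedExperiment::assay(x, "counts"))

#' @rdname cloneburst-generics
setMethod("sampleTotals", "SampleTable", function(x, ...)
    setNames(SummarizedExperiment::colData(x)$total, colnames(x)))

#' @rdname cloneburst-generics
setMethod("sampleRichness", "SampleTable", function(x, ...)
    setNames(SummarizedExperiment::colData(x)$richness, colnames(x)))

#' @rdname cloneburst-generics
setMethod("cloneIds", "SampleTable", function(x, ...) rownames(x))

setMethod("show", "SampleTable", function(object) {
    cat("SampleTable:", nrow(object), "clones x", ncol(object),
        "time points\n")
    tm <- sampleTimes(object)
    if (length(tm))
        cat(sprintf("  times (months): %s\n",
                    paste(signif(tm, 3), collapse = " ")))
    cat("  totals S(t_j):  ",
        paste(sampleTotals(object), collapse = " "), "\n")
    cat("  richness C_s(t_j):",
        paste(sampleRichness(object), collapse = " "), "\n")
})

#' Read a clone abundance table from TSV
#'
#' The dialect is: tab-separated, first column named `barcode`, remaining
#' column headers the sampling times in months (decimals allowed, an
#' optional leading "t" is stripped, e.g. `t4.5`). Body rows are a barcode
#' label followed by integer counts. Rows of all zeros (clones never
#' observed) are permitted but flagged with a message; they count toward
#' neither richness nor clone statistics.
#'
#' @param path file to read
#' @param dialect table dialect; only "tsv" is currently implemented, the
#'   argument is the adapter point for other layouts
#' @return a [SampleTable-class] with totals and richness computed
#' @export
readCountsTable <- function(path, dialect = "tsv") {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, check.names = FALSE, colClasses = "character")
    if (ncol(df) < 2 || tolower(names(df)[1]) != "barcode")
        stop("malformed header: expected 'barcode' then time columns, got: ",
             paste(head(names(df), 3), collapse = ", "))
    tm <- suppressWarnings(as.numeric(sub("^t", "", names(df)[-1])))
    if (any(is.na(tm)))
        stop("malformed header: non-numeric time column(s): ",
             paste(names(df)[-1][is.na(tm)], collapse = ", "))
    ids <- df[[1]]
    cts <- matrix(0L, nrow(df), length(tm))
    for (j in seq_along(tm)) {
        raw <- df[[j + 1]]
        v <- suppressWarnings(as.numeric(raw))
        bad <- which(is.na(v) | v < 0 | v != round(v))
        if (length(bad))
            stop(sprintf(
                "invalid count '%s' at row %d (barcode %s), column %s",
                raw[bad[1]], bad[1], ids[bad[1]], names(df)[j + 1]))
        cts[, j] <- as.integer(v)
    }
    if (nrow(cts) && any(rowSums(cts) == 0))
        message(sum(rowSums(cts) == 0),
                " clone(s) never observed (all-zero rows)")
    SampleTable(cts, timesMonths = tm, cloneIds = ids)
}

#' Write a clone abundance table to TSV
#'
#' Inverse of [readCountsTable()]; the round trip preserves counts exactly.
#'
#' @param x a [SampleTable-class]
#' @param path file to write
#' @return `path`, invisibly
#' @export
writeCountsTable <- function(x, path) {
    stopifnot(is(x, "SampleTable"))
    cts <- cloneCounts(x)
    df <- data.frame(barcode = rownames(cts), cts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c("barcode", sprintf("t%g", sampleTimes(x)))
    ok <- tryCatch({
        write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
        TRUE
    }, error = function(e) stop("cannot write table: ", conditionMessage(e)))
    invisible(path)
}
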