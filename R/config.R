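#' Read and write model configuration files
#'
#' One YAML file holds the model parameters, the sampling schedule, seeds
#' and (optionally) fitting grids. Defaults written by
#' `writeModelConfig(makePreset("ZH33")...)` are the ZH33 reference values.
#'
#' @param path YAML file
#' @return `readModelConfig`: list(params = [ModelParams-class],
#'   schedule = [SamplingSchedule-class], seed, fit = list or NULL)
#' @export
readModelConfig <- function(path) {
    if (!file.exists(path)) stop("config not found: ", path)
    y <- yaml::read_yaml(path)
    params <- paramsFromList(y$params)
    schedule <- new("SamplingSchedule",
                    timesMonths = as.numeric(y$schedule$times_months),
                    etaJ = as.numeric(y$schedule$eta_j))
    validObject(schedule)
    list(params = params, schedule = schedule,
         seed = y$seed, fit = y$fit)
}

#' @rdname readModelConfig
#' @param params a [ModelParams-class]
#' @param schedule a [SamplingSchedule-class]
#' @param seed integer seed recorded alongside
#' @param fit optional list of fitting grids
#' @export
writeModelConfig <- function(params, schedule, path, seed = 1,
                             fit = NULL) {
    pl <- paramsAsList(params)
    pl$hspcInit <- as.list(pl$hspcInit)
    y <- list(params = pl,
              schedule = list(times_months = schedule@timesMonths,
                              eta_j = schedule@etaJ),
              seed = seed)
    if (!is.null(fit)) y$fit <- fit
    yaml::write_yaml(y, path)
    invisible(path)
}

#' Write / read a machine-readable fit report
#'
#' JSON report containing the full parameter estimate, per-stage records,
#' the final EMD, seeds and the package version. `readFitReport`
#' reconstructs the [ModelParams-class]; the write-read round trip is
#' exact up to JSON number formatting (digits = NA keeps full precision).
#'
#' @param result a [FitResult-class]
#' @param path output file
#' @return `path` invisibly; `readFitReport` returns list(params, report)
#' @export
writeFitReport <- function(result, path) {
    stopifnot(is(result, "FitResult"))
    pl <- paramsAsList(result@bestParams)
    pl$hspcInit <- as.list(pl$hspcInit)
    stages <- lapply(result@stageRecords, function(s) {
        if (is.data.frame(s)) as.list(s) else s
    })
    rep <- list(package = "cloneburst",
                version = as.character(packageVersion("cloneburst")),
                seed = result@seed,
                replicates = result@replicates,
                params = pl,
                eta_multipliers = result@etaMultipliers,
                final_emd = result@finalEmd,
                stages = stages)
    ok <- tryCatch(
        jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                             null = "null", pretty = TRUE),
        error = function(e) stop("cannot write report: ",
                                 conditionMessage(e)))
    invisible(path)
}

#' @rdname writeFitReport
#' @export
readFitReport <- function(path) {
    if (!file.exists(path)) stop("report not found: ", path)
    y <- jsonlite::read_json(path, simplifyVector = TRUE)
    params <- paramsFromList(y$params)
    list(params = params, report = y)
}
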