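#' Construct an expression table
#'
#' @param data data.frame with columns `cell_id`, `zak`, `mkk4`, `mkk7`,
#'   `jnk`, `pakt`.
#' @param provenance "measured" or "synthetic".
#' @param normalized has the table been normalized to a reference mean of 1?
#' @return an [ExpressionTable-class] object.
#' @export
expressionTable <- function(data, provenance = "measured",
                            normalized = FALSE) {
    data$cell_id <- as.character(data$cell_id)
    new("ExpressionTable", data = data, provenance = provenance,
        normalized = normalized)
}

#' Number of cells in a container
#'
#' @param x an [ExpressionTable-class], [EnsembleResult-class] or
#'   [TrackSet-class] object.
#' @return integer cell count.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname nCells
#' @export
setMethod("nCells", "ExpressionTable", function(x) nrow(x@data))

#' @rdname nCells
#' @export
setMethod("nCells", "EnsembleResult", function(x) length(x@cellId))

#' @rdname nCells
#' @export
setMethod("nCells", "TrackSet",
          function(x) length(unique(x@data$cell_id)))

#' Normalize an expression table to reference means
#'
#' Divides each component by the mean measured in a reference population
#' (the parental line), so the reference population has mean 1 per
#' component.  Idempotent when the reference means are the table's own
#' component means.
#'
#' @param raw an [ExpressionTable-class] object.
#' @param referenceMeans named numeric vector of per-component reference
#'   means (> 0); defaults to the table's own component means.
#' @return a normalized [ExpressionTable-class] object.
#' @export
normalizeToReference <- function(raw, referenceMeans = NULL) {
    d <- raw@data
    if (is.null(referenceMeans))
        referenceMeans <- colMeans(d[.COMPONENTS])
    referenceMeans <- referenceMeans[.COMPONENTS]
    if (any(is.na(referenceMeans)) || any(referenceMeans <= 0))
        stop("reference means must be present and > 0 for all components")
    for (k in .COMPONENTS) d[[k]] <- d[[k]] / referenceMeans[[k]]
    expressionTable(d, provenance = raw@provenance, normalized = TRUE)
}

#' Simulate an ensemble of single cells
#'
#' Runs one basal and one saturated-stimulus simulation per cell of the
#' table, each starting from that cell's pre-stimulus steady state, and
#' records the per-condition peak active JNK.  Peaks are additionally
#' normalized to the highest simulated value across the ensemble.  A
#' failing cell is flagged and skipped; more than `maxFailFraction`
#' failures abort the run.
#'
#' @param table an [ExpressionTable-class] object.
#' @param params a [KineticParameters-class] object.
#' @param stimulusBasal,stimulusSat basal and saturating inputs (defaults
#'   50 and 1000 arbitrary stress units, i.e. basal = saturated/20).
#' @param duration simulated minutes per condition.
#' @param grid output grid (minutes).
#' @param maxFailFraction hard-error threshold on the per-cell failure
#'   rate.
#' @param seed seed recorded in the result when the table came from a
#'   seeded generator (metadata only; the simulation is deterministic).
#' @return an [EnsembleResult-class] object.
#' @examples
#' \donttest{
#' tab <- genExpressionTable(generatorConfig(nCells = 20L))
#' ens <- simulateEnsemble(tab)
#' impairedFraction(ens)
#' }
#' @export
simulateEnsemble <- function(table, params = defaultKineticParameters(),
                             stimulusBasal = 50, stimulusSat = 1000,
                             duration = 240, grid = 2,
                             maxFailFraction = 0.01, seed = NA_integer_) {
    if (stimulusBasal >= stimulusSat)
        stop("stimulusBasal must be smaller than stimulusSat")
    d <- table@data
    n <- nrow(d)
    basalPeak <- stimPeak <- rep(NA_real_, n)
    failed <- rep(FALSE, n)
    for (i in seq_len(n)) {
        res <- tryCatch({
            prof <- unlist(d[i, .COMPONENTS])
            net <- buildNetwork(prof, params)
            b <- simulateCell(net, stimulusBasal, duration = duration,
                              grid = grid, basal = stimulusBasal)
            s <- simulateCell(net, stimulusSat, duration = duration,
                              grid = grid, basal = stimulusBasal)
            c(peakActiveJNK(b), peakActiveJNK(s))
        }, error = function(e) NULL)
        if (is.null(res)) failed[i] <- TRUE
        else { basalPeak[i] <- res[1]; stimPeak[i] <- res[2] }
    }
    if (n > 0 && mean(failed) > maxFailFraction)
        stop(sprintf("%d of %d cells failed to simulate", sum(failed), n))
    mx <- suppressWarnings(max(c(basalPeak, stimPeak), na.rm = TRUE))
    norm <- if (is.finite(mx) && mx > 0) mx else 1
    new("EnsembleResult", cellId = as.character(d$cell_id),
        basalPeak = basalPeak, stimPeak = stimPeak,
        basalNorm = basalPeak / norm, stimNorm = stimPeak / norm,
        failed = failed,
        feedback = if (feedbackEnabled(params)) "full" else "none",
        seed = as.integer(seed), paramHash = .paramHash(params))
}

#' Fraction of JNK-impaired cells
#'
#' The operational definition of chemoresistance-prone cells: the fraction
#' of cells whose saturated-stimulus peak active JNK does not exceed the
#' population mean of the basal-condition peaks.  Cells exactly at the
#' mean count as impaired ("unable to activate above the mean").
#'
#' @param ens an [EnsembleResult-class] object.
#' @return fraction in `[0, 1]`.
#' @export
impairedFraction <- function(ens) {
    ok <- !ens@failed
    if (!any(ok)) stop("empty ensemble")
    mean(ens@stimPeak[ok] <= mean(ens@basalPeak[ok]))
}

#' Compare ensembles with and without the positive feedback
#'
#' Simulates the identical cells under the full model and under the
#' feedback knockout ([disableFeedback()]), and summarizes the amplitude
#' ratio and the coefficient-of-variation pair of the stimulated peaks.
#'
#' @inheritParams simulateEnsemble
#' @return list with elements `full` and `nofeedback` (both
#'   [EnsembleResult-class]) and `summary` (one-row data.frame with
#'   `mean_full`, `mean_nofb`, `amplitude_ratio`, `cov_full`, `cov_nofb`).
#' @export
feedbackComparison <- function(table, params = defaultKineticParameters(),
                               stimulusBasal = 50, stimulusSat = 1000,
                               duration = 240, grid = 2) {
    full <- simulateEnsemble(table, params, stimulusBasal, stimulusSat,
                             duration, grid)
    nofb <- simulateEnsemble(table, disableFeedback(params), stimulusBasal,
                             stimulusSat, duration, grid)
    okF <- !full@failed; okN <- !nofb@failed
    s <- data.frame(
        mean_full = mean(full@stimPeak[okF]),
        mean_nofb = mean(nofb@stimPeak[okN]),
        cov_full = coefficientOfVariation(full@stimPeak[okF]),
        cov_nofb = coefficientOfVariation(nofb@stimPeak[okN]))
    s$amplitude_ratio <- s$mean_full / s$mean_nofb
    list(full = full, nofeedback = nofb, summary = s)
}

#' Predict relative JNK activation from bulk profiles
#'
#' One deterministic saturated-stimulus simulation per named profile (e.g.
#' relative expression measured per cell line or tumor by quantitative
#' Western blotting), normalized to the maximum across the provided set.
#'
#' @param profiles named list of abundance vectors
#'   (see [expressionProfile()]).
#' @param params a [KineticParameters-class] object.
#' @param stimulusSat,stimulusBasal,duration,grid simulation settings.
#' @return data.frame (`name`, `peak`, `predicted` normalized to the set
#'   maximum, `error` message for invalid profiles).
#' @export
predictBulkResponse <- function(profiles,
                                params = defaultKineticParameters(),
                                stimulusSat = 1000, stimulusBasal = 50,
                                duration = 240, grid = 1) {
    if (length(profiles) < 1) stop("need at least one profile")
    if (is.null(names(profiles)))
        names(profiles) <- paste0("profile_", seq_along(profiles))
    peak <- rep(NA_real_, length(profiles))
    err <- rep(NA_character_, length(profiles))
    for (i in seq_along(profiles)) {
        res <- tryCatch(
            peakActiveJNK(simulateCell(buildNetwork(profiles[[i]], params),
                                       stimulusSat, duration = duration,
                                       grid = grid, basal = stimulusBasal)),
            error = function(e) e)
        if (inherits(res, "error")) err[i] <- conditionMessage(res)
        else peak[i] <- res
    }
    mx <- suppressWarnings(max(peak, na.rm = TRUE))
    data.frame(name = names(profiles), peak = peak,
               predicted = peak / ifelse(is.finite(mx) && mx > 0, mx, 1),
               error = err, row.names = NULL)
}

#' Write an ensemble result as CSV plus JSON sidecar
#'
#' The CSV carries one row per cell (`cell_id`, `basal_peak`, `stim_peak`,
#' `basal_norm`, `stim_norm`, `failed`); the sidecar records seed,
#' parameter hash, feedback mode and the run metadata passed in `extra`.
#'
#' @param ens an [EnsembleResult-class] object.
#' @param path CSV output path (`<path>.json` is written alongside).
#' @param extra named list merged into the sidecar.
#' @return invisibly, the CSV path.
#' @export
writeEnsembleResult <- function(ens, path, extra = list()) {
    utils::write.csv(as.data.frame(ens), path, row.names = FALSE)
    side <- c(list(seed = ens@seed, param_hash = ens@paramHash,
                   feedback = ens@feedback, n_cells = nCells(ens)),
              extra)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
    invisible(path)
}

#' @describeIn writeEnsembleResult coerce to the per-cell data.frame.
#' @param x an [EnsembleResult-class] object.
#' @param ... unused.
#' @export
as.data.frame.EnsembleResult <- function(x, ...) {
    data.frame(cell_id = x@cellId, basal_peak = x@basalPeak,
               stim_peak = x@stimPeak, basal_norm = x@basalNorm,
               stim_norm = x@stimNorm, failed = x@failed)
}
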