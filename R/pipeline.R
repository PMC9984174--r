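#' Load and validate a single-cell expression table
#'
#' @param path CSV/TSV file with columns `cell_id`, `zak`, `mkk4`, `mkk7`,
#'   `jnk`, `pakt`; the separator is inferred from the extension.
#' @param normalized is the table already normalized to reference mean 1?
#' @return an [ExpressionTable-class] object.  Extra columns are preserved
#'   with a warning; missing columns, non-numeric cells and duplicated
#'   cell ids raise descriptive errors.
#' @export
loadExpressionTable <- function(path, normalized = FALSE) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    d <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
    need <- c("cell_id", .COMPONENTS)
    missing <- setdiff(need, names(d))
    if (length(missing))
        stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
    for (k in .COMPONENTS)
        if (!is.numeric(d[[k]]))
            stop(sprintf("non-numeric values in column '%s'", k))
    dup <- d$cell_id[duplicated(d$cell_id)]
    if (length(dup))
        stop(sprintf("duplicated cell_id: %s", dup[1]))
    extra <- setdiff(names(d), need)
    if (length(extra))
        warning(sprintf("extra column(s) preserved: %s",
                        paste(extra, collapse = ", ")))
    expressionTable(d, provenance = "measured", normalized = normalized)
}

#' Load and validate a long-format track table
#'
#' @param path CSV/TSV file with columns `cell_id`, `time_min`,
#'   `ktr_ratio`, `reporter_mfi`, `caspase_mfi`.
#' @return a [TrackSet-class] object.
#' @export
loadTrackTable <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    d <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
    need <- c("cell_id", "time_min", "ktr_ratio", "reporter_mfi",
              "caspase_mfi")
    missing <- setdiff(need, names(d))
    if (length(missing))
        stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
    for (k in setdiff(need, "cell_id"))
        if (!is.numeric(d[[k]]))
            stop(sprintf("non-numeric values in column '%s'", k))
    d <- d[order(d$cell_id, d$time_min), , drop = FALSE]
    trackSet(d)
}

.runManifest <- function(seed, params, extra = list()) {
    c(list(package_version = as.character(utils::packageVersion("jnknoise")),
           seed = seed, param_hash = .paramHash(params),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      extra)
}

#' Run the single-cell ensemble experiment
#'
#' The full first-stage workflow: take (or generate) a normalized
#' single-cell expression table, simulate every cell at the basal and
#' saturating inputs, and summarize the emergent statistics -- the
#' JNK-impaired fraction, the output coefficient of variation, and the
#' with/without-feedback comparison.  With `outDir` set, writes the
#' per-cell ensemble CSVs (with JSON sidecars), a `summary.json` and a
#' run manifest.
#'
#' @param table an [ExpressionTable-class]; generated from `config` when
#'   NULL.
#' @param config a [GeneratorConfig-class] used when `table` is NULL.
#' @param params a [KineticParameters-class] object.
#' @param stimulusSat saturating input (stress units).
#' @param basalFraction basal input as a fraction of `stimulusSat`.
#' @param duration,grid simulation settings (minutes).
#' @param compareFeedback also run the feedback-knockout ensemble.
#' @param outDir optional output directory.
#' @return list with `ensemble`, optional `nofeedback`, `summary`
#'   (one-row data.frame) and `manifest`.
#' @export
runSingleCellExperiment <- function(table = NULL,
                                    config = generatorConfig(),
                                    params = defaultKineticParameters(),
                                    stimulusSat = 1000,
                                    basalFraction = 1 / 20,
                                    duration = 240, grid = 2,
                                    compareFeedback = TRUE,
                                    outDir = NULL) {
    seed <- if (is.null(table)) config@seed else NA_integer_
    if (is.null(table)) table <- genExpressionTable(config)
    basal <- stimulusSat * basalFraction
    ens <- simulateEnsemble(table, params, stimulusBasal = basal,
                            stimulusSat = stimulusSat, duration = duration,
                            grid = grid, seed = seed)
    ok <- !ens@failed
    summary <- data.frame(
        n_cells = nCells(ens),
        n_failed = sum(ens@failed),
        feedback = ens@feedback,
        impaired_fraction = impairedFraction(ens),
        cov_stim_percent = coefficientOfVariation(ens@stimPeak[ok]),
        cov_basal_percent = coefficientOfVariation(ens@basalPeak[ok]))
    nofb <- NULL
    if (compareFeedback && feedbackEnabled(params)) {
        nofb <- simulateEnsemble(table, disableFeedback(params),
                                 stimulusBasal = basal,
                                 stimulusSat = stimulusSat,
                                 duration = duration, grid = grid,
                                 seed = seed)
        okN <- !nofb@failed
        summary$cov_nofeedback_percent <-
            coefficientOfVariation(nofb@stimPeak[okN])
        summary$amplitude_ratio <-
            mean(ens@stimPeak[ok]) / mean(nofb@stimPeak[okN])
    }
    manifest <- .runManifest(seed, params,
                             list(stimulus_sat = stimulusSat,
                                  stimulus_basal = basal,
                                  duration = duration, grid = grid,
                                  feedback = ens@feedback))
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        writeEnsembleResult(ens, file.path(outDir, "ensemble.csv"),
                            extra = manifest)
        if (!is.null(nofb))
            writeEnsembleResult(nofb,
                                file.path(outDir, "ensemble_nofeedback.csv"),
                                extra = manifest)
        jsonlite::write_json(as.list(summary),
                             file.path(outDir, "summary.json"),
                             auto_unbox = TRUE, digits = NA)
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    list(ensemble = ens, nofeedback = nofb, summary = summary,
         manifest = manifest)
}

#' Run the single-cell threshold experiment
#'
#' The second-stage workflow on longitudinal traces: generate (or accept)
#' a track set, apply the expression-bound and tracking-coverage filters,
#' call caspase onsets, measure peak-window JNK activity (converted
#' through the reporter model and normalized to the highest value
#' recorded), group peaks by apoptotic outcome with gated statistics, and
#' estimate the commitment curve.
#'
#' @param tracks a [TrackSet-class]; generated end-to-end from `config`
#'   when NULL (expression table, ensemble, then tracks).
#' @param config a [GeneratorConfig-class] object.
#' @param params a [KineticParameters-class] object.
#' @param reporter a [ReporterParameters-class] object.
#' @param window peak-activity window in minutes (the early phase of
#'   drug-induced JNK activity).
#' @param mfiBounds reporter expression retention bounds (MFI).
#' @param coverageMode,minMinutes tracking-coverage filter settings.
#' @param caspaseThreshold onset cutoff (MFI).
#' @param bins commitment-curve bin count.
#' @param outDir optional output directory for the filter log, per-cell
#'   results, statistics CSV and manifest.
#' @return list with `tracks` (filtered), `filterLog`, `onsets`, `peaks`
#'   (per-cell normalized activity), `groups` ([OutcomeGroups-class]),
#'   `stats` (gated comparison row), `curve` (commitment curve), `truth`
#'   (generator ground truth when synthetic) and `manifest`.
#' @export
runThresholdExperiment <- function(tracks = NULL,
                                   config = generatorConfig(),
                                   params = defaultKineticParameters(),
                                   reporter = defaultReporterParameters(),
                                   window = c(0, 240),
                                   mfiBounds = c(10, 200),
                                   coverageMode = "min_minutes",
                                   minMinutes = 480,
                                   caspaseThreshold = 50,
                                   bins = 10,
                                   outDir = NULL) {
    truth <- NULL
    seed <- NA_integer_
    if (is.null(tracks)) {
        seed <- config@seed
        tab <- genExpressionTable(config)
        ens <- simulateEnsemble(tab, params, seed = config@seed)
        gen <- genCellTracks(ens, config, reporter)
        tracks <- gen$tracks
        truth <- gen$truth
    }
    filtered <- filterTrackingCoverage(
        filterExpressionBounds(tracks, mfiBounds[1], mfiBounds[2]),
        mode = coverageMode, minMinutes = minMinutes)
    onsets <- detectCaspaseOnsets(filtered, caspaseThreshold)
    peaks <- peakWindowActivities(filtered, window = window, rp = reporter,
                                  smooth = "median3")
    ## normalization anchor: the highest activity recorded across ALL
    ## tracks, so QC exclusions do not rescale the activity axis
    anchor <- max(peakWindowActivities(tracks, window = window,
                                       rp = reporter,
                                       smooth = "median3")$peak)
    peaks$peak <- if (anchor > 0) peaks$peak / anchor else peaks$peak
    groups <- groupByOutcome(peaks, onsets)
    stats <- if (groups@defined)
        gatedComparison(groups@apoptotic, groups@nonapoptotic)
    else data.frame(n1 = length(groups@apoptotic),
                    n2 = length(groups@nonapoptotic),
                    p = NA_real_, d = NA_real_, class = NA_character_,
                    gated = NA)
    outcomes <- !is.na(onsets$onset[match(peaks$cell_id, onsets$cell_id)])
    curve <- if (length(unique(outcomes)) > 1)
        commitmentCurve(peaks$peak, outcomes, bins = bins)
    else list(bins = NULL, midpoint = NA_real_, defined = FALSE)
    manifest <- .runManifest(seed, params,
                             list(window = window, mfi_bounds = mfiBounds,
                                  coverage_mode = coverageMode,
                                  min_minutes = minMinutes,
                                  caspase_threshold = caspaseThreshold,
                                  bins = bins,
                                  theta_estimate = curve$midpoint))
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(filtered@filterLog,
                         file.path(outDir, "filter_log.csv"),
                         row.names = FALSE)
        percell <- merge(peaks, onsets, by = "cell_id")
        utils::write.csv(percell, file.path(outDir, "cells.csv"),
                         row.names = FALSE)
        utils::write.csv(cbind(comparison_id = "apoptotic_vs_nonapoptotic",
                               stats),
                         file.path(outDir, "stats.csv"), row.names = FALSE)
        jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, na = "null")
    }
    list(tracks = filtered, filterLog = filtered@filterLog,
         onsets = onsets, peaks = peaks, groups = groups, stats = stats,
         curve = curve, truth = truth, manifest = manifest)
}
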