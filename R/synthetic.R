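#' Synthetic-study configuration
#'
#' Defaults emulate the study's measurement conditions: ensembles of
#' n = 2000 cells; independent log-normal expression noise with
#' per-component CoV targets spread over the 33-43% range measured by
#' five-color flow cytometry; 15-min trace sampling over 16 hours; a
#' phenomenological apoptotic commitment layer (logistic in the normalized
#' peak JNK activity, threshold 0.6, slope 20) standing in for the
#' downstream MCL-1/BCL-2 machinery; and caspase onset delayed into the
#' 8-24 h band.
#'
#' @param nCells number of cells.
#' @param cov named per-component CoV targets (fractions, > 0).
#' @param family noise distribution family ("lognormal").
#' @param seed integer seed; recorded in all outputs.
#' @param sampleInterval trace sampling interval in minutes (5 or 15 in
#'   the imaging protocols; any positive value accepted).
#' @param traceDuration trace length in minutes.
#' @param traceNoiseSD additive measurement noise SD on the C:N ratio
#'   (about 1% of the reporter's dynamic range, typical of high-content
#'   ratio imaging).
#' @param peakTime time of peak JNK activity in the trace drive (minutes;
#'   drug-induced JNK peaks at roughly 2 hours).
#' @param theta commitment threshold on the normalized peak-activity
#'   scale.
#' @param beta logistic slope of the commitment layer.
#' @param thresholdModifier multiplicative shift of theta (anti-apoptotic
#'   over-expression raises it, BH3 mimetics lower it).
#' @param primingFold named per-component fold-changes applied by
#'   [applyPrimingShift()] (HDAC-inhibitor priming up-shifts all five).
#' @param onsetBand caspase onset window (minutes after stimulation).
#' @param activityScale reporter-units activity driven by a normalized
#'   peak of 1 (kept below the 200-unit saturation cap so synthetic traces
#'   span the reporter's dynamic range the way the imaging data do).
#' @param mfiMeanlog,mfiSdlog log-normal parameters of the per-cell
#'   reporter expression level (chosen so a few percent of cells fall
#'   outside the 10-200 MFI retention bounds).
#' @param correlation optional 5x5 inter-component correlation matrix
#'   (identity by default: components sampled independently).
#' @return a [GeneratorConfig-class] object.
#' @export
generatorConfig <- function(nCells = 2000L,
                            cov = c(zak = 0.43, mkk4 = 0.35, mkk7 = 0.39,
                                    jnk = 0.33, pakt = 0.41),
                            family = "lognormal",
                            seed = 1L,
                            sampleInterval = 15, traceDuration = 960,
                            traceNoiseSD = 0.02,
                            peakTime = 120,
                            theta = 0.6, beta = 20,
                            thresholdModifier = 1,
                            primingFold = c(zak = 1, mkk4 = 1, mkk7 = 1,
                                            jnk = 1, pakt = 1),
                            onsetBand = c(480, 1440),
                            activityScale = 150,
                            mfiMeanlog = log(60), mfiSdlog = 0.8,
                            correlation = diag(5)) {
    new("GeneratorConfig", nCells = as.integer(nCells),
        cov = cov[.COMPONENTS], family = family, seed = as.integer(seed),
        sampleInterval = sampleInterval, traceDuration = traceDuration,
        traceNoiseSD = traceNoiseSD, peakTime = peakTime,
        theta = theta, beta = beta, thresholdModifier = thresholdModifier,
        primingFold = primingFold[.COMPONENTS], onsetBand = onsetBand,
        activityScale = activityScale,
        mfiMeanlog = mfiMeanlog, mfiSdlog = mfiSdlog,
        correlation = correlation)
}

#' Generate a flow-like single-cell expression table
#'
#' Samples each component log-normally with mean 1 and the configured
#' CoV; with the default identity correlation the components are
#' independent, otherwise a Gaussian copula on the log scale applies the
#' configured correlation matrix.  Pure function of the configuration
#' (including its seed).
#'
#' @param cfg a [GeneratorConfig-class] object.
#' @return a normalized synthetic [ExpressionTable-class].
#' @examples
#' tab <- genExpressionTable(generatorConfig(nCells = 100L))
#' @export
genExpressionTable <- function(cfg = generatorConfig()) {
    set.seed(cfg@seed)
    n <- cfg@nCells
    sdlog <- sqrt(log(1 + cfg@cov^2))
    z <- matrix(stats::rnorm(n * 5), n, 5)
    if (!identical(unname(cfg@correlation), diag(5))) {
        ch <- chol(cfg@correlation)
        z <- z %*% ch
    }
    d <- data.frame(cell_id = sprintf("cell_%05d", seq_len(n)))
    for (j in seq_along(.COMPONENTS)) {
        s <- sdlog[[j]]
        d[[.COMPONENTS[j]]] <- exp(z[, j] * s - s^2 / 2)
    }
    expressionTable(d, provenance = "synthetic", normalized = TRUE)
}

#' Apply a priming fold-change to an expression table
#'
#' Componentwise multiplication emulating pharmacological priming that
#' up-shifts network component expression.  Scale invariance of the CoV
#' means the noise structure is untouched; only the means move.
#'
#' @param table an [ExpressionTable-class] object.
#' @param foldChanges named per-component multipliers (> 0).
#' @return the shifted [ExpressionTable-class].
#' @export
applyPrimingShift <- function(table, foldChanges) {
    fc <- foldChanges[.COMPONENTS]
    if (any(is.na(fc)) || any(fc <= 0))
        stop("fold changes must be > 0 for all five components")
    d <- table@data
    for (k in .COMPONENTS) d[[k]] <- d[[k]] * fc[[k]]
    expressionTable(d, provenance = table@provenance,
                    normalized = table@normalized)
}

## per-cell activity drive: rise-and-decay profile peaking at peakTime
## with the cell's stimulated peak, floored at its basal level
.activityDrive <- function(basal, peak, times, peakTime) {
    shape <- (times / peakTime) * exp(1 - times / peakTime)
    outer(pmax(peak - basal, 0), shape) + basal
}

#' Generate synthetic biosensor tracks for an ensemble
#'
#' Drives the dynamic reporter model with a per-cell rise-and-decay
#' activity profile peaking at the cell's (normalized) stimulated peak
#' scaled into reporter units, adds Gaussian measurement noise to the
#' sampled C:N ratio, draws a per-cell reporter expression level (some
#' outside the 10-200 MFI bounds, to exercise the QC filters), and fills
#' the caspase channel from the commitment layer
#' ([genCaspaseOutcomes()]).
#'
#' @param ens an [EnsembleResult-class] object.
#' @param cfg a [GeneratorConfig-class] object.
#' @param rp a [ReporterParameters-class] object.
#' @return list with `tracks` (a [TrackSet-class]) and `truth`
#'   (data.frame `cell_id`, `peak_norm`, `apoptotic`, `onset`): the
#'   generator-side ground truth.
#' @export
genCellTracks <- function(ens, cfg = generatorConfig(),
                          rp = defaultReporterParameters()) {
    ok <- !ens@failed
    if (!any(ok)) stop("empty ensemble")
    id <- ens@cellId[ok]
    n <- length(id)
    times <- seq(0, cfg@traceDuration, by = cfg@sampleInterval)
    act <- .activityDrive(ens@basalNorm[ok] * cfg@activityScale,
                          ens@stimNorm[ok] * cfg@activityScale,
                          times, cfg@peakTime)
    set.seed(cfg@seed + 1L)
    ratio <- simulateReporterTraces(act, times, rp)
    if (cfg@traceNoiseSD > 0)
        ratio <- pmax(ratio + matrix(stats::rnorm(length(ratio), 0,
                                                  cfg@traceNoiseSD),
                                     nrow(ratio)), 1e-6)
    mfi <- stats::rlnorm(n, cfg@mfiMeanlog, cfg@mfiSdlog)
    casp <- genCaspaseOutcomes(stats::setNames(ens@stimNorm[ok], id), cfg,
                               times = times)
    d <- data.frame(
        cell_id = rep(id, each = length(times)),
        time_min = rep(times, n),
        ktr_ratio = as.vector(t(ratio)),
        reporter_mfi = rep(mfi, each = length(times)),
        caspase_mfi = casp$traces$caspase_mfi)
    list(tracks = trackSet(d),
         truth = data.frame(cell_id = id,
                            peak_norm = ens@stimNorm[ok],
                            apoptotic = casp$outcomes$apoptotic,
                            onset = casp$outcomes$onset))
}

#' Draw apoptotic outcomes and caspase traces from peak activities
#'
#' The generator-side commitment layer: apoptosis is Bernoulli with
#' probability `plogis(beta * (peak - theta * thresholdModifier))`;
#' apoptotic cells receive a caspase-reporter trace that first exceeds
#' 50 MFI at an onset time drawn on the sample grid within the configured
#' onset band (truncated to the trace duration).  Analysis-side code never
#' assumes this logistic form.
#'
#' @param peaks named numeric vector of per-cell peak activities on the
#'   normalized scale the threshold is defined on.
#' @param cfg a [GeneratorConfig-class] object.
#' @param times sample grid (minutes); defaults to the configured
#'   interval/duration.
#' @return list with `outcomes` (data.frame `cell_id`, `apoptotic`,
#'   `onset`; onset NA for nonapoptotic cells or onsets beyond the traced
#'   period) and `traces` (long data.frame `cell_id`, `time_min`,
#'   `caspase_mfi`).
#' @export
genCaspaseOutcomes <- function(peaks, cfg = generatorConfig(),
                               times = seq(0, cfg@traceDuration,
                                           by = cfg@sampleInterval)) {
    n <- length(peaks)
    id <- if (is.null(names(peaks))) sprintf("cell_%05d", seq_len(n))
          else names(peaks)
    set.seed(cfg@seed + 2L)
    p <- stats::plogis(cfg@beta *
                       (peaks - cfg@theta * cfg@thresholdModifier))
    apoptotic <- stats::runif(n) < p
    band <- cfg@onsetBand
    gridInBand <- times[times >= band[1] & times <= band[2]]
    onset <- rep(NA_real_, n)
    if (any(apoptotic)) {
        if (length(gridInBand) == 0)
            stop("onset band contains no sample time")
        onset[apoptotic] <- sample(gridInBand, sum(apoptotic),
                                   replace = TRUE)
    }
    base <- matrix(pmax(stats::rnorm(n * length(times), 5, 2), 0),
                   n, length(times))
    for (i in which(apoptotic)) {
        post <- times >= onset[i]
        base[i, post] <- 60 + 0.5 * (times[post] - onset[i]) +
            stats::rnorm(sum(post), 0, 2)
    }
    list(outcomes = data.frame(cell_id = id, apoptotic = apoptotic,
                               onset = onset),
         traces = data.frame(cell_id = rep(id, each = length(times)),
                             time_min = rep(times, n),
                             caspase_mfi = as.vector(t(base))))
}
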