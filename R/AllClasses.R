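#' @import methods
NULL

.COMPONENTS <- c("zak", "mkk4", "mkk7", "jnk", "pakt")

.RATE_NAMES <- c("kin", "kmz", "kpz",
                 "k4", "km4", "p4",
                 "k7", "km7", "p7",
                 "k44", "k77", "kmj", "pj",
                 "kfb", "pfb", "gfb",
                 "ka4", "ka7", "krec")

.TOTAL_NAMES <- c("zak", "mkk4", "mkk7", "jnk")

#' Kinetic parameters of the JNK network model
#'
#' Holds every rate constant of the cascade (catalytic rates and Michaelis
#' constants of the kinase steps, first-order phosphatase rates, the
#' stress-input coupling, the JNK-to-MKK7 feedback rate/gain and the
#' Akt cross-talk rates) together with the reference total concentration of
#' each protein pool.  Relative single-cell abundances multiply these
#' reference totals when a network is built for one cell.
#'
#' Slots:
#' \describe{
#'   \item{rates}{named numeric vector of the 19 kinetic constants
#'     (time unit minutes, concentrations in arbitrary units).}
#'   \item{totals}{named numeric vector; reference total concentration of
#'     zak, mkk4, mkk7 and jnk for the nominal (all-ones) cell.}
#' }
#'
#' The feedback is disabled exactly when the feedback catalytic rate
#' (`kfb`) is 0 and the gain multiplier contributes nothing (`gfb` = 1);
#' see [disableFeedback()].
#'
#' @seealso [calibrateNominal()], [defaultKineticParameters()],
#'   [buildNetwork()]
#' @export
setClass("KineticParameters",
         representation(rates = "numeric", totals = "numeric"))

setValidity("KineticParameters", function(object) {
    msg <- character()
    if (!identical(names(object@rates), .RATE_NAMES))
        msg <- c(msg, sprintf("rates must be named exactly: %s",
                              paste(.RATE_NAMES, collapse = ", ")))
    if (any(!is.finite(object@rates)) || any(object@rates < 0))
        msg <- c(msg, "all rate constants must be finite and >= 0")
    if (!identical(names(object@totals), .TOTAL_NAMES))
        msg <- c(msg, sprintf("totals must be named exactly: %s",
                              paste(.TOTAL_NAMES, collapse = ", ")))
    if (any(!is.finite(object@totals)) || any(object@totals <= 0))
        msg <- c(msg, "all reference totals must be finite and > 0")
    if (length(msg)) msg else TRUE
})

#' Single-cell JNK network instance
#'
#' The ODE system for one cell: kinetic parameters plus the cell's relative
#' expression profile (zak, mkk4, mkk7, jnk, pakt; reference mean 1), which
#' scales the protein pools and the Akt cross-talk flux.
#'
#' @seealso [buildNetwork()], [simulateCell()]
#' @export
setClass("ParameterizedNetwork",
         representation(profile = "numeric", params = "KineticParameters"))

setValidity("ParameterizedNetwork", function(object) {
    p <- object@profile
    if (!identical(names(p), .COMPONENTS))
        return(sprintf("profile must be named exactly: %s",
                       paste(.COMPONENTS, collapse = ", ")))
    if (any(!is.finite(p)) || any(p < 0))
        return("all relative abundances must be finite and >= 0")
    TRUE
})

#' Simulated single-cell trajectory
#'
#' Time course of one network simulation: the time grid (minutes), the
#' active (bis-phosphorylated) JNK series, optionally the full state matrix,
#' and the stimulus applied (arbitrary stress units, sustained step at t=0).
#'
#' @seealso [simulateCell()], [peakActiveJNK()]
#' @export
setClass("Trajectory",
         representation(time = "numeric", activeJNK = "numeric",
                        state = "matrix", stimulus = "numeric"))

setValidity("Trajectory", function(object) {
    if (length(object@time) != length(object@activeJNK))
        return("time and activeJNK must have equal length")
    if (length(object@time) > 1 && any(diff(object@time) <= 0))
        return("time must be strictly increasing")
    if (any(object@activeJNK < -1e-8))
        return("active JNK must be non-negative")
    TRUE
})

#' Single-cell expression table
#'
#' One row per cell with the relative abundance of each network component
#' (zak, mkk4, mkk7, jnk, pakt), as exported from five-color flow cytometry
#' or produced by [genExpressionTable()].  Abundances are relative to a
#' reference population mean of 1 once normalized.
#'
#' Slots:
#' \describe{
#'   \item{data}{data.frame with columns `cell_id` and the five components.}
#'   \item{provenance}{"measured" or "synthetic".}
#'   \item{normalized}{logical; TRUE once per-component means have been
#'     divided out against the declared reference.}
#' }
#' @export
setClass("ExpressionTable",
         representation(data = "data.frame", provenance = "character",
                        normalized = "logical"))

setValidity("ExpressionTable", function(object) {
    d <- object@data
    need <- c("cell_id", .COMPONENTS)
    if (!all(need %in% names(d)))
        return(sprintf("data must contain columns: %s",
                       paste(need, collapse = ", ")))
    if (anyDuplicated(d$cell_id))
        return(sprintf("duplicated cell_id: %s",
                       d$cell_id[anyDuplicated(d$cell_id)][1]))
    vals <- as.matrix(d[.COMPONENTS])
    if (nrow(d) > 0 && (any(!is.finite(vals)) || any(vals < 0)))
        return("all abundances must be finite and >= 0")
    if (!object@provenance %in% c("measured", "synthetic"))
        return("provenance must be 'measured' or 'synthetic'")
    TRUE
})

#' Ensemble simulation result
#'
#' Per-cell basal and saturated-stimulus peak active-JNK values for one
#' expression table, their normalized variants (divided by the highest
#' simulated value), per-cell failure flags, and provenance metadata
#' (feedback mode, seed where known, parameter hash).
#'
#' @seealso [simulateEnsemble()], [impairedFraction()]
#' @export
setClass("EnsembleResult",
         representation(cellId = "character",
                        basalPeak = "numeric", stimPeak = "numeric",
                        basalNorm = "numeric", stimNorm = "numeric",
                        failed = "logical", feedback = "character",
                        seed = "integer", paramHash = "character"))

setValidity("EnsembleResult", function(object) {
    n <- length(object@cellId)
    lens <- c(length(object@basalPeak), length(object@stimPeak),
              length(object@basalNorm), length(object@stimNorm),
              length(object@failed))
    if (any(lens != n))
        return("all per-cell slots must have equal length")
    ok <- !object@failed
    nrm <- c(object@basalNorm[ok], object@stimNorm[ok])
    if (length(nrm) && any(nrm < -1e-12 | nrm > 1 + 1e-12, na.rm = TRUE))
        return("normalized peaks must lie in [0, 1]")
    TRUE
})

#' Longitudinal single-cell track set
#'
#' Long-format per-cell biosensor time series plus the log of every QC
#' exclusion.  Each track carries the KTR cytoplasmic:nuclear ratio, the
#' reporter mean fluorescence intensity (expression level) and the
#' caspase-reporter intensity on a constant sampling grid.
#'
#' Slots:
#' \describe{
#'   \item{data}{data.frame with columns `cell_id`, `time_min`,
#'     `ktr_ratio`, `reporter_mfi`, `caspase_mfi`.}
#'   \item{filterLog}{data.frame (`cell_id`, `reason`) recording every
#'     excluded track.}
#' }
#' @seealso [filterExpressionBounds()], [filterTrackingCoverage()]
#' @export
setClass("TrackSet",
         representation(data = "data.frame", filterLog = "data.frame"))

setValidity("TrackSet", function(object) {
    d <- object@data
    need <- c("cell_id", "time_min", "ktr_ratio", "reporter_mfi",
              "caspase_mfi")
    if (!all(need %in% names(d)))
        return(sprintf("data must contain columns: %s",
                       paste(need, collapse = ", ")))
    if (!all(c("cell_id", "reason") %in% names(object@filterLog)))
        return("filterLog must contain columns cell_id, reason")
    if (nrow(d)) {
        bad <- vapply(split(d$time_min, d$cell_id),
                      function(t) any(diff(t) <= 0), logical(1))
        if (any(bad))
            return(sprintf("times not strictly increasing for cell %s",
                           names(bad)[bad][1]))
    }
    TRUE
})

#' Peak activities split by apoptotic outcome
#'
#' Peak JNK activity of apoptotic (caspase onset called) versus
#' nonapoptotic cells, with Cohen's d between the groups and the fraction
#' of apoptotic cells whose peak lies strictly above the nonapoptotic mean.
#'
#' @seealso [groupByOutcome()]
#' @export
setClass("OutcomeGroups",
         representation(apoptotic = "numeric", nonapoptotic = "numeric",
                        cohensD = "numeric", fractionAbove = "numeric",
                        defined = "logical"))

setValidity("OutcomeGroups", function(object) {
    if (object@defined &&
        (object@fractionAbove < 0 || object@fractionAbove > 1))
        return("fractionAbove must lie in [0, 1]")
    TRUE
})

#' Kinase translocation reporter parameters
#'
#' Four-state (phospho x compartment) reporter model: phosphorylation rate
#' per unit active kinase, constitutive dephosphorylation, and nuclear
#' import/export rates of the unphosphorylated and phosphorylated forms.
#' The phosphorylated form must be relatively cytoplasm-biased
#' (export/import ratio larger than the unphosphorylated form) so the
#' cytoplasmic:nuclear ratio increases monotonically with kinase activity.
#' `cap` is the activity saturation point applied on inversion
#' (200 concentration units by default) to stop measurement imprecision at
#' saturating ratios from exploding into the activity estimate.
#'
#' @seealso [steadyStateRatio()], [ratioToActivity()]
#' @export
setClass("ReporterParameters",
         representation(kPhos = "numeric", kDephos = "numeric",
                        importU = "numeric", exportU = "numeric",
                        importP = "numeric", exportP = "numeric",
                        cap = "numeric"))

setValidity("ReporterParameters", function(object) {
    r <- c(object@kPhos, object@kDephos, object@importU, object@exportU,
           object@importP, object@exportP, object@cap)
    if (any(!is.finite(r)) || any(r <= 0))
        return("all reporter rates and the cap must be finite and > 0")
    if (object@exportP / object@importP <= object@exportU / object@importU)
        return(paste("phosphorylated export/import balance must exceed the",
                     "unphosphorylated balance (monotone C:N ratio)"))
    TRUE
})

#' Synthetic-data generator configuration
#'
#' All knobs of the synthetic study: ensemble size, per-component
#' coefficient-of-variation targets of the log-normal expression noise,
#' random seed, trace sampling (interval/duration, minutes), measurement
#' noise, the phenomenological apoptotic commitment layer (threshold
#' `theta` on the normalized peak-activity scale, logistic slope `beta`,
#' a multiplicative threshold modifier emulating MCL-1/BCL-2
#' over-expression or BH3 mimetics), priming fold-changes per component,
#' the caspase onset band, and the reporter-drive scale.
#'
#' @seealso [generatorConfig()], [genExpressionTable()], [genCellTracks()]
#' @export
setClass("GeneratorConfig",
         representation(nCells = "integer", cov = "numeric",
                        family = "character", seed = "integer",
                        sampleInterval = "numeric", traceDuration = "numeric",
                        traceNoiseSD = "numeric",
                        peakTime = "numeric",
                        theta = "numeric", beta = "numeric",
                        thresholdModifier = "numeric",
                        primingFold = "numeric",
                        onsetBand = "numeric",
                        activityScale = "numeric",
                        mfiMeanlog = "numeric", mfiSdlog = "numeric",
                        correlation = "matrix"))

setValidity("GeneratorConfig", function(object) {
    msg <- character()
    if (object@nCells <= 0L) msg <- c(msg, "nCells must be > 0")
    if (!identical(names(object@cov), .COMPONENTS) ||
        any(object@cov <= 0))
        msg <- c(msg, "cov must be positive and named for all 5 components")
    if (!object@family %in% "lognormal")
        msg <- c(msg, "only the lognormal family is implemented")
    if (object@theta <= 0) msg <- c(msg, "theta must be > 0")
    if (object@thresholdModifier <= 0)
        msg <- c(msg, "thresholdModifier must be > 0")
    if (!identical(names(object@primingFold), .COMPONENTS) ||
        any(object@primingFold <= 0))
        msg <- c(msg, "primingFold must be positive for all 5 components")
    if (length(object@onsetBand) != 2L || diff(object@onsetBand) < 0)
        msg <- c(msg, "onsetBand must be an increasing length-2 interval")
    if (!identical(dim(object@correlation), c(5L, 5L)))
        msg <- c(msg, "correlation must be a 5x5 matrix")
    if (length(msg)) msg else TRUE
})
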