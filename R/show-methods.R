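#' @describeIn KineticParameters-class compact display.
#' @param object the object to display.
#' @export
setMethod("show", "KineticParameters", function(object) {
    cat("KineticParameters:", length(object@rates), "rate constants,",
        "feedback", if (feedbackEnabled(object)) "enabled" else "disabled",
        "\n")
    cat("  totals:", paste(sprintf("%s=%g", names(object@totals),
                                   object@totals), collapse = " "), "\n")
})

#' @describeIn ParameterizedNetwork-class compact display.
#' @param object the object to display.
#' @export
setMethod("show", "ParameterizedNetwork", function(object) {
    cat("ParameterizedNetwork for one cell\n  profile:",
        paste(sprintf("%s=%.3g", names(object@profile), object@profile),
              collapse = " "), "\n")
})

#' @describeIn Trajectory-class compact display.
#' @param object the object to display.
#' @export
setMethod("show", "Trajectory", function(object) {
    cat(sprintf(
        "Trajectory: %d points over %g min, stimulus %g, peak active JNK %.4g\n",
        length(object@time), max(object@time), object@stimulus,
        max(object@activeJNK)))
})

#' @describeIn ExpressionTable-class compact display.
#' @param object the object to display.
#' @export
setMethod("show", "ExpressionTable", function(object) {
    cat(sprintf("ExpressionTable: %d cells (%s, %s)\n", nrow(object@data),
                object@provenance,
                if (object@normalized) "normalized" else "raw"))
    if (nrow(object@data))
        cat("  component means:",
            paste(sprintf("%s=%.3f", .COMPONENTS,
                          colMeans(object@data[.COMPONENTS])),
                  collapse = " "), "\n")
})

#' @describeIn EnsembleResult-class compact display.
#' @param object the object to display.
#' @export
setMethod("show", "EnsembleResult", function(object) {
    ok <- !object@failed
    cat(sprintf("EnsembleResult: %d cells (%d failed), feedback %s\n",
                length(object@cellId), sum(object@failed), object@feedback))
    if (any(ok))
        cat(sprintf("  mean basal peak %.4g, mean stimulated peak %.4g\n",
                    mean(object@basalPeak[ok]), mean(object@stimPeak[ok])))
})

#' @describeIn TrackSet-class compact display.
#' @param object the object to display.
#' @export
setMethod("show", "TrackSet", function(object) {
    cat(sprintf("TrackSet: %d tracks, %d samples, %d logged exclusions\n",
                length(unique(object@data$cell_id)), nrow(object@data),
                nrow(object@filterLog)))
})

#' @describeIn OutcomeGroups-class compact display.
#' @param object the object to display.
#' @export
setMethod("show", "OutcomeGroups", function(object) {
    cat(sprintf("OutcomeGroups: %d apoptotic vs %d nonapoptotic cells\n",
                length(object@apoptotic), length(object@nonapoptotic)))
    if (object@defined)
        cat(sprintf("  Cohen's d = %.3f, fraction above nonapoptotic mean = %.3f\n",
                    object@cohensD, object@fractionAbove))
    else cat("  statistics undefined (a group is empty or degenerate)\n")
})

#' @describeIn ReporterParameters-class compact display.
#' @param object the object to display.
#' @export
setMethod("show", "ReporterParameters", function(object) {
    cat(sprintf(
        "ReporterParameters: ratio range [%.3g, %.3g], cap %g\n",
        object@exportU / object@importU, object@exportP / object@importP,
        object@cap))
})

#' @describeIn GeneratorConfig-class compact display.
#' @param object the object to display.
#' @export
setMethod("show", "GeneratorConfig", function(object) {
    cat(sprintf(
        "GeneratorConfig: %d cells, seed %d, theta %.3g, beta %.3g\n",
        object@nCells, object@seed, object@theta, object@beta))
})
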