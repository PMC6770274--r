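#' @describeIn SizeProfile-class compact display
#' @param object object to display
#' @export
setMethod("show", "SizeProfile", function(object) {
    cat(sprintf("SizeProfile: %s / %s\n", object@genome, object@compartment))
    cat(sprintf("  %d fragments in [%d, %d] bp\n", object@nTotal,
                object@window[1L], object@window[2L]))
    if (object@nTotal > 0)
        cat(sprintf("  modal %g bp, mean %.2f bp\n",
                    object@modal, object@meanLen))
    else cat("  (empty: modal/mean undefined)\n")
})

#' @describeIn PeriodicityResult-class compact display
#' @param object object to display
#' @export
setMethod("show", "PeriodicityResult", function(object) {
    if (object@ok)
        cat(sprintf(
            "PeriodicityResult: period %.1f bp (strength %.2f) in %g-%g bp\n",
            object@period, object@strength,
            object@region[1L], object@region[2L]))
    else cat("PeriodicityResult: undefined (region too sparse)\n")
})

#' @describeIn ClassificationSummary-class compact display
#' @param object object to display
#' @export
setMethod("show", "ClassificationSummary", function(object) {
    cat(sprintf("ClassificationSummary: %d templates\n", object@total))
    for (k in names(object@counts))
        cat(sprintf("  %-10s %8d  (%.4f%%)\n", k, object@counts[[k]],
                    100 * object@fractions[[k]]))
})

#' @describeIn CtdnaEstimate-class compact display
#' @param object object to display
#' @export
setMethod("show", "CtdnaEstimate", function(object) {
    cat(sprintf("CtdnaEstimate: %.4g%% ctDNA (mean VAF %.4g%%, %d sites)\n",
                100 * object@ctdnaFraction, 100 * object@meanVaf,
                object@nSites))
    cat(sprintf("  %d%% bootstrap CI: [%.4g%%, %.4g%%] (%d replicates)\n",
                round(100 * object@ciLevel), 100 * object@ciLo,
                100 * object@ciHi, object@nBootstrap))
})

#' @describeIn RegionGainTest-class compact display
#' @param object object to display
#' @export
setMethod("show", "RegionGainTest", function(object) {
    cat(sprintf(
        "RegionGainTest (%s): U = %g over %d region vs %d flank bins\n",
        object@method, object@U, object@nRegionBins, object@nFlankBins))
    cat(sprintf("  one-sided p (region > flank) = %.4g\n", object@pValue))
})

#' @describeIn GroupComparison-class compact display
#' @param object object to display
#' @export
setMethod("show", "GroupComparison", function(object) {
    cat(sprintf("GroupComparison: %s (n=%d, mean %.3f) vs %s (n=%d, mean %.3f)\n",
                object@labels[1L], object@nA, object@meanA,
                object@labels[2L], object@nB, object@meanB))
    if (object@ok)
        cat(sprintf("  Welch t = %.3f, df = %.2f, two-sided p = %.4g\n",
                    object@statistic, object@df, object@pValue))
    else cat("  (undefined: degenerate groups)\n")
})

#' @describeIn CorrelationResult-class compact display
#' @param object object to display
#' @export
setMethod("show", "CorrelationResult", function(object) {
    cat(sprintf("CorrelationResult: r(%s, %s) = %.3f (n = %d, p = %.4g)\n",
                object@variables[1L], object@variables[2L],
                object@r, object@n, object@pValue))
})

#' @describeIn LongitudinalSeries-class compact display
#' @param object object to display
#' @export
setMethod("show", "LongitudinalSeries", function(object) {
    cat(sprintf("LongitudinalSeries: patient %s, %d timepoints\n",
                object@patientId, nrow(object@series)))
    cat("  directions:", paste(c("-", "0", "+")[object@directions + 2L],
                               collapse = " "),
        if (object@reversal) " (reversal)" else "", "\n")
})
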