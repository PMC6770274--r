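#' Read a cohort sample table
#'
#' One row per blood sample. Recognized columns: \code{sample_id},
#' \code{patient_id}, \code{group}, \code{timepoint},
#' \code{mean_mt_length}, \code{ctdna_percent}, \code{tumor_size},
#' \code{ctdna_concentration}, \code{disease_state}. Missing values stay
#' \code{NA} and are handled pairwise-complete downstream.
#'
#' @param path TSV path.
#' @return data.frame.
#' @importFrom utils read.delim
#' @export
readCohortTable <- function(path) {
    read.delim(path, stringsAsFactors = FALSE)
}

#' Welch two-sample t test
#'
#' Unequal-variance (Welch) two-sided t test, the safe default when group
#' sizes are unbalanced. When either group is constant so that the test
#' statistic is undefined, the result is returned flagged rather than as
#' an error when \code{flagDegenerate} is \code{TRUE}.
#'
#' @param a,b numeric vectors (each of length >= 2 after NA removal).
#' @param labels character length-2 group labels.
#' @param flagDegenerate return a flagged (\code{ok = FALSE}) result
#'   instead of erroring when both groups are constant.
#' @return a \linkS4class{GroupComparison}.
#' @examples
#' welchTTest(c(1, 2, 3), c(4, 5, 6))
#' @importFrom stats t.test
#' @export
welchTTest <- function(a, b, labels = c("A", "B"), flagDegenerate = TRUE) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least two observations")
    res <- tryCatch(t.test(a, b, var.equal = FALSE),
                    error = function(e) NULL)
    if (is.null(res)) {
        if (!flagDegenerate) stop("degenerate groups: zero variance")
        return(new("GroupComparison", meanA = mean(a), meanB = mean(b),
                   nA = length(a), nB = length(b),
                   statistic = NA_real_, df = NA_real_, pValue = NA_real_,
                   labels = labels, ok = FALSE))
    }
    new("GroupComparison", meanA = mean(a), meanB = mean(b),
        nA = length(a), nB = length(b),
        statistic = unname(res$statistic), df = unname(res$parameter),
        pValue = res$p.value, labels = labels, ok = TRUE)
}

#' @rdname pValue
#' @export
setMethod("pValue", "GroupComparison", function(x) x@pValue)

#' Pearson correlation with t-based p-value
#'
#' Sample Pearson correlation on pairwise-complete observations, with the
#' two-sided p-value from \eqn{t = r \sqrt{(n-2)/(1-r^2)}}.
#'
#' @param x,y numeric vectors of equal length.
#' @param variables character length-2 variable names.
#' @return a \linkS4class{CorrelationResult}.
#' @examples
#' pearsonCorrelation(c(1, 2, 3), c(2, 4, 6))
#' @importFrom stats cor.test sd complete.cases
#' @export
pearsonCorrelation <- function(x, y, variables = c("x", "y")) {
    keep <- complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    n <- length(x)
    if (n < 3L) stop("at least three complete pairs are required")
    if (sd(x) == 0 || sd(y) == 0)
        stop("zero variance in one of the variables")
    res <- cor.test(x, y, method = "pearson")
    new("CorrelationResult", r = unname(res$estimate), n = n,
        pValue = res$p.value, variables = variables)
}

#' @rdname pValue
#' @export
setMethod("pValue", "CorrelationResult", function(x) x@pValue)

#' Dichotomize a cohort by ctDNA percentage
#'
#' Splits samples into high (\code{ctdna_percent} strictly greater than
#' the threshold, default 5 percent) and low groups and compares their
#' mean mt-cfDNA lengths with a Welch t test. Samples with missing ctDNA
#' percentage are excluded. When either group is empty or has fewer than
#' two samples, the comparison is returned as \code{NULL} (flagged
#' undefined in the result).
#'
#' @param samples cohort data.frame (see \code{\link{readCohortTable}}).
#' @param threshold ctDNA percentage cutoff (default 5).
#' @param valueCol column compared between groups (default
#'   \code{"mean_mt_length"}).
#' @return list with \code{high}, \code{low} (data.frames) and
#'   \code{comparison} (a \linkS4class{GroupComparison}, or \code{NULL}
#'   when undefined).
#' @examples
#' co <- simulateCohort(seed = 1)
#' dichotomizeByCtdna(co)$comparison
#' @export
dichotomizeByCtdna <- function(samples, threshold = 5,
                               valueCol = "mean_mt_length") {
    if (!"ctdna_percent" %in% names(samples))
        stop("samples lack a ctdna_percent column")
    known <- samples[!is.na(samples$ctdna_percent), , drop = FALSE]
    high <- known[known$ctdna_percent > threshold, , drop = FALSE]
    low <- known[known$ctdna_percent <= threshold, , drop = FALSE]
    comparison <- NULL
    if (nrow(high) >= 2L && nrow(low) >= 2L)
        comparison <- welchTTest(high[[valueCol]], low[[valueCol]],
                                 labels = c("high", "low"))
    list(high = high, low = low, comparison = comparison)
}

#' Longitudinal mt-cfDNA series for one patient
#'
#' Orders one patient's samples by timepoint and records the sign of the
#' change of mean mt-cfDNA length over each interval, flagging a
#' direction reversal (the pattern seen when disease state changes over
#' follow-up).
#'
#' @param samples data.frame of one patient's samples with columns
#'   \code{timepoint}, \code{mean_mt_length} and optionally
#'   \code{patient_id}, \code{disease_state}.
#' @return a \linkS4class{LongitudinalSeries}.
#' @examples
#' trackPatient(data.frame(timepoint = 1:4,
#'                         mean_mt_length = c(150, 160, 140, 130)))
#' @export
trackPatient <- function(samples) {
    if (nrow(samples) < 2L) stop("at least two timepoints are required")
    if (anyDuplicated(samples$timepoint))
        stop("duplicate timepoint for patient")
    ord <- order(samples$timepoint)
    samples <- samples[ord, , drop = FALSE]
    d <- diff(samples$mean_mt_length)
    directions <- as.integer(sign(d))
    nz <- directions[directions != 0L]
    reversal <- length(nz) >= 2L && any(diff(nz) != 0L)
    keep <- intersect(c("timepoint", "mean_mt_length", "disease_state"),
                      names(samples))
    new("LongitudinalSeries",
        patientId = as.character(
            if ("patient_id" %in% names(samples)) samples$patient_id[1L]
            else NA_character_),
        series = samples[, keep, drop = FALSE],
        directions = directions, reversal = reversal)
}
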