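#' Classify read pairs by species of origin
#'
#' Groups alignment records by template and calls each template
#' \code{graft} when every passing alignment (primary and secondary) lies
#' on graft contigs, \code{host} when every alignment lies on host
#' contigs, \code{ambiguous} when both genomes are hit, and
#' \code{unmapped} when no passing alignment exists. With a combined
#' two-genome reference, cross-genome secondary alignments are the
#' analogue of reads that map to both species' references.
#'
#' @param path SAM or BAM file with a combined two-genome header.
#' @param index contig index data.frame (see \code{\link{contigIndex}}).
#' @param minMapq minimum mapping quality for an alignment to count
#'   toward the call (secondary alignments are always considered;
#'   default 0).
#' @return data.frame with columns \code{readId} and \code{call}.
#' @examples
#' cfg <- demoSimulationConfig(seed = 1, nNuclear = 200)
#' idx <- contigIndex(cfg@graft, cfg@host)
#' sam <- tempfile(fileext = ".sam")
#' emitAlignments(simulateFragments(cfg)$fragments, idx, sam)
#' calls <- classifyTemplates(sam, idx)
#' @export
classifyTemplates <- function(path, index, minMapq = 0) {
    rec <- readAlignmentRecords(path)
    classifyRecords(rec, index, minMapq)
}

# classification core on a flat record data.frame (qname, flag, rname,
# mapq); exposed separately so single-template record groups can be
# classified without a file
classifyRecords <- function(rec, index, minMapq = 0) {
    mapped <- !is.na(rec$rname)
    if (any(!rec$rname[mapped] %in% index$contig))
        stop("alignment on contig absent from the contig index")
    secondary <- bitwAnd(rec$flag, 256L) > 0L
    pass <- mapped & (secondary | rec$mapq >= minMapq)
    genome <- rep(NA_character_, nrow(rec))
    genome[pass] <- index$genome[match(rec$rname[pass], index$contig)]
    byQ <- split(genome, rec$qname)
    call <- vapply(byQ, function(g) {
        g <- unique(g[!is.na(g)])
        if (length(g) == 0L) "unmapped"
        else if (length(g) > 1L) "ambiguous"
        else g
    }, character(1))
    data.frame(readId = names(byQ), call = unname(call),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize species classification calls
#'
#' @param calls data.frame from \code{\link{classifyTemplates}}, or a
#'   character vector of calls.
#' @return a \linkS4class{ClassificationSummary} with exact counts,
#'   fractions of all templates, and fractions of mapped templates only.
#' @examples
#' summarizeClassification(rep(c("graft", "host"), c(76, 24)))
#' @export
summarizeClassification <- function(calls) {
    if (is.data.frame(calls)) calls <- calls$call
    if (length(calls) == 0L) stop("at least one call is required")
    classes <- c("graft", "host", "ambiguous", "unmapped")
    if (any(!calls %in% classes))
        stop("unknown call class: ",
             paste(setdiff(unique(calls), classes), collapse = ", "))
    counts <- vapply(classes, function(k) sum(calls == k), integer(1))
    total <- length(calls)
    mapped <- total - counts[["unmapped"]]
    fracMapped <- if (mapped > 0) counts / mapped else counts * NA_real_
    fracMapped[["unmapped"]] <- NA_real_
    new("ClassificationSummary", counts = counts, total = total,
        fractions = counts / total, fractionsMapped = fracMapped)
}
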