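#' Extract cfDNA fragments from paired-end alignments
#'
#' Reconstructs one fragment per template from a SAM/BAM file: the
#' template is counted once at its leftmost mate (positive template
#' length), and the fragment interval spans the outermost mate
#' coordinates, the standard insert-size convention for cfDNA. Records
#' failing the filters (unpaired, not properly paired, below the mapping
#' quality floor) are skipped and counted. Genome and compartment are
#' assigned from the contig index; templates that also carry secondary
#' alignments on the other genome are marked \code{"ambiguous"}.
#'
#' @param path SAM or BAM file with a combined two-genome header.
#' @param index contig index data.frame (see \code{\link{contigIndex}}).
#' @param minMapq minimum mapping quality (default 20).
#' @param requireProperPair drop templates not flagged properly paired
#'   (default \code{TRUE}).
#' @return \code{GRanges} with mcols \code{readId}, \code{genome}
#'   (\code{graft}, \code{host} or \code{ambiguous}), \code{compartment}
#'   (\code{nuclear} or \code{mito}); skip counters are stored in
#'   \code{S4Vectors::metadata()} under \code{skipped}.
#' @examples
#' cfg <- demoSimulationConfig(seed = 1, nNuclear = 200)
#' idx <- contigIndex(cfg@graft, cfg@host)
#' sam <- tempfile(fileext = ".sam")
#' emitAlignments(simulateFragments(cfg)$fragments, idx, sam)
#' frags <- extractFragments(sam, idx)
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths<- seqlevels
#' @export
extractFragments <- function(path, index, minMapq = 20,
                             requireProperPair = TRUE) {
    rec <- readAlignmentRecords(path)
    mapped <- !is.na(rec$rname)
    if (any(!rec$rname[mapped] %in% index$contig))
        stop("alignment on contig absent from the contig index")

    secondary <- bitwAnd(rec$flag, 256L) > 0L
    paired <- bitwAnd(rec$flag, 1L) > 0L
    proper <- bitwAnd(rec$flag, 2L) > 0L

    prim <- !secondary & mapped
    keep <- prim & paired & (!requireProperPair | proper) &
        rec$mapq >= minMapq
    skippedUnpaired <- length(unique(rec$qname[prim & !paired]))
    skippedImproper <- length(unique(
        rec$qname[prim & paired & requireProperPair & !proper]))
    skippedMapq <- length(unique(
        rec$qname[prim & paired & (!requireProperPair | proper) &
                  rec$mapq < minMapq]))

    # one fragment per template, at the leftmost mate
    left <- keep & !is.na(rec$isize) & rec$isize > 0L
    sub <- rec[left, , drop = FALSE]

    genome <- index$genome[match(sub$rname, index$contig)]
    compartment <- index$compartment[match(sub$rname, index$contig)]

    # templates with secondary hits on the other genome are ambiguous
    secGenome <- index$genome[match(rec$rname[secondary], index$contig)]
    secByQ <- split(secGenome, rec$qname[secondary])
    if (length(secByQ)) {
        hit <- match(sub$qname, names(secByQ))
        amb <- rep(FALSE, nrow(sub))
        has <- which(!is.na(hit))
        if (length(has))
            amb[has] <- mapply(function(g, i) any(secByQ[[i]] != g),
                               genome[has], hit[has])
        genome[amb] <- "ambiguous"
    }

    gr <- GRanges(sub$rname, IRanges(start = sub$pos, width = sub$isize))
    seqlengths(gr) <- index$length[match(seqlevels(gr), index$contig)]
    gr$readId <- sub$qname
    gr$genome <- genome
    gr$compartment <- compartment
    metadata(gr)$skipped <- c(unpaired = skippedUnpaired,
                              improper = skippedImproper,
                              lowMapq = skippedMapq)
    gr
}

newSizeProfile <- function(lengths, genome, compartment,
                           window = c(30L, 1000L)) {
    window <- as.integer(window)
    lengths <- lengths[lengths >= window[1L] & lengths <= window[2L]]
    counts <- tabulate(lengths, nbins = window[2L])
    counts <- counts[window[1L]:window[2L]]
    names(counts) <- window[1L]:window[2L]
    n <- sum(counts)
    if (n > 0L) {
        lens <- window[1L]:window[2L]
        modal <- lens[which.max(counts)]
        meanLen <- sum(as.numeric(lens) * counts) / n
    } else {
        modal <- NA_real_
        meanLen <- NA_real_
    }
    storage.mode(counts) <- "integer"
    new("SizeProfile", counts = counts, nTotal = as.integer(n),
        modal = as.numeric(modal), meanLen = meanLen,
        genome = genome, compartment = compartment, window = window)
}

#' Size profile from a fragment set
#'
#' Builds the integer fragment-length histogram for one
#' (genome, compartment) selection. Ambiguous fragments are excluded
#' whenever a specific genome is requested, matching how per-genome
#' profiles are reported.
#'
#' @param fragments \code{GRanges} with \code{genome} and
#'   \code{compartment} mcols (from \code{\link{extractFragments}} or
#'   \code{\link{simulateFragments}}).
#' @param genome \code{"graft"}, \code{"host"} or \code{NULL} for all
#'   non-ambiguous fragments.
#' @param compartment \code{"nuclear"}, \code{"mito"} or \code{NULL} for
#'   both.
#' @param window integer length-2 retained length window (bp).
#' @return a \linkS4class{SizeProfile}.
#' @examples
#' sim <- simulateFragments(demoSimulationConfig(seed = 1, nNuclear = 2000))
#' sizeHistogram(sim$fragments, genome = "graft", compartment = "nuclear")
#' @importFrom GenomicRanges width
#' @export
sizeHistogram <- function(fragments, genome = NULL, compartment = NULL,
                          window = c(30L, 1000L)) {
    sel <- rep(TRUE, length(fragments))
    gLab <- if (is.null(genome)) "all" else genome
    cLab <- if (is.null(compartment)) "all" else compartment
    if (!is.null(fragments$genome)) {
        if (!is.null(genome)) sel <- sel & fragments$genome == genome
        else sel <- sel & fragments$genome != "ambiguous"
    }
    if (!is.null(compartment) && !is.null(fragments$compartment))
        sel <- sel & fragments$compartment == compartment
    newSizeProfile(width(fragments)[sel], gLab, cLab, window)
}

#' Size profile directly from a vector of fragment lengths
#'
#' @param lengths integer fragment lengths (bp).
#' @param genome,compartment labels stored on the profile.
#' @param window integer length-2 retained window (bp).
#' @return a \linkS4class{SizeProfile}.
#' @examples
#' sizeHistogramFromLengths(c(100, 200))
#' @export
sizeHistogramFromLengths <- function(lengths, genome = "all",
                                     compartment = "all",
                                     window = c(30L, 1000L)) {
    newSizeProfile(as.integer(lengths), genome, compartment, window)
}

#' @rdname modalLength
#' @export
setMethod("modalLength", "SizeProfile", function(x) x@modal)

#' @rdname meanLength
#' @export
setMethod("meanLength", "SizeProfile", function(x, window = NULL) {
    if (is.null(window)) return(x@meanLen)
    lens <- x@window[1L]:x@window[2L]
    sel <- lens >= window[1L] & lens <= window[2L]
    n <- sum(x@counts[sel])
    if (n == 0L) return(NA_real_)
    sum(as.numeric(lens[sel]) * x@counts[sel]) / n
})

#' @rdname profileCounts
#' @export
setMethod("profileCounts", "SizeProfile", function(x)
    stats::setNames(x@counts, x@window[1L]:x@window[2L]))

#' @rdname nFragments
#' @export
setMethod("nFragments", "SizeProfile", function(x) x@nTotal)

#' Detect sub-nucleosomal ladder periodicity
#'
#' Measures the dominant spacing of local histogram peaks in a
#' fragment-length region (default 50--150 bp, where nuclear cfDNA shows
#' an approximately 10.6 bp ladder). Counts are log-compressed
#' (\code{log1p}) so that the mono-nucleosome peak cannot dominate the
#' much smaller ladder teeth, detrended by subtracting a centered moving
#' average (window 21 bp), and the normalized autocorrelation of the
#' detrended signal is evaluated on a 0.1 bp lag grid across the search
#' band, using linear interpolation for fractional lags over a fixed
#' support (so the comparison window does not change with the lag). The
#' reported period is the lag of maximum autocorrelation (smallest lag
#' on ties).
#'
#' @param profile a \linkS4class{SizeProfile}.
#' @param region numeric length-2 fragment-length region analyzed (bp).
#' @param band numeric length-2 lag search band (bp).
#' @param detrendWindow moving-average window (bp, odd).
#' @param minBins minimum populated length bins required in the region.
#' @return a \linkS4class{PeriodicityResult}; \code{ok = FALSE} with
#'   \code{NA} period when the region is too sparse.
#' @examples
#' set.seed(1)
#' m <- fragmentLengthModel("nucleosomal_ladder", modalLength = 144,
#'                          modalSd = 3, ladderWeight = 0.3)
#' p <- sizeHistogramFromLengths(drawFragmentLengths(m, 1e5))
#' detectPeriodicity(p)
#' @importFrom stats approx
#' @export
detectPeriodicity <- function(profile, region = c(50, 150), band = c(8, 14),
                              detrendWindow = 21L, minBins = 30L) {
    lens <- profile@window[1L]:profile@window[2L]
    sel <- lens >= region[1L] & lens <= region[2L]
    y <- as.numeric(profile@counts[sel])
    x <- lens[sel]
    if (sum(y > 0) < minBins)
        return(new("PeriodicityResult", period = NA_real_,
                   strength = NA_real_, band = as.numeric(band),
                   region = as.numeric(region), ok = FALSE))
    ma <- stats::filter(log1p(y), rep(1 / detrendWindow, detrendWindow),
                        sides = 2)
    d <- log1p(y) - as.numeric(ma)
    keep <- !is.na(d)
    d <- d[keep]; xs <- x[keep]
    base <- xs[xs <= max(xs) - band[2L]]
    if (length(base) < 5L)
        return(new("PeriodicityResult", period = NA_real_,
                   strength = NA_real_, band = as.numeric(band),
                   region = as.numeric(region), ok = FALSE))
    d0 <- d[match(base, xs)]
    lags <- seq(band[1L], band[2L], by = 0.1)
    score <- vapply(lags, function(tau) {
        shifted <- approx(xs, d, xout = base + tau)$y
        ok <- !is.na(shifted)
        if (sum(ok) < 5L) return(NA_real_)
        a <- d0[ok]; b <- shifted[ok]
        den <- sqrt(sum(a^2) * sum(b^2))
        if (den == 0) return(NA_real_)
        sum(a * b) / den
    }, numeric(1))
    if (all(is.na(score)))
        return(new("PeriodicityResult", period = NA_real_,
                   strength = NA_real_, band = as.numeric(band),
                   region = as.numeric(region), ok = FALSE))
    best <- which(score == max(score, na.rm = TRUE))[1L]
    new("PeriodicityResult", period = lags[best],
        strength = max(0, min(1, score[best])),
        band = as.numeric(band), region = as.numeric(region), ok = TRUE)
}

#' Normalized mitochondrial cfDNA abundance
#'
#' Mitochondrial fragment count divided by the nuclear fragment count of
#' the same genome, the normalization that makes graft and host
#' mitochondrial yields comparable.
#'
#' @param mtCount mitochondrial fragment count.
#' @param nuclearCount nuclear fragment count of the same genome (> 0).
#' @return numeric ratio.
#' @examples
#' normalizedMtAbundance(10, 1000)
#' @export
normalizedMtAbundance <- function(mtCount, nuclearCount) {
    if (nuclearCount <= 0) stop("nuclearCount must be > 0")
    mtCount / nuclearCount
}
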