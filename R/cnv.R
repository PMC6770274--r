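#' Tile contigs into fixed-width genomic bins
#'
#' Tiles each contig into non-overlapping bins of exactly \code{width} bp
#' (default 5 kb); a trailing partial bin is dropped so that every bin's
#' fragment count is comparable.
#'
#' @param contigLengths named numeric vector of contig lengths (bp), or a
#'   contig index data.frame (see \code{\link{contigIndex}}).
#' @param width bin width in bp (default 5000).
#' @return \code{GRanges} of bins with an integer \code{count} mcol
#'   initialized to zero.
#' @examples
#' tileBins(c(chrA = 12000))
#' @importFrom GenomicRanges GRanges tileGenome width
#' @importFrom GenomeInfoDb seqlengths
#' @export
tileBins <- function(contigLengths, width = 5000) {
    if (is.data.frame(contigLengths))
        contigLengths <- stats::setNames(contigLengths$length,
                                         contigLengths$contig)
    if (width <= 0) stop("width must be > 0")
    if (any(contigLengths <= 0)) stop("contig lengths must be > 0")
    tileable <- contigLengths[contigLengths >= width]
    if (!length(tileable)) {
        bins <- GRanges()
        bins$count <- integer(0)
        return(bins)
    }
    bins <- tileGenome(tileable, tilewidth = width,
                       cut.last.tile.in.chrom = TRUE)
    bins <- bins[width(bins) == width]
    bins$count <- 0L
    bins
}

#' Count fragments per genomic bin
#'
#' Each fragment is assigned to the single bin containing its midpoint
#' (midpoint of the 0-based half-open interval, rounded down), so no
#' fragment is counted twice.
#'
#' @param fragments \code{GRanges} of fragments.
#' @param bins \code{GRanges} from \code{\link{tileBins}}.
#' @return \code{bins} with the \code{count} mcol filled in.
#' @examples
#' bins <- tileBins(c(chrA = 20000))
#' fr <- GenomicRanges::GRanges("chrA", IRanges::IRanges(4991, 5010))
#' countFragmentsInBins(fr, bins)
#' @importFrom GenomicRanges GRanges start end seqnames findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom GenomeInfoDb seqlengths seqlevels
#' @export
countFragmentsInBins <- function(fragments, bins) {
    if (length(fragments)) {
        sl <- seqlengths(fragments)
        known <- seqlevels(bins)
        fcontig <- as.character(seqnames(fragments))
        clen <- sl[fcontig]
        if (any(!is.na(clen) & end(fragments) > clen))
            stop("fragment interval outside contig bounds")
    }
    # midpoint of 0-based [start-1, end): floor((start-1 + end) / 2),
    # expressed 1-based as that value + 1
    mid1 <- floor((start(fragments) - 1 + end(fragments)) / 2) + 1
    mp <- GRanges(seqnames(fragments), IRanges(mid1, width = 1L))
    hits <- suppressWarnings(findOverlaps(mp, bins))
    counts <- tabulate(subjectHits(hits), nbins = length(bins))
    bins$count <- as.integer(counts)
    bins
}

# exact one-sided Mann-Whitney tail P(U >= u) for sample sizes m, n with
# no ties, via the exact null distribution of the rank-sum statistic
exactUTailP <- function(u, m, n) {
    stats::pwilcox(u - 1, m, n, lower.tail = FALSE)
}

# one-sided normal approximation to P(U >= u) with continuity correction
# and an Edgeworth kurtosis term (excess kurtosis of U under no ties:
# -(6/5)(m^2 + n^2 + mn + m + n) / (mn(N+1))); `values` supplies the
# pooled observations for the tie correction of the variance
normalUTailP <- function(u, m, n, values = NULL) {
    N <- m + n
    mu <- m * n / 2
    sig2 <- m * n * (N + 1) / 12
    if (!is.null(values)) {
        t <- table(values)
        sig2 <- m * n / 12 * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
    }
    if (sig2 <= 0) return(1)
    g2 <- -(6 / 5) * (m^2 + n^2 + m * n + m + n) / (m * n * (N + 1))
    z <- (u - 0.5 - mu) / sqrt(sig2)
    p <- pnorm(z, lower.tail = FALSE)
    # the Edgeworth kurtosis term is only reliable in the expansion's
    # validity range; beyond |z| = 4 both tails are negligible anyway
    if (abs(z) <= 4)
        p <- p + stats::dnorm(z) * g2 / 24 * (z^3 - 3 * z)
    min(1, max(p, .Machine$double.xmin))
}

#' One-sided Mann--Whitney copy-gain test
#'
#' Tests whether per-bin fragment counts inside a candidate region are
#' higher than in flanking bins. The U statistic counts region-flank bin
#' pairs where the region bin exceeds the flank bin (ties count 1/2).
#' For small problems (at most 1e5 group assignments) the p-value is an
#' exact permutation enumeration, which handles ties; with no ties and at
#' most \code{exactMax} region-flank pairs it is the exact tail of the
#' null distribution of U; otherwise a normal approximation with tie,
#' continuity and Edgeworth kurtosis corrections is used. Constant
#' identical counts give p = 1.
#'
#' @param bins \code{GRanges} with \code{count} mcol (from
#'   \code{\link{countFragmentsInBins}}).
#' @param region \code{GRanges} of the candidate gain region, or a string
#'   \code{"contig:start-end"} (1-based inclusive).
#' @param flankBinsPerSide flanking bins taken immediately adjacent on
#'   each side; defaults to the number of region bins.
#' @param exactMax largest \code{nRegion * nFlank} for which the exact
#'   tail is computed (default 400).
#' @return a \linkS4class{RegionGainTest}.
#' @examples
#' bins <- tileBins(c(chrA = 45000))
#' bins$count <- c(5L, 6L, 4L, 10L, 12L, 11L, 5L, 6L, 5L)
#' mannWhitneyGain(bins, "chrA:15001-30000")
#' @importFrom GenomicRanges GRanges start end seqnames
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom stats pnorm
#' @export
mannWhitneyGain <- function(bins, region, flankBinsPerSide = NULL,
                            exactMax = 400) {
    if (is.character(region)) {
        m <- regmatches(region,
                        regexec("^(.+):([0-9]+)-([0-9]+)$", region))[[1L]]
        if (length(m) != 4L) stop("region must be 'contig:start-end'")
        region <- GRanges(m[2L],
                          IRanges(as.numeric(m[3L]), as.numeric(m[4L])))
    }
    inRegion <- suppressWarnings(
        subsetByOverlaps(bins, region, type = "within"))
    nR <- length(inRegion)
    if (nR == 0L) stop("region contains no complete bins")
    k <- if (is.null(flankBinsPerSide)) nR else as.integer(flankBinsPerSide)
    same <- bins[as.character(seqnames(bins)) ==
                 as.character(seqnames(inRegion))[1L]]
    pos <- which(start(same) >= min(start(inRegion)) &
                 end(same) <= max(end(inRegion)))
    left <- same[seq_len(min(k, min(pos) - 1L)) + (min(pos) - 1L) -
                 min(k, min(pos) - 1L)]
    rightIdx <- seq(max(pos) + 1L, length.out = min(k, length(same) - max(pos)))
    right <- same[rightIdx[rightIdx <= length(same)]]
    x <- inRegion$count
    y <- c(left$count, right$count)
    nF <- length(y)
    if (nF < 2L) stop("at least two flanking bins are required")

    U <- sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y),
                    numeric(1)))
    ties <- anyDuplicated(c(x, y)) > 0L
    N <- nR + nF
    if (choose(N, nR) <= 1e5) {
        # full permutation enumeration over group assignments; handles
        # ties exactly (tied cross-group pairs contribute 1/2 to U)
        vals <- c(x, y)
        idx <- combn(N, nR)
        Us <- apply(idx, 2L, function(ii) {
            xs <- vals[ii]; ys <- vals[-ii]
            sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
        })
        p <- mean(Us >= U - 1e-9)
        method <- "exact"
    } else if (!ties && nR * nF <= exactMax) {
        p <- exactUTailP(U, nR, nF)
        method <- "exact"
    } else {
        p <- normalUTailP(U, nR, nF, values = c(x, y))
        method <- "normal"
    }
    new("RegionGainTest", region = region,
        nRegionBins = nR, nFlankBins = nF, U = U, pValue = p,
        method = method, direction = "gain")
}

#' @rdname pValue
#' @export
setMethod("pValue", "RegionGainTest", function(x) x@pValue)
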