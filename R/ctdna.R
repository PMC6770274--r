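#' Read a variant pileup table
#'
#' Reads the tab-separated pileup format emitted by
#' \code{\link{emitVariantPileups}}: one row per candidate SNV with
#' columns \code{contig}, \code{pos}, \code{ref}, \code{alt},
#' \code{ref_count}, \code{alt_count} and logical per-tissue presence
#' flags (e.g. \code{primary}, \code{met1}, \code{met2}, \code{cfdna},
#' \code{normal}).
#'
#' @param path TSV path.
#' @return data.frame.
#' @importFrom utils read.delim
#' @export
readPileupTable <- function(path) {
    pu <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("contig", "pos", "ref", "alt", "ref_count", "alt_count")
    miss <- setdiff(need, names(pu))
    if (length(miss))
        stop("pileup table lacks columns: ", paste(miss, collapse = ", "))
    pu
}

#' Read true variant sites from a VCF
#'
#' @param path VCF path.
#' @return data.frame with columns \code{contig}, \code{pos}, \code{ref},
#'   \code{alt}.
#' @importFrom VariantAnnotation readVcf ref alt
#' @importFrom GenomicRanges seqnames start
#' @importFrom SummarizedExperiment rowRanges
#' @export
readSitesVcf <- function(path) {
    vcf <- suppressWarnings(readVcf(path))
    rr <- rowRanges(vcf)
    data.frame(contig = as.character(seqnames(rr)),
               pos = start(rr),
               ref = as.character(ref(vcf)),
               alt = vapply(as(alt(vcf), "CharacterList"),
                            function(a) a[1L], character(1)),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Select tumor-specific heterozygous SNV sites
#'
#' Keeps sites that are present in at least one tumor lesion, absent in
#' the matched normal (buffy-coat reference), and supported in cfDNA by
#' at least \code{minAlt} alternate reads at depth at least
#' \code{minDepth}.
#'
#' @param sites pileup data.frame (see \code{\link{readPileupTable}}).
#' @param minDepth minimum cfDNA depth (ref + alt).
#' @param minAlt minimum cfDNA alternate reads.
#' @param tumorCols names of the tumor-lesion presence flag columns.
#' @param normalCol name of the matched-normal presence flag column.
#' @return the selected subset of \code{sites}.
#' @examples
#' pu <- emitVariantPileups(demoSimulationConfig(seed = 1, nNuclear = 0))
#' nrow(selectTumorSpecificSites(pu))
#' @export
selectTumorSpecificSites <- function(sites, minDepth = 10, minAlt = 2,
                                     tumorCols = c("primary", "met1", "met2"),
                                     normalCol = "normal") {
    tumorCols <- intersect(tumorCols, names(sites))
    if (!length(tumorCols)) stop("no tumor presence columns found")
    inTumor <- Reduce(`|`, lapply(tumorCols, function(cl) sites[[cl]]))
    inNormal <- if (normalCol %in% names(sites)) sites[[normalCol]]
                else rep(FALSE, nrow(sites))
    depth <- sites$ref_count + sites$alt_count
    keep <- inTumor & !inNormal & depth >= minDepth &
        sites$alt_count >= minAlt
    sites[keep, , drop = FALSE]
}

#' Variant allele frequency of one site
#'
#' @param refCount,altCount cfDNA reference and alternate read counts.
#' @return \code{altCount / (refCount + altCount)}; errors on zero depth.
#' @examples
#' computeSiteVaf(95, 5)
#' @export
computeSiteVaf <- function(refCount, altCount) {
    depth <- refCount + altCount
    if (any(depth <= 0)) stop("site has zero depth")
    altCount / depth
}

#' Estimate the ctDNA fraction from tumor-specific heterozygous sites
#'
#' The circulating-tumor-DNA fraction is estimated as twice the
#' unweighted mean variant allele frequency over the selected sites
#' (every site is heterozygous in the tumor, so a clonal site's expected
#' VAF is half the ctDNA fraction), capped at 1. A site-level bootstrap
#' percentile interval quantifies the uncertainty of the point estimate;
#' the interval is an addition to the classical point estimator.
#'
#' @param sites pileup data.frame with \code{ref_count} and
#'   \code{alt_count} columns (typically the output of
#'   \code{\link{selectTumorSpecificSites}}).
#' @param nBootstrap bootstrap replicates (default 2000).
#' @param level CI level (default 0.95).
#' @param seed optional RNG seed for the bootstrap.
#' @return a \linkS4class{CtdnaEstimate}.
#' @examples
#' sites <- data.frame(ref_count = rep(9520, 28), alt_count = rep(480, 28))
#' estimateCtdnaFraction(sites, seed = 1)
#' @importFrom stats quantile
#' @export
estimateCtdnaFraction <- function(sites, nBootstrap = 2000, level = 0.95,
                                  seed = NULL) {
    if (is.null(sites) || nrow(sites) == 0L)
        stop("at least one site with positive depth is required")
    vaf <- computeSiteVaf(sites$ref_count, sites$alt_count)
    fbar <- mean(vaf)
    frac <- min(1, 2 * fbar)
    boot <- function() {
        reps <- vapply(seq_len(nBootstrap), function(i)
            min(1, 2 * mean(vaf[sample.int(length(vaf), replace = TRUE)])),
            numeric(1))
        unname(quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        type = 7))
    }
    ci <- if (is.null(seed)) boot() else withSeed(seed, boot())
    new("CtdnaEstimate", nSites = length(vaf), meanVaf = fbar,
        ctdnaFraction = frac, ciLevel = level,
        ciLo = ci[1L], ciHi = ci[2L], nBootstrap = as.integer(nBootstrap))
}

#' @rdname ctdnaFraction
#' @export
setMethod("ctdnaFraction", "CtdnaEstimate", function(x) x@ctdnaFraction)

#' @rdname meanVaf
#' @export
setMethod("meanVaf", "CtdnaEstimate", function(x) x@meanVaf)

#' @rdname ctdnaCI
#' @export
setMethod("ctdnaCI", "CtdnaEstimate", function(x)
    c(level = x@ciLevel, lo = x@ciLo, hi = x@ciHi))

#' Pairwise mutation overlap between tissues
#'
#' Exact pairwise shared-site counts and Jaccard indices between
#' per-tissue mutation sets keyed on (contig, pos, ref, alt).
#'
#' @param siteSets named list; each element a data.frame with columns
#'   \code{contig}, \code{pos}, \code{ref}, \code{alt} (or a character
#'   vector of precomputed keys).
#' @return data.frame with columns \code{tissueA}, \code{tissueB},
#'   \code{nA}, \code{nB}, \code{shared}, \code{jaccard}, one row per
#'   unordered tissue pair.
#' @examples
#' a <- data.frame(contig = "c", pos = 1:3, ref = "A", alt = "T")
#' b <- data.frame(contig = "c", pos = 2:4, ref = "A", alt = "T")
#' mutationOverlap(list(met1 = a, met2 = b))
#' @importFrom utils combn
#' @export
mutationOverlap <- function(siteSets) {
    if (length(siteSets) < 2L) stop("at least two tissues are required")
    keys <- lapply(siteSets, function(s) {
        if (is.character(s)) return(unique(s))
        unique(paste(s$contig, s$pos, s$ref, s$alt, sep = ":"))
    })
    prs <- combn(names(keys), 2L)
    rows <- apply(prs, 2L, function(p) {
        a <- keys[[p[1L]]]; b <- keys[[p[2L]]]
        shared <- length(intersect(a, b))
        uni <- length(union(a, b))
        data.frame(tissueA = p[1L], tissueB = p[2L],
                   nA = length(a), nB = length(b), shared = shared,
                   jaccard = if (uni > 0) shared / uni else NA_real_,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
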