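#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Genome specification for one member of a two-genome reference
#'
#' Describes the contigs of one genome (graft tumor or host normal) in a
#' combined xenograft reference: a set of nuclear contigs plus a single
#' mitochondrial contig.
#'
#' @slot label single string, \code{"graft"} or \code{"host"}.
#' @slot nuclearContigs named numeric vector of nuclear contig lengths (bp).
#' @slot mitoContig named numeric vector of length 1: the mitochondrial
#'   contig and its length (bp).
#' @export
setClass("GenomeSpec",
    representation(label = "character",
                   nuclearContigs = "numeric",
                   mitoContig = "numeric"))

setValidity("GenomeSpec", function(object) {
    msg <- character()
    if (length(object@label) != 1L || !object@label %in% c("graft", "host"))
        msg <- c(msg, "label must be 'graft' or 'host'")
    nm <- c(names(object@nuclearContigs), names(object@mitoContig))
    if (is.null(names(object@nuclearContigs)) || is.null(names(object@mitoContig)) ||
        anyDuplicated(nm))
        msg <- c(msg, "contig names must be present and unique")
    if (length(object@mitoContig) != 1L)
        msg <- c(msg, "exactly one mitochondrial contig is required")
    if (any(c(object@nuclearContigs, object@mitoContig) <= 0))
        msg <- c(msg, "all contig lengths must be > 0")
    if (length(object@mitoContig) == 1L && object@mitoContig < 1000)
        msg <- c(msg, "mitochondrial contig length must be >= 1000")
    if (length(msg)) msg else TRUE
})

#' Fragment length model
#'
#' Parametric model for cfDNA fragment lengths. Two kinds are supported:
#' \describe{
#'   \item{\code{"nucleosomal_ladder"}}{a Gaussian mono-nucleosome peak at
#'     \code{modalLength} mixed, with probability \code{ladderWeight}, with a
#'     comb of equally weighted Gaussians at \code{modalLength - k *
#'     ladderPeriod} (k >= 1), truncated below at \code{ladderMin}. This
#'     reproduces the sub-nucleosomal ~10.6 bp ladder of nuclear cfDNA.}
#'   \item{\code{"gamma"}}{a gamma distribution with mean \code{meanLength}
#'     and shape \code{shape}, used for mitochondrial cfDNA whose size
#'     distribution is broad and non-nucleosomal.}
#' }
#' Drawn lengths are always restricted to the 30--1000 bp window that
#' paired-end cfDNA libraries capture reliably.
#'
#' @slot kind \code{"nucleosomal_ladder"} or \code{"gamma"}.
#' @slot modalLength,modalSd mono-nucleosome peak position and width (bp).
#' @slot ladderPeriod ladder spacing (bp), default 10.6.
#' @slot ladderMin smallest ladder tooth position retained (bp).
#' @slot ladderWeight mixture weight of the ladder comb, in [0, 1].
#' @slot meanLength,shape gamma mean (bp) and shape.
#' @export
setClass("FragmentLengthModel",
    representation(kind = "character",
                   modalLength = "numeric", modalSd = "numeric",
                   ladderPeriod = "numeric", ladderMin = "numeric",
                   ladderWeight = "numeric",
                   meanLength = "numeric", shape = "numeric"))

setValidity("FragmentLengthModel", function(object) {
    msg <- character()
    if (!object@kind %in% c("nucleosomal_ladder", "gamma"))
        msg <- c(msg, "kind must be 'nucleosomal_ladder' or 'gamma'")
    if (object@kind == "nucleosomal_ladder") {
        if (!is.finite(object@modalLength) || object@modalLength <= 0)
            msg <- c(msg, "modalLength must be > 0")
        if (!is.finite(object@modalSd) || object@modalSd <= 0)
            msg <- c(msg, "modalSd must be > 0")
        if (!is.finite(object@ladderPeriod) || object@ladderPeriod <= 0)
            msg <- c(msg, "ladderPeriod must be > 0")
        if (!is.finite(object@ladderWeight) ||
            object@ladderWeight < 0 || object@ladderWeight > 1)
            msg <- c(msg, "ladderWeight must lie in [0, 1]")
    } else {
        if (!is.finite(object@meanLength) || object@meanLength <= 0)
            msg <- c(msg, "meanLength must be > 0")
        if (!is.finite(object@shape) || object@shape <= 0)
            msg <- c(msg, "shape must be > 0")
    }
    if (length(msg)) msg else TRUE
})

#' Simulation configuration for the synthetic cfDNA generator
#'
#' Bundles everything the simulator needs: the two genomes, the per
#' (genome, compartment) fragment-length models, fragment counts, the
#' tumor fraction, the copy-gain region, the somatic SNV sites and the
#' cross-species ambiguity rate. The same configuration and seed always
#' reproduce byte-identical outputs.
#'
#' @slot seed integer RNG seed.
#' @slot nNuclear total nuclear fragments (graft + host).
#' @slot nMitoGraft,nMitoHost mitochondrial fragment counts per genome.
#' @slot tumorFraction fraction of nuclear fragments drawn from the graft
#'   genome (the simulated ctDNA fraction), in [0, 1].
#' @slot models named list of \linkS4class{FragmentLengthModel}s with
#'   elements \code{graft_nuclear}, \code{host_nuclear}, \code{graft_mito},
#'   \code{host_mito}.
#' @slot ambiguousFraction fraction of fragments flagged as mapping to both
#'   genomes.
#' @slot snvSites data.frame of heterozygous tumor-specific SNVs with
#'   columns \code{contig}, \code{pos}, \code{ref}, \code{alt}, \code{depth}.
#' @slot errorRate per-base sequencing error rate used in pileup emission.
#' @slot cnvRegion list with \code{contig}, \code{start}, \code{end}
#'   (0-based half-open) and \code{fold} (placement intensity multiplier,
#'   >= 1) describing a contiguous copy-gain region on the graft genome.
#' @slot graft,host \linkS4class{GenomeSpec}s.
#' @export
setClass("SimulationConfig",
    representation(seed = "numeric",
                   nNuclear = "numeric",
                   nMitoGraft = "numeric", nMitoHost = "numeric",
                   tumorFraction = "numeric",
                   models = "list",
                   ambiguousFraction = "numeric",
                   snvSites = "data.frame",
                   errorRate = "numeric",
                   cnvRegion = "list",
                   graft = "GenomeSpec", host = "GenomeSpec"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    cnt <- c(object@nNuclear, object@nMitoGraft, object@nMitoHost)
    if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != floor(cnt)))
        msg <- c(msg, "fragment counts must be non-negative integers")
    for (fr in c(tumorFraction = object@tumorFraction,
                 ambiguousFraction = object@ambiguousFraction,
                 errorRate = object@errorRate)) {
        if (!is.finite(fr) || fr < 0 || fr > 1) {
            msg <- c(msg, "tumorFraction, ambiguousFraction and errorRate must lie in [0, 1]")
            break
        }
    }
    need <- c("graft_nuclear", "host_nuclear", "graft_mito", "host_mito")
    if (!all(need %in% names(object@models)))
        msg <- c(msg, paste("models must contain:", paste(need, collapse = ", ")))
    if (length(object@cnvRegion) &&
        (is.null(object@cnvRegion$fold) || object@cnvRegion$fold < 1))
        msg <- c(msg, "cnvRegion fold must be >= 1")
    req <- c("contig", "pos", "ref", "alt", "depth")
    if (nrow(object@snvSites) && !all(req %in% names(object@snvSites)))
        msg <- c(msg, paste("snvSites must have columns:", paste(req, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Fragment size profile
#'
#' Integer histogram of fragment lengths over the 30--1000 bp window,
#' with the modal and mean length precomputed. The mode ties to the
#' smallest length.
#'
#' @slot counts named integer vector of per-length fragment counts; names
#'   are lengths in bp.
#' @slot nTotal total fragments in the profile.
#' @slot modal modal length (bp); \code{NA} when the profile is empty.
#' @slot meanLen mean length (bp); \code{NA} when the profile is empty.
#' @slot genome,compartment labels of the selection the profile describes.
#' @slot window integer vector of length 2, the length window (bp).
#' @export
setClass("SizeProfile",
    representation(counts = "integer", nTotal = "integer",
                   modal = "numeric", meanLen = "numeric",
                   genome = "character", compartment = "character",
                   window = "integer"))

setValidity("SizeProfile", function(object) {
    msg <- character()
    if (sum(object@counts) != object@nTotal)
        msg <- c(msg, "sum(counts) must equal nTotal")
    if (is.null(names(object@counts)))
        msg <- c(msg, "counts must be named by fragment length")
    if (object@nTotal > 0) {
        mx <- max(object@counts)
        at <- as.integer(names(object@counts))[which(object@counts == mx)]
        if (!isTRUE(object@modal == min(at)))
            msg <- c(msg, "modal must be the smallest length attaining the maximum count")
    }
    if (length(msg)) msg else TRUE
})

#' Ladder periodicity detection result
#'
#' @slot period detected period (bp, possibly fractional); \code{NA} when
#'   the region was too sparse.
#' @slot strength normalized autocorrelation at the detected lag, clipped
#'   to [0, 1].
#' @slot band numeric length-2 lag search band (bp).
#' @slot region numeric length-2 fragment-length region analyzed (bp).
#' @slot ok logical; \code{FALSE} when the result is undefined.
#' @export
setClass("PeriodicityResult",
    representation(period = "numeric", strength = "numeric",
                   band = "numeric", region = "numeric", ok = "logical"))

#' Read-pair species classification summary
#'
#' @slot counts named integer vector over the classes
#'   \code{graft}, \code{host}, \code{ambiguous}, \code{unmapped}.
#' @slot total total templates classified.
#' @slot fractions class fractions of all templates.
#' @slot fractionsMapped class fractions of mapped templates only
#'   (unmapped excluded from the denominator).
#' @export
setClass("ClassificationSummary",
    representation(counts = "integer", total = "integer",
                   fractions = "numeric", fractionsMapped = "numeric"))

setValidity("ClassificationSummary", function(object) {
    msg <- character()
    if (sum(object@counts) != object@total)
        msg <- c(msg, "counts must sum to total")
    if (object@total > 0 && abs(sum(object@fractions) - 1) > 1e-9)
        msg <- c(msg, "fractions must sum to 1")
    if (length(msg)) msg else TRUE
})

#' ctDNA fraction estimate
#'
#' Point estimate of the circulating-tumor-DNA fraction as twice the
#' unweighted mean variant allele frequency over tumor-specific
#' heterozygous sites, capped at 1, with a site-level bootstrap percentile
#' confidence interval.
#'
#' @slot nSites number of sites used.
#' @slot meanVaf unweighted mean VAF over sites.
#' @slot ctdnaFraction \code{min(1, 2 * meanVaf)}.
#' @slot ciLevel,ciLo,ciHi bootstrap percentile CI for the fraction.
#' @slot nBootstrap bootstrap replicates used.
#' @export
setClass("CtdnaEstimate",
    representation(nSites = "integer", meanVaf = "numeric",
                   ctdnaFraction = "numeric",
                   ciLevel = "numeric", ciLo = "numeric", ciHi = "numeric",
                   nBootstrap = "integer"))

setValidity("CtdnaEstimate", function(object) {
    msg <- character()
    if (!isTRUE(all.equal(object@ctdnaFraction, min(1, 2 * object@meanVaf))))
        msg <- c(msg, "ctdnaFraction must equal min(1, 2 * meanVaf)")
    if (length(msg)) msg else TRUE
})

#' Copy-gain rank-sum test result
#'
#' One-sided Mann--Whitney test of region bins having higher fragment
#' counts than flanking bins.
#'
#' @slot region \code{GRanges} of the tested region.
#' @slot nRegionBins,nFlankBins bin counts on each side of the comparison.
#' @slot U Mann--Whitney U statistic (region vs flank).
#' @slot pValue one-sided p-value (region > flank).
#' @slot method \code{"exact"} or \code{"normal"}.
#' @slot direction tested direction, always \code{"gain"}.
#' @export
setClass("RegionGainTest",
    representation(region = "GRanges",
                   nRegionBins = "integer", nFlankBins = "integer",
                   U = "numeric", pValue = "numeric",
                   method = "character", direction = "character"))

setValidity("RegionGainTest", function(object) {
    msg <- character()
    if (object@U < 0 ||
        object@U > as.numeric(object@nRegionBins) * object@nFlankBins)
        msg <- c(msg, "U must lie in [0, nRegionBins * nFlankBins]")
    if (!is.na(object@pValue) && (object@pValue <= 0 || object@pValue > 1))
        msg <- c(msg, "pValue must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Two-group Welch comparison
#'
#' @slot meanA,meanB group means.
#' @slot nA,nB group sizes.
#' @slot statistic Welch t statistic.
#' @slot df Welch--Satterthwaite degrees of freedom.
#' @slot pValue two-sided p-value.
#' @slot labels character length-2 group labels.
#' @slot ok logical; \code{FALSE} when the comparison is undefined
#'   (a group empty or both groups constant).
#' @export
setClass("GroupComparison",
    representation(meanA = "numeric", meanB = "numeric",
                   nA = "integer", nB = "integer",
                   statistic = "numeric", df = "numeric", pValue = "numeric",
                   labels = "character", ok = "logical"))

#' Pearson correlation result
#'
#' @slot r sample Pearson correlation.
#' @slot n complete pairs used.
#' @slot pValue two-sided p-value from the t transform of r.
#' @slot variables character length-2 variable names.
#' @export
setClass("CorrelationResult",
    representation(r = "numeric", n = "integer", pValue = "numeric",
                   variables = "character"))

setValidity("CorrelationResult", function(object) {
    if (is.finite(object@r) && abs(object@r) > 1 + 1e-12)
        "r must lie in [-1, 1]" else TRUE
})

#' Longitudinal mt-cfDNA series for one patient
#'
#' @slot patientId patient identifier.
#' @slot series data.frame with columns \code{timepoint},
#'   \code{mean_mt_length} and (optionally) \code{disease_state}, ordered
#'   by strictly increasing timepoint.
#' @slot directions integer vector of per-interval signs of change
#'   (+1, -1 or 0).
#' @slot reversal logical; \code{TRUE} when the direction of change
#'   reverses at some interior timepoint.
#' @export
setClass("LongitudinalSeries",
    representation(patientId = "character", series = "data.frame",
                   directions = "integer", reversal = "logical"))

setValidity("LongitudinalSeries", function(object) {
    tp <- object@series$timepoint
    if (length(tp) >= 2 && any(diff(tp) <= 0))
        "timepoints must be strictly increasing" else TRUE
})
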