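#' Construct a simulation configuration
#'
#' @param graft,host \linkS4class{GenomeSpec}s.
#' @param models named list of \linkS4class{FragmentLengthModel}s
#'   (\code{graft_nuclear}, \code{host_nuclear}, \code{graft_mito},
#'   \code{host_mito}).
#' @param seed integer RNG seed.
#' @param nNuclear total nuclear fragments.
#' @param nMitoGraft,nMitoHost mitochondrial fragment counts.
#' @param tumorFraction fraction of nuclear fragments from the graft
#'   genome (the simulated ctDNA fraction).
#' @param ambiguousFraction fraction of fragments flagged as
#'   cross-species ambiguous.
#' @param snvSites data.frame (\code{contig}, \code{pos}, \code{ref},
#'   \code{alt}, \code{depth}) of heterozygous tumor-specific SNVs.
#' @param errorRate per-base error rate in pileup emission.
#' @param cnvRegion list (\code{contig}, \code{start}, \code{end},
#'   \code{fold}) for the copy-gain region; empty list for none.
#' @return a \linkS4class{SimulationConfig}.
#' @seealso \code{\link{demoSimulationConfig}} for paper-scale defaults.
#' @export
simulationConfig <- function(graft, host, models, seed = 1L,
                             nNuclear = 1e5, nMitoGraft = 3000,
                             nMitoHost = 1500, tumorFraction = 0.096,
                             ambiguousFraction = 1.5e-4,
                             snvSites = data.frame(), errorRate = 0,
                             cnvRegion = list()) {
    new("SimulationConfig", seed = as.numeric(seed),
        nNuclear = as.numeric(nNuclear),
        nMitoGraft = as.numeric(nMitoGraft),
        nMitoHost = as.numeric(nMitoHost),
        tumorFraction = as.numeric(tumorFraction),
        models = models,
        ambiguousFraction = as.numeric(ambiguousFraction),
        snvSites = snvSites, errorRate = as.numeric(errorRate),
        cnvRegion = cnvRegion, graft = graft, host = host)
}

#' Demonstration configuration mirroring the xenograft study design
#'
#' Defaults encode the conditions the analyses are built around: nuclear
#' modal lengths 144 bp (graft tumor) and 169 bp (host), a 10.6 bp
#' sub-nucleosomal ladder (stronger in the tumor), mitochondrial gamma
#' means 109 bp (graft) vs 143 bp (host), tumor fraction 0.096, 28
#' heterozygous tumor-specific SNVs at depth 10 000, a fold-2 copy-gain
#' region spanning twenty 5 kb bins, and a 1.5e-4 cross-species ambiguity
#' rate. Genomes are toy 2 Mb single-nuclear-contig stand-ins plus
#' mitochondrial contigs of 16 569 bp (graft, human mtDNA length) and
#' 16 299 bp (host, mouse mtDNA length).
#'
#' @param seed integer RNG seed.
#' @param nNuclear total nuclear fragments (default 1e5).
#' @param tumorFraction graft share of nuclear fragments.
#' @param snvDepth per-site pileup depth.
#' @param errorRate per-base error rate for pileups.
#' @return a \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- demoSimulationConfig(seed = 1, nNuclear = 1000)
#' @export
demoSimulationConfig <- function(seed = 1L, nNuclear = 1e5,
                                 tumorFraction = 0.096,
                                 snvDepth = 10000, errorRate = 0) {
    graft <- genomeSpec("graft", c(graft_chr1 = 2e6),
                        c(graft_chrM = 16569))
    host <- genomeSpec("host", c(host_chr1 = 2e6),
                       c(host_chrM = 16299))
    models <- list(
        graft_nuclear = fragmentLengthModel("nucleosomal_ladder",
            modalLength = 144, modalSd = 3, ladderPeriod = 10.6,
            ladderMin = 50, ladderWeight = 0.3),
        host_nuclear = fragmentLengthModel("nucleosomal_ladder",
            modalLength = 169, modalSd = 3, ladderPeriod = 10.6,
            ladderMin = 50, ladderWeight = 0.1),
        graft_mito = fragmentLengthModel("gamma", meanLength = 109, shape = 8),
        host_mito = fragmentLengthModel("gamma", meanLength = 143, shape = 8))
    bases <- c("A", "C", "G", "T")
    k <- seq_len(28)
    snv <- data.frame(contig = "graft_chr1", pos = 50000L * k,
                      ref = bases[(k - 1L) %% 4L + 1L],
                      alt = bases[k %% 4L + 1L],
                      depth = as.integer(snvDepth),
                      stringsAsFactors = FALSE)
    simulationConfig(graft, host, models, seed = seed,
                     nNuclear = nNuclear, nMitoGraft = 3000,
                     nMitoHost = 1500, tumorFraction = tumorFraction,
                     ambiguousFraction = 1.5e-4, snvSites = snv,
                     errorRate = errorRate,
                     cnvRegion = list(contig = "graft_chr1",
                                      start = 1e6, end = 1.1e6, fold = 2))
}

# sample fragment start coordinates (0-based) uniformly along a contig,
# with placement intensity multiplied by `fold` inside [rs, re)
sampleStarts <- function(n, contigLen, fragLen, rs = NULL, re = NULL,
                         fold = 1) {
    maxStart <- contigLen - fragLen
    if (any(maxStart < 0)) stop("fragment longer than contig")
    if (is.null(rs) || fold == 1) {
        return(floor(runif(n) * (maxStart + 1)))
    }
    w <- re - rs
    outside <- contigLen - w
    pIn <- fold * w / (outside + fold * w)
    inReg <- runif(n) < pIn
    start <- numeric(n)
    start[inReg] <- rs + floor(runif(sum(inReg)) * w)
    nOut <- sum(!inReg)
    u <- floor(runif(nOut) * outside)
    start[!inReg] <- ifelse(u < rs, u, u + w)
    # clamp so the fragment fits on the contig
    pmin(start, maxStart)
}

#' Simulate a xenograft cfDNA fragment population
#'
#' Draws the configured numbers of nuclear and mitochondrial fragments.
#' Each nuclear fragment is assigned to the graft genome with probability
#' \code{tumorFraction}; lengths come from the per-(genome, compartment)
#' models; placement is uniform along contigs (nuclear contigs chosen
#' proportional to length) except inside the copy-gain region, where graft
#' nuclear placement intensity is multiplied by \code{fold}. A configured
#' fraction of fragments is flagged cross-species ambiguous.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{fragments}, a \code{GRanges} (0-based starts
#'   stored as 1-based ranges per Bioconductor convention) with mcols
#'   \code{readId}, \code{genome}, \code{compartment}, \code{ambiguous};
#'   and \code{truth}, a list recording the tumor fraction, expected
#'   per-site VAF (\code{tumorFraction / 2}, heterozygous sites), the
#'   copy-gain region and the configured counts.
#' @examples
#' sim <- simulateFragments(demoSimulationConfig(seed = 1, nNuclear = 500))
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
#' @importFrom stats rbinom
#' @export
simulateFragments <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    idx <- contigIndex(config@graft, config@host)
    cnv <- config@cnvRegion

    drawCompartment <- function(genome, compartment, n) {
        if (n == 0L)
            return(data.frame(contig = character(), start = numeric(),
                              len = integer()))
        model <- config@models[[paste(genome, compartment, sep = "_")]]
        len <- drawFragmentLengths(model, n)
        sub <- idx[idx$genome == genome & idx$compartment == compartment, ,
                   drop = FALSE]
        ci <- if (nrow(sub) == 1L) rep(1L, n)
              else sample.int(nrow(sub), n, replace = TRUE,
                              prob = sub$length)
        start <- numeric(n)
        for (j in seq_len(nrow(sub))) {
            sel <- ci == j
            if (!any(sel)) next
            useCnv <- length(cnv) > 0 && genome == "graft" &&
                compartment == "nuclear" && sub$contig[j] == cnv$contig
            start[sel] <- sampleStarts(sum(sel), sub$length[j], len[sel],
                rs = if (useCnv) cnv$start, re = if (useCnv) cnv$end,
                fold = if (useCnv) cnv$fold else 1)
        }
        data.frame(contig = sub$contig[ci], start = start, len = len)
    }

    withSeed(config@seed, {
        nG <- rbinom(1L, as.integer(config@nNuclear), config@tumorFraction)
        nH <- as.integer(config@nNuclear) - nG
        parts <- list(
            graft_nuclear = drawCompartment("graft", "nuclear", nG),
            host_nuclear = drawCompartment("host", "nuclear", nH),
            graft_mito = drawCompartment("graft", "mito",
                                         as.integer(config@nMitoGraft)),
            host_mito = drawCompartment("host", "mito",
                                        as.integer(config@nMitoHost)))
        df <- do.call(rbind, parts)
        lab <- strsplit(rep(names(parts), vapply(parts, nrow, 0L)), "_")
        nTot <- nrow(df)
        ambiguous <- runif(nTot) < config@ambiguousFraction
    })

    gr <- GRanges(df$contig,
                  IRanges(start = df$start + 1L, width = df$len))
    seqlengths(gr) <- idx$length[match(seqlevels(gr), idx$contig)]
    gr$readId <- sprintf("frag%08d", seq_len(nTot))
    gr$genome <- vapply(lab, `[`, "", 1L)
    gr$compartment <- vapply(lab, `[`, "", 2L)
    gr$ambiguous <- ambiguous
    names(gr) <- NULL

    truth <- list(tumorFraction = config@tumorFraction,
                  expectedVaf = config@tumorFraction / 2,
                  cnvRegion = cnv,
                  counts = list(nuclearGraft = nG, nuclearHost = nH,
                                mitoGraft = as.integer(config@nMitoGraft),
                                mitoHost = as.integer(config@nMitoHost)),
                  seed = config@seed)
    list(fragments = gr, truth = truth)
}

#' Emit simulated variant pileups and a truth VCF
#'
#' For each configured heterozygous tumor-specific SNV, draws the
#' alternate-allele count as Binomial(depth, tumorFraction / 2) plus
#' sequencing errors on the remaining reads at \code{errorRate}, and
#' writes a pileup TSV (counts plus per-tissue presence flags) and a
#' minimal VCFv4.2 of the true sites. Tumor-specific sites are flagged
#' present in the tumor lesions and absent in the matched normal.
#'
#' @param config a \linkS4class{SimulationConfig} with non-empty
#'   \code{snvSites}.
#' @param tsvPath,vcfPath output file paths (either may be \code{NULL} to
#'   skip writing).
#' @return invisibly, the pileup data.frame (columns \code{contig},
#'   \code{pos}, \code{ref}, \code{alt}, \code{ref_count},
#'   \code{alt_count}, \code{primary}, \code{met1}, \code{met2},
#'   \code{cfdna}, \code{normal}).
#' @examples
#' pu <- emitVariantPileups(demoSimulationConfig(seed = 1, nNuclear = 0))
#' @importFrom utils write.table
#' @export
emitVariantPileups <- function(config, tsvPath = NULL, vcfPath = NULL) {
    stopifnot(is(config, "SimulationConfig"))
    sites <- config@snvSites
    if (nrow(sites) == 0L) stop("config has no snvSites")
    p <- config@tumorFraction / 2
    withSeed(config@seed + 1L, {
        trueAlt <- rbinom(nrow(sites), sites$depth, p)
        errAlt <- rbinom(nrow(sites), sites$depth - trueAlt, config@errorRate)
    })
    alt <- trueAlt + errAlt
    pu <- data.frame(contig = sites$contig, pos = sites$pos,
                     ref = sites$ref, alt = sites$alt,
                     ref_count = sites$depth - alt, alt_count = alt,
                     primary = TRUE, met1 = TRUE, met2 = TRUE,
                     cfdna = alt > 0, normal = FALSE,
                     stringsAsFactors = FALSE)
    if (!is.null(tsvPath))
        write.table(pu, tsvPath, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    if (!is.null(vcfPath))
        writeSitesVcf(sites, vcfPath, contigIndex(config@graft, config@host))
    invisible(pu)
}

# minimal VCFv4.2 writer for true SNV sites
writeSitesVcf <- function(sites, path, idx) {
    hdr <- c("##fileformat=VCFv4.2",
             "##source=cfFragmentomics-simulator",
             sprintf("##contig=<ID=%s,length=%d>",
                     idx$contig, as.integer(idx$length)),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    rows <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.",
                    sites$contig, as.integer(sites$pos),
                    sprintf("site%03d", seq_len(nrow(sites))),
                    sites$ref, sites$alt)
    writeLines(c(hdr, rows), path)
    invisible(path)
}

#' Simulate a tumor-burden cohort table
#'
#' Generates one row per blood sample with the variables the cohort
#' analyses use: mean mt-cfDNA fragment length, ctDNA percentage, tumor
#' size and ctDNA concentration. Cancer samples draw a tumor size uniform
#' on [1, 10] (unitless, as in reanalyzed cohorts without stated units);
#' their mean mt-cfDNA length decreases linearly with tumor size
#' (\code{interceptCancer - slope * size} plus Gaussian noise), their
#' ctDNA percentage increases with tumor size, and ctDNA concentration is
#' proportional to the percentage. Healthy samples draw mt lengths around
#' \code{meanHealthy}. Defaults reproduce a hepatocellular-carcinoma-like
#' cohort: 16 cancer vs 32 healthy, cancer mean mt length about 162.4 bp
#' vs healthy 173.25 bp, and ctDNA percentage missing for a quarter of
#' cancer samples (handled pairwise-complete downstream).
#'
#' @param nCancer,nHealthy group sizes.
#' @param interceptCancer,slope,noiseSd cancer mt-length model (bp; bp per
#'   size unit; bp).
#' @param meanHealthy,sdHealthy healthy mt-length distribution (bp).
#' @param propMissingCtdna fraction of cancer samples with missing ctDNA
#'   percentage.
#' @param seed integer RNG seed.
#' @return data.frame with columns \code{sample_id}, \code{patient_id},
#'   \code{group}, \code{timepoint}, \code{mean_mt_length},
#'   \code{ctdna_percent}, \code{tumor_size}, \code{ctdna_concentration},
#'   \code{disease_state}.
#' @examples
#' head(simulateCohort(seed = 1))
#' @export
simulateCohort <- function(nCancer = 16, nHealthy = 32,
                           interceptCancer = 170.66, slope = 1.5,
                           noiseSd = 3, meanHealthy = 173.25,
                           sdHealthy = 5, propMissingCtdna = 0.25,
                           seed = 1L) {
    withSeed(seed, {
        size <- runif(nCancer, 1, 10)
        mtC <- interceptCancer - slope * size + rnorm(nCancer, 0, noiseSd)
        ctdnaPct <- pmax(0, 2 * size + rnorm(nCancer, 0, 2))
        conc <- pmax(0, ctdnaPct * runif(nCancer, 0.8, 1.2))
        miss <- sample.int(nCancer, round(propMissingCtdna * nCancer))
        mtH <- rnorm(nHealthy, meanHealthy, sdHealthy)
    })
    ctdnaPct[miss] <- NA_real_
    conc[miss] <- NA_real_
    n <- nCancer + nHealthy
    data.frame(
        sample_id = sprintf("S%03d", seq_len(n)),
        patient_id = sprintf("P%03d", seq_len(n)),
        group = rep(c("cancer", "healthy"), c(nCancer, nHealthy)),
        timepoint = 1L,
        mean_mt_length = c(mtC, mtH),
        ctdna_percent = c(ctdnaPct, rep(NA_real_, nHealthy)),
        tumor_size = c(size, rep(NA_real_, nHealthy)),
        ctdna_concentration = c(conc, rep(NA_real_, nHealthy)),
        disease_state = rep(c("cancer", "healthy"), c(nCancer, nHealthy)),
        stringsAsFactors = FALSE)
}
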