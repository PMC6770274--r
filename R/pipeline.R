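pipelineDefaults <- function() {
    list(
        seed = 1L,
        outdir = NULL,
        stages = list(simulate = TRUE, profile = TRUE, classify = TRUE,
                      ctdna = TRUE, cnv = TRUE, cohort = TRUE),
        inputs = list(bam = NULL, pileup = NULL, cohort_table = NULL),
        simulate = list(n_nuclear = 1e5, tumor_fraction = 0.096,
                        snv_depth = 10000, error_rate = 0),
        profile = list(min_mapq = 20),
        classify = list(min_mapq = 0),
        ctdna = list(min_depth = 10, min_alt = 2, n_bootstrap = 2000,
                     ci_level = 0.95),
        cnv = list(flank_bins_per_side = NULL, bin_width = 5000),
        cohort = list(threshold = 5, n_cancer = 16, n_healthy = 32))
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), fills every missing key
#' with its default, rejects unknown keys by name, and checks value
#' ranges. All violations are collected and reported together.
#'
#' @param path YAML file path, or \code{NULL} when \code{config} is
#'   given directly.
#' @param config configuration list (ignored when \code{path} is given).
#' @return the normalized configuration list (invisibly on error-free
#'   validation); errors with the full list of violations otherwise.
#' @examples
#' cfg <- validateConfig(config = list(seed = 7))
#' @importFrom yaml read_yaml write_yaml
#' @export
validateConfig <- function(path = NULL, config = list()) {
    if (!is.null(path)) {
        if (!file.exists(path)) stop("config file not found: ", path)
        config <- read_yaml(path)
        if (is.null(config)) config <- list()
    }
    defaults <- pipelineDefaults()
    errors <- character()
    merge <- function(def, got, prefix) {
        unknown <- setdiff(names(got), names(def))
        if (length(unknown))
            errors <<- c(errors, paste0("unknown key", if (length(unknown) > 1) "s",
                ": ", paste0(prefix, unknown, collapse = ", ")))
        for (k in names(def)) {
            if (!k %in% names(got) || is.null(got[[k]])) next
            if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
                def[[k]] <- merge(def[[k]], as.list(got[[k]]),
                                  paste0(prefix, k, "."))
            } else {
                def[[k]] <- got[[k]]
            }
        }
        def
    }
    cfg <- merge(defaults, as.list(config), "")
    inRange <- function(v, lo, hi, name) {
        if (!is.null(v) && (!is.numeric(v) || v < lo || v > hi))
            errors <<- c(errors, sprintf("%s must lie in [%s, %s] (got %s)",
                                         name, lo, hi, v))
    }
    inRange(cfg$simulate$tumor_fraction, 0, 1, "simulate.tumor_fraction")
    inRange(cfg$simulate$error_rate, 0, 1, "simulate.error_rate")
    inRange(cfg$ctdna$ci_level, 0, 1, "ctdna.ci_level")
    inRange(cfg$cohort$threshold, 0, 100, "cohort.threshold")
    if (cfg$simulate$n_nuclear < 0)
        errors <- c(errors, "simulate.n_nuclear must be >= 0")
    if (length(errors))
        stop("invalid configuration:\n  ",
             paste(errors, collapse = "\n  "), call. = FALSE)
    cfg
}

#' @importFrom jsonlite write_json
writeJson <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    invisible(path)
}

stageMessage <- function(stage, t0) {
    message(sprintf("[%s] %s finished in %.1f s", format(Sys.time(), "%T"),
                    stage, as.numeric(Sys.time()) - t0))
}

#' Run the full cfDNA analysis pipeline
#'
#' Orchestrates simulate, profile, classify, ctdna, cnv and cohort stages
#' in dependency order under one configuration and seed, writing every
#' artifact (SAM alignments, pileup TSV, truth VCF/JSON, profile tables,
#' stage JSONs) plus a consolidated \code{report.json} into the output
#' directory. A failed stage halts its dependents; independent stages
#' still run. Rerunning with the same configuration and seed reproduces
#' every stochastic output byte for byte.
#'
#' @param config configuration list or YAML path (see
#'   \code{\link{validateConfig}}).
#' @param outdir output directory; overrides the config's.
#' @param seed RNG seed; overrides the config's.
#' @return the run report, invisibly: per-stage status and key metrics,
#'   the seed, and an md5 hash of the normalized configuration.
#' @examples
#' rep <- runPipeline(list(simulate = list(n_nuclear = 500)),
#'                    outdir = tempfile())
#' @importFrom tools md5sum
#' @export
runPipeline <- function(config = list(), outdir = NULL, seed = NULL) {
    cfg <- if (is.character(config)) validateConfig(path = config)
           else validateConfig(config = config)
    if (!is.null(outdir)) cfg$outdir <- outdir
    if (!is.null(seed)) cfg$seed <- seed
    if (is.null(cfg$outdir)) stop("an output directory is required")
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

    cfgPath <- file.path(cfg$outdir, "config.yaml")
    yaml::write_yaml(cfg[setdiff(names(cfg), "outdir")], cfgPath)
    report <- list(seed = cfg$seed,
                   configHash = unname(md5sum(cfgPath)),
                   stages = list(), metrics = list())

    simCfg <- demoSimulationConfig(
        seed = cfg$seed,
        nNuclear = cfg$simulate$n_nuclear,
        tumorFraction = cfg$simulate$tumor_fraction,
        snvDepth = cfg$simulate$snv_depth,
        errorRate = cfg$simulate$error_rate)
    idx <- contigIndex(simCfg@graft, simCfg@host)

    samPath <- cfg$inputs$bam
    pileupPath <- cfg$inputs$pileup
    truth <- NULL
    runStage <- function(name, deps, fn) {
        if (!isTRUE(cfg$stages[[name]])) {
            report$stages[[name]] <<- "disabled"
            return(invisible(NULL))
        }
        failedDep <- deps[vapply(deps, function(d)
            identical(report$stages[[d]], "failed") ||
            identical(report$stages[[d]], "skipped"), logical(1))]
        if (length(failedDep)) {
            report$stages[[name]] <<- "skipped"
            message("skipping stage '", name, "' (dependency failed: ",
                    paste(failedDep, collapse = ", "), ")")
            return(invisible(NULL))
        }
        t0 <- as.numeric(Sys.time())
        res <- tryCatch({
            m <- fn()
            report$stages[[name]] <<- "ok"
            if (!is.null(m)) report$metrics[[name]] <<- m
            stageMessage(name, t0)
        }, error = function(e) {
            report$stages[[name]] <<- "failed"
            message("stage '", name, "' failed: ", conditionMessage(e))
        })
        invisible(NULL)
    }

    runStage("simulate", character(), function() {
        sim <- simulateFragments(simCfg)
        truth <<- sim$truth
        samPath <<- file.path(cfg$outdir, "sample.sam")
        emitAlignments(sim$fragments, idx, samPath)
        pileupPath <<- file.path(cfg$outdir, "pileup.tsv")
        emitVariantPileups(simCfg, pileupPath,
                           file.path(cfg$outdir, "sites.vcf"))
        writeJson(sim$truth, file.path(cfg$outdir, "truth.json"))
        list(nFragments = length(sim$fragments),
             tumorFraction = sim$truth$tumorFraction)
    })

    frags <- NULL
    runStage("profile", "simulate", function() {
        if (is.null(samPath)) stop("no alignment input (inputs.bam)")
        frags <<- extractFragments(samPath, idx,
                                   minMapq = cfg$profile$min_mapq)
        sel <- expand.grid(genome = c("graft", "host"),
                           compartment = c("nuclear", "mito"),
                           stringsAsFactors = FALSE)
        profs <- lapply(seq_len(nrow(sel)), function(i)
            sizeHistogram(frags, sel$genome[i], sel$compartment[i]))
        names(profs) <- paste(sel$genome, sel$compartment, sep = "_")
        tab <- do.call(rbind, lapply(names(profs), function(nm) {
            ct <- profileCounts(profs[[nm]])
            data.frame(selection = nm, length = as.integer(names(ct)),
                       count = as.integer(ct))[ct > 0, ]
        }))
        write.table(tab, file.path(cfg$outdir, "size_profiles.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        per <- detectPeriodicity(profs$graft_nuclear)
        nGn <- nFragments(profs$graft_nuclear)
        nHn <- nFragments(profs$host_nuclear)
        m <- list(
            modal = lapply(profs, modalLength),
            mean = lapply(profs, meanLength),
            n = lapply(profs, nFragments),
            ladderPeriod = if (per@ok) per@period else NA,
            ladderStrength = if (per@ok) per@strength else NA,
            mtAbundance = list(
                graft = if (nGn > 0)
                    normalizedMtAbundance(nFragments(profs$graft_mito), nGn)
                    else NA,
                host = if (nHn > 0)
                    normalizedMtAbundance(nFragments(profs$host_mito), nHn)
                    else NA))
        writeJson(m, file.path(cfg$outdir, "profile.json"))
        m
    })

    runStage("classify", "simulate", function() {
        if (is.null(samPath)) stop("no alignment input (inputs.bam)")
        summ <- summarizeClassification(
            classifyTemplates(samPath, idx,
                              minMapq = cfg$classify$min_mapq))
        m <- list(counts = as.list(summ@counts),
                  fractions = as.list(summ@fractions),
                  fractionsMapped = as.list(summ@fractionsMapped),
                  total = summ@total)
        writeJson(m, file.path(cfg$outdir, "classification.json"))
        m
    })

    runStage("ctdna", "simulate", function() {
        if (is.null(pileupPath)) stop("no pileup input (inputs.pileup)")
        pu <- readPileupTable(pileupPath)
        sel <- selectTumorSpecificSites(pu,
            minDepth = cfg$ctdna$min_depth, minAlt = cfg$ctdna$min_alt)
        est <- estimateCtdnaFraction(sel,
            nBootstrap = cfg$ctdna$n_bootstrap,
            level = cfg$ctdna$ci_level, seed = cfg$seed + 2L)
        m <- list(nSites = est@nSites, meanVaf = meanVaf(est),
                  ctdnaFraction = ctdnaFraction(est),
                  ci = as.list(ctdnaCI(est)))
        writeJson(m, file.path(cfg$outdir, "ctdna.json"))
        m
    })

    runStage("cnv", c("simulate", "profile"), function() {
        if (is.null(frags)) stop("no extracted fragments available")
        reg <- if (!is.null(truth)) truth$cnvRegion
               else simCfg@cnvRegion
        bins <- tileBins(idx, width = cfg$cnv$bin_width)
        gsel <- frags[frags$genome == "graft" &
                      frags$compartment == "nuclear"]
        bins <- countFragmentsInBins(gsel, bins)
        test <- mannWhitneyGain(bins,
            sprintf("%s:%d-%d", reg$contig, reg$start + 1L,
                    as.integer(reg$end)),
            flankBinsPerSide = cfg$cnv$flank_bins_per_side)
        m <- list(U = test@U, pValue = pValue(test),
                  nRegionBins = test@nRegionBins,
                  nFlankBins = test@nFlankBins, method = test@method)
        writeJson(m, file.path(cfg$outdir, "cnv.json"))
        m
    })

    runStage("cohort", character(), function() {
        co <- if (!is.null(cfg$inputs$cohort_table))
                  readCohortTable(cfg$inputs$cohort_table)
              else simulateCohort(nCancer = cfg$cohort$n_cancer,
                                  nHealthy = cfg$cohort$n_healthy,
                                  seed = cfg$seed + 3L)
        cmp <- welchTTest(co$mean_mt_length[co$group == "cancer"],
                          co$mean_mt_length[co$group == "healthy"],
                          labels = c("cancer", "healthy"))
        corr <- pearsonCorrelation(co$tumor_size, co$mean_mt_length,
                                   c("tumor_size", "mean_mt_length"))
        dich <- dichotomizeByCtdna(co, threshold = cfg$cohort$threshold)
        m <- list(
            groupComparison = list(meanCancer = cmp@meanA,
                meanHealthy = cmp@meanB, t = cmp@statistic,
                df = cmp@df, p = cmp@pValue),
            correlation = list(r = corr@r, n = corr@n, p = corr@pValue),
            dichotomized = if (is.null(dich$comparison)) NULL
                else list(meanHigh = dich$comparison@meanA,
                          meanLow = dich$comparison@meanB,
                          p = dich$comparison@pValue))
        writeJson(m, file.path(cfg$outdir, "cohort.json"))
        m
    })

    writeJson(report, file.path(cfg$outdir, "report.json"))
    invisible(report)
}
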