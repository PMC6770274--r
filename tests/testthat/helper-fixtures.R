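# shared fixture builders; everything is generated in code at test time

smallDemoConfig <- function(seed = 1L, nNuclear = 2000,
                            tumorFraction = 0.096, ...) {
    demoSimulationConfig(seed = seed, nNuclear = nNuclear,
                         tumorFraction = tumorFraction, ...)
}

demoIndex <- function(cfg = smallDemoConfig()) {
    contigIndex(cfg@graft, cfg@host)
}

# write a SAM file from raw record lines under the demo two-genome header
writeRawSam <- function(records, idx = demoIndex(),
                        path = tempfile(fileext = ".sam")) {
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", idx$contig, as.integer(idx$length)))
    writeLines(c(hdr, records), path)
    path
}

# profile built from an explicit length -> count map
profileFromCounts <- function(map) {
    sizeHistogramFromLengths(rep(as.integer(names(map)),
                                 times = as.integer(map)))
}

# independent permutation oracle for the one-sided Mann-Whitney gain p:
# enumerate all assignments of the pooled counts into region/flank groups
permutationGainP <- function(x, y) {
    vals <- c(x, y)
    m <- length(x)
    U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    idx <- utils::combn(length(vals), m)
    Us <- apply(idx, 2L, function(ii) {
        a <- vals[ii]; b <- vals[-ii]
        sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    })
    mean(Us >= U - 1e-9)
}
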