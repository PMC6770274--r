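#' Construct a GenomeSpec
#'
#' @param label \code{"graft"} (tumor genome) or \code{"host"} (normal
#'   genome).
#' @param nuclearContigs named numeric vector of nuclear contig lengths in
#'   bp, e.g. \code{c(graft_chr1 = 2e6)}.
#' @param mitoContig named numeric vector of length 1 giving the
#'   mitochondrial contig and its length; defaults to a 16 569 bp
#'   \code{<label>_chrM} (the human mtDNA length).
#' @return a \linkS4class{GenomeSpec}.
#' @examples
#' genomeSpec("host", c(host_chr1 = 1e6), c(host_chrM = 16299))
#' @export
genomeSpec <- function(label, nuclearContigs,
                       mitoContig = stats::setNames(16569, paste0(label, "_chrM"))) {
    new("GenomeSpec", label = label,
        nuclearContigs = nuclearContigs, mitoContig = mitoContig)
}

#' Contig index of a two-genome reference
#'
#' Maps every contig of the combined graft + host reference to its genome
#' of origin, compartment (nuclear or mitochondrial) and homologous contig
#' in the other genome (nuclear contigs pair by order, mitochondrial
#' contigs pair with each other). The index is the lookup table every
#' downstream module uses to assign fragments to a genome and compartment.
#'
#' @param graft,host \linkS4class{GenomeSpec}s.
#' @return data.frame with columns \code{contig}, \code{length},
#'   \code{genome}, \code{compartment}, \code{homolog}.
#' @examples
#' gi <- contigIndex(genomeSpec("graft", c(graft_chr1 = 1e6)),
#'                   genomeSpec("host", c(host_chr1 = 1e6)))
#' @export
contigIndex <- function(graft, host) {
    stopifnot(is(graft, "GenomeSpec"), is(host, "GenomeSpec"))
    one <- function(spec) {
        data.frame(
            contig = c(names(spec@nuclearContigs), names(spec@mitoContig)),
            length = unname(c(spec@nuclearContigs, spec@mitoContig)),
            genome = spec@label,
            compartment = c(rep("nuclear", length(spec@nuclearContigs)), "mito"),
            stringsAsFactors = FALSE)
    }
    idx <- rbind(one(graft), one(host))
    if (anyDuplicated(idx$contig))
        stop("duplicate contig name across genomes: ",
             paste(idx$contig[duplicated(idx$contig)], collapse = ", "))
    pairUp <- function(a, b) {
        # nuclear contigs pair by order; unmatched tails pair to the first
        h <- rep(b[1L], length(a))
        k <- seq_len(min(length(a), length(b)))
        h[k] <- b[k]
        h
    }
    gn <- names(graft@nuclearContigs); hn <- names(host@nuclearContigs)
    idx$homolog <- NA_character_
    idx$homolog[match(gn, idx$contig)] <- pairUp(gn, hn)
    idx$homolog[match(hn, idx$contig)] <- pairUp(hn, gn)
    idx$homolog[idx$contig == names(graft@mitoContig)] <- names(host@mitoContig)
    idx$homolog[idx$contig == names(host@mitoContig)] <- names(graft@mitoContig)
    idx
}

#' Build toy FASTA genomes for a two-genome reference
#'
#' Writes deterministic random (uniform-base) sequences for every contig
#' of the graft and host genomes, one FASTA per genome, and returns the
#' contig index. These toy genomes stand in for the real human/mouse
#' references: downstream analyses use only contig names and lengths, so
#' uniform random sequence is sufficient.
#'
#' @param graft,host \linkS4class{GenomeSpec}s.
#' @param dir output directory (created if needed).
#' @param seed integer RNG seed; the same spec and seed reproduce
#'   byte-identical FASTA files.
#' @return list with \code{graftFasta}, \code{hostFasta} (file paths) and
#'   \code{index} (the \code{\link{contigIndex}} data.frame).
#' @examples
#' gs <- genomeSpec("graft", c(graft_chr1 = 5000))
#' hs <- genomeSpec("host", c(host_chr1 = 5000))
#' res <- buildToyGenomes(gs, hs, tempfile(), seed = 1)
#' @importFrom Biostrings DNAStringSet writeXStringSet
#' @export
buildToyGenomes <- function(graft, host, dir, seed = 1L) {
    idx <- contigIndex(graft, host)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    withSeed(seed, {
        paths <- lapply(c("graft", "host"), function(g) {
            sub <- idx[idx$genome == g, , drop = FALSE]
            seqs <- DNAStringSet(vapply(sub$length, function(L)
                paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                      collapse = ""), character(1)))
            names(seqs) <- sub$contig
            path <- file.path(dir, paste0(g, ".fa"))
            writeXStringSet(seqs, path)
            path
        })
    })
    list(graftFasta = paths[[1L]], hostFasta = paths[[2L]], index = idx)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(as.integer(seed))
    eval.parent(substitute(expr))
}
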