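#' Write simulated fragments as paired-end SAM alignments
#'
#' Emits one properly-paired primary record pair per fragment: the
#' leftmost mate forward with a positive template length equal to the
#' fragment length, the rightmost mate reverse with the negative length.
#' Fragments flagged ambiguous additionally receive a secondary record
#' pair at the same coordinates on the homologous contig of the other
#' genome, mimicking reads that map to both species. Truth labels are
#' stored in optional fields (\code{XG}: genome, \code{XC}: compartment).
#' Sequences are omitted (\code{*}); every analysis here uses coordinates
#' only.
#'
#' @param fragments \code{GRanges} from \code{\link{simulateFragments}}.
#' @param index contig index data.frame (see \code{\link{contigIndex}}).
#' @param samPath output SAM path.
#' @param readLength mate read length in bp (capped at the fragment
#'   length).
#' @return invisibly, \code{samPath}.
#' @examples
#' cfg <- demoSimulationConfig(seed = 1, nNuclear = 200)
#' sim <- simulateFragments(cfg)
#' sam <- tempfile(fileext = ".sam")
#' emitAlignments(sim$fragments, contigIndex(cfg@graft, cfg@host), sam)
#' @importFrom GenomicRanges start end width seqnames
#' @export
emitAlignments <- function(fragments, index, samPath, readLength = 75L) {
    contig <- as.character(seqnames(fragments))
    bad <- !contig %in% index$contig
    if (any(bad)) stop("fragment on unknown contig: ", contig[which(bad)[1L]])
    clen <- index$length[match(contig, index$contig)]
    if (any(start(fragments) < 1L) || any(end(fragments) > clen))
        stop("fragment interval outside contig bounds")

    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", index$contig,
                     as.integer(index$length)),
             "@PG\tID:cfFragmentomics\tPN:cfFragmentomics")

    recPair <- function(qname, rname, pos1, tlen, rl, flagAdd, xg, xc) {
        cigar <- sprintf("%dM", rl)
        posR <- pos1 + tlen - rl
        tags <- sprintf("XG:Z:%s\tXC:Z:%s", xg, xc)
        c(sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t*\t*\t%s",
                  qname, 99L + flagAdd, rname, pos1, cigar, posR, tlen, tags),
          sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t*\t*\t%s",
                  qname, 147L + flagAdd, rname, posR, cigar, pos1, -tlen, tags))
    }

    L <- width(fragments)
    rl <- pmin(as.integer(readLength), L)
    pos1 <- start(fragments)
    recs <- as.vector(rbind(
        sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*\tXG:Z:%s\tXC:Z:%s",
                fragments$readId, contig, pos1, rl, pos1 + L - rl, L,
                fragments$genome, fragments$compartment),
        sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t*\t*\tXG:Z:%s\tXC:Z:%s",
                fragments$readId, contig, pos1 + L - rl, rl, pos1, -L,
                fragments$genome, fragments$compartment)))

    sec <- character(0)
    amb <- which(isTRUE0(fragments$ambiguous))
    if (length(amb)) {
        hom <- index$homolog[match(contig[amb], index$contig)]
        homLen <- index$length[match(hom, index$contig)]
        # keep the secondary pair on-contig if the homolog is shorter
        posS <- pmin(pos1[amb], pmax(1, homLen - L[amb] + 1))
        secs <- lapply(seq_along(amb), function(k) {
            i <- amb[k]
            recPair(fragments$readId[i], hom[k], posS[k], L[i], rl[i], 256L,
                    fragments$genome[i], fragments$compartment[i])
        })
        sec <- unlist(secs)
    }
    writeLines(c(hdr, recs, sec), samPath)
    invisible(samPath)
}

isTRUE0 <- function(x) if (is.null(x)) logical(0) else !is.na(x) & x

# Read a SAM or BAM file into a flat data.frame of alignment records.
# SAM input is converted through Rsamtools::asBam in a temporary
# directory.
#' @importFrom Rsamtools asBam scanBam ScanBamParam scanBamFlag
readAlignmentRecords <- function(path) {
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        dest <- tempfile()
        path <- suppressMessages(
            asBam(path, destination = dest, overwrite = TRUE,
                  indexDestination = FALSE))
    }
    what <- c("qname", "flag", "rname", "pos", "mapq", "isize")
    res <- scanBam(path, param = ScanBamParam(what = what))[[1L]]
    data.frame(qname = res$qname, flag = res$flag,
               rname = as.character(res$rname), pos = res$pos,
               mapq = res$mapq, isize = res$isize,
               stringsAsFactors = FALSE)
}
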