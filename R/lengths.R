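#' Construct a fragment length model
#'
#' @param kind \code{"nucleosomal_ladder"} or \code{"gamma"}.
#' @param modalLength mono-nucleosome peak (bp); ladder kind.
#' @param modalSd Gaussian peak SD (bp); ladder kind.
#' @param ladderPeriod ladder tooth spacing (bp).
#' @param ladderMin smallest tooth position retained (bp).
#' @param ladderWeight mixture weight of the sub-nucleosomal comb.
#' @param meanLength,shape gamma mean (bp) and shape; gamma kind.
#' @return a \linkS4class{FragmentLengthModel}.
#' @examples
#' tumorNuclear <- fragmentLengthModel("nucleosomal_ladder",
#'     modalLength = 144, modalSd = 3, ladderWeight = 0.3)
#' graftMito <- fragmentLengthModel("gamma", meanLength = 109)
#' @export
fragmentLengthModel <- function(kind = c("nucleosomal_ladder", "gamma"),
                                modalLength = NA_real_, modalSd = NA_real_,
                                ladderPeriod = 10.6, ladderMin = 50,
                                ladderWeight = 0.3,
                                meanLength = NA_real_, shape = 8) {
    kind <- match.arg(kind)
    new("FragmentLengthModel", kind = kind,
        modalLength = as.numeric(modalLength), modalSd = as.numeric(modalSd),
        ladderPeriod = as.numeric(ladderPeriod),
        ladderMin = as.numeric(ladderMin),
        ladderWeight = as.numeric(ladderWeight),
        meanLength = as.numeric(meanLength), shape = as.numeric(shape))
}

# tooth centers of the sub-nucleosomal comb, modalLength - k * period, k >= 1,
# truncated below at ladderMin
ladderTeeth <- function(model) {
    stopifnot(model@kind == "nucleosomal_ladder")
    k <- seq_len(max(0L, floor((model@modalLength - model@ladderMin) /
                               model@ladderPeriod)))
    model@modalLength - k * model@ladderPeriod
}

#' Draw fragment lengths from a model
#'
#' Draws \code{n} integer fragment lengths from a
#' \linkS4class{FragmentLengthModel} using the current RNG stream.
#' Lengths are rounded to integers and restricted to [30, 1000] bp by
#' resampling, mimicking the size window a paired-end cfDNA library
#' retains.
#'
#' @param model a \linkS4class{FragmentLengthModel}.
#' @param n number of lengths to draw (>= 0).
#' @return integer vector of length \code{n}.
#' @examples
#' set.seed(1)
#' L <- drawFragmentLengths(
#'     fragmentLengthModel("gamma", meanLength = 109), 1000)
#' @importFrom stats rnorm rgamma runif
#' @export
drawFragmentLengths <- function(model, n) {
    stopifnot(is(model, "FragmentLengthModel"))
    if (length(n) != 1L || !is.finite(n) || n < 0)
        stop("n must be a single non-negative number")
    n <- as.integer(n)
    drawOne <- function(m) {
        if (model@kind == "gamma") {
            rgamma(m, shape = model@shape,
                   scale = model@meanLength / model@shape)
        } else {
            teeth <- ladderTeeth(model)
            comb <- length(teeth) > 0 &
                runif(m) < model@ladderWeight
            mu <- rep(model@modalLength, m)
            if (any(comb))
                mu[comb] <- teeth[sample.int(length(teeth), sum(comb),
                                             replace = TRUE)]
            rnorm(m, mean = mu, sd = model@modalSd)
        }
    }
    out <- integer(0)
    need <- n
    while (need > 0L) {
        x <- as.integer(round(drawOne(need)))
        x <- x[x >= 30L & x <= 1000L]
        out <- c(out, x)
        need <- n - length(out)
    }
    out[seq_len(n)]
}

# Exact density (up to truncation renormalization) of the ladder model at
# integer lengths; used as an independent check that the histogram mode is
# dominated by the main Gaussian.
ladderDensity <- function(model, lengths) {
    stopifnot(model@kind == "nucleosomal_ladder")
    teeth <- ladderTeeth(model)
    main <- (1 - model@ladderWeight) *
        stats::dnorm(lengths, model@modalLength, model@modalSd)
    comb <- 0
    if (length(teeth))
        comb <- model@ladderWeight / length(teeth) *
            rowSums(outer(lengths, teeth,
                          function(l, t) stats::dnorm(l, t, model@modalSd)))
    main + comb
}
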