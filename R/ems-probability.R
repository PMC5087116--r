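# Analytic false-positive probabilities under the canonical EMS model:
# G/C-to-A/T transitions, uniformly and independently distributed over
# unmasked G/C sites.

#' Estimate the per-G/C-site canonical mutation rate
#'
#' The per-site rate mu is the number of canonical (G>A / C>T) SNVs called
#' in a line divided by its callable G/C bases.  Equivalently mu = d / g,
#' where d is the canonical mutation density per callable bp and g the
#' G/C fraction of callable sequence.
#'
#' @param nCanonicalSnvs number of canonical SNV calls.
#' @param callableGcBases callable G/C bases (must be positive); see
#'   \code{\link{callableGcBases}}.
#' @return the per-site rate, a single numeric in [0, 1].
#' @examples
#' estimateMu(10, 2e6)   # 5e-06
#' @export
estimateMu <- function(nCanonicalSnvs, callableGcBases) {
    if (length(callableGcBases) != 1L || is.na(callableGcBases) ||
        callableGcBases <= 0)
        .configError("callableGcBases must be a single positive number")
    if (nCanonicalSnvs < 0)
        .configError("nCanonicalSnvs must be non-negative")
    nCanonicalSnvs / callableGcBases
}

#' Probability that a contig is mutated by chance in one mutant
#'
#' Under independent per-site mutation at rate \code{mu}, the probability
#' that a contig with \code{gcBases} unmasked G/C sites carries at least
#' one canonical mutation in a single mutant line is
#' \deqn{p = 1 - (1 - \mu)^{n_{GC}}.}
#' The complement form is exact under the stated independence; in the
#' regime of interest (mu * gcBases well below 1) it agrees with the
#' linear approximation mu * gcBases.  Nondecreasing in both arguments.
#'
#' @param gcBases unmasked G/C sites in the contig (vectorised).
#' @param mu per-site mutation rate in [0, 1].
#' @return the per-mutant false-positive probability.
#' @examples
#' contigFalsePositiveProb(5280, 1e-5)
#' @seealso \code{\link{jointFalsePositive}}
#' @export
contigFalsePositiveProb <- function(gcBases, mu) {
    if (any(is.na(mu)) || any(mu < 0) || any(mu > 1))
        .configError("mu must be in [0, 1]")
    if (any(gcBases < 0))
        .configError("gcBases must be non-negative")
    # expm1/log1p form keeps precision at small mu
    -expm1(gcBases * log1p(-mu))
}

#' Joint false-positive probability across mutants
#'
#' The probability that the same contig is mutated by chance in every one
#' of the mutant lines: the product of the per-mutant probabilities, under
#' the independence of the mutagenesis of different lines.  Never exceeds
#' the smallest per-mutant probability.
#'
#' @param perMutantProbs numeric vector of per-mutant probabilities, each
#'   in [0, 1]; must be non-empty.
#' @return a single numeric probability.
#' @examples
#' jointFalsePositive(rep(0.11, 12))     # ~3.14e-12
#' formatOneIn(jointFalsePositive(rep(0.11, 12)))   # "1 in 3 x 10^11"
#' @export
jointFalsePositive <- function(perMutantProbs) {
    if (length(perMutantProbs) == 0L)
        .configError("perMutantProbs must be non-empty")
    if (any(is.na(perMutantProbs)) || any(perMutantProbs < 0) ||
        any(perMutantProbs > 1))
        .configError("probabilities must be in [0, 1]")
    prod(perMutantProbs)
}

#' Reciprocal of a probability, rounded to one significant figure
#'
#' @param p a probability in (0, 1].
#' @return 1/p rounded to one significant figure with half-up rounding
#'   (so 250 rounds to 300, matching the conventional "1 in X" rendering).
#' @seealso \code{\link{formatOneIn}}
#' @export
oneInReciprocal <- function(p) {
    if (length(p) != 1L || is.na(p) || p <= 0 || p > 1)
        .configError("p must be a single probability in (0, 1]")
    x <- 1 / p
    e <- floor(log10(x))
    m <- x / 10^e
    mr <- floor(m + 0.5)      # half-up, not banker's rounding
    if (mr >= 10) { mr <- 1; e <- e + 1 }
    mr * 10^e
}

#' Render a probability as "1 in X"
#'
#' Formats a small probability the way odds are conventionally quoted:
#' \code{"1 in X"} with X = 1/p rounded to one significant figure, and
#' rendered as mantissa x 10^exponent once X reaches 10,000.
#'
#' @param p a probability in (0, 1].
#' @return a character string.
#' @examples
#' formatOneIn(0.004)                       # "1 in 300"
#' formatOneIn(jointFalsePositive(rep(0.11, 12)))
#' @export
formatOneIn <- function(p) {
    x <- oneInReciprocal(p)
    if (x >= 1e4) {
        e <- floor(log10(x) + 1e-9)
        m <- round(x / 10^e)
        sprintf("1 in %d \u00d7 10^%d", as.integer(m), as.integer(e))
    } else {
        sprintf("1 in %d", as.integer(round(x)))
    }
}
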