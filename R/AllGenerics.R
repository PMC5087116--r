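# Generics for the package's S4 accessors.

#' @rdname ReferenceAssembly-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("contigIds", function(x) standardGeneric("contigIds"))

#' @rdname ReferenceAssembly-class
#' @export
setGeneric("contigLengths", function(x) standardGeneric("contigLengths"))

#' @rdname ReferenceAssembly-class
#' @export
setGeneric("gcUnmasked", function(x) standardGeneric("gcUnmasked"))

#' @rdname ReferenceAssembly-class
#' @export
setGeneric("unmaskedLengths", function(x) standardGeneric("unmaskedLengths"))

#' @rdname MutantCallSet-class
#' @export
setGeneric("mutantId", function(x) standardGeneric("mutantId"))

#' @rdname MutantCallSet-class
#' @export
setGeneric("snvCalls", function(x) standardGeneric("snvCalls"))

#' @rdname MutantCallSet-class
#' @export
setGeneric("nCalls", function(x) standardGeneric("nCalls"))

#' @rdname MutantCallSet-class
#' @export
setGeneric("callableBases", function(x) standardGeneric("callableBases"))

#' @rdname MutantCallSet-class
#' @export
setGeneric("callableGcBases", function(x) standardGeneric("callableGcBases"))

#' Fraction of canonical EMS calls
#'
#' The fraction of SNV calls that are canonical EMS transitions (G>A or
#' C>T).  EMS-derived mutants are expected near 1; values far below 1 point
#' to natural variation (e.g. a cultivar contaminant) or artifacts.
#'
#' @param x a \linkS4class{MutantCallSet}.
#' @return a single numeric fraction, or \code{NA} for an empty call set.
#' @examples
#' cs <- MutantCallSet("m1", data.frame(
#'     contig = "c1", pos = c(10L, 20L), ref = c("G", "A"),
#'     alt = c("A", "G"), frequency = 1, depth = 30L,
#'     canonical = c(TRUE, FALSE)), callableBases = 1000)
#' canonicalFraction(cs)  # 0.5
#' @export
setGeneric("canonicalFraction", function(x) standardGeneric("canonicalFraction"))

#' @rdname ContigRanking-class
#' @export
setGeneric("contigReports", function(x) standardGeneric("contigReports"))

#' @rdname ContigRanking-class
#' @export
setGeneric("contigHistogram", function(x) standardGeneric("contigHistogram"))

#' @rdname SimulatedExperiment-class
#' @export
setGeneric("causalContig", function(x) standardGeneric("causalContig"))

#' @rdname SimulatedExperiment-class
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
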