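#' Classify alignment columns by outgroup parsimony
#'
#' @param x a [ThreeTaxonAlignment-class].
#' @param ... further arguments for methods.
#' @return the alignment with per-column states filled.
#' @export
setGeneric("classifyColumns", function(x, ...)
    standardGeneric("classifyColumns"))

#' Per-column parsimony states
#'
#' @param x a classified [ThreeTaxonAlignment-class].
#' @return character vector of column states.
#' @export
setGeneric("columnStates", function(x) standardGeneric("columnStates"))

#' Count gap-free alignment columns
#'
#' @param x a [ThreeTaxonAlignment-class].
#' @return integer: columns with no gap in any sequence.
#' @export
setGeneric("alignableSites", function(x) standardGeneric("alignableSites"))

#' Per-domain substitution counts and relative-rate tests
#'
#' @param x a classified [ThreeTaxonAlignment-class].
#' @param map a [DomainMap-class].
#' @param ... further arguments for methods.
#' @return `data.frame`, one row per domain plus the whole protein.
#' @export
setGeneric("domainCounts", function(x, map, ...)
    standardGeneric("domainCounts"))

#' Lineage-specific in-frame deletions
#'
#' @param x a [ThreeTaxonAlignment-class].
#' @return `data.frame` with columns `lineage`, `start`, `length`.
#' @export
setGeneric("findDeletions", function(x) standardGeneric("findDeletions"))

#' Expected sperm-class distribution under meiosis-II nondisjunction
#'
#' @param params a [MeiosisParams-class].
#' @return named numeric distribution over sperm classes.
#' @export
setGeneric("spermPool", function(params) standardGeneric("spermPool"))

#' Expected progeny composition from a sperm pool
#'
#' @param pool named sperm-class distribution (from [spermPool()]).
#' @param params a [MeiosisParams-class].
#' @return a [BroodExpectation-class].
#' @export
setGeneric("progenyDistribution", function(pool, params)
    standardGeneric("progenyDistribution"))
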