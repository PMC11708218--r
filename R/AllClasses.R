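#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IRanges IRangesList
#' @importClassesFrom Biostrings AAStringSet DNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' TissueExpression: normalized read counts across sex-by-tissue samples
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] carrying one
#' `"nrc"` assay of nonnegative normalized read counts (NRC), with
#' required `colData` columns `sex`, `tissue` and `replicate`
#' identifying each library. Expression values are consumed as given;
#' no normalization is performed here.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [TissueExpression()], [tauTable()], [medianByGroup()]
#' @exportClass TissueExpression
setClass("TissueExpression", contains = "SummarizedExperiment")

setValidity("TissueExpression", function(object) {
    msg <- character()
    if (!"nrc" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'nrc' is required")
    else {
        a <- SummarizedExperiment::assay(object, "nrc")
        if (any(!is.finite(a)))
            msg <- c(msg, "all NRC values must be finite")
        else if (any(a < 0))
            msg <- c(msg, "all NRC values must be nonnegative")
    }
    cd <- SummarizedExperiment::colData(object)
    need <- c("sex", "tissue", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData must contain: ",
                             paste(miss, collapse = ", ")))
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids (rownames) must be unique")
    if (length(msg)) msg else TRUE
})

#' ThreeTaxonAlignment: two ingroup paralogs plus an outgroup
#'
#' Holds three aligned amino-acid sequences — ingroup lineages A and B
#' (e.g. two paralogs, or orthologs from two sister lineages) and an
#' outgroup O — together with an optional per-column parsimony
#' classification filled in by [classifyColumns()].
#'
#' Column states are one of `identical`, `subst_A`, `subst_B`,
#' `subst_O`, `ambiguous` (all three residues distinct), or `gapped`
#' (a gap in any sequence).
#'
#' @slot seqs An [Biostrings::AAStringSet] of length 3, names
#'   `c("A", "B", "O")`, all elements of equal width.
#' @slot states character vector of per-column states, or length 0
#'   before classification.
#' @seealso [ThreeTaxonAlignment()], [classifyColumns()],
#'   [domainCounts()], [findDeletions()]
#' @exportClass ThreeTaxonAlignment
setClass("ThreeTaxonAlignment",
         representation(seqs = "AAStringSet", states = "character"))

.COLUMN_STATES <- c("identical", "subst_A", "subst_B", "subst_O",
                    "ambiguous", "gapped")

setValidity("ThreeTaxonAlignment", function(object) {
    msg <- character()
    if (length(object@seqs) != 3L)
        msg <- c(msg, "exactly three sequences required")
    else {
        w <- Biostrings::width(object@seqs)
        if (length(unique(w)) != 1L)
            msg <- c(msg, "aligned sequences must have equal length")
        if (!identical(names(object@seqs), c("A", "B", "O")))
            msg <- c(msg, "sequences must be named A, B, O")
        if (length(object@states) &&
            length(object@states) != w[1L])
            msg <- c(msg, "states must have one entry per column")
    }
    if (length(object@states) &&
        !all(object@states %in% .COLUMN_STATES))
        msg <- c(msg, "unknown column state")
    if (length(msg)) msg else TRUE
})

#' DomainMap: named column intervals on a protein alignment
#'
#' Maps protein domains (e.g. kinase, linker, PBD, PB1, PB2) to sets
#' of alignment-column ranges. Ranges are stored 1-based inclusive as
#' an [IRanges::IRangesList], one element per domain. When the
#' canonical Plk domains are present, validity enforces that PB1 and
#' PB2 lie within the PBD and that kinase, linker and PBD are
#' mutually disjoint.
#'
#' @slot ranges named `IRangesList` of column intervals.
#' @seealso [DomainMap()], [domainCounts()], [readDomainMap()]
#' @exportClass DomainMap
setClass("DomainMap", representation(ranges = "IRangesList"))

setValidity("DomainMap", function(object) {
    r <- object@ranges
    msg <- character()
    if (length(r) && (is.null(names(r)) || anyDuplicated(names(r))))
        msg <- c(msg, "domains must be uniquely named")
    if (any(unlist(IRanges::start(r)) < 1L))
        msg <- c(msg, "domain ranges must start at column 1 or later")
    cols <- lapply(r, function(x)
        unique(unlist(mapply(seq.int, IRanges::start(x), IRanges::end(x),
                             SIMPLIFY = FALSE))))
    within <- function(inner, outer)
        all(cols[[inner]] %in% cols[[outer]])
    nm <- names(r)
    for (pb in c("PB1", "PB2"))
        if (all(c(pb, "PBD") %in% nm) && !within(pb, "PBD"))
            msg <- c(msg, paste0(pb, " must lie within PBD"))
    core <- intersect(c("kinase", "linker", "PBD"), nm)
    if (length(core) > 1L) {
        for (i in seq_len(length(core) - 1L))
            for (j in seq(i + 1L, length(core)))
                if (length(intersect(cols[[core[i]]], cols[[core[j]]])))
                    msg <- c(msg, paste0(core[i], " and ", core[j],
                                         " overlap"))
    }
    if (length(msg)) msg else TRUE
})

#' RelativeRateResult: Tajima one-degree-of-freedom relative-rate test
#'
#' Substitution counts on the two ingroup lineages and the chi-square
#' statistic \eqn{\chi^2 = (m_1 - m_2)^2 / (m_1 + m_2)} on 1 df.
#'
#' @slot m1,m2 substitution counts on lineages A and B.
#' @slot chi2 the test statistic.
#' @slot df degrees of freedom (always 1).
#' @slot p upper-tail chi-square p-value.
#' @slot nAlignable number of columns with no gap in any sequence
#'   (NA when the test was run from bare counts).
#' @seealso [tajimaRRT()]
#' @exportClass RelativeRateResult
setClass("RelativeRateResult",
         representation(m1 = "numeric", m2 = "numeric", chi2 = "numeric",
                        df = "numeric", p = "numeric",
                        nAlignable = "numeric"))

setValidity("RelativeRateResult", function(object) {
    msg <- character()
    if (object@m1 < 0 || object@m2 < 0)
        msg <- c(msg, "counts must be nonnegative")
    if (object@p < 0 || object@p > 1)
        msg <- c(msg, "p must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' MKResult: a McDonald-Kreitman 2x2 table with derived statistics
#'
#' Counts of nonsynonymous/synonymous fixed differences (Dn, Ds) and
#' polymorphisms within the focal species (Pn, Ps), the neutrality
#' index NI = (Pn/Ps)/(Dn/Ds), alpha = 1 - NI, and the exact-test
#' p-value. NI and alpha are `NA` when a denominator is zero.
#'
#' @slot Dn,Ds,Pn,Ps cell counts (integer after rounding policy).
#' @slot NI,alpha derived statistics, possibly `NA`.
#' @slot p two-sided exact-test p-value.
#' @slot focal name of the species whose polymorphism fills Pn/Ps.
#' @seealso [buildMKTable()], [mkExactTest()]
#' @exportClass MKResult
setClass("MKResult",
         representation(Dn = "numeric", Ds = "numeric", Pn = "numeric",
                        Ps = "numeric", NI = "numeric", alpha = "numeric",
                        p = "numeric", focal = "character"))

#' MeiosisParams: meiosis-II sex-chromosome transmission parameters
#'
#' Parameters of the meiosis-II nondisjunction model: per-spermatocyte
#' nondisjunction probabilities for X- and Y-bearing secondary
#' spermatocytes, viabilities of the five sperm classes, and
#' viabilities of the seven zygote karyotypes reachable from an
#' X-bearing euploid egg.
#'
#' @slot ndjX,ndjY probability that an X-bearing (Y-bearing)
#'   secondary spermatocyte nondisjoins at meiosis II.
#' @slot spermViability named numeric over
#'   `c("X","Y","XX","YY","nullo")`, each in \[0, 1\].
#' @slot zygoteViability named numeric over
#'   `c("XX","XY","XXX","XO","XYY")`, each in \[0, 1\].
#' @seealso [MeiosisParams()], [spermPool()], [progenyDistribution()]
#' @exportClass MeiosisParams
setClass("MeiosisParams",
         representation(ndjX = "numeric", ndjY = "numeric",
                        spermViability = "numeric",
                        zygoteViability = "numeric"))

.SPERM_CLASSES  <- c("X", "Y", "XX", "YY", "nullo")
.ZYGOTE_CLASSES <- c("XX", "XY", "XXX", "XO", "XYY")

setValidity("MeiosisParams", function(object) {
    msg <- character()
    pr <- c(object@ndjX, object@ndjY, object@spermViability,
            object@zygoteViability)
    if (any(!is.finite(pr)) || any(pr < 0) || any(pr > 1))
        msg <- c(msg, "all probabilities must lie in [0, 1]")
    if (!identical(names(object@spermViability), .SPERM_CLASSES))
        msg <- c(msg, "spermViability must cover X, Y, XX, YY, nullo")
    if (!identical(names(object@zygoteViability), .ZYGOTE_CLASSES))
        msg <- c(msg, "zygoteViability must cover XX, XY, XXX, XO, XYY")
    if (length(msg)) msg else TRUE
})

#' BroodExpectation: expected sperm pool and progeny composition
#'
#' Output of [progenyDistribution()]: the viability-renormalized sperm
#' class distribution, surviving zygote karyotype distribution, the
#' expected female fraction among progeny (X dose determines sex:
#' XX and XXX develop as females; XY, XO and XYY as males), and the
#' XO share among all surviving progeny.
#'
#' @slot spermFreq named distribution over sperm classes (sums to 1).
#' @slot zygoteFreq named distribution over surviving karyotypes.
#' @slot femaleFraction expected proportion of female progeny.
#' @slot xoMaleFraction XO share among all progeny.
#' @exportClass BroodExpectation
setClass("BroodExpectation",
         representation(spermFreq = "numeric", zygoteFreq = "numeric",
                        femaleFraction = "numeric",
                        xoMaleFraction = "numeric"))

setValidity("BroodExpectation", function(object) {
    msg <- character()
    if (abs(sum(object@spermFreq) - 1) > 1e-12)
        msg <- c(msg, "spermFreq must sum to 1")
    if (abs(sum(object@zygoteFreq) - 1) > 1e-12)
        msg <- c(msg, "zygoteFreq must sum to 1")
    if (length(msg)) msg else TRUE
})

#' ModelResult: tidy summary of one fitted brood model
#'
#' A uniform container for the mixed-model fits in the fertility
#' analyses: one row per tested term/contrast with estimate, standard
#' error, statistic (F or z), degrees of freedom where applicable and
#' p-value, plus the model formula, the estimation criterion and any
#' degradation notes (e.g. a random term dropped because its grouping
#' factor had a single level).
#'
#' @slot table `data.frame` with columns `term`, `estimate`, `se`,
#'   `statistic`, `stat_type`, `df1`, `df2`, `p_value`.
#' @slot formula character representation of the fitted model.
#' @slot method estimation criterion (e.g. `"REML (nlme::lme)"`).
#' @slot notes character vector of warnings/degradations.
#' @exportClass ModelResult
setClass("ModelResult",
         representation(table = "data.frame", formula = "character",
                        method = "character", notes = "character"))
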