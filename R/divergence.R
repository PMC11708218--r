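.AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K",
                  "M","F","P","S","T","W","Y","V","X","*","-")

#' Construct a ThreeTaxonAlignment
#'
#' @param a,b,o aligned amino-acid sequences (character strings or
#'   `AAString`s of equal length): ingroup lineage A, ingroup lineage
#'   B, and the outgroup.
#' @return a [ThreeTaxonAlignment-class].
#' @examples
#' aln <- ThreeTaxonAlignment("MKV", "MKL", "MKL")
#' classifyColumns(aln)
#' @export
ThreeTaxonAlignment <- function(a, b, o) {
    seqs <- Biostrings::AAStringSet(c(A = as.character(a),
                                      B = as.character(b),
                                      O = as.character(o)))
    chars <- strsplit(as.character(seqs), "")
    bad <- lapply(chars, function(x) which(!x %in% .AA_ALPHABET))
    if (any(lengths(bad) > 0)) {
        w <- which(lengths(bad) > 0)[1L]
        stop("illegal character in sequence ", names(seqs)[w],
             " at position ", bad[[w]][1L])
    }
    new("ThreeTaxonAlignment", seqs = seqs, states = character())
}

#' Read a ThreeTaxonAlignment from aligned FASTA
#'
#' The FASTA must contain exactly three records; roles are assigned
#' by matching record names (order-independent).
#'
#' @param path aligned FASTA file.
#' @param ingroupA,ingroupB,outgroup record names for the two ingroup
#'   lineages and the outgroup.
#' @return a [ThreeTaxonAlignment-class].
#' @export
readThreeTaxonAlignment <- function(path, ingroupA, ingroupB, outgroup) {
    seqs <- Biostrings::readAAStringSet(path)
    nm <- sub("\\s.*$", "", names(seqs))
    pick <- function(role, id) {
        i <- which(nm == id)
        if (length(i) != 1L)
            stop("record '", id, "' (", role, ") not found uniquely in ",
                 path)
        as.character(seqs[[i]])
    }
    ThreeTaxonAlignment(pick("ingroup A", ingroupA),
                        pick("ingroup B", ingroupB),
                        pick("outgroup", outgroup))
}

.alnMatrix <- function(x) {
    do.call(rbind, strsplit(as.character(x@seqs), ""))
}

#' @describeIn classifyColumns column-wise parsimony classification:
#'   a gap in any sequence makes the column `gapped`; all residues
#'   equal is `identical`; a residue unique to A (B = O) is a
#'   substitution on lineage A, and symmetrically for B and for the
#'   outgroup; three distinct residues admit two equally parsimonious
#'   placements and are `ambiguous`.
#' @export
setMethod("classifyColumns", "ThreeTaxonAlignment", function(x, ...) {
    m <- .alnMatrix(x)
    a <- m[1L, ]; b <- m[2L, ]; o <- m[3L, ]
    st <- rep("ambiguous", ncol(m))
    st[a == b & b == o] <- "identical"
    st[a != b & b == o] <- "subst_A"
    st[b != a & a == o] <- "subst_B"
    st[o != a & a == b] <- "subst_O"
    st[a == "-" | b == "-" | o == "-"] <- "gapped"
    x@states <- st
    validObject(x)
    x
})

#' @describeIn columnStates accessor; errors if [classifyColumns()]
#'   has not been run.
#' @export
setMethod("columnStates", "ThreeTaxonAlignment", function(x) {
    if (!length(x@states))
        stop("run classifyColumns() first")
    x@states
})

#' @describeIn alignableSites columns with no gap in any of the three
#'   sequences.
#' @export
setMethod("alignableSites", "ThreeTaxonAlignment", function(x) {
    m <- .alnMatrix(x)
    sum(colSums(m == "-") == 0L)
})

#' Tajima's one-degree-of-freedom relative-rate test
#'
#' Compares substitution counts on two lineages measured against a
#' shared outgroup: \eqn{\chi^2 = (m_1 - m_2)^2 / (m_1 + m_2)} on
#' 1 df. With `m1 = m2 = 0` the statistic is defined as 0 (p = 1).
#'
#' @param m1,m2 nonnegative substitution counts on lineages A and B.
#' @param nAlignable optional number of alignable sites, carried into
#'   the result for reporting divergence percentages.
#' @return a [RelativeRateResult-class].
#' @examples
#' tajimaRRT(80, 3)   # chi2 = 71.43, p < 1e-5
#' tajimaRRT(5, 5)    # chi2 = 0, p = 1
#' @export
tajimaRRT <- function(m1, m2, nAlignable = NA_real_) {
    if (m1 < 0 || m2 < 0) stop("counts must be nonnegative")
    tot <- m1 + m2
    chi2 <- if (tot == 0) 0 else (m1 - m2)^2 / tot
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    new("RelativeRateResult", m1 = m1, m2 = m2, chi2 = chi2, df = 1,
        p = p, nAlignable = nAlignable)
}

#' Construct a DomainMap
#'
#' @param ... named domain ranges, each a numeric vector
#'   `c(start, end)` (1-based inclusive alignment columns) or a
#'   two-column matrix of such ranges for split domains.
#' @return a [DomainMap-class].
#' @examples
#' DomainMap(kinase = c(1, 250), linker = c(251, 350),
#'           PBD = c(351, 576), PB1 = c(370, 450), PB2 = c(480, 570))
#' @export
DomainMap <- function(...) {
    args <- list(...)
    rl <- lapply(args, function(r) {
        r <- matrix(as.numeric(r), ncol = 2L, byrow = !is.matrix(r))
        IRanges::IRanges(start = r[, 1L], end = r[, 2L])
    })
    new("DomainMap", ranges = IRanges::IRangesList(rl))
}

#' Read a DomainMap from JSON
#'
#' The JSON maps domain names to `[start, end]` pairs (1-based
#' inclusive) or lists of pairs; keys starting with `_` are treated
#' as comments and ignored. A template with approximate canonical
#' Plk domain boundaries ships at
#' `system.file("extdata", "plk_domains.json", package = "polokit")`;
#' its ranges are conventions to be replaced with the user's own
#' curation, not measured constants.
#'
#' @param path JSON file.
#' @return a [DomainMap-class].
#' @export
readDomainMap <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    j <- j[!startsWith(names(j), "_")]
    do.call(DomainMap, lapply(j, function(r) {
        m <- matrix(as.numeric(unlist(r)), ncol = 2L, byrow = TRUE)
        m
    }))
}

.domainColumns <- function(map, domain, n) {
    r <- map@ranges[[domain]]
    if (any(IRanges::end(r) > n))
        stop("domain '", domain, "' extends past alignment column ", n)
    unique(unlist(mapply(seq.int, IRanges::start(r), IRanges::end(r),
                         SIMPLIFY = FALSE)))
}

#' @describeIn domainCounts restricts the classified columns to each
#'   domain's ranges and reruns the relative-rate test per domain; the
#'   row `whole` covers every column. Percent divergence columns give
#'   `100 * m / n_alignable` within the domain.
#' @export
setMethod("domainCounts", signature("ThreeTaxonAlignment", "DomainMap"),
          function(x, map, ...) {
    st <- columnStates(x)
    n <- length(st)
    doms <- c(list(whole = seq_len(n)),
              lapply(stats::setNames(names(map@ranges),
                                     names(map@ranges)),
                     .domainColumns, map = map, n = n))
    rows <- lapply(names(doms), function(d) {
        s <- st[doms[[d]]]
        m1 <- sum(s == "subst_A")
        m2 <- sum(s == "subst_B")
        na <- sum(s != "gapped")
        rr <- tajimaRRT(m1, m2, nAlignable = na)
        data.frame(domain = d, m1 = m1, m2 = m2, n_alignable = na,
                   pct_A = if (na > 0) 100 * m1 / na else NA_real_,
                   pct_B = if (na > 0) 100 * m2 / na else NA_real_,
                   chi2 = rr@chi2, df = 1, p = rr@p)
    })
    do.call(rbind, rows)
})

#' @describeIn findDeletions maximal runs of gap columns attributed
#'   by parsimony: gaps in exactly one ingroup while the outgroup has
#'   residues are deletions on that terminal lineage (`A` or `B`);
#'   gaps in both ingroups opposite an outgroup residue are placed on
#'   the internal branch (`shared`); gaps in the outgroup only are
#'   insertions in the ingroup ancestor, reported as `O`.
#' @export
setMethod("findDeletions", "ThreeTaxonAlignment", function(x) {
    m <- .alnMatrix(x)
    gA <- m[1L, ] == "-"; gB <- m[2L, ] == "-"; gO <- m[3L, ] == "-"
    lab <- rep("none", ncol(m))
    lab[gA & !gB & !gO] <- "A"
    lab[gB & !gA & !gO] <- "B"
    lab[gA & gB & !gO] <- "shared"
    lab[gO & !gA & !gB] <- "O"
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != "none"
    data.frame(lineage = r$values[keep], start = starts[keep],
               length = r$lengths[keep], row.names = NULL,
               stringsAsFactors = FALSE)
})

setMethod("show", "ThreeTaxonAlignment", function(object) {
    cat("ThreeTaxonAlignment:", Biostrings::width(object@seqs)[1L],
        "columns,", alignableSites(object), "alignable\n")
    if (length(object@states)) {
        tb <- table(factor(object@states, levels = .COLUMN_STATES))
        cat("  states:",
            paste(names(tb), as.integer(tb), sep = "=", collapse = " "),
            "\n")
    } else cat("  (columns not yet classified)\n")
})

setMethod("show", "RelativeRateResult", function(object) {
    cat(sprintf(
        "Relative-rate test: m1 = %d, m2 = %d, chi2(1) = %.2f, p = %.3g\n",
        object@m1, object@m2, object@chi2, object@p))
    if (!is.na(object@nAlignable))
        cat("  alignable sites:", object@nAlignable, "\n")
})
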