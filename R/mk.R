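#' SpeciesAlignment: in-frame coding sequences from many strains
#'
#' Aligned protein-coding sequences (alphabet A, C, G, T, N, -) of one
#' species, all of equal length divisible by three, in a common frame.
#'
#' @slot species species name.
#' @slot seqs a [Biostrings::DNAStringSet] of strain sequences.
#' @exportClass SpeciesAlignment
setClass("SpeciesAlignment",
         representation(species = "character", seqs = "DNAStringSet"))

setValidity("SpeciesAlignment", function(object) {
    msg <- character()
    w <- Biostrings::width(object@seqs)
    if (!length(w)) msg <- c(msg, "at least one strain required")
    else {
        if (length(unique(w)) != 1L)
            msg <- c(msg, "strain sequences must have equal length")
        if (w[1L] %% 3L != 0L)
            msg <- c(msg, "alignment length must be divisible by 3")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SpeciesAlignment
#'
#' @param species species name.
#' @param seqs character vector or `DNAStringSet` of aligned in-frame
#'   coding sequences.
#' @return a [SpeciesAlignment-class].
#' @export
SpeciesAlignment <- function(species, seqs) {
    new("SpeciesAlignment", species = species,
        seqs = Biostrings::DNAStringSet(seqs))
}

#' Read a SpeciesAlignment from aligned FASTA
#'
#' @param path FASTA of aligned in-frame coding sequences.
#' @param species species name (default: file name without extension).
#' @return a [SpeciesAlignment-class].
#' @export
readSpeciesAlignment <- function(path,
                                 species = sub("\\.[^.]*$", "",
                                               basename(path))) {
    SpeciesAlignment(species, Biostrings::readDNAStringSet(path))
}

setMethod("show", "SpeciesAlignment", function(object) {
    cat("SpeciesAlignment '", object@species, "': ",
        length(object@seqs), " strains x ",
        Biostrings::width(object@seqs)[1L], " nt (",
        Biostrings::width(object@seqs)[1L] %/% 3L, " codons)\n",
        sep = "")
})

.GENETIC_CODE <- Biostrings::GENETIC_CODE

.translateCodon <- function(codon) .GENETIC_CODE[[codon]]

.isStop <- function(codon) .GENETIC_CODE[[codon]] == "*"

# Per-position nonsynonymous weight for the change c1 -> c2, averaged
# over all minimal mutational pathways (orderings of the differing
# positions). Pathways passing through a stop codon are discarded
# unless every pathway does.
.pathwayEffects <- function(c1, c2) {
    s1 <- strsplit(c1, "")[[1L]]
    s2 <- strsplit(c2, "")[[1L]]
    diffs <- which(s1 != s2)
    k <- length(diffs)
    if (k == 0L) return(numeric(0))
    if (k == 1L) {
        w <- as.numeric(.translateCodon(c1) != .translateCodon(c2))
        return(stats::setNames(w, diffs))
    }
    perms <- .permutations(diffs)
    score <- function(ord) {
        cur <- s1
        eff <- stats::setNames(numeric(k), diffs)
        stopped <- FALSE
        for (p in ord) {
            nxt <- cur
            nxt[p] <- s2[p]
            from <- paste(cur, collapse = "")
            to <- paste(nxt, collapse = "")
            if (.isStop(to) && to != c2) stopped <- TRUE
            eff[as.character(p)] <-
                as.numeric(.translateCodon(from) != .translateCodon(to))
            cur <- nxt
        }
        list(eff = eff, stopped = stopped)
    }
    res <- lapply(perms, score)
    ok <- !vapply(res, `[[`, logical(1L), "stopped")
    if (!any(ok)) ok <- rep(TRUE, length(res))
    effs <- do.call(rbind, lapply(res[ok], `[[`, "eff"))
    colMeans(effs)
}

.permutations <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
        for (rest in .permutations(v[-i]))
            out <- c(out, list(c(v[i], rest)))
    out
}

.codonMatrix <- function(sp) {
    do.call(rbind, strsplit(as.character(sp@seqs), ""))
}

.majority <- function(x) names(which.max(table(x)))

#' Classify codon sites as polymorphic or fixed, synonymous or
#' nonsynonymous
#'
#' Walks the two species' alignments codon by codon. Codon columns
#' containing a gap or N in any strain of either species are excluded
#' entirely; codon columns where any strain carries an in-frame stop
#' are excluded with a warning. At each remaining nucleotide
#' position, alleles segregating within a species yield polymorphic
#' records for that species, and positions where both species are
#' monomorphic but for different alleles yield fixed records.
#'
#' Effects are scored against the genetic code in codon context:
#' polymorphic changes compare the two alleles with the remaining
#' positions at the species consensus; fixed differences at multi-hit
#' codons are averaged over all minimal mutational pathways between
#' the two species' consensus codons (Nei-Gojobori-style equal
#' weighting), yielding fractional per-record weights.
#'
#' @param sp1,sp2 [SpeciesAlignment-class] objects aligned to each
#'   other (equal length, common frame).
#' @return `data.frame` with one row per inferred change: `codon`
#'   (1-based index), `pos` (nucleotide position in the full
#'   alignment), `kind` (`polymorphic_sp1`, `polymorphic_sp2`,
#'   `fixed`), and fractional effect weights `w_nonsyn`, `w_syn`
#'   (summing to 1 per row). Attributes `n_excluded_gap` and
#'   `n_excluded_stop` count dropped codon columns; attribute
#'   `species` carries the two species names.
#' @export
classifyCodonSites <- function(sp1, sp2) {
    w1 <- Biostrings::width(sp1@seqs)[1L]
    w2 <- Biostrings::width(sp2@seqs)[1L]
    if (w1 != w2)
        stop("alignments differ in length (", w1, " vs ", w2, ")")
    m1 <- .codonMatrix(sp1)
    m2 <- .codonMatrix(sp2)
    nCodon <- w1 %/% 3L
    recs <- list()
    nGap <- 0L; nStop <- 0L
    for (cd in seq_len(nCodon)) {
        cols <- (3L * (cd - 1L) + 1L):(3L * cd)
        c1 <- m1[, cols, drop = FALSE]
        c2 <- m2[, cols, drop = FALSE]
        allnt <- c(c1, c2)
        if (any(allnt %in% c("-", "N"))) { nGap <- nGap + 1L; next }
        cods <- unique(c(apply(c1, 1L, paste, collapse = ""),
                         apply(c2, 1L, paste, collapse = "")))
        if (any(vapply(cods, .isStop, logical(1L)))) {
            nStop <- nStop + 1L
            next
        }
        cons1 <- apply(c1, 2L, .majority)
        cons2 <- apply(c2, 2L, .majority)

        # within-species polymorphism, consensus context
        for (sp in 1:2) {
            cm <- if (sp == 1L) c1 else c2
            cons <- if (sp == 1L) cons1 else cons2
            for (j in 1:3) {
                alleles <- unique(cm[, j])
                if (length(alleles) < 2L) next
                major <- .majority(cm[, j])
                for (alt in setdiff(alleles, major)) {
                    base <- cons
                    base[j] <- major
                    mut <- base
                    mut[j] <- alt
                    w <- as.numeric(
                        .translateCodon(paste(base, collapse = "")) !=
                        .translateCodon(paste(mut, collapse = "")))
                    recs[[length(recs) + 1L]] <- data.frame(
                        codon = cd, pos = cols[j],
                        kind = paste0("polymorphic_sp", sp),
                        w_nonsyn = w, w_syn = 1 - w)
                }
            }
        }

        # fixed differences: monomorphic in both, disjoint alleles
        fixedPos <- integer()
        for (j in 1:3) {
            a1 <- unique(c1[, j]); a2 <- unique(c2[, j])
            if (length(a1) == 1L && length(a2) == 1L && a1 != a2)
                fixedPos <- c(fixedPos, j)
        }
        if (length(fixedPos)) {
            from <- cons1
            to <- cons1
            to[fixedPos] <- cons2[fixedPos]
            wn <- .pathwayEffects(paste(from, collapse = ""),
                                  paste(to, collapse = ""))
            for (j in fixedPos) {
                w <- wn[[as.character(j)]]
                recs[[length(recs) + 1L]] <- data.frame(
                    codon = cd, pos = cols[j], kind = "fixed",
                    w_nonsyn = w, w_syn = 1 - w)
            }
        }
    }
    if (nStop > 0L)
        warning(nStop, " codon column(s) with internal stop excluded")
    out <- if (length(recs)) do.call(rbind, recs)
           else data.frame(codon = integer(), pos = integer(),
                           kind = character(), w_nonsyn = numeric(),
                           w_syn = numeric())
    attr(out, "n_excluded_gap") <- nGap
    attr(out, "n_excluded_stop") <- nStop
    attr(out, "species") <- c(sp1@species, sp2@species)
    out
}

#' Assemble the McDonald-Kreitman 2x2 table
#'
#' Sums fixed records into Dn/Ds and the focal species' polymorphic
#' records into Pn/Ps, applies the rounding policy to fractional
#' pathway counts, and computes NI = (Pn/Ps)/(Dn/Ds), alpha = 1 - NI
#' and the exact-test p-value ([mkExactTest()]; a G-test when
#' `rounding = "none"` leaves fractional cells).
#'
#' @param records output of [classifyCodonSites()].
#' @param focal which species' polymorphism fills Pn/Ps: `"sp1"`
#'   (default, the first alignment) or `"sp2"`.
#' @param rounding policy for fractional pathway counts: `"round"`
#'   (nearest integer, default), `"floor"`, or `"none"` (keep
#'   fractional; tested by G-test).
#' @return an [MKResult-class].
#' @examples
#' r <- data.frame(codon = 1:4, pos = 1:4,
#'                 kind = c("fixed", "fixed", "polymorphic_sp1",
#'                          "polymorphic_sp1"),
#'                 w_nonsyn = c(1, 0, 1, 0), w_syn = c(0, 1, 0, 1))
#' buildMKTable(r)
#' @export
buildMKTable <- function(records, focal = c("sp1", "sp2"),
                         rounding = c("round", "floor", "none")) {
    focal <- match.arg(focal)
    rounding <- match.arg(rounding)
    fx <- records$kind == "fixed"
    po <- records$kind == paste0("polymorphic_", focal)
    Dn <- sum(records$w_nonsyn[fx]); Ds <- sum(records$w_syn[fx])
    Pn <- sum(records$w_nonsyn[po]); Ps <- sum(records$w_syn[po])
    cells <- c(Dn = Dn, Ds = Ds, Pn = Pn, Ps = Ps)
    cells <- switch(rounding,
                    round = round(cells),
                    floor = floor(cells),
                    none = cells)
    NI <- if (cells["Ps"] > 0 && cells["Dn"] > 0 && cells["Ds"] > 0)
        unname((cells["Pn"] / cells["Ps"]) /
               (cells["Dn"] / cells["Ds"])) else NA_real_
    p <- if (rounding == "none" &&
             any(abs(cells - round(cells)) > 1e-9))
        .gTest2x2(cells["Dn"], cells["Ds"], cells["Pn"], cells["Ps"])
    else
        mkExactTest(cells["Dn"], cells["Ds"], cells["Pn"], cells["Ps"])
    spp <- attr(records, "species")
    new("MKResult", Dn = unname(cells["Dn"]), Ds = unname(cells["Ds"]),
        Pn = unname(cells["Pn"]), Ps = unname(cells["Ps"]),
        NI = NI, alpha = if (is.na(NI)) NA_real_ else 1 - NI, p = p,
        focal = if (!is.null(spp))
            spp[as.integer(substring(focal, 3L))] else focal)
}

#' Two-sided Fisher's exact test for the MK 2x2 table
#'
#' Direct hypergeometric enumeration with the table margins fixed:
#' the p-value is the sum of probabilities of all tables at most as
#' probable as the observed one (with the customary 1e-7 relative
#' slack on the comparison to absorb floating-point ties).
#'
#' @param Dn,Ds,Pn,Ps nonnegative integer cell counts; `Dn` may also
#'   be a 2x2 matrix `rbind(c(Dn, Pn), c(Ds, Ps))`.
#' @return two-sided p-value.
#' @examples
#' mkExactTest(1, 1, 1, 1)   # 1
#' mkExactTest(40, 20, 10, 20)
#' @export
mkExactTest <- function(Dn, Ds = NULL, Pn = NULL, Ps = NULL) {
    if (is.matrix(Dn)) {
        Ps <- Dn[2L, 2L]; Pn <- Dn[1L, 2L]
        Ds <- Dn[2L, 1L]; Dn <- Dn[1L, 1L]
    }
    cells <- c(Dn, Ds, Pn, Ps)
    if (any(cells < 0)) stop("cell counts must be nonnegative")
    if (any(abs(cells - round(cells)) > 1e-9))
        stop("non-integer cells: apply a rounding policy ",
             "(buildMKTable rounding = 'round' or 'floor') first")
    cells <- round(cells)
    Dn <- cells[1L]; Ds <- cells[2L]; Pn <- cells[3L]; Ps <- cells[4L]
    rowN <- Dn + Pn           # nonsynonymous total
    rowS <- Ds + Ps           # synonymous total
    colD <- Dn + Ds           # divergent total
    if (rowN + rowS == 0) return(1)
    k <- max(0L, colD - rowS):min(rowN, colD)
    d <- stats::dhyper(k, rowN, rowS, colD)
    dObs <- stats::dhyper(Dn, rowN, rowS, colD)
    min(1, sum(d[d <= dObs * (1 + 1e-7)]))
}

# Likelihood-ratio (G) test of independence for a 2x2 table; used
# when fractional pathway counts are kept.
.gTest2x2 <- function(Dn, Ds, Pn, Ps) {
    o <- c(Dn, Ds, Pn, Ps)
    n <- sum(o)
    if (n == 0) return(1)
    e <- c((Dn + Pn) * (Dn + Ds), (Ds + Ps) * (Dn + Ds),
           (Dn + Pn) * (Pn + Ps), (Ds + Ps) * (Pn + Ps)) / n
    keep <- o > 0
    g <- 2 * sum(o[keep] * log(o[keep] / e[keep]))
    stats::pchisq(max(0, g), df = 1, lower.tail = FALSE)
}

setMethod("show", "MKResult", function(object) {
    cat("McDonald-Kreitman table (polymorphism from ", object@focal,
        "):\n", sep = "")
    m <- matrix(c(object@Dn, object@Ds, object@Pn, object@Ps), 2L, 2L,
                dimnames = list(c("Nonsynon.", "Synon."),
                                c("Div", "Poly")))
    print(m)
    cat(sprintf("NI = %s, alpha = %s, p = %.3g\n",
                format(object@NI, digits = 3),
                format(object@alpha, digits = 3), object@p))
})
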