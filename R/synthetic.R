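.AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
           "P","S","T","W","Y","V")

# Run expr under a private RNG stream (seed + per-generator offset)
# and restore the caller's RNG state afterwards, so adding or
# reordering generator calls never perturbs other fixtures.
.withSeed <- function(seed, offset, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
    expr
}

#' Simulate a three-taxon protein alignment with planted
#' substitutions
#'
#' Draws a random ancestral protein and plants exactly `m1`, `m2` and
#' `mOut` single-residue substitutions on lineages A, B and the
#' outgroup at disjoint positions (no homoplasy), so that
#' [classifyColumns()] recovers the counts exactly. Optional in-frame
#' deletions gap the stated lineage ("A", "B", or "shared" for both
#' ingroups) while the outgroup keeps its residues; substitutions are
#' never planted in gapped columns.
#'
#' @param length alignment length in columns.
#' @param m1,m2,mOut substitution counts to plant on lineage A,
#'   lineage B, and the outgroup.
#' @param deletions optional list of `list(lineage, start, length)`.
#' @param seed integer seed; identical inputs give identical output.
#' @return a [ThreeTaxonAlignment-class].
#' @examples
#' aln <- simulateThreeTaxonProteins(567, m1 = 80, m2 = 3, seed = 1)
#' @export
simulateThreeTaxonProteins <- function(length, m1, m2, mOut = 0,
                                       deletions = NULL, seed = 1) {
    .withSeed(seed, 101L, {
        gapA <- rep(FALSE, length); gapB <- rep(FALSE, length)
        for (d in deletions) {
            idx <- d$start:(d$start + d$length - 1L)
            if (max(idx) > length)
                stop("deletion extends past alignment end")
            if (d$lineage %in% c("A", "shared")) gapA[idx] <- TRUE
            if (d$lineage %in% c("B", "shared")) gapB[idx] <- TRUE
        }
        free <- which(!gapA & !gapB)
        if (m1 + m2 + mOut > length(free))
            stop("requested substitutions exceed available columns")
        anc <- sample(.AA20, length, replace = TRUE)
        a <- anc; b <- anc; o <- anc
        pos <- sample(free, m1 + m2 + mOut)
        mutate <- function(res) vapply(res, function(r)
            sample(setdiff(.AA20, r), 1L), "")
        if (m1 > 0) { i <- pos[seq_len(m1)]; a[i] <- mutate(anc[i]) }
        if (m2 > 0) { i <- pos[m1 + seq_len(m2)]; b[i] <- mutate(anc[i]) }
        if (mOut > 0) { i <- pos[m1 + m2 + seq_len(mOut)]
                        o[i] <- mutate(anc[i]) }
        a[gapA] <- "-"; b[gapB] <- "-"
        ThreeTaxonAlignment(paste(a, collapse = ""),
                            paste(b, collapse = ""),
                            paste(o, collapse = ""))
    })
}

.codonNeighbors <- function(codon, effect) {
    s <- strsplit(codon, "")[[1L]]
    out <- character()
    for (j in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), s[j])) {
        v <- s; v[j] <- nt
        vc <- paste(v, collapse = "")
        if (.isStop(vc)) next
        syn <- .translateCodon(vc) == .translateCodon(codon)
        if ((effect == "syn") == syn) out <- c(out, vc)
    }
    out
}

#' Simulate two species' codon alignments with planted MK counts
#'
#' Draws a random stop-free ancestral coding sequence shared by both
#' species and plants, at disjoint codons, exactly `Pn`/`Ps`
#' nonsynonymous/synonymous polymorphisms within the focal (first)
#' species — the derived allele carried by a random nonempty proper
#' subset of its strains — and `Dn`/`Ds` fixed differences (the edit
#' applied to every strain of the second species). Each planted event
#' is a single-nucleotide edit chosen against the genetic code, so
#' [classifyCodonSites()] + [buildMKTable()] recover the four counts
#' exactly. With `multiHit = TRUE` one extra codon receives a
#' three-position fixed difference, producing fractional pathway
#' counts.
#'
#' @param nCodons number of codons.
#' @param Pn,Ps,Dn,Ds counts to plant.
#' @param nStrains1,nStrains2 strains per species (focal species
#'   first; `nStrains1 >= 3` so a proper subset is always possible).
#' @param multiHit plant one three-hit fixed-difference codon.
#' @param seed integer seed.
#' @return list of two [SpeciesAlignment-class] objects, `sp1`
#'   (focal) and `sp2`.
#' @export
simulateMKAlignments <- function(nCodons, Pn = 0, Ps = 0, Dn = 0,
                                 Ds = 0, nStrains1 = 30L,
                                 nStrains2 = 11L, multiHit = FALSE,
                                 seed = 1) {
    need <- Pn + Ps + Dn + Ds + as.integer(multiHit)
    if (need > nCodons)
        stop("planted events (", need, ") exceed codons (", nCodons, ")")
    .withSeed(seed, 202L, {
        codons <- names(.GENETIC_CODE)[.GENETIC_CODE != "*"]
        anc <- sample(codons, nCodons, replace = TRUE)
        s1 <- matrix(rep(anc, each = nStrains1), nStrains1, nCodons)
        s2 <- matrix(rep(anc, each = nStrains2), nStrains2, nCodons)
        slots <- sample(nCodons, need)
        take <- function(n) {
            if (n == 0L) return(integer(0))
            out <- slots[seq_len(n)]
            slots <<- slots[-seq_len(n)]
            out
        }
        plant <- function(cd, effect, where) {
            nb <- .codonNeighbors(anc[cd], effect)
            while (!length(nb)) {  # resample the ancestral codon
                anc[cd] <<- sample(codons, 1L)
                s1[, cd] <<- anc[cd]; s2[, cd] <<- anc[cd]
                nb <- .codonNeighbors(anc[cd], effect)
            }
            derived <- sample(nb, 1L)
            if (where == "poly") {
                k <- sample(seq_len(nStrains1 - 1L), 1L)
                rows <- sample(nStrains1, k)
                s1[rows, cd] <<- derived
            } else {
                s2[, cd] <<- derived
            }
        }
        for (cd in take(Pn)) plant(cd, "nonsyn", "poly")
        for (cd in take(Ps)) plant(cd, "syn", "poly")
        for (cd in take(Dn)) plant(cd, "nonsyn", "fixed")
        for (cd in take(Ds)) plant(cd, "syn", "fixed")
        if (multiHit) {
            cd <- take(1L)
            repeat {
                tgt <- sample(codons, 1L)
                if (sum(strsplit(anc[cd], "")[[1L]] !=
                        strsplit(tgt, "")[[1L]]) == 3L) break
            }
            s2[, cd] <- tgt
        }
        join <- function(m) apply(m, 1L, paste, collapse = "")
        list(sp1 = SpeciesAlignment("sp1", join(s1)),
             sp2 = SpeciesAlignment("sp2", join(s2)))
    })
}

#' Simulate a TissueExpression table with planted tau values
#'
#' Builds two-level log-scale profiles whose noiseless tau equals the
#' target exactly: the peak tissue gets `smax` and the remaining
#' tissues get `smax * (1 - tau)` (for a panel of N tissues the tau
#' formula then returns the target in closed form). Profiles are
#' converted back to the NRC scale (`10^S - 1`) and replicates
#' receive multiplicative lognormal noise, whose median is the
#' planted value, so replicate medians recover the target tau up to
#' noise. Background genes get random profiles.
#'
#' @param focal `data.frame` with columns `gene_id`, `sex`, `tau`,
#'   and optionally `peak_tissue` (default: first panel tissue) and
#'   `smax` (log10 peak expression, default 3). A (gene, sex)
#'   combination absent from `focal` is simulated as unexpressed.
#' @param tissues tissue panel (default: the six nonoverlapping
#'   samples: digestive, gonad, reproductive, thorax, abdomen, head).
#' @param sexes sexes to simulate.
#' @param nReplicates libraries per sex-tissue group.
#' @param nBackground number of random background genes.
#' @param noiseSd standard deviation of the replicate-level lognormal
#'   noise on the natural-log scale (0 = noiseless).
#' @param seed integer seed.
#' @return a [TissueExpression-class].
#' @examples
#' focal <- data.frame(gene_id = "dup", sex = "m", tau = 0.77)
#' te <- simulateExpressionTable(focal, seed = 2)
#' @export
simulateExpressionTable <- function(focal,
                                    tissues = c("digestive", "gonad",
                                                "reproductive",
                                                "thorax", "abdomen",
                                                "head"),
                                    sexes = c("f", "m"),
                                    nReplicates = 4L,
                                    nBackground = 0L,
                                    noiseSd = 0.1, seed = 1) {
    stopifnot(all(focal$tau >= 0), all(focal$tau <= 1))
    .withSeed(seed, 303L, {
        if (is.null(focal$peak_tissue)) focal$peak_tissue <- tissues[1L]
        if (is.null(focal$smax)) focal$smax <- 3
        genes <- unique(focal$gene_id)
        if (nBackground > 0L)
            genes <- c(genes, sprintf("bg%04d", seq_len(nBackground)))
        profile <- function(g, sx) {
            row <- focal[focal$gene_id == g & focal$sex == sx, ]
            if (nrow(row) == 1L) {
                s <- rep(row$smax * (1 - row$tau), length(tissues))
                s[match(row$peak_tissue, tissues)] <- row$smax
            } else if (g %in% focal$gene_id) {
                s <- rep(0, length(tissues))   # unexpressed in this sex
            } else {
                smax <- stats::runif(1, 1, 4)
                s <- rep(smax * (1 - stats::runif(1)), length(tissues))
                s[sample(length(tissues), 1L)] <- smax
            }
            10^s - 1
        }
        samples <- expand.grid(replicate = seq_len(nReplicates),
                               tissue = tissues, sex = sexes,
                               stringsAsFactors = FALSE)
        m <- matrix(0, length(genes), nrow(samples),
                    dimnames = list(genes, NULL))
        for (g in genes) for (sx in sexes) {
            nrc <- profile(g, sx)
            for (ti in seq_along(tissues)) {
                sel <- samples$sex == sx & samples$tissue == tissues[ti]
                noise <- if (noiseSd > 0)
                    exp(stats::rnorm(sum(sel), 0, noiseSd)) else 1
                m[g, sel] <- nrc[ti] * noise
            }
        }
        TissueExpression(m, sex = samples$sex, tissue = samples$tissue,
                         replicate = samples$replicate)
    })
}

#' Simulate per-male brood records
#'
#' Per male: a batch and strain are assigned at random; the expected
#' brood size is the transgene's mean scaled by lognormal batch and
#' strain random intercepts; the realized brood is negative-binomial
#' (`dispersion` = NB size; `Inf` gives Poisson); with probability
#' `1 - pSire` the male sires nothing (zero inflation); sexes are
#' allocated binomially with the transgene's female probability,
#' either given directly or derived from a meiosis-II parameter set
#' via [broodExpectation()].
#'
#' @param nMales males per transgene (recycled across transgenes).
#' @param transgenes transgene level names.
#' @param meanBrood expected brood size per transgene (recycled).
#' @param dispersion negative-binomial size parameter.
#' @param pFemale probability a progeny is female, per transgene
#'   (recycled); ignored for a transgene with an entry in `params`.
#' @param pSire probability a male sires any progeny (recycled).
#' @param params optional named list of [MeiosisParams-class], keyed
#'   by transgene, from which that transgene's `pFemale` is computed.
#' @param nBatches,nStrains numbers of batches and strains.
#' @param sdBatch,sdStrain SDs of the log-scale random intercepts.
#' @param seed integer seed.
#' @return `data.frame` of brood records (one vial per male).
#' @examples
#' rec <- simulateProgeny(50, transgenes = c("poloO", "dup1"),
#'                        pFemale = c(0.6, 0.5), seed = 3)
#' @export
simulateProgeny <- function(nMales, transgenes = "tg1", meanBrood = 40,
                            dispersion = 10, pFemale = 0.5, pSire = 1,
                            params = NULL, nBatches = 3L, nStrains = 2L,
                            sdBatch = 0, sdStrain = 0, seed = 1) {
    nT <- length(transgenes)
    nMales <- rep_len(nMales, nT)
    meanBrood <- rep_len(meanBrood, nT)
    pFemale <- rep_len(pFemale, nT)
    pSire <- rep_len(pSire, nT)
    .withSeed(seed, 404L, {
        bEff <- stats::rnorm(nBatches, 0, sdBatch)
        sEff <- stats::rnorm(nStrains, 0, sdStrain)
        out <- list()
        id <- 0L
        for (t in seq_len(nT)) {
            pf <- pFemale[t]
            if (!is.null(params) && transgenes[t] %in% names(params))
                pf <- broodExpectation(
                    params[[transgenes[t]]])@femaleFraction
            for (i in seq_len(nMales[t])) {
                id <- id + 1L
                b <- sample.int(nBatches, 1L)
                s <- sample.int(nStrains, 1L)
                mu <- meanBrood[t] * exp(bEff[b] + sEff[s])
                n <- if (stats::runif(1) > pSire[t]) 0L
                     else if (is.infinite(dispersion))
                         stats::rpois(1L, mu)
                     else stats::rnbinom(1L, size = dispersion, mu = mu)
                nf <- stats::rbinom(1L, n, pf)
                out[[id]] <- data.frame(
                    male_id = sprintf("m%05d", id),
                    transgene = transgenes[t],
                    strain = sprintf("strain%02d", s),
                    batch = sprintf("batch%02d", b),
                    n_female = nf, n_male = n - nf)
            }
        }
        validateProgenyRecords(do.call(rbind, out))
    })
}
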