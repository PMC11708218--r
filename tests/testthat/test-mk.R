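spAln <- function(name, ...) SpeciesAlignment(name, c(...))

test_that("single-codon fixed and polymorphic changes classify
          against the genetic code", {
    # Lys AAA vs Lys AAG: fixed synonymous
    r <- classifyCodonSites(spAln("p", "AAA", "AAA"),
                            spAln("q", "AAG", "AAG"))
    expect_equal(nrow(r), 1)
    expect_equal(r$kind, "fixed")
    expect_equal(r$w_syn, 1)
    # Lys/Arg segregating within species 1: polymorphic nonsynonymous
    r2 <- classifyCodonSites(spAln("p", "AAA", "AAA", "AGA"),
                             spAln("q", "AAA", "AAA"))
    expect_equal(nrow(r2), 1)
    expect_equal(r2$kind, "polymorphic_sp1")
    expect_equal(r2$w_nonsyn, 1)
})

test_that("multi-hit fixed codons average effects over minimal
          mutational pathways", {
    r <- classifyCodonSites(spAln("p", "TTT"), spAln("q", "GGG"))
    expect_equal(nrow(r), 3)
    expect_true(all(r$kind == "fixed"))
    expect_equal(r$w_nonsyn + r$w_syn, rep(1, 3))
    expect_equal(sum(r$w_nonsyn), pathwayOracle("TTT", "GGG"))
})

test_that("frame violations error and internal stops are excluded
          with a warning", {
    expect_error(classifyCodonSites(spAln("p", "AAAA"),
                                    spAln("q", "AAAA")),
                 "divisible by 3")
    expect_error(classifyCodonSites(spAln("p", "AAA"),
                                    spAln("q", "AAACCC")),
                 "differ in length")
    expect_warning(
        r <- classifyCodonSites(spAln("p", "TAAAAA"),
                                spAln("q", "TAAAAG")),
        "stop")
    expect_equal(nrow(r), 1)  # only the second codon survives
    expect_equal(r$codon, 2)
})

test_that("columns with gaps or N anywhere are excluded entirely", {
    r <- classifyCodonSites(spAln("p", "A-ACCC", "AAACCC"),
                            spAln("q", "AAACCG"))
    expect_equal(attr(r, "n_excluded_gap"), 1)
    expect_equal(r$codon, 2)
    expect_equal(r$kind, "fixed")
})

test_that("MK table arithmetic follows the definitions", {
    recs <- data.frame(
        codon = 1, pos = 1, kind = "fixed", w_nonsyn = 0, w_syn = 1)
    t1 <- buildMKTable(recs)
    expect_equal(c(t1@Dn, t1@Ds, t1@Pn, t1@Ps), c(0, 1, 0, 0))
    expect_true(is.na(t1@NI))

    recs2 <- rbind(
        data.frame(codon = 1:60, pos = 1:60, kind = "fixed",
                   w_nonsyn = rep(c(1, 0), c(40, 20)),
                   w_syn = rep(c(0, 1), c(40, 20))),
        data.frame(codon = 61:90, pos = 61:90,
                   kind = "polymorphic_sp1",
                   w_nonsyn = rep(c(1, 0), c(10, 20)),
                   w_syn = rep(c(0, 1), c(10, 20))))
    t2 <- buildMKTable(recs2)
    expect_equal(t2@NI, 0.25)
    expect_equal(t2@alpha, 0.75)
    expect_equal(t2@p, fisherEnumOracle(40, 20, 10, 20))

    empty <- classifyCodonSites(spAln("p", "AAA"), spAln("q", "AAA"))
    t0 <- buildMKTable(empty)
    expect_equal(c(t0@Dn, t0@Ds, t0@Pn, t0@Ps), c(0, 0, 0, 0))
    expect_true(is.na(t0@NI))
})

test_that("exact test matches enumeration, is transpose-invariant,
          and rejects fractional cells", {
    expect_equal(mkExactTest(1, 1, 1, 1), 1)
    set.seed(21)
    for (i in 1:50) {
        cells <- rpois(4, sample(c(2, 8, 25), 1))
        p <- mkExactTest(cells[1], cells[2], cells[3], cells[4])
        expect_equal(p, fisherEnumOracle(cells[1], cells[2],
                                         cells[3], cells[4]),
                     tolerance = 1e-12)
        expect_equal(p, fisher.test(rbind(cells[c(1, 3)],
                                          cells[c(2, 4)]))$p.value,
                     tolerance = 1e-9)
        # transposing rows and columns simultaneously: swap Ds <-> Pn
        expect_equal(mkExactTest(cells[1], cells[3], cells[2],
                                 cells[4]), p, tolerance = 1e-12)
    }
    expect_error(mkExactTest(1.5, 1, 1, 1), "rounding")
})

test_that("planted MK counts are recovered exactly from synthetic
          alignments", {
    sim <- simulateMKAlignments(300, Pn = 10, Ps = 20, Dn = 40,
                                Ds = 20, seed = 7)
    mk <- buildMKTable(classifyCodonSites(sim$sp1, sim$sp2))
    expect_equal(c(mk@Dn, mk@Ds, mk@Pn, mk@Ps), c(40, 20, 10, 20))
    expect_equal(mk@NI, 0.25)

    zero <- simulateMKAlignments(50, seed = 2)
    expect_equal(nrow(classifyCodonSites(zero$sp1, zero$sp2)), 0)
    expect_equal(length(unique(as.character(zero$sp1@seqs))), 1)
})

test_that("a monomorphic identical codon added to both species leaves
          the table unchanged", {
    sim <- simulateMKAlignments(100, Pn = 3, Ps = 4, Dn = 5, Ds = 6,
                                seed = 31)
    before <- buildMKTable(classifyCodonSites(sim$sp1, sim$sp2))
    pad <- function(sp) SpeciesAlignment(
        sp@species, paste0(as.character(sp@seqs), "GCT"))
    after <- buildMKTable(classifyCodonSites(pad(sim$sp1),
                                             pad(sim$sp2)))
    expect_equal(c(after@Dn, after@Ds, after@Pn, after@Ps),
                 c(before@Dn, before@Ds, before@Pn, before@Ps))
})

test_that("multi-hit planting produces fractional pathway counts that
          match the oracle", {
    sim <- simulateMKAlignments(80, Dn = 2, multiHit = TRUE, seed = 17)
    recs <- classifyCodonSites(sim$sp1, sim$sp2)
    multi <- recs[ave(recs$codon, recs$codon, FUN = length) == 3, ]
    expect_equal(nrow(multi), 3)
    c1 <- substr(as.character(sim$sp1@seqs[[1]]),
                 3 * (multi$codon[1] - 1) + 1, 3 * multi$codon[1])
    c2 <- substr(as.character(sim$sp2@seqs[[1]]),
                 3 * (multi$codon[1] - 1) + 1, 3 * multi$codon[1])
    expect_equal(sum(multi$w_nonsyn), pathwayOracle(c1, c2))
    # default rounding makes the table integer and testable
    mk <- buildMKTable(recs)
    expect_true(all(c(mk@Dn, mk@Ds) == round(c(mk@Dn, mk@Ds))))
})

test_that("focal-species switch moves which polymorphism is
          tabulated", {
    sim <- simulateMKAlignments(150, Pn = 6, Ps = 9, seed = 23)
    recs <- classifyCodonSites(sim$sp1, sim$sp2)
    t1 <- buildMKTable(recs, focal = "sp1")
    t2 <- buildMKTable(recs, focal = "sp2")
    expect_equal(c(t1@Pn, t1@Ps), c(6, 9))
    expect_equal(c(t2@Pn, t2@Ps), c(0, 0))
})
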