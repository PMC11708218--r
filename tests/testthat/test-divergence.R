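test_that("column classification follows three-taxon parsimony", {
    aln <- classifyColumns(ThreeTaxonAlignment("VKK", "LKR", "LKE"))
    expect_equal(columnStates(aln),
                 c("subst_A", "identical", "ambiguous"))
    aln2 <- classifyColumns(ThreeTaxonAlignment("MK-V", "MKLV", "MQLV"))
    expect_equal(columnStates(aln2),
                 c("identical", "subst_O", "gapped", "identical"))
})

test_that("malformed alignments are rejected with position info", {
    expect_error(ThreeTaxonAlignment("MK", "MKL", "MKL"), "equal length")
    expect_error(ThreeTaxonAlignment("MJ", "MK", "MK"),
                 "illegal character.*position 2")
})

test_that("column states partition the alignment exactly", {
    set.seed(7)
    for (i in 1:20) {
        aln <- simulateThreeTaxonProteins(
            120, m1 = sample(0:20, 1), m2 = sample(0:20, 1),
            mOut = sample(0:10, 1), seed = i)
        st <- columnStates(classifyColumns(aln))
        expect_length(st, 120)
        expect_true(all(st %in% c("identical", "subst_A", "subst_B",
                                  "subst_O", "ambiguous", "gapped")))
    }
})

test_that("classification agrees with the exhaustive small-parsimony
          oracle on random columns", {
    set.seed(11)
    a <- sample(AA20, 300, replace = TRUE)
    b <- sample(AA20, 300, replace = TRUE)
    o <- sample(AA20, 300, replace = TRUE)
    # bias toward informative patterns: copy some residues across taxa
    copy <- sample(300, 200)
    b[copy[1:100]] <- o[copy[1:100]]
    a[copy[101:200]] <- b[copy[101:200]]
    aln <- classifyColumns(ThreeTaxonAlignment(
        paste(a, collapse = ""), paste(b, collapse = ""),
        paste(o, collapse = "")))
    expected <- mapply(parsimonyOracle, a, b, o)
    expect_equal(unname(columnStates(aln)), unname(expected))
})

test_that("relative-rate statistic matches its closed form", {
    r <- tajimaRRT(80, 3)
    expect_equal(round(r@chi2, 2), 71.43)
    expect_equal(r@df, 1)
    expect_lt(r@p, 1e-5)
    r0 <- tajimaRRT(5, 5)
    expect_equal(r0@chi2, 0)
    expect_equal(r0@p, 1)
    expect_equal(tajimaRRT(7, 2)@chi2, 25 / 9)
    expect_equal(tajimaRRT(0, 0)@chi2, 0)
    expect_equal(tajimaRRT(0, 0)@p, 1)
    expect_error(tajimaRRT(-1, 2), "nonnegative")
})

test_that("swapping the ingroup lineages swaps counts but not chi2", {
    aln <- simulateThreeTaxonProteins(200, m1 = 15, m2 = 4, seed = 3)
    st <- columnStates(classifyColumns(aln))
    swapped <- classifyColumns(ThreeTaxonAlignment(
        as.character(aln@seqs[["B"]]), as.character(aln@seqs[["A"]]),
        as.character(aln@seqs[["O"]])))
    stS <- columnStates(swapped)
    expect_equal(sum(stS == "subst_A"), sum(st == "subst_B"))
    expect_equal(sum(stS == "subst_B"), sum(st == "subst_A"))
    expect_equal(tajimaRRT(sum(st == "subst_A"),
                           sum(st == "subst_B"))@chi2,
                 tajimaRRT(sum(stS == "subst_A"),
                           sum(stS == "subst_B"))@chi2)
})

test_that("planted per-lineage substitution counts are recovered
          exactly", {
    aln <- classifyColumns(
        simulateThreeTaxonProteins(567, m1 = 80, m2 = 3, seed = 1))
    st <- columnStates(aln)
    expect_equal(sum(st == "subst_A"), 80)
    expect_equal(sum(st == "subst_B"), 3)
    expect_equal(sum(st == "ambiguous"), 0)
})

test_that("domain counts respect the partition and localize planted
          substitutions", {
    aln <- classifyColumns(
        simulateThreeTaxonProteins(300, m1 = 25, m2 = 6, seed = 13))
    whole <- domainCounts(aln, DomainMap(all = c(1, 300)))
    expect_equal(whole[whole$domain == "all", "m1"],
                 whole[whole$domain == "whole", "m1"])
    halves <- domainCounts(aln, DomainMap(left = c(1, 150),
                                          right = c(151, 300)))
    expect_equal(sum(halves$m1[halves$domain %in% c("left", "right")]),
                 halves$m1[halves$domain == "whole"])
    expect_equal(sum(halves$n_alignable[
        halves$domain %in% c("left", "right")]),
        halves$n_alignable[halves$domain == "whole"])
    expect_error(domainCounts(aln, DomainMap(bad = c(200, 400))),
                 "past alignment")
})

test_that("substitutions planted inside one domain are counted only
          there", {
    anc <- paste(rep("A", 100), collapse = "")
    a <- strsplit(anc, "")[[1]]
    a[41:50] <- "V"       # all lineage-A changes inside the 'linker'
    aln <- classifyColumns(ThreeTaxonAlignment(
        paste(a, collapse = ""), anc, anc))
    dc <- domainCounts(aln, DomainMap(kinase = c(1, 40),
                                      linker = c(41, 60),
                                      PBD = c(61, 100)))
    expect_equal(dc$m1[dc$domain == "kinase"], 0)
    expect_equal(dc$m1[dc$domain == "linker"], 10)
    expect_equal(dc$m1[dc$domain == "PBD"], 0)
})

test_that("domain maps validate nesting and disjointness", {
    expect_error(DomainMap(kinase = c(1, 50), linker = c(40, 60)),
                 "overlap")
    expect_error(DomainMap(PBD = c(61, 100), PB1 = c(50, 70)),
                 "within PBD")
    expect_silent(DomainMap(kinase = c(1, 40), linker = c(41, 60),
                            PBD = c(61, 100), PB1 = c(65, 75),
                            PB2 = c(80, 95)))
})

test_that("deletions are assigned to the gapped lineage by
          parsimony", {
    d <- findDeletions(ThreeTaxonAlignment("MK--V", "MKLQV", "MKLQV"))
    expect_equal(d, data.frame(lineage = "A", start = 3L,
                               length = 2L))
    expect_equal(nrow(findDeletions(
        ThreeTaxonAlignment("MKV", "MKV", "MKV"))), 0)
    sh <- findDeletions(ThreeTaxonAlignment("M-KV", "M-KV", "MQKV"))
    expect_equal(sh$lineage, "shared")
    expect_equal(sh$length, 1L)
})

test_that("a nine-residue linker deletion with one shared column
          yields 567 alignable positions from 576", {
    aln <- simulateThreeTaxonProteins(
        576, m1 = 80, m2 = 3,
        deletions = list(list(lineage = "B", start = 301, length = 8),
                         list(lineage = "shared", start = 309,
                              length = 1)),
        seed = 1)
    expect_equal(alignableSites(aln), 567)
    d <- findDeletions(aln)
    expect_equal(sum(d$length[d$lineage %in% c("B", "shared")]), 9)
    expect_equal(sum(d$length[d$lineage == "shared"]), 1)
})

test_that("the shipped domain-map template parses, validates, and
          skips comment keys", {
    f <- system.file("extdata", "plk_domains.json",
                     package = "polokit")
    map <- readDomainMap(f)
    expect_setequal(names(map@ranges),
                    c("kinase", "linker", "PBD", "PB1", "PB2"))
    expect_true(validObject(map))
    # His518/Lys520 (outgroup protein coordinates) sit inside PB2
    pb2 <- map@ranges[["PB2"]]
    expect_true(all(c(518, 520) >= IRanges::start(pb2)[1] &
                    c(518, 520) <= IRanges::end(pb2)[1]))
})

test_that("FASTA round trip preserves roles", {
    aln <- simulateThreeTaxonProteins(50, 5, 2, seed = 4)
    f <- tempfile(fileext = ".faa")
    s <- aln@seqs
    names(s) <- c("dupA", "dupB", "outG")
    Biostrings::writeXStringSet(s, f)
    back <- readThreeTaxonAlignment(f, "dupA", "dupB", "outG")
    expect_equal(as.character(back@seqs), as.character(aln@seqs))
    expect_error(readThreeTaxonAlignment(f, "nope", "dupB", "outG"),
                 "nope")
})
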