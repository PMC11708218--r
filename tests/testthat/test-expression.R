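test_that("replicate medians collapse groups as sample medians", {
    nrc <- rbind(g1 = c(5, 5, 5, 5), g2 = c(1, 2, 3, 4),
                 g3 = c(0, 0, 0, 0))
    te <- TissueExpression(nrc, sex = rep("f", 4),
                           tissue = rep("gonad", 4), replicate = 1:4)
    med <- medianByGroup(te)
    expect_equal(med[, "f.gonad"], c(g1 = 5, g2 = 2.5, g3 = 0))
})

test_that("single-replicate groups return the table unchanged", {
    m <- matrix(runif(12), 3, 4,
                dimnames = list(paste0("g", 1:3), NULL))
    te <- TissueExpression(m, sex = rep("m", 4),
                           tissue = c("a", "b", "c", "d"),
                           replicate = rep(1L, 4))
    med <- medianByGroup(te)
    expect_equal(unname(med[, paste0("m.", c("a", "b", "c", "d"))]),
                 unname(m))
})

test_that("log transform maps powers of ten and rejects bad input", {
    expect_equal(logExpression(c(0, 9, 99)), c(0, 1, 2))
    expect_true(all(diff(logExpression(seq(0, 10, 0.5))) > 0))
    expect_error(logExpression(-1), "nonnegative")
    expect_error(logExpression(NaN), "finite")
})

test_that("tau hits its limit cases and the hand-computed example", {
    expect_identical(computeTau(c(2, 0, 0, 0, 0, 0)), 1)
    expect_identical(computeTau(rep(3, 6)), 0)
    # term-by-term: five tissues contribute 1 - log10(11)/log10(101)
    s <- logExpression(c(100, 10, 10, 10, 10, 10))
    expect_equal(computeTau(s), 5 * (1 - log10(11) / log10(101)) / 5)
    expect_equal(round(computeTau(s), 4), 0.4804)
})

test_that("tau guards degenerate profiles", {
    expect_error(computeTau(3), "at least two")
    expect_error(computeTau(c(1, -1, 2)), "nonnegative")
    expect_warning(t0 <- computeTau(rep(0, 6)), "undefined")
    expect_true(is.na(t0))
})

test_that("tau stays in [0,1], is permutation-invariant, and is
          monotone in non-maximal entries", {
    set.seed(42)
    for (i in 1:200) {
        n <- sample(2:8, 1)
        s <- runif(n, 0, 4)
        tau <- computeTau(s)
        expect_gte(tau, 0)
        expect_lte(tau, 1)
        expect_equal(computeTau(sample(s)), tau)
        # raising a non-maximal entry toward the max never raises tau
        j <- which.min(s)
        if (s[j] < max(s)) {
            s2 <- s
            s2[j] <- s[j] + runif(1) * (max(s) - s[j])
            expect_lte(computeTau(s2), tau + 1e-12)
        }
    }
})

test_that("mid-rank percentile handles ties and extremes", {
    expect_equal(expressionPercentile(3, c(1, 2, 3, 4, 5)), 50)
    expect_equal(expressionPercentile(-1, c(1, 2, 3)), 0)
    expect_equal(expressionPercentile(9, c(1, 2, 3)), 100)
    expect_equal(expressionPercentile(2, c(2, 2)), 50)
    expect_error(expressionPercentile(1, numeric(0)), "empty")
})

test_that("tauTable recovers planted tau (exactly when noiseless,
          within tolerance under replicate noise)", {
    focal <- data.frame(
        gene_id = c("anc", "anc", "dup", "dup"),
        sex = c("f", "m", "f", "m"),
        tau = c(0.59, 0.56, 1.00, 0.77),
        peak_tissue = "gonad", smax = c(3, 3, 0.8, 3.6))
    te0 <- simulateExpressionTable(focal, noiseSd = 0, seed = 5)
    tt0 <- tauTable(te0, tissues = c("digestive", "gonad",
                                     "reproductive", "thorax",
                                     "abdomen", "head"))
    got0 <- merge(focal[c("gene_id", "sex", "tau")], tt0,
                  by = c("gene_id", "sex"))
    expect_equal(got0$tau.y, got0$tau.x, tolerance = 1e-9)

    te <- simulateExpressionTable(focal, noiseSd = 0.1, seed = 5,
                                  nBackground = 20)
    tt <- tauTable(te, tissues = c("digestive", "gonad",
                                   "reproductive", "thorax",
                                   "abdomen", "head"))
    got <- merge(focal[c("gene_id", "sex", "tau")], tt,
                 by = c("gene_id", "sex"))
    expect_lt(max(abs(got$tau.y - got$tau.x)), 0.02)
})

test_that("tauTable names the missing sex-tissue group", {
    te <- TissueExpression(matrix(1, 1, 2, dimnames = list("g", NULL)),
                           sex = c("f", "f"),
                           tissue = c("gonad", "head"),
                           replicate = c(1L, 1L))
    expect_error(tauTable(te, tissues = c("gonad", "thorax")),
                 "f.thorax")
})

test_that("expression TSV round-trips through read/write", {
    focal <- data.frame(gene_id = "dup", sex = "m", tau = 0.77)
    te <- simulateExpressionTable(focal, nBackground = 5, seed = 9)
    f <- tempfile(fileext = ".tsv")
    writeExpressionTable(te, f)
    te2 <- readExpressionTable(f)
    expect_equal(SummarizedExperiment::assay(te2, "nrc"),
                 SummarizedExperiment::assay(te, "nrc"),
                 tolerance = 1e-12)
    expect_equal(
        as.data.frame(SummarizedExperiment::colData(te2)),
        as.data.frame(SummarizedExperiment::colData(te)))
})

test_that("invalid expression tables are rejected", {
    expect_error(TissueExpression(matrix(-1, 1, 1,
                                         dimnames = list("g", NULL)),
                                  "f", "gonad", 1L), "nonnegative")
    m <- matrix(1, 2, 1, dimnames = list(c("g", "g"), NULL))
    expect_error(TissueExpression(m, "f", "gonad", 1L), "unique")
})
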