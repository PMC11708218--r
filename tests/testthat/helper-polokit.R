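# Shared oracles, all independent of the implementation paths they
# check.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
          "P","S","T","W","Y","V")

# Exhaustive small parsimony for one gap-free column of a rooted
# three-taxon tree ((A,B),O): try all 20 ancestral states at the
# internal node, count changes on the three incident branches, and
# summarize the set of minimum-change assignments as a column state.
parsimonyOracle <- function(a, b, o) {
    changes <- vapply(AA20, function(n)
        (n != a) + (n != b) + (n != o), numeric(1))
    minc <- min(changes)
    if (minc == 0) return("identical")
    best <- AA20[changes == minc]
    # which branches change, for each minimal ancestral state
    patterns <- unique(vapply(best, function(n)
        paste0(as.integer(c(n != a, n != b, n != o)), collapse = ""),
        ""))
    if (length(patterns) > 1) return("ambiguous")
    switch(patterns,
           "100" = "subst_A", "010" = "subst_B", "001" = "subst_O",
           "ambiguous")
}

# Two-sided Fisher p for a 2x2 table by direct enumeration with
# log-choose arithmetic (no dhyper), same 1e-7 relative tie slack.
fisherEnumOracle <- function(Dn, Ds, Pn, Ps) {
    rowN <- Dn + Pn; rowS <- Ds + Ps; colD <- Dn + Ds
    if (rowN + rowS == 0) return(1)
    k <- max(0, colD - rowS):min(rowN, colD)
    logd <- lchoose(rowN, k) + lchoose(rowS, colD - k) -
        lchoose(rowN + rowS, colD)
    d <- exp(logd)
    dObs <- d[k == Dn]
    min(1, sum(d[d <= dObs * (1 + 1e-7)]))
}

# Per-pathway effect enumeration for a multi-nucleotide codon change:
# returns the average number of nonsynonymous steps over all
# orderings of the differing positions (stop-free paths preferred).
pathwayOracle <- function(c1, c2) {
    gc <- Biostrings::GENETIC_CODE
    s1 <- strsplit(c1, "")[[1]]; s2 <- strsplit(c2, "")[[1]]
    diffs <- which(s1 != s2)
    perms <- function(v) {
        if (length(v) <= 1) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (r in perms(v[-i])) out <- c(out, list(c(v[i], r)))
        out
    }
    res <- lapply(perms(diffs), function(ord) {
        cur <- s1; n <- 0; stopped <- FALSE
        for (p in ord) {
            nxt <- cur; nxt[p] <- s2[p]
            to <- paste(nxt, collapse = "")
            if (gc[[to]] == "*" && to != c2) stopped <- TRUE
            if (gc[[paste(cur, collapse = "")]] != gc[[to]]) n <- n + 1
            cur <- nxt
        }
        list(n = n, stopped = stopped)
    })
    ok <- !vapply(res, `[[`, logical(1), "stopped")
    if (!any(ok)) ok <- rep(TRUE, length(res))
    mean(vapply(res[ok], `[[`, numeric(1), "n"))
}

# Small helper: brood records with fully controlled cell values.
makeBroods <- function(nFemale, nMale, transgene = "tg1",
                       strain = "s1", batch = "b1") {
    n <- length(nFemale)
    validateProgenyRecords(data.frame(
        male_id = sprintf("m%03d", seq_len(n)),
        transgene = rep_len(transgene, n),
        strain = rep_len(strain, n),
        batch = rep_len(batch, n),
        n_female = nFemale, n_male = nMale))
}
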