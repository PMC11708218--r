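#' Read a per-male brood table from TSV
#'
#' Required columns: `male_id`, `transgene`, `strain`, `batch`,
#' `n_female`, `n_male`.
#'
#' @param path TSV file.
#' @return validated `data.frame` of brood records.
#' @export
readProgenyTable <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    validateProgenyRecords(df)
}

#' Validate brood records
#'
#' @param df `data.frame` with columns `male_id`, `transgene`,
#'   `strain`, `batch`, `n_female`, `n_male`.
#' @return the `data.frame`, with factors coerced.
#' @export
validateProgenyRecords <- function(df) {
    need <- c("male_id", "transgene", "strain", "batch",
              "n_female", "n_male")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("missing column(s): ", paste(miss, collapse = ", "))
    if (any(df$n_female < 0) || any(df$n_male < 0))
        stop("progeny counts must be nonnegative")
    if (anyDuplicated(df$male_id))
        stop("male_id must be unique (one vial per male)")
    for (f in c("transgene", "strain", "batch"))
        df[[f]] <- factor(df[[f]])
    df$male_id <- as.character(df$male_id)
    df
}

# Decide which random intercepts are estimable; single-level grouping
# factors degrade to fewer random terms with a recorded note.
.usableRandom <- function(df) {
    keep <- character()
    notes <- character()
    for (f in c("batch", "strain")) {
        if (nlevels(droplevels(df[[f]])) >= 2L) keep <- c(keep, f)
        else notes <- c(notes,
            paste0("random term '", f,
                   "' dropped: single level in the data"))
    }
    list(keep = keep, notes = notes)
}

.lmeRandom <- function(keep) {
    r <- lapply(keep, function(f) stats::as.formula("~1"))
    names(r) <- keep
    r
}

# REML fit with an optimizer fallback: degenerate but valid inputs
# (e.g. exactly balanced broods, zero variance components) can make
# nlminb report false convergence where optim succeeds.
.tryLme <- function(fixed, data, random) {
    tryCatch(
        nlme::lme(fixed, data = data, random = random,
                  method = "REML"),
        error = function(e)
            nlme::lme(fixed, data = data, random = random,
                      method = "REML",
                      control = nlme::lmeControl(opt = "optim")))
}

.tidyFixed <- function(tab, statType, pattern = NULL) {
    terms <- rownames(tab)
    if (!is.null(pattern)) {
        sel <- grepl(pattern, terms)
        tab <- tab[sel, , drop = FALSE]
        terms <- terms[sel]
    }
    hasDF <- "DF" %in% colnames(tab)
    data.frame(term = terms,
               estimate = tab[, 1L],
               se = tab[, 2L],
               statistic = tab[, if (hasDF) 4L else 3L],
               stat_type = statType,
               df1 = NA_real_,
               df2 = if (hasDF) tab[, "DF"] else NA_real_,
               p_value = tab[, ncol(tab)],
               row.names = NULL)
}

#' Mixed-effects model for progeny counts
#'
#' Linear mixed model of the number of progeny per vial with
#' transgene as fixed effect and batch and strain as random
#' intercepts (fit by REML through `nlme::lme`, treatment coding
#' relative to the first transgene level). Vials with zero progeny
#' are included: a count of zero is informative here. Grouping
#' factors with a single observed level are dropped from the random
#' part with a note; with no usable grouping factor the model
#' degrades to ordinary least squares.
#'
#' @param records brood records ([validateProgenyRecords()]).
#' @param response which count to model: `"total"` (default),
#'   `"female"`, or `"male"`.
#' @return a [ModelResult-class]: one row per transgene contrast
#'   (Wald t tests) and one `transgene (overall)` F row.
#' @export
fitCountModel <- function(records,
                          response = c("total", "female", "male")) {
    response <- match.arg(response)
    df <- validateProgenyRecords(records)
    if (nlevels(df$transgene) < 2L)
        stop("at least two transgene levels required")
    df$.y <- switch(response,
                    total = df$n_female + df$n_male,
                    female = df$n_female,
                    male = df$n_male)
    ur <- .usableRandom(df)
    if (length(ur$keep)) {
        fit <- .tryLme(.y ~ transgene, df, .lmeRandom(ur$keep))
        tab <- summary(fit)$tTable
        out <- .tidyFixed(tab, "t", "^transgene")
        an <- stats::anova(fit)
        out <- rbind(out, data.frame(
            term = "transgene (overall)", estimate = NA_real_,
            se = NA_real_, statistic = an["transgene", "F-value"],
            stat_type = "F", df1 = an["transgene", "numDF"],
            df2 = an["transgene", "denDF"],
            p_value = an["transgene", "p-value"]))
        method <- paste0("REML (nlme::lme), random intercepts: ",
                         paste(ur$keep, collapse = " + "))
    } else {
        fit <- stats::lm(.y ~ transgene, data = df)
        sm <- summary(fit)$coefficients
        out <- .tidyFixed(sm, "t", "^transgene")
        an <- stats::anova(fit)
        out <- rbind(out, data.frame(
            term = "transgene (overall)", estimate = NA_real_,
            se = NA_real_, statistic = an["transgene", "F value"],
            stat_type = "F", df1 = an["transgene", "Df"],
            df2 = an["Residuals", "Df"],
            p_value = an["transgene", "Pr(>F)"]))
        method <- "OLS (stats::lm); all random terms dropped"
    }
    new("ModelResult", table = out,
        formula = paste0(response, "_count ~ transgene, random = ",
                         if (length(ur$keep))
                             paste("~1 |", ur$keep, collapse = ", ")
                         else "(none)"),
        method = method, notes = ur$notes)
}

#' Mixed-effects logistic model for whether a male sired progeny
#'
#' Binomial GLMM (Laplace approximation, `lme4::glmer`) of the 0/1
#' siring outcome with transgene as fixed effect and batch and strain
#' as random intercepts; per-contrast Wald z statistics (treatment
#' coding). Complete or quasi-complete separation is flagged in the
#' notes (detected as an extreme fitted log-odds contrast).
#'
#' @param records brood records.
#' @param response count the male as siring if this response is
#'   positive: `"any"` progeny (default), `"female"`, or `"male"`.
#' @return a [ModelResult-class].
#' @export
fitSiredModel <- function(records, response = c("any", "female", "male")) {
    response <- match.arg(response)
    df <- validateProgenyRecords(records)
    df$.sired <- as.integer(switch(response,
                                   any = df$n_female + df$n_male,
                                   female = df$n_female,
                                   male = df$n_male) > 0)
    if (length(unique(df$.sired)) < 2L)
        stop("no variation in siring outcome: all males ",
             if (df$.sired[1L] == 1L) "sired" else "failed to sire")
    ur <- .usableRandom(df)
    notes <- ur$notes
    if (length(ur$keep)) {
        rterms <- paste0("(1 | ", ur$keep, ")", collapse = " + ")
        form <- stats::as.formula(paste(".sired ~ transgene +", rterms))
        fit <- suppressMessages(
            lme4::glmer(form, data = df, family = stats::binomial))
        tab <- summary(fit)$coefficients
        method <- "Laplace ML (lme4::glmer), binomial"
    } else {
        fit <- stats::glm(.sired ~ transgene, data = df,
                          family = stats::binomial)
        tab <- summary(fit)$coefficients
        method <- "ML (stats::glm), binomial; all random terms dropped"
    }
    out <- .tidyFixed(tab, "z", "^transgene")
    if (any(abs(out$estimate) > 10))
        notes <- c(notes, paste0(
            "possible complete separation (|log-odds| > 10); ",
            "consider pooling levels or penalized likelihood"))
    new("ModelResult", table = out,
        formula = paste0("sired_", response, " ~ transgene + ",
                         if (length(ur$keep))
                             paste0("(1|", ur$keep, ")", collapse = " + ")
                         else "(no random terms)"),
        method = method, notes = notes)
}

#' Mixed-effects sex-ratio model for one transgene
#'
#' Reshapes each vial into two rows (female count, male count) and
#' fits a linear mixed model with progeny sex and vial as fixed
#' effects and batch and strain as random intercepts
#' (REML, `nlme::lme`). The progeny-sex term's F test is the
#' headline result: a significant positive `sexfemale` estimate
#' means more female than male progeny. Vials with zero progeny are
#' excluded (their sex ratio is undefined); the number excluded is
#' recorded in the notes.
#'
#' @param records brood records for a single transgene (if several
#'   levels are present, pass `transgene` to select one).
#' @param transgene optional transgene level to subset to.
#' @return a [ModelResult-class] whose first row is the progeny-sex
#'   F test (`df1`, `df2` as in the containment ANOVA), followed by
#'   the `sexfemale` contrast.
#' @export
sexRatioModel <- function(records, transgene = NULL) {
    df <- validateProgenyRecords(records)
    if (!is.null(transgene))
        df <- droplevels(df[df$transgene == transgene, , drop = FALSE])
    if (nlevels(df$transgene) > 1L)
        stop("sex-ratio model is fit per transgene; subset first or ",
             "pass transgene=")
    zero <- df$n_female + df$n_male == 0
    notes <- character()
    if (any(zero)) {
        notes <- c(notes, paste0(sum(zero),
            " zero-progeny vial(s) excluded (sex ratio undefined)"))
        df <- df[!zero, , drop = FALSE]
    }
    if (!nrow(df)) stop("no vials with progeny")
    long <- rbind(
        data.frame(df[c("male_id", "strain", "batch")], sex = "female",
                   count = df$n_female),
        data.frame(df[c("male_id", "strain", "batch")], sex = "male",
                   count = df$n_male))
    long$sex <- stats::relevel(factor(long$sex), ref = "male")
    long$vial <- factor(long$male_id)
    ur <- .usableRandom(long)
    notes <- c(notes, ur$notes)
    if (length(ur$keep)) {
        fit <- .tryLme(count ~ sex + vial, long, .lmeRandom(ur$keep))
        an <- stats::anova(fit)
        tab <- summary(fit)$tTable
        method <- paste0("REML (nlme::lme), random intercepts: ",
                         paste(ur$keep, collapse = " + "))
        fRow <- data.frame(
            term = "sex (F test)", estimate = NA_real_, se = NA_real_,
            statistic = an["sex", "F-value"], stat_type = "F",
            df1 = an["sex", "numDF"], df2 = an["sex", "denDF"],
            p_value = an["sex", "p-value"])
    } else {
        fit <- stats::lm(count ~ sex + vial, data = long)
        an <- stats::anova(fit)
        tab <- summary(fit)$coefficients
        method <- "OLS (stats::lm); all random terms dropped"
        fRow <- data.frame(
            term = "sex (F test)", estimate = NA_real_, se = NA_real_,
            statistic = an["sex", "F value"], stat_type = "F",
            df1 = an["sex", "Df"], df2 = an["Residuals", "Df"],
            p_value = an["sex", "Pr(>F)"])
    }
    out <- rbind(fRow, .tidyFixed(tab, "t", "^sexfemale$"))
    new("ModelResult", table = out,
        formula = paste0("count ~ sex + vial, random = ",
                         if (length(ur$keep))
                             paste("~1 |", ur$keep, collapse = ", ")
                         else "(none)"),
        method = method, notes = notes)
}

#' Exact binomial test of a brood's sex ratio
#'
#' Per-male cross-check for the mixed sex-ratio model: two-sided
#' exact binomial test of the female count against p = 0.5.
#'
#' @param nFemale,nMale progeny counts (total must be >= 1).
#' @return list with `estimate` (female fraction) and `p`.
#' @examples
#' binomialSexRatio(10, 10)  # p = 1
#' binomialSexRatio(30, 10)
#' @export
binomialSexRatio <- function(nFemale, nMale) {
    n <- nFemale + nMale
    if (n < 1) stop("at least one progeny required")
    bt <- stats::binom.test(nFemale, n, p = 0.5,
                            alternative = "two.sided")
    list(estimate = nFemale / n, p = bt$p.value)
}

setMethod("show", "ModelResult", function(object) {
    cat("Model:", object@formula, "\n")
    cat("Fit:  ", object@method, "\n")
    if (length(object@notes))
        cat("Notes:", paste(object@notes, collapse = "; "), "\n")
    print(object@table, digits = 4)
})

#' Extract the tidy coefficient table from a ModelResult
#'
#' @param x a [ModelResult-class].
#' @return `data.frame` of terms, estimates and tests.
#' @export
modelTable <- function(x) {
    stopifnot(is(x, "ModelResult"))
    x@table
}
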