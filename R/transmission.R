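#' Construct MeiosisParams
#'
#' Parameters of the meiosis-II sex-chromosome transmission model.
#' Secondary spermatocytes are half X-bearing, half Y-bearing. A
#' normal equational division yields two single-chromatid sperm; a
#' nondisjoined division yields one disomic sperm (XX or YY, sister
#' chromatids co-inherited) and one nullo-XY sperm. Fertilization by
#' a euploid X-bearing egg maps sperm classes to zygote karyotypes
#' X -> XX, Y -> XY, XX -> XXX, YY -> XYY, nullo -> XO.
#'
#' Default viabilities encode the standard Drosophila expectations:
#' all sperm classes mature (set `spermViability["YY"] = 0` for a
#' Paris-drive-like regime where YY sperm fail to mature); XXX
#' zygotes have dramatically reduced viability (default 0.05 — low
#' but nonzero, configurable as no measured value exists); XO males
#' are viable (sterile, which affects interpretation, not counts).
#'
#' @param ndjX,ndjY meiosis-II nondisjunction probability for X- and
#'   Y-bearing secondary spermatocytes.
#' @param spermViability named numeric over
#'   `c("X","Y","XX","YY","nullo")`.
#' @param zygoteViability named numeric over
#'   `c("XX","XY","XXX","XO","XYY")`.
#' @return a [MeiosisParams-class].
#' @examples
#' MeiosisParams(ndjX = 0, ndjY = 0.2)
#' @export
MeiosisParams <- function(ndjX = 0, ndjY = 0,
                          spermViability = c(X = 1, Y = 1, XX = 1,
                                             YY = 1, nullo = 1),
                          zygoteViability = c(XX = 1, XY = 1,
                                              XXX = 0.05, XO = 1,
                                              XYY = 1)) {
    new("MeiosisParams", ndjX = ndjX, ndjY = ndjY,
        spermViability = spermViability[.SPERM_CLASSES],
        zygoteViability = zygoteViability[.ZYGOTE_CLASSES])
}

#' Read MeiosisParams from a JSON file
#'
#' Keys: `ndj_X`, `ndj_Y`, `sperm_viability` (object over X, Y, XX,
#' YY, nullo), `zygote_viability` (object over XX, XY, XXX, XO, XYY).
#' Missing keys take the constructor defaults.
#'
#' @param path JSON file.
#' @return a [MeiosisParams-class].
#' @export
readMeiosisParams <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    args <- list()
    if (!is.null(j$ndj_X)) args$ndjX <- j$ndj_X
    if (!is.null(j$ndj_Y)) args$ndjY <- j$ndj_Y
    if (!is.null(j$sperm_viability))
        args$spermViability <- unlist(j$sperm_viability)
    if (!is.null(j$zygote_viability))
        args$zygoteViability <- unlist(j$zygote_viability)
    do.call(MeiosisParams, args)
}

#' @describeIn spermPool enumerates the division outcome tree: an
#'   X-bearing spermatocyte contributes sperm mass
#'   `(1 - ndjX)` to class X and `ndjX / 2` each to XX and nullo
#'   (and symmetrically for Y), then weights by sperm viability and
#'   renormalizes.
#' @export
setMethod("spermPool", "MeiosisParams", function(params) {
    raw <- c(X = 0.5 * (1 - params@ndjX),
             Y = 0.5 * (1 - params@ndjY),
             XX = 0.25 * params@ndjX,
             YY = 0.25 * params@ndjY,
             nullo = 0.25 * params@ndjX + 0.25 * params@ndjY)
    w <- raw * params@spermViability[names(raw)]
    tot <- sum(w)
    if (tot <= 0)
        stop("all sperm classes inviable: empty pool")
    w / tot
})

.SPERM_TO_ZYGOTE <- c(X = "XX", Y = "XY", XX = "XXX", YY = "XYY",
                      nullo = "XO")
.FEMALE_KARYOTYPES <- c("XX", "XXX")

#' @describeIn progenyDistribution fertilizes each sperm class with a
#'   euploid X-bearing egg, weights the resulting karyotypes by
#'   zygote viability, renormalizes, and reads off the female
#'   fraction (X dose: XX and XXX female) and the XO share.
#' @export
setMethod("progenyDistribution", signature("numeric", "MeiosisParams"),
          function(pool, params) {
    if (abs(sum(pool) - 1) > 1e-9)
        stop("sperm pool must be a distribution summing to 1")
    z <- stats::setNames(numeric(length(.ZYGOTE_CLASSES)),
                         .ZYGOTE_CLASSES)
    for (cl in names(pool))
        z[.SPERM_TO_ZYGOTE[[cl]]] <- z[.SPERM_TO_ZYGOTE[[cl]]] +
            pool[[cl]]
    z <- z * params@zygoteViability[names(z)]
    tot <- sum(z)
    if (tot <= 0) stop("no surviving zygote class")
    z <- z / tot
    new("BroodExpectation", spermFreq = pool, zygoteFreq = z,
        femaleFraction = unname(sum(z[.FEMALE_KARYOTYPES])),
        xoMaleFraction = unname(z[["XO"]]))
})

#' Expected brood composition directly from parameters
#'
#' Convenience wrapper: `progenyDistribution(spermPool(params),
#' params)`.
#'
#' @param params a [MeiosisParams-class].
#' @return a [BroodExpectation-class].
#' @examples
#' broodExpectation(MeiosisParams())@femaleFraction  # 0.5
#' @export
broodExpectation <- function(params)
    progenyDistribution(spermPool(params), params)

#' Estimate nondisjunction rates from observed brood composition
#'
#' Inverts the transmission model: finds the (ndjX, ndjY) pair whose
#' predicted female fraction and XO-male fraction best match the
#' observations (least squares), by a coarse grid search followed by
#' local refinement. The viability maps are held fixed at the values
#' in `params`. When the residual surface is flat near the optimum
#' (many parameter pairs fit equally well), the configuration is
#' flagged non-identifiable.
#'
#' @param femaleFraction,xoMaleFraction observed values in \[0, 1\].
#' @param params a [MeiosisParams-class] supplying the viability maps
#'   (its ndj slots are ignored).
#' @param gridN grid resolution per axis for the initial search.
#' @return list with `ndjX`, `ndjY`, `residual` (root-mean-square
#'   misfit), and `identifiable` (logical).
#' @export
fitNdj <- function(femaleFraction, xoMaleFraction, params = MeiosisParams(),
                   gridN = 41L) {
    stopifnot(femaleFraction >= 0, femaleFraction <= 1,
              xoMaleFraction >= 0, xoMaleFraction <= 1)
    obj <- function(th) {
        p <- MeiosisParams(ndjX = th[1L], ndjY = th[2L],
                           spermViability = params@spermViability,
                           zygoteViability = params@zygoteViability)
        be <- tryCatch(broodExpectation(p), error = function(e) NULL)
        if (is.null(be)) return(Inf)
        (be@femaleFraction - femaleFraction)^2 +
            (be@xoMaleFraction - xoMaleFraction)^2
    }
    g <- seq(0, 1, length.out = gridN)
    grid <- expand.grid(x = g, y = g)
    vals <- apply(grid, 1L, obj)
    best <- which.min(vals)
    fit <- stats::optim(c(grid$x[best], grid$y[best]), obj,
                        method = "L-BFGS-B", lower = 0, upper = 1)
    resid <- sqrt(fit$value / 2)
    # flat surface: many grid points essentially as good as the optimum
    nearOpt <- sum(vals <= fit$value + 1e-8)
    list(ndjX = fit$par[1L], ndjY = fit$par[2L], residual = resid,
         identifiable = nearOpt <= max(3L, gridN %/% 10L))
}

setMethod("show", "MeiosisParams", function(object) {
    cat(sprintf("MeiosisParams: ndjX = %.3g, ndjY = %.3g\n",
                object@ndjX, object@ndjY))
    cat("  sperm viability: ",
        paste(names(object@spermViability), object@spermViability,
              sep = "=", collapse = " "), "\n")
    cat("  zygote viability:",
        paste(names(object@zygoteViability), object@zygoteViability,
              sep = "=", collapse = " "), "\n")
})

setMethod("show", "BroodExpectation", function(object) {
    cat("BroodExpectation\n  sperm: ",
        paste(names(object@spermFreq),
              sprintf("%.4f", object@spermFreq),
              sep = "=", collapse = " "), "\n")
    cat("  zygotes:",
        paste(names(object@zygoteFreq),
              sprintf("%.4f", object@zygoteFreq),
              sep = "=", collapse = " "), "\n")
    cat(sprintf("  female fraction = %.4f, XO fraction = %.4f\n",
                object@femaleFraction, object@xoMaleFraction))
})
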