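#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' RateSchedule: age-indexed population hazards
#'
#' Holds age-specific disease incidence and competing (other-cause) mortality
#' hazards on a yearly age grid, both expressed as per-person-year
#' probabilities. Registry rates supplied per 100,000 person-years are divided
#' by 100,000 on import (\code{\link{readRateSchedule}}); no exponential
#' conversion is applied because registry rates are small.
#'
#' @slot ages integer vector, strictly increasing (years).
#' @slot incidence numeric, disease hazard per person-year, in [0, 1).
#' @slot mortality numeric, competing mortality per person-year, in [0, 1).
#' @export
setClass("RateSchedule",
    slots = c(ages = "integer", incidence = "numeric", mortality = "numeric"))

setValidity("RateSchedule", function(object) {
    msg <- NULL
    n <- length(object@ages)
    if (length(object@incidence) != n || length(object@mortality) != n)
        msg <- c(msg, "ages, incidence and mortality must have equal length")
    if (n > 1L && any(diff(object@ages) <= 0L))
        msg <- c(msg, "ages must be strictly increasing")
    if (any(object@incidence < 0 | object@incidence >= 1, na.rm = TRUE))
        msg <- c(msg, "incidence hazards must lie in [0, 1)")
    if (any(object@mortality < 0 | object@mortality >= 1, na.rm = TRUE))
        msg <- c(msg, "mortality hazards must lie in [0, 1)")
    if (is.null(msg)) TRUE else msg
})

#' Construct a RateSchedule
#'
#' @param ages integer vector of ages (years), strictly increasing.
#' @param incidence per-person-year disease hazard at each age.
#' @param mortality per-person-year competing mortality hazard at each age.
#' @return A \linkS4class{RateSchedule}.
#' @examples
#' RateSchedule(40:45, rep(0.001, 6), rep(0.005, 6))
#' @export
RateSchedule <- function(ages, incidence, mortality) {
    new("RateSchedule", ages = as.integer(ages),
        incidence = as.numeric(incidence), mortality = as.numeric(mortality))
}

#' ORTable: per-category odds ratios from a logistic fit
#'
#' Association output of \code{\link{fitJointModel}} /
#' \code{\link{fitMarginalModels}}: per-category odds ratios with Wald 95\%
#' confidence intervals and p-values, cell counts, the category log-OR
#' coefficient vector and its covariance (consumed by
#' \code{\link{monteCarloRisk}}).
#'
#' @slot outcome character, the case definition contrasted against controls.
#' @slot reference character, the reference category (OR fixed at 1).
#' @slot stats data.frame with columns category, nCases, nControls, or,
#'   ciLo, ciHi, p, flag.
#' @slot beta named numeric, log-OR per estimable non-reference category.
#' @slot sigma covariance matrix of \code{beta} (symmetric PSD).
#' @export
setClass("ORTable",
    slots = c(outcome = "character", reference = "character",
              stats = "data.frame", beta = "numeric", sigma = "matrix"))

setValidity("ORTable", function(object) {
    msg <- NULL
    need <- c("category", "nCases", "nControls", "or", "ciLo", "ciHi", "p", "flag")
    if (!all(need %in% names(object@stats)))
        msg <- c(msg, "stats must have columns category/nCases/nControls/or/ciLo/ciHi/p/flag")
    else {
        if (!object@reference %in% object@stats$category)
            msg <- c(msg, "reference must be one of the categories")
        if (!all(names(object@beta) %in% object@stats$category))
            msg <- c(msg, "beta names must be categories")
    }
    k <- length(object@beta)
    if (!all(dim(object@sigma) == c(k, k)))
        msg <- c(msg, "sigma dimensions must match beta")
    else if (k > 0L) {
        if (max(abs(object@sigma - t(object@sigma))) > 1e-8)
            msg <- c(msg, "sigma must be symmetric")
        ev <- eigen(object@sigma, symmetric = TRUE, only.values = TRUE)$values
        if (any(ev < -1e-8 * max(1, abs(ev[1L]))))
            msg <- c(msg, "sigma must be positive semi-definite")
    }
    if (is.null(msg)) TRUE else msg
})

#' CategoryFrequencies: population category frequencies
#'
#' Population frequencies of risk categories reconstructed as a
#' prevalence-weighted mixture of case and control frequencies:
#' p_g = pi * f_case_g + (1 - pi) * f_ctrl_g.
#'
#' @slot categories character labels.
#' @slot p population frequency per category (sums to 1).
#' @slot prevalence mixing prevalence pi in [0, 1].
#' @slot fCase,fCtrl per-category frequencies among cases / controls.
#' @export
setClass("CategoryFrequencies",
    slots = c(categories = "character", p = "numeric", prevalence = "numeric",
              fCase = "numeric", fCtrl = "numeric"))

setValidity("CategoryFrequencies", function(object) {
    msg <- NULL
    n <- length(object@categories)
    if (length(object@p) != n || length(object@fCase) != n ||
        length(object@fCtrl) != n)
        msg <- c(msg, "frequency vectors must match categories in length")
    if (any(object@p < 0)) msg <- c(msg, "frequencies must be nonnegative")
    if (abs(sum(object@p) - 1) > 1e-9)
        msg <- c(msg, "population frequencies must sum to 1 (within 1e-9)")
    if (object@prevalence < 0 || object@prevalence > 1)
        msg <- c(msg, "prevalence must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' AbsoluteRiskCurve: cumulative risk by age with confidence bands
#'
#' Age-indexed cumulative disease risk per category, computed under competing
#' mortality. Produced deterministically by \code{\link{absoluteRiskCurve}}
#' (nIter = 0, zero-width bands) or by \code{\link{monteCarloRisk}} with
#' empirical 2.5/97.5 percentile bands over coefficient draws.
#'
#' @slot ages integer age grid.
#' @slot ar matrix (ages x categories) of cumulative risk in [0, 1],
#'   nondecreasing down each column.
#' @slot ciLo,ciHi matrices of the same shape bounding \code{ar}'s band.
#' @slot nIter integer, Monte Carlo iterations (0 = deterministic plug-in).
#' @export
setClass("AbsoluteRiskCurve",
    slots = c(ages = "integer", ar = "matrix", ciLo = "matrix",
              ciHi = "matrix", nIter = "integer"))

setValidity("AbsoluteRiskCurve", function(object) {
    msg <- NULL
    d <- dim(object@ar)
    if (d[1L] != length(object@ages))
        msg <- c(msg, "ar must have one row per age")
    if (!all(dim(object@ciLo) == d) || !all(dim(object@ciHi) == d))
        msg <- c(msg, "ciLo/ciHi must match ar in shape")
    if (any(object@ar < -1e-12 | object@ar > 1 + 1e-12, na.rm = TRUE))
        msg <- c(msg, "absolute risks must lie in [0, 1]")
    if (d[1L] > 1L && any(apply(object@ar, 2L, function(x) any(diff(x) < -1e-12))))
        msg <- c(msg, "absolute risk must be nondecreasing in age")
    if (any(object@ciLo > object@ciHi + 1e-12, na.rm = TRUE))
        msg <- c(msg, "ciLo must not exceed ciHi")
    if (is.null(msg)) TRUE else msg
})

#' InteractionTest: multiplicative interaction test result
#'
#' Likelihood-ratio and Wald tests of multiplicative interaction between PRS
#' category and carrier status (see \code{\link{testInteraction}}).
#'
#' @slot lrtStat,lrtDf,lrtP likelihood-ratio chi-square, df, p-value.
#' @slot waldStat,waldDf,waldP joint Wald chi-square on the product terms.
#' @export
setClass("InteractionTest",
    slots = c(lrtStat = "numeric", lrtDf = "integer", lrtP = "numeric",
              waldStat = "numeric", waldDf = "integer", waldP = "numeric"))

setValidity("InteractionTest", function(object) {
    msg <- NULL
    if (object@lrtStat < -1e-8 || object@waldStat < -1e-8)
        msg <- c(msg, "test statistics must be nonnegative")
    if (object@lrtDf < 1L || object@waldDf < 1L)
        msg <- c(msg, "degrees of freedom must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' GenoCohort: analysis-ready case-control cohort
#'
#' A \linkS4class{SummarizedExperiment} whose \code{dosage} assay holds PRS
#' variant dosages (variants x individuals, values in [0, 2]) and whose column
#' data carry the per-individual analysis variables: case/control status,
#' phenotype class, covariates (age, study, country, PC1..PC10), P/LP/D
#' carrier flag, PRS score and category, and the six-level joint
#' PRS-by-carrier category. Built by \code{\link{assembleCohort}}.
#'
#' @export
setClass("GenoCohort", contains = "SummarizedExperiment")

setValidity("GenoCohort", function(object) {
    msg <- NULL
    if (!"dosage" %in% assayNames(object))
        msg <- c(msg, "assay 'dosage' is required")
    else {
        d <- assay(object, "dosage")
        if (any(d < 0 | d > 2, na.rm = TRUE))
            msg <- c(msg, "dosages must lie in [0, 2]")
    }
    cd <- colData(object)
    need <- c("status", "outcomeClass", "age", "study", "carrier",
              "prsScore", "prsCategory", "jointCategory")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData missing column(s): ",
                             paste(miss, collapse = ", ")))
    else {
        expected <- paste0(as.character(cd$prsCategory),
                           ifelse(cd$carrier, "_carrier", "_noncarrier"))
        if (!all(as.character(cd$jointCategory) == expected))
            msg <- c(msg, "jointCategory inconsistent with prsCategory and carrier")
        if (!all(as.character(cd$status) %in% c("case", "control")))
            msg <- c(msg, "status must be 'case' or 'control'")
    }
    if (is.null(msg)) TRUE else msg
})
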