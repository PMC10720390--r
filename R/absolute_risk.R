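# Absolute risk under competing mortality: case-mix OR weighting,
# prevalence-weighted category frequencies, baseline calibration to the
# population incidence, discrete cumulative-risk accumulation, and Monte
# Carlo CI propagation from the logistic coefficient covariance.

#' Case-mix weighting of aggressive and nonaggressive odds ratios
#'
#' Combines aggressive- and nonaggressive-disease odds ratios into a single
#' overall-disease OR by the expected population case mix (default 37\%
#' aggressive / 63\% nonaggressive). Weighting is arithmetic on the OR scale
#' by default; \code{scale = "log"} weights on the log-OR scale instead.
#'
#' @param orAgg,orNonagg positive odds ratios (vectorized).
#' @param wAgg aggressive-case proportion in [0, 1] (default 0.37).
#' @param scale \code{"or"} (default) or \code{"log"}.
#' @return the weighted odds ratio(s).
#' @examples
#' weightOddsRatios(2.0, 1.0, 0.37)  # 1.37
#' @export
weightOddsRatios <- function(orAgg, orNonagg, wAgg = 0.37,
                             scale = c("or", "log")) {
    scale <- match.arg(scale)
    if (any(orAgg <= 0, na.rm = TRUE) || any(orNonagg <= 0, na.rm = TRUE))
        stop("odds ratios must be positive")
    if (wAgg < 0 || wAgg > 1) stop("wAgg must lie in [0, 1]")
    if (scale == "or") wAgg * orAgg + (1 - wAgg) * orNonagg
    else exp(wAgg * log(orAgg) + (1 - wAgg) * log(orNonagg))
}

#' Prevalence-weighted population category frequencies
#'
#' Reconstructs population category frequencies from the case and control
#' category frequencies observed in a (case-enriched) study:
#' p_g = pi * f_case_g + (1 - pi) * f_ctrl_g, with pi the population disease
#' prevalence (default 0.167).
#'
#' @param fCase,fCtrl named per-category frequencies among cases and controls
#'   (each summing to 1, matching names).
#' @param prev prevalence pi in [0, 1].
#' @return A \linkS4class{CategoryFrequencies}.
#' @export
populationFrequencies <- function(fCase, fCtrl, prev = 0.167) {
    if (prev < 0 || prev > 1) stop("prevalence must lie in [0, 1]")
    if (!identical(names(fCase), names(fCtrl)))
        stop("fCase and fCtrl must have identical category names")
    if (abs(sum(fCase) - 1) > 1e-6 || abs(sum(fCtrl) - 1) > 1e-6)
        stop("fCase and fCtrl must each sum to 1")
    p <- prev * fCase + (1 - prev) * fCtrl
    if (abs(sum(p) - 1) > 1e-9) p <- p / sum(p)
    new("CategoryFrequencies", categories = names(fCase), p = unname(p),
        prevalence = prev, fCase = unname(fCase), fCtrl = unname(fCtrl))
}

#' Category frequencies observed in a cohort
#'
#' Convenience wrapper: tabulates the joint-category frequencies among cases
#' and controls of a cohort and mixes them by prevalence
#' (\code{\link{populationFrequencies}}).
#'
#' @param cohort a \linkS4class{GenoCohort}.
#' @param prev population prevalence (default 0.167).
#' @param by \code{"joint"} (six categories), \code{"carrier"} or
#'   \code{"prs"}.
#' @return A \linkS4class{CategoryFrequencies}.
#' @export
cohortFrequencies <- function(cohort, prev = 0.167,
                              by = c("joint", "carrier", "prs")) {
    by <- match.arg(by)
    data <- cohortData(cohort)
    grp <- switch(by,
        joint = factor(data$jointCategory, levels = jointCategoryLevels()),
        carrier = factor(ifelse(data$carrier, "carrier", "noncarrier"),
                         levels = c("noncarrier", "carrier")),
        prs = data$prsCategory)
    fCase <- prop.table(table(grp[data$status == "case"]))
    fCtrl <- prop.table(table(grp[data$status == "control"]))
    populationFrequencies(as.numeric(fCase) |> setNames(names(fCase)),
                          as.numeric(fCtrl) |> setNames(names(fCtrl)),
                          prev = prev)
}

#' Calibrate the baseline hazard to the population incidence
#'
#' Solves the static-frequency calibration
#' lambda0(t) = lambda_pop(t) / sum_g p_g * r_g at every age, which
#' guarantees sum_g p_g * r_g * lambda0(t) = lambda_pop(t) exactly. Category
#' odds ratios are treated as relative risks r_g (reference category r = 1).
#'
#' With \code{dynamic = TRUE} the category frequencies are depleted with age,
#' p_g(t+1) proportional to p_g(t) * (1 - h_g(t) - mu(t)), and the baseline is
#' recalibrated at every age against the current mixture; this removes most of
#' the static approximation's late-age bias at the cost of the closed-form
#' identity (the identity then holds against the age-t mixture rather than the
#' baseline one).
#'
#' @param rates a \linkS4class{RateSchedule} with the population incidence.
#' @param freqs a \linkS4class{CategoryFrequencies}.
#' @param r named positive relative risks per category (must cover the
#'   frequency categories; reference = 1).
#' @param dynamic deplete high-risk categories with age (default FALSE:
#'   static frequencies, exact calibration identity).
#' @return numeric baseline hazard per age, named by age.
#' @export
calibrateBaseline <- function(rates, freqs, r, dynamic = FALSE) {
    cats <- freqs@categories
    if (!all(cats %in% names(r)))
        stop("relative risks missing for category(ies): ",
             paste(setdiff(cats, names(r)), collapse = ", "))
    r <- r[cats]
    if (any(!is.finite(r)) || any(r < 0))
        stop("relative risks must be finite and nonnegative")
    lam <- incidence(rates)
    if (!dynamic) {
        denom <- sum(freqs@p * r)
        if (denom == 0) stop("sum of p_g * r_g is zero; cannot calibrate")
        return(setNames(lam / denom, ages(rates)))
    }
    mu <- mortality(rates)
    p <- freqs@p
    lam0 <- numeric(length(lam))
    for (t in seq_along(lam)) {
        denom <- sum(p * r)
        if (denom == 0) stop("sum of p_g * r_g is zero; cannot calibrate")
        lam0[t] <- lam[t] / denom
        h <- pmin(r * lam0[t], 1)
        p <- p * pmax(1 - h - mu[t], 0)
        if (sum(p) == 0) stop("entire population depleted during calibration")
        p <- p / sum(p)
    }
    setNames(lam0, ages(rates))
}

.accumulateRisk <- function(h, mu) {
    surv <- cumprod(pmax(1 - h - mu, 0))
    survLag <- c(1, surv[-length(surv)])
    cumsum(pmin(h, 1) * survLag)
}

#' Absolute risk curves under competing mortality
#'
#' Accumulates the discrete cumulative disease risk from \code{ageStart} to
#' \code{ageEnd}: AR_g(a) = sum_t h_g(t) * prod_{s<t} (1 - h_g(s) - mu(s)),
#' with category hazard h_g(t) = min(r_g * lambda0(t), 1), competing
#' mortality mu(t) from the rate schedule, the survival factor floored at 0
#' and the risk clamped to [0, 1].
#'
#' @param lambda0 baseline hazard per age (from
#'   \code{\link{calibrateBaseline}}), aligned with \code{rates}.
#' @param r named (or scalar) relative risks, one curve per element.
#' @param rates a \linkS4class{RateSchedule} (supplies ages and mortality).
#' @param ageStart,ageEnd accumulation window (default: full grid).
#' @return An \linkS4class{AbsoluteRiskCurve} with \code{nIter = 0} and
#'   zero-width bands.
#' @export
absoluteRiskCurve <- function(lambda0, r, rates,
                              ageStart = min(ages(rates)),
                              ageEnd = max(ages(rates))) {
    grid <- ages(rates)
    if (!ageStart %in% grid || !ageEnd %in% grid || ageStart >= ageEnd)
        stop("ageStart/ageEnd must lie on the age grid with ageStart < ageEnd")
    win <- grid >= ageStart & grid <= ageEnd
    lam <- lambda0[win]
    mu <- mortality(rates)[win]
    if (is.null(names(r))) names(r) <- if (length(r) == 1L) "all"
        else paste0("category", seq_along(r))
    ar <- matrix(NA_real_, nrow = sum(win), ncol = length(r),
                 dimnames = list(NULL, names(r)))
    warned <- FALSE
    for (g in seq_along(r)) {
        h <- pmin(r[g] * lam, 1)
        if (!warned && any(h + mu > 1)) {
            warning("hazard + mortality exceeds 1 at some age; ",
                    "survival floored at 0")
            warned <- TRUE
        }
        ar[, g] <- pmin(pmax(.accumulateRisk(h, mu), 0), 1)
    }
    new("AbsoluteRiskCurve", ages = grid[win], ar = ar, ciLo = ar,
        ciHi = ar, nIter = 0L)
}

.drawCoefMatrix <- function(ort, nIter) {
    beta <- betaCoef(ort)
    sigma <- betaCov(ort)
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-10 * max(1, abs(ev[1L]))))
        stop("coefficient covariance is not positive semi-definite")
    draws <- MASS::mvrnorm(nIter, mu = beta, Sigma = sigma)
    if (nIter == 1L) draws <- matrix(draws, nrow = 1L,
                                     dimnames = list(NULL, names(beta)))
    colnames(draws) <- names(beta)
    draws
}

.relativeRisks <- function(ort, drawRow = NULL) {
    cats <- orTable(ort)$category
    flagged <- orTable(ort)$flag == "undefined_empty_cell"
    if (any(flagged))
        stop("category(ies) with undefined OR cannot enter absolute-risk ",
             "computation: ", paste(cats[flagged], collapse = ", "))
    b <- if (is.null(drawRow)) betaCoef(ort) else drawRow
    r <- setNames(rep(1, length(cats)), cats)
    r[names(b)] <- exp(b)
    r
}

#' Monte Carlo absolute risk curves with confidence bands
#'
#' Propagates logistic-coefficient uncertainty into the absolute risk scale:
#' per iteration, category log-ORs are drawn jointly from a multivariate
#' normal with the fitted mean and covariance, converted to relative risks,
#' and the baseline calibration and risk accumulation are re-run. The
#' reported point estimate is the mean across iterations and the bands are
#' the empirical 2.5/97.5 percentiles per age; results are reproducible for a
#' fixed seed. When a second OR table is supplied (aggressive +
#' nonaggressive fits), each iteration draws from both and combines the ORs
#' by the case-mix weight before computing the curve
#' (\code{\link{weightOddsRatios}}).
#'
#' @param ort an \linkS4class{ORTable} carrying beta and covariance.
#' @param freqs a \linkS4class{CategoryFrequencies} over the same categories.
#' @param rates a \linkS4class{RateSchedule}.
#' @param nIter Monte Carlo iterations (default 1000, minimum 2).
#' @param seed integer RNG seed.
#' @param ageStart,ageEnd accumulation window.
#' @param ortNonagg optional nonaggressive \linkS4class{ORTable}; when given,
#'   \code{ort} is interpreted as the aggressive table and the two are
#'   case-mix weighted per draw.
#' @param wAgg aggressive case-mix weight (default 0.37).
#' @param weightScale \code{"or"} or \code{"log"} weighting scale.
#' @return An \linkS4class{AbsoluteRiskCurve} (mean curve + percentile
#'   bands).
#' @export
monteCarloRisk <- function(ort, freqs, rates, nIter = 1000L, seed = 1L,
                           ageStart = min(ages(rates)),
                           ageEnd = max(ages(rates)), ortNonagg = NULL,
                           wAgg = 0.37, weightScale = c("or", "log")) {
    weightScale <- match.arg(weightScale)
    if (nIter < 2L) stop("nIter must be at least 2")
    set.seed(seed)
    draws1 <- .drawCoefMatrix(ort, nIter)
    draws2 <- if (!is.null(ortNonagg)) .drawCoefMatrix(ortNonagg, nIter)
    grid <- ages(rates)
    win <- grid >= ageStart & grid <= ageEnd
    nAges <- sum(win)
    cats <- freqs@categories
    acc <- array(NA_real_, dim = c(nAges, length(cats), nIter))
    for (it in seq_len(nIter)) {
        r1 <- .relativeRisks(ort, draws1[it, ])
        r <- if (is.null(draws2)) r1
        else {
            r2 <- .relativeRisks(ortNonagg, draws2[it, ])
            weightOddsRatios(r1[cats], r2[cats], wAgg, scale = weightScale)
        }
        lam0 <- calibrateBaseline(rates, freqs, r)
        crv <- absoluteRiskCurve(lam0, r[cats], rates, ageStart, ageEnd)
        acc[, , it] <- riskEstimates(crv)
    }
    ar <- apply(acc, c(1, 2), mean)
    ciLo <- apply(acc, c(1, 2), stats::quantile, probs = 0.025, names = FALSE)
    ciHi <- apply(acc, c(1, 2), stats::quantile, probs = 0.975, names = FALSE)
    dimnames(ar) <- dimnames(ciLo) <- dimnames(ciHi) <- list(NULL, cats)
    new("AbsoluteRiskCurve", ages = grid[win], ar = ar,
        ciLo = pmin(ciLo, ar), ciHi = pmax(ciHi, ar),
        nIter = as.integer(nIter))
}

#' Write absolute risk curves to long-format TSV
#'
#' @param curve an \linkS4class{AbsoluteRiskCurve}.
#' @param path output path; columns category, age, ar, ci_lo, ci_hi.
#' @return \code{path}, invisibly.
#' @export
writeRiskCurve <- function(curve, path) {
    ar <- riskEstimates(curve)
    out <- data.frame(
        category = rep(colnames(ar), each = nrow(ar)),
        age = rep(ages(curve), times = ncol(ar)),
        ar = as.vector(ar),
        ci_lo = as.vector(riskLower(curve)),
        ci_hi = as.vector(riskUpper(curve)))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
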