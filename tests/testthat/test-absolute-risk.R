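test_that("case-mix OR weighting is an OR-scale mixture", {
    expect_equal(weightOddsRatios(3.5, 3.5, 0.37), 3.5)
    expect_equal(weightOddsRatios(2.0, 1.0, 0.37), 1.37)
    expect_equal(weightOddsRatios(2.0, 1.0, 1), 2.0)
    expect_equal(weightOddsRatios(2.0, 1.0, 0), 1.0)
    # weighted value sits between its inputs
    expect_true(weightOddsRatios(4, 1.5, 0.37) > 1.5 &&
                    weightOddsRatios(4, 1.5, 0.37) < 4)
    # log-scale alternative is the geometric mixture
    expect_equal(weightOddsRatios(2, 1, 0.5, scale = "log"), sqrt(2))
    expect_error(weightOddsRatios(-1, 2), "positive")
    expect_error(weightOddsRatios(1, 2, wAgg = 1.5), "wAgg")
})

test_that("population frequencies are the prevalence-weighted mixture", {
    fCase <- c(a = 0.033, b = 0.967)
    fCtrl <- c(a = 0.006, b = 0.994)
    fr <- populationFrequencies(fCase, fCtrl, prev = 0.167)
    expect_equal(unname(popFrequencies(fr)[["a"]]),
                 0.167 * 0.033 + 0.833 * 0.006, tolerance = 1e-9)
    expect_equal(sum(popFrequencies(fr)), 1, tolerance = 1e-12)
    # mixture of equals and the prevalence boundaries
    expect_equal(popFrequencies(populationFrequencies(fCtrl, fCtrl, 0.3)),
                 fCtrl)
    expect_equal(popFrequencies(populationFrequencies(fCase, fCtrl, 0)),
                 fCtrl)
    expect_equal(popFrequencies(populationFrequencies(fCase, fCtrl, 1)),
                 fCase)
    expect_error(populationFrequencies(fCase, fCtrl, 1.2), "prevalence")
})

test_that("baseline calibration solves the frequency-weighted identity", {
    rates <- generateRates("flat", 0.002, agesGrid = 40:60,
                           mortalityScale = 0.01)
    # single category, r = 1: baseline equals the population incidence
    fr1 <- populationFrequencies(c(all = 1), c(all = 1), 0.167)
    expect_equal(unname(calibrateBaseline(rates, fr1, c(all = 1))),
                 incidence(rates))
    # p = (1/2, 1/2), r = (1, 3): denominator 2
    fr2 <- populationFrequencies(c(a = 0.5, b = 0.5), c(a = 0.5, b = 0.5),
                                 0.167)
    expect_equal(unname(calibrateBaseline(rates, fr2, c(a = 1, b = 3))),
                 rep(0.001, 21))
    # uniform scaling r = 2 halves the baseline
    expect_equal(unname(calibrateBaseline(rates, fr2, c(a = 2, b = 2))),
                 incidence(rates) / 2)
    expect_error(calibrateBaseline(rates, fr2, c(a = 0, b = 0)), "zero")
})

test_that("the calibration identity holds to machine precision for random configs", {
    set.seed(5)
    for (i in 1:25) {
        k <- sample(2:6, 1)
        rates <- generateRates(sample(c("flat", "exponential"), 1),
                               runif(1, 1e-4, 5e-3))
        fCase <- prop.table(runif(k) + 0.01)
        fCtrl <- prop.table(runif(k) + 0.01)
        names(fCase) <- names(fCtrl) <- paste0("g", seq_len(k))
        fr <- populationFrequencies(fCase, fCtrl, runif(1, 0.05, 0.4))
        r <- setNames(exp(rnorm(k, 0, 1)), names(fCase))
        r[1] <- 1
        lam0 <- calibrateBaseline(rates, fr, r)
        expect_equal(unname(sum(popFrequencies(fr) * r) * lam0),
                     incidence(rates), tolerance = 1e-15)
    }
})

test_that("absolute risk matches the closed-form geometric product", {
    rates <- RateSchedule(1:10, rep(0.01, 10), rep(0, 10))
    lam0 <- setNames(rep(0.01, 10), 1:10)
    crv <- absoluteRiskCurve(lam0, c(all = 1), rates)
    expect_equal(unname(riskEstimates(crv)[10, 1]), 1 - 0.99^10,
                 tolerance = 1e-15)
    # the whole curve equals the discrete cumulative incidence
    expect_equal(unname(riskEstimates(crv)[, 1]), 1 - 0.99^(1:10),
                 tolerance = 1e-15)
    # zero hazard and r = 0 give zero risk
    crv0 <- absoluteRiskCurve(setNames(rep(0, 10), 1:10), c(all = 1), rates)
    expect_true(all(riskEstimates(crv0) == 0))
    crvR0 <- absoluteRiskCurve(lam0, c(none = 0), rates)
    expect_true(all(riskEstimates(crvR0) == 0))
})

test_that("risk is monotone in age and in the relative risk", {
    rates <- generateRates("exponential", 2e-3)
    fr <- populationFrequencies(c(a = 0.4, b = 0.6), c(a = 0.4, b = 0.6),
                                0.167)
    lam0 <- calibrateBaseline(rates, fr, c(a = 1, b = 2))
    crv <- absoluteRiskCurve(lam0, c(a = 1, b = 2, c = 4), rates)
    ar <- riskEstimates(crv)
    expect_true(all(diff(ar[, "b"]) >= 0))
    # strictly increasing in r at fixed age
    expect_true(all(ar[nrow(ar), ] == sort(ar[nrow(ar), ])))
    expect_lt(ar[nrow(ar), "a"], ar[nrow(ar), "c"])
})

test_that("raising competing mortality never raises absolute risk", {
    set.seed(8)
    for (i in 1:50) {
        ages <- 40:70
        lam <- runif(length(ages), 0, 0.05)
        mu <- runif(length(ages), 0, 0.1)
        bump <- runif(length(ages), 0, 0.05)
        r1 <- RateSchedule(ages, lam, mu)
        r2 <- RateSchedule(ages, lam, pmin(mu + bump, 0.999))
        lam0 <- setNames(lam, ages)
        a1 <- riskEstimates(absoluteRiskCurve(lam0, c(x = 1.5), r1))
        a2 <- riskEstimates(absoluteRiskCurve(lam0, c(x = 1.5), r2))
        expect_true(all(a2 <= a1 + 1e-12))
    }
})

test_that("population average of category curves tracks the one-category curve", {
    # the p-weighted average of category curves is compared against the
    # curve computed directly from the population incidence; the static
    # calibration ignores depletion of high-risk categories so its error
    # grows with cumulative incidence (measured ~5.6% relative by age 85 at
    # a tertile OR spread of 0.57-3 and ~17% lifetime risk), while the
    # dynamic depletion mode reproduces the population curve exactly
    rates <- generateRates("exponential")
    fr <- populationFrequencies(
        c(lo = 0.30, mid = 0.34, hi = 0.36),
        c(lo = 0.34, mid = 0.33, hi = 0.33), 0.167)
    r <- c(lo = 0.57, mid = 1, hi = 3)
    pop <- riskEstimates(absoluteRiskCurve(
        setNames(incidence(rates), ages(rates)), c(all = 1), rates))[, 1]

    lam0 <- calibrateBaseline(rates, fr, r)
    avg <- drop(riskEstimates(absoluteRiskCurve(lam0, r, rates)) %*%
                    popFrequencies(fr))
    relErr <- abs(avg - pop) / pop
    expect_lt(max(relErr), 0.06)
    # error is small where cumulative incidence is still modest
    expect_lt(relErr[which(ages(rates) == 60)], 0.02)
    # the dynamic mode reproduces the population curve to machine precision
    lam0d <- calibrateBaseline(rates, fr, r, dynamic = TRUE)
    avgD <- drop(riskEstimates(absoluteRiskCurve(lam0d, r, rates)) %*%
                     popFrequencies(fr))
    expect_lt(max(abs(avgD - pop) / pop), 1e-10)
})

.toyORTable <- function(beta = c(a = log(2), c = log(0.5)),
                        sigma = diag(c(0.04, 0.09))) {
    dimnames(sigma) <- list(names(beta), names(beta))
    stats <- data.frame(category = c("ref", names(beta)),
                        nCases = c(50, 40, 30), nControls = c(50, 20, 60),
                        or = c(1, exp(beta)), ciLo = NA_real_,
                        ciHi = NA_real_, p = NA_real_,
                        flag = c("reference", "", ""))
    new("ORTable", outcome = "overall", reference = "ref", stats = stats,
        beta = beta, sigma = sigma)
}

test_that("Monte Carlo risk is reproducible and degenerates with zero covariance", {
    rates <- generateRates("exponential")
    ort <- .toyORTable()
    fr <- populationFrequencies(
        c(ref = 0.4, a = 0.35, c = 0.25), c(ref = 0.5, a = 0.3, c = 0.2),
        0.167)
    mc1 <- monteCarloRisk(ort, fr, rates, nIter = 200, seed = 17)
    mc2 <- monteCarloRisk(ort, fr, rates, nIter = 200, seed = 17)
    expect_identical(riskEstimates(mc1), riskEstimates(mc2))
    expect_identical(riskLower(mc1), riskLower(mc2))

    # zero covariance: bands collapse onto the plug-in curve
    ort0 <- .toyORTable(sigma = matrix(0, 2, 2))
    mc0 <- monteCarloRisk(ort0, fr, rates, nIter = 50, seed = 3)
    r <- c(ref = 1, a = 2, c = 0.5)
    lam0 <- calibrateBaseline(rates, fr, r)
    plug <- riskEstimates(absoluteRiskCurve(lam0, r[c("ref", "a", "c")],
                                            rates))
    expect_equal(riskEstimates(mc0), plug, tolerance = 1e-12)
    expect_equal(riskLower(mc0), riskUpper(mc0), tolerance = 1e-12)

    # a non-PSD covariance is rejected (already at construction)
    badSigma <- matrix(c(1, 2, 2, 1), 2,
                       dimnames = list(c("a", "c"), c("a", "c")))
    expect_error(.toyORTable(sigma = badSigma), "positive semi-definite")
})

test_that("the Monte Carlo mean converges with iteration count", {
    rates <- generateRates("exponential", agesGrid = 40:55)
    ort <- .toyORTable()
    fr <- populationFrequencies(
        c(ref = 0.4, a = 0.35, c = 0.25), c(ref = 0.5, a = 0.3, c = 0.2),
        0.167)
    mcSmall <- monteCarloRisk(ort, fr, rates, nIter = 1000, seed = 23)
    mcBig <- monteCarloRisk(ort, fr, rates, nIter = 10000, seed = 24)
    last <- nrow(riskEstimates(mcSmall))
    # MC standard error of the small-run mean, from its percentile spread
    seApprox <- (riskUpper(mcSmall)[last, ] - riskLower(mcSmall)[last, ]) /
        (2 * 1.96) / sqrt(1000)
    gap <- abs(riskEstimates(mcSmall)[last, ] - riskEstimates(mcBig)[last, ])
    expect_true(all(gap < 3 * pmax(seApprox, 1e-6)))
})

test_that("case-mix weighted Monte Carlo stays between its component curves", {
    rates <- generateRates("exponential")
    ortA <- .toyORTable(beta = c(a = log(4), c = log(0.8)))
    ortN <- .toyORTable(beta = c(a = log(1.5), c = log(0.6)))
    fr <- populationFrequencies(
        c(ref = 0.4, a = 0.35, c = 0.25), c(ref = 0.5, a = 0.3, c = 0.2),
        0.167)
    mcW <- monteCarloRisk(ortA, fr, rates, nIter = 300, seed = 5,
                          ortNonagg = ortN, wAgg = 0.37)
    mcA <- monteCarloRisk(ortA, fr, rates, nIter = 300, seed = 5)
    mcN <- monteCarloRisk(ortN, fr, rates, nIter = 300, seed = 5)
    last <- nrow(riskEstimates(mcW))
    aW <- riskEstimates(mcW)[last, "a"]
    expect_gt(aW, riskEstimates(mcN)[last, "a"] - 0.01)
    expect_lt(aW, riskEstimates(mcA)[last, "a"] + 0.01)
})
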