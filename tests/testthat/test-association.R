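# expand a 2xK count table into individual-level vectors
.expandCounts <- function(nCase, nCtrl, labels) {
    status <- rep(rep(c(TRUE, FALSE), length(labels)),
                  times = as.vector(rbind(nCase, nCtrl)))
    category <- rep(rep(labels, each = 2),
                    times = as.vector(rbind(nCase, nCtrl)))
    list(status = status, category = factor(category, levels = labels))
}

test_that("the unadjusted two-category OR equals the cross-product ratio", {
    # oracle: OR = (a*d)/(b*c) from the 2x2 table, by hand arithmetic
    x <- .expandCounts(nCase = c(30, 20), nCtrl = c(10, 40),
                       labels = c("exposed", "unexposed"))
    fit <- fitCategoryModel(x$status, x$category, ref = "unexposed")
    expect_equal(orTable(fit)$or[1], (30 * 40) / (20 * 10),
                 tolerance = 1e-7)   # 6.0

    x2 <- .expandCounts(nCase = c(40, 160), nCtrl = c(10, 490),
                        labels = c("carrier", "noncarrier"))
    fit2 <- fitCategoryModel(x2$status, x2$category, ref = "noncarrier")
    expect_equal(orTable(fit2)$or[1], (40 * 490) / (160 * 10),
                 tolerance = 1e-7)   # 12.25
})

test_that("identical category distributions in cases and controls give OR 1", {
    x <- .expandCounts(nCase = c(50, 80, 70), nCtrl = c(50, 80, 70),
                       labels = c("a", "b", "c"))
    fit <- fitCategoryModel(x$status, x$category, ref = "b")
    ors <- orTable(fit)$or
    expect_equal(ors, rep(1, 3), tolerance = 1e-8)
})

test_that("zero-cell categories are excluded and flagged, not fatal", {
    x <- .expandCounts(nCase = c(30, 20, 5), nCtrl = c(10, 40, 0),
                       labels = c("a", "b", "empty"))
    fit <- fitCategoryModel(x$status, x$category, ref = "b")
    st <- orTable(fit)
    expect_true(is.na(st$or[st$category == "empty"]))
    expect_equal(st$flag[st$category == "empty"], "undefined_empty_cell")
    # remaining categories still match the contingency oracle
    expect_equal(st$or[st$category == "a"], (30 * 40) / (20 * 10),
                 tolerance = 1e-7)
    # a nonzero but sparse cell triggers the instability warning
    xs <- .expandCounts(nCase = c(30, 20, 5), nCtrl = c(10, 40, 3),
                        labels = c("a", "b", "tiny"))
    expect_warning(fitCategoryModel(xs$status, xs$category, ref = "b"),
                   "sparse")
})

test_that("a cohort of controls only is rejected", {
    x <- .expandCounts(nCase = c(0, 0), nCtrl = c(10, 20),
                       labels = c("a", "b"))
    expect_error(fitCategoryModel(x$status, x$category, ref = "b"),
                 "at least one case")
})

test_that("relabeling the reference reproduces the original ORs", {
    x <- .expandCounts(nCase = c(30, 45, 80), nCtrl = c(60, 50, 40),
                       labels = c("low", "mid", "high"))
    fitMid <- fitCategoryModel(x$status, x$category, ref = "mid")
    fitLow <- fitCategoryModel(x$status, x$category, ref = "low")
    orMid <- setNames(orTable(fitMid)$or, orTable(fitMid)$category)
    orLow <- setNames(orTable(fitLow)$or, orTable(fitLow)$category)
    # back-transform: OR(high vs mid) = OR(high vs low) / OR(mid vs low)
    expect_equal(orMid[["high"]], orLow[["high"]] / orLow[["mid"]],
                 tolerance = 1e-7)
    expect_equal(orMid[["low"]], 1 / orLow[["mid"]], tolerance = 1e-7)
})

test_that("the joint model recovers generator truth within 3 SE (single cohort)", {
    toy <- makeToyCohort(n = 4000, seed = 314)
    fit <- fitJointModel(toy$cohort, "overall")
    truth <- toy$sim$truth$categoryLogOR
    b <- betaCoef(fit)
    se <- sqrt(diag(betaCov(fit)))
    for (g in names(b)) {
        expect_lt(abs(b[g] - truth[g]), 3 * se[g])
    }
    expect_identical(referenceCategory(fit), "intermediate_noncarrier")
})

test_that("marginal carrier and PRS fits use the right references", {
    toy <- makeToyCohort(n = 1500, seed = 21)
    m <- fitMarginalModels(toy$cohort, "overall")
    expect_identical(referenceCategory(m$carrier), "noncarrier")
    expect_identical(referenceCategory(m$prs), "intermediate")
    expect_gt(orTable(m$carrier)$or[2], 1)  # carrier OR generated at 4.5
    st <- orTable(m$prs)
    expect_gt(st$or[st$category == "high"], 1)
    expect_lt(st$or[st$category == "low"], 1)
})

test_that("aggressiveness outcomes subset the cases correctly", {
    toy <- makeToyCohort(n = 1500, seed = 22)
    cd <- cohortData(toy$cohort)
    fitAgg <- suppressWarnings(fitJointModel(toy$cohort, "aggressive"))
    expect_equal(sum(orTable(fitAgg)$nCases),
                 sum(cd$outcomeClass %in% c("aggressive",
                                            "metastatic-aggressive")))
    fitMet <- suppressWarnings(fitJointModel(toy$cohort, "metastatic"))
    expect_equal(sum(orTable(fitMet)$nCases),
                 sum(cd$outcomeClass == "metastatic-aggressive"))
    # unclassified cases contribute to overall only
    fitAll <- fitJointModel(toy$cohort, "overall")
    expect_equal(sum(orTable(fitAll)$nCases), sum(cd$status == "case"))
})

test_that("a strong generated product term is detected; forced-equal models give 0", {
    toy <- makeToyCohort(n = 12000, seed = 99, interactionLogOR = 1.2)
    it <- testInteraction(toy$cohort, "overall")
    expect_lt(lrtP(it), 0.001)
    expect_equal(it@lrtDf, 2L)

    # additive generation: both tests agree the term is unnecessary
    toy0 <- makeToyCohort(n = 4000, seed = 100)
    it0 <- testInteraction(toy0$cohort, "overall")
    expect_gt(lrtP(it0), 0.01)
    expect_equal(it0@waldDf, 2L)
    # continuous-scale variant runs with 1 df
    itC <- testInteraction(toy0$cohort, "overall", scale = "continuous")
    expect_equal(itC@lrtDf, 1L)
})

test_that("the penalized fit shrinks near-separated estimates", {
    x <- .expandCounts(nCase = c(20, 15), nCtrl = c(1, 30),
                       labels = c("sparse", "base"))
    fitML <- suppressWarnings(
        fitCategoryModel(x$status, x$category, ref = "base"))
    fitF <- suppressWarnings(
        fitCategoryModel(x$status, x$category, ref = "base", firth = TRUE))
    bML <- betaCoef(fitML)[["sparse"]]
    bF <- betaCoef(fitF)[["sparse"]]
    expect_true(is.finite(bF))
    expect_lt(abs(bF), abs(bML))
})
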