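# helpers to build annotation records concisely
annRow <- function(consequence, gene = "BRCA2", clinvar = "",
                   insilico = "", maf = 0.001, id = "v1") {
    data.frame(variant_id = id, gene = gene, consequence = consequence,
               clinvar = clinvar, insilico = insilico, maf = maf,
               stringsAsFactors = FALSE)
}

allDamaging <- paste(c("PolyPhen2-HumDiv", "PolyPhen2-HumVar", "LRT",
                       "MutationTaster", "SIFT"),
                     "damaging", sep = ":", collapse = ";")

test_that("the P/LP/D rules fire on the right evidence", {
    # truncating variant needs no other evidence
    r <- classifyVariants(annRow("frameshift_indel"))
    expect_true(r$plpd)
    expect_equal(r$rule, "truncating")

    # missense with a single likely-pathogenic laboratory assertion
    r <- classifyVariants(annRow("missense", gene = "ATM",
                                 clinvar = "GeneDX:likely_pathogenic",
                                 maf = 0.002))
    expect_true(r$plpd)
    expect_equal(r$rule, "clinvar")

    # synonymous is excluded even with all five predictors damaging
    r <- classifyVariants(annRow("synonymous", gene = "NBN",
                                 insilico = allDamaging))
    expect_false(r$plpd)
    expect_equal(r$rule, "excluded_class")

    # missense with in-silico consensus only
    r <- classifyVariants(annRow("missense", insilico = allDamaging))
    expect_true(r$plpd)
    expect_equal(r$rule, "insilico")

    # common variant fails the MAF < 1% filter even if truncating
    r <- classifyVariants(annRow("stop_gained", maf = 0.02))
    expect_false(r$plpd)
    expect_equal(r$rule, "common")

    # conflicting assertions: pathogenic by >=1 lab wins, conflict audited
    r <- classifyVariants(annRow("missense",
                                 clinvar = "Ambry:pathogenic;Emory:benign"))
    expect_true(r$plpd)
    expect_equal(r$rule, "clinvar_conflict")

    # gene outside the panel is skipped with an audit note, not an error
    r <- classifyVariants(annRow("frameshift_indel", gene = "TP53"))
    expect_false(r$plpd)
    expect_equal(r$rule, "outside_panel")
})

test_that("the in-silico consensus policies behave as configured", {
    twoOfFive <- paste0("LRT:damaging;SIFT:damaging;MutationTaster:tolerated;",
                        "PolyPhen2-HumDiv:tolerated;PolyPhen2-HumVar:tolerated")
    fourDamagingOneMissing <-
        paste0("LRT:damaging;SIFT:damaging;MutationTaster:damaging;",
               "PolyPhen2-HumDiv:damaging;PolyPhen2-HumVar:missing")
    twoAvailBothDamaging <- "LRT:damaging;SIFT:damaging"

    expect_false(classifyVariants(annRow("missense",
        insilico = twoOfFive), insilicoRule = "all")$plpd)
    expect_false(classifyVariants(annRow("missense",
        insilico = twoOfFive), insilicoRule = "majority")$plpd)
    expect_true(classifyVariants(annRow("missense",
        insilico = twoOfFive), insilicoRule = "any")$plpd)
    # "all" means all *available*, with at least 3 available
    expect_true(classifyVariants(annRow("missense",
        insilico = fourDamagingOneMissing), insilicoRule = "all")$plpd)
    expect_false(classifyVariants(annRow("missense",
        insilico = twoAvailBothDamaging), insilicoRule = "all")$plpd)
})

test_that("classification is order-independent and deterministic", {
    ann <- generateAnnotations(nPlpd = 20, nBenign = 30, seed = 9)
    truth <- ann$plpd_truth
    ann$plpd_truth <- NULL
    r1 <- classifyVariants(ann)
    perm <- sample(nrow(ann))
    r2 <- classifyVariants(ann[perm, ])
    expect_identical(r1$plpd[perm], r2$plpd)
    expect_identical(r1$rule[perm], r2$rule)
    expect_identical(r1$plpd, truth)
})

test_that("adding a pathogenic assertion never flips a missense to benign", {
    set.seed(3)
    for (i in 1:40) {
        calls <- paste(sample(c("damaging", "tolerated", "missing"), 5,
                              replace = TRUE),
                       collapse = ";")
        insilico <- paste(c("PolyPhen2-HumDiv", "PolyPhen2-HumVar", "LRT",
                            "MutationTaster", "SIFT"),
                          strsplit(calls, ";")[[1]], sep = ":",
                          collapse = ";")
        base <- annRow("missense", insilico = insilico,
                       maf = runif(1, 0, 0.009))
        withP <- base
        withP$clinvar <- "InVitae:pathogenic"
        before <- classifyVariants(base)$plpd
        after <- classifyVariants(withP)$plpd
        expect_false(before & !after)
        expect_true(after)  # pathogenic assertion is itself sufficient
    }
})

test_that("carriers hold >=1 alternate allele at >=1 P/LP/D variant", {
    cls <- data.frame(variant_id = c("vA", "vB", "vC"),
                      gene = "BRCA2", plpd = c(TRUE, FALSE, TRUE),
                      rule = c("truncating", "no_evidence", "clinvar"))
    g <- rbind(i1 = c(1, 0, 0),   # het at plpd vA -> carrier
               i2 = c(0, 2, 0),   # hom at non-plpd vB only -> not
               i3 = c(0, 0, 0),
               i4 = c(0, 1, 2))   # hom at plpd vC -> carrier
    colnames(g) <- c("vA", "vB", "vC")
    carr <- determineCarriers(g, cls)
    expect_identical(carr, c(i1 = TRUE, i2 = FALSE, i3 = FALSE, i4 = TRUE))

    # zero P/LP/D variants: everyone is a non-carrier
    clsNone <- cls
    clsNone$plpd <- FALSE
    expect_identical(determineCarriers(g, clsNone),
                     setNames(rep(FALSE, 4), rownames(g)))
})
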