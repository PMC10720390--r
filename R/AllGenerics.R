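# Accessor generics and show methods. Slots are never accessed directly by
# user code; these accessors are the supported surface.

#' @rdname RateSchedule-class
#' @param x,object a polyrisk S4 object.
#' @export
setGeneric("ages", function(x) standardGeneric("ages"))
#' @rdname RateSchedule-class
#' @export
setGeneric("incidence", function(x) standardGeneric("incidence"))
#' @rdname RateSchedule-class
#' @export
setGeneric("mortality", function(x) standardGeneric("mortality"))

#' @rdname RateSchedule-class
#' @export
setMethod("ages", "RateSchedule", function(x) x@ages)
#' @rdname RateSchedule-class
#' @export
setMethod("incidence", "RateSchedule", function(x) x@incidence)
#' @rdname RateSchedule-class
#' @export
setMethod("mortality", "RateSchedule", function(x) x@mortality)

setMethod("show", "RateSchedule", function(object) {
    cat("RateSchedule over ages", min(object@ages), "-", max(object@ages),
        sprintf("(%d grid points)\n", length(object@ages)))
    cat(sprintf("  incidence/person-year: %.3g - %.3g\n",
                min(object@incidence), max(object@incidence)))
    cat(sprintf("  competing mortality:   %.3g - %.3g\n",
                min(object@mortality), max(object@mortality)))
})

#' @rdname ORTable-class
#' @param x,object a polyrisk S4 object.
#' @export
setGeneric("orTable", function(x) standardGeneric("orTable"))
#' @rdname ORTable-class
#' @export
setGeneric("betaCoef", function(x) standardGeneric("betaCoef"))
#' @rdname ORTable-class
#' @export
setGeneric("betaCov", function(x) standardGeneric("betaCov"))
#' @rdname ORTable-class
#' @export
setGeneric("referenceCategory", function(x) standardGeneric("referenceCategory"))
#' @rdname ORTable-class
#' @export
setGeneric("outcomeLabel", function(x) standardGeneric("outcomeLabel"))

#' @rdname ORTable-class
#' @export
setMethod("orTable", "ORTable", function(x) x@stats)
#' @rdname ORTable-class
#' @export
setMethod("betaCoef", "ORTable", function(x) x@beta)
#' @rdname ORTable-class
#' @export
setMethod("betaCov", "ORTable", function(x) x@sigma)
#' @rdname ORTable-class
#' @export
setMethod("referenceCategory", "ORTable", function(x) x@reference)
#' @rdname ORTable-class
#' @export
setMethod("outcomeLabel", "ORTable", function(x) x@outcome)

setMethod("show", "ORTable", function(object) {
    cat(sprintf("ORTable (%s vs controls), reference = %s\n",
                object@outcome, object@reference))
    df <- object@stats
    df$or <- signif(df$or, 4)
    df$ciLo <- signif(df$ciLo, 4)
    df$ciHi <- signif(df$ciHi, 4)
    df$p <- signif(df$p, 3)
    print(df, row.names = FALSE)
})

#' @rdname CategoryFrequencies-class
#' @param x,object a polyrisk S4 object.
#' @export
setGeneric("popFrequencies", function(x) standardGeneric("popFrequencies"))
#' @rdname CategoryFrequencies-class
#' @export
setGeneric("prevalence", function(x) standardGeneric("prevalence"))
#' @rdname CategoryFrequencies-class
#' @export
setGeneric("caseFrequencies", function(x) standardGeneric("caseFrequencies"))
#' @rdname CategoryFrequencies-class
#' @export
setGeneric("controlFrequencies", function(x) standardGeneric("controlFrequencies"))

#' @rdname CategoryFrequencies-class
#' @export
setMethod("popFrequencies", "CategoryFrequencies",
          function(x) setNames(x@p, x@categories))
#' @rdname CategoryFrequencies-class
#' @export
setMethod("prevalence", "CategoryFrequencies", function(x) x@prevalence)
#' @rdname CategoryFrequencies-class
#' @export
setMethod("caseFrequencies", "CategoryFrequencies",
          function(x) setNames(x@fCase, x@categories))
#' @rdname CategoryFrequencies-class
#' @export
setMethod("controlFrequencies", "CategoryFrequencies",
          function(x) setNames(x@fCtrl, x@categories))

setMethod("show", "CategoryFrequencies", function(object) {
    cat(sprintf("CategoryFrequencies (prevalence = %.3f)\n", object@prevalence))
    print(round(setNames(object@p, object@categories), 6))
})

#' @rdname AbsoluteRiskCurve-class
#' @param x,object a polyrisk S4 object.
#' @export
setGeneric("riskEstimates", function(x) standardGeneric("riskEstimates"))
#' @rdname AbsoluteRiskCurve-class
#' @export
setGeneric("riskLower", function(x) standardGeneric("riskLower"))
#' @rdname AbsoluteRiskCurve-class
#' @export
setGeneric("riskUpper", function(x) standardGeneric("riskUpper"))
#' @rdname AbsoluteRiskCurve-class
#' @export
setGeneric("nIterations", function(x) standardGeneric("nIterations"))

#' @rdname AbsoluteRiskCurve-class
#' @export
setMethod("ages", "AbsoluteRiskCurve", function(x) x@ages)
#' @rdname AbsoluteRiskCurve-class
#' @export
setMethod("riskEstimates", "AbsoluteRiskCurve", function(x) x@ar)
#' @rdname AbsoluteRiskCurve-class
#' @export
setMethod("riskLower", "AbsoluteRiskCurve", function(x) x@ciLo)
#' @rdname AbsoluteRiskCurve-class
#' @export
setMethod("riskUpper", "AbsoluteRiskCurve", function(x) x@ciHi)
#' @rdname AbsoluteRiskCurve-class
#' @export
setMethod("nIterations", "AbsoluteRiskCurve", function(x) x@nIter)

setMethod("show", "AbsoluteRiskCurve", function(object) {
    last <- nrow(object@ar)
    cat(sprintf("AbsoluteRiskCurve, ages %d-%d, %d categories, nIter = %d\n",
                min(object@ages), max(object@ages), ncol(object@ar),
                object@nIter))
    cat(sprintf("  cumulative risk by age %d:\n", object@ages[last]))
    out <- data.frame(category = colnames(object@ar),
                      ar = signif(object@ar[last, ], 4),
                      ciLo = signif(object@ciLo[last, ], 4),
                      ciHi = signif(object@ciHi[last, ], 4))
    print(out, row.names = FALSE)
})

#' @rdname InteractionTest-class
#' @param x,object a polyrisk S4 object.
#' @export
setGeneric("lrtP", function(x) standardGeneric("lrtP"))
#' @rdname InteractionTest-class
#' @export
setGeneric("waldP", function(x) standardGeneric("waldP"))

#' @rdname InteractionTest-class
#' @export
setMethod("lrtP", "InteractionTest", function(x) x@lrtP)
#' @rdname InteractionTest-class
#' @export
setMethod("waldP", "InteractionTest", function(x) x@waldP)

setMethod("show", "InteractionTest", function(object) {
    cat("Multiplicative interaction (PRS category x carrier)\n")
    cat(sprintf("  LRT:  chi2 = %.4f, df = %d, p = %.4g\n",
                object@lrtStat, object@lrtDf, object@lrtP))
    cat(sprintf("  Wald: chi2 = %.4f, df = %d, p = %.4g\n",
                object@waldStat, object@waldDf, object@waldP))
})

#' @rdname GenoCohort-class
#' @param x,object a polyrisk S4 object.
#' @export
setGeneric("carrierStatus", function(x) standardGeneric("carrierStatus"))
#' @rdname GenoCohort-class
#' @export
setGeneric("prsScores", function(x) standardGeneric("prsScores"))
#' @rdname GenoCohort-class
#' @export
setGeneric("prsCategories", function(x) standardGeneric("prsCategories"))
#' @rdname GenoCohort-class
#' @export
setGeneric("jointCategories", function(x) standardGeneric("jointCategories"))
#' @rdname GenoCohort-class
#' @export
setGeneric("cohortData", function(x) standardGeneric("cohortData"))

#' @rdname GenoCohort-class
#' @export
setMethod("carrierStatus", "GenoCohort",
          function(x) setNames(colData(x)$carrier, colnames(x)))
#' @rdname GenoCohort-class
#' @export
setMethod("prsScores", "GenoCohort",
          function(x) setNames(colData(x)$prsScore, colnames(x)))
#' @rdname GenoCohort-class
#' @export
setMethod("prsCategories", "GenoCohort",
          function(x) setNames(colData(x)$prsCategory, colnames(x)))
#' @rdname GenoCohort-class
#' @export
setMethod("jointCategories", "GenoCohort",
          function(x) setNames(colData(x)$jointCategory, colnames(x)))
#' @rdname GenoCohort-class
#' @export
setMethod("cohortData", "GenoCohort", function(x) {
    df <- as.data.frame(colData(x))
    df$individual_id <- colnames(x)
    df
})

setMethod("show", "GenoCohort", function(object) {
    cd <- colData(object)
    cat(sprintf("GenoCohort: %d individuals (%d cases, %d controls), %d PRS variants\n",
                ncol(object), sum(cd$status == "case"),
                sum(cd$status == "control"), nrow(object)))
    cat("  joint categories:\n")
    print(table(cd$jointCategory))
})
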