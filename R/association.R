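# Six-category joint logistic model, marginal models, interaction tests.
# Fits are plain maximum likelihood via binomial IRLS (stats::glm,
# log-likelihood tolerance 1e-8, max 100 iterations); an optional
# Jeffreys-prior penalized fit is available for sparse tables.

.covariateFormulaParts <- function(data) {
    parts <- c("age")
    if (is.factor(data$study) && nlevels(droplevels(data$study)) > 1L)
        parts <- c(parts, "study")
    parts <- c(parts, intersect(paste0("pc", 1:10), names(data)))
    parts
}

# Jeffreys-prior (hat-diagonal adjusted score) penalized logistic fit.
.firthFit <- function(X, y, tol = 1e-8, maxit = 100L) {
    beta <- rep(0, ncol(X))
    for (it in seq_len(maxit)) {
        eta <- drop(X %*% beta)
        p <- stats::plogis(eta)
        w <- p * (1 - p)
        XW <- X * w
        info <- crossprod(X, XW)
        infoInv <- solve(info)
        h <- rowSums((X %*% infoInv) * XW)
        U <- crossprod(X, y - p + h * (0.5 - p))
        step <- drop(infoInv %*% U)
        beta <- beta + step
        if (max(abs(step)) < tol) break
    }
    list(coefficients = setNames(beta, colnames(X)), vcov = infoInv)
}

#' Fit a logistic category model
#'
#' Workhorse behind \code{\link{fitJointModel}} and
#' \code{\link{fitMarginalModels}}: maximum-likelihood logistic regression of
#' case status on category indicators (with a chosen reference) plus optional
#' adjustment covariates. Categories with zero cases or zero controls are
#' excluded from the fit and reported with an undefined OR and a flag;
#' per-category separation is flagged when estimates diverge.
#'
#' @param status logical or 0/1 vector (TRUE/1 = case).
#' @param category factor of category labels.
#' @param ref reference category label.
#' @param covariates optional data.frame of adjustment covariates (columns
#'   \code{age}, \code{study}, \code{pc1}..\code{pc10} are used when present).
#' @param outcome label stored in the result.
#' @param firth use the Jeffreys-prior penalized fit (default FALSE: plain
#'   ML, reproducing conventional wide CIs in sparse cells).
#' @return An \linkS4class{ORTable}.
#' @export
fitCategoryModel <- function(status, category, ref, covariates = NULL,
                             outcome = "overall", firth = FALSE) {
    y <- as.integer(as.logical(status))
    if (all(y == 1L) || all(y == 0L))
        stop("need at least one case and one control")
    category <- droplevels(factor(category))
    if (!ref %in% levels(category))
        stop("reference category '", ref, "' not present")
    counts <- table(category, factor(y, levels = 0:1))
    nCtrl <- counts[, 1L]
    nCase <- counts[, 2L]
    lev <- levels(category)
    estimable <- nCase > 0 & nCtrl > 0
    if (!estimable[ref])
        stop("reference category has zero cases or zero controls")
    if (any(pmin(nCase, nCtrl)[estimable] < 5))
        warning("sparse category cell(s) (<5 cases or controls); ",
                "plain ML estimates may be unstable")

    if (sum(estimable) < 2L) {
        warning("no estimable non-reference category (empty cells); ",
                "all ORs undefined")
        stats <- data.frame(category = lev, nCases = as.integer(nCase),
                            nControls = as.integer(nCtrl), or = NA_real_,
                            ciLo = NA_real_, ciHi = NA_real_, p = NA_real_,
                            flag = "undefined_empty_cell",
                            stringsAsFactors = FALSE)
        stats$or[stats$category == ref] <- 1
        stats$flag[stats$category == ref] <- "reference"
        return(new("ORTable", outcome = outcome, reference = ref,
                   stats = stats, beta = setNames(numeric(0), character(0)),
                   sigma = matrix(0, 0, 0)))
    }
    keepRows <- category %in% lev[estimable]
    fcat <- factor(as.character(category[keepRows]),
                   levels = c(ref, setdiff(lev[estimable], ref)))
    df <- data.frame(y = y[keepRows], .cat = fcat)
    rhs <- ".cat"
    if (!is.null(covariates)) {
        cov <- covariates[keepRows, , drop = FALSE]
        cov$study <- if ("study" %in% names(cov)) droplevels(factor(cov$study))
        parts <- intersect(.covariateFormulaParts(cov), names(cov))
        for (p in parts) df[[p]] <- cov[[p]]
        rhs <- paste(c(".cat", parts), collapse = " + ")
    }
    form <- stats::as.formula(paste("y ~", rhs))
    if (firth) {
        X <- stats::model.matrix(form, df)
        fit <- .firthFit(X, df$y)
        cf <- fit$coefficients
        V <- fit$vcov
        dimnames(V) <- list(names(cf), names(cf))
    } else {
        g <- stats::glm(form, family = stats::binomial(), data = df,
                        control = stats::glm.control(epsilon = 1e-8,
                                                     maxit = 100))
        if (!g$converged)
            stop("logistic fit did not converge within 100 IRLS iterations")
        cf <- stats::coef(g)
        V <- stats::vcov(g)
    }
    catTerms <- paste0(".cat", setdiff(levels(fcat), ref))
    catNames <- setdiff(levels(fcat), ref)
    beta <- cf[catTerms]
    names(beta) <- catNames
    keepBeta <- !is.na(beta)
    beta <- beta[keepBeta]
    sigma <- V[catTerms[keepBeta], catTerms[keepBeta], drop = FALSE]
    dimnames(sigma) <- list(names(beta), names(beta))
    se <- sqrt(diag(sigma))

    stats <- data.frame(category = lev, nCases = as.integer(nCase),
                        nControls = as.integer(nCtrl), or = NA_real_,
                        ciLo = NA_real_, ciHi = NA_real_, p = NA_real_,
                        flag = "", stringsAsFactors = FALSE)
    stats$or[stats$category == ref] <- 1
    stats$flag[stats$category == ref] <- "reference"
    for (g2 in names(beta)) {
        i <- which(stats$category == g2)
        b <- beta[g2]; s <- se[g2]
        stats$or[i] <- exp(b)
        stats$ciLo[i] <- exp(b - 1.96 * s)
        stats$ciHi[i] <- exp(b + 1.96 * s)
        stats$p[i] <- 2 * stats::pnorm(-abs(b / s))
        if (abs(b) > 15 || s > 100)
            stats$flag[i] <- "possible_separation"
    }
    stats$flag[!estimable & stats$category != ref] <- "undefined_empty_cell"
    new("ORTable", outcome = outcome, reference = ref, stats = stats,
        beta = beta, sigma = sigma)
}

.outcomeRows <- function(data, outcome) {
    isCtrl <- data$status == "control"
    keep <- switch(outcome,
        overall = rep(TRUE, nrow(data)),
        aggressive = isCtrl | data$outcomeClass %in%
            c("aggressive", "metastatic-aggressive"),
        nonaggressive = isCtrl | data$outcomeClass == "nonaggressive",
        metastatic = isCtrl | data$outcomeClass == "metastatic-aggressive",
        stop("unknown outcome: ", outcome))
    keep
}

#' Fit the six-category joint PRS-by-carrier model
#'
#' Logistic regression of case status on the six joint PRS-tertile-by-carrier
#' categories (reference: intermediate-PRS non-carriers), adjusted for age,
#' study indicators and the first 10 ancestry principal components. Outcomes
#' contrast controls against all cases (\code{overall}; unclassified cases
#' included) or the aggressive / nonaggressive / metastatic case subsets.
#'
#' @param cohort a \linkS4class{GenoCohort}.
#' @param outcome one of \code{overall}, \code{aggressive},
#'   \code{nonaggressive}, \code{metastatic}.
#' @param firth use the penalized fit (default FALSE).
#' @return An \linkS4class{ORTable}.
#' @export
fitJointModel <- function(cohort,
                          outcome = c("overall", "aggressive",
                                      "nonaggressive", "metastatic"),
                          firth = FALSE) {
    outcome <- match.arg(outcome)
    data <- cohortData(cohort)
    data <- data[.outcomeRows(data, outcome), , drop = FALSE]
    fitCategoryModel(data$status == "case", data$jointCategory,
                     ref = "intermediate_noncarrier",
                     covariates = data, outcome = outcome, firth = firth)
}

#' Fit marginal carrier and PRS models
#'
#' Two separate adjusted logistic fits with the same covariate set as the
#' joint model: carrier status alone (non-carrier reference) and PRS tertile
#' alone (intermediate reference).
#'
#' @inheritParams fitJointModel
#' @return list with elements \code{carrier} and \code{prs}, each an
#'   \linkS4class{ORTable}.
#' @export
fitMarginalModels <- function(cohort,
                              outcome = c("overall", "aggressive",
                                          "nonaggressive", "metastatic"),
                              firth = FALSE) {
    outcome <- match.arg(outcome)
    data <- cohortData(cohort)
    data <- data[.outcomeRows(data, outcome), , drop = FALSE]
    y <- data$status == "case"
    carrierCat <- factor(ifelse(data$carrier, "carrier", "noncarrier"),
                         levels = c("noncarrier", "carrier"))
    list(carrier = fitCategoryModel(y, carrierCat, ref = "noncarrier",
                                    covariates = data, outcome = outcome,
                                    firth = firth),
         prs = fitCategoryModel(y, data$prsCategory, ref = "intermediate",
                                covariates = data, outcome = outcome,
                                firth = firth))
}

#' Test multiplicative interaction between PRS and carrier status
#'
#' Compares the main-effects logistic model (PRS tertile indicators + carrier
#' + covariates) with the model adding the PRS-by-carrier product terms, via
#' the likelihood ratio test (2 df on the tertile scale) and the joint Wald
#' test on the product coefficients. With \code{scale = "continuous"} the
#' product of the standardized PRS with carrier status is tested instead
#' (1 df).
#'
#' @inheritParams fitJointModel
#' @param scale \code{"tertile"} (default) or \code{"continuous"}.
#' @return An \linkS4class{InteractionTest}.
#' @export
testInteraction <- function(cohort,
                            outcome = c("overall", "aggressive",
                                        "nonaggressive", "metastatic"),
                            scale = c("tertile", "continuous")) {
    outcome <- match.arg(outcome)
    scale <- match.arg(scale)
    data <- cohortData(cohort)
    data <- data[.outcomeRows(data, outcome), , drop = FALSE]
    df <- data.frame(y = as.integer(data$status == "case"),
                     carrier = as.integer(data$carrier),
                     prsCategory = droplevels(stats::relevel(
                         data$prsCategory, ref = "intermediate")),
                     age = data$age, study = droplevels(factor(data$study)))
    for (p in paste0("pc", 1:10)) df[[p]] <- data[[p]]
    df$prsStd <- as.numeric(scale(data$prsScore))
    covParts <- .covariateFormulaParts(df)
    main <- if (scale == "tertile") "prsCategory + carrier"
            else "prsStd + carrier"
    inter <- if (scale == "tertile") "prsCategory:carrier"
             else "prsStd:carrier"
    ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
    f0 <- stats::as.formula(paste("y ~", paste(c(main, covParts),
                                               collapse = " + ")))
    f1 <- stats::as.formula(paste("y ~", paste(c(main, inter, covParts),
                                               collapse = " + ")))
    g0 <- stats::glm(f0, family = stats::binomial(), data = df,
                     control = ctrl)
    g1 <- stats::glm(f1, family = stats::binomial(), data = df,
                     control = ctrl)
    lrtStat <- max(0, 2 * (as.numeric(stats::logLik(g1)) -
                               as.numeric(stats::logLik(g0))))
    lrtDf <- attr(stats::logLik(g1), "df") - attr(stats::logLik(g0), "df")
    expectedDf <- if (scale == "tertile") 2L else 1L
    if (lrtDf < expectedDf)
        warning("empty product-term cell(s): interaction tested with ",
                lrtDf, " df instead of ", expectedDf)
    if (lrtDf < 1L) stop("no estimable interaction terms")
    lrtP <- stats::pchisq(lrtStat, df = lrtDf, lower.tail = FALSE)

    cf <- stats::coef(g1)
    prodTerms <- grep(":", names(cf), value = TRUE)
    prodTerms <- prodTerms[!is.na(cf[prodTerms])]
    b <- cf[prodTerms]
    V <- stats::vcov(g1)[prodTerms, prodTerms, drop = FALSE]
    waldStat <- drop(t(b) %*% solve(V, b))
    waldDf <- length(b)
    waldP <- stats::pchisq(waldStat, df = waldDf, lower.tail = FALSE)
    new("InteractionTest", lrtStat = lrtStat, lrtDf = as.integer(lrtDf),
        lrtP = lrtP, waldStat = waldStat, waldDf = as.integer(waldDf),
        waldP = waldP)
}

#' Write an ORTable (and its covariance) to TSV
#'
#' @param ort an \linkS4class{ORTable}.
#' @param path output TSV path for the per-category statistics.
#' @param covPath optional path for the category log-OR covariance matrix.
#' @return \code{path}, invisibly.
#' @export
writeORTable <- function(ort, path, covPath = NULL) {
    df <- orTable(ort)
    df <- cbind(outcome = outcomeLabel(ort), df)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(covPath)) {
        V <- betaCov(ort)
        utils::write.table(data.frame(category = rownames(V), V,
                                      check.names = FALSE),
                           covPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}
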