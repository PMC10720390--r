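# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: independent PRS variants with log-additive weights,
# rare P/LP/D carrier status, disease risk log-additive in carrier status
# and PRS tertile, outcome-dependent (case-enriched) sampling, and clinical
# fields that reproduce the intended phenotype classes through
# classifyPhenotype().

#' Simulation configuration
#'
#' Builds and validates the generator configuration. Defaults mirror the
#' study conditions where they are printed: carrier frequency 0.6\% in
#' controls, carrier OR 4.5, high/low PRS tertile ORs 3.0 and 0.57, a 37\%
#' aggressive case mix, population prevalence 16.7\%, and a case-enriched
#' sample at the study's case fraction.
#'
#' @param nIndividuals sampled cohort size (default 3220).
#' @param nPrsVariants number of PRS variants (default 254).
#' @param alleleFreqRange effect-allele frequency range (uniform draw).
#' @param weightScale median per-allele weight (weights are log-normal about
#'   it); the default gives raw control scores with median in the mid-20s,
#'   as multi-ancestry weight sets produce.
#' @param carrierFreq population P/LP/D carrier frequency (default 0.006).
#' @param trueLogOR named list of true log-ORs: \code{carrier},
#'   \code{highVsInt}, \code{lowVsInt} (tertile scale) and \code{prsPerSd}
#'   (additional continuous effect, default 0).
#' @param caseFraction case fraction of the sampled cohort (default
#'   1796/3220).
#' @param aggressiveFraction aggressive fraction among cases (default 0.37).
#' @param metastaticFraction metastatic fraction among aggressive cases
#'   (default 0.3).
#' @param interactionLogOR departure from log-additivity, added to both
#'   carrier-by-low and carrier-by-high product terms (default 0).
#' @param prevalencePop population disease prevalence targeted by the
#'   intercept solver (default 0.167).
#' @param missingClinical fraction of cases with missing clinical fields
#'   (these become unclassified; default 0.02).
#' @param seed integer RNG seed.
#' @return validated configuration list (class \code{SimConfig}).
#' @export
simConfig <- function(nIndividuals = 3220L, nPrsVariants = 254L,
                      alleleFreqRange = c(0.005, 0.49), weightScale = 0.19,
                      carrierFreq = 0.006,
                      trueLogOR = list(carrier = log(4.5),
                                       highVsInt = log(3.0),
                                       lowVsInt = log(0.57), prsPerSd = 0),
                      caseFraction = 1796 / 3220,
                      aggressiveFraction = 0.37, metastaticFraction = 0.3,
                      interactionLogOR = 0, prevalencePop = 0.167,
                      missingClinical = 0.02, seed = 1L) {
    stopifnot(nIndividuals >= 10L, nPrsVariants >= 1L,
              alleleFreqRange[1L] > 0, alleleFreqRange[2L] < 0.5,
              alleleFreqRange[1L] < alleleFreqRange[2L],
              carrierFreq > 0, carrierFreq < 1,
              caseFraction > 0, caseFraction < 1,
              aggressiveFraction >= 0, aggressiveFraction <= 1,
              metastaticFraction >= 0, metastaticFraction <= 1,
              prevalencePop > 0, prevalencePop < 1,
              missingClinical >= 0, missingClinical < 1)
    need <- c("carrier", "highVsInt", "lowVsInt", "prsPerSd")
    miss <- setdiff(need, names(trueLogOR))
    if (length(miss))
        stop("trueLogOR missing component(s): ", paste(miss, collapse = ", "))
    cfg <- list(nIndividuals = as.integer(nIndividuals),
                nPrsVariants = as.integer(nPrsVariants),
                alleleFreqRange = alleleFreqRange,
                weightScale = weightScale, carrierFreq = carrierFreq,
                trueLogOR = trueLogOR, caseFraction = caseFraction,
                aggressiveFraction = aggressiveFraction,
                metastaticFraction = metastaticFraction,
                interactionLogOR = interactionLogOR,
                prevalencePop = prevalencePop,
                missingClinical = missingClinical, seed = as.integer(seed))
    class(cfg) <- "SimConfig"
    cfg
}

.solveIntercept <- function(lp, target) {
    f <- function(a) mean(stats::plogis(a + lp)) - target
    out <- try(stats::uniroot(f, c(-30, 30), tol = 1e-10), silent = TRUE)
    if (inherits(out, "try-error"))
        stop("unattainable case fraction / prevalence: intercept solver failed")
    out$root
}

.studyLabels <- c("MEC", "LAAPC", "LAC", "UGPCS")

.clinicalFields <- function(type, uganda, n) {
    # gleason, stage, psa, died chosen so classifyPhenotype reproduces `type`
    gl <- integer(n); st <- character(n); psa <- numeric(n)
    died <- rep(FALSE, n)
    if (type == "nonaggressive") {
        gl[] <- sample(5:7, n, replace = TRUE)
        st[] <- "localized"
        psa[] <- round(stats::runif(n, 0.5, 20), 1)
    } else if (type == "aggressive") {
        gl[] <- sample(8:10, n, replace = TRUE)
        st[] <- sample(c("localized", "regional"), n, replace = TRUE)
        psa[] <- round(stats::runif(n, 4, 45), 1)
        if (!uganda) died[stats::runif(n) < 0.15] <- TRUE
        if (uganda) psa[] <- round(stats::runif(n, 51, 99), 1)
    } else { # metastatic-aggressive
        gl[] <- sample(8:10, n, replace = TRUE)
        st[] <- "metastatic"
        psa[] <- round(stats::runif(n, 30, 95), 1)
        if (uganda) psa[] <- round(stats::runif(n, 101, 900), 1)
    }
    if (uganda) st[] <- NA_character_
    list(gleason = gl, stage = st, psa = psa, died = died)
}

#' Generate a complete synthetic case-control cohort
#'
#' Simulates a source population (independent PRS variant dosages from
#' binomial(2, f_j), fixed log-normal weights, Bernoulli carrier status,
#' noise covariates with small true effects) whose disease status follows a
#' logistic model that is log-additive in carrier status and PRS tertile
#' (population-tertile anchored), with an optional multiplicative
#' interaction term. The intercept is solved numerically so the population
#' prevalence matches the configuration, and cases/controls are then sampled
#' outcome-dependently to the configured case fraction, mirroring a
#' case-enriched study design. Case types (aggressive / nonaggressive /
#' metastatic) are assigned by the configured fractions and the clinical
#' fields (Gleason, stage, PSA, death) are filled per country so that
#' \code{\link{classifyPhenotype}} reproduces the intended class.
#'
#' @param cfg a \code{\link{simConfig}} object.
#' @param dir optional directory; when given, all outputs are written in the
#'   formats the readers consume (scoring TSV, dosage TSV, phenotype CSV,
#'   carrier TSV, truth JSON).
#' @return list with \code{scoring} (data.frame), \code{dosages}
#'   (individuals x variants matrix), \code{phenotypes} (data.frame),
#'   \code{carriers} (named logical), and \code{truth} (list: intercept, the
#'   six-category true log-ORs, population tertile cut points, prevalence).
#'   Deterministic given \code{cfg$seed}.
#' @export
generateCohort <- function(cfg, dir = NULL) {
    stopifnot(inherits(cfg, "SimConfig"))
    set.seed(cfg$seed)
    nv <- cfg$nPrsVariants
    nCases <- round(cfg$nIndividuals * cfg$caseFraction)
    nControls <- cfg$nIndividuals - nCases
    nPop <- max(cfg$nIndividuals,
                ceiling(1.2 * max(nCases / cfg$prevalencePop,
                                  nControls / (1 - cfg$prevalencePop))))

    f <- stats::runif(nv, cfg$alleleFreqRange[1L], cfg$alleleFreqRange[2L])
    w <- cfg$weightScale * exp(stats::rnorm(nv, 0, 0.5))
    vids <- sprintf("rs%06d", seq_len(nv))
    scoring <- data.frame(variant_id = vids,
                          chr = sample(1:22, nv, replace = TRUE),
                          pos = sample.int(2.4e8, nv),
                          effect_allele = sample(c("A", "C", "G", "T"), nv,
                                                 replace = TRUE),
                          other_allele = NA, weight = w,
                          stringsAsFactors = FALSE)
    scoring$other_allele <- vapply(scoring$effect_allele, function(a)
        sample(setdiff(c("A", "C", "G", "T"), a), 1L), character(1))

    G <- matrix(0, nrow = nPop, ncol = nv)
    for (j in seq_len(nv)) G[, j] <- stats::rbinom(nPop, 2L, f[j])
    colnames(G) <- vids
    prs <- drop(G %*% w)
    cut <- stats::quantile(prs, probs = c(1, 2) / 3, type = 7, names = FALSE)
    tert <- cut(prs, breaks = c(-Inf, cut[1L], cut[2L], Inf),
                labels = c("low", "intermediate", "high"), right = FALSE)
    carrier <- stats::runif(nPop) < cfg$carrierFreq

    study <- sample(.studyLabels, nPop, replace = TRUE,
                    prob = c(0.5, 0.05, 0.15, 0.3))
    country <- ifelse(study == "UGPCS", "Uganda", "US")
    age <- pmax(40L, pmin(90L, round(stats::rnorm(nPop, 67, 8))))
    pcs <- matrix(stats::rnorm(nPop * 10L), ncol = 10L,
                  dimnames = list(NULL, paste0("pc", 1:10)))

    b <- cfg$trueLogOR
    lp <- b$carrier * carrier +
        b$highVsInt * (tert == "high") + b$lowVsInt * (tert == "low") +
        b$prsPerSd * as.numeric(scale(prs)) +
        cfg$interactionLogOR * carrier * (tert == "high") +
        cfg$interactionLogOR * carrier * (tert == "low") +
        0.1 * (age - 67) / 10 + 0.1 * (study == "UGPCS") +
        0.05 * pcs[, 1L] + 0.05 * pcs[, 2L]
    alpha <- .solveIntercept(lp, cfg$prevalencePop)
    y <- stats::runif(nPop) < stats::plogis(alpha + lp)
    if (sum(y) < nCases || sum(!y) < nControls)
        stop("unattainable case fraction: simulated population too small ",
             "for the requested case/control counts")
    idx <- c(sample(which(y), nCases), sample(which(!y), nControls))
    idx <- sample(idx)                       # shuffle row order
    ids <- sprintf("IND%06d", seq_along(idx))

    status <- ifelse(y[idx], "case", "control")
    caseIdx <- which(status == "case")
    type <- rep(NA_character_, length(idx))
    nAgg <- round(length(caseIdx) * cfg$aggressiveFraction)
    aggIdx <- sample(caseIdx, nAgg)
    type[caseIdx] <- "nonaggressive"
    type[aggIdx] <- "aggressive"
    metIdx <- sample(aggIdx, round(nAgg * cfg$metastaticFraction))
    type[metIdx] <- "metastatic-aggressive"

    ph <- data.frame(individual_id = ids, status = status,
                     age = age[idx], study = study[idx],
                     country = country[idx],
                     gleason = NA_integer_, stage = NA_character_,
                     psa = NA_real_, died_of_disease = FALSE,
                     family_history = stats::runif(length(idx)) < 0.12,
                     stringsAsFactors = FALSE)
    for (p in paste0("pc", 1:10)) ph[[p]] <- pcs[idx, p]
    ug <- ph$country == "Uganda"
    for (tp in c("nonaggressive", "aggressive", "metastatic-aggressive")) {
        for (isUg in c(FALSE, TRUE)) {
            sel <- which(!is.na(type) & type == tp & ug == isUg)
            if (!length(sel)) next
            cf <- .clinicalFields(tp, isUg, length(sel))
            ph$gleason[sel] <- cf$gleason
            ph$stage[sel] <- cf$stage
            ph$psa[sel] <- cf$psa
            ph$died_of_disease[sel] <- cf$died
        }
    }
    # Uganda controls screened at PSA < 4
    ctrlUg <- which(status == "control" & ug)
    ph$psa[ctrlUg] <- round(stats::runif(length(ctrlUg), 0.1, 3.9), 1)
    # clinical missingness -> unclassified cases
    hide <- caseIdx[stats::runif(length(caseIdx)) < cfg$missingClinical]
    ph$gleason[hide] <- NA_integer_
    ph$stage[hide] <- NA_character_
    ph$psa[hide] <- NA_real_
    ph$died_of_disease[hide] <- FALSE

    dosages <- G[idx, , drop = FALSE]
    rownames(dosages) <- ids
    carriers <- setNames(carrier[idx], ids)
    ilor <- cfg$interactionLogOR
    truth <- list(
        intercept = alpha,
        trueLogOR = cfg$trueLogOR,
        categoryLogOR = c(low_noncarrier = b$lowVsInt,
                          high_noncarrier = b$highVsInt,
                          low_carrier = b$lowVsInt + b$carrier + ilor,
                          intermediate_carrier = b$carrier,
                          high_carrier = b$highVsInt + b$carrier + ilor),
        tertileCutpoints = cut,
        prevalencePop = cfg$prevalencePop,
        caseType = setNames(type, ids))

    out <- list(scoring = scoring, dosages = dosages, phenotypes = ph,
                carriers = carriers, truth = truth)
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        writeScoringFile(scoring, file.path(dir, "scoring.tsv"))
        writeDosages(dosages, file.path(dir, "dosages.tsv"))
        utils::write.csv(ph, file.path(dir, "phenotypes.csv"),
                         row.names = FALSE, quote = FALSE, na = "")
        utils::write.table(
            data.frame(individual_id = ids, carrier = carriers),
            file.path(dir, "carriers.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        jsonlite::write_json(truth[c("intercept", "trueLogOR",
                                     "categoryLogOR", "tertileCutpoints",
                                     "prevalencePop")],
                             file.path(dir, "truth.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    out
}

#' Generate rare-variant annotations with known truth labels
#'
#' Emits a mixture of record types covering every classifier rule branch:
#' truncating variants, ClinVar-asserted missense (with occasional benign
#' conflicts), in-silico-consensus-damaging missense, and non-P/LP/D records
#' (excluded consequence classes with deliberately strong other evidence,
#' common variants, missense without sufficient evidence, and missense with
#' fewer than three available predictors). Truth labels refer to the default
#' \code{"all"} consensus rule.
#'
#' @param genePanel gene symbols to draw from.
#' @param nPlpd number of true P/LP/D records (default 51).
#' @param nBenign number of non-P/LP/D records (default 100).
#' @param seed RNG seed.
#' @return annotation data.frame with an extra logical \code{plpd_truth}
#'   column.
#' @export
generateAnnotations <- function(genePanel = c("BRCA2", "ATM", "NBN", "PALB2"),
                                nPlpd = 51L, nBenign = 100L, seed = 1L) {
    stopifnot(nPlpd >= 0L, nBenign >= 0L)
    set.seed(seed)
    tools <- .insilicoTools
    pasteCalls <- function(calls) paste(names(calls), calls, sep = ":",
                                        collapse = ";")
    randCalls <- function() {
        calls <- sample(c("damaging", "tolerated", "missing"), 5L,
                        replace = TRUE)
        pasteCalls(setNames(calls, tools))
    }
    damagingCalls <- function() pasteCalls(setNames(rep("damaging", 5L),
                                                    tools))
    labs <- c("Ambry", "SCRP", "InVitae", "GeneDX", "Emory", "InSiGHT")
    rows <- vector("list", nPlpd + nBenign)
    k <- 0L
    mkRow <- function(cons, clinvar, insilico, maf, truth) {
        k <<- k + 1L
        rows[[k]] <<- data.frame(
            variant_id = sprintf("var%04d", k),
            gene = sample(genePanel, 1L), consequence = cons,
            clinvar = clinvar, insilico = insilico, maf = maf,
            plpd_truth = truth, stringsAsFactors = FALSE)
    }
    plpdBranch <- rep_len(c("truncating", "clinvar", "insilico",
                            "clinvar_conflict", "exon_boundary"), nPlpd)
    for (b in plpdBranch) {
        maf <- signif(stats::runif(1, 1e-4, 0.009), 3)
        switch(b,
            truncating = mkRow(sample(.truncatingClasses, 1L), "",
                               randCalls(), maf, TRUE),
            clinvar = mkRow("missense",
                            paste0(sample(labs, 1L), ":",
                                   sample(c("pathogenic",
                                            "likely_pathogenic"), 1L)),
                            randCalls(), maf, TRUE),
            clinvar_conflict = mkRow("missense",
                paste0(sample(labs, 1L), ":pathogenic;",
                       sample(labs, 1L), ":benign"),
                randCalls(), maf, TRUE),
            insilico = mkRow("missense", "", damagingCalls(), maf, TRUE),
            exon_boundary = mkRow("exon_boundary_codon_change", "",
                                  damagingCalls(), maf, TRUE))
    }
    benignBranch <- rep_len(c("excluded", "common", "weak", "few_predictors"),
                            nBenign)
    for (b in benignBranch) {
        switch(b,
            excluded = mkRow(sample(.excludedClasses, 1L),
                             paste0(sample(labs, 1L), ":pathogenic"),
                             damagingCalls(),
                             signif(stats::runif(1, 1e-4, 0.009), 3), FALSE),
            common = mkRow(sample(c(.truncatingClasses, "missense"), 1L),
                           paste0(sample(labs, 1L), ":pathogenic"),
                           damagingCalls(),
                           signif(stats::runif(1, 0.011, 0.4), 3), FALSE),
            weak = mkRow("missense",
                         sample(c("", paste0(sample(labs, 1L), ":vus"),
                                  paste0(sample(labs, 1L), ":benign")), 1L),
                         pasteCalls(setNames(
                             sample(c("damaging", "damaging", "tolerated",
                                      "tolerated", "tolerated")), tools)),
                         signif(stats::runif(1, 1e-4, 0.009), 3), FALSE),
            few_predictors = mkRow("missense", "",
                pasteCalls(setNames(c("damaging", "damaging", "missing",
                                      "missing", "missing"), tools)),
                signif(stats::runif(1, 1e-4, 0.009), 3), FALSE))
    }
    out <- do.call(rbind, rows)
    out[sample(nrow(out)), , drop = FALSE]
}

#' Generate a synthetic rate schedule
#'
#' Stand-in for registry incidence/competing-mortality schedules: either
#' flat hazards or exponentially increasing hazards that double every 10
#' years from the anchor at the first age.
#'
#' The exponential defaults give a population lifetime (age 40-85) disease
#' risk of about 17\% under competing mortality, with yearly incidence near
#' 1\% at age 70 and competing mortality near 11\% at 85 — registry-like
#' magnitudes for an elevated-incidence male cancer.
#'
#' @param shape \code{"exponential"} (doubling per decade) or \code{"flat"}.
#' @param scale incidence anchor hazard at the first age (per person-year).
#' @param agesGrid integer age grid (default 40:85).
#' @param mortalityScale competing-mortality anchor (default 0.005).
#' @return A \linkS4class{RateSchedule}.
#' @export
generateRates <- function(shape = c("exponential", "flat"), scale = 1.2e-3,
                          agesGrid = 40:85, mortalityScale = 0.005) {
    shape <- match.arg(shape)
    if (scale <= 0 || mortalityScale <= 0) stop("scale must be positive")
    grow <- function(anchor) {
        if (shape == "flat") rep(anchor, length(agesGrid))
        else anchor * 2 ^ ((agesGrid - agesGrid[1L]) / 10)
    }
    inc <- grow(scale)
    mor <- grow(mortalityScale)
    if (any(inc >= 1) || any(mor >= 1))
        stop("generated hazard reaches 1; reduce the scale")
    RateSchedule(agesGrid, inc, mor)
}

#' Generate rare-variant genotypes consistent with carrier truth
#'
#' For pipeline exercises: carriers receive one heterozygous call at a
#' random true-P/LP/D variant; everyone may additionally carry non-P/LP/D
#' variants at a background rate, so carrier determination must rely on the
#' classifier, not on raw genotype presence.
#'
#' @param ids individual ids.
#' @param carriers named logical carrier truth.
#' @param annotations annotation data.frame with \code{plpd_truth}.
#' @param seed RNG seed.
#' @param backgroundRate per-variant het rate for non-P/LP/D variants.
#' @return individuals x variants allele-count matrix.
#' @export
generateRareGenotypes <- function(ids, carriers, annotations, seed = 1L,
                                  backgroundRate = 0.005) {
    set.seed(seed)
    m <- matrix(0L, nrow = length(ids), ncol = nrow(annotations),
                dimnames = list(ids, annotations$variant_id))
    plpdVars <- annotations$variant_id[annotations$plpd_truth]
    if (length(plpdVars)) {
        for (id in ids[carriers[ids]]) {
            m[id, plpdVars[sample.int(length(plpdVars), 1L)]] <- 1L
        }
    }
    benignVars <- annotations$variant_id[!annotations$plpd_truth]
    for (v in benignVars) {
        hit <- stats::runif(length(ids)) < backgroundRate
        m[hit, v] <- 1L
    }
    m
}
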