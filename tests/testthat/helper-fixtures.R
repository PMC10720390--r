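# Shared fixtures, built in code.

writeTempScoring <- function(df, file = tempfile(fileext = ".tsv")) {
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    file
}

scoringDF <- function(n = 3) {
    data.frame(variant_id = paste0("rs", seq_len(n)),
               chr = rep(1, n), pos = seq_len(n) * 1000,
               effect_allele = rep("A", n), other_allele = rep("G", n),
               weight = round(seq_len(n) * 0.12, 2))
}

writeTempRates <- function(df, file = tempfile(fileext = ".csv")) {
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
    file
}

# minimal phenotype record(s) with sensible defaults
phenoDF <- function(n = 1, status = "case", age = 65, study = "MEC",
                    country = "US", gleason = NA, stage = NA, psa = NA,
                    died = FALSE, ids = NULL) {
    df <- data.frame(individual_id = ids %||% sprintf("P%03d", seq_len(n)),
                     status = status, age = age, study = study,
                     country = country, gleason = gleason, stage = stage,
                     psa = psa, died_of_disease = died,
                     family_history = FALSE, stringsAsFactors = FALSE)
    for (p in paste0("pc", 1:10)) df[[p]] <- 0
    df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small cohort with exaggerated carrier frequency so all six joint cells
# are populated at modest n (unit-test scale, not the study conditions)
makeToyCohort <- function(n = 1200, seed = 42, carrierFreq = 0.08,
                          interactionLogOR = 0, ...) {
    cfg <- simConfig(nIndividuals = n, nPrsVariants = 40,
                     carrierFreq = carrierFreq, caseFraction = 0.5,
                     interactionLogOR = interactionLogOR, seed = seed, ...)
    sim <- generateCohort(cfg)
    ctrl <- sim$phenotypes$individual_id[sim$phenotypes$status == "control"]
    filt <- filterPolymorphic(sim$scoring, sim$dosages, ctrl)
    prs <- assignPRSCategories(computePRS(filt$model, sim$dosages, ctrl),
                               ctrl)
    cohort <- suppressWarnings(
        assembleCohort(sim$phenotypes, sim$dosages, sim$carriers, prs))
    list(cohort = cohort, sim = sim)
}

# assemble a cohort from generator output using the full PRS path
assembleFromSim <- function(sim) {
    ctrl <- sim$phenotypes$individual_id[sim$phenotypes$status == "control"]
    filt <- filterPolymorphic(sim$scoring, sim$dosages, ctrl)
    prs <- assignPRSCategories(computePRS(filt$model, sim$dosages, ctrl),
                               ctrl)
    suppressWarnings(
        assembleCohort(sim$phenotypes, sim$dosages, sim$carriers, prs))
}
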