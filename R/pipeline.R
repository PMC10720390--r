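# Pipeline orchestration: simulate/ingest -> classify -> PRS -> association
# -> absolute risk, driven by a YAML configuration, with a reproducible run
# manifest (config snapshot, seeds, file digests, versions, warnings).

.requireFields <- function(x, fields, where) {
    miss <- setdiff(fields, names(x))
    if (length(miss))
        stop("pipeline config: missing field(s) in '", where, "': ",
             paste(miss, collapse = ", "))
}

.validatePipelineConfig <- function(cfg) {
    .requireFields(cfg, c("seed", "outcomes", "absrisk"), "top level")
    if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L ||
        cfg$seed != as.integer(cfg$seed))
        stop("pipeline config: 'seed' must be a single integer")
    if (is.null(cfg$simulate) && is.null(cfg$inputs))
        stop("pipeline config: need either a 'simulate' or an 'inputs' block")
    if (!is.null(cfg$inputs)) {
        .requireFields(cfg$inputs,
                       c("scoring", "dosages", "phenotypes", "annotations",
                         "rare_genotypes", "rates"), "inputs")
        for (f in unlist(cfg$inputs))
            if (!file.exists(f)) stop("pipeline config: missing input ", f)
    }
    .requireFields(cfg$absrisk, c("n_iter", "age_start", "age_end"),
                   "absrisk")
    ok <- c("overall", "aggressive", "nonaggressive", "metastatic")
    if (!all(unlist(cfg$outcomes) %in% ok))
        stop("pipeline config: outcomes must be among ",
             paste(ok, collapse = ", "))
    invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate (or ingest), variant
#' classification, carrier determination, PRS scoring and tertile
#' assignment, cohort assembly, six-category and marginal association fits,
#' interaction test, and Monte Carlo absolute risk — writing every stage
#' output as TSV under \code{outDir} together with a JSON run manifest
#' (config snapshot, seeds, md5 digests of every output, package versions,
#' collected warnings). Rerunning with an identical config reproduces
#' identical outputs.
#'
#' @param config path to a YAML configuration or an equivalent named list.
#'   Required fields: \code{seed}, \code{outcomes} (subset of overall /
#'   aggressive / nonaggressive / metastatic), \code{absrisk} (with
#'   \code{n_iter}, \code{age_start}, \code{age_end}, optional
#'   \code{prevalence}, \code{w_aggressive}) and either \code{simulate}
#'   (fields forwarded to \code{\link{simConfig}} plus optional
#'   \code{n_plpd}, \code{n_benign}, \code{rates_scale}) or \code{inputs}
#'   (paths: scoring, dosages, phenotypes, annotations, rare_genotypes,
#'   rates).
#' @param outDir output directory (created if needed).
#' @return the run manifest, invisibly.
#' @export
runPipeline <- function(config, outDir) {
    cfg <- if (is.character(config)) yaml::read_yaml(config) else config
    .validatePipelineConfig(cfg)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    warningsSeen <- character(0)
    noteWarning <- function(w) {
        warningsSeen <<- c(warningsSeen, conditionMessage(w))
        invokeRestart("muffleWarning")
    }
    seed <- as.integer(cfg$seed)
    outcomes <- unlist(cfg$outcomes)

    withCallingHandlers(warning = noteWarning, {
        if (!is.null(cfg$simulate)) {
            simArgs <- cfg$simulate
            nPlpd <- simArgs$n_plpd %||% 51L
            nBenign <- simArgs$n_benign %||% 100L
            ratesScale <- simArgs$rates_scale %||% 1.2e-3
            simArgs$n_plpd <- simArgs$n_benign <- simArgs$rates_scale <- NULL
            sc <- do.call(simConfig, c(simArgs, list(seed = seed)))
            sim <- generateCohort(sc)
            scoring <- sim$scoring
            dosages <- sim$dosages
            phenotypes <- sim$phenotypes
            annotations <- generateAnnotations(nPlpd = nPlpd,
                                               nBenign = nBenign,
                                               seed = seed + 1L)
            rare <- generateRareGenotypes(phenotypes$individual_id,
                                          sim$carriers, annotations,
                                          seed = seed + 2L)
            annotations$plpd_truth <- NULL
            rates <- generateRates("exponential", scale = ratesScale,
                                   agesGrid = cfg$absrisk$age_start:
                                       cfg$absrisk$age_end)
        } else {
            scoring <- readScoringFile(cfg$inputs$scoring)
            dosages <- readDosages(cfg$inputs$dosages)
            phenotypes <- readPhenotypes(cfg$inputs$phenotypes)
            annotations <- readAnnotations(cfg$inputs$annotations)
            rare <- readDosages(cfg$inputs$rare_genotypes)
            rates <- readRateSchedule(cfg$inputs$rates)
        }

        message("[classify] ", nrow(annotations), " annotated variants")
        classification <- classifyVariants(annotations)
        carriers <- determineCarriers(rare, classification)

        message("[prs] scoring ", nrow(dosages), " individuals")
        controlIds <- phenotypes$individual_id[phenotypes$status == "control"]
        filt <- filterPolymorphic(scoring, dosages, controlIds)
        prs <- computePRS(filt$model, dosages, controlIds)
        prs <- assignPRSCategories(prs, controlIds)

        message("[assemble] building cohort")
        cohort <- assembleCohort(phenotypes, dosages, carriers, prs)

        message("[assoc] fitting models: ", paste(outcomes, collapse = ", "))
        orTables <- lapply(outcomes, function(oc) fitJointModel(cohort, oc))
        names(orTables) <- outcomes
        marginals <- fitMarginalModels(cohort, "overall")
        interaction <- testInteraction(cohort, "overall")

        message("[absrisk] Monte Carlo, ", cfg$absrisk$n_iter, " iterations")
        prev <- cfg$absrisk$prevalence %||% 0.167
        wAgg <- cfg$absrisk$w_aggressive %||% 0.37
        freqs <- cohortFrequencies(cohort, prev = prev)
        riskTable <- if (all(c("aggressive", "nonaggressive") %in% outcomes))
            monteCarloRisk(orTables$aggressive, freqs, rates,
                           nIter = cfg$absrisk$n_iter, seed = seed + 3L,
                           ortNonagg = orTables$nonaggressive, wAgg = wAgg)
        else
            monteCarloRisk(orTables[[1L]], freqs, rates,
                           nIter = cfg$absrisk$n_iter, seed = seed + 3L)

        writeClassification(classification,
                            file.path(outDir, "classification.tsv"))
        utils::write.table(
            data.frame(individual_id = names(carriers), carrier = carriers),
            file.path(outDir, "carriers.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        writePRS(prs, file.path(outDir, "prs.tsv"))
        for (oc in outcomes)
            writeORTable(orTables[[oc]],
                         file.path(outDir, paste0("or_joint_", oc, ".tsv")),
                         file.path(outDir, paste0("or_cov_", oc, ".tsv")))
        writeORTable(marginals$carrier,
                     file.path(outDir, "or_marginal_carrier.tsv"))
        writeORTable(marginals$prs, file.path(outDir, "or_marginal_prs.tsv"))
        utils::write.table(
            data.frame(test = c("lrt", "wald"),
                       stat = c(interaction@lrtStat, interaction@waldStat),
                       df = c(interaction@lrtDf, interaction@waldDf),
                       p = c(interaction@lrtP, interaction@waldP)),
            file.path(outDir, "interaction.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        writeRiskCurve(riskTable, file.path(outDir, "absolute_risk.tsv"))
        writeRateSchedule(rates, file.path(outDir, "rates.csv"))
    })

    outputs <- list.files(outDir, full.names = TRUE)
    outputs <- outputs[basename(outputs) != "manifest.json"]
    manifest <- list(
        config = cfg,
        seed = seed,
        versions = list(polyrisk = as.character(
            utils::packageVersion("polyrisk")),
            R = R.version.string),
        outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                                   basename(outputs))),
        warnings = warningsSeen)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
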