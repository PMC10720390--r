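#' Read a PRS scoring file
#'
#' Reads a tab-separated scoring file in the PGS-Catalog style: one row per
#' variant with its effect allele, other allele and per-allele weight.
#'
#' @param path path to a TSV with header columns \code{variant_id}, \code{chr},
#'   \code{pos}, \code{effect_allele}, \code{other_allele}, \code{weight}.
#' @return data.frame of scoring entries in file order, weights numeric.
#' @export
readScoringFile <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("variant_id", "chr", "pos", "effect_allele", "other_allele",
              "weight")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("scoring file is missing required column(s): ",
             paste(miss, collapse = ", "))
    dup <- df$variant_id[duplicated(df$variant_id)]
    if (length(dup))
        stop("duplicate variant id(s) in scoring file: ",
             paste(unique(dup), collapse = ", "))
    df$pos <- as.integer(df$pos)
    df$weight <- as.numeric(df$weight)
    if (any(!is.finite(df$weight)))
        stop("non-numeric or non-finite weight(s) in scoring file")
    df[need]
}

#' Write a PRS scoring model to TSV
#'
#' @param model scoring data.frame as returned by \code{\link{readScoringFile}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeScoringFile <- function(model, path) {
    utils::write.table(model, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read an age-banded rate schedule
#'
#' Reads a CSV of age-band incidence and competing mortality rates expressed
#' per 100,000 person-years (the registry convention) and converts them to
#' per-person-year hazards by dividing by 100,000. Bands are inclusive
#' [age_start, age_end]; with \code{expand = TRUE} each band's rate is
#' repeated on a one-year age grid.
#'
#' @param path CSV with columns \code{age_start}, \code{age_end},
#'   \code{incidence_per_100k}, \code{mortality_per_100k}.
#' @param expand expand bands to a 1-year grid (default TRUE); otherwise the
#'   band start ages form the grid.
#' @return A \linkS4class{RateSchedule}.
#' @export
readRateSchedule <- function(path, expand = TRUE) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("age_start", "age_end", "incidence_per_100k",
              "mortality_per_100k")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("rate schedule is missing required column(s): ",
             paste(miss, collapse = ", "))
    if (nrow(df) == 0L) stop("no rate rows")
    if (any(df$incidence_per_100k < 0) || any(df$mortality_per_100k < 0))
        stop("negative rate in rate schedule")
    if (any(df$age_end < df$age_start))
        stop("age_end before age_start in rate schedule")
    df <- df[order(df$age_start), , drop = FALSE]
    if (nrow(df) > 1L &&
        any(df$age_start[-1L] <= df$age_end[-nrow(df)]))
        stop("overlapping age bands in rate schedule")
    if (expand) {
        ages <- unlist(mapply(seq, df$age_start, df$age_end,
                              SIMPLIFY = FALSE))
        reps <- df$age_end - df$age_start + 1L
        inc <- rep(df$incidence_per_100k, reps) / 1e5
        mor <- rep(df$mortality_per_100k, reps) / 1e5
    } else {
        ages <- df$age_start
        inc <- df$incidence_per_100k / 1e5
        mor <- df$mortality_per_100k / 1e5
    }
    RateSchedule(ages, inc, mor)
}

#' Write a RateSchedule back to band CSV
#'
#' Writes one-year bands (age_start = age_end) with rates re-expressed per
#' 100,000 person-years, so that \code{readRateSchedule} round-trips.
#'
#' @param rates a \linkS4class{RateSchedule}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeRateSchedule <- function(rates, path) {
    df <- data.frame(age_start = ages(rates), age_end = ages(rates),
                     incidence_per_100k = incidence(rates) * 1e5,
                     mortality_per_100k = mortality(rates) * 1e5)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

.phenoCols <- c("individual_id", "status", "age", "study", "country",
                "gleason", "stage", "psa", "died_of_disease",
                "family_history", paste0("pc", 1:10))

.asLogical <- function(x) {
    out <- rep(NA, length(x))
    out[x %in% c("TRUE", "true", "1", "yes")] <- TRUE
    out[x %in% c("FALSE", "false", "0", "no")] <- FALSE
    out
}

#' Read a phenotype table
#'
#' Reads the per-individual phenotype CSV: case/control status, age, study,
#' country, clinical fields used for phenotype classification (Gleason score,
#' stage, PSA, death from disease), family history and 10 ancestry principal
#' components. Missing values are empty cells.
#'
#' @param path CSV path with columns \code{individual_id}, \code{status},
#'   \code{age}, \code{study}, \code{country}, \code{gleason}, \code{stage},
#'   \code{psa}, \code{died_of_disease}, \code{family_history},
#'   \code{pc1}..\code{pc10}.
#' @return data.frame with typed columns.
#' @export
readPhenotypes <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    miss <- setdiff(.phenoCols, names(df))
    if (length(miss))
        stop("phenotype table is missing required column(s): ",
             paste(miss, collapse = ", "))
    df <- df[.phenoCols]
    df[df == ""] <- NA
    df$age <- as.integer(df$age)
    df$gleason <- as.integer(df$gleason)
    df$psa <- as.numeric(df$psa)
    df$died_of_disease <- .asLogical(df$died_of_disease)
    df$family_history <- .asLogical(df$family_history)
    for (p in paste0("pc", 1:10)) df[[p]] <- as.numeric(df[[p]])
    if (!all(df$status %in% c("case", "control")))
        stop("status must be 'case' or 'control'")
    if (any(df$age <= 0, na.rm = TRUE)) stop("age must be positive")
    if (any(df$psa < 0, na.rm = TRUE)) stop("psa must be nonnegative")
    bad <- df$stage[!is.na(df$stage)]
    if (!all(bad %in% c("localized", "regional", "metastatic")))
        stop("stage must be localized/regional/metastatic")
    df
}

#' Classify case phenotypes as aggressive / nonaggressive / metastatic
#'
#' Applies the study's clinical aggressiveness rules. A case is aggressive if
#' Gleason score > 7, or stage is regional/metastatic, or PSA > 50 ng/mL, or
#' the man died of the disease. Nonaggressive requires Gleason <= 7 with
#' localized stage (US studies) or Gleason <= 7 with PSA <= 50 (Uganda, where
#' staging is unavailable). Metastatic disease is stage = metastatic (US) or
#' PSA > 100 ng/mL (Uganda) and always implies aggressive, so such cases are
#' labelled \code{metastatic-aggressive}. Cases matching neither rule because
#' of missing fields are \code{unclassified}; they are kept in overall
#' analyses but excluded from aggressiveness contrasts.
#'
#' @param pheno phenotype data.frame (see \code{\link{readPhenotypes}}).
#' @return character vector: one of \code{control}, \code{nonaggressive},
#'   \code{aggressive}, \code{metastatic-aggressive}, \code{unclassified}.
#' @export
classifyPhenotype <- function(pheno) {
    n <- nrow(pheno)
    out <- character(n)
    isCase <- pheno$status == "case"
    caseFields <- !is.na(pheno$gleason) | !is.na(pheno$stage)
    if (any(!isCase & caseFields))
        warning(sum(!isCase & caseFields),
                " control(s) with case-only clinical fields; kept as controls")
    out[!isCase] <- "control"

    gl <- pheno$gleason
    st <- pheno$stage
    psa <- pheno$psa
    died <- pheno$died_of_disease
    ug <- !is.na(pheno$country) & pheno$country == "Uganda"

    agg <- (!is.na(gl) & gl > 7) |
        (!is.na(st) & st %in% c("regional", "metastatic")) |
        (!is.na(psa) & psa > 50) |
        (!is.na(died) & died)
    met <- ifelse(ug, !is.na(psa) & psa > 100,
                  !is.na(st) & st == "metastatic")
    nonagg <- ifelse(ug,
                     !is.na(gl) & gl <= 7 & !is.na(psa) & psa <= 50,
                     !is.na(gl) & gl <= 7 & !is.na(st) & st == "localized")

    out[isCase & met] <- "metastatic-aggressive"
    out[isCase & agg & !met] <- "aggressive"
    out[isCase & !agg & nonagg] <- "nonaggressive"
    out[isCase & !agg & !nonagg] <- "unclassified"
    out
}

#' Read a genotype dosage table
#'
#' TSV with one row per individual (first column \code{individual_id}) and one
#' column per variant holding effect-allele dosages in [0, 2]; empty cells are
#' missing.
#'
#' @param path TSV path.
#' @return numeric matrix, individuals x variants, rownames = individual ids.
#' @export
readDosages <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (names(df)[1L] != "individual_id")
        stop("dosage table must start with an individual_id column")
    ids <- df$individual_id
    if (anyDuplicated(ids))
        stop("duplicate individual id(s) in dosage table")
    m <- as.matrix(df[-1L])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (any(m < 0 | m > 2, na.rm = TRUE))
        stop("dosages must lie in [0, 2]")
    m
}

#' Write a dosage matrix to TSV
#'
#' @param dosages individuals x variants matrix with rownames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDosages <- function(dosages, path) {
    df <- data.frame(individual_id = rownames(dosages), dosages,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read effect-allele dosages from a VCF
#'
#' Extracts per-individual dosages from a VCF (DS field preferred, GT allele
#' counts as fallback) and orients them to a scoring model's effect allele.
#' Variants whose effect/other alleles are swapped relative to REF/ALT are
#' flipped (dosage 2 - d); variants whose allele pair does not match are
#' dropped with a warning. Coordinates follow the VCF 1-based convention.
#'
#' @param path VCF path (plain or bgzipped).
#' @param model optional scoring data.frame (\code{\link{readScoringFile}});
#'   when supplied, only model variants are returned, oriented to the effect
#'   allele.
#' @return numeric matrix, individuals x variants.
#' @export
readDosagesVCF <- function(path, model = NULL) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
        stop("VCF ingestion requires the VariantAnnotation package")
    vcf <- VariantAnnotation::readVcf(path)
    g <- VariantAnnotation::geno(vcf)
    if ("DS" %in% names(g)) {
        d <- t(as.matrix(g$DS))
        storage.mode(d) <- "double"
    } else if ("GT" %in% names(g)) {
        gt <- t(g$GT)
        cnt <- function(x) {
            alleles <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
            vapply(alleles, function(a) {
                if (any(a == ".")) return(NA_real_)
                sum(a != "0")
            }, numeric(1))
        }
        d <- apply(gt, 2L, cnt)
        if (is.null(dim(d))) d <- matrix(d, nrow = nrow(gt),
                                         dimnames = dimnames(gt))
    } else stop("VCF has neither DS nor GT genotype fields")
    ref <- as.character(VariantAnnotation::ref(vcf))
    alt <- vapply(VariantAnnotation::alt(vcf), function(a)
        as.character(a)[1L], character(1))
    colnames(d) <- names(SummarizedExperiment::rowRanges(vcf))
    if (is.null(model)) return(d)
    keep <- character(0)
    for (i in seq_len(nrow(model))) {
        vid <- model$variant_id[i]
        j <- match(vid, colnames(d))
        if (is.na(j)) next
        ea <- model$effect_allele[i]; oa <- model$other_allele[i]
        if (ea == alt[j] && oa == ref[j]) {
            keep <- c(keep, vid)
        } else if (ea == ref[j] && oa == alt[j]) {
            d[, j] <- 2 - d[, j]
            keep <- c(keep, vid)
        } else {
            warning("allele mismatch for ", vid, "; variant dropped")
        }
    }
    d[, keep, drop = FALSE]
}

#' Read a variant annotation table
#'
#' TSV with one row per rare variant: \code{variant_id}, \code{gene},
#' \code{consequence}, \code{clinvar} (semicolon-delimited
#' \code{lab:assertion} pairs), \code{insilico} (semicolon-delimited
#' \code{tool:call} pairs over the five predictors) and \code{maf}.
#'
#' @param path TSV path.
#' @return data.frame ready for \code{\link{classifyVariants}}.
#' @export
readAnnotations <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("variant_id", "gene", "consequence", "clinvar", "insilico",
              "maf")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("annotation table is missing required column(s): ",
             paste(miss, collapse = ", "))
    df$maf <- as.numeric(df$maf)
    if (any(df$maf < 0 | df$maf > 0.5, na.rm = TRUE))
        stop("maf must lie in [0, 0.5]")
    df[need]
}

#' Assemble the analysis-ready cohort
#'
#' Inner-joins phenotypes, PRS variant dosages, carrier flags and PRS results
#' on individual id, classifies case phenotypes, builds the six-level joint
#' PRS-by-carrier category, and drops (and counts) individuals with missing
#' genotypes, covariates, carrier status or PRS score. The join report is
#' stored in \code{metadata(cohort)$joinReport}.
#'
#' @param phenotypes data.frame from \code{\link{readPhenotypes}}.
#' @param dosages individuals x variants dosage matrix.
#' @param carriers named logical vector of carrier flags
#'   (\code{\link{determineCarriers}}).
#' @param prs data.frame with \code{individual_id}, \code{score},
#'   \code{category} (\code{\link{assignPRSCategories}}).
#' @return A \linkS4class{GenoCohort}.
#' @export
assembleCohort <- function(phenotypes, dosages, carriers, prs) {
    dup <- phenotypes$individual_id[duplicated(phenotypes$individual_id)]
    if (length(dup))
        stop("duplicate individual id(s) in phenotypes: ",
             paste(unique(dup), collapse = ", "))
    ids <- phenotypes$individual_id
    common <- Reduce(intersect, list(ids, rownames(dosages), names(carriers),
                                     prs$individual_id))
    if (length(common) == 0L)
        stop("no overlapping individual ids across inputs")
    report <- list(
        n_phenotypes = length(ids),
        dropped_no_genotype = sum(!ids %in% rownames(dosages)),
        dropped_no_carrier = sum(ids %in% rownames(dosages) &
                                     !ids %in% names(carriers)),
        dropped_no_prs = sum(ids %in% rownames(dosages) &
                                 ids %in% names(carriers) &
                                 !ids %in% prs$individual_id))
    ph <- phenotypes[match(common, phenotypes$individual_id), , drop = FALSE]
    pr <- prs[match(common, prs$individual_id), , drop = FALSE]
    carr <- carriers[common]
    covOk <- !is.na(ph$age) & !is.na(ph$study) &
        rowSums(is.na(ph[paste0("pc", 1:10)])) == 0L
    ok <- covOk & !is.na(carr) & !is.na(pr$score)
    report$dropped_missing_covariates <- sum(!covOk)
    report$dropped_missing_carrier_or_prs <- sum(covOk & !ok)
    common <- common[ok]
    if (length(common) == 0L)
        stop("no individuals left after dropping incomplete records")
    ph <- ph[ok, , drop = FALSE]
    pr <- pr[ok, , drop = FALSE]
    carr <- carr[ok]
    report$n_cohort <- length(common)
    report$dropped_total <- report$n_phenotypes - report$n_cohort

    outcome <- classifyPhenotype(ph)
    prsCat <- factor(as.character(pr$category),
                     levels = c("low", "intermediate", "high"))
    joint <- factor(paste0(as.character(prsCat),
                           ifelse(carr, "_carrier", "_noncarrier")),
                    levels = jointCategoryLevels())
    cd <- S4Vectors::DataFrame(
        status = factor(ph$status, levels = c("control", "case")),
        outcomeClass = outcome,
        age = ph$age, study = factor(ph$study), country = ph$country,
        gleason = ph$gleason, stage = ph$stage, psa = ph$psa,
        died_of_disease = ph$died_of_disease,
        family_history = ph$family_history,
        carrier = unname(carr), prsScore = pr$score, prsCategory = prsCat,
        jointCategory = joint, row.names = common)
    for (p in paste0("pc", 1:10)) cd[[p]] <- ph[[p]]
    dmat <- t(dosages[common, , drop = FALSE])
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(dosage = dmat), colData = cd)
    cohort <- new("GenoCohort", se)
    S4Vectors::metadata(cohort)$joinReport <- report
    cohort
}

#' Six joint PRS-by-carrier category labels
#'
#' @return character vector of the six category levels, reference
#'   (\code{intermediate_noncarrier}) included.
#' @export
jointCategoryLevels <- function() {
    c("low_noncarrier", "intermediate_noncarrier", "high_noncarrier",
      "low_carrier", "intermediate_carrier", "high_carrier")
}
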