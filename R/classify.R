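# Rule-based P/LP/D classification of rare variants and carrier determination.

.truncatingClasses <- c("frameshift_indel", "stop_gained",
                        "splice_donor_acceptor_loss")
.missenseClasses <- c("missense", "exon_boundary_codon_change")
.excludedClasses <- c("intronic", "utr5", "utr3", "inframe_indel",
                      "synonymous", "near_splice_outside_2bp")
.insilicoTools <- c("PolyPhen2-HumDiv", "PolyPhen2-HumVar", "LRT",
                    "MutationTaster", "SIFT")

# "lab:assertion;lab:assertion" -> named character vector (possibly empty)
.parsePairs <- function(s) {
    if (is.na(s) || !nzchar(s)) return(setNames(character(0), character(0)))
    parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    setNames(vapply(kv, `[`, character(1), 2L),
             vapply(kv, `[`, character(1), 1L))
}

.insilicoConsensus <- function(calls, rule) {
    calls <- calls[names(calls) %in% .insilicoTools]
    nonMissing <- calls[calls %in% c("damaging", "tolerated")]
    nDam <- sum(nonMissing == "damaging")
    nAvail <- length(nonMissing)
    switch(rule,
           all = nAvail >= 3L && nDam == nAvail,
           majority = nAvail >= 3L && nDam > nAvail / 2,
           any = nDam >= 1L)
}

#' Classify rare variants as P/LP/D
#'
#' Applies the pathogenicity rules to each annotated variant. A variant is
#' pathogenic / likely pathogenic / deleterious (P/LP/D) when its minor allele
#' frequency is below \code{mafThreshold} (default 1\%) and either (i) its
#' consequence is protein-truncating (frameshift indel, stop gain, essential
#' splice donor/acceptor loss), or (ii) it is a missense or exon start/end
#' codon change reported pathogenic or likely pathogenic in ClinVar by at
#' least one clinical laboratory, or (iii) such a missense variant without a
#' ClinVar pathogenic assertion reaches the in-silico predictor consensus
#' (PolyPhen2-HumDiv, PolyPhen2-HumVar, LRT, MutationTaster, SIFT). Intronic,
#' UTR, in-frame indel, synonymous and near-splice (outside the 2 bp
#' consensus site) variants are excluded regardless of any other evidence, as
#' are variants at or above the frequency threshold. Variants in genes
#' outside the panel are skipped with an audit note, never an error.
#'
#' @param annotations data.frame from \code{\link{readAnnotations}} (or built
#'   in code) with columns \code{variant_id}, \code{gene}, \code{consequence},
#'   \code{clinvar}, \code{insilico}, \code{maf}.
#' @param genePanel gene symbols to consider (default BRCA2, ATM, NBN, PALB2;
#'   the secondary panel BRCA1, RAD50, MLH1, MSH6 may be supplied instead).
#' @param insilicoRule consensus policy over the five predictors:
#'   \code{"all"} (default; every non-missing predictor damaging with at
#'   least 3 non-missing), \code{"majority"} (more than half of at least 3
#'   non-missing), or \code{"any"}.
#' @param mafThreshold rare-variant frequency cutoff (default 0.01, strict
#'   \code{<}).
#' @return data.frame with \code{variant_id}, \code{gene}, \code{plpd}
#'   (logical) and \code{rule} (audit label: \code{truncating},
#'   \code{clinvar}, \code{clinvar_conflict}, \code{insilico}, or the reason
#'   the variant was not classified P/LP/D).
#' @export
classifyVariants <- function(annotations,
                             genePanel = c("BRCA2", "ATM", "NBN", "PALB2"),
                             insilicoRule = c("all", "majority", "any"),
                             mafThreshold = 0.01) {
    insilicoRule <- match.arg(insilicoRule)
    allClasses <- c(.truncatingClasses, .missenseClasses, .excludedClasses)
    bad <- setdiff(unique(annotations$consequence), allClasses)
    if (length(bad))
        stop("unknown consequence class(es): ", paste(bad, collapse = ", "))
    n <- nrow(annotations)
    plpd <- logical(n)
    rule <- character(n)
    for (i in seq_len(n)) {
        cons <- annotations$consequence[i]
        if (!annotations$gene[i] %in% genePanel) {
            rule[i] <- "outside_panel"
            next
        }
        if (cons %in% .excludedClasses) {
            rule[i] <- "excluded_class"
            next
        }
        if (!is.na(annotations$maf[i]) && annotations$maf[i] >= mafThreshold) {
            rule[i] <- "common"
            next
        }
        if (cons %in% .truncatingClasses) {
            plpd[i] <- TRUE
            rule[i] <- "truncating"
            next
        }
        # missense / exon-boundary codon change
        cv <- .parsePairs(annotations$clinvar[i])
        path <- any(cv %in% c("pathogenic", "likely_pathogenic"))
        benign <- any(cv == "benign")
        if (path) {
            plpd[i] <- TRUE
            rule[i] <- if (benign) "clinvar_conflict" else "clinvar"
            next
        }
        calls <- .parsePairs(annotations$insilico[i])
        if (.insilicoConsensus(calls, insilicoRule)) {
            plpd[i] <- TRUE
            rule[i] <- "insilico"
        } else {
            rule[i] <- "no_evidence"
        }
    }
    data.frame(variant_id = annotations$variant_id,
               gene = annotations$gene, plpd = plpd, rule = rule,
               stringsAsFactors = FALSE)
}

#' Determine P/LP/D carrier status
#'
#' An individual is a carrier when holding at least one alternate allele at at
#' least one variant classified P/LP/D, aggregated across the gene panel.
#'
#' @param genotypes individuals x variants matrix of rare-variant allele
#'   counts (0/1/2; NA = no call). Individuals entirely absent (all-NA rows
#'   are still judged on observed calls; individuals not in the matrix are
#'   simply missing from the result and counted downstream).
#' @param classification data.frame from \code{\link{classifyVariants}}.
#' @return named logical vector of carrier flags.
#' @export
determineCarriers <- function(genotypes, classification) {
    plpdVars <- classification$variant_id[classification$plpd]
    plpdVars <- intersect(plpdVars, colnames(genotypes))
    if (length(plpdVars) == 0L)
        return(setNames(rep(FALSE, nrow(genotypes)), rownames(genotypes)))
    sub <- genotypes[, plpdVars, drop = FALSE]
    setNames(rowSums(sub >= 1, na.rm = TRUE) > 0, rownames(genotypes))
}

#' Write a classification table to TSV
#'
#' @param classification data.frame from \code{\link{classifyVariants}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeClassification <- function(classification, path) {
    utils::write.table(classification, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
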