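# Weighted-sum PRS: polymorphic filter, scoring, control-anchored tertiles.

.controlAlleleFreq <- function(dosages, controlIds, variants) {
    ctrl <- intersect(controlIds, rownames(dosages))
    if (length(ctrl) == 0L) stop("no controls present in dosage table")
    colMeans(dosages[ctrl, variants, drop = FALSE], na.rm = TRUE) / 2
}

#' Filter a PRS model to variants polymorphic in controls
#'
#' Retains scoring entries that are present in the dosage table and whose
#' minor allele frequency among controls exceeds \code{mafMin} (default 1\%),
#' mirroring the study's restriction to polymorphic variants.
#'
#' @param model scoring data.frame (\code{\link{readScoringFile}}).
#' @param dosages individuals x variants dosage matrix.
#' @param controlIds control individual ids.
#' @param mafMin minor-allele-frequency threshold (strict \code{>}).
#' @return list with \code{model} (filtered scoring data.frame) and
#'   \code{dropped} (data.frame of dropped variant ids and reasons).
#' @export
filterPolymorphic <- function(model, dosages, controlIds, mafMin = 0.01) {
    present <- model$variant_id %in% colnames(dosages)
    maf <- rep(NA_real_, nrow(model))
    if (any(present)) {
        f <- .controlAlleleFreq(dosages, controlIds,
                                model$variant_id[present])
        maf[present] <- pmin(f, 1 - f)
    } else {
        # still validate the control precondition
        .controlAlleleFreq(dosages, controlIds,
                           intersect(model$variant_id, colnames(dosages)))
    }
    keep <- present & !is.na(maf) & maf > mafMin
    dropped <- data.frame(
        variant_id = model$variant_id[!keep],
        reason = ifelse(!present[!keep], "absent_from_dosages",
                        "monomorphic_or_rare"),
        stringsAsFactors = FALSE)
    list(model = model[keep, , drop = FALSE], dropped = dropped)
}

#' Compute weighted-sum PRS scores
#'
#' The score is the weighted sum of effect-allele dosages,
#' s_i = sum_j w_j * g_ij. Sporadically missing dosages are mean-imputed as
#' twice the effect-allele frequency in controls (the standard PRS
#' convention); individuals missing more than \code{maxMissing} of the model
#' variants get a missing score and are reported.
#'
#' @param model scoring data.frame; every variant must have a dosage column.
#' @param dosages individuals x variants dosage matrix.
#' @param controlIds control ids used for imputation frequencies.
#' @param maxMissing maximum tolerated fraction of missing model variants per
#'   individual (default 0.1).
#' @param standardize center/scale scores to control mean 0, SD 1 (off by
#'   default; raw weighted sums are reported).
#' @return data.frame with \code{individual_id} and \code{score}; individuals
#'   exceeding \code{maxMissing} have \code{NA} score, counted in
#'   \code{attr(, "nScoreMissing")}.
#' @export
computePRS <- function(model, dosages, controlIds, maxMissing = 0.1,
                       standardize = FALSE) {
    miss <- setdiff(model$variant_id, colnames(dosages))
    if (length(miss))
        stop("model variant(s) missing from dosage table: ",
             paste(utils::head(miss, 5), collapse = ", "))
    G <- dosages[, model$variant_id, drop = FALSE]
    missFrac <- rowMeans(is.na(G))
    if (anyNA(G)) {
        eaf <- .controlAlleleFreq(dosages, controlIds, model$variant_id)
        for (j in which(colSums(is.na(G)) > 0L)) {
            G[is.na(G[, j]), j] <- 2 * eaf[j]
        }
    }
    scores <- drop(G %*% model$weight)
    scores[missFrac > maxMissing] <- NA_real_
    if (standardize) {
        ctrl <- intersect(controlIds, rownames(G))
        scores <- (scores - mean(scores[ctrl], na.rm = TRUE)) /
            stats::sd(scores[ctrl], na.rm = TRUE)
    }
    out <- data.frame(individual_id = rownames(G), score = unname(scores),
                      stringsAsFactors = FALSE)
    attr(out, "nScoreMissing") <- sum(missFrac > maxMissing)
    out
}

#' Assign control-anchored PRS tertile categories
#'
#' Cut points are the 33.3\% and 66.7\% quantiles (type-7 linear
#' interpolation at probabilities 1/3 and 2/3) of the control score
#' distribution; every individual, cases included, is then categorized by
#' those cut points with left-closed boundaries: low < q1 <= intermediate <
#' q2 <= high.
#'
#' @param scores data.frame from \code{\link{computePRS}}.
#' @param controlIds control individual ids (>= 3 scored controls required).
#' @return the input data.frame with a \code{category} factor
#'   (low/intermediate/high) added; tertile cut points in
#'   \code{attr(, "cutpoints")}.
#' @export
assignPRSCategories <- function(scores, controlIds) {
    ctrl <- scores$score[scores$individual_id %in% controlIds]
    ctrl <- ctrl[!is.na(ctrl)]
    if (length(ctrl) < 3L) stop("need at least 3 scored controls")
    if (max(ctrl) == min(ctrl)) stop("degenerate control distribution")
    q <- stats::quantile(ctrl, probs = c(1, 2) / 3, type = 7, names = FALSE)
    cat <- rep(NA_character_, nrow(scores))
    s <- scores$score
    cat[!is.na(s) & s < q[1L]] <- "low"
    cat[!is.na(s) & s >= q[1L] & s < q[2L]] <- "intermediate"
    cat[!is.na(s) & s >= q[2L]] <- "high"
    scores$category <- factor(cat, levels = c("low", "intermediate", "high"))
    attr(scores, "cutpoints") <- q
    scores
}

#' Write PRS results to TSV
#'
#' @param prs data.frame from \code{\link{assignPRSCategories}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePRS <- function(prs, path) {
    utils::write.table(prs, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
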