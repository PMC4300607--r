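# SNP- and sample-level quality control with an auditable removal report.
# Filter order is fixed so that every removed unit is attributed to exactly
# one (the first failing) filter:
#   SNPs:    autosome -> panel intersection -> quality -> call rate -> HWE
#   samples: quality -> call rate -> heterozygosity -> duplicates;
#            parent-offspring conflicts sever the pedigree link instead of
#            removing the animal.

#' Construct QC thresholds
#'
#' @param minQuality minimum mean per-call quality (GenCall-style), default
#'   0.15. Skipped when the dataset has no quality scores.
#' @param minCallRate minimum call rate for SNPs and samples, default 0.90.
#' @param minHweP minimum Hardy-Weinberg equilibrium p-value, default 1e-6.
#' @param hetSdLimit heterozygosity outlier limit in SDs, default 3.
#' @param dupConcordance genotype concordance above which two samples are
#'   treated as repeated sampling of one animal, default 0.99.
#' @param maxMendelRate maximum opposing-homozygote rate for a recorded
#'   parent-offspring pair, default 0.01.
#' @param autosomesOnly drop SNPs outside chromosomes 1-29, default TRUE.
#' @return A \linkS4class{QcThresholds}.
#' @export
qcThresholds <- function(minQuality = 0.15, minCallRate = 0.90,
                         minHweP = 1e-6, hetSdLimit = 3,
                         dupConcordance = 0.99, maxMendelRate = 0.01,
                         autosomesOnly = TRUE) {
    new("QcThresholds", minQuality = minQuality, minCallRate = minCallRate,
        minHweP = minHweP, hetSdLimit = hetSdLimit,
        dupConcordance = dupConcordance, maxMendelRate = maxMendelRate,
        autosomesOnly = autosomesOnly)
}

#' Hardy-Weinberg equilibrium p-value
#'
#' One-degree-of-freedom chi-square goodness-of-fit test of observed
#' genotype counts against the expected proportions p^2, 2pq, q^2, with the
#' allele frequency estimated from the sample. No continuity correction.
#' A monomorphic SNP returns p-value 1 (nothing to test).
#'
#' @param nAA,nAB,nBB genotype counts (vectorised).
#' @return P-value(s) in [0,1].
#' @examples
#' hwePvalue(25, 50, 25)  # exact HWE proportions -> 1
#' hwePvalue(50, 0, 50)   # no heterozygotes -> ~0
#' @export
hwePvalue <- function(nAA, nAB, nBB) {
    n <- nAA + nAB + nBB
    if (any(n < 1L)) stop("at least one genotype count required")
    p <- (2 * nAA + nAB) / (2 * n)
    mono <- p == 0 | p == 1
    q <- 1 - p
    e <- cbind(n * p^2, 2 * n * p * q, n * q^2)
    o <- cbind(nAA, nAB, nBB)
    chi2 <- rowSums(ifelse(e > 0, (o - e)^2 / e, 0))
    pv <- pchisq(chi2, df = 1, lower.tail = FALSE)
    pv[mono] <- 1
    unname(pv)
}

.emptyRemoved <- function() data.frame(
    unit = character(), axis = character(), filter = character(),
    statistic = numeric(), threshold = numeric(), stringsAsFactors = FALSE)

.removedRows <- function(units, axis, filter, statistic, threshold) {
    if (!length(units)) return(.emptyRemoved())
    data.frame(unit = units, axis = axis, filter = filter,
               statistic = statistic, threshold = threshold,
               stringsAsFactors = FALSE)
}

#' SNP-level quality control
#'
#' Removes, in order: non-autosomal SNPs (chromosome outside 1-29); SNPs
#' absent from the reference panel (when given); SNPs with mean call quality
#' below \code{minQuality} (skipped when the dataset carries no quality
#' scores); SNPs with call rate below \code{minCallRate}; SNPs with
#' Hardy-Weinberg p-value below \code{minHweP}. Each removal is attributed
#' to the first filter that the SNP fails.
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param thresholds a \linkS4class{QcThresholds}.
#' @param referencePanel optional \linkS4class{MarkerPanel}; SNPs not on it
#'   are removed (the "not in common with reference panel" rule).
#' @return \code{list(dataset =, report =)} with the filtered
#'   \linkS4class{GenotypeData} and a \linkS4class{QcReport}.
#' @export
snpQC <- function(x, thresholds = qcThresholds(), referencePanel = NULL) {
    if (nrow(x) == 0L) stop("dataset has no SNPs")
    removed <- .emptyRemoved()
    keep <- x
    map <- snpMap(keep)
    if (thresholds@autosomesOnly) {
        bad <- map$snp_id[map$chromosome < 1L | map$chromosome > 29L]
        removed <- rbind(removed, .removedRows(
            bad, "snp", "autosome",
            map$chromosome[match(bad, map$snp_id)], NA_real_))
        keep <- keep[!rownames(keep) %in% bad, ]
    }
    if (!is.null(referencePanel)) {
        bad <- setdiff(rownames(keep), snpIds(referencePanel))
        removed <- rbind(removed,
            .removedRows(bad, "snp", "panel", NA_real_, NA_real_))
        keep <- keep[!rownames(keep) %in% bad, ]
    }
    q <- qualityScores(keep)
    if (!is.null(q) && nrow(keep) > 0L) {
        mq <- rowMeans(q, na.rm = TRUE)
        bad <- rownames(keep)[!is.nan(mq) & mq < thresholds@minQuality]
        removed <- rbind(removed, .removedRows(
            bad, "snp", "quality", mq[match(bad, rownames(keep))],
            thresholds@minQuality))
        keep <- keep[!rownames(keep) %in% bad, ]
    }
    if (nrow(keep) > 0L) {
        cr <- callRate(keep, "snp")
        bad <- names(cr)[cr < thresholds@minCallRate]
        removed <- rbind(removed, .removedRows(
            bad, "snp", "call_rate", cr[bad], thresholds@minCallRate))
        keep <- keep[!rownames(keep) %in% bad, ]
    }
    if (nrow(keep) > 0L) {
        d <- dosageMatrix(keep)
        n0 <- rowSums(d == 0L, na.rm = TRUE)
        n1 <- rowSums(d == 1L, na.rm = TRUE)
        n2 <- rowSums(d == 2L, na.rm = TRUE)
        ok <- (n0 + n1 + n2) >= 1L
        pv <- rep(1, nrow(d))
        pv[ok] <- hwePvalue(n0[ok], n1[ok], n2[ok])
        bad <- rownames(keep)[pv < thresholds@minHweP]
        removed <- rbind(removed, .removedRows(
            bad, "snp", "hwe", pv[match(bad, rownames(keep))],
            thresholds@minHweP))
        keep <- keep[!rownames(keep) %in% bad, ]
    }
    report <- new("QcReport", removed = removed,
        nBefore = c(snp = nrow(x), sample = ncol(x)),
        nAfter = c(snp = nrow(keep), sample = ncol(keep)))
    if (nrow(keep) == 0L)
        stop("all ", nrow(x), " SNPs removed by QC (",
             paste(sprintf("%s: %d", names(table(removed$filter)),
                           table(removed$filter)), collapse = ", "), ")")
    list(dataset = keep, report = report)
}

#' Heterozygosity outlier samples
#'
#' Per-sample heterozygous fraction over called genotypes; samples outside
#' mean +/- \code{sdLimit} * SD (mean and SD over all samples) are flagged.
#' Returns an empty vector when the SD is zero.
#'
#' @param x a \linkS4class{GenotypeData} with at least 3 samples.
#' @param sdLimit number of standard deviations, default 3.
#' @return Character vector of outlier sample ids.
#' @export
heterozygosityOutliers <- function(x, sdLimit = 3) {
    if (ncol(x) < 3L) stop("need at least 3 samples")
    d <- dosageMatrix(x)
    het <- colMeans(d == 1L, na.rm = TRUE)
    s <- sd(het)
    if (is.na(s) || s == 0) return(character())
    m <- mean(het)
    names(het)[het < m - sdLimit * s | het > m + sdLimit * s]
}

#' Mendelian conflict rate between a child and a parent
#'
#' Fraction of jointly called SNPs at which the two genotypes are opposing
#' homozygotes (dosage 0 vs 2) - a Mendelian impossibility used to detect
#' pedigree or sample errors.
#'
#' @param child,parent equal-length dosage vectors.
#' @return Fraction in [0,1]; \code{NA} (flagged) when no SNP is jointly
#'   called.
#' @export
mendelConflictRate <- function(child, parent) {
    if (length(child) != length(parent))
        stop("child and parent vectors must have equal length")
    joint <- !is.na(child) & !is.na(parent)
    if (!any(joint)) return(NA_real_)
    opposing <- (child == 0L & parent == 2L) | (child == 2L & parent == 0L)
    sum(opposing[joint]) / sum(joint)
}

#' Sample-level quality control
#'
#' Removes samples failing mean call quality, call rate, or the
#' heterozygosity outlier check; detects duplicate pairs (genotype
#' concordance >= \code{dupConcordance}) and removes the lower-call-rate
#' member; recorded parent-offspring pairs whose opposing-homozygote rate
#' exceeds \code{maxMendelRate} have the pedigree link severed (parent set
#' to unknown) rather than the sample removed, preserving the genotypes for
#' population imputation.
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param ped a \linkS4class{Pedigree} covering the dataset samples.
#' @param thresholds a \linkS4class{QcThresholds}.
#' @return \code{list(dataset =, report =, pedigree =)}.
#' @export
sampleQC <- function(x, ped, thresholds = qcThresholds()) {
    removed <- .emptyRemoved()
    keep <- x
    q <- qualityScores(keep)
    if (!is.null(q)) {
        mq <- colMeans(q, na.rm = TRUE)
        bad <- colnames(keep)[!is.nan(mq) & mq < thresholds@minQuality]
        removed <- rbind(removed, .removedRows(
            bad, "sample", "quality", mq[match(bad, colnames(keep))],
            thresholds@minQuality))
        keep <- keep[, !colnames(keep) %in% bad]
    }
    if (ncol(keep) > 0L) {
        cr <- callRate(keep, "sample")
        bad <- names(cr)[cr < thresholds@minCallRate]
        removed <- rbind(removed, .removedRows(
            bad, "sample", "call_rate", cr[bad], thresholds@minCallRate))
        keep <- keep[, !colnames(keep) %in% bad]
    }
    if (ncol(keep) >= 3L) {
        out <- heterozygosityOutliers(keep, thresholds@hetSdLimit)
        if (length(out)) {
            het <- colMeans(dosageMatrix(keep) == 1L, na.rm = TRUE)
            removed <- rbind(removed, .removedRows(
                out, "sample", "heterozygosity", het[out],
                thresholds@hetSdLimit))
            keep <- keep[, !colnames(keep) %in% out]
        }
    }
    # duplicate detection: concordance over jointly called genotypes
    if (ncol(keep) >= 2L) {
        d <- dosageMatrix(keep)
        cr <- callRate(keep, "sample")
        drop <- character()
        ids <- colnames(d)
        for (i in seq_len(ncol(d) - 1L)) {
            if (ids[i] %in% drop) next
            di <- d[, i]
            for (j in seq((i + 1L), ncol(d))) {
                if (ids[j] %in% drop) next
                joint <- !is.na(di) & !is.na(d[, j])
                nj <- sum(joint)
                if (nj == 0L) next
                conc <- sum(di[joint] == d[joint, j]) / nj
                if (conc >= thresholds@dupConcordance) {
                    loser <- if (cr[ids[i]] < cr[ids[j]]) ids[i] else ids[j]
                    removed <- rbind(removed, .removedRows(
                        loser, "sample", "duplicate", conc,
                        thresholds@dupConcordance))
                    drop <- c(drop, loser)
                    if (loser == ids[i]) break
                }
            }
        }
        keep <- keep[, !colnames(keep) %in% drop]
    }
    # paternity check: sever conflicting pedigree links
    df <- pedRecords(ped)
    d <- dosageMatrix(keep)
    for (side in c("sire", "dam")) {
        rel <- df[[side]]
        check <- which(!is.na(rel) & df$animal %in% colnames(d) &
                       rel %in% colnames(d))
        for (k in check) {
            rate <- mendelConflictRate(d[, df$animal[k]], d[, rel[k]])
            if (!is.na(rate) && rate > thresholds@maxMendelRate) {
                removed <- rbind(removed, .removedRows(
                    paste0(df$animal[k], ":", rel[k]), "pedigree_link",
                    "mendel", rate, thresholds@maxMendelRate))
                df[[side]][k] <- NA_character_
            }
        }
    }
    report <- new("QcReport", removed = removed,
        nBefore = c(snp = nrow(x), sample = ncol(x)),
        nAfter = c(snp = nrow(keep), sample = ncol(keep)))
    list(dataset = keep, report = report, pedigree = pedigree(df))
}

#' Write a QC report as TSV
#'
#' @param report a \linkS4class{QcReport}.
#' @param file output path.
#' @export
writeQcReport <- function(report, file) {
    write.table(report@removed, file, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(file)
}

setMethod("show", "QcReport", function(object) {
    cat("QcReport:", nrow(object@removed), "removal(s)\n")
    cat(sprintf("  SNPs: %d -> %d; samples: %d -> %d\n",
        object@nBefore["snp"], object@nAfter["snp"],
        object@nBefore["sample"], object@nAfter["sample"]))
    if (nrow(object@removed))
        print(table(object@removed$axis, object@removed$filter))
})
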