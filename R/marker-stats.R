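# Elementary per-marker statistics. All denominators are over called
# genotypes only; missing calls never contribute.

#' Call rate per SNP or per sample
#'
#' Fraction of non-missing genotype calls along the chosen axis.
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param axis "snp" (default) or "sample".
#' @return Named numeric vector of fractions in [0,1].
#' @export
#' @rdname callRate
setMethod("callRate", "GenotypeData", function(x, axis = c("snp", "sample")) {
    axis <- match.arg(axis)
    d <- dosageMatrix(x)
    if (axis == "snp") {
        if (nrow(d) == 0L) stop("dataset has no SNPs")
        rowMeans(!is.na(d))
    } else {
        if (ncol(d) == 0L) stop("dataset has no samples")
        colMeans(!is.na(d))
    }
})

#' Minor allele frequency per SNP
#'
#' Per SNP, \code{min(p, 1 - p)} where p is the mean dosage over called
#' genotypes divided by 2, computed over the given sample subset. SNPs with
#' no called genotype in the subset get \code{NA} (undefined).
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param samples optional character vector of sample ids to restrict the
#'   frequency computation to (e.g. the reference population).
#' @return Named numeric vector of MAFs in [0, 0.5], \code{NA} where
#'   undefined.
#' @export
#' @rdname minorAlleleFreq
setMethod("minorAlleleFreq", "GenotypeData", function(x, samples = NULL) {
    d <- dosageMatrix(x)
    if (!is.null(samples)) {
        if (length(samples) == 0L) stop("empty sample subset")
        missing <- setdiff(samples, colnames(d))
        if (length(missing))
            stop("unknown sample id(s): ", paste(head(missing), collapse = ", "))
        d <- d[, samples, drop = FALSE]
    }
    p <- rowMeans(d, na.rm = TRUE) / 2
    p[is.nan(p)] <- NA_real_
    pmin(p, 1 - p)
})

#' Pairwise linkage disequilibrium (r-squared)
#'
#' Squared Pearson correlation of the dosage vectors of two SNPs over
#' jointly called samples. Returns \code{NA} (flagged undefined) when either
#' SNP has zero variance over the joint set. Symmetric in its arguments and
#' invariant to swapping allele A/B at either SNP.
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param snpI,snpJ SNP identifiers.
#' @return A single fraction in [0,1], or \code{NA} when undefined.
#' @export
pairwiseR2 <- function(x, snpI, snpJ) {
    d <- dosageMatrix(x)
    if (!snpI %in% rownames(d)) stop("unknown SNP id: ", snpI)
    if (!snpJ %in% rownames(d)) stop("unknown SNP id: ", snpJ)
    a <- d[snpI, ]; b <- d[snpJ, ]
    joint <- !is.na(a) & !is.na(b)
    if (sum(joint) < 2L)
        stop("fewer than 2 samples with both SNPs called")
    a <- a[joint]; b <- b[joint]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    unname(cor(a, b)^2)
}
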