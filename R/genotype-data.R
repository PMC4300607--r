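#' Construct a GenotypeData object
#'
#' @param dosage integer matrix of allele-B dosages (0/1/2, \code{NA} =
#'   missing call), SNPs in rows, samples in columns.
#' @param map data.frame with one row per SNP: columns \code{snp_id},
#'   \code{chromosome}, \code{position}, \code{alleleA}, \code{alleleB}.
#' @param sampleIds character vector of sample identifiers (defaults to
#'   \code{colnames(dosage)}).
#' @param quality optional numeric matrix of per-call quality scores in
#'   [0,1], same shape as \code{dosage}.
#' @param hap1,hap2 optional binary matrices of phased allele-B indicators;
#'   where dosage is called their sum must equal the dosage.
#'
#' @return A \linkS4class{GenotypeData} object.
#' @examples
#' d <- matrix(c(0L, 1L, 2L, NA), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("a1", "a2")))
#' m <- data.frame(snp_id = c("s1", "s2"), chromosome = 1L,
#'                 position = c(100L, 200L), alleleA = "A", alleleB = "G")
#' gd <- genotypeData(d, m)
#' dosageMatrix(gd)
#' @export
genotypeData <- function(dosage, map, sampleIds = colnames(dosage),
                         quality = NULL, hap1 = NULL, hap2 = NULL) {
    dosage <- as.matrix(dosage)
    storage.mode(dosage) <- "integer"
    if (is.null(sampleIds))
        sampleIds <- paste0("sample", seq_len(ncol(dosage)))
    stopifnot(nrow(dosage) == nrow(map), ncol(dosage) == length(sampleIds))
    need <- c("snp_id", "chromosome", "position", "alleleA", "alleleB")
    if (!all(need %in% names(map)))
        stop("map must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(map$snp_id)) stop("duplicate SNP ids in map")
    bad <- dosage[!is.na(dosage)]
    if (length(bad) && any(bad < 0L | bad > 2L))
        stop("dosage values must be 0, 1, 2 or NA")
    if (any(map$position < 1L)) stop("positions must be >= 1")
    if (any(map$alleleA == map$alleleB))
        stop("alleleA and alleleB must differ")
    dimnames(dosage) <- list(map$snp_id, sampleIds)
    assays <- list(dosage = dosage)
    if (!is.null(quality)) {
        quality <- as.matrix(quality)
        stopifnot(identical(dim(quality), dim(dosage)))
        if (any(quality < 0 | quality > 1, na.rm = TRUE))
            stop("quality scores must lie in [0,1]")
        dimnames(quality) <- dimnames(dosage)
        assays$quality <- quality
    }
    if (!is.null(hap1) || !is.null(hap2)) {
        if (is.null(hap1) || is.null(hap2))
            stop("hap1 and hap2 must be given together")
        hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
        storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
        stopifnot(identical(dim(hap1), dim(dosage)),
                  identical(dim(hap2), dim(dosage)))
        called <- !is.na(dosage) & !is.na(hap1) & !is.na(hap2)
        if (any((hap1 + hap2)[called] != dosage[called]))
            stop("haplotypes must sum to dosage at called cells")
        dimnames(hap1) <- dimnames(hap2) <- dimnames(dosage)
        assays$hap1 <- hap1
        assays$hap2 <- hap2
    }
    rd <- S4Vectors::DataFrame(
        chromosome = as.integer(map$chromosome),
        position = as.integer(map$position),
        alleleA = as.character(map$alleleA),
        alleleB = as.character(map$alleleB),
        row.names = map$snp_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays, rowData = rd)
    new("GenotypeData", se)
}

#' Dosage matrix accessor
#'
#' @param x a \linkS4class{GenotypeData} object.
#' @return Integer matrix of allele-B dosages, SNPs x samples, \code{NA}
#'   at missing calls.
#' @export
#' @rdname dosageMatrix
setMethod("dosageMatrix", "GenotypeData", function(x)
    SummarizedExperiment::assay(x, "dosage"))

#' SNP identifiers
#'
#' @param x a \linkS4class{GenotypeData} or \linkS4class{MarkerPanel}.
#' @return Character vector of SNP ids, in map/manifest order.
#' @export
#' @rdname snpIds
setMethod("snpIds", "GenotypeData", function(x) rownames(x))

#' @export
#' @rdname snpIds
setMethod("snpIds", "MarkerPanel", function(x) x@snpIds)

#' Sample identifiers
#'
#' @param x a \linkS4class{GenotypeData} object.
#' @export
#' @rdname sampleIds
setMethod("sampleIds", "GenotypeData", function(x) colnames(x))

#' Marker map accessor
#'
#' @param x a \linkS4class{GenotypeData} object.
#' @return data.frame with snp_id, chromosome, position, alleleA, alleleB.
#' @export
#' @rdname snpMap
setMethod("snpMap", "GenotypeData", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    data.frame(snp_id = rownames(x), chromosome = rd$chromosome,
               position = rd$position, alleleA = rd$alleleA,
               alleleB = rd$alleleB, row.names = NULL,
               stringsAsFactors = FALSE)
})

#' Phase status and haplotype accessors
#'
#' @param x a \linkS4class{GenotypeData} object.
#' @return \code{isPhased}: TRUE when hap1/hap2 assays are present;
#'   \code{haplotypeMatrices}: list with elements \code{hap1}, \code{hap2}
#'   (or NULL when unphased).
#' @export
#' @rdname isPhased
setMethod("isPhased", "GenotypeData", function(x)
    all(c("hap1", "hap2") %in% SummarizedExperiment::assayNames(x)))

#' @export
#' @rdname haplotypeMatrices
setMethod("haplotypeMatrices", "GenotypeData", function(x) {
    if (!isPhased(x)) return(NULL)
    list(hap1 = SummarizedExperiment::assay(x, "hap1"),
         hap2 = SummarizedExperiment::assay(x, "hap2"))
})

#' Quality score accessor
#'
#' @param x a \linkS4class{GenotypeData} object.
#' @return Numeric matrix of per-call quality scores, or NULL when absent.
#' @export
qualityScores <- function(x) {
    if (!"quality" %in% SummarizedExperiment::assayNames(x)) return(NULL)
    SummarizedExperiment::assay(x, "quality")
}

#' Construct a MarkerPanel
#'
#' @param name panel label.
#' @param snpIds character vector of SNP ids; duplicates are removed
#'   keeping the first occurrence.
#' @return A \linkS4class{MarkerPanel}.
#' @examples
#' markerPanel("toy3", c("snp1", "snp2", "snp3"))
#' @export
markerPanel <- function(name, snpIds) {
    new("MarkerPanel", name = name, snpIds = unique(as.character(snpIds)))
}

#' @export
#' @rdname panelName
setMethod("panelName", "MarkerPanel", function(x) x@name)

#' @describeIn markerPanel number of SNPs on the panel
#' @param x a MarkerPanel
#' @export
setMethod("length", "MarkerPanel", function(x) length(x@snpIds))

#' Construct a Pedigree
#'
#' @param records data.frame with columns animal, sire, dam, birth_year,
#'   pool (extra columns retained). Unknown parents/years as \code{NA};
#'   the strings "0" and "NA" are also treated as unknown. Parent ids
#'   without an animal record are auto-added as founders.
#' @return A \linkS4class{Pedigree}.
#' @examples
#' pedigree(data.frame(animal = c("A", "B"), sire = c(NA, "A"),
#'                     dam = NA, birth_year = c(2008L, 2011L), pool = "p"))
#' @export
pedigree <- function(records) {
    records <- as.data.frame(records, stringsAsFactors = FALSE)
    for (col in c("animal", "sire", "dam", "pool")) {
        if (!col %in% names(records))
            records[[col]] <- NA_character_
        records[[col]] <- as.character(records[[col]])
        if (col %in% c("sire", "dam"))
            records[[col]][records[[col]] %in% c("0", "NA", "")] <- NA_character_
    }
    if (!"birth_year" %in% names(records))
        records$birth_year <- NA_integer_
    records$birth_year <- suppressWarnings(as.integer(records$birth_year))
    missingParents <- setdiff(
        c(records$sire, records$dam), c(records$animal, NA))
    if (length(missingParents)) {
        founders <- records[0, , drop = FALSE][seq_along(missingParents), ]
        founders$animal <- missingParents
        founders$sire <- NA_character_
        founders$dam <- NA_character_
        founders$birth_year <- NA_integer_
        founders$pool <- NA_character_
        records <- rbind(founders, records)
    }
    new("Pedigree", records = records)
}

#' Pedigree records accessor
#'
#' @param x a \linkS4class{Pedigree}.
#' @return The records data.frame.
#' @export
#' @rdname pedRecords
setMethod("pedRecords", "Pedigree", function(x) x@records)

#' Restrict a dataset to a marker panel
#'
#' Keeps exactly the SNPs shared between the dataset and the panel, in map
#' (chromosome, position) order; samples are unchanged. Mirrors the removal
#' of SNPs not in common with a reference panel during data editing.
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param panel a \linkS4class{MarkerPanel}.
#' @return A \linkS4class{GenotypeData} with the intersected SNP set.
#' @export
#' @rdname restrictToPanel
setMethod("restrictToPanel", c("GenotypeData", "MarkerPanel"),
    function(x, panel) {
        keep <- rownames(x) %in% snpIds(panel)
        if (!any(keep)) stop("no SNPs shared between dataset and panel '",
                             panelName(panel), "'")
        x[keep, ]
    })

setMethod("show", "GenotypeData", function(object) {
    cat("GenotypeData:", nrow(object), "SNPs x", ncol(object), "samples\n")
    d <- dosageMatrix(object)
    cat(sprintf("  missing: %.2f%%; phased: %s; quality: %s\n",
        100 * mean(is.na(d)), isPhased(object),
        "quality" %in% SummarizedExperiment::assayNames(object)))
    chroms <- SummarizedExperiment::rowData(object)$chromosome
    cat("  chromosomes:", paste(unique(chroms), collapse = ", "), "\n")
})

setMethod("show", "MarkerPanel", function(object) {
    cat("MarkerPanel '", object@name, "': ", length(object@snpIds),
        " SNPs\n", sep = "")
})

setMethod("show", "Pedigree", function(object) {
    df <- object@records
    cat("Pedigree:", nrow(df), "animals;",
        sum(is.na(df$sire)), "unknown sires;",
        sum(is.na(df$dam)), "unknown dams\n")
})
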