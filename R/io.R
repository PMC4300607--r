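# File readers/writers for the workbench's interchange formats:
# PLINK PED/MAP text, minimal VCF (GT only), panel manifests, pedigree files.

# Accept a path, a connection, a single string with newlines, or a character
# vector of lines.
.sourceLines <- function(source) {
    if (inherits(source, "connection")) return(readLines(source))
    if (is.character(source) && length(source) == 1L &&
        !grepl("\n", source, fixed = TRUE) && file.exists(source))
        return(readLines(source))
    if (is.character(source) && length(source) == 1L)
        return(strsplit(source, "\n", fixed = TRUE)[[1]])
    as.character(source)
}

.splitWs <- function(lines) strsplit(trimws(lines), "[ \t]+")

#' Read genotypes from PLINK PED/MAP text files
#'
#' The MAP file has 4 whitespace columns (chromosome, SNP id, genetic
#' position, bp position); the PED file has 6 leading columns (family,
#' individual, sire, dam, sex, phenotype) followed by two allele columns per
#' SNP, with "0" denoting a missing allele. Alleles A/B are assigned per SNP
#' as (major, minor) by observed allele frequency, ties broken
#' lexicographically (the smaller character becomes the major allele A);
#' dosage counts copies of allele B. A genotype with any "0" allele is
#' recorded as missing.
#'
#' @param pedSource,mapSource file path, connection, or character lines.
#' @return A \linkS4class{GenotypeData}.
#' @examples
#' mapTxt <- c("1 snp1 0 100", "1 snp2 0 200")
#' pedTxt <- c("f1 id1 0 0 1 -9 A A G G", "f1 id2 0 0 2 -9 A G G G")
#' gd <- readPlink(pedTxt, mapTxt)
#' dosageMatrix(gd)
#' @export
readPlink <- function(pedSource, mapSource) {
    mapLines <- .sourceLines(mapSource)
    mapLines <- mapLines[nzchar(trimws(mapLines))]
    mapF <- .splitWs(mapLines)
    if (length(mapF) && any(lengths(mapF) != 4L))
        stop("MAP line ", which(lengths(mapF) != 4L)[1],
             ": expected 4 whitespace-delimited columns")
    nSnp <- length(mapF)
    chrom <- suppressWarnings(
        as.integer(vapply(mapF, `[`, "", 1L)))
    chrom[is.na(chrom)] <- 0L  # non-numeric chromosome codes -> non-autosomal
    ids <- vapply(mapF, `[`, "", 2L)
    pos <- as.integer(vapply(mapF, `[`, "", 4L))

    pedLines <- .sourceLines(pedSource)
    pedLines <- pedLines[nzchar(trimws(pedLines))]
    pedF <- .splitWs(pedLines)
    expLen <- 6L + 2L * nSnp
    badLine <- which(lengths(pedF) != expLen)
    if (length(badLine))
        stop("PED line ", badLine[1], ": expected ", expLen,
             " columns (6 + 2 per MAP SNP), found ", lengths(pedF)[badLine[1]])
    nSample <- length(pedF)
    sampleIds <- vapply(pedF, `[`, "", 2L)
    a1 <- matrix("0", nSample, nSnp)
    a2 <- matrix("0", nSample, nSnp)
    for (i in seq_len(nSample)) {
        al <- pedF[[i]][-(1:6)]
        a1[i, ] <- al[c(TRUE, FALSE)]
        a2[i, ] <- al[c(FALSE, TRUE)]
    }
    dosage <- matrix(NA_integer_, nSnp, nSample)
    alleleA <- character(nSnp)
    alleleB <- character(nSnp)
    for (j in seq_len(nSnp)) {
        al <- c(a1[, j], a2[, j])
        obs <- al[al != "0"]
        lev <- sort(unique(obs))
        if (length(lev) > 2L)
            stop("SNP '", ids[j], "': more than 2 distinct alleles (",
                 paste(lev, collapse = ","), ")")
        if (length(lev) == 0L) {
            alleleA[j] <- "A"; alleleB[j] <- "B"
            next
        }
        cnt <- table(factor(obs, levels = lev))
        if (length(lev) == 1L) {
            alleleA[j] <- lev
            alleleB[j] <- if (lev == "B") "A" else "B"
        } else {
            # major allele first; exact tie -> lexicographically smaller major
            major <- if (cnt[1] >= cnt[2]) lev[1] else lev[2]
            alleleA[j] <- major
            alleleB[j] <- setdiff(lev, major)
        }
        called <- a1[, j] != "0" & a2[, j] != "0"
        dosage[j, called] <- (a1[called, j] == alleleB[j]) +
            (a2[called, j] == alleleB[j])
    }
    genotypeData(dosage,
        data.frame(snp_id = ids, chromosome = chrom, position = pos,
                   alleleA = alleleA, alleleB = alleleB,
                   stringsAsFactors = FALSE),
        sampleIds = sampleIds)
}

#' Write genotypes as PLINK PED/MAP text
#'
#' Inverse of \code{\link{readPlink}}: missing genotypes are written as
#' "0 0". Reading the written text back reproduces the dosage matrix exactly
#' for any dataset whose allele B is the minor allele (ties resolved with
#' allele A lexicographically smaller), which holds for all datasets
#' produced by \code{readPlink}.
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param pedFile,mapFile optional paths; when given the text is also
#'   written to disk.
#' @return Invisibly, \code{list(ped =, map =)} character vectors of lines.
#' @export
writePlink <- function(x, pedFile = NULL, mapFile = NULL) {
    map <- snpMap(x)
    mapLines <- sprintf("%d %s 0 %d", map$chromosome, map$snp_id,
                        map$position)
    d <- dosageMatrix(x)
    n <- ncol(d)
    pedLines <- character(n)
    for (i in seq_len(n)) {
        di <- d[, i]
        g1 <- ifelse(is.na(di), "0", ifelse(di >= 1, map$alleleB, map$alleleA))
        g2 <- ifelse(is.na(di), "0", ifelse(di == 2, map$alleleB, map$alleleA))
        pedLines[i] <- paste("FAM", sampleIds(x)[i], "0 0 0 -9",
                             paste(rbind(g1, g2), collapse = " "))
    }
    if (!is.null(pedFile)) writeLines(pedLines, pedFile)
    if (!is.null(mapFile)) writeLines(mapLines, mapFile)
    invisible(list(ped = pedLines, map = mapLines))
}

#' Read a minimal VCF (GT field, biallelic records)
#'
#' Reads VCF 4.x text with a GT entry per sample. GT values 0/0, 0/1, 1/1
#' and ./. map to dosages 0, 1, 2 and missing, with REF as allele A and ALT
#' as allele B. When every genotype in the file is phased ("|" separator),
#' the phase is recorded into haplotype assays. Multiallelic records are
#' skipped; the count is available as
#' \code{metadata(x)$parseReport$skippedMultiallelic}.
#'
#' @param vcfSource file path, connection, or character lines.
#' @return A \linkS4class{GenotypeData}.
#' @export
readVcfMinimal <- function(vcfSource) {
    lines <- .sourceLines(vcfSource)
    lines <- lines[nzchar(trimws(lines))]
    hdr <- grep("^#CHROM", lines)
    if (!length(hdr)) stop("no #CHROM header line found")
    sampleIds <- .splitWs(lines[hdr[1]])[[1]][-(1:9)]
    body <- lines[seq_along(lines) > hdr[1] & !startsWith(lines, "#")]
    skipped <- 0L
    rows <- list(); mapRows <- list()
    for (ln in body) {
        f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        if (length(f) < 10L) f <- .splitWs(ln)[[1]]
        if (grepl(",", f[5], fixed = TRUE)) { skipped <- skipped + 1L; next }
        fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
        gtIdx <- match("GT", fmt)
        if (is.na(gtIdx)) { skipped <- skipped + 1L; next }
        gts <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, "", gtIdx)
        rows[[length(rows) + 1L]] <- gts
        mapRows[[length(mapRows) + 1L]] <-
            list(chrom = f[1], id = f[3], pos = f[2], ref = f[4], alt = f[5])
    }
    if (skipped > 0L)
        warning(skipped, " multiallelic/unsupported record(s) skipped")
    if (!length(rows)) stop("no usable VCF records")
    gt <- do.call(rbind, rows)
    allPhased <- all(grepl("^[0-9.]\\|[0-9.]$", gt) | gt %in% c(".", ".|."))
    h1 <- matrix(suppressWarnings(
        as.integer(substr(gt, 1, 1))), nrow(gt), ncol(gt))
    h2 <- matrix(suppressWarnings(
        as.integer(substr(gt, 3, 3))), nrow(gt), ncol(gt))
    dosage <- h1 + h2
    chrom <- suppressWarnings(
        as.integer(vapply(mapRows, function(r) r$chrom, "")))
    chrom[is.na(chrom)] <- 0L
    ids <- vapply(mapRows, function(r) r$id, "")
    blank <- ids %in% c(".", "")
    if (any(blank))
        ids[blank] <- sprintf("vcf_%s_%s",
            vapply(mapRows, function(r) r$chrom, "")[blank],
            vapply(mapRows, function(r) r$pos, "")[blank])
    map <- data.frame(
        snp_id = ids, chromosome = chrom,
        position = as.integer(vapply(mapRows, function(r) r$pos, "")),
        alleleA = vapply(mapRows, function(r) r$ref, ""),
        alleleB = vapply(mapRows, function(r) r$alt, ""),
        stringsAsFactors = FALSE)
    gd <- if (allPhased)
        genotypeData(dosage, map, sampleIds, hap1 = h1, hap2 = h2)
    else genotypeData(dosage, map, sampleIds)
    S4Vectors::metadata(gd)$parseReport <-
        list(skippedMultiallelic = skipped)
    gd
}

#' Load a marker panel manifest
#'
#' One SNP id per line; blank lines ignored; duplicate ids removed keeping
#' the first occurrence (the number removed is attached as attribute
#' \code{"nDuplicates"}).
#'
#' @param source file path, connection, or character lines.
#' @param name panel label.
#' @return A \linkS4class{MarkerPanel}.
#' @export
loadPanel <- function(source, name) {
    ids <- trimws(.sourceLines(source))
    ids <- ids[nzchar(ids)]
    if (!length(ids)) stop("panel manifest '", name, "' is empty")
    nDup <- sum(duplicated(ids))
    panel <- markerPanel(name, ids)
    attr(panel, "nDuplicates") <- nDup
    panel
}

#' Write a marker panel manifest
#'
#' @param panel a \linkS4class{MarkerPanel}.
#' @param file output path.
#' @export
writePanel <- function(panel, file) {
    writeLines(snpIds(panel), file)
    invisible(file)
}

#' Read a pedigree file
#'
#' Whitespace-delimited records with 4-5 columns: animal, sire, dam,
#' birth_year and optionally a pool (breed) label. "0" and "NA" denote
#' unknown parents or years.
#'
#' @param source file path, connection, or character lines.
#' @return A \linkS4class{Pedigree}.
#' @export
readPedigree <- function(source) {
    lines <- .sourceLines(source)
    lines <- lines[nzchar(trimws(lines))]
    f <- .splitWs(lines)
    if (any(lengths(f) < 4L | lengths(f) > 5L))
        stop("pedigree line ", which(lengths(f) < 4L | lengths(f) > 5L)[1],
             ": expected 4-5 whitespace-delimited columns")
    pedigree(data.frame(
        animal = vapply(f, `[`, "", 1L),
        sire = vapply(f, `[`, "", 2L),
        dam = vapply(f, `[`, "", 3L),
        birth_year = vapply(f, `[`, "", 4L),
        pool = vapply(f, function(x) if (length(x) >= 5L) x[5L] else NA_character_, ""),
        stringsAsFactors = FALSE))
}

#' Write a pedigree file
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param file output path.
#' @export
writePedigree <- function(ped, file) {
    df <- pedRecords(ped)
    enc <- function(x) ifelse(is.na(x), "0", as.character(x))
    writeLines(paste(df$animal, enc(df$sire), enc(df$dam),
                     enc(df$birth_year), enc(df$pool)), file)
    invisible(file)
}
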