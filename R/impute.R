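# Deterministic reference imputation engines, patterned on the
# family-then-population approach of deterministic livestock imputers:
#  - Mendelian family fill-in (only uniquely forced genotypes),
#  - inference of ungenotyped parents from >= minOffspringForParent
#    genotyped offspring via obligately transmitted alleles,
#  - population imputation by overlapping sliding-window haplotype matching
#    against a phased reference library, longest windows (closest
#    relatives) first, shrinking the window when no haplotype matches,
#  - one- and two-step orchestration across panel densities.
# All engines are deterministic and never alter an observed genotype.

#' Construct imputation options
#'
#' @param usePedigree run the Mendelian family step before population
#'   imputation (default TRUE).
#' @param windowSchedule strictly decreasing sliding-window sizes in SNPs,
#'   default c(512, 128, 32, 8).
#' @param minMatchFraction fraction of called target alleles a library
#'   haplotype must match within a window to be a candidate; default 1
#'   (exact matching, fully deterministic).
#' @param minOffspringForParent minimum genotyped offspring before an
#'   ungenotyped parent is inferred, default 4.
#' @param allowIncomplete leave unresolvable cells missing (default TRUE)
#'   instead of substituting the reference modal genotype.
#' @return An \linkS4class{ImputeOptions}.
#' @export
imputeOptions <- function(usePedigree = TRUE,
                          windowSchedule = c(512L, 128L, 32L, 8L),
                          minMatchFraction = 1,
                          minOffspringForParent = 4L,
                          allowIncomplete = TRUE) {
    new("ImputeOptions", usePedigree = usePedigree,
        windowSchedule = as.integer(windowSchedule),
        minMatchFraction = minMatchFraction,
        minOffspringForParent = as.integer(minOffspringForParent),
        allowIncomplete = allowIncomplete)
}

#' Build a haplotype library from a phased reference
#'
#' Collects the 2n reference haplotypes (optionally restricted to a panel),
#' collapsing duplicate haplotype patterns with their multiplicity and
#' source sample ids preserved.
#'
#' @param reference a phased \linkS4class{GenotypeData} (run
#'   \code{\link{phaseHeuristic}} first if unphased).
#' @param panel optional \linkS4class{MarkerPanel} to restrict to.
#' @return A \linkS4class{HaplotypeLibrary}.
#' @export
buildHaplotypeLibrary <- function(reference, panel = NULL) {
    if (!is.null(panel)) reference <- restrictToPanel(reference, panel)
    if (!isPhased(reference))
        stop("reference is unphased; apply phaseHeuristic() first")
    hp <- haplotypeMatrices(reference)
    n <- ncol(reference)
    H <- matrix(NA_integer_, nrow(reference), 2L * n)
    H[, seq(1, 2 * n, by = 2)] <- hp$hap1
    H[, seq(2, 2 * n, by = 2)] <- hp$hap2
    if (anyNA(H))
        stop("reference haplotypes contain missing alleles; ",
             "impute or complete the reference first")
    src <- rep(colnames(reference), each = 2L)
    keys <- apply(H, 2L, paste, collapse = "")
    first <- !duplicated(keys)
    uH <- H[, first, drop = FALSE]
    grp <- match(keys, keys[first])
    weights <- tabulate(grp, nbins = sum(first))
    sources <- split(src, grp)
    new("HaplotypeLibrary", snpIds = rownames(reference),
        chromosome = as.integer(
            SummarizedExperiment::rowData(reference)$chromosome),
        haps = uH, weights = as.integer(weights),
        sources = unname(sources))
}

#' @describeIn buildHaplotypeLibrary total number of haplotypes (with
#'   multiplicity).
#' @param x a HaplotypeLibrary.
#' @export
nHaplotypes <- function(x) sum(x@weights)

setMethod("show", "HaplotypeLibrary", function(object) {
    cat("HaplotypeLibrary:", length(object@snpIds), "SNPs;",
        sum(object@weights), "haplotypes (", ncol(object@haps),
        "unique )\n")
})

# candidate columns of H matching gamete g at its called sites in rows idx
.windowCandidates <- function(H, g, idx, minFrac) {
    k <- length(idx)
    if (k == 0L) return(seq_len(ncol(H)))
    matches <- colSums(H[idx, , drop = FALSE] == g[idx])
    which(matches >= ceiling(minFrac * k))
}

#' Phase genotypes heuristically
#'
#' Homozygous calls phase trivially. With a library, each sample is first
#' tested for an exact diplotype: a pair of library haplotypes whose sum
#' reproduces every called genotype on the chromosome (a sample duplicating
#' a library animal is thereby phased identically to it, up to pair order).
#' Otherwise heterozygous sites are phased left to right by a majority vote
#' of library haplotypes matching the surrounding window of already-known
#' first-gamete alleles; ties and voteless sites deterministically put
#' allele B on the first gamete. Without a library all heterozygous sites
#' take the deterministic fallback. Missing cells stay unphased (NA in both
#' gametes); gamete sums always reproduce the called dosage.
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param library optional \linkS4class{HaplotypeLibrary} on the same SNP
#'   set.
#' @param voteWindow number of known anchor sites on each side used for the
#'   majority vote (default 4).
#' @return \code{x} with hap1/hap2 assays added.
#' @export
phaseHeuristic <- function(x, library = NULL, voteWindow = 4L) {
    d <- dosageMatrix(x)
    h1 <- matrix(NA_integer_, nrow(d), ncol(d), dimnames = dimnames(d))
    h2 <- h1
    hom <- !is.na(d) & d != 1L
    h1[hom] <- h2[hom] <- d[hom] %/% 2L
    chrom <- SummarizedExperiment::rowData(x)$chromosome
    useLib <- !is.null(library)
    if (useLib && !identical(library@snpIds, rownames(d)))
        stop("library SNP set does not match the dataset")
    for (s in seq_len(ncol(d))) {
        for (cc in unique(chrom)) {
            idx <- which(chrom == cc)
            dc <- d[idx, s]
            het <- which(!is.na(dc) & dc == 1L)
            if (!length(het)) next
            phased <- FALSE
            if (useLib) {
                Hc <- library@haps[idx, , drop = FALSE]
                called <- which(!is.na(dc))
                # exact diplotype: some pair of library haplotypes sums to
                # the called dosage everywhere on this chromosome
                libKeys <- apply(Hc[called, , drop = FALSE], 2L,
                                 paste, collapse = "")
                for (u in seq_len(ncol(Hc))) {
                    comp <- dc[called] - Hc[called, u]
                    if (any(comp < 0L | comp > 1L)) next
                    v <- match(paste(comp, collapse = ""), libKeys)
                    if (!is.na(v)) {
                        h1[idx, s] <- ifelse(is.na(dc), NA_integer_, Hc[, u])
                        h2[idx, s] <- ifelse(is.na(dc), NA_integer_,
                                             dc - Hc[, u])
                        phased <- TRUE
                        break
                    }
                }
                if (!phased) {
                    g1 <- h1[idx, s]
                    for (site in het) {
                        known <- which(!is.na(g1))
                        lo <- known[known < site]
                        hi <- known[known > site]
                        anchors <- c(utils::tail(lo, voteWindow),
                                     utils::head(hi, voteWindow))
                        # best-matching library haplotypes vote on the phase
                        cand <- if (length(anchors)) {
                            mt <- colSums(Hc[anchors, , drop = FALSE] ==
                                          g1[anchors])
                            which(mt == max(mt))
                        } else seq_len(ncol(Hc))
                        vote <- sum(library@weights[cand] * Hc[site, cand]) /
                            sum(library@weights[cand])
                        g1[site] <- if (vote > 0.5) 1L
                            else if (vote < 0.5) 0L else 1L
                    }
                    h1[idx, s] <- g1
                    h2[idx, s] <- ifelse(is.na(dc), NA_integer_, dc - g1)
                    phased <- TRUE
                }
            }
            if (!phased) {  # no library: deterministic fallback
                h1[idx[het], s] <- 1L
                h2[idx[het], s] <- 0L
            }
        }
    }
    genotypeData(d, snpMap(x), sampleIds = colnames(d),
                 quality = qualityScores(x), hap1 = h1, hap2 = h2)
}

#' Mendelian family imputation
#'
#' Fills missing genotypes of the target samples only where family logic
#' forces a unique dosage: both parents homozygous force the child's
#' genotype; obligate transmissions of both alleles across an animal's
#' genotyped offspring (offspring homozygous, or heterozygous with the mate
#' homozygous for the other allele) force a heterozygote. Cells not
#' uniquely forced stay missing; cells with Mendelian-impossible
#' offspring/mate evidence are never filled.
#'
#' @param target \linkS4class{GenotypeData} whose missing cells are to be
#'   filled.
#' @param ped a \linkS4class{Pedigree}.
#' @param companions \linkS4class{GenotypeData} of genotyped relatives on
#'   the same SNP set (may share samples with \code{target}).
#' @return An \linkS4class{ImputationResult} (partial: fillStatus
#'   "observed", "family" or "unfilled").
#' @export
imputeFamily <- function(target, ped, companions) {
    d <- dosageMatrix(target)
    if (!identical(rownames(companions), rownames(d)))
        stop("companions must be on the same SNP set as the target")
    df <- pedRecords(ped)
    unknownIds <- setdiff(colnames(d), df$animal)
    if (length(unknownIds))
        stop("pedigree lacks target sample(s): ",
             paste(head(unknownIds), collapse = ", "))
    cd <- dosageMatrix(companions)
    pool <- cbind(cd, d[, setdiff(colnames(d), colnames(cd)), drop = FALSE])
    geno <- function(id) {
        if (is.na(id) || !id %in% colnames(pool))
            return(rep(NA_integer_, nrow(d)))
        pool[, id]
    }
    status <- matrix(ifelse(is.na(d), "unfilled", "observed"),
                     nrow(d), ncol(d), dimnames = dimnames(d))
    out <- d
    for (s in colnames(d)) {
        rec <- df[df$animal == s, ]
        sg <- geno(rec$sire)
        dg <- geno(rec$dam)
        miss <- is.na(out[, s])
        forced <- miss & !is.na(sg) & !is.na(dg) & sg != 1L & dg != 1L
        out[forced, s] <- (sg[forced] + dg[forced]) %/% 2L
        status[forced, s] <- "family"
        # obligate transmissions from genotyped offspring
        kidsS <- df[!is.na(df$sire) & df$sire == s, ]
        kidsD <- df[!is.na(df$dam) & df$dam == s, ]
        kids <- rbind(cbind(kid = kidsS$animal, mate = kidsS$dam),
                      cbind(kid = kidsD$animal, mate = kidsD$sire))
        if (!is.null(nrow(kids)) && nrow(kids)) {
            aCnt <- bCnt <- integer(nrow(d))
            conflict <- logical(nrow(d))
            for (r in seq_len(nrow(kids))) {
                o <- geno(kids[r, "kid"])
                if (all(is.na(o))) next
                mm <- geno(kids[r, "mate"])
                o0 <- !is.na(o) & o == 0L
                o2 <- !is.na(o) & o == 2L
                m0 <- !is.na(mm) & mm == 0L
                m2 <- !is.na(mm) & mm == 2L
                o1 <- !is.na(o) & o == 1L
                aCnt <- aCnt + o0 + (o1 & m2)
                bCnt <- bCnt + o2 + (o1 & m0)
                conflict <- conflict | (o0 & m2) | (o2 & m0)
            }
            miss <- is.na(out[, s])
            forcedHet <- miss & aCnt > 0L & bCnt > 0L & !conflict
            out[forcedHet, s] <- 1L
            status[forcedHet, s] <- "family"
        }
    }
    imputed <- genotypeData(out, snpMap(target), sampleIds = colnames(d))
    nMiss <- sum(is.na(d))
    new("ImputationResult", imputed = imputed, fillStatus = status,
        imputedCallRate = if (nMiss) sum(status == "family") / nMiss else 1)
}

#' Infer an ungenotyped parent from its offspring
#'
#' Collects, per SNP, the alleles the parent obligately transmitted: a
#' homozygous offspring pins one transmitted allele; a heterozygous
#' offspring whose other parent is homozygous pins the allele the mate
#' could not have given. Two distinct obligate alleles call the parent
#' heterozygous; a single allele seen in at least two independent
#' transmissions (and never the other) calls the corresponding homozygote
#' (the two-transmission rule guards against single genotyping errors).
#' Everything else stays missing. SNPs with a Mendelian-impossible
#' offspring/mate pair are left missing and counted. With fewer than
#' \code{minOffspringForParent} genotyped offspring the call is refused
#' (typed refusal, not an error).
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param genotypes \linkS4class{GenotypeData} holding the offspring (and
#'   mate) genotypes.
#' @param parentId the ungenotyped animal to infer.
#' @param options an \linkS4class{ImputeOptions}.
#' @return A list of class \code{"parentInference"}: \code{status}
#'   ("ok"/"refused"), \code{dosage} (named vector, NA where unresolved),
#'   \code{resolvedFraction}, \code{nConflicts}, \code{nOffspring}.
#' @export
inferUngenotypedParent <- function(ped, genotypes, parentId,
                                   options = imputeOptions()) {
    d <- dosageMatrix(genotypes)
    if (parentId %in% colnames(d))
        stop("'", parentId, "' is genotyped; nothing to infer")
    df <- pedRecords(ped)
    kidsS <- df[!is.na(df$sire) & df$sire == parentId, ]
    kidsD <- df[!is.na(df$dam) & df$dam == parentId, ]
    kids <- rbind(cbind(kid = kidsS$animal, mate = kidsS$dam),
                  cbind(kid = kidsD$animal, mate = kidsD$sire))
    kids <- kids[kids[, "kid"] %in% colnames(d), , drop = FALSE]
    n <- nrow(kids)
    if (n < options@minOffspringForParent)
        return(structure(list(
            status = "refused", dosage = NULL, resolvedFraction = 0,
            nConflicts = 0L, nOffspring = n,
            reason = sprintf(
                "%d genotyped offspring < required minimum of %d",
                n, options@minOffspringForParent)),
            class = "parentInference"))
    aCnt <- bCnt <- integer(nrow(d))
    conflict <- logical(nrow(d))
    for (r in seq_len(n)) {
        o <- d[, kids[r, "kid"]]
        mateId <- kids[r, "mate"]
        mm <- if (!is.na(mateId) && mateId %in% colnames(d))
            d[, mateId] else rep(NA_integer_, nrow(d))
        o0 <- !is.na(o) & o == 0L
        o2 <- !is.na(o) & o == 2L
        o1 <- !is.na(o) & o == 1L
        m0 <- !is.na(mm) & mm == 0L
        m2 <- !is.na(mm) & mm == 2L
        aCnt <- aCnt + o0 + (o1 & m2)
        bCnt <- bCnt + o2 + (o1 & m0)
        conflict <- conflict | (o0 & m2) | (o2 & m0)
    }
    dose <- rep(NA_integer_, nrow(d))
    dose[aCnt > 0L & bCnt > 0L] <- 1L
    dose[aCnt >= 2L & bCnt == 0L] <- 0L
    dose[bCnt >= 2L & aCnt == 0L] <- 2L
    dose[conflict] <- NA_integer_
    names(dose) <- rownames(d)
    structure(list(
        status = "ok", dosage = dose,
        resolvedFraction = mean(!is.na(dose)),
        nConflicts = sum(conflict), nOffspring = n, reason = NULL),
        class = "parentInference")
}

# fill one gamete on one chromosome by overlapping sliding windows.
# g: alleles with NA at cells to fill; Hc: library haplotypes on the
# chromosome; tieIndex breaks exact vote ties (gamete 1 takes the first
# tied candidate, gamete 2 the second, so a single-pair library
# reproduces the pair's dosage); returns the completed gamete (NA allowed
# when incomplete).
.fillGamete <- function(g, Hc, weights, schedule, minFrac, allowIncomplete,
                        tieIndex = 1L) {
    m <- length(g)
    res <- g
    calledAll <- which(!is.na(g))
    candSets <- list()
    cellSet <- integer(m)  # 0 = no candidate set recorded yet
    for (size in schedule) {
        if (!anyNA(res)) break
        size <- min(size, m)
        starts <- if (m <= size) 1L else
            unique(c(seq(1L, m - size + 1L, by = max(1L, size %/% 2L)),
                     m - size + 1L))
        for (a in starts) {
            b <- min(a + size - 1L, m)
            win <- a:b
            unf <- win[is.na(res[win])]
            if (!length(unf)) next
            idx <- win[!is.na(g[win])]
            cand <- .windowCandidates(Hc, g, idx, minFrac)
            if (!length(cand)) next
            sub <- Hc[unf, cand, drop = FALSE]
            agree <- rowSums(sub != sub[, 1]) == 0L
            res[unf[agree]] <- sub[agree, 1]
            dis <- unf[!agree]
            new <- dis[cellSet[dis] == 0L]
            if (length(new)) {
                candSets[[length(candSets) + 1L]] <- cand
                cellSet[new] <- length(candSets)
            }
        }
    }
    rest <- which(is.na(res))
    if (length(rest)) {
        for (sid in unique(cellSet[rest])) {
            cells <- rest[cellSet[rest] == sid]
            if (sid == 0L) {
                # no window with called anchors ever matched
                if (!allowIncomplete) {
                    af <- (Hc[cells, , drop = FALSE] %*% weights) /
                        sum(weights)
                    res[cells] <- as.integer(af >= 0.5)
                }
                next
            }
            cand <- candSets[[sid]]
            # fallback fill from the most-constrained window's candidates:
            # a haplotype agreeing with the gamete at every called site
            # chromosome-wide is a close relative and is copied (weighted
            # majority among several); otherwise the candidates vote cell
            # by cell (modal allele), approximating the conditional allele
            # frequency given the window anchors
            score <- colSums(Hc[calledAll, cand, drop = FALSE] ==
                             g[calledAll])
            perfect <- cand[score == length(calledAll)]
            use <- if (length(perfect)) perfect else cand
            af <- (Hc[cells, use, drop = FALSE] %*%
                   weights[use]) / sum(weights[use])
            tie <- use[min(tieIndex, length(use))]
            res[cells] <- ifelse(af > 0.5, 1L,
                ifelse(af < 0.5, 0L, Hc[cells, tie]))
        }
    }
    res
}

#' Population imputation by overlapping sliding-window haplotype matching
#'
#' For each target gamete and each window of the schedule (largest first,
#' overlapping by half the window), the candidate haplotypes are the
#' library entries matching the called target alleles in the window
#' (fraction >= \code{minMatchFraction}). Masked cells on which all
#' candidates agree are filled; disagreements are deferred to smaller
#' windows; windows with no matching haplotype are skipped (shortening the
#' window recruits more distant relatives). Cells still open after the
#' smallest window are filled from the most-constrained window's candidate
#' set, preferring the haplotype with maximal chromosome-wide agreement
#' with the gamete; cells whose every anchored window had no match are left
#' missing (or filled with the library modal allele when
#' \code{allowIncomplete = FALSE}). Deterministic throughout.
#'
#' @param target \linkS4class{GenotypeData} on (a subset of) the library
#'   SNP set; unphased targets are phased with \code{\link{phaseHeuristic}}
#'   against the library.
#' @param library a \linkS4class{HaplotypeLibrary}.
#' @param options an \linkS4class{ImputeOptions}.
#' @return An \linkS4class{ImputationResult}.
#' @export
imputePopulation <- function(target, library, options = imputeOptions()) {
    if (ncol(library@haps) == 0L) stop("empty haplotype library")
    target <- .expandToGrid(target, library)
    d <- dosageMatrix(target)
    if (!isPhased(target))
        target <- phaseHeuristic(target, library)
    hp <- haplotypeMatrices(target)
    chrom <- library@chromosome
    out <- d
    status <- matrix(ifelse(is.na(d), "unfilled", "observed"),
                     nrow(d), ncol(d), dimnames = dimnames(d))
    for (s in seq_len(ncol(d))) {
        for (cc in unique(chrom)) {
            idx <- which(chrom == cc)
            Hc <- library@haps[idx, , drop = FALSE]
            g1 <- .fillGamete(hp$hap1[idx, s], Hc, library@weights,
                              options@windowSchedule,
                              options@minMatchFraction,
                              options@allowIncomplete, tieIndex = 1L)
            g2 <- .fillGamete(hp$hap2[idx, s], Hc, library@weights,
                              options@windowSchedule,
                              options@minMatchFraction,
                              options@allowIncomplete, tieIndex = 2L)
            dd <- g1 + g2
            fill <- is.na(d[idx, s]) & !is.na(dd)
            out[idx[fill], s] <- dd[fill]
            status[idx[fill], s] <- "population"
        }
    }
    # observed genotypes pass through bit-exactly
    out[!is.na(d)] <- d[!is.na(d)]
    imputed <- genotypeData(out, snpMap(target), sampleIds = colnames(d))
    nMiss <- sum(is.na(d))
    new("ImputationResult", imputed = imputed, fillStatus = status,
        imputedCallRate = if (nMiss)
            sum(status == "population") / nMiss else 1)
}

# place a target dataset onto the library's SNP grid (missing rows -> NA)
.expandToGrid <- function(target, library) {
    if (identical(rownames(target), library@snpIds)) return(target)
    extra <- setdiff(rownames(target), library@snpIds)
    if (length(extra))
        stop("target has SNPs outside the library panel: ",
             paste(head(extra), collapse = ", "))
    d <- dosageMatrix(target)
    full <- matrix(NA_integer_, length(library@snpIds), ncol(d),
                   dimnames = list(library@snpIds, colnames(d)))
    full[rownames(d), ] <- d
    map <- snpMap(target)
    gridMap <- data.frame(snp_id = library@snpIds,
                          chromosome = library@chromosome,
                          position = NA_integer_, alleleA = "A",
                          alleleB = "B", stringsAsFactors = FALSE)
    hit <- match(map$snp_id, gridMap$snp_id)
    gridMap$position[hit] <- map$position
    gridMap$alleleA[hit] <- map$alleleA
    gridMap$alleleB[hit] <- map$alleleB
    # positions for SNPs absent from the target map are interpolated from
    # their neighbours so the grid stays sorted (used for reporting only)
    if (anyNA(gridMap$position))
        gridMap$position <- .fillPositions(gridMap$position,
                                           gridMap$chromosome)
    genotypeData(full, gridMap, sampleIds = colnames(d))
}

.fillPositions <- function(pos, chrom) {
    for (cc in unique(chrom)) {
        idx <- which(chrom == cc)
        p <- pos[idx]
        if (all(is.na(p))) {
            pos[idx] <- seq_along(idx)
            next
        }
        known <- which(!is.na(p))
        pos[idx] <- as.integer(round(stats::approx(
            known, p[known], xout = seq_along(idx), rule = 2)$y))
    }
    pos
}

#' One-step imputation: family first, then population
#'
#' With pedigree use enabled, missing genotypes are first filled by
#' Mendelian family logic (\code{\link{imputeFamily}}, using the reference
#' and the other targets as companions), then remaining cells by
#' \code{\link{imputePopulation}} against the phased reference library;
#' without a pedigree the population step runs alone. The fill status
#' records the source of every filled cell.
#'
#' @param target \linkS4class{GenotypeData} to impute (missing cells are
#'   the imputation targets).
#' @param reference \linkS4class{GenotypeData} on the full panel; phased
#'   references are used as-is, unphased ones are phased heuristically.
#' @param ped optional \linkS4class{Pedigree}; required when
#'   \code{options@usePedigree}.
#' @param options an \linkS4class{ImputeOptions}.
#' @return An \linkS4class{ImputationResult}.
#' @export
imputeGenotypes <- function(target, reference, ped = NULL,
                            options = imputeOptions()) {
    if (!isPhased(reference))
        reference <- phaseHeuristic(reference)
    library <- buildHaplotypeLibrary(reference)
    target <- .expandToGrid(target, library)
    d0 <- dosageMatrix(target)
    status <- matrix(ifelse(is.na(d0), "unfilled", "observed"),
                     nrow(d0), ncol(d0), dimnames = dimnames(d0))
    current <- target
    if (options@usePedigree && !is.null(ped)) {
        fam <- imputeFamily(current, ped, reference)
        status[fam@fillStatus == "family"] <- "family"
        current <- fam@imputed
    }
    pop <- imputePopulation(current, library, options)
    newPop <- pop@fillStatus == "population" & status == "unfilled"
    status[newPop] <- "population"
    out <- dosageMatrix(pop@imputed)
    out[!is.na(d0)] <- d0[!is.na(d0)]
    imputed <- genotypeData(out, snpMap(pop@imputed),
                            sampleIds = colnames(d0))
    nMiss <- sum(is.na(d0))
    new("ImputationResult", imputed = imputed, fillStatus = status,
        imputedCallRate = if (nMiss)
            sum(status %in% c("family", "population")) / nMiss else 1)
}

#' Two-step imputation through an intermediate panel
#'
#' Step 1 imputes the targets to the intermediate (mid) panel against the
#' mid-density reference (typically many animals); step 2 imputes the
#' step-1 output to the full (high) panel against the high-density
#' reference (typically few animals). Panels must nest: target SNPs within
#' the mid panel within the high panel. Fill status distinguishes the two
#' steps ("family_step1", "population_step2", ...).
#'
#' @param target \linkS4class{GenotypeData} on the low panel.
#' @param midReference \linkS4class{GenotypeData} on the mid panel.
#' @param highReference \linkS4class{GenotypeData} on the high panel.
#' @param ped optional \linkS4class{Pedigree}.
#' @param options an \linkS4class{ImputeOptions}.
#' @return An \linkS4class{ImputationResult} on the high panel.
#' @export
twoStepImpute <- function(target, midReference, highReference, ped = NULL,
                          options = imputeOptions()) {
    midIds <- rownames(midReference)
    highIds <- rownames(highReference)
    if (length(setdiff(midIds, highIds)))
        stop("panel nesting violated: mid panel has SNPs outside the high panel")
    called <- rownames(target)[rowSums(!is.na(dosageMatrix(target))) > 0]
    if (length(setdiff(called, midIds)))
        stop("panel nesting violated: target has called SNPs outside the mid panel")
    step1 <- imputeGenotypes(restrictToPanel(
        target, markerPanel("mid", midIds)), midReference, ped, options)
    step2 <- imputeGenotypes(step1@imputed, highReference, ped, options)
    status <- step2@fillStatus
    status[status %in% c("family", "population")] <-
        paste0(status[status %in% c("family", "population")], "_step2")
    s1 <- step1@fillStatus
    for (lab in c("family", "population")) {
        ij <- which(s1 == lab, arr.ind = TRUE)
        if (!nrow(ij)) next
        status[cbind(match(rownames(s1)[ij[, 1]], rownames(status)),
                     ij[, 2])] <- paste0(lab, "_step1")
    }
    td <- dosageMatrix(target)
    nMiss <- length(highIds) * ncol(td) - sum(!is.na(td))
    filled <- sum(status != "observed" & status != "unfilled")
    new("ImputationResult", imputed = step2@imputed, fillStatus = status,
        imputedCallRate = if (nMiss) filled / nMiss else 1)
}

setMethod("show", "ImputationResult", function(object) {
    tab <- table(object@fillStatus)
    cat("ImputationResult:", nrow(object@imputed), "SNPs x",
        ncol(object@imputed), "samples; imputed call rate",
        sprintf("%.4f", object@imputedCallRate), "\n")
    print(tab)
})
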