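# Custom low-density panel design: expand an anchor panel (e.g. an 8K chip)
# toward a target size with SNPs of high MAF, low LD against their selected
# neighbours, and near-even physical spacing between consecutive anchors.
# MAF and LD are hard constraints; spacing is the objective ("preferably
# evenly spaced").

#' DesignSpec: parameters of a low-density panel design
#'
#' @slot anchorPanel the panel being expanded (all its SNPs are kept).
#' @slot targetTotal requested total panel size.
#' @slot mafMin minimum minor allele frequency for added SNPs (exclusive),
#'   default 0.23.
#' @slot r2Max maximum LD (r-squared) between an added SNP and its nearest
#'   already-selected flanking SNPs (exclusive), default 0.088.
#' @slot candidatePool panel naming the SNPs additions may be drawn from
#'   (e.g. a 50K manifest).
#' @export
setClass("DesignSpec", representation(
    anchorPanel = "MarkerPanel", targetTotal = "integer", mafMin = "numeric",
    r2Max = "numeric", candidatePool = "MarkerPanel"))

setValidity("DesignSpec", function(object) {
    if (object@targetTotal < length(object@anchorPanel))
        return("targetTotal must be >= anchor panel size")
    if (object@mafMin < 0 || object@mafMin > 0.5)
        return("mafMin must lie in [0, 0.5]")
    if (object@r2Max < 0 || object@r2Max > 1)
        return("r2Max must lie in [0, 1]")
    TRUE
})

#' @rdname designLowDensityPanel
#' @param anchorPanel,candidatePool \linkS4class{MarkerPanel}s: the panel to
#'   expand and the pool additions may come from.
#' @param targetTotal requested total number of SNPs.
#' @param mafMin,r2Max hard constraints on added SNPs (defaults 0.23 and
#'   0.088).
#' @export
designSpec <- function(anchorPanel, targetTotal, candidatePool,
                       mafMin = 0.23, r2Max = 0.088) {
    new("DesignSpec", anchorPanel = anchorPanel,
        targetTotal = as.integer(targetTotal), mafMin = mafMin,
        r2Max = r2Max, candidatePool = candidatePool)
}

#' Ideal evenly-spaced positions inside an interval
#'
#' The k ideal positions for placing k SNPs evenly between two flanking
#' positions: \code{left + i * (right - left) / (k + 1)}, i = 1..k, rounded
#' to the nearest integer (round-half-even).
#'
#' @param leftBp,rightBp flanking base-pair positions, \code{leftBp <
#'   rightBp}.
#' @param k number of positions (k = 0 gives an empty vector).
#' @return Integer vector of length k.
#' @examples
#' intervalTargets(0, 100, 3)  # 25 50 75
#' @export
intervalTargets <- function(leftBp, rightBp, k) {
    if (k == 0L) return(integer())
    stopifnot(leftBp < rightBp, k >= 1L)
    as.integer(round(leftBp + seq_len(k) * (rightBp - leftBp) / (k + 1)))
}

# largest-remainder allocation of n among weights
.largestRemainder <- function(n, weights) {
    if (!length(weights)) return(integer())
    exact <- n * weights / sum(weights)
    base <- floor(exact)
    left <- n - sum(base)
    if (left > 0) {
        ord <- order(exact - base, decreasing = TRUE)
        base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
    }
    as.integer(base)
}

#' Design a low-density panel by MAF, LD and spacing
#'
#' Expands the anchor panel to \code{targetTotal} SNPs. Additions are
#' allocated to the intervals between consecutive anchor SNPs (within each
#' chromosome) proportionally to interval length with largest-remainder
#' rounding, then chosen greedily: for each ideal evenly-spaced position the
#' nearest candidate with MAF above \code{mafMin} and r-squared below
#' \code{r2Max} against both nearest already-selected flanking SNPs is
#' added. Distance ties are broken by higher MAF, then by lower SNP id.
#' When an interval runs out of eligible candidates, the panel is returned
#' short and the shortfall reported - never an exception.
#'
#' @param x a \linkS4class{GenotypeData} containing all candidate SNPs.
#' @param spec a \linkS4class{DesignSpec}.
#' @return \code{list(panel =, report =)}: the designed
#'   \linkS4class{MarkerPanel} (anchor plus additions, map order) and a
#'   data.frame with one row per interval (chromosome, left/right anchor
#'   position, quota, filled, reason).
#' @export
designLowDensityPanel <- function(x, spec) {
    stopifnot(is(spec, "DesignSpec"))
    if (spec@mafMin >= 0.5) stop("mafMin >= 0.5 leaves no eligible SNP")
    map <- snpMap(x)
    anchorIds <- intersect(snpIds(spec@anchorPanel), map$snp_id)
    nAdd <- spec@targetTotal - length(snpIds(spec@anchorPanel))
    maf <- minorAlleleFreq(x)
    candIds <- setdiff(intersect(snpIds(spec@candidatePool), map$snp_id),
                       anchorIds)
    candIds <- candIds[!is.na(maf[candIds]) & maf[candIds] > spec@mafMin]

    ord <- order(map$chromosome, map$position)
    map <- map[ord, ]
    anchorRows <- which(map$snp_id %in% anchorIds)
    # intervals between consecutive anchors on the same chromosome
    intervals <- data.frame(chromosome = integer(), leftId = character(),
        left = integer(), rightId = character(), right = integer(),
        stringsAsFactors = FALSE)
    if (length(anchorRows) >= 2L) {
        a <- anchorRows[-length(anchorRows)]
        b <- anchorRows[-1L]
        same <- map$chromosome[a] == map$chromosome[b]
        intervals <- data.frame(
            chromosome = map$chromosome[a][same],
            leftId = map$snp_id[a][same], left = map$position[a][same],
            rightId = map$snp_id[b][same], right = map$position[b][same],
            stringsAsFactors = FALSE)
    }
    if (nAdd == 0L || nrow(intervals) == 0L) {
        panel <- markerPanel(paste0(panelName(spec@anchorPanel), "_expanded"),
                             map$snp_id[map$snp_id %in% anchorIds])
        report <- cbind(intervals, quota = integer(nrow(intervals)),
                        filled = integer(nrow(intervals)),
                        reason = character(nrow(intervals)))
        return(list(panel = panel, report = report))
    }
    quota <- .largestRemainder(nAdd, pmax(intervals$right - intervals$left, 1))
    selected <- character()
    filled <- integer(nrow(intervals))
    reason <- character(nrow(intervals))
    for (iv in seq_len(nrow(intervals))) {
        k <- quota[iv]
        if (k == 0L) next
        inIv <- map$snp_id %in% candIds &
            map$chromosome == intervals$chromosome[iv] &
            map$position > intervals$left[iv] &
            map$position < intervals$right[iv]
        ivIds <- map$snp_id[inIv]
        ivPos <- map$position[inIv]
        ideal <- intervalTargets(intervals$left[iv], intervals$right[iv], k)
        chosenIds <- character()
        chosenPos <- integer()
        for (tpos in ideal) {
            if (!length(ivIds)) break
            avail <- !ivIds %in% chosenIds
            okLd <- vapply(seq_along(ivIds), function(ci) {
                if (!avail[ci]) return(FALSE)
                # nearest already-selected flank on each side
                flankPos <- c(intervals$left[iv], intervals$right[iv],
                              chosenPos)
                flankIds <- c(intervals$leftId[iv], intervals$rightId[iv],
                              chosenIds)
                below <- flankPos < ivPos[ci]
                above <- flankPos > ivPos[ci]
                flanks <- character()
                if (any(below))
                    flanks <- c(flanks, flankIds[below][
                        which.max(flankPos[below])])
                if (any(above))
                    flanks <- c(flanks, flankIds[above][
                        which.min(flankPos[above])])
                all(vapply(flanks, function(f) {
                    r2 <- tryCatch(pairwiseR2(x, ivIds[ci], f),
                                   error = function(e) NA_real_)
                    is.na(r2) || r2 < spec@r2Max
                }, logical(1)))
            }, logical(1))
            if (!any(okLd)) next
            dist <- abs(ivPos - tpos)
            dist[!okLd] <- Inf
            best <- which(dist == min(dist))
            if (length(best) > 1L) {
                bm <- maf[ivIds[best]]
                best <- best[bm == max(bm)]
                if (length(best) > 1L)
                    best <- best[order(ivIds[best])][1L]
            }
            chosenIds <- c(chosenIds, ivIds[best])
            chosenPos <- c(chosenPos, ivPos[best])
        }
        selected <- c(selected, chosenIds)
        filled[iv] <- length(chosenIds)
        reason[iv] <- if (filled[iv] < k) "no eligible candidate" else ""
    }
    keep <- map$snp_id[map$snp_id %in% c(anchorIds, selected)]
    panel <- markerPanel(paste0(panelName(spec@anchorPanel), "_expanded"),
                         keep)
    report <- cbind(intervals, quota = quota, filled = filled,
                    reason = reason, stringsAsFactors = FALSE)
    list(panel = panel, report = report)
}
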