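#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor pchisq rbeta rbinom rnorm rpois runif sd setNames
#' @importFrom utils head read.table write.table
NULL

#' GenotypeData: diploid SNP genotypes with marker map
#'
#' S4 container for biallelic autosomal SNP genotypes, built on
#' \linkS4class{SummarizedExperiment}. Rows are SNPs, columns are samples.
#' The \code{"dosage"} assay counts copies of allele B per genotype
#' (0, 1, 2 or \code{NA} for a missing call). Optional assays:
#' \code{"quality"} (per-call quality scores in [0,1], GenCall-style) and
#' \code{"hap1"}/\code{"hap2"} (phased binary allele-B indicators whose sum
#' equals dosage wherever dosage is called).
#'
#' The marker map lives in \code{rowData}: \code{chromosome} (integer;
#' autosomes are 1-29 on the bovine map, other codes are retained and flagged
#' non-autosomal by QC), \code{position} (1-based bp), \code{alleleA} and
#' \code{alleleB} (single characters, A major / B minor at load time).
#'
#' @seealso \code{\link{genotypeData}} for the constructor,
#'   \code{\link{readPlink}}, \code{\link{dosageMatrix}}
#' @export
setClass("GenotypeData", contains = "SummarizedExperiment")

#' MarkerPanel: an ordered SNP manifest
#'
#' A named, ordered set of SNP identifiers defining a genotyping chip
#' (e.g. the 3K...777K bovine panels). Order follows the manifest; duplicate
#' ids are removed at load time keeping the first occurrence.
#'
#' @slot name single character, the panel label.
#' @slot snpIds character vector of unique SNP identifiers.
#' @seealso \code{\link{markerPanel}}, \code{\link{loadPanel}},
#'   \code{\link{restrictToPanel}}
#' @export
setClass("MarkerPanel",
    representation(name = "character", snpIds = "character"))

setValidity("MarkerPanel", function(object) {
    if (length(object@name) != 1L) return("name must be a single string")
    if (anyDuplicated(object@snpIds)) return("duplicate SNP ids in panel")
    if (length(object@snpIds) == 0L) return("panel is empty")
    TRUE
})

#' Pedigree: animal/sire/dam/birth-year records
#'
#' Whitespace-file-backed pedigree with unknown-parent support. The records
#' data.frame has columns \code{animal}, \code{sire}, \code{dam} (character,
#' \code{NA} = unknown), \code{birth_year} (integer or \code{NA}) and
#' \code{pool} (population label, e.g. breed or cross). Extra columns are
#' retained (the simulator stores the pool of origin of each unknown parent
#' there). Any non-missing parent id without its own record is auto-added as
#' a founder. The pedigree must be cycle-free.
#'
#' @slot records data.frame as described above.
#' @seealso \code{\link{pedigree}}, \code{\link{readPedigree}}
#' @export
setClass("Pedigree", representation(records = "data.frame"))

setValidity("Pedigree", function(object) {
    df <- object@records
    need <- c("animal", "sire", "dam", "birth_year", "pool")
    if (!all(need %in% names(df)))
        return(paste("records must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(df$animal)) return("duplicate animal ids")
    if (any(!is.na(df$sire) & df$sire == df$animal) ||
        any(!is.na(df$dam) & df$dam == df$animal))
        return("animal recorded as its own parent")
    # cycle check: repeatedly peel animals whose parents are all resolved
    ps <- match(df$sire, df$animal)
    pd <- match(df$dam, df$animal)
    resolved <- is.na(ps) & is.na(pd)
    repeat {
        ok_s <- ifelse(is.na(ps), TRUE, resolved[ifelse(is.na(ps), 1L, ps)])
        ok_d <- ifelse(is.na(pd), TRUE, resolved[ifelse(is.na(pd), 1L, pd)])
        newly <- !resolved & ok_s & ok_d
        if (!any(newly)) break
        resolved <- resolved | newly
    }
    if (!all(resolved)) return("pedigree contains a cycle")
    TRUE
})

#' QC thresholds
#'
#' Thresholds for SNP- and sample-level quality control. Defaults follow
#' standard bovine chip QC practice: per-call quality (GenCall) >= 0.15,
#' call rate >= 0.90, Hardy-Weinberg P >= 1e-6, heterozygosity within
#' +/- 3 SD, duplicate concordance >= 0.99, Mendelian opposing-homozygote
#' rate <= 0.01, autosomes only.
#'
#' @seealso \code{\link{qcThresholds}}, \code{\link{snpQC}},
#'   \code{\link{sampleQC}}
#' @export
setClass("QcThresholds", representation(
    minQuality = "numeric", minCallRate = "numeric", minHweP = "numeric",
    hetSdLimit = "numeric", dupConcordance = "numeric",
    maxMendelRate = "numeric", autosomesOnly = "logical"))

setValidity("QcThresholds", function(object) {
    fr <- c(object@minQuality, object@minCallRate, object@dupConcordance,
            object@maxMendelRate)
    if (any(fr < 0 | fr > 1)) return("fractions must lie in [0,1]")
    if (object@minHweP < 0 || object@minHweP > 1)
        return("minHweP must lie in [0,1]")
    if (object@hetSdLimit <= 0) return("hetSdLimit must be > 0")
    TRUE
})

#' QC report
#'
#' Audit trail of a QC pass: one row per removed unit with the filter that
#' removed it (first failing filter in the documented order), the triggering
#' statistic and the threshold, plus before/after counts per axis.
#'
#' @slot removed data.frame with columns unit, axis ("snp"/"sample"),
#'   filter, statistic, threshold.
#' @slot nBefore,nAfter named integer vectors (snp, sample counts).
#' @export
setClass("QcReport", representation(
    removed = "data.frame", nBefore = "integer", nAfter = "integer"))

#' Simulation configuration
#'
#' Parameters of the pedigree-aware genotype simulator: marker grid, founder
#' pools with allele-frequency divergence (Balding-Nichols-style scatter with
#' parameter F around a shared base frequency), first-order-Markov LD along
#' founder haplotypes, pedigree shape, per-call missingness and error, and a
#' mandatory seed. Defaults emulate a two-breed-plus-crossbred beef cattle
#' population: offspring per sire ~ Normal(15.28, 17.38) truncated at 1, and
#' unknown-parent fractions giving ~70% of offspring with sire and/or dam
#' unknown.
#'
#' @seealso \code{\link{simConfig}}, \code{\link{simulatePopulation}}
#' @export
setClass("SimConfig", representation(
    nSnpsPerChrom = "integer", nChroms = "integer", chromLengthBp = "numeric",
    pools = "data.frame", crossbredFraction = "numeric", ldDecay = "numeric",
    generationSizes = "integer", offspringPerSireMean = "numeric",
    offspringPerSireSD = "numeric", unknownSireFraction = "numeric",
    unknownDamFraction = "numeric", birthYearStart = "integer",
    missingRate = "numeric", errorRate = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    fr <- c(object@crossbredFraction, object@unknownSireFraction,
            object@unknownDamFraction, object@missingRate, object@errorRate)
    if (any(fr < 0 | fr > 1)) return("fractions must lie in [0,1]")
    if (object@ldDecay < 0 || object@ldDecay >= 1)
        return("ldDecay must lie in [0,1)")
    if (length(object@seed) != 1L || is.na(object@seed))
        return("seed is mandatory")
    if (!all(c("name", "nFounders", "divergence") %in% names(object@pools)))
        return("pools needs columns name, nFounders, divergence")
    if (any(object@pools$divergence < 0 | object@pools$divergence > 1))
        return("pool divergence F must lie in [0,1]")
    TRUE
})

#' Haplotype library for population imputation
#'
#' Phased reference haplotypes on a full (target) panel, collapsed to unique
#' haplotype patterns with multiplicities. Columns of \code{haps} are unique
#' haplotypes (rows = panel SNPs, values 0/1), \code{weights} counts how many
#' reference gametes carry each pattern, and \code{sources} lists the
#' contributing sample ids.
#'
#' @seealso \code{\link{buildHaplotypeLibrary}}, \code{\link{imputePopulation}}
#' @export
setClass("HaplotypeLibrary", representation(
    snpIds = "character", chromosome = "integer", haps = "matrix",
    weights = "integer", sources = "list"))

setValidity("HaplotypeLibrary", function(object) {
    if (nrow(object@haps) != length(object@snpIds))
        return("haps rows must match snpIds")
    if (ncol(object@haps) != length(object@weights))
        return("weights must match haplotype columns")
    if (length(object@chromosome) != length(object@snpIds))
        return("chromosome must match snpIds")
    if (any(!(object@haps %in% c(0L, 1L))))
        return("library haplotypes must be binary")
    TRUE
})

#' Imputation options
#'
#' Tuning knobs of the reference imputers. \code{windowSchedule} is the
#' strictly decreasing list of sliding-window sizes (in SNPs) tried from
#' longest (close relatives, long haplotype match) to shortest (distant
#' relatives); \code{minMatchFraction} is the fraction of called target
#' alleles a library haplotype must match inside a window to be a candidate
#' (1 = exact matching); \code{minOffspringForParent} is the minimum number
#' of genotyped offspring required before an ungenotyped parent is inferred;
#' \code{allowIncomplete} leaves unresolvable cells missing instead of
#' substituting the reference modal genotype.
#'
#' @seealso \code{\link{imputeOptions}}, \code{\link{imputeGenotypes}}
#' @export
setClass("ImputeOptions", representation(
    usePedigree = "logical", windowSchedule = "integer",
    minMatchFraction = "numeric", minOffspringForParent = "integer",
    allowIncomplete = "logical"))

setValidity("ImputeOptions", function(object) {
    ws <- object@windowSchedule
    if (length(ws) == 0L || any(ws < 2L)) return("window sizes must be >= 2")
    if (length(ws) > 1L && any(diff(ws) >= 0))
        return("windowSchedule must be strictly decreasing")
    if (object@minMatchFraction < 0 || object@minMatchFraction > 1)
        return("minMatchFraction must lie in [0,1]")
    if (object@minOffspringForParent < 1L)
        return("minOffspringForParent must be >= 1")
    TRUE
})

#' Imputation result
#'
#' The imputed dataset plus an audit of where each genotype came from.
#' \code{fillStatus} is a character matrix aligned with the dosage matrix
#' with values \code{"observed"}, \code{"family"}, \code{"population"}
#' (suffixed \code{"_step1"}/\code{"_step2"} in two-step runs) or
#' \code{"unfilled"}. \code{imputedCallRate} is the fraction of
#' originally-missing cells that received a genotype. Observed cells are
#' never altered by any imputer.
#'
#' @export
setClass("ImputationResult", representation(
    imputed = "GenotypeData", fillStatus = "matrix",
    imputedCallRate = "numeric"))

#' Masked dataset: truth plus a low-density view
#'
#' Pairing of a complete ("truth") dataset with its masked low-density view:
#' genotypes at SNPs absent from the low-density panel are hidden for every
#' sample, emulating low-density genotyping with known truth. \code{mask} is
#' TRUE exactly at hidden cells; truth-missing cells are never counted as
#' masked.
#'
#' @seealso \code{\link{maskToPanel}}
#' @export
setClass("MaskedGenotypes", representation(
    truth = "GenotypeData", observed = "GenotypeData", mask = "matrix"))

setValidity("MaskedGenotypes", function(object) {
    if (!identical(dim(object@mask), dim(object@truth)))
        return("mask dimensions must match truth")
    if (!is.logical(object@mask)) return("mask must be logical")
    TRUE
})

#' Accuracy report
#'
#' Concordance rate (CR) and allelic R-squared overall and stratified by
#' animal, SNP, chromosome and minor-allele-frequency class, plus the
#' imputed-call rate and counts of animals per CR bin. Metric values lie in
#' [0,1]; units where a metric is undefined (no filled masked cells, or zero
#' variance for R-squared) carry \code{NA} and are excluded from means with
#' their count reported.
#'
#' @seealso \code{\link{evaluateImputation}}, \code{\link{runScenario}}
#' @export
setClass("AccuracyReport", representation(
    overall = "numeric", perAnimal = "data.frame", perSnp = "data.frame",
    perChromosome = "data.frame", perMafClass = "data.frame",
    crBinCounts = "integer", scenario = "list"))

#' Scenario configuration
#'
#' One imputation benchmarking scenario: how to split reference and
#' imputation populations (birth-year cutoff, with an optional pool pinned
#' to the reference side regardless of year), which panels to use, whether
#' pedigree information is used, one- or two-step imputation, imputer
#' options and the seed.
#'
#' @seealso \code{\link{scenarioConfig}}, \code{\link{runScenario}}
#' @export
setClass("ScenarioConfig", representation(
    name = "character", cutoffYear = "numeric", lowPanel = "MarkerPanel",
    midPanel = "ANY", includePool = "character", usePedigree = "logical",
    steps = "character", options = "ImputeOptions", seed = "integer"))

setValidity("ScenarioConfig", function(object) {
    if (!object@steps %in% c("one", "two"))
        return("steps must be 'one' or 'two'")
    if (object@steps == "two" && !is(object@midPanel, "MarkerPanel"))
        return("two-step scenarios need a midPanel")
    TRUE
})
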