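# Masking protocol, accuracy metrics (concordance rate, allelic R2) with
# the stratifications used in imputation benchmarking (per animal, per SNP,
# per chromosome, per MAF class, CR bins), and the scenario runner.
#
# Conventions: the CR denominator excludes cells the imputer left uncalled
# (the imputed-call rate is reported alongside); undefined metrics are NA,
# never silently NaN.

#' Mask genotypes down to a low-density panel
#'
#' Hides, for every sample, the genotypes at SNPs absent from the
#' low-density panel, emulating low-density genotyping with known truth.
#' Cells that are already missing in the truth are excluded from the mask.
#'
#' @param truth a \linkS4class{GenotypeData} (the high-density genotypes).
#' @param lowPanel a \linkS4class{MarkerPanel}; must not cover the whole
#'   truth SNP set (nothing to mask) and must intersect it.
#' @return A \linkS4class{MaskedGenotypes}.
#' @export
maskToPanel <- function(truth, lowPanel) {
    keep <- rownames(truth) %in% snpIds(lowPanel)
    if (!any(keep)) stop("low panel shares no SNPs with the truth set")
    if (all(keep)) stop("low panel covers every truth SNP; nothing to mask")
    d <- dosageMatrix(truth)
    mask <- matrix(FALSE, nrow(d), ncol(d), dimnames = dimnames(d))
    mask[!keep, ] <- TRUE
    mask[is.na(d)] <- FALSE  # truth-missing cells are never masked
    obs <- d
    obs[!keep, ] <- NA_integer_
    observed <- genotypeData(obs, snpMap(truth), sampleIds = colnames(d))
    new("MaskedGenotypes", truth = truth, observed = observed, mask = mask)
}

#' Split animals into reference and imputation populations
#'
#' Genotyped animals born in the cutoff year form the imputation
#' population; everyone else goes to the reference. A named pool (e.g. the
#' indicine analogue) can be pinned to the reference side regardless of
#' birth year.
#'
#' @param ped a \linkS4class{Pedigree} with birth years for the genotyped
#'   animals.
#' @param x a \linkS4class{GenotypeData}; its samples are the animals being
#'   split.
#' @param cutoffYear a year, or "latest" (default) for the most recent
#'   birth year among genotyped animals.
#' @param includePool optional pool name whose animals always stay in the
#'   reference.
#' @return \code{list(reference =, imputation =)} character vectors of
#'   sample ids.
#' @export
splitReferenceImputation <- function(ped, x, cutoffYear = "latest",
                                     includePool = NULL) {
    df <- pedRecords(ped)
    ids <- colnames(x)
    rec <- df[match(ids, df$animal), ]
    if (identical(cutoffYear, "latest")) {
        if (all(is.na(rec$birth_year)))
            stop("no birth years available to split on")
        cutoffYear <- max(rec$birth_year, na.rm = TRUE)
    }
    imp <- !is.na(rec$birth_year) & rec$birth_year == cutoffYear
    if (!is.null(includePool))
        imp <- imp & !(rec$pool %in% includePool)
    if (!any(imp)) stop("imputation population is empty at cutoff year ",
                        cutoffYear)
    list(reference = ids[!imp], imputation = ids[imp])
}

# shared bookkeeping: evaluated cells are masked cells where the imputer
# made a call; 'correct' marks agreement with the truth
.evalCells <- function(truth, imputed, mask) {
    td <- if (is(truth, "GenotypeData")) dosageMatrix(truth) else truth
    id <- if (is(imputed, "GenotypeData")) dosageMatrix(imputed) else imputed
    stopifnot(identical(dim(td), dim(id)), identical(dim(td), dim(mask)))
    if (!any(mask)) stop("no masked cells to evaluate")
    filled <- mask & !is.na(id)
    list(td = td, id = id, filled = filled,
         correct = filled & !is.na(td) & id == td)
}

.safeDiv <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Concordance rate of imputed genotypes
#'
#' Fraction of masked, imputed genotype calls that equal the truth. The
#' denominator excludes cells the imputer left uncalled (see
#' \code{imputedCallRate}); units with no evaluable cell are NA.
#'
#' @param truth,imputed \linkS4class{GenotypeData} or dosage matrices of
#'   identical shape.
#' @param mask logical matrix, TRUE at hidden cells.
#' @param scope "overall", "per-animal", "per-SNP" or "per-chromosome".
#' @param chromosomes integer vector of per-SNP chromosomes (needed for
#'   scope "per-chromosome" with matrix input; taken from the map when
#'   \code{truth} is a GenotypeData).
#' @return A fraction (overall) or a named vector per scope unit.
#' @export
concordanceRate <- function(truth, imputed, mask,
                            scope = c("overall", "per-animal", "per-SNP",
                                      "per-chromosome"),
                            chromosomes = NULL) {
    scope <- match.arg(scope)
    e <- .evalCells(truth, imputed, mask)
    switch(scope,
        "overall" = .safeDiv(sum(e$correct), sum(e$filled)),
        "per-animal" = setNames(
            .safeDiv(colSums(e$correct), colSums(e$filled)),
            colnames(e$td)),
        "per-SNP" = setNames(
            .safeDiv(rowSums(e$correct), rowSums(e$filled)),
            rownames(e$td)),
        "per-chromosome" = {
            if (is.null(chromosomes) && is(truth, "GenotypeData"))
                chromosomes <- SummarizedExperiment::rowData(
                    truth)$chromosome
            if (is.null(chromosomes))
                stop("per-chromosome scope needs chromosome assignments")
            num <- tapply(rowSums(e$correct), chromosomes, sum)
            den <- tapply(rowSums(e$filled), chromosomes, sum)
            setNames(.safeDiv(as.numeric(num), as.numeric(den)),
                     names(num))
        })
}

#' Allelic R-squared of imputed genotypes
#'
#' Squared Pearson correlation between the true and imputed minor-allele
#' dosages over filled masked cells, pooled overall or within each animal
#' or SNP. Undefined (NA) when fewer than two cells are evaluable or either
#' vector is constant. Invariant under dosage reflection (x to 2-x) of both
#' matrices.
#'
#' @inheritParams concordanceRate
#' @param scope "overall", "per-animal" or "per-SNP".
#' @return A fraction in [0,1] or a named vector, NA where undefined.
#' @export
allelicR2 <- function(truth, imputed, mask,
                      scope = c("overall", "per-animal", "per-SNP")) {
    scope <- match.arg(scope)
    e <- .evalCells(truth, imputed, mask)
    r2 <- function(x, y) {
        ok <- !is.na(x)
        x <- x[ok]; y <- y[ok]
        if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) return(NA_real_)
        cor(x, y)^2
    }
    switch(scope,
        "overall" = r2(e$td[e$filled], e$id[e$filled]),
        "per-animal" = setNames(vapply(seq_len(ncol(e$td)), function(j) {
            f <- e$filled[, j]
            r2(e$td[f, j], e$id[f, j])
        }, numeric(1)), colnames(e$td)),
        "per-SNP" = setNames(vapply(seq_len(nrow(e$td)), function(i) {
            f <- e$filled[i, ]
            r2(e$td[i, f], e$id[i, f])
        }, numeric(1)), rownames(e$td)))
}

#' Concordance rate stratified by MAF class
#'
#' Partitions masked SNPs into the minor-allele-frequency classes
#' [0, 0.01), [0.01, 0.05] and (0.05, 0.5] (boundary ownership: the middle
#' class is closed on both sides) and computes the concordance rate within
#' each class. Empty classes are NA.
#'
#' @inheritParams concordanceRate
#' @param maf numeric vector of per-SNP minor allele frequencies.
#' @param edges the two inner class boundaries, default c(0.01, 0.05).
#' @return Named numeric vector of per-class CRs with an attribute
#'   \code{"n"} giving filled masked cell counts per class.
#' @export
stratifyByMaf <- function(truth, imputed, mask, maf,
                          edges = c(0.01, 0.05)) {
    e <- .evalCells(truth, imputed, mask)
    stopifnot(length(maf) == nrow(e$td))
    cls <- ifelse(is.na(maf), NA_character_,
        ifelse(maf < edges[1], sprintf("<%g", edges[1]),
        ifelse(maf <= edges[2], sprintf("%g-%g", edges[1], edges[2]),
               sprintf(">%g", edges[2]))))
    levs <- c(sprintf("<%g", edges[1]),
              sprintf("%g-%g", edges[1], edges[2]),
              sprintf(">%g", edges[2]))
    num <- rowSums(e$correct); den <- rowSums(e$filled)
    out <- vapply(levs, function(lv) {
        sel <- !is.na(cls) & cls == lv
        .safeDiv(sum(num[sel]), sum(den[sel]))
    }, numeric(1))
    attr(out, "n") <- vapply(levs, function(lv)
        sum(den[!is.na(cls) & cls == lv]), numeric(1))
    out
}

#' Bin per-animal concordance rates
#'
#' Right-open bins except the last, which is closed at 1: with the default
#' edges c(0.90, 0.95, 0.99) the bins are [0, 0.90), [0.90, 0.95),
#' [0.95, 0.99) and [0.99, 1]. NA values are dropped; counts sum to the
#' number of non-NA values.
#'
#' @param values per-animal CR values in [0,1].
#' @param edges increasing bin edges inside (0,1).
#' @return Named integer vector of counts per bin.
#' @export
crBins <- function(values, edges = c(0.90, 0.95, 0.99)) {
    values <- values[!is.na(values)]
    stopifnot(all(values >= 0 & values <= 1))
    breaks <- c(0, edges, 1 + 1e-9)
    labs <- c(sprintf("[0,%g)", edges[1]),
              sprintf("[%g,%g)", edges[-length(edges)], edges[-1]),
              sprintf("[%g,1]", edges[length(edges)]))
    setNames(as.integer(table(cut(values, breaks, right = FALSE,
                                  labels = labs))), labs)
}

#' Arcsine square root transform
#'
#' \code{asin(sqrt(x))}: the variance-stabilising transform applied to
#' proportions (CR, allelic R2) before analysis of variance. Monotone on
#' [0,1] with range [0, pi/2].
#'
#' @param x fractions in [0,1].
#' @return Transformed values.
#' @export
arcsineSqrt <- function(x) {
    if (any(x < 0 | x > 1, na.rm = TRUE))
        stop("arcsineSqrt is defined on [0,1] only")
    asin(sqrt(x))
}

#' Evaluate an imputation result against the truth
#'
#' Computes the full accuracy report for a masked dataset and its
#' imputation: overall and stratified concordance rates, allelic R2,
#' imputed-call rate and CR-bin counts.
#'
#' @param masked a \linkS4class{MaskedGenotypes}.
#' @param result an \linkS4class{ImputationResult} on the same grid.
#' @param maf optional per-SNP MAF vector for the MAF-class decomposition
#'   (default: computed from the truth over all samples).
#' @param scenario list of scenario metadata to carry in the report.
#' @return An \linkS4class{AccuracyReport}.
#' @export
evaluateImputation <- function(masked, result, maf = NULL,
                               scenario = list()) {
    truth <- masked@truth
    imputed <- result@imputed
    mask <- masked@mask
    if (is.null(maf)) maf <- minorAlleleFreq(truth)
    perAnimalCr <- concordanceRate(truth, imputed, mask, "per-animal")
    perAnimalR2 <- allelicR2(truth, imputed, mask, "per-animal")
    perSnpCr <- concordanceRate(truth, imputed, mask, "per-SNP")
    perSnpR2 <- allelicR2(truth, imputed, mask, "per-SNP")
    chroms <- SummarizedExperiment::rowData(truth)$chromosome
    perChromCr <- concordanceRate(truth, imputed, mask, "per-chromosome",
                                  chromosomes = chroms)
    mafCr <- stratifyByMaf(truth, imputed, mask, maf)
    e <- .evalCells(truth, imputed, mask)
    filledPerAnimal <- colSums(e$filled)
    maskPerAnimal <- colSums(mask)
    new("AccuracyReport",
        overall = c(cr = concordanceRate(truth, imputed, mask, "overall"),
                    allelicR2 = allelicR2(truth, imputed, mask, "overall"),
                    imputedCallRate = result@imputedCallRate),
        perAnimal = data.frame(
            animal = colnames(mask), cr = unname(perAnimalCr),
            allelicR2 = unname(perAnimalR2),
            nMasked = unname(maskPerAnimal),
            nFilled = unname(filledPerAnimal), stringsAsFactors = FALSE),
        perSnp = data.frame(
            snp_id = rownames(mask), chromosome = chroms,
            maf = unname(maf), cr = unname(perSnpCr),
            allelicR2 = unname(perSnpR2), stringsAsFactors = FALSE),
        perChromosome = data.frame(
            chromosome = names(perChromCr), cr = unname(perChromCr),
            stringsAsFactors = FALSE),
        perMafClass = data.frame(
            class = names(mafCr), cr = as.numeric(mafCr),
            nFilled = as.numeric(attr(mafCr, "n")),
            stringsAsFactors = FALSE),
        crBinCounts = crBins(perAnimalCr),
        scenario = scenario)
}

setMethod("show", "AccuracyReport", function(object) {
    cat("AccuracyReport",
        if (length(object@scenario$name)) paste0("(", object@scenario$name, ")"),
        "\n")
    cat(sprintf("  overall CR %.4f; allelic R2 %.4f; imputed call rate %.4f\n",
        object@overall["cr"], object@overall["allelicR2"],
        object@overall["imputedCallRate"]))
    cat("  animals per CR bin:\n")
    print(object@crBinCounts)
})

#' Construct a scenario configuration
#'
#' @param lowPanel \linkS4class{MarkerPanel} the imputation animals are
#'   genotyped on.
#' @param name scenario label.
#' @param cutoffYear birth-year cutoff or "latest".
#' @param midPanel \linkS4class{MarkerPanel} for two-step runs.
#' @param includePool pool name(s) pinned to the reference population;
#'   use \code{character(0)} to pin none.
#' @param usePedigree use family information.
#' @param steps "one" or "two".
#' @param options an \linkS4class{ImputeOptions}.
#' @param seed integer seed (controls reference subsampling).
#' @param nHighRef optional cap on the number of high-density reference
#'   animals (two-step runs emulate a small high-density reference);
#'   NA = use all.
#' @return A \linkS4class{ScenarioConfig}.
#' @export
scenarioConfig <- function(lowPanel, name = panelName(lowPanel),
                           cutoffYear = "latest", midPanel = NULL,
                           includePool = character(0), usePedigree = TRUE,
                           steps = "one", options = imputeOptions(),
                           seed = 1L, nHighRef = NA_integer_) {
    options@usePedigree <- usePedigree
    cfg <- new("ScenarioConfig", name = name,
        cutoffYear = if (identical(cutoffYear, "latest")) NA_real_
            else as.numeric(cutoffYear),
        lowPanel = lowPanel,
        midPanel = if (is.null(midPanel)) NULL else midPanel,
        includePool = includePool, usePedigree = usePedigree,
        steps = steps, options = options, seed = as.integer(seed))
    attr(cfg, "nHighRef") <- as.integer(nHighRef)
    cfg
}

#' Run a full imputation benchmarking scenario
#'
#' Pipeline: split the genotyped animals into reference and imputation
#' populations by birth year (optionally pinning a pool to the reference),
#' run SNP and sample QC, mask the imputation animals down to the low
#' panel, impute in one or two steps, and score the result. Reference
#' phase is taken from the simulation truth (the engines phase targets
#' heuristically). Fully reproducible from the scenario seed.
#'
#' @param sim a \linkS4class{SimOutput}.
#' @param config a \linkS4class{ScenarioConfig}.
#' @param thresholds \linkS4class{QcThresholds} for the QC stage.
#' @return \code{list(report =, table =, result =, masked =, split =)}:
#'   the \linkS4class{AccuracyReport}, a tidy per-animal metric table
#'   (with arcsine-square-root transformed values) ready for external
#'   analysis of variance, the raw \linkS4class{ImputationResult}, the
#'   \linkS4class{MaskedGenotypes} and the population split.
#' @export
runScenario <- function(sim, config, thresholds = qcThresholds()) {
    stopifnot(is(sim, "SimOutput"), is(config, "ScenarioConfig"))
    observed <- sim@observed
    ped <- sim@pedigree
    qc <- snpQC(observed, thresholds)
    sq <- sampleQC(qc$dataset, ped, thresholds)
    dataset <- sq$dataset
    ped <- sq$pedigree
    cutoff <- if (is.na(config@cutoffYear)) "latest" else config@cutoffYear
    split <- splitReferenceImputation(ped, dataset, cutoff,
        includePool = if (length(config@includePool))
            config@includePool else NULL)
    truthRef <- sim@truth[rownames(dataset), split$reference]
    targetObs <- dataset[, split$imputation]
    masked <- maskToPanel(targetObs, config@lowPanel)
    pedArg <- if (config@usePedigree) ped else NULL
    set.seed(config@seed)
    nHighRef <- attr(config, "nHighRef")
    if (config@steps == "two") {
        midRef <- restrictToPanel(truthRef, config@midPanel)
        highIds <- if (!is.na(nHighRef) &&
                       nHighRef < length(split$reference))
            sort(sample(split$reference, nHighRef)) else split$reference
        highRef <- truthRef[, highIds]
        result <- twoStepImpute(masked@observed, midRef, highRef,
                                pedArg, config@options)
    } else {
        highIds <- if (!is.na(nHighRef) &&
                       nHighRef < length(split$reference))
            sort(sample(split$reference, nHighRef)) else split$reference
        result <- imputeGenotypes(masked@observed, truthRef[, highIds],
                                  pedArg, config@options)
    }
    report <- evaluateImputation(masked, result,
        maf = minorAlleleFreq(dataset, samples = split$reference),
        scenario = list(name = config@name, panel = panelName(config@lowPanel),
                        steps = config@steps,
                        usePedigree = config@usePedigree,
                        seed = config@seed))
    tab <- report@perAnimal
    tab$scenario <- config@name
    tab$panel <- panelName(config@lowPanel)
    tab$steps <- config@steps
    tab$usePedigree <- config@usePedigree
    tab$crAsin <- arcsineSqrt(tab$cr)
    tab$allelicR2Asin <- arcsineSqrt(tab$allelicR2)
    list(report = report, table = tab, result = result, masked = masked,
         split = split)
}

#' Thin a dataset's SNP map into an evenly spaced panel
#'
#' Utility for building benchmark low-density panels: keeps a given
#' fraction of SNPs, evenly spaced along each chromosome.
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param fraction fraction of SNPs to retain (0,1].
#' @param name panel label.
#' @return A \linkS4class{MarkerPanel}.
#' @export
evenPanel <- function(x, fraction, name = sprintf("even%.0f%%",
                                                  100 * fraction)) {
    stopifnot(fraction > 0, fraction <= 1)
    map <- snpMap(x)
    keep <- unlist(lapply(split(seq_len(nrow(map)), map$chromosome),
        function(idx) {
            k <- max(1L, round(length(idx) * fraction))
            idx[unique(as.integer(round(seq(1, length(idx),
                                            length.out = k))))]
        }))
    markerPanel(name, map$snp_id[sort(keep)])
}
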