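# phased reference + library shared across engine tests
libraryFixture <- function(seed = 23, nSnps = 150L) {
    sim <- simulatePopulation(smallSimConfig(seed, nSnps = nSnps,
                                             gens = c(40L, 15L)))
    truth <- simTruth(sim)
    list(sim = sim, truth = truth,
         library = buildHaplotypeLibrary(truth))
}

test_that("haplotype library collapses duplicates and indexes correctly", {
    fx <- libraryFixture()
    lib <- fx$library
    n <- ncol(fx$truth)
    expect_equal(nHaplotypes(lib), 2L * n)      # multiplicity preserved
    expect_lte(ncol(lib@haps), 2L * n)          # unique count <= 2n
    expect_equal(sum(lengths(lib@sources)), 2L * n)
    # one animal -> 2 haplotypes
    one <- buildHaplotypeLibrary(fx$truth[, 1])
    expect_equal(nHaplotypes(one), 2L)
    # window lookup agrees with a linear-scan oracle
    hp <- haplotypeMatrices(fx$truth)
    H <- lib@haps
    set.seed(1)
    for (i in 1:20) {
        a <- sample(nrow(H) - 10L, 1)
        idx <- a:(a + 9L)
        g <- hp$hap1[, sample(n, 1)]
        cand <- PanelImpute:::.windowCandidates(H, g, idx, 1)
        oracle <- which(vapply(seq_len(ncol(H)), function(u)
            all(H[idx, u] == g[idx]), logical(1)))
        expect_identical(cand, oracle)
    }
    # unphased reference is rejected
    unph <- genotypeData(dosageMatrix(fx$truth), snpMap(fx$truth),
                         sampleIds = colnames(fx$truth))
    expect_error(buildHaplotypeLibrary(unph), "unphased")
})

test_that("phase heuristic conserves dosage and recovers exact copies", {
    fx <- libraryFixture()
    # all-homozygous sample phases uniquely
    m <- nrow(fx$truth)
    hom <- matrix(c(0L, 2L)[1 + (seq_len(m) %% 2)], m, 1,
                  dimnames = list(rownames(fx$truth), "homzy"))
    ph <- phaseHeuristic(genotypeData(hom, snpMap(fx$truth)))
    hp <- haplotypeMatrices(ph)
    expect_identical(hp$hap1 + hp$hap2, hom)
    expect_identical(hp$hap1, hp$hap2)
    # a copy of a library animal is phased identically up to pair order
    copy <- genotypeData(dosageMatrix(fx$truth)[, 5, drop = FALSE],
                         snpMap(fx$truth), sampleIds = "copy")
    phc <- phaseHeuristic(copy, fx$library)
    hpc <- haplotypeMatrices(phc)
    orig <- haplotypeMatrices(fx$truth)
    sameOrder <- identical(hpc$hap1[, 1], orig$hap1[, 5]) &&
        identical(hpc$hap2[, 1], orig$hap2[, 5])
    flipped <- identical(hpc$hap1[, 1], orig$hap2[, 5]) &&
        identical(hpc$hap2[, 1], orig$hap1[, 5])
    expect_true(sameOrder || flipped)
    # conservation holds for arbitrary (noisy, incomplete) input
    noisy <- randomGenotypes(60, 8, missingRate = 0.3, seed = 4)
    pn <- phaseHeuristic(noisy)
    hn <- haplotypeMatrices(pn)
    d <- dosageMatrix(noisy)
    called <- !is.na(d)
    expect_identical((hn$hap1 + hn$hap2)[called], d[called])
})

test_that("family imputation fills only Mendelian-forced genotypes", {
    map <- toyMap(4)
    # child missing everywhere; sire/dam genotypes force cells 1 and 2 only
    d <- matrix(c(0L, 0L, 1L, 2L,   # sire
                  0L, 2L, 1L, NA,   # dam
                  NA, NA, NA, NA),  # child
                nrow = 4, dimnames = list(map$snp_id,
                                          c("sire", "dam", "child")))
    gd <- genotypeData(d, map)
    ped <- pedigree(data.frame(animal = c("sire", "dam", "child"),
        sire = c(NA, NA, "sire"), dam = c(NA, NA, "dam"),
        birth_year = 1L, pool = "p"))
    res <- imputeFamily(gd[, "child"], ped, gd)
    out <- dosageMatrix(res@imputed)[, "child"]
    expect_equal(unname(out), c(0L, 1L, NA, NA))
    expect_equal(unname(res@fillStatus[, "child"]),
                 c("family", "family", "unfilled", "unfilled"))
    # observed child cells are never altered
    d2 <- d; d2[1, "child"] <- 2L  # conflicting but observed
    gd2 <- genotypeData(d2, map)
    res2 <- imputeFamily(gd2[, "child"], ped, gd2)
    expect_equal(dosageMatrix(res2@imputed)["s0001", "child"], 2L)
})

test_that("ungenotyped-parent inference follows the offspring-count rules", {
    # fewer than 4 genotyped offspring: typed refusal
    few <- ungenotypedSireCase(3, seed = 1)
    r <- inferUngenotypedParent(few$ped, few$genotypes, "SIRE")
    expect_s3_class(r, "parentInference")
    expect_equal(r$status, "refused")
    expect_equal(r$nOffspring, 3L)
    # 4 offspring, mates aa, offspring dosages (1,1,0,0) -> parent dosage 1
    map <- toyMap(1)
    d <- matrix(c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L), nrow = 1,
                dimnames = list("s0001",
                    c(paste0("kid", 1:4), paste0("dam", 1:4))))
    ped <- pedigree(data.frame(
        animal = c("SIRE", colnames(d)),
        sire = c(NA, rep("SIRE", 4), rep(NA, 4)),
        dam = c(NA, paste0("dam", 1:4), rep(NA, 4)),
        birth_year = 1L, pool = "p"))
    rh <- inferUngenotypedParent(ped, genotypeData(d, map), "SIRE")
    expect_equal(unname(rh$dosage), 1L)
    # 6 offspring all BB with BB mates -> parent BB (two transmissions rule)
    d6 <- matrix(rep(2L, 12), nrow = 1,
                 dimnames = list("s0001",
                     c(paste0("kid", 1:6), paste0("dam", 1:6))))
    ped6 <- pedigree(data.frame(
        animal = c("SIRE", colnames(d6)),
        sire = c(NA, rep("SIRE", 6), rep(NA, 6)),
        dam = c(NA, paste0("dam", 1:6), rep(NA, 6)),
        birth_year = 1L, pool = "p"))
    r6 <- inferUngenotypedParent(ped6, genotypeData(d6, toyMap(1)), "SIRE")
    expect_equal(unname(r6$dosage), 2L)
    expect_equal(r6$resolvedFraction, 1)
    # genotyped parent is an error
    expect_error(inferUngenotypedParent(ped6,
        genotypeData(d6, toyMap(1)), "kid1"), "genotyped")
})

test_that("population imputation recovers exact copies and single candidates", {
    fx <- libraryFixture()
    truth <- fx$truth
    panel <- evenPanel(truth, 0.15)
    target <- genotypeData(dosageMatrix(truth)[, 8, drop = FALSE],
                           snpMap(truth), sampleIds = "copy")
    masked <- maskToPanel(target, panel)
    res <- imputePopulation(masked@observed, fx$library)
    expect_equal(concordanceRate(masked@truth, res@imputed, masked@mask), 1)
    expect_equal(res@imputedCallRate, 1)
    # library of a single animal: fills can only come from its two
    # haplotypes - forced wherever they agree, and always one of the
    # pair-consistent dosages elsewhere
    lib1 <- buildHaplotypeLibrary(truth[, 3])
    res1 <- imputePopulation(masked@observed, lib1)
    d1 <- dosageMatrix(res1@imputed)
    filled <- masked@mask & res1@fillStatus == "population"
    hp3 <- haplotypeMatrices(truth)
    h1 <- hp3$hap1[, 3]; h2 <- hp3$hap2[, 3]
    refM <- matrix(h1 + h2, nrow(d1), ncol(d1))
    agreeM <- matrix(h1 == h2, nrow(d1), ncol(d1))
    expect_true(all(d1[filled & agreeM] == refM[filled & agreeM]))
    rw <- row(d1)[filled]
    vals <- d1[filled]
    expect_true(all(vals == (h1 + h2)[rw] | vals == (2 * h1)[rw] |
                    vals == (2 * h2)[rw]))
    expect_error(imputePopulation(masked@observed,
        new("HaplotypeLibrary", snpIds = rownames(truth),
            chromosome = snpMap(truth)$chromosome,
            haps = matrix(integer(), nrow(truth), 0),
            weights = integer(), sources = list())), "empty")
})

test_that("the orchestrator is deterministic and never alters observed cells", {
    fx <- libraryFixture()
    sim <- fx$sim
    split <- splitReferenceImputation(simPedigree(sim), simObserved(sim))
    ref <- fx$truth[, split$reference]
    tgt <- simObserved(sim)[, split$imputation[1:6]]
    masked <- maskToPanel(tgt, evenPanel(tgt, 0.2))
    optNoPed <- imputeOptions(usePedigree = FALSE)
    a <- imputeGenotypes(masked@observed, ref, simPedigree(sim), optNoPed)
    b <- imputeGenotypes(masked@observed, ref, simPedigree(sim), optNoPed)
    expect_identical(dosageMatrix(a@imputed), dosageMatrix(b@imputed))
    expect_identical(a@fillStatus, b@fillStatus)
    # pedigree bypass equals population-only imputation
    lib <- buildHaplotypeLibrary(ref)
    pop <- imputePopulation(masked@observed, lib)
    expect_identical(dosageMatrix(a@imputed), dosageMatrix(pop@imputed))
    # observed genotypes pass through bit-exactly
    obs <- dosageMatrix(masked@observed)
    out <- dosageMatrix(a@imputed)
    expect_identical(out[!is.na(obs)], obs[!is.na(obs)])
    # family fills never create opposing-homozygote conflicts with a
    # genotyped parent
    withPed <- imputeGenotypes(masked@observed, ref, simPedigree(sim),
                               imputeOptions())
    dImp <- dosageMatrix(withPed@imputed)
    df <- pedRecords(simPedigree(sim))
    pool <- cbind(dosageMatrix(ref), dosageMatrix(masked@observed))
    for (s in colnames(dImp)) {
        fam <- withPed@fillStatus[, s] == "family"
        if (!any(fam)) next
        for (side in c("sire", "dam")) {
            p <- df[[side]][df$animal == s]
            if (is.na(p) || !p %in% colnames(pool)) next
            child <- dImp[fam, s]; par <- pool[fam, p]
            expect_equal(sum((child == 0L & par == 2L) |
                             (child == 2L & par == 0L), na.rm = TRUE), 0)
        }
    }
})

test_that("two-step imputation degenerates and nests correctly", {
    fx <- libraryFixture()
    sim <- fx$sim
    split <- splitReferenceImputation(simPedigree(sim), simObserved(sim))
    ref <- fx$truth[, split$reference]
    # targets taken from the truth so the low-panel view is complete
    tgt <- genotypeData(
        dosageMatrix(fx$truth)[, split$imputation[1:5], drop = FALSE],
        snpMap(fx$truth), sampleIds = split$imputation[1:5])
    mid <- evenPanel(tgt, 0.5, "mid")
    low <- evenPanel(restrictToPanel(tgt, mid), 0.2, "low")
    masked <- maskToPanel(tgt, low)
    opt <- imputeOptions(usePedigree = FALSE)
    # low = mid: step 1 has nothing to fill, so two-step collapses to the
    # single step against the high reference
    degen <- twoStepImpute(masked@observed, restrictToPanel(ref, low),
                           ref, NULL, opt)
    onestep <- imputeGenotypes(masked@observed, ref, NULL, opt)
    expect_identical(dosageMatrix(degen@imputed),
                     dosageMatrix(onestep@imputed))
    # nesting violations are rejected
    badMid <- restrictToPanel(ref, low)[1:10, ]
    expect_error(twoStepImpute(masked@observed, badMid, ref, NULL, opt),
                 "nesting")
    # a target duplicated in the mid reference reaches CR 1 after step 1
    dup <- genotypeData(dosageMatrix(fx$truth)[, 2, drop = FALSE],
                        snpMap(fx$truth), sampleIds = "dup")
    mdup <- maskToPanel(dup, low)
    res <- twoStepImpute(mdup@observed, restrictToPanel(fx$truth, mid),
                         fx$truth, NULL, opt)
    expect_equal(concordanceRate(mdup@truth, res@imputed, mdup@mask), 1)
})
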