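test_that("masking hides exactly the off-panel cells", {
    gd <- randomGenotypes(100, 12, seed = 8)
    keep <- markerPanel("low", sprintf("s%04d", 1:25))
    m <- maskToPanel(gd, keep)
    expect_equal(sum(colSums(m@mask) != 75), 0)  # 75 masked SNPs per sample
    expect_true(all(is.na(dosageMatrix(m@observed)[26:100, ])))
    expect_identical(dosageMatrix(m@observed)[1:25, ],
                     dosageMatrix(gd)[1:25, ])
    # truth-missing cells are excluded from the mask
    d <- dosageMatrix(gd)
    d[c(30L, 40L, 50L), 1] <- NA_integer_
    gdm <- genotypeData(d, snpMap(gd), sampleIds = colnames(d))
    mm <- maskToPanel(gdm, keep)
    expect_equal(sum(mm@mask), 75 * 12 - 3)
    # degenerate panels are rejected
    expect_error(maskToPanel(gd, markerPanel("all", rownames(gd))),
                 "nothing to mask")
    expect_error(maskToPanel(gd, markerPanel("other", "zzz")), "no SNPs")
    # one-SNP mask
    m1 <- maskToPanel(gd, markerPanel("minus1", sprintf("s%04d", 1:99)))
    expect_equal(sum(m1@mask), 12)
})

test_that("reference/imputation split follows birth year and pool pinning", {
    ped <- pedigree(data.frame(
        animal = sprintf("a%02d", 1:10),
        sire = NA, dam = NA,
        birth_year = c(rep(2009L, 4), rep(2010L, 3), rep(2011L, 3)),
        pool = c(rep("taurus", 8), "indicus", "indicus"),
        stringsAsFactors = FALSE))
    gd <- randomGenotypes(10, 10, seed = 1)
    colnames(gd) <- sprintf("a%02d", 1:10)
    sp <- splitReferenceImputation(ped, gd)
    expect_length(sp$imputation, 3)
    expect_length(sp$reference, 7)
    expect_setequal(sp$imputation, c("a08", "a09", "a10"))
    # pinning keeps the indicine-analogue animals in the reference
    spPin <- splitReferenceImputation(ped, gd, includePool = "indicus")
    expect_setequal(spPin$imputation, "a08")
    expect_true(all(c("a09", "a10") %in% spPin$reference))
    # all animals before the cutoff year -> empty imputation set -> error
    expect_error(splitReferenceImputation(ped, gd, cutoffYear = 2012),
                 "empty")
})

test_that("concordance rate matches a brute-force counting oracle", {
    set.seed(33)
    for (i in 1:20) {
        m <- sample(5:25, 1); n <- sample(3:10, 1)
        truth <- matrix(sample(0:2, m * n, TRUE), m, n,
                        dimnames = list(sprintf("s%02d", 1:m),
                                        sprintf("a%02d", 1:n)))
        imp <- truth
        flip <- matrix(runif(m * n) < 0.3, m, n)
        imp[flip] <- (imp[flip] + 1L) %% 3L
        imp[matrix(runif(m * n) < 0.1, m, n)] <- NA_integer_
        mask <- matrix(runif(m * n) < 0.5, m, n, dimnames = dimnames(truth))
        if (!any(mask)) next
        num <- den <- 0
        for (r in 1:m) for (cl in 1:n) {
            if (!mask[r, cl] || is.na(imp[r, cl])) next
            den <- den + 1
            if (imp[r, cl] == truth[r, cl]) num <- num + 1
        }
        if (den == 0) next
        expect_identical(concordanceRate(truth, imp, mask), num / den)
    }
    # trivial values
    t0 <- matrix(rep(0:2, 4), 3, 4, dimnames = list(paste0("s", 1:3),
                                                    paste0("a", 1:4)))
    mk <- matrix(TRUE, 3, 4, dimnames = dimnames(t0))
    expect_equal(concordanceRate(t0, t0, mk), 1)
})

test_that("allelic R2 equals the correlation oracle and is reflection-invariant", {
    truth <- matrix(c(0L, 1L, 2L, 2L, 0L), 5, 1,
                    dimnames = list(paste0("s", 1:5), "a1"))
    imp <- matrix(c(0L, 1L, 1L, 2L, 0L), 5, 1, dimnames = dimnames(truth))
    mask <- matrix(TRUE, 5, 1, dimnames = dimnames(truth))
    expect_equal(allelicR2(truth, imp, mask),
                 cor(truth[, 1], imp[, 1])^2, tolerance = 1e-12)
    expect_equal(allelicR2(truth, truth, mask), 1)
    expect_equal(allelicR2(truth, 2L - truth, mask), 1)  # reflection
    refl <- allelicR2(2L - truth, 2L - imp, mask)
    expect_equal(refl, allelicR2(truth, imp, mask), tolerance = 1e-12)
    # constant vectors are flagged undefined
    const <- matrix(1L, 5, 1, dimnames = dimnames(truth))
    expect_true(is.na(allelicR2(const, imp, mask)))
})

test_that("MAF stratification partitions SNPs with the documented boundaries", {
    set.seed(44)
    m <- 200; n <- 10
    truth <- matrix(sample(0:2, m * n, TRUE), m, n,
                    dimnames = list(sprintf("s%03d", 1:m),
                                    sprintf("a%02d", 1:n)))
    imp <- truth
    imp[matrix(runif(m * n) < 0.2, m, n)] <- 0L
    mask <- matrix(TRUE, m, n, dimnames = dimnames(truth))
    maf <- runif(m, 0, 0.5)
    maf[1] <- 0.01   # boundary: belongs to the middle class
    maf[2] <- 0.05   # boundary: still middle class
    out <- stratifyByMaf(truth, imp, mask, maf)
    expect_named(out, c("<0.01", "0.01-0.05", ">0.05"))
    cls <- cut(maf, c(-Inf, 0.01 - 1e-12, 0.05, Inf),
               labels = c("lo", "mid", "hi"), right = TRUE)
    expect_equal(as.integer(attr(out, "n")["0.01-0.05"]),
                 sum(cls == "mid") * n)
    # class CRs match direct computation
    for (lv in levels(cls)) {
        sel <- cls == lv
        expect_equal(unname(out[match(lv, levels(cls))]),
                     mean((imp == truth)[sel, ]), tolerance = 1e-12)
    }
})

test_that("CR bins are right-open with a closed top bin", {
    expect_equal(unname(crBins(c(0.89, 0.93, 0.96))),
                 c(1L, 1L, 1L, 0L))
    expect_equal(unname(crBins(rep(1, 5))), c(0L, 0L, 0L, 5L))
    expect_equal(unname(crBins(c(0.90, 0.95, 0.99))), c(0L, 1L, 1L, 1L))
    set.seed(9)
    v <- runif(1000)
    bins <- crBins(v)
    expect_equal(sum(bins), 1000L)
    expect_equal(unname(bins[1]), sum(v < 0.90))
    expect_equal(unname(bins[4]), sum(v >= 0.99))
})

test_that("arcsine square root transform matches its closed form", {
    expect_equal(arcsineSqrt(0), 0)
    expect_equal(arcsineSqrt(1), pi / 2)
    expect_equal(arcsineSqrt(0.5), pi / 4)
    x <- seq(0, 1, by = 0.1)
    expect_true(all(diff(arcsineSqrt(x)) > 0))  # monotone
    expect_error(arcsineSqrt(1.2), "\\[0,1\\]")
})

test_that("stratified CRs reaggregate to the overall CR", {
    sim <- simulatePopulation(smallSimConfig(3, nSnps = 120L,
                                             gens = c(30L, 12L)))
    run <- runScenario(sim, scenarioConfig(
        evenPanel(simObserved(sim), 0.25), seed = 2))
    rep <- run$report
    # masked-cell-weighted mean of MAF-class CRs equals the overall CR
    cls <- rep@perMafClass
    ok <- !is.na(cls$cr)
    expect_equal(sum(cls$cr[ok] * cls$nFilled[ok]) / sum(cls$nFilled[ok]),
                 unname(rep@overall["cr"]), tolerance = 1e-12)
    # per-animal reaggregation
    pa <- rep@perAnimal
    expect_equal(sum(pa$cr * pa$nFilled, na.rm = TRUE) /
                 sum(pa$nFilled[!is.na(pa$cr)]),
                 unname(rep@overall["cr"]), tolerance = 1e-12)
    # pipeline conservation: unmasked cells pass through bit-exactly
    obs <- dosageMatrix(run$masked@observed)
    out <- dosageMatrix(run$result@imputed)
    expect_identical(out[!is.na(obs)], obs[!is.na(obs)])
    # determinism of the whole scenario
    run2 <- runScenario(sim, scenarioConfig(
        evenPanel(simObserved(sim), 0.25), seed = 2))
    expect_equal(run2$report@overall, rep@overall)
    expect_identical(dosageMatrix(run2$result@imputed), out)
    # the tidy table carries the transformed metrics
    expect_true(all(c("crAsin", "allelicR2Asin") %in% names(run$table)))
    expect_equal(run$table$crAsin, arcsineSqrt(run$table$cr))
})
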