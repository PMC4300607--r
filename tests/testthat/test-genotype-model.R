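test_that("readPlink assigns major/minor alleles and codes dosage", {
    mapTxt <- c("1 snp1 0 100", "1 snp2 0 200")
    # snp1: AA, AG, GG, AG -> A:4 G:4 tie -> A major -> dosages 0,1,2,1
    pedTxt <- c("f a1 0 0 1 -9 A A C C",
                "f a2 0 0 1 -9 A G C C",
                "f a3 0 0 1 -9 G G C T",
                "f a4 0 0 1 -9 A G 0 0")
    gd <- readPlink(pedTxt, mapTxt)
    expect_equal(unname(dosageMatrix(gd)["snp1", ]), c(0L, 1L, 2L, 1L))
    m <- snpMap(gd)
    expect_equal(m$alleleA[1], "A")  # lexicographic tie-break
    expect_equal(m$alleleB[1], "G")
    # snp2: C major (5 of 6), T minor; "0 0" genotype missing
    expect_equal(unname(dosageMatrix(gd)["snp2", ]), c(0L, 0L, 1L, NA))
    expect_equal(m$alleleB[2], "T")
})

test_that("readPlink rejects malformed input", {
    expect_error(readPlink("f a1 0 0 1 -9 A A G", "1 s1 0 1\n1 s2 0 2"),
                 "PED line 1")
    expect_error(
        readPlink(c("f a1 0 0 1 -9 A A", "f a2 0 0 1 -9 C G",
                    "f a3 0 0 1 -9 T T"), "1 s1 0 1"),
        "more than 2 distinct alleles")
})

test_that("PLINK write/read round-trips the dosage matrix exactly", {
    raw <- randomGenotypes(40, 15, missingRate = 0.1, seed = 3)
    # canonicalise first: reading assigns allele B as the minor allele, so
    # round-trip equality is over read-produced datasets
    gd <- readPlink(writePlink(raw)$ped, writePlink(raw)$map)
    txt <- writePlink(gd)
    back <- readPlink(txt$ped, txt$map)
    expect_identical(unname(dosageMatrix(back)), unname(dosageMatrix(gd)))
    expect_identical(snpMap(back)$position, snpMap(gd)$position)
    # missing cells come back as written "0 0"
    expect_identical(is.na(dosageMatrix(back)), is.na(dosageMatrix(gd)))
    # degenerate: zero samples
    empty <- gd[, integer(0)]
    txt0 <- writePlink(empty)
    expect_length(txt0$ped, 0)
    expect_length(txt0$map, 40)
})

test_that("minimal VCF reader maps GT to dosage and records phase", {
    vcf <- c("##fileformat=VCFv4.2",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
             "1\t100\tv1\tA\tG\t.\t.\t.\tGT\t0/1\t1/1\t./.",
             "1\t200\tv2\tT\tC\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
             "1\t300\tv3\tA\tC,G\t.\t.\t.\tGT\t0/0\t0/0\t0/0")
    expect_warning(gd <- readVcfMinimal(vcf), "multiallelic")
    expect_equal(nrow(gd), 2)
    expect_equal(unname(dosageMatrix(gd)["v1", ]), c(1L, 2L, NA))
    expect_equal(snpMap(gd)$alleleA, c("A", "T"))  # REF is allele A
    expect_equal(S4Vectors::metadata(gd)$parseReport$skippedMultiallelic, 1L)
    expect_false(isPhased(gd))
    # fully phased file -> haplotypes recorded
    vcfP <- c("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
              "1\t100\tv1\tA\tG\t.\t.\t.\tGT\t0|1\t1|1\t0|0")
    gp <- readVcfMinimal(vcfP)
    expect_true(isPhased(gp))
    hp <- haplotypeMatrices(gp)
    expect_equal(unname(hp$hap1["v1", ]), c(0L, 1L, 0L))
    expect_equal(unname(hp$hap2["v1", ]), c(1L, 1L, 0L))
})

test_that("panel manifests load with duplicate handling", {
    p <- loadPanel(c("s1", "s2", "", "s3", "s2"), "toy")
    expect_equal(snpIds(p), c("s1", "s2", "s3"))
    expect_equal(attr(p, "nDuplicates"), 1L)
    expect_error(loadPanel(c("", "  "), "empty"), "empty")
    # a manifest at the scale of a commercial 3K chip loads cleanly
    big <- loadPanel(sprintf("snp%05d", seq_len(2900)), "chip3K")
    expect_length(snpIds(big), 2900)
})

test_that("restrictToPanel keeps the intersection in map order", {
    gd <- randomGenotypes(10, 4)
    all <- markerPanel("all", rownames(gd))
    expect_identical(dosageMatrix(restrictToPanel(gd, all)),
                     dosageMatrix(gd))
    sub <- markerPanel("sub", c("s0007", "s0002", "s0004", "nope"))
    r <- restrictToPanel(gd, sub)
    expect_equal(rownames(r), c("s0002", "s0004", "s0007"))
    expect_error(restrictToPanel(gd, markerPanel("none", "zzz")),
                 "no SNPs shared")
})

test_that("call rate and MAF match element-wise counting oracles", {
    for (seed in 1:5) {
        gd <- randomGenotypes(20, 30, missingRate = 0.2, seed = seed)
        d <- dosageMatrix(gd)
        crOracle <- apply(d, 1, function(r) sum(!is.na(r)) / length(r))
        expect_equal(unname(callRate(gd, "snp")), unname(crOracle))
        crS <- apply(d, 2, function(cl) sum(!is.na(cl)) / length(cl))
        expect_equal(unname(callRate(gd, "sample")), unname(crS))
        mafOracle <- apply(d, 1, function(r) {
            r <- r[!is.na(r)]
            if (!length(r)) return(NA_real_)
            p <- sum(r) / (2 * length(r))
            min(p, 1 - p)
        })
        expect_equal(unname(minorAlleleFreq(gd)), unname(mafOracle))
    }
})

test_that("MAF handles the documented edge cases", {
    d <- matrix(c(1L, 1L, 1L, 1L,    # all heterozygous -> 0.5
                  0L, 0L, 0L, 0L,    # all major hom -> 0
                  0L, 1L, 2L, 2L,    # plus a missing fifth sample below
                  NA, NA, NA, NA),
                nrow = 4, byrow = TRUE)
    d <- cbind(d, c(1L, 0L, NA, NA))
    gd <- genotypeData(d, toyMap(4), sampleIds = sprintf("x%d", 1:5))
    maf <- unname(minorAlleleFreq(gd))
    expect_equal(maf[1], 0.5)
    expect_equal(maf[2], 0)
    expect_equal(maf[3], 0.375)  # dosages (0,1,2,2,NA): 5/8 vs 3/8
    expect_true(is.na(maf[4]))
    expect_error(minorAlleleFreq(gd, samples = character(0)), "empty")
})

test_that("pairwise r2 equals squared correlation and is reflection-invariant", {
    gd <- randomGenotypes(10, 50, seed = 7)
    d <- dosageMatrix(gd)
    r2 <- pairwiseR2(gd, "s0001", "s0002")
    expect_equal(r2, cor(d[1, ], d[2, ])^2, tolerance = 1e-12)
    expect_equal(pairwiseR2(gd, "s0002", "s0001"), r2)      # symmetric
    expect_equal(pairwiseR2(gd, "s0003", "s0003"), 1)       # self
    # reflecting one SNP's coding leaves r2 unchanged
    d2 <- d; d2[1, ] <- 2L - d2[1, ]
    gd2 <- genotypeData(d2, toyMap(10), sampleIds = colnames(d))
    expect_equal(pairwiseR2(gd2, "s0001", "s0002"), r2, tolerance = 1e-12)
    # perfectly collinear pairs
    dd <- matrix(c(0L, 1L, 2L, 0L, 0L, 1L, 2L, 0L), nrow = 2, byrow = TRUE)
    gdd <- genotypeData(dd, toyMap(2), sampleIds = sprintf("y%d", 1:4))
    expect_equal(pairwiseR2(gdd, "s0001", "s0002"), 1)
    # zero variance -> flagged NA, not an error
    dz <- matrix(c(1L, 1L, 1L, 0L, 1L, 2L), nrow = 2, byrow = TRUE)
    gz <- genotypeData(dz, toyMap(2), sampleIds = sprintf("z%d", 1:3))
    expect_true(is.na(pairwiseR2(gz, "s0001", "s0002")))
})

test_that("independent SNPs show near-zero r2 at large n", {
    set.seed(42)
    n <- 10000
    d <- rbind(rbinom(n, 2, 0.4), rbinom(n, 2, 0.6))
    storage.mode(d) <- "integer"
    colnames(d) <- sprintf("i%05d", seq_len(n))
    gd <- genotypeData(d, toyMap(2))
    expect_lt(pairwiseR2(gd, "s0001", "s0002"), 0.01)
})

test_that("pedigree construction auto-adds founders and rejects cycles", {
    p <- pedigree(data.frame(animal = "B", sire = "A", dam = "0",
                             birth_year = 2011, pool = "x"))
    df <- pedRecords(p)
    expect_true("A" %in% df$animal)  # auto-added founder
    expect_true(is.na(df$dam[df$animal == "B"]))
    expect_error(pedigree(data.frame(
        animal = c("A", "B"), sire = c("B", "A"), dam = NA,
        birth_year = 2000, pool = "x")), "cycle")
    # round-trip through the file format
    tf <- tempfile()
    writePedigree(p, tf)
    back <- readPedigree(tf)
    expect_setequal(pedRecords(back)$animal, df$animal)
})
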