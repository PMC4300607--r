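# Programmatic fixtures shared across the test files.

# small marker map on one chromosome
toyMap <- function(m, chrom = 1L, spacing = 1000L) {
    data.frame(snp_id = sprintf("s%04d", seq_len(m)), chromosome = chrom,
               position = seq_len(m) * spacing, alleleA = "A",
               alleleB = "G", stringsAsFactors = FALSE)
}

# random dosage dataset with optional missingness
randomGenotypes <- function(m, n, missingRate = 0, seed = 1) {
    set.seed(seed)
    f <- runif(m, 0.05, 0.95)
    d <- matrix(rbinom(m * n, 2, rep(f, n)), m, n)
    if (missingRate > 0)
        d[matrix(runif(m * n) < missingRate, m, n)] <- NA_integer_
    colnames(d) <- sprintf("a%04d", seq_len(n))
    genotypeData(d, toyMap(m))
}

# small simulation for engine tests: two pools, two offspring generations
smallSimConfig <- function(seed, nSnps = 200L, gens = c(60L, 20L)) {
    simConfig(seed = seed, nSnpsPerChrom = nSnps, nChroms = 2L,
        generationSizes = gens,
        pools = data.frame(name = c("taurus", "indicus"),
                           nFounders = c(20L, 10L),
                           divergence = c(0.05, 0.15),
                           stringsAsFactors = FALSE))
}

# half-sib family with an ungenotyped sire: k genotyped offspring out of
# genotyped dams; returns truth sire dosage for scoring
ungenotypedSireCase <- function(k, seed, m = 500L) {
    set.seed(seed)
    map <- toyMap(m)
    f <- runif(m, 0.05, 0.95)
    sire <- rbinom(m, 2, f)
    kids <- matrix(NA_integer_, m, k)
    dams <- matrix(NA_integer_, m, k)
    for (j in seq_len(k)) {
        dg <- rbinom(m, 2, f)
        dams[, j] <- dg
        fromSire <- ifelse(sire == 1L, rbinom(m, 1, 0.5), sire %/% 2L)
        fromDam <- ifelse(dg == 1L, rbinom(m, 1, 0.5), dg %/% 2L)
        kids[, j] <- fromSire + fromDam
    }
    d <- cbind(kids, dams)
    colnames(d) <- c(sprintf("kid%02d", seq_len(k)),
                     sprintf("dam%02d", seq_len(k)))
    ped <- pedigree(data.frame(
        animal = c("SIRE", colnames(d)),
        sire = c(NA, rep("SIRE", k), rep(NA, k)),
        dam = c(NA, sprintf("dam%02d", seq_len(k)), rep(NA, k)),
        birth_year = 2010L, pool = "p", stringsAsFactors = FALSE))
    list(genotypes = genotypeData(d, map), ped = ped, sire = sire)
}
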