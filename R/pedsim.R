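# Pedigree-aware genotype simulator: founder haplotypes with tunable LD and
# between-pool divergence, a multi-generation half-sib pedigree with
# crossbreeding and unknown parents, gene dropping with Haldane crossovers
# (1 cM/Mb), and per-call missingness/error degradation. Everything is
# reproducible from the config seed.

#' Simulation output bundle
#'
#' @slot truth phased, complete \linkS4class{GenotypeData} for all
#'   genotyped animals.
#' @slot observed the same genotypes after missingness/error degradation
#'   (unphased).
#' @slot pedigree the simulated \linkS4class{Pedigree} (column
#'   \code{genotyped} marks animals present in the datasets).
#' @slot frequencies per-SNP ancestral allele-B frequencies: base pool and
#'   each configured pool.
#' @slot config the \linkS4class{SimConfig} used.
#' @export
setClass("SimOutput", representation(
    truth = "GenotypeData", observed = "GenotypeData",
    pedigree = "Pedigree", frequencies = "data.frame", config = "SimConfig"))

setMethod("show", "SimOutput", function(object) {
    cat("SimOutput:", ncol(object@truth), "genotyped animals x",
        nrow(object@truth), "SNPs;",
        nrow(pedRecords(object@pedigree)), "pedigree records\n")
})

#' Construct a simulation configuration
#'
#' Defaults describe the package's standard benchmark population: 2
#' chromosomes of 1,000 SNPs on 100 Mb (1 Morgan) each, two diverged founder
#' pools (a taurine and an indicine analogue, Balding-Nichols divergence
#' F = 0.05 and 0.15) plus crossbred offspring, strong adjacent-marker LD
#' (0.9), two offspring generations of 210 and 60 animals over 90 genotyped
#' founder males, offspring per sire ~ Normal(15.28, 17.38) truncated at 1,
#' unknown-parent fractions giving ~70\% of offspring with sire and/or dam
#' unknown, and light genotyping noise (0.5\% missing, 0.1\% error).
#'
#' @param seed mandatory integer seed; every downstream draw derives from
#'   it.
#' @param nSnpsPerChrom,nChroms,chromLengthBp marker grid.
#' @param pools data.frame with columns name, nFounders, divergence.
#' @param crossbredFraction probability that a mating crosses pools.
#' @param ldDecay adjacent-SNP allele copy probability in [0,1) along
#'   founder haplotypes.
#' @param generationSizes integer vector: number of offspring per
#'   generation (empty = founders only).
#' @param offspringPerSireMean,offspringPerSireSD offspring-per-sire
#'   distribution (normal, rounded, truncated at 1).
#' @param unknownSireFraction,unknownDamFraction per-offspring masking
#'   probabilities.
#' @param birthYearStart founders' birth year; generation g is born
#'   \code{birthYearStart + g}.
#' @param missingRate,errorRate per-call degradation rates.
#' @return A \linkS4class{SimConfig}.
#' @export
simConfig <- function(seed, nSnpsPerChrom = 1000L, nChroms = 2L,
                      chromLengthBp = 1e8,
                      pools = data.frame(
                          name = c("taurus", "indicus"),
                          nFounders = c(60L, 30L),
                          divergence = c(0.05, 0.15),
                          stringsAsFactors = FALSE),
                      crossbredFraction = 0.7, ldDecay = 0.9,
                      generationSizes = c(210L, 60L),
                      offspringPerSireMean = 15.28,
                      offspringPerSireSD = 17.38,
                      unknownSireFraction = 0.5,
                      unknownDamFraction = 0.4,
                      birthYearStart = 2008L,
                      missingRate = 0.005, errorRate = 0.001) {
    new("SimConfig", nSnpsPerChrom = as.integer(nSnpsPerChrom),
        nChroms = as.integer(nChroms), chromLengthBp = chromLengthBp,
        pools = pools, crossbredFraction = crossbredFraction,
        ldDecay = ldDecay, generationSizes = as.integer(generationSizes),
        offspringPerSireMean = offspringPerSireMean,
        offspringPerSireSD = offspringPerSireSD,
        unknownSireFraction = unknownSireFraction,
        unknownDamFraction = unknownDamFraction,
        birthYearStart = as.integer(birthYearStart),
        missingRate = missingRate, errorRate = errorRate,
        seed = as.integer(seed))
}

.simMap <- function(config) {
    n <- config@nSnpsPerChrom
    spacing <- config@chromLengthBp / n
    pos <- as.integer(round((seq_len(n) - 0.5) * spacing))
    do.call(rbind, lapply(seq_len(config@nChroms), function(cc)
        data.frame(snp_id = sprintf("snp_c%d_%05d", cc, seq_len(n)),
                   chromosome = cc, position = pos, alleleA = "A",
                   alleleB = "G", stringsAsFactors = FALSE)))
}

# first-order Markov haplotype chain: allele i copies allele i-1 with
# probability ld, otherwise a fresh Bernoulli(freq[i]) draw; the chain
# restarts at chromosome boundaries. freq = allele-B frequency per SNP.
.hapChain <- function(freq, chrom, nHap, ld) {
    m <- length(freq)
    h <- matrix(0L, m, nHap)
    fresh <- matrix(runif(m * nHap) < rep(freq, nHap), m, nHap)
    copy <- matrix(runif(m * nHap) < ld, m, nHap)
    newChrom <- c(TRUE, chrom[-1] != chrom[-m])
    copy[newChrom, ] <- FALSE
    h[1, ] <- fresh[1, ]
    for (i in seq_len(m)[-1])
        h[i, ] <- ifelse(copy[i, ], h[i - 1L, ], fresh[i, ])
    storage.mode(h) <- "integer"
    h
}

#' Simulate founder haplotype pools
#'
#' Draws per-SNP base allele frequencies uniform on (0.05, 0.95), scatters
#' pool-specific frequencies around them with a Balding-Nichols model
#' (Beta with mean p and variance F p(1-p); F = 0 reproduces the base), and
#' generates \code{2 * nFounders} haplotypes per pool as first-order Markov
#' chains with adjacent-allele copy probability \code{ldDecay}, restarting
#' at chromosome boundaries.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return \code{list(haplotypes =, frequencies =, map =)}: a named list of
#'   SNP x haplotype matrices per pool, the frequency table, and the marker
#'   map.
#' @export
simulateFounderHaplotypes <- function(config) {
    stopifnot(is(config, "SimConfig"))
    set.seed(config@seed)
    map <- .simMap(config)
    m <- nrow(map)
    base <- runif(m, 0.05, 0.95)
    freqs <- data.frame(snp_id = map$snp_id, base = base,
                        stringsAsFactors = FALSE)
    haps <- list()
    for (k in seq_len(nrow(config@pools))) {
        f <- config@pools$divergence[k]
        p <- if (f == 0) base else {
            shape <- (1 - f) / f
            pmin(pmax(rbeta(m, base * shape, (1 - base) * shape),
                      0.005), 0.995)
        }
        freqs[[config@pools$name[k]]] <- p
        haps[[config@pools$name[k]]] <- .hapChain(
            p, map$chromosome, 2L * config@pools$nFounders[k],
            config@ldDecay)
    }
    list(haplotypes = haps, frequencies = freqs, map = map)
}

# offspring-per-sire workloads: normal, rounded, truncated at >= 1
.drawOffspringCounts <- function(n, mean, sd) {
    pmax(1L, as.integer(round(rnorm(n, mean, sd))))
}

#' Simulate a pedigree with crossbred structure and unknown parents
#'
#' Founder males per pool are created genotyped; each offspring generation
#' is partitioned among sires drawn from earlier-generation males with
#' workloads from the configured offspring-per-sire distribution. Each
#' offspring gets a fresh (ungenotyped) founder dam whose pool crosses the
#' sire's pool with probability \code{crossbredFraction}; offspring of
#' mixed-pool matings carry the pool label "cross". Configured fractions of
#' offspring have their sire and/or dam recorded as unknown (the columns
#' \code{sire_pool}/\code{dam_pool} retain the pool of origin so gene
#' dropping can draw the missing gamete from the right pool). Birth years
#' follow generations.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A \linkS4class{Pedigree} whose records carry extra columns
#'   \code{sex}, \code{genotyped}, \code{sire_pool}, \code{dam_pool}.
#' @export
simulatePedigree <- function(config) {
    stopifnot(is(config, "SimConfig"))
    set.seed(config@seed + 1L)
    poolNames <- config@pools$name
    rec <- do.call(rbind, lapply(seq_len(nrow(config@pools)), function(k)
        data.frame(
            animal = sprintf("%s_M%03d", poolNames[k],
                             seq_len(config@pools$nFounders[k])),
            sire = NA_character_, dam = NA_character_,
            birth_year = config@birthYearStart, pool = poolNames[k],
            sex = "M", genotyped = TRUE, sire_pool = NA_character_,
            dam_pool = NA_character_, stringsAsFactors = FALSE)))
    damCounter <- 0L
    for (g in seq_along(config@generationSizes)) {
        size <- config@generationSizes[g]
        males <- rec$animal[rec$sex == "M"]
        sires <- sample(males)
        w <- .drawOffspringCounts(length(sires), config@offspringPerSireMean,
                                  config@offspringPerSireSD)
        sireOf <- rep(sires, times = w)
        if (length(sireOf) < size)  # recycle sires if workloads fell short
            sireOf <- c(sireOf, rep(sires, length.out = size - length(sireOf)))
        sireOf <- sireOf[seq_len(size)]
        rows <- vector("list", size)
        for (i in seq_len(size)) {
            s <- sireOf[i]
            sPool <- rec$pool[match(s, rec$animal)]
            sBase <- if (sPool %in% poolNames) sPool else poolNames[1]
            cross <- length(poolNames) > 1 &&
                runif(1) < config@crossbredFraction
            dPool <- if (cross) sample(setdiff(poolNames, sBase), 1) else sBase
            oPool <- if (identical(sBase, dPool) && sPool %in% poolNames)
                sPool else "cross"
            damKnown <- runif(1) >= config@unknownDamFraction
            sireKnown <- runif(1) >= config@unknownSireFraction
            damId <- NA_character_
            if (damKnown) {
                damCounter <- damCounter + 1L
                damId <- sprintf("dam_%05d", damCounter)
                rows[[i]] <- data.frame(
                    animal = damId, sire = NA_character_,
                    dam = NA_character_,
                    birth_year = config@birthYearStart, pool = dPool,
                    sex = "F", genotyped = FALSE,
                    sire_pool = NA_character_, dam_pool = NA_character_,
                    stringsAsFactors = FALSE)
            }
            rows[[i]] <- rbind(rows[[i]], data.frame(
                animal = sprintf("gen%d_%04d", g, i),
                sire = if (sireKnown) s else NA_character_,
                dam = damId,
                birth_year = config@birthYearStart + g, pool = oPool,
                sex = sample(c("M", "F"), 1), genotyped = TRUE,
                sire_pool = sPool, dam_pool = dPool,
                stringsAsFactors = FALSE))
        }
        rec <- rbind(rec, do.call(rbind, rows))
    }
    pedigree(rec)
}

# one recombinant gamete from a parent's haplotype pair (Haldane model,
# crossover count ~ Poisson(length in Morgans), positions uniform)
.recombine <- function(h1, h2, chrom, pos, chromLengthBp) {
    out <- integer(length(h1))
    for (cc in unique(chrom)) {
        idx <- which(chrom == cc)
        lm <- chromLengthBp / 1e8  # 1 cM per Mb
        k <- rpois(1, lm)
        start <- sample(1:2, 1)
        if (k == 0L) {
            out[idx] <- if (start == 1L) h1[idx] else h2[idx]
        } else {
            bp <- sort(runif(k, 0, chromLengthBp))
            seg <- (findInterval(pos[idx], bp) + start) %% 2L
            out[idx] <- ifelse(seg == 1L, h1[idx], h2[idx])
        }
    }
    out
}

#' Gene-drop haplotypes through a pedigree
#'
#' Each animal inherits one recombinant gamete per known parent (crossovers
#' Poisson with 1 cM/Mb, positions uniform, no interference); a gamete from
#' an unknown parent is a fresh founder haplotype drawn from the relevant
#' pool's frequency model. Founders take their haplotypes from the
#' simulated pool reservoirs (extra founders, e.g. dams, get fresh pool
#' haplotypes). Deterministic given the seed.
#'
#' @param ped a \linkS4class{Pedigree} (cycle-free by construction).
#' @param founders output of \code{\link{simulateFounderHaplotypes}}.
#' @param config the \linkS4class{SimConfig}.
#' @param seed RNG seed (defaults to \code{config seed + 2}).
#' @return A phased, complete \linkS4class{GenotypeData} covering every
#'   pedigree animal.
#' @export
geneDrop <- function(ped, founders, config, seed = config@seed + 2L) {
    stopifnot(is(ped, "Pedigree"))
    set.seed(seed)
    map <- founders$map
    m <- nrow(map)
    df <- pedRecords(ped)
    n <- nrow(df)
    poolNames <- config@pools$name
    # topological order: parents before offspring
    ord <- integer(0)
    resolved <- logical(n)
    repeat {
        ready <- !resolved &
            (is.na(df$sire) | df$sire %in% df$animal[resolved]) &
            (is.na(df$dam) | df$dam %in% df$animal[resolved])
        if (!any(ready)) break
        ord <- c(ord, which(ready))
        resolved[ready] <- TRUE
    }
    if (!all(resolved)) stop("pedigree contains a cycle")

    H1 <- matrix(NA_integer_, m, n, dimnames = list(map$snp_id, df$animal))
    H2 <- H1
    reservoirUsed <- setNames(integer(length(poolNames)), poolNames)
    # a gamete from the (finite) ancestral gene pool: recombination of two
    # reservoir haplotypes, so that all animals share ancestry to some
    # degree, as in a real breed of finite effective size
    freshHap <- function(pool) {
        if (!pool %in% poolNames) pool <- poolNames[1]
        res <- founders$haplotypes[[pool]]
        pick <- sample.int(ncol(res), 2L, replace = TRUE)
        .recombine(res[, pick[1]], res[, pick[2]], map$chromosome,
                   map$position, config@chromLengthBp)
    }
    founderPair <- function(pool) {
        if (!pool %in% poolNames)
            return(cbind(freshHap(pool), freshHap(pool)))
        used <- reservoirUsed[pool]
        res <- founders$haplotypes[[pool]]
        if (used + 2L <= ncol(res)) {
            reservoirUsed[pool] <<- used + 2L
            res[, used + (1:2), drop = FALSE]
        } else cbind(freshHap(pool), freshHap(pool))
    }
    for (i in ord) {
        sire <- df$sire[i]; dam <- df$dam[i]
        pool <- df$pool[i]
        if (is.na(pool)) pool <- poolNames[1]
        if (is.na(sire) && is.na(dam) && is.na(df$sire_pool[i] %||% NA)) {
            pr <- founderPair(pool)
            H1[, i] <- pr[, 1]; H2[, i] <- pr[, 2]
            next
        }
        sPool <- df$sire_pool[i] %||% NA
        dPool <- df$dam_pool[i] %||% NA
        if (is.na(sPool)) sPool <- pool
        if (is.na(dPool)) dPool <- pool
        H1[, i] <- if (!is.na(sire)) {
            j <- match(sire, df$animal)
            .recombine(H1[, j], H2[, j], map$chromosome, map$position,
                       config@chromLengthBp)
        } else freshHap(sPool)
        H2[, i] <- if (!is.na(dam)) {
            j <- match(dam, df$animal)
            .recombine(H1[, j], H2[, j], map$chromosome, map$position,
                       config@chromLengthBp)
        } else freshHap(dPool)
    }
    genotypeData(H1 + H2, map, sampleIds = df$animal, hap1 = H1, hap2 = H2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Degrade genotypes with missingness and error
#'
#' Each cell is independently set missing with \code{missingRate}; each
#' remaining called cell is replaced by one of the two other dosages
#' (uniformly) with \code{errorRate}. Phase is dropped. Deterministic given
#' the seed.
#'
#' @param truth a \linkS4class{GenotypeData}.
#' @param missingRate,errorRate per-cell rates in [0,1].
#' @param seed RNG seed.
#' @return An unphased \linkS4class{GenotypeData}.
#' @export
degradeGenotypes <- function(truth, missingRate, errorRate, seed) {
    stopifnot(missingRate >= 0, missingRate <= 1,
              errorRate >= 0, errorRate <= 1)
    set.seed(seed)
    d <- dosageMatrix(truth)
    miss <- matrix(runif(length(d)) < missingRate, nrow(d), ncol(d))
    d[miss] <- NA_integer_
    err <- !is.na(d) & matrix(runif(length(d)) < errorRate, nrow(d), ncol(d))
    if (any(err)) {
        shift <- sample(1:2, sum(err), replace = TRUE)
        d[err] <- (d[err] + shift) %% 3L
    }
    genotypeData(d, snpMap(truth), sampleIds = colnames(d))
}

#' Run the full simulator
#'
#' Founder haplotypes, pedigree, gene dropping and degradation in one call;
#' the genotype datasets cover the genotyped animals (founder males and all
#' offspring; dams are pedigree-only).
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A \linkS4class{SimOutput}.
#' @examples
#' sim <- simulatePopulation(simConfig(seed = 1, nSnpsPerChrom = 50,
#'     nChroms = 1, generationSizes = c(20L, 10L),
#'     pools = data.frame(name = c("a", "b"), nFounders = c(10L, 5L),
#'                        divergence = c(0.05, 0.15))))
#' sim
#' @export
simulatePopulation <- function(config) {
    founders <- simulateFounderHaplotypes(config)
    ped <- simulatePedigree(config)
    truthAll <- geneDrop(ped, founders, config)
    df <- pedRecords(ped)
    flag <- df$genotyped %||% rep(TRUE, nrow(df))
    flag[is.na(flag)] <- TRUE
    genotyped <- df$animal[flag]
    truth <- truthAll[, colnames(truthAll) %in% genotyped]
    observed <- degradeGenotypes(truth, config@missingRate,
                                 config@errorRate, config@seed + 3L)
    new("SimOutput", truth = truth, observed = observed, pedigree = ped,
        frequencies = founders$frequencies, config = config)
}

#' Accessors for SimOutput
#'
#' @param x a \linkS4class{SimOutput}.
#' @return \code{simTruth}/\code{simObserved}: \linkS4class{GenotypeData};
#'   \code{simPedigree}: \linkS4class{Pedigree}.
#' @export
simTruth <- function(x) x@truth
#' @rdname simTruth
#' @export
simObserved <- function(x) x@observed
#' @rdname simTruth
#' @export
simPedigree <- function(x) x@pedigree
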