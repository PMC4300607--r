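---
title: "Panel design and imputation benchmarking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Panel design and imputation benchmarking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PanelImpute)
```

PanelImpute is a workbench for a single experimental design used throughout
livestock genomics: hide the genotypes a low-density chip would not
measure, impute them back from a high-density reference population, and
score the result against the hidden truth. This vignette documents the
models behind each stage, the tunable parameters and their defaults, and
the design decisions taken where the methodology left genuine choices.

## Data model

Genotypes are biallelic autosomal SNP dosages 0/1/2 (copies of allele B)
with an explicit missing sentinel (`NA`) — never a silent zero. All
statistics define their denominator over called genotypes only. Allele B
is assigned per SNP at load time as the minor allele by observed
frequency, with exact ties resolved lexicographically (the smaller
character becomes allele A); every downstream quantity that matters (MAF,
r², CR, allelic R²) is invariant under reflecting this coding. The bovine
autosome range 1–29 is assumed; other chromosome codes survive parsing and
are removed by QC, so a file with X/Y markers loads and is cleaned rather
than rejected.

`GenotypeData` extends `SummarizedExperiment` (SNPs in rows, animals in
columns) with assays `dosage`, optionally `quality` (per-call scores in
[0, 1], as produced by array genotype callers) and `hap1`/`hap2` (phased
allele-B indicators constrained to sum to the dosage wherever it is
called).

## Quality control

SNP filters run in a fixed order — autosome, reference-panel
intersection, mean call quality (default ≥ 0.15), call rate (≥ 0.90),
Hardy–Weinberg equilibrium (p ≥ 1e-6) — so that each removed SNP is
attributed to exactly one filter and reports are reproducible. The HWE
test is the 1-df chi-square goodness-of-fit against p², 2pq, q² with the
allele frequency estimated from the sample, without continuity
correction: a deterministic, O(1) choice whose tail behaviour is all the
filter uses; monomorphic SNPs get p = 1. An exact test would differ
materially only at very small counts, which the call-rate filter has
already cleaned.

Sample filters run afterwards (quality, call rate, heterozygosity outside
mean ± 3 SD). Duplicate pairs — genotype concordance ≥ 0.99, a threshold
chosen to sit far above what two distinct relatives can reach and below
repeated-sampling concordance on arrays — lose their lower-call-rate
member. A recorded parent–offspring pair whose opposing-homozygote rate
exceeds 0.01 is treated as a pedigree error: the link is severed (parent
set unknown) rather than the animal removed, because the genotypes remain
perfectly usable for population imputation; only the family information
was wrong. Running SNP QC before sample QC is a documented choice (both
orders are available by calling the two functions in either order): SNP
artefacts corrupt per-sample statistics more than the reverse.

## Panel design

The designer expands an anchor panel (for instance an 8K chip) toward a
target size. MAF > 0.23 and r² < 0.088 against the nearest
already-selected flanking SNP on each side are *hard* constraints; even
spacing is the *objective*. Additions are allocated to inter-anchor
intervals proportionally to physical length (largest-remainder rounding),
and within an interval each ideal position `left + i·(right−left)/(k+1)`
takes the nearest eligible candidate, ties resolved by higher MAF then
lower SNP id. Which pairs the LD threshold applies to is genuinely
ambiguous in the field's practice; nearest-selected-neighbour LD is used
here because it is the pair that spacing-driven designs actually control,
and it makes the constraint verifiable post hoc from the final panel.
Infeasible intervals leave the panel short with a per-interval report —
a short panel is a result, not an error.

## The simulator

The generator produces the study conditions every benchmark in the
package runs under; it is first-class, tested code.

* **Founder pools.** Per-SNP base frequencies are uniform on
  (0.05, 0.95). Each pool (default: a taurine analogue, F = 0.05, and an
  indicine analogue, F = 0.15) scatters its own frequencies around the
  base with a Balding–Nichols Beta model (mean p, variance F·p(1−p)) —
  enough to emulate taurine/indicine divergence without modelling real
  cattle history.
* **LD.** Founder haplotypes are first-order Markov chains: allele *i*
  copies allele *i−1* with probability `ldDecay` (default 0.9), else
  draws fresh from the pool frequency; chains restart at chromosome
  boundaries. This gives tunable, seedable LD that decays geometrically
  with marker distance (correlation length ≈ 10 SNPs at 0.9) — adequate
  for exercising window matching, orders of magnitude faster than a
  coalescent, and deliberately not a model of real block structure.
* **Pedigree.** Default: 90 genotyped founder males (60 + 30 per pool)
  and two offspring generations of 210 and 60. Offspring are partitioned
  among sires with workloads drawn from Normal(15.28, 17.38) rounded and
  truncated at 1 — the half-sib family-size distribution typical of
  extensively managed beef herds. Each offspring receives a fresh
  ungenotyped dam; matings cross pools with probability 0.7, and
  offspring of mixed matings carry the pool label "cross". Per offspring,
  the sire record is masked unknown with probability 0.5 and the dam
  with 0.4, giving ~70% of offspring with at least one unknown parent.
  Birth years follow generations, so the youngest generation (60
  animals) forms the imputation population and everything older the
  reference (300) — the sizes all benchmarks in the package quote.
* **Gene dropping.** One recombinant gamete per known parent with
  crossover counts Poisson in map length (1 cM/Mb fixed, Haldane/no
  interference) and uniform positions. A gamete whose parent is unknown
  is drawn from the animal's pool of origin as a recombination of two
  reservoir haplotypes. The founder reservoir is *finite* by design:
  every founder gamete, including those of dams and unknown parents,
  traces back to the 2·nFounders pool haplotypes, so all animals share
  ancestry to some degree — the premise deterministic imputers rely on.
  An early draft drew unknown-parent gametes as fresh frequency-model
  chains; that silently gives the population an infinite effective size,
  no identity-by-descent, and an unrealistically hard imputation problem.
* **Degradation.** Cells go missing independently (default 0.5%), then
  surviving cells flip to one of the other two dosages uniformly (default
  0.1%) — symmetric dosage errors, no intensity model.

Everything derives from the config seed; changing only the seed changes
the output.

What passing benchmarks on this generator does **not** show: performance
under real haplotype-block LD, chip-specific error profiles, selection or
drift across generations, or X-chromosome behaviour. The generator's LD
range is short, so absolute accuracies at very sparse densities are
pessimistic relative to real cattle data at nominally similar panel
fractions; orderings and directions (denser beats sparser, two-step beats
one-step with a large mid reference) are the transferable results.

## Imputation engines

The engines are deterministic reference implementations of the
family-then-population approach, not replicas of any production tool.

**Family step.** Only uniquely forced genotypes are filled: both parents
homozygous force the child; obligate transmissions of *both* alleles
across an animal's genotyped offspring (offspring homozygous, or
heterozygous with the mate homozygous for the other allele) force a
heterozygote. Anything less than forced stays missing for the population
step. Ungenotyped-parent inference uses the same obligate-allele tally
with two extra rules: at least 4 genotyped offspring (below that the call
is refused, as a typed result rather than an error), and a homozygote call
requires the same allele in ≥ 2 independent transmissions with the other
allele never seen — a single genotyping error in one offspring then
cannot flip a call. SNPs with Mendelian-impossible offspring/mate pairs
stay missing and are counted.

**Phasing.** The population engine needs explicit gametes. Homozygous
cells phase trivially. With a library, a sample is first checked for an
exact diplotype (a library pair summing to its called dosage across the
chromosome — a sample duplicating a reference animal is thereby phased
identically to it); otherwise heterozygous sites are phased left to right
by a weighted majority vote of the library haplotypes that best match the
surrounding anchors (4 known sites each side), ties deterministically
assigning allele B to gamete 1. Reference panels simulated with truth
phase keep it; scenario runs therefore build the library from truth
haplotypes, which stands in for the internal phasing a production imputer
would do and isolates the benchmark signal to the matching engine itself.

**Population step.** Per target gamete and chromosome, windows from the
schedule (default 512/128/32/8 SNPs, each level overlapping by half)
collect candidate haplotypes matching all called gamete alleles in the
window (`minMatchFraction = 1`; relaxed matching is exposed but off by
default to keep the engine exactly reproducible). Masked cells on which
all candidates agree are filled; cells with disagreeing candidates defer
to smaller windows, and a window with *no* matching haplotype is simply
skipped — shortening the window is what recruits more distant relatives.
Cells still open after the smallest window are filled from the
most-constrained (largest non-empty) candidate set recorded for them:
if some candidate agrees with the gamete at every called site
chromosome-wide it is copied (a long exact match is a close relative —
this preserves perfect recovery of targets whose haplotypes are in the
library); otherwise the candidates vote per cell, which approximates the
conditional allele frequency given the anchors. Exact vote ties break by
candidate order, gamete 1 taking the first tied candidate and gamete 2
the second, so a single-pair library reproduces that pair's dosage.
Cells whose every anchored window had no match are left missing under
`allowIncomplete = TRUE` (the default — an imputed-call rate slightly
below 1 is information, not failure) or filled with the library modal
allele otherwise.

**Orchestration.** One-step: family (when a pedigree is supplied) then
population; observed genotypes pass through bit-exactly, and the fill
status of every cell is recorded. Two-step: impute to a mid panel against
the mid reference, then the result to the full panel against the high
reference, with panel nesting enforced and fill status distinguishing the
steps. Errors made in step 1 are deliberately treated as observations in
step 2, exactly as a two-stage pipeline on real data would.

## Evaluation conventions

Masking hides, for every imputation animal, the genotypes at SNPs off the
low panel; truth-missing cells are never masked. CR's denominator is the
masked cells *the imputer called*, with the imputed-call rate reported
alongside — conflating "wrong" with "not called" would reward reckless
filling. Allelic R² is computed per animal for headline means, per SNP
for diagnostics, and pooled overall; it is undefined (flagged `NA`, never
silently NaN) on constant vectors, and undefined units are excluded from
means with their counts visible in the report. MAF classes are
`[0, 0.01)`, `[0.01, 0.05]`, `(0.05, 0.5]` — the middle class owns both
boundaries — with MAF computed on the reference population (the animals
an analyst would actually have at their disposal; the full-data
alternative is available via the `samples` argument). CR bins are
right-open except the top bin. The scenario runner emits a tidy
per-animal table with arcsine-square-root transformed metrics as the
hand-off to external ANOVA; hypothesis testing itself is out of scope.

## Numerical and degenerate-input choices

Ideal panel positions round half-to-even (R's `round`). Metric
denominators of zero yield `NA`, never exceptions, except where an empty
result signals a configuration error (empty imputation population,
nothing to mask, empty library). Window schedules are clamped to the
chromosome length. All engines are deterministic: identical inputs and
options give bit-identical outputs, and every stochastic stage consumes
an explicit seed.

## Problem sizes

The package's standard benchmark uses 2 chromosomes × 1,000 SNPs and 360
genotyped animals (300 reference / 60 imputation), with panels retaining
5% / 15% / 50% of the SNPs; unit tests use smaller populations of the
same shape. These sizes were chosen so the full pipeline exercises every
code path at desk scale while a complete benchmark run stays in the
low minutes on a single core.

## Known limitations

* The population engine's accuracy depends on the phasing heuristic for
  real (truth-phase-free) references; a production deployment would phase
  references with a dedicated tool first.
* The simulator's Markov LD has no block structure and a single
  recombination map; per-chromosome accuracy differences are therefore
  much flatter than on real genomes.
* Minimal VCF support is read-only and biallelic; PED/MAP is the
  canonical interchange format. Binary PLINK, bgzip/tabix, sex
  chromosomes and multiallelic variants are out of scope.
* Ungenotyped-parent inference uses offspring (and mates) only; grandsire
  or mate-pedigree paths are not exploited.
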