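---
title: "Models and methods behind enuscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind enuscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(enuscreen)
```

`enuscreen` implements, as desk-scale computation, the analysis pipeline of
a three-generation ENU (N-ethyl-N-nitrosourea) mutagenesis screen in a large
animal: simulation of mutagenized pedigrees, trio-based de novo mutation
detection and rate estimation, mutation-spectrum summaries, parametric
linkage mapping, a causative-variant filtering cascade, and screen-design
calculators. This vignette describes the models, their assumptions, the
tunable parameters, and the numerical choices, in that order. Every
empirical statement here is computed by the package's test suite or by
`scripts/acceptance.R`; nothing is asserted from memory of any particular
dataset.

## The synthetic-data generator

The generator (`sim_config()`, `breed_screen()`) emulates the *study
conditions* of a pig mutagenesis screen, not pig biology in general.

**Mutagenesis.** A mutagenized G0 boar's gametes carry independent sets of
point mutations; the number per gamete is Binomial(genome size, per-site
rate) with positions uniform. The two calibrated per-site rates are
`1.63e-6` (65 mg/kg dose) and `5.86e-6` (85 mg/kg), selectable by dose label
in `sim_config()`. Each G1 offspring derives from a *fresh* gamete draw, so
no two G1 siblings share an induced mutation — an idealization of the
vanishingly small real sharing probability, and the assumption behind the
caller's cross-trio exclusion rule.

**Spectrum.** Substitution classes are drawn from a six-class
strand-collapsed spectrum whose transition mass is 0.712. Only that
aggregate is a measured calibration; the default within-group split
(G:C>A:T 0.45, A:T>G:C 0.262, the four transversions 0.072 each) is a
package default chosen to make G>A the dominant class, and is configurable.
Where genome sequence is known (inside annotated CDS, or when chromosome
sequence is attached) the class is drawn conditional on the reference base;
elsewhere the class is drawn from the full spectrum and a compatible
reference base recorded, so the marginal class distribution equals the
configured spectrum exactly — this is what makes the 71.2% calibration
recoverable from simulated draws.

**Meiosis.** Recombination uses Haldane's map function,
$\theta = \tfrac12(1 - e^{-2d})$ with $d$ in Morgans from a uniform
1 cM/Mb default, no interference, independent chromosomes. Only tracked
loci (induced mutations, background polymorphisms, array markers) are
transmitted; everything between them is irrelevant to the analyses.

**Breeding scheme.** One G0 boar x wild-type sow gives `n_g1` G1 boars; the
first G1 boar is mated to `dams_per_g1` wild-type sows (default 4, litter
size default 8); `g2_dams_backcrossed` G2 daughters (default 4) are
backcrossed to their G1 sire, exposing recessives in G3 at a 1/4 ratio from
carrier dams. Offspring sex is Bernoulli(1/2); if too few G2 daughters
arise, additional litters are drawn up to `litter_cap` before a
breeding-structure error. Sex chromosomes are not modeled; all simulated
chromosomes are autosomal.

**Phenotype.** A single causative locus (by default a missense variant
planted in the first G1 boar's mutation set) with mode dominant or
recessive and penetrance in [0, 1]: carriers (dominant) or
alternate-homozygotes (recessive) are affected with probability
`penetrance`, everyone else is unaffected.

**Sequencing and genotyping layers.** Reduced-representation (2b-RAD-like)
data are idealized as an independent Bernoulli site sample shared across
individuals (tag geometry does not matter for callable-site counting),
with per-site depth Poisson(`mean_depth`) and alternate reads
Binomial(depth, p), p = error, 1/2, 1 - error for genotypes 0/1/2. The SNP
array places markers at uniform spacing with founder allele frequencies
uniform on [0.05, 0.5] and independent missingness. WGS-style call sets are
error-free genotypes at the tracked sequence variants; the simulated
known-polymorphism list contains exactly the background polymorphisms.
Features of real data deliberately *not* emulated: alignment and mapping
artifacts, depth correlation along the genome, index hopping, linkage
disequilibrium among background polymorphisms, litter-size biology. Passing
tests therefore demonstrate correctness of the analysis logic under the
stated generative model, not robustness to real sequencing pathologies.

**Background polymorphisms** segregate in wild-type founders at `poly_rate`
per site (default 1e-4) with allele frequencies uniform on [0.05, 0.5] — a
deliberately thin stand-in for real SNP density, sufficient to exercise the
Mendelian-inheritance null of the caller and the known-SNP filter without
dominating runtime.

## The trio de novo model

`genotype_likelihoods()` gives L(g) = Binomial(alt; depth, p_g) with
p = (epsilon, 1/2, 1 - epsilon). `trio_posteriors()` enumerates all 27 trio
genotype configurations with Hardy-Weinberg parental priors at a single
background allele frequency and Mendelian transmission in which each gamete
mutates with probability mu. `pp_dnm` is the posterior mass of
configurations whose child genotype is unreachable without a mutation;
`pp_null` the mass of mutation-free configurations with a carrier child.
The published decision rule is applied verbatim: pp_dnm > 0.9,
pp_null < 0.001 (strict inequalities), depth at least 10 in *every* trio
member (the stringent reading of "either member", switchable via
`depth_rule = "any"`), and cross-trio exclusion of calls shared between
trios.

**Priors.** `trio_priors()` defaults to mu = 1e-6, pop_alt_freq = 1e-3,
epsilon = 0.01 — sensible for an unselected germline. For calling in a
*mutagenized* pedigree those priors are mis-specified by design:
`sim_trio_priors()` sets mu to the configured dose rate and pop_alt_freq to
match the simulated founder heterozygosity. This is ordinary empirical-Bayes
prior specification from known generative values, and it matters: with the
generic priors the pp_null criterion rejects clean de novo sites whenever a
parent's depth fluctuates low, because a ~20-read reference-homozygous
parent still leaves ~1e-6 of heterozygote likelihood against a 2e-3
heterozygosity prior.

**Rate estimation.** `estimate_frequency()` pools passing calls over a G0
family's trios and divides by pooled callable sites, with an exact Poisson
95% interval on the count. Even with matched priors the stringent
thresholds discard a depth-dependent 10-20% of true events (parental
sequencing-error reads inflate pp_null; children with few alternate reads
fail pp_dnm), so `caller_sensitivity()` estimates the detection probability
by spike-in simulation — sampling callable depth triples from the data,
drawing reads under the true-de-novo model, and applying the same
thresholds — and `estimate_frequency(..., sensitivity = alpha)` divides
rate and interval by it. Sensitivity-corrected rates are the standard
practice in de novo rate estimation; the uncorrected estimator remains the
default (`sensitivity = 1`).

## Consequence annotation

Coordinates are 1-based inclusive throughout (matching c.-notation, VCF and
GFF3); BED export is the only 0-based half-open surface, via one tested
conversion pair. Classes are intergenic, intronic, utr5, utr3, synonymous,
missense, nonsense; stop-gain is nonsense, stop-loss folds into missense;
splice sites are not a class of their own — intronic positions within 2 bp
of a CDS edge carry a `near_splice` flag. Precedence when annotations
overlap: CDS > UTR > intron > intergenic, alphabetically first gene
reported, all hits retained. Amino acids come from the standard genetic
code; minus-strand genes are handled by complementing the variant alleles
into transcription orientation, and the test suite checks that re-encoding
a gene on the opposite strand leaves every amino-acid call unchanged.

## Parametric linkage

`two_point_lod()` computes the exact joint likelihood of marker genotypes
and affection status under a two-locus model: 4 haplotypes (marker allele x
disease allele), 16 ordered diplotypes per individual,
linkage-equilibrium founder priors from the marker allele frequency and the
disease allele frequency q (default 1e-4), transmission with recombination
theta, penetrance vectors (0,1,1) dominant / (0,0,1) recessive by default —
the disease-model settings are configurable because real studies rarely
print them. The likelihood is evaluated by recursive conditioning on
parental genotypes, sire first, which handles the screen's sire-daughter
backcross loop exactly; a structural planning pass assigns every nuclear
family to the context that evaluates it and rejects unsupported loop
structures explicitly. The evaluator deduplicates individuals into
(genotype, affection) classes and groups leaf children, so scans over
hundreds of markers stay fast; agreement with brute-force enumeration over
all diplotype configurations is property-tested on random pedigrees of up
to seven individuals (an eight-individual enumeration, at 10^8
configurations, is beyond a reasonable oracle budget; the closed-form
checks cover larger meiosis counts).

Numerical choices: LOD(theta) = log10 L(theta) - log10 L(0.5) on a grid
(default 0 to 0.5 in steps of 0.01; the genome-scan examples in the tests
use coarser grids of 0.05-0.1 since two-point peak detection does not need
fine theta resolution); data incompatible with theta = 0 evaluate to a -99
sentinel rather than -Inf; missing genotypes are summed over; unknown
affection contributes no penetrance factor. Mapping pedigrees start at the
mutant founder (`subset_pedigree()`): a no-mutation linkage model cannot
explain an affected animal born to unaffected parents under full
penetrance, so the G0 generation is dropped exactly as real mapping studies
root their pedigrees at the proband's founding carrier.

`extract_regions()` reports maximal marker runs with LOD at or above the
threshold (default 3), tolerating up to 2 below-threshold markers inside a
run, with bounds at the outermost flanking below-threshold markers — a
conservative support-interval convention chosen because the field reports
regions as Mb intervals without printing their rule. `qc_markers()` applies
the published thresholds: call rate at least 0.90 and MAF at least 0.05.
`allelic_association()` is the textbook 1-df Pearson chi-squared on the
2x2 allele-count table.

## The candidate cascade

`filter_cascade()` applies five criteria in the published order —
inheritance pattern among sequenced affected/control animals, location
within a linkage region, absence from the known-polymorphism list
(matched on chromosome + position + alternate allele, tolerant of
reference-encoding dialects), protein-disrupting consequence (missense or
nonsense only; UTR and near-splice survivors go to an advisory list), and
complete co-segregation across the genotyped pedigree. The stages are pure
intersections, so the final set is provably order-independent (tested);
the order matters only for the per-stage audit counts. Dominant inheritance
requires heterozygosity in affecteds (not mere carriage), matching an
F1-mutagenesis model.

## Screen-design calculators

`burden_extrapolation()` scales a per-site rate r to
floor(r x genome size) genome-wide, floor(r x n_genes x mean CDS) coding,
and floor(coding x 0.55) amino-acid-changing mutations per G1, the fold
over the spontaneous rate r / 1.2e-8, and round-to-ten
n_genes / functional animals per gene hit. Flooring and the nearest-ten
rule are documented constants chosen to reproduce the published arithmetic
chain (4,580 / 16,466 / 57 / 31 / 710) from the published constants
(2.81e9 bp, 2.2e4 genes, 1.6e3 bp mean CDS, 55% amino-acid-changing,
1.2e-8 spontaneous). The fold ratio is reported unrounded.

`recessive_power()` is the closed form
$1 - [\tfrac12 + \tfrac12(1 - \text{penetrance}/4)^{k}]^{d}$ for d
backcrossed dams with k offspring each, cross-checked against a
Monte-Carlo oracle. `segregation_chi2()` is the 1-df Pearson test of an
affected count against an expected Mendelian ratio. `reference_range()`
builds per-stratum physiological ranges — outliers removed iteratively
beyond 3 SD until stable (an `iqr` strategy is available; the elimination
rule is unspecified in the field source, so it sits behind a switch), 95%
range as the 2.5th-97.5th percentiles of retained values, deviant cutoff at
mean +/- 2 SD with strict exceedance and repeat confirmation
(`flag_deviants()`, default 3 total deviating measurements).

## Problem sizes and determinism

The package's own test and acceptance workloads run on toy genomes of
2x10^7 to 10^8 bp with 5 trios, 40-90 informative meioses and 500 markers —
sizes chosen so that every statistical property (rate recovery at both dose
rates, 19/20 locus recovery, caller specificity) is testable in minutes on
one CPU while keeping every per-event quantity (depth, thresholds,
penetrance, rates) at the study's own values. All randomness flows from a
single integer seed through deterministic per-stage seed derivation
(`stage_seed`), so every pipeline, test and acceptance run is exactly
reproducible.

## Known limitations

Two-point linkage only (no multipoint walk over marker chains, no
haplotype reconstruction or IBD estimation); SNVs only (no indels,
structural variants or multi-allelic sites); one transcript per gene; no
X-linked inheritance; the trio caller assumes biallelic sites with a single
shared background allele frequency; the simulator's independence
assumptions (sites, polymorphisms, tags) understate the correlation
structure of real data.
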