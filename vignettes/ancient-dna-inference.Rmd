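---
title: "Population-genetic inference from low-coverage ancient genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genetic inference from low-coverage ancient genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adnapipe)
```

## Overview

`adnapipe` implements the inference stack commonly used to analyse
low-coverage ancient genomes against reference panels of genotyped
populations: pseudo-haploid genotype calling from read pileups,
relatedness screening by pairwise mismatch rates, f-statistics with block
jackknife standard errors, qpWave/qpAdm admixture modeling, least-squares
admixture-graph fitting, admixture dating from ancestry-covariance decay,
a sliding-window outgroup-f3 selection scan, and Y-haplogroup assignment.
A seeded synthetic-data generator produces every input the pipeline
consumes with known ground truth, which is how the package tests itself.

This vignette explains the models behind each stage, the tunable
parameters and their defaults, the numerical choices, and what the
simulation-based tests do and do not establish about real data.

## The synthetic-data generator

The generator is organised around an `AdmixtureGraph`: a rooted DAG whose
edges carry drift lengths `c >= 0` and whose admixture nodes mix two
parents with weight `alpha`.

* **Allele frequencies.** Root frequencies are i.i.d. Beta(a, b) draws;
  each edge applies Balding–Nichols drift (child frequency is Beta with
  mean `p` and variance `c p (1-p)`). When `c >= 1` the requested
  variance exceeds what a Beta can express and the draw degenerates to
  fixation; these truncations, and draws landing exactly on 0/1, are
  counted and reported in the `clipped` slot. The default root shape
  Beta(0.46, 0.46) gives an expected heterozygosity of about 0.24, so
  that simulated duplicate and unrelated pseudo-haploid pairs sit at the
  mismatch scales (~0.12 and ~0.24) familiar from ancient-DNA cohorts.
* **Genotypes.** Unrelated individuals are Hardy–Weinberg Binomial(2, p)
  draws; pedigree links overwrite columns (duplicates copy, a parent
  transmits one allele, full siblings share two simulated parents, a
  second-degree pair is grandparent–grandchild through one simulated
  intermediate).
* **Pileups.** Per site and library the depth is Poisson; each read
  carries one of the individual's alleles, a base and mapping quality, a
  strand and a position within the read. Deamination is modelled on the
  terminal 5 bases: with probability `damageRate` a C carried by a
  plus-strand read is emitted as T and a G on a minus-strand read as A —
  the reference-orientation image of C→T damage on the read's native
  strand. This is a deliberately simple end-damage model: real damage
  decays smoothly into the read rather than stopping at 5 bp.
* **Admixed chromosomes.** Each haplotype is a Markov path along the
  genetic map: switch events arrive at rate `g` per Morgan and each
  switch re-draws the ancestry as source 1 with probability `alpha`, so
  source-1 tracts are exponential with mean `1/((1-alpha) g)` Morgans.
  Consecutive same-state segments are merged before tract lengths are
  reported.
* **Genetic map.** Simulated panels use a uniform 1 cM/Mb map; no
  map heterogeneity is modelled.
* **Seeding.** A single integer seed is expanded into per-stage,
  per-group, per-individual streams by a string-keyed hash (`subSeed`),
  so outputs are bit-identical under a fixed seed and independent of
  evaluation order.

What the generator does *not* emulate: linkage within source populations
(sites are exchangeable given the graph), sequencing error beyond
deamination, reference bias, contamination, and real recombination-map
structure. Tests that pass on generator data therefore validate the
estimators' algebra and calibration, not their robustness to those
artefacts.

## Pseudo-haploid calling

At every panel site one eligible read is drawn uniformly and its base
reported as a haploid call. Eligibility: base quality ≥ 30, mapping
quality ≥ 30 (both configurable), the base more than `endTrim = 5`
positions from either read end, and the base matching one of the site's
two alleles (mismatching bases are ineligible, not errors). In
`single_strand` mode, C/T sites accept only minus-strand reads and G/A
sites only plus-strand reads, which removes the deamination-driven
spurious derived calls of single-stranded libraries at those sites.

The random draw is keyed by `(seed, chromosome, position, column)` after
placing eligible reads in a canonical order, so calls are invariant to
pileup row order and stable under subsetting. Reads of one individual
are pooled before the draw by default; `byLibrary = TRUE` keeps
libraries separate (used for duplicate detection).

One interaction deserves note: the generator confines damage to the
terminal 5 bases and the caller's default `endTrim = 5` removes exactly
those bases, so under defaults the call sets are damage-free in either
strand mode. The strand-rule tests therefore run with `endTrim = 0`,
which isolates the strand filter itself; on real data damage extends
beyond any fixed trim and both defences are complementary.

## Relatedness from pairwise mismatch rates

For pseudo-haploid calls of two individuals with kinship `phi`, the
expected mismatch rate is `(1 - phi) B`, where the baseline `B` is the
unrelated-pair expectation (approximately the population
heterozygosity). Duplicates sit near `B/2`, first-degree pairs near
`0.75 B`, second-degree near `0.875 B`. The baseline estimator sorts the
observed PMR values, splits clusters at gaps larger than 0.03 (half the
smallest class separation at `B ~ 0.24`) and takes the median of the
largest cluster, assuming most pairs are unrelated. Classification
assigns the nearest expected value — thresholds at the midpoints
`0.625 B`, `0.8125 B`, `0.9375 B` — and flags pairs within 2 SE of two
expected values as ambiguous. The midpoint rule is this package's
decision; published cohorts typically decide borderline cases with
likelihood-based IBD tools, for which `writeEigenstrat()` provides the
export hook. First-degree subtypes are deliberately not distinguished.
The default `minOverlap = 3000` keeps the binomial SE of a PMR below
about 0.008, small against the 0.03–0.06 class gaps.

## f-statistics and the block jackknife

With sample frequencies `a = x/n`, the per-SNP statistics are
`(a-b)^2` (f2), `(c-a)(c-b)` (f3 with target C) and `(a-b)(c-d)` (f4),
with the usual small-sample corrections `a(1-a)/(n-1)` subtracted for f2
and f3 where ploidy permits; the f3 correction is refused (with a
message) for pseudo-haploid targets, where the binomial within-individual
model behind it does not hold. A SNP contributes when every argument
population has `n >= 1` (`n >= 2` under a correction). The aggregate is
the unweighted mean over contributing SNPs — simplest and consistent with
the jackknife bookkeeping; a weighted variant is available through the
batch interface design rather than a hidden global switch.

Standard errors use the weighted block jackknife over contiguous 5 cM
genetic-map blocks (SNPs missing a genetic position are interpolated at
1 cM/Mb). The weighted formulas reduce to the plain delete-1 jackknife
at equal block sizes, which the tests verify against a brute-force
recomputation.

## qpWave and qpAdm

For left populations `l0..lk` and rights `r0..rm`, the matrix
`X[i, j] = f4(l0, l_i; r0, r_j)` has rank equal to the number of
independent ancestry streams minus one. The rank-`r` statistic minimizes
the Mahalanobis norm of `X - Xhat` over rank-`r` matrices `Xhat`
(alternating generalized least squares, 10 seeded restarts) with the
jackknife covariance `Q` of `vec(X)` as metric, on
`df = (k - r)(m - r)` degrees of freedom. Because `Q` is estimated from
a finite number of blocks (~100 at genome scale), the statistic is
referred to a Hotelling-style F distribution with `nBlocks - 1`
covariance degrees of freedom rather than the asymptotic chi-square; the
two coincide as blocks grow, and the null-calibration test (rank-0
p-values uniform over cladal simulations) is the ground truth for this
convention. Ridge regularization of `Q` starts at `1e-6` times the mean
diagonal and escalates tenfold to at most `1e-3` before erroring with
the condition number.

qpAdm estimates mixture weights by constrained generalized least
squares: `w` minimizes `w' X Omega^{-1} X' w` subject to `sum(w) = 1`,
where `Omega` is the covariance of the mixture contrasts implied by `Q`
(iterated from uniform weights). Standard errors rerun the whole solve
on each leave-one-block-out matrix. Weights outside `[0, 1]` are
reported as infeasible rather than clamped — an infeasible best fit is
how impossible models announce themselves. `allsnps = TRUE` (the
default) computes each f4 entry on its own maximal SNP set; `FALSE`
restricts to the global intersection. Exploding standard errors trigger
an explicit diagnostic that the rights do not differentiate the sources.

## Admixture-graph fitting

Expected f2 values between leaves follow from the covariance recursion:
each leaf carries a vector of expected edge traversals (admixture nodes
mix parental vectors by `alpha`, so covariances acquire `alpha^2`
weights), and `E f2(X, Y) = sum_e c_e (u_X(e) - u_Y(e))^2` with drift in
f2 units. For fixed admixture weights this is linear in the drift
lengths, so the fit is an exact non-negative generalized least squares
solve (Lawson–Hanson) nested inside a bounded search over the weights —
much better conditioned than a joint numeric optimization. The fit score
is the number of residual `|z| > 2`; zero-length branches are reported,
not errors, and unidentifiable parameter directions (the f2 basis cannot,
for instance, split drift across the root) are reported as a null-space
dimension. Edges may be pinned (`fixed` column) to express zero-length
admixture legs.

Greedy leaf addition enumerates every single-edge attachment and every
two-way admixture of edge pairs (`E + E(E-1)/2` candidates), refits each
against one shared f2 basis, and ranks by score, then parsimony (fewer
admixture events, then fewer zero-length internal branches), then
residual. The parsimony tie-break is needed because admixture
attachments strictly nest single-edge ones and would otherwise always
win on residual. The search is greedy by construction: the tests include
a fixture in which two insertion orders yield different final
topologies, making the order-dependence explicit rather than hidden.

## Admixture dating

For an admixed target, covariance between ancestry-informative alleles
decays with genetic distance `d` as `exp(-g d)` where `g` is the age of
the pulse in generations. Per SNP the weight is the source-frequency
difference `w = p1 - p2` and the residual is `geno/2 - (p1 + p2)/2`;
pair products `w_k w_l cov_i(r_k, r_l)` (covariance across individuals)
accumulate into distance bins of width `binsizeCM = 0.01` cM by default,
bin `i` covering `[i b, (i+1) b)`. The curve `A exp(-g d) + c` is fitted
by Levenberg–Marquardt least squares with multiple starting rates
(`5, 20, 50, 200`), `A >= 0`, `g > 0`; bins closer than
`minDistCM = 0.05` are excluded, where background LD would contaminate
real data. The standard error of `g` comes from leave-one-chromosome-out
refits with chromosome pair counts as jackknife weights.

The fitting window must cover the decay: the recovery tests use
`maxDistCM = 10` with `binsizeCM = 0.05` so that ages from 10 to 100
generations leave measurable curvature in the window; with the 1 cM
default window a 46-generation decay is nearly linear and the three
parameters trade off. Conversion to calendar dates requires an explicit
generation time and sample age (`generationsToYearsBP`); no generation
time is assumed.

## Selection scan

The scan contrasts a present-day target against an ancient panel
relative to an outgroup with per-SNP
`(c-a)(c-b) - c(1-c)/(nC-1)`, averaged in sliding windows (500 kb size,
10 kb step, anchored at multiples of the step from position 0,
half-open on 1-based coordinates). A SNP qualifies when it is covered in
all three panels, segregating in target or outgroup, and covered in
strictly more than 15 ancient individuals (the alternative literal
reading — more than one read per counted individual — is available via
`perIndividualReads`). Windows with fewer than 250 qualifying SNPs are
emitted without statistics. The window statistic is normalized by the
window's mean target heterozygosity to remove allele-frequency
dependence. Z-scores come from LD-block resampling: one qualifying
window per block per draw, mean and SD over blocks, averaged over 100
draws (a single draw reproduces the one-shot variant); candidate regions
merge overlapping windows above `z > 4` and are annotated with gene
intervals. The simulated null uses exchangeable SNPs, so its calibration
does not by itself demonstrate robustness to real LD structure — that is
what the block resampling is for on real data, where blocks come from a
published LD-block map rather than the uniform fallback.

## Y-haplogroup assignment

Reads covering branch-defining markers (supplied as TSV; public marker
trees are inputs, not bundled) are screened under the same quality gates
as genotype calling and tallied as derived or ancestral per branch. The
call is the deepest branch whose whole root-to-branch path has more
derived than ancestral support among covered markers — a deliberately
simple, auditable majority rule standing in for expert inspection; ties
and uncovered branches stop the path, off-path derived support is
flagged as a conflict, and `transversionsOnly` ignores C/T and G/A
markers wholesale when deamination is a concern.

## Problem sizes in the test-suite

The packaged tests run the full estimators on simulated studies sized to
keep the whole suite comfortably interactive while leaving the
statistical checks well powered: 50,000-SNP panels for mismatch-rate
calibration (20 replicates); 200 cladal and 100 non-cladal qpWave
simulations on 30,000-SNP, 100-block panels; 50 qpAdm replicates at
100,000 SNPs with six rights; 20 greedy-addition replicates at 50,000
SNPs; 50 dating replicates per age on 22 chromosomes; 20 null scans of
42,000 SNPs. These sizes are the package's own choices and can be scaled
up freely.

## Known limitations

* The generator's exchangeable-SNP design cannot test haplotype-scale
  phenomena; an external coalescent simulator is the right independent
  oracle for those.
* Graph fitting uses the linearized drift recursion; very long branches
  (f2 approaching heterozygosity scale) bend away from linearity.
* qpAdm covariances are estimated at the initial uniform weights and
  iterated only a few times; with very weak rights the reported blow-up
  diagnostic, not the point estimate, is the informative output.
* The PMR classifier assumes a single homogeneous cohort baseline;
  structured cohorts need per-population baselines.
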