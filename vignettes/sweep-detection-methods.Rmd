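---
title: "Detecting selection after a two-to-four generation domestication: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selection after a two-to-four generation domestication: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

# The scientific problem

Clonally propagated tree crops such as macadamia sit in an unusual corner of
domestication genetics: commercial cultivars are only two to four sexual
generations removed from wild trees, after which superior genotypes are
frozen by grafting ("one-step operation"). Two questions follow. First, can a
couple of rounds of intense orchard selection already leave detectable
selective sweeps — local troughs of diversity and peaks of wild-cultivar
differentiation? Second, does the genome carry the signature expected of
*mitotic* (somatic) selection under long clonal propagation, namely extensive
terminal runs of homozygosity, or only the signatures of its brief sexual
history?

`sweepscan` implements the full analysis chain for these questions: SNP
filtering, sliding-window diversity and differentiation statistics, a
cross-population composite-likelihood sweep scan, a composite top-percentile
sweep-calling procedure with gene annotation, folded site-frequency spectra,
LD decay, a synonymous-substitution dating calculator, and the terminal-ROH
test — plus a forward simulator of the wild/cultivar history so that every
stage can be validated end to end without any external data.

# The statistics

## Windowing

All windowed statistics use sliding windows of 50 kb advancing in 20-kb
steps (the field's convention for resequencing scans), 0-based half-open,
truncated at the chromosome end; the final partial windows are kept and
their per-bp statistics use the true span, so chromosome tails are not
silently discarded. Windows with fewer than `min_snps` SNPs (default 10) are
flagged undefined and excluded from percentile ranking: a percentile over
near-empty windows would rank noise.

## Diversity and the site frequency spectrum

Per window and population, nucleotide diversity is the sum of unbiased
per-site mean pairwise differences, `2*p*q*n/(n-1)` with `n` the non-missing
allele count, divided by the window span; it is tested against brute-force
pairwise Hamming averaging, which is its definition. Watterson's theta is
`S/a1(n)` per bp with `a1` the harmonic number; Tajima's D uses the standard
1989 constants. With missing data the per-window `n` for the D constants is
the *minimum* non-missing allele count over used sites, and sites with fewer
than 4 alleles are excluded — a conservative choice, made because no single-D
formula exists for per-site varying `n`. `S = 0` yields an undefined flag,
never 0. The folded SFS is computed at a fixed allele number `n`; by default
sites with missing calls are dropped, with expected hypergeometric
projection available as an option (`mode = "project"`).

## Differentiation

FST is the two-population Weir & Cockerham (1984) estimator from per-site
variance components `a` (among populations), `b` (among individuals within
populations) and `c` (within individuals), combined per window as the ratio
of sums `sum(a)/sum(a+b+c)` — the windowed convention of the standard
command-line tools. Negative estimates are reported as computed.

## The cross-population composite likelihood ratio

The sweep scan follows the XP-CLR idea: model the cultivar ("object")
allele frequency given the wild ("reference") frequency under pure drift,
versus drift plus hitchhiking, and score each window by the composite
likelihood ratio maximised over a selection-coefficient grid.

* **Drift**: the object pre-drift frequency `m` is perturbed by a normal
  with variance `omega * m * (1-m)`, truncated to (0,1) with the tail mass
  placed as atoms at 0 and 1. The genome-wide drift coefficient `omega` is
  estimated by method of moments,
  `mean[(p1-p2)^2 / (p1 (1-p1))] - mean[1/m1 + 1/m2]`, the subtraction
  removing expected binomial sampling variance, floored at `1e-4`.
* **Hitchhiking**: a lineage at recombination distance `r = rrate * d`
  Morgans from a site sweeping with coefficient `s` escapes the sweep with
  probability `c = 1 - epsilon^(r/s)` (`epsilon = 5e-5`, about `1/2N` for
  `N = 1e4`). The object frequency is then the two-point mixture: with
  probability `p1` the lineage class at frequency `(1-c) + c*p1`, with
  probability `1-p1` the class at `c*p1`. At `c = 1` the mixture collapses
  exactly to the neutral model — the identity that anchors the unit tests.
* **Scoring**: the focal point is the window midpoint,
  `CLR = 2 * max_s sum_sites [ll_sweep(s) - ll_neutral]`, floored at 0, with
  equal SNP weights. The default grid is
  `s in {0.001, 0.005, 0.01, 0.05, 0.1, 0.5}`.

Simplifications relative to the original program — equal SNP weights (no
correlation down-weighting), focal points at window midpoints only, a fixed
`s` grid — keep the statistic fast and fully testable; scores are therefore
comparable in *rank*, not in absolute value, to the original program's
output, and all calling below is rank-based (top percentiles).

**Numerics.** Each mixture component is integrated by a midpoint rule on a
uniform frequency grid (default 200 points, at least 100 enforced) plus the
boundary atoms; the midpoint rule on near-Gaussian integrands is spectrally
accurate once several grid points span one standard deviation. Components
whose drift sd falls below a fixed `3.5e-3` are evaluated as a binomial
point mass instead — the threshold is deliberately independent of the grid
size, so refining the grid is well defined; a doubling of the grid moves no
reported CLR by more than 0.1%, and the site likelihood agrees with a
1e5-point reference integration to four significant figures. Reference
frequencies carry a 0.5 pseudocount per allele class so reference-fixed
sites keep a finite likelihood. The integral kernel is implemented in C++
(Rcpp), as is conventional for scan statistics at this tier.

## Composite sweep calling

Mirroring the composite procedure used for such scans: a window is called
iff (i) its XP-CLR score is in the genome-wide top 5% (empirical type-7
quantile, inclusive of ties), (ii) its FST is in the top 5%, (iii) Tajima's
D is strictly negative in cultivars and strictly positive in the wild group,
per window. Percentiles are computed genome-wide over defined windows only.
The intermediate sets — XP-CLR top windows, and the XP-CLR-and-FST overlap
before the D narrowing — are kept as diagnostics, since published analyses
report such narrowing stages. Selected windows merge into maximal blocks
when overlapping *or* book-ended (the simplest deterministic rule consistent
with a step smaller than the window size); a gene joins a block iff their
half-open intervals overlap by at least 1 bp, and the report states the
selected-gene percentage rounded to two decimals (284 of 37,723 genes gives
0.75).

## Runs of homozygosity

The ROH scan is restricted to SNPs inside single-copy genes (multi-copy
regions breed artifactual homozygosity through collapsed paralogs). Runs are
maximal stretches of homozygous calls allowing up to `max_het` heterozygous
interruptions (default 0), found by a greedy left-to-right segmentation in
which the budget-breaking heterozygote starts the next run and runs are
trimmed to homozygous end points — so runs never overlap, and for
`max_het = 0` the runs plus their gaps reconstruct the sequence exactly.
Missing genotypes are transparent: skipped, neither breaking nor extending a
run (call-rate artifacts should not fragment runs). Defaults `min_snps = 25`
and no length floor are this package's own, conservative at desk scale; the
field-scale analyses name no standard algorithm. A run is *terminal* when it
contains the first or last retained SNP of its chromosome; a chromosome end
counts as "extensively homozygous" when a terminal run covers at least 25%
of the chromosome's SNP extent. That fraction is likewise an artifact
default — no quantitative criterion for "significant extensive" terminal
homozygosity is established in the field.

## Dating from synonymous substitutions

`divergence_date(ks, r) = Ks/(2r)` dates a divergence or whole-genome
duplication from the synonymous distance between the diverged copies. With a
Ks peak at 0.35 and the lotus-family substitution rate `4.175e-9` per site
per year it returns 41.9 million years; published datings of the same peak
differ by a few percent because the `r` actually used is rarely printed.

# The synthetic-data generator

## History and scale

The simulator emulates the study system: a large, stable wild outcrossing
population, and a cultivar population founded from it by a handful of trees
(`n_founders = 10`) followed by 2-4 sexual generations (`3` by default) of
intense artificial selection, then sampling of both groups
(20 + 20 diploids) for resequencing.

Forward simulation at the real parameters (per-generation mutation rate
`4.175e-9`, `1e-8` Morgans/bp, wild population sizes of many thousands) is
not feasible on a desk, so the tested mode is a standard rescaling: with
`N_wild = 200`, the default mutation rate `1.25e-6` preserves
`theta = 4*N*mu = 1e-3` per bp (several thousand SNPs per 1-Mb chromosome,
enough to exercise 50-kb windows), and the recombination rate `3e-6`
preserves the literal ratio `r/mu ~ 2.4`. The literal rates and the 8-year
generation time are carried in the config as metadata. Five 1-Mb
chromosomes are the default genome.

## Initialization

By default wild haplotypes are drawn from a neutral coalescent-style
generator with matched theta: the segregating-site count is Poisson with
mean `theta * L * a1(n)` and derived-allele counts follow the neutral
`1/i` law, with carriers assigned at random per site (linkage equilibrium).
This is exact for every per-site expectation the pipeline consumes (S,
pi, the SFS, Tajima's D) and is orders of magnitude faster than burn-in;
its one simplification is the absence of *background* LD among wild
haplotypes — all LD in the simulated data arises from the founding
bottleneck and breeding drift, which is precisely the signal the LD-decay
comparison measures. An explicit Wright-Fisher burn-in
(`init = "forward"`, `8*N` generations) is available and agrees with the
Watterson expectation; the truth record states which initializer ran.

## Mating and selection

Each breeding generation produces `fecundity * n_cult` juveniles by random
mating — mother and father always distinct, since these trees are
outcrossing and largely self-incompatible; allowing selfing would create
whole-chromosome autozygous tracts that the real mating system forbids.
Selection is *truncation on a phenotype*: each sweep locus contributes a
genotypic value of `0`, `s/2` or `s` (additive within locus, summed across
loci), an environmental deviate with sd `env_sd = 0.25` is added, and the
top `n_cult = 20` juveniles by phenotype become the next generation's
parents. This is the breeder's-equation model of artificial selection and
was chosen deliberately over per-generation viability weights
`(1, 1+s/2, 1+s)`: simple algebra shows viability selection cannot move an
allele from one founder copy (frequency `1/(2*n_founders)`) to high
frequency within 2-4 generations even at `s = 1`, whereas truncation
selection — selection among large open-pollinated seedling populations is
exactly how these cultivars were made — fixes strongly selected alleles in
two to three rounds while reducing exactly to the neutral Wright-Fisher
bottleneck at `s = 0`. Under this model the response is smoothly monotone
in `s`: `s = 0.1` barely shifts frequencies, `s = 0.5` usually reaches high
frequency, `s = 1` usually fixes.

Beneficial alleles absent from the founders are seeded at one copy; a
domestication phase that loses a beneficial allele restarts (up to 100
times) so the recorded truth set is always realized, and the final
beneficial-allele frequency in the full cultivar population is part of the
truth record. New mutations arise each generation in the survivors.

## Observation model

`emit_vcf()` writes VCFv4.2 with per-sample `GT:DP`: QUAL is drawn so that
a configurable fraction of sites (default 5%) falls below 30, depth is
Poisson around `mean_depth = 20`, and a configurable fraction of genotype
calls (default 2%) is masked — enough structure to make every filter rule
fire. All outputs (VCF, GFF3 gene tiling with a single-copy flag, truth
BED + JSON) are byte-identical given the same config and seed.

## What passing tests do and do not show

The generator reproduces the *per-site* neutral expectations exactly, the
bottleneck's allele-frequency drift, hitchhiking with crossover
recombination during the breeding generations, and a realistic observation
layer. It does not model background LD in the wild, population structure
within the wild group, clonal (mitotic) variation, gene conversion, indels
or genotyping error beyond missingness; chromosome lengths and gene
density are schematic. Tests passing on these data show the pipeline's
statistics, calling logic and power behave as designed under the stated
model — not that the pipeline's absolute scores match any particular real
data set, which is why acceptance is rank- and property-based.

# Problem sizes and reproducibility

The validation suites run, per replicate, one to five 1-Mb chromosomes with
roughly 2,000-14,000 filtered SNPs and 40 samples: 50 neutral replicates
for the calibration of the composite call (its false-call fraction is
structurally bounded by the marginal top-5% rules), 50 replicates per
selection strength `s in {0.1, 0.5, 1.0}` for power and recovery, and 50
replicate pairs for the terminal-ROH discrimination, with smaller replicate
counts in the quick-property tests. `scripts/acceptance.R` recomputes the
headline quantities from scratch with configurable seed; every simulation
seed derives from the one `--seed` argument, and all randomness flows
through R's RNG (including the C++ kernels), so identical invocations are
bit-reproducible.

# Known limitations

* XP-CLR scores are rank-comparable, not absolutely comparable, to the
  original program (different weighting, focal-point and grid choices).
* The drift model's truncated-normal approximation is coarse for sites
  within a few hundred bp of a strongly selected locus (component means at
  the boundary); the boundary atoms and point-mass collapse keep the
  likelihood proper there.
* Sexual-origin IBD tracts after an extreme desk-scale bottleneck can span
  a noticeable fraction of a short chromosome; on the default 1-Mb
  chromosomes the 25% terminal-extent threshold separates them from
  engineered clonal tracts, but much shorter chromosomes blur that margin
  (the real signature is defined on full-length chromosomes).
* `estimate_omega` assumes a shared genome-wide drift scale; per-chromosome
  heterogeneity (e.g. recombination deserts) is not modelled.
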