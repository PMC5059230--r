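---
title: "Methods: population genomics of a wild-rice diversity panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genomics of a wild-rice diversity panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orscpop)
```

This vignette is the package's own account of the statistical methods it
implements, the assumptions behind them, and the design choices made where
the methodology left room. The setting is a diversity panel of the wild
rice species complex (*Oryza rufipogon* / *O. nivara*, the ORSC) genotyped
at genome-wide SNPs, with accession metadata (species label, geography,
phenotypes), model-based ancestry proportions, chloroplast variant data,
and PCR assays at two domestication genes.

## Data model

Genotypes are unphased diploid dosages in {0, 1, 2} of the alternate
allele, with missing calls (`NA`) expected at GBS-like rates (~28 %).
Phase is ignored everywhere: a heterozygote is dosage 1 however it arose.
Positions are 1-based and sites are kept sorted by chromosome and
position; multi-allelic sites are dropped on VCF import because the
analyses assume biallelic SNPs. Missing data are handled by per-SNP
pairwise deletion throughout — no imputation, matching how sparse GBS
panels are usually analysed.

## SNP filtering

A SNP is retained when its call rate across the accessions in the matrix
at hand is strictly greater than 0.5 and its minor allele count, over
called alleles only, is at least 4 (a literal reading of "MAC > 3").
Computing the call rate on the current matrix rather than an original
panel makes the filter composable: filtering a population subset applies
the same rule to that subset, and the filter is idempotent.

## Differentiation, diversity, distance

Per SNP, Weir–Cockerham variance components are computed from allele and
heterozygote counts for r populations: with per-population sample sizes
$n_i$, allele frequencies $p_i$, and heterozygote fractions $h_i$,

$$a = \frac{\bar n}{n_c}\Big(s^2 - \frac{1}{\bar n - 1}\big(\bar p(1-\bar p) - \tfrac{r-1}{r}s^2 - \tfrac{\bar h}{4}\big)\Big),$$

with the analogous $b$ and $c = \bar h / 2$, and $\theta = a/(a+b+c)$.
SNPs monomorphic across the analysed groups have undefined $\theta$ and
are excluded from window sums. Windows are non-overlapping blocks of 100
SNPs within a chromosome (a trailing partial block is dropped); the window
value is the ratio of sums $\sum a / \sum(a+b+c)$ — the standard way to
combine variance components — and the genome-wide value is the mean of
window values with the 2.5/97.5 percentiles of the window distribution as
an empirical 95 % CI. The ratio of sums over all SNPs is also reported
(`overall_theta`); the two agree closely on homogeneous panels but the
windowed mean is the headline number. Negative per-window values are kept,
not clamped: the estimator is unbiased around zero and truncation would
bias genome means upward.

Nucleotide diversity uses the unbiased per-site heterozygosity
$\pi_i = \frac{n}{n-1}\,2p(1-p)$ over the $n$ called alleles, summed per
window and divided by the window span in kb (undefined when the first and
last SNP coincide). This equals the mean pairwise allele difference, which
is what the exhaustive oracle in the test suite computes.

Genetic distance between two accessions is the allele-sharing site
distance ($|x-y|/2 \in \{0, 0.5, 1\}$ on dosages) averaged over co-called
SNPs, then Jukes–Cantor corrected, $d = -\tfrac34\ln(1 - \tfrac43 p)$,
which is undefined at $p \ge 0.75$ — an error, not a clamp, since reaching
that saturation on real diploid data indicates something is wrong.
Group-pair distances average the corrected distance over inter-group
accession pairs and are computed only on SNPs polymorphic in the union of
the two groups: monomorphic sites carry no information about a pair and
deflate distances by a panel-dependent factor. Accession-level matrices
(for trees and Mantel tests) use all co-called SNPs. Neighbor-joining
trees come from `ape::nj`; bootstrap support resamples SNPs with
replacement, rebuilds distances and trees, and counts bipartitions with
`ape::prop.clades`.

## LD decay

Within a population, SNPs pass an LD-specific filter (≤ 30 % missing, at
least two accessions carrying the minor allele), then every
same-chromosome pair up to 10 Mb apart contributes the squared Pearson
correlation of dosage vectors over co-called accessions — composite LD,
which is well defined on unphased diploids and deterministic, unlike
EM-phased haplotype estimates. Pairs with fewer than 4 co-called
accessions or zero variance are skipped. Pairs are averaged in half-open
distance bins (a pair on an edge belongs to the right-hand bin); the
default edges run 0–10 Mb in 100-kb steps and are configurable, since the
appropriate resolution depends on marker density.

Because composite r² carries an upward small-sample bias of order
$1/n$, curves from populations of different sizes are not comparable.
The pipeline therefore analyses the reference population (the one whose
size equals the sub-sample size, 12 by default) once, and sub-samples
every larger population to 12 accessions 100 times — re-applying the SNP
filter inside each draw — reporting per-bin means and a 2.5/97.5
percentile band across draws. The same bias means a full-sample bin mean
from a larger panel sits slightly below the sub-sampled band's centre;
the band still covers it when haplotype structure (not sampling noise)
dominates the signal, which is the regime the coverage test exercises.

## Isolation by distance

Geographic distance is the haversine great-circle distance on a sphere of
radius 6371 km. Accessions without coordinates are excluded before either
matrix is formed — collections without location detail cannot enter the
test. The Mantel statistic is the Pearson correlation of lower triangles;
the null is built by jointly permuting rows and columns of the geographic
matrix, with $p = (\#\{|r^*| \ge |r|\} + 1)/(B + 1)$ at $B = 1000$
permutations. The add-one correction keeps $p > 0$ and matches standard
permutation practice. The test is two-sided on $|r|$ by default —
isolation by distance predicts positive correlation, but sidedness is a
reporting choice, so `sided = "greater"` and a `log1p` distance transform
are available as flags and off by default.

## Chloroplast haplotype networks

Accessions with any missing chloroplast site are excluded (logged), and
identical allele vectors collapse into haplotypes numbered by descending
count with lexicographic tie-breaks, so numbering is deterministic.
Indels are single characters with unit weight — each polymorphism one
evolutionary event.

The network is a minimum-spanning network: haplotype pairs are processed
in increasing Hamming distance, ties together; a connection is added when
the pair is within the connection limit and not already joined at a
network distance less than or equal to its Hamming distance, evaluated
against the graph as it stood before the current distance level. Equally
parsimonious alternatives are therefore all retained, which is exactly
what produces the loops characteristic of chloroplast networks
(parallelisms and reversals, not recombination). A connection of length
j introduces j−1 inferred intermediate nodes private to that connection;
how a parsimony program shares inferred intermediates between alternative
paths is not specified by the method, so connection-private intermediates
are the conservative choice. The probabilistic connection limit itself
(the 95–97 % statistical-parsimony bound) is accepted as an input
parameter — 6 steps by default for a ~25-site alignment — rather than
re-derived, keeping the algorithmic core exact while the probability
model stays with its original reference.

cpGroups are the connected components after removing connections longer
than a threshold (default: the network's own limit); components with at
least two sampled haplotypes become groups, singletons are flagged
independent. Decreasing the threshold only refines the partition, which
the tests check as a monotonicity property.

Ancestral states are called per site from outgroup frequencies: an allele
with outgroup frequency strictly above 0.65 that is also present in the
ingroup is ancestral, the alternative is derived, anything else —
including sites monomorphic overall — is unresolved rather than an error.

## Admixture, concordance, domestication loci

An accession is assigned to the subpopulation of its maximum ancestry
proportion when that maximum reaches 0.75; strictly below, it is admixed
(the boundary case is assigned, reading "less than 75 %" literally).
Concordance between subpopulations and species labels is a Pearson
chi-square without continuity correction on the contingency table,
excluding admixed accessions by default; the effect size is Cramér's V²,
$\chi^2 / (n \cdot \min(r-1, c-1))$, chosen because it reduces to
$\phi^2 = \chi^2/n$ for two-label tables, lies in [0, 1], and equals 1
exactly for a block-permutation table. The "r²" reported for such
associations in the literature is rarely defined precisely; V² is the
interpretation adopted here, applied to the groups × two-species table by
default with collapsing options exposed.

Indel genotypes are scored from PCR band lengths with a ±3 bp tolerance
(236/222 bp for the 14-bp *RC* deletion, 227/205 bp for the 22-bp *Bh4*
deletion); both bands mean heterozygous, an unexpected band is an error
naming the assay. The extended-haplotype scan selects SNPs in a region
(~580 kb around *RC* by default) with MAF > 0.05 and < 3 % missing across
the combined panels, then keeps those with a two-sided Fisher exact
p < 1e−5 for the allele-count difference between white-pericarp cultivated
and red-pericarp wild accessions (heterozygotes contribute one allele to
each class; chi-square is available as a flag, Fisher is the default for
exactness at small counts). The cultivated allele at each selected SNP is
the majority allele in the cultivated reference panel — ties drop the SNP
with a warning — and each accession is painted cultivated, wild,
heterozygous, or missing. An accession carrying the cultivated or
heterozygous state at all three in-gene focal markers (two SNPs and the
14-bp indel) is classified introgressed; wild at all three, wild; any
other pattern, including a missing focal marker, inconsistent.

## The synthetic-data generator

The generator exists so that every stage can be tested against known
truth. Its defaults mirror the study design the package targets: six
subpopulations of sizes (60, 40, 25, 40, 12, 38) — the 12-accession group
exercising the no-sub-sampling LD path — plus 71 symmetric-Dirichlet
admixed accessions (286 total, 24.8 % planted admixed, densely spanning
the 0.75 threshold); 28 % missing calls; twelve rice-like chromosomes of
23–45 Mb; per-group species-label probabilities matching reported
subpopulation compositions (91 %, 44 %, 100 %, 36 %, 17 %, 50 %
perennial). The default SNP count is 5000: desk-scale for tests and the
acceptance script while leaving window and LD geometry realistic; all
counts scale up by configuration.

Genotypes follow the Balding–Nichols model: ancestral frequency
$p \sim U(0.05, 0.95)$, group frequency
$\sim \mathrm{Beta}(p\frac{1-F}{F}, (1-p)\frac{1-F}{F})$ (a point mass at
F = 0), pure genotypes Binomial(2, group frequency), admixed alleles drawn
from groups sampled by the accession's Dirichlet ancestry. This model was
chosen over coalescent simulation because it is closed-form, fast, and its
F parameter is the Weir–Cockerham estimand, making parameter recovery a
meaningful test. By default SNPs are independent, which keeps those
marginals exact and Fst recovery unbiased. Linkage is opt-in
(`recomb_block_bp > 0`): each group then carries a finite pool of founder
haplotypes and every gamete is a block mosaic with exponential block
lengths, giving monotone r² decay on the block scale without a full
recombination model. The pool is finite, so unlinked loci still show the
$\approx 1/(n-1)$ correlation floor expected of composite r².

Geography places group centroids around a base point (20° N, 100° E) with
a configurable spread and scatters accessions with Gaussian jitter;
admixed accessions sit at the ancestry-weighted centroid average, so
geography correlates with ancestry the way a species-wide collection does.
Chloroplast haplotypes arise by stepwise mutation: each group founder is
`theta_cp` steps from a common root on group-disjoint site sets, in-group
accessions carry the founder or an interior walk state plus up to two
private extra steps, and outgroups lie at least six steps from the root,
borrowing one site per group walk so they stay distant from every in-group
clade. One site is an indel (a 69-bp-deletion analog) with a SNP "nested"
alongside it; the two are independent biallelic columns rather than a
literal nested encoding, which is sufficient for polarity tests. The
sites are chosen so outgroups remain ancestral at both, keeping their
polarity recoverable. Note a geometric constraint: with 25 sites, six
founder clades cannot simultaneously have within-clade variation and
pairwise separation beyond a 6-step limit, so clade-recovery tests use 40
sites and 4-step walks; the 25-site default instead produces the
reticulate, singly-connected networks typical of real panels. The
domestication panel plants a 40-SNP differentiated block (±290 kb around
a focal locus at rice-like coordinates on chromosome 7), the 14-bp
deletion as a pseudo-marker row (`alt = "DEL"`, invisible to SNP
selection), decoy SNPs violating each selection filter, and optional
phenotype/genotype discordants.

What the generator does not emulate: ascertainment bias of GBS SNP
discovery, non-uniform missingness (real GBS missingness is
depth-dependent), mutation-rate heterogeneity, selection, and realistic
demographic history. Passing tests therefore show that the estimators
recover the parameters of a well-specified generative model at realistic
scale — not that every property carries to real panels with those
additional artefacts.

## Numerical choices and degenerate inputs

Seeds: every stochastic routine takes an explicit seed and restores the
caller's RNG state; the pipeline derives per-stage streams from its master
seed by fixed offsets (geography +11, LD +12, Mantel +13, bootstrap +14)
so stages are individually reproducible. Q-matrix rows are renormalised
when within 1e−3 of summing to one, rejected otherwise. Degenerate cases
are deliberate: zero-variance distance matrices make the Mantel test
error (not return NA); empty filter results warn rather than error;
a chromosome with fewer SNPs than a window yields zero windows with a
warning; a population smaller than the sub-sample size is an error naming
the population.

## Problem sizes

The test suite runs at 50–5000 SNPs and 10–300 accessions; the acceptance
script uses the full 286-accession default panel at 5000 SNPs, six
replicate-calibrated Fst recoveries at 5000 SNPs each, 200 null Mantel
panels of n = 20 at 500 permutations, and 100 LD-decay seeds at 300 SNPs.
These sizes were chosen so the whole battery runs in a couple of minutes
on a laptop while every statistic still has enough replication to be
meaningfully checked.

## Known limitations

The statistical-parsimony probability bound is parameterised, not
computed; LD decay is summarised by binned means, not a fitted decay-rate
model (Hill–Weir), so "decay rate" comparisons between populations are
visual rather than parametric; the concordance effect size is one
defensible reading of an under-specified "r²"; and model-based ancestry
estimation itself (the variational algorithm producing Q matrices) is
consumed, not implemented — the package reads its standard meanQ output.
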