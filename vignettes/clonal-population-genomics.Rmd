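---
title: "Clonal population genomics with clonalpop: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal population genomics with clonalpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalpop)
```

## The problem

Many rare plants spread by rhizomes, so a field "individual" (a stem, or
ramet) is often one of many genetically identical copies of a single
genet. For a threatened species this matters twice over: population sizes
inferred from stem counts can exceed the number of reproductively
independent individuals by an order of magnitude, and diversity
statistics computed on ramets are pseudo-replicated. `clonalpop` packages
the analysis chain a conservation-genomics survey of such a species runs
on ddRAD SNP genotypes: locus filtering, per-population diversity and
inbreeding, pairwise divergence and isolation by distance, admixture and
discriminant structure, distance-threshold clone delimitation with
clonal-richness summaries, and a qualitative conservation genetic-value
rating per population.

This vignette documents the models and estimators, every tunable that
matters, the synthetic-data generator used to validate the chain, and
the package's own design decisions where the underlying procedures are
conventionally done "by eye".

## Data model

Genotypes are unphased diploid calls coded as alternate-allele counts
(0, 1, 2) with `NA` for missing; multiallelic and non-SNP VCF records
are dropped on input rather than split, since every downstream statistic
assumes biallelic loci. The locus presence filter keeps loci typed in at
least a fraction `min_presence` of samples (inclusive boundary: a locus
present in exactly 60% of samples passes a 0.6 filter). Typical ddRAD
datasets for non-model plants retain loci at 40–60% presence; stricter
cutoffs can discard most informative sites.

## Diversity and inbreeding

Per population and locus, observed heterozygosity is the fraction of
heterozygous calls among non-missing calls. Expected heterozygosity uses
Nei's small-sample-corrected gene diversity,

$$H_E = \frac{2n_c}{2n_c - 1}\left(1 - \hat q^2 - (1-\hat q)^2\right),$$

with $n_c$ the callable diploids and $\hat q$ the sample allele
frequency; population values are unweighted means over loci. Loci with
no calls in a population are excluded from that population's mean, while
loci monomorphic within a population contribute 0 — no within-population
re-filtering — so values are comparable across populations genotyped on
one common locus set. The inbreeding coefficient is the ratio of
averages, $F_{IS} = 1 - \bar H_O / \bar H_E$, which is robust to
low-diversity loci (the average-of-ratios explodes where $H_E$ is tiny);
it is reported as missing, never as zero, when $\bar H_E = 0$. The
heterozygosity deficit $\Delta H = H_E - H_O$ is carried as an explicit
column because conservation assessments read it directly.

This $H_E$ is the plain Nei estimator, not the hierfstat `Hs` variant
that additionally debiases using $H_O$; published tables computed with
the latter can differ in the third decimal, and their printed $F_{IS}$
(computed with per-locus weighting) need not equal
$1 - H_O/H_E$ of their own printed columns. `clonalpop` does not attempt
to reverse-engineer that weighting.

## Divergence and isolation by distance

Pairwise $F_{ST}$ is the Weir–Cockerham (1984) estimator: per locus the
variance components $a$ (among populations), $b$ (among individuals
within populations), and $c$ (within individuals) are computed from the
two populations' sample sizes, allele frequencies, and heterozygote
counts, and combined over loci as $\hat\theta = \sum a / \sum (a+b+c)$.
Loci where either population has fewer than two callable diploids, or
where all components vanish, are skipped for that pair. Negative
estimates are legitimate small-sample outcomes and are reported as
computed; clamping is a display decision, not an estimation one.

Population geographic positions are centroids of their samples'
coordinates (surveys georeference samples, not populations), and
distances are haversine great-circle kilometres (mean Earth radius
6371 km, i.e. 111.19 km per degree of latitude). The Mantel test
correlates the off-diagonal entries of the $F_{ST}$ and distance
matrices and permutes rows and columns of one matrix jointly;
because the scientific question is whether divergence *increases* with
distance, the test is one-sided with the add-one convention
$p = (1 + \#\{r_{perm} \ge r_{obs}\})/(n_{perm}+1)$ (9999 permutations
by default, seed required). The permutation machinery is `vegan`'s.

## Ancestry estimation and K selection

Individual ancestry proportions are estimated under the standard
admixture factorization: the probability of sample $i$ carrying genotype
state $j \in \{0,1,2\}$ at locus $l$ is
$\sum_k Q_{ik}\, G_{kjl}$, with $Q$ rows on the probability simplex and
$G_{k\cdot l}$ a per-cluster genotype-state distribution. The fit
maximizes the masked log-likelihood (missing calls simply drop out of
the sum) with a symmetric Dirichlet$(1+\alpha)$ prior on the rows of
$Q$, by expectation–maximization. EM was chosen over alternating
least-squares with simplex projection because it makes three properties
structural rather than empirical: the penalized loss is monotonically
non-increasing (asserted in the tests at every iteration), the simplex
and frequency constraints hold exactly at every step, and the training
loss is the same cross-entropy later used for model selection. The
regularization default $\alpha = 10$ acts as a mild pseudocount —
negligible against the thousands of observed calls per sample, but it
keeps memberships strictly positive and tempers degenerate solutions at
large K. Convergence is declared at a relative loss change below 1e-6
(500 iterations cap). Clusters are relabelled by the first sample index
attaining maximum membership so repeated runs plot stably.

K is selected by masked prediction: 5% of observed calls are held out
(masks are re-drawn, boundedly, if a locus would lose its last call),
the model is fitted for each candidate K, and held-out calls are scored
by cross-entropy; five mask/initialization replicates are averaged and
the minimizing K wins, ties to the smaller K. On panmictic data the
curve is flat-to-rising and K = 1 wins; overfitting at larger K shows up
directly as worse held-out prediction.

## DAPC

DAPC reduces the mean-imputed, centered genotype matrix to `n_pcs`
principal components and then seeks axes maximizing between- over
within-population variance. The discriminant step solves the ridge
regularized generalized eigenproblem $(W + \varepsilon I)^{-1}B$
directly (with $\varepsilon$ at $10^{-9}$ of the mean within-group
variance) rather than calling a classical LDA routine, because surveys
of highly structured species routinely produce populations fixed for
different alleles — zero within-group scatter — where classical LDA
implementations refuse to run. On non-degenerate data the axes agree
with `MASS::lda` (checked in the test suite); sample assignment is
nearest-centroid in discriminant space. Axis signs are fixed
(largest-magnitude loading positive), making scores invariant to locus
order. The number of PCs is chosen by stratified holdout
cross-validation: 10% of each population is held out (populations too
small to stratify stay whole in training, with a message), PCA and the
discriminant axes are refitted on training samples only, and the
candidate maximizing mean correct reassignment wins, ties to the fewest
PCs — retaining too many PCs overfits the discriminant space, and the
holdout curve exposes that.

## Clone delimitation

Genetic distance is the Prevosti distance on allele counts,
$d(i,j) = \sum_l |g_{il} - g_{jl}| / (2 L_{ij})$ over the $L_{ij}$ loci
where both calls are present: 0 for identical genotypes, 1 for opposite
homozygotes at every shared locus. A pair with no shared called locus is
an error, not a silent 0 — which is why a per-sample missingness cap
(default 25%) is applied before delimitation; the procedure is sensitive
to missing data.

Ramets of one genet differ only by genotyping error, so the distance
histogram of a clonal stand is bimodal: an error mode near 0 and an
unrelatedness mode further out. The threshold rule makes the
conventional eyeball decision algorithmic: sort the unique distances
below a search ceiling, take the largest gap between consecutive values,
and put $d^\*$ at its midpoint if the gap is at least `bin_width`
(default 0.005) with values on both sides. Two guards return "no
threshold" (every sample its own genet): no qualifying gap, or a minimum
pairwise distance already at or above a floor (default 0.04) — a stand
whose closest pair differs by 4% of alleles contains no plausible
clones. The defaults (ceiling 0.10, floor 0.04) are scaled to
low-diversity empirical ddRAD data where inter-genet distances sit below
0.10; on the package's own Balding–Nichols simulations, whose
Uniform(0.05, 0.95) ancestral frequencies make unrelated genotypes ~0.2
apart, the ceiling must be raised (`search_ceiling = 0.5`) so the gap
search can see the inter-genet mode. A fixed `threshold` argument
bypasses detection entirely, reproducing manually chosen per-population
cutoffs.

Clones are then read off a UPGMA (average-linkage) tree cut at height
$d^\*$: every subtree below the cut is one genet. UPGMA's monotone
heights make the genet count G non-increasing in $d^\*$ (a property the
tests assert), and tied merges are snapped to monotone to protect the
cut against ~1e-17 floating drift. Clonal richness is
$CR = (G-1)/(N-1)$: 0 for a monoclonal stand, 1 when every sample is
unique; $CR = 1$ by convention for a single sample. Spatial clone maps
pair assignments with coordinates and report an intermixing index — the
fraction of samples whose nearest spatial neighbour is a different
genet — which separates guerrilla (intermixed, index near 1) from
phalanx (clumped, index near 0) growth architectures.

## Conservation genetic value

The qualitative rating is a calibrated decision list over four
per-population inputs: divergence level (mean pairwise $\theta$ binned
at 0.05 / 0.15 / 0.20 into Low / Moderate / High / Very High,
left-closed bins), unique ancestry (some cluster with mean membership
≥ 0.5 in the population and < 0.2 in every other — a numeric stand-in
for reading private blocks off an ancestry barplot), $F_{IS}$, and
$H_O$:

* no unique ancestry → **Low**;
* unique ancestry, High or Very High divergence, and $F_{IS} < 0.05$ →
  **High**;
* otherwise → **Moderate**.

This is the minimal rule set consistent with all twelve rows of the
bundled *Scutellaria floridana* survey table (an exact 12/12 match,
asserted in the tests); it is a reconstruction of a verbal rubric, not
the original authors' code. $H_O$ is reported alongside but does not
gate the decision — the twelve labels are fully determined without an
$H_O$ cutoff, so imposing one would be uncalibrated.

## The synthetic-data generator

`simulate_clonal_snps()` emulates the sampling regime the pipeline
targets: ~12 populations of 10–35 stems, thousands of biallelic loci
with up to 40% missingness, moderate divergence, inbreeding, and clonal
groups. Ancestral allele frequencies are Uniform(0.05, 0.95); population
frequencies follow the Balding–Nichols construction
$\mathrm{Beta}(p(1-\theta)/\theta,\ (1-p)(1-\theta)/\theta)$ — the
minimal model with a target $F_{ST}$; genet genotypes are drawn with
heterozygote probability $2pq(1-F_{IS})$; each ramet copies its genet's
genotype and then flips each allele independently with probability
$\varepsilon$ (default 0.005; ddRAD genotyping error is rarely
quantified in survey datasets, so this is a free parameter) and masks
each call with the
missing rate (default 0.2). Ramet counts default to $1 +
\mathrm{Poisson}(0.7)$ per genet (mean 1.7 stems per clone, matching
field-scale clone-size summaries). Layouts: guerrilla scatters ramets
i.i.d. over the population extent; phalanx clusters them (Gaussian,
default sd 1e-4 degrees) around genet centers. `expected_summaries()`
returns the closed-form $H_E$, $H_O$, $F_{IS}$, $\theta$ implied by the
generating frequencies, used as oracles in the tests.

What the generator does *not* emulate: linkage between loci, coalescent
genealogies, spatially explicit gene flow, allele dropout that is
correlated across loci or samples, and the strongly skewed allele
frequency spectra of real ddRAD data. Passing recovery tests therefore
demonstrate estimator correctness under the stated model, not robustness
to every artifact of a real library.

## Numerical choices and problem sizes

Presence-boundary comparisons carry a 1e-9 tolerance so exact fractions
are kept. Admixture probabilities are floored at 1e-300 inside logs and
at 1e-9 when scoring held-out calls. The test and validation suites run
at sizes chosen to make the statistical assertions sharp but quick:
parameter-recovery checks use 5000 loci and 50 diploids per population
(bootstrap-over-loci standard errors, three-SE bands), clone recovery
uses hundreds of loci and tens of stems, the Mantel null calibration
uses 200 replicates of 8 populations at 499 permutations, and the
ancestry/K-selection checks use a few hundred loci and 30–45 samples.

## Known limitations

* Estimates are computed on ramets; with heavy clonality,
  frequency-based statistics ($\theta$, $F_{IS}$, $H_E$) are biased by
  pseudo-replication, as the worked example in the README shows. The
  intended workflow is delimit first, then rerun diversity statistics on
  one ramet per genet if clone-corrected values are needed (the package
  leaves that subsetting to the user via `subset_genotypes()`).
* The ancestry model is an admixture analogue fit by EM, not a port of
  any specific sNMF implementation; cross-entropy values are comparable
  within a run, not across software.
* The histogram-gap detector is deliberately conservative; per-dataset
  threshold overrides are first-class, because no automatic rule
  reproduces every judgment call made on real histograms.
* `write_vcf()` emits placeholder REF/ALT bases (genotype codes do not
  track alleles); round trips preserve the genotype matrix, not the
  original alleles.
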