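---
title: "Methods: diversity, differentiation, and sweep scans in popsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, differentiation, and sweep scans in popsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

popsweep analyses multi-sample biallelic SNP genotypes from diploid
populations nested in geographic groups — the sampling design of
reduced-representation (e.g. SLAF-seq/RAD-seq) population surveys of
wild vertebrates. This vignette is the package's account of the models
and estimators it implements, the tunable parameters that matter, what
the synthetic-data generator does and does not emulate, and the
numerical and design choices made where several defensible options
existed.

## Data model and site filtering

Genotypes are stored as unphased dosage codes 0/1/2 (`NA` missing);
phase in input VCFs is discarded because no statistic implemented here
uses it. All internal interval coordinates are 0-based half-open;
1-based inputs (VCF positions, GFF3) are converted at the boundary.

Site filters follow the standard reduced-representation QC pair:
minor allele frequency `maf >= 0.05` and site integrity (call rate)
`int >= 0.5`, both boundaries inclusive, both computed jointly over all
samples so that one genome-wide SNP set feeds every downstream
analysis. The alternate allele frequency at a site is
$p = (n_\text{het} + 2 n_\text{hom-alt}) / (2 n_\text{called})$,
from non-missing calls only; sites with no called genotype have
undefined MAF and never pass. Integrity is computed on the retained
biallelic set (whether upstream tools compute it before or after
removing non-SNP records is tool-dependent; the choice only relabels
the denominator of a filter the user controls anyway).

## Diversity statistics

At a biallelic site with allele frequencies $p, q$ and $n$ called
diploids, the unbiased gene diversity (expected heterozygosity) is

$$\hat h = \frac{2n}{2n-1}\left(1 - p^2 - q^2\right),$$

which equals the average number of pairwise differences among the $2n$
sampled alleles exactly — so per-SNP nucleotide diversity $\pi$ and
unbiased $H_e$ coincide at SNP sites by identity. Published tables
from windowed tools often report $\pi$ per base pair instead (summed
site diversities divided by a surveyed length), which yields values an
order of magnitude or more below $H_e$; both conventions are exposed
(`pi_snp` by default, `pi_bp` when a `surveyed_length` is supplied) and
results should state which one they use. Observed heterozygosity is
the pooled heterozygous-call fraction, and marker informativeness uses
Botstein's polymorphism information content
$PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$, so
$0 \le PIC \le 1 - \sum p_i^2$ always holds. Per population, allele
frequencies use only that population's calls; sites with fewer than two
called genotypes in a population are excluded from its averages, and the
summary's `Mean` row is the unweighted average across populations.

## F~ST~: Weir–Cockerham variance components

Differentiation uses the Weir & Cockerham (1984) moment estimator for
diploids: per site, among-population (`a`), among-individual (`b`) and
within-individual (`c`) variance components computed from sample sizes,
allele frequencies and observed heterozygote proportions, with the
sample-size-weighted means and $n_c$ of the unbalanced design. The
multi-locus estimate is the ratio of sums
$\hat\theta = \sum_\ell a_\ell / \sum_\ell (a_\ell+b_\ell+c_\ell)$
over sites informative for the pair (every population called, pooled
site polymorphic) — which makes $\hat\theta$ invariant to duplicating
sites. Small negative estimates are an expected property of the
moment estimator near $F_{ST} = 0$ and are not floored by default. A
subtlety worth knowing: $\hat\theta$ assumes independent sampling, so
literally duplicating a sample set into two "populations" produces the
estimator's small negative bias ($\approx -1/(2n-1)$), not zero; the
proper null is splitting one panmictic pool.

## AMOVA at the allele level

The hierarchical partition (among groups / among populations within
groups / within populations) is computed on allele units: each called
diploid contributes two alleles per locus, and every sum of squares
reduces to per-locus allele counts — for a set holding $m$ called
alleles of which $y$ are the alternate, $SS = y(m-y)/m$ — which makes
the computation phase-invariant and fast. Variance components are
estimated locus by locus with the standard unbalanced-design
expected-mean-square coefficients and combined across loci as ratios of
sums. This is a deliberate design choice: an AMOVA on squared Euclidean
distances between *genotype dosage vectors* collapses the
within-individual level and converges to $2F/(1+F)$ rather than $F$
under an island model, so its $\Phi_{ST}$ is not comparable to
$\hat\theta$ or to the output of the standard genotypic-AMOVA tools;
the allele-level formulation restores $\Phi_{ST} \approx \hat\theta$
(they agree to three decimals on simulated data here). Loci at which a
population has no called allele are excluded (counted in the result's
`flags`); negative components are reported as estimated, as the field's
reference implementation does, so percentages can leave $[0, 100]$ and
are flagged rather than truncated.

Permutation significance uses level-appropriate schemes: $\Phi_{ST}$
permutes individuals among populations across the whole sample,
$\Phi_{SC}$ permutes individuals among populations within their group,
and $\Phi_{CT}$ permutes whole populations among groups. p-values are
$(\#\{\Phi^* \ge \Phi\} + 1)/(B + 1)$, never zero, and bit-reproducible
given `(n_perm, seed)` (the seed is a required argument). A structural
caveat: permuting whole populations means the null distribution for
$\Phi_{CT}$ has as many support points as there are distinct
assignments of populations to groups. With many populations this is
fine; with, say, 3 populations in 2 groups there are only 3
arrangements, the p-value is effectively discrete on $\{1/3, 2/3, 1\}$,
and it is conservative but far from uniform. Designs with few
populations should read $\Phi_{CT}$ p-values as coarse-grained
bounds — this is a property of the permutation scheme itself, not of
the implementation.

## PCA

Patterson-style normalization: missing entries are imputed with the
site mean dosage, each site is centred by $2\hat p$ and scaled by
$\sqrt{2\hat p(1-\hat p)}$, monomorphic or all-missing sites are
excluded with a warning, and the samples-by-samples covariance across
normalized sites is eigendecomposed. Returned coordinates are the
unit-norm eigenvectors (the convention of the standard genotype-PCA
tools), with eigenvalues and per-axis variance proportions alongside.

## Windowed sweep scan

Chromosomes are tiled with non-overlapping 10-kb windows anchored at
coordinate 0 (a `offset` argument allows replicating 1-anchored tools);
the terminal window is truncated at the chromosome length. Per window
and per contrast (group A = control/numerator, group B = the contrast
group — direction is always explicit):

* `fst`: ratio-of-sums $\hat\theta$ over in-window informative sites,
  treating the two groups as the two populations;
* `pi_a`, `pi_b`: summed per-site unbiased gene diversities divided by
  the window length in bp (the per-bp convention of windowed-diversity
  tools — deliberately different from the per-SNP convention of the
  population summaries);
* `log2_ratio` $= \log_2(\pi_A/\pi_B)$, finite only when both
  diversities are positive.

Windows with fewer than `min_snps` SNPs (default 2), zero diversity in
either group, or no informative F~ST~ site are flagged uninformative
and excluded from quantile computation; zero-diversity windows are
excluded rather than pseudocounted (a `pseudocount` argument exists for
sensitivity analysis). Realized cutoffs are empirical type-7 quantiles
of the informative windows: F~ST~ at the 0.95 level and the ratio at
both 0.05 tails. Selection is joint and inclusive: windows with
`fst >= cutoff` and `log2_ratio >=` the upper cutoff are called
selected in group B (diversity depleted in B); the lower tail
symmetrically calls selection in group A. Both tails are used because
depletion in either group is a sweep signal in that group; using only
one tail would silently assume which group experienced selection.
Genes are candidates when their interval intersects a selected window
by at least 1 bp under the half-open convention (adjacency is not
overlap). Enrichment is a one-sided hypergeometric over-representation
test per term against a user-supplied term-to-gene mapping, flagged at
raw p < 0.05 with no multiple-testing correction by default (a BH
column is available) — raw-p flagging matches common practice in this
literature but should be interpreted accordingly.

## The synthetic-data generator

`simulate_dataset()` draws, per site, an ancestral frequency $p_0$
(uniform on [0.05, 0.95] by default — a polymorphic-ascertainment
spectrum mimicking a MAF-filtered SNP panel), then group frequencies
from the Balding–Nichols Beta law with divergence `f_ct`, population
frequencies around their group with `f_sc`, and genotypes as
Binomial(2, p) per individual (Hardy–Weinberg within populations).
Missingness is uniform at random. Sweeps are modelled as a
deterministic pull of the target's frequency toward the nearer
boundary, $p' = (1-s)\,p + s\,[p \ge 0.5]$; a group-targeted sweep
distorts the *group* frequency before the population draws so the whole
group sweeps coherently (at $s = 1$ the target group is exactly
monomorphic in the window). This creates the joint low-$\pi$ /
high-F~ST~ signature the scan detects, which is all the recovery tests
require.

Defaults pin the target study design: seven populations with sample
sizes (10, 5, 20, 12, 16, 10, 3) in two geographic groups,
`f_ct = 0.064` and `f_sc = 0.058` (the hierarchical fixation levels the
AMOVA estimates in that design), and 10% missing calls (the integrity
filter only bounds call rates below at 0.5; 10% is a realistic
post-filter average for reduced-representation data). The desk-scale
genome default — 2 chromosomes x 1 Mb x 2,000 SNPs — gives every
statistic a few thousand informative sites, the regime where their
standard errors are small, while keeping full runs to seconds; the
validation suite scales particular checks up (20,000 sites for
divergence recovery; 510 and 2,000 windows for the scan) or down as the
property requires.

What the generator does *not* emulate: linkage disequilibrium (sites
are independent, so window statistics are less autocorrelated than in
real genomes and empirical-tail cutoffs are slightly sharper than they
would be on real data); demography (bottlenecks, migration,
expansions — divergence is a single symmetric parameter per level);
sweep trajectories and hitchhiking flanks; non-uniform missingness and
genotyping error. Passing recovery tests therefore demonstrate that
the estimators measure what they claim under the model the field's
moment estimators themselves assume — not that any particular empirical
dataset meets those assumptions.

Randomness is driven by one base seed through a hierarchical
sub-stream scheme (a deterministic hash of the seed and a label path,
e.g. `geno/chr1/AKS`), so identical configurations reproduce
bit-for-bit and adding a population or chromosome never perturbs the
draws of existing ones. All seeded routines restore the caller's RNG
state.

## Orchestration

`run_pipeline()` runs filter, diversity, pairwise F~ST~, AMOVA per
grouping, PCA, and one sweep scan per configured contrast (with gene
overlap and enrichment when annotations are supplied), writing one TSV
per stage plus a `manifest.json` with the package version, seed, all
thresholds, and input checksums. Output files contain no timestamps,
so identical config + seed reproduces byte-identical files; stage
outputs are identical whether produced by `run_pipeline()` or the
individual functions with the same parameters. Configurations validate
fully (including referenced populations and groups) before any
computation. The package's interface is its functions plus this
orchestrator; there is no shell entry point, as is usual for analysis
packages of this kind.

## Known limitations

* No LD-aware statistics (haplotype-based sweep tests, iHS/XP-EHH) and
  no coalescent simulation; the generator's independence across sites
  is a modelling choice, not an oversight.
* $\Phi_{CT}$ permutation p-values are coarse when populations are few
  (see above).
* The per-bp $\pi$ convention depends on a surveyed length the user
  must supply; per-SNP $\pi$ and $H_e$ coincide by identity and should
  not be read as independent statistics.
* Enrichment is generic over user-supplied mappings; it does not fetch
  or curate GO/KEGG annotations.
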