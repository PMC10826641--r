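---
title: "Methods: introgression, divergence and discordance scans with introscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: introgression, divergence and discordance scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

## Scope and model of the data

`introscan` analyses small radiations sampled with one to a few diploid
genomes per species: a multi-sample VCF over scaffolds, a
sample-to-population map, CDS intervals, a rooted guide tree, and
optionally per-window gene trees and aligned CDS copies of a candidate
gene. Everything downstream works from a single container, the
`genotype_matrix`: biallelic sites with alternate-allele counts
(0/1/2/missing) per diploid sample. Invariant records from an "all
sites" VCF are retained because the diversity denominators need them.

## Filtering model

Import applies three soft filters in a fixed order, mirroring common
practice for medium-coverage short-read genotyping:

1. **Quality.** Sites with QUAL below the threshold (default 20) are not
   discarded but *converted to invariant reference*: a failed variant
   call is treated as evidence for the reference state, keeping the site
   in diversity denominators. Per-genotype GQ filtering is available as
   an alternative mode that blanks genotypes instead.
2. **Depth.** Genotypes below the per-genotype depth (default 2), and
   all genotypes at sites whose total depth falls outside the site
   bounds (defaults 3 and 60), become missing.
3. **Missingness.** Sites where more than 50% of genotypes are missing
   are dropped.

Multi-allelic and non-SNP records are dropped rather than decomposed:
every downstream statistic is a biallelic frequency formula. The filter
log accounts for every input record, and filtering is idempotent.

## Windowed diversity: pi, dxy, FST

Per site with $n$ non-missing alleles and alternate count $c$ in a
population, within-population differences are $c(n-c)$ over
$\binom{n}{2}$ comparisons; between populations, $c_A(n_B-c_B) +
(n_A-c_A)c_B$ over $n_A n_B$. Window values are **ratios of sums**, not
means of per-site ratios: sums of differences and of comparisons are
accumulated first and divided once. Under missing data this estimator is
unbiased, because a site contributes exactly the comparisons it
supports; invariant sites contribute comparisons only. A window with no
comparisons is `NA`, never 0.

FST uses the Weir–Cockerham (1984) two-population variance components
$a$ (among populations), $b$ (among individuals) and $c$ (within
individuals), in the allele-frequency form with observed heterozygosity
taken from the genotypes. The window estimate is
$\sum a / \sum (a+b+c)$; per-site FST values are never averaged, and the
estimator may legitimately be negative.

Divergence outliers are flagged per species pair after a missing-data
pre-filter (windows with more missing counts than counted comparisons
are removed), as windows whose dxy exceeds the genome-wide mean by more
than `z_threshold` (default 3) sample standard deviations (n−1
denominator). Shared outliers are the exact intersection of two outlier
sets over the same window system.

## Four-taxon introgression statistics

For an oriented trio (P1, P2, P3) plus outgroup O, with population
alternate-allele frequencies $p_1 \dots p_4$ per site:

$$\mathrm{ABBA} = (1-p_1)\,p_2\,p_3\,(1-p_4), \qquad
  \mathrm{BABA} = p_1\,(1-p_2)\,p_3\,(1-p_4)$$

* **Patterson's D** is $(\sum \mathrm{ABBA} - \sum \mathrm{BABA}) /
  (\sum \mathrm{ABBA} + \sum \mathrm{BABA})$. Significance uses a
  delete-one block jackknife over contiguous, equal-count blocks of
  informative sites in genome order (default 20 blocks):
  $SE^2 = \frac{B-1}{B}\sum_j (D_{-j} - \bar{D}_{-j})^2$, $Z = D/SE$,
  two-tailed normal p. Across all trios the per-trio p-values are
  compared against a Bonferroni-corrected $\alpha = 0.05$.
* **f4-ratio**: $f = S(P1,P2;P3,O)/S(P1,P3;P3,O)$ with
  $S = \sum p_3(1-p_4)(p_2-p_1)$ and P3 substituted for P2 in the
  denominator. It estimates the admixture fraction of a P3-like donor
  into P2. Because the same P3 sample appears in numerator and
  denominator, finite-sample drift within P3 inflates the denominator
  slightly and the estimator is mildly conservative (downward-biased);
  the calibration targets below account for this.
* **fdM** is computed in SNP-count sliding windows. The numerator is
  $\sum(\mathrm{ABBA}-\mathrm{BABA})$; the per-site denominator
  substitutes $p_D=\max(p_2,p_3)$ for both $p_2$ and $p_3$ when the
  site's numerator is non-negative, and $p_D=\max(p_1,p_3)$ for both
  $p_1$ and $p_3$ (with a sign flip) otherwise. Sites at which P3
  carries no derived allele relative to the outgroup
  ($p_3(1-p_4)=0$) have a zero numerator and are excluded from the
  denominator as well. This conditioning was the one genuinely open
  design choice; the chosen rule is pinned down by the requirement that
  swapping P1 and P2 negates fdM *exactly*, which the test suite
  enforces to 1e−12. Positive values indicate P2–P3 sharing, negative
  P1–P3 sharing, and fdM is symmetric about 0 under the null.
* **f-branch** assigns excess allele sharing to branches of the rooted
  guide tree: for branch $b$ and tip $C$ outside $b$ and its sister,
  $f_b(C)$ is the median over sister tips B of the minimum over
  descendant tips A of the f4-ratio for (B, A, C, O), truncated at 0.
  Cells where C descends from $b$ or its sister are marked invalid
  (inconsistent with the guide topology). Optional block-jackknife
  Z-scores flag cells with $Z > 3$.
* The **candidate-region elevation test** compares the fdM values of
  windows overlapping a region against the scaffold-wide mean (a
  constant) with a one-sample, upper-tailed t-test. When the region
  windows are constant the t statistic takes its analytic limit (0 or
  signed infinity) rather than erroring.

Trios are enumerated from the guide tree with (P1, P2) the pair with
the most recent common ancestor; polytomies are resolved
lexicographically and flagged.

## Tree-based discordance

* **Normalized RF distance** counts symmetric-difference bipartitions,
  divided by $2(n-3)$ for binary trees and by the total internal-edge
  count for polytomous trees. Topology identity everywhere in the
  package uses canonical bipartition sets (the sorted tip set of the
  side not containing the alphabetically first tip), so rooted inputs
  are compared unrooted.
* **Topology weighting** across multi-sample taxa: the weight of a
  taxon-level topology is the fraction of one-tip-per-taxon
  combinations whose induced subtree matches it. Enumeration is exact
  up to 10,000 combinations and seeded uniform sampling beyond, with a
  reported Monte-Carlo SE. Exact mode is preferred (and the default
  regime at this package's taxon counts) because it is deterministic
  and directly testable against brute-force enumeration. Internal-branch
  support sums the weights of all topologies in which a given taxon set
  forms a clade relative to the outgroup.
* **Concordance factors.** gCF per species-tree branch is the
  percentage of decisive gene trees (those with at least one tip in
  each of the four surrounding subtrees) containing the branch's
  bipartition. sCF samples quartets (one sequence per surrounding
  group, seeded), counts decisive sites (two states, two carriers
  each) supporting the concordant versus the two discordant pairings,
  and averages 100 × concordant/decisive over quartets, skipping
  quartets with no decisive site. Both are defined around binary
  branches of the species tree.

## Loss-of-function scan

Aligned CDS copies are compared against a functional reference row.
Maximal gap runs yield deletions (large when at least 100 bp, a
configurable threshold set well below the ~500 bp exon-removing
deletions the scan is designed to catch) and insertions; any indel with
length not divisible by 3 is a frameshift. The realized CDS (the
sample's row with gaps removed, so insertions shift the frame) is
translated with the standard genetic code; the first stop strictly
upstream of the realized terminal codon is a premature stop. No
"terminal tolerance" window is applied. Heterozygous sites are encoded
as IUPAC codes and both resolutions are evaluated: a codon where only
one allele creates a stop (or a replacement) is reported with `het`
zygosity. Nonsynonymous substitutions are reported only inside named
amino-acid domain intervals (e.g. SRS1–SRS6, heme-binding), supplied by
the user, and domains downstream of a frameshift are flagged as not
scanned because the frame there is ambiguous.

Verdicts: `LOF` for any large deletion, frameshift or premature stop;
`putative_reduced_function` for domain substitutions only; `intact`
otherwise. Copies sharing an identical event (kind, position, length)
are grouped into shared-mutation clusters.

## The synthetic-data generator

The simulator exists so every statistic can be validated against known
truth. Gene trees are drawn under the multispecies coalescent on an
ultrametric species tree with branch lengths in coalescent units
(2N generations): lineages within a branch coalesce at pairwise rate 1.
Migration is an instantaneous pulse — at the pulse time each lineage in
the recipient branch jumps to the donor branch with probability $f$ —
because that is the simplest model whose admixture fraction is exactly
the quantity the f4-ratio targets. Mutations are infinite-sites and
biallelic, placed on branches proportionally to length with a
per-tree Poisson count, so site patterns map cleanly onto ABBA/BABA
expectations without recurrent mutation. Diploids pair two simulated
haploid lineages; each gene tree occupies a fixed-width genomic block
(default 10 kb) so that windows cut across trees, emulating
recombination-driven landscape variation. The generator deliberately
omits within-tree recombination, selection, demographic size changes
and sequencing error; passing tests therefore validate the estimators
under their own model assumptions, not robustness to those violations.

CDS fixtures inject specified mutations (large deletions, frameshift
indels with optional explicit inserted bases, premature-stop and domain
substitutions, hom or het) into a random stop-free reference, producing
alignments with exact known truth for the scanner.

## Calibration study sizes

The test suite and the acceptance script run the following simulation
studies (problem sizes chosen to give each check clear resolution while
keeping a full run in minutes):

* MSC closed form: 10,000 gene trees on a species tree whose focal
  internal branch is 1 coalescent unit; concordant-topology frequency,
  gCF and internal-branch weight are compared with
  $1-\tfrac{2}{3}e^{-1} \approx 0.755$.
* Null calibration: 200 replicate datasets (4 populations × 4
  diploids, 650 gene-tree blocks, 100 expected SNPs per block, giving
  well over 2,000 informative sites each); mean D should sit within 3
  standard errors of 0 and the jackknife |Z| > 1.96 rate within
  [0.01, 0.12].
* Introgression recovery: 50 replicates with a P3→P2 pulse of
  f = 0.1 (1,100 blocks each, >5,000 informative sites); the mean
  f4-ratio should land within ±0.05 of 0.1 and D should be significant
  (Z > 3) in at least 90% of replicates. A five-taxon simulation with a
  tip-to-tip pulse checks that the f-branch matrix peaks at the correct
  (branch, tip) cell.
* Property checks at fixed seeds: exact pi/dxy oracle equality on 100
  random matrices with 20% missingness, fdM bounds/antisymmetry on
  1,000 windows, RF metric axioms on 100 random triples, topology
  weights against brute-force enumeration, and loss-of-function
  sensitivity and specificity of 1.0 on 100 injected fixtures.

## Numerical and degenerate-input conventions

Ratio statistics return `NA` (with a warning where informative) on zero
denominators. The jackknife flags SE = 0 as degenerate instead of
emitting an infinite Z. Windows never span scaffolds; terminal short
bp windows are kept but flagged `partial`. Coordinates are 0-based
half-open internally, 1-based in VCF, 1-based closed in GFF3; all
conversions happen at the I/O boundary. All stochastic steps (the
simulator, quartet and combination sampling) take explicit seeds, and
identical configs reproduce byte-identical pipeline outputs.

## Known limitations

Population allele frequencies are treated as observed; no finite-sample
bias correction is applied to the f4-ratio denominator, so admixture
fractions are slightly conservative at small sample sizes. gCF/sCF are
defined only around binary species-tree branches. The guide tree used
for trio orientation must be rooted, and f-branch requires at least
four populations beyond the outgroup. The LOF scanner consumes
alignments; it does not build them.
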