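---
title: "Methods: conservation, distances, thresholds and congruence in mitoBarcode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation, distances, thresholds and congruence in mitoBarcode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoBarcode)
```

mitoBarcode evaluates protein-coding mitochondrial loci as
species-identification markers. This vignette is the package's own account
of the statistical machinery: the models, the tunable parameters and their
defaults, the numerical decisions taken where a published description left
the choice open, what the synthetic-data generator does and does not
emulate, and the limits of what the validation suite shows.

## Per-site conservation

Variation at each alignment column is summarised as Shannon information
adapted to aligned sequences: with $p_b$ the frequency of base
$b \in \{A, C, G, T\}$ at the site,

$$R_s = 2 - H, \qquad H = -\sum_{b:\,p_b > 0} p_b \log_2 p_b ,$$

so a fully conserved DNA site carries $\log_2 4 = 2$ bits and an
equally-mixed site 0 bits.

Two decisions matter here.

*Heteroplasmy rule.* An IUPAC ambiguity call (a heteroplasmic position) is
counted in the number of sequences but contributes to **no** base count:
out of 100 sequences with 99 A and one A/G, the site is 99% A and 0% C, G
and T. Frequencies are **not** renormalised to sum to one afterwards — the
worked 99%-A convention fixes this, and renormalising would change $H$ at
exactly the sites the rule is meant to handle. A consequence is that
$\sum_b p_b < 1$ is possible; the entropy sum runs over observed bases only
and $R_s$ is clamped to $[0, 2]$.

*Gaps.* The rule is stated for heteroplasmy; we extend the same treatment
to gap characters. This keeps the frequency vector monotone (adding a gap
can never raise a base's frequency) and avoids inventing a fifth symbol
with its own entropy contribution.

An approximate small-sample bias correction
($e = 3/(2 n \ln 2)$ subtracted from $R_s$) is implemented as an option of
`siteRs()` but **off by default**: the plain statistic is the one whose
worked values (2 bits at identity; $2 + 0.99\log_2 0.99$ at the 99%-A site)
the tests pin down.

Sliding windows of size $X$ report $\sum R_s / 2X$, i.e. the fraction of a
fully conserved window; the defaults $X \in \{101, 401, 601\}$ bp are the
fragment sizes typically sequenced for the two classic barcoding loci.
Windows advance by one site and are anchored at their 1-based start; a
window equal to the alignment length reproduces the mean conservation
percentage exactly (this identity is property-tested).

A site is *variable* when at least two distinct unambiguous bases occur,
and *singleton-variable* when exactly two occur, the minority base in a
single sequence and the majority base in at least two — so a 1-vs-1 column
in a two-sequence alignment is variable but not singleton.

## Distance suite

All distances operate after **complete deletion**: every column holding a
gap or ambiguity in *any* sequence is removed for all pairs (pairwise
deletion is available as a non-default flag). The surviving columns keep a
map to their original coordinates, so codon-position partitions are always
computed in the original frame.

*p-distance* is the proportion of differing sites. The *Kimura
2-parameter* distance is
$d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$ with $P$ and $Q$ the
transition and transversion proportions. When $1-2P-Q \le 0$ or
$1-2Q \le 0$ the pair is *saturated*: scalar calls raise an error of class
`saturationError`, matrix builders record `NA` with a flag, and summaries
exclude flagged pairs and report how many were excluded — we prefer an
explicit exclusion count to silently propagating infinities.

Distances are stored in substitutions per site; the ×100 presentation used
in barcoding reports is a formatting flag applied by accessors and
writers, never a property of the stored values.

*Nei–Gojobori dS/dN* follows the original pathway conventions under the
vertebrate mitochondrial genetic code (AGA/AGG and TAA/TAG stops, ATA Met,
TGA Trp; the code table comes from Biostrings). Synonymous site counts are
fractional: per codon position, the fraction of the three single-base
alternatives that preserve the amino acid, so $S + N = 3 \times$ codons by
construction; changes *to* stop codons count as non-synonymous in the site
fractions. Differences between codons are averaged over the $k!$ orderings
of single-base steps, excluding any pathway that visits a stop codon;
where at least one pathway survives, $sd + nd$ equals the number of
differing positions. Codon pairs whose every pathway crosses a stop are
skipped from the numerators with a reported count; distances are in the
p-distance flavour (no multiple-hit correction), so on very short inputs
dS can legitimately exceed 1. The whole 64×64 pathway table is
cross-checked in the tests against an independent recursive enumeration
over all 3,600 ordered sense-codon pairs.

*Bootstrap standard errors* resample alignment columns (codons, for
dS/dN) with replacement, recompute the overall mean pairwise distance per
replicate, and report the standard deviation across replicates. The
default of 1,000 replicates follows standard practice for these loci; the
seed is a required argument, and identical seeds give identical results.
For a two-sequence p-distance the bootstrap SE is checked against the
analytic binomial value $\sqrt{p(1-p)/L}$.

## Threshold discrimination

Pairs are labelled same- or different-species through the taxonomy's
collapse map, so samples of named subspecies of one species are
same-species pairs. Classification against a K2P (×100) threshold uses
**strict** `<`: a pair exactly at the threshold is a negative
(different-species) call. Published descriptions say only "below" and
"greater than", which never defines equality; strictness is the documented
default and the non-strict orientation is exposed as a flag. With distances
stored at double precision, ties at the threshold essentially occur only
when users quantise, so the choice rarely moves a count — but it is pinned
by a test either way.

The 2×2 table (same/different species × positive/negative call) yields
false positive rate $n_{aB}/n_a$, false negative rate $n_{Ab}/n_A$,
sensitivity, specificity, PPV and NPV. A metric with a zero denominator is
reported as `NA` rather than raising — degenerate tables occur routinely
in small simulations. The marginal identities are property-tested on random
tables.

The ROC curve sweeps the threshold over every distinct observed distance
(smaller = positive); the trapezoid AUC equals the Mann–Whitney
$U/(n_A n_a)$ statistic with ties counted one half (oracle-tested against
brute-force pair counting), and its standard error uses the Hanley–McNeil
formula under the distribution-free assumption — the published analysis
names only the software used, and Hanley–McNeil is that software's
non-parametric default.

The gap scan reports the largest intraspecific and smallest interspecific
distance and, when the former is below the latter, the open gap interval
between them; a histogram with bin width 0.1 (×100 scale) accompanies it.
The bin width is our choice — fine enough to resolve a gap of width 1 into
ten empty bins.

## Neighbor-joining and congruence

`njTree()` implements Saitou–Nei agglomeration with the standard
Q-criterion. Two numerical choices are pinned down explicitly because they
affect reproducibility:

* **Tie-breaking** scans the Q matrix row-major and takes the first strict
  minimum, i.e. the lowest (row, column) index — repeated runs on tied
  (e.g. ultrametric) inputs give identical trees.
* **Negative branch estimates** are clamped to zero with the deficit
  transferred to the sibling edge, preserving the path length between the
  two joined nodes (the common Kuhner–Felsenstein adjustment).

On additive matrices the generating topology and branch lengths are
recovered exactly (tested against randomised 4–8-taxon cases and ape's
independent implementation).

Congruence with a ranked taxonomy is formalised through **unrooted
bipartitions**: a group's correctly grouped members are those in the
largest subset forming one entire side of some edge with no non-group
leaves, both orientations of every edge considered. Published scorings of
rooted figures translate to this semantics whenever the root lies outside
the group, and unlike rooted-clade counting the score cannot change under
re-rooting (property-tested). Groups fragmented into several pieces score
their largest pure fragment — how published analyses scored multi-fragment
groups is not stated, so the maximum-pure-subset rule is our documented
choice. Singleton groups count as correctly grouped by convention. The
*per-sample* variant scores every sample; the *species-collapsed* variant
first prunes the tree to one representative per species (the first listed,
for determinism), so five conspecific subspecies samples count once.

## The synthetic-data generator

`simulationConfig()` defines a balanced ranked taxonomy (superorders ×
orders × families × species × samples) and an evolutionary process; its
defaults are the study conditions under which the pipeline is validated:

* **2 × 2 × 2 × 3 species × 2 samples** (48 sequences, 24 species) of
  **1,200 bp** — a desk-scale analogue of a mammalian two-locus survey,
  with sequence length near the ~1.1–1.5 kb of the classic barcoding
  genes.
* `interDepth = 0.25` substitutions/site between congeneric species and
  rank factors 1.3/1.6/2.0 for family/order/superorder splits put
  interspecific K2P (×100) values in the ~20–50 range (observed mean ≈ 34),
  matching the magnitudes reported for mammalian mitochondrial loci;
  `intraDepth = 0.004` puts intraspecific values well below 1, so the
  classical 1.5/2.0/2.5 thresholds all fall inside the barcoding gap.
* `kappa = 4` is a typical mitochondrial transition/transversion rate
  ratio; `posRateMultipliers = c(0.6, 0.2, 2.2)` average 1 (so overall
  expected divergence equals the configured depth) and reproduce the
  3rd > 1st > 2nd codon-position rate ordering characteristic of coding
  genes.
* `heteroplasmyRate = 1e-5` per cell mirrors the rarity of heteroplasmic
  calls in real mitogenome surveys (a handful per thousand sequences).

Sequences evolve site-independently using the **exact K2P branch
transition probabilities** (not discrete mutation sampling), so the
expected divergence between two tips equals their additive path length
times the position-class multiplier — this is what makes parameter-recovery
tests meaningful: the estimator's target is known exactly. The root
sequence is uniform over stop-free codons of the vertebrate mitochondrial
code, so the reading frame starts stop-free (stops may still arise along
branches; dS/dN analysis skips such codons under its lenient flag).

What the generator does **not** emulate: indels (alignments are generated
gapless; gap handling is exercised through fixtures), base-composition
bias, rate variation within a position class, coalescent variation in
within-species sampling, and selection (dS/dN structure arises only through
the genetic code, not through an explicit codon model — the
codon-position multipliers are a deliberately crude surrogate that
reproduces rate orderings but not realistic dS/dN ratios). Passing tests
therefore demonstrate correctness of the estimators and scoring rules
under the assumed model, not robustness to alignment error, compositional
heterogeneity or model misspecification in real data.

## Problem sizes and determinism

The validation suite runs at sizes chosen to make every check sharp but
quick: parameter recovery uses 100 replicate two-sequence simulations of
10,002 bp at true divergence 0.2 (the estimator's relative bias there is
under 2%); the end-to-end analogue uses the default 48-sequence
configuration; oracle equivalences run over all 3,600 ordered sense-codon
pairs, ROC inputs up to 200 pairs, and 4–8-taxon additive matrices. All
randomness flows from explicit seeds: generator output, bootstrap
resampling and pipeline reports are bit-reproducible given the same
configuration and seed, and the JSON report writer is byte-stable.

## Known limitations

* Saturated K2P pairs are excluded from summaries rather than imputed;
  data sets deep enough to saturate should use model-based distances
  outside this package's scope (no gamma correction or ML distances).
* The congruence score is topological only; it ignores branch support and
  treats a group displaced by a single leaf the same as one scattered
  widely (both lose only the smaller fragments).
* dS/dN are p-distance flavoured; no Jukes–Cantor-style correction is
  applied to synonymous saturation, which is substantial at third
  positions for deep mammalian comparisons.
* `runLocusComparison()` analyses each locus independently; it does not
  test loci against each other (no paired significance test), it reports
  the per-locus statistics side by side for the user to compare.
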