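# mitoBarcode

Tools for evaluating protein-coding mitochondrial genes — classically
cytochrome *b* (cyt *b*, human mtDNA 14,747–15,887) and cytochrome oxidase
subunit I (COI, 5,904–7,445) — as DNA-barcoding markers for species
identification, and for scoring how well trees built from them recover a
ranked taxonomy.

The package is aimed at molecular ecologists, forensic scientists and
systematists who need to (i) quantify per-site conservation of a candidate
locus, (ii) measure intra- and interspecific divergence, (iii) pick and
statistically validate a distance threshold for species assignment, and
(iv) check that the locus reconstructs known taxonomic groupings.

## What it computes

**Conservation.** Per-site conservation in bits,

    Rs = 2 − H,   H = −Σ_b p_b log2 p_b   (b ∈ {A, C, G, T})

so a fully conserved site scores 2 bits (log2 4) and a maximally variable
one 0. Heteroplasmic calls (IUPAC ambiguity codes) and gaps count toward
the number of sequences but toward no base: 99 A plus one A/G call out of
100 sequences is 99% A and 0% C, G, T. Sliding windows of 101/401/601 bp
report Σ Rs / 2X, the fraction of a fully conserved window.

**Distances.** Nucleotide p-distance; the Kimura 2-parameter distance

    d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)

with P/Q the transition/transversion proportions; both partitioned by codon
position; and Nei–Gojobori synonymous and non-synonymous p-distances
(dS, dN) under the vertebrate mitochondrial code (AGA/AGG and TAA/TAG
stops, ATA = Met, TGA = Trp), with mutational-pathway averaging and
stop-codon exclusion. Standard errors come from 1,000 bootstrap replicates
over alignment columns (codons for dS/dN). Complete deletion — dropping
every column with a gap or ambiguity in any sequence — precedes distance
computation.

**Discrimination.** Pairs of samples are labelled same- or
different-species after collapsing subspecies, and classified against a
K2P (×100) threshold (strictly below = same-species call). The resulting
2×2 contingency table yields false positive/negative rates, sensitivity,
specificity, PPV and NPV; a threshold sweep yields the ROC curve, whose
trapezoid AUC equals the Mann–Whitney U statistic (ties at ½) with a
Hanley–McNeil standard error. A gap scan reports the barcoding gap between
the largest intraspecific and smallest interspecific distance.

**Phylogeny.** Neighbor-joining (Saitou–Nei) tree construction with
deterministic tie-breaking, and congruence scoring: each taxonomic group's
correctly grouped members are those in its largest pure bipartition of the
(unrooted) tree, accounted either per sample or with conspecific samples
collapsed to one representative.

**Simulation.** A generator of balanced ranked taxonomies and alignments
evolved under the exact K2P process, with codon-position rate multipliers,
a configurable barcoding gap and rare injected heteroplasmy — so the whole
pipeline can be validated against known truth.

## Worked example

Simulate a two-superorder, 24-species study (48 samples, 1,200 bp) with a
clear barcoding gap, then run the discrimination and congruence analysis:

```r
library(mitoBarcode)

sim <- simulateLocus(simulationConfig(seed = 1))
k2p <- pairwiseMatrix(sim$alignment, "k2p")
str(distanceSummary(k2p, x100 = TRUE))
#> List of 5
#>  $ mean             : num 33.8
#>  $ max              : num 46.2
#>  $ min              : num 0.0834
#>  $ nPairs           : int 1128
#>  $ saturatedExcluded: int 0

pairs <- labelPairs(k2p, sim$taxonomy)
g <- gapScan(pairs)
c(g$maxIntra, g$minInter)
#> [1]  0.6706405 19.1816067
```

Every intraspecific K2P (×100) value sits below 0.68 and every
interspecific one above 19.2, so all three classical thresholds (1.5, 2.0,
2.5) fall inside the barcoding gap and classify perfectly:

```r
thresholdMetrics(contingencyTable(pairs, 1.5))
#>      fpRate      fnRate sensitivity specificity         ppv         npv
#>           0           0           1           1           1           1
rocCurve(pairs)$auc
#> [1] 1

tree <- njTree(k2p)
congruenceAcrossRanks(tree, sim$taxonomy)
#>         rank           variant overallPercent
#> 1 superorder        per_sample            100
#> 2      order        per_sample            100
#> ...                                       100
```

The same machinery reproduces published threshold statistics from their
raw contingency cells. For a pooled mammalian cyt *b* database of 1,343
sequences at a K2P (×100) threshold of 1.5 (90 false positives, no false
negatives, 456,056 positive and 445,097 negative calls):

```r
ct <- contingencyFromCounts(naB = 90, nAb = 0, nB = 456056, nb = 445097,
                            threshold = 1.5)
round(thresholdMetrics(ct), 6)
#>      fpRate      fnRate sensitivity specificity         ppv         npv
#>    0.000202    0.000000    1.000000    0.999798    0.999803    1.000000
```

i.e. a false positive rate of 2.02×10⁻⁴ and a positive predictive value of
0.9998 — the behaviour that makes a 1.5% K2P threshold a defensible
species-assignment rule for mammals.

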