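mammal_k2p_contingency_counts.tsv

Published threshold-classification count cells for a combined mammalian
cytochrome b / COI barcode database of 1,343 mitogenome-derived sequences
(n = 901,153 pairwise K2P x100 comparisons). One row per locus and
threshold; columns are the false-positive (naB) and false-negative (nAb)
cells and the negative/positive column totals (nb, nB) of the two-by-two
contingency table. Derived quantities (false positive rate, specificity,
positive predictive value, ...) are never stored: they are recomputed by
contingencyFromCounts() + thresholdMetrics().
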