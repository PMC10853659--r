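Package: poolscan
Title: Replicated Pool-Seq Genome Scans with Local-Score Smoothing and LD Islands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-scan workflow for detecting genomic regions associated with
    a binary life-history phenotype from pooled low-coverage sequencing
    replicated across localities. Reads popoolation2-style sync allele counts,
    applies depth/individual/minor-allele-frequency site filters, computes
    per-site FST, Fisher's exact test and Cochran-Mantel-Haenszel statistics,
    smooths -log10 p-value tracks with the Lindley local-score process using
    quantile-derived penalties, and calls consensus outlier regions across
    tests and penalties. Estimates pairwise r2 from individual genotype
    likelihoods by EM over haplotype frequencies, summarizes LD in sliding
    windows, detects LD-outlier islands with a run-length/gap/IQR rule, and
    tests for long-range LD with exact Wilcoxon signed-rank tests. Includes a
    synthetic-data generator with planted divergent regions and
    founder-haplotype LD blocks for calibration and recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
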