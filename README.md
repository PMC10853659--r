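# poolscan

Genome scans for a binary life-history phenotype — consecutive versus skip
spawning in iteroparous salmonids, or any replicated two-group contrast —
from pooled, low-coverage whole-genome sequencing. The analysis substrate is
the per-site, per-pool nucleotide read-count table (popoolation2 `sync`
layout); individual-level linkage disequilibrium uses genotype likelihoods,
not genotype calls, because per-individual coverage is far below 1x.

The workflow:

1. **Site filters** — every pool ≥ 10 reads (and ≥ 3 individuals where
   individual coverage is known), global minor allele frequency ≥ 0.005
   (0.05 for LD input); multiallelic sites reduced to the top two
   nucleotides by global count.
2. **Per-site statistics** — FST ((H_T − H_S)/H_T on read frequencies,
   averaged over localities), Fisher's exact test of allele proportions
   between phenotypes (two-sided, probability-mass rule), and the
   Cochran–Mantel–Haenszel test across locality strata:
   X² = (|Σₖ aₖ − Σₖ E[aₖ]|)² / Σₖ Var[aₖ] ~ χ²₁.
3. **Local score** — Lindley smoothing hᵢ = max(0, hᵢ₋₁ + sᵢ − ξ) of the
   s = −log₁₀ p tracks, with ξ set to the 0.75/0.85/0.95/0.99 quantiles of
   the score distribution; permutation thresholds at FDR 0.05
   (Benjamini–Hochberg across chromosome maxima); excursion segments.
4. **Consensus** — regions supported by ≥ 2 ξ quantiles for *both* CMH and
   FET.
5. **LD arm** — pairwise r² by EM over haplotype frequencies from genotype
   likelihoods (within 100 kb, 1 Mb for long-range chromosomes),
   100 kb / 5 kb window means, LD-outlier islands (series of ≥ 20 window
   steps, gaps ≤ 2, mean LD > median + 2×IQR, centromere masked), and an
   ends-versus-whole Wilcoxon signed-rank test for long-range LD.
6. **Report** — consensus regions intersected with LD islands and annotated
   with nearby features.

A synthetic-data generator (replicated phenotype contrasts, planted
divergent regions, founder-haplotype LD blocks, genotype likelihoods) makes
every stage testable against planted truth. The methods vignette
(`vignettes/poolseq-genome-scan.Rmd`) documents the models, defaults, and
design choices.

## Worked example

The `analysis/` directory is a numbered workflow over the package. It
simulates a two-locality, two-phenotype design on two chromosomes — one
planted 200 kb divergent region (Δp = 0.4) inside a 400 kb LD island on
chr1, and a high-LD centromere-like region on chr2 that must be masked, not
reported — then runs the full scan:

```sh
Rscript analysis/01_simulate.R     # sync + Beagle GLs + truth BEDs -> results/sim/
Rscript analysis/02_site_stats.R   # filters, FST/FET/CMH, window FST -> results/scan/
Rscript analysis/03_local_score.R  # Lindley scans, thresholds, consensus
Rscript analysis/04_ld_scan.R      # EM r2, LD windows, islands, long-range test
Rscript analysis/05_report.R       # intersection with islands, truth check
```

Output of the final steps (abridged):

```
cmh : xi = 0.91 1.26 2.24 8.06 -> 4 segments
fet : xi = 0.79 1.16 2.18 9.79 -> 6 segments
consensus regions (>= 2 xi for both CMH and FET):
  chrom   start     end     support
1  chr1 2492457 2728573 cmh:4;fet:4

LD islands after masking the centromere:
  chrom   start     end     score n_steps
1  chr1 2340000 2865000 0.2346342      85

long-range groups: 4 ; significant at 0.05: 0

planted divergent region: chr1 2500000 - 2700000
consensus regions with island overlap:
  chrom   start     end     support            ld_island
1  chr1 2492457 2728573 cmh:4;fet:4 chr1:2340000-2865000
-> the planted region is recovered by the consensus scan
```

Reading this: the consensus scan recovers the planted chr1 interval (all
four ξ quantiles of both tests support it, `cmh:4;fet:4`), the island
caller finds the planted LD block while the masked chr2 centromere is not
reported, the recovered region is flagged as lying inside the island, and
the ends-versus-whole test finds no long-range LD beyond the island —
contiguous high LD, not linkage between distant regions.

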