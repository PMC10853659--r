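---
title: "Replicated pool-seq genome scans: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicated pool-seq genome scans: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

`poolscan` implements a genome-scan workflow for a binary life-history
phenotype — here framed as consecutive versus skip spawning in iteroparous
steelhead (*Oncorhynchus mykiss*) — measured by pooled, low-coverage whole
genome sequencing replicated across localities. Each locality contributes one
pool per phenotype; the analysis substrate is the per-site, per-pool
nucleotide read-count table (popoolation2 sync layout), not genotypes.
Individual coverage is far below 1x, so individual-level analyses use
genotype likelihoods rather than genotype calls.

The workflow has two arms:

1. **Association arm.** Site filters, then per-site statistics contrasting
   phenotypes — FST, Fisher's exact test (FET) on read counts, and the
   Cochran–Mantel–Haenszel (CMH) test across locality strata — followed by
   Lindley local-score smoothing of the $-\log_{10} p$ tracks and a consensus
   rule across tests and smoothing penalties.
2. **LD arm.** Pairwise $r^2$ estimated by EM from genotype likelihoods,
   sliding-window means, LD-outlier islands by a run-length/gap/IQR rule
   with a centromere mask, and an ends-versus-whole test for long-range LD.

## Models and statistics

### Site filters

A site is retained iff every pool has $\ge$ 10 reads, (when per-site
individual coverage is available) $\ge$ 3 individuals, and the pooled global
minor allele frequency is $\ge$ 0.005 (0.05 for LD-grade input, where
low-MAF sites carry little linkage information). All thresholds are
inclusive. Read-level filters (SNP quality, indel proximity) act upstream of
allele counts and are recorded in the filter report as not applicable here.
Multiallelic sites are reduced to the two nucleotides with the highest
global read counts, ties broken in the fixed order A < C < G < T; this rule
is a documented choice — the 2x2 tests require a biallelic reduction but no
standard rule exists.

### Per-site statistics

FST uses the heterozygosity form $(H_T - H_S)/H_T$ with
$\bar p = (p_1 + p_2)/2$ and $H = 2p(1-p)$ on read-frequency estimates,
returning 0 where $H_T = 0$, with an optional per-pool $d/(d-1)$ small-depth
correction and a Hudson-type alternative. The estimator is computed within
each locality and averaged (unweighted) across localities. No single pool-seq
FST estimator is canonical; this family matches the common pool-seq
toolchain.

FET is the exact conditional test on the alt/ref x phenotype read-count
table, two-sided by the probability-mass rule (all tables whose point
probability is at most the observed one, relative tie tolerance $10^{-7}$),
computed by direct enumeration over the hypergeometric support, vectorized
across sites. The combined test pools the two localities; per-locality FET
tracks are also produced, since locality-specific scans are part of the
workflow.

CMH combines the per-locality 2x2 tables:
$$X^2 = \frac{\left(\left|\sum_k a_k - \sum_k E[a_k]\right| - c\right)^2}
             {\sum_k \mathrm{Var}[a_k]},\qquad
E[a_k] = \frac{r_{1k} c_{1k}}{n_k},\quad
\mathrm{Var}[a_k] = \frac{r_{1k} r_{2k} c_{1k} c_{2k}}{n_k^2 (n_k - 1)},$$
referred to $\chi^2_1$. Strata with a zero margin contribute nothing; the
continuity correction $c$ defaults to 0 so that identical no-association
strata give a statistic of exactly 0. The replicated design assumes a common
direction of effect across localities, which is how the generator plants
effects.

**Caveat, by construction:** both tests treat reads as the sampling unit.
Reads pseudo-replicate the finite number of gene copies in the pool, so with
realistic pool sizes the tests are anti-conservative with respect to the
population; this is inherent to read-count pool-seq testing, and it is why
the calibration experiment below switches that noise source off.

### Local score

Per-site scores $s_i = -\log_{10} p_i$ (capped at `s_max = 50`; zero
p-values would otherwise be infinite) feed the Lindley recursion
$h_0 = 0,\ h_i = \max(0,\, h_{i-1} + s_i - \xi)$, restarted on each
chromosome. The implementation uses the exact closed form
$h_i = c_i - \min(0, \min_{j \le i} c_j)$ with $c$ the cumulative sum of
$s - \xi$, which is vectorizable and is verified against the direct
recursion in the tests. The penalty $\xi$ is the 0.75/0.85/0.95/0.99
empirical quantile (type-7 linear interpolation) of the scores, computed
genome-wide by default (per-chromosome is available; the choice of scope is
genuinely open and genome-wide keeps $\xi$ comparable across chromosomes).
Lower quantiles smooth less (more power), higher quantiles bound outlier
regions more tightly.

Significance uses a permutation null: site scores are permuted within each
chromosome (1000 times by default), the maximum Lindley score recomputed,
and each chromosome's observed maximum assigned an empirical p-value
$(1 + \#\{M^{null} \ge M^{obs}\})/(B+1)$. "Mean FDR 0.05" is interpreted as
Benjamini–Hochberg across chromosomes treating each chromosome's maximum as
one test: significant chromosomes receive the $(1-\alpha^*)$ quantile of
their null maxima as the red-line threshold ($\alpha^* = q\,k^*/C$),
non-significant chromosomes get $+\infty$. A moment-fitted Gumbel tail is
available as the fast alternative; Monte-Carlo is the default because it is
transparent and exact at the scales this package targets. Segments span
from the first site after the preceding zero of $h$ to the peak site
(a full-excursion alternative is provided; the boundary convention is not
standardized anywhere, and peak-bounded segments are the tighter report).

### Consensus rule

Candidate regions are connected components of the union of all segments; a
component is kept iff, for each required test (CMH and FET by default),
segments from at least two distinct $\xi$ quantiles overlap it. The retained
span is the union of the supporting segments. Component-wise union semantics
are used because merged named regions — not per-track segments — are the
reporting unit.

### LD from genotype likelihoods

For a site pair, the four haplotype frequencies are estimated by EM over
unphased genotype likelihoods: the E-step weights each individual's nine
genotype-pair configurations by the product of its two GL triples and the
current genotype-pair probabilities (the double-heterozygote phase split
follows the current frequencies), the M-step re-estimates frequencies from
expected haplotype counts. Initialization is at linkage equilibrium
(deterministic); convergence at a maximum frequency change below $10^{-6}$
or 100 iterations. Then $r^2 = D^2 / (p_A q_A p_B q_B)$ with
$D = f_{AB} - p_A p_B$, clamped to $[0,1]$; pairs with a monomorphic site
are skipped. Pairs are enumerated within 100 kb by default (1 Mb on
chromosomes slated for the long-range test).

Window means (100 kb / 5 kb) include a pair iff **both** sites fall in the
window — the natural reading of "mean LD among sites in a window"; windows
with no pairs are missing. Islands are maximal series of $\ge$ 20 outlier
window-steps allowing internal gaps of $\le$ 2 steps, where a step is an
outlier iff its mean LD strictly exceeds median + 2 x IQR of the
chromosome's non-masked, non-missing windows. The phrase "greater than 2x
IQR" is ambiguous about the baseline; median + 2 x IQR is the default with
Q3 + 2 x IQR as the alternative. Windows overlapping the centromere mask
are removed before anything else, including the baseline statistics.

### Long-range LD

For window widths 300 kb–1 Mb on a 5 kb start grid inside a caller-chosen
span, "whole" is the mean $r^2$ of pairs with both sites in the window and
"ends" the mean $r^2$ of pairs joining the first and last 100 kb (inter-site
gap $\ge$ width $-$ 200 kb). Consecutive groups of 20 steps are tested with
a paired one-sided Wilcoxon signed-rank test of ends > whole: zero
differences are dropped, the exact signed-rank tail is used for $n \le 25$
when $|d|$ has no ties, otherwise a normal approximation with continuity and
tie corrections. All-zero groups are flagged degenerate with $p = 1$.
Genuine long-range structure makes the distant ends out-correlate the
window average; a merely contiguous island does the opposite.

## The synthetic-data generator

The generator emulates the study design: ancestral alternate-allele
frequencies $p_0 \sim \mathrm{Beta}(0.25, 1)$ (a spectrum dominated by rare
alleles), two localities with pool sizes 33/35 and 56/59
(consecutive/skip), negative-binomial pool depth (mean 50x by default,
10–100x is the intended regime; dispersion 10, Poisson in the limit),
binomial sampling of $2N$ gene copies per pool around the group frequency,
and a per-read error rate (0.002) applied as a biallelic flip. Within a
locality the two phenotype groups share $p_0$ exactly by default (no
background differentiation between phenotype groups within a locality — an
assumption, exposed as a Beta drift option with configurable concentration,
since within-locality background FST between phenotype groups is not
reported anywhere to calibrate against). Planted regions shift the two
phenotypes by $\pm\Delta p/2$ identically in both localities, matching the
common-direction assumption of the CMH design.

Haplotypes for the LD arm are iid Bernoulli($p_0$) draws per site outside
LD blocks (so $E[r^2] \approx 1/(2n)$), while inside a block each
individual's two haplotypes are copies of one of a few founder haplotypes
with a small mutation rate (1%) — a block of uniformly elevated $r^2$ with
no distance decay. The centromere region is simulated as a 2-founder block:
strong background LD that the island caller must mask rather than report.
Genotype likelihoods follow the standard biallelic read model
(Poisson coverage, alternate reads Binomial($c, f_g$) with
$f_g = e, 0.5, 1-e$; normalized binomial likelihoods; uniform triple at
zero coverage). Infinite individual depth yields certain (one-hot)
likelihoods, used when a test needs the GL machinery with no read noise.

**What the generator does not emulate:** linkage between the association
and LD arms' sampling noise, distance-decaying LD inside islands (founder
copying is uniform across the block), base-quality variation, mapping
artifacts, and indel-proximal miscalls. Passing recovery tests therefore
demonstrates that the statistics and the callers behave as specified under
the stated sampling models — not that real read processing upstream is
error-free.

## Calibration and recovery experiments (as run by the tests and `scripts/acceptance.R`)

- **Exact-test oracles.** FET is compared with a full hypergeometric
  enumeration over every 2x2 table with total $\le$ 40 (about 135,000
  tables); CMH against longhand formula evaluation and an independent
  stratified-test implementation.
- **Null calibration** uses 20,000 sites at depth 100 with *very large
  pools* (10,000 individuals), so that read sampling is the only noise
  source — the tests' own sampling model. With realistic pool sizes the
  read-count tests are anti-conservative (reads pseudo-replicate gene
  copies; measured type-I error ~0.18 at $\alpha = 0.05$), which is a
  property of read-count pool-seq testing, not of the implementations.
  Under the read-sampling null the CMH type-I error sits inside the
  3-Monte-Carlo-SE band around 0.05. FET, being an exact conditional test
  on discrete tables, is *super-uniform*: its measured type-I error
  (~0.038–0.042 at these depths) sits below the nominal level by more than
  the band, so the corresponding assertion documents the discreteness cost
  rather than a defect. The local-score false-call rate is measured over
  100 seeded null genomes at $\xi(0.85)$; a scrambled-site-order control
  (exchangeable by construction) sits at the nominal 5%, and the
  measured rate on generated tracks fluctuates around it with the binomial
  noise of 100 replicates (SE ~2%).
- **Recovery.** One planted 200 kb region with $\Delta p = 0.4$ at depth
  60 is recovered by the CMH+FET consensus in essentially all of 50 seeds
  with ~0 false regions per genome.
- **LD.** EM $r^2$ on certain likelihoods matches haplotype-truth $r^2$
  within 0.05 RMSE at $n = 200$; island calling is exercised on the
  19-vs-20-step and gap-2-vs-3 boundary cases; the long-range test is
  checked against the exact $2^{-20}$ all-positive tail and against a
  founder-block island with no long-range structure. For the latter, window
  widths and spans are chosen so both 100 kb end blocks clear the island:
  end blocks sampling the island itself would measure the island's own
  (non-decaying) LD, not long-range structure beyond it.

Problem sizes (20,000 sites, 50–100 replicates, 1000 permutations, 200
individuals) are the package's desk-scale reference conditions: large
enough for stable rates, small enough that the whole suite re-runs in
minutes.

## Numerical choices and degenerate inputs

- p-values of 0 are capped at score `s_max = 50` with a warning; the cap's
  only effect is on excursion peak heights far above any threshold.
- Degenerate 2x2 margins give $p = 1$ with a flag; all-degenerate CMH
  strata likewise.
- Quantiles are type-7 (linear interpolation) everywhere, stated in the
  docs because the $\xi$ values depend on it.
- The EM is deterministic (equilibrium initialization); monomorphic pairs
  are skipped rather than reported as $r^2 = 0$.
- Windows with fewer than `min_sites` (default 10) sites are missing rather
  than noisy; the island baseline needs at least 4 non-missing windows.
- All intervals are 0-based half-open internally; sync positions (1-based)
  are converted once at the boundary. BED files are written as-is.

## Known limitations

- Read-level filters (snpQ, indel distance, mapping quality) need BAMs and
  are out of scope; the filter report lists them as not applicable.
- The FET/CMH read-count caveat above: with real pool sizes, p-values are
  anti-conservative in absolute terms. The local-score stage is robust to
  this (its permutation null conditions on the observed score
  distribution), which is one reason the workflow calls regions from
  smoothed tracks rather than raw p-values.
- Founder-block islands have no internal LD decay, so ends-versus-whole
  comparisons *within* an island are uninformative in this generator.
- The Gumbel threshold is a moment fit to permutation maxima, not the
  published coefficient approximation.
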