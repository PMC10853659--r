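#!/usr/bin/env Rscript
# Build the synthetic study: two localities x two spawning phenotypes of
# pooled counts on two chromosomes, with one planted divergent region that
# sits inside a founder-haplotype LD island on chr1, and a high-LD
# centromere-like region on chr2 that the island caller must mask. Writes
# the sync file, Beagle-layout genotype likelihoods, truth BEDs and a
# manifest under results/sim/.

library(poolscan)

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(
  seed = 20260923L,
  n_chromosomes = 2L,
  chrom_length = 6e6,
  n_sites = 6000L,
  depth_mean = 60,
  planted_regions = data.frame(chrom = "chr1", start = 2.5e6, end = 2.7e6,
                               delta_p = 0.4),
  ld_blocks = data.frame(chrom = "chr1", start = 2.4e6, end = 2.8e6,
                         n_founders = 4L),
  centromere = data.frame(chrom = "chr2", start = 1e6, end = 1.6e6),
  n_individuals = 100L,
  ind_depth_mean = Inf)

freqs <- simulate_site_frequencies(cfg)
counts <- simulate_pool_counts(freqs, cfg)
write_sync(counts, file.path(out, "pools.sync"))

# GL input for the LD stage: thin to ~1 site / 8 kb to keep the pairwise
# stage small, as one would subset a genome-wide GL file per chromosome
glsim <- simulate_gl_matrix(cfg, freqs)
keep <- seq(1, length(glsim$gl$pos), by = 8)
gl <- gl_matrix(glsim$gl$chrom[keep], glsim$gl$pos[keep],
                glsim$gl$allele1[keep], glsim$gl$allele2[keep],
                glsim$gl$gl[keep, , , drop = FALSE])
write_beagle(gl, file.path(out, "individuals.beagle"))

write_bed(freqs$truth$divergent_regions, file.path(out, "truth_divergent.bed"))
write_bed(freqs$truth$ld_islands, file.path(out, "truth_ld_islands.bed"))
write_bed(freqs$truth$centromere, file.path(out, "centromere_mask.bed"))
write.table(counts$pools, file.path(out, "pools.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

manifest <- data.frame(
  key = c("seed", "n_chromosomes", "chrom_length", "n_sites_per_chrom",
          "depth_mean", "planted_delta_p", "n_individuals_gl"),
  value = c(cfg$seed, cfg$n_chromosomes, cfg$chrom_length, cfg$n_sites,
            cfg$depth_mean, 0.4, cfg$n_individuals))
write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("simulated", length(counts$pos), "sites in", nrow(counts$pools),
    "pools;", length(gl$pos), "GL sites;",
    "truth: 1 divergent region, 1 LD island, 1 masked centromere\n")
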