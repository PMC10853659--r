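#!/usr/bin/env Rscript
# Site filtering and per-site statistics: reads the simulated sync file,
# applies the depth >= 10 / global MAF >= 0.005 filters, computes per-site
# FST (averaged over localities), FET (combined and per locality) and CMH
# across the two locality strata, and the 100 kb / 5 kb sliding-window FST.

library(poolscan)

sim <- "results/sim"
out <- "results/scan"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

pools <- read.table(file.path(sim, "pools.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
counts <- read_sync(file.path(sim, "pools.sync"), pools = pools)
bc <- biallelic_reduce(counts)
flt <- filter_sites(bc, filter_params())
cat("filter:", flt$sites_in, "sites in,", flt$sites_retained, "retained\n")
print(flt$report)
bc <- poolscan:::subset_biallelic(bc, flt$keep)

stats <- site_stats(bc)
write.table(stats, file.path(out, "site_stats.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

fst_win <- sliding_window_mean(stats$chrom, stats$pos, stats$fst,
                               window = 1e5, step = 5e3, min_sites = 10)
write.table(fst_win, file.path(out, "fst_windows.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("top FST windows:\n")
print(head(fst_win[order(-fst_win$mean), ], 5))
cat("smallest CMH p:", format(min(stats$cmh_p), digits = 3),
    "at", stats$chrom[which.min(stats$cmh_p)],
    stats$pos[which.min(stats$cmh_p)], "\n")
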