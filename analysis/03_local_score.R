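#!/usr/bin/env Rscript
# Local-score smoothing of the CMH and FET p-value tracks across the four
# xi quantiles (0.75/0.85/0.95/0.99 of the -log10 p distribution), with
# permutation-derived significance thresholds at FDR 0.05, followed by the
# consensus rule: a region must be supported by two or more xi values for
# both CMH and FET.

library(poolscan)

out <- "results/scan"
stats <- read.table(file.path(out, "site_stats.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)

lp <- local_score_params(n_permutations = 1000L, seed = 20260923L)
segs <- list()
for (tn in c("cmh", "fet", "fet_A", "fet_B")) {
  col <- c(cmh = "cmh_p", fet = "fet_p", fet_A = "fet_p_A",
           fet_B = "fet_p_B")[[tn]]
  sc <- local_score_scan(stats$chrom, stats$pos, stats[[col]], lp, tn)
  segs[[tn]] <- sc$segments
  cat(tn, ": xi =", paste(round(sc$xi, 2), collapse = " "),
      "->", nrow(sc$segments), "segments\n")
  write.table(sc$thresholds, file.path(out, paste0("thresholds_", tn, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
segments <- do.call(rbind, c(segs, list(make.row.names = FALSE)))
write.table(as.data.frame(segments), file.path(out, "segments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

consensus <- consensus_regions(segments, consensus_rule())
write.table(as.data.frame(consensus), file.path(out, "consensus.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nconsensus regions (>= 2 xi for both CMH and FET):\n")
print(as.data.frame(consensus)[, c("chrom", "start", "end", "support")])
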