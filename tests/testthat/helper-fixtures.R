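# Shared fixture builders; everything is generated in code at test time.

# Null study design with very large pools: switches off gene-copy resampling
# so pooled read counts follow the read-sampling model the 2x2 tests assume.
null_config <- function(seed, n_sites = 5000, depth_mean = 100) {
  sim_config(seed = seed, n_sites = n_sites, chrom_length = 1e7,
             depth_mean = depth_mean,
             groups = data.frame(
               locality = c("A", "A", "B", "B"),
               phenotype = c("consecutive", "skip", "consecutive", "skip"),
               n_individuals = rep(10000L, 4)),
             error_rate = 0)
}

# Filtered biallelic counts from a config.
sim_filtered_counts <- function(cfg, params = filter_params()) {
  fr <- simulate_site_frequencies(cfg)
  pc <- simulate_pool_counts(fr, cfg)
  bc <- biallelic_reduce(pc)
  keep <- filter_sites(bc, params)$keep
  poolscan:::subset_biallelic(bc, keep)
}

# Per-locality 2x2 count matrices (alt/ref x phenotype), strata = localities.
strata_tables <- function(bc, phen = c("consecutive", "skip")) {
  pools <- bc$pools
  locs <- unique(pools$locality)
  n <- length(bc$pos)
  A <- B <- C <- D <- matrix(0, n, length(locs))
  for (j in seq_along(locs)) {
    s1 <- which(pools$locality == locs[j] & pools$phenotype == phen[1])
    s2 <- which(pools$locality == locs[j] & pools$phenotype == phen[2])
    A[, j] <- bc$alt[, s1]
    B[, j] <- bc$alt[, s2]
    C[, j] <- bc$tot[, s1] - A[, j]
    D[, j] <- bc$tot[, s2] - B[, j]
  }
  list(A = A, B = B, C = C, D = D)
}

# Certain (one-hot) genotype likelihood triples for a genotype vector.
one_hot_gl <- function(g) {
  m <- matrix(0, length(g), 3)
  m[cbind(seq_along(g), g + 1)] <- 1
  m
}

# Reference EM for haplotype frequencies from hard genotype pairs; the
# independent oracle for em_r2 on certain likelihoods.
hard_genotype_em <- function(g1, g2, tol = 1e-10, max_iter = 500) {
  n <- length(g1)
  tab <- matrix(0, 3, 3)
  for (i in seq_len(n)) tab[g1[i] + 1, g2[i] + 1] <- tab[g1[i] + 1, g2[i] + 1] + 1
  p1 <- mean(g1) / 2; p2 <- mean(g2) / 2
  f <- c(f00 = (1 - p1) * (1 - p2), f01 = (1 - p1) * p2,
         f10 = p1 * (1 - p2), f11 = p1 * p2)
  f <- pmax(f, 1e-9); f <- f / sum(f)
  for (it in seq_len(max_iter)) {
    # unambiguous contributions: genotype pair (a,b) with a or b not 1
    # splits into known haplotype counts; double het splits by phase odds
    cnt <- c(0, 0, 0, 0)
    for (a in 0:2) for (b in 0:2) {
      nc <- tab[a + 1, b + 1]
      if (nc == 0) next
      if (a == 1 && b == 1) {
        # phases: (01,10) prob f01*f10 vs (00,11) prob f00*f11
        w_cis <- f[1] * f[4]; w_trans <- f[2] * f[3]
        tot <- w_cis + w_trans
        pc <- if (tot > 0) w_cis / tot else 0.5
        cnt <- cnt + nc * c(pc, 1 - pc, 1 - pc, pc)
      } else {
        # haplotype dosages are determined: site1 alleles a split as
        # floor/ceil over the two haplotypes only ambiguous when a==1
        h1a <- if (a == 2) c(1, 1) else if (a == 0) c(0, 0) else c(0, 1)
        h2b <- if (b == 2) c(1, 1) else if (b == 0) c(0, 0) else c(0, 1)
        if (a != 1 && b != 1) {
          for (k in 1:2) {
            hap <- 2 * h1a[k] + h2b[k] + 1
            cnt[hap] <- cnt[hap] + nc
          }
        } else if (a == 1) {
          # one haplotype carries alt at site1, both share site2 allele b/2
          al2 <- b / 2
          cnt[2 * 1 + al2 + 1] <- cnt[2 * 1 + al2 + 1] + nc
          cnt[2 * 0 + al2 + 1] <- cnt[2 * 0 + al2 + 1] + nc
        } else {
          al1 <- a / 2
          cnt[2 * al1 + 1 + 1] <- cnt[2 * al1 + 1 + 1] + nc
          cnt[2 * al1 + 0 + 1] <- cnt[2 * al1 + 0 + 1] + nc
        }
      }
    }
    fn <- cnt / (2 * n)
    if (max(abs(fn - f)) < tol) { f <- fn; break }
    f <- fn
  }
  pA <- f[3] + f[4]; pB <- f[2] + f[4]
  D <- f[4] - pA * pB
  den <- pA * (1 - pA) * pB * (1 - pB)
  list(freqs = unname(f), r2 = if (den > 0) D^2 / den else NA_real_)
}

# r2 from true haplotypes (allelic correlation squared).
hap_r2 <- function(h_i, h_j) {
  if (sd(h_i) == 0 || sd(h_j) == 0) return(NA_real_)
  cor(h_i, h_j)^2
}
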