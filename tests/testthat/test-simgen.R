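test_that("null frequencies are shared within locality; planted shifts are exact", {
  cfg <- sim_config(seed = 5, n_sites = 500, chrom_length = 1e6)
  fr <- simulate_site_frequencies(cfg)
  expect_equal(fr$freq[, "A.consecutive"], fr$freq[, "A.skip"])
  expect_equal(fr$freq[, "B.consecutive"], fr$freq[, "B.skip"])

  cfg2 <- sim_config(seed = 5, n_sites = 500, chrom_length = 1e6,
                     planted_regions = data.frame(chrom = "chr1", start = 0,
                                                  end = 1e6, delta_p = 0.4))
  fr2 <- simulate_site_frequencies(cfg2)
  # phenotype frequencies are clamp(p0 +/- 0.2) in both localities
  expect_equal(fr2$freq[, "A.consecutive"], pmin(1, fr2$p0 + 0.2))
  expect_equal(fr2$freq[, "A.skip"], pmax(0, fr2$p0 - 0.2))
  expect_equal(fr2$freq[, "A.consecutive"], fr2$freq[, "B.consecutive"])
  # p0 = 0.5 -> 0.7 / 0.3 exactly
  mid <- which(abs(fr2$p0 - 0.5) < 0.2)[1]
  expect_equal(as.numeric(fr2$freq[mid, "A.consecutive"]), fr2$p0[mid] + 0.2)
  expect_equal(as.numeric(fr2$freq[mid, "B.skip"]), fr2$p0[mid] - 0.2)
})

test_that("generator output is a pure function of the config seed", {
  cfg <- sim_config(seed = 77, n_sites = 300, chrom_length = 1e6,
                    ld_blocks = data.frame(chrom = "chr1", start = 1e5,
                                           end = 3e5, n_founders = 4))
  a1 <- simulate_site_frequencies(cfg)
  # interleave other RNG use to show independence from ambient state
  runif(10)
  a2 <- simulate_site_frequencies(cfg)
  expect_identical(a1, a2)
  expect_identical(simulate_pool_counts(a1, cfg), simulate_pool_counts(a2, cfg))
  h1 <- simulate_haplotypes_with_ld(cfg, a1)
  h2 <- simulate_haplotypes_with_ld(cfg, a2)
  expect_identical(h1, h2)
})

test_that("degenerate frequencies give degenerate counts; depth has the configured mean", {
  cfg <- sim_config(seed = 8, n_sites = 10000, chrom_length = 1e7,
                    depth_mean = 50, error_rate = 0)
  fr <- simulate_site_frequencies(cfg)
  fr$freq[, ] <- 0
  pc <- simulate_pool_counts(fr, cfg)
  bc <- biallelic_reduce(pc)
  expect_true(all(bc$alt == 0))
  fr$freq[, ] <- 1
  pc1 <- simulate_pool_counts(fr, cfg)
  # all reads carry the alternate allele at every depth
  nuc_tot <- apply(pc1$counts, 1:2, sum)
  alt_max <- apply(pc1$counts, 1:2, max)
  expect_equal(nuc_tot, alt_max)
  # law of large numbers: observed mean depth within 2% of 50
  expect_lt(abs(mean(nuc_tot) - 50) / 50, 0.02)
})

test_that("pooled frequency estimate recovers the pool frequency at high depth", {
  cfg <- sim_config(seed = 12, n_sites = 2000, chrom_length = 1e6,
                    depth_mean = 1000, depth_dispersion = Inf, error_rate = 0,
                    groups = data.frame(locality = "A",
                                        phenotype = c("consecutive", "skip"),
                                        n_individuals = c(50000L, 50000L)))
  fr <- simulate_site_frequencies(cfg)
  fr$freq[, ] <- 0.3
  pc <- simulate_pool_counts(fr, cfg)
  bc <- biallelic_reduce(pc)
  est <- pooled_freq(bc$alt[, 1], bc$tot[, 1])
  est <- ifelse(est > 0.5, 1 - est, est)  # allele1 is the global major
  # binomial standard error at depth 1000 is ~0.015, so 0.05 bounds the
  # per-site error for essentially every site
  expect_lt(mean(abs(est - 0.3)), 0.05)
  expect_lt(unname(quantile(abs(est - 0.3), 0.99)), 0.05)
})

test_that("two founders with no mutation give |r| = 1 within a block", {
  cfg <- sim_config(seed = 21, n_sites = 60, chrom_length = 1e5,
                    n_individuals = 80, mutation_rate = 0,
                    maf_alpha = 1, maf_beta = 1,
                    ld_blocks = data.frame(chrom = "chr1", start = 0,
                                           end = 1e5, n_founders = 2))
  h <- simulate_haplotypes_with_ld(cfg)
  haps <- cbind(h$hap1, h$hap2)
  poly <- which(apply(haps, 1, sd) > 0)
  expect_gt(length(poly), 5)
  cc <- abs(cor(t(haps[poly, ])))
  expect_equal(unname(cc), matrix(1, length(poly), length(poly)),
               tolerance = 1e-12)
})

test_that("sites in different blocks are nearly independent (r2 ~ 1/2n)", {
  cfg <- sim_config(seed = 22, n_sites = 200, chrom_length = 1e6,
                    n_individuals = 200, maf_alpha = 1, maf_beta = 1,
                    ld_blocks = data.frame(chrom = "chr1",
                                           start = c(0, 5e5),
                                           end = c(2e5, 7e5),
                                           n_founders = c(3, 3)))
  h <- simulate_haplotypes_with_ld(cfg)
  haps <- cbind(h$hap1, h$hap2)
  in1 <- h$sites$pos - 1 < 2e5
  in2 <- h$sites$pos - 1 >= 5e5 & h$sites$pos - 1 < 7e5
  poly <- apply(haps, 1, sd) > 0
  r2 <- outer(which(in1 & poly), which(in2 & poly),
              Vectorize(function(i, j) cor(haps[i, ], haps[j, ])^2))
  expect_lt(mean(r2), 0.05)
})

test_that("genotype likelihoods follow the biallelic read model", {
  g <- matrix(c(0L, 1L, 2L), 3, 1)
  # zero coverage -> uniform triple
  gl0 <- genotype_likelihoods_from_genotypes(g, 1e-9, 0.01, seed = 2)
  expect_equal(unname(gl0[1, 1, ]), rep(1 / 3, 3))
  # 30 alternate reads out of 30 -> homozygous alternate dominates
  gl <- array(0, dim = c(1, 1, 3))
  for (gg in 0:2) gl[1, 1, gg + 1] <- dbinom(30, 30, c(0.01, 0.5, 0.99)[gg + 1])
  gl <- gl / sum(gl)
  expect_equal(which.max(gl[1, 1, ]), 3L)
  # simulated triples are normalized
  gsim <- matrix(sample(0:2, 400, replace = TRUE), 40, 10)
  glx <- genotype_likelihoods_from_genotypes(gsim, 3, 0.02, seed = 7)
  expect_lt(max(abs(glx[, , 1] + glx[, , 2] + glx[, , 3] - 1)), 1e-12)
  # deep coverage recovers the genotype
  gld <- genotype_likelihoods_from_genotypes(gsim, 60, 0.01, seed = 8)
  called <- apply(gld, 1:2, which.max) - 1L
  expect_gt(mean(called == gsim), 0.999)
})

test_that("null FET p-values are uniform or super-uniform", {
  bc <- sim_filtered_counts(null_config(seed = 303, n_sites = 5000),
                            filter_params(min_global_maf = 0.05))
  tb <- strata_tables(bc)
  p <- fisher_exact_2x2(rowSums(tb$A), rowSums(tb$B),
                        rowSums(tb$C), rowSums(tb$D))$p
  # one-sided KS: the ECDF must not exceed the uniform (no excess small p)
  ks <- suppressWarnings(ks.test(p, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})
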