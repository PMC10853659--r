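make_bc <- function(alt, tot) {
  n <- nrow(alt)
  structure(list(chrom = rep("chr1", n), pos = seq_len(n) * 10L,
                 allele1 = rep("A", n), allele2 = rep("C", n),
                 alt = alt, tot = tot,
                 pools = pool_info(paste0("p", seq_len(ncol(alt))),
                                   rep(c("A", "B"), each = 2),
                                   rep(c("consecutive", "skip"), 2),
                                   rep(30L, ncol(alt)))),
            class = "biallelic_counts")
}

test_that("site filters apply inclusive thresholds with first-rule attribution", {
  tot <- rbind(c(9, 50, 50, 50),    # depth fail (one pool at 9 < 10)
               c(50, 50, 50, 50),   # MAF fail: 0.004 < 0.005
               c(10, 10, 10, 10),   # exact boundary: retained
               c(1000, 1000, 1000, 1000))
  alt <- rbind(c(4, 20, 20, 20),
               c(0, 0, 0, 0),       # global MAF 0 < 0.005
               c(1, 0, 0, 1),       # global MAF = 2/40 = 0.05
               c(2, 2, 0, 0))       # global MAF 4/4000 = 0.001
  res <- filter_sites(make_bc(alt, tot), filter_params())
  expect_equal(res$keep, c(FALSE, FALSE, TRUE, FALSE))
  rep_ <- res$report
  expect_equal(rep_$removed[rep_$rule == "min_reads_per_sample"], 1)
  expect_equal(rep_$removed[rep_$rule == "min_global_maf"], 2)
  expect_equal(res$sites_in,
               res$sites_retained + sum(rep_$removed, na.rm = TRUE))
  # exact MAF boundary 0.005 is retained (site with 1/200)
  tot2 <- matrix(50, 1, 4); alt2 <- matrix(c(1, 0, 0, 0), 1)
  expect_true(filter_sites(make_bc(alt2, tot2))$keep)
  # individuals rule only with coverage supplied
  ind <- matrix(c(2, 5, 5, 5), 1)
  expect_false(filter_sites(make_bc(alt2, tot2), filter_params(),
                            individuals = ind)$keep)
})

test_that("pooled_freq is alt/total with NA at zero depth", {
  expect_equal(pooled_freq(30, 100), 0.3)
  expect_equal(pooled_freq(0, 50), 0)
  expect_equal(pooled_freq(50, 50), 1)
  expect_true(is.na(pooled_freq(0, 0)))
})

test_that("site_fst matches hand arithmetic and is symmetric and relabel-invariant", {
  expect_equal(site_fst(0.5, 0.5), 0)
  expect_equal(site_fst(1, 0), 1)
  expect_equal(site_fst(0.8, 0.2), (0.5 - 0.32) / 0.5)
  set.seed(4)
  p1 <- runif(200); p2 <- runif(200)
  expect_equal(site_fst(p1, p2), site_fst(p2, p1))
  expect_equal(site_fst(p1, p2), site_fst(1 - p1, 1 - p2))
  expect_true(all(site_fst(p1, p2) >= 0 & site_fst(p1, p2) <= 1))
  # depth correction shrinks the estimate at small depth
  expect_lt(site_fst(0.8, 0.2, 10, 10, depth_correction = TRUE),
            site_fst(0.8, 0.2))
})

test_that("FET matches known exact values and flags degenerate margins", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p, 1)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10)$p, 2 / choose(20, 10),
               tolerance = 1e-12)
  res <- fisher_exact_2x2(0, 0, 3, 7)
  expect_equal(res$p, 1)
  expect_true(res$degenerate)
})

test_that("FET agrees with fisher.test across random tables", {
  set.seed(99)
  n <- 300
  a <- rpois(n, 6); b <- rpois(n, 6); c <- rpois(n, 8); d <- rpois(n, 8)
  ours <- fisher_exact_2x2(a, b, c, d)
  ref <- vapply(seq_len(n), function(i)
    fisher.test(matrix(c(a[i], c[i], b[i], d[i]), 2))$p.value, numeric(1))
  expect_equal(ours$p, ref, tolerance = 1e-10)
})

test_that("CMH statistic matches the stratified score formula", {
  # identical no-association strata: statistic exactly 0
  r0 <- cmh_test_tables(array(rep(c(5, 5, 5, 5), 2), dim = c(2, 2, 2)))
  expect_equal(r0$stat, 0)
  expect_equal(r0$p, 1)
  # K = 1 equals the longhand 1-df score chi-square
  tb <- array(c(12, 3, 5, 10), dim = c(2, 2, 1))
  r1 <- cmh_test_tables(tb)
  a <- 12; r1k <- 12 + 5; r2k <- 3 + 10; c1k <- 12 + 3; c2k <- 5 + 10; nk <- 30
  e <- r1k * c1k / nk
  v <- r1k * r2k * c1k * c2k / (nk^2 * (nk - 1))
  expect_equal(r1$stat, (a - e)^2 / v, tolerance = 1e-12)
  # two identical effect strata, hand-computed
  tb2 <- array(rep(c(16, 4, 4, 16), 2), dim = c(2, 2, 2))
  r2 <- cmh_test_tables(tb2)
  expect_equal(r2$stat, 144 / (2 * (20 * 20 * 20 * 20) / (40^2 * 39)),
               tolerance = 1e-12)
  expect_equal(r2$p, pchisq(r2$stat, 1, lower.tail = FALSE))
  # zero-margin stratum contributes nothing
  tb3 <- array(c(16, 4, 4, 16, 0, 0, 3, 7), dim = c(2, 2, 2))
  expect_equal(cmh_test_tables(tb3)$stat,
               cmh_test_tables(array(c(16, 4, 4, 16), dim = c(2, 2, 1)))$stat)
  # all strata degenerate
  r4 <- cmh_test_tables(array(c(0, 0, 3, 7), dim = c(2, 2, 1)))
  expect_true(r4$degenerate)
  expect_equal(r4$p, 1)
})

test_that("CMH agrees with mantelhaen.test and gains power with replication", {
  set.seed(17)
  for (i in 1:25) {
    K <- sample(2:4, 1)
    tb <- array(rpois(4 * K, 10) + 1, dim = c(2, 2, K))
    ours <- cmh_test_tables(tb)
    ref <- mantelhaen.test(tb, correct = FALSE)
    expect_equal(ours$stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
  # statistic is monotone increasing in the number of identical effect strata
  one <- c(16, 4, 4, 16)
  stats <- vapply(1:5, function(K)
    cmh_test_tables(array(rep(one, K), dim = c(2, 2, K)))$stat, numeric(1))
  expect_true(all(diff(stats) > 0))
})

test_that("sliding windows average sites in [start, start+window)", {
  pos <- seq(1000L, 200000L, by = 1000L)
  w <- sliding_window_mean(rep("chr1", length(pos)), pos,
                           rep(0.3, length(pos)), window = 1e5, step = 5e3,
                           min_sites = 1)
  expect_true(all(abs(w$mean[w$n_sites > 0] - 0.3) < 1e-12))
  # a window with no sites is missing
  w2 <- sliding_window_mean("chr1", 500000L, 0.7, window = 1e5, step = 5e3,
                            min_sites = 1, chrom_length = c(chr1 = 6e5))
  expect_true(any(is.na(w2$mean)))
  expect_equal(w2$mean[w2$start == 4e5], 0.7)
})

test_that("sliding windows equal brute-force recomputation on random sites", {
  set.seed(8)
  n <- 10000
  pos <- sort(sample.int(2e6, n))
  val <- rnorm(n)
  chrom <- rep("chr1", n)
  got <- sliding_window_mean(chrom, pos, val, window = 1e5, step = 5e3,
                             min_sites = 10)
  for (i in sample(nrow(got), 50)) {
    s <- got$start[i]
    inw <- pos - 1 >= s & pos - 1 < s + 1e5
    want <- if (sum(inw) >= 10) mean(val[inw]) else NA_real_
    expect_equal(got$mean[i], want)
    expect_equal(got$n_sites[i], sum(inw))
  }
})
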