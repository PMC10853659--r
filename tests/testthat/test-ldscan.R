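test_that("em_r2 is exact on perfectly correlated certain genotypes", {
  set.seed(20)
  g <- sample(0:2, 50, replace = TRUE)
  fit <- em_r2(one_hot_gl(g), one_hot_gl(g))
  expect_equal(fit$r2, 1, tolerance = 1e-6)
  # complementary coding (allele relabeling at one site) also gives r2 = 1
  fit2 <- em_r2(one_hot_gl(g), one_hot_gl(2L - g))
  expect_equal(fit2$r2, 1, tolerance = 1e-6)
})

test_that("em_r2 on independent loci is near zero (E[r2] ~ 1/2n)", {
  set.seed(21)
  g1 <- rbinom(500, 2, 0.4); g2 <- rbinom(500, 2, 0.3)
  fit <- em_r2(one_hot_gl(g1), one_hot_gl(g2))
  expect_lt(fit$r2, 0.02)
})

test_that("em_r2 on certain likelihoods equals the hard-genotype EM oracle", {
  set.seed(22)
  for (i in 1:10) {
    n <- 120
    # correlated pair via shared haplotypes
    h1a <- rbinom(n, 1, 0.4); h1b <- rbinom(n, 1, 0.4)
    flip <- rbinom(n, 1, 0.15)
    h2a <- ifelse(flip, 1 - h1a, h1a); h2b <- ifelse(flip, 1 - h1b, h1b)
    g1 <- h1a + h1b; g2 <- h2a + h2b
    ours <- em_r2(one_hot_gl(g1), one_hot_gl(g2), tol = 1e-10,
                  max_iter = 500)
    ref <- hard_genotype_em(g1, g2)
    if (is.na(ref$r2)) next
    expect_equal(ours$freqs, ref$freqs, tolerance = 1e-6)
    expect_equal(ours$r2, min(1, max(0, ref$r2)), tolerance = 1e-6)
  }
})

test_that("em_r2 is symmetric in its two sites", {
  set.seed(23)
  gl1 <- matrix(runif(90), 30); gl1 <- gl1 / rowSums(gl1)
  gl2 <- matrix(runif(90), 30); gl2 <- gl2 / rowSums(gl2)
  a <- em_r2(gl1, gl2); b <- em_r2(gl2, gl1)
  expect_equal(a$r2, b$r2, tolerance = 1e-9)
})

test_that("pairwise_ld honors the distance cap", {
  g <- matrix(rbinom(300, 2, 0.5), 3, 100)
  gl <- gl_matrix(rep("chr1", 3), c(1L, 50001L, 200001L), rep("A", 3),
                  rep("C", 3),
                  genotype_likelihoods_from_genotypes(g, Inf, 0.01))
  prs <- pairwise_ld(gl, max_dist = 1e5)
  expect_equal(nrow(prs), 1)
  expect_equal(prs$pos1, 1L)
  expect_equal(prs$pos2, 50001L)
  expect_equal(nrow(pairwise_ld(gl, max_dist = 0)), 0)
})

test_that("pair enumeration equals brute force on random positions", {
  set.seed(24)
  pos <- sort(sample.int(5e5, 200))
  g <- matrix(rbinom(200 * 20, 2, 0.5), 200, 20)
  keep <- apply(g, 1, function(x) length(unique(x)) > 1)
  pos <- pos[keep]; g <- g[keep, , drop = FALSE]
  gl <- gl_matrix(rep("chr1", length(pos)), pos, rep("A", length(pos)),
                  rep("C", length(pos)),
                  genotype_likelihoods_from_genotypes(g, Inf, 0.01))
  prs <- pairwise_ld(gl, max_dist = 5e4, max_iter = 5)
  brute <- sum(outer(pos, pos, function(a, b) b > a & b - a <= 5e4))
  # monomorphic-in-sample pairs may be dropped; count those separately
  mono <- vapply(seq_along(pos), function(i) length(unique(g[i, ])) == 1,
                 logical(1))
  expect_equal(nrow(prs), brute - sum(outer(mono, mono, `|`) &
                                        outer(pos, pos, function(a, b)
                                          b > a & b - a <= 5e4)))
})

test_that("window mean LD uses both-sites-in-window membership", {
  pairs <- data.frame(chrom = "chr1",
                      pos1 = c(10001L, 60001L, 95001L),
                      pos2 = c(20001L, 70001L, 130001L),
                      dist = c(10000L, 10000L, 35000L),
                      r2 = c(0.8, 0.8, 0.8))
  tw <- window_mean_ld(pairs, window = 1e5, step = 5e3,
                       chrom_length = c(chr1 = 2e5))
  expect_true(all(abs(tw$mean_ld[!is.na(tw$mean_ld)] - 0.8) < 1e-12))
  # the boundary-spanning pair is excluded from the window [0, 1e5)
  w0 <- tw[tw$start == 0, ]
  expect_equal(w0$n_pairs, 2)
})

test_that("window mean LD equals brute-force recomputation", {
  set.seed(25)
  n <- 500
  p1 <- sample.int(3e5, n)
  d <- sample.int(5e4, n)
  pairs <- data.frame(chrom = "chr1", pos1 = p1, pos2 = p1 + d, dist = d,
                      r2 = runif(n))
  got <- window_mean_ld(pairs, window = 1e5, step = 5e3)
  for (i in sample(nrow(got), 40)) {
    s <- got$start[i]
    inw <- pairs$pos1 - 1 >= s & pairs$pos2 - 1 < s + 1e5
    expect_equal(got$n_pairs[i], sum(inw))
    if (sum(inw) > 0) expect_equal(got$mean_ld[i], mean(pairs$r2[inw]))
  }
})

island_track <- function(vals, step = 5e3, window = 1e5) {
  n <- length(vals)
  data.frame(chrom = "chr1", start = (seq_len(n) - 1) * step,
             end = (seq_len(n) - 1) * step + window,
             n_pairs = 50L, mean_ld = vals)
}

test_that("island rule enforces the run-length and gap boundaries", {
  set.seed(26)
  base <- runif(300, 0.05, 0.10)
  # 30 consecutive elevated steps -> one island
  v <- base; v[101:130] <- 0.9
  isl <- ld_outlier_islands(island_track(v))
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start, 100 * 5e3)
  expect_equal(isl$end, 129 * 5e3 + 1e5)
  expect_equal(isl$n_steps, 30L)
  # 19 consecutive steps: below the minimum run
  v19 <- base; v19[101:119] <- 0.9
  expect_equal(nrow(ld_outlier_islands(island_track(v19))), 0)
  # 20 steps qualify
  v20 <- base; v20[101:120] <- 0.9
  expect_equal(nrow(ld_outlier_islands(island_track(v20))), 1)
  # two 15-step runs: a 3-step gap breaks them, a 2-step gap joins them
  vgap3 <- base; vgap3[c(101:115, 119:133)] <- 0.9
  expect_equal(nrow(ld_outlier_islands(island_track(vgap3))), 0)
  vgap2 <- base; vgap2[c(101:115, 118:132)] <- 0.9
  isl2 <- ld_outlier_islands(island_track(vgap2))
  expect_equal(nrow(isl2), 1)
  expect_equal(isl2$n_steps, 30L)
})

test_that("masked windows are excluded before the baseline and calling", {
  set.seed(27)
  base <- runif(300, 0.05, 0.10)
  v <- base; v[151:180] <- 0.9
  track <- island_track(v)
  # masking the island region removes the call entirely
  mask <- regions("chr1", 150 * 5e3, 180 * 5e3 + 1e5)
  expect_equal(nrow(ld_outlier_islands(track, mask = mask)), 0)
  # prepending masked windows does not change calls
  pre <- island_track(rep(0.95, 30))
  shifted <- track
  shifted$start <- shifted$start + 30 * 5e3
  shifted$end <- shifted$end + 30 * 5e3
  both <- rbind(pre, shifted)
  mask2 <- regions("chr1", 0, 30 * 5e3 + 1e5 - 5e3)
  isl_a <- ld_outlier_islands(track)
  isl_b <- ld_outlier_islands(both, mask = mask2)
  expect_equal(isl_b$end - isl_b$start, isl_a$end - isl_a$start)
  expect_equal(isl_b$n_steps, isl_a$n_steps)
})

test_that("lowering the IQR multiplier never removes an island", {
  set.seed(28)
  v <- runif(400, 0.05, 0.12)
  v[51:85] <- runif(35, 0.5, 0.9)
  v[201:260] <- runif(60, 0.3, 0.6)
  strict <- ld_outlier_islands(island_track(v), island_params(iqr_multiplier = 2))
  loose <- ld_outlier_islands(island_track(v), island_params(iqr_multiplier = 1))
  for (i in seq_len(nrow(strict))) {
    covered <- any(loose$start <= strict$start[i] &
                     loose$end >= strict$end[i])
    expect_true(covered)
  }
})

test_that("signed-rank test matches the exact tail and wilcox.test", {
  # all 20 differences positive: exact one-sided p = 1/2^20
  res <- wilcoxon_signed_rank(1:20 + (1:20) / 40, 1:20 - (1:20) / 40,
                              "greater")
  expect_equal(res$p, 2^-20)
  expect_true(res$exact)
  # all differences zero: degenerate
  z <- wilcoxon_signed_rank(rep(1, 10), rep(1, 10))
  expect_true(z$degenerate)
  expect_equal(z$p, 1)
  # agreement with wilcox.test on zero-free tie-free data
  set.seed(29)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15)
    ours <- wilcoxon_signed_rank(x, y, "greater")
    ref <- wilcox.test(x, y, paired = TRUE, alternative = "greater",
                       exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("ends-vs-whole test sees no long-range LD in a contiguous island", {
  # construct pairs: high LD inside one 400 kb island, background elsewhere
  set.seed(30)
  pos <- sort(sample.int(2e6, 600))
  mk_pairs <- function(pos, max_d) {
    idx <- which(outer(pos, pos, function(a, b) b > a & b - a <= max_d),
                 arr.ind = TRUE)
    data.frame(chrom = "chr1", pos1 = pos[idx[, 1]], pos2 = pos[idx[, 2]],
               dist = pos[idx[, 2]] - pos[idx[, 1]])
  }
  pairs <- mk_pairs(pos, 1e6)
  inside <- pairs$pos1 - 1 >= 6e5 & pairs$pos2 - 1 < 1.4e6
  # LD decays with distance (as physical linkage does), strongly elevated
  # inside the island
  pairs$r2 <- ifelse(inside, 0.9, 0.06) * exp(-pairs$dist / 2e5) +
    runif(nrow(pairs), 0, 0.01)
  res <- long_range_ld_test(pairs, regions("chr1", 0, 2e6),
                            long_range_params(widths = c(3e5, 5e5, 1e6)))
  ok <- !res$tests$degenerate
  expect_gt(sum(ok), 5)
  expect_true(all(res$tests$p[ok] > 0.05))
  # whole >= ends on average where both defined
  st <- res$steps[!is.na(res$steps$whole) & !is.na(res$steps$ends), ]
  expect_gt(mean(st$whole - st$ends), 0)
})
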