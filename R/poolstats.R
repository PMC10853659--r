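#' Site-filter parameters
#'
#' @param min_reads_per_sample minimum total reads in every pool (default 10).
#' @param min_individuals_per_sample minimum individuals observed per pool,
#'   applied only when per-site individual coverage is supplied (default 3).
#' @param min_global_maf minimum pooled global minor-allele frequency
#'   (default 0.005; use 0.05 for LD-grade input).
#' @return list of class `filter_params`.
#' @export
filter_params <- function(min_reads_per_sample = 10L,
                          min_individuals_per_sample = 3L,
                          min_global_maf = 0.005) {
  stopifnot(min_reads_per_sample >= 1, min_global_maf >= 0,
            min_global_maf < 0.5)
  structure(list(min_reads_per_sample = min_reads_per_sample,
                 min_individuals_per_sample = min_individuals_per_sample,
                 min_global_maf = min_global_maf),
            class = "filter_params")
}

#' Apply per-site depth/individual/MAF filters
#'
#' A site is retained iff every pool has at least `min_reads_per_sample`
#' reads, (when `individuals` is supplied) at least
#' `min_individuals_per_sample` individuals, and the pooled global minor
#' allele frequency is at least `min_global_maf`; all thresholds are
#' inclusive. Removals are attributed to the first failing rule in the order
#' depth, individuals, MAF. Read-quality (snpQ) and indel-proximity filters
#' operate on reads upstream of allele counts and are reported as not
#' applicable.
#'
#' @param counts a `biallelic_counts` object ([biallelic_reduce()]).
#' @param params a [filter_params()] list.
#' @param individuals optional sites x pools matrix of individuals observed.
#' @return list with `keep` (logical per site) and `report` (data.frame of
#'   per-rule removal counts; sites_in = sites_retained + sum(removed)).
#' @export
filter_sites <- function(counts, params = filter_params(),
                         individuals = NULL) {
  stopifnot(inherits(counts, "biallelic_counts"))
  n <- length(counts$pos)
  fail_depth <- rowSums(counts$tot < params$min_reads_per_sample) > 0
  fail_ind <- if (is.null(individuals)) rep(FALSE, n) else
    rowSums(individuals < params$min_individuals_per_sample) > 0
  alt_glob <- rowSums(counts$alt)
  tot_glob <- rowSums(counts$tot)
  f <- ifelse(tot_glob > 0, alt_glob / tot_glob, 0)
  maf <- pmin(f, 1 - f)
  fail_maf <- maf < params$min_global_maf
  keep <- !(fail_depth | fail_ind | fail_maf)
  # first rule wins for attribution
  attr_depth <- fail_depth
  attr_ind <- fail_ind & !fail_depth
  attr_maf <- fail_maf & !fail_depth & !fail_ind
  report <- data.frame(
    rule = c("min_reads_per_sample", "min_individuals_per_sample",
             "min_global_maf", "snpQ", "indel_proximity"),
    removed = c(sum(attr_depth), sum(attr_ind), sum(attr_maf), NA, NA),
    applicable = c(TRUE, !is.null(individuals), TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  list(keep = keep, report = report, sites_in = n, sites_retained = sum(keep))
}

#' Pooled allele-frequency estimate
#'
#' @param alt_count alternate-allele read count.
#' @param total_count total read count; zero totals yield `NA` (such sites
#'   must already be filtered).
#' @return alt_count / total_count.
#' @export
pooled_freq <- function(alt_count, total_count) {
  ifelse(total_count > 0, alt_count / total_count, NA_real_)
}

#' Per-site FST between two samples
#'
#' Default estimator is (H_T - H_S)/H_T on read-frequency estimates with
#' p-bar the unweighted mean of the two sample frequencies and H = 2p(1-p);
#' returns 0 where H_T = 0. With `depth_correction`, each sample's
#' heterozygosity in H_S is multiplied by d/(d-1) using that sample's read
#' depth. The Hudson-type alternative uses
#' ((p1-p2)^2 - p1 q1/(d1-1) - p2 q2/(d2-1)) / (p1 q2 + p2 q1).
#' Reported values are clamped to [0, 1].
#'
#' @param p1,p2 sample alternate-allele frequencies in [0, 1] (vectorized).
#' @param d1,d2 read depths, required for `depth_correction` or `hudson`.
#' @param method `"hartl"` (default) or `"hudson"`.
#' @param depth_correction apply the d/(d-1) small-depth correction to H_S.
#' @return numeric FST in [0, 1].
#' @export
site_fst <- function(p1, p2, d1 = NULL, d2 = NULL,
                     method = c("hartl", "hudson"),
                     depth_correction = FALSE) {
  method <- match.arg(method)
  if (method == "hartl") {
    pbar <- (p1 + p2) / 2
    ht <- 2 * pbar * (1 - pbar)
    h1 <- 2 * p1 * (1 - p1)
    h2 <- 2 * p2 * (1 - p2)
    if (depth_correction) {
      stopifnot(!is.null(d1), !is.null(d2))
      h1 <- h1 * ifelse(d1 > 1, d1 / (d1 - 1), NA_real_)
      h2 <- h2 * ifelse(d2 > 1, d2 / (d2 - 1), NA_real_)
    }
    hs <- (h1 + h2) / 2
    fst <- ifelse(ht > 0, (ht - hs) / ht, 0)
  } else {
    stopifnot(!is.null(d1), !is.null(d2))
    num <- (p1 - p2)^2 - p1 * (1 - p1) / pmax(d1 - 1, 1) -
      p2 * (1 - p2) / pmax(d2 - 1, 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    fst <- ifelse(den > 0, num / den, 0)
  }
  pmin(1, pmax(0, fst))
}

#' Two-sided Fisher's exact test for 2x2 tables, vectorized
#'
#' Exact hypergeometric two-sided p by the probability-mass rule: the sum of
#' probabilities of all tables (with the observed margins) whose point
#' probability does not exceed the observed one, with relative tolerance
#' 1e-7 for ties. Tables are alt/ref x group read counts. A zero row or
#' column margin gives p = 1 with a degenerate flag.
#'
#' @param a,b,c,d vectorized cell counts: a = alt reads group 1, b = alt
#'   reads group 2, c = ref reads group 1, d = ref reads group 2.
#' @return data.frame with columns p and degenerate.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n,
            all(c(a, b, c, d) >= 0))
  m_alt <- a + b
  m_ref <- c + d
  k1 <- a + c
  degen <- m_alt == 0 | m_ref == 0 | k1 == 0 | (b + d) == 0
  p <- rep(1, n)
  idx <- which(!degen)
  p[idx] <- vapply(idx, function(i) {
    lo <- max(0L, k1[i] - m_ref[i])
    hi <- min(m_alt[i], k1[i])
    probs <- dhyper(lo:hi, m_alt[i], m_ref[i], k1[i])
    obs <- probs[a[i] - lo + 1L]
    sum(probs[probs <= obs * (1 + 1e-7)])
  }, numeric(1))
  data.frame(p = pmin(p, 1), degenerate = degen)
}

#' Cochran-Mantel-Haenszel test over stratified 2x2 tables, vectorized
#'
#' Statistic (|sum_k a_k - sum_k E[a_k]| - cc)^2 / sum_k Var[a_k] with
#' E[a_k] = r1k c1k / nk and Var[a_k] = r1k r2k c1k c2k / (nk^2 (nk - 1)),
#' referred to a chi-square with 1 df. Strata with a zero margin or total
#' below 2 contribute nothing; sites where all strata are degenerate get
#' p = 1 with a flag. The continuity correction defaults to 0 so identical
#' no-association strata give a statistic of exactly 0.
#'
#' @param a,b,c,d matrices sites x strata: a = alt group 1, b = alt group 2,
#'   c = ref group 1, d = ref group 2 per stratum.
#' @param cc continuity correction, 0 (default) or 0.5.
#' @return data.frame with columns stat, p, degenerate.
#' @export
cmh_test <- function(a, b, c, d, cc = 0) {
  a <- as.matrix(a); b <- as.matrix(b); c <- as.matrix(c); d <- as.matrix(d)
  stopifnot(all(dim(a) == dim(b)), all(dim(a) == dim(c)),
            all(dim(a) == dim(d)), cc %in% c(0, 0.5))
  r1 <- a + b; r2 <- c + d
  c1 <- a + c; c2 <- b + d
  nk <- r1 + r2
  ok <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0 & nk >= 2
  e <- ifelse(ok, r1 * c1 / nk, 0)
  v <- ifelse(ok, r1 * r2 * c1 * c2 / (nk^2 * (nk - 1)), 0)
  aa <- ifelse(ok, a, 0)
  num <- pmax(abs(rowSums(aa) - rowSums(e)) - cc, 0)^2
  den <- rowSums(v)
  degen <- den == 0
  stat <- ifelse(degen, 0, num / ifelse(degen, 1, den))
  p <- ifelse(degen, 1, pchisq(stat, df = 1, lower.tail = FALSE))
  data.frame(stat = stat, p = p, degenerate = degen)
}

#' CMH test from a stacked 2x2xK array
#'
#' Convenience single-site interface over [cmh_test()].
#' @param tables 2 x 2 x K array; rows alt/ref, columns the two groups.
#' @param cc continuity correction.
#' @return one-row data.frame (stat, p, degenerate).
#' @export
cmh_test_tables <- function(tables, cc = 0) {
  stopifnot(length(dim(tables)) == 3, all(dim(tables)[1:2] == 2))
  cmh_test(a = t(tables[1, 1, ]), b = t(tables[1, 2, ]),
           c = t(tables[2, 1, ]), d = t(tables[2, 2, ]), cc = cc)
}

#' Per-site association statistics for a replicated phenotype contrast
#'
#' Builds, for each retained site, the read-count 2x2 table alt/ref x
#' phenotype within each locality (the CMH strata), computes per-locality
#' FST and its unweighted mean across localities, the two-sided FET on
#' phenotype-pooled counts (plus per-locality FETs), and the CMH test across
#' localities.
#'
#' @param counts a `biallelic_counts` object, already filtered.
#' @param phenotype_levels optional length-2 character giving the phenotype
#'   contrast order; defaults to the order of appearance in the pool table.
#' @param fst_method,fst_depth_correction passed to [site_fst()].
#' @param cmh_cc continuity correction for [cmh_test()].
#' @return data.frame (`site_stats`): chrom, pos, allele1, allele2,
#'   per-group frequencies, fst (mean across localities), per-locality
#'   fet_p_<locality>, fet_p (combined), cmh_stat, cmh_p.
#' @export
site_stats <- function(counts, phenotype_levels = NULL,
                       fst_method = "hartl", fst_depth_correction = FALSE,
                       cmh_cc = 0) {
  stopifnot(inherits(counts, "biallelic_counts"))
  pools <- counts$pools
  if (is.null(phenotype_levels)) phenotype_levels <- unique(pools$phenotype)
  stopifnot(length(phenotype_levels) == 2)
  locs <- unique(pools$locality)
  n <- length(counts$pos)
  sum_group <- function(mat, sel)
    if (sum(sel) == 1) mat[, sel] else rowSums(mat[, sel, drop = FALSE])
  K <- length(locs)
  A <- B <- C <- D <- matrix(0, n, K, dimnames = list(NULL, locs))
  fst_loc <- matrix(NA_real_, n, K)
  for (j in seq_len(K)) {
    s1 <- pools$locality == locs[j] & pools$phenotype == phenotype_levels[1]
    s2 <- pools$locality == locs[j] & pools$phenotype == phenotype_levels[2]
    A[, j] <- sum_group(counts$alt, s1)
    B[, j] <- sum_group(counts$alt, s2)
    t1 <- sum_group(counts$tot, s1)
    t2 <- sum_group(counts$tot, s2)
    C[, j] <- t1 - A[, j]
    D[, j] <- t2 - B[, j]
    fst_loc[, j] <- site_fst(pooled_freq(A[, j], t1), pooled_freq(B[, j], t2),
                             d1 = t1, d2 = t2, method = fst_method,
                             depth_correction = fst_depth_correction)
  }
  out <- data.frame(chrom = counts$chrom, pos = counts$pos,
                    allele1 = counts$allele1, allele2 = counts$allele2,
                    stringsAsFactors = FALSE)
  freqs <- counts$alt / counts$tot
  colnames(freqs) <- paste0("freq_", pools$pool)
  out <- cbind(out, freqs)
  out$fst <- rowMeans(fst_loc)
  for (j in seq_len(K))
    out[[paste0("fet_p_", locs[j])]] <-
      fisher_exact_2x2(A[, j], B[, j], C[, j], D[, j])$p
  out$fet_p <- fisher_exact_2x2(rowSums(A), rowSums(B),
                                rowSums(C), rowSums(D))$p
  cmh <- cmh_test(A, B, C, D, cc = cmh_cc)
  out$cmh_stat <- cmh$stat
  out$cmh_p <- cmh$p
  out
}

#' Sliding-window mean of a per-site track
#'
#' Windows of `window` bp tile each chromosome at `step` bp starting from 0;
#' a window's value is the unweighted mean of per-site values whose (0-based)
#' position falls in [start, start + window). Windows holding fewer than
#' `min_sites` sites yield NA.
#'
#' @param chrom,pos site coordinates (pos 1-based).
#' @param values per-site values.
#' @param window,step window width and step in bp (defaults 100 kb / 5 kb).
#' @param min_sites minimum sites for a window value (default 10).
#' @param chrom_length optional named vector of chromosome lengths; windows
#'   extend to the last site otherwise.
#' @return data.frame: chrom, start, end (0-based half-open), n_sites, mean.
#' @export
sliding_window_mean <- function(chrom, pos, values, window = 1e5, step = 5e3,
                                min_sites = 10, chrom_length = NULL) {
  out <- list()
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    p0 <- pos[sel] - 1  # 0-based
    v <- values[sel]
    ord <- order(p0)
    p0 <- p0[ord]; v <- v[ord]
    len <- if (!is.null(chrom_length) && ch %in% names(chrom_length))
      chrom_length[[ch]] else max(p0) + 1
    starts <- seq(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    cs0 <- c(0, cumsum(ifelse(is.na(v), 0, v)))
    cn0 <- c(0L, cumsum(!is.na(v)))
    lo <- findInterval(starts - 0.5, p0) + 1L
    hi <- findInterval(starts + window - 0.5, p0)
    nw <- ifelse(hi >= lo, cn0[hi + 1L] - cn0[lo], 0L)
    sw <- ifelse(hi >= lo, cs0[hi + 1L] - cs0[lo], 0)
    m <- ifelse(nw >= max(min_sites, 1L), sw / nw, NA_real_)
    out[[ch]] <- data.frame(chrom = ch, start = starts,
                            end = pmin(starts + window, len),
                            n_sites = nw, mean = m,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
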