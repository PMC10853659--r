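# Haplotypes are indexed 1..4 = (0,0), (0,1), (1,0), (1,1) alternate-allele
# dosages at (site1, site2). The 16 ordered haplotype pairs map to the 9
# unordered genotype pairs indexed m = 3*g1 + g2 + 1.
HAP_DOSE <- cbind(s1 = c(0L, 0L, 1L, 1L), s2 = c(0L, 1L, 0L, 1L))
PAIR_H <- rep(1:4, times = 4)
PAIR_K <- rep(1:4, each = 4)
PAIR_M <- 3L * (HAP_DOSE[PAIR_H, 1] + HAP_DOSE[PAIR_K, 1]) +
  (HAP_DOSE[PAIR_H, 2] + HAP_DOSE[PAIR_K, 2]) + 1L
# 9x16 aggregation of ordered haplotype pairs into genotype pairs, and the
# 4x4 genotype-pair index of each (h, k) ordered pair
AGG_9x16 <- vapply(1:9, function(m) as.numeric(PAIR_M == m),
                   numeric(16))
M_4x4 <- matrix(PAIR_M, 4, 4)  # [h, k]

#' Pairwise r2 from genotype likelihoods by EM over haplotype frequencies
#'
#' Maximum-likelihood estimation of the four two-locus haplotype frequencies
#' from unphased genotype likelihoods: the expectation step weights each
#' individual's nine genotype-pair configurations by the product of its two
#' GL triples and the current genotype-pair probabilities (resolving the
#' double-heterozygote phase ambiguity by the current frequencies), and the
#' maximization step re-estimates the frequencies from the expected
#' haplotype counts. Initialization is at linkage equilibrium
#' (f_AB = p_A p_B); convergence when the largest frequency change is below
#' `tol` or after `max_iter` iterations. Returns r2 = D^2 / (p_A q_A p_B
#' q_B) with D = f_AB - p_A p_B, clamped to \[0, 1\].
#'
#' @param gl1,gl2 n x 3 matrices of normalized genotype likelihoods at the
#'   two sites (rows are individuals).
#' @param tol,max_iter EM convergence controls.
#' @return list: r2, D, freqs (length-4 haplotype frequencies f00, f01, f10,
#'   f11), p1, p2, n_iter. Monomorphic pairs (estimated MAF 0 at either
#'   site) return r2 = NA.
#' @export
em_r2 <- function(gl1, gl2, tol = 1e-6, max_iter = 100L) {
  stopifnot(nrow(gl1) == nrow(gl2), ncol(gl1) == 3, ncol(gl2) == 3,
            nrow(gl1) >= 2)
  # 9-column per-individual likelihood of each genotype pair
  L <- matrix(0, nrow(gl1), 9)
  for (g1 in 0:2) for (g2 in 0:2)
    L[, 3 * g1 + g2 + 1] <- gl1[, g1 + 1] * gl2[, g2 + 1]
  # initialize at linkage equilibrium from marginal dosage means
  p1 <- mean(gl1[, 2] * 0.5 + gl1[, 3])
  p2 <- mean(gl2[, 2] * 0.5 + gl2[, 3])
  f <- c((1 - p1) * (1 - p2), (1 - p1) * p2, p1 * (1 - p2), p1 * p2)
  f <- pmax(f, 1e-8); f <- f / sum(f)
  n <- nrow(gl1)
  it <- 0L
  repeat {
    it <- it + 1L
    fp <- f[PAIR_H] * f[PAIR_K]
    P9 <- as.vector(crossprod(AGG_9x16, fp))
    denom <- as.vector(L %*% P9)
    denom[denom <= 0] <- 1e-300
    u9 <- as.vector(crossprod(L, 1 / denom))
    # expected haplotype counts / (2n): f_h * sum_k f_k * u9[m(h,k)] / n
    U <- matrix(u9[M_4x4], 4, 4)
    fnew <- f * as.vector(U %*% f) / n
    fnew <- fnew / sum(fnew)
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol || it >= max_iter) break
  }
  pA <- f[3] + f[4]
  pB <- f[2] + f[4]
  den <- pA * (1 - pA) * pB * (1 - pB)
  if (den <= 0)
    return(list(r2 = NA_real_, D = NA_real_, freqs = f, p1 = pA, p2 = pB,
                n_iter = it))
  D <- f[4] - pA * pB
  list(r2 = min(1, max(0, D^2 / den)), D = D, freqs = f, p1 = pA, p2 = pB,
       n_iter = it)
}

#' Estimated alternate-allele frequency per GL site
#'
#' Posterior-mean dosage under a flat genotype prior, halved; used for the
#' MAF pre-filter on LD input.
#' @param gl a [gl_matrix()] object.
#' @return numeric frequency per site.
#' @export
gl_site_freq <- function(gl) {
  m <- 0.5 * gl$gl[, , 2] + gl$gl[, , 3]
  if (is.null(dim(m))) m <- matrix(m, nrow = length(gl$pos))
  rowMeans(m)
}

#' Minor-allele-frequency filter for GL input
#'
#' @param gl a [gl_matrix()] object.
#' @param min_maf minimum estimated MAF (default 0.05, the LD-grade filter).
#' @return filtered [gl_matrix()].
#' @export
filter_gl_maf <- function(gl, min_maf = 0.05) {
  p <- gl_site_freq(gl)
  keep <- pmin(p, 1 - p) >= min_maf
  gl_matrix(gl$chrom[keep], gl$pos[keep], gl$allele1[keep],
            gl$allele2[keep], gl$gl[keep, , , drop = FALSE])
}

#' All pairwise r2 within a distance cap
#'
#' Runs [em_r2()] for every same-chromosome site pair with inter-site
#' distance at most `max_dist` bp. Pairs where either site is monomorphic
#' are skipped.
#'
#' @param gl a [gl_matrix()] object (MAF-filtered; see [filter_gl_maf()]).
#' @param max_dist maximum pos2 - pos1 in bp (e.g. 1e5; 1e6 for
#'   long-range-LD chromosomes).
#' @param tol,max_iter EM controls passed to [em_r2()].
#' @return data.frame (`ld_pairs`): chrom, pos1, pos2, dist, r2, D, fAB.
#' @export
pairwise_ld <- function(gl, max_dist, tol = 1e-6, max_iter = 100L) {
  out <- list()
  for (ch in unique(gl$chrom)) {
    idx <- which(gl$chrom == ch)
    pos <- gl$pos[idx]
    n <- length(idx)
    if (n < 2) next
    hi <- findInterval(pos + max_dist, pos)
    for (ii in seq_len(n)) {
      if (hi[ii] <= ii) next
      for (jj in (ii + 1):hi[ii]) {
        fit <- em_r2(gl$gl[idx[ii], , ], gl$gl[idx[jj], , ],
                     tol = tol, max_iter = max_iter)
        if (is.na(fit$r2)) next
        out[[length(out) + 1]] <- c(i = idx[ii], j = idx[jj], r2 = fit$r2,
                                    D = fit$D, fAB = fit$freqs[4])
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), pos1 = integer(0),
                      pos2 = integer(0), dist = integer(0), r2 = numeric(0),
                      D = numeric(0), fAB = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(chrom = gl$chrom[m[, "i"]], pos1 = gl$pos[m[, "i"]],
             pos2 = gl$pos[m[, "j"]],
             dist = gl$pos[m[, "j"]] - gl$pos[m[, "i"]],
             r2 = m[, "r2"], D = m[, "D"], fAB = m[, "fAB"],
             stringsAsFactors = FALSE)
}

#' Sliding-window mean LD
#'
#' A pair belongs to a window iff both of its sites lie within the window
#' (0-based half-open \[start, start + window)); the window value is the mean
#' r2 of member pairs, NA where a window holds none.
#'
#' @param pairs an `ld_pairs` data.frame from [pairwise_ld()].
#' @param window,step window width and step in bp (defaults 100 kb / 5 kb).
#' @param chrom_length optional named chromosome lengths.
#' @return data.frame: chrom, start, end, n_pairs, mean_ld.
#' @export
window_mean_ld <- function(pairs, window = 1e5, step = 5e3,
                           chrom_length = NULL) {
  out <- list()
  for (ch in unique(pairs$chrom)) {
    sel <- pairs$chrom == ch
    p1 <- pairs$pos1[sel] - 1; p2 <- pairs$pos2[sel] - 1
    r2 <- pairs$r2[sel]
    len <- if (!is.null(chrom_length) && ch %in% names(chrom_length))
      chrom_length[[ch]] else max(p2) + 1
    starts <- seq(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    nw <- mw <- numeric(length(starts))
    for (w in seq_along(starts)) {
      s <- starts[w]
      inw <- p1 >= s & p2 < s + window
      nw[w] <- sum(inw)
      mw[w] <- if (nw[w] > 0) mean(r2[inw]) else NA_real_
    }
    out[[ch]] <- data.frame(chrom = ch, start = starts,
                            end = pmin(starts + window, len),
                            n_pairs = nw, mean_ld = mw,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' LD-island detection parameters
#'
#' @param min_run minimum outlier window-steps in a series (default 20; the
#'   10-20 range sets a conservative boundary).
#' @param max_gap maximum non-outlier steps allowed inside a series
#'   (default 2).
#' @param iqr_multiplier outlier cutoff multiplier (default 2).
#' @param baseline `"median"` (default) or `"q3"`: the cutoff is baseline +
#'   iqr_multiplier x IQR.
#' @param scope `"per_chromosome"` (default) or `"genomewide"` baseline
#'   statistics.
#' @return list of class `island_params`.
#' @export
island_params <- function(min_run = 20L, max_gap = 2L, iqr_multiplier = 2,
                          baseline = c("median", "q3"),
                          scope = c("per_chromosome", "genomewide")) {
  stopifnot(min_run >= 1, max_gap >= 0, iqr_multiplier > 0)
  structure(list(min_run = as.integer(min_run), max_gap = as.integer(max_gap),
                 iqr_multiplier = iqr_multiplier,
                 baseline = match.arg(baseline), scope = match.arg(scope)),
            class = "island_params")
}

#' LD-outlier islands by the run/gap/IQR rule
#'
#' Windows overlapping the exclusion mask (e.g. the high-background-LD
#' centromeric region) are removed before anything else, including the
#' baseline statistics. A window-step is an outlier iff its mean LD is
#' strictly greater than baseline + iqr_multiplier x IQR, with
#' median/Q1/Q3/IQR computed from the non-masked, non-missing windows of the
#' chromosome. Islands are maximal series of at least `min_run` outlier
#' steps allowing internal gaps of at most `max_gap` consecutive non-outlier
#' steps; the island region spans the first to the last outlier window.
#'
#' @param track window track from [window_mean_ld()].
#' @param params an [island_params()] list.
#' @param mask optional [regions()] exclusion mask.
#' @return a [regions()] data.frame (score = island mean LD) with columns
#'   n_steps (outlier steps) added.
#' @export
ld_outlier_islands <- function(track, params = island_params(), mask = NULL) {
  if (!is.null(mask) && nrow(mask) > 0) {
    tr_reg <- regions(track$chrom, track$start, track$end)
    hit <- strict_overlap(tr_reg, mask)
    if (nrow(hit) > 0) track <- track[-unique(hit$query), , drop = FALSE]
  }
  glob_vals <- track$mean_ld[!is.na(track$mean_ld)]
  out <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    vals <- if (params$scope == "genomewide") glob_vals else
      tr$mean_ld[!is.na(tr$mean_ld)]
    if (length(vals) < 4) next  # no baseline estimable
    qs <- quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- qs[3] - qs[1]
    base <- if (params$baseline == "median") qs[2] else qs[3]
    cutoff <- base + params$iqr_multiplier * iqr
    is_out <- !is.na(tr$mean_ld) & tr$mean_ld > cutoff
    oi <- which(is_out)
    if (length(oi) == 0) next
    # group outlier steps separated by <= max_gap non-outlier steps
    grp <- cumsum(c(1, diff(oi) > params$max_gap + 1))
    for (g in unique(grp)) {
      members <- oi[grp == g]
      if (length(members) < params$min_run) next
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = tr$start[members[1]],
        end = tr$end[members[length(members)]],
        score = mean(tr$mean_ld[members]), n_steps = length(members),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    z <- empty_regions(); z$n_steps <- integer(0)
    return(z)
  }
  df <- do.call(rbind, out)
  r <- regions(df$chrom, df$start, df$end, score = df$score)
  r$n_steps <- df$n_steps
  r
}

#' One-sided Wilcoxon signed-rank test (zero-drop, exact for small n)
#'
#' Differences of exactly zero are dropped; with no ties in |d| and n <= 25
#' the exact signed-rank null distribution is used, otherwise a normal
#' approximation with continuity and tie correction. All differences zero
#' gives p = 1 with a degenerate flag.
#'
#' @param x,y paired observations; tests `x > y` (alternative "greater") or
#'   `x < y` ("less").
#' @param alternative one-sided direction.
#' @return list: statistic W (sum of positive ranks), n (non-zero pairs), p,
#'   degenerate, exact.
#' @export
wilcoxon_signed_rank <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, n = 0L, p = 1, degenerate = TRUE,
                exact = FALSE))
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= 25) {
    p <- if (alternative == "greater")
      psignrank(W - 1, n, lower.tail = FALSE)
    else psignrank(W, n)
    return(list(statistic = W, n = n, p = p, degenerate = FALSE,
                exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- if (alternative == "greater") (W - mu - 0.5) / sqrt(sigma2)
  else (W - mu + 0.5) / sqrt(sigma2)
  p <- if (alternative == "greater") pnorm(z, lower.tail = FALSE) else pnorm(z)
  list(statistic = W, n = n, p = p, degenerate = FALSE, exact = FALSE)
}

#' Long-range LD test parameters
#'
#' @param widths window widths in bp (default 300 kb to 1 Mb in 100 kb
#'   increments).
#' @param step window start step in bp (default 5 kb).
#' @param end_width width of the two end blocks (default 100 kb), so the
#'   minimum inter-site gap for "ends" pairs is width - 2 x end_width.
#' @param group_size steps per Wilcoxon group (default 20, i.e. 100 kb of
#'   starts).
#' @return list of class `long_range_params`.
#' @export
long_range_params <- function(widths = seq(3e5, 1e6, by = 1e5), step = 5e3,
                              end_width = 1e5, group_size = 20L) {
  stopifnot(all(widths >= 2 * end_width + 1), step > 0, group_size >= 2)
  structure(list(widths = widths, step = step, end_width = end_width,
                 group_size = as.integer(group_size)),
            class = "long_range_params")
}

#' Ends-versus-whole long-range LD test
#'
#' For each window width W and each window start on the step grid inside the
#' analysis span: "whole" is the mean r2 over pairs with both sites in the
#' window, and "ends" is the mean r2 over pairs with one site in the first
#' `end_width` bp and the other in the last `end_width` bp (inter-site gap
#' at least W - 2 x end_width). For each consecutive group of `group_size`
#' steps, a paired one-sided Wilcoxon signed-rank test of ends > whole is
#' run on the (ends, whole) step pairs. Long-range LD beyond physical
#' proximity shows up as significant groups; a single contiguous LD island
#' gives whole >= ends and non-significant groups.
#'
#' @param pairs `ld_pairs` from [pairwise_ld()], computed with `max_dist` at
#'   least the largest width.
#' @param span a one-row [regions()] data.frame: the analysis interval.
#' @param params a [long_range_params()] list.
#' @return list: `tests` (width, group, n_steps, n_used, W, p, degenerate)
#'   and `steps` (width, start, whole, ends).
#' @export
long_range_ld_test <- function(pairs, span, params = long_range_params()) {
  stopifnot(nrow(span) == 1)
  sel <- pairs$chrom == span$chrom
  p1 <- pairs$pos1[sel] - 1; p2 <- pairs$pos2[sel] - 1
  r2 <- pairs$r2[sel]
  ew <- params$end_width
  steps_out <- list(); tests_out <- list()
  for (W in params$widths) {
    starts <- seq(span$start, span$end - W, by = params$step)
    if (length(starts) == 0) next
    whole <- ends <- rep(NA_real_, length(starts))
    for (i in seq_along(starts)) {
      s <- starts[i]
      inw <- p1 >= s & p2 < s + W
      if (any(inw)) whole[i] <- mean(r2[inw])
      ine <- p1 >= s & p1 < s + ew & p2 >= s + W - ew & p2 < s + W
      if (any(ine)) ends[i] <- mean(r2[ine])
    }
    steps_out[[length(steps_out) + 1]] <-
      data.frame(width = W, start = starts, whole = whole, ends = ends)
    grp <- ceiling(seq_along(starts) / params$group_size)
    for (g in unique(grp)) {
      gi <- which(grp == g)
      use <- gi[!is.na(whole[gi]) & !is.na(ends[gi])]
      wt <- wilcoxon_signed_rank(ends[use], whole[use],
                                 alternative = "greater")
      tests_out[[length(tests_out) + 1]] <- data.frame(
        width = W, group = g, n_steps = length(gi), n_used = length(use),
        W = wt$statistic, p = wt$p, degenerate = wt$degenerate)
    }
  }
  list(tests = do.call(rbind, tests_out), steps = do.call(rbind, steps_out))
}
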