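#' Local-score parameters
#'
#' @param xi_quantiles quantiles of the per-site -log10 p distribution used
#'   as the smoothing penalty xi (default 0.75, 0.85, 0.95, 0.99). Lower
#'   quantiles smooth less and give more power; higher quantiles give more
#'   precisely bounded outlier regions.
#' @param fdr_target target false discovery rate for segment calling
#'   (default 0.05).
#' @param threshold_method `"monte_carlo"` (permutation, default) or
#'   `"gumbel"` (moment-fitted Gumbel to the permutation null maxima).
#' @param n_permutations permutation replicates for the null maximum
#'   (default 1000, minimum 100).
#' @param s_max cap on -log10 p for zero/underflowing p-values (default 50).
#' @param xi_scope `"genomewide"` (default) or `"per_chromosome"` quantile
#'   computation.
#' @param boundary segment boundary convention: `"peak"` (excursion start to
#'   peak, default) or `"full"` (start to return to zero).
#' @param seed RNG seed for permutations.
#' @return list of class `local_score_params`.
#' @export
local_score_params <- function(xi_quantiles = c(0.75, 0.85, 0.95, 0.99),
                               fdr_target = 0.05,
                               threshold_method = c("monte_carlo", "gumbel"),
                               n_permutations = 1000L,
                               s_max = 50,
                               xi_scope = c("genomewide", "per_chromosome"),
                               boundary = c("peak", "full"),
                               seed = 1L) {
  stopifnot(all(xi_quantiles > 0 & xi_quantiles < 1),
            fdr_target > 0, fdr_target <= 1, n_permutations >= 100)
  structure(list(xi_quantiles = xi_quantiles, fdr_target = fdr_target,
                 threshold_method = match.arg(threshold_method),
                 n_permutations = as.integer(n_permutations), s_max = s_max,
                 xi_scope = match.arg(xi_scope),
                 boundary = match.arg(boundary), seed = as.integer(seed)),
            class = "local_score_params")
}

#' Per-site scores from p-values
#'
#' s_i = -log10 p_i, capped at `s_max` (zero p-values would otherwise be
#' infinite); a warning is raised when capping occurs.
#' @param p p-values in \[0, 1\].
#' @param s_max score cap.
#' @return numeric scores >= 0.
#' @export
p_to_score <- function(p, s_max = 50) {
  stopifnot(all(p >= 0 & p <= 1))
  s <- -log10(p)
  if (any(s > s_max)) {
    warning(sum(s > s_max), " score(s) capped at s_max = ", s_max)
    s <- pmin(s, s_max)
  }
  s
}

#' Smoothing penalty xi from a score quantile
#'
#' xi is the q-th empirical quantile (type-7 linear interpolation) of the
#' per-site scores -log10 p over the analysis set, by default all retained
#' sites genome-wide.
#' @param p per-site p-values.
#' @param q quantile in (0, 1).
#' @param s_max score cap, see [p_to_score()].
#' @return numeric xi.
#' @export
xi_from_quantile <- function(p, q, s_max = 50) {
  stopifnot(length(p) > 0, q > 0, q < 1)
  unname(quantile(p_to_score(p, s_max), q, type = 7))
}

#' Lindley local-score recursion
#'
#' h_0 = 0, h_i = max(0, h_(i-1) + s_i - xi). Computed in closed form as
#' c_i - min(0, min_(j<=i) c_j) with c the cumulative sum of s - xi, which
#' equals the recursion exactly.
#' @param s per-site scores, ordered by position within one chromosome.
#' @param xi smoothing penalty.
#' @return numeric vector h >= 0, same length as `s`.
#' @export
lindley <- function(s, xi) {
  if (length(s) == 0) return(numeric(0))
  cs <- cumsum(s - xi)
  cs - pmin(0, cummin(cs))
}

#' Lindley tracks per chromosome
#'
#' Applies [lindley()] with an independent restart on every chromosome.
#' @param chrom,pos site coordinates (sites ordered by position within
#'   chromosome).
#' @param p per-site p-values.
#' @param xi smoothing penalty.
#' @param s_max score cap.
#' @return data.frame: chrom, pos, s, h; attribute `xi`.
#' @export
lindley_track <- function(chrom, pos, p, xi, s_max = 50) {
  s <- p_to_score(p, s_max)
  h <- numeric(length(s))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    if (is.unsorted(pos[sel]))
      stop("sites must be ordered by position within chromosome ", ch)
    h[sel] <- lindley(s[sel], xi)
  }
  out <- data.frame(chrom = chrom, pos = pos, s = s, h = h,
                    stringsAsFactors = FALSE)
  attr(out, "xi") <- xi
  out
}

null_max_lindley <- function(s, xi, n_permutations) {
  vapply(seq_len(n_permutations), function(i) {
    cs <- cumsum(sample(s) - xi)
    max(cs - pmin(0, cummin(cs)))
  }, numeric(1))
}

#' Per-chromosome significance thresholds for Lindley excursions
#'
#' Monte-Carlo method: site scores are permuted within each chromosome
#' `n_permutations` times and the maximum Lindley score recomputed, giving
#' the chromosome's null maximum distribution. Each chromosome's observed
#' maximum gets an empirical p-value; Benjamini-Hochberg across chromosomes
#' (each chromosome's maximum treated as one test) selects the adjusted
#' level alpha* = fdr_target * k / C, and significant chromosomes receive
#' the (1 - alpha*) empirical quantile of their null maxima as threshold;
#' non-significant chromosomes get +Inf (nothing callable). The Gumbel
#' method replaces the empirical quantile with the quantile of a Gumbel
#' distribution moment-fitted to the permutation null maxima.
#'
#' @param chrom,pos,p as in [lindley_track()].
#' @param xi smoothing penalty.
#' @param params a [local_score_params()] list.
#' @return data.frame per chromosome: chrom, obs_max, p_emp, threshold.
#' @export
significance_threshold <- function(chrom, pos, p, xi, params = local_score_params()) {
  s <- p_to_score(p, params$s_max)
  chroms <- unique(chrom)
  C <- length(chroms)
  set.seed(params$seed)
  res <- lapply(chroms, function(ch) {
    sc <- s[chrom == ch]
    obs <- max(lindley(sc, xi))
    nm <- null_max_lindley(sc, xi, params$n_permutations)
    list(obs = obs, nm = nm,
         p_emp = (1 + sum(nm >= obs)) / (params$n_permutations + 1))
  })
  p_emp <- vapply(res, `[[`, numeric(1), "p_emp")
  ord <- order(p_emp)
  k <- max(c(0, which(p_emp[ord] <= params$fdr_target * seq_len(C) / C)))
  alpha_star <- if (k == 0) NA_real_ else params$fdr_target * k / C
  thr <- rep(Inf, C)
  if (k > 0) {
    sig <- p_emp <= alpha_star
    for (i in which(sig)) {
      nm <- res[[i]]$nm
      if (all(nm == 0)) { thr[i] <- Inf; next }  # degenerate null track
      thr[i] <- if (params$threshold_method == "monte_carlo")
        unname(quantile(nm, 1 - alpha_star, type = 7))
      else gumbel_quantile(nm, 1 - alpha_star)
    }
  }
  data.frame(chrom = chroms,
             obs_max = vapply(res, `[[`, numeric(1), "obs"),
             p_emp = p_emp, threshold = thr, stringsAsFactors = FALSE)
}

# Moment fit of a Gumbel to null maxima; quantile at prob q.
gumbel_quantile <- function(x, q) {
  scale <- sd(x) * sqrt(6) / pi
  loc <- mean(x) - 0.5772156649 * scale
  loc - scale * log(-log(q))
}

#' Call excursion segments from a Lindley track
#'
#' A maximal excursion is a run where h rises from 0 and returns to 0 (or the
#' chromosome ends). Excursions whose maximum exceeds the threshold are
#' emitted as regions spanning from the first site after the preceding zero
#' to the site where h attains its maximum (`boundary = "peak"`), or to the
#' last site of the excursion (`boundary = "full"`); peak height and position
#' are recorded.
#'
#' @param track a [lindley_track()] data.frame.
#' @param thresholds data.frame from [significance_threshold()], or a single
#'   numeric threshold applied to every chromosome.
#' @param boundary `"peak"` or `"full"`.
#' @return a [regions()] data.frame with peak_pos, peak (score) columns.
#' @export
call_segments <- function(track, thresholds, boundary = c("peak", "full")) {
  boundary <- match.arg(boundary)
  if (is.numeric(thresholds))
    thresholds <- data.frame(chrom = unique(track$chrom),
                             threshold = thresholds)
  out <- list()
  for (ch in unique(track$chrom)) {
    thr <- thresholds$threshold[thresholds$chrom == ch]
    if (length(thr) == 0 || !is.finite(thr)) next
    stopifnot(thr > 0)
    sel <- track$chrom == ch
    h <- track$h[sel]; pos <- track$pos[sel]
    pos_run <- h > 0
    if (!any(pos_run)) next
    r <- rle(pos_run)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      i0 <- starts[j]; i1 <- ends[j]
      hmax <- max(h[i0:i1])
      if (hmax <= thr) next
      ipk <- i0 + which.max(h[i0:i1]) - 1L
      iend <- if (boundary == "peak") ipk else i1
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = pos[i0] - 1, end = pos[iend],
        peak = hmax, peak_pos = pos[ipk], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    z <- empty_regions()
    z$peak <- numeric(0); z$peak_pos <- numeric(0)
    return(z)
  }
  df <- do.call(rbind, out)
  r <- regions(df$chrom, df$start, df$end, score = df$peak)
  r$peak <- df$peak; r$peak_pos <- df$peak_pos
  r
}

#' Local-score scan of one p-value track across xi quantiles
#'
#' For each configured xi quantile: derives xi from the score distribution,
#' runs the Lindley recursion per chromosome, computes permutation
#' significance thresholds at the FDR target, and calls segments.
#'
#' @param chrom,pos,p per-site track (sorted by position within chromosome).
#' @param params a [local_score_params()] list.
#' @param test_label label stored in the output (e.g. "cmh", "fet").
#' @return list with `segments` (one [regions()] data.frame with columns
#'   test, xi_q, xi added), `thresholds`, and `xi` (named vector).
#' @export
local_score_scan <- function(chrom, pos, p, params = local_score_params(),
                             test_label = "test") {
  segs <- list(); thrs <- list()
  xis <- setNames(numeric(length(params$xi_quantiles)),
                  paste0("q", params$xi_quantiles))
  for (i in seq_along(params$xi_quantiles)) {
    q <- params$xi_quantiles[i]
    if (params$xi_scope == "per_chromosome") {
      # xi, thresholds and segments per chromosome
      seg_list <- list(); thr_list <- list()
      for (ch in unique(chrom)) {
        sel <- chrom == ch
        xi_ch <- xi_from_quantile(p[sel], q, params$s_max)
        tr <- lindley_track(chrom[sel], pos[sel], p[sel], xi_ch, params$s_max)
        th <- significance_threshold(chrom[sel], pos[sel], p[sel], xi_ch, params)
        seg_list[[ch]] <- call_segments(tr, th, params$boundary)
        thr_list[[ch]] <- th
      }
      sg <- do.call(rbind, seg_list)
      th <- do.call(rbind, thr_list)
      xis[i] <- NA_real_
    } else {
      xi <- xi_from_quantile(p, q, params$s_max)
      xis[i] <- xi
      tr <- lindley_track(chrom, pos, p, xi, params$s_max)
      th <- significance_threshold(chrom, pos, p, xi, params)
      sg <- call_segments(tr, th, params$boundary)
    }
    if (nrow(sg) > 0) {
      sg$test <- test_label; sg$xi_q <- q; sg$xi <- xis[i]
    } else {
      sg$test <- character(0); sg$xi_q <- numeric(0); sg$xi <- numeric(0)
    }
    th$test <- test_label; th$xi_q <- q
    segs[[i]] <- sg; thrs[[i]] <- th
  }
  list(segments = do.call(rbind, segs), thresholds = do.call(rbind, thrs),
       xi = xis)
}
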