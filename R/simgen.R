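#' Simulation configuration for replicated pool-seq scans
#'
#' Defines the study design the generator emulates: two phenotype groups
#' (consecutive vs. skip spawners) sampled in each of two genetically distinct
#' localities, pooled and sequenced at moderate depth, with optional planted
#' regions of replicated phenotype-associated frequency divergence and
#' founder-haplotype LD blocks.
#'
#' Defaults mirror the motivating study design: pool sizes 33/35 (locality A)
#' and 56/59 (locality B) consecutive/skip spawners, pool depth in the
#' 10-100x range (mean 50x), and an alternate-allele frequency spectrum with
#' many rare alleles (Beta(0.25, 1)).
#'
#' @param seed integer RNG seed; all generator output is a pure function of
#'   the full config including this seed.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_sites variant sites per chromosome.
#' @param groups data.frame with columns locality, phenotype, n_individuals;
#'   one row per pool.
#' @param depth_mean mean pool sequencing depth (reads/site/pool).
#' @param depth_dispersion negative-binomial size parameter for depth
#'   overdispersion; `Inf` gives Poisson depth.
#' @param maf_alpha,maf_beta shape of the Beta ancestral alternate-allele
#'   frequency distribution.
#' @param planted_regions data.frame (chrom, start, end, delta_p): regions
#'   where the two phenotypes diverge by `delta_p` identically in every
#'   locality (0-based half-open bp intervals).
#' @param ld_blocks data.frame (chrom, start, end, n_founders): regions where
#'   individual haplotypes are copies of a small founder set, creating
#'   elevated r2.
#' @param centromere optional data.frame (chrom, start, end): a high-LD
#'   region simulated like a 2-founder block and reported in the truth set as
#'   the mask, not as an LD island.
#' @param error_rate per-read base-error probability (alleles flip).
#' @param ind_depth_mean per-individual mean coverage for GL simulation;
#'   `Inf` yields certain (one-hot) genotype likelihoods.
#' @param n_individuals individuals for haplotype/GL simulation.
#' @param drift_concentration Beta concentration for locality drift around
#'   the ancestral frequency; `Inf` (default) disables drift so phenotype
#'   groups within a locality share null frequencies exactly.
#' @param mutation_rate per-site probability that a copied founder haplotype
#'   allele is flipped.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 1L,
                       chrom_length = 1e7,
                       n_sites = 20000L,
                       groups = data.frame(
                         locality = c("A", "A", "B", "B"),
                         phenotype = c("consecutive", "skip",
                                       "consecutive", "skip"),
                         n_individuals = c(33L, 35L, 56L, 59L)),
                       depth_mean = 50,
                       depth_dispersion = 10,
                       maf_alpha = 0.25,
                       maf_beta = 1,
                       planted_regions = NULL,
                       ld_blocks = NULL,
                       centromere = NULL,
                       error_rate = 0.002,
                       ind_depth_mean = 4,
                       n_individuals = 200L,
                       drift_concentration = Inf,
                       mutation_rate = 0.01) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length, n_sites = as.integer(n_sites),
              groups = groups, depth_mean = depth_mean,
              depth_dispersion = depth_dispersion,
              maf_alpha = maf_alpha, maf_beta = maf_beta,
              planted_regions = planted_regions, ld_blocks = ld_blocks,
              centromere = centromere, error_rate = error_rate,
              ind_depth_mean = ind_depth_mean,
              n_individuals = as.integer(n_individuals),
              drift_concentration = drift_concentration,
              mutation_rate = mutation_rate)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_sites >= 1, cfg$chrom_length >= cfg$n_sites,
            cfg$depth_mean > 0, cfg$maf_alpha > 0, cfg$maf_beta > 0,
            cfg$error_rate >= 0, cfg$error_rate < 0.5,
            all(cfg$groups$n_individuals >= 1))
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  for (tab in list(cfg$planted_regions, cfg$ld_blocks, cfg$centromere)) {
    if (is.null(tab)) next
    stopifnot(all(tab$chrom %in% chroms), all(tab$start >= 0),
              all(tab$end > tab$start), all(tab$end <= cfg$chrom_length))
  }
  if (!is.null(cfg$planted_regions))
    stopifnot(all(abs(cfg$planted_regions$delta_p) <= 1))
  if (!is.null(cfg$ld_blocks))
    stopifnot(all(cfg$ld_blocks$n_founders >= 2))
  invisible(cfg)
}

group_labels <- function(groups) paste(groups$locality, groups$phenotype, sep = ".")

#' Simulate per-site true allele frequencies per group
#'
#' Draws an ancestral alternate-allele frequency p0 ~ Beta(maf_alpha,
#' maf_beta) per site. Outside planted regions both phenotypes in a locality
#' share the locality frequency (p0, optionally perturbed by Beta drift per
#' locality). Inside a planted region the first phenotype level gets
#' clamp(p + delta_p/2) and the second clamp(p - delta_p/2), identically in
#' every locality, so the direction of effect is replicated as the CMH design
#' assumes.
#'
#' @param config a [sim_config()].
#' @return list with `sites` (chrom, pos), `freq` (sites x pools matrix of
#'   true pool frequencies), and `truth` (divergent_regions, ld_islands,
#'   centromere).
#' @export
simulate_site_frequencies <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  chrom <- rep(chroms, each = config$n_sites)
  pos <- unlist(lapply(chroms, function(ch)
    sort(sample.int(config$chrom_length, config$n_sites))))
  n <- length(pos)
  p0 <- rbeta(n, config$maf_alpha, config$maf_beta)
  groups <- config$groups
  phen_levels <- unique(groups$phenotype)
  loc_levels <- unique(groups$locality)
  # locality base frequencies (drift off by default: identical to p0)
  loc_freq <- matrix(p0, n, length(loc_levels),
                     dimnames = list(NULL, loc_levels))
  if (is.finite(config$drift_concentration)) {
    k <- config$drift_concentration
    for (l in loc_levels) {
      a <- pmax(p0 * k, 1e-8); b <- pmax((1 - p0) * k, 1e-8)
      loc_freq[, l] <- rbeta(n, a, b)
    }
  }
  shift <- numeric(n)
  if (!is.null(config$planted_regions)) {
    pr <- config$planted_regions
    for (i in seq_len(nrow(pr))) {
      inside <- chrom == pr$chrom[i] & pos - 1 >= pr$start[i] &
        pos - 1 < pr$end[i]
      shift[inside] <- pr$delta_p[i]
    }
  }
  freq <- matrix(0, n, nrow(groups),
                 dimnames = list(NULL, group_labels(groups)))
  for (g in seq_len(nrow(groups))) {
    base <- loc_freq[, groups$locality[g]]
    sgn <- if (groups$phenotype[g] == phen_levels[1]) +0.5 else -0.5
    freq[, g] <- pmin(1, pmax(0, base + sgn * shift))
  }
  truth <- list(
    divergent_regions = if (is.null(config$planted_regions)) empty_regions()
      else regions(config$planted_regions$chrom, config$planted_regions$start,
                   config$planted_regions$end,
                   score = config$planted_regions$delta_p),
    ld_islands = if (is.null(config$ld_blocks)) empty_regions()
      else regions(config$ld_blocks$chrom, config$ld_blocks$start,
                   config$ld_blocks$end),
    centromere = if (is.null(config$centromere)) empty_regions()
      else regions(config$centromere$chrom, config$centromere$start,
                   config$centromere$end))
  list(sites = data.frame(chrom = chrom, pos = pos,
                          stringsAsFactors = FALSE),
       freq = freq, p0 = p0, truth = truth)
}

#' Simulate pooled read counts from true pool frequencies
#'
#' Per pool and site: depth d ~ NegBin(mean = depth_mean, size =
#' depth_dispersion) (Poisson when dispersion is infinite); the pool's
#' realized allele frequency comes from binomial sampling of 2 x pool-size
#' gene copies around the true frequency; alternate reads ~ Binomial(d, p')
#' where p' folds in the per-read error rate as a biallelic flip
#' p'(1 - e) + (1 - p')e. Reference and alternate alleles are assigned
#' distinct nucleotides per site and the result is emitted in sync
#' nucleotide-count layout.
#'
#' @param freqs result of [simulate_site_frequencies()].
#' @param config the same [sim_config()].
#' @return a [pool_counts()] object.
#' @export
simulate_pool_counts <- function(freqs, config) {
  set.seed(config$seed + 1L)
  n <- nrow(freqs$sites)
  groups <- config$groups
  k <- nrow(groups)
  e <- config$error_rate
  # allele nucleotides: ref and a distinct alt per site
  acgt <- c("A", "C", "G", "T")
  ref_i <- sample.int(4, n, replace = TRUE)
  alt_i <- 1L + (ref_i - 1L + sample.int(3, n, replace = TRUE)) %% 4L
  counts <- array(0L, dim = c(n, k, 6))
  for (g in seq_len(k)) {
    p <- freqs$freq[, g]
    copies <- 2L * groups$n_individuals[g]
    p_pool <- rbinom(n, copies, p) / copies
    d <- if (is.finite(config$depth_dispersion))
      rnbinom(n, size = config$depth_dispersion, mu = config$depth_mean)
    else rpois(n, config$depth_mean)
    p_read <- p_pool * (1 - e) + (1 - p_pool) * e
    alt <- rbinom(n, d, p_read)
    refc <- d - alt
    ref_col <- match(acgt[ref_i], NUCS)
    alt_col <- match(acgt[alt_i], NUCS)
    counts[cbind(seq_len(n), g, ref_col)] <- refc
    counts[cbind(seq_len(n), g, alt_col)] <- alt
  }
  pools <- pool_info(group_labels(groups), groups$locality, groups$phenotype,
                     groups$n_individuals)
  pool_counts(freqs$sites$chrom, freqs$sites$pos, acgt[ref_i], counts, pools)
}

#' Simulate phased haplotypes with block LD structure
#'
#' Outside LD blocks, each haplotype's allele at each site is an independent
#' Bernoulli draw from the site's ancestral frequency, so r2 between sites is
#' ~1/(2n) in expectation. Inside an LD block (and the centromere region,
#' simulated as a 2-founder block), each of an individual's two haplotypes is
#' a copy of one of `n_founders` founder haplotypes with a small per-site
#' mutation probability, producing elevated pairwise r2 across the block.
#'
#' @param config a [sim_config()].
#' @param freqs optional result of [simulate_site_frequencies()] to reuse its
#'   site positions and ancestral frequencies; generated if missing.
#' @return list with `sites`, `hap1`, `hap2` (sites x individuals 0/1
#'   matrices), `geno` (hap1 + hap2), and `truth`.
#' @export
simulate_haplotypes_with_ld <- function(config, freqs = NULL) {
  validate_sim_config(config)
  if (is.null(freqs)) freqs <- simulate_site_frequencies(config)
  set.seed(config$seed + 2L)
  n <- nrow(freqs$sites)
  n_ind <- config$n_individuals
  p0 <- freqs$p0
  hap1 <- matrix(rbinom(n * n_ind, 1L, p0), n, n_ind)
  hap2 <- matrix(rbinom(n * n_ind, 1L, p0), n, n_ind)
  blocks <- config$ld_blocks
  if (!is.null(config$centromere)) {
    cen <- config$centromere
    cen$n_founders <- 2L
    blocks <- rbind(blocks[, c("chrom", "start", "end", "n_founders")],
                    cen[, c("chrom", "start", "end", "n_founders")])
  }
  if (!is.null(blocks)) {
    for (b in seq_len(nrow(blocks))) {
      inside <- which(freqs$sites$chrom == blocks$chrom[b] &
                        freqs$sites$pos - 1 >= blocks$start[b] &
                        freqs$sites$pos - 1 < blocks$end[b])
      if (length(inside) == 0) next
      nf <- blocks$n_founders[b]
      founders <- matrix(rbinom(length(inside) * nf, 1L, p0[inside]),
                         length(inside), nf)
      pick1 <- sample.int(nf, n_ind, replace = TRUE)
      pick2 <- sample.int(nf, n_ind, replace = TRUE)
      h1 <- founders[, pick1, drop = FALSE]
      h2 <- founders[, pick2, drop = FALSE]
      if (config$mutation_rate > 0) {
        flip1 <- matrix(rbinom(length(h1), 1L, config$mutation_rate),
                        nrow(h1), ncol(h1))
        flip2 <- matrix(rbinom(length(h2), 1L, config$mutation_rate),
                        nrow(h2), ncol(h2))
        h1 <- (h1 + flip1) %% 2L
        h2 <- (h2 + flip2) %% 2L
      }
      hap1[inside, ] <- h1
      hap2[inside, ] <- h2
    }
  }
  list(sites = freqs$sites, hap1 = hap1, hap2 = hap2, geno = hap1 + hap2,
       truth = freqs$truth)
}

#' Genotype likelihoods from true genotypes under a biallelic read model
#'
#' Per individual and site, the read count is Poisson(ind_depth_mean) and
#' alternate reads are Binomial(c, f_g) with f_0 = error_rate, f_1 = 0.5,
#' f_2 = 1 - error_rate. The genotype likelihood is the binomial pmf of the
#' observed alternate reads under each genotype, normalized to sum to one;
#' individuals with zero reads get the uniform triple. An infinite
#' `ind_depth_mean` returns certain (one-hot) likelihoods.
#'
#' @param genotypes sites x individuals matrix with entries in 0/1/2.
#' @param ind_depth_mean mean per-individual coverage.
#' @param error_rate per-read error probability, in (0, 0.5).
#' @param seed RNG seed.
#' @return sites x individuals x 3 array of normalized likelihoods.
#' @export
genotype_likelihoods_from_genotypes <- function(genotypes, ind_depth_mean,
                                                error_rate, seed = 1L) {
  stopifnot(all(genotypes %in% 0:2))
  n <- nrow(genotypes); m <- ncol(genotypes)
  gl <- array(0, dim = c(n, m, 3))
  if (is.infinite(ind_depth_mean)) {
    for (g in 0:2) gl[, , g + 1] <- (genotypes == g) * 1
    return(gl)
  }
  stopifnot(error_rate > 0, error_rate < 0.5)
  set.seed(seed)
  f <- c(error_rate, 0.5, 1 - error_rate)
  cnt <- matrix(rpois(n * m, ind_depth_mean), n, m)
  altr <- matrix(rbinom(n * m, cnt, f[genotypes + 1]), n, m)
  for (g in 0:2) gl[, , g + 1] <- dbinom(altr, cnt, f[g + 1])
  tot <- gl[, , 1] + gl[, , 2] + gl[, , 3]
  for (g in 0:2) gl[, , g + 1] <- gl[, , g + 1] / tot
  # zero-read individuals: dbinom(0, 0, f) = 1 for all g -> already uniform
  gl
}

#' Simulate a genotype-likelihood matrix with LD structure
#'
#' Convenience wrapper: haplotypes from [simulate_haplotypes_with_ld()], then
#' [genotype_likelihoods_from_genotypes()] at the configured individual
#' coverage, packaged as a [gl_matrix()].
#'
#' @param config a [sim_config()].
#' @param freqs optional frequency simulation to share sites with the pooled
#'   counts.
#' @return list with `gl` (a [gl_matrix()]), `haps` (the haplotype
#'   simulation), and `truth`.
#' @export
simulate_gl_matrix <- function(config, freqs = NULL) {
  haps <- simulate_haplotypes_with_ld(config, freqs)
  gl <- genotype_likelihoods_from_genotypes(
    haps$geno, config$ind_depth_mean,
    max(config$error_rate, 1e-4), seed = config$seed + 3L)
  glm <- gl_matrix(haps$sites$chrom, haps$sites$pos,
                   rep("A", nrow(haps$sites)), rep("C", nrow(haps$sites)), gl)
  list(gl = glm, haps = haps, truth = haps$truth)
}
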