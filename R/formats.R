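#' @importFrom stats quantile median sd pchisq pnorm dbinom dhyper rbeta
#'   rbinom rnbinom rpois psignrank setNames
#' @importFrom utils read.table write.table
NULL

NUCS <- c("A", "T", "C", "G", "N", "del")

#' Pool sample metadata table
#'
#' Builds the per-pool metadata carried by an allele-count matrix: one row per
#' pool with its locality and phenotype labels and the number of individuals
#' pooled.
#'
#' @param pool character vector of pool names.
#' @param locality character vector, sampling locality of each pool.
#' @param phenotype character vector, phenotype group of each pool.
#' @param n_individuals integer vector, individuals contributing to each pool.
#' @return data.frame with columns pool, locality, phenotype, n_individuals.
#' @export
pool_info <- function(pool, locality, phenotype, n_individuals) {
  stopifnot(length(pool) == length(locality),
            length(pool) == length(phenotype),
            length(pool) == length(n_individuals),
            !anyDuplicated(pool))
  data.frame(pool = as.character(pool), locality = as.character(locality),
             phenotype = as.character(phenotype),
             n_individuals = as.integer(n_individuals),
             stringsAsFactors = FALSE)
}

#' Construct an allele-count matrix
#'
#' Container for per-site, per-pool nucleotide read counts in popoolation2
#' sync layout. Positions are 1-based and must be strictly increasing within
#' each chromosome.
#'
#' @param chrom character vector of chromosome labels per site.
#' @param pos integer vector of 1-based positions.
#' @param ref character vector of reference bases.
#' @param counts numeric array of dimension sites x pools x 6, nucleotide
#'   order A, T, C, G, N, del.
#' @param pools pool metadata from [pool_info()].
#' @return object of class `pool_counts`.
#' @export
pool_counts <- function(chrom, pos, ref, counts, pools) {
  n <- length(chrom)
  stopifnot(length(pos) == n, length(ref) == n,
            length(dim(counts)) == 3, dim(counts)[1] == n,
            dim(counts)[3] == 6, dim(counts)[2] == nrow(pools))
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions not strictly increasing within chromosome ", ch)
  }
  dimnames(counts) <- list(NULL, pools$pool, NUCS)
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), counts = counts, pools = pools),
            class = "pool_counts")
}

#' @export
print.pool_counts <- function(x, ...) {
  cat("pool_counts:", length(x$pos), "sites,", nrow(x$pools), "pools,",
      length(unique(x$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Read a popoolation2 sync file
#'
#' Parses tab-separated sync lines of the form
#' `chrom pos ref A:T:C:G:N:del [A:T:C:G:N:del ...]`, one colon-separated
#' count block per pool. Malformed lines are reported by line number.
#'
#' @param path file path.
#' @param pools optional pool metadata ([pool_info()]); if `NULL`, pools are
#'   named pool1..poolK with empty locality/phenotype.
#' @return a [pool_counts()] object.
#' @export
read_sync <- function(path, pools = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty sync file: ", path)
    k <- if (is.null(pools)) 0L else nrow(pools)
    if (is.null(pools))
      pools <- pool_info(character(0), character(0), character(0), integer(0))
    return(pool_counts(character(0), integer(0), character(0),
                       array(0, dim = c(0, k, 6)), pools))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1]))
    stop("sync line ", which(nf != nf[1])[1], ": expected ", nf[1],
         " columns, found ", nf[which(nf != nf[1])[1]])
  if (nf[1] < 4) stop("sync line 1: fewer than 4 columns")
  k <- nf[1] - 3L
  m <- matrix(unlist(fields), ncol = nf[1], byrow = TRUE)
  chrom <- m[, 1]
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos)) stop("sync line ", which(is.na(pos))[1], ": non-integer position")
  counts <- array(0L, dim = c(nrow(m), k, 6))
  for (j in seq_len(k)) {
    parts <- strsplit(m[, 3 + j], ":", fixed = TRUE)
    if (any(lengths(parts) != 6))
      stop("sync line ", which(lengths(parts) != 6)[1],
           ": pool column ", j, " does not have 6 counts")
    v <- suppressWarnings(as.integer(unlist(parts)))
    if (anyNA(v))
      stop("sync line ", ceiling(which(is.na(v))[1] / 6),
           ": non-integer count in pool column ", j)
    counts[, j, ] <- matrix(v, ncol = 6, byrow = TRUE)
  }
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("sync file not sorted: positions not strictly increasing on ", ch,
           " near line ", which(chrom == ch)[which(diff(p) <= 0)[1] + 1L])
  }
  if (is.null(pools))
    pools <- pool_info(paste0("pool", seq_len(k)), rep("", k), rep("", k),
                       rep(0L, k))
  if (nrow(pools) != k)
    stop("pool metadata has ", nrow(pools), " pools but file has ", k)
  pool_counts(chrom, pos, m[, 3], counts, pools)
}

#' Write a pool_counts object as a sync file
#' @param x a [pool_counts()] object.
#' @param path output path.
#' @export
write_sync <- function(x, path) {
  stopifnot(inherits(x, "pool_counts"))
  k <- nrow(x$pools)
  poolcols <- vapply(seq_len(k), function(j) {
    do.call(paste, c(lapply(1:6, function(a) format(x$counts[, j, a], scientific = FALSE, trim = TRUE)),
                     sep = ":"))
  }, character(length(x$pos)))
  if (length(x$pos) == 1) poolcols <- matrix(poolcols, nrow = 1)
  lines <- do.call(paste, c(list(x$chrom, x$pos, x$ref),
                            lapply(seq_len(k), function(j) poolcols[, j]),
                            sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Genomic region table
#'
#' Regions are kept 0-based half-open internally, matching on-disk BED.
#'
#' @param chrom character vector.
#' @param start,end numeric, 0-based half-open bounds; `start < end` required.
#' @param name,score optional per-region annotation.
#' @param strand optional strand (`+`, `-`, `*`).
#' @return data.frame with class `regions` prepended.
#' @export
regions <- function(chrom, start, end, name = NA_character_,
                    score = NA_real_, strand = NA_character_) {
  if (any(start >= end)) stop("region start must be < end")
  if (any(start < 0)) stop("region start must be >= 0")
  out <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                    end = as.numeric(end),
                    name = rep_len(as.character(name), length(chrom)),
                    score = rep_len(as.numeric(score), length(chrom)),
                    strand = rep_len(as.character(strand), length(chrom)),
                    stringsAsFactors = FALSE)
  class(out) <- c("regions", "data.frame")
  out
}

empty_regions <- function() regions(character(0), numeric(0), numeric(0))

#' Write regions to BED
#'
#' BED is 0-based half-open, matching the internal convention, so coordinates
#' are written as-is. Name and score columns are included when present
#' (BED4/BED5/BED6).
#' @param x a [regions()] data.frame.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  if (any(x$start >= x$end)) stop("region start must be < end")
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  has_strand <- "strand" %in% names(x) && any(!is.na(x$strand))
  has_score <- "score" %in% names(x) && (any(!is.na(x$score)) || has_strand)
  has_name <- "name" %in% names(x) && (any(!is.na(x$name)) || has_score)
  if (has_name) cols <- c(cols, list(ifelse(is.na(x$name), ".", x$name)))
  if (has_score) cols <- c(cols, list(ifelse(is.na(x$score), ".",
                                             format(x$score, trim = TRUE))))
  if (has_strand) cols <- c(cols, list(ifelse(is.na(x$strand), ".", x$strand)))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a BED file into a regions table
#' @param path BED3..BED6 file.
#' @return a [regions()] data.frame.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_regions())
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 3)) stop("BED line ", which(nf < 3)[1], ": fewer than 3 columns")
  m <- lapply(seq_len(max(nf)), function(j)
    vapply(f, function(r) if (length(r) >= j) r[j] else NA_character_, ""))
  start <- as.numeric(m[[2]]); end <- as.numeric(m[[3]])
  if (any(start >= end))
    stop("BED line ", which(start >= end)[1], ": start >= end")
  regions(m[[1]], start, end,
          name = if (max(nf) >= 4) na_dot(m[[4]]) else NA_character_,
          score = if (max(nf) >= 5) suppressWarnings(as.numeric(na_dot(m[[5]]))) else NA_real_,
          strand = if (max(nf) >= 6) na_dot(m[[6]]) else NA_character_)
}

na_dot <- function(x) ifelse(is.na(x) | x == ".", NA, x)

#' Read a GFF3 feature file reduced to regions
#'
#' Keeps chromosome, interval (converted from GFF's 1-based closed to the
#' internal 0-based half-open convention), strand, and a name extracted from
#' the attribute column (`Name=` or `ID=`).
#' @param path GFF3 file.
#' @param types optional character vector of feature types to keep (column 3).
#' @return a [regions()] data.frame.
#' @export
read_gff <- function(path, types = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_regions())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 9)) stop("GFF line ", which(lengths(f) < 9)[1],
                                ": fewer than 9 columns")
  m <- matrix(unlist(lapply(f, `[`, 1:9)), ncol = 9, byrow = TRUE)
  keep <- if (is.null(types)) rep(TRUE, nrow(m)) else m[, 3] %in% types
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0) return(empty_regions())
  attr_name <- function(a) {
    for (key in c("Name=[^;]+", "ID=[^;]+")) {
      nm <- regmatches(a, regexpr(key, a))
      if (length(nm)) return(sub("^[^=]+=", "", nm[1]))
    }
    NA_character_
  }
  regions(m[, 1], as.numeric(m[, 4]) - 1, as.numeric(m[, 5]),
          name = vapply(m[, 9], attr_name, "", USE.NAMES = FALSE),
          strand = na_dot(m[, 7]))
}

#' Overlap and proximity between two region sets
#'
#' For every query region, reports each feature that overlaps it (distance 0)
#' or lies within `max_gap` bp of it on the same chromosome. Distance is the
#' gap in bp between the closest ends of the two intervals.
#'
#' @param query,features [regions()] data.frames.
#' @param max_gap maximum gap in bp for a non-overlapping feature to be
#'   reported; 0 reports overlaps only.
#' @return data.frame with columns query (row index into `query`), feature
#'   (row index into `features`), distance.
#' @export
overlap_regions <- function(query, features, max_gap = 0) {
  out <- data.frame(query = integer(0), feature = integer(0),
                    distance = numeric(0))
  if (nrow(query) == 0 || nrow(features) == 0) return(out)
  for (ch in intersect(unique(query$chrom), unique(features$chrom))) {
    qi <- which(query$chrom == ch)
    fi <- which(features$chrom == ch)
    qr <- IRanges::IRanges(start = query$start[qi] + 1, end = query$end[qi])
    fr <- IRanges::IRanges(start = features$start[fi] + 1, end = features$end[fi])
    hits <- IRanges::findOverlaps(qr, fr, maxgap = max_gap)
    if (length(hits) == 0) next
    qh <- S4Vectors::queryHits(hits); fh <- S4Vectors::subjectHits(hits)
    d <- IRanges::distance(qr[qh], fr[fh])
    out <- rbind(out, data.frame(query = qi[qh], feature = fi[fh],
                                 distance = as.numeric(d)))
  }
  out[order(out$query, out$distance, out$feature), , drop = FALSE]
}

# Pairs of (query, feature) indices with >= 1 bp of true overlap.
strict_overlap <- function(query, features) {
  out <- data.frame(query = integer(0), feature = integer(0))
  for (ch in intersect(unique(query$chrom), unique(features$chrom))) {
    qi <- which(query$chrom == ch)
    fi <- which(features$chrom == ch)
    for (i in qi) {
      hit <- fi[features$start[fi] < query$end[i] &
                  features$end[fi] > query$start[i]]
      if (length(hit))
        out <- rbind(out, data.frame(query = i, feature = hit))
    }
  }
  out
}

#' Reduce nucleotide counts to a biallelic site table
#'
#' At each site the two nucleotides with the highest global (summed over
#' pools) read counts define the allele pair; ties are broken by the fixed
#' order A < C < G < T. N and deletion counts are parsed upstream but excluded
#' from allele tallies. The first allele is the globally more frequent one;
#' alternate counts refer to the second.
#'
#' @param x a [pool_counts()] object.
#' @return object of class `biallelic_counts`: chrom, pos, allele1, allele2,
#'   and matrices `alt` (reads of allele2) and `tot` (allele1+allele2 reads),
#'   sites x pools.
#' @export
biallelic_reduce <- function(x) {
  stopifnot(inherits(x, "pool_counts"))
  acgt <- c("A", "C", "G", "T")
  cn <- x$counts[, , match(acgt, NUCS), drop = FALSE]  # tie order A<C<G<T
  glob <- apply(cn, c(1, 3), sum)
  if (length(x$pos) == 0) glob <- matrix(0, 0, 4)
  # order() is stable, so equal counts resolve in A<C<G<T order
  top2 <- t(apply(glob, 1, function(g) order(g, decreasing = TRUE)[1:2]))
  if (length(x$pos) == 0) top2 <- matrix(integer(0), 0, 2)
  n <- length(x$pos); k <- dim(cn)[2]
  a1 <- matrix(0, n, k); a2 <- matrix(0, n, k)
  for (i in seq_len(n)) {
    a1[i, ] <- cn[i, , top2[i, 1]]
    a2[i, ] <- cn[i, , top2[i, 2]]
  }
  colnames(a1) <- colnames(a2) <- x$pools$pool
  structure(list(chrom = x$chrom, pos = x$pos,
                 allele1 = acgt[top2[, 1]], allele2 = acgt[top2[, 2]],
                 alt = a2, tot = a1 + a2, pools = x$pools),
            class = "biallelic_counts")
}

#' @export
print.biallelic_counts <- function(x, ...) {
  cat("biallelic_counts:", length(x$pos), "sites,", nrow(x$pools), "pools\n")
  invisible(x)
}

subset_biallelic <- function(x, keep) {
  structure(list(chrom = x$chrom[keep], pos = x$pos[keep],
                 allele1 = x$allele1[keep], allele2 = x$allele2[keep],
                 alt = x$alt[keep, , drop = FALSE],
                 tot = x$tot[keep, , drop = FALSE], pools = x$pools),
            class = "biallelic_counts")
}

#' Genotype-likelihood matrix container
#'
#' Per-site, per-individual normalized likelihood triples for carrying
#' 0, 1 or 2 copies of the alternate allele.
#'
#' @param chrom,pos site coordinates (1-based positions, sorted within
#'   chromosome).
#' @param allele1,allele2 allele pair labels.
#' @param gl numeric array sites x individuals x 3; each triple must sum to 1.
#' @return object of class `gl_matrix`.
#' @export
gl_matrix <- function(chrom, pos, allele1, allele2, gl) {
  n <- length(chrom)
  stopifnot(length(pos) == n, dim(gl)[1] == n, dim(gl)[3] == 3)
  if (n > 0) {
    s <- gl[, , 1] + gl[, , 2] + gl[, , 3]
    if (any(abs(s - 1) > 1e-6)) stop("GL triples must sum to 1")
  }
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("GL positions not strictly increasing within chromosome ", ch)
  }
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 allele1 = as.character(allele1),
                 allele2 = as.character(allele2), gl = gl),
            class = "gl_matrix")
}

#' Write genotype likelihoods in Beagle text layout
#'
#' Columns: marker (`chrom_pos`), allele1, allele2, then three likelihood
#' columns per individual (genotype 0/1/2 alternate copies).
#' @param x a [gl_matrix()] object.
#' @param path output path.
#' @export
write_beagle <- function(x, path) {
  n_ind <- dim(x$gl)[2]
  hdr <- c("marker", "allele1", "allele2",
           paste0("Ind", rep(seq_len(n_ind), each = 3)))
  flat <- matrix(aperm(x$gl, c(3, 2, 1)), nrow = length(x$pos), byrow = TRUE)
  lines <- do.call(paste, c(list(paste0(x$chrom, "_", x$pos), x$allele1,
                                 x$allele2),
                            lapply(seq_len(ncol(flat)), function(j)
                              format(flat[, j], digits = 8, trim = TRUE)),
                            sep = "\t"))
  writeLines(c(paste(hdr, collapse = "\t"), lines), path)
  invisible(path)
}

#' Read genotype likelihoods from Beagle text layout
#' @param path file written by [write_beagle()] or equivalent.
#' @return a [gl_matrix()] object.
#' @export
read_beagle <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  if ((ncol(tab) - 3) %% 3 != 0)
    stop("Beagle file must have 3 likelihood columns per individual")
  n_ind <- (ncol(tab) - 3) %/% 3
  marker <- tab[[1]]
  us <- regexpr("_[0-9]+$", marker)
  chrom <- substr(marker, 1, us - 1)
  pos <- as.integer(substring(marker, us + 1))
  m <- as.matrix(tab[, -(1:3), drop = FALSE])
  gl <- aperm(array(t(m), dim = c(3, n_ind, nrow(tab))), c(3, 2, 1))
  gl_matrix(chrom, pos, tab[[2]], tab[[3]], gl)
}
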