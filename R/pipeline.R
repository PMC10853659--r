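#' Consensus-rule configuration
#'
#' A candidate region is retained when, for every required test, local-score
#' segments from at least `min_xi_count` distinct xi quantiles overlap it —
#' the "two or more quantiles of xi for both CMH and FET" rule.
#'
#' @param min_xi_count minimum distinct xi quantiles per required test
#'   (default 2).
#' @param require_tests character vector of test labels that must each
#'   supply the xi support (default `c("cmh", "fet")`).
#' @return list of class `consensus_rule`.
#' @export
consensus_rule <- function(min_xi_count = 2L,
                           require_tests = c("cmh", "fet")) {
  stopifnot(min_xi_count >= 1, length(require_tests) >= 1)
  structure(list(min_xi_count = as.integer(min_xi_count),
                 require_tests = require_tests),
            class = "consensus_rule")
}

merge_intervals <- function(chrom, start, end) {
  ord <- order(chrom, start, end)
  chrom <- chrom[ord]; start <- start[ord]; end <- end[ord]
  oc <- character(0); os <- numeric(0); oe <- numeric(0)
  for (i in seq_along(chrom)) {
    n <- length(oc)
    if (n > 0 && oc[n] == chrom[i] && start[i] <= oe[n]) {
      oe[n] <- max(oe[n], end[i])
    } else {
      oc <- c(oc, chrom[i]); os <- c(os, start[i]); oe <- c(oe, end[i])
    }
  }
  data.frame(chrom = oc, start = os, end = oe, stringsAsFactors = FALSE)
}

#' Consensus outlier regions across tests and xi quantiles
#'
#' Candidate regions are the connected components of the union of all
#' segments. A component is retained iff, for each required test, segments
#' from at least `min_xi_count` distinct xi quantiles overlap it; the
#' retained region's span is the union of its supporting segments (those
#' from required tests).
#'
#' @param segments a segment [regions()] data.frame with columns test and
#'   xi_q (e.g. rbind of [local_score_scan()] outputs).
#' @param rule a [consensus_rule()] list.
#' @return a [regions()] data.frame with columns support (e.g.
#'   "cmh:2;fet:3") and n_tests.
#' @export
consensus_regions <- function(segments, rule = consensus_rule()) {
  if (is.null(segments) || nrow(segments) == 0) return(empty_consensus())
  comp <- merge_intervals(segments$chrom, segments$start, segments$end)
  out <- list()
  for (i in seq_len(nrow(comp))) {
    inside <- segments$chrom == comp$chrom[i] &
      segments$start < comp$end[i] & segments$end > comp$start[i]
    sup <- segments[inside, , drop = FALSE]
    counts <- vapply(rule$require_tests, function(tn)
      length(unique(sup$xi_q[sup$test == tn])), integer(1))
    if (any(counts < rule$min_xi_count)) next
    backing <- sup[sup$test %in% rule$require_tests, , drop = FALSE]
    out[[length(out) + 1]] <- data.frame(
      chrom = comp$chrom[i], start = min(backing$start),
      end = max(backing$end),
      support = paste(paste0(rule$require_tests, ":", counts),
                      collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty_consensus())
  df <- do.call(rbind, out)
  r <- regions(df$chrom, df$start, df$end)
  r$support <- df$support
  r
}

empty_consensus <- function() {
  z <- empty_regions()
  z$support <- character(0)
  z
}

#' Label consensus regions with overlapping LD islands
#'
#' A consensus region is labeled with every island sharing at least 1 bp of
#' overlap with it.
#' @param consensus,islands [regions()] data.frames.
#' @return `consensus` with columns ld_island (semicolon-joined
#'   "chrom:start-end" ids, NA if none) and n_islands added.
#' @export
intersect_with_islands <- function(consensus, islands) {
  consensus$ld_island <- NA_character_
  consensus$n_islands <- 0L
  if (nrow(consensus) == 0 || is.null(islands) || nrow(islands) == 0)
    return(consensus)
  hits <- strict_overlap(consensus, islands)
  if (nrow(hits) == 0) return(consensus)
  ids <- paste0(islands$chrom, ":", islands$start, "-", islands$end)
  for (qi in unique(hits$query)) {
    fi <- hits$feature[hits$query == qi]
    consensus$ld_island[qi] <- paste(ids[fi], collapse = ";")
    consensus$n_islands[qi] <- length(fi)
  }
  consensus
}

#' Annotate regions with overlapping or nearby features
#'
#' @param x [regions()] to annotate.
#' @param features gene/feature [regions()] (e.g. from [read_gff()]).
#' @param max_gap report features within this many bp (default 25 kb).
#' @return `x` with columns nearest_feature and feature_distance added.
#' @export
annotate_features <- function(x, features, max_gap = 25000) {
  x$nearest_feature <- NA_character_
  x$feature_distance <- NA_real_
  if (nrow(x) == 0 || is.null(features) || nrow(features) == 0) return(x)
  hits <- overlap_regions(x, features, max_gap = max_gap)
  if (nrow(hits) == 0) return(x)
  for (qi in unique(hits$query)) {
    h <- hits[hits$query == qi, , drop = FALSE]
    best <- h[which.min(h$distance), ]
    nm <- features$name[best$feature]
    x$nearest_feature[qi] <- if (is.na(nm))
      paste0(features$chrom[best$feature], ":",
             features$start[best$feature]) else nm
    x$feature_distance[qi] <- best$distance
  }
  x
}

#' Run the full replicated pool-seq genome scan
#'
#' Stages: biallelic reduction of the allele counts, site filtering,
#' per-site statistics (FST per locality and averaged, FET combined and per
#' locality, CMH across localities), sliding-window FST, local-score scans
#' of the CMH and FET p-value tracks over the configured xi quantiles with
#' permutation thresholds at the FDR target, consensus calling, optional LD
#' windows + island detection from genotype likelihoods, island
#' intersection, and optional feature annotation. Deterministic for a fixed
#' seed (the permutation thresholds are the only stochastic stage).
#'
#' @param counts a [pool_counts()] object or path to a sync file.
#' @param pools pool metadata, required when `counts` is a path.
#' @param filter a [filter_params()] list.
#' @param ls_params a [local_score_params()] list.
#' @param rule a [consensus_rule()] list.
#' @param gl optional [gl_matrix()] (or Beagle path) for the LD stage.
#' @param ld_max_dist distance cap for pairwise LD (default 1e5).
#' @param island an [island_params()] list.
#' @param mask optional high-LD exclusion mask ([regions()]).
#' @param features optional feature [regions()] for annotation.
#' @param fet_per_locality also run local score on each locality's FET track
#'   (default TRUE); these tracks inform the report but the consensus rule
#'   uses the labels in `rule$require_tests`.
#' @param window,step sliding-window width and step in bp.
#' @param min_sites minimum sites per FST window.
#' @param chrom_length optional named chromosome lengths.
#' @param out_dir optional directory; when given, report tables are written
#'   as TSV/BED.
#' @param seed RNG seed (overrides `ls_params$seed`).
#' @return a `report_bundle` list: consensus (annotated), segments,
#'   thresholds, xi, site_stats, fst_windows, ld_windows, islands,
#'   long_range (NULL here; see [long_range_ld_test()]), filter_report, and
#'   stage_log.
#' @export
run_scan <- function(counts, pools = NULL,
                     filter = filter_params(),
                     ls_params = local_score_params(),
                     rule = consensus_rule(),
                     gl = NULL, ld_max_dist = 1e5,
                     island = island_params(),
                     mask = NULL, features = NULL,
                     fet_per_locality = TRUE,
                     window = 1e5, step = 5e3, min_sites = 10,
                     chrom_length = NULL,
                     out_dir = NULL, seed = NULL) {
  log <- list()
  note <- function(stage, ...) {
    msg <- paste0(...)
    message("[", stage, "] ", msg)
    log[[length(log) + 1]] <<- list(stage = stage, detail = msg)
  }
  if (!is.null(seed)) ls_params$seed <- as.integer(seed)
  if (is.character(counts)) counts <- read_sync(counts, pools)
  stopifnot(inherits(counts, "pool_counts"))
  note("read", length(counts$pos), " sites, ", nrow(counts$pools), " pools")

  bc <- biallelic_reduce(counts)
  flt <- filter_sites(bc, filter)
  bc <- subset_biallelic(bc, flt$keep)
  note("filter", flt$sites_in, " sites in, ", flt$sites_retained,
       " retained")
  if (flt$sites_retained == 0) stop("filter stage retained no sites")

  stats <- site_stats(bc)
  note("site_stats", nrow(stats), " sites with FST/FET/CMH")

  fst_win <- sliding_window_mean(stats$chrom, stats$pos, stats$fst,
                                 window = window, step = step,
                                 min_sites = min_sites,
                                 chrom_length = chrom_length)
  note("fst_windows", sum(!is.na(fst_win$mean)), " non-missing windows")

  tracks <- list(cmh = stats$cmh_p, fet = stats$fet_p)
  if (fet_per_locality) {
    loc_cols <- grep("^fet_p_", names(stats), value = TRUE)
    for (cl in loc_cols) tracks[[sub("fet_p_", "fet_", cl)]] <- stats[[cl]]
  }
  segs <- list(); thrs <- list(); xis <- list()
  for (tn in names(tracks)) {
    sc <- local_score_scan(stats$chrom, stats$pos, tracks[[tn]],
                           params = ls_params, test_label = tn)
    segs[[tn]] <- sc$segments; thrs[[tn]] <- sc$thresholds
    xis[[tn]] <- sc$xi
    note("local_score", tn, ": ", nrow(sc$segments), " segments")
  }
  segments <- do.call(rbind, c(segs, list(make.row.names = FALSE)))
  thresholds <- do.call(rbind, c(thrs, list(make.row.names = FALSE)))

  consensus <- consensus_regions(segments, rule)
  note("consensus", nrow(consensus), " consensus regions")

  ld_windows <- NULL; islands <- NULL
  if (!is.null(gl)) {
    if (is.character(gl)) gl <- read_beagle(gl)
    gl <- filter_gl_maf(gl, min_maf = 0.05)
    prs <- pairwise_ld(gl, max_dist = ld_max_dist)
    ld_windows <- window_mean_ld(prs, window = window, step = step,
                                 chrom_length = chrom_length)
    islands <- ld_outlier_islands(ld_windows, island, mask = mask)
    note("ld", nrow(prs), " pairs, ", nrow(islands), " islands")
  }
  consensus <- intersect_with_islands(consensus, islands)
  if (!is.null(features)) consensus <- annotate_features(consensus, features)

  bundle <- list(consensus = consensus, segments = segments,
                 thresholds = thresholds, xi = xis, site_stats = stats,
                 fst_windows = fst_win, ld_windows = ld_windows,
                 islands = islands, filter_report = flt$report,
                 stage_log = log)
  class(bundle) <- "report_bundle"
  if (!is.null(out_dir)) write_report(bundle, out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("poolscan report:", nrow(x$site_stats), "sites analyzed;",
      nrow(x$segments), "local-score segments;",
      nrow(x$consensus), "consensus region(s)\n")
  if (nrow(x$consensus) > 0)
    print(as.data.frame(x$consensus)[, c("chrom", "start", "end", "support",
                                         "ld_island")])
  invisible(x)
}

#' Write report tables of a scan
#'
#' Emits site_stats.tsv, fst_windows.tsv, segments.bed, thresholds.tsv,
#' consensus.tsv, and (when present) ld_windows.tsv and islands.bed.
#' @param bundle a `report_bundle` from [run_scan()].
#' @param out_dir output directory (created if needed).
#' @export
write_report <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(bundle$site_stats, "site_stats.tsv")
  wt(bundle$fst_windows, "fst_windows.tsv")
  wt(as.data.frame(bundle$segments), "segments.tsv")
  if (nrow(bundle$segments) > 0)
    write_bed(regions(bundle$segments$chrom, bundle$segments$start,
                      bundle$segments$end,
                      name = paste0(bundle$segments$test, "_q",
                                    bundle$segments$xi_q),
                      score = bundle$segments$peak),
              file.path(out_dir, "segments.bed"))
  wt(bundle$thresholds, "thresholds.tsv")
  wt(as.data.frame(bundle$consensus), "consensus.tsv")
  if (!is.null(bundle$ld_windows)) wt(bundle$ld_windows, "ld_windows.tsv")
  if (!is.null(bundle$islands) && nrow(bundle$islands) > 0)
    write_bed(bundle$islands, file.path(out_dir, "islands.bed"))
  invisible(out_dir)
}
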