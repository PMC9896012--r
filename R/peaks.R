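# Dual-caller peak detection and consensus. Two deliberately different
# in-house callers stand in for the published MACS/T-PIC pair: caller A tests
# enrichment over an input control, caller B uses smoothed local shape and
# prominence. The consensus / reproducibility / canonical-site logic on top
# is exact.

# overlap helper on 0-based half-open intervals: for each row of `a`, TRUE
# if it overlaps any row of `b` by >= 1 bp
overlaps_any <- function(a, b) {
  out <- logical(nrow(a))
  if (nrow(a) == 0L || nrow(b) == 0L) return(out)
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch)
    bi <- which(b$chrom == ch)
    if (!length(bi)) next
    qa <- IRanges::IRanges(a$start[ai] + 1L, a$end[ai])
    qb <- IRanges::IRanges(b$start[bi] + 1L, b$end[bi])
    out[ai] <- IRanges::overlapsAny(qa, qb)
  }
  out
}

new_peaks <- function(chrom = character(), start = numeric(),
                      end = numeric(), summit = numeric(),
                      score = numeric(), total_count = numeric()) {
  data.frame(chrom = chrom, start = start, end = end,
             name = if (length(chrom)) sprintf("peak_%d", seq_along(chrom))
                    else character(),
             score = score, strand = rep(".", length(chrom)),
             summit = summit, total_count = total_count,
             stringsAsFactors = FALSE)
}

# summit rule shared by both callers: position of maximal depth; on a
# plateau, the floor of the midpoint of the leftmost maximal run
summit_position <- function(depth_bins, bin_index0, binwidth) {
  mx <- max(depth_bins)
  runs <- rle(depth_bins == mx)
  ends <- cumsum(runs$lengths)
  first <- which(runs$values)[1L]
  i1 <- if (first == 1L) 1L else ends[first - 1L] + 1L
  i2 <- ends[first]
  mid_bin <- floor((i1 + i2) / 2)
  floor((bin_index0 + mid_bin - 0.5) * binwidth)
}

#' Caller A: enrichment over an input control
#'
#' Flags bins whose library-size-scaled sample/control fold change exceeds
#' `min_fold` and whose Poisson upper-tail p-value (control rate as the
#' expectation) is below `alpha`; maximal runs of flagged bins are merged
#' within `merge_gap` bp and kept when at least `min_len` bp long. The
#' summit is the position of maximal sample depth.
#'
#' @param sample,control [coverage_track()]s on the same genome.
#' @param min_fold minimum scaled fold change per bin.
#' @param alpha Poisson upper-tail significance per bin.
#' @param min_len minimum peak length (bp).
#' @param merge_gap merge flagged runs separated by at most this many bp.
#' @param fragment_width fragment width used to convert depth area into
#'   count units for `total_count`.
#' @param summit_bandwidth running-mean window (bp) applied to the sample
#'   depth before locating the summit; detection itself uses the raw
#'   bins. Defaults to half the fragment width.
#' @return peak `data.frame` (interval columns plus `summit`, `score` =
#'   mean log2 fold change, `total_count`).
#' @export
call_peaks_enrichment <- function(sample, control, min_fold = 4,
                                  alpha = 1e-4, min_len = 50,
                                  merge_gap = 100, fragment_width = 200,
                                  summit_bandwidth = fragment_width / 2) {
  if (!identical(sort(names(sample$depth)), sort(names(control$depth))))
    stop("sample and control tracks cover different chromosomes")
  out <- list()
  bw <- sample$binwidth
  for (ch in names(sample$depth)) {
    s <- sample$depth[[ch]]
    k <- max(1L, round(summit_bandwidth / bw))
    if (k %% 2L == 0L) k <- k + 1L
    s_sm <- if (k > 1L) as.numeric(stats::filter(s, rep(1 / k, k),
                                                 sides = 2)) else s
    s_sm[is.na(s_sm)] <- 0
    c0 <- control$depth[[ch]] * (sample$libsize / control$libsize)
    c0 <- pmax(c0, 1e-3)
    fold <- s / c0
    pv <- ppois(ceiling(s) - 1, lambda = c0, lower.tail = FALSE)
    flag <- fold >= min_fold & pv < alpha
    if (!any(flag)) next
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    runs <- cbind(starts[r$values], ends[r$values])
    # merge runs separated by <= merge_gap bp
    if (nrow(runs) > 1L) {
      keep <- list(runs[1L, ])
      for (i in 2:nrow(runs)) {
        last <- keep[[length(keep)]]
        if ((runs[i, 1L] - last[2L] - 1L) * bw <= merge_gap)
          keep[[length(keep)]][2L] <- runs[i, 2L]
        else keep[[length(keep) + 1L]] <- runs[i, ]
      }
      runs <- do.call(rbind, keep)
    }
    for (i in seq_len(nrow(runs))) {
      b1 <- runs[i, 1L]; b2 <- runs[i, 2L]
      if ((b2 - b1 + 1L) * bw < min_len) next
      st <- (b1 - 1L) * bw; en <- b2 * bw
      seg <- s[b1:b2]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = st, end = en,
        summit = summit_position(s_sm[b1:b2], b1 - 1L, bw),
        score = mean(log2(fold[b1:b2])),
        total_count = sum(seg) * bw / fragment_width)
    }
  }
  if (!length(out)) return(new_peaks())
  df <- do.call(rbind, out)
  new_peaks(df$chrom, df$start, df$end, df$summit, df$score, df$total_count)
}

#' Caller B: smoothed local shape and prominence
#'
#' Smooths the track with a running mean of width `bandwidth` bp, finds
#' local maxima, and keeps those whose prominence over the flanking minima
#' (up to the nearest higher ground) exceeds `prominence`. Peak extent runs
#' to the half-prominence level on each side. A deliberately different
#' decision rule from [call_peaks_enrichment()].
#'
#' @param sample a [coverage_track()].
#' @param bandwidth smoothing window (bp), must be positive.
#' @param prominence minimum prominence in depth units.
#' @param fragment_width fragment width for `total_count` units.
#' @return peak `data.frame` as in [call_peaks_enrichment()].
#' @export
call_peaks_shape <- function(sample, bandwidth = 50, prominence = 5,
                             fragment_width = 200) {
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  bw <- sample$binwidth
  k <- max(1L, round(bandwidth / bw))
  if (k %% 2L == 0L) k <- k + 1L
  out <- list()
  for (ch in names(sample$depth)) {
    s <- sample$depth[[ch]]
    sm <- if (k > 1L) as.numeric(stats::filter(s, rep(1 / k, k),
                                               sides = 2)) else s
    sm[is.na(sm)] <- 0
    n <- length(sm)
    # candidate summits: strictly higher than both neighbours, or plateau
    # (leftmost bin of a maximal run higher than both flanks)
    r <- rle(sm)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    vals <- r$values
    nk <- length(vals)
    is_max <- vapply(seq_len(nk), function(i) {
      left <- if (i == 1L) -Inf else vals[i - 1L]
      right <- if (i == nk) -Inf else vals[i + 1L]
      vals[i] > left && vals[i] > right
    }, TRUE)
    cand <- which(is_max & vals >= prominence)  # base >= 0, so h >= prom needed
    if (!length(cand)) next
    ord <- cand[order(vals[cand], decreasing = TRUE)]
    taken <- logical(n)
    for (i in ord) {
      h <- vals[i]
      # walk left/right over runs to the first strictly higher run
      lmin <- h; j <- i - 1L
      while (j >= 1L && vals[j] < h) { lmin <- min(lmin, vals[j]); j <- j - 1L }
      if (j < 1L) lmin <- min(lmin, 0)
      rmin <- h; j <- i + 1L
      while (j <= nk && vals[j] < h) { rmin <- min(rmin, vals[j]); j <- j + 1L }
      if (j > nk) rmin <- min(rmin, 0)
      prom <- h - max(lmin, rmin)
      if (prom < prominence) next
      level <- h - prom / 2
      # extent: bins around the summit run with smoothed value > level
      b1 <- starts[i]
      while (b1 > 1L && sm[b1 - 1L] > level) b1 <- b1 - 1L
      b2 <- ends[i]
      while (b2 < n && sm[b2 + 1L] > level) b2 <- b2 + 1L
      if (any(taken[b1:b2])) next     # already claimed by a taller peak
      taken[b1:b2] <- TRUE
      seg <- s[b1:b2]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = (b1 - 1L) * bw, end = b2 * bw,
        summit = summit_position(sm[b1:b2], b1 - 1L, bw),
        score = prom,
        total_count = sum(seg) * bw / fragment_width)
    }
  }
  if (!length(out)) return(new_peaks())
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  new_peaks(df$chrom, df$start, df$end, df$summit, df$score, df$total_count)
}

#' Dual-caller consensus
#'
#' Keeps peaks from caller A that overlap at least one caller-B peak by
#' >= 1 bp; coordinates (and summit, counts) come from caller A.
#'
#' @param peaksA,peaksB peak `data.frame`s.
#' @return subset of `peaksA`.
#' @export
consensus <- function(peaksA, peaksB) {
  peaksA[overlaps_any(peaksA, peaksB), , drop = FALSE]
}

#' Replicate reproducibility
#'
#' Peaks present in both replicates (>= 1 bp overlap); replicate-1
#' coordinates are retained.
#'
#' @param rep1,rep2 peak `data.frame`s from the two replicates.
#' @return subset of `rep1`.
#' @export
reproducible <- function(rep1, rep2) {
  rep1[overlaps_any(rep1, rep2), , drop = FALSE]
}

#' Blacklist exclusion
#'
#' Removes peaks overlapping any blacklist interval by >= 1 bp.
#'
#' @param peaks peak `data.frame`.
#' @param blacklist interval `data.frame`.
#' @return filtered peaks.
#' @export
exclude_blacklist <- function(peaks, blacklist) {
  peaks[!overlaps_any(peaks, blacklist), , drop = FALSE]
}

#' Empirical background threshold
#'
#' The type-7 (linear interpolation) empirical quantile of counts over
#' random background regions; peaks are kept only when their total count
#' strictly exceeds it.
#'
#' @param counts counts over the background regions.
#' @param q quantile level in (0, 1); default 0.9999.
#' @return threshold in count units.
#' @export
background_threshold <- function(counts, q = 0.9999) {
  if (length(counts) == 0L) stop("empty background region set")
  if (length(counts) < 1 / (1 - q))
    warning("fewer than 1/(1-q) background regions; the ", q,
            " quantile is poorly resolved")
  unname(quantile(counts, q, type = 7))
}

#' Filter peaks on the background threshold
#'
#' @param peaks peak `data.frame` with a `total_count` column.
#' @param threshold count threshold from [background_threshold()].
#' @return peaks with `total_count > threshold` (strict).
#' @export
filter_peaks <- function(peaks, threshold) {
  peaks[peaks$total_count > threshold, , drop = FALSE]
}

#' Sample random background regions
#'
#' Non-overlapping regions of the given width placed away from a set of
#' excluded intervals (the planted/known sites), used to build the empirical
#' background distribution.
#'
#' @param n number of regions.
#' @param width region width (bp).
#' @param genome_length,chrom genome geometry.
#' @param exclude interval `data.frame` to avoid (>= 1 bp overlap).
#' @param seed integer seed.
#' @return interval `data.frame`.
#' @export
sample_background_regions <- function(n, width, genome_length,
                                      chrom = "chrS", exclude = NULL,
                                      seed = 1L) {
  set.seed(seed)
  # draw from a lattice of disjoint slots, then drop slots near excluded sites
  n_slots <- floor(genome_length / width)
  slots <- seq_len(n_slots) - 1L
  cand <- genomic_intervals(rep(chrom, n_slots), slots * width,
                            slots * width + width)
  if (!is.null(exclude) && nrow(exclude))
    cand <- cand[!overlaps_any(cand, exclude), , drop = FALSE]
  if (nrow(cand) < n) {
    warning("only ", nrow(cand), " background slots available; using all")
    n <- nrow(cand)
  }
  cand[sort(sample(nrow(cand), n)), , drop = FALSE]
}

#' Canonical binding sites
#'
#' A canonical site is a factor peak reproducible in both replicates that
#' also overlaps (>= 1 bp) an ARNT peak reproducible in both of its
#' replicates. Site coordinates come from the factor peak.
#'
#' @param factor_rep1,factor_rep2 factor peaks per replicate (already
#'   consensus-called and background-filtered).
#' @param arnt_rep1,arnt_rep2 ARNT peaks per replicate.
#' @return peak `data.frame` of canonical sites.
#' @export
canonical_sites <- function(factor_rep1, factor_rep2, arnt_rep1, arnt_rep2) {
  f <- reproducible(factor_rep1, factor_rep2)
  a <- reproducible(arnt_rep1, arnt_rep2)
  consensus(f, a)
}

#' Union of per-condition site universes
#'
#' Sites from successive sets are added only when they do not overlap
#' (>= 1 bp) a site already in the union, so each genomic location is
#' represented once, with coordinates from the first set that contained it.
#'
#' @param site_sets list of peak `data.frame`s.
#' @return one peak `data.frame`.
#' @export
union_sites <- function(site_sets) {
  site_sets <- Filter(function(x) nrow(x) > 0L, site_sets)
  if (!length(site_sets)) return(new_peaks())
  u <- site_sets[[1L]]
  for (s in site_sets[-1L]) {
    add <- s[!overlaps_any(s, u), , drop = FALSE]
    u <- rbind(u[, intersect(names(u), names(add)), drop = FALSE],
               add[, intersect(names(u), names(add)), drop = FALSE])
  }
  u <- u[order(u$chrom, u$start), , drop = FALSE]
  rownames(u) <- NULL
  u
}

#' Venn classification of canonical sites across factors
#'
#' Pools the three factors' site sets, forms connected components under
#' >= 1 bp overlap, and labels each component by the set of factors
#' contributing to it. Counts satisfy inclusion-exclusion exactly on the
#' component labels.
#'
#' @param ahr,hif1,hif2 canonical-site `data.frame`s per factor.
#' @return object of class `venn_sites`: `clusters` (one row per merged
#'   site with logical factor columns and `class`), `counts` (named counts
#'   per exclusive Venn region), `union` (total distinct sites) and
#'   `report` (per-factor overlap percentages via [overlap_percent()]).
#' @export
classify_venn <- function(ahr, hif1, hif2) {
  sets <- list(AHR = ahr, HIF1 = hif1, HIF2 = hif2)
  pooled <- do.call(rbind, lapply(names(sets), function(f) {
    s <- sets[[f]]
    if (nrow(s) == 0L)
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), factor = character()))
    data.frame(chrom = s$chrom, start = s$start, end = s$end, factor = f,
               stringsAsFactors = FALSE)
  }))
  if (nrow(pooled) == 0L)
    stop("no sites supplied")
  comp <- integer(nrow(pooled))
  offset <- 0L
  for (ch in unique(pooled$chrom)) {
    idx <- which(pooled$chrom == ch)
    ir <- IRanges::IRanges(pooled$start[idx] + 1L, pooled$end[idx])
    red <- IRanges::reduce(ir)
    hit <- IRanges::findOverlaps(ir, red, select = "first")
    comp[idx] <- offset + hit
    offset <- offset + length(red)
  }
  comp <- match(comp, sort(unique(comp)))
  present <- function(f) as.logical(tapply(pooled$factor == f, comp, any))
  cl <- data.frame(component = sort(unique(comp)),
                   AHR = present("AHR"), HIF1 = present("HIF1"),
                   HIF2 = present("HIF2"))
  first_idx <- vapply(split(seq_len(nrow(pooled)), comp), min, 0L)
  cl$chrom <- pooled$chrom[first_idx]
  cl$start <- vapply(split(pooled$start, comp), min, 0)
  cl$end <- vapply(split(pooled$end, comp), max, 0)
  cl$class <- apply(cl[, c("AHR", "HIF1", "HIF2")], 1L, function(p)
    paste(c("AHR", "HIF1", "HIF2")[p], collapse = "."))
  counts <- table(factor(cl$class, levels = c(
    "AHR", "HIF1", "HIF2", "AHR.HIF1", "AHR.HIF2", "HIF1.HIF2",
    "AHR.HIF1.HIF2")))
  n_union <- nrow(cl)
  n_multi <- sum(rowSums(cl[, c("AHR", "HIF1", "HIF2")]) > 1L)
  n_shared_ahr_hif <- sum(cl$AHR & (cl$HIF1 | cl$HIF2))
  report <- list(
    union = n_union,
    multi_factor = n_multi,
    pct_multi = overlap_percent(n_multi, n_union),
    pct_of_AHR = overlap_percent(n_shared_ahr_hif, sum(cl$AHR)),
    pct_of_HIF1 = overlap_percent(sum(cl$AHR & cl$HIF1), sum(cl$HIF1)),
    pct_of_HIF2 = overlap_percent(sum(cl$AHR & cl$HIF2), sum(cl$HIF2)))
  structure(list(clusters = cl, counts = c(counts), union = n_union,
                 report = report), class = "venn_sites")
}

#' @export
print.venn_sites <- function(x, ...) {
  cat("Venn classification of", x$union, "distinct canonical sites\n")
  print(x$counts)
  cat("multi-factor sites:", x$report$multi_factor,
      sprintf("(%d%% of union)\n", x$report$pct_multi))
  invisible(x)
}

#' Union size by inclusion-exclusion
#'
#' `|A union B| = |A| + |B| - |A intersect B|`, the arithmetic behind the
#' Venn report's union counts.
#'
#' @param nA,nB set sizes.
#' @param nAB intersection size.
#' @return union size.
#' @export
venn_union <- function(nA, nB, nAB) nA + nB - nAB

#' Overlap percentage, rounded to the nearest integer percent
#'
#' @param n_shared number of shared sites.
#' @param n_total denominator set size.
#' @return integer percent.
#' @export
overlap_percent <- function(n_shared, n_total) {
  if (n_total == 0) return(NA_integer_)
  as.integer(round(100 * n_shared / n_total))
}

#' Annotate sites with the signed distance to the nearest TSS
#'
#' Distance is measured summit-to-TSS and signed in gene coordinates:
#' negative when the summit lies upstream (5') of the TSS with respect to
#' the gene's strand. Ties are broken toward the smaller absolute distance,
#' then toward the first TSS in (chrom, position, gene) sort order.
#'
#' @param sites peak/site `data.frame` with a `summit` column.
#' @param tss `data.frame` with columns `gene`, `chrom`, `pos` (0-based TSS
#'   coordinate) and `strand` (`+`/`-`).
#' @return `sites` with `nearest_gene` and `dist_tss` columns added.
#' @export
annotate_tss <- function(sites, tss) {
  stopifnot(all(c("gene", "chrom", "pos", "strand") %in% names(tss)))
  tss <- tss[order(tss$chrom, tss$pos, tss$gene), , drop = FALSE]
  sites$nearest_gene <- NA_character_
  sites$dist_tss <- NA_real_
  for (i in seq_len(nrow(sites))) {
    cand <- tss[tss$chrom == sites$chrom[i], , drop = FALSE]
    if (!nrow(cand)) next
    ad <- abs(sites$summit[i] - cand$pos)
    j <- which(ad == min(ad))[1L]
    d <- sites$summit[i] - cand$pos[j]
    if (cand$strand[j] == "-") d <- -d
    sites$nearest_gene[i] <- cand$gene[j]
    sites$dist_tss[i] <- d
  }
  sites
}

#' Histogram bins of TSS distances on a symmetric log-spaced grid
#'
#' @param dists signed distances from [annotate_tss()].
#' @param breaks positive log-spaced break points (bp); the grid is
#'   mirrored across zero.
#' @return `data.frame` of bin labels and counts.
#' @export
tss_distance_histogram <- function(dists,
                                   breaks = 10^seq(2, 6, by = 0.5)) {
  grid <- c(-rev(breaks), 0, breaks)
  cut_f <- cut(dists, breaks = grid, include.lowest = TRUE)
  data.frame(bin = levels(cut_f), count = as.integer(table(cut_f)),
             stringsAsFactors = FALSE)
}
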