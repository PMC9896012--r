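# Region counting, RPKM, MA normalisation across samples, summit-distance
# statistics and sample-correlation clustering.

#' Count signal in regions
#'
#' Coverage-level surrogate for fragment counting: the count in a region is
#' the area under the track within it divided by the fragment width. The
#' read-shift used upstream to centre fragments is carried as metadata only.
#'
#' @param track a [coverage_track()].
#' @param regions interval `data.frame`.
#' @param fragment_width fragment width in bp.
#' @return numeric vector of counts, one per region.
#' @export
count_in_regions <- function(track, regions, fragment_width = 200) {
  bw <- track$binwidth
  vapply(seq_len(nrow(regions)), function(i) {
    v <- track$depth[[regions$chrom[i]]]
    if (is.null(v)) return(0)
    b1 <- floor(regions$start[i] / bw) + 1L
    b2 <- min(ceiling(regions$end[i] / bw), length(v))
    if (b2 < b1) return(0)
    sum(v[b1:b2]) * bw / fragment_width
  }, 0)
}

#' Reads per kilobase per million (RPKM)
#'
#' `rpkm = count / (length/1000) / (libsize/1e6)`.
#'
#' @param counts count vector or matrix (features x samples).
#' @param lengths region lengths in bp (recycled across samples).
#' @param libsize per-sample library sizes.
#' @return RPKM values with the shape of `counts`.
#' @export
rpkm <- function(counts, lengths, libsize) {
  if (is.matrix(counts)) {
    sweep(counts / (lengths / 1000), 2L, libsize / 1e6, "/")
  } else {
    counts / (lengths / 1000) / (libsize / 1e6)
  }
}

#' MA normalisation against a reference sample
#'
#' For each sample j an ordinary least squares line `x_ref = u + v * x_j`
#' is fitted over the common features (those occupied in both samples) on
#' the log2 scale (pseudocount added first), and the sample is transformed
#' as `x_j' = u + v * x_j`. After normalisation the log-ratio M shows no
#' mean or trend against the log-average A over the common features.
#'
#' @param mat raw signal matrix (features x samples).
#' @param common logical matrix or vector marking the common features used
#'   for each fit (a vector applies to all samples); at least 10 common
#'   features are required, otherwise the function falls back to a global
#'   median-of-ratios shift with a warning.
#' @param ref reference column (name or index), left unchanged.
#' @param pseudocount added before taking log2 (default 0.5).
#' @param log_input set `TRUE` if `mat` is already on the log2 scale.
#' @return list: `normalised` (log2 matrix), `params` (per-sample `u`, `v`).
#' @export
ma_normalise <- function(mat, common = NULL, ref = 1L, pseudocount = 0.5,
                         log_input = FALSE) {
  x <- if (log_input) as.matrix(mat) else log2(as.matrix(mat) + pseudocount)
  ns <- ncol(x)
  if (is.character(ref)) ref <- match(ref, colnames(x))
  if (is.null(common)) common <- rep(TRUE, nrow(x))
  if (is.vector(common)) common <- matrix(common, nrow(x), ns)
  params <- data.frame(sample = if (is.null(colnames(x)))
    paste0("sample_", seq_len(ns)) else colnames(x), u = 0, v = 1)
  xr <- x[, ref]
  for (j in seq_len(ns)) {
    if (j == ref) next
    msk <- common[, j] & common[, ref]
    if (sum(msk) < 10L) {
      warning("fewer than 10 common features for sample ", colnames(x)[j],
              "; falling back to median-of-ratios shift")
      u <- median(xr - x[, j]); v <- 1
    } else {
      xj <- x[msk, j]
      if (var(xj) == 0) stop("degenerate fit: zero variance in sample ",
                             colnames(x)[j])
      v <- cov(xj, xr[msk]) / var(xj)
      u <- mean(xr[msk]) - v * mean(xj)
    }
    params$u[j] <- u; params$v[j] <- v
    x[, j] <- u + v * x[, j]
  }
  list(normalised = x, params = params)
}

#' Summit distances at shared sites
#'
#' Pairs each site in `sitesA` with the overlapping site in `sitesB`
#' (>= 1 bp; the first overlap in coordinate order) and reports the
#' absolute summit separation, its median, and a two-sided Mann-Whitney
#' comparison against an optional control distance distribution.
#'
#' @param sitesA,sitesB site `data.frame`s with `summit` columns.
#' @param control optional numeric vector of control distances.
#' @return list: `distances`, `median`, and (with a control) `p_value`
#'   from a two-sided Mann-Whitney test.
#' @export
summit_distance <- function(sitesA, sitesB, control = NULL) {
  d <- numeric(0)
  for (ch in unique(sitesA$chrom)) {
    ai <- which(sitesA$chrom == ch)
    bi <- which(sitesB$chrom == ch)
    if (!length(bi)) next
    qa <- IRanges::IRanges(sitesA$start[ai] + 1L, sitesA$end[ai])
    qb <- IRanges::IRanges(sitesB$start[bi] + 1L, sitesB$end[bi])
    hit <- IRanges::findOverlaps(qa, qb, select = "first")
    ok <- !is.na(hit)
    d <- c(d, abs(sitesA$summit[ai][ok] - sitesB$summit[bi][hit[ok]]))
  }
  out <- list(distances = d, median = if (length(d)) median(d) else NA_real_)
  if (!is.null(control) && length(d) && length(control)) {
    out$p_value <- wilcox.test(d, control, exact = FALSE)$p.value
  }
  out
}

#' Pairwise sample correlation and hierarchical clustering
#'
#' Pearson r-squared between all sample pairs over the site universe,
#' followed by average-linkage agglomerative clustering on distance
#' `1 - r^2`. Columns are pre-sorted by label so that merge order is
#' deterministic under ties.
#'
#' @param mat signal matrix (sites x samples), replicate-averaged.
#' @return list: `r2` matrix, `hclust` object, `order` (leaf labels).
#' @export
correlate_and_cluster <- function(mat) {
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  r2 <- cor(mat, method = "pearson")^2
  hc <- hclust(as.dist(1 - r2), method = "average")
  list(r2 = r2, hclust = hc, order = colnames(mat)[hc$order])
}

#' Plot a sample-correlation heat map
#'
#' Base-graphics image of the clustered r-squared matrix.
#'
#' @param cc result of [correlate_and_cluster()].
#' @param ... passed to [graphics::image()].
#' @return invisibly, the reordered matrix.
#' @export
plot_correlation_heatmap <- function(cc, ...) {
  m <- cc$r2[cc$hclust$order, cc$hclust$order]
  n <- ncol(m)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, ]), axes = FALSE,
                  xlab = "", ylab = "",
                  col = grDevices::hcl.colors(50, "Greens", rev = TRUE), ...)
  graphics::axis(1, seq_len(n), colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(n), rev(rownames(m)), las = 2, cex.axis = 0.7)
  invisible(m)
}
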