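#' @importFrom stats median quantile sd var cov cor cor.test wilcox.test
#'   fisher.test p.adjust pnorm ppois rnbinom rpois rnorm runif binom.test
#'   setNames complete.cases hclust as.dist
#' @importFrom utils read.table write.table head tail modifyList
NULL

# ---- genomic intervals -------------------------------------------------------
# All coordinates are 0-based half-open (BED convention). Any 1-based display
# is formatting only.

#' Construct a genomic interval table
#'
#' Creates the interval data frame used throughout the package: 0-based
#' half-open spans with optional name, score and strand columns.
#'
#' @param chrom character vector of chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions (must exceed `start`).
#' @param name optional feature names.
#' @param score optional numeric scores.
#' @param strand strand tokens, one of `"+"`, `"-"`, `"."`.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, score = NULL,
                              strand = NULL) {
  n <- length(chrom)
  if (is.null(name)) name <- rep(".", n)
  if (is.null(score)) score <- rep(0, n)
  if (is.null(strand)) strand <- rep(".", n)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   name = as.character(name),
                   score = as.numeric(score),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(!nzchar(df$chrom))) stop("empty chromosome name")
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop("invalid interval at record ", bad[1L],
         ": require 0 <= start < end (start=", df$start[bad[1L]],
         ", end=", df$end[bad[1L]], ")")
  if (any(!df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(df)
}

#' Read a BED file
#'
#' Parses BED3/BED6(+) records into the package's interval table. Coordinates
#' are kept 0-based half-open exactly as in the file; record order is
#' preserved and columns beyond the sixth are retained as `extra1`,
#' `extra2`, ...
#'
#' @param path path to a tab-separated BED file.
#' @return interval `data.frame` (see [genomic_intervals()]).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(genomic_intervals(character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1L], ": fewer than 3 columns")
  starts <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(starts) || anyNA(ends))
    stop("malformed BED line ", which(is.na(starts) | is.na(ends))[1L],
         ": non-numeric coordinate")
  bad <- which(starts >= ends)
  if (length(bad))
    stop("validation error at BED line ", bad[1L], ": start >= end")
  df <- genomic_intervals(
    chrom = vapply(fields, `[`, "", 1L),
    start = starts, end = ends,
    name = if (max(nf) >= 4L) vapply(fields, function(f)
      if (length(f) >= 4L) f[4L] else ".", "") else NULL,
    score = if (max(nf) >= 5L) suppressWarnings(as.numeric(vapply(
      fields, function(f) if (length(f) >= 5L) f[5L] else "0", ""))) else NULL,
    strand = if (max(nf) >= 6L) vapply(fields, function(f)
      if (length(f) >= 6L) f[6L] else ".", "") else NULL)
  mx <- max(nf)
  if (mx > 6L) {
    for (k in seq_len(mx - 6L)) {
      df[[paste0("extra", k)]] <- vapply(fields, function(f)
        if (length(f) >= 6L + k) f[6L + k] else NA_character_, "")
    }
  }
  df
}

#' Write intervals as BED
#'
#' @param intervals interval `data.frame`.
#' @param path output file path.
#' @param columns number of standard BED columns to write (3 or 6); extra
#'   columns present in `intervals` are appended after the sixth.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, columns = 6L) {
  validate_intervals(intervals)
  base <- intervals[, c("chrom", "start", "end")]
  base$start <- format(base$start, scientific = FALSE, trim = TRUE)
  base$end <- format(base$end, scientific = FALSE, trim = TRUE)
  if (columns >= 6L) {
    base$name <- intervals$name
    base$score <- intervals$score
    base$strand <- intervals$strand
    extra <- grep("^extra", names(intervals), value = TRUE)
    for (e in extra) base[[e]] <- intervals[[e]]
  }
  write.table(base, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- coverage tracks ---------------------------------------------------------

#' Construct a coverage track
#'
#' Binned, chromosome-indexed read-depth arrays with the bin width and the
#' library size (total mapped fragments) attached.
#'
#' @param depth named list of non-negative numeric vectors, one per
#'   chromosome, giving per-bin depth.
#' @param binwidth bin width in bp.
#' @param chromlen named numeric vector of chromosome lengths in bp.
#' @param libsize library size (total mapped fragments), must be positive.
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(depth, binwidth = 1, chromlen = NULL,
                           libsize = NULL) {
  stopifnot(is.list(depth), !is.null(names(depth)))
  if (is.null(chromlen))
    chromlen <- vapply(depth, length, 0) * binwidth
  for (ch in names(depth)) {
    if (any(depth[[ch]] < 0)) stop("negative depth on ", ch)
    if (length(depth[[ch]]) * binwidth < chromlen[[ch]])
      stop("depth array on ", ch, " does not span declared length")
  }
  if (is.null(libsize)) libsize <- max(1, sum(unlist(depth)) * binwidth)
  if (libsize <= 0) stop("library size must be > 0")
  structure(list(depth = depth, binwidth = binwidth,
                 chromlen = chromlen, libsize = libsize),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$depth), "chromosome(s), bin width",
      x$binwidth, "bp, library size", format(x$libsize), "\n")
  invisible(x)
}

#' Read a bedGraph file into a coverage track
#'
#' Records must be sorted and non-overlapping within each chromosome;
#' unspecified positions get depth 0.
#'
#' @param path bedGraph file path.
#' @param chromlen named vector of chromosome lengths; defaults to the
#'   furthest record end per chromosome.
#' @param binwidth bin width of the returned track (bp); record boundaries
#'   must align to it.
#' @return a [coverage_track()].
#' @export
read_bedgraph <- function(path, chromlen = NULL, binwidth = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(
    read.table(path, sep = "\t", col.names = c("chrom", "start", "end", "value"),
               colClasses = c("character", "numeric", "numeric", "numeric")),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) NULL else stop(e)
    })
  if (is.null(tab) || nrow(tab) == 0L) {
    if (is.null(chromlen)) chromlen <- c(chr = binwidth)
    depth <- lapply(chromlen, function(L) numeric(ceiling(L / binwidth)))
    return(coverage_track(depth, binwidth, chromlen, libsize = 1))
  }
  if (any(tab$value < 0)) stop("validation error: negative bedGraph value")
  if (is.null(chromlen))
    chromlen <- tapply(tab$end, tab$chrom, max)
  depth <- list()
  for (ch in names(chromlen)) {
    nb <- ceiling(chromlen[[ch]] / binwidth)
    v <- numeric(nb)
    rec <- tab[tab$chrom == ch, , drop = FALSE]
    if (nrow(rec)) {
      rec <- rec[order(rec$start), , drop = FALSE]
      if (any(rec$start[-1L] < rec$end[-nrow(rec)]))
        stop("validation error: overlapping bedGraph records on ", ch)
      for (i in seq_len(nrow(rec))) {
        b0 <- floor(rec$start[i] / binwidth) + 1L
        b1 <- ceiling(rec$end[i] / binwidth)
        v[b0:b1] <- rec$value[i]
      }
    }
    depth[[ch]] <- v
  }
  coverage_track(depth, binwidth, chromlen)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal depth are collapsed into single records; zero runs are
#' omitted.
#'
#' @param track a [coverage_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$depth)) {
    v <- track$depth[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths) * track$binwidth
    starts <- c(0, ends[-length(ends)])
    keep <- r$values != 0
    if (any(keep)) {
      writeLines(sprintf("%s\t%s\t%s\t%g", ch,
                         format(starts[keep], scientific = FALSE, trim = TRUE),
                         format(pmin(ends[keep], track$chromlen[[ch]]),
                                scientific = FALSE, trim = TRUE),
                         r$values[keep]), con)
    }
  }
  invisible(path)
}

# ---- count matrices ----------------------------------------------------------

#' Construct a count matrix
#'
#' Features-by-samples counts with library sizes and a normalisation state
#' flag that only moves forward (`raw` -> `rpkm` or `ma-normalised`).
#'
#' @param counts numeric matrix, features in rows, samples in columns; must
#'   have row and column names.
#' @param libsize per-sample library sizes; defaults to column sums.
#' @param state normalisation state flag.
#' @param binwidth,shift bin width and read shift used to build a binned
#'   matrix (metadata only).
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, libsize = NULL,
                         state = c("raw", "rpkm", "ma-normalised"),
                         binwidth = NA, shift = NA) {
  state <- match.arg(state)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("feature_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("validation error: duplicate feature IDs")
  if (any(counts < 0, na.rm = TRUE)) stop("negative counts")
  if (is.null(libsize)) libsize <- colSums(counts)
  structure(list(counts = counts, libsize = libsize, state = state,
                 binwidth = binwidth, shift = shift),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples [", x$state, "]\n")
  invisible(x)
}

#' Read a feature-by-sample table
#'
#' First column holds feature IDs, header row holds sample IDs. Round-trips
#' through [write_table()] losslessly for integer counts.
#'
#' @param path TSV path.
#' @return numeric matrix with feature IDs as row names.
#' @export
read_table_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, sep = "\t", header = TRUE, row.names = NULL,
                    check.names = FALSE, colClasses = "character")
  ids <- tab[[1L]]
  if (anyDuplicated(ids))
    stop("validation error: duplicate feature IDs (",
         ids[duplicated(ids)][1L], ")")
  body <- tab[, -1L, drop = FALSE]
  mat <- matrix(NA_real_, nrow(body), ncol(body),
                dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("parse error: non-numeric cell at row '", ids[bad[1L]],
           "', column '", colnames(body)[j], "'")
    mat[, j] <- v
  }
  mat
}

#' Write a feature-by-sample table
#'
#' @param mat numeric matrix with row and column names (or a
#'   [count_matrix()]).
#' @param path output TSV path.
#' @param id_col header for the feature-ID column.
#' @return `path`, invisibly.
#' @export
write_table_matrix <- function(mat, path, id_col = "feature") {
  if (inherits(mat, "count_matrix")) mat <- mat$counts
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- run configuration -------------------------------------------------------

#' Default run configuration
#'
#' Every tunable threshold of the pipeline with its default, in one nested
#' list. Runs log the fully resolved configuration together with the seed so
#' stochastic steps are reproducible.
#'
#' @param seed integer seed for all stochastic stages.
#' @return a named list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    conditions = c("normoxia_vehicle", "normoxia_ITE", "normoxia_FICZ",
                   "hypoxia_vehicle", "hypoxia_ITE", "hypoxia_FICZ"),
    factors = c("AHR", "HIF1", "HIF2", "ARNT"),
    background_quantile = 0.9999,   # empirical background filter level
    caller = list(min_fold = 4, alpha = 1e-4, min_len = 50, merge_gap = 100,
                  bandwidth = 50, prominence = 5),
    pseudocount = 0.5,
    gsea = list(weight = 1, nperm = 10000, ranking = "product"),
    alpha_bh = 0.05,
    flank = 100,                    # bp around summits for motif scanning
    fragment_width = 200,
    bin_size = 1000, shift_size = 150,
    score_aggregate = "mean",
    correlation = "spearman")
  class(cfg) <- c("run_config", "list")
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' @param cfg a configuration list as produced by [default_config()] or
#'   [read_config()].
#' @return `cfg`, invisibly, or an error describing the offending field.
#' @export
validate_config <- function(cfg) {
  q <- cfg$background_quantile
  if (!is.numeric(q) || q <= 0 || q >= 1)
    stop("background_quantile must lie in (0, 1)")
  if (cfg$gsea$nperm < 1) stop("gsea$nperm must be >= 1")
  if (!cfg$gsea$ranking %in% c("product", "literal"))
    stop("gsea$ranking must be 'product' or 'literal'")
  if (cfg$pseudocount < 0) stop("pseudocount must be >= 0")
  if (is.null(cfg$seed)) stop("config must carry a seed")
  invisible(cfg)
}

#' Read / write run configuration as YAML
#'
#' @param path YAML file path.
#' @return for `read_config`, a validated `run_config`; for `write_config`,
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config(seed = if (is.null(cfg$seed)) 1L else cfg$seed)
  cfg <- utils::modifyList(base, cfg)
  class(cfg) <- c("run_config", "list")
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param cfg configuration list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
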