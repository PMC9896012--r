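# shared fixture builders; everything is generated in code at test time

# a single-chromosome track from a depth vector
toy_track <- function(depth, binwidth = 1, chrom = "chr1", libsize = NULL) {
  coverage_track(setNames(list(depth), chrom), binwidth = binwidth,
                 chromlen = setNames(length(depth) * binwidth, chrom),
                 libsize = if (is.null(libsize)) max(1, sum(depth) * binwidth)
                           else libsize)
}

# a triangular bump of given apex height on a flat background
bump_track <- function(n = 2000, apex = 500, height = 20, halfwidth = 100,
                       background = 1) {
  x <- seq_len(n) - 0.5
  d <- background + height * pmax(0, 1 - abs(x - apex) / halfwidth)
  toy_track(d)
}

random_intervals <- function(n, genome = 10000, max_w = 200,
                             chrom = "chr1") {
  s <- sample.int(genome - max_w, n, replace = TRUE)
  genomic_intervals(rep(chrom, n), s,
                    s + sample.int(max_w, n, replace = TRUE),
                    name = sprintf("iv%04d", seq_len(n)))
}

# O(n^2) brute-force >= 1 bp overlap on 0-based half-open intervals
brute_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(a$chrom[i] == b$chrom & a$start[i] < b$end & b$start < a$end[i])
  }, TRUE)
}

as_peaks <- function(iv) {
  iv$summit <- floor((iv$start + iv$end) / 2)
  iv$total_count <- iv$score
  iv
}

# brute-force weighted running-sum enrichment score, step by step
brute_es <- function(pi_sorted, member, weight = 1) {
  N <- length(pi_sorted)
  nh <- sum(member)
  nr <- sum(abs(pi_sorted[member])^weight)
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    run <- if (member[i]) run + abs(pi_sorted[i])^weight / nr
           else run - 1 / (N - nh)
    if (abs(run) > abs(best)) best <- run
  }
  best
}
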