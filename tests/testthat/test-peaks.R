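test_that("the enrichment caller finds constructed bumps and nothing else", {
  flat <- toy_track(rep(1, 2000), libsize = 2000)
  expect_equal(nrow(call_peaks_enrichment(flat, flat)), 0L)

  tr <- bump_track(apex = 500, height = 20)
  ctrl <- toy_track(rep(1, 2000), libsize = tr$libsize)
  pk <- call_peaks_enrichment(tr, ctrl, min_fold = 4, min_len = 20)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$summit - 500), 2)

  # two bumps 1 kb apart stay separate
  x <- seq_len(3000) - 0.5
  d <- 1 + 20 * pmax(0, 1 - abs(x - 800) / 100) +
    20 * pmax(0, 1 - abs(x - 1800) / 100)
  tr2 <- toy_track(d)
  ctrl2 <- toy_track(rep(1, 3000), libsize = tr2$libsize)
  pk2 <- call_peaks_enrichment(tr2, ctrl2, min_fold = 4, min_len = 20)
  expect_equal(nrow(pk2), 2L)

  bad <- toy_track(rep(1, 100), chrom = "chrX")
  expect_error(call_peaks_enrichment(tr, bad), "different chromosomes")
})

test_that("the shape caller uses prominence and plateau midpoints", {
  tr <- bump_track(apex = 500, height = 20)
  pk <- call_peaks_shape(tr, bandwidth = 20, prominence = 5)
  expect_equal(nrow(pk), 1L)
  pk_a <- call_peaks_enrichment(tr, toy_track(rep(1, 2000),
                                              libsize = tr$libsize))
  expect_true(overlaps_any(pk_a, pk)[1])

  # sawtooth noise below the prominence threshold yields nothing
  saw <- toy_track(rep(c(1, 2), 500))
  expect_equal(nrow(call_peaks_shape(saw, bandwidth = 1, prominence = 5)),
               0L)

  # broad plateau: summit at the plateau midpoint
  d <- c(rep(0, 400), rep(10, 201), rep(0, 400))
  pk3 <- call_peaks_shape(toy_track(d), bandwidth = 1, prominence = 5)
  expect_equal(nrow(pk3), 1L)
  expect_equal(pk3$summit, 500)
  expect_error(call_peaks_shape(tr, bandwidth = 0), "bandwidth")
})

test_that("consensus keeps 1 bp overlaps and respects half-open ends", {
  a <- as_peaks(genomic_intervals("chr1", 100, 200))
  b1 <- as_peaks(genomic_intervals("chr1", 199, 300))
  b2 <- as_peaks(genomic_intervals("chr1", 200, 300))
  expect_equal(nrow(consensus(a, b1)), 1L)
  expect_equal(nrow(consensus(a, b2)), 0L)
})

test_that("overlap-based operations agree with the quadratic oracle", {
  set.seed(31)
  for (i in 1:5) {
    a <- as_peaks(random_intervals(60))
    b <- as_peaks(random_intervals(40))
    keep <- brute_overlaps_any(a, b)
    expect_equal(consensus(a, b), a[keep, ], ignore_attr = TRUE)
    expect_equal(reproducible(a, b), a[keep, ], ignore_attr = TRUE)
    expect_equal(exclude_blacklist(a, b), a[!keep, ], ignore_attr = TRUE)
  }
})

test_that("consensus and filters only ever remove caller-A peaks", {
  set.seed(32)
  a <- as_peaks(random_intervals(50))
  b <- as_peaks(random_intervals(30))
  cons <- consensus(a, b)
  expect_true(all(cons$name %in% a$name))
  expect_equal(cons[, c("start", "end")],
               a[match(cons$name, a$name), c("start", "end")],
               ignore_attr = TRUE)
})

test_that("the background threshold is the type-7 quantile", {
  expect_equal(suppressWarnings(background_threshold(1:10000, 0.9999)),
               1 + 0.9999 * 9999)
  expect_equal(background_threshold(rep(7, 100), 0.5), 7)
  expect_equal(background_threshold(1:3, 0.5), 2)
  expect_error(background_threshold(numeric(), 0.5), "empty")
  # sorted-array interpolation oracle
  set.seed(33)
  x <- rnorm(500)
  for (q in c(0.25, 0.9, 0.99)) {
    xs <- sort(x)
    h <- (length(x) - 1) * q + 1
    oracle <- xs[floor(h)] + (h - floor(h)) * (xs[ceiling(h)] - xs[floor(h)])
    expect_equal(background_threshold(x, q), oracle, tolerance = 1e-12)
  }
})

test_that("peak filtering is strict and matches brute force", {
  pk <- as_peaks(genomic_intervals(rep("chr1", 3), c(0, 100, 200),
                                   c(50, 150, 250)))
  pk$total_count <- c(5, 10, 11)
  expect_equal(nrow(filter_peaks(pk, 10)), 1L)
  pk$total_count <- c(0, 2, 3)
  expect_equal(nrow(filter_peaks(pk, 0)), 2L)
  set.seed(34)
  pk2 <- as_peaks(random_intervals(100))
  pk2$total_count <- rpois(100, 20)
  expect_equal(filter_peaks(pk2, 18), pk2[pk2$total_count > 18, ],
               ignore_attr = TRUE)
})

test_that("raising the background quantile never adds peaks", {
  set.seed(35)
  bg <- rpois(5000, 20)
  pk <- as_peaks(random_intervals(200))
  pk$total_count <- rpois(200, 30)
  n_kept <- vapply(c(0.5, 0.9, 0.99, 0.999, 0.9999), function(q)
    nrow(filter_peaks(pk, suppressWarnings(background_threshold(bg, q)))),
    0L)
  expect_true(all(diff(n_kept) <= 0))
})

test_that("canonical sites equal the brute-force four-set intersection", {
  a <- as_peaks(genomic_intervals("chr1", 100, 200))
  no_arnt <- as_peaks(genomic_intervals("chr1", 5000, 5100))
  expect_equal(nrow(canonical_sites(a, a, no_arnt, no_arnt)), 0L)
  expect_equal(nrow(canonical_sites(a, a, a, a)), 1L)
  set.seed(36)
  f1 <- as_peaks(random_intervals(50)); f2 <- as_peaks(random_intervals(50))
  a1 <- as_peaks(random_intervals(50)); a2 <- as_peaks(random_intervals(50))
  got <- canonical_sites(f1, f2, a1, a2)
  keep_f <- brute_overlaps_any(f1, f2)
  rep_f <- f1[keep_f, ]
  rep_a <- a1[brute_overlaps_any(a1, a2), ]
  expect_equal(got, rep_f[brute_overlaps_any(rep_f, rep_a), ],
               ignore_attr = TRUE)
})

test_that("Venn classification matches brute-force set computation", {
  # disjoint toy sets: no intersections, union 3
  mk <- function(s) as_peaks(genomic_intervals("chr1", s, s + 100))
  v <- classify_venn(mk(0), mk(1000), mk(2000))
  expect_equal(v$union, 3L)
  expect_equal(unname(v$counts[c("AHR", "HIF1", "HIF2")]), c(1L, 1L, 1L))
  expect_equal(sum(v$counts[grepl("\\.", names(v$counts))]), 0L)

  set.seed(37)
  for (i in 1:3) {
    ahr <- random_intervals(30, genome = 5000)
    hif1 <- random_intervals(30, genome = 5000)
    hif2 <- random_intervals(20, genome = 5000)
    v <- classify_venn(as_peaks(ahr), as_peaks(hif1), as_peaks(hif2))
    # brute-force connected components on the pooled intervals
    pool <- rbind(cbind(ahr[1:3], f = "AHR"), cbind(hif1[1:3], f = "HIF1"),
                  cbind(hif2[1:3], f = "HIF2"))
    n <- nrow(pool)
    adj <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
      pool$start[i] < pool$end[j] && pool$start[j] < pool$end[i]))
    comp <- seq_len(n)
    repeat {
      new <- vapply(seq_len(n), function(i) min(comp[adj[i, ]]), 0L)
      if (identical(new, comp)) break
      comp <- new
    }
    classes <- vapply(split(pool$f, comp), function(fs)
      paste(c("AHR", "HIF1", "HIF2")[c("AHR", "HIF1", "HIF2") %in% fs],
            collapse = "."), "")
    expect_equal(v$union, length(unique(comp)))
    expect_equal(unname(c(v$counts[v$counts > 0])),
                 unname(c(table(classes)[names(v$counts[v$counts > 0])])))
    # inclusion-exclusion holds exactly on the component labels
    cl <- v$clusters
    expect_equal(venn_union(sum(cl$HIF1), sum(cl$HIF2),
                            sum(cl$HIF1 & cl$HIF2)),
                 sum(cl$HIF1 | cl$HIF2))
  }
})

test_that("TSS annotation signs distances in gene coordinates", {
  tss <- data.frame(gene = c("gplus", "gminus"),
                    chrom = c("chr1", "chr1"),
                    pos = c(1500, 500), strand = c("+", "-"))
  s <- as_peaks(genomic_intervals("chr1", 950, 1050))
  s$summit <- 1000
  ann_p <- annotate_tss(s, tss[1, ])
  expect_equal(ann_p$dist_tss, -500)     # 500 bp 5' of a + gene
  ann_m <- annotate_tss(s, tss[2, ])
  expect_equal(ann_m$dist_tss, -500)     # 500 bp 5' reading the - strand
})

test_that("nearest-TSS assignment matches brute-force search", {
  set.seed(38)
  tss <- data.frame(gene = paste0("g", 1:40), chrom = "chr1",
                    pos = sample.int(10000, 40),
                    strand = sample(c("+", "-"), 40, TRUE))
  s <- as_peaks(random_intervals(30))
  ann <- annotate_tss(s, tss)
  for (i in seq_len(nrow(s))) {
    d <- abs(s$summit[i] - tss$pos)
    expect_equal(abs(ann$dist_tss[i]), min(d))
  }
  h <- tss_distance_histogram(ann$dist_tss)
  expect_equal(sum(h$count), nrow(s))
})

test_that("planted sites are recovered as canonical sites", {
  m <- occupancy_model(n_sites = c(AHR = 20, AHR.HIF1 = 10))
  cfg <- default_config(seed = 3L)
  set.seed(301)
  sites <- simulate_sites(m, genome_length = 2e5, spacing = 3000)
  occ <- simulate_occupancy(m, sites, "normoxia_ITE")
  sim_f <- simulate_chip(occ[, "AHR"], sites, factor = "AHR", scale = 40,
                         background = 5, alpha = 0.02,
                         genome_length = 2e5, seed = 302L)
  sim_a <- simulate_chip(occ[, "ARNT"], sites, factor = "ARNT", scale = 40,
                         background = 5, alpha = 0.02,
                         genome_length = 2e5, seed = 303L)
  ctrl <- simulate_chip(rep(0, nrow(sites)), sites, scale = 40,
                        background = 5, alpha = 0.02, replicates = 1,
                        genome_length = 2e5, seed = 304L)$tracks[[1]]
  bg <- sample_background_regions(300, 400, 2e5, exclude = sites,
                                  seed = 305L)
  call_one <- function(tr) {
    pk <- consensus(call_peaks_enrichment(tr, ctrl),
                    call_peaks_shape(tr, bandwidth = 50, prominence = 5))
    thr <- suppressWarnings(background_threshold(
      count_in_regions(tr, bg), cfg$background_quantile))
    filter_peaks(pk, thr)
  }
  canon <- canonical_sites(call_one(sim_f$tracks$rep1),
                           call_one(sim_f$tracks$rep2),
                           call_one(sim_a$tracks$rep1),
                           call_one(sim_a$tracks$rep2))
  planted_found <- brute_overlaps_any(sites, canon)
  expect_gte(mean(planted_found), 0.95)
  unplanted <- !brute_overlaps_any(canon, sites)
  expect_lte(mean(unplanted), 0.01)
})
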