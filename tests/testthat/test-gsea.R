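test_that("size factors recover scalings and ignore gene order", {
  set.seed(71)
  m <- matrix(rpois(500 * 4, 100), 500,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:4)))
  m[, 1] <- m[, 2]
  expect_equal(unname(size_factors(cbind(m[, 1], m[, 1]))), c(1, 1))
  doubled <- cbind(m, s5 = 2 * m[, 1])
  sf <- size_factors(doubled)
  expect_equal(unname(sf["s5"] / sf[1]), 2, tolerance = 1e-10)
  perm <- sample(nrow(m))
  expect_equal(size_factors(m[perm, ]), size_factors(m))
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(72)
  m <- matrix(rnbinom(300 * 6, mu = 150, size = 8), 300,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:6)))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("the ranking statistic follows its two documented modes", {
  de <- data.frame(feature = c("up", "null", "down"),
                   phi = c(2, 0, -2),
                   p_value = c(0.01, 0.5, 0.01),
                   q_value = c(0.03, 0.5, 0.03))
  rk <- rank_genes(de, mode = "product")
  expect_equal(rk$pi[rk$gene == "up"], 4)
  expect_equal(rk$pi[rk$gene == "null"], 0)
  expect_equal(rk$pi[rk$gene == "down"], -4)
  lit <- rank_genes(de, mode = "literal")
  expect_equal(lit$pi[lit$gene == "up"], 4)
  # the two readings diverge for significant down-regulation
  expect_equal(lit$pi[lit$gene == "down"], 0)
  grid <- expand.grid(phi = c(-2, 2), p = c(0.01, 0.5))
  div <- data.frame(grid,
                    product = grid$phi * (-log10(grid$p)),
                    literal = grid$phi - log10(grid$p))
  expect_true(any(sign(div$product) != sign(div$literal)))
})

test_that("the enrichment score hits its boundary case", {
  rk <- data.frame(gene = paste0("g", 1:20), pi = seq(20, 1))
  res <- gsea_preranked(rk, "g1", nperm = 50, seed = 1L)
  expect_equal(res$es, 1)
  expect_error(gsea_preranked(rk, character(0)), "empty")
  expect_error(gsea_preranked(rk, rk$gene), "as large as")
  expect_error(gsea_preranked(rk, "absent"), "no member")
})

test_that("ES equals the brute-force running sum on 50-gene lists", {
  set.seed(73)
  for (i in 1:10) {
    pi <- sort(rnorm(50, 0, 2), decreasing = TRUE)
    rk <- data.frame(gene = paste0("g", 1:50), pi = pi)
    gs <- sample(rk$gene, sample(3:15, 1))
    got <- gsea_preranked(rk, gs, nperm = 1, seed = i)$es
    expect_equal(got, brute_es(pi, rk$gene %in% gs), tolerance = 1e-12)
  }
})

test_that("ES agrees with the fgsea statistic and negates under reversal", {
  skip_if_not_installed("fgsea")
  set.seed(74)
  pi <- sort(rnorm(200, 0, 2), decreasing = TRUE)
  rk <- data.frame(gene = paste0("g", 1:200), pi = pi)
  for (i in 1:5) {
    gs <- sample(rk$gene, 15)
    es <- gsea_preranked(rk, gs, nperm = 1, seed = i)$es
    ref <- fgsea::calcGseaStat(setNames(pi, rk$gene),
                               selectedStats = which(rk$gene %in% gs),
                               gseaParam = 1)
    expect_equal(es, ref, tolerance = 1e-8)
    rev_rk <- data.frame(gene = rev(rk$gene), pi = -rev(pi))
    es_rev <- gsea_preranked(rev_rk, gs, nperm = 1, seed = i)$es
    expect_equal(es_rev, -es, tolerance = 1e-8)
  }
  expect_true(abs(gsea_preranked(rk, rk$gene[seq(1, 200, by = 10)],
                                 nperm = 1, seed = 1)$es) < 0.35)
})

test_that("gene-set construction follows the binding/induction rules", {
  sc <- data.frame(nearest_gene = c("gA", "gA", "gH", "gC", "gX"),
                   class = c("AHR", "AHR", "HIF1", "AHR.HIF1", "AHR"))
  de_up <- function(genes, universe) data.frame(
    feature = universe, phi = ifelse(universe %in% genes, 2, 0),
    p_value = ifelse(universe %in% genes, 1e-6, 0.9),
    q_value = ifelse(universe %in% genes, 1e-5, 0.9))
  uni <- c("gA", "gH", "gC", "gX")
  sets <- build_gene_sets(sc, de_ite = de_up(c("gA", "gC"), uni),
                          de_hypoxia = de_up(c("gH", "gC"), uni))
  expect_setequal(sets$ahr_bound_only, c("gA", "gX"))
  expect_equal(sets$hif_bound_only, "gH")
  expect_equal(sets$co_bound, "gC")
  expect_equal(sets$ahr_targets, "gA")   # gX bound but not induced
  expect_equal(sets$hif_targets, "gH")
  expect_equal(sets$common_targets, "gC")
  # row order never matters
  sets2 <- build_gene_sets(sc[sample(5), ], de_ite = de_up(c("gA", "gC"), uni),
                           de_hypoxia = de_up(c("gH", "gC"), uni))
  expect_identical(sets, sets2)
})

test_that("randomised gene-set construction matches brute-force set algebra", {
  set.seed(75)
  for (i in 1:3) {
    genes <- paste0("g", 1:30)
    sc <- data.frame(
      nearest_gene = sample(genes, 60, replace = TRUE),
      class = sample(c("AHR", "HIF1", "HIF2", "AHR.HIF1", "AHR.HIF2",
                       "HIF1.HIF2"), 60, replace = TRUE))
    de1 <- data.frame(feature = genes, phi = rnorm(30),
                      p_value = runif(30))
    de1$q_value <- bh_adjust(de1$p_value)
    de2 <- data.frame(feature = genes, phi = rnorm(30),
                      p_value = runif(30))
    de2$q_value <- bh_adjust(de2$p_value)
    sets <- suppressWarnings(build_gene_sets(sc, de1, de2, alpha = 0.3))
    for (g in genes) {
      cls <- sc$class[sc$nearest_gene == g]
      if (!length(cls)) next
      ahr <- any(grepl("AHR", cls)); hif <- any(grepl("HIF", cls))
      expect_equal(g %in% sets$ahr_bound_only, ahr && !hif)
      expect_equal(g %in% sets$co_bound, ahr && hif)
      up1 <- de1$phi[de1$feature == g] > 0 & de1$q_value[de1$feature == g] < 0.3
      up2 <- de2$phi[de2$feature == g] > 0 & de2$q_value[de2$feature == g] < 0.3
      expect_equal(g %in% sets$common_targets, ahr && hif && up1 && up2)
    }
  }
})

test_that("additivity recovery holds for an additive generator", {
  set.seed(76)
  n_genes <- 40
  genes <- data.frame(gene = paste0("g", 1:n_genes),
                      site = "s1", base = 300, beta = 1)
  # independent additive effects: each stimulus contributes its own
  # occupancy increment, the combination sums in log space
  occ0 <- c(s1 = 0); occ_h <- c(s1 = 5); occ_i <- c(s1 = 7)
  occ_b <- c(s1 = 12)
  cts <- function(occ, seed) simulate_rna(genes, occ, occ_max = 10,
                                          alpha = 0.05, n = 6, seed = seed)
  de_h <- nb_wald(cts(occ0, 1), cts(occ_h, 2), alpha = 0.05)
  de_i <- nb_wald(cts(occ0, 3), cts(occ_i, 4), alpha = 0.05)
  de_b <- nb_wald(cts(occ0, 5), cts(occ_b, 6), alpha = 0.05)
  add <- additivity(de_h, de_i, de_b, genes$gene)
  expect_equal(unname(add$medians["phi_both"]),
               unname(add$medians["phi_additive"]), tolerance = 0.15)
  # all-zero effects: all medians near zero
  de0a <- nb_wald(cts(occ0, 7), cts(occ0, 8), alpha = 0.05)
  de0b <- nb_wald(cts(occ0, 9), cts(occ0, 10), alpha = 0.05)
  de0c <- nb_wald(cts(occ0, 11), cts(occ0, 12), alpha = 0.05)
  add0 <- additivity(de0a, de0b, de0c, genes$gene)
  expect_lt(max(abs(add0$medians)), 0.1)
  one <- additivity(de_h, de_i, de_b, "g1")
  expect_equal(nrow(one$table), 1L)
  expect_equal(unname(one$medians["phi_hyp"]), one$table$phi_hyp)
})

test_that("GSEA p-values are uniform under a null ranking", {
  set.seed(77)
  rk <- data.frame(gene = paste0("g", 1:800), pi = rnorm(800))
  rk <- rk[order(-rk$pi), ]
  ps <- vapply(1:300, function(i)
    gsea_preranked(rk, sample(rk$gene, 20), nperm = 200,
                   seed = 10000L + i)$p_value, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
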