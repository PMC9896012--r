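# Gene-level differential expression, target-set construction from binding
# classes, the pre-ranking statistic, weighted pre-ranked GSEA and the
# dual-target additivity analysis.

#' Median-of-ratios size factors
#'
#' Each sample's factor is the median ratio of its counts to the
#' geometric-mean pseudo-reference, over genes with all-positive counts.
#'
#' @param counts genes x samples count matrix.
#' @return named per-sample size factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts <= 0) == 0L
  if (!any(keep)) stop("no gene has all-positive counts")
  lg <- log(counts[keep, , drop = FALSE])
  ref <- rowMeans(lg)
  apply(lg, 2L, function(x) exp(median(x - ref)))
}

#' Gene-level differential expression
#'
#' Size-factor normalisation followed by the package's NB Wald machinery
#' ([estimate_dispersion()] + [nb_wald()]) and BH adjustment.
#'
#' @param counts genes x samples matrix covering both groups.
#' @param group1,group2 column names or indices of the two groups.
#' @param eps pseudocount for the fold change.
#' @return a `diff_result` data frame (see [nb_wald()]).
#' @export
gene_de <- function(counts, group1, group2, eps = 0.5) {
  counts <- as.matrix(counts)
  sf <- size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  c1 <- norm[, group1, drop = FALSE]
  c2 <- norm[, group2, drop = FALSE]
  alpha <- estimate_dispersion(cbind(c1, c2))
  nb_wald(c1, c2, alpha = alpha, eps = eps)
}

#' Build target gene sets from binding classes and induction calls
#'
#' Genes are linked to sites by nearest TSS (each site votes for its
#' nearest gene). A gene is "bound only" by a factor when it has at least
#' one linked site and every linked site carries only that factor's class;
#' "co-bound" when it is linked to at least one AHR-class site and one
#' HIF-class site (possibly the same shared site). "Up-regulated" means
#' `phi > 0` and `q < alpha` in the given contrast. Common targets are
#' co-bound genes up-regulated under both stimuli.
#'
#' @param site_classes `data.frame` with columns `nearest_gene` and
#'   `class` (dot-separated factor memberships, e.g. `"AHR.HIF1"`).
#' @param de_ite,de_hypoxia `diff_result` tables for the AHR-stimulus and
#'   hypoxia contrasts.
#' @param alpha BH significance threshold for "up-regulated".
#' @return list of character vectors: `ahr_bound_only`, `hif_bound_only`,
#'   `co_bound`, `ahr_targets`, `hif_targets`, `common_targets`.
#' @export
build_gene_sets <- function(site_classes, de_ite, de_hypoxia,
                            alpha = 0.05) {
  site_classes <- site_classes[!is.na(site_classes$nearest_gene), ,
                               drop = FALSE]
  members <- strsplit(site_classes$class, ".", fixed = TRUE)
  has_ahr <- vapply(members, function(m) "AHR" %in% m, TRUE)
  has_hif <- vapply(members, function(m) any(c("HIF1", "HIF2") %in% m), TRUE)
  genes <- sort(unique(site_classes$nearest_gene))
  g_ahr <- tapply(has_ahr, site_classes$nearest_gene, any)[genes]
  g_hif <- tapply(has_hif, site_classes$nearest_gene, any)[genes]
  ahr_bound_only <- genes[g_ahr & !g_hif]
  hif_bound_only <- genes[g_hif & !g_ahr]
  co_bound <- genes[g_ahr & g_hif]
  up <- function(de) de$feature[de$phi > 0 & de$q_value < alpha]
  up_ite <- up(de_ite)
  up_hyp <- up(de_hypoxia)
  sets <- list(ahr_bound_only = ahr_bound_only,
               hif_bound_only = hif_bound_only,
               co_bound = co_bound,
               ahr_targets = intersect(ahr_bound_only, up_ite),
               hif_targets = intersect(hif_bound_only, up_hyp),
               common_targets = intersect(co_bound,
                                          intersect(up_ite, up_hyp)))
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty))
    warning("empty gene set(s): ", paste(empty, collapse = ", "))
  sets
}

#' Pre-ranking statistic
#'
#' Combines the log2 fold change and the p-value into one ranking score.
#' The default `"product"` mode uses the sign-aware product
#' `pi = phi * (-log10 p)`; the `"literal"` mode uses the difference
#' `pi = phi - log10(p)`. P-values are floored at 1e-300; ties in `pi`
#' are broken by gene ID for determinism.
#'
#' @param de a `diff_result` table.
#' @param mode `"product"` or `"literal"`.
#' @return `data.frame` (`gene`, `pi`) sorted by decreasing `pi`.
#' @export
rank_genes <- function(de, mode = c("product", "literal")) {
  mode <- match.arg(mode)
  p <- pmax(de$p_value, 1e-300)
  pi <- switch(mode,
               product = de$phi * (-log10(p)),
               literal = de$phi - log10(p))
  out <- data.frame(gene = de$feature, pi = pi, stringsAsFactors = FALSE)
  out[order(-out$pi, out$gene), , drop = FALSE]
}

# weighted running-sum enrichment score for hit positions `pos` (sorted,
# 1-based) in a ranked list of length N with |pi| weights `w_abs`
gsea_es <- function(pos, w_abs, N, weight = 1) {
  k <- length(pos)
  wh <- w_abs[pos]^weight
  nr <- sum(wh)
  wh <- if (nr == 0) rep(1 / k, k) else wh / nr   # all-zero weights: uniform
  miss <- 1 / (N - k)
  cum_hit <- cumsum(wh)
  # running value right after hit j, and right before hit j
  after <- cum_hit - (pos - seq_len(k)) * miss
  before <- c(0, cum_hit[-k]) - (pos - 1L - (seq_len(k) - 1L)) * miss
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Pre-ranked weighted GSEA
#'
#' Running-sum statistic over the ranked list: hits add
#' `|pi|^w / sum_hits |pi|^w`, misses subtract `1/(N - N_hit)`; the
#' enrichment score is the signed maximum deviation. The null is built
#' from random gene sets of equal size drawn without replacement, and the
#' p-value compares against same-sign null scores:
#' `p = (1 + #{same sign, |ES_null| >= |ES|}) / (n_same_sign + 1)`.
#'
#' @param ranked ranked table from [rank_genes()].
#' @param gene_set character vector of genes.
#' @param weight GSEA weight `w` (default 1).
#' @param nperm number of permutations (default 10000).
#' @param seed integer seed for the permutation null.
#' @return list of class `gsea_result`: `es`, `p_value`, `n_hits`,
#'   `nperm`, `seed`.
#' @export
gsea_preranked <- function(ranked, gene_set, weight = 1, nperm = 10000,
                           seed = 1L) {
  N <- nrow(ranked)
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0L) stop("empty gene set")
  hits <- which(ranked$gene %in% gene_set)
  k <- length(hits)
  if (k == 0L) stop("gene set has no member in the ranked universe")
  if (k >= N) stop("gene set as large as the ranked universe")
  w_abs <- abs(ranked$pi)
  es <- gsea_es(hits, w_abs, N, weight)
  set.seed(seed)
  null_es <- vapply(seq_len(nperm), function(i)
    gsea_es(sort(sample.int(N, k)), w_abs, N, weight), 0)
  same <- null_es[sign(null_es) == sign(es)]
  p <- (1 + sum(abs(same) >= abs(es))) / (length(same) + 1)
  structure(list(es = es, p_value = p, n_hits = k, nperm = nperm,
                 seed = seed), class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.3f, p = %.4g (%d hits, %d permutations)\n",
              x$es, x$p_value, x$n_hits, x$nperm))
  invisible(x)
}

#' Additivity of dual-target regulation
#'
#' For each common-target gene, compares the response to each stimulus
#' alone and to the combination against the additive prediction
#' `phi_hyp + phi_ite`, and tests whether the combined response exceeds
#' the larger single response by a sign test.
#'
#' @param de_hyp,de_ite,de_both `diff_result` tables for hypoxia alone,
#'   the AHR ligand alone, and the combination (all vs the same control).
#' @param genes common-target gene IDs.
#' @return list: `table` (per-gene `phi_hyp`, `phi_ite`, `phi_both`,
#'   `phi_additive`), `medians`, `p_super_additive` (sign test of
#'   `phi_both > max(phi_hyp, phi_ite)`).
#' @export
additivity <- function(de_hyp, de_ite, de_both, genes) {
  pick <- function(de) de$phi[match(genes, de$feature)]
  tab <- data.frame(gene = genes,
                    phi_hyp = pick(de_hyp),
                    phi_ite = pick(de_ite),
                    phi_both = pick(de_both),
                    stringsAsFactors = FALSE)
  tab$phi_additive <- tab$phi_hyp + tab$phi_ite
  med <- vapply(tab[, -1L], median, 0, na.rm = TRUE)
  gt <- tab$phi_both > pmax(tab$phi_hyp, tab$phi_ite)
  gt <- gt[!is.na(gt)]
  p <- if (length(gt)) binom.test(sum(gt), length(gt))$p.value else NA_real_
  list(table = tab, medians = med, p_super_additive = p)
}
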