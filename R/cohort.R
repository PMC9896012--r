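# Signature definition, metagene composite scoring of a paired
# tumour/normal cohort, paired testing, copy-number stratification and
# score correlation.

#' Define disjoint pathway signatures
#'
#' HIF signature = HIF-bound-only and hypoxia-up genes; AHR signature =
#' AHR-bound-only and ligand-up genes; genes appearing in both candidate
#' lists are excluded from both single-factor signatures and the common
#' set is carried separately.
#'
#' @param hif_candidates,ahr_candidates candidate gene vectors (bound-only
#'   and up-regulated, from [build_gene_sets()]).
#' @param common_targets common-target gene vector.
#' @return list of class `signatures` with `HIF`, `AHR`, `common`
#'   character vectors; `HIF` and `AHR` are disjoint from each other and
#'   from `common`.
#' @export
define_signatures <- function(hif_candidates, ahr_candidates,
                              common_targets = character()) {
  both <- intersect(hif_candidates, ahr_candidates)
  hif <- setdiff(hif_candidates, union(both, common_targets))
  ahr <- setdiff(ahr_candidates, union(both, common_targets))
  structure(list(HIF = sort(hif), AHR = sort(ahr),
                 common = sort(unique(common_targets))),
            class = "signatures")
}

#' @export
print.signatures <- function(x, ...) {
  cat("signatures: HIF =", length(x$HIF), "genes, AHR =", length(x$AHR),
      "genes, common =", length(x$common), "genes\n")
  invisible(x)
}

#' Composite pathway-activation score
#'
#' Per-gene z-standardisation of `log2(x + 1)` across all cohort samples,
#' then the unweighted mean over the signature genes present in the
#' matrix. Scores are invariant to per-sample additive shifts of the
#' log-expression and to per-gene affine rescalings.
#'
#' @param expr genes x samples expression matrix; set `log_input = TRUE`
#'   when already log-scaled.
#' @param genes signature gene vector.
#' @param log_input whether `expr` is already on the log scale.
#' @param min_coverage minimum fraction of signature genes that must be
#'   present (default 0.5); below it an error is raised.
#' @param aggregate `"mean"` (default) or `"median"` across genes.
#' @return named numeric vector of per-sample scores; the achieved
#'   coverage fraction is attached as attribute `coverage`.
#' @export
composite_score <- function(expr, genes, log_input = TRUE,
                            min_coverage = 0.5,
                            aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  expr <- as.matrix(expr)
  if (!log_input) expr <- log2(expr + 1)
  present <- intersect(genes, rownames(expr))
  coverage <- length(present) / length(genes)
  if (coverage < min_coverage)
    stop(sprintf("signature coverage %.0f%% below %.0f%%",
                 100 * coverage, 100 * min_coverage))
  z <- expr[present, , drop = FALSE]
  mu <- rowMeans(z)
  sdv <- apply(z, 1L, sd)
  sdv[sdv == 0] <- 1
  z <- (z - mu) / sdv
  score <- if (aggregate == "mean") colMeans(z) else apply(z, 2L, median)
  attr(score, "coverage") <- coverage
  score
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped; with n <= 25 informative pairs the exact
#' signed-rank null is used, above that the normal approximation with
#' continuity correction. All-zero differences give p = 1 by convention.
#'
#' @param x,y paired score vectors (e.g. tumour and normal), aligned by
#'   patient.
#' @return list: `V` statistic, `p_value`, `n_used` (non-zero pairs),
#'   `method`.
#' @export
paired_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    message("all paired differences are zero; returning p = 1")
    return(list(V = 0, p_value = 1, n_used = 0L, method = "degenerate"))
  }
  exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(
    wilcox.test(nz, exact = exact, correct = TRUE))
  list(V = unname(wt$statistic), p_value = wt$p.value,
       n_used = length(nz),
       method = if (exact) "exact" else "normal approximation")
}

#' Copy-number-stratified trend analysis
#'
#' Jonckheere-Terpstra trend test across ordered copy-number groups with a
#' seeded permutation null (two-sided), plus pairwise Mann-Whitney tests
#' as a secondary output.
#'
#' @param scores per-sample composite scores.
#' @param groups ordered factor (or vector coercible to one) of
#'   copy-number groups, ordered from no loss to greatest loss.
#' @param nperm permutations for the trend null.
#' @param seed integer seed.
#' @return list: `medians` per group, `JT` statistic, `p_value`
#'   (permutation, two-sided), `pairwise` (`data.frame` of group pairs and
#'   Mann-Whitney p-values).
#' @export
cn_stratified <- function(scores, groups, nperm = 2000, seed = 1L) {
  if (!is.ordered(groups)) groups <- factor(groups, levels = unique(groups),
                                            ordered = TRUE)
  groups <- droplevels(groups)
  lev <- levels(groups)
  if (length(lev) < 2L) stop("trend undefined with a single group")
  jt_stat <- function(sc, gr) {
    s <- 0
    for (i in seq_len(length(lev) - 1L)) for (j in (i + 1L):length(lev)) {
      xi <- sc[gr == lev[i]]; xj <- sc[gr == lev[j]]
      s <- s + sum(outer(xi, xj, "<")) + 0.5 * sum(outer(xi, xj, "=="))
    }
    s
  }
  obs <- jt_stat(scores, groups)
  set.seed(seed)
  null <- vapply(seq_len(nperm), function(i)
    jt_stat(scores, sample(groups)), 0)
  centred <- abs(null - mean(null))
  p <- (1 + sum(centred >= abs(obs - mean(null)))) / (nperm + 1)
  pairs <- utils::combn(lev, 2L)
  pw <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                   p_value = apply(pairs, 2L, function(pr)
                     wilcox.test(scores[groups == pr[1L]],
                                 scores[groups == pr[2L]],
                                 exact = FALSE)$p.value),
                   stringsAsFactors = FALSE)
  list(medians = tapply(scores, groups, median), JT = obs, p_value = p,
       pairwise = pw)
}

#' Correlation between pathway composite scores
#'
#' Spearman rank correlation (default) between per-sample HIF and AHR
#' scores with a two-sided t-approximation p-value; Pearson available.
#'
#' @param x,y score vectors over the same samples.
#' @param method `"spearman"` or `"pearson"`.
#' @return list: `rho`, `p_value`, `method`.
#' @export
score_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, method = method)
}
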