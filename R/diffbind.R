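# Negative-binomial Wald tests between conditions, BH correction, and the
# shared-vs-individual stratified comparison behind the cis-cooperation
# analysis.

#' Method-of-moments dispersion with shrinkage
#'
#' Per-feature NB dispersion `alpha = max(0, (s^2 - m)/m^2)` on
#' size-factor-scaled counts, shrunk 50/50 toward the trimmed-mean
#' dispersion across features. Poisson data shrink to ~0.
#'
#' @param counts features x replicates matrix (all replicates of all
#'   groups may be pooled per condition beforehand; dispersion is assumed
#'   shared across conditions).
#' @param size_factors optional per-column scaling factors.
#' @param trim trim fraction for the cross-feature mean.
#' @return named numeric vector of shrunk dispersions.
#' @export
estimate_dispersion <- function(counts, size_factors = NULL, trim = 0.1) {
  counts <- as.matrix(counts)
  if (!is.null(size_factors))
    counts <- sweep(counts, 2L, size_factors, "/")
  m <- rowMeans(counts)
  s2 <- apply(counts, 1L, var)
  raw <- ifelse(m > 0, pmax(0, (s2 - m) / m^2), 0)
  centre <- mean(raw, trim = trim)
  setNames(0.5 * raw + 0.5 * centre, rownames(counts))
}

#' Negative-binomial Wald test between two groups
#'
#' Per feature: `phi = log2((m2 + eps)/(m1 + eps))`, with the standard
#' error obtained by the delta method from the NB variance
#' `(m_i + alpha * m_i^2)/n_i` propagated to the log2 ratio. The Wald
#' statistic `z = phi/SE` is referred to the standard normal, two-sided.
#'
#' @param counts1,counts2 features x replicates matrices (normalised
#'   counts) for the two groups; a vector is treated as a single feature.
#' @param alpha per-feature NB dispersion (recycled).
#' @param eps pseudocount keeping `phi` finite at zero counts.
#' @return `data.frame` of class `diff_result`: `feature`, `phi`, `se`,
#'   `wald`, `p_value`, `q_value` (BH-adjusted).
#' @export
nb_wald <- function(counts1, counts2, alpha = 0, eps = 0.5) {
  if (is.vector(counts1)) counts1 <- matrix(counts1, nrow = 1L)
  if (is.vector(counts2)) counts2 <- matrix(counts2, nrow = 1L)
  n1 <- ncol(counts1); n2 <- ncol(counts2)
  if (n1 < 1L || n2 < 1L) stop("each group needs at least one replicate")
  m1 <- rowMeans(counts1); m2 <- rowMeans(counts2)
  alpha <- rep_len(alpha, length(m1))
  phi <- log2((m2 + eps) / (m1 + eps))
  v1 <- (m1 + alpha * m1^2) / n1
  v2 <- (m2 + alpha * m2^2) / n2
  se <- sqrt(v1 / (m1 + eps)^2 + v2 / (m2 + eps)^2) / log(2)
  se <- pmax(se, 1e-12)
  z <- phi / se
  p <- 2 * pnorm(-abs(z))
  ids <- rownames(counts1)
  if (is.null(ids)) ids <- paste0("feature_", seq_along(phi))
  res <- data.frame(feature = ids, phi = phi, se = se, wald = z,
                    p_value = p, q_value = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(res) <- c("diff_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR control with monotonicity enforcement.
#'
#' @param p vector of p-values.
#' @return adjusted q-values.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Shared-vs-individual stratified comparison
#'
#' Compares the per-site log2 fold changes of shared sites (co-bound by
#' the opposing factor) against individually bound sites: reports the two
#' stratum medians, the Mann-Whitney U statistic and two-sided p-value,
#' and a direction flag (`TRUE` when shared sites are less repressed,
#' i.e. `median_shared > median_individual`).
#'
#' @param phi_shared,phi_individual log2 fold-change vectors.
#' @return list with `median_shared`, `median_individual`, `U`, `p_value`,
#'   `shared_less_repressed`.
#' @export
stratified_comparison <- function(phi_shared, phi_individual) {
  wt <- wilcox.test(phi_shared, phi_individual, exact = FALSE)
  list(median_shared = median(phi_shared),
       median_individual = median(phi_individual),
       U = unname(wt$statistic),
       p_value = wt$p.value,
       shared_less_repressed =
         median(phi_shared) > median(phi_individual))
}
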