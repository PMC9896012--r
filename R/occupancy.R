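# Competitive-dimerization occupancy model: AHR, HIF-1a and HIF-2a compete
# for a shared limiting partner (ARNT); the dimer fraction of factor X in
# condition c saturates as a_X / (K + sum_Y a_Y), and occupancy at a shared
# site is boosted by the partner's dimer fraction through the cis-cooperation
# coefficient gamma.

FACTORS <- c("AHR", "HIF1", "HIF2")
SITE_CLASSES <- c("AHR", "HIF1", "HIF2", "AHR.HIF1", "AHR.HIF2", "HIF1.HIF2")

#' Construct a competitive-dimerization occupancy model
#'
#' The model holds per-condition activities of the three alpha-class factors,
#' the competition constant of the shared-partner pool, the cis-cooperation
#' coefficient, and the site table (class, strength, motif offset).
#'
#' @param activities numeric matrix, conditions in rows, factors
#'   (`AHR`, `HIF1`, `HIF2`) in columns; activities must be non-negative.
#'   Defaults to the six-condition design
#'   \{normoxia, hypoxia\} x \{vehicle, ITE, FICZ\} with FICZ activating AHR
#'   more weakly than ITE.
#' @param K competition constant (> 0) of the shared partner pool.
#' @param gamma cis-cooperation coefficient (>= 0): at a shared site, each
#'   factor's occupancy is multiplied by `1 + gamma * f_partner`.
#' @param n_sites number of sites per class, a named vector over
#'   `AHR`, `HIF1`, `HIF2`, `AHR.HIF1`, `AHR.HIF2`, `HIF1.HIF2`.
#' @param site_strength mean site strength S (occupancy scale per site);
#'   individual strengths are drawn log-normally around it by
#'   [simulate_sites()].
#' @param motif_offset distance in bp between the paired motifs at shared
#'   sites (default 40).
#' @return an object of class `occupancy_model`.
#' @export
occupancy_model <- function(activities = NULL, K = 1, gamma = 0,
                            n_sites = c(AHR = 40, HIF1 = 40, HIF2 = 20,
                                        AHR.HIF1 = 20, AHR.HIF2 = 10,
                                        HIF1.HIF2 = 10),
                            site_strength = 10, motif_offset = 40) {
  if (is.null(activities)) {
    activities <- rbind(
      normoxia_vehicle = c(AHR = 0.02, HIF1 = 0.02, HIF2 = 0.02),
      normoxia_ITE     = c(AHR = 1.00, HIF1 = 0.02, HIF2 = 0.02),
      normoxia_FICZ    = c(AHR = 0.70, HIF1 = 0.02, HIF2 = 0.02),
      hypoxia_vehicle  = c(AHR = 0.02, HIF1 = 1.00, HIF2 = 0.80),
      hypoxia_ITE      = c(AHR = 1.00, HIF1 = 1.00, HIF2 = 0.80),
      hypoxia_FICZ     = c(AHR = 0.70, HIF1 = 1.00, HIF2 = 0.80))
  }
  activities <- as.matrix(activities)
  if (is.null(colnames(activities)) || !all(FACTORS %in% colnames(activities)))
    stop("activities must have columns AHR, HIF1, HIF2")
  if (any(activities < 0)) stop("activities must be >= 0")
  if (K <= 0) stop("K must be > 0")
  if (gamma < 0) stop("gamma must be >= 0")
  stopifnot(all(names(n_sites) %in% SITE_CLASSES))
  structure(list(activities = activities[, FACTORS, drop = FALSE], K = K,
                 gamma = gamma, n_sites = n_sites,
                 site_strength = site_strength, motif_offset = motif_offset),
            class = "occupancy_model")
}

#' @export
print.occupancy_model <- function(x, ...) {
  cat("Competitive-dimerization occupancy model\n")
  cat("  conditions:", paste(rownames(x$activities), collapse = ", "), "\n")
  cat("  K =", x$K, " gamma =", x$gamma,
      " sites =", sum(x$n_sites), "\n")
  invisible(x)
}

#' Dimer fractions in a condition
#'
#' `f_X = a_X / (K + sum_Y a_Y)`: the fraction of each factor present as an
#' ARNT dimer given competitive saturation of the shared partner pool.
#'
#' @param model an [occupancy_model()].
#' @param condition condition label (row of the activity matrix).
#' @return named numeric vector over `AHR`, `HIF1`, `HIF2`; values lie in
#'   \[0, 1\] and sum to < 1.
#' @export
dimer_fractions <- function(model, condition) {
  if (!condition %in% rownames(model$activities))
    stop("unknown condition label: ", condition)
  a <- model$activities[condition, ]
  a / (model$K + sum(a))
}

#' Simulate a site table
#'
#' Places sites of each class along a single synthetic chromosome at least
#' `spacing` bp apart and assigns log-normal strengths around the model's
#' mean strength. Shared sites carry both factors' motifs separated by the
#' model's motif offset; the primary motif sits at the site midpoint.
#'
#' @param model an [occupancy_model()].
#' @param genome_length chromosome length in bp.
#' @param spacing minimum distance between adjacent site midpoints (bp).
#' @param site_width width of each site interval (bp).
#' @param chrom chromosome name.
#' @return a `data.frame`: one row per site with columns `chrom`, `start`,
#'   `end`, `name`, `class`, `strength`, and per-factor motif positions
#'   (`motif_AHR`, `motif_HIF1`, `motif_HIF2`; `NA` when the factor has no
#'   motif there).
#' @export
simulate_sites <- function(model, genome_length = 2e6, spacing = 2000,
                           site_width = 400, chrom = "chrS") {
  n_tot <- sum(model$n_sites)
  if (n_tot * spacing > genome_length - spacing)
    stop("genome too short for ", n_tot, " sites at ", spacing, " bp spacing")
  slots <- seq(spacing, genome_length - spacing, length.out = n_tot)
  mid <- round(slots + runif(n_tot, -spacing / 5, spacing / 5))
  cls <- rep(names(model$n_sites), model$n_sites)
  cls <- sample(cls)                       # interleave classes along the chrom
  strength <- model$site_strength * exp(rnorm(n_tot, 0, 0.25))
  d <- model$motif_offset
  has_ahr <- grepl("AHR", cls)
  has_hif1 <- grepl("HIF1", cls)
  has_hif2 <- grepl("HIF2", cls)
  shared <- has_ahr & (has_hif1 | has_hif2)
  # at shared sites the AHR motif sits d bp left of the HIF motif
  motif_ahr <- ifelse(has_ahr, ifelse(shared, mid - d %/% 2 - d %% 2, mid), NA)
  motif_hif <- ifelse(shared, mid + d %/% 2, mid)
  data.frame(chrom = chrom,
             start = mid - site_width / 2, end = mid + site_width / 2,
             name = sprintf("site_%03d", seq_len(n_tot)),
             class = cls, strength = strength,
             motif_AHR = motif_ahr,
             motif_HIF1 = ifelse(has_hif1, motif_hif, NA),
             motif_HIF2 = ifelse(has_hif2, motif_hif, NA),
             stringsAsFactors = FALSE)
}

#' Deterministic per-site occupancy
#'
#' Occupancy of factor X at site s in condition c is
#' `S_s * f_X(c) * m_(X,s) * (1 + gamma * f_P(s,c))` where `m` indicates a
#' motif for X at s and `f_P` is the partner factor's dimer fraction at
#' shared sites (0 elsewhere). The ARNT column is the sum over factors,
#' since every bound dimer contains the shared partner.
#'
#' @param model an [occupancy_model()].
#' @param sites site table from [simulate_sites()].
#' @param condition condition label.
#' @return numeric matrix, sites x factors (`AHR`, `HIF1`, `HIF2`, `ARNT`).
#' @export
simulate_occupancy <- function(model, sites, condition) {
  f <- dimer_fractions(model, condition)
  n <- nrow(sites)
  occ <- matrix(0, n, 4L, dimnames = list(sites$name,
                                          c(FACTORS, "ARNT")))
  for (X in FACTORS) {
    m <- !is.na(sites[[paste0("motif_", X)]])
    partner <- partner_fraction(sites$class, X, f)
    occ[, X] <- sites$strength * f[[X]] * as.numeric(m) *
      (1 + model$gamma * partner)
  }
  occ[, "ARNT"] <- rowSums(occ[, FACTORS, drop = FALSE])
  occ
}

# dimer fraction of the co-binding partner at shared sites; 0 at single
# factor sites. For the two-HIF shared class each HIF's partner is the other
# HIF; a factor absent from the site contributes 0.
partner_fraction <- function(class, X, f) {
  out <- numeric(length(class))
  for (i in seq_along(class)) {
    members <- strsplit(class[i], ".", fixed = TRUE)[[1L]]
    if (X %in% members && length(members) > 1L) {
      others <- setdiff(members, X)
      out[i] <- sum(f[others])
    }
  }
  out
}

#' Simulate ChIP-seq counts and coverage for one factor and condition
#'
#' Per-site expected counts are `background + scale * occupancy`; observed
#' replicate counts are negative-binomial with mean lambda and variance
#' `lambda + alpha * lambda^2`. Coverage is the expectation shaped as a
#' triangular kernel of the fragment width centred on the planted motif
#' (shared sites place one kernel per factor motif for the respective
#' factor), sampled per bin with the same NB noise.
#'
#' @param occupancy per-site occupancy vector for the factor being "pulled
#'   down" (a column of [simulate_occupancy()]).
#' @param sites site table.
#' @param factor factor name, used to centre kernels on that factor's motif.
#' @param scale counts per occupancy unit.
#' @param background expected background count per site-sized window.
#' @param alpha NB dispersion (0 reduces to Poisson).
#' @param fragment_width fragment width in bp (kernel base width).
#' @param replicates number of replicate draws.
#' @param genome_length,binwidth,chrom track geometry.
#' @param make_tracks if `FALSE`, skip coverage tracks and return counts
#'   only (much faster for count-level analyses).
#' @param seed integer seed; the same seed reproduces the output bit for
#'   bit.
#' @return list with `counts` (sites x replicates matrix) and `tracks`
#'   (list of [coverage_track()] per replicate, or `NULL`).
#' @export
simulate_chip <- function(occupancy, sites, factor = "AHR", scale = 10,
                          background = 5, alpha = 0.05, fragment_width = 200,
                          replicates = 2, genome_length = 2e6, binwidth = 10,
                          chrom = "chrS", make_tracks = TRUE, seed = 1L) {
  if (replicates < 1) stop("replicates must be >= 1")
  if (alpha < 0) stop("alpha must be >= 0")
  set.seed(seed)
  lambda <- background + scale * occupancy
  counts <- matrix(0, length(lambda), replicates,
                   dimnames = list(sites$name,
                                   paste0("rep", seq_len(replicates))))
  for (r in seq_len(replicates)) counts[, r] <- rnb(lambda, alpha)
  tracks <- NULL
  if (make_tracks) {
    nb <- ceiling(genome_length / binwidth)
    centres <- (seq_len(nb) - 0.5) * binwidth
    # per-base background rate chosen so a site-width window integrates to
    # `background` counts' worth of area (area = count * fragment_width)
    site_w <- sites$end[1L] - sites$start[1L]
    bg_rate <- background * fragment_width / site_w
    mu <- rep(bg_rate, nb)
    mpos <- sites[[paste0("motif_", factor)]]
    if (is.null(mpos)) mpos <- rep(NA_real_, nrow(sites))  # e.g. ARNT
    for (i in seq_len(nrow(sites))) {
      pos <- mpos[i]
      if (is.na(pos)) pos <- (sites$start[i] + sites$end[i]) / 2
      lam <- scale * occupancy[i]
      if (lam <= 0) next
      # unit triangle of half-base W integrates to W, so height lam gives the
      # site an area of lam * fragment_width = count * fragment_width
      tri <- pmax(0, 1 - abs(centres - pos) / fragment_width)
      mu <- mu + lam * tri
    }
    tracks <- vector("list", replicates)
    for (r in seq_len(replicates)) {
      noisy <- rnb(mu, alpha)
      tracks[[r]] <- coverage_track(
        depth = setNames(list(noisy), chrom), binwidth = binwidth,
        chromlen = setNames(genome_length, chrom),
        libsize = sum(noisy) * binwidth / fragment_width)
    }
    names(tracks) <- paste0("rep", seq_len(replicates))
  }
  list(counts = counts, tracks = tracks)
}

# NB draw parameterised by mean/dispersion; alpha = 0 falls back to Poisson
rnb <- function(mu, alpha) {
  if (alpha == 0) rpois(length(mu), mu) else
    rnbinom(length(mu), size = 1 / alpha, mu = mu)
}

#' Simulate RNA-seq gene counts driven by site occupancy
#'
#' Each gene linked to a site responds to that site's occupancy:
#' `mu_g(c) = base_g * 2^(beta_g * occ(c) / occ_max)`, with NB noise of
#' dispersion `alpha`. Genes without a linked site keep their baseline mean
#' in every condition.
#'
#' @param genes `data.frame` with columns `gene`, `base` (baseline mean) and
#'   `beta` (log2 effect at full occupancy), plus `site` (name of linked
#'   site or `NA`).
#' @param occupancy named per-site occupancy (driving factor-level signal),
#'   typically the ARNT column of [simulate_occupancy()].
#' @param occ_max occupancy treated as "full" for effect scaling; default
#'   the maximum of `occupancy`.
#' @param alpha NB dispersion.
#' @param n number of replicates.
#' @param seed integer seed.
#' @return integer matrix genes x replicates.
#' @export
simulate_rna <- function(genes, occupancy, occ_max = NULL, alpha = 0.05,
                         n = 6, seed = 1L) {
  set.seed(seed)
  if (is.null(occ_max)) occ_max <- max(occupancy, 1e-9)
  occ <- ifelse(is.na(genes$site), 0,
                unname(occupancy[genes$site]))
  occ[is.na(occ)] <- 0
  mu <- genes$base * 2^(genes$beta * occ / occ_max)
  counts <- matrix(0L, nrow(genes), n,
                   dimnames = list(genes$gene, paste0("rep", seq_len(n))))
  for (r in seq_len(n)) counts[, r] <- rnb(mu, alpha)
  counts
}

#' Simulate a paired tumour/normal expression cohort
#'
#' Tumour samples shift HIF-signature genes by `+delta_hif` and
#' AHR-signature genes by `delta_ahr` on the log2 scale (common-signature
#' genes by their sum), multiplied by a copy-number-group dose factor; a
#' shared per-patient tumour factor couples the two signatures within a
#' sample, mimicking the patient-to-patient variation in pathway activation
#' that drives the score correlation.
#'
#' @param n_pairs number of tumour/normal pairs.
#' @param genes_hif,genes_ahr,genes_common signature gene ID vectors.
#' @param n_background number of unrelated background genes.
#' @param delta_hif,delta_ahr tumour log2 shifts (HIF positive, AHR
#'   negative in the default design).
#' @param cn_groups ordered copy-number group labels; tumours are assigned
#'   uniformly and the shift is multiplied by `cn_dose[group]`.
#' @param cn_dose named multiplier per group.
#' @param sigma per-gene log-normal noise SD.
#' @param seed integer seed.
#' @return list with `expr` (genes x samples log2 expression matrix) and
#'   `meta` (`data.frame`: sample, patient, tissue, cn_group).
#' @export
simulate_cohort <- function(n_pairs = 72,
                            genes_hif = paste0("HIFG", 1:50),
                            genes_ahr = paste0("AHRG", 1:30),
                            genes_common = paste0("COMG", 1:10),
                            n_background = 200,
                            delta_hif = 0.5, delta_ahr = -0.5,
                            cn_groups = c("0", "-1", "-2"),
                            cn_dose = c("0" = 0.6, "-1" = 1.0, "-2" = 1.4),
                            sigma = 1, seed = 1L) {
  set.seed(seed)
  genes_bg <- if (n_background > 0) paste0("BGG", seq_len(n_background))
              else character()
  genes <- c(genes_hif, genes_ahr, genes_common, genes_bg)
  n_s <- 2L * n_pairs
  patient <- rep(sprintf("P%03d", seq_len(n_pairs)), each = 2L)
  tissue <- rep(c("normal", "tumour"), n_pairs)
  sample_id <- paste0(patient, "_", substr(tissue, 1, 1))
  cn_t <- sample(cn_groups, n_pairs, replace = TRUE)
  cn <- rep(cn_t, each = 2L)
  cn[tissue == "normal"] <- "0"
  base <- rnorm(length(genes), 8, 1)
  expr <- matrix(rnorm(length(genes) * n_s, 0, sigma), length(genes), n_s,
                 dimnames = list(genes, sample_id)) + base
  # per-patient pathway activation factor shared by the two signatures:
  # tumours with stronger HIF activation show the stronger AHR suppression
  act <- rnorm(n_pairs, 1, 0.4)
  for (p in seq_len(n_pairs)) {
    j <- 2L * p            # tumour column
    dose <- cn_dose[[cn_t[p]]] * act[p]
    expr[genes_hif, j] <- expr[genes_hif, j] + delta_hif * dose
    expr[genes_ahr, j] <- expr[genes_ahr, j] + delta_ahr * dose
    expr[genes_common, j] <- expr[genes_common, j] +
      (delta_hif + delta_ahr) * dose
  }
  meta <- data.frame(sample = sample_id, patient = patient, tissue = tissue,
                     cn_group = cn, stringsAsFactors = FALSE)
  list(expr = expr, meta = meta)
}

#' Generate a synthetic genome with planted NCGTG motifs
#'
#' Background sequence is i.i.d. uniform ACGT; at each site the factor
#' motifs are written at their planted positions: `GCGTG` for AHR (the
#' xenobiotic response element) and `ACGTG` for HIF (the hypoxia response
#' element), on the plus strand.
#'
#' @param sites site table from [simulate_sites()].
#' @param genome_length chromosome length in bp.
#' @param chrom chromosome name.
#' @param seed integer seed.
#' @return a [Biostrings::DNAStringSet] of length 1.
#' @export
simulate_genome <- function(sites, genome_length = 2e6, chrom = "chrS",
                            seed = 1L) {
  set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE)
  plant <- function(pos, motif) {
    # pos is the motif centre; write the 5-mer starting at pos - 2 (0-based)
    s0 <- round(pos) - 2L
    idx <- (s0 + 1L):(s0 + 5L)
    base[idx] <<- strsplit(motif, "")[[1L]]
  }
  for (i in seq_len(nrow(sites))) {
    if (!is.na(sites$motif_AHR[i])) plant(sites$motif_AHR[i], "GCGTG")
    hifpos <- sites$motif_HIF1[i]
    if (is.na(hifpos)) hifpos <- sites$motif_HIF2[i]
    if (!is.na(hifpos)) plant(hifpos, "ACGTG")
  }
  seqs <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(seqs) <- chrom
  seqs
}
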