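# End-to-end orchestration on synthetic data: occupancy model -> ChIP
# coverage -> consensus peaks -> canonical sites -> Venn/TSS -> differential
# binding -> motifs -> RNA DE + GSEA -> cohort scoring, with a manifest of
# per-stage checksums.

# fixed derivation of per-stage child seeds so each stage is reproducible
# independently of stage order
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 10007 + k * 101) %% 2147483647)
}

checksum <- function(obj) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(obj, f, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Simulate the full study dataset
#'
#' Builds the six-condition, four-factor synthetic design: site table and
#' genome with planted motifs, ChIP coverage tracks (for the conditions
#' used in peak calling) and per-condition site counts, an occupancy-driven
#' gene table with RNA counts, and a paired tumour/normal cohort.
#'
#' @param model an [occupancy_model()].
#' @param config a [default_config()] list (supplies the seed and
#'   geometry).
#' @param genome_length synthetic chromosome length (bp).
#' @param chip_scale,chip_background,chip_alpha ChIP count model
#'   parameters.
#' @param track_conditions conditions for which coverage tracks are built;
#'   count matrices are produced for every condition.
#' @return list with `sites`, `genome`, `tracks` (nested
#'   factor/condition/replicate), `control` track, `counts` (per condition:
#'   sites x (factor x replicate)), `occupancy` (per condition), `genes`,
#'   `rna` (per condition gene count matrices), `tss`.
#' @export
simulate_dataset <- function(model = occupancy_model(),
                             config = default_config(),
                             genome_length = 2e6,
                             chip_scale = 40, chip_background = 5,
                             chip_alpha = 0.02,
                             track_conditions = c("normoxia_ITE",
                                                  "hypoxia_vehicle")) {
  seed <- config$seed
  set.seed(stage_seed(seed, 1L))
  sites <- simulate_sites(model, genome_length = genome_length)
  genome <- simulate_genome(sites, genome_length = genome_length,
                            seed = stage_seed(seed, 2L))
  conds <- rownames(model$activities)
  occupancy <- lapply(setNames(conds, conds), function(cc)
    simulate_occupancy(model, sites, cc))
  fw <- config$fragment_width
  tracks <- list(); counts <- list()
  k <- 10L
  for (cc in conds) {
    cnt <- NULL
    for (f in c("AHR", "HIF1", "HIF2", "ARNT")) {
      k <- k + 1L
      sim <- simulate_chip(occupancy[[cc]][, f], sites, factor = f,
                           scale = chip_scale, background = chip_background,
                           alpha = chip_alpha, fragment_width = fw,
                           replicates = 2, genome_length = genome_length,
                           make_tracks = cc %in% track_conditions,
                           seed = stage_seed(seed, k))
      colnames(sim$counts) <- paste(f, colnames(sim$counts), sep = "_")
      cnt <- cbind(cnt, sim$counts)
      if (!is.null(sim$tracks)) tracks[[cc]][[f]] <- sim$tracks
    }
    counts[[cc]] <- cnt
  }
  control <- simulate_chip(rep(0, nrow(sites)), sites, factor = "AHR",
                           scale = chip_scale, background = chip_background,
                           alpha = chip_alpha, fragment_width = fw,
                           replicates = 1, genome_length = genome_length,
                           make_tracks = TRUE,
                           seed = stage_seed(seed, 99L))$tracks[[1L]]
  # one responsive gene per site (TSS 500 bp downstream of the site end on
  # +, upstream of the start on -) plus unlinked background genes
  set.seed(stage_seed(seed, 3L))
  n_site <- nrow(sites)
  strand <- sample(c("+", "-"), n_site, replace = TRUE)
  tss_pos <- ifelse(strand == "+", sites$end + 500, sites$start - 500)
  genes <- data.frame(gene = sub("site", "gene", sites$name),
                      site = sites$name,
                      base = exp(rnorm(n_site, log(200), 0.5)),
                      beta = 3, stringsAsFactors = FALSE)
  n_bg <- 300L
  gaps <- round(seq(1000, genome_length - 1000, length.out = n_bg))
  bg <- data.frame(gene = sprintf("bg_gene_%03d", seq_len(n_bg)),
                   site = NA_character_,
                   base = exp(rnorm(n_bg, log(200), 0.5)),
                   beta = 0, stringsAsFactors = FALSE)
  genes_all <- rbind(genes, bg)
  tss <- data.frame(gene = genes_all$gene, chrom = sites$chrom[1L],
                    pos = c(tss_pos, gaps),
                    strand = c(strand, sample(c("+", "-"), n_bg,
                                              replace = TRUE)),
                    stringsAsFactors = FALSE)
  occ_max <- max(vapply(occupancy, function(o) max(o[, "ARNT"]), 0))
  rna <- list()
  for (i in seq_along(conds)) {
    rna[[conds[i]]] <- simulate_rna(genes_all, occupancy[[conds[i]]][, "ARNT"],
                                    occ_max = occ_max, alpha = 0.05, n = 6,
                                    seed = stage_seed(seed, 200L + i))
  }
  list(sites = sites, genome = genome, tracks = tracks, control = control,
       counts = counts, occupancy = occupancy, genes = genes_all,
       rna = rna, tss = tss)
}

call_condition_sites <- function(tracks_cond, factor, control, cfg,
                                 background_regions) {
  cp <- cfg$caller
  reps <- lapply(tracks_cond[[factor]], function(tr) {
    a <- call_peaks_enrichment(tr, control, min_fold = cp$min_fold,
                               alpha = cp$alpha, min_len = cp$min_len,
                               merge_gap = cp$merge_gap,
                               fragment_width = cfg$fragment_width)
    b <- call_peaks_shape(tr, bandwidth = cp$bandwidth,
                          prominence = cp$prominence,
                          fragment_width = cfg$fragment_width)
    cons <- consensus(a, b)
    bg_counts <- count_in_regions(tr, background_regions,
                                  fragment_width = cfg$fragment_width)
    thr <- background_threshold(bg_counts, cfg$background_quantile)
    filter_peaks(cons, thr)
  })
  reps
}

#' Run the whole pipeline on synthetic data
#'
#' Executes every stage on a dataset generated under the occupancy model
#' and returns the per-figure analogue results together with a run
#' manifest (seed, resolved config, per-stage checksums).
#'
#' @param config a [default_config()]; `config$seed` drives every
#'   stochastic stage through fixed per-stage child seeds.
#' @param model an [occupancy_model()].
#' @param genome_length synthetic chromosome length in bp.
#' @param n_background_regions background regions for the empirical
#'   threshold.
#' @return list of class `crossbind_run` with elements `dataset`,
#'   `sites` (per factor), `venn`, `tss_annotation`, `diff`
#'   (per-contrast), `stratified`, `summit`, `motifs`, `rna_de`,
#'   `gene_sets`, `gsea`, `additivity`, `cohort`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(),
                         model = occupancy_model(gamma = 0.5),
                         genome_length = 2e6,
                         n_background_regions = 2000) {
  validate_config(config)
  seed <- config$seed
  manifest <- list(timestamp = format(Sys.time(), tz = "UTC"),
                   seed = seed, config = unclass(config),
                   checksums = list(), warnings = character())
  ds <- simulate_dataset(model, config, genome_length = genome_length)
  manifest$checksums$dataset <- checksum(ds$counts)

  # --- canonical sites per factor --------------------------------------
  width_guess <- median(ds$sites$end - ds$sites$start)
  bg_regions <- sample_background_regions(
    n_background_regions, width_guess, genome_length,
    chrom = ds$sites$chrom[1L], exclude = ds$sites,
    seed = stage_seed(seed, 7L))
  ahr_reps <- call_condition_sites(ds$tracks[["normoxia_ITE"]], "AHR",
                                   ds$control, config, bg_regions)
  arnt_ite_reps <- call_condition_sites(ds$tracks[["normoxia_ITE"]], "ARNT",
                                        ds$control, config, bg_regions)
  hif1_reps <- call_condition_sites(ds$tracks[["hypoxia_vehicle"]], "HIF1",
                                    ds$control, config, bg_regions)
  hif2_reps <- call_condition_sites(ds$tracks[["hypoxia_vehicle"]], "HIF2",
                                    ds$control, config, bg_regions)
  arnt_hyp_reps <- call_condition_sites(ds$tracks[["hypoxia_vehicle"]],
                                        "ARNT", ds$control, config,
                                        bg_regions)
  sites_called <- list(
    AHR = canonical_sites(ahr_reps[[1L]], ahr_reps[[2L]],
                          arnt_ite_reps[[1L]], arnt_ite_reps[[2L]]),
    HIF1 = canonical_sites(hif1_reps[[1L]], hif1_reps[[2L]],
                           arnt_hyp_reps[[1L]], arnt_hyp_reps[[2L]]),
    HIF2 = canonical_sites(hif2_reps[[1L]], hif2_reps[[2L]],
                           arnt_hyp_reps[[1L]], arnt_hyp_reps[[2L]]))
  manifest$checksums$sites <- checksum(sites_called)
  venn <- classify_venn(sites_called$AHR, sites_called$HIF1,
                        sites_called$HIF2)
  cl <- venn$clusters
  cl$summit <- floor((cl$start + cl$end) / 2)
  tss_ann <- annotate_tss(cl, ds$tss)

  # --- differential binding (count level, planted-site regions) --------
  contrasts <- list(
    AHR_hypoxia = c("normoxia_ITE", "hypoxia_ITE", "AHR"),
    HIF1_ITE = c("hypoxia_vehicle", "hypoxia_ITE", "HIF1"),
    HIF2_ITE = c("hypoxia_vehicle", "hypoxia_ITE", "HIF2"))
  diff <- list()
  for (nm in names(contrasts)) {
    ct <- contrasts[[nm]]
    f <- ct[3L]
    cols <- paste0(f, "_rep", 1:2)
    c1 <- ds$counts[[ct[1L]]][, cols]
    c2 <- ds$counts[[ct[2L]]][, cols]
    al <- estimate_dispersion(cbind(c1, c2))
    diff[[nm]] <- nb_wald(c1, c2, alpha = al, eps = config$pseudocount)
  }
  manifest$checksums$diff <- checksum(diff)

  # --- stratified shared-vs-individual comparison ----------------------
  cls <- ds$sites$class
  strat <- list(
    AHR = stratified_comparison(
      diff$AHR_hypoxia$phi[cls %in% c("AHR.HIF1", "AHR.HIF2")],
      diff$AHR_hypoxia$phi[cls == "AHR"]),
    HIF1 = stratified_comparison(
      diff$HIF1_ITE$phi[cls == "AHR.HIF1"],
      diff$HIF1_ITE$phi[cls == "HIF1"]))

  # --- summit distances at shared sites --------------------------------
  shared_ahr <- sites_called$AHR[overlaps_any(sites_called$AHR,
                                              sites_called$HIF1), ,
                                 drop = FALSE]
  summit <- summit_distance(shared_ahr, sites_called$HIF1)

  # --- motif variants ---------------------------------------------------
  # the planted motif sits at the site midpoint, so centre windows there
  seq_by_class <- lapply(setNames(c("AHR", "HIF1", "HIF2"),
                                  c("AHR", "HIF1", "HIF2")), function(cc) {
    sub <- ds$sites[cls == cc, ]
    sub$summit <- floor((sub$start + sub$end) / 2)
    site_sequences(ds$genome, sub, config$flank)
  })
  bg_sub <- bg_regions[seq_len(min(200L, nrow(bg_regions))), ]
  bg_sub$summit <- floor((bg_sub$start + bg_sub$end) / 2)
  motifs <- top_variant_by_class(seq_by_class,
                                 site_sequences(ds$genome, bg_sub,
                                                config$flank))
  manifest$checksums$motifs <- checksum(motifs)

  # --- RNA DE, gene sets, GSEA -----------------------------------------
  de_ite <- gene_de(cbind(ds$rna$normoxia_vehicle, ds$rna$normoxia_ITE),
                    1:6, 7:12)
  de_hyp <- gene_de(cbind(ds$rna$normoxia_vehicle, ds$rna$hypoxia_vehicle),
                    1:6, 7:12)
  de_both <- gene_de(cbind(ds$rna$normoxia_vehicle, ds$rna$hypoxia_ITE),
                     1:6, 7:12)
  de_comp <- gene_de(cbind(ds$rna$normoxia_ITE, ds$rna$hypoxia_ITE),
                     1:6, 7:12)
  site_gene <- data.frame(nearest_gene = ds$genes$gene[
    match(ds$sites$name, ds$genes$site)], class = cls,
    stringsAsFactors = FALSE)
  gene_sets <- build_gene_sets(site_gene, de_ite, de_hyp,
                               alpha = config$alpha_bh)
  ranked_ite <- rank_genes(de_ite, mode = config$gsea$ranking)
  ranked_comp <- rank_genes(de_comp, mode = config$gsea$ranking)
  nperm <- min(config$gsea$nperm, 2000L)  # desk-scale default for the run
  gsea <- list(
    ahr_in_ite = gsea_preranked(ranked_ite, gene_sets$ahr_bound_only,
                                weight = config$gsea$weight, nperm = nperm,
                                seed = stage_seed(seed, 31L)),
    ahr_in_hypoxia_ite = gsea_preranked(ranked_comp,
                                        gene_sets$ahr_bound_only,
                                        weight = config$gsea$weight,
                                        nperm = nperm,
                                        seed = stage_seed(seed, 32L)))
  addit <- additivity(de_hyp, de_ite, de_both, gene_sets$common_targets)

  # --- cohort ----------------------------------------------------------
  sigs <- define_signatures(gene_sets$hif_targets, gene_sets$ahr_targets,
                            gene_sets$common_targets)
  coh <- simulate_cohort(n_pairs = 72,
                         genes_hif = sigs$HIF, genes_ahr = sigs$AHR,
                         genes_common = sigs$common,
                         seed = stage_seed(seed, 41L))
  sc_hif <- composite_score(coh$expr, sigs$HIF)
  sc_ahr <- composite_score(coh$expr, sigs$AHR)
  tum <- coh$meta$tissue == "tumour"
  cohort <- list(
    scores = data.frame(coh$meta, hif = sc_hif, ahr = sc_ahr),
    hif_tumour_vs_normal = paired_wilcoxon(sc_hif[tum], sc_hif[!tum]),
    ahr_tumour_vs_normal = paired_wilcoxon(sc_ahr[tum], sc_ahr[!tum]),
    cn_trend_hif = cn_stratified(
      sc_hif[tum], factor(coh$meta$cn_group[tum],
                          levels = c("0", "-1", "-2"), ordered = TRUE),
      seed = stage_seed(seed, 42L)),
    cn_trend_ahr = cn_stratified(
      sc_ahr[tum], factor(coh$meta$cn_group[tum],
                          levels = c("0", "-1", "-2"), ordered = TRUE),
      seed = stage_seed(seed, 43L)),
    correlation = score_correlation(sc_hif[tum], sc_ahr[tum],
                                    method = config$correlation))
  manifest$checksums$cohort <- checksum(cohort$scores)

  structure(list(dataset = ds, sites = sites_called, venn = venn,
                 tss_annotation = tss_ann, diff = diff, stratified = strat,
                 summit = summit, motifs = motifs,
                 rna_de = list(ite = de_ite, hypoxia = de_hyp,
                               both = de_both, competition = de_comp),
                 gene_sets = gene_sets, gsea = gsea, additivity = addit,
                 cohort = cohort, manifest = manifest),
            class = "crossbind_run")
}

#' @export
print.crossbind_run <- function(x, ...) {
  cat("crossbind pipeline run (seed ", x$manifest$seed, ")\n", sep = "")
  cat("  canonical sites: AHR =", nrow(x$sites$AHR),
      " HIF1 =", nrow(x$sites$HIF1), " HIF2 =", nrow(x$sites$HIF2), "\n")
  cat("  Venn union:", x$venn$union, "distinct sites;",
      x$venn$report$multi_factor, "multi-factor\n")
  cat("  AHR hypoxic repression: median phi(shared) =",
      round(x$stratified$AHR$median_shared, 3),
      "vs phi(individual) =",
      round(x$stratified$AHR$median_individual, 3), "\n")
  cat("  median AHR-HIF1 summit distance:", x$summit$median, "bp\n")
  invisible(x)
}
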