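# NCGTG core-motif scanning and variant-preference analysis: HIF favours
# the ACGTG hypoxia response element, AHR the GCGTG xenobiotic response
# element; the scanner tests that dichotomy directly.

#' Extract site sequences around summits
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param sites site `data.frame` with `chrom` and `summit` columns.
#' @param flank bp either side of the summit.
#' @return character vector of sequences named by site.
#' @export
site_sequences <- function(genome, sites, flank = 100) {
  vapply(seq_len(nrow(sites)), function(i) {
    chr <- genome[[sites$chrom[i]]]
    s <- max(1L, round(sites$summit[i]) - flank + 1L)   # 1-based
    e <- min(length(chr), round(sites$summit[i]) + flank + 1L)
    as.character(Biostrings::subseq(chr, s, e))
  }, "", USE.NAMES = FALSE) |>
    setNames(if (!is.null(sites$name)) sites$name
             else paste0("site_", seq_len(nrow(sites))))
}

#' Scan sequences for the NCGTG core motif
#'
#' Reports every occurrence of `NCGTG` on both strands (a minus-strand hit
#' appears as `CACGN` in the given sequence); overlapping hits are all
#' reported. The variant is the N base as read on the hit strand.
#'
#' @param seqs named character vector of site sequences.
#' @return `data.frame`: `site`, `offset` (0-based start of the pentamer in
#'   the given sequence), `strand`, `variant`.
#' @export
scan_ncgtg <- function(seqs) {
  if (is.null(names(seqs))) names(seqs) <- paste0("site_", seq_along(seqs))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- toupper(seqs[[i]])
    plus <- gregexpr("(?=(.CGTG))", s, perl = TRUE)[[1L]]
    minus <- gregexpr("(?=(CACG.))", s, perl = TRUE)[[1L]]
    rows <- list()
    if (plus[1L] != -1L) {
      off <- as.integer(plus) - 1L
      rows[[1L]] <- data.frame(site = names(seqs)[i], offset = off,
                               strand = "+",
                               variant = substring(s, off + 1L, off + 1L),
                               stringsAsFactors = FALSE)
    }
    if (minus[1L] != -1L) {
      off <- as.integer(minus) - 1L
      rows[[2L]] <- data.frame(site = names(seqs)[i], offset = off,
                               strand = "-",
                               variant = unname(
                                 comp[substring(s, off + 5L, off + 5L)]),
                               stringsAsFactors = FALSE)
    }
    out[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(site = character(), offset = integer(),
                      strand = character(), variant = character(),
                      stringsAsFactors = FALSE)
  res[order(match(res$site, names(seqs)), res$offset, res$strand), ,
      drop = FALSE] -> res
  rownames(res) <- NULL
  res
}

#' Per-variant enrichment of NCGTG motifs
#'
#' For each variant N in \{A, C, G, T\}, a 2x2 Fisher exact test of
#' presence (>= 1 hit of that variant) in foreground versus background
#' sites, with the fold change of presence frequencies. Infinite folds
#' (background frequency 0) are capped and flagged.
#'
#' @param fg_hits,bg_hits hit tables from [scan_ncgtg()].
#' @param n_fg,n_bg total numbers of foreground / background sites
#'   (including sites without hits).
#' @param fold_cap reported fold when the background frequency is zero.
#' @return `data.frame`: `variant`, `fg_freq`, `bg_freq`, `fold`,
#'   `capped`, `p_value`.
#' @export
variant_enrichment <- function(fg_hits, bg_hits, n_fg, n_bg,
                               fold_cap = 1e6) {
  res <- lapply(c("A", "C", "G", "T"), function(v) {
    fg_pos <- length(unique(fg_hits$site[fg_hits$variant == v]))
    bg_pos <- length(unique(bg_hits$site[bg_hits$variant == v]))
    tab <- matrix(c(fg_pos, n_fg - fg_pos, bg_pos, n_bg - bg_pos), 2L)
    ff <- fg_pos / n_fg
    bf <- bg_pos / n_bg
    fold <- if (bf == 0) {
      if (ff == 0) 1 else fold_cap
    } else ff / bf
    data.frame(variant = v, fg_freq = ff, bg_freq = bf,
               fold = fold, capped = bf == 0 && ff > 0,
               p_value = fisher.test(tab)$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Top enriched NCGTG variant per site class
#'
#' Convenience wrapper: scans foreground sequences per class against a
#' common background and reports the variant with the largest enrichment
#' fold (ties broken by smaller p-value).
#'
#' @param seqs_by_class named list of character vectors of site sequences.
#' @param bg_seqs background sequences.
#' @return `data.frame`: `class`, `top_variant`, `fold`, `p_value`.
#' @export
top_variant_by_class <- function(seqs_by_class, bg_seqs) {
  bg_hits <- scan_ncgtg(bg_seqs)
  out <- lapply(names(seqs_by_class), function(cl) {
    fg <- seqs_by_class[[cl]]
    enr <- variant_enrichment(scan_ncgtg(fg), bg_hits,
                              n_fg = length(fg), n_bg = length(bg_seqs))
    enr <- enr[order(-enr$fold, enr$p_value), , drop = FALSE]
    data.frame(class = cl, top_variant = enr$variant[1L],
               fold = enr$fold[1L], p_value = enr$p_value[1L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
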