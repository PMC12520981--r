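#' Copy-number-weighted binomial test for ecDNA trans partners
#'
#' For each 500 kb interval i on chromosomes other than the ecDNA locus,
#' counts its contacts with the candidate bins (N_i) and compares the
#' observed per-chromosome interaction fraction P_i = N_i / sum_g N_g with
#' the expectation E_i = CN_i / sum_g CN_g under the null hypothesis that a
#' region's interaction frequency with ecDNA is weighted only by its copy
#' number. The upper-tail p-value is P(X >= N_i) with
#' X ~ Binomial(sum_g N_g, E_i); normalisation and the binomial total are
#' per trans chromosome, while Bonferroni correction is applied across all
#' emitted intervals genome-wide. Intervals with adjusted p < `alpha` are
#' flagged significant.
#'
#' @param pseudobulk triplet tibble from [aggregate_pseudobulk()] at the test
#'   resolution (500 kb typical).
#' @param cnv a `cnv_profile` on the same binning (copy per bin).
#' @param ecdna_bins global bins of the ecDNA candidate locus.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param eps floor applied to E_i when CN_i = 0 but N_i > 0.
#' @return tibble with one row per tested interval: `bin`, `chrom`, `n_contacts`
#'   (N_i), `p_obs` (P_i), `copy` (CN_i), `e_exp` (E_i), `p_value`, `p_adj`,
#'   `significant`. Chromosomes with zero total contacts to the locus are
#'   skipped with a warning.
#' @export
significant_trans_partners <- function(pseudobulk, cnv, ecdna_bins,
                                       alpha = 0.05, eps = 1e-6) {
  g <- attr(pseudobulk, "genome")
  chrom_of <- bin_chrom(g)
  own_chroms <- unique(chrom_of[ecdna_bins])
  test_chroms <- setdiff(g$chrom_names, c(own_chroms, g$excluded_chroms))
  # contacts of each bin with the locus
  tr <- pseudobulk[(pseudobulk$bin1 %in% ecdna_bins) !=
                     (pseudobulk$bin2 %in% ecdna_bins), ]
  partner <- ifelse(tr$bin1 %in% ecdna_bins, tr$bin2, tr$bin1)
  cnt <- tapply(tr$count, partner, sum)
  B <- n_bins(g)
  N <- numeric(B)
  N[as.integer(names(cnt))] <- cnt
  copy <- cnv$inferred_copy
  copy[is.na(copy)] <- 0
  rows <- lapply(test_chroms, function(ch) {
    bins <- which(chrom_of == ch)
    tot <- sum(N[bins])
    if (tot == 0) {
      warning("chromosome ", ch, " has no contacts with the locus; skipped")
      return(NULL)
    }
    cn_tot <- sum(copy[bins])
    e <- if (cn_tot > 0) copy[bins] / cn_tot else rep(1 / length(bins), length(bins))
    e <- ifelse(e == 0 & N[bins] > 0, eps, e)
    tibble::tibble(
      bin = bins, chrom = ch, n_contacts = N[bins],
      p_obs = N[bins] / tot, copy = copy[bins], e_exp = e,
      p_value = stats::pbinom(N[bins] - 1, tot, e, lower.tail = FALSE)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out$p_adj <- stats::p.adjust(out$p_value, method = "bonferroni")
  out$significant <- out$p_adj < alpha
  out
}

#' Shuffle-null test for ecDNA hub formation
#'
#' Builds a background hub-index distribution by shuffling the chromosome
#' identity of every trans contact of the query bin within each cell
#' (uniformly over eligible chromosomes, keeping each cell's trans total
#' fixed), recomputing the per-cell hub index, and comparing observed versus
#' null medians with a Wilcoxon signed-rank test (one-sided: observed
#' greater).
#'
#' @param set an `sc_cellset` at the feature resolution.
#' @param bin global query bin.
#' @param barcodes cells to include (default all).
#' @param n_shuffles number of shuffles (>= 1).
#' @param seed RNG seed.
#' @return list with `observed` (per-cell hub indices), `null` (matrix cells
#'   x shuffles), `observed_median`, `null_median`, `p_value`, and
#'   `null_trans_totals` (per-cell totals of the final shuffle, for
#'   conservation checks).
#' @export
shuffle_hub_null <- function(set, bin, barcodes = set$barcodes,
                             n_shuffles = 100, seed = 1) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  set.seed(seed)
  counts <- lapply(barcodes, function(bc) trans_counts_by_chrom(set, bc, bin))
  keep <- vapply(counts, function(x) sum(x) > 0, logical(1))
  counts <- counts[keep]
  if (length(counts) == 0) stop("no cell has trans contacts at this bin")
  observed <- vapply(counts, hub_index, numeric(1))
  n_chrom <- length(counts[[1]])
  null <- matrix(NA_real_, length(counts), n_shuffles)
  totals <- numeric(length(counts))
  for (s in seq_len(n_shuffles)) {
    for (i in seq_along(counts)) {
      tot <- sum(counts[[i]])
      shuf <- tabulate(sample.int(n_chrom, tot, replace = TRUE), n_chrom)
      null[i, s] <- hub_index(shuf)
      totals[i] <- sum(shuf)
    }
  }
  null_per_cell <- rowMeans(null)
  p <- stats::wilcox.test(observed, null_per_cell, paired = TRUE,
                          alternative = "greater", exact = FALSE)$p.value
  list(
    observed = observed, null = null,
    observed_median = stats::median(observed),
    null_median = stats::median(null),
    p_value = p,
    null_trans_totals = totals
  )
}
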