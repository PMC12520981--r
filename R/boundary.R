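#' Refine ecDNA boundaries at 10 kb resolution
#'
#' ecDNA candidates called at 1 Mb are sharpened by profiling local
#' interactions at 10 kb: within the candidate region, each 10 kb bin's
#' contacts to other bins of the region are summed, the profile is smoothed
#' with a rolling mean (window `smooth_w`), and first differences are taken.
#' Bins where |difference| exceeds the mean |difference| over the region are
#' changepoints; consecutive changepoints form runs, each weighted by its
#' cumulative change, and runs carrying less than half the maximum
#' cumulative change are discarded as noise. The left boundary is placed at
#' the outermost (leftmost) qualifying rising run and the right boundary at
#' the outermost falling run (run midpoints compensate the smoothing
#' spread). If no rising or no falling changepoint clears the cutoff the
#' candidate region is returned unchanged with `refined = FALSE`.
#'
#' @param pseudobulk_10kb triplet tibble from [aggregate_pseudobulk()] on a
#'   10 kb binning.
#' @param candidate_region integer vector of contiguous global 10 kb bins.
#' @param smooth_w rolling-mean window in bins (default 3).
#' @return list with `start_bin`, `end_bin` (global bins, inclusive),
#'   `refined` flag, and the per-bin `profile` tibble (`bin`, `local_sum`,
#'   `smoothed`).
#' @export
refine_ecdna_boundary <- function(pseudobulk_10kb, candidate_region,
                                  smooth_w = 3) {
  bins <- sort(candidate_region)
  tr <- pseudobulk_10kb[pseudobulk_10kb$bin1 %in% bins &
                          pseudobulk_10kb$bin2 %in% bins, ]
  s <- numeric(length(bins))
  names(s) <- bins
  add <- tapply(tr$count, tr$bin1, sum)
  s[names(add)] <- s[names(add)] + add
  off <- tr[tr$bin1 != tr$bin2, ]
  if (nrow(off) > 0) {
    add2 <- tapply(off$count, off$bin2, sum)
    s[names(add2)] <- s[names(add2)] + add2
  }
  sm <- rolling_mean(as.numeric(s), smooth_w)
  d <- diff(sm)
  cutoff <- mean(abs(d))
  rising <- which(d > cutoff)
  falling <- which(d < -cutoff)
  profile <- tibble::tibble(bin = bins, local_sum = as.numeric(s),
                            smoothed = sm)
  if (length(rising) == 0 || length(falling) == 0) {
    return(list(start_bin = bins[1], end_bin = bins[length(bins)],
                refined = FALSE, profile = profile))
  }
  run_mid <- function(idx, first) {
    splits <- cumsum(c(1, diff(idx) != 1))
    runs <- split(idx, splits)
    weight <- vapply(runs, function(r) abs(sum(d[r])), numeric(1))
    runs <- runs[weight >= 0.5 * max(weight)]
    run <- runs[[if (first) 1 else length(runs)]]
    run[ceiling(length(run) / 2)]
  }
  left <- run_mid(rising, first = TRUE) + 1L
  right <- run_mid(falling, first = FALSE)
  if (left > right) {
    return(list(start_bin = bins[1], end_bin = bins[length(bins)],
                refined = FALSE, profile = profile))
  }
  list(start_bin = bins[left], end_bin = bins[right], refined = TRUE,
       profile = profile)
}

#' Classify genes relative to refined ecDNA boundaries
#'
#' A gene is an "ecDNA gene" iff its body lies strictly within the refined
#' interval (genes straddling a boundary are excluded). When two boundaries
#' are compared (e.g. parental versus resistant ecDNA), genes inside both
#' are "shared", genes inside exactly one are "variable", sided 5' or 3' by
#' their position relative to the shared core.
#'
#' @param genes tibble with `chrom`, `start`, `end`, `gene` (1-based
#'   inclusive gene bodies).
#' @param interval_a list/tibble row with `chrom`, `start`, `end`.
#' @param interval_b optional second interval on the same chromosome.
#' @return `genes` with an added `class` column: one of `none`, `ecdna`
#'   (single interval), or `none`/`shared`/`variable_5prime`/
#'   `variable_3prime` (two intervals).
#' @export
ecdna_genes <- function(genes, interval_a, interval_b = NULL) {
  inside <- function(int) {
    genes$chrom == int$chrom & genes$start >= int$start & genes$end <= int$end
  }
  in_a <- inside(interval_a)
  if (is.null(interval_b)) {
    return(dplyr::mutate(genes, class = ifelse(in_a, "ecdna", "none")))
  }
  in_b <- inside(interval_b)
  core_start <- max(interval_a$start, interval_b$start)
  core_end <- min(interval_a$end, interval_b$end)
  cls <- rep("none", nrow(genes))
  cls[in_a & in_b] <- "shared"
  one <- xor(in_a, in_b)
  cls[one & genes$end <= core_start] <- "variable_5prime"
  cls[one & genes$start >= core_end] <- "variable_3prime"
  # variable genes overlapping the core (possible with nested intervals):
  # side by gene midpoint relative to the core midpoint
  rem <- one & cls == "none"
  mid <- (genes$start + genes$end) / 2
  cls[rem] <- ifelse(mid[rem] < (core_start + core_end) / 2,
                     "variable_5prime", "variable_3prime")
  dplyr::mutate(genes, class = cls)
}

#' Spearman correlation of gene copy number and expression across cells
#'
#' For each gene, the inferred copy number is averaged over the 10 kb bins
#' covering the gene body per cell, and the Spearman correlation coefficient
#' with the gene's expression is computed across matched cells. Genes whose
#' copy (or expression) is constant across cells have an undefined
#' correlation and are flagged.
#'
#' @param expr numeric matrix, cells in rows (rownames = barcodes), genes in
#'   columns.
#' @param cnv_per_cell_10kb tibble `barcode`, `bin`, `inferred_copy` on a
#'   10 kb binning.
#' @param genes tibble `chrom`, `start`, `end`, `gene`.
#' @param genome the 10 kb `sc_genome`.
#' @return tibble `gene`, `scc`, `n_cells`, `constant` flag.
#' @export
copy_expression_correlation <- function(expr, cnv_per_cell_10kb, genes,
                                        genome) {
  gb <- genome_bins(genome)
  out <- lapply(seq_len(nrow(genes)), function(k) {
    gbins <- gb$bin[gb$chrom == genes$chrom[k] &
                      gb$end >= genes$start[k] & gb$start <= genes$end[k]]
    copies <- cnv_per_cell_10kb |>
      dplyr::filter(.data$bin %in% gbins) |>
      dplyr::group_by(.data$barcode) |>
      dplyr::summarise(copy = mean(.data$inferred_copy, na.rm = TRUE),
                       .groups = "drop")
    gene <- genes$gene[k]
    copies <- copies[is.finite(copies$copy), ]
    common <- intersect(copies$barcode, rownames(expr))
    if (length(common) < 3 || !gene %in% colnames(expr)) {
      return(tibble::tibble(gene = gene, scc = NA_real_,
                            n_cells = length(common), constant = NA))
    }
    e <- expr[common, gene]
    cp <- copies$copy[match(common, copies$barcode)]
    if (stats::sd(cp) == 0 || stats::sd(e) == 0) {
      return(tibble::tibble(gene = gene, scc = NA_real_,
                            n_cells = length(common), constant = TRUE))
    }
    tibble::tibble(
      gene = gene,
      scc = stats::cor(e, cp, method = "spearman"),
      n_cells = length(common), constant = FALSE
    )
  })
  dplyr::bind_rows(out)
}
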